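# Synthetic multielectrode-array recordings containing propagating spikes
# and dB/dt-induced stimulation artifacts; electrical images;
# transition-triggered artifact averages; artifact-axis regression;
# spatiotemporal spike/artifact classification; event-triggered stimulus
# averages.
#
# Units in this module: electrode positions in micrometers, time in
# seconds, waveforms in microvolts, fields in microtesla.

#' Planar electrode array layout
#'
#' Hexagonally packed electrode sites filling a rectangular region.
#' Defaults emulate a 512-electrode array covering 1890 um x 900 um.
#'
#' @param n_electrodes Number of sites (default 512).
#' @param width,height Array extent in micrometers.
#' @param sampling_rate Recording sample rate in Hz (default 20000; must
#'   exceed twice the band-pass upper edge).
#' @return Object of class `electrode_layout`: `positions` (n x 2, um),
#'   `width`, `height`, `sampling_rate`, `pitch`.
#' @export
electrode_array_layout <- function(n_electrodes = 512, width = 1890,
                                   height = 900, sampling_rate = 20000) {
  n_electrodes <- as.integer(n_electrodes)
  stopifnot(n_electrodes >= 1L, width > 0, height > 0, sampling_rate > 0)
  # choose a hexagonal pitch so the packing provides at least n sites
  pitch <- sqrt(width * height / n_electrodes / (sqrt(3) / 2))
  repeat {
    ncol_ <- floor(width / pitch) + 1L
    nrow_ <- floor(height / (pitch * sqrt(3) / 2)) + 1L
    if (ncol_ * nrow_ >= n_electrodes) break
    pitch <- pitch * 0.99
  }
  pos <- matrix(0, 0, 2)
  for (r in seq_len(nrow_) - 1L) {
    xoff <- if (r %% 2L == 1L) pitch / 2 else 0
    xs <- xoff + pitch * (seq_len(ncol_) - 1L)
    xs <- xs[xs <= width]
    pos <- rbind(pos, cbind(xs, r * pitch * sqrt(3) / 2))
  }
  pos <- pos[pos[, 2] <= height, , drop = FALSE]
  pos <- pos[seq_len(n_electrodes), , drop = FALSE]
  colnames(pos) <- c("x", "y")
  structure(list(positions = pos, width = width, height = height,
                 sampling_rate = sampling_rate, pitch = pitch),
            class = "electrode_layout")
}

# biphasic spike kernel: a dominant narrow lobe (peak 1 at t = 0) followed
# by an opposite shallow lobe twice as wide, weighted so the kernel
# integrates to zero exactly; t and tau in seconds
biphasic_kernel <- function(t, tau) {
  exp(-t^2 / (2 * tau^2)) -
    0.5 * exp(-(t - 2.5 * tau)^2 / (2 * (2 * tau)^2))
}

# smooth induction-artifact kernel: the derivative of a smooth (Gaussian)
# step, i.e. a Gaussian pulse, peak 1 at t = 0; width tau in seconds
artifact_kernel <- function(t, tau) {
  exp(-t^2 / (2 * tau^2))
}

#' Spike template of a single cell
#'
#' Spatiotemporal footprint of one cell's spike: a biphasic somatic
#' waveform whose amplitude decays with distance as
#' `1 / (1 + (d / lambda)^2)`, plus a delayed, attenuated axonal
#' contribution that propagates along a polyline at the conduction
#' velocity.
#'
#' @param soma Soma position (um, 2-vector).
#' @param amplitude Somatic peak amplitude (uV, > 0; applied
#'   negative-going).
#' @param lambda Spatial decay constant (um, default 30).
#' @param axon_path Polyline (k x 2 matrix, um) starting at the soma, or
#'   `NULL` for no axon.
#' @param velocity Conduction velocity (m/s, default 1).
#' @param tau Kernel time constant (s, default 2e-4).
#' @param axon_gain Axonal amplitude relative to the soma (default 0.4).
#' @return Object of class `spike_template`.
#' @export
spike_template <- function(soma, amplitude, lambda = 30, axon_path = NULL,
                           velocity = 1, tau = 2e-4, axon_gain = 0.4) {
  stopifnot(length(soma) == 2L, amplitude > 0, velocity > 0, lambda > 0,
            tau > 0)
  if (!is.null(axon_path)) {
    axon_path <- as.matrix(axon_path)
    stopifnot(ncol(axon_path) == 2L)
  }
  structure(list(soma = as.numeric(soma), amplitude = amplitude,
                 lambda = lambda, axon_path = axon_path,
                 velocity = velocity, tau = tau, axon_gain = axon_gain),
            class = "spike_template")
}

# per-electrode amplitude (uV, signed negative-going) and delay (s) of a
# template on a layout; axonal contribution uses the nearest point of a
# densely resampled polyline and its arc length for the delay
template_footprint <- function(template, layout) {
  pos <- layout$positions
  d_soma <- sqrt((pos[, 1] - template$soma[1])^2 +
                   (pos[, 2] - template$soma[2])^2)
  amp_soma <- -template$amplitude / (1 + (d_soma / template$lambda)^2)
  amp_axon <- rep(0, nrow(pos))
  delay_axon <- rep(0, nrow(pos))
  if (!is.null(template$axon_path) && nrow(template$axon_path) >= 2L) {
    # resample the polyline at ~15 um steps (delay resolution 15 us at
    # 1 m/s, below the 50 us sample period of a 20 kHz recording)
    p <- template$axon_path
    seg <- sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
    arc <- c(0, cumsum(seg))
    s <- seq(0, arc[length(arc)], by = 15)
    ax <- cbind(stats::approx(arc, p[, 1], s)$y, stats::approx(arc, p[, 2], s)$y)
    dmat <- outer(pos[, 1], ax[, 1], `-`)^2 + outer(pos[, 2], ax[, 2], `-`)^2
    j <- max.col(-dmat)
    d_ax <- sqrt(dmat[cbind(seq_len(nrow(pos)), j)])
    amp_axon <- -template$axon_gain * template$amplitude /
      (1 + (d_ax / template$lambda)^2)
    delay_axon <- s[j] * 1e-6 / template$velocity   # um -> m, then / (m/s)
  }
  list(amp_soma = amp_soma, amp_axon = amp_axon, delay_axon = delay_axon)
}

# electrodes x samples waveform matrix of one template at the layout's
# sampling rate; times relative to the somatic spike time
template_waveforms <- function(template, layout, t) {
  fp <- template_footprint(template, layout)
  M <- outer(fp$amp_soma, biphasic_kernel(t, template$tau))
  if (any(fp$amp_axon != 0)) {
    tm <- outer(-fp$delay_axon, t, `+`)   # t - delay per electrode
    M <- M + fp$amp_axon * biphasic_kernel(tm, template$tau)
  }
  M
}

#' Icosahedron stimulus directions
#'
#' The 12 vertices of a regular icosahedron, normalized to unit length, in
#' a fixed orientation (cyclic permutations of `(0, +/-1, +/-phi)` with
#' `phi` the golden ratio). The set is antipodally symmetric, and dot
#' products between distinct vertices take only the values `+/- 1/sqrt(5)`
#' and `-1`.
#'
#' @return Matrix (12 x 3) of unit vectors.
#' @export
icosahedron_directions <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    cbind(0, c(1, 1, -1, -1), c(phi, -phi, phi, -phi)),
    cbind(c(1, 1, -1, -1), c(phi, -phi, phi, -phi), 0),
    cbind(c(phi, -phi, phi, -phi), 0, c(1, 1, -1, -1))
  )
  v / sqrt(1 + phi^2)
}

#' Random icosahedral magnetic stimulus sequence
#'
#' A random sequence of switches between the 12 icosahedron field vectors
#' at a common magnitude, one new vector per segment, consecutive segments
#' always differing. Defaults follow the stimulation protocol: 50 uT
#' magnitude, 200 ms segments.
#'
#' @param n_segments Number of stimulus segments.
#' @param magnitude Field magnitude (uT, default 50).
#' @param segment_duration Segment length (s, default 0.2).
#' @param seed RNG seed.
#' @param vertex_index Optional explicit vertex sequence (integers 1..12,
#'   consecutive entries differing); overrides the random draw.
#' @return Object of class `mag_stimulus`: `directions` (12 x 3),
#'   `magnitude`, `segment_duration`, `vertex_index` (per segment),
#'   `transitions` data.frame (`time`, `from`, `to`, `dB1..3` in uT) and
#'   `duration`.
#' @export
mag_stimulus_sequence <- function(n_segments, magnitude = 50,
                                  segment_duration = 0.2, seed = 20220722,
                                  vertex_index = NULL) {
  dirs <- icosahedron_directions()
  if (is.null(vertex_index)) {
    stopifnot(n_segments >= 2L, magnitude > 0, segment_duration > 0)
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    set.seed(seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    idx <- integer(n_segments)
    idx[1] <- sample.int(12L, 1L)
    for (k in 2:n_segments) {
      idx[k] <- sample(setdiff(1:12, idx[k - 1]), 1L)
    }
  } else {
    idx <- as.integer(vertex_index)
    n_segments <- length(idx)
    stopifnot(n_segments >= 2L, all(idx >= 1L), all(idx <= 12L),
              all(diff(idx) != 0L))
  }
  k <- 2:n_segments
  dB <- (dirs[idx[k], , drop = FALSE] - dirs[idx[k - 1], , drop = FALSE]) *
    magnitude
  transitions <- data.frame(time = (k - 1) * segment_duration,
                            from = idx[k - 1], to = idx[k],
                            dB1 = dB[, 1], dB2 = dB[, 2], dB3 = dB[, 3])
  structure(list(directions = dirs, magnitude = magnitude,
                 segment_duration = segment_duration,
                 vertex_index = idx, transitions = transitions,
                 duration = n_segments * segment_duration, seed = seed),
            class = "mag_stimulus")
}

# zero-phase band-pass of an electrodes x samples matrix
bandpass_traces <- function(traces, fs, band) {
  if (is.null(band)) return(traces)
  stopifnot(length(band) == 2L, band[1] > 0, band[2] > band[1])
  if (fs <= 2 * band[2]) {
    stop("sampling rate must exceed twice the band-pass upper edge",
         call. = FALSE)
  }
  bf <- signal::butter(2, band / (fs / 2), type = "pass")
  for (e in seq_len(nrow(traces))) {
    traces[e, ] <- signal::filtfilt(bf, traces[e, ])
  }
  traces
}

#' Simulate a multielectrode recording with spikes and induction artifacts
#'
#' Builds synthetic array traces: each cell fires at Poisson times and
#' contributes its spatiotemporal template; each magnetic field transition
#' adds an induction-artifact pulse simultaneously on all electrodes with
#' peak amplitude `(coupling . dB) * electrode_scale`, proportional to the
#' field step (a dB/dt artifact band-limited by the recording chain);
#' Gaussian noise is added and the result is band-pass filtered with a
#' zero-phase (forward-backward) Butterworth filter.
#'
#' @param layout An [electrode_array_layout()].
#' @param cells List of `list(template = spike_template, rate = Hz)`; may
#'   be empty.
#' @param stimulus A [mag_stimulus_sequence()], or `NULL` for no magnetic
#'   stimulation.
#' @param coupling Induction coupling vector (uV per uT of field step).
#' @param electrode_scale Per-electrode artifact scale (scalar or length-n
#'   vector, default 1: routing-independent pickup).
#' @param noise_std Gaussian noise (uV) before filtering.
#' @param bandpass Band edges in Hz (default `c(80, 2000)`), or `NULL` to
#'   skip filtering.
#' @param artifact_tau Artifact kernel width (s, default 3e-4).
#' @param duration Recording length (s); default from the stimulus.
#' @param seed RNG seed.
#' @return Object of class `mea_recording`: `traces` (electrodes x
#'   samples, uV), `layout`, `sampling_rate`, `spike_times` (list per
#'   cell), `stimulus`, `cells`, `coupling`.
#' @export
simulate_recording <- function(layout, cells = list(), stimulus = NULL,
                               coupling = c(0, 0, 0), electrode_scale = 1,
                               noise_std = 10, bandpass = c(80, 2000),
                               artifact_tau = 3e-4, duration = NULL,
                               seed = 20220722) {
  stopifnot(inherits(layout, "electrode_layout"))
  fs <- layout$sampling_rate
  if (!is.null(bandpass) && fs <= 2 * bandpass[2]) {
    stop("sampling rate must exceed twice the band-pass upper edge",
         call. = FALSE)
  }
  if (is.null(duration)) {
    if (is.null(stimulus)) stop("give 'duration' or a stimulus", call. = FALSE)
    duration <- stimulus$duration
  }
  n_e <- nrow(layout$positions)
  n_s <- round(duration * fs)
  if (n_e * n_s > 5e8) stop("recording too large", call. = FALSE)
  scale_e <- rep_len(electrode_scale, n_e)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  traces <- if (noise_std > 0) {
    matrix(stats::rnorm(n_e * n_s, 0, noise_std), n_e, n_s)
  } else {
    matrix(0, n_e, n_s)
  }
  # spikes
  half <- 0.002
  tker <- seq(-half, half, by = 1 / fs)
  spike_times <- vector("list", length(cells))
  for (ci in seq_along(cells)) {
    cell <- cells[[ci]]
    n_spk <- stats::rpois(1, cell$rate * duration)
    if (n_spk * n_e > 5e8) stop("firing rate too high", call. = FALSE)
    tt <- sort(stats::runif(n_spk, half, duration - half))
    spike_times[[ci]] <- tt
    if (n_spk == 0) next
    M <- template_waveforms(cell$template, layout, tker)
    for (t0 in tt) {
      k0 <- round(t0 * fs)
      cols <- k0 + seq_along(tker) - which.min(abs(tker))
      ok <- cols >= 1 & cols <= n_s
      traces[, cols[ok]] <- traces[, cols[ok]] + M[, ok]
    }
  }
  # induction artifacts at field transitions
  if (!is.null(stimulus) && any(coupling != 0)) {
    ahalf <- 6 * artifact_tau
    ta <- seq(-ahalf, ahalf, by = 1 / fs)
    ker <- artifact_kernel(ta, artifact_tau)
    dB <- as.matrix(stimulus$transitions[, c("dB1", "dB2", "dB3")])
    amp <- drop(dB %*% coupling)       # uV per transition
    for (i in seq_len(nrow(dB))) {
      k0 <- round(stimulus$transitions$time[i] * fs)
      cols <- k0 + seq_along(ta) - which.min(abs(ta))
      ok <- cols >= 1 & cols <= n_s
      traces[, cols[ok]] <- traces[, cols[ok]] +
        outer(scale_e * amp[i], ker[ok])
    }
  }
  traces <- bandpass_traces(traces, fs, bandpass)
  structure(list(traces = traces, layout = layout, sampling_rate = fs,
                 spike_times = spike_times, stimulus = stimulus,
                 cells = cells, coupling = coupling, seed = seed),
            class = "mea_recording")
}

#' Electrical image of an event class
#'
#' The average spatiotemporal waveform across the array in a peri-event
#' window, plus per-electrode peak statistics (signed peak amplitude and
#' peak latency). Events too close to the trace edges are dropped and
#' counted.
#'
#' @param recording An [simulate_recording()] result, or a plain
#'   electrodes x samples matrix (then give `sampling_rate`).
#' @param event_times Event times (s), >= 1 after edge dropping.
#' @param window Window around the event in ms, `c(before, after)` with
#'   `before < after`.
#' @param sampling_rate Required when `recording` is a plain matrix.
#' @return Object of class `electrical_image`: `waveforms` (electrodes x
#'   samples, uV), `time_ms`, `peak_amplitude` (signed, uV),
#'   `peak_latency_ms`, `n_events`, `n_dropped`.
#' @export
electrical_image <- function(recording, event_times, window = c(-1, 2),
                             sampling_rate = NULL) {
  if (inherits(recording, "mea_recording")) {
    traces <- recording$traces
    fs <- recording$sampling_rate
  } else {
    traces <- as.matrix(recording)
    fs <- sampling_rate
    if (is.null(fs)) stop("give 'sampling_rate' for matrix input", call. = FALSE)
  }
  stopifnot(length(window) == 2L, window[1] < window[2])
  k_lo <- round(window[1] * 1e-3 * fs)
  k_hi <- round(window[2] * 1e-3 * fs)
  n_s <- ncol(traces)
  k0 <- round(event_times * fs)
  ok <- (k0 + k_lo) >= 1 & (k0 + k_hi) <= n_s
  dropped <- sum(!ok)
  k0 <- k0[ok]
  if (length(k0) == 0L) stop("no events within the trace bounds", call. = FALSE)
  rel <- k_lo:k_hi
  acc <- matrix(0, nrow(traces), length(rel))
  for (k in k0) acc <- acc + traces[, k + rel, drop = FALSE]
  wave <- acc / length(k0)
  aw <- abs(wave)
  pk <- max.col(aw, ties.method = "first")
  idx <- cbind(seq_len(nrow(wave)), pk)
  structure(list(waveforms = wave, time_ms = rel / fs * 1e3,
                 peak_amplitude = wave[idx],
                 peak_latency_ms = rel[pk] / fs * 1e3,
                 n_events = length(k0), n_dropped = dropped),
            class = "electrical_image")
}

#' Transition-triggered artifact images
#'
#' One [electrical_image()] per observed ordered stimulus transition
#' `(from, to)`; classes without observed transitions are omitted.
#'
#' @param recording An [simulate_recording()] result with a stimulus.
#' @param window Peri-transition window in ms.
#' @return Named list (names `"from->to"`) of entries
#'   `list(from, to, dB, n, image)`.
#' @export
transition_triggered_images <- function(recording, window = c(-2, 4)) {
  stopifnot(inherits(recording, "mea_recording"))
  tr <- recording$stimulus$transitions
  if (is.null(tr)) stop("recording has no stimulus transition log", call. = FALSE)
  key <- paste0(tr$from, "->", tr$to)
  out <- list()
  for (k in unique(key)) {
    sel <- key == k
    img <- electrical_image(recording, tr$time[sel], window)
    out[[k]] <- list(from = tr$from[sel][1], to = tr$to[sel][1],
                     dB = c(tr$dB1[sel][1], tr$dB2[sel][1], tr$dB3[sel][1]),
                     n = sum(sel), image = img)
  }
  out
}

#' Fit the induction-artifact axis
#'
#' Least-squares fit of the signed artifact peak amplitude against the
#' three components of the field step `dB` across transition classes
#' (regression through the origin: a zero field step induces nothing).
#' The amplitude of each class is read at a common reference electrode and
#' a common peak sample, so in the noise-free model the fit is exact.
#'
#' @param ttimages Result of [transition_triggered_images()].
#' @return List with `axis` (unit 3-vector), `coefficients` (uV/uT),
#'   `r_squared`, `reference_electrode`.
#' @export
fit_artifact_axis <- function(ttimages) {
  if (length(ttimages) < 4L) {
    stop("need at least 4 transition classes", call. = FALSE)
  }
  dB <- t(vapply(ttimages, function(x) x$dB, numeric(3)))
  if (qr(dB)$rank < 3L) {
    stop("field steps are rank deficient; cannot identify a 3-d axis",
         call. = FALSE)
  }
  # reference electrode: largest total peak energy across classes
  pk <- vapply(ttimages, function(x) abs(x$image$peak_amplitude),
               numeric(nrow(ttimages[[1]]$image$waveforms)))
  ref <- which.max(rowSums(pk^2))
  # common peak sample on the reference electrode
  pooled <- rowSums(vapply(ttimages,
                           function(x) abs(x$image$waveforms[ref, ]),
                           numeric(ncol(ttimages[[1]]$image$waveforms))))
  # vapply above returns samples x classes; pooled is per sample
  s0 <- which.max(pooled)
  amp <- vapply(ttimages, function(x) x$image$waveforms[ref, s0], numeric(1))
  fit <- stats::lm.fit(dB, amp)
  coefs <- unname(fit$coefficients)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum(amp^2)
  list(axis = coefs / vec_norm(coefs),
       coefficients = coefs,
       r_squared = 1 - ss_res / ss_tot,
       reference_electrode = ref)
}

#' Classify an electrical image as spike or artifact
#'
#' Spatiotemporal separation statistic: biological spikes appear on few
#' electrodes with latencies spreading along the axon, while induction
#' artifacts appear over large areas identically and simultaneously. The
#' spread index is the fraction of electrodes whose peak exceeds
#' `rel_threshold` of the maximum; the latency dispersion is the standard
#' deviation (ms) of peak latencies over those electrodes. An image is
#' labeled `"artifact"` if the spread exceeds `spread_threshold` and the
#' dispersion stays below `dispersion_threshold`, else `"spike"`.
#'
#' @param image An [electrical_image()].
#' @param spread_threshold Default 0.5.
#' @param dispersion_threshold Default 0.2 ms.
#' @param rel_threshold Supra-threshold level relative to the maximum peak
#'   (default 0.3).
#' @return List with `label` (`"spike"`/`"artifact"`/`"unclassifiable"`),
#'   `spread_index`, `latency_dispersion_ms`, `n_supra`.
#' @export
classify_event <- function(image, spread_threshold = 0.5,
                           dispersion_threshold = 0.2,
                           rel_threshold = 0.3) {
  stopifnot(inherits(image, "electrical_image"))
  peaks <- abs(image$peak_amplitude)
  mx <- max(peaks)
  if (!is.finite(mx) || mx == 0) {
    return(list(label = "unclassifiable", spread_index = NA_real_,
                latency_dispersion_ms = NA_real_, n_supra = 0L))
  }
  supra <- peaks > rel_threshold * mx
  spread <- mean(supra)
  # the dispersion statistic needs >= 2 supra-threshold electrodes; a
  # single-electrode event cannot exhibit the array-wide simultaneity of
  # an artifact and is labeled spike (the single-electrode ambiguity)
  disp <- if (sum(supra) >= 2L) {
    stats::sd(image$peak_latency_ms[supra])
  } else {
    NA_real_
  }
  label <- if (spread > spread_threshold && !is.na(disp) &&
               disp < dispersion_threshold) {
    "artifact"
  } else {
    "spike"
  }
  list(label = label, spread_index = spread, latency_dispersion_ms = disp,
       n_supra = sum(supra))
}

#' Random spike template on a layout
#'
#' Draws a plausible ganglion-cell template: a soma over the recorded
#' lattice (a random electrode plus a sub-pitch offset, so every cell is
#' actually sampled by the array, as a sorted cell would be), log-uniform
#' somatic amplitude, a straight axon in a random direction, and slight
#' conduction-velocity jitter. Uses the current RNG state.
#'
#' @param layout An [electrode_array_layout()].
#' @param amplitude_range Somatic amplitude range (uV).
#' @param axon_length_range Axon length range (um).
#' @return A [spike_template()].
#' @export
random_spike_template <- function(layout, amplitude_range = c(80, 300),
                                  axon_length_range = c(300, 1200)) {
  e <- sample.int(nrow(layout$positions), 1L)
  soma <- layout$positions[e, ] +
    stats::runif(2, -layout$pitch / 2, layout$pitch / 2)
  amp <- exp(stats::runif(1, log(amplitude_range[1]), log(amplitude_range[2])))
  len <- stats::runif(1, axon_length_range[1], axon_length_range[2])
  ang <- stats::runif(1, 0, 2 * pi)
  axon <- rbind(soma, soma + len * c(cos(ang), sin(ang)))
  spike_template(soma, amp, axon_path = axon,
                 velocity = stats::runif(1, 0.8, 1.2))
}

#' Default spike/artifact classification scenario
#'
#' Generates the benchmark population of event-class images: spike-like
#' images from random cell templates and artifact-like images from
#' simultaneous array-wide pulses, each with averaging noise, emulating
#' images computed from many events. Population sizes default to 367
#' spike classes and 144 artifact classes. Separation of the two
#' populations in (spread, dispersion) space is by construction.
#'
#' @param n_spike,n_artifact Population sizes.
#' @param layout An [electrode_array_layout()].
#' @param image_noise_std Residual noise in the averaged images (uV).
#' @param artifact_amplitude_range Artifact peak range (uV).
#' @param seed RNG seed.
#' @return List with `images` (list of [electrical_image()]-like objects),
#'   `labels` (character vector `"spike"`/`"artifact"`).
#' @export
classification_scenario <- function(n_spike = 367, n_artifact = 144,
                                    layout = electrode_array_layout(),
                                    image_noise_std = 2,
                                    artifact_amplitude_range = c(50, 200),
                                    seed = 20220722) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  fs <- layout$sampling_rate
  t <- seq(-1e-3, 1e-3, by = 1 / fs)
  n_e <- nrow(layout$positions)
  atau <- 3e-4
  make_image <- function(wave) {
    wave <- wave + matrix(stats::rnorm(length(wave), 0, image_noise_std),
                          nrow(wave))
    aw <- abs(wave)
    pk <- max.col(aw, ties.method = "first")
    idx <- cbind(seq_len(nrow(wave)), pk)
    structure(list(waveforms = wave, time_ms = t * 1e3,
                   peak_amplitude = wave[idx],
                   peak_latency_ms = t[pk] * 1e3,
                   n_events = NA_integer_, n_dropped = 0L),
              class = "electrical_image")
  }
  images <- vector("list", n_spike + n_artifact)
  for (i in seq_len(n_spike)) {
    tpl <- random_spike_template(layout)
    images[[i]] <- make_image(template_waveforms(tpl, layout, t))
  }
  ker <- artifact_kernel(t, atau)
  for (i in seq_len(n_artifact)) {
    amp <- stats::runif(1, artifact_amplitude_range[1],
                        artifact_amplitude_range[2]) *
      sample(c(-1, 1), 1)
    images[[n_spike + i]] <- make_image(outer(rep(amp, n_e), ker))
  }
  list(images = images,
       labels = c(rep("spike", n_spike), rep("artifact", n_artifact)))
}

#' Area under the ROC curve
#'
#' Mann-Whitney AUC of a score that should be larger for the positive
#' class.
#'
#' @param scores Numeric scores.
#' @param positive Logical, `TRUE` for the positive class.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, positive) {
  stopifnot(length(scores) == length(positive), any(positive), any(!positive))
  r <- rank(scores)
  n_pos <- sum(positive)
  n_neg <- sum(!positive)
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Event-triggered stimulus average
#'
#' Mean stimulus value at a set of lags before each event, for a
#' frame-based stimulus updating at a fixed rate (e.g. binary visual noise
#' at 120 Hz). For events uncorrelated with the stimulus the average is
#' flat at the stimulus mean; for a visually driven cell it recovers the
#' temporal integration kernel.
#'
#' @param event_times Event times (s); events whose full lag range is not
#'   covered by the frame log are dropped.
#' @param frames Stimulus frame values: vector (single pixel) or matrix
#'   (frames x pixels).
#' @param frame_rate Frames per second (default 120).
#' @param n_lags Number of frame lags before the event (default 30).
#' @return `data.frame` with `lag_s` (<= 0) and `average` (one column per
#'   pixel).
#' @export
triggered_stimulus_average <- function(event_times, frames,
                                       frame_rate = 120, n_lags = 30) {
  if (length(event_times) == 0L) stop("no events given", call. = FALSE)
  frames <- if (is.matrix(frames)) frames else matrix(frames, ncol = 1)
  n_f <- nrow(frames)
  lag_s <- -(seq_len(n_lags) - 1L) / frame_rate
  acc <- matrix(0, n_lags, ncol(frames))
  used <- 0L
  for (t0 in event_times) {
    idx <- floor((t0 + lag_s) * frame_rate) + 1L
    if (any(idx < 1L) || any(idx > n_f)) next
    acc <- acc + frames[idx, , drop = FALSE]
    used <- used + 1L
  }
  if (used == 0L) stop("no events covered by the frame log", call. = FALSE)
  out <- data.frame(lag_s = lag_s)
  out <- cbind(out, as.data.frame(acc / used))
  names(out)[-1] <- paste0("average", seq_len(ncol(acc)))
  attr(out, "n_events") <- used
  out
}
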