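# multielectrode artifact lab: synthetic recordings, electrical images,
# artifact-axis regression, spike/artifact separation

small_layout <- function(n = 32, fs = 20000) {
  electrode_array_layout(n, width = 400, height = 200, sampling_rate = fs)
}

test_that("icosahedron directions have the exact vertex geometry", {
  v <- icosahedron_directions()
  expect_equal(nrow(v), 12)
  expect_equal(sqrt(rowSums(v^2)), rep(1, 12), tolerance = 1e-12)
  dots <- tcrossprod(v)
  off <- dots[row(dots) != col(dots)]
  ok <- abs(off - 1 / sqrt(5)) < 1e-9 | abs(off + 1 / sqrt(5)) < 1e-9 |
    abs(off + 1) < 1e-9
  expect_true(all(ok))
  # antipodal symmetry
  for (i in 1:12) {
    expect_true(any(sqrt(rowSums(sweep(v, 2, -v[i, ])^2)) < 1e-9))
  }
})

test_that("stimulus sequences avoid self-transitions and are reproducible", {
  st <- mag_stimulus_sequence(100, seed = 5)
  expect_true(all(diff(st$vertex_index) != 0))
  expect_identical(st$vertex_index,
                   mag_stimulus_sequence(100, seed = 5)$vertex_index)
  # field steps take only the three icosahedral chord lengths
  dB <- sqrt(st$transitions$dB1^2 + st$transitions$dB2^2 +
               st$transitions$dB3^2)
  chords <- 50 * sqrt(c(2 - 2 / sqrt(5), 2 + 2 / sqrt(5), 4))
  expect_true(all(vapply(dB, function(x) any(abs(x - chords) < 1e-9),
                         logical(1))))
  expect_equal(max(dB), 100, tolerance = 1e-9)
})

test_that("electrode layouts fill the rectangle", {
  lay <- electrode_array_layout()
  expect_equal(nrow(lay$positions), 512)
  expect_true(all(lay$positions[, 1] >= 0 & lay$positions[, 1] <= 1890))
  expect_true(all(lay$positions[, 2] >= 0 & lay$positions[, 2] <= 900))
})

test_that("zero coupling leaves only spikes and noise", {
  lay <- small_layout()
  stim <- two_way_stimulus()
  rec <- simulate_recording(lay, list(), stim, coupling = c(0, 0, 0),
                            noise_std = 5, seed = 2)
  tti <- transition_triggered_images(rec, window = c(-1, 2))
  peaks <- vapply(tti, function(x) max(abs(x$image$peak_amplitude)),
                  numeric(1))
  expect_lt(max(peaks), 5 * 4)   # noise floor, no artifact structure
})

test_that("artifact peaks scale linearly with the field step projection", {
  lay <- small_layout(16)
  stim <- mag_stimulus_sequence(80, segment_duration = 0.05, seed = 9)
  cpl <- c(-0.74, 0.67, 0.07) * 2
  rec <- simulate_recording(lay, list(), stim, coupling = cpl,
                            noise_std = 0, bandpass = NULL, seed = 2)
  tti <- transition_triggered_images(rec, window = c(-1, 2))
  proj <- vapply(tti, function(x) sum(x$dB * cpl), numeric(1))
  amp <- vapply(tti, function(x) x$image$waveforms[1, which.min(abs(x$image$time_ms))],
                numeric(1))
  fit <- lm(amp ~ proj)
  expect_equal(coef(fit)[["proj"]], 1, tolerance = 1e-9)
  expect_lt(max(abs(residuals(fit))), 1e-9)
})

test_that("spike latency increases along the axon at the set velocity", {
  # toy 3-electrode layout along the axon of a single cell
  lay <- structure(list(positions = cbind(c(10, 210, 410), c(10, 10, 10)),
                        width = 420, height = 20, sampling_rate = 20000,
                        pitch = 200), class = "electrode_layout")
  tpl <- spike_template(c(10, 10), 200,
                        axon_path = rbind(c(10, 10), c(410, 10)),
                        velocity = 1)
  tr <- matrix(0, 3, 2000)
  t <- seq(-1e-3, 2e-3, by = 1 / 20000)
  M <- magstimkit:::template_waveforms(tpl, lay, t)
  tr[, 1000 + seq_along(t) - which.min(abs(t))] <- M
  img <- electrical_image(tr, 1000 / 20000, window = c(-1, 2),
                          sampling_rate = 20000)
  lat <- img$peak_latency_ms
  # 200 um at 1 m/s = 0.2 ms between successive electrodes
  expect_equal(lat[2] - lat[1], 0.2, tolerance = 0.06)
  expect_equal(lat[3] - lat[2], 0.2, tolerance = 0.06)
})

test_that("a single noiseless spike reproduces its template exactly", {
  lay <- small_layout()
  tpl <- spike_template(c(100, 100), 150,
                        axon_path = rbind(c(100, 100), c(380, 180)))
  fs <- lay$sampling_rate
  t <- seq(-1e-3, 2e-3, by = 1 / fs)
  M <- magstimkit:::template_waveforms(tpl, lay, t)
  tr <- matrix(0, nrow(lay$positions), 4000)
  k0 <- 2000
  tr[, k0 + seq_along(t) - which.min(abs(t))] <- M
  img <- electrical_image(tr, k0 / fs, window = c(-1, 2), sampling_rate = fs)
  expect_equal(img$waveforms, M, tolerance = 1e-12)
  expect_equal(img$n_events, 1)
})

test_that("averaging N repeats shrinks image noise like 1/sqrt(N)", {
  fs <- 20000
  set.seed(7)
  tr <- matrix(rnorm(8 * 120000, 0, 10), 8, 120000)
  noise_at <- function(N) {
    ev <- (seq_len(N)) * 0.08
    img <- electrical_image(tr, ev, window = c(-1, 2), sampling_rate = fs)
    stopifnot(img$n_events == N)
    sd(img$waveforms)
  }
  s4 <- noise_at(4); s16 <- noise_at(16); s64 <- noise_at(64)
  expect_equal(s4 / s16, 2, tolerance = 0.35)
  expect_equal(s16 / s64, 2, tolerance = 0.35)
})

test_that("events at the trace edge are dropped and counted", {
  tr <- matrix(0, 4, 1000)
  img <- electrical_image(tr, c(0.001, 0.025), window = c(-10, 10),
                          sampling_rate = 20000)
  expect_equal(img$n_events, 1)
  expect_equal(img$n_dropped, 1)
  expect_error(electrical_image(tr, 0.0001, window = c(-40, 40),
                                sampling_rate = 20000), "bounds")
})

test_that("artifact images are simultaneous and antisymmetric under reversal", {
  lay <- small_layout(16)
  stim <- two_way_stimulus()
  cpl <- c(-0.74, 0.67, 0.07) * 2
  rec <- simulate_recording(lay, list(), stim, coupling = cpl,
                            noise_std = 0, bandpass = NULL, seed = 4)
  tti <- transition_triggered_images(rec, window = c(-1, 2))
  # simultaneity: zero latency dispersion before noise
  img <- tti[["1->7"]]$image
  expect_lt(sd(img$peak_latency_ms), 1e-12)
  # self-consistent polarity reversal, exact in the noise-free model
  expect_equal(tti[["1->7"]]$image$waveforms,
               -tti[["7->1"]]$image$waveforms, tolerance = 1e-12)
})

test_that("artifact axis is exact without noise and close with noise", {
  lay <- small_layout(16)
  cpl_dir <- c(-0.74, 0.67, 0.07) / sqrt(sum(c(-0.74, 0.67, 0.07)^2))
  # noise-free: exact recovery, R^2 = 1
  stim <- mag_stimulus_sequence(60, segment_duration = 0.05, seed = 13)
  rec0 <- simulate_recording(lay, list(), stim, coupling = c(0, 0, 1),
                             noise_std = 0, bandpass = NULL, seed = 5)
  fa0 <- fit_artifact_axis(transition_triggered_images(rec0, c(-1, 2)))
  expect_equal(abs(fa0$axis), c(0, 0, 1), tolerance = 1e-9)
  expect_equal(fa0$r_squared, 1, tolerance = 1e-12)
  # noisy: planted axis recovered within 2 degrees, R^2 >= 0.99
  stim2 <- mag_stimulus_sequence(400, segment_duration = 0.05, seed = 15)
  rec <- simulate_recording(lay, list(), stim2, coupling = cpl_dir * 3,
                            noise_std = 5, seed = 6)
  fa <- fit_artifact_axis(transition_triggered_images(rec, c(-1, 2)))
  expect_lt(axis_angle_deg(fa$axis, cpl_dir), 2)
  expect_gte(fa$r_squared, 0.99)
  # more transitions per class tighten the estimate (averaged over seeds
  # to damp Monte-Carlo fluctuation)
  angle_at <- function(n_seg, seeds) {
    mean(vapply(seeds, function(sd) {
      stim_k <- mag_stimulus_sequence(n_seg, segment_duration = 0.05,
                                      seed = 15 + sd)
      rec_k <- simulate_recording(lay, list(), stim_k,
                                  coupling = cpl_dir * 0.6,
                                  noise_std = 15, seed = 6 + sd)
      fa_k <- fit_artifact_axis(transition_triggered_images(rec_k, c(-1, 2)))
      axis_angle_deg(fa_k$axis, cpl_dir)
    }, numeric(1)))
  }
  expect_gt(angle_at(40, 1:3), angle_at(400, 1:3))
})

test_that("band-pass filtering is zero-phase", {
  lay <- small_layout()
  tpl <- spike_template(c(100, 100), 150)
  fs <- lay$sampling_rate
  t <- seq(-1e-3, 2e-3, by = 1 / fs)
  M <- magstimkit:::template_waveforms(tpl, lay, t)
  tr <- matrix(0, nrow(lay$positions), 4000)
  tr[, 2000 + seq_along(t) - which.min(abs(t))] <- M
  trf <- magstimkit:::bandpass_traces(tr, fs, c(80, 2000))
  img <- electrical_image(tr, 0.1, window = c(-1, 2), sampling_rate = fs)
  imgf <- electrical_image(trf, 0.1, window = c(-1, 2), sampling_rate = fs)
  big <- abs(img$peak_amplitude) > 30
  expect_lte(max(abs(img$peak_latency_ms[big] - imgf$peak_latency_ms[big])),
             1e3 / fs + 1e-9)
})

test_that("spread and dispersion separate spikes from artifacts", {
  lay <- small_layout()
  n_e <- nrow(lay$positions)
  t <- seq(-1e-3, 1e-3, by = 1 / lay$sampling_rate)
  ker <- magstimkit:::artifact_kernel(t, 3e-4)
  mk_img <- function(wave) {
    aw <- abs(wave)
    pk <- max.col(aw, ties.method = "first")
    idx <- cbind(seq_len(nrow(wave)), pk)
    structure(list(waveforms = wave, time_ms = t * 1e3,
                   peak_amplitude = wave[idx],
                   peak_latency_ms = t[pk] * 1e3,
                   n_events = 1L, n_dropped = 0L),
              class = "electrical_image")
  }
  # uniform simultaneous artifact: spread exactly 1, labeled artifact
  art <- mk_img(outer(rep(100, n_e), ker))
  ca <- classify_event(art)
  expect_equal(ca$spread_index, 1)
  expect_identical(ca$label, "artifact")
  # artifact restricted to one electrode resembles a spike
  single <- outer(c(100, rep(0, n_e - 1)), ker)
  cs <- classify_event(mk_img(single))
  expect_identical(cs$label, "spike")
})

test_that("the default scenario separates perfectly", {
  sc <- classification_scenario(seed = 101)
  res <- lapply(sc$images, classify_event)
  labs <- vapply(res, `[[`, "", "label")
  expect_identical(labs, sc$labels)
  spread <- vapply(res, `[[`, 1, "spread_index")
  expect_equal(roc_auc(spread, sc$labels == "artifact"), 1)
})

test_that("triggered stimulus averages expose visual correlation", {
  set.seed(51)
  frames <- sample(c(-1, 1), 4000, replace = TRUE)
  dur <- 4000 / 120
  # artifact-like events independent of the stimulus: flat average
  ev <- runif(400, 1, dur - 1)
  sta <- triggered_stimulus_average(ev, frames)
  expect_lt(max(abs(sta$average1)), 4 / sqrt(attr(sta, "n_events")))
  # an ON cell firing after bright frames recovers its kernel
  frame_t <- (seq_along(frames) - 1) / 120
  lag1 <- 2   # fires ~2 frames after a bright frame
  bright <- which(frames > 0)
  ev_on <- (bright[bright < 3900] + lag1 - 1) / 120 + 0.001
  sta_on <- triggered_stimulus_average(ev_on, frames)
  expect_gt(sta_on$average1[lag1 + 1], 0.9)
  mean_rest <- mean(abs(sta_on$average1[-(lag1 + 1)]))
  expect_lt(mean_rest, 0.2)
  expect_error(triggered_stimulus_average(numeric(0), frames), "no events")
})
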