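# Behavioral model of the voltage-controlled coil current source: static
# transfer, power budget, second-order closed-loop dynamics with a slew-rate
# ceiling, and double-wrapped sham blanking.

#' Coil driver model
#'
#' Behavioral parameters of the constant-current coil driver. The static
#' transfer is `I = divider * U_control / R_shunt`, clipped to the current
#' limit and to the voltage compliance `(supply - dropout) / coil_R`. The
#' closed loop is modeled as a canonical second-order system with damping
#' ratio `zeta` (the frequency-compensation knob) and natural frequency
#' `omega_n`, with the physical slew ceiling `di/dt <= (supply - dropout) /
#' coil_L`. Defaults give ~15 % overshoot and a 2 %-band settling time of
#' 400 microseconds.
#'
#' @param R_shunt Current-sense shunt (ohm, > 0).
#' @param control_divider Input divider gain (0 < g <= 1).
#' @param supply Supply voltage magnitude (V, symmetric rails).
#' @param dropout Output-stage dropout (V, default 4).
#' @param current_limit Continuous output current limit (A, default 3).
#' @param coil_R,coil_L Coil resistance (ohm) and inductance (H); defaults
#'   are the x-axis pair of the reference system (10.1 ohm, 1.05 mH).
#' @param zeta Damping ratio (> 0, default 0.517).
#' @param omega_n Natural frequency (rad/s; default tuned for 400 us
#'   settling at the default `zeta`: `omega_n = 4 / (zeta * 4e-4)`).
#' @return Object of class `driver_model`.
#' @export
driver_model <- function(R_shunt = 1, control_divider = 1, supply = 15,
                         dropout = 4, current_limit = 3,
                         coil_R = 10.1, coil_L = 1.05e-3,
                         zeta = 0.517, omega_n = NULL) {
  if (R_shunt <= 0 || coil_R <= 0 || coil_L <= 0) {
    stop("resistances and inductances must be > 0", call. = FALSE)
  }
  if (control_divider <= 0 || control_divider > 1) {
    stop("'control_divider' must be in (0, 1]", call. = FALSE)
  }
  if (zeta <= 0) stop("'zeta' must be > 0", call. = FALSE)
  if (supply <= dropout) stop("'supply' must exceed 'dropout'", call. = FALSE)
  if (is.null(omega_n)) omega_n <- 4 / (zeta * 4e-4)
  structure(list(R_shunt = R_shunt, control_divider = control_divider,
                 supply = supply, dropout = dropout,
                 current_limit = current_limit,
                 coil_R = coil_R, coil_L = coil_L,
                 zeta = zeta, omega_n = omega_n),
            class = "driver_model")
}

compliance_current <- function(model) {
  (model$supply - model$dropout) / model$coil_R
}

#' Static current transfer
#'
#' `I = control_divider * U_control / R_shunt`, clipped to the current
#' limit and to the voltage compliance of the output stage. Clipping sets
#' the `"saturated"` attribute instead of raising an error.
#'
#' @param model A [driver_model()].
#' @param U_control Control voltage (V); vectorized.
#' @return Coil current (A) with logical attribute `saturated`.
#' @export
static_current <- function(model, U_control) {
  I <- model$control_divider * U_control / model$R_shunt
  lim <- min(model$current_limit, compliance_current(model))
  sat <- abs(I) > lim
  I[sat] <- sign(I[sat]) * lim
  attr(I, "saturated") <- sat
  I
}

#' Minimum supply voltage for a target current
#'
#' The supply must cover the Ohmic coil voltage plus the output-stage
#' dropout: `I_max * coil_R + dropout`.
#'
#' @param I_max Maximum coil current (A, > 0).
#' @param coil_R Coil resistance (ohm, > 0).
#' @param dropout Dropout voltage (V, >= 0; default 4).
#' @return Minimum supply voltage (V).
#' @export
min_supply_voltage <- function(I_max, coil_R, dropout = 4) {
  if (I_max < 0 || coil_R <= 0 || dropout < 0) {
    stop("inputs must be positive", call. = FALSE)
  }
  I_max * coil_R + dropout
}

#' Amplifier power dissipation
#'
#' Steady-state thermal dissipation of the output stage:
#' `P = (supply - |coil_voltage|) * |I|`.
#'
#' @param supply Supply voltage (V).
#' @param coil_voltage Voltage across the coil (V, |.| <= supply).
#' @param I Coil current (A).
#' @return Dissipated power (W).
#' @export
power_dissipation <- function(supply, coil_voltage, I) {
  if (any(abs(coil_voltage) > supply)) {
    stop("|coil_voltage| must not exceed the supply", call. = FALSE)
  }
  (supply - abs(coil_voltage)) * abs(I)
}

#' Closed-loop step response
#'
#' Canonical second-order unity-DC-gain step response with parameters
#' `(zeta, omega_n)`, followed by a slew-rate limiter enforcing
#' `|di/dt| <= (supply - dropout) / coil_L`. Reports the current trace,
#' peak overshoot (%), and the settling time into a +/- 2 % band.
#'
#' @param model A [driver_model()].
#' @param I_target Step amplitude (A).
#' @param duration Simulated time (s).
#' @param dt Time step (s); must resolve the dynamics
#'   (`dt <= 0.05 / omega_n`).
#' @param slew_limit Apply the slew ceiling (default `TRUE`).
#' @param band Settling band as a fraction of the step (default 0.02).
#' @return List with `time`, `current`, `overshoot_pct`,
#'   `settling_time`, `slew_max` (A/s).
#' @export
step_response <- function(model, I_target, duration = 2e-3, dt = NULL,
                          slew_limit = TRUE, band = 0.02) {
  stopifnot(inherits(model, "driver_model"))
  if (is.null(dt)) dt <- 0.02 / model$omega_n
  if (dt > 0.05 / model$omega_n) {
    stop("'dt' too coarse to resolve omega_n (need dt <= 0.05/omega_n)",
         call. = FALSE)
  }
  tt <- seq(0, duration, by = dt)
  z <- model$zeta
  wn <- model$omega_n
  if (z < 1) {
    wd <- wn * sqrt(1 - z^2)
    y <- 1 - exp(-z * wn * tt) * (cos(wd * tt) + z / sqrt(1 - z^2) *
                                    sin(wd * tt))
  } else if (z == 1) {
    y <- 1 - exp(-wn * tt) * (1 + wn * tt)
  } else {
    s1 <- -wn * (z - sqrt(z^2 - 1))
    s2 <- -wn * (z + sqrt(z^2 - 1))
    y <- 1 + (s2 * exp(s1 * tt) - s1 * exp(s2 * tt)) / (s1 - s2)
  }
  current <- I_target * y
  if (slew_limit) {
    max_step <- (model$supply - model$dropout) / model$coil_L * dt
    out <- numeric(length(current))
    prev <- 0
    for (k in seq_along(current)) {
      d <- current[k] - prev
      prev <- prev + sign(d) * min(abs(d), max_step)
      out[k] <- prev
    }
    current <- out
  }
  overshoot <- (max(abs(current)) - abs(I_target)) / abs(I_target) * 100
  outside <- abs(current - I_target) > band * abs(I_target)
  settling <- if (any(outside)) tt[max(which(outside))] + dt else 0
  list(time = tt, current = current,
       overshoot_pct = max(0, overshoot),
       settling_time = settling,
       slew_max = max(abs(diff(current))) / dt)
}

#' Closed-loop frequency response
#'
#' Magnitude and phase of the canonical second-order closed-loop transfer
#' function `H(jw) = wn^2 / (wn^2 - w^2 + 2j zeta wn w)` at the requested
#' frequencies.
#'
#' @param model A [driver_model()].
#' @param frequencies Frequencies in Hz (> 0).
#' @return `data.frame` with `frequency`, `gain`, `gain_db`, `phase_deg`.
#' @export
frequency_response <- function(model, frequencies) {
  if (any(frequencies <= 0)) stop("'frequencies' must be > 0", call. = FALSE)
  w <- 2 * pi * frequencies
  wn <- model$omega_n
  H <- wn^2 / (wn^2 - w^2 + 2i * model$zeta * wn * w)
  data.frame(frequency = frequencies,
             gain = Mod(H),
             gain_db = 20 * log10(Mod(H)),
             phase_deg = Arg(H) * 180 / pi)
}

#' Sham (double-wrapped) field blanking
#'
#' In the anti-serial wiring of a double-wrapped coil the two windings
#' carry the same current in opposite senses: the coil current, coil
#' resistance and dissipated power are unchanged, but the generated field
#' is canceled exactly. The field scale factor is 1 (serial) or 0
#' (anti-serial); residual field in the sham state is the ambient field
#' only.
#'
#' @param model A [driver_model()].
#' @param polarity `"serial"` or `"anti_serial"`.
#' @param U_control Control voltage (V).
#' @return List with `current` (A) and `field_factor` (0 or 1).
#' @export
sham_blanking <- function(model, polarity = c("serial", "anti_serial"),
                          U_control) {
  polarity <- match.arg(polarity)
  I <- static_current(model, U_control)
  list(current = I, field_factor = if (polarity == "serial") 1 else 0)
}
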