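#' Activation trace model for the optical lipid clamp
#'
#' Parameterises the photocurrent shapes seen under repetitive
#' photoswitching of a DAG analogue: the first (naive-state) activation
#' follows a power exponential plus a linear component,
#' `I0 + A*(1 - exp(-(t - t0)/tau))^p + m*(t - t0)`, while activations after
#' the first use the sensitized-state overrides (smaller tau, smaller p,
#' optionally larger A) and no linear term. Blue-light epochs relax the
#' current mono-exponentially back to baseline.
#'
#' @param baseline baseline current density I0, pA/pF.
#' @param A activation amplitude, pA/pF.
#' @param tau_s activation time constant, s.
#' @param p power (>= 1); ~4 for naive activation, interpreted as
#'   conformational transitions in all four subunits.
#' @param m linear slope, pA/pF/s (naive state only).
#' @param deact_tau_s blue-light deactivation time constant, s.
#' @param noise_sd Gaussian noise SD, pA/pF.
#' @param sens_tau_s,sens_p,sens_A sensitized-state overrides applied from
#'   the second UV epoch onward. Defaults: `tau_s/3`, `2`, `1.2 * A`.
#' @return `lg_trace_model` object.
#' @export
trace_model <- function(baseline = 0, A = 50, tau_s = 2, p = 3.6, m = 1,
                        deact_tau_s = 0.5, noise_sd = 1,
                        sens_tau_s = tau_s / 3, sens_p = 2, sens_A = 1.2 * A) {
  vals <- c(baseline, A, tau_s, p, m, deact_tau_s, noise_sd,
            sens_tau_s, sens_p, sens_A)
  if (any(!is.finite(vals)))
    stop_lg("non-finite trace-model parameter", class = "lipidgate_validation_error")
  if (tau_s <= 0 || sens_tau_s <= 0)
    stop_lg("time constants must be > 0", class = "lipidgate_validation_error")
  if (p < 1 || sens_p < 1)
    stop_lg("power p must be >= 1", class = "lipidgate_validation_error")
  if (noise_sd < 0)
    stop_lg("noise SD must be >= 0", class = "lipidgate_validation_error")
  structure(list(baseline = baseline, A = A, tau_s = tau_s, p = p, m = m,
                 deact_tau_s = deact_tau_s, noise_sd = noise_sd,
                 sens_tau_s = sens_tau_s, sens_p = sens_p, sens_A = sens_A),
            class = "lg_trace_model")
}

#' Illumination protocol (ordered UV/blue epochs)
#'
#' @param start_s epoch start times, s.
#' @param duration_s epoch durations, s.
#' @param wavelength_nm 365 (UV, activating) or 430 (blue, deactivating).
#' @param intensity_pct illumination intensity in (0, 100].
#' @return `lg_protocol` data.frame with one row per epoch.
#' @export
illumination_protocol <- function(start_s, duration_s, wavelength_nm,
                                  intensity_pct = 100) {
  n <- length(start_s)
  ep <- data.frame(start_s = as.numeric(start_s),
                   duration_s = as.numeric(duration_s),
                   wavelength_nm = as.numeric(wavelength_nm),
                   intensity_pct = rep_len(as.numeric(intensity_pct), n))
  if (any(!ep$wavelength_nm %in% c(365, 430)))
    stop_lg("wavelength must be 365 or 430 nm", class = "lipidgate_protocol_error")
  if (any(ep$duration_s <= 0) || any(ep$intensity_pct <= 0 | ep$intensity_pct > 100))
    stop_lg("invalid epoch duration or intensity", class = "lipidgate_protocol_error")
  if (is.unsorted(ep$start_s, strictly = TRUE))
    stop_lg("epochs must be chronological", class = "lipidgate_protocol_error")
  ends <- ep$start_s + ep$duration_s
  if (n > 1 && any(ep$start_s[-1] < ends[-n] - 1e-12))
    stop_lg("epochs overlap", class = "lipidgate_protocol_error")
  class(ep) <- c("lg_protocol", "data.frame")
  ep
}

#' Standard repetitive photocycling protocol
#'
#' Builds the double-pulse (or n-pulse) protocol used in the lipid-clamp
#' experiments: an optional blue pre-illumination step, then `n_cycles` of
#' UV activation followed by blue deactivation. The first UV pulse can be
#' shortened/attenuated (threshold protocols: 1 s at 30%).
#'
#' @param n_cycles number of UV/blue cycles.
#' @param uv_s,blue_s UV and blue epoch durations, s.
#' @param pre_blue_s duration of the blue pre-illumination (0 = none;
#'   20 s in the reference protocol).
#' @param first_uv_s,first_uv_intensity duration / intensity of the first
#'   UV pulse (defaults: same as the rest, 100%).
#' @param gap_s dark gap between epochs, s (default 0: epochs contiguous, as
#'   in the reference photocycling protocols).
#' @param t0_s time of the first epoch start, s.
#' @return `lg_protocol`.
#' @export
photocycle_protocol <- function(n_cycles = 2, uv_s = 10, blue_s = 10,
                                pre_blue_s = 0, first_uv_s = uv_s,
                                first_uv_intensity = 100, gap_s = 0,
                                t0_s = 1) {
  start <- numeric(); dur <- numeric(); wl <- numeric(); int <- numeric()
  t <- t0_s
  if (pre_blue_s > 0) {
    start <- c(start, t); dur <- c(dur, pre_blue_s); wl <- c(wl, 430); int <- c(int, 100)
    t <- t + pre_blue_s + gap_s
  }
  for (k in seq_len(n_cycles)) {
    u <- if (k == 1) first_uv_s else uv_s
    ui <- if (k == 1) first_uv_intensity else 100
    start <- c(start, t); dur <- c(dur, u); wl <- c(wl, 365); int <- c(int, ui)
    t <- t + u + gap_s
    start <- c(start, t); dur <- c(dur, blue_s); wl <- c(wl, 430); int <- c(int, 100)
    t <- t + blue_s + gap_s
  }
  illumination_protocol(start, dur, wl, int)
}

# noiseless model current on a time grid, following the protocol epoch by
# epoch; value is held during dark gaps and decays during blue epochs
model_current <- function(model, protocol, times) {
  I <- rep(model$baseline, length(times))
  level <- model$baseline
  uv_seen <- 0L
  n_ep <- nrow(protocol)
  for (e in seq_len(n_ep)) {
    t0 <- protocol$start_s[e]
    t1 <- t0 + protocol$duration_s[e]
    nxt <- if (e < n_ep) protocol$start_s[e + 1] else Inf
    inside <- times >= t0 & times < t1
    after <- times >= t1 & times < nxt
    if (protocol$wavelength_nm[e] == 365) {
      uv_seen <- uv_seen + 1L
      dt <- times[inside] - t0
      if (uv_seen == 1L) {
        I[inside] <- model$baseline +
          model$A * (1 - exp(-dt / model$tau_s))^model$p + model$m * dt
        level <- model$baseline +
          model$A * (1 - exp(-(t1 - t0) / model$tau_s))^model$p +
          model$m * (t1 - t0)
      } else {
        I[inside] <- model$baseline +
          model$sens_A * (1 - exp(-dt / model$sens_tau_s))^model$sens_p
        level <- model$baseline +
          model$sens_A * (1 - exp(-(t1 - t0) / model$sens_tau_s))^model$sens_p
      }
    } else {
      dt <- times[inside] - t0
      I[inside] <- model$baseline + (level - model$baseline) * exp(-dt / model$deact_tau_s)
      level <- model$baseline +
        (level - model$baseline) * exp(-(t1 - t0) / model$deact_tau_s)
    }
    I[after] <- level
  }
  I
}

#' Simulate a whole-cell photocurrent trace
#'
#' @param model a [trace_model()].
#' @param protocol an [illumination_protocol()].
#' @param seed RNG seed for the additive Gaussian noise.
#' @param sample_rate_hz sampling rate (default 200 Hz).
#' @param t_end_s trace end time; default 2 s past the last epoch.
#' @param holding_mv holding potential annotation, mV.
#' @return `lg_trace` data.frame (`time_s`, `value`) with attributes
#'   `kind = "current"`, `units = "pA/pF"`, `protocol`, `holding_mv`.
#' @export
simulate_current_trace <- function(model, protocol, seed = 1,
                                   sample_rate_hz = 200, t_end_s = NULL,
                                   holding_mv = -40) {
  stopifnot(inherits(model, "lg_trace_model"), inherits(protocol, "lg_protocol"))
  if (is.null(t_end_s))
    t_end_s <- max(protocol$start_s + protocol$duration_s) + 2
  times <- seq(0, t_end_s, by = 1 / sample_rate_hz)
  I <- model_current(model, protocol, times)
  set.seed(as.integer(seed))
  if (model$noise_sd > 0) I <- I + rnorm(length(I), sd = model$noise_sd)
  lg_trace(times, I, kind = "current", units = "pA/pF",
           protocol = protocol, holding_mv = holding_mv)
}

#' Simulate an F/F0 fluorescence trace driven by the model current
#'
#' A low-pass filtered copy of the noiseless current deviation from
#' baseline, mapped linearly onto F/F0 = 1 + gain * filtered(|dI|). Exactly
#' 1 whenever the driving current is identically baseline.
#'
#' @inheritParams simulate_current_trace
#' @param gain fluorescence gain per pA/pF (default 0.01).
#' @param filter_tau_s low-pass time constant, s (default 1).
#' @param sample_rate_hz sampling rate (default 1 Hz, as in ratiometric
#'   imaging at one frame per second).
#' @param noise_sd optional Gaussian noise on F/F0 (default 0).
#' @return `lg_trace` with `kind = "fluorescence"`, values strictly positive.
#' @export
simulate_fluorescence <- function(model, protocol, seed = 1, gain = 0.01,
                                  filter_tau_s = 1, sample_rate_hz = 1,
                                  t_end_s = NULL, noise_sd = 0) {
  stopifnot(inherits(model, "lg_trace_model"), inherits(protocol, "lg_protocol"))
  if (is.null(t_end_s))
    t_end_s <- max(protocol$start_s + protocol$duration_s) + 5
  times <- seq(0, t_end_s, by = 1 / sample_rate_hz)
  dI <- abs(model_current(model, protocol, times) - model$baseline)
  dt <- 1 / sample_rate_hz
  a <- dt / (filter_tau_s + dt)
  y <- numeric(length(dI))
  for (i in seq_along(dI)[-1]) y[i] <- y[i - 1] + a * (dI[i] - y[i - 1])
  f <- 1 + gain * y
  set.seed(as.integer(seed))
  if (noise_sd > 0) f <- f + rnorm(length(f), sd = noise_sd)
  f <- pmax(f, 1e-6)
  lg_trace(times, f, kind = "fluorescence", units = "F/F0", protocol = protocol)
}

#' Construct a trace object
#' @param time_s sample times, s (monotone).
#' @param value sample values.
#' @param kind `"current"` or `"fluorescence"`.
#' @param units unit string.
#' @param protocol optional `lg_protocol` annotation.
#' @param holding_mv optional holding potential.
#' @return `lg_trace` data.frame.
#' @export
lg_trace <- function(time_s, value, kind = "current", units = "pA/pF",
                     protocol = NULL, holding_mv = NULL) {
  stopifnot(length(time_s) == length(value), all(is.finite(value)))
  if (is.unsorted(time_s, strictly = TRUE))
    stop_lg("trace time must be strictly increasing", class = "lipidgate_trace_error")
  tr <- data.frame(time_s = time_s, value = value)
  attr(tr, "kind") <- kind
  attr(tr, "units") <- units
  attr(tr, "protocol") <- protocol
  attr(tr, "holding_mv") <- holding_mv
  class(tr) <- c("lg_trace", "data.frame")
  tr
}
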