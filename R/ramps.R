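#' Net I-V curve from a voltage ramp
#'
#' Net current = stimulated sweep minus background sweep at matched
#' voltages (background interpolated onto the stimulated voltage grid when
#' the grids differ). Ramps span the standard -130 to +80 mV protocol.
#'
#' @param ramp data.frame with `voltage_mv` and `current` (pA/pF) for the
#'   stimulated sweep; voltage strictly monotone.
#' @param background same for the background (pre-stimulus) sweep, or `NULL`
#'   for no subtraction.
#' @return `lg_iv` data.frame (`voltage_mv`, `current`).
#' @export
iv_from_ramp <- function(ramp, background = NULL) {
  stopifnot(all(c("voltage_mv", "current") %in% names(ramp)))
  v <- ramp$voltage_mv
  if (is.unsorted(v, strictly = TRUE) && is.unsorted(rev(v), strictly = TRUE))
    stop_lg("ramp voltage must be strictly monotone", class = "lipidgate_iv_error")
  net <- ramp$current
  if (!is.null(background)) {
    bg <- approx(background$voltage_mv, background$current, xout = v,
                 rule = 2)$y
    net <- net - bg
  }
  out <- data.frame(voltage_mv = v, current = net)
  class(out) <- c("lg_iv", "data.frame")
  out
}

#' Reversal potential of an I-V curve
#'
#' Zero crossing nearest 0 mV, located by linear interpolation between the
#' bracketing samples. Returns `NA` when the current never changes sign on
#' the ramp.
#'
#' @param iv `lg_iv` (or data.frame with `voltage_mv`, `current`).
#' @return reversal potential in mV, or `NA_real_`.
#' @export
reversal_potential <- function(iv) {
  v <- iv$voltage_mv; i <- iv$current
  o <- order(v); v <- v[o]; i <- i[o]
  exact <- v[i == 0]
  cross <- which(i[-length(i)] * i[-1] < 0)
  cands <- c(exact,
             vapply(cross, function(k)
               v[k] - i[k] * (v[k + 1] - v[k]) / (i[k + 1] - i[k]), 1.0))
  if (!length(cands)) return(NA_real_)
  cands[which.min(abs(cands))]
}

#' Current densities at reference voltages
#'
#' Reads the net current density off an I-V curve at the standard
#' -90 and +70 mV reference voltages (linear interpolation).
#'
#' @param iv `lg_iv`.
#' @param at voltages, mV.
#' @return named numeric vector.
#' @export
current_density_at <- function(iv, at = c(-90, 70)) {
  o <- order(iv$voltage_mv)
  setNames(approx(iv$voltage_mv[o], iv$current[o], xout = at, rule = 2)$y,
           paste0(at, "mV"))
}

#' Simulate a noisy ramp I-V sweep with a known reversal potential
#'
#' Linear conductance toy sweep `I = g * (V - e_rev)` plus Gaussian noise,
#' used to validate reversal-potential recovery.
#'
#' @param e_rev_mv true reversal potential, mV.
#' @param g conductance slope, pA/pF per mV.
#' @param v_from,v_to,step_mv ramp span and voltage step.
#' @param noise_sd Gaussian noise SD on the current (default 0.2 pA/pF, a
#'   typical residual after 2 kHz low-pass filtering).
#' @param seed RNG seed.
#' @return `lg_iv`.
#' @export
simulate_ramp_iv <- function(e_rev_mv = 4.2, g = 0.5, v_from = -130,
                             v_to = 80, step_mv = 1, noise_sd = 0.2, seed = 1) {
  v <- seq(v_from, v_to, by = step_mv)
  set.seed(as.integer(seed))
  i <- g * (v - e_rev_mv) + rnorm(length(v), sd = noise_sd)
  out <- data.frame(voltage_mv = v, current = i)
  class(out) <- c("lg_iv", "data.frame")
  out
}
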