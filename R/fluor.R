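#' Normalize raw fluorescence to F/F0
#'
#' Mode `"background"` (the reference method) divides the cell trace by a
#' background series recorded in a cell-free area; mode `"baseline"` divides
#' by the mean of the cell's own pre-stimulus window.
#'
#' @param cell `lg_trace` (or data.frame `time_s`/`value`) of raw cell
#'   fluorescence.
#' @param reference background series (same grid as `cell`, or a scalar) for
#'   mode `"background"`; ignored for `"baseline"`.
#' @param mode `"background"` or `"baseline"`.
#' @param pre_window_s pre-stimulus window `c(from, to)` for `"baseline"`
#'   (default: everything before the first sample + 1 s).
#' @return `lg_trace` with `kind = "fluorescence"` (F/F0).
#' @export
f_over_f0 <- function(cell, reference = NULL,
                      mode = c("background", "baseline"),
                      pre_window_s = NULL) {
  mode <- match.arg(mode)
  tm <- cell$time_s; y <- cell$value
  if (mode == "background") {
    if (is.null(reference))
      stop_lg("background mode needs a reference", class = "lipidgate_fluor_error")
    ref <- if (length(reference) == 1) rep(reference, length(y))
           else reference$value %||% reference
    if (length(ref) != length(y))
      stop_lg("reference length mismatch", class = "lipidgate_fluor_error")
    if (any(!is.finite(ref)) || any(ref <= 0))
      stop_lg("reference must be strictly positive", class = "lipidgate_fluor_error")
    f <- y / ref
  } else {
    pre_window_s <- pre_window_s %||% c(tm[1], tm[1] + 1)
    sel <- tm >= pre_window_s[1] & tm <= pre_window_s[2]
    f0 <- mean(y[sel])
    if (!is.finite(f0) || f0 <= 0)
      stop_lg("pre-stimulus mean must be strictly positive",
              class = "lipidgate_fluor_error")
    f <- y / f0
  }
  lg_trace(tm, f, kind = "fluorescence", units = "F/F0",
           protocol = attr(cell, "protocol"))
}

#' Per-epoch fluorescence peaks
#'
#' Maximum change in F/F0 within each UV epoch plus a configurable tail
#' (the indicator lags the current).
#'
#' @param trace F/F0 `lg_trace`.
#' @param protocol `lg_protocol`; defaults to the trace annotation.
#' @param tail_s seconds past the UV epoch end included in the search.
#' @return data.frame (`uv_index`, `t_peak_s`, `peak_dff0`).
#' @export
epoch_peaks <- function(trace, protocol = NULL, tail_s = 2) {
  protocol <- protocol %||% attr(trace, "protocol")
  if (is.null(protocol)) stop_lg("no protocol available",
                                 class = "lipidgate_protocol_error")
  uv <- which(protocol$wavelength_nm == 365)
  rows <- lapply(seq_along(uv), function(k) {
    e <- uv[k]
    sel <- trace$time_s >= protocol$start_s[e] &
      trace$time_s <= protocol$start_s[e] + protocol$duration_s[e] + tail_s
    if (!any(sel)) return(data.frame(uv_index = k, t_peak_s = NA_real_,
                                     peak_dff0 = NA_real_))
    i <- which(sel)[which.max(trace$value[sel])]
    data.frame(uv_index = k, t_peak_s = trace$time_s[i],
               peak_dff0 = trace$value[i] - 1)
  })
  do.call(rbind, rows)
}
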