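#' Lipid molecules within a cutoff of the protein
#'
#' A lipid molecule counts once if any of its beads lies within `cutoff` of
#' any protein bead (minimum-image distances). This is the whole-tetramer
#' molecule count used to follow lipid-shell equilibration over time.
#'
#' @param frame `lg_frame`.
#' @param topology `lg_topology`.
#' @param cutoff contact cutoff, nm (default 0.6, the CG bead contact
#'   distance).
#' @param method neighbor-search method, see [pairs_within_cutoff()].
#' @return named integer vector, one count per lipid species present in the
#'   topology.
#' @export
lipid_molecules_near_protein <- function(frame, topology, cutoff = 0.6,
                                         method = "auto") {
  stopifnot(inherits(frame, "lg_frame"))
  prot <- which(topology$species == "PROTEIN")
  lip <- which(topology$species != "PROTEIN")
  species_present <- intersect(LIPID_SPECIES, unique(topology$species))
  counts <- setNames(integer(length(species_present)), species_present)
  if (!length(prot) || !length(lip)) return(counts)
  pr <- pairs_within_cutoff(frame$positions[prot, , drop = FALSE],
                            frame$positions[lip, , drop = FALSE],
                            frame$box, cutoff, periodic_z = frame$periodic_z,
                            method = method)
  if (nrow(pr)) {
    mols <- unique(topology$molecule_id[lip[pr$j]])
    sp <- topology$species[match(mols, topology$molecule_id)]
    tb <- table(sp)
    counts[names(tb)] <- as.integer(tb)
  }
  counts
}

#' Bead-pair contacts between a site's residues and one lipid species
#'
#' Counts (site-residue bead, lipid bead) pairs within the cutoff --- the
#' bead-level contact definition --- summed over all subunits the site is
#' replicated on, or broken down per subunit.
#'
#' @param frame `lg_frame`.
#' @param topology `lg_topology`.
#' @param site a [site_definition()].
#' @param species one lipid species label.
#' @param cutoff contact cutoff, nm.
#' @param per_subunit return a per-subunit vector instead of the total?
#' @param method neighbor-search method.
#' @return integer pair count (or named vector per subunit).
#' @export
site_bead_contacts <- function(frame, topology, site, species, cutoff = 0.6,
                               per_subunit = FALSE, method = "auto") {
  stopifnot(inherits(site, "lg_site"))
  check_species(species)
  sb <- which(topology$species == "PROTEIN" &
                topology$resid %in% site$resids &
                topology$subunit %in% site$subunits)
  if (!length(sb))
    stop_lg("site %s residues not present in topology", site$name,
            class = "lipidgate_site_error")
  lb <- which(topology$species == species)
  if (!length(lb)) {
    if (per_subunit) return(setNames(integer(length(site$subunits)),
                                     site$subunits))
    return(0L)
  }
  pr <- pairs_within_cutoff(frame$positions[sb, , drop = FALSE],
                            frame$positions[lb, , drop = FALSE],
                            frame$box, cutoff, periodic_z = frame$periodic_z,
                            method = method)
  if (!per_subunit) return(nrow(pr))
  su <- topology$subunit[sb[pr$i]]
  out <- setNames(integer(length(site$subunits)), site$subunits)
  tb <- table(factor(su, levels = site$subunits))
  out[names(tb)] <- as.integer(tb)
  out
}

#' Centered moving average with edge truncation
#'
#' Window is truncated (not padded) at the series edges, so a constant
#' series is unchanged and no phase lag is introduced.
#'
#' @param x numeric series.
#' @param k window length in points; rounded up to the nearest odd value.
#' @return smoothed series, same length.
#' @export
moving_average <- function(x, k) {
  n <- length(x)
  k <- max(1L, as.integer(k)); if (k %% 2L == 0L) k <- k + 1L
  h <- (k - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L); hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# shared aggregation: per-repeat frame series -> smoothed, mean, sd
aggregate_series <- function(series_list, times, window_ns) {
  dt <- if (length(times) > 1) times[2] - times[1] else window_ns
  if (window_ns < dt)
    stop_lg("window (%g ns) shorter than the frame interval (%g ns)",
            window_ns, dt, class = "lipidgate_window_error")
  k <- round(window_ns / dt)
  sm <- lapply(series_list, function(m) apply(m, 2, moving_average, k = k))
  sm <- lapply(sm, function(m) matrix(m, nrow = length(times),
                                      dimnames = dimnames(series_list[[1]])))
  arr <- simplify2array(sm)                       # frames x series x repeats
  mean_m <- apply(arr, c(1, 2), mean)
  sd_m <- if (length(series_list) >= 2) apply(arr, c(1, 2), sd) else NULL
  list(smoothed = sm, mean = mean_m, sd = sd_m)
}

new_timeseries <- function(times, raw, agg, window_ns, cutoff, what) {
  structure(list(time_ns = times, raw = raw, smoothed = agg$smoothed,
                 mean = agg$mean, sd = agg$sd, window_ns = window_ns,
                 cutoff = cutoff, what = what, n_repeats = length(raw)),
            class = "lg_timeseries")
}

#' @export
print.lg_timeseries <- function(x, ...) {
  cat(sprintf("<lg_timeseries> %s: %d frames x %d series, %d repeat(s), window %g ns\n",
              x$what, length(x$time_ns), ncol(x$mean), x$n_repeats, x$window_ns))
  invisible(x)
}

#' Tidy a contact time series
#' @param x `lg_timeseries`.
#' @param ... unused.
#' @return data.frame with `time_ns`, `series`, `mean`, `sd`.
#' @export
as.data.frame.lg_timeseries <- function(x, ...) {
  nm <- colnames(x$mean)
  out <- data.frame(
    time_ns = rep(x$time_ns, length(nm)),
    series = rep(nm, each = length(x$time_ns)),
    mean = as.vector(x$mean))
  out$sd <- if (!is.null(x$sd)) as.vector(x$sd) else NA_real_
  out
}

#' Windowed cross-repeat contact time series
#'
#' Evaluates a per-frame contact metric on every repeat, smooths each
#' repeat's series with a centered moving average of `window_ns`, then takes
#' the cross-repeat mean and standard deviation (the dark line and light
#' band of the reference figures).
#'
#' @param trajectories list of `lg_trajectory` sharing one time grid.
#' @param metric per-frame function `(frame, topology) -> named numeric`;
#'   see [metric_near_protein()], [metric_site_contacts()],
#'   [metric_dag_occupancy()].
#' @param window_ns moving-average window, ns (default 200).
#' @return `lg_timeseries`.
#' @export
contact_timeseries <- function(trajectories, metric, window_ns = 200) {
  if (inherits(trajectories, "lg_trajectory")) trajectories <- list(trajectories)
  times <- trajectories[[1]]$times_ns
  for (tr in trajectories)
    if (!isTRUE(all.equal(tr$times_ns, times)))
      stop_lg("repeats do not share a time grid", class = "lipidgate_grid_error")
  raw <- lapply(trajectories, function(tr) {
    rows <- lapply(seq_len(n_frames(tr)),
                   function(i) metric(get_frame(tr, i), tr$topology))
    do.call(rbind, rows)
  })
  agg <- aggregate_series(raw, times, window_ns)
  new_timeseries(times, raw, agg, window_ns, cutoff = attr(metric, "cutoff"),
                 what = attr(metric, "label") %||% "metric")
}

#' Per-frame metric: lipid molecules near the protein
#' @param cutoff contact cutoff, nm.
#' @return metric function for [contact_timeseries()].
#' @export
metric_near_protein <- function(cutoff = 0.6) {
  f <- function(frame, topology)
    lipid_molecules_near_protein(frame, topology, cutoff = cutoff)
  attr(f, "cutoff") <- cutoff
  attr(f, "label") <- "molecules within cutoff of protein"
  f
}

#' Per-frame metric: bead contacts of one species at a site
#' @param site a [site_definition()].
#' @param species lipid species.
#' @param cutoff contact cutoff, nm.
#' @return metric function for [contact_timeseries()].
#' @export
metric_site_contacts <- function(site, species = "DAG", cutoff = 0.6) {
  f <- function(frame, topology)
    c(contacts = site_bead_contacts(frame, topology, site, species, cutoff))
  attr(f, "cutoff") <- cutoff
  attr(f, "label") <- sprintf("%s bead contacts at %s", species, site$name)
  f
}

#' Per-frame metric: distinct DAG molecules at a site
#' @inheritParams metric_site_contacts
#' @return metric function for [contact_timeseries()].
#' @export
metric_dag_occupancy <- function(site = site_definition("L2"), cutoff = 0.6) {
  f <- function(frame, topology)
    c(DAG = distinct_molecules_at_site(frame, topology, site, "DAG", cutoff))
  attr(f, "cutoff") <- cutoff
  attr(f, "label") <- sprintf("DAG occupancy of %s", site$name)
  f
}

distinct_molecules_at_site <- function(frame, topology, site, species, cutoff,
                                       method = "auto") {
  sb <- which(topology$species == "PROTEIN" &
                topology$resid %in% site$resids &
                topology$subunit %in% site$subunits)
  if (!length(sb))
    stop_lg("site %s undefined in topology", site$name, class = "lipidgate_site_error")
  lb <- which(topology$species == species)
  if (!length(lb)) return(0L)
  pr <- pairs_within_cutoff(frame$positions[sb, , drop = FALSE],
                            frame$positions[lb, , drop = FALSE],
                            frame$box, cutoff, periodic_z = frame$periodic_z,
                            method = method)
  length(unique(topology$molecule_id[lb[pr$j]]))
}

#' DAG occupancy of the L2 sites over time
#'
#' Per frame, the number of distinct DAG molecules with at least one bead
#' within `cutoff` of any L2 residue bead of any subunit (the tetramer's
#' lipidation level), windowed and aggregated across repeats.
#'
#' @param trajectories list of `lg_trajectory`.
#' @param site site definition (default L2).
#' @param cutoff contact cutoff, nm.
#' @param window_ns moving-average window, ns.
#' @return `lg_timeseries` with a single `DAG` series.
#' @export
dag_occupancy <- function(trajectories, site = site_definition("L2"),
                          cutoff = 0.6, window_ns = 200) {
  if (inherits(trajectories, "lg_trajectory")) trajectories <- list(trajectories)
  if (!any(trajectories[[1]]$topology$species == "DAG"))
    stop_lg("no DAG in topology", class = "lipidgate_species_error")
  contact_timeseries(trajectories, metric_dag_occupancy(site, cutoff),
                     window_ns = window_ns)
}

#' Per-residue lipid-species contact fingerprint
#'
#' Accumulates bead contacts between each site residue (pooled over the four
#' subunits) and every lipid species over all frames of the evaluation
#' window and all repeats, then expresses each species as a percentage of
#' that residue's total contacts. The evaluation window should lie after
#' equilibration (the reference analysis uses the final 25 µs).
#'
#' @param trajectories list of `lg_trajectory`.
#' @param site a [site_definition()].
#' @param from_ns,to_ns evaluation window bounds on the trajectory time axis
#'   (defaults: 25% of the run to the end).
#' @param cutoff contact cutoff, nm.
#' @return `lg_fingerprint` data.frame (`resid`, `species`, `count`, `pct`,
#'   `no_contacts`), with the wide count matrix as attribute `"matrix"`.
#' @export
contact_fingerprint <- function(trajectories, site, from_ns = NULL,
                                to_ns = NULL, cutoff = 0.6) {
  if (inherits(trajectories, "lg_trajectory")) trajectories <- list(trajectories)
  times <- trajectories[[1]]$times_ns
  from_ns <- from_ns %||% (max(times) * 0.25)
  to_ns <- to_ns %||% max(times)
  sel <- which(times >= from_ns & times <= to_ns)
  if (!length(sel))
    stop_lg("empty evaluation window [%g, %g] ns", from_ns, to_ns,
            class = "lipidgate_window_error")
  topology <- trajectories[[1]]$topology
  species_present <- intersect(LIPID_SPECIES, unique(topology$species))
  counts <- matrix(0L, length(site$resids), length(species_present),
                   dimnames = list(site$resids, species_present))
  sb <- which(topology$species == "PROTEIN" & topology$resid %in% site$resids &
                topology$subunit %in% site$subunits)
  lb <- which(topology$species != "PROTEIN")
  for (tr in trajectories) {
    for (i in sel) {
      fr <- get_frame(tr, i)
      pr <- pairs_within_cutoff(fr$positions[sb, , drop = FALSE],
                                fr$positions[lb, , drop = FALSE],
                                fr$box, cutoff, periodic_z = fr$periodic_z)
      if (!nrow(pr)) next
      tb <- table(factor(topology$resid[sb[pr$i]], levels = site$resids),
                  factor(topology$species[lb[pr$j]], levels = species_present))
      counts <- counts + as.integer(tb)
    }
  }
  tot <- rowSums(counts)
  pct <- counts / ifelse(tot > 0, tot, NA) * 100
  out <- data.frame(
    resid = rep(site$resids, times = length(species_present)),
    species = rep(species_present, each = length(site$resids)),
    count = as.vector(counts),
    pct = as.vector(pct),
    no_contacts = rep(tot == 0, times = length(species_present)))
  attr(out, "matrix") <- counts
  attr(out, "site") <- site$name
  attr(out, "window_ns") <- c(from_ns, to_ns)
  class(out) <- c("lg_fingerprint", "data.frame")
  out
}

#' Detect the equilibration onset of a series
#'
#' Earliest time after which the sliding-window mean stays within
#' `tol * |final mean|` of the final window mean for the remainder of the
#' series. Returns `NA` when no onset leaves at least one full probe window
#' of remainder.
#'
#' @param x numeric series (e.g. a smoothed contact count).
#' @param time_ns time grid; defaults to the sample index.
#' @param window_ns probe window (default a tenth of the span).
#' @param tol relative tolerance (default 0.05).
#' @return onset time (same units as `time_ns`), or `NA_real_`.
#' @export
detect_equilibration <- function(x, time_ns = seq_along(x), window_ns = NULL,
                                 tol = 0.05) {
  n <- length(x)
  stopifnot(n == length(time_ns))
  window_ns <- window_ns %||% ((max(time_ns) - min(time_ns)) / 10)
  dt <- if (n > 1) time_ns[2] - time_ns[1] else 1
  k <- max(1L, round(window_ns / dt))
  if (n < 2 * k + 1) stop_lg("series shorter than twice the probe window",
                             class = "lipidgate_window_error")
  roll <- moving_average(x, 2L * (k %/% 2L) + 1L)
  final <- mean(x[(n - k + 1):n])
  band <- tol * abs(final)
  if (band == 0) band <- tol  # flat-at-zero series
  ok <- abs(roll - final) <= band
  # earliest index from which ok holds for the remainder
  run <- rev(cumprod(rev(ok)))
  idx <- which(run == 1)[1]
  if (is.na(idx) || time_ns[idx] > max(time_ns) - window_ns) return(NA_real_)
  time_ns[idx]
}

#' Leaflet assignment from bead height with hysteresis
#'
#' Assigns `inner` when the reference-bead Z drops below the bilayer
#' midplane minus the hysteresis half-width, `outer` above the midplane plus
#' it; in between, the previous assignment is kept to suppress flicker.
#'
#' @param z reference-bead heights (nm).
#' @param midplane bilayer midplane height (nm), e.g. the mean phosphate Z.
#' @param prev previous assignments (`"inner"`/`"outer"`) or `NULL` for the
#'   first frame (then the midplane alone decides).
#' @param hysteresis half-width of the dead band, nm (default 0.5).
#' @return character vector of `"inner"`/`"outer"`.
#' @export
assign_leaflet <- function(z, midplane, prev = NULL, hysteresis = 0.5) {
  if (is.null(prev)) return(ifelse(z < midplane, "inner", "outer"))
  stopifnot(length(prev) == length(z))
  out <- prev
  out[z < midplane - hysteresis] <- "inner"
  out[z > midplane + hysteresis] <- "outer"
  out
}

#' Per-frame outer-leaflet DAG count from bead heights
#'
#' Analysis-side leaflet bookkeeping (independent of the generator's internal
#' state): applies [assign_leaflet()] frame by frame to the DAG reference
#' beads, using the protein midplane (or the mean lipid Z) as the divider.
#'
#' @param traj `lg_trajectory`.
#' @param hysteresis dead-band half width, nm.
#' @return integer vector, outer-leaflet DAG molecules per frame.
#' @export
outer_dag_count <- function(traj, hysteresis = 0.5) {
  topology <- traj$topology
  dag <- which(topology$species == "DAG")
  if (!length(dag)) return(integer(n_frames(traj)))
  protein <- attr(topology, "protein")
  mid <- if (!is.null(protein)) protein$z_mid else mean(traj$positions[, 3, 1])
  prev <- NULL
  out <- integer(n_frames(traj))
  for (f in seq_len(n_frames(traj))) {
    prev <- assign_leaflet(traj$positions[dag, 3, f], mid, prev, hysteresis)
    out[f] <- sum(prev == "outer")
  }
  out
}
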