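#' Simulate a coarse-grained membrane trajectory
#'
#' Propagates the site-and-dwell stochastic model from an initial frame:
#' lipids take 2D Brownian steps within their leaflet (periodic wrap in X/Y),
#' DAG flips between leaflets as a Poisson process --- suppressed to rate 0
#' while the Z-restraint phase is active --- and lipids entering a free
#' pocket's capture radius bind with the species' capture probability,
#' dwelling for an exponential residence time frozen at the pocket center
#' (plus a small jitter). The protein is fixed throughout. Runs are fully
#' reproducible for a given seed.
#'
#' Pockets open toward the inner leaflet; only inner-leaflet lipids are
#' captured. Bound DAG does not flip.
#'
#' @param frame0 initial `lg_frame` from [build_membrane()].
#' @param topology matching `lg_topology` (carrying the protein model).
#' @param binding a [binding_model()].
#' @param schedule a [simulation_schedule()].
#' @param seed integer RNG seed.
#' @return `lg_trajectory`: list with `times_ns`, `positions` (N x 3 x F
#'   array), `box`, `topology`, `leaflet` (lipids x frames character matrix,
#'   the generator's ground truth), `bound_site` (lipids x frames, `NA` or
#'   pocket site name), and the inputs' metadata.
#' @export
simulate_trajectory <- function(frame0, topology, binding, schedule, seed = 1) {
  stopifnot(inherits(frame0, "lg_frame"), inherits(topology, "lg_topology"),
            inherits(binding, "lg_binding"), inherits(schedule, "lg_schedule"))
  if (nrow(frame0$positions) != nrow(topology))
    stop_lg("frame has %d beads but topology %d", nrow(frame0$positions),
            nrow(topology), class = "lipidgate_topology_error")
  for (v in c(binding$dwell_ns, binding$capture_prob, binding$flip_rate_per_us,
              binding$diffusion))
    if (any(!is.finite(v)))
      stop_lg("non-finite binding parameter", class = "lipidgate_validation_error")

  protein <- attr(topology, "protein")
  box <- frame0$box
  set.seed(as.integer(seed))

  is_lip <- topology$species != "PROTEIN"
  lip_idx <- which(is_lip)
  n_lip <- length(lip_idx)
  species <- topology$species[lip_idx]
  leaflet <- topology$leaflet0[lip_idx]
  pos <- frame0$positions[lip_idx, , drop = FALSE]

  times <- schedule$times_ns
  n_frames <- length(times)
  dt <- schedule$dt_ns
  restr_end <- schedule$restrained_us * 1000

  pockets <- if (!is.null(protein)) protein$pockets else
    data.frame(site = character(), subunit = integer(),
               cx = numeric(), cy = numeric(), cz = numeric(), radius = numeric())
  n_pk <- nrow(pockets)
  occupant <- rep(0L, n_pk)        # lipid row index occupying each pocket
  unbind_at <- rep(Inf, n_pk)
  bound_pocket <- rep(0L, n_lip)   # 0 = free

  z_inner <- if (!is.null(protein)) protein$z_inner else min(pos[, 3])
  z_outer <- if (!is.null(protein)) protein$z_outer else max(pos[, 3])

  sd_step <- sqrt(2 * binding$diffusion[species] * dt)
  flip_p <- 1 - exp(-binding$flip_rate_per_us * dt / 1000)
  is_dag <- species == "DAG"

  positions <- array(NA_real_, c(nrow(topology), 3, n_frames))
  leaflet_mat <- matrix(NA_character_, n_lip, n_frames)
  site_mat <- matrix(NA_character_, n_lip, n_frames)
  positions[!is_lip, , ] <- frame0$positions[!is_lip, , drop = FALSE]
  positions[lip_idx, , 1] <- pos
  leaflet_mat[, 1] <- leaflet

  for (f in 2:max(n_frames, 2)) {
    if (n_frames < 2) break
    t_now <- times[f]
    restrained <- t_now <= restr_end

    free <- bound_pocket == 0L
    # Brownian step for free lipids
    nf <- sum(free)
    if (nf) {
      pos[free, 1] <- (pos[free, 1] + rnorm(nf, sd = sd_step[free])) %% box[1]
      pos[free, 2] <- (pos[free, 2] + rnorm(nf, sd = sd_step[free])) %% box[2]
    }
    # DAG flip-flop (free DAG only; suppressed while restrained)
    if (!restrained && flip_p > 0) {
      cand <- which(free & is_dag)
      if (length(cand)) {
        flips <- cand[runif(length(cand)) < flip_p]
        if (length(flips)) {
          leaflet[flips] <- ifelse(leaflet[flips] == "inner", "outer", "inner")
          pos[flips, 3] <- ifelse(leaflet[flips] == "inner", z_inner, z_outer)
        }
      }
    }
    # releases
    done <- which(occupant != 0L & unbind_at <= t_now)
    for (pk in done) {
      li <- occupant[pk]
      bound_pocket[li] <- 0L
      occupant[pk] <- 0L
      unbind_at[pk] <- Inf
      ang <- runif(1, 0, 2 * pi)
      pos[li, 1] <- (pockets$cx[pk] + 0.9 * cos(ang)) %% box[1]
      pos[li, 2] <- (pockets$cy[pk] + 0.9 * sin(ang)) %% box[2]
    }
    # captures: free inner-leaflet lipids within a free pocket's radius
    if (n_pk) {
      free_inner <- which(bound_pocket == 0L & leaflet == "inner")
      for (pk in which(occupant == 0L)) {
        if (!length(free_inner)) break
        dx <- abs(pos[free_inner, 1] - pockets$cx[pk]); dx <- pmin(dx, box[1] - dx)
        dy <- abs(pos[free_inner, 2] - pockets$cy[pk]); dy <- pmin(dy, box[2] - dy)
        near <- free_inner[dx * dx + dy * dy <= pockets$radius[pk]^2]
        if (!length(near)) next
        near <- near[sample.int(length(near))]
        pcap <- binding$capture_prob[pockets$site[pk], species[near]]
        hit <- which(runif(length(near)) < pcap)
        if (!length(hit)) next
        li <- near[hit[1]]
        occupant[pk] <- li
        bound_pocket[li] <- pk
        unbind_at[pk] <- t_now +
          rexp(1, rate = 1 / binding$dwell_ns[pockets$site[pk], species[li]])
        free_inner <- setdiff(free_inner, li)
      }
      # bound lipids sit at the pocket center +- jitter
      bnd <- which(bound_pocket != 0L)
      if (length(bnd)) {
        pk <- bound_pocket[bnd]
        pos[bnd, 1] <- pockets$cx[pk] + rnorm(length(bnd), sd = 0.05)
        pos[bnd, 2] <- pockets$cy[pk] + rnorm(length(bnd), sd = 0.05)
        pos[bnd, 3] <- pockets$cz[pk]
      }
    }
    positions[lip_idx, , f] <- pos
    leaflet_mat[, f] <- leaflet
    site_mat[, f] <- ifelse(bound_pocket > 0L, pockets$site[bound_pocket], NA)
  }

  structure(list(times_ns = times, positions = positions, box = box,
                 topology = topology, periodic_z = frame0$periodic_z,
                 leaflet = leaflet_mat, bound_site = site_mat,
                 schedule = schedule, binding = binding, seed = as.integer(seed)),
            class = "lg_trajectory")
}

#' @export
print.lg_trajectory <- function(x, ...) {
  cat(sprintf("<lg_trajectory> %d beads x %d frames, %.0f-%.0f ns\n",
              dim(x$positions)[1], dim(x$positions)[3],
              min(x$times_ns), max(x$times_ns)))
  invisible(x)
}

#' Extract one frame of a trajectory
#' @param traj `lg_trajectory`.
#' @param i frame index.
#' @return `lg_frame`.
#' @export
get_frame <- function(traj, i) {
  stopifnot(i >= 1, i <= dim(traj$positions)[3])
  lg_frame(traj$times_ns[i], traj$positions[, , i], traj$box,
           periodic_z = traj$periodic_z)
}

#' Number of frames in a trajectory
#' @param traj `lg_trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) dim(traj$positions)[3]

#' Simulate a full repeated membrane scenario
#'
#' Convenience wrapper: builds one membrane per repeat and simulates it,
#' deriving per-repeat seeds from `seed` so repeats are independent but the
#' whole set is reproducible.
#'
#' @param dag_inner_pct inner-leaflet DAG mole percent (0, 2 or 10 shipped).
#' @param spec optional [membrane_spec()]; built from `dag_inner_pct` if `NULL`.
#' @param protein optional [protein_model()].
#' @param binding optional [binding_model()].
#' @param schedule optional [simulation_schedule()].
#' @param seed base seed.
#' @return list of `lg_trajectory`, length `schedule$n_repeats`.
#' @export
simulate_membrane_scenario <- function(dag_inner_pct = 2, spec = NULL,
                                       protein = protein_model(),
                                       binding = binding_model(),
                                       schedule = simulation_schedule(),
                                       seed = 1) {
  if (is.null(spec)) {
    comp <- membrane_composition(dag_inner_pct)
    spec <- membrane_spec(inner = comp$inner, outer = comp$outer)
  }
  lapply(seq_len(schedule$n_repeats), function(r) {
    s <- (as.integer(seed) * 1009L + r * 7919L) %% 2147483647L
    sys <- build_membrane(spec, protein, seed = s)
    simulate_trajectory(sys$frame, sys$topology, binding, schedule, seed = s + 1L)
  })
}
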