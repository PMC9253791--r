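# Shared fixtures and independent oracles, built in code at test time.

# small membrane system for fast trajectory tests
tiny_system <- function(dag_inner_pct = 10, lipids = 120, box = c(14, 14, 12),
                        seed = 1) {
  comp <- membrane_composition(dag_inner_pct)
  spec <- membrane_spec(box = box, lipids_per_leaflet = lipids,
                        inner = comp$inner, outer = comp$outer)
  protein <- protein_model(center = box[1:2] / 2, z_mid = box[3] / 2)
  sys <- build_membrane(spec, protein, seed = seed)
  c(sys, list(spec = spec, protein = protein))
}

tiny_trajectory <- function(dag_inner_pct = 10, lipids = 120,
                            restrained_us = 1, total_us = 4, seed = 1,
                            binding = binding_model()) {
  sys <- tiny_system(dag_inner_pct, lipids, seed = seed)
  sch <- simulation_schedule(restrained_us = restrained_us,
                             total_us = total_us, n_repeats = 1)
  simulate_trajectory(sys$frame, sys$topology, binding, sch, seed = seed + 1)
}

# independent O(N^2) pair oracle: plain per-bead loop, no shared code with
# the package's vectorised or cell-list implementations
oracle_pairs <- function(pos_a, pos_b, box, cutoff, periodic_z = FALSE) {
  res_i <- integer(); res_j <- integer()
  for (i in seq_len(nrow(pos_a))) {
    for (j in seq_len(nrow(pos_b))) {
      d2 <- 0
      for (k in 1:3) {
        d <- abs(pos_a[i, k] - pos_b[j, k])
        if (k < 3 || periodic_z) d <- min(d, box[k] - d)
        d2 <- d2 + d * d
      }
      if (d2 <= cutoff^2) { res_i <- c(res_i, i); res_j <- c(res_j, j) }
    }
  }
  data.frame(i = res_i, j = res_j)
}

# random frame + topology for oracle-equivalence checks
random_frame <- function(n_protein, n_lipid, box, seed) {
  set.seed(seed)
  n <- n_protein + n_lipid
  pos <- cbind(runif(n, 0, box[1]), runif(n, 0, box[2]), runif(n, 0, box[3]))
  species <- c(rep("PROTEIN", n_protein),
               sample(c("PC", "PE", "PS", "Chol", "DAG"), n_lipid,
                      replace = TRUE))
  topo <- data.frame(
    bead_id = seq_len(n),
    molecule_id = c(rep(1L, n_protein), 1L + seq_len(n_lipid)),
    species = species,
    resid = c(rep(615L, n_protein), rep(NA_integer_, n_lipid)),
    subunit = c(rep(1:4, length.out = n_protein), rep(NA_integer_, n_lipid)),
    leaflet0 = c(rep(NA_character_, n_protein),
                 rep("inner", n_lipid)),
    stringsAsFactors = FALSE)
  class(topo) <- c("lg_topology", "data.frame")
  list(frame = lg_frame(0, pos, box), topology = topo)
}

# noisy first-activation segment at the reference parameters
noisy_segment <- function(seed, noise_sd = 1, rate_hz = 100, dur_s = 10,
                          A = 50, tau = 2, p = 3.6, m = 1) {
  model <- trace_model(A = A, tau_s = tau, p = p, m = m, noise_sd = noise_sd)
  proto <- photocycle_protocol(n_cycles = 1, uv_s = dur_s, blue_s = 3)
  tr <- simulate_current_trace(model, proto, seed = seed,
                               sample_rate_hz = rate_hz)
  segment_photocycles(tr)[[1]]$segment
}
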