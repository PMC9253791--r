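test_that("molecule counting matches the textbook examples", {
  # protein bead at the origin, one PC bead 0.5 nm away: within 0.6 nm
  topo <- data.frame(bead_id = 1:2, molecule_id = 1:2,
                     species = c("PROTEIN", "PC"),
                     resid = c(615L, NA), subunit = c(1L, NA),
                     leaflet0 = c(NA, "inner"))
  class(topo) <- c("lg_topology", "data.frame")
  fr <- lg_frame(0, rbind(c(0, 0, 0), c(0.5, 0, 0)), c(10, 10, 10))
  expect_identical(lipid_molecules_near_protein(fr, topo),
                   c(PC = 1L))
  # periodic wrap: bead at 1.95 in a 2.0 nm box is 0.05 nm away
  fr2 <- lg_frame(0, rbind(c(0, 0, 0), c(1.95, 0, 0)), c(2, 2, 2))
  expect_identical(lipid_molecules_near_protein(fr2, topo, cutoff = 0.6),
                   c(PC = 1L))
  # ambiguity guard: cutoff at or above half the smallest periodic edge
  expect_error(lipid_molecules_near_protein(fr2, topo, cutoff = 1.0),
               class = "lipidgate_ambiguity_error")
})

test_that("site contacts count bead pairs, not molecules", {
  # one DAG bead within cutoff of two L2 residue beads -> 2 pairs
  topo <- data.frame(bead_id = 1:3, molecule_id = c(1L, 1L, 2L),
                     species = c("PROTEIN", "PROTEIN", "DAG"),
                     resid = c(615L, 652L, NA), subunit = c(1L, 1L, NA),
                     leaflet0 = c(NA, NA, "inner"))
  class(topo) <- c("lg_topology", "data.frame")
  fr <- lg_frame(0, rbind(c(0, 0, 0), c(0.4, 0, 0), c(0.2, 0.3, 0)),
                 c(10, 10, 10))
  l2 <- site_definition("L2")
  expect_identical(site_bead_contacts(fr, topo, l2, "DAG"), 2L)
  expect_identical(site_bead_contacts(fr, topo, l2, "PC"), 0L)
  expect_error(site_bead_contacts(fr, topo, l2, "XX"),
               class = "lipidgate_species_error")
  # distinct-molecule counting: both pockets occupied -> occupancy 2
  topo2 <- data.frame(bead_id = 1:4, molecule_id = c(1L, 1L, 2L, 3L),
                      species = c("PROTEIN", "PROTEIN", "DAG", "DAG"),
                      resid = c(652L, 652L, NA, NA),
                      subunit = c(1L, 2L, NA, NA),
                      leaflet0 = c(NA, NA, "inner", "inner"))
  class(topo2) <- c("lg_topology", "data.frame")
  fr2 <- lg_frame(0, rbind(c(0, 0, 0), c(5, 5, 0), c(0.3, 0, 0),
                           c(5.3, 5, 0)), c(10, 10, 10))
  expect_identical(
    lipidgate:::distinct_molecules_at_site(fr2, topo2, l2, "DAG", 0.6), 2L)
})

test_that("both neighbor-search paths match an independent O(N^2) oracle", {
  set.seed(99)
  for (k in 1:12) {
    box <- runif(3, 2.5, 8)
    cutoff <- runif(1, 0.3, min(box) / 2 - 0.05)
    na <- sample(5:60, 1); nb <- sample(5:120, 1)
    pa <- cbind(runif(na, 0, box[1]), runif(na, 0, box[2]), runif(na, 0, box[3]))
    pb <- cbind(runif(nb, 0, box[1]), runif(nb, 0, box[2]), runif(nb, 0, box[3]))
    for (pz in c(TRUE, FALSE)) {
      ref <- oracle_pairs(pa, pb, box, cutoff, periodic_z = pz)
      ref <- ref[order(ref$i, ref$j), ]
      br <- pairs_within_cutoff(pa, pb, box, cutoff, periodic_z = pz,
                                method = "brute")
      cl <- pairs_within_cutoff(pa, pb, box, cutoff, periodic_z = pz,
                                method = "cell")
      expect_identical(unname(as.matrix(br)), unname(as.matrix(ref)))
      expect_identical(unname(as.matrix(cl)), unname(as.matrix(ref)))
    }
  }
})

test_that("contact counts are translation invariant and cutoff monotone", {
  rf <- random_frame(20, 80, box = c(6, 6, 6), seed = 17)
  base <- lipid_molecules_near_protein(rf$frame, rf$topology, cutoff = 0.8)
  for (shift in list(c(1.3, -2.1, 0.7), c(5.9, 0.2, -4))) {
    pos <- sweep(rf$frame$positions, 2, shift, "+")
    fr <- lg_frame(0, pos, rf$frame$box)
    fr$periodic_z <- rf$frame$periodic_z
    expect_identical(lipid_molecules_near_protein(fr, rf$topology, cutoff = 0.8),
                     base)
  }
  counts <- vapply(c(0.3, 0.6, 0.9, 1.2, 1.5),
                   function(co) sum(lipid_molecules_near_protein(
                     rf$frame, rf$topology, cutoff = co)), 1L)
  expect_true(all(diff(counts) >= 0))
  # species closure: never more molecules than exist
  n_lip <- sum(rf$topology$species != "PROTEIN")
  expect_lte(sum(lipid_molecules_near_protein(rf$frame, rf$topology, 1.5)),
             n_lip)
})

test_that("windowing behaves like a centered, edge-truncated average", {
  expect_equal(moving_average(rep(3, 10), 5), rep(3, 10))
  expect_equal(moving_average(1:5, 3), c(1.5, 2, 3, 4, 4.5))
  traj <- tiny_trajectory(seed = 21, total_us = 2, restrained_us = 0.5)
  ts5 <- contact_timeseries(list(traj, traj, traj, traj, traj),
                            metric_near_protein(0.6), window_ns = 200)
  expect_true(all(ts5$sd == 0))
  expect_error(contact_timeseries(traj, metric_near_protein(0.6),
                                  window_ns = 10),
               class = "lipidgate_window_error")
})

test_that("DAG-L2 contacts appear only after DAG reaches the pockets", {
  traj <- tiny_trajectory(dag_inner_pct = 10, restrained_us = 1, total_us = 4,
                          seed = 31)
  ts <- contact_timeseries(traj, metric_site_contacts(site_definition("L2"),
                                                      "DAG"),
                           window_ns = 200)
  expect_equal(unname(ts$raw[[1]][1, 1]), 0)  # no DAG at a pocket at t0
  expect_gt(mean(ts$mean[ts$time_ns > 2000, 1]), 0)
})

test_that("fingerprint percentages are a valid decomposition", {
  traj <- tiny_trajectory(dag_inner_pct = 10, seed = 41)
  fp <- contact_fingerprint(traj, site_definition("L2"), from_ns = 1000)
  sums <- tapply(fp$pct, fp$resid, sum)
  contacted <- !tapply(fp$no_contacts, fp$resid, any)
  expect_true(all(abs(sums[contacted] - 100) < 1e-6))
  # single-species membrane: that species owns every contacted residue
  sys <- tiny_system(dag_inner_pct = 0, lipids = 100, seed = 2)
  spec1 <- membrane_spec(box = c(14, 14, 12), lipids_per_leaflet = 100,
                         inner = c(PC = 100), outer = c(PC = 100))
  sysm <- build_membrane(spec1, sys$protein, seed = 3)
  sch <- simulation_schedule(restrained_us = 0.5, total_us = 2, n_repeats = 1)
  trm <- simulate_trajectory(sysm$frame, sysm$topology, binding_model(), sch,
                             seed = 4)
  fpm <- contact_fingerprint(trm, site_definition("L1"), from_ns = 0)
  expect_true(all(fpm$pct[!fpm$no_contacts & fpm$species == "PC"] == 100))
})

test_that("equilibration detection finds onsets where expected", {
  expect_equal(detect_equilibration(rep(5, 100), 1:100, window_ns = 10), 1)
  step <- c(rep(0, 50), rep(10, 150))
  onset <- detect_equilibration(step, seq_len(200), window_ns = 20)
  expect_gte(onset, 50)
  expect_error(detect_equilibration(1:5, 1:5, window_ns = 10),
               class = "lipidgate_window_error")
  # saturating series: onset strictly inside the run
  x <- 10 * (1 - exp(-(0:199) / 20))
  on2 <- detect_equilibration(x, 0:199, window_ns = 20)
  expect_true(is.finite(on2) && on2 < 199)
})
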