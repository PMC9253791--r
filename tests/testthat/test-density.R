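static_traj <- function(pos, species, box = c(2, 2, 2), frames = 10) {
  n <- nrow(pos)
  topo <- data.frame(bead_id = seq_len(n), molecule_id = seq_len(n),
                     species = species, resid = NA_integer_,
                     subunit = NA_integer_, leaflet0 = "inner")
  class(topo) <- c("lg_topology", "data.frame")
  arr <- array(rep(pos, frames), c(n, 3, frames))
  structure(list(times_ns = seq_len(frames), positions = arr, box = box,
                 topology = topo, periodic_z = FALSE),
            class = "lg_trajectory")
}

test_that("a static bead accumulates all its frames in one voxel", {
  tr <- static_traj(matrix(c(0.55, 0.25, 1.15), 1), "DAG", frames = 10)
  g <- accumulate_density(tr, "DAG", edge = 0.1)
  expect_equal(sum(g$values), 10)
  expect_equal(g$values[6, 3, 12], 10)
  expect_identical(sum(g$values > 0), 1L)
})

test_that("density counts are conserved and normalisation scales them", {
  traj <- tiny_trajectory(dag_inner_pct = 10, lipids = 60,
                          restrained_us = 0.5, total_us = 2, seed = 13)
  n_dag <- sum(traj$topology$species == "DAG")
  g <- accumulate_density(traj, "DAG", edge = 0.25)
  expect_equal(sum(g$values), n_dag * n_frames(traj))
  gn <- accumulate_density(traj, "DAG", edge = 0.25, normalize = "density")
  expect_equal(sum(gn$values) * 0.25^3 * n_frames(traj),
               n_dag * n_frames(traj))
  expect_error(accumulate_density(traj, "DAG", frames = integer()),
               class = "lipidgate_window_error")
  expect_error(accumulate_density(traj, "PC4"),
               class = "lipidgate_species_error")
})

test_that("integer-voxel translations permute voxel values", {
  tr <- static_traj(cbind(runif(40, 0, 2), runif(40, 0, 2), runif(40, 0, 2)),
                    rep("DAG", 40), frames = 1)
  g1 <- accumulate_density(tr, "DAG", edge = 0.25)
  tr$positions <- tr$positions + rep(c(0.5, 0.75, 0.25), each = 40)
  g2 <- accumulate_density(tr, "DAG", edge = 0.25)
  expect_identical(sort(as.vector(g1$values)), sort(as.vector(g2$values)))
})

test_that("OpenDX files round-trip and have a hand-checkable header", {
  g <- accumulate_density(static_traj(matrix(c(0.15, 0.15, 0.15), 1), "DAG",
                                      box = c(0.4, 0.4, 0.4), frames = 3),
                          "DAG", edge = 0.2)
  expect_identical(g$dims, c(2L, 2L, 2L))
  path <- withr::local_tempfile(fileext = ".dx")
  write_dx(g, path)
  lines <- readLines(path)
  expect_identical(lines[2], "object 1 class gridpositions counts 2 2 2")
  expect_identical(lines[3], "origin 0 0 0")
  expect_match(lines[4], "^delta 0.2")
  back <- read_dx(path)
  expect_identical(back$values, g$values)
  expect_identical(back$dims, g$dims)
  expect_equal(back$edge, g$edge)
  expect_identical(back$species, "DAG")
  expect_identical(back$n_frames, 3L)
})

test_that("DAG density is enriched near an L2 pocket vs the bulk", {
  traj <- tiny_trajectory(dag_inner_pct = 10, lipids = 150,
                          restrained_us = 1, total_us = 6, seed = 77)
  g <- accumulate_density(traj, "DAG", edge = 0.2,
                          frames = which(traj$times_ns > 2000))
  pk <- attr(traj$topology, "protein")$pockets
  l2 <- pk[pk$site == "L2", ]
  at_site <- sum(vapply(seq_len(nrow(l2)), function(i)
    integrate_density_sphere(g, c(l2$cx[i], l2$cy[i], l2$cz[i]), 1.0), 1.0))
  bulk_pts <- list(c(1.5, 1.5), c(12.5, 1.5), c(1.5, 12.5), c(12.5, 12.5))
  bulk <- sum(vapply(bulk_pts, function(p)
    integrate_density_sphere(g, c(p, l2$cz[1]), 1.0), 1.0))
  expect_gt(at_site, bulk)
})
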