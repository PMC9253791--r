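test_that("largest-remainder rounding gives exact totals and counts", {
  expect_identical(largest_remainder(c(DAG = 10, PC = 90), 400),
                   c(DAG = 40L, PC = 360L))
  set.seed(42)
  for (k in 1:20) {
    m <- sample(2:5, 1)
    w <- runif(m); pct <- 100 * w / sum(w)
    names(pct) <- paste0("s", seq_len(m))
    total <- sample(1:500, 1)
    cnt <- largest_remainder(pct, total)
    expect_identical(sum(cnt), total)
    expect_true(all(abs(cnt - pct / 100 * total) < 1))
  }
})

test_that("membrane composition validation enforces the invariants", {
  expect_error(membrane_spec(inner = c(PC = 50, PE = 49)),
               class = "lipidgate_spec_error")
  expect_error(membrane_spec(inner = c(PC = 110, PE = -10)),
               class = "lipidgate_spec_error")
  expect_error(membrane_spec(inner = c(PC = 50, XX = 50)),
               class = "lipidgate_species_error")
  # box too small for the lipid count at the stated area per lipid
  expect_error(membrane_spec(box = c(5, 5, 12), lipids_per_leaflet = 650),
               class = "lipidgate_sizing_error")
})

test_that("built membranes carry exact per-leaflet species counts", {
  sys <- tiny_system(dag_inner_pct = 10, lipids = 200, seed = 3)
  topo <- sys$topology
  lip <- topo[topo$species != "PROTEIN", ]
  expect_identical(sum(lip$leaflet0 == "inner"), 200L)
  expect_identical(sum(lip$leaflet0 == "outer"), 200L)
  expect_identical(sum(lip$species == "DAG" & lip$leaflet0 == "inner"), 20L)
  expect_identical(sum(lip$species == "DAG" & lip$leaflet0 == "outer"), 0L)
})

test_that("2% inner-leaflet DAG is 1% of all lipids with equal leaflets", {
  sys <- tiny_system(dag_inner_pct = 2, lipids = 200, seed = 1)
  lip <- sys$topology[sys$topology$species != "PROTEIN", ]
  expect_equal(100 * sum(lip$species == "DAG") / nrow(lip), 1)
})

test_that("a DAG-free composition yields a DAG-free topology", {
  sys <- tiny_system(dag_inner_pct = 0, lipids = 100, seed = 1)
  expect_false("DAG" %in% sys$topology$species)
})

test_that("lipid placement avoids the protein footprint", {
  sys <- tiny_system(lipids = 150, seed = 5)
  lip <- which(sys$topology$species != "PROTEIN")
  ctr <- sys$protein$positions[1, 1:2] * 0 + c(7, 7)
  r <- sqrt((sys$frame$positions[lip, 1] - 7)^2 +
              (sys$frame$positions[lip, 2] - 7)^2)
  # jitter can nudge a lattice site slightly inward, but never deep inside
  expect_true(all(r > sys$protein$footprint_radius - 0.5))
})
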