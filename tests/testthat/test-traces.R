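test_that("protocol validation rejects overlap and disorder", {
  expect_error(illumination_protocol(c(0, 5), c(10, 5), c(365, 430)),
               class = "lipidgate_protocol_error")
  expect_error(illumination_protocol(c(5, 0), c(1, 1), c(365, 430)),
               class = "lipidgate_protocol_error")
  expect_error(illumination_protocol(0, 10, 500),
               class = "lipidgate_protocol_error")
  ok <- illumination_protocol(c(0, 10), c(10, 10), c(365, 430))
  expect_s3_class(ok, "lg_protocol")
})

test_that("the noiseless UV current follows the closed form", {
  # p = 1, m = 0: at t - t0 = tau * ln 2 the current is baseline + A/2
  model <- trace_model(baseline = 2, A = 40, tau_s = 1.5, p = 1, m = 0,
                       noise_sd = 0)
  proto <- photocycle_protocol(n_cycles = 1, uv_s = 10, blue_s = 3)
  tr <- simulate_current_trace(model, proto, seed = 1, sample_rate_hz = 1000)
  t_half <- proto$start_s[1] + 1.5 * log(2)
  v <- approx(tr$time_s, tr$value, xout = t_half)$y
  expect_equal(v, 2 + 20, tolerance = 1e-5)
  # p = 1, m = 0 reduces to the simple exponential everywhere in the epoch
  sel <- tr$time_s >= proto$start_s[1] & tr$time_s < proto$start_s[1] + 10
  expect_equal(tr$value[sel],
               2 + 40 * (1 - exp(-(tr$time_s[sel] - proto$start_s[1]) / 1.5)),
               tolerance = 1e-12)
})

test_that("sensitized epochs produce the slow-then-fast morphology", {
  model <- trace_model(noise_sd = 0.5)
  proto <- photocycle_protocol(n_cycles = 2, uv_s = 10, blue_s = 10)
  tr <- simulate_current_trace(model, proto, seed = 3)
  res <- fit_photocycles(tr)
  expect_gt(res$fits[[1]]$par[["tau"]], res$fits[[2]]$par[["tau"]])
})

test_that("trace noise is seed-reproducible", {
  model <- trace_model()
  proto <- photocycle_protocol(n_cycles = 1)
  a <- simulate_current_trace(model, proto, seed = 9)
  b <- simulate_current_trace(model, proto, seed = 9)
  c <- simulate_current_trace(model, proto, seed = 10)
  expect_identical(a$value, b$value)
  expect_false(identical(a$value, c$value))
})

test_that("fluorescence is positive, unit at rest, and linear in amplitude", {
  proto <- photocycle_protocol(n_cycles = 2, uv_s = 10, blue_s = 10)
  flat <- trace_model(A = 0, m = 0, sens_A = 0, noise_sd = 0)
  f0 <- simulate_fluorescence(flat, proto)
  expect_true(all(f0$value == 1))

  m1 <- trace_model(A = 25, m = 0, sens_A = 0, noise_sd = 0)
  m2 <- trace_model(A = 50, m = 0, sens_A = 0, noise_sd = 0)
  f1 <- simulate_fluorescence(m1, proto)
  f2 <- simulate_fluorescence(m2, proto)
  expect_equal(max(f2$value) - 1, 2 * (max(f1$value) - 1), tolerance = 1e-9)
  expect_true(all(f1$value > 0))

  # larger sensitized amplitude -> larger second peak
  ms <- trace_model(A = 30, m = 0, sens_A = 60, sens_tau_s = 0.7, noise_sd = 0)
  fs <- simulate_fluorescence(ms, proto)
  pk <- epoch_peaks(fs, proto)
  expect_gt(pk$peak_dff0[2], pk$peak_dff0[1])
})

test_that("trace model validation enforces parameter ranges", {
  expect_error(trace_model(tau_s = 0), class = "lipidgate_validation_error")
  expect_error(trace_model(p = 0.5), class = "lipidgate_validation_error")
  expect_error(trace_model(noise_sd = -1), class = "lipidgate_validation_error")
})
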