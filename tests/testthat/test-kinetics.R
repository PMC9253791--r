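test_that("segmentation pairs UV epochs with their blue terminations", {
  proto <- photocycle_protocol(n_cycles = 2, uv_s = 10, blue_s = 10,
                               pre_blue_s = 20)
  model <- trace_model(noise_sd = 0)
  tr <- simulate_current_trace(model, proto, seed = 1)
  segs <- segment_photocycles(tr)
  expect_length(segs, 2)  # the pre-blue epoch yields no segment
  expect_equal(segs[[1]]$start_s, proto$start_s[proto$wavelength_nm == 365][1])
  # segments span UV start to blue onset
  uv1 <- which(proto$wavelength_nm == 365)[1]
  expect_lt(max(segs[[1]]$segment$time_s),
            proto$start_s[uv1] + proto$duration_s[uv1] + 1e-9)
  # an empty protocol yields an empty list
  empty <- illumination_protocol(numeric(), numeric(), numeric())
  expect_length(segment_photocycles(tr, empty), 0)
  # a UV epoch outside the samples errors
  late <- illumination_protocol(1e4, 10, 365)
  expect_error(segment_photocycles(tr, late),
               class = "lipidgate_protocol_error")
})

test_that("noiseless fits recover the generating parameters", {
  model <- trace_model(noise_sd = 0)  # A=50, tau=2, p=3.6, m=1
  proto <- photocycle_protocol(n_cycles = 2, uv_s = 10, blue_s = 10)
  tr <- simulate_current_trace(model, proto, seed = 1)
  segs <- segment_photocycles(tr)
  f1 <- fit_activation(segs[[1]]$segment, "power_exp_linear")
  expect_true(f1$converged)
  expect_equal(f1$par[["A"]], 50, tolerance = 1e-3)
  expect_equal(f1$par[["tau"]], 2, tolerance = 1e-3)
  expect_equal(f1$par[["p"]], 3.6, tolerance = 1e-3)
  expect_equal(f1$par[["m"]], 1, tolerance = 1e-3)
  f2 <- fit_activation(segs[[2]]$segment, "power_exp")
  expect_equal(f2$par[["tau"]], 2 / 3, tolerance = 1e-3)
  expect_equal(f2$par[["p"]], 2, tolerance = 1e-3)
  # idempotence: refitting the fit's own prediction returns the same theta
  pred <- predict(f1, segs[[1]]$segment$time_s)
  refit <- fit_activation(data.frame(time_s = segs[[1]]$segment$time_s,
                                     value = pred), "power_exp_linear")
  expect_equal(refit$par, f1$par, tolerance = 1e-3)
})

test_that("fixing p = 1, m = 0 reduces to a simple exponential fit", {
  tm <- seq(0, 8, by = 0.01)
  y <- 3 + 20 * (1 - exp(-tm / 1.7))
  f <- fit_activation(data.frame(time_s = tm, value = y), "power_exp_linear",
                      fix = list(p = 1, m = 0))
  expect_equal(f$par[["tau"]], 1.7, tolerance = 1e-4)
  expect_equal(f$par[["p"]], 1)
  expect_equal(f$par[["m"]], 0)
  # closed-form log-linear estimate on the same data agrees
  z <- log(1 - (y - 3) / 20); z[!is.finite(z)] <- NA
  tau_lm <- -1 / unname(coef(lm(z ~ tm - 1))[1])
  expect_equal(f$par[["tau"]], tau_lm, tolerance = 1e-4)
})

test_that("fits are scale- and shift-equivariant on noiseless data", {
  seg <- noisy_segment(seed = 1, noise_sd = 0)
  f <- fit_activation(seg, "power_exp_linear")
  seg2 <- data.frame(time_s = seg$time_s, value = 3 * seg$value)
  f2 <- fit_activation(seg2, "power_exp_linear",
                       bounds = list(m = c(-30, 30)))
  expect_equal(f2$par[["A"]], 3 * f$par[["A"]], tolerance = 1e-3)
  expect_equal(f2$par[["m"]], 3 * f$par[["m"]], tolerance = 5e-3)
  expect_equal(f2$par[["tau"]], f$par[["tau"]], tolerance = 1e-3)
  expect_equal(f2$par[["p"]], f$par[["p"]], tolerance = 1e-2)
  seg3 <- data.frame(time_s = seg$time_s + 5, value = seg$value)
  f3 <- fit_activation(seg3, "power_exp_linear")
  expect_equal(f3$t0, f$t0 + 5)
  expect_equal(f3$par[["tau"]], f$par[["tau"]], tolerance = 1e-3)
  expect_equal(f3$par[["p"]], f$par[["p"]], tolerance = 1e-3)
  expect_equal(f3$par[["A"]], f$par[["A"]], tolerance = 1e-3)
})

test_that("the optimiser never worsens its objective and flags edge cases", {
  seg <- noisy_segment(seed = 5)
  f <- fit_activation(seg, "power_exp_linear")
  expect_lte(f$loss_value, f$loss_initial)
  expect_true(f$converged)
  # degenerate flat segment: amplitude pinned at zero with a warning
  flat <- data.frame(time_s = seq(0, 5, 0.1), value = rep(2, 51))
  expect_warning(ff <- fit_activation(flat, "power_exp_linear"),
                 "flat segment")
  expect_identical(ff$par[["A"]], 0)
  expect_true(ff$degenerate)
  expect_error(fit_activation(data.frame(time_s = 1:5, value = 1:5)),
               class = "lipidgate_fit_error")
})

test_that("a bounded Levenberg-Marquardt fit cross-checks the optimiser", {
  # independent route on noiseless simple-exponential data
  tm <- seq(0, 10, by = 0.02)
  y <- 1 + 30 * (1 - exp(-tm / 2.5))
  f <- fit_activation(data.frame(time_s = tm, value = y), "power_exp_linear",
                      fix = list(p = 1, m = 0))
  nls_fit <- minpack.lm::nlsLM(
    y ~ I0 + A * (1 - exp(-tm / tau)),
    start = list(I0 = 0, A = 20, tau = 1),
    lower = c(-50, 0, 1e-3), upper = c(50, 300, 100))
  expect_equal(f$par[["tau"]], unname(coef(nls_fit)[["tau"]]),
               tolerance = 1e-4)
  expect_equal(f$par[["A"]], unname(coef(nls_fit)[["A"]]), tolerance = 1e-4)
})

test_that("sensitization is the tau fold change with flag propagation", {
  mk <- function(tau, conv = TRUE)
    lipidgate:::new_activation_fit("power_exp",
                                   c(I0 = 0, A = 1, tau = tau, p = 2),
                                   0, list(), "soft_l1", 0, 0, conv, 0, NA, 10)
  expect_equal(sensitization(mk(2), mk(2))$fold_change, 1)
  expect_equal(sensitization(mk(5), mk(1))$fold_change, 5)
  expect_true(sensitization(mk(5), mk(1))$converged)
  expect_false(sensitization(mk(5, conv = FALSE), mk(1))$converged)
})
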