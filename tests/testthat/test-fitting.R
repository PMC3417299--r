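test_that("coefficient of determination matches its definition", {
  resp <- c(8, 10, 12, 14)
  expect_equal(coefficient_of_determination(resp, resp), 1)
  expect_equal(coefficient_of_determination(rep(mean(resp), 4), resp), 0)
  expect_equal(coefficient_of_determination(c(9, 10, 12, 13), resp), 0.9)
  expect_error(coefficient_of_determination(c(1, 2), c(3, 3)),
               "zero variance")
})

test_that("paired signed-rank comparison has the exact small-sample null", {
  a <- seq(0.3, 0.75, length.out = 10)
  expect_warning(res <- compare_fits(a, a), "zero")
  expect_equal(res$p_value, 1)
  res2 <- compare_fits(a, a + 1)
  expect_equal(res2$statistic, 55)
  expect_equal(res2$p_value, 2 / 1024)
  # equal-quality fits rarely reach significance
  withr::with_seed(31, {
    p_vals <- replicate(20, {
      base <- runif(12, 0.3, 0.8)
      compare_fits(base + rnorm(12, 0, 0.05),
                   base + rnorm(12, 0, 0.05))$p_value
    })
  })
  expect_gte(mean(p_vals > 0.05), 0.9)
})

test_that("noise-free self-simulation is recovered for every model", {
  sq_c <- generate_condition_sequence("IR-C", 1)
  sq_n <- generate_condition_sequence("IR-NC", 1)
  cases <- list(
    list(model = "categorical", params = group_categorical(), seq = sq_c,
         truth = c(p_c = 0.74, w_m = 0.33, delta_x = -0.04)),
    list(model = "cuecomb", params = group_cuecomb(), seq = sq_c,
         truth = c(w_m = 0.38, w_fu = 0.55, delta_x = -0.05)),
    list(model = "basic", params = group_basic(), seq = sq_n,
         truth = c(w_m = 0.33, delta_x = -0.05))
  )
  for (cs in cases) {
    obs <- run_sequence(cs$params, cs$seq)
    fit <- fit_observer(cs$model, cs$seq, obs)
    expect_true(fit$converged)
    expect_lt(fit$ss, 1e-12)
    expect_equal(fit$par, cs$truth, tolerance = 1e-3)
    expect_equal(fit$r_squared, 1, tolerance = 1e-10)
    # zero residuals give zero-width intervals around the estimate
    expect_equal(fit$ci95[, "lower"], fit$par, tolerance = 1e-4)
    expect_equal(fit$ci95[, "upper"], fit$par, tolerance = 1e-4)
  }
})

test_that("fit results are d0-invariant", {
  sq <- generate_condition_sequence("IR-C", 1)
  obs <- run_sequence(group_categorical(), sq)
  f1 <- fit_observer("categorical", sq, obs,
                     fit_options(starts = "small", d0 = 0.01))
  f2 <- fit_observer("categorical", sq, obs,
                     fit_options(starts = "small", d0 = 0.1))
  expect_equal(f1$par, f2$par, tolerance = 1e-6)
})

test_that("confidence intervals are symmetric and widen with noise", {
  sq <- generate_condition_sequence("IR-C", 1)
  p <- group_categorical()
  fit_at <- function(noise) {
    tab <- simulate_subject(p, sq, noise_sd = noise, seed = 23)
    fit_observer("categorical", sq, tab, fit_options(starts = "small"))
  }
  f_lo <- fit_at(0.08)
  f_hi <- fit_at(0.16)
  expect_equal(f_lo$ci95[, "upper"] - f_lo$par,
               f_lo$par - f_lo$ci95[, "lower"])
  width <- function(f) f$ci95[, "upper"] - f$ci95[, "lower"]
  expect_gt(mean(width(f_hi)), mean(width(f_lo)))
  # intervals bracket the point estimate
  expect_true(all(f_hi$ci95[, "lower"] <= f_hi$par),
              all(f_hi$par <= f_hi$ci95[, "upper"]))
})

test_that("fit input validation catches misaligned and non-finite data", {
  sq <- generate_condition_sequence("IR-NC", 1)
  obs <- run_sequence(group_basic(), sq)
  expect_error(fit_observer("basic", sq, obs[1:50, ]), "do not match")
  bad <- obs
  bad$reproduced_distance_m[3] <- NA
  expect_error(fit_observer("basic", sq, bad), "non-finite")
})

test_that("categorical fits degrade gracefully when sigma_s is misspecified", {
  sq <- generate_condition_sequence("IR-C", 1)
  obs <- run_sequence(group_categorical(), sq)  # generated at sigma_s = 0.15
  for (ss in c(0.10, 0.20)) {
    f <- fit_observer("categorical", sq, obs,
                      fit_options(sigma_s = ss, starts = "small"))
    expect_true(f$converged)
    expect_gt(f$r_squared, 0.98)
    # the misspecification is absorbed mostly by the cue reliability
    expect_lt(abs(f$par[["p_c"]] - 0.74), 0.15)
    expect_lt(abs(f$par[["w_m"]] - 0.33), 0.05)
  }
})

test_that("parameter recovery harness reports near-zero noise-free bias", {
  sq <- generate_condition_sequence("IR-C", 1)
  rec <- parameter_recovery_experiment(group_categorical(), sq,
                                       noise_sd = 0, n_replicates = 1,
                                       seed = 1,
                                       options = fit_options(starts = "small"))
  expect_true(all(abs(rec$bias) < 1e-3))
  expect_equal(rec$parameter, c("p_c", "w_m", "delta_x"))
  rec_b <- parameter_recovery_experiment(group_basic(),
                                         generate_condition_sequence("IR-NC", 1),
                                         noise_sd = 0, n_replicates = 1,
                                         seed = 1,
                                         options = fit_options(starts = "small"))
  expect_true(all(abs(rec_b$bias) < 1e-3))
})
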