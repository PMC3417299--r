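test_that("log transform and back-transform behave as stated", {
  expect_equal(to_log(10, 0.01), log(1000))
  expect_equal(to_log(0.01, 0.01), 0)
  expect_equal(from_log(log(1000), 0, 0.01), 10)
  d <- c(0.5, 5, 19)
  expect_equal(from_log(to_log(d, 0.02), 0, 0.02), d)
  # a shift acts multiplicatively on the linear scale
  x <- 4.2
  expect_equal(from_log(x, -0.04, 0.01) / from_log(x, 0, 0.01), exp(-0.04))
  expect_error(to_log(-1, 0.01), "positive")
})

test_that("Kalman recursion: diffuse start, fixed point, steady state", {
  st <- kalman_state(q = 0.05, r = 0.0225)
  up <- kalman_step(st, 3.7)
  expect_equal(up$gain, 1)
  expect_equal(up$state$mean, 3.7)
  expect_equal(up$state$p, st$r)

  # q/r = 0.5 with p = 0.5 r is a fixed point with gain 0.5
  st <- kalman_state(q = 0.5, r = 1, mean = 0, p = 0.5)
  up <- kalman_step(st, 1)
  expect_equal(up$gain, 0.5)
  expect_equal(up$state$p, 0.5)
  expect_equal(up$state$mean, 0.5)

  # gains converge to the closed-form root of q/r = k^2/(1-k)
  for (rho in c(0.1625, 0.05, 1, 3)) {
    st <- kalman_state(q = rho, r = 1)
    k <- NA_real_
    for (i in 1:200) {
      up <- kalman_step(st, 0)
      st <- up$state
      k <- up$gain
    }
    k_star <- steady_state_gain(rho)
    expect_lt(abs(k - k_star), 1e-8)
    expect_equal(k_star^2 / (1 - k_star), rho)
  }
  expect_equal(steady_state_gain(0.1625), 0.33, tolerance = 1e-2)
  expect_error(kalman_state(q = 0.1, r = 0), "positive")
})

test_that("category posteriors normalize and match direct Bayes evaluation", {
  p <- categorical_params(p_c = 0.5, rho = 0.2, delta_x = 0, sigma_s = 0.15)
  st <- make_cat_state(p, mu = c(6.5, 7.5), sigma_a2 = 0.04)
  # symmetric measurement, uninformative reliability -> equal weights
  expect_equal(category_posteriors(7, 1, st, p), c(0.5, 0.5),
               ignore_attr = TRUE)
  # full reliability puts all mass on the cued category
  p1 <- categorical_params(p_c = 1, rho = 0.2, sigma_s = 0.15)
  st1 <- make_cat_state(p1, mu = c(6.5, 7.5), sigma_a2 = 0.04)
  expect_equal(category_posteriors(6.2, 2, st1, p1), c(0, 1),
               ignore_attr = TRUE)

  # generic weights equal brute-force Bayes over the two-category joint
  withr::with_seed(11, {
    for (rep in 1:20) {
      pc <- runif(1, 0.3, 1)
      pp <- categorical_params(p_c = pc, rho = 0.2, sigma_s = 0.15)
      mu <- sort(rnorm(2, 7, 0.8))
      sa2 <- runif(1, 0.01, 0.3)
      stt <- make_cat_state(pp, mu, sa2)
      s <- rnorm(1, 7, 0.7)
      cue <- sample(1:2, 1)
      w <- category_posteriors(s, cue, stt, pp)
      expect_equal(sum(w), 1)
      cue_mass <- if (cue == 1) c(pc, 1 - pc) else c(1 - pc, pc)
      joint <- cue_mass * dnorm(s, mu, sqrt(0.15^2 + sa2))
      expect_equal(w, joint / sum(joint), ignore_attr = TRUE,
                   tolerance = 1e-12)
    }
  })
  expect_error(category_posteriors(7, 3, st, p), "out of range")
})

test_that("posterior-mean estimates match grid-quadrature references", {
  withr::with_seed(21, {
    for (rep in 1:25) {
      # categorical
      pc <- runif(1, 0.4, 1)
      ss <- runif(1, 0.08, 0.3)
      p <- categorical_params(p_c = pc, rho = 0.2, sigma_s = ss)
      mu <- sort(rnorm(2, 7, 0.8))
      sa2 <- runif(1, 0.02, 0.4)
      st <- make_cat_state(p, mu, sa2)
      s <- rnorm(1, 7, 0.6)
      cue <- sample(1:2, 1)
      expect_equal(categorical_estimate(s, cue, st, p),
                   grid_posterior_mean_categorical(s, cue, mu, sa2, ss^2,
                                                   pc, n_grid = 10001),
                   tolerance = 1e-6)
      # cue combination
      pcc <- cuecomb_params(rho_t = 0.2, rho_c = 0.2, sigma_s = ss)
      mu_t <- rnorm(1, 7, 0.5)
      c_mp <- rnorm(2, 7, 0.8)
      st2 <- runif(1, 0.05, 0.8)
      sc2 <- runif(2, 0.05, 0.8)
      stc <- make_cc_state(pcc, mu_t, st2, c_mp, sc2)
      expect_equal(cuecomb_estimate(s, cue, stc, pcc),
                   grid_posterior_mean_cuecomb(s, c_mp[cue], mu_t, st2,
                                               sc2[cue], ss^2,
                                               n_grid = 10001),
                   tolerance = 1e-6)
    }
  })
})

test_that("limiting cases of the categorical estimate hold", {
  p1 <- categorical_params(p_c = 1, rho = 0.2, sigma_s = 0.15)
  st <- make_cat_state(p1, mu = c(6.4, 7.6), sigma_a2 = 0.05)
  s <- 6.9
  w_m <- 0.05 / (0.05 + 0.15^2)
  expect_equal(categorical_estimate(s, 1, st, p1),
               w_m * s + (1 - w_m) * 6.4)
  # p_c = 1/n reduces to the no-cue branch
  ph <- categorical_params(p_c = 0.5, rho = 0.2, sigma_s = 0.15)
  sth <- make_cat_state(ph, mu = c(6.4, 7.6), sigma_a2 = 0.05)
  for (s in c(6.2, 7.0, 7.9)) {
    expect_equal(categorical_estimate(s, 1, sth, ph),
                 categorical_estimate(s, NA, sth, ph))
    expect_equal(categorical_estimate(s, 2, sth, ph),
                 categorical_estimate(s, NA, sth, ph))
  }
})

test_that("cue-combination estimate: fixed point and weight algebra", {
  p <- cuecomb_params(rho_t = 0.3, rho_c = 0.3, sigma_s = 0.15)
  st <- make_cc_state(p, mu_t = 7, sigma_t2 = 0.2, c_mp = c(7, 7),
                      sigma_c2 = c(0.1, 0.1))
  expect_equal(cuecomb_estimate(7, 1, st, p), 7)
  # sigma_C^2 = sigma_S^2 gives w_m = 1/2: estimate is symmetric in (s, c_mp)
  r <- 0.15^2
  st2 <- make_cc_state(p, mu_t = 7, sigma_t2 = 0.2, c_mp = c(6.8, 7.4),
                       sigma_c2 = c(r, r))
  e_a <- cuecomb_estimate(7.2, 1, st2, p)
  st3 <- make_cc_state(p, mu_t = 7, sigma_t2 = 0.2, c_mp = c(7.2, 7.4),
                       sigma_c2 = c(r, r))
  e_b <- cuecomb_estimate(6.8, 1, st3, p)
  expect_equal(e_a, e_b)
  expect_error(cuecomb_estimate(7, NA, st, p), "cue")
})

test_that("step_trial initializes on trial 1 and updates only cued filters", {
  p <- group_categorical()
  st <- observer_state(p)
  s1 <- to_log(11, p$d0)
  res <- step_trial(st, p, 1, s1)
  expect_equal(res$reproduced_m, from_log(s1, p$delta_x, p$d0))
  expect_equal(res$state$filters$cat_1$mean, s1)
  expect_equal(res$state$filters$cat_2$mean, s1)
  expect_equal(res$state$filters$cat_1$p, p$sigma_s^2)

  # a short-cued trial leaves the long category untouched
  s2 <- to_log(7, p$d0)
  res2 <- step_trial(res$state, p, 1, s2)
  expect_equal(res2$state$filters$cat_2$mean, s1)
  expect_false(isTRUE(all.equal(res2$state$filters$cat_1$mean, s1)))
  expect_error(step_trial(res$state, p, NA, s2), "cue")
})

test_that("p_C = 1 categorical and w_fu = 1 cue-combination coincide", {
  sq <- generate_condition_sequence("IR-C", seed = 3)
  rho <- gain_to_rho(0.4)
  a <- run_sequence(categorical_params(p_c = 1, rho = rho, delta_x = -0.04),
                    sq)
  b <- run_sequence(cuecomb_params(rho_t = Inf, rho_c = rho,
                                   delta_x = -0.04), sq)
  expect_equal(a$reproduced_distance_m, b$reproduced_distance_m,
               tolerance = 1e-12)
})

test_that("deterministic runs: convergence, determinism, d0-invariance", {
  # constant-distance input drives the basic model to its fixed point
  p <- group_basic()
  const_seq <- generate_condition_sequence("IR-NC", 1)
  const_seq$sample_distance_m <- 9
  rt <- run_sequence(p, const_seq)
  target <- from_log(to_log(9, p$d0), p$delta_x, p$d0)
  gaps <- abs(rt$reproduced_distance_m - target)
  expect_true(all(diff(gaps) <= 1e-12))
  expect_equal(rt$reproduced_distance_m[100], target, tolerance = 1e-6)

  sq <- generate_condition_sequence("IR-C", 2)
  pc <- group_categorical()
  r1 <- run_sequence(pc, sq, noise_sd = 0.1, seed = 9)
  r2 <- run_sequence(pc, sq, noise_sd = 0.1, seed = 9)
  expect_identical(r1$reproduced_distance_m, r2$reproduced_distance_m)

  # changing d0 leaves every reproduced distance unchanged
  for (maker in list(
    function(d0) categorical_params(0.74, gain_to_rho(0.33), -0.04, d0 = d0),
    function(d0) cuecomb_params(0.05, 0.17, -0.05, d0 = d0),
    function(d0) basic_params(gain_to_rho(0.33), -0.05, d0 = d0)
  )) {
    ra <- run_sequence(maker(0.01), sq)
    rb <- run_sequence(maker(0.001), sq)
    expect_equal(rb$reproduced_distance_m, ra$reproduced_distance_m,
                 tolerance = 1e-10)
  }
})

test_that("estimates are monotone in the measurement for fixed state", {
  p <- group_categorical()
  st <- make_cat_state(p, mu = c(6.4, 7.6), sigma_a2 = 0.05)
  s_grid <- seq(5.5, 8.5, length.out = 60)
  for (cue in 1:2) {
    est <- vapply(s_grid, function(s) categorical_estimate(s, cue, st, p),
                  numeric(1))
    expect_true(all(diff(est) > 0))
  }
  pcc <- group_cuecomb()
  stc <- make_cc_state(pcc, mu_t = 7, sigma_t2 = 0.3, c_mp = c(6.5, 7.5),
                       sigma_c2 = c(0.1, 0.1))
  est <- vapply(s_grid, function(s) cuecomb_estimate(s, 1, stc, pcc),
                numeric(1))
  expect_true(all(diff(est) > 0))
})

test_that("state trajectories are recorded per trial and filter", {
  sq <- generate_condition_sequence("IR-C", 1)
  rt <- run_sequence(group_cuecomb(), sq, trajectory = TRUE)
  tr <- state_trajectory(rt)
  expect_equal(nrow(tr), 100 * 3)  # prior + two cue maps
  expect_setequal(unique(tr$filter_id), c("prior", "map_1", "map_2"))
  expect_true(all(tr$variance > 0))
  expect_error(state_trajectory(run_sequence(group_cuecomb(), sq)))
})
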