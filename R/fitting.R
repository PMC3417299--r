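logit <- function(p) log(p / (1 - p))
# clamped away from {0, 1} so implied noise ratios stay finite during search
invlogit <- function(x) pmin(pmax(1 / (1 + exp(-x)), 1e-12), 1 - 1e-12)

# Natural-scale parameter names per model. Weights are steady-state weights;
# the underlying q/r ratios are recovered via gain_to_rho() /
# cuecomb_rhos_from_weights().
fit_par_names <- function(model) {
  switch(model,
    basic = c("w_m", "delta_x"),
    categorical = c("p_c", "w_m", "delta_x"),
    cuecomb = c("w_m", "w_fu", "delta_x"),
    stop("unknown model: ", model)
  )
}

natural_to_transformed <- function(model, par) {
  nm <- fit_par_names(model)
  tp <- par[nm]
  for (k in setdiff(nm, "delta_x")) tp[k] <- logit(par[k])
  tp
}

transformed_to_natural <- function(model, theta) {
  nm <- fit_par_names(model)
  par <- setNames(as.numeric(theta), nm)
  for (k in setdiff(nm, "delta_x")) par[k] <- invlogit(par[k])
  par
}

params_from_natural <- function(model, par, options) {
  switch(model,
    basic = basic_params(rho = gain_to_rho(par[["w_m"]]),
                         delta_x = par[["delta_x"]],
                         d0 = options$d0, sigma_s = options$sigma_s),
    categorical = categorical_params(p_c = par[["p_c"]],
                                     rho = gain_to_rho(par[["w_m"]]),
                                     delta_x = par[["delta_x"]],
                                     d0 = options$d0,
                                     sigma_s = options$sigma_s),
    cuecomb = {
      rhos <- cuecomb_rhos_from_weights(par[["w_m"]], par[["w_fu"]])
      cuecomb_params(rho_t = rhos[["rho_t"]], rho_c = rhos[["rho_c"]],
                     delta_x = par[["delta_x"]],
                     d0 = options$d0, sigma_s = options$sigma_s)
    }
  )
}

# Deterministic (noise-free) model predictions in meters for the test trials.
predict_responses <- function(model, par, sequence, options) {
  tt <- test_trials(sequence)
  cue_idx <- cue_index_from_label(tt$cue_label)
  params <- params_from_natural(model, par, options)
  run_core(params, tt$sample_distance_m, cue_idx)$reproduced_m
}

multi_start_grid <- function(model, starts = c("full", "small")) {
  starts <- match.arg(starts)
  w_grid <- c(0.2, 0.4, 0.6)
  dx_grid <- c(-0.2, 0, 0.2)
  if (starts == "small") {
    w_grid <- 0.4
    dx_grid <- 0
  }
  g <- switch(model,
    basic = expand.grid(w_m = w_grid, delta_x = dx_grid),
    categorical = expand.grid(p_c = if (starts == "small") 0.75 else
                                c(0.55, 0.75, 0.95),
                              w_m = w_grid, delta_x = dx_grid),
    cuecomb = expand.grid(w_m = w_grid,
                          w_fu = if (starts == "small") 0.5 else
                            c(0.25, 0.5, 0.75),
                          delta_x = dx_grid)
  )
  g[fit_par_names(model)]
}

#' Options for observer model fitting
#'
#' @param sigma_s Log-scale measurement noise SD held fixed during fitting
#'   (same role as in simulation; only the categorical density evaluations
#'   depend on its absolute value).
#' @param d0 Normalization constant (meters); fits are invariant to it.
#' @param starts `"full"` for the complete multi-start grid, `"small"` for a
#'   single central start (faster; adequate for well-behaved data).
#' @param maxiter,ftol,ptol Levenberg-Marquardt control settings.
#' @return A list of class `fit_options`.
#' @export
fit_options <- function(sigma_s = 0.15, d0 = 0.01, starts = "full",
                        maxiter = 200, ftol = 1e-13, ptol = 1e-13) {
  stopifnot(sigma_s > 0, d0 > 0)
  structure(list(sigma_s = sigma_s, d0 = d0, starts = starts,
                 maxiter = maxiter, ftol = ftol, ptol = ptol),
            class = "fit_options")
}

#' Fit an observer model to a response series
#'
#' Estimates the model's free parameters by minimizing the summed squared
#' differences between the deterministic model prediction and the observed
#' reproduced distance on every test trial (Levenberg-Marquardt via
#' [minpack.lm::nls.lm()]). Free parameters: shift term `delta_x` plus the
#' steady-state measurement weight `w_m` (basic), the cue reliability `p_c`
#' and `w_m` (categorical), or `w_m` and the fusion weight `w_fu`
#' (cue-combination). Weights and probabilities are optimized on the logit
#' scale to respect their bounds; reported on the natural scale together
#' with the implied `q/r` ratios. A fixed multi-start grid guards against
#' local minima; the best start wins.
#'
#' @param model `"basic"`, `"categorical"`, or `"cuecomb"`.
#' @param sequence The `trial_sequence` the responses were collected on.
#' @param responses A `response_table` (or data frame with columns
#'   `sample_distance_m`, `reproduced_distance_m`) aligned with the
#'   sequence's test trials.
#' @param options A [fit_options()] list.
#' @return An `observer_fit` object: list with `model`, `par` (natural
#'   scale), `rho` (implied noise ratios), `ci95` (from
#'   [parameter_cis()]), `predictions`, `residuals`, `ss`, `r_squared`,
#'   `converged`, `n_evals`, `options`.
#' @examples
#' sq <- generate_condition_sequence("IR-NC", seed = 1)
#' pars <- basic_params(rho = gain_to_rho(0.33), delta_x = -0.05)
#' obs <- run_sequence(pars, sq)
#' fit <- fit_observer("basic", sq, obs, fit_options(starts = "small"))
#' fit$par
#' @export
fit_observer <- function(model, sequence, responses,
                         options = fit_options()) {
  model <- match.arg(model, c("basic", "categorical", "cuecomb"))
  tt <- test_trials(sequence)
  obs <- responses$reproduced_distance_m
  if (length(obs) != nrow(tt)) {
    stop("responses (", length(obs), ") do not match the sequence's ",
         nrow(tt), " test trials")
  }
  if (any(!is.finite(obs))) stop("non-finite reproduced distances")

  big <- 1e6
  resid_fun <- function(theta) {
    if (any(!is.finite(theta))) return(rep(big, length(obs)))
    par <- transformed_to_natural(model, theta)
    res <- predict_responses(model, par, sequence, options) - obs
    res[!is.finite(res)] <- big
    res
  }

  grid <- multi_start_grid(model, options$starts)
  best <- NULL
  n_evals <- 0L
  ctrl <- minpack.lm::nls.lm.control(maxiter = options$maxiter,
                                     ftol = options$ftol,
                                     ptol = options$ptol)
  for (i in seq_len(nrow(grid))) {
    theta0 <- natural_to_transformed(model, unlist(grid[i, ]))
    fit <- minpack.lm::nls.lm(par = theta0, fn = resid_fun, control = ctrl)
    n_evals <- n_evals + fit$niter
    if (any(!is.finite(unlist(fit$par)))) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
    if (best$deviance < 1e-18) break
  }

  par <- transformed_to_natural(model, best$par)
  preds <- predict_responses(model, par, sequence, options)
  resid <- obs - preds
  ss <- sum(resid^2)
  rho <- switch(model,
    basic = c(rho = unname(gain_to_rho(par[["w_m"]]))),
    categorical = c(rho = unname(gain_to_rho(par[["w_m"]]))),
    cuecomb = cuecomb_rhos_from_weights(par[["w_m"]], par[["w_fu"]])
  )
  out <- structure(list(
    model = model, par = par, rho = rho, ci95 = NULL,
    predictions = preds, residuals = resid, ss = ss,
    r_squared = coefficient_of_determination(preds, obs),
    converged = best$info %in% 1:4, n_evals = n_evals,
    options = options, sequence = sequence
  ), class = "observer_fit")
  out$ci95 <- parameter_cis(out, responses)
  out
}

#' @export
print.observer_fit <- function(x, ...) {
  cat("<observer_fit>", x$model, "model,",
      length(x$predictions), "trials\n")
  est <- rbind(estimate = x$par, lower = x$ci95[, 1], upper = x$ci95[, 2])
  print(round(est, 4))
  cat("R-squared:", format(x$r_squared, digits = 4),
      " SS:", format(x$ss, digits = 4),
      " converged:", x$converged, "\n")
  invisible(x)
}

#' Asymptotic 95% confidence intervals for fitted parameters
#'
#' Standard nonlinear-regression intervals from the Jacobian of the model
#' predictions with respect to the natural-scale parameters at the optimum:
#' residual variance `s^2 = SS/(N - P)`, covariance `s^2 (J'J)^{-1}`, and
#' `estimate +/- t_{0.975, N-P} * sqrt(diag)`. A singular `J'J` yields
#' unbounded intervals with a warning.
#'
#' @param fit An `observer_fit`.
#' @param responses The response table the fit was computed on (unused
#'   beyond length checking; residuals are taken from the fit).
#' @return Matrix with one row per parameter, columns `lower`, `upper`.
#' @export
parameter_cis <- function(fit, responses = NULL) {
  stopifnot(inherits(fit, "observer_fit"))
  par <- fit$par
  nm <- names(par)
  n <- length(fit$predictions)
  p <- length(par)
  J <- matrix(0, n, p, dimnames = list(NULL, nm))
  for (k in nm) {
    h <- 1e-5 * max(1, abs(par[[k]]))
    lo <- hi <- par
    hi[k] <- par[[k]] + h
    lo[k] <- par[[k]] - h
    # keep probability/weight parameters strictly inside (0, 1)
    if (k != "delta_x") {
      hi[k] <- min(hi[k], 1 - 1e-12)
      lo[k] <- max(lo[k], 1e-12)
    }
    J[, k] <- (predict_responses(fit$model, hi, fit$sequence, fit$options) -
                 predict_responses(fit$model, lo, fit$sequence,
                                   fit$options)) / (hi[k] - lo[k])
  }
  s2 <- fit$ss / (n - p)
  jtj <- crossprod(J)
  cov <- tryCatch(s2 * solve(jtj), error = function(e) NULL)
  if (is.null(cov) || any(!is.finite(diag(cov))) || any(diag(cov) < 0)) {
    warning("singular Jacobian cross-product; reporting unbounded intervals")
    se <- rep(Inf, p)
  } else {
    se <- sqrt(diag(cov))
  }
  half <- qt(0.975, df = n - p) * se
  cbind(lower = par - half, upper = par + half)
}

#' Coefficient of determination
#'
#' `R^2 = 1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)`: the
#' proportion of response variability accounted for by the model
#' predictions.
#'
#' @param predictions,responses Equal-length numeric vectors (`responses`
#'   may also be a `response_table`).
#' @return A single number `<= 1` (negative when the model does worse than
#'   the response mean).
#' @export
coefficient_of_determination <- function(predictions, responses) {
  if (is.data.frame(responses)) responses <- responses$reproduced_distance_m
  stopifnot(length(predictions) == length(responses),
            length(responses) >= 2)
  ss_tot <- sum((responses - mean(responses))^2)
  if (ss_tot == 0) stop("responses have zero variance; R-squared undefined")
  1 - sum((responses - predictions)^2) / ss_tot
}

# Exact two-sided signed-rank p-value under the sign-flip null, supporting
# tied |differences| via midranks (doubled to stay on an integer lattice).
# Dynamic programming over the distribution of W = sum of ranks of the
# positive differences.
exact_signed_rank_p <- function(d) {
  r2 <- round(2 * rank(abs(d)))      # doubled midranks: integers
  w_obs <- sum(r2[d > 0])
  total <- sum(r2)
  dist <- numeric(total + 1)         # index = value + 1
  dist[1] <- 1
  for (w in r2) {
    shifted <- c(rep(0, w), dist[seq_len(total + 1 - w)])
    dist <- (dist + shifted) / 2
  }
  p_le <- sum(dist[seq_len(w_obs + 1)])
  p_ge <- sum(dist[(w_obs + 1):(total + 1)])
  min(1, 2 * min(p_le, p_ge))
}

#' Compare per-subject goodness of fit of two models
#'
#' Paired two-sided Wilcoxon signed-rank test on per-subject `R^2` values:
#' the exact sign-flip null distribution is enumerated for 25 or fewer
#' nonzero differences (ties in the absolute differences handled by
#' midranks), with the normal approximation (continuity-corrected, via
#' [stats::wilcox.test()]) above. Zero differences are dropped; identical
#' lists give `p = 1` with a warning.
#'
#' @param r2_model_a,r2_model_b Paired numeric vectors (length `>= 5`).
#' @return List with `statistic` (signed-rank V of `b - a`), `p_value`,
#'   `n_nonzero`.
#' @export
compare_fits <- function(r2_model_a, r2_model_b) {
  stopifnot(length(r2_model_a) == length(r2_model_b),
            length(r2_model_a) >= 5)
  d <- r2_model_b - r2_model_a
  d <- d[d != 0]
  if (length(d) == 0) {
    warning("all paired differences are zero; p = 1 by convention")
    return(list(statistic = NA_real_, p_value = 1, n_nonzero = 0L))
  }
  v <- sum(rank(abs(d))[d > 0])
  p <- if (length(d) <= 25) {
    exact_signed_rank_p(d)
  } else {
    suppressWarnings(
      wilcox.test(d, alternative = "two.sided", mu = 0, exact = FALSE,
                  correct = TRUE)$p.value
    )
  }
  list(statistic = v, p_value = p, n_nonzero = length(d))
}

#' Simulate-and-refit parameter recovery
#'
#' Simulates `n_replicates` synthetic subjects from known parameters, refits
#' the generating model to each, and summarizes per-parameter bias and RMSE.
#' With `noise_sd = 0` and one replicate this is the self-consistency check:
#' bias should vanish to optimizer tolerance.
#'
#' @param params Generating `observer_params`.
#' @param sequence A `trial_sequence`.
#' @param noise_sd Measurement noise SD for the simulated subjects.
#' @param n_replicates Number of simulate-fit replicates.
#' @param seed Master seed.
#' @param options [fit_options()] used for refitting.
#' @return Tibble with columns `parameter`, `true`, `mean_estimate`, `bias`,
#'   `rmse`; the individual fits are attached as attribute `fits`.
#' @export
parameter_recovery_experiment <- function(params, sequence, noise_sd = 0,
                                          n_replicates = 1, seed = 1,
                                          options = fit_options()) {
  stopifnot(inherits(params, "observer_params"), n_replicates >= 1)
  model <- params$model
  w <- steady_state_weights(params)
  true_par <- switch(model,
    basic = c(w_m = unname(w[["w_m"]]), delta_x = params$delta_x),
    categorical = c(p_c = params$p_c, w_m = unname(w[["w_m"]]),
                    delta_x = params$delta_x),
    cuecomb = c(w_m = unname(w[["w_m"]]), w_fu = unname(w[["w_fu"]]),
                delta_x = params$delta_x)
  )
  cohort <- simulate_cohort(n_replicates, params, sequence,
                            noise_sd = noise_sd, seed = seed)
  fits <- lapply(cohort, function(tab) {
    fit_observer(model, sequence, tab, options)
  })
  est <- t(vapply(fits, function(f) f$par, true_par))
  summ <- tibble::tibble(
    parameter = names(true_par),
    true = unname(true_par),
    mean_estimate = colMeans(est),
    bias = colMeans(est) - unname(true_par),
    rmse = sqrt(colMeans((t(t(est) - unname(true_par)))^2))
  )
  attr(summ, "fits") <- fits
  summ
}
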