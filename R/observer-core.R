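#' Logarithmic stimulus representation
#'
#' Magnitudes are represented internally on a natural-log scale
#' (Weber-Fechner): `to_log()` maps a distance in meters to the unit-free
#' internal value `ln(d_m / d0)`; `from_log()` maps a log-scale estimate back
#' to meters, `d_r = exp(x_est + delta_x) * d0`, where the shift term
#' `delta_x` selects the loss function (mean/median/mode of the log-normal
#' posterior differ by a constant log-scale shift).
#'
#' @param d_m Distance in meters (positive).
#' @param d0 Normalization constant in meters (positive, much smaller than 1).
#' @param x_est Log-scale estimate.
#' @param delta_x Shift term, log-units.
#' @return Numeric vector: log-units (`to_log`) or meters (`from_log`).
#' @examples
#' to_log(10, 0.01)           # log(1000)
#' from_log(log(1000), 0, 0.01)  # 10
#' @export
to_log <- function(d_m, d0) {
  if (any(d_m <= 0) || any(d0 <= 0)) stop("distances and d0 must be positive")
  log(d_m / d0)
}

#' @rdname to_log
#' @export
from_log <- function(x_est, delta_x, d0) {
  if (any(d0 <= 0)) stop("d0 must be positive")
  exp(x_est + delta_x) * d0
}

#' Scalar Kalman filter for a random-walk state
#'
#' The observers' learnable states (category means, mapped cue values, the
#' global prior mean) each follow a random walk `x_i = x_{i-1} + n_q`
#' observed through `y_i = x_i + n_r`, with process noise variance `q` and
#' measurement noise variance `r`. For this system the Kalman recursion
#' reduces to
#' \deqn{k_i = (p_{i-1} + q) / (p_{i-1} + q + r), \quad p_i = k_i r, \quad
#'       \hat x_i = (1 - k_i)\hat x_{i-1} + k_i y_i.}
#' A filter starts diffuse (no estimate): its first update has gain 1, so the
#' state is initialized with the first observation and `p = r`.
#'
#' @param q Process noise variance (log-units squared, `>= 0`; `Inf` allowed).
#' @param r Measurement noise variance (log-units squared, positive).
#' @param mean Optional initial state mean (default: diffuse, no estimate).
#' @param p Optional initial a-posteriori variance (required with `mean`).
#' @param state A `kalman_state`.
#' @param y Observation (log-units, finite).
#' @return `kalman_state()` returns a `kalman_state` object; `kalman_step()`
#'   a list with elements `state` (updated) and `gain`;
#'   `a_priori_variance()` the current a-priori variance `p + q` (infinite
#'   while diffuse).
#' @examples
#' st <- kalman_state(q = 0.1, r = 1)
#' kalman_step(st, 2.5)$gain   # 1: diffuse first update
#' @export
kalman_state <- function(q, r, mean = NA_real_, p = NA_real_) {
  if (!is.finite(r) || r <= 0) stop("measurement noise variance r must be positive")
  if (q < 0) stop("process noise variance q must be nonnegative")
  if (!is.na(mean) && is.na(p)) stop("initial mean requires an initial variance p")
  structure(list(mean = mean, p = p, q = q, r = r,
                 n_updates = if (is.na(mean)) 0L else 1L),
            class = "kalman_state")
}

#' @rdname kalman_state
#' @export
kalman_step <- function(state, y) {
  stopifnot(inherits(state, "kalman_state"), is.finite(y))
  if (state$n_updates == 0L) {
    k <- 1
  } else {
    prior_var <- state$p + state$q
    k <- if (is.infinite(prior_var)) 1 else prior_var / (prior_var + state$r)
  }
  state$mean <- if (k == 1) y else (1 - k) * state$mean + k * y
  state$p <- k * state$r
  state$n_updates <- state$n_updates + 1L
  list(state = state, gain = k)
}

#' @rdname kalman_state
#' @export
a_priori_variance <- function(state) {
  stopifnot(inherits(state, "kalman_state"))
  if (state$n_updates == 0L) Inf else state$p + state$q
}

#' Create the learnable state of an observer model
#'
#' Bundles the Kalman filters a model learns with: a single prior filter for
#' the basic model; one filter per category mean for the categorical model;
#' a global prior filter plus one mapped-cue filter per cue value for the
#' cue-combination model. All filters start diffuse and are initialized with
#' the first observation by [step_trial()].
#'
#' @param params An `observer_params` object.
#' @param n_cues Number of distinct cue values in the design (default 2).
#' @return An `observer_state` object: list with elements `model`,
#'   `filters` (named list of `kalman_state`s), `initialized`.
#' @export
observer_state <- function(params, n_cues = 2L) {
  stopifnot(inherits(params, "observer_params"))
  r <- params$sigma_s^2
  filters <- switch(params$model,
    basic = list(prior = kalman_state(params$rho * r, r)),
    categorical = setNames(
      replicate(params$n_categories, kalman_state(params$rho * r, r),
                simplify = FALSE),
      paste0("cat_", seq_len(params$n_categories))),
    cuecomb = c(
      list(prior = kalman_state(params$rho_t * r, r)),
      setNames(replicate(n_cues, kalman_state(params$rho_c * r, r),
                         simplify = FALSE),
               paste0("map_", seq_len(n_cues)))),
    stop("unknown model: ", params$model)
  )
  structure(list(model = params$model, filters = filters, initialized = FALSE),
            class = "observer_state")
}

#' Posterior category probabilities given measurement and symbolic cue
#'
#' Evaluates the categorical model's posterior over categories,
#' `P(a_i | s, c_j) = P(c_j | a_i) * alpha_{i,j}(s)`, where the presented cue
#' is correct with reliability `p_c` and wrong cues share the remaining mass
#' `(1 - p_c)/(n - 1)`, and `alpha_{i,j}(s)` is the normalized measurement
#' evidence with `S | A ~ N(mu_A, sigma_S^2 + sigma_A^2)`. Each category's
#' `sigma_A^2` is its filter's current a-priori variance. With
#' `cue_index = NA` (no cue / uninformative cue `P(c|a) = 1/n`) the weights
#' reduce to the measurement evidence alone.
#'
#' If all category densities underflow (measurement far outside the learned
#' range) the weights fall back to the cue-only masses.
#'
#' @param s Log-scale measurement.
#' @param cue_index Integer cue/category index, or `NA` for no cue.
#' @param state An initialized `observer_state` for the categorical model.
#' @param params `categorical_params()`.
#' @return Numeric vector of category weights (nonnegative, summing to 1).
#' @export
category_posteriors <- function(s, cue_index, state, params) {
  stopifnot(inherits(state, "observer_state"), state$model == "categorical")
  if (!state$initialized) stop("observer state is not initialized")
  n <- params$n_categories
  mu <- vapply(state$filters, function(f) f$mean, numeric(1))
  var_a <- vapply(state$filters, a_priori_variance, numeric(1))
  dens <- dnorm(s, mean = mu, sd = sqrt(params$sigma_s^2 + var_a))
  cue_mass <- if (is.na(cue_index)) {
    rep(1 / n, n)
  } else {
    if (cue_index < 1 || cue_index > n) stop("cue_index out of range")
    m <- rep((1 - params$p_c) / (n - 1), n)
    m[cue_index] <- params$p_c
    m
  }
  num <- cue_mass * dens
  tot <- sum(num)
  if (!is.finite(tot) || tot <= 0) return(cue_mass / sum(cue_mass))
  num / tot
}

# Measurement weight w_m = sigma_A^2 / (sigma_A^2 + sigma_S^2), evaluated at
# a given a-priori variance; equals the Kalman gain that filter would apply.
measurement_weight <- function(var_a, r) {
  if (is.infinite(var_a)) 1 else var_a / (var_a + r)
}

#' Posterior-mean estimates of the observer models
#'
#' `categorical_estimate()` computes the categorical model's posterior mean
#' \deqn{E[T|s,c_j] = w_m s + (1 - w_m) \sum_i P(a_i|s,c_j)\,\mu_{a_i},}
#' with `w_m` derived from the cued category filter's current a-priori
#' variance (`w_m = sigma_A^2 / (sigma_A^2 + sigma_S^2)`, the running Kalman
#' gain). With `cue_index = NA` the uninformative-cue reduction is used
#' (category weights from the measurement alone; `w_m` from the mean
#' a-priori variance across categories).
#'
#' `cuecomb_estimate()` computes the cue-combination model's posterior mean
#' \deqn{E[T|s,c_{mp}] = (1 - w_{fu})\,\mu_T +
#'       w_{fu}\,[(1 - w_m)\,c_{mp} + w_m s],}
#' with `w_m = sigma_C^2 / (sigma_S^2 + sigma_C^2)`,
#' `sigma_CS^2 = sigma_C^2 sigma_S^2 / (sigma_C^2 + sigma_S^2)` and
#' `w_fu = sigma_T^2 / (sigma_T^2 + sigma_CS^2)`, where `sigma_T^2` and
#' `sigma_C^2` are the current a-priori variances of the prior and the cued
#' mapping filter and `sigma_S^2 = r`.
#'
#' `basic_estimate()` is the single-prior special case
#' `w_m s + (1 - w_m) mu_T`.
#'
#' @param s Log-scale measurement.
#' @param cue_index Integer cue index (`NA` allowed only for the categorical
#'   no-cue branch).
#' @param state Initialized `observer_state` of the matching model.
#' @param params The matching `observer_params`.
#' @return The log-scale posterior-mean estimate (numeric scalar).
#' @export
categorical_estimate <- function(s, cue_index, state, params) {
  w <- category_posteriors(s, cue_index, state, params)
  mu <- vapply(state$filters, function(f) f$mean, numeric(1))
  var_a <- if (is.na(cue_index)) {
    mean(vapply(state$filters, a_priori_variance, numeric(1)))
  } else {
    a_priori_variance(state$filters[[cue_index]])
  }
  w_m <- measurement_weight(var_a, params$sigma_s^2)
  w_m * s + (1 - w_m) * sum(w * mu)
}

#' @rdname categorical_estimate
#' @export
cuecomb_estimate <- function(s, cue_index, state, params) {
  stopifnot(inherits(state, "observer_state"), state$model == "cuecomb")
  if (!state$initialized) stop("observer state is not initialized")
  if (is.na(cue_index)) stop("cue-combination estimate requires a cue")
  map <- state$filters[[paste0("map_", cue_index)]]
  if (is.null(map)) stop("cue_index out of range")
  r <- params$sigma_s^2
  sigma_t2 <- a_priori_variance(state$filters$prior)
  sigma_c2 <- a_priori_variance(map)
  w_m <- measurement_weight(sigma_c2, r)
  sigma_cs2 <- if (is.infinite(sigma_c2)) r else sigma_c2 * r / (sigma_c2 + r)
  w_fu <- if (is.infinite(sigma_t2)) 1 else sigma_t2 / (sigma_t2 + sigma_cs2)
  fused <- (1 - w_m) * map$mean + w_m * s
  if (w_fu == 1) fused else (1 - w_fu) * state$filters$prior$mean + w_fu * fused
}

#' @rdname categorical_estimate
#' @export
basic_estimate <- function(s, state, params) {
  stopifnot(inherits(state, "observer_state"), state$model == "basic")
  if (!state$initialized) stop("observer state is not initialized")
  f <- state$filters$prior
  w_m <- measurement_weight(a_priori_variance(f), params$sigma_s^2)
  w_m * s + (1 - w_m) * f$mean
}

#' Run one trial of an observer model
#'
#' Produces the model's response for the current trial from the *pre-update*
#' state, then performs the trial's learning step: the basic model updates
#' its prior filter with the measurement; the categorical model updates only
#' the cued category's filter; the cue-combination model updates both the
#' global prior filter and the cued mapping filter. On the first trial all
#' filters are initialized with the first observation (diffuse gain-1
#' update) and the response equals the back-transformed measurement.
#'
#' @param state An `observer_state`.
#' @param params The matching `observer_params`.
#' @param cue_index Integer cue index (`NA` for the basic model / no cue).
#' @param s Log-scale measurement of the trial's sample distance.
#' @return List with `reproduced_m` (meters), `x_est` (log-units), `state`
#'   (post-update), and `gains` (named numeric, the gains applied).
#' @export
step_trial <- function(state, params, cue_index, s) {
  stopifnot(inherits(state, "observer_state"),
            inherits(params, "observer_params"),
            state$model == params$model)
  gains <- c()
  if (!state$initialized) {
    x_est <- s
    for (nm in names(state$filters)) {
      up <- kalman_step(state$filters[[nm]], s)
      state$filters[[nm]] <- up$state
      gains[nm] <- up$gain
    }
    state$initialized <- TRUE
  } else {
    x_est <- switch(state$model,
      basic = basic_estimate(s, state, params),
      categorical = categorical_estimate(s, cue_index, state, params),
      cuecomb = cuecomb_estimate(s, cue_index, state, params)
    )
    upd <- switch(state$model,
      basic = "prior",
      categorical = {
        if (is.na(cue_index)) stop("categorical update requires a cue")
        paste0("cat_", cue_index)
      },
      cuecomb = {
        if (is.na(cue_index)) stop("cue-combination update requires a cue")
        c("prior", paste0("map_", cue_index))
      }
    )
    for (nm in upd) {
      up <- kalman_step(state$filters[[nm]], s)
      state$filters[[nm]] <- up$state
      gains[nm] <- up$gain
    }
  }
  list(reproduced_m = from_log(x_est, params$delta_x, params$d0),
       x_est = x_est, state = state, gains = gains)
}

# Fast inner loop shared by run_sequence() and the fitter: takes raw vectors,
# returns reproduced distances (meters) and optionally the state trajectory.
run_core <- function(params, d_m, cue_idx, noise = 0, trajectory = FALSE) {
  n <- length(d_m)
  s <- log(d_m / params$d0) + noise
  state <- observer_state(params)
  out <- numeric(n)
  traj <- if (trajectory) vector("list", n) else NULL
  for (i in seq_len(n)) {
    res <- step_trial(state, params, cue_idx[i], s[i])
    state <- res$state
    out[i] <- res$reproduced_m
    if (trajectory) {
      fid <- names(state$filters)
      traj[[i]] <- data.frame(
        trial = i, filter_id = fid,
        mean = vapply(state$filters, function(f) f$mean, numeric(1)),
        variance = vapply(state$filters, function(f) f$p, numeric(1)),
        gain = unname(res$gains[fid]),
        row.names = NULL
      )
    }
  }
  list(reproduced_m = out,
       trajectory = if (trajectory) do.call(rbind, traj) else NULL)
}

cue_index_from_label <- function(labels) {
  idx <- match(labels, CUE_LEVELS)
  idx
}

#' Run an observer model over a trial sequence
#'
#' Feeds the test trials of a sequence to an observer model in order and
#' collects its reproduced distances. With `noise_sd = 0` (default) the run
#' is the deterministic model prediction (`s_i = ln(d_i/d0)`); with
#' `noise_sd > 0`, seeded Gaussian measurement noise is added on the log
#' scale (`s_i = ln(d_i/d0) + e_i`, `e_i ~ N(0, noise_sd^2)`).
#'
#' The categorical and cue-combination models require cue labels and are
#' therefore only applicable to the cued condition; the basic model ignores
#' cues and applies to any condition.
#'
#' @param params An `observer_params` object (selects the model).
#' @param sequence A `trial_sequence`.
#' @param noise_sd Log-scale measurement noise SD (`>= 0`).
#' @param seed Seed for the measurement noise (required if `noise_sd > 0`).
#' @param trajectory If `TRUE`, attach the per-trial filter trajectory.
#' @return A `response_table`: tibble with columns `index`, `condition`,
#'   `cue_label`, `range_label`, `sample_distance_m`,
#'   `reproduced_distance_m`; attributes `model`, `params`, `noise_sd`,
#'   `seed`, and (optionally) `trajectory`.
#' @examples
#' sq <- generate_condition_sequence("IR-C", seed = 1)
#' pars <- categorical_params(p_c = 0.74, rho = gain_to_rho(0.33),
#'                            delta_x = -0.04)
#' head(run_sequence(pars, sq))
#' @export
run_sequence <- function(params, sequence, noise_sd = 0, seed = NULL,
                         trajectory = FALSE) {
  stopifnot(inherits(params, "observer_params"), noise_sd >= 0)
  tt <- test_trials(sequence)
  cue_idx <- cue_index_from_label(tt$cue_label)
  if (params$model != "basic" && anyNA(cue_idx)) {
    stop("the ", params$model,
         " model requires cue labels on every test trial")
  }
  noise <- if (noise_sd > 0) {
    if (is.null(seed)) stop("seed required when noise_sd > 0")
    withr::with_seed(as.integer(seed),
                     rnorm(nrow(tt), 0, noise_sd))
  } else {
    0
  }
  core <- run_core(params, tt$sample_distance_m, cue_idx,
                   noise = noise, trajectory = trajectory)
  out <- tibble::tibble(
    index = tt$index,
    condition = tt$condition,
    cue_label = tt$cue_label,
    range_label = tt$range_label,
    sample_distance_m = tt$sample_distance_m,
    reproduced_distance_m = core$reproduced_m
  )
  structure(out, class = c("response_table", class(out)),
            model = params$model, params = params, noise_sd = noise_sd,
            seed = seed,
            trajectory = if (trajectory) tibble::as_tibble(core$trajectory))
}

#' Export a run's filter trajectory
#'
#' @param responses A `response_table` produced with `trajectory = TRUE`.
#' @return Tibble `trial, filter_id, mean, variance, gain`.
#' @export
state_trajectory <- function(responses) {
  tr <- attr(responses, "trajectory")
  if (is.null(tr)) stop("responses were produced without trajectory = TRUE")
  tr
}
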