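#' Steady-state Kalman gain and its inverse
#'
#' For the random-walk state-space model used by the observers, the Kalman
#' gain converges to a fixed point `k*` determined only by the process- to
#' measurement-noise ratio `rho = q/r`, via `rho = k*^2 / (1 - k*)`.
#' `steady_state_gain()` solves for `k*` given `rho`; `gain_to_rho()` is the
#' inverse mapping. The steady-state gain equals the asymptotic measurement
#' weight `w_m`, which is how fitted ratios are reported.
#'
#' @param rho Nonnegative process/measurement noise variance ratio `q/r`.
#'   `Inf` is allowed and maps to gain 1.
#' @param w Gain/weight in `[0, 1)` (1 allowed, mapping to `rho = Inf`).
#' @return A numeric vector.
#' @examples
#' steady_state_gain(0.5)            # 0.5: q/r = 0.25/0.5
#' gain_to_rho(steady_state_gain(2)) # 2
#' @export
steady_state_gain <- function(rho) {
  stopifnot(all(rho >= 0))
  ifelse(is.infinite(rho), 1, (-rho + sqrt(rho^2 + 4 * rho)) / 2)
}

#' @rdname steady_state_gain
#' @export
gain_to_rho <- function(w) {
  stopifnot(all(w >= 0), all(w <= 1))
  ifelse(w == 1, Inf, w^2 / (1 - w))
}

new_observer_params <- function(model, fields) {
  structure(c(list(model = model), fields), class = "observer_params")
}

#' Observer model parameter sets
#'
#' Constructors for the three observer models' parameters. All models share:
#'
#' * `delta_x`: the shift term (log-units) encoding the estimator's loss
#'   function -- the mean, median, and mode of the log-normal posterior on the
#'   linear scale differ by a constant shift of the log-scale estimate.
#' * `d0`: normalization constant (meters, much smaller than 1) making the
#'   log representation `ln(d/d0)` unit-free. Results are invariant to `d0`.
#' * `sigma_s`: measurement noise SD on the log scale. Only the categorical
#'   model's density evaluations depend on its absolute value; for the other
#'   models only noise *ratios* matter. It also scales the simulator's
#'   measurement noise.
#'
#' Model-specific parameters:
#'
#' * `basic_params()`: `rho = q/r` for the single prior filter; the
#'   steady-state gain of that filter is the measurement weight `w_m`.
#' * `categorical_params()`: cue reliability `p_c` (probability that the
#'   presented cue names the generating category), `rho` shared by the
#'   per-category filters, and the number of categories `n_categories`.
#' * `cuecomb_params()`: `rho_t` for the global prior filter and `rho_c`
#'   shared by the per-cue mapping filters; their steady states determine the
#'   fusion weight `w_fu` and measurement weight `w_m`.
#'
#' @param rho,rho_t,rho_c Nonnegative noise variance ratios `q/r`
#'   (dimensionless); `rho_t = Inf` gives fusion weight 1.
#' @param p_c Cue reliability in `[0, 1]`.
#' @param delta_x Shift term, log-units.
#' @param d0 Normalization constant, meters.
#' @param sigma_s Log-scale measurement noise SD (positive).
#' @param n_categories Number of categories (>= 2).
#' @return An `observer_params` object (a classed list).
#' @examples
#' categorical_params(p_c = 0.74, rho = gain_to_rho(0.33), delta_x = -0.04)
#' @export
basic_params <- function(rho, delta_x = 0, d0 = 0.01, sigma_s = 0.15) {
  stopifnot(rho >= 0, d0 > 0, sigma_s > 0, is.finite(delta_x))
  new_observer_params("basic", list(rho = rho, delta_x = delta_x, d0 = d0,
                                    sigma_s = sigma_s))
}

#' @rdname basic_params
#' @export
categorical_params <- function(p_c, rho, delta_x = 0, d0 = 0.01,
                               sigma_s = 0.15, n_categories = 2L) {
  stopifnot(p_c >= 0, p_c <= 1, rho >= 0, d0 > 0, sigma_s > 0,
            is.finite(delta_x), n_categories >= 2)
  new_observer_params("categorical",
                      list(p_c = p_c, rho = rho, delta_x = delta_x, d0 = d0,
                           sigma_s = sigma_s,
                           n_categories = as.integer(n_categories)))
}

#' @rdname basic_params
#' @export
cuecomb_params <- function(rho_t, rho_c, delta_x = 0, d0 = 0.01,
                           sigma_s = 0.15) {
  stopifnot(rho_t >= 0, rho_c >= 0, d0 > 0, sigma_s > 0, is.finite(delta_x))
  new_observer_params("cuecomb",
                      list(rho_t = rho_t, rho_c = rho_c, delta_x = delta_x,
                           d0 = d0, sigma_s = sigma_s))
}

#' @export
print.observer_params <- function(x, ...) {
  cat("<observer_params> model:", x$model, "\n")
  flds <- x[setdiff(names(x), "model")]
  for (nm in names(flds)) cat(" ", nm, "=", format(flds[[nm]]), "\n")
  invisible(x)
}

#' Report steady-state weights implied by a parameter set
#'
#' Converts the fitted/assumed noise ratios to the asymptotic weights the
#' models are usually described by: the measurement weight `w_m` for all
#' models, plus the fusion weight `w_fu` for the cue-combination model
#' (computed from the steady-state a-priori variances of the prior and
#' cue-map filters with `sigma_S^2 = r`).
#'
#' @param params An `observer_params` object.
#' @return Named numeric vector of steady-state weights.
#' @export
steady_state_weights <- function(params) {
  stopifnot(inherits(params, "observer_params"))
  switch(params$model,
    basic = c(w_m = steady_state_gain(params$rho)),
    categorical = c(w_m = steady_state_gain(params$rho)),
    cuecomb = {
      k_t <- steady_state_gain(params$rho_t)
      k_c <- steady_state_gain(params$rho_c)
      # a-priori variances at steady state: k/(1-k) * r; sigma_CS^2 = k_c * r
      a_t <- if (k_t >= 1) Inf else k_t / (1 - k_t)
      w_fu <- if (is.infinite(a_t)) 1 else a_t / (a_t + k_c)
      c(w_m = k_c, w_fu = w_fu)
    },
    stop("unknown model: ", params$model)
  )
}

# Inverse of steady_state_weights for the cue-combination model:
# given target steady-state (w_m, w_fu), return (rho_t, rho_c).
cuecomb_rhos_from_weights <- function(w_m, w_fu) {
  stopifnot(w_m > 0, w_m < 1, w_fu > 0, w_fu <= 1)
  rho_c <- gain_to_rho(w_m)
  if (w_fu == 1) return(c(rho_t = Inf, rho_c = rho_c))
  a_t <- w_m * w_fu / (1 - w_fu)   # k_t/(1-k_t), using sigma_CS^2 = k_c r
  k_t <- a_t / (1 + a_t)
  c(rho_t = gain_to_rho(k_t), rho_c = rho_c)
}
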