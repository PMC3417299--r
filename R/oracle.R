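#' Grid-quadrature reference posterior means
#'
#' Independent numerical references for the models' closed-form posterior
#' means, computed by direct quadrature of the generative densities over a
#' fine grid of target values T:
#'
#' * categorical: posterior proportional to
#'   `N(s; T, sigma_s^2) * sum_i P(c_j|a_i) N(T; mu_i, sigma_a^2)` (shared
#'   category variance, uniform category prior);
#' * cue-combination: posterior proportional to
#'   `N(s; T, sigma_s^2) * N(c_mp; T, sigma_c^2) * N(T; mu_t, sigma_t^2)`.
#'
#' These evaluate the same quantities as [categorical_estimate()] and
#' [cuecomb_estimate()] by brute force rather than by the closed forms, and
#' exist to verify those closed forms numerically.
#'
#' @param s Log-scale measurement.
#' @param cue_index Cued category (integer), or `NA` for an uninformative
#'   cue.
#' @param mu Numeric vector of category means (categorical).
#' @param sigma_a2 Shared category variance.
#' @param sigma_s2 Measurement noise variance.
#' @param p_c Cue reliability.
#' @param c_mp Mapped cue value (cue-combination).
#' @param sigma_c2 Cue-signal variance.
#' @param mu_t,sigma_t2 Prior mean and variance (cue-combination).
#' @param n_grid Number of grid points (default 20001).
#' @param span Half-width of the grid in posterior SDs beyond the extreme
#'   component means (default 8).
#' @return The quadrature posterior mean (numeric scalar).
#' @export
grid_posterior_mean_categorical <- function(s, cue_index, mu, sigma_a2,
                                            sigma_s2, p_c,
                                            n_grid = 20001, span = 8) {
  n <- length(mu)
  cue_mass <- if (is.na(cue_index)) {
    rep(1 / n, n)
  } else {
    m <- rep((1 - p_c) / (n - 1), n)
    m[cue_index] <- p_c
    m
  }
  sd_max <- sqrt(max(sigma_a2, sigma_s2))
  lo <- min(c(mu, s)) - span * sd_max
  hi <- max(c(mu, s)) + span * sd_max
  tt <- seq(lo, hi, length.out = n_grid)
  mix <- rowSums(vapply(seq_len(n), function(i) {
    cue_mass[i] * dnorm(tt, mu[i], sqrt(sigma_a2))
  }, numeric(n_grid)))
  post <- dnorm(s, tt, sqrt(sigma_s2)) * mix
  sum(tt * post) / sum(post)
}

#' @rdname grid_posterior_mean_categorical
#' @export
grid_posterior_mean_cuecomb <- function(s, c_mp, mu_t, sigma_t2, sigma_c2,
                                        sigma_s2, n_grid = 20001,
                                        span = 8) {
  sd_max <- sqrt(max(sigma_t2, sigma_c2, sigma_s2))
  lo <- min(c(s, c_mp, mu_t)) - span * sd_max
  hi <- max(c(s, c_mp, mu_t)) + span * sd_max
  tt <- seq(lo, hi, length.out = n_grid)
  post <- dnorm(s, tt, sqrt(sigma_s2)) * dnorm(c_mp, tt, sqrt(sigma_c2)) *
    dnorm(tt, mu_t, sqrt(sigma_t2))
  sum(tt * post) / sum(post)
}
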