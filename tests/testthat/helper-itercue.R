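# Shared fixtures: parameter sets at the group-mean working point and
# hand-built observer states for the estimation checks.

group_categorical <- function(...) {
  categorical_params(p_c = 0.74, rho = gain_to_rho(0.33), delta_x = -0.04,
                     ...)
}

group_cuecomb <- function(delta_x = -0.05, ...) {
  rhos <- itercue:::cuecomb_rhos_from_weights(0.38, 0.55)
  cuecomb_params(rho_t = rhos[["rho_t"]], rho_c = rhos[["rho_c"]],
                 delta_x = delta_x, ...)
}

group_basic <- function(w_m = 0.33, delta_x = -0.05, ...) {
  basic_params(rho = gain_to_rho(w_m), delta_x = delta_x, ...)
}

# Categorical observer state with prescribed category means and a shared
# a-priori variance sigma_a2 (the generative model's regime).
make_cat_state <- function(params, mu, sigma_a2) {
  st <- observer_state(params)
  st$initialized <- TRUE
  q <- params$rho * params$sigma_s^2
  for (i in seq_along(mu)) {
    st$filters[[i]]$mean <- mu[i]
    st$filters[[i]]$p <- sigma_a2 - q
    st$filters[[i]]$n_updates <- 2L
  }
  st
}

# Cue-combination observer state with prescribed prior/map means and
# a-priori variances.
make_cc_state <- function(params, mu_t, sigma_t2, c_mp, sigma_c2) {
  st <- observer_state(params)
  st$initialized <- TRUE
  r <- params$sigma_s^2
  st$filters$prior$mean <- mu_t
  st$filters$prior$p <- sigma_t2 - params$rho_t * r
  st$filters$prior$n_updates <- 2L
  for (i in seq_along(c_mp)) {
    nm <- paste0("map_", i)
    st$filters[[nm]]$mean <- c_mp[i]
    st$filters[[nm]]$p <- sigma_c2[i] - params$rho_c * r
    st$filters[[nm]]$n_updates <- 2L
  }
  st
}
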