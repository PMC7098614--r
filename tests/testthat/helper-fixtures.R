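# shared fixtures, built once per run
.pop_cache <- new.env(parent = emptyenv())

test_pop <- function() {
  if (is.null(.pop_cache$pop)) .pop_cache$pop <- default_population()
  .pop_cache$pop
}

# small population with an explicit correlation matrix (identity plus one
# correlated pair), handy for analytic oracles
block_population <- function(rho = 0.8, p = 4, mu = NULL, var = NULL) {
  R <- diag(p)
  R[1, 2] <- R[2, 1] <- rho
  if (is.null(mu)) mu <- seq(2, length.out = p)
  if (is.null(var)) var <- rep(1, p)
  population_params(
    mu = mu, var = var, R = R,
    labels = tibble::tibble(variable = paste0("v", seq_len(p)),
                            endpoint = paste0("v", seq_len(p)),
                            time = NA_character_))
}

# single-endpoint population with q time points and exchangeable correlation
endpoint_population <- function(q = 3, rho = 0.5, mu = 10, var = 4) {
  R <- matrix(rho, q, q)
  diag(R) <- 1
  population_params(
    mu = rep(mu, q), var = rep(var, q), R = R,
    labels = tibble::tibble(variable = paste0("ep.t", seq_len(q)),
                            endpoint = "ep", time = paste0("t", seq_len(q))))
}

quick_trial <- function(n = 10, d = 0, seed = 1, pop = test_pop(), ...) {
  sample_trial(scenario_spec(n, cohens_d = d, ...), pop, seed = seed)
}

# circle of radius sqrt(scale) centred at `center`, as a conf_ellipse
make_circle <- function(center, radius = 1) {
  structure(list(center = center, shape = diag(2), scale = radius^2, n = Inf),
            class = "conf_ellipse")
}
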