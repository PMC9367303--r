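# Shared fixtures: everything is generated in code at test time.

# half-normal perpendicular distances truncated at W
hn_distances <- function(n, sigma = 0.12, W = 0.3, seed = 1) {
  set.seed(seed)
  y <- abs(stats::rnorm(3 * n, 0, sigma))
  y[y <= W][seq_len(n)]
}

# small default environment shared across tests
small_env <- function(seed = 1, nx = 40, ny = 120) {
  make_environment(grid_spec(nx, ny), seed = seed)
}

# independent conditional log-likelihood for the half-normal key
# (closed-form ESW via pnorm), used as a grid-search oracle
hn_loglik <- function(sigma, y, W) {
  mu <- sigma * sqrt(2 * pi) * (stats::pnorm(W / sigma) - 0.5)
  sum(-y^2 / (2 * sigma^2)) - length(y) * log(mu)
}

# a minimal detection-model stub when only the ESW matters
esw_stub <- function(esw, W = 1) {
  structure(list(esw = esw, W = W, key = "uniform", adjustment = "none",
                 orders = integer(0), key_par = numeric(0),
                 adj_par = numeric(0)),
            class = "detection_model")
}
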