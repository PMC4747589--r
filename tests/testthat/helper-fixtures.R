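# Shared fixtures: small schedules, populations and studies built in code.

toy_schedule <- function(duration = 200)
  shock_schedule(cbind(c(30, 90), c(38, 98)), duration)

# constant-input signal on [0, T] (u = value everywhere)
const_input <- function(value = 1, T_end = 600, step = 1) {
  inp <- build_input(shock_schedule(NULL, T_end), 0, 0, step)
  inp$values[] <- value
  inp
}

quick_config <- function(n_cells = 40, ...) {
  study_config(n_cells = n_cells, birth_range = c(60, 240), ...)
}

# reduced-iteration SAEM settings for unit tests
quick_saem <- function(seed = 1, ...)
  saem_config(n_burnin = 60, n_sa = 40, seed = seed, ...)

# independent multivariate-normal log-density via solve()/determinant(),
# deliberately a different route than the package's Cholesky evaluation
mvn_logd_oracle <- function(z, mu, S) {
  d <- length(mu)
  -0.5 * d * log(2 * pi) -
    0.5 * as.numeric(determinant(S, logarithm = TRUE)$modulus) -
    0.5 * drop(t(z - mu) %*% solve(S) %*% (z - mu))
}
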