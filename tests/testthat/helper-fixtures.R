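# shared fixture builders (small sizes keep the unit tests quick)

small_four_source <- function(seed = 1, n = 2000) four_source_fixture(seed, n)

whitened <- function(fx, rank_tol = 1e-10) {
  whiten_signals(center_signals(signal_matrix(fx$observations)), rank_tol)
}

# analytic unit-variance laplace sample
rlaplace_unit <- function(n) {
  u <- runif(n) - 0.5
  -sign(u) * log(1 - 2 * abs(u)) / sqrt(2)
}

# augmented Lagrangian (maximization form) used as the finite-difference
# oracle for the learning rule; flat parametrization, fixed mu
aug_lagrangian <- function(w, Z, r, mu, xi, gamma, spec, measure = "corr") {
  y <- drop(crossprod(w, Z))
  eps <- if (measure == "corr") -mean(y * r) else mean((y - r)^2)
  J <- spec$rho * (mean(spec$G(y)) - spec$gauss_moment)^2
  J - (max(0, mu + gamma * (eps - xi))^2 - mu^2) / (2 * gamma)
}
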