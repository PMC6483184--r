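# random valid usage matrix (Dirichlet rows via gamma draws)
random_usage <- function(n_agents, n_variants = 2) {
  P <- matrix(rgamma(n_agents * n_variants, shape = 1), n_agents, n_variants)
  P / rowSums(P)
}

# independent quadrature oracle for the beta-binomial log-density of one
# speaker: integrate the binomial likelihood against the beta density
bb_log_density_quad <- function(x, n, alpha, beta) {
  log(stats::integrate(function(q) dbinom(x, n, q) * dbeta(q, alpha, beta),
                       0, 1, rel.tol = 1e-12, abs.tol = 0)$value)
}
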