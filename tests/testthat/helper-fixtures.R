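# Shared fixtures, all generated in code.

# two seasonal components of opposite phase; quick to fit and trivially
# separable, used wherever a known clustering is needed
two_phase_params <- function(n_genera = 60, theta = 8, intercept = log(30)) {
  sim_params(
    n_genera = n_genera, k_true = 2,
    beta = rbind(c(intercept, 0,  1, 0, 0),
                 c(intercept, 0, -1, 0, 0)),
    theta = rep(theta, 2), mixing_weights = c(0.5, 0.5)
  )
}

# small random count table with uneven genus abundances
random_count_table <- function(G = 20, S = 10, seed = 1, lambda = 40) {
  withr::with_seed(seed, {
    m <- matrix(rnbinom(G * S, mu = rep(exp(rnorm(G, log(lambda), 1)), S), size = 3),
                G, S)
    dimnames(m) <- list(sprintf("g%03d", seq_len(G)), sprintf("s%03d", seq_len(S)))
    m
  })
}

# design matrix (with intercept) of iid standard normal predictors
random_design <- function(n, p, seed = 1) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", seq_len(p))))
    as.data.frame(X)
  })
}
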