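# Shared fixtures and independent oracles for the test suite.

# 3-subject toy with hand-computable risk sets:
#   subjects (a, y, delta): (0.2, 1.0, 1), (0.5, 0.8, 0), (0.1, 0.6, 1)
toy_sample <- function() {
  lbrc_sample(data.frame(a = c(0.2, 0.5, 0.1),
                         y = c(1.0, 0.8, 0.6),
                         delta = c(1, 0, 1),
                         x1 = c(0, 1, 0)))
}

scenario_model <- function(id = "I", beta = c(log(2), log(0.8))) {
  lb_model(id, beta = beta)
}

# Naive leave-one-out jackknife: full recomputation of the estimator on
# each reduced sample (the slow reference path for the tallied fast path).
naive_jackknife <- function(sample, est_fun, grid) {
  n <- nrow(sample)
  full <- surv_eval(est_fun(sample), grid)
  df <- as.data.frame(sample)
  out <- matrix(NA_real_, n, length(grid))
  for (i in seq_len(n)) {
    loo <- est_fun(lbrc_sample(df[-i, , drop = FALSE]))
    out[i, ] <- n * full - (n - 1) * surv_eval(loo, grid)
  }
  out
}

# Direct maximization of the Vardi observed-data log-likelihood over the
# probability simplex via a softmax parametrization (independent of the EM
# path).
direct_vardi_max <- function(tk, d, cnt, n_starts = 5, seed = 1) {
  K <- length(tk)
  negll <- function(par) {
    p <- exp(par - max(par))
    p <- p / sum(p)
    -lbpseudo:::vardi_loglik(tk, d, cnt, p)
  }
  set.seed(seed)
  best <- Inf
  for (s in seq_len(n_starts)) {
    start <- if (s == 1) rep(0, K) else stats::rnorm(K)
    fit <- stats::optim(start, negll, method = "BFGS",
                        control = list(maxit = 2000, reltol = 1e-14))
    if (fit$value < best) best <- fit$value
  }
  -best
}

# Closed-form conditional survival under the simulator's Cox-Weibull models
true_surv_at <- function(model, t, x) true_survival(model, t, x)
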