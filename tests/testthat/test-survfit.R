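test_that("risk indicator counts both time scales", {
  s <- toy_sample()
  # subject 1: (a=0.2, y=1.0, d=1): both windows cover t = 0.9
  expect_equal(risk_indicator(s, 0.9), c(2L, 0L, 0L))
  # t = 0.6: subjects 1,2 on the truncation scale, 3 on both
  expect_equal(risk_indicator(s, 0.6), c(1L, 1L, 2L))
  # beyond every y
  expect_equal(risk_indicator(s, 1.5), c(0L, 0L, 0L))
})

test_that("Wang product-limit matches the hand computation on the toy", {
  # At u = 0.6: dHn = 1/3, risk sum = 1+1+2 => Rn = 4/6, factor = 1/2.
  # At u = 1.0: risk sum = 2 (subject 1 on both scales), factor = 0.
  w <- surv_wang(toy_sample())
  expect_equal(w$time, c(0.6, 1.0))
  expect_equal(w$surv, c(0.5, 0))
  expect_equal(surv_eval(w, c(0.1, 0.6, 0.99, 2)), c(1, 0.5, 0.5, 0))
})

test_that("LTRC product-limit matches hand risk sets and reduces to KM", {
  l <- surv_ltrc(toy_sample())
  # r(0.6) = 3, d = 1 => 2/3;  r(1.0) = 1, d = 1 => 0
  expect_equal(l$surv, c(2 / 3, 0))
  skip_if_not_installed("survival")
  # with a = 0 it is the ordinary Kaplan-Meier
  set.seed(5)
  n <- 80
  y <- rexp(n, 2); cc <- runif(n, 0, 1.5)
  s <- lbrc_sample(data.frame(a = 0, y = pmin(y, cc),
                              delta = as.numeric(y <= cc), x1 = 0))
  km <- survival::survfit(survival::Surv(s$y, s$delta) ~ 1)
  ours <- surv_eval(surv_ltrc(s), km$time)
  expect_equal(ours, km$surv, tolerance = 1e-12)
  # and with a > 0 it matches the left-truncated Kaplan-Meier
  s2 <- simulate_lbrc(lb_model("I"), 150, censor_scale = 3, seed = 8)
  km2 <- survival::survfit(
    survival::Surv(s2$a, s2$y, s2$delta) ~ 1)
  ours2 <- surv_eval(surv_ltrc(s2), km2$time)
  expect_equal(ours2, km2$surv, tolerance = 1e-12)
})

test_that("Wang estimator is consistent under the uniform-truncation design", {
  s <- simulate_lbrc(lb_model("I", beta = c(0, 0)), 5000, seed = 42)
  w <- surv_wang(s)
  tt <- seq(0.1, 1.0, by = 0.05)
  expect_lt(max(abs(surv_eval(w, tt) - exp(-2 * tt))), 0.03)
  l <- surv_ltrc(s)
  tl <- seq(0.3, 1.0, by = 0.05)
  expect_lt(max(abs(surv_eval(l, tl) - exp(-2 * tl))), 0.05)
})

test_that("Vardi NPMLE: degenerate support gives a unit step", {
  s <- lbrc_sample(data.frame(a = c(0.1, 0.2, 0.05), y = c(0.5, 0.5, 0.5),
                              delta = c(1, 1, 1), x1 = 0))
  v <- surv_vardi(s)
  expect_equal(v$time, 0.5)
  expect_equal(v$surv, 0)
  expect_equal(surv_eval(v, c(0.49, 0.51)), c(1, 0))
})

test_that("EM log-likelihood is non-decreasing and the fit maximizes it", {
  s <- simulate_lbrc(lb_model("I"), 60, censor_scale = 2, seed = 14)
  prep <- lbpseudo:::vardi_prep(s$y, s$delta)
  p <- rep(1 / prep$K, prep$K)
  ll_prev <- -Inf
  for (k in 1:40) {
    fit <- lbpseudo:::vardi_em(prep$tk, prep$d, prep$cnt, prep$n, p,
                               tol = 0, max_iter = 1)
    expect_gte(fit$loglik, ll_prev - 1e-10)
    ll_prev <- fit$loglik
    p <- fit$p
  }
})

test_that("EM matches a direct simplex maximization on tiny samples", {
  cases <- list(
    data.frame(a = c(0.1, 0.3, 0.2, 0.1), y = c(0.9, 1.4, 0.7, 1.1),
               delta = c(1, 1, 1, 0), x1 = 0),
    data.frame(a = c(0.2, 0.1, 0.4, 0.3, 0.1, 0.2),
               y = c(0.8, 1.2, 0.9, 1.5, 0.6, 1.0),
               delta = c(1, 0, 1, 1, 1, 0), x1 = 0),
    data.frame(a = rep(0.05, 8),
               y = c(0.4, 0.5, 0.6, 0.8, 0.9, 1.1, 1.2, 1.4),
               delta = c(1, 1, 0, 1, 0, 1, 1, 1), x1 = 0))
  for (df in cases) {
    s <- lbrc_sample(df)
    v <- surv_vardi(s, tol = 1e-12)
    prep <- lbpseudo:::vardi_prep(s$y, s$delta)
    ll_direct <- direct_vardi_max(prep$tk, prep$d, prep$cnt)
    expect_lt(abs(v$extra$loglik - ll_direct), 1e-6)
  }
})

test_that("Vardi and Wang estimators agree in large samples", {
  m <- lb_model("I")
  cc <- calibrate_censoring(m, 0.25, n_pilot = 5000)
  s <- simulate_lbrc(m, 2000, censor_scale = as.numeric(cc), seed = 33)
  v <- surv_vardi(s)
  w <- surv_wang(s)
  expect_true(v$converged)
  tt <- seq(0.4, 1.3, by = 0.1)
  expect_lt(max(abs(surv_eval(v, tt) - surv_eval(w, tt))), 0.03)
})

test_that("influence function is mean-zero and vanishes before the event", {
  s <- simulate_lbrc(lb_model("I"), 5000, censor_scale = 4, seed = 55)
  phi <- influence_phi(s, 0.8)
  expect_lt(abs(mean(phi)), 0.02)
  # a subject with y > t contributes no event term; a censored subject
  # whose risk window starts after t contributes nothing at all
  expect_true(all(phi[s$delta == 0 & s$a > 0.8] == 0))
  expect_true(all(phi[s$y > 0.8] <= 0))   # only the integral term remains
})

test_that("curves are proper step survival functions on random inputs", {
  for (seed in 1:4) {
    s <- simulate_lbrc(lb_model(sample(c("I", "II", "III"), 1)), 120,
                       censor_scale = 1.5, seed = seed)
    for (f in list(surv_wang, surv_ltrc, surv_vardi)) {
      cv <- f(s)
      expect_true(all(diff(cv$surv) <= 1e-12))
      expect_true(all(cv$surv >= 0 & cv$surv <= 1))
      expect_equal(surv_eval(cv, min(cv$time) / 2), 1)
    }
  }
})

test_that("counting processes match their definitions", {
  s <- simulate_lbrc(lb_model("I"), 300, censor_scale = 2, seed = 6)
  rp <- risk_process(s, c(0.5, max(s$y), max(s$y) + 1))
  expect_equal(rp$H_n[2], sum(s$delta == 1) / nrow(s))
  expect_equal(rp$R_n[3], 0)
  expect_true(all(diff(risk_process(s, seq(0, 3, 0.1))$H_n) >= 0))
})

test_that("empirical risk function matches its population form", {
  # R(t) = S(t) w(t) / mu with w(t) = int_0^t G, G uniform residual
  # censoring survival; checked under Scenario I with beta = 0.
  m <- lb_model("I", beta = c(0, 0))
  cscale <- 2
  s <- simulate_lbrc(m, 5e4, censor_scale = cscale, seed = 99)
  mu <- 0.5                        # E(T) for Exp(rate 2)
  for (t0 in c(0.4, 0.8)) {
    w_t <- t0 - t0^2 / (2 * cscale)
    pop <- exp(-2 * t0) * w_t / mu
    ri <- risk_indicator(s, t0)
    emp <- mean(ri) / 2
    mc_err <- sd(ri / 2) / sqrt(length(ri))
    expect_lt(abs(emp - pop), 3 * mc_err + 1e-8)
  }
})
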