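# helper to wrap a plain matrix as a pseudo-matrix for the fitter
as_pseudo <- function(values, grid, valid = rep(TRUE, nrow(values))) {
  structure(values, grid = time_grid(grid), estimator = "wang",
            valid = valid, class = "lb_pseudo")
}

test_that("complementary log-log link and inverse behave", {
  expect_equal(inv_cloglog(log(log(2))), 0.5)
  expect_equal(inv_cloglog(-Inf), 1)
  expect_equal(inv_cloglog(Inf), 0)
  eta <- seq(-5, 3, length.out = 41)
  expect_lt(max(abs(cloglog(inv_cloglog(eta)) - eta)), 1e-12)
  x <- c(0.3, 1e-6, 1 - 1e-6)
  expect_lt(max(abs(inv_cloglog(cloglog(x)) - x)), 1e-12)
})

test_that("noiseless responses recover the truth exactly", {
  set.seed(7)
  n <- 150
  x <- cbind(x1 = rbinom(n, 1, 0.5), x2 = runif(n, -1, 1))
  theta0 <- c(-0.2, 0.7, -0.22)
  mu <- inv_cloglog(drop(cbind(1, x) %*% theta0))
  fit <- fit_pseudo_gee(as_pseudo(matrix(mu, ncol = 1), 0.5), x)
  expect_true(fit$converged)
  expect_lt(max(abs(fit$theta - theta0)), 1e-8)
  # all per-subject scores vanish, so the sandwich is the zero matrix
  expect_lt(max(abs(fit$vcov)), 1e-12)
})

test_that("solver agrees with a derivative-free root search (m=1, p=1)", {
  x <- matrix(c(0, 0, 1, 1), ncol = 1, dimnames = list(NULL, "x1"))
  s_vals <- matrix(c(0.8, 0.65, 0.45, 0.28), ncol = 1)
  fit <- fit_pseudo_gee(as_pseudo(s_vals, 0.5), x)
  # independent construction of U(theta) from the estimating equation
  U <- function(th) {
    eta <- th[1] + th[2] * x[, 1]
    mu <- exp(-exp(eta))
    dmu <- -exp(eta - exp(eta))
    c(sum(dmu * (s_vals - mu)), sum(dmu * x[, 1] * (s_vals - mu)))
  }
  opt <- optim(c(0, 0), function(th) sum(U(th)^2), method = "Nelder-Mead",
               control = list(reltol = 1e-16, maxit = 5000))
  expect_lt(max(abs(fit$theta - opt$par)), 1e-6)
  expect_lt(max(abs(U(fit$theta))), 1e-8)
})

test_that("sandwich matches a finite-difference construction", {
  set.seed(15)
  n <- 60; m <- 3
  x <- cbind(x1 = rbinom(n, 1, 0.5), x2 = runif(n, -1, 1))
  theta0 <- c(-0.4, 0.1, 0.5, 0.7, -0.22)
  eta <- rep(theta0[1:3], n) +
    drop(x %*% theta0[4:5])[rep(seq_len(n), each = m)]
  s_vals <- matrix(inv_cloglog(eta) + rnorm(n * m, 0, 0.15),
                   n, m, byrow = TRUE)
  fit <- fit_pseudo_gee(as_pseudo(s_vals, c(0.4, 0.6, 0.8)), x)
  expect_true(fit$converged)
  th <- fit$theta
  # rebuild the sandwich with finite-difference derivatives of the inverse
  # link: I = sum (dmu)^2 x x' and the per-subject scores, no analytic dmu
  X <- cbind(diag(3)[rep(1:3, n), ], x[rep(seq_len(n), each = m), ])
  etas <- drop(X %*% th)
  h <- 1e-6
  dmu_fd <- (inv_cloglog(etas + h) - inv_cloglog(etas - h)) / (2 * h)
  I_fd <- crossprod(X * dmu_fd)
  w_fd <- dmu_fd * (as.vector(t(s_vals)) - inv_cloglog(etas))
  Ui_fd <- rowsum(X * w_fd, rep(seq_len(n), each = m))
  fd <- solve(I_fd) %*% crossprod(Ui_fd) %*% solve(I_fd)
  expect_lt(max(abs(fit$vcov - fd) / (abs(fd) + 1e-8)), 1e-4)
})

test_that("covariate rescaling transforms coefficients and intervals", {
  set.seed(23)
  m <- lb_model("I")
  s <- simulate_lbrc(m, 150, censor_scale = 3, seed = 23)
  grid <- c(0.5, 0.8)
  ps <- pseudo_lbrc(s, "wang", grid = grid)
  f1 <- fit_pseudo_gee(ps, s)
  covariate_scale <- 4
  xs <- cbind(x1 = s$x1, x2 = s$x2 * covariate_scale)
  f2 <- fit_pseudo_gee(ps, xs)
  expect_equal(f2$theta[["x2"]], f1$theta[["x2"]] / covariate_scale,
               tolerance = 1e-6)
  expect_equal(f2$theta[1:2], f1$theta[1:2], tolerance = 1e-6)
  ci1 <- wald_ci(f1); ci2 <- wald_ci(f2)
  expect_equal(unname(ci2["x2", ]), unname(ci1["x2", ] / covariate_scale),
               tolerance = 1e-6)
})

test_that("Wald intervals use the normal multiplier and handle degeneracy", {
  expect_equal(qnorm(0.975), 1.959964, tolerance = 1e-6)
  set.seed(2)
  x <- matrix(rbinom(40, 1, 0.5), ncol = 1, dimnames = list(NULL, "x1"))
  mu <- inv_cloglog(-0.1 + 0.4 * x[, 1])
  fit <- fit_pseudo_gee(as_pseudo(matrix(mu, ncol = 1), 0.5), x)
  ci <- wald_ci(fit, 0.95)
  expect_equal(unname(ci[, "lower"]), unname(fit$theta))  # zero variance
  expect_equal(unname(ci[, "upper"]), unname(fit$theta))
})

test_that("validity rule flags divergence and extreme coefficients", {
  set.seed(3)
  x <- cbind(x1 = rbinom(60, 1, 0.5), x2 = runif(60, -1, 1))
  mu <- inv_cloglog(drop(cbind(1, x) %*% c(-0.2, 0.7, -0.2)))
  fit <- fit_pseudo_gee(as_pseudo(matrix(mu, ncol = 1), 0.5), x)
  expect_true(is_valid_fit(fit))
  bad <- fit; bad$theta[2] <- 25
  expect_false(is_valid_fit(bad))
  nc <- fit; nc$converged <- FALSE
  expect_false(is_valid_fit(nc))
  expect_false(is_valid_fit(fit, coef_bound = 0.5))
})

test_that("estimating-equation residual is below tolerance on real fits", {
  s <- simulate_lbrc(lb_model("II"), 200, censor_scale = 2, seed = 71)
  ps <- pseudo_lbrc(s, "ltrc", grid = seq(0.4, 1.0, 0.2))
  fit <- fit_pseudo_gee(ps, s)
  expect_true(fit$converged)
  expect_lt(fit$score_max, 1e-4)
})
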