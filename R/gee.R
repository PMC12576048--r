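#' Complementary log-log link and its inverse
#'
#' \eqn{g(x) = \log(-\log x)} linearizes the Cox survival relation
#' \eqn{\log(-\log S(t \mid x)) = \log\Lambda_0(t) + x^\top\beta}. The
#' inverse is \eqn{g^{-1}(\eta) = \exp(-e^\eta)}, with derivative
#' \eqn{-\exp(\eta - e^\eta)}; both saturate cleanly at the floating-point
#' limits.
#'
#' @param x survival probability in (0, 1).
#' @param eta real linear predictor.
#' @return Numeric vector.
#' @export
cloglog <- function(x) log(-log(x))

#' @rdname cloglog
#' @export
inv_cloglog <- function(eta) exp(-exp(eta))

dinv_cloglog <- function(eta) -exp(eta - exp(eta))

## Stacked design: m time-specific intercept indicators followed by the
## covariate columns; one block of m rows per subject.
stack_design <- function(x, m) {
  n <- nrow(x); p <- ncol(x)
  X <- matrix(0, n * m, m + p)
  rows <- seq_len(n * m)
  tau_of_row <- rep(seq_len(m), n)
  X[cbind(rows, tau_of_row)] <- 1
  X[, m + seq_len(p)] <- x[rep(seq_len(n), each = m), , drop = FALSE]
  X
}

#' Fit the pseudo-observation GEE with complementary log-log link
#'
#' Solves the estimating equation
#' \deqn{U(\theta) = \sum_i \frac{\partial g^{-1}(\check x_i^\top\theta)}
#' {\partial\theta}^\top V_i^{-1}\{\hat S_i - g^{-1}(\check x_i^\top\theta)\}
#' = 0}
#' for \eqn{\theta = (\beta_0, \beta)}, where the intercept block
#' \eqn{\beta_0 = (\log\Lambda_0(\tau_1), \ldots, \log\Lambda_0(\tau_m))}
#' holds one intercept per grid point, \eqn{\check x_i} appends the
#' time-point indicators to the covariates, and the working covariance
#' \eqn{V_i} is the identity (the single-time-point convention extended to
#' the independence working model; the sandwich estimator corrects any
#' misspecification). Estimation is damped Newton scoring with step
#' halving; pseudo-values enter untransformed even when outside [0, 1].
#'
#' @param pseudo an \code{"lb_pseudo"} matrix from [pseudo_lbrc()].
#' @param sample the [lbrc_sample()] the pseudo-values were computed from
#'   (supplies the covariates), or a plain covariate matrix with one row
#'   per subject.
#' @param tol convergence tolerance: \code{max|U| < tol} and Newton step
#'   norm below \code{tol} (default 1e-8).
#' @param max_iter Newton iteration cap (default 100).
#' @param coef_bound validity bound applied by [is_valid_fit()] and stored
#'   on the fit (default 10).
#' @return Object of class \code{"lb_gee"}: coefficients \code{theta},
#'   sandwich covariance \code{vcov}, \code{converged}, iteration count,
#'   the number of subjects excluded as invalid, and bookkeeping (grid,
#'   coefficient names, m, p).
#' @export
fit_pseudo_gee <- function(pseudo, sample, tol = 1e-8, max_iter = 100,
                           coef_bound = 10) {
  stopifnot(inherits(pseudo, "lb_pseudo"))
  grid <- attr(pseudo, "grid")
  m <- ncol(pseudo)
  x <- if (inherits(sample, "lbrc_sample")) covariate_matrix(sample)
       else as.matrix(sample)
  stopifnot(nrow(x) == nrow(pseudo))
  cn <- colnames(x)
  if (is.null(cn)) cn <- paste0("x", seq_len(ncol(x)))
  valid <- attr(pseudo, "valid")
  if (is.null(valid)) valid <- rep(TRUE, nrow(pseudo))
  valid <- valid & !apply(pseudo, 1, anyNA)
  n_invalid <- sum(!valid)
  S <- pseudo[valid, , drop = FALSE]
  x <- x[valid, , drop = FALSE]
  n <- nrow(S); p <- ncol(x)
  if (m + p >= n) stop("more parameters than subjects")
  X <- stack_design(x, m)
  s_vec <- as.vector(t(S))                       # subject-major stacking
  subj <- rep(seq_len(n), each = m)
  # init: beta = 0, intercepts from clamped column means through the link
  mu0 <- pmin(pmax(colMeans(S), 1e-6), 1 - 1e-6)
  theta <- c(cloglog(mu0), rep(0, p))
  score <- function(th) {
    eta <- drop(X %*% th)
    mu <- inv_cloglog(eta)
    dmu <- dinv_cloglog(eta)
    w <- dmu * (s_vec - mu)
    list(U = drop(crossprod(X, w)), eta = eta, mu = mu, dmu = dmu, w = w)
  }
  # With the identity working covariance the score U(theta) is exactly the
  # gradient of -(1/2) sum (s - mu)^2, so the root is found by minimizing
  # that least-squares objective with Levenberg-Marquardt: the scoring
  # matrix sum (dmu)^2 x x' is the Gauss-Newton Hessian, and the ridge is
  # raised until a step decreases the objective, which can only fail at a
  # root (U ~ 0). Convergence is declared when max|U| < tol.
  sse <- function(th) sum((s_vec - inv_cloglog(drop(X %*% th)))^2)
  sc <- score(theta)
  obj <- sse(theta)
  converged <- FALSE
  iter <- 0L
  singular <- FALSE
  stalled <- FALSE
  ridge <- 0
  while (iter < max_iter) {
    iter <- iter + 1L
    if (max(abs(sc$U)) < tol) { converged <- TRUE; break }
    info <- crossprod(X * sc$dmu)                # sum (dmu)^2 x x'
    dscale <- mean(diag(info))
    if (!is.finite(dscale) || dscale <= 0) { singular <- TRUE; break }
    accepted <- FALSE
    repeat {
      M <- info + ridge * dscale * diag(ncol(info))
      step <- tryCatch(solve(M, sc$U), error = function(e) NULL)
      if (!is.null(step) && all(is.finite(step))) {
        cand <- theta + step
        obj_new <- sse(cand)
        if (is.finite(obj_new) && obj_new <= obj * (1 + 1e-14)) {
          accepted <- TRUE
          break
        }
      }
      ridge <- if (ridge == 0) 1e-6 else ridge * 10
      if (ridge > 1e10) break
    }
    if (!accepted) { stalled <- TRUE; break }    # no descent direction left
    theta <- cand
    obj <- obj_new
    sc <- score(theta)
    ridge <- ridge / 10
  }
  # A stalled search sits at the floating-point floor of the objective:
  # accept it as a root when the score is tiny on the sqrt(tol) scale.
  # Exhausting max_iter, by contrast, is divergence and stays unconverged.
  if (!converged && stalled && max(abs(sc$U)) < sqrt(tol))
    converged <- TRUE
  # Boundary divergence: if a covariate's weight column has collapsed
  # (fitted survival 0 for every subject carrying it), its estimate ran to
  # the boundary rather than to a root - an invalid, non-converged fit.
  if (converged) {
    winfo <- colSums((X * sc$dmu)^2)
    if (any(winfo[m + seq_len(p)] <= 1e-12 * max(winfo)))
      converged <- FALSE
  }
  names(theta) <- c(paste0("logLambda0(", signif(unclass(grid), 6), ")"), cn)
  vcov <- matrix(NA_real_, m + p, m + p)
  if (!singular)
    vcov <- sandwich_cov(X, sc, subj, m + p)
  dimnames(vcov) <- list(names(theta), names(theta))
  structure(list(theta = theta, vcov = vcov, converged = converged,
                 n_iter = iter, n_invalid = n_invalid, n = n, m = m, p = p,
                 grid = grid, coef_names = cn, score_max = max(abs(sc$U)),
                 coef_bound = coef_bound,
                 estimator = attr(pseudo, "estimator")),
            class = "lb_gee")
}

## Sandwich covariance I^{-1} (sum_i U_i U_i') I^{-1} with per-subject
## score vectors U_i stacking that subject's m rows.
sandwich_cov <- function(X, sc, subj, q) {
  info <- crossprod(X * sc$dmu)
  # Equilibrate before inverting: grid points where the fitted survival is
  # ~0 (or ~1) contribute near-zero weight columns, which makes the raw
  # matrix look singular although the system is well posed after scaling.
  d <- diag(info)
  # A grid point whose fitted survival underflows to 0 leaves a zero-weight
  # intercept column: that intercept is unidentified (log Lambda0 -> +Inf)
  # and gets NA variance; the remaining block is inverted after scaling.
  act <- which(is.finite(d) & d > 0)
  if (length(act) == 0)
    stop("information matrix is singular: no identified parameters")
  D <- 1 / sqrt(d[act])
  info_s <- info[act, act, drop = FALSE] * outer(D, D)
  cond <- tryCatch(kappa(info_s), error = function(e) Inf)
  if (!is.finite(cond) || cond > 1e10)
    stop("information matrix is numerically singular (condition number ",
         format(cond, digits = 3), ")")
  Iinv <- outer(D, D) * solve(info_s)
  Ui <- rowsum(X * sc$w, subj)                   # n x q per-subject scores
  meat <- crossprod(Ui[, act, drop = FALSE])
  V <- matrix(NA_real_, q, q)
  Vact <- Iinv %*% meat %*% Iinv
  V[act, act] <- (Vact + t(Vact)) / 2
  V
}

#' @export
coef.lb_gee <- function(object, ...) object$theta

#' @export
vcov.lb_gee <- function(object, ...) object$vcov

#' Wald confidence intervals from a pseudo-observation GEE fit
#'
#' \eqn{\hat\theta_j \pm z_{1-(1-\mathrm{level})/2}\sqrt{\hat\Sigma_{jj}}}
#' using the sandwich covariance.
#'
#' @param fit an \code{"lb_gee"} fit.
#' @param level confidence level (default 0.95).
#' @return Matrix with columns \code{lower}, \code{upper}, one row per
#'   coefficient.
#' @export
wald_ci <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "lb_gee"), level > 0, level < 1)
  z <- stats::qnorm(1 - (1 - level) / 2)
  se <- sqrt(pmax(diag(fit$vcov), 0))
  out <- cbind(lower = fit$theta - z * se, upper = fit$theta + z * se)
  rownames(out) <- names(fit$theta)
  out
}

#' Validity rule for a GEE fit
#'
#' A fit is invalid when the Newton iteration did not converge or any
#' covariate coefficient is unrealistically extreme
#' (\eqn{|\hat\beta_j| >} \code{coef_bound}); invalid replicates are
#' excluded (and counted) by the replication harness.
#'
#' @param fit an \code{"lb_gee"} fit.
#' @param coef_bound bound on the covariate coefficients (defaults to the
#'   value stored on the fit, itself defaulting to 10).
#' @return Logical flag.
#' @export
is_valid_fit <- function(fit, coef_bound = fit$coef_bound) {
  stopifnot(inherits(fit, "lb_gee"))
  if (is.null(coef_bound)) coef_bound <- 10
  beta <- fit$theta[fit$m + seq_len(fit$p)]
  isTRUE(fit$converged) && all(is.finite(beta)) &&
    all(abs(beta) <= coef_bound)
}

#' @export
print.lb_gee <- function(x, ...) {
  cat("Pseudo-observation GEE (cloglog link, ", x$estimator,
      " pseudo-values)\n", sep = "")
  cat("  subjects: ", x$n, " (", x$n_invalid, " excluded), time points: ",
      x$m, "\n", sep = "")
  cat("  converged: ", x$converged, " after ", x$n_iter, " iterations\n",
      sep = "")
  print(summary_table(x))
  invisible(x)
}

summary_table <- function(fit, level = 0.95) {
  se <- sqrt(pmax(diag(fit$vcov), 0))
  z <- fit$theta / se
  ci <- wald_ci(fit, level)
  data.frame(coefficient = names(fit$theta), estimate = fit$theta,
             se = se, z = z, p = 2 * stats::pnorm(-abs(z)),
             lower = ci[, "lower"], upper = ci[, "upper"],
             row.names = NULL, check.names = FALSE)
}

#' Tabulate a fitted pseudo-observation GEE
#'
#' Coefficient, estimate, sandwich SE, z statistic, two-sided p-value and
#' Wald interval, as a plain data frame (writable as delimited text).
#'
#' @param object an \code{"lb_gee"} fit.
#' @param level confidence level.
#' @param ... unused.
#' @return A data frame.
#' @export
summary.lb_gee <- function(object, level = 0.95, ...) {
  summary_table(object, level)
}
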