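#' Length-biased risk-set indicator
#'
#' For each subject the at-risk value
#' \eqn{R_i(t) = I(A_i \le t \le Y_i) + \Delta_i I(\tilde V_i \le t \le Y_i)}
#' with \eqn{\tilde V_i = Y_i - A_i}, taking values in \{0, 1, 2\}. The
#' second term exploits the exchangeability of the truncation and residual
#' times under stationary incidence: an uncensored subject contributes risk
#' on both its truncation-time and residual-time scales, doubling the
#' effective risk set relative to a plain left-truncated one.
#'
#' @param sample an [lbrc_sample()].
#' @param t a single time (>= 0).
#' @return Integer vector of length n with values 0, 1 or 2.
#' @export
risk_indicator <- function(sample, t) {
  stopifnot(inherits(sample, "lbrc_sample"), length(t) == 1, t >= 0)
  v <- sample$y - sample$a
  as.integer(sample$a <= t & t <= sample$y) +
    as.integer(sample$delta == 1 & v <= t & t <= sample$y)
}

## Shared tallies for the product-limit estimators: distinct uncensored
## times u, event counts d, and the two risk-set totals
##   risk2(u) = sum_i R_i(u)              (length-biased, Wang)
##   risk1(u) = #{i : a_i < u <= y_i}     (left-truncated KM)
## Counting uses sorted marginals: #{a <= u} - #{y < u} counts subjects with
## a <= u <= y because a <= y always.
event_tallies <- function(sample) {
  y <- sample$y; a <- sample$a; delta <- sample$delta
  v <- y - a
  u <- sort(unique(y[delta == 1]))
  if (!length(u)) stop("no uncensored events in the sample")
  d <- tabulate(match(y[delta == 1], u), nbins = length(u))
  sa <- sort(a); sy <- sort(y)
  sv1 <- sort(v[delta == 1]); sy1 <- sort(y[delta == 1])
  n_ay  <- findInterval(u, sa) - findInterval(u, sy, left.open = TRUE)
  n_vy  <- findInterval(u, sv1) - findInterval(u, sy1, left.open = TRUE)
  risk1 <- findInterval(u, sa, left.open = TRUE) -
    findInterval(u, sy, left.open = TRUE)
  list(u = u, d = d, risk2 = n_ay + n_vy, risk1 = risk1,
       n = nrow(sample))
}

## Per-subject contribution of subject i to risk2 over the event-time grid u
risk2_contrib <- function(u, a_i, y_i, v_i, delta_i) {
  (a_i <= u & u <= y_i) + (delta_i == 1) * (v_i <= u & u <= y_i)
}

## Turn hazard-increment factors into a curve, applying the zero-risk rule
## (skip factors with an empty risk set, warn, flag) and flooring at 0.
pl_curve <- function(u, d, risk, label, denom_scale = 1, warn = TRUE) {
  zero <- risk <= 0
  fac <- rep(1, length(u))
  fac[!zero] <- 1 - d[!zero] / (denom_scale * risk[!zero])
  fac <- pmax(fac, 0)
  if (any(zero & d > 0) && warn)
    warning("zero risk set at ", sum(zero & d > 0),
            " uncensored time(s); factor skipped")
  lb_survcurve(u, cumprod(fac), estimator = label,
               flagged = any(zero & d > 0))
}

#' Product-limit survival estimator for length-biased data (Wang)
#'
#' The closed-form product-limit estimator
#' \eqn{\hat S^W(t) = \prod_{u \le t} \{1 - dH_n(u)/R_n(u)\}} where
#' \eqn{H_n(t) = n^{-1}\sum_i \Delta_i I(Y_i \le t)} counts uncensored
#' failures and \eqn{R_n(t) = (2n)^{-1}\sum_i R_i(t)} is the length-biased
#' risk function built from [risk_indicator()]. Consistent for the
#' *unbiased* survival function S under length-biased sampling with
#' residual censoring.
#'
#' Ties among uncensored times aggregate into a single factor; factors are
#' floored at 0; an event time with an empty risk set is skipped with a
#' warning and the curve is flagged.
#'
#' @param sample an [lbrc_sample()] with at least one uncensored event.
#' @return An [lb_survcurve()].
#' @export
surv_wang <- function(sample) {
  tl <- event_tallies(sample)
  # dH/Rn = (d/n) / (risk2/(2n)) = 2 d / risk2
  pl_curve(tl$u, tl$d, tl$risk2, "wang", denom_scale = 0.5)
}

#' Left-truncation-adjusted Kaplan-Meier estimator
#'
#' The standard product-limit estimator for left-truncated right-censored
#' data: factor \eqn{1 - d(u)/r(u)} at each distinct uncensored time, with
#' risk set \eqn{r(u) = \#\{i : a_i < u \le y_i\}}. It ignores the uniform
#' distribution of the truncation times, so it serves as the
#' general-left-truncation comparator for the length-biased estimators.
#' With all \code{a = 0} it reduces to the ordinary Kaplan-Meier estimator.
#'
#' @inheritParams surv_wang
#' @return An [lb_survcurve()].
#' @export
surv_ltrc <- function(sample) {
  tl <- event_tallies(sample)
  pl_curve(tl$u, tl$d, tl$risk1, "ltrc")
}

#' Empirical influence function of the Wang estimator
#'
#' Plug-in version of the first-order influence term of the product-limit
#' estimator for length-biased data:
#' \deqn{\hat\phi_i(t) = \frac{\Delta_i I(Y_i \le t)}{R_n(Y_i)} -
#'   \frac12 \sum_{u \le t} R_n(u)^{-2} R_i(u)\, \Delta H_n(u),}
#' which is mean-zero in large samples and linearizes
#' \eqn{\hat S^W(t) \approx S(t)\{1 - n^{-1}\sum_i \phi_i(t)\}}. Used as a
#' variance/linearization oracle for the jackknife pseudo-values.
#'
#' @param sample an [lbrc_sample()].
#' @param t single evaluation time within the observed event range.
#' @return Numeric vector of length n.
#' @export
influence_phi <- function(sample, t) {
  stopifnot(length(t) == 1, t > 0)
  tl <- event_tallies(sample)
  n <- tl$n
  Rn_u <- tl$risk2 / (2 * n)
  dH_u <- tl$d / n
  in_t <- tl$u <= t
  w <- numeric(length(tl$u))
  pos <- in_t & Rn_u > 0
  w[pos] <- dH_u[pos] / Rn_u[pos]^2
  W <- c(0, cumsum(w))                      # W[k+1] = sum_{u_j <= u_k} w_j
  cum_at <- function(x) W[findInterval(x, tl$u) + 1L]
  cum_below <- function(x) W[findInterval(x, tl$u, left.open = TRUE) + 1L]
  a <- sample$a; y <- sample$y; delta <- sample$delta; v <- y - a
  # per subject, sum of w(u) over event times u <= t inside each risk
  # window (w is already zero beyond t, so cum_at(y) caps at t itself)
  term2 <- pmax(cum_at(y) - cum_below(a), 0) +
    (delta == 1) * pmax(cum_at(y) - cum_below(v), 0)
  Rn_y <- numeric(n)
  ev <- delta == 1 & y <= t
  if (any(ev)) {
    tl_y <- risk2_at(sample, y[ev])
    Rn_y[ev] <- tl_y / (2 * n)
  }
  term1 <- numeric(n)
  term1[ev] <- 1 / Rn_y[ev]
  term1 - 0.5 * term2
}

## sum_i R_i(t) evaluated at arbitrary times (vectorized)
risk2_at <- function(sample, t) {
  a <- sample$a; y <- sample$y; delta <- sample$delta; v <- y - a
  sa <- sort(a); sy <- sort(y)
  sv1 <- sort(v[delta == 1]); sy1 <- sort(y[delta == 1])
  (findInterval(t, sa) - findInterval(t, sy, left.open = TRUE)) +
    (findInterval(t, sv1) - findInterval(t, sy1, left.open = TRUE))
}

#' Empirical counting and risk processes for length-biased data
#'
#' Returns \eqn{H_n(t)} (fraction of uncensored failures up to t) and
#' \eqn{R_n(t)} (half the mean of the [risk_indicator()] values), the two
#' ingredients of the Wang product-limit estimator.
#'
#' @param sample an [lbrc_sample()].
#' @param t vector of evaluation times.
#' @return Data frame with columns \code{t}, \code{H_n}, \code{R_n}.
#' @export
risk_process <- function(sample, t) {
  stopifnot(inherits(sample, "lbrc_sample"), all(t >= 0))
  n <- nrow(sample)
  y1 <- sort(sample$y[sample$delta == 1])
  H <- findInterval(t, y1) / n
  R <- risk2_at(sample, t) / (2 * n)
  data.frame(t = t, H_n = H, R_n = R)
}
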