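#' Time grids for pseudo-observations
#'
#' Pseudo-observations are computed on a fixed grid
#' \eqn{\tau_1 < \cdots < \tau_m}. `time_grid()` validates an explicit
#' grid; `default_grid()` builds the quantile grid used for real-data
#' analyses: probabilities \eqn{k/(m+1)}, \eqn{k = 1, \dots, m}, of the
#' uncensored total times (so \code{m = 9} gives the 10th-90th percentiles),
#' with linear interpolation between order statistics.
#'
#' @param times strictly increasing positive times.
#' @return Numeric vector of class \code{"lb_grid"}.
#' @export
time_grid <- function(times) {
  times <- as.numeric(times)
  stopifnot(length(times) >= 1, all(times > 0),
            !is.unsorted(times, strictly = TRUE))
  structure(times, class = "lb_grid")
}

#' @rdname time_grid
#' @param sample an [lbrc_sample()].
#' @param m number of grid points (requires at least \code{m} uncensored
#'   observations).
#' @export
default_grid <- function(sample, m = 9) {
  y1 <- sample$y[sample$delta == 1]
  if (length(y1) < m)
    stop("need at least ", m, " uncensored observations for an m = ", m,
         " quantile grid")
  q <- stats::quantile(y1, probs = seq_len(m) / (m + 1), names = FALSE,
                       type = 7)
  if (anyDuplicated(q)) stop("quantile grid has tied time points")
  time_grid(q)
}

#' @rdname time_grid
#' @param spec grid specification string \code{"from:to:by"}, e.g.
#'   \code{"0.4:1.3:0.1"} for the ten equally spaced simulation-study
#'   points.
#' @export
parse_grid <- function(spec) {
  parts <- suppressWarnings(as.numeric(strsplit(spec, ":", fixed = TRUE)[[1]]))
  if (length(parts) != 3 || anyNA(parts))
    stop("grid spec must be 'from:to:by', e.g. '0.4:1.3:0.1'")
  time_grid(seq(parts[1], parts[2], by = parts[3]))
}

#' Jackknife pseudo-observations of the survival function
#'
#' For each subject i and grid point \eqn{\tau_j}, the jackknife
#' pseudo-value
#' \eqn{\hat S_i(\tau_j) = n \hat S(\tau_j) - (n-1)\hat S^{(-i)}(\tau_j)},
#' where \eqn{\hat S} is the chosen survival estimator on the full sample
#' and \eqn{\hat S^{(-i)}} its leave-one-out counterpart. Pseudo-values act
#' as surrogate responses for \eqn{I(\tilde T_i > \tau_j)} in the
#' regression step and may lie outside [0, 1].
#'
#' Leave-one-out curves for the product-limit estimators are obtained by
#' subtracting the deleted subject's contribution from the event and
#' risk-set tallies, which is algebraically identical to a full
#' recomputation but costs O(n) per subject. The NPMLE is refitted by EM,
#' warm-started from the full-sample masses with the deleted subject's
#' share removed and renormalized. Grid points beyond a leave-one-out
#' curve's last event reuse its last value (right-constant convention).
#'
#' @param sample an [lbrc_sample()] with n >= 3.
#' @param estimator \code{"wang"}, \code{"vardi"}, \code{"ltrc"}, or
#'   \code{"empirical"} (the jackknife of the plain empirical survival of
#'   \code{y}, a test hook whose pseudo-values are exactly
#'   \eqn{I(y_i > \tau_j)}).
#' @param grid a [time_grid()] (or numeric vector of strictly increasing
#'   times).
#' @param tol,max_iter EM controls passed to [surv_vardi()] (ignored for
#'   the closed-form estimators).
#' @return An n x m matrix of class \code{"lb_pseudo"} with attributes
#'   \code{grid}, \code{estimator} and \code{valid} (per-subject logical;
#'   a subject is invalid when its leave-one-out estimator is undefined,
#'   e.g. no events remain).
#' @export
pseudo_lbrc <- function(sample, estimator = c("wang", "ltrc", "vardi",
                                              "empirical"),
                        grid, tol = 1e-8, max_iter = 5000) {
  estimator <- match.arg(estimator)
  if (!inherits(grid, "lb_grid")) grid <- time_grid(grid)
  n <- nrow(sample)
  stopifnot(n >= 3)
  out <- switch(estimator,
                wang = pseudo_pl(sample, grid, lb = TRUE),
                ltrc = pseudo_pl(sample, grid, lb = FALSE),
                vardi = pseudo_vardi(sample, grid, tol, max_iter),
                empirical = pseudo_empirical(sample, grid))
  dimnames(out$values) <- list(NULL, signif(unclass(grid), 6))
  structure(out$values, grid = grid, estimator = estimator,
            valid = out$valid, class = "lb_pseudo")
}

#' Write a pseudo-observation matrix as delimited text
#'
#' Long format with columns \code{subject,tau,pseudo_value}, one row per
#' (subject, grid point); invalid subjects are omitted.
#'
#' @param pseudo an \code{"lb_pseudo"} matrix.
#' @param path output file path.
#' @export
write_pseudo <- function(pseudo, path) {
  stopifnot(inherits(pseudo, "lb_pseudo"))
  grid <- as.numeric(attr(pseudo, "grid"))
  valid <- which(attr(pseudo, "valid"))
  df <- data.frame(subject = rep(valid, each = length(grid)),
                   tau = rep(grid, length(valid)),
                   pseudo_value = as.vector(t(pseudo[valid, ,
                                                     drop = FALSE])))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.lb_pseudo <- function(x, ...) {
  cat("Pseudo-observation matrix (", attr(x, "estimator"), "): ",
      nrow(x), " subjects x ", ncol(x), " time points; ",
      sum(!attr(x, "valid")), " invalid subject(s)\n", sep = "")
  invisible(x)
}

## step-evaluate a cumulative product at the grid
eval_steps <- function(u, vals, grid) {
  c(1, vals)[findInterval(grid, u) + 1L]
}

## Jackknife for the two product-limit estimators via tally subtraction.
## lb = TRUE: Wang factors 1 - 2 d(u)/risk2(u); FALSE: 1 - d(u)/risk1(u).
pseudo_pl <- function(sample, grid, lb) {
  tl <- event_tallies(sample)
  n <- tl$n
  u <- tl$u; K <- length(u)
  d <- tl$d
  risk <- if (lb) tl$risk2 else tl$risk1
  scale <- if (lb) 2 else 1
  full_fac <- ifelse(risk > 0, pmax(1 - scale * d / pmax(risk, 1), 0), 1)
  S_full <- eval_steps(u, cumprod(full_fac), grid)
  a <- sample$a; y <- sample$y; delta <- sample$delta; v <- y - a
  pos <- ifelse(delta == 1, match(y, u), NA_integer_)
  vals <- matrix(NA_real_, n, length(grid))
  valid <- rep(TRUE, n)
  for (i in seq_len(n)) {
    di <- d
    if (!is.na(pos[i])) di[pos[i]] <- di[pos[i]] - 1L
    ri <- if (lb) risk - risk2_contrib(u, a[i], y[i], v[i], delta[i])
          else risk - ((a[i] < u) & (u <= y[i]))
    if (all(di == 0)) { valid[i] <- FALSE; next }
    fac <- ifelse(ri > 0, pmax(1 - scale * di / pmax(ri, 1), 0), 1)
    S_i <- eval_steps(u, cumprod(fac), grid)
    vals[i, ] <- n * S_full - (n - 1) * S_i
  }
  list(values = vals, valid = valid)
}

## Jackknife for the NPMLE: EM refits warm-started from the full fit.
pseudo_vardi <- function(sample, grid, tol, max_iter) {
  n <- nrow(sample)
  y <- sample$y; delta <- sample$delta
  prep <- vardi_prep(y, delta)
  fit <- vardi_em(prep$tk, prep$d, prep$cnt, n,
                  rep(1 / prep$K, prep$K), tol, max_iter)
  S_full <- vardi_grid_eval(prep$tk, fit$p, grid)
  pos <- ifelse(delta == 1, match(y, prep$tk), NA_integer_)
  jmap <- findInterval(y, prep$tk, left.open = TRUE) + 1L
  jmap[jmap > prep$K] <- prep$K
  vals <- matrix(NA_real_, n, length(grid))
  valid <- rep(TRUE, n)
  for (i in seq_len(n)) {
    if (delta[i] == 1) {
      k <- pos[i]
      if (prep$d[k] > 1L) {
        tk_i <- prep$tk; d_i <- prep$d; cnt_i <- prep$cnt
        d_i[k] <- d_i[k] - 1L
        p0 <- fit$p * (d_i + cnt_i) / pmax(prep$d + prep$cnt, 1)
      } else {
        if (prep$K == 1L) { valid[i] <- FALSE; next }
        tk_i <- prep$tk[-k]; d_i <- prep$d[-k]
        # censored observations re-map to the reduced support
        z <- y[delta == 0]
        j <- findInterval(z, tk_i, left.open = TRUE) + 1L
        j[j > length(tk_i)] <- length(tk_i)
        cnt_i <- tabulate(j, nbins = length(tk_i))
        p0 <- fit$p[-k]
      }
    } else {
      tk_i <- prep$tk; d_i <- prep$d; cnt_i <- prep$cnt
      cnt_i[jmap[i]] <- cnt_i[jmap[i]] - 1L
      p0 <- fit$p
    }
    p0 <- pmax(p0, 1e-12); p0 <- p0 / sum(p0)
    ref <- vardi_em(tk_i, d_i, cnt_i, n - 1L, p0, tol, max_iter)
    S_i <- vardi_grid_eval(tk_i, ref$p, grid)
    vals[i, ] <- n * S_full - (n - 1) * S_i
  }
  list(values = vals, valid = valid)
}

vardi_grid_eval <- function(tk, p, grid) {
  r <- p / tk
  tail_r <- rev(cumsum(rev(r)))
  c(tail_r, 0)[findInterval(grid, tk) + 1L] / tail_r[1]
}

## Test hook: jackknife of the empirical survival of y; equals I(y_i > tau)
## exactly, computed through the actual leave-one-out arithmetic.
pseudo_empirical <- function(sample, grid) {
  n <- nrow(sample)
  y <- sample$y
  S_full <- vapply(unclass(grid), function(tt) mean(y > tt), 0)
  vals <- matrix(NA_real_, n, length(grid))
  for (i in seq_len(n)) {
    S_i <- vapply(unclass(grid), function(tt) mean(y[-i] > tt), 0)
    vals[i, ] <- n * S_full - (n - 1) * S_i
  }
  list(values = vals, valid = rep(TRUE, n))
}
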