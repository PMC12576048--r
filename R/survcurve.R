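#' Step-function survival curve
#'
#' Container for the nonparametric survival estimates: a right-continuous,
#' non-increasing step function equal to 1 before the first jump and
#' constant after the last one.
#'
#' @param time strictly increasing positive jump times.
#' @param surv survival values at (and after) each jump, in [0, 1],
#'   non-increasing.
#' @param estimator label: \code{"wang"}, \code{"vardi"}, \code{"ltrc"}, ...
#' @param converged logical; \code{FALSE} when an iterative fit stopped at
#'   its iteration cap.
#' @param flagged logical; \code{TRUE} when a zero-risk event time was
#'   skipped.
#' @param extra list of estimator-specific components (e.g. the fitted
#'   length-biased masses for the NPMLE).
#' @return Object of class \code{"lb_survcurve"}.
#' @export
lb_survcurve <- function(time, surv, estimator = "custom", converged = TRUE,
                         flagged = FALSE, extra = list()) {
  stopifnot(length(time) == length(surv))
  if (length(time)) {
    stopifnot(all(time > 0), !is.unsorted(time, strictly = TRUE),
              all(surv >= -1e-12), all(surv <= 1 + 1e-12))
    surv <- pmin(pmax(surv, 0), 1)
    if (any(diff(surv) > 1e-12)) stop("survival values must be non-increasing")
  }
  structure(list(time = as.numeric(time), surv = as.numeric(surv),
                 estimator = estimator, converged = converged,
                 flagged = flagged, extra = extra),
            class = "lb_survcurve")
}

#' Evaluate a survival curve
#'
#' Right-continuous step evaluation: 1 before the first jump, the last
#' value after the final jump.
#'
#' @param curve an [lb_survcurve()].
#' @param t vector of evaluation times (>= 0).
#' @return Vector of survival probabilities.
#' @export
surv_eval <- function(curve, t) {
  stopifnot(inherits(curve, "lb_survcurve"), all(t >= 0))
  c(1, curve$surv)[findInterval(t, curve$time) + 1L]
}

#' @export
print.lb_survcurve <- function(x, ...) {
  cat("Survival curve (", x$estimator, "): ", length(x$time),
      " jump times", sep = "")
  if (length(x$time))
    cat(" on [", signif(min(x$time), 4), ", ", signif(max(x$time), 4), "]",
        sep = "")
  if (!x$converged) cat("  [NOT CONVERGED]")
  if (x$flagged) cat("  [zero-risk event time skipped]")
  cat("\n")
  invisible(x)
}

#' @export
as.data.frame.lb_survcurve <- function(x, ...) {
  data.frame(time = c(0, x$time), survival = c(1, x$surv))
}

#' Write a survival curve as delimited text
#'
#' Two columns \code{time,survival} with an initial row \code{0,1}.
#'
#' @param curve an [lb_survcurve()].
#' @param path output file path.
#' @export
write_survcurve <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
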