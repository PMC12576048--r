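#' Construct a length-biased right-censored sample
#'
#' The basic data container: one row per subject with truncation time
#' \code{a} (onset to recruitment), total observed time \code{y} (onset to
#' event or censoring), event indicator \code{delta}, and covariate columns.
#' All downstream estimators take this class.
#'
#' @param data data frame with columns \code{a}, \code{y}, \code{delta}
#'   followed by covariate columns (any names), or a data frame containing
#'   at least those columns.
#' @param covariates character vector naming the covariate columns; defaults
#'   to every column other than \code{a}, \code{y}, \code{delta}.
#' @return Object of class \code{c("lbrc_sample", "data.frame")}.
#' @export
lbrc_sample <- function(data, covariates = NULL) {
  stopifnot(is.data.frame(data))
  need <- c("a", "y", "delta")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("missing required columns: ", paste(miss, collapse = ", "))
  if (is.null(covariates))
    covariates <- setdiff(names(data), need)
  data <- as.data.frame(data)[, c(need, covariates), drop = FALSE]
  validate_lbrc(data, covariates)
  structure(data, covariates = covariates,
            class = c("lbrc_sample", "data.frame"))
}

validate_lbrc <- function(data, covariates) {
  if (nrow(data) < 2) stop("an LBRC sample needs at least 2 subjects")
  for (cl in c("a", "y", "delta", covariates))
    if (!is.numeric(data[[cl]]))
      stop("column '", cl, "' must be numeric")
  if (anyNA(data)) stop("missing values are not allowed in an LBRC sample")
  bad <- which(!(data$a >= 0 & data$a <= data$y))
  if (length(bad))
    stop("rows violating 0 <= a <= y: ", paste(bad, collapse = ", "))
  if (!all(data$delta %in% c(0, 1)))
    stop("delta must be binary (0/1)")
  invisible(data)
}

#' @export
print.lbrc_sample <- function(x, ...) {
  cat("LBRC sample: ", nrow(x), " subjects, ",
      sum(x$delta == 1), " events (censoring ",
      sprintf("%.1f%%", 100 * mean(x$delta == 0)), "), covariates: ",
      paste(attr(x, "covariates"), collapse = ", "), "\n", sep = "")
  print(utils::head(as.data.frame(x)))
  if (nrow(x) > 6) cat("... (", nrow(x) - 6, " more rows)\n", sep = "")
  invisible(x)
}

covariate_matrix <- function(sample) {
  cn <- attr(sample, "covariates")
  as.matrix(as.data.frame(sample)[, cn, drop = FALSE])
}

n_subjects <- function(sample) nrow(sample)
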