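#' Read and write LBRC cohorts as delimited text
#'
#' Cohort files are plain CSV with header \code{a,y,delta,x1,...,xp}; one
#' row per subject, no missing values. `read_lbrc()` validates each row
#' (0 <= a <= y, binary delta) and reports offending data lines by number.
#'
#' @param path file path.
#' @return `read_lbrc()`: an [lbrc_sample()]; `write_lbrc()`: the path,
#'   invisibly.
#' @export
read_lbrc <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("a", "y", "delta")
  if (!all(need %in% names(df)) ||
      !identical(names(df)[seq_len(3)], need))
    stop("expected header starting 'a,y,delta' in ", path)
  for (cl in names(df))
    if (!is.numeric(df[[cl]]))
      stop("non-numeric column '", cl, "' in ", path)
  if (anyNA(df)) {
    bad <- which(apply(df, 1, anyNA))
    stop("missing values on line(s) ", paste(bad + 1L, collapse = ", "),
         " of ", path)
  }
  bad <- which(!(df$a >= 0 & df$a <= df$y))
  if (length(bad))
    stop("0 <= a <= y violated on line(s) ",
         paste(bad + 1L, collapse = ", "), " of ", path)
  if (!all(df$delta %in% c(0, 1))) {
    bad <- which(!(df$delta %in% c(0, 1)))
    stop("non-binary delta on line(s) ", paste(bad + 1L, collapse = ", "),
         " of ", path)
  }
  lbrc_sample(df)
}

#' @rdname read_lbrc
#' @param sample an [lbrc_sample()].
#' @export
write_lbrc <- function(sample, path) {
  stopifnot(inherits(sample, "lbrc_sample"))
  utils::write.csv(as.data.frame(sample), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Prepare the Channing House data for length-biased analysis
#'
#' Restricts a Channing House style data frame (columns \code{sex},
#' \code{entry}, \code{exit} in months of age, \code{cens} = death
#' indicator, optionally \code{time} = months in residence) to residents
#' aged 65 or older at entry and moves the time origin to age 65 (780
#' months): \code{a = entry - 780}, \code{y = exit - 780},
#' \code{delta = cens}, with a single binary covariate \code{male}
#' (\code{1} for men, the reference group). A record whose exit age
#' precedes its entry age is impossible; when a \code{time} column is
#' available such records are repaired as \code{exit = entry + time},
#' otherwise they are dropped with a warning.
#'
#' @param data data frame as described (e.g. \code{boot::channing}).
#' @param origin_months age origin in months (default 780 = 65 years).
#' @return An [lbrc_sample()] with covariate \code{male}; the achieved
#'   censoring fraction is attached as attribute \code{"censoring"}.
#' @export
prepare_channing <- function(data, origin_months = 780) {
  need <- c("sex", "entry", "exit", "cens")
  stopifnot(all(need %in% names(data)))
  bad <- which(data$exit < data$entry)
  if (length(bad)) {
    if ("time" %in% names(data)) {
      data$exit[bad] <- data$entry[bad] + data$time[bad]
      warning(length(bad), " record(s) with exit < entry repaired as ",
              "entry + time")
    } else {
      data <- data[-bad, , drop = FALSE]
      warning(length(bad), " record(s) with exit < entry dropped")
    }
  }
  keep <- data$entry >= origin_months
  if (!any(keep)) stop("no subjects at or above the age origin")
  d <- data[keep, , drop = FALSE]
  out <- lbrc_sample(data.frame(
    a = d$entry - origin_months,
    y = d$exit - origin_months,
    delta = as.numeric(d$cens),
    male = as.numeric(d$sex == "Male")))
  attr(out, "censoring") <- mean(out$delta == 0)
  out
}
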