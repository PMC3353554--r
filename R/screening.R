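#' Descriptive statistics and m +/- 3s outlier thresholds
#'
#' Computes the univariate summary used to screen each per-date
#' phenology dataset before variography: mean, sample variance
#' (n - 1 denominator), standard deviation, minimum, maximum,
#' coefficient of variation, and the outlier thresholds
#' `m - 3s` / `m + 3s` below or above which a value is treated as an
#' outlier.
#'
#' @param values Numeric phase values (or a [pheno_dataset()]).
#' @return An object of class `"descriptive_stats"`: a list with
#'   `n`, `mean`, `variance`, `sd`, `min`, `max`, `cv`,
#'   `lower_threshold`, `upper_threshold`, and a character vector
#'   `flags` (e.g. `"single_observation"`, `"cv_undefined"`).
#' @export
#' @examples
#' s <- descriptive_stats(c(0.2, 0.8, 1.2, 1.4, 1.0, 1.6, 1.1))
#' s$upper_threshold
descriptive_stats <- function(values) {
  if (inherits(values, "pheno_dataset")) values <- values$values
  values <- as.numeric(values)
  if (length(values) == 0) stop("empty dataset", call. = FALSE)
  if (anyNA(values) || any(!is.finite(values))) {
    stop("values must be finite and non-missing", call. = FALSE)
  }
  n <- length(values)
  m <- mean(values)
  flags <- character(0)
  if (n == 1) {
    v <- 0
    flags <- c(flags, "single_observation")
  } else {
    v <- stats::var(values)
  }
  s <- sqrt(v)
  if (m == 0) {
    cv <- NA_real_
    flags <- c(flags, "cv_undefined")
  } else {
    cv <- s / m
  }
  thr <- compute_thresholds(m, s)
  structure(
    list(n = n, mean = m, variance = v, sd = s,
         min = min(values), max = max(values), cv = cv,
         lower_threshold = thr[["lower"]],
         upper_threshold = thr[["upper"]], flags = flags),
    class = "descriptive_stats")
}

#' @export
print.descriptive_stats <- function(x, ...) {
  cat(sprintf(paste0("<descriptive_stats> n = %d, mean = %.3f, ",
                     "variance = %.3f, range [%.2f, %.2f]\n"),
              x$n, x$mean, x$variance, x$min, x$max))
  cat(sprintf("  outlier thresholds (m +/- 3s): [%.3f, %.3f]\n",
              x$lower_threshold, x$upper_threshold))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Outlier thresholds m +/- 3s
#'
#' @param m Dataset mean (phase units).
#' @param s Dataset standard deviation (phase units, non-negative).
#' @return Named numeric vector `c(lower = m - 3 s, upper = m + 3 s)`.
#' @export
#' @examples
#' compute_thresholds(2.82, sqrt(0.41))
compute_thresholds <- function(m, s) {
  if (!is.finite(m) || !is.finite(s)) {
    stop("`m` and `s` must be finite", call. = FALSE)
  }
  if (s < 0) stop("standard deviation must be non-negative", call. = FALSE)
  c(lower = m - 3 * s, upper = m + 3 * s)
}

#' Flag outliers against m +/- 3s thresholds
#'
#' A value is an outlier iff it lies strictly below the lower or
#' strictly above the upper threshold; boundary values are kept.
#'
#' @param values Numeric phase values.
#' @param stats A `descriptive_stats` object (normally computed from the
#'   same values).
#' @return Logical vector, `TRUE` where the value is an outlier.
#' @export
flag_outliers <- function(values, stats) {
  stopifnot(inherits(stats, "descriptive_stats"))
  if (inherits(values, "pheno_dataset")) values <- values$values
  values <- as.numeric(values)
  values < stats$lower_threshold | values > stats$upper_threshold
}

#' Per-date descriptive summary table
#'
#' Applies [descriptive_stats()] to every dataset in a list and lays the
#' results out as one row per date (mean, variance, minimum, maximum, n,
#' thresholds, outlier count) — the screening table of the workflow.
#'
#' @param datasets A named list of [pheno_dataset()] objects (as
#'   returned by [read_observations()] with `points`).
#' @return A data.frame with one row per date.
#' @export
describe_datasets <- function(datasets) {
  if (inherits(datasets, "pheno_dataset")) datasets <- list(datasets)
  rows <- lapply(datasets, function(ds) {
    st <- descriptive_stats(ds)
    data.frame(date = format(ds$date), n = st$n, mean = st$mean,
               variance = st$variance, sd = st$sd, minimum = st$min,
               maximum = st$max, cv = st$cv,
               lower_threshold = st$lower_threshold,
               upper_threshold = st$upper_threshold,
               n_outliers = sum(flag_outliers(ds, st)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
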