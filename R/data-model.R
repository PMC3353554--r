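#' Validate a table of sampling points
#'
#' A sampling-point table describes the monitoring network: one
#' georeferenced site per row with projected planar coordinates in
#' metres, altitude above sea level and bioclimatic zone.
#'
#' @param df A data.frame with columns `id`, `x`, `y`, `altitude`,
#'   `zone`.
#' @return The validated data.frame with class `"sampling_points"`.
#' @export
as_sampling_points <- function(df) {
  required <- c("id", "x", "y", "altitude", "zone")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("sampling-point table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- df[, required]
  df$id <- as.character(df$id)
  for (col in c("x", "y", "altitude")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) | !is.finite(v))
    if (length(bad)) {
      stop(sprintf("non-numeric or non-finite `%s` at row(s) %s", col,
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
    df[[col]] <- v
  }
  dup <- which(duplicated(df$id))
  if (length(dup)) {
    stop("duplicate sampling-point id(s) at row(s) ",
         paste(dup, collapse = ", "), ": ",
         paste(unique(df$id[dup]), collapse = ", "), call. = FALSE)
  }
  bad_alt <- which(df$altitude < 0)
  if (length(bad_alt)) {
    stop("negative altitude at row(s) ", paste(bad_alt, collapse = ", "),
         call. = FALSE)
  }
  zones <- c("termomediterranean", "mesomediterranean")
  df$zone <- tolower(as.character(df$zone))
  bad_zone <- which(!df$zone %in% zones)
  if (length(bad_zone)) {
    stop("unknown bioclimatic zone at row(s) ",
         paste(bad_zone, collapse = ", "),
         " (expected termomediterranean or mesomediterranean)",
         call. = FALSE)
  }
  rownames(df) <- NULL
  class(df) <- c("sampling_points", "data.frame")
  df
}

#' Construct a per-date phenology dataset
#'
#' Bundles the sampling points observed on one date with their phase
#' values (0-4 scale, means of five quadrat scores).  This is the unit
#' every geostatistical operation consumes.
#'
#' @param points A `sampling_points` table (or coercible data.frame).
#' @param values Numeric phase values, one per row of `points`, each on
#'   \[0, 4\].
#' @param date The observation date (coerced with [as.Date()]).
#' @return An object of class `"pheno_dataset"`: a list with elements
#'   `date`, `points`, `values` (named by point id).
#' @export
pheno_dataset <- function(points, values, date) {
  if (!inherits(points, "sampling_points")) points <- as_sampling_points(points)
  values <- as.numeric(values)
  if (length(values) != nrow(points)) {
    stop("`values` must have one entry per sampling point (",
         length(values), " values for ", nrow(points), " points)",
         call. = FALSE)
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop("phase values must be finite and non-missing", call. = FALSE)
  }
  bad <- which(values < 0 | values > 4)
  if (length(bad)) {
    stop("phase value(s) outside [0, 4] for point(s) ",
         paste(points$id[bad], collapse = ", "), call. = FALSE)
  }
  structure(
    list(date = as.Date(date), points = points,
         values = stats::setNames(values, points$id)),
    class = "pheno_dataset")
}

#' @export
print.pheno_dataset <- function(x, ...) {
  cat(sprintf("<pheno_dataset> %s: n = %d, phase range [%.2f, %.2f]\n",
              format(x$date), length(x$values),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
length.pheno_dataset <- function(x) length(x$values)

#' Validate a daily airborne pollen series
#'
#' @param df A data.frame with columns `date` and `count`
#'   (pollen grains per cubic metre per day).
#' @return The validated data.frame with class `"pollen_series"`,
#'   dates strictly increasing.
#' @export
as_pollen_series <- function(df) {
  if (!all(c("date", "count") %in% names(df))) {
    stop("pollen series needs columns `date` and `count`", call. = FALSE)
  }
  df <- data.frame(date = as.Date(df$date),
                   count = as.numeric(df$count))
  if (anyNA(df$date)) {
    stop("unparseable pollen date at row(s) ",
         paste(which(is.na(df$date)), collapse = ", "), call. = FALSE)
  }
  bad <- which(is.na(df$count) | df$count < 0)
  if (length(bad)) {
    stop("negative or missing pollen count at row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (is.unsorted(df$date, strictly = TRUE)) {
    stop("pollen dates must be strictly increasing", call. = FALSE)
  }
  class(df) <- c("pollen_series", "data.frame")
  df
}

# Euclidean distance matrix of a point set (planar metres).
point_distances <- function(points) {
  as.matrix(stats::dist(cbind(points$x, points$y)))
}
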