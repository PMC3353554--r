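#' Read a sampling-point table from delimited text
#'
#' Expects a comma-separated file with header
#' `id,x,y,altitude,zone`; coordinates in planar metres, altitude in
#' metres a.s.l., zone one of `termomediterranean` /
#' `mesomediterranean`.  Malformed rows are reported by row number.
#'
#' @param path Path to the CSV file.
#' @return A validated `sampling_points` data.frame.
#' @seealso [cordoba_points()] for the bundled study network.
#' @export
read_points <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  as_sampling_points(df)
}

#' Write a sampling-point table
#' @param points A `sampling_points` data.frame.
#' @param path Output CSV path.
#' @export
write_points <- function(points, path) {
  if (!inherits(points, "sampling_points")) points <- as_sampling_points(points)
  utils::write.csv(points, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' The ten sampling points of the Cordoba study network
#'
#' The monitoring network bundled with the package: ten sites across the
#' city of Cordoba and the lower Sierra, five in the termomediterranean
#' belt (92-217 m) and five in the mesomediterranean belt (251-585 m).
#' Coordinates are projected planar metres.
#'
#' @return A `sampling_points` data.frame with 10 rows.
#' @export
#' @examples
#' cordoba_points()
cordoba_points <- function() {
  read_points(system.file("extdata", "sampling_points_cordoba.csv",
                          package = "phenokrige", mustWork = TRUE))
}

#' Read per-date phenology observations
#'
#' Expects a comma-separated file with header `point_id,date,phase`;
#' dates ISO-8601, phase on \[0, 4\].  Out-of-range or malformed rows are
#' rejected by row number.
#'
#' @param path Path to the CSV file.
#' @param points Optional `sampling_points` table; when supplied, the
#'   observations are split by date into a list of [pheno_dataset()]
#'   objects (ids must match the point table).
#' @return A data.frame of class `"pheno_observations"` with columns
#'   `point_id`, `date`, `phase` — or, when `points` is given, a named
#'   list of `pheno_dataset` objects keyed by ISO date.
#' @export
read_observations <- function(path, points = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  required <- c("point_id", "date", "phase")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("observations file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  dates <- as.Date(df$date)
  if (anyNA(dates) && nrow(df)) {
    stop("unparseable date at row(s) ",
         paste(which(is.na(dates)), collapse = ", "), call. = FALSE)
  }
  phase <- suppressWarnings(as.numeric(df$phase))
  bad <- which(is.na(phase) | phase < 0 | phase > 4)
  if (length(bad)) {
    stop("phase missing or outside [0, 4] at row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  obs <- data.frame(point_id = as.character(df$point_id),
                    date = dates, phase = phase)
  class(obs) <- c("pheno_observations", "data.frame")
  if (is.null(points)) return(obs)
  split_observations(obs, points)
}

#' Split an observation table into per-date phenology datasets
#'
#' @param obs A `pheno_observations` data.frame (`point_id`, `date`,
#'   `phase`).
#' @param points A `sampling_points` table covering every observed id.
#' @return A named list of [pheno_dataset()] objects keyed by ISO date,
#'   in date order.
#' @export
split_observations <- function(obs, points) {
  if (!inherits(points, "sampling_points")) points <- as_sampling_points(points)
  unknown <- setdiff(unique(obs$point_id), points$id)
  if (length(unknown)) {
    stop("observation point id(s) absent from the point table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  dates <- sort(unique(obs$date))
  out <- lapply(dates, function(d) {
    sub <- obs[obs$date == d, , drop = FALSE]
    if (anyDuplicated(sub$point_id)) {
      stop("duplicate observation for point(s) ",
           paste(unique(sub$point_id[duplicated(sub$point_id)]),
                 collapse = ", "), " on ", format(d), call. = FALSE)
    }
    pts <- points[match(sub$point_id, points$id), , drop = FALSE]
    rownames(pts) <- NULL
    class(pts) <- c("sampling_points", "data.frame")
    pheno_dataset(pts, sub$phase, d)
  })
  stats::setNames(out, format(dates))
}

#' Write phenology observations to delimited text
#'
#' @param x Either a `pheno_observations` data.frame or a list of
#'   [pheno_dataset()] objects.
#' @param path Output CSV path.
#' @export
write_observations <- function(x, path) {
  if (inherits(x, "pheno_dataset")) x <- list(x)
  if (is.list(x) && !is.data.frame(x)) {
    x <- do.call(rbind, lapply(x, function(ds) {
      data.frame(point_id = ds$points$id,
                 date = rep(ds$date, length(ds$values)),
                 phase = unname(ds$values))
    }))
  }
  out <- data.frame(point_id = x$point_id, date = format(as.Date(x$date)),
                    phase = sprintf("%.6f", x$phase))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a daily pollen series from delimited text
#'
#' Expects header `date,count` with ISO dates and daily mean
#' concentrations in pollen grains per cubic metre.
#'
#' @param path Path to the CSV file.
#' @return A validated `pollen_series` data.frame.
#' @export
read_pollen <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_pollen_series(df)
}

#' Write a daily pollen series
#' @param series A `pollen_series` data.frame.
#' @param path Output CSV path.
#' @export
write_pollen <- function(series, path) {
  series <- as_pollen_series(series)
  out <- data.frame(date = format(series$date),
                    count = sprintf("%.6f", series$count))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a phenology grid as an ESRI ASCII raster
#'
#' Emits the standard `.asc` layout: a six-line header
#' (`ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`,
#' `NODATA_value`) followed by rows of values, north row first.
#'
#' @param grid A [pheno_grid()] object.
#' @param path Output path (conventionally `.asc`).
#' @param digits Significant digits written per cell (default 10).
#' @export
write_ascii_grid <- function(grid, path, digits = 10) {
  stopifnot(inherits(grid, "pheno_grid"))
  if (nrow(grid$values) < 1 || ncol(grid$values) < 1) {
    stop("cannot write an empty grid", call. = FALSE)
  }
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(grid$values)),
    sprintf("nrows %d", nrow(grid$values)),
    sprintf("xllcorner %.6f", grid$xll),
    sprintf("yllcorner %.6f", grid$yll),
    sprintf("cellsize %.6f", grid$cellsize),
    sprintf("NODATA_value %s", format(grid$nodata))), con)
  fmt <- paste0("%.", digits, "g")
  vals <- grid$values
  vals[is.na(vals)] <- grid$nodata
  for (i in seq_len(nrow(vals))) {
    writeLines(paste(sprintf(fmt, vals[i, ]), collapse = " "), con)
  }
  invisible(path)
}

#' Read an ESRI ASCII raster into a phenology grid
#'
#' @param path Path to a `.asc` file.
#' @param validate Passed through to [pheno_grid()]: check that values
#'   lie on the phase scale \[0, 4\].
#' @return A [pheno_grid()] object (NODATA cells become `NA`).
#' @export
read_ascii_grid <- function(path, validate = TRUE) {
  lines <- readLines(path)
  if (length(lines) < 7) stop("not an ESRI ASCII grid: ", path, call. = FALSE)
  hdr <- list()
  for (i in 1:6) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) != 2) {
      stop("malformed header line ", i, " in ", path, call. = FALSE)
    }
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  if (!all(need %in% names(hdr))) {
    stop("ESRI ASCII header incomplete in ", path, call. = FALSE)
  }
  body <- lines[-(1:6)]
  body <- body[nzchar(trimws(body))]
  vals <- as.numeric(unlist(strsplit(trimws(body), "\\s+")))
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc) {
    stop(sprintf("expected %d values, found %d in %s", nr * nc,
                 length(vals), path), call. = FALSE)
  }
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == hdr$nodata_value] <- NA_real_
  pheno_grid(m, xll = hdr$xllcorner, yll = hdr$yllcorner,
             cellsize = hdr$cellsize, nodata = hdr$nodata_value,
             validate = validate)
}
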