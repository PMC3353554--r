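#' Construct a phenology raster grid
#'
#' A regular north-up raster of phase values over a planar bounding
#' box.  Row 1 of the value matrix is the northernmost row (the ESRI
#' ASCII convention); `NA` cells are NODATA.
#'
#' @param values Numeric matrix (nrows x ncols), row 1 = north.
#' @param xll,yll Coordinates of the lower-left corner, metres.
#' @param cellsize Cell size in metres.
#' @param nodata NODATA sentinel used on disk (default -9999).
#' @param clamp_flags Optional logical matrix marking cells whose value
#'   was clamped to \[0, 4\] during estimation.
#' @param validate Check that non-NA values lie on \[0, 4\]
#'   (default `TRUE`).
#' @return An object of class `"pheno_grid"`.
#' @export
pheno_grid <- function(values, xll, yll, cellsize, nodata = -9999,
                       clamp_flags = NULL, validate = TRUE) {
  values <- as.matrix(values)
  if (nrow(values) < 1 || ncol(values) < 1) {
    stop("grid must have at least one cell", call. = FALSE)
  }
  if (cellsize <= 0) stop("`cellsize` must be positive", call. = FALSE)
  if (validate) {
    bad <- !is.na(values) & (values < 0 | values > 4)
    if (any(bad)) {
      stop(sum(bad), " grid value(s) outside the phase scale [0, 4]",
           call. = FALSE)
    }
  }
  if (!is.null(clamp_flags)) {
    clamp_flags <- as.matrix(clamp_flags)
    stopifnot(identical(dim(clamp_flags), dim(values)))
  }
  structure(list(values = values, xll = xll, yll = yll,
                 cellsize = cellsize, nodata = nodata,
                 clamp_flags = clamp_flags),
            class = "pheno_grid")
}

#' @export
print.pheno_grid <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf(paste0("<pheno_grid> %d x %d cells of %.0f m, origin ",
                     "(%.1f, %.1f)\n"),
              nrow(x$values), ncol(x$values), x$cellsize, x$xll, x$yll))
  if (length(v)) {
    cat(sprintf("  values: [%.3f, %.3f], NODATA cells: %d\n",
                min(v), max(v), sum(is.na(x$values))))
  } else {
    cat("  all cells NODATA\n")
  }
  if (!is.null(x$clamp_flags) && any(x$clamp_flags)) {
    cat("  clamped cells:", sum(x$clamp_flags), "\n")
  }
  invisible(x)
}

#' @export
dim.pheno_grid <- function(x) dim(x$values)

#' Value of the grid cell containing a point
#'
#' @param grid A [pheno_grid()].
#' @param x,y Point coordinates in metres (vectorised).
#' @return Cell values (`NA` outside the grid or on NODATA cells).
#' @export
grid_extract <- function(grid, x, y) {
  col <- floor((x - grid$xll) / grid$cellsize) + 1
  row_from_south <- floor((y - grid$yll) / grid$cellsize) + 1
  row <- nrow(grid$values) - row_from_south + 1
  ok <- col >= 1 & col <= ncol(grid$values) &
    row >= 1 & row <= nrow(grid$values)
  out <- rep(NA_real_, length(x))
  out[ok] <- grid$values[cbind(row[ok], col[ok])]
  out
}

#' Classify the full-flowering band of a phenological map
#'
#' Cells with a kriged phase between `lo` and `hi` (inclusive; default
#' 1.5-2.5) mark populations at full flowering — shedding pollen at
#' their maximum — and so the areas contributing most to the airborne
#' pollen curve.
#'
#' @param grid A [pheno_grid()].
#' @param lo,hi Band bounds in phase units, `lo < hi`.
#' @return An object of class `"flowering_mask"`: list with the grid
#'   geometry, logical `mask` (NA on NODATA cells) and `area_fraction`
#'   (masked cells over valid cells).
#' @export
#' @examples
#' g <- pheno_grid(matrix(c(1.0, 1.5, 2.0, 2.5, 3.0), nrow = 1),
#'                 xll = 0, yll = 0, cellsize = 100)
#' classify_full_flowering(g)$area_fraction  # 0.6
classify_full_flowering <- function(grid, lo = 1.5, hi = 2.5) {
  stopifnot(inherits(grid, "pheno_grid"))
  if (!(lo < hi)) stop("`lo` must be below `hi`", call. = FALSE)
  valid <- !is.na(grid$values)
  if (!any(valid)) stop("all grid cells are NODATA", call. = FALSE)
  mask <- grid$values >= lo & grid$values <= hi
  structure(list(xll = grid$xll, yll = grid$yll,
                 cellsize = grid$cellsize, mask = mask,
                 band = c(lo = lo, hi = hi),
                 area_fraction = sum(mask, na.rm = TRUE) / sum(valid)),
            class = "flowering_mask")
}

#' @export
print.flowering_mask <- function(x, ...) {
  cat(sprintf(paste0("<flowering_mask> band [%.2f, %.2f]: area fraction ",
                     "%.3f\n"), x$band["lo"], x$band["hi"],
              x$area_fraction))
  invisible(x)
}

#' Integer phase-class map
#'
#' Assigns each cell to the nearest integer phenophase 0-4
#' (round half up: 1.5 maps to class 2), the binning used for map
#' legends.  Clamp flags of the source grid are carried along.
#'
#' @param grid A [pheno_grid()].
#' @return A `pheno_grid` of integer classes 0-4.
#' @export
phase_class_map <- function(grid) {
  stopifnot(inherits(grid, "pheno_grid"))
  cls <- floor(grid$values + 0.5)
  cls[cls < 0] <- 0
  cls[cls > 4] <- 4
  pheno_grid(cls, xll = grid$xll, yll = grid$yll,
             cellsize = grid$cellsize, nodata = grid$nodata,
             clamp_flags = grid$clamp_flags, validate = TRUE)
}

#' Altitude gradient of a phenological map
#'
#' Spearman rank correlation between the altitude of the sampling
#' points and the kriged phase of the cells containing them.  Negative
#' values mean lower-altitude sites are phenologically ahead (the
#' expected pattern when flowering advances from the lowlands up the
#' Sierra).
#'
#' @param grid A [pheno_grid()].
#' @param points A `sampling_points` table (>= 2 distinct altitudes).
#' @return List with `statistic` (rho, `NA` when degenerate), `n`, and
#'   `flags`.
#' @export
elevation_gradient_summary <- function(grid, points) {
  stopifnot(inherits(grid, "pheno_grid"))
  if (!inherits(points, "sampling_points")) points <- as_sampling_points(points)
  phase <- grid_extract(grid, points$x, points$y)
  keep <- !is.na(phase)
  alt <- points$altitude[keep]
  phase <- phase[keep]
  if (length(alt) < 2 || length(unique(alt)) < 2) {
    stop("need at least 2 points with distinct altitudes inside the grid",
         call. = FALSE)
  }
  flags <- character(0)
  if (length(unique(phase)) < 2) {
    rho <- NA_real_
    flags <- "constant_phase"
  } else {
    rho <- stats::cor(alt, phase, method = "spearman")
  }
  list(statistic = rho, n = length(alt), flags = flags)
}
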