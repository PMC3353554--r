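#' The five phenophases of the flowering scale
#'
#' Integer codes 0-4 with their meanings: 0 = before flowering
#' (inflorescence emerged, no open flowers), 1 = start of flowering
#' (up to 25% of flowers open), 2 = full flowering (25-75% open, maximum
#' pollen shedding), 3 = ending (more than 75% open, anthers emptying),
#' 4 = past flowering (anthers empty).
#'
#' @return A named integer vector of the five phase codes.
#' @export
#' @examples
#' phenophase_codes()
phenophase_codes <- function() {
  c(before_flowering = 0L, start_flowering = 1L, full_flowering = 2L,
    ending_flowering = 3L, past_flowering = 4L)
}

#' Score a phenophase from the fraction of open flowers
#'
#' Assigns the integer phenophase (0-4) from the observed fraction of
#' open flowers in the inflorescence and the anther state.  A flower
#' counts as open when its stamens are exerted.  Boundary fractions
#' (exactly 25% or 75%) are assigned to the lower-numbered phase.
#'
#' @param fraction_open Fraction of open flowers, on \[0, 1\].  Vectorised.
#' @param inflorescence_emerged Logical; has the inflorescence emerged?
#'   Before emergence the scale is undefined and `NA` is returned.
#' @param anthers_empty Logical; are (almost) all anthers empty?  When
#'   `TRUE` the plant is past flowering (phase 4) regardless of
#'   `fraction_open`.
#' @return Integer phenophase code(s) in 0-4 (`NA` before emergence).
#' @export
#' @examples
#' assign_phenophase(0.10)                        # 1: start of flowering
#' assign_phenophase(0.50)                        # 2: full flowering
#' assign_phenophase(0.90, anthers_empty = TRUE)  # 4: past flowering
assign_phenophase <- function(fraction_open, inflorescence_emerged = TRUE,
                              anthers_empty = FALSE) {
  if (!is.numeric(fraction_open)) {
    stop("`fraction_open` must be numeric", call. = FALSE)
  }
  bad <- !is.na(fraction_open) &
    (fraction_open < 0 | fraction_open > 1)
  if (any(bad)) {
    stop("`fraction_open` must lie in [0, 1]; offending value(s): ",
         paste(fraction_open[bad], collapse = ", "), call. = FALSE)
  }
  n <- max(length(fraction_open), length(inflorescence_emerged),
           length(anthers_empty))
  f <- rep_len(fraction_open, n)
  emerged <- rep_len(as.logical(inflorescence_emerged), n)
  empty <- rep_len(as.logical(anthers_empty), n)

  phase <- rep.int(NA_integer_, n)
  phase[empty] <- 4L
  open <- !empty
  phase[open & f == 0] <- 0L
  phase[open & f > 0 & f <= 0.25] <- 1L
  phase[open & f > 0.25 & f <= 0.75] <- 2L
  phase[open & f > 0.75] <- 3L
  phase[!emerged] <- NA_integer_
  phase
}
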