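#' @include AllClasses.R constructors.R utils.R
NULL

#' T-maze group score
#'
#' \code{(N_CS+ - N_CS-) / (N_CS+ + N_CS-)}: the trained preference of one
#' group of flies between the shock-paired (CS+) and unpaired (CS-) odors.
#' The formula is applied literally, so aversive memory gives negative
#' scores; see \code{\link{derivedIndices}} for the presentation-sign flag.
#'
#' @param nPlus,nMinus fly counts in the CS+ and CS- arms.
#' @return Score in [-1, 1].
#' @export
groupScore <- function(nPlus, nMinus) {
  tot <- nPlus + nMinus
  if (any(tot <= 0)) stop("N_CS+ + N_CS- must be positive", call. = FALSE)
  (nPlus - nMinus) / tot
}

#' Performance index from a reciprocal pair of groups
#'
#' One performance-index value is the mean of the scores of two genetically
#' identical groups conditioned in reciprocal experiments (either odorant
#' as CS+) and tested consecutively — averaging out any innate preference
#' for one odor.
#'
#' @param counts a validated behavior-counts data.frame (see
#'   \code{\link{behaviorCounts}}) holding exactly the two groups of one
#'   reciprocal pair, or a numeric(2) of the two group scores when
#'   \code{odors} supplies their CS+ odors.
#' @param odors character(2) CS+ odors, required for numeric input.
#' @return Performance index (numeric(1)).
#' @export
performanceIndex <- function(counts, odors = NULL) {
  if (is.numeric(counts)) {
    scores <- counts
    if (is.null(odors)) stop("odors required for numeric scores",
                             call. = FALSE)
  } else {
    counts <- behaviorCounts(counts)
    scores <- groupScore(counts$N_CS_plus, counts$N_CS_minus)
    odors <- counts$odor_as_CSplus
  }
  if (length(scores) != 2L)
    stop("a performance index needs exactly two reciprocal groups",
         call. = FALSE)
  if (odors[1] == odors[2])
    stop("pairing error: both groups used '", odors[1], "' as CS+",
         call. = FALSE)
  mean(scores)
}

#' Performance indices for a whole counts table
#'
#' Splits the table by \code{pair_id} and applies
#' \code{\link{performanceIndex}} to each reciprocal pair.
#'
#' @param counts behavior-counts data.frame with a \code{pair_id} column.
#' @return Named numeric of per-pair performance indices.
#' @export
performanceIndices <- function(counts) {
  counts <- behaviorCounts(counts)
  vapply(split(counts, counts$pair_id), performanceIndex, numeric(1))
}

#' Avoidance and attraction indices
#'
#' The avoidance index is computed exactly like the performance index; the
#' attraction index is the performance index multiplied by -1. With
#' \code{presentationSign = TRUE} the sign is flipped for plotting
#' positive memory scores (the printed formula yields CS+-ward scores).
#'
#' @param score a performance-index-form score.
#' @param type \code{"performance"}, \code{"avoidance"} or
#'   \code{"attraction"}.
#' @param presentationSign flip the sign for display.
#' @return Transformed index.
#' @export
derivedIndices <- function(score, type = c("performance", "avoidance",
                                           "attraction"),
                           presentationSign = FALSE) {
  type <- match.arg(type)
  out <- switch(type, performance = score, avoidance = score,
                attraction = -score)
  if (presentationSign) -out else out
}

#' Mean, SEM and n of a set of index values
#'
#' n is the number of independent index values (reciprocal pairs), not the
#' number of flies. A single value reports \code{SEM = NA}.
#'
#' @param values numeric vector of indices.
#' @return list \code{mean, sem, n}.
#' @export
summarizeIndices <- function(values) {
  n <- length(values)
  list(mean = mean(values),
       sem = if (n > 1L) stats::sd(values) / sqrt(n) else NA_real_,
       n = n)
}
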