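#' @include AllClasses.R constructors.R utils.R
NULL

# Separable anisotropic 3D Gaussian blur. sigmaUm is a scalar in um; each
# axis uses sigmaUm / voxelSize[axis] voxels. Kernel truncated at 3 sigma,
# boundary handled by renormalizing the truncated kernel (no spill).
gaussianBlur3D <- function(a, sigmaUm, voxelSize) {
  stopIfNot3D(a)
  for (ax in 1:3) {
    s <- sigmaUm / voxelSize[ax]
    if (s <= 0) next
    n <- dim(a)[ax]
    half <- max(1L, ceiling(3 * s))
    off <- -half:half
    w <- exp(-off^2 / (2 * s^2))
    # banded convolution matrix with renormalized rows at the edges
    K <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- i + off
      ok <- j >= 1 & j <= n
      K[i, j[ok]] <- w[ok] / sum(w[ok])
    }
    perm <- switch(ax, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
    ap <- aperm(a, perm)
    dp <- dim(ap)
    ap <- K %*% matrix(ap, nrow = dp[1])
    dim(ap) <- dp
    a <- aperm(ap, order(perm))
  }
  a
}

# Global Otsu threshold of a numeric array (flattened so 3D stacks yield a
# single threshold, not one per slice).
otsuThreshold <- function(a) {
  rng <- range(a)
  if (diff(rng) == 0) return(rng[1])
  x <- (a - rng[1]) / diff(rng)
  th <- EBImage::otsu(EBImage::Image(as.vector(x), dim = c(length(x), 1L)))
  th * diff(rng) + rng[1]
}

#' Build a boolean mask from registered expression volumes
#'
#' The automated mask path used for presynaptic-terminal masks: overlay the
#' replicate volumes by voxelwise maximum, contrast-stretch to [0, 1],
#' Gaussian-blur (sigma in um), and auto-threshold (Otsu). With
#' \code{mode = "threshold_only"} the blur step is skipped.
#'
#' @param volumes list of aligned \linkS4class{ExpressionVolume}.
#' @param mode \code{"overlay_auto"} (default) or \code{"threshold_only"}.
#' @param blurSigma Gaussian sigma in um (default 1.0).
#' @param regionLabel label for the resulting mask.
#' @return A \linkS4class{VoxelMask}.
#' @export
buildMask <- function(volumes, mode = c("overlay_auto", "threshold_only"),
                      blurSigma = 1.0, regionLabel = "mask") {
  mode <- match.arg(mode)
  if (!length(volumes)) stop("need at least one volume", call. = FALSE)
  for (v in volumes[-1]) checkAligned(volumes[[1]], v)
  overlay <- Reduce(pmax, lapply(volumes, grid))
  if (max(overlay) == 0) stop("empty mask: all-zero overlay", call. = FALSE)
  overlay <- (overlay - min(overlay)) / (max(overlay) - min(overlay))
  if (mode == "overlay_auto")
    overlay <- gaussianBlur3D(overlay, blurSigma, voxelSize(volumes[[1]]))
  th <- otsuThreshold(overlay)
  VoxelMask(overlay > th, voxelSize = voxelSize(volumes[[1]]),
            templateId = volumes[[1]]@templateId, regionLabel = regionLabel)
}

#' Overlap score of one expression volume against target and peduncle masks
#'
#' Counts suprathreshold voxels of the line's signal inside the target
#' (MBON-axon) mask and inside the peduncle mask, and combines them into the
#' final score. The default combination is subtraction
#' (\code{target - peduncle}), which permits the large negative scores seen
#' for lines with strong Kenyon-cell expression; a ratio mode is available.
#'
#' @param volume an \linkS4class{ExpressionVolume}.
#' @param target,peduncle disjoint aligned \linkS4class{VoxelMask}s.
#' @param signalThreshold numeric threshold on the raw signal; \code{NULL}
#'   (default) uses the volume's global Otsu threshold.
#' @param normalization \code{"subtraction"} (default) or \code{"ratio"}
#'   (\code{target / (peduncle + 1)}).
#' @param method \code{"count"} (suprathreshold voxel count, default) or
#'   \code{"intensity"} (sum of suprathreshold intensities).
#' @return One-row data.frame: \code{line_id, target_overlap,
#'   peduncle_overlap, final_score}.
#' @export
overlapScore <- function(volume, target, peduncle, signalThreshold = NULL,
                         normalization = c("subtraction", "ratio"),
                         method = c("count", "intensity")) {
  normalization <- match.arg(normalization)
  method <- match.arg(method)
  checkAligned(volume, target)
  checkAligned(volume, peduncle)
  if (any(grid(target) & grid(peduncle)))
    stop("target and peduncle masks must be disjoint", call. = FALSE)
  g <- grid(volume)
  if (is.null(signalThreshold)) signalThreshold <- otsuThreshold(g)
  supra <- g > signalThreshold
  ov <- function(maskGrid) {
    if (method == "count") sum(supra & maskGrid)
    else sum(g[supra & maskGrid])
  }
  to <- ov(grid(target))
  po <- ov(grid(peduncle))
  score <- switch(normalization,
                  subtraction = to - po,
                  ratio = to / (po + 1))
  data.frame(line_id = volume@lineId, target_overlap = to,
             peduncle_overlap = po, final_score = score,
             stringsAsFactors = FALSE)
}

#' Score a whole library of lines
#'
#' Applies \code{\link{overlapScore}} to each volume. Replicate volumes of
#' the same line (same \code{line_id}) are scored per brain and averaged
#' before ranking.
#'
#' @inheritParams overlapScore
#' @param volumes list of \linkS4class{ExpressionVolume}.
#' @param ... passed to \code{\link{overlapScore}}.
#' @return data.frame of per-line results.
#' @export
screenLibrary <- function(volumes, target, peduncle, ...) {
  rows <- do.call(rbind, lapply(volumes, overlapScore, target = target,
                                peduncle = peduncle, ...))
  agg <- stats::aggregate(
    rows[c("target_overlap", "peduncle_overlap", "final_score")],
    by = list(line_id = rows$line_id), FUN = mean)
  agg[order(agg$line_id), , drop = FALSE]
}

#' Rank screen results and select the top quantile
#'
#' Sorts descending by final score (ties broken lexicographically by line
#' id) and marks lines whose score reaches the empirical selection quantile
#' — the screen kept the top ~100 of ~3,500 lines at the 97th percentile.
#'
#' @param results data.frame with \code{line_id} and \code{final_score}.
#' @param quantile selection quantile in (0, 1), default 0.97.
#' @return The results, sorted, with \code{rank} and \code{selected} added.
#' @export
rankAndSelect <- function(results, quantile = 0.97) {
  if (!nrow(results)) stop("no results to rank", call. = FALSE)
  if (quantile <= 0 || quantile >= 1)
    stop("quantile must be in (0, 1)", call. = FALSE)
  o <- order(-results$final_score, results$line_id)
  results <- results[o, , drop = FALSE]
  results$rank <- seq_len(nrow(results))
  cut <- stats::quantile(results$final_score, probs = quantile, names = FALSE)
  results$selected <- results$final_score >= cut
  rownames(results) <- NULL
  results
}

#' Percent overlap of one mask with another
#'
#' \code{100 * |a intersect b| / |a|}: the share of the query mask \code{a}
#' (e.g. a PD2 axon mask) covered by \code{b} (e.g. DAN dendrites).
#' Asymmetric in its arguments by construction. The candidate flag uses the
#' strict \code{> 15}\% rule used to pick pairs for double-labeling
#' follow-up.
#'
#' @param a query \linkS4class{VoxelMask} (denominator).
#' @param b reference \linkS4class{VoxelMask}.
#' @return Percent overlap (numeric(1)) with attribute \code{candidate}
#'   (\code{TRUE} iff strictly greater than 15).
#' @export
maskPercentOverlap <- function(a, b) {
  checkAligned(a, b)
  na <- sum(grid(a))
  if (na == 0) stop("query mask is empty", call. = FALSE)
  pct <- 100 * sum(grid(a) & grid(b)) / na
  structure(pct, candidate = pct > 15)
}
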