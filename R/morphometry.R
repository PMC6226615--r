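#' @include AllClasses.R constructors.R utils.R
NULL

# Decompose the (possibly compartment-restricted) skeleton into unbranched
# chains: maximal paths whose interior nodes have exactly one retained
# child and a retained parent.
skeletonChains <- function(nodes, keep) {
  idx <- which(keep)
  pidx <- match(nodes$parent_id, nodes$node_id)
  edgeKept <- keep & !is.na(pidx)
  edgeKept[edgeKept] <- keep[pidx[edgeKept]]
  kids <- split(which(edgeKept), pidx[edgeKept])
  nKids <- integer(nrow(nodes))
  nKids[as.integer(names(kids))] <- lengths(kids)
  # chain heads: retained nodes whose upstream edge is absent or whose
  # parent is a branch point; a kept upstream edge pulls the parent in so
  # the cable across branch points is not lost (duplicates deduped later)
  heads <- idx[vapply(idx, function(i)
    !edgeKept[i] || nKids[pidx[i]] > 1L, logical(1))]
  lapply(heads, function(h) {
    chain <- if (edgeKept[h]) c(pidx[h], h) else h
    cur <- h
    while (nKids[cur] == 1L) {
      cur <- kids[[as.character(cur)]]
      chain <- c(chain, cur)
    }
    chain
  })
}

resampleChain <- function(xyz, step) {
  if (nrow(xyz) < 2L) return(xyz)
  seg <- sqrt(rowSums(diff(xyz)^2))
  cum <- c(0, cumsum(seg))
  L <- cum[length(cum)]
  if (L == 0) return(xyz[1, , drop = FALSE])
  at <- seq(0, L, by = step)
  if (at[length(at)] < L) at <- c(at, L)
  t(vapply(at, function(d) {
    j <- findInterval(d, cum, rightmost.closed = TRUE)
    j <- min(j, length(seg))
    f <- if (seg[j] > 0) (d - cum[j]) / seg[j] else 0
    xyz[j, ] + f * (xyz[j + 1, ] - xyz[j, ])
  }, numeric(3)))
}

#' Convert a skeleton to dotprops
#'
#' Resamples the selected compartments to a uniform step and attaches to
#' each point the dominant direction (first principal component) of its k
#' nearest points. When restricting to \code{axon} and/or \code{dendrite},
#' primary neurite and primary dendrite nodes are stripped first — their
#' tight fasciculation otherwise dominates similarity scores.
#'
#' @param skeleton a \linkS4class{NeuronSkeleton}.
#' @param compartments compartment labels to keep (default: all).
#' @param resampleStep um between resampled points (default 1).
#' @param k neighbor count for the tangent estimate (default 5).
#' @return A \linkS4class{Dotprops}.
#' @export
toDotprops <- function(skeleton, compartments = NULL, resampleStep = 1,
                       k = 5) {
  nd <- skeleton@nodes
  keep <- rep(TRUE, nrow(nd))
  if (!is.null(compartments)) {
    bad <- setdiff(compartments, COMPARTMENT_LEVELS)
    if (length(bad))
      stop("unknown compartment label(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    keep <- skeleton@compartment %in% compartments
    if (!any(keep))
      stop("neuron '", skeleton@neuronId, "' has no nodes labelled ",
           paste(compartments, collapse = "/"), call. = FALSE)
  }
  chains <- skeletonChains(nd, keep)
  xyz <- as.matrix(nd[c("x", "y", "z")])
  pts <- do.call(rbind, lapply(chains, function(ch)
    resampleChain(xyz[ch, , drop = FALSE], resampleStep)))
  pts <- unique(pts)
  if (is.null(pts) || nrow(pts) < 2L)
    stop("fewer than 2 points after restriction/resampling", call. = FALSE)
  kk <- min(k, nrow(pts))
  nn <- RANN::nn2(pts, pts, k = kk)
  vects <- t(vapply(seq_len(nrow(pts)), function(i) {
    nb <- pts[nn$nn.idx[i, ], , drop = FALSE]
    cv <- stats::cov(nb)
    ev <- eigen(cv, symmetric = TRUE)
    v <- ev$vectors[, 1]
    v / sqrt(sum(v^2))
  }, numeric(3)))
  new("Dotprops", points = pts, vects = vects, neuronId = skeleton@neuronId,
      resampleStep = resampleStep)
}

#' Raw NBLAST score of a query against a target
#'
#' For every query point, finds the nearest target point and accumulates
#' \code{f(d, adp)} where d is the Euclidean distance and adp the absolute
#' dot product of the two unit tangents. The default scoring function is
#' the parametric exponential form \code{exp(-d / sigma) * adp} with
#' \code{sigma = 3} um; alternatively a binned log-odds scoring table (see
#' \code{\link{readScoringMatrix}}) is applied by (d, adp) bin lookup.
#'
#' @param query,target \linkS4class{Dotprops}.
#' @param scoring \code{NULL} for the parametric form, or a scoring table
#'   from \code{\link{readScoringMatrix}}.
#' @param sigma distance constant in um for the parametric form.
#' @return Raw score (numeric(1)). A self-comparison scores exactly the
#'   number of points under the parametric form (d = 0, adp = 1).
#' @export
nblastRaw <- function(query, target, scoring = NULL, sigma = 3) {
  nn <- RANN::nn2(target@points, query@points, k = 1)
  d <- nn$nn.dists[, 1]
  adp <- abs(rowSums(query@vects * target@vects[nn$nn.idx[, 1], ,
                                                drop = FALSE]))
  if (is.null(scoring)) {
    sum(exp(-d / sigma) * adp)
  } else {
    di <- pmin(pmax(findInterval(d, scoring$distBreaks,
                                 rightmost.closed = TRUE), 1L),
               length(scoring$distBreaks) - 1L)
    ai <- pmin(pmax(findInterval(adp, scoring$adpBreaks,
                                 rightmost.closed = TRUE), 1L),
               length(scoring$adpBreaks) - 1L)
    sum(scoring$logOdds[cbind(di, ai)])
  }
}

#' Read a binned log-odds NBLAST scoring matrix
#'
#' CSV schema: columns \code{dist_lo, dist_hi, adp_lo, adp_hi, log_odds},
#' one row per (distance bin, dot-product bin) cell; bins must tile a
#' regular grid.
#'
#' @param path CSV file.
#' @return A list with \code{distBreaks}, \code{adpBreaks}, \code{logOdds}
#'   usable as the \code{scoring} argument of \code{\link{nblastRaw}}.
#' @export
readScoringMatrix <- function(path) {
  df <- utils::read.csv(path)
  distBreaks <- sort(unique(c(df$dist_lo, df$dist_hi)))
  adpBreaks <- sort(unique(c(df$adp_lo, df$adp_hi)))
  lo <- matrix(NA_real_, length(distBreaks) - 1L, length(adpBreaks) - 1L)
  di <- match(df$dist_lo, distBreaks[-length(distBreaks)])
  ai <- match(df$adp_lo, adpBreaks[-length(adpBreaks)])
  lo[cbind(di, ai)] <- df$log_odds
  if (anyNA(lo)) stop("scoring matrix does not tile the bin grid",
                      call. = FALSE)
  list(distBreaks = distBreaks, adpBreaks = adpBreaks, logOdds = lo)
}

#' All-pairs NBLAST score matrix
#'
#' Computes raw scores for every ordered pair, normalized scores (raw
#' divided by the query's self-score, so the diagonal is exactly 1), and
#' the symmetric mean of the two directed normalized scores.
#'
#' @param dotprops list of \linkS4class{Dotprops}.
#' @param ... passed to \code{\link{nblastRaw}}.
#' @return A \linkS4class{ScoreMatrix}.
#' @export
scoreMatrix <- function(dotprops, ...) {
  ids <- vapply(dotprops, neuronId, character(1))
  n <- length(dotprops)
  raw <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) for (j in seq_len(n))
    raw[i, j] <- nblastRaw(dotprops[[i]], dotprops[[j]], ...)
  norm <- raw / diag(raw)
  diag(norm) <- 1
  new("ScoreMatrix", ids = ids, raw = raw, normalized = norm,
      mean = (norm + t(norm)) / 2)
}

#' Cluster neurons into putative cell types
#'
#' Hierarchical agglomeration with Ward's criterion on Euclidean distances
#' between the rows of the (by default mean-normalized) score matrix, then
#' a flat cut at \code{k} groups or height \code{h}.
#'
#' @param sm a \linkS4class{ScoreMatrix}.
#' @param k number of groups, or \code{NULL}.
#' @param h cut height, used when \code{k} is \code{NULL}.
#' @param use \code{"mean"} (default) or \code{"normalized"} scores.
#' @return Named integer vector of cluster labels, with the
#'   \code{\link[stats]{hclust}} tree as attribute \code{"tree"}.
#' @export
clusterTypes <- function(sm, k = NULL, h = NULL,
                         use = c("mean", "normalized")) {
  use <- match.arg(use)
  m <- slot(sm, use)
  if (length(sm@ids) < 2L) stop("need at least 2 neurons", call. = FALSE)
  if (!is.null(k) && k > length(sm@ids))
    stop("k exceeds the number of neurons", call. = FALSE)
  hc <- stats::hclust(stats::dist(m), method = "ward.D2")
  labels <- if (!is.null(k)) stats::cutree(hc, k = k)
            else stats::cutree(hc, h = h)
  names(labels) <- sm@ids
  structure(labels, tree = hc)
}
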