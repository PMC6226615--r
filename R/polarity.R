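#' @include AllClasses.R constructors.R utils.R
NULL

# per-node synapse counts for one neuron, honoring the counting mode:
# connector_once counts each presynaptic connector once at its pre node;
# per_link weights it by the number of outgoing (post) links it makes.
synapseCountsAtNodes <- function(skeleton, table, countingMode) {
  lk <- table@links
  mine <- lk[lk$neuron_id == skeleton@neuronId, , drop = FALSE]
  nid <- skeleton@nodes$node_id
  pre <- numeric(length(nid)); post <- numeric(length(nid))
  prel <- mine[mine$role == "pre", , drop = FALSE]
  if (nrow(prel)) {
    w <- if (countingMode == "connector_once") rep(1, nrow(prel)) else {
      fan <- table(lk$connector_id[lk$role == "post"])
      as.numeric(fan[as.character(prel$connector_id)])
    }
    agg <- tapply(w, factor(prel$node_id, levels = nid), sum, default = 0)
    pre <- as.numeric(agg)
  }
  postl <- mine[mine$role == "post", , drop = FALSE]
  if (nrow(postl))
    post <- as.numeric(table(factor(postl$node_id, levels = nid)))
  list(pre = pre, post = post)
}

#' Axon--dendrite split by centrifugal synapse flow centrality
#'
#' For each node v with distal subtree T(v) (the side away from the root),
#' the centrifugal synapse flow centrality is
#' \code{SFC(v) = (total_post - post_in(T(v))) * pre_in(T(v))} — the number
#' of (postsynapse, presynapse) pairs whose tree path crosses v with the
#' postsynapse on the root side. The split is placed at the SFC maximum
#' (ties resolved to the most root-proximal node, then the lowest node id).
#' The side of the split holding more than half of the presynapses becomes
#' the axon. Remaining nodes are labelled dendrite, with the unsynapsed
#' proximal stretch of the root path as primary neurite (plus the root as
#' soma) and the unsynapsed stretch linking the two arbors as primary
#' dendrite.
#'
#' @param skeleton a \linkS4class{NeuronSkeleton}.
#' @param table a \linkS4class{ConnectorTable} with this neuron's synapses.
#' @param countingMode \code{"connector_once"} (default; polyadic
#'   presynapses counted once) or \code{"per_link"} (each outgoing
#'   connection counted).
#' @return A \linkS4class{CompartmentSplit}.
#' @export
flowCentrality <- function(skeleton,
                           table,
                           countingMode = c("connector_once", "per_link")) {
  countingMode <- match.arg(countingMode)
  nd <- skeleton@nodes
  n <- nrow(nd)
  cnt <- synapseCountsAtNodes(skeleton, table, countingMode)
  if (sum(cnt$pre) == 0 || sum(cnt$post) == 0)
    stop("unsplittable: neuron '", skeleton@neuronId,
         "' needs at least one presynapse and one postsynapse",
         call. = FALSE)
  ord <- topoOrder(nd)
  pidx <- match(nd$parent_id, nd$node_id)
  preSub <- cnt$pre; postSub <- cnt$post
  for (i in rev(ord)) {              # accumulate subtree sums toward root
    p <- pidx[i]
    if (!is.na(p)) {
      preSub[p] <- preSub[p] + preSub[i]
      postSub[p] <- postSub[p] + postSub[i]
    }
  }
  totPost <- sum(cnt$post)
  sfc <- (totPost - postSub) * preSub
  names(sfc) <- nd$node_id
  depth <- integer(n); depth[ord[1]] <- 0L
  for (i in ord[-1]) depth[i] <- depth[pidx[i]] + 1L
  best <- which(sfc == max(sfc))
  best <- best[order(depth[best], nd$node_id[best])][1]
  # distal side of the split = axon iff it holds > 50% of presynapses
  distalPre <- preSub[best]
  swapped <- !(distalPre > sum(cnt$pre) / 2)
  inSub <- logical(n); inSub[best] <- TRUE
  for (i in ord) if (!is.na(pidx[i]) && inSub[pidx[i]]) inSub[i] <- TRUE
  comp <- rep(if (swapped) "dendrite" else "axon", n)
  comp[!inSub] <- if (swapped) "axon" else "dendrite"
  # root path refinement: soma, primary neurite, primary dendrite
  hasSyn <- cnt$pre + cnt$post > 0
  synSub <- hasSyn
  for (i in rev(ord)) {
    p <- pidx[i]
    if (!is.na(p)) synSub[p] <- synSub[p] | synSub[i]
  }
  path <- integer(0); v <- best
  while (!is.na(v)) { path <- c(v, path); v <- pidx[v] }  # root ... split
  if (length(path) > 1) {
    onPath <- logical(n); onPath[path] <- TRUE
    # does node p (on path) carry a synapse or an off-path synapse-bearing
    # side branch?
    bears <- vapply(path, function(p) {
      if (hasSyn[p]) return(TRUE)
      kids <- which(!is.na(pidx) & pidx == p)
      any(!onPath[kids] & synSub[kids])
    }, logical(1))
    bears[length(path)] <- TRUE       # the split node ends the path
    proxEnd <- which(bears)[1] - 1L   # nodes strictly before first synapse
    if (is.na(proxEnd)) proxEnd <- 0L
    if (proxEnd >= 1L)
      comp[path[seq_len(proxEnd)]] <- "primary_neurite"
    interior <- setdiff(which(bears), length(path))
    if (length(interior)) {
      distStart <- max(interior) + 1L  # after last synapse-bearing point
      if (distStart <= length(path) - 1L)
        comp[path[distStart:(length(path) - 1L)]] <- "primary_dendrite"
    }
  }
  comp[ord[1]] <- "soma"
  names(comp) <- nd$node_id
  split <- new("CompartmentSplit", neuronId = skeleton@neuronId, sfc = sfc,
               splitNodeId = nd$node_id[best], compartment = comp,
               preByCompartment = numeric(0), postByCompartment = numeric(0),
               segregationIndex = NA_real_, countingMode = countingMode)
  split@preByCompartment <- compartmentSynapseTotals(cnt$pre, comp, nd, pidx)
  split@postByCompartment <- compartmentSynapseTotals(cnt$post, comp, nd,
                                                      pidx)
  split@segregationIndex <- segregationIndex(split)
  split
}

# Total synapse weight per {axon, dendrite}; weight sitting on soma /
# primary neurite / primary dendrite nodes is assigned to the nearer arbor
# by path distance (unweighted hops along the tree).
compartmentSynapseTotals <- function(w, comp, nd, pidx) {
  out <- c(axon = 0, dendrite = 0)
  carry <- which(w > 0)
  if (!length(carry)) return(out)
  direct <- comp[carry] %in% c("axon", "dendrite")
  for (i in carry[direct]) out[comp[i]] <- out[comp[i]] + w[i]
  stray <- carry[!direct]
  if (length(stray)) {
    adj <- lapply(seq_along(pidx), function(i) integer(0))
    for (i in seq_along(pidx)) if (!is.na(pidx[i])) {
      adj[[i]] <- c(adj[[i]], pidx[i])
      adj[[pidx[i]]] <- c(adj[[pidx[i]]], i)
    }
    bfsDist <- function(sources) {
      d <- rep(Inf, length(pidx)); d[sources] <- 0
      frontier <- sources
      while (length(frontier)) {
        nxt <- unique(unlist(adj[frontier]))
        nxt <- nxt[d[nxt] == Inf]
        d[nxt] <- d[frontier[1]] + 1  # level-synchronous, uniform hops
        frontier <- nxt
      }
      d
    }
    dA <- bfsDist(which(comp == "axon"))
    dD <- bfsDist(which(comp == "dendrite"))
    for (i in stray) {
      side <- if (dA[i] < dD[i]) "axon" else "dendrite"
      out[side] <- out[side] + w[i]
    }
  }
  out
}

#' Entropy-based axon--dendrite segregation index
#'
#' For compartment i holding \code{N_i} synapses of which a fraction
#' \code{p_i} are presynaptic, the compartment entropy is
#' \code{S_i = -(p_i ln p_i + (1 - p_i) ln(1 - p_i))} (with 0 ln 0 := 0);
#' the observed entropy is the synapse-weighted mean
#' \code{S = sum_i (N_i / N) S_i}, the reference entropy \code{S_hat} is
#' evaluated at the whole-cell presynaptic fraction, and
#' \code{SI = 1 - S / S_hat} — 0 for totally unsegregated neurons, 1 for
#' complete polarization. If \code{S_hat = 0} (all synapses of one role)
#' the index is defined as 0.
#'
#' @param split a \linkS4class{CompartmentSplit} (from
#'   \code{\link{flowCentrality}}).
#' @return SI in [0, 1].
#' @export
segregationIndex <- function(split) {
  pre <- split@preByCompartment
  post <- split@postByCompartment
  N <- pre + post
  if (any(N == 0))
    stop("both compartments must contain synapses", call. = FALSE)
  if (sum(N) < 2) stop("need at least two synapses", call. = FALSE)
  ent <- function(p) {
    terms <- c(p, 1 - p)
    -sum(ifelse(terms > 0, terms * log(terms), 0))
  }
  S <- sum((N / sum(N)) * vapply(pre / N, ent, numeric(1)))
  Shat <- ent(sum(pre) / sum(N))
  if (Shat == 0) return(0)
  max(0, min(1, 1 - S / Shat))
}
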