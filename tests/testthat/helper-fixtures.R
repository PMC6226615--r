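# Shared fixtures and independent oracles for the test suite. Oracles are
# deliberately written as direct, naive computations so they stay
# independent of the package's implementation paths.

# ---- tiny hand-built skeletons -----------------------------------------

chainSkeleton <- function(n = 3, step = 10, id = "chain") {
  NeuronSkeleton(data.frame(node_id = seq_len(n),
                            parent_id = c(NA, seq_len(n - 1)),
                            x = (seq_len(n) - 1) * step, y = 0, z = 0,
                            radius = 1),
                 neuronId = id)
}

# root (1) with two child chains: A = nodes 2..(1+nA), B = nodes after
twoArborSkeleton <- function(nA = 3, nB = 3, id = "twoarbor") {
  idsA <- 1 + seq_len(nA)
  idsB <- 1 + nA + seq_len(nB)
  nodes <- data.frame(
    node_id = c(1L, idsA, idsB),
    parent_id = c(NA, 1L, idsA[-nA], 1L, idsB[-nB]),
    x = c(0, seq_len(nA) * 5, -seq_len(nB) * 5),
    y = 0, z = 0, radius = 1)
  NeuronSkeleton(nodes, neuronId = id)
}

# a connector table giving `neuron` pre/post links at the stated node ids
synapsesAt <- function(neuron, preNodes = integer(), postNodes = integer(),
                       fanout = 1L, neuropil = "LH",
                       partner = "partner") {
  rows <- list(); conns <- list(); cid <- 0L
  for (nd in preNodes) {
    cid <- cid + 1L
    conns[[cid]] <- data.frame(connector_id = cid, x = 0, y = 0, z = 0,
                               neuropil = neuropil)
    rows[[length(rows) + 1L]] <- data.frame(
      connector_id = cid, neuron_id = neuron, node_id = nd, role = "pre")
    rows[[length(rows) + 1L]] <- data.frame(
      connector_id = rep(cid, fanout), neuron_id = partner,
      node_id = seq_len(fanout), role = "post")
  }
  for (nd in postNodes) {
    cid <- cid + 1L
    conns[[cid]] <- data.frame(connector_id = cid, x = 0, y = 0, z = 0,
                               neuropil = neuropil)
    rows[[length(rows) + 1L]] <- data.frame(
      connector_id = cid, neuron_id = partner, node_id = 1L, role = "pre")
    rows[[length(rows) + 1L]] <- data.frame(
      connector_id = cid, neuron_id = neuron, node_id = nd, role = "post")
  }
  ConnectorTable(do.call(rbind, conns), do.call(rbind, rows))
}

# random valid rooted tree with n nodes (node ids shuffled, not 1..n order)
randomTreeSkeleton <- function(n, seed, id = paste0("rt", seed)) {
  set.seed(seed)
  parent <- c(NA, vapply(2:n, function(i) sample(i - 1L, 1L), integer(1)))
  ids <- sample(n) + 100L
  NeuronSkeleton(data.frame(node_id = ids,
                            parent_id = c(NA, ids[parent[-1]]),
                            x = rnorm(n, sd = 20), y = rnorm(n, sd = 20),
                            z = rnorm(n, sd = 20), radius = 1),
                 neuronId = id)
}

# random synapse table for one neuron over its node ids
randomSynapses <- function(skeleton, nPre, nPost, seed) {
  set.seed(seed)
  ids <- skeletonNodes(skeleton)$node_id
  synapsesAt(neuronId(skeleton),
             preNodes = sample(ids, nPre, replace = TRUE),
             postNodes = sample(ids, nPost, replace = TRUE))
}

# ---- independent oracles ------------------------------------------------

# Brute-force centrifugal SFC: enumerate (post link, pre connector) pairs
# and count, for each node v, pairs whose tree path crosses v with the
# post on the root side, i.e. pre node in subtree(v), post node outside.
# Subtree membership derived via ancestor chains walked node by node.
bruteForceSFC <- function(skeleton, table, perLink = FALSE) {
  nd <- skeletonNodes(skeleton)
  lk <- connectorLinks(table)
  mine <- lk[lk$neuron_id == neuronId(skeleton), ]
  ancestors <- function(node) {
    out <- integer(0)
    while (!is.na(node)) {
      out <- c(out, node)
      node <- nd$parent_id[match(node, nd$node_id)]
    }
    out
  }
  preRows <- mine[mine$role == "pre", ]
  if (perLink) {
    fan <- table(lk$connector_id[lk$role == "post"])
    preNodes <- rep(preRows$node_id,
                    as.integer(fan[as.character(preRows$connector_id)]))
  } else preNodes <- preRows$node_id
  postNodes <- mine$node_id[mine$role == "post"]
  anc <- lapply(stats::setNames(nm = nd$node_id), function(v) ancestors(v))
  sfc <- stats::setNames(numeric(nrow(nd)), nd$node_id)
  for (v in nd$node_id) {
    preIn <- sum(vapply(preNodes, function(p)
      v %in% anc[[as.character(p)]], logical(1)))
    postOut <- sum(vapply(postNodes, function(p)
      !(v %in% anc[[as.character(p)]]), logical(1)))
    sfc[as.character(v)] <- postOut * preIn
  }
  sfc
}

# O(n^2) all-pairs nearest-neighbor NBLAST loop
bruteForceNblast <- function(query, target, sigma = 3) {
  qp <- query@points; qv <- query@vects
  tp <- target@points; tv <- target@vects
  total <- 0
  for (i in seq_len(nrow(qp))) {
    d2 <- colSums((t(tp) - qp[i, ])^2)
    j <- which.min(d2)
    total <- total + exp(-sqrt(d2[j]) / sigma) * abs(sum(qv[i, ] * tv[j, ]))
  }
  total
}

# Brute-force Ward agglomeration on row vectors: at each step merge the
# pair of clusters whose union minimizes the increase in total
# within-cluster sum of squares. Returns the sequence of merged member
# sets (as sorted id vectors).
bruteForceWardMerges <- function(rows) {
  clusters <- lapply(seq_len(nrow(rows)), identity)
  merges <- list()
  ess <- function(members) {
    m <- rows[members, , drop = FALSE]
    sum(sweep(m, 2, colMeans(m))^2)
  }
  while (length(clusters) > 1) {
    best <- NULL; bestCost <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      cost <- ess(c(clusters[[i]], clusters[[j]])) -
        ess(clusters[[i]]) - ess(clusters[[j]])
      if (cost < bestCost - 1e-12) { bestCost <- cost; best <- c(i, j) }
    }
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    merges[[length(merges) + 1L]] <- merged
    clusters <- c(clusters[-best], list(merged))
  }
  merges
}

# hclust merge matrix -> sequence of merged member sets
hclustMergeSets <- function(hc) {
  sets <- list()
  out <- list()
  for (s in seq_len(nrow(hc$merge))) {
    members <- unlist(lapply(hc$merge[s, ], function(m)
      if (m < 0) -m else sets[[m]]))
    sets[[s]] <- members
    out[[s]] <- sort(members)
  }
  out
}

adjustedRand <- function(a, b) mclust::adjustedRandIndex(a, b)
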