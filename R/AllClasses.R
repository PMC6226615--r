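#' @import methods
NULL

COMPARTMENT_LEVELS <- c("soma", "primary_neurite", "dendrite",
                        "primary_dendrite", "axon", "unassigned")

#' Registered 3D expression volume
#'
#' Holds the registered fluorescence signal of one driver line as a 3D scalar
#' grid in a common template space, together with the (possibly anisotropic)
#' voxel size in micrometres.
#'
#' @slot grid 3D numeric array, non-negative.
#' @slot voxelSize numeric(3), voxel edge lengths in um (x, y, z).
#' @slot templateId character(1), identifier of the template brain.
#' @slot lineId character(1), identifier of the driver line.
#' @export
setClass("ExpressionVolume",
  representation(grid = "array", voxelSize = "numeric",
                 templateId = "character", lineId = "character"))

setValidity("ExpressionVolume", function(object) {
  msg <- character()
  if (length(dim(object@grid)) != 3L)
    msg <- c(msg, "grid must be a 3D array")
  if (any(dim(object@grid) < 1L))
    msg <- c(msg, "all grid dimensions must be >= 1")
  if (length(object@voxelSize) != 3L || any(!is.finite(object@voxelSize)) ||
      any(object@voxelSize <= 0))
    msg <- c(msg, "voxelSize must be 3 positive reals (um)")
  if (any(object@grid < 0, na.rm = TRUE))
    msg <- c(msg, "grid values must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Boolean region mask aligned to a template space
#'
#' @slot grid 3D logical array.
#' @slot voxelSize numeric(3), um.
#' @slot templateId character(1).
#' @slot regionLabel character(1), e.g. \code{"LH-axon-mask"} or
#'   \code{"peduncle"}.
#' @export
setClass("VoxelMask",
  representation(grid = "array", voxelSize = "numeric",
                 templateId = "character", regionLabel = "character"))

setValidity("VoxelMask", function(object) {
  msg <- character()
  if (length(dim(object@grid)) != 3L)
    msg <- c(msg, "grid must be a 3D array")
  if (!is.logical(object@grid))
    msg <- c(msg, "mask grid must be logical")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    msg <- c(msg, "voxelSize must be 3 positive reals (um)")
  if (length(msg)) msg else TRUE
})

#' Rooted-tree neuron skeleton
#'
#' A neuronal morphology as a rooted tree of sample points, CATMAID/SWC
#' style. Exactly one node is the root (parent \code{NA}); every other node
#' points at an existing parent and the edge set forms a tree. Each node
#' carries a compartment label (soma, primary_neurite, dendrite,
#' primary_dendrite, axon, unassigned) and a microtubule flag (whether
#' microtubules are still apparent at that point; the vast majority of
#' postsynapses in this system sit on microtubule-free twigs).
#'
#' @slot nodes data.frame with columns \code{node_id} (integer),
#'   \code{parent_id} (integer, \code{NA} for the root), \code{x,y,z} (um),
#'   \code{radius} (um, >= 0).
#' @slot compartment character vector parallel to \code{nodes}.
#' @slot microtubule logical vector parallel to \code{nodes}.
#' @slot neuronId character(1).
#' @export
setClass("NeuronSkeleton",
  representation(nodes = "data.frame", compartment = "character",
                 microtubule = "logical", neuronId = "character"))

validateSkeletonNodes <- function(nodes) {
  msg <- character()
  need <- c("node_id", "parent_id", "x", "y", "z", "radius")
  if (!all(need %in% names(nodes)))
    return(paste("nodes must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(nodes$node_id))
    msg <- c(msg, "duplicate node ids")
  roots <- which(is.na(nodes$parent_id))
  if (length(roots) != 1L)
    msg <- c(msg, sprintf("exactly one root required, found %d (%s)",
                          length(roots),
                          paste(nodes$node_id[roots], collapse = ",")))
  dangling <- !is.na(nodes$parent_id) &
    !(nodes$parent_id %in% nodes$node_id)
  if (any(dangling))
    msg <- c(msg, sprintf("dangling parent ids for nodes: %s",
                          paste(nodes$node_id[dangling], collapse = ",")))
  if (any(nodes$radius < 0, na.rm = TRUE))
    msg <- c(msg, "negative radius")
  if (!length(msg)) {
    # n_edges == n_nodes - 1 holds by construction (one parent per non-root
    # node); still need acyclicity/connectivity: every node must reach root.
    idx <- match(nodes$parent_id, nodes$node_id)
    n <- nrow(nodes)
    reached <- logical(n)
    reached[is.na(nodes$parent_id)] <- TRUE
    for (pass in seq_len(n)) {
      newly <- !reached & reached[idx]
      newly[is.na(newly)] <- FALSE
      if (!any(newly)) break
      reached[newly] <- TRUE
    }
    if (!all(reached))
      msg <- c(msg, sprintf("cycle or disconnected component at nodes: %s",
                            paste(nodes$node_id[!reached], collapse = ",")))
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
}

setValidity("NeuronSkeleton", function(object) {
  msg <- character()
  v <- validateSkeletonNodes(object@nodes)
  if (!isTRUE(v)) msg <- c(msg, v)
  n <- nrow(object@nodes)
  if (length(object@compartment) != n || length(object@microtubule) != n)
    msg <- c(msg, "compartment/microtubule must be parallel to nodes")
  bad <- setdiff(unique(object@compartment), COMPARTMENT_LEVELS)
  if (length(bad))
    msg <- c(msg, paste("unknown compartment label(s):",
                        paste(bad, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Polyadic synapse (connector) table
#'
#' CATMAID-convention synapses: each connector is one presynaptic T-bar with
#' exactly one pre link and one or more post links (polyadic).
#'
#' @slot connectors data.frame: \code{connector_id, x, y, z, neuropil}.
#' @slot links data.frame: \code{connector_id, neuron_id, node_id, role}
#'   with role in \code{c("pre", "post")}.
#' @export
setClass("ConnectorTable",
  representation(connectors = "data.frame", links = "data.frame"))

setValidity("ConnectorTable", function(object) {
  msg <- character()
  cn <- c("connector_id", "x", "y", "z", "neuropil")
  ln <- c("connector_id", "neuron_id", "node_id", "role")
  if (!all(cn %in% names(object@connectors)))
    msg <- c(msg, paste("connectors needs columns:", paste(cn, collapse = ", ")))
  if (!all(ln %in% names(object@links)))
    msg <- c(msg, paste("links needs columns:", paste(ln, collapse = ", ")))
  if (!length(msg)) {
    if (anyDuplicated(object@connectors$connector_id))
      msg <- c(msg, "duplicate connector ids")
    if (!all(object@links$role %in% c("pre", "post")))
      msg <- c(msg, "link role must be 'pre' or 'post'")
    if (!all(object@links$connector_id %in% object@connectors$connector_id))
      msg <- c(msg, "link refers to unknown connector")
    npre <- table(factor(object@links$connector_id[object@links$role == "pre"],
                         levels = object@connectors$connector_id))
    npost <- table(factor(object@links$connector_id[object@links$role == "post"],
                          levels = object@connectors$connector_id))
    bad <- names(npre)[npre != 1L]
    if (length(bad))
      msg <- c(msg, sprintf("connector(s) without exactly one pre link: %s",
                            paste(utils::head(bad, 5L), collapse = ",")))
    bad <- names(npost)[npost < 1L]
    if (length(bad))
      msg <- c(msg, sprintf("connector(s) without post links: %s",
                            paste(utils::head(bad, 5L), collapse = ",")))
  }
  if (length(msg)) msg else TRUE
})

#' Point cloud with unit tangents (dotprops)
#'
#' The substrate of NBLAST scoring: the skeleton resampled to roughly uniform
#' spacing, each point carrying the dominant local direction of its
#' k-neighborhood as a unit vector.
#'
#' @slot points n x 3 numeric matrix (um).
#' @slot vects n x 3 numeric matrix of unit tangents.
#' @slot neuronId character(1).
#' @slot resampleStep numeric(1), um.
#' @export
setClass("Dotprops",
  representation(points = "matrix", vects = "matrix",
                 neuronId = "character", resampleStep = "numeric"))

setValidity("Dotprops", function(object) {
  msg <- character()
  if (ncol(object@points) != 3L || ncol(object@vects) != 3L)
    msg <- c(msg, "points and vects must have 3 columns")
  if (nrow(object@points) < 2L)
    msg <- c(msg, "dotprops needs >= 2 points")
  if (nrow(object@points) != nrow(object@vects))
    msg <- c(msg, "points/vects row mismatch")
  else {
    nrm <- sqrt(rowSums(object@vects^2))
    if (any(abs(nrm - 1) > 1e-6))
      msg <- c(msg, "tangents must be unit vectors (|t| = 1 +- 1e-6)")
  }
  if (length(msg)) msg else TRUE
})

#' Pairwise morphology-similarity score matrix
#'
#' @slot ids character vector of neuron ids (rows = queries, cols = targets).
#' @slot raw raw NBLAST scores.
#' @slot normalized raw scores divided by the query's self-score (diagonal 1).
#' @slot mean arithmetic mean of the two directed normalized scores
#'   (symmetric).
#' @export
setClass("ScoreMatrix",
  representation(ids = "character", raw = "matrix",
                 normalized = "matrix", mean = "matrix"))

setValidity("ScoreMatrix", function(object) {
  n <- length(object@ids)
  for (s in c("raw", "normalized", "mean"))
    if (!all(dim(slot(object, s)) == c(n, n)))
      return(sprintf("%s matrix must be %d x %d", s, n, n))
  if (any(abs(diag(object@normalized) - 1) > 1e-12))
    return("normalized self-scores must equal 1")
  if (max(abs(object@mean - t(object@mean))) > 1e-12)
    return("mean matrix must be symmetric")
  TRUE
})

#' Axon--dendrite split of a skeleton
#'
#' Result of the centrifugal synapse-flow-centrality split: per-node SFC
#' values, the chosen split node, per-node compartment labels, synapse counts
#' per compartment, and the entropy-based segregation index.
#'
#' @slot neuronId character(1).
#' @slot sfc named integer-valued numeric, per-node centrifugal SFC.
#' @slot splitNodeId integer(1).
#' @slot compartment named character, per-node labels.
#' @slot preByCompartment,postByCompartment named numeric; synapse counts for
#'   the axon and dendrite compartments used by the segregation index.
#' @slot segregationIndex numeric(1) in [0, 1].
#' @slot countingMode \code{"connector_once"} or \code{"per_link"}.
#' @export
setClass("CompartmentSplit",
  representation(neuronId = "character", sfc = "numeric",
                 splitNodeId = "integer", compartment = "character",
                 preByCompartment = "numeric", postByCompartment = "numeric",
                 segregationIndex = "numeric", countingMode = "character"))

setValidity("CompartmentSplit", function(object) {
  msg <- character()
  if (!object@countingMode %in% c("connector_once", "per_link"))
    msg <- c(msg, "countingMode must be connector_once or per_link")
  si <- object@segregationIndex
  if (length(si) == 1L && is.finite(si) && (si < -1e-9 || si > 1 + 1e-9))
    msg <- c(msg, "segregation index must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Calcium fluorescence time series
#'
#' @slot values numeric fluorescence trace (raw F).
#' @slot samplePeriod numeric(1), s (e.g. 0.128 or 0.640).
#' @slot stimulusOnset numeric(1), s from trace start.
#' @slot stimulusDuration numeric(1), s.
#' @slot condition character(1), e.g. \code{"permissive"}/\code{"restrictive"}
#'   or \code{"paired"}/\code{"unpaired"}.
#' @slot roiId character(1).
#' @slot trueAmplitude numeric(1); ground-truth response amplitude for
#'   synthetic traces (\code{NA} for real data).
#' @export
setClass("CalciumTrace",
  representation(values = "numeric", samplePeriod = "numeric",
                 stimulusOnset = "numeric", stimulusDuration = "numeric",
                 condition = "character", roiId = "character",
                 trueAmplitude = "numeric"))

setValidity("CalciumTrace", function(object) {
  msg <- character()
  if (any(!is.finite(object@values)))
    msg <- c(msg, "trace values must be finite")
  if (object@samplePeriod <= 0)
    msg <- c(msg, "sample period must be positive")
  span <- length(object@values) * object@samplePeriod
  if (object@stimulusOnset < 0 || object@stimulusOnset > span)
    msg <- c(msg, "stimulus onset must lie within the trace span")
  if (length(msg)) msg else TRUE
})
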