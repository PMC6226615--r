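#' @include AllClasses.R
NULL

#' Construct an ExpressionVolume
#'
#' @param grid 3D non-negative numeric array.
#' @param voxelSize numeric(3), um.
#' @param templateId,lineId identifiers.
#' @return An \linkS4class{ExpressionVolume}.
#' @export
ExpressionVolume <- function(grid, voxelSize = c(1, 1, 1),
                             templateId = "template", lineId = "line") {
  new("ExpressionVolume", grid = grid, voxelSize = as.numeric(voxelSize),
      templateId = templateId, lineId = lineId)
}

#' Construct a VoxelMask
#'
#' @param grid 3D logical array.
#' @param voxelSize numeric(3), um.
#' @param templateId template identifier.
#' @param regionLabel region name, e.g. \code{"peduncle"}.
#' @return A \linkS4class{VoxelMask}.
#' @export
VoxelMask <- function(grid, voxelSize = c(1, 1, 1),
                      templateId = "template", regionLabel = "region") {
  storage.mode(grid) <- "logical"
  new("VoxelMask", grid = grid, voxelSize = as.numeric(voxelSize),
      templateId = templateId, regionLabel = regionLabel)
}

#' Construct a NeuronSkeleton
#'
#' @param nodes data.frame with columns
#'   \code{node_id, parent_id, x, y, z, radius}.
#' @param compartment per-node labels (default \code{"unassigned"}).
#' @param microtubule per-node logical (default \code{TRUE}).
#' @param neuronId identifier.
#' @return A \linkS4class{NeuronSkeleton}.
#' @export
NeuronSkeleton <- function(nodes, compartment = NULL, microtubule = NULL,
                           neuronId = "neuron") {
  n <- nrow(nodes)
  if (is.null(compartment)) compartment <- rep("unassigned", n)
  if (is.null(microtubule)) microtubule <- rep(TRUE, n)
  nodes$node_id <- as.integer(nodes$node_id)
  nodes$parent_id <- as.integer(nodes$parent_id)
  rownames(nodes) <- NULL
  new("NeuronSkeleton", nodes = nodes, compartment = as.character(compartment),
      microtubule = as.logical(microtubule), neuronId = neuronId)
}

#' Construct (and validate) a ConnectorTable
#'
#' Enforces the polyadic-connector invariant (exactly one pre link, at least
#' one post link per connector). When \code{skeletons} are supplied, link
#' node ids are additionally checked to exist in the named neuron.
#'
#' @param connectors data.frame \code{connector_id, x, y, z, neuropil}.
#' @param links data.frame \code{connector_id, neuron_id, node_id, role}.
#' @param skeletons optional list of \linkS4class{NeuronSkeleton}.
#' @return A \linkS4class{ConnectorTable}.
#' @export
ConnectorTable <- function(connectors, links, skeletons = NULL) {
  rownames(connectors) <- rownames(links) <- NULL
  obj <- new("ConnectorTable", connectors = connectors, links = links)
  if (!is.null(skeletons)) checkLinksAgainstSkeletons(obj, skeletons)
  obj
}

checkLinksAgainstSkeletons <- function(table, skeletons) {
  ids <- vapply(skeletons, neuronId, character(1))
  names(skeletons) <- ids
  lk <- table@links
  unknown <- !(lk$neuron_id %in% ids)
  if (any(unknown))
    stop("links reference unknown neuron(s): ",
         paste(unique(lk$neuron_id[unknown]), collapse = ", "), call. = FALSE)
  for (id in unique(lk$neuron_id)) {
    nid <- lk$node_id[lk$neuron_id == id]
    missing <- setdiff(nid, skeletons[[id]]@nodes$node_id)
    if (length(missing))
      stop(sprintf("link node id(s) not present in neuron '%s': %s", id,
                   paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

#' Construct a CalciumTrace
#'
#' @param values raw fluorescence samples.
#' @param samplePeriod s per sample (0.128 for olfactory, 0.640 for
#'   thermogenetic acquisitions).
#' @param stimulusOnset,stimulusDuration s.
#' @param condition,roiId metadata strings.
#' @param trueAmplitude ground-truth response amplitude (synthetic data).
#' @return A \linkS4class{CalciumTrace}.
#' @export
CalciumTrace <- function(values, samplePeriod = 0.128, stimulusOnset = 0,
                         stimulusDuration = 2, condition = "permissive",
                         roiId = "roi", trueAmplitude = NA_real_) {
  new("CalciumTrace", values = as.numeric(values),
      samplePeriod = samplePeriod, stimulusOnset = stimulusOnset,
      stimulusDuration = stimulusDuration, condition = condition,
      roiId = roiId, trueAmplitude = trueAmplitude)
}

#' Validate a table of T-maze fly counts
#'
#' @param df data.frame with columns \code{group_id, pair_id,
#'   odor_as_CSplus, N_CS_plus, N_CS_minus} and optionally \code{genotype},
#'   \code{temperature_condition}.
#' @return The validated data.frame (invisibly unchanged).
#' @export
behaviorCounts <- function(df) {
  need <- c("group_id", "pair_id", "odor_as_CSplus", "N_CS_plus",
            "N_CS_minus")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("behavior counts missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(df$N_CS_plus < 0 | df$N_CS_minus < 0))
    stop("fly counts must be non-negative", call. = FALSE)
  if (any(df$N_CS_plus + df$N_CS_minus <= 0))
    stop("each group needs N_CS+ + N_CS- > 0 for scoring", call. = FALSE)
  df
}
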