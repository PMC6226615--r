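#' @include AllClasses.R constructors.R utils.R
NULL

# SWC type codes used on write; the authoritative labels travel in the
# companion CSV because standard codes cannot express primary_neurite /
# primary_dendrite.
swcTypeFromCompartment <- c(soma = 1L, axon = 2L, dendrite = 3L,
                            primary_dendrite = 4L, primary_neurite = 7L,
                            unassigned = 0L)
compartmentFromSwcType <- c("0" = "unassigned", "1" = "soma", "2" = "axon",
                            "3" = "dendrite", "4" = "primary_dendrite",
                            "7" = "primary_neurite")

#' Read and write SWC skeletons
#'
#' Standard 7-column SWC (id, type, x, y, z, radius, parent; whitespace
#' delimited, \code{#} comments, parent \code{-1} for the root), coordinates
#' in um in template space. Compartment and microtubule labels are carried
#' in a companion CSV (\code{node_id, compartment, microtubule}) because SWC
#' type codes cannot express the primary neurite / primary dendrite
#' distinction; the type column is still set from the nearest standard code.
#'
#' @param path SWC file path.
#' @param labelsPath companion label CSV; defaults to
#'   \code{<path>.labels.csv}, read when present, and always written by
#'   \code{writeSwc}.
#' @param neuronId identifier (defaults to the file stem).
#' @return \code{readSwc}: a \linkS4class{NeuronSkeleton}.
#' @export
readSwc <- function(path, labelsPath = paste0(path, ".labels.csv"),
                    neuronId = sub("\\.[^.]+$", "", basename(path))) {
  tab <- utils::read.table(path, comment.char = "#",
                           col.names = c("node_id", "type", "x", "y", "z",
                                         "radius", "parent_id"))
  tab$parent_id[tab$parent_id == -1] <- NA_integer_
  v <- validateSkeletonNodes(tab[c("node_id", "parent_id", "x", "y", "z",
                                   "radius")])
  if (!isTRUE(v)) stop("invalid SWC '", path, "': ", v, call. = FALSE)
  comp <- unname(compartmentFromSwcType[as.character(tab$type)])
  comp[is.na(comp)] <- "unassigned"
  micro <- rep(TRUE, nrow(tab))
  if (!is.null(labelsPath) && file.exists(labelsPath)) {
    lab <- utils::read.csv(labelsPath)
    m <- match(tab$node_id, lab$node_id)
    comp[!is.na(m)] <- lab$compartment[m[!is.na(m)]]
    micro[!is.na(m)] <- as.logical(lab$microtubule[m[!is.na(m)]])
  }
  NeuronSkeleton(tab[c("node_id", "parent_id", "x", "y", "z", "radius")],
                 compartment = comp, microtubule = micro, neuronId = neuronId)
}

#' @rdname readSwc
#' @param skeleton a \linkS4class{NeuronSkeleton}.
#' @export
writeSwc <- function(skeleton, path,
                     labelsPath = paste0(path, ".labels.csv")) {
  nd <- skeleton@nodes
  type <- unname(swcTypeFromCompartment[skeleton@compartment])
  type[is.na(type)] <- 0L
  out <- data.frame(nd$node_id, type,
                    formatC(nd$x, format = "f", digits = 4),
                    formatC(nd$y, format = "f", digits = 4),
                    formatC(nd$z, format = "f", digits = 4),
                    formatC(nd$radius, format = "f", digits = 4),
                    ifelse(is.na(nd$parent_id), -1L, nd$parent_id))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# SWC export of neuron %s", skeleton@neuronId), con)
  utils::write.table(out, con, quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  if (!is.null(labelsPath))
    utils::write.csv(data.frame(node_id = nd$node_id,
                                compartment = skeleton@compartment,
                                microtubule = skeleton@microtubule),
                     labelsPath, row.names = FALSE)
  invisible(path)
}

#' Read / write polyadic connector tables
#'
#' CSV schema: \code{connector_id, x, y, z, neuropil, neuron_id, node_id,
#' role} — one row per link; connector position and neuropil are repeated
#' on each of its rows. Validation enforces the polyadic invariant and,
#' when skeletons are supplied, that every link's node exists in its neuron.
#'
#' @param path CSV path.
#' @param skeletons optional list of \linkS4class{NeuronSkeleton} to
#'   validate node references against.
#' @return \code{readConnectors}: a \linkS4class{ConnectorTable}.
#' @export
readConnectors <- function(path, skeletons = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("connector_id", "x", "y", "z", "neuropil", "neuron_id",
            "node_id", "role")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("connector CSV missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  conn <- unique(df[c("connector_id", "x", "y", "z", "neuropil")])
  ConnectorTable(conn,
                 df[c("connector_id", "neuron_id", "node_id", "role")],
                 skeletons = skeletons)
}

#' @rdname readConnectors
#' @param table a \linkS4class{ConnectorTable}.
#' @export
writeConnectors <- function(table, path) {
  df <- merge(table@links, table@connectors, by = "connector_id",
              sort = FALSE)
  df <- df[c("connector_id", "x", "y", "z", "neuropil", "neuron_id",
             "node_id", "role")]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Cable length of a skeleton
#'
#' Sum of parent--child Euclidean edge lengths, optionally restricted to a
#' compartment set or to a \linkS4class{VoxelMask}. An edge counts towards a
#' restriction iff its child node passes it (compartment membership, or the
#' child's coordinate falling inside the mask) — a simple, order-independent
#' rule.
#'
#' @param skeleton a \linkS4class{NeuronSkeleton}.
#' @param compartments optional character vector of compartment labels.
#' @param mask optional \linkS4class{VoxelMask}.
#' @return Cable length in um.
#' @examples
#' nd <- data.frame(node_id = 1:3, parent_id = c(NA, 1, 2),
#'                  x = c(0, 10, 20), y = 0, z = 0, radius = 1)
#' cableLength(NeuronSkeleton(nd))  # 20
#' @export
cableLength <- function(skeleton, compartments = NULL, mask = NULL) {
  nd <- skeleton@nodes
  child <- which(!is.na(nd$parent_id))
  keep <- rep(TRUE, length(child))
  if (!is.null(compartments)) {
    bad <- setdiff(compartments, COMPARTMENT_LEVELS)
    if (length(bad))
      stop("unknown compartment label(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    keep <- keep & skeleton@compartment[child] %in% compartments
  }
  if (!is.null(mask)) {
    idx <- umToVoxel(as.matrix(nd[child, c("x", "y", "z")]), voxelSize(mask))
    dm <- dim(grid(mask))
    inside <- idx[, 1] >= 1 & idx[, 1] <= dm[1] &
      idx[, 2] >= 1 & idx[, 2] <= dm[2] &
      idx[, 3] >= 1 & idx[, 3] <= dm[3]
    inMask <- logical(length(child))
    inMask[inside] <- grid(mask)[idx[inside, , drop = FALSE]]
    keep <- keep & inMask
  }
  child <- child[keep]
  if (!length(child)) return(0)
  par <- match(nd$parent_id[child], nd$node_id)
  d <- sqrt((nd$x[child] - nd$x[par])^2 + (nd$y[child] - nd$y[par])^2 +
            (nd$z[child] - nd$z[par])^2)
  sum(d)
}
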