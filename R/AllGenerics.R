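#' @include AllClasses.R
NULL

#' Accessors for lhcircuit classes
#'
#' @param x an object.
#' @return The slot contents: a 3D array for \code{grid}, a numeric(3) for
#'   \code{voxelSize}, data.frames for \code{skeletonNodes},
#'   \code{connectors} and \code{connectorLinks}, a character vector for
#'   \code{compartments}.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("grid", function(x) standardGeneric("grid"))
#' @rdname accessors
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))
#' @rdname accessors
#' @export
setGeneric("skeletonNodes", function(x) standardGeneric("skeletonNodes"))
#' @rdname accessors
#' @export
setGeneric("compartments", function(x) standardGeneric("compartments"))
#' @rdname accessors
#' @export
setGeneric("connectors", function(x) standardGeneric("connectors"))
#' @rdname accessors
#' @export
setGeneric("connectorLinks", function(x) standardGeneric("connectorLinks"))
#' @rdname accessors
#' @export
setGeneric("neuronId", function(x) standardGeneric("neuronId"))
#' @rdname accessors
#' @export
setGeneric("segregationIndexValue",
           function(x) standardGeneric("segregationIndexValue"))

#' @rdname accessors
setMethod("grid", "ExpressionVolume", function(x) x@grid)
#' @rdname accessors
setMethod("grid", "VoxelMask", function(x) x@grid)
#' @rdname accessors
setMethod("voxelSize", "ExpressionVolume", function(x) x@voxelSize)
#' @rdname accessors
setMethod("voxelSize", "VoxelMask", function(x) x@voxelSize)
#' @rdname accessors
setMethod("skeletonNodes", "NeuronSkeleton", function(x) x@nodes)
#' @rdname accessors
setMethod("compartments", "NeuronSkeleton", function(x) x@compartment)
#' @rdname accessors
setMethod("compartments", "CompartmentSplit", function(x) x@compartment)
#' @rdname accessors
setMethod("connectors", "ConnectorTable", function(x) x@connectors)
#' @rdname accessors
setMethod("connectorLinks", "ConnectorTable", function(x) x@links)
#' @rdname accessors
setMethod("neuronId", "NeuronSkeleton", function(x) x@neuronId)
#' @rdname accessors
setMethod("neuronId", "Dotprops", function(x) x@neuronId)
#' @rdname accessors
setMethod("neuronId", "CompartmentSplit", function(x) x@neuronId)
#' @rdname accessors
setMethod("segregationIndexValue", "CompartmentSplit",
          function(x) x@segregationIndex)

setMethod("show", "ExpressionVolume", function(object) {
  cat(sprintf("ExpressionVolume '%s' [%s voxels @ %s um, template %s]\n",
              object@lineId, paste(dim(object@grid), collapse = "x"),
              paste(signif(object@voxelSize, 3), collapse = "x"),
              object@templateId))
})

setMethod("show", "VoxelMask", function(object) {
  cat(sprintf("VoxelMask '%s' [%s voxels, %d set, template %s]\n",
              object@regionLabel, paste(dim(object@grid), collapse = "x"),
              sum(object@grid), object@templateId))
})

setMethod("show", "NeuronSkeleton", function(object) {
  tab <- table(object@compartment)
  cat(sprintf("NeuronSkeleton '%s': %d nodes (%s)\n", object@neuronId,
              nrow(object@nodes),
              paste(sprintf("%s:%d", names(tab), as.integer(tab)),
                    collapse = ", ")))
})

setMethod("show", "ConnectorTable", function(object) {
  cat(sprintf("ConnectorTable: %d connectors, %d links (%d pre, %d post)\n",
              nrow(object@connectors), nrow(object@links),
              sum(object@links$role == "pre"),
              sum(object@links$role == "post")))
})

setMethod("show", "Dotprops", function(object) {
  cat(sprintf("Dotprops '%s': %d points, step %.3g um\n", object@neuronId,
              nrow(object@points), object@resampleStep))
})

setMethod("show", "ScoreMatrix", function(object) {
  cat(sprintf("ScoreMatrix: %d neurons (raw / normalized / mean)\n",
              length(object@ids)))
})

setMethod("show", "CompartmentSplit", function(object) {
  cat(sprintf(
    "CompartmentSplit '%s': split at node %d, SI = %.3f (%s)\n",
    object@neuronId, object@splitNodeId, object@segregationIndex,
    object@countingMode))
})

setMethod("show", "CalciumTrace", function(object) {
  cat(sprintf(
    "CalciumTrace '%s' (%s): %d samples @ %.3g s, stimulus %gs+%gs\n",
    object@roiId, object@condition, length(object@values),
    object@samplePeriod, object@stimulusOnset, object@stimulusDuration))
})
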