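#' @include AllClasses.R constructors.R
NULL

# ---- NRRD (raw encoding) ------------------------------------------------
# Minimal detached-header-free NRRD support: enough to carry a 3D scalar
# grid plus voxel spacings. Raw little-endian encoding only.

nrrdTypeMap <- list(
  "unsigned char" = list(what = "integer", size = 1L, signed = FALSE),
  uchar = list(what = "integer", size = 1L, signed = FALSE),
  uint8 = list(what = "integer", size = 1L, signed = FALSE),
  short = list(what = "integer", size = 2L, signed = TRUE),
  "unsigned short" = list(what = "integer", size = 2L, signed = FALSE),
  uint16 = list(what = "integer", size = 2L, signed = FALSE),
  int = list(what = "integer", size = 4L, signed = TRUE),
  float = list(what = "numeric", size = 4L, signed = TRUE),
  double = list(what = "numeric", size = 8L, signed = TRUE))

readNrrdArray <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!startsWith(magic, "NRRD"))
    stop("not an NRRD file: ", path, call. = FALSE)
  fields <- list()
  repeat {
    ln <- readLines(con, n = 1L)
    if (length(ln) == 0L || ln == "") break
    if (startsWith(ln, "#")) next
    kv <- regmatches(ln, regexpr(":=?", ln), invert = TRUE)[[1]]
    fields[[tolower(trimws(kv[1]))]] <- trimws(kv[2])
  }
  type <- fields[["type"]]
  spec <- nrrdTypeMap[[type]]
  if (is.null(spec)) stop("unsupported NRRD type: ", type, call. = FALSE)
  if (!identical(fields[["encoding"]], "raw"))
    stop("only raw NRRD encoding is supported", call. = FALSE)
  sizes <- as.integer(strsplit(fields[["sizes"]], "\\s+")[[1]])
  n <- prod(sizes)
  vals <- readBin(con, what = spec$what, n = n, size = spec$size,
                  signed = if (spec$size >= 4L) TRUE else spec$signed,
                  endian = "little")
  spacing <- rep(1, length(sizes))
  if (!is.null(fields[["spacings"]]))
    spacing <- as.numeric(strsplit(fields[["spacings"]], "\\s+")[[1]])
  list(data = array(as.numeric(vals), dim = sizes), spacing = spacing,
       fields = fields)
}

writeNrrdArray <- function(data, path, spacing = rep(1, 3),
                           type = "double") {
  spec <- nrrdTypeMap[[type]]
  if (is.null(spec)) stop("unsupported NRRD type: ", type, call. = FALSE)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("NRRD0004",
           paste0("type: ", type),
           paste0("dimension: ", length(dim(data))),
           paste0("sizes: ", paste(dim(data), collapse = " ")),
           paste0("spacings: ", paste(spacing, collapse = " ")),
           "encoding: raw",
           "endian: little",
           "")
  writeLines(hdr, con)
  vals <- as.vector(data)
  if (spec$what == "integer") vals <- as.integer(round(vals))
  writeBin(vals, con, size = spec$size, endian = "little")
  invisible(path)
}

# ---- public volume / mask I/O ------------------------------------------

#' Read / write registered volumes and masks
#'
#' Volumes are carried as NRRD (raw encoding, with voxel spacings) or
#' multi-page TIFF (spacing supplied by the caller, since plain TIFF carries
#' no z calibration). The format is picked from the file extension.
#'
#' @param path file path ending in \code{.nrrd}, \code{.tif} or
#'   \code{.tiff}.
#' @param voxelSize numeric(3) um; for TIFF input this must be supplied,
#'   for NRRD it is read from the header.
#' @param templateId,lineId,regionLabel metadata attached to the object.
#' @return \code{readVolume}: an \linkS4class{ExpressionVolume};
#'   \code{readMask}: a \linkS4class{VoxelMask}.
#' @export
readVolume <- function(path, voxelSize = NULL, templateId = "template",
                       lineId = sub("\\.[^.]+$", "", basename(path))) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "nrrd") {
    r <- readNrrdArray(path)
    if (is.null(voxelSize)) voxelSize <- r$spacing
    g <- r$data
  } else if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    g <- array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
    if (is.null(voxelSize))
      stop("voxelSize must be supplied for TIFF volumes", call. = FALSE)
  } else stop("unsupported volume format: .", ext, call. = FALSE)
  ExpressionVolume(g, voxelSize = voxelSize, templateId = templateId,
                   lineId = lineId)
}

#' @rdname readVolume
#' @param volume an \linkS4class{ExpressionVolume}.
#' @export
writeVolume <- function(volume, path) {
  ext <- tolower(tools::file_ext(path))
  g <- grid(volume)
  if (ext == "nrrd") {
    writeNrrdArray(g, path, spacing = voxelSize(volume))
  } else if (ext %in% c("tif", "tiff")) {
    mx <- max(g)
    if (mx > 1) g <- g / mx  # TIFF float pages are stored in [0, 1]
    pages <- lapply(seq_len(dim(g)[3]), function(k) g[, , k])
    tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  } else stop("unsupported volume format: .", ext, call. = FALSE)
  invisible(path)
}

#' @rdname readVolume
#' @export
readMask <- function(path, voxelSize = NULL, templateId = "template",
                     regionLabel = sub("\\.[^.]+$", "", basename(path))) {
  vol <- readVolume(path, voxelSize = voxelSize, templateId = templateId)
  VoxelMask(grid(vol) > 0.5, voxelSize = voxelSize(vol),
            templateId = templateId, regionLabel = regionLabel)
}

#' @rdname readVolume
#' @param mask a \linkS4class{VoxelMask}.
#' @export
writeMask <- function(mask, path) {
  ext <- tolower(tools::file_ext(path))
  g <- grid(mask) * 1
  if (ext == "nrrd") {
    writeNrrdArray(g, path, spacing = voxelSize(mask), type = "uint8")
  } else {
    storage.mode(g) <- "double"
    writeVolume(ExpressionVolume(g, voxelSize = voxelSize(mask)), path)
  }
  invisible(path)
}
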