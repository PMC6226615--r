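# Internal helpers shared across modules.

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards. Generators derive one substream per entity so
# output is independent of generation order.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Deterministic substream seed: mixes a base seed with an entity counter,
# kept within 32-bit integer range.
substreamSeed <- function(seed, counter) {
  as.integer((as.numeric(seed) %% 2147483647) * 7919 + 104729 * counter) %%
    2147483647L
}

stopIfNot3D <- function(a, what = "array") {
  if (length(dim(a)) != 3L)
    stop(what, " must be a 3D array", call. = FALSE)
}

checkAligned <- function(a, b) {
  if (!all(dim(grid(a)) == dim(grid(b))))
    stop("shape mismatch between '", class(a)[1], "' and '", class(b)[1],
         "'", call. = FALSE)
  if (any(abs(voxelSize(a) - voxelSize(b)) > 1e-9))
    stop("voxel size mismatch", call. = FALSE)
  invisible(TRUE)
}

# um -> 1-based voxel index, voxel centers at (i + 0.5) * voxelSize for
# 0-based i (so 1-based index j covers [ (j-1)*vs, j*vs )).
umToVoxel <- function(xyz, voxelSize) {
  xyz <- rbind(xyz)
  idx <- sweep(xyz, 2, voxelSize, "/")
  storage.mode(idx) <- "double"
  floor(idx) + 1L
}

# 1-based voxel index -> um coordinate of the voxel center.
voxelToUm <- function(idx, voxelSize) {
  idx <- rbind(idx)
  sweep(idx - 0.5, 2, voxelSize, "*")
}

# children adjacency list for a skeleton nodes table, keyed by row index
childIndexList <- function(nodes) {
  pidx <- match(nodes$parent_id, nodes$node_id)
  split(seq_len(nrow(nodes))[!is.na(pidx)], pidx[!is.na(pidx)])
}

# row indices in root-first (topological) order
topoOrder <- function(nodes) {
  pidx <- match(nodes$parent_id, nodes$node_id)
  n <- nrow(nodes)
  depth <- rep(NA_integer_, n)
  depth[is.na(pidx)] <- 0L
  repeat {
    todo <- which(is.na(depth) & !is.na(depth[pidx]))
    if (!length(todo)) break
    depth[todo] <- depth[pidx[todo]] + 1L
  }
  order(depth)
}
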