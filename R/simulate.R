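#' @include AllClasses.R constructors.R utils.R screen.R
NULL

#' Simulation configuration
#'
#' One configuration object drives every generator, and identical
#' configurations (including the seed) give bit-identical output. Defaults
#' describe the study conditions the pipeline was designed around: a
#' 200-line expression screen with 5 planted positives and 20 peduncle
#' confounds; 3 morphological families of 5 neurons each; polyadic fan-out
#' 1 + Poisson(6.8) (mean 7.8); 128 ms calcium sampling with 2 s odor
#' pulses; groups of 50 flies in reciprocal T-maze pairs.
#'
#' @param seed integer RNG seed.
#' @param volumeShape integer(3) voxel grid, minimum c(16, 16, 8).
#' @param voxelUm numeric(3) voxel size in um.
#' @param nLines number of simulated driver lines.
#' @param nPositives,nConfounds counts of planted positive / peduncle
#'   confound lines (their ids are drawn deterministically from the seed).
#' @param confoundTargetSignal if TRUE, confounds additionally carry weak
#'   target-region signal (off by default so the planted positives are the
#'   unique suprathreshold-target lines).
#' @param families list of per-family skeleton parameter lists
#'   (\code{nNeurons, nBranches, branchLen, jitterUm, offsetUm,
#'   calyxBranch}, optionally \code{shapeSeed} — families sharing a shape
#'   seed share the same stereotyped branch directions — and
#'   \code{registrationUm}, the whole-cell placement scatter: ~1 um for
#'   light-level registration, 0 for single-EM-volume tracings);
#'   \code{NULL} gives 3 separated families x 5 neurons.
#' @param nPre,nPost synapse placements per neuron.
#' @param mixing compartment mixing fraction m in [0, 1]: probability that
#'   a presynapse lands on the dendritic arbor (and a postsynapse on the
#'   axonal arbor). m = 0 is perfect segregation, m = 0.5 fully mixed.
#' @param fanout sampler for polyadic fan-outs: either a function
#'   \code{function(n)} returning n integers >= 1, or a named numeric
#'   probability vector whose names are the support. Default
#'   \code{1 + Poisson(6.8)}.
#' @param calcium list: \code{baseline, amplitude, tau, noiseSd,
#'   samplePeriod, duration, onset, stimulusDuration, nTraces}.
#' @param behavior list: \code{p, groupSize, nPairs, bias} (bias is an
#'   additive arm preference for the first odor, cancelled by reciprocal
#'   averaging).
#' @return A classed list (\code{SimulationConfig}).
#' @export
simulationConfig <- function(seed = 0L,
                             volumeShape = c(64L, 64L, 32L),
                             voxelUm = c(0.56, 0.56, 1.0),
                             nLines = 200L,
                             nPositives = 5L,
                             nConfounds = 20L,
                             confoundTargetSignal = FALSE,
                             families = NULL,
                             nPre = 40L, nPost = 60L, mixing = 0,
                             fanout = function(n) 1L + stats::rpois(n, 6.8),
                             calcium = list(),
                             behavior = list()) {
  if (mixing < 0 || mixing > 1) stop("mixing must lie in [0, 1]")
  if (nPre < 0 || nPost < 0 || nLines < 0) stop("counts must be >= 0")
  if (is.numeric(fanout)) {
    support <- as.numeric(names(fanout))
    if (any(is.na(support)) || any(support < 1))
      stop("fanout distribution support must be integers >= 1")
  }
  if (is.null(families)) {
    families <- lapply(1:3, function(f)
      list(nNeurons = 5L, nBranches = 5L, branchLen = 18, jitterUm = 1.5,
           offsetUm = c(45 * (f - 1), 0, 0), calyxBranch = FALSE))
    names(families) <- paste0("family", 1:3)
  }
  calcium <- utils::modifyList(
    list(baseline = 100, amplitude = 50, tau = 1.0, noiseSd = 2,
         samplePeriod = 0.128, duration = 20, onset = 5,
         stimulusDuration = 2, nTraces = 6L), calcium)
  if (calcium$samplePeriod <= 0) stop("sample period must be positive")
  if (calcium$tau <= 0) stop("decay constant must be positive")
  if (calcium$baseline <= 0) stop("baseline must be positive")
  behavior <- utils::modifyList(
    list(p = 0.5, groupSize = 50L, nPairs = 12L, bias = 0), behavior)
  if (behavior$p < 0 || behavior$p > 1) stop("p must lie in [0, 1]")
  if (behavior$groupSize < 1) stop("group size must be >= 1")
  structure(list(seed = as.integer(seed),
                 volumeShape = as.integer(volumeShape), voxelUm = voxelUm,
                 nLines = as.integer(nLines),
                 nPositives = as.integer(nPositives),
                 nConfounds = as.integer(nConfounds),
                 confoundTargetSignal = confoundTargetSignal,
                 families = families, nPre = as.integer(nPre),
                 nPost = as.integer(nPost), mixing = mixing,
                 fanout = fanout, calcium = calcium, behavior = behavior),
            class = "SimulationConfig")
}

sampleFanout <- function(cfg, n) {
  f <- cfg$fanout
  if (is.function(f)) return(as.integer(f(n)))
  support <- as.integer(names(f))
  sample(support, n, replace = TRUE, prob = f)
}

# fractional box -> voxel index ranges within a shape
fracBox <- function(shape, fx, fy, fz) {
  list(x = max(1, round(fx[1] * shape[1])):round(fx[2] * shape[1]),
       y = max(1, round(fy[1] * shape[2])):round(fy[2] * shape[2]),
       z = max(1, round(fz[1] * shape[3])):round(fz[2] * shape[3]))
}

boxMask <- function(shape, box, voxelUm, label) {
  g <- array(FALSE, shape)
  g[box$x, box$y, box$z] <- TRUE
  VoxelMask(g, voxelSize = voxelUm, regionLabel = label)
}

# Rasterize a jittered polyline into `a`, depositing `amp` at the voxel
# under sample points every ~half voxel along each segment.
rasterPolyline <- function(a, ctrl, amp, voxelUm) {
  dm <- dim(a)
  step <- min(voxelUm) / 2
  for (s in seq_len(nrow(ctrl) - 1)) {
    p0 <- ctrl[s, ]; p1 <- ctrl[s + 1, ]
    len <- sqrt(sum((p1 - p0)^2))
    ts <- seq(0, 1, length.out = max(2L, ceiling(len / step)))
    pts <- cbind(p0[1] + ts * (p1[1] - p0[1]),
                 p0[2] + ts * (p1[2] - p0[2]),
                 p0[3] + ts * (p1[3] - p0[3]))
    idx <- umToVoxel(pts, voxelUm)
    ok <- idx[, 1] >= 1 & idx[, 1] <= dm[1] & idx[, 2] >= 1 &
      idx[, 2] <= dm[2] & idx[, 3] >= 1 & idx[, 3] <= dm[3]
    a[idx[ok, , drop = FALSE]] <- amp
  }
  a
}

# random polyline control points inside a voxel box, in um
polylineInBox <- function(box, voxelUm, nCtrl = 6L) {
  ctrl <- cbind(stats::runif(nCtrl, min(box$x) - 1, max(box$x)) + 0.5,
                stats::runif(nCtrl, min(box$y) - 1, max(box$y)) + 0.5,
                stats::runif(nCtrl, min(box$z) - 1, max(box$z)) + 0.5)
  sweep(ctrl, 2, voxelUm, "*")
}

#' Generate a synthetic expression-pattern library
#'
#' Emulates the registered GAL4 image database screened against an MBON
#' axon mask: planted positive lines carry bright tubular (Gaussian-blurred
#' polyline) signal inside the target region, confound lines carry bright
#' signal in the Kenyon-cell peduncle, and every other line expresses
#' somewhere else in the volume over a dim background. Ground-truth labels
#' are returned alongside disjoint target and peduncle masks.
#'
#' @param cfg a \code{\link{simulationConfig}}.
#' @return list with \code{volumes} (list of
#'   \linkS4class{ExpressionVolume}), \code{target} and \code{peduncle}
#'   (\linkS4class{VoxelMask}), and \code{truth} (data.frame
#'   \code{line_id, label}, label in positive/confound/negative).
#' @export
makeExpressionLibrary <- function(cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  shape <- cfg$volumeShape
  if (any(shape < c(16L, 16L, 8L)))
    stop("volume shape must be at least 16 x 16 x 8", call. = FALSE)
  targetBox <- fracBox(shape, c(0.10, 0.35), c(0.60, 0.90), c(0.55, 0.85))
  pedBox <- fracBox(shape, c(0.55, 0.68), c(0.10, 0.55), c(0.25, 0.50))
  target <- boxMask(shape, targetBox, cfg$voxelUm, "LH-axon-mask")
  peduncle <- boxMask(shape, pedBox, cfg$voxelUm, "peduncle")
  if (any(grid(target) & grid(peduncle)))
    stop("target and peduncle masks overlap", call. = FALSE)
  ids <- sprintf("L%04d", seq_len(cfg$nLines))
  if (cfg$nLines == 0L)
    return(list(volumes = list(), target = target, peduncle = peduncle,
                truth = data.frame(line_id = character(),
                                   label = character())))
  lab <- withSeed(substreamSeed(cfg$seed, 0L), {
    lab <- rep("negative", cfg$nLines)
    special <- sample(cfg$nLines, cfg$nPositives + cfg$nConfounds)
    lab[special[seq_len(cfg$nPositives)]] <- "positive"
    lab[special[cfg$nPositives + seq_len(cfg$nConfounds)]] <- "confound"
    lab
  })
  elseBox <- fracBox(shape, c(0.70, 0.97), c(0.55, 0.95), c(0.10, 0.45))
  volumes <- lapply(seq_len(cfg$nLines), function(i) {
    withSeed(substreamSeed(cfg$seed, i), {
      a <- array(0, shape)
      nb <- prod(shape)
      bg <- sample(nb, round(0.002 * nb))  # sparse dim autofluorescence
      a[bg] <- stats::runif(length(bg), 2, 8)
      if (lab[i] == "positive") {
        a <- rasterPolyline(a, polylineInBox(targetBox, cfg$voxelUm, 8L),
                            220, cfg$voxelUm)
      } else if (lab[i] == "confound") {
        a <- rasterPolyline(a, polylineInBox(pedBox, cfg$voxelUm, 8L),
                            220, cfg$voxelUm)
        if (cfg$confoundTargetSignal)
          a <- rasterPolyline(a, polylineInBox(targetBox, cfg$voxelUm, 3L),
                              120, cfg$voxelUm)
      } else {
        a <- rasterPolyline(a, polylineInBox(elseBox, cfg$voxelUm, 6L),
                            220, cfg$voxelUm)
      }
      a <- gaussianBlur3D(a, 1.0, cfg$voxelUm)
      ExpressionVolume(a, voxelSize = cfg$voxelUm, lineId = ids[i])
    })
  })
  list(volumes = volumes, target = target, peduncle = peduncle,
       truth = data.frame(line_id = ids, label = lab,
                          stringsAsFactors = FALSE))
}

# ---- skeleton population -----------------------------------------------

# Grow a chain of n nodes from node `from` (row index) toward `to` (um).
# Jitter displaces the branch endpoint as a whole (smooth, neurite-like
# deviation); per-node noise stays small so the chain remains smooth and
# local tangents stay meaningful.
growChain <- function(nodes, from, to, n, jitter, compartment, radius = 0.3) {
  p0 <- as.numeric(nodes$df[from, c("x", "y", "z")])
  toJ <- to + stats::rnorm(3, 0, jitter)
  for (k in seq_len(n)) {
    t <- k / n
    p <- p0 + t * (toJ - p0) + stats::rnorm(3, 0, jitter / 5)
    id <- nrow(nodes$df) + 1L
    nodes$df[id, ] <- list(id, nodes$df$node_id[from], p[1], p[2], p[3],
                           radius)
    nodes$comp[id] <- compartment
    from <- id
  }
  nodes$tip <- from
  nodes
}

# Stereotyped per-family arbor shape: branch directions are a property of
# the cell type (drawn once from the family's shape seed); individual
# neurons only jitter around that shared blueprint.
familyShape <- function(fam, cfgSeed, famIndex) {
  shapeSeed <- if (!is.null(fam$shapeSeed)) fam$shapeSeed else famIndex
  withSeed(substreamSeed(cfgSeed, 500L + 7L * shapeSeed), {
    unitDirs <- function(n) {
      m <- matrix(stats::rnorm(3 * n), n, 3)
      m / sqrt(rowSums(m^2))
    }
    list(dend = unitDirs(fam$nBranches), axon = unitDirs(fam$nBranches),
         calyx = unitDirs(3L))
  })
}

buildNeuron <- function(fam, shape, neuronId, seed) {
  withSeed(seed, {
    # whole-cell placement scatter: ~1 um emulates light-level
    # registration accuracy; 0 emulates skeletons traced in one EM volume
    regUm <- if (!is.null(fam$registrationUm)) fam$registrationUm else 1
    base <- fam$offsetUm + stats::rnorm(3, 0, regUm)
    somaPos <- base + c(0, -25, 8)
    dendCenter <- base
    axonCenter <- base + c(0, 28, -6)
    nodes <- list(df = data.frame(node_id = 1L, parent_id = NA_integer_,
                                  x = somaPos[1], y = somaPos[2],
                                  z = somaPos[3], radius = 2),
                  comp = "soma", tip = 1L)
    nodes <- growChain(nodes, 1L, dendCenter, 5L, fam$jitterUm / 3,
                       "primary_neurite")
    dendRoot <- nodes$tip
    nodes$comp[dendRoot] <- "dendrite"
    for (b in seq_len(fam$nBranches))
      nodes <- growChain(nodes, dendRoot,
                         dendCenter + shape$dend[b, ] * fam$branchLen, 6L,
                         fam$jitterUm, "dendrite")
    if (isTRUE(fam$calyxBranch)) {
      # calycal projection: a long trunk to a distant neuropil ending in
      # a small stereotyped tuft
      calyxCenter <- dendCenter + c(0, -12, 45)
      nodes <- growChain(nodes, dendRoot, calyxCenter, 12L, fam$jitterUm,
                         "dendrite")
      calyxRoot <- nodes$tip
      for (b in 1:3)
        nodes <- growChain(nodes, calyxRoot,
                           calyxCenter + shape$calyx[b, ] * 10, 5L,
                           fam$jitterUm, "dendrite")
    }
    nodes <- growChain(nodes, dendRoot, axonCenter, 5L, fam$jitterUm / 3,
                       "primary_dendrite")
    axonRoot <- nodes$tip
    nodes$comp[axonRoot] <- "axon"
    for (b in seq_len(fam$nBranches))
      nodes <- growChain(nodes, axonRoot,
                         axonCenter + shape$axon[b, ] * fam$branchLen, 6L,
                         fam$jitterUm, "axon")
    NeuronSkeleton(nodes$df, compartment = nodes$comp, neuronId = neuronId)
  })
}

#' Generate a synthetic neuron population with polyadic connectors
#'
#' Builds rooted-tree skeletons in morphological families (soma, primary
#' neurite, dendritic arbor, primary dendrite, axonal arbor), places
#' postsynapses on the dendritic arbor and presynapses on the axonal arbor
#' with mixing fraction m (m = 0: perfect segregation; m = 0.5: fully
#' mixed), and wires polyadic connectors whose fan-outs follow the
#' configured distribution, with post links sampled across the population's
#' postsynaptic placements.
#'
#' @param cfg a \code{\link{simulationConfig}}.
#' @return list with \code{skeletons} (list of
#'   \linkS4class{NeuronSkeleton}), \code{connectors}
#'   (\linkS4class{ConnectorTable}), and \code{truth} (data.frame
#'   \code{neuron_id, family}).
#' @export
makeNeuronPopulation <- function(cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  if (!length(cfg$families)) stop("need at least one family", call. = FALSE)
  famNames <- names(cfg$families)
  if (is.null(famNames)) famNames <- paste0("family", seq_along(cfg$families))
  skeletons <- list(); truth <- list(); counter <- 0L
  for (f in seq_along(cfg$families)) {
    fam <- cfg$families[[f]]
    shape <- familyShape(fam, cfg$seed, f)
    for (j in seq_len(fam$nNeurons)) {
      counter <- counter + 1L
      id <- sprintf("%s_n%02d", famNames[f], j)
      skeletons[[counter]] <- buildNeuron(
        fam, shape, id, substreamSeed(cfg$seed, 1000L + counter))
      truth[[counter]] <- data.frame(neuron_id = id, family = famNames[f],
                                     stringsAsFactors = FALSE)
    }
  }
  truth <- do.call(rbind, truth)
  # synapse placements per neuron: arbor choice with mixing m
  placements <- lapply(seq_along(skeletons), function(i) {
    sk <- skeletons[[i]]
    withSeed(substreamSeed(cfg$seed, 2000L + i), {
      dend <- sk@nodes$node_id[sk@compartment == "dendrite"]
      axon <- sk@nodes$node_id[sk@compartment == "axon"]
      pick <- function(n, wrongArbor, rightArbor) {
        wrong <- stats::runif(n) < cfg$mixing
        out <- integer(n)
        if (any(wrong)) out[wrong] <- sample(wrongArbor, sum(wrong),
                                             replace = TRUE)
        if (any(!wrong)) out[!wrong] <- sample(rightArbor, sum(!wrong),
                                               replace = TRUE)
        out
      }
      list(pre = pick(cfg$nPre, dend, axon),
           post = pick(cfg$nPost, axon, dend))
    })
  })
  ids <- vapply(skeletons, neuronId, character(1))
  postPool <- do.call(rbind, lapply(seq_along(placements), function(i)
    data.frame(neuron_id = ids[i], node_id = placements[[i]]$post,
               stringsAsFactors = FALSE)))
  connRows <- list(); linkRows <- list(); cid <- 0L
  for (i in seq_along(skeletons)) {
    sk <- skeletons[[i]]
    pre <- placements[[i]]$pre
    if (!length(pre)) next
    withSeed(substreamSeed(cfg$seed, 3000L + i), {
      fo <- sampleFanout(cfg, length(pre))
      for (j in seq_along(pre)) {
        cid <- cid + 1L
        nd <- sk@nodes[match(pre[j], sk@nodes$node_id), ]
        connRows[[cid]] <- data.frame(
          connector_id = cid, x = nd$x, y = nd$y, z = nd$z,
          neuropil = "LH", stringsAsFactors = FALSE)
        tgt <- postPool[sample(nrow(postPool), fo[j], replace = TRUE), ]
        linkRows[[cid]] <- rbind(
          data.frame(connector_id = cid, neuron_id = ids[i],
                     node_id = pre[j], role = "pre",
                     stringsAsFactors = FALSE),
          data.frame(connector_id = cid, neuron_id = tgt$neuron_id,
                     node_id = tgt$node_id, role = "post",
                     stringsAsFactors = FALSE))
      }
    })
  }
  table <- ConnectorTable(do.call(rbind, connRows), do.call(rbind, linkRows),
                          skeletons = skeletons)
  list(skeletons = skeletons, connectors = table, truth = truth)
}

#' Generate synthetic calcium traces
#'
#' Each trace is baseline + amplitude x (stimulus-locked exponential-decay
#' kernel) + Gaussian noise, sampled at the configured frame period. The
#' kernel peaks at the stimulus-onset sample and decays with time constant
#' tau. The planted amplitude is stored as ground truth.
#'
#' @param cfg a \code{\link{simulationConfig}}. \code{cfg$calcium$amplitude}
#'   may be a vector, recycled across traces.
#' @return list of \linkS4class{CalciumTrace}.
#' @export
makeCalciumDataset <- function(cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  p <- cfg$calcium
  n <- round(p$duration / p$samplePeriod)
  t <- (seq_len(n) - 1) * p$samplePeriod
  amps <- rep_len(p$amplitude, p$nTraces)
  conds <- rep_len(if (!is.null(p$condition)) p$condition else "permissive",
                   p$nTraces)
  lapply(seq_len(p$nTraces), function(i) {
    withSeed(substreamSeed(cfg$seed, 4000L + i), {
      # kernel peaks (value 1) at the first frame acquired after the
      # valve switch and decays with time constant tau
      tPeak <- t[min(which(t >= p$onset - 1e-9))]
      kernel <- ifelse(t >= tPeak, exp(-(t - tPeak) / p$tau), 0)
      vals <- p$baseline + amps[i] * kernel +
        stats::rnorm(n, 0, p$noiseSd)
      CalciumTrace(vals, samplePeriod = p$samplePeriod,
                   stimulusOnset = p$onset,
                   stimulusDuration = p$stimulusDuration,
                   condition = conds[i], roiId = sprintf("roi%03d", i),
                   trueAmplitude = amps[i])
    })
  })
}

#' Generate synthetic T-maze counts
#'
#' Groups of flies choose the CS+ arm with probability p (optionally
#' shifted by an additive preference for the first odor, +bias when it is
#' the CS+ and -bias when it is not, which reciprocal averaging cancels);
#' \code{N_CS+ ~ Binomial(groupSize, p_eff)}. Groups come in reciprocal
#' pairs differing only in which odor served as CS+.
#'
#' @param cfg a \code{\link{simulationConfig}}.
#' @return data.frame of behavior counts (see \code{\link{behaviorCounts}}).
#' @export
makeBehaviorDataset <- function(cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  b <- cfg$behavior
  rows <- lapply(seq_len(b$nPairs), function(k) {
    withSeed(substreamSeed(cfg$seed, 5000L + k), {
      pe <- pmin(1, pmax(0, c(b$p + b$bias, b$p - b$bias)))
      nplus <- stats::rbinom(2, b$groupSize, pe)
      data.frame(group_id = sprintf("pair%03d_%s", k, c("A", "B")),
                 pair_id = sprintf("pair%03d", k),
                 odor_as_CSplus = c("Oct", "Mch"),
                 N_CS_plus = nplus, N_CS_minus = b$groupSize - nplus,
                 genotype = "synthetic",
                 temperature_condition = "restrictive",
                 stringsAsFactors = FALSE)
    })
  })
  behaviorCounts(do.call(rbind, rows))
}
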