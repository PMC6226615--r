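test_that("generators are deterministic given the config", {
  cfg <- simulationConfig(seed = 7, nLines = 6, nPositives = 1,
                          nConfounds = 1)
  a <- makeExpressionLibrary(cfg)
  b <- makeExpressionLibrary(cfg)
  expect_identical(lapply(a$volumes, grid), lapply(b$volumes, grid))
  expect_identical(a$truth, b$truth)
  p1 <- makeNeuronPopulation(cfg)
  p2 <- makeNeuronPopulation(cfg)
  expect_identical(lapply(p1$skeletons, skeletonNodes),
                   lapply(p2$skeletons, skeletonNodes))
  expect_identical(connectorLinks(p1$connectors),
                   connectorLinks(p2$connectors))
  expect_identical(makeBehaviorDataset(cfg), makeBehaviorDataset(cfg))
  expect_identical(lapply(makeCalciumDataset(cfg), function(t) t@values),
                   lapply(makeCalciumDataset(cfg), function(t) t@values))
})

test_that("expression library plants positives in target, confounds in peduncle", {
  cfg <- simulationConfig(seed = 0, nLines = 40, nPositives = 4,
                          nConfounds = 6)
  lib <- makeExpressionLibrary(cfg)
  # brute-force voxel counting oracle: suprathreshold (per-volume Otsu)
  # voxels inside the target mask, counted directly
  counts <- vapply(lib$volumes, function(v) {
    g <- grid(v)
    sum(g > lhcircuit:::otsuThreshold(g) & grid(lib$target))
  }, numeric(1))
  lab <- lib$truth$label
  expect_true(min(counts[lab == "positive"]) >
                max(counts[lab != "positive"]))
  pedCounts <- vapply(lib$volumes, function(v) {
    g <- grid(v)
    sum(g > lhcircuit:::otsuThreshold(g) & grid(lib$peduncle))
  }, numeric(1))
  expect_true(all(pedCounts[lab == "confound"] > 0))
  expect_false(any(grid(lib$target) & grid(lib$peduncle)))
  # vacuous case: empty library still returns the masks
  empty <- makeExpressionLibrary(simulationConfig(seed = 0, nLines = 0,
                                                  nPositives = 0,
                                                  nConfounds = 0))
  expect_length(empty$volumes, 0)
  expect_s4_class(empty$target, "VoxelMask")
})

test_that("neuron population has valid trees with compartment-structured synapses", {
  cfg <- simulationConfig(seed = 1, mixing = 0)
  pop <- makeNeuronPopulation(cfg)
  for (sk in pop$skeletons) expect_true(validObject(sk))
  expect_true(validObject(pop$connectors))
  # m = 0: every pre link on the axon arbor, every post link on dendrite
  lk <- connectorLinks(pop$connectors)
  for (sk in pop$skeletons[1:3]) {
    comp <- setNames(compartments(sk), skeletonNodes(sk)$node_id)
    mine <- lk[lk$neuron_id == neuronId(sk), ]
    expect_true(all(comp[as.character(mine$node_id[mine$role == "pre"])]
                    == "axon"))
    expect_true(all(comp[as.character(mine$node_id[mine$role == "post"])]
                    == "dendrite"))
  }
  # fanout = delta(1) => every connector has exactly one post link
  cfg1 <- simulationConfig(seed = 1, fanout = c("1" = 1))
  pop1 <- makeNeuronPopulation(cfg1)
  lk1 <- connectorLinks(pop1$connectors)
  expect_true(all(table(lk1$connector_id[lk1$role == "post"]) == 1))
  expect_error(simulationConfig(fanout = c("0" = 0.5, "2" = 0.5)),
               "support")
  # families are geometrically coherent: within-family mean pairwise
  # node-to-node NN distance below the between-family mean (direct loop)
  nnDist <- function(a, b) {
    pa <- as.matrix(skeletonNodes(a)[c("x", "y", "z")])
    pb <- as.matrix(skeletonNodes(b)[c("x", "y", "z")])
    mean(vapply(seq_len(nrow(pa)), function(i)
      sqrt(min(colSums((t(pb) - pa[i, ])^2))), numeric(1)))
  }
  fam <- pop$truth$family
  within <- c(); between <- c()
  idx <- seq_along(pop$skeletons)
  for (i in idx) for (j in idx) {
    if (i >= j) next
    d <- nnDist(pop$skeletons[[i]], pop$skeletons[[j]])
    if (fam[i] == fam[j]) within <- c(within, d) else between <- c(between, d)
  }
  expect_lt(mean(within), mean(between))
})

test_that("calcium traces follow the planted kernel", {
  cfgZero <- simulationConfig(seed = 2, calcium = list(noiseSd = 0,
                                                       amplitude = 0))
  tr <- makeCalciumDataset(cfgZero)[[1]]
  expect_true(all(tr@values == tr@values[1]))
  cfgClean <- simulationConfig(seed = 2, calcium = list(noiseSd = 0))
  tr2 <- makeCalciumDataset(cfgClean)[[1]]
  tGrid <- (seq_along(tr2@values) - 1) * tr2@samplePeriod
  expect_identical(which.max(tr2@values),
                   which(tGrid >= tr2@stimulusOnset)[1])
  # Monte-Carlo amplitude recovery: fitted peak ~ planted amplitude;
  # estimator noise SD is sigma * sqrt(1 + 1/nBaselineSamples)
  sigma <- 1.5
  cfgMC <- simulationConfig(seed = 3, calcium = list(noiseSd = sigma,
                                                     nTraces = 200L))
  peaks <- vapply(makeCalciumDataset(cfgMC), function(t) {
    s <- dff(t)
    s$dff[s$onsetSample] * s$F0
  }, numeric(1))
  expect_lt(abs(mean(peaks) - 50),
            3 * sigma * sqrt(1 + 1 / 16) / sqrt(200))
  expect_error(simulationConfig(calcium = list(samplePeriod = 0)),
               "positive")
})

test_that("behavior counts are reciprocal-paired binomials", {
  cfg <- simulationConfig(seed = 4, behavior = list(p = 1, nPairs = 5L))
  bd <- makeBehaviorDataset(cfg)
  expect_true(all(bd$N_CS_minus == 0))
  expect_true(all(table(bd$pair_id) == 2))
  expect_true(all(tapply(bd$odor_as_CSplus, bd$pair_id,
                         function(o) length(unique(o))) == 2))
  cfgH <- simulationConfig(seed = 4,
                           behavior = list(p = 0.5, nPairs = 2000L))
  scores <- with(makeBehaviorDataset(cfgH),
                 groupScore(N_CS_plus, N_CS_minus))
  se <- sd(scores) / sqrt(length(scores))
  expect_lt(abs(mean(scores) - 0), 3 * se + 1e-3)
})
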