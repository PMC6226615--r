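straightDotprops <- function(n = 30, step = 1) {
  toDotprops(chainSkeleton(n, step = 5), resampleStep = step)
}

test_that("dotprops tangents recover local geometry", {
  dp <- straightDotprops()
  # straight line: every tangent parallel to x (up to sign)
  expect_true(all(abs(abs(dp@vects[, 1]) - 1) < 1e-9))
  expect_true(all(abs(sqrt(rowSums(dp@vects^2)) - 1) < 1e-6))
  # resampling spacing: consecutive points ~1 um apart along the chain
  d <- sqrt(rowSums(diff(dp@points)^2))
  expect_true(all(abs(d - 1) < 1e-6))
  # L-shaped polyline: corner tangents equal the principal direction of
  # the local k-neighborhood from an independent eigen-decomposition
  nL <- 21L
  nodes <- data.frame(node_id = 1:nL, parent_id = c(NA, 1:(nL - 1)),
                      x = c(seq(0, 10, 1), rep(10, 10)),
                      y = c(rep(0, 11), seq(1, 10, 1)), z = 0, radius = 1)
  dpL <- toDotprops(NeuronSkeleton(nodes, neuronId = "L"), k = 5)
  for (i in seq_len(nrow(dpL@points))) {
    d2 <- colSums((t(dpL@points) - dpL@points[i, ])^2)
    nb <- dpL@points[order(d2)[1:5], ]
    pc <- eigen(cov(nb), symmetric = TRUE)$vectors[, 1]
    expect_gt(abs(sum(pc * dpL@vects[i, ])), 1 - 1e-6)
  }
  # compartment restriction errors when the label is absent
  expect_error(toDotprops(chainSkeleton(5), compartments = "axon"),
               "no nodes")
})

test_that("dotprops restriction strips primary neurite and dendrite", {
  pop <- makeNeuronPopulation(simulationConfig(seed = 6))
  sk <- pop$skeletons[[1]]
  dpAxon <- toDotprops(sk, compartments = "axon")
  nd <- skeletonNodes(sk)
  axonBox <- nd[compartments(sk) == "axon", c("x", "y", "z")]
  pad <- 5
  expect_true(all(dpAxon@points[, 1] > min(axonBox$x) - pad &
                  dpAxon@points[, 1] < max(axonBox$x) + pad))
  expect_gt(nrow(toDotprops(sk)@points), nrow(dpAxon@points))
})

test_that("nblastRaw matches the closed form and the O(n^2) oracle", {
  dp <- straightDotprops()
  n <- nrow(dp@points)
  expect_equal(nblastRaw(dp, dp), n)  # f(0, 1) per point
  # lone pair at distance d with parallel tangents
  mk <- function(x) new("Dotprops",
                        points = rbind(c(x, 0, 0), c(x + 100, 0, 0)),
                        vects = rbind(c(1, 0, 0), c(1, 0, 0)),
                        neuronId = "p", resampleStep = 1)
  d <- 2.5
  s <- nblastRaw(mk(0), mk(d))
  expect_equal(s, exp(-d / 3) + exp(-min(d, 100 - d) / 3))
  # 50-point random pairs vs brute-force all-pairs loop
  set.seed(9)
  for (rep in 1:5) {
    rand <- function() {
      p <- matrix(rnorm(150, sd = 10), 50, 3)
      v <- matrix(rnorm(150), 50, 3)
      v <- v / sqrt(rowSums(v^2))
      new("Dotprops", points = p, vects = v, neuronId = "r",
          resampleStep = 1)
    }
    q <- rand(); t <- rand()
    expect_equal(nblastRaw(q, t), bruteForceNblast(q, t), tolerance = 1e-6)
  }
})

test_that("rigid motions leave raw scores unchanged", {
  set.seed(10)
  pop <- makeNeuronPopulation(simulationConfig(seed = 10))
  d1 <- toDotprops(pop$skeletons[[1]])
  d2 <- toDotprops(pop$skeletons[[2]])
  theta <- 0.7
  R <- rbind(c(cos(theta), -sin(theta), 0),
             c(sin(theta), cos(theta), 0), c(0, 0, 1))
  shift <- c(12, -5, 30)
  rot <- function(dp) new("Dotprops",
                          points = sweep(dp@points %*% t(R), 2, shift, "+"),
                          vects = dp@vects %*% t(R), neuronId = dp@neuronId,
                          resampleStep = dp@resampleStep)
  expect_equal(nblastRaw(rot(d1), rot(d2)), nblastRaw(d1, d2),
               tolerance = 1e-6)
})

test_that("score matrices normalize and symmetrize correctly", {
  pop <- makeNeuronPopulation(simulationConfig(seed = 0))
  dps <- lapply(pop$skeletons[c(1, 2, 6, 7, 11)], toDotprops)
  sm <- scoreMatrix(dps)
  expect_true(all(diag(sm@normalized) == 1))
  expect_equal(sm@mean, t(sm@mean))
  # identical neurons score a mean of 1
  twin <- scoreMatrix(list(dps[[1]],
                           new("Dotprops", points = dps[[1]]@points,
                               vects = dps[[1]]@vects, neuronId = "copy",
                               resampleStep = 1)))
  expect_equal(twin@mean[1, 2], 1)
  # planted families: within-family mean scores exceed between-family
  fam <- pop$truth$family[c(1, 2, 6, 7, 11)]
  sameFam <- outer(fam, fam, "==") & !diag(TRUE, 5)
  expect_gt(min(sm@mean[sameFam]), max(sm@mean[!sameFam & !diag(TRUE, 5)]))
})

test_that("binned log-odds scoring tables apply by bin lookup", {
  f <- file.path(tempdir(), "smat.csv")
  gridDf <- expand.grid(dist_lo = c(0, 5), adp_lo = c(0, 0.5))
  gridDf$dist_hi <- gridDf$dist_lo + 5
  gridDf$adp_hi <- gridDf$adp_lo + 0.5
  gridDf$log_odds <- c(4, -1, 8, 2)  # favors near, aligned points
  write.csv(gridDf, f, row.names = FALSE)
  sc <- readScoringMatrix(f)
  mkPt <- function(p, v) new("Dotprops", points = rbind(p, p + c(0, 0, 50)),
                             vects = rbind(v, v), neuronId = "x",
                             resampleStep = 1)
  q <- mkPt(c(0, 0, 0), c(1, 0, 0))
  t1 <- mkPt(c(1, 0, 0), c(1, 0, 0))  # near, aligned -> bin (1, 2) = 8
  expect_equal(nblastRaw(q, t1, scoring = sc), 8 + 8)
  t2 <- mkPt(c(7, 0, 0), c(0, 1, 0))  # far, orthogonal -> bin (2, 1) = -1
  expect_equal(nblastRaw(q, t2, scoring = sc), -1 - 1)
  unlink(f)
})

test_that("Ward clustering matches brute-force agglomeration and truth", {
  # two duplicates + one distant neuron at k = 2
  m <- matrix(c(1, 0.95, 0.1,
                0.95, 1, 0.12,
                0.1, 0.12, 1), 3, 3, byrow = TRUE)
  m <- (m + t(m)) / 2
  sm <- new("ScoreMatrix", ids = c("a", "b", "c"), raw = m, normalized = m,
            mean = m)
  lab <- clusterTypes(sm, k = 2)
  expect_identical(lab[["a"]], lab[["b"]])
  expect_false(lab[["a"]] == lab[["c"]])
  expect_error(clusterTypes(sm, k = 5), "exceeds")
  # hand-made 4x4 matrix: merge sequence equals direct Ward agglomeration
  m4 <- matrix(c(1.0, 0.9, 0.2, 0.1,
                 0.9, 1.0, 0.25, 0.15,
                 0.2, 0.25, 1.0, 0.6,
                 0.1, 0.15, 0.6, 1.0), 4, 4, byrow = TRUE)
  m4 <- (m4 + t(m4)) / 2
  sm4 <- new("ScoreMatrix", ids = letters[1:4], raw = m4, normalized = m4,
             mean = m4)
  tree <- attr(clusterTypes(sm4, k = 2), "tree")
  expect_identical(hclustMergeSets(tree), bruteForceWardMerges(m4))
  # 3 planted families x 5 neurons recover exactly at k = 3
  pop <- makeNeuronPopulation(simulationConfig(seed = 0))
  dps <- lapply(pop$skeletons, toDotprops)
  labels <- clusterTypes(scoreMatrix(dps), k = 3)
  expect_equal(adjustedRand(labels, pop$truth$family), 1.0)
})

test_that("a calyx-only difference separates in dendrite but not axon scores", {
  # single-EM-volume setting: same stereotyped arbors (shared shape seed),
  # no registration scatter, differing only in the calycal dendritic tuft
  mkFam <- function(cal) list(nNeurons = 4L, nBranches = 6L,
                              branchLen = 18, jitterUm = 0.75,
                              offsetUm = c(0, 0, 0), calyxBranch = cal,
                              shapeSeed = 1L, registrationUm = 0)
  fams <- list(pd2a = mkFam(TRUE), pd2b = mkFam(FALSE))
  pop <- makeNeuronPopulation(simulationConfig(seed = 0, families = fams))
  byComp <- function(compartment) {
    dps <- lapply(pop$skeletons, toDotprops, compartments = compartment)
    clusterTypes(scoreMatrix(dps), k = 2)
  }
  ariDend <- adjustedRand(byComp("dendrite"), pop$truth$family)
  ariAxon <- adjustedRand(byComp("axon"), pop$truth$family)
  expect_equal(ariDend, 1.0)
  expect_lt(ariAxon, 1.0)
})
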