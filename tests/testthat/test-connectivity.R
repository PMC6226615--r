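# hand-built table: target "pd" receives 8 postsynapses in the LH,
# 3 from "A", 1 from "B", 4 from unnamed neurons, plus 2 in the calyx
handTable <- function() {
  conns <- data.frame(connector_id = 1:10, x = 0, y = 0, z = 0,
                      neuropil = c(rep("LH", 8), "CA", "CA"))
  mkPre <- function(cid, who) data.frame(connector_id = cid,
                                         neuron_id = who, node_id = 1L,
                                         role = "pre")
  mkPost <- function(cid, who) data.frame(connector_id = cid,
                                          neuron_id = who, node_id = 2L,
                                          role = "post")
  links <- rbind(
    do.call(rbind, lapply(1:3, mkPre, who = "A")),
    mkPre(4, "B"),
    do.call(rbind, Map(mkPre, 5:8, paste0("u", 5:8))),
    do.call(rbind, lapply(9:10, mkPre, who = "A")),
    do.call(rbind, lapply(1:10, mkPost, who = "pd")))
  ConnectorTable(conns, links)
}

test_that("partner counts give fractions of the target's links in the region", {
  pb <- partnerCounts(handTable(), "pd", "incoming", neuropil = "LH")
  expect_equal(pb$fraction[pb$partner == "A"], 3 / 8)
  expect_equal(pb$fraction[pb$partner == "B"], 1 / 8)
  expect_equal(sum(pb$fraction), 1)
  expect_equal(sum(pb$count), 8)
  # category mapping leaves the remainder in other/undefined
  cats <- c(A = "MBON", B = "uniglomerular_PN")
  pbc <- partnerCounts(handTable(), "pd", "incoming", neuropil = "LH",
                       categories = cats)
  expect_equal(pbc$fraction[pbc$partner == "other/undefined"], 0.5)
  expect_error(partnerCounts(handTable(), "pd", neuropil = "AL"),
               "unknown neuropil")
  expect_error(partnerCounts(handTable(), "nobody"), "not present")
  # single partner supplying everything: fraction 1
  solo <- handTable()
  lk <- connectorLinks(solo)
  lk$neuron_id[lk$role == "pre"] <- "A"
  solo2 <- ConnectorTable(connectors(solo), lk)
  pb1 <- partnerCounts(solo2, "pd", "incoming", neuropil = "LH")
  expect_equal(pb1$fraction, 1)
})

test_that("conservation: incoming counts sum to the target's postsynapses", {
  pop <- makeNeuronPopulation(simulationConfig(seed = 8))
  tb <- pop$connectors
  lk <- connectorLinks(tb)
  tgt <- neuronId(pop$skeletons[[1]])
  pb <- partnerCounts(tb, tgt, "incoming", neuropil = "LH")
  expect_equal(sum(pb$count),
               sum(lk$neuron_id == tgt & lk$role == "post"))
  expect_equal(sum(pb$fraction), 1, tolerance = 1e-12)
})

test_that("polyadic fan-out statistics use the sample SD", {
  # fan-outs 2, 3, 4 -> mean 3, sd 1
  conns <- data.frame(connector_id = 1:3, x = 0, y = 0, z = 0,
                      neuropil = "LH")
  links <- rbind(
    data.frame(connector_id = 1:3, neuron_id = "m", node_id = 1L,
               role = "pre"),
    data.frame(connector_id = rep(1:3, times = 2:4), neuron_id = "t",
               node_id = 1L, role = "post"))
  st <- polyadicStats(ConnectorTable(conns, links), "m")
  expect_equal(st$mean, 3)
  expect_equal(st$sd, 1)
  expect_equal(st$n, 3)
  # all monadic: mean 1, sd 0
  links1 <- links[links$connector_id == 1 |
                    (links$role == "post" & !duplicated(links$connector_id,
                                                        fromLast = FALSE)), ]
  mono <- ConnectorTable(conns[1, ],
                         rbind(data.frame(connector_id = 1, neuron_id = "m",
                                          node_id = 1L, role = "pre"),
                               data.frame(connector_id = 1, neuron_id = "t",
                                          node_id = 1L, role = "post")))
  stm <- polyadicStats(mono, "m")
  expect_equal(stm$mean, 1)
  expect_equal(stm$sd, NA_real_)
  expect_error(polyadicStats(mono, "t"), "no presynapses")
  # mean x count equals the total post links (conservation)
  pop <- makeNeuronPopulation(simulationConfig(seed = 9))
  tb <- pop$connectors
  id1 <- neuronId(pop$skeletons[[1]])
  st1 <- polyadicStats(tb, id1)
  lk <- connectorLinks(tb)
  myConn <- lk$connector_id[lk$neuron_id == id1 & lk$role == "pre"]
  expect_equal(st1$mean * st1$n,
               sum(lk$role == "post" & lk$connector_id %in% myConn))
  # generator fan-out recovery: 1 + Poisson(6.8) -> mean near 7.8
  allFan <- unlist(lapply(pop$skeletons, function(s)
    polyadicStats(tb, neuronId(s))$fanouts))
  expect_lt(abs(mean(allFan) - 7.8), 3 * sd(allFan) / sqrt(length(allFan)))
})

test_that("excitatory share bounds bracket the focal input", {
  b <- excitatoryShareBounds(c(uniglomerular_PN = 26.5, MBON = 4.6,
                               `other/undefined` = 15.6), "MBON")
  expect_equal(unname(b["lower"]), 9.850107, tolerance = 1e-6)
  expect_equal(unname(b["upper"]), 14.790997, tolerance = 1e-6)
  # no undefined input: bounds coincide
  b0 <- excitatoryShareBounds(c(uniglomerular_PN = 26.5, MBON = 4.6),
                              "MBON")
  expect_equal(unname(b0["lower"]), unname(b0["upper"]))
  # absent focal category: (0, 0)
  expect_equal(unname(excitatoryShareBounds(
    c(uniglomerular_PN = 26.5, `other/undefined` = 5), "MBON")),
    c(0, 0))
  # focal set but no known-excitatory mass in the denominator
  expect_error(excitatoryShareBounds(c(`other/undefined` = 5,
                                       LH_local = 1), "LH_local"),
               "excitatory")
})

test_that("heatmap matrices normalize per target and neuropil", {
  tb <- handTable()
  groups <- c(A = "DA1", B = "DC3", u5 = "DA1")
  hm <- connectivityHeatmap(tb, targets = "pd", groupBy = groups,
                            neuropils = c("LH", "CA"))
  # LH: 8 postsynapses; DA1 gets A(3) + u5(1) = 4, DC3 gets 1
  expect_equal(hm$counts["DA1", "pd|LH"], 4L)
  expect_equal(hm$normalized["DA1", "pd|LH"], 4 / 8)
  expect_equal(hm$normalized["DC3", "pd|LH"], 1 / 8)
  # CA: 2 postsynapses, both from A -> denominators differ per neuropil
  expect_equal(hm$normalized["DA1", "pd|CA"], 2 / 2)
  # column order: descending total count
  expect_identical(colnames(hm$counts),
                   names(sort(colSums(hm$counts), decreasing = TRUE)))
  # groups with no connectivity are dropped
  groups2 <- c(groups, zz = "VA6")
  hm2 <- connectivityHeatmap(tb, "pd", groups2, c("LH", "CA"))
  expect_false("VA6" %in% rownames(hm2$counts))
})
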