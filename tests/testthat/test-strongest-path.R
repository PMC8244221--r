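test_that("dual weight is the negated log of the penalized confidence", {
  expect_equal(dualWeight(1, 1), 0)
  expect_equal(dualWeight(1, 0.95), -log(0.95))
  expect_equal(dualWeight(0.5, 0.95), -(log(0.95) + log(0.5)))
  expect_equal(dualWeight(c(1, 0.5), 0.95),
               c(-log(0.95), -(log(0.95) + log(0.5))))
  expect_error(dualWeight(0, 0.95), class = "spInputError")
  expect_error(dualWeight(1.2, 0.95), class = "spInputError")
  expect_error(dualWeight(0.5, 0), class = "spInputError")
  expect_error(dualWeight(0.5, 1.1), class = "spInputError")
})

test_that("the length penalty arbitrates between short weak and long strong paths", {
  # two-hop 0.9*0.9 beats direct 0.7: 0.81 * 0.95^2 = 0.731025 > 0.665
  net <- makeNet(c("A", "B", "A"), c("B", "C", "C"), c(0.9, 0.9, 0.7),
                 directed = TRUE)
  res <- strongestPath(net, "A", "C")
  expect_true(pathFound(res))
  expect_equal(pathNodes(res), c("A", "B", "C"))
  expect_equal(res@product, 0.81)
  expect_equal(res@penalizedScore, 0.81 * 0.95^2)
  expect_equal(res@penalizedScore, 0.731025)

  # raising the direct edge to 0.78 flips the winner: 0.78 * 0.95 = 0.741
  net2 <- makeNet(c("A", "B", "A"), c("B", "C", "C"), c(0.9, 0.9, 0.78),
                  directed = TRUE)
  res2 <- strongestPath(net2, "A", "C")
  expect_equal(pathNodes(res2), c("A", "C"))
  expect_equal(res2@penalizedScore, 0.741)
})

test_that("input validation: disjointness, emptiness, damping range", {
  net <- makeNet("A", "B", 0.9)
  expect_error(strongestPath(net, "A", "A"), class = "spInputError")
  expect_error(strongestPath(net, character(), "B"), class = "spInputError")
  expect_error(strongestPath(net, "A", "B", damping = 0), class = "spInputError")
  expect_error(strongestPath(net, "A", "B", damping = 1.5),
               class = "spInputError")
  expect_error(epsilonSubnetwork(net, "A", "B", epsilon = -1),
               class = "spInputError")
})

test_that("disconnected source/target sets yield a first-class no-path result", {
  net <- makeNet(c("A", "C"), c("B", "D"), c(0.9, 0.9), directed = TRUE)
  res <- strongestPath(net, "A", "D")
  expect_false(pathFound(res))
  expect_equal(pathNodes(res), character())
  sub <- epsilonSubnetwork(net, "A", "D", epsilon = 1)
  expect_false(pathFound(sub))
  expect_equal(nodeLabels(sub), character())
})

test_that("dual length and penalized score stay log-consistent", {
  for (s in 1:20) {
    cfg <- sweepSetup(s)
    if (!length(cfg$targets)) next
    res <- strongestPath(cfg$net, cfg$sources, cfg$targets, damping = cfg$d)
    if (!pathFound(res)) next
    expect_lt(abs(res@dualLength + log(res@penalizedScore)), 1e-9)
    expect_equal(res@edgeCount, length(pathNodes(res)) - 1L)
    expect_false(anyDuplicated(pathNodes(res)) > 0)
  }
})

test_that("equal-score ties resolve to fewer edges, then lexicographic labels", {
  # two identical-score two-hop routes: B1 vs B2 -> B1 by label order
  net <- makeNet(c("A", "B1", "A", "B2"), c("B1", "C", "B2", "C"),
                 c(0.8, 0.8, 0.8, 0.8), directed = TRUE)
  expect_equal(pathNodes(strongestPath(net, "A", "C")), c("A", "B1", "C"))

  # with all confidences 1 and D = 1 every path ties; fewest edges wins
  net2 <- makeNet(c("A", "A", "M"), c("C", "M", "C"), c(1, 1, 1),
                  directed = TRUE)
  res <- strongestPath(net2, "A", "C", damping = 1)
  expect_equal(pathNodes(res), c("A", "C"))
})

test_that("multi-source/multi-sink queries take the best pair", {
  net <- makeNet(c("a1", "a2", "x"), c("x", "x", "b1"), c(0.5, 0.9, 0.9),
                 directed = TRUE)
  res <- strongestPath(net, c("a1", "a2"), "b1")
  expect_equal(pathNodes(res), c("a2", "x", "b1"))
  expect_equal(res@product, 0.81)
})

test_that("epsilon subnetwork widens monotonically around the optimal path", {
  # diamond: A->X->B at 0.9/0.9 (dual 0.313310), A->Y->B at 0.8/0.8 (0.548874)
  net <- makeNet(c("A", "X", "A", "Y"), c("X", "B", "Y", "B"),
                 c(0.9, 0.9, 0.8, 0.8), directed = TRUE)
  wX <- 2 * -(log(0.95) + log(0.9))
  wY <- 2 * -(log(0.95) + log(0.8))
  s1 <- epsilonSubnetwork(net, "A", "B", epsilon = 0.1)
  expect_setequal(nodeLabels(s1), c("A", "X", "B"))
  expect_equal(s1@wStar, wX)
  s2 <- epsilonSubnetwork(net, "A", "B", epsilon = 0.3)
  expect_setequal(nodeLabels(s2), c("A", "X", "Y", "B"))
  expect_true(wY - wX < 0.3)  # the widening is exactly the Y-route slack
  # epsilon = 0 retains exactly the optimal-path nodes
  s0 <- epsilonSubnetwork(net, "A", "B", epsilon = 0)
  expect_setequal(nodeLabels(s0), c("A", "X", "B"))
  expect_true(all(nodeLabels(s0) %in% nodeLabels(s1)))
})

test_that("sparse mode drops edges that lie on no epsilon-suboptimal path", {
  # diamond plus a cross edge X->Y: at eps = 0.25 node Y still qualifies
  # (a+b = 0.5489 <= w* + eps = 0.5633) but the best path through X->Y
  # costs 0.5877 > w* + eps, so sparse mode must drop that edge
  net <- makeNet(c("A", "X", "A", "Y", "X"), c("X", "B", "Y", "B", "Y"),
                 c(0.9, 0.9, 0.8, 0.8, 0.9), directed = TRUE)
  dense <- epsilonSubnetwork(net, "A", "B", epsilon = 0.25, sparse = FALSE)
  sparse <- epsilonSubnetwork(net, "A", "B", epsilon = 0.25, sparse = TRUE)
  eKey <- function(x) paste(edgeTable(x)$source, edgeTable(x)$target)
  expect_true("X Y" %in% eKey(dense))
  expect_false("X Y" %in% eKey(sparse))
  expect_true(all(eKey(sparse) %in% eKey(dense)))
  expect_equal(nodeLabels(sparse), nodeLabels(dense))
})

test_that("layers report BFS hop distance from the source set", {
  net <- makeNet(c("A", "X", "A", "Y"), c("X", "B", "Y", "B"),
                 c(0.9, 0.9, 0.8, 0.8), directed = TRUE)
  sub <- epsilonSubnetwork(net, "A", "B", epsilon = 1)
  expect_equal(unname(sub@layers[c("A", "X", "Y", "B")]), c(0L, 1L, 1L, 2L))
})

test_that("forward/backward distances match the exhaustive relaxation oracle", {
  for (s in c(3, 17, 42, 101, 202)) {
    cfg <- sweepSetup(s)
    if (!length(cfg$targets)) next
    sub <- epsilonSubnetwork(cfg$net, cfg$sources, cfg$targets,
                             damping = cfg$d, epsilon = 0.5)
    if (!pathFound(sub)) next
    orc <- fwDualOracle(cfg$net, cfg$sources, cfg$targets, cfg$d)
    expect_equal(sub@wStar, orc$wStar, tolerance = 1e-9)
    labs <- nodeLabels(sub)
    expect_equal(unname(sub@a[labs]), unname(orc$a[labs]), tolerance = 1e-9)
    expect_equal(unname(sub@b[labs]), unname(orc$b[labs]), tolerance = 1e-9)
  }
})
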