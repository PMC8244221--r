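test_that("network parsing interns nodes, merges duplicates and validates scores", {
  f <- writeNetFile(c("A", "B"), c("B", "C"), c(0.9, 0.8))
  net <- readNetwork(f)
  expect_equal(nNodes(net), 3L)
  expect_equal(nrow(edgeTable(net)), 2L)
  expect_false(isDirected(net))

  # duplicate edges keep the maximum confidence, in either orientation
  f2 <- writeNetFile(c("A", "A", "B"), c("B", "B", "A"), c(0.5, 0.7, 0.6))
  net2 <- readNetwork(f2)
  expect_equal(nrow(edgeTable(net2)), 1L)
  expect_equal(edgeTable(net2)$p, 0.7)
  # directed: (A,B) and (B,A) are distinct
  net2d <- readNetwork(f2, directed = TRUE)
  expect_equal(nrow(edgeTable(net2d)), 2L)
  expect_equal(sort(edgeTable(net2d)$p), c(0.6, 0.7))

  err <- expect_error(readNetwork(writeNetFile("A", "B", 1.5)),
                      class = "spFormatError")
  expect_match(conditionMessage(err), "line 1")
  expect_error(readNetwork(writeNetFile("A", "B", 0)), class = "spFormatError")
  f3 <- tempfile(); writeLines("A\tB", f3)
  expect_error(readNetwork(f3), class = "spFormatError")
})

test_that("self-loops are dropped and scoreDivisor rescales before validation", {
  f <- writeNetFile(c("A", "B"), c("A", "C"), c(0.9, 0.8))
  expect_message(net <- readNetwork(f), "self-loop")
  expect_equal(nrow(edgeTable(net)), 1L)

  f2 <- writeNetFile(c("A", "B"), c("B", "C"), c(900, 850))
  net2 <- readNetwork(f2, scoreDivisor = 1000)
  expect_equal(sort(edgeTable(net2)$p), c(0.85, 0.9))
  expect_error(readNetwork(f2), class = "spFormatError")
})

test_that("annotation-backed parsing resolves endpoints and rejects ambiguity", {
  af <- tempfile(); writeLines(c("TP53\tp53", "MDM2\tQ00987", "EGFR"), af)
  tab <- readAnnotation(af)
  f <- writeNetFile(c("p53"), c("Q00987"), 0.9)
  net <- readNetwork(f, annotation = tab)
  expect_equal(nNodes(net), 3L)  # spans all annotated nodes, incl. isolated
  expect_equal(edgeTable(net)$source, "TP53")
  expect_equal(edgeTable(net)$target, "MDM2")

  expect_error(readNetwork(writeNetFile("nope", "TP53", 0.5), annotation = tab),
               class = "spInputError")
  af2 <- tempfile(); writeLines(c("G1\tshared", "G2\tshared"), af2)
  expect_error(readNetwork(writeNetFile("shared", "G1", 0.5),
                           annotation = readAnnotation(af2)),
               class = "spInputError")
})

test_that("induced subgraph keeps exactly inner edges and is idempotent", {
  net <- makeNet(c("A", "B", "C"), c("B", "C", "A"), c(0.9, 0.9, 0.9))
  sub <- inducedSubgraph(net, c("A", "B"))
  expect_equal(nodeLabels(sub), c("A", "B"))
  expect_equal(nrow(edgeTable(sub)), 1L)
  expect_equal(edgeTable(sub)$p, 0.9)

  all <- inducedSubgraph(net, nodeLabels(net))
  expect_equal(edgeTable(all), edgeTable(net))

  solo <- inducedSubgraph(net, "A")
  expect_equal(nodeLabels(solo), "A")
  expect_equal(nrow(edgeTable(solo)), 0L)

  twice <- inducedSubgraph(sub, c("A", "B"))
  expect_equal(edgeTable(twice), edgeTable(sub))
  expect_error(inducedSubgraph(net, "Z"), class = "spInputError")
})

test_that("tsv write/parse round-trips node, edge and weight sets", {
  net <- makeNet(c("A", "B", "C"), c("B", "C", "D"), c(0.9, 0.25, 0.6180339887))
  out <- tempfile(fileext = ".tsv")
  writeNetwork(net, out, "tsv")
  back <- readNetwork(out)
  expect_setequal(nodeLabels(back), nodeLabels(net))
  key <- function(n) {
    e <- edgeTable(n)
    sort(sprintf("%s|%s|%.12g", pmin(e$source, e$target),
                 pmax(e$source, e$target), e$p))
  }
  expect_equal(key(back), key(net))

  empty <- makeNet(character(), character(), numeric(), labels = "A")
  writeNetwork(empty, out, "tsv")
  expect_equal(length(readLines(out)), 0L)
})

test_that("sif export writes pp interaction lines plus an attribute sidecar", {
  net <- makeNet("A", "B", 0.9)
  out <- tempfile(fileext = ".sif")
  writeNetwork(net, out, "sif")
  expect_equal(readLines(out), "A pp B")
  attrs <- readLines(paste0(out, ".attrs.tsv"))
  expect_match(attrs[2], "^A\tpp\tB\t0\\.9$")
})
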