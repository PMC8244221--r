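signedFile <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}

test_that("TRRUST-dialect parsing maps modes to signs case-insensitively", {
  net <- readSignedNetwork(signedFile(c("TP53\tCDK1\tRepression",
                                        "TP53\tPGF\tActivation")))
  e <- edgeTable(net)
  expect_equal(nrow(e), 2L)
  expect_equal(e$sign[e$target == "CDK1"], -1L)
  expect_equal(e$sign[e$target == "PGF"], 1L)

  expect_message(net2 <- readSignedNetwork(signedFile(c("A\tB\tUnknown",
                                                        "A\tC\tactivation"))),
                 "unknown")
  expect_equal(nrow(edgeTable(net2)), 1L)

  err <- expect_error(readSignedNetwork(signedFile("A\tB\tSometimes")),
                      class = "spFormatError")
  expect_match(conditionMessage(err), "line 1")
})

test_that("unknown-mode edges follow the requested policy", {
  f <- signedFile(c("A\tB\tUnknown"))
  pos <- readSignedNetwork(f, unknownPolicy = "positive")
  expect_equal(edgeTable(pos)$sign, 1L)
  both <- readSignedNetwork(f, unknownPolicy = "both")
  expect_setequal(edgeTable(both)$sign, c(-1L, 1L))
})

test_that("conflicting-sign parallel edges are kept distinct, duplicates merged", {
  net <- readSignedNetwork(signedFile(c("A\tB\tActivation", "A\tB\tRepression",
                                        "A\tB\tActivation")))
  expect_equal(nrow(edgeTable(net)), 2L)
  expect_setequal(edgeTable(net)$sign, c(-1L, 1L))
})

test_that("sign product classifies paths; reversal and concatenation behave", {
  expect_equal(classifyPath(c(1, 1)), "activating")
  expect_equal(classifyPath(c(1, -1)), "inhibitory")
  expect_equal(classifyPath(c(-1, -1)), "activating")  # double repression
  expect_error(classifyPath(integer()), class = "spInputError")
  expect_error(classifyPath(c(1, 0)), class = "spInputError")
  for (s in 1:10) {
    signs <- ifelse(withr::with_seed(s, runif(5)) < 0.5, -1, 1)
    expect_equal(classifyPath(signs), classifyPath(rev(signs)))
    other <- c(1, -1, -1)
    expect_equal(classifyPath(c(signs, other)) == "activating",
                 classifyPath(signs) == classifyPath(other))
  }
})

test_that("hop-minimal paths are found per pair and filtered by mode", {
  net <- readSignedNetwork(signedFile(c("TF1\tg1\tActivation",
                                        "g1\tg2\tRepression")))
  res <- regulatoryPaths(net, "TF1", "g2")
  expect_equal(nrow(res), 1L)
  expect_equal(res$mode, "inhibitory")
  expect_equal(res$length, 2L)
  expect_equal(res$nodes[[1]], c("TF1", "g1", "g2"))
  expect_equal(nrow(regulatoryPaths(net, "TF1", "g2",
                                    modeFilter = "activating")), 0L)

  # a direct edge beats any two-hop alternative
  net2 <- readSignedNetwork(signedFile(c("s\tt\tActivation",
                                         "s\tm\tActivation",
                                         "m\tt\tActivation")))
  res2 <- regulatoryPaths(net2, "s", "t")
  expect_equal(nrow(res2), 1L)
  expect_equal(res2$length, 1L)

  # two minimal paths with opposite modes are both reported
  net3 <- readSignedNetwork(signedFile(c("s\tx\tActivation",
                                         "x\tt\tActivation",
                                         "s\ty\tActivation",
                                         "y\tt\tRepression")))
  res3 <- regulatoryPaths(net3, "s", "t")
  expect_equal(nrow(res3), 2L)
  expect_setequal(res3$mode, c("activating", "inhibitory"))
})

test_that("unreachable pairs are reported aside and self-pairs are skipped", {
  net <- readSignedNetwork(signedFile(c("a\tb\tActivation",
                                        "c\td\tRepression")))
  res <- regulatoryPaths(net, c("a", "b"), c("b", "d"))
  np <- attr(res, "noPath")
  expect_true(all(res$length >= 1L))
  expect_false(any(res$source == res$target))
  expect_true(nrow(np) >= 1L)
  expect_true(any(np$source == "a" & np$target == "d"))
})

test_that("returned path sets match exhaustive enumeration on random networks", {
  for (s in c(2, 9, 31, 64)) {
    net <- randomSignedNetwork(7, 0.3, inhibitoryFraction = 0.4, seed = s)
    labs <- nodeLabels(net)
    res <- regulatoryPaths(net, labs[1], labs[6:7])
    for (t in labs[6:7]) {
      got <- res[res$target == t, , drop = FALSE]
      gotKeys <- sort(vapply(seq_len(nrow(got)), function(i)
        paste(paste(got$nodes[[i]], collapse = ","),
              paste(got$signs[[i]], collapse = ","), sep = "|"), character(1)))
      expect_equal(gotKeys, signedOracle(net, labs[1], t))
    }
  }
})
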