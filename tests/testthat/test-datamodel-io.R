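test_that("expression files parse into validated containers", {
  f <- withr::local_tempfile(fileext = ".tsv")
  m <- matrix(round(rexp(15), 3), 3, 5,
              dimnames = list(c("gA", "gB", "gC"), paste0("t", 0:4)))
  write.table(data.frame(gene = rownames(m), m), f, sep = "\t",
              quote = FALSE, row.names = FALSE)
  tse <- readExpression(f, times = 0:4)
  expect_s4_class(tse, "TimeSeriesExperiment")
  expect_equal(dim(tse), c(3L, 5L))
  expect_equal(timePoints(tse), 0:4)
  expect_equal(nReplicates(tse), 1L)
  expect_equal(unname(exprsMatrix(tse)), unname(m))
  # the column -> (time, replicate) mapping is recorded and reversible
  mp <- S4Vectors::metadata(tse)$columnMapping
  expect_equal(mp$time, rep(0:4, each = 1))
  expect_equal(mp$column, paste0("t", 0:4))
})

test_that("a 17-point series at 10-unit spacing yields a 17-point grid", {
  f <- withr::local_tempfile(fileext = ".tsv")
  times <- seq(0, 160, by = 10)
  m <- matrix(rexp(34), 2, 17, dimnames = list(c("g1", "g2"), NULL))
  write.table(data.frame(gene = rownames(m), m), f, sep = "\t",
              quote = FALSE, row.names = FALSE)
  tse <- readExpression(f, times = times)
  expect_length(timePoints(tse), 17L)
  expect_equal(diff(timePoints(tse)), rep(10, 16))
})

test_that("malformed expression input fails with informative errors", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tc1\tc2", "gX\t1\t2", "gX\t3\t4"), f)
  expect_error(readExpression(f, times = 0:1), "gX")

  writeLines(c("gene\tc1\tc2", "gA\t1\toops", "gB\t3\t4"), f)
  expect_error(readExpression(f, times = 0:1), "gA")

  writeLines(c("gene\tc1\tc2", "gA\t1\t2"), f)
  expect_error(readExpression(f, times = 0:2, nRep = 2), "mismatch")
})

test_that("missing markers are read as NA and replicate layouts map columns", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("gene,a,b,c,d", "g1,1,NA,3,4", "g2,5,6,7,8"), f)
  tse <- readExpression(f, times = c(0, 10), nRep = 2)
  expect_true(is.na(exprsMatrix(tse)["g1", 2]))
  cd <- SummarizedExperiment::colData(tse)
  expect_equal(cd$time, c(0, 0, 10, 10))
  expect_equal(cd$replicate, c(1L, 2L, 1L, 2L))
})

test_that("GMT parsing honours the dialect", {
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines("sce04111\tcell cycle\tCDC6\tMCM2", f)
  sets <- readGMT(f)
  expect_length(sets, 1L)
  expect_setequal(sets$sce04111, c("CDC6", "MCM2"))
  expect_equal(attr(sets, "description")[["sce04111"]], "cell cycle")

  writeLines(character(), f)
  expect_length(readGMT(f), 0L)

  # sets may share genes; blank lines are skipped
  writeLines(c("p1\td1\tA\tB", "", "p2\td2\tB\tC", "p3\td3\tC"), f)
  sets <- readGMT(f)
  expect_length(sets, 3L)
  expect_true("B" %in% sets$p1 && "B" %in% sets$p2)

  writeLines(c("p1\td1\tA", "p2\tonlytwo"), f)
  expect_error(readGMT(f), "line 2")
})

test_that("network JSON round-trips losslessly", {
  sim <- simulateTimeSeries(simulationSpec(
    kTrue = 3, genesPerCluster = 8, times = 0:7, family = "impulse",
    shifts = c(0, 2, 4), noiseSd = 0.1, seed = 11,
    pathways = list(list(id = "pwA", fractions = c(.5, .5, 0),
                         size = 12))))
  net <- buildClusterNetwork(sim$tse, sim$labels, seed = 11)
  f <- withr::local_tempfile(fileext = ".json")
  writeNetwork(net, f, format = "json")
  back <- readNetwork(f)
  expect_equal(clusterOrder(back), clusterOrder(net))
  expect_length(networkNodes(back), 3L)
  expect_length(networkEdges(back), 2L)
  for (i in seq_along(networkNodes(net))) {
    expect_equal(networkNodes(back)[[i]]$mean,
                 networkNodes(net)[[i]]$mean, tolerance = 1e-12)
    expect_setequal(networkNodes(back)[[i]]$genes,
                    networkNodes(net)[[i]]$genes)
  }
})

test_that("annotated edges and degenerate networks serialize", {
  fit <- fitClusterGP(rbind(sin(0:4), sin(0:4) + 0.01), 0:4, seed = 1)
  labels <- setNames(rep(1L, 3), c("a", "b", "c"))
  net1 <- buildNetwork(labels, list(`1` = fit), order = "1")
  expect_length(networkEdges(net1), 0L)
  f <- withr::local_tempfile(fileext = ".json")
  writeNetwork(net1, f)
  expect_length(networkNodes(readNetwork(f)), 1L)

  labels2 <- setNames(c(1L, 1L, 2L), c("a", "b", "c"))
  ann <- data.frame(pathway = "pwX", tailFrom = 0.3, tailTo = 0.2,
                    tailUnion = 0.01)
  net2 <- buildNetwork(labels2, list(`1` = fit, `2` = fit),
                       order = c("2", "1"), annotations = list(ann))
  writeNetwork(net2, f)
  back <- readNetwork(f)
  expect_equal(networkEdges(back)[[1]]$annotations$pathway, "pwX")
  expect_equal(networkEdges(back)[[1]]$annotations$tailUnion, 0.01)
  expect_equal(networkEdges(back)[[1]]$from, "2")

  expect_error(writeNetwork(net2, f, format = "xml"))
  # graph formats export without error
  f2 <- withr::local_tempfile(fileext = ".graphml")
  expect_no_error(writeNetwork(net2, f2, format = "graphml"))
  f3 <- withr::local_tempfile(fileext = ".dot")
  expect_no_error(writeNetwork(net2, f3, format = "dot"))
})

test_that("simulate -> cluster -> network -> evaluate compose through files", {
  dir <- withr::local_tempdir()
  sim <- simulateTimeSeries(scrnaLikeSpec(
    seed = 5, genesPerCluster = rep(15L, 3), noiseSd = 0.15))
  fx <- file.path(dir, "expr.tsv")
  writeExpression(sim$tse, fx)
  tse <- readExpression(fx, times = timePoints(sim$tse))
  expect_equal(exprsMatrix(tse), exprsMatrix(sim$tse), tolerance = 1e-12)

  scan <- gapScan(tse, kRange = c(1, 4), B = 4, mode = "gp", seed = 5)
  lab <- clusterLabels(scan)
  net <- buildClusterNetwork(tse, lab, seed = 5)
  fn <- file.path(dir, "net.json")
  writeNetwork(net, fn)
  back <- readNetwork(fn)
  genes <- unlist(lapply(networkNodes(back), `[[`, "genes"))
  expect_setequal(genes, rownames(tse))
  expect_gte(pairF1(sim$labels, lab[names(sim$labels)]), 0.9)
})
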