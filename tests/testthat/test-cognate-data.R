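table1 <- function() {
  readCognateMatrix(system.file("extdata", "table1_slavic.csv",
                                package = "lexcal"))
}

test_that("the bundled Slavic worked example parses to the printed matrix", {
  m <- table1()
  expect_equal(dim(m@values), c(5L, 5L))
  expect_equal(rownames(m@values),
               c("Slovene", "Polish", "Czech", "Ukrainian", "Rusyn"))
  sizes <- table(m@partition)
  expect_equal(unname(sizes[["two"]]), 1L)
  expect_equal(unname(sizes[["belly"]]), 4L)
  # the numeral is cognate in every language
  expect_equal(unname(m@values[, "dwo"]), rep(1L, 5))
})

test_that("matrices round-trip through both dialects", {
  set.seed(5)
  tt <- simulateYuleTree(0.5, 6)
  ck <- clockModel(0.1, 0.3, rBranchRates(10, 0.3))
  m <- simulateMatrix(tt, ck, covarionParams(0.5, 1, c(0.4, 0.6)),
                      partitionRates(c(1.4, 0.6)), 30)
  for (fmt in c("csv", "nexus")) {
    path <- tempfile(fileext = paste0(".", if (fmt == "csv") "csv" else "nex"))
    writeCognateMatrix(m, path, fmt)
    m2 <- readCognateMatrix(path)
    expect_equal(unname(m2@values), unname(m@values))
    expect_equal(m2@partition, m@partition)
    expect_equal(rownames(m2@values), rownames(m@values))
  }
})

test_that("malformed inputs are rejected", {
  p <- tempfile(fileext = ".csv")
  writeLines(c("language,meaning,cognate_id,value", "A,two,c1,2"), p)
  expect_error(readCognateMatrix(p), "non-binary")
  writeLines("language,meaning,cognate_id,value", p)
  expect_error(readCognateMatrix(p), "empty meaning")
  writeLines(c("language,meaning,cognate_id,value",
               "A,two,c1,1", "A,belly,c1,0"), p)
  expect_error(readCognateMatrix(p), "more than one meaning")
  nx <- tempfile(fileext = ".nex")
  writeLines(c("#NEXUS", "BEGIN DATA;", "MATRIX", "A 01", "A 10", ";",
               "END;", "BEGIN SETS;", "CHARSET two = 1 2;", "END;"), nx)
  expect_error(readCognateMatrix(nx), "duplicate")
})

test_that("missing data is representable on disk but refused by the likelihood", {
  v <- matrix(c(1L, NA, 0L, 1L), 2, 2, dimnames = list(c("A", "B"), NULL))
  m <- cognateMatrix(v, c("x", "x"))
  path <- tempfile(fileext = ".csv")
  writeCognateMatrix(m, path)
  m2 <- readCognateMatrix(path)
  expect_true(is.na(m2@values[2, 1]))
  tt <- simulateYuleTree(1, 2, seed = 1)
  ck <- clockModel(0.1, 0, c(1, 1))
  expect_error(
    correctedPartitionLogLik(m2@values, tt, ck, covarionParams(0.5, 1),
                             correction = FALSE),
    "missing")
})

test_that("ascertainment filter removes all-absent columns and counts them", {
  v <- cbind(matrix(1L, 4, 9), 0L)
  rownames(v) <- paste0("L", 1:4)
  m <- cognateMatrix(v, rep(c("a", "b"), each = 5))
  out <- applyAscertainmentFilter(m)
  expect_equal(ncol(out$matrix@values), 9L)
  expect_equal(unname(out$removed), c(0L, 1L))
  expect_true(out$matrix@ascertained)
  # Table 1 has no all-absent columns: filtering is a no-op
  t1 <- applyAscertainmentFilter(table1())
  expect_equal(ncol(t1$matrix@values), 5L)
  expect_equal(sum(t1$removed), 0L)
  # a meaning emptied by the filter signals a degenerate simulation
  v2 <- cbind(matrix(1L, 4, 2), matrix(0L, 4, 2))
  rownames(v2) <- paste0("L", 1:4)
  m2 <- cognateMatrix(v2, rep(c("a", "b"), each = 2))
  expect_error(applyAscertainmentFilter(m2), "zero columns")
  expect_equal(unique(applyAscertainmentFilter(m2, onEmpty = "drop")$matrix@partition),
               "a")
})

test_that("filtered per-meaning column counts equal k_i minus removals", {
  set.seed(6)
  tt <- simulateYuleTree(0.4, 5)
  ck <- clockModel(0.05, 0.3, rBranchRates(8, 0.3))
  m <- simulateMatrix(tt, ck, covarionParams(0.3, 1, c(0.85, 0.15)),
                      partitionRates(c(1.5, 0.5)), 300)
  out <- applyAscertainmentFilter(m)
  for (mm in unique(m@partition)) {
    expect_equal(sum(out$matrix@partition == mm),
                 sum(m@partition == mm) - out$removed[[mm]])
  }
  expect_gt(sum(out$removed), 0)  # low present frequency leaves absences
})

test_that("partition building covers the three schemes and weight modes", {
  m <- table1()
  pm <- buildPartitions(m, partitionSpec("per_meaning", weightsMode = "cognates"))
  expect_equal(vapply(pm, `[[`, 0, "weight"), c(1, 4))
  expect_equal(vapply(pm, `[[`, "", "name"), c("two", "belly"))
  single <- buildPartitions(m, partitionSpec("single", weightsMode = "equal"))
  expect_length(single, 1)
  expect_equal(single[[1]]$weight, 1)
  expect_equal(single[[1]]$columns, 1:5)
  expect_equal(buildPartitions(m, partitionSpec("single"))[[1]]$weight, 5)
  # binned: meaning cognate counts {3,4,7,12}, width 5 -> bins {1-5}:2, {6-10}:1, {11-15}:1
  v <- matrix(1L, 2, 26, dimnames = list(c("A", "B"), NULL))
  meanings <- rep(c("w", "x", "y", "z"), times = c(3, 4, 7, 12))
  mb <- cognateMatrix(v, meanings)
  bp <- buildPartitions(mb, partitionSpec("binned", binWidth = 5,
                                          weightsMode = "meanings"))
  expect_equal(vapply(bp, `[[`, "", "name"),
               c("bin_1-5", "bin_6-10", "bin_11-15"))
  expect_equal(vapply(bp, `[[`, 0, "weight"), c(2, 1, 1))
  bc <- buildPartitions(mb, partitionSpec("binned", binWidth = 5,
                                          weightsMode = "cognates"))
  expect_equal(vapply(bc, `[[`, 0, "weight"), c(7, 7, 12))
  expect_equal(sort(unlist(lapply(bp, `[[`, "columns"))), 1:26)
})
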