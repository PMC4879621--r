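test_that("filter breakdown partitions reads with fixed priority", {
  ## 10 reads: 2 duplicates, 1 improper, 3 off-target, 4 clean
  rows <- list(
    mkRead("r1", 1), mkRead("r2", 101), mkRead("r3", 201),
    mkRead("r4", 301),
    mkRead("d1", 1, dup = TRUE), mkRead("d2", 1, dup = TRUE),
    mkRead("i1", 401, proper = FALSE),
    mkRead("o1", 5001, on_target = FALSE),
    mkRead("o2", 5101, on_target = FALSE),
    mkRead("o3", 5201, on_target = FALSE))
  rt <- do.call(mkReadTable, rows)
  res <- filterReads(rt)
  cts <- filterCounts(res$breakdown)
  expect_equal(unname(cts[c("pass", "duplicate", "improper_pair",
                            "off_target", "unmapped")]),
               c(4, 2, 1, 3, 0))
  expect_equal(unname(filterRates(res$breakdown)[c("duplicate",
                                                   "improper_pair",
                                                   "off_target", "pass")]),
               c(0.2, 0.1, 0.3, 0.4))
  ## counts partition exactly; rates sum to 1
  expect_identical(sum(cts[c("unmapped", "duplicate", "improper_pair",
                             "off_target", "pass")]), cts[["total"]])
  expect_equal(sum(filterRates(res$breakdown)), 1)
  ## all flags clean
  clean <- filterReads(do.call(mkReadTable, rows[1:4]))
  expect_equal(unname(filterRates(clean$breakdown)[["pass"]]), 1)
})

test_that("a read failing two filters lands in the first category only", {
  both <- mkReadTable(
    mkRead("x", 5001, dup = TRUE, on_target = FALSE),
    mkRead("y", 1))
  bd <- filterReads(both)$breakdown
  cts <- filterCounts(bd)
  expect_equal(unname(cts[["duplicate"]]), 1)
  expect_equal(unname(cts[["off_target"]]), 0)
  expect_identical(sum(cts[c("unmapped", "duplicate", "improper_pair",
                             "off_target", "pass")]), cts[["total"]])
  ## unmapped wins over everything
  un <- filterReads(mkReadTable(
    mkRead("z", 1, mapped = FALSE, dup = TRUE, proper = FALSE)))$breakdown
  expect_equal(unname(filterCounts(un)[["unmapped"]]), 1)
})

test_that("down-sampling is seeded, pair-preserving and size-exact", {
  rg <- tinyRegions(5000)
  g <- simulateGenotypes(2, rg, 0.01, seed = 1)
  ds <- simulateReads(PoolSpec(names(g)), g,
                      LibrarySimParams(100, 4000, seed = 2), rg)
  rt <- readRecords(ds, "sample1")
  n <- nrow(readRecords(rt))
  ## identity at full size
  expect_identical(readRecords(downsampleReads(rt, targetReads = n,
                                               seed = 1)),
                   readRecords(rt))
  ## same seed, same subset; different seed, different subset
  a <- downsampleReads(rt, targetReads = n / 2, seed = 42)
  b <- downsampleReads(rt, targetReads = n / 2, seed = 42)
  expect_identical(readRecords(a), readRecords(b))
  cc <- downsampleReads(rt, targetReads = n / 2, seed = 43)
  expect_false(identical(readRecords(a), readRecords(cc)))
  ## pairs stay together
  ra <- readRecords(a)
  expect_true(all(table(ra$pair_id) == 2))
  expect_equal(nrow(ra), n / 2)
  ## 50% down-sampling halves the mean depth (averaged over seeds)
  full <- meanDepth(coverageProfile(rt, rg))
  halves <- sapply(1:10, function(s)
    meanDepth(coverageProfile(downsampleReads(rt, targetReads = n / 2,
                                              seed = s), rg)))
  expect_equal(mean(halves), full / 2, tolerance = 0.02)
  ## over-asking errors
  expect_error(downsampleReads(rt, targetReads = n + 2, seed = 1),
               "exceeds")
})

test_that("depth-mode down-sampling hits a raw mean depth target", {
  rg <- tinyRegions(5000)
  g <- simulateGenotypes(2, rg, 0.01, seed = 1)
  ds <- simulateReads(PoolSpec(names(g)), g,
                      LibrarySimParams(100, 5000, seed = 2,
                                       onTargetFraction = 0.6), rg)
  rt <- readRecords(ds, "sample1")
  sub <- downsampleReads(rt, targetDepth = 50, regions = rg, seed = 7)
  raw <- PoolCapQC:::.rawMeanDepth(readRecords(sub), rg)
  expect_equal(raw, 50, tolerance = 0.05)
  expect_error(downsampleReads(rt, targetDepth = 1e6, regions = rg,
                               seed = 1), "exceeds")
})

test_that("coverage profiles follow interval arithmetic", {
  rg <- tinyRegions(1000)
  one <- mkReadTable(mkRead("r1", 1, span = 100))
  pr <- coverageProfile(one, rg)
  expect_equal(meanDepth(pr), 0.1)
  expect_equal(unname(coverageEfficiency(pr, 1)), 10)
  ## no reads: mean 0, >=1x is 0, >=0x is 100
  empty <- ReadRecordTable(readRecords(one)[0, ])
  pe <- coverageProfile(empty, rg)
  expect_equal(meanDepth(pe), 0)
  expect_equal(unname(coverageEfficiency(pe, c(0, 1))), c(100, 0))
  ## doubling the read set doubles depth pointwise
  two <- ReadRecordTable(rbind(readRecords(one), readRecords(one)))
  expect_equal(depthTable(coverageProfile(two, rg))$depth,
               2 * depthTable(pr)$depth)
  expect_error(coverageProfile(one, GenomicRanges::GRanges()), "empty")
})

test_that("efficiency curve is the survival function of the depth vector", {
  rg <- tinyRegions(2000)
  g <- simulateGenotypes(2, rg, 0.01, seed = 9)
  ds <- simulateReads(PoolSpec(names(g)), g,
                      LibrarySimParams(50, 2000, seed = 3), rg)
  pr <- coverageProfile(filterReads(readRecords(ds, "sample1"))$pass, rg)
  d <- depthTable(pr)$depth
  grid <- c(0, 1, 5, 10, 50, 100, 200)
  eff <- coverageEfficiency(pr, grid)
  expect_equal(unname(eff),
               sapply(grid, function(x) 100 * mean(d >= x)))
  expect_true(all(diff(eff) <= 0))
  expect_equal(unname(eff[["0"]]), 100)
})

test_that("percent of targets above a depth handles exact thresholds", {
  pr <- new("CoverageProfile",
            depth = data.frame(chrom = "chr1", pos = 1:10,
                               depth = rep(c(600, 400), each = 5)))
  expect_equal(percentTargetsAbove(pr, 500), 50)
  prU <- new("CoverageProfile",
             depth = data.frame(chrom = "chr1", pos = 1:10, depth = 600))
  expect_equal(percentTargetsAbove(prU, 500), 100)
  expect_equal(percentTargetsAbove(prU, 600), 0)   # strict >
})

test_that("saturation curve matches direct computation and is concave on
           complexity-limited data", {
  rg <- tinyRegions(3000)
  g <- simulateGenotypes(2, rg, 0.01, seed = 5)
  ds <- simulateReads(PoolSpec(names(g)), g,
                      LibrarySimParams(6.25, 8000, seed = 6), rg)
  rt <- readRecords(ds, "sample1")
  n <- nrow(readRecords(rt))
  ## grid = full data reproduces the direct value
  direct <- meanDepth(coverageProfile(filterReads(rt)$pass, rg))
  sc <- saturationCurve(rt, rg, grid = n, seed = 1)
  expect_equal(sc$mean_depth, direct)
  ## concavity of the seed-averaged curve at low input mass: second
  ## differences are non-positive in expectation, tested against their
  ## Monte-Carlo standard error
  grid <- round(seq(0.25, 1, by = 0.25) * n)
  curves <- sapply(1:20, function(s)
    saturationCurve(rt, rg, grid, seed = s)$mean_depth)
  avg <- rowMeans(curves)
  expect_true(all(diff(avg) > 0))           # more reads, more depth
  d2 <- apply(curves, 2, function(x) diff(diff(x)))
  se2 <- apply(d2, 1, sd) / sqrt(ncol(curves))
  expect_true(all(rowMeans(d2) <= 3 * se2))
  expect_error(saturationCurve(rt, rg, grid = n + 10, seed = 1), "exceeds")
})

test_that("SAM ingestion maps FLAG bits onto read-record columns", {
  skip_if_not_installed("Rsamtools")
  sam <- file.path(tempdir(), "toy.sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:chr1\tLN:10000",
    ## proper pair, mapped, on target
    "p1\t99\tchr1\t100\t60\t50M\t=\t200\t150\tGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGG\t*",
    ## duplicate (0x400 + 0x2 + paired flags)
    "p2\t1123\tchr1\t300\t60\t50M\t=\t400\t150\tGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGG\t*",
    ## not properly paired
    "p3\t97\tchr1\t500\t60\t50M\t=\t9000\t8550\tGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGG\t*",
    ## off target
    "p4\t99\tchr1\t9500\t60\t50M\t=\t9600\t150\tGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGG\t*",
    ## unmapped
    "p5\t77\t*\t0\t0\t*\t*\t0\t0\tGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGG\t*"),
    sam)
  rt <- readRecordsFromSam(sam, tinyRegions(1000, start = 1), "s")
  r <- readRecords(rt)
  r <- r[order(r$pair_id), ]
  expect_equal(r$mapped, c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_equal(r$duplicate[r$pair_id == "p2"], TRUE)
  expect_equal(r$proper_pair[r$pair_id == "p3"], FALSE)
  expect_equal(r$on_target, c(TRUE, TRUE, TRUE, FALSE, FALSE))
})
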