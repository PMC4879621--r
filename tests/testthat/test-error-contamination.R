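test_that("background rates are counts over depth with zeros included", {
  bg <- new("BackgroundAlleleCatalog",
            alleles = data.frame(chrom = "chr1", pos = c(1L, 2L, 3L),
                                 allele = c("A", "A", "A"),
                                 stringsAsFactors = FALSE),
            universeSize = 400, span = 100)
  ## allele A seen 3 times at depth 1000 at pos 1; unseen at pos 2;
  ## zero depth at pos 3
  act <- mkCounts("s", pos = c(1L, 2L), allele = "A", count = c(3, 0),
                  depth = c(1000, 500))
  act@depth <- rbind(act@depth, data.frame(chrom = "chr1", pos = 3L,
                                           depth = 0))
  d <- backgroundRates(act, bg)
  expect_equal(sort(errorFreqs(d)), c(0, 0.003))
  expect_equal(d@mean, mean(c(0.003, 0)))
  expect_equal(d@nExcluded, 1)
  ## an error-free simulation yields an all-zero distribution
  rg <- tinyRegions(2000)
  g <- simulateGenotypes(2, rg, 0.01, seed = 2)
  ds <- simulateReads(PoolSpec(names(g)), g,
                      LibrarySimParams(50, 2000, seed = 3,
                                       perBaseErrorRate = 0), rg)
  bgSim <- buildBackgroundCatalog(genotypeCatalog(g), rg)
  dSim <- backgroundRates(alleleCounts(ds, "sample1"), bgSim)
  expect_equal(dSim@mean, 0)
  expect_true(all(errorFreqs(dSim) == 0))
})

test_that("contamination groups follow the shared-control / specific-test
           set algebra", {
  ## 2 samples: allele G at pos 1 background in A, genotype in B
  gA <- data.frame(chrom = "chr1", pos = 2L, allele = "A",
                   stringsAsFactors = FALSE)
  gB <- data.frame(chrom = "chr1", pos = 1L, allele = "G",
                   stringsAsFactors = FALSE)
  bgA <- data.frame(chrom = "chr1", pos = c(1L, 5L), allele = c("G", "T"),
                    stringsAsFactors = FALSE)
  bgB <- data.frame(chrom = "chr1", pos = c(2L, 5L), allele = c("A", "T"),
                    stringsAsFactors = FALSE)
  gr <- buildContaminationGroups(list(A = gA, B = gB),
                                 list(A = bgA, B = bgB))
  expect_equal(gr$test$A, data.frame(chrom = "chr1", pos = 1L,
                                     allele = "G",
                                     stringsAsFactors = FALSE))
  expect_equal(gr$test$B, data.frame(chrom = "chr1", pos = 2L,
                                     allele = "A",
                                     stringsAsFactors = FALSE))
  ## allele background in all samples -> shared control group
  expect_equal(gr$control$pos, 5L)
  expect_error(buildContaminationGroups(list(A = gA), list(A = bgA)),
               "at least 2")
})

test_that("contamination group construction matches brute-force set algebra
           on a toy 8-line catalog", {
  set.seed(404)
  nS <- 8
  universe <- expand.grid(pos = 1:20, allele = c("A", "C", "G", "T"),
                          stringsAsFactors = FALSE)
  samples <- paste0("S", seq_len(nS))
  gt <- list(); bg <- list()
  for (s in samples) {
    isGt <- runif(nrow(universe)) < 0.1
    isBg <- !isGt & runif(nrow(universe)) < 0.8
    gt[[s]] <- data.frame(chrom = "chr1", pos = universe$pos[isGt],
                          allele = universe$allele[isGt],
                          stringsAsFactors = FALSE)
    bg[[s]] <- data.frame(chrom = "chr1", pos = universe$pos[isBg],
                          allele = universe$allele[isBg],
                          stringsAsFactors = FALSE)
  }
  gr <- buildContaminationGroups(gt, bg)
  key <- function(df) paste(df$pos, df$allele)
  ## brute force: loop over every allele of the universe
  for (i in seq_len(nrow(universe))) {
    k <- paste(universe$pos[i], universe$allele[i])
    inBg <- vapply(samples, function(s) k %in% key(bg[[s]]), NA)
    inGt <- vapply(samples, function(s) k %in% key(gt[[s]]), NA)
    expect_equal(k %in% key(gr$control), all(inBg))
    for (s in samples) {
      expectTest <- inBg[[s]] && any(inGt[setdiff(samples, s)]) &&
        !all(inBg)
      expect_equal(k %in% key(gr$test[[s]]), expectTest)
    }
  }
  ## groups disjoint per sample; control identical across samples by
  ## construction; total never exceeds the universe
  for (s in samples)
    expect_length(intersect(key(gr$test[[s]]), key(gr$control)), 0L)
  expect_lte(nrow(gr$control) + sum(vapply(gr$test, nrow, 0L)),
             nS * nrow(universe))
})

test_that("the contamination estimate is the difference of test-group means", {
  ## printed-style means: single 0.052%, multi 0.077% at one test allele;
  ## shared control allele near 0.012%
  grp <- list(
    test = list(A = data.frame(chrom = "chr1", pos = 9L, allele = "G",
                               stringsAsFactors = FALSE)),
    control = data.frame(chrom = "chr1", pos = 13L, allele = "A",
                         stringsAsFactors = FALSE))
  single <- list(A = mkCounts("A", pos = c(9L, 13L), allele = c("G", "A"),
                              count = c(52, 12), depth = 1e5))
  multi <- list(A = mkCounts("A", pos = c(9L, 13L), allele = c("G", "A"),
                             count = c(77, 11), depth = 1e5))
  rep_ <- estimateContamination(single, multi, grp)
  expect_equal(100 * rep_@testMeans[["single"]], 0.052, tolerance = 1e-12)
  expect_equal(100 * rep_@testMeans[["multi"]], 0.077, tolerance = 1e-12)
  expect_equal(100 * contaminationEstimate(rep_), 0.025,
               tolerance = 1e-9)
  expect_equal(100 * rep_@controlMeans[["single"]], 0.012,
               tolerance = 1e-12)
  ## identical tables in both conditions -> estimate 0
  same <- estimateContamination(single, single, grp)
  expect_equal(contaminationEstimate(same), 0)
  ## sample mismatch errors
  expect_error(estimateContamination(single, list(B = multi$A), grp),
               "differ")
})

test_that("count thinning preserves mean rates in expectation", {
  grp <- list(
    test = list(A = data.frame(chrom = "chr1", pos = 9L, allele = "G",
                               stringsAsFactors = FALSE)),
    control = data.frame(chrom = "chr1", pos = 13L, allele = "A",
                         stringsAsFactors = FALSE))
  act <- mkCounts("A", pos = c(9L, 13L), allele = c("G", "A"),
                  count = c(500, 100), depth = 1e6)
  ests <- sapply(1:20, function(s)
    estimateContamination(list(A = act), list(A = act), grp,
                          downsampleTo = 5000, readSpan = 100,
                          seed = s)@testMeans[["multi"]])
  expect_equal(mean(ests), 500 / 1e6, tolerance = 0.1)
})

test_that("error histograms are normalized and bin correctly", {
  dz <- new("ErrorDistribution", freq = rep(0, 10), mean = 0, sd = 0,
            nExcluded = 0)
  h <- errorHistogram(dz, c(0, 1e-4, 1e-3, 1))
  expect_equal(h$mass, c(1, 0, 0))
  ## two equal groups at distinct frequencies -> two bins at 0.5
  d2 <- new("ErrorDistribution", freq = c(rep(2e-4, 5), rep(2e-3, 5)),
            mean = mean(c(rep(2e-4, 5), rep(2e-3, 5))), sd = 0,
            nExcluded = 0)
  h2 <- errorHistogram(d2, c(0, 1e-3, 1e-2, 1))
  expect_equal(h2$mass, c(0.5, 0.5, 0))
  expect_equal(sum(h2$mass), 1)
  de <- new("ErrorDistribution", freq = numeric(0), mean = NA_real_,
            sd = NA_real_, nExcluded = 0)
  expect_error(errorHistogram(de, c(0, 1)), "empty")
  expect_error(errorHistogram(d2, c(0.5, 0.1)), "increasing")
})

test_that("equal-coverage samples have superimposable background
           histograms and multiplex-invariant control groups", {
  rg <- tinyRegions(4000)
  g <- simulateGenotypes(4, rg, 0.01, seed = 21)
  p <- PoolSpec(names(g))
  bg <- buildBackgroundCatalog(genotypeCatalog(g), rg)
  hb <- c(0, 1e-4, 2e-4, 5e-4, 1e-3, 1)
  hists <- lapply(1:2, function(i) {
    ds <- simulateReads(p, g, LibrarySimParams(100, 5000, seed = 30 + i),
                        rg, sampleName = paste0("s", i))
    errorHistogram(backgroundRates(alleleCounts(ds, paste0("s", i)), bg),
                   hb)
  })
  ## same error process, same coverage: sup distance between histograms
  ## stays small
  expect_lt(max(abs(hists[[1]]$mass - hists[[2]]$mass)), 0.05)
})
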