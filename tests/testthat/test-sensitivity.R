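test_that("detection sensitivity matches on position, allele and class", {
  tr <- mkTruth(pos = c(101, 201, 301, 401),
                alt = c("G", "G", "G", "G"),
                maf = c(0.04, 0.08, 0.12, 0.5))
  ## calls superset of truth: sensitivity 1 in every non-empty bin
  all4 <- mkCallSet("lib", pos = c(101, 201, 301, 401, 501))
  st <- detectionSensitivity(tr, all4)
  b <- sensitivityBins(st)
  expect_equal(b$sensitivity[b$expected > 0], rep(1, 4))
  expect_equal(st@overall, 1)
  ## class must match: an indel call does not detect an SNV truth record
  wrongClass <- CallSet("lib", data.frame(
    chrom = "chr1", pos = 101L, ref = syntheticReference(101), alt = "G",
    class = "indel", af = 0.5, stringsAsFactors = FALSE))
  st2 <- detectionSensitivity(tr, wrongClass)
  expect_equal(st2@overall, 0)
  ## bins must be increasing and must cover the truth MAFs
  expect_error(detectionSensitivity(tr, all4, bins = c(0, 0.5, 0.2, 1)),
               "increasing")
  expect_error(detectionSensitivity(tr, all4, bins = c(0.05, 0.1, 1)),
               "outside")
  empty <- new("VariantTruthSet", records = truthRecords(tr)[0, ])
  expect_error(detectionSensitivity(empty, all4), "empty truth")
})

test_that("the naive detector applies both thresholds", {
  ## pos 9 (ref C): allele G at 30/500 = 6% with thresholds (5%, 5) calls
  act <- mkCounts("s", pos = 9L, allele = "G", count = 30, depth = 500)
  cs <- naiveDetector(act, minFraction = 0.05, minAltReads = 5)
  expect_equal(callTable(cs)$pos, 9L)
  expect_equal(callTable(cs)$af, 0.06)
  ## count below min_alt_reads is never called, whatever the fraction
  act2 <- mkCounts("s", pos = 9L, allele = "G", count = 2, depth = 4)
  cs2 <- naiveDetector(act2, minFraction = 0.05, minAltReads = 5)
  expect_equal(nrow(callTable(cs2)), 0L)
  ## reference alleles are never emitted
  expect_false(any(callTable(cs)$alt == syntheticReference(
    callTable(cs)$pos)))
  expect_error(naiveDetector(act, minFraction = 0), "positive")
})

test_that("naive detection probability matches the exact binomial tail", {
  ## depth 500, true MAF 5%, thresholds (0.025, 5): a site is called iff
  ## X >= max(5, ceiling(0.025 * 500)) = 13, X ~ Binomial(500, 0.05)
  depth <- 500; maf <- 0.05; nSites <- 1000
  k <- max(5, ceiling(0.025 * depth))
  pExpect <- pbinom(k - 1, depth, maf, lower.tail = FALSE)
  set.seed(777)
  x <- rbinom(nSites, depth, maf)
  pos <- seq(9, by = 4, length.out = nSites)   # ref C everywhere
  act <- mkCounts("s", pos = pos, allele = "G", count = x, depth = depth)
  cs <- naiveDetector(act, minFraction = 0.025, minAltReads = 5)
  pObs <- nrow(callTable(cs)) / nSites
  se <- sqrt(pExpect * (1 - pExpect) / nSites)
  expect_lt(abs(pObs - pExpect), 4 * se + 1e-9)
})

test_that("low-coverage masking drops under-covered truth positions", {
  tr <- mkTruth(pos = c(10, 20, 30), alt = "G", maf = c(0.1, 0.2, 0.3))
  prof <- function(d) new("CoverageProfile",
                          depth = data.frame(chrom = "chr1", pos = c(10L, 20L, 30L),
                                             depth = d))
  ## mean depths (150, 250, 199) against threshold 200: one site survives
  profiles <- list(prof(c(100, 300, 199)), prof(c(200, 200, 199)))
  kept <- maskLowCoverage(tr, profiles, 200)
  expect_equal(truthRecords(kept)$pos, 20L)
  ## threshold 0 is the identity
  expect_equal(truthRecords(maskLowCoverage(tr, profiles, 0)),
               truthRecords(tr))
  ## everything below threshold empties the truth set
  expect_equal(nrow(truthRecords(maskLowCoverage(tr, profiles, 1e6))), 0L)
  ## truth position absent from a profile errors
  short <- list(prof(c(1, 1, 1)),
                new("CoverageProfile",
                    depth = data.frame(chrom = "chr1", pos = 10L,
                                       depth = 5)))
  expect_error(maskLowCoverage(tr, short, 10), "absent")
})

test_that("masking cold spots cannot lower per-bin sensitivity when the
           masked sites are the undetected ones", {
  set.seed(31)
  n <- 60
  pos <- seq(9, by = 4, length.out = n)
  maf <- runif(n, 0.02, 0.9)
  tr <- mkTruth(pos = pos, alt = "G", maf = maf)
  ## depth-dependent dropout: low-depth sites go undetected
  depth <- ifelse(runif(n) < 0.3, 50, 400)
  detected <- depth >= 400
  calls <- mkCallSet("lib", pos = pos[detected])
  prof <- new("CoverageProfile",
              depth = data.frame(chrom = "chr1", pos = as.integer(pos),
                                 depth = depth))
  before <- sensitivityBins(detectionSensitivity(tr, calls))
  masked <- maskLowCoverage(tr, list(prof), 200)
  after <- sensitivityBins(detectionSensitivity(masked, calls))
  ok <- before$expected > 0 & after$expected > 0
  expect_true(all(after$sensitivity[ok] >= before$sensitivity[ok]))
})

test_that("concordance classes count detection multiplicity", {
  ## identical call sets: everything found in all three
  a <- mkCallSet("a", c(1, 5, 9))
  cc <- concordanceClassify(list(a, mkCallSet("b", c(1, 5, 9)),
                                 mkCallSet("c", c(1, 5, 9))))
  expect_equal(unname(concordanceClasses(cc)), c(0, 0, 3))
  ## disjoint call sets: everything private
  cd <- concordanceClassify(list(mkCallSet("a", 1), mkCallSet("b", 5),
                                 mkCallSet("c", 9)))
  expect_equal(unname(concordanceClasses(cd)), c(3, 0, 0))
  ## {A,B}, {B,C}, {B}: multiplicities A=1 B=3 C=1
  s1 <- mkCallSet("a", c(1, 5)); s2 <- mkCallSet("b", c(5, 9))
  s3 <- mkCallSet("c", 5)
  ce <- concordanceClassify(list(s1, s2, s3))
  expect_equal(unname(concordanceClasses(ce)), c(2, 0, 1))
  expect_equal(names(concordanceClasses(ce)),
               c("private", "shared_by_2", "found_in_3"))
  ## permutation invariance
  cp <- concordanceClassify(list(s3, s1, s2))
  expect_equal(concordanceClasses(cp), concordanceClasses(ce))
  expect_error(concordanceClassify(list(s1)), "at least 2")
})

test_that("concordance multiplicities match brute-force enumeration", {
  set.seed(99)
  k <- 4
  sets <- lapply(seq_len(k), function(i)
    mkCallSet(paste0("lib", i), sort(sample(seq(1, 197, by = 4), 15))))
  cc <- concordanceClassify(sets)
  v <- cc@variants
  for (i in seq_len(nrow(v))) {
    m <- sum(vapply(sets, function(s) v$pos[i] %in% callTable(s)$pos, NA))
    expect_equal(v$n_libraries[i], m)
  }
  expect_equal(sum(concordanceClasses(cc)), nrow(v))
})
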