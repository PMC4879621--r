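test_that("genotype classification follows the frequency windows", {
  ## ref at pos 1 is C (synthetic rule); alt A at various frequencies
  cat <- mkCatalog(line = c("L1", "L2", "L3", "L4", "L5"),
                   pos = 1, allele = "A",
                   freq = c(0.50, 0.95, 0.75, 0.40, 0.905))
  st <- classifyGenotypes(cat)
  states <- setNames(st$state, st$line)
  expect_equal(states[["L1"]], "het")       # 0.50 inside [0.40, 0.60]
  expect_equal(states[["L2"]], "hom")       # 0.95 > 0.90
  expect_equal(states[["L3"]], "excluded")  # 0.75 in neither window
  expect_equal(states[["L4"]], "het")       # boundary included
  expect_equal(states[["L5"]], "hom")       # strict > 0.90
  ## window misuse
  expect_error(classifyGenotypes(cat, hetWindow = c(0.6, 0.4)), "interval")
  expect_error(classifyGenotypes(cat, hetWindow = c(0.4, 0.95)),
               "overlap")
  ## missing depth errors
  bad <- cat
  bad@calls$depth[1] <- NA_real_
  expect_error(classifyGenotypes(bad), "depth")
})

test_that("expected pool MAF is ratio-weighted dosage", {
  lines <- sprintf("L%02d", 1:10)
  st <- data.frame(line = "L01", chrom = "chr1", pos = 1L, ref = "C",
                   alt = "A", freq = 0.5, state = "het",
                   stringsAsFactors = FALSE)
  attr(st, "lines") <- lines
  equal10 <- PoolSpec(lines)
  ## private het in a 10-line equal pool: the 5% truth-set floor
  expect_equal(expectedMaf(equal10, st, "chr1", 1L, "A"), 0.05)
  ## hom in every constituent: MAF 1
  stAll <- do.call(rbind, lapply(lines, function(l)
    transform(st, line = l, state = "hom", freq = 1)))
  attr(stAll, "lines") <- lines
  expect_equal(expectedMaf(equal10, stAll, "chr1", 1L, "A"), 1.0)
  ## weighted two-line pool: 0.5 x 1 + 0.5 x 0.5
  st2 <- data.frame(line = c("a", "b"), chrom = "chr1", pos = 1L,
                    ref = "C", alt = "A", freq = c(0.95, 0.5),
                    state = c("hom", "het"), stringsAsFactors = FALSE)
  attr(st2, "lines") <- c("a", "b")
  expect_equal(expectedMaf(PoolSpec(c("a", "b"), c(0.5, 0.5)),
                           st2, "chr1", 1L, "A"), 0.75)
  ## permutation invariance: constituents and ratios permuted together
  pPerm <- PoolSpec(c("b", "a"), c(0.5, 0.5))
  expect_equal(expectedMaf(pPerm, st2, "chr1", 1L, "A"), 0.75)
  pW <- PoolSpec(c("a", "b"), c(0.3, 0.7))
  pWPerm <- PoolSpec(c("b", "a"), c(0.7, 0.3))
  expect_equal(expectedMaf(pW, st2, "chr1", 1L, "A"),
               expectedMaf(pWPerm, st2, "chr1", 1L, "A"))
  ## unknown constituent errors
  expect_error(expectedMaf(PoolSpec(c("a", "zz")), st2, "chr1", 1L, "A"),
               "unknown constituent")
})

test_that("SNV truth sets compose classification and pool arithmetic", {
  lines <- sprintf("L%02d", 1:10)
  ## one het site private to L01; one line with nothing
  cat <- mkCatalog(line = "L01", pos = 101, allele = "A", freq = 0.5,
                   lines = lines)
  ts <- buildTruthSet(PoolSpec(lines), cat)
  r <- truthRecords(ts)
  expect_equal(nrow(r), 1L)
  expect_equal(r$expected_maf, 0.05)
  expect_equal(r$class, "SNV")
  expect_equal(r$indel_length, 0L)
  ## excluded frequencies contribute nothing
  cat2 <- mkCatalog(line = c("L01", "L02"), pos = c(101, 101),
                    allele = "A", freq = c(0.5, 0.75), lines = lines)
  r2 <- truthRecords(buildTruthSet(PoolSpec(lines), cat2))
  expect_equal(r2$expected_maf, 0.05)
})

test_that("indel truth sets use observed frequency, concatenated over pools", {
  ## 5-indel toy catalog over 3 lines
  idl <- data.frame(
    line = c("A", "A", "B", "B", "C"),
    pos = c(11L, 21L, 11L, 31L, 41L),
    allele = c("+AC", "-T", "+AC", "-GGG", "+TTTT"),
    freq = c(0.12, 0.30, 0.08, 0.20, 0.05), stringsAsFactors = FALSE)
  cat <- mkCatalog(idl$line, idl$pos, idl$allele, idl$freq,
                   lines = c("A", "B", "C"))
  pools <- list(p1 = PoolSpec(c("A", "B"), c(0.5, 0.5)),
                p2 = PoolSpec(c("A", "B", "C"), c(0.2, 0.3, 0.5)),
                p3 = PoolSpec("C"))
  ts <- buildTruthSet(pools, cat, class = "indel")
  r <- truthRecords(ts)
  ## brute-force oracle: enumerate pool x indel allele, sum ratio x freq
  expected <- list()
  for (pn in names(pools)) {
    ratios <- poolRatios(pools[[pn]])
    keys <- unique(paste(idl$pos, idl$allele))
    for (k in keys) {
      rows <- idl[paste(idl$pos, idl$allele) == k, ]
      maf <- 0
      for (i in seq_len(nrow(rows)))
        if (rows$line[i] %in% names(ratios))
          maf <- maf + ratios[[rows$line[i]]] * rows$freq[i]
      if (maf > 0) expected[[paste(pn, k)]] <- maf
    }
  }
  expect_equal(nrow(r), length(expected))
  got <- setNames(r$expected_maf, paste(r$pool, r$pos, r$alt))
  expect_equal(got[names(expected)], unlist(expected), tolerance = 1e-12,
               ignore_attr = FALSE)
  ## indel lengths decoded from the allele encoding
  expect_equal(sort(unique(r$indel_length)), c(1L, 2L, 3L, 4L))
  ## truth set and background catalogue are disjoint by construction
  bg <- buildBackgroundCatalog(cat, tinyRegions(50))
  bgKeys <- with(backgroundAlleles(bg), paste(pos, allele))
  expect_length(intersect(paste(r$pos, r$alt), bgKeys), 0L)
})

test_that("background catalogue keeps alleles rare in every line", {
  lines <- c("L1", "L2")
  rg <- tinyRegions(100)
  ## pos 1 (ref C): allele A at 0.5% in both lines -> background
  ## pos 2 (ref G): allele A at 0.5% in L1 but 5% in L2 -> excluded
  cat <- mkCatalog(line = c("L1", "L2", "L1", "L2"),
                   pos = c(1, 1, 2, 2), allele = "A",
                   freq = c(0.005, 0.005, 0.005, 0.05), lines = lines)
  bg <- buildBackgroundCatalog(cat, rg)
  expect_equal(universeSize(bg), 400)
  keys <- with(backgroundAlleles(bg), paste(pos, allele))
  expect_true("1 A" %in% keys)
  expect_false("2 A" %in% keys)
  ## uncatalogued positions contribute their three non-reference alleles
  expect_true(all(c("3 A", "3 C", "3 G") %in% keys))  # ref at 3 is T
  expect_false("3 T" %in% keys)
  ## reference allele becomes background when hom-alternate in every line
  cat2 <- mkCatalog(line = c("L1", "L2"), pos = 5, allele = "A",
                    freq = c(0.995, 0.999), lines = lines)
  bg2 <- buildBackgroundCatalog(cat2, rg)
  k2 <- with(backgroundAlleles(bg2), paste(pos, allele))
  expect_true(paste(5, syntheticReference(5)) %in% k2)  # ref C rare now
  expect_false("5 A" %in% k2)
  expect_error(buildBackgroundCatalog(cat, rg, maxFreq = 1.5), "maxFreq")
})

test_that("genotype alleles use a strict 10% threshold", {
  cat <- mkCatalog(line = c("L1", "L1", "L1"), pos = c(1, 2, 3),
                   allele = "A", freq = c(0.12, 0.10, 0.09))
  ga <- genotypeAlleles(cat)[["L1"]]
  expect_equal(ga$pos, 1L)                 # only 0.12 passes; 0.10 exact fails
  ## reference-only line over explicit regions: only reference alleles
  catEmpty <- new("GenotypeCatalog",
                  calls = data.frame(line = character(), chrom = character(),
                                     pos = integer(), allele = character(),
                                     freq = numeric(), depth = numeric()),
                  lines = "L9")
  ga2 <- genotypeAlleles(catEmpty, regions = tinyRegions(8))[["L9"]]
  expect_equal(nrow(ga2), 8L)
  expect_identical(ga2$allele, syntheticReference(ga2$pos))
})
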