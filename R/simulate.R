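## Synthetic-data generator: genotypes, molecule pools, reads, pileups.
## Everything is driven by an explicit seed and is reproducible bit-for-bit.

#' LibrarySimParams: parameters of one simulated sequencing library
#'
#' Library complexity is driven by input DNA mass: the expected number of
#' unique capturable molecules per locus is
#' \code{inputMassNg / massPerHaploidGenomeNg * conversionEfficiency}
#' (mass over the 3.3 pg haploid-genome mass gives genome copies; the
#' conversion efficiency is the fraction surviving library construction and
#' capture). Read pairs are then drawn \emph{with replacement} from the
#' unique molecules, so PCR duplicates are repeat draws beyond the first and
#' the duplicate rate falls as input mass grows at fixed read count.
#'
#' @slot inputMassNg input DNA mass in ng (the study axis spans 6.25-200 ng).
#' @slot massPerHaploidGenomeNg mass of one haploid genome copy in ng
#'   (default 0.0033, i.e. 3.3 pg).
#' @slot conversionEfficiency fraction of genome copies that become unique
#'   capturable molecules, in (0, 1] (default 0.01).
#' @slot totalReadPairs number of read pairs sequenced.
#' @slot onTargetFraction fraction of pairs landing on target, in (0, 1].
#' @slot improperPairFraction fraction of pairs flagged improper, in [0, 1).
#' @slot perBaseErrorRate substitution error probability per sequenced base;
#'   errors substitute uniformly among the 3 non-template alleles.
#' @slot contaminationFraction fraction of on-target pairs drawn from
#'   co-captured samples' molecule pools, in [0, 1).
#' @slot readSpan read length in bp (default 100; pairs are 2 x readSpan
#'   with adjacent non-overlapping mates).
#' @slot seed integer seed; regenerating with the same seed reproduces
#'   identical tables.
#'
#' @seealso [LibrarySimParams()], [simulateReads()]
#' @exportClass LibrarySimParams
setClass("LibrarySimParams",
  representation(inputMassNg = "numeric",
                 massPerHaploidGenomeNg = "numeric",
                 conversionEfficiency = "numeric",
                 totalReadPairs = "numeric",
                 onTargetFraction = "numeric",
                 improperPairFraction = "numeric",
                 perBaseErrorRate = "numeric",
                 contaminationFraction = "numeric",
                 readSpan = "numeric",
                 seed = "numeric"))

setValidity("LibrarySimParams", function(object) {
  msg <- character()
  if (object@inputMassNg <= 0) msg <- c(msg, "inputMassNg must be positive")
  if (object@massPerHaploidGenomeNg <= 0)
    msg <- c(msg, "massPerHaploidGenomeNg must be positive")
  if (object@conversionEfficiency <= 0 || object@conversionEfficiency > 1)
    msg <- c(msg, "conversionEfficiency must lie in (0, 1]")
  if (object@totalReadPairs < 1)
    msg <- c(msg, "totalReadPairs must be a positive integer")
  if (object@onTargetFraction <= 0 || object@onTargetFraction > 1)
    msg <- c(msg, "onTargetFraction must lie in (0, 1]")
  if (object@improperPairFraction < 0 || object@improperPairFraction >= 1)
    msg <- c(msg, "improperPairFraction must lie in [0, 1)")
  if (object@perBaseErrorRate < 0 || object@perBaseErrorRate >= 1)
    msg <- c(msg, "perBaseErrorRate must lie in [0, 1)")
  if (object@contaminationFraction < 0 || object@contaminationFraction >= 1)
    msg <- c(msg, "contaminationFraction must lie in [0, 1)")
  if (object@readSpan < 1) msg <- c(msg, "readSpan must be positive")
  mols <- object@inputMassNg / object@massPerHaploidGenomeNg *
    object@conversionEfficiency
  if (!(mols > 0)) msg <- c(msg, "unique-molecule expectation must be > 0")
  if (length(msg)) msg else TRUE
})

#' @rdname LibrarySimParams-class
#' @param inputMassNg,totalReadPairs,seed required parameters; see slots.
#' @param massPerHaploidGenomeNg,conversionEfficiency,onTargetFraction,improperPairFraction,perBaseErrorRate,contaminationFraction,readSpan
#'   optional parameters with the defaults given in the slot documentation.
#' @return A validated \code{LibrarySimParams} object.
#' @examples
#' LibrarySimParams(inputMassNg = 50, totalReadPairs = 2e4, seed = 1)
#' @export
LibrarySimParams <- function(inputMassNg, totalReadPairs, seed,
                             massPerHaploidGenomeNg = 0.0033,
                             conversionEfficiency = 0.01,
                             onTargetFraction = 0.6,
                             improperPairFraction = 0.02,
                             perBaseErrorRate = 5e-4,
                             contaminationFraction = 0,
                             readSpan = 100) {
  new("LibrarySimParams",
      inputMassNg = inputMassNg,
      massPerHaploidGenomeNg = massPerHaploidGenomeNg,
      conversionEfficiency = conversionEfficiency,
      totalReadPairs = as.numeric(totalReadPairs),
      onTargetFraction = onTargetFraction,
      improperPairFraction = improperPairFraction,
      perBaseErrorRate = perBaseErrorRate,
      contaminationFraction = contaminationFraction,
      readSpan = readSpan,
      seed = as.numeric(seed))
}

#' Expected number of unique capturable molecules per locus
#'
#' @param params a [LibrarySimParams-class].
#' @return \code{inputMassNg / massPerHaploidGenomeNg *
#'   conversionEfficiency}.
#' @export
uniqueMoleculeMean <- function(params) {
  params@inputMassNg / params@massPerHaploidGenomeNg *
    params@conversionEfficiency
}

#' Simulate diploid cell-line genotypes over a target
#'
#' Draws a shared set of candidate variant sites (Poisson with mean
#' \code{variantDensity * span}, uniformly placed over the targeted bases,
#' one alternate allele per site) and then assigns each line an independent
#' state at every site: absent, heterozygous or homozygous. This emulates a
#' panel of cell lines individually genotyped at high depth; pooling such
#' lines at known ratios yields variants spanning a range of expected MAF.
#'
#' @param nLines number of cell lines.
#' @param regions [GenomicRanges::GRanges] of target intervals (non-empty).
#' @param variantDensity expected variants per targeted base (> 0, and
#'   \code{variantDensity * span} must be at least 1).
#' @param seed integer seed; the call is deterministic given the seed.
#' @param hetProb,homProb per-line probability that a candidate site is
#'   heterozygous / homozygous (their sum at most 1; the remainder is
#'   absent).
#' @param lineIds identifiers, default \code{"L01"}, \code{"L02"}, ...
#' @return Named list of [CellLineGenome-class], one per line.
#' @examples
#' rg <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 10000))
#' g <- simulateGenotypes(10, rg, variantDensity = 0.01, seed = 7)
#' g[[1]]
#' @export
simulateGenotypes <- function(nLines, regions, variantDensity, seed,
                              hetProb = 0.35, homProb = 0.15,
                              lineIds = sprintf("L%02d", seq_len(nLines))) {
  if (length(regions) == 0L) stop("empty target regions")
  if (variantDensity <= 0) stop("variantDensity must be positive")
  if (nLines < 1) stop("nLines must be at least 1")
  if (hetProb < 0 || homProb < 0 || hetProb + homProb > 1)
    stop("hetProb and homProb must be non-negative and sum to at most 1")
  tp <- targetPositions(regions)
  span <- nrow(tp)
  if (variantDensity * span < 1)
    stop("variantDensity x span must give at least 1 expected variant")
  withSeed(seed, {
    nSites <- min(rpois(1L, variantDensity * span), span)
    idx <- sort(sample.int(span, nSites))
    sites <- tp[idx, , drop = FALSE]
    ref <- syntheticReference(sites$pos)
    alt <- vapply(ref, function(r) sample(setdiff(.NUC, r), 1L), "",
                  USE.NAMES = FALSE)
    out <- lapply(lineIds, function(id) {
      state <- sample(c("absent", "het", "hom"), nSites, replace = TRUE,
                      prob = c(1 - hetProb - homProb, hetProb, homProb))
      keep <- state != "absent"
      new("CellLineGenome", lineId = id,
          variants = data.frame(chrom = sites$chrom[keep],
                                pos = sites$pos[keep],
                                ref = ref[keep], alt = alt[keep],
                                genotype = state[keep],
                                stringsAsFactors = FALSE))
    })
    names(out) <- lineIds
    out
  })
}

#' Truth genotype catalog from simulated genomes
#'
#' Converts simulated diploid genomes into the per-line allele-frequency
#' table a deep individual sequencing run would ideally report: alternate
#' alleles at frequency 0.5 (het) or 1.0 (hom), with the reference allele
#' carrying the complement, at a nominal uniform depth.
#'
#' @param genomes list of [CellLineGenome-class].
#' @param depth nominal per-position depth recorded in the catalog
#'   (default 2000, i.e. deep individual sequencing).
#' @return A [GenotypeCatalog-class].
#' @export
genotypeCatalog <- function(genomes, depth = 2000) {
  pieces <- lapply(genomes, function(g) {
    v <- variantTable(g)
    if (nrow(v) == 0L)
      return(data.frame(line = character(), chrom = character(),
                        pos = integer(), allele = character(),
                        freq = numeric(), depth = numeric(),
                        stringsAsFactors = FALSE))
    af <- ifelse(v$genotype == "hom", 1.0, 0.5)
    rbind(
      data.frame(line = lineId(g), chrom = v$chrom, pos = v$pos,
                 allele = v$alt, freq = af, depth = depth,
                 stringsAsFactors = FALSE),
      data.frame(line = lineId(g), chrom = v$chrom, pos = v$pos,
                 allele = v$ref, freq = 1 - af, depth = depth,
                 stringsAsFactors = FALSE))
  })
  calls <- do.call(rbind, pieces)
  rownames(calls) <- NULL
  new("GenotypeCatalog", calls = calls,
      lines = vapply(genomes, lineId, ""))
}

## Unique-molecule pool of one library: per fragment-length window the
## molecule count is Poisson with the mass-derived mean; each molecule gets
## a uniform start inside its window, a constituent line by mixing ratio and
## a haplotype (het alt alleles carried with probability 1/2).
.moleculePool <- function(pool, genomes, params, regions, prefix) {
  red <- GenomicRanges::reduce(regions)
  fragLen <- as.integer(2 * params@readSpan)
  winStart <- integer(0); winWidth <- integer(0); winChrom <- character(0)
  winMax <- integer(0)
  for (i in seq_along(red)) {
    s <- seq(start(red)[i], end(red)[i], by = fragLen)
    winStart <- c(winStart, s)
    winWidth <- c(winWidth, pmin(fragLen, end(red)[i] - s + 1L))
    winChrom <- c(winChrom, rep(as.character(seqnames(red))[i], length(s)))
    ## fragments stay inside their region so both mates overlap the target
    winMax <- c(winMax, rep(max(start(red)[i], end(red)[i] - fragLen + 1L),
                            length(s)))
  }
  lam <- uniqueMoleculeMean(params)
  nPer <- rpois(length(winStart), lam)
  m <- sum(nPer)
  widx <- rep(seq_along(winStart), nPer)
  startPos <- pmin(winStart[widx] + floor(runif(m) * winWidth[widx]),
                   winMax[widx])
  line <- sample(constituents(pool), m, replace = TRUE,
                 prob = poolRatios(pool))
  mol <- data.frame(molecule_id = paste0(prefix, seq_len(m)),
                    chrom = winChrom[widx],
                    start = as.integer(startPos),
                    line = line, stringsAsFactors = FALSE)
  ## haplotype: which alt alleles does each molecule carry
  allv <- do.call(rbind, lapply(genomes[constituents(pool)], function(g) {
    v <- variantTable(g)
    if (nrow(v) == 0L) return(NULL)
    cbind(v, line = lineId(g), stringsAsFactors = FALSE)
  }))
  alts <- data.frame(molecule_id = character(), chrom = character(),
                     pos = integer(), alt = character(),
                     stringsAsFactors = FALSE)
  if (!is.null(allv) && nrow(allv) && m > 0) {
    molGr <- GRanges(mol$chrom, IRanges(mol$start, mol$start + fragLen - 1L))
    varGr <- GRanges(allv$chrom, IRanges(allv$pos, allv$pos))
    ov <- GenomicRanges::findOverlaps(molGr, varGr, ignore.strand = TRUE)
    mi <- S4Vectors::queryHits(ov); vi <- S4Vectors::subjectHits(ov)
    same <- mol$line[mi] == allv$line[vi]
    mi <- mi[same]; vi <- vi[same]
    carried <- ifelse(allv$genotype[vi] == "hom", TRUE,
                      runif(length(vi)) < 0.5)
    mi <- mi[carried]; vi <- vi[carried]
    alts <- data.frame(molecule_id = mol$molecule_id[mi],
                       chrom = allv$chrom[vi], pos = allv$pos[vi],
                       alt = allv$alt[vi], stringsAsFactors = FALSE)
  }
  list(mol = mol, alts = alts, fragLen = fragLen)
}

## Per-position depth of a set of reads over the targeted bases.
.depthOverRegions <- function(reads, regions) {
  tp <- targetPositions(regions)
  if (nrow(reads) == 0L)
    return(cbind(tp, depth = 0L))
  gr <- GRanges(reads$chrom,
                IRanges(reads$pos, reads$pos + reads$span - 1L))
  cov <- GenomicRanges::coverage(gr)
  red <- GenomicRanges::reduce(regions)
  depth <- integer(0)
  for (i in seq_along(red)) {
    chr <- as.character(seqnames(red))[i]
    w <- width(red)[i]
    if (!chr %in% names(cov)) { depth <- c(depth, integer(w)); next }
    rl <- cov[[chr]]
    s <- start(red)[i]; e <- end(red)[i]
    inside <- min(e, length(rl))
    v <- if (s <= inside)
      as.integer(S4Vectors::window(rl, s, inside)) else integer(0)
    depth <- c(depth, c(v, integer(w - length(v))))
  }
  cbind(tp, depth = depth)
}

#' Simulate a sequencing library from a pooled specimen
#'
#' Generates read records and a post-filter pileup for one library:
#' \enumerate{
#'   \item a unique-molecule pool is drawn (Poisson per fragment-window with
#'     the mass-derived mean; see [LibrarySimParams-class]), each molecule
#'     assigned a constituent line by mixing ratio and a haplotype;
#'   \item read pairs are sampled with replacement from the molecules;
#'     repeat draws of a molecule beyond the first are flagged duplicates;
#'   \item off-target and improper pairs are emitted at their configured
#'     fractions; a \code{contaminationFraction} of on-target pairs is drawn
#'     from the co-captured samples' molecule pools instead of the
#'     library's own (molecule-level contamination, as in pooled capture);
#'   \item per-base substitution errors replace the template base with one
#'     of the 3 other alleles uniformly;
#'   \item allele counts are piled up from pass-filter reads (mapped,
#'     non-duplicate, proper, on-target), i.e. after duplicate removal.
#' }
#'
#' @param pool [PoolSpec-class] of the library's specimen.
#' @param genomes named list of [CellLineGenome-class] covering the pool's
#'   constituents (and those of any co-captured pools).
#' @param params [LibrarySimParams-class].
#' @param regions [GenomicRanges::GRanges] of target intervals.
#' @param cocaptured optional named list of [PoolSpec-class]: the other
#'   specimens in the same capture reaction, required when
#'   \code{contaminationFraction > 0}.
#' @param sampleName sample identifier for the emitted tables.
#' @return A [SimulatedDataset-class] holding this sample's
#'   [ReadRecordTable-class] and [AlleleCountTable-class] plus the truth and
#'   provenance.
#' @examples
#' rg <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 5000))
#' g <- simulateGenotypes(4, rg, 0.005, seed = 1)
#' p <- PoolSpec(names(g))
#' ds <- simulateReads(p, g, LibrarySimParams(50, 5000, seed = 2), rg)
#' ds
#' @export
simulateReads <- function(pool, genomes, params, regions,
                          cocaptured = NULL, sampleName = "sample1") {
  stopifnot(is(pool, "PoolSpec"), is(params, "LibrarySimParams"))
  validObject(pool); validObject(params)
  if (!all(constituents(pool) %in% names(genomes)))
    stop("pool constituents missing from the genome list: ",
         paste(setdiff(constituents(pool), names(genomes)), collapse = ", "))
  if (params@contaminationFraction > 0 && length(cocaptured) == 0L)
    stop("contamination requested but no co-captured samples given")
  withSeed(params@seed, {
    own <- .moleculePool(pool, genomes, params, regions,
                         prefix = paste0(sampleName, "_m"))
    coc <- NULL
    if (length(cocaptured)) {
      if (is.null(names(cocaptured)))
        names(cocaptured) <- paste0("cocap", seq_along(cocaptured))
      pools <- lapply(seq_along(cocaptured), function(i) {
        withSeed(childSeed(params@seed, names(cocaptured)[i]),
                 .moleculePool(cocaptured[[i]], genomes, params, regions,
                               prefix = paste0(names(cocaptured)[i], "_m")))
      })
      coc <- list(mol = do.call(rbind, lapply(pools, `[[`, "mol")),
                  alts = do.call(rbind, lapply(pools, `[[`, "alts")))
    }
    nPairs <- as.integer(params@totalReadPairs)
    nOff <- rbinom(1L, nPairs, 1 - params@onTargetFraction)
    nOn <- nPairs - nOff
    nCon <- if (params@contaminationFraction > 0)
      rbinom(1L, nOn, params@contaminationFraction) else 0L
    nOwn <- nOn - nCon
    if (nrow(own$mol) == 0L)
      stop("molecule pool is empty; increase input mass or conversion ",
           "efficiency")
    oIdx <- sample.int(nrow(own$mol), nOwn, replace = TRUE)
    pairMol <- own$mol[oIdx, , drop = FALSE]
    if (nCon > 0L) {
      cIdx <- sample.int(nrow(coc$mol), nCon, replace = TRUE)
      pairMol <- rbind(pairMol, coc$mol[cIdx, , drop = FALSE])
    }
    dup <- duplicated(pairMol$molecule_id)
    span <- as.integer(params@readSpan)
    ## off-target pairs land in a decoy interval beyond the target
    offChrom <- as.character(seqnames(regions))[1L]
    offBase <- max(end(regions)) + 100L * span
    offStart <- offBase + floor(runif(nOff) * 50000)
    pairStart <- c(pairMol$start, as.integer(offStart))
    pairChrom <- c(pairMol$chrom, rep(offChrom, nOff))
    pairLine <- c(pairMol$line, rep(NA_character_, nOff))
    pairMolId <- c(pairMol$molecule_id, rep(NA_character_, nOff))
    pairOn <- c(rep(TRUE, nOn), rep(FALSE, nOff))
    pairDup <- c(dup, rep(FALSE, nOff))
    nAll <- nOn + nOff
    pairProper <- runif(nAll) >= params@improperPairFraction
    pairId <- sprintf("%s_p%07d", sampleName, seq_len(nAll))
    reads <- data.frame(
      read_id = c(paste0(pairId, "/1"), paste0(pairId, "/2")),
      pair_id = rep(pairId, 2L),
      sample = sampleName,
      chrom = rep(pairChrom, 2L),
      pos = c(pairStart, pairStart + span),
      span = span,
      mapped = TRUE,
      on_target = rep(pairOn, 2L),
      proper_pair = rep(pairProper, 2L),
      duplicate = rep(pairDup, 2L),
      source_line = rep(pairLine, 2L),
      molecule_id = rep(pairMolId, 2L),
      stringsAsFactors = FALSE)
    rrt <- ReadRecordTable(reads)
    allAlts <- rbind(own$alts, if (!is.null(coc)) coc$alts)
    act <- .pileup(reads, allAlts, regions, params, sampleName)
    new("SimulatedDataset",
        readRecords = setNames(list(rrt), sampleName),
        alleleCounts = setNames(list(act), sampleName),
        truth = list(genomes = genomes, pool = pool,
                     catalog = genotypeCatalog(genomes),
                     regions = regions, cocaptured = cocaptured),
        provenance = list(sample = sampleName,
                          seed = params@seed,
                          params = .paramsAsList(params),
                          generated = "PoolCapQC simulateReads"))
  })
}

.paramsAsList <- function(p) {
  sn <- slotNames("LibrarySimParams")
  setNames(lapply(sn, function(s) slot(p, s)), sn)
}

## Pileup of pass-filter reads: truth alleles from molecule haplotypes, then
## per-base errors as uniformly placed distinct (read, offset) cells.
.pileup <- function(reads, alts, regions, params, sampleName) {
  pf <- reads[reads$mapped & !reads$duplicate & reads$proper_pair &
                reads$on_target, , drop = FALSE]
  depth <- .depthOverRegions(pf, regions)
  key <- .posKey(depth$chrom, depth$pos)
  ## truth alt counts from molecule haplotypes
  altCount <- data.frame(chrom = character(), pos = integer(),
                         allele = character(), count = numeric(),
                         stringsAsFactors = FALSE)
  hasAlt <- !is.na(pf$molecule_id) & pf$molecule_id %in% alts$molecule_id
  if (any(hasAlt) && nrow(alts)) {
    j <- merge(pf[hasAlt, c("molecule_id", "pos", "span")], alts,
               by = "molecule_id")
    j <- j[j$pos.y >= j$pos.x & j$pos.y <= j$pos.x + j$span - 1L, ,
           drop = FALSE]
    if (nrow(j)) {
      agg <- stats::aggregate(list(count = rep(1, nrow(j))),
                              by = list(chrom = j$chrom, pos = j$pos.y,
                                        allele = j$alt), FUN = sum)
      altCount <- agg
    }
  }
  ## per-base substitution errors on pass-filter reads
  errDelta <- NULL
  if (params@perBaseErrorRate > 0 && nrow(pf)) {
    span <- as.integer(params@readSpan)
    totalBases <- nrow(pf) * span
    nErr <- rbinom(1L, totalBases, params@perBaseErrorRate)
    if (nErr > 0L) {
      cells <- sample.int(totalBases, nErr)
      ri <- (cells - 1L) %/% span + 1L
      off <- (cells - 1L) %% span
      p <- pf$pos[ri] + off
      chrom <- pf$chrom[ri]
      inTarget <- .posKey(chrom, p) %in% key
      ri <- ri[inTarget]; p <- p[inTarget]; chrom <- chrom[inTarget]
      if (length(p)) {
        templ <- syntheticReference(p)
        ak <- paste(pf$molecule_id[ri], chrom, p)
        if (nrow(alts)) {
          hit <- match(ak, paste(alts$molecule_id, alts$chrom, alts$pos))
          templ[!is.na(hit)] <- alts$alt[hit[!is.na(hit)]]
        }
        newAll <- vapply(templ,
                         function(t) sample(setdiff(.NUC, t), 1L), "",
                         USE.NAMES = FALSE)
        errDelta <- rbind(
          data.frame(chrom = chrom, pos = p, allele = templ, count = -1,
                     stringsAsFactors = FALSE),
          data.frame(chrom = chrom, pos = p, allele = newAll, count = 1,
                     stringsAsFactors = FALSE))
      }
    }
  }
  ## assemble counts: implied reference + alt + error deltas
  refCount <- depth$depth
  if (nrow(altCount)) {
    sumAlt <- tapply(altCount$count, .posKey(altCount$chrom, altCount$pos),
                     sum)
    hit <- match(names(sumAlt), key)
    refCount[hit] <- refCount[hit] - as.numeric(sumAlt)
  }
  counts <- rbind(
    data.frame(chrom = depth$chrom, pos = depth$pos,
               allele = syntheticReference(depth$pos), count = refCount,
               stringsAsFactors = FALSE),
    altCount, errDelta)
  agg <- stats::aggregate(list(count = counts$count),
                          by = list(chrom = counts$chrom, pos = counts$pos,
                                    allele = counts$allele), FUN = sum)
  agg <- agg[agg$count != 0 |
               agg$allele == syntheticReference(agg$pos), , drop = FALSE]
  agg <- agg[order(agg$chrom, agg$pos, agg$allele), , drop = FALSE]
  AlleleCountTable(sampleName, agg,
                   depth[, c("chrom", "pos", "depth")])
}
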