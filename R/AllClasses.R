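## Central S4 containers. All genomic tables use 1-based positions with an
## explicit `chrom` column; BED input/output converts at the boundary.

.checkCols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    return(sprintf("%s is missing column(s): %s", what,
                   paste(miss, collapse = ", ")))
  NULL
}

#' PoolSpec: constituents and mixing ratios of a pooled specimen
#'
#' Defines every expected-MAF computation: an ordered set of constituent
#' cell-line identifiers and their non-negative mixing ratios, which must sum
#' to 1 (tolerance 1e-9).
#'
#' @slot constituents character vector of constituent line identifiers.
#' @slot ratios numeric vector of mixing ratios, parallel to
#'   \code{constituents}.
#'
#' @seealso [PoolSpec()], [expectedMaf()], [buildTruthSet()]
#' @exportClass PoolSpec
setClass("PoolSpec",
  representation(constituents = "character", ratios = "numeric"))

setValidity("PoolSpec", function(object) {
  msg <- character()
  if (length(object@constituents) < 1L)
    msg <- c(msg, "a pool needs at least one constituent")
  if (length(object@constituents) != length(object@ratios))
    msg <- c(msg, "constituents and ratios differ in length")
  if (anyDuplicated(object@constituents))
    msg <- c(msg, "constituent identifiers must be unique")
  if (any(object@ratios < 0))
    msg <- c(msg, "ratios must be non-negative")
  if (length(object@ratios) &&
      abs(sum(object@ratios) - 1) >= 1e-9)
    msg <- c(msg, sprintf("ratios must sum to 1 (got %.12f)",
                          sum(object@ratios)))
  if (length(msg)) msg else TRUE
})

#' CellLineGenome: diploid variant truth for one simulated cell line
#'
#' Variant states of a single constituent line: each row is one alternate
#' allele at one position with a genotype state of \code{"het"} or
#' \code{"hom"}. The reference base is implied by [syntheticReference()].
#'
#' @slot lineId single line identifier.
#' @slot variants data.frame with columns \code{chrom}, \code{pos},
#'   \code{ref}, \code{alt}, \code{genotype}; at most one alternate genotype
#'   per position.
#'
#' @seealso [simulateGenotypes()], [genotypeCatalog()]
#' @exportClass CellLineGenome
setClass("CellLineGenome",
  representation(lineId = "character", variants = "data.frame"))

setValidity("CellLineGenome", function(object) {
  msg <- character()
  if (length(object@lineId) != 1L)
    msg <- c(msg, "lineId must be a single identifier")
  bad <- .checkCols(object@variants,
                    c("chrom", "pos", "ref", "alt", "genotype"), "variants")
  if (!is.null(bad)) return(bad)
  v <- object@variants
  if (nrow(v)) {
    if (!all(v$genotype %in% c("het", "hom")))
      msg <- c(msg, "genotype states must be 'het' or 'hom'")
    if (anyDuplicated(paste(v$chrom, v$pos)))
      msg <- c(msg, "at most one alternate genotype per position per line")
  }
  if (length(msg)) msg else TRUE
})

#' GenotypeCatalog: per-line, per-position allele frequencies
#'
#' Observed allele frequencies from deep sequencing of individual constituent
#' lines (or from simulation truth). One row per (line, position, allele)
#' with its frequency and the total depth at that position. Alleles absent
#' from the table have frequency 0. SNV alleles are single bases; indel
#' alleles are encoded \code{"+SEQ"} (insertion) / \code{"-SEQ"} (deletion).
#'
#' @slot calls data.frame with columns \code{line}, \code{chrom}, \code{pos},
#'   \code{allele}, \code{freq}, \code{depth}.
#' @slot lines character vector of catalogued line identifiers.
#'
#' @seealso [genotypeCatalog()], [classifyGenotypes()],
#'   [buildBackgroundCatalog()]
#' @exportClass GenotypeCatalog
setClass("GenotypeCatalog",
  representation(calls = "data.frame", lines = "character"))

setValidity("GenotypeCatalog", function(object) {
  bad <- .checkCols(object@calls,
                    c("line", "chrom", "pos", "allele", "freq", "depth"),
                    "calls")
  if (!is.null(bad)) return(bad)
  cc <- object@calls
  msg <- character()
  if (nrow(cc)) {
    if (any(cc$freq < 0 | cc$freq > 1))
      msg <- c(msg, "frequencies must lie in [0, 1]")
    if (any(cc$depth <= 0))
      msg <- c(msg, "depth must be positive at catalogued positions")
    if (!all(cc$line %in% object@lines))
      msg <- c(msg, "calls reference lines absent from the line list")
    ## per (line, position) the four nucleotide frequencies may not exceed 1
    snv <- cc[cc$allele %in% c("A", "C", "G", "T"), , drop = FALSE]
    if (nrow(snv)) {
      tot <- tapply(snv$freq, paste(snv$line, snv$chrom, snv$pos), sum)
      if (any(tot > 1 + 1e-6))
        msg <- c(msg, "nucleotide frequencies at a position exceed 1")
    }
  }
  if (length(msg)) msg else TRUE
})

#' VariantTruthSet: expected variants of a pooled specimen
#'
#' One record per (position, alternate allele) with nonzero expected MAF in
#' the pool, carrying the variant class and, for indels, the indel length.
#'
#' @slot records data.frame with columns \code{chrom}, \code{pos},
#'   \code{ref}, \code{alt}, \code{class} (\code{"SNV"}/\code{"indel"}),
#'   \code{indel_length}, \code{expected_maf}, \code{pool}.
#'
#' @seealso [buildTruthSet()], [detectionSensitivity()], [maskLowCoverage()]
#' @exportClass VariantTruthSet
setClass("VariantTruthSet", representation(records = "data.frame"))

setValidity("VariantTruthSet", function(object) {
  bad <- .checkCols(object@records,
                    c("chrom", "pos", "ref", "alt", "class",
                      "indel_length", "expected_maf", "pool"), "records")
  if (!is.null(bad)) return(bad)
  r <- object@records
  msg <- character()
  if (nrow(r)) {
    if (any(r$expected_maf <= 0 | r$expected_maf > 1))
      msg <- c(msg, "expected_maf must lie in (0, 1]")
    if (!all(r$class %in% c("SNV", "indel")))
      msg <- c(msg, "class must be 'SNV' or 'indel'")
    if (any(r$class == "SNV" & r$indel_length != 0))
      msg <- c(msg, "SNV records must have indel_length 0")
  }
  if (length(msg)) msg else TRUE
})

#' BackgroundAlleleCatalog: alleles absent from every constituent
#'
#' The set of (position, allele) pairs whose frequency is at most the
#' background threshold (default 1\%) in every constituent line, drawn from
#' the universe of 4 nucleotides at every targeted base. Reads supporting a
#' background allele in a pool measure sequencing error plus contamination.
#'
#' @slot alleles data.frame with columns \code{chrom}, \code{pos},
#'   \code{allele}.
#' @slot universeSize number of possible alleles, 4 x target span.
#' @slot span target span in bp.
#'
#' @seealso [buildBackgroundCatalog()], [backgroundRates()]
#' @exportClass BackgroundAlleleCatalog
setClass("BackgroundAlleleCatalog",
  representation(alleles = "data.frame", universeSize = "numeric",
                 span = "numeric"))

setValidity("BackgroundAlleleCatalog", function(object) {
  bad <- .checkCols(object@alleles, c("chrom", "pos", "allele"), "alleles")
  if (!is.null(bad)) return(bad)
  msg <- character()
  if (object@universeSize != 4 * object@span)
    msg <- c(msg, "universeSize must equal 4 x span")
  if (nrow(object@alleles) > object@universeSize)
    msg <- c(msg, "catalogue exceeds the allele universe")
  if (length(msg)) msg else TRUE
})

#' ReadRecordTable: minimal per-read alignment facts
#'
#' One row per read with the flags that drive filter accounting and coverage:
#' mapped, duplicate, proper-pair and on-target status, plus position and
#' span. Mates share a \code{pair_id} so down-sampling can keep or drop both
#' together. Simulated reads also carry their source line and unique-molecule
#' identifier.
#'
#' @slot reads data.frame with columns \code{read_id}, \code{pair_id},
#'   \code{sample}, \code{chrom}, \code{pos}, \code{span}, \code{mapped},
#'   \code{on_target}, \code{proper_pair}, \code{duplicate},
#'   \code{source_line}, \code{molecule_id}.
#'
#' @seealso [filterReads()], [downsampleReads()], [coverageProfile()],
#'   [readRecordsFromSam()]
#' @exportClass ReadRecordTable
setClass("ReadRecordTable", representation(reads = "data.frame"))

.READ_COLS <- c("read_id", "pair_id", "sample", "chrom", "pos", "span",
                "mapped", "on_target", "proper_pair", "duplicate",
                "source_line", "molecule_id")

setValidity("ReadRecordTable", function(object) {
  bad <- .checkCols(object@reads, .READ_COLS, "reads")
  if (!is.null(bad)) return(bad)
  r <- object@reads
  msg <- character()
  for (fl in c("mapped", "on_target", "proper_pair", "duplicate"))
    if (!is.logical(r[[fl]]))
      msg <- c(msg, sprintf("flag column '%s' must be logical", fl))
  if (nrow(r) && any(r$span <= 0))
    msg <- c(msg, "read spans must be positive")
  if (length(msg)) msg else TRUE
})

#' AlleleCountTable: post-filter per-position allele counts
#'
#' The pileup on which error, contamination and sensitivity computations
#' operate: per (position, allele) the supporting read count after duplicate
#' removal, and per position the total depth. Counts at a position sum to
#' that position's depth; alleles without a row have count 0.
#'
#' @slot sample sample identifier.
#' @slot counts data.frame with columns \code{chrom}, \code{pos},
#'   \code{allele}, \code{count}.
#' @slot depth data.frame with columns \code{chrom}, \code{pos},
#'   \code{depth}.
#'
#' @seealso [backgroundRates()], [naiveDetector()], [estimateContamination()]
#' @exportClass AlleleCountTable
setClass("AlleleCountTable",
  representation(sample = "character", counts = "data.frame",
                 depth = "data.frame"))

setValidity("AlleleCountTable", function(object) {
  bad <- .checkCols(object@counts, c("chrom", "pos", "allele", "count"),
                    "counts")
  if (!is.null(bad)) return(bad)
  bad <- .checkCols(object@depth, c("chrom", "pos", "depth"), "depth")
  if (!is.null(bad)) return(bad)
  msg <- character()
  if (nrow(object@counts)) {
    if (any(object@counts$count < 0))
      msg <- c(msg, "counts must be non-negative")
    key <- paste(object@counts$chrom, object@counts$pos)
    tot <- tapply(object@counts$count, key, sum)
    dep <- setNames(object@depth$depth,
                    paste(object@depth$chrom, object@depth$pos))
    common <- intersect(names(tot), names(dep))
    if (length(common) && any(abs(tot[common] - dep[common]) > 1e-9))
      msg <- c(msg, "allele counts at a position must sum to its depth")
    if (!all(names(tot) %in% names(dep)))
      msg <- c(msg, "counted positions missing from the depth table")
  }
  if (length(msg)) msg else TRUE
})

#' CoverageProfile: per-base depth over the target
#'
#' Depth of every targeted base, with the mean depth and the coverage
#' efficiency curve (percent of targeted bases at or above any depth)
#' derivable from it.
#'
#' @slot depth data.frame with columns \code{chrom}, \code{pos},
#'   \code{depth}, one row per targeted base.
#'
#' @seealso [coverageProfile()], [percentTargetsAbove()],
#'   [coverageEfficiency()]
#' @exportClass CoverageProfile
setClass("CoverageProfile", representation(depth = "data.frame"))

setValidity("CoverageProfile", function(object) {
  bad <- .checkCols(object@depth, c("chrom", "pos", "depth"), "depth")
  if (!is.null(bad)) return(bad)
  if (nrow(object@depth) && any(object@depth$depth < 0))
    return("depths must be non-negative")
  TRUE
})

#' FilterBreakdown: read-filter accounting
#'
#' Partition of all reads into unmapped, duplicate, improper-pair,
#' off-target and pass-filter categories (each read assigned to its first
#' failing category), with rates as fractions of the total.
#'
#' @slot counts named numeric: \code{total}, \code{unmapped},
#'   \code{duplicate}, \code{improper_pair}, \code{off_target}, \code{pass}.
#'
#' @seealso [filterReads()]
#' @exportClass FilterBreakdown
setClass("FilterBreakdown", representation(counts = "numeric"))

.FILTER_CATS <- c("unmapped", "duplicate", "improper_pair", "off_target",
                  "pass")

setValidity("FilterBreakdown", function(object) {
  need <- c("total", .FILTER_CATS)
  if (!all(need %in% names(object@counts)))
    return(sprintf("counts must be named: %s", paste(need, collapse = ", ")))
  if (sum(object@counts[.FILTER_CATS]) != object@counts[["total"]])
    return("filter categories must partition the total")
  TRUE
})

#' ErrorDistribution: background error-rate distribution
#'
#' One observed frequency per catalogued background allele (0 when no read
#' supports it), with summary mean and standard deviation. Zero-depth
#' catalogued positions are excluded and counted.
#'
#' @slot freq numeric vector of per-allele frequencies.
#' @slot mean,sd summary statistics over \code{freq}.
#' @slot nExcluded number of catalogued alleles excluded for zero depth.
#'
#' @seealso [backgroundRates()], [errorHistogram()]
#' @exportClass ErrorDistribution
setClass("ErrorDistribution",
  representation(freq = "numeric", mean = "numeric", sd = "numeric",
                 nExcluded = "numeric"))

setValidity("ErrorDistribution", function(object) {
  if (length(object@freq) && any(object@freq < 0 | object@freq > 1))
    return("frequencies must lie in [0, 1]")
  TRUE
})

#' ContaminationReport: single- vs multiplex contamination comparison
#'
#' Per-sample test-group and control-group mean background rates under each
#' plex condition, and the contamination estimate: multiplex test-group mean
#' minus single-plex test-group mean. Control-group means travel alongside
#' as the sanity check (no contamination pathway touches shared-background
#' alleles).
#'
#' @slot perSample data.frame with columns \code{sample}, \code{condition},
#'   \code{test_mean}, \code{control_mean}.
#' @slot testMeans,controlMeans named numeric, one value per condition
#'   (\code{single}, \code{multi}), averaged across samples.
#' @slot estimate multiplex test mean minus single-plex test mean.
#'
#' @seealso [estimateContamination()]
#' @exportClass ContaminationReport
setClass("ContaminationReport",
  representation(perSample = "data.frame", testMeans = "numeric",
                 controlMeans = "numeric", estimate = "numeric"))

setValidity("ContaminationReport", function(object) {
  need <- c("single", "multi")
  if (!all(need %in% names(object@testMeans)) ||
      !all(need %in% names(object@controlMeans)))
    return("testMeans and controlMeans need 'single' and 'multi' entries")
  est <- object@testMeans[["multi"]] - object@testMeans[["single"]]
  if (abs(est - object@estimate) > 1e-12)
    return("estimate must equal multi test mean minus single test mean")
  TRUE
})

#' CallSet: variant calls from one library
#'
#' One record per (position, alternate allele, class) with the observed
#' allele fraction; produced by an external caller (ingested from VCF) or by
#' [naiveDetector()].
#'
#' @slot library library/sample identifier.
#' @slot calls data.frame with columns \code{chrom}, \code{pos}, \code{ref},
#'   \code{alt}, \code{class}, \code{af}.
#'
#' @seealso [naiveDetector()], [readCallSet()], [detectionSensitivity()],
#'   [concordanceClassify()]
#' @exportClass CallSet
setClass("CallSet",
  representation(library = "character", calls = "data.frame"))

setValidity("CallSet", function(object) {
  bad <- .checkCols(object@calls,
                    c("chrom", "pos", "ref", "alt", "class", "af"), "calls")
  if (!is.null(bad)) return(bad)
  cc <- object@calls
  if (nrow(cc) && anyDuplicated(paste(cc$chrom, cc$pos, cc$alt, cc$class)))
    return("one record per (position, alt, class) per library")
  TRUE
})

#' SensitivityTable: detection sensitivity by expected-MAF bin
#'
#' Expected and detected truth-variant counts per expected-MAF bin, with
#' sensitivity = detected / expected and the overall fraction.
#'
#' @slot bins data.frame with columns \code{bin}, \code{maf_lo},
#'   \code{maf_hi}, \code{expected}, \code{detected}, \code{sensitivity},
#'   \code{percent} (rounded to integer percent).
#' @slot overall overall detected / expected.
#'
#' @seealso [detectionSensitivity()]
#' @exportClass SensitivityTable
setClass("SensitivityTable",
  representation(bins = "data.frame", overall = "numeric"))

setValidity("SensitivityTable", function(object) {
  b <- object@bins
  bad <- .checkCols(b, c("bin", "maf_lo", "maf_hi", "expected", "detected",
                         "sensitivity", "percent"), "bins")
  if (!is.null(bad)) return(bad)
  if (nrow(b) && any(b$detected > b$expected))
    return("detected cannot exceed expected in any bin")
  ok <- b$expected > 0
  if (any(ok) && any(b$sensitivity[ok] < 0 | b$sensitivity[ok] > 1))
    return("sensitivity must lie in [0, 1]")
  TRUE
})

#' ConcordanceTable: multi-library agreement of variant calls
#'
#' Each variant in the union of k call sets labelled by the number of
#' libraries detecting it, with summary counts per multiplicity class
#' (for k = 3: private, shared-by-2, found-in-3).
#'
#' @slot variants data.frame with columns \code{chrom}, \code{pos},
#'   \code{alt}, \code{class}, \code{n_libraries}.
#' @slot classes named numeric of counts per multiplicity (1..k).
#' @slot k number of libraries compared.
#'
#' @seealso [concordanceClassify()]
#' @exportClass ConcordanceTable
setClass("ConcordanceTable",
  representation(variants = "data.frame", classes = "numeric",
                 k = "numeric"))

setValidity("ConcordanceTable", function(object) {
  bad <- .checkCols(object@variants,
                    c("chrom", "pos", "alt", "class", "n_libraries"),
                    "variants")
  if (!is.null(bad)) return(bad)
  if (sum(object@classes) != nrow(object@variants))
    return("class counts must sum to the union size")
  TRUE
})

#' SimulatedDataset: everything one simulation run produced
#'
#' Read records and allele counts per sample, the generating truth
#' (genomes, catalog, pool specs, regions) and a provenance record of
#' parameters and seed, sufficient to regenerate identical tables.
#'
#' @slot readRecords named list of [ReadRecordTable-class], one per sample.
#' @slot alleleCounts named list of [AlleleCountTable-class], one per sample.
#' @slot truth list: \code{genomes}, \code{catalog}, \code{pools},
#'   \code{regions}.
#' @slot provenance list of parameters and seeds.
#'
#' @seealso [simulateReads()], [writeDataset()]
#' @exportClass SimulatedDataset
setClass("SimulatedDataset",
  representation(readRecords = "list", alleleCounts = "list",
                 truth = "list", provenance = "list"))
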