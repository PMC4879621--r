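## MAF-stratified detection sensitivity, low-coverage masking and
## multi-library concordance.

.truthKey <- function(df) paste(df$chrom, df$pos, df$alt, df$class)

#' Detection sensitivity by expected-MAF bin
#'
#' A truth record counts as detected iff a call matches its position,
#' alternate allele and variant class exactly (indel alleles are compared on
#' their left-aligned \code{"+SEQ"}/\code{"-SEQ"} encoding). Truth records
#' are binned by expected MAF into left-open, right-closed bins over the
#' supplied edges (default (0, 0.05], (0.05, 0.10], (0.10, 0.15],
#' (0.15, 1]) and the per-bin and overall sensitivity reported, both as the
#' raw fraction and rounded to integer percent.
#'
#' @param truth a [VariantTruthSet-class] (non-empty).
#' @param calls a [CallSet-class], or a list of them (their union detects).
#' @param bins strictly increasing MAF edges covering every truth MAF.
#' @return A [SensitivityTable-class].
#' @examples
#' tr <- new("VariantTruthSet", records = data.frame(
#'   chrom = "chr1", pos = 1:4, ref = "A", alt = "G", class = "SNV",
#'   indel_length = 0L, expected_maf = c(0.03, 0.08, 0.2, 0.6),
#'   pool = "p1"))
#' cs <- CallSet("lib1", data.frame(chrom = "chr1", pos = c(2:4),
#'   ref = "A", alt = "G", class = "SNV", af = c(0.07, 0.18, 0.55)))
#' detectionSensitivity(tr, cs)
#' @export
detectionSensitivity <- function(truth, calls,
                                 bins = c(0, 0.05, 0.10, 0.15, 1)) {
  stopifnot(is(truth, "VariantTruthSet"))
  tr <- truthRecords(truth)
  if (nrow(tr) == 0L) stop("empty truth set")
  if (any(diff(bins) <= 0))
    stop("bins must be strictly increasing (non-overlapping)")
  if (is(calls, "CallSet")) calls <- list(calls)
  callKeys <- unique(unlist(lapply(calls,
                                   function(cs) .truthKey(callTable(cs)))))
  detected <- .truthKey(tr) %in% callKeys
  bi <- cut(tr$expected_maf, bins, right = TRUE, include.lowest = FALSE)
  if (anyNA(bi))
    stop("some truth MAFs fall outside the bin edges")
  expct <- as.numeric(table(bi))
  det <- as.numeric(tapply(detected, bi, sum, default = 0))
  det[is.na(det)] <- 0
  sens <- ifelse(expct > 0, det / expct, NA_real_)
  tab <- data.frame(bin = levels(bi),
                    maf_lo = bins[-length(bins)], maf_hi = bins[-1L],
                    expected = expct, detected = det,
                    sensitivity = sens,
                    percent = ifelse(is.na(sens), NA_real_,
                                     round(100 * sens)),
                    stringsAsFactors = FALSE)
  new("SensitivityTable", bins = tab,
      overall = sum(det) / sum(expct))
}

#' Naive threshold variant detector
#'
#' Plumbing stand-in for a somatic caller, so the sensitivity machinery can
#' run on synthetic pileups: emits every non-reference allele whose
#' frequency is at least \code{minFraction} and whose supporting read count
#' is at least \code{minAltReads}. It implements no error model beyond the
#' two thresholds.
#'
#' @param counts an [AlleleCountTable-class].
#' @param minFraction minimum allele fraction (> 0).
#' @param minAltReads minimum supporting reads (> 0).
#' @param reference optional data.frame (\code{chrom}, \code{pos},
#'   \code{ref}); default the [syntheticReference()] rule.
#' @return A [CallSet-class] named after the sample.
#' @export
naiveDetector <- function(counts, minFraction = 0.02, minAltReads = 5,
                          reference = NULL) {
  stopifnot(is(counts, "AlleleCountTable"))
  if (minFraction <= 0 || minAltReads <= 0)
    stop("thresholds must be positive")
  cnt <- alleleCounts(counts)
  dep <- depthTable(counts)
  ref <- if (is.null(reference)) syntheticReference(cnt$pos) else
    reference$ref[match(.posKey(cnt$chrom, cnt$pos),
                        .posKey(reference$chrom, reference$pos))]
  d <- dep$depth[match(.posKey(cnt$chrom, cnt$pos),
                       .posKey(dep$chrom, dep$pos))]
  af <- ifelse(d > 0, cnt$count / d, 0)
  sel <- !is.na(ref) & cnt$allele != ref & af >= minFraction &
    cnt$count >= minAltReads
  out <- data.frame(chrom = cnt$chrom[sel], pos = cnt$pos[sel],
                    ref = ref[sel], alt = cnt$allele[sel],
                    class = ifelse(cnt$allele[sel] %in% .NUC, "SNV",
                                   "indel"),
                    af = af[sel], stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos, out$alt), , drop = FALSE]
  CallSet(sampleId(counts), out)
}

#' Mask truth variants at low-coverage positions
#'
#' Drops truth records at positions whose mean depth across a panel of
#' reference coverage profiles falls below a threshold. This mirrors the
#' practice of removing systematically under-covered target positions
#' (e.g. below 200x mean coverage over high-input reference libraries)
#' before scoring sensitivity, which isolates library performance from
#' capture-design cold spots.
#'
#' @param truth a [VariantTruthSet-class].
#' @param profiles list of [CoverageProfile-class] reference profiles; all
#'   truth positions must be present in each.
#' @param minMeanDepth threshold; records with mean depth < threshold are
#'   dropped (0 keeps everything).
#' @return A filtered [VariantTruthSet-class].
#' @export
maskLowCoverage <- function(truth, profiles, minMeanDepth) {
  stopifnot(is(truth, "VariantTruthSet"))
  if (is(profiles, "CoverageProfile")) profiles <- list(profiles)
  tr <- truthRecords(truth)
  if (nrow(tr) == 0L) return(truth)
  key <- .posKey(tr$chrom, tr$pos)
  depths <- vapply(profiles, function(p) {
    d <- depthTable(p)
    v <- d$depth[match(key, .posKey(d$chrom, d$pos))]
    if (anyNA(v))
      stop("truth position(s) absent from a reference coverage profile")
    as.numeric(v)
  }, numeric(nrow(tr)))
  mu <- if (is.null(dim(depths))) depths else rowMeans(depths)
  new("VariantTruthSet", records = {
    out <- tr[mu >= minMeanDepth, , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Classify variant concordance across libraries
#'
#' Labels every variant in the union of k call sets by the number of
#' libraries detecting it and tallies the multiplicity classes — for three
#' libraries: private to a library, shared by two, or found in all three.
#' The counts are invariant to the order of the libraries.
#'
#' @param callSets list of at least two [CallSet-class] objects.
#' @return A [ConcordanceTable-class].
#' @examples
#' mk <- function(lib, pos) CallSet(lib, data.frame(chrom = "chr1",
#'   pos = pos, ref = "A", alt = "G", class = "SNV", af = 0.5))
#' concordanceClassify(list(mk("a", c(1, 2)), mk("b", c(2, 3)),
#'                          mk("c", 2)))
#' @export
concordanceClassify <- function(callSets) {
  if (length(callSets) < 2L) stop("at least 2 call sets are required")
  k <- length(callSets)
  keys <- lapply(callSets, function(cs) unique(.truthKey(callTable(cs))))
  tab <- table(unlist(keys))
  allCalls <- do.call(rbind, lapply(callSets, function(cs)
    callTable(cs)[, c("chrom", "pos", "alt", "class")]))
  allCalls <- allCalls[!duplicated(.truthKey(allCalls)), , drop = FALSE]
  mult <- as.integer(tab[.truthKey(allCalls)])
  variants <- data.frame(allCalls, n_libraries = mult,
                         stringsAsFactors = FALSE)
  variants <- variants[order(variants$chrom, variants$pos, variants$alt), ,
                       drop = FALSE]
  rownames(variants) <- NULL
  lab <- vapply(seq_len(k), function(m) {
    if (m == 1L) "private"
    else if (k == 3L && m == 2L) "shared_by_2"
    else if (k == 3L && m == 3L) "found_in_3"
    else paste0("shared_by_", m)
  }, "")
  classes <- setNames(vapply(seq_len(k),
                             function(m) sum(mult == m), 0), lab)
  new("ConcordanceTable", variants = variants, classes = classes, k = k)
}
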