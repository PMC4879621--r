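## Accessors and show() methods. Slot access stays inside the package.

#' Accessors for PoolCapQC containers
#'
#' Small extractor functions for the package's S4 containers:
#' \code{constituents()}/\code{poolRatios()} for [PoolSpec-class];
#' \code{lineId()}/\code{variantTable()} for [CellLineGenome-class];
#' \code{catalogCalls()}/\code{catalogLines()} for [GenotypeCatalog-class];
#' \code{truthRecords()} for [VariantTruthSet-class];
#' \code{backgroundAlleles()}/\code{universeSize()} for
#' [BackgroundAlleleCatalog-class]; \code{readRecords()} for
#' [ReadRecordTable-class] and [SimulatedDataset-class];
#' \code{alleleCounts()}/\code{depthTable()}/\code{sampleId()} for
#' [AlleleCountTable-class]; \code{meanDepth()} for [CoverageProfile-class];
#' \code{filterCounts()}/\code{filterRates()} for [FilterBreakdown-class];
#' \code{errorFreqs()} for [ErrorDistribution-class];
#' \code{contaminationEstimate()} for [ContaminationReport-class];
#' \code{callTable()}/\code{libraryId()} for [CallSet-class];
#' \code{sensitivityBins()} for [SensitivityTable-class];
#' \code{concordanceClasses()} for [ConcordanceTable-class];
#' \code{truthData()}/\code{provenance()} for [SimulatedDataset-class].
#'
#' @param x the container.
#' @param ... for \code{readRecords()} and \code{alleleCounts()} on a
#'   [SimulatedDataset-class]: \code{sample}, the sample name to extract
#'   (omit for the full named list).
#' @return The corresponding slot value (data.frame, vector or list).
#' @name accessors
#' @aliases constituents poolRatios lineId variantTable catalogCalls
#'   catalogLines truthRecords backgroundAlleles universeSize readRecords
#'   alleleCounts depthTable sampleId meanDepth filterCounts filterRates
#'   errorFreqs contaminationEstimate callTable libraryId sensitivityBins
#'   concordanceClasses truthData provenance
#' @examples
#' p <- PoolSpec(paste0("L", 1:10), rep(0.1, 10))
#' constituents(p)
#' poolRatios(p)
NULL

#' @rdname accessors
#' @export
setMethod("constituents", "PoolSpec", function(x) x@constituents)
#' @rdname accessors
#' @export
setMethod("poolRatios", "PoolSpec",
          function(x) setNames(x@ratios, x@constituents))
#' @rdname accessors
#' @export
setMethod("lineId", "CellLineGenome", function(x) x@lineId)
#' @rdname accessors
#' @export
setMethod("variantTable", "CellLineGenome", function(x) x@variants)
#' @rdname accessors
#' @export
setMethod("catalogCalls", "GenotypeCatalog", function(x) x@calls)
#' @rdname accessors
#' @export
setMethod("catalogLines", "GenotypeCatalog", function(x) x@lines)
#' @rdname accessors
#' @export
setMethod("truthRecords", "VariantTruthSet", function(x) x@records)
#' @rdname accessors
#' @export
setMethod("backgroundAlleles", "BackgroundAlleleCatalog",
          function(x) x@alleles)
#' @rdname accessors
#' @export
setMethod("universeSize", "BackgroundAlleleCatalog",
          function(x) x@universeSize)
#' @rdname accessors
#' @export
setMethod("readRecords", "ReadRecordTable", function(x, ...) x@reads)
#' @rdname accessors
#' @export
setMethod("alleleCounts", "AlleleCountTable", function(x, ...) x@counts)
#' @rdname accessors
#' @export
setMethod("depthTable", "AlleleCountTable", function(x) x@depth)
#' @rdname accessors
#' @export
setMethod("sampleId", "AlleleCountTable", function(x) x@sample)
#' @rdname accessors
#' @export
setMethod("depthTable", "CoverageProfile", function(x) x@depth)
#' @rdname accessors
#' @export
setMethod("meanDepth", "CoverageProfile",
          function(x) if (nrow(x@depth)) mean(x@depth$depth) else 0)
#' @rdname accessors
#' @export
setMethod("filterCounts", "FilterBreakdown", function(x) x@counts)
#' @rdname accessors
#' @export
setMethod("filterRates", "FilterBreakdown", function(x) {
  n <- x@counts[["total"]]
  if (n == 0) return(setNames(rep(NA_real_, length(.FILTER_CATS)),
                              .FILTER_CATS))
  x@counts[.FILTER_CATS] / n
})
#' @rdname accessors
#' @export
setMethod("errorFreqs", "ErrorDistribution", function(x) x@freq)
#' @rdname accessors
#' @export
setMethod("contaminationEstimate", "ContaminationReport",
          function(x) x@estimate)
#' @rdname accessors
#' @export
setMethod("callTable", "CallSet", function(x) x@calls)
#' @rdname accessors
#' @export
setMethod("libraryId", "CallSet", function(x) x@library)
#' @rdname accessors
#' @export
setMethod("sensitivityBins", "SensitivityTable", function(x) x@bins)
#' @rdname accessors
#' @export
setMethod("concordanceClasses", "ConcordanceTable", function(x) x@classes)
#' @rdname accessors
#' @export
setMethod("readRecords", "SimulatedDataset", function(x, sample) {
  if (missing(sample)) x@readRecords else x@readRecords[[sample]]
})
#' @rdname accessors
#' @export
setMethod("alleleCounts", "SimulatedDataset", function(x, sample) {
  if (missing(sample)) x@alleleCounts else x@alleleCounts[[sample]]
})
#' @rdname accessors
#' @export
setMethod("truthData", "SimulatedDataset", function(x) x@truth)
#' @rdname accessors
#' @export
setMethod("provenance", "SimulatedDataset", function(x) x@provenance)

setMethod("show", "PoolSpec", function(object) {
  cat(sprintf("PoolSpec with %d constituent(s)\n",
              length(object@constituents)))
  print(poolRatios(object))
})

setMethod("show", "CellLineGenome", function(object) {
  v <- object@variants
  cat(sprintf("CellLineGenome '%s': %d variant(s) (%d het, %d hom)\n",
              object@lineId, nrow(v), sum(v$genotype == "het"),
              sum(v$genotype == "hom")))
})

setMethod("show", "GenotypeCatalog", function(object) {
  cat(sprintf("GenotypeCatalog: %d line(s), %d allele record(s)\n",
              length(object@lines), nrow(object@calls)))
})

setMethod("show", "VariantTruthSet", function(object) {
  r <- object@records
  cat(sprintf(
    "VariantTruthSet: %d record(s) (%d SNV, %d indel), expected MAF %s\n",
    nrow(r), sum(r$class == "SNV"), sum(r$class == "indel"),
    if (nrow(r)) sprintf("%.3f-%.3f", min(r$expected_maf),
                         max(r$expected_maf)) else "-"))
})

setMethod("show", "BackgroundAlleleCatalog", function(object) {
  cat(sprintf(
    "BackgroundAlleleCatalog: %d of %d possible alleles (span %d bp)\n",
    nrow(object@alleles), object@universeSize, object@span))
})

setMethod("show", "ReadRecordTable", function(object) {
  r <- object@reads
  cat(sprintf("ReadRecordTable: %d read(s) in %d pair(s)\n",
              nrow(r), length(unique(r$pair_id))))
})

setMethod("show", "AlleleCountTable", function(object) {
  cat(sprintf(
    "AlleleCountTable '%s': %d position(s), mean depth %.1f\n",
    object@sample, nrow(object@depth),
    if (nrow(object@depth)) mean(object@depth$depth) else 0))
})

setMethod("show", "CoverageProfile", function(object) {
  cat(sprintf("CoverageProfile: %d targeted base(s), mean depth %.2f\n",
              nrow(object@depth), meanDepth(object)))
})

setMethod("show", "FilterBreakdown", function(object) {
  cat("FilterBreakdown\n")
  print(rbind(count = object@counts[c("total", .FILTER_CATS)],
              rate = c(1, filterRates(object))))
})

setMethod("show", "ErrorDistribution", function(object) {
  cat(sprintf(
    "ErrorDistribution: %d allele(s), mean %.3g, sd %.3g (%d excluded)\n",
    length(object@freq), object@mean, object@sd, object@nExcluded))
})

setMethod("show", "ContaminationReport", function(object) {
  cat("ContaminationReport\n")
  cat(sprintf("  test-group means:    single %.4g  multi %.4g\n",
              object@testMeans[["single"]], object@testMeans[["multi"]]))
  cat(sprintf("  control-group means: single %.4g  multi %.4g\n",
              object@controlMeans[["single"]],
              object@controlMeans[["multi"]]))
  cat(sprintf("  contamination estimate: %.4g\n", object@estimate))
})

setMethod("show", "CallSet", function(object) {
  cat(sprintf("CallSet '%s': %d call(s)\n", object@library,
              nrow(object@calls)))
})

setMethod("show", "SensitivityTable", function(object) {
  cat(sprintf("SensitivityTable (overall %.3f)\n", object@overall))
  print(object@bins, row.names = FALSE)
})

setMethod("show", "ConcordanceTable", function(object) {
  cat(sprintf("ConcordanceTable over %d libraries\n", object@k))
  print(object@classes)
})

setMethod("show", "SimulatedDataset", function(object) {
  cat(sprintf("SimulatedDataset: %d sample(s): %s\n",
              length(object@readRecords),
              paste(names(object@readRecords), collapse = ", ")))
})
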