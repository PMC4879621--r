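## Filter accounting, seeded down-sampling, coverage and saturation curves.

#' Filter reads and account for every category
#'
#' Pass-filter reads are mapped, non-duplicate, properly paired and
#' on-target. Each failing read is assigned to the \emph{first} failing
#' category in the fixed priority order unmapped, duplicate, improper pair,
#' off-target, so the categories partition the total and the rates sum to 1.
#'
#' @param reads a [ReadRecordTable-class].
#' @return list with elements \code{pass} (a [ReadRecordTable-class] of
#'   pass-filter reads) and \code{breakdown} (a [FilterBreakdown-class]).
#' @examples
#' rg <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 5000))
#' g <- simulateGenotypes(2, rg, 0.005, seed = 1)
#' ds <- simulateReads(PoolSpec(names(g)), g,
#'                     LibrarySimParams(50, 2000, seed = 2), rg)
#' filterReads(readRecords(ds, "sample1"))$breakdown
#' @export
filterReads <- function(reads) {
  stopifnot(is(reads, "ReadRecordTable"))
  r <- readRecords(reads)
  cat_ <- rep("pass", nrow(r))
  cat_[!r$on_target] <- "off_target"
  cat_[!r$proper_pair] <- "improper_pair"
  cat_[r$duplicate] <- "duplicate"
  cat_[!r$mapped] <- "unmapped"
  counts <- vapply(.FILTER_CATS, function(k) sum(cat_ == k), 0)
  bd <- new("FilterBreakdown",
            counts = c(total = nrow(r), counts))
  list(pass = ReadRecordTable(r[cat_ == "pass", , drop = FALSE]),
       breakdown = bd)
}

## Raw mean depth: on-region bases of ALL reads (before filtering) per
## targeted base.
.rawMeanDepth <- function(r, regions) {
  if (nrow(r) == 0L) return(0)
  gr <- GRanges(r$chrom, IRanges(r$pos, r$pos + r$span - 1L))
  hits <- GenomicRanges::findOverlaps(gr, GenomicRanges::reduce(regions),
                                      ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  red <- GenomicRanges::reduce(regions)
  ov <- pmin(end(gr)[qi], end(red)[si]) - pmax(start(gr)[qi],
                                               start(red)[si]) + 1L
  sum(as.numeric(ov)) / targetSpan(regions)
}

#' In-silico down-sampling of reads
#'
#' Seeded uniform random selection of a read subset without replacement,
#' preserving pairs (both mates kept or dropped together). The target can be
#' a total read count, or a raw mean depth — defined as on-region bases of
#' all reads before any filtering divided by the target span — in which case
#' the pair count whose expected raw depth matches the target is selected.
#'
#' @param reads a [ReadRecordTable-class].
#' @param targetReads total read count to keep (at most the reads
#'   available).
#' @param targetDepth raw mean depth to aim for (requires \code{regions});
#'   give exactly one of \code{targetReads}/\code{targetDepth}.
#' @param regions target intervals, needed for \code{targetDepth}.
#' @param seed integer seed; the same seed reproduces the same subset.
#' @return A [ReadRecordTable-class] with the selected reads in their
#'   original order.
#' @export
downsampleReads <- function(reads, targetReads = NULL, targetDepth = NULL,
                            regions = NULL, seed) {
  stopifnot(is(reads, "ReadRecordTable"))
  if (is.null(targetReads) == is.null(targetDepth))
    stop("give exactly one of targetReads or targetDepth")
  r <- readRecords(reads)
  pairs <- unique(r$pair_id)
  nReads <- nrow(r)
  if (!is.null(targetDepth)) {
    if (is.null(regions)) stop("targetDepth mode needs regions")
    cur <- .rawMeanDepth(r, regions)
    if (cur <= 0) stop("reads have no on-region bases")
    if (targetDepth > cur)
      stop(sprintf("target depth %.1f exceeds available raw depth %.1f",
                   targetDepth, cur))
    nKeep <- round(targetDepth / cur * length(pairs))
  } else {
    if (targetReads > nReads)
      stop("target exceeds the available read count")
    nKeep <- round(targetReads / nReads * length(pairs))
  }
  if (nKeep >= length(pairs)) return(ReadRecordTable(r))
  keep <- withSeed(seed, sample(pairs, nKeep))
  ReadRecordTable(r[r$pair_id %in% keep, , drop = FALSE])
}

#' Per-base coverage profile over the target
#'
#' Accumulates read intervals into per-base depth over the (reduced) target
#' regions. Normally computed on pass-filter reads (see [filterReads()]);
#' passing unfiltered reads yields the raw profile.
#'
#' @param reads a [ReadRecordTable-class].
#' @param regions non-empty target intervals.
#' @return A [CoverageProfile-class].
#' @examples
#' rr <- ReadRecordTable(data.frame(
#'   read_id = "r1/1", pair_id = "r1", sample = "s", chrom = "chr1",
#'   pos = 1L, span = 100L, mapped = TRUE, on_target = TRUE,
#'   proper_pair = TRUE, duplicate = FALSE, source_line = NA,
#'   molecule_id = NA))
#' pr <- coverageProfile(rr,
#'   GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 1000)))
#' meanDepth(pr)              # 0.1
#' percentTargetsAbove(pr, 0) # 10
#' @export
coverageProfile <- function(reads, regions) {
  stopifnot(is(reads, "ReadRecordTable"))
  if (length(regions) == 0L) stop("empty target regions")
  new("CoverageProfile",
      depth = .depthOverRegions(readRecords(reads), regions))
}

#' Coverage efficiency: percent of targeted bases at or above a depth
#'
#' The empirical survival function of the per-base depth vector: for each
#' requested depth d, the percent of targeted bases with depth >= d.
#' Monotone non-increasing in d and 100 at d = 0.
#'
#' @param profile a [CoverageProfile-class].
#' @param depths numeric vector of depths d.
#' @return Named numeric vector of percentages.
#' @export
coverageEfficiency <- function(profile, depths) {
  stopifnot(is(profile, "CoverageProfile"))
  d <- depthTable(profile)$depth
  setNames(vapply(depths, function(x) 100 * mean(d >= x), 0),
           as.character(depths))
}

#' Percent of targeted bases covered above a depth
#'
#' Fraction of targeted bases with depth strictly greater than \code{d},
#' as a percent (e.g. "percentage of targets covered >500x").
#'
#' @param profile a [CoverageProfile-class].
#' @param d depth threshold.
#' @return Percentage in [0, 100].
#' @export
percentTargetsAbove <- function(profile, d) {
  stopifnot(is(profile, "CoverageProfile"))
  v <- depthTable(profile)$depth
  if (length(v) == 0L) return(0)
  100 * mean(v > d)
}

#' Saturation curve: pass-filter depth against total reads
#'
#' For each total-read count on the grid, down-sample the reads
#' (pair-preserving, seeded), filter, and record the mean pass-filter depth.
#' On complexity-limited libraries the curve is concave: beyond the unique-
#' molecule supply extra reads are mostly duplicates and add no depth.
#'
#' @param reads a [ReadRecordTable-class] (unfiltered).
#' @param regions target intervals.
#' @param grid increasing vector of total-read counts, each at most the
#'   available read count.
#' @param seed integer seed (each grid point uses a derived child seed).
#' @return data.frame with columns \code{total_reads}, \code{mean_depth}.
#' @export
saturationCurve <- function(reads, regions, grid, seed) {
  stopifnot(is(reads, "ReadRecordTable"))
  if (any(grid > nrow(readRecords(reads))))
    stop("grid point exceeds the available read count")
  md <- vapply(seq_along(grid), function(i) {
    sub <- downsampleReads(reads, targetReads = grid[i],
                           seed = childSeed(seed, paste0("sat", i)))
    meanDepth(coverageProfile(filterReads(sub)$pass, regions))
  }, 0)
  data.frame(total_reads = grid, mean_depth = md)
}

#' Read records from a SAM/BAM file
#'
#' Maps standard FLAG bits onto the package's read-record columns: 0x4
#' (unmapped), 0x400 (duplicate), 0x2 (proper pair); on-target is at least
#' 1 bp overlap with a target interval. SAM input is converted with
#' [Rsamtools::asBam()] first.
#'
#' @param path SAM or BAM file.
#' @param regions target intervals for the on-target flag.
#' @param sample sample identifier to record.
#' @return A [ReadRecordTable-class].
#' @export
readRecordsFromSam <- function(path, regions, sample = "sample1") {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("Rsamtools is required for SAM/BAM ingestion")
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE))
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "qwidth"))
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  flag <- x$flag
  mapped <- bitwAnd(flag, 0x4) == 0
  pos <- ifelse(is.na(x$pos), 0L, x$pos)
  span <- ifelse(is.na(x$qwidth) | x$qwidth <= 0, 1L, x$qwidth)
  df <- data.frame(
    read_id = paste0(x$qname, "/", ifelse(bitwAnd(flag, 0x40) > 0, 1L, 2L)),
    pair_id = x$qname,
    sample = sample,
    chrom = as.character(x$rname),
    pos = pos, span = span,
    mapped = mapped,
    on_target = FALSE,
    proper_pair = bitwAnd(flag, 0x2) > 0,
    duplicate = bitwAnd(flag, 0x400) > 0,
    source_line = NA_character_,
    molecule_id = NA_character_,
    stringsAsFactors = FALSE)
  ok <- df$mapped & !is.na(df$chrom)
  if (any(ok))
    df$on_target[ok] <- .readsOnTarget(df[ok, , drop = FALSE], regions)
  ReadRecordTable(df)
}
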