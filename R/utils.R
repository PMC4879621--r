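.NUC <- c("A", "C", "G", "T")

## Run expr with a private RNG stream; the caller's .Random.seed is untouched.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("a single integer seed is required")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Derive a child seed from a parent seed and a stage label, stays < 2^31.
childSeed <- function(seed, label) {
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483587) + 1L
}

.posKey <- function(chrom, pos) paste(chrom, pos, sep = ":")
.alleleKey <- function(chrom, pos, allele) paste(chrom, pos, allele, sep = ":")

#' Construct a PoolSpec
#'
#' @param constituents character vector of constituent line identifiers.
#' @param ratios mixing ratios (non-negative, summing to 1). Defaults to an
#'   equal mix.
#' @return A [PoolSpec-class].
#' @examples
#' PoolSpec(paste0("L", 1:10))            # equal 10-line pool
#' PoolSpec(c("a", "b"), c(0.75, 0.25))
#' @export
PoolSpec <- function(constituents,
                     ratios = rep(1 / length(constituents),
                                  length(constituents))) {
  new("PoolSpec", constituents = as.character(constituents),
      ratios = as.numeric(ratios))
}

#' Construct a ReadRecordTable from a data.frame
#'
#' @param reads data.frame carrying the columns listed under
#'   [ReadRecordTable-class].
#' @return A [ReadRecordTable-class].
#' @export
ReadRecordTable <- function(reads) {
  rownames(reads) <- NULL
  new("ReadRecordTable", reads = reads)
}

#' Construct an AlleleCountTable
#'
#' @param sample sample identifier.
#' @param counts data.frame (\code{chrom}, \code{pos}, \code{allele},
#'   \code{count}).
#' @param depth data.frame (\code{chrom}, \code{pos}, \code{depth}).
#' @return An [AlleleCountTable-class].
#' @export
AlleleCountTable <- function(sample, counts, depth) {
  rownames(counts) <- NULL
  rownames(depth) <- NULL
  new("AlleleCountTable", sample = as.character(sample),
      counts = counts, depth = depth)
}

#' Construct a CallSet
#'
#' @param library library identifier.
#' @param calls data.frame (\code{chrom}, \code{pos}, \code{ref},
#'   \code{alt}, \code{class}, \code{af}).
#' @return A [CallSet-class].
#' @export
CallSet <- function(library, calls) {
  rownames(calls) <- NULL
  new("CallSet", library = as.character(library), calls = calls)
}

#' Synthetic reference base at a position
#'
#' The simulator's implied reference genome: a deterministic cycle over
#' A, C, G, T by position (\code{ACGT[(pos mod 4) + 1]}). This is a synthetic
#' stand-in, not a real genome; it gives every targeted base a defined
#' reference allele without storing sequence, so the background-allele
#' universe (4 alleles per base) is well defined.
#'
#' @param pos integer vector of 1-based positions.
#' @return Character vector of reference bases.
#' @examples
#' syntheticReference(1:8)
#' @export
syntheticReference <- function(pos) .NUC[(as.integer(pos) %% 4L) + 1L]

#' Enumerate targeted bases
#'
#' Expands a set of target regions into one row per targeted base, after
#' reducing overlaps.
#'
#' @param regions a [GenomicRanges::GRanges] of target intervals.
#' @return data.frame with columns \code{chrom}, \code{pos}.
#' @export
targetPositions <- function(regions) {
  if (length(regions) == 0L) stop("empty target regions")
  red <- GenomicRanges::reduce(regions)
  data.frame(
    chrom = rep(as.character(seqnames(red)), width(red)),
    pos = unlist(lapply(seq_along(red),
                        function(i) seq(start(red)[i], end(red)[i]))),
    stringsAsFactors = FALSE)
}

#' Total targeted span in bp
#'
#' @param regions a [GenomicRanges::GRanges] of target intervals; overlaps
#'   are merged before summing.
#' @return Numeric span in bases.
#' @export
targetSpan <- function(regions) {
  if (length(regions) == 0L) stop("empty target regions")
  sum(as.numeric(width(GenomicRanges::reduce(regions))))
}

#' Size of the possible-allele universe of a target
#'
#' Four nucleotide alleles at every targeted base: \code{4 * targetSpan()}.
#' For a 2,171,886-bp panel this is 8,687,544 possible alleles.
#'
#' @param regions a [GenomicRanges::GRanges] of target intervals.
#' @return Numeric count of possible (position, allele) pairs.
#' @examples
#' rg <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 1000))
#' alleleUniverseSize(rg)  # 4000
#' @export
alleleUniverseSize <- function(regions) 4 * targetSpan(regions)

## Overlap of read intervals [pos, pos+span-1] with target regions, >=1 bp.
.readsOnTarget <- function(reads, regions) {
  if (nrow(reads) == 0L) return(logical(0))
  gr <- GRanges(reads$chrom, IRanges(reads$pos, reads$pos + reads$span - 1L))
  IRanges::overlapsAny(gr, regions, ignore.strand = TRUE)
}
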