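## Pool model: constituent genotype classification, expected pool MAF,
## truth sets and the background-allele catalogue.

#' Classify constituent genotypes by allele frequency
#'
#' Labels every catalogued non-reference nucleotide allele of every line as
#' heterozygous (frequency inside the het window, default 40-60\%,
#' boundaries included), homozygous (frequency strictly above the hom
#' threshold, default 90\%) or excluded. Excluded alleles do not enter
#' truth sets. Indel alleles (encoded \code{"+SEQ"}/\code{"-SEQ"}) are not
#' classified here; indel truth sets use observed frequencies directly (see
#' [buildTruthSet()]).
#'
#' @param catalog a [GenotypeCatalog-class].
#' @param hetWindow closed frequency interval for heterozygous calls,
#'   default \code{c(0.40, 0.60)}.
#' @param homThreshold strict lower bound for homozygous calls, default
#'   \code{0.90}.
#' @param reference optional data.frame (\code{chrom}, \code{pos},
#'   \code{ref}) giving the reference base at catalogued positions; by
#'   default the [syntheticReference()] rule.
#' @return data.frame with columns \code{line}, \code{chrom}, \code{pos},
#'   \code{ref}, \code{alt}, \code{freq}, \code{state} (\code{"het"},
#'   \code{"hom"} or \code{"excluded"}), carrying the full line list as
#'   \code{attr(, "lines")}.
#' @examples
#' g <- simulateGenotypes(3,
#'   GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 2000)),
#'   0.01, seed = 1)
#' head(classifyGenotypes(genotypeCatalog(g)))
#' @export
classifyGenotypes <- function(catalog, hetWindow = c(0.40, 0.60),
                              homThreshold = 0.90, reference = NULL) {
  stopifnot(is(catalog, "GenotypeCatalog"))
  if (length(hetWindow) != 2L || hetWindow[1] > hetWindow[2])
    stop("hetWindow must be an interval c(lo, hi) with lo <= hi")
  if (hetWindow[2] > homThreshold)
    stop("het window and hom threshold overlap")
  cc <- catalogCalls(catalog)
  if (nrow(cc) && anyNA(cc$depth))
    stop("catalogue is missing depth at some positions")
  cc <- cc[cc$allele %in% .NUC, , drop = FALSE]
  ref <- if (is.null(reference)) syntheticReference(cc$pos) else
    reference$ref[match(.posKey(cc$chrom, cc$pos),
                        .posKey(reference$chrom, reference$pos))]
  keep <- !is.na(ref) & cc$allele != ref
  cc <- cc[keep, , drop = FALSE]; ref <- ref[keep]
  state <- rep("excluded", nrow(cc))
  state[cc$freq >= hetWindow[1] & cc$freq <= hetWindow[2]] <- "het"
  state[cc$freq > homThreshold] <- "hom"
  out <- data.frame(line = cc$line, chrom = cc$chrom, pos = cc$pos,
                    ref = ref, alt = cc$allele, freq = cc$freq,
                    state = state, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "lines") <- catalogLines(catalog)
  out
}

.dosage <- function(state) {
  ifelse(state == "hom", 1.0, ifelse(state == "het", 0.5, 0.0))
}

#' Expected pool MAF of an allele
#'
#' The expected minor allele frequency of an allele in a pooled specimen:
#' the sum over constituents of mixing ratio times allele dosage, with
#' dosage 0.5 for a heterozygous, 1.0 for a homozygous and 0 for an absent
#' or excluded state (diploid constituents). A variant heterozygous in one
#' of 10 equally mixed lines therefore has expected MAF 0.05, the lower
#' bound of a 10-line pool's truth range.
#'
#' @param pool a [PoolSpec-class].
#' @param states classification table from [classifyGenotypes()].
#' @param chrom,pos,allele the allele to evaluate.
#' @return Expected MAF in [0, 1].
#' @examples
#' states <- data.frame(line = "L01", chrom = "chr1", pos = 101L,
#'                      ref = "A", alt = "G", freq = 0.5, state = "het")
#' attr(states, "lines") <- paste0("L", sprintf("%02d", 1:10))
#' expectedMaf(PoolSpec(attr(states, "lines")), states, "chr1", 101L, "G")
#' @export
expectedMaf <- function(pool, states, chrom, pos, allele) {
  stopifnot(is(pool, "PoolSpec"))
  known <- attr(states, "lines")
  if (is.null(known)) known <- unique(states$line)
  unknown <- setdiff(constituents(pool), known)
  if (length(unknown))
    stop("unknown constituent(s): ", paste(unknown, collapse = ", "))
  hit <- states[states$chrom == chrom & states$pos == pos &
                  states$alt == allele, , drop = FALSE]
  dos <- setNames(.dosage(hit$state), hit$line)
  r <- poolRatios(pool)
  sum(r * ifelse(is.na(dos[names(r)]), 0, dos[names(r)]))
}

#' Build a variant truth set for one or more pools
#'
#' For SNVs, expected MAF is mixing ratio times genotype dosage summed over
#' constituents ([expectedMaf()]); for indels, expected MAF is mixing ratio
#' times the constituent line's \emph{observed} indel frequency, since indel
#' variants originate from tumour lines whose allele fraction need not sit
#' at a diploid dosage. One record is emitted per (position, alternate
#' allele) with nonzero expected MAF; multiple pools yield concatenated
#' records tagged with their pool name.
#'
#' @param pool a [PoolSpec-class], or a named list of them.
#' @param catalog a [GenotypeCatalog-class] covering every constituent.
#' @param class \code{"SNV"} or \code{"indel"}.
#' @param hetWindow,homThreshold,reference passed to [classifyGenotypes()]
#'   for SNVs.
#' @return A [VariantTruthSet-class].
#' @examples
#' g <- simulateGenotypes(10,
#'   GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 10000)),
#'   0.01, seed = 7)
#' buildTruthSet(PoolSpec(names(g)), genotypeCatalog(g))
#' @export
buildTruthSet <- function(pool, catalog, class = c("SNV", "indel"),
                          hetWindow = c(0.40, 0.60), homThreshold = 0.90,
                          reference = NULL) {
  class <- match.arg(class)
  pools <- if (is(pool, "PoolSpec")) list(pool1 = pool) else pool
  if (length(pools) == 0L) stop("empty pool list")
  if (is.null(names(pools)))
    names(pools) <- paste0("pool", seq_along(pools))
  stopifnot(is(catalog, "GenotypeCatalog"))
  recs <- lapply(names(pools), function(pn) {
    p <- pools[[pn]]
    validObject(p)
    unknown <- setdiff(constituents(p), catalogLines(catalog))
    if (length(unknown))
      stop("pool constituent(s) absent from catalog: ",
           paste(unknown, collapse = ", "))
    r <- poolRatios(p)
    if (class == "SNV") {
      st <- classifyGenotypes(catalog, hetWindow, homThreshold, reference)
      st <- st[st$line %in% constituents(p) & st$state != "excluded", ,
               drop = FALSE]
      if (nrow(st) == 0L) return(NULL)
      contrib <- r[st$line] * .dosage(st$state)
      key <- paste(st$chrom, st$pos, st$alt)
      maf <- tapply(contrib, key, sum)
      first <- st[!duplicated(key), , drop = FALSE]
      maf <- maf[paste(first$chrom, first$pos, first$alt)]
      data.frame(chrom = first$chrom, pos = first$pos, ref = first$ref,
                 alt = first$alt, class = "SNV", indel_length = 0L,
                 expected_maf = as.numeric(maf), pool = pn,
                 stringsAsFactors = FALSE)
    } else {
      cc <- catalogCalls(catalog)
      cc <- cc[grepl("^[+-]", cc$allele) & cc$line %in% constituents(p) &
                 cc$freq > 0, , drop = FALSE]
      if (nrow(cc) == 0L) return(NULL)
      contrib <- r[cc$line] * cc$freq
      key <- paste(cc$chrom, cc$pos, cc$allele)
      maf <- tapply(contrib, key, sum)
      first <- cc[!duplicated(key), , drop = FALSE]
      maf <- maf[paste(first$chrom, first$pos, first$allele)]
      ref <- if (is.null(reference)) syntheticReference(first$pos) else
        reference$ref[match(.posKey(first$chrom, first$pos),
                            .posKey(reference$chrom, reference$pos))]
      data.frame(chrom = first$chrom, pos = first$pos, ref = ref,
                 alt = first$allele, class = "indel",
                 indel_length = nchar(sub("^[+-]", "", first$allele)),
                 expected_maf = as.numeric(maf), pool = pn,
                 stringsAsFactors = FALSE)
    }
  })
  recs <- do.call(rbind, recs)
  if (is.null(recs))
    recs <- data.frame(chrom = character(), pos = integer(),
                       ref = character(), alt = character(),
                       class = character(), indel_length = integer(),
                       expected_maf = numeric(), pool = character(),
                       stringsAsFactors = FALSE)
  recs <- recs[recs$expected_maf > 0, , drop = FALSE]
  recs <- recs[order(recs$pool, recs$chrom, recs$pos, recs$alt), ,
               drop = FALSE]
  rownames(recs) <- NULL
  new("VariantTruthSet", records = recs)
}

#' Catalogue background alleles of a target
#'
#' Enumerates the possible-allele universe (4 nucleotides at every targeted
#' base, i.e. \code{4 * span} alleles) and keeps the alleles whose frequency
#' is at most \code{maxFreq} (default 1\%) in \emph{every} catalogued line.
#' Positions absent from the catalogue are treated as reference-homozygous
#' in every line (simulation truth semantics), so their three non-reference
#' alleles are background; with \code{assumeCovered = FALSE} such positions
#' are instead excluded with a warning, which is the conservative choice for
#' real catalogues with incomplete coverage.
#'
#' @param catalog a [GenotypeCatalog-class] (all lines in one catalog; use
#'   [subsetCatalog()] for a per-sample catalogue).
#' @param regions [GenomicRanges::GRanges] target intervals.
#' @param maxFreq background threshold, default 0.01.
#' @param reference optional data.frame (\code{chrom}, \code{pos},
#'   \code{ref}); default [syntheticReference()].
#' @param assumeCovered treat uncatalogued positions as reference-homozygous
#'   (default TRUE).
#' @return A [BackgroundAlleleCatalog-class].
#' @examples
#' rg <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 1000))
#' g <- simulateGenotypes(4, rg, 0.01, seed = 3)
#' buildBackgroundCatalog(genotypeCatalog(g), rg)
#' @export
buildBackgroundCatalog <- function(catalog, regions, maxFreq = 0.01,
                                   reference = NULL, assumeCovered = TRUE) {
  stopifnot(is(catalog, "GenotypeCatalog"))
  if (maxFreq <= 0 || maxFreq >= 1) stop("maxFreq must lie in (0, 1)")
  tp <- targetPositions(regions)
  span <- targetSpan(regions)
  ref <- if (is.null(reference)) syntheticReference(tp$pos) else
    reference$ref[match(.posKey(tp$chrom, tp$pos),
                        .posKey(reference$chrom, reference$pos))]
  if (anyNA(ref)) stop("reference base missing for some targeted positions")
  cc <- catalogCalls(catalog)
  cc <- cc[cc$allele %in% .NUC, , drop = FALSE]
  lines <- catalogLines(catalog)
  key <- .posKey(tp$chrom, tp$pos)

  if (!assumeCovered && length(lines)) {
    perLinePos <- tapply(cc$line, .posKey(cc$chrom, cc$pos),
                         function(l) length(unique(l)))
    partial <- names(perLinePos)[perLinePos < length(lines)]
    uncov <- setdiff(key, names(perLinePos))
    dropKeys <- union(partial, uncov)
    if (length(dropKeys)) {
      warning(length(dropKeys),
              " position(s) not catalogued in every line were excluded")
      keep <- !(key %in% dropKeys)
      tp <- tp[keep, , drop = FALSE]; ref <- ref[keep]
      key <- key[keep]
    }
  }

  ## non-reference alleles: background unless some line shows > maxFreq
  cand <- data.frame(
    chrom = rep(tp$chrom, each = 3L),
    pos = rep(tp$pos, each = 3L),
    allele = unlist(lapply(ref, setdiff, x = .NUC)),
    stringsAsFactors = FALSE)
  high <- cc[cc$freq > maxFreq, , drop = FALSE]
  excl <- unique(.alleleKey(high$chrom, high$pos, high$allele))
  cand <- cand[!(.alleleKey(cand$chrom, cand$pos, cand$allele) %in% excl), ,
               drop = FALSE]

  ## reference allele: background only where every line's reference
  ## frequency (explicit, or 1 minus its non-reference total) is <= maxFreq
  refRows <- NULL
  if (nrow(cc) && length(lines)) {
    refAtPos <- ref[match(.posKey(cc$chrom, cc$pos), key)]
    isRef <- !is.na(refAtPos) & cc$allele == refAtPos
    nonRefTot <- tapply(cc$freq[!isRef],
                        paste(cc$line, .posKey(cc$chrom, cc$pos))[!isRef],
                        sum)
    explicitRef <- setNames(cc$freq[isRef],
                            paste(cc$line, .posKey(cc$chrom, cc$pos))[isRef])
    posCand <- unique(.posKey(cc$chrom, cc$pos))
    ok <- vapply(posCand, function(pk) {
      all(vapply(lines, function(l) {
        lk <- paste(l, pk)
        f <- if (lk %in% names(explicitRef)) explicitRef[[lk]]
        else if (lk %in% names(nonRefTot)) 1 - nonRefTot[[lk]]
        else 1
        f <= maxFreq
      }, NA))
    }, NA)
    if (any(ok)) {
      i <- match(posCand[ok], key)
      i <- i[!is.na(i)]
      if (length(i))
        refRows <- data.frame(chrom = tp$chrom[i], pos = tp$pos[i],
                              allele = ref[i], stringsAsFactors = FALSE)
    }
  }
  alleles <- rbind(cand, refRows)
  alleles <- alleles[order(alleles$chrom, alleles$pos, alleles$allele), ,
                     drop = FALSE]
  rownames(alleles) <- NULL
  new("BackgroundAlleleCatalog", alleles = alleles,
      universeSize = 4 * span, span = span)
}

#' Subset a genotype catalog to selected lines
#'
#' @param catalog a [GenotypeCatalog-class].
#' @param lines line identifiers to keep.
#' @return A [GenotypeCatalog-class] restricted to \code{lines}.
#' @export
subsetCatalog <- function(catalog, lines) {
  stopifnot(is(catalog, "GenotypeCatalog"))
  miss <- setdiff(lines, catalogLines(catalog))
  if (length(miss))
    stop("line(s) absent from catalog: ", paste(miss, collapse = ", "))
  cc <- catalogCalls(catalog)
  new("GenotypeCatalog", calls = cc[cc$line %in% lines, , drop = FALSE],
      lines = lines)
}

#' Genotype alleles of each line
#'
#' Alleles with frequency strictly greater than \code{minFreq} (default
#' 10\%) in a line are that line's genotype alleles. When \code{regions} is
#' supplied, implied reference alleles at uncatalogued positions (frequency
#' 1 in that line) are included; otherwise only catalogued alleles are
#' considered.
#'
#' @param catalog a [GenotypeCatalog-class].
#' @param minFreq strict threshold, default 0.10.
#' @param regions optional [GenomicRanges::GRanges]; include implied
#'   reference alleles over these positions.
#' @param reference optional reference table as in
#'   [buildBackgroundCatalog()].
#' @return Named list (per line) of data.frames with columns \code{chrom},
#'   \code{pos}, \code{allele}.
#' @export
genotypeAlleles <- function(catalog, minFreq = 0.10, regions = NULL,
                            reference = NULL) {
  stopifnot(is(catalog, "GenotypeCatalog"))
  if (minFreq <= 0 || minFreq >= 1) stop("minFreq must lie in (0, 1)")
  cc <- catalogCalls(catalog)
  out <- lapply(catalogLines(catalog), function(l) {
    mine <- cc[cc$line == l & cc$freq > minFreq, , drop = FALSE]
    g <- data.frame(chrom = mine$chrom, pos = mine$pos,
                    allele = mine$allele, stringsAsFactors = FALSE)
    if (!is.null(regions)) {
      tp <- targetPositions(regions)
      ref <- if (is.null(reference)) syntheticReference(tp$pos) else
        reference$ref[match(.posKey(tp$chrom, tp$pos),
                            .posKey(reference$chrom, reference$pos))]
      listed <- .posKey(cc$chrom[cc$line == l], cc$pos[cc$line == l])
      implied <- !(.posKey(tp$chrom, tp$pos) %in% listed)
      g <- rbind(g, data.frame(chrom = tp$chrom[implied],
                               pos = tp$pos[implied],
                               allele = ref[implied],
                               stringsAsFactors = FALSE))
    }
    g <- g[order(g$chrom, g$pos, g$allele), , drop = FALSE]
    rownames(g) <- NULL
    g
  })
  names(out) <- catalogLines(catalog)
  out
}
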