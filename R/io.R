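## File-format boundary: TSV tables, BED regions (rtracklayer), VCF
## (vcfR), YAML provenance. Everything round-trips through the readers.

#' Write / read target regions as BED
#'
#' BED is 0-based half-open on disk; in memory regions are 1-based
#' [GenomicRanges::GRanges]. Conversion is handled by rtracklayer.
#'
#' @param regions a [GenomicRanges::GRanges].
#' @param path file path.
#' @return \code{writeRegionsBed}: the path, invisibly;
#'   \code{readRegionsBed}: a [GenomicRanges::GRanges].
#' @export
writeRegionsBed <- function(regions, path) {
  rtracklayer::export.bed(regions, path)
  invisible(path)
}

#' @rdname writeRegionsBed
#' @export
readRegionsBed <- function(path) {
  gr <- rtracklayer::import.bed(path)
  granges(gr)
}

.READ_CLASSES <- c(read_id = "character", pair_id = "character",
                   sample = "character", chrom = "character",
                   pos = "integer", span = "integer", mapped = "logical",
                   on_target = "logical", proper_pair = "logical",
                   duplicate = "logical", source_line = "character",
                   molecule_id = "character")

#' Write / read a read-record table as TSV
#'
#' @param reads a [ReadRecordTable-class].
#' @param path file path.
#' @return \code{writeReadRecords}: the path, invisibly;
#'   \code{readReadRecords}: a [ReadRecordTable-class].
#' @export
writeReadRecords <- function(reads, path) {
  stopifnot(is(reads, "ReadRecordTable"))
  write.table(readRecords(reads), path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname writeReadRecords
#' @export
readReadRecords <- function(path) {
  df <- read.delim(path, colClasses = .READ_CLASSES,
                   stringsAsFactors = FALSE)
  ReadRecordTable(df)
}

#' Write / read an allele-count table as TSV
#'
#' Columns \code{chrom}, \code{pos}, \code{allele}, \code{count},
#' \code{depth} (per-position depth repeated on each allele row).
#' Positions present in the depth table but carrying no count rows are
#' written with allele \code{"."} and count 0 so the file is lossless.
#'
#' @param counts an [AlleleCountTable-class].
#' @param path file path.
#' @param sample sample identifier for \code{readAlleleCounts}.
#' @return \code{writeAlleleCounts}: the path, invisibly;
#'   \code{readAlleleCounts}: an [AlleleCountTable-class].
#' @export
writeAlleleCounts <- function(counts, path) {
  stopifnot(is(counts, "AlleleCountTable"))
  cnt <- alleleCounts(counts)
  dep <- depthTable(counts)
  d <- dep$depth[match(.posKey(cnt$chrom, cnt$pos),
                       .posKey(dep$chrom, dep$pos))]
  out <- data.frame(cnt, depth = d, stringsAsFactors = FALSE)
  bare <- !(.posKey(dep$chrom, dep$pos) %in% .posKey(cnt$chrom, cnt$pos))
  if (any(bare))
    out <- rbind(out, data.frame(chrom = dep$chrom[bare],
                                 pos = dep$pos[bare], allele = ".",
                                 count = 0, depth = dep$depth[bare],
                                 stringsAsFactors = FALSE))
  out <- out[order(out$chrom, out$pos, out$allele), , drop = FALSE]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeAlleleCounts
#' @export
readAlleleCounts <- function(path, sample = "sample1") {
  df <- read.delim(path, colClasses = c(chrom = "character",
                                        pos = "integer",
                                        allele = "character",
                                        count = "numeric",
                                        depth = "numeric"),
                   stringsAsFactors = FALSE)
  dep <- df[!duplicated(.posKey(df$chrom, df$pos)),
            c("chrom", "pos", "depth")]
  rownames(dep) <- NULL
  cnt <- df[df$allele != ".", c("chrom", "pos", "allele", "count")]
  AlleleCountTable(sample, cnt, dep)
}

#' Write / read a variant truth set as TSV
#'
#' @param truth a [VariantTruthSet-class].
#' @param path file path.
#' @return \code{writeTruthSet}: the path, invisibly;
#'   \code{readTruthSet}: a [VariantTruthSet-class].
#' @export
writeTruthSet <- function(truth, path) {
  stopifnot(is(truth, "VariantTruthSet"))
  write.table(truthRecords(truth), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname writeTruthSet
#' @export
readTruthSet <- function(path) {
  df <- read.delim(path, colClasses = c(chrom = "character",
                                        pos = "integer", ref = "character",
                                        alt = "character",
                                        class = "character",
                                        indel_length = "integer",
                                        expected_maf = "numeric",
                                        pool = "character"),
                   stringsAsFactors = FALSE)
  new("VariantTruthSet", records = df)
}

#' Write a cell-line genome as a truth VCF
#'
#' One diploid sample column with GT 0/1 (het) or 1/1 (hom). vcfR writes
#' block-gzipped VCF (\code{.vcf.gz}).
#'
#' @param genome a [CellLineGenome-class].
#' @param path output path (\code{.vcf.gz}).
#' @return The path, invisibly.
#' @export
writeGenomeVcf <- function(genome, path) {
  stopifnot(is(genome, "CellLineGenome"))
  v <- variantTable(genome)
  fix <- matrix(".", nrow = nrow(v), ncol = 8,
                dimnames = list(NULL, c("CHROM", "POS", "ID", "REF", "ALT",
                                        "QUAL", "FILTER", "INFO")))
  if (nrow(v)) {
    fix[, "CHROM"] <- v$chrom
    fix[, "POS"] <- as.character(v$pos)
    fix[, "REF"] <- v$ref
    fix[, "ALT"] <- v$alt
    fix[, "FILTER"] <- "PASS"
  }
  gt <- matrix(c(rep("GT", nrow(v)),
                 ifelse(v$genotype == "hom", "1/1", "0/1")),
               nrow = nrow(v), ncol = 2,
               dimnames = list(NULL, c("FORMAT", lineId(genome))))
  vcf <- new(methods::getClass("vcfR", where = asNamespace("vcfR")),
             meta = c("##fileformat=VCFv4.2",
                      "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"),
             fix = fix, gt = gt)
  vcfR::write.vcf(vcf, file = path)
  invisible(path)
}

#' Read a cell-line genome from a truth VCF
#'
#' @param path VCF path (plain or gzipped).
#' @param lineId optional identifier; default the VCF sample name.
#' @return A [CellLineGenome-class].
#' @export
readGenomeVcf <- function(path, lineId = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- t(as.matrix(fix))
  n <- nrow(vcf@fix)
  sampleName <- colnames(vcf@gt)[-1L][1L]
  if (is.null(lineId)) lineId <- sampleName
  if (n == 0L)
    return(new("CellLineGenome", lineId = lineId,
               variants = data.frame(chrom = character(), pos = integer(),
                                     ref = character(), alt = character(),
                                     genotype = character(),
                                     stringsAsFactors = FALSE)))
  gtv <- vcf@gt[, 2L]
  gtv <- sub(":.*$", "", gtv)
  new("CellLineGenome", lineId = lineId,
      variants = data.frame(chrom = as.character(fix[, "CHROM"]),
                            pos = as.integer(fix[, "POS"]),
                            ref = as.character(fix[, "REF"]),
                            alt = as.character(fix[, "ALT"]),
                            genotype = ifelse(gtv == "1/1", "hom", "het"),
                            stringsAsFactors = FALSE))
}

#' Ingest a call set from VCF
#'
#' Maps VCF records onto the package's call representation: SNVs keep their
#' single-base REF/ALT; insertions become \code{"+SEQ"} and deletions
#' \code{"-SEQ"} anchored at POS (left-aligned VCF convention). The allele
#' fraction is taken from an \code{AF=} INFO field when present.
#'
#' @param path VCF path.
#' @param library library identifier (default the file name).
#' @return A [CallSet-class].
#' @export
readCallSet <- function(path, library = basename(path)) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  if (nrow(fix) == 0L)
    return(CallSet(library, data.frame(chrom = character(),
                                       pos = integer(), ref = character(),
                                       alt = character(),
                                       class = character(), af = numeric(),
                                       stringsAsFactors = FALSE)))
  ref <- as.character(fix[, "REF"]); alt <- as.character(fix[, "ALT"])
  isSnv <- nchar(ref) == 1L & nchar(alt) == 1L
  allele <- character(length(ref)); cls <- character(length(ref))
  allele[isSnv] <- alt[isSnv]; cls[isSnv] <- "SNV"
  ins <- nchar(alt) > nchar(ref)
  del <- nchar(alt) < nchar(ref)
  allele[ins & !isSnv] <- paste0("+", substring(alt[ins & !isSnv],
                                                nchar(ref[ins & !isSnv]) + 1L))
  allele[del & !isSnv] <- paste0("-", substring(ref[del & !isSnv],
                                                nchar(alt[del & !isSnv]) + 1L))
  cls[!isSnv] <- "indel"
  info <- as.character(fix[, "INFO"])
  af <- suppressWarnings(as.numeric(sub("^.*AF=([0-9.eE+-]+).*$", "\\1",
                                        info)))
  af[!grepl("AF=", info)] <- NA_real_
  refOut <- ifelse(isSnv, ref, substring(ref, 1L, 1L))
  CallSet(library,
          data.frame(chrom = as.character(fix[, "CHROM"]),
                     pos = as.integer(fix[, "POS"]), ref = refOut,
                     alt = allele, class = cls, af = af,
                     stringsAsFactors = FALSE))
}

#' Write a simulated dataset to a directory
#'
#' Emits regions as BED, truth genotypes as one VCF per line, read records
#' and allele counts as TSV per sample, the pool specification and
#' provenance as YAML, and a manifest of every file with its MD5 checksum.
#' The tables round-trip losslessly through [readDataset()].
#'
#' @param ds a [SimulatedDataset-class].
#' @param outDir output directory (created if needed).
#' @return data.frame manifest (\code{file}, \code{md5}), invisibly written
#'   to \code{manifest.tsv} as well.
#' @export
writeDataset <- function(ds, outDir) {
  stopifnot(is(ds, "SimulatedDataset"))
  ok <- dir.exists(outDir) || dir.create(outDir, recursive = TRUE,
                                         showWarnings = FALSE)
  if (!ok || file.access(outDir, 2L) != 0L)
    stop("output directory is not writable: ", outDir)
  truth <- truthData(ds)
  files <- character()
  writeRegionsBed(truth$regions, file.path(outDir, "regions.bed"))
  files <- c(files, "regions.bed")
  for (g in truth$genomes) {
    f <- sprintf("truth_%s.vcf.gz", lineId(g))
    writeGenomeVcf(g, file.path(outDir, f))
    files <- c(files, f)
  }
  for (s in names(readRecords(ds))) {
    f <- sprintf("read_records_%s.tsv", s)
    writeReadRecords(readRecords(ds, s), file.path(outDir, f))
    files <- c(files, f)
    f <- sprintf("allele_counts_%s.tsv", s)
    writeAlleleCounts(alleleCounts(ds, s), file.path(outDir, f))
    files <- c(files, f)
  }
  ## ratios as 17-significant-digit strings so doubles round-trip exactly
  yaml::write_yaml(list(constituents = constituents(truth$pool),
                        ratios = format(unname(poolRatios(truth$pool)),
                                        digits = 17, trim = TRUE)),
                   file.path(outDir, "pool.yaml"))
  files <- c(files, "pool.yaml")
  yaml::write_yaml(provenance(ds), file.path(outDir, "provenance.yaml"))
  files <- c(files, "provenance.yaml")
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(outDir, files))),
    stringsAsFactors = FALSE)
  write.table(manifest, file.path(outDir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

#' Read a simulated dataset back from a directory
#'
#' @param dir directory written by [writeDataset()].
#' @return list with \code{regions}, \code{genomes}, \code{readRecords},
#'   \code{alleleCounts}, \code{pool}, \code{provenance}, \code{manifest}.
#' @export
readDataset <- function(dir) {
  manifest <- read.delim(file.path(dir, "manifest.tsv"),
                         stringsAsFactors = FALSE)
  regions <- readRegionsBed(file.path(dir, "regions.bed"))
  vcfs <- manifest$file[grepl("^truth_.*\\.vcf(\\.gz)?$", manifest$file)]
  genomes <- lapply(vcfs, function(f) readGenomeVcf(file.path(dir, f)))
  names(genomes) <- vapply(genomes, lineId, "")
  rrFiles <- manifest$file[grepl("^read_records_.*\\.tsv$", manifest$file)]
  samples <- sub("^read_records_(.*)\\.tsv$", "\\1", rrFiles)
  rr <- lapply(rrFiles, function(f) readReadRecords(file.path(dir, f)))
  names(rr) <- samples
  ac <- lapply(samples, function(s)
    readAlleleCounts(file.path(dir, sprintf("allele_counts_%s.tsv", s)), s))
  names(ac) <- samples
  pool <- yaml::read_yaml(file.path(dir, "pool.yaml"))
  list(regions = regions, genomes = genomes, readRecords = rr,
       alleleCounts = ac,
       pool = PoolSpec(pool$constituents,
                       as.numeric(unlist(pool$ratios))),
       provenance = yaml::read_yaml(file.path(dir, "provenance.yaml")),
       manifest = manifest)
}
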