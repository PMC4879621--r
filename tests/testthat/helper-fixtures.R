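## Shared fixtures: everything is built in code at test time.

tinyRegions <- function(span = 1000, chrom = "chr1", start = 1) {
  GenomicRanges::GRanges(chrom,
                         IRanges::IRanges(start, start + span - 1))
}

## One read row; mates are modelled as independent rows unless pairs matter.
mkRead <- function(id, pos, span = 100, mapped = TRUE, on_target = TRUE,
                   proper = TRUE, dup = FALSE, chrom = "chr1",
                   pair = id, sample = "s1", molecule = NA_character_,
                   line = NA_character_) {
  data.frame(read_id = id, pair_id = pair, sample = sample, chrom = chrom,
             pos = as.integer(pos), span = as.integer(span),
             mapped = mapped, on_target = on_target, proper_pair = proper,
             duplicate = dup, source_line = line, molecule_id = molecule,
             stringsAsFactors = FALSE)
}

mkReadTable <- function(...) ReadRecordTable(do.call(rbind, list(...)))

## Genotype catalog from (line, pos, allele, freq) vectors; depth constant.
mkCatalog <- function(line, pos, allele, freq, depth = 1000,
                      lines = unique(line)) {
  new("GenotypeCatalog",
      calls = data.frame(line = line, chrom = "chr1", pos = as.integer(pos),
                         allele = allele, freq = freq, depth = depth,
                         stringsAsFactors = FALSE),
      lines = lines)
}

mkTruth <- function(pos, alt, maf, class = "SNV",
                    indel_length = ifelse(class == "indel",
                                          nchar(sub("^[+-]", "", alt)), 0L),
                    ref = syntheticReference(pos), pool = "p1") {
  new("VariantTruthSet",
      records = data.frame(chrom = "chr1", pos = as.integer(pos),
                           ref = ref, alt = alt, class = class,
                           indel_length = as.integer(indel_length),
                           expected_maf = maf, pool = pool,
                           stringsAsFactors = FALSE))
}

mkCallSet <- function(lib, pos, alt = "G", class = "SNV", af = 0.5,
                      ref = syntheticReference(pos)) {
  CallSet(lib, data.frame(chrom = "chr1", pos = as.integer(pos), ref = ref,
                          alt = alt, class = class, af = af,
                          stringsAsFactors = FALSE))
}

## Allele-count table at given positions: one non-reference allele count
## plus the implied reference remainder, so counts sum to depth.
mkCounts <- function(sample, pos, allele, count, depth) {
  ref <- syntheticReference(pos)
  stopifnot(all(allele != ref))
  cnt <- rbind(
    data.frame(chrom = "chr1", pos = as.integer(pos), allele = allele,
               count = count, stringsAsFactors = FALSE),
    data.frame(chrom = "chr1", pos = as.integer(pos), allele = ref,
               count = depth - count, stringsAsFactors = FALSE))
  AlleleCountTable(sample, cnt,
                   data.frame(chrom = "chr1", pos = as.integer(pos),
                              depth = depth, stringsAsFactors = FALSE))
}

## Expected distinct molecules when n draws hit M equally likely molecules.
expectedDistinct <- function(n, M) M * (1 - (1 - 1 / M)^n)
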