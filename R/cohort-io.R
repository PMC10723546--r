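## Data model ------------------------------------------------------------
##
## Variants, copy-number segments and SVs are plain data.frames with fixed
## column sets (the convention of Battenberg-style tooling); a tumour sample
## is an S3 list bundling them with purity/ploidy/clinical fields.

VARIANT_COLS <- c("chrom", "pos", "ref", "alt", "ref_depth", "alt_depth",
                  "variant_class", "context", "gene", "consequence",
                  "multiplicity", "clonal", "ccf")
SEGMENT_COLS <- c("chrom", "start", "end", "major_cn", "minor_cn",
                  "clonal_fraction")
SV_COLS <- c("chrom1", "pos1", "strand1", "chrom2", "pos2", "strand2",
             "sv_class", "callers")
SV_CLASSES <- c("deletion", "tandem-duplication", "inversion",
                "translocation", "unclassified")
CONSEQUENCES <- c("missense", "truncating", "synonymous", "non-coding",
                  "other")

#' Build a somatic variant table
#'
#' @param chrom,pos,ref,alt core VCF-style fields (`pos` 1-based).
#' @param ref_depth,alt_depth supporting read counts; their sum must be
#'   positive for every record.
#' @param gene,consequence,context,multiplicity,clonal,ccf optional
#'   annotations (NA where unknown).
#' @return validated data.frame with the package's variant columns.
#' @export
variant_table <- function(chrom, pos, ref, alt, ref_depth, alt_depth,
                          gene = NA_character_, consequence = NA_character_,
                          context = NA_character_,
                          multiplicity = NA_integer_, clonal = NA,
                          ccf = NA_real_) {
  df <- data.frame(
    chrom = as.character(chrom), pos = as.integer(pos),
    ref = as.character(ref), alt = as.character(alt),
    ref_depth = as.integer(ref_depth), alt_depth = as.integer(alt_depth),
    variant_class = classify_variant(ref, alt),
    context = as.character(context), gene = as.character(gene),
    consequence = as.character(consequence),
    multiplicity = as.integer(multiplicity), clonal = as.logical(clonal),
    ccf = as.numeric(ccf), stringsAsFactors = FALSE
  )
  validate_variants(df)
  df
}

classify_variant <- function(ref, alt) {
  ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "SNV",
         ifelse(nchar(alt) > nchar(ref), "insertion", "deletion"))
}

validate_variants <- function(df) {
  missing <- setdiff(VARIANT_COLS, names(df))
  if (length(missing))
    stop_invalid("variant table missing columns: %s",
                 paste(missing, collapse = ", "))
  tot <- df$ref_depth + df$alt_depth
  if (any(tot <= 0L))
    stop_invalid("variant with zero total depth at %s:%d",
                 df$chrom[tot <= 0][1], df$pos[tot <= 0][1])
  bad <- df$variant_class != classify_variant(df$ref, df$alt)
  if (any(bad))
    stop_invalid("variant_class inconsistent with alleles at %s:%d",
                 df$chrom[bad][1], df$pos[bad][1])
  invisible(df)
}

#' Variant allele fraction
#' @param variants variant table.
#' @return numeric vector alt/(alt+ref).
#' @export
vaf <- function(variants) {
  variants$alt_depth / (variants$alt_depth + variants$ref_depth)
}

#' Build an allele-specific copy-number segment table
#'
#' Battenberg-style columns; coordinates 1-based inclusive. Segments must be
#' non-overlapping per chromosome and satisfy `major_cn >= minor_cn`.
#'
#' @param chrom,start,end segment interval.
#' @param major_cn,minor_cn integer allele-specific copy numbers.
#' @param clonal_fraction fraction of tumour cells carrying the segment state.
#' @export
segment_table <- function(chrom, start, end, major_cn, minor_cn,
                          clonal_fraction = 1) {
  df <- data.frame(
    chrom = as.character(chrom), start = as.integer(start),
    end = as.integer(end), major_cn = as.integer(major_cn),
    minor_cn = as.integer(minor_cn),
    clonal_fraction = as.numeric(clonal_fraction), stringsAsFactors = FALSE
  )
  validate_segments(df)
  df
}

validate_segments <- function(df) {
  if (any(df$end < df$start)) stop_invalid("segment with end < start")
  if (any(df$major_cn < df$minor_cn))
    stop_invalid("segment with major_cn < minor_cn")
  if (any(df$minor_cn < 0)) stop_invalid("negative copy number")
  if (any(df$clonal_fraction <= 0 | df$clonal_fraction > 1))
    stop_invalid("clonal_fraction outside (0,1]")
  for (ch in unique(df$chrom)) {
    s <- df[df$chrom == ch, ]
    s <- s[order(s$start), ]
    if (nrow(s) > 1 && any(s$start[-1] <= s$end[-nrow(s)]))
      stop_invalid("overlapping segments on %s", ch)
  }
  invisible(df)
}

#' Build a structural-variant table
#'
#' One row per rearrangement: a breakpoint pair with orientation, class and
#' the set of callers supporting it (comma-separated). Intrachromosomal pairs
#' are stored with `pos1 <= pos2`.
#'
#' @param chrom1,pos1,strand1,chrom2,pos2,strand2 breakpoint pair.
#' @param sv_class one of deletion, tandem-duplication, inversion,
#'   translocation, unclassified.
#' @param callers comma-separated caller names.
#' @export
sv_table <- function(chrom1, pos1, strand1, chrom2, pos2, strand2,
                     sv_class = "unclassified", callers = "") {
  df <- data.frame(
    chrom1 = as.character(chrom1), pos1 = as.integer(pos1),
    strand1 = as.character(strand1), chrom2 = as.character(chrom2),
    pos2 = as.integer(pos2), strand2 = as.character(strand2),
    sv_class = as.character(sv_class), callers = as.character(callers),
    stringsAsFactors = FALSE
  )
  flip <- df$chrom1 == df$chrom2 & df$pos1 > df$pos2
  if (any(flip)) {
    tmp <- df[flip, c("pos1", "strand1")]
    df$pos1[flip] <- df$pos2[flip]
    df$strand1[flip] <- df$strand2[flip]
    df$pos2[flip] <- tmp$pos1
    df$strand2[flip] <- tmp$strand1
  }
  if (!all(df$sv_class %in% SV_CLASSES))
    stop_invalid("unknown sv_class: %s",
                 paste(setdiff(df$sv_class, SV_CLASSES), collapse = ","))
  df
}

#' Construct a tumour sample
#'
#' @param sample_id identifier.
#' @param purity tumour cell fraction rho in (0,1].
#' @param ploidy mean tumour copy number.
#' @param age_at_sampling years.
#' @param grade,stage ordinal clinical covariates (integers).
#' @param variants,segments,svs component tables (may be empty).
#' @return object of class `tumour_sample`.
#' @export
tumour_sample <- function(sample_id, purity, ploidy = 2,
                          age_at_sampling = NA_real_, grade = NA_integer_,
                          stage = NA_integer_,
                          variants = empty_variants(),
                          segments = empty_segments(), svs = empty_svs()) {
  if (purity <= 0 || purity > 1) stop_invalid("purity outside (0,1]")
  validate_variants(variants)
  validate_segments(segments)
  structure(list(
    sample_id = as.character(sample_id), purity = purity, ploidy = ploidy,
    age_at_sampling = age_at_sampling, grade = grade, stage = stage,
    variants = variants, segments = segments, svs = svs
  ), class = "tumour_sample")
}

#' @export
print.tumour_sample <- function(x, ...) {
  cat(sprintf(
    "<tumour_sample %s> purity %.2f, ploidy %.2f, %d variants, %d segments, %d SVs\n",
    x$sample_id, x$purity, x$ploidy, nrow(x$variants), nrow(x$segments),
    nrow(x$svs)))
  invisible(x)
}

empty_variants <- function() {
  df <- data.frame(chrom = character(), pos = integer(), ref = character(),
                   alt = character(), ref_depth = integer(),
                   alt_depth = integer(), variant_class = character(),
                   context = character(), gene = character(),
                   consequence = character(), multiplicity = integer(),
                   clonal = logical(), ccf = numeric(),
                   stringsAsFactors = FALSE)
  df
}

empty_segments <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             major_cn = integer(), minor_cn = integer(),
             clonal_fraction = numeric(), stringsAsFactors = FALSE)
}

empty_svs <- function() {
  data.frame(chrom1 = character(), pos1 = integer(), strand1 = character(),
             chrom2 = character(), pos2 = integer(), strand2 = character(),
             sv_class = character(), callers = character(),
             stringsAsFactors = FALSE)
}

## VCF I/O ----------------------------------------------------------------

#' Write somatic SNVs/indels to a VCF 4.2 file
#'
#' Single-sample VCF with `AD` (ref,alt) and `DP` FORMAT fields and the
#' package's annotations (gene, consequence, trinucleotide context) as INFO
#' keys. Output is deterministic: records sorted by (chrom, pos, ref, alt).
#'
#' @param variants variant table.
#' @param path output file.
#' @param sample_name sample column header.
#' @export
write_snv_vcf <- function(variants, path, sample_name = "TUMOUR") {
  validate_variants(variants)
  ord <- order(variants$chrom, variants$pos, variants$ref, variants$alt)
  v <- variants[ord, , drop = FALSE]
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=renalwgs",
    '##INFO=<ID=GENE,Number=1,Type=String,Description="Gene symbol">',
    '##INFO=<ID=CSQ,Number=1,Type=String,Description="Consequence class">',
    '##INFO=<ID=CTX,Number=1,Type=String,Description="Trinucleotide context label">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths (ref,alt)">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Total depth">',
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
           sample_name)
  )
  info <- vapply(seq_len(nrow(v)), function(i) {
    parts <- character(0)
    if (!is.na(v$gene[i])) parts <- c(parts, paste0("GENE=", v$gene[i]))
    if (!is.na(v$consequence[i])) parts <- c(parts, paste0("CSQ=", v$consequence[i]))
    if (!is.na(v$context[i])) parts <- c(parts, paste0("CTX=", v$context[i]))
    if (!length(parts)) "." else paste(parts, collapse = ";")
  }, character(1))
  geno <- sprintf("%d,%d:%d", v$ref_depth, v$alt_depth,
                  v$ref_depth + v$alt_depth)
  body <- if (nrow(v)) {
    paste(v$chrom, v$pos, ".", v$ref, v$alt, ".", "PASS", info, "AD:DP",
          geno, sep = "\t")
  } else character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read somatic SNVs/indels from a VCF file
#'
#' Parses with `VariantAnnotation::readVcf`; requires per-record read depths,
#' either an `AD` FORMAT field (ref,alt) or `DP` plus `AF`.
#'
#' @param path VCF file (plain text or bgzipped).
#' @return variant table.
#' @export
read_snv_vcf <- function(path) {
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  n <- length(vcf)
  if (n == 0) return(empty_variants())
  rr <- SummarizedExperiment::rowRanges(vcf)
  alt <- as.character(unlist(VariantAnnotation::alt(vcf)))
  if (length(alt) != n)
    stop_invalid("multi-allelic records not supported; normalise first")
  g <- VariantAnnotation::geno(vcf)
  if (!("AD" %in% names(g)))
    stop_invalid("VCF lacks AD depth FORMAT field: %s", path)
  ad <- g$AD[, 1]
  if (is.matrix(ad)) ad <- split(ad, seq_len(nrow(ad)))
  ref_d <- vapply(ad, function(x) as.integer(x[1]), integer(1))
  alt_d <- vapply(ad, function(x) as.integer(x[2]), integer(1))
  bad <- is.na(ref_d) | is.na(alt_d)
  if (any(bad))
    stop_invalid("record without depths: %s", names(vcf)[bad][1])
  info <- VariantAnnotation::info(vcf)
  get_info <- function(key) {
    if (key %in% names(info)) {
      x <- as.character(info[[key]])
      x[x == "."] <- NA_character_
      x
    } else rep(NA_character_, n)
  }
  variant_table(
    chrom = as.character(GenomeInfoDb::seqnames(rr)),
    pos = BiocGenerics::start(rr),
    ref = as.character(VariantAnnotation::ref(vcf)),
    alt = alt, ref_depth = ref_d, alt_depth = alt_d,
    gene = get_info("GENE"), consequence = get_info("CSQ"),
    context = get_info("CTX")
  )
}

## Tab-delimited tables ---------------------------------------------------

#' Read / write Battenberg-style segment tables
#'
#' Tab-delimited with columns chrom, start, end, major_cn, minor_cn,
#' clonal_fraction (1-based inclusive coordinates).
#' @param path file path.
#' @export
read_segments <- function(path) {
  df <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
  validate_segments(df[SEGMENT_COLS])
  df[SEGMENT_COLS]
}

#' @rdname read_segments
#' @param segments segment table.
#' @export
write_segments <- function(segments, path) {
  validate_segments(segments)
  data.table::fwrite(segments[SEGMENT_COLS], path, sep = "\t")
  invisible(path)
}

#' Read / write structural variants as BEDPE
#'
#' Standard 10-column BEDPE (0-based half-open breakpoint intervals of width
#' 1) plus `caller` and `sv_class` columns.
#' @param path file path.
#' @export
read_sv_bedpe <- function(path) {
  df <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
  sv_table(chrom1 = df$chrom1, pos1 = df$start1 + 1L, strand1 = df$strand1,
           chrom2 = df$chrom2, pos2 = df$start2 + 1L, strand2 = df$strand2,
           sv_class = df$sv_class, callers = df$caller)
}

#' @rdname read_sv_bedpe
#' @param svs SV table.
#' @export
write_sv_bedpe <- function(svs, path) {
  out <- data.frame(
    chrom1 = svs$chrom1, start1 = svs$pos1 - 1L, end1 = svs$pos1,
    chrom2 = svs$chrom2, start2 = svs$pos2 - 1L, end2 = svs$pos2,
    name = if (nrow(svs)) sprintf("sv%05d", seq_len(nrow(svs))) else character(0),
    score = ".", strand1 = svs$strand1, strand2 = svs$strand2,
    caller = svs$callers, sv_class = svs$sv_class, stringsAsFactors = FALSE
  )
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Read / write the per-cohort clinical table
#' @param path TSV with sample_id, purity, ploidy, age_at_sampling, grade,
#'   stage.
#' @export
read_clinical <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
}

#' @rdname read_clinical
#' @param clinical data.frame.
#' @export
write_clinical <- function(clinical, path) {
  data.table::fwrite(clinical, path, sep = "\t")
  invisible(path)
}
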