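## Genetic immune-evasion classification: HLA loss of heterozygosity from
## allele-specific copy number, HLA mutation, and antigen-presenting-gene
## (APG) inactivation.

TRUNCATING <- "truncating"
HLA_GENES <- c("HLA-A", "HLA-B", "HLA-C")

#' Default antigen-presenting gene list
#'
#' A literature-based 22-gene antigen processing/presentation set used as the
#' bundled default; analyses with a study-specific list should pass it
#' explicitly (one gene symbol per line via [read_gene_list()]).
#' @return character vector of 22 gene symbols.
#' @export
default_apg_genes <- function() {
  c("B2M", "TAP1", "TAP2", "TAPBP", "TAPBPL", "CALR", "CANX", "PDIA3",
    "ERAP1", "ERAP2", "PSMB5", "PSMB6", "PSMB7", "PSMB8", "PSMB9",
    "PSMB10", "HSPA5", "HSP90AA1", "CIITA", "NLRC5", "RFX5", "RFXAP")
}

#' Read a one-gene-per-line list
#' @param path text file.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x)]
}

#' HLA loss-of-heterozygosity call from copy-number segments
#'
#' Segment-based surrogate for allele-resolved HLA LOH detection: the locus
#' is LOH when the length-weighted majority of its covered extent has
#' `minor_cn == 0` at clonal fraction >= 0.5.
#'
#' @param sample `tumour_sample`.
#' @param hla_locus list/row with `chrom`, `start`, `end` (1-based
#'   inclusive).
#' @param min_coverage minimum covered fraction of the locus (default 0.5);
#'   below it the call is NA (missing, not FALSE).
#' @return TRUE/FALSE, or NA when coverage is insufficient.
#' @export
hla_loh_call <- function(sample, hla_locus, min_coverage = 0.5) {
  s <- sample$segments
  s <- s[s$chrom == hla_locus$chrom & s$end >= hla_locus$start &
           s$start <= hla_locus$end, , drop = FALSE]
  locus_len <- hla_locus$end - hla_locus$start + 1
  if (nrow(s) == 0) return(NA)
  ov <- pmin(s$end, hla_locus$end) - pmax(s$start, hla_locus$start) + 1
  if (sum(ov) / locus_len < min_coverage) return(NA)
  loh <- s$minor_cn == 0 & s$clonal_fraction >= 0.5
  sum(ov[loh]) > sum(ov) / 2
}

#' Nonsynonymous HLA class I mutation flag
#' @param sample `tumour_sample`.
#' @param hla_genes gene symbols (default HLA-A/B/C).
#' @return logical.
#' @export
hla_mutation_call <- function(sample, hla_genes = HLA_GENES) {
  v <- sample$variants
  any(!is.na(v$gene) & v$gene %in% hla_genes & !is.na(v$consequence) &
        v$consequence %in% c("missense", TRUNCATING))
}

#' Antigen-presenting-gene inactivation
#'
#' TRUE when any listed gene carries a truncating mutation, or a missense
#' mutation flagged pathogenic (via `pathogenic_variants`). In biallelic
#' mode, a qualifying mutation counts only when the gene is also under LOH
#' (`loh_genes`).
#'
#' @param sample `tumour_sample`.
#' @param apg_list gene symbols (default [default_apg_genes()]).
#' @param pathogenic_variants optional logical vector parallel to
#'   `sample$variants` marking pathogenic missense calls.
#' @param biallelic require LOH of the gene in addition to the mutation.
#' @param loh_genes genes under LOH (used in biallelic mode).
#' @return list(inactivated, evidence) where evidence is a data.frame of
#'   (gene, alteration).
#' @export
apg_inactivation <- function(sample, apg_list = default_apg_genes(),
                             pathogenic_variants = NULL, biallelic = FALSE,
                             loh_genes = character(0)) {
  if (!length(apg_list)) stop_invalid("empty antigen-presenting gene list")
  v <- sample$variants
  if (is.null(pathogenic_variants))
    pathogenic_variants <- rep(FALSE, nrow(v))
  in_apg <- !is.na(v$gene) & v$gene %in% apg_list
  trunc <- in_apg & !is.na(v$consequence) & v$consequence == TRUNCATING
  path_mis <- in_apg & !is.na(v$consequence) &
    v$consequence == "missense" & pathogenic_variants
  qual <- trunc | path_mis
  if (biallelic) qual <- qual & v$gene %in% loh_genes
  evidence <- data.frame(
    gene = v$gene[qual],
    alteration = ifelse(trunc[qual], "truncating", "pathogenic-missense"),
    stringsAsFactors = FALSE)
  list(inactivated = any(qual), evidence = evidence)
}

#' Classify a tumour for genetic immune evasion
#'
#' Escape is the OR of three component flags: HLA LOH, HLA mutation, and APG
#' inactivation. Missing components (e.g. HLA locus not covered) are
#' recorded and never silently coerced to FALSE; a sample with every
#' component missing is unclassifiable.
#'
#' @param sample `tumour_sample`.
#' @param hla_locus locus definition for [hla_loh_call()] (NULL skips the
#'   component, recorded missing).
#' @param apg_list APG gene symbols.
#' @param pathogenic_variants,biallelic,loh_genes passed to
#'   [apg_inactivation()].
#' @return list of class `immune_escape_call`: sample_id, hla_loh,
#'   hla_mutation, apg_inactivation, escaped, missing, evidence.
#' @export
classify_escape <- function(sample, hla_locus = NULL,
                            apg_list = default_apg_genes(),
                            pathogenic_variants = NULL, biallelic = FALSE,
                            loh_genes = character(0)) {
  loh <- if (is.null(hla_locus)) NA else hla_loh_call(sample, hla_locus)
  mut <- hla_mutation_call(sample)
  apg <- apg_inactivation(sample, apg_list,
                          pathogenic_variants = pathogenic_variants,
                          biallelic = biallelic, loh_genes = loh_genes)
  flags <- c(hla_loh = loh, hla_mutation = mut,
             apg_inactivation = apg$inactivated)
  if (all(is.na(flags))) stop_invalid("all escape components missing")
  evidence <- apg$evidence
  if (isTRUE(loh))
    evidence <- rbind(evidence, data.frame(gene = "HLA", alteration = "LOH"))
  if (isTRUE(mut))
    evidence <- rbind(evidence,
                      data.frame(gene = "HLA", alteration = "mutation"))
  structure(list(
    sample_id = sample$sample_id, hla_loh = loh, hla_mutation = mut,
    apg_inactivation = apg$inactivated,
    escaped = any(flags, na.rm = TRUE),
    missing = names(flags)[is.na(flags)], evidence = evidence
  ), class = "immune_escape_call")
}

#' Summarise escape calls over a cohort
#' @param calls list of `immune_escape_call`s.
#' @return list with per-component counts and the escaped fraction.
#' @export
summarize_escape <- function(calls) {
  n <- length(calls)
  cnt <- function(f) sum(vapply(calls, function(x) isTRUE(x[[f]]), logical(1)))
  list(n = n, hla_loh = cnt("hla_loh"), hla_mutation = cnt("hla_mutation"),
       apg_inactivation = cnt("apg_inactivation"), escaped = cnt("escaped"),
       escaped_fraction = cnt("escaped") / n)
}
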