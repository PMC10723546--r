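## Somatic-call curation: the cohort-level cleaning steps applied before any
## downstream analysis.

#' Remove somatic indels near common germline indels
#'
#' A somatic indel is removed when any germline-panel indel on the same
#' chromosome lies within `window_bp` of its position. The boundary is
#' inclusive by default (distance exactly `window_bp` removes the call);
#' set `inclusive = FALSE` for a strict-inequality reading.
#'
#' @param somatic_indels variant table containing only insertions/deletions.
#' @param germline_panel data.frame with at least `chrom` and `pos`
#'   (indel-only panel, e.g. parsed from a population VCF).
#' @param window_bp proximity window in bp (default 10).
#' @param inclusive whether distance == window_bp removes (default TRUE).
#' @return list with elements `kept` and `removed`, a partition of the input.
#' @export
filter_indels_near_germline <- function(somatic_indels, germline_panel,
                                        window_bp = 10, inclusive = TRUE) {
  validate_variants(somatic_indels)
  if (any(somatic_indels$variant_class == "SNV"))
    stop_invalid("filter_indels_near_germline: input contains SNVs")
  if (nrow(germline_panel) == 0 || nrow(somatic_indels) == 0) {
    return(list(kept = somatic_indels,
                removed = somatic_indels[integer(0), , drop = FALSE]))
  }
  hit <- logical(nrow(somatic_indels))
  for (ch in unique(somatic_indels$chrom)) {
    idx <- which(somatic_indels$chrom == ch)
    panel_pos <- sort(germline_panel$pos[germline_panel$chrom == ch])
    if (!length(panel_pos)) next
    pos <- somatic_indels$pos[idx]
    ## nearest panel position via sorted lookup
    right <- findInterval(pos, panel_pos) # index of largest panel <= pos
    d_left <- ifelse(right >= 1, pos - panel_pos[pmax(right, 1)], Inf)
    d_right <- ifelse(right < length(panel_pos),
                      panel_pos[pmin(right + 1L, length(panel_pos))] - pos,
                      Inf)
    dmin <- pmin(d_left, d_right)
    hit[idx] <- if (inclusive) dmin <= window_bp else dmin < window_bp
  }
  list(kept = somatic_indels[!hit, , drop = FALSE],
       removed = somatic_indels[hit, , drop = FALSE])
}

#' Multi-caller structural-variant consensus
#'
#' Calls from different callers are merged by single linkage: two calls are
#' linked when both breakpoints lie within `slop_bp`, strand orientations
#' match at both ends, and their classes are compatible (identical, or either
#' is "unclassified"). A consensus record is emitted for every cluster
#' supported by at least `min_callers` distinct callers, with breakpoint
#' positions set to the cluster medians and the class set to the most common
#' classified label.
#'
#' @param callsets named list (caller name -> SV table).
#' @param slop_bp breakpoint matching window (default 300).
#' @param min_callers minimum distinct supporting callers (default 2).
#' @return consensus SV table with `callers` holding the sorted supporting
#'   set, comma-separated.
#' @export
consensus_sv <- function(callsets, slop_bp = 300, min_callers = 2) {
  if (length(callsets) < 2)
    stop_invalid("consensus_sv needs at least two callsets")
  if (is.null(names(callsets)) || any(names(callsets) == ""))
    stop_invalid("callsets must be a named list")
  all <- do.call(rbind, lapply(names(callsets), function(cl) {
    df <- callsets[[cl]]
    if (nrow(df) == 0) return(NULL)
    df$callers <- cl
    df
  }))
  if (is.null(all) || nrow(all) == 0) return(empty_svs())
  ## canonical chromosome-pair key so chr ordering does not matter
  key <- paste(pmin(all$chrom1, all$chrom2), pmax(all$chrom1, all$chrom2))
  out <- list()
  for (k in unique(key)) {
    grp <- all[key == k, , drop = FALSE]
    n <- nrow(grp)
    parent <- uf_new(n)
    if (n > 1) {
      for (i in seq_len(n - 1)) {
        for (j in seq((i + 1), n)) {
          if (sv_match(grp[i, ], grp[j, ], slop_bp))
            parent <- uf_union(parent, i, j)
        }
      }
    }
    comp <- uf_components(parent)
    for (cid in unique(comp)) {
      cl <- grp[comp == cid, , drop = FALSE]
      callers <- sort(unique(cl$callers))
      if (length(callers) < min_callers) next
      cls <- cl$sv_class[cl$sv_class != "unclassified"]
      cons_class <- if (length(cls)) names(sort(table(cls),
                                                decreasing = TRUE))[1]
                    else "unclassified"
      out[[length(out) + 1]] <- sv_table(
        chrom1 = cl$chrom1[1], pos1 = as.integer(round(median(cl$pos1))),
        strand1 = cl$strand1[1], chrom2 = cl$chrom2[1],
        pos2 = as.integer(round(median(cl$pos2))), strand2 = cl$strand2[1],
        sv_class = cons_class, callers = paste(callers, collapse = ",")
      )
    }
  }
  if (!length(out)) return(empty_svs())
  res <- do.call(rbind, out)
  res <- res[order(res$chrom1, res$pos1, res$chrom2, res$pos2), ]
  rownames(res) <- NULL
  res
}

sv_match <- function(a, b, slop_bp) {
  same <- a$chrom1 == b$chrom1 && a$chrom2 == b$chrom2 &&
    abs(a$pos1 - b$pos1) <= slop_bp && abs(a$pos2 - b$pos2) <= slop_bp &&
    a$strand1 == b$strand1 && a$strand2 == b$strand2
  swapped <- a$chrom1 == b$chrom2 && a$chrom2 == b$chrom1 &&
    a$chrom1 != a$chrom2 &&
    abs(a$pos1 - b$pos2) <= slop_bp && abs(a$pos2 - b$pos1) <= slop_bp &&
    a$strand1 == b$strand2 && a$strand2 == b$strand1
  class_ok <- a$sv_class == b$sv_class || a$sv_class == "unclassified" ||
    b$sv_class == "unclassified"
  (same || swapped) && class_ok
}

#' Tumour mutational burden
#'
#' @param sample `tumour_sample` (or a variant table).
#' @param callable_mb callable genome size in megabases.
#' @return list with `snv_per_mb` and `indel_per_mb`.
#' @export
compute_tmb <- function(sample, callable_mb) {
  if (!is.numeric(callable_mb) || callable_mb <= 0)
    stop_invalid("callable_mb must be > 0")
  v <- if (inherits(sample, "tumour_sample")) sample$variants else sample
  list(snv_per_mb = sum(v$variant_class == "SNV") / callable_mb,
       indel_per_mb = sum(v$variant_class != "SNV") / callable_mb)
}

## Trinucleotide context ---------------------------------------------------

SUB_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

#' The 96 trinucleotide substitution classes
#'
#' Pyrimidine-centred labels of the form `"ACA:C>A"`, ordered by substitution
#' then flanking bases (the conventional mutational-signature ordering).
#' @return character vector of length 96.
#' @export
context_classes <- function() {
  bases <- c("A", "C", "G", "T")
  out <- character(0)
  for (sub in SUB_CLASSES) {
    centre <- substr(sub, 1, 1)
    for (up in bases) for (down in bases) {
      out <- c(out, paste0(up, centre, down, ":", sub))
    }
  }
  out
}

#' Trinucleotide context label of an SNV
#'
#' Returns the pyrimidine-centred 96-class label. When the reference base is
#' a purine the trinucleotide and the substitution are reverse-complemented
#' so that every SNV maps onto one of the 96 canonical classes.
#'
#' @param chrom,pos,ref,alt the SNV.
#' @param reference_fetcher function(chrom, start, end) returning the
#'   reference sequence (1-based inclusive coordinates).
#' @return label such as `"ACG:C>T"`.
#' @export
trinucleotide_context <- function(chrom, pos, ref, alt, reference_fetcher) {
  if (nchar(ref) != 1 || nchar(alt) != 1)
    stop_invalid("trinucleotide_context requires an SNV")
  tri <- toupper(as.character(reference_fetcher(chrom, pos - 1L, pos + 1L)))
  if (nchar(tri) != 3)
    stop_invalid("reference fetch did not return a trinucleotide")
  if (substr(tri, 2, 2) != toupper(ref))
    stop_invalid("reference mismatch at %s:%d: genome has %s, variant ref %s",
                 chrom, pos, substr(tri, 2, 2), ref)
  if (toupper(ref) %in% c("A", "G")) {
    tri <- revcomp(tri)
    ref <- revcomp(ref)
    alt <- revcomp(alt)
  }
  paste0(tri, ":", toupper(ref), ">", toupper(alt))
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Annotate every SNV in a variant table with its context label
#' @param variants variant table.
#' @param reference_fetcher as in [trinucleotide_context()].
#' @return variant table with `context` filled for SNVs.
#' @export
annotate_contexts <- function(variants, reference_fetcher) {
  snv <- which(variants$variant_class == "SNV")
  variants$context[snv] <- vapply(snv, function(i) {
    trinucleotide_context(variants$chrom[i], variants$pos[i],
                          variants$ref[i], variants$alt[i],
                          reference_fetcher)
  }, character(1))
  variants
}
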