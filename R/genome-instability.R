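## Copy-number summary metrics: wGII, WGD call, arm-level alteration matrix
## and enrichment.

#' Weighted genome instability index
#'
#' Per autosome, the fraction of covered length whose total copy number
#' differs from the rounded sample ploidy; wGII is the unweighted mean over
#' autosomes so small chromosomes count as much as large ones.
#'
#' @param sample `tumour_sample`.
#' @param autosomes genome table (default [human_autosomes()]).
#' @param min_coverage minimum fraction of the autosomal genome the segments
#'   must cover (default 0.9); below this the index is undefined (NA).
#' @return value in `[0, 1]`, or NA when coverage is insufficient.
#' @export
wgii <- function(sample, autosomes = human_autosomes(), min_coverage = 0.9) {
  s <- sample$segments
  s <- s[s$chrom %in% autosomes$chrom, , drop = FALSE]
  ref_ploidy <- round(sample$ploidy)
  tot_len <- sum(as.numeric(autosomes$length))
  cov_len <- sum(as.numeric(s$end - s$start + 1))
  if (cov_len / tot_len < min_coverage) {
    message(sprintf("wgii undefined: segments cover %.1f%% of autosomes",
                    100 * cov_len / tot_len))
    return(NA_real_)
  }
  fracs <- vapply(autosomes$chrom, function(ch) {
    seg <- s[s$chrom == ch, , drop = FALSE]
    if (nrow(seg) == 0) return(0)
    len <- as.numeric(seg$end - seg$start + 1)
    alt <- (seg$major_cn + seg$minor_cn) != ref_ploidy
    sum(len[alt]) / sum(len)
  }, numeric(1))
  mean(fracs)
}

#' Whole-genome duplication call
#'
#' WGD when the length-weighted fraction of the covered autosomal genome
#' with major copy number >= 2 exceeds `threshold`.
#'
#' @param sample `tumour_sample`.
#' @param threshold genome fraction cutoff (default 0.5, strict inequality).
#' @param autosomes genome table restricting which chromosomes count;
#'   NULL uses all segments.
#' @return logical.
#' @export
call_wgd <- function(sample, threshold = 0.5, autosomes = NULL) {
  s <- sample$segments
  if (!is.null(autosomes))
    s <- s[s$chrom %in% autosomes$chrom, , drop = FALSE]
  if (nrow(s) == 0) return(FALSE)
  len <- as.numeric(s$end - s$start + 1)
  sum(len[s$major_cn >= 2]) / sum(len) > threshold
}

#' Arm-level alteration matrix
#'
#' An arm is called gained (lost) in a sample when at least half of its
#' segment-covered length carries total copy number above (below) the
#' rounded sample ploidy; otherwise neutral. Segments straddling an arm
#' boundary are apportioned by overlap length.
#'
#' @param cohort list of `tumour_sample`s.
#' @param arms arm table from [arm_definitions()] / [human_arms()].
#' @return character matrix arms x samples with entries
#'   "gain"/"loss"/"neutral"; rownames `chrom_arm`.
#' @export
arm_alteration_matrix <- function(cohort, arms = human_arms()) {
  arm_ids <- paste0(arms$chrom, arms$arm)
  res <- matrix("neutral", nrow = nrow(arms), ncol = length(cohort),
                dimnames = list(arm_ids,
                                vapply(cohort, `[[`, "", "sample_id")))
  arm_gr <- GenomicRanges::GRanges(arms$chrom,
                                   IRanges::IRanges(arms$start, arms$end))
  for (k in seq_along(cohort)) {
    smp <- cohort[[k]]
    seg <- smp$segments
    if (nrow(seg) == 0) next
    ref_ploidy <- round(smp$ploidy)
    seg_gr <- GenomicRanges::GRanges(seg$chrom,
                                     IRanges::IRanges(seg$start, seg$end))
    hits <- GenomicRanges::findOverlaps(seg_gr, arm_gr)
    ov <- IRanges::pintersect(seg_gr[S4Vectors::queryHits(hits)],
                              arm_gr[S4Vectors::subjectHits(hits)])
    ov_len <- as.numeric(BiocGenerics::width(ov))
    tot_cn <- (seg$major_cn + seg$minor_cn)[S4Vectors::queryHits(hits)]
    arm_idx <- S4Vectors::subjectHits(hits)
    arm_len <- as.numeric(arms$end - arms$start + 1)
    for (a in unique(arm_idx)) {
      sel <- arm_idx == a
      up <- sum(ov_len[sel][tot_cn[sel] > ref_ploidy])
      down <- sum(ov_len[sel][tot_cn[sel] < ref_ploidy])
      if (up / arm_len[a] >= 0.5) res[a, k] <- "gain"
      else if (down / arm_len[a] >= 0.5) res[a, k] <- "loss"
    }
  }
  res
}

#' Arm-level alteration enrichment
#'
#' For each direction (gain, loss) the background probability is the
#' cohort-wide mean per-arm alteration rate in that direction; each arm is
#' then tested for excess by a binomial upper tail, with Benjamini-Hochberg
#' adjustment across arms x directions.
#'
#' @param matrix arm alteration matrix from [arm_alteration_matrix()].
#' @param min_samples minimum cohort size (default 10).
#' @return data.frame: arm, direction, altered, n, background_rate, p, q.
#' @export
arm_enrichment_test <- function(matrix, min_samples = 10) {
  n <- ncol(matrix)
  if (n < min_samples)
    stop_invalid("arm_enrichment_test needs >= %d samples", min_samples)
  out <- list()
  for (dir in c("gain", "loss")) {
    hits <- rowSums(matrix == dir)
    bg <- mean(matrix == dir)
    if (bg == 0 && any(hits > 0)) {
      warning("zero background rate with observed alterations; using pseudo-count")
      bg <- 0.5 / (n * nrow(matrix))
    }
    p <- if (bg == 0) rep(1, nrow(matrix))
         else stats::pbinom(hits - 1, n, bg, lower.tail = FALSE)
    out[[dir]] <- data.frame(arm = rownames(matrix), direction = dir,
                             altered = as.integer(hits), n = n,
                             background_rate = bg, p = p,
                             stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res$q <- bh_adjust(res$p)
  rownames(res) <- NULL
  res[order(res$q, res$p), ]
}
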