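## Rearrangement hotspot detection: breakpoint binning, covariate-adjusted
## Poisson background, piecewise constant fitting of the observed/expected
## ratio, segment-level tail tests, and fragile-site exclusion.

#' Tile a genome into uniform bins
#'
#' @param genome genome table (`chrom`, `length`).
#' @param bin_width bin size in bp (default 100 kb).
#' @return data.frame `chrom`, `start`, `end` (0-based half-open), tiling
#'   each chromosome; the terminal bin is truncated at the chromosome end.
#' @export
make_bins <- function(genome, bin_width = 1e5) {
  stopifnot(bin_width > 0)
  out <- lapply(seq_len(nrow(genome)), function(i) {
    starts <- seq(0, genome$length[i] - 1, by = bin_width)
    data.frame(chrom = genome$chrom[i], start = as.numeric(starts),
               end = pmin(starts + bin_width, genome$length[i]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Bin structural-variant breakpoints
#'
#' Every breakpoint end contributes one count to its containing bin: both
#' ends of intrachromosomal events, and each end of a translocation on its
#' own chromosome. Total counts equal twice the number of SVs.
#'
#' @param svs SV table (cohort-pooled).
#' @param genome genome table.
#' @param bin_width bin size (default 100 kb).
#' @return bins data.frame with a `count` column.
#' @export
bin_breakpoints <- function(svs, genome, bin_width = 1e5) {
  bins <- make_bins(genome, bin_width)
  bins$count <- 0
  ends <- data.frame(
    chrom = c(svs$chrom1, svs$chrom2),
    pos = c(svs$pos1, svs$pos2), stringsAsFactors = FALSE)
  glen <- setNames(genome$length, genome$chrom)
  if (nrow(ends)) {
    unknown <- !(ends$chrom %in% names(glen))
    if (any(unknown))
      stop_invalid("breakpoint on unknown chromosome %s",
                   ends$chrom[unknown][1])
    if (any(ends$pos > glen[ends$chrom] | ends$pos < 1))
      stop_invalid("breakpoint beyond chromosome end")
    for (ch in unique(ends$chrom)) {
      sel <- which(bins$chrom == ch)
      ## pos is 1-based; bin index via 0-based half-open bins
      idx <- floor((ends$pos[ends$chrom == ch] - 1) / bin_width) + 1L
      tab <- tabulate(idx, nbins = length(sel))
      bins$count[sel] <- bins$count[sel] + tab
    }
  }
  bins
}

#' Fit a covariate-adjusted Poisson background to binned counts
#'
#' Poisson log-linear regression (IRLS via `stats::glm`) of per-bin counts
#' on standardized covariate tracks. With collinear covariates the fit falls
#' back to a small-ridge penalised IRLS and warns. Fitted expectations are
#' rescaled (a no-op for a converged intercept fit) so that
#' `sum(expected) == sum(observed)`.
#'
#' @param counts binned counts from [bin_breakpoints()].
#' @param covariates named list of numeric vectors on the same bin grid
#'   (or a data.frame); may be empty for an intercept-only background.
#' @return `counts` with `expected` column; coefficients in
#'   `attr(,"coefficients")`.
#' @export
fit_background <- function(counts, covariates = list()) {
  y <- counts$count
  if (is.data.frame(covariates)) covariates <- as.list(covariates)
  if (!length(covariates)) {
    counts$expected <- rep(mean(y), length(y))
    attr(counts, "coefficients") <- c(intercept = log(mean(y)))
    return(counts)
  }
  z <- vapply(covariates, function(x) {
    if (length(x) != length(y))
      stop_invalid("covariate track not on the bin grid")
    s <- sd(x)
    if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }, numeric(length(y)))
  colnames(z) <- names(covariates) %||% paste0("cov", seq_along(covariates))
  keep <- apply(z, 2, function(col) any(col != 0))
  z <- z[, keep, drop = FALSE]
  if (!ncol(z)) return(fit_background(counts, list()))
  qrz <- qr(cbind(1, z))
  if (qrz$rank < ncol(z) + 1) {
    warning("collinear covariates; ridge-penalised fit used")
    fit <- ridge_poisson_irls(y, z, lambda = 1e-4)
    eta <- fit$eta
    coefs <- fit$beta
  } else {
    df <- data.frame(y = y, z)
    fit <- glm(y ~ ., data = df, family = poisson())
    eta <- fit$linear.predictors
    coefs <- stats::coef(fit)
  }
  expected <- exp(eta)
  expected <- expected * sum(y) / sum(expected)
  counts$expected <- expected
  attr(counts, "coefficients") <- coefs
  counts
}

ridge_poisson_irls <- function(y, z, lambda = 1e-4, max_iter = 100,
                               tol = 1e-8) {
  x <- cbind(1, z)
  p <- ncol(x)
  beta <- c(log(mean(y) + 1e-9), rep(0, p - 1))
  pen <- diag(lambda, p); pen[1, 1] <- 0 # do not shrink the intercept
  for (it in seq_len(max_iter)) {
    eta <- drop(x %*% beta)
    mu <- exp(pmin(eta, 30))
    wz <- eta + (y - mu) / mu
    xtw <- t(x * mu)
    beta_new <- solve(xtw %*% x + pen, xtw %*% wz)
    if (max(abs(beta_new - beta)) < tol) { beta <- beta_new; break }
    beta <- beta_new
  }
  list(beta = drop(beta), eta = drop(x %*% beta))
}

#' Piecewise constant fitting by exact dynamic programming
#'
#' Minimises the penalised least-squares criterion
#' `sum_s sum_{i in s} (x_i - mean_s)^2 + gamma * (#segments)`
#' per chromosome, over all segmentations with segments of at least
#' `min_bins` bins. The dynamic program is exact (O(n^2) per chromosome).
#'
#' @param values numeric signal per bin (e.g. observed/expected ratio).
#' @param chrom chromosome per bin (same length); a single chromosome is
#'   assumed when NULL.
#' @param gamma positive penalty per segment; NULL selects a modified-BIC
#'   default `2 * sigma^2 * log(n)` with a difference-based variance
#'   estimate.
#' @param min_bins minimum segment length in bins (default 2; tracks shorter
#'   than this form one segment).
#' @return data.frame: chrom, start_bin, end_bin (1-based bin indices within
#'   chromosome), n_bins, mean.
#' @export
pcf_segment <- function(values, chrom = NULL, gamma = NULL, min_bins = 2) {
  if (is.null(chrom)) chrom <- rep("chr", length(values))
  stopifnot(length(chrom) == length(values))
  if (!is.null(gamma) && gamma <= 0) stop_invalid("gamma must be > 0")
  if (is.null(gamma)) {
    d <- diff(values)
    sigma2 <- if (length(d)) max(var(d) / 2, 1e-12) else 1e-12
    gamma <- 2 * sigma2 * log(max(length(values), 2))
  }
  out <- lapply(unique(chrom), function(ch) {
    x <- values[chrom == ch]
    seg <- pcf_dp(x, gamma, min_bins)
    seg$chrom <- ch
    seg
  })
  res <- do.call(rbind, out)
  res[c("chrom", "start_bin", "end_bin", "n_bins", "mean")]
}

pcf_dp <- function(x, gamma, min_bins) {
  n <- length(x)
  one_seg <- function() data.frame(start_bin = 1L, end_bin = n,
                                   n_bins = n, mean = mean(x))
  if (n < 2 * min_bins) return(one_seg())
  cs <- c(0, cumsum(x))
  cs2 <- c(0, cumsum(x^2))
  ## cost of segment (i..j]: SS - sum^2/len, vectorised over i
  best <- rep(Inf, n + 1)
  best[1] <- 0
  prev <- integer(n + 1)
  for (j in seq_len(n)) {
    if (j < min_bins) next
    i <- 0:(j - min_bins) # segment (i, j] has length j - i >= min_bins
    valid <- i == 0 | i >= min_bins # prefix before the cut must be splittable
    i <- i[valid & is.finite(best[i + 1])]
    if (!length(i)) next
    len <- j - i
    cost <- (cs2[j + 1] - cs2[i + 1]) - (cs[j + 1] - cs[i + 1])^2 / len
    tot <- best[i + 1] + cost + gamma
    k <- which.min(tot)
    best[j + 1] <- tot[k]
    prev[j + 1] <- i[k]
  }
  if (!is.finite(best[n + 1])) return(one_seg())
  cuts <- integer(0)
  j <- n
  while (j > 0) {
    cuts <- c(prev[j + 1], cuts)
    j <- prev[j + 1]
  }
  starts <- cuts + 1L
  ends <- c(cuts[-1], n)
  data.frame(start_bin = starts, end_bin = as.integer(ends),
             n_bins = as.integer(ends - starts + 1L),
             mean = vapply(seq_along(starts), function(k)
               mean(x[starts[k]:ends[k]]), numeric(1)))
}

#' Aggregate binned observed/expected over PCF segments
#'
#' @param segments output of [pcf_segment()].
#' @param counts binned track with `count` and `expected` columns.
#' @return `segments` with genomic `start`/`end`, `observed`, `expected`.
#' @export
segment_totals <- function(segments, counts) {
  segments$observed <- NA_real_
  segments$expected <- NA_real_
  segments$start <- NA_real_
  segments$end <- NA_real_
  for (ch in unique(segments$chrom)) {
    b <- counts[counts$chrom == ch, , drop = FALSE]
    sel <- which(segments$chrom == ch)
    for (k in sel) {
      idx <- segments$start_bin[k]:segments$end_bin[k]
      segments$observed[k] <- sum(b$count[idx])
      segments$expected[k] <- sum(b$expected[idx])
      segments$start[k] <- b$start[idx[1]]
      segments$end[k] <- b$end[idx[length(idx)]]
    }
  }
  segments
}

#' Call rearrangement hotspots from fitted segments
#'
#' Per segment, the p-value is the Poisson upper tail
#' `P(X >= observed | expected)`; q-values are Benjamini-Hochberg across
#' segments, and a hotspot requires both `q <= fdr` and a rate ratio of at
#' least `min_rate_ratio`.
#'
#' Because segments are selected by the segmentation scan, adjusting only
#' across the handful of emitted segments is anti-conservative. By default
#' the Benjamini-Hochberg family size is therefore the number of bins
#' scanned (`family = "bins"`), a scan-level correction; `family =
#' "segments"` gives the naive adjustment.
#'
#' A recurrence floor is applied on top of significance: a hotspot must hold
#' at least `min_observed` breakpoint ends (two per SV, so the default of 10
#' asks for roughly five independent events) — isolated spikes supported by
#' one or two rearrangements are never called regardless of their tail
#' probability.
#'
#' @param segments output of [segment_totals()].
#' @param fdr FDR threshold (default 0.05).
#' @param min_rate_ratio minimum observed/expected (default 2).
#' @param min_observed minimum breakpoint ends in a hotspot (default 10).
#' @param family multiple-testing family: "bins" (default) or "segments".
#' @return data.frame of all segments with rate_ratio, p, q, hotspot flag.
#' @export
call_hotspots <- function(segments, fdr = 0.05, min_rate_ratio = 2,
                          min_observed = 10,
                          family = c("bins", "segments")) {
  family <- match.arg(family)
  exp0 <- segments$expected <= 0 & segments$observed > 0
  if (any(exp0)) {
    warning("segments with zero expectation; 0.5 pseudo-expected applied")
    segments$expected[exp0] <- 0.5
  }
  segments$rate_ratio <- ifelse(segments$expected > 0,
                                segments$observed / segments$expected, 0)
  segments$p <- ifelse(
    segments$observed == 0, 1,
    ppois(segments$observed - 1, segments$expected, lower.tail = FALSE))
  n_tests <- if (family == "bins") {
    max(sum(segments$n_bins), length(segments$p))
  } else length(segments$p)
  segments$q <- p.adjust(segments$p, method = "BH", n = n_tests)
  segments$hotspot <- segments$q <= fdr &
    segments$rate_ratio >= min_rate_ratio &
    segments$observed >= min_observed
  segments
}

#' Flag hotspots at putative fragile sites
#'
#' A hotspot is flagged when it overlaps a listed fragile interval, or when
#' it contains a large gene (>= `min_gene_bp`) whose mean replication-timing
#' value falls in the latest-replicating decile genome-wide (higher track
#' value = later replication).
#'
#' @param hotspots hotspot table from [call_hotspots()] (rows with
#'   `hotspot == TRUE` are annotated; others pass through unflagged).
#' @param fragile_intervals data.frame chrom/start/end (0-based half-open)
#'   of curated fragile sites, or NULL.
#' @param large_genes data.frame chrom/start/end/gene, or NULL.
#' @param replication_track binned track (chrom/start/end/value), or NULL.
#' @param min_gene_bp size cutoff for "large" genes (default 600 kb).
#' @return hotspots with `fragile_flag` and `flag_reason` columns, plus
#'   attribute "filtered": the hotspot rows surviving exclusion.
#' @export
flag_fragile <- function(hotspots, fragile_intervals = NULL,
                         large_genes = NULL, replication_track = NULL,
                         min_gene_bp = 6e5) {
  if (is.null(fragile_intervals) && is.null(large_genes))
    stop_invalid("provide at least one fragile-site resource")
  hotspots$fragile_flag <- FALSE
  hotspots$flag_reason <- NA_character_
  hs_rows <- which(hotspots$hotspot)
  if (length(hs_rows)) {
    hs_gr <- GenomicRanges::GRanges(
      hotspots$chrom[hs_rows],
      IRanges::IRanges(hotspots$start[hs_rows] + 1, hotspots$end[hs_rows]))
    if (!is.null(fragile_intervals) && nrow(fragile_intervals)) {
      fr_gr <- GenomicRanges::GRanges(
        fragile_intervals$chrom,
        IRanges::IRanges(fragile_intervals$start + 1, fragile_intervals$end))
      hit <- IRanges::overlapsAny(hs_gr, fr_gr)
      hotspots$fragile_flag[hs_rows[hit]] <- TRUE
      hotspots$flag_reason[hs_rows[hit]] <- "listed-site"
    }
    if (!is.null(large_genes) && nrow(large_genes) &&
        !is.null(replication_track)) {
      big <- large_genes[large_genes$end - large_genes$start >= min_gene_bp,
                         , drop = FALSE]
      if (nrow(big)) {
        gene_gr <- GenomicRanges::GRanges(
          big$chrom, IRanges::IRanges(big$start + 1, big$end))
        rt_gr <- GenomicRanges::GRanges(
          replication_track$chrom,
          IRanges::IRanges(replication_track$start + 1,
                           replication_track$end))
        ov <- GenomicRanges::findOverlaps(gene_gr, rt_gr)
        gene_rt <- vapply(seq_len(nrow(big)), function(g) {
          vals <- replication_track$value[
            S4Vectors::subjectHits(ov)[S4Vectors::queryHits(ov) == g]]
          if (length(vals)) mean(vals) else NA_real_
        }, numeric(1))
        cutoff <- quantile(replication_track$value, 0.9, na.rm = TRUE)
        late_big <- which(!is.na(gene_rt) & gene_rt >= cutoff)
        if (length(late_big)) {
          hit <- IRanges::overlapsAny(hs_gr, gene_gr[late_big])
          newly <- hs_rows[hit & !hotspots$fragile_flag[hs_rows]]
          hotspots$fragile_flag[newly] <- TRUE
          hotspots$flag_reason[newly] <- "large-late-gene"
        }
      }
    }
  }
  attr(hotspots, "filtered") <-
    hotspots[hotspots$hotspot & !hotspots$fragile_flag, , drop = FALSE]
  hotspots
}

#' End-to-end hotspot detection
#'
#' Bins cohort breakpoints, fits the covariate background, segments the
#' observed/expected ratio by PCF and calls hotspots.
#'
#' @param svs pooled cohort SV table.
#' @param genome genome table.
#' @param covariates named list of per-bin covariate vectors (optional).
#' @param bin_width,gamma,min_bins,fdr,min_rate_ratio tuning parameters.
#' @return segment table from [call_hotspots()] with binned track in
#'   `attr(,"track")`.
#' @export
detect_sv_hotspots <- function(svs, genome, covariates = list(),
                               bin_width = 1e5, gamma = NULL, min_bins = 2,
                               fdr = 0.05, min_rate_ratio = 2,
                               min_observed = 10) {
  track <- bin_breakpoints(svs, genome, bin_width)
  track <- fit_background(track, covariates)
  ratio <- ifelse(track$expected > 0, track$count / track$expected, 0)
  segs <- pcf_segment(ratio, chrom = track$chrom, gamma = gamma,
                      min_bins = min_bins)
  segs <- segment_totals(segs, track)
  res <- call_hotspots(segs, fdr = fdr, min_rate_ratio = min_rate_ratio,
                       min_observed = min_observed)
  attr(res, "track") <- track
  res
}
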