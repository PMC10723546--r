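## Shared fixture builders; everything generated in code, no binary files.

## In-memory reference fetcher over named chromosome sequences.
make_fetcher <- function(seqs) {
  function(chrom, start, end) substr(seqs[[chrom]], start, end)
}

## A diploid sample with one gained segment, variants placed directly.
toy_sample <- function(purity = 1, segments = NULL, variants = NULL,
                       ploidy = 2, id = "T1") {
  if (is.null(segments))
    segments <- segment_table("chr1", 1, 1e6, 1, 1)
  if (is.null(variants)) variants <- empty_variants()
  tumour_sample(id, purity = purity, ploidy = ploidy,
                variants = variants, segments = segments)
}

## Random variant table for round-trip property tests.
random_variants <- function(n, seed) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
  idx <- sample.int(n, max(1, n %/% 5)) # some indels
  ref[idx] <- paste0(ref[idx], "T")
  alt[idx] <- substr(ref[idx], 1, 1)
  depth <- sample(20:100, n, replace = TRUE)
  altd <- pmin(depth - 1L, rpois(n, depth / 3))
  variant_table(
    chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
    pos = sample.int(1e6, n), ref = ref, alt = alt,
    ref_depth = depth - altd, alt_depth = altd,
    gene = sample(c(NA, "VHL", "PBRM1"), n, replace = TRUE),
    consequence = sample(c(NA, "missense", "truncating"), n, replace = TRUE))
}

## Exhaustive penalised-least-squares segmentation by plain recursion over
## all cut sets (independent oracle for pcf_segment; n kept small).
pcf_oracle <- function(x, gamma, min_bins = 1) {
  n <- length(x)
  best_cost <- Inf
  best_cuts <- NULL
  sse <- function(seg) sum((seg - mean(seg))^2)
  ## enumerate segmentations via binary cut vectors (n <= ~16) or DP for
  ## larger n with plain un-vectorised loops
  if (n <= 16) {
    for (mask in 0:(2^(n - 1) - 1)) {
      cuts <- which(bitwAnd(mask, 2^(0:(n - 2))) > 0)
      bounds <- c(0, cuts, n)
      lens <- diff(bounds)
      if (any(lens < min_bins)) next
      cost <- gamma * length(lens)
      for (s in seq_along(lens))
        cost <- cost + sse(x[(bounds[s] + 1):bounds[s + 1]])
      if (cost < best_cost) {
        best_cost <- cost
        best_cuts <- bounds
      }
    }
    list(cost = best_cost, bounds = best_cuts)
  } else {
    f <- rep(Inf, n + 1)
    f[1] <- 0
    back <- integer(n + 1)
    for (j in 1:n) {
      for (i in 0:(j - min_bins)) {
        if (i != 0 && i < min_bins) next
        if (!is.finite(f[i + 1])) next
        cost <- f[i + 1] + sse(x[(i + 1):j]) + gamma
        if (cost < f[j + 1]) {
          f[j + 1] <- cost
          back[j + 1] <- i
        }
      }
    }
    bounds <- n
    j <- n
    while (j > 0) {
      j <- back[j + 1]
      bounds <- c(j, bounds)
    }
    list(cost = f[n + 1], bounds = bounds)
  }
}

## Direct-summation Poisson upper tail (oracle).
pois_tail_oracle <- function(k, lambda, terms = 5000) {
  if (k <= 0) return(1)
  1 - sum(exp(-lambda + (0:(k - 1)) * log(lambda) - lfactorial(0:(k - 1))))
}

## Tiny genome used across tests.
tiny_genome <- function(n_chrom = 2, len = 2e6) {
  synthetic_genome(n_chrom = n_chrom, chrom_length = len)
}
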