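test_that("breakpoint binning conserves 2 x n_SV and places translocations", {
  g <- tiny_genome()
  sv <- sv_table("chr1", 150000, "+", "chr1", 160000, "-", "deletion")
  b <- bin_breakpoints(sv, g, 1e5)
  expect_equal(b$count[b$chrom == "chr1" & b$start == 1e5], 2)
  expect_equal(sum(b$count), 2)

  tr <- sv_table("chr1", 50000, "+", "chr2", 1950000, "-", "translocation")
  b2 <- bin_breakpoints(tr, g, 1e5)
  expect_equal(b2$count[b2$chrom == "chr1" & b2$start == 0], 1)
  expect_equal(b2$count[b2$chrom == "chr2" & b2$start == 1.9e6], 1)

  set.seed(4)
  for (rep in 1:5) {
    n <- 200
    rnd <- sv_table(chrom1 = sample(g$chrom, n, TRUE),
                    pos1 = sample.int(2e6, n, TRUE), strand1 = "+",
                    chrom2 = sample(g$chrom, n, TRUE),
                    pos2 = sample.int(2e6, n, TRUE), strand2 = "-")
    expect_equal(sum(bin_breakpoints(rnd, g, 1e5)$count), 2 * n)
  }
  bad <- sv_table("chr1", 1, "+", "chr1", 3e6, "-")
  expect_error(bin_breakpoints(bad, g, 1e5), "beyond")
})

test_that("background fit: intercept-only, GLM recovery, constant covariate", {
  g <- tiny_genome()
  set.seed(12)
  b <- bin_breakpoints(empty_svs(), g, 1e5)
  b$count <- rpois(nrow(b), 3)
  f <- fit_background(b, list())
  expect_equal(f$expected, rep(mean(b$count), nrow(b)))

  ## beta recovery at 30,000 bins
  n <- 30000
  z <- rnorm(n)
  counts <- data.frame(chrom = "chr1", start = 0, end = 1,
                       count = rpois(n, exp(1 + 0.7 * z)))
  f2 <- fit_background(counts, list(cov = z))
  beta <- attr(f2, "coefficients")[["cov"]]
  expect_lt(abs(beta - 0.7), 0.05)
  expect_lt(abs(sum(f2$expected) - sum(counts$count)),
            1e-6 * sum(counts$count))

  ## adding a constant covariate leaves expectations unchanged
  f3 <- fit_background(counts, list(cov = z, const = rep(5, n)))
  expect_equal(f3$expected, f2$expected, tolerance = 1e-8)

  ## collinear covariates fall back to ridge with a warning
  expect_warning(f4 <- fit_background(counts, list(a = z, b = 2 * z)),
                 "ridge")
  expect_lt(abs(sum(f4$expected) - sum(counts$count)), 1e-6 * sum(counts$count))
})

test_that("pcf_segment equals the exhaustive DP oracle", {
  set.seed(3)
  seg_cost <- function(x, segs, gamma) {
    tot <- gamma * nrow(segs)
    for (k in seq_len(nrow(segs))) {
      s <- x[segs$start_bin[k]:segs$end_bin[k]]
      tot <- tot + sum((s - mean(s))^2)
    }
    tot
  }
  ## small signals, exhaustive enumeration over all cut sets
  for (rep in 1:8) {
    x <- rnorm(12) + rep(c(0, sample(0:4, 1)), each = 6)
    gamma <- runif(1, 0.5, 4)
    got <- pcf_segment(x, gamma = gamma, min_bins = 1)
    oracle <- pcf_oracle(x, gamma, min_bins = 1)
    expect_equal(seg_cost(x, got, gamma), oracle$cost, tolerance = 1e-9)
  }
  ## min_bins = 2 respected against the looped DP oracle on 200 bins
  x <- c(rnorm(120), rnorm(80, 5))
  got <- pcf_segment(x, gamma = 1, min_bins = 2)
  oracle <- pcf_oracle(x, 1, min_bins = 2)
  expect_equal(seg_cost(x, got, 1), oracle$cost, tolerance = 1e-9)
  expect_true(all(got$n_bins >= 2))

  ## the 0 -> 5 step changepoint is recovered exactly
  step <- rep(c(0, 5), each = 100)
  gs <- pcf_segment(step, gamma = 1)
  expect_equal(nrow(gs), 2)
  expect_equal(gs$end_bin[1], 100)
  expect_equal(gs$mean, c(0, 5))

  ## limits: constant input one segment; gamma -> Inf one segment;
  ## gamma -> 0 with min_bins 1 gives every bin its own segment
  expect_equal(nrow(pcf_segment(rep(2, 50), gamma = 1)), 1)
  expect_equal(nrow(pcf_segment(rnorm(50), gamma = 1e9)), 1)
  expect_equal(nrow(pcf_segment(rnorm(20), gamma = 1e-12, min_bins = 1)), 20)

  ## chromosome processing order does not matter
  v1 <- rnorm(30); v2 <- rnorm(30, 3)
  a <- pcf_segment(c(v2, v1), rep(c("chr2", "chr1"), each = 30), gamma = 2)
  b <- pcf_segment(c(v1, v2), rep(c("chr1", "chr2"), each = 30), gamma = 2)
  expect_equal(a[a$chrom == "chr1", ], b[b$chrom == "chr1", ],
               ignore_attr = TRUE)
  expect_equal(a[a$chrom == "chr2", ], b[b$chrom == "chr2", ],
               ignore_attr = TRUE)
})

test_that("hotspot calling: Poisson tails, monotone FDR, pseudo-floor", {
  segs <- data.frame(chrom = "chr1", start_bin = c(1, 11), end_bin = c(10, 20),
                     n_bins = 10, mean = c(1, 10),
                     observed = c(3, 30), expected = c(3, 3),
                     start = c(0, 1e6), end = c(1e6, 2e6))
  res <- call_hotspots(segs)
  expect_equal(res$p[2], pois_tail_oracle(30, 3), tolerance = 1e-10)
  expect_equal(res$p[1], ppois(2, 3, lower.tail = FALSE))
  expect_true(res$hotspot[2])
  expect_false(res$hotspot[1])

  ## obs = exp everywhere: nothing called
  flat <- segs
  flat$observed <- flat$expected <- c(5, 5)
  expect_false(any(call_hotspots(flat)$hotspot))

  ## lowering fdr never adds hotspots
  strict <- call_hotspots(segs, fdr = 0.001)
  loose <- call_hotspots(segs, fdr = 0.05)
  expect_true(all(!strict$hotspot | loose$hotspot))

  ## zero expectation with observations: pseudo-floor with warning
  z <- segs
  z$expected <- c(0, 0)
  expect_warning(rz <- call_hotspots(z), "pseudo")
  expect_true(all(rz$expected == 0.5))
})

test_that("fragile-site flagging and exclusion bookkeeping", {
  hs <- data.frame(chrom = "chr1", start_bin = 1, end_bin = 10, n_bins = 10,
                   mean = 5, observed = 50, expected = 5,
                   start = seq(0, 36e6, by = 1e6),
                   end = seq(1e6, 37e6, by = 1e6))
  hs <- hs[1:37, ]
  hs$rate_ratio <- 10
  hs$p <- 1e-8
  hs$q <- 1e-7
  hs$hotspot <- TRUE
  expect_error(flag_fragile(hs), "resource")

  ## empty fragile resources: nothing flagged
  r0 <- flag_fragile(hs, fragile_intervals = data.frame(
    chrom = character(), start = numeric(), end = numeric()))
  expect_false(any(r0$fragile_flag))

  ## 10 of 37 overlap listed fragile sites -> 27 survive
  fragile <- data.frame(chrom = "chr1", start = seq(0, 9e6, by = 1e6),
                        end = seq(0.5e6, 9.5e6, by = 1e6))
  r <- flag_fragile(hs, fragile_intervals = fragile)
  expect_equal(sum(r$fragile_flag), 10)
  expect_equal(unique(r$flag_reason[r$fragile_flag]), "listed-site")
  expect_equal(nrow(attr(r, "filtered")), 27)

  ## large late-replicating gene triggers the second criterion
  genes <- data.frame(chrom = "chr1", start = 20e6, end = 20.7e6,
                      gene = "BIGGENE")
  rt <- data.frame(chrom = "chr1", start = seq(0, 36e6, by = 1e6),
                   end = seq(1e6, 37e6, by = 1e6),
                   value = c(rep(0, 20), 10, rep(0, 16)))
  r2 <- flag_fragile(hs, fragile_intervals = fragile, large_genes = genes,
                     replication_track = rt)
  expect_true(r2$fragile_flag[21])
  expect_equal(r2$flag_reason[21], "large-late-gene")
})

test_that("planted hotspots are recovered on an inhomogeneous background", {
  ## 20 seeded genomes, 5 x fold-10 hotspots, covariate-driven background;
  ## adjusted detection must find all with <= 1 false positive in total,
  ## and the unadjusted baseline must do worse than that
  cfg <- simulation_config(
    genome = synthetic_genome(n_chrom = 4, chrom_length = 6e7),
    ## cohort-pooled breakpoint density: ~19,756 SVs over ~3.1 Gb
    sv_background_rate = 13,
    sv_covariate_effects = c(replication_timing = 0.7, gc = 0.4),
    hotspot_specs = list(
      list(chrom = "chr1", start = 10e6, end = 11e6, fold = 10),
      list(chrom = "chr2", start = 30e6, end = 31e6, fold = 10),
      list(chrom = "chr3", start = 5e6, end = 6e6, fold = 10),
      list(chrom = "chr3", start = 50e6, end = 51e6, fold = 10),
      list(chrom = "chr4", start = 20e6, end = 21e6, fold = 10)),
    seed = 1)
  overlaps_true <- function(seg) {
    any(vapply(cfg$hotspot_specs, function(h) {
      seg$chrom == h$chrom & seg$start < h$end & seg$end > h$start
    }, logical(1)))
  }
  found <- 0; fp_adj <- 0; fp_raw <- 0; missed <- 0
  for (seed in 1:20) {
    sv <- simulate_sv_landscape(cfg, seed = 1000 + seed)
    covs <- attr(sv, "covariates")
    res <- detect_sv_hotspots(sv, cfg$genome, covariates = covs)
    hits <- res[res$hotspot, , drop = FALSE]
    ok <- vapply(seq_len(nrow(hits)), function(i) overlaps_true(hits[i, ]),
                 logical(1))
    fp_adj <- fp_adj + sum(!ok)
    recovered <- vapply(cfg$hotspot_specs, function(h) {
      any(hits$chrom == h$chrom & hits$start < h$end & hits$end > h$start)
    }, logical(1))
    missed <- missed + sum(!recovered)

    raw <- detect_sv_hotspots(sv, cfg$genome, covariates = list())
    rhits <- raw[raw$hotspot, , drop = FALSE]
    rok <- vapply(seq_len(nrow(rhits)), function(i) overlaps_true(rhits[i, ]),
                  logical(1))
    fp_raw <- fp_raw + sum(!rok)
  }
  expect_equal(missed, 0)
  expect_lte(fp_adj, 1)
  expect_gt(fp_raw, 1)
})
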