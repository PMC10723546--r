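test_that("assign_multiplicity matches a likelihood-grid oracle", {
  ## rho = 1, state (2,1), VAF 0.667 at depth 300 -> m = 2, clonal
  call <- assign_multiplicity(200, 100, 2, 1, purity = 1)
  expect_equal(call$multiplicity, 2)
  expect_true(call$clonal)

  ## rho = 1, (1,1), VAF 0.5 -> m = 1, ccf 1
  call2 <- assign_multiplicity(150, 150, 1, 1, purity = 1)
  expect_equal(call2$multiplicity, 1)
  expect_equal(call2$ccf, 1)
  expect_true(call2$clonal)

  ## rho = 0.5, (1,1), VAF 0.05 at depth 500 -> subclonal, ccf ~ 0.2
  call3 <- assign_multiplicity(25, 475, 1, 1, purity = 0.5)
  expect_equal(call3$multiplicity, 1)
  expect_equal(call3$ccf, 0.2, tolerance = 0.01)
  expect_false(call3$clonal)
  expect_lt(call3$ci[2], 1)

  ## grid oracle on random cases: best m maximises dbinom over candidates
  set.seed(14)
  for (rep in 1:25) {
    major <- sample(1:4, 1); minor <- sample(0:major, 1)
    rho <- runif(1, 0.3, 1)
    depth <- sample(50:400, 1)
    alt <- sample.int(depth, 1)
    call <- assign_multiplicity(alt, depth - alt, major, minor, rho)
    nt <- major + minor
    vm <- pmin(seq_len(major) * rho / (rho * nt + 2 * (1 - rho)), 1 - 1e-9)
    oracle_m <- which.max(dbinom(alt, depth, vm))
    expect_equal(call$multiplicity, oracle_m)
  }
  expect_error(assign_multiplicity(5, 5, 0, 0, 1), "untimeable")
})

test_that("molecular time estimators and their boundary behaviour", {
  expect_equal(molecular_time_gain(50, 0, "2+1")$t, 0)
  expect_equal(molecular_time_gain(0, 50, "2+0")$t, 1)
  r <- molecular_time_gain(30, 10, "2+1")
  expect_equal(r$t, 0.6)
  expect_true(r$ci_low <= 0.6 && 0.6 <= r$ci_high)
  ## 2+2 estimator: n1 = 4mu(1-t), n2 = 2mu t -> t = 2 n2/(n1 + 2 n2)
  expect_equal(molecular_time_gain(40, 10, "2+2")$t, 2 * 10 / 60)
  expect_error(molecular_time_gain(5, 5, "2+1"), "untimeable")

  ## forward-simulation recovery: 500 tumours at t = 0.6, mu = 100
  set.seed(77)
  t_hat <- replicate(500, {
    n2 <- rpois(1, 100 * 0.6)
    n1 <- rpois(1, 100 * (3 - 2 * 0.6))
    3 * n2 / (n1 + 2 * n2)
  })
  expect_gte(mean(t_hat), 0.58)
  expect_lte(mean(t_hat), 0.62)
})

test_that("time_wgd pools 2+2 segments and requires a WGD genome", {
  seg <- segment_table("chr1", c(1, 2e6 + 1), c(2e6, 4e6), c(2, 2), c(2, 2))
  diploid <- toy_sample(segments = segment_table("chr1", 1, 4e6, 1, 1))
  expect_error(time_wgd(diploid), "WGD")

  ## all multiplicity-2 mutations -> t = 1
  set.seed(15)
  v2 <- variant_table("chr1", sort(sample.int(4e6, 60)), "C", "T",
                      ref_depth = rbinom(60, 80, 0.5),
                      alt_depth = rbinom(60, 80, 0.5) + 20)
  smp <- toy_sample(purity = 1, ploidy = 4, segments = seg, variants = v2)
  ## with purity 1 and (2,2): v2 = 0.5, v1 = 0.25; all VAF ~ 0.5 -> t ~ 1
  tw <- time_wgd(smp, min_informative = 20)
  expect_gt(tw$t, 0.95)

  ## pooling equals the weighted per-segment combination on a toy
  smp2 <- call_multiplicities(smp)
  cnt1 <- informative_counts(smp2, smp2$segments[1, ], method = "map")
  cnt2 <- informative_counts(smp2, smp2$segments[2, ], method = "map")
  pooled <- molecular_time_gain(cnt1$n1 + cnt2$n1, cnt1$n2 + cnt2$n2, "2+2",
                                min_informative = 10)
  expect_equal(pooled$t,
               2 * (cnt1$n2 + cnt2$n2) /
                 (cnt1$n1 + cnt2$n1 + 2 * (cnt1$n2 + cnt2$n2)))
})

test_that("chronological lead time: closed forms and numeric inversion", {
  ## constant rate (a = 1): L = A(1 - t)
  m1 <- rate_model(clock_rate = 0.1, acceleration = 1, initiation_lead = 0)
  b <- expected_burden(m1, 60)
  expect_equal(chronological_lead_time(0.5, 60, m1, b), 30)
  expect_equal(chronological_lead_time(1, 60, m1, b), 0)

  ## two-phase model vs numeric inversion of the cumulative-rate function
  m2 <- rate_model(clock_rate = 0.1, acceleration = 5, initiation_lead = 10)
  A <- 60
  B <- expected_burden(m2, A)
  cum_rate <- function(g) { # burden accrued by age g
    stats::integrate(function(u) ifelse(u < A - 10, 0.1, 0.5), 0, g,
                     subdivisions = 1000)$value
  }
  for (t in c(0.2, 0.5, 0.8, 0.95)) {
    L <- chronological_lead_time(t, A, m2, B)
    g <- stats::uniroot(function(g) cum_rate(g) - t * B, c(0, A),
                        tol = 1e-10)$root
    expect_equal(L, A - g, tolerance = 0.02) # integrate() straddles the jump
  }

  ## molecular_time_for_lead is the exact inverse
  for (L in c(0, 5, 9.2, 25, 50)) {
    t <- molecular_time_for_lead(L, A, m2)
    expect_equal(chronological_lead_time(t, A, m2, B), L, tolerance = 1e-9)
  }

  ## inconsistent burden triggers a rescale message but stays on scale
  expect_message(L <- chronological_lead_time(0.5, 60, m2, 2 * B),
                 "rescaled")
  expect_true(L >= 0 && L <= 60)
})

test_that("driver clonality odds ratio uses the Haldane correction", {
  r <- driver_clonality_or(10, 0, 100, 100)
  expect_equal(r$odds_ratio, (10.5 / 0.5) / (100.5 / 100.5))
  expect_true(r$ci_low < r$odds_ratio & r$odds_ratio < r$ci_high)
  ## equal split -> OR = 1; label swap inverts
  expect_equal(driver_clonality_or(5, 5, 50, 50)$odds_ratio, 1)
  a <- driver_clonality_or(8, 2, 30, 60)
  b <- driver_clonality_or(2, 8, 60, 30)
  expect_equal(a$odds_ratio, 1 / b$odds_ratio)
  expect_error(driver_clonality_or(0, 0, 1, 1), "no mutations")
})

test_that("Bradley-Terry ordering: dominance, symmetry, duplication", {
  pairs <- data.frame(earlier = rep("A", 20), later = rep("B", 20))
  r <- relative_event_ordering(pairs)
  expect_equal(r$event[1], "A")
  expect_gt(r$strength[1], r$strength[2])

  ## cyclic evidence A>B>C>A equally -> equal strengths
  cyc <- data.frame(earlier = rep(c("A", "B", "C"), each = 10),
                    later = rep(c("B", "C", "A"), each = 10))
  rc <- relative_event_ordering(cyc)
  expect_lt(max(rc$strength) - min(rc$strength), 1e-6)

  ## duplicating every pair leaves the ranking unchanged
  r2 <- relative_event_ordering(rbind(pairs, pairs))
  expect_equal(r2$strength, r$strength, tolerance = 1e-6)

  ## disconnected graphs are ranked per component with a warning
  disc <- rbind(pairs, data.frame(earlier = "X", later = "Y"))
  expect_warning(rd <- relative_event_ordering(disc), "disconnected")
  expect_equal(sort(unique(rd$component)), c(1, 2))
})

test_that("precedence pairs follow the extraction rules", {
  v <- variant_table("chr1", c(100, 200), "C", "T", c(30, 60), c(30, 10),
                     gene = c("VHL", "KMT2C"))
  v$clonal <- c(TRUE, FALSE)
  v$multiplicity <- c(1L, 1L)
  s <- toy_sample(purity = 1, variants = v)
  pp <- extract_precedence_pairs(list(s))
  expect_equal(pp$earlier, "VHL")
  expect_equal(pp$later, "KMT2C")

  ## timed CNAs ordered only when CIs are disjoint
  tm <- data.frame(chrom = c("chr1", "chr1"), start = c(1, 5e5),
                   end = c(4e5, 9e5), state = c("2+1", "2+0"),
                   n1 = 50, n2 = 10, t = c(0.1, 0.8),
                   ci_low = c(0.05, 0.7), ci_high = c(0.2, 0.9))
  pp2 <- extract_precedence_pairs(list(s), list(tm))
  expect_true(any(pp2$earlier == "gain_chr1:2+1" &
                    pp2$later == "gain_chr1:2+0"))
  ## overlapping CIs contribute no pair
  tm$ci_low <- c(0.05, 0.1); tm$ci_high <- c(0.2, 0.9)
  pp3 <- extract_precedence_pairs(list(s), list(tm))
  expect_false(any(grepl("^gain", pp3$earlier) & grepl("^gain", pp3$later)))
})
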