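test_that("variant table enforces its invariants", {
  expect_error(variant_table("chr1", 1, "A", "T", 0, 0),
               "zero total depth")
  v <- variant_table("chr1", c(10, 20), c("A", "AT"), c("G", "A"),
                     c(30, 30), c(10, 15))
  expect_equal(v$variant_class, c("SNV", "deletion"))
  expect_true(all(vaf(v) >= 0 & vaf(v) <= 1))
})

test_that("segment table rejects overlap and inverted intervals", {
  expect_error(segment_table("chr1", c(1, 50), c(100, 200), 1, 1),
               "overlapping")
  expect_error(segment_table("chr1", 100, 50, 1, 1), "end < start")
  expect_error(segment_table("chr1", 1, 10, 1, 2), "major_cn < minor_cn")
})

test_that("sv_table orders intrachromosomal breakpoints", {
  sv <- sv_table("chr1", 500, "+", "chr1", 100, "-", "deletion", "manta")
  expect_equal(sv$pos1, 100)
  expect_equal(sv$strand1, "-")
  expect_equal(sv$pos2, 500)
})

test_that("VCF round trip is lossless, empty body gives empty table", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "t.vcf")
  write_snv_vcf(empty_variants(), path)
  expect_equal(nrow(read_snv_vcf(path)), 0)

  v <- variant_table(
    chrom = c("chr1", "chr1", "chr2"), pos = c(100, 200, 50),
    ref = c("A", "C", "ATT"), alt = c("G", "T", "A"),
    ref_depth = c(30, 40, 25), alt_depth = c(10, 20, 12),
    gene = c("VHL", NA, "PBRM1"),
    consequence = c("missense", NA, "truncating"),
    context = c(NA, "ACA:C>T", NA))
  write_snv_vcf(v, path)
  back <- read_snv_vcf(path)
  expect_equal(back, v[order(v$chrom, v$pos), ], ignore_attr = TRUE)
})

test_that("tabular readers round-trip randomized records", {
  dir <- withr::local_tempdir()
  for (seed in 1:3) {
    v <- random_variants(40, seed)
    p <- file.path(dir, sprintf("v%d.vcf", seed))
    write_snv_vcf(v, p)
    expect_equal(read_snv_vcf(p),
                 v[order(v$chrom, v$pos, v$ref, v$alt), ],
                 ignore_attr = TRUE)
  }
  seg <- segment_table("chr1", c(1, 1001), c(1000, 5000), c(2, 1),
                       c(1, 1), c(1, 0.8))
  sp <- file.path(dir, "s.tsv")
  write_segments(seg, sp)
  expect_equal(read_segments(sp), seg, ignore_attr = TRUE)

  sv <- sv_table(c("chr1", "chr2"), c(100, 5000), c("+", "-"),
                 c("chr1", "chr3"), c(900, 70), c("-", "+"),
                 c("deletion", "translocation"), c("manta,delly", "lumpy"))
  bp <- file.path(dir, "s.bedpe")
  write_sv_bedpe(sv, bp)
  expect_equal(read_sv_bedpe(bp), sv, ignore_attr = TRUE)
})

test_that("indel filter matches brute-force scan and honours the boundary", {
  mk <- function(pos) variant_table("chr1", pos, "AT", "A", 30, 10)
  somatic <- mk(c(100, 111, 150))
  panel <- data.frame(chrom = "chr1", pos = 105)
  res <- filter_indels_near_germline(somatic, panel, window_bp = 10)
  expect_setequal(res$removed$pos, c(100, 111))
  expect_setequal(res$kept$pos, 150)

  ## distance exactly 10 removed (inclusive), 11 kept; exclusive flips it
  som2 <- mk(c(115, 116))
  res2 <- filter_indels_near_germline(som2, panel, window_bp = 10)
  expect_equal(res2$removed$pos, 115)
  res2x <- filter_indels_near_germline(som2, panel, window_bp = 10,
                                       inclusive = FALSE)
  expect_equal(nrow(res2x$removed), 0)

  ## empty panel keeps everything; SNVs rejected
  res3 <- filter_indels_near_germline(somatic,
                                      data.frame(chrom = character(),
                                                 pos = integer()))
  expect_equal(nrow(res3$kept), 3)
  expect_error(
    filter_indels_near_germline(variant_table("chr1", 5, "A", "T", 10, 5),
                                panel), "SNV")

  ## brute-force oracle on random inputs
  set.seed(42)
  for (rep in 1:5) {
    sp <- sort(sample.int(5000, 300))
    pp <- sort(sample.int(5000, 60))
    som <- variant_table("chr1", sp, "AT", "A", 30, 10)
    pan <- data.frame(chrom = "chr1", pos = pp)
    res <- filter_indels_near_germline(som, pan, window_bp = 10)
    brute <- vapply(sp, function(p) any(abs(pp - p) <= 10), logical(1))
    expect_setequal(res$removed$pos, sp[brute])
    expect_equal(nrow(res$kept) + nrow(res$removed), length(sp))
  }
})

test_that("consensus_sv merges by single linkage across callers", {
  base <- list(chrom1 = "chr1", pos1 = 1000L, strand1 = "+",
               chrom2 = "chr1", pos2 = 9000L, strand2 = "-")
  mk <- function(p1, p2, cls = "deletion") {
    sv_table("chr1", p1, "+", "chr1", p2, "-", cls)
  }
  callsets <- list(manta = mk(1000, 9000), lumpy = mk(1100, 9100),
                   delly = mk(500000, 600000))
  res <- consensus_sv(callsets, slop_bp = 300, min_callers = 2)
  expect_equal(nrow(res), 1)
  expect_equal(res$callers, "lumpy,manta")
  expect_equal(res$pos1, 1050) # median of 1000,1100

  ## chain-linking: a-b and b-c within slop, a-c not
  chain <- list(a = mk(1000, 9000), b = mk(1250, 9000), c = mk(1500, 9000))
  res2 <- consensus_sv(chain, slop_bp = 300, min_callers = 3)
  expect_equal(nrow(res2), 1)
  expect_equal(res2$callers, "a,b,c")

  ## singleton dropped at min_callers = 2
  expect_equal(nrow(consensus_sv(list(a = mk(1, 100), b = mk(5e5, 6e5)))), 0)

  ## permutation invariance in caller order
  res_rev <- consensus_sv(rev(callsets), slop_bp = 300, min_callers = 2)
  expect_equal(res, res_rev)

  ## incompatible classes are not merged; unclassified merges with anything
  incompat <- list(a = mk(1000, 9000, "deletion"),
                   b = mk(1000, 9000, "inversion"))
  expect_equal(nrow(consensus_sv(incompat)), 0)
  mixed <- list(a = mk(1000, 9000, "deletion"),
                b = mk(1000, 9000, "unclassified"))
  resm <- consensus_sv(mixed)
  expect_equal(resm$sv_class, "deletion")
})

test_that("TMB arithmetic", {
  v <- random_variants(100, 1)
  smp <- toy_sample(variants = v)
  expect_error(compute_tmb(smp, 0), "callable_mb")
  r <- compute_tmb(smp, 50)
  expect_equal(r$snv_per_mb, sum(v$variant_class == "SNV") / 50)
  r2 <- compute_tmb(smp, 100)
  expect_equal(r2$snv_per_mb, r$snv_per_mb / 2)
  expect_equal(compute_tmb(toy_sample(), 10)$snv_per_mb, 0)
  ## worked example: 5,640 SNVs over 3,000 Mb = 1.88/Mb
  big <- toy_sample(variants = variant_table(
    "chr1", seq_len(5640), "A", "T", 30, 10))
  expect_equal(compute_tmb(big, 3000)$snv_per_mb, 1.88)
})

test_that("trinucleotide context collapses all 12 substitutions correctly", {
  fetch <- make_fetcher(list(chr1 = "GACGT")) # positions 1..5
  expect_equal(trinucleotide_context("chr1", 3, "C", "T", fetch), "ACG:C>T")
  ## purine ref reported on the reverse complement
  fetchG <- make_fetcher(list(chr1 = "TTGAA"))
  expect_equal(trinucleotide_context("chr1", 3, "G", "A", fetchG),
               "TCA:C>T")

  ## oracle: enumerate all 12 ref>alt pairs in a fixed AxT flank
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (ref in c("A", "C", "G", "T")) {
    for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
      f <- make_fetcher(list(chr1 = paste0("A", ref, "T")))
      got <- trinucleotide_context("chr1", 2, ref, alt, f)
      if (ref %in% c("C", "T")) {
        expect_equal(got, paste0("A", ref, "T:", ref, ">", alt))
      } else {
        expect_equal(got, paste0("A", comp[ref], "T:",
                                 comp[ref], ">", comp[alt]))
      }
      expect_true(got %in% context_classes())
    }
  }

  expect_error(trinucleotide_context("chr1", 3, "A", "T",
                                     make_fetcher(list(chr1 = "GACGT"))),
               "mismatch")
  expect_error(trinucleotide_context("chr1", 3, "CT", "C", fetch), "SNV")
})
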