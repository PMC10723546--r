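## Synthetic tumour-cohort generator with full ground truth.
##
## Mutation placement follows the same timing algebra the estimators invert:
## for a clonal gain at molecular time t with per-copy clonal intensity mu
## (expected mutations per copy over the segment), the multiplicity-2 and
## multiplicity-1 counts are Poisson with means
##   2+1: (mu*t, mu*(3 - 2t));  2+0: (mu*t, 2*mu*(1 - t));
##   2+2: (2*mu*t, 4*mu*(1 - t));  diploid 1+1: (0, 2*mu).
## Read counts are binomial at Poisson depth with expected VAF
## m*rho*c / (rho*n_t + 2*(1 - rho)).

#' Default kidney-like trinucleotide mutation profile
#'
#' Relative weights over the 96 substitution classes emulating a clock-like
#' background (CpG-elevated C>T as in SBS1, mildly elevated T>C as in
#' SBS5/SBS40); normalised to sum to 1. Signature fitting itself is out of
#' scope — only a context-inhomogeneous background is needed.
#' @return named numeric of length 96 summing to 1.
#' @export
default_context_profile <- function() {
  cls <- context_classes()
  w <- rep(1, length(cls))
  names(w) <- cls
  w[endsWith(cls, ":C>T") & substr(cls, 3, 3) == "G"] <- 8 # NpCpG C>T
  w[endsWith(cls, ":T>C")] <- 1.8
  w / sum(w)
}

#' Simulation configuration
#'
#' The stated world of the synthetic cohort. Defaults mirror the quantities
#' the source cohort reports where available (WGD in 16.6% of tumours with a
#' mean lead of 9.2 years; HLA LOH 5.9%, HLA mutation 0.5%, APG inactivation
#' 3.1%; a 2+1 gain with a 35.5-year lead emulating 5q gain) and otherwise
#' use values chosen once for realism (60x depth, purity 0.5-0.9, clock rate
#' 0.05 mut/Mb/year with 5-fold acceleration over the final 10 years).
#'
#' @param n_samples cohort size.
#' @param genome genome table (`synthetic_genome()` by default).
#' @param depth_mean mean sequencing depth (Poisson).
#' @param purity_range uniform sampling interval for purity, within (0,1].
#' @param context_rates named 96-class relative weights (normalised
#'   internally).
#' @param gain_events list of lists with chrom, start, end, major, minor and
#'   either `time` (molecular, in `[0,1]`) or `lead_years`.
#' @param wgd_fraction fraction of samples with whole-genome duplication.
#' @param wgd_lead_years chronological lead of WGD in affected samples.
#' @param sv_background_rate breakpoints per Mb.
#' @param sv_class_mix named mixture over intrachromosomal SV classes.
#' @param hotspot_specs list of lists with chrom, start, end, fold (>= 1).
#' @param sv_covariate_effects named numeric log-linear effects of the
#'   simulated covariate tracks on breakpoint intensity.
#' @param driver_element_specs list of lists with element_id, chrom, start,
#'   end, fold (>= 1): mutation intensity inside the element is multiplied
#'   by fold.
#' @param escape_specs list with per-sample probabilities `hla_loh`,
#'   `hla_mutation`, `apg` (or a data.frame of explicit per-sample flags).
#' @param hla_locus list(chrom, start, end): the synthetic HLA class I locus.
#' @param clock_rate_per_year,acceleration_factor,initiation_lead_years the
#'   two-phase rate model (see [rate_model()]).
#' @param age_range uniform sampling interval for age at sampling.
#' @param subclonal_fraction subclonal burden as a fraction of clonal burden.
#' @param subclonal_ccf cancer-cell fraction of subclonal mutations.
#' @param indel_fraction fraction of somatic calls simulated as indels.
#' @param seed master seed; per-sample streams are derived from it.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(
    n_samples = 100,
    genome = synthetic_genome(),
    depth_mean = 60,
    purity_range = c(0.5, 0.9),
    context_rates = default_context_profile(),
    gain_events = list(
      list(chrom = "chr2", start = 1L, end = 30000000L, major = 2L,
           minor = 1L, lead_years = 35.5),
      list(chrom = "chr3", start = 10000000L, end = 40000000L, major = 2L,
           minor = 0L, time = 0.5)),
    wgd_fraction = 0.166,
    wgd_lead_years = 9.2,
    sv_background_rate = 0.5,
    sv_class_mix = c(deletion = 0.35, `tandem-duplication` = 0.25,
                     inversion = 0.2, unclassified = 0.2),
    hotspot_specs = list(),
    sv_covariate_effects = c(replication_timing = 0, gc = 0),
    driver_element_specs = list(),
    escape_specs = list(hla_loh = 0.059, hla_mutation = 0.005, apg = 0.031),
    hla_locus = list(chrom = "chr4", start = 20000001L, end = 22000000L),
    clock_rate_per_year = 0.05,
    acceleration_factor = 5,
    initiation_lead_years = 10,
    age_range = c(45, 80),
    subclonal_fraction = 0.25,
    subclonal_ccf = 0.4,
    indel_fraction = 0.05,
    seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "simulation_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  if (cfg$n_samples < 1) stop_invalid("n_samples must be >= 1")
  if (cfg$depth_mean <= 0) stop_invalid("depth_mean must be positive")
  if (cfg$clock_rate_per_year <= 0)
    stop_invalid("clock rate must be positive")
  if (any(cfg$purity_range <= 0) || any(cfg$purity_range > 1))
    stop_invalid("purity_range outside (0,1]")
  bnd <- cfg$genome$arm_boundary %||% cfg$genome$centromere
  if (is.null(bnd) || any(bnd <= 0) || any(bnd >= cfg$genome$length))
    stop_invalid("arm boundary must lie strictly inside each chromosome")
  for (g in cfg$gain_events) {
    if (!is.null(g$time) && (g$time < 0 || g$time > 1))
      stop_invalid("gain molecular time outside [0,1]")
    if (!(seg_state(g$major, g$minor) %in% TIMEABLE_STATES))
      stop_invalid("unsupported gain state %s", seg_state(g$major, g$minor))
  }
  for (h in cfg$hotspot_specs)
    if (h$fold < 1) stop_invalid("hotspot fold-enrichment must be >= 1")
  for (e in cfg$driver_element_specs)
    if (e$fold < 1) stop_invalid("element fold-enrichment must be >= 1")
  if (cfg$wgd_fraction < 0 || cfg$wgd_fraction > 1)
    stop_invalid("wgd_fraction outside [0,1]")
  if (cfg$sv_background_rate <= 0)
    stop_invalid("sv_background_rate must be positive")
  if (cfg$acceleration_factor < 1)
    stop_invalid("acceleration_factor must be >= 1")
  invisible(cfg)
}

config_rate_model <- function(cfg) {
  rate_model(cfg$clock_rate_per_year, cfg$acceleration_factor,
             cfg$initiation_lead_years)
}

## Build the per-sample segment table: baseline state everywhere, gains and
## the HLA-LOH lesion overlaid.
build_segments <- function(cfg, wgd, hla_loh) {
  base_major <- if (wgd) 2L else 1L
  base_minor <- if (wgd) 2L else 1L
  events <- cfg$gain_events
  if (hla_loh) {
    events <- c(events, list(list(
      chrom = cfg$hla_locus$chrom, start = cfg$hla_locus$start,
      end = cfg$hla_locus$end, major = base_major, minor = 0L,
      time = NA_real_)))
  }
  rows <- list()
  for (i in seq_len(nrow(cfg$genome))) {
    ch <- cfg$genome$chrom[i]
    len <- cfg$genome$length[i]
    ev <- Filter(function(e) e$chrom == ch, events)
    ev <- ev[order(vapply(ev, `[[`, numeric(1), "start"))]
    cursor <- 1L
    for (e in ev) {
      if (e$start > cursor)
        rows[[length(rows) + 1]] <- list(ch, cursor, e$start - 1L,
                                         base_major, base_minor)
      rows[[length(rows) + 1]] <- list(ch, e$start, e$end,
                                       as.integer(e$major),
                                       as.integer(e$minor))
      cursor <- e$end + 1L
    }
    if (cursor <= len)
      rows[[length(rows) + 1]] <- list(ch, cursor, len,
                                       base_major, base_minor)
  }
  segment_table(
    chrom = vapply(rows, `[[`, "", 1),
    start = vapply(rows, function(r) r[[2]], numeric(1)),
    end = vapply(rows, function(r) r[[3]], numeric(1)),
    major_cn = vapply(rows, function(r) r[[4]], numeric(1)),
    minor_cn = vapply(rows, function(r) r[[5]], numeric(1)))
}

## Draw variant rows for one copy-number segment.
sample_variant_block <- function(cfg, n, chrom, start, end, mult, ccf,
                                 purity, n_t) {
  if (n <= 0) return(NULL)
  pos <- sort(sample.int(end - start + 1L, n, replace = TRUE) + start - 1L)
  profile <- cfg$context_rates / sum(cfg$context_rates)
  is_indel <- runif(n) < cfg$indel_fraction
  cls <- sample(names(profile), n, replace = TRUE, prob = profile)
  ref <- substr(cls, 2, 2)
  alt <- substr(cls, 7, 7)
  ctx <- cls
  ## indels: 1-bp insertions/deletions, no trinucleotide class
  ins <- is_indel & runif(n) < 0.5
  del <- is_indel & !ins
  ref[ins] <- "A"; alt[ins] <- "AT"
  ref[del] <- "AT"; alt[del] <- "A"
  ctx[is_indel] <- NA_character_
  vaf <- pmin(mult * purity * ccf / (purity * n_t + 2 * (1 - purity)), 1)
  depth <- pmax(1L, rpois(n, cfg$depth_mean))
  alt_d <- rbinom(n, depth, vaf)
  variant_table(chrom = chrom, pos = pos, ref = ref, alt = alt,
                ref_depth = depth - alt_d, alt_depth = alt_d,
                context = ctx)
}

#' Simulate one tumour sample with ground truth
#'
#' @param config `simulation_config`.
#' @param sample_index index in 1..n_samples (fixes the per-sample RNG
#'   stream).
#' @return list with `sample` (a `tumour_sample`, SVs included) and `truth`
#'   (gain times, escape flags, per-variant multiplicity/CCF).
#' @export
simulate_sample <- function(config, sample_index) {
  validate_config(config)
  if (sample_index < 1 || sample_index > config$n_samples)
    stop_invalid("sample_index outside 1..n_samples")
  set.seed(derive_seed(config$seed, sample_index))
  model <- config_rate_model(config)

  purity <- runif(1, config$purity_range[1], config$purity_range[2])
  age <- round(runif(1, config$age_range[1], config$age_range[2]))
  wgd <- runif(1) < config$wgd_fraction
  esc <- config$escape_specs
  if (is.data.frame(esc)) {
    flags <- esc[sample_index, ]
    hla_loh <- isTRUE(flags$hla_loh)
    hla_mut <- isTRUE(flags$hla_mutation)
    apg <- isTRUE(flags$apg)
  } else {
    hla_loh <- runif(1) < esc$hla_loh
    hla_mut <- runif(1) < esc$hla_mutation
    apg <- runif(1) < esc$apg
  }

  burden <- expected_burden(model, age) # clonal SNVs+indels per Mb, diploid
  mu_copy_mb <- burden / 2 # per-copy intensity per Mb

  segments <- build_segments(config, wgd, hla_loh)
  gain_truth <- list()
  blocks <- list()
  truth_rows <- list()

  add_block <- function(block, mult, ccf, clonal) {
    if (is.null(block)) return()
    blocks[[length(blocks) + 1]] <<- block
    truth_rows[[length(truth_rows) + 1]] <<- data.frame(
      chrom = block$chrom, pos = block$pos, true_multiplicity = mult,
      true_ccf = ccf, true_clonal = clonal, stringsAsFactors = FALSE)
  }

  gain_time <- function(e) {
    if (!is.null(e$time) && !is.na(e$time)) e$time
    else molecular_time_for_lead(e$lead_years, age, model)
  }
  gain_lookup <- list()
  for (e in config$gain_events) {
    t <- gain_time(e)
    gain_lookup[[paste(e$chrom, e$start)]] <- t
    gain_truth[[length(gain_truth) + 1]] <- data.frame(
      chrom = e$chrom, start = e$start, end = e$end,
      state = seg_state(e$major, e$minor), t = t,
      lead_years = chronological_lead_time(t, age, model, burden),
      stringsAsFactors = FALSE)
  }
  t_wgd <- if (wgd) molecular_time_for_lead(config$wgd_lead_years, age,
                                            model) else NA_real_

  for (i in seq_len(nrow(segments))) {
    seg <- segments[i, ]
    n_t <- seg$major_cn + seg$minor_cn
    len_mb <- (seg$end - seg$start + 1) / 1e6
    mu <- mu_copy_mb * len_mb
    state <- seg_state(seg$major_cn, seg$minor_cn)
    key <- paste(seg$chrom, seg$start)
    t <- gain_lookup[[key]] %||%
      (if (wgd && state == "2+2") t_wgd else NA_real_)
    if (state %in% TIMEABLE_STATES && !is.na(t)) {
      means <- switch(state,
        "2+1" = c(m2 = mu * t, m1 = mu * (3 - 2 * t)),
        "2+0" = c(m2 = mu * t, m1 = 2 * mu * (1 - t)),
        "2+2" = c(m2 = 2 * mu * t, m1 = 4 * mu * (1 - t)))
      add_block(sample_variant_block(config, rpois(1, means["m2"]),
                                     seg$chrom, seg$start, seg$end, 2, 1,
                                     purity, n_t), 2L, 1, TRUE)
      add_block(sample_variant_block(config, rpois(1, means["m1"]),
                                     seg$chrom, seg$start, seg$end, 1, 1,
                                     purity, n_t), 1L, 1, TRUE)
    } else {
      ## untimed state: all clonal mutations at multiplicity 1 per copy
      add_block(sample_variant_block(config, rpois(1, n_t * mu),
                                     seg$chrom, seg$start, seg$end, 1, 1,
                                     purity, n_t), 1L, 1, TRUE)
    }
    ## subclonal mutations at the configured CCF
    n_sub <- rpois(1, config$subclonal_fraction * 2 * mu)
    add_block(sample_variant_block(config, n_sub, seg$chrom, seg$start,
                                   seg$end, 1, config$subclonal_ccf,
                                   purity, n_t),
              1L, config$subclonal_ccf, FALSE)
  }

  ## non-coding driver elements: extra clonal mutations at (fold - 1) x
  for (e in config$driver_element_specs) {
    seg_idx <- which(segments$chrom == e$chrom & segments$start <= e$start &
                       segments$end >= e$end)[1]
    n_t <- if (is.na(seg_idx)) 2L else
      segments$major_cn[seg_idx] + segments$minor_cn[seg_idx]
    len_mb <- (e$end - e$start + 1) / 1e6
    extra <- rpois(1, (e$fold - 1) * 2 * mu_copy_mb * len_mb)
    blk <- sample_variant_block(config, extra, e$chrom, e$start, e$end,
                                1, 1, purity, n_t)
    if (!is.null(blk)) {
      blk$gene <- e$element_id
      blk$consequence <- "non-coding"
      add_block(blk, 1L, 1, TRUE)
    }
  }

  variants <- if (length(blocks)) do.call(rbind, blocks) else empty_variants()
  truth_variants <- if (length(truth_rows)) do.call(rbind, truth_rows)
                    else NULL

  ## escape lesions: truncating mutations in HLA / a random APG
  escape_variant <- function(gene, chrom, pos, n_t) {
    depth <- max(1L, rpois(1, config$depth_mean))
    vaf <- min(purity / (purity * n_t + 2 * (1 - purity)), 1)
    alt_d <- rbinom(1, depth, vaf)
    variant_table(chrom = chrom, pos = pos, ref = "C", alt = "A",
                  ref_depth = depth - alt_d, alt_depth = alt_d,
                  gene = gene, consequence = "truncating")
  }
  if (hla_mut) {
    variants <- rbind(variants, escape_variant(
      "HLA-A", config$hla_locus$chrom, config$hla_locus$start + 1000L, 2L))
  }
  apg_gene <- NA_character_
  if (apg) {
    apg_gene <- sample(default_apg_genes(), 1)
    variants <- rbind(variants, escape_variant(
      apg_gene, config$genome$chrom[1], 500000L, 2L))
  }

  ploidy <- {
    len <- as.numeric(segments$end - segments$start + 1)
    sum(len * (segments$major_cn + segments$minor_cn)) / sum(len)
  }
  smp <- tumour_sample(
    sample_id = sprintf("S%04d", sample_index), purity = purity,
    ploidy = ploidy, age_at_sampling = age,
    grade = sample(1:4, 1), stage = sample(1:4, 1),
    variants = variants, segments = segments)
  truth <- list(
    sample_id = smp$sample_id, purity = purity, age = age,
    burden_per_mb = burden, wgd = wgd, t_wgd = t_wgd,
    wgd_lead_years = if (wgd) config$wgd_lead_years else NA_real_,
    gains = if (length(gain_truth)) do.call(rbind, gain_truth) else NULL,
    hla_loh = hla_loh, hla_mutation = hla_mut, apg = apg,
    apg_gene = apg_gene, variants = truth_variants)
  list(sample = smp, truth = truth)
}

#' Simulate a cohort-level structural-variant landscape
#'
#' Breakpoints arise from an inhomogeneous Poisson process over genome bins:
#' log-intensity = log(background per bin) + covariate effects +
#' log(fold) inside hotspot intervals. Breakpoints are paired uniformly at
#' random into SV records; intrachromosomal pairs draw a class from the
#' configured mixture, interchromosomal pairs are translocations.
#'
#' @param config `simulation_config`.
#' @param seed RNG seed for this landscape.
#' @param bin_width intensity bin width (default 100 kb).
#' @return SV table; attributes: `bins` (with true per-bin intensity),
#'   `covariates` (named list of tracks), `hotspots` (true intervals).
#' @export
simulate_sv_landscape <- function(config, seed = config$seed,
                                  bin_width = 1e5) {
  validate_config(config)
  if (nrow(config$genome) == 0) stop_invalid("empty genome")
  set.seed(seed)
  bins <- make_bins(config$genome, bin_width)
  nb <- nrow(bins)
  ## smooth synthetic covariate tracks (replication timing-like, GC-like)
  mk_track <- function() {
    phase <- runif(1, 0, 2 * pi)
    per <- runif(1, 40, 120)
    sin(seq_len(nb) / per * 2 * pi + phase) + rnorm(nb, 0, 0.2)
  }
  covs <- lapply(config$sv_covariate_effects, function(b) mk_track())
  names(covs) <- names(config$sv_covariate_effects)
  log_int <- log(config$sv_background_rate * (bins$end - bins$start) / 1e6)
  for (k in seq_along(covs)) {
    z <- (covs[[k]] - mean(covs[[k]])) / sd(covs[[k]])
    log_int <- log_int + config$sv_covariate_effects[[k]] * z
  }
  for (h in config$hotspot_specs) {
    sel <- bins$chrom == h$chrom & bins$start >= h$start & bins$end <= h$end
    log_int[sel] <- log_int[sel] + log(h$fold)
  }
  counts <- rpois(nb, exp(log_int))
  total <- sum(counts)
  if (total < 2) {
    out <- empty_svs()
  } else {
    bp <- data.frame(
      chrom = rep(bins$chrom, counts),
      pos = rep(bins$start, counts) +
        ceiling(runif(total) * rep(bins$end - bins$start, counts)))
    ord <- sample.int(total)
    half <- floor(total / 2)
    a <- bp[ord[seq_len(half)], ]
    b <- bp[ord[half + seq_len(half)], ]
    intra <- a$chrom == b$chrom
    cls <- character(half)
    cls[intra] <- sample(names(config$sv_class_mix), sum(intra),
                         replace = TRUE, prob = config$sv_class_mix)
    cls[!intra] <- "translocation"
    out <- sv_table(chrom1 = a$chrom, pos1 = a$pos,
                    strand1 = sample(c("+", "-"), half, replace = TRUE),
                    chrom2 = b$chrom, pos2 = b$pos,
                    strand2 = sample(c("+", "-"), half, replace = TRUE),
                    sv_class = cls, callers = "sim")
  }
  bins$intensity <- exp(log_int)
  attr(out, "bins") <- bins
  attr(out, "covariates") <- covs
  attr(out, "hotspots") <- config$hotspot_specs
  out
}

#' Simulate a full cohort
#'
#' @param config `simulation_config`.
#' @param with_svs also draw a per-sample SV landscape (default TRUE).
#' @return list with `samples` (list of `tumour_sample`) and `truth`
#'   (per-sample ground-truth list; cohort-level SV hotspot intervals).
#' @export
simulate_cohort <- function(config, with_svs = TRUE) {
  samples <- vector("list", config$n_samples)
  truth <- vector("list", config$n_samples)
  for (i in seq_len(config$n_samples)) {
    res <- simulate_sample(config, i)
    if (with_svs) {
      svs <- simulate_sv_landscape(config,
                                   seed = derive_seed(config$seed, -i))
      res$sample$svs <- svs
    }
    samples[[i]] <- res$sample
    truth[[i]] <- res$truth
  }
  list(samples = samples, truth = truth,
       hotspots = config$hotspot_specs, config_seed = config$seed)
}

#' Write a simulated cohort to disk
#'
#' Emits per-sample VCF, segment TSV and BEDPE, a cohort clinical table and
#' a ground-truth JSON, all deterministic given the cohort. Files round-trip
#' through the package readers losslessly.
#'
#' @param cohort output of [simulate_cohort()].
#' @param out_dir output directory (created if needed).
#' @return invisible manifest data.frame (file, kind, n_records), also
#'   written as `manifest.json`.
#' @export
write_cohort <- function(cohort, out_dir) {
  samples <- cohort$samples
  if (!length(samples)) stop_invalid("empty cohort")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  note <- function(file, kind, n) manifest[[length(manifest) + 1]] <<-
    data.frame(file = file, kind = kind, n_records = n,
               stringsAsFactors = FALSE)
  for (s in samples) {
    vcf <- file.path(out_dir, paste0(s$sample_id, ".snv.vcf"))
    write_snv_vcf(s$variants, vcf, sample_name = s$sample_id)
    note(basename(vcf), "vcf", nrow(s$variants))
    seg <- file.path(out_dir, paste0(s$sample_id, ".segments.tsv"))
    write_segments(s$segments, seg)
    note(basename(seg), "segments", nrow(s$segments))
    bedpe <- file.path(out_dir, paste0(s$sample_id, ".sv.bedpe"))
    write_sv_bedpe(s$svs, bedpe)
    note(basename(bedpe), "bedpe", nrow(s$svs))
  }
  clinical <- data.frame(
    sample_id = vapply(samples, `[[`, "", "sample_id"),
    purity = vapply(samples, `[[`, 0, "purity"),
    ploidy = vapply(samples, `[[`, 0, "ploidy"),
    age_at_sampling = vapply(samples, `[[`, 0, "age_at_sampling"),
    grade = vapply(samples, function(s) as.integer(s$grade), 0L),
    stage = vapply(samples, function(s) as.integer(s$stage), 0L),
    stringsAsFactors = FALSE)
  write_clinical(clinical, file.path(out_dir, "clinical.tsv"))
  note("clinical.tsv", "clinical", nrow(clinical))
  jsonlite::write_json(cohort$truth, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  note("ground_truth.json", "truth", length(cohort$truth))
  mf <- do.call(rbind, manifest)
  jsonlite::write_json(mf, file.path(out_dir, "manifest.json"),
                       digits = NA, pretty = TRUE)
  invisible(mf)
}

#' Read a written cohort back into memory
#' @param dir directory written by [write_cohort()].
#' @return list of `tumour_sample`s.
#' @export
read_cohort <- function(dir) {
  clinical <- read_clinical(file.path(dir, "clinical.tsv"))
  lapply(seq_len(nrow(clinical)), function(i) {
    id <- clinical$sample_id[i]
    tumour_sample(
      sample_id = id, purity = clinical$purity[i],
      ploidy = clinical$ploidy[i],
      age_at_sampling = clinical$age_at_sampling[i],
      grade = clinical$grade[i], stage = clinical$stage[i],
      variants = read_snv_vcf(file.path(dir, paste0(id, ".snv.vcf"))),
      segments = read_segments(file.path(dir, paste0(id, ".segments.tsv"))),
      svs = read_sv_bedpe(file.path(dir, paste0(id, ".sv.bedpe"))))
  })
}
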