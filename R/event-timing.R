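## Timing of copy-number events from mutation multiplicities.
##
## Model. In a clonal tumour of purity rho, a mutation on m of the n_t tumour
## copies at a locus has expected VAF
##     v_m = m * rho / (rho * n_t + 2 * (1 - rho)).
## Mutations that occurred before a gain are carried on the duplicated copy
## and end up at multiplicity 2; mutations after the gain are at multiplicity
## 1. Writing t in [0,1] for the fraction of the clonal mutation burden
## accrued before the gain and mu for the per-copy clonal mutation intensity:
##   2+1 gain:  E[n2] = mu*t,   E[n1] = mu*(3 - 2t)
##   2+0 (CN-LOH): E[n2] = mu*t, E[n1] = 2*mu*(1 - t)
##   2+2 (WGD):  E[n2] = 2*mu*t, E[n1] = 4*mu*(1 - t)
## giving the moment estimators t = 3*n2/(n1 + 2*n2) (2+1) and
## t = 2*n2/(n1 + 2*n2) (2+0 and 2+2).

TIMEABLE_STATES <- c("2+1", "2+0", "2+2")

#' Two-phase somatic mutation-rate model
#'
#' Constant clock rate `clock_rate` (mutations/Mb/year per diploid genome)
#' from birth until `initiation_lead` years before sampling, then
#' `acceleration` times that rate. Used to convert molecular times into
#' chronological gain ages.
#'
#' @param clock_rate baseline mutations per Mb per year (default 0.05).
#' @param acceleration rate multiplier after tumour initiation, >= 1
#'   (default 5).
#' @param initiation_lead years between tumour initiation and sampling
#'   (default 10).
#' @return object of class `rate_model`.
#' @export
rate_model <- function(clock_rate = 0.05, acceleration = 5,
                       initiation_lead = 10) {
  if (clock_rate <= 0) stop_invalid("clock_rate must be > 0")
  if (acceleration < 1) stop_invalid("acceleration must be >= 1")
  if (initiation_lead < 0) stop_invalid("initiation_lead must be >= 0")
  structure(list(clock_rate = clock_rate, acceleration = acceleration,
                 initiation_lead = initiation_lead), class = "rate_model")
}

#' Expected clonal burden per Mb under a rate model
#' @param model `rate_model`.
#' @param age age at sampling in years.
#' @return mutations per Mb.
#' @export
expected_burden <- function(model, age) {
  if (age < model$initiation_lead)
    stop_invalid("initiation_lead exceeds age")
  model$clock_rate * (age - model$initiation_lead) +
    model$acceleration * model$clock_rate * model$initiation_lead
}

#' Assign mutation multiplicity and cancer-cell fraction
#'
#' The best multiplicity maximises the binomial likelihood of the observed
#' alt depth over candidate multiplicities 1..major_cn. The CCF estimate is
#' the observed VAF rescaled by the copy-number/purity factor, and the call
#' is clonal when the exact binomial 95% CI for the CCF includes (or lies
#' above) 1.
#'
#' @param alt_depth,ref_depth read counts at the site.
#' @param major_cn,minor_cn copy number of the containing segment.
#' @param purity tumour purity rho in (0,1].
#' @param conf CI level for the clonality call (default 0.95).
#' @return list with `multiplicity`, `ccf`, `clonal`, `ci` (CCF scale), and
#'   `loglik` per candidate multiplicity.
#' @export
assign_multiplicity <- function(alt_depth, ref_depth, major_cn, minor_cn,
                                purity, conf = 0.95) {
  n_t <- major_cn + minor_cn
  if (n_t == 0) stop_invalid("segment with zero total copy number is untimeable")
  if (purity <= 0 || purity > 1) stop_invalid("purity outside (0,1]")
  depth <- alt_depth + ref_depth
  if (depth <= 0) stop_invalid("zero read depth")
  denom <- purity * n_t + 2 * (1 - purity)
  m_cand <- seq_len(max(major_cn, 1L))
  v_m <- pmin(m_cand * purity / denom, 1 - 1e-9)
  ll <- dbinom(alt_depth, depth, v_m, log = TRUE)
  m <- m_cand[which.max(ll)]
  obs_vaf <- alt_depth / depth
  ccf <- obs_vaf * denom / (purity * m)
  ci_vaf <- binom.test(alt_depth, depth, conf.level = conf)$conf.int
  ci <- ci_vaf * denom / (purity * m)
  clonal <- (ci[1] <= 1 && ci[2] >= 1) || ci[1] > 1
  list(multiplicity = m, ccf = ccf, clonal = clonal,
       ci = as.numeric(ci), loglik = setNames(ll, m_cand))
}

#' Multiplicity calls for every variant in a sample
#'
#' Maps each SNV to its containing copy-number segment and calls
#' multiplicity/clonality; variants outside any segment are left NA.
#'
#' @param sample `tumour_sample`.
#' @param conf CI level.
#' @return the sample with `multiplicity`, `clonal`, `ccf` columns filled.
#' @export
call_multiplicities <- function(sample, conf = 0.95) {
  v <- sample$variants
  s <- sample$segments
  if (nrow(v) == 0 || nrow(s) == 0) return(sample)
  seg_gr <- GenomicRanges::GRanges(s$chrom, IRanges::IRanges(s$start, s$end))
  var_gr <- GenomicRanges::GRanges(v$chrom, IRanges::IRanges(v$pos, v$pos))
  hits <- GenomicRanges::findOverlaps(var_gr, seg_gr, select = "first")
  rho <- sample$purity
  alpha <- 1 - conf
  for (j in unique(hits[!is.na(hits)])) {
    idx <- which(!is.na(hits) & hits == j)
    n_t <- s$major_cn[j] + s$minor_cn[j]
    if (n_t == 0) next
    denom <- rho * n_t + 2 * (1 - rho)
    m_cand <- seq_len(max(s$major_cn[j], 1L))
    v_m <- pmin(m_cand * rho / denom, 1 - 1e-9)
    alt <- v$alt_depth[idx]
    depth <- alt + v$ref_depth[idx]
    ll <- vapply(v_m, function(p) dbinom(alt, depth, p, log = TRUE),
                 numeric(length(idx)))
    if (is.null(dim(ll))) ll <- matrix(ll, nrow = length(idx))
    m <- m_cand[max.col(ll, ties.method = "first")]
    obs_vaf <- alt / depth
    ccf <- obs_vaf * denom / (rho * m)
    ## exact Clopper-Pearson CI on the VAF, rescaled to CCF
    lo <- stats::qbeta(alpha / 2, alt, depth - alt + 1)
    hi <- stats::qbeta(1 - alpha / 2, alt + 1, depth - alt)
    lo[alt == 0] <- 0
    hi[alt == depth] <- 1
    ci_lo <- lo * denom / (rho * m)
    ci_hi <- hi * denom / (rho * m)
    v$multiplicity[idx] <- m
    v$ccf[idx] <- ccf
    v$clonal[idx] <- (ci_lo <= 1 & ci_hi >= 1) | ci_lo > 1
  }
  sample$variants <- v
  sample
}

#' Molecular time of a clonal copy-number gain
#'
#' @param n1 count of informative clonal mutations at multiplicity 1.
#' @param n2 count at multiplicity 2.
#' @param state copy-number state: "2+1", "2+0" or "2+2".
#' @param min_informative minimum n1+n2 to attempt timing (default 20).
#' @param n_boot multinomial bootstrap resamples for the CI (default 200).
#' @param conf CI level (default 0.95).
#' @return list with `t`, `ci_low`, `ci_high`, `n1`, `n2`, `state`; or an
#'   error if the segment is uninformative.
#' @export
molecular_time_gain <- function(n1, n2, state,
                                min_informative = 20, n_boot = 200,
                                conf = 0.95) {
  state <- match.arg(state, TIMEABLE_STATES)
  if (n1 < 0 || n2 < 0) stop_invalid("negative mutation counts")
  n <- n1 + n2
  if (n < min_informative)
    stop_invalid("untimeable: %d informative mutations < %d", n,
                 min_informative)
  est <- function(a, b) {
    t <- if (state == "2+1") 3 * b / (a + 2 * b) else 2 * b / (a + 2 * b)
    min(max(t, 0), 1)
  }
  t_hat <- est(n1, n2)
  bs <- rmultinom(n_boot, as.integer(round(n)), c(n1, n2) / n)
  t_bs <- apply(bs, 2, function(x) est(x[1], x[2]))
  alpha <- (1 - conf) / 2
  ci <- unname(quantile(t_bs, c(alpha, 1 - alpha), names = FALSE))
  list(t = t_hat, ci_low = ci[1], ci_high = ci[2], n1 = n1, n2 = n2,
       state = state)
}

#' Informative multiplicity counts for a segment
#'
#' Splits the clonal mutations inside a segment into multiplicity-1 and
#' multiplicity-2 counts. `method = "map"` counts hard per-variant calls
#' from [call_multiplicities()]. `method = "em"` (default for timing)
#' instead fits a two-component binomial mixture with known component VAFs
#' and returns the expected counts `n * pi_hat`: hard assignment is biased
#' towards the majority component whenever the two VAF distributions
#' overlap (moderate depth or purity), and the mixture MLE removes that
#' bias.
#'
#' @param sample `tumour_sample` after [call_multiplicities()].
#' @param segment one row of the segment table.
#' @param method "em" or "map".
#' @return list(n1, n2) (real-valued under "em").
#' @export
informative_counts <- function(sample, segment, method = c("em", "map")) {
  method <- match.arg(method)
  v <- sample$variants
  if (method == "map") {
    inside <- v$chrom == segment$chrom & v$pos >= segment$start &
      v$pos <= segment$end & !is.na(v$multiplicity) & !is.na(v$clonal) &
      v$clonal & v$multiplicity %in% c(1L, 2L)
    return(list(n1 = sum(inside & v$multiplicity == 1),
                n2 = sum(inside & v$multiplicity == 2)))
  }
  inside <- v$chrom == segment$chrom & v$pos >= segment$start &
    v$pos <= segment$end
  if (sum(inside) == 0) return(list(n1 = 0, n2 = 0))
  n_t <- segment$major_cn + segment$minor_cn
  denom <- sample$purity * n_t + 2 * (1 - sample$purity)
  v1 <- min(sample$purity / denom, 1 - 1e-9)
  v2 <- min(2 * sample$purity / denom, 1 - 1e-9)
  fit <- mixture_multiplicity(v$alt_depth[inside],
                              v$alt_depth[inside] + v$ref_depth[inside],
                              v1, v2)
  n <- sum(inside)
  list(n1 = n * fit$pi[2], n2 = n * fit$pi[3])
}

## Three-component binomial mixture over a segment's mutations: a subclonal
## component with free VAF (bounded below v1), plus the clonal
## multiplicity-1 and multiplicity-2 components at their known VAFs.
## Returns mixing weights (sub, m1, m2) and the fitted subclonal VAF.
mixture_multiplicity <- function(alt, depth, v1, v2, tol = 1e-8,
                                 max_iter = 500) {
  pi_k <- c(0.2, 0.5, 0.3)
  vs <- 0.4 * v1
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    f <- cbind(dbinom(alt, depth, vs), dbinom(alt, depth, v1),
               dbinom(alt, depth, v2))
    num <- sweep(f, 2, pi_k, `*`)
    rowsum_ <- rowSums(num) + 1e-300
    r <- num / rowsum_
    pi_k <- colMeans(r)
    ws <- sum(r[, 1] * alt) / max(sum(r[, 1] * depth), 1e-12)
    vs <- min(max(ws, 0.02 * v1), 0.9 * v1)
    ll <- sum(log(rowsum_))
    if (abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  list(pi = pi_k, v_sub = vs)
}

seg_state <- function(major_cn, minor_cn) {
  paste0(major_cn, "+", minor_cn)
}

#' Time every eligible gained segment of a sample
#'
#' Runs [call_multiplicities()] if needed, then times each clonal segment in
#' a supported state (2+1, 2+0, 2+2) holding enough informative mutations.
#'
#' @param sample `tumour_sample`.
#' @param method informative-count extraction, see [informative_counts()].
#' @inheritParams molecular_time_gain
#' @return data.frame with one row per timed segment: chrom, start, end,
#'   state, n1, n2, t, ci_low, ci_high.
#' @export
time_gains <- function(sample, min_informative = 20, n_boot = 200,
                       conf = 0.95, method = c("em", "map")) {
  method <- match.arg(method)
  if (method == "map" && all(is.na(sample$variants$multiplicity)))
    sample <- call_multiplicities(sample)
  out <- list()
  for (i in seq_len(nrow(sample$segments))) {
    seg <- sample$segments[i, ]
    st <- seg_state(seg$major_cn, seg$minor_cn)
    if (!(st %in% TIMEABLE_STATES) || seg$clonal_fraction < 1) next
    cnt <- informative_counts(sample, seg, method = method)
    if (cnt$n1 + cnt$n2 < min_informative) next
    tm <- molecular_time_gain(cnt$n1, cnt$n2, st,
                              min_informative = min_informative,
                              n_boot = n_boot, conf = conf)
    out[[length(out) + 1]] <- data.frame(
      chrom = seg$chrom, start = seg$start, end = seg$end, state = st,
      n1 = cnt$n1, n2 = cnt$n2, t = tm$t, ci_low = tm$ci_low,
      ci_high = tm$ci_high, stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), state = character(), n1 = integer(),
                      n2 = integer(), t = numeric(), ci_low = numeric(),
                      ci_high = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Molecular time of whole-genome duplication
#'
#' Pools informative multiplicity-1/2 counts across all clonal 2+2 segments
#' and applies the 2+2 estimator with a pooled multinomial bootstrap.
#'
#' @param sample `tumour_sample`; must satisfy the WGD call ([call_wgd()]).
#' @param method informative-count extraction, see [informative_counts()].
#' @inheritParams molecular_time_gain
#' @return as [molecular_time_gain()], with `state = "2+2"`.
#' @export
time_wgd <- function(sample, min_informative = 20, n_boot = 200,
                     conf = 0.95, method = c("em", "map")) {
  method <- match.arg(method)
  if (!call_wgd(sample))
    stop_invalid("time_wgd requires a WGD sample")
  if (method == "map" && all(is.na(sample$variants$multiplicity)))
    sample <- call_multiplicities(sample)
  n1 <- 0L; n2 <- 0L
  for (i in seq_len(nrow(sample$segments))) {
    seg <- sample$segments[i, ]
    if (seg$major_cn == 2 && seg$minor_cn == 2 && seg$clonal_fraction >= 1) {
      cnt <- informative_counts(sample, seg, method = method)
      n1 <- n1 + cnt$n1
      n2 <- n2 + cnt$n2
    }
  }
  molecular_time_gain(n1, n2, "2+2", min_informative = min_informative,
                      n_boot = n_boot, conf = conf)
}

#' Chronological lead time of a gain
#'
#' Inverts the two-phase cumulative mutation-rate curve: the clonal burden
#' accrued before the gain is `t * B` (B = clonal burden per Mb); if that
#' falls inside the constant-rate phase the gain age is `t*B / r0`, otherwise
#' the excess accrues at the accelerated rate. The lead time is years between
#' the gain and sampling, L = age - gain_age.
#'
#' When the observed burden disagrees with the model prediction by more than
#' `rescale_tol` (relative), the clock rate is rescaled so the model
#' reproduces the observed burden, and a message is emitted.
#'
#' @param t molecular time in `[0, 1]`.
#' @param age age at sampling (years).
#' @param model `rate_model`.
#' @param burden_per_mb observed clonal SNV burden per Mb.
#' @param rescale_tol relative tolerance before rescaling (default 0.2).
#' @return lead time L in years (0 <= L <= age).
#' @export
chronological_lead_time <- function(t, age, model, burden_per_mb,
                                    rescale_tol = 0.2) {
  if (t < 0 || t > 1) stop_invalid("molecular time outside [0,1]")
  if (age <= 0) stop_invalid("age must be positive")
  tau <- model$initiation_lead
  if (tau > age) stop_invalid("initiation_lead exceeds age")
  a <- model$acceleration
  r0 <- model$clock_rate
  b_pred <- expected_burden(model, age)
  if (abs(burden_per_mb - b_pred) / b_pred > rescale_tol) {
    r0 <- burden_per_mb / ((age - tau) + a * tau)
    message(sprintf(
      "clock rate rescaled from %.4g to %.4g to match observed burden",
      model$clock_rate, r0))
  }
  before <- t * burden_per_mb
  b_phase1 <- r0 * (age - tau)
  gain_age <- if (before <= b_phase1) before / r0
              else (age - tau) + (before - b_phase1) / (a * r0)
  max(min(age - gain_age, age), 0)
}

#' Molecular time of a gain with a given chronological lead
#'
#' Exact inverse of [chronological_lead_time()] under a consistent burden:
#' given the years between a gain and sampling, returns the fraction of the
#' clonal burden accrued before the gain.
#'
#' @param lead years before sampling (0 <= lead <= age).
#' @param age age at sampling.
#' @param model `rate_model`.
#' @return molecular time t in `[0, 1]`.
#' @export
molecular_time_for_lead <- function(lead, age, model) {
  if (lead < 0 || lead > age) stop_invalid("lead outside [0, age]")
  tau <- model$initiation_lead
  a <- model$acceleration
  r0 <- model$clock_rate
  gain_age <- age - lead
  before <- r0 * min(gain_age, age - tau) +
    a * r0 * max(0, gain_age - (age - tau))
  before / expected_burden(model, age)
}

#' Odds ratio that mutations in a gene are clonal
#'
#' Compares the clonal/subclonal split of a gene's mutations against all
#' other mutations, with a Haldane-Anscombe 0.5 correction in every cell and
#' a Woolf logit confidence interval.
#'
#' @param clonal_gene,subclonal_gene counts in the gene.
#' @param clonal_rest,subclonal_rest counts elsewhere.
#' @param conf CI level (default 0.95).
#' @return list(odds_ratio, ci_low, ci_high).
#' @export
driver_clonality_or <- function(clonal_gene, subclonal_gene,
                                clonal_rest, subclonal_rest, conf = 0.95) {
  if (clonal_gene + subclonal_gene == 0)
    stop_invalid("gene has no mutations")
  x <- c(clonal_gene, subclonal_gene, clonal_rest, subclonal_rest) + 0.5
  or <- (x[1] / x[2]) / (x[3] / x[4])
  se <- sqrt(sum(1 / x))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  list(odds_ratio = or, ci_low = or * exp(-z * se),
       ci_high = or * exp(z * se))
}

#' Clonality odds ratios for a cohort and gene
#'
#' @param cohort list of `tumour_sample`s with multiplicities called.
#' @param gene gene symbol.
#' @return as [driver_clonality_or()].
#' @export
cohort_clonality_or <- function(cohort, gene) {
  cg <- sg <- cr <- sr <- 0L
  seen <- FALSE
  for (s in cohort) {
    v <- s$variants
    v <- v[!is.na(v$clonal), , drop = FALSE]
    in_gene <- !is.na(v$gene) & v$gene == gene
    if (any(in_gene)) seen <- TRUE
    cg <- cg + sum(in_gene & v$clonal)
    sg <- sg + sum(in_gene & !v$clonal)
    cr <- cr + sum(!in_gene & v$clonal)
    sr <- sr + sum(!in_gene & !v$clonal)
  }
  if (!seen) stop_invalid("gene %s absent from cohort", gene)
  driver_clonality_or(cg, sg, cr, sr)
}

#' Rank events from pairwise precedence evidence
#'
#' Fits a Bradley-Terry model by minorisation-maximisation to the precedence
#' pairs (each row: an event observed before another in one tumour). Events
#' in disconnected comparison components are ranked within their component
#' (with a warning); strengths are normalised to mean 1 per component.
#'
#' @param precedence_pairs data.frame with columns `earlier`, `later`.
#' @param tol convergence tolerance on strengths (default 1e-8).
#' @param max_iter iteration cap.
#' @return data.frame ordered by decreasing strength: event, strength,
#'   component, wins, losses.
#' @export
relative_event_ordering <- function(precedence_pairs, tol = 1e-8,
                                    max_iter = 10000) {
  if (nrow(precedence_pairs) == 0) stop_invalid("no precedence pairs")
  events <- sort(unique(c(precedence_pairs$earlier, precedence_pairs$later)))
  k <- length(events)
  w <- matrix(0, k, k, dimnames = list(events, events)) # w[i,j] = i before j
  for (r in seq_len(nrow(precedence_pairs))) {
    i <- match(precedence_pairs$earlier[r], events)
    j <- match(precedence_pairs$later[r], events)
    w[i, j] <- w[i, j] + 1
  }
  n_ij <- w + t(w)
  ## connectivity
  parent <- uf_new(k)
  idx <- which(n_ij > 0, arr.ind = TRUE)
  for (r in seq_len(nrow(idx)))
    parent <- uf_union(parent, idx[r, 1], idx[r, 2])
  comp <- uf_components(parent)
  if (length(unique(comp)) > 1)
    warning("comparison graph is disconnected; ranking per component")
  p <- rep(1, k)
  wins <- rowSums(w)
  for (it in seq_len(max_iter)) {
    denom <- vapply(seq_len(k), function(i) {
      js <- which(n_ij[i, ] > 0)
      if (!length(js)) return(1)
      sum(n_ij[i, js] / (p[i] + p[js]))
    }, numeric(1))
    p_new <- ifelse(wins > 0, wins / denom, p * 1e-3)
    ## normalise within components (MM fixes strengths up to per-component scale)
    for (cc in unique(comp)) {
      sel <- comp == cc
      p_new[sel] <- p_new[sel] / mean(p_new[sel])
    }
    if (max(abs(p_new - p)) < tol) { p <- p_new; break }
    p <- p_new
  }
  out <- data.frame(event = events, strength = p,
                    component = match(comp, unique(comp)),
                    wins = rowSums(w), losses = colSums(w),
                    stringsAsFactors = FALSE)
  out <- out[order(out$component, -out$strength), ]
  rownames(out) <- NULL
  out
}

#' Extract precedence pairs from a timed, multiplicity-called cohort
#'
#' Rules: a clonal driver mutation precedes any subclonal driver mutation in
#' the same tumour; a multiplicity-2 mutation inside a timed clonal gain
#' precedes that gain; two timed copy-number events are ordered when their
#' bootstrap CIs are disjoint. Ties contribute no pair.
#'
#' @param cohort list of `tumour_sample`s.
#' @param timings list (per sample) of [time_gains()] tables, optional.
#' @return data.frame of `earlier`, `later` event labels.
#' @export
extract_precedence_pairs <- function(cohort, timings = NULL) {
  pairs <- list()
  add <- function(a, b) pairs[[length(pairs) + 1]] <<- data.frame(
    earlier = a, later = b, stringsAsFactors = FALSE)
  for (si in seq_along(cohort)) {
    s <- cohort[[si]]
    v <- s$variants
    drv <- !is.na(v$gene) & !is.na(v$clonal)
    cl_genes <- unique(v$gene[drv & v$clonal])
    sub_genes <- unique(v$gene[drv & !v$clonal])
    for (a in cl_genes) for (b in setdiff(sub_genes, a)) add(a, b)
    tm <- if (!is.null(timings)) timings[[si]] else NULL
    if (!is.null(tm) && nrow(tm)) {
      labels <- paste0("gain_", tm$chrom, ":", tm$state)
      ## mult-2 driver mutation precedes its containing timed gain
      for (r in seq_len(nrow(tm))) {
        inside <- drv & v$chrom == tm$chrom[r] & v$pos >= tm$start[r] &
          v$pos <= tm$end[r] & !is.na(v$multiplicity) & v$multiplicity == 2
        for (g in unique(v$gene[inside])) add(g, labels[r])
      }
      ## order timed events by disjoint bootstrap CIs
      if (nrow(tm) > 1) {
        for (a in seq_len(nrow(tm) - 1)) for (b in seq(a + 1, nrow(tm))) {
          if (tm$ci_high[a] < tm$ci_low[b]) add(labels[a], labels[b])
          else if (tm$ci_high[b] < tm$ci_low[a]) add(labels[b], labels[a])
        }
      }
    }
  }
  if (!length(pairs))
    return(data.frame(earlier = character(), later = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, pairs)
}
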