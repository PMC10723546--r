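## Non-coding driver recurrence testing against a trinucleotide-context
## background, pairwise co-occurrence analysis, and the pathogenic-fraction
## comparison.
##
## Background model. Each 96-class substitution context c has a cohort-wide
## per-site mutation rate r_c; an element e with n_{e,c} callable sites of
## context c then expects mu_e = sum_c n_{e,c} * r_c mutations. Observed
## element counts y_e are modelled as negative binomial around mu_e with a
## single dispersion theta shared across elements (estimated by maximum
## likelihood, method-of-moments fallback), and recurrence is the NB upper
## tail P(Y >= y_e) with Benjamini-Hochberg control across elements.

#' Cohort-wide per-context mutation rates
#'
#' @param variants variant table (or list of samples) with `context` filled
#'   for SNVs.
#' @param callable_abundance named numeric: callable site count per 96-class
#'   context, summed over the cohort (per-sample abundance times samples).
#' @return named numeric rate per site per class (0 for unobserved classes
#'   present in `callable_abundance`).
#' @export
estimate_context_rates <- function(variants, callable_abundance) {
  if (is.list(variants) && !is.data.frame(variants))
    variants <- do.call(rbind, lapply(variants, `[[`, "variants"))
  snv <- variants[variants$variant_class == "SNV" & !is.na(variants$context),
                  , drop = FALSE]
  counts <- table(factor(snv$context, levels = names(callable_abundance)))
  orphan <- setdiff(unique(snv$context), names(callable_abundance))
  if (length(orphan))
    stop_invalid("mutations observed in context %s with no callable abundance",
                 orphan[1])
  bad <- counts > 0 & callable_abundance[names(counts)] <= 0
  if (any(bad))
    stop_invalid("context %s has mutations but zero abundance",
                 names(counts)[bad][1])
  rates <- as.numeric(counts) / as.numeric(callable_abundance[names(counts)])
  rates[callable_abundance[names(counts)] <= 0] <- 0
  setNames(rates, names(counts))
}

#' Expected mutation count of an element under the context background
#'
#' @param element list with `element_id` and `context_abundance` (named
#'   numeric site counts per context).
#' @param rates per-context rates from [estimate_context_rates()].
#' @return expected count mu_e.
#' @export
expected_element_count <- function(element, rates) {
  ab <- element$context_abundance
  if (is.null(ab) || !length(ab)) return(0)
  used <- intersect(names(ab), names(rates))
  missing <- names(ab)[ab > 0 & !(names(ab) %in% names(rates))]
  if (length(missing) && any(rates > 0))
    stop_invalid("element %s has abundance in context %s with no rate",
                 element$element_id %||% "?", missing[1])
  sum(ab[used] * rates[used])
}

nb_loglik <- function(log_theta, y, mu) {
  sum(dnbinom(y, size = exp(log_theta), mu = mu, log = TRUE))
}

estimate_nb_theta <- function(y, mu) {
  keep <- mu > 0
  y <- y[keep]; mu <- mu[keep]
  if (!length(y)) return(Inf)
  fit <- try(optimize(nb_loglik, c(-8, 20), y = y, mu = mu,
                      maximum = TRUE), silent = TRUE)
  theta <- if (!inherits(fit, "try-error")) exp(fit$maximum) else NA_real_
  if (is.na(theta) || !is.finite(theta)) {
    ## method-of-moments: alpha = 1/theta from sum[(y-mu)^2 - mu] / sum mu^2
    alpha <- sum((y - mu)^2 - mu) / sum(mu^2)
    theta <- if (alpha <= 0) Inf else 1 / alpha
  }
  ## near the boundary the likelihood is flat: treat as Poisson
  if (theta > exp(19)) theta <- Inf
  theta
}

nb_upper_tail <- function(y, mu, theta) {
  ## P(Y >= y); y = 0 gives 1 by construction
  if (y <= 0) return(1)
  if (mu <= 0) return(if (y > 0) 0 else 1) # callers guard mu == 0
  if (is.infinite(theta)) ppois(y - 1, mu, lower.tail = FALSE)
  else pnbinom(y - 1, size = theta, mu = mu, lower.tail = FALSE)
}

#' Recurrence test of genomic elements
#'
#' @param elements list of elements, each a list with `element_id`,
#'   optionally `intervals` (data.frame chrom/start/end, 0-based half-open)
#'   and `context_abundance`.
#' @param observed named integer of observed counts per element; if NULL,
#'   computed by overlapping `variants` with each element's intervals.
#' @param variants cohort variant table (used when `observed` is NULL).
#' @param rates per-context background rates; required unless `expected`
#'   given.
#' @param expected optional named numeric of precomputed mu_e.
#' @param fdr call threshold on q (default 0.05).
#' @return data.frame (one row per element): element_id, observed, expected,
#'   theta, p, q, called.
#' @export
test_elements <- function(elements, observed = NULL, variants = NULL,
                          rates = NULL, expected = NULL, fdr = 0.05) {
  if (length(elements) < 20)
    stop_invalid("test_elements needs >= 20 elements for dispersion estimation")
  ids <- vapply(elements, function(e) e$element_id, character(1))
  if (is.null(expected)) {
    if (is.null(rates)) stop_invalid("supply rates or expected")
    expected <- vapply(elements, expected_element_count, numeric(1),
                       rates = rates)
  }
  if (is.null(observed)) {
    if (is.null(variants)) stop_invalid("supply observed or variants")
    observed <- vapply(elements, function(e) {
      iv <- e$intervals
      sum(vapply(seq_len(nrow(iv)), function(i) {
        sum(variants$chrom == iv$chrom[i] & variants$pos > iv$start[i] &
              variants$pos <= iv$end[i])
      }, numeric(1)))
    }, numeric(1))
  }
  observed <- as.numeric(observed)
  expected <- as.numeric(expected)
  if (all(observed == 0)) {
    return(data.frame(element_id = ids, observed = 0, expected = expected,
                      theta = Inf, p = 1, q = 1, called = FALSE,
                      stringsAsFactors = FALSE))
  }
  theta <- estimate_nb_theta(observed, expected)
  p <- vapply(seq_along(observed), function(i) {
    mu <- expected[i]
    if (mu <= 0) {
      if (observed[i] > 0) {
        warning(sprintf("element %s observed with zero expectation; 0.5 floor",
                        ids[i]))
        mu <- 0.5
      } else return(1)
    }
    nb_upper_tail(observed[i], mu, theta)
  }, numeric(1))
  q <- bh_adjust(p)
  data.frame(element_id = ids, observed = observed, expected = expected,
             theta = theta, p = p, q = q, called = q <= fdr,
             stringsAsFactors = FALSE)
}

#' Pairwise driver co-occurrence / mutual exclusivity
#'
#' Two-sided Fisher exact test per gene pair on the 2x2 sample table.
#' Direction from the Haldane-Anscombe-corrected odds ratio (applied to the
#' OR only, not the p-value); genes mutated in all or no samples are
#' untestable and excluded from the Benjamini-Hochberg family.
#'
#' @param mutation_matrix binary gene x sample matrix.
#' @return data.frame: gene_a, gene_b, n11, n10, n01, n00, odds_ratio, p, q,
#'   direction, testable.
#' @export
cooccurrence_test <- function(mutation_matrix) {
  if (nrow(mutation_matrix) < 2 || ncol(mutation_matrix) < 2)
    stop_invalid("need >= 2 genes and >= 2 samples")
  m <- mutation_matrix != 0
  genes <- rownames(m) %||% paste0("gene", seq_len(nrow(m)))
  constant <- rowSums(m) %in% c(0L, ncol(m))
  rows <- list()
  for (i in seq_len(nrow(m) - 1)) for (j in seq(i + 1, nrow(m))) {
    n11 <- sum(m[i, ] & m[j, ]); n10 <- sum(m[i, ] & !m[j, ])
    n01 <- sum(!m[i, ] & m[j, ]); n00 <- sum(!m[i, ] & !m[j, ])
    testable <- !constant[i] && !constant[j]
    p <- if (testable)
      fisher.test(matrix(c(n11, n01, n10, n00), 2))$p.value else NA_real_
    or <- ((n11 + 0.5) * (n00 + 0.5)) / ((n10 + 0.5) * (n01 + 0.5))
    rows[[length(rows) + 1]] <- data.frame(
      gene_a = genes[i], gene_b = genes[j], n11 = n11, n10 = n10,
      n01 = n01, n00 = n00, odds_ratio = or, p = p,
      direction = ifelse(or < 1, "mutually-exclusive", "co-occurring"),
      testable = testable, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  res$q <- NA_real_
  res$q[res$testable] <- bh_adjust(res$p[res$testable])
  res[order(res$q), ]
}

#' Compare two pathogenic-call fractions
#'
#' Two-proportion chi-square test with continuity correction, as used to
#' contrast the pathogenic fraction of driver-gene missense SNVs against
#' non-driver genes.
#'
#' @param hit_a,total_a numerator/denominator of the first group.
#' @param hit_b,total_b second group.
#' @return list(fraction_a, fraction_b, p_value).
#' @export
pathogenicity_fraction_compare <- function(hit_a, total_a, hit_b, total_b) {
  if (total_a <= 0 || total_b <= 0) stop_invalid("totals must be positive")
  if (hit_a > total_a || hit_b > total_b)
    stop_invalid("hits exceed totals")
  fa <- hit_a / total_a
  fb <- hit_b / total_b
  p <- if (hit_a + hit_b == 0) 1
       else prop.test(c(hit_a, hit_b), c(total_a, total_b))$p.value
  list(fraction_a = fa, fraction_b = fb, p_value = p)
}
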