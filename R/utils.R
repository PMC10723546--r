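#' @importFrom stats p.adjust ppois pnbinom dnbinom dbinom rbinom rpois runif
#'   rmultinom optimize glm poisson fisher.test binom.test prop.test var
#'   setNames quantile rnorm median sd ks.test
#' @importFrom utils head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) stop(sprintf(...), call. = FALSE)

#' Convert between coordinate conventions
#'
#' All VCF and segment-table coordinates in this package are 1-based inclusive;
#' bins, BED and BEDPE intervals are 0-based half-open. These two helpers are
#' the only place the conversion happens.
#'
#' @param start,end interval bounds in the source convention.
#' @return A two-column matrix-like list with converted `start` and `end`.
#' @keywords internal
to_zero_based <- function(start, end) list(start = start - 1L, end = end)

#' @rdname to_zero_based
#' @keywords internal
to_one_based <- function(start, end) list(start = start + 1L, end = end)

#' Benjamini-Hochberg adjusted p-values
#'
#' Thin wrapper kept so every module adjusts within a single explicitly stated
#' test family.
#' @param p numeric vector of p-values.
#' @return adjusted q-values.
#' @keywords internal
bh_adjust <- function(p) p.adjust(p, method = "BH")

## Union-find with path compression; used for single-linkage clustering of
## structural-variant calls and for connectivity of the event-ordering graph.
uf_new <- function(n) seq_len(n)

uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

uf_union <- function(parent, i, j) {
  ri <- uf_find(parent, i)
  rj <- uf_find(parent, j)
  if (ri != rj) parent[ri] <- rj
  parent
}

uf_components <- function(parent) {
  vapply(seq_along(parent), function(i) uf_find(parent, i), integer(1))
}

## Deterministic per-sample seed derived from a master seed; stays < 2^31.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(index) * 104729) %% 2147483647)
}
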