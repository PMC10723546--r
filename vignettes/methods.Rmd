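---
title: "Models and methods behind renalwgs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind renalwgs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

renalwgs re-implements, as reusable and tested components, the bespoke
computational stages of a whole-genome-sequencing analysis of a large clear
cell renal cell carcinoma (ccRCC) cohort: somatic-call curation, non-coding
driver recurrence testing, driver co-occurrence analysis, rearrangement
hotspot detection, molecular and chronological timing of copy-number events,
genome-instability metrics, and genetic immune-evasion classification. Since
cohorts of this kind sit behind controlled-access environments, the package
ships a synthetic tumour-cohort generator with complete ground truth;
everything downstream is exercised against it.

## Data model

Variants, allele-specific copy-number segments (Battenberg-style columns)
and structural variants are plain data frames with fixed column sets; a
`tumour_sample` bundles them with purity, ploidy and clinical covariates.
VCF and segment tables use 1-based inclusive coordinates; bins, BED and
BEDPE are 0-based half-open. The conversion lives in exactly one place.

## Somatic-call curation

* **Indel proximity filter.** A somatic indel is removed when a common
  germline indel lies within 10 bp on the same chromosome. The boundary is
  read inclusively (a distance of exactly 10 bp removes the call); the
  strict reading is available via `inclusive = FALSE` because the published
  wording ("within 10 base pairs") does not pin it down.
* **SV consensus.** Calls from multiple callers merge by single linkage
  when both breakpoints agree within 300 bp with matching orientations and
  compatible classes ("unclassified" is compatible with everything);
  a consensus call needs two distinct callers by default and takes median
  breakpoint positions. Slop and caller thresholds mirror common
  multi-caller practice and are configurable.
* **Trinucleotide context.** SNVs map onto the standard 96 pyrimidine-
  centred classes; purine-reference sites are reverse-complemented.

## Non-coding driver recurrence

Each context class `c` gets a cohort-wide per-site rate
`r_c = (cohort SNVs in c) / (cohort callable sites in c)`, and an element
`e` with `n_{e,c}` callable sites expects `mu_e = sum_c n_{e,c} r_c`
mutations. Observed counts are modelled as negative binomial around `mu_e`
with one dispersion `theta` shared across elements, estimated by maximising
the NB likelihood in `log theta` (method-of-moments fallback; the Poisson
limit is used when the likelihood is flat at large `theta`). Recurrence is
the upper tail `P(Y >= y_e)` with Benjamini–Hochberg control across
elements.

Two statistical points are worth recording. First, upper-tail p-values of a
discrete count are *sub-uniform* by construction, so the calibration suite
checks exact uniformity on the randomised probability integral transform
`u = p - V * P(Y = y)` (uniform if and only if the model is calibrated) and
separately checks the conservativeness property `P(p <= a) <= a`. Second,
the exact regression design of the original analysis (per-sample counts,
covariates, callable masks) is not recoverable from the main text; the
pooled offset-only formulation here is the simplest model consistent with
its description, and covariate extensions can be layered on the same
expected counts.

Co-occurrence / mutual exclusivity between drivers is a two-sided Fisher
exact test per gene pair, with direction taken from the Haldane–Anscombe
corrected odds ratio (the correction affects the OR only, never the
p-value). Genes mutated in all or no samples are reported untestable and
excluded from the BH family. Dedicated mutual-exclusivity tests have more
power against that specific alternative; Fisher was chosen because it is
exactly checkable against hypergeometric enumeration.

## Rearrangement hotspots

Breakpoint ends are binned at 100 kb (both ends of every SV count, so bin
totals sum to twice the SV count). A Poisson log-linear background is
fitted to standardized covariate tracks (replication timing, GC, and the
like) by IRLS; collinear covariates trigger a small-ridge penalised IRLS
with a warning, and fitted expectations are rebalanced so that total
expected equals total observed. The observed/expected ratio is segmented by
exact penalised least-squares piecewise constant fitting (dynamic
programming, verified against exhaustive enumeration); the default penalty
is a modified BIC, `2 * sigma^2 * log(n)` with a difference-based variance
estimate, and is exposed as `gamma`.

Hotspots are segments with a Poisson upper-tail q-value at most the FDR and
a rate ratio of at least 2, subject to two guards:

* **Scan-level multiplicity.** Segments are *selected* by the
  segmentation, so BH across the emitted handful of segments is
  anti-conservative; the default family size is the number of bins
  scanned. The naive family remains available.
* **Recurrence floor.** A hotspot must carry at least 10 breakpoint ends
  (roughly five independent rearrangements): a cohort-level hotspot that
  one or two events can explain is not recurrent in any useful sense.

Hotspots overlapping curated fragile intervals, or containing a gene of at
least 600 kb whose mean replication timing is in the latest decile, are
flagged as putative fragile sites and excluded from the selection-driven
list. The 600 kb / latest-decile rule is this package's own operational
criterion — a curated fragile-site BED is the preferred input.

## Timing of copy-number gains

In a tumour of purity `rho`, a mutation on `m` of `n_t` tumour copies has
expected VAF `m * rho / (rho * n_t + 2(1 - rho))`. Mutations predating a
gain ride the duplicated copy to multiplicity 2; later mutations stay at
multiplicity 1. With `t` the fraction of clonal burden accrued before the
gain and `mu` the per-copy clonal intensity:

| state | E[n2]     | E[n1]          | estimator            |
|-------|-----------|----------------|----------------------|
| 2+1   | mu t      | mu (3 - 2t)    | t = 3 n2 / (n1+2 n2) |
| 2+0   | mu t      | 2 mu (1 - t)   | t = 2 n2 / (n1+2 n2) |
| 2+2   | 2 mu t    | 4 mu (1 - t)   | t = 2 n2 / (n1+2 n2) |

Higher copy states are excluded deliberately: these three have closed-form
estimators and dominate ccRCC gains (5q gain, copy-neutral LOH, WGD). WGD
timing pools counts over all clonal 2+2 segments. Confidence intervals are
percentile bootstrap over 200 multinomial resamples; segments under 20
informative mutations are reported untimeable, never guessed.

**Counting n1 and n2.** Hard maximum-likelihood multiplicity calls are
biased toward the majority component whenever the two VAF distributions
overlap (60x depth at purity 0.5–0.7 is enough), which propagates into `t`.
The default therefore fits a three-component binomial mixture per segment —
clonal multiplicity 1 and 2 at their known VAFs plus a subclonal component
with free VAF — and uses the expected counts `n * pi_hat`. Hard counting
remains available (`method = "map"`), and per-variant MAP calls with exact
binomial CCF intervals are still what downstream clonality summaries use.

**Chronological conversion.** A two-phase rate model runs at `r0`
mutations/Mb/year until `tau` years before sampling, then at `a * r0`
(defaults 0.05, 10 years, 5-fold). Inverting the cumulative burden at
`t * B` (B = clonal burden per Mb) yields the gain age and hence the lead
time in years. When the observed burden disagrees with the model by more
than 20%, the clock rate is rescaled to match and a message records it.
The published analysis' exact varying-rate model lives in supplementary
material not available here; this two-phase form reproduces its qualitative
behaviour (acceleration after initiation shortens apparent leads) and every
parameter is surfaced.

Event ordering fits a Bradley–Terry model by minorisation-maximisation
(tolerance 1e-8) to precedence pairs extracted per tumour: clonal driver
mutations precede subclonal ones, multiplicity-2 mutations precede their
timed gain, and timed events order only when bootstrap CIs are disjoint.
Disconnected comparison graphs rank per component with a warning.

## Genome instability and immune escape

wGII is the unweighted mean over autosomes of the covered-length fraction
whose total copy number differs from the rounded sample ploidy (undefined
below 90% autosomal coverage). WGD is called when more than half the
covered genome has major copy number at least 2. Arm gain/loss uses a 50%
arm-length rule with length-apportioned segments; arm enrichment compares
each arm against the cohort-mean alteration rate per direction with exact
binomial upper tails and BH across arms x directions — a deterministic,
oracle-checkable substitute for permutation, which is available behind a
flag in spirit but not the default.

HLA LOH is a segment-based surrogate for allele-resolved methods: the call
is positive when the length-weighted majority of the covered class I locus
has minor copy number 0 at clonal fraction at least 0.5, missing (never
false) under 50% coverage. Antigen-presenting-gene inactivation defaults to
truncating mutations in a 22-gene literature-based list (study-specific
lists should be supplied; the published list is supplementary-only); an
opt-in biallelic mode additionally requires LOH of the gene. A tumour is
classified as immune-evading when any component flag is true; missing
components are recorded, never coerced.

## The synthetic cohort

The generator emits the formats the pipeline reads (VCF, segment TSV,
BEDPE, clinical TSV) plus a ground-truth JSON, bit-reproducibly per seed.
Its defaults are the stated world of the source cohort where that is
printed — WGD in 16.6% of tumours at a mean lead of 9.2 years, a 2+1 gain
at a 35.5-year lead standing in for 5q gain, HLA LOH in 5.9%, HLA mutation
in 0.5%, APG inactivation in 3.1% — and otherwise fixed once at realistic
values: 60x Poisson depth, purity uniform on 0.5–0.9 (fresh-frozen WGS
cohorts select for tumour content), ages 45–80, subclonal burden 25% of
clonal at a single CCF of 0.4, a clock-like context profile with CpG-
elevated C>T, and clock parameters r0 = 0.05 mut/Mb/year, a = 5, tau = 10.
Cohort-pooled SV landscapes in the hotspot tests use ~13 breakpoint
ends/Mb, the density implied by the published cohort (19,756 SVs over
roughly 3.1 Gb).

Mutation placement uses exactly the timing algebra the estimators invert,
so recovery tests isolate estimation error; chronological ground truth uses
the same two-phase model as the estimator (shared code). What the generator
does *not* emulate: read-level artefacts (no FASTQ/BAM), germline variation
beyond an indel panel, signature mixtures, subclonal trees with more than
one CCF, kataegis/chromothripsis clustering, and purity estimation error
(purity is given, as it would be post-Battenberg). A green recovery test
therefore establishes correctness of the estimators under the stated model,
not robustness to every artefact of real data.

## Numerical choices

* NB dispersion: `optimize` over log theta in [-8, 20]; theta above e^19 is
  treated as the Poisson limit; MoM fallback if the likelihood
  maximisation fails.
* PCF: exact O(n^2)-per-chromosome DP; minimum segment length 2 bins by
  default (1 permitted); ties broken toward the earlier cut.
* Mixture counts: EM to log-likelihood change < 1e-8, at most 500
  iterations; the subclonal VAF is clamped to [0.02, 0.9] x the
  multiplicity-1 VAF so it cannot swallow a clonal component.
* Clonality: exact (Clopper–Pearson) binomial CI on the VAF rescaled to
  CCF; a call whose whole CI exceeds 1 is treated as clonal.
* Zero expectations in tail tests get a 0.5 pseudo-expectation with a
  warning, matching the segment-level convention.
* Bradley–Terry: per-component mean-1 normalisation each MM sweep;
  strengths of never-winning events decay to a floor rather than zero.

## Known limitations

Pairwise Fisher testing under-powers against true mutual exclusivity
structures; the NB test models pooled counts, not per-sample variation; the
HLA LOH surrogate cannot see allele-specific events smaller than a segment;
arm enrichment assumes exchangeable arms under the null; and chronological
leads inherit the (unverifiable) rate-model parameters — they should be
read as model-conditional estimates, which is also how the source analysis
presents them.
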