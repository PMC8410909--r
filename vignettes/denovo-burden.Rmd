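---
title: "Normalized de novo burden analysis: models, parameters, and design choices"
author: "dnburden"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normalized de novo burden analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnburden)
```

## The statistical model

The package quantifies the contribution of de novo mutation to autism by
comparing event incidence between affected children and unaffected siblings.
The central difficulty is that raw de novo counts are confounded: sequencing
coverage, parental age and residual cell-line artifacts all move the
observed per-child count. Instead of regressing these covariates out, the
analysis normalizes by a *presumed-neutral* event class measured in the same
children — synonymous variants for coding classes, intergenic indels for
intronic indels — on the argument that subject and normalization class are
affected near-identically by the confounders while only the subject class
responds to affected status.

For subject-class totals $S_a, S_u$ and normalization totals $N_a, N_u$ in
the affected and unaffected groups, the null expectation in the affected
group is

$$ES_a = S_u \cdot \frac{N_a}{N_u},$$

and the two reported effect measures are the ascertainment differential

$$AD = 100 \cdot \frac{S_a - ES_a}{C_a}$$

(excess per 100 affected children; interpretable as the percent of affected
children whose diagnosis the class contributed to *only* under the
assumption that contributory events are rare enough that no child carries
two) and the percent contributory

$$PC = 100 \cdot \frac{S_a - ES_a}{S_a}.$$

For de novo CNVs the normalization class is replaced by the number of
children — `mode = "child_count"` sets $N \equiv 1$ per child, so
$ES_a = S_u \cdot C_a / C_u$. This is the documented specialization of the
general formula, used where per-event normalization classes are unavailable
and detection power has been equalized instead (the ≥ 4 kb size filter).

### Inference

* **Permutation p.** Affected/unaffected labels are permuted with group
  sizes fixed; each child carries its $(S, N)$ pair, and $ES_a$ and $AD$
  are recomputed per permutation. The reported p is the one-sided upper
  tail of the observed $AD$ under a normal fitted to the 1,000 permuted
  $AD$s. Fitting a normal rather than counting exceedances lets the p-value
  fall below $1/(n_{perm}+1)$; the cost is reliance on approximate normality
  of the permuted statistic, which holds well at cohort scale. If the
  permuted values are constant (fully degenerate input) the p is reported
  as 1 with a warning rather than NaN.
* **Bootstrap CIs.** Children are resampled with replacement within each
  group; 95% intervals are the 2.5/97.5 percentiles over 1,000 resampled
  $AD$ and $PC$ values. The percentile method was chosen over BCa for
  transparency; at these sample sizes the difference is immaterial.
* **Aggregation.** Disjoint classes with different normalizations (e.g.
  synonymous-normalized LGDs plus child-count-normalized coding CNVs) are
  combined by summing observed and expected counts; the permutation shuffles
  children *once*, jointly carrying all class counts, so between-class
  dependence within a child is preserved. Expected counts are summed at
  full precision — summing the display-rounded per-class expectations can
  differ in the last digit.
* **Affected-vs-affected comparison.** The statistic is $AD_1 - AD_2$, each
  term computed against its own fixed unaffected baseline, with children
  permuted between the two affected groups. An alternative statistic (rate
  difference) would ignore the normalization; the AD difference was chosen
  because AD is the quantity being compared throughout.

Permutation and bootstrap use independent seed streams (`seed` and
`seed + 1`), so requesting bootstrap intervals never changes a p-value.

### Display conventions

Expected counts print at 1 decimal, AD at 2, PC at 1; full precision is kept
internally everywhere. Contribution ranges combine endpoint-with-endpoint
(lo·lo, hi·hi), the low-risk contribution $L$ is quoted at integer precision
by truncation, and the case-proportion weighting uses the unrounded
multiplex proportion $13{,}775/78{,}959 = 0.1745$ — the rounded 0.17/0.83
pair does not reproduce the quoted overall range.

## Drift QC

Lymphoblastoid cell lines accumulate culture variants that look de novo;
affected samples show inflated substitution counts and alternative allele
ratios well below the heterozygous expectation. Each child is summarized by

* `adjusted_subs` — observed de novo substitutions divided by the child's
  estimated detection power (so low-coverage children are not mistaken for
  clean ones), and
* `mean_alt_ratio` — the unweighted mean of per-substitution alternative
  allele ratios. True heterozygous de novo calls center near 0.47 rather
  than 0.5 (slight reference bias); culture variants are subclonal and pull
  the mean down.

Whole-blood children define a bivariate Gaussian via plain sample moments
(a single fit, no robust estimator and no iterative trimming — an optional
refit excluding ellipse outliers was considered and rejected as it changed
nothing at realistic contamination levels). A child passes iff its squared
Mahalanobis distance is at most $\chi^2_{0.999}(2) = 13.8155$; the boundary
counts as PASS. Children with zero observed substitutions have an undefined
mean ratio and are flagged `INCOMPLETE`: they are excluded from both the fit
and the downstream burden groups. The fit pools all whole-blood children
regardless of collection; a caller wanting a single-collection fit simply
subsets the statistics table first.

The ellipse is defined on the raw (count, ratio) plane. Plotting may use a
linear-below/log-above axis for counts, but that is display only — the
model is fitted on the untransformed variables.

## Effect annotation

Small-variant classes follow severity precedence **coding > splice-site >
intercoding-intronic > intergenic**, taking the most severe consequence
across transcripts:

* Coding substitutions are classified by codon: stop-gain → LGD, silent →
  SYN, otherwise MIS (stop-loss is treated as missense; it is not an LGD
  under the nonsense/frameshift/splice definition).
* Coding indels: frameshift (length change not divisible by 3) → LGD;
  in-frame coding indels fit none of the tested classes and fall to OTHER.
* Canonical splice sites are the 2 bp at each end of every intron of a
  coding transcript (the GT/AG positions); any variant footprint touching
  them is LGD. Because of this precedence the intronic classes can never
  contain splice-site variants — there is deliberately no separate
  "exclude splice from IID" switch.
* ISB/IID require the whole variant footprint inside an intron whose two
  flanking exons both contain coding bases *of the same transcript*
  (same-transcript semantics; the alternative any-transcript reading was
  rejected as it lets two unrelated transcripts manufacture an intercoding
  label).
* IGSB/IGID require the footprint fully outside all transcript spans.
* Everything else — UTR exons, UTR-splitting introns, noncoding
  transcripts, partial overlaps — is OTHER, as are all chrX events, which
  the group comparisons exclude (hemizygosity makes male/female rates
  incomparable).

Indel footprints use VCF left-anchored alleles: a deletion's footprint is
the deleted bases, an insertion's the two flanking bases.

CNV classes use any-bp overlap: CODING if any coding exon base of any
transcript is touched, else GENIC_NONCODING if any transcript is touched,
else INTERGENIC. For CNVs confined to exactly one (coding) gene, a subclass
distinguishes coding, intercoding-intronic and peripheral (UTRs and
UTR-splitting introns) with the same precedence. The `filter_events` size
threshold is inclusive: "at least 4 kb" keeps a 4,000 bp event.

## Detection power

**SNV power** follows the binomial read-count simulation: parents get
(depth, 0) ref/alt counts, the child's alternative count is
Binomial(p = 0.47, N = depth), and the 2×3 matrix goes through a trio
genotyper; power is the detected fraction of 10,000 positions. The bundled
genotyper is a *stand-in*: a binomial log-likelihood-ratio score (de novo
heterozygous child vs all-reference trio under an error rate of 0.005), a
two-sided binomial allele-ratio consistency test, a minimum alternative-read
count, and zero tolerated parental alternative reads. Its score scale is not
numerically comparable to any production caller's thresholds; only the
simulation *procedure* around it is the point. Defaults
(`min_denovo_score = 20` natural-log units, `min_alt_reads = 3`,
`min_consistency = 0.001`) give the qualitative behavior the procedure
needs: zero power at zero depth, steep gains from 5× to 40×, saturation
near 1 by 40×.

**CNV power** plants deletion-like signal without simulating reads: male
children are hemizygous on chrX, so their X read-depth bins run at half the
autosomal level. Per simulation a random male child's autosomal bin values
over a random window are replaced by his chrX values over an equal-sized
window (masked bins — the pseudoautosomal/telomere/centromere stand-ins —
are never selected), and a read-depth deletion finder is asked to recover
the window; detection is any-bp overlap of a call with the planted region.
The bundled finder is again a minimal stand-in: per-bin z-scores against the
across-sample column distribution, calling maximal runs of ≥ 3 bins at
z ≤ −3 within a chromosome, with zero-variance columns treated as signal-free
and a 20-sample minimum for stable column statistics. The default size grid
is 1–10 kb in 1 kb steps; the `sizes` argument accepts any grid (e.g.
extending to 100 kb) since the procedure is size-agnostic. Bin width
defaults to 100 bp.

## The synthetic cohort generator

`simulate_children`/`simulate_denovo_calls` generate cohorts with exactly
the structure the analysis assumes — which is what makes the test suite's
recoveries meaningful and bounds what they show:

* Per-child event count ~ Poisson(`base_sub_rate` +
  `paternal_age_slope` · father_age), thinned by a saturating detection
  probability $1 - e^{-\text{coverage}/10}$. Parental ages are
  Normal(33, 5) truncated to [18, 60]; coverage Normal(30, 5) truncated
  below at 1×.
* Class proportions default to per-child magnitudes of realistic scale:
  ≈ 0.26 synonymous, ≈ 0.085 LGD, ≈ 2 intercoding-intronic indels and ≈ 3
  intergenic indels per child, with intronic and intergenic substitutions
  dominating the total of ≈ 65.
* Events are placed at class-consistent genomic sites of a deterministic
  toy genome (two autosomes plus chrX; gene templates guarantee multi-exon
  coding, noncoding, UTR-containing transcripts and all placement classes;
  coding sequence is rewritten stop-free so stop-gains are well-defined).
* Read support: depth ~ Poisson(child coverage), alternative reads ~
  Binomial(depth, 0.47), floored at one alternative read.
* Drift is a two-component mixture, not a continuum: a fraction of LCL
  children (`drift_fraction`) have counts inflated by
  `drift_count_multiplier` (default 5) and per-variant allele-ratio
  parameters drawn Beta(2, 6) (mean 0.25). The multiplier and Beta shape
  are not estimates of real cell lines — the magnitudes are chosen to
  reproduce the qualitative separated-phases picture and are exposed in
  `cohort_spec`.
* Planted signal: an affected child receives at most one extra event of
  class *k* with probability `planted_AD[k]`/100 — never more than one,
  matching the interpretability assumption of the AD statistic. The plant
  is an unbiased AD target by construction.

`simulate_burden_counts` is a count-level shortcut for inference studies:
per-child (subject, normalization) Poisson pairs sharing a Gamma exposure
factor (CV 0.15) that emulates the joint covariate influence on both
classes. It is used where hundreds of replicate cohorts are needed and
genomic placement is irrelevant.

What the generator does **not** emulate: mutational sequence context,
haplotype structure, transmitted variation, recurrent hotspots, caller
artifacts correlated across children, and mosaicism. Passing recovery tests
therefore demonstrate correctness of the statistical machinery under its
own assumptions, not robustness of the study design to real-data pathology.

## Numerical choices and degenerate inputs

* $\chi^2_{0.999}(2)$ has the closed form $-2\ln(0.001)$; the test suite
  checks the quantile against it.
* Singular covariance (e.g. all drift points identical) raises an error
  suggesting degenerate input; the positive-definiteness check is
  scale-invariant (correlation-scaled determinant), so rescaling an axis by
  constants never flips a fit between valid and singular — classification
  is affine-equivariant.
* Permutations producing a zero-count normalization group are dropped from
  the normal fit (finite values only); constant permutation distributions
  yield p = 1 with a warning.
* PC is undefined (NA with warning) when $S_a = 0$; bootstrap PC values
  with resampled $S_a = 0$ are excluded from the percentiles.
* `expected_count` demands $N_u > 0$; `ascertainment_differential` demands
  $C_a > 0$.
* Boundary conventions: ellipse boundary is PASS; the CNV size filter is
  inclusive at 4,000 bp; a point variant at position $p$ corresponds to the
  half-open interval $[p-1, p)$.

## Problem sizes in the test suite

The suite runs cohorts of 1,000–2,000 children for the drift and
class-placement recoveries, 200 replicate cohorts for permutation
calibration and bootstrap coverage, 100 replicates at the published group
sizes (1,869/1,874/1,107) for end-to-end signal recovery, 10,000 positions
per SNV power estimate, and 120–150 simulations per CNV power point. These
sizes keep each statistical check's Monte-Carlo error comfortably inside
the asserted bands while the full suite completes in about a minute.

## Known limitations

* The affected-vs-affected permutation test has limited replicate-level
  power at the published sample sizes: for a planted 6% vs 1.5% LGD-scale
  contrast the expected permutation z is ≈ 3.1, so individual replicates
  reach p < 0.01 only ~80% of the time even though the median p is well
  below 0.01. Detecting such a contrast *reliably* at the 0.01 level needs
  either larger cohorts or aggregation over classes.
* The AD's causal interpretation inherits the normalization assumption
  (equal covariate response of subject and neutral class) and the ≤ 1
  contributory event per child assumption; both fail gracefully (AD remains
  a valid excess measure) but the "percent of children" reading does not.
* The stand-in genotyper and deletion finder bound what the power numbers
  mean: they characterize the simulation harness, not any production
  caller.
* The contribution model is interval arithmetic, deliberately without
  uncertainty propagation: the inputs (per-class contributions, risk-class
  proportions) carry no CIs, so neither do the outputs.
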