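---
title: "Screening gene pairs for synergistic chemo-sensitivity: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening gene pairs for synergistic chemo-sensitivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem and the model

Synthetic lethality proper — two genes whose joint inactivation kills the
cell — is hard to observe in tumour samples, because the doubly mutated cells
are gone. Its conditional form is observable: the doubly mutated cell line is
viable but *more sensitive* to a drug at sublethal dose. `scscreen` searches
drug-response panels for exactly this signature, hypothesis-free, over all
gene pairs and all drugs.

The unit of analysis is a (drug, gene pair) triple. For a drug $D$ and pair
$(A, B)$, the cell lines with an IC50 measurement for $D$ are partitioned by
damaging-mutation status into WW, WM, MW and MM (first letter = $A$,
second = $B$). The *model P value* is the two-sided pooled-variance t test of
mean $\ln \mathrm{IC50}$ (ln µM), MM versus the pooled WW ∪ WM ∪ MW. Within
each drug the model P values of all size-eligible pairs are
Benjamini–Hochberg adjusted to Q values. A **candidate SCS set** must have

* all four groups of size ≥ `min_group_size` (default 5),
* $Q <$ `q_threshold` (default 0.05),
* mean MM below mean non-MM (sensitisation direction), and
* $\max(\mathrm{MM}) < \mathrm{median(WW)}$ on $\ln \mathrm{IC50}$
  (`mm_ww_filter`, see below).

The pooled t test assumes approximately normal within-group log-IC50 with a
common variance; a Welch option (`t_variant = "welch"`) relaxes the variance
assumption. The test is two-sided and the direction is enforced by a separate
flag rather than a one-sided test, so a reported P value always has the
conventional two-sided meaning.

## What counts as a damaging mutation

Cell-line side (the matrix the screen runs on):

* **LoF**: stop-loss or nonsense classifications;
* **damaging missense**: SIFT score `< 0.05` *and* PolyPhen score `> 0.908`,
  both strict inequalities, consumed as pre-computed annotation (the package
  never re-scores variants). A missing score is an explicit `NA` and never
  passes a threshold. `missense_rule = "either"` switches the conjunction to
  a union for sensitivity analyses;
* **CNV deletion**: gene-level homozygous deletion, the only copy-number
  category that can produce a damaging call.

The binary matrix entry is the union of the three category indicators; the
per-category counts are retained for burden-style summaries. Genes damaged in
fewer than `min_mutated_lines = 10` *distinct* cell lines are removed
(multiple hits in one line count once). The ≥10-line filter is applied to the
union indicator, not to any single category — the category-specific
alternative is not distinguishable from published summary counts alone, and
the union reading matches a count table assembled from all three categories.

Cohort side (patients, MAF vocabulary): missense, nonsense, splice-site and
translation-start-site classes are damaging; everything else (Silent in
particular) is not.

## Tunable parameters

| Parameter | Default | Units / range | Why this default |
|---|---|---|---|
| `sift_cut` | 0.05 | score in [0,1], strict `<` | standard "deleterious" cut |
| `polyphen_cut` | 0.908 | score in [0,1], strict `>` | standard "probably damaging" cut |
| `min_mutated_lines` | 10 | distinct cell lines | removes genes too rare to ever form testable MM groups |
| `min_group_size` | 5 | cell lines per group | smallest reported MM group in published screens of this design is exactly 5, so the inclusive reading is used; `6` gives the strict "more than five" reading |
| `q_threshold` | 0.05 | FDR level | matches the conventional 0.05 significance level used throughout |
| `mm_ww_filter` | `mm_max_lt_ww_median` | — | see below |
| `t_variant` | `pooled` | — | Student's t, the classical choice for these panel sizes |
| `commercial_only` | `TRUE` | — | candidate sets are meant to be actionable |

**The MM/WW filter.** A sensitisation criterion should demand that even the
*least* sensitive doubly mutated line responds better than the typical
double-wild-type line: $\max(\mathrm{MM}) < \mathrm{median(WW)}$. The
opposite direction ($>$) is also selectable (`mm_max_gt_ww_median`) because
method descriptions of this screen family state it both ways; as a
sensitivity filter the `<` direction is the coherent one and is the default.
With the strong effects the screen targets, the choice mainly affects
borderline candidates.

**BH batch definition.** The drug-wise BH batch is the set of pairs passing
the size filter for that drug (pairs without a testable MM group contribute
no P value). Degenerate tests (zero pooled variance) are excluded from the
batch with a warning rather than entering as P = 0 or NaN.

## Combined partners, burden, clustering, survival

Partners of an anchor gene are pooled over candidate pairs — per drug
(`drug_specific`) or across a drug cluster (`multidrug`) — and lines are
relabelled WWC/WMC/MWC/MMC by anchor status × "any partner mutated", with
`burden` = number of mutated partners. A singleton partner set reproduces the
pairwise labels exactly (tested). Burden strata are either exact counts or
zero/one/two-plus; comparisons use Student's t and one-way ANOVA. Tissue
restriction (e.g. melanoma-only re-analysis) is a row filter on cell-line
metadata applied before any operation, not a separate code path.

Clustering uses `stats::hclust` on Euclidean distance with complete linkage
(monotone merge heights) for both the binary gene × drug membership matrix
(genes appearing ≥ 2 times among candidate sets; raw binary values, no
similarity transform) and the drug × tissue matrix of MM-line counts,
min–max scaled per drug to [0, 1]. A constant drug row scales to all zeros —
the degenerate case must map somewhere, and zero (= "no tissue signal")
keeps such drugs from dominating distances. Min–max scaling is idempotent.
Tissue enrichment is the plain chi-squared homogeneity statistic
$\sum (O-E)^2/E$ without continuity correction, with the standard warning
when an expected cell drops below 5.

Survival uses the `survival` package throughout: product-limit curves, the
log-rank test, and Cox proportional-hazards fits with Efron tie handling.
The KM median follows the standard product-limit convention — the first time
the curve reaches 0.5, averaging the two adjacent event times when it sits
exactly at 0.5 — so with no censoring it equals the sample median. The
mutation profile enters Cox models as a four-level factor with WWC as the
reference; pairwise hazard ratios (e.g. MMC vs WWC) come from two-group
refits, which is how such ratios are conventionally quoted. Monotone
likelihood / separation warnings from the fitter are surfaced in the result
(`flags`) instead of being dropped. Whether the "mutation profile" covariate
should instead be a binary MM indicator is genuinely open; the four-level
factor is strictly more informative and nests the binary coding.

## The synthetic-data generator

`generate_panel()` emulates the *structure* of a GDSC-like export at desk
scale: Bernoulli damaging indicators per gene (default probability 0.12 over
150 lines, giving expected damaged-line counts comfortably above the
10-line filter), Normal $\ln \mathrm{IC50}$ baselines per drug (default
N(2.5, 1) — a 12 µM-centred spread), two-level tissue labels, a 5% replicate
fraction, and coding-variant/CNV records whose SIFT/PolyPhen scores and
classes guarantee the intended damaging call, plus non-damaging decoys.
Planted pairs shift the MM group's mean by `delta`; specifying `n_mm` fixes
the number of doubly mutant lines exactly (accidental co-mutations elsewhere
are removed), because the screen's group-size precondition must hold
deterministically for power experiments. A pair planted for several drugs
shares one MM set. `planted_combined` adds `delta` per mutated partner to
anchor-mutated lines, the additive burden signal.

`generate_cohort()` assigns group labels at exact largest-remainder counts,
draws exponential survival with group-specific hazards, censors with an
independent exponential time whose rate is solved numerically so the
*expected* censoring fraction hits the target, and emits MAF rows that make
`classify_patients()` reproduce the labels exactly (wild-type patients carry
Silent filler rows so that every patient appears in the mutation table).

What the generator deliberately does **not** emulate: mutational signatures,
tissue-specific mutation spectra, gene–gene co-occurrence beyond the planted
structure, dose-response curve shape (IC50s are taken as given), or any
mechanistic relation between drug class and target genes. Tests passing on
synthetic data therefore demonstrate statistical correctness of the
machinery — error control, power against planted effects, label round-trips —
not biological validity on real panels.

A property worth knowing when reading screen output: with a strong planted
effect, pairs whose MM lines *overlap* the planted MM set inherit part of the
shift and can reach significance. This is not an artefact; the screen tests
marginal group differences, and correlated discoveries are intrinsic to the
design (on real data, co-mutated passengers behave the same way). The worked
analysis in `analysis/03_screen.R` shows both the planted recoveries and a
few such overlap candidates.

## Numerical choices and degenerate inputs

* The vectorised screen core computes group sums via cross-products of the
  status matrix; pooled variances are clipped at zero against floating-point
  round-off. Equivalence with a naive per-pair implementation is tested
  pair-for-pair to 1e-10.
* BH adjustment delegates to `stats::p.adjust(method = "BH")`; tests verify
  it against an explicit step-up enumeration over all permutations of small
  P-vectors.
* `model_p()` on zero-variance data raises a degenerate-test error rather
  than returning a misleading 0/1.
* Empty result tables can be written (header plus a `#types:` line) so that
  round-tripping preserves column classes exactly, including zero-row
  tables.
* Chi-squared tests never use Yates correction, so toy tables match the
  textbook formula exactly.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run at sizes chosen to make the
statistical properties measurable while keeping a laptop-scale footprint:
null error control over 21 genes (210 pairs) × 3 drugs × 100 seeds; power
against a planted −2 ln-IC50 shift (σ = 0.5, 10 MM lines) over 100 seeds;
burden monotonicity at 400 lines over 20 seeds; survival recovery of a
planted hazard ratio 0.44 at 500 patients per arm over 50 seeds. At these
sizes the expected Monte-Carlo error is small relative to every margin
tested (e.g. the null false-candidate rate is bounded by the FDR level plus
two Monte-Carlo standard errors).

## Known limitations

* The screen's t test is marginal: it does not model tissue composition or
  other confounders, so tissue-driven IC50 structure can masquerade as a
  pair effect (the clustering/enrichment module is the diagnostic, not a
  correction).
* BH within drug controls FDR per drug, not family-wide across drugs.
* Pairwise "MM significantly lower than the other three groups" is
  implemented as the pooled non-MM comparison (the definition of the model
  P), not as three separate pairwise tests; the latter reading would be
  strictly more conservative.
* With very sparse matrices the MM/WW filter consumes per-pair group extrema
  and is the only part of the screen that loops over pairs; on panels of
  thousands of genes, restrict `pairs` or pre-filter by group size if
  runtime matters.
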