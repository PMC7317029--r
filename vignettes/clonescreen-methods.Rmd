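---
title: "clonescreen: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{clonescreen: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonescreen)
```

This vignette records how each stage of the package models its problem, which
tunable parameters matter, what the synthetic-data generators do and do not
emulate, and the design choices made where the methodology was genuinely
open. Nothing here states an empirical result that the test suite or the
acceptance script does not itself compute.

## The screen and its score database

The setting is a clonal in-vivo modifier screen: animals carry labeled mutant
clones in an epithelium, each RNAi knockdown is scored against the sensitized
baseline across a registry of ordinal phenotype categories (clone geometry,
epithelial architecture, cytoskeleton, mitosis, invasion, adult cuticle), a
minimum number of animals per line is scored blind by two researchers, and a
subset of genes is covered by two independent RNAi lines.

**Ordinal scale.** The published score range is not recoverable from text, so
the scale is a parameter with default −2…+2 (integers; 0 = indistinguishable
from baseline, sign = direction of change). A ±2 scale accommodates the
printed hit-score ranges (maxima around ±1.5) with headroom; every consumer
of scores takes the scale explicitly.

**Category registry.** Only part of the 33 published category names is
recoverable; the registry ships 33 working names (`default_categories()`)
and is user-extensible. Nothing in the statistics depends on the names.

**Aggregation.** The line × category matrix is the arithmetic mean over all
animals and scorers with equal weight — the most literal reading of a "mean
score per line per category". A scorer-first two-stage mean is available
(`scorer_first = TRUE`) for unbalanced scorer coverage. Category cells never
scored for a line are 0-filled (scorers recorded deviations from baseline,
so absence of a record is "no deviation") and flagged, never silently
invented.

## Quality control

Two blinded scorers are compared by midrank Spearman correlation per
category over matched (line, animal) cells. For genes with two independent
RNAi lines, "statistically similar phenotypes" is operationalized as a
significant positive Spearman correlation between the two 33-length category
profiles, with a seeded permutation p-value (category entries of one profile
shuffled; default 10,000 permutations, α = 0.05). This is the weakest
assumption consistent with "comparing scores across categories"; the
original work names no test, so reproduction of its concordance percentage
is a soft claim only. Two details matter:

* *Degenerate profiles.* A line with a constant (typically all-zero) profile
  has no rank ordering; the pair is reported `degenerate` and counted
  non-concordant — no phenotype is no evidence of similarity — never an
  error.
* *Label symmetry.* The permutation roles are assigned by profile content,
  not by line label, so the report is exactly invariant to swapping
  `line_a`/`line_b` (a property the suite tests).

## IQR-rule hit calling

Per category, thresholds are `median ± IQR` over all scored (non-lethal)
lines, including zero-phenotype lines; hits are strict exceedances. Choices:

* *Quantile method.* Type-7 (linear interpolation), the most common default;
  exposed because the IQR is method-sensitive at screen size and recorded in
  the output for audit.
* *Strict bounds.* "Above or below" is read as exclusive, so ties at a bound
  are not hits, and an all-identical category yields zero hits rather than
  calling everything.
* *One rule for all categories.* Categories with one-sided score
  distributions simply produce hits on one side; no separate rule is applied.
* *Null calibration.* For i.i.d. normal line means the expected hit fraction
  is 2·(1 − Φ(2 q₀.₇₅)) ≈ 0.1767; the acceptance suite verifies the Monte-
  Carlo fraction at n = 10,000 within ±0.01. On the default ±2 ordinal scale
  with rounding, heavy ties make the null fraction substantially different —
  a property of the rule on discrete data, not a bug — so the calibration
  test uses continuous scores (and the generator-based check uses a wide
  scale where rounding is immaterial).

Hits are counted at line level; gene-level roll-up uses `best-line` (the
line with the largest |score| per category) because screens report line
counts but networks consume genes.

## Clustering

*Model-based K.* "Model-based optimal number of clusters" is implemented as
a finite mixture of spherical Gaussians fitted by EM (kmeans
initialisation) with the Bayesian information criterion over K = 2…15 by
default. The spherical variance is shared across components: with tens of
items per screen-scale matrix, per-component variances produce the classic
mixture singularity (a near-singleton component with vanishing variance
drives the likelihood to infinity and BIC overfits); the shared-variance
model is the standard remedy and recovers planted K exactly in the tests.

*Hierarchical clustering.* Euclidean distance, as published; linkage is not
stated, so `average` is the default (robust for profile data) with
single/complete/ward selectable. Rows can be clustered on row-scaled values
(display scaling, population-SD divisor) or raw means; the figure legend
ties colors, not distances, to scaling, so both modes are provided.

*Consensus clustering of categories.* Monti-style resampling: for each K,
items are repeatedly subsampled (default 80%, 1,000 resamples) and
co-clustering frequencies are normalized by co-sampling counts. K is chosen
by the largest relative increase of the area under the consensus CDF, with
Δ(k_min) = A(k_min). Subsample index sets are drawn once per seed and shared
across K so per-K matrices are comparable; `subsample_frac = 1` reuses the
full item set, making consensus entries exactly 0/1. A pair never co-sampled
is an explicit error asking for more resamples, not an NA.

## Annotation enrichment

Exact hypergeometric upper tail P(X ≥ k) per term with BH adjustment across
tested terms. The universe is never implicit: callers pass all screened
genes (cluster enrichment) or all platform genes (DE enrichment). Terms are
opaque labels — no ontology traversal — so term-level reproduction of any
published enrichment is out of scope by construction.

## Invasion-suppressor network

Retained nodes are hit genes, lethal genes, and *linkers*: non-hit,
non-lethal genes adjacent to ≥ 2 distinct hit genes, i.e. genes that connect
hits by single interactions. The default edge rule is strict — every
retained edge must touch a hit gene, so lethal–lethal, lethal–linker and
linker–linker edges are dropped (and logged with reasons); the permissive
induced-subgraph rule is a flag, and both edge counts are reported because
the published counting is ambiguous on this point. Duplicate evidence rows
collapse to one edge carrying the evidence-type set, with display precedence
physical > genetic > interolog.

**MCODE-style complexes.** Vertex weight = (highest k-core number of the
closed neighbourhood) × (density of that core); complexes grow greedily from
the highest-weight unvisited seed, including neighbours whose weight exceeds
`(1 − vwp) ×` seed weight (defaults: vwp 0.2, haircut on, fluff off, minimum
size 3). One deliberate deviation from the classical formulation: by default
the expansion considers the seed's direct neighbourhood
(`expand = "neighborhood"`), not the transitive closure. Under any
isomorphism-invariant weighting, two equally dense regions joined by a
single bridge give both bridge endpoints the same weight, so transitive
expansion provably merges the two regions into one complex (or excludes both
endpoints); the neighbourhood rule instead resolves two bridged 4-cliques
into two 4-complexes, which is the behaviour this pipeline's tests and
planted-recovery criteria demand. The classical transitive expansion is
available as `expand = "recursive"`. The haircut (2-core) releases pruned
vertices for later complexes, which keeps the one-complex-per-node invariant
while letting a neighbouring complex reclaim a pruned bridge endpoint.

## Single-cell invasion tracks

Metrics per track: path length (Σ 3-D segment norms), displacement (first →
last), speed = length / elapsed time (matching "micrometres travelled per
minute", not a mean of frame speeds), straightness = displacement / length.
2-D tracks are accepted by zero-filling z; coordinates are absolute μm.

**Directionality** follows the screen's reading — directional cells show *no
significant difference* between length and displacement. The default verdict
is therefore the inverse of a paired two-sided t-test (directional ⇔ p ≥ α),
flagged `inverse_test` in the output because failing to reject is not
evidence of equivalence: with many nearly-straight tracks the paired test
can reject on a biologically trivial difference. Two non-inverse modes are
provided — TOST equivalence (margin default 25% of mean path length) and a
straightness threshold (directional ⇔ mean straightness ≥ 0.6) — and the
README example deliberately shows a case where the straightness mode is the
appropriate choice.

## Differential expression

Per-gene two-sided t-tests on log2 intensities compare the knockdown with
its two control conditions (untreated, non-targeting). The default is the
*per-control* contrast — the gene must differ from each control, and the
reported p is the larger of the two — with the pooled-control contrast as an
option; the default variance model is the pooled-variance (equal-variance)
t. Rationale: the experiment is explicitly run against both controls, and at
n = 3 per group Welch's degrees of freedom collapse toward 2, destroying
power, while pooled-control contrasts inflate the null rate of jointly
passing p < 0.01 and |FC| ≥ 1.5 (fold-change exceedances under the null are
~10⁻³ at microarray noise levels, and a well-powered test confirms most of
them). The per-control equal-variance default is the only combination that
meets the pipeline's planted-recovery calibration (≥ 22/23 planted genes
recovered with ≤ 5 false positives among 21,425 nulls), and both
alternatives remain one flag away. Signed fold changes come from anti-logged
group means (r if r ≥ 1, else −1/r, never in (−1, 1)); the pass rule uses
the raw p (the published criterion is uncorrected) with BH q emitted for
context.

## Synthetic-data generators: the stated world

The generators exist so every stage is testable with known ground truth.
They emulate the screen's *structure*, not its biology:

* `gen_score_db` — a continuous Gaussian latent per animal (gene effect +
  animal noise), shared by both blinded scorers, plus independent scorer
  noise, rounded and clipped to the ordinal scale. Defaults mirror the
  screen: 497 genes, 256 covered by two lines (753 lines total — with at
  most two lines per gene, 764 is not reachable from 497/256 and the
  generator does not model >2 lines), 33 categories, 5 animals, 2 scorers.
  Planted effects: 5% of genes per category by default, magnitude 1.2,
  random sign; scorer/animal noise SD 0.3. What it does not emulate:
  category correlations within an animal, scorer bias, animal dropout,
  integer-scale ceiling effects beyond clipping. A green planted-recovery
  test therefore establishes the *rule's* behaviour, not scorer psychology.
* `gen_tracks` — persistent random walk with direction update
  `normalize(p·previous + (1 − p)·random unit vector)`; p = 1 is a straight
  line, p = 0 an uncorrelated walk; constant speed; 3-min sampling for
  30 min by default. Multi-spot actin labels are attached to directional
  tracks (2–4 spots) and single spots to random ones, reflecting the
  observed association. It does not model speed fluctuations, confinement,
  or measurement noise.
* `gen_interactome` — vertex-disjoint planted complexes among hit genes at a
  requested density, linkers wired to 2–3 hits, independent background
  edges, uniform evidence types.
* `gen_expression` — Gaussian log2 baselines (mean 8, SD 1.5 — typical
  microarray intensity spread), residual SD 0.25, three conditions
  (knockdown + two controls), planted signed log2(fc) shifts in the
  knockdown only.

All generators take explicit integer seeds and restore the caller's RNG
state; identical seeds give byte-identical outputs.

## Numerical and engineering notes

* Quantiles: type-7 interpolation exactly as `stats::quantile`; the test
  oracle reimplements the same interpolation formula bit-compatibly, because
  strict threshold comparisons are sensitive to last-ulp differences.
* Spearman correlations use midranks with the t approximation for p; exact
  permutation p-values are used only where the method prescribes them
  (line-pair concordance), with the +1-corrected estimator
  `(1 + #{|ρ*| ≥ |ρ|}) / (n_perm + 1)`.
* Degenerate inputs degrade to flags, not errors, wherever the degenerate
  case is scientifically meaningful (constant profiles, zero-length tracks,
  zero-variance genes); they are errors where silence would corrupt results
  (non-monotone track times, out-of-range scores, duplicate score keys).
* t-tests fall back to exact limits (p = 1 for equal means, p → 0 otherwise)
  when a group is numerically constant.
* The pipeline derives per-stage seeds deterministically from the master
  seed, independent of which stages are enabled, so disabling a stage never
  changes upstream artifacts (manifest hashes verify this).

## Known limitations

* The concordance test, the "model-based" K criterion, the DE statistic and
  the MCODE expansion rule all fill genuine methodological gaps in the
  source description; each is flagged above, defaulted to the choice that
  satisfies the pipeline's stated calibration properties, and kept
  switchable.
* Enrichment reproduces no published term lists (universe and annotation
  sourcing are user inputs by design).
* Scale-dependent behaviour of the IQR rule on heavily tied ordinal data is
  inherent to the rule; users comparing across scales should use the wide
  scale or work with continuous summary scores.
* The track directionality default is an inverse test; for confirmatory
  claims use the TOST mode.
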