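---
title: "Weight-coefficient network pharmacology: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weight-coefficient network pharmacology: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wcnp)
```

## The problem

Over-representation analysis (ORA) of the targets of a multi-component
preparation treats every target as equally supported: a pathway's rank
depends only on how improbable its overlap with the query set is. For a
preparation like an essential oil this discards two measurable facts — how
much of each component the oil contains (GC-MS peak-area percent, I) and how
much of an oral dose reaches circulation (oral bioavailability, OB). A
pathway whose targets are hit only by trace constituents can out-rank one
driven by the dominant, bioavailable components. `wcnp` implements the
corrective: a linear weighting cascade propagated from components to targets
to pathways, used to re-rank ORA output.

## The model

**Component weight.** \(A = \mathrm{OB} \times I\), with OB a fraction in
\([0,1]\) and I on the percent scale (0–100). A `content_scale = "fraction"`
switch converts 0–1 contents on ingestion. Because every downstream use of
the cascade is rank-only and the cascade is linear, the scale choice rescales
all scores uniformly and cannot change any ranking; it is fixed at percent
for reproducibility. OB must be supplied by the caller — a missing OB is an
error, never an imputed value.

**Target weight.** \(B(t) = \sum_{c \to t} A(c)\) over the component–target
edge map. Two deliberate conventions:

- duplicate (component, target) edges — the same interaction reported by
  several prediction databases — are collapsed before summation, because
  repeated database hits are evidence redundancy, not dosage;
- a compound name occurring in the component table under two CAS numbers
  (e.g. two resolved isomers sharing a display name) contributes *both* row
  scores to any target linked to that name: they are distinct constituents
  with distinct contents.

A component linked to several targets contributes its full A to each; nothing
is split. Targets without edges are absent from B, not zero-filled.

**Pathway weight.** \(C(p) = \sum_{t \in p} B(t)\), with unscored pathway
members contributing zero. C is a raw sum with no pathway-size correction —
a documented caveat: large pathways accumulate weight by size alone, which is
one reason C is used to *re-rank* a significance-filtered list rather than
as a test statistic.

**Enrichment.** Upper-tail hypergeometric probability
\(P(X \ge k)\), \(X \sim \mathrm{Hypergeom}(N, K, n)\) — the one-sided
Fisher exact test of over-representation — computed with `stats::phyper`,
with Benjamini–Hochberg correction (`stats::p.adjust`) across exactly the
pathways tested. The background universe defaults to the union of all
pathway genes (the annotation universe) and is configurable; distinct
collections (e.g. GO-BP and KEGG) should be run as separate calls and hence
separate BH families.

**Re-ranking.** Pathways are ordered by descending C; `rank_delta =
unweighted_rank − weighted_rank`, so a pathway promoted from 12th to 2nd has
a delta of +10. Re-ranking is a pure permutation — p-values, overlaps and
the pathway multiset are untouched — and is idempotent. Whether to combine C
with the p-value was an open design choice; `wcnp` ranks by C alone with the
p-value only as a tie-break, which keeps the two orderings independently
interpretable and makes the all-equal-weights case collapse exactly onto the
unweighted order.

**Deterministic tie-breaks.** Unweighted: ascending p, then descending
overlap k, then pathway id. Weighted: descending C, then ascending p, then
pathway id. Output tables are therefore byte-stable, which the test suite
relies on.

## Retention-index annotation

Components are placed on the Kováts scale by linear interpolation between
bracketing n-alkanes:
\(RI = 100Z + 100\,(Z'-Z)\,\frac{t_x - t_R(Z)}{t_R(Z') - t_R(Z)}\), where
\(Z\) is the largest ladder carbon with \(t_R(Z) \le t_x\) and \(Z'\) the
next ladder entry. For consecutive alkanes this is the classical formula;
ladders with skipped carbons interpolate across the gap, keeping RI
continuous and strictly increasing. A ladder member maps to \(100Z\) exactly
(asserted, not left to floating-point luck). Retention times outside the
ladder are an error: the formula is an interpolant and extrapolated indices
would be silent guesses.

## Threshold semantics

- DEGs: `fdr < 0.05` (strict) and `|log2FC| >= 1` (inclusive) by default.
  Published criteria are often stated inconsistently between a methods
  section and a results section (e.g. a fold-change cut of 2 in one place
  and 1 in another); both bounds and both comparison directions are explicit
  arguments so any published rule can be reproduced exactly. A gene passing
  at `log2fc == 0` is excluded with a warning — it is neither up- nor
  down-regulated, and keeping it would break `n_up + n_down = |selected|`.
- PPI confidence: strictly greater than 0.9 ("highest confidence"), so a
  combined score of exactly 0.900 is removed. The 0–1000 STRING dialect is
  auto-detected (any score above 1) with an explicit override.

## The synthetic-data generator

`sim_config()` fixes the study conditions; `generate_bundle()` realizes them
deterministically from a single integer seed (the caller's RNG state is left
untouched). Defaults: 20 components, 60 candidate targets, 25 pathways of
10–40 genes over a 500-gene universe, 10% of the universe differentially
expressed, and a 26-gene key-target intersection — sizes chosen to mirror a
typical single-oil GC-MS table (about 20 constituents, one dominant at
roughly 30% of peak area; contents are drawn from a symmetric Dirichlet with
concentration 0.5 to reproduce that skew) and a desk-scale
network-pharmacology study. OB is uniform on (0.2, 0.9).

The planted structure makes re-ranking, not enrichment, the discriminating
step: the planted pathway holds only 5 of the 26 key targets (mediocre
p-value), but those 5 are wired to the top `round(2 × planted_weight_boost)`
components by A (6 at the default boost of 3), while six decoy pathways each
hold 9 of the remaining 21 key targets wired only to 1–3 random components.
The decoys therefore beat the planted pathway on p-value (its median
unweighted rank is 7 across seeds) while its C score exceeds all others by
construction. At `planted_weight_boost = 1` no extra wiring beyond two edges
is added and the manifest simply records the actual C ordering. The DE model
is intentionally simple — signal genes at ±2.5 log2 units with N(0, 0.3)
noise and FDR ~ U(0, 0.04), null genes at N(0, 0.3) with FDR ~ U(0.05, 1) —
because the pipeline consumes a thresholded DE table and never performs DE
inference.

`ground_truth()` recomputes every planted quantity with a deliberately naive
triple loop over (component, edge, pathway-member) incidences, kept separate
from the pipeline code path, and `generate_bundle()` writes it as
`manifest.json`; the tests require the pipeline's C scores to match it to
1e-9.

What the generator does *not* emulate — and therefore what passing tests do
not establish about real data: correlated prediction errors in
component–target maps, incomplete or biased disease-gene catalogues,
pathway-annotation redundancy (real KEGG/GO sets overlap far more than
independent Dirichlet draws), and any DE-inference artefacts. Results on
real inputs inherit all of those upstream uncertainties.

## Numerical and degenerate-input choices

- Hypergeometric p via `phyper(k − 1, K, N − K, n, lower.tail = FALSE)`;
  validated in the suite against exhaustive subset enumeration for every
  universe of at most 12 genes.
- BH via `p.adjust`, validated against the textbook step-up formula
  \(\min_{j \ge i} m\,p_{(j)}/j\) capped at 1.
- Empty inputs flow through: empty edge maps give all-zero C and leave the
  unweighted order unchanged; an empty key-target set makes the pipeline
  skip enrichment and network stages with an explicit run-report notice.
- Pathways missing from the C map are scored 0 with a warning, so a partial
  weighting never silently reorders the rest.
- File emission rounds contents to 6 decimals and OB to 4, which makes the
  decimal representation exact and bundle generation byte-reproducible.

## Problem sizes used by the checks

The test suite validates the RI interpolant on 1,000 random ladders, the
weighting cascade against the brute-force triple loop on 200 random
instances (≤ 20 components, ≤ 60 targets, ≤ 25 pathways), threshold
monotonicity and the PPI filter on 100 random tables each, and the planted
signal end-to-end on 50 seeded bundles; `scripts/acceptance.R` repeats the
planted-signal cycle over 50 seeds derived from its `--seed` argument. These
sizes keep the whole suite under a minute on one CPU while leaving each
property statistically meaningful.

## Known limitations

- C has no pathway-size normalization (by design, see above).
- Gene symbols are matched by upper-cased string identity; no alias or
  ortholog mapping.
- The package builds and exports networks but computes no centrality
  metrics; visual analytics belong to Cytoscape or igraph directly.
- OB values are inputs; predicting them from structure is out of scope.
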