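---
title: "Molecular networking and coculture enrichment: methods and design notes"
author: "fbmnr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Molecular networking and coculture enrichment: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fbmnr)
```

# Scope

`fbmnr` analyzes untargeted LC-MS/MS metabolomics of a three-group
microbial design — fungal monoculture, bacterial monoculture, and
fungal–bacterial coculture — through five stages: spectral filtering,
modified-cosine molecular networking, cross-polarity merging,
a replicate-consistent enrichment screen, and a three-way color encoding
for network visualization. A sixth component, the synthetic-data
generator, exists so that each stage can be validated against planted
ground truth without any external data. Upstream peak picking and feature
extraction (producing the MGF and feature-table inputs) and downstream
structure annotation are out of scope.

# Spectral model and filtering

An MS/MS spectrum is a precursor m/z plus a centroided peak list. Two
filters precede all scoring, both standard in feature-based molecular
networking:

* **Precursor-region removal** (`removePrecursorRegion`): every fragment
  within ±17 Da of the precursor m/z is discarded. The boundary is
  treated as *inclusive* (a fragment exactly 17 Da away is removed):
  "within" is read conservatively, and an inclusive boundary removes
  strictly more residual precursor/isotope signal.
* **Windowed top-k** (`windowFilterTopK`): a peak survives iff it ranks
  within the top 6 by intensity among all peaks within ±50 Da *of its own
  m/z*. The window is centered per peak rather than binned; centered
  windows make the filter idempotent (survivors still rank top-k among
  survivors), which binning does not guarantee. Intensity ties break by
  ascending m/z.

# Modified cosine

Intensities are square-root transformed and scaled to unit Euclidean
norm. The square root damps the dominance of base peaks; the unit norm
makes self-similarity exactly 1, which anchors the score scale and the
0.70 edge threshold. Candidate peak pairs match either directly
(|Δm/z| ≤ 0.05 Da) or shifted by the precursor mass difference — the
signature move of the modified cosine, which lets a compound and its
mass-shifted analog (e.g. ±CH₂) pair their common-backbone fragments.

A one-to-one pairing is selected *greedily by descending intensity
product*, with deterministic ties (ascending m/z in the first spectrum,
then the second). Greedy selection is O(P² log P), deterministic, and the
convention of this score family. It is worth being precise about its
accuracy: greedy is provably optimal when no fragment has two candidate
partners, and can be strictly suboptimal when conflicts exist — e.g. when
one fragment matches one peak directly and another via the shift. In
centroided data (no two peaks closer than the fragment tolerance),
conflicts require a near-coincidence between the precursor difference and
a fragment-pair difference and arise in roughly one per thousand random
related-spectrum pairs; the exhaustive-oracle comparison in the test
suite quantifies this. The score is clamped to [0, 1]; by Cauchy–Schwarz
it cannot genuinely exceed 1.

# Network rules

Three rules apply in a fixed order, each a pure operation:

1. **Thresholds**: an edge requires score > 0.70 *and* ≥ 6 matched peaks.
   The matched-peak criterion is a single configurable `minMatched` with
   an inclusive ≥ 6 default, used identically for network edges and
   library matching; the inclusive reading is the ecosystem convention.
2. **Mutual top-k** (`mutualTopkFilter`): an edge survives iff each
   endpoint ranks within the other's top 10 highest-scoring neighbors,
   ranks computed on the thresholded edge set (the rule filters existing
   edges; it does not consult sub-threshold similarities). Rank ties
   break by ascending node id.
3. **Family cap** (`capFamilySize`): while any connected component
   exceeds 100 nodes, its lowest-scoring edge is removed (ties by
   ascending node-id pair) and components are recomputed after every
   single removal — recomputing per removal, not in batches, removes the
   minimum number of edges under the greedy rule.

Because every tie anywhere breaks by node id, identical inputs produce
byte-identical networks regardless of input order. Nodes are never
removed by these rules; `dropSingletons` truncates degree-zero nodes from
the *display* network only, while quantitative tables retain every
feature.

# Cross-polarity merge

Positive-mode features are assumed to ionize as [M+H]⁺ and negative-mode
as [M−H]⁻, so neutral mass is m/z ∓ 1.007276466 Da. Nodes from opposite
polarities merge when neutral masses differ by < 20 ppm and retention
times by < 0.15 min — both strict inequalities ("less than"). Two
conventions had to be fixed where the procedure is underdetermined:

* the **ppm reference** is the mean of the two neutral masses (at 20 ppm
  the choice among mean/min/max changes nothing in practice, but a fixed
  convention is required for exact testability);
* **conflict resolution** is one-to-one greedy by ascending ppm (ties by
  ascending RT difference, then node ids) when one node has several
  in-tolerance candidates.

Edges from both input networks are inherited onto merged nodes, keeping
the maximum score when two input edges collapse onto the same merged
pair. The merge is symmetric in argument order, and node count is
conserved: |merged| + #pairs = |pos| + |neg|.

# Enrichment screen

Heights are first row-sum normalized: each sample scaled to a total of
10⁶, preserving within-sample proportions (idempotent; an all-zero
sample is an error naming the sample). Group aggregation is the
arithmetic mean of replicates. A feature passes for a condition iff:

* (a) it is detected (> `detectionFloor`, default 0, i.e. any positive
  height) in **every** coculture replicate;
* (b) its coculture mean is ≥ 4× the fungal monoculture mean AND ≥ 4×
  the bacterial monoculture mean, where a zero monoculture mean with a
  positive coculture mean is flagged *not detectable* (the dash in
  printed tables) and counts as satisfying that comparison; 0/0 is
  undefined and fails;
* (c) a one-tailed two-sample Student's t (pooled variance, df = n₁+n₂−2,
  upper tail) gives p < 0.05 against **both** monocultures.

Choices worth making explicit: the t statistic is pooled-variance, not
Welch, because the procedure names Student's t; it is computed on the
linear normalized scale by default (the quantities compared are peak
height ratios), with a `logScale` option for log(x+1); the fold-change
gate is inclusive (≥ 4); and **no multiple-testing correction** enters
the pass flag — the screen is a stated raw one-tailed threshold combined
with a hard fold-change gate, and the report carries BH-adjusted
p-values as informational columns only. Degenerate zero-variance t cases
use the limit convention p = 0.5 (equal means), p = 0 (coculture
strictly greater), p = 1 (strictly smaller).

A practical property the tests make visible: row-sum normalization
couples features. If enriched features carry a non-negligible share of a
sample's total signal, normalization deflates their observed fold
change. Real untargeted tables contain thousands of features, so any one
compound is a negligible fraction of the total; the synthetic generator
reproduces this regime with constitutive background features (below).

# Three-way color encoding

Each group has an anchor hue (defaults 0°, 120°, 240°). A node's hue is
the angle of Σ wᵢ·(cos hᵢ, sin hᵢ) with weights wᵢ the three group means
normalized to sum 1. This barycentric vector-sum construction was adopted
as a well-defined stand-in for the cited three-way coloring, whose exact
formula is not reproduced in the source describing it; it has the
correct extremes (a single-group feature takes that group's anchor hue
exactly) and is scale-invariant. When the weighted vectors cancel (all
three means equal) the hue is undefined and the node renders neutral
gray.

Transparency uses d = max − min of the three group means — "intensity
difference" is ambiguous between pairwise differences and the range; the
range was chosen as the simplest quantity with the intended
monotonicity. d is normalized to the minimum and maximum of the
*reference group's* (default coculture) means over the displayed nodes,
clipped to [0, 1], then square-root transformed: α = √(clip((d −
ref_min)/(ref_max − ref_min))). The square root lifts mid-range
differences, emphasizing features well above the transparency floor;
α is monotone non-decreasing in d.

# Synthetic data: what it emulates, and what it does not

`SimulationConfig()` defaults define the reference dataset:

| parameter | default | rationale |
|---|---|---|
| families × members | 5 × 4 | enough structure to test partition recovery at spectrum-pair cost O(n²) |
| base-mass spacing | ≥ 50 Da + jitter | families unambiguous at 0.05 Da fragment tolerance |
| modification deltas | +14.0157, +2.0157 Da (cumulative) | common biochemical shifts (CH₂, H₂); config, not doctrine |
| backbone fragments | 8, spread ≥ ~25 Da apart | survive the ±50 Da top-6 filter; > 6 matched peaks after noise |
| mass error | ±3 ppm uniform | routine high-resolution accuracy |
| RT jitter | ±0.03 min | well inside the 0.15 min merge tolerance |
| noise peaks | 3 per spectrum, ~1–2% base intensity | low-level chemical noise |
| replicate CV | 20% log-normal | typical biological replicate spread for peak heights |
| dropout | 5% | emulates non-detection (the dash in reports) |
| dual-mode fraction | 40% | exercises the merge with both paired and unpaired nodes |
| planted enrichment | 5 compounds at 8-fold | clearly above the 4-fold gate, below trivial separation at CV 20% |
| replicates | 4 per group | the three-group, four-replicate design |
| background features | 150 | see below |

Members of a family keep half their backbone fragments at fixed m/z
(charge-retained ions → direct matches) and shift the other half by the
member's cumulative modification delta (neutral-loss ions → shifted
matches), so family recovery genuinely requires the modified cosine's
shift rule. Replicate heights are group mean × LogNormal(0, σ) with σ =
√log(1+CV²) (median-1 multiplicative noise — heights are positive and
the screen works on ratios), zeroed with the dropout probability
*before* normalization, as real non-detections are.

**Background features** (default 150) appear in the feature table only —
no MS/MS, so they are never networked, exactly like real features
dropped for lacking fragmentation spectra. They give the table a stable
total ion current so that row-sum normalization is not distorted by the
planted enriched compounds; without them a 28-feature table with 7
enriched features deflates observed fold changes below the gate purely
through normalization.

Determinism: every random draw comes from an integer-indexed stream
(`seed` hashed with the compound/feature index), so output is identical
across sessions and platforms and independent of evaluation order.
Generated MGF files are written with 17 significant digits and
round-trip bit-identically.

What the generator does **not** emulate: chimeric spectra, co-eluting
isomers, adducts beyond [M±H]±, isotope envelopes, retention-time drift
between samples, correlated (batch) noise, and intensity-dependent mass
error. Passing tests therefore demonstrate the correctness of the
implemented rules under the stated statistical structure, not robustness
to every artifact of real LC-MS/MS data.

# Validation design and problem sizes

The test suite checks every operation against an independent route:
exhaustive optimal-pairing enumeration for the modified cosine (spectra
≤ 6 peaks, 1,000 seeded pairs), a from-scratch BFS/rank implementation of
the three network rules (200 random 15-node score matrices, with a
deliberately tight mutual-k of 3 and family cap of 5 so both rules
bind), `stats::t.test(var.equal = TRUE)` for the screen's t statistic,
and planted ground truth for family recovery, merge precision/recall
(both must be exactly 1), type-I error (1,000 null features: rejection
rate inside the 99% binomial envelope [0.033, 0.069] at α = 0.05, full
screen ≤ 0.5%), and power (50 planted features: ≥ 90% recovered at
8-fold, ≤ 10% passing at 2-fold, the fold gate dominating). The
null/power simulations set dropout to zero so the measured quantity is
the screen's statistical behavior, not detection loss. These sizes keep
the whole suite under a minute while leaving each estimate's sampling
error far from its acceptance margin.

# Known limitations

* Greedy peak pairing can be marginally suboptimal under candidate
  conflicts (quantified above); an optimal-assignment scorer was
  deliberately not used, to keep determinism and the conventional
  behavior of this score family.
* The screen tests each feature and condition marginally; the pass flag
  applies no multiple-testing correction by design, and BH columns are
  informational.
* The merge assumes exactly one adduct per polarity; multimers, sodium
  adducts and in-source fragments will not be reconciled.
* `buildNetwork` scores all pairs (O(n²) modified cosines); it is meant
  for feature sets in the hundreds-to-thousands, not raw scan data.
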