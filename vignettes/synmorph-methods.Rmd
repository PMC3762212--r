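---
title: "Models and methods behind synmorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind synmorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synmorph)
```

## The measurement problem

Flash-and-freeze electron microscopy captures snapshots of synaptic membrane
traffic: motor neurons expressing channelrhodopsin are stimulated with a
single light pulse and high-pressure frozen at a defined interval (20 ms to
10 s), then serial 33-nm sections through each neuromuscular junction are
annotated — the plasma membrane trace, the dense projection (the scaffold at
the center of the active zone), the flanking adherens junctions, and every
vesicle and membrane pit with its position and diameter. synmorph consumes
those annotations (it never touches micrographs) and computes the
quantitative readouts of the experiment: vesicle pool sizes over time,
distance distributions, endocytic structure counts by site, recovery
kinetics, a membrane-area balance sheet, and diameter mixture models.

## Data model and units

A condition dataset (`syn_dataset`) is a set of linked tibbles: one row per
synapse reconstruction (4–6 contiguous profiles sharing a dense projection),
per profile (with the membrane polyline, dense-projection polygon, and
junction marks as coordinate matrices), per vesicle and per pit. All lengths
are nm, areas nm², times ms; the out-of-plane coordinate is implicit as
`section_index × 33 nm`. JSON is the canonical on-disk form; a flat CSV
dialect (one row per structure, metadata repeated) is provided for
spreadsheets. `validate_dataset()` returns violations as data rather than
errors; the on-membrane placement tolerance for junction marks and pit
mouths is 5 nm, reflecting annotation jitter.

## Classification rules

Pools partition every vesicle by its **edge** distance to the membrane
(circle of radius diameter/2 about the annotated center, against the
polyline):

* **docked** — edge distance ≤ 2 nm. Contact is operationalized as a 2-nm
  tolerance rather than exactly zero because annotated coordinates carry
  jitter; the tolerance is a parameter.
* **tethered** — within 30 nm with a tether seen by the annotator. The
  tether is a visual feature; geometry alone cannot recover it, so the flag
  is taken from the annotation.
* **30-nm pool** — within 30 nm, no tether.
* **cytoplasmic** — everything else.

Kinds: a dense core makes a dense-core vesicle regardless of size; a clear
vesicle strictly larger than 35 nm is a large vesicle (35.0 nm exactly is
still a synaptic vesicle). Zones: the active zone is the membrane arc from
the dense projection to the flanking junction marks; a vesicle belongs to
the zone containing its membrane foot-point, boundaries assigned inward.
Sites for endocytic structures use 3D distances across sections
(`sqrt(x² + z²)`, z in 33-nm steps): dense-projection-associated within
100 nm of the nearest dense-projection edge, junction-associated within
50 nm of a junction mark. A structure inside both radii is counted at the
dense projection (the primary association) and flagged `site_ambiguous` for
audit — the source study does not state how such cases were counted, so the
precedence is this package's decision. Pits with a synaptic-vesicle-sized
mouth (≤ 35 nm) away from a junction are exocytic (fusion intermediates);
other pits are endocytic, split at the hemisphere (`depth < width/2` is
shallow) because no explicit shallow/deep boundary is stated and the
hemisphere is the natural geometric cut.

## Morphometry and statistics

Distances to the dense projection are measured center-to-nearest-edge, with
a reserved "touching" histogram column (vesicle edge within 2 nm of the
dense-projection edge in its own section) followed by half-open 33-nm bins —
so a non-touching structure at exactly 0 nm falls in bin 1 and one at
exactly 33.0 nm in bin 2, making boundaries deterministic. Counts are
rescaled to a typical active zone (670 nm of membrane from the dense
projection to the junctions, summed over both flanks) or a typical
varicosity cross-section (60,700 nm²) so terminal-size variation does not
masquerade as pool changes. SEMs are per profile for vesicle pools and per
synapse for endocytic structures, following the study's two aggregation
scopes.

Group comparisons use the two-sided Mann-Whitney U test: exact by full
enumeration of all `choose(n1+n2, n1)` rank assignments when both groups
have ≤ 8 observations (the package's own implementation; `wilcox.test`
serves as an independent cross-check in the test suite), and the normal
approximation with tie and continuity corrections otherwise. Bonferroni
adjustment divides alpha by the number of comparisons (0.05/7 ≈ 0.007 for
the seven-timepoint comparison).

## Kinetic models

Only time constants are printed in the source material; the functional
forms are the standard ones for these processes, adopted here as a design
decision:

* docked-pool refill: `y(t) = y_inf − (y_inf − y_0)·exp(−t/τ)`;
* pit resolution: `y(t) = y_inf + (y_0 − y_inf)·exp(−(t − t_peak)/τ)` with
  `t_peak` fixed at the first (peak) point;
* paired-pulse recovery: `y(t) = 1 − A_f·exp(−t/τ_f) − A_s·exp(−t/τ_s)`
  with non-negative amplitudes, the asymptote fixed at full recovery, and
  components ordered fast < slow after fitting.

Fits are Levenberg-Marquardt least squares, weighted 1/SEM² when SEMs are
supplied and unweighted otherwise (whether the original fits were weighted
is unstated; weighting is the default whenever SEMs exist because the
per-timepoint precision varies severalfold). τ is initialized from a
log-linear regression on asymptote-normalized data; the decay and
double-exponential fits add deterministic multi-starts over the initial τ
because the log-linear guess can land far off when late timepoints sit at
zero. Degenerate inputs (constant series, increasing "decays") come back as
flagged results, not exceptions. Residual-resampling bootstrap intervals
(`bootstrap_ci()`) quantify fit uncertainty.

## Diameter mixtures

Large-vesicle diameters are fitted as k-component Gaussian sums by least
squares on the binned histogram (bin width 2 nm) rather than maximum
likelihood on raw diameters, because the goodness-of-fit statistic of
interest is an R² on histogram counts, which presupposes a curve fit to
bins. Weights are unconstrained non-negative, so the fitted curve
integrates to approximately the observed count. Component standard
deviations are floored at the bin width: a component narrower than one bin
acts as a per-bin delta and would let a 3-component model interpolate a
10-bin histogram. Each k-fit is warm-started from the (k−1)-fit plus a
zero-weight extra component, which guarantees RSS is non-increasing in k;
when a histogram has fewer bins than a model has parameters (k = 3 needs 9)
the optimizer is skipped and the warm start kept, flagged as non-converged.

Each fit reports two information criteria. The least-squares form
`n·ln(RSS/n) + 2p` (`n` bins, `p = 3k` by default, switchable to `3k − 1`)
is the convention under which the printed values were presumably computed.
For *ranking*, however, `compare_mixtures()` defaults to a Poisson-deviance
AIC of the same fitted curves: in simulation at these bin counts the RSS
form chases individual noisy bins — on unimodal synthetic samples it
selects k > 1 more than half the time, while the deviance form keeps k = 1
in ~90% of replicates and identifies bimodal samples emulating the observed
diameter distribution in ~100% — so the likelihood-based score is the
scientifically defensible default, with `criterion = "aic_ls"` available.
Ties break toward the smaller k. The exact published AIC values cannot be
reproduced because the underlying raw diameter sample is not published;
what the package reproduces is the ranking behavior. The published peak
separation (38 vs 46 nm) corresponds to a sphere-area difference of
`π(46² − 38²) ≈ 2111 nm²` — roughly, though not exactly, the 2700 nm² of
one synaptic vesicle (within ~25%), consistent with the interpretation
that the larger population absorbs one extra vesicle of membrane.

## The membrane budget

The budget compares membrane added by exocytosis against membrane recovered
by endocytosis at 300 ms and 1 s. Per-structure surface areas default to
the published rounded constants (synaptic vesicle 2700 nm², small/large
dense-projection classes 4300/6600 nm², junction structure 6000 nm²) so the
worked arithmetic reproduces digit for digit; an exact `4πr²` mode exists
because the published numbers themselves mix conventions — 24 junction
structures at 1 s are printed as 140,000 nm², which only
`24 × 4π(43.2/2)² ≈ 140,758` rounded to two significant figures yields
(the stated 6000 nm² constant would give 144,000). Observed dense-projection
large vesicles are corrected for departure (47% at 300 ms, 50% at 1 s
already moved away), the internalized total splits 70/30 between the
diameter classes with the small-class count truncated toward zero (matching
the published 18/8 and 35/15 splits), and synaptic-vesicle equivalents
truncate the total area over 2700 nm² (304,200/2700 → 112). The
Results section of the source prints 111 equivalents at 300 ms where its
Methods compute 112; the package reproduces the Methods arithmetic. The
release-per-synapse range is always an explicit input (6–7 vesicles at both
worked timepoints, per the printed ranges 132–154 and 138–161), never
inferred silently from a dataset.

## What the synthetic generator emulates — and what it does not

The generator exists so that every analysis is testable without raw data.
Its defaults encode the study conditions: docked vesicles Poisson per
profile around `2.5 − 1.6·exp(−t/2400 ms)` (2.5 unstimulated, 0.9 after a
stimulus), tethered around 3.1/2.6 with the same refill constant; junction
pits per synapse peaking at 1.45 (29 pits over 20 synapses) at 300 ms and
decaying with τ = 1400 ms — which predicts 0.88 at 1 s, matching the counted
20 over 23 synapses; dense-projection large vesicles peaking at 50 ms with
knots anchored to the counted 14/20 at 300 ms and 25/23 at 1 s; synaptic
vesicle diameters normal about 29.3 nm with sd 1.3 nm — anchored to the
printed fusing-vesicle statistic 28.4 ± 0.3 SEM over 17 structures, which
implies a per-vesicle sd near 1.2 — truncated to (15, 35]; large-vesicle
diameters a 38/46 nm mixture with 70/30 weights (the printed 18/8 and
35/15 class splits) and sd 2 nm, truncated above 35 nm (the unimodal fit
to such samples has R² ≈ 0.75, close to the printed 0.78);
junctions 250–350 nm from the dense projection with an asymmetric long side
up to ~1000 nm; profile areas about 60,700 nm²; paired-pulse recovery with
τ = 100 and 2200 ms, amplitudes 0.3/0.5, and measurement noise sd 0.05.
Values the study does not print — the 30-nm pool mean (1.5), the
cytoplasmic pool (25 per profile), dense-core vesicles (0.3), perisynaptic
docked vesicles (0.5), and the shapes of the endocytic time courses between
their anchored knots (piecewise-linear in log-time) — are single realistic
choices documented here, not calibration dials.

Structures are placed so that generated labels are *provably* consistent
with the classifier: docked vesicle edges land within the 2-nm contact
tolerance, tethered/30-nm vesicles in (2, 30] nm, junction structures
within the 50-nm radius, and placement margins absorb the membrane's
curvature noise. The generator writes its intent into `true_*` columns, and
a cross-module test demands 100% agreement between those labels and
`classify_dataset()` output.

Two scale conventions deserve a note. First, the generator's pool means are
defined on the per-profile count scale — the scale of the printed means —
while the study also reports normalization to a typical active zone or
profile area; generated geometry varies around the reference values, so
normalized means agree with raw means only to first order, and calibration
checks therefore measure raw per-profile counts. Second, what the generator
does **not** emulate: correlated counts within a synapse, annotation error
on diameters, section-loss artifacts, non-Poisson overdispersion between
animals, or realistic axon cross-section shapes (the membrane is a gently
noisy line). Passing recovery tests therefore show that the estimators
recover known parameters under idealized sampling at the study's n — not
that real annotations are this clean.

The freeze-timing simulator implements the trigger arithmetic: the freezer
needs 170 ms (± 20 ms trial-to-trial jitter, uniform) from the start signal
to pressure, plus 8 ms from pressure to freezing, so a commanded 1 s
interval triggers the freezer 822 ms after the light and a commanded 100 ms
interval 78 ms *before* it; realized intervals are reconstructed post hoc
from the actual delay, and trials where the light fires after freezing are
flagged.

## Replicate studies and problem sizes

The packaged simulation studies (`docked_refill_study()`,
`paired_pulse_study()`, `pit_resolution_study()`) regenerate a full
synthetic experiment per replicate at the study's own sampling — e.g. the
freeze series uses 10–24 synapses per timepoint, mirroring the published
50–121 profiles per timepoint — fit it, and report the recovered τ; 200
seeded replicates per study give stable medians while keeping a full run in
the minutes range. Replicate i derives its seed as `base_seed × 1000 + i`,
so studies are reproducible from a single integer. The paired-pulse τ_slow
estimator is right-skewed at the configured noise (its median sits several
percent above the true 2200 ms); this is a property of fitting four free
parameters to one noisy 11-point series, documented rather than corrected.

## Numerical choices and degenerate inputs

Point-to-polyline distances are exact segment projections (vectorized
points × segments); polygon edge distances clamp to zero inside the
polygon. Histogram bin edges are lower-inclusive. `correct_for_departure`
rounds to the nearest integer; the 70/30 split truncates; vesicle
equivalents truncate — each choice matches one of the published worked
numbers and is asserted in the tests. Mixture fits refuse samples with
fewer than 10 diameters or zero spread; kinetic fits refuse fewer than 4
(6 for the double exponential) points and flag constant or increasing
series instead of erroring. All randomness flows through explicit seeds,
and generator calls restore the caller's RNG state.

## Known limitations

The pipeline assumes one dense projection per synapse (the reconstruction
definition), pools profiles across animals with no mixed-effect structure,
and treats annotation coordinates as exact apart from the fixed tolerances.
The CSV dialect restores extra-column types by inference (numeric, logical,
then character), so exotic types survive only as text. The per-synapse
endocytic time courses between anchored knots are qualitative
approximations; analyses that depend on the exact shape of those curves
between 50 and 300 ms should treat generator output as illustrative only.
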