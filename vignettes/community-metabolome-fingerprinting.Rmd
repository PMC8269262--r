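---
title: "Community metabolome fingerprinting: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Community metabolome fingerprinting: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`metamodes` turns untargeted LC-MS peak tables from marine particulate
samples and phytoplankton cultures into comparable metabolite
fingerprints, and asks whether groups of metabolites share abundance
patterns across space and taxonomy. This vignette documents the models and
procedures each stage implements, the tunable parameters and their
defaults, what the synthetic-data generator does and does not emulate, and
the design choices made where several readings were defensible.

```{r setup}
library(metamodes)
```

## The data model

The unit of observation is the *mass feature*: an LC-MS peak identified by
its mass-to-charge ratio and retention time, e.g. `I121.0684R10.7` (m/z to
four decimal places, retention time in minutes to one decimal place;
rounding is round-half-even, the behaviour of C `sprintf` on IEEE doubles —
the identifier convention itself does not fix a rounding rule, so we
document ours rather than guess). Retention time is stored in seconds
because dereplication windows are specified in seconds; only the identifier
renders minutes.

A `peak_table` couples a features × samples area matrix to feature
metadata (m/z, retention time, chromatography column, ionization polarity)
and sample metadata (role, replicate group, volume filtered or biovolume,
position). Missing areas (`NA`) mean *not detected or not integrated* and
are never silently treated as measured zeros; each downstream statistic
states its missing-value policy. Sample roles partition the columns into
biological samples, pooled QC injections (a mixture of all samples injected
repeatedly, whose spread estimates instrument noise), and matrix blanks
(the second of two filters run in series, which carries dissolved-pool and
contaminant signal).

## Quality-control filters

Four per-feature filters run in a fixed order (configurable):

1. **Pooled CV**: a feature fails when its coefficient of variation across
   pooled injections is strictly greater than 30% (`cv_threshold = 0.30`).
   The CV is the sample standard deviation over the mean.
2. **Replicate variability**: fails when the mean within-replicate-group CV
   is strictly greater than the CV over all biological samples. CV (rather
   than variance) makes the comparison scale-free.
3. **Presence**: fails when the feature is detected (non-missing, nonzero)
   in fewer than 50% of biological sample columns; *at least* half is
   inclusive, so 18 of 36 passes. Presence is counted per sample column,
   not per station.
4. **Blank**: fails when the mean biological-sample area (missing counted
   as zero) is less than 3 × the mean blank area; exactly 3 × passes, and a
   zero blank can never fail a feature.

Boundary semantics are deliberate readings of "greater than 30%", "at
least 50%" and "three times larger", and each threshold is an argument.
Filters are idempotent and invariant to reordering sample columns within a
role; internal-standard rows are exempt.

## Dereplication

One metabolite can appear as several mass features: natural-abundance
isotopologues (13C +1.003355 Da, 15N +0.997035 Da, 34S +1.995796 Da),
adducts (Na +21.981944, NH4 +17.026549, K +37.955882 relative to the
protonated ion in positive mode; Cl +35.976678 relative to the
deprotonated ion in negative mode) and doubly charged twins at
`(m + 1.007276) / 2`. A candidate satellite is flagged when its mass
difference to a parent matches an offset within `ppm_tol` (default 5 ppm,
Orbitrap-class accuracy; no tolerance is fixed by the identifier
convention, so this is configurable), it co-elutes within the column's
retention-time window (3 s reversed-phase, 6 s HILIC, read as an absolute
gap `|ΔRT| ≤ window`), and its mean area is smaller than the parent's
(satellite intensity scales with the parent). When two parents could
explain one satellite, the larger-area parent wins, then the lower feature
index — determinism over heuristic sophistication. Chains collapse to the
ultimate parent and cycles are an error, never silently broken. A
cross-sample correlation requirement would be a natural extra evidence
rule but is not part of the procedure; satellites are annotated on mass,
time and area alone.

## Normalization and standardization

**B-MIS** (best-matched internal standard): for each feature, every spiked
internal standard is tried as a normalizer — the adjusted area in sample
*s* is `area_s × mean(IS over pooled) / IS_s` — and scored by the CV it
leaves across pooled injections. The winning candidate is accepted only if
it improves the pooled CV by at least 40% relative to no normalization
(`min_improvement = 0.4`, the acceptance cutoff of the B-MIS method
literature; the exact cutoff used in any given study is rarely printed, so
it is an argument). Candidates are evaluated on pooled injections only and
applied to all columns; the baseline is always in the candidate set, so
B-MIS can never leave a feature worse than raw.

Environmental areas are then divided by the volume filtered; culture areas
by the biovolume harvested. Cultures are *not* B-MIS-normalized: they sit
in different matrices and batches, so the culture path is biovolume →
log10 → per-feature maximum standardization, which lets only
order-of-magnitude differences drive distances. Environmental tables are
standardized per feature to the total peak area across samples (row
fractions summing to one), which cancels any per-feature rescaling.

## Mode discovery

Metabolites are clustered by their abundance pattern across samples with
k-medoids on Euclidean distances of the standardized rows. `pam_cluster`
is the deterministic BUILD + SWAP algorithm with all ties broken toward
the lowest index; because steepest-descent over single swaps can stall in
a local optimum (verified against the reference implementation, which
stalls identically), the SWAP phase also restarts from deterministic
farthest-first medoid sets (8 starts by default) and keeps the best
objective. `clara_cluster` repeats PAM on random subsamples
(`draw_size = 40 + 2k`, 5 draws — the classic defaults), augments each
draw with the best medoids so far, and keeps the draw minimizing total
dissimilarity over all objects; with a draw covering all objects it
reduces exactly to PAM.

The number of modes is chosen from the average silhouette width curve
(singleton clusters score 0 by convention). We return the *local maximum
with the highest average silhouette width* (ties to the smaller k;
endpoints compared one-sided, with a warning when only a boundary
qualifies). We prefer this to "smallest local maximum" because the
silhouette curve of gradient-structured data reproducibly shows a minor
early bump — merging several quasi-linear shapes against tight peaked
shapes — that would otherwise shadow the dominant structure; on planted
five-shape data the highest-local-maximum rule recovers the true k in
essentially every seed while the smallest-local-maximum rule almost never
does.

Features never detected in a dataset are assigned to an explicit
`not_observed` pseudo-mode rather than dropped, because "not observed in
culture" is itself an informative pattern that participates in
cross-dataset comparison. Mode labels are letters by decreasing size
(`a` largest).

NMDS (Kruskal stress-1, monotone regression, best of multiple random
starts) is delegated to vegan; ANOSIM is computed directly from rank
dissimilarities, with the p-value obtained by exhaustive enumeration of
all label permutations when n ≤ 8 and by seeded Monte Carlo permutation
with the +1 correction otherwise.

## Mode-overlap enrichment and metaclusters

Whether a mode from one dataset shares more metabolites with a mode from
another dataset than random assignment would give is tested by Monte
Carlo: the second partition's label vector is permuted uniformly across
the shared feature universe (1,000 draws by default), all pairwise shared
counts are recomputed each draw, and
`p = (1 + #(shared_perm ≥ shared_obs)) / (1 + n_perm)`. Permuting either
side gives the same null for pairwise overlap, so which argument is
permuted is immaterial; the estimator's +1 correction keeps p above zero.
No multiple-testing correction is applied across mode pairs — edges are
reported at raw p < 0.05, matching the reporting convention for such
networks — and the permutation p converges to the exact hypergeometric
tail in the two-mode case, which the tests verify.

The network has one node per mode of size ≥ 10 (smaller modes are too
unstable to interpret, and 10 matches the display cutoff conventional for
mode panels), including the `not_observed` pseudo-mode by default (it can
carry real signal — metabolites absent from cultures but structured in the
environment — and can be excluded with a flag). Edges are enriched
cross-dataset pairs. A *metacluster* is a connected component rooted in a
culture-dataset mode; component delineation is automated as rooted
connected components, which is an explicit interpretation of what is
usually drawn by hand around network hulls. A metabolite belongs to the
metacluster when it is in the rooting culture mode *and* in at least two
of the component's environmental modes. Components with several culture
modes yield one metacluster per root (compound sets stay disjoint because
each metabolite has exactly one culture mode); components with no culture
mode are reported as unrooted.

## Absolute quantification

For compounds with authentic standards,

\[
\mathrm{Concentration} = \frac{\mathrm{Area}}{RF} \times
\frac{V_\mathrm{reconst}}{V_\mathrm{filtered}} \times \frac{1}{RF_\mathrm{ratio}}
\]

with the response factor RF the mean of area/concentration over the
standard injections bracketing a batch (the combination rule across
before/after injections is a documented choice), `vol_reconst_L` defaulting
to 400 µL, and RF_ratio the matrix/water response ratio correcting
ionization suppression, measured once on a representative particulate
matrix and shared across batches (overridable per batch). Sample dilution
before injection enters as a per-sample multiplicative factor. Compounds
whose standard arrived after a batch are transferred through a
structurally matched standard analyzed in both:
`RF_relative = RF_analyte / RF_matched`, and the earlier batch's RF is
`RF_relative × RF_matched` there — an exact algebraic round trip.
Concentrations convert to carbon and nitrogen equivalents through the
formula's element counts, to fractions of bulk particulate carbon or
nitrogen, and to intracellular concentrations by dividing moles on filter
by total biovolume (1 µm³ = 10⁻¹⁵ L; reported in mM). Compounds known to
be unstable in methanol-based extraction (notably DMSP) should be flagged
and excluded from carbon-fraction sums.

## The synthetic-data generator

Real deposited LC-MS datasets are too large to re-process at desk scale,
so every stage is validated on synthetic data with full ground truth. The
generator emulates:

- a **signature matrix** (species × features) with a core-metabolome block
  present in all species, taxon-group-specific blocks, and rare features
  carried by a single species at low abundance. Defaults mirror the study
  scale: 313 features, 21 species in 5 broad groups, 52 core and 123
  group-specific features; abundances are log-normal within blocks.
- **environmental samples** as gradient-weighted mixtures of group-mean
  signatures along a latitude axis (36 stations by default), with five
  built-in weight shapes — monotone increase, flat, a sharp northern peak,
  a mid-axis peak, monotone decrease — plus a total-biomass scalar. A
  small weight floor (0.05) keeps every group present everywhere so no
  true feature is dropped by the presence filter by construction. The
  planted mode of a feature is its signature block.
- **instrument artifacts**: per-column multiplicative log-normal drift
  shared (or, optionally, not shared) with spiked internal standards whose
  drifted areas are exact; pooled QC columns equal to the per-feature mean
  of sample columns (missing contributing zero) with optional injection
  noise; matrix blanks at 10% of each feature's mean sample area; and
  optional contaminant-only features whose blank level equals their sample
  level, so they must fail a 3× blank criterion.
- **satellite features** at the exact mass offsets above, co-eluting with
  their parents at a fixed area fraction (15%), with optional Gaussian
  m/z jitter (ppm) and uniform retention-time jitter.
- **planted concentrations** through the inverse of the quantification
  equation (`area_from_concentration`), giving exact round-trip targets.

Noise is multiplicative log-normal throughout because peak areas are
positive and heteroscedastic. All generators are deterministic given a
seed and restore the caller's RNG state.

What the generator does **not** emulate: chromatographic peak shapes and
integration error, ionization suppression beyond a single matrix factor,
isotope fine structure, retention-time drift between batches, correlated
(structured) noise across features, and compositional closure of real
communities. Passing tests therefore demonstrate that each algorithm
recovers the structure it targets under its stated statistical model, not
that the model captures every failure mode of real LC-MS data.

## Numerical choices and problem sizes

- Ties everywhere in clustering break toward the lowest index; swap
  improvements must exceed 10⁻¹² to count, so iteration terminates.
- Validation sizes are chosen to finish in minutes on one CPU while
  staying at the study's scale where it matters: mode recovery uses 313
  features × 36 samples with five planted shapes at noise σ = 0.1 (20
  seeds for the auto-k check); the enrichment null uses 300 features with
  a realistic mode-size profile, 200 replicates × 1,000 permutations;
  PAM optimality is checked against exhaustive search on 25 eight-point
  instances; ANOSIM p-values are enumerated exactly up to n = 8.
- The permutation p floor is `1/(n_perm + 1)`; with discrete overlap
  counts the test is slightly conservative (null rejection near 3–4% at
  nominal 5%), which the validation treats as acceptable type-I behaviour.

## Known limitations

- B-MIS assumes at least two pooled injections and internal standards
  detected in every column; an internal standard with any missing area is
  excluded as a candidate.
- The culture standardization requires biovolume-normalized areas above 1
  in instrument units for log10/max to be monotone; nonpositive areas are
  treated as missing.
- CLARA's subsampling can split very small true modes; for feature counts
  in the hundreds PAM on the full distance matrix is feasible and
  preferable (`draw_size ≥ n`).
- Whether the pseudo-mode should take part in the permutation universe is
  a modelling decision; both behaviours are supported
  (`include_not_observed`), defaulting to participation.
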