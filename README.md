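# metamodes

Community metabolome fingerprinting from untargeted LC-MS feature tables.

Marine phytoplankton fix carbon into thousands of small polar metabolites —
osmolytes, amino acids, organic sulfur compounds — that make up a large,
labile slice of particulate organic matter and fuel the microbial loop.
Which compounds are present, and at what concentration, depends on which
phytoplankton are present. `metamodes` is for oceanographers and
environmental metabolomics groups who want to test exactly that: whether
bulk community metabolomes carry a fingerprint of phytoplankton community
composition, and which compound groups travel together across taxonomy and
environmental gradients.

The package implements the full analysis chain between a peak table and
that conclusion:

- **Feature tables** — validated features × samples containers with the
  `I<mz>R<rt>` mass-feature identifier convention (m/z to 4 decimals,
  retention time in minutes to 1 decimal), CSV/TSV readers and writers,
  and empirical-formula parsing for compound libraries.
- **Quality control** — pooled-sample CV filter (fail when CV > 30%),
  replicate-variability filter (mean within-replicate CV > whole-set CV),
  presence filter (detected in ≥ 50% of samples) and matrix-blank filter
  (mean sample area ≥ 3 × mean blank area).
- **Dereplication** — removal of ¹³C/¹⁵N/³⁴S isotopologues, Na⁺/NH₄⁺/K⁺/Cl⁻
  adducts and doubly charged twins at `(m + 1.007276)/2`, flagged within
  3-s (RP) / 6-s (HILIC) retention-time windows at 5 ppm mass tolerance.
- **Normalization** — B-MIS (best-matched internal standard) removal of
  instrument drift scored on pooled QC injections; volume / biovolume
  normalization; total-peak-area standardization (environmental) and
  log₁₀/max standardization (cultures).
- **Mode discovery** — deterministic PAM and CLARA k-medoids on Euclidean
  distances of standardized rows, with the number of modes selected at a
  local maximum of the average silhouette width and an explicit
  `not_observed` pseudo-mode for features absent from a dataset.
- **Enrichment network** — a Monte Carlo permutation test (default 1,000
  permutations) for whether two modes from different datasets share more
  metabolites than random assignment,
  `p = (1 + #{shared_perm ≥ shared_obs}) / (1 + n_perm)`; modes with
  ≥ 10 compounds become nodes, pairs with p < 0.05 become edges, and
  connected components rooted in a culture mode become *metaclusters*
  whose member compounds must sit in the root mode and in ≥ 2
  environmental modes of the component.
- **Quantification** — absolute concentrations via
  `Concentration = (Area/RF) · (Vol_reconst/Vol_filtered) · (1/RF_ratio)`,
  relative response factors for calibration transfer between batches,
  carbon/nitrogen equivalents, fractions of bulk particulate pools, and
  intracellular concentrations from biovolume.
- **Synthetic data** — a generator that plants taxon-structured signature
  blocks, gradient-weighted community mixtures, shared instrument drift,
  satellite features and true concentrations, with the full ground truth
  returned for validation. Supporting statistics (NMDS with Kruskal
  stress-1 via vegan, exact-enumeration ANOSIM) round out the toolkit.

## Worked example

Simulate a transect-style dataset with drift, contaminants and satellite
features, then run the environmental chain end to end:

```r
library(metamodes)

sig <- generate_signatures(seed = 1)                 # 313 features, 21 species
env <- simulate_environment_table(sig, community_design(36, 5), n_reps = 2,
                                  noise_sigma = 0.1, seed = 1)
art <- add_instrument_artifacts(env, drift_sigma = 0.3, n_contaminants = 8,
                                injection_noise_sigma = 0.02, seed = 1)
sat <- add_adducts_isotopes(art, rates = c(`13C` = 0.05, Na = 0.05), seed = 1)

out <- run_environmental_pipeline(sat$table, seed = 2)
print(out$qc)
#> <qc_report> 358 features: 350 pass; fails: cv=0 replicate=0 presence=0 blank=8
print(out$partition)
#> <mode_partition> transect: 313 features in 3 modes (avg sil 0.693)
#>
#>   a   b   c
#> 218  51  44
```

All 8 planted contaminant-only features fail the blank filter and nothing
else does; the 32 planted satellites are removed by dereplication; the 313
true features are grouped into abundance modes named by decreasing size.
Quantification converts areas to concentrations and elemental equivalents:

```r
ctx <- quant_context(rf = 1e5, rf_ratio = 0.8, vol_filtered_L = 10)
concentration_in_sample(1e6, ctx)
#> [1] 0.5                                  # nM in the original seawater
element_equivalents(0.5, list(n_C = 7, n_N = 1))   # e.g. homarine, C7H7NO2
#>   nM_C nM_N
#> 1  3.5  0.5
```

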