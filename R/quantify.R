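# Absolute quantification of identified compounds.
#
# The central relation converts a peak area to a concentration in the
# original water sample:
#
#   Concentration = (Area / RF) * (Vol_reconst / Vol_filtered) * (1 / RF_ratio)
#
# where RF is the response factor (peak area per unit concentration,
# area per uM, measured on authentic standards in water), RF_ratio corrects
# for matrix ionization effects (RF in a representative particulate matrix
# over RF in water), Vol_reconst is the reconstitution volume (400 uL by
# default) and Vol_filtered the seawater volume filtered (or the total
# biovolume, expressed in liters, for cultures). An optional per-sample
# dilution factor multiplies the result when samples were diluted before
# injection.

#' Quantification context
#'
#' Bundles everything needed to turn an area into a concentration.
#'
#' @param rf response factor, area per uM, > 0.
#' @param rf_ratio matrix/water response-factor ratio, > 0.
#' @param vol_filtered_L volume filtered (liters), > 0.
#' @param vol_reconst_L reconstitution volume (liters), default 400 uL.
#' @param dilution_factor per-sample dilution correction (3 for 1 part
#'   sample + 2 parts water), >= 1.
#' @return object of class `quant_context`.
#' @export
quant_context <- function(rf, rf_ratio = 1, vol_filtered_L,
                          vol_reconst_L = 400e-6, dilution_factor = 1) {
  for (nm in c("rf", "rf_ratio", "vol_filtered_L", "vol_reconst_L",
               "dilution_factor")) {
    v <- get(nm)
    assert_scalar_number(v, nm)
    if (v <= 0) stop_invalid("`%s` must be > 0", nm)
  }
  structure(list(rf = rf, rf_ratio = rf_ratio,
                 vol_filtered_L = vol_filtered_L,
                 vol_reconst_L = vol_reconst_L,
                 dilution_factor = dilution_factor),
            class = "quant_context")
}

#' Response factor from standard injections
#'
#' Standards are injected before and after each batch; the batch RF is the
#' mean of area/concentration over the injections.
#'
#' @param standard_areas peak areas of the standard injections.
#' @param standard_concentrations matching concentrations (uM), > 0.
#' @return RF in area per uM.
#' @export
compute_rf <- function(standard_areas, standard_concentrations) {
  if (length(standard_areas) != length(standard_concentrations)) {
    stop_invalid("areas and concentrations must have equal length")
  }
  if (!length(standard_areas)) stop_invalid("need >= 1 standard injection")
  if (any(standard_concentrations <= 0)) {
    stop_invalid("standard concentrations must be > 0")
  }
  if (any(standard_areas <= 0)) stop_invalid("standard areas must be > 0")
  mean(standard_areas / standard_concentrations)
}

#' Matrix/water response-factor ratio
#' @param rf_matrix RF measured in a representative particulate matrix.
#' @param rf_water RF measured in water.
#' @return dimensionless RF ratio.
#' @export
compute_rf_ratio <- function(rf_matrix, rf_water) {
  assert_scalar_number(rf_matrix, "rf_matrix")
  assert_scalar_number(rf_water, "rf_water")
  if (rf_matrix <= 0 || rf_water <= 0) stop_invalid("RFs must be > 0")
  rf_matrix / rf_water
}

#' Relative response factor and batch transfer
#'
#' When a compound's standard was only analyzed in a later batch, its RF in
#' an earlier batch is estimated through a structurally matched standard
#' analyzed in both: `RF_relative = RF_analyte / RF_matched`, and the
#' estimated RF in the earlier batch is
#' `RF_relative * RF_matched(in that batch)`.
#'
#' @param rf_analyte analyte RF in the batch where both were analyzed.
#' @param rf_matched matched-standard RF in that same batch.
#' @return `compute_rf_relative`: the dimensionless relative RF.
#' @export
compute_rf_relative <- function(rf_analyte, rf_matched) {
  assert_scalar_number(rf_analyte, "rf_analyte")
  assert_scalar_number(rf_matched, "rf_matched")
  if (rf_analyte <= 0 || rf_matched <= 0) stop_invalid("RFs must be > 0")
  rf_analyte / rf_matched
}

#' @rdname compute_rf_relative
#' @param rf_relative a relative RF from [compute_rf_relative()].
#' @param rf_matched_in_batch matched-standard RF in the target batch.
#' @return `estimate_rf`: the estimated analyte RF in the target batch.
#' @export
estimate_rf <- function(rf_relative, rf_matched_in_batch) {
  assert_scalar_number(rf_relative, "rf_relative")
  assert_scalar_number(rf_matched_in_batch, "rf_matched_in_batch")
  if (rf_relative <= 0 || rf_matched_in_batch <= 0) {
    stop_invalid("inputs must be > 0")
  }
  rf_relative * rf_matched_in_batch
}

#' Concentration of a compound in the original sample
#'
#' Applies the central quantification relation; with RF in area per uM the
#' result is returned in nM.
#'
#' @param area peak area(s), >= 0.
#' @param ctx a [quant_context()].
#' @return concentration(s) in nM.
#' @export
concentration_in_sample <- function(area, ctx) {
  stopifnot(inherits(ctx, "quant_context"))
  if (any(!is.finite(area)) || any(area < 0)) {
    stop_invalid("`area` must be finite and >= 0")
  }
  conc_uM <- (area / ctx$rf) * (ctx$vol_reconst_L / ctx$vol_filtered_L) *
    (1 / ctx$rf_ratio) * ctx$dilution_factor
  conc_uM * 1000
}

#' Expected peak area for a known concentration
#'
#' Inverse of [concentration_in_sample()]; used to plant true
#' concentrations in synthetic data for round-trip validation.
#'
#' @param conc_nM concentration(s) in nM.
#' @inheritParams concentration_in_sample
#' @return peak area(s).
#' @export
area_from_concentration <- function(conc_nM, ctx) {
  stopifnot(inherits(ctx, "quant_context"))
  (conc_nM / 1000) * ctx$rf * ctx$rf_ratio *
    (ctx$vol_filtered_L / ctx$vol_reconst_L) / ctx$dilution_factor
}

#' Carbon and nitrogen equivalents of a concentration
#'
#' @param conc compound concentration(s), nM.
#' @param compound one row of a [read_compound_library()] table (or any
#'   list with `n_C` and `n_N`).
#' @return data.frame with `nM_C` and `nM_N`.
#' @export
element_equivalents <- function(conc, compound) {
  if (is.null(compound$n_C) || is.null(compound$n_N)) {
    stop_invalid("compound must carry element counts n_C and n_N")
  }
  data.frame(nM_C = conc * compound$n_C, nM_N = conc * compound$n_N)
}

#' Fraction of a bulk elemental pool
#'
#' @param total_nM sum of metabolite carbon (or nitrogen) concentrations, nM.
#' @param bulk_nM bulk particulate carbon (or nitrogen) concentration, nM,
#'   > 0.
#' @return fraction (0.029 means 2.9%).
#' @export
fraction_of_bulk <- function(total_nM, bulk_nM) {
  assert_scalar_number(bulk_nM, "bulk_nM")
  if (bulk_nM <= 0) stop_invalid("`bulk_nM` must be > 0")
  total_nM / bulk_nM
}

#' Intracellular concentration from moles on filter and biovolume
#'
#' Moles harvested divided by the total cell volume (1 um^3 = 1e-15 L),
#' reported in mM.
#'
#' @param moles_on_filter moles of the compound collected.
#' @param total_biovolume_um3 total biovolume harvested, um^3, > 0.
#' @return intracellular concentration in mM.
#' @export
intracellular_concentration <- function(moles_on_filter, total_biovolume_um3) {
  assert_scalar_number(total_biovolume_um3, "total_biovolume_um3")
  if (total_biovolume_um3 <= 0) stop_invalid("biovolume must be > 0")
  volume_L <- total_biovolume_um3 * 1e-15
  (moles_on_filter / volume_L) * 1000 # mol/L -> mM
}
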