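# Normalization: removal of instrument-derived obscuring variability via
# best-matched internal standards (B-MIS), normalization to volume filtered
# or biovolume, and the standardizations used before multivariate analysis.

#' Normalize areas to volume filtered or biovolume
#'
#' Divides each biological sample column by its `vol_filtered_L`
#' (environmental samples) or `biovolume_um3` (cultures). Pooled and blank
#' columns have no sampled volume and are left untouched.
#'
#' @param table a [peak_table()].
#' @return a [peak_table()] with updated units.
#' @export
volume_normalize <- function(table) {
  stopifnot(inherits(table, "peak_table"))
  s <- table$samples
  is_sample <- s$role == "sample"
  vol <- ifelse(!is.na(s$vol_filtered_L), s$vol_filtered_L, s$biovolume_um3)
  bad <- is_sample & (is.na(vol) | vol <= 0)
  if (any(bad)) {
    stop_invalid("missing or nonpositive volume for sample(s): %s",
                 paste(utils::head(s$sample_id[bad], 5L), collapse = ", "))
  }
  areas <- table$areas
  idx <- which(is_sample)
  areas[, idx] <- sweep(areas[, idx, drop = FALSE], 2, vol[idx], `/`)
  unit <- if (any(!is.na(s$vol_filtered_L[is_sample]))) "area per L"
          else "area per um3"
  peak_table(table$features, s, areas, units = unit)
}

#' B-MIS normalization
#'
#' Best-matched internal standard normalization: for each feature, every
#' internal standard is tried as a normalizer — the candidate-adjusted area
#' in sample s is `area_s * mean(IS over pooled) / IS_s` — and scored by the
#' coefficient of variation it leaves across the pooled QC injections. The
#' candidate with the lowest pooled CV is accepted only if it improves on
#' the no-normalization baseline by at least `min_improvement` (relative CV
#' reduction); otherwise the feature keeps its raw areas. The chosen
#' normalizer is then applied across all columns.
#'
#' @param table a [peak_table()] containing internal-standard rows and
#'   pooled samples.
#' @param internal_standards feature ids of the internal standards; default
#'   is the table's `is_internal_standard` flag.
#' @param pooled_ids sample ids of pooled injections; default role "pooled".
#' @param min_improvement minimum relative CV improvement over baseline
#'   (0.4 = 40%) for a normalizer to be accepted.
#' @return list with `table` (normalized areas; internal-standard rows kept
#'   untouched) and `result`, a data.frame per feature: chosen normalizer
#'   ("none" when baseline is kept), baseline and best pooled CV, and the
#'   relative improvement.
#' @export
bmis_normalize <- function(table, internal_standards = NULL,
                           pooled_ids = NULL, min_improvement = 0.4) {
  stopifnot(inherits(table, "peak_table"))
  is_ids <- internal_standards %||%
    table$features$feature_id[table$features$is_internal_standard]
  pooled_ids <- pooled_ids %||% samples_by_role(table, "pooled")
  if (length(pooled_ids) < 2L) stop_invalid("B-MIS needs >= 2 pooled samples")
  if (!length(is_ids)) stop_invalid("B-MIS needs >= 1 internal standard")
  missing_is <- setdiff(is_ids, table$features$feature_id)
  if (length(missing_is)) {
    stop_invalid("internal standard(s) not in table: %s",
                 paste(missing_is, collapse = ", "))
  }

  areas <- table$areas
  usable <- vapply(is_ids, function(id) {
    ok <- all(!is.na(areas[id, ]) & areas[id, ] > 0)
    if (!ok) warning(sprintf(
      "internal standard %s has zero/missing areas; excluded as candidate", id))
    ok
  }, logical(1))
  cand <- is_ids[usable]

  target <- setdiff(table$features$feature_id, is_ids)
  P <- areas[target, pooled_ids, drop = FALSE]
  baseline_cv <- apply(P, 1L, cv_or_na)

  best_cv <- baseline_cv
  chosen <- rep("none", length(target))
  if (length(cand)) {
    for (id in cand) {
      f <- areas[id, pooled_ids] / mean(areas[id, pooled_ids])
      adj <- sweep(P, 2, f, `/`)
      cvs <- apply(adj, 1L, cv_or_na)
      better <- !is.na(cvs) & (is.na(best_cv) | cvs < best_cv)
      best_cv[better] <- cvs[better]
      chosen[better] <- id
    }
  }
  improvement <- ifelse(is.na(baseline_cv) | baseline_cv == 0, 0,
                        (baseline_cv - best_cv) / baseline_cv)
  accept <- chosen != "none" & improvement >= min_improvement
  chosen[!accept] <- "none"
  best_cv[!accept] <- baseline_cv[!accept]

  out <- areas
  for (id in unique(chosen[accept])) {
    f_all <- areas[id, ] / mean(areas[id, pooled_ids])
    rows <- target[chosen == id]
    out[rows, ] <- sweep(areas[rows, , drop = FALSE], 2, f_all, `/`)
  }
  result <- data.frame(feature_id = target, chosen = chosen,
                       cv_baseline = baseline_cv, cv_normalized = best_cv,
                       improvement = improvement, row.names = NULL)
  list(table = peak_table(table$features, table$samples, out,
                          units = table$units),
       result = result)
}

#' Standardize to total peak area (environmental sample sets)
#'
#' Per feature, each biological sample's area divided by the feature's total
#' area over all biological samples, so each row sums to one. Missing areas
#' contribute zero.
#'
#' @param table a [peak_table()].
#' @return matrix (features x biological samples) of fractions.
#' @export
standardize_to_total <- function(table) {
  stopifnot(inherits(table, "peak_table"))
  sample_ids <- samples_by_role(table, "sample")
  m <- table$areas[, sample_ids, drop = FALSE]
  m[is.na(m)] <- 0
  tot <- rowSums(m)
  zero <- tot <= 0
  if (any(zero)) {
    stop_invalid("all-zero feature(s): %s",
                 paste(utils::head(rownames(m)[zero], 5L), collapse = ", "))
  }
  sweep(m, 1L, tot, `/`)
}

#' Standardize culture peak areas (log10 / max)
#'
#' For each feature, `log10(area)` divided by the maximum `log10(area)`
#' observed across all culture samples, so only order-of-magnitude
#' differences drive downstream distances. Areas that are missing or <= 0
#' stay missing (`NA`); replace them with 0 when building clustering input.
#'
#' @param table a [peak_table()] of biovolume-normalized culture areas.
#' @return matrix (features x biological samples) of standardized values
#'   with per-feature maximum 1.
#' @export
standardize_culture <- function(table) {
  stopifnot(inherits(table, "peak_table"))
  sample_ids <- samples_by_role(table, "sample")
  m <- table$areas[, sample_ids, drop = FALSE]
  m[!is.na(m) & m <= 0] <- NA
  lg <- log10(m)
  mx <- apply(lg, 1L, function(r) if (all(is.na(r))) NA_real_ else max(r, na.rm = TRUE))
  out <- sweep(lg, 1L, mx, `/`)
  out
}
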