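# Convenience orchestrator for the environmental processing chain.

#' Run the environmental processing chain on one dataset
#'
#' B-MIS normalization, the four QC filters, satellite dereplication,
#' volume normalization and mode discovery, in the order used for
#' environmental sample sets. Returns every intermediate so each stage can
#' be inspected.
#'
#' @param table a raw [peak_table()] with pooled and blank columns and
#'   internal-standard rows.
#' @param k number of modes (NULL auto-selects at a local silhouette
#'   maximum).
#' @param qc_filters which QC filters to run (see [qc_filter()]).
#' @param min_improvement B-MIS acceptance threshold.
#' @param ppm_tol dereplication mass tolerance (ppm).
#' @param seed RNG seed for clustering.
#' @param ... passed to [discover_modes()].
#' @return list with `bmis`, `qc`, `dereplication`, `normalized_table` and
#'   `partition`.
#' @export
run_environmental_pipeline <- function(table, k = NULL,
                                       qc_filters = c("cv", "replicate",
                                                      "presence", "blank"),
                                       min_improvement = 0.4, ppm_tol = 5,
                                       seed = 1, ...) {
  stopifnot(inherits(table, "peak_table"))
  bmis <- bmis_normalize(table, min_improvement = min_improvement)
  qc <- qc_filter(bmis$table, filters = qc_filters)
  filtered <- apply_qc(bmis$table, qc)
  ann <- annotate_satellites(filtered, ppm_tol = ppm_tol)
  derep <- dereplicate_table(filtered, ann)
  keep_bio <- !derep$table$features$is_internal_standard
  bio <- subset_peak_table(
    derep$table, derep$table$features$feature_id[keep_bio])
  normalized <- volume_normalize(bio)
  partition <- discover_modes(normalized, mode = "environmental", k = k,
                              seed = seed, ...)
  list(bmis = bmis, qc = qc, dereplication = derep,
       normalized_table = normalized, partition = partition)
}
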