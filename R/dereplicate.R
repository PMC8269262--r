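# Dereplication: flag isotopologue, adduct and doubly charged satellite
# features of other features and remove them so each metabolite carries a
# single statistical weight.
#
# A candidate satellite j of parent i is flagged when
#   * the mass difference matches the kind's exact offset within `ppm_tol`
#     parts-per-million of the satellite m/z,
#   * the retention-time gap is at most the column window (3 s RP, 6 s HILIC),
#   * the satellite's mean area is smaller than the parent's (isotopologue
#     and adduct intensity scales with the parent).
# When several parents explain one satellite the parent with the larger mean
# area wins (ties: lower feature index).

DEFAULT_RT_WINDOW_SEC <- c(RP = 3, HILIC = 6)

rt_window_for <- function(features, window_sec) {
  if (!is.null(window_sec)) return(window_sec)
  col <- unique(features$column)
  if (length(col) != 1L) {
    stop_invalid("features span multiple chromatography columns; pass `window_sec`")
  }
  DEFAULT_RT_WINDOW_SEC[[col]]
}

satellite_annotation_frame <- function() {
  data.frame(satellite_id = character(0), parent_id = character(0),
             kind = character(0), mass_error_ppm = numeric(0),
             rt_gap_sec = numeric(0))
}

# core pair scan shared by the three finders
scan_pairs <- function(features, mean_area, kinds, window_sec, ppm_tol) {
  n <- nrow(features)
  out <- list()
  if (n < 2L) return(satellite_annotation_frame())
  mz <- features$mz
  rt <- features$rt_sec
  rt_ok <- abs(outer(rt, rt, `-`)) <= window_sec
  area_ok <- outer(mean_area, mean_area, `>`) # parent (row) > satellite (col)
  for (kind in kinds) {
    expected <- if (kind == "2+") (mz + PROTON_MASS) / 2
                else mz + MASS_OFFSETS[[kind]]
    # err[i, j]: observed satellite j against expectation from parent i
    err <- outer(expected, mz, function(e, m) m - e)
    tol <- matrix(ppm_tol * 1e-6 * mz, n, n, byrow = TRUE)
    hit <- abs(err) <= tol & rt_ok & area_ok
    diag(hit) <- FALSE
    idx <- which(hit, arr.ind = TRUE)
    if (!nrow(idx)) next
    out[[kind]] <- data.frame(
      satellite_id = features$feature_id[idx[, 2L]],
      parent_id = features$feature_id[idx[, 1L]],
      kind = kind,
      mass_error_ppm = err[idx] / mz[idx[, 2L]] * 1e6,
      rt_gap_sec = rt[idx[, 2L]] - rt[idx[, 1L]],
      parent_area = mean_area[idx[, 1L]],
      parent_index = idx[, 1L])
  }
  if (!length(out)) return(satellite_annotation_frame())
  ann <- do.call(rbind, out)
  rownames(ann) <- NULL
  # one parent per satellite: largest mean area, then lowest index
  ann <- ann[order(ann$satellite_id, -ann$parent_area, ann$parent_index), ]
  ann <- ann[!duplicated(ann$satellite_id), ]
  ann$parent_area <- NULL
  ann$parent_index <- NULL
  rownames(ann) <- NULL
  ann
}

prepare_features <- function(table, polarity = NULL) {
  stopifnot(inherits(table, "peak_table"))
  feats <- table$features
  pol <- unique(feats$polarity)
  if (length(pol) != 1L) stop_invalid("features mix polarities; split the table first")
  if (!is.null(polarity) && pol != polarity) {
    stop_invalid("table polarity is %s, not %s", pol, polarity)
  }
  sample_ids <- samples_by_role(table, "sample")
  a <- table$areas[, sample_ids, drop = FALSE]
  a[is.na(a)] <- 0
  list(features = feats, mean_area = rowMeans(a), polarity = pol)
}

#' Find isotopologue satellites (13C, 15N, 34S)
#'
#' @param table a [peak_table()] (one column, one polarity).
#' @param window_sec retention-time window in seconds; default 3 s for RP,
#'   6 s for HILIC.
#' @param ppm_tol mass tolerance in ppm of the satellite m/z.
#' @return data.frame of satellite annotations (satellite_id, parent_id,
#'   kind, mass_error_ppm, rt_gap_sec).
#' @export
find_isotopologues <- function(table, window_sec = NULL, ppm_tol = 5) {
  p <- prepare_features(table)
  scan_pairs(p$features, p$mean_area, c("13C", "15N", "34S"),
             rt_window_for(p$features, window_sec), ppm_tol)
}

#' Find adduct satellites (Na, NH4, K in positive mode; Cl in negative)
#'
#' @inheritParams find_isotopologues
#' @param kinds adduct kinds to search; defaults to all kinds formed in the
#'   table's polarity. Requesting a kind the polarity cannot form is an
#'   error.
#' @return data.frame of satellite annotations.
#' @export
find_adducts <- function(table, window_sec = NULL, ppm_tol = 5, kinds = NULL) {
  p <- prepare_features(table)
  allowed <- intersect(satellite_kinds_for_polarity(p$polarity),
                       c("Na", "NH4", "K", "Cl"))
  kinds <- kinds %||% allowed
  bad <- setdiff(kinds, allowed)
  if (length(bad)) {
    stop_invalid("adduct kind(s) %s are not formed in %s mode",
                 paste(bad, collapse = ", "), p$polarity)
  }
  scan_pairs(p$features, p$mean_area, kinds,
             rt_window_for(p$features, window_sec), ppm_tol)
}

#' Find doubly charged satellites
#'
#' Each positive-mode feature at m (treated as the singly protonated ion)
#' may have a co-eluting doubly charged twin at `(m + 1.007276)/2`.
#'
#' @inheritParams find_isotopologues
#' @return data.frame of satellite annotations.
#' @export
find_multiply_charged <- function(table, window_sec = NULL, ppm_tol = 5) {
  p <- prepare_features(table, polarity = "pos")
  scan_pairs(p$features, p$mean_area, "2+",
             rt_window_for(p$features, window_sec), ppm_tol)
}

#' Find all satellite features
#'
#' Union of [find_isotopologues()], [find_adducts()] and (positive mode)
#' [find_multiply_charged()], with one parent kept per satellite (largest
#' mean area).
#'
#' @inheritParams find_isotopologues
#' @return data.frame of satellite annotations.
#' @export
annotate_satellites <- function(table, window_sec = NULL, ppm_tol = 5) {
  p <- prepare_features(table)
  kinds <- satellite_kinds_for_polarity(p$polarity)
  scan_pairs(p$features, p$mean_area, kinds,
             rt_window_for(p$features, window_sec), ppm_tol)
}

#' Remove annotated satellites from a peak table
#'
#' Satellites are removed and parents retained. Chains (a satellite of a
#' satellite) collapse to the ultimate parent; a feature that is both parent
#' and satellite is removed only in its satellite role. Cycles among the
#' annotations are an error.
#'
#' @param table a [peak_table()].
#' @param annotations data.frame from [annotate_satellites()] or friends.
#' @return list with `table` (satellites removed) and `removed` (data.frame
#'   of satellite_id, ultimate parent_id, kind).
#' @export
dereplicate_table <- function(table, annotations) {
  stopifnot(inherits(table, "peak_table"))
  if (!nrow(annotations)) {
    return(list(table = table, removed = satellite_annotation_frame()))
  }
  unknown <- setdiff(c(annotations$satellite_id, annotations$parent_id),
                     table$features$feature_id)
  if (length(unknown)) {
    stop_invalid("annotations reference unknown feature(s): %s",
                 paste(utils::head(unknown, 5L), collapse = ", "))
  }
  parent_of <- stats::setNames(annotations$parent_id, annotations$satellite_id)
  resolve <- function(id) {
    seen <- character(0)
    while (id %in% names(parent_of)) {
      if (id %in% seen) {
        stop_invalid("annotation cycle: %s",
                     paste(c(seen, id), collapse = " -> "))
      }
      seen <- c(seen, id)
      id <- parent_of[[id]]
    }
    id
  }
  removed <- annotations
  removed$parent_id <- vapply(removed$satellite_id, resolve, character(1))
  keep <- setdiff(table$features$feature_id, removed$satellite_id)
  list(table = subset_peak_table(table, feature_ids = keep),
       removed = removed)
}
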