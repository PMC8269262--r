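# Feature-level quality-control filters, applied in the order:
# pooled-sample CV -> replicate variability -> presence -> matrix blank.
#
# Boundary semantics (documented, configurable by threshold):
#   * CV filter fails on CV strictly greater than the threshold;
#   * replicate filter fails when the mean within-replicate-group CV is
#     strictly greater than the CV over all biological samples;
#   * presence passes when the detected fraction is at least the minimum;
#   * blank filter passes when the mean sample area is at least
#     `fold` times the mean blank area (missing areas count as zero there).

#' Coefficient of variation
#'
#' Sample standard deviation divided by the mean, ignoring missing values.
#'
#' @param values numeric vector of areas (>= 2 non-missing values).
#' @return CV as a ratio (0.30 means 30%).
#' @export
compute_cv <- function(values) {
  v <- values[!is.na(values)]
  if (length(v) < 2L) stop_invalid("CV needs >= 2 non-missing values")
  m <- mean(v)
  if (m <= 0) stop_invalid("CV undefined for mean <= 0")
  stats::sd(v) / m
}

cv_or_na <- function(values) {
  v <- values[!is.na(values)]
  if (length(v) < 2L || mean(v) <= 0) return(NA_real_)
  stats::sd(v) / mean(v)
}

#' Run the quality-control filters on a peak table
#'
#' Computes per-feature statistics and pass/fail flags for the four filters.
#' Internal-standard rows are exempt (never flagged). Filters whose inputs
#' are absent either error (`pooled_cv`, `blank` — the stage must be skipped
#' explicitly via `filters`) or are skipped with a warning (`replicate`).
#'
#' @param table a [peak_table()].
#' @param cv_threshold pooled-sample CV above which a feature fails.
#' @param min_presence minimum fraction of biological samples in which a
#'   feature must be detected (non-missing, nonzero).
#' @param blank_fold required ratio of mean sample area to mean blank area.
#' @param filters which filters to run, in order.
#' @return object of class `qc_report`: data.frame with per-feature
#'   statistics, flags `cv_fail`, `replicate_fail`, `presence_fail`,
#'   `blank_fail`, and `pass` (all run flags false).
#' @export
qc_filter <- function(table, cv_threshold = 0.30, min_presence = 0.5,
                      blank_fold = 3,
                      filters = c("cv", "replicate", "presence", "blank")) {
  stopifnot(inherits(table, "peak_table"))
  filters <- match.arg(filters, several.ok = TRUE)
  fid <- table$features$feature_id
  n <- length(fid)
  rep_groups <- table$samples$replicate_group[table$samples$role == "sample"]
  report <- data.frame(
    feature_id = fid,
    pooled_cv = NA_real_, replicate_cv = NA_real_, overall_cv = NA_real_,
    presence_fraction = NA_real_, blank_fold = NA_real_,
    cv_fail = FALSE, replicate_fail = FALSE, presence_fail = FALSE,
    blank_fail = FALSE)

  sample_ids <- samples_by_role(table, "sample")
  pooled_ids <- samples_by_role(table, "pooled")
  blank_ids <- samples_by_role(table, c("blank", "medium_blank"))

  if ("cv" %in% filters) {
    if (length(pooled_ids) < 2L) {
      stop_invalid(paste0("pooled CV filter needs >= 2 pooled samples; ",
                          "drop \"cv\" from `filters` to skip it"))
    }
    report$pooled_cv <- apply(table$areas[, pooled_ids, drop = FALSE], 1L,
                              cv_or_na)
    report$cv_fail <- !is.na(report$pooled_cv) &
      report$pooled_cv > cv_threshold
  }

  if ("replicate" %in% filters) {
    groups <- rep_groups[!is.na(rep_groups)]
    multi <- names(which(table(groups) >= 2L))
    if (!length(multi)) {
      warning("no replicate groups with >= 2 members; replicate filter skipped")
    } else {
      sam <- table$areas[, sample_ids, drop = FALSE]
      grp <- table$samples$replicate_group[match(sample_ids,
                                                 table$samples$sample_id)]
      within <- sapply(multi, function(g) {
        apply(sam[, grp %in% g, drop = FALSE], 1L, cv_or_na)
      })
      within <- matrix(within, nrow = n)
      report$replicate_cv <- rowMeans(within, na.rm = TRUE)
      report$overall_cv <- apply(sam, 1L, cv_or_na)
      report$replicate_fail <- !is.na(report$replicate_cv) &
        !is.na(report$overall_cv) &
        report$replicate_cv > report$overall_cv
    }
  }

  if ("presence" %in% filters) {
    sam <- table$areas[, sample_ids, drop = FALSE]
    report$presence_fraction <-
      rowMeans(!is.na(sam) & sam > 0)
    report$presence_fail <- report$presence_fraction < min_presence
  }

  if ("blank" %in% filters) {
    if (!length(blank_ids)) {
      stop_invalid(paste0("blank filter needs >= 1 blank sample; ",
                          "drop \"blank\" from `filters` to skip it"))
    }
    sam <- table$areas[, sample_ids, drop = FALSE]
    blk <- table$areas[, blank_ids, drop = FALSE]
    sam[is.na(sam)] <- 0
    blk[is.na(blk)] <- 0
    mean_sample <- rowMeans(sam)
    mean_blank <- rowMeans(blk)
    report$blank_fold <- ifelse(mean_blank > 0, mean_sample / mean_blank, Inf)
    report$blank_fail <- mean_sample < blank_fold * mean_blank
  }

  is_is <- table$features$is_internal_standard
  for (flag in c("cv_fail", "replicate_fail", "presence_fail", "blank_fail")) {
    report[[flag]][is_is] <- FALSE
  }
  report$pass <- !(report$cv_fail | report$replicate_fail |
                     report$presence_fail | report$blank_fail)
  class(report) <- c("qc_report", class(report))
  report
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(
    "<qc_report> %d features: %d pass; fails: cv=%d replicate=%d presence=%d blank=%d\n",
    nrow(x), sum(x$pass), sum(x$cv_fail), sum(x$replicate_fail),
    sum(x$presence_fail), sum(x$blank_fail)))
  invisible(x)
}

#' Keep only features that pass QC
#'
#' @param table a [peak_table()].
#' @param report a [qc_filter()] report for that table.
#' @return filtered [peak_table()].
#' @export
apply_qc <- function(table, report) {
  stopifnot(inherits(table, "peak_table"), inherits(report, "qc_report"))
  if (!identical(report$feature_id, table$features$feature_id)) {
    stop_invalid("report does not match the table's features")
  }
  subset_peak_table(table, feature_ids = report$feature_id[report$pass])
}
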