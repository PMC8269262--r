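# Domain types and tabular I/O for peak tables, sample metadata and
# compound libraries.
#
# A mass feature is an LC-MS peak defined by its mass-to-charge ratio (m/z)
# and retention time. Feature identifiers follow the field convention
# "I<mz>R<rt>", with m/z rendered to 4 decimal places and retention time in
# minutes rendered to 1 decimal place, e.g. "I121.0684R10.7". Retention time
# is stored internally in seconds (dereplication windows are in seconds);
# only the identifier renders minutes.

SAMPLE_ROLES <- c("sample", "pooled", "blank", "medium_blank")
CHROMATOGRAPHY_COLUMNS <- c("HILIC", "RP")
POLARITIES <- c("pos", "neg")

#' Build a mass-feature identifier
#'
#' Renders the "I<mz>R<rt>" identifier used for unidentified mass features:
#' m/z to 4 decimal places, retention time in minutes to 1 decimal place.
#' Rounding is round-half-even (the default of C `sprintf` on IEEE doubles).
#'
#' @param mz mass-to-charge ratio (> 0).
#' @param rt_min retention time in minutes (>= 0).
#' @return character vector of identifiers.
#' @examples
#' make_feature_id(121.0684, 10.7)
#' @export
make_feature_id <- function(mz, rt_min) {
  if (!is.numeric(mz) || !is.numeric(rt_min) || any(!is.finite(mz)) ||
      any(!is.finite(rt_min))) {
    stop_invalid("`mz` and `rt_min` must be finite numbers")
  }
  if (any(mz <= 0)) stop_invalid("`mz` must be > 0")
  if (any(rt_min < 0)) stop_invalid("`rt_min` must be >= 0")
  sprintf("I%.4fR%.1f", mz, rt_min)
}

#' Parse a mass-feature identifier
#'
#' Inverse of [make_feature_id()] at the rendered precision.
#'
#' @param id character vector of "I<mz>R<rt>" identifiers.
#' @return data.frame with columns `mz` and `rt_min`.
#' @export
parse_feature_id <- function(id) {
  if (!is.character(id)) stop_invalid("`id` must be character")
  pattern <- "^I([0-9]+\\.[0-9]{4})R([0-9]+\\.[0-9])$"
  bad <- !grepl(pattern, id)
  if (any(bad)) {
    stop_invalid("malformed feature id(s): %s",
                 paste(utils::head(id[bad], 5L), collapse = ", "))
  }
  data.frame(
    mz = as.numeric(sub(pattern, "\\1", id)),
    rt_min = as.numeric(sub(pattern, "\\2", id))
  )
}

#' Construct a peak table
#'
#' The universal currency between pipeline stages: a features x samples
#' matrix of peak areas plus feature and sample metadata. Missing areas (`NA`)
#' mean "not detected/integrated" and are distinct from a measured zero.
#'
#' @param features data.frame with columns `feature_id`, `mz`, `rt_sec`,
#'   `column` ("HILIC" or "RP") and `polarity` ("pos" or "neg").
#' @param samples data.frame with columns `sample_id`, `dataset_id`, `role`
#'   (one of sample/pooled/blank/medium_blank) and optionally
#'   `replicate_group`, `vol_filtered_L`, `biovolume_um3`, `latitude`,
#'   `depth_m`, `organism`.
#' @param areas numeric matrix (features x samples) of non-negative peak
#'   areas; `NA` marks a missing (undetected) value.
#' @param units free-text unit tag carried through normalization steps.
#' @return object of class `peak_table`.
#' @export
peak_table <- function(features, samples, areas, units = "area") {
  features <- as.data.frame(features)
  samples <- as.data.frame(samples)
  areas <- as.matrix(areas)
  storage.mode(areas) <- "double"

  required_f <- c("feature_id", "mz", "rt_sec", "column", "polarity")
  missing_f <- setdiff(required_f, names(features))
  if (length(missing_f)) {
    stop_invalid("features table lacks column(s): %s",
                 paste(missing_f, collapse = ", "))
  }
  required_s <- c("sample_id", "dataset_id", "role")
  missing_s <- setdiff(required_s, names(samples))
  if (length(missing_s)) {
    stop_invalid("samples table lacks column(s): %s",
                 paste(missing_s, collapse = ", "))
  }
  for (opt in c("replicate_group", "organism")) {
    if (!opt %in% names(samples)) samples[[opt]] <- NA_character_
  }
  for (opt in c("vol_filtered_L", "biovolume_um3", "latitude", "depth_m")) {
    if (!opt %in% names(samples)) samples[[opt]] <- NA_real_
  }

  if (anyDuplicated(features$feature_id)) {
    dup <- unique(features$feature_id[duplicated(features$feature_id)])
    stop_invalid("duplicate feature_id(s): %s",
                 paste(utils::head(dup, 5L), collapse = ", "))
  }
  if (anyDuplicated(samples$sample_id)) {
    dup <- unique(samples$sample_id[duplicated(samples$sample_id)])
    stop_invalid("duplicate sample_id(s): %s",
                 paste(utils::head(dup, 5L), collapse = ", "))
  }
  if (!all(samples$role %in% SAMPLE_ROLES)) {
    stop_invalid("sample roles must be one of: %s",
                 paste(SAMPLE_ROLES, collapse = ", "))
  }
  if (!all(features$column %in% CHROMATOGRAPHY_COLUMNS)) {
    stop_invalid("feature column must be HILIC or RP")
  }
  if (!all(features$polarity %in% POLARITIES)) {
    stop_invalid("feature polarity must be pos or neg")
  }
  ok_mz <- is.na(features$mz) | features$mz > 0
  if (!all(ok_mz)) stop_invalid("feature mz must be > 0")
  ok_rt <- is.na(features$rt_sec) | features$rt_sec >= 0
  if (!all(ok_rt)) stop_invalid("feature rt_sec must be >= 0")

  if (nrow(areas) != nrow(features) || ncol(areas) != nrow(samples)) {
    stop_invalid(
      "areas matrix is %d x %d but there are %d features and %d samples",
      nrow(areas), ncol(areas), nrow(features), nrow(samples))
  }
  if (any(areas < 0, na.rm = TRUE)) {
    bad <- which(areas < 0, arr.ind = TRUE)
    stop_invalid("negative peak areas at %d cell(s), first at feature %s",
                 nrow(bad), features$feature_id[bad[1L, 1L]])
  }
  dimnames(areas) <- list(features$feature_id, samples$sample_id)

  if (!"is_internal_standard" %in% names(features)) {
    features$is_internal_standard <- FALSE
  }

  structure(
    list(features = features, samples = samples, areas = areas,
         units = units),
    class = "peak_table")
}

#' @export
print.peak_table <- function(x, ...) {
  cat(sprintf("<peak_table> %d features x %d samples (units: %s)\n",
              nrow(x$features), nrow(x$samples), x$units))
  roles <- table(x$samples$role)
  cat("  samples by role:",
      paste(sprintf("%s=%d", names(roles), roles), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.peak_table <- function(x) dim(x$areas)

#' Sample ids of a given role
#' @param table a [peak_table()].
#' @param role one of "sample", "pooled", "blank", "medium_blank".
#' @return character vector of sample ids.
#' @export
samples_by_role <- function(table, role) {
  stopifnot(inherits(table, "peak_table"))
  table$samples$sample_id[table$samples$role %in% role]
}

#' Subset a peak table by feature id and/or sample id
#' @param table a [peak_table()].
#' @param feature_ids,sample_ids ids to keep (NULL keeps all).
#' @return a [peak_table()].
#' @export
subset_peak_table <- function(table, feature_ids = NULL, sample_ids = NULL) {
  stopifnot(inherits(table, "peak_table"))
  fi <- feature_ids %||% table$features$feature_id
  si <- sample_ids %||% table$samples$sample_id
  missing_f <- setdiff(fi, table$features$feature_id)
  missing_s <- setdiff(si, table$samples$sample_id)
  if (length(missing_f) || length(missing_s)) {
    stop_invalid("unknown ids requested: %s",
                 paste(utils::head(c(missing_f, missing_s), 5L),
                       collapse = ", "))
  }
  peak_table(
    features = table$features[match(fi, table$features$feature_id), ,
                              drop = FALSE],
    samples = table$samples[match(si, table$samples$sample_id), ,
                            drop = FALSE],
    areas = table$areas[fi, si, drop = FALSE],
    units = table$units)
}

# ---- file I/O --------------------------------------------------------------

#' Write / read a peak-table area matrix
#'
#' The on-disk layout is a delimited text file with the feature id in the
#' first column (`feature_id`) and one column per sample; empty cells or `NA`
#' encode missing areas. Feature m/z and retention time are recovered from the
#' identifier; chromatography column and polarity are per-file properties
#' supplied at read time.
#'
#' @param table a [peak_table()].
#' @param path file path.
#' @param delim field delimiter (default comma).
#' @export
write_peak_table <- function(table, path, delim = ",") {
  stopifnot(inherits(table, "peak_table"))
  df <- data.frame(feature_id = table$features$feature_id,
                   table$areas, check.names = FALSE)
  utils::write.table(df, path, sep = delim, row.names = FALSE, qmethod = "double")
  invisible(path)
}

#' @rdname write_peak_table
#' @param samples sample metadata data.frame (or result of
#'   [read_sample_metadata()]); if `NULL`, minimal metadata with role
#'   "sample" is constructed from the header.
#' @param column,polarity chromatography column and ionization polarity of
#'   every feature in the file.
#' @return `read_peak_table` returns a [peak_table()].
#' @export
read_peak_table <- function(path, samples = NULL, column = "HILIC",
                            polarity = "pos", delim = ",") {
  if (!file.exists(path)) stop_invalid("no such file: %s", path)
  df <- utils::read.table(path, sep = delim, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1L] != "feature_id") {
    stop_invalid("first column must be `feature_id`, got `%s`", names(df)[1L])
  }
  ids <- as.character(df[[1L]])
  areas <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(areas) <- "double"
  parsed <- tryCatch(parse_feature_id(ids), error = function(e) NULL)
  features <- data.frame(
    feature_id = ids,
    mz = if (is.null(parsed)) NA_real_ else parsed$mz,
    rt_sec = if (is.null(parsed)) NA_real_ else parsed$rt_min * 60,
    column = column, polarity = polarity)
  if (is.null(samples)) {
    samples <- data.frame(sample_id = colnames(areas),
                          dataset_id = "dataset", role = "sample")
  } else {
    samples <- as.data.frame(samples)
    keep <- match(colnames(areas), samples$sample_id)
    if (anyNA(keep)) {
      stop_invalid("samples metadata lacks sample id(s): %s",
                   paste(utils::head(colnames(areas)[is.na(keep)], 5L),
                         collapse = ", "))
    }
    samples <- samples[keep, , drop = FALSE]
  }
  peak_table(features, samples, areas)
}

#' Read / write sample metadata
#'
#' Columns: `sample_id`, `dataset_id`, `role`, and optionally
#' `replicate_group`, `vol_filtered_L`, `biovolume_um3`, `latitude`,
#' `depth_m`, `organism`. For `role = "sample"` exactly one of
#' `vol_filtered_L` (environmental) or `biovolume_um3` (cultures) must be
#' present.
#'
#' @param path file path.
#' @param delim field delimiter.
#' @return data.frame of validated sample records.
#' @export
read_sample_metadata <- function(path, delim = ",") {
  if (!file.exists(path)) stop_invalid("no such file: %s", path)
  df <- utils::read.table(path, sep = delim, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  required <- c("sample_id", "dataset_id", "role")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop_invalid("sample metadata lacks column(s): %s",
                 paste(missing, collapse = ", "))
  }
  if (anyDuplicated(df$sample_id)) {
    stop_invalid("duplicate sample_id(s): %s",
                 paste(unique(df$sample_id[duplicated(df$sample_id)]),
                       collapse = ", "))
  }
  if (!all(df$role %in% SAMPLE_ROLES)) {
    stop_invalid("roles must be one of: %s", paste(SAMPLE_ROLES, collapse = ", "))
  }
  for (opt in c("vol_filtered_L", "biovolume_um3")) {
    if (!opt %in% names(df)) df[[opt]] <- NA_real_
  }
  is_sample <- df$role == "sample"
  has_vol <- !is.na(df$vol_filtered_L)
  has_bio <- !is.na(df$biovolume_um3)
  bad <- is_sample & (has_vol == has_bio) # neither or both
  if (any(bad)) {
    stop_invalid(
      "role=sample rows must carry exactly one of vol_filtered_L/biovolume_um3: %s",
      paste(utils::head(df$sample_id[bad], 5L), collapse = ", "))
  }
  df
}

#' @rdname read_sample_metadata
#' @param samples data.frame of sample records.
#' @export
write_sample_metadata <- function(samples, path, delim = ",") {
  utils::write.table(as.data.frame(samples), path, sep = delim,
                     row.names = FALSE, qmethod = "double")
  invisible(path)
}

# ---- compound library ------------------------------------------------------

MONOISOTOPIC_MASS <- c(
  C = 12, H = 1.0078250319, N = 14.0030740052, O = 15.9949146221,
  S = 31.97207069, P = 30.97376151, Na = 22.98976928, K = 38.9637064864,
  Cl = 34.968852682)

#' Parse an empirical formula
#'
#' @param formula empirical formula string, e.g. `"C7H7NO2"` (homarine).
#' @return named integer vector of element counts.
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L)
  if (!grepl("^([A-Z][a-z]?[0-9]*)+$", formula)) {
    stop_invalid("cannot parse formula: %s", formula)
  }
  m <- gregexpr("[A-Z][a-z]?[0-9]*", formula)[[1L]]
  tokens <- regmatches(formula, list(m))[[1L]]
  elements <- sub("[0-9]*$", "", tokens)
  counts <- sub("^[A-Za-z]+", "", tokens)
  counts <- ifelse(counts == "", 1L, as.integer(counts))
  tapply(counts, elements, sum)
}

#' Monoisotopic mass of an empirical formula
#' @inheritParams parse_formula
#' @return mass in Da.
#' @export
monoisotopic_mass <- function(formula) {
  counts <- parse_formula(formula)
  unknown <- setdiff(names(counts), names(MONOISOTOPIC_MASS))
  if (length(unknown)) {
    stop_invalid("no monoisotopic mass for element(s): %s",
                 paste(unknown, collapse = ", "))
  }
  sum(MONOISOTOPIC_MASS[names(counts)] * counts)
}

#' Read a compound library
#'
#' Columns: `name`, `formula`, and optionally `matched_feature_id`. Element
#' counts (C, N, S) and the monoisotopic mass are derived from the formula.
#'
#' @inheritParams read_sample_metadata
#' @return data.frame with columns name, formula, n_C, n_N, n_S,
#'   monoisotopic_mass, matched_feature_id.
#' @export
read_compound_library <- function(path, delim = ",") {
  if (!file.exists(path)) stop_invalid("no such file: %s", path)
  df <- utils::read.table(path, sep = delim, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  missing <- setdiff(c("name", "formula"), names(df))
  if (length(missing)) {
    stop_invalid("compound library lacks column(s): %s",
                 paste(missing, collapse = ", "))
  }
  if (!"matched_feature_id" %in% names(df)) df$matched_feature_id <- NA_character_
  counts <- lapply(df$formula, parse_formula)
  pick <- function(el) vapply(counts, function(x) {
    v <- x[el]
    if (is.na(v)) 0L else as.integer(v)
  }, integer(1))
  df$n_C <- pick("C")
  df$n_N <- pick("N")
  df$n_S <- pick("S")
  df$monoisotopic_mass <- vapply(df$formula, monoisotopic_mass, numeric(1))
  df
}
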