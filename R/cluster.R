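# Mode discovery: k-medoids clustering of metabolites by their abundance
# pattern across samples, with the number of modes chosen at a local
# maximum of the average silhouette width.
#
# PAM is the classic BUILD + SWAP algorithm on a full dissimilarity matrix,
# made deterministic by breaking all ties toward the lowest feature index.
# CLARA repeats PAM on random subsamples (each augmented with the best
# medoids so far) and keeps the draw whose medoids minimize total
# dissimilarity over all objects.

as_square_dissimilarity <- function(d) {
  D <- if (inherits(d, "dist")) as.matrix(d) else as.matrix(d)
  if (nrow(D) != ncol(D)) stop_invalid("dissimilarity matrix must be square")
  if (any(abs(D - t(D)) > 1e-8)) stop_invalid("dissimilarity matrix must be symmetric")
  if (any(abs(diag(D)) > 1e-12)) stop_invalid("dissimilarity diagonal must be zero")
  D
}

#' Mode partition object
#'
#' A per-dataset assignment of each feature to exactly one mode. Features
#' absent from the dataset may occupy the explicit pseudo-mode
#' `"not_observed"`.
#'
#' @param labels named character vector, feature id -> mode label.
#' @param dataset_id dataset the partition belongs to.
#' @param medoids feature ids of the mode medoids (optional).
#' @param k number of modes (excluding the pseudo-mode).
#' @param avg_silhouette average silhouette width (optional).
#' @param objective total dissimilarity to nearest medoid (optional).
#' @return object of class `mode_partition`.
#' @export
mode_partition <- function(labels, dataset_id = "dataset", medoids = NULL,
                           k = length(setdiff(unique(labels), "not_observed")),
                           avg_silhouette = NA_real_, objective = NA_real_) {
  if (is.null(names(labels))) stop_invalid("labels must be named by feature id")
  structure(list(labels = stats::setNames(as.character(labels), names(labels)),
                 dataset_id = dataset_id, medoids = medoids, k = k,
                 avg_silhouette = avg_silhouette, objective = objective),
            class = "mode_partition")
}

#' @export
print.mode_partition <- function(x, ...) {
  sizes <- sort(table(x$labels), decreasing = TRUE)
  cat(sprintf("<mode_partition> %s: %d features in %d modes (avg sil %.3f)\n",
              x$dataset_id, length(x$labels), length(sizes),
              x$avg_silhouette))
  print(sizes)
  invisible(x)
}

partition_labels <- function(x) {
  if (inherits(x, "mode_partition")) x$labels
  else if (is.character(x) && !is.null(names(x))) x
  else stop_invalid("expected a mode_partition or a named character vector")
}

#' PAM k-medoids clustering on a dissimilarity matrix
#'
#' BUILD phase: start from the object minimizing total dissimilarity, then
#' greedily add the object with the largest cost reduction. SWAP phase:
#' repeatedly apply the single medoid/non-medoid exchange with the largest
#' cost decrease until no exchange improves the objective. Because steepest
#' descent over single exchanges can stall in a local optimum, the SWAP
#' phase is additionally run from `n_starts - 1` deterministic
#' farthest-first starting sets (seeded at successive objects) and the best
#' final objective is kept. All ties break toward the lowest object index,
#' so the result is deterministic.
#'
#' @param d square symmetric dissimilarity matrix (or `dist`).
#' @param k number of clusters, `2 <= k < n`.
#' @param max_iter cap on SWAP iterations per start.
#' @param n_starts number of starting medoid sets (1 = BUILD only).
#' @param dataset_id label stored in the partition.
#' @return a [mode_partition()] with integer mode labels `"1" ... "k"`
#'   (ordered by medoid index), plus `medoids` and the final `objective`.
#' @export
pam_cluster <- function(d, k, max_iter = 200L, n_starts = 8L,
                        dataset_id = "dataset") {
  D <- as_square_dissimilarity(d)
  n <- nrow(D)
  if (k < 2L || k >= n) stop_invalid("need 2 <= k < n (k=%d, n=%d)", k, n)
  ids <- rownames(D) %||% as.character(seq_len(n))

  build_start <- function() {
    med <- which.min(colSums(D))
    while (length(med) < k) {
      d1 <- do.call(pmin, lapply(med, function(m) D[, m]))
      gains <- rep(-Inf, n)
      for (h in setdiff(seq_len(n), med)) {
        gains[h] <- sum(pmax(d1 - D[, h], 0))
      }
      med <- c(med, which.max(gains))
    }
    sort(med)
  }
  farthest_first <- function(seed_obj) {
    med <- seed_obj
    while (length(med) < k) {
      d1 <- do.call(pmin, lapply(med, function(m) D[, m]))
      d1[med] <- -Inf
      med <- c(med, which.max(d1))
    }
    sort(med)
  }
  swap_phase <- function(med) {
    for (iter in seq_len(max_iter)) {
      Dm <- D[, med, drop = FALSE]
      n1 <- max.col(-Dm, ties.method = "first")
      d1 <- Dm[cbind(seq_len(n), n1)]
      Dm2 <- Dm
      Dm2[cbind(seq_len(n), n1)] <- Inf
      d2 <- Dm2[cbind(seq_len(n), max.col(-Dm2, ties.method = "first"))]
      cand <- setdiff(seq_len(n), med)
      A <- D[, cand, drop = FALSE]
      base <- pmin(A - d1, 0)
      best_delta <- -1e-12
      best_mi <- NA_integer_
      best_h <- NA_integer_
      for (mi in seq_along(med)) {
        contrib <- base
        rows <- which(n1 == mi)
        if (length(rows)) {
          contrib[rows, ] <- pmin(A[rows, , drop = FALSE], d2[rows]) - d1[rows]
        }
        deltas <- colSums(contrib)
        j <- which.min(deltas)
        if (deltas[j] < best_delta) {
          best_delta <- deltas[j]
          best_mi <- mi
          best_h <- cand[j]
        }
      }
      if (is.na(best_mi)) break
      med[best_mi] <- best_h
      med <- sort(med)
    }
    med
  }
  objective_of <- function(med) {
    sum(apply(D[, med, drop = FALSE], 1L, min))
  }

  starts <- c(list(build_start()),
              lapply(seq_len(max(0L, min(n, n_starts) - 1L)), farthest_first))
  best_med <- NULL
  best_obj <- Inf
  for (st in starts) {
    med <- swap_phase(st)
    obj <- objective_of(med)
    if (obj < best_obj - 1e-12) {
      best_obj <- obj
      best_med <- med
    }
  }
  med <- best_med

  Dm <- D[, med, drop = FALSE]
  n1 <- max.col(-Dm, ties.method = "first")
  objective <- sum(Dm[cbind(seq_len(n), n1)])
  labels <- stats::setNames(as.character(n1), ids)
  sil <- silhouette_widths(D, n1)
  mode_partition(labels, dataset_id = dataset_id, medoids = ids[med], k = k,
                 avg_silhouette = mean(sil), objective = objective)
}

#' CLARA k-medoids clustering for larger data
#'
#' Repeats PAM on random subsamples of the rows (each augmented to include
#' the best medoids found so far), assigns every row to its nearest medoid
#' by Euclidean distance, and keeps the draw minimizing the total
#' dissimilarity. With `draw_size >= n` this reduces exactly to PAM on the
#' full data.
#'
#' @param data numeric matrix; rows are the objects to cluster (features),
#'   columns the samples.
#' @param k number of clusters.
#' @param n_draws number of subsample draws.
#' @param draw_size subsample size; default `min(n, 40 + 2k)`. Values above
#'   `n` are clamped with a warning.
#' @param seed RNG seed.
#' @param dataset_id label stored in the partition.
#' @return a [mode_partition()].
#' @export
clara_cluster <- function(data, k, n_draws = 5, draw_size = NULL, seed = 1,
                          dataset_id = "dataset") {
  data <- as.matrix(data)
  n <- nrow(data)
  ids <- rownames(data) %||% as.character(seq_len(n))
  draw_size <- draw_size %||% min(n, 40 + 2 * k)
  if (draw_size > n) {
    warning(sprintf("draw_size %d > n %d; clamped", draw_size, n))
    draw_size <- n
  }
  if (draw_size < k + 1L) stop_invalid("draw_size must exceed k")
  with_seed(seed, {
    best <- NULL
    for (t in seq_len(n_draws)) {
      if (draw_size >= n) {
        sub <- seq_len(n)
      } else {
        keep <- if (is.null(best)) integer(0) else best$med
        pool <- setdiff(seq_len(n), keep)
        sub <- sort(c(keep, sample(pool, draw_size - length(keep))))
      }
      p <- pam_cluster(as.matrix(stats::dist(data[sub, , drop = FALSE])), k)
      med <- sub[match(p$medoids, as.character(seq_along(sub)))]
      # rownames of the subsample distance are original row names when set
      if (!is.null(rownames(data))) med <- sub[match(p$medoids, ids[sub])]
      cross <- vapply(med, function(m) {
        sqrt(rowSums(sweep(data, 2, data[m, ], `-`)^2))
      }, numeric(n))
      n1 <- max.col(-cross, ties.method = "first")
      obj <- sum(cross[cbind(seq_len(n), n1)])
      if (is.null(best) || obj < best$obj) {
        best <- list(med = med, obj = obj, n1 = n1)
      }
    }
    ord <- order(best$med)
    relabel <- match(seq_along(best$med), ord)
    labels <- stats::setNames(as.character(relabel[best$n1]), ids)
    D <- as.matrix(stats::dist(data))
    sil <- silhouette_widths(D, relabel[best$n1])
    mode_partition(labels, dataset_id = dataset_id,
                   medoids = ids[best$med[ord]], k = k,
                   avg_silhouette = mean(sil), objective = best$obj)
  })
}

#' Silhouette widths
#'
#' Standard silhouette: `s_i = (b_i - a_i) / max(a_i, b_i)` with `a_i` the
#' mean dissimilarity to the own cluster and `b_i` the smallest mean
#' dissimilarity to another cluster. Members of singleton clusters get 0.
#'
#' @param d square dissimilarity matrix (or `dist`).
#' @param labels cluster labels, one per object.
#' @return numeric vector of silhouette widths in `[-1, 1]`.
#' @export
silhouette_widths <- function(d, labels) {
  D <- as_square_dissimilarity(d)
  n <- nrow(D)
  labels <- as.character(labels)
  stopifnot(length(labels) == n)
  groups <- split(seq_len(n), labels)
  sizes <- lengths(groups)
  # mean dissimilarity of each object to each cluster
  M <- vapply(groups, function(idx) {
    rowSums(D[, idx, drop = FALSE])
  }, numeric(n))
  s <- numeric(n)
  for (i in seq_len(n)) {
    g <- labels[i]
    ng <- sizes[[g]]
    if (ng <= 1L) { s[i] <- 0; next }
    a <- M[i, g] / (ng - 1L)
    others <- setdiff(names(groups), g)
    b <- min(M[i, others] / sizes[others])
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  s
}

#' Select the number of modes at a local silhouette maximum
#'
#' Computes the average silhouette width for each candidate `k` and returns
#' the local maximum of the curve (`s(k) > s(k-1)` and `s(k) > s(k+1)`;
#' endpoints compared one-sided) with the highest average silhouette width,
#' so a minor early bump cannot shadow the dominant structure; ties go to
#' the smallest `k`. When the curve is monotone over the whole range the
#' boundary `k` is returned with a warning; a flat curve falls back to the
#' argmax with a warning.
#'
#' @param data numeric matrix, rows are objects.
#' @param k_min,k_max candidate range.
#' @param n_draws,draw_size CLARA parameters (see [clara_cluster()]).
#' @param seed RNG seed.
#' @return list with `k`, `silhouette` (named vector of the full curve) and
#'   `partitions` (one [mode_partition()] per candidate `k`).
#' @export
select_k_silhouette <- function(data, k_min = 2, k_max = 8, n_draws = 5,
                                draw_size = NULL, seed = 1) {
  data <- as.matrix(data)
  if (k_max >= nrow(data)) stop_invalid("k_max must be < number of objects")
  if (k_min < 2 || k_min > k_max) stop_invalid("need 2 <= k_min <= k_max")
  ks <- k_min:k_max
  parts <- lapply(ks, function(k) {
    clara_cluster(data, k, n_draws = n_draws, draw_size = draw_size,
                  seed = child_seed(seed, k))
  })
  s <- vapply(parts, function(p) p$avg_silhouette, numeric(1))
  names(s) <- ks
  names(parts) <- ks
  is_max <- vapply(seq_along(ks), function(i) {
    left <- i == 1L || s[i] > s[i - 1L]
    right <- i == length(ks) || s[i] > s[i + 1L]
    left && right
  }, logical(1))
  interior <- is_max & seq_along(ks) > 1L & seq_along(ks) < length(ks)
  if (any(is_max)) {
    cand_idx <- which(is_max)
    pick <- cand_idx[which.max(s[cand_idx])]
    if (!any(interior) && (pick == 1L || pick == length(ks))) {
      warning("no interior silhouette maximum; boundary k selected")
    }
  } else {
    pick <- which.max(s)
    warning("silhouette curve has no local maximum; returning argmax")
  }
  list(k = ks[pick], silhouette = s, partitions = parts)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same objects;
#' 1 means identical partitions, 0 the expected agreement of independent
#' ones.
#'
#' @param a,b label vectors of equal length (or named vectors; matched by
#'   name when both are named).
#' @return adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    common <- intersect(names(a), names(b))
    a <- a[common]
    b <- b[common]
  }
  stopifnot(length(a) == length(b), length(a) > 0)
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

#' Discover metabolite modes in a dataset
#'
#' Standardizes the peak table (total-peak-area fractions for environmental
#' sample sets, log10/max for cultures), assigns features that were never
#' detected in the dataset to the `"not_observed"` pseudo-mode, clusters the
#' remaining features with CLARA (auto-selecting `k` at a local silhouette
#' maximum unless `k` is given), and names modes by decreasing size
#' (`"a"` largest, as is conventional for mode panels).
#'
#' @param table a [peak_table()], already normalized as appropriate.
#' @param mode `"environmental"` (total-standardization) or `"culture"`
#'   (log10/max standardization; missing rendered 0 for distances).
#' @param k number of modes, or `NULL` to auto-select.
#' @param k_min,k_max candidate range for auto-selection.
#' @param n_draws,draw_size CLARA parameters.
#' @param dataset_id label stored in the partition; default the table's
#'   dataset id.
#' @param seed RNG seed.
#' @return a [mode_partition()] covering every feature of the table
#'   (internal standards excluded).
#' @export
discover_modes <- function(table, mode = c("environmental", "culture"),
                           k = NULL, k_min = 2, k_max = 8, n_draws = 5,
                           draw_size = NULL, dataset_id = NULL, seed = 1) {
  stopifnot(inherits(table, "peak_table"))
  mode <- match.arg(mode)
  dataset_id <- dataset_id %||% table$samples$dataset_id[1L]
  keep <- !table$features$is_internal_standard
  tab <- subset_peak_table(table, table$features$feature_id[keep])
  sample_ids <- samples_by_role(tab, "sample")
  raw <- tab$areas[, sample_ids, drop = FALSE]
  observed <- rowSums(!is.na(raw) & raw > 0) > 0
  obs_tab <- subset_peak_table(tab, rownames(raw)[observed])
  X <- if (mode == "environmental") standardize_to_total(obs_tab)
       else {
         m <- standardize_culture(obs_tab)
         m[is.na(m)] <- 0
         m
       }
  part <- if (is.null(k)) {
    sel <- select_k_silhouette(X, k_min = k_min, k_max = k_max,
                               n_draws = n_draws, draw_size = draw_size,
                               seed = seed)
    sel$partitions[[as.character(sel$k)]]
  } else {
    clara_cluster(X, k, n_draws = n_draws, draw_size = draw_size, seed = seed)
  }
  # rename modes by decreasing size: a, b, c, ...
  sizes <- sort(table(part$labels), decreasing = TRUE)
  new_names <- if (length(sizes) <= 26) letters[seq_along(sizes)]
               else sprintf("m%02d", seq_along(sizes))
  map <- stats::setNames(new_names, names(sizes))
  labels <- stats::setNames(map[part$labels], names(part$labels))
  not_obs <- rownames(raw)[!observed]
  labels <- c(labels, stats::setNames(rep("not_observed", length(not_obs)),
                                      not_obs))
  labels <- labels[tab$features$feature_id]
  medoids <- stats::setNames(part$medoids, map[as.character(
    seq_along(part$medoids))])
  mode_partition(labels, dataset_id = dataset_id, medoids = medoids,
                 k = part$k, avg_silhouette = part$avg_silhouette,
                 objective = part$objective)
}
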