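# Nonmetric ordination and rank-based group testing.
#
# NMDS is delegated to vegan (Kruskal stress-1 via monotone regression with
# multiple random starts); ANOSIM is computed directly from rank
# dissimilarities, with exact enumeration of all label permutations for
# small sample sets and seeded Monte Carlo permutations otherwise.

#' Nonmetric multidimensional scaling
#'
#' Kruskal NMDS on a dissimilarity matrix, minimizing stress-1, best of
#' several random starts (via [vegan::metaMDS()]).
#'
#' @param d dissimilarity matrix or `dist`.
#' @param ndim number of ordination dimensions.
#' @param n_starts maximum number of random starts.
#' @param seed RNG seed.
#' @return object of class `ordination_result`: list with `points`
#'   (centered sample coordinates), `stress` (in `[0, 1]`), `converged`
#'   and `seed`.
#' @export
nmds <- function(d, ndim = 2, n_starts = 20, seed = 1) {
  D <- as_square_dissimilarity(d)
  if (ndim >= nrow(D)) stop_invalid("ndim must be < number of samples")
  fit <- with_seed(seed, {
    vegan::metaMDS(stats::as.dist(D), k = ndim, trymax = n_starts,
                   trace = 0, autotransform = FALSE, wascores = FALSE)
  })
  pts <- scale(fit$points, center = TRUE, scale = FALSE)
  structure(list(points = pts, stress = fit$stress,
                 converged = isTRUE(fit$converged > 0) || isTRUE(fit$converged),
                 seed = seed),
            class = "ordination_result")
}

#' @export
print.ordination_result <- function(x, ...) {
  cat(sprintf("<ordination_result> %d samples, %d dims, stress %.4f (%s)\n",
              nrow(x$points), ncol(x$points), x$stress,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

# all permutations of 1..n as a matrix (n! rows); n is expected to be small
all_permutations <- function(n) {
  P <- matrix(1L, 1L, 1L)
  for (m in 2:n) {
    blocks <- lapply(seq_len(m), function(pos) {
      left <- if (pos > 1L) P[, seq_len(pos - 1L), drop = FALSE] else NULL
      right <- if (pos <= m - 1L) P[, pos:(m - 1L), drop = FALSE] else NULL
      cbind(left, m, right)
    })
    P <- do.call(rbind, blocks)
  }
  P
}

#' Analysis of similarities (ANOSIM)
#'
#' `R = (mean between-group rank - mean within-group rank) / (M/2)` with
#' `M = n(n-1)/2` ranked dissimilarities. The p-value is obtained by
#' permuting group labels: exact enumeration of all `n!` permutations when
#' `n <= exact_max` (then `p = #(R_perm >= R_obs) / n!`, the identity
#' included), otherwise `n_perm` seeded random permutations with the +1
#' correction `p = (1 + #(R_perm >= R_obs)) / (1 + n_perm)`.
#'
#' @param d dissimilarity matrix or `dist`.
#' @param groups group labels, one per sample; >= 2 groups with >= 2
#'   members each.
#' @param n_perm number of Monte Carlo permutations.
#' @param seed RNG seed (Monte Carlo only).
#' @param exact_max largest n for which the null is fully enumerated.
#' @return object of class `anosim_result`: list with `R`, `p`, `n_perm`
#'   (permutations actually used), `exact` and `seed`.
#' @export
anosim <- function(d, groups, n_perm = 999, seed = 1, exact_max = 8) {
  D <- as_square_dissimilarity(d)
  n <- nrow(D)
  groups <- as.character(groups)
  stopifnot(length(groups) == n)
  sizes <- table(groups)
  if (length(sizes) < 2L || any(sizes < 2L)) {
    stop_invalid("ANOSIM needs >= 2 groups with >= 2 members each")
  }
  if (n_perm < 1) stop_invalid("n_perm must be >= 1")
  pair <- which(upper.tri(D), arr.ind = TRUE)
  r <- rank(D[upper.tri(D)])
  M <- length(r)
  R_of <- function(g) {
    within <- g[pair[, 1L]] == g[pair[, 2L]]
    (mean(r[!within]) - mean(r[within])) / (M / 2)
  }
  R_obs <- R_of(groups)
  if (n <= exact_max) {
    P <- all_permutations(n)
    R_null <- apply(P, 1L, function(idx) R_of(groups[idx]))
    p <- mean(R_null >= R_obs - 1e-12)
    res <- list(R = R_obs, p = p, n_perm = nrow(P), exact = TRUE, seed = NULL)
  } else {
    count <- with_seed(seed, {
      sum(vapply(seq_len(n_perm), function(i) {
        R_of(groups[sample.int(n)]) >= R_obs - 1e-12
      }, logical(1)))
    })
    p <- (1 + count) / (1 + n_perm)
    res <- list(R = R_obs, p = p, n_perm = n_perm, exact = FALSE, seed = seed)
  }
  structure(res, class = "anosim_result")
}

#' @export
print.anosim_result <- function(x, ...) {
  cat(sprintf("<anosim_result> R = %.3f, p = %.4g (%s, %d permutations)\n",
              x$R, x$p, if (x$exact) "exact" else "Monte Carlo", x$n_perm))
  invisible(x)
}
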