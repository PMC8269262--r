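# Cross-dataset mode-overlap enrichment and metacluster assembly.
#
# Two mode partitions over the same metabolite universe are compared by the
# number of metabolites each pair of modes shares. A Monte Carlo null is
# generated by uniformly permuting one partition's label vector (mode sizes
# preserved), recomputing all shared counts each draw; the per-pair p-value
# uses the +1 correction so it is never exactly zero. Modes of different
# datasets whose overlap is enriched at p < alpha become edges of a
# network; connected components rooted in a culture-derived mode become
# metaclusters.

#' Observed shared-metabolite counts between two partitions
#'
#' @param partition_a,partition_b [mode_partition()]s (or named label
#'   vectors) over the same feature universe. Features absent from one
#'   dataset occupy its `"not_observed"` pseudo-mode.
#' @return integer matrix of counts, modes of `a` in rows, modes of `b` in
#'   columns; entries sum to the universe size.
#' @export
observed_shared <- function(partition_a, partition_b) {
  la <- partition_labels(partition_a)
  lb <- partition_labels(partition_b)
  extra_a <- setdiff(names(la), names(lb))
  extra_b <- setdiff(names(lb), names(la))
  if (length(extra_a) || length(extra_b)) {
    stop_invalid(
      "partitions cover different universes; only in a: %s; only in b: %s",
      paste(utils::head(extra_a, 3L), collapse = ","),
      paste(utils::head(extra_b, 3L), collapse = ","))
  }
  lb <- lb[names(la)]
  unclass(table(factor(la), factor(lb)))
}

#' Permutation enrichment of shared metabolites between modes
#'
#' For every pair of modes (one from each partition), tests whether the
#' observed number of shared metabolites exceeds what random assignment
#' would give. The null permutes `partition_b`'s label vector uniformly
#' across the universe (`n_perm` draws), recomputing all pairwise shared
#' counts each draw; `p = (1 + #(shared_perm >= shared_obs)) / (1 + n_perm)`.
#'
#' @inheritParams observed_shared
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @return object of class `enrichment_result`: list with matrices
#'   `shared` (observed counts) and `p` (per mode pair), plus `n_perm` and
#'   `seed`.
#' @export
permutation_enrichment <- function(partition_a, partition_b, n_perm = 1000,
                                   seed = 1) {
  if (n_perm < 1) stop_invalid("n_perm must be >= 1")
  obs <- observed_shared(partition_a, partition_b)
  la <- partition_labels(partition_a)
  lb <- partition_labels(partition_b)[names(la)]
  fa <- factor(la)
  fb <- factor(lb)
  ia <- as.integer(fa)
  ib <- as.integer(fb)
  na <- nlevels(fa)
  nb <- nlevels(fb)
  n <- length(ia)
  obs_vec <- as.vector(obs)
  geq <- integer(na * nb)
  with_seed(seed, {
    for (t in seq_len(n_perm)) {
      cnt <- tabulate((ib[sample.int(n)] - 1L) * na + ia, na * nb)
      geq <- geq + (cnt >= obs_vec)
    }
  })
  p <- matrix((1 + geq) / (1 + n_perm), na, nb,
              dimnames = dimnames(obs))
  structure(list(shared = obs, p = p, n_perm = n_perm, seed = seed),
            class = "enrichment_result")
}

#' Build the mode-overlap enrichment network
#'
#' Tests every cross-dataset pair of modes over all pairwise dataset
#' combinations. Nodes are modes with at least `min_mode_size` metabolites
#' (the `"not_observed"` pseudo-mode included when `include_not_observed`);
#' edges connect mode pairs enriched at `p < alpha` (no multiple-testing
#' correction, matching the reporting convention of raw P < 0.05 networks).
#'
#' @param partitions named list of [mode_partition()]s, one per dataset,
#'   all over the same feature universe.
#' @param alpha edge significance level.
#' @param min_mode_size smallest mode kept as a node.
#' @param n_perm permutations per dataset pair.
#' @param include_not_observed should the `"not_observed"` pseudo-mode take
#'   part in the permutation universe and the network?
#' @param seed RNG seed.
#' @return object of class `enrichment_network`: list with `nodes`
#'   (data.frame dataset, mode, size), `edges` (data.frame dataset_a,
#'   mode_a, dataset_b, mode_b, shared, p) and `graph` (igraph object whose
#'   vertex names are `"dataset::mode"`).
#' @export
build_network <- function(partitions, alpha = 0.05, min_mode_size = 10,
                          n_perm = 1000, include_not_observed = TRUE,
                          seed = 1) {
  stopifnot(is.list(partitions), length(partitions) >= 2L)
  if (is.null(names(partitions))) {
    names(partitions) <- vapply(partitions, function(p) p$dataset_id,
                                character(1))
  }
  labels <- lapply(partitions, partition_labels)

  nodes <- do.call(rbind, lapply(names(labels), function(ds) {
    tab <- table(labels[[ds]])
    data.frame(dataset = ds, mode = names(tab), size = as.integer(tab))
  }))
  if (!include_not_observed) nodes <- nodes[nodes$mode != "not_observed", ]
  nodes <- nodes[nodes$size >= min_mode_size, ]
  rownames(nodes) <- NULL

  pairs <- utils::combn(names(labels), 2L, simplify = FALSE)
  edges <- list()
  for (pr in pairs) {
    la <- labels[[pr[1L]]]
    lb <- labels[[pr[2L]]]
    if (!include_not_observed) {
      keep <- names(la)[la != "not_observed" &
                          lb[names(la)] != "not_observed"]
      la <- la[keep]
      lb <- lb[keep]
    }
    enr <- permutation_enrichment(la, lb, n_perm = n_perm,
                                  seed = child_seed(seed, match(pr[2L], names(labels)) +
                                                      10L * match(pr[1L], names(labels))))
    hit <- which(enr$p < alpha, arr.ind = TRUE)
    if (nrow(hit)) {
      edges[[paste(pr, collapse = "|")]] <- data.frame(
        dataset_a = pr[1L], mode_a = rownames(enr$p)[hit[, 1L]],
        dataset_b = pr[2L], mode_b = colnames(enr$p)[hit[, 2L]],
        shared = enr$shared[hit], p = enr$p[hit])
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges)
           else data.frame(dataset_a = character(0), mode_a = character(0),
                           dataset_b = character(0), mode_b = character(0),
                           shared = integer(0), p = numeric(0))
  rownames(edges) <- NULL
  # restrict edges to retained nodes
  node_key <- paste(nodes$dataset, nodes$mode, sep = "::")
  key_a <- paste(edges$dataset_a, edges$mode_a, sep = "::")
  key_b <- paste(edges$dataset_b, edges$mode_b, sep = "::")
  keep <- key_a %in% node_key & key_b %in% node_key
  edges <- edges[keep, , drop = FALSE]

  g <- igraph::graph_from_data_frame(
    data.frame(from = key_a[keep], to = key_b[keep]),
    directed = FALSE,
    vertices = data.frame(name = node_key, dataset = nodes$dataset,
                          mode = nodes$mode, size = nodes$size))
  structure(list(nodes = nodes, edges = edges, graph = g, alpha = alpha,
                 min_mode_size = min_mode_size),
            class = "enrichment_network")
}

#' @export
print.enrichment_network <- function(x, ...) {
  cat(sprintf("<enrichment_network> %d nodes, %d edges (alpha %.3g, min mode size %d)\n",
              nrow(x$nodes), nrow(x$edges), x$alpha, x$min_mode_size))
  invisible(x)
}

#' Assign metaclusters from the enrichment network
#'
#' A metacluster is a connected component of the network rooted in a
#' culture-dataset mode. A metabolite is a member when it belongs to the
#' rooting culture mode and to at least `min_env_modes` of the component's
#' environmental modes. Components containing several culture modes are
#' split, one metacluster per root; components with no culture mode are
#' reported as unrooted and yield no metacluster.
#'
#' @param network an [build_network()] result.
#' @param partitions the named list of partitions the network was built
#'   from.
#' @param culture_dataset_id name of the culture dataset.
#' @param min_env_modes minimum number of environmental member modes a
#'   metabolite must belong to.
#' @return list with `metaclusters` (each: name, root, member_modes,
#'   compounds) and `unrooted` (list of components without a culture mode).
#' @export
assign_metaclusters <- function(network, partitions,
                                culture_dataset_id = "cultures",
                                min_env_modes = 2) {
  stopifnot(inherits(network, "enrichment_network"))
  if (is.null(names(partitions))) {
    names(partitions) <- vapply(partitions, function(p) p$dataset_id,
                                character(1))
  }
  if (!culture_dataset_id %in% names(partitions)) {
    stop_invalid("no partition named %s", culture_dataset_id)
  }
  labels <- lapply(partitions, partition_labels)
  comp <- igraph::components(network$graph)
  membership <- split(names(comp$membership), comp$membership)

  metaclusters <- list()
  unrooted <- list()
  for (nodes in membership) {
    ds <- sub("::.*$", "", nodes)
    md <- sub("^.*::", "", nodes)
    roots <- which(ds == culture_dataset_id)
    if (!length(roots)) {
      if (length(nodes) > 1L) unrooted <- c(unrooted, list(nodes))
      next
    }
    env_nodes <- nodes[ds != culture_dataset_id]
    env_ds <- ds[ds != culture_dataset_id]
    env_md <- md[ds != culture_dataset_id]
    for (ri in roots) {
      root_mode <- md[ri]
      in_root <- names(labels[[culture_dataset_id]])[
        labels[[culture_dataset_id]] == root_mode]
      if (length(env_nodes)) {
        n_env <- rowSums(vapply(seq_along(env_nodes), function(j) {
          labels[[env_ds[j]]][in_root] == env_md[j]
        }, logical(length(in_root))))
      } else {
        n_env <- rep(0L, length(in_root))
      }
      compounds <- in_root[n_env >= min_env_modes]
      metaclusters[[length(metaclusters) + 1L]] <- list(
        name = sprintf("%s::%s", culture_dataset_id, root_mode),
        root = nodes[ri], member_modes = nodes, compounds = compounds)
    }
  }
  list(metaclusters = metaclusters, unrooted = unrooted)
}
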