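# Shared fixture builders. Everything is generated in code; no data files.

# A tiny hand-written peak table: 3 features x (4 samples + 2 pooled + 1 blank)
toy_peak_table <- function() {
  features <- data.frame(
    feature_id = c("I100.0000R1.0", "I200.0000R2.0", "I300.0000R3.0"),
    mz = c(100, 200, 300), rt_sec = c(60, 120, 180),
    column = "HILIC", polarity = "pos")
  samples <- data.frame(
    sample_id = c("s1", "s2", "s3", "s4", "p1", "p2", "b1"),
    dataset_id = "toy",
    role = c(rep("sample", 4), "pooled", "pooled", "blank"),
    replicate_group = c("g1", "g1", "g2", "g2", NA, NA, NA),
    vol_filtered_L = c(10, 10, 5, 5, NA, NA, NA))
  areas <- matrix(c(
    100, 110, 120, 130, 115, 116, 10,
    200, 210, 220, 230, 215, 216, 20,
    NA,  310, 320, 330, 315, 316, 30), 3, 7, byrow = TRUE)
  peak_table(features, samples, areas)
}

# named label vector helper
labelled <- function(labels, ids) stats::setNames(labels, ids)

# a peak table holding features at given mz/rt (seconds), one sample column
feature_only_table <- function(mz, rt_sec, mean_area = NULL, column = "HILIC",
                               polarity = "pos") {
  n <- length(mz)
  mean_area <- mean_area %||% rep(1000, n)
  features <- data.frame(
    feature_id = make_feature_id(mz, rt_sec / 60),
    mz = mz, rt_sec = rt_sec, column = column, polarity = polarity)
  samples <- data.frame(sample_id = c("s1", "s2"), dataset_id = "toy",
                        role = "sample", vol_filtered_L = 1)
  areas <- cbind(mean_area, mean_area)
  colnames(areas) <- samples$sample_id
  peak_table(features, samples, areas)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# hand-built enrichment network from explicit nodes and edges
manual_network <- function(nodes, edges, alpha = 0.05, min_mode_size = 1) {
  key <- paste(nodes$dataset, nodes$mode, sep = "::")
  g <- igraph::graph_from_data_frame(
    data.frame(from = paste(edges$dataset_a, edges$mode_a, sep = "::"),
               to = paste(edges$dataset_b, edges$mode_b, sep = "::")),
    directed = FALSE,
    vertices = data.frame(name = key, dataset = nodes$dataset,
                          mode = nodes$mode, size = nodes$size))
  structure(list(nodes = nodes, edges = edges, graph = g, alpha = alpha,
                 min_mode_size = min_mode_size),
            class = "enrichment_network")
}

# independent ANOSIM R: direct formula on rank dissimilarities
oracle_anosim_R <- function(D, groups) {
  dv <- D[upper.tri(D)]
  r <- rank(dv)
  pair <- which(upper.tri(D), arr.ind = TRUE)
  within <- groups[pair[, 1]] == groups[pair[, 2]]
  (mean(r[!within]) - mean(r[within])) / (length(r) / 2)
}
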