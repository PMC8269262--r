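test_that("observed shared counts form a contingency matrix over the universe", {
  ids <- sprintf("f%02d", 1:20)
  a <- labelled(rep(c("A", "B"), each = 10), ids)
  b <- labelled(rep(c("X", "Y"), each = 10), ids)
  m <- observed_shared(a, b)
  expect_equal(m["A", "X"], 10)
  expect_equal(m["B", "Y"], 10)
  expect_equal(sum(m), 20)
  # identical partitions give a diagonal of mode sizes
  m2 <- observed_shared(a, a)
  expect_equal(unname(diag(m2)), c(10, 10))
  expect_equal(sum(m2) - sum(diag(m2)), 0)
  # marginals are conserved whatever the second labeling
  b3 <- labelled(sample(rep(c("X", "Y", "Z"), c(5, 5, 10))), ids)
  expect_equal(unname(rowSums(observed_shared(a, b3))), c(10, 10))
  # mismatched universes error with the difference listed
  expect_error(observed_shared(a, b[1:15]), "universes")
})

test_that("permutation p-values converge to the hypergeometric tail", {
  ids <- sprintf("f%02d", 1:20)
  a <- labelled(rep(c("A", "B"), each = 10), ids)
  b <- labelled(rep("Y", 20), ids)
  b[c(ids[1:8], ids[11:12])] <- "X" # overlap with A = 8
  enr <- permutation_enrichment(a, b, n_perm = 4000, seed = 7)
  exact <- phyper(7, 10, 10, 10, lower.tail = FALSE)
  mc_se <- sqrt(exact * (1 - exact) / 4000)
  expect_lt(abs(enr$p["A", "X"] - exact), 2 * mc_se + 1 / 4001)
  # determinism
  enr2 <- permutation_enrichment(a, b, n_perm = 4000, seed = 7)
  expect_identical(enr$p, enr2$p)
  expect_error(permutation_enrichment(a, b, n_perm = 0), "n_perm")
})

test_that("p-values respect the +1 floor at maximal overlap", {
  ids <- sprintf("f%02d", 1:30)
  a <- labelled(rep(c("A", "B", "C"), each = 10), ids)
  enr <- permutation_enrichment(a, a, n_perm = 500, seed = 8)
  expect_gte(min(enr$p), 1 / 501)
  expect_equal(unname(diag(enr$p) < 0.05), rep(TRUE, 3))
})

test_that("network construction applies alpha and the minimum mode size", {
  ids <- sprintf("f%02d", 1:40)
  a <- mode_partition(labelled(rep(c("a", "b"), each = 20), ids), "ds1")
  b <- mode_partition(labelled(rep(c("a", "b"), each = 20), ids), "ds2")
  net <- build_network(list(ds1 = a, ds2 = b), n_perm = 300, seed = 9)
  # identical partitions: perfect matching of corresponding modes
  expect_equal(nrow(net$edges), 2)
  expect_identical(sort(paste(net$edges$mode_a, net$edges$mode_b)),
                   c("a a", "b b"))
  # a mode under the size threshold is not a node
  small <- mode_partition(
    labelled(rep(c("a", "b", "c"), c(9, 20, 11)), ids), "ds3")
  net2 <- build_network(list(ds1 = a, ds3 = small), n_perm = 300,
                        min_mode_size = 10, seed = 9)
  expect_false(any(net2$nodes$dataset == "ds3" & net2$nodes$mode == "a"))
})

test_that("independent partitions produce edges at roughly the alpha rate", {
  ids <- sprintf("f%03d", 1:300)
  sizes <- c(60, 60, 60, 60, 60)
  hits <- 0
  pairs <- 0
  for (r in 1:25) {
    set.seed(100 + r)
    a <- labelled(sample(rep(paste0("a", 1:5), sizes)), ids)
    b <- labelled(sample(rep(paste0("b", 1:5), sizes)), ids)
    enr <- permutation_enrichment(a, b, n_perm = 400, seed = 200 + r)
    hits <- hits + sum(enr$p < 0.05)
    pairs <- pairs + length(enr$p)
  }
  expect_gt(hits / pairs, 0.01)
  expect_lt(hits / pairs, 0.09)
})

test_that("metacluster membership follows the two-condition rule", {
  # toy: culture mode C-a rooted to env modes T-a, Z-a, G-a
  ids <- sprintf("c%02d", 1:12)
  cultures <- mode_partition(labelled(
    c(rep("a", 6), rep("b", 6)), ids), "cultures")
  transect <- mode_partition(labelled(
    c(rep("a", 8), rep("b", 4)), ids), "transect")
  npsg <- mode_partition(labelled(
    c(rep("a", 4), rep("b", 8)), ids), "npsg")
  nptz <- mode_partition(labelled(
    c("a", "a", "b", "b", "a", "a", rep("b", 6)), ids), "nptz")
  nodes <- data.frame(
    dataset = c("cultures", "transect", "npsg", "nptz"),
    mode = "a", size = c(6, 8, 4, 6))
  edges <- data.frame(
    dataset_a = "cultures", mode_a = "a",
    dataset_b = c("transect", "npsg", "nptz"), mode_b = "a",
    shared = c(6, 4, 4), p = 0.01)
  net <- manual_network(nodes, edges)
  mc <- assign_metaclusters(net, list(cultures = cultures,
                                      transect = transect,
                                      npsg = npsg, nptz = nptz),
                            "cultures")
  expect_length(mc$metaclusters, 1)
  members <- mc$metaclusters[[1]]$compounds
  # c01/c02: in C-a, T-a, Z-a, G-a -> members
  expect_true(all(c("c01", "c02") %in% members))
  # c05/c06: in C-a, T-a and G-a (2 env modes) -> members
  expect_true(all(c("c05", "c06") %in% members))
  # c03/c04: in C-a, T-a, Z-a... check: c03 is in C-a, T-a, Z-a (npsg a), nptz b
  expect_true(all(c("c03", "c04") %in% members))
  # compounds in only one environmental member mode are excluded
  ids7 <- "c07" # cultures b -> not in root mode
  expect_false(ids7 %in% members)
})

test_that("a compound needs the root mode and two environmental modes", {
  ids <- c("x1", "x2", "x3")
  cultures <- mode_partition(labelled(c("a", "a", "b"), ids), "cultures")
  transect <- mode_partition(labelled(c("a", "a", "a"), ids), "transect")
  npsg <- mode_partition(labelled(c("a", "b", "a"), ids), "npsg")
  nptz <- mode_partition(labelled(c("b", "b", "a"), ids), "nptz")
  nodes <- data.frame(dataset = c("cultures", "transect", "npsg", "nptz"),
                      mode = "a", size = 1)
  edges <- data.frame(dataset_a = "cultures", mode_a = "a",
                      dataset_b = c("transect", "npsg", "nptz"),
                      mode_b = "a", shared = 1, p = 0.01)
  net <- manual_network(nodes, edges)
  parts <- list(cultures = cultures, transect = transect, npsg = npsg,
                nptz = nptz)
  members <- assign_metaclusters(net, parts, "cultures")$metaclusters[[1]]$compounds
  expect_true("x1" %in% members)   # root + T-a + Z-a
  expect_false("x2" %in% members)  # root + only T-a
  expect_false("x3" %in% members)  # T-a, Z-a, G-a but not the root mode
})

test_that("metacluster compound sets are disjoint across roots", {
  ids <- sprintf("y%02d", 1:20)
  cultures <- mode_partition(labelled(rep(c("a", "b"), each = 10), ids),
                             "cultures")
  transect <- mode_partition(labelled(rep(c("a", "b"), each = 10), ids),
                             "transect")
  npsg <- mode_partition(labelled(rep(c("a", "b"), each = 10), ids), "npsg")
  nodes <- expand.grid(dataset = c("cultures", "transect", "npsg"),
                       mode = c("a", "b"), stringsAsFactors = FALSE)
  nodes$size <- 10
  edges <- data.frame(
    dataset_a = "cultures", mode_a = c("a", "a", "b", "b"),
    dataset_b = c("transect", "npsg", "transect", "npsg"),
    mode_b = c("a", "a", "b", "b"), shared = 10, p = 0.001)
  net <- manual_network(nodes, edges)
  mc <- assign_metaclusters(net, list(cultures = cultures,
                                      transect = transect, npsg = npsg),
                            "cultures")
  sets <- lapply(mc$metaclusters, `[[`, "compounds")
  expect_length(mc$metaclusters, 2)
  expect_length(intersect(sets[[1]], sets[[2]]), 0)
  expect_setequal(unlist(sets), ids)
})
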