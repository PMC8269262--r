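test_that("isotopologues are flagged inside the RT window and ppm tolerance", {
  # 13C pair, 1 s apart, HILIC window 6 s
  tab <- feature_only_table(mz = c(121.0684, 121.0684 + 1.003355),
                            rt_sec = c(642, 643), mean_area = c(1000, 150))
  ann <- find_isotopologues(tab)
  expect_equal(nrow(ann), 1)
  expect_equal(ann$kind, "13C")
  expect_equal(ann$parent_id, tab$features$feature_id[1])
  expect_lt(abs(ann$mass_error_ppm), 1)

  # same masses, 15 s apart: outside the window
  tab2 <- feature_only_table(mz = c(121.0684, 122.071755),
                             rt_sec = c(642, 657), mean_area = c(1000, 150))
  expect_equal(nrow(find_isotopologues(tab2)), 0)

  # offset off by 0.00293 Da on m/z 122: outside 5 ppm (~0.0006 Da)
  tab3 <- feature_only_table(mz = c(121.0684, 121.0684 + 1.00628),
                             rt_sec = c(642, 643), mean_area = c(1000, 150))
  expect_equal(nrow(find_isotopologues(tab3, ppm_tol = 5)), 0)

  # area rule: a heavier feature larger than the lighter one is no satellite
  tab4 <- feature_only_table(mz = c(121.0684, 122.071755),
                             rt_sec = c(642, 643), mean_area = c(150, 1000))
  expect_equal(nrow(find_isotopologues(tab4)), 0)
})

test_that("adducts respect polarity and the column RT window", {
  # Na adduct of [M+H]+ 100.0757 co-eluting
  tab <- feature_only_table(mz = c(100.0757, 100.0757 + 21.981944),
                            rt_sec = c(300, 301), mean_area = c(1000, 200))
  ann <- find_adducts(tab)
  expect_equal(ann$kind, "Na")
  # Cl adduct in negative mode
  tabn <- feature_only_table(mz = c(150.0000, 150.0000 + 35.976678),
                             rt_sec = c(300, 301), mean_area = c(1000, 200),
                             polarity = "neg")
  expect_equal(find_adducts(tabn)$kind, "Cl")
  # requesting Cl in positive mode is an error
  expect_error(find_adducts(tab, kinds = "Cl"), "not formed")
  # RP window is 3 s: a 10 s gap is not flagged
  tabrp <- feature_only_table(mz = c(100.0757, 122.057644),
                              rt_sec = c(300, 310), mean_area = c(1000, 200),
                              column = "RP")
  expect_equal(nrow(find_adducts(tabrp)), 0)
})

test_that("doubly charged twins are found at (m + proton)/2", {
  tab <- feature_only_table(mz = c(301.1500, (301.1500 + 1.007276) / 2),
                            rt_sec = c(300, 300), mean_area = c(1000, 300))
  ann <- find_multiply_charged(tab)
  expect_equal(ann$kind, "2+")
  expect_equal(ann$satellite_id, tab$features$feature_id[2])
  # wrong half-mass is not flagged
  tab2 <- feature_only_table(mz = c(301.1500, 151.2000), rt_sec = c(300, 300),
                             mean_area = c(1000, 300))
  expect_equal(nrow(find_multiply_charged(tab2)), 0)
  expect_equal(nrow(find_multiply_charged(
    feature_only_table(301.15, 300, 1000))), 0)
})

test_that("dereplication removes satellites transitively and keeps parents", {
  # chain: A <- B (13C of A) <- C (13C of B)
  mzA <- 200
  tab <- feature_only_table(mz = c(mzA, mzA + 1.003355, mzA + 2 * 1.003355),
                            rt_sec = c(300, 300, 300),
                            mean_area = c(1000, 200, 40))
  ids <- tab$features$feature_id
  ann <- find_isotopologues(tab)
  res <- dereplicate_table(tab, ann)
  expect_identical(res$table$features$feature_id, ids[1])
  expect_setequal(res$removed$satellite_id, ids[2:3])
  expect_true(all(res$removed$parent_id == ids[1])) # collapsed to ultimate parent

  # empty annotations: identity
  res0 <- dereplicate_table(tab, ann[0, ])
  expect_identical(res0$table$features$feature_id, ids)

  # cycles are reported
  cyc <- data.frame(satellite_id = ids[c(1, 2)], parent_id = ids[c(2, 1)],
                    kind = "13C", mass_error_ppm = 0, rt_gap_sec = 0)
  expect_error(dereplicate_table(tab, cyc), "cycle")
})

test_that("annotation is invariant to feature input order", {
  sig <- generate_signatures(n_groups = 1, species_per_group = 2, n_core = 30,
                             n_specific_per_group = 0, n_rare = 0, seed = 10)
  env <- simulate_environment_table(sig, community_design(6, 1), seed = 10)
  sat <- add_adducts_isotopes(env, rates = c(`13C` = 0.2, Na = 0.2), seed = 10)
  tab <- sat$table
  ann1 <- annotate_satellites(tab)
  perm <- sample(tab$features$feature_id)
  ann2 <- annotate_satellites(subset_peak_table(tab, feature_ids = perm))
  key <- function(a) sort(paste(a$satellite_id, a$parent_id, a$kind))
  expect_identical(key(ann1), key(ann2))
})

test_that("planted satellites are recovered perfectly without jitter", {
  for (pol in c("pos", "neg")) {
    sig <- generate_signatures(n_groups = 1, species_per_group = 2,
                               n_core = 60, n_specific_per_group = 0,
                               n_rare = 0, polarity = pol, seed = 11)
    env <- simulate_environment_table(sig, community_design(8, 1), seed = 11)
    sat <- add_adducts_isotopes(env, ppm_jitter = 0, rt_jitter_sec = 0,
                                seed = 11) # all kinds legal for the polarity
    ann <- annotate_satellites(sat$table)
    truth_key <- paste(sat$truth$satellites$satellite_id,
                       sat$truth$satellites$parent_id)
    found_key <- paste(ann$satellite_id, ann$parent_id)
    expect_true(length(truth_key) > 0)
    expect_identical(sort(found_key), sort(truth_key)) # precision = recall = 1
  }
})
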