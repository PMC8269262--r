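test_that("compute_cv is sd/mean with missing values ignored", {
  expect_equal(compute_cv(c(100, 150, 200)), 50 / 150)
  expect_equal(compute_cv(c(5, 5, 5, 5)), 0)
  expect_equal(compute_cv(c(100, 110, 120)), 10 / 110)
  expect_equal(compute_cv(c(100, NA, 200)), sd(c(100, 200)) / 150)
  expect_error(compute_cv(c(NA, NA)), ">= 2")
  expect_error(compute_cv(c(0, 0)), "mean")
})

make_qc_table <- function(sample_mat, pooled_mat = NULL, blank_mat = NULL,
                          rep_groups = NULL) {
  n <- nrow(sample_mat)
  features <- data.frame(feature_id = sprintf("f%02d", seq_len(n)),
                         mz = 100 + seq_len(n), rt_sec = 60 + seq_len(n),
                         column = "HILIC", polarity = "pos")
  mats <- list(sample = sample_mat, pooled = pooled_mat, blank = blank_mat)
  mats <- mats[!vapply(mats, is.null, logical(1))]
  roles <- rep(names(mats), vapply(mats, ncol, integer(1)))
  areas <- do.call(cbind, mats)
  samples <- data.frame(
    sample_id = sprintf("%s%d", roles, stats::ave(seq_along(roles), roles,
                                                  FUN = seq_along)),
    dataset_id = "toy", role = roles,
    replicate_group = NA_character_, vol_filtered_L = 1)
  if (!is.null(rep_groups)) {
    samples$replicate_group[samples$role == "sample"] <- rep_groups
  }
  colnames(areas) <- samples$sample_id
  peak_table(features, samples, areas)
}

test_that("pooled CV filter uses a strict 30% boundary", {
  tab <- make_qc_table(
    sample_mat = matrix(100, 3, 2),
    pooled_mat = rbind(c(100, 150, 200),   # CV 0.333 -> fail
                       c(100, 110, 120),   # CV 0.091 -> pass
                       c(100, 100 + 100 * sqrt(18) / (sqrt(2) * 10), 100)))
  # third row engineered near the boundary; test the strict rule directly
  rep <- qc_filter(tab, filters = "cv")
  expect_true(rep$cv_fail[1])
  expect_false(rep$cv_fail[2])
  # exactly at the threshold passes (strictly greater fails)
  vals <- c(70, 100, 130) # sd 30, mean 100 -> CV exactly 0.30
  tab2 <- make_qc_table(matrix(100, 1, 2), pooled_mat = matrix(vals, 1))
  rep2 <- qc_filter(tab2, filters = "cv")
  expect_equal(rep2$pooled_cv, 0.30)
  expect_false(rep2$cv_fail)
  # no pooled samples is an explicit error
  expect_error(qc_filter(make_qc_table(matrix(100, 1, 2)), filters = "cv"),
               "pooled")
})

test_that("replicate filter compares within-group CV to the whole set", {
  # groups (1,3) and (1,3): mean within CV 0.707 > overall CV 0.577 -> fail
  tab <- make_qc_table(matrix(c(1, 3, 1, 3), 1), rep_groups = c("a", "a", "b", "b"))
  rep <- qc_filter(tab, filters = "replicate")
  expect_equal(rep$replicate_cv, sqrt(2) / 2)
  expect_equal(rep$overall_cv, sd(c(1, 3, 1, 3)) / 2)
  expect_true(rep$replicate_fail)
  # groups (2,2) and (8,8): within CV 0 -> pass
  tab2 <- make_qc_table(matrix(c(2, 2, 8, 8), 1), rep_groups = c("a", "a", "b", "b"))
  expect_false(qc_filter(tab2, filters = "replicate")$replicate_fail)
  # a single group spanning the whole set: within == overall, strict > passes
  tab3 <- make_qc_table(matrix(c(1, 5, 9), 1), rep_groups = c("a", "a", "a"))
  expect_false(qc_filter(tab3, filters = "replicate")$replicate_fail)
  # no replicate groups: skipped with a warning
  tab4 <- make_qc_table(matrix(1:4, 1), rep_groups = c("a", "b", "c", "d"))
  expect_warning(qc_filter(tab4, filters = "replicate"), "skipped")
})

test_that("presence filter counts detected sample columns inclusively", {
  mk <- function(n_present, n_total = 36) {
    matrix(c(rep(100, n_present), rep(NA, n_total - n_present)), 1)
  }
  expect_false(qc_filter(make_qc_table(mk(18)), filters = "presence")$presence_fail)
  expect_true(qc_filter(make_qc_table(mk(17)), filters = "presence")$presence_fail)
  expect_false(qc_filter(make_qc_table(mk(36)), filters = "presence")$presence_fail)
  # a measured zero does not count as presence
  tabz <- make_qc_table(matrix(c(100, 0, NA, 100), 1))
  expect_equal(qc_filter(tabz, filters = "presence")$presence_fraction, 0.5)
})

test_that("blank filter requires samples >= 3x the blank mean", {
  tab <- make_qc_table(
    sample_mat = rbind(c(290, 290), c(300, 300), c(100, 100)),
    blank_mat = rbind(c(100, 100), c(100, 100), c(0, 0)))
  rep <- qc_filter(tab, filters = "blank")
  expect_true(rep$blank_fail[1])   # 2.9x < 3x
  expect_false(rep$blank_fail[2])  # exactly 3x passes
  expect_false(rep$blank_fail[3])  # zero blank always passes
  expect_error(qc_filter(make_qc_table(matrix(1, 1, 2)), filters = "blank"),
               "blank")
})

test_that("filters are idempotent and invariant to column order within roles", {
  sig <- generate_signatures(n_groups = 2, species_per_group = c(2, 2),
                             n_core = 15, n_specific_per_group = c(5, 5),
                             n_rare = 5, seed = 9)
  env <- simulate_environment_table(sig, community_design(10, 2), n_reps = 2,
                                    noise_sigma = 0.15, seed = 9)
  art <- add_instrument_artifacts(env, drift_sigma = 0.2, n_contaminants = 4,
                                  injection_noise_sigma = 0.1, seed = 9)
  tab <- art$table
  rep1 <- qc_filter(tab)
  survivors <- apply_qc(tab, rep1)
  rep2 <- qc_filter(survivors)
  expect_true(all(rep2$pass)) # idempotent: survivors all pass again

  # permute sample columns within roles: same survivor set
  perm <- unlist(lapply(split(seq_len(nrow(tab$samples)), tab$samples$role),
                        sample))
  tab_perm <- subset_peak_table(tab, sample_ids = tab$samples$sample_id[perm])
  rep_perm <- qc_filter(tab_perm)
  expect_identical(rep_perm$pass[order(rep_perm$feature_id)],
                   rep1$pass[order(rep1$feature_id)])
})
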