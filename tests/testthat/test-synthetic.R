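test_that("signature generation is deterministic and block-structured", {
  sig1 <- generate_signatures(seed = 5)
  sig2 <- generate_signatures(seed = 5)
  expect_identical(sig1, sig2)
  expect_identical(dim(sig1$abundance), c(21L, 313L))

  # core features nonzero in every species; group-specific only in-group
  core <- sig1$features$feature_id[sig1$features$block == "core"]
  expect_true(all(sig1$abundance[, core] > 0))
  for (g in unique(sig1$species$group)) {
    gf <- sig1$features$feature_id[sig1$features$block == g]
    in_g <- sig1$species$group == g
    expect_true(all(sig1$abundance[in_g, gf] > 0))
    expect_true(all(sig1$abundance[!in_g, gf] == 0))
  }
  # rare features carried by exactly one species
  rare <- sig1$features$feature_id[sig1$features$block == "rare"]
  expect_true(all(colSums(sig1$abundance[, rare] > 0) == 1))

  expect_error(generate_signatures(species_per_group = c(0, 1, 1, 1, 1)),
               ">= 1 species")
  # one group, all-core: every feature nonzero in both species
  tiny <- generate_signatures(n_groups = 1, species_per_group = 2,
                              n_core = 3, n_specific_per_group = 0,
                              n_rare = 0, seed = 2)
  expect_true(all(tiny$abundance > 0))
})

test_that("culture simulation: noiseless areas equal signature x biovolume", {
  sig <- generate_signatures(n_groups = 2, species_per_group = c(2, 2),
                             n_core = 5, n_specific_per_group = c(4, 4),
                             n_rare = 2, seed = 3)
  cul <- simulate_culture_table(sig, n_reps = 3, noise_sigma = 0,
                                biovolume_um3 = 1e9, seed = 3)
  tab <- cul$table
  expect_equal(nrow(tab$samples), 12)
  expect_identical(unname(table(tab$samples$replicate_group)),
                   rep(3L, 4), ignore_attr = TRUE)
  for (sp in sig$species$species_id) {
    cols <- tab$samples$sample_id[tab$samples$organism == sp]
    expected <- sig$abundance[sp, ] * 1e9
    got <- tab$areas[, cols[1]]
    expect_equal(unname(got[expected > 0]), unname(expected[expected > 0]))
    expect_true(all(is.na(got[expected == 0]))) # absent means missing, not 0
  }
  expect_error(simulate_culture_table(sig, noise_sigma = -1), ">= 0")
})

test_that("environment simulation mixes signatures along the gradient", {
  sig <- generate_signatures(n_groups = 1, species_per_group = 2, n_core = 4,
                             n_specific_per_group = 0, n_rare = 0, seed = 4)
  des <- community_design(n_samples = 10, n_groups = 1, floor = 0)
  env <- simulate_environment_table(sig, des, n_reps = 1, noise_sigma = 0,
                                    seed = 4)
  # single group with monotone-increasing weights: every feature monotone
  expect_true(all(apply(env$table$areas, 1, function(r) all(diff(r) > 0))))

  # zero biomass zeroes a sample
  des0 <- community_design(n_samples = 10, n_groups = 1,
                           biomass = c(0, rep(1e9, 9)), floor = 0)
  env0 <- simulate_environment_table(sig, des0, noise_sigma = 0, seed = 4)
  expect_true(all(is.na(env0$table$areas[, 1])))
  expect_true(all(env0$truth$expected_abundance[, 1] == 0))

  # dimension mismatch between design and signature groups
  sig5 <- generate_signatures(seed = 4)
  expect_error(simulate_environment_table(sig5, des), "groups")
})

test_that("instrument artifacts: drift, pooled conservation, IS identity", {
  sig <- generate_signatures(n_groups = 2, species_per_group = c(2, 2),
                             n_core = 10, n_specific_per_group = c(5, 5),
                             n_rare = 0, seed = 6)
  env <- simulate_environment_table(sig, community_design(8, 2), n_reps = 2,
                                    noise_sigma = 0.1, seed = 6)

  # drift_sigma = 0: original sample columns unchanged, rows/columns appended
  a0 <- add_instrument_artifacts(env, drift_sigma = 0, seed = 6)
  orig <- env$table$samples$sample_id
  expect_equal(a0$table$areas[rownames(env$table$areas), orig],
               env$table$areas)
  expect_true(all(a0$truth$drift == 1))

  # pooled column equals the mean of sample columns (missing as zero)
  bio <- env$table$areas
  bio[is.na(bio)] <- 0
  pooled <- a0$table$areas[rownames(bio), a0$truth$pooled_ids[1]]
  expect_equal(unname(pooled), unname(rowMeans(bio)))

  # shared drift: IS area in pooled sample s / mean = f_s / mean(f)
  a1 <- add_instrument_artifacts(env, drift_sigma = 0.4, seed = 7)
  is1 <- a1$truth$internal_standards[1]
  f <- a1$truth$drift[a1$truth$pooled_ids]
  v <- a1$table$areas[is1, a1$truth$pooled_ids]
  expect_equal(unname(v / mean(v)), unname(f / mean(f)))

  # determinism
  a2 <- add_instrument_artifacts(env, drift_sigma = 0.4, seed = 7)
  expect_identical(a1$table$areas, a2$table$areas)
})

test_that("planted satellites sit at the exact mass offsets", {
  sig <- generate_signatures(n_groups = 1, species_per_group = 2, n_core = 40,
                             n_specific_per_group = 0, n_rare = 0, seed = 8)
  env <- simulate_environment_table(sig, community_design(6, 1), seed = 8)

  sat <- add_adducts_isotopes(env, rates = c(`13C` = 0.2, `2+` = 0.2),
                              ppm_jitter = 0, rt_jitter_sec = 0, seed = 8)
  tr <- sat$truth$satellites
  expect_true(nrow(tr) > 0)
  feats <- sat$table$features
  mz_of <- stats::setNames(feats$mz, feats$feature_id)
  c13 <- tr[tr$kind == "13C", ]
  expect_equal(unname(mz_of[c13$satellite_id]),
               unname(mz_of[c13$parent_id]) + 1.003355)
  dd <- tr[tr$kind == "2+", ]
  expect_equal(unname(mz_of[dd$satellite_id]),
               (unname(mz_of[dd$parent_id]) + 1.007276) / 2)

  # rate 0 plants nothing; polarity-incompatible kind errors
  none <- add_adducts_isotopes(env, rates = c(`13C` = 0), seed = 8)
  expect_identical(nrow(none$truth$satellites), 0L)
  expect_error(add_adducts_isotopes(env, rates = c(Cl = 0.1), seed = 8),
               "not formed in pos mode")
})
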