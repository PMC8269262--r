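# Synthetic-data generator.
#
# Emulates the statistical structure the downstream analysis assumes: a core
# metabolome shared by all taxa plus taxon-specific metabolite blocks;
# environmental samples as gradient-weighted mixtures of taxon signatures;
# per-sample multiplicative instrument drift shared with spiked internal
# standards; pooled QC samples and matrix blanks; and planted
# isotopologue/adduct/doubly-charged satellite features. Everything planted
# is recorded in a truth object so each pipeline stage can be scored against
# known ground truth.

# exact mass offsets (Da) between a satellite ion and its parent
MASS_OFFSETS <- c(
  `13C` = 1.003355,   # one 13C for 12C substitution
  `15N` = 0.997035,
  `34S` = 1.995796,
  Na  = 21.981944,    # [M+Na]+ vs [M+H]+
  NH4 = 17.026549,    # [M+NH4]+ vs [M+H]+
  K   = 37.955882,    # [M+K]+ vs [M+H]+
  Cl  = 35.976678)    # [M+Cl]- vs [M-H]-
PROTON_MASS <- 1.007276
SATELLITE_KINDS <- c(names(MASS_OFFSETS), "2+")

satellite_kinds_for_polarity <- function(polarity) {
  if (polarity == "pos") c("13C", "15N", "34S", "Na", "NH4", "K", "2+")
  else c("13C", "15N", "34S", "Cl")
}

random_feature_frame <- function(n, column = "HILIC", polarity = "pos",
                                 mz_range = c(80, 800),
                                 rt_range_sec = c(60, 1140)) {
  mz <- stats::runif(n, mz_range[1L], mz_range[2L])
  rt <- stats::runif(n, rt_range_sec[1L], rt_range_sec[2L])
  ids <- make_feature_id(mz, rt / 60)
  while (anyDuplicated(ids)) { # ids carry 4 decimals; collisions are rare
    dup <- which(duplicated(ids))
    mz[dup] <- mz[dup] + 0.0007
    ids <- make_feature_id(mz, rt / 60)
  }
  data.frame(feature_id = ids, mz = mz, rt_sec = rt,
             column = column, polarity = polarity)
}

#' Generate a species x feature signature matrix
#'
#' Plants the block structure seen across cultured phytoplankton: a core
#' block of metabolites present in every species, taxon-group-specific
#' blocks present only within one group, and rare metabolites carried by a
#' single species at low abundance. Mean abundances (per unit biovolume)
#' are log-normal draws within blocks.
#'
#' Defaults mirror the study scale: 313 features over 21 species in 5 broad
#' taxonomic groups, with 52 core and 123 group-specific metabolites.
#'
#' @param n_groups number of taxonomic groups.
#' @param species_per_group integer vector (length `n_groups`) of species
#'   counts per group.
#' @param n_core number of core-metabolome features (nonzero in all species).
#' @param n_specific_per_group integer vector of features specific to each
#'   group (nonzero only within that group).
#' @param n_rare number of rare features, each carried by a single random
#'   species at low abundance.
#' @param meanlog,sdlog log-normal parameters of block abundances.
#' @param column,polarity chromatography column / polarity of the features.
#' @param seed RNG seed.
#' @return object of class `signature_matrix`: list with `abundance`
#'   (species x features), `features` (with per-feature `block` label) and
#'   `species` (with `group`).
#' @export
generate_signatures <- function(n_groups = 5,
                                species_per_group = c(4, 6, 4, 4, 3),
                                n_core = 52,
                                n_specific_per_group = c(25, 25, 25, 24, 24),
                                n_rare = 138,
                                meanlog = log(1e3), sdlog = 1,
                                column = "HILIC", polarity = "pos",
                                seed = 1) {
  stopifnot(n_groups >= 1, length(species_per_group) == n_groups,
            length(n_specific_per_group) == n_groups)
  if (any(species_per_group < 1)) stop_invalid("each group needs >= 1 species")
  if (n_core < 0 || n_rare < 0 || any(n_specific_per_group < 0)) {
    stop_invalid("feature counts must be >= 0")
  }
  n_species <- sum(species_per_group)
  n_features <- n_core + sum(n_specific_per_group) + n_rare
  if (n_features < 1) stop_invalid("no features requested")

  with_seed(seed, {
    features <- random_feature_frame(n_features, column, polarity)
    block <- c(rep("core", n_core),
               rep(sprintf("g%d", seq_len(n_groups)), n_specific_per_group),
               rep("rare", n_rare))
    features$block <- block
    group <- rep(sprintf("g%d", seq_len(n_groups)), species_per_group)
    species <- data.frame(
      species_id = sprintf("%s_sp%02d", group,
                           unlist(lapply(species_per_group, seq_len))),
      group = group)
    abundance <- matrix(0, n_species, n_features,
                        dimnames = list(species$species_id,
                                        features$feature_id))
    for (j in seq_len(n_features)) {
      carriers <- switch(
        substr(block[j], 1, 1),
        c = seq_len(n_species),              # core
        g = which(group == block[j]),        # group-specific
        r = sample.int(n_species, 1L))       # rare: one random species
      level <- stats::rlnorm(length(carriers), meanlog, sdlog)
      if (block[j] == "rare") level <- level * 0.1
      abundance[carriers, j] <- level
    }
    structure(list(abundance = abundance, features = features,
                   species = species),
              class = "signature_matrix")
  })
}

#' @export
print.signature_matrix <- function(x, ...) {
  cat(sprintf("<signature_matrix> %d species x %d features; blocks: %s\n",
              nrow(x$abundance), ncol(x$abundance),
              paste(sprintf("%s=%d", names(table(x$features$block)),
                            table(x$features$block)), collapse = ", ")))
  invisible(x)
}

#' Community design along an environmental gradient
#'
#' Per-sample mixing weights of taxonomic groups along a monotone axis
#' (latitude by default). The default shapes plant the gradient patterns the
#' clustering stage must recover: monotone increase, flat, two peaked bumps
#' at different positions, and monotone decrease. A small floor keeps every
#' group present everywhere so no true feature drops below the presence
#' filter by construction.
#'
#' @param n_samples number of stations along the axis.
#' @param n_groups number of taxonomic groups (<= 5 shapes are built in;
#'   more groups recycle the shape set with shifted peaks).
#' @param axis numeric axis values (default latitudes 23..38 N).
#' @param biomass total-biomass scalar per sample (recycled).
#' @param floor minimum weight.
#' @return object of class `community_design`: list with `axis`, `weights`
#'   (samples x groups) and `biomass`.
#' @export
community_design <- function(n_samples = 36, n_groups = 5,
                             axis = seq(23, 38, length.out = n_samples),
                             biomass = 1e9, floor = 0.05) {
  stopifnot(n_samples >= 2, n_groups >= 1, length(axis) == n_samples)
  if (any(diff(axis) <= 0)) stop_invalid("axis must be strictly monotone")
  x <- (axis - min(axis)) / diff(range(axis))
  shape <- function(i) {
    switch(((i - 1L) %% 5L) + 1L,
           0.2 + 0.8 * x,                       # monotone increase
           rep(0.5, length(x)),                 # flat / no pattern
           exp(-(x - 0.8)^2 / (2 * 0.09^2)),    # sharp peak in the north
           exp(-(x - 0.35)^2 / (2 * 0.12^2)),   # peak mid-axis
           1 - 0.8 * x)                         # monotone decrease
  }
  weights <- vapply(seq_len(n_groups), shape, numeric(n_samples))
  weights <- pmax(weights, floor)
  dimnames(weights) <- list(NULL, sprintf("g%d", seq_len(n_groups)))
  structure(list(axis = axis, weights = weights,
                 biomass = rep_len(biomass, n_samples)),
            class = "community_design")
}

#' Simulate a culture peak table
#'
#' One or more replicate harvests per species; the noiseless area equals
#' signature x biovolume, with multiplicative log-normal replicate noise on
#' top. Features a species does not carry are missing (`NA`), not zero.
#'
#' @param sig a [generate_signatures()] result.
#' @param n_reps biological replicates per species.
#' @param noise_sigma sd (log scale) of replicate noise.
#' @param biovolume_um3 biovolume harvested per sample.
#' @param dataset_id dataset label.
#' @param seed RNG seed.
#' @return list with elements `table` ([peak_table()]) and `truth` (list with
#'   `true_modes`, the planted block label per feature, plus the inputs).
#' @export
simulate_culture_table <- function(sig, n_reps = 3, noise_sigma = 0.2,
                                   biovolume_um3 = 1e9,
                                   dataset_id = "cultures", seed = 1) {
  stopifnot(inherits(sig, "signature_matrix"), n_reps >= 1)
  if (noise_sigma < 0) stop_invalid("`noise_sigma` must be >= 0")
  n_species <- nrow(sig$abundance)
  n_features <- ncol(sig$abundance)
  with_seed(seed, {
    samples <- data.frame(
      sample_id = sprintf("cul_%s_r%d",
                          rep(sig$species$species_id, each = n_reps),
                          rep(seq_len(n_reps), n_species)),
      dataset_id = dataset_id, role = "sample",
      replicate_group = rep(sig$species$species_id, each = n_reps),
      biovolume_um3 = biovolume_um3,
      organism = rep(sig$species$species_id, each = n_reps))
    base <- t(sig$abundance)[, rep(seq_len(n_species), each = n_reps),
                             drop = FALSE] * biovolume_um3
    noise <- matrix(stats::rlnorm(length(base), 0, noise_sigma),
                    nrow(base), ncol(base))
    areas <- base * noise
    areas[base == 0] <- NA_real_
    colnames(areas) <- samples$sample_id
    tab <- peak_table(sig$features, samples, areas)
    truth <- list(
      signature = sig,
      true_modes = stats::setNames(sig$features$block,
                                   sig$features$feature_id),
      noise_sigma = noise_sigma, biovolume_um3 = biovolume_um3)
    list(table = tab, truth = truth)
  })
}

#' Simulate an environmental peak table
#'
#' True abundance of feature j in sample s is
#' `biomass_s * sum_g w_{s,g} * mean signature of j within group g`; observed
#' areas add multiplicative log-normal noise. The planted mode of each
#' feature is its signature block (core features follow total biomass,
#' group-specific features follow their group's gradient shape).
#'
#' @param sig a [generate_signatures()] result.
#' @param design a [community_design()].
#' @param n_reps replicate filters per station (replicate columns share the
#'   station's mixing weights).
#' @param noise_sigma sd (log scale) of observation noise.
#' @param vol_filtered_L volume filtered per sample (liters).
#' @param dataset_id dataset label.
#' @param seed RNG seed.
#' @return list with `table` and `truth` (planted modes, expected abundances,
#'   design).
#' @export
simulate_environment_table <- function(sig, design = community_design(),
                                       n_reps = 1, noise_sigma = 0.2,
                                       vol_filtered_L = 10,
                                       dataset_id = "transect", seed = 1) {
  stopifnot(inherits(sig, "signature_matrix"),
            inherits(design, "community_design"), n_reps >= 1)
  if (noise_sigma < 0) stop_invalid("`noise_sigma` must be >= 0")
  n_groups_sig <- length(unique(sig$species$group))
  if (ncol(design$weights) != n_groups_sig) {
    stop_invalid("design has %d groups but signatures have %d",
                 ncol(design$weights), n_groups_sig)
  }
  groups <- sort(unique(sig$species$group))
  # group-mean signature: groups x features
  gmean <- do.call(rbind, lapply(groups, function(g) {
    colMeans(sig$abundance[sig$species$group == g, , drop = FALSE])
  }))
  n_stations <- nrow(design$weights)
  true_station <- (design$weights %*% gmean) * design$biomass # stations x feats
  with_seed(seed, {
    station <- rep(seq_len(n_stations), each = n_reps)
    samples <- data.frame(
      sample_id = sprintf("env_s%02d_r%d", station,
                          rep(seq_len(n_reps), n_stations)),
      dataset_id = dataset_id, role = "sample",
      replicate_group = sprintf("st%02d", station),
      vol_filtered_L = vol_filtered_L,
      latitude = design$axis[station])
    base <- t(true_station)[, station, drop = FALSE] # features x samples
    noise <- matrix(stats::rlnorm(length(base), 0, noise_sigma),
                    nrow(base), ncol(base))
    areas <- base * noise
    areas[base == 0] <- NA_real_
    colnames(areas) <- samples$sample_id
    tab <- peak_table(sig$features, samples, areas)
    truth <- list(
      signature = sig, design = design,
      true_modes = stats::setNames(sig$features$block,
                                   sig$features$feature_id),
      expected_abundance = t(true_station),
      noise_sigma = noise_sigma)
    list(table = tab, truth = truth)
  })
}

#' Plant instrument artifacts: drift, internal standards, pooled QCs, blanks
#'
#' Appends pooled QC columns (the per-feature mean over sample columns,
#' missing values contributing zero, with optional injection noise), matrix
#' blank columns (a configurable fraction of each feature's mean sample
#' area), optional contaminant-only features (blank level equal to sample
#' level, so they fail a 3x blank criterion), and internal-standard feature
#' rows. Every column then gets a multiplicative drift factor
#' `f = lognormal(0, drift_sigma)`; internal standards carry exactly
#' `base x f` in each column when `is_share_drift = TRUE` (the situation
#' B-MIS normalization can correct), or an independent drift when `FALSE`.
#'
#' @param sim list with `table`/`truth` from a simulate_* call, or a bare
#'   [peak_table()].
#' @param drift_sigma sd (log scale) of per-column drift.
#' @param n_internal_standards number of spiked internal-standard rows.
#' @param is_share_drift do internal standards share the sample drift?
#' @param n_pooled number of pooled QC injections.
#' @param n_blanks number of matrix blank columns.
#' @param n_contaminants number of contaminant-only features to plant.
#' @param blank_fraction blank level of true features relative to their mean
#'   sample area.
#' @param injection_noise_sigma sd (log scale) of pooled-injection noise.
#' @param seed RNG seed.
#' @return list with `table` and `truth`; the truth gains `drift` (named
#'   per-column factor), `internal_standards`, `contaminants`, `pooled_ids`,
#'   `blank_ids`.
#' @export
add_instrument_artifacts <- function(sim, drift_sigma = 0.3,
                                     n_internal_standards = 5,
                                     is_share_drift = TRUE,
                                     n_pooled = 5, n_blanks = 2,
                                     n_contaminants = 0,
                                     blank_fraction = 0.1,
                                     injection_noise_sigma = 0,
                                     seed = 1) {
  if (inherits(sim, "peak_table")) sim <- list(table = sim, truth = list())
  tab <- sim$table
  stopifnot(inherits(tab, "peak_table"))
  if (drift_sigma < 0) stop_invalid("`drift_sigma` must be >= 0")
  with_seed(seed, {
    features <- tab$features
    samples <- tab$samples
    areas <- tab$areas
    sample_ids <- samples_by_role(tab, "sample")
    dataset <- samples$dataset_id[1L]
    scale0 <- stats::median(areas[, sample_ids], na.rm = TRUE)

    contaminant_ids <- character(0)
    if (n_contaminants > 0) {
      cf <- random_feature_frame(n_contaminants, features$column[1L],
                                 features$polarity[1L])
      while (any(cf$feature_id %in% features$feature_id)) {
        cf$mz <- cf$mz + 0.0007
        cf$feature_id <- make_feature_id(cf$mz, cf$rt_sec / 60)
      }
      contaminant_ids <- cf$feature_id
      lvl <- stats::rlnorm(n_contaminants, log(scale0), 0.5)
      carea <- matrix(rep(lvl, ncol(areas)), n_contaminants, ncol(areas))
      features <- rbind(features,
                        conform_feature_frame(cf, features, "contaminant"))
      areas <- rbind(areas, carea)
      rownames(areas) <- features$feature_id
    }

    area0 <- ifelse(is.na(areas), 0, areas) # missing contributes zero
    mean_sample <- rowMeans(area0[, sample_ids, drop = FALSE])

    pooled_ids <- sprintf("%s_pooled_%d", dataset, seq_len(n_pooled))
    pooled <- matrix(rep(rowMeans(area0[, sample_ids, drop = FALSE]),
                         n_pooled), nrow(areas), n_pooled)
    if (injection_noise_sigma > 0) {
      pooled <- pooled * matrix(stats::rlnorm(length(pooled), 0,
                                              injection_noise_sigma),
                                nrow(pooled), ncol(pooled))
    }

    blank_ids <- sprintf("%s_blank_%d", dataset, seq_len(n_blanks))
    blank_level <- mean_sample * blank_fraction
    blank_level[rownames(areas) %in% contaminant_ids] <-
      mean_sample[rownames(areas) %in% contaminant_ids] # carryover = signal
    blanks <- matrix(rep(blank_level, n_blanks), nrow(areas), n_blanks)

    areas <- cbind(areas, pooled, blanks)
    new_samples <- data.frame(
      sample_id = c(pooled_ids, blank_ids),
      dataset_id = dataset,
      role = c(rep("pooled", n_pooled), rep("blank", n_blanks)))
    samples <- merge_sample_frames(samples, new_samples)
    colnames(areas) <- samples$sample_id

    # internal-standard rows
    is_ids <- character(0)
    if (n_internal_standards > 0) {
      isf <- random_feature_frame(n_internal_standards, features$column[1L],
                                  features$polarity[1L])
      isf$feature_id <- sprintf("IS_%s", isf$feature_id)
      is_ids <- isf$feature_id
      is_base <- stats::rlnorm(n_internal_standards, log(scale0), 0.3)
      is_area <- matrix(rep(is_base, ncol(areas)),
                        n_internal_standards, ncol(areas))
      features <- rbind(features,
                        conform_feature_frame(isf, features,
                                              "internal_standard"))
      areas <- rbind(areas, is_area)
      rownames(areas) <- features$feature_id
    }

    drift <- stats::rlnorm(ncol(areas), 0, drift_sigma)
    names(drift) <- colnames(areas)
    areas <- sweep(areas, 2, drift, `*`)
    if (n_internal_standards > 0 && !is_share_drift) {
      own <- stats::rlnorm(ncol(areas), 0, drift_sigma)
      areas[is_ids, ] <- sweep(areas[is_ids, , drop = FALSE], 2,
                               own / drift, `*`)
    }

    features$is_internal_standard <- features$feature_id %in% is_ids
    tab2 <- peak_table(features, samples, areas, units = tab$units)
    truth <- sim$truth
    truth$drift <- drift
    truth$internal_standards <- is_ids
    truth$contaminants <- contaminant_ids
    truth$pooled_ids <- pooled_ids
    truth$blank_ids <- blank_ids
    list(table = tab2, truth = truth)
  })
}

# make a new feature frame carry every column of the reference frame
conform_feature_frame <- function(new, ref, block = NA_character_) {
  for (nm in setdiff(names(ref), names(new))) {
    new[[nm]] <- if (nm == "block") block
      else if (is.logical(ref[[nm]])) FALSE
      else if (is.numeric(ref[[nm]])) NA_real_
      else NA_character_
  }
  new[, names(ref), drop = FALSE]
}

# row-bind sample frames with differing optional columns
merge_sample_frames <- function(a, b) {
  for (nm in setdiff(names(a), names(b))) {
    b[[nm]] <- if (is.numeric(a[[nm]])) NA_real_ else NA_character_
  }
  for (nm in setdiff(names(b), names(a))) {
    a[[nm]] <- if (is.numeric(b[[nm]])) NA_real_ else NA_character_
  }
  rbind(a, b[, names(a), drop = FALSE])
}

#' Plant adduct, isotopologue and doubly charged satellite features
#'
#' For a random subset of parent features (per kind), appends a satellite
#' feature at the exact mass offset of that kind (13C/15N/34S isotopologues,
#' Na/NH4/K adducts in positive mode, Cl in negative mode, or the doubly
#' charged ion at `(m + 1.007276)/2`), co-eluting with its parent. Satellite
#' areas are a fixed fraction of the parent's. Optional jitter perturbs the
#' satellite m/z (Gaussian, sd in ppm) and retention time (uniform, seconds).
#'
#' @param sim list with `table`/`truth`, or a bare [peak_table()].
#' @param rates named vector of per-kind planting rates in `[0, 1]`
#'   (fraction of features receiving a satellite of that kind); kinds must be
#'   compatible with the table's polarity.
#' @param ppm_jitter sd of satellite mass error, in ppm.
#' @param rt_jitter_sec half-width of the uniform retention-time offset.
#' @param satellite_fraction satellite area relative to the parent.
#' @param seed RNG seed.
#' @return list with `table` and `truth`; the truth gains `satellites`, a
#'   data.frame (satellite_id, parent_id, kind).
#' @export
add_adducts_isotopes <- function(sim, rates = NULL, ppm_jitter = 0,
                                 rt_jitter_sec = 0,
                                 satellite_fraction = 0.15, seed = 1) {
  if (inherits(sim, "peak_table")) sim <- list(table = sim, truth = list())
  tab <- sim$table
  stopifnot(inherits(tab, "peak_table"))
  polarity <- tab$features$polarity[1L]
  allowed <- satellite_kinds_for_polarity(polarity)
  if (is.null(rates)) rates <- stats::setNames(rep(0.05, length(allowed)), allowed)
  bad_kind <- setdiff(names(rates), SATELLITE_KINDS)
  if (length(bad_kind)) {
    stop_invalid("unknown satellite kind(s): %s", paste(bad_kind, collapse = ", "))
  }
  incompatible <- setdiff(names(rates), allowed)
  if (length(incompatible)) {
    stop_invalid("kind(s) %s are not formed in %s mode",
                 paste(incompatible, collapse = ", "), polarity)
  }
  if (any(rates < 0 | rates > 1)) stop_invalid("rates must be in [0, 1]")
  with_seed(seed, {
    features <- tab$features
    areas <- tab$areas
    eligible <- which(!features$is_internal_standard)
    sat_rows <- list()
    for (kind in names(rates)) {
      n_sat <- round(rates[[kind]] * length(eligible))
      if (n_sat < 1) next
      parents <- sample(eligible, n_sat)
      pm <- features$mz[parents]
      mz <- if (kind == "2+") (pm + PROTON_MASS) / 2 else pm + MASS_OFFSETS[[kind]]
      if (ppm_jitter > 0) mz <- mz * (1 + stats::rnorm(n_sat, 0, ppm_jitter * 1e-6))
      rt <- features$rt_sec[parents] +
        if (rt_jitter_sec > 0) stats::runif(n_sat, -rt_jitter_sec, rt_jitter_sec) else 0
      ids <- make_feature_id(mz, rt / 60)
      clash <- ids %in% c(features$feature_id, unlist(lapply(sat_rows, `[[`, "feature_id")))
      while (any(clash)) {
        mz[clash] <- mz[clash] + 0.0002
        ids <- make_feature_id(mz, rt / 60)
        clash <- ids %in% c(features$feature_id,
                            unlist(lapply(sat_rows, `[[`, "feature_id")))
      }
      sat_rows[[kind]] <- data.frame(
        feature_id = ids, mz = mz, rt_sec = rt,
        column = features$column[parents], polarity = polarity,
        parent_id = features$feature_id[parents], kind = kind)
    }
    if (!length(sat_rows)) {
      truth <- sim$truth
      truth$satellites <- data.frame(satellite_id = character(0),
                                     parent_id = character(0),
                                     kind = character(0))
      list(table = tab, truth = truth)
    } else {
      sats <- do.call(rbind, sat_rows)
      rownames(sats) <- NULL
      sat_areas <- areas[sats$parent_id, , drop = FALSE] * satellite_fraction
      rownames(sat_areas) <- sats$feature_id
      new_features <- conform_feature_frame(
        sats[, c("feature_id", "mz", "rt_sec", "column", "polarity")],
        features, "satellite")
      features2 <- rbind(features, new_features)
      areas2 <- rbind(areas, sat_areas)
      tab2 <- peak_table(features2, tab$samples, areas2, units = tab$units)
      truth <- sim$truth
      truth$satellites <- data.frame(satellite_id = sats$feature_id,
                                     parent_id = sats$parent_id,
                                     kind = sats$kind)
      list(table = tab2, truth = truth)
    }
  })
}
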