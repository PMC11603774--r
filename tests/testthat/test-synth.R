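test_that("cohort generation honors counts, batching and determinism", {
  cfg <- sim_config(seed = 4)
  co <- generate_cohort(cfg)
  m <- co$manifest
  expect_equal(sum(m$matrix == "serum"), 95)
  expect_equal(sum(m$matrix == "urine"), 95)
  expect_equal(sum(m$outcome == "preterm" & m$matrix == "serum"), 35)
  expect_equal(sum(m$outcome == "preterm" & m$matrix == "urine"), 35)
  expect_true(all(m$creatinine[m$matrix == "urine"] > 0))
  # paired serum/urine run in the same batch
  bt <- tapply(m$batch, m$participant, function(b) length(unique(b)))
  expect_true(all(bt == 1))

  tiny <- generate_cohort(sim_config(n_samples = 4, n_preterm = 1,
                                     n_batches = 4, n_features_pos = 200,
                                     n_differential = 5,
                                     n_corr_clusters = 1, seed = 1))
  expect_equal(as.vector(table(tiny$manifest$batch)), rep(2L, 4))

  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  expect_error(sim_config(n_samples = 10, n_preterm = 10), "n_preterm")
  expect_error(sim_config(missing_rate = 1), "missing_rate")
  expect_error(sim_config(cluster_r = 1), "cluster_r")
})

test_that("feature tables carry the planted structure", {
  cfg <- sim_config(seed = 9)
  co <- generate_cohort(cfg)
  sim <- generate_feature_tables(cfg, co$manifest)
  tr <- sim$truth
  h <- hydrogen_mass()

  # neutralization arithmetic: [M+H]+ of M = 282.16768 sits at 283.17550
  expect_equal(round(282.16768 + h, 5), 283.17550)

  # pair partners satisfy the merge tolerances; decoys violate one
  fp <- sim$pos$features; fn <- sim$neg$features
  for (pid in names(tr$pair_map)) {
    i <- match(pid, fp$feature_id); j <- match(tr$pair_map[[pid]],
                                               fn$feature_id)
    expect_lte(ppm_error(fp$mz[i] - h, fn$mz[j] + h), 5)
    expect_lt(abs(fp$rt[i] - fn$rt[j]), 0.5)
  }
  for (k in seq_len(nrow(tr$decoy_pairs))) {
    i <- match(tr$decoy_pairs$pos[k], fp$feature_id)
    j <- match(tr$decoy_pairs$neg[k], fn$feature_id)
    violates <- ppm_error(fp$mz[i] - h, fn$mz[j] + h) > 5 ||
      abs(fp$rt[i] - fn$rt[j]) >= 0.5
    expect_true(violates)
  }

  # all censored entries are strictly below the MDL in the latent table
  na_cells <- is.na(sim$pos$abundance)
  expect_true(all(10^tr$latent$pos[na_cells] < cfg$mdl))

  # planted differential features: mean latent log2 group difference
  # within 0.2 of the planted effect (per-feature estimates carry
  # sampling noise ~0.25 log2 units at n = 95, so the planted-set mean is
  # the recoverable quantity)
  ser_pre <- co$manifest$matrix == "serum" & co$manifest$outcome == "preterm"
  ser_trm <- co$manifest$matrix == "serum" & co$manifest$outcome == "term"
  lat <- tr$latent$pos[tr$differential_feature_ids, ]
  d <- (rowMeans(lat[, ser_pre]) - rowMeans(lat[, ser_trm])) / log10(2)
  expect_lt(abs(mean(d) - cfg$effect_log2fc), 0.2)

  # planted clusters reach the target correlation via the latent factor
  cl <- tr$cluster_memberships[[1]]
  cm <- cor(t(tr$latent$pos[cl, co$manifest$matrix == "serum"]))
  expect_lt(abs(mean(cm[upper.tri(cm)]) - cfg$cluster_r), 0.12)

  # adduct satellites link to existing parents
  expect_true(all(tr$adduct_map %in% fp$feature_id))
  expect_true(all(names(tr$adduct_map) %in% fp$feature_id))

  # censoring disabled leaves no missing values
  cfg0 <- sim_config(missing_rate = 0, mdl = 0, seed = 2)
  sim0 <- generate_feature_tables(cfg0, generate_cohort(cfg0)$manifest)
  expect_false(anyNA(sim0$pos$abundance))
  expect_false(anyNA(sim0$neg$abundance))

  # determinism
  expect_identical(sim$pos$abundance,
                   generate_feature_tables(cfg, co$manifest)$pos$abundance)
})

test_that("generated spectra and library support every annotation branch", {
  cfg <- sim_config(seed = 5)
  co <- generate_cohort(cfg)
  sim <- generate_feature_tables(cfg, co$manifest)
  sp <- generate_spectra(cfg, sim)

  roles <- sp$truth
  expect_true(all(c("exact", "standard", "partial", "near_miss") %in%
                    roles))
  # every cluster feature has an exact-match library entry with its
  # ground-truth source tag
  cl_ids <- unlist(sim$truth$cluster_memberships, use.names = FALSE)
  lib_names <- vapply(sp$library, `[[`, "", "name")
  expect_true(all(paste0("CMPD_", cl_ids) %in% lib_names))

  # one-fragment spectra are excluded from the annotatable set
  one <- names(roles)[roles == "one_fragment"]
  if (length(one)) {
    expect_equal(nrow(sp$spectra[[one[1]]]$fragments), 1)
    expect_equal(require_product_ions(one, sp$spectra), character(0))
  }
  # an exact self-match scores 100
  ex <- names(roles)[roles == "exact"][1]
  ent <- sp$library[[match(paste0("CMPD_", ex), lib_names)]]
  expect_equal(spectral_match_score(sp$spectra[[ex]], ent), 100)

  expect_identical(sp$truth, generate_spectra(cfg, sim)$truth)
})

test_that("null+planted simulator is deterministic and well-formed", {
  s1 <- simulate_null_planted(n_features = 100, n_planted = 10, seed = 3)
  s2 <- simulate_null_planted(n_features = 100, n_planted = 10, seed = 3)
  expect_identical(s1, s2)
  expect_equal(dim(s1$abundance), c(100, 95))
  expect_equal(sum(s1$groups == "preterm"), 35)
  expect_false(anyNA(s1$abundance))
})
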