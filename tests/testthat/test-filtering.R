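test_that("adduct removal keeps link roots only", {
  ab <- matrix(1e5, 4, 4, dimnames = list(c("A", "B", "C", "D"), NULL))
  # chain A -> B -> C plus an unlinked D: only roots C and D survive
  ft <- make_table(ab, adduct_link = c("B", "C", NA, NA))
  out <- remove_linked_adducts(ft)
  expect_setequal(out$features$feature_id, c("C", "D"))
  expect_equal(attr(out, "n_dropped"), 2L)

  # satellite removed, parent kept
  ft2 <- make_table(matrix(1e5, 2, 4, dimnames = list(c("MH", "MNa"),
                                                      NULL)),
                    adduct_link = c(NA, "MH"))
  out2 <- remove_linked_adducts(ft2)
  expect_equal(out2$features$feature_id, "MH")

  # no links: identity
  ft3 <- make_table(ab)
  expect_equal(remove_linked_adducts(ft3)$features$feature_id,
               ft3$features$feature_id)
  # dangling link is a validation error
  ft4 <- make_table(ab[1:2, ], adduct_link = c("NOPE", NA))
  expect_error(remove_linked_adducts(ft4), "missing feature id: NOPE")
  # idempotence
  expect_equal(remove_linked_adducts(out)$features$feature_id,
               out$features$feature_id)
})

test_that("blank filtering drops background features by mean ratio", {
  ab <- matrix(c(9e4, 9e4, 9e4, 9e4,
                 9e4, 9e4, 9e4, 9e4,
                 9e4, 9e4, 9e4, 9e4), 3, 4, byrow = TRUE,
               dimnames = list(c("clean", "edge", "dirty"), NULL))
  ft <- make_table(ab)
  blanks <- matrix(c(0, 0,            # zero blank: always kept
                     3e4, 3e4,        # exactly threshold x mean: dropped
                     9e4, 9e4),       # blank equals sample mean: dropped
                   3, 2, byrow = TRUE,
                   dimnames = list(rownames(ab), c("b1", "b2")))
  out <- filter_blanks(ft, blanks, ratio_threshold = 1 / 3)
  expect_equal(out$features$feature_id, "clean")
  expect_error(filter_blanks(ft, NULL), "empty")
  expect_error(filter_blanks(ft, blanks[, 0, drop = FALSE]), "empty")
})

test_that("frequency cutoff is inclusive and respects the noise floor", {
  n <- 95
  mk_row <- function(k) c(rep(5e4, k), rep(NA, n - k))
  ab <- rbind(`67` = mk_row(67),   # 70.5% -> retained
              `66` = mk_row(66),   # 69.5% -> dropped
              low = rep(5e3, n))   # present but under the noise floor
  ft <- make_table(ab, samples = make_samples(n))
  out <- apply_frequency_cutoff(ft, 0.70)
  expect_equal(out$features$feature_id, "67")
  expect_equal(out$features$detection_frequency, 67 / 95)

  # cutoff 0 still drops an undetected feature
  allna <- make_table(matrix(NA_real_, 1, 4,
                             dimnames = list("gone", NULL)))
  expect_equal(nrow(apply_frequency_cutoff(allna, 0)$features), 0)
  # idempotence
  expect_equal(apply_frequency_cutoff(out, 0.70)$features$feature_id,
               "67")
})

test_that("product-ion filter keeps features with informative MS2", {
  spectra <- list(
    three = ms2_spectrum(100, data.frame(mz = c(50, 60, 70),
                                         intensity = c(1, 2, 3))),
    one = ms2_spectrum(100, data.frame(mz = 50, intensity = 1)))
  expect_equal(require_product_ions(c("three", "one", "none"), spectra),
               "three")
})

test_that("cross-polarity merge matches the worked example and rejects
           out-of-tolerance pairs", {
  samples <- make_samples(4)
  mk <- function(ids, mz, rt, mode) {
    make_table(matrix(1e5, length(ids), 4, dimnames = list(ids, NULL)),
               mz = mz, rt = rt, ion_mode = mode, samples = samples)
  }
  pos <- mk(c("p1", "p2", "p3"), c(283.17550, 150.10000, 320.20000),
            c(10.00, 5.00, 8.00), "positive")
  # n1 pairs with p1 (0.14 ppm, dRT 0.2); n2 violates RT (0.60); n3 mass
  neg <- mk(c("n1", "n2", "n3"),
            c(281.15990,               # pairs with p1: 0.14 ppm, dRT 0.20
              148.08436,               # mass-exact partner of p2, dRT 0.60
              318.18436 * (1 + 8e-6)), # partner of p3 at 8 ppm error
            c(10.20, 5.60, 8.10), "negative")
  res <- merge_esi_modes(pos, neg)
  expect_equal(res$merges$pos_feature_id, "p1")
  expect_equal(res$merges$neg_feature_id, "n1")
  expect_equal(res$merges$mass_error_ppm, 0.14, tolerance = 0.02)
  expect_equal(res$merges$delta_rt, 0.20, tolerance = 1e-9)
  expect_equal(res$merges$neutral_mass_pos, 282.16768, tolerance = 1e-5)
  # merged table: one row for the pair, pass-through for the rest
  expect_equal(nrow(res$table$features), 5)
  expect_equal(sum(!is.na(res$table$features$merged_partner)), 1)
  # sample mismatch is an error
  neg2 <- neg; neg2$samples$sample_id[1] <- "zzz"
  colnames(neg2$abundance)[1] <- "zzz"
  expect_error(merge_esi_modes(pos, neg2), "same samples")
})

test_that("merge equals the brute-force oracle on randomized tables", {
  h <- hydrogen_mass()
  for (seed in 1:4) {
    set.seed(seed)
    n_p <- 120; n_n <- 100; n_pair <- 25
    M <- runif(n_pair, 150, 550)
    pos_mz <- c(M + h + runif(n_pair, -1, 1) * M * 3e-6,
                runif(n_p - n_pair, 100, 600))
    pos_rt <- runif(n_p, 0.5, 14)
    neg_mz <- c(M - h, runif(n_n - n_pair, 100, 600))
    neg_rt <- c(pos_rt[seq_len(n_pair)] + runif(n_pair, -0.45, 0.45),
                runif(n_n - n_pair, 0.5, 14))
    samples <- make_samples(3)
    pos <- make_table(matrix(1e5, n_p, 3), mz = pos_mz, rt = pos_rt,
                      samples = samples)
    neg <- make_table(matrix(2e5, n_n, 3,
                             dimnames = list(sprintf("N%03d",
                                                     seq_len(n_n)))),
                      mz = neg_mz, rt = pmax(neg_rt, 0.1),
                      ion_mode = "negative", samples = samples)
    got <- merge_esi_modes(pos, neg)$merges
    want <- oracle_merge(pos, neg, h = h)
    expect_equal(got$pos_feature_id, want$pos)
    expect_equal(got$neg_feature_id, want$neg)
    expect_equal(got$mass_error_ppm, want$ppm, tolerance = 1e-9)
  }
})

test_that("merge recovers all planted pairs and rejects all decoys", {
  cfg <- sim_config(seed = 21)
  sim <- generate_feature_tables(cfg, generate_cohort(cfg)$manifest)
  mg <- merge_esi_modes(sim$pos, sim$neg)
  tm <- sim$truth$pair_map
  got <- setNames(mg$merges$neg_feature_id, mg$merges$pos_feature_id)
  expect_true(all(got[names(tm)] == tm))
  planted_decoy <- paste(sim$truth$decoy_pairs$pos,
                         sim$truth$decoy_pairs$neg)
  expect_false(any(paste(mg$merges$pos_feature_id,
                         mg$merges$neg_feature_id) %in% planted_decoy))
})
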