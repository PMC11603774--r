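spec2 <- function(mzs, ints, prec = 200, rt = NA_real_) {
  ms2_spectrum(prec, data.frame(mz = mzs, intensity = ints), rt = rt)
}

test_that("spectral match score is a weighted cosine", {
  a <- spec2(c(100.0000, 150.0000), c(50, 50))
  b <- spec2(c(100.0000, 200.0000), c(50, 50))
  # half-overlapping unit-norm vectors -> cosine 1/2
  expect_equal(spectral_match_score(a, b), 50.0)
  # self-similarity and symmetry
  expect_equal(spectral_match_score(a, a), 100)
  expect_equal(spectral_match_score(a, b), spectral_match_score(b, a))
  # no shared fragments within tolerance -> 0
  c2 <- spec2(c(300.0, 400.0), c(10, 10))
  expect_equal(spectral_match_score(a, c2), 0)
  # tolerance boundary: 10 ppm window
  d <- spec2(100.0000 * (1 + 8e-6), 50)
  expect_gt(spectral_match_score(spec2(100, 50), d), 0)
  e <- spec2(100.0000 * (1 + 20e-6), 50)
  expect_equal(spectral_match_score(spec2(100, 50), e), 0)
  # sqrt-intensity weighting: intensities 1 vs 4 weight as 1 vs 2
  f1 <- spec2(c(100, 150), c(1, 4))
  f2 <- spec2(100, 1)
  expect_equal(spectral_match_score(f1, f2), 100 * 1 / sqrt(5))
  expect_error(spectral_match_score(a, spec2(numeric(0), numeric(0))),
               "empty")
})

test_that("level assignment follows the confidence rules and partitions
           its evidence space", {
  expect_equal(assign_level(TRUE, 99, TRUE, 0.03, 1, 2), 1L)
  expect_equal(assign_level(TRUE, 92, FALSE), 2L)
  expect_equal(assign_level(TRUE, 75, FALSE), 3L)
  expect_equal(assign_level(TRUE, 30, FALSE), 4L)
  expect_equal(assign_level(TRUE, NA), 4L)
  expect_equal(assign_level(FALSE), 5L)
  # standard failing one Level-1 condition falls through to the score
  expect_equal(assign_level(TRUE, 95, TRUE, 0.07, 1, 2), 2L)   # RT out
  expect_equal(assign_level(TRUE, 95, TRUE, 0.03, 6, 2), 2L)   # precursor
  expect_equal(assign_level(TRUE, 95, TRUE, 0.03, 1, 6), 2L)   # product

  # property: total function, always one level in 1..5
  set.seed(42)
  for (i in 1:200) {
    lv <- assign_level(
      has_ms2 = sample(c(TRUE, FALSE), 1),
      score = sample(c(NA, runif(1, 0, 100)), 1),
      is_standard = sample(c(TRUE, FALSE), 1),
      rt_error = sample(c(NA, runif(1, 0, 0.2)), 1),
      precursor_ppm = sample(c(NA, runif(1, 0, 10)), 1),
      max_product_ppm = sample(c(NA, runif(1, 0, 10)), 1))
    expect_true(lv %in% 1:5)
  }
})

test_that("source attribution copies category sets", {
  sp <- spec2(100, 1)
  multi <- library_entry("d-camphor-like", sp,
                         sources = c("drug", "natural_product",
                                     "personal_care_product"))
  expect_setequal(attribute_sources(multi),
                  c("drug", "natural_product", "personal_care_product"))
  expect_equal(attribute_sources(library_entry("x", sp)), "unknown")
  expect_equal(attribute_sources(
    library_entry("y", sp, sources = "exogenous_contaminant")),
    "exogenous_contaminant")
})

test_that("annotate_spectra picks the best candidate and levels it", {
  q <- spec2(c(80, 120, 160, 240), c(100, 100, 100, 100), prec = 300,
             rt = 6.0)
  lib <- list(
    library_entry("exact", spec2(c(80, 120, 160, 240), c(100, 100, 100,
                                                         100), prec = 300),
                  sources = "endogenous_metabolite"),
    library_entry("partial", spec2(c(80, 120, 160, 600), c(100, 100, 100,
                                                           100),
                                   prec = 300.0005)))
  ann <- annotate_spectra(list(f1 = q), lib)
  expect_equal(ann$compound_name, "exact")
  expect_equal(ann$match_score, 100)
  expect_equal(ann$level, 2L)
  expect_equal(ann$sources, "endogenous_metabolite")

  # one-fragment spectrum -> Level 5, no candidate
  ann5 <- annotate_spectra(list(f2 = spec2(80, 100, prec = 300)), lib)
  expect_equal(ann5$level, 5L)
  expect_true(is.na(ann5$compound_name))

  # nothing in the precursor window -> Level 4
  ann4 <- annotate_spectra(list(f3 = spec2(c(80, 120), c(1, 1),
                                           prec = 500, rt = 1)), lib)
  expect_equal(ann4$level, 4L)

  # authentic standard with RT -> Level 1
  lib1 <- list(library_entry("std", spec2(c(80, 120, 160, 240),
                                          c(100, 100, 100, 100),
                                          prec = 300),
                             rt = 6.02, is_authentic_standard = TRUE))
  ann1 <- annotate_spectra(list(f1 = q), lib1)
  expect_equal(ann1$level, 1L)
})

test_that("annotation transfer obeys tolerances, tie rule and the
           brute-force oracle", {
  samples <- make_samples(4)
  feats <- make_table(matrix(1e5, 3, 4, dimnames = list(c("g1", "g2",
                                                          "g3"), NULL)),
                      mz = c(283.17556, 283.17600, 150.0),
                      rt = c(10.05, 10.04, 2.0), samples = samples)
  ann <- data.frame(query_id = "q1", precursor_mz = 283.17550, rt = 10.00,
                    compound_name = "peg-n6", formula = "",
                    match_score = 95, level = 2L, sources = "drug",
                    precursor_ppm = 0.2, rt_error = NA,
                    n_matched_fragments = 4, stringsAsFactors = FALSE)
  out <- transfer_annotations(feats, ann)
  # worked example: 0.21 ppm, 0.05 min -> attached; g2 (1.8 ppm) loses
  expect_equal(out$table$features$annotation_name,
               c("peg-n6", NA, NA))
  expect_equal(nrow(out$unmatched), 0)

  # RT 0.15 min away: not attached
  ann2 <- ann; ann2$rt <- 10.20
  out2 <- transfer_annotations(feats, ann2)
  expect_true(all(is.na(out2$table$features$annotation_name)))
  expect_equal(nrow(out2$unmatched), 1)

  # randomized oracle equivalence (up to 1000 features)
  set.seed(7)
  nf <- 1000
  big <- make_table(matrix(1e5, nf, 4), mz = runif(nf, 100, 600),
                    rt = runif(nf, 0.5, 14), samples = samples)
  pick <- sample(nf, 60)
  anns <- data.frame(
    query_id = sprintf("q%02d", 1:60),
    precursor_mz = big$features$mz[pick] *
      (1 + runif(60, -3e-6, 3e-6)),
    rt = big$features$rt[pick] + runif(60, -0.15, 0.15),
    compound_name = sprintf("c%02d", 1:60), formula = "",
    match_score = runif(60, 50, 100), level = 2L, sources = "drug",
    precursor_ppm = NA, rt_error = NA, n_matched_fragments = 3,
    stringsAsFactors = FALSE)
  got <- transfer_annotations(big, anns)$table$features
  want <- oracle_transfer(big$features, anns)
  for (k in seq_len(nrow(anns))) {
    if (is.na(want[k])) {
      expect_false(anns$compound_name[k] %in% got$annotation_name)
    } else {
      expect_equal(
        got$annotation_name[match(want[k], got$feature_id)],
        anns$compound_name[k])
    }
  }
})

test_that("detection frequency by group splits by outcome and matrix", {
  samples <- make_samples(10, n_preterm = 4)
  ab <- matrix(NA_real_, 2, 10, dimnames = list(c("A", "B"), NULL))
  ab[1, samples$outcome == "preterm"] <- 1e5   # preterm-only compound
  ab[2, ] <- 1e5
  ft <- make_table(ab, samples = samples)
  ft$features$annotation_name <- c("only-preterm", "everywhere")
  ft$features$annotation_level <- c(2L, 2L)
  ft$features$annotation_score <- 95
  ft$features$annotation_sources <- "drug"
  out <- detection_frequency_by_group(ft)
  expect_equal(out$pct_preterm[out$compound == "only-preterm"], 100)
  expect_equal(out$pct_term[out$compound == "only-preterm"], 0)
  expect_equal(out$pct_preterm[out$compound == "everywhere"], 100)

  # empty group reported as missing
  s1 <- samples; s1$outcome <- "term"
  ft1 <- ft; ft1$samples <- s1
  out1 <- detection_frequency_by_group(ft1)
  expect_false("pct_preterm" %in% names(out1))
})
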