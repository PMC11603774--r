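# table with annotation columns set directly, for network unit tests
annotated_table <- function(logmat, sources, levels = 2L,
                            samples = NULL) {
  ft <- make_table(10^logmat, samples = samples)
  ft$features$annotation_name <- paste0("cmpd_",
                                        ft$features$feature_id)
  ft$features$annotation_level <- rep_len(levels, nrow(logmat))
  ft$features$annotation_score <- 95
  ft$features$annotation_sources <- sources
  ft
}

test_that("edges follow the absolute-correlation rule with sign", {
  endo_log <- log10(c(1, 2, 3, 4) * 1e4)
  logm <- rbind(endo = endo_log,
                up = endo_log + log10(2),  # x doubled: r = +1
                down = 10 - endo_log)      # anti-proportional: r = -1
  ft <- annotated_table(logm, c("endogenous_metabolite",
                                "exogenous_contaminant", "drug"))
  net <- build_network(ft, r_threshold = 0.5)
  expect_equal(nrow(net$nodes), 3)
  expect_setequal(net$nodes$category,
                  c("endogenous", "exogenous", "exogenous"))
  e <- net$edges
  up <- e[e$to == "up" | e$from == "up", ]
  down <- e[e$to == "down" | e$from == "down", ]
  expect_equal(up$r[1], 1)
  expect_equal(up$sign[1], "positive")
  expect_equal(down$r[1], -1)
  expect_equal(down$sign[1], "negative")
  # exogenous-exogenous pairs are never candidates
  expect_false(any(e$from == "up" & e$to == "down" |
                     e$from == "down" & e$to == "up"))
  expect_error(build_network(ft_subset(ft, samples = 1:2)),
               ">= 3 samples")
})

test_that("only the allowed annotation levels become nodes", {
  set.seed(2)
  logm <- matrix(rnorm(4 * 10, 5, 0.3), 4, 10)
  ft <- annotated_table(logm, "endogenous_metabolite",
                        levels = c(1L, 2L, 3L, 4L))
  ft$features$annotation_name[4] <- NA
  ft$features$annotation_level[4] <- NA
  net <- build_network(ft)
  expect_setequal(net$nodes$level, c(1L, 2L))
})

test_that("network equals the brute-force oracle on random instances", {
  set.seed(19)
  for (rep in 1:3) {
    nf <- 40; n <- 30
    logm <- matrix(rnorm(nf * n, 5, 0.3), nf, n)
    # plant a correlated pair so some edges exist
    logm[2, ] <- logm[1, ] + rnorm(n, 0, 0.1)
    src <- sample(c("endogenous_metabolite", "exogenous_contaminant",
                    "drug", ""), nf, replace = TRUE)
    ft <- annotated_table(logm, src)
    net <- build_network(ft, r_threshold = 0.5)
    want <- oracle_network(ft_log10(ft), categorize_sources(src), 0.5)
    got_keys <- paste(net$edges$from, net$edges$to)
    want_keys <- if (is.null(want)) character(0)
                 else paste(want$from, want$to)
    expect_setequal(got_keys, want_keys)
    if (length(want_keys))
      expect_equal(net$edges$r[match(want_keys, got_keys)], want$r,
                   tolerance = 1e-12)
  }
})

test_that("removing a node leaves remaining edge weights unchanged", {
  set.seed(4)
  logm <- matrix(rnorm(6 * 50, 5, 0.3), 6, 50)
  logm[2, ] <- logm[1, ] * 0.9 + rnorm(50, 0, 0.05)
  logm[4, ] <- logm[3, ] * 0.9 + rnorm(50, 0, 0.05)
  ft <- annotated_table(logm, rep(c("endogenous_metabolite",
                                    "exogenous_contaminant"), 3))
  full <- build_network(ft, r_threshold = 0.3)
  sub <- build_network(ft_subset(ft, features = 1:5), r_threshold = 0.3)
  shared <- merge(full$edges, sub$edges, by = c("from", "to"))
  expect_gt(nrow(shared), 0)
  expect_equal(shared$r.x, shared$r.y, tolerance = 1e-12)
})

test_that("independent features essentially never form edges at n=95", {
  set.seed(6)
  n <- 95
  logm <- matrix(rnorm(60 * n, 5, 0.3), 60, n)
  ft <- annotated_table(logm, rep(c("endogenous_metabolite",
                                    "exogenous_contaminant"), 30))
  net <- build_network(ft, r_threshold = 0.5)
  # 30*30 + choose(30,2) = 1335 candidate pairs, null edge prob ~1e-6
  expect_lt(nrow(net$edges) / 1335, 0.01)
})

test_that("group proportions give per-node detection pies", {
  samples <- make_samples(10, n_preterm = 5)
  ab <- matrix(NA_real_, 2, 10, dimnames = list(c("A", "B"), NULL))
  ab[1, c(1:5, 6:8)] <- 1e5          # 5 preterm + 3 term detections
  ab[2, samples$outcome == "term"] <- 1e5
  ft <- make_table(ab, samples = samples)
  ft$features$annotation_name <- c("a", "b")
  ft$features$annotation_level <- 2L
  ft$features$annotation_score <- 95
  ft$features$annotation_sources <- c("endogenous_metabolite",
                                      "exogenous_contaminant")
  # impute so correlations are defined, then build on the detected mask
  net <- build_network(impute_below_mdl(ft, seed = 1), r_threshold = 0.99)
  net <- group_proportions(net, impute_below_mdl(ft, seed = 1))
  i <- match(c("A", "B"), net$nodes$id)
  expect_equal(net$nodes$pct_preterm[i], c(5 / 8 * 100, 0))
  expect_equal(net$nodes$pct_term[i], c(3 / 8 * 100, 100))
  expect_equal(rowSums(cbind(net$nodes$pct_preterm,
                             net$nodes$pct_term)[i, ]), c(100, 100))
})

test_that("a never-detected node warns and reports missing proportions", {
  samples <- make_samples(6)
  ab <- matrix(c(rep(1e5, 6), rep(5e2, 6)), 2, 6, byrow = TRUE,
               dimnames = list(c("A", "B"), NULL))
  ft <- make_table(ab, samples = samples)
  ft$features$annotation_name <- c("a", "b")
  ft$features$annotation_level <- 2L
  ft$features$annotation_score <- 95
  ft$features$annotation_sources <- "endogenous_metabolite"
  net <- build_network(ft, r_threshold = 0.999)
  expect_warning(out <- group_proportions(net, ft), "never detected")
  expect_true(is.na(out$nodes$pct_preterm[match("B", out$nodes$id)]))
})
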