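#' Generate synthetic ESI+/ESI- feature tables with planted ground truth
#'
#' Abundances are simulated on the log10 scale: each feature has a latent
#' mean and standard deviation, a per-matrix (serum/urine) offset, additive
#' per-batch shifts plus per-batch residual scaling (exactly the model the
#' parametric batch correction assumes), and censoring to missing of any
#' measured area below the method detection limit. Planted structure:
#' preterm/term differential features in serum, cross-polarity `[M+H]+` /
#' `[M-H]-` pairs of shared neutral molecules (plus decoy near-pairs that
#' violate a merge tolerance), positive-mode adduct satellites linked to
#' their parents, latent-factor correlation clusters, and blank-artifact
#' features whose laboratory-blank areas rival their sample areas.
#'
#' @param config a [sim_config()].
#' @param manifest sample manifest from [generate_cohort()].
#' @return list with `pos` and `neg` (`feature_table`s), `blanks` (list of
#'   two matrices, features x 3 laboratory blanks), and `truth` (planted
#'   ground truth: differential ids, pair map, decoy pairs, adduct map,
#'   cluster memberships and source tags, batch parameters, blank artifact
#'   ids, and the uncensored latent log10 matrices).
#' @export
generate_feature_tables <- function(config, manifest) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 1L, {
    h <- hydrogen_mass()
    n_s <- nrow(manifest)
    is_urine <- manifest$matrix == "urine"
    is_serum <- !is_urine
    is_preterm <- manifest$outcome == "preterm"
    batch <- manifest$batch
    nc <- config$n_corr_clusters
    csz <- config$cluster_size

    # ---- positive-mode feature layout ---------------------------------
    np <- config$n_features_pos
    idx <- 0L
    take <- function(k) { out <- idx + seq_len(k); idx <<- idx + k; out }
    i_pair_p <- take(config$n_shared_neutrals)
    i_decoy_p <- take(config$n_decoys)
    i_clust <- take(nc * csz)
    i_diff <- take(config$n_differential)
    i_blankart <- take(config$n_blank_artifacts)
    i_bg_p <- (idx + 1L):np

    pos_id <- sprintf("F_P%04d", seq_len(np))
    nn <- config$n_features_neg
    neg_id <- sprintf("F_N%04d", seq_len(nn))
    i_pair_n <- seq_len(config$n_shared_neutrals)
    i_decoy_n <- config$n_shared_neutrals + seq_len(config$n_decoys)

    # ---- m/z and RT ---------------------------------------------------
    pos_mz <- round(runif(np, 100, 600), 5)
    pos_rt <- round(runif(np, 0.5, 14), 3)
    neg_mz <- round(runif(nn, 100, 600), 5)
    neg_rt <- round(runif(nn, 0.5, 14), 3)

    # true cross-polarity pairs: shared neutral mass, RT within 0.5 min
    M_pair <- runif(config$n_shared_neutrals, 150, 550)
    pos_mz[i_pair_p] <- round(M_pair + h, 5)
    neg_mz[i_pair_n] <- round(M_pair - h, 5)
    neg_rt[i_pair_n] <- round(pos_rt[i_pair_p] +
                                runif(config$n_shared_neutrals, -0.2, 0.2), 3)

    # decoys violating exactly one tolerance each
    decoy_type <- rep(c("mass", "rt"), length.out = config$n_decoys)
    M_dec <- runif(config$n_decoys, 150, 550)
    pos_mz[i_decoy_p] <- round(M_dec + h, 5)
    for (k in seq_len(config$n_decoys)) {
      if (decoy_type[k] == "mass") {
        err <- sample(c(-1, 1), 1) * runif(1, 10, 20) * 1e-6
        neg_mz[i_decoy_n[k]] <- round(M_dec[k] * (1 + err) - h, 5)
        neg_rt[i_decoy_n[k]] <- round(pos_rt[i_decoy_p[k]] +
                                        runif(1, -0.2, 0.2), 3)
      } else {
        neg_mz[i_decoy_n[k]] <- round(M_dec[k] - h, 5)
        neg_rt[i_decoy_n[k]] <- round(pos_rt[i_decoy_p[k]] +
                                        sample(c(-1, 1), 1) *
                                        runif(1, 0.6, 1.0), 3)
      }
    }
    neg_rt <- pmax(neg_rt, 0.1)

    # ---- latent abundance model --------------------------------------
    well_detected_p <- logical(np)
    well_detected_p[c(i_clust, i_diff)] <- TRUE
    diff_shift10 <- config$effect_log2fc * log10(2)

    sim_mode <- function(n_f, well_detected, cluster_of = NULL,
                         diff_idx = integer(0)) {
      sigma <- runif(n_f, 0.25, 0.45)
      log_mdl <- if (config$mdl > 0) log10(config$mdl) else -Inf
      mat_off <- rnorm(n_f, 0, 0.3)
      if (config$mdl > 0 && config$missing_rate > 0) {
        p_f <- ifelse(well_detected,
                      runif(n_f, 0, min(config$missing_rate, 0.1)),
                      runif(n_f, 0, 2 * config$missing_rate))
        p_f <- pmin(pmax(p_f, 1e-4), 0.9)
        # p_f is a ceiling on the censoring fraction in either matrix:
        # anchor mu so the lower of the two matrix means still satisfies it
        mu <- log_mdl - sigma * qnorm(p_f) - pmin(mat_off, 0)
      } else {
        mu <- runif(n_f, 5, 7)
      }
      eps <- matrix(rnorm(n_f * n_s), n_f, n_s)
      if (!is.null(cluster_of)) {
        u <- matrix(rnorm(nc * n_s), nc, n_s)
        for (f in which(!is.na(cluster_of))) {
          eps[f, ] <- sqrt(config$cluster_r) * u[cluster_of[f], ] +
            sqrt(1 - config$cluster_r) * eps[f, ]
        }
      }
      lat <- mu + outer(mat_off, as.numeric(is_urine)) +
        sweep(sweep(eps, 1, sigma, `*`), 2,
              config$batch_scale[batch], `*`) +
        matrix(config$batch_shift[batch], n_f, n_s, byrow = TRUE)
      if (length(diff_idx))
        lat[diff_idx, is_serum & is_preterm] <-
          lat[diff_idx, is_serum & is_preterm] + diff_shift10
      lat
    }

    cluster_of <- rep(NA_integer_, np)
    cluster_of[i_clust] <- rep(seq_len(nc), each = csz)
    lat_pos <- sim_mode(np, well_detected_p, cluster_of, i_diff)
    lat_neg <- sim_mode(nn, logical(nn))

    # adduct satellites: constant abundance ratio to their parent
    adduct_map <- character(0)
    if (config$n_adducts > 0) {
      parents <- sample(i_bg_p, min(config$n_adducts, length(i_bg_p)))
      sat_id <- sprintf("F_PA%03d", seq_along(parents))
      ratio <- runif(length(parents), 0.1, 0.5)
      lat_sat <- lat_pos[parents, , drop = FALSE] + log10(ratio)
      lat_pos <- rbind(lat_pos, lat_sat)
      pos_id_all <- c(pos_id, sat_id)
      pos_mz_all <- c(pos_mz, round(pos_mz[parents] + 21.98194, 5))
      pos_rt_all <- c(pos_rt, pos_rt[parents])
      adduct_link <- c(rep(NA_character_, np), pos_id[parents])
      adduct_map <- setNames(pos_id[parents], sat_id)
    } else {
      pos_id_all <- pos_id; pos_mz_all <- pos_mz; pos_rt_all <- pos_rt
      adduct_link <- rep(NA_character_, np)
    }

    censor <- function(lat) {
      a <- 10^lat
      if (config$mdl > 0 && config$missing_rate > 0) a[a < config$mdl] <- NA
      a
    }
    ab_pos <- censor(lat_pos)
    ab_neg <- censor(lat_neg)
    dimnames(ab_pos) <- list(pos_id_all, manifest$sample_id)
    dimnames(ab_neg) <- list(neg_id, manifest$sample_id)
    dimnames(lat_pos) <- dimnames(ab_pos)
    dimnames(lat_neg) <- dimnames(ab_neg)

    # laboratory blanks (3 HPLC-water injections per mode)
    mk_blanks <- function(n_f, ids, artifact_idx = integer(0),
                          sample_mean = NULL) {
      b <- matrix(10^rnorm(n_f * 3, 2.5, 0.3), n_f, 3,
                  dimnames = list(ids, paste0("BLK", 1:3)))
      if (length(artifact_idx))
        b[artifact_idx, ] <- matrix(
          sample_mean[artifact_idx] * runif(length(artifact_idx) * 3,
                                            0.9, 1.1),
          length(artifact_idx), 3)
      b
    }
    blanks_pos <- mk_blanks(length(pos_id_all), pos_id_all, i_blankart,
                            rowMeans(ab_pos, na.rm = TRUE))
    blanks_neg <- mk_blanks(nn, neg_id)

    mk_table <- function(ids, mz, rt, mode, link, ab) {
      feature_table(
        features = data.frame(feature_id = ids, mz = mz, rt = rt,
                              ion_mode = mode, adduct_link = link,
                              stringsAsFactors = FALSE),
        abundance = ab,
        samples = manifest
      )
    }
    pos <- mk_table(pos_id_all, pos_mz_all, pos_rt_all, "positive",
                    adduct_link, ab_pos)
    neg <- mk_table(neg_id, neg_mz, neg_rt, "negative",
                    rep(NA_character_, nn), ab_neg)

    clusters <- split(pos_id[i_clust], rep(seq_len(nc), each = csz))
    cluster_sources <- setNames(
      rep_len(c("endogenous_metabolite", "exogenous_contaminant"),
              length(i_clust)),
      pos_id[i_clust])

    truth <- list(
      differential_feature_ids = pos_id[i_diff],
      pair_map = setNames(neg_id[i_pair_n], pos_id[i_pair_p]),
      decoy_pairs = data.frame(pos = pos_id[i_decoy_p],
                               neg = neg_id[i_decoy_n],
                               type = decoy_type, stringsAsFactors = FALSE),
      adduct_map = adduct_map,
      cluster_memberships = clusters,
      cluster_sources = cluster_sources,
      batch_params = list(shift = config$batch_shift,
                          scale = config$batch_scale),
      blank_artifact_ids = pos_id[i_blankart],
      latent = list(pos = lat_pos, neg = lat_neg),
      effect_log2fc = config$effect_log2fc
    )
    list(pos = pos, neg = neg,
         blanks = list(pos = blanks_pos, neg = blanks_neg),
         truth = truth)
  })
}

#' Null-plus-planted simulation for FDR calibration
#'
#' A lean single-matrix design used to measure empirical false-discovery
#' rates of the differential-testing procedure: `n_features` independent
#' log10-normal features over `n_samples` samples split into two outcome
#' groups, with `n_planted` features given a group-mean shift of
#' `effect_log2fc` on the log2 scale. No censoring, batches, or clusters.
#'
#' @param n_samples total samples (default 95, the cohort size).
#' @param n_group1 size of the first (preterm) group; default 35.
#' @param n_features number of features.
#' @param n_planted number of truly differential features.
#' @param effect_log2fc planted log2 fold change.
#' @param sd_log10 residual standard deviation on the log10 scale.
#' @param seed integer seed.
#' @return list with `abundance` (linear-scale matrix features x samples),
#'   `groups` (character vector "preterm"/"term"), `planted` (row indices of
#'   true effects).
#' @export
simulate_null_planted <- function(n_samples = 95, n_group1 = 35,
                                  n_features = 1000, n_planted = 100,
                                  effect_log2fc = 2, sd_log10 = 0.3,
                                  seed = 1L) {
  with_seed(seed, {
    groups <- c(rep("preterm", n_group1), rep("term", n_samples - n_group1))
    mu <- runif(n_features, 5, 7)
    lat <- mu + matrix(rnorm(n_features * n_samples, 0, sd_log10),
                       n_features, n_samples)
    planted <- seq_len(n_planted)
    lat[planted, groups == "preterm"] <-
      lat[planted, groups == "preterm"] + effect_log2fc * log10(2)
    dimnames(lat) <- list(sprintf("F%04d", seq_len(n_features)),
                          sprintf("S%03d", seq_len(n_samples)))
    list(abundance = 10^lat, groups = groups, planted = planted)
  })
}
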