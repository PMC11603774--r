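#' Simulation configuration
#'
#' Defines the "stated world" the synthetic cohort emulates: 95 mother
#' participants each contributing one serum and one urine sample, 35 preterm
#' outcomes, an instrumental run split over 4 batches with additive
#' (log-scale) location shifts and multiplicative variance scaling, censoring
#' of areas below a method detection limit, planted preterm/term differential
#' features, cross-polarity ion pairs sharing a neutral molecule, adduct
#' satellites, decoy near-pairs, and latent-factor correlation clusters.
#'
#' @param n_samples number of participants (sample pairs).
#' @param n_preterm number of preterm outcomes among participants.
#' @param n_batches number of instrument batches; pairs are assigned
#'   round-robin.
#' @param n_features_pos,n_features_neg base feature counts per ESI mode
#'   (excluding adduct satellites).
#' @param n_shared_neutrals features planted in both polarities as
#'   `[M+H]+` / `[M-H]-` of a shared neutral molecule.
#' @param n_decoys near-pairs that violate at least one merge tolerance
#'   (mass error 10-20 ppm or delta-RT 0.6-1.0 min), to exercise rejection.
#' @param n_adducts extra positive-mode satellites carrying an
#'   `adduct_link` to their parent feature.
#' @param n_differential features with a planted preterm/term group-mean
#'   difference in serum.
#' @param effect_log2fc planted log2 fold change for differential features.
#' @param batch_shift per-batch additive offsets on the log10 scale.
#' @param batch_scale per-batch multiplicative scaling of the residual
#'   standard deviation.
#' @param mdl method detection limit on the area scale; simulated areas
#'   below it are censored to missing. Matches the default noise floor.
#' @param missing_rate target mean fraction of censored cells for background
#'   features (per-feature censoring fractions are drawn uniformly on
#'   `(0, 2 * missing_rate)`). Planted differential and cluster features are
#'   treated as well-detected chemicals (fractions on `(0, min(missing_rate,
#'   0.1))`), reflecting that compounds carried through a 70% detection
#'   filter are detected in most samples.
#' @param n_corr_clusters number of planted correlation clusters.
#' @param cluster_size features per cluster.
#' @param cluster_r target pairwise Pearson correlation within a cluster,
#'   achieved through a shared latent factor.
#' @param n_blank_artifacts features planted with laboratory-blank areas
#'   comparable to sample areas (removed by blank filtering).
#' @param frac_ms2 fraction of features receiving a pooled-sample MS2
#'   spectrum.
#' @param creatinine_median,creatinine_gsd lognormal parameters (median
#'   mg/dL and geometric standard deviation) for urinary creatinine.
#' @param seed integer seed; all generator randomness derives from it.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 95, n_preterm = 35, n_batches = 4,
                       n_features_pos = 300, n_features_neg = 200,
                       n_shared_neutrals = 30, n_decoys = 10, n_adducts = 20,
                       n_differential = 40, effect_log2fc = 2,
                       batch_shift = c(0, 0.3, -0.2, 0.15),
                       batch_scale = c(1, 1.2, 0.9, 1.1),
                       mdl = 1e4, missing_rate = 0.1,
                       n_corr_clusters = 3, cluster_size = 6, cluster_r = 0.7,
                       n_blank_artifacts = 5, frac_ms2 = 0.5,
                       creatinine_median = 100, creatinine_gsd = 1.5,
                       seed = 1L) {
  cfg <- structure(as.list(environment()), class = "sim_config")
  if (n_preterm >= n_samples)
    stop("n_preterm must be < n_samples", call. = FALSE)
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must be in [0, 1)", call. = FALSE)
  if (abs(cluster_r) >= 1)
    stop("cluster_r must be in (-1, 1)", call. = FALSE)
  if (length(batch_shift) != n_batches || length(batch_scale) != n_batches)
    stop("batch_shift/batch_scale must have length n_batches", call. = FALSE)
  if (any(batch_scale <= 0))
    stop("batch_scale must be positive", call. = FALSE)
  n_special <- n_shared_neutrals + 2 * n_decoys + n_corr_clusters *
    cluster_size + n_differential + n_blank_artifacts
  if (n_special > n_features_pos)
    stop("n_features_pos too small for the planted structure (needs >= ",
         n_special, ")", call. = FALSE)
  if (n_shared_neutrals + n_decoys > n_features_neg)
    stop("n_features_neg too small for pairs + decoys", call. = FALSE)
  cfg
}

#' Generate a synthetic cohort manifest
#'
#' One serum and one urine record per participant; batch labels assigned
#' round-robin over batches (both members of a pair run in the same batch,
#' emulating urine analyzed alongside its paired serum); exactly
#' `n_preterm` preterm outcomes; urinary creatinine drawn lognormal.
#'
#' @param config a [sim_config()].
#' @return list with `manifest` (data.frame: sample_id, participant, matrix,
#'   batch, outcome, creatinine) and `truth` (list with the outcome and
#'   batch assignments).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n <- config$n_samples
    pid <- sprintf("P%03d", seq_len(n))
    batch <- ((seq_len(n) - 1L) %% config$n_batches) + 1L
    outcome <- rep("term", n)
    outcome[sample.int(n, config$n_preterm)] <- "preterm"
    creat <- rlnorm(n, meanlog = log(config$creatinine_median),
                    sdlog = log(config$creatinine_gsd))
    manifest <- rbind(
      data.frame(sample_id = paste0(pid, "_S"), participant = pid,
                 matrix = "serum", batch = batch, outcome = outcome,
                 creatinine = NA_real_, stringsAsFactors = FALSE),
      data.frame(sample_id = paste0(pid, "_U"), participant = pid,
                 matrix = "urine", batch = batch, outcome = outcome,
                 creatinine = creat, stringsAsFactors = FALSE)
    )
    rownames(manifest) <- NULL
    list(manifest = manifest,
         truth = list(outcome = setNames(outcome, pid),
                      batch = setNames(batch, pid)))
  })
}
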