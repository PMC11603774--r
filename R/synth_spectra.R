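#' Generate pooled-sample MS2 spectra and a matching spectral library
#'
#' Attaches synthetic fragment spectra to a fraction of positive-mode
#' features (emulating data-dependent MS2 on pooled samples) and writes a
#' library containing exact matches for some of them, partial matches whose
#' score falls in the probable/tentative band, near-misses scoring below the
#' candidate threshold, and a handful of authentic-standard entries with
#' reference retention times that support Level-1 confirmation. Every planted
#' correlation-cluster feature receives an exact library match carrying its
#' ground-truth source category, so the downstream network stage sees
#' annotated Level 1-2 endogenous and exogenous compounds.
#'
#' @param config a [sim_config()].
#' @param sim result of [generate_feature_tables()] (tables plus truth).
#' @return list with `spectra` (named list of [ms2_spectrum()], names are
#'   the originating feature ids), `library` (list of [library_entry()]),
#'   and `truth` (named role per feature: exact / standard / partial /
#'   near_miss / one_fragment / no_entry).
#' @export
generate_spectra <- function(config, sim) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 2L, {
    feats <- sim$pos$features
    truth <- sim$truth
    cl_ids <- unlist(truth$cluster_memberships, use.names = FALSE)
    diff_ids <- truth$differential_feature_ids
    other <- setdiff(feats$feature_id[is.na(feats$adduct_link)],
                     c(cl_ids, diff_ids, truth$blank_artifact_ids))
    n_extra <- max(0L, round(config$frac_ms2 * nrow(feats)) -
                     length(cl_ids) - length(diff_ids))
    extra <- sample(other, min(n_extra, length(other)))

    roles <- c(
      setNames(rep("exact", length(cl_ids)), cl_ids),
      setNames(sample(c("exact", "partial"), length(diff_ids),
                      replace = TRUE), diff_ids),
      setNames(sample(c("exact", "partial", "near_miss", "one_fragment",
                        "no_entry"), length(extra), replace = TRUE,
                      prob = c(0.4, 0.2, 0.2, 0.1, 0.1)), extra)
    )
    # a few exact matches double as in-house authentic standards
    exact_ids <- names(roles)[roles == "exact"]
    std_ids <- head(exact_ids, 6)
    roles[std_ids] <- "standard"

    spectra <- list()
    library <- list()
    for (fid in names(roles)) {
      role <- roles[[fid]]
      row <- feats[feats$feature_id == fid, ]
      prec <- row$mz * (1 + runif(1, -0.5, 0.5) * 1e-6)
      rt_q <- row$rt + runif(1, -0.02, 0.02)
      n_frag <- if (role == "one_fragment") 1L else sample(4:6, 1)
      equalize <- role %in% c("partial", "near_miss")
      frag <- data.frame(
        mz = round(sort(runif(n_frag, 50, max(51, prec - 1))), 4),
        intensity = if (equalize) rep(100, n_frag) else
          round(runif(n_frag, 20, 100), 1)
      )
      spectra[[fid]] <- ms2_spectrum(prec, frag, "positive", rt = rt_q)
      if (role %in% c("one_fragment", "no_entry")) next

      lib_frag <- switch(role,
        exact = , standard = frag,
        partial = {  # share all but one fragment -> score (n-1)/n in (50,90]
          f <- frag
          f$mz[n_frag] <- round(f$mz[n_frag] + 5 + runif(1, 0, 3), 4)
          f
        },
        near_miss = {  # share a single fragment -> score 1/n < 50
          f <- frag
          keep <- sample(n_frag, 1)
          shift <- setdiff(seq_len(n_frag), keep)
          f$mz[shift] <- round(f$mz[shift] + 5 + runif(length(shift), 0, 3),
                               4)
          f
        })
      srcs <- if (fid %in% names(truth$cluster_sources)) {
        truth$cluster_sources[[fid]]
      } else if (runif(1) < 0.2) {
        character(0)  # unknown origin
      } else {
        sample(.SOURCE_CATEGORIES, sample(1:2, 1))
      }
      library[[length(library) + 1L]] <- library_entry(
        name = paste0("CMPD_", fid),
        spectrum = ms2_spectrum(row$mz, lib_frag, "positive"),
        neutral_mass = row$mz - hydrogen_mass(),
        rt = if (role == "standard") row$rt + runif(1, -0.02, 0.02)
             else NA_real_,
        sources = srcs,
        is_authentic_standard = role == "standard"
      )
    }
    list(spectra = spectra, library = library, truth = roles)
  })
}
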