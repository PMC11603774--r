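#' Remove adduct satellites linked to other ions
#'
#' Features whose `adduct_link` points (directly or through a chain of
#' links) to another feature are dropped; link roots are retained. A link to
#' an id absent from the table is a validation error.
#'
#' @param table a [feature_table()].
#' @return filtered `feature_table`; the number of dropped features is
#'   recorded in `attr(x, "n_dropped")`.
#' @export
remove_linked_adducts <- function(table) {
  f <- table$features
  if (!"adduct_link" %in% names(f) || all(is.na(f$adduct_link))) {
    attr(table, "n_dropped") <- 0L
    return(table)
  }
  link <- f$adduct_link
  bad <- !is.na(link) & !(link %in% f$feature_id)
  if (any(bad))
    stop("adduct_link points to missing feature id: ",
         link[bad][1], call. = FALSE)
  keep <- is.na(link)  # roots of every link chain
  out <- ft_subset(table, features = which(keep))
  attr(out, "n_dropped") <- sum(!keep)
  bl <- attr(table, "blanks")
  if (!is.null(bl)) attr(out, "blanks") <- bl[keep, , drop = FALSE]
  out
}

#' Filter features by laboratory-blank contamination
#'
#' A feature is dropped when its mean blank area reaches
#' `ratio_threshold` times its mean sample area (missing treated as
#' non-detected, i.e. excluded from the sample mean). A blank mean of zero
#' always keeps the feature.
#'
#' @param table a [feature_table()].
#' @param blanks numeric matrix features x blank injections (defaults to the
#'   table's `"blanks"` attribute); must be nonempty.
#' @param ratio_threshold blank-to-sample mean ratio at which a feature is
#'   considered background (default 1/3).
#' @return filtered `feature_table`.
#' @export
filter_blanks <- function(table, blanks = attr(table, "blanks"),
                          ratio_threshold = 1 / 3) {
  if (is.null(blanks) || ncol(blanks) == 0L)
    stop("blank set is empty", call. = FALSE)
  if (nrow(blanks) != nrow(table$features))
    stop("blank matrix rows must match features", call. = FALSE)
  blank_mean <- rowMeans(blanks, na.rm = TRUE)
  blank_mean[is.nan(blank_mean)] <- 0
  sample_mean <- rowMeans(table$abundance, na.rm = TRUE)
  sample_mean[is.nan(sample_mean)] <- 0
  keep <- blank_mean < ratio_threshold * sample_mean | blank_mean == 0
  out <- ft_subset(table, features = which(keep))
  attr(out, "n_dropped") <- sum(!keep)
  attr(out, "blanks") <- blanks[keep, , drop = FALSE]
  out
}

#' Apply the detection-frequency cutoff
#'
#' "Detected" means a non-missing area above the instrument noise floor
#' (both conditions). Features detected in at least `cutoff_fraction` of
#' samples (inclusive) are retained; the per-feature detection frequency is
#' stored in the `detection_frequency` feature column.
#'
#' @param table a [feature_table()].
#' @param cutoff_fraction minimum detection frequency in (0, 1]
#'   (default 0.70).
#' @param noise_floor minimum real-signal peak area (default 10000).
#' @return filtered `feature_table`.
#' @export
apply_frequency_cutoff <- function(table, cutoff_fraction = 0.70,
                                   noise_floor = 1e4) {
  if (cutoff_fraction < 0 || cutoff_fraction > 1)
    stop("cutoff_fraction must be in [0, 1]", call. = FALSE)
  det <- !is.na(table$abundance) & table$abundance > noise_floor
  freq <- rowMeans(det)
  keep <- freq >= cutoff_fraction & freq > 0
  out <- ft_subset(table, features = which(keep))
  out$features$detection_frequency <- freq[keep]
  attr(out, "n_dropped") <- sum(!keep)
  bl <- attr(table, "blanks")
  if (!is.null(bl)) attr(out, "blanks") <- bl[keep, , drop = FALSE]
  out
}

#' Keep only features with informative MS2 spectra
#'
#' @param features character vector of feature ids (or a `feature_table`).
#' @param spectra named list of [ms2_spectrum()] keyed by feature id.
#' @param min_fragments minimum fragment count (default 2).
#' @return subset of feature ids (or of the table) having a spectrum with
#'   at least `min_fragments` fragments.
#' @export
require_product_ions <- function(features, spectra, min_fragments = 2) {
  ids <- if (inherits(features, "feature_table"))
    features$features$feature_id else features
  n_frag <- vapply(ids, function(id) {
    s <- spectra[[id]]
    if (is.null(s)) 0L else nrow(s$fragments)
  }, integer(1))
  keep <- n_frag >= min_fragments
  if (inherits(features, "feature_table")) {
    out <- ft_subset(features, features = which(keep))
    attr(out, "n_dropped") <- sum(!keep)
    out
  } else ids[keep]
}

#' Merge ESI+ and ESI- feature tables by shared neutral mass
#'
#' Neutral mass is `mz - 1.00782` for positive mode and `mz + 1.00782` for
#' negative mode (one monoisotopic hydrogen atom). Candidate cross-polarity
#' pairs satisfying mass error <= `ppm_tol` and |delta RT| < `rt_tol` are
#' matched one-to-one greedily by ascending ppm error, ties broken by
#' smaller RT difference, then lexicographically smaller positive feature
#' id. For a merged pair, the abundance row whose mode has the higher
#' median area feeds downstream statistics; the partner's areas are kept in
#' the merge record. Unpaired features pass through unchanged.
#'
#' @param pos,neg `feature_table`s sharing the same sample set.
#' @param ppm_tol mass tolerance in ppm (default 5).
#' @param rt_tol retention-time tolerance in minutes, exclusive
#'   (default 0.5).
#' @param h_mass hydrogen atom mass used for neutralization
#'   (default [hydrogen_mass()]).
#' @return list with `table` (merged `feature_table`) and `merges`
#'   (data.frame of merge records: ids, neutral masses, ppm error, delta
#'   RT, chosen mode).
#' @export
merge_esi_modes <- function(pos, neg, ppm_tol = 5, rt_tol = 0.5,
                            h_mass = hydrogen_mass()) {
  if (!identical(pos$samples$sample_id, neg$samples$sample_id))
    stop("positive and negative tables must share the same samples",
         call. = FALSE)
  fp <- pos$features; fn <- neg$features
  mp <- fp$mz - h_mass
  mn <- fn$mz + h_mass

  # candidate pairs within tolerance (block by coarse mass bin for speed)
  cand <- NULL
  if (nrow(fp) && nrow(fn)) {
    ord_n <- order(mn)
    mn_s <- mn[ord_n]
    rows <- vector("list", nrow(fp))
    for (i in seq_len(nrow(fp))) {
      w <- mp[i] * ppm_tol * 1e-6 * 1.5
      lo <- findInterval(mp[i] - w, mn_s) + 1L
      hi <- findInterval(mp[i] + w, mn_s)
      if (hi < lo) next
      j <- ord_n[lo:hi]
      ppm <- ppm_error(mp[i], mn[j])
      drt <- abs(fp$rt[i] - fn$rt[j])
      ok <- ppm <= ppm_tol & drt < rt_tol
      if (any(ok))
        rows[[i]] <- data.frame(pi = i, ni = j[ok], ppm = ppm[ok],
                                drt = drt[ok])
    }
    cand <- do.call(rbind, rows)
  }

  merges <- data.frame(pos_feature_id = character(0),
                       neg_feature_id = character(0),
                       neutral_mass_pos = numeric(0),
                       neutral_mass_neg = numeric(0),
                       mass_error_ppm = numeric(0), delta_rt = numeric(0),
                       kept_mode = character(0), stringsAsFactors = FALSE)
  if (!is.null(cand) && nrow(cand)) {
    cand <- cand[order(cand$ppm, cand$drt, fp$feature_id[cand$pi],
                       fn$feature_id[cand$ni]), , drop = FALSE]
    used_p <- logical(nrow(fp)); used_n <- logical(nrow(fn))
    sel <- logical(nrow(cand))
    for (k in seq_len(nrow(cand))) {
      i <- cand$pi[k]; j <- cand$ni[k]
      if (!used_p[i] && !used_n[j]) {
        used_p[i] <- TRUE; used_n[j] <- TRUE; sel[k] <- TRUE
      }
    }
    cand <- cand[sel, , drop = FALSE]
    med_p <- apply(pos$abundance[cand$pi, , drop = FALSE], 1, median,
                   na.rm = TRUE)
    med_n <- apply(neg$abundance[cand$ni, , drop = FALSE], 1, median,
                   na.rm = TRUE)
    merges <- data.frame(
      pos_feature_id = fp$feature_id[cand$pi],
      neg_feature_id = fn$feature_id[cand$ni],
      neutral_mass_pos = mp[cand$pi], neutral_mass_neg = mn[cand$ni],
      mass_error_ppm = cand$ppm, delta_rt = cand$drt,
      kept_mode = ifelse(!is.na(med_p) & (is.na(med_n) | med_p >= med_n),
                         "positive", "negative"),
      stringsAsFactors = FALSE)
  }

  # assemble merged table: paired features collapse to one record carrying
  # the higher-median mode's abundances; everything else passes through
  drop_p <- fp$feature_id %in%
    merges$pos_feature_id[merges$kept_mode == "negative"]
  drop_n <- fn$feature_id %in%
    merges$neg_feature_id[merges$kept_mode == "positive"]
  keep_pos <- ft_subset(pos, features = which(!drop_p))
  keep_neg <- ft_subset(neg, features = which(!drop_n))
  merged_ids <- c(merges$pos_feature_id, merges$neg_feature_id)
  feats <- rbind(keep_pos$features, keep_neg$features)
  feats$merged_partner <- NA_character_
  mpi <- match(merges$pos_feature_id, feats$feature_id)
  feats$merged_partner[mpi[!is.na(mpi)]] <-
    merges$neg_feature_id[!is.na(mpi)]
  mni <- match(merges$neg_feature_id, feats$feature_id)
  feats$merged_partner[mni[!is.na(mni)]] <-
    merges$pos_feature_id[!is.na(mni)]
  ab <- rbind(keep_pos$abundance, keep_neg$abundance)
  tab <- feature_table(feats, ab, pos$samples)
  list(table = tab, merges = merges)
}
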