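#' Weighted-cosine spectral match score
#'
#' Fragments of the two spectra are aligned greedily within
#' `fragment_tol_ppm`; the score is 100 times the cosine similarity of the
#' intensity-normalized fragment vectors with square-root intensity
#' weighting (`intensity^0.5 * mz^0`). Symmetric in its arguments: identical
#' spectra score 100, spectra sharing no fragment within tolerance score 0.
#'
#' @param query,library_entry an [ms2_spectrum()] each (a [library_entry()]
#'   is accepted for the second argument).
#' @param fragment_tol_ppm fragment m/z tolerance in ppm (default 10).
#' @return score in `[0, 100]`.
#' @export
spectral_match_score <- function(query, library_entry,
                                 fragment_tol_ppm = 10) {
  if (inherits(library_entry, "library_entry"))
    library_entry <- library_entry$spectrum
  fq <- query$fragments; fl <- library_entry$fragments
  if (nrow(fq) == 0L || nrow(fl) == 0L)
    stop("cannot score an empty spectrum", call. = FALSE)
  wq <- sqrt(fq$intensity); wl <- sqrt(fl$intensity)
  pairs <- match_fragments(fq$mz, fl$mz, fragment_tol_ppm)
  if (!nrow(pairs)) return(0)
  dot <- sum(wq[pairs$i] * wl[pairs$j])
  100 * dot / (sqrt(sum(wq^2)) * sqrt(sum(wl^2)))
}

# Greedy one-to-one fragment alignment by ascending ppm error.
match_fragments <- function(mz_a, mz_b, tol_ppm) {
  cand <- NULL
  for (i in seq_along(mz_a)) {
    ppm <- ppm_error(mz_a[i], mz_b)
    ok <- which(ppm <= tol_ppm)
    if (length(ok))
      cand <- rbind(cand, data.frame(i = i, j = ok, ppm = ppm[ok]))
  }
  if (is.null(cand))
    return(data.frame(i = integer(0), j = integer(0), ppm = numeric(0)))
  cand <- cand[order(cand$ppm), , drop = FALSE]
  used_a <- logical(length(mz_a)); used_b <- logical(length(mz_b))
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    if (!used_a[cand$i[k]] && !used_b[cand$j[k]]) {
      used_a[cand$i[k]] <- TRUE; used_b[cand$j[k]] <- TRUE
      keep[k] <- TRUE
    }
  }
  cand[keep, , drop = FALSE]
}

#' Assign a Schymanski-style identification confidence level
#'
#' Level 1: best match is an authentic standard whose reference RT is
#' within 0.05 min and whose precursor and all matched product ions are
#' within 5 ppm. Level 2: library spectrum match with score > 90.
#' Level 3: a candidate exists with 50 < score <= 90. Level 4: informative
#' MS2 (>= 2 fragments) but no candidate above 50. Level 5: no usable MS2.
#' The five branches partition the whole evidence space.
#'
#' @param has_ms2 does the feature have an MS2 spectrum with >= 2
#'   fragments?
#' @param score best match score (NA when no candidate).
#' @param is_standard is the best-matching entry an authentic standard with
#'   a reference RT?
#' @param rt_error |feature RT - reference RT| in minutes (NA if no
#'   reference RT).
#' @param precursor_ppm precursor mass error vs the best entry, ppm.
#' @param max_product_ppm largest ppm error over the matched product ions.
#' @param rt_tol,ion_tol_ppm Level-1 thresholds (defaults 0.05 min, 5 ppm).
#' @param score_l2,score_l3 score thresholds for Levels 2 and 3
#'   (defaults 90 and 50).
#' @return integer level 1-5.
#' @export
assign_level <- function(has_ms2, score = NA_real_, is_standard = FALSE,
                         rt_error = NA_real_, precursor_ppm = NA_real_,
                         max_product_ppm = NA_real_,
                         rt_tol = 0.05, ion_tol_ppm = 5,
                         score_l2 = 90, score_l3 = 50) {
  if (!isTRUE(has_ms2)) return(5L)
  if (is.na(score)) return(4L)
  if (isTRUE(is_standard) && !is.na(rt_error) && rt_error < rt_tol &&
      !is.na(precursor_ppm) && precursor_ppm < ion_tol_ppm &&
      !is.na(max_product_ppm) && max_product_ppm < ion_tol_ppm)
    return(1L)
  if (score > score_l2) return(2L)
  if (score > score_l3) return(3L)
  4L
}

#' Copy source categories from a library entry
#'
#' @param library_entry a [library_entry()].
#' @return its category set, or `"unknown"` when the entry carries none.
#' @export
attribute_sources <- function(library_entry) {
  if (length(library_entry$sources)) library_entry$sources else "unknown"
}

#' Annotate pooled MS2 spectra against a spectral library
#'
#' Each query spectrum is scored against every library entry of the same
#' ion mode whose precursor lies within `precursor_tol_ppm`; the best-
#' scoring entry becomes the candidate, a confidence level is assigned with
#' [assign_level()], and sources are copied with [attribute_sources()].
#' Spectra with fewer than `min_fragments` fragments are Level 5 (no usable
#' MS2) and receive no candidate.
#'
#' @param spectra named list of [ms2_spectrum()] (names are query ids).
#' @param library list of [library_entry()].
#' @param precursor_tol_ppm precursor window for candidate entries
#'   (default 10).
#' @param fragment_tol_ppm fragment alignment tolerance (default 10).
#' @param min_fragments minimum informative fragment count (default 2).
#' @param ... thresholds forwarded to [assign_level()].
#' @return data.frame of annotations: query id, precursor m/z, RT,
#'   compound name, formula, match score, level, sources (pipe-collapsed),
#'   and evidence columns (precursor ppm error, RT error, matched
#'   fragments).
#' @export
annotate_spectra <- function(spectra, library, precursor_tol_ppm = 10,
                             fragment_tol_ppm = 10, min_fragments = 2,
                             ...) {
  lib_prec <- vapply(library, function(e) e$spectrum$precursor_mz, 0)
  lib_mode <- vapply(library, function(e) e$spectrum$ion_mode, "")
  rows <- lapply(names(spectra), function(id) {
    q <- spectra[[id]]
    has_ms2 <- nrow(q$fragments) >= min_fragments
    best <- NULL; best_score <- NA_real_
    if (has_ms2 && length(library)) {
      cand <- which(lib_mode == q$ion_mode &
                      ppm_error(q$precursor_mz, lib_prec) <=
                      precursor_tol_ppm)
      for (ci in cand) {
        sc <- spectral_match_score(q, library[[ci]], fragment_tol_ppm)
        if (is.na(best_score) || sc > best_score) {
          best_score <- sc; best <- library[[ci]]
        }
      }
    }
    if (!is.null(best)) {
      pairs <- match_fragments(q$fragments$mz, best$spectrum$fragments$mz,
                               fragment_tol_ppm)
      prec_ppm <- ppm_error(q$precursor_mz, best$spectrum$precursor_mz)
      rt_err <- if (!is.na(best$rt) && !is.na(q$rt))
        abs(q$rt - best$rt) else NA_real_
      max_prod <- if (nrow(pairs)) max(pairs$ppm) else NA_real_
      level <- assign_level(has_ms2, best_score,
                            best$is_authentic_standard && !is.na(best$rt),
                            rt_err, prec_ppm, max_prod, ...)
      keep <- level <= 3  # a sub-threshold candidate is no identification
      data.frame(
        query_id = id, precursor_mz = q$precursor_mz, rt = q$rt,
        compound_name = if (keep) best$name else NA_character_,
        formula = if (keep) best$formula else NA_character_,
        match_score = best_score, level = level,
        sources = if (keep) paste(attribute_sources(best), collapse = "|")
                  else NA_character_,
        precursor_ppm = prec_ppm, rt_error = rt_err,
        n_matched_fragments = nrow(pairs), stringsAsFactors = FALSE)
    } else {
      data.frame(query_id = id, precursor_mz = q$precursor_mz, rt = q$rt,
                 compound_name = NA_character_, formula = NA_character_,
                 match_score = NA_real_,
                 level = assign_level(has_ms2),
                 sources = NA_character_, precursor_ppm = NA_real_,
                 rt_error = NA_real_, n_matched_fragments = 0L,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Transfer pooled-sample annotations onto an MS1 feature table
#'
#' An annotation attaches to the feature satisfying |delta RT| <= `rt_tol`
#' and mass error <= `ppm_tol`; when several features qualify, the lowest
#' ppm error wins. Equivalent to a brute-force all-pairs tolerance search
#' with that tie rule.
#'
#' @param ms1_table a [feature_table()].
#' @param annotations data.frame from [annotate_spectra()] (needs
#'   `precursor_mz` and `rt`).
#' @param rt_tol RT tolerance in minutes (default 0.1).
#' @param ppm_tol mass tolerance in ppm (default 2).
#' @return list with `table` (features gain `annotation_*` columns) and
#'   `unmatched` (annotation rows that attached to no feature).
#' @export
transfer_annotations <- function(ms1_table, annotations, rt_tol = 0.1,
                                 ppm_tol = 2) {
  f <- ms1_table$features
  f$annotation_name <- NA_character_
  f$annotation_level <- NA_integer_
  f$annotation_score <- NA_real_
  f$annotation_sources <- NA_character_
  matched <- logical(nrow(annotations))
  if (nrow(annotations)) {
    for (k in seq_len(nrow(annotations))) {
      ppm <- ppm_error(annotations$precursor_mz[k], f$mz)
      drt <- abs(annotations$rt[k] - f$rt)
      ok <- which(ppm <= ppm_tol & drt <= rt_tol)
      if (!length(ok)) next
      i <- ok[which.min(ppm[ok])]
      # keep the better-scoring annotation if two land on one feature
      if (!is.na(f$annotation_score[i]) &&
          isTRUE(f$annotation_score[i] >= annotations$match_score[k]))
        next
      f$annotation_name[i] <- annotations$compound_name[k]
      f$annotation_level[i] <- annotations$level[k]
      f$annotation_score[i] <- annotations$match_score[k]
      f$annotation_sources[i] <- annotations$sources[k]
      matched[k] <- TRUE
    }
  }
  ms1_table$features <- f
  list(table = ms1_table,
       unmatched = annotations[!matched, , drop = FALSE])
}

#' Detection frequency of annotated compounds by outcome group
#'
#' For each annotated Level 1-2 compound, the percentage of samples in
#' which it is detected, split by outcome group and sample matrix. Empty
#' groups yield NA with no error.
#'
#' @param table a [feature_table()] with `annotation_*` feature columns.
#' @param group_label sample column defining the two groups
#'   (default `"outcome"`).
#' @param levels annotation levels included (default 1:2).
#' @param noise_floor detection floor passed to [ft_detected()].
#' @return data.frame: feature id, compound, matrix, and percent detected
#'   per group.
#' @export
detection_frequency_by_group <- function(table, group_label = "outcome",
                                         levels = 1:2, noise_floor = 1e4) {
  f <- table$features
  sel <- which(!is.na(f$annotation_level) & f$annotation_level %in% levels)
  det <- ft_detected(table, noise_floor)
  grp <- table$samples[[group_label]]
  mat <- if ("matrix" %in% names(table$samples)) table$samples$matrix
         else "all"
  groups <- sort(unique(grp))
  rows <- list()
  for (i in sel) {
    for (m in unique(mat)) {
      sm <- mat == m
      pct <- vapply(groups, function(gv) {
        idx <- sm & grp == gv
        if (!any(idx)) return(NA_real_)
        100 * mean(det[i, idx])
      }, 0)
      rows[[length(rows) + 1L]] <- data.frame(
        feature_id = f$feature_id[i], compound = f$annotation_name[i],
        matrix = m, t(setNames(pct, paste0("pct_", groups))),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame()
  rownames(out) <- NULL
  out
}
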