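# Fixture builders and independent brute-force oracles shared across tests.

make_samples <- function(n, matrix = "serum", batches = 1L,
                         n_preterm = floor(n / 3)) {
  data.frame(
    sample_id = sprintf("S%03d", seq_len(n)),
    matrix = rep_len(matrix, n),
    batch = rep_len(seq_len(batches), n),
    outcome = c(rep("preterm", n_preterm), rep("term", n - n_preterm)),
    creatinine = ifelse(rep_len(matrix, n) == "urine", 100, NA_real_),
    stringsAsFactors = FALSE)
}

make_table <- function(ab, mz = NULL, rt = NULL, ion_mode = "positive",
                       samples = NULL, adduct_link = NULL) {
  nf <- nrow(ab)
  ids <- rownames(ab)
  if (is.null(ids)) {
    ids <- sprintf("F%03d", seq_len(nf))
    rownames(ab) <- ids
  }
  if (is.null(samples)) samples <- make_samples(ncol(ab))
  colnames(ab) <- samples$sample_id
  feature_table(
    features = data.frame(
      feature_id = ids,
      mz = if (is.null(mz)) seq(100, 500, length.out = nf) else mz,
      rt = if (is.null(rt)) seq(1, 10, length.out = nf) else rt,
      ion_mode = rep_len(ion_mode, nf),
      adduct_link = if (is.null(adduct_link)) NA_character_
                    else adduct_link,
      stringsAsFactors = FALSE),
    abundance = ab, samples = samples)
}

# O(n^2) enumeration of tolerance-satisfying cross-polarity pairs followed
# by the same greedy selection rule (independent of the package's blocked
# implementation).
oracle_merge <- function(pos, neg, ppm_tol = 5, rt_tol = 0.5,
                         h = 1.00782) {
  fp <- pos$features; fn <- neg$features
  cand <- NULL
  for (i in seq_len(nrow(fp))) {
    for (j in seq_len(nrow(fn))) {
      mp <- fp$mz[i] - h; mn <- fn$mz[j] + h
      ppm <- abs(mp - mn) / ((mp + mn) / 2) * 1e6
      drt <- abs(fp$rt[i] - fn$rt[j])
      if (ppm <= ppm_tol && drt < rt_tol)
        cand <- rbind(cand, data.frame(
          pos = fp$feature_id[i], neg = fn$feature_id[j],
          ppm = ppm, drt = drt, stringsAsFactors = FALSE))
    }
  }
  if (is.null(cand)) return(data.frame(pos = character(0),
                                       neg = character(0)))
  cand <- cand[order(cand$ppm, cand$drt, cand$pos, cand$neg), ,
               drop = FALSE]
  out <- NULL
  up <- character(0); un <- character(0)
  for (k in seq_len(nrow(cand))) {
    if (!(cand$pos[k] %in% up) && !(cand$neg[k] %in% un)) {
      up <- c(up, cand$pos[k]); un <- c(un, cand$neg[k])
      out <- rbind(out, cand[k, ])
    }
  }
  out
}

# brute-force all-pairs correlation network over annotated rows
oracle_network <- function(logmat, category, r_threshold = 0.5) {
  ids <- rownames(logmat)
  out <- NULL
  n <- nrow(logmat)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (category[i] != "endogenous" && category[j] != "endogenous") next
      r <- cor(logmat[i, ], logmat[j, ])
      if (abs(r) > r_threshold)
        out <- rbind(out, data.frame(from = ids[i], to = ids[j], r = r,
                                     stringsAsFactors = FALSE))
    }
  }
  out
}

# brute-force annotation transfer: all-pairs tolerance search, lowest ppm
oracle_transfer <- function(features, annotations, rt_tol = 0.1,
                            ppm_tol = 2) {
  res <- rep(NA_character_, nrow(annotations))
  for (k in seq_len(nrow(annotations))) {
    best <- NA_character_; best_ppm <- Inf
    for (i in seq_len(nrow(features))) {
      ppm <- abs(annotations$precursor_mz[k] - features$mz[i]) /
        ((annotations$precursor_mz[k] + features$mz[i]) / 2) * 1e6
      drt <- abs(annotations$rt[k] - features$rt[i])
      if (ppm <= ppm_tol && drt <= rt_tol && ppm < best_ppm) {
        best <- features$feature_id[i]; best_ppm <- ppm
      }
    }
    res[k] <- best
  }
  res
}
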