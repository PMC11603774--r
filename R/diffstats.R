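#' Principal component analysis with PC-covariate correlation
#'
#' PCA of feature-standardized log10 abundances (samples as observations).
#' The scores of PCs 1-3 are correlated (Pearson, two-sided) against each
#' covariate: binary covariates coded 0/1, batch coded as an integer with a
#' companion one-way ANOVA p-value. Constant features are excluded with a
#' warning.
#'
#' @param table a [feature_table()] with no missing values and >= 3
#'   samples.
#' @param covariates sample columns to correlate against (default matrix,
#'   batch, outcome; absent columns are skipped).
#' @return a `pca_summary`: `scores` and `loadings` for PCs 1-3,
#'   `var_explained` for all PCs, and `correlations` (data.frame: PC,
#'   covariate, r, p, and ANOVA p for batch).
#' @export
run_pca <- function(table, covariates = c("matrix", "batch", "outcome")) {
  if (nrow(table$samples) < 3) stop("need >= 3 samples", call. = FALSE)
  x <- ft_log10(table)
  if (anyNA(x)) stop("PCA requires a fully imputed table", call. = FALSE)
  v <- row_vars(x)
  if (any(v == 0)) {
    warning(sum(v == 0), " constant feature(s) excluded from PCA")
    x <- x[v > 0, , drop = FALSE]
  }
  xs <- (x - rowMeans(x)) / sqrt(row_vars(x))
  pr <- prcomp(t(xs), center = TRUE, scale. = FALSE)
  npc <- min(3L, ncol(pr$x))
  varexp <- pr$sdev^2 / sum(pr$sdev^2)
  covariates <- intersect(covariates, names(table$samples))
  rows <- list()
  for (pc in seq_len(npc)) {
    for (cv in covariates) {
      val <- table$samples[[cv]]
      if (length(unique(val)) < 2) next
      num <- if (is.numeric(val)) val else as.integer(factor(val)) - 1L
      ct <- suppressWarnings(cor.test(pr$x[, pc], num))
      p_anova <- if (cv == "batch" && length(unique(val)) > 2) {
        anova(aov(pr$x[, pc] ~ factor(val)))[["Pr(>F)"]][1]
      } else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        pc = pc, covariate = cv, r = unname(ct$estimate),
        p = ct$p.value, p_anova = p_anova, stringsAsFactors = FALSE)
    }
  }
  structure(list(
    scores = pr$x[, seq_len(npc), drop = FALSE],
    loadings = pr$rotation[, seq_len(npc), drop = FALSE],
    var_explained = varexp,
    correlations = do.call(rbind, rows)),
    class = "pca_summary")
}

#' @export
print.pca_summary <- function(x, ...) {
  cat("<pca_summary> variance explained:",
      paste0(sprintf("PC%d=%.1f%%", seq_len(min(3, length(x$var_explained))),
                     100 * x$var_explained[seq_len(min(3,
                       length(x$var_explained)))]), collapse = ", "), "\n")
  print(x$correlations)
  invisible(x)
}

# Vectorized per-row Welch t-test on a log-scale matrix.
row_welch <- function(x, in_a) {
  xa <- x[, in_a, drop = FALSE]; xb <- x[, !in_a, drop = FALSE]
  na <- ncol(xa); nb <- ncol(xb)
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- rowSums((xa - ma)^2) / (na - 1)
  vb <- rowSums((xb - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  tstat <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  list(t = tstat, df = df, p = p)
}

#' Per-feature two-group differential testing
#'
#' Welch (unequal-variance) t-test on log10 abundances per feature, with
#' Benjamini-Hochberg adjustment over all tested features at a 5%
#' false-discovery target. The log2 fold change is computed from the
#' linear-scale group means (group A over group B).
#'
#' @param x a [feature_table()] or a linear-scale abundance matrix
#'   (features x samples, no missing values).
#' @param groups for a matrix: character/factor vector of group labels per
#'   column. For a `feature_table`: the sample column name holding the
#'   labels (default `"outcome"`).
#' @param group_a label of the numerator group; defaults to `"preterm"`
#'   when present, otherwise the first label.
#' @return data.frame of class `differential_result`: feature_id, log2fc,
#'   t, df, p, q.
#' @export
differential_test <- function(x, groups = "outcome", group_a = NULL) {
  if (inherits(x, "feature_table")) {
    labels <- x$samples[[groups]]
    ids <- x$features$feature_id
    mat <- x$abundance
  } else {
    labels <- groups
    ids <- rownames(x)
    if (is.null(ids)) ids <- sprintf("F%04d", seq_len(nrow(x)))
    mat <- x
  }
  if (anyNA(mat))
    stop("differential testing requires a fully imputed table",
         call. = FALSE)
  labels <- as.character(labels)
  lv <- unique(labels)
  if (length(lv) != 2) stop("need exactly 2 groups", call. = FALSE)
  if (is.null(group_a)) group_a <- if ("preterm" %in% lv) "preterm"
                                   else lv[1]
  in_a <- labels == group_a
  if (sum(in_a) < 2 || sum(!in_a) < 2)
    stop("each group needs >= 2 samples", call. = FALSE)
  lmat <- log10(pmax(mat, 1))
  w <- row_welch(lmat, in_a)
  log2fc <- log2(rowMeans(mat[, in_a, drop = FALSE]) /
                   rowMeans(mat[, !in_a, drop = FALSE]))
  out <- data.frame(feature_id = ids, log2fc = log2fc, t = w$t, df = w$df,
                    p = w$p, q = bh_adjust(w$p), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("differential_result", "data.frame")
  out
}

#' Volcano classification of differential results
#'
#' `up` if `p < p_cut` and `log2fc > fc_cut`; `down` if `p < p_cut` and
#' `log2fc < -fc_cut`; otherwise `not_significant`. The three classes
#' partition the input for any thresholds.
#'
#' @param results data.frame from [differential_test()].
#' @param p_cut p-value cutoff (default 0.05).
#' @param fc_cut log2 fold-change cutoff (default 1.2).
#' @param use_q classify on the BH-adjusted q instead of raw p
#'   (default FALSE, matching a volcano drawn on raw p).
#' @return `results` with a `volcano_class` column.
#' @export
volcano_classify <- function(results, p_cut = 0.05, fc_cut = 1.2,
                             use_q = FALSE) {
  p <- if (use_q) results$q else results$p
  cls <- rep("not_significant", nrow(results))
  cls[p < p_cut & results$log2fc > fc_cut] <- "up"
  cls[p < p_cut & results$log2fc < -fc_cut] <- "down"
  results$volcano_class <- cls
  results
}

#' Hierarchical-clustering structures for a heatmap
#'
#' Average-linkage clustering: features on correlation distance
#' (`1 - Pearson r` between feature profiles), samples on Euclidean
#' distance over feature-standardized values. Returns the linkage trees and
#' leaf orders plus the standardized matrix in leaf order; rendering is the
#' caller's business.
#'
#' @param table a [feature_table()] with no missing values, >= 2 features
#'   and >= 2 samples.
#' @return list with `feature_hclust`, `sample_hclust`, `feature_order`,
#'   `sample_order`, `matrix` (standardized log10, reordered).
#' @export
cluster_heatmap_matrix <- function(table) {
  x <- ft_log10(table)
  if (anyNA(x)) stop("clustering requires a fully imputed table",
                     call. = FALSE)
  if (nrow(x) < 2 || ncol(x) < 2)
    stop("need >= 2 features and >= 2 samples", call. = FALSE)
  v <- row_vars(x)
  if (any(v == 0))
    stop("constant feature: correlation distance undefined", call. = FALSE)
  xs <- (x - rowMeans(x)) / sqrt(v)
  df <- as.dist(1 - cor(t(x)))
  hf <- hclust(df, method = "average")
  hs <- hclust(dist(t(xs)), method = "average")
  list(feature_hclust = hf, sample_hclust = hs,
       feature_order = hf$order, sample_order = hs$order,
       matrix = xs[hf$order, hs$order, drop = FALSE])
}
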