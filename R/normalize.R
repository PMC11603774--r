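#' Creatinine normalization of urine abundances
#'
#' Corrects urinary dilution by scaling every urine sample's areas by the
#' ratio of the cohort median creatinine to that sample's creatinine
#' (`strategy = "median-ratio"`, the default), or by dividing areas by the
#' sample creatinine (`strategy = "divide"`). Serum samples are unchanged.
#'
#' @param table a [feature_table()].
#' @param strategy `"median-ratio"` or `"divide"`.
#' @return normalized `feature_table`.
#' @export
creatinine_normalize <- function(table,
                                 strategy = c("median-ratio", "divide")) {
  strategy <- match.arg(strategy)
  s <- table$samples
  if (!"matrix" %in% names(s) || !any(s$matrix == "urine")) return(table)
  ur <- which(s$matrix == "urine")
  cr <- s$creatinine[ur]
  if (any(is.na(cr)) || any(cr <= 0))
    stop("urine sample with missing or non-positive creatinine: ",
         s$sample_id[ur][which(is.na(cr) | cr <= 0)[1]], call. = FALSE)
  fac <- switch(strategy,
                "median-ratio" = median(cr) / cr,
                "divide" = 1 / cr)
  table$abundance[, ur] <- sweep(table$abundance[, ur, drop = FALSE], 2,
                                 fac, `*`)
  table
}

#' Impute below-detection-limit values from a truncated normal
#'
#' For each feature, missing entries are replaced by draws from
#' `Normal(median, sd)` of the observed log10 areas, truncated above at the
#' smaller of the minimum observed log10 area and log10(MDL), so every fill
#' represents a value below what was measurable. Observed values are never
#' modified. The pre-imputation detection mask is preserved in the
#' `"detected"` attribute of the result.
#'
#' @param table a [feature_table()], already frequency-filtered (every
#'   feature needs >= 2 observed values).
#' @param mdl method detection limit on the area scale, or NULL to truncate
#'   at the observed minimum only.
#' @param seed integer seed making the fills reproducible.
#' @return imputed `feature_table` with no missing cells.
#' @export
impute_below_mdl <- function(table, mdl = NULL, seed = 1L) {
  a <- table$abundance
  n_obs <- rowSums(!is.na(a))
  if (any(n_obs < 2))
    stop("feature with < 2 observed values cannot be imputed: ",
         table$features$feature_id[which(n_obs < 2)[1]], call. = FALSE)
  attr(table, "detected") <- !is.na(a)
  with_seed(seed, {
    for (i in which(rowSums(is.na(a)) > 0)) {
      x <- a[i, ]
      obs <- log10(pmax(x[!is.na(x)], 1))
      m <- median(obs); s <- sd(obs)
      upper <- min(min(obs), if (!is.null(mdl) && mdl > 0) log10(mdl)
                   else Inf)
      k <- sum(is.na(x))
      if (s <= 0) {
        fill <- rep(upper, k)
      } else {
        pu <- pnorm(upper, m, s)
        fill <- if (pu <= 0) rep(upper, k)
                else qnorm(runif(k) * pu, m, s)
      }
      a[i, is.na(x)] <- 10^fill
    }
  })
  table$abundance <- a
  table
}

#' Parametric empirical-Bayes batch correction
#'
#' Location/scale batch-effect adjustment on log10 areas: (1) feature-wise
#' standardization that retains the design terms of scientific interest
#' (sample matrix and outcome, when present with >= 2 levels); (2)
#' method-of-moments estimation of the prior hyperparameters — normal for
#' the additive batch effects gamma, inverse-gamma for the multiplicative
#' variance effects delta^2 — across features; (3) iterative EB shrinkage of
#' the per-batch, per-feature estimates to their posteriors until the
#' maximum absolute change falls below `conv` (capped at `max_iter`
#' iterations, with a warning and the last iterate on non-convergence);
#' (4) adjusted data `(Z - gamma_hat) / delta_hat` back-transformed to the
#' original location and scale.
#'
#' @param table a [feature_table()] with no missing values (impute first).
#' @param batches batch labels per sample (defaults to the manifest's
#'   `batch` column); every batch needs >= 2 samples.
#' @param covariates character vector of sample columns preserved during
#'   standardization (default matrix and outcome).
#' @param conv convergence threshold on the EB updates (default 1e-4).
#' @param max_iter iteration cap (default 100).
#' @param eb apply empirical-Bayes shrinkage (default TRUE). With
#'   `eb = FALSE` the raw per-batch estimates are used; batch means are
#'   then removed exactly and per-feature grand means are preserved to
#'   numerical precision, at the cost of noisier per-feature adjustments.
#'   Under shrinkage, grand means are preserved only approximately
#'   (relative error around 1e-3 at cohort scale).
#' @return list with `table` (corrected `feature_table`, linear-scale
#'   areas) and `model` (a `batch_model`: per-feature grand means, pooled
#'   SDs, per-batch gamma/delta^2 estimates and prior hyperparameters).
#' @export
combat_correct <- function(table, batches = table$samples$batch,
                           covariates = c("matrix", "outcome"),
                           conv = 1e-4, max_iter = 100, eb = TRUE) {
  a <- table$abundance
  if (anyNA(a))
    stop("batch correction requires a fully imputed table", call. = FALSE)
  batches <- as.factor(batches)
  nb <- nlevels(batches)
  if (nb < 2) {
    model <- structure(list(n_batches = 1L, note = "single batch: no-op"),
                       class = "batch_model")
    return(list(table = table, model = model))
  }
  tab_n <- table(batches)
  if (any(tab_n < 2))
    stop("batch with a single sample: ",
         names(tab_n)[tab_n < 2][1], call. = FALSE)

  x <- log10(pmax(a, 1))
  n <- ncol(x); g <- nrow(x)
  batchmod <- stats::model.matrix(~ -1 + batches)
  covmod <- NULL
  for (cv in covariates) {
    v <- table$samples[[cv]]
    if (!is.null(v) && length(unique(v)) > 1) {
      mm <- stats::model.matrix(~ as.factor(v))[, -1, drop = FALSE]
      colnames(mm) <- paste0(cv, seq_len(ncol(mm)))
      covmod <- cbind(covmod, mm)
    }
  }
  design <- cbind(batchmod, covmod)
  if (qr(design)$rank < ncol(design))
    stop("design matrix is confounded (batch collinear with covariates)",
         call. = FALSE)
  b_hat <- solve(crossprod(design), crossprod(design, t(x)))
  n_batch <- as.numeric(tab_n)
  grand_mean <- crossprod(n_batch / n, b_hat[seq_len(nb), , drop = FALSE])
  # ML variance of the full-model residuals, as in the parametric EB model
  var_pooled <- drop((x - t(design %*% b_hat))^2 %*% rep(1 / n, n))
  if (any(var_pooled <= 0))
    stop("constant feature: cannot standardize", call. = FALSE)

  stand_mean <- matrix(grand_mean, g, n)
  if (!is.null(covmod)) {
    tmp <- design
    tmp[, seq_len(nb)] <- 0
    stand_mean <- stand_mean + t(tmp %*% b_hat)
  }
  z <- (x - stand_mean) / sqrt(var_pooled)

  gamma_hat <- t(apply(z, 1, function(r) tapply(r, batches, mean)))
  delta_hat <- t(apply(z, 1, function(r) tapply(r, batches, var)))
  gamma_bar <- colMeans(gamma_hat)
  t2 <- apply(gamma_hat, 2, var)
  a_prior <- apply(delta_hat, 2, function(d)
    (2 * var(d) + mean(d)^2) / var(d))
  b_prior <- apply(delta_hat, 2, function(d)
    (mean(d) * var(d) + mean(d)^3) / var(d))

  gamma_star <- gamma_hat
  delta_star <- delta_hat
  adjusted <- z
  converged <- TRUE
  for (b in seq_len(nb)) {
    zb <- z[, batches == levels(batches)[b], drop = FALSE]
    ni <- ncol(zb)
    g_old <- gamma_hat[, b]
    d_old <- delta_hat[, b]
    it <- 0L
    if (eb) repeat {
      it <- it + 1L
      g_new <- (ni * t2[b] * gamma_hat[, b] + d_old * gamma_bar[b]) /
        (ni * t2[b] + d_old)
      sum2 <- rowSums((zb - g_new)^2)
      d_new <- (0.5 * sum2 + b_prior[b]) / (ni / 2 + a_prior[b] - 1)
      change <- max(abs(g_new - g_old), abs(d_new - d_old))
      g_old <- g_new; d_old <- d_new
      if (change < conv) break
      if (it >= max_iter) {
        warning("EB shrinkage did not converge for batch ",
                levels(batches)[b], " (last change ",
                signif(change, 3), "); returning last iterate")
        converged <- FALSE
        break
      }
    }
    gamma_star[, b] <- g_old
    delta_star[, b] <- d_old
    adjusted[, batches == levels(batches)[b]] <-
      (zb - g_old) / sqrt(d_old)
  }

  corrected <- adjusted * sqrt(var_pooled) + stand_mean
  out <- table
  out$abundance <- 10^corrected
  dimnames(out$abundance) <- dimnames(a)
  model <- structure(list(
    n_batches = nb, batch_levels = levels(batches),
    grand_mean = drop(grand_mean), var_pooled = var_pooled,
    gamma_hat = gamma_hat, delta_hat = delta_hat,
    gamma_star = gamma_star, delta_star = delta_star,
    gamma_bar = gamma_bar, t2 = t2,
    a_prior = a_prior, b_prior = b_prior, converged = converged),
    class = "batch_model")
  list(table = out, model = model)
}

#' @export
print.batch_model <- function(x, ...) {
  cat("<batch_model> ", x$n_batches, " batches\n", sep = "")
  if (!is.null(x$gamma_star)) {
    cat("  mean additive effect (standardized units) per batch:\n")
    print(round(colMeans(x$gamma_star), 4))
  }
  invisible(x)
}
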