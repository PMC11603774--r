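#' Construct a feature table
#'
#' The central container of the pipeline: a features-by-samples peak-area
#' matrix plus per-feature metadata (m/z, retention time, ionization mode,
#' adduct links, annotations) and per-sample metadata (matrix type, batch,
#' outcome, creatinine). Missing (below detection limit) areas are encoded as
#' `NA`, never 0: a zero is a legal measured area.
#'
#' @param features data.frame with at least `feature_id` (unique, character),
#'   `mz` (Da, > 0), `rt` (minutes, >= 0), `ion_mode` (`"positive"` or
#'   `"negative"`). Optional: `adduct_link` (parent `feature_id` for adduct
#'   satellites, NA otherwise) and annotation columns.
#' @param abundance numeric matrix, rows = features (rownames = feature_id),
#'   columns = samples (colnames = sample_id); entries >= 0 or NA.
#' @param samples data.frame with `sample_id` (unique), `matrix` (`"serum"` /
#'   `"urine"`), `batch` (integer), `outcome` (`"preterm"` / `"term"`), and
#'   `creatinine` (mg/dL, required and > 0 for urine samples).
#' @return object of class `feature_table`.
#' @export
feature_table <- function(features, abundance, samples) {
  features <- as.data.frame(features)
  samples <- as.data.frame(samples)
  abundance <- as.matrix(abundance)
  ft <- structure(
    list(features = features, abundance = abundance, samples = samples),
    class = "feature_table"
  )
  validate_feature_table(ft)
  ft
}

#' Validate a feature table's invariants
#'
#' Checks id uniqueness, dimension consistency, positivity of m/z and areas,
#' and the creatinine requirement for urine samples. Stops with an
#' informative message on the first violation.
#'
#' @param ft a `feature_table`.
#' @return `ft`, invisibly.
#' @export
validate_feature_table <- function(ft) {
  f <- ft$features; s <- ft$samples; a <- ft$abundance
  need_f <- c("feature_id", "mz", "rt", "ion_mode")
  miss <- setdiff(need_f, names(f))
  if (length(miss)) stop("features missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(f$feature_id))
    stop("duplicate feature_id: ",
         f$feature_id[duplicated(f$feature_id)][1], call. = FALSE)
  if (anyDuplicated(s$sample_id))
    stop("duplicate sample_id: ",
         s$sample_id[duplicated(s$sample_id)][1], call. = FALSE)
  if (any(f$mz <= 0, na.rm = TRUE)) stop("mz must be > 0", call. = FALSE)
  if (any(f$rt < 0, na.rm = TRUE)) stop("rt must be >= 0", call. = FALSE)
  if (!all(f$ion_mode %in% c("positive", "negative")))
    stop("ion_mode must be 'positive' or 'negative'", call. = FALSE)
  if (nrow(a) != nrow(f) || ncol(a) != nrow(s))
    stop("abundance matrix dimensions (", nrow(a), " x ", ncol(a),
         ") inconsistent with metadata (", nrow(f), " features, ",
         nrow(s), " samples)", call. = FALSE)
  if (!identical(rownames(a), as.character(f$feature_id)))
    stop("abundance rownames must equal features$feature_id", call. = FALSE)
  if (!identical(colnames(a), as.character(s$sample_id)))
    stop("abundance colnames must equal samples$sample_id", call. = FALSE)
  if (any(a < 0, na.rm = TRUE))
    stop("negative peak area found", call. = FALSE)
  if ("matrix" %in% names(s)) {
    ur <- s$matrix == "urine"
    if (any(ur)) {
      cr <- s$creatinine[ur]
      if (is.null(s$creatinine) || any(is.na(cr)) || any(cr <= 0))
        stop("every urine sample needs creatinine > 0", call. = FALSE)
    }
  }
  invisible(ft)
}

#' @export
print.feature_table <- function(x, ...) {
  a <- x$abundance
  nmiss <- sum(is.na(a))
  cat("<feature_table> ", nrow(a), " features x ", ncol(a), " samples\n",
      sep = "")
  cat("  modes: ", paste(names(table(x$features$ion_mode)),
                         table(x$features$ion_mode),
                         sep = "=", collapse = ", "), "\n", sep = "")
  if ("matrix" %in% names(x$samples))
    cat("  sample matrix: ",
        paste(names(table(x$samples$matrix)), table(x$samples$matrix),
              sep = "=", collapse = ", "), "\n", sep = "")
  cat("  missing cells: ", nmiss, " (",
      sprintf("%.1f", 100 * nmiss / length(a)), "%)\n", sep = "")
  invisible(x)
}

#' Subset a feature table by features and/or samples
#'
#' The `detected` attribute (pre-imputation detection mask, if present) is
#' subset alongside the abundance matrix.
#'
#' @param ft a `feature_table`.
#' @param features logical/integer/character index into features (character
#'   matches `feature_id`).
#' @param samples index into samples (character matches `sample_id`).
#' @return a `feature_table`.
#' @export
ft_subset <- function(ft, features = NULL, samples = NULL) {
  fi <- seq_len(nrow(ft$features))
  si <- seq_len(nrow(ft$samples))
  if (!is.null(features)) {
    fi <- if (is.character(features)) {
      match(features, ft$features$feature_id)
    } else which(rep(TRUE, nrow(ft$features)))[features]
    if (anyNA(fi)) stop("unknown feature id in subset", call. = FALSE)
  }
  if (!is.null(samples)) {
    si <- if (is.character(samples)) {
      match(samples, ft$samples$sample_id)
    } else which(rep(TRUE, nrow(ft$samples)))[samples]
    if (anyNA(si)) stop("unknown sample id in subset", call. = FALSE)
  }
  out <- ft
  out$features <- ft$features[fi, , drop = FALSE]
  rownames(out$features) <- NULL
  out$samples <- ft$samples[si, , drop = FALSE]
  rownames(out$samples) <- NULL
  out$abundance <- ft$abundance[fi, si, drop = FALSE]
  det <- attr(ft, "detected")
  if (!is.null(det)) attr(out, "detected") <- det[fi, si, drop = FALSE]
  out
}

# log10 abundance matrix; zeros/NAs guarded by a floor of 1 (log10 -> 0)
ft_log10 <- function(ft) {
  a <- ft$abundance
  a[!is.na(a) & a < 1] <- 1
  log10(a)
}

#' Detection mask of a feature table
#'
#' A cell is "detected" when its area is non-missing and above the
#' instrument noise floor. After imputation the original mask is preserved
#' in the `detected` attribute; this helper returns it, falling back to the
#' current NA/floor pattern.
#'
#' @param ft a `feature_table`.
#' @param noise_floor minimum peak area counted as a real signal
#'   (default 10000, the Orbitrap background-noise level).
#' @return logical matrix, features x samples.
#' @export
ft_detected <- function(ft, noise_floor = 1e4) {
  det <- attr(ft, "detected")
  if (!is.null(det)) return(det)
  !is.na(ft$abundance) & ft$abundance > noise_floor
}
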