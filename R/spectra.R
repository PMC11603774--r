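#' Construct an MS2 spectrum
#'
#' @param precursor_mz precursor ion m/z in Da.
#' @param fragments data.frame with columns `mz` (Da) and `intensity`
#'   (arbitrary units, > 0). Stored sorted by ascending m/z.
#' @param ion_mode `"positive"` or `"negative"`.
#' @param rt optional retention time in minutes.
#' @return object of class `ms2_spectrum`.
#' @export
ms2_spectrum <- function(precursor_mz, fragments, ion_mode = "positive",
                         rt = NA_real_) {
  fragments <- as.data.frame(fragments)
  stopifnot(all(c("mz", "intensity") %in% names(fragments)))
  if (nrow(fragments) && any(fragments$intensity <= 0))
    stop("fragment intensities must be > 0", call. = FALSE)
  fragments <- fragments[order(fragments$mz), c("mz", "intensity"),
                         drop = FALSE]
  rownames(fragments) <- NULL
  structure(list(precursor_mz = precursor_mz, rt = rt, ion_mode = ion_mode,
                 fragments = fragments),
            class = "ms2_spectrum")
}

#' @export
print.ms2_spectrum <- function(x, ...) {
  cat("<ms2_spectrum> precursor ", sprintf("%.5f", x$precursor_mz), " (",
      x$ion_mode, "), ", nrow(x$fragments), " fragments",
      if (!is.na(x$rt)) sprintf(", RT %.3f min", x$rt), "\n", sep = "")
  invisible(x)
}

# the five source/use categories; anything else is "unknown"
.SOURCE_CATEGORIES <- c("endogenous_metabolite", "natural_product", "drug",
                        "personal_care_product", "exogenous_contaminant")

#' Construct a spectral-library entry
#'
#' @param name compound name.
#' @param spectrum an [ms2_spectrum()].
#' @param formula elemental formula string, or `""`/NA if unknown. When both
#'   formula and `neutral_mass` are present they must agree within 5 ppm.
#' @param neutral_mass neutral monoisotopic mass in Da; computed from the
#'   formula when omitted.
#' @param rt optional reference retention time (minutes); required for
#'   Level-1 confirmation against an authentic standard.
#' @param sources character vector, subset of the five source/use
#'   categories (endogenous metabolite, natural product, drug, personal
#'   care product, exogenous contaminant); empty means unknown origin.
#' @param is_authentic_standard TRUE when the entry comes from an in-house
#'   authentic standard (required for Level 1).
#' @return object of class `library_entry`.
#' @export
library_entry <- function(name, spectrum, formula = "",
                          neutral_mass = NULL, rt = NA_real_,
                          sources = character(0),
                          is_authentic_standard = FALSE) {
  stopifnot(inherits(spectrum, "ms2_spectrum"))
  fm <- if (!is.null(formula) && !is.na(formula) && nzchar(formula))
    formula_mass(formula) else NA_real_
  if (is.null(neutral_mass)) neutral_mass <- fm
  if (!is.na(fm) && !is.na(neutral_mass) &&
      ppm_error(fm, neutral_mass) > 5)
    stop("neutral_mass inconsistent with formula (> 5 ppm): ", name,
         call. = FALSE)
  bad <- setdiff(sources, .SOURCE_CATEGORIES)
  if (length(bad))
    stop("unknown source category: ", paste(bad, collapse = ", "),
         call. = FALSE)
  structure(list(name = name, formula = formula,
                 neutral_mass = neutral_mass, rt = rt, spectrum = spectrum,
                 sources = sources,
                 is_authentic_standard = isTRUE(is_authentic_standard)),
            class = "library_entry")
}

#' @export
print.library_entry <- function(x, ...) {
  cat("<library_entry> ", x$name,
      if (x$is_authentic_standard) " [standard]", "\n", sep = "")
  cat("  neutral mass ", sprintf("%.5f", x$neutral_mass), " Da, ",
      nrow(x$spectrum$fragments), " fragments, sources: ",
      if (length(x$sources)) paste(x$sources, collapse = "|") else "unknown",
      "\n", sep = "")
  invisible(x)
}
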