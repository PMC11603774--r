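#' Read an alignment CSV into a feature table
#'
#' The canonical alignment dialect has columns `feature_id, mz, rt,
#' ion_mode, adduct_link` followed by one column per sample. Empty cells are
#' missing (below-MDL) areas; zero is a legal measured area and is never
#' confused with missing. Columns belonging to laboratory blanks (identified
#' by a `role == "blank"` row in the manifest, or by the `blank_pattern`
#' fallback) are routed into a separate blank matrix stored in the
#' `"blanks"` attribute of the returned table.
#'
#' @param path CSV file path.
#' @param ion_mode expected ionization mode of the file; a mismatch with a
#'   declared `ion_mode` column is an error.
#' @param manifest sample manifest data.frame (see [read_manifest()]);
#'   sample columns are matched to its `sample_id`s. Optional `role` column
#'   marks `"blank"` columns.
#' @param blank_pattern regex routing unmatched columns to the blank table
#'   when the manifest has no `role` column.
#' @return a [feature_table()] (blank matrix, if any, in `attr(x, "blanks")`).
#' @export
read_alignment <- function(path, ion_mode, manifest = NULL,
                           blank_pattern = "^BLK") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("feature_id", "mz", "rt", "ion_mode", "adduct_link")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("malformed alignment header in ", path, ": missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(raw$feature_id))
    stop("duplicate feature_id in ", path, ": ",
         raw$feature_id[duplicated(raw$feature_id)][1], call. = FALSE)
  if (!all(raw$ion_mode %in% ion_mode))
    stop("ion_mode column disagrees with requested mode '", ion_mode, "'",
         call. = FALSE)
  sample_cols <- setdiff(names(raw), need)
  blank_cols <- if (!is.null(manifest) && "role" %in% names(manifest)) {
    intersect(sample_cols, manifest$sample_id[manifest$role == "blank"])
  } else grep(blank_pattern, sample_cols, value = TRUE)
  data_cols <- setdiff(sample_cols, blank_cols)
  ab <- as.matrix(raw[, data_cols, drop = FALSE])
  storage.mode(ab) <- "double"
  neg <- which(!is.na(ab) & ab < 0, arr.ind = TRUE)
  if (nrow(neg))
    stop("negative area in ", path, " at feature ",
         raw$feature_id[neg[1, 1]], ", sample ", data_cols[neg[1, 2]],
         call. = FALSE)
  rownames(ab) <- raw$feature_id
  smp <- if (!is.null(manifest)) {
    m <- manifest[match(data_cols, manifest$sample_id), , drop = FALSE]
    if (anyNA(m$sample_id))
      stop("sample column(s) absent from manifest: ",
           paste(data_cols[is.na(m$sample_id)], collapse = ", "),
           call. = FALSE)
    rownames(m) <- NULL
    m
  } else data.frame(sample_id = data_cols, stringsAsFactors = FALSE)
  ft <- feature_table(
    features = raw[, c("feature_id", "mz", "rt", "ion_mode", "adduct_link")],
    abundance = ab, samples = smp)
  if (length(blank_cols)) {
    bl <- as.matrix(raw[, blank_cols, drop = FALSE])
    storage.mode(bl) <- "double"
    rownames(bl) <- raw$feature_id
    attr(ft, "blanks") <- bl
  }
  ft
}

#' Write a feature table as an alignment CSV
#'
#' Inverse of [read_alignment()]: m/z written with 5 decimals, RT with 3,
#' areas at full precision, missing areas as empty cells. Blank columns
#' (from the `"blanks"` attribute or the `blanks` argument) are appended
#' after the sample columns.
#'
#' @param ft a [feature_table()].
#' @param path output path.
#' @param blanks optional blank matrix (features x blanks) to append.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(ft, path, blanks = attr(ft, "blanks")) {
  f <- ft$features
  out <- data.frame(
    feature_id = f$feature_id,
    mz = sprintf("%.5f", f$mz),
    rt = sprintf("%.3f", f$rt),
    ion_mode = f$ion_mode,
    adduct_link = if ("adduct_link" %in% names(f)) f$adduct_link
                  else NA_character_,
    stringsAsFactors = FALSE, check.names = FALSE)
  out <- cbind(out, as.data.frame(ft$abundance, check.names = FALSE))
  if (!is.null(blanks))
    out <- cbind(out, as.data.frame(blanks, check.names = FALSE))
  write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read / write a sample manifest CSV
#'
#' Columns: `sample_id`, `matrix` (serum/urine), `batch`, `outcome`
#' (preterm/term), `creatinine` (mg/dL, urine only), plus any extras
#' (e.g. `participant`, `role`).
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  m <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "matrix", "batch", "outcome")
  miss <- setdiff(need, names(m))
  if (length(miss))
    stop("manifest missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(m$sample_id))
    stop("duplicate sample_id in manifest", call. = FALSE)
  m
}

#' @rdname read_manifest
#' @param manifest data.frame to write.
#' @export
write_manifest <- function(manifest, path) {
  write.csv(manifest, path, row.names = FALSE, na = "")
  invisible(path)
}
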