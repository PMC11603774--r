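#' Write spectra or library entries in MSP (NIST-style text) format
#'
#' Accepts either a list of [library_entry()] objects or a named list of
#' [ms2_spectrum()] objects (names become the block NAME). Source categories
#' and the authentic-standard flag are carried in a `COMMENT` field
#' (`sources=a|b; standard=true`), the neutral mass in `MONOISOTOPICMASS`.
#'
#' @param x list of entries or named list of spectra.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_msp <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  emit <- function(name, spec, formula = "", neutral_mass = NA,
                   rt = NA, sources = character(0), standard = FALSE) {
    lines <- c(paste0("NAME: ", name))
    if (!is.na(formula) && nzchar(formula))
      lines <- c(lines, paste0("FORMULA: ", formula))
    if (!is.na(neutral_mass))
      lines <- c(lines, sprintf("MONOISOTOPICMASS: %.5f", neutral_mass))
    lines <- c(lines, sprintf("PRECURSORMZ: %.5f", spec$precursor_mz),
               paste0("IONMODE: ",
                      if (spec$ion_mode == "positive") "Positive"
                      else "Negative"))
    rt_use <- if (!is.na(rt)) rt else spec$rt
    if (!is.na(rt_use))
      lines <- c(lines, sprintf("RETENTIONTIME: %.3f", rt_use))
    com <- c(if (length(sources)) paste0("sources=",
                                         paste(sources, collapse = "|")),
             if (standard) "standard=true")
    if (length(com))
      lines <- c(lines, paste0("COMMENT: ", paste(com, collapse = "; ")))
    lines <- c(lines, paste0("Num Peaks: ", nrow(spec$fragments)),
               sprintf("%.4f\t%g", spec$fragments$mz,
                       spec$fragments$intensity), "")
    writeLines(lines, con)
  }
  if (length(x)) {
    if (inherits(x[[1]], "library_entry")) {
      for (e in x) emit(e$name, e$spectrum, e$formula, e$neutral_mass,
                        e$rt, e$sources, e$is_authentic_standard)
    } else {
      nms <- names(x)
      if (is.null(nms)) stop("spectra list must be named", call. = FALSE)
      for (i in seq_along(x)) emit(nms[i], x[[i]])
    }
  }
  invisible(path)
}

#' Read an MSP spectral library
#'
#' Parses NIST-style MSP blocks (NAME / FORMULA / PRECURSORMZ /
#' RETENTIONTIME / Num Peaks). A block whose fragment count disagrees with
#' its `Num Peaks` declaration, or that lacks a precursor, is a parse error
#' reported with the block index. Entries without RETENTIONTIME are valid
#' but can only support Level >= 2 annotation.
#'
#' @param path MSP file path.
#' @return list of [library_entry()].
#' @export
read_msp <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  starts <- grep("^NAME:", lines, ignore.case = TRUE)
  if (!length(starts)) return(list())
  ends <- c(starts[-1] - 1L, length(lines))
  entries <- vector("list", length(starts))
  for (b in seq_along(starts)) {
    blk <- lines[starts[b]:ends[b]]
    blk <- blk[nzchar(trimws(blk))]
    kv <- grep("^[A-Za-z ]+:", blk, value = TRUE)
    get <- function(key) {
      hit <- grep(paste0("^", key, ":"), kv, ignore.case = TRUE,
                  value = TRUE)
      if (!length(hit)) return(NA_character_)
      trimws(sub("^[^:]+:", "", hit[1]))
    }
    np_line <- grep("^Num Peaks:", blk, ignore.case = TRUE)
    if (!length(np_line))
      stop("MSP block ", b, ": missing 'Num Peaks'", call. = FALSE)
    n_peaks <- as.integer(trimws(sub("^[^:]+:", "", blk[np_line[1]])))
    frag_lines <- blk[-seq_len(np_line[1])]
    frag_lines <- frag_lines[!grepl("^[A-Za-z]", frag_lines)]
    if (length(frag_lines) != n_peaks)
      stop("MSP block ", b, " ('", get("NAME"), "'): found ",
           length(frag_lines), " fragment lines but 'Num Peaks: ",
           n_peaks, "'", call. = FALSE)
    frag <- if (n_peaks > 0) {
      parts <- strsplit(trimws(frag_lines), "[\t ;]+")
      data.frame(mz = as.numeric(vapply(parts, `[`, "", 1)),
                 intensity = as.numeric(vapply(parts, `[`, "", 2)))
    } else data.frame(mz = numeric(0), intensity = numeric(0))
    if (anyNA(frag))
      stop("MSP block ", b, ": unparseable fragment line", call. = FALSE)
    prec <- as.numeric(get("PRECURSORMZ"))
    if (is.na(prec))
      stop("MSP block ", b, ": missing PRECURSORMZ", call. = FALSE)
    mode <- tolower(get("IONMODE"))
    mode <- if (is.na(mode) || startsWith(mode, "p")) "positive"
            else "negative"
    rt <- suppressWarnings(as.numeric(get("RETENTIONTIME")))
    com <- get("COMMENT")
    sources <- character(0); standard <- FALSE
    if (!is.na(com)) {
      m <- regmatches(com, regexpr("sources=[^;]+", com))
      if (length(m))
        sources <- strsplit(sub("sources=", "", m), "\\|")[[1]]
      standard <- grepl("standard=true", com, fixed = TRUE)
    }
    nm_mass <- suppressWarnings(as.numeric(get("MONOISOTOPICMASS")))
    spec <- ms2_spectrum(prec, frag, mode, rt = rt)
    fo <- get("FORMULA")
    entries[[b]] <- library_entry(
      name = get("NAME"), spectrum = spec,
      formula = if (is.na(fo)) "" else fo,
      neutral_mass = if (is.na(nm_mass)) NULL else nm_mass,
      rt = rt, sources = sources, is_authentic_standard = standard)
  }
  entries
}

#' Read an MSP file as a named list of spectra
#'
#' Convenience wrapper over [read_msp()] for pooled-sample MS2 files: the
#' block NAME becomes the list name and only the spectrum is kept.
#'
#' @param path MSP file path.
#' @return named list of [ms2_spectrum()].
#' @export
read_msp_spectra <- function(path) {
  entries <- read_msp(path)
  out <- lapply(entries, function(e) {
    s <- e$spectrum
    s$rt <- e$rt
    s
  })
  names(out) <- vapply(entries, `[[`, "", "name")
  out
}
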