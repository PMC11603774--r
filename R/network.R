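# Map a pipe-collapsed source string to a network node category.
categorize_sources <- function(sources) {
  vapply(sources, function(s) {
    if (is.na(s) || !nzchar(s) || identical(s, "unknown")) return("unknown")
    parts <- strsplit(s, "|", fixed = TRUE)[[1]]
    if ("endogenous_metabolite" %in% parts) "endogenous" else "exogenous"
  }, "", USE.NAMES = FALSE)
}

#' Build the endogenous-exogenous chemical correlation network
#'
#' Nodes are annotated compounds at the allowed confidence levels.
#' Candidate edges are pairs involving at least one endogenous metabolite
#' (endogenous vs all other annotated chemicals); an edge is kept when the
#' absolute Pearson correlation of the two features' log10 abundance
#' vectors exceeds `r_threshold`. Both correlation signs are retained and
#' flagged; export-time filtering by sign is the caller's choice.
#'
#' @param table a [feature_table()] with `annotation_*` feature columns,
#'   imputed and batch-corrected; >= 3 samples.
#' @param r_threshold absolute-correlation edge threshold (default 0.5,
#'   exclusive).
#' @param levels annotation levels admitted as nodes (default 1:2).
#' @return object of class `chem_network`: `nodes` (id, name, category,
#'   level, mean_area) and `edges` (from, to, r, sign).
#' @export
build_network <- function(table, r_threshold = 0.5, levels = 1:2) {
  if (nrow(table$samples) < 3)
    stop("need >= 3 samples for robust correlation", call. = FALSE)
  f <- table$features
  sel <- which(!is.na(f$annotation_level) & f$annotation_level %in% levels)
  nodes <- data.frame(
    id = f$feature_id[sel],
    name = f$annotation_name[sel],
    category = categorize_sources(f$annotation_sources[sel]),
    level = f$annotation_level[sel],
    mean_area = rowMeans(table$abundance[sel, , drop = FALSE],
                         na.rm = TRUE),
    stringsAsFactors = FALSE)
  rownames(nodes) <- NULL
  edges <- data.frame(from = character(0), to = character(0),
                      r = numeric(0), sign = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(nodes) >= 2) {
    x <- log10(pmax(table$abundance[sel, , drop = FALSE], 1))
    if (anyNA(x)) stop("network requires a fully imputed table",
                       call. = FALSE)
    cm <- suppressWarnings(cor(t(x)))
    endo <- nodes$category == "endogenous"
    rows <- list()
    for (i in seq_len(nrow(nodes) - 1)) {
      for (j in (i + 1):nrow(nodes)) {
        if (!endo[i] && !endo[j]) next
        r <- cm[i, j]
        if (!is.na(r) && abs(r) > r_threshold)
          rows[[length(rows) + 1L]] <- data.frame(
            from = nodes$id[i], to = nodes$id[j], r = r,
            sign = if (r > 0) "positive" else "negative",
            stringsAsFactors = FALSE)
      }
    }
    if (length(rows)) edges <- do.call(rbind, rows)
  }
  structure(list(nodes = nodes, edges = edges), class = "chem_network")
}

#' @export
print.chem_network <- function(x, ...) {
  cat("<chem_network> ", nrow(x$nodes), " nodes (",
      paste(names(table(x$nodes$category)), table(x$nodes$category),
            sep = "=", collapse = ", "), "), ",
      nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Per-node outcome-group detection proportions
#'
#' For each network node, among the samples in which the compound is
#' detected (pre-imputation detection mask), the percentage of detections
#' falling in each outcome group — the numbers behind the node pie charts.
#' A node detected nowhere gets missing proportions with a warning.
#'
#' @param network a [build_network()] result.
#' @param table the [feature_table()] the network was built from.
#' @param group_label sample column with the outcome labels
#'   (default `"outcome"`).
#' @param noise_floor detection floor passed to [ft_detected()].
#' @return the network with `pct_<group>` columns added to its nodes.
#' @export
group_proportions <- function(network, table, group_label = "outcome",
                              noise_floor = 1e4) {
  det <- ft_detected(table, noise_floor)
  grp <- table$samples[[group_label]]
  groups <- sort(unique(grp))
  idx <- match(network$nodes$id, table$features$feature_id)
  pct <- matrix(NA_real_, nrow(network$nodes), length(groups),
                dimnames = list(NULL, paste0("pct_", groups)))
  for (k in seq_along(idx)) {
    d <- det[idx[k], ]
    if (!any(d)) {
      warning("node never detected: ", network$nodes$id[k])
      next
    }
    pct[k, ] <- vapply(groups, function(gv) 100 * sum(d & grp == gv), 0) /
      sum(d)
  }
  network$nodes <- cbind(network$nodes, as.data.frame(pct))
  network
}
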