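#' Export a chemical network to node-link JSON or GraphML
#'
#' Nodes carry name, category, level, mean area and any group-proportion
#' columns; edges carry the Pearson R and its sign. Both formats are
#' loadable by standard graph tooling (d3-style node-link JSON; GraphML via
#' igraph). An empty network yields a valid file with an empty node list.
#'
#' @param network a `chem_network` from [build_network()].
#' @param path output path.
#' @param format `"json"` (node-link) or `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_graph_file <- function(network, path,
                             format = c("json", "graphml")) {
  format <- match.arg(format)
  if (format == "json") {
    obj <- list(
      nodes = if (nrow(network$nodes)) network$nodes else list(),
      links = if (nrow(network$edges)) {
        e <- network$edges
        names(e)[names(e) == "from"] <- "source"
        names(e)[names(e) == "to"] <- "target"
        e
      } else list())
    jsonlite::write_json(obj, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, na = "null")
  } else {
    v <- network$nodes
    # igraph reserves the vertex attribute "name" for the id
    names(v)[names(v) == "name"] <- "compound"
    g <- igraph::graph_from_data_frame(
      if (nrow(network$edges)) network$edges else
        data.frame(from = character(0), to = character(0)),
      directed = FALSE, vertices = v)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Re-import a graph file written by [write_graph_file()]
#'
#' @param path file path.
#' @param format `"json"` or `"graphml"`.
#' @return a `chem_network`.
#' @export
read_graph_file <- function(path, format = c("json", "graphml")) {
  format <- match.arg(format)
  if (format == "json") {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    nodes <- as.data.frame(obj$nodes, stringsAsFactors = FALSE)
    edges <- as.data.frame(obj$links, stringsAsFactors = FALSE)
    if (nrow(edges)) {
      names(edges)[names(edges) == "source"] <- "from"
      names(edges)[names(edges) == "target"] <- "to"
    } else {
      edges <- data.frame(from = character(0), to = character(0),
                          r = numeric(0), sign = character(0))
    }
  } else {
    g <- igraph::read_graph(path, format = "graphml")
    va <- igraph::vertex_attr(g)
    nodes <- as.data.frame(va, stringsAsFactors = FALSE)
    names(nodes)[names(nodes) == "name"] <- "id"
    if ("compound" %in% names(nodes))
      names(nodes)[names(nodes) == "compound"] <- "name"
    el <- igraph::as_edgelist(g)
    ea <- igraph::edge_attr(g)
    edges <- data.frame(from = el[, 1], to = el[, 2],
                        stringsAsFactors = FALSE)
    for (nm in names(ea)) edges[[nm]] <- ea[[nm]]
  }
  structure(list(nodes = nodes, edges = edges), class = "chem_network")
}
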