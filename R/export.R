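#' Convert a network to an igraph object
#'
#' [RegulatoryNetwork-class] becomes a directed graph with node attributes
#' `signed_score`, `size_category`, `log2fc`, `selected`, `anchor`;
#' [CategoryGraph-class] becomes an undirected graph with node attributes
#' `signed_score`, `supercategory`, `q_value`, `node_id` and edge attribute
#' `weight` (shared genes). `NA` numeric attributes are encoded as `NaN` so
#' GraphML round-trips are exact.
#'
#' @param network a [RegulatoryNetwork-class] or [CategoryGraph-class].
#' @return An [igraph][igraph::igraph-package] graph.
#' @export
asIgraph <- function(network) {
  nan <- function(x) ifelse(is.na(x), NaN, x)
  if (is(network, "RegulatoryNetwork")) {
    n <- network@nodes
    v <- data.frame(name = n$gene, size_category = n$size_category,
                    signed_score = nan(n$signed_score),
                    log2fc = nan(n$log2fc),
                    selected = n$selected, anchor = n$anchor,
                    stringsAsFactors = FALSE)
    e <- network@edgeTable
    g <- igraph::graph_from_data_frame(
      d = data.frame(from = e$regulator, to = e$target,
                     stringsAsFactors = FALSE),
      directed = TRUE, vertices = v)
  } else if (is(network, "CategoryGraph")) {
    n <- network@nodes
    v <- data.frame(name = n$category, supercategory = n$supercategory,
                    signed_score = nan(n$signed_score),
                    q_value = nan(n$q_value), node_id = n$node_id,
                    stringsAsFactors = FALSE)
    e <- network@edgeTable
    g <- igraph::graph_from_data_frame(
      d = data.frame(from = e$cat1, to = e$cat2,
                     weight = e$shared_genes, stringsAsFactors = FALSE),
      directed = FALSE, vertices = v)
  } else stop("unsupported network class: ", class(network), call. = FALSE)
  g
}

#' Export a network for Cytoscape
#'
#' Formats: `graphml` (full node/edge attributes; re-importable with
#' [readNetworkGraphML()]), `sif` (topology only; isolated nodes get an
#' orphan line with just the node name), and `node_edge_tsv` (two TSVs,
#' `<path>_nodes.tsv` and `<path>_edges.tsv`, carrying all attributes).
#'
#' @param network a [RegulatoryNetwork-class] or [CategoryGraph-class].
#' @param format one of `"graphml"`, `"sif"`, `"node_edge_tsv"`.
#' @param path output path (prefix for `node_edge_tsv`).
#' @return Character vector of written paths, invisibly.
#' @export
exportNetwork <- function(network, format = c("graphml", "sif",
                                              "node_edge_tsv"), path) {
  if (!is.character(format) || !all(format %in% c("graphml", "sif",
                                                  "node_edge_tsv")))
    stop("invalid format: ", paste(format, collapse = ","), call. = FALSE)
  format <- match.arg(format)
  isReg <- is(network, "RegulatoryNetwork")
  if (!isReg && !is(network, "CategoryGraph"))
    stop("unsupported network class: ", class(network), call. = FALSE)
  nodes <- network@nodes
  e <- network@edgeTable

  if (format == "graphml") {
    igraph::write_graph(asIgraph(network), path, format = "graphml")
    return(invisible(path))
  }
  if (format == "sif") {
    relation <- if (isReg) "regulates" else "shares"
    from <- if (isReg) e$regulator else e$cat1
    to <- if (isReg) e$target else e$cat2
    lines <- if (nrow(e)) paste(from, relation, to) else character()
    ids <- if (isReg) nodes$gene else nodes$category
    orphan <- setdiff(ids, c(from, to))
    writeLines(c(lines, orphan), path)
    return(invisible(path))
  }
  nodePath <- paste0(path, "_nodes.tsv")
  edgePath <- paste0(path, "_edges.tsv")
  .writeTSV(nodes, nodePath)
  .writeTSV(e, edgePath)
  invisible(c(nodePath, edgePath))
}

#' Re-import a GraphML file exported by [exportNetwork()]
#'
#' @param path GraphML path.
#' @return An igraph graph with the exported attributes.
#' @export
readNetworkGraphML <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  igraph::read_graph(path, format = "graphml")
}
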