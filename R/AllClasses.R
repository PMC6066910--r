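#' InteractionDB: a directed TF-to-target interaction database
#'
#' Holds a deduplicated set of directed regulator-to-target edges. The set of
#' targets of one regulator is its regulon. Gene identifiers are upper-cased
#' symbols; transcription factors are themselves genes and may appear as
#' targets of other factors.
#'
#' @slot edges data.frame with character columns `regulator`, `target`,
#'   `source` (free-text provenance label, may be `NA`). No duplicate
#'   (regulator, target) pairs, no self-edges.
#'
#' @seealso [InteractionDB()], [readInteractions()], [generateInteractionDB()]
#' @exportClass InteractionDB
setClass("InteractionDB", slots = c(edges = "data.frame"))

setValidity("InteractionDB", function(object) {
  e <- object@edges
  if (!all(c("regulator", "target", "source") %in% names(e)))
    return("edges must have columns regulator, target, source")
  if (nrow(e) == 0L) return(TRUE)
  if (!is.character(e$regulator) || !is.character(e$target))
    return("regulator and target must be character")
  if (any(e$regulator == e$target))
    return("self-edges (regulator == target) are not allowed")
  if (anyDuplicated(paste0(e$regulator, "\r", e$target)))
    return("duplicate edges are not allowed")
  TRUE
})

#' Construct an InteractionDB from an edge table
#'
#' Symbols are upper-cased, duplicate edges collapsed, and self-edges dropped
#' with a warning (real databases occasionally list autoregulation, which the
#' regulon model excludes by definition).
#'
#' @param regulator,target character vectors of equal length (gene symbols).
#' @param source optional character vector of per-edge provenance labels.
#' @return An [InteractionDB-class] object.
#' @examples
#' db <- InteractionDB(c("GATA2", "GATA2"), c("KLF1", "NFE2"))
#' nEdges(db)
#' @export
InteractionDB <- function(regulator = character(), target = character(),
                          source = NA_character_) {
  stopifnot(length(regulator) == length(target))
  if (length(regulator) == 0L) {
    return(new("InteractionDB",
               edges = data.frame(regulator = character(),
                                  target = character(),
                                  source = character(),
                                  stringsAsFactors = FALSE)))
  }
  e <- data.frame(regulator = .normSymbols(regulator, "regulator"),
                  target = .normSymbols(target, "target"),
                  source = rep_len(as.character(source), length(regulator)),
                  stringsAsFactors = FALSE)
  self <- e$regulator == e$target
  if (any(self)) {
    warning(sum(self), " self-edge(s) dropped (e.g. ",
            e$regulator[which(self)[1L]], ")", call. = FALSE)
    e <- e[!self, , drop = FALSE]
  }
  e <- e[!duplicated(paste0(e$regulator, "\r", e$target)), , drop = FALSE]
  rownames(e) <- NULL
  new("InteractionDB", edges = e)
}

#' @describeIn InteractionDB-class edge table accessor
#' @param x,object an `InteractionDB`
#' @export
edges <- function(x) {
  stopifnot(is(x, "InteractionDB"))
  x@edges
}

#' @describeIn InteractionDB-class number of edges
#' @export
nEdges <- function(x) nrow(edges(x))

#' @describeIn InteractionDB-class sorted unique regulator symbols
#' @export
regulators <- function(x) sort(unique(edges(x)$regulator))

setMethod("show", "InteractionDB", function(object) {
  e <- object@edges
  cat("InteractionDB with", nrow(e), "edges,",
      length(unique(e$regulator)), "regulators,",
      length(unique(e$target)), "targets\n")
  if (nrow(e) > 0L) {
    sizes <- table(e$regulator)
    cat("  regulon size: min", min(sizes), "/ median", median(sizes),
        "/ max", max(sizes), "\n")
  }
})

#' DEResult: per-gene differential-expression results for one contrast
#'
#' @slot table data.frame with columns `gene`, `log2fc` (group B over group
#'   A), `p_value`, `q_value` (BH-FDR), `direction` (`up`/`down`/`nc`).
#' @slot contrast character(1), contrast label.
#' @slot groupA,groupB character vectors of sample IDs.
#' @slot fdrThreshold,lfcThreshold numeric(1) thresholds used by
#'   [classifyDE()] (`NA` until classification).
#' @slot untested character, genes dropped before testing (all-zero counts in
#'   both groups).
#'
#' @seealso [deTest()], [classifyDE()], [deSets()]
#' @exportClass DEResult
setClass("DEResult",
         slots = c(table = "data.frame", contrast = "character",
                   groupA = "character", groupB = "character",
                   fdrThreshold = "numeric", lfcThreshold = "numeric",
                   untested = "character"))

setValidity("DEResult", function(object) {
  tb <- object@table
  need <- c("gene", "log2fc", "p_value", "q_value", "direction")
  if (!all(need %in% names(tb)))
    return(paste("table must have columns", paste(need, collapse = ", ")))
  if (anyDuplicated(tb$gene)) return("duplicate gene symbols in table")
  p <- tb$p_value
  if (any(p < 0 | p > 1, na.rm = TRUE)) return("p_value outside [0, 1]")
  if (!all(tb$direction %in% c("up", "down", "nc")))
    return("direction must be up/down/nc")
  TRUE
})

#' @describeIn DEResult-class per-gene results as a data.frame
#' @param x,object a `DEResult`
#' @export
deTable <- function(x) {
  stopifnot(is(x, "DEResult"))
  x@table
}

#' @describeIn DEResult-class the up/down/nc gene sets as a named list
#' @export
deSets <- function(x) {
  tb <- deTable(x)
  list(up = tb$gene[tb$direction == "up"],
       down = tb$gene[tb$direction == "down"],
       nc = tb$gene[tb$direction == "nc"])
}

#' @describeIn DEResult-class the tested gene universe
#' @export
deUniverse <- function(x) deTable(x)$gene

setMethod("show", "DEResult", function(object) {
  tb <- object@table
  cat("DEResult for contrast '", object@contrast, "': ",
      nrow(tb), " genes tested (", length(object@untested), " untested)\n",
      sep = "")
  cat("  up:", sum(tb$direction == "up"),
      " down:", sum(tb$direction == "down"),
      " nc:", sum(tb$direction == "nc"), "\n")
  if (!is.na(object@fdrThreshold))
    cat("  thresholds: FDR <=", object@fdrThreshold,
        ", |log2FC| >=", object@lfcThreshold, "\n")
})

#' RegulatoryNetwork: a scored TF network for one contrast
#'
#' Nodes are the selected regulons plus anchor genes; edges are the
#' interaction-database edges restricted to included nodes. Node annotations
#' carry the signed log-FDR regulon score (colour in a Cytoscape rendering),
#' the gene's own log2 fold change and its size category
#' (U = upregulated, NC = no change, D = downregulated).
#'
#' @slot nodes data.frame: `gene`, `size_category`, `signed_score`, `log2fc`,
#'   `selected`, `anchor`.
#' @slot edgeTable data.frame: `regulator`, `target`.
#' @slot contrast character(1).
#' @exportClass RegulatoryNetwork
setClass("RegulatoryNetwork",
         slots = c(nodes = "data.frame", edgeTable = "data.frame",
                   contrast = "character"))

setValidity("RegulatoryNetwork", function(object) {
  n <- object@nodes; e <- object@edgeTable
  if (!all(c("gene", "size_category", "signed_score", "log2fc",
             "selected", "anchor") %in% names(n)))
    return("nodes missing required columns")
  if (!all(c("regulator", "target") %in% names(e)))
    return("edgeTable missing required columns")
  if (nrow(e) > 0L &&
      !all(c(e$regulator, e$target) %in% n$gene))
    return("every edge endpoint must be a node")
  if (anyDuplicated(n$gene)) return("duplicate node genes")
  TRUE
})

setMethod("show", "RegulatoryNetwork", function(object) {
  cat("RegulatoryNetwork ('", object@contrast, "'): ",
      nrow(object@nodes), " nodes, ", nrow(object@edgeTable), " edges\n",
      sep = "")
})

#' CategoryGraph: GO category enrichment graph for one contrast
#'
#' Nodes are annotation categories passing a display FDR filter, scored for
#' enrichment (positive signed score) or depletion (negative) of DE genes;
#' undirected edges connect categories sharing universe genes, weighted by
#' the shared-gene count.
#'
#' @slot nodes data.frame: `category`, `name`, `node_id`, `n_category`, `k`,
#'   `p_value`, `q_value`, `signed_score`, `supercategory`.
#' @slot edgeTable data.frame: `cat1`, `cat2`, `shared_genes`.
#' @slot contrast character(1).
#' @exportClass CategoryGraph
setClass("CategoryGraph",
         slots = c(nodes = "data.frame", edgeTable = "data.frame",
                   contrast = "character"))

setValidity("CategoryGraph", function(object) {
  n <- object@nodes; e <- object@edgeTable
  if (!all(c("category", "node_id", "k", "q_value", "signed_score",
             "supercategory") %in% names(n)))
    return("nodes missing required columns")
  if (!all(c("cat1", "cat2", "shared_genes") %in% names(e)))
    return("edgeTable missing required columns")
  if (nrow(e) > 0L) {
    if (any(e$shared_genes < 1)) return("edge weight must be >= 1")
    if (!all(c(e$cat1, e$cat2) %in% n$category))
      return("every edge endpoint must be a node")
  }
  TRUE
})

setMethod("show", "CategoryGraph", function(object) {
  cat("CategoryGraph ('", object@contrast, "'): ",
      nrow(object@nodes), " categories, ", nrow(object@edgeTable),
      " shared-gene edges\n", sep = "")
})

#' ZMatrix: row-standardised expression of a marker panel
#'
#' @slot z numeric matrix, genes x samples; each non-constant row has mean 0
#'   and sample SD 1 (denominator n-1); constant rows are all zero.
#' @slot panel character(1), panel label.
#' @slot missingGenes character, panel genes absent from the expression
#'   matrix (reported, never silently dropped).
#' @slot constantRows character, genes whose row was constant.
#' @exportClass ZMatrix
setClass("ZMatrix",
         slots = c(z = "matrix", panel = "character",
                   missingGenes = "character", constantRows = "character"))

setValidity("ZMatrix", function(object) {
  z <- object@z
  if (nrow(z) > 0L) {
    const <- rownames(z) %in% object@constantRows
    if (any(const) && any(abs(z[const, , drop = FALSE]) > 1e-9))
      return("constant rows must be all zero")
    if (any(!const)) {
      m <- rowMeans(z[!const, , drop = FALSE])
      s <- apply(z[!const, , drop = FALSE], 1L, sd)
      if (any(abs(m) > 1e-9) || any(abs(s - 1) > 1e-9))
        return("non-constant rows must have mean 0 and sample SD 1")
    }
  }
  TRUE
})

setMethod("show", "ZMatrix", function(object) {
  cat("ZMatrix panel '", object@panel, "': ", nrow(object@z), " genes x ",
      ncol(object@z), " samples", sep = "")
  if (length(object@missingGenes))
    cat(" (missing: ", paste(object@missingGenes, collapse = ", "), ")",
        sep = "")
  cat("\n")
})

#' @describeIn ZMatrix-class the z-score matrix
#' @param x,object a `ZMatrix`
#' @export
zValues <- function(x) {
  stopifnot(is(x, "ZMatrix"))
  x@z
}
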