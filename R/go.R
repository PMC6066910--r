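#' Read a gene-to-category annotation table
#'
#' Two dialects: a two-column TSV `gene<TAB>category_id` (header optional,
#' detected by a `gene` first field), and a GAF-style tab-separated subset
#' where column 3 is the gene symbol, column 5 the GO ID and column 9 the
#' ontology aspect -- only cellular-component rows (aspect `C`) are kept.
#' Symbols are upper-cased and duplicate (gene, category) pairs collapsed.
#'
#' @param path file path.
#' @param format `"two_column_tsv"` or `"gaf_subset"`.
#' @param namesPath optional TSV `category_id<TAB>name` with human-readable
#'   term names.
#' @return list with `annotations` (data.frame `gene`, `category`) and
#'   `names` (data.frame `category`, `name`; synthesised from IDs when no
#'   names file is given). Empty files yield empty tables with a warning.
#' @export
readAnnotations <- function(path, format = c("two_column_tsv", "gaf_subset"),
                            namesPath = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "!")]
  emptyTab <- data.frame(gene = character(), category = character(),
                         stringsAsFactors = FALSE)
  if (format == "two_column_tsv") {
    if (length(lines) &&
        tolower(strsplit(lines[1L], "\t")[[1L]][1L]) == "gene")
      lines <- lines[-1L]
    if (length(lines) == 0L) {
      warning("empty annotation file: ", path, call. = FALSE)
      ann <- emptyTab
    } else {
      parts <- strsplit(lines, "\t", fixed = TRUE)
      bad <- which(vapply(parts, length, 1L) < 2L)
      if (length(bad))
        stop("parse error in ", path, " at line ", bad[1L],
             ": expected 2 tab-separated fields", call. = FALSE)
      ann <- data.frame(gene = .normSymbols(vapply(parts, `[[`, "", 1L)),
                        category = vapply(parts, `[[`, "", 2L),
                        stringsAsFactors = FALSE)
    }
  } else {
    if (length(lines) == 0L) {
      warning("empty annotation file: ", path, call. = FALSE)
      ann <- emptyTab
    } else {
      parts <- strsplit(lines, "\t", fixed = TRUE)
      bad <- which(vapply(parts, length, 1L) < 9L)
      if (length(bad))
        stop("parse error in ", path, " at line ", bad[1L],
             ": GAF rows need >= 9 tab-separated fields", call. = FALSE)
      aspect <- vapply(parts, `[[`, "", 9L)
      keep <- aspect == "C"
      parts <- parts[keep]
      if (length(parts) == 0L) {
        warning("no cellular-component rows in ", path, call. = FALSE)
        ann <- emptyTab
      } else {
        ann <- data.frame(gene = .normSymbols(vapply(parts, `[[`, "", 3L)),
                          category = vapply(parts, `[[`, "", 5L),
                          stringsAsFactors = FALSE)
      }
    }
  }
  if (nrow(ann) > 0L)
    ann <- ann[!duplicated(paste0(ann$gene, "\r", ann$category)), ,
               drop = FALSE]
  rownames(ann) <- NULL
  ids <- sort(unique(ann$category))
  nm <- data.frame(category = ids, name = ids, stringsAsFactors = FALSE)
  if (!is.null(namesPath)) {
    nt <- read.delim(namesPath, header = FALSE, stringsAsFactors = FALSE,
                     col.names = c("category", "name"))
    hit <- match(nm$category, nt$category)
    nm$name[!is.na(hit)] <- nt$name[hit[!is.na(hit)]]
  }
  list(annotations = ann, names = nm)
}

#' The default GO-CC term-name to supercategory map
#'
#' Maps plasma-membrane / cell-surface / extracellular-matrix term names to
#' `cell_surface` and cytoskeletal term names to `cytoskeleton` by keyword;
#' shipped as an editable TSV (`category pattern<TAB>supercategory`) in
#' `inst/extdata/supercategories.tsv`. Matching is case-insensitive
#' substring matching on the term name (or ID when no name is known);
#' unmapped terms become `other`.
#'
#' @return data.frame with columns `pattern`, `supercategory`.
#' @export
defaultSupercategoryMap <- function() {
  read.delim(system.file("extdata", "supercategories.tsv",
                         package = "regulonet"),
             stringsAsFactors = FALSE)
}

#' Assign supercategories to category terms
#'
#' @param categories category IDs.
#' @param names human-readable names matched against the map patterns
#'   (defaults to the IDs).
#' @param map data.frame `pattern`, `supercategory`; either keyword patterns
#'   (matched case-insensitively as fixed substrings) or exact category IDs.
#' @return Character vector in `{cell_surface, cytoskeleton, other}`.
#' @export
assignSupercategories <- function(categories, names = categories,
                                  map = defaultSupercategoryMap()) {
  out <- rep("other", length(categories))
  for (i in seq_len(nrow(map))) {
    hit <- grepl(map$pattern[i], names, ignore.case = TRUE, fixed = FALSE) |
      categories == map$pattern[i]
    out[hit] <- map$supercategory[i]
  }
  out
}

#' Score one annotation category against a DE set
#'
#' Same statistical core as regulon scoring: the category members within the
#' universe are tested against the DE set with an upper-tail hypergeometric
#' for enrichment and a lower-tail for depletion; the smaller tail is
#' reported as `p_value` with matching `direction`.
#'
#' @param category category ID.
#' @param deSet DE gene set (typically up, down or combined for one
#'   contrast).
#' @param annotations data.frame `gene`, `category` (e.g. from
#'   [readAnnotations()]).
#' @param universe background gene set; standard practice is the tested
#'   genes that carry at least one annotation.
#' @param minSize minimum category members in the universe (default 3).
#' @return One-row data.frame `category`, `n_universe`, `n_category`, `k`,
#'   `p_enrich`, `p_deplete`, `p_value`, `direction`; `NULL` if the category
#'   is too small in the universe.
#' @export
scoreCategory <- function(category, deSet, annotations, universe,
                          minSize = 3L) {
  if (!category %in% annotations$category)
    stop("unknown category: ", category, call. = FALSE)
  members <- unique(annotations$gene[annotations$category == category])
  universe <- unique(universe)
  members <- intersect(members, universe)
  n <- length(members)
  if (n < minSize) return(NULL)
  N <- length(universe)
  K <- length(intersect(unique(deSet), universe))
  k <- length(intersect(members, deSet))
  pe <- .hyperEnrich(k, K, N, n)
  pd <- .hyperDeplete(k, K, N, n)
  if (K == 0L) {
    p <- 1; direction <- "none"
  } else if (pe <= pd) {
    p <- pe; direction <- "enriched"
  } else {
    p <- pd; direction <- "depleted"
  }
  data.frame(category = category, n_universe = N, n_category = n, k = k,
             p_enrich = pe, p_deplete = pd, p_value = p,
             direction = direction, stringsAsFactors = FALSE)
}

#' Score all categories for one contrast
#'
#' Applies [scoreCategory()] to every category, adjusts with BH-FDR across
#' categories, and attaches the signed score (`-log10(q)` for enriched,
#' `log10(q)` for depleted, 0 for none) and the supercategory.
#'
#' @param annotations data.frame `gene`, `category`.
#' @param deSet DE gene set.
#' @param universe background gene set; default: annotated genes (callers
#'   normally pass tested-and-annotated genes).
#' @param minSize minimum category size in universe.
#' @param names optional data.frame `category`, `name`.
#' @param map supercategory map (see [assignSupercategories()]).
#' @return data.frame ordered by q then category, with `node_id` giving the
#'   stable 1-based rank order.
#' @export
scoreCategories <- function(annotations, deSet,
                            universe = unique(annotations$gene),
                            minSize = 3L, names = NULL,
                            map = defaultSupercategoryMap()) {
  cats <- sort(unique(annotations$category))
  rows <- lapply(cats, function(cc)
    scoreCategory(cc, deSet, annotations, universe, minSize))
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0L) {
    warning("no admissible categories", call. = FALSE)
    return(data.frame(category = character(), name = character(),
                      node_id = integer(), n_universe = integer(),
                      n_category = integer(), k = integer(),
                      p_value = numeric(), q_value = numeric(),
                      direction = character(), signed_score = numeric(),
                      supercategory = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, rows)
  res$q_value <- bhAdjust(res$p_value)
  res$signed_score <- ifelse(res$direction == "enriched",
                             .negLog10(res$q_value),
                             ifelse(res$direction == "depleted",
                                    -.negLog10(res$q_value), 0))
  nm <- if (is.null(names)) res$category else {
    hit <- match(res$category, names$category)
    ifelse(is.na(hit), res$category, names$name[hit])
  }
  res$name <- nm
  res$supercategory <- assignSupercategories(res$category, nm, map)
  res <- res[order(res$q_value, res$category), , drop = FALSE]
  res$node_id <- seq_len(nrow(res))
  rownames(res) <- NULL
  res[, c("category", "name", "node_id", "n_universe", "n_category", "k",
          "p_value", "q_value", "direction", "signed_score",
          "supercategory")]
}

#' Build the GO category graph for one contrast
#'
#' Nodes are the scored categories passing the display FDR filter; an
#' undirected edge joins every pair of displayed categories sharing at least
#' one universe gene, weighted by the shared-gene count
#' `|annotated(c1) n annotated(c2) n universe|`.
#'
#' @param scores data.frame from [scoreCategories()].
#' @param annotations data.frame `gene`, `category`.
#' @param universe background gene set used for the shared-gene counts.
#' @param qThreshold display filter on `q_value` (default 0.1).
#' @param contrast label stored on the graph.
#' @return A [CategoryGraph-class].
#' @export
buildCategoryGraph <- function(scores, annotations, universe,
                               qThreshold = 0.1, contrast = "contrast") {
  keep <- scores[scores$q_value <= qThreshold, , drop = FALSE]
  universe <- unique(universe)
  memb <- lapply(keep$category, function(cc)
    intersect(unique(annotations$gene[annotations$category == cc]),
              universe))
  names(memb) <- keep$category
  edgeRows <- list()
  if (nrow(keep) >= 2L) {
    idx <- utils::combn(nrow(keep), 2L)
    for (j in seq_len(ncol(idx))) {
      a <- idx[1L, j]; b <- idx[2L, j]
      w <- length(intersect(memb[[a]], memb[[b]]))
      if (w >= 1L)
        edgeRows[[length(edgeRows) + 1L]] <-
          data.frame(cat1 = keep$category[a], cat2 = keep$category[b],
                     shared_genes = w, stringsAsFactors = FALSE)
    }
  }
  edgeTable <- if (length(edgeRows)) do.call(rbind, edgeRows) else
    data.frame(cat1 = character(), cat2 = character(),
               shared_genes = integer(), stringsAsFactors = FALSE)
  rownames(keep) <- NULL
  new("CategoryGraph", nodes = keep, edgeTable = edgeTable,
      contrast = contrast)
}

#' Write category scores as TSV
#'
#' @param scores data.frame from [scoreCategories()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeCategoryScores <- function(scores, path) .writeTSV(scores, path)
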