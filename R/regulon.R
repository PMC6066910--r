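#' Score one regulon against a classified DE contrast
#'
#' Tests whether the regulon's members (its targets restricted to the tested
#' gene universe) are over-represented among the upregulated genes
#' (`p_up`, upper hypergeometric tail), over-represented among the
#' downregulated genes (`p_down`), or under-represented in the combined DE
#' set (`p_depletion`, lower tail on `k_up + k_down`). The dominant
#' direction is the smallest of the three probabilities; ties are broken
#' toward the direction with the larger overlap count, then toward up. With
#' no DE genes at all the dominant direction is `none`.
#'
#' @param db an [InteractionDB-class].
#' @param tf regulator symbol whose regulon is scored.
#' @param de a classified [DEResult-class] (directions assigned).
#' @param universe gene universe; defaults to the genes tested in `de`.
#'   The regulon is intersected with the universe before scoring.
#' @param minRegulonSize regulons smaller than this after intersection are
#'   not scored (returns `NULL` with a message). Default 3.
#' @return One-row data.frame with columns `tf`, `n_universe`, `n_regulon`,
#'   `k_up`, `k_down`, `p_up`, `p_down`, `p_depletion`, `p_dominant`,
#'   `direction`, `odds_ratio`, `tf_log2fc`; or `NULL` if skipped.
#' @examples
#' db <- InteractionDB(rep("TF1", 4), c("G1", "G2", "G3", "G4"))
#' @export
scoreRegulon <- function(db, tf, de, universe = deUniverse(de),
                         minRegulonSize = 3L) {
  stopifnot(is(db, "InteractionDB"), is(de, "DEResult"))
  members <- intersect(regulonOf(db, tf), universe)
  sets <- deSets(de)
  score <- .scoreMembers(members, sets, universe, minRegulonSize)
  if (is.null(score)) {
    .msg("regulon ", tf, " skipped: fewer than ", minRegulonSize,
         " members in the universe")
    return(NULL)
  }
  tb <- deTable(de)
  tfLfc <- tb$log2fc[match(.normSymbols(tf), tb$gene)]
  cbind(data.frame(tf = .normSymbols(tf), stringsAsFactors = FALSE),
        score,
        data.frame(tf_log2fc = if (length(tfLfc)) tfLfc else NA_real_,
                   stringsAsFactors = FALSE))
}

# Direction-aware hypergeometric scoring of one member set against up/down
# DE sets within a universe. Shared by regulon and category scoring.
#' @noRd
.scoreMembers <- function(members, sets, universe, minSize) {
  universe <- unique(universe)
  members <- intersect(unique(members), universe)
  n <- length(members)
  if (n < minSize) return(NULL)
  N <- length(universe)
  up <- intersect(sets$up, universe)
  down <- intersect(sets$down, universe)
  kUp <- length(intersect(members, up))
  kDown <- length(intersect(members, down))
  Kup <- length(up); Kdown <- length(down)
  pUp <- .hyperEnrich(kUp, Kup, N, n)
  pDown <- .hyperEnrich(kDown, Kdown, N, n)
  pDep <- .hyperDeplete(kUp + kDown, Kup + Kdown, N, n)

  if (Kup + Kdown == 0L) {
    direction <- "none"; pDom <- 1; orDom <- NA_real_
  } else {
    ps <- c(up = pUp, down = pDown, depleted = pDep)
    best <- names(ps)[ps == min(ps)]
    if (length(best) > 1L) {
      # tie-break: larger overlap count, then up
      pref <- c(up = kUp, down = kDown, depleted = -1L)[best]
      best <- best[order(-pref, match(best, c("up", "down", "depleted")))]
    }
    direction <- best[1L]
    pDom <- unname(ps[direction])
    orDom <- switch(direction,
                    up = .overlapOddsRatio(kUp, Kup, N, n),
                    down = .overlapOddsRatio(kDown, Kdown, N, n),
                    depleted = .overlapOddsRatio(kUp + kDown, Kup + Kdown,
                                                 N, n))
  }
  data.frame(n_universe = N, n_regulon = n, k_up = kUp, k_down = kDown,
             p_up = pUp, p_down = pDown, p_depletion = pDep,
             p_dominant = pDom, direction = direction, odds_ratio = orDom,
             stringsAsFactors = FALSE)
}

#' Score every admissible regulon for one contrast
#'
#' Applies [scoreRegulon()] to every regulator in the database, adjusts the
#' dominant-direction p-values with BH-FDR across regulons within the
#' contrast, attaches the signed log-FDR score (`-log10(q)` for up-dominant
#' regulons, `log10(q)`, i.e. negative, for down-dominant or depleted ones),
#' assigns the TF's own size category (`U` / `NC` / `D` from its log2 fold
#' change), and flags selected regulons by the data-driven rule
#' `q <= alphaSelect` AND dominant overlap `>= kMin` AND odds ratio
#' `>= orMin`. Depleted regulons are never selected (selection targets
#' active programs). Rows are ordered by q then tf.
#'
#' @param db an [InteractionDB-class].
#' @param de a classified [DEResult-class].
#' @param universe gene universe (default: tested genes).
#' @param minRegulonSize minimum members in universe (default 3).
#' @param alphaSelect selection FDR threshold (default 0.05).
#' @param kMin minimum dominant-direction overlap for selection (default 3).
#' @param orMin minimum odds ratio for selection (default 2).
#' @param sizeCategoryLfc |log2FC| separating U/D from NC (default 0.585,
#'   i.e. 1.5-fold).
#' @return data.frame with one row per scored regulon; columns as in
#'   [scoreRegulon()] plus `contrast`, `q_value`, `signed_score`,
#'   `size_category`, `selected`. Zero rows (with a warning) if no regulon
#'   is admissible.
#' @export
scoreContrast <- function(db, de, universe = deUniverse(de),
                          minRegulonSize = 3L, alphaSelect = 0.05,
                          kMin = 3L, orMin = 2, sizeCategoryLfc = 0.585) {
  stopifnot(is(db, "InteractionDB"), is(de, "DEResult"))
  if (all(is.na(deTable(de)$q_value)))
    stop("DE result has no directions: run classifyDE() first", call. = FALSE)
  tfs <- regulators(db)
  tb <- deTable(de)
  sets <- deSets(de)
  universe <- unique(universe)

  rows <- vector("list", length(tfs))
  for (i in seq_along(tfs)) {
    members <- intersect(regulonOf(db, tfs[i]), universe)
    sc <- .scoreMembers(members, sets, universe, minRegulonSize)
    if (is.null(sc)) next
    tfLfc <- tb$log2fc[match(tfs[i], tb$gene)]
    rows[[i]] <- cbind(data.frame(tf = tfs[i], stringsAsFactors = FALSE),
                       sc,
                       data.frame(tf_log2fc = tfLfc,
                                  stringsAsFactors = FALSE))
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0L) {
    warning("no admissible regulons for contrast '", de@contrast, "'",
            call. = FALSE)
    return(.emptyScores(de@contrast))
  }
  res <- do.call(rbind, rows)
  res$contrast <- de@contrast
  res$q_value <- bhAdjust(res$p_dominant)
  res$signed_score <- ifelse(res$direction == "up", .negLog10(res$q_value),
                             ifelse(res$direction %in% c("down", "depleted"),
                                    -.negLog10(res$q_value), 0))
  res$size_category <- sizeCategory(res$tf_log2fc, sizeCategoryLfc)
  kDom <- ifelse(res$direction == "up", res$k_up,
                 ifelse(res$direction == "down", res$k_down, 0L))
  res$selected <- res$direction %in% c("up", "down") &
    res$q_value <= alphaSelect & kDom >= kMin &
    !is.na(res$odds_ratio) & res$odds_ratio >= orMin
  res <- res[order(res$q_value, res$tf), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' @noRd
.emptyScores <- function(contrast) {
  data.frame(tf = character(), n_universe = integer(), n_regulon = integer(),
             k_up = integer(), k_down = integer(), p_up = numeric(),
             p_down = numeric(), p_depletion = numeric(),
             p_dominant = numeric(), direction = character(),
             odds_ratio = numeric(), tf_log2fc = numeric(),
             contrast = rep(contrast, 0L), q_value = numeric(),
             signed_score = numeric(), size_category = character(),
             selected = logical(), stringsAsFactors = FALSE)
}

#' Size category from a log2 fold change
#'
#' `U` (upregulated) if `log2fc >= threshold`, `D` if `<= -threshold`, else
#' `NC`; `NA` fold changes (gene untested) map to `NC`.
#'
#' @param log2fc numeric vector.
#' @param threshold |log2FC| cut (default 0.585, 1.5-fold).
#' @return Character vector in `{U, NC, D}`.
#' @export
sizeCategory <- function(log2fc, threshold = 0.585) {
  out <- rep("NC", length(log2fc))
  out[!is.na(log2fc) & log2fc >= threshold] <- "U"
  out[!is.na(log2fc) & log2fc <= -threshold] <- "D"
  out
}

#' Write regulon scores as TSV
#'
#' Columns `tf, contrast, n_regulon, k_up, k_down, p_up, p_down,
#' p_depletion, q, direction, signed_score, tf_log2fc, size_category,
#' selected`.
#'
#' @param scores data.frame from [scoreContrast()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeRegulonScores <- function(scores, path) {
  cols <- c(tf = "tf", contrast = "contrast", n_regulon = "n_regulon",
            k_up = "k_up", k_down = "k_down", p_up = "p_up",
            p_down = "p_down", p_depletion = "p_depletion", q = "q_value",
            direction = "direction", signed_score = "signed_score",
            tf_log2fc = "tf_log2fc", size_category = "size_category",
            selected = "selected")
  out <- scores[, unname(cols), drop = FALSE]
  names(out) <- names(cols)
  .writeTSV(out, path)
}

#' Assemble the regulatory network for one contrast
#'
#' Nodes are the selected regulons' TFs plus the anchor genes (default
#' `GATA2`); edges are all database edges with both endpoints in the node
#' set. Each node carries its size category (from its own log2 fold change),
#' the signed regulon score where the gene was scored as a regulon, and
#' flags for selection and anchor status. An anchor absent from both the
#' database and the DE table is still included, unannotated, with a warning.
#'
#' @param db an [InteractionDB-class].
#' @param scores data.frame from [scoreContrast()] for the same contrast as
#'   `de`.
#' @param de the classified [DEResult-class].
#' @param anchors genes always included (default `"GATA2"`).
#' @param sizeCategoryLfc threshold passed to [sizeCategory()].
#' @return A [RegulatoryNetwork-class].
#' @export
buildNetwork <- function(db, scores, de, anchors = "GATA2",
                         sizeCategoryLfc = 0.585) {
  stopifnot(is(db, "InteractionDB"), is(de, "DEResult"))
  anchors <- unique(.normSymbols(anchors, "anchor"))
  e <- edges(db)
  tb <- deTable(de)
  known <- unique(c(e$regulator, e$target, tb$gene))
  unknown <- setdiff(anchors, known)
  if (length(unknown))
    warning("anchor gene(s) absent from database and DE result: ",
            paste(unknown, collapse = ", "), call. = FALSE)

  selectedTfs <- scores$tf[scores$selected]
  nodeGenes <- sort(unique(c(selectedTfs, anchors)))
  lfc <- tb$log2fc[match(nodeGenes, tb$gene)]
  sIdx <- match(nodeGenes, scores$tf)
  nodes <- data.frame(
    gene = nodeGenes,
    size_category = sizeCategory(lfc, sizeCategoryLfc),
    signed_score = ifelse(is.na(sIdx), NA_real_, scores$signed_score[sIdx]),
    log2fc = lfc,
    selected = nodeGenes %in% selectedTfs,
    anchor = nodeGenes %in% anchors,
    stringsAsFactors = FALSE)
  keep <- e$regulator %in% nodeGenes & e$target %in% nodeGenes
  edgeTable <- e[keep, c("regulator", "target"), drop = FALSE]
  rownames(edgeTable) <- NULL
  new("RegulatoryNetwork", nodes = nodes, edgeTable = edgeTable,
      contrast = de@contrast)
}
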