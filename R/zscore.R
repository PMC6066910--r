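#' Default HE / non-HE marker panels
#'
#' Marker genes distinguishing hemogenic endothelium (HE) from
#' non-hemogenic endothelium: HE cells express higher RHAG, GFI1, RUNX1,
#' NTS and BMPER, while non-HE cells express higher SOX17, COL15A1, CAV1,
#' SCG5 and EMCN.
#'
#' @return Named list of character vectors (`HE`, `nonHE`).
#' @examples
#' markerPanels()$HE
#' @export
markerPanels <- function() {
  list(HE = c("RHAG", "GFI1", "RUNX1", "NTS", "BMPER"),
       nonHE = c("SOX17", "COL15A1", "CAV1", "SCG5", "EMCN"))
}

#' Row z-scores of a marker panel
#'
#' Standardises each selected gene's expression row to mean 0 and sample SD
#' 1 (denominator n-1), the usual heatmap scaling. Constant rows become all
#' zeros and are flagged; panel genes absent from the matrix are reported in
#' the result's metadata, never silently dropped.
#'
#' @param expr numeric matrix of (normalised) expression, genes x samples,
#'   with row names.
#' @param panel character vector of panel genes, unique symbols.
#' @param panelName label stored on the result.
#' @return A [ZMatrix-class].
#' @examples
#' m <- rbind(G1 = c(1, 2, 3), G2 = c(5, 5, 5))
#' colnames(m) <- c("s1", "s2", "s3")
#' zValues(rowZScore(m, c("G1", "G2")))
#' @export
rowZScore <- function(expr, panel, panelName = "panel") {
  if (!is.matrix(expr) || is.null(rownames(expr)))
    stop("expr must be a matrix with row names", call. = FALSE)
  if (ncol(expr) < 2L)
    stop("invalid input: need >= 2 samples to standardise rows",
         call. = FALSE)
  panel <- unique(.normSymbols(panel, "panel gene"))
  present <- panel[panel %in% rownames(expr)]
  missing <- setdiff(panel, present)
  x <- expr[present, , drop = FALSE]
  if (nrow(x) == 0L) {
    z <- matrix(numeric(), nrow = 0L, ncol = ncol(expr),
                dimnames = list(character(), colnames(expr)))
    return(new("ZMatrix", z = z, panel = panelName,
               missingGenes = missing, constantRows = character()))
  }
  mu <- rowMeans(x)
  s <- apply(x, 1L, sd)
  const <- s < 1e-12
  z <- (x - mu) / ifelse(const, 1, s)
  z[const, ] <- 0
  new("ZMatrix", z = z, panel = panelName,
      missingGenes = missing, constantRows = rownames(x)[const])
}

#' Write a ZMatrix as TSV
#'
#' Gene-by-sample table with a leading `gene` column; missing panel genes
#' are recorded as comment header lines (`# missing: ...`).
#'
#' @param zm a [ZMatrix-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeZMatrix <- function(zm, path) {
  stopifnot(is(zm, "ZMatrix"))
  con <- file(path, "w")
  on.exit(close(con))
  if (length(zm@missingGenes))
    writeLines(paste0("# missing: ",
                      paste(zm@missingGenes, collapse = ",")), con)
  if (length(zm@constantRows))
    writeLines(paste0("# constant: ",
                      paste(zm@constantRows, collapse = ",")), con)
  df <- data.frame(gene = rownames(zm@z), zm@z, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}
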