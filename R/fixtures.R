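#' Write simulated data as plain-text fixtures
#'
#' Emits `interactions.tsv` (regulator/target/source), `counts.tsv` (first
#' column `gene`, then one integer column per sample), `metadata.tsv`
#' (`sample, subset, genotype, dox, replicate`) and `truth.json` (per
#' contrast: perturbed genes with log2 fold change, active regulons with
#' direction). Files round-trip losslessly through [readInteractions()],
#' [readCountMatrix()] and [readTruth()].
#'
#' @param db an [InteractionDB-class].
#' @param se the count [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class].
#' @param truth the ground-truth list from [simulateCounts()] (or `NULL` to
#'   skip `truth.json`).
#' @param dir output directory (created if absent).
#' @return Named character vector of the written paths, invisibly.
#' @export
writeFixtures <- function(db, se, truth, dir) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create directory: ", dir, call. = FALSE)
  }
  paths <- c(interactions = file.path(dir, "interactions.tsv"),
             counts = file.path(dir, "counts.tsv"),
             metadata = file.path(dir, "metadata.tsv"),
             truth = file.path(dir, "truth.json"))
  writeInteractions(db, paths[["interactions"]])

  counts <- assay(se, "counts")
  .writeTSV(data.frame(gene = rownames(counts), counts,
                       check.names = FALSE, stringsAsFactors = FALSE),
            paths[["counts"]])
  cd <- as.data.frame(colData(se))
  .writeTSV(data.frame(sample = rownames(cd), cd,
                       check.names = FALSE, stringsAsFactors = FALSE),
            paths[["metadata"]])

  if (!is.null(truth)) {
    obj <- lapply(names(truth$deGenes), function(cn) {
      list(genes = truth$deGenes[[cn]],
           regulons = truth$activeRegulons[[cn]])
    })
    names(obj) <- names(truth$deGenes)
    jsonlite::write_json(obj, paths[["truth"]], dataframe = "rows",
                         auto_unbox = TRUE, digits = NA)
  } else {
    paths <- paths[names(paths) != "truth"]
  }
  invisible(paths)
}

#' Read a count matrix and its sample metadata
#'
#' @param countsPath TSV with first column `gene`, remaining columns samples,
#'   integer cells.
#' @param metadataPath TSV with columns `sample, subset, genotype, dox,
#'   replicate`; every count column must have a metadata row.
#' @return A [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#'   with a `counts` assay.
#' @export
readCountMatrix <- function(countsPath, metadataPath) {
  for (p in c(countsPath, metadataPath))
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  tab <- read.delim(countsPath, check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (names(tab)[1L] != "gene")
    stop("counts file must start with a 'gene' column", call. = FALSE)
  genes <- .normSymbols(tab$gene, "gene")
  if (anyDuplicated(genes))
    stop("duplicate gene symbols in counts file", call. = FALSE)
  counts <- as.matrix(tab[, -1L, drop = FALSE])
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  storage.mode(counts) <- "integer"
  rownames(counts) <- genes

  meta <- read.delim(metadataPath, stringsAsFactors = FALSE)
  need <- c("sample", "subset", "genotype", "dox", "replicate")
  if (!all(need %in% names(meta)))
    stop("metadata must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  missing <- setdiff(colnames(counts), meta$sample)
  if (length(missing))
    stop("samples missing from metadata: ", paste(missing, collapse = ", "),
         call. = FALSE)
  meta <- meta[match(colnames(counts), meta$sample), , drop = FALSE]
  SummarizedExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(meta[, c("subset", "genotype", "dox",
                                            "replicate")],
                                   row.names = meta$sample))
}

#' Read a ground-truth JSON file written by [writeFixtures()]
#'
#' @param path truth.json path.
#' @return list with `deGenes` and `activeRegulons`, each a per-contrast list
#'   of data.frames.
#' @export
readTruth <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  fix <- function(x, cols) {
    if (is.null(x) || length(x) == 0L)
      return(stats::setNames(as.data.frame(rep(list(character()),
                                               length(cols)),
                                           stringsAsFactors = FALSE), cols))
    as.data.frame(x, stringsAsFactors = FALSE)
  }
  list(deGenes = lapply(obj, function(cn) fix(cn$genes, c("gene", "lfc"))),
       activeRegulons = lapply(obj, function(cn)
         fix(cn$regulons, c("tf", "direction"))))
}
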