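#' Generate a synthetic TF-to-target interaction database
#'
#' Regulon sizes are drawn from a truncated negative binomial centred on
#' `meanRegulonSize` (minimum 3, shape 2 -- heavy-tailed like curated regulon
#' databases), capped at `nTargets`. Target sharing between regulons is
#' governed by a single shared pool of `meanRegulonSize` targets: each slot of
#' a regulon comes from the pool with probability `regulonOverlap`, otherwise
#' from the private remainder of the target universe. Two degenerate cases
#' are defined exactly: `meanRegulonSize == nTargets` makes every regulon
#' cover all targets, and `regulonOverlap == 1` gives every regulon the
#' shared pool verbatim (identical target sets).
#'
#' Regulators are named `TF001, TF002, ...` and targets `G00001, ...`; TFs
#' are genes and may be targeted by other TFs (with the same overlap rule).
#'
#' @param nTfs number of transcription factors (>= 1).
#' @param nTargets number of distinct non-TF target genes
#'   (>= `meanRegulonSize`).
#' @param meanRegulonSize mean regulon size (>= 3).
#' @param regulonOverlap pairwise target-sharing control in \[0, 1\].
#' @param seed integer seed; the same seed gives an identical edge set.
#' @return An [InteractionDB-class].
#' @examples
#' db <- generateInteractionDB(5, 100, 10, 0.2, seed = 1)
#' db
#' @export
generateInteractionDB <- function(nTfs, nTargets, meanRegulonSize,
                                  regulonOverlap = 0, seed = 1L) {
  .assertCount(nTfs, "nTfs")
  .assertCount(nTargets, "nTargets")
  .assertCount(meanRegulonSize, "meanRegulonSize", min = 3L)
  .assertFraction(regulonOverlap, "regulonOverlap")
  .assertCount(seed, "seed", min = 0L)
  if (meanRegulonSize > nTargets)
    stop("invalid config: meanRegulonSize (", meanRegulonSize,
         ") exceeds nTargets (", nTargets, ")", call. = FALSE)

  tfs <- sprintf("TF%03d", seq_len(nTfs))
  targets <- sprintf("G%05d", seq_len(nTargets))
  genes <- c(targets, tfs)   # TFs can target other TFs

  withr::with_seed(as.integer(seed), {
    if (meanRegulonSize == nTargets) {
      sizes <- rep(nTargets, nTfs)       # boundary case: full coverage
    } else {
      sizes <- 3L + rnbinom(nTfs, mu = meanRegulonSize - 3L, size = 2)
      sizes <- pmin(sizes, nTargets)
    }
    pool <- sample(targets, meanRegulonSize)
    edgeList <- vector("list", nTfs)
    for (i in seq_len(nTfs)) {
      tf <- tfs[i]
      if (regulonOverlap >= 1) {
        tg <- pool
      } else if (meanRegulonSize == nTargets) {
        tg <- targets
      } else {
        nShared <- min(rbinom(1L, sizes[i], regulonOverlap), length(pool))
        shared <- if (nShared > 0L) sample(pool, nShared) else character()
        priv <- setdiff(genes, c(shared, tf))
        tg <- c(shared, sample(priv, sizes[i] - nShared))
      }
      edgeList[[i]] <- data.frame(regulator = tf, target = setdiff(tg, tf),
                                  stringsAsFactors = FALSE)
    }
  })
  e <- do.call(rbind, edgeList)
  InteractionDB(e$regulator, e$target, source = "synthetic")
}

#' Read a TF-to-target interaction database
#'
#' Two dialects are supported: a three-column TSV with header
#' `regulator<TAB>target<TAB>source` (the `source` column optional), and
#' Cytoscape SIF (`source relation target1 target2 ...`, whitespace- or
#' tab-delimited). Symbols are upper-cased, duplicates collapsed, and
#' self-edges dropped with a warning.
#'
#' @param path file path.
#' @param format `"tsv"` or `"sif"`.
#' @return An [InteractionDB-class]; an empty file yields a valid empty
#'   database with a warning.
#' @export
readInteractions <- function(path, format = c("tsv", "sif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (format == "tsv") {
    if (length(lines) <= 1L) {
      warning("empty interaction file: ", path, call. = FALSE)
      return(InteractionDB())
    }
    body <- lines[-1L]  # header
    parts <- strsplit(body, "\t", fixed = TRUE)
    bad <- which(vapply(parts, length, 1L) < 2L)
    if (length(bad))
      stop("parse error in ", path, " at line ", bad[1L] + 1L,
           ": expected at least 2 tab-separated fields", call. = FALSE)
    reg <- vapply(parts, `[[`, "", 1L)
    tgt <- vapply(parts, `[[`, "", 2L)
    src <- vapply(parts, function(p) if (length(p) >= 3L) p[[3L]] else NA_character_, "")
    return(InteractionDB(reg, tgt, src))
  }
  # SIF: one source, a relation, zero or more targets per line
  if (length(lines) == 0L) {
    warning("empty interaction file: ", path, call. = FALSE)
    return(InteractionDB())
  }
  reg <- character(); tgt <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1L]]
    if (length(f) == 1L) next            # orphan node line: no edges
    if (length(f) == 2L)
      stop("parse error in ", path, " at line ", i,
           ": SIF line with a relation but no target", call. = FALSE)
    reg <- c(reg, rep(f[1L], length(f) - 2L))
    tgt <- c(tgt, f[-(1:2)])
  }
  if (length(reg) == 0L) {
    warning("interaction file has no edges: ", path, call. = FALSE)
    return(InteractionDB())
  }
  InteractionDB(reg, tgt)
}

#' Write an InteractionDB as TSV
#'
#' @param db an [InteractionDB-class].
#' @param path output path; dialect `regulator<TAB>target<TAB>source`.
#' @return the path, invisibly.
#' @export
writeInteractions <- function(db, path) {
  stopifnot(is(db, "InteractionDB"))
  .writeTSV(edges(db), path)
}

#' Regulon of a transcription factor
#'
#' The set of known targets of `tf` in the database.
#'
#' @param db an [InteractionDB-class].
#' @param tf regulator gene symbol (case-insensitive).
#' @return Character vector of target symbols, sorted.
#' @export
regulonOf <- function(db, tf) {
  stopifnot(is(db, "InteractionDB"))
  tf <- .normSymbols(tf, "regulator")
  stopifnot(length(tf) == 1L)
  e <- edges(db)
  if (!tf %in% e$regulator)
    stop("unknown regulator: ", tf, call. = FALSE)
  sort(unique(e$target[e$regulator == tf]))
}

#' Upstream regulators of a gene
#'
#' All regulators with an edge into `gene`; the empty set if the gene is
#' untargeted or absent.
#'
#' @param db an [InteractionDB-class].
#' @param gene gene symbol.
#' @return Character vector of regulator symbols, sorted (possibly empty).
#' @export
regulatorsOf <- function(db, gene) {
  stopifnot(is(db, "InteractionDB"))
  gene <- .normSymbols(gene, "gene")
  stopifnot(length(gene) == 1L)
  e <- edges(db)
  sort(unique(e$regulator[e$target == gene]))
}

#' Common upstream regulators of a gene set
#'
#' The intersection over `genes` of [regulatorsOf()]; used to ask which TFs
#' co-regulate a panel of genes (e.g. the shared upstream regulators of
#' KLF1, NFE2 and GFI1B).
#'
#' @param db an [InteractionDB-class].
#' @param genes nonempty character vector of gene symbols.
#' @return Character vector of regulator symbols, sorted (possibly empty).
#' @export
commonRegulators <- function(db, genes) {
  stopifnot(is(db, "InteractionDB"))
  if (length(genes) == 0L)
    stop("invalid input: 'genes' must be nonempty", call. = FALSE)
  genes <- unique(.normSymbols(genes, "gene"))
  Reduce(intersect, lapply(genes, function(g) regulatorsOf(db, g)))
}

#' Per-gene upstream-regulator counts
#'
#' Summary used to report regulatory load (how many TFs target each gene).
#'
#' @param db an [InteractionDB-class].
#' @param genes genes to summarise; default all targets in the database.
#' @return data.frame with columns `gene`, `n_regulators`.
#' @export
regulatorCounts <- function(db, genes = NULL) {
  stopifnot(is(db, "InteractionDB"))
  e <- edges(db)
  if (is.null(genes)) genes <- sort(unique(e$target))
  else genes <- unique(.normSymbols(genes, "gene"))
  n <- vapply(genes, function(g) length(unique(e$regulator[e$target == g])), 1L)
  data.frame(gene = genes, n_regulators = as.integer(n),
             row.names = NULL, stringsAsFactors = FALSE)
}
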