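#' Median-of-ratios size factors
#'
#' Per-sample normalisation constants computed as the median, over reference
#' genes, of the ratio of that sample's count to the gene's geometric mean
#' across samples. Reference genes are those with a nonzero count in every
#' sample (a gene with a zero anywhere contributes to no sample's median).
#' The factors are rescaled so their geometric mean is exactly 1, making
#' them comparable across runs.
#'
#' @param counts a count matrix (genes x samples) or a
#'   [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#'   with a `counts` assay.
#' @return Named numeric vector of positive size factors, one per sample.
#' @examples
#' m <- matrix(c(10, 20, 30, 20, 40, 60), ncol = 2,
#'             dimnames = list(c("A", "B", "C"), c("s1", "s2")))
#' computeSizeFactors(m)   # c(1/sqrt(2), sqrt(2))
#' @export
computeSizeFactors <- function(counts) {
  m <- .countsMatrix(counts)
  if (ncol(m) < 1L) stop("no samples", call. = FALSE)
  ref <- rowSums(m > 0) == ncol(m)
  if (!any(ref))
    stop("normalization impossible: no gene has nonzero counts in all samples",
         call. = FALSE)
  logGeo <- rowMeans(log(m[ref, , drop = FALSE]))
  sf <- apply(m[ref, , drop = FALSE], 2L,
              function(cnt) exp(median(log(cnt) - logGeo)))
  sf <- sf / exp(mean(log(sf)))
  sf
}

#' @noRd
.countsMatrix <- function(counts) {
  if (is(counts, "SummarizedExperiment")) counts <- assay(counts, "counts")
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  counts
}

#' Size-factor-normalised counts
#'
#' @param counts as in [computeSizeFactors()].
#' @param sizeFactors optional precomputed factors; computed if `NULL`.
#' @return Matrix of counts divided column-wise by the size factors.
#' @export
normalizedCounts <- function(counts, sizeFactors = NULL) {
  m <- .countsMatrix(counts)
  if (is.null(sizeFactors)) sizeFactors <- computeSizeFactors(m)
  stopifnot(length(sizeFactors) == ncol(m), all(sizeFactors > 0))
  sweep(m, 2L, sizeFactors, `/`)
}

# Vectorised Welch two-sample t statistics on the rows of two matrices of
# log2 values. Variances are floored to keep the denominator and the
# Welch-Satterthwaite df defined for zero-variance genes.
#' @noRd
.welchRows <- function(a, b, varFloor = 1e-8) {
  n1 <- ncol(a); n2 <- ncol(b)
  m1 <- rowMeans(a); m2 <- rowMeans(b)
  v1 <- pmax(rowSums((a - m1)^2) / (n1 - 1), varFloor)
  v2 <- pmax(rowSums((b - m2)^2) / (n2 - 1), varFloor)
  se2 <- v1 / n1 + v2 / n2
  t <- (m2 - m1) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(t), df)
  # equal means and (floored) zero spread in both groups: no evidence
  degenerate <- abs(m2 - m1) < 1e-12
  p[degenerate] <- 1
  t[degenerate] <- 0
  list(log2fc = m2 - m1, t = t, df = df, p = pmin(p, 1))
}

#' Welch differential-expression test for one contrast
#'
#' Counts are size-factor normalised, shifted by a pseudocount, log2
#' transformed, and compared per gene between two sample groups with a
#' two-sided Welch t test (Welch-Satterthwaite degrees of freedom). The
#' log2 fold change is group B minus group A on the log2 scale. Genes with
#' zero counts across all samples of both groups are dropped before testing
#' and reported in the `untested` slot. Multiple-testing adjustment is left
#' to [classifyDE()] / [bhAdjust()] (the returned `q_value` is `NA`).
#'
#' @param counts matrix or SummarizedExperiment with a `counts` assay.
#' @param groupA,groupB disjoint character vectors of sample (column) names;
#'   each needs >= 2 replicates.
#' @param contrast contrast label stored in the result.
#' @param pseudocount positive shift before log2 (default 1).
#' @param sizeFactors optional precomputed size factors for all columns of
#'   `counts`.
#' @return A [DEResult-class] with `log2fc` and `p_value` filled.
#' @examples
#' m <- matrix(rpois(600, 50), nrow = 100,
#'             dimnames = list(sprintf("G%03d", 1:100),
#'                             sprintf("s%d", 1:6)))
#' de <- deTest(m, paste0("s", 1:3), paste0("s", 4:6), "demo")
#' de
#' @export
deTest <- function(counts, groupA, groupB, contrast = "contrast",
                   pseudocount = 1, sizeFactors = NULL) {
  m <- .countsMatrix(counts)
  .assertPositive(pseudocount, "pseudocount")
  if (length(intersect(groupA, groupB)))
    stop("invalid contrast: groups overlap (",
         paste(intersect(groupA, groupB), collapse = ", "), ")",
         call. = FALSE)
  missing <- setdiff(c(groupA, groupB), colnames(m))
  if (length(missing))
    stop("samples not in count matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (length(groupA) < 2L || length(groupB) < 2L)
    stop("insufficient replication: each group needs >= 2 replicates",
         call. = FALSE)

  if (is.null(sizeFactors))
    sizeFactors <- computeSizeFactors(m[, c(groupA, groupB), drop = FALSE])
  else
    sizeFactors <- sizeFactors[match(c(groupA, groupB), colnames(m))]
  norm <- normalizedCounts(m[, c(groupA, groupB), drop = FALSE], sizeFactors)

  tested <- rowSums(m[, c(groupA, groupB), drop = FALSE]) > 0
  lg <- log2(norm + pseudocount)
  a <- lg[tested, groupA, drop = FALSE]
  b <- lg[tested, groupB, drop = FALSE]
  w <- .welchRows(a, b)

  tb <- data.frame(gene = rownames(m)[tested],
                   log2fc = unname(w$log2fc),
                   p_value = unname(w$p),
                   q_value = NA_real_,
                   direction = "nc",
                   stringsAsFactors = FALSE)
  new("DEResult", table = tb, contrast = contrast,
      groupA = groupA, groupB = groupB,
      fdrThreshold = NA_real_, lfcThreshold = NA_real_,
      untested = rownames(m)[!tested])
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up BH-FDR in input order: `q_(i) = min_(j>=i) p_(j) * m / j`, capped
#' at 1 (delegates to [stats::p.adjust()]).
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return Adjusted values in the input order.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03))  # all 0.03
#' @export
bhAdjust <- function(p) {
  if (!is.numeric(p) || any(is.na(p)) || any(p < 0 | p > 1))
    stop("invalid p: values must be numeric in [0, 1]", call. = FALSE)
  p.adjust(p, method = "BH")
}

#' Classify genes as up / down / nc for a contrast
#'
#' Fills `q_value` with BH-adjusted p-values and assigns direction: `up` if
#' `q <= fdrThreshold` and `log2fc >= lfcThreshold`, `down` if
#' `q <= fdrThreshold` and `log2fc <= -lfcThreshold`, else `nc`. The three
#' classes partition the tested genes.
#'
#' @param de a [DEResult-class] from [deTest()].
#' @param fdrThreshold BH-FDR cutoff (default 0.05).
#' @param lfcThreshold minimum |log2 fold change| (default 1).
#' @return The classified [DEResult-class].
#' @export
classifyDE <- function(de, fdrThreshold = 0.05, lfcThreshold = 1) {
  stopifnot(is(de, "DEResult"))
  if (fdrThreshold < 0 || lfcThreshold < 0)
    stop("invalid config: thresholds must be non-negative", call. = FALSE)
  tb <- de@table
  tb$q_value <- bhAdjust(tb$p_value)
  tb$direction <- "nc"
  sig <- tb$q_value <= fdrThreshold
  tb$direction[sig & tb$log2fc >= lfcThreshold] <- "up"
  tb$direction[sig & tb$log2fc <= -lfcThreshold] <- "down"
  de@table <- tb
  de@fdrThreshold <- fdrThreshold
  de@lfcThreshold <- lfcThreshold
  validObject(de)
  de
}

#' Write per-gene DE results as TSV
#'
#' Columns `gene, log2fc, p_value, q_value, direction, contrast`.
#'
#' @param de a [DEResult-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeDEResults <- function(de, path) {
  stopifnot(is(de, "DEResult"))
  tb <- deTable(de)
  tb$contrast <- de@contrast
  .writeTSV(tb, path)
}

#' Samples of a SummarizedExperiment matching a selector
#'
#' @param se SummarizedExperiment with `subset`, `genotype`, `dox` in
#'   `colData`.
#' @param selector named list over those fields; `NULL` fields match all.
#' @return Character vector of sample names.
#' @export
samplesMatching <- function(se, selector) {
  cd <- as.data.frame(colData(se))
  bad <- setdiff(names(selector), c("subset", "genotype", "dox"))
  if (length(bad))
    stop("unknown contrast selector field: ", paste(bad, collapse = ", "),
         call. = FALSE)
  keep <- rep(TRUE, nrow(cd))
  for (f in names(selector))
    keep <- keep & cd[[f]] == selector[[f]]
  rownames(cd)[keep]
}
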