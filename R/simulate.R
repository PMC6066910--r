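#' SimulationConfig: study design for the synthetic count generator
#'
#' Encodes the simulated experiment: sorted cell subsets by genotype and
#' doxycycline status with replicate counts, negative-binomial noise
#' parameters, library-size variation, the contrasts of interest, and which
#' regulons are transcriptionally active (and how strongly) in each
#' contrast. The defaults emulate a sorted-subset knockout RNA-seq design:
#' three subsets (HE, nonHE, CD43pos) x two genotypes (WT, KO), three
#' replicates each, with one wild-type-versus-knockout contrast per subset.
#'
#' @slot nGenes simulated gene universe size.
#' @slot groups data.frame `subset`, `genotype`, `dox`, `n_replicates`.
#' @slot contrasts named list; each element has selectors `a` and `b`
#'   (named lists over subset/genotype/dox). Fold changes are group B over
#'   group A.
#' @slot baselineMean median of the log-normal per-gene baseline means
#'   (counts).
#' @slot dispersion NB dispersion alpha, variance = mu + alpha * mu^2.
#' @slot libSizeRange log-uniform range of per-sample library-size factors.
#' @slot activeRegulons data.frame `tf`, `contrast`, `lfc` (log2),
#'   `fraction_responsive` in (0, 1].
#' @slot seed integer seed.
#' @exportClass SimulationConfig
setClass("SimulationConfig",
         slots = c(nGenes = "numeric", groups = "data.frame",
                   contrasts = "list", baselineMean = "numeric",
                   dispersion = "numeric", libSizeRange = "numeric",
                   activeRegulons = "data.frame", seed = "numeric"))

setValidity("SimulationConfig", function(object) {
  if (object@dispersion <= 0) return("dispersion must be > 0")
  if (object@nGenes < 1) return("nGenes must be >= 1")
  if (length(object@libSizeRange) != 2L || any(object@libSizeRange <= 0) ||
      diff(object@libSizeRange) < 0)
    return("libSizeRange must be two positive increasing numbers")
  g <- object@groups
  if (!all(c("subset", "genotype", "dox", "n_replicates") %in% names(g)))
    return("groups must have subset, genotype, dox, n_replicates")
  if (nrow(g) == 0L || any(g$n_replicates < 1))
    return("at least one group with >= 1 replicate is required")
  ar <- object@activeRegulons
  if (nrow(ar) > 0L) {
    if (!all(c("tf", "contrast", "lfc", "fraction_responsive") %in% names(ar)))
      return("activeRegulons must have tf, contrast, lfc, fraction_responsive")
    if (any(ar$fraction_responsive <= 0 | ar$fraction_responsive > 1))
      return("fraction_responsive must be in (0, 1]")
    if (!all(ar$contrast %in% names(object@contrasts)))
      return("activeRegulons reference unknown contrast ids")
  }
  if (is.null(names(object@contrasts)) ||
      any(!nzchar(names(object@contrasts))))
    return("contrasts must be a named list")
  TRUE
})

#' @rdname SimulationConfig-class
#' @param nGenes,groups,contrasts,baselineMean,dispersion,libSizeRange,activeRegulons,seed
#'   see the corresponding slots.
#' @return A `SimulationConfig`.
#' @examples
#' cfg <- SimulationConfig(nGenes = 2000, seed = 7)
#' cfg
#' @export
SimulationConfig <- function(nGenes = 15000,
                             groups = defaultGroups(),
                             contrasts = defaultContrasts(),
                             baselineMean = 400,
                             dispersion = 0.1,
                             libSizeRange = c(0.5, 2),
                             activeRegulons = emptyActiveRegulons(),
                             seed = 1L) {
  if (is.list(activeRegulons) && !is.data.frame(activeRegulons))
    activeRegulons <- do.call(rbind, lapply(activeRegulons, as.data.frame))
  new("SimulationConfig", nGenes = nGenes, groups = groups,
      contrasts = contrasts, baselineMean = baselineMean,
      dispersion = dispersion, libSizeRange = libSizeRange,
      activeRegulons = activeRegulons, seed = seed)
}

#' @rdname SimulationConfig-class
#' @export
defaultGroups <- function() {
  g <- expand.grid(genotype = c("KO", "WT"),
                   subset = c("HE", "nonHE", "CD43pos"),
                   dox = "no", stringsAsFactors = FALSE)
  g$n_replicates <- 3L
  g[, c("subset", "genotype", "dox", "n_replicates")]
}

#' @rdname SimulationConfig-class
#' @export
defaultContrasts <- function() {
  mk <- function(s) list(a = list(subset = s, genotype = "KO", dox = "no"),
                         b = list(subset = s, genotype = "WT", dox = "no"))
  list(HE = mk("HE"), nonHE = mk("nonHE"), CD43pos = mk("CD43pos"))
}

#' @rdname SimulationConfig-class
#' @export
emptyActiveRegulons <- function() {
  data.frame(tf = character(), contrast = character(),
             lfc = numeric(), fraction_responsive = numeric(),
             stringsAsFactors = FALSE)
}

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", object@nGenes, "genes,",
      sum(object@groups$n_replicates), "samples in",
      nrow(object@groups), "groups,",
      length(object@contrasts), "contrasts,",
      nrow(object@activeRegulons), "active regulons (seed",
      object@seed, ")\n")
})

#' @noRd
.sampleTable <- function(groups) {
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    g <- groups[i, ]
    data.frame(sample = sprintf("%s_%s_%s_%d", g$subset, g$genotype, g$dox,
                                seq_len(g$n_replicates)),
               subset = g$subset, genotype = g$genotype, dox = g$dox,
               replicate = seq_len(g$n_replicates),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Samples matching a contrast selector (all non-NULL fields must agree).
#' @noRd
.selectSamples <- function(meta, selector) {
  keep <- rep(TRUE, nrow(meta))
  for (f in c("subset", "genotype", "dox")) {
    if (!is.null(selector[[f]])) keep <- keep & meta[[f]] == selector[[f]]
  }
  meta$sample[keep]
}

#' Simulate a regulon-structured RNA-seq count matrix with ground truth
#'
#' Counts are negative binomial with per-gene log-normal baseline means
#' (median `baselineMean`, sdlog 1), per-sample log-uniform library-size
#' factors, and variance `mu + alpha * mu^2`. For each row of
#' `activeRegulons`, a random `fraction_responsive` of the TF's targets (and
#' the TF itself) receive the stated log2 fold change in the contrast's
#' group B relative to group A. The returned ground truth records exactly
#' which genes and regulons were perturbed per contrast.
#'
#' The gene universe is the database's genes padded with unregulated filler
#' genes (`X...`) up to `nGenes`.
#'
#' @param db an [InteractionDB-class].
#' @param config a [SimulationConfig-class].
#' @return A list with elements `se` (a
#'   [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#'   with a `counts` assay and sample metadata in `colData`) and `truth`
#'   (list with `deGenes`: per-contrast data.frame of `gene`, `lfc`;
#'   `activeRegulons`: per-contrast data.frame of `tf`, `direction`).
#' @examples
#' db <- generateInteractionDB(10, 500, 10, 0.1, seed = 1)
#' sim <- simulateCounts(db, SimulationConfig(nGenes = 600, seed = 1))
#' sim$se
#' @export
simulateCounts <- function(db, config) {
  stopifnot(is(db, "InteractionDB"), is(config, "SimulationConfig"))
  e <- edges(db)
  dbGenes <- sort(unique(c(e$regulator, e$target)))
  if (length(dbGenes) > config@nGenes)
    stop("nGenes (", config@nGenes, ") smaller than the database universe (",
         length(dbGenes), " genes)", call. = FALSE)
  nFill <- config@nGenes - length(dbGenes)
  genes <- c(dbGenes, sprintf("X%05d", seq_len(nFill)))

  ar <- config@activeRegulons
  if (nrow(ar) > 0L) {
    ar$tf <- .normSymbols(ar$tf, "regulator")
    missing <- setdiff(ar$tf, unique(e$regulator))
    if (length(missing))
      stop("unknown regulator in activeRegulons: ",
           paste(missing, collapse = ", "), call. = FALSE)
  }

  meta <- .sampleTable(config@groups)
  nS <- nrow(meta)
  nG <- length(genes)

  withr::with_seed(as.integer(config@seed), {
    baselines <- rlnorm(nG, meanlog = log(config@baselineMean), sdlog = 1)
    lib <- exp(runif(nS, log(config@libSizeRange[1L]),
                     log(config@libSizeRange[2L])))

    # per-contrast log2-effect vectors over genes
    effect <- list()
    truthGenes <- list(); truthReg <- list()
    for (cn in names(config@contrasts)) {
      effect[[cn]] <- numeric(nG)
      truthGenes[[cn]] <- data.frame(gene = character(), lfc = numeric(),
                                     stringsAsFactors = FALSE)
      truthReg[[cn]] <- data.frame(tf = character(), direction = character(),
                                   stringsAsFactors = FALSE)
    }
    if (nrow(ar) > 0L) {
      for (i in seq_len(nrow(ar))) {
        cn <- ar$contrast[i]
        tg <- regulonOf(db, ar$tf[i])
        nResp <- max(1L, ceiling(ar$fraction_responsive[i] * length(tg)))
        resp <- if (nResp >= length(tg)) tg else sample(tg, nResp)
        resp <- c(ar$tf[i], resp)        # the TF's own mRNA responds too
        idx <- match(resp, genes)
        effect[[cn]][idx] <- effect[[cn]][idx] + ar$lfc[i]
        truthReg[[cn]] <- rbind(truthReg[[cn]],
                                data.frame(tf = ar$tf[i],
                                           direction = if (ar$lfc[i] >= 0)
                                             "up" else "down",
                                           stringsAsFactors = FALSE))
      }
      for (cn in names(config@contrasts)) {
        nz <- which(effect[[cn]] != 0)
        truthGenes[[cn]] <- data.frame(gene = genes[nz],
                                       lfc = effect[[cn]][nz],
                                       stringsAsFactors = FALSE)
      }
    }

    # per-sample log2 multipliers: group B samples of each contrast carry
    # that contrast's effect
    logMu <- matrix(log2(baselines), nrow = nG, ncol = nS)
    for (cn in names(config@contrasts)) {
      bSamples <- .selectSamples(meta, config@contrasts[[cn]]$b)
      sIdx <- match(bSamples, meta$sample)
      if (length(sIdx))
        logMu[, sIdx] <- logMu[, sIdx] + effect[[cn]]
    }
    mu <- sweep(2^logMu, 2L, lib, `*`)
    counts <- matrix(rnbinom(nG * nS, mu = as.vector(mu),
                             size = 1 / config@dispersion),
                     nrow = nG, ncol = nS)
  })
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(genes, meta$sample)

  se <- SummarizedExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(meta[, c("subset", "genotype", "dox",
                                            "replicate")],
                                   row.names = meta$sample))
  S4Vectors::metadata(se)$contrasts <- config@contrasts
  S4Vectors::metadata(se)$seed <- config@seed
  list(se = se,
       truth = list(deGenes = truthGenes, activeRegulons = truthReg))
}

#' Generate a synthetic gene-to-category annotation table
#'
#' Companion generator for the GO-style category analysis: assigns genes to
#' `nCategories` overlapping categories of geometric mean size
#' `meanCategorySize`, with synthetic term names and a supercategory map
#' cycling over cell_surface, cytoskeleton and other. Category IDs use a
#' `GO:SYN` prefix to mark them as synthetic.
#'
#' @param genes gene symbols to annotate from.
#' @param nCategories number of categories.
#' @param meanCategorySize mean genes per category.
#' @param seed integer seed.
#' @return list with `annotations` (data.frame `gene`, `category`), `names`
#'   (data.frame `category`, `name`), `supercategories` (data.frame
#'   `category`, `supercategory`).
#' @export
generateAnnotations <- function(genes, nCategories = 30,
                                meanCategorySize = 40, seed = 1L) {
  .assertCount(nCategories, "nCategories")
  .assertCount(meanCategorySize, "meanCategorySize")
  genes <- unique(.normSymbols(genes, "gene"))
  supers <- c("cell_surface", "cytoskeleton", "other")
  withr::with_seed(as.integer(seed), {
    rows <- lapply(seq_len(nCategories), function(i) {
      sz <- min(length(genes),
                max(3L, rnbinom(1L, mu = meanCategorySize, size = 3)))
      data.frame(gene = sample(genes, sz),
                 category = sprintf("GO:SYN%04d", i),
                 stringsAsFactors = FALSE)
    })
  })
  ann <- do.call(rbind, rows)
  ids <- sprintf("GO:SYN%04d", seq_len(nCategories))
  list(annotations = ann,
       names = data.frame(category = ids,
                          name = sprintf("synthetic category %d",
                                         seq_len(nCategories)),
                          stringsAsFactors = FALSE),
       supercategories = data.frame(
         category = ids,
         supercategory = supers[(seq_len(nCategories) - 1L) %% 3L + 1L],
         stringsAsFactors = FALSE))
}
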