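# Shared fixture builders. Everything is generated in code; no data files.

suppressMessages(library(SummarizedExperiment))

# A tiny hand-written database used by the set-algebra tests.
tinyDB <- function() {
  InteractionDB(
    regulator = c("A", "A", "B", "C", "C", "C"),
    target    = c("G1", "G2", "G1", "G2", "G3", "G4"))
}

# Build a classified DEResult directly from its gene sets. p/q values are
# synthesised consistently (small for DE genes, large otherwise) so that
# validity holds; the scoring functions only consume the direction calls.
mkDE <- function(universe, up = character(), down = character(),
                 lfc = NULL, contrast = "test") {
  stopifnot(all(up %in% universe), all(down %in% universe))
  direction <- ifelse(universe %in% up, "up",
                      ifelse(universe %in% down, "down", "nc"))
  if (is.null(lfc))
    lfc <- ifelse(direction == "up", 2, ifelse(direction == "down", -2, 0))
  p <- ifelse(direction == "nc", 0.9, 1e-4)
  tb <- data.frame(gene = universe, log2fc = lfc, p_value = p,
                   q_value = pmin(p * 2, 1), direction = direction,
                   stringsAsFactors = FALSE)
  new("DEResult", table = tb, contrast = contrast,
      groupA = character(), groupB = character(),
      fdrThreshold = 0.05, lfcThreshold = 1, untested = character())
}

# One global-null simulation (no active regulons) scored end to end.
simNullContrast <- function(seed, nGenes = 2000, nTfs = 100,
                            nTargets = 1800, meanRegulonSize = 15) {
  db <- generateInteractionDB(nTfs, nTargets, meanRegulonSize, 0.1,
                              seed = seed)
  cfg <- SimulationConfig(nGenes = nGenes, seed = seed)
  sim <- simulateCounts(db, cfg)
  gA <- samplesMatching(sim$se, list(subset = "HE", genotype = "KO"))
  gB <- samplesMatching(sim$se, list(subset = "HE", genotype = "WT"))
  de <- classifyDE(deTest(sim$se, gA, gB, "HE"))
  list(db = db, de = de, se = sim$se)
}

# Five active regulons with ~50 responsive targets each (disjoint regulons),
# four replicates per group: the recovery design.
simRecoveryContrast <- function(seed) {
  db <- generateInteractionDB(100, 2000, 50, 0, seed = seed)
  groups <- defaultGroups()
  groups$n_replicates <- 4L
  active <- data.frame(tf = sprintf("TF%03d", 1:5), contrast = "HE",
                       lfc = 2, fraction_responsive = 1,
                       stringsAsFactors = FALSE)
  cfg <- SimulationConfig(nGenes = 2100, groups = groups,
                          activeRegulons = active, seed = seed)
  sim <- simulateCounts(db, cfg)
  gA <- samplesMatching(sim$se, list(subset = "HE", genotype = "KO"))
  gB <- samplesMatching(sim$se, list(subset = "HE", genotype = "WT"))
  de <- classifyDE(deTest(sim$se, gA, gB, "HE"))
  list(db = db, de = de, truth = sim$truth,
       activeTfs = sprintf("TF%03d", 1:5))
}

# Exhaustive hypergeometric oracle: enumerate every possible draw of size n
# from the universe and count overlaps with the success set. Independent of
# phyper by construction.
enumTailProbs <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)  # successes are elements 1..K
  c(upper = mean(hits >= k), lower = mean(hits <= k))
}

# Monte-Carlo permutation oracle for the same quantities.
permTailProbs <- function(N, K, n, k, nPerm = 20000, seed = 1) {
  withr::with_seed(seed, {
    hits <- replicate(nPerm, sum(sample.int(N, n) <= K))
  })
  c(upper = mean(hits >= k), lower = mean(hits <= k))
}

writeTempConfig <- function(lines) {
  path <- tempfile(fileext = ".yaml")
  writeLines(lines, path)
  path
}

# Small, fast pipeline config used by the pipeline tests.
smallPipelineConfig <- function(outDir, seed = 1) {
  writeTempConfig(c(
    sprintf("seed: %d", seed),
    sprintf("out_dir: %s", outDir),
    "simulate:",
    "  n_genes: 900",
    "  n_tfs: 30",
    "  n_targets: 800",
    "  mean_regulon_size: 12",
    "  regulon_overlap: 0.1",
    "  n_replicates: 4",
    "  active_auto: {n_per_contrast: 4, lfc: 3, fraction_responsive: 1}",
    "  annotations: {n_categories: 15, mean_category_size: 30}",
    "anchors: [GATA2]"))
}
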