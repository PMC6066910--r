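#' Deterministic study-scale active-regulon layout
#'
#' Picks `nPerContrast` regulators per contrast (consecutive blocks of the
#' sorted regulator list, so contrasts perturb disjoint regulons) and
#' alternates the sign of the log2 fold change within each block -- a
#' convenient way to lay out a multi-contrast simulation without listing
#' every TF by hand.
#'
#' @param db an [InteractionDB-class].
#' @param contrasts character vector of contrast ids.
#' @param nPerContrast active regulons per contrast.
#' @param lfc magnitude of the log2 fold change (default 2).
#' @param fractionResponsive fraction of each regulon's targets that respond
#'   (default 0.8).
#' @return data.frame suitable for the `activeRegulons` slot of
#'   [SimulationConfig()].
#' @export
autoActiveRegulons <- function(db, contrasts, nPerContrast, lfc = 2,
                               fractionResponsive = 0.8) {
  tfs <- regulators(db)
  need <- nPerContrast * length(contrasts)
  if (need > length(tfs))
    stop("database has only ", length(tfs), " regulators; need ", need,
         call. = FALSE)
  rows <- list()
  for (i in seq_along(contrasts)) {
    block <- tfs[((i - 1L) * nPerContrast + 1L):(i * nPerContrast)]
    rows[[i]] <- data.frame(
      tf = block, contrast = contrasts[i],
      lfc = ifelse(seq_along(block) %% 2L == 1L, lfc, -lfc),
      fraction_responsive = fractionResponsive,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' @noRd
.yamlToSelector <- function(x) {
  # YAML parses bare yes/no as logicals; map them back to factor levels
  lapply(x, function(v) {
    if (is.logical(v)) (if (v) "yes" else "no") else as.character(v)
  })
}

#' @noRd
.cfgNum <- function(x, default) if (is.null(x)) default else as.numeric(x)

#' @noRd
.validateConfigKeys <- function(cfg) {
  allowed <- c("seed", "out_dir", "simulate", "inputs", "contrasts",
               "thresholds", "anchors", "panels")
  bad <- setdiff(names(cfg), allowed)
  if (length(bad))
    stop("invalid config key: ", paste(bad, collapse = ", "), call. = FALSE)
  if (is.null(cfg$simulate) && is.null(cfg$inputs))
    stop("config must declare either 'simulate' or 'inputs'", call. = FALSE)
  if (!is.null(cfg$simulate)) {
    sa <- c("n_genes", "n_tfs", "n_targets", "mean_regulon_size",
            "regulon_overlap", "baseline_mean", "dispersion",
            "lib_size_range", "n_replicates", "active_regulons",
            "active_auto", "annotations")
    bad <- setdiff(names(cfg$simulate), sa)
    if (length(bad))
      stop("invalid config key: simulate.", paste(bad, collapse = ", "),
           call. = FALSE)
  }
  if (!is.null(cfg$inputs)) {
    ia <- c("counts", "metadata", "interactions", "interactions_format",
            "annotations", "annotations_format", "annotation_names")
    bad <- setdiff(names(cfg$inputs), ia)
    if (length(bad))
      stop("invalid config key: inputs.", paste(bad, collapse = ", "),
           call. = FALSE)
  }
  if (!is.null(cfg$thresholds)) {
    ta <- c("fdr", "lfc", "alpha_select", "k_min", "or_min", "min_regulon",
            "size_category_lfc", "go_q", "pseudocount")
    bad <- setdiff(names(cfg$thresholds), ta)
    if (length(bad))
      stop("invalid config key: thresholds.", paste(bad, collapse = ", "),
           call. = FALSE)
  }
  invisible(TRUE)
}

#' Run the full analysis pipeline from a YAML config
#'
#' Stages: simulate or load inputs, median-of-ratios normalisation, Welch DE
#' per contrast, regulon scoring and selection, regulatory-network assembly
#' and export (GraphML + SIF), GO category scoring and category graph,
#' marker-panel z-score matrices, and a JSON run manifest with per-stage row
#' counts. The same config and seed reproduce identical artifact files.
#'
#' The config declares either a `simulate:` block (synthetic database,
#' counts and annotations) or an `inputs:` block (paths to
#' counts/metadata/interactions/annotations TSVs), plus optional
#' `contrasts:` (default: WT-versus-KO within each of HE, nonHE, CD43pos;
#' selector values for `dox` should be quoted in YAML), `thresholds:`,
#' `anchors:` (default GATA2) and `panels:` (default HE/non-HE marker
#' panels). Unknown keys are rejected by name.
#'
#' @param configPath YAML config path.
#' @param outDir output directory; overrides the config's `out_dir`
#'   (default `"regulonet_artifacts"`).
#' @param seed overrides the config's `seed` when not `NULL`.
#' @return Invisibly, a list with the artifact `dir`, the `manifest` list,
#'   and the in-memory `results` (per-contrast DE, scores, networks).
#' @export
runPipeline <- function(configPath, outDir = NULL, seed = NULL) {
  if (!file.exists(configPath))
    stop("missing input file: ", configPath, call. = FALSE)
  cfg <- yaml::read_yaml(configPath)
  .validateConfigKeys(cfg)
  seed <- as.integer(seed %||% cfg$seed %||% 1L)
  outDir <- outDir %||% cfg$out_dir %||% "regulonet_artifacts"
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  logPath <- file.path(outDir, "run.log")
  logCon <- file(logPath, "w")
  on.exit(close(logCon), add = TRUE)
  log <- function(...) {
    txt <- paste0(...)
    writeLines(txt, logCon)
    .msg(txt)
  }
  manifest <- list(package = as.character(packageVersion("regulonet")),
                   r_version = paste(R.version$major, R.version$minor,
                                     sep = "."),
                   seed = seed,
                   config_md5 = unname(md5sum(configPath)),
                   stages = list())

  contrasts <- if (!is.null(cfg$contrasts)) {
    lapply(cfg$contrasts, function(cc)
      list(a = .yamlToSelector(cc$a), b = .yamlToSelector(cc$b)))
  } else defaultContrasts()

  # stage 1: inputs
  ann <- NULL; annNames <- NULL; superMap <- defaultSupercategoryMap()
  if (!is.null(cfg$simulate)) {
    s <- cfg$simulate
    db <- generateInteractionDB(
      nTfs = .cfgNum(s$n_tfs, 100),
      nTargets = .cfgNum(s$n_targets, 2000),
      meanRegulonSize = .cfgNum(s$mean_regulon_size, 20),
      regulonOverlap = .cfgNum(s$regulon_overlap, 0.1),
      seed = seed)
    groups <- defaultGroups()
    groups$n_replicates <- as.integer(.cfgNum(s$n_replicates, 3))
    active <- emptyActiveRegulons()
    if (!is.null(s$active_regulons))
      active <- do.call(rbind, lapply(s$active_regulons, function(r)
        data.frame(tf = r$tf, contrast = r$contrast, lfc = r$lfc,
                   fraction_responsive = r$fraction_responsive,
                   stringsAsFactors = FALSE)))
    if (!is.null(s$active_auto))
      active <- rbind(active, autoActiveRegulons(
        db, names(contrasts),
        nPerContrast = .cfgNum(s$active_auto$n_per_contrast, 10),
        lfc = .cfgNum(s$active_auto$lfc, 2),
        fractionResponsive = .cfgNum(s$active_auto$fraction_responsive,
                                     0.8)))
    simCfg <- SimulationConfig(
      nGenes = .cfgNum(s$n_genes, 15000), groups = groups,
      contrasts = contrasts,
      baselineMean = .cfgNum(s$baseline_mean, 400),
      dispersion = .cfgNum(s$dispersion, 0.1),
      libSizeRange = as.numeric(s$lib_size_range %||% c(0.5, 2)),
      activeRegulons = active, seed = seed)
    sim <- simulateCounts(db, simCfg)
    se <- sim$se; truth <- sim$truth
    writeFixtures(db, se, truth, file.path(outDir, "inputs"))
    annCfg <- s$annotations %||% list()
    annAll <- generateAnnotations(
      rownames(se), nCategories = .cfgNum(annCfg$n_categories, 30),
      meanCategorySize = .cfgNum(annCfg$mean_category_size, 40),
      seed = seed)
    ann <- annAll$annotations; annNames <- annAll$names
    superMap <- data.frame(pattern = annAll$supercategories$category,
                           supercategory =
                             annAll$supercategories$supercategory,
                           stringsAsFactors = FALSE)
    log("simulate: ", nrow(se), " genes x ", ncol(se), " samples, ",
        nEdges(db), " interactions")
  } else {
    ip <- cfg$inputs
    for (p in c(ip$counts, ip$metadata, ip$interactions))
      if (!file.exists(p)) stop("missing input file: ", p, call. = FALSE)
    db <- readInteractions(ip$interactions,
                           format = ip$interactions_format %||% "tsv")
    se <- readCountMatrix(ip$counts, ip$metadata)
    truth <- NULL
    if (!is.null(ip$annotations)) {
      a <- readAnnotations(ip$annotations,
                           format = ip$annotations_format %||%
                             "two_column_tsv",
                           namesPath = ip$annotation_names)
      ann <- a$annotations; annNames <- a$names
    }
    log("load: ", nrow(se), " genes x ", ncol(se), " samples, ",
        nEdges(db), " interactions")
  }
  manifest$stages$input <- list(genes = nrow(se), samples = ncol(se),
                                interactions = nEdges(db),
                                regulons = length(regulators(db)))

  # stage 2: normalisation
  sf <- computeSizeFactors(se)
  log("size factors: range ", sprintf("%.3f", min(sf)), " - ",
      sprintf("%.3f", max(sf)))

  th <- cfg$thresholds %||% list()
  fdr <- .cfgNum(th$fdr, 0.05); lfcThr <- .cfgNum(th$lfc, 1)
  anchors <- toupper(unlist(cfg$anchors %||% "GATA2"))

  results <- list()
  for (cn in names(contrasts)) {
    gA <- samplesMatching(se, contrasts[[cn]]$a)
    gB <- samplesMatching(se, contrasts[[cn]]$b)
    if (length(gA) == 0L || length(gB) == 0L)
      stop("contrast '", cn, "': selector matches no samples", call. = FALSE)
    de <- deTest(se, gA, gB, contrast = cn,
                 pseudocount = .cfgNum(th$pseudocount, 1),
                 sizeFactors = sf)
    de <- classifyDE(de, fdr, lfcThr)
    writeDEResults(de, file.path(outDir, paste0("de_results_", cn, ".tsv")))
    sets <- deSets(de)
    log("de ", cn, ": tested ", nrow(deTable(de)), ", up ",
        length(sets$up), ", down ", length(sets$down))

    scores <- scoreContrast(
      db, de, minRegulonSize = .cfgNum(th$min_regulon, 3),
      alphaSelect = .cfgNum(th$alpha_select, 0.05),
      kMin = .cfgNum(th$k_min, 3), orMin = .cfgNum(th$or_min, 2),
      sizeCategoryLfc = .cfgNum(th$size_category_lfc, 0.585))
    writeRegulonScores(scores,
                       file.path(outDir,
                                 paste0("regulon_scores_", cn, ".tsv")))
    net <- buildNetwork(db, scores, de, anchors = anchors,
                        sizeCategoryLfc = .cfgNum(th$size_category_lfc,
                                                  0.585))
    exportNetwork(net, "graphml",
                  file.path(outDir, paste0("network_", cn, ".graphml")))
    exportNetwork(net, "sif",
                  file.path(outDir, paste0("network_", cn, ".sif")))
    log("regulon ", cn, ": scored ", nrow(scores), ", selected ",
        sum(scores$selected))

    goScores <- NULL; catGraph <- NULL
    if (!is.null(ann) && nrow(ann) > 0L) {
      universe <- intersect(deUniverse(de), unique(ann$gene))
      deSet <- c(sets$up, sets$down)
      goScores <- scoreCategories(ann, deSet, universe = universe,
                                  names = annNames, map = superMap)
      writeCategoryScores(goScores,
                          file.path(outDir,
                                    paste0("category_scores_", cn, ".tsv")))
      catGraph <- buildCategoryGraph(goScores, ann, universe,
                                     qThreshold = .cfgNum(th$go_q, 0.1),
                                     contrast = cn)
      .writeTSV(catGraph@edgeTable,
                file.path(outDir, paste0("category_edges_", cn, ".tsv")))
      log("go ", cn, ": ", nrow(goScores), " categories scored, ",
          nrow(catGraph@nodes), " displayed")
    }

    manifest$stages[[paste0("contrast_", cn)]] <- list(
      tested = nrow(deTable(de)), untested = length(de@untested),
      up = length(sets$up), down = length(sets$down),
      nc = length(sets$nc),
      regulons_scored = nrow(scores),
      regulons_selected = sum(scores$selected),
      network_nodes = nrow(net@nodes), network_edges = nrow(net@edgeTable),
      categories_scored = if (is.null(goScores)) 0L else nrow(goScores))
    results[[cn]] <- list(de = de, scores = scores, network = net,
                          goScores = goScores, categoryGraph = catGraph)
  }

  # marker z-score panels on log2 normalised expression, all samples
  panels <- if (is.null(cfg$panels) || identical(cfg$panels, "default"))
    markerPanels() else lapply(cfg$panels, function(p) toupper(unlist(p)))
  lg <- log2(normalizedCounts(se, sf) + 1)
  for (pn in names(panels)) {
    zm <- rowZScore(lg, panels[[pn]], panelName = pn)
    writeZMatrix(zm, file.path(outDir, paste0("zscore_", pn, ".tsv")))
    log("zscore ", pn, ": ", nrow(zValues(zm)), " genes (",
        length(zm@missingGenes), " missing)")
  }
  manifest$stages$panels <- lapply(panels, length)

  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  log("done")
  .msg("artifacts in ", outDir)
  invisible(list(dir = outDir, manifest = manifest, results = results,
                 truth = truth))
}
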