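# End-to-end orchestration: loads -> three screens x three load types ->
# combined models -> independence check -> expression layer, from a single
# config, with a manifest auditing every FDR family. Outputs are plain TSV
# + JSON and byte-identical across reruns of the same config + seed.

.asEffectMap <- function(x) {
  if (is.null(x)) return(NULL)
  if (is.data.frame(x)) return(x)
  do.call(rbind, lapply(x, function(r)
    data.frame(tissue = r$tissue, drug = r$drug, beta = as.numeric(r$beta),
               load_type = r$load_type, stringsAsFactors = FALSE)))
}

#' Validate and normalise a pipeline run configuration
#'
#' A run config is a list (or a YAML file holding one) with either a
#' `simulate` block (arguments for [cohortConfig()] plus the planted
#' `effectMap`) or an `inputs` block (paths: `seg`, `variants`,
#' `annotations`, `response`, optional `expression`, `gene_sets`,
#' `drivers`), plus analysis parameters: `afMin` (0.10),
#' `neutralThreshold` (0), `minTissue` (8), `fdrLevel` (0.10), `scopes`
#' (default all three), `loadTypes` (default `cn`, `mut`, `combined`),
#' `seed`, optional `pairs` candidates (`tissues`, `drugs`) and an optional
#' `panel` gene list path for the expression layer.
#'
#' @param config List or YAML path.
#' @return The validated config list with defaults filled in.
#' @export
runConfig <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  defaults <- list(afMin = 0.10, neutralThreshold = 0, minTissue = 8L,
                   fdrLevel = 0.10,
                   scopes = c("pan_cancer", "pan_drug", "pair"),
                   loadTypes = c("cn", "mut", "combined"), seed = 1L,
                   pandrugNorm = "tissue-drug",
                   minN = list(pan_cancer = 10L, pan_drug = 30L, pair = 7L),
                   pairs = list(tissues = NULL, drugs = NULL), panel = NULL)
  for (k in names(defaults))
    if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  if (!length(config$scopes))
    stop("config error: empty scope list")
  bad <- setdiff(config$scopes, c("pan_cancer", "pan_drug", "pair"))
  if (length(bad)) stop("config error: unknown scope(s): ",
                        paste(bad, collapse = ", "))
  if (!is.numeric(config$fdrLevel) || config$fdrLevel <= 0 ||
      config$fdrLevel >= 1)
    stop("config error: fdrLevel must lie in (0, 1)")
  if (is.null(config$simulate) == is.null(config$inputs))
    stop("config error: exactly one of 'simulate' or 'inputs' is required")
  if (!is.null(config$inputs)) {
    need <- c("seg", "variants", "annotations", "response")
    miss <- setdiff(need, names(config$inputs))
    if (length(miss)) stop("config error: inputs block missing: ",
                           paste(miss, collapse = ", "))
    for (p in unlist(config$inputs[sapply(config$inputs, is.character)]))
      if (!file.exists(p)) stop("config error: input path not found: ", p)
  }
  config
}

#' Run the full genetic-load analysis pipeline
#'
#' Executes, from one validated config: load computation with tissue-wise
#' z-normalisation; the pan-cancer, pan-drug and tissue-drug screens for
#' the copy-number and mutation loads; lasso-combined models and their
#' screen per scope; the load-independence check; and, when expression
#' data are present, the pathway-enrichment and gene-panel screens. Writes
#' one TSV per result table, a JSON manifest auditing sample counts and
#' FDR-family sizes, a plain-text run log and, for simulated cohorts, the
#' planted truth plus a true/false-positive evaluation of every flagged
#' unit. Outputs are deterministic (byte-identical) given config + seed.
#'
#' Pair-screen candidates default to the drugs and tissues flagged by the
#' pan-cancer and pan-drug screens (either load type, Spearman FDR), but
#' explicit candidate lists in `config$pairs` take precedence.
#'
#' @param config List or YAML path (see [runConfig()]).
#' @param outDir Output directory, created if needed.
#' @return Invisibly, a list with the loads, all result tables, the
#'   combined models, the manifest and the output paths.
#' @export
runPipeline <- function(config, outDir) {
  config <- runConfig(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  log <- character(0)
  say <- function(...) {
    line <- sprintf(...)
    log <<- c(log, line)
    message(line)
  }

  ## data ------------------------------------------------------------------
  truth <- NULL
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    sim$effectMap <- .asEffectMap(sim$effectMap)
    simSeed <- if (!is.null(sim$seed)) sim$seed else config$seed
    sim$seed <- NULL
    gen <- generateCohort(do.call(cohortConfig, sim), seed = simSeed)
    cohort <- gen$cohort
    truth <- gen$truth
    say("simulated cohort: %d cell lines, %d tissues, %d drugs (seed %d)",
        nrow(sampleAnnotations(cohort)),
        length(unique(sampleAnnotations(cohort)$tissue)),
        ncol(drugResponse(cohort)), simSeed)
  } else {
    inp <- config$inputs
    cohort <- readCohort(inp$seg, inp$variants, inp$annotations,
                         inp$response, expression = inp$expression,
                         geneSets = inp$gene_sets, drivers = inp$drivers)
    say("read cohort: %d cell lines, %d tissues",
        nrow(sampleAnnotations(cohort)),
        length(unique(sampleAnnotations(cohort)$tissue)))
  }

  ## loads -----------------------------------------------------------------
  loads <- suppressMessages(computeLoads(
    cohort, afMin = config$afMin,
    neutralThreshold = config$neutralThreshold,
    minTissue = config$minTissue))
  nExcl <- sum(!loads$included)
  say("loads computed: %d cell lines, %d excluded (tissue < %d cell lines)",
      nrow(loads), nExcl, config$minTissue)
  response <- drugResponse(cohort)
  level <- config$fdrLevel

  results <- list()
  manifestFamilies <- list()
  runScreen <- function(scope, lt, fun, ...) {
    res <- suppressMessages(suppressWarnings(fun(...)))
    key <- paste(scope, lt, sep = ".")
    results[[key]] <<- res
    manifestFamilies[[key]] <<- list(tests = nrow(res),
                                     flagged = nrow(screenHits(res, level)))
    say("screen %s / %s: %d tests, %d flagged at FDR <= %.2g",
        scope, lt, nrow(res), nrow(screenHits(res, level)), level)
    res
  }

  singleTypes <- intersect(config$loadTypes, c("cn", "mut"))
  ## pan-cancer and pan-drug (always computed when pair candidates are
  ## needed, reported only for requested scopes)
  needPan <- "pair" %in% config$scopes &&
    (is.null(config$pairs$tissues) || is.null(config$pairs$drugs))
  panCancer <- list(); panDrug <- list()
  for (lt in singleTypes) {
    if ("pan_cancer" %in% config$scopes || needPan)
      panCancer[[lt]] <- suppressMessages(suppressWarnings(
        panCancerScreen(loads, response, lt,
                        minN = config$minN$pan_cancer)))
    if ("pan_drug" %in% config$scopes || needPan)
      panDrug[[lt]] <- suppressMessages(suppressWarnings(
        panDrugScreen(loads, response, lt, minPairs = config$minN$pan_drug,
                      norm = config$pandrugNorm)))
  }
  for (lt in singleTypes) {
    if ("pan_cancer" %in% config$scopes)
      runScreen("pan_cancer", lt, function(...) panCancer[[lt]])
    if ("pan_drug" %in% config$scopes)
      runScreen("pan_drug", lt, function(...) panDrug[[lt]])
  }

  ## pair screen -----------------------------------------------------------
  candTissues <- config$pairs$tissues
  candDrugs <- config$pairs$drugs
  if ("pair" %in% config$scopes) {
    if (is.null(candDrugs))
      candDrugs <- unique(unlist(lapply(panCancer, function(r)
        screenHits(r, level)$unit)))
    if (is.null(candTissues))
      candTissues <- unique(unlist(lapply(panDrug, function(r)
        screenHits(r, level)$unit)))
    say("pair-screen candidates: %d tissues x %d drugs",
        length(candTissues), length(candDrugs))
    for (lt in singleTypes)
      runScreen("pair", lt, pairScreen, loads, response,
                tissues = candTissues, drugs = candDrugs, loadType = lt,
                minN = config$minN$pair)
  }

  ## combined load ---------------------------------------------------------
  models <- list()
  if ("combined" %in% config$loadTypes) {
    for (scope in config$scopes) {
      mods <- suppressMessages(combinedLoadModels(
        loads, response, scope = scope,
        tissues = if (scope == "pair") candTissues,
        drugs = if (scope == "pair") candDrugs,
        seed = config$seed, minN = config$minN$pair))
      models[[scope]] <- mods
      res <- suppressWarnings(combinedScreen(mods, scope = scope))
      key <- paste(scope, "combined", sep = ".")
      results[[key]] <- res
      manifestFamilies[[key]] <- list(tests = nrow(res),
                                      flagged = nrow(screenHits(res, level)))
      say("screen %s / combined: %d usable units of %d, %d flagged",
          scope, nrow(res), length(mods), nrow(screenHits(res, level)))
    }
  }

  ## independence ----------------------------------------------------------
  indep <- loadIndependenceCheck(loads)
  indepTissue <- suppressWarnings(loadIndependenceCheck(loads,
                                                        perTissue = TRUE))
  say("independence check: pooled raw r = %.3f, z r = %.3f",
      indep$r[1L], indep$r[2L])

  ## expression layer ------------------------------------------------------
  exprResults <- list()
  expr <- exprMatrix(cohort)
  if (ncol(expr) && length(geneSets(cohort))) {
    scores <- suppressMessages(enrichmentScores(expr, geneSets(cohort)))
    for (lt in singleTypes)
      exprResults[[paste0("pathway.", lt)]] <-
        suppressMessages(suppressWarnings(pathwayLoadScreen(scores, loads, lt)))
    panel <- if (!is.null(config$panel)) readGeneList(config$panel)
             else defaultGrowthFactorPanel()
    if (length(intersect(panel, rownames(expr)))) {
      for (lt in singleTypes)
        exprResults[[paste0("panel.", lt)]] <-
          suppressMessages(suppressWarnings(
            genePanelLoadScreen(expr, panel, loads, lt)))
    } else {
      say("no panel genes present in expression matrix; panel screen skipped")
    }
    say("expression layer: %d gene sets scored over %d samples",
        nrow(scores), ncol(scores))
  }

  ## write outputs ---------------------------------------------------------
  paths <- c(loads = file.path(outDir, "loads.tsv"))
  utils::write.table(as.data.frame(loads), paths["loads"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (scope in unique(sub("\\..*$", "", names(results)))) {
    tab <- do.call(rbind, unname(results[grep(paste0("^", scope, "\\."),
                                              names(results))]))
    p <- file.path(outDir, paste0("table_", scope, ".tsv"))
    paths[paste0("table_", scope)] <- p
    utils::write.table(tab, p, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  paths["independence"] <- file.path(outDir, "independence.tsv")
  utils::write.table(rbind(indep,
                           cbind(values = paste0("tissue:",
                                                 indepTissue$tissue),
                                 indepTissue[, -1L])),
                     paths["independence"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  for (k in names(exprResults)) {
    p <- file.path(outDir, paste0("expression_", sub("\\.", "_", k), ".tsv"))
    paths[k] <- p
    utils::write.table(exprResults[[k]], p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }

  ## truth evaluation ------------------------------------------------------
  if (!is.null(truth)) {
    evalRows <- list()
    for (key in names(results)) {
      hits <- screenHits(results[[key]], level)
      if (!nrow(hits)) next
      scope <- sub("\\..*$", "", key)
      trueUnits <- switch(scope,
                          pan_cancer = truth$true_drugs,
                          pan_drug = truth$true_tissues,
                          pair = truth$true_pairs)
      evalRows[[key]] <- data.frame(
        family = key, unit = hits$unit, q_rho = hits$q_rho,
        label = ifelse(hits$unit %in% trueUnits, "TP", "FP"),
        stringsAsFactors = FALSE)
    }
    evalTab <- if (length(evalRows)) do.call(rbind, evalRows)
               else data.frame(family = character(), unit = character(),
                               q_rho = numeric(), label = character())
    rownames(evalTab) <- NULL
    paths["evaluation"] <- file.path(outDir, "evaluation.tsv")
    utils::write.table(evalTab, paths["evaluation"], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    paths["truth"] <- file.path(outDir, "truth.json")
    jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    say("evaluation: %d flagged units labelled against truth", nrow(evalTab))
  }

  ## manifest + log --------------------------------------------------------
  manifest <- list(
    package = "loadscreen",
    version = as.character(utils::packageVersion("loadscreen")),
    seed = config$seed,
    fdr_level = level,
    n_cell_lines = nrow(loads),
    n_tissues = length(unique(loads$tissue)),
    n_tissues_excluded = length(unique(loads$tissue[!loads$included])),
    n_cell_lines_excluded = nExcl,
    families = manifestFamilies,
    config = config[setdiff(names(config), "simulate")])
  paths["manifest"] <- file.path(outDir, "manifest.json")
  jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  paths["log"] <- file.path(outDir, "run.log")
  writeLines(log, paths["log"])

  invisible(list(loads = loads, results = results, models = models,
                 independence = indep, independence_by_tissue = indepTissue,
                 expression = exprResults, manifest = manifest,
                 truth = truth, paths = paths))
}
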