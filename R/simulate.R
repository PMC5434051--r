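# Synthetic-cohort generator: tissue-structured copy-number and mutation
# loads (drawn independently), eight-point dose-response curves whose
# activity areas realize planted load->sensitivity effects in z-space, and
# expression with load-linked gene-set shifts. Fully deterministic given a
# seed, with the planted truth returned alongside the data.

#' Configuration for a synthetic cohort
#'
#' Defaults emulate a CCLE-like screen: 20 tissue types of uneven size
#' (8-60 cell lines), 24 drugs with eight-point dose-response curves,
#' tissue-specific baseline load distributions (log-normal segment sizes
#' and magnitudes; negative-binomial variant counts), statistically
#' independent copy-number and mutation loads, and a small fraction of
#' unscreened (missing) cell-line/drug combinations. Effects are planted in
#' z-space per (tissue, drug) via `effectMap`; with the default empty map
#' every drug is null.
#'
#' @param nTissues Number of tissue types (default 20).
#' @param cellsPerTissue Integer range of cell lines per tissue (default
#'   `c(8, 60)`; sizes are drawn uniformly, giving uneven tissues).
#' @param nDrugs Number of drugs (default 24).
#' @param nChromosomes Chromosomes in the synthetic genome (default 22).
#' @param segmentsPerCell Integer range of altered segments per cell line.
#' @param neutralFrac Fraction of additional exactly copy-neutral segments
#'   (log2 = 0) per cell line, exercising the neutral-segment handling.
#' @param cnModel Log-normal location/scale parameters for per-tissue
#'   segment `|log2|` magnitude and segment length (see defaults).
#' @param mutModel Per-tissue negative-binomial variant-count model plus
#'   the fraction of variants below the allelic-fraction cutoff
#'   (`afBelowFrac`) and in driver genes (`driverFrac`).
#' @param effectMap data.frame with columns `tissue`, `drug`, `beta`,
#'   `load_type` (`"cn"` or `"mut"`): planted effect sizes on the z-load ->
#'   z-activity scale. See [betaForRankCor()] to target a rank correlation.
#' @param noiseSd Residual SD of z-scale activity (default 0.8).
#' @param responseModel Dose-response synthesis parameters: the 8
#'   log-spaced concentrations, Hill slope, maximal inhibition, per-drug
#'   mean activity-area range, per-(tissue, drug) baseline shift SD and
#'   activity-area SD.
#' @param missingFrac Fraction of (cell line, drug) activity values set
#'   missing (default 0.05; not every line is screened for every drug).
#' @param expressionModel `NULL` (no expression layer) or a list with
#'   `nGenes`, `nSets`, `setSize` (range), `baseMean`, `noiseSd`,
#'   `setCouplings` (data.frame `set`, `load_type`, `gamma`) and
#'   `geneCouplings` (data.frame `gene`, `load_type`, `gamma`): planted
#'   additive shifts of gamma x z-load on member-gene expression.
#' @param addSmallTissue If `TRUE`, adds a 7-cell tissue to exercise the
#'   minimum-tissue-size exclusion path.
#' @param driverGenes Driver symbols used when assigning driver variants;
#'   `NULL` uses the packaged list.
#' @return A `CohortConfig` (validated list).
#' @export
cohortConfig <- function(nTissues = 20L, cellsPerTissue = c(8L, 60L),
                         nDrugs = 24L, nChromosomes = 22L,
                         segmentsPerCell = c(15L, 60L), neutralFrac = 0.25,
                         cnModel = list(volMeanlog = log(0.3),
                                        volSdlogTissue = 0.35,
                                        volSdlogWithin = 0.5,
                                        lenMeanlog = log(5e6),
                                        lenSdlogTissue = 0.3,
                                        lenSdlogWithin = 1),
                         mutModel = list(meanlog = log(60),
                                         sdlogTissue = 0.4, size = 4,
                                         afBelowFrac = 0.15,
                                         driverFrac = 0.10,
                                         nSeqGenes = 1500L),
                         effectMap = NULL, noiseSd = 0.8,
                         responseModel = list(
                           concentrations = 8 * 3.1623^(-(7:0)),
                           hill = 1.5, emax = 0.97,
                           drugMeanRange = c(1.2, 4.2),
                           tissueShiftSd = 0.5, areaSd = 0.7),
                         missingFrac = 0.05, expressionModel = NULL,
                         addSmallTissue = FALSE, driverGenes = NULL) {
  if (is.null(effectMap))
    effectMap <- data.frame(tissue = character(), drug = character(),
                            beta = numeric(), load_type = character())
  cfg <- list(nTissues = as.integer(nTissues),
              cellsPerTissue = as.integer(cellsPerTissue),
              nDrugs = as.integer(nDrugs),
              nChromosomes = as.integer(nChromosomes),
              segmentsPerCell = as.integer(segmentsPerCell),
              neutralFrac = neutralFrac, cnModel = cnModel,
              mutModel = mutModel, effectMap = effectMap, noiseSd = noiseSd,
              responseModel = responseModel, missingFrac = missingFrac,
              expressionModel = expressionModel,
              addSmallTissue = isTRUE(addSmallTissue),
              driverGenes = driverGenes)
  stopifnot(cfg$nTissues >= 1L, cfg$nDrugs >= 1L,
            all(cfg$cellsPerTissue >= 1L), cfg$noiseSd > 0,
            cfg$missingFrac >= 0, cfg$missingFrac < 1,
            length(cfg$responseModel$concentrations) == 8L)
  if (nrow(effectMap)) {
    stopifnot(all(c("tissue", "drug", "beta", "load_type") %in%
                    colnames(effectMap)),
              all(is.finite(effectMap$beta)),
              all(effectMap$load_type %in% c("cn", "mut")))
    if (any(abs(effectMap$beta) > 3))
      stop("infeasible effect size: |beta| > 3 cannot be realized ",
           "within the dose-response noise model")
  }
  structure(cfg, class = "CohortConfig")
}

#' Effect size targeting a planted Spearman correlation
#'
#' Converts a target rank correlation into the z-space slope `beta` such
#' that `activity_z = beta * load_z + noiseSd * eps` realizes it for
#' Gaussian loads, using the Pearson/Spearman relation for the bivariate
#' normal (`rho_pearson = 2 sin(pi rho_spearman / 6)`).
#'
#' @param rhoS Target Spearman correlation in (-1, 1).
#' @param noiseSd Residual SD of the activity model.
#' @return The slope `beta`.
#' @export
betaForRankCor <- function(rhoS, noiseSd = 0.8) {
  stopifnot(abs(rhoS) < 1)
  rhoP <- 2 * sin(pi * rhoS / 6)
  rhoP * noiseSd / sqrt(1 - rhoP^2)
}

#' Inhibition fractions along a Hill dose-response curve
#'
#' `inhibition(c) = emax * c^hill / (c^hill + ec50^hill)`, monotone
#' non-decreasing in concentration, equal to `emax / 2` at `c = ec50`.
#'
#' @param concentrations Positive concentration vector.
#' @param ec50 Half-maximal concentration (> 0).
#' @param hill Hill slope (> 0).
#' @param emax Maximal inhibition fraction in \[0, 1\].
#' @return Inhibition fractions, one per concentration.
#' @export
hillInhibition <- function(concentrations, ec50, hill, emax) {
  stopifnot(ec50 > 0, hill > 0, emax >= 0, emax <= 1,
            all(concentrations > 0))
  emax / (1 + (ec50 / concentrations)^hill)
}

#' Activity area of an eight-point dose-response curve
#'
#' The area over the relative-growth-inhibition curve, taken as the sum of
#' the eight inhibition fractions: range 0 (inert) to 8 (full kill at all
#' doses); larger means more drug-sensitive.
#'
#' @param inhibition Numeric vector of exactly 8 inhibition fractions in
#'   \[0, 1\].
#' @return The activity area (dimensionless).
#' @examples
#' activityArea(c(0, 0, .1, .2, .4, .7, .9, 1)) # 3.3
#' @export
activityArea <- function(inhibition) {
  if (length(inhibition) != 8L)
    stop("an eight-point dose-response curve is required")
  if (any(!is.finite(inhibition)) || any(inhibition < 0 | inhibition > 1))
    stop("inhibition fractions must lie in [0, 1]")
  sum(inhibition)
}

# Solve for the EC50 whose Hill curve attains a target activity area on the
# fixed concentration grid (area is monotone decreasing in EC50).
.solveEC50 <- function(targetArea, concentrations, hill, emax) {
  f <- function(le) {
    sum(emax / (1 + (10^le / concentrations)^hill)) - targetArea
  }
  lo <- log10(min(concentrations)) - 8
  hi <- log10(max(concentrations)) + 8
  10^stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' Generate a synthetic cohort with known planted truth
#'
#' Draws a full cohort under `config`: tissue-labelled cell lines,
#' copy-number segments and point variants with tissue-specific baseline
#' distributions (the two loads are drawn independently), eight-point
#' dose-response curves whose activity areas realize the planted
#' (tissue, drug) effects plus Gaussian noise in z-space, and (optionally)
#' an expression matrix with gene sets and planted load-linked shifts. The
#' result round-trips losslessly through the package's file readers via
#' [writeCohort()]. Byte-identical outputs are guaranteed for identical
#' `(config, seed)`.
#'
#' @param config A `CohortConfig` from [cohortConfig()].
#' @param seed Integer seed; all randomness derives from it.
#' @return A list with `cohort` (a [LoadCohort-class]) and `truth`: the
#'   realized per-cell loads and z-scores, the effect map with its implied
#'   Pearson/Spearman targets, the lists of truly associated drugs,
#'   tissues and pairs per scope, planted expression couplings, and the
#'   seed.
#' @export
generateCohort <- function(config = cohortConfig(), seed = 1L) {
  stopifnot(inherits(config, "CohortConfig"))
  .withSeed(seed, .generateCohortImpl(config, seed))
}

.generateCohortImpl <- function(config, seed) {
  ## cohort skeleton -------------------------------------------------------
  sizes <- if (length(unique(config$cellsPerTissue)) == 1L)
    rep(config$cellsPerTissue[1L], config$nTissues)
  else sample(seq(config$cellsPerTissue[1L], config$cellsPerTissue[2L]),
              config$nTissues, replace = TRUE)
  tissueNames <- sprintf("TISSUE%02d", seq_len(config$nTissues))
  if (config$addSmallTissue) {
    tissueNames <- c(tissueNames, "TISSUE_SMALL")
    sizes <- c(sizes, 7L)
  }
  tissue <- rep(tissueNames, sizes)
  nCells <- length(tissue)
  cells <- sprintf("CL%04d", seq_len(nCells))
  drugs <- sprintf("DRUG%02d", seq_len(config$nDrugs))
  chromLen <- round(seq(2.4e8, 5e7, length.out = config$nChromosomes))

  ## copy-number segments --------------------------------------------------
  cnm <- config$cnModel
  tVolMu <- stats::setNames(
    cnm$volMeanlog + stats::rnorm(length(tissueNames), 0, cnm$volSdlogTissue),
    tissueNames)
  tLenMu <- stats::setNames(
    cnm$lenMeanlog + stats::rnorm(length(tissueNames), 0, cnm$lenSdlogTissue),
    tissueNames)
  nAlt <- sample(seq(config$segmentsPerCell[1L], config$segmentsPerCell[2L]),
                 nCells, replace = TRUE)
  nNeut <- round(config$neutralFrac * nAlt)
  nSeg <- nAlt + nNeut
  segSample <- rep(cells, nSeg)
  segTissue <- rep(tissue, nSeg)
  altered <- unlist(lapply(seq_len(nCells), function(i)
    c(rep(TRUE, nAlt[i]), rep(FALSE, nNeut[i]))), use.names = FALSE)
  total <- length(segSample)
  mag <- stats::rlnorm(total, tVolMu[segTissue], cnm$volSdlogWithin)
  sign <- sample(c(-1, 1), total, replace = TRUE)
  log2r <- ifelse(altered, sign * mag, 0)
  len <- pmax(1, pmin(round(stats::rlnorm(total, tLenMu[segTissue],
                                          cnm$lenSdlogWithin)), 3e7))
  chrom <- sample(seq_along(chromLen), total, replace = TRUE,
                  prob = chromLen / sum(chromLen))
  start <- floor(stats::runif(total, 1, pmax(2, chromLen[chrom] - len)))
  segments <- GRanges(seqnames = as.character(chrom),
                      ranges = IRanges(start = start, end = start + len - 1),
                      sample_id = segSample, log2_ratio = log2r)

  ## point variants --------------------------------------------------------
  mm <- config$mutModel
  drv <- if (is.null(config$driverGenes)) defaultDriverGenes()
         else config$driverGenes
  tMutMu <- stats::setNames(
    exp(mm$meanlog + stats::rnorm(length(tissueNames), 0, mm$sdlogTissue)),
    tissueNames)
  nVar <- stats::rnbinom(nCells, mu = tMutMu[tissue], size = mm$size)
  vSample <- rep(cells, nVar)
  totalV <- length(vSample)
  isDriver <- stats::runif(totalV) < mm$driverFrac
  gene <- ifelse(isDriver,
                 sample(drv, totalV, replace = TRUE),
                 sprintf("G%04d", sample.int(mm$nSeqGenes, totalV,
                                             replace = TRUE)))
  below <- stats::runif(totalV) < mm$afBelowFrac
  af <- ifelse(below, stats::runif(totalV, 0.01, 0.0999),
               stats::runif(totalV, 0.10, 1))
  classification <- sample(c("missense", "silent", "nonsense", "other"),
                           totalV, replace = TRUE,
                           prob = c(0.55, 0.25, 0.10, 0.10))
  variants <- DataFrame(sample_id = vSample, gene = gene,
                        allelic_fraction = af,
                        classification = classification)

  ## realized loads (ground truth, direct arithmetic) ----------------------
  vol <- abs(log2r) * len
  cnLoad <- vapply(cells, function(s) {
    i <- segSample == s & log2r != 0
    if (!any(i)) 0 else sum(vol[i]) / sum(i)
  }, numeric(1))
  mutKeep <- af >= 0.10 & !(gene %in% drv)
  mutLoad <- stats::setNames(
    as.integer(table(factor(vSample[mutKeep], levels = cells))), cells)
  zWithin <- function(v) {
    out <- rep(NA_real_, length(v))
    for (t in tissueNames) {
      i <- tissue == t
      if (sum(i) >= 2L && stats::sd(v[i]) > 0)
        out[i] <- (v[i] - mean(v[i])) / stats::sd(v[i])
    }
    out
  }
  cnZ <- zWithin(cnLoad)
  mutZ <- zWithin(mutLoad)

  ## activity areas from planted effects via dose-response curves ----------
  rm_ <- config$responseModel
  conc <- rm_$concentrations
  areaLo <- 0.02
  areaHi <- 8 * rm_$emax - 0.02
  drugMu <- stats::runif(config$nDrugs, rm_$drugMeanRange[1L],
                         rm_$drugMeanRange[2L])
  muTD <- outer(rep(1, length(tissueNames)), drugMu) +
    matrix(stats::rnorm(length(tissueNames) * config$nDrugs, 0,
                        rm_$tissueShiftSd),
           length(tissueNames), config$nDrugs)
  muTD <- .clamp(muTD, 0.6, 5.8)
  dimnames(muTD) <- list(tissueNames, drugs)
  betaTD <- matrix(0, length(tissueNames), config$nDrugs,
                   dimnames = list(tissueNames, drugs))
  typeTD <- matrix("cn", length(tissueNames), config$nDrugs,
                   dimnames = list(tissueNames, drugs))
  em <- config$effectMap
  for (k in seq_len(nrow(em))) {
    betaTD[em$tissue[k], em$drug[k]] <- em$beta[k]
    typeTD[em$tissue[k], em$drug[k]] <- em$load_type[k]
  }
  response <- matrix(NA_real_, nCells, config$nDrugs,
                     dimnames = list(cells, drugs))
  eps <- matrix(stats::rnorm(nCells * config$nDrugs), nCells, config$nDrugs)
  for (j in seq_len(config$nDrugs)) {
    beta <- betaTD[tissue, j]
    zl <- ifelse(typeTD[tissue, j] == "cn", cnZ, mutZ)
    zl[is.na(zl)] <- 0
    ztarget <- beta * zl + config$noiseSd * eps[, j]
    zstd <- ztarget / sqrt(beta^2 + config$noiseSd^2)
    area <- .clamp(muTD[tissue, j] + rm_$areaSd * zstd, areaLo, areaHi)
    for (i in seq_len(nCells)) {
      ec50 <- .solveEC50(area[i], conc, rm_$hill, rm_$emax)
      response[i, j] <- activityArea(hillInhibition(conc, ec50, rm_$hill,
                                                    rm_$emax))
    }
  }
  if (config$missingFrac > 0) {
    nMiss <- round(config$missingFrac * length(response))
    response[sample.int(length(response), nMiss)] <- NA_real_
  }

  ## expression layer ------------------------------------------------------
  expression <- matrix(numeric(0), 0, 0,
                       dimnames = list(character(), character()))
  sets <- list()
  xm <- config$expressionModel
  if (!is.null(xm)) {
    genes <- sprintf("G%04d", seq_len(xm$nGenes))
    expression <- matrix(stats::rnorm(xm$nGenes * nCells, 0, xm$noiseSd),
                         xm$nGenes, nCells,
                         dimnames = list(genes, cells)) +
      stats::rnorm(xm$nGenes, xm$baseMean, 1)
    sizes_ <- sample(seq(xm$setSize[1L], xm$setSize[2L]), xm$nSets,
                     replace = TRUE)
    sets <- lapply(sizes_, function(k) sample(genes, k))
    names(sets) <- sprintf("SET%02d", seq_len(xm$nSets))
    sc <- xm$setCouplings
    if (!is.null(sc)) for (k in seq_len(nrow(sc))) {
      zl <- if (sc$load_type[k] == "cn") cnZ else mutZ
      zl[is.na(zl)] <- 0
      members <- sets[[sc$set[k]]]
      expression[members, ] <- expression[members, ] +
        rep(sc$gamma[k] * zl, each = length(members))
    }
    gc_ <- xm$geneCouplings
    if (!is.null(gc_)) for (k in seq_len(nrow(gc_))) {
      zl <- if (gc_$load_type[k] == "cn") cnZ else mutZ
      zl[is.na(zl)] <- 0
      expression[gc_$gene[k], ] <- expression[gc_$gene[k], ] + gc_$gamma[k] * zl
    }
  }

  ## assemble --------------------------------------------------------------
  cohort <- LoadCohort(
    segments = segments, variants = variants,
    annotations = DataFrame(sample_id = cells, tissue = tissue),
    response = response, expression = if (nrow(expression)) expression else NULL,
    geneSets = sets, driverGenes = drv)
  rhoP <- if (nrow(em)) em$beta / sqrt(em$beta^2 + config$noiseSd^2)
          else numeric(0)
  truth <- list(
    loads = data.frame(sample_id = cells, tissue = tissue,
                       cn_load = unname(cnLoad), mut_load = unname(mutLoad),
                       cn_load_z = cnZ, mut_load_z = mutZ,
                       stringsAsFactors = FALSE),
    effect_map = cbind(em,
                       pearson_target = rhoP,
                       spearman_target = (6 / pi) * asin(rhoP / 2)),
    true_pairs = if (nrow(em)) paste(em$tissue, em$drug, sep = "|")
                 else character(0),
    true_drugs = unique(em$drug),
    true_tissues = unique(em$tissue),
    set_couplings = if (is.null(xm)) NULL else xm$setCouplings,
    gene_couplings = if (is.null(xm)) NULL else xm$geneCouplings,
    seed = seed,
    tissue_sizes = stats::setNames(sizes, tissueNames))
  list(cohort = cohort, truth = truth)
}

#' Write a cohort to its on-disk file formats
#'
#' Emits the SEG file, variant table, annotation table, activity-area
#' matrix, expression matrix (if any), GMT gene sets (if any), driver list
#' and, when supplied, the planted truth as JSON -- all in the formats the
#' package's readers consume, enabling lossless round-trips.
#'
#' @param cohort A [LoadCohort-class].
#' @param dir Output directory (created if needed).
#' @param truth Optional truth list from [generateCohort()].
#' @return Invisibly, a named character vector of the written paths.
#' @export
writeCohort <- function(cohort, dir, truth = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    seg = file.path(dir, "segments.seg"),
    variants = file.path(dir, "variants.tsv"),
    annotations = file.path(dir, "annotations.tsv"),
    response = file.path(dir, "activity_area.tsv"))
  writeSegmentFile(cnSegments(cohort), paths["seg"])
  writeVariantFile(variantTable(cohort), paths["variants"])
  utils::write.table(as.data.frame(sampleAnnotations(cohort)),
                     paths["annotations"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeMatrixFile(drugResponse(cohort), paths["response"])
  if (ncol(exprMatrix(cohort))) {
    paths["expression"] <- file.path(dir, "expression.tsv")
    writeMatrixFile(exprMatrix(cohort), paths["expression"])
  }
  if (length(geneSets(cohort))) {
    paths["gene_sets"] <- file.path(dir, "gene_sets.gmt")
    writeGeneSets(geneSets(cohort), paths["gene_sets"])
  }
  paths["drivers"] <- file.path(dir, "driver_genes.txt")
  writeLines(driverGenes(cohort), paths["drivers"])
  if (!is.null(truth)) {
    paths["truth"] <- file.path(dir, "truth.json")
    jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(paths)
}
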