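# Combined genetic load: lasso-penalised linear combination of the two
# z-scored loads fitted to predict z-scored activity area, per analysis
# unit, with cross-validated penalty selection.

.unusable <- function(unit, n, reason) {
  new("CombinedLoadModel", unit = unit, intercept = NA_real_,
      wCn = 0, wMut = 0, penalty = NA_real_, usable = FALSE,
      reason = reason, predictions = numeric(0), observed = numeric(0),
      n = as.integer(n))
}

#' Fit the lasso-combined two-load model for one analysis unit
#'
#' Regresses z-scored activity area on the two z-scored loads with lasso
#' regularisation (via [glmnet::cv.glmnet] along its default
#' regularisation path), selecting the penalty by k-fold cross-validated
#' mean squared error. The default selection rule is the conventional
#' one-standard-error rule (`rule = "1se"`), which shrinks both
#' coefficients to zero on uninformative data; `rule = "min"` picks the
#' CV-minimising penalty instead. Coefficients come from the full-data fit
#' at the selected penalty. The model is `usable` only when at least one
#' load coefficient is non-zero; unusable models carry no predictions and
#' are excluded from the combined-load FDR family downstream.
#'
#' Fold assignment is a deterministic function of `(seed, n)`, so repeated
#' runs are bit-for-bit reproducible. When `n < 10` the fit falls back to
#' leave-one-out cross-validation.
#'
#' @param cnZ,mutZ,activityZ Aligned numeric vectors (z-scored copy-number
#'   load, mutation load and activity area); pairwise-complete rows are
#'   used.
#' @param nFolds Cross-validation folds (default 5).
#' @param seed Integer seed for the fold assignment.
#' @param rule `"1se"` (default) or `"min"` penalty selection.
#' @param lambda Optional fixed penalty; skips cross-validation and fits at
#'   exactly this value (0 gives ordinary least squares).
#' @param evaluation `"insample"` (default) stores full-data fitted values
#'   as predictions, mirroring the protocol of evaluating the combination
#'   on the data used to choose its weights (which can slightly inflate
#'   downstream significance); `"holdout"` stores the cross-validation
#'   out-of-fold (prevalidated) predictions at the selected penalty
#'   instead.
#' @param unit Label stored in the returned model.
#' @return A [CombinedLoadModel-class].
#' @export
fitCombined <- function(cnZ, mutZ, activityZ, nFolds = 5L, seed = 1L,
                        rule = c("1se", "min"), lambda = NULL,
                        evaluation = c("insample", "holdout"),
                        unit = "unit") {
  rule <- match.arg(rule)
  evaluation <- match.arg(evaluation)
  ok <- is.finite(cnZ) & is.finite(mutZ) & is.finite(activityZ)
  x <- cbind(cn = cnZ[ok], mut = mutZ[ok])
  y <- activityZ[ok]
  nm <- if (!is.null(names(activityZ))) names(activityZ)[ok]
        else as.character(seq_along(y))
  n <- length(y)
  if (n < 7L)
    return(.unusable(unit, n, sprintf("too few observations (n = %d < 7)", n)))
  if (stats::sd(y) == 0)
    return(.unusable(unit, n, "constant activity"))
  if (stats::sd(x[, 1L]) == 0 && stats::sd(x[, 2L]) == 0)
    return(.unusable(unit, n, "both loads constant"))
  preval <- NULL
  if (!is.null(lambda)) {
    fit <- glmnet::glmnet(x, y, standardize = FALSE)
    co <- as.numeric(glmnet::coef.glmnet(fit, s = lambda, exact = TRUE,
                                         x = x, y = y))
    sel <- lambda
  } else {
    nf <- if (n < 10L) n else as.integer(nFolds)
    foldid <- .withSeed(.foldSeed(seed, n), sample(rep_len(seq_len(nf), n)))
    cv <- suppressWarnings(
      glmnet::cv.glmnet(x, y, foldid = foldid, standardize = FALSE,
                        keep = (evaluation == "holdout")))
    sel <- if (rule == "1se") cv$lambda.1se else cv$lambda.min
    co <- as.numeric(glmnet::coef.glmnet(cv, s = sel))
    if (evaluation == "holdout")
      preval <- cv$fit.preval[, match(sel, cv$lambda)]
  }
  wCn <- co[2L]; wMut <- co[3L]
  if (abs(wCn) + abs(wMut) == 0)
    return(.unusable(unit, n, "both coefficients shrunk to zero"))
  pred <- if (!is.null(preval)) as.numeric(preval)
          else as.numeric(co[1L] + x %*% c(wCn, wMut))
  new("CombinedLoadModel", unit = unit, intercept = co[1L], wCn = wCn,
      wMut = wMut, penalty = sel, usable = TRUE, reason = character(0),
      predictions = stats::setNames(pred, nm),
      observed = stats::setNames(y, nm), n = as.integer(n))
}

# Assemble per-unit (cn_z, mut_z, activity_z) observations for a scope.
.combinedObservations <- function(loads, response, scope, tissues = NULL,
                                  drugs = NULL, norm = "tissue-drug") {
  tissueOf <- stats::setNames(loads$tissue, loads$sample_id)
  responseZ <- zNormalizeResponse(response, tissueOf, mode = norm)
  zc <- .loadZ(loads, "cn"); zm <- .loadZ(loads, "mut")
  samples0 <- loads$sample_id[loads$included]
  samples0 <- intersect(samples0, rownames(responseZ))
  obs <- list()
  if (scope == "pan_cancer") {
    for (d in colnames(response))
      obs[[d]] <- list(cn = zc[samples0], mut = zm[samples0],
                       y = responseZ[samples0, d], drug = d)
  } else if (scope == "pan_drug") {
    for (t in unique(loads$tissue[loads$included])) {
      s <- intersect(loads$sample_id[loads$tissue == t], samples0)
      k <- ncol(responseZ)
      obs[[t]] <- list(cn = rep(zc[s], times = k), mut = rep(zm[s], times = k),
                       y = as.vector(responseZ[s, , drop = FALSE]), tissue = t)
    }
  } else if (scope == "pair") {
    for (t in intersect(tissues, unique(loads$tissue[loads$included]))) {
      s <- intersect(loads$sample_id[loads$tissue == t], samples0)
      for (d in intersect(drugs, colnames(response)))
        obs[[paste(t, d, sep = "|")]] <-
          list(cn = zc[s], mut = zm[s], y = responseZ[s, d],
               tissue = t, drug = d)
    }
  } else stop("unknown scope: ", scope)
  obs
}

#' Fit combined-load models for every unit of a screen
#'
#' @param loads A [LoadTable-class].
#' @param response Activity-area matrix.
#' @param scope `"pan_cancer"` (one model per drug), `"pan_drug"` (per
#'   tissue, pooled pairs) or `"pair"` (per tissue-drug combination).
#' @param tissues,drugs Candidates, required for `scope = "pair"`.
#' @param nFolds,seed,rule,evaluation Passed to [fitCombined()].
#' @param minN Minimum observations per unit (units below are returned
#'   unusable).
#' @return Named list of [CombinedLoadModel-class] objects.
#' @export
combinedLoadModels <- function(loads, response,
                               scope = c("pan_cancer", "pan_drug", "pair"),
                               tissues = NULL, drugs = NULL, nFolds = 5L,
                               seed = 1L, rule = "1se",
                               evaluation = "insample", minN = 7L) {
  scope <- match.arg(scope)
  obs <- .combinedObservations(loads, response, scope, tissues, drugs)
  models <- lapply(names(obs), function(u) {
    o <- obs[[u]]
    ok <- is.finite(o$cn) & is.finite(o$mut) & is.finite(o$y)
    if (sum(ok) < minN)
      return(.unusable(u, sum(ok), sprintf("n = %d < %d", sum(ok), minN)))
    fitCombined(o$cn, o$mut, stats::setNames(o$y, names(o$cn)),
                nFolds = nFolds, seed = seed, rule = rule,
                evaluation = evaluation, unit = u)
  })
  names(models) <- names(obs)
  models
}

#' Association screen for combined-load models
#'
#' For each usable model, correlates its in-sample predicted activity with
#' the observed activity (one-sided Spearman and Pearson, H1: positive) and
#' adjusts p-values across the family of usable units only.
#'
#' @param models Named list of [CombinedLoadModel-class] objects (see
#'   [combinedLoadModels()]).
#' @param scope Scope label recorded in the result rows.
#' @return A data.frame in the same layout as the single-load screens,
#'   with `load_type = "combined"`; empty (with a warning) when no unit is
#'   usable.
#' @export
combinedScreen <- function(models, scope = "pan_cancer") {
  usable <- Filter(function(m) m@usable, models)
  if (!length(usable)) {
    warning("no usable combined-load models; empty result")
    return(.screenFamily(list(), scope, "combined", 0L))
  }
  obs <- lapply(usable, function(m) {
    parts <- strsplit(m@unit, "|", fixed = TRUE)[[1L]]
    list(x = m@predictions, y = m@observed,
         tissue = if (length(parts) == 2L) parts[1L] else NULL,
         drug = if (length(parts) == 2L) parts[2L]
                else if (scope == "pan_cancer") m@unit else NULL)
  })
  names(obs) <- vapply(usable, function(m) m@unit, character(1))
  out <- .screenFamily(obs, scope, "combined", 0L)
  if (scope == "pan_drug" && nrow(out)) out$tissue <- out$unit
  out
}

#' Independence check between the two load measures
#'
#' Two-sided Pearson and Spearman correlations between copy-number and
#' mutation load, on the raw scores (all cell lines pooled) and on the
#' within-tissue z-scores, plus optionally one two-sided test per tissue.
#' Under the passenger-load model the two measures carry independent
#' information, so these correlations are expected to be near zero.
#'
#' @param loads A [LoadTable-class].
#' @param perTissue If `TRUE`, returns one row per tissue (>= 3 cell
#'   lines), testing the raw loads within that tissue.
#' @return A data.frame with columns `values` (or `tissue`), `r`, `p_r`,
#'   `rho`, `p_rho`, `n`; p-values are two-sided.
#' @export
loadIndependenceCheck <- function(loads, perTissue = FALSE) {
  if (perTissue) {
    tissues <- unique(loads$tissue)
    rows <- lapply(tissues, function(t) {
      i <- loads$tissue == t
      pe <- corTest(loads$cn_load[i], loads$mut_load[i], "pearson",
                    "two.sided")
      sp <- corTest(loads$cn_load[i], loads$mut_load[i], "spearman",
                    "two.sided")
      data.frame(tissue = t, r = pe$estimate, p_r = pe$p.value,
                 rho = sp$estimate, p_rho = sp$p.value, n = pe$n)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    return(out)
  }
  raw_pe <- corTest(loads$cn_load, loads$mut_load, "pearson", "two.sided")
  raw_sp <- corTest(loads$cn_load, loads$mut_load, "spearman", "two.sided")
  z_pe <- corTest(loads$cn_load_z, loads$mut_load_z, "pearson", "two.sided")
  z_sp <- corTest(loads$cn_load_z, loads$mut_load_z, "spearman", "two.sided")
  data.frame(values = c("raw", "z"),
             r = c(raw_pe$estimate, z_pe$estimate),
             p_r = c(raw_pe$p.value, z_pe$p.value),
             rho = c(raw_sp$estimate, z_sp$estimate),
             p_rho = c(raw_sp$p.value, z_sp$p.value),
             n = c(raw_pe$n, z_pe$n))
}
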