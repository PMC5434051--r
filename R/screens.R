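# The three association screens between z-normalised load and z-normalised
# drug sensitivity: pan-cancer (per drug, all tissues pooled), pan-drug (per
# tissue, all drugs pooled) and per tissue-drug pair. Each screen forms its
# own FDR family per load type, mirroring one results table each.

#' Z-normalise an activity-area matrix within tissues
#'
#' With `mode = "tissue-drug"` (default) each drug column is z-scored
#' separately within each tissue, which removes both between-tissue and
#' between-drug baseline differences; this is the normalisation the pooled
#' pan-drug screen needs, since drugs differ in mean activity. With
#' `mode = "tissue"` all entries of a tissue are z-scored together.
#' Cells with fewer than two non-missing values or zero variance give `NA`.
#'
#' @param response Activity matrix, cell lines x drugs.
#' @param tissueOf Named character vector mapping sample -> tissue.
#' @param mode `"tissue-drug"` or `"tissue"`.
#' @return Matrix of z-scores, same shape as `response`.
#' @export
zNormalizeResponse <- function(response, tissueOf,
                               mode = c("tissue-drug", "tissue")) {
  mode <- match.arg(mode)
  z <- response
  z[] <- NA_real_
  tis <- tissueOf[rownames(response)]
  for (t in unique(tis[!is.na(tis)])) {
    rows <- which(tis == t)
    if (mode == "tissue") {
      v <- response[rows, , drop = FALSE]
      ok <- is.finite(v)
      if (sum(ok) >= 2L && stats::sd(v[ok]) > 0)
        z[rows, ] <- (v - mean(v[ok])) / stats::sd(v[ok])
    } else {
      for (j in seq_len(ncol(response))) {
        v <- response[rows, j]
        ok <- is.finite(v)
        if (sum(ok) >= 2L) {
          s <- stats::sd(v[ok])
          if (is.finite(s) && s > 0)
            z[rows, j][ok] <- (v[ok] - mean(v[ok])) / s
        }
      }
    }
  }
  z
}

# Run both correlation tests over a named list of observation sets and
# adjust within the family. Each element: list(x=, y=); elements with fewer
# than minN pairwise-complete observations are skipped with a message and
# untestable units are dropped from the family with a warning.
.screenFamily <- function(obs, scope, loadType, minN,
                          alternative = "greater") {
  rows <- list()
  for (u in names(obs)) {
    o <- obs[[u]]
    ok <- is.finite(o$x) & is.finite(o$y)
    n <- sum(ok)
    if (n < minN) {
      message(sprintf("[%s/%s] '%s' skipped: n = %d < %d",
                      scope, loadType, u, n, minN))
      next
    }
    sp <- corTest(o$x, o$y, "spearman", alternative)
    pe <- corTest(o$x, o$y, "pearson", alternative)
    if (sp$untestable || pe$untestable) {
      warning(sprintf("[%s/%s] '%s' untestable (constant values); excluded from FDR family",
                      scope, loadType, u))
      next
    }
    rows[[u]] <- data.frame(
      scope = scope, unit = u,
      tissue = if (!is.null(o$tissue)) o$tissue else NA_character_,
      drug = if (!is.null(o$drug)) o$drug else NA_character_,
      load_type = loadType,
      rho = sp$estimate, p_rho = sp$p.value, q_rho = NA_real_,
      r = pe$estimate, p_r = pe$p.value, q_r = NA_real_,
      n = n, stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(scope = character(), unit = character(),
                      tissue = character(), drug = character(),
                      load_type = character(), rho = numeric(),
                      p_rho = numeric(), q_rho = numeric(), r = numeric(),
                      p_r = numeric(), q_r = numeric(), n = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$q_rho <- bhAdjust(out$p_rho)
  out$q_r <- bhAdjust(out$p_r)
  out
}

# z-score vector of the requested load for included samples, named by sample.
.loadZ <- function(loads, loadType) {
  z <- loads[[.loadColumn(loadType)]]
  stats::setNames(z, loads$sample_id)
}

#' Pan-cancer screen: one test per drug, all tissues pooled
#'
#' For each drug, tests for a positive correlation between the
#' within-tissue z-normalised load and the within-tissue z-normalised
#' activity area across all included cell lines. The FDR family is all
#' drugs for the given load type.
#'
#' @param loads A [LoadTable-class].
#' @param response Activity-area matrix, cell lines x drugs.
#' @param loadType `"cn"` or `"mut"`.
#' @param minN Minimum cell lines per drug (default 10); smaller drugs are
#'   skipped with a message.
#' @param responseZ Optional pre-computed z-normalised response (to reuse
#'   across screens).
#' @return A data.frame with one row per tested drug: Spearman `rho`,
#'   one-sided `p_rho`, FDR `q_rho`, Pearson `r`, `p_r`, `q_r`, and `n`.
#' @export
panCancerScreen <- function(loads, response, loadType = c("cn", "mut"),
                            minN = 10L, responseZ = NULL) {
  loadType <- match.arg(loadType)
  tissueOf <- stats::setNames(loads$tissue, loads$sample_id)
  if (is.null(responseZ))
    responseZ <- zNormalizeResponse(response, tissueOf)
  z <- .loadZ(loads, loadType)
  samples <- intersect(names(z)[!is.na(z)], rownames(responseZ))
  obs <- lapply(colnames(response), function(d)
    list(x = z[samples], y = responseZ[samples, d], drug = d))
  names(obs) <- colnames(response)
  .screenFamily(obs, "pan_cancer", loadType, minN)
}

#' Pan-drug screen: one test per tissue, all drugs pooled
#'
#' Within each tissue, observations are (cell line, drug) pairs pooled over
#' all drugs, which averages over drug-specific effects; the reported `n`
#' is the pair count. The load z-score repeats across a cell line's drugs;
#' activity is z-normalised within each (tissue, drug) cell by default so
#' that between-drug mean differences do not confound the pooled
#' correlation (`norm = "tissue"` reproduces plain within-tissue
#' normalisation). The FDR family is all tissues for the load type.
#'
#' @param loads A [LoadTable-class].
#' @param response Activity-area matrix.
#' @param loadType `"cn"` or `"mut"`.
#' @param minPairs Minimum number of (cell line, drug) pairs per tissue
#'   (default 30).
#' @param norm Activity normalisation mode (see [zNormalizeResponse()]).
#' @return A data.frame with one row per tested tissue.
#' @export
panDrugScreen <- function(loads, response, loadType = c("cn", "mut"),
                          minPairs = 30L, norm = c("tissue-drug", "tissue")) {
  loadType <- match.arg(loadType)
  norm <- match.arg(norm)
  tissueOf <- stats::setNames(loads$tissue, loads$sample_id)
  responseZ <- zNormalizeResponse(response, tissueOf, mode = norm)
  z <- .loadZ(loads, loadType)
  tissues <- unique(loads$tissue[loads$included])
  obs <- lapply(tissues, function(t) {
    samples <- loads$sample_id[loads$tissue == t & !is.na(z[loads$sample_id])]
    samples <- intersect(samples, rownames(responseZ))
    if (!length(samples))
      return(list(x = numeric(0), y = numeric(0), tissue = t))
    yz <- responseZ[samples, , drop = FALSE]
    list(x = rep(z[samples], times = ncol(yz)), y = as.vector(yz), tissue = t)
  })
  names(obs) <- tissues
  .screenFamily(obs, "pan_drug", loadType, minPairs)
}

#' Tissue-drug pair screen
#'
#' Tests every supplied (tissue, drug) combination with at least `minN`
#' cell lines for a positive load-sensitivity correlation. Candidates are
#' normally the tissues and drugs flagged by the pan-drug and pan-cancer
#' screens; the FDR family is all tested combinations for the load type.
#'
#' @param loads A [LoadTable-class].
#' @param response Activity-area matrix.
#' @param tissues,drugs Candidate tissue and drug names; all combinations
#'   are tested. Empty candidates yield an empty result with a warning.
#' @param loadType `"cn"` or `"mut"`.
#' @param minN Minimum cell lines per combination (default 7).
#' @return A data.frame with one row per tested (tissue, drug) pair;
#'   `unit` is `"tissue|drug"` and the `tissue`/`drug` columns carry the
#'   parts.
#' @export
pairScreen <- function(loads, response, tissues, drugs,
                       loadType = c("cn", "mut"), minN = 7L) {
  loadType <- match.arg(loadType)
  if (!length(tissues) || !length(drugs)) {
    warning("empty candidate tissue or drug list; no pairs tested")
    return(.screenFamily(list(), "pair", loadType, minN))
  }
  tissues <- intersect(tissues, unique(loads$tissue[loads$included]))
  drugs <- intersect(drugs, colnames(response))
  z <- .loadZ(loads, loadType)
  obs <- list()
  for (t in tissues) {
    samples <- loads$sample_id[loads$tissue == t & !is.na(z[loads$sample_id])]
    samples <- intersect(samples, rownames(response))
    for (d in drugs) {
      obs[[paste(t, d, sep = "|")]] <-
        list(x = z[samples], y = response[samples, d], tissue = t, drug = d)
    }
  }
  .screenFamily(obs, "pair", loadType, minN)
}

#' Units flagged by a screen at an FDR level
#'
#' @param result A screen result data.frame.
#' @param level FDR level (default 0.10).
#' @param coefficient Which family to threshold: `"rho"` (Spearman, default)
#'   or `"r"` (Pearson).
#' @return The flagged subset of `result`.
#' @export
screenHits <- function(result, level = 0.10, coefficient = c("rho", "r")) {
  coefficient <- match.arg(coefficient)
  q <- if (coefficient == "rho") result$q_rho else result$q_r
  result[!is.na(q) & q <= level, , drop = FALSE]
}
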