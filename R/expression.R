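# Expression layer: per-sample gene-set enrichment scores (standardized
# mean-rank statistic) and correlation screens linking scores, or single
# panel genes, to the genetic loads. Tests here are two-sided: both up- and
# down-regulated programs are of interest.

#' Per-sample gene-set enrichment scores (standardized mean rank)
#'
#' For each sample, all `G` measured genes are ranked ascending (average
#' ranks for ties). A set with `m` member genes present and mean member
#' rank `Rbar` scores
#' `(Rbar - (G + 1)/2) / sqrt((G + 1) * (G - m) / (12 * m))`,
#' the Wilcoxon-style standardized mean-rank statistic: 0 in expectation
#' for a random set, approximately unit variance, positive when the set is
#' expressed above the sample's typical gene, and antisymmetric under
#' reversal of the sample's expression profile. The score depends on the
#' expression values only through their ranks, so it is invariant under any
#' strictly monotone transform.
#'
#' Sets with fewer than two member genes present in the expression rows are
#' skipped with a message (once per set). A set covering all measured genes
#' is degenerate (`G = m`) and is likewise skipped.
#'
#' @param expression Numeric matrix, genes x samples.
#' @param sets Named list of character vectors of gene symbols.
#' @return Numeric matrix, sets (retained) x samples.
#' @export
enrichmentScores <- function(expression, sets) {
  stopifnot(nrow(expression) >= 2L, length(sets) >= 1L)
  G <- nrow(expression)
  ranks <- apply(expression, 2L, rank)
  keep <- vapply(sets, function(s) {
    m <- sum(rownames(expression) %in% s)
    m >= 2L && m < G
  }, logical(1))
  if (any(!keep))
    message("skipping ", sum(!keep),
            " gene set(s) with < 2 members measured (or covering all genes): ",
            paste(names(sets)[!keep], collapse = ", "))
  sets <- sets[keep]
  out <- matrix(NA_real_, length(sets), ncol(expression),
                dimnames = list(names(sets), colnames(expression)))
  for (i in seq_along(sets)) {
    idx <- which(rownames(expression) %in% sets[[i]])
    m <- length(idx)
    denom <- sqrt((G + 1) * (G - m) / (12 * m))
    rbar <- colMeans(ranks[idx, , drop = FALSE])
    out[i, ] <- (rbar - (G + 1) / 2) / denom
  }
  out
}

# Shared worker: correlate each row of a value matrix against a load
# z-score, two-sided, BH within the family.
.rowLoadScreen <- function(values, loads, loadType, scope) {
  z <- .loadZ(loads, loadType)
  samples <- intersect(colnames(values), names(z)[!is.na(z)])
  if (length(samples) < 3L)
    stop("fewer than 3 samples shared between values and load table")
  obs <- lapply(rownames(values), function(rn)
    list(x = values[rn, samples], y = z[samples]))
  names(obs) <- rownames(values)
  out <- .screenFamily(obs, scope, loadType, minN = 3L,
                       alternative = "two.sided")
  out$tissue <- NULL
  out$drug <- NULL
  out
}

#' Correlate pathway enrichment scores with a genetic load
#'
#' Two-sided Spearman and Pearson correlations between each gene set's
#' per-sample enrichment score and the within-tissue z-normalised load,
#' with BH adjustment across all sets for the given load type. Both signs
#' are of interest: positively associated programs (e.g. DNA-damage
#' checkpoints) and negatively associated ones are reported alike.
#'
#' @param scores Enrichment-score matrix from [enrichmentScores()].
#' @param loads A [LoadTable-class].
#' @param loadType `"cn"` or `"mut"`.
#' @return A data.frame, one row per gene set, with two-sided p-values and
#'   FDR q-values.
#' @export
pathwayLoadScreen <- function(scores, loads, loadType = c("cn", "mut")) {
  loadType <- match.arg(loadType)
  .rowLoadScreen(scores, loads, loadType, "pathway")
}

#' Correlate single-gene expression with a genetic load
#'
#' Two-sided correlation screen over a gene panel (by default a
#' growth-factor receptor panel, see [defaultGrowthFactorPanel()]): each
#' panel gene's expression across samples versus the z-normalised load,
#' BH-adjusted across panel genes per load type. Genes with constant
#' expression are excluded with a message; panel genes absent from the
#' expression matrix trigger an error naming them when none remain.
#'
#' @param expression Numeric matrix, genes x samples.
#' @param panel Character vector of gene symbols.
#' @param loads A [LoadTable-class].
#' @param loadType `"cn"` or `"mut"`.
#' @return A data.frame, one row per testable panel gene.
#' @export
genePanelLoadScreen <- function(expression, panel, loads,
                                loadType = c("cn", "mut")) {
  loadType <- match.arg(loadType)
  present <- intersect(panel, rownames(expression))
  if (!length(present))
    stop("no panel genes found in expression matrix; missing: ",
         paste(utils::head(setdiff(panel, rownames(expression)), 10L),
               collapse = ", "))
  vals <- expression[present, , drop = FALSE]
  constant <- apply(vals, 1L, function(v) stats::sd(v, na.rm = TRUE) == 0)
  constant[is.na(constant)] <- TRUE
  if (any(constant)) {
    message("excluding ", sum(constant), " constant panel gene(s): ",
            paste(present[constant], collapse = ", "))
    vals <- vals[!constant, , drop = FALSE]
  }
  if (!nrow(vals)) stop("no testable panel genes after filtering")
  .rowLoadScreen(vals, loads, loadType, "panel")
}
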