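#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
#' @importFrom GenomicRanges GRanges seqnames start end width
#' @importFrom IRanges IRanges
NULL

#' Cohort container for a genetic-load analysis
#'
#' A `LoadCohort` bundles everything one cohort-level analysis needs: the
#' segmented copy-number profiles, the point-variant table, the cell-line
#' annotations (tissue of origin), the drug-response matrix (activity areas),
#' and optionally a gene-expression matrix, gene sets and a driver-gene
#' exclusion list.
#'
#' @slot segments A [GenomicRanges::GRanges] of copy-number segments with
#'   metadata columns `sample_id` (character) and `log2_ratio` (numeric,
#'   median-centred log2 copy-number ratio).
#' @slot variants A [S4Vectors::DataFrame] with columns `sample_id`, `gene`,
#'   `allelic_fraction` (proportion in \[0, 1\]) and `classification`.
#' @slot annotations A [S4Vectors::DataFrame] with columns `sample_id` and
#'   `tissue`; one row per cell line.
#' @slot response Numeric matrix, cell lines x drugs, of activity areas
#'   (area over the growth-inhibition curve; larger = more sensitive).
#'   Unscreened combinations are `NA`.
#' @slot expression Numeric matrix, genes x cell lines, of normalised
#'   expression values. May have zero rows when no expression data exist.
#' @slot geneSets Named list of character vectors of gene symbols.
#' @slot driverGenes Character vector of driver symbols excluded from the
#'   mutation load.
#'
#' @seealso [LoadCohort()] for construction, [computeLoads()] for the next
#'   pipeline step.
#' @exportClass LoadCohort
setClass("LoadCohort",
  slots = c(
    segments    = "GRanges",
    variants    = "DataFrame",
    annotations = "DataFrame",
    response    = "matrix",
    expression  = "matrix",
    geneSets    = "list",
    driverGenes = "character"
  )
)

setValidity("LoadCohort", function(object) {
  msg <- character()
  seg <- object@segments
  if (length(seg)) {
    mc <- mcols(seg)
    if (!all(c("sample_id", "log2_ratio") %in% colnames(mc)))
      msg <- c(msg, "segments must carry 'sample_id' and 'log2_ratio' metadata columns")
    else {
      if (any(is.na(mc$sample_id)) || any(!nzchar(mc$sample_id)))
        msg <- c(msg, "segment sample_id must be non-empty")
      if (any(!is.finite(mc$log2_ratio)))
        msg <- c(msg, "segment log2_ratio must be finite")
    }
  }
  v <- object@variants
  if (nrow(v)) {
    need <- c("sample_id", "gene", "allelic_fraction", "classification")
    if (!all(need %in% colnames(v)))
      msg <- c(msg, paste("variants must have columns:", paste(need, collapse = ", ")))
    else if (any(v$allelic_fraction < 0 | v$allelic_fraction > 1, na.rm = TRUE))
      msg <- c(msg, "allelic_fraction must lie in [0, 1]")
  }
  ann <- object@annotations
  if (!all(c("sample_id", "tissue") %in% colnames(ann)))
    msg <- c(msg, "annotations must have columns 'sample_id' and 'tissue'")
  else {
    if (anyDuplicated(ann$sample_id))
      msg <- c(msg, "annotations sample_id must be unique")
    if (any(is.na(ann$tissue)) || any(!nzchar(ann$tissue)))
      msg <- c(msg, "tissue labels must be non-empty")
    known <- ann$sample_id
    if (nrow(object@response) && !all(rownames(object@response) %in% known))
      msg <- c(msg, "every response sample must appear in annotations")
    if (ncol(object@expression) && !all(colnames(object@expression) %in% known))
      msg <- c(msg, "every expression sample must appear in annotations")
  }
  if (length(msg)) msg else TRUE
})

#' Per-cell-line genetic load table
#'
#' A [S4Vectors::DataFrame] subclass holding, per cell line, the raw
#' copy-number load (mean absolute alteration volume, bp x |log2|), the raw
#' mutation load (filtered variant count), their within-tissue z-scores, and
#' an inclusion flag (`FALSE` for cell lines in tissues below the minimum
#' tissue size, whose z-scores are `NA`).
#'
#' Required columns: `sample_id`, `tissue`, `cn_load`, `mut_load`,
#' `cn_load_z`, `mut_load_z`, `included`.
#'
#' @seealso [computeLoads()]
#' @exportClass LoadTable
setClass("LoadTable", contains = "DFrame")

setValidity("LoadTable", function(object) {
  need <- c("sample_id", "tissue", "cn_load", "mut_load",
            "cn_load_z", "mut_load_z", "included")
  msg <- character()
  if (!all(need %in% colnames(object)))
    return(paste("LoadTable requires columns:", paste(need, collapse = ", ")))
  if (any(object$cn_load < 0, na.rm = TRUE))
    msg <- c(msg, "cn_load must be >= 0")
  if (any(object$mut_load < 0, na.rm = TRUE) ||
      any(object$mut_load != round(object$mut_load), na.rm = TRUE))
    msg <- c(msg, "mut_load must be a non-negative integer count")
  if (length(msg)) msg else TRUE
})

#' Lasso-combined two-load model for one analysis unit
#'
#' Result of regressing (z-scored) activity area on the two (z-scored)
#' genetic loads with lasso regularisation for one analysis unit (a drug, a
#' tissue, or a tissue-drug pair). A model is `usable` only when at least
#' one load coefficient is non-zero at the selected penalty; unusable models
#' are excluded from the combined-load FDR family.
#'
#' @slot unit Label of the analysis unit.
#' @slot intercept Fitted intercept (z-scored activity units).
#' @slot wCn,wMut Lasso coefficients on the z-scored copy-number and
#'   mutation loads (dimensionless).
#' @slot penalty Selected regularisation strength (lambda).
#' @slot usable Logical; `TRUE` iff `|wCn| + |wMut| > 0`.
#' @slot reason Why a model is unusable (empty when usable).
#' @slot predictions Named numeric vector of in-sample predicted activity
#'   (defined only when usable).
#' @slot observed Named numeric vector of observed activity for the same
#'   observations.
#' @slot n Number of complete observations used in the fit.
#'
#' @seealso [fitCombined()], [combinedScreen()]
#' @exportClass CombinedLoadModel
setClass("CombinedLoadModel",
  slots = c(
    unit        = "character",
    intercept   = "numeric",
    wCn         = "numeric",
    wMut        = "numeric",
    penalty     = "numeric",
    usable      = "logical",
    reason      = "character",
    predictions = "numeric",
    observed    = "numeric",
    n           = "integer"
  )
)

setValidity("CombinedLoadModel", function(object) {
  if (length(object@usable) != 1L) return("usable must be a single flag")
  if (object@usable && !(abs(object@wCn) + abs(object@wMut) > 0))
    return("usable model must have a non-zero load coefficient")
  if (!object@usable && length(object@predictions))
    return("unusable model must not carry predictions")
  TRUE
})
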