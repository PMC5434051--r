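#' @rdname LoadCohort-accessors
#' @export
setGeneric("cnSegments", function(x) standardGeneric("cnSegments"))

#' @rdname LoadCohort-accessors
#' @export
setGeneric("variantTable", function(x) standardGeneric("variantTable"))

#' @rdname LoadCohort-accessors
#' @export
setGeneric("sampleAnnotations", function(x) standardGeneric("sampleAnnotations"))

#' @rdname LoadCohort-accessors
#' @export
setGeneric("drugResponse", function(x) standardGeneric("drugResponse"))

#' @rdname LoadCohort-accessors
#' @export
setGeneric("exprMatrix", function(x) standardGeneric("exprMatrix"))

#' @rdname LoadCohort-accessors
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))

#' @rdname LoadCohort-accessors
#' @export
setGeneric("driverGenes", function(x) standardGeneric("driverGenes"))

#' Accessors for LoadCohort components
#'
#' `cnSegments()` returns the segment `GRanges`; `variantTable()` the variant
#' `DataFrame`; `sampleAnnotations()` the sample-to-tissue `DataFrame`;
#' `drugResponse()` the activity-area matrix (cell lines x drugs);
#' `exprMatrix()` the expression matrix (genes x cell lines); `geneSets()`
#' the named list of gene sets; `driverGenes()` the driver exclusion list.
#'
#' @param x A [LoadCohort-class] object.
#' @return The corresponding slot value.
#' @name LoadCohort-accessors
#' @aliases cnSegments variantTable sampleAnnotations drugResponse
#'   exprMatrix geneSets driverGenes
NULL

setMethod("cnSegments", "LoadCohort", function(x) x@segments)
setMethod("variantTable", "LoadCohort", function(x) x@variants)
setMethod("sampleAnnotations", "LoadCohort", function(x) x@annotations)
setMethod("drugResponse", "LoadCohort", function(x) x@response)
setMethod("exprMatrix", "LoadCohort", function(x) x@expression)
setMethod("geneSets", "LoadCohort", function(x) x@geneSets)
setMethod("driverGenes", "LoadCohort", function(x) x@driverGenes)

setMethod("show", "LoadCohort", function(object) {
  ann <- object@annotations
  cat("LoadCohort with", nrow(ann), "cell lines across",
      length(unique(ann$tissue)), "tissues\n")
  cat("  segments   :", length(object@segments), "intervals,",
      length(unique(mcols(object@segments)$sample_id)), "profiled samples\n")
  cat("  variants   :", nrow(object@variants), "records,",
      length(unique(object@variants$sample_id)), "profiled samples\n")
  cat("  response   :", nrow(object@response), "x", ncol(object@response),
      "(cell lines x drugs)\n")
  cat("  expression :", nrow(object@expression), "genes x",
      ncol(object@expression), "cell lines\n")
  cat("  gene sets  :", length(object@geneSets),
      " | driver exclusion list:", length(object@driverGenes), "genes\n")
})

setMethod("show", "CombinedLoadModel", function(object) {
  cat("CombinedLoadModel for unit '", object@unit, "' (n = ", object@n, ")\n",
      sep = "")
  if (object@usable) {
    cat(sprintf("  activity_z = %.4f + %.4f * cn_z + %.4f * mut_z  (lambda = %.4g)\n",
                object@intercept, object@wCn, object@wMut, object@penalty))
  } else {
    cat("  unusable:", object@reason, "\n")
  }
})
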