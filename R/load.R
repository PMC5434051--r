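#' Alteration volume of copy-number segments
#'
#' The volume of a segment is the absolute copy-number change times its
#' length: `|log2_ratio| * (end - start + 1)`. Amplifications and deletions
#' contribute equally; a copy-neutral segment has volume zero.
#'
#' @param segments A `GRanges` with a `log2_ratio` metadata column.
#' @return Numeric vector of volumes (bp x |log2|), one per segment.
#' @examples
#' gr <- GenomicRanges::GRanges("1", IRanges::IRanges(11, 20),
#'                              sample_id = "A", log2_ratio = -0.5)
#' segmentVolume(gr) # 5
#' @export
segmentVolume <- function(segments) {
  abs(mcols(segments)$log2_ratio) * width(segments)
}

#' Per-sample copy-number load
#'
#' The copy-number load of a cell line is the mean alteration volume of its
#' copy-number changes. A segment counts as altered when
#' `|log2_ratio| > neutralThreshold`. With `meanOver = "altered"` (default)
#' the mean is taken over altered segments only, which is robust to how
#' finely copy-neutral stretches happen to be segmented; with
#' `meanOver = "all"` neutral segments contribute zero volume but enter the
#' denominator.
#'
#' @param segments `GRanges` with `sample_id` and `log2_ratio` metadata
#'   columns (possibly many samples).
#' @param neutralThreshold Non-negative `|log2|` cutoff below which a
#'   segment is considered copy-neutral (default 0: any non-zero change is
#'   an alteration).
#' @param meanOver `"altered"` or `"all"`; denominator of the mean.
#' @return Named numeric vector of loads, one per sample present in
#'   `segments`. A sample whose segments are all neutral gets load 0.
#'   Samples with no segments at all are simply absent (missing, not zero).
#' @export
copyNumberLoad <- function(segments, neutralThreshold = 0,
                           meanOver = c("altered", "all")) {
  meanOver <- match.arg(meanOver)
  stopifnot(neutralThreshold >= 0)
  sample_id <- mcols(segments)$sample_id
  vol <- segmentVolume(segments)
  altered <- abs(mcols(segments)$log2_ratio) > neutralThreshold
  samples <- unique(sample_id)
  out <- vapply(samples, function(s) {
    sel <- sample_id == s
    a <- sel & altered
    if (!any(a)) return(0)
    if (meanOver == "altered") mean(vol[a]) else sum(vol[a]) / sum(sel)
  }, numeric(1))
  names(out) <- samples
  out
}

#' Per-sample mutation load
#'
#' Counts a cell line's point variants after (i) removing variants with
#' allelic fraction below `afMin` (variants at exactly `afMin` are kept) and
#' (ii) removing variants in driver genes, so that the count approximates
#' the passenger burden. A classification filter (e.g. silent-only) is
#' available; the default counts all classes.
#'
#' @param variants Variant table (`DataFrame`/data.frame) with columns
#'   `sample_id`, `gene`, `allelic_fraction` and `classification`.
#' @param driverGenes Character vector of driver symbols to exclude.
#' @param afMin Minimum allelic fraction, a proportion in \[0, 1\]
#'   (default 0.10).
#' @param classes Optional character vector of variant classes to keep
#'   (`NULL` = all classes).
#' @return Named integer vector of counts, one per sample present in
#'   `variants` (samples whose variants are all filtered out count 0).
#' @export
mutationLoad <- function(variants, driverGenes = character(), afMin = 0.10,
                         classes = NULL) {
  stopifnot(afMin >= 0, afMin <= 1)
  if (nrow(variants) == 0L) return(stats::setNames(integer(0), character(0)))
  keep <- variants$allelic_fraction >= afMin &
    !(variants$gene %in% driverGenes)
  if (!is.null(classes)) keep <- keep & variants$classification %in% classes
  samples <- unique(variants$sample_id)
  counts <- table(factor(variants$sample_id[keep], levels = samples))
  stats::setNames(as.integer(counts), samples)
}

#' Within-group z-score normalisation with small-group exclusion
#'
#' Within each group of at least `minGroupSize` members the values are
#' centred by the group mean and scaled by the group sample standard
#' deviation (n - 1 denominator). Groups below the minimum size are flagged
#' excluded and their z-scores are missing; groups whose non-missing values
#' have zero standard deviation yield missing z-scores with a warning
#' (degenerate group) but remain included.
#'
#' @param values Numeric vector (may contain `NA`).
#' @param groups Group label per value.
#' @param minGroupSize Minimum number of members for a group to be retained
#'   (default 8; must be >= 2).
#' @return A list with `z` (numeric, `NA` where not computable) and
#'   `included` (logical, `FALSE` for members of undersized groups).
#' @examples
#' zNormalizeByGroup(c(2, 4, 6), rep("t", 3), minGroupSize = 2)$z # -1 0 1
#' @export
zNormalizeByGroup <- function(values, groups, minGroupSize = 8L) {
  stopifnot(length(values) == length(groups), minGroupSize >= 2L)
  z <- rep(NA_real_, length(values))
  included <- rep(FALSE, length(values))
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (length(idx) < minGroupSize) next
    included[idx] <- TRUE
    v <- values[idx]
    ok <- is.finite(v)
    if (sum(ok) < 2L) next
    s <- stats::sd(v[ok])
    if (!is.finite(s) || s == 0) {
      warning(sprintf("group '%s' has zero variance; z-scores set missing", g))
      next
    }
    z[idx][ok] <- (v[ok] - mean(v[ok])) / s
  }
  list(z = z, included = included)
}

#' Compute the per-cell-line load table for a cohort
#'
#' Runs the two load scores over every annotated cell line and z-normalises
#' each within its tissue of origin. Tissues with fewer than `minTissue`
#' cell lines are excluded (flag `included = FALSE`, z-scores missing), as
#' small tissues cannot support a stable within-tissue normalisation. Cell
#' lines without any copy-number segments have a missing `cn_load`
#' (reported via a message, never coerced to zero); cell lines absent from
#' the variant table count zero variants.
#'
#' @param cohort A [LoadCohort-class].
#' @param afMin Allelic-fraction cutoff for the mutation load (default 0.10).
#' @param neutralThreshold `|log2|` cutoff for the copy-number load
#'   (default 0).
#' @param minTissue Minimum tissue size retained (default 8).
#' @param meanOver Denominator convention for [copyNumberLoad()].
#' @param classes Optional variant-class filter for [mutationLoad()].
#' @param dropChroms Chromosome labels to drop before scoring (default
#'   none: sex chromosomes and mitochondria are kept if present).
#' @return A [LoadTable-class] with one row per annotated cell line.
#' @export
computeLoads <- function(cohort, afMin = 0.10, neutralThreshold = 0,
                         minTissue = 8L, meanOver = c("altered", "all"),
                         classes = NULL, dropChroms = character()) {
  meanOver <- match.arg(meanOver)
  ann <- sampleAnnotations(cohort)
  seg <- cnSegments(cohort)
  if (length(dropChroms))
    seg <- seg[!(as.character(seqnames(seg)) %in% dropChroms)]
  cn <- copyNumberLoad(seg, neutralThreshold, meanOver)
  mut <- mutationLoad(variantTable(cohort), driverGenes(cohort), afMin,
                      classes)
  samples <- ann$sample_id
  cnv <- unname(cn[samples])
  nmiss <- sum(is.na(cnv))
  if (nmiss)
    message(nmiss, " cell line(s) have no copy-number segments; cn_load missing")
  mutv <- unname(mut[samples])
  mutv[is.na(mutv)] <- 0L
  zc <- zNormalizeByGroup(cnv, ann$tissue, minTissue)
  zm <- zNormalizeByGroup(mutv, ann$tissue, minTissue)
  new("LoadTable", DataFrame(
    sample_id = samples, tissue = ann$tissue,
    cn_load = cnv, mut_load = as.integer(mutv),
    cn_load_z = zc$z, mut_load_z = zm$z,
    included = zc$included
  ))
}

# Pick the z-score column for a load type.
.loadColumn <- function(loadType) {
  switch(loadType, cn = "cn_load_z", mut = "mut_load_z",
         stop("loadType must be 'cn' or 'mut'"))
}
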