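#' Read a SEG file of segmented copy-number calls
#'
#' Parses the standard tab-delimited SEG layout: sample, chromosome, start,
#' end, segment mean (log2 ratio), with an optional probe-count column
#' between the end coordinate and the segment mean (the segment mean is
#' always taken from the last column). Coordinates are interpreted as
#' 1-based inclusive, so a segment's length is `end - start + 1`.
#'
#' @param path Path to a tab-delimited SEG file with a header row.
#' @return A [GenomicRanges::GRanges] with one range per data row, in input
#'   order, carrying metadata columns `sample_id` and `log2_ratio`.
#' @examples
#' seg <- tempfile(fileext = ".seg")
#' writeLines(c("sample\tchrom\tstart\tend\tseg.mean",
#'              "A\t1\t100\t200\t0.8", "B\t2\t1\t50\t-1.2"), seg)
#' readSegmentFile(seg)
#' @export
readSegmentFile <- function(path) {
  if (!file.exists(path)) .fileError(path, "file not found")
  dat <- utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(dat) < 5L) {
    roles <- c("sample", "chromosome", "start", "end", "segment mean")
    .fileError(path, sprintf(
      "SEG format error: expected >= 5 tab-delimited columns, found %d (missing '%s')",
      ncol(dat), roles[ncol(dat) + 1L]))
  }
  if (nrow(dat) == 0L) {
    warning(sprintf("%s: no data rows (header only); returning empty segment set",
                    basename(path)))
    return(GRanges(sample_id = character(), log2_ratio = numeric()))
  }
  line <- seq_len(nrow(dat)) + 1L # header is line 1
  sample_id <- dat[[1L]]
  chrom <- dat[[2L]]
  start <- suppressWarnings(as.integer(dat[[3L]]))
  end <- suppressWarnings(as.integer(dat[[4L]]))
  log2_ratio <- suppressWarnings(as.numeric(dat[[ncol(dat)]]))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) .fileError(path, sprintf(
    "non-integer genomic coordinate at line %d", line[bad[1L]]))
  bad <- which(is.na(log2_ratio))
  if (length(bad)) .fileError(path, sprintf(
    "non-numeric segment mean (log2 ratio) at line %d", line[bad[1L]]))
  bad <- which(end < start)
  if (length(bad)) .fileError(path, sprintf(
    "invalid segment (end < start) at line %d", line[bad[1L]]))
  bad <- which(is.na(sample_id) | !nzchar(sample_id))
  if (length(bad)) .fileError(path, sprintf(
    "empty sample identifier at line %d", line[bad[1L]]))
  GRanges(seqnames = chrom, ranges = IRanges(start = start, end = end),
          sample_id = sample_id, log2_ratio = log2_ratio)
}

#' Write segments back to SEG format
#'
#' @param segments A `GRanges` as returned by [readSegmentFile()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
writeSegmentFile <- function(segments, path) {
  df <- data.frame(sample = mcols(segments)$sample_id,
                   chrom = as.character(seqnames(segments)),
                   start = start(segments), end = end(segments),
                   seg.mean = .fmtNum(mcols(segments)$log2_ratio))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.matchColumn <- function(nms, candidates) {
  hit <- which(tolower(nms) %in% candidates)
  if (length(hit)) hit[1L] else NA_integer_
}

#' Read a MAF-like point-variant table
#'
#' Columns are resolved by header name, never by position. Recognised
#' headers (case-insensitive): sample (`sample`, `sample_id`,
#' `tumor_sample_barcode`), gene (`gene`, `hugo_symbol`, `gene_symbol`),
#' allelic fraction (`allelic_fraction`, `allele_fraction`, `af`,
#' `tumor_f`), classification (`classification`, `variant_classification`;
#' optional). Allelic fractions may be recorded as proportions (0.25) or as
#' percents (25 or "25%"); the `afMode` switch selects the convention and
#' values are always stored as proportions.
#'
#' @param path Path to a tab-delimited variant file with a header row.
#' @param afMode `"proportion"` (default) or `"percent"`.
#' @return A [S4Vectors::DataFrame] with columns `sample_id`, `gene`,
#'   `allelic_fraction` (proportion) and `classification`, in input order.
#' @export
readVariantFile <- function(path, afMode = c("proportion", "percent")) {
  afMode <- match.arg(afMode)
  if (!file.exists(path)) .fileError(path, "file not found")
  dat <- utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  nms <- colnames(dat)
  isamp <- .matchColumn(nms, c("sample", "sample_id", "tumor_sample_barcode"))
  igene <- .matchColumn(nms, c("gene", "hugo_symbol", "gene_symbol"))
  iaf <- .matchColumn(nms, c("allelic_fraction", "allele_fraction", "af",
                             "tumor_f", "allelic_frac"))
  iclass <- .matchColumn(nms, c("classification", "variant_classification",
                                "class"))
  missing <- c("sample", "gene", "allelic fraction")[is.na(c(isamp, igene, iaf))]
  if (length(missing)) .fileError(path, sprintf(
    "variant format error: missing required column(s): %s",
    paste(missing, collapse = ", ")))
  if (nrow(dat) == 0L) {
    warning(sprintf("%s: no data rows (header only)", basename(path)))
    return(DataFrame(sample_id = character(), gene = character(),
                     allelic_fraction = numeric(), classification = character()))
  }
  line <- seq_len(nrow(dat)) + 1L
  afraw <- sub("%$", "", trimws(dat[[iaf]]))
  af <- suppressWarnings(as.numeric(afraw))
  bad <- which(is.na(af))
  if (length(bad)) .fileError(path, sprintf(
    "non-numeric allelic fraction at line %d", line[bad[1L]]))
  if (afMode == "percent") af <- af / 100
  bad <- which(af < 0 | af > 1)
  if (length(bad)) .fileError(path, sprintf(
    "allelic fraction outside [0, 1] after conversion at line %d", line[bad[1L]]))
  DataFrame(
    sample_id = dat[[isamp]],
    gene = dat[[igene]],
    allelic_fraction = af,
    classification = if (is.na(iclass)) rep(NA_character_, nrow(dat))
                     else dat[[iclass]]
  )
}

#' Write a variant table back to tab-delimited form
#' @param variants A `DataFrame` as returned by [readVariantFile()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
writeVariantFile <- function(variants, path) {
  df <- as.data.frame(variants)
  df$allelic_fraction <- .fmtNum(df$allelic_fraction)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a labelled numeric matrix (expression or activity-area table)
#'
#' The first column holds row labels and the header holds column labels.
#' The delimiter (tab or comma) is sniffed from the header line. Missing
#' cells (`NA`, empty) are preserved as missing, never imputed to zero.
#'
#' @param path Path to a TSV/CSV matrix file.
#' @return A numeric matrix with dimnames.
#' @export
readMatrixFile <- function(path) {
  if (!file.exists(path)) .fileError(path, "file not found")
  header <- readLines(path, n = 1L)
  sep <- if (lengths(gregexpr("\t", header, fixed = TRUE)) >=
             lengths(gregexpr(",", header, fixed = TRUE))) "\t" else ","
  nf <- utils::count.fields(path, sep = sep, quote = "\"", comment.char = "")
  if (length(unique(nf)) > 1L) {
    bad <- which(nf != nf[1L])[1L]
    .fileError(path, sprintf("ragged row: line %d has %d fields, expected %d",
                             bad, nf[bad], nf[1L]))
  }
  dat <- utils::read.table(path, sep = sep, header = TRUE, quote = "\"",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           comment.char = "")
  labels <- as.character(dat[[1L]])
  if (anyDuplicated(labels)) .fileError(path, sprintf(
    "duplicate row label '%s'", labels[duplicated(labels)][1L]))
  m <- as.matrix(dat[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- labels
  m
}

#' Write a labelled numeric matrix
#' @param m Numeric matrix with dimnames.
#' @param path Output file path.
#' @param sep Field separator (tab by default).
#' @return Invisibly, `path`.
#' @export
writeMatrixFile <- function(m, path, sep = "\t") {
  fm <- matrix(.fmtNum(m), nrow(m), ncol(m), dimnames = dimnames(m))
  df <- data.frame(id = rownames(m), fm, check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then member symbols, tab-delimited.
#' Duplicate genes within a set are removed (first occurrence kept); sets
#' with fewer than two unique genes are dropped with a warning.
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors.
#' @export
readGeneSets <- function(path) {
  if (!file.exists(path)) .fileError(path, "file not found")
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 2L)
  if (length(short)) .fileError(path, sprintf(
    "GMT format error at line %d: need at least name and description", short[1L]))
  nms <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(nms)) .fileError(path, sprintf(
    "duplicate gene-set name '%s'", nms[duplicated(nms)][1L]))
  sets <- lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  names(sets) <- nms
  small <- lengths(sets) < 2L
  if (any(small)) {
    warning(sprintf("dropping %d gene set(s) with < 2 unique genes: %s",
                    sum(small), paste(nms[small], collapse = ", ")))
    sets <- sets[!small]
  }
  sets
}

#' Write gene sets in GMT format
#' @param sets Named list of character vectors.
#' @param path Output file path.
#' @param descriptions Optional character vector of set descriptions.
#' @return Invisibly, `path`.
#' @export
writeGeneSets <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a plain-text gene list (one symbol per line, '#' comments)
#' @param path Path to the list file.
#' @return Character vector of unique symbols, in file order.
#' @export
readGeneList <- function(path) {
  if (!file.exists(path)) .fileError(path, "file not found")
  lines <- sub("#.*$", "", readLines(path))
  lines <- trimws(lines)
  unique(lines[nzchar(lines)])
}

#' Read a sample-annotation table (sample_id, tissue)
#'
#' Tab-delimited with a header; columns are matched by name (`sample_id`/
#' `sample` and `tissue`/`site`/`tissue_of_origin`) and fall back to the
#' first two columns.
#'
#' @param path Path to the annotation TSV.
#' @return A [S4Vectors::DataFrame] with columns `sample_id` and `tissue`.
#' @export
readAnnotations <- function(path) {
  if (!file.exists(path)) .fileError(path, "file not found")
  dat <- utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(dat) < 2L) .fileError(path, "annotation table needs >= 2 columns")
  isamp <- .matchColumn(colnames(dat), c("sample_id", "sample", "cell_line"))
  itis <- .matchColumn(colnames(dat), c("tissue", "site", "tissue_of_origin"))
  if (is.na(isamp)) isamp <- 1L
  if (is.na(itis)) itis <- 2L
  DataFrame(sample_id = dat[[isamp]], tissue = dat[[itis]])
}

#' Construct a LoadCohort from in-memory components
#'
#' @param segments `GRanges` of copy-number segments (see [readSegmentFile()]).
#' @param variants Variant table (`DataFrame` or data.frame) with columns
#'   `sample_id`, `gene`, `allelic_fraction` and optionally `classification`.
#' @param annotations Sample annotation table with columns `sample_id`,
#'   `tissue`.
#' @param response Activity-area matrix, cell lines x drugs.
#' @param expression Optional expression matrix, genes x cell lines.
#' @param geneSets Optional named list of gene sets.
#' @param driverGenes Optional character vector of driver symbols; defaults
#'   to the packaged curated consensus list (see [defaultDriverGenes()]).
#' @return A validated [LoadCohort-class].
#' @export
LoadCohort <- function(segments, variants, annotations, response,
                       expression = NULL, geneSets = list(),
                       driverGenes = defaultDriverGenes()) {
  variants <- DataFrame(variants)
  if (!"classification" %in% colnames(variants) && nrow(variants))
    variants$classification <- NA_character_
  if (nrow(variants) == 0L)
    variants <- DataFrame(sample_id = character(), gene = character(),
                          allelic_fraction = numeric(),
                          classification = character())
  annotations <- DataFrame(annotations)
  if (is.null(expression))
    expression <- matrix(numeric(0), 0, 0,
                         dimnames = list(character(), character()))
  new("LoadCohort", segments = segments, variants = variants,
      annotations = annotations, response = response, expression = expression,
      geneSets = geneSets, driverGenes = as.character(driverGenes))
}

#' Read a cohort from its component files
#'
#' @param seg,variants,annotations,response File paths for the SEG file,
#'   variant table, annotation table and activity-area matrix.
#' @param expression,geneSets,drivers Optional paths for the expression
#'   matrix, GMT gene sets and driver exclusion list.
#' @param afMode Allelic-fraction convention for the variant file
#'   (see [readVariantFile()]).
#' @return A [LoadCohort-class].
#' @export
readCohort <- function(seg, variants, annotations, response,
                       expression = NULL, geneSets = NULL, drivers = NULL,
                       afMode = "proportion") {
  LoadCohort(
    segments = readSegmentFile(seg),
    variants = readVariantFile(variants, afMode = afMode),
    annotations = readAnnotations(annotations),
    response = readMatrixFile(response),
    expression = if (is.null(expression)) NULL else readMatrixFile(expression),
    geneSets = if (is.null(geneSets)) list() else readGeneSets(geneSets),
    driverGenes = if (is.null(drivers)) defaultDriverGenes()
                  else readGeneList(drivers)
  )
}

#' Packaged curated driver-gene exclusion list
#'
#' A curated consensus list of well-known oncogenes and tumour suppressors
#' shipped with the package (`inst/extdata/driver_genes.txt`). Variants in
#' these genes are excluded from the mutation load so that the count
#' reflects passenger, not driver, alterations. The file is plain text and
#' user-replaceable; pass any list to [computeLoads()] via the cohort's
#' `driverGenes`.
#'
#' @return Character vector of gene symbols.
#' @export
defaultDriverGenes <- function() {
  readGeneList(system.file("extdata", "driver_genes.txt",
                           package = "loadscreen", mustWork = TRUE))
}

#' Packaged growth-factor gene panel
#'
#' A curated, editable panel of growth-factor receptors, their ligands and
#' closely related genes (`inst/extdata/growth_factor_panel.txt`), assembled
#' from the well-known receptor tyrosine kinase families (EGFR/ERBB, FGFR,
#' PDGFR, IGF, VEGFR, TRK, EPH and relatives). Intended for
#' [genePanelLoadScreen()]; substitute any panel file via [readGeneList()].
#'
#' @return Character vector of gene symbols.
#' @export
defaultGrowthFactorPanel <- function() {
  readGeneList(system.file("extdata", "growth_factor_panel.txt",
                           package = "loadscreen", mustWork = TRUE))
}
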