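#' FPKM from fragment counts and gene lengths
#'
#' `FPKM(g, s) = count(g, s) / ((length(g)/1e3) * (total(s)/1e6))`, i.e.
#' fragments per kilobase of transcript per million mapped fragments.
#' The returned matrix carries a `detection_floor` attribute (default
#' 1e-3 FPKM), the minimum detectable expression value; values below it
#' are kept numerically but treated as not detected by [is_detected()].
#'
#' @param counts non-negative integer matrix, genes x samples, with row
#'   and column names.
#' @param lengths named vector of transcript lengths in base pairs,
#'   covering every gene in `counts`.
#' @param detection_floor FPKM value below which a gene counts as
#'   unexpressed.
#' @return numeric matrix of FPKM values with attribute
#'   `detection_floor`.
#' @export
compute_fpkm <- function(counts, lengths, detection_floor = DETECTION_FLOOR) {
  if (any(counts < 0)) stopf("counts must be non-negative")
  missing <- setdiff(rownames(counts), names(lengths))
  if (length(missing)) {
    stopf("no length for gene(s): %s", paste(head(missing, 5), collapse = ", "))
  }
  len <- lengths[rownames(counts)]
  if (any(len <= 0)) stopf("gene lengths must be positive")
  totals <- colSums(counts)
  if (nrow(counts) > 0 && any(totals == 0)) {
    stopf("sample(s) with zero total count: %s",
          paste(colnames(counts)[totals == 0], collapse = ", "))
  }
  fpkm <- sweep(counts / (len / 1e3), 2, totals / 1e6, "/")
  if (nrow(counts) == 0) fpkm <- matrix(numeric(0), 0, ncol(counts),
                                        dimnames = dimnames(counts))
  structure(fpkm, detection_floor = detection_floor)
}

#' @rdname compute_fpkm
#' @param x an FPKM matrix (or vector).
#' @param floor detection floor; defaults to the matrix's
#'   `detection_floor` attribute.
#' @return `is_detected()` returns a logical matrix: `x >= floor`.
#' @export
is_detected <- function(x, floor = attr(x, "detection_floor") %||% DETECTION_FLOOR) {
  x >= floor
}

#' Median-of-ratios (DESeq-style) size factors
#'
#' For sample `j`, `s_j` is the median over genes (restricted to genes
#' with a positive count in every sample) of `count(g, j)` divided by the
#' gene's geometric mean across samples.  Dividing each sample by its
#' factor equalizes the mass composition between samples.
#'
#' @param counts non-negative count matrix, genes x samples.
#' @return named positive numeric vector of per-sample size factors.
#' @export
size_factors <- function(counts) {
  if (any(counts < 0)) stopf("counts must be non-negative")
  logc <- log(counts)
  usable <- rowSums(is.finite(logc)) == ncol(counts)  # positive in all samples
  if (!any(usable)) {
    stopf(paste("no gene has a positive count in every sample;",
                "pseudo-reference fallback is disabled"))
  }
  logmean <- rowMeans(logc[usable, , drop = FALSE])
  sf <- apply(logc[usable, , drop = FALSE], 2,
              function(col) exp(median(col - logmean)))
  setNames(sf, colnames(counts))
}

#' Divide an expression matrix by per-sample size factors
#'
#' @param x genes x samples matrix (counts or FPKM).
#' @param sf size factors from [size_factors()], aligned to `colnames(x)`.
#' @return matrix of the same shape, attributes preserved.
#' @export
apply_size_factors <- function(x, sf) {
  if (!is.null(names(sf))) sf <- sf[colnames(x)]
  if (length(sf) != ncol(x) || anyNA(sf)) {
    stopf("size factors do not match the matrix columns")
  }
  out <- sweep(x, 2, sf, "/")
  attributes(out)$detection_floor <- attr(x, "detection_floor")
  out
}

#' Average replicate samples into one profile per condition
#'
#' Collapses a genes x samples matrix to genes x conditions, where a
#' condition is a (species, limb, stage) combination, by the arithmetic
#' mean of FPKM across replicates.  Downstream correlation and
#' clustering operate on these condition profiles.
#'
#' @param x genes x samples expression matrix.
#' @param info sample metadata with columns `sample`, `species`, `limb`,
#'   `stage` covering `colnames(x)`.
#' @return genes x conditions matrix; columns named
#'   `species_limb_stage`, with a `conditions` attribute holding the
#'   per-column metadata.
#' @export
average_replicates <- function(x, info) {
  info <- info[match(colnames(x), info$sample), , drop = FALSE]
  if (anyNA(info$sample)) stopf("sample metadata does not cover all columns")
  key <- paste(info$species, info$limb, info$stage, sep = "_")
  ukey <- unique(key)
  out <- vapply(ukey, function(k) {
    rowMeans(x[, key == k, drop = FALSE])
  }, numeric(nrow(x)))
  if (nrow(x) == 1L) out <- matrix(out, 1L, length(ukey))
  dimnames(out) <- list(rownames(x), ukey)
  meta <- info[match(ukey, key), c("species", "limb", "stage"), drop = FALSE]
  rownames(meta) <- NULL
  attr(out, "conditions") <- meta
  attr(out, "detection_floor") <- attr(x, "detection_floor")
  out
}

#' Floored log2 transform of FPKM
#'
#' `log2(x + floor)` with the detection floor as pseudocount, so
#' unexpressed genes map to `log2(floor)` instead of `-Inf`.
#'
#' @param x FPKM values.
#' @param floor pseudocount; defaults to the detection floor.
#' @return log2-transformed values.
#' @export
log2_fpkm <- function(x, floor = attr(x, "detection_floor") %||% DETECTION_FLOOR) {
  log2(x + floor)
}
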