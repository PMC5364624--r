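#' Per-gene fore/hind expression divergence within a species
#'
#' `score(g) = |log2((FPKM_fore(g) + eps) / (FPKM_hind(g) + eps))|`; the
#' divergent set is every gene at or above the 75th percentile of the
#' scores ("75% percentile and above", ties included).  Symmetric in the
#' two limbs.
#'
#' @param fore,hind named FPKM vectors over a common gene set (one
#'   species, one stage).
#' @param eps pseudocount, defaulting to the detection floor.
#' @param percentile quantile defining the divergent set.
#' @return object of class `divergence_scores`: `scores` (named,
#'   >= 0), `threshold`, `divergent` (character), `context`.
#' @export
score_within <- function(fore, hind, eps = DETECTION_FLOOR, percentile = 0.75) {
  genes <- intersect(names(fore), names(hind))
  if (!length(genes)) stopf("empty common gene set")
  s <- abs(log2((fore[genes] + eps) / (hind[genes] + eps)))
  divergence_scores(s, percentile, context = "within")
}

#' Per-gene expression divergence among species (one limb, one stage)
#'
#' `score(g)` is the standard deviation across species of
#' `log2(FPKM + eps)` over the ortholog core set; the divergent set uses
#' the same 75th-percentile rule as [score_within()].
#'
#' @param expr genes x species matrix of FPKM over the ortholog core
#'   set (rows indexed by a common gene key).
#' @inheritParams score_within
#' @return a `divergence_scores` object.
#' @export
score_among <- function(expr, eps = DETECTION_FLOOR, percentile = 0.75) {
  if (ncol(expr) < 2L) stopf("need >= 2 species")
  if (!nrow(expr)) stopf("empty gene set")
  if (anyNA(expr)) {
    bad <- rownames(expr)[apply(is.na(expr), 1, any)]
    stopf("gene(s) missing in a species: %s", paste(head(bad, 5), collapse = ", "))
  }
  lx <- log2(expr + eps)
  s <- apply(lx, 1, sd)
  divergence_scores(s, percentile, context = "among")
}

divergence_scores <- function(scores, percentile, context) {
  thr <- quantile(scores, percentile, names = FALSE)
  structure(list(scores = scores, threshold = thr,
                 divergent = names(scores)[scores >= thr],
                 percentile = percentile, context = context),
            class = "divergence_scores")
}

#' Overlap of divergent gene sets
#'
#' Intersects named gene sets, reports pairwise and all-set overlap as
#' a percentage of a stated gene universe, and annotates the overall
#' intersection with a user-supplied list of known limb-development
#' genes (replacing web-based enrichment).
#'
#' @param sets named list (>= 2) of character gene sets.
#' @param universe the gene universe the percentages refer to (e.g. the
#'   ortholog core set).
#' @param annotation optional character vector of annotated gene
#'   symbols; see [limb_gene_list()].
#' @return object of class `overlap_report`: `intersection`,
#'   `intersection_percent`, `pairwise_percent` (matrix), `sizes`,
#'   `annotated`, `universe_size`.
#' @export
overlap_report <- function(sets, universe, annotation = NULL) {
  if (length(sets) < 2L) stopf("need >= 2 gene sets")
  if (!length(universe)) stopf("empty gene universe")
  nm <- names(sets)
  if (is.null(nm) || any(nm == "")) stopf("sets must be named")
  inter <- Reduce(intersect, sets)
  U <- length(unique(universe))
  pw <- matrix(NA_real_, length(sets), length(sets), dimnames = list(nm, nm))
  for (i in seq_along(sets)) {
    for (j in seq_along(sets)) {
      pw[i, j] <- length(intersect(sets[[i]], sets[[j]])) / U * 100
    }
  }
  annotated <- if (is.null(annotation)) character(0) else intersect(inter, annotation)
  structure(list(intersection = inter,
                 intersection_percent = length(inter) / U * 100,
                 pairwise_percent = pw,
                 sizes = lengths(sets),
                 annotated = annotated,
                 universe_size = U),
            class = "overlap_report")
}

#' Packaged list of known limb-development genes
#'
#' A plain-text, user-editable list of gene symbols with established
#' roles in limb development (fore/hind identity factors, Hox genes,
#' limb signaling factors), used to annotate divergent-set
#' intersections.
#'
#' @param path optional path to an alternative one-symbol-per-line file.
#' @return character vector of gene symbols.
#' @export
limb_gene_list <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "limb_genes.txt", package = "limbphylo")
  }
  x <- readLines(path)
  x <- trimws(x)
  x[nzchar(x) & !startsWith(x, "#")]
}
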