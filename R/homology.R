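#' Build the cross-species ortholog core set
#'
#' Starting from a designated reference species, a reference gene joins
#' the core set iff its hits at `E <= e_max` identify exactly one
#' subject gene in every other species.  Reference genes matching more
#' than one gene in any species are filtered out (conservative
#' multi-match rule; ties at equal E-value count as multiple matches),
#' as are genes missing from at least one species.  Groups that would
#' reuse a subject gene already claimed by another group are dropped so
#' that no gene belongs to two groups.
#'
#' @param hits homology hit data frame (`qseqid`, `qspecies`, `sseqid`,
#'   `sspecies`, `evalue`).
#' @param species character vector of species to cover; defaults to all
#'   species present in `hits`.
#' @param reference the reference species whose transcriptome anchors
#'   the groups.
#' @param e_max E-value threshold for an acceptable ortholog hit.
#' @return data frame of class `ortholog_core_set` with one column per
#'   species (reference first) and one row per ortholog group.
#' @export
build_core_orthologs <- function(hits, species = NULL, reference,
                                 e_max = 1e-20) {
  if (e_max <= 0) stopf("e_max must be positive")
  if (is.null(species)) {
    species <- sort(unique(c(hits$qspecies, hits$sspecies)))
  }
  if (!reference %in% species) {
    stopf("reference species '%s' not among species", reference)
  }
  others <- setdiff(species, reference)
  empty <- function() {
    out <- as.data.frame(setNames(rep(list(character(0)), length(species)),
                                  c(reference, others)))
    class(out) <- c("ortholog_core_set", class(out))
    out
  }
  h <- hits[hits$qspecies == reference & hits$sspecies %in% others &
              hits$evalue <= e_max, , drop = FALSE]
  if (!nrow(h)) {
    if (!any(hits$qspecies == reference)) {
      stopf("reference species '%s' absent from hit table", reference)
    }
    return(empty())
  }

  # distinct subject genes per (reference gene, species)
  key <- paste(h$qseqid, h$sspecies, sep = "\r")
  subj <- tapply(h$sseqid, key, function(x) unique(x), simplify = FALSE)
  n_subj <- lengths(subj)
  ref_genes <- sort(unique(h$qseqid))

  multi <- unique(sub("\r.*$", "", names(n_subj)[n_subj > 1L]))
  candidates <- setdiff(ref_genes, multi)

  # species coverage per candidate
  cov <- tapply(h$sspecies[h$qseqid %in% candidates],
                h$qseqid[h$qseqid %in% candidates],
                function(x) length(unique(x)))
  keep <- names(cov)[cov == length(others)]
  incomplete <- setdiff(candidates, keep)
  if (length(incomplete)) {
    warnf("%d reference gene(s) dropped for missing a homologue in >= 1 species (e.g. %s)",
          length(incomplete), paste(head(incomplete, 3), collapse = ", "))
  }
  if (!length(keep)) return(empty())

  groups <- data.frame(ref = sort(keep), stringsAsFactors = FALSE)
  for (sp in others) {
    m <- h[h$sspecies == sp & h$qseqid %in% groups$ref, c("qseqid", "sseqid")]
    groups[[sp]] <- m$sseqid[match(groups$ref, m$qseqid)]
  }
  names(groups)[1L] <- reference

  # enforce disjointness: drop every group sharing a subject gene
  for (sp in others) {
    dup <- groups[[sp]] %in% groups[[sp]][duplicated(groups[[sp]])]
    if (any(dup)) {
      warnf("%d group(s) dropped: subject gene claimed by multiple reference genes in %s",
            sum(dup), sp)
      groups <- groups[!dup, , drop = FALSE]
    }
  }
  rownames(groups) <- NULL
  class(groups) <- c("ortholog_core_set", class(groups))
  groups
}

# Rank every tree node by the number of leaves in its subtree; for a
# ladder (caterpillar) tree this yields the phylostratum ladder
# 1 (species-specific) .. K (root).  Returns, for a focal leaf, the rank
# of the MRCA with every other leaf.
mrca_ranks <- function(tree, focal) {
  leaves <- tree$tip.label
  if (!focal %in% leaves) stopf("focal species '%s' not a tree leaf", focal)
  others <- setdiff(leaves, focal)
  M <- ape::mrca(tree)
  vapply(others, function(sp) {
    node <- M[focal, sp]
    length(clade_tips(tree, node))
  }, numeric(1))
}

#' Assign phylostrata (evolutionary gene ages) for a focal species
#'
#' A gene's phylostratum (ps) is determined by the most distant
#' phylogenetic node, relative to the focal species, that contains a
#' detectable homologue at `E <= e_max`.  Nodes are ranked by the number
#' of leaves in their subtree, so species-specific genes get ps 1
#' (youngest) and genes shared with all K species get ps K (oldest).
#' This ranking is exact for ladder trees such as
#' `(((bat,pig),mouse),opossum)`; on balanced trees distinct nodes of
#' equal size share a rank.
#'
#' @param hits homology hit data frame; both hit directions are used.
#' @param tree species tree (`phylo` or Newick string).
#' @param focal focal species (a tree leaf).
#' @param genes optional character vector: the focal species' gene
#'   universe.  Genes without any homolog hit get ps 1.  Defaults to the
#'   focal genes appearing in `hits`.
#' @param e_max E-value threshold for homologue detection.
#' @return named integer vector of ps per gene, with attributes `focal`
#'   and `orientation` (`"higher ps = older"`).
#' @export
assign_phylostrata <- function(hits, tree, focal, genes = NULL, e_max = 1e-5) {
  if (!inherits(tree, "phylo")) tree <- ape::read.tree(text = tree)
  leaves <- tree$tip.label
  seen <- unique(c(hits$qspecies, hits$sspecies))
  unknown <- setdiff(seen, leaves)
  if (length(unknown)) {
    stopf("species in hit table not on tree: %s", paste(unknown, collapse = ", "))
  }
  ranks <- mrca_ranks(tree, focal)

  fwd <- hits[hits$qspecies == focal & hits$evalue <= e_max, c("qseqid", "sspecies")]
  rev <- hits[hits$sspecies == focal & hits$evalue <= e_max, c("sseqid", "qspecies")]
  names(rev) <- names(fwd)
  reach <- rbind(fwd, rev)
  reach <- reach[reach$sspecies != focal, , drop = FALSE]

  if (is.null(genes)) genes <- sort(unique(reach$qseqid))
  ps <- setNames(rep(1L, length(genes)), genes)
  if (nrow(reach)) {
    reach <- reach[reach$qseqid %in% genes, , drop = FALSE]
    r <- ranks[reach$sspecies]
    best <- tapply(r, reach$qseqid, max)
    ps[names(best)] <- as.integer(best)
  }
  attr(ps, "focal") <- focal
  attr(ps, "orientation") <- "higher ps = older"
  ps
}

#' Validate homologue calls by clustering pairwise homolog counts
#'
#' Computes the symmetric matrix `N[i, j]` = number of genes of species
#' `i` with at least one homologue in species `j` at `E <= e_max`,
#' clusters species by average linkage on the distance `max(N) - N`, and
#' flags whether the resulting dendrogram has Robinson-Foulds distance 0
#' to the given species tree (i.e. exactly mirrors the phylogeny).
#'
#' @inheritParams assign_phylostrata
#' @return list of class `homolog_clustering`: `counts` (matrix `N`),
#'   `dendrogram` (`hclust`), `rf` (Robinson-Foulds distance),
#'   `matches_tree` (logical), `tie` (logical: all off-diagonal counts
#'   equal).
#' @export
homolog_count_clustering <- function(hits, tree, e_max = 1e-5) {
  if (!inherits(tree, "phylo")) tree <- ape::read.tree(text = tree)
  species <- tree$tip.label
  if (length(species) < 3L) {
    stopf("topology comparison needs >= 3 species")
  }
  unknown <- setdiff(unique(c(hits$qspecies, hits$sspecies)), species)
  if (length(unknown)) {
    stopf("species in hit table not on tree: %s", paste(unknown, collapse = ", "))
  }
  h <- hits[hits$evalue <= e_max, , drop = FALSE]
  N <- matrix(0, length(species), length(species),
              dimnames = list(species, species))
  for (i in species) {
    for (j in species) {
      if (i == j) next
      gi <- unique(c(h$qseqid[h$qspecies == i & h$sspecies == j],
                     h$sseqid[h$sspecies == i & h$qspecies == j]))
      N[i, j] <- length(gi)
    }
  }
  Nsym <- (N + t(N)) / 2
  off <- Nsym[upper.tri(Nsym)]
  tie <- length(unique(off)) == 1L
  D <- max(Nsym) - Nsym
  diag(D) <- 0
  hc <- hclust(as.dist(D), method = "average")
  phy <- ape::as.phylo(hc)
  rf <- ape::dist.topo(ape::unroot(phy), ape::unroot(tree))[1L]
  matches <- !tie && rf == 0
  if (tie) {
    warnf("all pairwise homolog counts are equal; dendrogram topology is a tie")
  }
  structure(list(counts = N, dendrogram = hc, rf = rf,
                 matches_tree = matches, tie = tie),
            class = "homolog_clustering")
}
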