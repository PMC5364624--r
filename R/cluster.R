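# Multiscale bootstrap significance for hierarchical clustering of
# expression profiles (pvclust-style, reimplemented).

# Average-linkage dendrogram on 1 - Spearman distance.  Undefined
# correlations (constant profiles, possible in bootstrap resamples) are
# treated as 0.
profile_hclust <- function(profiles) {
  r <- suppressWarnings(cor(profiles, method = "spearman"))
  r[is.na(r)] <- 0
  diag(r) <- 1
  hclust(as.dist(1 - r), method = "average")
}

# The leaf-label set of every internal node of an hclust, as a sorted
# "\r"-joined key.  Order follows the merge order.
cluster_keys <- function(hc) {
  labs <- hc$labels
  n <- length(labs)
  sets <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    members <- character(0)
    for (k in 1:2) {
      x <- hc$merge[i, k]
      members <- c(members, if (x < 0) labs[-x] else sets[[x]])
    }
    sets[[i]] <- members
  }
  vapply(sets, function(s) paste(sort(s), collapse = "\r"), character(1))
}

#' Bootstrap-significant hierarchical clustering of expression profiles
#'
#' Clusters profiles by average linkage on `1 - Spearman` distance and
#' attaches to every internal node a bootstrap probability (BP) and an
#' approximately unbiased p-value (AU) estimated by multiscale bootstrap
#' resampling of genes: for each scale `s`, `n_boot` resamples of
#' `round(s * n)` genes are drawn with replacement and the proportion of
#' resampled dendrograms containing the node is recorded.  AU is then
#' obtained from the weighted least-squares fit of
#' `qnorm(1 - BP_s)` against `(sqrt(r), 1/sqrt(r))` (with `r` the
#' realized resample-size ratio): `AU = 1 - pnorm(v - c)` for fitted
#' coefficients `(v, c)`.  Nodes whose BP is 0 or 1 at every scale have
#' a degenerate fit; their AU is set to that limit and flagged.
#'
#' @param profiles numeric matrix, genes x profiles (>= 3 profiles).
#' @param n_boot bootstrap resamples per scale.
#' @param scales resample-size multipliers, spanning values below and
#'   above 1 (pvclust-style default `seq(0.5, 1.4, 0.1)`).
#' @param seed optional RNG seed.
#' @param au_cutoff significance threshold on AU.
#' @return object of class `cluster_significance`: `hclust`, `edges`
#'   (data frame with node members, BP at scale 1, AU, `significant`,
#'   `degenerate`), `bp` (node x scale matrix), `scales`.
#' @export
significant_clustering <- function(profiles, n_boot = 1000,
                                   scales = seq(0.5, 1.4, 0.1),
                                   seed = NULL, au_cutoff = 0.95) {
  p <- ncol(profiles)
  if (p < 2L) stopf("need >= 2 profiles")
  if (p == 2L) {
    # single trivial join: no testable internal node, no p-values
    hc <- profile_hclust(profiles)
    edges <- data.frame(node = integer(0), members = character(0),
                        bp = numeric(0), au = numeric(0),
                        significant = logical(0), degenerate = logical(0))
    return(structure(list(hclust = hc, edges = edges,
                          bp = matrix(numeric(0), 0, length(scales)),
                          scales = scales, r = rep(1, length(scales)),
                          au_cutoff = au_cutoff),
                     class = "cluster_significance"))
  }
  if (!any(scales < 1) || !any(scales > 1)) {
    stopf("scales must span values below and above 1")
  }
  n <- nrow(profiles)
  hc <- profile_hclust(profiles)
  keys <- cluster_keys(hc)

  with_seed(seed, {
    bp <- matrix(0, length(keys), length(scales),
                 dimnames = list(NULL, as.character(scales)))
    r_real <- numeric(length(scales))
    for (si in seq_along(scales)) {
      m <- max(3L, round(scales[si] * n))
      r_real[si] <- m / n
      hitcount <- setNames(numeric(length(keys)), keys)
      for (b in seq_len(n_boot)) {
        idx <- sample.int(n, m, replace = TRUE)
        bkeys <- cluster_keys(profile_hclust(profiles[idx, , drop = FALSE]))
        present <- unique(bkeys)
        hit <- present[present %in% keys]
        hitcount[hit] <- hitcount[hit] + 1
      }
      bp[, si] <- hitcount / n_boot
    }

    fit <- t(vapply(seq_along(keys), function(i) {
      au_from_bp(bp[i, ], r_real, n_boot)
    }, numeric(2)))
    au <- fit[, 1L]
    degen <- as.logical(fit[, 2L])

    members <- vapply(strsplit(keys, "\r", fixed = TRUE),
                      paste, character(1), collapse = ",")
    edges <- data.frame(
      node = seq_along(keys), members = members,
      bp = bp[, which.min(abs(r_real - 1))], au = au,
      significant = au >= au_cutoff, degenerate = degen,
      stringsAsFactors = FALSE)
    structure(list(hclust = hc, edges = edges, bp = bp, scales = scales,
                   r = r_real, au_cutoff = au_cutoff),
              class = "cluster_significance")
  })
}

# WLS fit of the multiscale BP curve -> (AU, degenerate flag).
au_from_bp <- function(bp_s, r, n_boot) {
  use <- bp_s > 0 & bp_s < 1
  if (sum(use) < 2L) {
    # degenerate: all resamples agree (or disagree) at every usable scale
    au <- if (mean(bp_s) >= 0.5) 1 else 0
    return(c(au, 1))
  }
  z <- qnorm(1 - bp_s[use])
  rr <- r[use]
  X <- cbind(sqrt(rr), 1 / sqrt(rr))
  w <- n_boot * dnorm(z)^2 / (bp_s[use] * (1 - bp_s[use]))
  fit <- tryCatch(unname(stats::lm.wfit(X, z, w)$coefficients),
                  error = function(e) c(NA_real_, NA_real_))
  if (anyNA(fit)) {
    return(c(bp_s[which.min(abs(r - 1))], 1))
  }
  c(1 - pnorm(fit[1L] - fit[2L]), 0)
}

#' Export an annotated dendrogram as Newick
#'
#' Node labels carry `AU|BP` (rounded to 2 digits) for interoperability
#' with tree viewers.
#'
#' @param cs a `cluster_significance` object.
#' @return Newick string.
#' @export
cluster_newick <- function(cs) {
  phy <- ape::as.phylo(cs$hclust)
  n <- length(cs$hclust$labels)
  keys <- cluster_keys(cs$hclust)
  lab <- sprintf("%.2f|%.2f", cs$edges$au, cs$edges$bp)
  # match each ape internal node to its merge by leaf-set key
  node_lab <- character(phy$Nnode)
  for (j in seq_len(phy$Nnode)) {
    tips <- clade_tips(phy, n + j)
    key <- paste(sort(tips), collapse = "\r")
    hit <- match(key, keys)
    node_lab[j] <- if (is.na(hit)) "" else lab[hit]
  }
  phy$node.label <- node_lab
  ape::write.tree(phy)
}
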