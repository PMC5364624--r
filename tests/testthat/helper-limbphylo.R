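# Shared fixtures and independent oracles for the test suite.

DEFAULT_TREE <- "(((bat,pig),mouse),opossum);"

# Scaled-down generator configuration for fast tests.
small_cfg <- function(...) {
  args <- list(...)
  defaults <- list(n_core_orthologs = 120, n_specific_per_species = 30,
                   n_clade_specific = 15, limb_effect_genes = 10,
                   limb_effect_size = 6, noise_sd = 0.25, n_replicates = 2,
                   seq_depth = 2e5, seed = 1L)
  do.call(sim_config, utils::modifyList(defaults, args))
}

# Replicate-averaged genes x stages matrix for one (species, limb).
stage_expr <- function(ds, sp, limb) {
  prof <- average_replicates(ds$fpkm[[sp]], ds$samples)
  cols <- sprintf("%s_%s_%s", sp, limb, c("ridge", "bud", "paddle"))
  expr <- prof[, cols, drop = FALSE]
  colnames(expr) <- c("ridge", "bud", "paddle")
  expr
}

# Core-ortholog genes x species matrix at one (limb, stage).
core_profiles <- function(ds, core, limb, stage) {
  pm <- sapply(names(core), function(sp) {
    prof <- average_replicates(ds$fpkm[[sp]], ds$samples)
    prof[core[[sp]], sprintf("%s_%s_%s", sp, limb, stage)]
  })
  rownames(pm) <- core[[1L]]
  pm
}

# Independent Spearman oracle: rank (average ties), then the Pearson
# product-moment formula written out.
spearman_bf <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Exact bootstrap probabilities for an n-gene profile matrix by
# enumerating every gene multiset of size n with its multinomial weight.
enumerate_bp <- function(profiles) {
  n <- nrow(profiles)
  keys <- limbphylo:::cluster_keys(limbphylo:::profile_hclust(profiles))
  exact <- setNames(numeric(length(keys)), keys)
  grid <- do.call(expand.grid, rep(list(0:n), n))
  grid <- grid[rowSums(grid) == n, , drop = FALSE]
  for (i in seq_len(nrow(grid))) {
    k <- as.integer(grid[i, ])
    w <- factorial(n) / prod(factorial(k)) / n^n
    idx <- rep(seq_len(n), k)
    bk <- unique(limbphylo:::cluster_keys(
      limbphylo:::profile_hclust(profiles[idx, , drop = FALSE])))
    hit <- bk[bk %in% keys]
    exact[hit] <- exact[hit] + w
  }
  exact
}

# Hand-written 4-species homology fixture on (((bat,pig),mouse),opossum).
# bat gene -> species reached (at E <= 1e-5):
#   b1: pig, mouse, opossum  (ps 4)
#   b2: pig                  (ps 2)
#   b3: mouse                (ps 3)
#   b4: none                 (ps 1)
#   b5: opossum              (ps 4)
#   b6: pig, mouse           (ps 3)
toy_hits <- function() {
  rec <- function(q, qs, s, ss, e = 1e-30) {
    data.frame(qseqid = q, qspecies = qs, sseqid = s, sspecies = ss,
               evalue = e, stringsAsFactors = FALSE)
  }
  rbind(
    rec("b1", "bat", "p1", "pig"), rec("b1", "bat", "m1", "mouse"),
    rec("b1", "bat", "o1", "opossum"),
    rec("b2", "bat", "p2", "pig"),
    rec("b3", "bat", "m3", "mouse"),
    rec("b5", "bat", "o5", "opossum"),
    rec("b6", "bat", "p6", "pig"), rec("b6", "bat", "m6", "mouse")
  )
}
toy_ps_expected <- c(b1 = 4L, b2 = 2L, b3 = 3L, b4 = 1L, b5 = 4L, b6 = 3L)
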