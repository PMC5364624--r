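#' Configuration for the synthetic limb-development dataset generator
#'
#' Describes a multi-species, two-limb (fore/hind), three-stage
#' (ridge/bud/paddle) bulk expression experiment with planted structure:
#' a shared ortholog core, clade-restricted and species-specific genes
#' (phylostratum classes), stage-dependent cross-species divergence,
#' fore/hind-divergent genes, and a configurable transcriptome-age trend.
#'
#' Defaults emulate the four-species study design the package targets:
#' tree `(((bat,pig),mouse),opossum)`, a 6,583-gene ortholog core, and the
#' reported species-specific gene counts (3,828 bat / 10,841 pig /
#' 21,693 mouse / 14,789 opossum).  Tests and examples scale these down.
#'
#' @param species_tree rooted Newick string or `ape::phylo` with named,
#'   unique leaves (>= 2).
#' @param n_core_orthologs number of ortholog groups present in every
#'   species (phylostratum K genes).
#' @param n_specific_per_species named non-negative integer vector of
#'   species-specific (phylostratum 1) gene counts, one per leaf; a single
#'   unnamed value is recycled.  `NULL` uses the built-in counts for the
#'   default four species, otherwise 200 per species.
#' @param n_clade_specific genes restricted to each internal clade below
#'   the root (phylostrata 2..K-1); a single value is recycled over
#'   clades, or a vector named by clade key (sorted leaf names joined by
#'   `"+"`).
#' @param stage_divergence_sd named non-negative vector, one value per
#'   stage in `c("ridge","bud","paddle")`: the per-species log2 deviation
#'   s.d. from the ancestral profile at that stage.  The default increases
#'   ridge -> bud -> paddle, planting progressively diverging stages.
#' @param limb_effect_genes number of core ortholog genes planted as
#'   fore/hind divergent (in every species).
#' @param limb_effect_size log2 fore-minus-hind difference given to
#'   planted genes (sign randomized per gene).
#' @param tai_shape transcriptome-age trend planted in the data: one of
#'   `"hourglass"` (oldest transcriptome at the bud stage),
#'   `"reverse_hourglass"`, `"monotone_decreasing"` or `"flat"`.
#' @param tai_effect_size log2 boost applied to the oldest
#'   (all-species) genes at the stages implied by `tai_shape`.
#' @param noise_sd per-replicate log2 measurement noise s.d.
#' @param n_replicates replicates per (species, limb, stage) condition.
#' @param seq_depth total fragments per sample for the Poisson count
#'   model.
#' @param seed integer seed; the whole dataset is a deterministic
#'   function of the configuration.
#' @param base_log2_mean,base_log2_sd distribution of per-gene baseline
#'   log2 expression.
#' @param condition_sd s.d. of the shared (ancestral) per-stage deviation
#'   of each gene's profile; shared between limbs so that, with zero
#'   divergence and noise, only planted genes differ between fore and
#'   hind.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(species_tree = "(((bat,pig),mouse),opossum);",
                       n_core_orthologs = 6583,
                       n_specific_per_species = NULL,
                       n_clade_specific = 500,
                       stage_divergence_sd = c(ridge = 0.4, bud = 0.8, paddle = 1.2),
                       limb_effect_genes = 50,
                       limb_effect_size = 4,
                       tai_shape = c("flat", "hourglass", "reverse_hourglass",
                                     "monotone_decreasing"),
                       tai_effect_size = 0,
                       noise_sd = 0.25,
                       n_replicates = 2,
                       seq_depth = 2e7,
                       seed = 1L,
                       base_log2_mean = 3,
                       base_log2_sd = 2,
                       condition_sd = 0.5) {
  tree <- if (inherits(species_tree, "phylo")) species_tree
          else ape::read.tree(text = species_tree)
  if (is.null(tree)) stopf("species_tree could not be parsed as Newick")
  leaves <- tree$tip.label
  if (length(leaves) < 2L) stopf("species tree must have >= 2 leaves")
  if (anyDuplicated(leaves)) stopf("species tree leaf names must be unique")

  tai_shape <- match.arg(tai_shape)

  if (is.null(n_specific_per_species)) {
    study <- c(bat = 3828, pig = 10841, mouse = 21693, opossum = 14789)
    n_specific_per_species <- if (setequal(leaves, names(study))) {
      study[leaves]
    } else {
      setNames(rep(200L, length(leaves)), leaves)
    }
  }
  if (is.null(names(n_specific_per_species))) {
    n_specific_per_species <- setNames(
      rep(as.integer(n_specific_per_species), length.out = length(leaves)), leaves)
  }
  if (!setequal(names(n_specific_per_species), leaves)) {
    stopf("n_specific_per_species must be named by the tree leaves")
  }
  n_specific_per_species <- n_specific_per_species[leaves]

  clades <- internal_clades(tree)
  if (is.null(names(n_clade_specific))) {
    n_clade_specific <- setNames(
      rep(as.integer(n_clade_specific), length.out = length(clades)),
      names(clades))
  }
  n_clade_specific <- n_clade_specific[names(clades)]
  n_clade_specific[is.na(n_clade_specific)] <- 0L
  names(n_clade_specific) <- names(clades)

  if (!setequal(names(stage_divergence_sd), STAGES)) {
    stopf("stage_divergence_sd must be named exactly by stages %s",
          paste(STAGES, collapse = ", "))
  }
  stage_divergence_sd <- stage_divergence_sd[STAGES]
  if (any(stage_divergence_sd < 0) || noise_sd < 0 || tai_effect_size < 0 ||
      condition_sd < 0 || base_log2_sd < 0) {
    stopf("standard deviations and effect sizes must be >= 0")
  }
  if (any(c(n_core_orthologs, n_specific_per_species, n_clade_specific,
            limb_effect_genes) < 0)) {
    stopf("gene counts must be >= 0")
  }
  if (seq_depth <= 0) stopf("seq_depth must be positive")
  if (n_replicates < 1) stopf("n_replicates must be >= 1")
  if (limb_effect_genes > n_core_orthologs) {
    stopf("limb_effect_genes (%d) exceeds n_core_orthologs (%d)",
          limb_effect_genes, n_core_orthologs)
  }

  structure(list(
    tree = tree,
    species = leaves,
    n_core_orthologs = as.integer(n_core_orthologs),
    n_specific_per_species = setNames(as.integer(n_specific_per_species), leaves),
    n_clade_specific = n_clade_specific,
    clades = clades,
    stage_divergence_sd = stage_divergence_sd,
    limb_effect_genes = as.integer(limb_effect_genes),
    limb_effect_size = limb_effect_size,
    tai_shape = tai_shape,
    tai_effect_size = tai_effect_size,
    noise_sd = noise_sd,
    n_replicates = as.integer(n_replicates),
    seq_depth = seq_depth,
    seed = as.integer(seed),
    base_log2_mean = base_log2_mean,
    base_log2_sd = base_log2_sd,
    condition_sd = condition_sd
  ), class = "sim_config")
}

# Internal clades strictly below the root, keyed by sorted leaf names.
internal_clades <- function(tree) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  internal <- setdiff(unique(tree$edge[, 1L]), integer(0))
  internal <- internal[internal != root]
  out <- list()
  for (node in sort(internal)) {
    tips <- clade_tips(tree, node)
    if (length(tips) >= 2L) out[[paste(sort(tips), collapse = "+")]] <- sort(tips)
  }
  out
}

# Leaf labels under a node of an ape tree.
clade_tips <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  kids <- tree$edge[tree$edge[, 1L] == node, 2L]
  unlist(lapply(kids, clade_tips, tree = tree))
}

# Stage weights (ridge, bud, paddle) applied to the oldest genes for each
# planted transcriptome-age trend.
tai_stage_weights <- function(shape) {
  switch(shape,
         flat = c(0, 0, 0),
         hourglass = c(0, 1, 0),
         reverse_hourglass = c(1, 0, 1),
         monotone_decreasing = c(1, 0.5, 0),
         stopf("unknown tai_shape '%s'", shape))
}

#' Generate a synthetic multi-species limb-development dataset
#'
#' Draws a complete dataset from a [sim_config()]: per-species fragment
#' counts, gene lengths, FPKM matrices, sample metadata, a cross-species
#' homology hit table, the species tree, and a truth record of all
#' planted structure.
#'
#' The model: each ancestral gene gets a baseline log2 expression and a
#' shared per-stage deviation; each species' value at a (limb, stage)
#' condition adds an independent normal deviation with s.d.
#' `stage_divergence_sd[stage]`; planted limb genes add +/-
#' `limb_effect_size` between fore and hind; the oldest genes get a
#' stage-profile boost per `tai_shape`.  Replicates add log2 noise with
#' s.d. `noise_sd`; FPKM is `2^log2`; counts are Poisson with mean
#' proportional to FPKM x gene length, scaled to `seq_depth` fragments
#' per sample.  Homology hits (E-value 1e-30) are emitted for every gene
#' pair descending from the same ancestral gene; species-specific genes
#' get none.
#'
#' @param cfg a [sim_config()].
#' @return an object of class `sim_dataset`: a list with elements
#'   `counts`, `fpkm`, `lengths` (per-species lists), `samples` (data
#'   frame), `homology` (data frame), `tree` (`phylo`), and `truth`
#'   (planted ps per gene, planted limb-divergent genes, configuration
#'   echo).
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, generate_dataset_impl(cfg))
}

generate_dataset_impl <- function(cfg) {
  species <- cfg$species
  K <- length(species)

  ## --- gene catalog -------------------------------------------------
  base_ids <- character(0)
  gene_species <- list()   # base id -> species carrying it
  gene_ps <- integer(0)

  if (cfg$n_core_orthologs > 0) {
    ids <- sprintf("core%05d", seq_len(cfg$n_core_orthologs))
    base_ids <- c(base_ids, ids)
    gene_species <- c(gene_species, setNames(rep(list(species), length(ids)), ids))
    gene_ps <- c(gene_ps, setNames(rep(K, length(ids)), ids))
  }
  for (ck in names(cfg$clades)) {
    n <- cfg$n_clade_specific[[ck]]
    if (n > 0) {
      tag <- gsub("[^A-Za-z0-9]+", ".", ck)
      ids <- sprintf("cl.%s.%04d", tag, seq_len(n))
      base_ids <- c(base_ids, ids)
      gene_species <- c(gene_species,
                        setNames(rep(list(cfg$clades[[ck]]), n), ids))
      gene_ps <- c(gene_ps, setNames(rep(length(cfg$clades[[ck]]), n), ids))
    }
  }
  for (sp in species) {
    n <- cfg$n_specific_per_species[[sp]]
    if (n > 0) {
      ids <- sprintf("sp.%s.%05d", sp, seq_len(n))
      base_ids <- c(base_ids, ids)
      gene_species <- c(gene_species, setNames(rep(list(sp), n), ids))
      gene_ps <- c(gene_ps, setNames(rep(1L, n), ids))
    }
  }
  n_genes <- length(base_ids)

  lengths_bp <- if (n_genes) {
    setNames(pmax(200, round(rlnorm(n_genes, log(1800), 0.45))), base_ids)
  } else {
    setNames(numeric(0), character(0))
  }

  ## --- ancestral log2 means -----------------------------------------
  conditions <- expand.grid(stage = STAGES, limb = LIMBS,
                            KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  conditions <- conditions[order(match(conditions$limb, LIMBS),
                                 match(conditions$stage, STAGES)), ]
  cond_key <- paste(conditions$limb, conditions$stage, sep = "_")

  base_mu <- rnorm(n_genes, cfg$base_log2_mean, cfg$base_log2_sd)
  stage_dev <- matrix(rnorm(n_genes * length(STAGES), 0, cfg$condition_sd),
                      nrow = n_genes, ncol = length(STAGES),
                      dimnames = list(base_ids, STAGES))

  ancestral <- matrix(0, n_genes, nrow(conditions),
                      dimnames = list(base_ids, cond_key))
  for (i in seq_len(nrow(conditions))) {
    ancestral[, i] <- base_mu + stage_dev[, conditions$stage[i]]
  }

  ## planted fore/hind divergent genes (core orthologs, all species)
  core_ids <- base_ids[gene_ps == K & startsWith(base_ids, "core")]
  planted <- character(0)
  if (cfg$limb_effect_genes > 0 && length(core_ids)) {
    planted <- sort(sample(core_ids, cfg$limb_effect_genes))
    sign <- sample(c(-1, 1), length(planted), replace = TRUE)
    half <- sign * cfg$limb_effect_size / 2
    for (i in seq_len(nrow(conditions))) {
      shift <- if (conditions$limb[i] == "fore") half else -half
      ancestral[planted, i] <- ancestral[planted, i] + shift
    }
  }

  ## transcriptome-age trend: boost the oldest (all-species) genes
  w <- tai_stage_weights(cfg$tai_shape)
  if (cfg$tai_effect_size > 0 && any(w != 0) && length(core_ids)) {
    old <- base_ids[gene_ps == K]
    for (i in seq_len(nrow(conditions))) {
      ancestral[old, i] <- ancestral[old, i] +
        cfg$tai_effect_size * w[match(conditions$stage[i], STAGES)]
    }
  }

  ## --- per-species expression, replicates, counts -------------------
  rep_grid <- merge(conditions, data.frame(replicate = seq_len(cfg$n_replicates)))
  rep_grid <- rep_grid[order(match(rep_grid$limb, LIMBS),
                             match(rep_grid$stage, STAGES),
                             rep_grid$replicate), ]

  counts <- fpkm <- lengths <- list()
  samples <- list()
  truth_ps <- list()

  for (sp in species) {
    has <- vapply(gene_species, function(s) sp %in% s, logical(1))
    ids <- base_ids[has]
    sp_ids <- if (length(ids)) paste(sp, ids, sep = "_") else character(0)
    nc <- nrow(conditions)

    div <- matrix(0, length(ids), nc, dimnames = list(ids, cond_key))
    for (i in seq_len(nc)) {
      sdv <- cfg$stage_divergence_sd[[conditions$stage[i]]]
      if (sdv > 0 && length(ids)) div[, i] <- rnorm(length(ids), 0, sdv)
    }
    sp_log2 <- ancestral[ids, , drop = FALSE] + div

    sample_ids <- sprintf("%s_%s_%s_r%d", sp, rep_grid$limb, rep_grid$stage,
                          rep_grid$replicate)
    y <- matrix(0, length(ids), length(sample_ids),
                dimnames = list(sp_ids, sample_ids))
    for (j in seq_along(sample_ids)) {
      ck <- paste(rep_grid$limb[j], rep_grid$stage[j], sep = "_")
      eps <- if (cfg$noise_sd > 0 && length(ids)) {
        rnorm(length(ids), 0, cfg$noise_sd)
      } else 0
      y[, j] <- sp_log2[, ck] + eps
    }
    fp <- 2^y
    len <- setNames(lengths_bp[ids], sp_ids)

    cm <- matrix(0L, length(ids), length(sample_ids),
                 dimnames = list(sp_ids, sample_ids))
    if (length(ids)) {
      for (j in seq_along(sample_ids)) {
        mu <- fp[, j] * (len / 1e3)
        mu <- mu / sum(mu) * cfg$seq_depth
        cm[, j] <- rpois(length(mu), mu)
      }
    }

    counts[[sp]] <- cm
    fpkm[[sp]] <- structure(fp, detection_floor = DETECTION_FLOOR)
    lengths[[sp]] <- len
    samples[[sp]] <- data.frame(sample = sample_ids, species = sp,
                                limb = rep_grid$limb, stage = rep_grid$stage,
                                replicate = rep_grid$replicate,
                                stringsAsFactors = FALSE)
    truth_ps[[sp]] <- setNames(as.integer(gene_ps[ids]), sp_ids)
  }

  ## --- homology table ------------------------------------------------
  hom <- list()
  if (K >= 2 && n_genes) {
    for (i in seq_len(K - 1L)) {
      for (j in seq(i + 1L, K)) {
        a <- species[i]; b <- species[j]
        shared <- base_ids[vapply(gene_species,
                                  function(s) all(c(a, b) %in% s), logical(1))]
        if (length(shared)) {
          qa <- paste(a, shared, sep = "_"); qb <- paste(b, shared, sep = "_")
          hom[[length(hom) + 1L]] <- data.frame(
            qseqid = c(qa, qb), qspecies = c(rep(a, length(qa)), rep(b, length(qb))),
            sseqid = c(qb, qa), sspecies = c(rep(b, length(qb)), rep(a, length(qa))),
            evalue = 1e-30, stringsAsFactors = FALSE)
        }
      }
    }
  }
  homology <- if (length(hom)) do.call(rbind, hom) else {
    data.frame(qseqid = character(0), qspecies = character(0),
               sseqid = character(0), sspecies = character(0),
               evalue = numeric(0), stringsAsFactors = FALSE)
  }

  truth <- list(
    ps = truth_ps,
    limb_divergent_base = planted,
    limb_divergent = lapply(setNames(species, species),
                            function(sp) {
                              keep <- planted[vapply(gene_species[planted],
                                                     function(s) sp %in% s, logical(1))]
                              if (length(keep)) paste(sp, keep, sep = "_") else character(0)
                            }),
    stage_divergence_sd = as.list(cfg$stage_divergence_sd),
    tai_shape = cfg$tai_shape,
    tai_effect_size = cfg$tai_effect_size,
    seed = cfg$seed
  )

  structure(list(
    counts = counts, fpkm = fpkm, lengths = lengths,
    samples = do.call(rbind, c(samples, list(make.row.names = FALSE))),
    homology = homology, tree = cfg$tree, truth = truth, config = cfg
  ), class = "sim_dataset")
}

#' Write a synthetic dataset to a directory of plain-text files
#'
#' Emits per-species count/FPKM/length TSVs, a combined sample table, the
#' homology hit TSV, the Newick species tree, a JSON truth record and a
#' JSON manifest listing every file with its row count.  Output is
#' byte-identical for a fixed configuration and seed, and round-trips
#' losslessly through [read_dataset()].
#'
#' @param ds a `sim_dataset` from [generate_dataset()].
#' @param dir output directory (created if needed).
#' @return the manifest, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "sim_dataset"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE)) {
    stopf("cannot create output directory %s", dir)
  }
  files <- list()
  add <- function(name, path, rows) {
    files[[name]] <<- list(file = basename(path), rows = rows)
  }

  tp <- file.path(dir, "tree.nwk")
  ape::write.tree(ds$tree, file = tp)
  add("tree", tp, length(ds$tree$tip.label))

  sp_path <- file.path(dir, "samples.tsv")
  write_sample_info_tsv(ds$samples, sp_path)
  add("samples", sp_path, nrow(ds$samples))

  for (sp in names(ds$counts)) {
    p <- file.path(dir, sprintf("counts_%s.tsv", sp))
    write_matrix_tsv(ds$counts[[sp]], p); add(paste0("counts_", sp), p, nrow(ds$counts[[sp]]))
    p <- file.path(dir, sprintf("fpkm_%s.tsv", sp))
    write_matrix_tsv(ds$fpkm[[sp]], p); add(paste0("fpkm_", sp), p, nrow(ds$fpkm[[sp]]))
    p <- file.path(dir, sprintf("lengths_%s.tsv", sp))
    write_lengths_tsv(ds$lengths[[sp]], p); add(paste0("lengths_", sp), p, length(ds$lengths[[sp]]))
  }

  hp <- file.path(dir, "homology.tsv")
  write_homology_tsv(ds$homology, hp)
  add("homology", hp, nrow(ds$homology))

  tp <- file.path(dir, "truth.json")
  jsonlite::write_json(ds$truth, tp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  add("truth", tp, NA)

  manifest <- list(species = names(ds$counts), files = files)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' @rdname write_dataset
#' @param dir directory previously written by [write_dataset()].
#' @return `read_dataset()` returns a list with the same `counts`,
#'   `fpkm`, `lengths`, `samples`, `homology`, `tree` and `truth`
#'   elements as the in-memory dataset.
#' @export
read_dataset <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  species <- manifest$species
  out <- list(counts = list(), fpkm = list(), lengths = list())
  for (sp in species) {
    cm <- read_matrix_tsv(file.path(dir, sprintf("counts_%s.tsv", sp)))
    storage.mode(cm) <- "integer"
    out$counts[[sp]] <- cm
    fp <- read_matrix_tsv(file.path(dir, sprintf("fpkm_%s.tsv", sp)))
    out$fpkm[[sp]] <- structure(fp, detection_floor = DETECTION_FLOOR)
    out$lengths[[sp]] <- read_lengths_tsv(file.path(dir, sprintf("lengths_%s.tsv", sp)))
  }
  out$samples <- read_sample_info_tsv(file.path(dir, "samples.tsv"))
  out$homology <- read_homology_tsv(file.path(dir, "homology.tsv"))
  out$tree <- ape::read.tree(file.path(dir, "tree.nwk"))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  truth$ps <- lapply(truth$ps, function(x) setNames(as.integer(x), names(x)))
  out$truth <- truth
  out
}
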