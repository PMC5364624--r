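test_that("configuration validation rejects bad inputs", {
  expect_error(sim_config(species_tree = "(onlyone);"), ">= 2 leaves")
  expect_error(sim_config(stage_divergence_sd = c(ridge = 0, bud = 0, palm = 0)),
               "stage")
  expect_error(sim_config(seq_depth = 0), "seq_depth")
  expect_error(sim_config(noise_sd = -1), ">= 0")
  expect_error(sim_config(tai_shape = "zigzag"))
  expect_error(sim_config(n_core_orthologs = 5, limb_effect_genes = 10),
               "exceeds")
})

test_that("zero-divergence limit: cross-species Spearman is exactly 1", {
  cfg <- small_cfg(stage_divergence_sd = c(ridge = 0, bud = 0, paddle = 0),
                   noise_sd = 0, limb_effect_genes = 0, n_replicates = 1)
  ds <- generate_dataset(cfg)
  core <- suppressWarnings(
    build_core_orthologs(ds$homology, species = ds$tree$tip.label,
                         reference = "bat"))
  for (stg in c("ridge", "bud", "paddle")) {
    pm <- core_profiles(ds, core, "fore", stg)
    r <- spearman_matrix(pm)
    expect_true(all(abs(r - 1) < 1e-12))
  }
})

test_that("study-scale configuration yields the 6,583-gene core and 6 condition groups", {
  cfg <- sim_config(n_core_orthologs = 6583, n_specific_per_species = 50,
                    n_clade_specific = 25, n_replicates = 2, seq_depth = 1e6,
                    seed = 5)
  ds <- generate_dataset(cfg)
  for (sp in names(ds$fpkm)) {
    info <- ds$samples[ds$samples$species == sp, ]
    expect_equal(nrow(unique(info[, c("limb", "stage")])), 6L)
  }
  core <- suppressWarnings(
    build_core_orthologs(ds$homology, species = ds$tree$tip.label,
                         reference = "bat"))
  expect_equal(nrow(core), 6583L)
})

test_that("planted limb-divergent truth behaves at the effect-size limits", {
  # no effect -> nothing flagged
  ds0 <- generate_dataset(small_cfg(limb_effect_genes = 0))
  expect_length(ds0$truth$limb_divergent_base, 0L)
  # large effect, zero noise -> planted genes are exactly the top-|planted|
  cfg <- small_cfg(limb_effect_genes = 10, limb_effect_size = 8,
                   noise_sd = 0,
                   stage_divergence_sd = c(ridge = 0, bud = 0, paddle = 0),
                   n_replicates = 1)
  ds <- generate_dataset(cfg)
  for (sp in names(ds$fpkm)) {
    prof <- average_replicates(ds$fpkm[[sp]], ds$samples)
    dv <- score_within(prof[, sprintf("%s_fore_bud", sp)],
                       prof[, sprintf("%s_hind_bud", sp)])
    top <- names(sort(dv$scores, decreasing = TRUE))[seq_along(ds$truth$limb_divergent[[sp]])]
    expect_setequal(top, ds$truth$limb_divergent[[sp]])
  }
})

test_that("homolog sharing scales with phylogenetic proximity", {
  ds <- generate_dataset(small_cfg())
  n_pair <- function(a, b) {
    length(unique(ds$homology$qseqid[ds$homology$qspecies == a &
                                       ds$homology$sspecies == b]))
  }
  # core-only pairs have exactly n_core hits; clade pairs have more
  expect_equal(n_pair("bat", "opossum"), 120L)
  expect_equal(n_pair("mouse", "opossum"), 120L)
  expect_gt(n_pair("bat", "mouse"), n_pair("bat", "opossum"))
  expect_gt(n_pair("bat", "pig"), n_pair("bat", "mouse"))
  # species-specific genes never appear in the homology table
  spec <- names(ds$truth$ps$bat)[ds$truth$ps$bat == 1L]
  expect_false(any(spec %in% c(ds$homology$qseqid, ds$homology$sseqid)))
})

test_that("fixed seed gives byte-identical files; round trip is lossless", {
  cfg <- small_cfg(seed = 31)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  m1 <- write_dataset(generate_dataset(cfg), d1)
  write_dataset(generate_dataset(cfg), d2)
  files <- list.files(d1)
  expect_identical(files, list.files(d2))
  expect_identical(unname(tools::md5sum(file.path(d1, files))),
                   unname(tools::md5sum(file.path(d2, files))))

  ds <- generate_dataset(cfg)
  rt <- read_dataset(d1)
  for (sp in names(ds$fpkm)) {
    expect_identical(rt$fpkm[[sp]][, ], ds$fpkm[[sp]][, ])
    expect_identical(rt$counts[[sp]][, ], ds$counts[[sp]][, ])
    expect_identical(rt$lengths[[sp]], ds$lengths[[sp]])
  }
  expect_identical(rt$samples, ds$samples)
  expect_identical(rt$homology, ds$homology)

  # manifest row counts match independently recounted dimensions
  for (sp in names(ds$counts)) {
    expect_equal(m1$files[[paste0("counts_", sp)]]$rows, nrow(ds$counts[[sp]]))
  }
  expect_equal(m1$files$homology$rows, nrow(ds$homology))
  expect_equal(m1$files$samples$rows, nrow(ds$samples))
})

test_that("an empty dataset writes valid files and reads back empty", {
  cfg <- small_cfg(n_core_orthologs = 0, n_specific_per_species = 0,
                   n_clade_specific = 0, limb_effect_genes = 0)
  ds <- generate_dataset(cfg)
  d <- withr::local_tempdir()
  write_dataset(ds, d)
  rt <- read_dataset(d)
  expect_equal(nrow(rt$fpkm$bat), 0L)
  expect_equal(nrow(rt$homology), 0L)
  expect_equal(nrow(rt$samples), nrow(ds$samples))
})
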