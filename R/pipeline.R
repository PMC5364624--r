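#' Pipeline configuration
#'
#' Declarative description of a full analysis run: either a `simulate`
#' block (arguments for [sim_config()]) or an `input_dir` in the layout
#' written by [write_dataset()], plus thresholds for every stage.  The
#' single global `seed` fans out to per-stage seeds by a counter-based
#' derivation so stages are independently reproducible.
#'
#' @param simulate named list of [sim_config()] arguments, or `NULL`
#'   when `input_dir` is given.
#' @param input_dir directory of input files ([write_dataset()] layout),
#'   or `NULL` when simulating.
#' @param out_dir output directory for the results bundle.
#' @param seed global integer seed.
#' @param stages which stages to run, in dependency order.
#' @param reference_species reference for ortholog core-set
#'   construction; defaults to the first tree leaf.
#' @param e_max_orthologs,e_max_ps E-value thresholds for the core set
#'   and for homologue detection in age assignment.
#' @param intensities,n_draws subsampling design for conservation CIs.
#' @param n_boot,scales,au_cutoff multiscale bootstrap design.
#' @param n_perm VTAI permutation count.
#' @param percentile divergent-set percentile.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = NULL, input_dir = NULL,
                            out_dir = tempfile("limbphylo_run_"),
                            seed = 1L,
                            stages = c("data", "normalize", "orthologs",
                                       "ages", "conservation", "cluster",
                                       "tai", "divergence"),
                            reference_species = NULL,
                            e_max_orthologs = 1e-20, e_max_ps = 1e-5,
                            intensities = seq(0.5, 1, 0.1), n_draws = 500,
                            n_boot = 1000, scales = seq(0.5, 1.4, 0.1),
                            au_cutoff = 0.95, n_perm = 1000,
                            percentile = 0.75) {
  if (is.null(simulate) && is.null(input_dir)) {
    stopf("either a simulate block or an input_dir is required")
  }
  if (!is.null(input_dir) && !dir.exists(input_dir)) {
    stopf("input_dir does not exist: %s", input_dir)
  }
  known <- c("data", "normalize", "orthologs", "ages", "conservation",
             "cluster", "tai", "divergence")
  bad <- setdiff(stages, known)
  if (length(bad)) stopf("unknown stage(s): %s", paste(bad, collapse = ", "))
  deps <- list(normalize = "data", orthologs = "data", ages = "orthologs",
               conservation = c("normalize", "orthologs"),
               cluster = c("normalize", "orthologs"),
               tai = c("normalize", "ages"),
               divergence = c("normalize", "orthologs"))
  for (st in stages) {
    need <- setdiff(deps[[st]], stages)
    if (length(need)) {
      stopf("stage '%s' requires stage(s): %s", st, paste(need, collapse = ", "))
    }
  }
  if (!(e_max_orthologs > 0 && e_max_ps > 0)) stopf("E-value thresholds must be positive")
  if (percentile <= 0 || percentile >= 1) stopf("percentile must be in (0,1)")
  if (au_cutoff <= 0 || au_cutoff > 1) stopf("au_cutoff must be in (0,1]")
  structure(list(simulate = simulate, input_dir = input_dir,
                 out_dir = out_dir, seed = as.integer(seed), stages = stages,
                 reference_species = reference_species,
                 e_max_orthologs = e_max_orthologs, e_max_ps = e_max_ps,
                 intensities = intensities, n_draws = n_draws,
                 n_boot = n_boot, scales = scales, au_cutoff = au_cutoff,
                 n_perm = n_perm, percentile = percentile),
            class = "pipeline_config")
}

# counter-based per-stage seed derivation, kept below 2^31
stage_seed <- function(seed, i) as.integer((abs(seed) %% 20000000L) * 100L + i)

#' Run the full analysis pipeline
#'
#' Executes the configured stages in dependency order -- simulate/load,
#' normalize, ortholog core set, phylostratigraphy, conservation,
#' cluster significance, TAI/VTAI, divergence sets -- writing a results
#' bundle of TSV/JSON files plus a manifest.  Two runs with the same
#' configuration and seed produce byte-identical bundles.  A failing
#' stage aborts with the stage named and leaves a `<stage>.partial`
#' marker next to any partial outputs.
#'
#' @param cfg a [pipeline_config()] (or a named list of its arguments, or
#'   a path to a JSON file of them).
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) {
    cfg <- do.call(pipeline_config,
                   jsonlite::read_json(cfg, simplifyVector = TRUE))
  } else if (!inherits(cfg, "pipeline_config")) {
    cfg <- do.call(pipeline_config, cfg)
  }
  out <- cfg$out_dir
  if (!dir.exists(out) && !dir.create(out, recursive = TRUE)) {
    stopf("cannot create output directory %s", out)
  }
  env <- new.env(parent = emptyenv())
  manifest <- list(seed = cfg$seed, stages = list(), files = character(0))

  run_stage <- function(name, i, fun) {
    if (!name %in% cfg$stages) return()
    marker <- file.path(out, paste0(name, ".partial"))
    file.create(marker)
    res <- tryCatch(fun(stage_seed(cfg$seed, i)),
                    error = function(e) {
                      stopf("stage '%s' failed: %s", name, conditionMessage(e))
                    })
    unlink(marker)
    manifest$stages[[name]] <<- list(seed = stage_seed(cfg$seed, i),
                                     files = res %||% character(0))
  }

  run_stage("data", 1L, function(sd) {
    if (!is.null(cfg$simulate)) {
      sim_args <- cfg$simulate
      if (is.null(sim_args$seed)) sim_args$seed <- sd
      env$ds <- generate_dataset(do.call(sim_config, sim_args))
      ddir <- file.path(out, "data")
      write_dataset(env$ds, ddir)
      paste0("data/", list.files(ddir))
    } else {
      env$ds <- read_dataset(cfg$input_dir)
      character(0)
    }
  })

  run_stage("normalize", 2L, function(sd) {
    ds <- env$ds
    files <- character(0)
    env$profiles <- list()
    for (sp in names(ds$counts)) {
      fp <- compute_fpkm(ds$counts[[sp]], ds$lengths[[sp]])
      sf <- size_factors(ds$counts[[sp]])
      fp_norm <- apply_size_factors(fp, sf)
      prof <- average_replicates(fp_norm, ds$samples)
      env$profiles[[sp]] <- prof
      f <- sprintf("profiles_%s.tsv", sp)
      write_matrix_tsv(prof, file.path(out, f))
      files <- c(files, f)
    }
    files
  })

  run_stage("orthologs", 3L, function(sd) {
    ds <- env$ds
    ref <- cfg$reference_species %||% ds$tree$tip.label[1L]
    env$core <- build_core_orthologs(ds$homology, species = ds$tree$tip.label,
                                     reference = ref,
                                     e_max = cfg$e_max_orthologs)
    write.table(as.data.frame(env$core), file.path(out, "orthologs.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    "orthologs.tsv"
  })

  run_stage("ages", 4L, function(sd) {
    ds <- env$ds
    files <- character(0)
    env$ps <- list()
    for (sp in names(ds$counts)) {
      ps <- assign_phylostrata(ds$homology, ds$tree, sp,
                               genes = rownames(ds$counts[[sp]]),
                               e_max = cfg$e_max_ps)
      env$ps[[sp]] <- ps
      f <- sprintf("ps_%s.tsv", sp)
      write.table(data.frame(gene = names(ps), ps = as.integer(ps)),
                  file.path(out, f), sep = "\t", quote = FALSE,
                  row.names = FALSE)
      files <- c(files, f)
    }
    hcc <- homolog_count_clustering(ds$homology, ds$tree, e_max = cfg$e_max_ps)
    jsonlite::write_json(list(counts = hcc$counts, rf = hcc$rf,
                              matches_tree = hcc$matches_tree, tie = hcc$tie),
                         file.path(out, "homolog_clustering.json"),
                         auto_unbox = TRUE, digits = NA, matrix = "rowmajor",
                         pretty = TRUE)
    c(files, "homolog_clustering.json")
  })

  run_stage("conservation", 5L, function(sd) {
    files <- character(0)
    for (limb in LIMBS) {
      res <- list()
      for (stg in STAGES) {
        prof <- core_profile_matrix(env$profiles, env$core, limb, stg)
        res[[stg]] <- subsample_conservation(prof, cfg$intensities,
                                             cfg$n_draws, seed = sd)
        sd <- sd + 1L
      }
      cmp <- list()
      pairs <- utils::combn(STAGES, 2, simplify = FALSE)
      for (pr in pairs) {
        for (f in cfg$intensities) {
          cc <- compare_conservation(res[[pr[1]]], res[[pr[2]]], f)
          cmp[[sprintf("%s_vs_%s@%g", pr[1], pr[2], f)]] <-
            list(nonoverlapping = cc$nonoverlapping, t_p_value = cc$t_p_value)
        }
      }
      f <- sprintf("conservation_%s.json", limb)
      jsonlite::write_json(
        list(c = lapply(res, function(x) x$c_full),
             ci = lapply(res, function(x) x$ci),
             comparisons = cmp),
        file.path(out, f), auto_unbox = TRUE, digits = NA,
        matrix = "rowmajor", pretty = TRUE)
      files <- c(files, f)
      env$conservation[[limb]] <- res
    }
    files
  })

  run_stage("cluster", 6L, function(sd) {
    files <- character(0)
    # within-species: 6 condition profiles over the species' genes
    for (sp in names(env$profiles)) {
      cs <- significant_clustering(env$profiles[[sp]], n_boot = cfg$n_boot,
                                   scales = cfg$scales, seed = sd,
                                   au_cutoff = cfg$au_cutoff)
      sd <- sd + 1L
      f <- sprintf("cluster_within_%s.nwk", sp)
      writeLines(cluster_newick(cs), file.path(out, f))
      files <- c(files, f)
    }
    # among-species: one dendrogram per (limb, stage) over core orthologs
    for (limb in LIMBS) {
      for (stg in STAGES) {
        prof <- core_profile_matrix(env$profiles, env$core, limb, stg)
        cs <- significant_clustering(prof, n_boot = cfg$n_boot,
                                     scales = cfg$scales, seed = sd,
                                     au_cutoff = cfg$au_cutoff)
        sd <- sd + 1L
        f <- sprintf("cluster_among_%s_%s.nwk", limb, stg)
        writeLines(cluster_newick(cs), file.path(out, f))
        files <- c(files, f)
      }
    }
    files
  })

  run_stage("tai", 7L, function(sd) {
    rows <- list(); tests <- list()
    for (sp in names(env$profiles)) {
      for (limb in LIMBS) {
        prof <- env$profiles[[sp]]
        cols <- sprintf("%s_%s_%s", sp, limb, STAGES)
        if (!all(cols %in% colnames(prof))) next
        expr <- prof[, cols, drop = FALSE]
        colnames(expr) <- STAGES
        tp <- tai_profile(expr, env$ps[[sp]], species = sp, limb = limb)
        vt <- vtai_test(expr, env$ps[[sp]], n_perm = cfg$n_perm, seed = sd)
        sd <- sd + 1L
        for (stg in STAGES) {
          rows[[length(rows) + 1L]] <- data.frame(
            species = sp, limb = limb, stage = stg, tai = tp$tai[[stg]])
        }
        tests[[paste(sp, limb, sep = "_")]] <- list(
          vtai = vt$vtai_observed, gamma_shape = vt$gamma_shape,
          gamma_rate = vt$gamma_rate, p_value = vt$p_value,
          shape = tp$shape, seed = vt$seed)
      }
    }
    tai_df <- do.call(rbind, rows)
    tai_df$tai <- sprintf("%.17g", tai_df$tai)
    write.table(tai_df, file.path(out, "tai.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(tests, file.path(out, "vtai.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    c("tai.tsv", "vtai.json")
  })

  run_stage("divergence", 8L, function(sd) {
    files <- character(0)
    ref <- names(env$core)[1L]
    ann <- limb_gene_list()
    overlaps <- list()
    for (stg in STAGES) {
      within_sets <- list()
      for (sp in names(env$profiles)) {
        prof <- env$profiles[[sp]]
        fc <- sprintf("%s_fore_%s", sp, stg); hc <- sprintf("%s_hind_%s", sp, stg)
        if (!all(c(fc, hc) %in% colnames(prof))) next
        dv <- score_within(prof[, fc], prof[, hc], percentile = cfg$percentile)
        # map to ortholog-group key (reference gene id) for cross-species overlap
        grp <- env$core[[ref]][match(dv$divergent, env$core[[sp]])]
        within_sets[[sp]] <- grp[!is.na(grp)]
        f <- sprintf("divergence_within_%s_%s.tsv", sp, stg)
        write.table(data.frame(gene = names(dv$scores),
                               score = sprintf("%.17g", dv$scores),
                               divergent = names(dv$scores) %in% dv$divergent),
                    file.path(out, f), sep = "\t", quote = FALSE,
                    row.names = FALSE)
        files <- c(files, f)
      }
      for (limb in LIMBS) {
        prof <- core_profile_matrix(env$profiles, env$core, limb, stg)
        rownames(prof) <- env$core[[ref]]
        dv <- score_among(prof, percentile = cfg$percentile)
        f <- sprintf("divergence_among_%s_%s.tsv", limb, stg)
        write.table(data.frame(gene = names(dv$scores),
                               score = sprintf("%.17g", dv$scores),
                               divergent = names(dv$scores) %in% dv$divergent),
                    file.path(out, f), sep = "\t", quote = FALSE,
                    row.names = FALSE)
        files <- c(files, f)
      }
      if (length(within_sets) >= 2L) {
        ov <- overlap_report(within_sets, universe = env$core[[ref]],
                             annotation = ann)
        overlaps[[stg]] <- list(
          intersection = ov$intersection,
          intersection_percent = ov$intersection_percent,
          pairwise_percent = ov$pairwise_percent,
          annotated = ov$annotated, universe_size = ov$universe_size)
      }
    }
    jsonlite::write_json(overlaps, file.path(out, "overlap.json"),
                         auto_unbox = TRUE, digits = NA,
                         matrix = "rowmajor", pretty = TRUE)
    c(files, "overlap.json")
  })

  manifest$files <- unlist(lapply(manifest$stages, `[[`, "files"),
                           use.names = FALSE)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

# genes x species matrix of core-ortholog profiles at one (limb, stage)
core_profile_matrix <- function(profiles, core, limb, stage) {
  species <- names(core)
  cols <- lapply(species, function(sp) {
    cn <- sprintf("%s_%s_%s", sp, limb, stage)
    prof <- profiles[[sp]]
    if (!cn %in% colnames(prof)) {
      stopf("profile column %s missing", cn)
    }
    prof[core[[sp]], cn]
  })
  m <- do.call(cbind, cols)
  dimnames(m) <- list(core[[1L]], species)
  m
}
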