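test_that("TAI formula: hand-evaluated cases and invariances", {
  # (ps, e) = {(1, 1), (4, 3)} -> 13/4
  expect_equal(compute_tai(c(g1 = 1, g2 = 3), c(g1 = 1, g2 = 4)), 3.25)
  # constant ps -> TAI equals it regardless of expression
  e <- c(a = 0.2, b = 7, c = 30)
  expect_equal(compute_tai(e, c(a = 2, b = 2, c = 2)), 2)
  # homogeneity of degree zero in expression
  ps <- c(a = 1, b = 3, c = 4)
  expect_equal(compute_tai(e * 17, ps), compute_tai(e, ps))
  # bounds
  expect_gte(compute_tai(e, ps), 1); expect_lte(compute_tai(e, ps), 4)
  expect_error(compute_tai(c(a = 0, b = 0), c(a = 1, b = 2)), "all-zero")
  expect_error(compute_tai(c(a = 1, z = 1), ps), "z")
})

test_that("TAI profiles classify planted trend shapes", {
  expect_equal(classify_tai_shape(c(2, 2, 2)), "flat")
  expect_equal(classify_tai_shape(c(2, 3, 2.5)), "hourglass")
  expect_equal(classify_tai_shape(c(3, 2, 2.8)), "reverse_hourglass")
  expect_equal(classify_tai_shape(c(3, 2.5, 2)), "monotone")
  expect_equal(classify_tai_shape(c(2, 2 + 1e-9, 2)), "flat")

  shapes <- c(hourglass = "hourglass", reverse_hourglass = "reverse_hourglass",
              monotone_decreasing = "monotone")
  for (planted in names(shapes)) {
    ds <- generate_dataset(small_cfg(tai_shape = planted, tai_effect_size = 2,
                                     limb_effect_genes = 0, n_replicates = 1,
                                     seed = 11))
    tp <- tai_profile(stage_expr(ds, "bat", "fore"), ds$truth$ps$bat,
                      species = "bat", limb = "fore")
    expect_equal(tp$shape, unname(shapes[planted]))
    if (planted == "monotone_decreasing") {
      expect_lt(tp$tai[["paddle"]], tp$tai[["ridge"]])
    }
  }

  bad <- list(ridge = c(g1 = 1), bud = c(g2 = 1))
  expect_error(tai_profile(bad, c(g1 = 1, g2 = 1)), "differs")
})

test_that("VTAI test: degenerate zero-variance input gives p = 1", {
  e <- abs(rnorm(30)) + 0.1
  expr <- cbind(ridge = e, bud = e, paddle = e)
  rownames(expr) <- paste0("g", 1:30)
  ps <- setNames(rep(1:3, 10), rownames(expr))
  expect_warning(vt <- vtai_test(expr, ps, n_perm = 100, seed = 1),
                 "degenerate")
  expect_equal(vt$vtai_observed, 0)
  expect_equal(vt$p_value, 1)
})

test_that("surrogate VTAIs respect the phylostratum range bound", {
  set.seed(12)
  expr <- matrix(abs(rnorm(150, 10)), 50, 3,
                 dimnames = list(paste0("g", 1:50),
                                 c("ridge", "bud", "paddle")))
  ps <- setNames(sample(1:4, 50, TRUE), rownames(expr))
  vt <- vtai_test(expr, ps, n_perm = 300, seed = 2)
  # each surrogate TAI lies in [1, 4]; its across-stage population
  # variance can be at most ((max - min) / 2)^2
  expect_true(all(vt$null_surrogates >= 0))
  expect_true(all(vt$null_surrogates <= ((max(ps) - min(ps)) / 2)^2))
  expect_equal(length(vt$null_surrogates), 300L)
})

test_that("gamma-fitted p agrees with the empirical permutation p", {
  set.seed(9)
  expr <- matrix(abs(rnorm(600, 10, 2)), 200, 3,
                 dimnames = list(paste0("g", 1:200),
                                 c("ridge", "bud", "paddle")))
  ps <- setNames(sample(1:4, 200, TRUE), rownames(expr))
  vt <- vtai_test(expr, ps, n_perm = 10000, seed = 4)
  expect_lt(abs(vt$p_value - vt$p_empirical), 0.02)
})

test_that("planted reverse-hourglass is detected with high power", {
  # balanced age-class composition (as in the study species, which carry
  # large species-specific gene fractions): the age index only responds
  # to expression shifts when no single ps class dominates
  hits <- 0
  for (s in 1:20) {
    ds <- generate_dataset(small_cfg(n_core_orthologs = 100,
                                     n_specific_per_species = 100,
                                     n_clade_specific = 30,
                                     tai_shape = "reverse_hourglass",
                                     tai_effect_size = 2,
                                     limb_effect_genes = 0, n_replicates = 1,
                                     seed = 400 + s))
    vt <- vtai_test(stage_expr(ds, "bat", "fore"), ds$truth$ps$bat,
                    n_perm = 200, seed = s)
    if (vt$p_value < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 18)
})
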