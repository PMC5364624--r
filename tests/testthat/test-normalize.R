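toy_counts <- function() {
  m <- matrix(c(10, 999990,
                20, 999980), ncol = 2,
              dimnames = list(c("gA", "gB"), c("s1", "s2")))
  m
}

test_that("FPKM formula: hand-evaluated toy cases", {
  counts <- toy_counts()
  lengths <- c(gA = 1000, gB = 2000)
  fp <- compute_fpkm(counts, lengths)
  # count 10, length 1 kb, total 1e6 -> FPKM 10
  expect_equal(fp["gA", "s1"], 10)
  expect_equal(fp["gA", "s2"], 20)
  # zero count -> zero FPKM
  counts["gA", "s1"] <- 0; counts["gB", "s1"] <- 1e6
  expect_equal(compute_fpkm(counts, lengths)["gA", "s1"], 0)
})

test_that("detection floor flags sub-floor FPKM as not detected", {
  fp <- structure(matrix(c(5e-4, 1e-3, 2), 3, 1,
                         dimnames = list(c("a", "b", "c"), "s")),
                  detection_floor = 1e-3)
  det <- is_detected(fp)
  expect_identical(as.vector(det), c(FALSE, TRUE, TRUE))
})

test_that("FPKM errors name the offending sample or gene", {
  counts <- toy_counts()
  expect_error(compute_fpkm(counts, c(gA = 1000)), "gB")
  counts[, "s2"] <- 0
  expect_error(compute_fpkm(counts, c(gA = 1000, gB = 2000)), "s2")
})

test_that("FPKM is invariant to uniform count scaling within a sample", {
  set.seed(4)
  counts <- matrix(rpois(50, 40) + 1, 10, 5,
                   dimnames = list(paste0("g", 1:10), paste0("s", 1:5)))
  lengths <- setNames(sample(500:3000, 10), rownames(counts))
  fp1 <- compute_fpkm(counts, lengths)
  counts2 <- counts; counts2[, 3] <- counts2[, 3] * 7
  fp2 <- compute_fpkm(counts2, lengths)
  expect_equal(fp1[, ], fp2[, ])
})

test_that("median-of-ratios size factors match definition and properties", {
  # identical samples -> all factors 1
  m <- matrix(rep(c(5, 10, 20), 3), 3, 3,
              dimnames = list(letters[1:3], paste0("s", 1:3)))
  expect_equal(unname(size_factors(m)), c(1, 1, 1))

  # doubled sample -> factor ratio 2 (closed form for 2 samples)
  m2 <- cbind(A = c(5, 10, 20), B = 2 * c(5, 10, 20))
  rownames(m2) <- letters[1:3]
  sf <- size_factors(m2)
  expect_equal(unname(sf["B"] / sf["A"]), 2)

  # brute-force oracle on a toy with a zero-bearing (excluded) gene; an
  # odd number of included genes keeps the median interpolation-free
  m3 <- matrix(c(10, 20, 0, 40, 80, 15,
                 20, 10, 5, 80, 40, 45,
                 30, 30, 9, 60, 60, 15), 6, 3,
               dimnames = list(paste0("g", 1:6), paste0("s", 1:3)))
  incl <- apply(m3 > 0, 1, all)
  gm <- apply(m3[incl, ], 1, function(x) prod(x)^(1 / length(x)))
  oracle <- apply(m3[incl, ], 2, function(col) median(col / gm))
  expect_equal(size_factors(m3), oracle)

  # scale-equivariance relative to the shared geometric-mean reference:
  # scaling sample 2 by 3 scales its factor by 3 relative to the others
  m4 <- m3; m4[, 2] <- m4[, 2] * 3
  rel <- size_factors(m4) / size_factors(m3)
  expect_equal(unname(rel["s2"] / rel["s1"]), 3)
  expect_equal(unname(rel["s2"] / rel["s3"]), 3)

  # fixed point: factors of the normalized matrix are all equal
  set.seed(8)
  m5 <- matrix(rpois(60, 100) + 1, 12, 5,
               dimnames = list(paste0("g", 1:12), paste0("s", 1:5)))
  m5[, 4] <- m5[, 4] * 4
  norm <- apply_size_factors(m5, size_factors(m5))
  post <- size_factors(norm)
  expect_lt(diff(range(post)), 1e-12)

  # all-zero-overlap matrix -> informative error
  m6 <- diag(5); dimnames(m6) <- list(paste0("g", 1:5), paste0("s", 1:5))
  expect_error(size_factors(m6), "pseudo-reference")
})

test_that("replicate averaging produces one profile per condition", {
  ds <- generate_dataset(small_cfg(n_replicates = 3))
  prof <- average_replicates(ds$fpkm$bat, ds$samples)
  expect_equal(ncol(prof), 6L)
  cond <- attr(prof, "conditions")
  expect_setequal(paste(cond$limb, cond$stage),
                  as.vector(outer(c("fore", "hind"),
                                  c("ridge", "bud", "paddle"), paste)))
  # averaging oracle for one condition
  ids <- ds$samples$sample[ds$samples$species == "bat" &
                             ds$samples$limb == "fore" &
                             ds$samples$stage == "bud"]
  expect_equal(prof[, "bat_fore_bud"], rowMeans(ds$fpkm$bat[, ids]))
})

test_that("log2_fpkm uses the floor as pseudocount", {
  x <- structure(c(0, 1), detection_floor = 1e-3)
  expect_equal(as.vector(log2_fpkm(x)), log2(c(1e-3, 1 + 1e-3)))
})
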