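#' Spearman correlation matrix between expression profiles
#'
#' Rank correlation with average ranks for ties; diagonal fixed at 1.
#' A constant profile has undefined rank correlation: its entries are
#' returned as `NA` with a warning.
#'
#' @param profiles numeric matrix, genes x profiles (>= 3 genes,
#'   >= 2 profiles), columns labeled.
#' @return symmetric correlation matrix.
#' @export
spearman_matrix <- function(profiles) {
  if (ncol(profiles) < 2L) stopf("need >= 2 profiles")
  if (nrow(profiles) < 3L) stopf("need >= 3 genes")
  const <- apply(profiles, 2, function(x) diff(range(x)) == 0)
  if (any(const)) {
    warnf("constant profile(s) have undefined rank correlation: %s",
          paste(colnames(profiles)[const], collapse = ", "))
  }
  r <- suppressWarnings(cor(profiles, method = "spearman"))
  diag(r) <- 1
  r
}

#' Mean pairwise Spearman conservation statistic
#'
#' The conservation of expression across `k` species at one stage is
#' summarized as `c = mean over all k(k-1)/2 species pairs of the
#' Spearman coefficient r[i, j]` between their profiles over a common
#' ortholog set.
#'
#' @inheritParams spearman_matrix
#' @return the scalar `c`.
#' @export
mean_pairwise_spearman <- function(profiles) {
  if (ncol(profiles) < 2L) stopf("need >= 2 profiles (species)")
  r <- spearman_matrix(profiles)
  mean(r[upper.tri(r)])
}

#' Subsampling robustness of the conservation statistic
#'
#' Draws `n_draws` random gene subsets (without replacement) at each
#' subsampling intensity, recomputes the mean pairwise Spearman `c` on
#' each subset, and summarizes each intensity's distribution by its
#' 2.5/97.5 percentile interval.  At intensity 1 every draw uses the
#' full gene set, so the interval has width zero.
#'
#' @inheritParams spearman_matrix
#' @param intensities fractions in (0, 1] of the gene set to sample.
#' @param n_draws subsets per intensity.
#' @param seed optional RNG seed.
#' @return object of class `conservation_result`: `c_full`,
#'   `distributions` (list, per intensity), `ci` (matrix with columns
#'   `lo`, `hi`), `n`, `k`.
#' @export
subsample_conservation <- function(profiles, intensities = seq(0.5, 1, 0.1),
                                   n_draws = 500, seed = NULL) {
  if (any(intensities <= 0 | intensities > 1)) {
    stopf("intensities must lie in (0, 1]")
  }
  if (n_draws < 1) stopf("n_draws must be >= 1")
  n <- nrow(profiles)
  c_full <- mean_pairwise_spearman(profiles)
  with_seed(seed, {
    dist_list <- lapply(intensities, function(f) {
      m <- round(f * n)
      if (m < 3L) stopf("subset size %d at intensity %g is below 3 genes", m, f)
      vapply(seq_len(n_draws), function(i) {
        idx <- sample.int(n, m)
        mean_pairwise_spearman(profiles[idx, , drop = FALSE])
      }, numeric(1))
    })
    names(dist_list) <- as.character(intensities)
    ci <- t(vapply(dist_list, quantile, numeric(2),
                   probs = c(0.025, 0.975), names = FALSE))
    colnames(ci) <- c("lo", "hi")
    structure(list(c_full = c_full, intensities = intensities,
                   distributions = dist_list, ci = ci,
                   n = n, k = ncol(profiles)),
              class = "conservation_result")
  })
}

#' Compare two stages' conservation distributions
#'
#' Two stages are "significantly different" at an intensity when their
#' 95% subsampling intervals do not overlap.  A two-sample t-test over
#' the subsample distributions is also reported for the full-set style
#' comparison.
#'
#' @param a,b `conservation_result` objects for the two stages.
#' @param intensity which subsampling intensity to compare at.
#' @return list: `nonoverlapping` (logical), `ci_a`, `ci_b`,
#'   `t_p_value`.
#' @export
compare_conservation <- function(a, b, intensity) {
  key <- as.character(intensity)
  if (!key %in% names(a$distributions) || !key %in% names(b$distributions)) {
    stopf("intensity %s not present in both results", key)
  }
  ca <- a$ci[key, ]; cb <- b$ci[key, ]
  nonov <- ca["lo"] > cb["hi"] || cb["lo"] > ca["hi"]
  da <- a$distributions[[key]]; db <- b$distributions[[key]]
  tp <- if (sd(da) == 0 && sd(db) == 0) {
    if (mean(da) == mean(db)) 1 else 0
  } else {
    stats::t.test(da, db)$p.value
  }
  list(nonoverlapping = unname(nonov),
       ci_a = ca, ci_b = cb, t_p_value = tp)
}
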