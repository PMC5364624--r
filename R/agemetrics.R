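#' Transcriptome age index (TAI)
#'
#' The TAI of a transcriptome at one developmental stage is the
#' expression-weighted mean phylostratum:
#' `TAI = sum(ps_i * e_i) / sum(e_i)` over the `n` genes, where `ps_i`
#' is gene i's evolutionary age class and `e_i` its expression.  Smaller
#' TAI means a younger transcriptome.  TAI is invariant to rescaling all
#' expression values and is bounded by `[min(ps), max(ps)]`.
#'
#' @param e non-negative expression values (one condition); if named,
#'   aligned to `ps` by name.
#' @param ps integer phylostrata, one per gene.
#' @return scalar TAI.
#' @export
compute_tai <- function(e, ps) {
  if (!is.null(names(e)) && !is.null(names(ps))) {
    missing <- setdiff(names(e), names(ps))
    if (length(missing)) {
      stopf("no phylostratum for gene(s): %s",
            paste(head(missing, 5), collapse = ", "))
    }
    ps <- ps[names(e)]
  }
  if (length(e) != length(ps)) stopf("e and ps lengths differ")
  if (anyNA(ps)) stopf("phylostrata contain NA")
  if (any(e < 0)) stopf("expression must be non-negative")
  tot <- sum(e)
  if (tot <= 0) stopf("all-zero expression: TAI undefined")
  sum(ps * e) / tot
}

#' TAI profile across developmental stages
#'
#' Computes one TAI per stage (ridge, bud, paddle order) over a common
#' gene universe and classifies the trend shape.
#'
#' @param expr genes x stages matrix with stage column names, or a named
#'   list of per-stage expression vectors over identical genes.
#' @param ps named phylostratum vector covering the genes.
#' @param species,limb optional labels carried along.
#' @param tol stage differences below `tol` count as ties.
#' @return object of class `tai_profile`: `tai` (named numeric),
#'   `shape`, `n`, `species`, `limb`.
#' @export
tai_profile <- function(expr, ps, species = NA_character_,
                        limb = NA_character_, tol = 1e-6) {
  if (is.list(expr) && !is.matrix(expr)) {
    universe <- names(expr[[1L]])
    for (s in names(expr)) {
      d <- c(setdiff(names(expr[[s]]), universe),
             setdiff(universe, names(expr[[s]])))
      if (length(d)) {
        stopf("stage '%s' gene set differs (e.g. %s)", s,
              paste(head(d, 5), collapse = ", "))
      }
    }
    expr <- do.call(cbind, lapply(expr, function(x) x[universe]))
    rownames(expr) <- universe
  }
  stages <- intersect(STAGES, colnames(expr))
  if (length(stages) < 2L) stopf("need >= 2 of the stages %s",
                                 paste(STAGES, collapse = ", "))
  tai <- vapply(stages, function(s) compute_tai(setNames(expr[, s], rownames(expr)), ps),
                numeric(1))
  structure(list(tai = tai, shape = classify_tai_shape(tai, tol),
                 n = nrow(expr), species = species, limb = limb),
            class = "tai_profile")
}

#' @rdname tai_profile
#' @param tai named numeric of per-stage TAIs in developmental order.
#' @return `classify_tai_shape()` returns one of `"hourglass"`
#'   (mid-stage oldest), `"reverse_hourglass"` (mid-stage youngest),
#'   `"monotone"`, or `"flat"`.
#' @export
classify_tai_shape <- function(tai, tol = 1e-6) {
  if (length(tai) < 3L) {
    return(if (abs(diff(range(tai))) < tol) "flat" else "monotone")
  }
  d <- diff(tai)
  s <- sign(d) * (abs(d) >= tol)
  if (all(s == 0)) return("flat")
  if (s[1L] > 0 && s[2L] < 0) return("hourglass")
  if (s[1L] < 0 && s[2L] > 0) return("reverse_hourglass")
  "monotone"
}

#' Permutation test for flatness of the TAI profile (VTAI)
#'
#' The test statistic is `VTAI`, the variance of the per-stage TAIs
#' (population variance over the stage values).  The null distribution
#' is generated by randomly permuting the phylostratum assignments over
#' genes -- one shared permutation applied to all stages, preserving
#' cross-stage expression correlation -- recomputing `VTAI` for each of
#' `n_perm` surrogates, and fitting a gamma distribution to the
#' surrogates (maximum likelihood, with moment matching as fallback).
#' The p-value is the upper-tail gamma probability at the observed
#' `VTAI`.  If the surrogates are degenerate (all equal) the empirical
#' permutation p-value is reported with a warning.
#'
#' @param expr genes x stages expression matrix (stage column names).
#' @param ps named phylostratum vector covering the genes.
#' @param n_perm number of surrogates (>= 100).
#' @param seed optional RNG seed.
#' @return object of class `vtai_test`: `vtai_observed`, `tai`,
#'   `null_surrogates`, `gamma_shape`, `gamma_rate`, `p_value`,
#'   `p_empirical`, `n_perm`, `seed`.
#' @export
vtai_test <- function(expr, ps, n_perm = 1000, seed = NULL) {
  if (n_perm < 100) stopf("n_perm must be >= 100")
  stages <- intersect(STAGES, colnames(expr))
  if (length(stages) < 2L) stopf("need >= 2 stages")
  expr <- expr[, stages, drop = FALSE]
  if (!is.null(names(ps))) {
    missing <- setdiff(rownames(expr), names(ps))
    if (length(missing)) {
      stopf("no phylostratum for gene(s): %s",
            paste(head(missing, 5), collapse = ", "))
    }
    ps <- ps[rownames(expr)]
  }
  ps <- as.numeric(ps)
  tot <- colSums(expr)
  if (any(tot <= 0)) stopf("stage(s) with all-zero expression")
  W <- sweep(expr, 2, tot, "/")          # per-stage expression weights

  pop_var <- function(x) mean((x - mean(x))^2)
  tai_obs <- as.numeric(crossprod(W, ps))
  names(tai_obs) <- stages
  vtai <- pop_var(tai_obs)

  with_seed(seed, {
    n <- length(ps)
    P <- vapply(seq_len(n_perm), function(i) ps[sample.int(n)],
                numeric(n))
    S <- crossprod(as.matrix(W), P)       # stages x n_perm surrogate TAIs
    surr <- colMeans(S^2) - colMeans(S)^2
    p_emp <- (1 + sum(surr >= vtai)) / (n_perm + 1)

    if (sd(surr) == 0) {
      warnf("degenerate null (all surrogate VTAIs equal); empirical p reported")
      return(structure(list(vtai_observed = vtai, tai = tai_obs,
                            null_surrogates = surr, gamma_shape = NA_real_,
                            gamma_rate = NA_real_, p_value = p_emp,
                            p_empirical = p_emp, n_perm = n_perm, seed = seed),
                       class = "vtai_test"))
    }
    m <- mean(surr); v <- var(surr)
    shape <- m^2 / v; rate <- m / v       # moment-matching start / fallback
    fit <- tryCatch(
      suppressWarnings(MASS::fitdistr(surr, "gamma",
                                      start = list(shape = shape, rate = rate),
                                      lower = c(1e-10, 1e-10))),
      error = function(e) NULL)
    if (!is.null(fit)) {
      shape <- fit$estimate[["shape"]]; rate <- fit$estimate[["rate"]]
    }
    p <- pgamma(vtai, shape = shape, rate = rate, lower.tail = FALSE)
    structure(list(vtai_observed = vtai, tai = tai_obs,
                   null_surrogates = surr, gamma_shape = shape,
                   gamma_rate = rate, p_value = p, p_empirical = p_emp,
                   n_perm = n_perm, seed = seed),
              class = "vtai_test")
  })
}
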