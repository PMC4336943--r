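# Model-adequacy procedures: site cross-validation between two models,
# posterior-predictive homoplasy, and saturation-slope analysis.

#' Site cross-validation between two models
#'
#' Repeatedly splits the alignment columns into a learning set (`fraction`,
#' default 90%) and a test set, fits both model specifications on the same
#' learning columns (fixed topology; learning-set parameters frozen for
#' scoring), and scores each replicate by the summed test-site
#' log-likelihood. The reported score is `model2 - model1`, so model 1 is
#' the reference and a negative mean score means the reference fits better.
#'
#' @param aln An [msa].
#' @param tree Fixed topology.
#' @param spec1 Reference [model_spec()] (model 1).
#' @param spec2 Alternative [model_spec()] (model 2).
#' @param fraction Learning fraction, in (0.5, 1).
#' @param reps Number of random splits (default 10).
#' @param seed Integer seed.
#' @return A `cv_report`: tibble with one row per replicate (`rep`,
#'   `score1`, `score2`, `delta`, `delta_per_site`, `n_test`); attributes
#'   `mean`, `sd`, `mean_per_site`, model names, `fraction`, `seed`.
#'   Supports [tidy()]/[glance()].
#' @export
cross_validate <- function(aln, tree, spec1, spec2, fraction = 0.9, reps = 10,
                           seed = 1L) {
  if (fraction <= 0.5 || fraction >= 1) abort("`fraction` must be in (0.5, 1)")
  L <- n_sites(aln)
  n_learn <- floor(fraction * L)
  if (L - n_learn < 10) abort("test set smaller than 10 sites")
  set.seed(seed)
  rows <- purrr::map(seq_len(reps), function(r) {
    learn <- sort(sample.int(L, n_learn))
    test <- setdiff(seq_len(L), learn)
    a_learn <- msa_subset(aln, columns = learn)
    a_test <- msa_subset(aln, columns = test)
    f1 <- fit_model(a_learn, tree, spec1, seed = seed + r)
    f2 <- fit_model(a_learn, tree, spec2, seed = seed + r)
    s1 <- sum(site_log_likelihoods(f1, a_test))
    s2 <- sum(site_log_likelihoods(f2, a_test))
    tibble(rep = r, score1 = s1, score2 = s2, delta = s2 - s1,
           delta_per_site = (s2 - s1) / length(test), n_test = length(test))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "mean") <- mean(out$delta)
  attr(out, "sd") <- stats::sd(out$delta)
  attr(out, "mean_per_site") <- mean(out$delta_per_site)
  attr(out, "model1") <- spec1$name
  attr(out, "model2") <- spec2$name
  attr(out, "fraction") <- fraction
  attr(out, "seed") <- seed
  class(out) <- c("cv_report", class(out))
  out
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("Cross-validation %s (reference) vs %s: score %.2f +/- %.2f over %d reps\n",
              attr(x, "model1"), attr(x, "model2"), attr(x, "mean"),
              attr(x, "sd"), nrow(x)))
  cat("  (negative score = reference model fits better)\n")
  invisible(x)
}

#' Saturation-slope analysis
#'
#' Regresses compared leaf-pair distance vectors (patristic distances under
#' other models, and optionally the observed uncorrected p-distance) on the
#' reference tree's patristic distances, by OLS with intercept. The smaller
#' the slope, the more saturation the compared distances hide relative to
#' the reference.
#'
#' @param reference_tree Reference tree with branch lengths (e.g. the
#'   best-fitting model's tree).
#' @param other_trees Named list of trees to compare (may be empty).
#' @param aln Optional [msa]; adds the observed p-distance as a comparison.
#' @return A `saturation_report`: tibble `comparison`, `slope`, `intercept`,
#'   `r_squared`; attribute `pairs` holds the pairwise vectors for plotting.
#'   Supports [autoplot()].
#' @export
saturation_analysis <- function(reference_tree, other_trees = list(), aln = NULL) {
  taxa <- reference_tree$tip.label
  if (length(taxa) < 3) abort("need at least 3 taxa")
  ref <- patristic_matrix(reference_tree)[taxa, taxa]
  ut <- upper.tri(ref)
  vecs <- list()
  for (nm in names(other_trees)) {
    tr <- other_trees[[nm]]
    if (!setequal(tr$tip.label, taxa)) abort("trees must share one taxon set")
    vecs[[nm]] <- patristic_matrix(tr)[taxa, taxa][ut]
  }
  if (!is.null(aln)) {
    vecs[["observed_p"]] <- p_distance(msa_subset(aln, taxa = taxa))[taxa, taxa][ut]
  }
  if (!length(vecs)) abort("nothing to compare: supply `other_trees` and/or `aln`")
  x <- ref[ut]
  rows <- purrr::imap(vecs, function(y, nm) {
    fit <- stats::lm(y ~ x)
    tibble(comparison = nm, slope = unname(stats::coef(fit)[2]),
           intercept = unname(stats::coef(fit)[1]),
           # exact fits (e.g. a vector against itself) trip a harmless
           # "essentially perfect fit" warning in summary.lm
           r_squared = suppressWarnings(summary(fit)$r.squared))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "pairs") <- dplyr::bind_rows(purrr::imap(vecs, function(y, nm) {
    tibble(comparison = nm, reference = x, compared = y)
  }))
  class(out) <- c("saturation_report", class(out))
  out
}

#' Posterior-predictive homoplasy test
#'
#' The observed homoplasy excess (parsimony length minus the per-site
#' minimum) is compared to its distribution under `R` replicate datasets
#' simulated from a fitted model on its tree. A positive z-score means the
#' observed data carry more homoplasy than the model predicts — the
#' signature of a model underestimating convergence.
#'
#' @param aln Observed [msa].
#' @param tree Tree used for the parsimony statistic.
#' @param fit `het_fit` to simulate replicates from.
#' @param R Number of replicates (`>= 1`).
#' @param seed Integer seed.
#' @return A `ppred_homoplasy` list: `h_obs`, `h_sim` (vector), `z`
#'   (`NA` when the simulated spread is zero), `p` (upper-tail,
#'   add-one Monte Carlo).
#' @export
ppred_homoplasy <- function(aln, tree, fit, R = 100, seed = 1L) {
  if (R < 1) abort("R must be >= 1")
  h_obs <- homoplasy_excess(tree, aln)
  L <- n_sites(aln)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, R)
  h_sim <- vapply(seq_len(R), function(r) {
    rep_aln <- simulate_under_fit(fit, L, seed = rep_seeds[r])
    homoplasy_excess(tree, rep_aln)
  }, numeric(1))
  s <- stats::sd(h_sim)
  z <- if (is.na(s) || s == 0) NA_real_ else (h_obs - mean(h_sim)) / s
  p <- (1 + sum(h_sim >= h_obs)) / (R + 1)
  structure(list(h_obs = h_obs, h_sim = h_sim, z = z, p = p, R = R,
                 seed = seed), class = "ppred_homoplasy")
}

#' @export
print.ppred_homoplasy <- function(x, ...) {
  cat(sprintf("Posterior-predictive homoplasy: observed %d, simulated %.1f +/- %.1f, z = %s, p = %.3g\n",
              x$h_obs, mean(x$h_sim), stats::sd(x$h_sim),
              ifelse(is.na(x$z), "NA", sprintf("%.2f", x$z)), x$p))
  invisible(x)
}
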