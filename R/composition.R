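# Base-composition statistics and the posterior-predictive compositional
# homogeneity test. Frequencies are always over unambiguous residues only
# (gaps and ambiguity codes excluded from denominators).

#' Per-taxon residue composition
#'
#' Frequencies of each residue class per taxon (optionally per codon
#' position), with A+T content for nucleotide data and across-taxon mean and
#' sample standard deviation attached as attributes.
#'
#' @param aln An [msa].
#' @param by_codon_position Split PCG columns by codon position (requires
#'   column annotation).
#' @return Tibble: `taxon`, one `freq_*` column per residue class, `n_used`
#'   (unambiguous residues) and, for nucleotides, `at_content`. Attributes
#'   `mean_at` / `sd_at` give the across-taxon summary.
#' @export
composition_table <- function(aln, by_codon_position = FALSE) {
  states <- if (aln$alphabet == "nucleotide") NT_STATES else AA_STATES
  codes <- msa_codes(aln)
  one_block <- function(cd, label = NA_integer_) {
    counts <- t(apply(cd, 1, tabulate, nbins = length(states)))
    n_used <- rowSums(counts)
    freq <- counts / ifelse(n_used == 0, NA_real_, n_used)
    colnames(freq) <- paste0("freq_", states)
    out <- dplyr::bind_cols(tibble(taxon = rownames(cd)), as_tibble(freq))
    out$n_used <- as.integer(n_used)
    if (aln$alphabet == "nucleotide") {
      out$at_content <- out$freq_A + out$freq_T
    }
    if (by_codon_position) out <- dplyr::mutate(out, codon_pos = label, .after = "taxon")
    out
  }
  if (by_codon_position) {
    if (is.null(aln$cols) || !"codon_pos" %in% names(aln$cols)) {
      abort("per-codon-position composition needs column annotations")
    }
    res <- purrr::map(1:3, function(p) {
      ix <- which(!is.na(aln$cols$codon_pos) & aln$cols$codon_pos == p)
      one_block(codes[, ix, drop = FALSE], p)
    })
    out <- dplyr::bind_rows(res)
  } else {
    out <- one_block(codes)
  }
  if (aln$alphabet == "nucleotide" && !by_codon_position) {
    attr(out, "mean_at") <- mean(out$at_content, na.rm = TRUE)
    attr(out, "sd_at") <- stats::sd(out$at_content)
  }
  out
}

#' Chi-square test of compositional homogeneity
#'
#' Pearson chi-square on the taxa-by-residue count table (unambiguous
#' residues only); residue classes with zero total count are dropped and
#' noted. A conventional quick companion to the posterior-predictive test —
#' note it ignores phylogenetic correlation, so it is calibrated for
#' independent sequences, anti-conservative on a tree.
#'
#' @param aln An [msa] with at least 2 taxa.
#' @return List (`comp_chi2`) with `statistic`, `df`, `p_value`,
#'   `dropped_classes`, and the count `table`.
#' @export
chi2_homogeneity <- function(aln) {
  if (n_taxa(aln) < 2) abort("need at least 2 taxa")
  states <- if (aln$alphabet == "nucleotide") NT_STATES else AA_STATES
  codes <- msa_codes(aln)
  counts <- t(apply(codes, 1, tabulate, nbins = length(states)))
  colnames(counts) <- states
  rownames(counts) <- rownames(codes)
  dropped <- colnames(counts)[colSums(counts) == 0]
  counts <- counts[, colSums(counts) > 0, drop = FALSE]
  if (ncol(counts) < 2) abort("fewer than two residue classes with data")
  E <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  stat <- sum((counts - E)^2 / E)
  df <- (nrow(counts) - 1) * (ncol(counts) - 1)
  structure(list(statistic = stat, df = df,
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE),
                 dropped_classes = dropped, table = counts),
            class = "comp_chi2")
}

#' @export
print.comp_chi2 <- function(x, ...) {
  cat(sprintf("Chi-square compositional homogeneity: X2 = %.3f, df = %d, p = %.3g\n",
              x$statistic, x$df, x$p_value))
  if (length(x$dropped_classes)) {
    cat("  dropped empty classes:", paste(x$dropped_classes, collapse = ", "), "\n")
  }
  invisible(x)
}

# per-taxon L1 deviation from pooled composition
comp_deviation <- function(codes, k) {
  counts <- t(apply(codes, 1, tabulate, nbins = k))
  tot <- colSums(counts)
  fg <- tot / sum(tot)
  n <- rowSums(counts)
  f <- counts / ifelse(n == 0, NA_real_, n)
  rowSums(abs(f - rep(fg, each = nrow(f))))
}

#' Posterior-predictive test of compositional homogeneity
#'
#' For each taxon the observed statistic is the L1 distance between its
#' composition and the pooled composition. `R` replicate alignments are
#' simulated under the fitted (homogeneous) model on the fitted tree; the
#' Monte-Carlo p-value per taxon is `(1 + #{replicate >= observed}) / (R+1)`.
#' Taxa with `p < alpha` are flagged as compositionally heterogeneous.
#'
#' @param aln Observed [msa].
#' @param fit Homogeneous `het_fit` (single profile) on the same taxa.
#' @param R Number of posterior-predictive replicates.
#' @param alpha Flagging level.
#' @param seed Integer seed.
#' @return Tibble (`comp_ppred`): `taxon`, `statistic`, `p_value`, `flagged`;
#'   attributes `R`, `alpha`, `seed`.
#' @export
ppred_composition_test <- function(aln, fit, R = 100, alpha = 0.05, seed = 1L) {
  if (nrow(fit$profiles) != 1) {
    abort("posterior-predictive composition test needs a homogeneous (C = 1) fit")
  }
  if (!setequal(msa_taxa(aln), fit$tree$tip.label)) {
    abort("fit and alignment taxa differ")
  }
  if (R < 20) warn("R < 20 gives a very coarse p-value resolution")
  k <- fit$k
  codes <- msa_codes(aln)
  obs <- comp_deviation(codes, k)
  L <- n_sites(aln)
  exceed <- setNames(rep(0L, length(obs)), names(obs))
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, R)
  for (r in seq_len(R)) {
    rep_aln <- simulate_under_fit(fit, L, seed = rep_seeds[r])
    stat <- comp_deviation(msa_codes(rep_aln)[names(obs), , drop = FALSE], k)
    exceed <- exceed + as.integer(stat >= obs)
  }
  p <- (1 + exceed) / (R + 1)
  out <- tibble(taxon = names(obs), statistic = unname(obs),
                p_value = unname(p), flagged = unname(p < alpha))
  attr(out, "R") <- R; attr(out, "alpha") <- alpha; attr(out, "seed") <- seed
  class(out) <- c("comp_ppred", class(out))
  out
}
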