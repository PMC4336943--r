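# Pairwise heterogeneous-sequence-divergence scoring: a sliding-window
# similarity score calibrated against a within-pair randomization null, in
# [-1, +1]. Negative scores mean a pair looks no more similar than randomly
# shuffled sequences of the same composition (mutual saturation /
# heterogeneous divergence); positive scores mean non-random similarity.
# This is an in-house scorer in the spirit of published divergence-matrix
# tools, not a byte-level re-implementation of any of them.

#' Scoring scheme for divergence scoring
#'
#' Nucleotides score match/mismatch (default +1/0); amino acids use
#' BLOSUM62. Gaps and ambiguity are excluded from scoring.
#'
#' @param alphabet `"nucleotide"` or `"amino_acid"`.
#' @param match,mismatch Nucleotide scores.
#' @return A `scoring_scheme`: list with the residue score matrix.
#' @export
scoring_scheme <- function(alphabet = c("nucleotide", "amino_acid"),
                           match = 1, mismatch = 0) {
  alphabet <- match.arg(alphabet)
  if (alphabet == "nucleotide") {
    m <- matrix(mismatch, 4, 4, dimnames = list(NT_STATES, NT_STATES))
    diag(m) <- match
  } else {
    if (!requireNamespace("Biostrings", quietly = TRUE)) {
      abort("amino-acid scoring needs the Biostrings package (BLOSUM62)")
    }
    b62 <- get(utils::data("BLOSUM62", package = "Biostrings",
                           envir = environment()))
    m <- b62[AA_STATES, AA_STATES]
  }
  structure(list(alphabet = alphabet, S = m), class = "scoring_scheme")
}

#' Heterogeneous-divergence score for one taxon pair
#'
#' Sliding windows (stride = half window) score the mean residue similarity
#' of the pair over columns where both taxa are unambiguous. The null
#' distribution per window comes from `shuffles` random permutations of the
#' second taxon's residues across the pair's scorable columns. Each window
#' score is `(obs - null_mean)` normalized by the attainable range above
#' (or below) the null mean and clipped to `[-1, 1]`; the pair score is the
#' mean over windows with at least `window/2` scorable columns.
#'
#' @param aln An [msa].
#' @param i,j Taxon labels or indices.
#' @param scheme A [scoring_scheme()]; default chosen by alphabet.
#' @param window Window size in columns (`>= 5`); `"auto"` gives
#'   `max(20, floor(L/50))`.
#' @param shuffles Number of permutations (`>= 20`).
#' @param seed Integer seed.
#' @return Scalar score in `[-1, 1]`, `+1` for `i == j`, `NA` if no window
#'   is scorable.
#' @export
pair_score <- function(aln, i, j, scheme = NULL, window = "auto",
                       shuffles = 100, seed = 1L) {
  if (is.character(i)) i <- match(i, msa_taxa(aln))
  if (is.character(j)) j <- match(j, msa_taxa(aln))
  if (anyNA(c(i, j))) abort("taxon not found")
  if (i == j) return(1)
  scheme <- scheme %||% scoring_scheme(aln$alphabet)
  L <- n_sites(aln)
  if (identical(window, "auto")) window <- max(20, L %/% 50)
  if (window < 5) abort("window must be >= 5")
  if (shuffles < 20) abort("shuffles must be >= 20")
  codes <- msa_codes(aln)
  xi <- codes[i, ]; xj <- codes[j, ]
  sc <- xi > 0L & xj > 0L
  if (!any(sc)) return(NA_real_)
  S <- scheme$S
  row_min <- apply(S, 1, min)
  s_obs <- rep(0, L); s_max <- rep(0, L); s_min <- rep(0, L)
  s_obs[sc] <- S[cbind(xi[sc], xj[sc])]
  s_max[sc] <- S[cbind(xi[sc], xi[sc])]
  s_min[sc] <- row_min[xi[sc]]
  set.seed(seed)
  xj_sc <- xj[sc]
  s_perm <- vapply(seq_len(shuffles), function(r) {
    v <- rep(0, L)
    v[sc] <- S[cbind(xi[sc], sample(xj_sc))]
    v
  }, numeric(L))
  stride <- max(1L, window %/% 2L)
  starts <- seq.int(1L, max(1L, L - window + 1L), by = stride)
  csum <- function(v) cumsum(c(0, v))
  c_sc <- csum(sc); c_obs <- csum(s_obs); c_max <- csum(s_max); c_min <- csum(s_min)
  c_perm <- apply(rbind(0, s_perm), 2, cumsum)
  win <- function(cs, a, b) cs[b + 1] - cs[a]
  scores <- vapply(starts, function(a) {
    b <- min(L, a + window - 1L)
    n_sc <- win(c_sc, a, b)
    if (n_sc < window / 2) return(NA_real_)
    obs <- win(c_obs, a, b) / n_sc
    mx <- win(c_max, a, b) / n_sc
    mn <- win(c_min, a, b) / n_sc
    null_mean <- mean((c_perm[b + 1, ] - c_perm[a, ]) / n_sc)
    if (obs >= null_mean) {
      den <- mx - null_mean
      if (den <= 1e-12) 0 else min(1, (obs - null_mean) / den)
    } else {
      den <- null_mean - mn
      if (den <= 1e-12) 0 else max(-1, (obs - null_mean) / den)
    }
  }, numeric(1))
  if (all(is.na(scores))) return(NA_real_)
  mean(scores, na.rm = TRUE)
}

#' Heterogeneous-divergence matrix
#'
#' [pair_score()] for every taxon pair. Diagonal is `+1` by convention.
#'
#' @inheritParams pair_score
#' @return A `divergence_matrix`: symmetric numeric matrix in `[-1, 1]` with
#'   attributes `window`, `shuffles`, `seed`. Supports [autoplot()].
#' @export
heterogeneity_matrix <- function(aln, scheme = NULL, window = "auto",
                                 shuffles = 100, seed = 1L) {
  taxa <- msa_taxa(aln)
  n <- length(taxa)
  scheme <- scheme %||% scoring_scheme(aln$alphabet)
  m <- matrix(1, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    m[i, j] <- m[j, i] <- pair_score(aln, i, j, scheme, window, shuffles,
                                     seed = seed + i * n + j)
  }
  structure(m, window = window, shuffles = shuffles, seed = seed,
            class = c("divergence_matrix", "matrix"))
}

#' @export
print.divergence_matrix <- function(x, ...) {
  cat(sprintf("<divergence_matrix> %d taxa; mean off-diagonal score %.3f\n",
              nrow(x), mean(x[upper.tri(x)], na.rm = TRUE)))
  invisible(x)
}
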