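# Nonsynonymous substitution rate (Ka) by the Nei-Gojobori (1986) method
# under the invertebrate mitochondrial code, tip-to-ancestor branch lengths,
# and their correlation.

# Per-codon nonsynonymous site count: at each position, the fraction of the
# three possible single-nucleotide changes that are nonsynonymous (changes to
# stop codons count as nonsynonymous).
codon_n_sites <- local({
  cache <- new.env(parent = emptyenv())
  function(codon) {
    if (!is.null(cache[[codon]])) return(cache[[codon]])
    aa <- codon_table[[codon]]
    n <- 0
    for (pos in 1:3) {
      for (b in NT_STATES) {
        if (b == substr(codon, pos, pos)) next
        mut <- codon
        substr(mut, pos, pos) <- b
        if (codon_table[[mut]] != aa || codon_table[[mut]] == "*") n <- n + 1 / 3
      }
    }
    cache[[codon]] <- n
    n
  }
})

# Average (Nd, Sd) over all minimal substitution pathways between two codons.
# Pathways passing through a stop codon are excluded unless none remain.
codon_path_counts <- function(c1, c2) {
  diff_pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  nd <- length(diff_pos)
  if (nd == 0) return(c(Nd = 0, Sd = 0))
  perms <- if (nd == 1) list(diff_pos) else {
    if (nd == 2) list(diff_pos, rev(diff_pos)) else {
      p <- list()
      for (a in 1:3) for (b in setdiff(1:3, a)) {
        p[[length(p) + 1]] <- diff_pos[c(a, b, setdiff(1:3, c(a, b)))]
      }
      p
    }
  }
  score_path <- function(ord) {
    cur <- c1; ndn <- 0; sdn <- 0; via_stop <- FALSE
    for (pos in ord) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(c2, pos, pos)
      a1 <- codon_table[[cur]]; a2 <- codon_table[[nxt]]
      if (a2 == "*" && nxt != c2) via_stop <- TRUE
      if (a1 == a2 && a1 != "*") sdn <- sdn + 1 else ndn <- ndn + 1
      cur <- nxt
    }
    c(ndn, sdn, via_stop)
  }
  sc <- t(vapply(perms, score_path, numeric(3)))
  keep <- sc[, 3] == 0
  if (!any(keep)) keep <- rep(TRUE, nrow(sc))
  c(Nd = mean(sc[keep, 1]), Sd = mean(sc[keep, 2]))
}

#' Pairwise nonsynonymous rate (Ka), Nei-Gojobori
#'
#' Nonsynonymous substitutions per nonsynonymous site between two sequences
#' of a codon-complete alignment, under the invertebrate mitochondrial code.
#' Sites are counted per Nei & Gojobori (1986) and averaged over the two
#' sequences; codons differing at several positions average the
#' nonsynonymous/synonymous split over all minimal substitution pathways
#' (pathways through stops excluded). The Jukes-Cantor correction
#' `Ka = -(3/4) log(1 - (4/3) pN)` is applied; pairwise deletion skips codon
#' pairs containing gaps, ambiguity, or stop codons.
#'
#' @param aln Codon-complete nucleotide [msa].
#' @param taxon,reference Taxon labels present in `aln`.
#' @return One-row tibble: `taxon`, `reference`, `Ka`, `pN`, `N`, `Nd`,
#'   `codons_used`, `codons_skipped`. `Ka` is `NA` when saturated
#'   (`pN >= 3/4`).
#' @export
ka_pairwise <- function(aln, taxon, reference) {
  if (aln$alphabet != "nucleotide") abort("Ka needs nucleotide data")
  L <- n_sites(aln)
  if (L %% 3 != 0) abort("alignment length must be a multiple of 3")
  if (!all(c(taxon, reference) %in% msa_taxa(aln))) abort("taxon not in alignment")
  s1 <- aln$mat[taxon, ]; s2 <- aln$mat[reference, ]
  cod1 <- apply(matrix(s1, nrow = 3), 2, paste, collapse = "")
  cod2 <- apply(matrix(s2, nrow = 3), 2, paste, collapse = "")
  clean <- function(x) grepl("^[ACGT]{3}$", x) & translate_codon(x) != "*"
  usable <- clean(cod1) & clean(cod2)
  n_skip <- sum(!usable)
  if (!any(usable)) abort("no usable codon pairs")
  cod1 <- cod1[usable]; cod2 <- cod2[usable]
  N1 <- sum(vapply(cod1, codon_n_sites, numeric(1)))
  N2 <- sum(vapply(cod2, codon_n_sites, numeric(1)))
  N <- (N1 + N2) / 2
  diffs <- cod1 != cod2
  Nd <- 0
  if (any(diffs)) {
    pc <- vapply(unique(paste(cod1[diffs], cod2[diffs])), function(key) {
      parts <- strsplit(key, " ")[[1]]
      codon_path_counts(parts[1], parts[2])["Nd"]
    }, numeric(1))
    key_all <- paste(cod1[diffs], cod2[diffs])
    Nd <- sum(pc[key_all])
  }
  pN <- Nd / N
  ka <- if (pN >= 3 / 4) NA_real_ else -(3 / 4) * log(1 - (4 / 3) * pN)
  tibble(taxon = taxon, reference = reference, Ka = ka, pN = pN, N = N,
         Nd = Nd, codons_used = sum(usable), codons_skipped = n_skip)
}

#' Ka for every taxon against a reference
#'
#' @param aln Codon-complete nucleotide [msa].
#' @param reference Reference taxon label.
#' @return Tibble with one row per non-reference taxon, in alignment order.
#' @export
ka_table <- function(aln, reference) {
  if (!reference %in% msa_taxa(aln)) abort("reference taxon not in alignment")
  others <- setdiff(msa_taxa(aln), reference)
  dplyr::bind_rows(purrr::map(others, ka_pairwise, aln = aln, reference = reference))
}

#' Tip-to-ancestor branch lengths
#'
#' Sum of branch lengths from each ingroup tip to the most recent common
#' ancestor of the ingroup, which must be monophyletic.
#'
#' @param tree Rooted `ape::phylo` with branch lengths.
#' @param ingroup_taxa Character vector of ingroup tips.
#' @return Tibble `taxon`, `branch_length`.
#' @export
tip_to_mrca_lengths <- function(tree, ingroup_taxa) {
  if (is.null(tree$edge.length)) abort("tree has no branch lengths")
  if (anyNA(tree$edge.length)) abort("missing branch length on an edge")
  if (!all(ingroup_taxa %in% tree$tip.label)) abort("ingroup taxa missing from tree")
  if (!ape::is.monophyletic(tree, ingroup_taxa)) {
    abort("ingroup is not monophyletic in the tree")
  }
  mrca <- ape::getMRCA(tree, ingroup_taxa)
  len <- vapply(ingroup_taxa, function(tx) {
    tip <- which(tree$tip.label == tx)
    nodes <- ape::nodepath(tree, tip, mrca)
    sum(vapply(seq_len(length(nodes) - 1), function(i) {
      e <- which(tree$edge[, 1] == nodes[i + 1] & tree$edge[, 2] == nodes[i] |
                 tree$edge[, 1] == nodes[i] & tree$edge[, 2] == nodes[i + 1])
      tree$edge.length[e]
    }, numeric(1)))
  }, numeric(1))
  tibble(taxon = ingroup_taxa, branch_length = unname(len))
}

#' Correlate Ka with branch length
#'
#' Pearson correlation between per-taxon Ka and tip-to-ancestor branch
#' length; taxa with undefined (saturated) Ka are excluded and listed.
#'
#' @param ka A [ka_table()] result.
#' @param lengths A [tip_to_mrca_lengths()] result.
#' @return List (`rate_correlation`): tibble `data`, `r`, `r_squared`,
#'   `excluded`.
#' @export
correlate_rates <- function(ka, lengths) {
  d <- dplyr::inner_join(ka[, c("taxon", "Ka")], lengths, by = "taxon")
  excluded <- d$taxon[is.na(d$Ka)]
  d <- d[!is.na(d$Ka), ]
  if (nrow(d) < 3) abort("need at least 3 complete (Ka, branch length) pairs")
  r <- stats::cor(d$Ka, d$branch_length)
  structure(list(data = d, r = r, r_squared = r^2, excluded = excluded),
            class = "rate_correlation")
}

#' @export
print.rate_correlation <- function(x, ...) {
  cat(sprintf("Ka vs branch length: r = %.3f, R^2 = %.3f (n = %d)\n",
              x$r, x$r_squared, nrow(x$data)))
  invisible(x)
}
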