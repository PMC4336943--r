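# Dataset assembly: concatenation of per-gene alignments, codon-position
# extraction, translation to amino acids, and column masking. The eight named
# dataset recipes (PCG, PCG12, PCGRNA, PCG12RNA, AA and their masked "-Al"
# variants) are built from these four primitives.

#' Concatenate per-gene alignments into a supermatrix
#'
#' Taxa missing from a gene are filled with `?` for that block (with a
#' warning). Column annotations carry the gene name, gene type, and a cyclic
#' codon-position label (1/2/3 from the reading-frame start) for PCG columns.
#'
#' @param gene_alns Named list of [msa] objects, one per gene.
#' @param types Optional named character vector mapping gene name to type
#'   (`"PCG"`, `"rRNA"`, `"tRNA"`); genes without a type are labelled `NA` and
#'   treated as non-coding.
#' @param order Gene order for the concatenation (default: list order).
#' @return List with `aln` (the concatenated [msa]) and `scheme`
#'   (a `partition_scheme` tibble).
#' @export
concatenate_genes <- function(gene_alns, types = NULL, order = names(gene_alns)) {
  if (is.null(names(gene_alns)) || any(names(gene_alns) == "")) {
    abort("`gene_alns` must be a named list")
  }
  if (anyDuplicated(order)) abort("duplicate gene names in concatenation order")
  gene_alns <- gene_alns[order]
  alphabet <- gene_alns[[1]]$alphabet
  taxa <- unique(unlist(lapply(gene_alns, msa_taxa)))
  miss_char <- "?"
  blocks <- list(); col_meta <- list()
  for (g in names(gene_alns)) {
    a <- gene_alns[[g]]
    if (a$alphabet != alphabet) abort("mixed alphabets across genes")
    m <- matrix(miss_char, length(taxa), ncol(a$mat), dimnames = list(taxa, NULL))
    absent <- setdiff(taxa, msa_taxa(a))
    if (length(absent)) {
      warn(sprintf("gene %s: missing taxa filled with '?': %s",
                   g, paste(absent, collapse = ", ")))
    }
    m[msa_taxa(a), ] <- a$mat
    blocks[[g]] <- m
    type <- if (!is.null(types)) unname(types[g]) else NA_character_
    cp <- if (identical(type, "PCG")) (seq_len(ncol(m)) - 1L) %% 3L + 1L else rep(NA_integer_, ncol(m))
    col_meta[[g]] <- tibble(gene = g, type = type, codon_pos = cp)
  }
  mat <- do.call(cbind, blocks)
  cols <- dplyr::bind_rows(col_meta)
  lens <- vapply(blocks, ncol, integer(1))
  ends <- cumsum(lens)
  scheme <- tibble(block = names(gene_alns),
                   datatype = if (alphabet == "nucleotide") "DNA" else "AA",
                   columns = purrr::map2(ends - lens + 1L, ends, seq.int))
  class(scheme) <- c("partition_scheme", class(scheme))
  list(aln = msa(mat, alphabet, cols), scheme = scheme)
}

#' Extract codon positions
#'
#' Keeps protein-coding columns whose codon position is in `keep`; non-PCG
#' columns (RNA genes) are always retained.
#'
#' @param aln An [msa] whose PCG columns carry `codon_pos` annotation.
#' @param keep Subset of `c(1, 2, 3)`.
#' @return An [msa].
#' @export
extract_codon_positions <- function(aln, keep = c(1, 2)) {
  if (is.null(aln$cols)) abort("alignment has no column annotations")
  is_pcg <- !is.na(aln$cols$type) & aln$cols$type == "PCG"
  if (any(is_pcg & is.na(aln$cols$codon_pos))) {
    abort("PCG column without codon-position label")
  }
  sel <- !is_pcg | aln$cols$codon_pos %in% keep
  msa_subset(aln, columns = which(sel))
}

#' Translate a protein-coding alignment
#'
#' Translates a codon-complete nucleotide alignment of protein-coding columns
#' under the invertebrate mitochondrial code. Codons containing a gap become
#' `-`; codons containing ambiguity become `X`; stop codons become `X` and
#' their count is reported via the `stops` attribute.
#'
#' @param aln An [msa] of PCG columns only, length divisible by 3.
#' @return Amino-acid [msa]; attribute `stops` holds the number of stop
#'   codons rendered as `X`.
#' @export
translate_alignment <- function(aln) {
  if (aln$alphabet != "nucleotide") abort("translation needs nucleotide input")
  L <- ncol(aln$mat)
  if (L %% 3 != 0) abort(sprintf("alignment length %d not divisible by 3", L))
  if (!is.null(aln$cols) && any(!is.na(aln$cols$type) & aln$cols$type != "PCG")) {
    abort("translation requires protein-coding columns only")
  }
  n <- nrow(aln$mat)
  first <- aln$mat[, seq(1, L, 3), drop = FALSE]
  second <- aln$mat[, seq(2, L, 3), drop = FALSE]
  third <- aln$mat[, seq(3, L, 3), drop = FALSE]
  codons <- matrix(paste0(first, second, third), nrow = n)
  aa <- matrix(translate_codon(codons), nrow = n)
  has_gap <- first == "-" | second == "-" | third == "-"
  aa[is.na(aa)] <- "X"          # codons with N/?/X
  aa[has_gap] <- "-"
  n_stop <- sum(aa == "*")
  aa[aa == "*"] <- "X"
  rownames(aa) <- rownames(aln$mat)
  cols <- NULL
  if (!is.null(aln$cols)) {
    cols <- aln$cols[seq(1, L, 3), c("gene", "type"), drop = FALSE]
  }
  out <- msa(aa, "amino_acid", cols)
  attr(out, "stops") <- n_stop
  out
}

#' Mask poorly aligned columns
#'
#' A two-threshold masking rule: a column is dropped when its gap fraction
#' exceeds `gap_threshold`, or when the share of non-gap residues that
#' disagree with the column's majority residue exceeds `mismatch_threshold`.
#' This is an in-house heuristic in the spirit of automated alignment
#' trimmers, not a re-implementation of any particular tool.
#'
#' @param aln An [msa].
#' @param gap_threshold Maximum tolerated gap fraction (in `[0,1]`).
#' @param mismatch_threshold Maximum tolerated mismatch score (in `[0,1]`).
#' @return List with `aln` (masked [msa]) and `report`, a tibble with one row
#'   per source column: `source_column`, `gap_fraction`, `mismatch`, `kept`,
#'   and `new_column` (NA for dropped columns).
#' @export
mask_columns <- function(aln, gap_threshold = 0.5, mismatch_threshold = 0.8) {
  if (gap_threshold < 0 || gap_threshold > 1 || mismatch_threshold < 0 ||
      mismatch_threshold > 1) {
    abort("masking thresholds must be in [0, 1]")
  }
  n <- nrow(aln$mat)
  gap_frac <- colSums(aln$mat == "-") / n
  unamb <- is_unambiguous(aln$mat, aln$alphabet)
  dim(unamb) <- dim(aln$mat)
  mism <- vapply(seq_len(ncol(aln$mat)), function(j) {
    res <- aln$mat[unamb[, j], j]
    if (length(res) == 0) return(1)
    1 - max(table(res)) / length(res)
  }, numeric(1))
  kept <- gap_frac <= gap_threshold & mism <= mismatch_threshold
  report <- tibble(source_column = seq_len(ncol(aln$mat)),
                   gap_fraction = gap_frac, mismatch = mism, kept = kept,
                   new_column = ifelse(kept, cumsum(kept), NA_integer_))
  attr(report, "thresholds") <- c(gap = gap_threshold, mismatch = mismatch_threshold)
  list(aln = msa_subset(aln, columns = which(kept)), report = report)
}

#' Build one of the named mitogenome datasets
#'
#' Assembles a dataset recipe from a simulated dataset (or any named list of
#' per-gene alignments plus a gene table): `PCG` (all protein-coding
#' positions), `PCG12` (third positions removed), `PCGRNA` (PCG + rRNA +
#' tRNA), `PCG12RNA`, `AA` (translated PCGs), and their per-gene-masked
#' `*_Al` variants (`PCG_Al`, `PCGRNA_Al`, `AA_Al`).
#'
#' @param x A `sim_dataset`, or a named list of [msa] per-gene alignments.
#' @param name Dataset name (case-insensitive; `-` and `_` equivalent).
#' @param genes Gene table (required when `x` is a plain list).
#' @param gap_threshold,mismatch_threshold Masking thresholds for `*_Al`.
#' @return List with `aln` and `scheme` (and `mask_reports` for `*_Al`).
#' @export
build_dataset <- function(x, name, genes = NULL,
                          gap_threshold = 0.5, mismatch_threshold = 0.8) {
  if (inherits(x, "sim_dataset")) {
    gene_alns <- x$genes
    genes <- tibble(gene = names(x$genes), type = NA_character_)
    lk <- unique(x$site_info[, c("gene", "type")])
    genes$type <- lk$type[match(genes$gene, lk$gene)]
  } else {
    gene_alns <- x
    if (is.null(genes)) abort("`genes` table required for a plain gene list")
  }
  key <- toupper(gsub("-", "_", name))
  masked <- grepl("_AL$", key)
  base <- sub("_AL$", "", key)
  if (!base %in% c("PCG", "PCG12", "PCGRNA", "PCG12RNA", "AA")) {
    abort(paste0("unknown dataset name: ", name))
  }
  types <- setNames(genes$type, genes$gene)
  use <- if (base %in% c("PCG", "PCG12", "AA")) genes$gene[genes$type == "PCG"] else genes$gene
  sel <- gene_alns[use]
  mask_reports <- NULL
  if (masked) {
    mk <- purrr::map(sel, mask_columns, gap_threshold = gap_threshold,
                     mismatch_threshold = mismatch_threshold)
    sel <- purrr::map(mk, "aln")
    mask_reports <- purrr::map(mk, "report")
  }
  cc <- concatenate_genes(sel, types = types)
  out <- cc
  if (base %in% c("PCG12", "PCG12RNA")) {
    out$aln <- extract_codon_positions(cc$aln, keep = c(1, 2))
    out$scheme <- scheme_from_cols(out$aln)
  }
  if (base == "AA") {
    out$aln <- translate_alignment(cc$aln)
    out$scheme <- scheme_from_cols(out$aln)
  }
  out$name <- name
  out$mask_reports <- mask_reports
  out
}

# rebuild a contiguous partition scheme from column annotations
scheme_from_cols <- function(aln) {
  g <- aln$cols$gene
  runs <- rle(g)
  ends <- cumsum(runs$lengths)
  scheme <- tibble(block = runs$values,
                   datatype = if (aln$alphabet == "nucleotide") "DNA" else "AA",
                   columns = purrr::map2(ends - runs$lengths + 1L, ends, seq.int))
  class(scheme) <- c("partition_scheme", class(scheme))
  scheme
}
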