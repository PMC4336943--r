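#' @importFrom tibble tibble as_tibble
#' @importFrom rlang abort warn %||%
#' @importFrom stats setNames
NULL

NT_CHARS <- c("A", "C", "G", "T", "-", "N", "?", "X")
AA_CHARS <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
              "M", "F", "P", "S", "T", "W", "Y", "V", "-", "X", "?", "*")
NT_STATES <- c("A", "C", "G", "T")
AA_STATES <- AA_CHARS[1:20]

#' Multiple sequence alignment container
#'
#' An `msa` object wraps a taxa-by-columns character matrix together with its
#' declared alphabet and optional per-column annotations (source gene, gene
#' type, codon position). All downstream diagnostics in hetphylo operate on
#' this container.
#'
#' @param mat Character matrix, rows named by taxon.
#' @param alphabet `"nucleotide"` or `"amino_acid"`.
#' @param cols Optional per-column annotation: a data frame with one row per
#'   alignment column and columns `gene`, `type` (`"PCG"`, `"rRNA"`, `"tRNA"`
#'   or `NA`) and `codon_pos` (1, 2, 3 or `NA`).
#' @return An object of class `msa`.
#' @export
msa <- function(mat, alphabet = c("nucleotide", "amino_acid"), cols = NULL) {
  alphabet <- match.arg(alphabet)
  if (!is.matrix(mat) || !is.character(mat)) {
    abort("`mat` must be a character matrix of single residues.")
  }
  if (is.null(rownames(mat)) || anyNA(rownames(mat)) || any(rownames(mat) == "")) {
    abort("alignment rows must be named by taxon")
  }
  rownames(mat) <- gsub("\\s+", "_", trimws(rownames(mat)))
  if (anyDuplicated(rownames(mat))) {
    abort(paste0("duplicate taxon id: ", rownames(mat)[duplicated(rownames(mat))][1]))
  }
  mat[] <- toupper(mat)
  if (alphabet == "nucleotide") mat[mat == "U"] <- "T"
  legal <- if (alphabet == "nucleotide") NT_CHARS else AA_CHARS
  bad <- which(!(mat %in% legal))
  if (length(bad) > 0) {
    i <- arrayInd(bad[1], dim(mat))
    abort(sprintf("illegal character '%s' for %s alphabet (taxon %s, column %d)",
                  mat[bad[1]], alphabet, rownames(mat)[i[1]], i[2]))
  }
  if (!is.null(cols)) {
    cols <- as_tibble(cols)
    if (nrow(cols) != ncol(mat)) {
      abort("`cols` must have one row per alignment column")
    }
  }
  structure(list(mat = mat, alphabet = alphabet, cols = cols), class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("<msa> %d taxa x %d columns (%s)\n",
              nrow(x$mat), ncol(x$mat), x$alphabet))
  if (!is.null(x$cols) && !is.null(x$cols$gene)) {
    cat("  genes:", length(unique(x$cols$gene)), "\n")
  }
  invisible(x)
}

#' @export
dim.msa <- function(x) dim(x$mat)

#' Number of taxa / columns of an alignment
#' @param x An `msa`.
#' @return Integer scalar.
#' @export
n_taxa <- function(x) nrow(x$mat)

#' @rdname n_taxa
#' @export
n_sites <- function(x) ncol(x$mat)

#' Taxon labels of an alignment
#' @param x An `msa`.
#' @return Character vector of taxon ids in row order.
#' @export
msa_taxa <- function(x) rownames(x$mat)

#' Subset an alignment
#'
#' Selects taxa and/or columns, carrying the per-column annotation along.
#'
#' @param x An `msa`.
#' @param taxa Character or integer selector of rows (default all).
#' @param columns Integer selector of columns (default all).
#' @return An `msa`.
#' @export
msa_subset <- function(x, taxa = NULL, columns = NULL) {
  mat <- x$mat
  cols <- x$cols
  if (!is.null(taxa)) {
    if (is.character(taxa)) {
      missing <- setdiff(taxa, rownames(mat))
      if (length(missing)) abort(paste0("taxa not in alignment: ", paste(missing, collapse = ", ")))
    }
    mat <- mat[taxa, , drop = FALSE]
  }
  if (!is.null(columns)) {
    mat <- mat[, columns, drop = FALSE]
    if (!is.null(cols)) cols <- cols[columns, , drop = FALSE]
  }
  msa(mat, x$alphabet, cols)
}

#' Convert an alignment to a tibble
#'
#' One row per taxon per column; useful for dplyr-style summaries.
#'
#' @param x An `msa`.
#' @param ... Unused.
#' @return A tibble with `taxon`, `column`, `residue`, plus any per-column
#'   annotation fields.
#' @export
as_tibble.msa <- function(x, ...) {
  out <- tibble(
    taxon = rep(rownames(x$mat), times = ncol(x$mat)),
    column = rep(seq_len(ncol(x$mat)), each = nrow(x$mat)),
    residue = as.vector(x$mat)
  )
  if (!is.null(x$cols)) {
    out <- dplyr::bind_cols(out, x$cols[out$column, , drop = FALSE])
  }
  out
}

# state set per character, as index vector into the state alphabet;
# gap and full ambiguity give the empty/full set per `gap_as`.
state_sets <- function(alphabet) {
  if (alphabet == "nucleotide") {
    states <- NT_STATES
    amb <- c("N", "?", "X")
  } else {
    states <- AA_STATES
    amb <- c("X", "?", "*")
  }
  sets <- lapply(states, function(s) match(s, states))
  names(sets) <- states
  for (a in amb) sets[[a]] <- seq_along(states)
  sets[["-"]] <- integer(0)
  sets
}

is_unambiguous <- function(chars, alphabet) {
  states <- if (alphabet == "nucleotide") NT_STATES else AA_STATES
  chars %in% states
}

# integer coding: 1..k for plain states, 0 for anything ambiguous/gap
msa_codes <- function(x) {
  states <- if (x$alphabet == "nucleotide") NT_STATES else AA_STATES
  m <- match(x$mat, states)
  m[is.na(m)] <- 0L
  matrix(m, nrow = nrow(x$mat), dimnames = dimnames(x$mat))
}
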