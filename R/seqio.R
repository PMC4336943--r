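#' Read a FASTA alignment
#'
#' Parses aligned FASTA into an [msa]. Sequences are upper-cased and, for the
#' nucleotide alphabet, `U` is normalized to `T`. All records must have equal
#' length; a ragged file is an error naming the offending record.
#'
#' @param x Path to a FASTA file, or a character string/vector of FASTA text.
#' @param alphabet `"nucleotide"` or `"amino_acid"`.
#' @return An [msa].
#' @export
read_fasta <- function(x, alphabet = c("nucleotide", "amino_acid")) {
  alphabet <- match.arg(alphabet)
  lines <- slurp_lines(x)
  lines <- sub("\\s+$", "", lines)
  lines <- lines[lines != ""]
  hdr <- grepl("^>", lines)
  if (!any(hdr) || !hdr[1]) abort("not FASTA: no leading '>' header")
  idx <- cumsum(hdr)
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- sub("\\s.*$", "", ids)
  seqs <- vapply(split(lines[!hdr], idx[!hdr]),
                 function(ss) paste(ss, collapse = ""), character(1))
  if (length(seqs) != length(ids)) abort("FASTA record with no sequence lines")
  lens <- nchar(seqs)
  if (any(lens == 0)) abort(paste0("empty sequence for record ", ids[lens == 0][1]))
  if (length(unique(lens)) > 1) {
    bad <- ids[lens != lens[1]][1]
    abort(sprintf("ragged alignment: record '%s' has length %d, expected %d",
                  bad, lens[ids == bad][1], lens[1]))
  }
  mat <- do.call(rbind, strsplit(seqs, ""))
  rownames(mat) <- ids
  msa(mat, alphabet)
}

#' Write a FASTA alignment
#'
#' @param aln An [msa].
#' @param path Output file path.
#' @param width Line-wrap width for sequence lines.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(aln, path, width = 70) {
  seqs <- apply(aln$mat, 1, paste, collapse = "")
  out <- character(0)
  for (i in seq_along(seqs)) {
    body <- gsub(sprintf("(.{1,%d})", width), "\\1\n", seqs[i])
    out <- c(out, paste0(">", names(seqs)[i]), strsplit(body, "\n")[[1]])
  }
  writeLines(out, path)
  invisible(path)
}

#' Read/write relaxed PHYLIP
#'
#' Relaxed PHYLIP: a header line `ntaxa nchar`, then one record per line as
#' `label<space>sequence`, labels up to 250 characters with no whitespace.
#'
#' @param x Path or character text.
#' @param alphabet `"nucleotide"` or `"amino_acid"`.
#' @return An [msa] (reader) or `path` invisibly (writer).
#' @export
read_relaxed_phylip <- function(x, alphabet = c("nucleotide", "amino_acid")) {
  alphabet <- match.arg(alphabet)
  lines <- slurp_lines(x)
  lines <- lines[trimws(lines) != ""]
  hd <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(hd) < 2) abort("bad PHYLIP header")
  nt <- as.integer(hd[1]); nc <- as.integer(hd[2])
  body <- lines[-1]
  if (length(body) != nt) abort(sprintf("PHYLIP: header says %d taxa, found %d rows", nt, length(body)))
  parts <- strsplit(trimws(body), "\\s+")
  ids <- vapply(parts, `[`, character(1), 1)
  seqs <- vapply(parts, function(p) paste(p[-1], collapse = ""), character(1))
  if (any(nchar(seqs) != nc)) {
    bad <- ids[nchar(seqs) != nc][1]
    abort(sprintf("PHYLIP: record '%s' length %d != header %d", bad,
                  nchar(seqs[ids == bad][1]), nc))
  }
  mat <- do.call(rbind, strsplit(seqs, ""))
  rownames(mat) <- ids
  msa(mat, alphabet)
}

#' @rdname read_relaxed_phylip
#' @param aln An [msa].
#' @param path Output file path.
#' @export
write_relaxed_phylip <- function(aln, path) {
  ids <- rownames(aln$mat)
  if (any(nchar(ids) > 250)) abort("taxon label longer than 250 characters")
  seqs <- apply(aln$mat, 1, paste, collapse = "")
  writeLines(c(sprintf("%d %d", nrow(aln$mat), ncol(aln$mat)),
               paste(ids, seqs)), path)
  invisible(path)
}

#' Read/write newick trees
#'
#' Thin wrappers over ape's newick parser/writer so that trees round-trip
#' (topology, branch lengths to 1e-9, node support labels).
#'
#' @param x Path to a newick file or a newick string.
#' @return An `ape::phylo` (reader) or `path`/string (writer).
#' @export
read_newick <- function(x) {
  if (length(x) == 1 && !grepl("\\(", x) && file.exists(x)) {
    tr <- ape::read.tree(x)
  } else {
    tr <- ape::read.tree(text = paste(x, collapse = ""))
  }
  if (is.null(tr)) abort("failed to parse newick input")
  tr
}

#' @rdname read_newick
#' @param tree An `ape::phylo`.
#' @param path Output path; if `NULL` the newick string is returned.
#' @export
write_newick <- function(tree, path = NULL) {
  txt <- ape::write.tree(tree, digits = 12)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

#' Read a RAxML-style partition specification
#'
#' Lines of the form `DNA, cox1 = 1-1534` with 1-based inclusive ranges;
#' a `\3` suffix denotes a codon-position stride (every third column from the
#' range start), and multiple comma-separated ranges are unioned.
#'
#' @param x Path or character text.
#' @param n_col Optional alignment length used to bound-check ranges.
#' @return A `partition_scheme`: tibble with `block`, `datatype` and a
#'   `columns` list-column of sorted 1-based column indices.
#' @export
read_partition_spec <- function(x, n_col = NULL) {
  lines <- slurp_lines(x)
  lines <- trimws(lines)
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  blocks <- purrr::map(lines, parse_partition_line)
  out <- dplyr::bind_rows(blocks)
  if (anyDuplicated(out$block)) abort("duplicate partition block names")
  all_cols <- unlist(out$columns)
  dup <- unique(all_cols[duplicated(all_cols)])
  if (length(dup) > 0) {
    abort(sprintf("overlapping partition ranges at columns %s",
                  paste(utils::head(dup, 5), collapse = ",")))
  }
  if (!is.null(n_col) && length(all_cols) && max(all_cols) > n_col) {
    abort(sprintf("partition range exceeds alignment length (%d > %d)",
                  max(all_cols), n_col))
  }
  class(out) <- c("partition_scheme", class(out))
  out
}

parse_partition_line <- function(line) {
  m <- regmatches(line, regexec("^([A-Za-z]+)\\s*,\\s*([^=]+?)\\s*=\\s*(.+)$", line))[[1]]
  if (length(m) != 4) abort(paste0("cannot parse partition line: ", line))
  ranges <- strsplit(m[4], ",")[[1]]
  cols <- integer(0)
  for (r in trimws(ranges)) {
    rm <- regmatches(r, regexec("^(\\d+)\\s*-\\s*(\\d+)(\\\\(\\d+))?$", r))[[1]]
    if (length(rm) == 0) {
      rm1 <- regmatches(r, regexec("^(\\d+)$", r))[[1]]
      if (length(rm1) == 0) abort(paste0("cannot parse range: ", r))
      cols <- c(cols, as.integer(rm1[2]))
      next
    }
    a <- as.integer(rm[2]); b <- as.integer(rm[3])
    if (a > b) abort(paste0("descending range: ", r))
    stride <- if (rm[4] != "") as.integer(rm[5]) else 1L
    cols <- c(cols, seq.int(a, b, by = stride))
  }
  tibble(block = trimws(m[3]), datatype = toupper(m[2]),
         columns = list(sort(unique(cols))))
}

#' Write a partition scheme
#'
#' Emits contiguous ranges in the RAxML dialect; non-contiguous blocks are
#' written as comma-separated runs.
#'
#' @param scheme A `partition_scheme` tibble.
#' @param path Output path; `NULL` returns the text.
#' @return The text lines, invisibly when written to `path`.
#' @export
write_partition_spec <- function(scheme, path = NULL) {
  fmt_run <- function(cols) {
    br <- c(0, which(diff(cols) != 1), length(cols))
    runs <- purrr::map_chr(seq_len(length(br) - 1), function(i) {
      seg <- cols[(br[i] + 1):br[i + 1]]
      if (length(seg) == 1) as.character(seg) else sprintf("%d-%d", seg[1], seg[length(seg)])
    })
    paste(runs, collapse = ", ")
  }
  lines <- purrr::map_chr(seq_len(nrow(scheme)), function(i) {
    sprintf("%s, %s = %s", scheme$datatype[i], scheme$block[i], fmt_run(scheme$columns[[i]]))
  })
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

slurp_lines <- function(x) {
  if (length(x) == 1 && !grepl("[\n>]", x) && file.exists(x)) {
    readLines(x, warn = FALSE)
  } else {
    unlist(strsplit(x, "\n", fixed = TRUE))
  }
}
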