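# Invertebrate mitochondrial genetic code (NCBI translation table 5).
# Codon order: first/second/third base each cycling T, C, A, G.
INVERT_MITO_AA <- "FFLLSSSSYY**CCWWLLLLPPPPHHQQRRRRIIMMTTTTNNKKSSSSVVVVAAAADDEEGGGG"

codon_table <- local({
  b <- c("T", "C", "A", "G")
  codons <- as.vector(t(outer(as.vector(t(outer(b, b, paste0))), b, paste0)))
  setNames(strsplit(INVERT_MITO_AA, "")[[1]], codons)
})

#' Translate a codon under the invertebrate mitochondrial code
#'
#' @param codon Character vector of 3-letter nucleotide codons.
#' @return Amino-acid characters; `"*"` for stop codons, `NA` for codons
#'   containing anything other than A/C/G/T.
#' @export
translate_codon <- function(codon) {
  unname(codon_table[toupper(codon)])
}

#' The invertebrate mitochondrial codon table
#'
#' @return Named character vector mapping all 64 codons to amino acids
#'   (`"*"` = stop).
#' @export
invert_mito_code <- function() codon_table
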