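# Shared helpers: tiny alignments and simulations built in code.

tiny_msa <- function(seqs, alphabet = "nucleotide") {
  mat <- do.call(rbind, strsplit(seqs, ""))
  rownames(mat) <- names(seqs)
  msa(mat, alphabet)
}

# quick one-gene simulation under a plain reversible model
quick_sim <- function(newick, n_sites, seed, exch = rep(1, 6),
                      freq = rep(0.25, 4), gamma_shape = Inf, scale = 1) {
  tr <- read_newick(newick)
  tr$edge.length <- tr$edge.length * scale
  cfg <- simulation_config(tr, exch = exch, freq = freq,
                           gamma_shape = gamma_shape,
                           codon_scalers = c(1, 1, 1), seed = seed)
  simulate_dataset(cfg, tibble::tibble(gene = "g", type = "rRNA",
                                       length = as.integer(n_sites)))
}

balanced6 <- "((a:0.2,b:0.3):0.08,(c:0.25,d:0.2):0.08,(e:0.25,f:0.3):0.05);"

# the 29-taxon fixture is reused across several test files; build it once
paraneoptera_cached <- local({
  env <- new.env()
  function(seed = 1) {
    key <- paste0("s", seed)
    if (is.null(env[[key]])) env[[key]] <- make_paraneoptera_fixture(seed = seed)
    env[[key]]
  }
})

# simple p-distance NJ inference for LBE tests
infer_pnj <- function(a) {
  d <- p_distance(a)
  if (anyNA(d)) d[is.na(d)] <- max(d, na.rm = TRUE) * 1.5
  suppressWarnings(neighbor_joining(d))
}
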