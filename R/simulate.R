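# Synthetic-data generator: evolves nucleotide alignments along a tree under
# a reversible base model, with discrete-gamma and codon-position rate
# variation and optional lineage-specific overrides (rate multiplier and/or a
# replacement stationary composition switched on at the clade's stem branch,
# i.e. a non-stationary process).

#' Simulation configuration
#'
#' @param tree Rooted or unrooted `ape::phylo` with branch lengths
#'   (substitutions/site under the base model).
#' @param exch Six GTR exchangeabilities in order AC, AG, AT, CG, CT, GT.
#' @param freq Base stationary composition (A, C, G, T; sums to 1).
#' @param gamma_shape Discrete-gamma shape; `Inf` disables rate variation.
#' @param k_gamma Number of gamma categories.
#' @param codon_scalers Relative rates of codon positions 1, 2, 3 (applied to
#'   protein-coding columns; RNA columns get scaler 1). Third position fastest
#'   by default.
#' @param lineage_overrides List of overrides, each a list with `clade`
#'   (character vector of tip labels forming a monophyletic group), `rate`
#'   (branch-length multiplier > 0) and optionally `freq` (replacement
#'   composition used on all branches inside the clade, including its stem).
#' @param seed Integer seed; all randomness in the simulator flows from it.
#' @return A `sim_config` list.
#' @export
simulation_config <- function(tree,
                              exch = c(1, 4, 1, 1, 4, 1),
                              freq = at_rich_freq(0.75),
                              gamma_shape = 0.5,
                              k_gamma = 4,
                              codon_scalers = c(0.7, 0.45, 1.85),
                              lineage_overrides = list(),
                              seed = 1L) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) abort("config tree needs branch lengths")
  if (any(tree$edge.length < 0)) abort("negative branch length in config tree")
  freq <- as.numeric(freq)
  if (length(freq) != 4 || abs(sum(freq) - 1) > 1e-12) {
    abort("`freq` must be 4 frequencies summing to 1")
  }
  if (length(exch) != 6 || any(exch < 0)) abort("`exch` must be 6 non-negative reals")
  if (!identical(gamma_shape, Inf) && gamma_shape <= 0) abort("gamma shape must be > 0")
  if (any(codon_scalers <= 0)) abort("codon position scalers must be > 0")
  for (ov in lineage_overrides) {
    if (is.null(ov$clade) || !all(ov$clade %in% tree$tip.label)) {
      abort("override clade contains taxa absent from the tree")
    }
    if (!is.null(ov$rate) && ov$rate <= 0) abort("override rate multiplier must be > 0")
    if (!is.null(ov$freq) && abs(sum(ov$freq) - 1) > 1e-12) {
      abort("override composition must sum to 1")
    }
  }
  structure(list(tree = tree, exch = exch, freq = freq,
                 gamma_shape = gamma_shape, k_gamma = k_gamma,
                 codon_scalers = codon_scalers,
                 lineage_overrides = lineage_overrides, seed = as.integer(seed)),
            class = "sim_config")
}

#' Gene table for a typical insect mitogenome
#'
#' Thirteen protein-coding genes (10,749 aligned nucleotides in total), two
#' rRNAs and 22 tRNAs. Applying the default exclusion list (five tRNAs not
#' alignable across all taxa) retains 17 tRNAs; the retained RNA genes total
#' 3,264 nt, so PCG + RNA = 14,013 nt.
#'
#' @param exclude tRNA genes dropped before any concatenation. The default
#'   mirrors the standard exclusion of tRNA-His, tRNA-Asn, tRNA-Met, tRNA-Ala
#'   and tRNA-Ser(AGN).
#' @return Tibble with `gene`, `type` (`PCG`/`rRNA`/`tRNA`) and `length`.
#' @export
mito_gene_table <- function(exclude = c("trnH", "trnN", "trnM", "trnA", "trnS1")) {
  pcg <- tibble(
    gene = c("atp6", "atp8", "cox1", "cox2", "cox3", "cytb", "nad1", "nad2",
             "nad3", "nad4", "nad4l", "nad5", "nad6"),
    type = "PCG",
    length = c(672L, 156L, 1530L, 681L, 783L, 1131L, 933L, 963L, 351L, 1332L,
               291L, 1437L, 489L)
  )
  rrna <- tibble(gene = c("rrnL", "rrnS"), type = "rRNA", length = c(1245L, 745L))
  trna_names <- c("trnF", "trnV", "trnL1", "trnL2", "trnI", "trnM", "trnW",
                  "trnC", "trnY", "trnS1", "trnS2", "trnP", "trnT", "trnA",
                  "trnG", "trnN", "trnD", "trnE", "trnH", "trnQ", "trnK", "trnR")
  trna_len <- rep(75L, 22)
  trna_len[trna_names == "trnR"] <- 74L
  trna <- tibble(gene = trna_names, type = "tRNA", length = trna_len)
  out <- dplyr::bind_rows(pcg, rrna, trna)
  out[!(out$gene %in% exclude), ]
}

# classify each edge by override membership; returns integer model id per
# edge (1 = base) plus the per-model composition and rate multiplier
classify_edges <- function(tree, overrides) {
  n_edge <- nrow(tree$edge)
  model_id <- rep(1L, n_edge)
  mult <- rep(1, n_edge)
  freqs <- list(NULL)  # slot 1 = base
  for (i in seq_along(overrides)) {
    ov <- overrides[[i]]
    tips <- match(ov$clade, tree$tip.label)
    if (length(tips) == 1) {
      nodes <- tips
      stem_child <- tips
    } else {
      mrca <- ape::getMRCA(tree, tips)
      desc <- phangorn::Descendants(tree, mrca, type = "tips")[[1]]
      if (!setequal(desc, tips)) {
        abort(sprintf("override clade %d is not monophyletic in the tree (boundary ambiguous)", i))
      }
      nodes <- c(unlist(phangorn::Descendants(tree, mrca, type = "all")), mrca)
      stem_child <- mrca
    }
    sel <- tree$edge[, 2] %in% nodes
    if (any(model_id[sel] != 1L)) abort("overlapping lineage overrides")
    model_id[sel] <- i + 1L
    mult[sel] <- ov$rate %||% 1
    freqs[[i + 1L]] <- ov$freq
  }
  list(model_id = model_id, mult = mult, freqs = freqs)
}

# Evolve `n_sites` sites down `tree`. `edge_model` indexes into `eigs`
# (a list of model_eigen structures); `edge_len` is the effective length;
# `site_rates` multiplies lengths per site. Returns tips-by-sites integer
# state matrix.
sim_states <- function(tree, n_sites, eigs, edge_model, edge_len, site_rates,
                       root_freq) {
  tree <- stats::reorder(tree, "cladewise")   # parents before children
  n_tip <- length(tree$tip.label)
  n_node <- max(tree$edge)
  k <- eigs[[1]]$k
  groups <- split(seq_len(n_sites), factor(signif(site_rates, 12)))
  grp_rate <- as.numeric(names(groups))
  states <- matrix(0L, n_node, n_sites)
  root <- tree$edge[1, 1]
  states[root, ] <- sample.int(k, n_sites, replace = TRUE, prob = root_freq)
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1]; chd <- tree$edge[e, 2]
    me <- eigs[[edge_model[e]]]
    for (g in seq_along(groups)) {
      idx <- groups[[g]]
      p <- pmat(me, edge_len[e] * grp_rate[g])
      ps <- states[par, idx]
      out <- integer(length(idx))
      for (s in seq_len(k)) {
        w <- which(ps == s)
        if (length(w)) out[w] <- sample.int(k, length(w), replace = TRUE, prob = p[s, ])
      }
      states[chd, idx] <- out
    }
  }
  m <- states[seq_len(n_tip), , drop = FALSE]
  rownames(m) <- tree$tip.label
  m
}

#' Simulate a multigene mitogenome-style dataset
#'
#' Sites evolve root-to-tips under the configured GTR model; protein-coding
#' genes get cyclic codon-position rate scalers, every site gets a discrete
#' gamma category, and branches inside an override clade use the override
#' composition (non-stationary switch at the stem) with lengths multiplied by
#' the override rate.
#'
#' @param config A [simulation_config()].
#' @param genes Gene table (tibble with `gene`, `type`, `length`), e.g.
#'   [mito_gene_table()]. PCG lengths must be multiples of 3.
#' @return A `sim_dataset`: list with per-gene alignments (`genes`), the
#'   concatenated alignment (`aln`), `scheme` (partition scheme), the true
#'   `tree`, `site_info` (per-site gene, type, codon position, gamma category
#'   and total rate multiplier), per-taxon `target_freq`, and `config`.
#' @export
simulate_dataset <- function(config, genes = mito_gene_table()) {
  stopifnot(inherits(config, "sim_config"))
  genes <- as_tibble(genes)
  if (any(genes$type == "PCG" & genes$length %% 3 != 0)) {
    abort("PCG gene lengths must be multiples of 3")
  }
  set.seed(config$seed)
  tree <- config$tree
  cls <- classify_edges(tree, config$lineage_overrides)
  eigs <- lapply(seq_along(cls$freqs), function(i) {
    f <- cls$freqs[[i]] %||% config$freq
    model_eigen(config$exch, f)
  })
  edge_len <- tree$edge.length * cls$mult

  site_info <- tidyr::uncount(genes, weights = genes$length, .id = "offset")
  site_info$codon_pos <- ifelse(site_info$type == "PCG",
                                (site_info$offset - 1L) %% 3L + 1L, NA_integer_)
  n_sites <- nrow(site_info)
  if (identical(config$gamma_shape, Inf)) {
    g_rates <- 1; g_cat <- rep(1L, n_sites)
  } else {
    g_rates <- discrete_gamma_rates(config$gamma_shape, config$k_gamma)
    g_cat <- sample.int(config$k_gamma, n_sites, replace = TRUE)
  }
  scaler <- ifelse(is.na(site_info$codon_pos), 1, config$codon_scalers[site_info$codon_pos])
  site_rates <- g_rates[g_cat] * scaler
  site_info$gamma_cat <- g_cat
  site_info$rate <- site_rates

  m <- sim_states(tree, n_sites, eigs, cls$model_id, edge_len, site_rates, config$freq)
  chars <- matrix(NT_STATES[m], nrow = nrow(m), dimnames = list(rownames(m), NULL))

  cols <- tibble(gene = site_info$gene, type = site_info$type,
                 codon_pos = site_info$codon_pos)
  aln <- msa(chars, "nucleotide", cols)

  per_gene <- purrr::map(split(seq_len(n_sites), factor(site_info$gene, levels = unique(genes$gene))),
                         function(ix) msa_subset(aln, columns = ix))
  ends <- cumsum(genes$length)
  scheme <- tibble(block = genes$gene,
                   datatype = ifelse(genes$type == "PCG", "DNA", "RNA"),
                   columns = purrr::map2(ends - genes$length + 1L, ends, seq.int))
  class(scheme) <- c("partition_scheme", class(scheme))

  target <- matrix(rep(config$freq, each = length(tree$tip.label)),
                   ncol = 4, dimnames = list(tree$tip.label, NT_STATES))
  for (ov in config$lineage_overrides) {
    if (!is.null(ov$freq)) target[ov$clade, ] <- rep(ov$freq, each = length(ov$clade))
  }

  tree_eff <- tree
  tree_eff$edge.length <- edge_len

  structure(list(genes = per_gene, aln = aln, scheme = scheme, tree = tree,
                 tree_effective = tree_eff,
                 site_info = as_tibble(site_info[, c("gene", "type", "codon_pos",
                                                     "gamma_cat", "rate")]),
                 target_freq = target, config = config),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("<sim_dataset> %d taxa, %d genes, %d concatenated columns (seed %d)\n",
              n_taxa(x$aln), length(x$genes), n_sites(x$aln), x$config$seed))
  invisible(x)
}

paraneoptera_newick <- function() {
  barklice <- "(Psococerastis_sp:0.12,(Longivalvus_sp:0.10,Lepidopsocid_sp:0.11):0.04):0.05"
  booklice <- "(Liposcelis_bostrychophila:0.14,Liposcelis_decolor:0.13):0.08"
  lice <- "((Pediculus_humanus:0.10,Pthirus_pubis:0.11):0.04,(Haematopinus_suis:0.12,Bothriometopus_macrocnemis:0.13):0.03):0.09"
  psocodea <- sprintf("(%s,(%s,%s):0.06):0.07", barklice, booklice, lice)
  thrips <- "(Thrips_imaginis:0.12,(Frankliniella_occidentalis:0.10,Scirtothrips_dorsalis:0.11):0.05):0.10"
  sterno <- "((Aphis_gossypii:0.13,Pachypsylla_venusta:0.14):0.04,(Bemisia_tabaci:0.12,Trialeurodes_vaporariorum:0.11):0.05):0.07"
  hemi_rest <- "((Nilaparvata_lugens:0.12,(Philaenus_spumarius:0.10,Magicicada_tredecim:0.11):0.03):0.04,(Hackeriella_veitchi:0.13,((Triatoma_dimidiata:0.11,Riptortus_pedestris:0.10):0.03,(Halyomorpha_halys:0.08,(Nezara_viridula:0.07,Aelia_sibirica:0.08):0.03):0.04):0.04):0.03):0.05"
  hemiptera <- sprintf("(%s,%s):0.06", sterno, hemi_rest)
  ingroup <- sprintf("(%s,(%s,%s):0.04):0.08", psocodea, thrips, hemiptera)
  outgroup <- "((Locusta_migratoria:0.25,Gryllotalpa_orientalis:0.22):0.06,(Periplaneta_americana:0.20,Tamolanica_tamolana:0.21):0.05):0.08"
  sprintf("(%s,%s);", ingroup, outgroup)
}

#' Paraneoptera-like synthetic fixture
#'
#' A 29-taxon dataset (25 ingroup + 4 outgroup) over the full mitogenome gene
#' table, with four fast clades (parasitic lice, booklice, thrips and a
#' sternorrhynchan clade; rate multipliers around 1.8x) of which two mutually
#' non-sister clades (parasitic lice and Sternorrhyncha) additionally carry a
#' shifted, more AT-rich composition. The ground-truth clade map is returned
#' alongside the data.
#'
#' @param seed Integer seed.
#' @param genes Gene table; defaults to [mito_gene_table()].
#' @param scale Global branch-length multiplier (1 = default depth).
#' @return A `sim_dataset` with an extra `clades` element naming the taxon
#'   groups (outgroup, barklice, booklice, lice, thrips, sternorrhyncha,
#'   hemiptera_other) and `fast_clades`/`shifted_clades` metadata.
#' @export
make_paraneoptera_fixture <- function(seed = 1L, genes = mito_gene_table(), scale = 1) {
  tree <- read_newick(paraneoptera_newick())
  tree$edge.length <- tree$edge.length * scale
  clades <- list(
    outgroup = c("Locusta_migratoria", "Gryllotalpa_orientalis",
                 "Periplaneta_americana", "Tamolanica_tamolana"),
    barklice = c("Psococerastis_sp", "Longivalvus_sp", "Lepidopsocid_sp"),
    booklice = c("Liposcelis_bostrychophila", "Liposcelis_decolor"),
    lice = c("Pediculus_humanus", "Pthirus_pubis", "Haematopinus_suis",
             "Bothriometopus_macrocnemis"),
    thrips = c("Thrips_imaginis", "Frankliniella_occidentalis", "Scirtothrips_dorsalis"),
    sternorrhyncha = c("Aphis_gossypii", "Pachypsylla_venusta", "Bemisia_tabaci",
                       "Trialeurodes_vaporariorum"),
    hemiptera_other = c("Nilaparvata_lugens", "Philaenus_spumarius",
                        "Magicicada_tredecim", "Hackeriella_veitchi",
                        "Triatoma_dimidiata", "Riptortus_pedestris",
                        "Halyomorpha_halys", "Nezara_viridula", "Aelia_sibirica")
  )
  shifted <- at_rich_freq(0.82)
  overrides <- list(
    list(clade = clades$lice, rate = 1.9, freq = shifted),
    list(clade = clades$booklice, rate = 1.85),
    list(clade = clades$thrips, rate = 1.6),
    list(clade = clades$sternorrhyncha, rate = 1.55, freq = shifted)
  )
  cfg <- simulation_config(tree, freq = at_rich_freq(0.74),
                           lineage_overrides = overrides, seed = seed)
  out <- simulate_dataset(cfg, genes)
  out$clades <- clades
  out$ingroup <- setdiff(tree$tip.label, clades$outgroup)
  out$fast_clades <- c("lice", "booklice", "thrips", "sternorrhyncha")
  out$shifted_clades <- c("lice", "sternorrhyncha")
  out
}

#' Competing-signal fixture for slow-fast stripping
#'
#' Eight taxa in four cherries. Half the sites evolve fast (4x) on a tree
#' whose short central edge groups the focal clade (a1, a2, c, d); the other
#' half evolve slowly (0.25x) on a tree whose central edge supports a
#' conflicting grouping. The focal deep signal therefore lives on the
#' fast-evolving sites: with all data it wins, and once the fastest ~50% of
#' sites are stripped the conflicting slow signal is what remains. The
#' cherries are clades under both regimes, so they provide the
#' rate-assignment groups and a stable control clade.
#'
#' @param seed Integer seed.
#' @param n_sites Total sites (half per regime).
#' @param fast_scale,slow_scale Branch-length multipliers of the two regimes.
#' @return List: `aln`, `groups` (the four cherries), `focal` (the
#'   fast-supported deep clade), `control` (a cherry), `site_regime`
#'   (`"slow"`/`"fast"` per column).
#' @export
make_slowfast_fixture <- function(seed = 1L, n_sites = 3000, fast_scale = 4,
                                  slow_scale = 0.25) {
  base_fast <- "(((a1:0.1,a2:0.1):0.1,(c:0.1,d:0.1):0.1):0.05,((e1:0.1,e2:0.1):0.1,(f1:0.1,f2:0.1):0.1):0.05);"
  base_slow <- "(((a1:0.1,a2:0.1):0.1,(e1:0.1,e2:0.1):0.1):0.05,((c:0.1,d:0.1):0.1,(f1:0.1,f2:0.1):0.1):0.05);"
  half <- as.integer(n_sites) %/% 2L
  sim_half <- function(nwk, scale, s, n) {
    tr <- read_newick(nwk)
    tr$edge.length <- tr$edge.length * scale
    cfg <- simulation_config(tr, exch = rep(1, 6), freq = c(.3, .2, .2, .3),
                             gamma_shape = Inf, codon_scalers = c(1, 1, 1),
                             seed = s)
    simulate_dataset(cfg, tibble(gene = "g", type = "rRNA", length = n))$aln
  }
  slow <- sim_half(base_slow, slow_scale, seed, half)
  fast <- sim_half(base_fast, fast_scale, seed + 104729L, as.integer(n_sites) - half)
  aln <- msa(cbind(slow$mat, fast$mat[rownames(slow$mat), ]), "nucleotide")
  list(aln = aln,
       groups = list(g1 = c("a1", "a2"), g2 = c("c", "d"),
                     g3 = c("e1", "e2"), g4 = c("f1", "f2")),
       focal = c("a1", "a2", "c", "d"),
       conflict = c("a1", "a2", "e1", "e2"),
       control = c("a1", "a2"),
       site_regime = rep(c("slow", "fast"), c(half, as.integer(n_sites) - half)))
}

#' Felsenstein-zone fixture for long-branch attraction
#'
#' A four- or six-taxon tree in which two non-sister taxa (`A`, `B`) sit on
#' long branches separated by a short internal branch, evolved under
#' Jukes-Cantor without rate variation. Uncorrected-distance methods tend to
#' group the two long branches; distance corrections recover the true tree.
#'
#' @param seed Integer seed.
#' @param internal_len,long_len,short_len Branch lengths (substitutions/site).
#' @param n_sites Number of sites.
#' @param n_taxa 4, 6 or 8 taxa. The 8-taxon variant adds a third short
#'   cherry (E1, E2) outside the two long-branch clades, breaking the
#'   symmetry so that long-branch relocation is observable after removing
#'   either long taxon (the geometry the long-branch-extraction test needs).
#' @return A `sim_dataset` with `truth` metadata: the long-branch taxa and
#'   the true unrooted splits.
#' @export
make_lba_fixture <- function(seed = 1L, internal_len = 0.1, long_len = 1.0,
                             short_len = 0.05, n_sites = 5000, n_taxa = 4) {
  if (any(c(long_len, short_len) <= 0) || internal_len < 0) {
    abort("branch lengths must be positive (internal may be 0)")
  }
  h <- max(internal_len / 2, 1e-9)
  nwk <- if (n_taxa == 4) {
    sprintf("((A:%g,C:%g):%g,(B:%g,D:%g):%g);",
            long_len, short_len, h, long_len, short_len, h)
  } else if (n_taxa == 6) {
    sprintf("((A:%g,(C1:%g,C2:%g):%g):%g,(B:%g,(D1:%g,D2:%g):%g):%g);",
            long_len, short_len, short_len, short_len, h,
            long_len, short_len, short_len, short_len, h)
  } else if (n_taxa == 8) {
    sprintf("(((A:%g,(C1:%g,C2:%g):%g):%g,(B:%g,(D1:%g,D2:%g):%g):%g):%g,(E1:%g,E2:%g):%g);",
            long_len, short_len, short_len, short_len, h,
            long_len, short_len, short_len, short_len, h,
            h, short_len, short_len, short_len)
  } else {
    abort("`n_taxa` must be 4, 6 or 8")
  }
  tree <- read_newick(nwk)
  cfg <- simulation_config(tree, exch = rep(1, 6), freq = rep(0.25, 4),
                           gamma_shape = Inf, codon_scalers = c(1, 1, 1),
                           seed = seed)
  genes <- tibble(gene = "sim", type = "rRNA", length = as.integer(n_sites))
  out <- simulate_dataset(cfg, genes)
  out$truth <- list(
    long_taxa = c("A", "B"),
    true_tree = tree,
    sister_of_A = if (n_taxa == 4) "C" else c("C1", "C2"),
    sister_of_B = if (n_taxa == 4) "D" else c("D1", "D2")
  )
  out
}
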