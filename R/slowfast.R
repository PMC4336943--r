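# Slow-fast site-rate assignment, progressive stripping of the fastest
# sites, recovery scans, and the long-branch-extraction test.

#' Slow-fast site rates
#'
#' Assigns each site an integer rate: the sum, over predefined taxon groups,
#' of Fitch parsimony steps on the group's induced subtree (built by
#' neighbor joining on within-group p-distances; for groups of 2-3 taxa the
#' topology is unique). Sites invariant within every group get rate 0;
#' between-group differences carry no steps, so the rate captures
#' within-group substitution activity only.
#'
#' @param aln An [msa].
#' @param groups Named list of disjoint taxon sets, each with >= 2 taxa.
#' @return A `site_rate_table` tibble: `site`, `rate`; attributes `groups`
#'   and `histogram`.
#' @export
slowfast_rates <- function(aln, groups) {
  if (anyDuplicated(unlist(groups))) abort("groups must be disjoint")
  sizes <- lengths(groups)
  if (any(sizes < 2)) abort("every group needs at least 2 taxa")
  if (!all(unlist(groups) %in% msa_taxa(aln))) abort("group taxon not in alignment")
  rate <- integer(n_sites(aln))
  for (g in groups) {
    sub <- msa_subset(aln, taxa = g)
    tr <- group_subtree(sub)
    masks <- fitch_masks(sub)[tr$tip.label, , drop = FALSE]
    rate <- rate + fitch_engine(tr, masks)$per_site
  }
  out <- tibble(site = seq_along(rate), rate = rate)
  attr(out, "groups") <- groups
  attr(out, "histogram") <- table(rate)
  class(out) <- c("site_rate_table", class(out))
  out
}

# within-group subtree; topology is irrelevant for <= 3 taxa
group_subtree <- function(sub) {
  n <- n_taxa(sub)
  if (n == 2) {
    return(read_newick(sprintf("(%s:1,%s:1);", msa_taxa(sub)[1], msa_taxa(sub)[2])))
  }
  if (n == 3) {
    return(read_newick(sprintf("(%s:1,%s:1,%s:1);", msa_taxa(sub)[1],
                               msa_taxa(sub)[2], msa_taxa(sub)[3])))
  }
  d <- p_distance(sub)
  if (anyNA(d)) d[is.na(d)] <- max(d, na.rm = TRUE)
  neighbor_joining(d)
}

#' Strip the fastest-evolving sites
#'
#' For each retained fraction, keeps the lowest-rate `ceiling(f * L)` sites;
#' ties at the cut are broken by original column order (leftmost kept), so
#' successive steps are strictly nested.
#'
#' @param aln An [msa].
#' @param rates A [slowfast_rates()] table (or numeric vector, one per site).
#' @param steps Strictly decreasing retained fractions in (0, 1].
#' @return Named list (`"f=1.00"`, ...) with elements `aln` (stripped [msa])
#'   and `sites` (kept source columns).
#' @export
strip_fastest <- function(aln, rates, steps = c(1, 0.9, 0.8, 0.7, 0.6, 0.5)) {
  if (inherits(rates, "site_rate_table")) rates <- rates$rate
  L <- n_sites(aln)
  if (length(rates) != L) abort("one rate per column required")
  if (any(steps <= 0 | steps > 1) || any(diff(steps) >= 0)) {
    abort("`steps` must be strictly decreasing fractions in (0, 1]")
  }
  ord <- order(rates)          # stable: ties keep original column order
  out <- purrr::map(steps, function(f) {
    m <- ceiling(f * L)
    if (m < 1) abort("stripping left an empty alignment")
    keep <- sort(ord[seq_len(m)])
    list(aln = msa_subset(aln, columns = keep), sites = keep)
  })
  names(out) <- sprintf("f=%.2f", steps)
  out
}

#' Slow-fast recovery scan
#'
#' Strips the fastest sites step by step and records, per step and focal
#' clade, whether the clade is recovered by the chosen inference and a
#' bootstrap support proxy (proportion of `B` site-resampled replicates
#' recovering the clade).
#'
#' @param aln An [msa].
#' @param groups Rate-assignment groups (see [slowfast_rates()]).
#' @param focal_clades Named list of taxon sets to track.
#' @param steps Retained fractions, strictly decreasing in (0, 1].
#' @param inference `"nj_logdet"` (default) or `"nj_p"`.
#' @param B Bootstrap replicates for the support proxy.
#' @param seed Integer seed.
#' @return A `slowfast_report` tibble: `fraction`, `n_sites`, `clade`,
#'   `recovered`, `support`.
#' @export
slowfast_scan <- function(aln, groups, focal_clades,
                          steps = c(1, 0.9, 0.8, 0.7, 0.6, 0.5),
                          inference = c("nj_logdet", "nj_p"), B = 100,
                          seed = 1L) {
  inference <- match.arg(inference)
  infer <- function(a) {
    d <- if (inference == "nj_logdet") logdet_distance(a) else p_distance(a)
    if (anyNA(d)) d[is.na(d)] <- max(d, na.rm = TRUE) * 1.5
    neighbor_joining(d)
  }
  rates <- slowfast_rates(aln, groups)
  stripped <- strip_fastest(aln, rates, steps)
  set.seed(seed)
  rows <- purrr::imap(stripped, function(st, nm) {
    tr <- infer(st$aln)
    boot_hits <- setNames(rep(0L, length(focal_clades)), names(focal_clades))
    for (b in seq_len(B)) {
      ix <- sample.int(n_sites(st$aln), replace = TRUE)
      tb <- try(infer(msa_subset(st$aln, columns = ix)), silent = TRUE)
      if (inherits(tb, "try-error")) next
      for (cl in names(focal_clades)) {
        boot_hits[cl] <- boot_hits[cl] + has_clade(tb, focal_clades[[cl]])
      }
    }
    tibble(fraction = as.numeric(sub("^f=", "", nm)),
           n_sites = n_sites(st$aln),
           clade = names(focal_clades),
           recovered = vapply(focal_clades, function(cl) has_clade(tr, cl), logical(1)),
           support = unname(boot_hits) / B)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "inference") <- inference
  attr(out, "seed") <- seed
  class(out) <- c("slowfast_report", class(out))
  out
}

#' Long-branch extraction test
#'
#' Removes taxon set A (then B) from the alignment, re-runs the inference,
#' and asks whether the remaining focal set keeps the sister group it has in
#' the baseline tree (restricted to the shared taxa). If both sets stay put,
#' their baseline grouping is not attributable to long-branch attraction;
#' if either relocates, LBA is suspected.
#'
#' @param aln An [msa].
#' @param inference_fn Function mapping an [msa] to an `ape::phylo`.
#' @param setA,setB Disjoint taxon sets present in the alignment.
#' @return An `lbe_report` list: baseline and reduced trees, per-removal
#'   sister groups, `stayed_A`/`stayed_B`, RF distances on shared taxa, and
#'   `verdict` (`"LBA-suspected"` or `"LBA-not-supported"`).
#' @export
lbe_test <- function(aln, inference_fn, setA, setB) {
  taxa <- msa_taxa(aln)
  if (!all(c(setA, setB) %in% taxa)) abort("focal taxa missing from alignment")
  if (length(intersect(setA, setB))) abort("setA and setB must be disjoint")
  baseline <- inference_fn(aln)
  grouped <- has_clade(baseline, c(setA, setB))
  one_removal <- function(removed, kept_set) {
    reduced_aln <- msa_subset(aln, taxa = setdiff(taxa, removed))
    reduced <- inference_fn(reduced_aln)
    base_red <- ape::drop.tip(baseline, removed)
    expected <- sister_of(base_red, kept_set)
    observed <- sister_of(reduced, kept_set)
    list(tree = reduced,
         expected_sister = expected, observed_sister = observed,
         stayed = identical(expected, observed),
         rf = rf_distance(reduced, base_red))
  }
  remA <- one_removal(setA, setB)
  remB <- one_removal(setB, setA)
  verdict <- if (remA$stayed && remB$stayed) "LBA-not-supported" else "LBA-suspected"
  structure(list(setA = setA, setB = setB, baseline = baseline,
                 grouped_in_baseline = grouped,
                 remove_A = remA, remove_B = remB,
                 stayed_A = remB$stayed, stayed_B = remA$stayed,
                 verdict = verdict),
            class = "lbe_report")
}

#' @export
print.lbe_report <- function(x, ...) {
  cat(sprintf("Long-branch extraction: %s\n", x$verdict))
  cat(sprintf("  remove A -> B's sister: %s (expected %s)\n",
              paste(x$remove_A$observed_sister, collapse = ","),
              paste(x$remove_A$expected_sister, collapse = ",")))
  cat(sprintf("  remove B -> A's sister: %s (expected %s)\n",
              paste(x$remove_B$observed_sister, collapse = ","),
              paste(x$remove_B$expected_sister, collapse = ",")))
  invisible(x)
}
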