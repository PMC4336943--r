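test_that("Ka equals zero for identical sequences and skips bad codons", {
  a <- tiny_msa(c(x = "ATGGCTTTT", y = "ATGGCTTTT"))
  r <- ka_pairwise(a, "x", "y")
  expect_equal(r$Ka, 0)
  expect_equal(r$codons_used, 3)

  b <- tiny_msa(c(x = "ATGG-TTTT", y = "ATGGCTTTT"))
  r2 <- ka_pairwise(b, "x", "y")
  expect_equal(r2$codons_used, 2)
  expect_equal(r2$codons_skipped, 1)
})

test_that("single-codon Ka matches the pathway-enumeration oracle", {
  pairs <- list(c("TTT", "GTT"),   # one nonsynonymous difference
                c("TTT", "TTC"),   # one synonymous difference
                c("ATG", "ACT"),   # two differences
                c("TTA", "GAT"),   # three differences
                c("AAA", "AGG"))   # passes near AGA/AGG (Ser in mito code)
  for (pr in pairs) {
    a <- tiny_msa(setNames(pr, c("x", "y")))
    r <- ka_pairwise(a, "x", "y")
    o <- oracle_ng(pr[1], pr[2])
    expect_equal(r$N, o$N, tolerance = 1e-12, label = paste(pr, collapse = "/"))
    expect_equal(r$Nd, o$Nd, tolerance = 1e-12, label = paste(pr, collapse = "/"))
    pn <- o$Nd / o$N
    ka_expected <- if (pn >= 0.75) NA_real_ else -(3 / 4) * log(1 - 4 / 3 * pn)
    expect_equal(r$Ka, ka_expected, tolerance = 1e-12)
  }
  # explicit check of the classic F->V case
  o <- oracle_ng("TTT", "GTT")
  expect_equal(o$Nd, 1)
})

test_that("Ka is symmetric and monotone in divergence", {
  set.seed(8)
  codons <- names(invert_mito_code())
  sense <- codons[invert_mito_code() != "*"]
  for (i in 1:10) {
    s1 <- paste(sample(sense, 5, TRUE), collapse = "")
    s2 <- paste(sample(sense, 5, TRUE), collapse = "")
    a <- tiny_msa(c(x = s1, y = s2))
    expect_equal(ka_pairwise(a, "x", "y")$Ka, ka_pairwise(a, "y", "x")$Ka)
  }
  mean_ka <- vapply(c(0.05, 0.3), function(t) {
    kas <- vapply(1:20, function(s) {
      sim <- quick_sim(sprintf("(a:%g,b:%g);", t / 2, t / 2), 1500, 400 + s,
                       freq = c(.3, .2, .2, .3))
      ka_pairwise(sim$aln, "a", "b")$Ka
    }, numeric(1))
    mean(kas, na.rm = TRUE)
  }, numeric(1))
  expect_lt(mean_ka[1], mean_ka[2])
})

test_that("ka_table covers all non-reference taxa in order", {
  a <- tiny_msa(c(x = "ATGGCT", y = "ATGGCA", z = "TTGGCT"))
  kt <- ka_table(a, "x")
  expect_equal(kt$taxon, c("y", "z"))
  expect_false("x" %in% kt$taxon)
  expect_error(ka_table(a, "nope"), "reference")
  a2 <- tiny_msa(c(x = "ATGGCT", y = "ATGGCA"))
  expect_equal(nrow(ka_table(a2, "x")), 1L)
})

test_that("tip-to-ancestor path lengths sum correctly", {
  tr <- read_newick("((a:0.1,b:0.2):0.3,c:0.6);")
  out <- tip_to_mrca_lengths(tr, c("a", "b", "c"))
  expect_equal(out$branch_length[out$taxon == "a"], 0.4)
  expect_equal(out$branch_length[out$taxon == "c"], 0.6)
  out2 <- tip_to_mrca_lengths(tr, c("a", "b"))
  expect_equal(out2$branch_length, c(0.1, 0.2))
  tr2 <- read_newick("((a:0.1,c:0.2):0.3,(b:0.1,d:0.2):0.1);")
  expect_error(tip_to_mrca_lengths(tr2, c("a", "b")), "monophyletic")
})

test_that("rate correlation handles exact, null, and error cases", {
  ka <- tibble::tibble(taxon = c("a", "b", "c", "d"), Ka = c(0.1, 0.2, 0.3, 0.4))
  bl <- tibble::tibble(taxon = c("a", "b", "c", "d"),
                       branch_length = 2 * ka$Ka)
  expect_equal(correlate_rates(ka, bl)$r_squared, 1)

  bl0 <- tibble::tibble(taxon = c("a", "b", "c", "d"),
                        branch_length = c(1, -1, -1, 1))
  ka0 <- tibble::tibble(taxon = c("a", "b", "c", "d"), Ka = c(1, 1, -1, -1))
  expect_equal(correlate_rates(ka0, bl0)$r_squared, 0)

  expect_error(correlate_rates(ka[1:2, ], bl[1:2, ]), "3 complete")
})

test_that("fixture Ka ranks fast clades above slow ones and tracks branch length", {
  fx <- paraneoptera_cached(1)
  pcg <- build_dataset(fx, "PCG")$aln
  kt <- ka_table(pcg, "Locusta_migratoria")
  mean_of <- function(g) mean(kt$Ka[kt$taxon %in% fx$clades[[g]]])
  expect_gt(mean_of("lice"), mean_of("barklice"))
  expect_gt(mean_of("booklice"), mean_of("hemiptera_other"))
  expect_gt(mean_of("thrips"), mean_of("barklice"))

  bl <- tip_to_mrca_lengths(fx$tree_effective, fx$ingroup)
  cr <- correlate_rates(kt[kt$taxon %in% fx$ingroup, ], bl)
  expect_gt(cr$r_squared, 0.8)
})
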