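test_that("zero branch lengths propagate the root draw unchanged", {
  fx <- quick_sim("((a:0,b:0):0,(c:0,d:0):0);", 200, 4)
  m <- fx$aln$mat
  for (t in c("b", "c", "d")) expect_identical(m[t, ], unname(m["a", ]))
})

test_that("two-taxon divergence matches the Jukes-Cantor expectation", {
  fx <- quick_sim("(a:0.15,b:0.15);", 10000, 7)
  p <- mean(fx$aln$mat["a", ] != fx$aln$mat["b", ])
  expected <- 3 / 4 * (1 - exp(-4 * 0.3 / 3))
  se <- sqrt(expected * (1 - expected) / 10000)
  expect_lt(abs(p - expected), 4 * se)
})

test_that("the 29-taxon fixture is deterministic and carries ground truth", {
  fx <- paraneoptera_cached(1)
  expect_equal(n_taxa(fx$aln), 29L)
  expect_length(fx$ingroup, 25L)
  expect_equal(n_sites(fx$aln), 14013L)
  fx2 <- make_paraneoptera_fixture(seed = 1)
  expect_identical(fx$aln$mat, fx2$aln$mat)
  fx3 <- make_paraneoptera_fixture(seed = 2)
  expect_false(identical(fx$aln$mat, fx3$aln$mat))
  expect_setequal(fx$fast_clades, c("lice", "booklice", "thrips", "sternorrhyncha"))
})

test_that("tip composition converges to the lineage target on long branches", {
  # one override branch long enough to reach the shifted stationary state
  tr <- read_newick("(a:0.05,b:6);")
  shifted <- c(0.5, 0.08, 0.07, 0.35)
  cfg <- simulation_config(tr, exch = rep(1, 6), freq = rep(0.25, 4),
                           gamma_shape = Inf, codon_scalers = c(1, 1, 1),
                           lineage_overrides = list(list(clade = "b", rate = 1,
                                                         freq = shifted)),
                           seed = 5)
  sim <- simulate_dataset(cfg, tibble::tibble(gene = "g", type = "rRNA",
                                              length = 50000L))
  ct <- composition_table(sim$aln)
  obs_b <- unlist(ct[ct$taxon == "b", paste0("freq_", c("A", "C", "G", "T"))])
  expect_lt(max(abs(obs_b - shifted)), 0.01)
  obs_a <- unlist(ct[ct$taxon == "a", paste0("freq_", c("A", "C", "G", "T"))])
  expect_lt(max(abs(obs_a - 0.25)), 0.01)
})

test_that("substitution pattern on a long branch matches the configured model", {
  exch <- c(1, 4, 1, 1, 4, 1)
  freq <- c(0.35, 0.15, 0.15, 0.35)
  me <- hetphylo:::model_eigen(exch, freq)
  for (s in 1:3) {
    fx <- quick_sim("(a:0.4,b:0.4);", 8000, s + 30, exch = exch, freq = freq)
    codes <- hetphylo:::msa_codes(fx$aln)
    obs <- table(factor(codes[1, ], 1:4), factor(codes[2, ], 1:4))
    P <- hetphylo:::pmat(me, 0.8)
    expected <- 8000 * freq * P
    chi2 <- sum((obs - expected)^2 / expected)
    # 16 cells, 0 fitted parameters here: df = 15
    expect_gt(stats::pchisq(chi2, df = 15, lower.tail = FALSE), 0.01)
  }
})

test_that("top gamma-category sites accumulate more parsimony steps", {
  fx <- quick_sim(balanced6, 6000, 9, gamma_shape = 0.4)
  # gamma categories recorded per site
  fx$site_info$steps <- parsimony_length(fx$tree, fx$aln)$per_site
  top <- fx$site_info$steps[fx$site_info$gamma_cat == 4]
  bottom <- fx$site_info$steps[fx$site_info$gamma_cat == 1]
  tt <- stats::t.test(top, bottom, alternative = "greater")
  expect_lt(tt$p.value, 0.01)
})

test_that("override clades must be monophyletic and well-formed", {
  tr <- read_newick("((a:1,b:1):1,(c:1,d:1):1);")
  cfg_bad <- simulation_config(tr, lineage_overrides =
                                 list(list(clade = c("a", "c"), rate = 2)))
  expect_error(simulate_dataset(cfg_bad,
                                tibble::tibble(gene = "g", type = "rRNA", length = 10L)),
               "monophyletic")
  expect_error(simulation_config(tr, gamma_shape = -1), "> 0")
  expect_error(simulation_config(tr, lineage_overrides =
                                   list(list(clade = "zz", rate = 2))),
               "absent")
})

test_that("LBA fixture geometry behaves as designed", {
  fx <- make_lba_fixture(seed = 3, n_sites = 5000)
  d <- p_distance(fx$aln)
  # the two long branches look closer to each other than either is to its
  # true sister only in corrected terms; in p-distance terms saturation
  # compresses A-B below additivity, which drives the attraction
  expect_gt(d["A", "B"], d["A", "C"])
  add <- patristic_matrix(fx$truth$true_tree)
  expect_lt(d["A", "B"] / add["A", "B"], d["C", "D"] / add["C", "D"])

  # degenerate zero-length internal branch is tolerated
  fx0 <- make_lba_fixture(seed = 1, internal_len = 0, n_sites = 500)
  expect_equal(n_sites(fx0$aln), 500L)
  tr <- suppressWarnings(neighbor_joining(p_distance(fx0$aln)))
  expect_s3_class(tr, "phylo")

  # symmetric case: no LBA geometry, NJ on near-true distances is right
  fxs <- make_lba_fixture(seed = 2, internal_len = 0.3, long_len = 0.1,
                          short_len = 0.1, n_sites = 4000)
  tr2 <- suppressWarnings(neighbor_joining(p_distance(fxs$aln)))
  expect_true(has_clade(tr2, c("A", "C")))
})
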