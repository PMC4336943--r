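test_that("p-distance handles identity, mismatch, and pairwise deletion", {
  a <- tiny_msa(c(x = "AAAA", y = "AATT", z = "AAAA"))
  d <- p_distance(a)
  expect_equal(d["x", "y"], 0.5)
  expect_equal(d["x", "z"], 0)
  b <- tiny_msa(c(x = "AA--", y = "A-AA"))
  expect_equal(p_distance(b)["x", "y"], 0)   # only column 1 comparable
  c2 <- tiny_msa(c(x = "--", y = "AA"))
  expect_true(is.na(p_distance(c2)["x", "y"]))
})

test_that("p-distance matches the Jukes-Cantor curve on average", {
  ps <- vapply(1:100, function(s) {
    sim <- quick_sim("(a:0.15,b:0.15);", 800, 2000 + s)
    p_distance(sim$aln)["a", "b"]
  }, numeric(1))
  expected <- 3 / 4 * (1 - exp(-0.4))
  se <- sqrt(expected * (1 - expected) / 800) / sqrt(100)
  expect_lt(abs(mean(ps) - expected), 3 * se)
})

test_that("logdet distance agrees with ape's paralinear distance", {
  fx <- make_lba_fixture(seed = 3, n_sites = 1200)
  mine <- logdet_distance(fx$aln)
  rows <- lapply(asplit(fx$aln$mat, 1), tolower)
  ref <- as.matrix(ape::dist.dna(ape::as.DNAbin(rows), model = "paralin",
                                 pairwise.deletion = TRUE))
  ref <- ref[rownames(mine), colnames(mine)]
  expect_equal(unclass(mine), ref, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("NJ recovers additive trees and rejects incomplete input", {
  tr <- read_newick("(((a:0.1,b:0.2):0.05,c:0.3):0.07,(d:0.12,e:0.2):0.05,f:0.4);")
  d <- patristic_matrix(tr)
  nj <- neighbor_joining(d)
  expect_equal(rf_distance(nj, tr), 0L)
  # taxon order must not matter
  perm <- sample(rownames(d))
  nj2 <- neighbor_joining(d[perm, perm])
  expect_equal(rf_distance(nj2, tr), 0L)

  d3 <- patristic_matrix(read_newick("(a:0.1,b:0.2,c:0.3);"))
  nj3 <- neighbor_joining(d3)
  expect_equal(sort(nj3$edge.length), c(0.1, 0.2, 0.3))

  dd <- d; dd[1, 2] <- dd[2, 1] <- NA
  expect_error(neighbor_joining(dd), "undefined")
})

test_that("Fitch steps match definitions and the exhaustive oracle", {
  t1 <- read_newick("((a1:1,a2:1):1,(g1:1,g2:1):1);")
  t2 <- read_newick("((a1:1,g1:1):1,(a2:1,g2:1):1);")
  site <- tiny_msa(c(a1 = "A", a2 = "A", g1 = "G", g2 = "G"))
  expect_equal(parsimony_length(t1, site)$total, 1L)
  expect_equal(parsimony_length(t2, site)$total, 2L)
  expect_equal(min_steps(site), 1L)
  expect_equal(homoplasy_excess(t1, site), 0L)
  expect_equal(homoplasy_excess(t2, site), 1L)

  set.seed(12)
  tr6 <- read_newick("(((a:1,b:1):1,c:1):1,(d:1,e:1):1,f:1);")
  for (i in 1:25) {
    chars <- sample(c("A", "C", "G", "T", "-"), 6, TRUE,
                    prob = c(.24, .24, .24, .24, .04))
    names(chars) <- c("a", "b", "c", "d", "e", "f")
    aln1 <- tiny_msa(chars)
    st <- match(chars, c("A", "C", "G", "T"))
    names(st) <- names(chars)
    expect_equal(parsimony_length(tr6, aln1)$total,
                 oracle_fitch(tr6, st), label = paste(chars, collapse = ""))
  }
})

test_that("Fitch totals agree with phangorn on clean data", {
  fx <- quick_sim(balanced6, 300, 5)
  ours <- parsimony_length(fx$tree, fx$aln)$total
  dat <- phangorn::phyDat(fx$aln$mat, type = "DNA")
  expect_equal(ours, phangorn::parsimony(fx$tree, dat))
})

test_that("patristic and RF utilities behave", {
  expect_equal(patristic_matrix(read_newick("(a:0.1,b:0.2);"))["a", "b"], 0.3)
  tr <- read_newick("((a:1,b:1):1,(c:1,d:1):1);")
  expect_equal(rf_distance(tr, tr), 0L)
  tr2 <- read_newick("((a:1,c:1):1,(b:1,d:1):1);")
  expect_gt(rf_distance(tr, tr2), 0L)
})

test_that("clade and sister queries work on unrooted trees", {
  tr <- read_newick("(((a:1,b:1):1,c:1):1,(d:1,e:1):1,f:1);")
  expect_true(has_clade(tr, c("a", "b")))
  expect_true(has_clade(tr, c("d", "e")))
  expect_false(has_clade(tr, c("a", "c", "d")))
  expect_true(has_clade(tr, "a"))
  # rooted at the alphabetically first outside tip ("c" resp. "a")
  expect_equal(sister_of(tr, c("a", "b")), c("d", "e", "f"))
  expect_equal(sister_of(tr, c("d", "e")), "f")
  expect_equal(sister_of(tr, "f"), c("d", "e"))
})

test_that("exhaustive ML search recovers a 5-taxon simulated topology", {
  hits <- 0
  for (s in 1:3) {
    tr <- read_newick("((a:0.15,b:0.2):0.08,(c:0.18,d:0.12):0.06,e:0.2);")
    sim <- quick_sim("((a:0.15,b:0.2):0.08,(c:0.18,d:0.12):0.06,e:0.2);",
                     1200, 70 + s, exch = c(1, 3, 1, 1, 3, 1),
                     freq = c(.35, .15, .2, .3))
    res <- exhaustive_ml_topology(sim$aln, spec_gtr(gamma = FALSE), seed = s)
    expect_equal(nrow(res$table), 15L)
    expect_equal(max(res$table$logL), res$logL)
    hits <- hits + (rf_distance(res$tree, tr) == 0)
  }
  expect_equal(hits, 3)
  expect_error(exhaustive_ml_topology(paraneoptera_cached(1)$aln), "8 taxa")
})
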