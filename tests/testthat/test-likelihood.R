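test_that("discrete gamma matches the reference discretization", {
  for (a in c(0.2, 0.37, 1, 5)) {
    expect_equal(discrete_gamma_rates(a, 4), phangorn::discrete.gamma(a, 4),
                 tolerance = 1e-12)
  }
  expect_equal(mean(discrete_gamma_rates(0.31, 8)), 1, tolerance = 1e-12)
  expect_error(discrete_gamma_rates(-1), "> 0")
})

test_that("pruning equals brute-force state enumeration on a 4-leaf tree", {
  tr <- read_newick("((a:0.1,b:0.2):0.05,(c:0.15,d:0.3):0.07);")
  sim <- quick_sim("((a:0.1,b:0.2):0.05,(c:0.15,d:0.3):0.07);", 150, 3,
                   exch = c(1, 2, 1, 1, 3, 1), freq = c(.3, .2, .2, .3))
  exch <- c(1, 2, 1, 1, 3, 1); freq <- c(.3, .2, .2, .3)
  tree_po <- stats::reorder(tr, "postorder")
  codes <- hetphylo:::msa_codes(sim$aln)
  cp <- hetphylo:::compress_patterns(codes[tree_po$tip.label, , drop = FALSE])
  tipp <- hetphylo:::tip_partials(cp$patterns, 4L)
  lp <- hetphylo:::class_log_pattern_lik(tree_po, tipp, exch, freq,
                                         tree_po$edge.length, 1)
  brute <- oracle_loglik_4leaf(tree_po, cp$patterns, exch, freq)
  expect_lt(max(abs(lp - brute)), 1e-8)
})

test_that("total likelihood matches phangorn at fixed parameters", {
  tr <- read_newick("((a:0.1,b:0.2):0.05,(c:0.15,d:0.3):0.07);")
  sim <- quick_sim("((a:0.1,b:0.2):0.05,(c:0.15,d:0.3):0.07);", 400, 5,
                   exch = c(1, 2, 1, 1, 3, 1), freq = c(.3, .2, .2, .3),
                   gamma_shape = 0.6)
  exch <- c(1, 2, 1, 1, 3, 1); freq <- c(.3, .2, .2, .3)
  tree_po <- stats::reorder(tr, "postorder")
  codes <- hetphylo:::msa_codes(sim$aln)
  cp <- hetphylo:::compress_patterns(codes[tree_po$tip.label, , drop = FALSE])
  tipp <- hetphylo:::tip_partials(cp$patterns, 4L)
  lp <- hetphylo:::class_log_pattern_lik(tree_po, tipp, exch, freq,
                                         tree_po$edge.length,
                                         discrete_gamma_rates(0.6, 4))
  mine <- sum(cp$weights * lp)
  dat <- phangorn::phyDat(sim$aln$mat, type = "DNA")
  ref <- phangorn::pml(tr, dat, bf = freq, Q = exch, k = 4, shape = 0.6)$logLik
  expect_equal(mine, ref, tolerance = 1e-8)
})

test_that("likelihood is invariant to re-rooting under a reversible model", {
  tr <- read_newick("((a:0.1,b:0.2):0.05,(c:0.15,d:0.3):0.07);")
  sim <- quick_sim("((a:0.1,b:0.2):0.05,(c:0.15,d:0.3):0.07);", 300, 9)
  f1 <- fit_model(sim$aln, tr, spec_jc(), seed = 1)
  tr2 <- ape::root(ape::unroot(tr), outgroup = "c", resolve.root = TRUE)
  f2 <- fit_model(sim$aln, tr2, spec_jc(), seed = 1)
  expect_equal(f1$logL, f2$logL, tolerance = 1e-4)
})

test_that("GTR+G fit on rate-constant JC data recovers the truth", {
  sim <- quick_sim("((a:0.1,b:0.2):0.05,(c:0.15,d:0.3):0.07);", 5000, 13)
  fit <- fit_model(sim$aln, sim$tree, spec_gtr(gamma = TRUE), seed = 1)
  expect_true(all(abs(fit$exch / mean(fit$exch) - 1) < 0.10))
  expect_true(all(abs(fit$profiles[1, ] - 0.25) < 0.02))
  expect_gte(fit$gamma_shape, 5)
})

test_that("mixture fit recovers three planted composition profiles", {
  tr <- read_newick(balanced6)
  mk <- function(freq, seed) quick_sim(balanced6, 400, seed, freq = freq)$aln$mat
  profs <- rbind(c(.7, .1, .1, .1), c(.1, .7, .1, .1), c(.1, .1, .1, .7))
  aln <- msa(cbind(mk(profs[1, ], 31), mk(profs[2, ], 32), mk(profs[3, ], 33)),
             "nucleotide")
  fit <- fit_model(aln, tr, model_spec(exch = "equal", freq = "free", C = 3,
                                       gamma = FALSE, n_restarts = 2,
                                       tol = 1e-4), seed = 2)
  # match fitted classes to planted profiles by L1 distance over permutations
  perms <- list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
  best <- min(vapply(perms, function(p)
    sum(abs(fit$profiles[p, ] - profs)), numeric(1)))
  expect_lt(best / 3, 0.15 * 2)  # mean L1 per class below 0.3

  # class assignment accuracy against planted site classes
  gr <- 1
  ml <- hetphylo:::mixture_log_pattern_lik(
    fit$tree, hetphylo:::tip_partials(
      hetphylo:::compress_patterns(
        hetphylo:::msa_codes(aln)[fit$tree$tip.label, ])$patterns, 4L),
    fit$exch, fit$profiles, fit$weights, gr)
  map <- hetphylo:::compress_patterns(hetphylo:::msa_codes(aln)[fit$tree$tip.label, ])$map
  assigned <- apply(ml$by_class + log(fit$weights), 2, which.max)[map]
  truth <- rep(1:3, each = 400)
  acc <- max(vapply(perms, function(p) mean(p[assigned] == truth), numeric(1)))
  expect_gt(acc, 0.8)
})

test_that("mixture likelihood never falls below the homogeneous fit", {
  sim <- quick_sim(balanced6, 500, 41, freq = c(.4, .2, .1, .3))
  s1 <- model_spec(exch = "equal", freq = "free", C = 1, gamma = FALSE)
  s2 <- model_spec(exch = "equal", freq = "free", C = 2, gamma = FALSE,
                   n_restarts = 1, tol = 1e-4)
  f1 <- fit_model(sim$aln, sim$tree, s1, seed = 1)
  f2 <- fit_model(sim$aln, sim$tree, s2, seed = 1)
  expect_gte(f2$logL, f1$logL - 1e-6)
})

test_that("site log-likelihoods are consistent with the fit", {
  sim <- quick_sim(balanced6, 400, 19, freq = c(.35, .15, .15, .35))
  fit <- fit_model(sim$aln, sim$tree, spec_gtr(), seed = 1)
  sl <- site_log_likelihoods(fit, sim$aln)
  expect_length(sl, 400)
  expect_equal(sum(sl), fit$logL, tolerance = 1e-6)

  const <- tiny_msa(stats::setNames(rep("A", 6), msa_taxa(sim$aln)))
  varied <- tiny_msa(stats::setNames(c("A", "C", "G", "T", "A", "C"),
                                     msa_taxa(sim$aln)))
  expect_gt(site_log_likelihoods(fit, const), site_log_likelihoods(fit, varied))

  empty <- msa_subset(sim$aln, columns = integer(0))
  expect_length(site_log_likelihoods(fit, empty), 0)
})

test_that("simulation under a fit is seed-deterministic and model-faithful", {
  sim <- quick_sim("(a:0.2,b:0.2);", 500, 23)
  fit <- fit_model(sim$aln, sim$tree, spec_jc(), seed = 1)
  r1 <- simulate_under_fit(fit, 800, seed = 11)
  r2 <- simulate_under_fit(fit, 800, seed = 11)
  expect_identical(r1$mat, r2$mat)
  expect_equal(n_sites(simulate_under_fit(fit, 0, seed = 1)), 0L)

  t_hat <- sum(fit$tree$edge.length)
  ps <- vapply(1:40, function(s)
    p_distance(simulate_under_fit(fit, 2000, seed = 100 + s))["a", "b"],
    numeric(1))
  expected <- 3 / 4 * (1 - exp(-4 * t_hat / 3))
  expect_lt(abs(mean(ps) - expected), 3 * sqrt(expected * (1 - expected) / 2000) / sqrt(40))
})

test_that("fits demand enough sites per mixture class", {
  sim <- quick_sim(balanced6, 120, 29)
  expect_error(fit_model(sim$aln, sim$tree,
                         model_spec(exch = "equal", freq = "free", C = 3,
                                    gamma = FALSE)), "at least")
})
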