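test_that("cross-validation splits partition the columns at the 90/10 ratio", {
  sim <- quick_sim(balanced6, 437, 3)
  L <- 437
  set.seed(99)
  learn <- sort(sample.int(L, floor(0.9 * L)))
  test <- setdiff(seq_len(L), learn)
  expect_length(learn, floor(0.9 * L))
  expect_length(intersect(learn, test), 0)
  expect_setequal(c(learn, test), seq_len(L))

  cv <- cross_validate(sim$aln, sim$tree, spec_jc(), spec_jc(), reps = 2,
                       seed = 1)
  expect_equal(unique(cv$n_test), L - floor(0.9 * L))
  expect_error(cross_validate(sim$aln, sim$tree, spec_jc(), spec_jc(),
                              fraction = 0.4), "0.5")
  small <- msa_subset(sim$aln, columns = 1:60)
  expect_error(cross_validate(small, sim$tree, spec_jc(), spec_jc()),
               "10 sites")
})

test_that("identical models give a near-zero CV score", {
  sim <- quick_sim(balanced6, 400, 7, freq = c(.35, .15, .15, .35))
  cv <- cross_validate(sim$aln, sim$tree, spec_jc(), spec_jc(), reps = 5,
                       seed = 2)
  expect_lt(abs(attr(cv, "mean")), 2 * attr(cv, "sd") / sqrt(5) + 1e-6)
})

test_that("CV score distribution is invariant to column order", {
  sim <- quick_sim(balanced6, 300, 11, freq = c(.4, .15, .15, .3))
  cv1 <- cross_validate(sim$aln, sim$tree, spec_jc(), spec_gtr(gamma = FALSE),
                        reps = 3, seed = 5)
  set.seed(1); perm <- sample.int(300)
  cv2 <- cross_validate(msa_subset(sim$aln, columns = perm), sim$tree,
                        spec_jc(), spec_gtr(gamma = FALSE), reps = 3, seed = 5)
  # same seed, permuted columns: different site draws but compatible scale
  expect_lt(abs(attr(cv1, "mean") - attr(cv2, "mean")),
            4 * (attr(cv1, "sd") + attr(cv2, "sd")))
})

test_that("CV prefers the generating model over a nested simpler one", {
  sim <- quick_sim(balanced6, 600, 17, exch = c(1, 6, 1, 1, 6, 1),
                   freq = c(.4, .1, .1, .4))
  cv <- cross_validate(sim$aln, sim$tree, spec_jc(), spec_gtr(gamma = FALSE),
                       reps = 5, seed = 3)
  expect_gt(attr(cv, "mean"), 0)
  expect_gt(sum(cv$delta > 0), 3)
  g <- glance(cv)
  expect_equal(g$model1, "JC")
  expect_equal(g$reps, 5L)
})

test_that("saturation regression honors its exact identities", {
  tr <- read_newick("((a:0.2,b:0.3):0.1,(c:0.25,d:0.2):0.1,e:0.3);")
  sat <- saturation_analysis(tr, list(self = tr))
  expect_equal(sat$slope[sat$comparison == "self"], 1)
  expect_equal(sat$intercept[sat$comparison == "self"], 0, tolerance = 1e-12)
  expect_equal(sat$r_squared[sat$comparison == "self"], 1)
  expect_error(saturation_analysis(read_newick("(a:1,b:1);"),
                                   list(x = read_newick("(a:1,b:1);"))),
               "3 taxa")
})

test_that("observed distances flatten against the true tree as depth grows", {
  deep_slope <- function(depth, s) {
    sim <- quick_sim("((a:0.4,b:0.4):0.15,(c:0.4,d:0.4):0.15,(e:0.5,f:0.5):0.1);",
                     1500, s, scale = depth)
    tr <- sim$tree
    sat <- saturation_analysis(tr, list(), aln = sim$aln)
    sat$slope[sat$comparison == "observed_p"]
  }
  s1 <- vapply(1:5, function(s) deep_slope(1, 500 + s), numeric(1))
  s2 <- vapply(1:5, function(s) deep_slope(2, 600 + s), numeric(1))
  expect_lt(mean(s1), 1)
  expect_lt(mean(s2), mean(s1))

  # shallow regime: near-linear, slope close to 1 (averaged — the OLS slope
  # over 10 leaf pairs at p-distances of a few percent is noisy per seed)
  shallow <- vapply(1:5, function(s) {
    sim <- quick_sim("((a:0.02,b:0.02):0.01,(c:0.02,d:0.02):0.01,e:0.03);",
                     10000, 700 + s)
    sat <- saturation_analysis(sim$tree, list(), aln = sim$aln)
    sat$slope[sat$comparison == "observed_p"]
  }, numeric(1))
  expect_gt(mean(shallow), 0.85)
  expect_lte(mean(shallow), 1.02)
})

test_that("posterior-predictive homoplasy flags under-predicted convergence", {
  # homogeneous fit on composition-mixture data underestimates homoplasy
  zs <- vapply(1:3, function(s) {
    tr <- read_newick(balanced6)
    mk <- function(freq, sd) quick_sim(balanced6, 250, sd, freq = freq)$aln$mat
    aln <- msa(cbind(mk(c(.7, .1, .1, .1), s * 10 + 1),
                     mk(c(.1, .7, .1, .1), s * 10 + 2),
                     mk(c(.1, .1, .1, .7), s * 10 + 3)), "nucleotide")
    fit <- fit_model(aln, tr, model_spec(exch = "equal", freq = "free",
                                         gamma = FALSE), seed = s)
    ppred_homoplasy(aln, tr, fit, R = 40, seed = s)$z
  }, numeric(1))
  expect_gt(mean(zs), 0)

  sim <- quick_sim(balanced6, 300, 77)
  fit <- fit_model(sim$aln, sim$tree, spec_jc(), seed = 1)
  expect_error(ppred_homoplasy(sim$aln, sim$tree, fit, R = 0), "R must be")

  # zero-spread simulated homoplasy: z undefined, p still reported
  const <- tiny_msa(stats::setNames(rep("AAAAAAAAAAAAAAAAAAAAAAAAAAAAAA", 6),
                                    msa_taxa(sim$aln)))
  fit0 <- fit_model(quick_sim(balanced6, 60, 5)$aln, sim$tree,
                    spec_jc(), seed = 1)
  fit0$tree$edge.length[] <- 1e-7
  r <- ppred_homoplasy(const, fit0$tree, fit0, R = 10, seed = 2)
  expect_true(is.na(r$z))
  expect_true(r$p > 0 && r$p <= 1)
})
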