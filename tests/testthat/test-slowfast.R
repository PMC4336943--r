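test_that("slow-fast rates follow the within-group step definition", {
  taxa <- c(a1 = "AAAA", a2 = "AAGA", g1 = "GAGC", g2 = "GAGT")
  aln <- tiny_msa(taxa)
  groups <- list(A = c("a1", "a2"), G = c("g1", "g2"))
  rt <- slowfast_rates(aln, groups)
  # col1 constant: 0; col2 between-group difference only: 0;
  # col3 within-A difference: 1; col4 within-G difference (+ between): 1
  expect_equal(rt$rate, c(0L, 0L, 1L, 1L))

  one4 <- tiny_msa(c(w = "A", x = "C", y = "G", z = "G"))
  rt4 <- slowfast_rates(one4, list(all = c("w", "x", "y", "z")))
  expect_gte(rt4$rate, 2L)

  expect_error(slowfast_rates(aln, list(A = "a1", G = c("g1", "g2"))),
               "at least 2")
  expect_error(slowfast_rates(aln, list(A = c("a1", "a2"), B = c("a2", "g1"))),
               "disjoint")
})

test_that("rates are invariant to within-group taxon order", {
  fx <- quick_sim(balanced6, 500, 31, gamma_shape = 0.4)
  g1 <- list(x = c("a", "b", "c"), y = c("d", "e", "f"))
  g2 <- list(x = c("c", "a", "b"), y = c("f", "e", "d"))
  expect_equal(slowfast_rates(fx$aln, g1)$rate, slowfast_rates(fx$aln, g2)$rate)
})

test_that("stripping is nested, ordered, and tie-stable", {
  aln <- quick_sim(balanced6, 100, 37)$aln
  rates <- rep(0L, 100)
  st <- strip_fastest(aln, rates, steps = c(1, 0.5))
  expect_equal(st[["f=1.00"]]$sites, 1:100)
  expect_equal(st[["f=0.50"]]$sites, 1:50)   # ties broken leftmost

  rt <- slowfast_rates(aln, list(x = c("a", "b", "c"), y = c("d", "e", "f")))
  st2 <- strip_fastest(aln, rt, steps = c(1, 0.8, 0.6, 0.5))
  for (i in 2:4) {
    expect_true(all(st2[[i]]$sites %in% st2[[i - 1]]$sites))
    expect_equal(length(st2[[i]]$sites), ceiling(c(1, .8, .6, .5)[i] * 100))
  }
  expect_error(strip_fastest(aln, rates, steps = c(0.5, 0.9)), "decreasing")
})

test_that("slow-fast rates track the simulator's true site rates", {
  for (s in 1:3) {
    fx <- quick_sim(balanced6, 4000, 80 + s, gamma_shape = 0.4)
    rt <- slowfast_rates(fx$aln, list(x = c("a", "b", "c"), y = c("d", "e", "f")))
    rho <- stats::cor(rt$rate, fx$site_info$rate, method = "spearman")
    expect_gt(rho, 0.5)
  }
})

test_that("true fast sites are enriched among the stripped columns", {
  fx <- quick_sim(balanced6, 4000, 91, gamma_shape = 0.3)
  rt <- slowfast_rates(fx$aln, list(x = c("a", "b", "c"), y = c("d", "e", "f")))
  st <- strip_fastest(fx$aln, rt, steps = c(1, 0.7))
  removed <- setdiff(seq_len(4000), st[["f=0.70"]]$sites)
  top <- fx$site_info$gamma_cat == 4
  enrichment <- mean(top[removed]) / mean(top)
  expect_gte(enrichment, 2)
})

test_that("a fast-site-borne clade is lost by 50% stripping; stable clades persist", {
  fx <- make_slowfast_fixture(seed = 5)
  sf <- slowfast_scan(fx$aln, fx$groups,
                      list(focal = fx$focal, control = fx$control),
                      steps = c(1, 0.5), B = 40, seed = 5)
  full <- sf[sf$fraction == 1, ]
  half <- sf[sf$fraction == 0.5, ]
  expect_true(full$recovered[full$clade == "focal"])
  expect_gt(full$support[full$clade == "focal"], 0.5)
  expect_false(half$recovered[half$clade == "focal"])
  expect_lt(half$support[half$clade == "focal"], 0.3)
  expect_true(all(sf$recovered[sf$clade == "control"]))
  expect_true(all(sf$support[sf$clade == "control"] > 0.8))

  # single-step scan equals the baseline inference
  sf1 <- slowfast_scan(fx$aln, fx$groups, list(focal = fx$focal),
                       steps = 1, B = 10, seed = 2)
  expect_equal(nrow(sf1), 1L)
  expect_equal(sf1$n_sites, n_sites(fx$aln))
})

test_that("long-branch extraction separates artifact from true grouping", {
  fx <- make_lba_fixture(seed = 6, n_taxa = 8, n_sites = 5000)
  r <- lbe_test(fx$aln, infer_pnj, "A", "B")
  expect_true(r$grouped_in_baseline)
  expect_equal(r$verdict, "LBA-suspected")

  nwk <- paste0("(((A:1.0,B:1.0):0.3,((C1:0.05,C2:0.05):0.1,",
                "(D1:0.05,D2:0.05):0.1):0.05):0.1,(E1:0.05,E2:0.05):0.05);")
  ts <- quick_sim(nwk, 5000, 6)
  r2 <- lbe_test(ts$aln, infer_pnj, "A", "B")
  expect_equal(r2$verdict, "LBA-not-supported")

  expect_error(lbe_test(fx$aln, infer_pnj, "ZZ", "B"), "missing")
  expect_error(lbe_test(fx$aln, infer_pnj, c("A", "B"), "B"), "disjoint")
})
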