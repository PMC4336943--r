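# Desk-scale likelihood core: Felsenstein pruning over site patterns,
# GTR+Gamma optimization on a fixed topology, and a finite compositional
# profile mixture ("CAT-like") fit by generalized EM. The engine is generic
# in the state space, so nucleotide and amino-acid data share one code path.

logsumexp <- function(m) {
  # column-wise log-sum-exp of a matrix of logs
  mx <- apply(m, 2, max)
  mx + log(colSums(exp(m - rep(mx, each = nrow(m)))))
}

compress_patterns <- function(codes) {
  key <- apply(codes, 2, paste, collapse = ",")
  first <- which(!duplicated(key))
  map <- match(key, key[first])
  list(patterns = codes[, first, drop = FALSE],
       weights = as.numeric(tabulate(map, length(first))),
       map = map)
}

tip_partials <- function(patterns, k) {
  n_tip <- nrow(patterns)
  out <- vector("list", n_tip)
  for (i in seq_len(n_tip)) {
    m <- matrix(0, k, ncol(patterns))
    st <- patterns[i, ]
    amb <- st == 0L
    m[cbind(st[!amb], which(!amb))] <- 1
    m[, amb] <- 1
    out[[i]] <- m
  }
  names(out) <- rownames(patterns)
  out
}

# One pruning pass for a single rate matrix and rate multiplier.
# Returns log pattern likelihoods.
prune_pass <- function(tree_po, tipp, me, elen, root_freq) {
  edge <- tree_po$edge
  n_tip <- length(tree_po$tip.label)
  n_node <- max(edge)
  k <- me$k
  acc <- vector("list", n_node)
  lsc <- vector("list", n_node)
  for (e in seq_len(nrow(edge))) {
    par <- edge[e, 1]; ch <- edge[e, 2]
    if (ch <= n_tip) {
      part <- tipp[[ch]]; lch <- 0
    } else {
      part <- acc[[ch]]; lch <- lsc[[ch]]
    }
    m <- pmat(me, elen[e]) %*% part
    sc <- colSums(m)
    sc[sc <= 0] <- 1e-300
    m <- m / rep(sc, each = k)
    lch <- lch + log(sc)
    if (is.null(acc[[par]])) {
      acc[[par]] <- m; lsc[[par]] <- lch
    } else {
      acc[[par]] <- acc[[par]] * m; lsc[[par]] <- lsc[[par]] + lch
    }
  }
  root <- edge[nrow(edge), 1]
  lik <- colSums(acc[[root]] * root_freq)
  lik[lik <= 0] <- 1e-300
  log(lik) + lsc[[root]]
}

# Log pattern likelihoods for one mixture class (gamma-averaged).
class_log_pattern_lik <- function(tree_po, tipp, exch, freq, bl, gamma_rates) {
  me <- model_eigen(exch, freq)
  P <- ncol(tipp[[1]])
  lr <- vapply(gamma_rates, function(r) {
    prune_pass(tree_po, tipp, me, bl * r, freq)
  }, numeric(P))
  if (length(gamma_rates) == 1) return(as.numeric(lr))
  lr <- matrix(lr, nrow = P)          # vapply drops dims when P == 1
  logsumexp(t(lr)) - log(length(gamma_rates))
}

# Mixture log pattern likelihoods: returns list(log_pat, by_class C x P).
mixture_log_pattern_lik <- function(tree_po, tipp, exch, profiles, weights,
                                    gamma_rates) {
  C <- nrow(profiles)
  P <- ncol(tipp[[1]])
  by_class <- vapply(seq_len(C), function(c) {
    class_log_pattern_lik(tree_po, tipp, exch, profiles[c, ],
                          tree_po$edge.length, gamma_rates)
  }, numeric(P))
  by_class <- t(matrix(by_class, nrow = P))   # C x P even when P == 1
  log_pat <- if (C == 1) as.numeric(by_class) + 0 else logsumexp(by_class + log(weights))
  list(log_pat = log_pat, by_class = by_class)
}

#' Substitution model specification
#'
#' Describes the model family [fit_model()] optimizes: how exchangeabilities
#' and the composition profile(s) are treated, the number of mixture classes
#' `C`, and whether discrete-gamma rate variation is included.
#'
#' @param name Display name.
#' @param exch `"free"` (GTR-style, optimized), `"equal"` (all equal, the
#'   Jukes-Cantor/Poisson exchangeability pattern) or `"fixed"` (supply
#'   `exch_fixed`, e.g. an empirical amino-acid matrix).
#' @param freq `"free"` (optimized), `"empirical"` (observed frequencies),
#'   `"equal"`, or `"fixed"` (supply `freq_fixed`).
#' @param C Number of compositional profile classes; `C > 1` gives the
#'   site-heterogeneous mixture fit by EM.
#' @param gamma Logical; include discrete-gamma among-site rate variation.
#' @param k_gamma Number of gamma categories.
#' @param exch_fixed,freq_fixed Fixed parameter values when requested.
#' @param n_restarts Seeded EM restarts for `C > 1` (best fit kept).
#' @param tol EM convergence tolerance on the log-likelihood.
#' @param max_iter Maximum EM iterations.
#' @param optim_maxit Iteration cap for the numerical optimizer.
#' @return A `model_spec` list.
#' @export
model_spec <- function(name = NULL,
                       exch = c("free", "equal", "fixed"),
                       freq = c("free", "empirical", "equal", "fixed"),
                       C = 1, gamma = TRUE, k_gamma = 4,
                       exch_fixed = NULL, freq_fixed = NULL,
                       n_restarts = 5, tol = 1e-6, max_iter = 500,
                       optim_maxit = 200) {
  exch <- match.arg(exch)
  freq <- match.arg(freq)
  if (exch == "fixed" && is.null(exch_fixed)) abort("exch = 'fixed' needs `exch_fixed`")
  if (freq == "fixed" && is.null(freq_fixed)) abort("freq = 'fixed' needs `freq_fixed`")
  if (C < 1) abort("C must be >= 1")
  structure(list(name = name %||% sprintf("%s/%s C=%d%s", exch, freq, C,
                                          if (gamma) "+G" else ""),
                 exch = exch, freq = freq, C = as.integer(C), gamma = gamma,
                 k_gamma = k_gamma, exch_fixed = exch_fixed,
                 freq_fixed = freq_fixed, n_restarts = n_restarts, tol = tol,
                 max_iter = max_iter, optim_maxit = optim_maxit),
            class = "model_spec")
}

#' @rdname model_spec
#' @export
spec_jc <- function(gamma = FALSE) {
  model_spec(name = "JC", exch = "equal", freq = "equal", gamma = gamma)
}

#' @rdname model_spec
#' @export
spec_gtr <- function(gamma = TRUE) {
  model_spec(name = if (gamma) "GTR+G" else "GTR", exch = "free", freq = "free",
             gamma = gamma)
}

#' @rdname model_spec
#' @param ... Passed on to [model_spec()].
#' @export
spec_cat <- function(C = 4, gamma = TRUE, ...) {
  model_spec(name = sprintf("CAT-C%d", C), exch = "equal", freq = "free",
             C = C, gamma = gamma, ...)
}

#' @rdname model_spec
#' @export
spec_catgtr <- function(C = 4, gamma = TRUE, ...) {
  model_spec(name = sprintf("CAT+GTR-C%d", C), exch = "free", freq = "free",
             C = C, gamma = gamma, ...)
}

#' @rdname model_spec
#' @export
spec_mtart <- function(gamma = TRUE) {
  ref <- aa_reference_model("mtArt")
  model_spec(name = "mtArt", exch = "fixed", freq = "fixed",
             exch_fixed = ref$exch, freq_fixed = ref$freq, gamma = gamma)
}

empirical_freq <- function(codes, k) {
  tab <- tabulate(codes[codes > 0L], k)
  if (sum(tab) == 0) return(rep(1 / k, k))
  f <- tab / sum(tab)
  (f + 1e-6) / sum(f + 1e-6)
}

softmax <- function(x) { e <- exp(x - max(x)); e / sum(e) }

#' Fit a substitution model on a fixed topology
#'
#' For `C = 1`, branch lengths, the gamma shape, and any free
#' exchangeabilities/frequencies are optimized numerically (L-BFGS-B on log
#' scale) under Felsenstein pruning. For `C > 1`, branch lengths and gamma
#' shape are first fit under the homogeneous `C = 1` model and then held
#' fixed while class profiles and weights are fit by generalized EM
#' (responsibility-weighted numerical update of each profile), with the best
#' of `n_restarts` seeded starts kept.
#'
#' @param aln An [msa].
#' @param tree Fixed topology (`ape::phylo`); branch lengths, if present,
#'   seed the optimization.
#' @param spec A [model_spec()].
#' @param seed Integer seed (EM restarts, jitter).
#' @return A `het_fit` object: tree with fitted branch lengths, fitted
#'   `exch`, `profiles` (C x states), `weights`, `gamma_shape`, `logL`,
#'   and bookkeeping fields. Supports [tidy()]/[glance()].
#' @export
fit_model <- function(aln, tree, spec = spec_gtr(), seed = 1L) {
  stopifnot(inherits(aln, "msa"), inherits(tree, "phylo"))
  if (!setequal(tree$tip.label, msa_taxa(aln))) {
    abort("tree tips and alignment taxa differ")
  }
  if (n_sites(aln) < 50 * spec$C) {
    abort(sprintf("need at least %d sites to fit C=%d classes", 50 * spec$C, spec$C))
  }
  k <- if (aln$alphabet == "nucleotide") 4L else 20L
  codes <- msa_codes(aln)
  tree_po <- stats::reorder(tree, "postorder")
  cp <- compress_patterns(codes[tree_po$tip.label, , drop = FALSE])
  tipp <- tip_partials(cp$patterns, k)
  wts <- cp$weights

  n_ex <- k * (k - 1) / 2
  exch0 <- switch(spec$exch,
                  equal = rep(1, n_ex),
                  fixed = spec$exch_fixed,
                  free = rep(1, n_ex))
  freq0 <- switch(spec$freq,
                  equal = rep(1 / k, k),
                  fixed = spec$freq_fixed,
                  empirical = empirical_freq(codes, k),
                  free = empirical_freq(codes, k))
  bl0 <- tree_po$edge.length %||% rep(0.1, nrow(tree_po$edge))
  bl0 <- pmax(bl0, 1e-6)
  alpha0 <- 1

  n_edge <- length(bl0)
  free_exch <- spec$exch == "free"
  free_freq <- spec$freq %in% c("free")
  par0 <- log(bl0)
  lower <- rep(log(1e-7), n_edge); upper <- rep(log(20), n_edge)
  if (free_exch) {
    par0 <- c(par0, rep(0, n_ex - 1))
    lower <- c(lower, rep(-8, n_ex - 1)); upper <- c(upper, rep(8, n_ex - 1))
  }
  if (free_freq) {
    par0 <- c(par0, log(freq0[-k] / freq0[k]))
    lower <- c(lower, rep(-12, k - 1)); upper <- c(upper, rep(12, k - 1))
  }
  if (spec$gamma) {
    par0 <- c(par0, log(alpha0))
    lower <- c(lower, log(0.02)); upper <- c(upper, log(100))
  }

  unpack <- function(par) {
    i <- n_edge
    bl <- exp(par[seq_len(n_edge)])
    exch <- exch0
    if (free_exch) { exch <- c(exp(par[i + seq_len(n_ex - 1)]), 1); i <- i + n_ex - 1 }
    freq <- freq0
    if (free_freq) { freq <- softmax(c(par[i + seq_len(k - 1)], 0)); i <- i + k - 1 }
    alpha <- if (spec$gamma) exp(par[i + 1]) else Inf
    list(bl = bl, exch = exch, freq = freq, alpha = alpha)
  }
  gamma_rates <- function(alpha) {
    if (is.infinite(alpha)) 1 else discrete_gamma_rates(alpha, spec$k_gamma)
  }
  negll <- function(par) {
    p <- unpack(par)
    lp <- class_log_pattern_lik(tree_po, tipp, p$exch, p$freq, p$bl,
                                gamma_rates(p$alpha))
    v <- -sum(wts * lp)
    if (!is.finite(v)) return(1e10)
    v
  }
  opt <- stats::optim(par0, negll, method = "L-BFGS-B", lower = lower,
                      upper = upper,
                      control = list(maxit = spec$optim_maxit, factr = 1e9))
  p1 <- unpack(opt$par)
  tree_fit <- tree_po
  tree_fit$edge.length <- p1$bl
  logL1 <- -opt$value

  profiles <- matrix(p1$freq, nrow = 1)
  weights <- 1
  logL <- logL1
  em_trace <- NULL

  if (spec$C > 1) {
    gr <- gamma_rates(p1$alpha)
    best <- NULL
    set.seed(seed)
    # restart 0 starts every class at the homogeneous solution: a fixed point
    # of EM, so the final mixture can never score below the C = 1 fit
    for (rs in 0:spec$n_restarts) {
      prof <- if (rs == 0) {
        matrix(rep(p1$freq, spec$C), nrow = spec$C, byrow = TRUE)
      } else {
        init_profiles(cp$patterns, wts, spec$C, k, jitter = rs > 1)
      }
      w <- rep(1 / spec$C, spec$C)
      prev <- -Inf; trace <- numeric(0)
      for (it in seq_len(spec$max_iter)) {
        ml <- mixture_log_pattern_lik(tree_fit, tipp, p1$exch, prof, w, gr)
        ll <- sum(wts * ml$log_pat)
        trace <- c(trace, ll)
        if (ll - prev < spec$tol && it > 2) break
        prev <- ll
        # E-step: responsibilities
        lw <- ml$by_class + log(w)
        resp <- exp(lw - rep(logsumexp(lw), each = spec$C))
        # M-step: weights and profiles
        w <- as.numeric(resp %*% wts); w <- w / sum(w)
        for (cc in seq_len(spec$C)) {
          rw <- resp[cc, ] * wts
          if (sum(rw) < 1e-8) next
          obj <- function(th) {
            f <- softmax(c(th, 0))
            -sum(rw * class_log_pattern_lik(tree_fit, tipp, p1$exch, f,
                                            tree_fit$edge.length, gr))
          }
          th0 <- log(prof[cc, -k] / prof[cc, k])
          o <- stats::optim(th0, obj, method = "BFGS",
                            control = list(maxit = 10, reltol = 1e-5))
          prof[cc, ] <- softmax(c(o$par, 0))
        }
      }
      if (is.null(best) || prev > best$logL) {
        best <- list(profiles = prof, weights = w, logL = prev, trace = trace)
      }
    }
    profiles <- best$profiles
    weights <- best$weights
    logL <- best$logL
    em_trace <- best$trace
  }

  np <- length(par0) + (spec$C > 1) * (spec$C - 1) * k  # free params (approx.)
  structure(list(
    spec = spec, alphabet = aln$alphabet, k = k,
    tree = tree_fit, exch = p1$exch, profiles = profiles, weights = weights,
    gamma_shape = p1$alpha, k_gamma = spec$k_gamma,
    logL = logL, logL_homogeneous = logL1,
    converged = opt$convergence == 0, em_trace = em_trace,
    n_sites = n_sites(aln), n_patterns = ncol(cp$patterns),
    np = np, seed = seed
  ), class = "het_fit")
}

# initial profiles: k-means on per-pattern tip-state composition
init_profiles <- function(patterns, wts, C, k, jitter = FALSE) {
  comp <- t(apply(patterns, 2, function(col) {
    tab <- tabulate(col[col > 0L], k)
    if (sum(tab) == 0) rep(1 / k, k) else tab / sum(tab)
  }))
  if (jitter) {
    centers <- comp[sample.int(nrow(comp), C), , drop = FALSE]
  } else {
    km <- try(stats::kmeans(comp, centers = C, nstart = 2), silent = TRUE)
    centers <- if (inherits(km, "try-error")) {
      comp[sample.int(nrow(comp), C), , drop = FALSE]
    } else km$centers
  }
  centers <- centers + 0.02
  centers / rowSums(centers)
}

#' @export
print.het_fit <- function(x, ...) {
  cat(sprintf("<het_fit> %s | %d-state | C=%d | logL = %.3f\n",
              x$spec$name, x$k, nrow(x$profiles), x$logL))
  invisible(x)
}

#' Per-site log-likelihoods under a fitted model
#'
#' Evaluates the fitted model (all parameters frozen) on an alignment over
#' the same taxa — typically the held-out columns of a cross-validation
#' split. Mixture models integrate sites over profile classes with the
#' fitted weights.
#'
#' @param fit A `het_fit`.
#' @param aln An [msa] over (a subset of) the fit's taxa.
#' @return Numeric vector of per-site log-likelihoods (length `ncol(aln)`).
#' @export
site_log_likelihoods <- function(fit, aln) {
  if (n_sites(aln) == 0) return(numeric(0))
  if (!setequal(msa_taxa(aln), fit$tree$tip.label)) {
    abort("alignment taxa must match the fitted tree")
  }
  codes <- msa_codes(aln)
  cp <- compress_patterns(codes[fit$tree$tip.label, , drop = FALSE])
  tipp <- tip_partials(cp$patterns, fit$k)
  gr <- if (is.infinite(fit$gamma_shape)) 1 else
    discrete_gamma_rates(fit$gamma_shape, fit$k_gamma)
  ml <- mixture_log_pattern_lik(fit$tree, tipp, fit$exch, fit$profiles,
                                fit$weights, gr)
  ml$log_pat[cp$map]
}

#' Simulate an alignment under a fitted model
#'
#' Sites draw a profile class from the fitted mixture weights and a discrete
#' gamma category, then evolve along the fitted tree.
#'
#' @param fit A `het_fit`.
#' @param n_sites Number of sites (0 gives an empty alignment).
#' @param seed Integer seed.
#' @param tree Optional replacement tree (defaults to the fitted one).
#' @return An [msa] with attributes `class_id` and `rate` per site.
#' @export
simulate_under_fit <- function(fit, n_sites, seed = 1L, tree = NULL) {
  tree <- tree %||% fit$tree
  states <- if (fit$k == 4) NT_STATES else AA_STATES
  if (n_sites == 0) {
    m <- matrix(character(0), nrow = length(tree$tip.label), ncol = 0,
                dimnames = list(tree$tip.label, NULL))
    return(msa(m, fit$alphabet))
  }
  set.seed(seed)
  C <- nrow(fit$profiles)
  cls <- sample.int(C, n_sites, replace = TRUE, prob = fit$weights)
  gr <- if (is.infinite(fit$gamma_shape)) 1 else
    discrete_gamma_rates(fit$gamma_shape, fit$k_gamma)
  gcat <- sample.int(length(gr), n_sites, replace = TRUE)
  rates <- gr[gcat]
  out <- matrix(NA_character_, length(tree$tip.label), n_sites,
                dimnames = list(tree$tip.label, NULL))
  for (cc in seq_len(C)) {
    idx <- which(cls == cc)
    if (!length(idx)) next
    me <- model_eigen(fit$exch, fit$profiles[cc, ])
    m <- sim_states(tree, length(idx), list(me), rep(1L, nrow(tree$edge)),
                    tree$edge.length, rates[idx], fit$profiles[cc, ])
    out[rownames(m), idx] <- matrix(states[m], nrow = nrow(m))
  }
  res <- msa(out, fit$alphabet)
  attr(res, "class_id") <- cls
  attr(res, "rate") <- rates
  res
}
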