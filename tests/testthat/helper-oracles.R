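# Independent oracles used by unit and acceptance tests. Each is written as
# a direct enumeration, deliberately sharing no code with the package paths
# it checks.

# Nei-Gojobori single-codon oracle: recursive enumeration of substitution
# orderings under the invertebrate mitochondrial code.
oracle_ng <- function(cod1, cod2) {
  code <- invert_mito_code()
  n_sites_codon <- function(cod) {
    tot <- 0
    for (pos in 1:3) {
      for (b in c("A", "C", "G", "T")) {
        if (substr(cod, pos, pos) == b) next
        alt <- cod
        substr(alt, pos, pos) <- b
        syn <- (code[[alt]] == code[[cod]]) && code[[alt]] != "*"
        tot <- tot + (!syn) / 3
      }
    }
    tot
  }
  enum_paths <- function(from, to) {
    dif <- which(strsplit(from, "")[[1]] != strsplit(to, "")[[1]])
    if (!length(dif)) return(list(list(nd = 0, sd = 0, stop = FALSE)))
    out <- list()
    for (pos in dif) {
      nxt <- from
      substr(nxt, pos, pos) <- substr(to, pos, pos)
      step_syn <- (code[[from]] == code[[nxt]]) && code[[from]] != "*"
      hit_stop <- code[[nxt]] == "*" && nxt != to
      for (rest in enum_paths(nxt, to)) {
        out[[length(out) + 1]] <- list(nd = rest$nd + (!step_syn),
                                       sd = rest$sd + step_syn,
                                       stop = rest$stop || hit_stop)
      }
    }
    out
  }
  paths <- enum_paths(cod1, cod2)
  ok <- Filter(function(p) !p$stop, paths)
  if (!length(ok)) ok <- paths
  list(N = (n_sites_codon(cod1) + n_sites_codon(cod2)) / 2,
       Nd = mean(vapply(ok, `[[`, numeric(1), "nd")))
}

# Exhaustive parsimony oracle: minimum changes over all internal-state
# labelings; missing tips (NA) constrain nothing.
oracle_fitch <- function(tree, states) {
  tree <- stats::reorder(tree, "postorder")
  edge <- tree$edge
  nt <- length(tree$tip.label)
  ints <- sort(unique(edge[, 1]))
  grid <- as.matrix(expand.grid(rep(list(1:4), length(ints))))
  best <- Inf
  for (g in seq_len(nrow(grid))) {
    asg <- stats::setNames(grid[g, ], ints)
    cost <- 0
    for (e in seq_len(nrow(edge))) {
      ch <- edge[e, 2]
      cs <- if (ch <= nt) states[tree$tip.label[ch]] else asg[as.character(ch)]
      if (is.na(cs)) next
      cost <- cost + (asg[as.character(edge[e, 1])] != cs)
    }
    best <- min(best, cost)
  }
  best
}

# Brute-force likelihood oracle on a 4-leaf tree: sums over internal state
# assignments, with transition matrices from a truncated series expansion.
oracle_loglik_4leaf <- function(tree, patterns, exch, freq) {
  tree <- stats::reorder(tree, "postorder")
  Q <- hetphylo:::rate_matrix(exch, freq)
  expm_series <- function(M) {
    out <- diag(4); term <- diag(4)
    for (k in 1:60) { term <- term %*% M / k; out <- out + term }
    out
  }
  P <- lapply(seq_len(nrow(tree$edge)),
              function(e) expm_series(Q * tree$edge.length[e]))
  edge <- tree$edge
  ints <- sort(unique(edge[, 1]))
  grid <- as.matrix(expand.grid(rep(list(1:4), length(ints))))
  root <- edge[nrow(edge), 1]
  vapply(seq_len(ncol(patterns)), function(s) {
    st <- patterns[, s]
    tot <- 0
    for (g in seq_len(nrow(grid))) {
      asg <- stats::setNames(grid[g, ], ints)
      pr <- freq[asg[as.character(root)]]
      for (e in seq_len(nrow(edge))) {
        par <- asg[as.character(edge[e, 1])]
        ch <- edge[e, 2]
        cs <- if (ch <= 4) st[ch] else asg[as.character(ch)]
        if (ch <= 4 && cs == 0) next
        pr <- pr * P[[e]][par, cs]
      }
      tot <- tot + pr
    }
    log(tot)
  }, numeric(1))
}
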