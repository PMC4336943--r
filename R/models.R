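# Reversible substitution-model machinery shared by the simulator and the
# likelihood core. Everything is generic in the number of states so the same
# code serves nucleotide (k = 4) and amino-acid (k = 20) data.

# Build a symmetric exchangeability matrix from the lower-triangle vector in
# column-wise (PAML) order: (2,1),(3,1),...,(k,1),(3,2),...
exch_matrix <- function(exch, k) {
  if (is.matrix(exch)) {
    stopifnot(nrow(exch) == k, ncol(exch) == k)
    return((exch + t(exch)) / 2)
  }
  stopifnot(length(exch) == k * (k - 1) / 2)
  m <- matrix(0, k, k)
  m[lower.tri(m)] <- exch
  m + t(m)
}

# Scaled rate matrix Q with stationary distribution `freq`:
# Q[i,j] = s[i,j] * freq[j], diagonal set so rows sum to 0, scaled to one
# expected substitution per unit time at stationarity.
rate_matrix <- function(exch, freq) {
  k <- length(freq)
  s <- exch_matrix(exch, k)
  q <- s * rep(freq, each = k)
  diag(q) <- 0
  diag(q) <- -rowSums(q)
  mu <- -sum(freq * diag(q))
  if (mu <= 0) abort("degenerate rate matrix (zero total rate)")
  q / mu
}

# Eigen-decomposition of a reversible Q via symmetrization, giving fast and
# numerically stable transition probabilities P(t).
model_eigen <- function(exch, freq) {
  freq <- pmax(freq, 1e-9)   # numerical floor: zero frequencies break the
  freq <- freq / sum(freq)   # symmetrized eigen-decomposition
  q <- rate_matrix(exch, freq)
  d <- sqrt(freq)
  s <- q * (d / rep(d, each = length(d)))      # diag(d) Q diag(1/d), symmetric
  s <- (s + t(s)) / 2
  e <- eigen(s, symmetric = TRUE)
  list(
    values = e$values,
    right = e$vectors / d,                     # diag(1/d) V
    left = t(e$vectors * d),                   # t(V) diag(d)
    freq = freq,
    k = length(freq)
  )
}

# Transition probability matrix P(t) = exp(Qt); rows renormalized after
# clipping tiny negative round-off.
pmat <- function(me, t) {
  p <- (me$right * rep(exp(me$values * t), each = me$k)) %*% me$left
  p[p < 0] <- 0
  p / rowSums(p)
}

#' Discrete-gamma rate categories
#'
#' Mean-normalized discrete approximation to the gamma(shape, rate = shape)
#' distribution using `k` equal-probability categories, each represented by
#' its conditional mean.
#'
#' @param alpha Gamma shape parameter (> 0).
#' @param k Number of categories (default 4).
#' @return Numeric vector of `k` relative rates with mean 1.
#' @export
discrete_gamma_rates <- function(alpha, k = 4) {
  if (!is.numeric(alpha) || alpha <= 0) abort("gamma shape `alpha` must be > 0")
  if (k == 1) return(1)
  q <- stats::qgamma(seq(0, 1, length.out = k + 1), shape = alpha, rate = alpha)
  p <- stats::pgamma(q, shape = alpha + 1, rate = alpha)
  r <- k * diff(p)
  r / (mean(r))
}

# default nucleotide stationary composition of an AT-rich insect mitogenome
at_rich_freq <- function(at = 0.75, a_bias = 0.55, c_share = 0.5) {
  c(A = at * a_bias, C = (1 - at) * c_share,
    G = (1 - at) * (1 - c_share), T = at * (1 - a_bias))
}

# mtArt-style fixed amino-acid reference model (exchangeabilities + stationary
# frequencies from phangorn's model tables)
aa_reference_model <- function(name = "mtArt") {
  Q <- NULL; bf <- NULL
  phangorn_get <- get("getModelAA", envir = asNamespace("phangorn"))
  phangorn_get(name, bf = TRUE, Q = TRUE)
  list(exch = Q, freq = unname(bf))
}
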