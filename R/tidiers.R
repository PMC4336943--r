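#' @importFrom generics tidy glance augment
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a fitted substitution model
#'
#' One row per parameter: branch lengths, exchangeabilities, per-class
#' profile frequencies and weights, and the gamma shape.
#'
#' @param x A `het_fit`.
#' @param ... Unused.
#' @return A tibble with `term`, `class`, `estimate`.
#' @export
tidy.het_fit <- function(x, ...) {
  states <- if (x$k == 4) NT_STATES else AA_STATES
  bl <- tibble(term = paste0("branch_", seq_along(x$tree$edge.length)),
               class = NA_integer_, estimate = x$tree$edge.length)
  ex <- tibble(term = paste0("exch_", seq_along(x$exch)),
               class = NA_integer_, estimate = as.numeric(x$exch))
  prof <- purrr::map_dfr(seq_len(nrow(x$profiles)), function(cc) {
    tibble(term = paste0("freq_", states), class = cc,
           estimate = as.numeric(x$profiles[cc, ]))
  })
  w <- tibble(term = "weight", class = seq_along(x$weights),
              estimate = as.numeric(x$weights))
  g <- tibble(term = "gamma_shape", class = NA_integer_, estimate = x$gamma_shape)
  dplyr::bind_rows(bl, ex, prof, w, g)
}

#' One-line summary of a fitted model
#'
#' @param x A `het_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `model`, `logL`, `n_classes`, `gamma_shape`,
#'   `n_sites`, `n_patterns`, `np`, `converged`.
#' @export
glance.het_fit <- function(x, ...) {
  tibble(model = x$spec$name, logL = x$logL, n_classes = nrow(x$profiles),
         gamma_shape = x$gamma_shape, n_sites = x$n_sites,
         n_patterns = x$n_patterns, np = x$np, converged = x$converged)
}

#' Tidy a cross-validation report
#'
#' @param x A `cv_report`.
#' @param ... Unused.
#' @return Per-replicate tibble (the report itself, without attributes).
#' @export
tidy.cv_report <- function(x, ...) {
  as_tibble(unclass(x)[c("rep", "score1", "score2", "delta", "delta_per_site",
                         "n_test")])
}

#' Summarize a cross-validation report
#'
#' @param x A `cv_report`.
#' @param ... Unused.
#' @return One-row tibble: `model1`, `model2`, `mean_score`, `sd_score`,
#'   `mean_per_site`, `reps`, `fraction`.
#' @export
glance.cv_report <- function(x, ...) {
  tibble(model1 = attr(x, "model1"), model2 = attr(x, "model2"),
         mean_score = attr(x, "mean"), sd_score = attr(x, "sd"),
         mean_per_site = attr(x, "mean_per_site"), reps = nrow(x),
         fraction = attr(x, "fraction"))
}

#' Tidy a divergence matrix into pair rows
#'
#' @param x A `divergence_matrix`.
#' @param ... Unused.
#' @return Tibble `taxon1`, `taxon2`, `score` (each unordered pair once).
#' @export
tidy.divergence_matrix <- function(x, ...) {
  taxa <- rownames(x)
  ut <- which(upper.tri(x), arr.ind = TRUE)
  tibble(taxon1 = taxa[ut[, 1]], taxon2 = taxa[ut[, 2]],
         score = x[upper.tri(x)])
}

#' Tidy a posterior-predictive homoplasy report
#'
#' @param x A `ppred_homoplasy`.
#' @param ... Unused.
#' @return One-row tibble: `h_obs`, `h_sim_mean`, `h_sim_sd`, `z`, `p`, `R`.
#' @export
tidy.ppred_homoplasy <- function(x, ...) {
  tibble(h_obs = x$h_obs, h_sim_mean = mean(x$h_sim),
         h_sim_sd = stats::sd(x$h_sim), z = x$z, p = x$p, R = x$R)
}

#' Tidy a rate-correlation result
#'
#' @param x A `rate_correlation`.
#' @param ... Unused.
#' @return The per-taxon (Ka, branch length) tibble.
#' @export
tidy.rate_correlation <- function(x, ...) x$data

#' @rdname tidy.rate_correlation
#' @export
glance.rate_correlation <- function(x, ...) {
  tibble(r = x$r, r_squared = x$r_squared, n = nrow(x$data),
         n_excluded = length(x$excluded))
}
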