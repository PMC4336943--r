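# End-to-end orchestration: a declarative config drives dataset assembly and
# every diagnostic stage, with per-stage failure isolation, TSV/JSON outputs
# in write-once stage directories, and a checksum manifest.

#' Small simulation config for pipeline runs
#'
#' An 8-taxon, configurable-length dataset with one fast, AT-shifted clade —
#' the smallest geometry that exercises every diagnostic stage.
#'
#' @param n_sites Total concatenated length (PCG block ~70%, one RNA block).
#' @param seed Integer seed.
#' @param n_taxa Number of taxa (8 supported).
#' @return A `sim_dataset`.
#' @export
make_small_fixture <- function(n_sites = 2000, seed = 1L, n_taxa = 8) {
  if (n_taxa != 8) abort("the small fixture is 8 taxa")
  nwk <- paste0("(((a1:0.10,a2:0.12):0.06,(a3:0.11,a4:0.09):0.05):0.08,",
                "((b1:0.10,b2:0.11):0.05,(b3:0.12,b4:0.10):0.06):0.08);")
  tree <- read_newick(nwk)
  pcg_len <- (round(n_sites * 0.7) %/% 3L) * 3L
  genes <- tibble(gene = c("pcgA", "rnaA"), type = c("PCG", "rRNA"),
                  length = c(pcg_len, as.integer(n_sites - pcg_len)))
  cfg <- simulation_config(
    tree, freq = at_rich_freq(0.74),
    lineage_overrides = list(list(clade = c("b3", "b4"), rate = 1.8,
                                  freq = at_rich_freq(0.84))),
    seed = seed)
  out <- simulate_dataset(cfg, genes)
  out$clades <- list(a_left = c("a1", "a2"), a_right = c("a3", "a4"),
                     b_left = c("b1", "b2"), b_fast = c("b3", "b4"))
  out
}

default_pipeline_config <- function() {
  list(
    seed = 1L,
    out_dir = tempfile("hetphylo_run_"),
    input = list(mode = "simulate", preset = "small", n_sites = 2000),
    datasets = c("PCG", "PCG12", "PCGRNA", "AA"),
    reference_taxon = NULL,
    groups = NULL,
    focal_clades = NULL,
    lbe = NULL,
    stages = c("datasets", "composition", "rates", "heterodiv", "fit",
               "crossval", "ppred", "saturation", "slowfast", "lbe"),
    params = list(ppred_R = 20, cv_reps = 3, shuffles = 30, boot_B = 30,
                  steps = c(1, 0.8, 0.6, 0.5), cat_classes = 2)
  )
}

read_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1 && file.exists(config)) {
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(default_pipeline_config(), config)
  cfg
}

#' Run the full diagnostics pipeline
#'
#' Executes the configured stages in dependency order on simulated (or
#' supplied) data, writing machine-readable outputs and a run manifest under
#' `out_dir`. Stage failures are isolated: later stages that do not depend
#' on the failed one still run, and the manifest records per-stage status.
#'
#' @param config A config list or a path to a YAML file. Recognized fields:
#'   `seed`, `out_dir`, `input` (`mode = "simulate"` with `preset`
#'   `"small"`/`"paraneoptera"` and `n_sites`, or `mode = "files"` with
#'   `fasta`, `genes`, `tree`), `datasets`, `reference_taxon`, `groups`,
#'   `focal_clades`, `lbe` (`setA`, `setB`), `stages`, and `params`
#'   (`ppred_R`, `cv_reps`, `shuffles`, `boot_B`, `steps`, `cat_classes`).
#' @return A `run_manifest` list: per-stage status, output file checksums,
#'   seeds, timestamps.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- read_pipeline_config(config)
  t0 <- Sys.time()
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  status <- list()
  results <- new.env(parent = emptyenv())

  # ---- pre-flight: resolve input and validate references before compute
  if ("rates" %in% cfg$stages && is.null(cfg$reference_taxon)) {
    abort("config error: rates stage enabled but no `reference_taxon` given")
  }
  simdat <- pipeline_input(cfg)
  taxa <- msa_taxa(simdat$aln)
  named_taxa <- c(cfg$reference_taxon, unlist(cfg$groups),
                  unlist(cfg$focal_clades), unlist(cfg$lbe))
  if (!all(named_taxa %in% taxa)) {
    abort(paste0("config error: unresolved taxa: ",
                 paste(setdiff(named_taxa, taxa), collapse = ", ")))
  }
  if (is.null(cfg$groups)) cfg$groups <- simdat$clades[lengths(simdat$clades) >= 2][1:2]
  if (is.null(cfg$focal_clades)) cfg$focal_clades <- simdat$clades[1]

  stage <- function(name, deps = character(0), fun) {
    if (!name %in% cfg$stages) { status[[name]] <<- "skipped"; return(invisible()) }
    if (length(deps) && !all(unlist(status[deps]) == "ok")) {
      status[[name]] <<- paste0("blocked by ", paste(deps, collapse = ","))
      return(invisible())
    }
    dir <- file.path(cfg$out_dir, name)
    dir.create(dir, showWarnings = FALSE)
    res <- tryCatch({ fun(dir); "ok" },
                    error = function(e) paste0("error: ", conditionMessage(e)))
    status[[name]] <<- res
    invisible()
  }
  p <- cfg$params

  stage("datasets", fun = function(dir) {
    built <- purrr::map(cfg$datasets, function(nm) build_dataset(simdat, nm))
    names(built) <- cfg$datasets
    for (nm in cfg$datasets) {
      write_relaxed_phylip(built[[nm]]$aln, file.path(dir, paste0(nm, ".phy")))
      write_partition_spec(built[[nm]]$scheme, file.path(dir, paste0(nm, ".parts")))
    }
    write_newick(simdat$tree, file.path(dir, "true_tree.nwk"))
    assign("built", built, envir = results)
  })

  get_nt <- function() {
    b <- get("built", envir = results)
    nm <- intersect(c("PCGRNA", "PCG"), names(b))[1]
    b[[nm]]$aln
  }

  stage("composition", deps = "datasets", fun = function(dir) {
    aln <- get_nt()
    ct <- composition_table(aln)
    utils::write.table(ct, file.path(dir, "composition.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    chi <- chi2_homogeneity(aln)
    jsonlite::write_json(list(statistic = chi$statistic, df = chi$df,
                              p_value = chi$p_value),
                         file.path(dir, "chi2.json"), auto_unbox = TRUE)
    assign("comp", ct, envir = results)
  })

  stage("rates", deps = "datasets", fun = function(dir) {
    b <- get("built", envir = results)
    pcg <- if ("PCG" %in% names(b)) b$PCG$aln else build_dataset(simdat, "PCG")$aln
    kt <- ka_table(pcg, cfg$reference_taxon)
    utils::write.table(kt, file.path(dir, "ka.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    ingroup <- simdat$ingroup %||% setdiff(taxa, cfg$reference_taxon)
    corr <- tryCatch({
      bl <- tip_to_mrca_lengths(simdat$tree, ingroup)
      cr <- correlate_rates(kt, bl)
      jsonlite::write_json(list(r = cr$r, r_squared = cr$r_squared),
                           file.path(dir, "ka_branchlength.json"), auto_unbox = TRUE)
      cr
    }, error = function(e) NULL)
    assign("ka", kt, envir = results)
  })

  stage("heterodiv", deps = "datasets", fun = function(dir) {
    m <- heterogeneity_matrix(get_nt(), shuffles = p$shuffles, seed = cfg$seed)
    utils::write.table(round(unclass(m), 4), file.path(dir, "divergence_matrix.tsv"),
                       sep = "\t", quote = FALSE)
    assign("hetmat", m, envir = results)
  })

  stage("fit", deps = "datasets", fun = function(dir) {
    aln <- get_nt()
    d <- logdet_distance(aln); d[is.na(d)] <- max(d, na.rm = TRUE) * 1.5
    tr <- neighbor_joining(d)
    fit1 <- fit_model(aln, tr, spec_gtr(), seed = cfg$seed)
    fitC <- fit_model(aln, tr, spec_cat(C = p$cat_classes, n_restarts = 2),
                      seed = cfg$seed)
    for (nm in c("fit1", "fitC")) {
      f <- get(nm)
      jsonlite::write_json(list(model = f$spec$name, logL = f$logL,
                                exch = f$exch, profiles = f$profiles,
                                weights = f$weights, gamma_shape = f$gamma_shape,
                                seed = f$seed),
                           file.path(dir, paste0(nm, ".json")),
                           auto_unbox = TRUE, digits = 10)
    }
    assign("nj_tree", tr, envir = results)
    assign("fit_hom", fit1, envir = results)
    assign("fit_mix", fitC, envir = results)
  })

  stage("crossval", deps = "fit", fun = function(dir) {
    aln <- get_nt()
    tr <- get("nj_tree", envir = results)
    cv <- cross_validate(aln, tr, spec_gtr(gamma = FALSE),
                         spec_cat(C = p$cat_classes, gamma = FALSE, n_restarts = 1),
                         reps = p$cv_reps, seed = cfg$seed)
    utils::write.table(cv, file.path(dir, "cv.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    jsonlite::write_json(list(mean = attr(cv, "mean"), sd = attr(cv, "sd"),
                              model1 = attr(cv, "model1"), model2 = attr(cv, "model2")),
                         file.path(dir, "cv.json"), auto_unbox = TRUE)
  })

  stage("ppred", deps = "fit", fun = function(dir) {
    aln <- get_nt()
    fit1 <- get("fit_hom", envir = results)
    pc <- ppred_composition_test(aln, fit1, R = p$ppred_R, seed = cfg$seed)
    utils::write.table(pc, file.path(dir, "ppred_composition.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    ph <- ppred_homoplasy(aln, fit1$tree, fit1, R = p$ppred_R, seed = cfg$seed)
    jsonlite::write_json(list(h_obs = ph$h_obs, z = ph$z, p = ph$p),
                         file.path(dir, "ppred_homoplasy.json"), auto_unbox = TRUE)
  })

  stage("saturation", deps = "fit", fun = function(dir) {
    aln <- get_nt()
    sat <- saturation_analysis(get("fit_hom", envir = results)$tree,
                               list(true = simdat$tree), aln = aln)
    utils::write.table(sat, file.path(dir, "saturation.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  })

  stage("slowfast", deps = "datasets", fun = function(dir) {
    sf <- slowfast_scan(get_nt(), cfg$groups, cfg$focal_clades,
                        steps = p$steps, B = p$boot_B, seed = cfg$seed)
    utils::write.table(sf, file.path(dir, "slowfast.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  })

  stage("lbe", deps = "datasets", fun = function(dir) {
    sets <- cfg$lbe %||% list(setA = cfg$focal_clades[[1]][1],
                              setB = cfg$focal_clades[[1]][2])
    infer <- function(a) {
      d <- p_distance(a); d[is.na(d)] <- max(d, na.rm = TRUE) * 1.5
      neighbor_joining(d)
    }
    lbe <- lbe_test(get_nt(), infer, sets$setA, sets$setB)
    jsonlite::write_json(list(verdict = lbe$verdict,
                              stayed_A = lbe$stayed_A, stayed_B = lbe$stayed_B),
                         file.path(dir, "lbe.json"), auto_unbox = TRUE)
  })

  files <- list.files(cfg$out_dir, recursive = TRUE, full.names = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("hetphylo")),
    seed = cfg$seed,
    started = format(t0), finished = format(Sys.time()),
    stages = status,
    checksums = as.list(setNames(unname(tools::md5sum(files)),
                                 sub(paste0(cfg$out_dir, "/"), "", files)))
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  class(manifest) <- "run_manifest"
  manifest
}

pipeline_input <- function(cfg) {
  inp <- cfg$input
  if (identical(inp$mode, "simulate")) {
    if (identical(inp$preset, "paraneoptera")) {
      return(make_paraneoptera_fixture(seed = cfg$seed))
    }
    return(make_small_fixture(n_sites = inp$n_sites %||% 2000, seed = cfg$seed))
  }
  if (identical(inp$mode, "files")) {
    genes_tab <- as_tibble(utils::read.delim(inp$genes))
    alns <- purrr::map(setNames(inp$fasta, genes_tab$gene), read_fasta)
    cc <- concatenate_genes(alns, setNames(genes_tab$type, genes_tab$gene))
    sim <- list(genes = alns, aln = cc$aln, scheme = cc$scheme,
                site_info = cc$aln$cols,
                tree = read_newick(inp$tree))
    class(sim) <- "sim_dataset"
    return(sim)
  }
  abort("config error: input mode must be 'simulate' or 'files'")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest>\n")
  for (nm in names(x$stages)) cat(sprintf("  %-12s %s\n", nm, x$stages[[nm]]))
  invisible(x)
}
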