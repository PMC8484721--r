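#' Pipeline stage: simulate a synthetic study
#'
#' Writes a host tree (Newick), a species-level observation table (TSV),
#' optionally a Ct-level table (TSV), and a provenance sidecar (JSON) to
#' `out_dir`. Each stage of the pipeline consumes and emits plain files so
#' that real data can replace any synthetic stage.
#'
#' @param out_dir Output directory (created if missing).
#' @param config A [sim_config()]; the `seed` argument overrides its seed.
#' @param seed Integer seed.
#' @param ct Also emit a Ct-level table via [simulate_ct_experiment()].
#' @param ct_config A [ct_sim_config()] when `ct = TRUE`.
#' @return Invisibly, named vector of written paths.
#' @export
pipeline_simulate <- function(out_dir, config = sim_config(), seed = NULL,
                              ct = FALSE, ct_config = ct_sim_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  tree <- simulate_host_tree(config$n_species, seed = config$seed)
  obs <- simulate_viral_load(tree, config)
  paths <- c(tree = file.path(out_dir, "host_tree.nwk"),
             obs = file.path(out_dir, "observations.tsv"))
  ape::write.tree(tree, paths[["tree"]])
  write_observation_tsv(obs, paths[["obs"]])
  if (ct) {
    ct_tab <- simulate_ct_experiment(obs, ct_config, seed = config$seed + 1L)
    paths <- c(paths, ct = file.path(out_dir, "ct_table.tsv"))
    write_ct_tsv(ct_tab, paths[["ct"]])
  }
  write_provenance(out_dir, "simulate", seed = config$seed,
                   config = config[setdiff(names(config), c("V_p", "V_s"))],
                   n_obs = nrow(obs))
  invisible(paths)
}

#' Pipeline stage: qPCR preprocessing
#'
#' Reads a raw Ct table, applies exclusion filters and plate correction,
#' computes log2 fold changes, and writes the observation table plus an
#' exclusion log.
#'
#' @param ct_path Path to a raw Ct TSV.
#' @param out_dir Output directory.
#' @param reference_peaks Named vector of reference melt peaks (`viral`,
#'   `housekeeping`); `NULL` skips melt filtering.
#' @return Invisibly, named vector of written paths.
#' @export
pipeline_qpcr <- function(ct_path, out_dir,
                          reference_peaks = c(viral = 82, housekeeping = 78)) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ct <- read_ct_tsv(ct_path)
  res <- qpcr_pipeline(ct, reference_peaks)
  paths <- c(obs = file.path(out_dir, "observations.tsv"),
             exclusions = file.path(out_dir, "exclusion_log.tsv"))
  write_observation_tsv(res$obs, paths[["obs"]])
  excl <- res$exclusions
  if (is.null(excl)) excl <- data.frame()
  if (nrow(res$dropped)) {
    for (i in seq_len(nrow(res$dropped))) {
      warning("dropped replicate ", res$dropped$species[i], "/",
              res$dropped$virus[i], "/", res$dropped$bio_rep[i], ": ",
              res$dropped$reason[i], call. = FALSE)
    }
  }
  utils::write.table(excl, paths[["exclusions"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_provenance(out_dir, "qpcr", seed = NA,
                   config = list(reference_peaks = as.list(reference_peaks)),
                   n_obs = nrow(res$obs), n_excluded = nrow(excl),
                   n_dropped = nrow(res$dropped))
  invisible(paths)
}

#' Pipeline stage: fit the phylogenetic mixed model
#'
#' @param obs_path Observation TSV.
#' @param tree_path Host tree (Newick/NEXUS).
#' @param out_dir Output directory.
#' @param species_effect Fit the full model (heritability) or the reduced
#'   model (repeatability/correlations).
#' @param mcmc A [vpmm_mcmc()].
#' @param prior A [vpmm_prior()].
#' @param seed Integer seed.
#' @param covariates Optional covariate columns.
#' @return The `vpmm` fit, invisibly; draws written as TSV with a
#'   provenance sidecar.
#' @export
pipeline_fit <- function(obs_path, tree_path, out_dir,
                         species_effect = TRUE, mcmc = vpmm_mcmc(),
                         prior = vpmm_prior(), seed = 1L, covariates = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  obs <- read_observation_tsv(obs_path)
  tree <- read_host_tree(tree_path)
  fit <- vpmm(obs, tree = tree, species_effect = species_effect,
              covariates = covariates, prior = prior, mcmc = mcmc,
              seed = seed)
  draws_path <- file.path(out_dir, sprintf(
    "draws_model%d.tsv", if (species_effect) 1L else 2L))
  utils::write.table(posterior_draws(fit), draws_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_provenance(out_dir, "fit", seed = seed,
                   config = list(species_effect = species_effect,
                                 n_iter = mcmc$n_iter, burn_in = mcmc$burn_in,
                                 thin = mcmc$thin,
                                 data_digest = digest_file(obs_path)),
                   n_obs = nrow(obs), ess = as.list(round(fit$ess, 1)))
  invisible(fit)
}

#' Pipeline stage: derived summaries
#'
#' @param fit_full `vpmm` fit with species effect (or `NULL`).
#' @param fit_reduced `vpmm` fit without species effect.
#' @param out_dir Output directory.
#' @return The [viral_load_report()], invisibly; JSON and TSV written.
#' @export
pipeline_summarize <- function(fit_full, fit_reduced, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rep <- viral_load_report(fit_full, fit_reduced)
  utils::write.table(rep$table, file.path(out_dir, "summary_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(rep$correlations[c("pair", "mean", "lower", "upper")],
                     file.path(out_dir, "correlations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  json <- list(
    fold_change = rep$fold_change[c("virus", "mean", "lower", "upper")],
    repeatability = rep$repeatability[c("virus", "mean", "lower", "upper")],
    heritability = if (!is.null(rep$heritability))
      rep$heritability[c("virus", "mean", "lower", "upper")],
    correlations = rep$correlations[c("pair", "mean", "lower", "upper")],
    correlation_differences = rep$correlation_differences)
  jsonlite::write_json(json, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  write_provenance(out_dir, "summarize", seed = NA, config = list())
  invisible(rep)
}

write_provenance <- function(out_dir, stage, seed, config, ...) {
  prov <- c(list(stage = stage, seed = seed,
                 package_version = as.character(utils::packageVersion("virophylo")),
                 r_version = as.character(getRversion()),
                 config = config), list(...))
  jsonlite::write_json(prov, file.path(out_dir, paste0(stage, "_provenance.json")),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(NULL)
}

digest_file <- function(path) {
  # cheap content fingerprint without external digest packages
  x <- readBin(path, "raw", n = file.info(path)$size)
  sprintf("size%d-sum%.0f", length(x), sum(as.integer(x)))
}
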