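#' Pipeline run configuration
#'
#' Bundles every setting of a full analysis run.  A seed is mandatory:
#' all randomness (imputation, MCMC) flows from it, split
#' deterministically per stage.
#'
#' @param concentrations path to the concentration CSV, or a
#'   [conc_matrix()]
#' @param clinical path to the clinical CSV, or a [clinical_table()]
#' @param out_dir output directory
#' @param fluid `"cyst"` or `"plasma"`: samples of the other fluid are
#'   dropped before analysis
#' @param merge list of `list(labels =, new_label =)` group-merge rules
#'   applied in order (e.g. HGD + Cancer -> "HGD/Cancer")
#' @param covariates model covariates (default age + BMI)
#' @param fc_pairs list of `c(g, h)` group pairs for fold-change tables;
#'   `NULL` = all pairs
#' @param n_draws,n_chains,warmup sampler settings
#' @param drop_fraction,power_grid,max_components classifier settings
#' @param markers marker columns for the Pearson screen (set to
#'   `character(0)` to skip)
#' @param seed integer root seed (mandatory)
#' @return a `run_config`
#' @export
run_config <- function(concentrations, clinical, out_dir,
                       fluid = "cyst", merge = list(),
                       covariates = c("age", "bmi"),
                       fc_pairs = NULL,
                       n_draws = 20000, n_chains = 4, warmup = 1000,
                       drop_fraction = 0.05,
                       power_grid = seq(0.05, 0.95, by = 0.05),
                       max_components = 8,
                       markers = c("ca19_9", "albumin", "bilirubin"),
                       seed = NULL) {
  if (is.null(seed)) stop("run_config requires a seed")
  if (!fluid %in% c("cyst", "plasma")) stop("fluid must be cyst or plasma")
  structure(list(concentrations = concentrations, clinical = clinical,
                 out_dir = out_dir, fluid = fluid, merge = merge,
                 covariates = covariates, fc_pairs = fc_pairs,
                 n_draws = n_draws, n_chains = n_chains, warmup = warmup,
                 drop_fraction = drop_fraction, power_grid = power_grid,
                 max_components = max_components, markers = markers,
                 seed = as.integer(seed)),
            class = "run_config")
}

# deterministic per-stage seed derived from the root seed
stage_seed <- function(seed, stage) {
  (as.double(seed) * 48271 + stage * 16807) %% (2^31 - 1)
}

# cheap stable fingerprint of the configuration for the manifest
config_hash <- function(config) {
  js <- jsonlite::toJSON(config[setdiff(names(config),
                                        c("concentrations", "clinical"))],
                         auto_unbox = TRUE, digits = 12, force = TRUE)
  u <- utf8ToInt(as.character(js))
  sprintf("%08x", sum(u * seq_along(u)) %% 4294967296)
}

#' Run the full analysis pipeline
#'
#' Executes the published stage order -- log transform, modified 80
#' percent filter, QRILC imputation, hierarchical model fit, fold
#' changes, confounder adjustment + standardization, PCA/clustering,
#' CPPLS-DA classification with VIP elimination, marker correlations --
#' and writes every stage output plus a JSON manifest to
#' `config$out_dir`.  Re-running with an identical config reproduces
#' identical outputs.
#'
#' @param config a [run_config()]
#' @return the manifest (invisibly): list of stage output paths, config
#'   hash and session info
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config_hash = config_hash(config),
                   seed = config$seed,
                   r_version = as.character(getRversion()),
                   stages = list())
  stage_log <- character(0)
  finish_stage <- function(name, path) {
    manifest$stages[[name]] <<- path
    stage_log <<- c(stage_log, sprintf("%s: %s", name, path))
    message("[ipmnomics] stage ", name, " -> ", path)
  }
  fail <- function(name, err) {
    manifest$failed_stage <- name
    manifest$error <- conditionMessage(err)
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         force = TRUE)
    stop("pipeline failed at stage '", name, "': ",
         conditionMessage(err), call. = FALSE)
  }

  raw <- if (inherits(config$concentrations, "conc_matrix"))
    config$concentrations else read_concentration_csv(config$concentrations)
  clinical <- if (inherits(config$clinical, "clinical_table"))
    config$clinical else read_clinical_csv(config$clinical)
  cl <- clinical[clinical$fluid == config$fluid, , drop = FALSE]
  if (!nrow(cl))
    stop("no samples with fluid '", config$fluid, "' in clinical table")
  class(cl) <- class(clinical)
  for (mg in config$merge)
    cl <- merge_groups(cl, mg$labels, mg$new_label)
  cl$group <- droplevels(cl$group)
  raw <- cm_subset(raw, cols = colnames(raw) %in% cl$sample_id)

  ## 1: preprocess (transform -> filter -> impute)
  pre <- tryCatch(preprocess(raw, cl, seed = stage_seed(config$seed, 1)),
                  error = function(e) fail("preprocess", e))
  p1 <- file.path(config$out_dir, "preprocessed.csv")
  utils::write.csv(data.frame(molecule = rownames(pre$values),
                              class = unname(pre$mol_class), pre$values,
                              check.names = FALSE), p1, row.names = FALSE)
  write_filter_report(pre$filter_report,
                      file.path(config$out_dir, "filter_report.tsv"))
  finish_stage("preprocess", p1)

  ## 2: hierarchical model
  fit <- tryCatch(suppressWarnings(fit_hier_model(
    pre, cl, model_spec(levels(cl$group), covariates = config$covariates),
    n_draws = config$n_draws, n_chains = config$n_chains,
    warmup = config$warmup, seed = stage_seed(config$seed, 2))),
    error = function(e) fail("fit", e))
  p2 <- file.path(config$out_dir, "posterior_summary.csv")
  utils::write.csv(posterior_summary(fit), p2, row.names = FALSE)
  finish_stage("fit", p2)

  ## 3: fold changes
  pairs <- config$fc_pairs
  if (is.null(pairs)) {
    g <- fit$groups
    pairs <- list()
    for (a in seq_along(g)) for (b in seq_along(g))
      if (a < b) pairs[[length(pairs) + 1]] <- c(g[b], g[a])
  }
  p3 <- file.path(config$out_dir, "fold_changes.tsv")
  fc_all <- do.call(rbind, lapply(pairs, function(pr) {
    fc <- fold_changes(fit, pr[1], pr[2])
    cbind(comparison = paste(pr[1], "vs", pr[2]), as.data.frame(fc))
  }))
  utils::write.table(fc_all, p3, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  finish_stage("foldchange", p3)

  ## 4: adjust + standardize
  adj <- tryCatch(adjust_matrix(pre, cl, fit),
                  error = function(e) fail("adjust", e))
  p4 <- file.path(config$out_dir, "adjusted.csv")
  utils::write.csv(data.frame(sample_id = rownames(adj), adj,
                              check.names = FALSE), p4, row.names = FALSE)
  finish_stage("adjust", p4)

  ## 5: PCA + clustering orders
  pca <- pca_project(adj, n_components = 2)
  ord <- ward_cluster_order(adj)
  p5 <- file.path(config$out_dir, "pca_scores.csv")
  utils::write.csv(data.frame(sample_id = rownames(adj),
                              group = as.character(cl$group[
                                match(rownames(adj), cl$sample_id)]),
                              pca$scores,
                              sample_leaf = order(ord$sample_order)[
                                seq_len(nrow(adj))],
                              check.names = FALSE),
                   p5, row.names = FALSE)
  finish_stage("pca", p5)

  ## 6: classification with VIP elimination
  elim <- tryCatch(recursive_elimination(
    adj, cl$group[match(rownames(adj), cl$sample_id)],
    drop_fraction = config$drop_fraction, power_grid = config$power_grid,
    max_components = config$max_components),
    error = function(e) fail("classify", e))
  p6 <- file.path(config$out_dir, "classification_report.tsv")
  write_classification_report(elim$final_report, p6, fluid = config$fluid)
  utils::write.table(cbind(elim$trace), file.path(config$out_dir,
                                                  "elimination_trace.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(elim$vip, file.path(config$out_dir, "vip_ranking.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  finish_stage("classify", p6)

  ## 7: marker correlations
  p7 <- file.path(config$out_dir, "correlations.tsv")
  if (length(config$markers)) {
    corr <- tryCatch(marker_correlations(adj, cl, markers = config$markers),
                     error = function(e) fail("correlate", e))
    utils::write.table(corr, p7, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    utils::write.table(data.frame(), p7, sep = "\t", row.names = FALSE)
  }
  finish_stage("correlate", p7)

  manifest$log <- stage_log
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(manifest)
}

#' Posterior summary table
#'
#' Medians and 95 percent credibility intervals for the grand mean, the
#' scales, and every group-by-molecule and covariate-by-molecule effect.
#'
#' @param draws a `posterior_draws`
#' @return a data.frame with columns parameter, median, lo95, hi95
#' @export
posterior_summary <- function(draws) {
  stopifnot(inherits(draws, "posterior_draws"))
  k <- length(draws$groups); m <- length(draws$molecules)
  V <- length(draws$covariates)
  mats <- cbind(theta = draws$theta, sigma = draws$sigma,
                alpha = draws$alpha, beta = draws$beta,
                draws$zeta,
                matrix(draws$eta, nrow = draws$n_draws),
                if (V > 0) matrix(draws$gamma[, seq_len(V), , drop = FALSE],
                                  nrow = draws$n_draws))
  nm <- c("theta", "sigma", "alpha", "beta",
          paste0("zeta[", draws$groups, "]"),
          paste0("eta[", rep(draws$groups, m), ",",
                 rep(draws$molecules, each = k), "]"),
          if (V > 0) paste0("gamma[", rep(draws$covariates, m), ",",
                            rep(draws$molecules, each = V), "]"))
  qs <- matrixStats::colQuantiles(mats, probs = c(0.025, 0.5, 0.975))
  data.frame(parameter = nm, median = qs[, 2], lo95 = qs[, 1],
             hi95 = qs[, 3], row.names = NULL)
}
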