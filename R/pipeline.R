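#' Build and validate a pipeline configuration
#'
#' Collects the stage parameters of the end-to-end run into one strict
#' list: unknown keys are rejected, all randomness flows from `seed`
#' through named per-stage substreams.
#'
#' @param seed master seed.
#' @param simulate list passed to [synthetic_config()] plus
#'   `validation = list(gene_keep_fraction, platform_shift_sd, n_samples)`
#'   and `control = list(n_samples)`.
#' @param preprocess list: `min_total_count`, `n_top`.
#' @param cluster list: `k_range`, `n_runs`, `theta`, `max_iter`, `tol`.
#' @param transfer list: `bootstrap_iterations`.
#' @param validate list: `scenarios`, `n_folds`, `baseline_draws`,
#'   `baseline_genes` (NULL = signature size).
#' @param phenotype list: `tests` (subset of `"chi2"`, `"ancova"`),
#'   `covariates`.
#' @return validated `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L,
                            simulate = list(),
                            preprocess = list(min_total_count = 10,
                                              n_top = 1000),
                            cluster = list(k_range = 2:5, n_runs = 20,
                                           theta = 0.5, max_iter = 500,
                                           tol = 1e-5),
                            transfer = list(bootstrap_iterations = 200),
                            validate = list(scenarios = "all_genes",
                                            n_folds = 10,
                                            baseline_draws = 0,
                                            baseline_genes = NULL),
                            phenotype = list(tests = c("chi2", "ancova"),
                                             covariates = "sex")) {
  check_keys <- function(x, allowed, where) {
    bad <- setdiff(names(x), allowed)
    if (length(bad)) stop("unknown ", where, " keys: ",
                          paste(bad, collapse = ", "))
  }
  check_keys(simulate, c(names(formals(synthetic_config)), "validation",
                         "control"), "simulate")
  check_keys(preprocess, c("min_total_count", "n_top"), "preprocess")
  check_keys(cluster, c("k_range", "n_runs", "theta", "max_iter", "tol"),
             "cluster")
  check_keys(transfer, "bootstrap_iterations", "transfer")
  check_keys(validate, c("scenarios", "n_folds", "baseline_draws",
                         "baseline_genes"), "validate")
  check_keys(phenotype, c("tests", "covariates"), "phenotype")
  if (seed != round(seed)) stop("seed must be an integer")
  structure(list(seed = as.integer(seed), simulate = simulate,
                 preprocess = preprocess, cluster = cluster,
                 transfer = transfer, validate = validate,
                 phenotype = phenotype),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys mirror the arguments of
#'   [pipeline_config()].
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

# Deterministic per-stage seeds derived from the master seed.
stage_seeds <- function(seed) {
  set.seed(seed)
  stats::setNames(sample.int(.Machine$integer.max - 1, 6),
                  c("simulate", "cluster", "transfer", "bootstrap",
                    "validate", "baseline"))
}

#' Run the end-to-end subtyping pipeline on synthetic data
#'
#' Sequences all stages: simulate a discovery cohort (plus a matched
#' validation cohort and signature-free controls), preprocess, consensus
#' cluster, extract signatures, transfer the labels to the validation
#' cohort with bootstrap stability, run the case/control signature
#' classifier, and test cluster-phenotype associations. Writes every
#' artifact under `out_dir` together with a manifest JSON recording
#' parameters, seeds and per-file hashes, so two runs with the same config
#' are byte-identical.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @return invisibly, a list with the stage results and the manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- stage_seeds(config$seed)
  stage <- "simulate"
  res <- tryCatch({
    sim_args <- config$simulate
    val_spec <- sim_args$validation %||%
      list(gene_keep_fraction = 0.6, platform_shift_sd = 0.1,
           n_samples = 100)
    ctl_spec <- sim_args$control %||% list(n_samples = 60)
    sim_args$validation <- sim_args$control <- NULL
    sim_args$seed <- seeds[["simulate"]]
    cfg <- do.call(synthetic_config, sim_args)
    discovery <- generate_discovery(cfg)
    validation <- generate_validation(
      discovery, gene_keep_fraction = val_spec$gene_keep_fraction,
      platform_shift_sd = val_spec$platform_shift_sd,
      n_samples = val_spec$n_samples, seed = seeds[["simulate"]] %% 100000 + 1)
    control <- generate_control(cfg, n_samples = ctl_spec$n_samples,
                                seed = seeds[["simulate"]] %% 100000 + 2)
    write_dataset(discovery, file.path(out_dir, "discovery"))
    write_dataset(validation, file.path(out_dir, "validation"))

    stage <- "preprocess"
    prep <- preprocess(discovery,
                       min_total_count = config$preprocess$min_total_count,
                       n_top = config$preprocess$n_top)
    write_expression(prep$matrix, file.path(out_dir, "vst.tsv"))

    stage <- "cluster"
    cc <- consensus_cluster(prep$matrix$values,
                            k_range = config$cluster$k_range,
                            n_runs = config$cluster$n_runs,
                            theta = config$cluster$theta,
                            max_iter = config$cluster$max_iter,
                            tol = config$cluster$tol,
                            seed = seeds[["cluster"]])
    fit <- nsnmf_factorize(prep$matrix$values, cc$chosen_k,
                           theta = config$cluster$theta,
                           max_iter = config$cluster$max_iter,
                           tol = config$cluster$tol,
                           seed = seeds[["cluster"]])
    model <- extract_informative_genes(fit)
    utils::write.table(
      data.frame(sample_id = names(model$sample_labels),
                 cluster = model$sample_labels),
      file.path(out_dir, "cluster_labels.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    sig_df <- do.call(rbind, lapply(names(model$informative_genes),
      function(cl) if (length(model$informative_genes[[cl]]))
        data.frame(gene_id = model$informative_genes[[cl]], cluster = cl)))
    utils::write.table(sig_df, file.path(out_dir, "informative_genes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(k_range = cc$k_range, chosen_k = cc$chosen_k,
                              cophenetic = cc$summary$cophenetic),
                         file.path(out_dir, "rank_scan.json"),
                         auto_unbox = TRUE, digits = NA)

    stage <- "transfer"
    val_prep <- preprocess(validation,
                           min_total_count = config$preprocess$min_total_count,
                           n_top = NULL)
    shared <- intersect_genes(model$informative_genes, val_prep$matrix)
    lda <- fit_lda(prep$matrix$values[
      intersect(shared, rownames(prep$matrix$values)), , drop = FALSE],
      model$sample_labels)
    assign_res <- assign_clusters(lda, val_prep$matrix$values)
    boot <- bootstrap_stability(lda, val_prep$matrix$values,
                                n_iterations = config$transfer$bootstrap_iterations,
                                seed = seeds[["bootstrap"]])
    utils::write.table(
      data.frame(sample_id = names(assign_res$labels),
                 label = assign_res$labels, assign_res$posteriors),
      file.path(out_dir, "assignments.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    jsonlite::write_json(
      list(n_iterations = boot$n_iterations,
           median_accuracy = boot$median_accuracy,
           accuracy_ci = boot$accuracy_ci,
           median_silhouette = boot$median_silhouette,
           silhouette_ci = boot$silhouette_ci),
      file.path(out_dir, "stability.json"), auto_unbox = TRUE, digits = NA)

    stage <- "validate"
    cv <- NULL
    if (length(config$validate$scenarios)) {
      sig1 <- model$informative_genes[[1]]
      ctl_prep <- vst_transform(control)
      common <- intersect(intersect(sig1, rownames(ctl_prep$values)),
                          rownames(prep$matrix$values))
      cases1 <- names(model$sample_labels)[model$sample_labels == 1]
      xcase <- t(prep$matrix$values[common, cases1, drop = FALSE])
      xctl <- t(ctl_prep$values[common, , drop = FALSE])
      xx <- rbind(xcase, xctl)
      yy <- factor(rep(c("case", "control"), c(nrow(xcase), nrow(xctl))),
                   levels = c("control", "case"))
      cv <- lapply(config$validate$scenarios, function(sc)
        run_scenario(xx, yy, scenario = sc,
                     n_folds = config$validate$n_folds,
                     seed = seeds[["validate"]]))
      names(cv) <- config$validate$scenarios
      metrics <- do.call(rbind, lapply(names(cv), function(sc)
        cbind(scenario = sc, cv[[sc]]$metrics)))
      utils::write.table(metrics, file.path(out_dir, "cv_metrics.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }

    stage <- "phenotype"
    pheno <- discovery$phenotype
    pheno$cluster_assigned <- model$sample_labels[pheno$sample_id]
    chi <- NULL
    anc <- NULL
    if ("chi2" %in% config$phenotype$tests) {
      totals <- as.numeric(table(factor(pheno$cluster_assigned)))
      pos <- as.numeric(tapply(pheno$sex == "M",
                               factor(pheno$cluster_assigned), sum))
      chi <- chi_square_independence(build_binary_table(pos, totals, "male"))
    }
    if ("ancova" %in% config$phenotype$tests) {
      gate <- normality_gate(pheno$age_at_onset)
      anc <- ancova_oneway(gate$values, pheno$cluster_assigned,
                           covariates = pheno[config$phenotype$covariates])
      anc$transform_applied <- gate$decision
    }
    jsonlite::write_json(
      list(chi_square = if (!is.null(chi))
             list(statistic = chi$statistic, df = chi$df,
                  p_value = chi$p_value),
           ancova = if (!is.null(anc))
             list(F = anc$F, p_value = anc$p_value,
                  transform = anc$transform_applied)),
      file.path(out_dir, "phenotype.json"), auto_unbox = TRUE, digits = NA)

    list(discovery = discovery, validation = validation, prep = prep,
         consensus = cc, model = model, lda = lda, assignment = assign_res,
         bootstrap = boot, cv = cv, chi_square = chi, ancova = anc)
  }, error = function(e)
    stop("pipeline failed in stage '", stage, "': ", conditionMessage(e),
         call. = FALSE))

  files <- sort(setdiff(list.files(out_dir, recursive = TRUE),
                        "manifest.json"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("nmfsubtypes")),
    seed = config$seed, stage_seeds = as.list(seeds),
    parameters = unclass(config)[c("simulate", "preprocess", "cluster",
                                   "transfer", "validate", "phenotype")],
    hashes = as.list(tools::md5sum(file.path(out_dir, files))))
  names(manifest$hashes) <- files
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res$manifest <- manifest
  invisible(res)
}
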