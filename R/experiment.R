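# Experiment configuration, IO and the end-to-end pipeline
#
# A single YAML-configurable entry point runs the full study design on a
# cohort: two-factor confound balancing, the scrambled-CNN ensemble with
# vote aggregation and the logistic-growth projection, per-subject
# guided Grad-CAM maps with network effect sizes, and the half-edge
# occlusion grid. Every stage derives its seed from the master seed, so
# a config re-run reproduces all deterministic outputs bit-identically.

#' Write / read a phenotype table
#'
#' CSV with header `subject_id,sex,condition,age,icv,mfd,dvars,spike_pct`.
#'
#' @param phenotypes data.frame as from [generate_phenotypes()].
#' @param path file path.
#' @return `read_phenotypes` returns the data.frame.
#' @export
write_phenotypes <- function(phenotypes, path) {
  utils::write.csv(phenotypes, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "sex", "condition")
  if (!all(need %in% names(d)))
    stop2("phenotype file lacks column(s): ",
          paste(setdiff(need, names(d)), collapse = ", "))
  d
}

#' Write / read a cohort connectome container
#'
#' One file per cohort keyed by subject id (an RDS container holding the
#' `wavelet_cohort` edge array).
#'
#' @param cohort a `wavelet_cohort`.
#' @param path file path (conventionally `.rds`).
#' @return `read_cohort` returns the `wavelet_cohort`.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "wavelet_cohort"))
  saveRDS(cohort, path)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  x <- readRDS(path)
  if (!inherits(x, "wavelet_cohort")) stop2("not a wavelet_cohort container")
  x
}

#' Experiment configuration
#'
#' @param n_subjects synthetic cohort size (ignored when `cohort_path`
#'   is given).
#' @param cohort_path optional existing cohort container + phenotype CSV
#'   prefix (reads `<prefix>.rds` and `<prefix>.csv`).
#' @param effect_network name of the bundled network carrying the
#'   planted effect (`NULL` for a null cohort).
#' @param effect_condition,effect_size,effect_bands planted-effect knobs
#'   (see [effect_entry()]).
#' @param k ensemble members.
#' @param occlusion_k members per occlusion arm (0 skips occlusion).
#' @param networks_path optional networks YAML override.
#' @param modes occlusion edge modes.
#' @param member,balance option lists overriding [member_config()] /
#'   [balance_config()] defaults.
#' @param out_dir output directory.
#' @param seed master seed.
#' @return object of class `experiment_config`.
#' @export
experiment_config <- function(n_subjects = 400L, cohort_path = NULL,
                              effect_network = "SAL",
                              effect_condition = "rest", effect_size = 1.5,
                              effect_bands = 1:3,
                              k = 10L, occlusion_k = 0L,
                              networks_path = NULL,
                              modes = "inner",
                              member = list(), balance = list(),
                              out_dir = "results", seed = 1L) {
  structure(list(n_subjects = n_subjects, cohort_path = cohort_path,
                 effect_network = effect_network,
                 effect_condition = effect_condition,
                 effect_size = effect_size, effect_bands = effect_bands,
                 k = k, occlusion_k = occlusion_k,
                 networks_path = networks_path, modes = modes,
                 member = member, balance = balance,
                 out_dir = out_dir, seed = seed),
            class = "experiment_config")
}

#' Read an experiment configuration from YAML
#'
#' @param path YAML file whose keys mirror the [experiment_config()]
#'   arguments.
#' @return an `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  if (!file.exists(path)) stop2("config file not found: ", path)
  do.call(experiment_config, yaml::read_yaml(path))
}

#' Validate an experiment configuration
#'
#' @param config an `experiment_config`.
#' @return character vector of issues; empty iff runnable.
#' @export
validate_config <- function(config) {
  issues <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) issues <<- c(issues, msg)
  chk(inherits(config, "experiment_config"), "not an experiment_config")
  chk(is_count(config$k) && config$k >= 1, "k must be a positive integer")
  chk(is_count(config$occlusion_k), "occlusion_k must be a non-negative integer")
  if (is.null(config$cohort_path))
    chk(is_count(config$n_subjects) && config$n_subjects >= 60,
        "n_subjects must be an integer >= 60")
  else {
    chk(file.exists(paste0(config$cohort_path, ".rds")),
        paste0("cohort container not found: ", config$cohort_path, ".rds"))
    chk(file.exists(paste0(config$cohort_path, ".csv")),
        paste0("phenotype table not found: ", config$cohort_path, ".csv"))
  }
  if (!is.null(config$networks_path))
    chk(file.exists(config$networks_path),
        paste0("networks file not found: ", config$networks_path))
  if (!is.null(config$effect_network)) {
    nets <- tryCatch(load_networks(config$networks_path), error = function(e) NULL)
    chk(!is.null(nets) && config$effect_network %in% names(nets),
        paste0("unknown effect_network: ", config$effect_network))
    chk(is.finite(config$effect_size), "effect_size must be finite")
    chk(config$effect_condition %in% c("rest", "task", "both"),
        "effect_condition must be rest/task/both")
  }
  p_thr <- config$balance$p_threshold %||% 0.10
  chk(p_thr > 0 && p_thr < 1, "p_threshold must lie in (0,1)")
  issues
}

#' Run the full experiment
#'
#' Stages in order: cohort (synthesize or load), two-factor balancing,
#' ensemble training + votes + growth-curve fit, subject CAMs + network
#' effect sizes, and (if `occlusion_k > 0`) the occlusion grid. Outputs
#' are written under `out_dir` as JSON/CSV; the function halts on the
#' first failing stage, leaving earlier outputs in place.
#'
#' @param config an [experiment_config()].
#' @param progress print per-stage progress.
#' @return invisibly, a list with all stage results.
#' @export
run_full_experiment <- function(config, progress = TRUE) {
  issues <- validate_config(config)
  if (length(issues)) stop2("invalid config: ", paste(issues, collapse = "; "))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (progress) message(sprintf(...))
  nets <- load_networks(config$networks_path)
  t_all <- Sys.time()

  # stage: cohort
  t0 <- Sys.time()
  if (is.null(config$cohort_path)) {
    plan <- list()
    if (!is.null(config$effect_network))
      plan <- list(effect_entry(nets[[config$effect_network]]$nodes,
                                config$effect_condition, config$effect_size,
                                config$effect_bands))
    spec <- cohort_spec(config$n_subjects, effect_plan = plan,
                        seed = substream_seed(config$seed, "cohort"))
    phenotypes <- generate_phenotypes(spec)
    cohort <- generate_connectomes(phenotypes, spec)
  } else {
    cohort <- read_cohort(paste0(config$cohort_path, ".rds"))
    phenotypes <- read_phenotypes(paste0(config$cohort_path, ".csv"))
    if (!identical(phenotypes$subject_id, cohort$subject_id))
      stop2("stage cohort: phenotype/container subject ids disagree")
  }
  write_phenotypes(phenotypes, file.path(config$out_dir, "phenotypes.csv"))
  say("stage cohort: %d subjects [%.1fs]", nrow(phenotypes),
      as.numeric(Sys.time() - t0, units = "secs"))

  # stage: balance
  t0 <- Sys.time()
  bal_cfg <- do.call(balance_config,
                     utils::modifyList(list(seed = substream_seed(config$seed,
                                                                  "balance")),
                                       config$balance))
  bal <- balance_two_factor(phenotypes, bal_cfg)
  if (bal$sex_certificate$status != "success")
    stop2("stage balance: sex balancing failed")
  cert <- list(sex = unclass(bal$sex_certificate),
               condition = unclass(bal$condition_certificate))
  jsonlite::write_json(cert, file.path(config$out_dir, "balance.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  say("stage balance: retained %d [%.1fs]", length(bal$retained),
      as.numeric(Sys.time() - t0, units = "secs"))

  # stage: ensemble
  t0 <- Sys.time()
  mem_cfg <- do.call(member_config, config$member)
  ens <- run_ensemble(cohort$edges, phenotypes, config$k, mem_cfg,
                      balance_cfg = bal_cfg,
                      seed = substream_seed(config$seed, "ensemble"),
                      progress = progress)
  utils::write.csv(data.frame(subject_id = phenotypes$subject_id[ens$votes$subject],
                              n_models = ens$votes$n_models,
                              mean_probability = ens$votes$vote,
                              label = ens$votes$label),
                   file.path(config$out_dir, "votes.csv"), row.names = FALSE)
  utils::write.csv(ens$curve, file.path(config$out_dir, "curve.csv"),
                   row.names = FALSE)
  fit <- if (config$k >= 4) fit_growth_curve(ens$curve$size, ens$curve$auroc)
         else NULL
  jsonlite::write_json(list(
    member_auroc_mean = mean(ens$member_aurocs),
    member_auroc_sd = stats::sd(ens$member_aurocs),
    ensemble_auroc = ens$ensemble_auroc, rest_auroc = ens$rest_auroc,
    task_auroc = ens$task_auroc, coverage = ens$coverage,
    growth_fit = if (is.null(fit)) NULL else unclass(fit)),
    file.path(config$out_dir, "ensemble.json"), auto_unbox = TRUE,
    digits = NA, force = TRUE)
  say("stage ensemble: AUROC %.4f (members %.4f +/- %.4f) [%.1fs]",
      ens$ensemble_auroc, mean(ens$member_aurocs), stats::sd(ens$member_aurocs),
      as.numeric(Sys.time() - t0, units = "secs"))

  # stage: saliency
  t0 <- Sys.time()
  cams <- aggregate_cams(ens$members, cohort$edges)
  eff <- network_effect_sizes(cams, nets, phenotypes$condition)
  utils::write.csv(eff, file.path(config$out_dir, "cam_effect_sizes.csv"),
                   row.names = FALSE)
  say("stage saliency: %d subject CAMs [%.1fs]", nrow(cams$cam),
      as.numeric(Sys.time() - t0, units = "secs"))

  # stage: occlusion
  occ <- NULL
  if (config$occlusion_k > 0L) {
    t0 <- Sys.time()
    occ <- run_occlusion(cohort$edges, phenotypes, nets,
                         modes = config$modes, k = config$occlusion_k,
                         member_cfg = mem_cfg, balance_cfg = bal_cfg,
                         seed = substream_seed(config$seed, "occlusion"),
                         progress = progress)
    utils::write.csv(occ$table, file.path(config$out_dir, "occlusion.csv"),
                     row.names = FALSE)
    say("stage occlusion: %d cells [%.1fs]",
        nrow(occ$table), as.numeric(Sys.time() - t0, units = "secs"))
  }
  say("experiment complete [%.1fs total]",
      as.numeric(Sys.time() - t_all, units = "secs"))
  invisible(list(phenotypes = phenotypes, cohort = cohort, balance = bal,
                 ensemble = ens, growth_fit = fit, cams = cams,
                 effect_sizes = eff, occlusion = occ))
}
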