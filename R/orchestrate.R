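# End-to-end orchestration: one manifest (seed, cohort configuration,
# stage list, problem sizes) drives simulate -> emulate pipelines ->
# age-predict -> lifespan-radar -> icc -> variance-ratio ->
# longitudinal-eval, writing every stage's table as plain CSV plus a JSON
# manifest with content checksums. Per-stage seeds are derived from the
# master seed by stable hashing, so adding or dropping a stage never
# perturbs another stage's randomness.

ALL_STAGES <- c("simulate", "age_predict", "lifespan_radar", "icc",
                "variance_ratio", "longitudinal_eval")

#' Build a run manifest
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed; every stage derives its own seed from it.
#' @param config A [cohort_config()] for the generators.
#' @param stages Subset of the available stages, in execution order.
#' @param n_cross Cross-sectional cohort size.
#' @param n_rescan Scan-rescan cohort size.
#' @param n_permutations Age-prediction resplits.
#' @param n_trees Random-forest size.
#' @param mcmc An [mcmc_config()] for the variance-ratio stage.
#' @param vr_regions Region codes fitted in the variance-ratio stage
#'   (default: all 62; a subset keeps demo runs short).
#' @return List of class `run_manifest`.
#' @export
run_manifest <- function(out_dir, seed = 1L, config = cohort_config(),
                         stages = ALL_STAGES, n_cross = 400, n_rescan = 100,
                         n_permutations = 50, n_trees = 200,
                         mcmc = mcmc_config(n_chains = 2,
                                            n_iterations = 1200,
                                            n_warmup = 400),
                         vr_regions = dkt_region_codes()) {
  unknown <- setdiff(stages, ALL_STAGES)
  if (length(unknown))
    stop_config("unknown stage name(s): %s", paste(unknown, collapse = ", "))
  structure(list(out_dir = out_dir, seed = as.integer(seed), config = config,
                 stages = stages, n_cross = n_cross, n_rescan = n_rescan,
                 n_permutations = n_permutations, n_trees = n_trees,
                 mcmc = mcmc, vr_regions = vr_regions,
                 version = as.character(utils::packageVersion("cortexeval")),
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
            class = "run_manifest")
}

#' Execute every stage of a run manifest
#'
#' Stage failures halt with the stage name; partial outputs are preserved.
#' Reruns with the same manifest produce byte-identical CSV outputs.
#'
#' @param manifest A [run_manifest()].
#' @param verbose Log one line per stage.
#' @return Invisibly, the manifest augmented with `outputs` (file ->
#'   md5 checksum); also written as `manifest.json` in the output directory.
#' @export
run_full_evaluation <- function(manifest, verbose = TRUE) {
  stopifnot(inherits(manifest, "run_manifest"))
  dir.create(manifest$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))
  cfg <- manifest$config
  cfg$seed <- derive_seed(manifest$seed, "simulate")
  outputs <- character()
  emit <- function(obj, name) {
    path <- file.path(manifest$out_dir, name)
    if (is.data.frame(obj)) write_thickness_table(obj, path)
    outputs <<- c(outputs, path)
    path
  }
  run_stage <- function(name, fun) {
    if (!name %in% manifest$stages) return(invisible(NULL))
    say("stage %s ...", name)
    tryCatch(fun(), error = function(e)
      stop_config("stage '%s' failed: %s", name, conditionMessage(e)))
  }

  env <- new.env()
  run_stage("simulate", function() {
    cs <- generate_cross_sectional(cfg, manifest$n_cross)
    env$cross <- emulate_pipeline_pair(cs$table, cfg)
    lg <- generate_longitudinal(cfg)
    env$long <- emulate_pipeline_pair(lg$table, cfg)
    env$rescan <- generate_scan_rescan(cfg, manifest$n_rescan)
    emit(env$cross$A, "cross_sectional_A.csv")
    emit(env$cross$B, "cross_sectional_B.csv")
    emit(env$long$A, "longitudinal_A.csv")
    emit(env$long$B, "longitudinal_B.csv")
    emit(env$rescan, "scan_rescan.csv")
  })
  run_stage("age_predict", function() {
    ap_cfg <- age_prediction_config(
      n_permutations = manifest$n_permutations,
      n_trees = manifest$n_trees,
      seed = derive_seed(manifest$seed, "age_predict"))
    res <- lapply(env$cross, function(tab)
      run_age_prediction(tab, ap_cfg))
    env$age <- res
    df <- data.frame(
      pipeline = rep(names(res), each = manifest$n_permutations),
      permutation = rep(seq_len(manifest$n_permutations), length(res)),
      rmse = unlist(lapply(res, function(r) r$rmse_per_permutation)),
      stringsAsFactors = FALSE)
    emit(df, "age_prediction_rmse.csv")
  })
  run_stage("lifespan_radar", function() {
    models <- lapply(env$cross, fit_lifespan_models)
    radar <- predict_relative_thickness(models,
                                        age_range = cfg$age_range)
    env$radar <- radar
    emit(radar, "lifespan_radar.csv")
  })
  run_stage("icc", function() {
    pair <- emulate_pipeline_pair(env$rescan, cfg)
    icc <- do.call(rbind, lapply(names(pair), function(pl) {
      d <- compute_icc(pair[[pl]])
      cbind(pipeline = pl, d)
    }))
    emit(icc, "icc.csv")
  })
  run_stage("variance_ratio", function() {
    mc <- manifest$mcmc
    mc$seed <- derive_seed(manifest$seed, "variance_ratio")
    fits <- lapply(env$long, function(tab)
      fit_all_regions(tab, mcmc = mc, regions = manifest$vr_regions))
    summ <- summarize_pipelines(fits)
    emit(summ$per_region, "variance_ratio_per_region.csv")
    emit(summ$across_regions, "variance_ratio_summary.csv")
  })
  run_stage("longitudinal_eval", function() {
    for (pl in names(env$long)) {
      res <- run_longitudinal_evaluation(env$long[[pl]])
      emit(res, sprintf("longitudinal_contrasts_%s.csv", pl))
    }
  })

  sums <- tools::md5sum(outputs)
  manifest$outputs <- as.list(sums)
  meta <- manifest
  meta$config <- unclass(meta$config)
  meta$mcmc <- unclass(meta$mcmc)
  jsonlite::write_json(unclass(meta),
                       file.path(manifest$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("wrote %d output files to %s", length(outputs), manifest$out_dir)
  invisible(manifest)
}
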