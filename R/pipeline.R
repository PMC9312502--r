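#' Default pipeline configuration
#'
#' Flat key-value configuration for [run_pipeline()]. Keys mirror
#' [sim_config()] plus: `sediment.advective_min_grain_um` (classifier
#' threshold), `rf.ntree`, `rf.mtry_min`/`rf.mtry_max`,
#' `rf_bpc.ntree`/`rf_bpc.mtry` (reference BPc map protocol),
#' `overlay.hot_quantile`, `overlay.delta_quantile`.
#'
#' @param seed integer master seed.
#' @return named list of defaults.
#' @export
pipeline_defaults <- function(seed = 1L) {
  c(unclass(sim_config(seed = seed)),
    list(sediment.advective_min_grain_um = 177,
         rf.ntree = 1000L, rf.mtry_min = 1L, rf.mtry_max = 5L,
         rf_bpc.ntree = 500L, rf_bpc.mtry = 3L,
         overlay.hot_quantile = 0.75, overlay.delta_quantile = 0.10))
}

#' Read and validate a pipeline configuration file
#'
#' YAML file of scalar keys; unknown keys are an error (no silent typos),
#' missing keys take their defaults.
#'
#' @param path YAML config file.
#' @param seed seed used for keys not set in the file.
#' @return validated configuration list.
#' @export
read_pipeline_config <- function(path, seed = 1L) {
  user <- yaml::read_yaml(path)
  defaults <- pipeline_defaults(seed = seed)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  defaults[names(user)] <- user
  validate_pipeline_config(defaults)
}

validate_pipeline_config <- function(cfg) {
  sim_keys <- names(formals(sim_config))
  do.call(sim_config, cfg[intersect(names(cfg), sim_keys)])  # re-validate
  stopifnot(cfg$sediment.advective_min_grain_um > 0,
            cfg$rf.ntree >= 1L, cfg$rf.mtry_min >= 1L,
            cfg$rf.mtry_max >= cfg$rf.mtry_min,
            cfg$overlay.hot_quantile > 0, cfg$overlay.hot_quantile <= 1,
            cfg$overlay.delta_quantile >= 0,
            cfg$overlay.delta_quantile < 1)
  cfg
}

#' Run the full synthetic-data analysis pipeline
#'
#' Executes simulate -> index -> temporal -> map -> overlay -> validate on
#' generated inputs, writing every stage product as a text file under
#' `out_dir` and returning a run manifest (config snapshot, seed, per-stage
#' timings, MD5 digest of every output). Reruns with an identical seed and
#' configuration reproduce identical digests. A stage failure aborts with a
#' stage-named error; products of completed stages are left on disk.
#'
#' @param config configuration list from [pipeline_defaults()] or
#'   [read_pipeline_config()]; a path to a YAML file is also accepted.
#' @param out_dir output directory (created if needed).
#' @param seed master seed (overrides the config's seed when given).
#' @param quiet suppress stage progress messages.
#' @return A `bip_manifest` (invisibly): `config`, `seed`, `stages`
#'   (timings), `files` (name -> md5), plus in-memory stage results in
#'   `results`.
#' @export
run_pipeline <- function(config = pipeline_defaults(), out_dir,
                         seed = NULL, quiet = FALSE) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_pipeline_config(config,
                                   seed = if (is.null(seed)) 1L else seed)
  }
  config <- validate_pipeline_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  say <- function(...) if (!quiet) message("[benthirr] ", ...)
  stage_times <- numeric(0)
  run_stage <- function(name, fun) {
    say("stage: ", name)
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    stage_times[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }
  sim_keys <- names(formals(sim_config))
  cfg <- do.call(sim_config, config[intersect(names(config), sim_keys)])
  results <- list()

  # -- simulate ------------------------------------------------------------
  results$sim <- run_stage("simulate", function() {
    scores <- gen_scores(cfg)
    comm <- gen_communities(cfg, scores)
    land <- gen_landscape(cfg)
    write_score_table(scores, file.path(out_dir, "scores.csv"))
    write_community_csv(comm$samples, file.path(out_dir, "community.csv"))
    utils::write.csv(comm$stations, file.path(out_dir, "stations.csv"),
                     row.names = FALSE, quote = FALSE)
    write_stack(land$stack, file.path(out_dir, "rasters"))
    list(scores = scores, comm = comm, land = land)
  })
  scores <- results$sim$scores
  comm <- results$sim$comm
  land <- results$sim$land

  # -- index ---------------------------------------------------------------
  results$index <- run_stage("index", function() {
    rule <- system_rule(config$sediment.advective_min_grain_um)
    res <- lapply(comm$samples, function(s)
      bipc(s, scores, classify_system(s, rule)))
    write_index_table(res, file.path(out_dir, "index.csv"))
    res
  })
  idx_df <- read_index_table(file.path(out_dir, "index.csv"))

  # -- temporal ------------------------------------------------------------
  results$temporal <- run_stage("temporal", function() {
    cmp <- tukey_letters(idx_df$bipc, idx_df$station)
    ctr <- system_contrast(idx_df$bipc, idx_df$system)
    letters_df <- data.frame(station = names(cmp$letters),
                             mean_log10 = as.numeric(cmp$means[names(cmp$letters)]),
                             letters = unname(cmp$letters))
    utils::write.csv(letters_df, file.path(out_dir, "temporal_letters.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(data.frame(ratio = ctr$ratio,
                                mean_advective = ctr$mean_advective,
                                mean_diffusive = ctr$mean_diffusive,
                                tukey_p = ctr$tukey_p),
                     file.path(out_dir, "system_contrast.csv"),
                     row.names = FALSE, quote = FALSE)
    list(letters = cmp, contrast = ctr)
  })

  # -- map -----------------------------------------------------------------
  results$map <- run_stage("map", function() {
    pred <- extract_stations(land$stack, land$stations$x, land$stations$y)
    fit <- fit_bip_map(land$stations$bipc, pred,
                       ntree = config$rf.ntree,
                       mtry_range = config$rf.mtry_min:config$rf.mtry_max,
                       seed = cfg$seed)
    surf <- predict_bip_raster(fit, land$stack)
    write_ascii_grid(surf$log_raster, file.path(out_dir, "bipc_map.asc"))
    write_fit_report(fit, file.path(out_dir, "fit_report.yaml"))
    list(fit = fit, surface = surf)
  })

  # -- overlay (reference BPc surface vs BIPc surface) ---------------------
  results$overlay <- run_stage("overlay", function() {
    # reference surface: BPc mapping protocol (500 trees, 3 vars/node) on
    # the landscape's companion bioturbation response
    pred <- extract_stations(land$stack, land$stations$x, land$stations$y)
    fit_ref <- fit_bip_map(land$stations$bpc, pred,
                           ntree = config$rf_bpc.ntree,
                           mtry_range = config$rf_bpc.mtry,
                           seed = cfg$seed + 1L)
    ref_surf <- predict_bip_raster(fit_ref, land$stack)
    ov <- overlay_hotspots(results$map$surface$log_raster,
                           ref_surf$log_raster,
                           hot_quantile = config$overlay.hot_quantile,
                           delta_quantile = config$overlay.delta_quantile)
    write_overlay(ov, file.path(out_dir, "overlay.asc"))
    ov
  })

  # -- validate ------------------------------------------------------------
  results$validate <- run_stage("validate", function() {
    n_cores <- min(cfg$n_cores, nrow(comm$truth))
    core_truth <- comm$truth$true_bipc[seq_len(n_cores)]
    meas <- gen_measurements(cfg, core_truth,
                             core_ids = comm$truth$station[seq_len(n_cores)])
    utils::write.csv(meas, file.path(out_dir, "measurements.csv"),
                     row.names = FALSE, quote = FALSE)
    engine_bipc <- idx_df$bipc[seq_len(n_cores)]
    cm <- corr_matrix(data.frame(bipc = engine_bipc,
                                 irrigation = meas$value))
    write_corr_matrix(cm, file.path(out_dir, "validation_matrix.csv"))
    cm
  })

  files <- sort(setdiff(list.files(out_dir, recursive = TRUE),
                        "manifest.yaml"))
  digests <- tools::md5sum(file.path(out_dir, files))
  names(digests) <- files
  manifest <- structure(list(config = config, seed = cfg$seed,
                             stages = stage_times,
                             files = as.list(digests),
                             results = results),
                        class = "bip_manifest")
  yaml::write_yaml(list(seed = cfg$seed,
                        stages = as.list(stage_times),
                        files = as.list(digests)),
                   file.path(out_dir, "manifest.yaml"))
  say("done: ", length(files), " output file(s) in ", out_dir)
  invisible(manifest)
}

#' @export
print.bip_manifest <- function(x, ...) {
  cat("Pipeline run manifest (seed", x$seed, ")\n")
  cat("  stages:", paste(sprintf("%s %.2fs", names(x$stages),
                                 unlist(x$stages)), collapse = ", "), "\n")
  cat("  outputs:", length(x$files), "file(s)\n")
  invisible(x)
}

# long-format community CSV used by the pipeline and the readers
write_community_csv <- function(samples, path) {
  rows <- lapply(samples, function(s) {
    r <- s$records
    if (nrow(r) == 0L) {
      return(data.frame(station = s$station_id, date = s$date,
                        taxon = "", abundance_ind_m2 = NA_real_,
                        biomass_afdw_g_m2 = NA_real_, depth_cm = NA_real_,
                        median_grain_um = s$median_grain_um,
                        stringsAsFactors = FALSE))
    }
    data.frame(station = s$station_id, date = s$date, taxon = r$taxon,
               abundance_ind_m2 = r$abundance,
               biomass_afdw_g_m2 = r$biomass_afdw,
               depth_cm = r$depth_measured,
               median_grain_um = s$median_grain_um,
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

write_fit_report <- function(fit, path) {
  yaml::write_yaml(list(
    ntree = fit$ntree,
    mtry = fit$mtry,
    mtry_tested = as.list(fit$mtry_tested),
    var_explained_pct = fit$var_explained_pct,
    kendall_tau = fit$kendall_tau,
    kendall_p = fit$kendall_p,
    retained = fit$retained,
    dropped = if (nrow(fit$dropped) > 0L) fit$dropped$dropped else list(),
    importance_pct_inc_mse = as.list(round(fit$importance, 6)),
    seed = fit$seed), path)
  invisible(path)
}
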