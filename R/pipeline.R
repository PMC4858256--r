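#' Pipeline run configuration
#'
#' Collects every tunable of the simulate-to-statistics pipeline with the
#' documented defaults: percentile (99.5th) dynamic-range scaling,
#' Frangi scales 1-4 px with beta 0.5 and image-adaptive c,
#' Otsu-seeded hysteresis vessel binarization within the disc,
#' signal-strength QC cutoff 6, pooled t-tests.
#' Configurations round-trip losslessly through
#' [write_run_config()] / [read_run_config()] (JSON).
#'
#' @param scene Named list of arguments for [scene_spec()].
#' @param cohort Named list of arguments for [cohort_spec()].
#' @param scale_mode,scale_probs Dynamic-range mapping (see
#'   [scale_to_dynamic_range()]).
#' @param scales,beta,frangi_c Vesselness parameters (see [vesselness()]).
#' @param binarize_method,binarize_threshold Vessel binarization (see
#'   [binarize_vessels()]).
#' @param qc_cutoff Minimum acceptable signal strength.
#' @param ttest_mode `"pooled"` or `"welch"`.
#' @param seed Master seed; the cohort stage derives `seed + 1`.
#' @return An object of class `onh_run_config`.
#' @export
run_config <- function(scene = list(), cohort = list(),
                       scale_mode = "percentile", scale_probs = 0.995,
                       scales = c(1, 2, 3, 4), beta = 0.5, frangi_c = NULL,
                       binarize_method = "hysteresis", binarize_threshold = 0.5,
                       qc_cutoff = 6, ttest_mode = "pooled", seed = 1L) {
  stopifnot(scale_mode %in% c("percentile", "max"),
            binarize_method %in% c("hysteresis", "otsu", "fixed"),
            ttest_mode %in% c("pooled", "welch"))
  structure(list(
    scene = scene, cohort = cohort,
    scale_mode = scale_mode, scale_probs = scale_probs,
    scales = scales, beta = beta, frangi_c = frangi_c,
    binarize_method = binarize_method,
    binarize_threshold = binarize_threshold,
    qc_cutoff = qc_cutoff, ttest_mode = ttest_mode,
    seed = as.integer(seed)
  ), class = "onh_run_config")
}

#' @rdname run_config
#' @param config An `onh_run_config`.
#' @param path JSON file path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "onh_run_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$scales <- as.numeric(obj$scales)
  do.call(run_config, obj)
}

#' Run the full simulate-to-statistics pipeline
#'
#' Chains the seven stages — simulate, flow, segment, enface, vessels,
#' metrics, stats — writing each stage's artifacts under `out_dir` and a
#' `manifest.json` recording package version, configuration, seeds,
#' per-stage status and timings. Stages are fail-fast: artifacts are
#' staged in a scratch subdirectory and committed only on success, so a
#' failed run quarantines its partial outputs under `.staging/` and never
#' overwrites previously committed results; stages after a failure are
#' not attempted.
#'
#' @param config An `onh_run_config`.
#' @param out_dir Output directory.
#' @param volume_dir Optional directory holding a pre-existing volume
#'   (written by [write_volume()]) used instead of simulating one.
#' @return Invisibly, a list with the per-eye `metrics` tibble, the
#'   statistics `tables`, the `manifest`, and `out_dir`.
#' @export
run_pipeline <- function(config = run_config(), out_dir,
                         volume_dir = NULL) {
  stopifnot(inherits(config, "onh_run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  staging_root <- file.path(out_dir, ".staging")
  stage_names <- c("simulate", "flow", "segment", "enface", "vessels",
                   "metrics", "stats")
  manifest <- list(
    package = "onhperf",
    version = as.character(utils::packageVersion("onhperf")),
    seed = config$seed,
    config = unclass(config),
    stages = lapply(stage_names, function(s) {
      list(name = s, status = "not_attempted", seconds = NA, outputs = list())
    })
  )
  names(manifest$stages) <- stage_names
  env <- new.env(parent = emptyenv())

  commit <- function(stage) {
    src <- file.path(staging_root, stage)
    dst <- file.path(out_dir, stage)
    if (dir.exists(src)) {
      unlink(dst, recursive = TRUE)
      file.rename(src, dst)
    }
    dst
  }
  write_manifest <- function() {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }

  run_stage <- function(stage, fun) {
    sdir <- file.path(staging_root, stage)
    dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
    t0 <- proc.time()[["elapsed"]]
    ok <- tryCatch({
      fun(sdir)
      TRUE
    }, error = function(e) {
      manifest$stages[[stage]]$status <<- "failed"
      manifest$stages[[stage]]$error <<- conditionMessage(e)
      manifest$stages[[stage]]$seconds <<-
        round(proc.time()[["elapsed"]] - t0, 3)
      FALSE
    })
    if (!ok) {
      write_manifest()
      abort(c(sprintf("pipeline stage '%s' failed; later stages not attempted",
                      stage),
              "i" = manifest$stages[[stage]]$error,
              "i" = sprintf("partial outputs quarantined under %s",
                            file.path(staging_root, stage))))
    }
    dst <- commit(stage)
    manifest$stages[[stage]]$status <<- "ok"
    manifest$stages[[stage]]$seconds <<- round(proc.time()[["elapsed"]] - t0, 3)
    manifest$stages[[stage]]$outputs <<- as.list(list.files(dst))
    invisible(NULL)
  }

  run_stage("simulate", function(sdir) {
    if (is.null(volume_dir)) {
      sargs <- config$scene
      if (is.null(sargs$seed)) sargs$seed <- config$seed
      spec <- do.call(scene_spec, sargs)
      sim <- generate_volume(spec)
      env$volume <- sim$volume
      env$truth <- sim$truth
      write_volume(sim$volume, file.path(sdir, "volume"))
      env$extent_mm <- spec$extent_mm
    } else {
      env$extent_mm <- NULL  # read with the volume in the flow stage
    }
    cargs <- config$cohort
    if (is.null(cargs$seed)) cargs$seed <- config$seed + 1L
    env$cohort <- generate_cohort(do.call(cohort_spec, cargs))
    readr::write_csv(env$cohort, file.path(sdir, "cohort.csv"))
  })

  run_stage("flow", function(sdir) {
    if (!is.null(volume_dir)) {
      env$volume <- read_volume(volume_dir)
      env$extent_mm <- env$volume$extent_mm
    }
    flow <- compute_flow(env$volume)
    env$flow <- scale_to_dynamic_range(flow, mode = config$scale_mode,
                                       probs = config$scale_probs)
    jsonlite::write_json(
      list(scale_factor = env$flow$scale_factor, mode = env$flow$mode),
      file.path(sdir, "flow_scale.json"), auto_unbox = TRUE, digits = NA)
  })

  run_stage("segment", function(sdir) {
    structural <- structural_volume(env$volume)
    layers <- segment_layers(structural)
    layers <- delineate_disc_margin(structural, layers,
                                    extent_mm = env$extent_mm %||% 2.4)
    env$layers <- layers
    write_layers(layers, file.path(sdir, "layers.json"))
  })

  run_stage("enface", function(sdir) {
    mask <- prelc_mask(env$layers, nz = dim(env$flow$flow)[3])
    env$enface <- mip_enface(env$flow, mask)
    write_map(env$enface$mip, file.path(sdir, "mip.csv"))
  })

  run_stage("vessels", function(sdir) {
    ef <- vesselness(env$enface, scales = config$scales, beta = config$beta,
                     c = config$frangi_c)
    ef <- binarize_vessels(ef, method = config$binarize_method,
                           t = config$binarize_threshold,
                           roi = env$layers$disc_mask)
    env$enface <- ef
    write_map(ef$vesselness, file.path(sdir, "vesselness.csv"))
    write_map(ef$vessel_mask, file.path(sdir, "vessel_mask.csv"))
  })

  run_stage("metrics", function(sdir) {
    env$metrics <- compute_perfusion_metrics(
      env$enface, env$layers$disc_mask,
      eye_id = "synthetic_eye", signal_strength = 10, motion = FALSE)
    readr::write_csv(env$metrics, file.path(sdir, "metrics.csv"))
  })

  run_stage("stats", function(sdir) {
    coh <- qc_filter(env$cohort, cutoff = config$qc_cutoff)
    coh <- dplyr::filter(coh, .data$qc_pass)
    env$tables <- build_tables(coh, ttest_mode = config$ttest_mode)
    write_tables(env$tables, sdir)
  })

  unlink(staging_root, recursive = TRUE)
  write_manifest()
  invisible(list(metrics = env$metrics, tables = env$tables,
                 manifest = manifest, out_dir = out_dir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
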