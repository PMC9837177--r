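#' Default end-to-end pipeline configuration
#'
#' Collects every tunable of the pipeline with its standard default:
#' SVD compression and explained-variance target 0.99, localization
#' threshold 0.75, axis training fraction 0.2 with 5 folds, attention
#' tertiles (top/bottom 33rd percentile, fixed in the generator), 2000
#' angle surrogates, psychometric lapse 0.2 with slopes 2/90 and 5/90 per
#' degree, 13 difficulty levels, and the RNN schedule (50 units, 25 frames,
#' 25 epochs, batch 640). `rnn$n_per_level` defaults to the desk-scale 640
#' trials per level per attention state; the study-scale value is 6400.
#'
#' @param seed master seed; every stage derives its stream from it.
#' @param n_trials imaging trials to simulate.
#' @param grid atlas grid side (pixels).
#' @param run_rnn train and analyze the recurrent model as part of the run.
#' @return nested configuration list.
#' @export
default_config <- function(seed = 1L, n_trials = 400L, grid = 64L,
                           run_rnn = FALSE) {
  list(
    seed = as.integer(seed),
    synth = list(grid = as.integer(grid), pixel_size_um = 50,
                 n_trials = as.integer(n_trials),
                 spec = planted_signal_spec(), tparams = trial_params(),
                 psych = psychometric_params()),
    preprocess = list(low = 0.1, high = 8, bin_um = 130, overlap = 0.5,
                      target_fps = 30),
    decompose = list(ev_target = 0.99, loc_threshold = 0.75,
                     svd_ev = 0.99, rank_per_area = 2L),
    axes = list(cv_folds = 5L, train_frac = 0.2),
    geometry = list(n_surrogates = 2000L),
    rnn = list(config = rnn_config(), n_per_level = 640L,
               n_per_level_full = 6400L),
    run_rnn = isTRUE(run_rnn))
}

.stage <- function(name, config_hash, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed (config %s): %s",
                 name, config_hash, conditionMessage(e)), call. = FALSE))
}

#' Run the full analysis pipeline on synthetic data
#'
#' simulate -> preprocess -> decompose -> state axes -> geometry
#' (-> recurrent model), returning a consolidated report with every
#' figure-level statistic: per-variable cross-validated d' curves, the
#' axis angle matrix with its surrogate null interval, hierarchical
#' clustering order, the spatial-distribution index of the choice axis,
#' five-group d' coordinates, the piecewise fit of the choice d' curve,
#' and (optionally) the recurrent model's psychometric curves and axis
#' angles. The report is deterministic given (config, seed).
#'
#' @param config from [default_config()].
#' @param keep_objects also return the session, decomposition and pair
#'   objects (large).
#' @return list of class `mesochoice_report`.
#' @export
run_pipeline <- function(config = default_config(), keep_objects = FALSE) {
  h <- substr(paste(
    format(sum(utils::head(unlist(lapply(config, function(x)
      as.numeric(utils::head(unlist(x), 20)))), 40), na.rm = TRUE),
      digits = 12), config$seed, sep = "-"), 1, 24)
  seed <- config$seed

  sim <- .stage("simulate", h, {
    atlas <- make_area_atlas(config$synth$grid, config$synth$grid,
                             config$synth$pixel_size_um, seed = seed)
    simulate_session(atlas, config$synth$spec, config$synth$tparams,
                     config$synth$n_trials, config$synth$psych,
                     seed = seed + 1L)
  })
  pre <- .stage("preprocess", h,
    bandpass_and_bin(sim$session, config$preprocess$low,
                     config$preprocess$high, config$preprocess$bin_um,
                     config$preprocess$overlap,
                     config$preprocess$target_fps))
  dec <- .stage("decompose", h,
    loca_nmf(pre, loc_threshold = config$decompose$loc_threshold,
             ev_target = config$decompose$ev_target,
             svd_ev = config$decompose$svd_ev,
             rank_per_area = config$decompose$rank_per_area))

  fs <- pre$frame_rate
  n_frames <- dim(pre$data)[3]
  variables <- c("stimulus", "wheel", "saccade", "attention", "choice")
  pairs <- list(); curves <- list(); axes_w <- list()
  for (v in variables) {
    pairs[[v]] <- .stage(paste0("axes/", v), h,
      build_group_pair(sim$trials, v, fs, pre$pre_stim, n_frames,
                       seed = seed + 2L))
    curves[[v]] <- .stage(paste0("axes/", v), h, suppressWarnings(
      dprime_curve(dec, pairs[[v]], config$axes$cv_folds,
                   config$axes$train_frac, seed = seed + 3L,
                   baseline_time = if (v == "attention") 0 else NULL)))
    axes_w[[v]] <- suppressWarnings(
      state_axis(dec, pairs[[v]], window = TRUE))
  }
  # pre/post movement choice axes for the geometry block
  pr <- pairs$choice
  choice_pre <- choice_post <- pr
  choice_pre$win_frames <- pr$win_frames[pr$win_frames < 0]
  choice_post$win_frames <- pr$win_frames[pr$win_frames >= 0]
  axes_w$choice_pre <- suppressWarnings(
    state_axis(dec, choice_pre, window = TRUE))
  axes_w$choice_post <- suppressWarnings(
    state_axis(dec, choice_post, window = TRUE))

  geometry <- .stage("geometry", h, {
    angles <- axis_angle_matrix(axes_w)
    null_ci <- surrogate_angle_null(axes_w$choice,
                                    config$geometry$n_surrogates,
                                    seed = seed + 4L)
    area_dp <- vapply(dec$atlas$area_names, function(a)
      max(abs(suppressWarnings(
        area_axis(dec, pairs$choice, a, cv_folds = config$axes$cv_folds,
                  train_frac = config$axes$train_frac,
                  seed = seed + 5L)$curve$dprime))), numeric(1))
    global_dp <- max(abs(curves$choice$dprime))
    list(angles = unclass(angles),
         null_ci = c(lo = null_ci$lo, hi = null_ci$hi),
         cluster_order = cluster_axes(angles)$order,
         cluster_labels = rownames(angles),
         area_dprime = area_dp,
         sdi_choice = sdi(global_dp, area_dp),
         group_dprime = suppressWarnings(
           group_dprime_5d(dec, pairs$choice,
                           cv_folds = config$axes$cv_folds,
                           train_frac = config$axes$train_frac,
                           seed = seed + 6L)),
         piecewise_choice = unclass(
           piecewise_fit(curves$choice)))
  })

  rnn <- NULL
  if (isTRUE(config$run_rnn)) {
    rnn <- .stage("rnn", h, {
      mdl <- build_rnn(config$rnn$config, seed = seed + 7L)
      ds <- make_rnn_dataset(config$synth$psych, config$rnn$n_per_level,
                             config = config$rnn$config, seed = seed + 8L)
      mdl <- train_rnn(mdl, ds, seed = seed + 9L)
      ev <- make_rnn_dataset(config$synth$psych,
                             max(100L, config$rnn$n_per_level %/% 2L),
                             config = config$rnn$config, seed = seed + 10L)
      tr <- rnn_trace(mdl, ev)
      sx <- suppressWarnings(rnn_state_axes(tr, seed = seed + 11L))
      list(history = mdl$history,
           psychometric = rnn_psychometric(mdl, seed = seed + 12L),
           angles = unclass(sx$angles),
           attention_angle = sx$attention_angle,
           dprime = sx$dprime)
    })
  }

  report <- list(
    config_hash = h,
    header = list(seed = seed,
                  ev_target = config$decompose$ev_target,
                  loc_threshold = config$decompose$loc_threshold,
                  svd_ev = config$decompose$svd_ev,
                  train_frac = config$axes$train_frac,
                  cv_folds = config$axes$cv_folds,
                  n_surrogates = config$geometry$n_surrogates,
                  lapse = config$synth$psych$lapse,
                  slope_low = config$synth$psych$slope_low,
                  slope_high = config$synth$psych$slope_high,
                  n_levels = config$synth$tparams$n_levels,
                  rnn_epochs = config$rnn$config$epochs,
                  rnn_batch = config$rnn$config$batch_size),
    decomposition = list(n_components = ncol(dec$spatial),
                         ev_total = dec$ev_total,
                         localization = dec$localization,
                         component_area = dec$component_area),
    dprime_curves = lapply(curves, function(cu)
      list(times = cu$times, dprime = cu$dprime,
           n_per_group = cu$n_per_group)),
    geometry = geometry,
    rnn = rnn)
  if (keep_objects)
    report$objects <- list(session = sim$session, trials = sim$trials,
                           preprocessed = pre, decomposition = dec,
                           pairs = pairs, axes = axes_w)
  class(report) <- "mesochoice_report"
  report
}

#' Write a pipeline report to JSON
#' @param report a `mesochoice_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  report$objects <- NULL
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  invisible(path)
}
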