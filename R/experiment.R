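#' Configure a full decoding experiment
#'
#' Bundles every knob of the simulate -> preprocess -> align -> train ->
#' evaluate workflow with explicit seeds and a chronological train/test
#' split: recording blocks are ordered in time and the final
#' `test_frac` of blocks is held out, so no training sample postdates a
#' test sample.
#'
#' @param sleeve_size Sleeve size class (default `"small"`).
#' @param movements Movement labels (or `"all"` for the full 12).
#' @param reps_per_block Repetitions of each movement per block.
#' @param n_blocks Number of recording blocks.
#' @param profile `"stroke"` or `"able"`; also sets the default center
#'   window (2.5 s stroke, 1.5 s able).
#' @param impairment,snr_db,latency_range,amplitude_cv,movement_scores
#'   Simulator settings; see [sim_params()].
#' @param shift_mode Cue alignment: `"none"`, `"static"`, `"dynamic"`.
#' @param static_shift_s Shift used when `shift_mode = "static"`.
#' @param max_shift_s Dynamic-shift bound (default 2 s).
#' @param window_s Center-window width; defaults from `profile`.
#' @param model `"LR"`, `"SVM"` or `"MLP"`.
#' @param mlp_epochs,mlp_max_lr MLP training overrides.
#' @param grid [grid_search_spec()] for the linear models.
#' @param test_frac Final fraction of blocks held out (default 0.25).
#' @param subset Optional [subset_spec()].
#' @param continuous Also decode the full test stream and score the per-cue
#'   success rate (default `TRUE`).
#' @param seed Master seed; every stochastic stage derives its own seed
#'   from it.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(sleeve_size = "small", movements = "all",
                              reps_per_block = 1L, n_blocks = 4L,
                              profile = c("stroke", "able"), impairment = 0,
                              snr_db = 15, latency_range = c(0.2, 1.2),
                              amplitude_cv = 0.15, movement_scores = NULL,
                              shift_mode = c("dynamic", "static", "none"),
                              static_shift_s = 0.8, max_shift_s = 2,
                              window_s = NULL, model = c("MLP", "LR", "SVM"),
                              mlp_epochs = 400L, mlp_max_lr = 1e-3,
                              grid = grid_search_spec(), test_frac = 0.25,
                              subset = NULL, continuous = TRUE, seed = 1) {
  profile <- match.arg(profile)
  shift_mode <- match.arg(shift_mode)
  model <- match.arg(model)
  if (n_blocks < 2L) abort("Need at least 2 blocks (one train, one test).")
  if (test_frac <= 0 || test_frac >= 1) abort("`test_frac` must be in (0, 1).")
  window_s <- window_s %||% switch(profile, stroke = 2.5, able = 1.5)
  structure(
    list(
      sleeve_size = sleeve_size, movements = movements,
      reps_per_block = reps_per_block, n_blocks = as.integer(n_blocks),
      profile = profile, impairment = impairment, snr_db = snr_db,
      latency_range = latency_range, amplitude_cv = amplitude_cv,
      movement_scores = movement_scores, shift_mode = shift_mode,
      static_shift_s = static_shift_s, max_shift_s = max_shift_s,
      window_s = window_s, model = model, mlp_epochs = as.integer(mlp_epochs),
      mlp_max_lr = mlp_max_lr, grid = grid, test_frac = test_frac,
      subset = subset, continuous = continuous, seed = as.integer(seed)
    ),
    class = "experiment_config"
  )
}

#' Run a full decoding experiment
#'
#' Simulates the configured recording blocks, preprocesses them (causal
#' filtering, 100 ms RMS bins, training-statistics normalization, 4-bin
#' stacking), aligns cue labels per block, builds center-window datasets,
#' fits the configured classifier on the training blocks, and evaluates on
#' the held-out final blocks. The chronological split is asserted, not
#' assumed.
#'
#' @param config An [experiment_config()].
#' @param out_dir Optional directory: artifacts (model bundle, report JSON,
#'   manifest) are written there.
#' @return A list of class `emg_experiment`: `report` (an `emg_eval` on the
#'   center-window test set), `continuous_report` (stream decoding with
#'   success rate, if requested), `model`, `norm_stats`, `shifts`,
#'   `manifest`.
#' @export
run_experiment <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  layout <- make_sleeve_layout(config$sleeve_size)
  seeds <- child_seeds(config$seed, 3L * config$n_blocks + 1L)

  n_test <- max(1L, ceiling(config$test_frac * config$n_blocks))
  n_train <- config$n_blocks - n_test
  if (n_train < 1L) abort("Configuration leaves no training blocks.")
  is_test <- seq_len(config$n_blocks) > n_train
  # chronology guard: every training block precedes every test block
  stopifnot(max(which(!is_test)) < min(which(is_test)))

  blocks <- vector("list", config$n_blocks)
  for (b in seq_len(config$n_blocks)) {
    schedule <- make_cue_schedule(
      config$movements, config$reps_per_block, config$profile,
      seed = seeds[3L * b - 2L]
    )
    params <- sim_params(
      impairment = config$impairment, snr_db = config$snr_db,
      latency_range = config$latency_range, amplitude_cv = config$amplitude_cv,
      movement_scores = config$movement_scores, seed = seeds[3L * b - 1L]
    )
    rec <- simulate_emg(schedule, layout, params)
    filt <- bandpass_notch(rec)
    blocks[[b]] <- list(
      recording = rec, features = rms_bins(filt), schedule = schedule,
      seed = seeds[3L * b]
    )
  }

  norm_stats <- fit_normalizer(
    do.call(rbind, lapply(blocks[!is_test], function(bl) bl$features$rms))
  )

  shifts <- vector("list", config$n_blocks)
  for (b in seq_len(config$n_blocks)) {
    ft <- apply_normalizer(blocks[[b]]$features, norm_stats)
    sched <- blocks[[b]]$schedule
    shifted <- switch(config$shift_mode,
      none = sched,
      static = static_shift(sched, config$static_shift_s),
      dynamic = {
        sr <- dynamic_shift(summarize_activity(ft), sched,
          max_shift_s = config$max_shift_s
        )
        shifts[[b]] <- sr
        sr$shifted_schedule
      }
    )
    ft <- stack_history(ft, 4L)
    ds <- extract_center_windows(ft, shifted, config$window_s)
    blocks[[b]]$features_n <- ft
    blocks[[b]]$shifted_schedule <- shifted
    blocks[[b]]$dataset <- ds
  }

  if (!is.null(config$subset)) {
    for (b in seq_len(config$n_blocks)) {
      blocks[[b]]$dataset <- build_subset(
        blocks[[b]]$dataset, blocks[[b]]$shifted_schedule, config$subset
      )
    }
  }

  bind_ds <- function(idx) {
    list(
      x = do.call(rbind, lapply(blocks[idx], function(bl) bl$dataset$x)),
      y = unlist(lapply(blocks[idx], function(bl) bl$dataset$y))
    )
  }
  train <- bind_ds(which(!is_test))
  test <- bind_ds(which(is_test))

  model_seed <- seeds[length(seeds)]
  model <- switch(config$model,
    LR = fit_linear(train$x, train$y, "LR", config$grid, seed = model_seed),
    SVM = fit_linear(train$x, train$y, "SVM", config$grid, seed = model_seed),
    MLP = fit_mlp(
      train$x, train$y,
      mlp_spec(ncol(train$x),
        n_classes = length(unique(train$y)),
        epochs = config$mlp_epochs, max_lr = config$mlp_max_lr
      ),
      seed = model_seed
    )
  )

  pred <- predict(model, test$x)
  report <- eval_report(pred, test$y)

  continuous_report <- NULL
  if (isTRUE(config$continuous) && is.null(config$subset)) {
    preds <- list()
    truths <- list()
    srs <- numeric(0)
    for (b in which(is_test)) {
      ft <- blocks[[b]]$features_n
      valid <- ft$valid
      p <- predict(model, ft$stacked[valid, , drop = FALSE])
      full <- c(rep("Rest", sum(!valid)), p)
      sched <- blocks[[b]]$shifted_schedule
      truth <- schedule_bin_labels(sched, length(full))
      preds[[length(preds) + 1L]] <- full
      truths[[length(truths) + 1L]] <- truth
      srs <- c(srs, success_rate(full, sched)$rate)
    }
    continuous_report <- list(
      bin_accuracy = bin_accuracy(unlist(preds), unlist(truths)),
      chance_level = chance_level(unlist(truths)),
      success_rate = mean(srs)
    )
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("hdemg")),
    config = config[setdiff(names(config), "grid")],
    seeds = seeds,
    n_train_samples = nrow(train$x),
    n_test_samples = nrow(test$x),
    classes = model$classes,
    report_hash = rlang::hash(report)
  )

  out <- structure(
    list(
      report = report, continuous_report = continuous_report,
      model = model, norm_stats = norm_stats,
      shifts = shifts[!vapply(shifts, is.null, logical(1))],
      train_labels = train$y, test_labels = test$y,
      manifest = manifest
    ),
    class = "emg_experiment"
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    export_model(model, file.path(out_dir, "model.json"))
    write_report_json(report, file.path(out_dir, "report.json"))
    write_norm_stats(norm_stats, file.path(out_dir, "norm_stats.json"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
      auto_unbox = TRUE, digits = NA, null = "null", force = TRUE
    )
  }
  out
}

#' @export
print.emg_experiment <- function(x, ...) {
  print(x$report)
  if (!is.null(x$continuous_report)) {
    cat(sprintf(
      "  continuous: accuracy %.1f%%, success rate %.1f%%\n",
      100 * x$continuous_report$bin_accuracy,
      100 * x$continuous_report$success_rate
    ))
  }
  invisible(x)
}

#' @export
glance.emg_experiment <- function(x, ...) {
  dplyr::bind_cols(
    glance(x$report),
    tibble::tibble(
      model = x$model$kind,
      continuous_accuracy = x$continuous_report$bin_accuracy %||% NA_real_,
      continuous_success_rate = x$continuous_report$success_rate %||% NA_real_
    )
  )
}

#' Read an experiment configuration from YAML
#'
#' @param path YAML file whose keys mirror [experiment_config()] arguments.
#' @return An `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- names(formals(experiment_config))
  extra <- setdiff(names(cfg), known)
  if (length(extra)) {
    abort(paste0("Unknown config field(s): ", paste(extra, collapse = ", ")))
  }
  do.call(experiment_config, cfg)
}
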