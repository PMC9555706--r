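# Pipeline composition: {imputation} -> {diurnal baseline} -> {residual
# model}, in either order, with additive recomposition at prediction time.

#' Resolution profiles
#'
#' `desk` is the fast experimentation profile used throughout the test
#' suite (small hidden size, fewer epochs, strided windows); `full` is the
#' full-scale profile (H = 256, 30 epochs, every sliding window).
#'
#' @param profile `"desk"` or `"full"`.
#' @return list of stage defaults.
#' @export
profile_defaults <- function(profile = c("desk", "full")) {
  profile <- match.arg(profile)
  if (profile == "desk") {
    list(hidden = 32, epochs = 12, stride = 2, batch_size = 64,
         target_frac = 0.25, window = 8, knn_hidden = 32,
         sthm = list(max_iter = 20, tol = 1e-4))
  } else {
    list(hidden = 256, epochs = 30, stride = 1, batch_size = 64,
         target_frac = 0.25, window = 8, knn_hidden = 256,
         sthm = list(max_iter = 50, tol = 1e-5))
  }
}

#' Declarative pipeline specification
#'
#' @param imputation `"none"` or `"sthm"` (state-space gap filling of the
#'   *inputs*; the loss and evaluation only ever see truly observed cells).
#' @param baseline `"none"`, `"spline_per_site"`, or `"spline_average"`.
#' @param model `"none"`, `"mprnn"`, `"knn_rnn"`, or `"sthm_forecast"`.
#' @param order `"baseline_first"` (model fits baseline residuals) or
#'   `"model_first"` (baseline fits model residuals); ignored when either
#'   stage is `"none"`.
#' @param profile resolution profile, see [profile_defaults()].
#' @param K neighbor count for `knn_rnn`.
#' @param seed master seed for all stochastic stages.
#' @param ... stage-default overrides (e.g. `epochs`, `hidden`, `stride`).
#' @return a `pipeline_spec`.
#' @export
pipeline_spec <- function(imputation = c("none", "sthm"),
                          baseline = c("none", "spline_per_site", "spline_average"),
                          model = c("none", "mprnn", "knn_rnn", "sthm_forecast"),
                          order = c("baseline_first", "model_first"),
                          profile = c("desk", "full"), K = 5, seed = 1, ...) {
  spec <- list(imputation = match.arg(imputation),
               baseline = match.arg(baseline),
               model = match.arg(model),
               order = match.arg(order),
               profile = match.arg(profile), K = K, seed = as.integer(seed),
               overrides = list(...))
  if (spec$baseline == "none" && spec$model == "none") {
    stopf("pipeline_spec: at least one of baseline/model must be set")
  }
  if (spec$model == "sthm_forecast" && spec$baseline != "none") {
    stopf(paste("pipeline_spec: sthm_forecast carries its own mean structure",
                "and cannot be composed with a spline baseline"))
  }
  class(spec) <- "pipeline_spec"
  spec
}

#' Named pipeline presets
#'
#' The ten standard model compositions, from single-stage baselines to the
#' full hybrid (state-space imputation, per-sensor spline baseline,
#' residual message-passing network), which is also available as `"best"`.
#'
#' @param name preset name; see `names(pipeline_presets())`.
#' @param ... passed through to [pipeline_spec()] (profile, seed, overrides).
#' @return `preset_pipeline`: a `pipeline_spec`; `pipeline_presets`: the
#'   named list of preset arguments.
#' @export
pipeline_presets <- function() {
  list(
    sthm = list(model = "sthm_forecast"),
    knn_rnn = list(model = "knn_rnn"),
    mprnn = list(model = "mprnn"),
    spline_per_site = list(baseline = "spline_per_site"),
    sthm_spline = list(imputation = "sthm", baseline = "spline_per_site"),
    knn_rnn_residual_spline = list(model = "knn_rnn",
                                   baseline = "spline_per_site",
                                   order = "model_first"),
    mprnn_residual_spline = list(model = "mprnn",
                                 baseline = "spline_per_site",
                                 order = "model_first"),
    spline_residual_mprnn = list(baseline = "spline_per_site",
                                 model = "mprnn", order = "baseline_first"),
    best = list(imputation = "sthm", baseline = "spline_per_site",
                model = "mprnn", order = "baseline_first"),
    mprnn_sthm_avg_spline = list(imputation = "sthm",
                                 baseline = "spline_average",
                                 model = "mprnn", order = "model_first")
  )
}

#' @rdname pipeline_presets
#' @export
preset_pipeline <- function(name, ...) {
  presets <- pipeline_presets()
  if (!name %in% names(presets)) {
    stopf("unknown preset '%s'; available: %s", name,
          paste(names(presets), collapse = ", "))
  }
  do.call(pipeline_spec, c(presets[[name]], list(...)))
}

# Subtract a baseline matrix from a panel (keeping the mask), unbounded.
panel_minus <- function(panel, base_mat) {
  vals <- panel$values - base_mat
  vals[!panel$mask] <- NA_real_
  readings_panel(vals, panel$timestamps, sites = panel$sites,
                 mask = panel$mask, bounds = NULL)
}

#' Fit a composed pipeline and predict over the held-out span
#'
#' Chronologically splits the panel, fits the configured stages on the
#' training span, and produces rolling one-hour-ahead predictions for every
#' site over the test span. Stages compose additively: the residual model's
#' predictions are added back onto the baseline it was trained against.
#'
#' @param spec a [pipeline_spec()] or preset name.
#' @param observed the observed [readings_panel] over the full span.
#' @param sites site table with coordinates and tiers.
#' @param split training fraction (default 0.75) or `POSIXct` boundary.
#' @return a `pipeline_fit`: list with `spec`, fitted stage objects,
#'   `predictions` (panel over the full grid, valid on the test span),
#'   `test` (observed test panel), and `split` bookkeeping.
#' @export
fit_pipeline <- function(spec, observed, sites, split = 0.75) {
  if (is.character(spec)) spec <- preset_pipeline(spec)
  stopifnot(inherits(spec, "pipeline_spec"))
  prof <- utils::modifyList(profile_defaults(spec$profile), spec$overrides)
  seed <- spec$seed
  geom <- build_geometry(sites[match(observed$sites, sites$site_id), , drop = FALSE])
  parts <- split_train_test(observed, split)
  train <- parts$train
  tt <- length(observed$timestamps)
  n_train <- length(train$timestamps)
  test_idx <- (n_train + 1L):tt
  w <- prof$window

  stage <- list()

  # -- imputation of inputs ---------------------------------------------
  if (spec$imputation == "sthm" || spec$model == "sthm_forecast") {
    stage$sthm <- fit_sthm(train, sites = sites, dist = geom$dist,
                           config = prof$sthm)
  }
  inputs_full <- if (spec$imputation == "sthm") {
    sthm_impute(stage$sthm, observed)
  } else {
    observed
  }
  inputs_train <- subset_panel(inputs_full, time_idx = seq_len(n_train))

  predictions <- NULL

  if (spec$model == "sthm_forecast") {
    pred <- predict_sthm(stage$sthm, observed)
    predictions <- subset_panel(pred, time_idx = test_idx)
  } else if (spec$baseline != "none" && spec$model != "none" &&
             spec$order == "model_first") {
    # model on raw values, then a spline on the model's residuals
    stage$model <- fit_stage_model(spec, prof, train, inputs_full, n_train,
                                   geom, sites, seed)
    pred_train <- stage_model_predict(spec, stage$model, inputs_full,
                                      from = w + 2L, to = n_train, w, seed)
    resid_mask <- train$mask & pred_train$mask[, seq_len(n_train), drop = FALSE]
    resid_vals <- train$values - pred_train$values[, seq_len(n_train), drop = FALSE]
    resid_vals[!resid_mask] <- NA_real_
    resid_train <- readings_panel(resid_vals, train$timestamps,
                                  sites = train$sites, mask = resid_mask,
                                  bounds = NULL)
    stage$spline <- fit_spline(resid_train, scope = spline_scope(spec))
    pred_test <- stage_model_predict(spec, stage$model, inputs_full,
                                     from = n_train + 1L, to = tt, w, seed)
    base_mat <- eval_spline_matrix(stage$spline, observed$sites,
                                   observed$timestamps)
    vals <- pred_test$values + base_mat
    vals[!pred_test$mask] <- NA_real_
    predictions <- subset_panel(
      readings_panel(vals, observed$timestamps, sites = observed$sites,
                     mask = pred_test$mask, bounds = NULL),
      time_idx = test_idx)
  } else {
    # baseline (optional), then model on baseline residuals (optional)
    base_mat_full <- NULL
    if (spec$baseline != "none") {
      stage$spline <- fit_spline(inputs_train, scope = spline_scope(spec))
      base_mat_full <- eval_spline_matrix(stage$spline, observed$sites,
                                          observed$timestamps)
    }
    if (spec$model == "none") {
      vals <- base_mat_full
      predictions <- subset_panel(
        readings_panel(vals, observed$timestamps, sites = observed$sites,
                       mask = matrix(TRUE, nrow(vals), ncol(vals)),
                       bounds = NULL),
        time_idx = test_idx)
    } else {
      model_targets <- if (is.null(base_mat_full)) train else {
        panel_minus(train, base_mat_full[, seq_len(n_train), drop = FALSE])
      }
      model_inputs_full <- if (is.null(base_mat_full)) inputs_full else {
        panel_minus(inputs_full, base_mat_full)
      }
      stage$model <- fit_stage_model(spec, prof, model_targets,
                                     model_inputs_full, n_train, geom,
                                     sites, seed,
                                     denom_panel = if (!is.null(base_mat_full)) train)
      pred_test <- stage_model_predict(spec, stage$model, model_inputs_full,
                                       from = n_train + 1L, to = tt, w, seed)
      vals <- pred_test$values
      if (!is.null(base_mat_full)) vals <- vals + base_mat_full
      vals[!pred_test$mask] <- NA_real_
      predictions <- subset_panel(
        readings_panel(vals, observed$timestamps, sites = observed$sites,
                       mask = pred_test$mask, bounds = NULL),
        time_idx = test_idx)
    }
  }

  structure(list(spec = spec, profile = prof, stage = stage,
                 predictions = predictions, test = parts$test,
                 n_train = n_train, sites = sites),
            class = "pipeline_fit")
}

spline_scope <- function(spec) {
  if (spec$baseline == "spline_average") "average" else "per_site"
}

# Train the residual/raw model stage on the training span. Every stage
# optimizes the declared percentage objective of the FINAL prediction:
# models fit to raw levels use the target itself as denominator, while
# models fit to baseline residuals use the raw observed level (under an
# additive baseline, |residual error|/level IS the final prediction's
# percentage error). Overridable via the profile's `loss` ("mse").
fit_stage_model <- function(spec, prof, targets_train, inputs_full, n_train,
                            geom, sites, seed, denom_panel = NULL) {
  inputs_train <- subset_panel(inputs_full, time_idx = seq_len(n_train))
  stage_loss <- prof$loss %||% (if (is.null(denom_panel)) "mape" else "mae")
  if (spec$model == "mprnn") {
    m <- init_mprnn(targets_train$sites, geom$dist, hidden = prof$hidden,
                    seed = substream_seed(seed, 51L))
    train_mprnn(m, targets_train, inputs_train, epochs = prof$epochs,
                batch_size = prof$batch_size, window = prof$window,
                stride = prof$stride, target_frac = prof$target_frac,
                loss = stage_loss, denom_panel = denom_panel,
                seed = substream_seed(seed, 52L))
  } else if (spec$model == "knn_rnn") {
    train_knn_rnn(targets_train, inputs_train, sites = sites,
                  dist = geom$dist, K = spec$K, hidden = prof$knn_hidden,
                  epochs = prof$epochs, batch_size = prof$batch_size,
                  window = prof$window, stride = prof$stride,
                  loss = stage_loss, denom_panel = denom_panel,
                  seed = substream_seed(seed, 53L))
  } else {
    stopf("no model stage for spec model '%s'", spec$model)
  }
}

stage_model_predict <- function(spec, model, inputs_full, from, to, window, seed) {
  if (inherits(model, "mprnn_model")) {
    predict_mprnn(model, inputs_full, from = from, to = to, window = window,
                  seed = substream_seed(seed, 54L, from))
  } else {
    predict_knn_rnn(model, inputs_full, from = from, to = to, window = window,
                    seed = substream_seed(seed, 54L, from))
  }
}

#' @export
print.pipeline_fit <- function(x, ...) {
  s <- x$spec
  cat(sprintf("<pipeline_fit> imputation=%s baseline=%s model=%s order=%s (%s profile)\n",
              s$imputation, s$baseline, s$model, s$order, s$profile))
  cat(sprintf("  trained on %d h, predictions over %d test hours\n",
              x$n_train, length(x$test$timestamps)))
  invisible(x)
}

#' Builder closure for ablation studies
#'
#' Wraps a spec into the `build_fn(observed, sites, seed)` contract used by
#' [ablate_network_size()]: refit the pipeline on the given subnetwork and
#' return its test-span predictions.
#'
#' @param spec a [pipeline_spec()] or preset name.
#' @param split training fraction.
#' @return a function `(observed, sites, seed) -> prediction panel`.
#' @export
pipeline_builder <- function(spec, split = 0.75) {
  if (is.character(spec)) spec <- preset_pipeline(spec)
  force(split)
  function(observed, sites, seed) {
    sp <- spec
    sp$seed <- as.integer(seed)
    fit_pipeline(sp, observed, sites, split = split)$predictions
  }
}

#' Run a configured end-to-end experiment
#'
#' Simulates (or loads) a dataset, fits a pipeline, evaluates it, and
#' writes a deterministic artifacts directory: the resolved configuration,
#' test-span predictions, and a versioned JSON report. Re-running with the
#' same configuration and seed reproduces every artifact byte-for-byte.
#'
#' @param config a list (or YAML file path) with fields: `sim` (arguments
#'   to [sim_config()]) or `data` (list with `readings`/`sites` CSV paths),
#'   `pipeline` (preset name, or argument list for [pipeline_spec()]),
#'   `split` (training fraction, default 0.75), `seed`,
#'   `hazard_threshold` (default 60), `out_dir`.
#' @param dry_run print the resolved stage plan and return it without
#'   computing.
#' @return invisibly, the report list (with `out_dir` noted when written).
#' @export
run_experiment <- function(config, dry_run = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- as.integer(config$seed %||% 1)
  split <- config$split %||% 0.75
  spec <- if (is.character(config$pipeline)) {
    preset_pipeline(config$pipeline, seed = seed,
                    profile = config$profile %||% "desk")
  } else {
    do.call(pipeline_spec, utils::modifyList(
      list(seed = seed, profile = config$profile %||% "desk"),
      config$pipeline))
  }

  plan <- list(
    data = if (!is.null(config$data)) "load CSVs" else "simulate synthetic city",
    split = split,
    imputation = spec$imputation, baseline = spec$baseline,
    model = spec$model, order = spec$order, profile = spec$profile,
    seed = seed
  )
  if (dry_run) {
    message("resolved stage plan:")
    for (nm in names(plan)) message(sprintf("  %-10s %s", nm, plan[[nm]]))
    return(invisible(plan))
  }

  if (!is.null(config$data)) {
    ds <- load_dataset(config$data$readings, config$data$sites,
                       tz = config$data$tz %||% "Asia/Kolkata")
    observed <- ds$panel; sites <- ds$sites; truth <- NULL
  } else {
    sim_args <- utils::modifyList(list(seed = seed), config$sim %||% list())
    city <- simulate_city(do.call(sim_config, sim_args))
    observed <- city$observed; sites <- city$sites; truth <- city$truth
  }

  message(sprintf("[pipeline] fitting %s/%s/%s on %d sites x %d h",
                  spec$imputation, spec$baseline, spec$model,
                  length(observed$sites), length(observed$timestamps)))
  fit <- fit_pipeline(spec, observed, sites, split = split)

  truth_test <- if (!is.null(truth)) {
    subset_panel(truth, time_idx = (fit$n_train + 1L):length(observed$timestamps))
  } else {
    fit$test
  }
  report <- list(
    schema = "pmcast-report/1",
    config = plan,
    metrics = list(
      mape = mape(fit$predictions, truth_test),
      rmse = rmse(fit$predictions, truth_test)
    )
  )
  rep_sites <- per_sensor_report(fit$predictions, truth_test, sites = sites)
  report$per_site <- rep_sites$per_site
  report$aggregate <- rep_sites$aggregate
  hz <- tryCatch(
    hazard_detection(fit$predictions, truth_test,
                     threshold = config$hazard_threshold %||% 60),
    error = function(e) NULL)
  if (!is.null(hz)) {
    report$hazard <- list(threshold = config$hazard_threshold %||% 60,
                          precision = hz$precision, recall = hz$recall,
                          counts = as.list(hz$counts))
  }

  out_dir <- config$out_dir
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    yaml::write_yaml(plan, file.path(out_dir, "resolved_config.yaml"))
    write_panel(fit$predictions, file.path(out_dir, "predictions.csv"))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    report$out_dir <- out_dir
    message(sprintf("[pipeline] artifacts written to %s", out_dir))
  }
  invisible(report)
}
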