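#' Default run configuration
#'
#' The nested configuration consumed by [run_pipeline()] and the command
#' line interface. Every entry has a default; configurations loaded from
#' YAML are validated against this structure and unknown keys are rejected.
#'
#' @return A nested named list.
#' @export
default_run_config <- function() {
  list(
    seed = 1L,
    synth = list(duration_s = 120, sampling_rate = 2000,
                 band = list(f1 = 20, f2 = 450), at_frac = 0.5,
                 mf_drop_frac = 0.3, rms_gain = 1.5, input_snr_db = 5,
                 n_records = 4L),
    wavelet = list(name = "db45", max_level = 4L),
    threshold = list(kind = "improved", lambda_rule = "heursure",
                     fixed_lambda = 0, k = 2L, m = 0.5, pool = "node",
                     threshold_approx = TRUE, sparse_fallback = FALSE),
    window = list(width_s = 2, step_s = 2),
    band = list(f1 = 10, f2 = 500),
    sequence = list(seq_len = 5L),
    split = list(train_frac = 0.7, val_frac = 0.1, test_frac = 0.2),
    classifier = list(model = "lstm", units = 100L, fc_units = 32L,
                      epochs = 50L, batch_size = 70L,
                      learning_rate = 0.001, dropout = 0.5,
                      optimizer = "adam", patience = 10L),
    benchmark = list(n_seeds = 10L)
  )
}

# Merge a user config into the defaults, rejecting unknown keys at any
# nesting depth.
merge_run_config <- function(user, defaults = default_run_config(),
                             path = "") {
  if (is.null(user)) return(defaults)
  if (!is.list(user)) stop("configuration must be a named list", call. = FALSE)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop(sprintf("unknown configuration key(s): %s",
                 paste0(path, unknown, collapse = ", ")), call. = FALSE)
  }
  for (nm in names(user)) {
    if (is.list(defaults[[nm]])) {
      defaults[[nm]] <- merge_run_config(user[[nm]], defaults[[nm]],
                                         paste0(path, nm, "."))
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

#' Load and validate a run configuration from YAML
#'
#' @param path Path to a YAML file; `NULL` returns the defaults.
#' @return A validated configuration list.
#' @export
read_run_config <- function(path = NULL) {
  user <- if (is.null(path)) NULL else yaml::read_yaml(path)
  merge_run_config(user)
}

config_to_synth <- function(cfg, seed) {
  synth_config(duration_s = cfg$synth$duration_s,
               sampling_rate = cfg$synth$sampling_rate,
               band = band_spec(cfg$synth$band$f1, cfg$synth$band$f2),
               at_frac = cfg$synth$at_frac,
               mf_drop_frac = cfg$synth$mf_drop_frac,
               rms_gain = cfg$synth$rms_gain,
               input_snr_db = cfg$synth$input_snr_db,
               seed = seed)
}

config_to_threshold <- function(cfg, kind = NULL) {
  th <- cfg$threshold
  threshold_config(kind = if (is.null(kind)) th$kind else kind,
                   lambda_rule = th$lambda_rule,
                   fixed_lambda = th$fixed_lambda, k = th$k, m = th$m,
                   pool = th$pool, threshold_approx = th$threshold_approx,
                   sparse_fallback = th$sparse_fallback)
}

#' Denoising benchmark across threshold functions
#'
#' Generates seeded synthetic sEMG records at the configured input SNR,
#' denoises each with the hard, soft and improved threshold functions, and
#' scores every run against the clean reference with output SNR and RMSE.
#'
#' @param config A run configuration (see [default_run_config()]).
#' @param n_seeds Number of independent records (default from config).
#' @param seed Base seed; record `i` uses `seed + i - 1`.
#' @return A `data.frame` with columns `kind`, `seed`, `snr_db`, `rmse`,
#'   plus attribute `summary` (mean per kind).
#' @export
denoise_benchmark <- function(config = default_run_config(),
                              n_seeds = config$benchmark$n_seeds,
                              seed = config$seed) {
  rows <- list()
  for (i in seq_len(n_seeds)) {
    gt <- generate_semg(config_to_synth(config, seed + i - 1L))
    for (kind in c("hard", "soft", "improved")) {
      dn <- wp_denoise(gt$noisy, config_to_threshold(config, kind),
                       wavelet = config$wavelet$name,
                       max_level = config$wavelet$max_level)
      rows[[length(rows) + 1L]] <- data.frame(
        kind = kind, seed = seed + i - 1L,
        snr_db = snr_db(gt$clean, dn$signal),
        rmse = rmse(gt$clean, dn$signal))
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "summary") <- stats::aggregate(
    cbind(snr_db, rmse) ~ kind, data = out, FUN = mean)
  out
}

#' End-to-end fatigue recognition pipeline
#'
#' Runs the full chain on synthetic data: generate records, denoise each
#' with the configured threshold function, extract windowed features,
#' group them into labelled sequences, stratified-split, train the chosen
#' classifier, and evaluate on the held-out test set.
#'
#' @param config A run configuration (see [default_run_config()]).
#' @param verbose Log stage progress via `message()`.
#' @return A list of class `pipeline_result` with `features`
#'   (`feature_matrix` over all records), `dataset`, `split`, `model`,
#'   `report` (the test-set `eval_report`) and `manifest` (the effective
#'   configuration).
#' @export
run_pipeline <- function(config = default_run_config(), verbose = FALSE) {
  log_ <- function(fmt, ...) if (verbose) {
    message(sprintf(paste0("[pipeline] ", fmt), ...))
  }
  t0 <- Sys.time()
  n_rec <- config$synth$n_records
  wspec <- window_spec(config$window$width_s, config$window$step_s)
  band <- band_spec(config$band$f1, config$band$f2)
  feats <- list()
  for (i in seq_len(n_rec)) {
    gt <- generate_semg(config_to_synth(config, config$seed + i - 1L))
    log_("record %d/%d generated (%.0f s @ %g Hz)", i, n_rec,
         gt$config$duration_s, gt$config$sampling_rate)
    dn <- wp_denoise(gt$noisy, config_to_threshold(config),
                     wavelet = config$wavelet$name,
                     max_level = config$wavelet$max_level)
    fm <- extract_features(dn$signal, wspec, band, gt$at_time_s)
    fm$channel <- sprintf("rec%02d", i)
    feats[[i]] <- fm
  }
  features <- do.call(rbind, feats)
  class(features) <- c("feature_matrix", "data.frame")
  log_("features: %d windows over %d records", nrow(features), n_rec)

  dataset <- features_to_dataset(features, config$sequence$seq_len)
  sp <- stratified_split(dataset,
                         split_spec(config$split$train_frac,
                                    config$split$val_frac,
                                    config$split$test_frac,
                                    seed = config$seed))
  log_("split: %d train / %d val / %d test sequences",
       length(sp$train$x), length(sp$val$x), length(sp$test$x))

  cl <- config$classifier
  model <- switch(
    cl$model,
    lstm = train_lstm(sp$train, sp$val, lstm_config(
      units = cl$units, fc_units = cl$fc_units, epochs = cl$epochs,
      batch_size = cl$batch_size, learning_rate = cl$learning_rate,
      dropout = cl$dropout, optimizer = cl$optimizer,
      patience = cl$patience, seed = config$seed)),
    cnn = train_cnn(sp$train, sp$val, cnn_config(
      epochs = cl$epochs, batch_size = cl$batch_size,
      patience = cl$patience, seed = config$seed)),
    svm = train_svm(sp$train),
    stop(sprintf("unknown classifier model '%s'", cl$model), call. = FALSE)
  )
  report <- evaluate_model(model, sp$test)
  log_("test accuracy %.4f (%.1f s elapsed)", report$acc,
       as.numeric(difftime(Sys.time(), t0, units = "secs")))
  structure(
    list(features = features, dataset = dataset, split = sp, model = model,
         report = report, manifest = config),
    class = "pipeline_result"
  )
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %s classifier | test ",
              x$manifest$classifier$model))
  print(x$report)
  invisible(x)
}

#' Serialize an evaluation report to JSON
#' @param report An `eval_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_eval_json <- function(report, path) {
  jsonlite::write_json(
    list(counts = as.list(report$counts),
         acc = report$acc, sn = report$sn, sp = report$sp, pr = report$pr),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
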