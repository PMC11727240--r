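# End-to-end driver: simulate -> condition -> features -> embeddings ->
# classification, with every artifact written to disk under deterministic
# names and a manifest that records the full configuration and per-stage
# counts, so a run is reproducible from its manifest alone.

#' Pipeline configuration
#'
#' All stage parameters with their documented defaults. The single `seed`
#' feeds every stochastic stage through derived sub-seeds.
#'
#' @param classes Class labels (one task family).
#' @param n_per_class Recordings per class.
#' @param jaws `"both"`, `"maxilla"` or `"mandible"`.
#' @param fs,duration,snr_db,drift_amp,drift_freq,crosstalk Simulator
#'   settings (see [simulate_recording()]).
#' @param lowpass,drift_cutoff,ica Conditioning settings
#'   (see [condition_recording()]).
#' @param window_s,aggregate Feature settings (see
#'   [build_feature_table()]).
#' @param embed_method,embed_dims,perplexity Embedding settings.
#' @param ratio,models Classification settings.
#' @param seed Master seed.
#' @param save_recordings Write the raw and conditioned recordings to disk
#'   (CSV + sidecar per recording)?
#' @return A validated list of class `occl_config`.
#' @export
pipeline_config <- function(classes = malocclusion_classes(),
                            n_per_class = 20,
                            jaws = "both", fs = 50, duration = 10,
                            snr_db = 20, drift_amp = 0.5, drift_freq = 0.3,
                            crosstalk = 0.15, lowpass = 20,
                            drift_cutoff = 1, ica = TRUE, window_s = 1,
                            aggregate = "per_recording_mean",
                            embed_method = "tsne", embed_dims = 3,
                            perplexity = 30, ratio = 0.8,
                            models = .MODEL_NAMES, seed = 1,
                            save_recordings = TRUE) {
  cfg <- list(
    classes = classes, n_per_class = n_per_class, jaws = jaws, fs = fs,
    duration = duration, snr_db = snr_db, drift_amp = drift_amp,
    drift_freq = drift_freq, crosstalk = crosstalk, lowpass = lowpass,
    drift_cutoff = drift_cutoff, ica = ica, window_s = window_s,
    aggregate = aggregate, embed_method = embed_method,
    embed_dims = embed_dims, perplexity = perplexity, ratio = ratio,
    models = models, seed = as.integer(seed),
    save_recordings = save_recordings
  )
  stopifnot(cfg$n_per_class >= 1, cfg$fs > 0, cfg$drift_freq < 1,
            cfg$ratio > 0, cfg$ratio < 1,
            cfg$embed_method %in% c("pca", "tsne", "none"))
  structure(cfg, class = c("occl_config", "list"))
}

#' Read/write a pipeline configuration
#'
#' Flat human-readable YAML; round-trips losslessly.
#'
#' @param config An `occl_config`.
#' @param path File path.
#' @return `read_config()` returns the validated `occl_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' Run the full analysis pipeline
#'
#' Stages: simulate a balanced dataset; condition every recording
#' (low-pass, drift removal, optional ICA + alignment); build and
#' normalise the feature table; fit the requested embedding; run the
#' balanced split and seven-model benchmark. Artifacts written under
#' `out_dir`: `config.yaml`, `features.csv` (raw) and
#' `features_normalized.csv`, `coords.csv`, `report.json`,
#' `manifest.json`, and (optionally) `recordings/` + `conditioned/`.
#' Identical configurations yield byte-identical artifacts.
#'
#' @param config An [pipeline_config()].
#' @param out_dir Writable output directory (created if missing).
#' @return A list with `features`, `features_normalized`, `split`,
#'   `suite`, `report`, `embedding` and `manifest`, invisibly also written
#'   to disk.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "occl_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = unclass(config), stages = list())
  seeds <- .derive_seeds(config$seed, 4)
  write_config(config, file.path(out_dir, "config.yaml"))

  note <- function(stage, ...) {
    message(sprintf("[%s] %s", stage, sprintf(...)))
  }

  recs <- simulate_dataset(
    config$n_per_class, config$classes, seed = seeds[1],
    jaws = config$jaws, fs = config$fs, duration = config$duration,
    snr_db = config$snr_db, drift_amp = config$drift_amp,
    drift_freq = config$drift_freq, crosstalk = config$crosstalk
  )
  note("simulate", "%d recordings (%d classes x %d)", length(recs),
       length(config$classes), config$n_per_class)
  manifest$stages$simulate <- list(n_recordings = length(recs),
                                   seed = seeds[1])
  if (isTRUE(config$save_recordings)) {
    rec_dir <- file.path(out_dir, "recordings")
    dir.create(rec_dir, showWarnings = FALSE)
    for (r in recs) {
      write_recording(r, file.path(rec_dir, attr(r, "subject_id")))
    }
  }

  cond_seeds <- .derive_seeds(seeds[2], length(recs))
  cond <- lapply(seq_along(recs), function(i) {
    condition_recording(recs[[i]], lowpass = config$lowpass,
                        drift_cutoff = config$drift_cutoff,
                        ica = config$ica, seed = cond_seeds[i])
  })
  note("condition", "lowpass %s Hz, drift < %s Hz, ica = %s",
       config$lowpass, config$drift_cutoff, config$ica)
  manifest$stages$condition <- list(lowpass = config$lowpass,
                                    drift_cutoff = config$drift_cutoff,
                                    ica = config$ica)
  if (isTRUE(config$save_recordings)) {
    cond_dir <- file.path(out_dir, "conditioned")
    dir.create(cond_dir, showWarnings = FALSE)
    for (r in cond) {
      write_recording(r, file.path(cond_dir, attr(r, "subject_id")))
    }
  }

  features <- build_feature_table(cond, aggregate = config$aggregate,
                                  window_s = config$window_s)
  readr::write_csv(features, file.path(out_dir, "features.csv"),
                   progress = FALSE)
  note("features", "%d rows x %d feature columns", nrow(features),
       length(feature_columns(features)))
  manifest$stages$features <- list(rows = nrow(features),
                                   columns = length(feature_columns(features)))

  split <- balanced_split(features, ratio = config$ratio, seed = seeds[3])
  scaling <- feature_scaling(features[split$train, ])
  normalized <- normalize_features(features, scaling)
  readr::write_csv(normalized, file.path(out_dir, "features_normalized.csv"),
                   progress = FALSE)

  embedding <- NULL
  if (config$embed_method != "none") {
    embedding <- if (config$embed_method == "pca") {
      model <- pca_fit(normalized, k = config$embed_dims)
      pca_project(model, normalized)
    } else {
      tidy(tsne_embed(normalized, dims = config$embed_dims,
                      perplexity = min(config$perplexity,
                                       floor((nrow(normalized) - 1) / 3)),
                      seed = seeds[4]))
    }
    readr::write_csv(embedding, file.path(out_dir, "coords.csv"),
                     progress = FALSE)
    note("embed", "%s -> %dD", config$embed_method, config$embed_dims)
  }
  manifest$stages$embed <- list(method = config$embed_method)

  suite <- train_suite(normalized[split$train, ], models = config$models,
                       seed = seeds[3])
  report <- evaluate_suite(suite, normalized[split$test, ])
  write_report(report, file.path(out_dir, "report.json"))
  note("train-eval", "%d models, test accuracy (first): %.3f",
       length(suite$models), report$models[[1]]$accuracy)
  manifest$stages$classify <- list(
    n_train = length(split$train), n_test = length(split$test),
    models = suite$models, failures = suite$failures
  )

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(features = features, features_normalized = normalized,
                 split = split, suite = suite, report = report,
                 embedding = embedding, manifest = manifest))
}
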