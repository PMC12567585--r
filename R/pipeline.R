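#' Default run configuration
#'
#' Nested configuration covering every stage of the pipeline: synthetic
#' cohort spec, windowing, model (ViT / BiLSTM / fusion), training, feature
#' selection and outputs. Every tunable default of the package surfaces
#' here as a key.
#'
#' @param tiny Use the CPU-scale preset (tiny ViT on 32x32 images,
#'   learning rate 1e-3). `tiny = FALSE` configures the full-size
#'   architecture (224x224 images, 768-dim ViT).
#' @param output_dir Where [run_pipeline()] writes artifacts.
#' @return Nested `run_config` list; validate with
#'   [validate_run_config()].
#' @export
default_run_config <- function(tiny = TRUE, output_dir = tempfile("actimodal_run_")) {
  vit <- if (tiny) vit_config_tiny() else vit_config()
  structure(list(
    seed = 42L,
    output_dir = output_dir,
    input_dir = NULL,           # NULL -> simulate; else ingest CSVs from here
    write_images = FALSE,
    cohort = list(n_subjects = 50L, prevalence = 0.26,
                  minutes_per_subject = 2, rate_hz = 100, effect_size = 2,
                  snap_shift = 0.9, enmo_cap = 6, missing_rate = 0),
    windowing = list(window_sec = 10, image_size = vit$image_size,
                     frames_per_sample = 5L, channel_mode = "replicate",
                     clip_negative = FALSE),
    clinical = list(feature_cols = clinical_feature_defaults(),
                    sd_denom = "n-1", t_threshold = 55,
                    column_map = NULL),
    model = list(vit = unclass(vit),
                 lstm = list(hidden = if (tiny) 32L else 128L, layers = 2L),
                 fusion = list(kind = "cross_attention",
                               d_k = if (tiny) 32L else 128L, heads = 4L,
                               dropout = 0.5, single_token = FALSE)),
    train = list(epochs = 20L, learning_rate = if (tiny) 1e-3 else 1e-4,
                 batch_size = 8L, weight_decay = 1e-5, dropout = 0.5,
                 focal_gamma = 2, class_weight_mode = "inverse"),
    split = list(fractions = c(0.55, 0.15, 0.30))
  ), class = "run_config")
}

#' Validate a run configuration against the schema
#'
#' Recursively checks `cfg` against the key structure of
#' [default_run_config()]: unknown keys anywhere in the nesting are
#' rejected, which catches typos before any computation starts.
#'
#' @param cfg A run configuration list.
#' @return `cfg`, invisibly, with class `run_config`; errors on unknown
#'   keys.
#' @export
validate_run_config <- function(cfg) {
  schema <- unclass(default_run_config())
  check <- function(node, ref, path) {
    unknown <- setdiff(names(node), names(ref))
    if (length(unknown))
      stop(sprintf("unknown config key(s) at %s: %s", path,
                   paste(unknown, collapse = ", ")))
    for (nm in names(node)) {
      if (is.list(ref[[nm]]) && !is.null(names(ref[[nm]])) &&
          !is.null(node[[nm]])) {
        if (!is.list(node[[nm]]))
          stop(sprintf("config key %s/%s must be a section", path, nm))
        check(node[[nm]], ref[[nm]], paste0(path, "/", nm))
      }
    }
  }
  check(unclass(cfg), schema, "")
  structure(utils::modifyList(schema, unclass(cfg)), class = "run_config")
}

#' Run the full pipeline
#'
#' Executes simulate (or ingest) -> encode -> clinical preprocessing ->
#' split -> train -> evaluate, writing a run manifest that snapshots the
#' configuration, seed, stage timings, input hashes and artifact paths.
#' Re-running with the same configuration and seed reproduces the metrics
#' exactly. If a stage fails, the manifest records the failed stage and
#' already-produced artifacts stay on disk for inspection.
#'
#' @param cfg A run configuration ([default_run_config()]); validated
#'   before anything runs.
#' @return The run manifest (list), invisibly; also written as
#'   `manifest.json` in the output directory.
#' @export
run_pipeline <- function(cfg = default_run_config()) {
  cfg <- validate_run_config(cfg)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = unclass(cfg), seed = cfg$seed,
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   r_version = as.character(getRversion()),
                   package_version = as.character(utils::packageVersion("actimodal")),
                   stages = list(), artifacts = list(), input_hashes = list(),
                   status = "running")
  write_manifest <- function() {
    tmp <- file.path(cfg$output_dir, ".manifest.json.tmp")
    jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
    file.rename(tmp, file.path(cfg$output_dir, "manifest.json"))
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) e)
    manifest$stages[[name]] <<- list(
      seconds = round(proc.time()[["elapsed"]] - t0, 3),
      ok = !inherits(res, "error"))
    if (inherits(res, "error")) {
      manifest$status <<- paste0("failed:", name)
      write_manifest()
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(res)))
    }
    res
  }

  cohort <- stage("ingest", {
    if (is.null(cfg$input_dir)) {
      generate_cohort(cohort_spec(
        n_subjects = cfg$cohort$n_subjects, prevalence = cfg$cohort$prevalence,
        minutes_per_subject = cfg$cohort$minutes_per_subject,
        rate_hz = cfg$cohort$rate_hz, effect_size = cfg$cohort$effect_size,
        snap_shift = cfg$cohort$snap_shift, seed = cfg$seed,
        enmo_cap = cfg$cohort$enmo_cap,
        missing_rate = cfg$cohort$missing_rate))
    } else {
      read_cohort_dir(cfg$input_dir, cfg$cohort$rate_hz,
                      cfg$clinical$column_map)
    }
  })
  if (!is.null(cfg$input_dir)) {
    files <- list.files(cfg$input_dir, full.names = TRUE)
    manifest$input_hashes <- as.list(tools::md5sum(files))
  }

  wcfg <- window_config(cfg$windowing$window_sec, cfg$windowing$image_size,
                        cfg$windowing$frames_per_sample,
                        cfg$windowing$channel_mode,
                        cfg$windowing$clip_negative)
  sequences <- stage("encode", encode_cohort(cohort, wcfg))
  if (isTRUE(cfg$write_images)) {
    img_dir <- file.path(cfg$output_dir, "images")
    stage("export_images", write_image_sequences(sequences, img_dir))
    manifest$artifacts$images <- img_dir
  }

  prep <- stage("prep_clinical", {
    table <- build_cohort_table(cohort$clinical,
                                sd_denom = cfg$clinical$sd_denom,
                                threshold = cfg$clinical$t_threshold)
    split <- subject_split(table$subject_id, table$label,
                           cfg$split$fractions, seed = cfg$seed)
    std <- standardise_features(table, split$train,
                                cfg$clinical$feature_cols)
    list(table = table, split = split, std = std)
  })

  fitted <- stage("train", {
    mcfg <- model_config(
      vit = do.call(vit_config, cfg$model$vit),
      lstm = bilstm_config(cfg$model$vit$embed_dim, cfg$model$lstm$hidden,
                           cfg$model$lstm$layers),
      fusion = do.call(fusion_config, cfg$model$fusion),
      d_tab = ncol(prep$std$features),
      n_frames = cfg$windowing$frames_per_sample)
    labels <- stats::setNames(prep$table$label, prep$table$subject_id)
    mk <- function(set)
      build_samples(Filter(function(s) s$subject_id %in% set, sequences),
                    prep$std$features, labels, mcfg$vit)
    tcfg <- train_config(cfg$train$epochs, cfg$train$learning_rate,
                         cfg$train$batch_size, cfg$train$weight_decay,
                         cfg$train$dropout, cfg$seed, cfg$train$focal_gamma,
                         cfg$train$class_weight_mode)
    model <- build_model(mcfg, seed = cfg$seed)
    list(model = train_model(model, mk(prep$split$train),
                             mk(prep$split$val), tcfg),
         mk = mk)
  })

  ev <- stage("evaluate", evaluate_model(fitted$model, fitted$mk(prep$split$test)))
  metrics_path <- file.path(cfg$output_dir, "metrics.json")
  write_metrics_json(ev, metrics_path)
  roc <- roc_points(ev$subject_predictions$p_pos, ev$subject_predictions$label)
  roc_path <- file.path(cfg$output_dir, "roc_subject.csv")
  utils::write.csv(roc, roc_path, row.names = FALSE)
  manifest$artifacts$metrics <- metrics_path
  manifest$artifacts$roc <- roc_path
  manifest$metrics <- list(sequence = ev$sequence, subject = ev$subject)
  manifest$status <- "ok"
  write_manifest()
  invisible(manifest)
}

# Ingest a directory produced by write_cohort_csv() (or equivalent):
# <id>_accel.csv per subject + clinical.csv.
read_cohort_dir <- function(dir, rate_hz = 100, column_map = NULL) {
  clin_path <- file.path(dir, "clinical.csv")
  if (!file.exists(clin_path)) stop("clinical.csv not found in ", dir)
  clinical <- read_clinical_csv(clin_path)
  cmap <- if (is.null(column_map))
    c(time = "timestamp", x = "x", y = "y", z = "z") else unlist(column_map)
  subjects <- lapply(clinical$subject_id, function(id) {
    p <- file.path(dir, paste0(id, "_accel.csv"))
    if (!file.exists(p)) stop("missing accelerometer file for subject ", id)
    list(subject_id = id,
         series = read_accelerometer_csv(p, cmap, rate_hz))
  })
  list(subjects = subjects, clinical = clinical)
}
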