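# Config-driven end-to-end orchestration with file handoff between stages,
# plus packaged fixture studies used by the tests and examples.

#' Default pipeline configuration
#'
#' @param ... Named overrides of the defaults (unknown names are an
#'   error). `study` entries are passed to [make_study()]; `preprocess`
#'   to [study_observations()]; `fit` to [venose()].
#' @return A validated config list of class `"venose_config"`.
#' @export
venose_config <- function(...) {
  cfg <- list(
    seed = 1,
    study = list(
      gases = c("CH2O", "CH2O2", "CH3COOH"),
      concentrations = seq(250, 3000, length.out = 7),
      repetitions = 1,
      n_sa = 7,
      baseline_cycles = 10,
      exposure_cycles = 12,
      recovery_cycles = 4
    ),
    preprocess = list(discard = 2, smooth = TRUE,
                      window_length = 11, polyorder = 3),
    fit = list(k = 8, kernel = "quadratic", folds = 10)
  )
  over <- list(...)
  for (nm in names(over)) {
    if (!nm %in% names(cfg)) stop("unknown config entry: ", nm)
    if (is.list(cfg[[nm]])) {
      sub <- over[[nm]]
      bad <- setdiff(names(sub), names(cfg[[nm]]))
      if (length(bad)) stop("unknown config entry: ", nm, "$", bad[1])
      cfg[[nm]][names(sub)] <- sub
    } else {
      cfg[[nm]] <- over[[nm]]
    }
  }
  validate_config(cfg)
  structure(cfg, class = "venose_config")
}

validate_config <- function(cfg) {
  s <- cfg$study
  if (length(s$gases) == 0) stop("config invalid: empty gas list")
  if (s$repetitions < 1) stop("config invalid: repetitions must be >= 1")
  if (any(s$concentrations <= 0)) {
    stop("config invalid: concentrations must be positive")
  }
  if (cfg$preprocess$discard < 0 ||
      cfg$preprocess$discard >= s$exposure_cycles) {
    stop("config invalid: discard leaves no exposure cycles")
  }
  invisible(cfg)
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys follow [venose_config()].
#' @return A `venose_config`.
#' @export
read_config <- function(path) {
  do.call(venose_config, yaml::read_yaml(path))
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(cfg), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Run the full virtual e-nose pipeline
#'
#' Orchestrates simulate -> preprocess -> features -> select/classify/
#' quantify, writing every artifact (trace CSVs, cycle matrix + metadata,
#' feature table, selection JSON, classification and quantification
#' reports, LDA scores, a provenance manifest and a Markdown summary)
#' under `out_dir`. Later stages read the CSV artifacts written by earlier
#' ones, so stages can be re-run individually.
#'
#' @param config A [venose_config()] (or path to a YAML file).
#' @param out_dir Output directory (created; must be writable).
#' @param stages Subset of
#'   `c("simulate", "preprocess", "features", "model")` to run; `"model"`
#'   covers selection, classification and quantification. Defaults to all.
#' @param quiet Suppress per-stage progress messages.
#' @return Invisibly, a list with the `venose` fit (when the model stage
#'   ran) and the paths written.
#' @export
run_pipeline <- function(config = venose_config(), out_dir,
                         stages = c("simulate", "preprocess", "features",
                                    "model"),
                         quiet = FALSE) {
  if (is.character(config)) config <- read_config(config)
  validate_config(config)
  stages <- match.arg(stages, several.ok = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- proc.time()[3]
  hash <- config_hash(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  program <- temperature_program()
  fit <- NULL

  if ("simulate" %in% stages) {
    study <- do.call(make_study, c(config$study, list(seed = config$seed)))
    trace_dir <- file.path(out_dir, "traces")
    dir.create(trace_dir, showWarnings = FALSE)
    for (i in seq_along(study$traces)) {
      write_trace_csv(study$traces[[i]],
                      file.path(trace_dir, sprintf("exposure_%03d.csv", i)))
    }
    labels <- study$labels
    write.csv(labels, file.path(out_dir, "labels.csv"), row.names = FALSE)
    paths$traces <- trace_dir
    say("simulate: %d exposures (%d samples each)",
        length(study$traces), nrow(study$traces[[1]]))
  } else {
    study <- NULL
  }

  if ("preprocess" %in% stages) {
    if (is.null(study)) study <- reload_study(out_dir, config)
    obs <- do.call(study_observations,
                   c(list(study = study), config$preprocess))
    write.csv(obs$signal, file.path(out_dir, "cycles.csv"),
              row.names = FALSE)
    write.csv(obs$meta[c("cycle_idx", "gas", "conc_ppb", "phase")],
              file.path(out_dir, "cycle_meta.csv"), row.names = FALSE)
    paths$cycles <- file.path(out_dir, "cycles.csv")
    say("preprocess: %d observation cycles", nrow(obs$signal))
  } else {
    obs <- NULL
  }

  if ("features" %in% stages) {
    if (is.null(obs)) obs <- reload_cycles(out_dir, program)
    features <- extract_features(obs)
    write.csv(as.data.frame(features), file.path(out_dir, "features.csv"),
              row.names = FALSE)
    catalog <- attr(features, "catalog")
    jsonlite::write_json(
      catalog[c("name", "family", "start", "end")],
      file.path(out_dir, "catalog.json"), auto_unbox = TRUE, digits = NA)
    paths$features <- file.path(out_dir, "features.csv")
    say("features: %d x %d feature matrix", nrow(features),
        nrow(catalog))
  } else {
    features <- NULL
  }

  if ("model" %in% stages) {
    if (is.null(features)) features <- reload_features(out_dir, program)
    fit <- do.call(venose, c(list(features = features),
                             config$fit, list(seed = config$seed)))
    write_reports(fit, out_dir)
    paths$reports <- out_dir
    say("model: gas-identity accuracy %.1f%%", fit$classification$accuracy)
  }

  manifest <- list(
    config_hash = hash, seed = config$seed,
    stages = stages, elapsed_s = round(proc.time()[3] - t0, 2),
    files = list.files(out_dir, recursive = TRUE))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(unclass(config), file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(fit = fit, paths = paths, config_hash = hash))
}

reload_study <- function(out_dir, config) {
  labels <- read.csv(file.path(out_dir, "labels.csv"),
                     stringsAsFactors = FALSE)
  files <- sprintf("exposure_%03d.csv", labels$exposure)
  traces <- lapply(file.path(out_dir, "traces", files), read_trace_csv)
  structure(list(traces = traces, labels = labels,
                 config = c(config$study,
                            list(program = temperature_program(),
                                 model = gas_response_model(),
                                 seed = config$seed))),
            class = "venose_study")
}

reload_cycles <- function(out_dir, program) {
  sig <- as.matrix(read.csv(file.path(out_dir, "cycles.csv")))
  meta <- read.csv(file.path(out_dir, "cycle_meta.csv"),
                   stringsAsFactors = FALSE)
  structure(list(signal = unname(sig), meta = meta, program = program,
                 standardized = TRUE),
            class = "cycle_set")
}

reload_features <- function(out_dir, program) {
  df <- read.csv(file.path(out_dir, "features.csv"),
                 stringsAsFactors = FALSE, check.names = FALSE)
  structure(df, class = c("venose_features", "data.frame"),
            catalog = feature_catalog(program))
}

write_reports <- function(fit, out_dir) {
  sel <- fit$selection
  jsonlite::write_json(
    list(selected = sel$selected, scores = sel$scores,
         criterion = sel$criterion, seed = sel$seed),
    file.path(out_dir, "selection.json"), auto_unbox = TRUE, digits = NA)

  cls <- fit$classification
  write.csv(as.data.frame.matrix(cls$confusion),
            file.path(out_dir, "confusion_gas.csv"))
  jsonlite::write_json(
    list(accuracy_pct = cls$accuracy,
         class_rate_pct = as.list(cls$class_rate),
         kernel = cls$kernel, folds = cls$folds),
    file.path(out_dir, "classification_gas.json"),
    auto_unbox = TRUE, digits = NA)

  write.csv(fit$lda$scores, file.path(out_dir, "lda_scores.csv"),
            row.names = FALSE)

  for (g in names(fit$quantification)) {
    q <- fit$quantification[[g]]$report
    cr <- fit$concentration[[g]]$report
    write.csv(data.frame(true_ppb = q$true, predicted_ppb = q$predicted),
              file.path(out_dir, sprintf("predicted_vs_true_%s.csv", g)),
              row.names = FALSE)
    jsonlite::write_json(
      list(gas = g, r2 = q$r2, rmse_ppb = q$rmse, ncomp = q$ncomp,
           n_train = q$n_train, n_test = q$n_test,
           concentration_accuracy_pct = cr$accuracy),
      file.path(out_dir, sprintf("quantification_%s.json", g)),
      auto_unbox = TRUE, digits = NA)
  }
  write_summary_md(fit, file.path(out_dir, "summary.md"))
}

write_summary_md <- function(fit, path) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("# Virtual e-nose run summary\n")
  w("Selected features: %s\n", paste(fit$selection$selected,
                                     collapse = ", "))
  w("## Gas identity (%d-fold CV %s SVM)\n", fit$folds, fit$kernel)
  w("Validation accuracy: %.1f%%\n", fit$classification$accuracy)
  w("Confusion matrix (counts):\n")
  cm <- as.data.frame.matrix(fit$classification$confusion)
  w("| true\\pred | %s |", paste(colnames(cm), collapse = " | "))
  w("|---|%s", paste(rep("---|", ncol(cm)), collapse = ""))
  for (r in rownames(cm)) {
    w("| %s | %s |", r, paste(cm[r, ], collapse = " | "))
  }
  w("\n## Per-gas concentration models\n")
  w("| gas | conc. accuracy (%%) | PLSR R2 | RMSE (ppb) |")
  w("|---|---|---|---|")
  for (g in names(fit$quantification)) {
    q <- fit$quantification[[g]]$report
    cr <- fit$concentration[[g]]$report
    w("| %s | %.1f | %.3f | %.0f |", g, cr$accuracy, q$r2, q$rmse)
  }
  invisible(path)
}

#' Packaged fixture studies
#'
#' Two ready-made simulated studies: `"tiny"` (2 gases x 2 levels, short
#' phases) for fast unit tests, and `"demo"`, shaped like the full study
#' design — 3 VOCs and synthetic air, 7 concentration levels from 250 to
#' 3000 ppb, 8 exposure cycles per exposure so that after discarding 2
#' settling cycles each gas contributes 42 observations (168 in total).
#'
#' @param size `"tiny"` or `"demo"`.
#' @param seed Master seed.
#' @return A `venose_study`.
#' @export
make_fixtures <- function(size = c("tiny", "demo"), seed = 1) {
  size <- match.arg(size)
  if (size == "tiny") {
    make_study(gases = c("CH2O", "CH3COOH"),
               concentrations = c(500, 2000),
               repetitions = 1, n_sa = 2,
               baseline_cycles = 3, exposure_cycles = 5,
               recovery_cycles = 1, seed = seed)
  } else {
    make_study(gases = c("CH2O", "CH2O2", "CH3COOH"),
               concentrations = seq(250, 3000, length.out = 7),
               repetitions = 1, n_sa = 7,
               baseline_cycles = 10, exposure_cycles = 8,
               recovery_cycles = 4, seed = seed)
  }
}
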