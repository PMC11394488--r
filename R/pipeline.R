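# End-to-end orchestration. A single JSON config with one section per stage
# drives simulate -> splits -> keyset -> crossval -> evaluate; every stage
# seeds its own RNG stream from the global seed, so reruns with the same
# config reproduce every output bit for bit.

default_sections <- function() {
  list(
    synthetic_data = list(n_rc = 71, n_nrc = 118, slides_per_patient = c(1, 3),
                          n_instances = c(40, 80), dim = 64, witness_rate = 0.2,
                          effect_size = 4, true_hr = 2.3, censor_horizon = 60),
    preprocess = list(sat_threshold = 8, median_radius = 2, patch_size = 896,
                      min_tissue_frac = 0.5),
    tumor_bulk = list(threshold = 0.5, closing_radius = 1, min_object_cells = 8,
                      use_convex_hull = TRUE),
    crl = list(rank_energy = 0.9, max_rank = 32, keys_per_slide = 4),
    model = list(d_hidden = 16, l_gate = 8),
    train = list(learning_rate = 8e-5, weight_decay = 1e-5, min_epochs = 5,
                 patience = 5, max_epochs = 50),
    eval = list(aggregate = "max", threshold = 0.5, horizon = 60),
    splits = list(k = 5, val_fraction = 1 / 6)
  )
}

#' Build and validate a pipeline configuration
#'
#' Nested named list with one section per stage plus a global `seed` and
#' `out_dir`. Unknown sections or keys are rejected; values are validated
#' against the module contracts (by constructing the stage configs) before
#' any stage runs.
#'
#' @param ... Section overrides, e.g.
#'   `pipeline_config(synthetic_data = list(n_rc = 20))`.
#' @param seed Global integer seed.
#' @param out_dir Run directory.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(..., seed = 1L, out_dir = tempfile("damil_run_")) {
  defaults <- default_sections()
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  assert_that(!length(unknown), "unknown config section(s): %s",
              paste(unknown, collapse = ", "))
  cfg <- defaults
  for (sec in names(overrides)) {
    bad <- setdiff(names(overrides[[sec]]), names(defaults[[sec]]))
    assert_that(!length(bad), "unknown key(s) in section %s: %s",
                sec, paste(bad, collapse = ", "))
    cfg[[sec]][names(overrides[[sec]])] <- overrides[[sec]]
  }
  cfg$seed <- as.integer(seed)
  cfg$out_dir <- out_dir
  validate_pipeline_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_pipeline_config <- function(cfg) {
  sd <- cfg$synthetic_data
  do.call(cohort_spec, c(sd, list(seed = cfg$seed)))  # constructor validates
  do.call(crl_config, cfg$crl)
  do.call(train_config, c(cfg$train, list(seed = cfg$seed)))
  damil_config(d = sd$dim, d_hidden = cfg$model$d_hidden,
               l_gate = cfg$model$l_gate, seed = cfg$seed)
  assert_that(cfg$eval$aggregate %in% c("max", "mean"),
              "eval$aggregate must be max or mean")
  invisible(cfg)
}

#' Read / write a pipeline config as JSON
#'
#' @param cfg A [pipeline_config()].
#' @param path JSON file path.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  seed <- raw$seed %||% 1L
  out_dir <- raw$out_dir %||% tempfile("damil_run_")
  raw$seed <- NULL; raw$out_dir <- NULL
  do.call(pipeline_config, c(raw, list(seed = seed, out_dir = out_dir)))
}

#' Run the full synthetic pipeline
#'
#' Executes the five stages — simulate, splits, keyset (per fold, inside
#' cross-validation), crossval, evaluate — and writes a self-describing run
#' directory: the config copy, a manifest with stage status and output
#' digests, the cohort and predictions CSVs, metrics and Cox JSON, and the
#' Kaplan-Meier table.
#'
#' @param cfg A [pipeline_config()] (or path to its JSON).
#' @param quiet Suppress progress messages.
#' @return The run directory path, invisibly; its manifest lists every stage.
#' @export
run_pipeline <- function(cfg = pipeline_config(), quiet = FALSE) {
  if (is.character(cfg)) cfg <- read_config(cfg)
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_config(cfg, file.path(cfg$out_dir, "config.json"))
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  stages <- character(0)
  run_stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      stop_damil("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
    stages <<- c(stages, name)
    say("stage %s: done", name)
    res
  }

  spec <- run_stage("simulate", {
    do.call(cohort_spec, c(cfg$synthetic_data,
                           list(seed = derive_seed(cfg$seed, 1L))))
  })
  sim <- gen_cohort(spec)
  write_cohort(sim$cohort, file.path(cfg$out_dir, "cohort.csv"))

  plan <- run_stage("splits", {
    make_splits(sim$cohort, k = cfg$splits$k,
                val_fraction = cfg$splits$val_fraction,
                seed = derive_seed(cfg$seed, 2L))
  })

  crl <- run_stage("keyset", do.call(crl_config, cfg$crl))

  cv <- run_stage("crossval", {
    run_crossval(
      sim$bags, sim$cohort, plan = plan, crl = crl,
      model_config = damil_config(d = spec$dim, d_hidden = cfg$model$d_hidden,
                                  l_gate = cfg$model$l_gate,
                                  seed = derive_seed(cfg$seed, 3L)),
      tc = do.call(train_config,
                   c(cfg$train, list(seed = derive_seed(cfg$seed, 4L))))
    )
  })
  utils::write.csv(cv$predictions, file.path(cfg$out_dir, "predictions.csv"),
                   row.names = FALSE)

  report <- run_stage("evaluate", {
    evaluate_predictions(cv$predictions, sim$cohort,
                         aggregate = cfg$eval$aggregate,
                         threshold = cfg$eval$threshold,
                         horizon = cfg$eval$horizon)
  })
  jsonlite::write_json(cv$metrics, file.path(cfg$out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(unclass(report$cox), file.path(cfg$out_dir, "cox.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(report$km, file.path(cfg$out_dir, "km.csv"),
                   row.names = FALSE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("damil")),
    seed = cfg$seed,
    stages = lapply(stages, function(s) list(name = s, status = "completed")),
    digests = list(
      cohort = unname(tools::md5sum(file.path(cfg$out_dir, "cohort.csv"))),
      predictions = unname(tools::md5sum(file.path(cfg$out_dir, "predictions.csv")))
    )
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(cfg$out_dir)
}

#' Evaluate pooled predictions: metrics, Cox stratification, KM table
#'
#' @param predictions Slide-level predictions (from [run_crossval()]).
#' @param cohort The cohort table.
#' @param aggregate Patient aggregation rule, `"max"` or `"mean"`.
#' @param threshold Risk-group threshold.
#' @param horizon Censoring horizon in months.
#' @return List with `slide_metrics`, `patient` (per-patient groups), `cox`
#'   (a `cox_result`), and `km` (product-limit table).
#' @export
evaluate_predictions <- function(predictions, cohort, aggregate = "max",
                                 threshold = 0.5, horizon = 60) {
  slide_metrics <- classification_metrics(predictions$p_rc, predictions$label,
                                          threshold)
  patient <- aggregate_patient(predictions, method = aggregate,
                               threshold = threshold)
  records <- survival_records(patient, cohort)
  cox <- if (length(unique(records$group)) == 2L) {
    cox_univariate(records, horizon = horizon)
  } else {
    structure(list(beta = NA_real_, hr = NA_real_, se = NA_real_,
                   ci_low = NA_real_, ci_high = NA_real_, p = NA_real_,
                   n = nrow(records), n_events = sum(records$event),
                   converged = FALSE, flag = "degenerate_grouping"),
              class = "cox_result")
  }
  km <- km_table(records, horizon = horizon)
  list(slide_metrics = slide_metrics, patient = patient, cox = cox, km = km)
}
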