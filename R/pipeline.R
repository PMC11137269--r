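# End-to-end orchestration: generate/load -> filter -> per-wave clustering
# -> profiles -> trajectories -> associations, with deterministic seed
# fan-out and a run manifest.

#' Validate a pipeline run configuration
#'
#' A run configuration is a plain list (or a YAML/JSON file) with:
#' \describe{
#'   \item{seed}{master seed; every stochastic stage receives a substream
#'     seed derived deterministically from it.}
#'   \item{out_dir}{output directory.}
#'   \item{generator}{list of [cohort_config()] arguments, \emph{or}}
#'   \item{input}{list with `patients`, `diagnoses`, `dispensations` CSV
#'     paths.}
#'   \item{prevalence_threshold}{default 0.01.}
#'   \item{k / k_candidates}{fixed pattern count, or candidates (default 2:6).}
#'   \item{n_init, max_iter, tol, ch_tolerance, essential_params}{clustering
#'     defaults, see [fit_patterns()].}
#'   \item{acute_labels}{acute conditions to model; default the 3 most
#'     common.}
#'   \item{render_figures}{default `TRUE`.}
#' }
#'
#' @param config list or path to a YAML/JSON file.
#' @return the normalised configuration list.
#' @export
validate_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  if (!is.list(config)) stop_field("config", "must be a list or a file path")
  for (f in c("seed", "out_dir")) {
    if (is.null(config[[f]])) stop_field(f, "is required")
  }
  if (!is.numeric(config$seed) || length(config$seed) != 1L) {
    stop_field("seed", "must be a single integer")
  }
  if (is.null(config$generator) && is.null(config$input)) {
    stop_field("generator/input", "exactly one input source is required")
  }
  if (!is.null(config$input)) {
    for (f in c("patients", "diagnoses", "dispensations")) {
      if (is.null(config$input[[f]])) stop_field(paste0("input$", f), "is required")
    }
  }
  config$prevalence_threshold <- config$prevalence_threshold %||% 0.01
  config$k_candidates <- config$k_candidates %||% 2:6
  config$n_init <- config$n_init %||% 10L
  config$max_iter <- config$max_iter %||% 100L
  config$tol <- config$tol %||% 1e-6
  config$ch_tolerance <- config$ch_tolerance %||% 0.10
  config$essential_params <- config$essential_params %||% list()
  config$render_figures <- config$render_figures %||% TRUE
  if (config$prevalence_threshold < 0 || config$prevalence_threshold > 1) {
    stop_field("prevalence_threshold", "must lie in [0, 1]")
  }
  config
}

#' Run the full multimorbidity-pattern pipeline
#'
#' Executes every stage on one cohort: generate (or load) the records,
#' restrict to the multimorbid closed cohort, build the three wave
#' datasets, fit patterns per wave, profile them, link trajectories, fit
#' the mortality and acute-disease association models, and write all
#' artifacts (`labels.csv`, `kselection.json`, `patterns.json`, per-wave
#' profile CSVs, `flows.csv`, an alluvial figure, `associations.json`) plus
#' a `manifest.json` recording versions, seeds, input hashes and stage
#' timings. Re-running with an identical configuration reproduces identical
#' outputs.
#'
#' @param config a run configuration (list or YAML/JSON path), see
#'   [validate_run_config()].
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  config <- validate_run_config(config)
  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    timings[[stage]] <<- round(t1 - t0, 3)
    t0 <<- t1
  }
  seeds <- list(generator = derive_seed(config$seed, 1L),
                clustering = derive_seed(config$seed, 2L))

  input_hashes <- NULL
  if (!is.null(config$generator)) {
    gen_args <- config$generator
    gen_args$seed <- seeds$generator
    cohort <- simulate_cohort(do.call(cohort_config, gen_args))
  } else {
    cohort <- read_cohort(config$input$patients, config$input$diagnoses,
                          config$input$dispensations)
    input_hashes <- as.list(tools::md5sum(unlist(config$input)))
  }
  tick("input")

  cohort <- multimorbidity_filter(cohort)
  baseline_n <- nrow(cohort$patients)
  tick("filter")

  fits <- list()
  for (w in 1:3) {
    wv <- build_wave(cohort, w, config$prevalence_threshold)
    fits[[w]] <- fit_patterns(
      wv, cohort = cohort, k = config[["k"]],
      k_candidates = config$k_candidates,
      seed = derive_seed(seeds$clustering, w),
      n_init = config$n_init, max_iter = config$max_iter, tol = config$tol,
      essential_params = config$essential_params,
      ch_tolerance = config$ch_tolerance)
  }
  tick("clustering")

  labels_df <- do.call(rbind, lapply(fits, function(f) {
    data.frame(patient_id = f$included_ids, wave = f$wave_label,
               pattern_index = f$labels, stringsAsFactors = FALSE)
  }))
  utils::write.csv(labels_df, file.path(out, "labels.csv"), row.names = FALSE)

  ksel <- lapply(fits, function(f) {
    if (is.null(f$kselection)) {
      list(wave = f$wave_label, chosen_k = f$k, fixed = TRUE)
    } else {
      list(wave = f$wave_label, chosen_k = f$kselection$chosen_k,
           rationale = f$kselection$rationale,
           candidates = f$kselection$table)
    }
  })
  jsonlite::write_json(ksel, file.path(out, "kselection.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  for (f in fits) {
    prof <- f$profiles
    utils::write.csv(as.data.frame(prof),
                     file.path(out, sprintf("profiles_%s.csv", f$wave_label)),
                     row.names = FALSE)
  }
  patterns_json <- lapply(fits, function(f) {
    list(wave = f$wave_label, k = f$k,
         profiles = as.data.frame(f$profiles),
         conditions = attr(f$profiles, "conditions"))
  })
  jsonlite::write_json(patterns_json, file.path(out, "patterns.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  tick("profiles")

  traj <- link_waves(cohort, fits)
  export_alluvial(traj, out, render = config$render_figures)
  tick("trajectories")

  assoc <- list()
  assoc$mortality_8y <- fit_mortality_model(cohort, fits[[1]], horizon_wave = 3L)
  assoc$mortality_4y <- fit_mortality_model(cohort, fits[[1]], horizon_wave = 2L)
  assoc$mortality_4y_from_wave2 <- fit_mortality_model(cohort, fits[[2]],
                                                       horizon_wave = 3L)
  acute_labels <- config$acute_labels
  if (is.null(acute_labels)) {
    ac <- cohort$diagnoses[cohort$diagnoses$kind == "acute", , drop = FALSE]
    acute_labels <- names(sort(table(ac$condition_label), decreasing = TRUE))
    acute_labels <- utils::head(acute_labels, 3L)
  }
  for (lab in acute_labels) {
    for (w in 2:3) {
      nm <- sprintf("acute_%s_wave_%s", lab, fits[[w]]$wave_label)
      assoc[[nm]] <- tryCatch(fit_acute_model(cohort, fits[[w]], lab),
                              error = function(e) list(error = conditionMessage(e)))
    }
  }
  assoc_json <- lapply(assoc, function(a) {
    if (inherits(a, "mm_assoc")) {
      list(outcome = a$outcome, reference = a$reference,
           reference_how = a$reference_how, n = a$n, table = a$table)
    } else a
  })
  jsonlite::write_json(assoc_json, file.path(out, "associations.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  tick("associations")

  artifacts <- list.files(out, full.names = TRUE)
  artifacts <- artifacts[basename(artifacts) != "manifest.json"]
  manifest <- list(
    package = "mmpatterns",
    version = as.character(utils::packageVersion("mmpatterns")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    master_seed = config$seed,
    stage_seeds = seeds,
    baseline_n = baseline_n,
    accounting = {
      st2 <- wave_status(cohort, 2L); st3 <- wave_status(cohort, 3L)
      cohort_accounting(baseline_n,
                        deaths = c(sum(st2 == "dead"), sum(st3 == "dead") - sum(st2 == "dead")),
                        lost = c(sum(st2 == "lost"), sum(st3 == "lost") - sum(st2 == "lost")))
    },
    chosen_k = vapply(fits, function(f) f$k, integer(1)),
    input_hashes = input_hashes,
    output_hashes = as.list(tools::md5sum(artifacts)),
    timings_s = as.list(timings)
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
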