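#' Write a simulated cohort to plain-text files
#'
#' One directory per cohort: `subjects.csv`, a `manifest.yaml` recording the
#' simulation config, protocol and seed, and one subdirectory per subject
#' with `counts_<site>.csv` (`sample_index,x,y,z`), `hr.csv`
#' (`second,bpm`) and `ee.csv` (`window_index,kcal`).
#'
#' @param cohort A `tabata_cohort`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "tabata_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(cohort$subjects, file.path(dir, "subjects.csv"))
  cfg <- cohort$config
  manifest <- list(
    seed = cohort$seed,
    n_subjects = nrow(cohort$subjects),
    protocol = unclass(cfg$protocol),
    config = lapply(unclass(cfg)[setdiff(names(cfg), "protocol")], function(v) {
      if (is.numeric(v) && !is.null(names(v))) as.list(v) else v
    })
  )
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  for (id in names(cohort$sessions)) {
    s <- cohort$sessions[[id]]
    sdir <- file.path(dir, id)
    dir.create(sdir, showWarnings = FALSE)
    for (site in names(s$counts)) {
      readr::write_csv(s$counts[[site]],
                       file.path(sdir, paste0("counts_", site, ".csv")))
    }
    readr::write_csv(s$hr, file.path(sdir, "hr.csv"))
    readr::write_csv(s$ee, file.path(sdir, "ee.csv"))
  }
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Cohort directory.
#' @return A `tabata_cohort`.
#' @export
read_cohort <- function(dir) {
  manifest <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  pr <- manifest$protocol
  protocol <- tabata_protocol(pr$n_stages, pr$exercise_s, pr$interval_s,
                              pr$window_s)
  cfg_raw <- manifest$config
  cfg_args <- lapply(cfg_raw, function(v) {
    if (is.list(v)) unlist(v) else v
  })
  cfg_args$protocol <- protocol
  config <- do.call(sim_config, cfg_args[names(cfg_args) %in%
                                           names(formals(sim_config))])
  subjects <- readr::read_csv(file.path(dir, "subjects.csv"),
                              show_col_types = FALSE)
  sessions <- lapply(subjects$subject_id, function(id) {
    sdir <- file.path(dir, id)
    counts_files <- list.files(sdir, pattern = "^counts_.*\\.csv$")
    sites <- sub("^counts_(.*)\\.csv$", "\\1", counts_files)
    counts <- lapply(counts_files, function(f) {
      readr::read_csv(file.path(sdir, f), show_col_types = FALSE)
    })
    names(counts) <- sites
    # keep the configured site order
    counts <- counts[intersect(names(config$site_scale), sites)]
    structure(
      list(
        subject = subjects[subjects$subject_id == id, ],
        protocol = protocol,
        sampling_rate = config$sampling_rate,
        counts = counts,
        hr = readr::read_csv(file.path(sdir, "hr.csv"),
                             show_col_types = FALSE),
        ee = readr::read_csv(file.path(sdir, "ee.csv"),
                             show_col_types = FALSE)
      ),
      class = "tabata_session"
    )
  })
  names(sessions) <- subjects$subject_id
  sessions <- lapply(sessions, function(s) {
    s$ee <- tibble(window_index = s$ee$window_index, kcal = s$ee$kcal)
    s
  })
  structure(
    list(subjects = subjects, sessions = sessions, config = config,
         seed = manifest$seed),
    class = "tabata_cohort"
  )
}

#' Write a features table as CSV
#'
#' @param features A [window_features()] / [cohort_features()] tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  readr::write_csv(features, path)
  invisible(path)
}

#' Read a features table written by [write_features()]
#'
#' @param path CSV file.
#' @return Tibble.
#' @export
read_features <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Serialise a fitted model to JSON
#'
#' Works for both `ee_lm` (coefficients, p-values, r-squared) and `ee_bpnn`
#' (layer sizes, weights, scaling, training config, seed). Numeric values
#' are written at full precision so the network round-trips bit-exactly.
#'
#' @param model An `ee_lm` or `ee_bpnn`.
#' @param path Output JSON file.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  if (inherits(model, "ee_lm")) {
    payload <- list(
      type = "ee_lm", period = model$period, source = model$source,
      intercept = model$intercept,
      terms = model$terms, r_squared = model$r_squared,
      intercept_only = model$intercept_only
    )
  } else if (inherits(model, "ee_bpnn")) {
    payload <- list(
      type = "ee_bpnn", period = model$period %||% NULL,
      n_input = model$n_input, n_hidden = model$n_hidden,
      n_output = model$n_output, seed = model$seed,
      w1 = model$w1, w2 = model$w2,
      scaling = model$scaling,
      config = if (!is.null(model$config)) unclass(model$config) else NULL,
      history = model$history
    )
  } else stop("unsupported model class", call. = FALSE)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a model written by [write_model()]
#'
#' @param path JSON file.
#' @return An `ee_lm` or `ee_bpnn`.
#' @export
read_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(p$type, "ee_lm")) {
    terms <- as_tibble(p$terms)
    if (!"p_value" %in% names(terms)) terms$p_value <- NA_real_  # all-NA column
    structure(
      list(period = p$period, intercept = p$intercept,
           terms = terms, r_squared = p$r_squared,
           fit = NULL, intercept_only = isTRUE(p$intercept_only),
           source = p$source),
      class = "ee_lm"
    )
  } else if (identical(p$type, "ee_bpnn")) {
    m <- structure(
      list(n_input = p$n_input, n_hidden = p$n_hidden,
           n_output = p$n_output,
           w1 = matrix(p$w1, nrow = p$n_hidden),
           w2 = matrix(p$w2, nrow = p$n_output),
           scaling = if (is.null(p$scaling)) NULL else list(
             features = p$scaling$features,
             x_min = unlist(p$scaling$x_min),
             x_max = unlist(p$scaling$x_max),
             t_min = p$scaling$t_min, t_max = p$scaling$t_max
           ),
           seed = p$seed,
           history = as.numeric(p$history %||% numeric(0))),
      class = "ee_bpnn"
    )
    if (!is.null(p$config)) m$config <- do.call(train_config, p$config)
    if (!is.null(p$period)) m$period <- p$period
    m
  } else stop("unrecognised model file", call. = FALSE)
}

#' Write a validation report to JSON
#'
#' @param report An `ee_validation_report`.
#' @param path Output JSON file.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "ee_validation_report"))
  payload <- list(
    type = "ee_validation_report",
    n_test_subjects = report$n_test_subjects,
    convention = report$convention,
    overall = report$overall,
    by_period = report$by_period,
    by_stage = report$by_stage,
    n_above = report$n_above,
    bland_altman = as.data.frame(report$bland_altman),
    predictions = report$predictions
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' Read a report written by [write_report()]
#'
#' @param path JSON file.
#' @return An `ee_validation_report`.
#' @export
read_report <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$type, "ee_validation_report")) {
    stop("not a validation-report file", call. = FALSE)
  }
  structure(
    list(
      predictions = as_tibble(p$predictions),
      overall = as_tibble(p$overall),
      by_period = as_tibble(p$by_period),
      by_stage = as_tibble(p$by_stage),
      n_above = as_tibble(p$n_above),
      bland_altman = as_tibble(p$bland_altman),
      n_test_subjects = p$n_test_subjects,
      convention = p$convention
    ),
    class = "ee_validation_report"
  )
}

#' Export the predicted-vs-measured series as CSV
#'
#' @param report An `ee_validation_report`.
#' @param path Output CSV file.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(report, path) {
  stopifnot(inherits(report, "ee_validation_report"))
  readr::write_csv(report$predictions, path)
  invisible(path)
}

#' Write a pipeline configuration to YAML
#'
#' @param config A [pipeline_config()].
#' @param path Output YAML file.
#' @return `path`, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  sim <- unclass(config$sim)
  payload <- list(
    protocol = unclass(sim$protocol),
    sim = lapply(sim[setdiff(names(sim), "protocol")], function(v) {
      if (is.numeric(v) && !is.null(names(v))) as.list(v) else v
    }),
    train = unclass(config$train),
    pipeline = list(
      n_subjects = config$n_subjects, ratio_train = config$ratio_train,
      n_test = config$n_test, p_enter = config$p_enter,
      p_remove = config$p_remove,
      n_hidden_exercise = config$n_hidden_exercise,
      n_hidden_interval = config$n_hidden_interval,
      hidden_search = config$hidden_search,
      convention = config$convention, seed = config$seed
    )
  )
  yaml::write_yaml(payload, path, precision = 15)
  invisible(path)
}

#' Read a pipeline configuration written by [write_pipeline_config()]
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  p <- yaml::read_yaml(path)
  pr <- p$protocol
  protocol <- tabata_protocol(pr$n_stages, pr$exercise_s, pr$interval_s,
                              pr$window_s)
  sim_args <- lapply(p$sim, function(v) if (is.list(v)) unlist(v) else v)
  sim_args$protocol <- protocol
  sim <- do.call(sim_config,
                 sim_args[names(sim_args) %in% names(formals(sim_config))])
  train <- do.call(train_config,
                   p$train[names(p$train) %in% names(formals(train_config))])
  pl <- p$pipeline
  pipeline_config(
    sim = sim, n_subjects = pl$n_subjects, ratio_train = pl$ratio_train,
    n_test = pl$n_test, p_enter = pl$p_enter, p_remove = pl$p_remove,
    train = train, n_hidden_exercise = pl$n_hidden_exercise,
    n_hidden_interval = pl$n_hidden_interval,
    hidden_search = isTRUE(pl$hidden_search), convention = pl$convention,
    seed = pl$seed
  )
}
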