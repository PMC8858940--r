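#' End-to-end pipeline configuration
#'
#' Bundles every stage option: the simulation config, cohort size, split,
#' stepwise thresholds, network training settings and hidden-node choices,
#' and the MAPE convention. A single global seed deterministically derives
#' the per-stage seeds, so one integer reproduces the whole run.
#'
#' @param sim A [sim_config()].
#' @param n_subjects Cohort size.
#' @param ratio_train Training proportion for the subject split.
#' @param n_test Optional explicit validation-group size overriding the
#'   ratio.
#' @param p_enter,p_remove Stepwise thresholds.
#' @param train A [train_config()].
#' @param n_hidden_exercise,n_hidden_interval Hidden-node counts of the two
#'   networks (the published architectures use 6 and 10).
#' @param hidden_search If `TRUE`, pick each count by
#'   [hidden_node_search()] over [heuristic_hidden_range()] instead.
#' @param convention MAPE denominator convention.
#' @param seed Global seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(), n_subjects = 45,
                            ratio_train = 0.75, n_test = NULL,
                            p_enter = 0.05, p_remove = 0.10,
                            train = train_config(),
                            n_hidden_exercise = 6, n_hidden_interval = 10,
                            hidden_search = FALSE,
                            convention = "measured", seed = 1) {
  stopifnot(inherits(sim, "sim_config"), inherits(train, "bpnn_train_config"))
  structure(
    list(sim = sim, n_subjects = n_subjects, ratio_train = ratio_train,
         n_test = n_test, p_enter = p_enter, p_remove = p_remove,
         train = train, n_hidden_exercise = n_hidden_exercise,
         n_hidden_interval = n_hidden_interval,
         hidden_search = hidden_search, convention = convention,
         seed = seed),
    class = "pipeline_config"
  )
}

#' Run the full modelling pipeline on a synthetic cohort
#'
#' Simulate -> window features -> correlation screen -> stepwise linear
#' regression and backpropagation network per period -> evaluation on the
#' held-out subjects. Fully reproducible from `(config, config$seed)`.
#'
#' @param config A [pipeline_config()].
#' @return List of class `ee_pipeline_result`: `cohort`, `split`,
#'   `correlation` (both periods), `models` (`lr_exercise`, `lr_interval`,
#'   `nn_exercise`, `nn_interval`), optional `node_search`, and `report`
#'   (an `ee_validation_report`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  seeds <- withr::with_seed(config$seed,
                            sample.int(.Machine$integer.max - 1L, 5))
  cohort <- simulate_cohort(config$sim, config$n_subjects, seed = seeds[1])
  split <- split_subjects(cohort$subjects$subject_id,
                          ratio_train = config$ratio_train,
                          seed = seeds[2], n_test = config$n_test)

  train_cohort <- cohort
  train_cohort$sessions <- cohort$sessions[split$train]
  train_cohort$subjects <-
    cohort$subjects[cohort$subjects$subject_id %in% split$train, ]

  cand_ex <- candidate_table_exercise(train_cohort)
  cand_in <- candidate_table_interval(train_cohort)
  correlation <- dplyr::bind_rows(
    ee_correlation(cand_ex, period = "exercise"),
    ee_correlation(cand_in, period = "interval")
  )

  lr_ex <- stepwise_fit(cand_ex, period = "exercise",
                        p_enter = config$p_enter, p_remove = config$p_remove)
  lr_in <- stepwise_fit(cand_in, period = "interval",
                        p_enter = config$p_enter, p_remove = config$p_remove)

  feats <- cohort_features(train_cohort, sites = config$sim$ee_site)
  f_ex <- feats[feats$period == "exercise", ]
  f_in <- feats[feats$period == "interval", ]

  node_search <- NULL
  h_ex <- config$n_hidden_exercise
  h_in <- config$n_hidden_interval
  if (isTRUE(config$hidden_search)) {
    cands <- heuristic_hidden_range(length(bpnn_feature_names()), 1)
    cfg_ex <- config$train; cfg_ex$seed <- seeds[3]
    cfg_in <- config$train; cfg_in$seed <- seeds[4]
    search_ex <- hidden_node_search(f_ex, candidates = cands, config = cfg_ex)
    search_in <- hidden_node_search(f_in, candidates = cands, config = cfg_in)
    h_ex <- search_ex$best
    h_in <- search_in$best
    node_search <- list(exercise = search_ex, interval = search_in)
  }
  cfg_ex <- config$train; cfg_ex$seed <- seeds[3]
  cfg_in <- config$train; cfg_in$seed <- seeds[4]
  nn_ex <- fit_bpnn(f_ex, n_hidden = h_ex, config = cfg_ex)
  nn_ex$period <- "exercise"
  nn_in <- fit_bpnn(f_in, n_hidden = h_in, config = cfg_in)
  nn_in$period <- "interval"

  report <- evaluate_models(cohort, split$test, lr_ex, lr_in, nn_ex, nn_in,
                            convention = config$convention,
                            nn_site = config$sim$ee_site)
  structure(
    list(cohort = cohort, split = split, correlation = correlation,
         models = list(lr_exercise = lr_ex, lr_interval = lr_in,
                       nn_exercise = nn_ex, nn_interval = nn_in),
         node_search = node_search, report = report, config = config),
    class = "ee_pipeline_result"
  )
}

#' @export
print.ee_pipeline_result <- function(x, ...) {
  cat(sprintf("<ee_pipeline_result> %d subjects (%d train / %d test)\n",
              nrow(x$cohort$subjects), length(x$split$train),
              length(x$split$test)))
  print(x$report)
  invisible(x)
}
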