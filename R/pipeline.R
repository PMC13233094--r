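#' Read and validate a pipeline configuration
#'
#' Configurations are flat JSON objects whose keys mirror the [sim_config()]
#' arguments (network pipeline) plus the human-study keys
#' `n_per_curriculum`, `nu`, `lapse`, `learner_eta`, `learner_init_std`.
#' Unknown keys are an error (fail-closed).
#'
#' @param path JSON file path, or a named list.
#' @return Named list of configuration values.
#' @export
read_config <- function(path) {
  cfg <- if (is.character(path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else path
  allowed <- c(names(formals(sim_config)),
               "n_per_curriculum", "nu", "lapse", "learner_eta",
               "learner_init_std")
  bad <- setdiff(names(cfg), allowed)
  if (length(bad))
    stop("unknown configuration keys: ", paste(bad, collapse = ", "))
  cfg
}

build_sim_config <- function(cfg, seed = NULL) {
  keys <- intersect(names(cfg), names(formals(sim_config)))
  args <- cfg[keys]
  if (!is.null(seed)) args$master_seed <- seed
  do.call(sim_config, args)
}

manifest <- function(config, outputs, master_seed) {
  list(package = "curricsim",
       version = as.character(utils::packageVersion("curricsim")),
       timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
       master_seed = master_seed,
       config = config[setdiff(names(config), "curricula_schedules")],
       outputs = outputs)
}

#' Simulate network populations for every configured curriculum
#'
#' Runs [run_population()] per curriculum, writes one CSV of records per
#' curriculum plus a JSON run manifest listing every output and the full
#' configuration, and returns the study.
#'
#' @param config Path to a JSON configuration, or a named list
#'   ([read_config()] keys); omitted keys take the [sim_config()] defaults.
#' @param out_dir Output directory.
#' @param seed Optional master-seed override.
#' @return Invisibly, the `"curriculum_study"`.
#' @export
cl_simulate_networks <- function(config = list(), out_dir = "results",
                                 seed = NULL) {
  cfg <- read_config(config)
  sc <- build_sim_config(cfg, seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  study <- list()
  outputs <- character(0)
  for (cur in sc$curricula) {
    message(sprintf("[curricsim] simulating %s curriculum (%d networks, d = %d)",
                    cur, sc$n_networks, sc$d))
    pop <- run_population(sc, cur)
    study[[cur]] <- pop
    outputs <- c(outputs, write_population_csv(pop, out_dir))
  }
  class(study) <- "curriculum_study"
  mf <- manifest(unclass(sc), outputs, sc$master_seed)
  jsonlite::write_json(mf, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(study)
}

#' Summarize simulated populations into a machine-readable report
#'
#' Reads the per-curriculum record CSVs from a results directory and writes
#' `summary.json` containing every pairwise pooled-SD Cohen's d between
#' hard-test accuracy distributions and the per-curriculum proportions above
#' the achiever threshold in the final training unit and at test.
#'
#' @param results_dir Directory holding `population_<curriculum>.csv` files.
#' @param threshold Achiever threshold.
#' @return Invisibly, the summary list.
#' @export
cl_analyze <- function(results_dir = "results", threshold = 0.65) {
  files <- list.files(results_dir, "^population_.*\\.csv$", full.names = TRUE)
  if (!length(files)) stop("no population CSV files in ", results_dir)
  recs <- lapply(files, utils::read.csv)
  names(recs) <- sub("^population_(.*)\\.csv$", "\\1", basename(files))
  if (length(recs) < length(c("ascending", "hard", "random", "bad")))
    warning("fewer than four curricula present; partial analysis")
  accs <- lapply(recs, function(r) r$test_acc)
  effects <- if (length(recs) >= 2) effect_size_table(accs) else
    data.frame(pair = character(0), d = numeric(0))
  achiev <- lapply(recs, function(r) {
    s <- achiever_split(r$final_train_acc, r$test_acc, threshold)
    list(prop_above_train = s$prop_above_train,
         prop_above_test = s$prop_above_test)
  })
  out <- list(threshold = threshold,
              mean_test_accuracy = lapply(accs, mean),
              effect_sizes = effects,
              achiever_proportions = achiev)
  jsonlite::write_json(out, file.path(results_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out)
}

#' Simulate and analyze a synthetic human study
#'
#' Generates the four-arm RDK study with the configured responder, writes the
#' per-trial CSV, the analysis tables (contrasts, binned trajectories) and a
#' manifest.
#'
#' @param config Path to JSON configuration or named list; recognized keys:
#'   `n_per_curriculum`, `nu`, `lapse`, `learner_eta`, `learner_init_std`,
#'   `master_seed`.
#' @param out_dir Output directory.
#' @param seed Optional master-seed override.
#' @return Invisibly, list with the study and its analysis.
#' @export
cl_simulate_humans <- function(config = list(), out_dir = "results_human",
                               seed = NULL) {
  cfg <- read_config(config)
  learner <- default_learner()
  if (!is.null(cfg$nu)) learner$nu <- cfg$nu
  if (!is.null(cfg$lapse)) learner$lapse <- cfg$lapse
  if (!is.null(cfg$learner_eta)) learner$eta_step <- cfg$learner_eta
  if (!is.null(cfg$learner_init_std)) learner$init_std <- cfg$learner_init_std
  n_arm <- if (!is.null(cfg$n_per_curriculum)) cfg$n_per_curriculum else 50L
  ms <- if (!is.null(seed)) seed else
    if (!is.null(cfg$master_seed)) cfg$master_seed else 1L
  message(sprintf("[curricsim] simulating human study: %d participants/arm", n_arm))
  study <- generate_study(n_arm, learner, ms)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  csv <- write_study_csv(study, out_dir)
  an <- analyze_human_study(study)
  utils::write.csv(an$contrasts, file.path(out_dir, "contrasts.csv"),
                   row.names = FALSE)
  utils::write.csv(an$binned, file.path(out_dir, "binned_training.csv"),
                   row.names = FALSE)
  mf <- manifest(list(n_per_curriculum = n_arm, learner = learner),
                 c(csv, file.path(out_dir, c("contrasts.csv",
                                             "binned_training.csv"))), ms)
  jsonlite::write_json(mf, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(study = study, analysis = an))
}
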