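# End-to-end orchestration: simulate -> screen -> select (x6) ->
# evaluate-frequencies -> assess-validity -> characterize. Every stage
# reads/writes fixed file names under output_dir so stages can be rerun in
# isolation, and all randomness fans out from the single config seed.

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Pipeline configuration
#'
#' @param seed global seed; per-stage sub-seeds are derived by fixed
#'   offsets so stages remain reproducible when rerun in isolation.
#' @param output_dir directory for all stage outputs.
#' @param n_workers cohort size.
#' @param simulation a [sim_params()]; defaults to
#'   `sim_params(n_workers, seed)`.
#' @param planted_fraction fraction of workers with planted pre-existing
#'   hearing loss (exercises the screening filter).
#' @param methods selection methods to run (subset of m1..m6).
#' @param model a [diagnostic_model_spec()] for method 6 and the frequency
#'   evaluation; its seed is forced to `seed + 101`.
#' @param freq_sets frequency sets for [evaluate_frequency_sets()].
#' @param n_per_group method-6 group quota.
#' @param alpha significance level for face validity.
#' @return a `nihl_pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, output_dir = tempfile("nihl_run_"),
                            n_workers = 6000,
                            simulation = NULL,
                            planted_fraction = 0.03,
                            methods = paste0("m", 1:6),
                            model = diagnostic_model_spec(),
                            freq_sets = NIHL_DEFAULT_FREQ_SETS,
                            n_per_group = 150,
                            alpha = 0.05) {
  if (is.null(simulation))
    simulation <- sim_params(n_workers = n_workers, seed = seed)
  model$seed <- as.integer(seed + 101L)
  stopifnot(all(methods %in% paste0("m", 1:6)))
  structure(list(seed = as.integer(seed), output_dir = output_dir,
                 simulation = simulation,
                 planted_fraction = planted_fraction, methods = methods,
                 model = model, freq_sets = freq_sets,
                 n_per_group = n_per_group, alpha = alpha),
            class = "nihl_pipeline_config")
}

cfg_path <- function(config, ...) file.path(config$output_dir, ...)

read_stage_cohort <- function(config, file) {
  p <- cfg_path(config, file)
  if (!file.exists(p))
    stop("missing upstream output ", file,
         " - run the earlier stage first")
  read_cohort_csv(p)
}

stage_simulate <- function(config) {
  x <- generate_cohort(config$simulation)
  x <- generate_preemployment(x, config$simulation,
                              config$planted_fraction)
  write_cohort_csv(x, cfg_path(config, "cohort.csv"))
  c("cohort.csv")
}

stage_screen <- function(config) {
  x <- read_stage_cohort(config, "cohort.csv")
  res <- apply_study_exclusions(x)
  write_cohort_csv(res$cohort, cfg_path(config, "screened.csv"))
  write_json_file(unclass(res$report),
                  cfg_path(config, "filter_report.json"))
  c("screened.csv", "filter_report.json")
}

selection_to_list <- function(sel) {
  list(method_id = sel$method_id, sg_ids = sel$sg_ids,
       rg_ids = sel$rg_ids, score = as.list(sel$score),
       metadata = sel$metadata)
}

list_to_selection <- function(l) {
  selection_result(l$method_id, unlist(l$sg_ids), unlist(l$rg_ids),
                   unlist(l$score), l$metadata)
}

stage_select <- function(config, method_id) {
  x <- read_stage_cohort(config, "screened.csv")
  files <- character(0)
  if (method_id == "m6") {
    res <- run_ml_method(x, config$model, config$n_per_group)
    write_json_file(selection_to_list(res$selection),
                    cfg_path(config, "selection_m6.json"))
    utils::write.csv(res$eval$per_subject,
                     cfg_path(config, "m6_per_subject.csv"),
                     row.names = FALSE)
    write_json_file(list(per_algorithm = res$eval$per_algorithm,
                         pooled = as.list(res$eval$pooled)),
                    cfg_path(config, "m6_model_eval.json"))
    write_json_file(list(control_ids = res$control_ids),
                    cfg_path(config, "m6_control.json"))
    files <- c("selection_m6.json", "m6_per_subject.csv",
               "m6_model_eval.json", "m6_control.json")
    if (!is.null(res$refined)) {
      write_json_file(selection_to_list(res$refined),
                      cfg_path(config, "selection_m6_refined.json"))
      files <- c(files, "selection_m6_refined.json")
    }
  } else {
    res <- run_classical_method(x, method_id)
    f <- paste0("selection_", method_id, ".json")
    write_json_file(selection_to_list(res$selection), cfg_path(config, f))
    files <- f
  }
  files
}

stage_evaluate <- function(config) {
  x <- read_stage_cohort(config, "screened.csv")
  res <- evaluate_frequency_sets(x, config$freq_sets, config$model)
  ranked <- rank_frequency_sets(res)
  utils::write.csv(ranked[, c("freq_set", "n_freqs", "mean_auc", "sd_auc",
                              "mean_accuracy", "sd_accuracy", "ok")],
                   cfg_path(config, "freq_eval.csv"), row.names = FALSE)
  c("freq_eval.csv")
}

stage_assess <- function(config) {
  x <- read_stage_cohort(config, "screened.csv")
  scores <- list()
  for (m in config$methods) {
    f <- cfg_path(config, paste0("selection_", m, ".json"))
    if (!file.exists(f)) next
    sel <- list_to_selection(jsonlite::read_json(f, simplifyVector = FALSE))
    if (length(sel$sg_ids) == 0 || length(sel$rg_ids) == 0) {
      warning("method ", m, " produced an empty group; not assessed",
              call. = FALSE)
      next
    }
    # assess on the method's own filtered cohort
    xm <- apply_method_criteria(x, m)$cohort
    scores[[m]] <- assess_method(xm, sel, config$alpha)
  }
  if (length(scores) == 0)
    stop("no selection outputs found to assess")
  ranked <- rank_methods(scores)
  write_json_file(
    list(ranking = vapply(ranked, `[[`, character(1), "method_id"),
         scores = lapply(ranked, unclass)),
    cfg_path(config, "validity.json"))
  c("validity.json")
}

stage_characterize <- function(config) {
  x <- read_stage_cohort(config, "screened.csv")
  ref_f <- cfg_path(config, "selection_m6_refined.json")
  sel_f <- cfg_path(config, "selection_m6.json")
  sel <- list_to_selection(jsonlite::read_json(sel_f,
                                               simplifyVector = FALSE))
  if (file.exists(ref_f)) {
    ref <- list_to_selection(jsonlite::read_json(ref_f,
                                                 simplifyVector = FALSE))
    # the 2-SD refinement can legitimately empty a group; characterize the
    # unrefined selection in that case
    if (length(ref$sg_ids) > 0 && length(ref$rg_ids) > 0) sel <- ref
  }
  ctrl <- unlist(jsonlite::read_json(cfg_path(config, "m6_control.json"),
                                     simplifyVector = TRUE))
  xc <- apply_method_criteria(x, "m6")$cohort
  groups <- list(sg = sel$sg_ids, rg = sel$rg_ids, control = ctrl)
  groups <- Filter(function(g) length(g) > 0, groups)
  summaries <- lapply(groups, function(ids) unclass(summarize_group(xc, ids)))
  write_json_file(summaries, cfg_path(config, "group_summaries.json"))
  slopes <- group_slopes(xc, groups)
  utils::write.csv(slopes, cfg_path(config, "slopes.csv"),
                   row.names = FALSE)
  c("group_summaries.json", "slopes.csv")
}

#' Run the full analysis pipeline
#'
#' Executes all stages in order under `config$output_dir` and writes a
#' manifest (`manifest.json`) enumerating every file produced, with md5
#' checksums. Rerunning with the same config reproduces the bundle
#' byte-identically. A stage failure aborts with the stage name; outputs
#' of completed stages are preserved.
#'
#' @param config a [pipeline_config()].
#' @param stages subset of
#'   `c("simulate","screen","select","evaluate","assess","characterize")`.
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "screen", "select",
                                    "evaluate", "assess", "characterize")) {
  stopifnot(inherits(config, "nihl_pipeline_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  run_stage <- function(name, fun) {
    message("[nihlscreen] stage: ", name)
    out <- tryCatch(fun(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    files <<- c(files, out)
  }
  if ("simulate" %in% stages)
    run_stage("simulate", function() stage_simulate(config))
  if ("screen" %in% stages)
    run_stage("screen", function() stage_screen(config))
  if ("select" %in% stages)
    for (m in config$methods)
      run_stage(paste0("select:", m),
                local({ mm <- m; function() stage_select(config, mm) }))
  if ("evaluate" %in% stages)
    run_stage("evaluate", function() stage_evaluate(config))
  if ("assess" %in% stages)
    run_stage("assess", function() stage_assess(config))
  if ("characterize" %in% stages)
    run_stage("characterize", function() stage_characterize(config))

  manifest <- list(
    seed = config$seed,
    stages = stages,
    files = lapply(setNames(files, files), function(f)
      list(md5 = unname(tools::md5sum(cfg_path(config, f))))))
  write_json_file(manifest, cfg_path(config, "manifest.json"))
  invisible(manifest)
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `screen`, `select --method m1..m6`,
#' `evaluate-freqs`, `assess`, `characterize`, `run-all`. Options:
#' `--seed <int>`, `--out <dir>`, `--n-workers <int>`,
#' `--config <json>` (a JSON object overriding `pipeline_config()`
#' defaults: seed, n_workers, planted_fraction, methods, n_per_group,
#' alpha). Logs go to stderr.
#'
#' @param args character vector (defaults to the command line).
#' @return exit status, invisibly.
#' @export
nihl_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: nihl <simulate|screen|select|evaluate-freqs|assess|",
    "             characterize|run-all> [--method m1..m6] [--seed N]",
    "             [--out DIR] [--n-workers N] [--config FILE.json]",
    sep = "\n")
  if (length(args) == 0) { message(usage); return(invisible(1L)) }
  cmd <- args[1]
  opts <- list(seed = 1L, out = "nihl_out", n_workers = 6000,
               method = NULL, config = NULL)
  i <- 2
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    key <- gsub("-", "_", key)
    if (!key %in% names(opts)) stop("unknown option: ", args[i])
    opts[[key]] <- args[i + 1]
    i <- i + 2
  }
  extra <- list()
  if (!is.null(opts$config))
    extra <- jsonlite::read_json(opts$config, simplifyVector = TRUE)
  base <- list(seed = as.integer(opts$seed), output_dir = opts$out,
               n_workers = as.integer(opts$n_workers))
  config <- do.call(pipeline_config, modifyList(base, extra))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)

  stage_map <- c(simulate = "simulate", screen = "screen",
                 "evaluate-freqs" = "evaluate", assess = "assess",
                 characterize = "characterize")
  if (cmd == "run-all") {
    run_pipeline(config)
  } else if (cmd == "select") {
    if (is.null(opts$method)) stop("select requires --method m1..m6")
    stage_select(config, opts$method)
  } else if (cmd %in% names(stage_map)) {
    run_pipeline(config, stages = stage_map[[cmd]])
  } else {
    message(usage)
    return(invisible(1L))
  }
  invisible(0L)
}
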