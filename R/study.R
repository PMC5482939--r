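# Study orchestration and persistence: scenario definitions, reproducible
# multi-run execution with resumable artifacts, and the report.

#' Define a sampling scenario
#'
#' A scenario is one combination of sampling algorithm, tuning/adaptation
#' settings and initialization scheme.
#'
#' @param name scenario label.
#' @param algorithm sampler name, see [run_sampler()].
#' @param init `"rnd"` (prior draws) or `"ms"` (multi-start optimization).
#' @param control a [sampler_control()].
#' @param n_starts multi-start count when `init = "ms"`.
#' @return a list of class `scenario`.
#' @export
scenario <- function(name, algorithm, init = c("rnd", "ms"),
                     control = sampler_control(), n_starts = 20) {
  structure(list(name = name, algorithm = algorithm, init = match.arg(init),
                 control = control, n_starts = n_starts),
            class = "scenario")
}

# Deterministic per-(scenario, run) seeds derived from the master seed.
derive_seeds <- function(master_seed, n_scenarios, n_runs) {
  with_seed(master_seed,
    matrix(sample.int(.Machine$integer.max - 1L, n_scenarios * n_runs),
           nrow = n_scenarios))
}

#' Run a study: scenarios x repeated runs
#'
#' Executes `n_runs` independent sampler runs for every scenario on one
#' benchmark problem and dataset. Per-run seeds are derived
#' deterministically from the master seed, so a study is reproducible as a
#' whole and per run. With `out_dir` set, each completed run is written as
#' a CSV trace plus JSON metadata side-car, and existing artifacts are not
#' recomputed (resumability).
#'
#' For `"ms"` initialization, one multi-start optimization is performed per
#' scenario; each run samples its starting point(s) from the retained
#' optima under its own seed, and the optimization CPU time is spread
#' across the scenario's runs so that efficiency comparisons include the
#' initialization overhead.
#'
#' @param problem a [benchmark_problem()].
#' @param data dataset tibble.
#' @param scenarios list of [scenario()] objects.
#' @param n_runs runs per scenario.
#' @param n_iter iterations per run.
#' @param seed master seed.
#' @param out_dir optional artifact directory.
#' @param verbose log progress to stderr.
#' @return a list of `sampler_run` objects (scenario-major order).
#' @export
run_study <- function(problem, data, scenarios, n_runs, n_iter, seed,
                      out_dir = NULL, verbose = FALSE) {
  stopifnot(length(scenarios) >= 1, n_runs >= 1)
  seeds <- derive_seeds(seed, length(scenarios), n_runs)
  cfg_hash <- config_hash(list(problem = problem$model$name,
                               scenarios = lapply(scenarios, function(s)
                                 s[c("name", "algorithm", "init")]),
                               n_runs = n_runs, n_iter = n_iter, seed = seed))
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  runs <- list()
  for (si in seq_along(scenarios)) {
    sc <- scenarios[[si]]
    ms <- NULL; ms_cpu_share <- 0
    if (sc$init == "ms") {
      ms <- multistart_optimize(problem, data, n_starts = sc$n_starts,
                                seed = seeds[si, 1])
      ms_cpu_share <- attr(ms, "cpu_seconds") / n_runs
    }
    n_chains <- switch(sc$algorithm,
                       pt = sc$control$n_temps,
                       phs = sc$control$n_aux + 1L, 1L)
    for (ri in seq_len(n_runs)) {
      run_id <- sprintf("%s_run%03d", sc$name, ri)
      if (!is.null(out_dir)) {
        path <- file.path(out_dir, paste0(run_id, ".csv"))
        if (file.exists(path) && file.exists(meta_path(path))) {
          runs[[run_id]] <- load_run(path)
          next
        }
      }
      if (verbose) message("running ", run_id)
      init <- if (is.null(ms)) NULL else
        init_from_multistart(ms, n_chains, seed = seeds[si, ri],
                             lower = problem$theta_min,
                             upper = problem$theta_max)
      run <- run_sampler(problem, data, algorithm = sc$algorithm,
                         n_iter = n_iter, init = init, seed = seeds[si, ri],
                         control = sc$control, scenario = sc$name,
                         extra_cpu_seconds = ms_cpu_share)
      run$config_hash <- cfg_hash
      if (!is.null(out_dir))
        save_run(run, file.path(out_dir, paste0(run_id, ".csv")))
      runs[[run_id]] <- run
    }
  }
  runs
}

config_hash <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, force = TRUE), tf)
  unname(tools::md5sum(tf))
}

meta_path <- function(path) sub("\\.csv$", ".json", path)

#' Persist / load a sampler run
#'
#' A run is stored as a CSV (trace columns plus `log_posterior`) with a
#' JSON metadata side-car (algorithm, settings, seed, problem, scenario,
#' CPU seconds, acceptance statistics, config hash).
#'
#' @param run a `sampler_run`.
#' @param path CSV path (`.json` side-car derived from it).
#' @return `save_run()` returns `path` invisibly; `load_run()` the
#'   reconstructed `sampler_run`.
#' @export
save_run <- function(run, path) {
  df <- as.data.frame(run$trace)
  df$log_posterior <- run$log_posterior
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(algorithm = run$algorithm,
               settings = unclass(run$settings),
               seed = run$seed, problem = run$problem,
               scenario = run$scenario, n_iter = run$n_iter,
               cpu_seconds = run$cpu_seconds,
               acceptance_rate = run$acceptance_rate,
               swap_rate = run$swap_rate,
               ladder = run$ladder,
               config_hash = run$config_hash)
  jsonlite::write_json(meta[!vapply(meta, is.null, TRUE)], meta_path(path),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_run
#' @export
load_run <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  meta <- jsonlite::read_json(meta_path(path), simplifyVector = TRUE)
  trace <- as.matrix(df[, setdiff(names(df), "log_posterior"), drop = FALSE])
  run <- list(trace = trace, log_posterior = df$log_posterior,
              acceptance_rate = meta$acceptance_rate,
              cpu_seconds = meta$cpu_seconds,
              algorithm = meta$algorithm, settings = meta$settings,
              seed = meta$seed, problem = meta$problem,
              scenario = meta$scenario, n_iter = meta$n_iter,
              swap_rate = meta$swap_rate, ladder = meta$ladder,
              config_hash = meta$config_hash)
  class(run) <- "sampler_run"
  run
}

#' Read a study configuration file
#'
#' JSON or YAML with fields `problem`, `n_runs`, `n_iter`, `seed`,
#' `out_dir`, optional `data_csv` (defaults to data generated at the
#' problem's true parameters with the master seed), and `scenarios`: a list
#' of records with `name`, `algorithm`, optional `init`, `n_starts` and
#' `control` overrides (passed to [sampler_control()]).
#'
#' @param path configuration file path.
#' @return a list with the parsed configuration and built [scenario()]s.
#' @export
read_study_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE,
                                  simplifyDataFrame = FALSE)
  req <- c("problem", "n_runs", "n_iter", "seed", "scenarios")
  missing <- setdiff(req, names(cfg))
  if (length(missing))
    stop("study config is missing fields: ", paste(missing, collapse = ", "))
  sc_list <- cfg$scenarios
  if (is.data.frame(sc_list))
    sc_list <- lapply(seq_len(nrow(sc_list)), function(i)
      as.list(sc_list[i, , drop = FALSE]))
  cfg$scenarios <- lapply(sc_list, function(s) {
    ctl <- do.call(sampler_control, as.list(s$control %||% list()))
    scenario(name = s$name, algorithm = s$algorithm,
             init = s$init %||% "rnd", control = ctl,
             n_starts = s$n_starts %||% 20)
  })
  cfg
}

# ---- CLI entry points -------------------------------------------------------

#' Command-line operations
#'
#' Thin entry points behind the `mcmcbench` command-line script
#' (`inst/cli/mcmcbench`): dataset generation, study execution, single-run
#' diagnostics and the study report.
#'
#' @param problem_name benchmark name, see [make_benchmark()].
#' @param seed RNG seed.
#' @param out output CSV path.
#' @return `cli_generate()` returns the dataset path invisibly.
#' @export
cli_generate <- function(problem_name, seed, out) {
  problem <- make_benchmark(problem_name)
  if (is.null(problem$theta_true))
    stop("problem ", problem_name, " has no generating parameters; ",
         "supply experimental data instead")
  data <- generate_data(problem, seed = seed)
  write_dataset(data, out)
  jsonlite::write_json(list(problem = problem_name,
                            theta = unclass(problem$theta_true), seed = seed),
                       paste0(out, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(out)
}

#' @rdname cli_generate
#' @param config_path study configuration file (JSON/YAML), see
#'   [read_study_config()].
#' @export
cli_sample <- function(config_path) {
  cfg <- read_study_config(config_path)
  problem <- make_benchmark(cfg$problem)
  data <- if (!is.null(cfg$data_csv)) read_dataset(cfg$data_csv)
          else generate_data(problem, seed = cfg$seed)
  run_study(problem, data, cfg$scenarios, n_runs = cfg$n_runs,
            n_iter = cfg$n_iter, seed = cfg$seed,
            out_dir = cfg$out_dir %||% "runs", verbose = TRUE)
  invisible(cfg$out_dir %||% "runs")
}

#' @rdname cli_generate
#' @param run_path path to a run artifact CSV.
#' @export
cli_diagnose <- function(run_path, out = NULL) {
  run <- load_run(run_path)
  rep <- diagnose_run(run)
  if (!is.null(out))
    jsonlite::write_json(rep, out, auto_unbox = TRUE, digits = NA)
  rep
}

#' @rdname cli_generate
#' @param run_dir directory of run artifacts.
#' @param out_csv,out_json report outputs (CSV summary, JSON grouping dump).
#' @param force mix artifacts with differing config hashes.
#' @export
cli_report <- function(run_dir, out_csv = file.path(run_dir, "report.csv"),
                       out_json = file.path(run_dir, "grouping.json"),
                       force = FALSE) {
  paths <- sort(list.files(run_dir, pattern = "\\.csv$", full.names = TRUE))
  paths <- paths[basename(paths) != basename(out_csv)]
  if (length(paths) < 2) stop("need at least 2 completed runs in ", run_dir)
  runs <- lapply(paths, load_run)
  hashes <- unique(na.omit(vapply(runs, function(r)
    r$config_hash %||% NA_character_, "")))
  if (length(hashes) > 1 && !force)
    stop("artifacts come from different configurations; use force = TRUE")
  summary <- summarize_study(runs)
  utils::write.csv(as.data.frame(summary), out_csv, row.names = FALSE)
  grouping <- attr(summary, "grouping")
  jsonlite::write_json(
    list(partition = grouping$partition, group_sizes = grouping$group_sizes,
         neglected = grouping$neglected, min_size = grouping$min_size,
         well_exploring = attr(summary, "exploration")$well_exploring),
    out_json, auto_unbox = FALSE, digits = NA)
  summary
}
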