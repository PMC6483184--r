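#' Read / write speaker counts
#'
#' CSV dialect: header `speaker_id,year,tokens,novel`.  Rows with
#' `novel > tokens` (or non-positive token counts) are rejected with the
#' offending row numbers.
#'
#' @param path file path.
#' @return the validated speaker-counts data.frame.
#' @export
read_speaker_counts <- function(path) {
  counts <- read.csv(path, stringsAsFactors = FALSE)
  validate_speaker_counts(counts)
  counts
}

#' @rdname read_speaker_counts
#' @param counts a speaker-counts data.frame.
#' @export
write_speaker_counts <- function(counts, path) {
  validate_speaker_counts(counts)
  write.csv(counts, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write census tables
#'
#' CSV dialect: header `year,l1_count,l2_count`.
#'
#' @param path file path.
#' @return the validated census data.frame.
#' @export
read_census <- function(path) {
  census <- read.csv(path, stringsAsFactors = FALSE)
  validate_census(census)
  census
}

#' @rdname read_census
#' @param census a census data.frame.
#' @export
write_census <- function(census, path) {
  validate_census(census)
  write.csv(census, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a demographic schedule
#'
#' CSV dialect: `year,deaths,births,recruits` (total deaths; the per-class
#' split is reconstructed from the census when needed, so regenerate
#' schedules with [census_to_schedule()] for simulation use).
#'
#' @param schedule a `demographic_schedule` (or compatible data.frame).
#' @param path file path.
#' @export
write_schedule <- function(schedule, path) {
  write.csv(schedule[, c("year", "deaths", "births", "recruits")], path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) read.csv(path, stringsAsFactors = FALSE)

#' Write / read trajectories and ensemble summaries
#'
#' Trajectory CSV dialect: `run_id,year,mean_novel,n,n_l1,n_l2,innovations`;
#' summary dialect: `year,mean,sd,ci_lo,ci_hi`.
#'
#' @param ensemble a `shift_ensemble` (or a long run data.frame).
#' @param path file path.
#' @export
write_trajectories <- function(ensemble, path) {
  runs <- if (inherits(ensemble, "shift_ensemble")) ensemble$runs
          else ensemble
  write.csv(runs, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path) read.csv(path, stringsAsFactors = FALSE)

#' @rdname write_trajectories
#' @export
write_ensemble_summary <- function(ensemble, path) {
  write.csv(get_summary(ensemble), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_ensemble_summary <- function(path) read.csv(path,
                                                 stringsAsFactors = FALSE)

#' Read a simulation config from a flat key-value (YAML) file
#'
#' Keys mirror the arguments of [simulation_config()]; an additional
#' `census_file` key points at a census CSV for the census regime.
#'
#' @param path YAML file path.
#' @return a `simulation_config`.
#' @export
read_sim_config <- function(path) {
  keys <- yaml::read_yaml(path)
  if (!is.list(keys)) stop(sprintf("config file '%s' is not a key-value map",
                                   path), call. = FALSE)
  if (!is.null(keys$census_file)) {
    keys$census <- read_census(file.path(dirname(path), keys$census_file))
    keys$census_file <- NULL
  }
  known <- names(formals(simulation_config))
  unknown <- setdiff(names(keys), known)
  if (length(unknown) > 0)
    stop(sprintf("unknown config key(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  do.call(simulation_config, keys)
}

#' Write a run manifest
#'
#' Records the config snapshot, master seed, derived run seeds, package
#' version, and output paths, so a run can be reproduced bit-for-bit.
#'
#' @param path output JSON path.
#' @param config a `simulation_config`.
#' @param master_seed integer master seed.
#' @param seeds derived per-run seeds.
#' @param outputs character vector of output file paths.
#' @export
write_manifest <- function(path, config, master_seed, seeds, outputs) {
  snap <- unclass(config)
  snap$params <- unclass(snap$params)
  if (!is.null(snap$rates)) snap$rates <- unclass(snap$rates)
  jsonlite::write_json(
    list(package = "shiftsim",
         version = as.character(packageVersion("shiftsim")),
         created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         master_seed = master_seed, run_seeds = seeds,
         config = snap, outputs = outputs),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Run a replicate ensemble from a config file
#'
#' Reads a flat-key config, runs the ensemble, and writes the trajectory
#' CSV, ensemble summary CSV and a JSON manifest into `out_dir`.  The
#' file-level entry point behind the `simulate` CLI subcommand.
#'
#' @param config_path path to a YAML config (see [read_sim_config()]).
#' @param out_dir output directory (created if missing).
#' @param n_runs replicate runs (default 10).
#' @param master_seed integer master seed (default 1).
#' @return invisibly, the `shift_ensemble`.
#' @export
cli_simulate <- function(config_path, out_dir, n_runs = 10L,
                         master_seed = 1L) {
  config <- read_sim_config(config_path)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ens <- run_ensemble(config, n_runs = n_runs, master_seed = master_seed)
  traj <- file.path(out_dir, "trajectories.csv")
  summ <- file.path(out_dir, "ensemble_summary.csv")
  write_trajectories(ens, traj)
  write_ensemble_summary(ens, summ)
  write_manifest(file.path(out_dir, "manifest.json"), config, master_seed,
                 ens$seeds, c(traj, summ))
  invisible(ens)
}

#' Compare a model against speaker-count data across an innovation grid
#'
#' The full model-data comparison for one model: fit per-year
#' beta-binomial MLEs to the counts, sweep the innovation rate, apply the
#' interval-overlap fit criterion per setting, select the minimum-MSE
#' setting, rerun it with a larger replicate set, and compute the joint
#' tail probability of the data MLEs.
#'
#' @param config a `simulation_config` (census regime for data
#'   comparisons; its `mu` is swept).
#' @param counts a speaker-counts data.frame with a `year` column.
#' @param mu_grid innovation rates to sweep.
#' @param n_runs replicate runs per grid point (default 10).
#' @param n_rep replicate runs for the selected setting (default 100).
#' @param master_seed integer master seed.
#' @param bootstrap_reps bootstrap replicates for the data MLE intervals.
#' @return an object of class `model_comparison`: list with `mle_points`,
#'   `sweep_mu`, `overlap` (logical per setting), `mse` (per setting),
#'   `best_mu`, `joint_probability`, `best_ensemble`.
#' @export
compare_to_data <- function(config, counts, mu_grid, n_runs = 10L,
                            n_rep = 100L, master_seed = 1L,
                            bootstrap_reps = 500L) {
  mle_points <- fit_betabinom_by_year(counts,
                                      bootstrap_reps = bootstrap_reps)
  sweep <- run_sweep(config, mu_grid, n_runs = n_runs,
                     master_seed = master_seed)
  overlap <- vapply(sweep, overlap_fit_check, logical(1),
                    mle_points = mle_points)
  sel <- select_min_mse(sweep, mle_points)
  cfg_best <- config
  cfg_best$params <- learning_params(l = config$params$l, mu = sel$mu,
                                     novel_index = config$params$novel_index)
  best <- run_ensemble(cfg_best, n_runs = n_rep,
                       master_seed = master_seed + length(mu_grid))
  jp <- joint_tail_probability(best, mle_points)
  structure(list(model = config$model, mle_points = mle_points,
                 sweep_mu = mu_grid, overlap = unname(overlap),
                 mse = sel$mse, best_mu = sel$mu,
                 joint_probability = jp, best_ensemble = best),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("<model_comparison> %s over mu in {%s}\n", x$model,
              paste(format(x$sweep_mu, trim = TRUE), collapse = ", ")))
  cat("  data MLEs:",
      paste(sprintf("%d: %.3f", x$mle_points$year, x$mle_points$mle),
            collapse = ", "), "\n")
  cat(sprintf("  settings passing the interval-overlap criterion: %d of %d\n",
              sum(x$overlap), length(x$overlap)))
  cat(sprintf("  min-MSE mu = %g; joint tail probability = %.4f\n",
              x$best_mu, x$joint_probability))
  invisible(x)
}

#' Run the two-model comparison pipeline and write a report
#'
#' Runs [compare_to_data()] for model 1 (entry-only innovation) and model 2
#' (SLA window), and writes a plain-text report plus a JSON version into
#' `out_dir`.  The file-level entry point behind the `compare` CLI
#' subcommand.
#'
#' @param counts_path speaker-counts CSV.
#' @param census_path census CSV.
#' @param out_dir output directory.
#' @param mu_grid innovation grid (default 0.01-0.1 step 0.01).
#' @param n_runs,n_rep,master_seed,bootstrap_reps see [compare_to_data()].
#' @param l learning weight (default 0.05).
#' @param scale census scale divisor (default 100).
#' @return invisibly, a list with both `model_comparison` objects.
#' @export
cli_compare <- function(counts_path, census_path, out_dir,
                        mu_grid = seq(0.01, 0.1, by = 0.01),
                        n_runs = 10L, n_rep = 100L, master_seed = 1L,
                        bootstrap_reps = 500L, l = 0.05, scale = 100) {
  counts <- read_speaker_counts(counts_path)
  census <- read_census(census_path)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- lapply(c("model1", "model2"), function(m) {
    cfg <- simulation_config(model = m, regime = "census", census = census,
                             l = l, scale = scale)
    compare_to_data(cfg, counts, mu_grid, n_runs = n_runs, n_rep = n_rep,
                    master_seed = master_seed,
                    bootstrap_reps = bootstrap_reps)
  })
  names(res) <- c("model1", "model2")
  report <- file.path(out_dir, "comparison_report.txt")
  con <- file(report, "w"); on.exit(close(con))
  for (m in names(res)) {
    r <- res[[m]]
    writeLines(sprintf("== %s ==", m), con)
    writeLines(sprintf("data MLE: %s",
                       paste(sprintf("%d: %.4f [%.4f, %.4f]",
                                     r$mle_points$year, r$mle_points$mle,
                                     r$mle_points$ci_lo,
                                     r$mle_points$ci_hi),
                             collapse = "; ")), con)
    for (i in seq_along(r$sweep_mu))
      writeLines(sprintf("mu = %-5g overlap = %-5s mse = %.6f",
                         r$sweep_mu[i], r$overlap[i], r$mse[i]), con)
    writeLines(sprintf("min-MSE mu = %g", r$best_mu), con)
    writeLines(sprintf("joint tail probability = %.4f", r$joint_probability),
               con)
    writeLines("", con)
  }
  jsonlite::write_json(
    lapply(res, function(r)
      list(model = r$model,
           mle = r$mle_points[, c("year", "mle", "ci_lo", "ci_hi")],
           mu_grid = r$sweep_mu, overlap = r$overlap, mse = r$mse,
           best_mu = r$best_mu, joint_probability = r$joint_probability)),
    file.path(out_dir, "comparison_report.json"),
    auto_unbox = TRUE, digits = NA)
  invisible(res)
}
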