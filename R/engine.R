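#' Simulation configuration
#'
#' Assembles everything a run needs: the innovation model, the demographic
#' regime, rates or a census table, learning parameters, and the schedule
#' of rounds and years.
#'
#' Under `model1`, L2 speakers may innovate only at the moment they enter
#' the population.  Under `model2`, second-language acquisition is treated
#' as a multi-year process: for `sla_window_years` years after entry
#' (default 7), every such L2 speaker may additionally adopt the novel
#' variant with probability `mu` at the start of each year.  Entry counts
#' as the first opportunity, so a recruit gets exactly `sla_window_years`
#' opportunities in total; set `sla_entry_counts = FALSE` for the variant
#' in which the annual passes come on top of the entry draw.
#'
#' @param model `"model1"` (innovation at entry only) or `"model2"`
#'   (multi-year SLA innovation window).
#' @param regime `"fixed"`, `"expanding"`, or `"census"`.
#' @param n_variants number of variants (default 2).
#' @param N0 initial population size for fixed/expanding regimes.
#' @param census census table (data.frame `year,l1_count,l2_count`) for the
#'   census regime; its year span sets the horizon.
#' @param b,r,d per-capita birth, recruitment and death rates for the
#'   fixed/expanding regimes.  Defaults: `b` = 0.007, `r` = 0.063; `d`
#'   defaults to `b + r` in the fixed regime (pure replacement) and to
#'   `b + r - 0.05` in the expanding regime (growth rate 0.05).
#' @param l learning weight (default 0.05).
#' @param mu innovation probability (default 0).
#' @param novel_index index of the novel variant (default 2).
#' @param rounds_per_year interaction rounds per model year (default 365).
#' @param years horizon in years (default 100; for the census regime the
#'   census span is used).
#' @param sla_window_years length of the SLA innovation window, model2 only
#'   (default 7).
#' @param sla_entry_counts if `TRUE` (default) the entry-time draw counts
#'   as the first of the `sla_window_years` opportunities.
#' @param mortality per-capita death rate used to build the census-regime
#'   schedule (default 0.02).
#' @param scale census-regime population divisor for desk-scale runs
#'   (default 100; use 1 for full fidelity).
#' @param initial_l2_tenure tenure assigned to L2 speakers present at the
#'   start.  Default `sla_window_years`: the initial stock are established
#'   speakers past their acquisition window, consistent with starting from
#'   a fully conservative population.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(model = c("model1", "model2"),
                              regime = c("fixed", "expanding", "census"),
                              n_variants = 2L, N0 = 100L, census = NULL,
                              b = 0.007, r = 0.063, d = NULL,
                              l = 0.05, mu = 0, novel_index = 2L,
                              rounds_per_year = 365L, years = 100L,
                              sla_window_years = 7L, sla_entry_counts = TRUE,
                              mortality = 0.02, scale = 100,
                              initial_l2_tenure = NULL) {
  model <- match.arg(model)
  regime <- match.arg(regime)
  params <- learning_params(l = l, mu = mu, novel_index = novel_index)
  if (rounds_per_year < 0 || years < 1 || sla_window_years < 1)
    stop("rounds_per_year, years and sla_window_years must be positive",
         call. = FALSE)
  rates <- NULL
  if (regime == "census") {
    if (is.null(census))
      stop("census regime needs a census table", call. = FALSE)
    validate_census(census)
    years <- census$year[nrow(census)] - census$year[1]
  } else {
    if (is.null(d)) d <- if (regime == "fixed") b + r else b + r - 0.05
    rates <- rate_set(b, r, d)
  }
  if (is.null(initial_l2_tenure)) initial_l2_tenure <- sla_window_years
  structure(list(model = model, regime = regime,
                 n_variants = as.integer(n_variants), N0 = as.integer(N0),
                 census = census, rates = rates, params = params,
                 rounds_per_year = as.integer(rounds_per_year),
                 years = as.integer(years),
                 sla_window_years = as.integer(sla_window_years),
                 sla_entry_counts = isTRUE(sla_entry_counts),
                 mortality = mortality, scale = scale,
                 initial_l2_tenure = as.integer(initial_l2_tenure)),
            class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf("<simulation_config> %s, %s regime, %d variants\n",
              x$model, x$regime, x$n_variants))
  cat(sprintf("  l = %g, mu = %g, %d rounds/year, %d years\n",
              x$params$l, x$params$mu, x$rounds_per_year, x$years))
  if (!is.null(x$rates))
    cat(sprintf("  rates: b = %g, r = %g, d = %g (g = %g)\n",
                x$rates$b, x$rates$r, x$rates$d, x$rates$g))
  if (x$regime == "census")
    cat(sprintf("  census %d-%d, mortality %g, scale %g\n",
                x$census$year[1], x$census$year[nrow(x$census)],
                x$mortality, x$scale))
  invisible(x)
}

#' SLA innovation pass at a year boundary
#'
#' Every L2 speaker still inside the second-language-acquisition window
#' independently adopts the novel-variant indicator distribution with
#' probability `mu`.  Called after the yearly tenure increment, so with
#' entry counting as the tenure-0 opportunity an agent gets exactly
#' `sla_window_years` opportunities in total.
#'
#' @param pop a `speaker_population` (tenures already incremented for the
#'   new year).
#' @param params a `learning_params`.
#' @param sla_window_years window length in years.
#' @param entry_counts whether the entry-time draw counts as the first
#'   opportunity (default `TRUE`; if `FALSE`, eligibility extends one year,
#'   giving entry plus `sla_window_years` annual passes).
#' @return the population, with innovation events counted.
#' @export
sla_mutation_pass <- function(pop, params, sla_window_years = 7L,
                              entry_counts = TRUE) {
  limit <- sla_window_years - as.integer(isTRUE(entry_counts)) + 1L
  eligible <- which(pop$speaker_class == "L2" & pop$tenure < limit)
  if (length(eligible) == 0 || params$mu == 0) return(pop)
  hit <- eligible[runif(length(eligible)) < params$mu]
  if (length(hit) > 0) {
    pop$probs[hit, ] <- 0
    pop$probs[hit, params$novel_index] <- 1
    pop$innovations <- pop$innovations + length(hit)
  }
  pop
}

# initial population for a config
init_population <- function(config) {
  if (config$regime == "census") {
    sched <- census_to_schedule(config$census, mortality = config$mortality,
                                scale = config$scale)
    targ <- attr(sched, "targets")
    pop <- conservative_population(n_l1 = targ$l1[1], n_l2 = targ$l2[1],
                                   n_variants = config$n_variants,
                                   year = targ$year[1],
                                   l2_tenure = config$initial_l2_tenure)
    list(pop = pop, schedule = sched)
  } else {
    list(pop = conservative_population(n_l1 = config$N0,
                                       n_variants = config$n_variants),
         schedule = NULL)
  }
}

#' Advance a population by one model year
#'
#' Runs `rounds_per_year` interaction rounds, increments tenures at the
#' year boundary, applies the model2 SLA innovation pass, then performs the
#' regime's demographic turnover, and finally advances the year counter.
#'
#' @param pop a `speaker_population`.
#' @param config a `simulation_config`.
#' @param schedule the `demographic_schedule` for the census regime
#'   (ignored otherwise).
#' @return the population one year later.
#' @export
run_year <- function(pop, config, schedule = NULL) {
  if (config$rounds_per_year > 0)
    pop$probs <- interaction_rounds_cpp(pop$probs, config$params$l,
                                        config$rounds_per_year)
  drift <- abs(rowSums(pop$probs) - 1)
  if (any(drift > 1e-9)) {
    warning("usage distributions drifted from unit sum; renormalizing",
            call. = FALSE)
    pop$probs <- pop$probs / rowSums(pop$probs)
  }
  pop$tenure <- pop$tenure + 1L
  if (config$model == "model2")
    pop <- sla_mutation_pass(pop, config$params, config$sla_window_years,
                             config$sla_entry_counts)
  pop <- switch(config$regime,
    fixed = fixed_step(pop, config$rates, config$params),
    expanding = expanding_step(pop, config$rates, config$params),
    census = schedule_step(pop, schedule, config$params))
  pop$year <- pop$year + 1L
  pop
}

trajectory_row <- function(pop, novel_index) {
  data.frame(year = pop$year,
             mean_novel = population_mean(pop)[novel_index],
             n = n_agents(pop),
             n_l1 = sum(pop$speaker_class == "L1"),
             n_l2 = sum(pop$speaker_class == "L2"),
             innovations = pop$innovations)
}

#' Run one simulation
#'
#' A deterministic function of `(config, seed)`.  Records, per year, the
#' population mean usage of the novel variant, the population size and
#' composition, and the cumulative count of innovation events.
#'
#' @param config a `simulation_config`.
#' @param seed integer seed.
#' @param initial_population optional `speaker_population` overriding the
#'   default all-conservative start (used e.g. to study absorbing states).
#' @return a data.frame of class `trajectory` with columns `year`,
#'   `mean_novel`, `n`, `n_l1`, `n_l2`, `innovations` (first row is the
#'   initial state).
#' @export
run_simulation <- function(config, seed, initial_population = NULL) {
  set.seed(seed)
  st <- init_population(config)
  pop <- if (is.null(initial_population)) st$pop else initial_population
  rows <- vector("list", config$years + 1L)
  rows[[1]] <- trajectory_row(pop, config$params$novel_index)
  for (y in seq_len(config$years)) {
    pop <- run_year(pop, config, st$schedule)
    rows[[y + 1]] <- trajectory_row(pop, config$params$novel_index)
  }
  out <- do.call(rbind, rows)
  attr(out, "seed") <- seed
  attr(out, "config") <- config
  class(out) <- c("trajectory", "data.frame")
  out
}

#' Run a replicate ensemble
#'
#' Runs `n_runs` independent simulations of one configuration with seeds
#' derived from `master_seed`, and summarizes the per-year novel-variant
#' mean usage across runs (see [ensemble_interval()] for the interval
#' convention).
#'
#' @param config a `simulation_config`.
#' @param n_runs number of replicate runs.
#' @param master_seed integer seed from which all run seeds derive.
#' @return an object of class `shift_ensemble`: list with `runs` (long
#'   data.frame with `run_id` prepended to the trajectory columns),
#'   `summary` (data.frame `year,mean,sd,ci_lo,ci_hi`), `seeds`, `config`.
#' @export
run_ensemble <- function(config, n_runs = 10L, master_seed = 1L) {
  if (n_runs < 1) stop("need at least one run", call. = FALSE)
  set.seed(master_seed)
  seeds <- sample.int(.Machine$integer.max, n_runs)
  runs <- lapply(seq_len(n_runs), function(i) {
    tr <- run_simulation(config, seeds[i])
    cbind(run_id = i, as.data.frame(tr))
  })
  runs <- do.call(rbind, runs)
  years <- sort(unique(runs$year))
  summ <- do.call(rbind, lapply(years, function(y) {
    v <- runs$mean_novel[runs$year == y]
    iv <- ensemble_interval(v, warn_single = FALSE)
    data.frame(year = y, mean = iv[["mean"]], sd = iv[["sd"]],
               ci_lo = iv[["ci_lo"]], ci_hi = iv[["ci_hi"]])
  }))
  structure(list(runs = runs, summary = summ, seeds = seeds,
                 config = config, n_runs = n_runs),
            class = "shift_ensemble")
}

#' @export
print.shift_ensemble <- function(x, ...) {
  last <- x$summary[nrow(x$summary), ]
  cat(sprintf(
    "<shift_ensemble> %d runs of %s/%s, mu = %g\n", x$n_runs,
    x$config$model, x$config$regime, x$config$params$mu))
  cat(sprintf("  final year %d: mean novel usage %.4f (sd %.4f)\n",
              last$year, last$mean, last$sd))
  invisible(x)
}

#' Sweep an innovation-rate grid
#'
#' Runs one ensemble per value of `mu`, holding everything else fixed.
#'
#' @param config a `simulation_config` (its `mu` is overridden).
#' @param mu_grid numeric vector of innovation rates.
#' @param n_runs replicate runs per grid point.
#' @param master_seed integer; grid point i uses `master_seed + i - 1`.
#' @return a named list of `shift_ensemble` objects (names are the mu
#'   values), of class `shift_sweep`.
#' @export
run_sweep <- function(config, mu_grid, n_runs = 10L, master_seed = 1L) {
  if (length(mu_grid) < 1) stop("empty mu grid", call. = FALSE)
  out <- lapply(seq_along(mu_grid), function(i) {
    cfg <- config
    cfg$params <- learning_params(l = config$params$l, mu = mu_grid[i],
                                  novel_index = config$params$novel_index)
    run_ensemble(cfg, n_runs = n_runs, master_seed = master_seed + i - 1L)
  })
  names(out) <- format(mu_grid, trim = TRUE)
  structure(out, mu_grid = mu_grid, class = "shift_sweep")
}
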