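#' Per-capita demographic rates
#'
#' @param b birth rate of L1 speakers per capita per year.
#' @param r recruitment rate of L2 speakers per capita per year.
#' @param d death rate per capita per year.
#' @return an object of class `rate_set`.
#' @export
rate_set <- function(b, r, d) {
  v <- c(b = b, r = r, d = d)
  if (!is.numeric(v) || anyNA(v) || any(v < 0) || any(v > 1))
    stop("rates b, r, d must lie in [0, 1]", call. = FALSE)
  structure(list(b = b, r = r, d = d, g = b + r - d), class = "rate_set")
}

# unbiased integer realization of a fractional count: floor plus a Bernoulli
# on the fractional part
stoch_round <- function(x) {
  f <- floor(x)
  as.integer(f + (runif(length(x)) < x - f))
}

# append newly initialized agents to a population; snapshot is the
# pre-turnover population used for parent sampling and recruit means
add_newborns <- function(pop, snapshot, k) {
  if (k <= 0) return(pop)
  n_snap <- nrow(snapshot$probs)
  if (n_snap < 2)
    stop("newborns need two distinct parents in the population",
         call. = FALSE)
  usage <- matrix(0, k, ncol(pop$probs))
  for (i in seq_len(k)) {
    par <- sample.int(n_snap, 2L)  # distinct by construction
    usage[i, ] <- (snapshot$probs[par[1], ] + snapshot$probs[par[2], ]) / 2
  }
  pop$probs <- rbind(pop$probs, usage)
  pop$speaker_class <- c(pop$speaker_class, rep("L1", k))
  pop$tenure <- c(pop$tenure, rep(0L, k))
  pop
}

add_recruits <- function(pop, snapshot, k, params) {
  if (k <= 0) return(pop)
  nv <- ncol(pop$probs)
  snap_mean <- colMeans(snapshot$probs)
  innovate <- runif(k) < params$mu
  usage <- matrix(snap_mean, k, nv, byrow = TRUE)
  if (any(innovate)) {
    usage[innovate, ] <- 0
    usage[innovate, params$novel_index] <- 1
  }
  pop$probs <- rbind(pop$probs, usage)
  pop$speaker_class <- c(pop$speaker_class, rep("L2", k))
  pop$tenure <- c(pop$tenure, rep(0L, k))
  pop$innovations <- pop$innovations + sum(innovate)
  pop
}

drop_agents <- function(pop, idx) {
  if (length(idx) == 0) return(pop)
  pop$probs <- pop$probs[-idx, , drop = FALSE]
  pop$speaker_class <- pop$speaker_class[-idx]
  pop$tenure <- pop$tenure[-idx]
  pop
}

#' Yearly turnover in a fixed-size population
#'
#' `round(d * N)` uniformly chosen agents die; each is replaced by an L1
#' newborn with probability `b / (b + r)` and otherwise by an L2 recruit.
#' Newborn parents and recruit means come from the pre-turnover snapshot.
#' N is unchanged.
#'
#' @param pop a `speaker_population`.
#' @param rates a `rate_set`.
#' @param params a `learning_params` (supplies `mu` and `novel_index`).
#' @return the population after turnover.
#' @export
fixed_step <- function(pop, rates, params) {
  N <- n_agents(pop)
  deaths <- as.integer(round(rates$d * N))
  if (deaths == 0) return(pop)
  if (rates$b + rates$r == 0)
    stop("fixed regime with deaths needs b + r > 0", call. = FALSE)
  snapshot <- pop
  victims <- sample.int(N, deaths)
  births <- rbinom(1L, deaths, rates$b / (rates$b + rates$r))
  pop <- drop_agents(pop, victims)
  pop <- add_newborns(pop, snapshot, births)
  add_recruits(pop, snapshot, deaths - births, params)
}

#' Yearly turnover in an expanding population
#'
#' Deaths, L1 births and L2 recruitments are integer realizations of
#' `d*N`, `b*N` and `r*N` (floor plus Bernoulli on the fractional
#' part), so the expected growth rate is `g = b + r - d`.  Deaths are
#' sampled uniformly; newborns and recruits are initialized from the
#' pre-turnover snapshot.
#'
#' @inheritParams fixed_step
#' @return the population after turnover.
#' @export
expanding_step <- function(pop, rates, params) {
  N <- n_agents(pop)
  counts <- stoch_round(N * c(rates$d, rates$b, rates$r))
  deaths <- counts[1]; births <- counts[2]; recruits <- counts[3]
  if (N - deaths + births + recruits < 1)
    stop(sprintf(
      "demographic step would empty the population (N = %d, deaths = %d)",
      N, deaths), call. = FALSE)
  snapshot <- pop
  if (deaths > 0) pop <- drop_agents(pop, sample.int(N, min(deaths, N)))
  pop <- add_newborns(pop, snapshot, births)
  add_recruits(pop, snapshot, recruits, params)
}

#' Census table of L1/L2 speaker counts in Maputo
#'
#' Counts of Portuguese speakers in Maputo, Mozambique, by first (L1) or
#' second (L2) language, from the 1980, 1997 and 2007 censuses plus the
#' 1975 independence-year estimate.  The 1975 L1 figure is an estimate
#' accounting for the emigration of native speakers around independence.
#'
#' @return data.frame with columns `year`, `l1_count`, `l2_count`.
#' @export
maputo_census <- function() {
  data.frame(year = c(1975L, 1980L, 1997L, 2007L),
             l1_count = c(100, 6525, 241709, 470690),
             l2_count = c(20000, 326521, 599438, 612992))
}

validate_census <- function(census) {
  need <- c("year", "l1_count", "l2_count")
  if (!all(need %in% names(census)))
    stop("census table needs columns year, l1_count, l2_count",
         call. = FALSE)
  if (nrow(census) < 2 || any(diff(census$year) <= 0))
    stop("census years must be strictly increasing", call. = FALSE)
  if (any(census$l1_count < 0) || any(census$l2_count < 0))
    stop("census counts must be non-negative", call. = FALSE)
  invisible(census)
}

# per-year class targets by geometric interpolation between census anchors
# (linear when an endpoint is zero, where a geometric path is undefined)
interpolate_census <- function(census) {
  years <- census$year[1]:census$year[nrow(census)]
  interp1 <- function(counts) {
    out <- numeric(length(years))
    for (i in seq_len(nrow(census) - 1)) {
      y0 <- census$year[i]; y1 <- census$year[i + 1]
      c0 <- counts[i]; c1 <- counts[i + 1]
      span <- y0:y1
      frac <- (span - y0) / (y1 - y0)
      vals <- if (c0 > 0 && c1 > 0) c0 * (c1 / c0)^frac
              else c0 + (c1 - c0) * frac
      out[match(span, years)] <- vals
    }
    out
  }
  data.frame(year = years, l1 = interp1(census$l1_count),
             l2 = interp1(census$l2_count))
}

#' Build a per-year demographic schedule from a census table
#'
#' Between consecutive census years the L1 and L2 totals are interpolated
#' geometrically to per-year targets.  Each year, `round(mortality * N)`
#' deaths are apportioned to the two classes by current composition
#' (largest remainder); L1 births and L2 recruitments are then the net
#' changes needed to hit the next year's targets plus replacement of that
#' class's deaths.  If a class shrinks faster than mortality allows, the
#' implied negative births/recruits are clamped to zero and the deficit is
#' added as extra deaths in that class (with a warning).  With `scale > 1`
#' the per-year targets are divided by `scale` and realized by stochastic
#' remainder rounding for desk-scale runs; at `scale = 1` applying the
#' schedule reproduces the census totals at every census year exactly.
#'
#' @param census data.frame with columns `year`, `l1_count`, `l2_count`.
#' @param mortality per-capita death rate per year (default 0.02).
#' @param scale positive divisor applied to all counts (default 1).
#' @return an object of class `demographic_schedule`: a data.frame with
#'   columns `year`, `deaths`, `deaths_l1`, `deaths_l2`, `births`,
#'   `recruits` (one row per transition year), with the per-year class
#'   targets attached as attribute `targets`.
#' @export
census_to_schedule <- function(census, mortality = 0.02, scale = 1) {
  validate_census(census)
  if (!is.numeric(mortality) || mortality < 0 || mortality > 1)
    stop("mortality must lie in [0, 1]", call. = FALSE)
  if (!is.numeric(scale) || scale <= 0)
    stop("scale must be positive", call. = FALSE)
  targ <- interpolate_census(census)
  if (scale != 1) {
    anchor <- targ$year %in% census$year
    l1 <- stoch_round(targ$l1 / scale)
    l2 <- stoch_round(targ$l2 / scale)
    # keep anchors deterministic so replicate runs share census-year totals
    l1[anchor] <- round(targ$l1[anchor] / scale)
    l2[anchor] <- round(targ$l2[anchor] / scale)
    targ$l1 <- l1; targ$l2 <- l2
  } else {
    targ$l1 <- round(targ$l1); targ$l2 <- round(targ$l2)
  }
  if (targ$l1[1] + targ$l2[1] < 1)
    stop("scaled initial population is empty; lower `scale`", call. = FALSE)
  ny <- nrow(targ) - 1
  sched <- data.frame(year = targ$year[seq_len(ny)], deaths = 0L,
                      deaths_l1 = 0L, deaths_l2 = 0L, births = 0L,
                      recruits = 0L)
  clamped <- FALSE
  for (i in seq_len(ny)) {
    N <- targ$l1[i] + targ$l2[i]
    deaths <- as.integer(round(mortality * N))
    # apportion deaths to classes by composition (nearest integer for L1,
    # remainder to L2), capped by class size
    d1 <- if (N > 0) as.integer(round(deaths * targ$l1[i] / N)) else 0L
    d1 <- min(d1, targ$l1[i])
    d2 <- deaths - d1
    if (d2 > targ$l2[i]) { d1 <- d1 + (d2 - targ$l2[i]); d2 <- targ$l2[i] }
    births <- targ$l1[i + 1] - targ$l1[i] + d1
    recruits <- targ$l2[i + 1] - targ$l2[i] + d2
    if (births < 0) { d1 <- d1 - births; births <- 0L; clamped <- TRUE }
    if (recruits < 0) { d2 <- d2 - recruits; recruits <- 0L; clamped <- TRUE }
    sched[i, -1] <- c(d1 + d2, d1, d2, births, recruits)
  }
  if (clamped)
    warning("census shrinks faster than mortality allows; ",
            "clamped negative births/recruits to zero with extra deaths",
            call. = FALSE)
  structure(sched, targets = targ, scale = scale, mortality = mortality,
            class = c("demographic_schedule", "data.frame"))
}

#' Apply one year of a census-driven schedule to a population
#'
#' Removes the scheduled number of deaths (uniformly within each speaker
#' class), then adds the scheduled L1 newborns and L2 recruits, all
#' initialized from the pre-turnover snapshot.  Hitting the per-class death
#' counts exactly is what lets the schedule reproduce the census totals.
#'
#' @param pop a `speaker_population` whose `year` matches a schedule row.
#' @param schedule a `demographic_schedule`.
#' @param params a `learning_params`.
#' @return the population after turnover (year unchanged; the caller owns
#'   the year counter).
#' @export
schedule_step <- function(pop, schedule, params) {
  row <- which(schedule$year == pop$year)
  if (length(row) != 1)
    stop(sprintf("no schedule row for year %d", pop$year), call. = FALSE)
  snapshot <- pop
  l1_idx <- which(pop$speaker_class == "L1")
  l2_idx <- which(pop$speaker_class == "L2")
  d1 <- min(schedule$deaths_l1[row], length(l1_idx))
  d2 <- min(schedule$deaths_l2[row], length(l2_idx))
  victims <- c(sample_vec(l1_idx, d1), sample_vec(l2_idx, d2))
  pop <- drop_agents(pop, victims)
  pop <- add_newborns(pop, snapshot, schedule$births[row])
  add_recruits(pop, snapshot, schedule$recruits[row], params)
}
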