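#' Validate a usage distribution (or matrix of them)
#'
#' A usage distribution is an agent's probability vector over the variants of
#' one linguistic feature: entries in \[0, 1\] summing to one.  By convention
#' variant 1 is the conservative (pre-contact) variant and variant 2 the
#' designated novel variant.
#'
#' @param probs numeric vector, or matrix with one distribution per row.
#' @param tol tolerance on the unit sum (default 1e-12).
#' @return `probs`, invisibly, after validation.
#' @export
validate_usage <- function(probs, tol = 1e-12) {
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1)
  if (!is.numeric(probs) || ncol(probs) < 2)
    stop("a usage distribution needs at least two variants", call. = FALSE)
  if (anyNA(probs) || any(probs < 0) || any(probs > 1))
    stop("usage probabilities must lie in [0, 1]", call. = FALSE)
  sums <- rowSums(probs)
  if (any(abs(sums - 1) > tol))
    stop(sprintf("usage distribution does not sum to 1 (max |sum - 1| = %.3g)",
                 max(abs(sums - 1))), call. = FALSE)
  invisible(probs)
}

#' Construct a speaker population
#'
#' A population holds one agent per row: a usage distribution, a speaker
#' class (`"L1"` native or `"L2"` second-language), and for L2 speakers the
#' tenure in years since entering the speech community (0 in the entry year,
#' incremented at each year boundary).
#'
#' @param probs numeric matrix of usage distributions, one agent per row.
#' @param speaker_class character vector, `"L1"` or `"L2"`, one per agent.
#' @param tenure integer vector of years since entry (default 0).
#' @param year starting model/calendar year (default 0).
#' @return an object of class `speaker_population`.
#' @examples
#' pop <- new_population(matrix(c(1, 0), 3, 2, byrow = TRUE),
#'                       speaker_class = c("L1", "L1", "L2"))
#' population_mean(pop)
#' @export
new_population <- function(probs, speaker_class,
                           tenure = rep(0L, nrow(probs)), year = 0L) {
  probs <- as.matrix(probs)
  validate_usage(probs)
  speaker_class <- as.character(speaker_class)
  if (length(speaker_class) != nrow(probs))
    stop("one speaker class per agent is required", call. = FALSE)
  if (!all(speaker_class %in% c("L1", "L2")))
    stop("speaker_class must be 'L1' or 'L2'", call. = FALSE)
  tenure <- as.integer(tenure)
  if (length(tenure) != nrow(probs) || any(tenure < 0))
    stop("tenure must be a non-negative integer per agent", call. = FALSE)
  structure(list(probs = unname(probs), speaker_class = speaker_class,
                 tenure = tenure, year = as.integer(year),
                 innovations = 0L),
            class = "speaker_population")
}

#' Initialize a population in which everyone uses the conservative variant
#'
#' All agents start with probability 1 on variant 1, the standard variant
#' before contact-induced innovation.
#'
#' @param n_l1,n_l2 numbers of L1 and L2 agents.
#' @param n_variants number of variants (>= 2).
#' @param year starting year.
#' @param l2_tenure tenure assigned to the initial L2 agents (established
#'   speakers by default have unknown, old entry dates; see
#'   [simulation_config()]).
#' @return a `speaker_population`.
#' @export
conservative_population <- function(n_l1, n_l2 = 0L, n_variants = 2L,
                                    year = 0L, l2_tenure = 0L) {
  n <- n_l1 + n_l2
  if (n < 1) stop("population must contain at least one agent", call. = FALSE)
  probs <- matrix(0, n, n_variants)
  probs[, 1] <- 1
  new_population(probs,
                 speaker_class = rep(c("L1", "L2"), c(n_l1, n_l2)),
                 tenure = rep(c(0L, as.integer(l2_tenure)), c(n_l1, n_l2)),
                 year = year)
}

#' Number of agents in a population
#' @param pop a `speaker_population`.
#' @return integer population size.
#' @export
n_agents <- function(pop) nrow(pop$probs)

#' Population mean usage
#'
#' The element-wise mean of the agents' usage distributions: the population
#' mean use of each variant.
#'
#' @param pop a `speaker_population`.
#' @return numeric vector, a valid usage distribution.
#' @export
population_mean <- function(pop) {
  if (n_agents(pop) < 1) stop("empty population has no mean usage",
                              call. = FALSE)
  colMeans(pop$probs)
}

#' @export
print.speaker_population <- function(x, ...) {
  m <- population_mean(x)
  cat(sprintf("<speaker_population> %d agents (%d L1, %d L2), year %d\n",
              n_agents(x), sum(x$speaker_class == "L1"),
              sum(x$speaker_class == "L2"), x$year))
  cat("  mean usage:", paste(sprintf("%.4f", m), collapse = " "), "\n")
  invisible(x)
}

# sample k elements of x without the length-1 surprise of sample()
sample_vec <- function(x, k) x[sample.int(length(x), k)]
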