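#' Learning and innovation parameters
#'
#' @param l learning weight in \[0, 1\]: how far an agent moves toward a
#'   heard variant after one interaction.
#' @param mu innovation probability in \[0, 1\]: the chance that an entering
#'   (or, under the SLA model, a recently entered) L2 speaker adopts the
#'   novel variant outright.
#' @param novel_index index of the designated novel variant (default 2;
#'   variant 1 is the conservative variant and cannot be the novel one).
#' @return an object of class `learning_params`.
#' @export
learning_params <- function(l = 0.05, mu = 0, novel_index = 2L) {
  if (!is.numeric(l) || length(l) != 1 || is.na(l) || l < 0 || l > 1)
    stop("learning weight l must lie in [0, 1]", call. = FALSE)
  if (!is.numeric(mu) || length(mu) != 1 || is.na(mu) || mu < 0 || mu > 1)
    stop("innovation rate mu must lie in [0, 1]", call. = FALSE)
  novel_index <- as.integer(novel_index)
  if (novel_index == 1L || novel_index < 1L)
    stop("novel_index must be a variant index other than 1", call. = FALSE)
  structure(list(l = l, mu = mu, novel_index = novel_index),
            class = "learning_params")
}

#' Utter a variant
#'
#' Samples one variant index from an agent's usage distribution, consuming
#' exactly one uniform draw.
#'
#' @param usage numeric usage distribution.
#' @return integer variant index.
#' @examples
#' utter(c(1, 0))  # always 1
#' @export
utter <- function(usage) {
  validate_usage(usage)
  u <- runif(1)
  1L + findInterval(u, cumsum(usage)[-length(usage)])
}

#' Learning update after hearing a variant
#'
#' The heard variant's probability gains `(1 - p) * l`; every other variant
#' loses `p * l`.  The unit sum is conserved algebraically.
#'
#' @param usage usage distribution (vector), or a matrix of them (one agent
#'   per row, all updating toward the same heard variant).
#' @param heard index of the variant heard.
#' @param l learning weight in \[0, 1\].
#' @return updated distribution(s), same shape as `usage`.
#' @examples
#' update_usage(c(0.5, 0.5), heard = 2, l = 0.1)  # (0.45, 0.55)
#' @export
update_usage <- function(usage, heard, l) {
  if (!is.numeric(l) || length(l) != 1 || is.na(l) || l < 0 || l > 1)
    stop("learning weight l must lie in [0, 1]", call. = FALSE)
  vec <- is.null(dim(usage))
  P <- if (vec) matrix(usage, nrow = 1) else as.matrix(usage)
  validate_usage(P)
  heard <- as.integer(heard)
  if (heard < 1 || heard > ncol(P))
    stop("heard is not a legal variant index", call. = FALSE)
  P <- P * (1 - l)
  P[, heard] <- P[, heard] + l
  if (vec) drop(P) else P
}

#' One round of pairwise interactions
#'
#' Agents are paired by a uniformly random perfect matching (one uniformly
#' chosen agent idles when N is odd).  Within a pair both agents utter a
#' variant from their pre-round distributions, then both update toward the
#' partner's utterance via the learning rule.  Each agent interacts at most
#' once per round.  The round is neutral: it leaves the expected population
#' mean usage of every variant unchanged (see [expected_round_change()]).
#'
#' @param pop a `speaker_population` with at least two agents.
#' @param params a `learning_params` object (only `l` is used; innovation
#'   happens at demographic turnover, not during interaction).
#' @return the updated population.
#' @export
interaction_round <- function(pop, params) {
  if (n_agents(pop) < 2)
    stop("an interaction round needs at least two agents", call. = FALSE)
  pop$probs <- interaction_rounds_cpp(pop$probs, params$l, 1L)
  pop
}

#' Initialize a newborn L1 speaker
#'
#' A newborn averages the usage distributions of two distinct randomly
#' chosen 'parents', reflecting acquisition from a small number of native
#' models.
#'
#' @param parent_a,parent_b usage distributions of the two parents.
#' @return an agent state: list with `usage`, `speaker_class = "L1"`,
#'   `tenure_years = 0`.
#' @export
init_newborn <- function(parent_a, parent_b) {
  validate_usage(parent_a)
  validate_usage(parent_b)
  list(usage = (parent_a + parent_b) / 2, speaker_class = "L1",
       tenure_years = 0L)
}

#' Initialize a recruited L2 speaker
#'
#' A recruit averages the whole population (acquiring the language from many
#' models): its usage equals the population mean.  With probability `mu` it
#' instead innovates, entering with probability 1 on the novel variant.
#'
#' @param pop_mean population mean usage at recruitment time (the
#'   pre-turnover snapshot mean).
#' @param params a `learning_params` object providing `mu` and
#'   `novel_index`.
#' @return an agent state: list with `usage`, `speaker_class = "L2"`,
#'   `tenure_years = 0`, and logical `innovated`.
#' @export
init_recruit <- function(pop_mean, params) {
  validate_usage(pop_mean)
  innovated <- params$mu > 0 && runif(1) < params$mu
  usage <- if (innovated) indicator_usage(length(pop_mean),
                                          params$novel_index) else pop_mean
  list(usage = usage, speaker_class = "L2", tenure_years = 0L,
       innovated = innovated)
}

#' Replace an agent's usage by the novel-variant indicator
#'
#' The agent's usage becomes probability 1 on the novel variant and 0
#' elsewhere, discarding anything learned so far; speaker class and tenure
#' are untouched.  This is the innovation event of the SLA model.
#'
#' @param agent an agent state (list with at least `usage`).
#' @param novel_index index of the novel variant.
#' @return the agent with usage replaced.
#' @export
mutate_to_novel <- function(agent, novel_index = 2L) {
  agent$usage <- indicator_usage(length(agent$usage), novel_index)
  agent
}

indicator_usage <- function(n_variants, index) {
  u <- numeric(n_variants)
  u[index] <- 1
  u
}

#' Exact expected change in population mean usage over one round
#'
#' Enumerates every perfect matching of the agents (for odd N, every choice
#' of idle agent times every matching of the rest) and every joint utterance
#' outcome, weighting by matching and utterance probabilities, and returns
#' the expected post-round minus pre-round population mean usage per
#' variant.  The interaction dynamic is neutral, so this is zero for every
#' variant up to floating-point error — this function is the analytic check
#' of that property.  Intended for small populations (N <= 8).
#'
#' @param probs usage matrix, one agent per row.
#' @param l learning weight.
#' @return numeric vector of expected changes, one per variant.
#' @examples
#' P <- rbind(c(0.2, 0.8), c(0.7, 0.3), c(0.5, 0.5), c(1, 0))
#' expected_round_change(P, l = 0.05)  # ~ c(0, 0)
#' @export
expected_round_change <- function(probs, l) {
  probs <- as.matrix(probs)
  validate_usage(probs)
  N <- nrow(probs)
  nv <- ncol(probs)
  if (N < 2 || N > 8)
    stop("exact enumeration supports 2 <= N <= 8", call. = FALSE)
  pre <- colMeans(probs)
  post <- numeric(nv)

  enumerate_pairings <- function(ids) {
    # all perfect matchings of an even id set, as lists of 2-column rows
    if (length(ids) == 0) return(list(matrix(integer(0), 0, 2)))
    a <- ids[1]
    out <- list()
    for (j in seq_along(ids)[-1]) {
      rest <- enumerate_pairings(ids[-c(1, j)])
      out <- c(out, lapply(rest, function(m) rbind(c(a, ids[j]), m)))
    }
    out
  }

  idle_sets <- if (N %% 2 == 0) list(integer(0)) else as.list(seq_len(N))
  total_w <- 0
  for (idle in idle_sets) {
    ids <- setdiff(seq_len(N), idle)
    matchings <- enumerate_pairings(ids)
    w_match <- 1 / (length(idle_sets) * length(matchings))
    for (m in matchings) {
      npair <- nrow(m)
      # enumerate joint utterance outcomes across all pairs
      grids <- vector("list", 2L * npair)
      for (p in seq_len(npair)) {
        grids[[2 * p - 1]] <- seq_len(nv)
        grids[[2 * p]] <- seq_len(nv)
      }
      outcomes <- as.matrix(expand.grid(grids))
      for (row in seq_len(nrow(outcomes))) {
        P <- probs
        w <- w_match
        for (p in seq_len(npair)) {
          a <- m[p, 1]; b <- m[p, 2]
          ua <- outcomes[row, 2 * p - 1]; ub <- outcomes[row, 2 * p]
          w <- w * probs[a, ua] * probs[b, ub]
        }
        if (w == 0) next
        for (p in seq_len(npair)) {
          a <- m[p, 1]; b <- m[p, 2]
          ua <- outcomes[row, 2 * p - 1]; ub <- outcomes[row, 2 * p]
          P[a, ] <- update_usage(P[a, ], ub, l)
          P[b, ] <- update_usage(P[b, ], ua, l)
        }
        post <- post + w * colMeans(P)
        total_w <- total_w + w
      }
    }
  }
  # total_w sums to 1 up to floating error; no renormalization needed
  post - pre
}
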