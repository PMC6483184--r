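#' Generate beta-binomial speaker counts
#'
#' Emulates the structure assumed for the corpus data: each speaker has a
#' latent usage probability drawn from a beta distribution with the given
#' mean and concentration (`alpha + beta`), and produces a binomial count
#' of novel tokens.  Degenerate means 0 and 1 are allowed for boundary
#' tests.
#'
#' @param n_speakers number of speakers.
#' @param tokens tokens per speaker: a single value, a vector of length
#'   `n_speakers`, or `NULL` to draw uniformly from 5-40 (mimicking uneven
#'   interview yields).
#' @param mean target population mean usage in \[0, 1\].
#' @param concentration beta concentration `alpha + beta` (> 0, default 10:
#'   moderate speaker heterogeneity).
#' @param year recording year to stamp on the rows (default `NA`).
#' @param seed optional integer seed (set for a self-contained
#'   deterministic table; omit to use the ambient RNG stream).
#' @return a speaker-counts data.frame: `speaker_id`, `year`, `tokens`,
#'   `novel`.
#' @examples
#' counts <- generate_speaker_counts(50, tokens = 20, mean = 0.169,
#'                                   concentration = 10, seed = 1)
#' pooled_proportion(counts)
#' @export
generate_speaker_counts <- function(n_speakers, tokens = NULL, mean = 0.1,
                                    concentration = 10, year = NA_integer_,
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (mean < 0 || mean > 1) stop("mean must lie in [0, 1]", call. = FALSE)
  if (concentration <= 0) stop("concentration must be positive",
                               call. = FALSE)
  if (is.null(tokens)) tokens <- sample(5:40, n_speakers, replace = TRUE)
  if (length(tokens) == 1) tokens <- rep(tokens, n_speakers)
  if (length(tokens) != n_speakers || any(tokens < 1))
    stop("tokens must give at least one token per speaker", call. = FALSE)
  q <- if (mean == 0) rep(0, n_speakers)
       else if (mean == 1) rep(1, n_speakers)
       else rbeta(n_speakers, mean * concentration,
                  (1 - mean) * concentration)
  data.frame(speaker_id = sprintf("s%03d", seq_len(n_speakers)),
             year = year, tokens = as.integer(tokens),
             novel = rbinom(n_speakers, tokens, q))
}

#' Generate a multi-year synthetic corpus
#'
#' One [generate_speaker_counts()] call per row of `spec`, stacked.
#'
#' @param spec data.frame with columns `year`, `n_speakers`, `tokens`
#'   (`NA` for the 5-40 default sampler), `mean`, `concentration`.
#' @param seed optional integer seed for the whole corpus.
#' @return a speaker-counts data.frame.
#' @export
generate_corpus <- function(spec, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(seq_len(nrow(spec)), function(i) {
    tok <- spec$tokens[i]
    generate_speaker_counts(spec$n_speakers[i],
                            tokens = if (is.na(tok)) NULL else tok,
                            mean = spec$mean[i],
                            concentration = spec$concentration[i],
                            year = spec$year[i])
  })
  do.call(rbind, out)
}

#' Generate a synthetic census table
#'
#' Builds a census with phase-wise geometric growth: within each phase the
#' L1 and L2 counts grow by constant yearly factors reaching the phase
#' multiplier at the phase end.  Mimics the three-phase structure of the
#' Maputo table (see [maputo_census()] for the real one).
#'
#' @param start_l1,start_l2 initial class counts (> 0).
#' @param phases data.frame with columns `years` (phase length),
#'   `l1_mult`, `l2_mult` (growth multipliers over the phase).
#' @param start_year first census year (default 0).
#' @param every keep a row every `every` years (default: phase endpoints
#'   only, `every = NA`).
#' @return a census data.frame `year,l1_count,l2_count`.
#' @export
generate_census <- function(start_l1, start_l2, phases, start_year = 0L,
                            every = NA) {
  if (start_l1 <= 0 || start_l2 <= 0)
    stop("starting counts must be positive", call. = FALSE)
  year <- start_year; l1 <- start_l1; l2 <- start_l2
  rows <- list(data.frame(year = year, l1_count = l1, l2_count = l2))
  for (i in seq_len(nrow(phases))) {
    ny <- phases$years[i]
    f1 <- phases$l1_mult[i]^(1 / ny)
    f2 <- phases$l2_mult[i]^(1 / ny)
    for (y in seq_len(ny)) {
      l1 <- l1 * f1; l2 <- l2 * f2; year <- year + 1L
      keep <- y == ny || (!is.na(every) && y %% every == 0)
      if (keep)
        rows[[length(rows) + 1]] <- data.frame(year = year,
                                               l1_count = round(l1),
                                               l2_count = round(l2))
    }
  }
  out <- do.call(rbind, rows)
  validate_census(out)
  out
}
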