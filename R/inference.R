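#' Validate a speaker-counts table
#'
#' Speaker counts record, per speaker and recording year, the number of
#' tokens of the variable context (`tokens`) and how many of them used the
#' novel variant (`novel`).
#'
#' @param counts data.frame with columns `speaker_id`, `year`, `tokens`,
#'   `novel` (`speaker_id`/`year` optional for single-sample fits).
#' @return `counts`, invisibly.
#' @export
validate_speaker_counts <- function(counts) {
  if (!all(c("tokens", "novel") %in% names(counts)))
    stop("speaker counts need columns tokens and novel", call. = FALSE)
  bad <- which(counts$tokens < 1 | counts$novel < 0 |
                 counts$novel > counts$tokens)
  if (length(bad) > 0)
    stop(sprintf("invalid counts in row(s) %s: need 1 <= tokens and 0 <= novel <= tokens",
                 paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
  invisible(counts)
}

#' Pooled proportion of novel-variant tokens
#'
#' Total novel tokens over total tokens — the sample mean usage when all
#' tokens are pooled across speakers.
#'
#' @param counts a speaker-counts table.
#' @return pooled proportion in \[0, 1\].
#' @export
pooled_proportion <- function(counts) {
  validate_speaker_counts(counts)
  sum(counts$novel) / sum(counts$tokens)
}

#' Beta-binomial log-likelihood of speaker counts
#'
#' Each speaker's novel-token count is binomial with a speaker-specific
#' usage probability drawn from a Beta(alpha, beta) distribution, whose
#' mean `alpha / (alpha + beta)` is the population mean frequency of usage.
#' Computed via log-gamma (through `lbeta`/`lchoose`) for stability.
#'
#' @param counts a speaker-counts table.
#' @param alpha,beta positive shape parameters.
#' @return the log-likelihood (sum over speakers).
#' @export
betabinom_loglik <- function(counts, alpha, beta) {
  validate_speaker_counts(counts)
  if (!is.numeric(alpha) || !is.numeric(beta) || alpha <= 0 || beta <= 0)
    stop("alpha and beta must be positive", call. = FALSE)
  x <- counts$novel; n <- counts$tokens
  sum(lchoose(n, x) + lbeta(x + alpha, n - x + beta) - lbeta(alpha, beta))
}

# maximize the beta-binomial likelihood on (logit mean, log concentration)
# coordinates from several starts; returns list(alpha, beta, loglik).
# log-concentration is box-bounded at 15: beyond exp(15) the model is
# numerically indistinguishable from a plain binomial and the lbeta
# difference loses precision to cancellation.
optimize_betabinom <- function(counts, init = NULL) {
  x <- counts$novel; n <- counts$tokens
  negll <- function(th) {
    m <- stats::plogis(th[1]); conc <- exp(th[2])
    a <- m * conc; b <- (1 - m) * conc
    if (!is.finite(a) || !is.finite(b) || a <= 0 || b <= 0) return(1e10)
    v <- -sum(lchoose(n, x) + lbeta(x + a, n - x + b) - lbeta(a, b))
    if (!is.finite(v)) 1e10 else v
  }
  m0 <- sum(x) / sum(n)
  m0 <- min(max(m0, 1e-3), 1 - 1e-3)
  starts <- if (is.null(init))
    rbind(c(stats::qlogis(m0), log(5)),
          c(stats::qlogis(m0), log(20)),
          c(stats::qlogis(m0), log(200)),
          c(0, 0))
  else rbind(init)  # warm start (bootstrap refits from the full-data MLE)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      optim(starts[i, ], negll, method = "L-BFGS-B",
            lower = c(-30, -30), upper = c(30, 15),
            control = list(factr = 1e6, maxit = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("beta-binomial optimization failed", call. = FALSE)
  m <- stats::plogis(best$par[1]); conc <- exp(best$par[2])
  list(alpha = m * conc, beta = (1 - m) * conc, loglik = -best$value)
}

#' Maximum-likelihood beta-binomial fit of mean usage
#'
#' Fits the beta-binomial model to speaker counts by multi-start
#' quasi-Newton maximization on (logit mean, log concentration)
#' coordinates, and attaches a 95%
#' nonparametric bootstrap confidence interval for the mean (resampling
#' speakers, percentile method).  Datasets in which every speaker's count
#' is 0 (or saturated) get a boundary fit: mean 0 (or 1) with
#' `boundary = TRUE` and a degenerate interval.
#'
#' @param counts a speaker-counts table (>= 2 speakers).
#' @param bootstrap_reps bootstrap replicates for the CI (default 500; 0
#'   skips the interval).
#' @param conf confidence level (default 0.95).
#' @return an object of class `betabinom_fit`: list with `alpha`, `beta`,
#'   `mean`, `ci_lo`, `ci_hi`, `loglik`, `boundary`, `n_speakers`.
#' @export
fit_betabinom <- function(counts, bootstrap_reps = 500L, conf = 0.95) {
  validate_speaker_counts(counts)
  if (nrow(counts) < 2)
    stop("need at least two speakers to fit", call. = FALSE)
  if (sum(counts$novel) == 0 || all(counts$novel == counts$tokens)) {
    m <- if (sum(counts$novel) == 0) 0 else 1
    return(structure(list(alpha = NA_real_, beta = NA_real_, mean = m,
                          ci_lo = m, ci_hi = m, loglik = 0,
                          boundary = TRUE, n_speakers = nrow(counts)),
                     class = "betabinom_fit"))
  }
  opt <- optimize_betabinom(counts)
  est_mean <- opt$alpha / (opt$alpha + opt$beta)
  ci <- c(NA_real_, NA_real_)
  if (bootstrap_reps > 0) {
    warm <- c(stats::qlogis(est_mean), log(opt$alpha + opt$beta))
    xs <- counts$novel; ns <- counts$tokens
    boots <- vapply(seq_len(bootstrap_reps), function(i) {
      idx <- sample.int(length(xs), replace = TRUE)
      cc <- data.frame(tokens = ns[idx], novel = xs[idx])
      if (sum(cc$novel) == 0) return(0)
      if (all(cc$novel == cc$tokens)) return(1)
      o <- optimize_betabinom(cc, init = warm)
      o$alpha / (o$alpha + o$beta)
    }, numeric(1))
    ci <- unname(quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2)))
  }
  structure(list(alpha = opt$alpha, beta = opt$beta, mean = est_mean,
                 ci_lo = ci[1], ci_hi = ci[2], loglik = opt$loglik,
                 boundary = FALSE, n_speakers = nrow(counts)),
            class = "betabinom_fit")
}

#' @export
print.betabinom_fit <- function(x, ...) {
  cat(sprintf("<betabinom_fit> mean usage %.4f", x$mean))
  if (!is.na(x$ci_lo)) cat(sprintf(" [%.4f, %.4f]", x$ci_lo, x$ci_hi))
  if (x$boundary) cat(" (boundary)")
  cat(sprintf("\n  alpha = %.3g, beta = %.3g, loglik = %.3f, %d speakers\n",
              x$alpha, x$beta, x$loglik, x$n_speakers))
  invisible(x)
}

#' Fit beta-binomial means per recording year
#'
#' @param counts a speaker-counts table with a `year` column.
#' @param bootstrap_reps,conf passed to [fit_betabinom()].
#' @return data.frame with one row per year: `year`, `mle` (the fitted
#'   mean), `ci_lo`, `ci_hi`, plus the list of fits as attribute `fits`.
#' @export
fit_betabinom_by_year <- function(counts, bootstrap_reps = 500L,
                                  conf = 0.95) {
  if (!"year" %in% names(counts))
    stop("counts need a year column", call. = FALSE)
  years <- sort(unique(counts$year))
  fits <- lapply(years, function(y)
    fit_betabinom(counts[counts$year == y, , drop = FALSE],
                  bootstrap_reps = bootstrap_reps, conf = conf))
  out <- data.frame(year = years,
                    mle = vapply(fits, `[[`, numeric(1), "mean"),
                    ci_lo = vapply(fits, `[[`, numeric(1), "ci_lo"),
                    ci_hi = vapply(fits, `[[`, numeric(1), "ci_hi"))
  attr(out, "fits") <- fits
  out
}

#' Ensemble interval from replicate run values
#'
#' Treats the per-run values of a year statistic as draws from a normal
#' distribution and returns the sample mean with a 95% interval of
#' mean +/- 1.96 * sd.  The sd is the spread across runs, not a standard
#' error: the interval describes where a single run is expected to land.
#'
#' @param values numeric vector of per-run values (>= 2 for an interval).
#' @param conf confidence level (default 0.95).
#' @param warn_single warn when only one value is supplied (default TRUE).
#' @return named numeric vector `mean`, `sd`, `ci_lo`, `ci_hi`.
#' @export
ensemble_interval <- function(values, conf = 0.95, warn_single = TRUE) {
  if (length(values) < 1) stop("no values", call. = FALSE)
  if (length(values) < 2) {
    if (warn_single)
      warning("a single run gives no spread; interval undefined",
              call. = FALSE)
    return(c(mean = values, sd = NA_real_, ci_lo = NA_real_,
             ci_hi = NA_real_))
  }
  z <- qnorm(1 - (1 - conf) / 2)
  m <- mean(values); s <- sd(values)
  c(mean = m, sd = s, ci_lo = m - z * s, ci_hi = m + z * s)
}

get_summary <- function(x) {
  if (inherits(x, "shift_ensemble")) x$summary else x
}

#' Does an ensemble's interval cover the data MLEs in every year?
#'
#' The fit criterion: a parameter setting is a potential fit only if its
#' 95% ensemble interval contains the data's maximum-likelihood mean usage
#' in every observation year.
#'
#' @param ensemble a `shift_ensemble` or its summary data.frame
#'   (`year, mean, sd, ci_lo, ci_hi`).
#' @param mle_points data.frame with columns `year` and `mle`.
#' @return single logical.
#' @export
overlap_fit_check <- function(ensemble, mle_points) {
  summ <- get_summary(ensemble)
  rows <- match(mle_points$year, summ$year)
  if (anyNA(rows))
    stop(sprintf("ensemble does not cover year(s) %s",
                 paste(mle_points$year[is.na(rows)], collapse = ", ")),
         call. = FALSE)
  all(summ$ci_lo[rows] <= mle_points$mle &
        mle_points$mle <= summ$ci_hi[rows])
}

#' Mean squared distance between ensemble means and data MLEs
#'
#' @inheritParams overlap_fit_check
#' @return mean over observation years of squared (ensemble mean - MLE).
#' @export
ensemble_mse <- function(ensemble, mle_points) {
  summ <- get_summary(ensemble)
  rows <- match(mle_points$year, summ$year)
  if (anyNA(rows)) stop("ensemble does not cover all data years",
                        call. = FALSE)
  mean((summ$mean[rows] - mle_points$mle)^2)
}

#' Select the innovation rate with minimum MSE against the data
#'
#' @param sweep a `shift_sweep` (list of ensembles over a mu grid), or any
#'   named list of ensembles/summaries with attribute `mu_grid`.
#' @param mle_points data.frame with columns `year` and `mle`.
#' @return list with `mu` (selected rate), `index`, `mse` (vector over the
#'   grid), `ensemble` (the selected ensemble).  Ties go to the smaller mu.
#' @export
select_min_mse <- function(sweep, mle_points) {
  if (length(sweep) < 1) stop("empty candidate set", call. = FALSE)
  mu_grid <- attr(sweep, "mu_grid")
  if (is.null(mu_grid)) mu_grid <- as.numeric(names(sweep))
  mse <- vapply(sweep, ensemble_mse, numeric(1), mle_points = mle_points)
  ord <- order(mse, mu_grid)  # ties broken by smaller mu
  best <- ord[1]
  list(mu = mu_grid[best], index = best, mse = unname(mse),
       ensemble = sweep[[best]])
}

#' Joint tail probability of the data MLEs under an ensemble
#'
#' For each observation year, fits a normal to the replicate run values
#' (summarized as mean `m_y` and sd `s_y`) and computes the probability of
#' a value at least as extreme as the data MLE; years are treated as
#' independent conditional on the model, so the joint probability is the
#' product over years.
#'
#' @inheritParams overlap_fit_check
#' @param sided `"two"` (default) for `2 * min(Phi(z), 1 - Phi(z))` per
#'   year, or `"one"` for the one-sided tail `1 - Phi(|z|)`.
#' @return joint probability in (0, 1].
#' @export
joint_tail_probability <- function(ensemble, mle_points,
                                   sided = c("two", "one")) {
  sided <- match.arg(sided)
  summ <- get_summary(ensemble)
  rows <- match(mle_points$year, summ$year)
  if (anyNA(rows)) stop("ensemble does not cover all data years",
                        call. = FALSE)
  s <- summ$sd[rows]
  if (any(!is.finite(s) | s <= 0))
    stop("degenerate ensemble spread (sd <= 0) in a data year; ",
         "more replicate runs are needed", call. = FALSE)
  z <- (mle_points$mle - summ$mean[rows]) / s
  per_year <- if (sided == "two") 2 * pmin(pnorm(z), 1 - pnorm(z))
              else 1 - pnorm(abs(z))
  prod(per_year)
}
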