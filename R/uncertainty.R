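#' Specify Monte-Carlo parameter uncertainty
#'
#' Each rate parameter is perturbed independently around its point value with
#' a stated relative standard deviation, either as a truncated normal on the
#' percent scale or as a beta distribution on the fraction scale (moment
#' matched). Sampled entry shares are renormalised to sum to 100 and
#' discontinuation probabilities are re-derived, so every draw is a valid
#' parameter set.
#'
#' @param spread relative standard deviation of each parameter, percent of
#'   its point value (default 5).
#' @param draws number of Monte-Carlo draws (>= 2; default 1000).
#' @param family `"truncnorm"` (default) or `"beta"`.
#' @param level interval level (default 0.95, percentile method).
#' @param seed integer RNG seed; each draw index addresses its own substream
#'   so draws are order-independent.
#' @return An object of class `uncertainty_spec`.
#' @export
uncertainty_spec <- function(spread = 5, draws = 1000,
                             family = c("truncnorm", "beta"),
                             level = 0.95, seed = 1L) {
  family <- match.arg(family)
  stopifnot(spread >= 0, draws >= 2, level > 0, level < 1)
  structure(list(spread = spread, draws = as.integer(draws), family = family,
                 level = level, seed = as.integer(seed)),
            class = "uncertainty_spec")
}

# deterministic per-draw substream seed (kept inside 32-bit signed range)
draw_seed <- function(seed, draw_index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(draw_index) * 16807) %%
               2147483647)
}

perturb_value <- function(x, spread, family) {
  if (x == 0 || spread == 0) return(x)
  sd <- spread / 100 * x
  if (family == "truncnorm") {
    for (i in 1:100) {
      v <- stats::rnorm(1, x, sd)
      if (v >= 0 && v <= 100) return(v)
    }
    stop("could not draw a value in [0,100] around ", x, call. = FALSE)
  } else {
    m <- x / 100
    v <- (sd / 100)^2
    if (v >= m * (1 - m)) {
      stop("beta spread too large for value ", x, call. = FALSE)
    }
    k <- m * (1 - m) / v - 1
    100 * stats::rbeta(1, m * k, (1 - m) * k)
  }
}

#' Draw one perturbed parameter set
#'
#' Deterministic given `(spec$seed, draw_index)`. Entry shares, retention,
#' success, death, and the heroin-transition rate are perturbed; shares are
#' renormalised to sum to 100 and discontinuation is re-derived. Draws whose
#' derived discontinuation falls outside \[0,100\] are rejected and redrawn
#' (bounded retries).
#'
#' @param p the point-value `parameter_set`.
#' @param spec an `uncertainty_spec`.
#' @param draw_index positive integer identifying the draw.
#' @return A valid `parameter_set`; with `spread = 0`, `p` itself.
#' @export
sample_parameter_set <- function(p, spec, draw_index) {
  if (spec$spread == 0) return(p)
  set.seed(draw_seed(spec$seed, draw_index))
  for (attempt in 1:50) {
    q <- p
    q$entry_share[] <- vapply(p$entry_share, perturb_value, 0,
                              spread = spec$spread, family = spec$family)
    q$entry_share <- q$entry_share / sum(q$entry_share) * 100
    q$retention[] <- vapply(p$retention, perturb_value, 0,
                            spread = spec$spread, family = spec$family)
    q$success[] <- vapply(p$success, perturb_value, 0,
                          spread = spec$spread, family = spec$family)
    q$death[] <- vapply(p$death, perturb_value, 0,
                        spread = spec$spread, family = spec$family)
    q$heroin_transition <- perturb_value(p$heroin_transition, spec$spread,
                                         spec$family)
    q <- tryCatch(derive_discontinuation(q), error = function(e) NULL)
    if (!is.null(q)) return(q)
  }
  stop("over half the candidate draws were invalid; use a smaller spread",
       call. = FALSE)
}

eval_statistic <- function(q, factor, horizon, mode, outcome, statistic,
                           year, decade, window) {
  base <- run_scenario(q, 1, horizon, mode)
  alt <- run_scenario(q, factor, horizon, mode)
  switch(statistic,
    rel_change = {
      pc <- per_year_change(alt, base, outcome)
      pc$rel_change_pct[year]
    },
    abs_change = {
      pc <- per_year_change(alt, base, outcome)
      pc$abs_change[year]
    },
    decade_percent = decade_theta(alt, base, outcome, decade)$percent,
    cum_change = cumulative_window(alt, outcome, window[1], window[2]) -
      cumulative_window(base, outcome, window[1], window[2])
  )
}

#' Monte-Carlo interval for a scenario contrast
#'
#' Propagates parameter uncertainty through the model: for each draw, one
#' perturbed parameter set is used for BOTH the baseline and the scenario arm
#' (common random parameters), the contrast statistic is computed, and a
#' percentile interval is formed across draws. The point estimate always
#' comes from the unperturbed parameters.
#'
#' @param p the point-value `parameter_set`.
#' @param factor scenario coverage factor.
#' @param horizon model years.
#' @param mode `"fixed_shares"` or `"flow_based"`.
#' @param outcome `"deaths"`, `"heroin"` or `"abstinence"`.
#' @param statistic `"rel_change"` (per-year relative change, percent, at
#'   `year`), `"abs_change"` (per-year absolute change at `year`),
#'   `"decade_percent"` (decade theta x 10 at `decade`), or `"cum_change"`
#'   (cumulative absolute change over `window`).
#' @param spec an `uncertainty_spec`.
#' @param year,decade,window arguments of the chosen statistic.
#' @return An `interval_estimate`: `point`, `lower`, `upper`, `level`,
#'   `draws` (numeric vector of per-draw statistics), `n_failed`, `seed`.
#' @export
monte_carlo_comparison <- function(p, factor, horizon = 30,
                                   mode = c("fixed_shares", "flow_based"),
                                   outcome = c("deaths", "heroin", "abstinence"),
                                   statistic = c("rel_change", "abs_change",
                                                 "decade_percent", "cum_change"),
                                   spec = uncertainty_spec(),
                                   year = 1, decade = 1, window = c(1, 10)) {
  mode <- match.arg(mode)
  outcome <- match.arg(outcome)
  statistic <- match.arg(statistic)
  point <- eval_statistic(p, factor, horizon, mode, outcome, statistic,
                          year, decade, window)
  vals <- rep(NA_real_, spec$draws)
  n_failed <- 0L
  for (i in seq_len(spec$draws)) {
    vals[i] <- tryCatch({
      q <- sample_parameter_set(p, spec, i)
      eval_statistic(q, factor, horizon, mode, outcome, statistic,
                     year, decade, window)
    }, error = function(e) NA_real_)
    if (is.na(vals[i])) n_failed <- n_failed + 1L
  }
  if (n_failed > 0.1 * spec$draws) {
    stop(n_failed, " of ", spec$draws, " draws failed; check the spread",
         call. = FALSE)
  }
  ok <- vals[!is.na(vals)]
  alpha <- (1 - spec$level) / 2
  ci <- unname(stats::quantile(ok, c(alpha, 1 - alpha)))
  structure(list(point = point, lower = ci[1], upper = ci[2],
                 level = spec$level, draws = ok, n_failed = n_failed,
                 seed = spec$seed, statistic = statistic, outcome = outcome,
                 factor = factor),
            class = "interval_estimate")
}

#' @export
print.interval_estimate <- function(x, ...) {
  cat(sprintf("<interval_estimate> %s / %s, factor %.2f\n",
              x$outcome, x$statistic, x$factor))
  cat(sprintf("  point %.4f  %.0f%% CI [%.4f, %.4f]  (%d draws, %d failed)\n",
              x$point, 100 * x$level, x$lower, x$upper,
              length(x$draws), x$n_failed))
  invisible(x)
}
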