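check_comparable <- function(alt, base) {
  stopifnot(inherits(alt, "trajectory"), inherits(base, "trajectory"))
  if (alt$horizon != base$horizon) {
    stop("trajectories have different horizons (", alt$horizon, " vs ",
         base$horizon, ")", call. = FALSE)
  }
  if (alt$mode != base$mode) {
    stop("cross-mode comparisons are refused (", alt$mode, " vs ",
         base$mode, ")", call. = FALSE)
  }
}

#' Per-year scenario contrast
#'
#' Absolute change `alt - base` and relative change `(alt - base)/base * 100`
#' of a total outcome series, year by year. Positive values mean the
#' alternative scenario exceeds the baseline. Years where the baseline is
#' zero get `NA` relative change with `rel_defined = FALSE` rather than
#' NaN propagation.
#'
#' @param alt,base `trajectory` objects with equal horizon and mode
#'   (`base` is conventionally the factor-1 run of the same parameters).
#' @param outcome `"deaths"`, `"heroin"` or `"abstinence"`.
#' @return A tibble with columns `outcome`, `year`, `base`, `alt`,
#'   `abs_change`, `rel_change_pct`, `rel_defined`.
#' @export
per_year_change <- function(alt, base,
                            outcome = c("deaths", "heroin", "abstinence")) {
  outcome <- match.arg(outcome)
  check_comparable(alt, base)
  a <- outcome_series(base, outcome)
  b <- outcome_series(alt, outcome)
  defined <- a != 0
  rel <- ifelse(defined, (b - a) / a * 100, NA_real_)
  tibble::tibble(
    outcome = outcome,
    year = seq_len(alt$horizon),
    base = a, alt = b,
    abs_change = b - a,
    rel_change_pct = rel,
    rel_defined = defined
  )
}

#' Decade-level cumulative-change statistic
#'
#' For a decade d (years 10(d-1)+1 .. 10d) the statistic is the sum of the
#' per-year relative changes expressed as fractions,
#' \deqn{\theta_d = \sum_{t \in d} (B_t - A_t)/A_t,}
#' where B is the alternative and A the baseline series; the decade's
#' percentage change is defined as `theta * 10`, and the cumulative absolute
#' change is `sum(B_t - A_t)`.
#'
#' @param alt,base comparable `trajectory` objects (horizon >= 10 * decade).
#' @param outcome `"deaths"`, `"heroin"` or `"abstinence"`.
#' @param decade decade index (1 = years 1-10, 2 = 11-20, 3 = 21-30).
#' @return A one-row tibble: `outcome`, `decade`, `cumulative`, `theta`,
#'   `percent` (= `theta * 10`).
#' @export
decade_theta <- function(alt, base,
                         outcome = c("deaths", "heroin", "abstinence"),
                         decade) {
  outcome <- match.arg(outcome)
  check_comparable(alt, base)
  if (decade < 1 || alt$horizon < 10 * decade) {
    stop("decade ", decade, " outside horizon ", alt$horizon, call. = FALSE)
  }
  years <- (10 * (decade - 1) + 1):(10 * decade)
  a <- outcome_series(base, outcome)[years]
  b <- outcome_series(alt, outcome)[years]
  if (any(a == 0)) {
    stop("baseline outcome is zero within decade ", decade,
         "; theta undefined", call. = FALSE)
  }
  theta <- sum((b - a) / a)
  tibble::tibble(outcome = outcome, decade = as.integer(decade),
                 cumulative = sum(b - a), theta = theta,
                 percent = theta * 10)
}

#' Cumulative outcome over a year window
#'
#' Sum of a total outcome series over the inclusive window
#' `first_year..last_year`.
#'
#' @param traj a `trajectory`.
#' @param outcome `"deaths"`, `"heroin"` or `"abstinence"`.
#' @param first_year,last_year window bounds, `1 <= first <= last <= horizon`.
#' @return A single count.
#' @export
cumulative_window <- function(traj,
                              outcome = c("deaths", "heroin", "abstinence"),
                              first_year, last_year) {
  outcome <- match.arg(outcome)
  if (first_year < 1 || last_year > traj$horizon || first_year > last_year) {
    stop("invalid window [", first_year, ", ", last_year, "] for horizon ",
         traj$horizon, call. = FALSE)
  }
  sum(outcome_series(traj, outcome)[first_year:last_year])
}

#' Decade summary grid across scenarios
#'
#' Runs the baseline and each scenario factor and assembles the full
#' decade x scenario x outcome grid of cumulative changes and theta
#' statistics (the layout of a decade-summary table).
#'
#' @param p a `parameter_set`.
#' @param factors coverage factors to contrast with the factor-1 baseline;
#'   defaults to the six scenarios `(1.25, 1.5, 1.75, 0.75, 0.5, 0.25)`.
#' @param horizon model years (a multiple of 10; default 30).
#' @param mode advancement mode, see [run_scenario()].
#' @return A tibble with one row per outcome x decade x factor, columns
#'   `outcome`, `decade`, `factor`, `coverage_pct`, `cumulative`, `theta`,
#'   `percent`.
#' @export
decade_summary_grid <- function(p, factors = c(1.25, 1.5, 1.75, 0.75, 0.5, 0.25),
                                horizon = 30,
                                mode = c("fixed_shares", "flow_based")) {
  mode <- match.arg(mode)
  base <- run_scenario(p, 1, horizon, mode)
  n_dec <- horizon %/% 10
  rows <- list()
  for (f in factors) {
    alt <- run_scenario(p, f, horizon, mode)
    cov <- round_half_up(total_coverage(p) * f, 2)
    for (oc in c("deaths", "heroin", "abstinence")) {
      for (d in seq_len(n_dec)) {
        r <- decade_theta(alt, base, oc, d)
        r$factor <- f
        r$coverage_pct <- cov
        rows[[length(rows) + 1]] <- r
      }
    }
  }
  out <- do.call(rbind, rows)
  out[, c("outcome", "decade", "factor", "coverage_pct",
          "cumulative", "theta", "percent")]
}
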