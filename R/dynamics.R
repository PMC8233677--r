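#' Population target for a model year
#'
#' Prevalence of dependence is held constant, so the dependent population
#' follows demographic growth only. With a constant annual rate r the year-t
#' target is `initial_population * (1 + r)^(t - 1)`; with an explicit series
#' of per-year growth factors it is the cumulative product. Year 1 always
#' returns the initial population exactly.
#'
#' @param p a `parameter_set`.
#' @param year model year index (>= 1).
#' @return Population count (continuous).
#' @export
population_target <- function(p, year) {
  if (year < 1) stop("year must be >= 1", call. = FALSE)
  if (year == 1) return(p$initial_population)
  if (!is.null(p$growth$series)) {
    s <- p$growth$series
    if (length(s) < year - 1) {
      stop("growth series has ", length(s), " factors but year ", year,
           " needs ", year - 1, call. = FALSE)
    }
    p$initial_population * prod(s[seq_len(year - 1)])
  } else {
    p$initial_population * (1 + p$growth$rate / 100)^(year - 1)
  }
}

#' Calibrate a constant growth rate to a cumulative total
#'
#' Returns the annual rate (percent) whose compounding over `steps` annual
#' increments yields the given cumulative growth: e.g. 28.93% total growth
#' over 29 steps gives about 0.880%/yr.
#'
#' @param total_growth_pct cumulative percent growth over the whole window.
#' @param steps number of annual increments (29 for a 30-year run).
#' @return Annual growth rate in percent.
#' @export
calibrate_growth_rate <- function(total_growth_pct, steps = 29) {
  100 * ((1 + total_growth_pct / 100)^(1 / steps) - 1)
}

new_state <- function(year, stock) {
  structure(list(year = as.integer(year),
                 stock = stock[treatment_groups()]),
            class = "compartment_state")
}

#' Initial allocation of the dependent population
#'
#' Allocates the year-1 population across the four compartments by the annual
#' entry shares: `stock[g] = initial_population * entry_share[g] / 100`.
#'
#' @param p a `parameter_set`.
#' @return A `compartment_state` for year 1.
#' @export
initial_allocation <- function(p) {
  new_state(1L, p$initial_population * p$entry_share / 100)
}

#' Within-year outcome flows
#'
#' Computes the three modelled consequences on start-of-year stocks:
#' deaths per group (`stock * death% * mortality_scale`), abstinence events
#' per group (`stock * success%`), and heroin transitions from the untreated
#' compartment (`stock * gamma%`). Abstinence is an annual event counter and
#' does not remove persons from the stocks: the discontinuation derivation
#' leaves no residual outflow for abstainers, and total dependence grows at
#' the demographic rate.
#'
#' @param s a `compartment_state`.
#' @param p a `parameter_set`.
#' @return A list of class `annual_outcomes` with components `deaths` (named
#'   by group), `heroin_transitions` (scalar), `abstinence_events` (named by
#'   group).
#' @export
annual_outcomes <- function(s, p) {
  structure(list(
    deaths = s$stock * p$death / 100 * p$mortality_scale,
    heroin_transitions = unname(s$stock[["UNTREATED"]] * p$heroin_transition / 100),
    abstinence_events = s$stock * p$success / 100
  ), class = "annual_outcomes")
}

#' Advance one year, fixed-shares mode
#'
#' Quasi-static advancement for constant-coverage scenarios: the next year's
#' total is set to [population_target()] and reallocated across compartments
#' by the entry shares, so outcomes are independent of history and linear in
#' the coverage factor.
#'
#' @param s a `compartment_state`.
#' @param p a `parameter_set`.
#' @return The `compartment_state` for the next year.
#' @export
advance_fixed_shares <- function(s, p) {
  target <- population_target(p, s$year + 1)
  new_state(s$year + 1L, target * p$entry_share / 100)
}

#' Advance one year, flow-based mode
#'
#' Explicit stock-and-flow advancement. Within the year, each treated group's
#' start-of-year stock splits into stayers (retention for MMT/BMT, treatment
#' success for detoxification), deaths, and discontinuers who move to the
#' untreated pool at year end; the untreated compartment loses deaths and
#' heroin transitions. At the start of the next year the post-flow untreated
#' pool redistributes across all four compartments by the entry shares
#' (stayers remain in place), and finally the untreated compartment is topped
#' up -- never drawn down -- with new dependents so that the total matches
#' [population_target()] for the next year. The full flow ledger is attached
#' as attribute `"ledger"`.
#'
#' @param s a `compartment_state`.
#' @param p a `parameter_set`.
#' @return The next `compartment_state`, with a `"ledger"` attribute listing
#'   `deaths`, `heroin_transitions`, `stayers`, `discontinued`, `entries`,
#'   and `replenishment`.
#' @export
advance_flow_based <- function(s, p) {
  ms <- p$mortality_scale
  deaths <- s$stock * p$death / 100 * ms
  stay_pct <- c(MMT = p$retention[["MMT"]], BMT = p$retention[["BMT"]],
                DETOX = p$success[["DETOX"]])
  # outflow identity stay + death + discontinuation = 100 holds at ms = 1;
  # under a mortality_scale the death flow scales and the residual goes to
  # stayers so stocks never go negative
  stayers <- s$stock[TREATED] * stay_pct / 100 +
    s$stock[TREATED] * p$death[TREATED] / 100 * (1 - ms)
  discontinued <- s$stock[TREATED] * p$discontinuation[TREATED] / 100
  heroin <- s$stock[["UNTREATED"]] * p$heroin_transition / 100
  w_after <- s$stock[["UNTREATED"]] - deaths[["UNTREATED"]] - heroin
  if (w_after < -1e-9) {
    stop("untreated outflows exceed the untreated stock", call. = FALSE)
  }
  pool <- max(w_after, 0) + sum(discontinued)
  entries <- pool * p$entry_share / 100
  stock <- c(stayers, UNTREATED = 0)[treatment_groups()] + entries
  target <- population_target(p, s$year + 1)
  replenishment <- target - sum(stock)
  if (replenishment < -1e-6 * target) {
    stop("infeasible flow advance: total stocks ", format(sum(stock)),
         " exceed the population target ", format(target),
         " for year ", s$year + 1, call. = FALSE)
  }
  replenishment <- max(replenishment, 0)
  stock[["UNTREATED"]] <- stock[["UNTREATED"]] + replenishment
  out <- new_state(s$year + 1L, stock)
  attr(out, "ledger") <- list(
    deaths = deaths, heroin_transitions = unname(heroin),
    stayers = stayers, discontinued = discontinued,
    entries = entries, replenishment = unname(replenishment)
  )
  out
}

#' Run a coverage scenario
#'
#' Scales coverage by `factor`, allocates the initial population, and iterates
#' the annual cycle for `horizon` years: outcomes are computed on
#' start-of-year stocks, then the state is advanced. Deterministic given its
#' inputs.
#'
#' @param p a `parameter_set` (baseline coverage).
#' @param factor positive coverage multiplier (1 = status quo).
#' @param horizon number of model years (default 30).
#' @param mode `"fixed_shares"` (default; quasi-static, reproduces year-1
#'   quantities and is linear in the factor) or `"flow_based"` (explicit
#'   stock-and-flow dynamics).
#' @return A `trajectory` object: matrices `stocks`, `deaths`,
#'   `abstinence_events` (years x groups), vectors `heroin_transitions` and
#'   `population`, plus `scenario_factor`, `mode`, `horizon`.
#' @export
run_scenario <- function(p, factor = 1, horizon = 30,
                         mode = c("fixed_shares", "flow_based")) {
  mode <- match.arg(mode)
  if (horizon < 1) stop("horizon must be >= 1", call. = FALSE)
  ps <- scale_coverage(p, factor)
  groups <- treatment_groups()
  stocks <- deaths <- abst <- matrix(
    NA_real_, horizon, 4, dimnames = list(NULL, groups))
  heroin <- numeric(horizon)
  ledgers <- if (mode == "flow_based") vector("list", horizon - 1) else NULL
  s <- initial_allocation(ps)
  for (t in seq_len(horizon)) {
    o <- annual_outcomes(s, ps)
    stocks[t, ] <- s$stock
    deaths[t, ] <- o$deaths
    abst[t, ] <- o$abstinence_events
    heroin[t] <- o$heroin_transitions
    if (t < horizon) {
      s <- switch(mode,
                  fixed_shares = advance_fixed_shares(s, ps),
                  flow_based = advance_flow_based(s, ps))
      if (mode == "flow_based") ledgers[[t]] <- attr(s, "ledger")
    }
  }
  structure(list(
    scenario_factor = factor,
    mode = mode,
    horizon = as.integer(horizon),
    stocks = stocks,
    deaths = deaths,
    heroin_transitions = heroin,
    abstinence_events = abst,
    population = rowSums(stocks),
    ledgers = ledgers,
    parameters = ps
  ), class = "trajectory")
}

#' Extract a per-year total outcome series from a trajectory
#'
#' @param traj a `trajectory`.
#' @param outcome one of `"deaths"`, `"heroin"`, `"abstinence"`.
#' @return Numeric vector of length `horizon` (totals across groups).
#' @export
outcome_series <- function(traj, outcome = c("deaths", "heroin", "abstinence")) {
  outcome <- match.arg(outcome)
  switch(outcome,
         deaths = rowSums(traj$deaths),
         heroin = traj$heroin_transitions,
         abstinence = rowSums(traj$abstinence_events))
}

#' Tidy view of a trajectory
#'
#' One row per year x group with the stock and outcome flows, plus the
#' scenario factor and mode; heroin transitions are attributed to the
#' untreated group and zero elsewhere.
#'
#' @param x a `trajectory`.
#' @param ... unused.
#' @return A tibble with columns `year`, `group`, `stock`, `deaths`,
#'   `heroin_transitions`, `abstinence_events`, `scenario`, `mode`.
#' @export
as_tibble.trajectory <- function(x, ...) {
  groups <- treatment_groups()
  h <- x$horizon
  tibble::tibble(
    year = rep(seq_len(h), times = 4),
    group = rep(groups, each = h),
    stock = as.vector(x$stocks),
    deaths = as.vector(x$deaths),
    heroin_transitions = as.vector(
      vapply(groups, function(g)
        if (g == "UNTREATED") x$heroin_transitions else numeric(h),
        numeric(h))),
    abstinence_events = as.vector(x$abstinence_events),
    scenario = x$scenario_factor,
    mode = x$mode
  )
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %s mode, factor %.2f, %d years\n",
              x$mode, x$scenario_factor, x$horizon))
  cat(sprintf("  population %s -> %s\n",
              format(round(x$population[1]), big.mark = ","),
              format(round(x$population[x$horizon]), big.mark = ",")))
  cat(sprintf("  year 1: deaths %s, heroin %s, abstinence %s\n",
              format(round(sum(x$deaths[1, ])), big.mark = ","),
              format(round(x$heroin_transitions[1]), big.mark = ","),
              format(round(sum(x$abstinence_events[1, ])), big.mark = ",")))
  invisible(x)
}
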