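# Small parameter sets and trajectory builders used across the suite.

# Toy population of 3 persons split between MMT and the untreated group,
# with round rates chosen so the one-year flow ledger can be checked by hand.
toy_params <- function() {
  parameter_set(
    prevalence = 1, initial_population = 3,
    entry_share = c(MMT = 50, BMT = 0, DETOX = 0, UNTREATED = 50),
    retention = c(MMT = 50, BMT = 50),
    success = c(MMT = 20, BMT = 20, DETOX = 50, UNTREATED = 0),
    death = c(MMT = 10, BMT = 10, DETOX = 10, UNTREATED = 20),
    heroin_transition = 10,
    growth = 0
  )
}

# All mass untreated, every rate zero: a closed static system.
inert_params <- function(pop = 1000) {
  parameter_set(
    prevalence = 1, initial_population = pop,
    entry_share = c(MMT = 0, BMT = 0, DETOX = 0, UNTREATED = 100),
    retention = c(MMT = 100, BMT = 100),
    success = c(MMT = 0, BMT = 0, DETOX = 100, UNTREATED = 0),
    death = c(MMT = 0, BMT = 0, DETOX = 0, UNTREATED = 0),
    heroin_transition = 0,
    growth = 0
  )
}

# Minimal trajectory object wrapping given total outcome series (all totals
# carried in the MMT column / the heroin vector), for comparison-module tests
# that only consume outcome_series().
synthetic_trajectory <- function(deaths = NULL, heroin = NULL,
                                 abstinence = NULL, mode = "fixed_shares",
                                 factor = 2) {
  h <- max(length(deaths), length(heroin), length(abstinence))
  groups <- treatment_groups()
  mat <- function(x) {
    m <- matrix(0, h, 4, dimnames = list(NULL, groups))
    if (!is.null(x)) m[, 1] <- x
    m
  }
  structure(list(
    scenario_factor = factor, mode = mode, horizon = as.integer(h),
    stocks = mat(NULL), deaths = mat(deaths),
    heroin_transitions = if (is.null(heroin)) numeric(h) else heroin,
    abstinence_events = mat(abstinence),
    population = numeric(h), ledgers = NULL, parameters = NULL
  ), class = "trajectory")
}

table1_config_path <- function() {
  system.file("extdata", "table1_defaults.json", package = "opiumdyn",
              mustWork = TRUE)
}
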