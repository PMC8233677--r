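default_synth_ranges <- function() {
  list(
    prevalence = c(0.5, 5), pop = c(1e5, 2e6),
    theta = NULL,                       # NULL -> flat simplex x 100
    b_m = c(10, 60), b_b = c(10, 60),
    psi_m = c(5, 50), psi_b = c(5, 50), psi_d = c(2, 30), psi_w = c(0.2, 5),
    k_m = c(0.1, 5), k_b = c(0.1, 5), k_d = c(0.1, 5), k_w = c(0.5, 8),
    gamma_w = c(0.2, 5), beta = c(0, 2)
  )
}

runif_in <- function(r) if (r[1] == r[2]) r[1] else stats::runif(1, r[1], r[2])

#' Generate a random valid parameter set
#'
#' Draws entry shares from a flat simplex (scaled to percent), rates uniformly
#' within ranges constrained so that retention + death <= 100 (maintenance)
#' and success + death <= 100 (detoxification), then derives discontinuation.
#' The result always passes [validate_parameters()]. Ranges can be overridden
#' or pinned (`lo == hi`) per ascii symbol via `constraints`; pinning every
#' value to the packaged defaults reproduces them exactly.
#'
#' @param seed integer seed; same seed, same output.
#' @param constraints optional named list of `c(lo, hi)` ranges (keys:
#'   `prevalence`, `pop`, `theta_m`..`theta_w` — supplied jointly pins the
#'   shares —, `b_m`, `b_b`, `psi_m`..`psi_w`, `k_m`..`k_w`, `gamma_w`,
#'   `beta`).
#' @return A validated `parameter_set`.
#' @export
random_parameter_set <- function(seed, constraints = NULL) {
  set.seed(as.integer(seed))
  rg <- utils::modifyList(default_synth_ranges(), as.list(constraints)[
    intersect(names(constraints), names(default_synth_ranges()))])
  theta_keys <- c("theta_m", "theta_b", "theta_d", "theta_w")
  for (attempt in 1:100) {
    if (all(theta_keys %in% names(constraints))) {
      shares <- vapply(constraints[theta_keys], runif_in, 0)
    } else {
      e <- -log(stats::runif(4))            # flat Dirichlet(1,1,1,1)
      shares <- e / sum(e) * 100
    }
    names(shares) <- treatment_groups()
    if (abs(sum(shares) - 100) > 1e-9) {
      stop("theta constraints must keep shares summing to 100", call. = FALSE)
    }
    death <- c(MMT = runif_in(rg$k_m), BMT = runif_in(rg$k_b),
               DETOX = runif_in(rg$k_d), UNTREATED = runif_in(rg$k_w))
    retention <- c(MMT = runif_in(rg$b_m), BMT = runif_in(rg$b_b))
    success <- c(MMT = runif_in(rg$psi_m), BMT = runif_in(rg$psi_b),
                 DETOX = runif_in(rg$psi_d), UNTREATED = runif_in(rg$psi_w))
    if (retention[["MMT"]] + death[["MMT"]] > 100 ||
        retention[["BMT"]] + death[["BMT"]] > 100 ||
        success[["DETOX"]] + death[["DETOX"]] > 100) next
    p <- tryCatch(parameter_set(
      prevalence = runif_in(rg$prevalence),
      initial_population = round(runif_in(rg$pop)),
      entry_share = shares, retention = retention, success = success,
      death = death, heroin_transition = runif_in(rg$gamma_w),
      growth = runif_in(rg$beta)
    ), error = function(e) NULL)
    if (!is.null(p)) return(p)
  }
  stop("could not generate a valid parameter set under the given constraints",
       call. = FALSE)
}

#' Constraints pinning the generator to the packaged defaults
#'
#' @return A named list of degenerate ranges for [random_parameter_set()].
#' @export
table1_constraints <- function() {
  d <- table1_defaults()
  pin <- function(x) c(x, x)
  list(prevalence = pin(d$prevalence), pop = pin(d$initial_population),
       theta_m = pin(d$entry_share[["MMT"]]),
       theta_b = pin(d$entry_share[["BMT"]]),
       theta_d = pin(d$entry_share[["DETOX"]]),
       theta_w = pin(d$entry_share[["UNTREATED"]]),
       b_m = pin(d$retention[["MMT"]]), b_b = pin(d$retention[["BMT"]]),
       psi_m = pin(d$success[["MMT"]]), psi_b = pin(d$success[["BMT"]]),
       psi_d = pin(d$success[["DETOX"]]), psi_w = pin(d$success[["UNTREATED"]]),
       k_m = pin(d$death[["MMT"]]), k_b = pin(d$death[["BMT"]]),
       k_d = pin(d$death[["DETOX"]]), k_w = pin(d$death[["UNTREATED"]]),
       gamma_w = pin(d$heroin_transition), beta = pin(d$growth$rate))
}

#' Generate a random per-year demographic growth series
#'
#' Per-step growth factors `1 + rate/100` with optional normal jitter on the
#' rate; jitter 0 reduces to the constant rate. Factors are floored at a
#' small positive value.
#'
#' @param seed integer seed.
#' @param horizon number of annual steps (>= 1).
#' @param mean_rate mean annual growth rate, percent.
#' @param jitter standard deviation of the per-year rate, percent points.
#' @return Numeric vector of `horizon` positive growth factors.
#' @export
random_growth_series <- function(seed, horizon, mean_rate, jitter = 0) {
  if (horizon < 1) stop("horizon must be >= 1", call. = FALSE)
  set.seed(as.integer(seed))
  rates <- if (jitter == 0) rep(mean_rate, horizon)
           else stats::rnorm(horizon, mean_rate, jitter)
  pmax(1 + rates / 100, 1e-6)
}

#' Agent-based microsimulation of the treatment model
#'
#' Individual-level oracle for the deterministic dynamics: `n_agents` agents
#' undergo independent Bernoulli/multinomial transitions with the same annual
#' probabilities and the same within-year order (outcome events counted on
#' start-of-year groups, then end-of-year flows, then reallocation and
#' replenishment with new untreated agents). Aggregated counts are scaled by
#' `initial_population / n_agents` so the output is comparable to
#' [run_scenario()]. Abstinence is a counted event and does not change an
#' agent's state; death and heroin transition remove the agent.
#'
#' In `flow_based` mode each agent in a treated group draws one of
#' stay / die / discontinue (probabilities: retention -- or success for
#' detoxification -- death, discontinuation), and untreated agents draw
#' stay / die / heroin; discontinuers and staying untreated agents are then
#' reallocated by the entry shares. In `fixed_shares` mode the whole
#' next-year population is reallocated by the entry shares after deaths and
#' heroin removals, topping up (or trimming, for this quasi-static mode) to
#' the population target.
#'
#' @param p a `parameter_set`.
#' @param n_agents number of simulated agents (>= 1).
#' @param horizon number of model years.
#' @param seed integer seed; deterministic per seed.
#' @param mode `"fixed_shares"` or `"flow_based"`.
#' @return A `trajectory` (mode tagged `micro_<mode>`) with scaled stocks and
#'   outcome counts.
#' @export
microsimulate <- function(p, n_agents, horizon = 3, seed = 1,
                          mode = c("fixed_shares", "flow_based")) {
  mode <- match.arg(mode)
  stopifnot(n_agents >= 1, horizon >= 1)
  set.seed(as.integer(seed))
  groups <- treatment_groups()
  scale <- p$initial_population / n_agents
  ms <- p$mortality_scale
  # group id per agent, 1..4; start from entry-share multinomial
  g <- sample.int(4, n_agents, replace = TRUE, prob = p$entry_share)
  stocks <- deaths <- abst <- matrix(0, horizon, 4,
                                     dimnames = list(NULL, groups))
  heroin <- numeric(horizon)
  phi4 <- c(p$discontinuation, UNTREATED = 0)[groups]
  for (t in seq_len(horizon)) {
    n_g <- tabulate(g, 4)
    stocks[t, ] <- n_g * scale
    # one competing-event draw per agent for the removing/moving events:
    # die, then (treated) discontinue or (untreated) transition to heroin,
    # else stay -- same marginal probabilities as the deterministic rates.
    # Abstinence is a separate independent event draw that leaves the agent
    # in place.
    u <- stats::runif(length(g))
    p_die <- p$death[g] / 100 * ms
    p_leave <- ifelse(g == 4, p$heroin_transition / 100, phi4[g] / 100)
    dead <- u < p_die
    left <- !dead & u < p_die + p_leave          # discontinued or heroin
    abstained <- stats::runif(length(g)) < p$success[g] / 100
    deaths[t, ] <- tabulate(g[dead], 4) * scale
    abst[t, ] <- tabulate(g[abstained], 4) * scale
    heroin[t] <- sum(left & g == 4) * scale
    if (t == horizon) break
    target_n <- round(population_target(p, t + 1) / scale)
    if (mode == "flow_based") {
      keep <- !dead & !(g == 4 & left)           # heroin agents exit the model
      g2 <- g[keep]
      pool <- (g2 != 4 & left[keep]) | g2 == 4   # discontinuers + untreated
      if (any(pool)) {
        g2[pool] <- sample.int(4, sum(pool), replace = TRUE,
                               prob = p$entry_share)
      }
      topup <- target_n - length(g2)             # new dependents -> untreated
      if (topup > 0) g2 <- c(g2, rep(4L, topup))
      g <- g2
    } else {
      g <- sample.int(4, max(target_n, 0L), replace = TRUE,
                      prob = p$entry_share)
    }
  }
  structure(list(
    scenario_factor = 1, mode = paste0("micro_", mode),
    horizon = as.integer(horizon),
    stocks = stocks, deaths = deaths, heroin_transitions = heroin,
    abstinence_events = abst, population = rowSums(stocks),
    ledgers = NULL, parameters = p
  ), class = "trajectory")
}
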