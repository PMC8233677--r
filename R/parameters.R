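#' Treatment groups of the compartmental model
#'
#' The model partitions the opium-dependent population into four mutually
#' exclusive compartments: methadone maintenance treatment (`MMT`),
#' buprenorphine maintenance treatment (`BMT`), detoxification followed by
#' relapse-prevention care (`DETOX`), and people without treatment or in
#' non-evidence-based care (`UNTREATED`).
#'
#' @return Character vector of the four group labels, in canonical order.
#' @export
treatment_groups <- function() c("MMT", "BMT", "DETOX", "UNTREATED")

TREATED <- c("MMT", "BMT", "DETOX")

# ascii config key -> (field, group) lookup used by load_parameters()
PARAM_KEYS <- list(
  theta_m = c("entry_share", "MMT"),    theta_b = c("entry_share", "BMT"),
  theta_d = c("entry_share", "DETOX"),  theta_w = c("entry_share", "UNTREATED"),
  b_m     = c("retention", "MMT"),      b_b     = c("retention", "BMT"),
  psi_m   = c("success", "MMT"),        psi_b   = c("success", "BMT"),
  psi_d   = c("success", "DETOX"),      psi_w   = c("success", "UNTREATED"),
  phi_m   = c("discontinuation", "MMT"), phi_b  = c("discontinuation", "BMT"),
  phi_d   = c("discontinuation", "DETOX"),
  k_m     = c("death", "MMT"),          k_b     = c("death", "BMT"),
  k_d     = c("death", "DETOX"),        k_w     = c("death", "UNTREATED")
)

#' Round half away from zero
#'
#' Display rounding used throughout: ties go up in absolute value (the
#' convention of the source tables), unlike [base::round()]'s round-half-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Construct a model parameter set
#'
#' Builds and validates the full annual-probability parameter set of the
#' treatment model. All probabilities are stored on the percent scale, exactly
#' as tabulated, and converted to fractions only inside arithmetic.
#'
#' Discontinuation probabilities (transition to the untreated compartment at
#' year end) may be omitted; they are then derived by
#' [derive_discontinuation()] so that each treated group's annual outflow
#' percentages sum to exactly 100.
#'
#' @param prevalence prevalence of opium dependence in the 15-64 population,
#'   percent.
#' @param initial_population number of opium-dependent persons at model year 1.
#' @param entry_share named numeric vector (percent) over all four groups:
#'   annual share of the dependent population allocated to each compartment.
#'   Must sum to 100.
#' @param retention named numeric (percent) for `MMT` and `BMT`: probability of
#'   staying in maintenance treatment one full year.
#' @param success named numeric (percent) for all four groups: probability of
#'   illegal-opiate abstinence in the 12th month (treatment success).
#' @param death named numeric (percent) for all four groups: annual death
#'   probability.
#' @param heroin_transition annual probability (percent) that an untreated
#'   person transitions to heroin dependence.
#' @param growth demographic growth of the dependent population: either a
#'   single constant annual rate in percent, or a list with elements `rate`
#'   (percent) or `series` (per-year growth factors, e.g. `1.0088`). The
#'   default rate reproduces 28.93% cumulative growth over 29 annual steps.
#' @param discontinuation optional named numeric (percent) for the treated
#'   groups; derived if `NULL`.
#' @param mortality_scale dimensionless multiplier applied to all death
#'   probabilities (calibration hook), default 1.
#' @return An object of class `parameter_set`.
#' @seealso [table1_defaults()], [load_parameters()], [scale_coverage()]
#' @export
parameter_set <- function(prevalence, initial_population, entry_share,
                          retention, success, death, heroin_transition,
                          growth = default_growth_rate(),
                          discontinuation = NULL, mortality_scale = 1) {
  if (is.numeric(growth) && is.null(names(growth))) {
    growth <- list(rate = growth, series = NULL)
  }
  growth$rate <- if (is.null(growth$series)) growth$rate else NULL
  p <- structure(list(
    prevalence = as.numeric(prevalence),
    initial_population = as.numeric(initial_population),
    entry_share = entry_share[treatment_groups()],
    retention = retention[c("MMT", "BMT")],
    success = success[treatment_groups()],
    discontinuation = if (is.null(discontinuation)) NULL else
      discontinuation[TREATED],
    death = death[treatment_groups()],
    heroin_transition = as.numeric(heroin_transition),
    growth = growth,
    mortality_scale = as.numeric(mortality_scale)
  ), class = "parameter_set")
  if (is.null(p$discontinuation)) p <- derive_discontinuation(p)
  validate_parameters(p)
}

#' Default calibrated demographic growth rate
#'
#' Annual growth rate (percent) such that 29 annual increments produce 28.93%
#' cumulative growth of the dependent population over a 30-year run:
#' \eqn{100 \times (1.2893^{1/29} - 1)}.
#'
#' @return A single numeric percent value (about 0.88).
#' @export
default_growth_rate <- function() 100 * (1.2893^(1 / 29) - 1)

#' Validate a parameter set
#'
#' Checks range and consistency constraints: entry shares sum to 100 (within
#' 1e-9 on the percent scale), all probabilities lie in \[0, 100\], prevalence
#' in (0, 100), positive population, and the outflow-sum identities
#' `retention + death + discontinuation = 100` for the maintenance groups and
#' `success + death + discontinuation = 100` for detoxification.
#'
#' @param p a `parameter_set`.
#' @return `p` invisibly-validated (returned unchanged) or an error naming the
#'   offending symbol.
#' @export
validate_parameters <- function(p) {
  stopifnot(inherits(p, "parameter_set"))
  chk_range <- function(x, nm, lo = 0, hi = 100, open_lo = FALSE) {
    bad <- !is.finite(x) | x < lo | x > hi | (open_lo & x <= lo)
    if (any(bad)) {
      lab <- if (is.null(names(x))) nm else paste0(nm, "[", names(x)[bad], "]")
      stop("parameter out of range: ", paste(lab, collapse = ", "),
           " = ", paste(format(x[bad]), collapse = ", "), call. = FALSE)
    }
  }
  chk_range(p$prevalence, "prevalence", open_lo = TRUE)
  if (!is.finite(p$initial_population) || p$initial_population <= 0) {
    stop("initial_population must be > 0", call. = FALSE)
  }
  for (f in c("entry_share", "retention", "success", "discontinuation", "death")) {
    v <- p[[f]]
    if (anyNA(v)) stop("missing value in ", f, ": ",
                       paste(names(v)[is.na(v)], collapse = ", "), call. = FALSE)
    chk_range(v, f)
  }
  chk_range(p$heroin_transition, "heroin_transition")
  if (abs(sum(p$entry_share) - 100) > 1e-9) {
    stop("entry shares must sum to 100 (got ",
         format(sum(p$entry_share), digits = 15), ")", call. = FALSE)
  }
  for (g in c("MMT", "BMT")) {
    s <- p$retention[[g]] + p$death[[g]] + p$discontinuation[[g]]
    if (abs(s - 100) > 1e-9) {
      stop("outflow percentages for ", g, " must sum to 100 (got ",
           format(s, digits = 15), ")", call. = FALSE)
    }
  }
  sD <- p$success[["DETOX"]] + p$death[["DETOX"]] + p$discontinuation[["DETOX"]]
  if (abs(sD - 100) > 1e-9) {
    stop("outflow percentages for DETOX must sum to 100 (got ",
         format(sD, digits = 15), ")", call. = FALSE)
  }
  if (!is.null(p$growth$series)) {
    if (any(p$growth$series <= 0)) stop("growth series factors must be positive",
                                        call. = FALSE)
  } else if (!is.finite(p$growth$rate)) {
    stop("growth rate must be finite", call. = FALSE)
  }
  if (!is.finite(p$mortality_scale) || p$mortality_scale < 0) {
    stop("mortality_scale must be non-negative", call. = FALSE)
  }
  p
}

#' Derive annual discontinuation probabilities
#'
#' Each treated compartment's annual outflow percentages sum to 100: persons
#' either stay, die, or discontinue (transition to the untreated compartment
#' at year end). The "stay" quantity is one-year retention for the maintenance
#' groups but treatment success for detoxification -- the only reading that
#' closes the flow balance for all three treated groups. Hence
#' \deqn{\Phi_M = 100 - B_M - K_M,\quad \Phi_B = 100 - B_B - K_B,\quad
#'       \Phi_D = 100 - \Psi_D - K_D.}
#' No discontinuation is defined for the untreated compartment.
#'
#' The operation is idempotent: it recomputes the three values from retention,
#' success and death regardless of any values already present.
#'
#' @param p a `parameter_set` (possibly with `discontinuation` unset).
#' @return `p` with `discontinuation` filled in and re-validated.
#' @export
derive_discontinuation <- function(p) {
  phi <- c(
    MMT   = 100 - p$retention[["MMT"]] - p$death[["MMT"]],
    BMT   = 100 - p$retention[["BMT"]] - p$death[["BMT"]],
    DETOX = 100 - p$success[["DETOX"]] - p$death[["DETOX"]]
  )
  if (any(phi < 0 | phi > 100)) {
    stop("derived discontinuation outside [0,100] for ",
         paste(names(phi)[phi < 0 | phi > 100], collapse = ", "), call. = FALSE)
  }
  p$discontinuation <- phi
  validate_parameters(p)
}

#' Total annual treatment coverage
#'
#' Sum of the entry shares of the three evidence-based treatment compartments,
#' in percent of the dependent population (28.5 under the packaged defaults).
#'
#' @param p a `parameter_set`.
#' @return Coverage in percent.
#' @export
total_coverage <- function(p) sum(p$entry_share[TREATED])

#' Scale treatment coverage for a scenario
#'
#' Multiplies each treated entry share (MMT, BMT, DETOX) by `factor` and
#' absorbs the complement into the untreated share, preserving the relative
#' mix within treatment. A factor of 1.25 on the defaults raises total
#' coverage from 28.5% to 35.63%; 0.25 lowers it to 7.13%.
#'
#' @param p a `parameter_set`.
#' @param factor positive scenario multiplier on coverage.
#' @return A new validated `parameter_set`.
#' @export
scale_coverage <- function(p, factor) {
  if (!is.finite(factor) || factor <= 0) {
    stop("coverage factor must be > 0", call. = FALSE)
  }
  treated <- p$entry_share[TREATED] * factor
  if (sum(treated) > 100 + 1e-9) {
    stop("scenario infeasible: scaled treated shares sum to ",
         format(sum(treated), digits = 6), "% > 100%", call. = FALSE)
  }
  p$entry_share[TREATED] <- treated
  p$entry_share[["UNTREATED"]] <- 100 - sum(treated)
  validate_parameters(p)
}

#' Decompose total coverage into per-group entry shares
#'
#' Reproduces the arithmetic behind the default entry shares: a stated
#' fraction of total coverage belongs to detoxification/relapse prevention;
#' the remainder is maintenance treatment, split between MMT and BMT.
#' With total coverage 28.5%, detox fraction 8.5% and MMT fraction 79.42% of
#' maintenance, the shares are MMT 20.71%, BMT 5.37%, DETOX 2.42% (2-decimal
#' display rounding only; full precision is returned).
#'
#' @param total_coverage total treatment coverage, percent of dependents.
#' @param detox_fraction percent of total coverage belonging to the detox
#'   group.
#' @param mmt_fraction_of_maintenance percent of the maintenance total
#'   belonging to MMT.
#' @return Named numeric vector of shares (percent) for MMT, BMT, DETOX and
#'   UNTREATED (the complement to 100).
#' @export
coverage_decomposition <- function(total_coverage, detox_fraction,
                                   mmt_fraction_of_maintenance) {
  for (v in c(total_coverage, detox_fraction, mmt_fraction_of_maintenance)) {
    if (!is.finite(v) || v < 0 || v > 100) {
      stop("coverage decomposition inputs must lie in [0, 100]", call. = FALSE)
    }
  }
  detox <- total_coverage * detox_fraction / 100
  maintenance <- total_coverage - detox
  mmt <- maintenance * mmt_fraction_of_maintenance / 100
  bmt <- maintenance - mmt
  c(MMT = mmt, BMT = bmt, DETOX = detox,
    UNTREATED = 100 - total_coverage)
}

#' Packaged default parameter set
#'
#' The tabulated national parameter values for opium-dependence treatment in
#' Iran (2019 baseline): prevalence 2.06% of the 15-64 population, 1,180,553
#' dependents, entry shares 20.71/5.37/2.42/71.50, one-year retention 33.3%
#' (MMT) and 30.0% (BMT), success 27/26/10/1%, death 0.77/0.39/0.53/2.91%,
#' heroin transition 1.5%/yr from the untreated compartment. Discontinuation
#' probabilities are derived (65.93, 69.61, 89.47). Demographic growth
#' defaults to the calibrated [default_growth_rate()].
#'
#' @return A validated `parameter_set`.
#' @export
table1_defaults <- function() {
  load_parameters(system.file("extdata", "table1_defaults.json",
                              package = "opiumdyn", mustWork = TRUE))
}

#' Load a parameter set from a JSON configuration
#'
#' Reads a JSON document whose keys are the ascii parameter aliases
#' (`theta_m`, `theta_b`, `theta_d`, `theta_w`, `b_m`, `b_b`, `psi_m`,
#' `psi_b`, `psi_d`, `psi_w`, `k_m`, `k_b`, `k_d`, `k_w`, `gamma_w`, `beta`,
#' `pop`, `prevalence`, and optionally `phi_m`/`phi_b`/`phi_d`,
#' `mortality_scale`, `growth_series`). Missing discontinuation entries are
#' derived; any other missing required field is a configuration error naming
#' the field.
#'
#' @param config path to a JSON file, or an already-parsed named list.
#' @return A validated `parameter_set`.
#' @export
load_parameters <- function(config) {
  cfg <- if (is.character(config)) {
    jsonlite::read_json(config, simplifyVector = TRUE)
  } else {
    config
  }
  required <- c("prevalence", "pop", "theta_m", "theta_b", "theta_d", "theta_w",
                "b_m", "b_b", "psi_m", "psi_b", "psi_d", "psi_w",
                "k_m", "k_b", "k_d", "k_w", "gamma_w")
  missing <- setdiff(required, names(cfg))
  if (length(missing)) {
    stop("configuration missing required field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  field <- function(f) {
    keys <- names(PARAM_KEYS)[vapply(PARAM_KEYS, function(k) k[1] == f, TRUE)]
    out <- vapply(keys, function(k) {
      v <- cfg[[k]]
      if (is.null(v)) NA_real_ else as.numeric(v)
    }, 0)
    names(out) <- vapply(PARAM_KEYS[keys], `[`, "", 2)
    out
  }
  phi <- field("discontinuation")
  growth <- if (!is.null(cfg$growth_series)) {
    list(series = as.numeric(cfg$growth_series))
  } else if (!is.null(cfg$beta)) {
    list(rate = as.numeric(cfg$beta))
  } else {
    list(rate = default_growth_rate())
  }
  parameter_set(
    prevalence = cfg$prevalence,
    initial_population = cfg$pop,
    entry_share = field("entry_share"),
    retention = field("retention"),
    success = field("success"),
    death = field("death"),
    heroin_transition = cfg$gamma_w,
    growth = growth,
    discontinuation = if (anyNA(phi)) NULL else phi,
    mortality_scale = if (is.null(cfg$mortality_scale)) 1
                      else as.numeric(cfg$mortality_scale)
  )
}

#' @export
print.parameter_set <- function(x, ...) {
  cat("<parameter_set>\n")
  cat(sprintf("  population %s at prevalence %.2f%%\n",
              format(x$initial_population, big.mark = ","), x$prevalence))
  cat(sprintf("  coverage %.2f%%  (MMT %.2f | BMT %.2f | DETOX %.2f | UNTREATED %.2f)\n",
              round_half_up(total_coverage(x), 2),
              round_half_up(x$entry_share[["MMT"]], 2),
              round_half_up(x$entry_share[["BMT"]], 2),
              round_half_up(x$entry_share[["DETOX"]], 2),
              round_half_up(x$entry_share[["UNTREATED"]], 2)))
  cat(sprintf("  retention M/B %.1f/%.1f  success M/B/D/W %.1f/%.1f/%.1f/%.1f\n",
              x$retention[["MMT"]], x$retention[["BMT"]],
              x$success[["MMT"]], x$success[["BMT"]],
              x$success[["DETOX"]], x$success[["UNTREATED"]]))
  cat(sprintf("  discontinuation M/B/D %.2f/%.2f/%.2f  death M/B/D/W %.2f/%.2f/%.2f/%.2f\n",
              x$discontinuation[["MMT"]], x$discontinuation[["BMT"]],
              x$discontinuation[["DETOX"]],
              x$death[["MMT"]], x$death[["BMT"]], x$death[["DETOX"]],
              x$death[["UNTREATED"]]))
  g <- if (is.null(x$growth$series)) sprintf("constant %.4f%%/yr", x$growth$rate)
       else sprintf("explicit series (%d steps)", length(x$growth$series))
  cat(sprintf("  heroin transition %.2f%%/yr  growth %s\n",
              x$heroin_transition, g))
  invisible(x)
}
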