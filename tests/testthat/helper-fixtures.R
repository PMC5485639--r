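# Shared fixtures and independent oracles used across the suite.

# Published per-zone benchmarking values (top-decile mean, overall mean,
# absolute gap, integer percentage gap). Two cells are known not to
# recompute from the printed means because of upstream rounding: the
# rainfed absolute gap (printed 1666, arithmetic 1665) and the MRS
# percentage (printed 219, arithmetic 218); `gap_abs`/`gap_pct` here hold
# the exact arithmetic, `printed_*` the published integers.
table2_printed <- function() {
  tibble::tribble(
    ~zone,        ~top, ~overall, ~gap_abs, ~gap_pct, ~printed_abs, ~printed_pct,
    "lg",          597,      279,      318,      114,          318,          114,
    "mrd",         627,      213,      414,      194,          414,          194,
    "mrs",        1000,      314,      686,      218,          686,          219,
    "rainfed",    2304,      639,     1665,      261,         1666,          261,
    "irrigated",  2812,     1159,     1653,      143,         1653,          143
  )
}

# a survey population whose per-zone overall and top-decile means equal the
# published ones exactly: 10 farms per zone, the top farm at the top-decile
# mean and the other nine sharing the remainder of the zone total
table2_fixture_population <- function() {
  t2 <- table2_printed()
  rows <- purrr::pmap_dfr(t2, function(zone, top, overall, ...) {
    rest <- (10 * overall - top) / 9
    tibble::tibble(farm_id = paste0(zone, "_", 1:10), zone = zone,
                   milk_yield = c(rep(rest, 9), top))
  })
  survey_table(rows)
}

# published best modelled lactation yields and benchmark attainable yields
# for the two Indian zones, and the rainfed milk/profit rows used for the
# ranking-by-key property
table4_best_modelled <- function() {
  list(rainfed = list(best = 1990, attainable = 2304),
       irrigated = list(best = 2636, attainable = 2812))
}

table4_rainfed_rank_fixture <- function() {
  tibble::tibble(
    scenario = c("buffalo_high_concentrate", "crossbred_high_concentrate"),
    milk_per_cow_lactation = c(1796, 1990),
    milk_per_farm_year = c(3514, 3809),
    annual_profit = c(96639, 34543)
  )
}

# quadrature oracles for the normal/half-normal composed error, computed by
# numerical integration over u >= 0 (independent of the closed forms in the
# package)
oracle_density <- function(eps, sigma_sq, gamma) {
  sv <- sqrt((1 - gamma) * sigma_sq)
  su <- sqrt(gamma * sigma_sq)
  vapply(eps, function(e) {
    stats::integrate(function(u) dnorm(e - u, 0, sv) * 2 * dnorm(u, 0, su),
                     0, Inf, rel.tol = 1e-12)$value
  }, numeric(1))
}

oracle_te <- function(eps, sigma_sq, gamma) {
  sv <- sqrt((1 - gamma) * sigma_sq)
  su <- sqrt(gamma * sigma_sq)
  vapply(eps, function(e) {
    num <- stats::integrate(function(u)
      exp(-u) * dnorm(e - u, 0, sv) * 2 * dnorm(u, 0, su),
      0, Inf, rel.tol = 1e-12)$value
    den <- stats::integrate(function(u)
      dnorm(e - u, 0, sv) * 2 * dnorm(u, 0, su),
      0, Inf, rel.tol = 1e-12)$value
    num / den
  }, numeric(1))
}

# a minimal frontier_fit-shaped object for testing the z-test band mapping
# at chosen (gamma, se) without refitting
fit_stub <- function(gamma, se_gamma) {
  structure(list(gamma = gamma,
                 std_errors = c(gamma = se_gamma)),
            class = "frontier_fit")
}

# short-horizon copy of a shipped scenario, for fast dynamic tests
short_scenario <- function(region = "ethiopia_mrd", scenario = "baseline",
                           horizon = 120) {
  cfg <- gen_fixtures(region)[[scenario]]
  cfg$horizon <- horizon
  cfg
}
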