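#' Run a household dairy simulation
#'
#' Advances a cohort-structured herd month by month over the configured
#' horizon (default 20 years). Each month: feeds are allocated from
#' on-farm stocks (with purchases for purchasable feeds), milk production
#' and liveweight change follow the energy/protein allowances, breeders
#' conceive/calve and all stock face condition-dependent mortality, and
#' the management rules (male sales, replacements, culling, breeder
#' bounds) are applied. Annual profit is income from milk and livestock
#' sales minus purchased feed and health/mating costs.
#'
#' Dynamics are deterministic expected-value by default (continuous
#' cohorts); `stochastic = TRUE` draws integer demographic events from a
#' seeded generator. Summary statistics average the final years after a
#' burn-in (default 5 years) so the herd has equilibrated from its
#' arbitrary starting state.
#'
#' @param config A [scenario_config()] (validated before the loop).
#' @param seed Integer seed for the stochastic mode.
#' @param stochastic Draw integer demographic events instead of using
#'   expected values.
#' @param burn_in Months excluded from the summary (default 60).
#' @returns An object of class `simulation_result`: `summary` (one-row
#'   tibble: `herd_size`, `calving_interval`, `milk_per_cow_lactation`,
#'   `milk_per_cow_year`, `milk_per_farm_year`, `turnoff`,
#'   `mortality_pct`, `annual_profit`), `trace` (monthly tibble),
#'   `feed_trace` (per-feed monthly mass balance), `config`.
#' @export
#' @examples
#' cfg <- gen_fixtures("ethiopia_mrs")$baseline
#' cfg$horizon <- 120
#' res <- run_scenario(cfg)
#' tidy(res)
run_scenario <- function(config, seed = NULL, stochastic = FALSE,
                         burn_in = 60) {
  validate_scenario(config)
  if (!is.null(seed)) set.seed(seed)
  breed <- config$breed
  srw <- breed$mature_weight
  days <- .kc$days
  horizon <- config$horizon
  stopifnot(burn_in < horizon)

  n0 <- config$init_breeders
  ch <- new_cohorts(
    class = c("breeder", "heifer"),
    count = c(n0, max(0.3 * n0, 0.5)),
    age = c(48, breed$age_first_mating / 2),
    weight = c(0.9 * srw, target_weight(breed$age_first_mating / 2, breed)),
    lact = 0L, preg = 0L)

  feed_names <- names(config$feeds)
  stocks <- stats::setNames(numeric(length(feed_names)), feed_names)
  trace_cols <- c("month", "cal_month", "opening", "births", "deaths",
                  "sold_head", "closing", "herd_total", "breeders",
                  "heifers", "calvings", "milk_kg", "milk_rev",
                  "sales_rev", "feed_cost", "health_cost",
                  "sold_male_calf", "sold_growing_male",
                  "sold_female_calf", "sold_heifer", "sold_cull",
                  "me_mj", "milk_mj", "mobil_mj", "maint_mj", "preg_mj",
                  "breeder_condition")
  trace_m <- matrix(NA_real_, horizon, length(trace_cols),
                    dimnames = list(NULL, trace_cols))
  feed_m <- vector("list", horizon)
  price_vec <- unlist(config$animal_prices[c("male_calf", "growing_male",
                                             "female_calf", "heifer",
                                             "cull")])

  for (t in seq_len(horizon)) {
    m <- (t - 1L) %% 12L + 1L
    opening <- sum(ch$count)
    counts <- count_by_class(ch)

    al <- .allocate_core(counts, config$ration, config$feeds, stocks, m)
    stocks <- al$stocks

    # energy, milk and liveweight; calves below weaning age are reared
    # outside the feed budget (residual suckling/roughage) at half
    # potential growth
    is_calf <- (ch$class == "female_calf" | ch$class == "male_calf") &
      ch$age < .kc$weaning
    me_hd <- al$me[ch$class]
    cp_hd <- al$cp[ch$class]
    me_hd[is_calf | is.na(me_hd)] <- 0
    cp_hd[is_calf | is.na(cp_hd)] <- 0

    fed <- which(!is_calf)
    step <- .milk_step(ch$weight[fed], ch$lact[fed], me_hd[fed],
                       cp_hd[fed], breed, ch$preg[fed])
    ch$weight[fed] <- ch$weight[fed] + step$delta_weight * days
    ch$weight[is_calf] <- ch$weight[is_calf] +
      0.5 * breed$growth_rate_potential * days
    adult <- ch$class == "breeder"
    ch$weight[adult] <- pmin(pmax(ch$weight[adult], 0.4 * srw), 1.1 * srw)
    ch$weight[!adult] <- pmin(pmax(ch$weight[!adult],
                                   0.8 * breed$birth_weight), srw)

    cnt_fed <- ch$count[fed]
    milk_kg <- sum(step$milk * cnt_fed) * days
    br_rows <- which(adult)
    cond <- if (length(br_rows))
      sum(ch$weight[br_rows] * ch$count[br_rows]) /
        (sum(ch$count[br_rows]) * srw) else NA_real_

    rm_ <- reproduction_and_mortality_step(ch, breed,
                                           config$base_mortality,
                                           stochastic)
    ch <- rm_$cohorts
    mg <- herd_management_step(ch, config)
    ch <- mg$cohorts

    closing <- sum(ch$count)
    counts_end <- count_by_class(ch)
    sales_rev <- sum(mg$sales * price_vec)
    health <- config$health_mating_cost / 12 * closing

    trace_m[t, ] <- c(
      t, m, opening, rm_$births, rm_$deaths, mg$sold_head, closing,
      closing, counts_end[["breeder"]], counts_end[["heifer"]],
      rm_$calvings, milk_kg, milk_kg * config$milk_price, sales_rev,
      al$cost, health, mg$sales,
      sum(me_hd[fed] * cnt_fed) * days,
      sum(step$milk_mj * cnt_fed) * days,
      sum(step$mobilized_mj * cnt_fed) * days,
      sum(step$maintenance * cnt_fed) * days,
      sum(step$pregnancy * cnt_fed) * days,
      cond)
    feed_m[[t]] <- al$balance
  }

  trace <- tibble::as_tibble(trace_m)
  feed_trace <- tibble::as_tibble(do.call(rbind, feed_m))
  feed_trace$feed <- rep(feed_names, horizon)
  feed_trace$month <- rep(seq_len(horizon), each = length(feed_names))

  win <- trace[trace$month > burn_in, ]
  yrs <- nrow(win) / 12
  mean_breeders <- mean(win$breeders)
  herd_size <- mean(win$herd_total)
  calvings_yr <- sum(win$calvings) / yrs
  milk_farm <- sum(win$milk_kg) / yrs
  ci <- if (calvings_yr > 0) 12 * mean_breeders / calvings_yr else Inf
  milk_cow_yr <- if (mean_breeders > 0) milk_farm / mean_breeders else 0
  milk_lact <- if (calvings_yr > 0) milk_farm / calvings_yr else 0
  year_id <- (win$month - 1) %/% 12
  profit_yr <- vapply(split(win, year_id), annual_economics, numeric(1),
                      config = config)

  summary <- tibble::tibble(
    region = config$region, scenario = config$scenario,
    currency = config$currency,
    herd_size = herd_size, calving_interval = ci,
    milk_per_cow_lactation = milk_lact, milk_per_cow_year = milk_cow_yr,
    milk_per_farm_year = milk_farm,
    turnoff = sum(win$sold_head) / yrs,
    mortality_pct = 100 * sum(win$deaths) / yrs / herd_size,
    annual_profit = mean(profit_yr))

  structure(list(summary = summary, trace = trace,
                 feed_trace = feed_trace, config = config),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("Household dairy simulation: %s / %s (%d months)\n",
              x$config$region, x$config$scenario, x$config$horizon))
  print(x$summary)
  invisible(x)
}

#' @rdname run_scenario
#' @param x A `simulation_result`.
#' @param ... Unused.
#' @method tidy simulation_result
#' @export
tidy.simulation_result <- function(x, ...) x$summary

#' @rdname run_scenario
#' @method glance simulation_result
#' @export
glance.simulation_result <- function(x, ...) {
  dplyr::select(x$summary, "herd_size", "calving_interval",
                "milk_per_farm_year", "annual_profit")
}

#' Plot the monthly herd and milk trajectory
#'
#' @param x A `simulation_result`.
#' @param ... Unused.
#' @returns A ggplot object: herd size, breeders and monthly milk over
#'   the simulation.
#' @method autoplot simulation_result
#' @export
autoplot.simulation_result <- function(x, ...) {
  tr <- x$trace
  long <- tidyr::pivot_longer(
    tr[, c("month", "herd_total", "breeders", "milk_kg")],
    -"month", names_to = "series", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$month, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~series, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "simulation month", y = NULL,
                  title = paste(x$config$region, x$config$scenario)) +
    ggplot2::theme_minimal()
}

#' Run every scenario of a region
#'
#' Runs the baseline and each intervention configuration and stacks their
#' summaries, preserving the library's scenario order. Simulation errors
#' are re-raised with the scenario label attached.
#'
#' @param configs Named list of [scenario_config()] (e.g. one element of
#'   [scenario_library()]).
#' @param seed,stochastic,burn_in Passed to [run_scenario()].
#' @returns A tibble of summaries, one row per scenario, in input order.
#' @export
run_region <- function(configs, seed = NULL, stochastic = FALSE,
                       burn_in = 60) {
  rows <- purrr::imap(configs, function(cfg, nm) {
    tryCatch(tidy(run_scenario(cfg, seed = seed, stochastic = stochastic,
                               burn_in = burn_in)),
             error = function(e) {
               abort(paste0("scenario '", nm, "': ", conditionMessage(e)),
                     parent = e)
             })
  })
  dplyr::bind_rows(rows)
}
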