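#' Compare modelled yields with the benchmarked attainable yield
#'
#' Integrates the two strands of the analysis: the best simulated
#' per-lactation milk yield across a region's scenarios is expressed as a
#' percentage of the benchmark attainable yield (the top-decile mean from
#' the survey). A flag marks regions where combined interventions push
#' modelled production past what the top producers currently achieve.
#' Note the caveat that modelled households and surveyed households may
#' come from different states within a region; the comparison is
#' indicative, not a like-for-like ratio.
#'
#' @param results Tibble of scenario summaries ([run_region()] output or
#'   equivalent with `scenario` and `milk_per_cow_lactation` columns).
#' @param benchmark One row of a [benchmark_yield_gaps()] result (or any
#'   list with `zone` and `top_decile_mean`).
#' @returns A one-row tibble of class `gap_report`: `region`, `zone`,
#'   `attainable_yield`, `best_modelled_yield`, `best_scenario`,
#'   `modelled_over_attainable` (unrounded %),
#'   `modelled_over_attainable_pct` (integer display value),
#'   `exceeds_attainable`. The per-scenario table is kept in attribute
#'   `scenarios`.
#' @export
#' @examples
#' gap_report(
#'   tibble::tibble(region = "india_rainfed", scenario = "best",
#'                  milk_per_cow_lactation = 1990),
#'   list(zone = "rainfed", top_decile_mean = 2304))
gap_report <- function(results, benchmark) {
  attainable <- benchmark$top_decile_mean
  if (is.null(attainable) || !is.finite(attainable) || attainable <= 0) {
    abort("attainable yield must be positive",
          class = "dairygap_validation_error")
  }
  stopifnot("milk_per_cow_lactation" %in% names(results),
            nrow(results) >= 1)
  best_i <- which.max(results$milk_per_cow_lactation)
  best <- results$milk_per_cow_lactation[best_i]
  ratio <- 100 * best / attainable
  out <- tibble::tibble(
    region = if ("region" %in% names(results))
      results$region[best_i] else NA_character_,
    zone = benchmark$zone %||% NA_character_,
    attainable_yield = attainable,
    best_modelled_yield = best,
    best_scenario = if ("scenario" %in% names(results))
      results$scenario[best_i] else NA_character_,
    modelled_over_attainable = ratio,
    modelled_over_attainable_pct = round_half_up(ratio),
    exceeds_attainable = best > attainable)
  attr(out, "scenarios") <- results
  class(out) <- c("gap_report", class(out))
  out
}

#' Rank intervention scenarios by milk or profit
#'
#' Stable descending sort of scenario summaries by the chosen key, with
#' both the milk and the profit ranking reported side by side — the
#' interventions with the highest milk yields are not always the most
#' profitable.
#'
#' @param results Tibble of scenario summaries with `scenario`,
#'   `milk_per_farm_year` and `annual_profit` columns (>= 2 rows).
#' @param key Ranking key.
#' @returns `results` with `rank_milk` and `rank_profit` columns,
#'   arranged by the chosen key (descending, stable).
#' @export
rank_interventions <- function(results,
                               key = c("milk_per_farm_year",
                                       "annual_profit")) {
  key <- match.arg(key)
  stopifnot(nrow(results) >= 2)
  rank_of <- function(v) {
    # stable descending rank: ties keep input order
    ord <- order(-v, seq_along(v))
    rk <- integer(length(v))
    rk[ord] <- seq_along(v)
    rk
  }
  out <- results
  out$rank_milk <- rank_of(results$milk_per_farm_year)
  out$rank_profit <- rank_of(results$annual_profit)
  out[order(out[[if (key == "milk_per_farm_year") "rank_milk" else
    "rank_profit"]]), ]
}
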