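#' Select the top decile of milk yields
#'
#' Returns the ceiling(n/10) largest values of a yield vector, i.e. the
#' "top 10% most productive farms" with at least one farm kept in small
#' groups. Ties at the cutoff are broken by taking the earliest-indexed
#' records, so the selection always has exactly ceiling(n/10) elements and
#' is reproducible.
#'
#' @param yields Numeric vector of per-head milk yields (finite, >= 0).
#' @returns The selected yields, with the chosen indices in attribute
#'   `indices`.
#' @export
#' @examples
#' select_top_decile(1:10)   # -> 10
#' select_top_decile(rep(5, 15))  # ties: first two records
select_top_decile <- function(yields) {
  if (length(yields) == 0L) {
    abort("empty yield vector", class = "dairygap_empty_input_error")
  }
  stopifnot(all(is.finite(yields)), all(yields >= 0))
  k <- ceiling(length(yields) / 10)
  idx <- order(-yields, seq_along(yields))[seq_len(k)]
  structure(yields[idx], indices = idx)
}

#' Compute the relative yield gap for one group of farms
#'
#' The attainable yield is the mean of the top decile ([select_top_decile()]);
#' the gap is its difference from the overall mean, absolute
#' (kg/head/lactation) and as a percentage increase over the overall mean.
#' The reported percentage (`gap_pct_rounded`) rounds half away from zero
#' to the nearest integer; the unrounded value is kept in `gap_pct`.
#'
#' If the overall mean is zero the percentage is undefined: `gap_pct`
#' is returned as `NA` with a warning while `gap_abs` is still computed.
#'
#' @param table A `survey_df` (or any data frame with the yield column).
#' @param yield_col Name of the yield column.
#' @returns One-row tibble: `zone`, `n`, `top_decile_mean`, `overall_mean`,
#'   `gap_abs`, `gap_pct`, `gap_pct_rounded`.
#' @export
#' @examples
#' compute_yield_gap(survey_table(data.frame(milk_yield = 1:10)))
compute_yield_gap <- function(table, yield_col = "milk_yield") {
  y <- table[[yield_col]]
  if (is.null(y) || length(y) == 0L) {
    abort("no yield values", class = "dairygap_empty_input_error")
  }
  top <- select_top_decile(y)
  overall <- mean(y)
  top_mean <- mean(top)
  gap_abs <- top_mean - overall
  if (overall > 0) {
    gap_pct <- 100 * gap_abs / overall
  } else {
    warn("overall mean is zero: gap percentage undefined")
    gap_pct <- NA_real_
  }
  zone <- if ("zone" %in% names(table)) unique(table$zone) else "all"
  if (length(zone) != 1L) zone <- paste(sort(zone), collapse = "+")
  tibble::tibble(
    zone = zone, n = length(y),
    top_decile_mean = top_mean, overall_mean = overall,
    gap_abs = gap_abs, gap_pct = gap_pct,
    gap_pct_rounded = round_half_up(gap_pct)
  )
}

#' Benchmark yield gaps for every zone in a survey
#'
#' Runs [compute_yield_gap()] on each zone partition of the table and
#' stacks the results, one row per zone in lexicographic zone order
#' (deterministic under record permutation).
#'
#' @param table A `survey_df` with a `zone` column.
#' @returns A tibble of class `benchmark_df`, one row per zone.
#' @export
benchmark_yield_gaps <- function(table) {
  groups <- group_by_zone(table)
  out <- dplyr::bind_rows(lapply(groups, compute_yield_gap))
  class(out) <- c("benchmark_df", class(out))
  out
}

#' Plot benchmarked attainable versus mean yields by zone
#'
#' @param x A `benchmark_df` from [benchmark_yield_gaps()].
#' @param ... Unused.
#' @returns A ggplot object: paired bars of overall and top-decile mean
#'   yield per zone, annotated with the percentage gap.
#' @method autoplot benchmark_df
#' @export
autoplot.benchmark_df <- function(x, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(x)[, c("zone", "overall_mean", "top_decile_mean")],
    -"zone", names_to = "measure", values_to = "yield")
  long$measure <- factor(long$measure,
                         levels = c("overall_mean", "top_decile_mean"),
                         labels = c("all farms", "top 10% farms"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$zone, y = .data$yield,
                                     fill = .data$measure)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "agricultural zone",
                  y = "milk yield (kg/head/lactation)", fill = NULL) +
    ggplot2::theme_minimal()
}
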