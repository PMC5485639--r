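#' Construct a farm survey table
#'
#' A survey table is a tibble with one row per surveyed household carrying a
#' `farm_id`, a `zone` label, a per-head milk yield (`milk_yield`, kg per
#' head per lactation) and, optionally, named farm output and input
#' quantity columns used by the frontier stage. The output/input column
#' names are recorded as attributes so downstream code does not have to
#' guess roles.
#'
#' @param df A data frame containing at least the yield column.
#' @param farm_id,zone,milk_yield Column names (strings) holding the farm
#'   identifier, zone label and per-head milk yield. Missing `farm_id` or
#'   `zone` columns are synthesised (`farm_1...`, `"all"`).
#' @param outputs,inputs Character vectors naming output and input quantity
#'   columns (may be empty).
#' @returns A tibble of class `survey_df` with attributes `output_names`
#'   and `input_names`. Rows with missing or negative values in any mapped
#'   column are dropped; the number dropped is stored in attribute
#'   `dropped`.
#' @export
#' @examples
#' survey_table(data.frame(farm = 1:3, zone = "LG", milk = c(100, 200, 300)),
#'              farm_id = "farm", milk_yield = "milk")
survey_table <- function(df, farm_id = "farm_id", zone = "zone",
                         milk_yield = "milk_yield",
                         outputs = character(), inputs = character()) {
  df <- tibble::as_tibble(df)
  for (col in c(milk_yield, outputs, inputs)) {
    if (!col %in% names(df)) {
      abort(paste0("mapped column not found in data: '", col, "'"),
            class = "dairygap_schema_error")
    }
  }
  out <- tibble::tibble(
    farm_id = if (farm_id %in% names(df)) as.character(df[[farm_id]]) else
      paste0("farm_", seq_len(nrow(df))),
    zone = if (zone %in% names(df)) as.character(df[[zone]]) else "all",
    milk_yield = as.numeric(df[[milk_yield]])
  )
  for (col in c(outputs, inputs)) out[[col]] <- as.numeric(df[[col]])

  value_cols <- c("milk_yield", outputs, inputs)
  ok <- rep(TRUE, nrow(out))
  for (col in value_cols) ok <- ok & !is.na(out[[col]]) & out[[col]] >= 0
  dropped <- sum(!ok)
  out <- out[ok, ]
  if (nrow(out) == 0L) {
    abort("no usable rows after dropping missing/negative values",
          class = "dairygap_empty_table_error")
  }
  structure(out,
            output_names = outputs, input_names = inputs, dropped = dropped,
            class = c("survey_df", class(out)))
}

#' Read a farm survey CSV
#'
#' Reads a comma-separated survey file (header row, `.` decimal, UTF-8) and
#' maps its columns onto the survey-table schema. Rows with missing or
#' negative values in mapped columns are dropped and counted. Optionally a
#' plain-text ingest log (rows read / dropped) is written.
#'
#' @param path Path to a CSV file.
#' @param farm_id,zone,milk_yield,outputs,inputs Column mapping, as in
#'   [survey_table()].
#' @param per_farm If `TRUE` the yield column is a whole-farm quantity and
#'   is divided by `cow_col` to give per-head yield.
#' @param cow_col Column with the number of milking cows (required when
#'   `per_farm = TRUE`).
#' @param log_file Optional path; if given, a short ingest log is written.
#' @returns A `survey_df` tibble; attribute `dropped` counts removed rows.
#' @export
read_survey_csv <- function(path, farm_id = "farm_id", zone = "zone",
                            milk_yield = "milk_yield",
                            outputs = character(), inputs = character(),
                            per_farm = FALSE, cow_col = NULL,
                            log_file = NULL) {
  if (!file.exists(path)) {
    abort(paste0("survey file not found: ", path),
          class = "dairygap_io_error")
  }
  # read everything as character and convert with as.numeric(), which is
  # correctly rounded, so written doubles round-trip bit-exactly
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(
                           .default = readr::col_character()))
  n_read <- nrow(raw)
  if (per_farm) {
    if (is.null(cow_col) || !cow_col %in% names(raw)) {
      abort("per_farm = TRUE requires an existing `cow_col`",
            class = "dairygap_schema_error")
    }
    raw[[milk_yield]] <- as.numeric(raw[[milk_yield]]) /
      as.numeric(raw[[cow_col]])
  }
  tab <- survey_table(raw, farm_id = farm_id, zone = zone,
                      milk_yield = milk_yield,
                      outputs = outputs, inputs = inputs)
  if (!is.null(log_file)) {
    writeLines(c(
      paste0("file: ", path),
      paste0("rows read: ", n_read),
      paste0("rows dropped (missing/negative): ", attr(tab, "dropped")),
      paste0("rows kept: ", nrow(tab))
    ), log_file)
  }
  tab
}

#' Write a cleaned survey table back to CSV
#'
#' @param table A `survey_df`.
#' @param path Output file path.
#' @returns `path`, invisibly.
#' @export
write_survey_csv <- function(table, path) {
  out <- tibble::as_tibble(table)
  # 17 significant digits so doubles survive the round-trip exactly
  for (col in names(out)) {
    if (is.numeric(out[[col]])) out[[col]] <- sprintf("%.17g", out[[col]])
  }
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Split a survey table by agricultural zone
#'
#' Partitions the table into one survey table per zone label. Every record
#' lands in exactly one group, so group sizes sum to the input row count.
#'
#' @param table A `survey_df`.
#' @returns A named list of `survey_df` tibbles, names sorted
#'   lexicographically.
#' @export
group_by_zone <- function(table) {
  stopifnot(nrow(table) > 0)
  zones <- sort(unique(table$zone))
  out <- lapply(zones, function(z) {
    g <- table[table$zone == z, ]
    attributes(g)[c("output_names", "input_names")] <-
      attributes(table)[c("output_names", "input_names")]
    class(g) <- class(table)
    g
  })
  names(out) <- zones
  out
}
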