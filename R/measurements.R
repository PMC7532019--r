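# Flow-rate measurement tables.
#
# Two interchangeable CSV dialects, auto-detected by header:
#   long:    speed_rpm,flow_ul_per_h          (one row per replicate)
#   summary: speed_rpm,mean_ul_per_h,sd_ul_per_h,n
# Internally everything converges on the summary form: one row per speed
# with mean, sd and replicate count.

#' Summarise flow measurements per speed
#'
#' Accepts either replicate-level data (columns `speed_rpm`, `flow_ul_h`)
#' or an already-summarised table (`speed_rpm`, `mean_ul_h`, `sd_ul_h`,
#' `n`) and returns the summary form: one row per unique speed, sorted by
#' speed, with the per-speed mean, standard deviation and replicate count.
#' A single replicate gets sd 0.
#'
#' @param data A data frame in either form.
#' @return A tibble with columns `speed_rpm`, `mean_ul_h`, `sd_ul_h`, `n`.
#' @examples
#' camp <- simulate_campaign(campaign_design(seed = 1))
#' summarise_flow(camp)
#' @export
summarise_flow <- function(data) {
  stopifnot(is.data.frame(data))
  if (all(c("speed_rpm", "flow_ul_h") %in% names(data))) {
    out <- data |>
      dplyr::group_by(.data$speed_rpm) |>
      dplyr::summarise(
        mean_ul_h = mean(.data$flow_ul_h),
        sd_ul_h = if (dplyr::n() > 1) sd(.data$flow_ul_h) else 0,
        n = dplyr::n(),
        .groups = "drop"
      ) |>
      dplyr::arrange(.data$speed_rpm)
  } else if (all(c("speed_rpm", "mean_ul_h", "sd_ul_h", "n") %in% names(data))) {
    out <- as_tibble(data)[, c("speed_rpm", "mean_ul_h", "sd_ul_h", "n")] |>
      dplyr::arrange(.data$speed_rpm)
  } else {
    abort(paste0(
      "Cannot interpret measurement table: need columns (speed_rpm, flow_ul_h) ",
      "for replicates or (speed_rpm, mean_ul_h, sd_ul_h, n) for summaries."
    ))
  }
  if (anyDuplicated(out$speed_rpm)) abort("Speeds must be unique in summary form.")
  if (any(out$n < 1)) abort("Each speed needs at least one replicate.")
  if (any(out$sd_ul_h < 0)) abort("Standard deviations must be >= 0.")
  if (any(out$speed_rpm < 0)) abort("Speeds must be >= 0 rpm.")
  out
}

#' Read a flow-measurement CSV
#'
#' Auto-detects the dialect by header: `speed_rpm,flow_ul_per_h` (long, one
#' row per replicate) or `speed_rpm,mean_ul_per_h,sd_ul_per_h,n` (summary).
#'
#' @param path Path to the CSV file.
#' @return A tibble: long form with columns `speed_rpm`, `flow_ul_h`, or
#'   summary form with `speed_rpm`, `mean_ul_h`, `sd_ul_h`, `n`.
#' @seealso [write_flow_measurements()], [summarise_flow()]
#' @export
read_flow_measurements <- function(path) {
  header <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
  if (identical(header, c("speed_rpm", "flow_ul_per_h"))) {
    d <- readr::read_csv(path, col_types = "dd")
    tibble(speed_rpm = d$speed_rpm, flow_ul_h = d$flow_ul_per_h)
  } else if (identical(header, c("speed_rpm", "mean_ul_per_h", "sd_ul_per_h", "n"))) {
    d <- readr::read_csv(path, col_types = "dddi")
    tibble(speed_rpm = d$speed_rpm, mean_ul_h = d$mean_ul_per_h,
           sd_ul_h = d$sd_ul_per_h, n = d$n)
  } else {
    abort(paste0(
      "Unrecognized header: expected `speed_rpm,flow_ul_per_h` or ",
      "`speed_rpm,mean_ul_per_h,sd_ul_per_h,n`, got `",
      paste(header, collapse = ","), "`."
    ))
  }
}

#' Write a flow-measurement CSV
#'
#' Emits the long dialect when replicate-level data are supplied and the
#' summary dialect otherwise (or when `format = "summary"` forces
#' summarisation first).
#'
#' @param data A data frame in either measurement form.
#' @param path Output path.
#' @param format `"auto"` (default), `"long"` or `"summary"`.
#' @return `path`, invisibly.
#' @export
write_flow_measurements <- function(data, path, format = c("auto", "long", "summary")) {
  format <- match.arg(format)
  has_long <- all(c("speed_rpm", "flow_ul_h") %in% names(data))
  if (format == "auto") format <- if (has_long) "long" else "summary"
  if (format == "long") {
    if (!has_long) abort("Long output needs replicate-level data (`flow_ul_h` column).")
    readr::write_csv(
      tibble(speed_rpm = data$speed_rpm, flow_ul_per_h = data$flow_ul_h), path
    )
  } else {
    s <- summarise_flow(data)
    readr::write_csv(
      tibble(speed_rpm = s$speed_rpm, mean_ul_per_h = s$mean_ul_h,
             sd_ul_per_h = s$sd_ul_h, n = s$n), path
    )
  }
  invisible(path)
}
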