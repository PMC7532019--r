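# ggplot2 views of campaigns, fits and model-variant comparisons.

#' Plot a flow-measurement campaign
#'
#' Per-speed means with +/- 1 sd error bars; replicate points are overlaid
#' when replicate-level data are supplied.
#'
#' @param data Measurements in either form accepted by [summarise_flow()].
#' @return A ggplot object.
#' @examples
#' plot_flow_campaign(simulate_campaign(campaign_design(seed = 3)))
#' @export
plot_flow_campaign <- function(data) {
  s <- summarise_flow(data)
  p <- ggplot2::ggplot(s, ggplot2::aes(x = .data$speed_rpm, y = .data$mean_ul_h)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_ul_h - .data$sd_ul_h,
                   ymax = .data$mean_ul_h + .data$sd_ul_h),
      width = 4
    ) +
    ggplot2::geom_point(shape = 15, size = 2.5) +
    ggplot2::labs(x = "rotation speed (rpm)", y = "flow rate (µl/h)") +
    ggplot2::theme_minimal()
  if ("flow_ul_h" %in% names(data)) {
    p <- p + ggplot2::geom_point(
      data = data, ggplot2::aes(y = .data$flow_ul_h),
      alpha = 0.3, size = 1
    )
  }
  p
}

#' @describeIn fit_threshold_model Fitted threshold curve over the measured
#'   means (error bars: +/- 1 sd).
#' @method autoplot flow_fit
#' @export
autoplot.flow_fit <- function(object, ...) {
  s <- object$data
  grid <- tibble(speed_rpm = seq(0, max(s$speed_rpm) * 1.05, length.out = 300))
  curve <- predict_flow(object$model, grid)
  plot_flow_campaign(s) +
    ggplot2::geom_line(
      data = curve,
      ggplot2::aes(x = .data$speed_rpm, y = .data$flow_ul_h),
      color = "#2c7fb8", linewidth = 0.8
    ) +
    ggplot2::geom_vline(
      xintercept = rad_s_to_rpm(object$model$omega0),
      linetype = "dashed", color = "grey50"
    ) +
    ggplot2::labs(
      subtitle = sprintf(
        "pinned threshold fit: omega0 = %.3g rpm%s, R² = %.2f",
        rad_s_to_rpm(object$model$omega0),
        if (is.finite(object$p_v_pa)) sprintf(" (p_v = %.3g Pa)", object$p_v_pa) else "",
        object$r_squared
      )
    )
}

#' Overlay all four model-variant curves on a campaign
#'
#' Draws the hydrostatic-only, centrifugal-only and combined forward
#' predictions (geometry-derived coefficients) and the fitted pinned model
#' over the measured means — the standard diagnostic for deciding whether
#' capillary pinning is needed to explain the data.
#'
#' @inheritParams compare_variants
#' @return A ggplot object.
#' @examples
#' camp <- simulate_campaign(campaign_design(seed = 3))
#' plot_variant_curves(camp, organ_disc_geometry(), water_properties(37))
#' @export
plot_variant_curves <- function(data, geometry, fluid,
                                B_mode = c("fitted", "fixed_from_geometry")) {
  B_mode <- match.arg(B_mode)
  s <- summarise_flow(data)
  speeds <- seq(0, max(s$speed_rpm) * 1.05, length.out = 300)
  fit <- fit_threshold_model(s, geometry = geometry, fluid = fluid, B_mode = B_mode)
  models <- list(
    hydrostatic_only = flow_model("hydrostatic_only", geometry = geometry, fluid = fluid),
    centrifugal_only = flow_model("centrifugal_only", geometry = geometry, fluid = fluid),
    combined = flow_model("combined", geometry = geometry, fluid = fluid),
    combined_pinned = fit$model
  )
  curves <- purrr::imap(models, function(m, nm) {
    dplyr::mutate(predict_flow(m, speeds), variant = nm)
  }) |> dplyr::bind_rows()
  plot_flow_campaign(s) +
    ggplot2::geom_line(
      data = curves,
      ggplot2::aes(x = .data$speed_rpm, y = .data$flow_ul_h,
                   color = .data$variant),
      linewidth = 0.8
    ) +
    ggplot2::scale_color_manual(values = c(
      hydrostatic_only = "black", centrifugal_only = "#d7301f",
      combined = "#2b8cbe", combined_pinned = "#31a354"
    )) +
    ggplot2::labs(color = "model variant")
}
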