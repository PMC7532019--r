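# Error-weighted fitting of the pinned threshold model
#   Q(omega) = 0                        for omega <  omega0
#   Q(omega) = B (omega^2 - omega0^2)   for omega >= omega0
# to per-speed flow means, minimizing sum_i w_i (Q_i - model(omega_i))^2
# with w_i = 1/sem_i^2 (sem = sd/sqrt(n), the standard error of the mean).
#
# The objective is non-smooth in omega0 wherever the threshold crosses a
# data speed, so instead of a generic gradient optimizer we profile: for
# each candidate omega0 the optimal B has a closed weighted-least-squares
# form, the profiled SSR is scanned on a dense omega0 grid and the best
# grid point is refined by a local 1-D search. Zero-flow points below the
# threshold still contribute to the SSR through their weights.

#' Closed-form calibration of the threshold model through two points
#'
#' Two exact measurements (omega1, Q1), (omega2, Q2) with positive flows
#' determine the pinned model uniquely: with k = Q2/Q1,
#' omega0^2 = (k omega1^2 - omega2^2)/(k - 1) and B = Q1/(omega1^2 -
#' omega0^2). Points lying on a pure omega^2 law (k equal to the squared
#' speed ratio) make omega0 indeterminate at the boundary and are resolved
#' as omega0 = 0. The result interpolates both inputs exactly and is
#' symmetric in the point order. Serves as the independent oracle for the
#' general fitter.
#'
#' @param point1,point2 Length-2 numeric vectors `c(speed_rpm, flow_ul_h)`
#'   with distinct speeds and strictly positive flows.
#' @return A list with `B_ul_h_per_rad2_s2`, `omega0_rad_s` and
#'   `omega0_rpm`.
#' @examples
#' two_point_solve(c(100, 97), c(200, 445))
#' @export
two_point_solve <- function(point1, point2) {
  stopifnot(is.numeric(point1), length(point1) == 2,
            is.numeric(point2), length(point2) == 2)
  if (point1[1] == point2[1]) abort("The two points must have distinct speeds.")
  if (point1[2] <= 0 || point2[2] <= 0) abort("Both flows must be > 0.")
  # order so omega1 < omega2; the solution is symmetric
  if (point1[1] > point2[1]) { tmp <- point1; point1 <- point2; point2 <- tmp }
  w1 <- rpm_to_rad_s(point1[1]); q1 <- point1[2]
  w2 <- rpm_to_rad_s(point2[1]); q2 <- point2[2]
  k <- q2 / q1
  omega0_sq <- (k * w1^2 - w2^2) / (k - 1)
  # pure omega^2 law (or sub-quadratic growth): no resolvable threshold
  if (!is.finite(omega0_sq) || omega0_sq < 0) omega0_sq <- 0
  if (omega0_sq >= w1^2) {
    abort("Inconsistent points: the implied threshold exceeds the slower measured speed.")
  }
  B <- q1 / (w1^2 - omega0_sq)
  list(
    B_ul_h_per_rad2_s2 = B,
    omega0_rad_s = sqrt(omega0_sq),
    omega0_rpm = rad_s_to_rpm(sqrt(omega0_sq))
  )
}

#' Pinned flow model calibrated through two measured points
#'
#' Convenience wrapper: [two_point_solve()] plus [flow_model()]. Attaching
#' a geometry and fluid makes the threshold convertible to a burst
#' pressure.
#'
#' @inheritParams two_point_solve
#' @param geometry,fluid Optional [disc_geometry()] / [fluid_properties()]
#'   to attach.
#' @return A `combined_pinned` [flow_model()].
#' @examples
#' m <- calibrate_two_point(c(100, 97), c(200, 445))
#' predict_flow(m, c(100, 200))
#' @export
calibrate_two_point <- function(point1, point2, geometry = NULL, fluid = NULL) {
  sol <- two_point_solve(point1, point2)
  flow_model("combined_pinned", geometry = geometry, fluid = fluid,
             B = sol$B_ul_h_per_rad2_s2, B_units = "ul_h_per_rad2_s2",
             omega0 = sol$omega0_rad_s)
}

# pinned-model prediction in ul/h space, vectorized over omega
pinned_mean <- function(B, omega0, omega) {
  ifelse(omega < omega0, 0, B * (omega^2 - omega0^2))
}

# weighted SSR profiled over B for fixed omega0; returns list(ssr, B)
profile_B <- function(omega0, omega, y, w) {
  x <- pmax(0, omega^2 - omega0^2)
  sxx <- sum(w * x * x)
  if (sxx <= 0) return(list(ssr = sum(w * y^2), B = NA_real_))
  B <- sum(w * x * y) / sxx
  list(ssr = sum(w * (y - B * x)^2), B = B)
}

# internal fitting core in (rad/s, ul/h) space
fit_core <- function(omega, y, w, B_fixed = NULL, n_grid = 2000) {
  omega_max <- max(omega)
  grid <- seq(0, omega_max, length.out = n_grid)
  ssr_at <- if (is.null(B_fixed)) {
    function(o0) profile_B(o0, omega, y, w)$ssr
  } else {
    function(o0) sum(w * (y - pinned_mean(B_fixed, o0, omega))^2)
  }
  # vectorized grid scan: X[i, j] = max(0, omega_i^2 - grid_j^2)
  X <- pmax(outer(omega^2, grid^2, "-"), 0)
  if (is.null(B_fixed)) {
    sxx <- colSums(w * X * X)
    B_grid <- ifelse(sxx > 0, colSums(w * y * X) / sxx, 0)
  } else {
    B_grid <- rep(B_fixed, n_grid)
  }
  resid <- y - X * rep(B_grid, each = length(y))
  ssr_grid <- colSums(w * resid^2)
  j <- which.min(ssr_grid)
  lo <- grid[max(1, j - 1)]
  hi <- grid[min(n_grid, j + 1)]
  omega0 <- if (hi > lo) {
    opt <- optimize(ssr_at, interval = c(lo, hi), tol = 1e-12)
    # a second, tighter pass polishes the minimum to near machine precision
    half <- max(1e-9, (hi - lo) * 1e-4)
    opt2 <- optimize(ssr_at, interval = c(max(0, opt$minimum - half),
                                          min(omega_max, opt$minimum + half)),
                     tol = .Machine$double.eps^0.75)
    if (opt2$objective <= opt$objective) opt2$minimum else opt$minimum
  } else grid[j]
  if (ssr_at(0) <= ssr_at(omega0)) omega0 <- 0 # boundary beats interior
  if (is.null(B_fixed)) {
    pb <- profile_B(omega0, omega, y, w)
    list(omega0 = omega0, B = pb$B, ssr = pb$ssr)
  } else {
    list(omega0 = omega0, B = B_fixed, ssr = ssr_at(omega0))
  }
}

#' Fit the capillary-pinning threshold model to flow measurements
#'
#' Estimates the flow coefficient B and the burst threshold omega0 of the
#' pinned model from a flow-rate-vs-speed campaign by error-weighted least
#' squares, with weights 1/sem_i^2 (sem = sd/sqrt(n) per speed). When every
#' sd is zero the fit falls back to unweighted least squares with a
#' warning; a mix of zero and nonzero sds is an error. With
#' `B_mode = "fixed_from_geometry"` the coefficient is pinned to its
#' geometry-derived value and only the threshold is estimated.
#'
#' The fitted threshold is converted to a burst pressure p_v = p_h +
#' omega0^2 * 1/2 rho (r2^2 - r1^2) when a geometry and fluid are supplied;
#' without radii the fit reports omega0 only and leaves `p_v_pa` as `NA`
#' (the conversion is impossible without r1 and r2).
#'
#' @param data Measurements in either form accepted by [summarise_flow()].
#' @param geometry Optional [disc_geometry()] (required for
#'   `B_mode = "fixed_from_geometry"` and for burst-pressure conversion).
#' @param fluid Optional [fluid_properties()].
#' @param B_mode `"fitted"` (default: B and omega0 both free) or
#'   `"fixed_from_geometry"` (B from [B_from_geometry()], omega0 free).
#' @param n_grid Number of threshold candidates in the profile scan.
#' @return An object of class `flow_fit`; see [tidy.flow_fit()] and
#'   [glance.flow_fit()] for tabular views.
#' @examples
#' camp <- simulate_campaign(campaign_design(seed = 7))
#' fit <- fit_threshold_model(camp, organ_disc_geometry(), water_properties(37))
#' glance(fit)
#' @export
fit_threshold_model <- function(data, geometry = NULL, fluid = NULL,
                                B_mode = c("fitted", "fixed_from_geometry"),
                                n_grid = 2000) {
  B_mode <- match.arg(B_mode)
  s <- summarise_flow(data)
  if (all(s$mean_ul_h == 0)) abort("Model unidentifiable: all measured flows are zero.")
  n_pos <- sum(s$mean_ul_h > 0)
  if (B_mode == "fitted" && n_pos < 2) {
    abort("Fitting both B and omega0 needs at least two speeds with nonzero mean flow.")
  }
  has_geom <- !is.null(geometry) && !is.null(fluid)
  if (B_mode == "fixed_from_geometry" && !has_geom) {
    abort("`B_mode = \"fixed_from_geometry\"` requires `geometry` and `fluid`.")
  }

  sem <- s$sd_ul_h / sqrt(s$n)
  if (all(sem == 0)) {
    warn("All per-speed sds are zero: falling back to an unweighted fit.")
    w <- rep(1, nrow(s))
  } else if (any(sem == 0)) {
    abort("Some (but not all) per-speed sds are zero: weights 1/sem^2 are undefined. Supply scatter for every speed or none.")
  } else {
    w <- 1 / sem^2
  }

  omega <- rpm_to_rad_s(s$speed_rpm)
  B_fixed <- if (B_mode == "fixed_from_geometry") {
    m3_s_to_ul_h(as.numeric(B_from_geometry(geometry, fluid)))
  } else NULL
  core <- fit_core(omega, s$mean_ul_h, w, B_fixed = B_fixed, n_grid = n_grid)
  if (!is.finite(core$B) || core$B <= 0) {
    abort("Model unidentifiable: the fitted flow coefficient is not positive (no increasing trend in the data).")
  }

  model <- flow_model("combined_pinned", geometry = geometry, fluid = fluid,
                      B = core$B, B_units = "ul_h_per_rad2_s2",
                      omega0 = core$omega0)
  model$B_provenance <- if (B_mode == "fitted") "fitted" else "assumed"
  fitted_ul_h <- pinned_mean(core$B, core$omega0, omega)
  # unweighted R^2 against the mean of per-speed means, comparable across
  # weighting schemes
  sst <- sum((s$mean_ul_h - mean(s$mean_ul_h))^2)
  r2 <- if (sst > 0) 1 - sum((s$mean_ul_h - fitted_ul_h)^2) / sst else NA_real_

  p_v <- if (has_geom) model_burst_pressure(model) else NA_real_

  structure(
    list(
      model = model,
      B_mode = B_mode,
      data = s,
      weights = w,
      weighted = !all(sem == 0),
      fitted_ul_h = fitted_ul_h,
      weighted_ssr = core$ssr,
      r_squared = r2,
      n_points = nrow(s),
      p_v_pa = p_v,
      geometry = geometry,
      fluid = fluid,
      n_grid = n_grid
    ),
    class = "flow_fit"
  )
}

#' Parametric-bootstrap uncertainty of the fitted burst pressure
#'
#' Resamples each per-speed mean from Normal(mean_i, sem_i), refits the
#' threshold model with the original settings, and summarises the scatter
#' of the burst pressure (or of omega0 when no geometry is attached): the
#' bootstrap standard error and the percentile 95% confidence interval.
#' The bootstrap is chosen over asymptotic covariance because the threshold
#' parameter is non-regular (the objective is only piecewise smooth in
#' omega0). Deterministic for a fixed seed.
#'
#' @param fit A [fit_threshold_model()] result.
#' @param n_boot Number of bootstrap resamples, >= 100.
#' @param seed Integer seed.
#' @param n_grid Profile grid size used in the refits (coarser than the
#'   primary fit is fine; each refit is refined locally).
#' @return A list with `parameter` (`"p_v_pa"` or `"omega0_rad_s"`),
#'   `estimate`, `se`, `ci95` (length-2 vector), `n_boot`, `n_failed` and
#'   `boot` (tibble of resampled estimates).
#' @examples
#' camp <- simulate_campaign(campaign_design(seed = 7))
#' fit <- fit_threshold_model(camp, organ_disc_geometry(), water_properties(37))
#' fit_uncertainty(fit, n_boot = 100, seed = 1)$ci95
#' @export
fit_uncertainty <- function(fit, n_boot = 200, seed = 1, n_grid = 500) {
  stopifnot(inherits(fit, "flow_fit"), n_boot >= 100)
  s <- fit$data
  sem <- s$sd_ul_h / sqrt(s$n)
  has_geom <- !is.null(fit$geometry) && !is.null(fit$fluid)
  parameter <- if (has_geom) "p_v_pa" else "omega0_rad_s"
  estimate <- if (has_geom) fit$p_v_pa else fit$model$omega0

  if (all(sem == 0)) {
    return(list(parameter = parameter, estimate = estimate, se = 0,
                ci95 = c(estimate, estimate), n_boot = n_boot, n_failed = 0L,
                boot = tibble(estimate = rep(estimate, 0))))
  }

  refit_one <- function(y_star) {
    d <- tibble(speed_rpm = s$speed_rpm, mean_ul_h = y_star,
                sd_ul_h = s$sd_ul_h, n = s$n)
    f <- fit_threshold_model(d, geometry = fit$geometry, fluid = fit$fluid,
                             B_mode = fit$B_mode, n_grid = n_grid)
    if (has_geom) f$p_v_pa else f$model$omega0
  }

  draws <- withr::with_seed(seed, {
    lapply(seq_len(n_boot), function(b) {
      y_star <- rnorm(nrow(s), mean = s$mean_ul_h, sd = sem)
      tryCatch(refit_one(y_star), error = function(e) NA_real_)
    })
  })
  vals <- unlist(draws)
  n_failed <- sum(!is.finite(vals))
  if (n_failed > 0.2 * n_boot) {
    abort(sprintf(
      "Bootstrap refits failed for %d of %d resamples (> 20%%): the model is too weakly identified by these data for a bootstrap interval.",
      n_failed, n_boot
    ))
  }
  vals <- vals[is.finite(vals)]
  list(
    parameter = parameter,
    estimate = estimate,
    se = sd(vals),
    ci95 = unname(quantile(vals, c(0.025, 0.975))),
    n_boot = n_boot,
    n_failed = as.integer(n_failed),
    boot = tibble(estimate = vals)
  )
}

#' Compare the four flow-model variants against measurements
#'
#' Evaluates the three non-pinned variants with their geometry-derived
#' coefficients (pure forward predictions, nothing fitted) and the pinned
#' variant via [fit_threshold_model()], scoring each by the same weighted
#' SSR used in fitting, and ranks them best first.
#'
#' @inheritParams fit_threshold_model
#' @return A tibble with columns `variant`, `weighted_ssr`, `r_squared`,
#'   `B_ul_h_per_rad2_s2`, `omega0_rad_s`, `p_v_pa`, sorted by
#'   `weighted_ssr`.
#' @examples
#' camp <- simulate_campaign(campaign_design(seed = 7))
#' compare_variants(camp, organ_disc_geometry(), water_properties(37))
#' @export
compare_variants <- function(data, geometry, fluid,
                             B_mode = c("fitted", "fixed_from_geometry"),
                             n_grid = 2000) {
  B_mode <- match.arg(B_mode)
  s <- summarise_flow(data)
  sem <- s$sd_ul_h / sqrt(s$n)
  w <- if (all(sem == 0)) rep(1, nrow(s)) else {
    if (any(sem == 0)) abort("Mixed zero and nonzero sds: weights undefined.")
    1 / sem^2
  }
  omega <- rpm_to_rad_s(s$speed_rpm)
  sst <- sum((s$mean_ul_h - mean(s$mean_ul_h))^2)

  score <- function(pred) {
    tibble(
      weighted_ssr = sum(w * (s$mean_ul_h - pred)^2),
      r_squared = if (sst > 0) 1 - sum((s$mean_ul_h - pred)^2) / sst else NA_real_
    )
  }

  rows <- purrr::map(setdiff(.flow_variants, "combined_pinned"), function(v) {
    m <- flow_model(v, geometry = geometry, fluid = fluid)
    pred <- m3_s_to_ul_h(predict_flow_si(m, omega))
    dplyr::bind_cols(
      tibble(variant = v, B_ul_h_per_rad2_s2 = m3_s_to_ul_h(m$B_si),
             omega0_rad_s = NA_real_, p_v_pa = NA_real_),
      score(pred)
    )
  })
  fit <- fit_threshold_model(s, geometry = geometry, fluid = fluid,
                             B_mode = B_mode, n_grid = n_grid)
  rows <- c(rows, list(dplyr::bind_cols(
    tibble(variant = "combined_pinned",
           B_ul_h_per_rad2_s2 = m3_s_to_ul_h(fit$model$B_si),
           omega0_rad_s = fit$model$omega0, p_v_pa = fit$p_v_pa),
    tibble(weighted_ssr = fit$weighted_ssr, r_squared = fit$r_squared)
  )))
  dplyr::bind_rows(rows) |>
    dplyr::relocate("variant", "weighted_ssr", "r_squared") |>
    dplyr::arrange(.data$weighted_ssr)
}

#' @describeIn fit_threshold_model Parameter table of a fit: one row per
#'   parameter (`B`, `omega0`, and `p_v` when convertible).
#' @param x,object A `flow_fit` object.
#' @param ... Unused.
#' @method tidy flow_fit
#' @export
tidy.flow_fit <- function(x, ...) {
  rows <- tibble(
    term = c("B", "omega0"),
    estimate = c(m3_s_to_ul_h(x$model$B_si), x$model$omega0),
    unit = c("ul/h per (rad/s)^2", "rad/s"),
    mode = c(if (x$B_mode == "fitted") "fitted" else "fixed_from_geometry", "fitted")
  )
  if (is.finite(x$p_v_pa)) {
    rows <- dplyr::bind_rows(rows, tibble(
      term = "p_v", estimate = x$p_v_pa, unit = "Pa", mode = "derived"
    ))
  }
  rows
}

#' @describeIn fit_threshold_model One-row fit summary.
#' @method glance flow_fit
#' @export
glance.flow_fit <- function(x, ...) {
  tibble(
    variant = x$model$variant,
    B_mode = x$B_mode,
    weighted = x$weighted,
    weighted_ssr = x$weighted_ssr,
    r_squared = x$r_squared,
    n_points = x$n_points,
    omega0_rad_s = x$model$omega0,
    omega0_rpm = rad_s_to_rpm(x$model$omega0),
    p_v_pa = x$p_v_pa
  )
}

#' @export
print.flow_fit <- function(x, ...) {
  cat("<flow_fit: combined_pinned>\n")
  cat(sprintf("  %d speeds, %s, B %s\n", x$n_points,
              if (x$weighted) "weighted by 1/sem^2" else "unweighted",
              x$B_mode))
  cat(sprintf("  B        %.4g ul/h per (rad/s)^2\n", m3_s_to_ul_h(x$model$B_si)))
  cat(sprintf("  omega0   %.4g rad/s (%.4g rpm)\n", x$model$omega0,
              rad_s_to_rpm(x$model$omega0)))
  if (is.finite(x$p_v_pa)) {
    cat(sprintf("  p_v      %.4g Pa\n", x$p_v_pa))
  } else {
    cat("  p_v      not convertible (no geometry with r1, r2 supplied)\n")
  }
  cat(sprintf("  weighted SSR %.4g, R^2 %.3f\n", x$weighted_ssr, x$r_squared))
  invisible(x)
}

#' Write a JSON fit report
#'
#' Emits the fitted parameters, uncertainty (when supplied) and provenance
#' flags as a JSON object with keys `variant`, `B`, `omega0_rad_s`,
#' `p_v_Pa`, `se_Pa`, `ci95_Pa`, `weighted_SSR`, `r_squared`, `provenance`.
#'
#' @param fit A [fit_threshold_model()] result.
#' @param path Output path.
#' @param uncertainty Optional [fit_uncertainty()] result.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path, uncertainty = NULL) {
  stopifnot(inherits(fit, "flow_fit"))
  prov <- if (!is.null(fit$geometry)) {
    weakest_provenance(geometry_provenance(fit$geometry)[c("r_inner", "r_outer")])
  } else NA_character_
  report <- list(
    variant = fit$model$variant,
    B = m3_s_to_ul_h(fit$model$B_si),
    B_units = "ul/h per (rad/s)^2",
    B_mode = fit$B_mode,
    omega0_rad_s = fit$model$omega0,
    p_v_Pa = fit$p_v_pa,
    se_Pa = if (!is.null(uncertainty)) uncertainty$se else NA_real_,
    ci95_Pa = if (!is.null(uncertainty)) uncertainty$ci95 else c(NA_real_, NA_real_),
    weighted_SSR = fit$weighted_ssr,
    r_squared = fit$r_squared,
    n_points = fit$n_points,
    provenance = prov
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
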