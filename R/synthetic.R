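# Synthetic flow-measurement campaigns.
#
# Emulates the measurement procedure the models are fitted to: the disc is
# rotated at each speed for a fixed collection time (1 h by default) and
# the flow rate is determined by weighing the collected effluent, with at
# least 8 replicates per speed summarized by mean and standard deviation.
# Noise is applied to the flow value (Gaussian, truncated at zero by
# resampling); the effluent mass is then derived exactly from the noisy
# flow, so mass bookkeeping is conserved by construction.

#' Design of a synthetic flow-measurement campaign
#'
#' Describes the measurement grid, replication, collection time, noise
#' model and ground-truth flow model of a simulated campaign. The defaults
#' are the reference measurement design: speeds 0-200 rpm in 50 rpm steps,
#' 8 replicates per speed, 1 h collections, and a pinned-model truth
#' calibrated through the two reference operating points (97 ul/h at
#' 100 rpm, 445 ul/h at 200 rpm). Replicate scatter is sd =
#' max(relative_sd * true flow, floor_sd): a 12% relative term plus a
#' 3 ul/h floor so the 0 rpm point scatters at the detection level rather
#' than being exactly zero.
#'
#' @param speeds_rpm Measurement speeds in rpm.
#' @param n_replicates Replicates per speed, >= 1.
#' @param duration_s Collection duration per replicate in s, > 0.
#' @param relative_sd Relative component of the replicate sd, >= 0.
#' @param floor_sd_ul_h Additive noise floor in ul/h, >= 0.
#' @param truth A [flow_model()] used as ground truth; defaults to the
#'   two-point-calibrated pinned model attached to `geometry`/`fluid`.
#' @param geometry A [disc_geometry()] (default [organ_disc_geometry()]).
#' @param fluid A [fluid_properties()] (default [water_properties()] at
#'   37 degC).
#' @param seed Integer seed; campaigns are bit-reproducible per seed.
#' @return An object of class `campaign_design`.
#' @examples
#' campaign_design(seed = 1)
#' @export
campaign_design <- function(speeds_rpm = c(0, 50, 100, 150, 200),
                            n_replicates = 8L,
                            duration_s = 3600,
                            relative_sd = 0.12,
                            floor_sd_ul_h = 3,
                            truth = NULL,
                            geometry = organ_disc_geometry(),
                            fluid = water_properties(37),
                            seed = 1L) {
  stopifnot(is.numeric(speeds_rpm), all(speeds_rpm >= 0),
            n_replicates >= 1, duration_s > 0,
            relative_sd >= 0, floor_sd_ul_h >= 0)
  truth <- truth %||% calibrate_two_point(c(100, 97), c(200, 445),
                                          geometry = geometry, fluid = fluid)
  stopifnot(inherits(truth, "flow_model"))
  structure(
    list(
      speeds_rpm = sort(unique(as.numeric(speeds_rpm))),
      n_replicates = as.integer(n_replicates),
      duration_s = duration_s,
      relative_sd = relative_sd,
      floor_sd_ul_h = floor_sd_ul_h,
      truth = truth,
      geometry = geometry,
      fluid = fluid,
      seed = as.integer(seed)
    ),
    class = "campaign_design"
  )
}

#' @export
print.campaign_design <- function(x, ...) {
  cat("<campaign_design>\n")
  cat(sprintf("  speeds      %s rpm\n", paste(x$speeds_rpm, collapse = ", ")))
  cat(sprintf("  replicates  %d per speed, %g s collections\n",
              x$n_replicates, x$duration_s))
  cat(sprintf("  noise       sd = max(%.3g * truth, %.3g ul/h), truncated at 0\n",
              x$relative_sd, x$floor_sd_ul_h))
  cat(sprintf("  truth       %s, seed %d\n", x$truth$variant, x$seed))
  invisible(x)
}

# zero-truncated Gaussian draws by resampling (not clipping): clipping
# would put a point mass at exactly 0 and distort the sd
rnorm_trunc0 <- function(n, mean, sd) {
  out <- rnorm(n, mean, sd)
  bad <- which(out < 0)
  guard <- 0L
  while (length(bad) > 0) {
    out[bad] <- rnorm(length(bad), mean[bad], sd[bad])
    bad <- bad[out[bad] < 0]
    guard <- guard + 1L
    if (guard > 10000L) abort("Truncated-normal resampling did not terminate; the noise model is degenerate.")
  }
  out
}

#' Simulate a flow-measurement campaign
#'
#' For each speed, the true flow comes from the design's ground-truth model
#' and each replicate is drawn from Normal(truth, sd) truncated at zero,
#' with sd = max(relative_sd * truth, floor_sd). The effluent mass of each
#' replicate is derived exactly from its (noisy) flow as
#' flow x duration x density, mirroring how flow is measured by weighing.
#' Identical designs and seeds give bit-identical campaigns.
#'
#' @param design A [campaign_design()].
#' @return A tibble with one row per replicate: `speed_rpm`, `replicate`,
#'   `flow_ul_h`, `true_flow_ul_h`, `effluent_mass_mg`, `duration_s`.
#'   Feed it directly to [fit_threshold_model()] or [summarise_flow()].
#' @examples
#' camp <- simulate_campaign(campaign_design(seed = 42))
#' summarise_flow(camp)
#' @export
simulate_campaign <- function(design) {
  stopifnot(inherits(design, "campaign_design"))
  truth <- predict_flow(design$truth, design$speeds_rpm)
  grid <- tidyr::expand_grid(
    speed_rpm = design$speeds_rpm,
    replicate = seq_len(design$n_replicates)
  ) |>
    dplyr::left_join(truth[, c("speed_rpm", "flow_ul_h")], by = "speed_rpm") |>
    dplyr::rename(true_flow_ul_h = "flow_ul_h")
  sd_vec <- pmax(design$relative_sd * grid$true_flow_ul_h, design$floor_sd_ul_h)
  flows <- withr::with_seed(design$seed, {
    if (all(sd_vec == 0)) grid$true_flow_ul_h
    else rnorm_trunc0(nrow(grid), grid$true_flow_ul_h, sd_vec)
  })
  rho <- design$fluid$density
  grid |>
    dplyr::mutate(
      flow_ul_h = flows,
      effluent_mass_mg = ul_h_to_m3_s(flows) * design$duration_s * rho * 1e6,
      duration_s = design$duration_s
    ) |>
    dplyr::relocate("speed_rpm", "replicate", "flow_ul_h")
}

#' Perturb the assumed geometry fields for sensitivity studies
#'
#' Multiplies every length tagged `"assumed"` (for the bundled geometry:
#' the pumping-column radii r1, r2 and the channel length L) by an
#' independent lognormal factor with log-sd `relative_sd`. Printed and
#' derived fields are returned bit-identically: provenance is a contract,
#' not a comment.
#'
#' @param geom A [disc_geometry()].
#' @param relative_sd Log-scale sd of the perturbation factors, in
#'   `[0, 0.5]`.
#' @param seed Integer seed.
#' @return A perturbed [disc_geometry()].
#' @examples
#' perturb_geometry(organ_disc_geometry(), relative_sd = 0.1, seed = 1)
#' @export
perturb_geometry <- function(geom, relative_sd, seed = 1L) {
  stopifnot(inherits(geom, "disc_geometry"),
            is.numeric(relative_sd), relative_sd >= 0, relative_sd <= 0.5)
  if (relative_sd == 0) return(geom)
  prov <- geometry_provenance(geom)
  targets <- intersect(names(prov)[prov == "assumed"], .geometry_length_fields)
  factors <- withr::with_seed(seed, exp(rnorm(length(targets), 0, relative_sd)))
  out <- geom
  for (i in seq_along(targets)) out[[targets[i]]] <- geom[[targets[i]]] * factors[i]
  attributes(out) <- attributes(geom)
  out
}
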