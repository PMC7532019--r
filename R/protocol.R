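# Spin-protocol planning: centrifugal cell loading (single- and multi-cell
# type) and continuous centrifugal perfusion, with cell-budget arithmetic.
# All RCF values are reported at the tissue-chamber radius.

new_protocol <- function(type, steps, extra = list()) {
  structure(
    c(list(type = type, steps = steps), extra),
    class = c(paste0(type, "_protocol"), "disc_protocol")
  )
}

loading_step <- function(step, purpose, label, speed_rpm, duration_s, geom,
                         concentration_per_ul, volume_ul, incubation_gap_min = NA_real_) {
  r <- rcf(speed_rpm, geom$chamber_radius)
  tibble(
    step = as.integer(step), purpose = purpose, label = label,
    speed_rpm = speed_rpm, duration_s = duration_s,
    rcf_g = r, effective_gravity_g = effective_gravity(r),
    concentration_per_ul = concentration_per_ul, volume_ul = volume_ul,
    cells_per_chamber = concentration_per_ul * volume_ul,
    incubation_gap_min = incubation_gap_min
  )
}

#' Plan a single-cell-type centrifugal loading protocol
#'
#' Computes the rotation speed that delivers a target RCF at the
#' tissue-chamber radius, and the cell budget: cells per chamber per step is
#' exactly concentration x volume. Loading can be repeated (`n_steps`) to
#' top chambers up, e.g. doubling a 20 000-cell load to 40 000. Targets
#' above 100 g are flagged (gentler accelerations are the norm for loading
#' viable cells); below 1000 g is enforced.
#'
#' @param suspension A list or one-row data frame with
#'   `concentration_per_ul` (cells/ul) and `volume_ul` (ul per tissue
#'   channel).
#' @param target_rcf_g Loading RCF at the chamber radius, in g; in
#'   (0, 1000].
#' @param duration_s Spin duration per step in s (default 300 = 5 min).
#' @param geometry A [disc_geometry()].
#' @param n_steps Number of identical loading repetitions, >= 1.
#' @return A `loading_protocol`: steps tibble plus totals and flags.
#' @examples
#' plan_loading(list(concentration_per_ul = 4000, volume_ul = 5),
#'              target_rcf_g = 46.4)
#' @export
plan_loading <- function(suspension, target_rcf_g, duration_s = 300,
                         geometry = organ_disc_geometry(), n_steps = 1L) {
  suspension <- as.list(suspension)
  stopifnot(
    is.numeric(suspension$concentration_per_ul), suspension$concentration_per_ul >= 0,
    is.numeric(suspension$volume_ul), suspension$volume_ul >= 0,
    is.numeric(target_rcf_g), length(target_rcf_g) == 1,
    is.numeric(duration_s), duration_s > 0, n_steps >= 1
  )
  if (target_rcf_g <= 0 || target_rcf_g > 1000) {
    abort("`target_rcf_g` must lie in (0, 1000] g.")
  }
  speed <- speed_for_rcf(target_rcf_g, geometry$chamber_radius)
  steps <- dplyr::bind_rows(lapply(seq_len(n_steps), function(i) {
    loading_step(i, "load", "cells", speed, duration_s, geometry,
                 suspension$concentration_per_ul, suspension$volume_ul)
  }))
  flags <- character()
  if (target_rcf_g > 100) {
    flags <- c(flags, sprintf(
      "loading RCF %.3g g exceeds 100 g, the commonly used cell-handling acceleration",
      target_rcf_g
    ))
  }
  per_chamber <- sum(steps$cells_per_chamber)
  new_protocol("loading", steps, list(
    suspension = suspension[c("concentration_per_ul", "volume_ul")],
    cells_per_chamber_per_step = steps$cells_per_chamber[1],
    cells_per_chamber_total = per_chamber,
    total_cells_disc = disc_cell_budget(geometry, per_chamber),
    rcf_provenance = unname(geometry_provenance(geometry)[["chamber_radius"]]),
    flags = flags
  ))
}

#' Plan a layered (multi-cell-type) loading protocol
#'
#' One spin per layer at a common speed, with an incubation gap between
#' consecutive layers for initial cell aggregation. Layer order is
#' preserved. For a single cell type use [plan_loading()].
#'
#' @param layers A data frame with columns `label`, `concentration_per_ul`,
#'   `volume_ul`; one row per layer, at least two layers.
#' @param speed_rpm Loading speed in rpm, shared by all layers.
#' @param duration_s Spin duration per layer in s.
#' @param incubation_gap_min Incubation between consecutive layers in
#'   minutes (recorded as protocol metadata; no flow during the gap is
#'   modelled).
#' @param geometry A [disc_geometry()].
#' @return A `loading_protocol` with one step per layer.
#' @examples
#' layers <- tibble::tibble(
#'   label = c("ASC", "FB", "ASC"),
#'   concentration_per_ul = 1000, volume_ul = 5
#' )
#' plan_layers(layers, speed_rpm = 1500)
#' @export
plan_layers <- function(layers, speed_rpm = 1500, duration_s = 300,
                        incubation_gap_min = 120,
                        geometry = organ_disc_geometry()) {
  stopifnot(is.data.frame(layers),
            all(c("label", "concentration_per_ul", "volume_ul") %in% names(layers)))
  if (nrow(layers) < 2) {
    abort("A layered protocol needs at least two layers; use `plan_loading()` for a single cell type.")
  }
  stopifnot(is.numeric(speed_rpm), speed_rpm >= 0, duration_s > 0)
  steps <- dplyr::bind_rows(lapply(seq_len(nrow(layers)), function(i) {
    loading_step(i, "load_layer", layers$label[i], speed_rpm, duration_s, geometry,
                 layers$concentration_per_ul[i], layers$volume_ul[i],
                 incubation_gap_min = if (i < nrow(layers)) incubation_gap_min else NA_real_)
  }))
  flags <- character()
  if (steps$rcf_g[1] > 100) {
    flags <- c(flags, sprintf(
      "loading RCF %.3g g exceeds 100 g, the commonly used cell-handling acceleration",
      steps$rcf_g[1]
    ))
  }
  per_chamber <- sum(steps$cells_per_chamber)
  new_protocol("loading", steps, list(
    layers = as_tibble(layers),
    cells_per_chamber_per_step = steps$cells_per_chamber,
    cells_per_chamber_total = per_chamber,
    total_cells_disc = disc_cell_budget(geometry, per_chamber),
    rcf_provenance = unname(geometry_provenance(geometry)[["chamber_radius"]]),
    flags = flags
  ))
}

#' Plan a continuous centrifugal perfusion
#'
#' Resolves a perfusion operating point from either a rotation speed or a
#' target flow (via the supplied flow model), and reports the in-plane RCF
#' at the chamber radius, the effective gravity sensed by the cells, the
#' predicted flow with its provenance, and a hypergravity flag that fires
#' exactly when the in-plane RCF exceeds 1 g — perfusion is meant to run
#' below 1 g so the cells do not experience sustained hypergravity.
#'
#' @param model A [flow_model()] (fitted/calibrated, or geometry-derived).
#' @param speed_rpm Target rotation speed in rpm. Give exactly one of
#'   `speed_rpm` and `flow_ul_h`.
#' @param flow_ul_h Target flow in ul/h.
#' @param geometry A [disc_geometry()].
#' @param reservoir_volume_ul Optional usable reservoir volume in ul; when
#'   given, the reservoir service interval (h) is volume / flow.
#' @return A `perfusion_protocol`.
#' @examples
#' m <- calibrate_two_point(c(100, 97), c(200, 445),
#'                          geometry = organ_disc_geometry(),
#'                          fluid = water_properties(37))
#' plan_perfusion(m, speed_rpm = 100)
#' plan_perfusion(m, flow_ul_h = 445)
#' @export
plan_perfusion <- function(model, speed_rpm = NULL, flow_ul_h = NULL,
                           geometry = organ_disc_geometry(),
                           reservoir_volume_ul = NULL) {
  stopifnot(inherits(model, "flow_model"))
  if (is.null(speed_rpm) == is.null(flow_ul_h)) {
    abort("Give exactly one of `speed_rpm` and `flow_ul_h`.")
  }
  if (is.null(speed_rpm)) {
    stopifnot(is.numeric(flow_ul_h), length(flow_ul_h) == 1, flow_ul_h >= 0)
    if (model$variant == "combined_pinned" && flow_ul_h > 0 &&
        model$omega0 > 0 && flow_ul_h < 1e-12) {
      abort(sprintf(
        "Flow target below the threshold model's resolvable minimum: the valve only bursts at omega0 = %.4g rad/s.",
        model$omega0
      ))
    }
    speed_rpm <- speed_for_flow(model, flow_ul_h)
  }
  stopifnot(is.numeric(speed_rpm), length(speed_rpm) == 1, speed_rpm >= 0)
  pred <- predict_flow(model, speed_rpm)
  r <- rcf(speed_rpm, geometry$chamber_radius)
  flags <- character()
  if (r > 1) {
    flags <- c(flags, sprintf(
      "hypergravity: in-plane RCF %.3g g exceeds 1 g at %g rpm", r, speed_rpm
    ))
  }
  steps <- tibble(
    step = 1L, purpose = "perfuse", label = "continuous rotation",
    speed_rpm = speed_rpm, duration_s = NA_real_,
    rcf_g = r, effective_gravity_g = effective_gravity(r)
  )
  new_protocol("perfusion", steps, list(
    speed_rpm = speed_rpm,
    rcf_at_chamber_g = r,
    effective_gravity_g = effective_gravity(r),
    flow_ul_h = pred$flow_ul_h[1],
    flow_provenance = pred$provenance[1],
    rcf_provenance = unname(geometry_provenance(geometry)[["chamber_radius"]]),
    service_interval_h = if (!is.null(reservoir_volume_ul) && pred$flow_ul_h[1] > 0) {
      reservoir_volume_ul / pred$flow_ul_h[1]
    } else NA_real_,
    flags = flags
  ))
}

#' Total cell demand of a fully loaded disc
#'
#' total = cells per chamber x n_systems x chambers per system. With the
#' bundled 4 x 5 layout and up to 40 000 cells per chamber, a full disc of
#' 20 constructs needs at most 800 000 cells — under a million.
#'
#' @param geometry A [disc_geometry()].
#' @param cells_per_chamber Cells in each chamber, >= 0.
#' @return Total cell count for the disc.
#' @examples
#' disc_cell_budget(organ_disc_geometry(), 40000)
#' @export
disc_cell_budget <- function(geometry, cells_per_chamber) {
  stopifnot(inherits(geometry, "disc_geometry"),
            is.numeric(cells_per_chamber), all(cells_per_chamber >= 0))
  cells_per_chamber * geometry$n_systems * geometry$chambers_per_system
}

#' @export
print.disc_protocol <- function(x, ...) {
  cat(sprintf("<%s_protocol>\n", x$type))
  print(x$steps)
  if (x$type == "loading") {
    cat(sprintf("  cells/chamber total: %g; disc total: %g\n",
                x$cells_per_chamber_total, x$total_cells_disc))
  } else {
    cat(sprintf("  flow %.4g ul/h [%s], RCF %.3g g, effective gravity %.3g g\n",
                x$flow_ul_h, x$flow_provenance, x$rcf_at_chamber_g,
                x$effective_gravity_g))
  }
  for (f in x$flags) cat("  ! ", f, "\n", sep = "")
  invisible(x)
}

# ---- YAML round trip ----------------------------------------------------

steps_to_yaml <- function(steps) {
  lapply(seq_len(nrow(steps)), function(i) {
    row <- as.list(steps[i, ])
    lapply(row, function(v) if (is.numeric(v)) num_to_chr(v) else v)
  })
}

steps_from_yaml <- function(rows, template) {
  dplyr::bind_rows(lapply(rows, function(row) {
    out <- row
    for (nm in names(template)) {
      if (is.numeric(template[[nm]]) && !is.integer(template[[nm]])) {
        out[[nm]] <- chr_to_num(row[[nm]])
      } else if (is.integer(template[[nm]])) {
        out[[nm]] <- as.integer(chr_to_num(row[[nm]]))
      }
    }
    as_tibble(out[names(template)])
  }))
}

#' Serialize a protocol to YAML, and back
#'
#' Protocols round-trip losslessly: all numeric fields are written as
#' full-precision strings.
#'
#' @param protocol A protocol from [plan_loading()], [plan_layers()] or
#'   [plan_perfusion()].
#' @param path File path.
#' @return `write_protocol()`: `path` invisibly; `read_protocol()`: the
#'   protocol object.
#' @export
write_protocol <- function(protocol, path) {
  stopifnot(inherits(protocol, "disc_protocol"))
  scalars <- protocol[setdiff(names(protocol), c("type", "steps", "suspension",
                                                 "layers", "flags"))]
  scalars <- lapply(scalars, function(v) if (is.numeric(v)) num_to_chr(v) else v)
  doc <- list(protocol = list(
    type = protocol$type,
    steps = steps_to_yaml(protocol$steps),
    scalars = scalars,
    flags = as.list(protocol$flags)
  ))
  if (!is.null(protocol$suspension)) {
    doc$protocol$suspension <- lapply(protocol$suspension, num_to_chr)
  }
  if (!is.null(protocol$layers)) doc$protocol$layers <- steps_to_yaml(protocol$layers)
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path) {
  doc <- yaml::read_yaml(path)$protocol
  if (is.null(doc)) abort("Config has no `protocol:` section.")
  step_template <- tibble(
    step = integer(), purpose = character(), label = character(),
    speed_rpm = numeric(), duration_s = numeric(), rcf_g = numeric(),
    effective_gravity_g = numeric()
  )
  if (doc$type == "loading") {
    step_template$concentration_per_ul <- numeric()
    step_template$volume_ul <- numeric()
    step_template$cells_per_chamber <- numeric()
    step_template$incubation_gap_min <- numeric()
  }
  steps <- steps_from_yaml(doc$steps, step_template)
  extra <- lapply(doc$scalars, function(v) {
    if (is.character(v)) {
      num <- chr_to_num(v)
      if (all(is.na(num) == (v == "NA"))) num else v
    } else v
  })
  extra$flags <- unlist(doc$flags) %||% character()
  if (!is.null(doc$suspension)) extra$suspension <- lapply(doc$suspension, chr_to_num)
  if (!is.null(doc$layers)) {
    extra$layers <- steps_from_yaml(doc$layers, tibble(
      label = character(), concentration_per_ul = numeric(), volume_ul = numeric()
    ))
  }
  new_protocol(doc$type, steps, extra)
}
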