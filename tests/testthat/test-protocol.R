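test_that("plan_loading reproduces the reference loading step", {
  p <- plan_loading(list(concentration_per_ul = 4000, volume_ul = 5),
                    target_rcf_g = 46.4)
  expect_equal(p$steps$speed_rpm, 1000, tolerance = 1e-3)
  expect_equal(p$steps$rcf_g, 46.4, tolerance = 1e-9)
  expect_identical(p$cells_per_chamber_per_step, 20000)
  expect_identical(p$total_cells_disc, 400000)
  expect_length(p$flags, 0)
  expect_identical(p$rcf_provenance, "derived")
})

test_that("repeating the loading step doubles the cell budget", {
  p <- plan_loading(list(concentration_per_ul = 4000, volume_ul = 5),
                    target_rcf_g = 46.4, n_steps = 2L)
  expect_equal(nrow(p$steps), 2)
  expect_identical(p$cells_per_chamber_total, 40000)
  expect_identical(p$total_cells_disc, 800000)
  expect_lte(p$total_cells_disc, 1e6)
})

test_that("loading edge cases: wetting runs, flags and bounds", {
  # volume 0: a valid wetting-only protocol with zero cells
  p0 <- plan_loading(list(concentration_per_ul = 4000, volume_ul = 0),
                     target_rcf_g = 46.4)
  expect_identical(p0$cells_per_chamber_total, 0)
  # above 100 g: flagged but allowed
  pf <- plan_loading(list(concentration_per_ul = 1000, volume_ul = 5),
                     target_rcf_g = 200)
  expect_length(pf$flags, 1)
  expect_match(pf$flags, "100 g")
  expect_error(plan_loading(list(concentration_per_ul = 1000, volume_ul = 5),
                            target_rcf_g = 0), "\\(0, 1000\\]")
  expect_error(plan_loading(list(concentration_per_ul = 1000, volume_ul = 5),
                            target_rcf_g = 1500), "\\(0, 1000\\]")
})

test_that("plan_layers builds the reference three-layer protocol", {
  layers <- tibble::tibble(
    label = c("ASC", "FB", "ASC"),
    concentration_per_ul = 1000, volume_ul = 5
  )
  p <- plan_layers(layers, speed_rpm = 1500)
  expect_equal(nrow(p$steps), 3)
  expect_identical(p$steps$label, c("ASC", "FB", "ASC")) # order preserved
  expect_identical(p$cells_per_chamber_per_step, rep(5000, 3))
  expect_identical(p$cells_per_chamber_total, 15000)
  expect_identical(format_g(p$steps$rcf_g[1]), "104.4")
  # incubation gaps sit between consecutive layers, not after the last
  expect_equal(p$steps$incubation_gap_min, c(120, 120, NA))
  expect_error(plan_layers(layers[1, ]), "at least two")
})

test_that("plan_perfusion resolves both target forms as mutual inverses", {
  m <- test_truth()
  p_speed <- plan_perfusion(m, speed_rpm = 100)
  expect_equal(p_speed$flow_ul_h, 97, tolerance = 1e-9)
  expect_identical(format_g(p_speed$rcf_at_chamber_g), "0.46")
  expect_identical(format_g(p_speed$effective_gravity_g), "1.1")
  expect_length(p_speed$flags, 0)

  p_flow <- plan_perfusion(m, flow_ul_h = 445)
  expect_equal(p_flow$speed_rpm, 200, tolerance = 1e-9)

  # round trip speed -> flow -> speed
  p_back <- plan_perfusion(m, flow_ul_h = p_speed$flow_ul_h)
  expect_equal(p_back$speed_rpm, 100, tolerance = 1e-9)

  # at rest the pinned model gives zero flow and exactly 1 g
  p0 <- plan_perfusion(m, speed_rpm = 0)
  expect_identical(p0$flow_ul_h, 0)
  expect_identical(p0$effective_gravity_g, 1)

  expect_error(plan_perfusion(m), "exactly one")
  expect_error(plan_perfusion(m, speed_rpm = 100, flow_ul_h = 97), "exactly one")
})

test_that("the hypergravity flag fires exactly when rcf exceeds 1 g", {
  m <- test_truth()
  g <- test_geom()
  at_1g <- speed_for_rcf(1, g$chamber_radius)
  below <- plan_perfusion(m, speed_rpm = at_1g * 0.999)
  above <- plan_perfusion(m, speed_rpm = at_1g * 1.001)
  expect_length(below$flags, 0)
  expect_length(above$flags, 1)
  expect_match(above$flags, "hypergravity")
})

test_that("the reservoir service interval is volume over flow", {
  m <- test_truth()
  p <- plan_perfusion(m, speed_rpm = 100, reservoir_volume_ul = 970)
  expect_equal(p$service_interval_h, 10, tolerance = 1e-9)
  p2 <- plan_perfusion(m, speed_rpm = 100)
  expect_true(is.na(p2$service_interval_h))
})

test_that("disc_cell_budget is exact arithmetic", {
  g <- test_geom()
  expect_identical(disc_cell_budget(g, 40000), 800000)
  expect_identical(disc_cell_budget(g, 0), 0)
  expect_error(disc_cell_budget(g, -5))
})

test_that("all protocol types round-trip losslessly through YAML", {
  protos <- list(
    plan_loading(list(concentration_per_ul = 4000, volume_ul = 5),
                 target_rcf_g = 46.4, n_steps = 2L),
    plan_layers(tibble::tibble(label = c("ASC", "FB", "ASC"),
                               concentration_per_ul = 1000, volume_ul = 5)),
    plan_perfusion(test_truth(), speed_rpm = 100, reservoir_volume_ul = 970),
    plan_perfusion(test_truth(), speed_rpm = 200)
  )
  for (p in protos) {
    path <- withr::local_tempfile(fileext = ".yaml")
    write_protocol(p, path)
    back <- read_protocol(path)
    expect_identical(back$steps, p$steps)
    expect_identical(back$flags, p$flags)
    for (f in setdiff(names(p), c("steps", "flags"))) {
      expect_identical(back[[f]], p[[f]], label = f)
    }
  }
})
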