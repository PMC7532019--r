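test_that("pinned flow equals the channel law with p_v as constant backpressure", {
  g <- test_geom(); fl <- test_fluid()
  p_v <- 97
  m <- flow_model("combined_pinned", geometry = g, fluid = fl, p_v = p_v)
  p_h <- hydrostatic_pressure(fl, g$head_height)
  for (omega in c(1, 10, 100)) {
    if (omega < m$omega0) next
    speed <- rad_s_to_rpm(omega)
    dp <- centrifugal_pressure(fl, speed, g$r_inner, g$r_outer) + p_h - p_v
    expect_equal(
      predict_flow(m, speed)$flow_ul_h,
      channel_flow(g, fl, dp, units = "ul_h"),
      tolerance = 1e-12
    )
  }
  # below the threshold the valve holds and the flow is exactly zero,
  # including at omega = omega0 itself (both branches agree there)
  expect_identical(predict_flow(m, rad_s_to_rpm(m$omega0 * 0.99))$flow_ul_h, 0)
  expect_equal(predict_flow(m, rad_s_to_rpm(m$omega0))$flow_ul_h, 0)
})

test_that("omega0 <-> burst pressure conversions are exact inverses", {
  g <- test_geom(); fl <- test_fluid()
  p_h <- hydrostatic_pressure(fl, g$head_height)
  for (p_v in c(80, 97, 140, 500)) {
    o0 <- omega0_from_burst(p_v, p_h, fl, g$r_inner, g$r_outer)
    expect_equal(burst_from_omega0(o0, p_h, fl, g$r_inner, g$r_outer), p_v,
                 tolerance = 1e-14)
  }
  # a valve weaker than the hydrostatic head bursts at rest
  expect_identical(omega0_from_burst(p_h / 2, p_h, fl, g$r_inner, g$r_outer), 0)
  expect_error(omega0_from_burst(97, 78, fl, 0.05, 0.01))
  expect_error(burst_from_omega0(-1, 78, fl, 0.01, 0.045))
})

test_that("combined dominates pinned pointwise for the same coefficient", {
  g <- test_geom(); fl <- test_fluid()
  pinned <- flow_model("combined_pinned", geometry = g, fluid = fl, p_v = 97)
  combined <- flow_model("combined", geometry = g, fluid = fl)
  speeds <- seq(0, 300, length.out = 121)
  expect_true(all(predict_flow(combined, speeds)$flow_ul_h >=
                    predict_flow(pinned, speeds)$flow_ul_h))
})

test_that("every variant is non-decreasing in rotation speed", {
  g <- test_geom(); fl <- test_fluid()
  speeds <- seq(0, 400, length.out = 401)
  for (v in c("hydrostatic_only", "centrifugal_only", "combined")) {
    m <- flow_model(v, geometry = g, fluid = fl)
    expect_true(all(diff(predict_flow(m, speeds)$flow_ul_h) >= 0), label = v)
  }
  mp <- flow_model("combined_pinned", geometry = g, fluid = fl, p_v = 97)
  expect_true(all(diff(predict_flow(mp, speeds)$flow_ul_h) >= 0))
})

test_that("speed_for_flow inverts each variant on its valid domain", {
  g <- test_geom(); fl <- test_fluid()
  targets <- c(50, 97, 445, 1000)

  mc <- flow_model("centrifugal_only", geometry = g, fluid = fl)
  expect_equal(predict_flow(mc, speed_for_flow(mc, targets))$flow_ul_h,
               targets, tolerance = 1e-12)

  mb <- flow_model("combined", geometry = g, fluid = fl)
  base <- m3_s_to_ul_h(mb$q_hydrostatic_si)
  ok <- base + targets
  expect_equal(predict_flow(mb, speed_for_flow(mb, ok))$flow_ul_h,
               ok, tolerance = 1e-12)
  expect_error(speed_for_flow(mb, base / 2), "unreachable|baseline")

  mp <- flow_model("combined_pinned", geometry = g, fluid = fl, p_v = 97)
  expect_equal(predict_flow(mp, speed_for_flow(mp, targets))$flow_ul_h,
               targets, tolerance = 1e-12)
  # a zero target under a pinned model canonically maps to rest
  expect_identical(speed_for_flow(mp, 0), 0)

  mh <- flow_model("hydrostatic_only", geometry = g, fluid = fl)
  expect_error(speed_for_flow(mh, 100), "does not depend")
})

test_that("flow_model validates its argument combinations", {
  g <- test_geom(); fl <- test_fluid()
  expect_error(flow_model("combined_pinned"), "Supply either")
  expect_error(flow_model("combined"), "Supply either")
  expect_error(flow_model("combined", geometry = g, fluid = fl, omega0 = 1),
               "only apply")
  expect_error(flow_model("combined_pinned", geometry = g, fluid = fl,
                          omega0 = 1, p_v = 97), "not both")
  expect_error(flow_model("combined_pinned", B = 1, p_v = 97), "needs")
  expect_error(flow_model("combined_pinned", B = -1))
  # B in either unit system describes the same model
  m1 <- flow_model("combined_pinned", B = 1.06, omega0 = 4.2)
  m2 <- flow_model("combined_pinned", B = ul_h_to_m3_s(1.06), B_units = "si",
                   omega0 = 4.2)
  expect_equal(m1$B_si, m2$B_si)
})

test_that("burst-pressure conversion declines without radii", {
  m <- flow_model("combined_pinned", B = 1.06, omega0 = 4.24)
  expect_error(model_burst_pressure(m), "r1, r2")
  pv <- model_burst_pressure(m, geometry = test_geom(), fluid = test_fluid())
  expect_true(is.finite(pv) && pv > 0)
  expect_error(model_burst_pressure(flow_model("combined", geometry = test_geom(),
                                               fluid = test_fluid())))
})

test_that("predict_flow accepts data frames and rejects negative speeds", {
  m <- test_truth()
  df <- tibble::tibble(speed_rpm = c(0, 100, 200), run = c("a", "b", "c"))
  out <- predict_flow(m, df)
  expect_identical(out$run, df$run)
  expect_equal(out$flow_ul_h[2:3], c(97, 445), tolerance = 1e-12)
  expect_identical(unique(out$provenance), "fitted")
  expect_error(predict_flow(m, -5))
})

test_that("flow models round-trip through YAML bit-exactly", {
  m <- test_truth()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_flow_model(m, path)
  m2 <- read_flow_model(path, geometry = test_geom(), fluid = test_fluid())
  expect_identical(m2$B_si, m$B_si)
  expect_identical(m2$omega0, m$omega0)
  expect_identical(m2$variant, m$variant)
  expect_identical(m2$B_provenance, "fitted")
})
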