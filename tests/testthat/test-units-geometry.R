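test_that("rpm <-> rad/s conversion is exact and vectorized", {
  expect_equal(rpm_to_rad_s(60), 2 * pi)
  expect_equal(rpm_to_rad_s(0), 0)
  speeds <- c(0, 1, 100, 1000, 4000)
  expect_equal(rad_s_to_rpm(rpm_to_rad_s(speeds)), speeds)
  expect_equal(G0, 9.80665)
})

test_that("flow unit conversion round-trips", {
  q <- c(0, 97, 445, 1e6)
  expect_equal(m3_s_to_ul_h(ul_h_to_m3_s(q)), q)
  expect_equal(m3_s_to_ul_h(1), 3.6e12)
})

test_that("format_g matches protocol-table granularity", {
  expect_identical(
    format_g(c(0.4641, 1.856, 11.60, 46.41, 104.42, 742.5, 1200.4)),
    c("0.46", "1.9", "11.6", "46.4", "104.4", "742.5", "1200")
  )
  expect_identical(format_g(NA_real_), NA_character_)
  expect_error(format_g(-1))
})

test_that("fluid_properties validates its inputs", {
  fl <- fluid_properties(993.3, 6.92e-4, 0.07, temperature = 37)
  expect_s3_class(fl, "fluid_properties")
  expect_equal(fl$density, 993.3)
  expect_error(fluid_properties(400, 1e-3, 0.07), "sanity band")
  expect_error(fluid_properties(2500, 1e-3, 0.07), "sanity band")
  expect_error(fluid_properties(1000, 0, 0.07), "viscosity")
  expect_error(fluid_properties(1000, 1e-3, -0.01), "surface_tension")
})

test_that("water table returns fixed handbook values and refuses interpolation", {
  w37 <- water_properties(37)
  expect_equal(w37$density, 993.3)
  expect_equal(w37$viscosity, 0.692e-3)
  expect_equal(w37$surface_tension, 0.0700)
  expect_equal(water_properties(4)$density, 1000.0)
  expect_equal(water_properties(20)$surface_tension, 0.0728)
  expect_equal(water_properties(25)$viscosity, 0.890e-3)
  expect_error(water_properties(30), "no interpolation")
  expect_error(water_properties(150), "liquid water")
})

test_that("geometry carries provenance tags with sane defaults", {
  geom <- test_geom()
  prov <- geometry_provenance(geom)
  expect_identical(unname(prov["chamber_radius"]), "derived")
  expect_identical(unname(prov["r_inner"]), "assumed")
  expect_identical(unname(prov["r_outer"]), "assumed")
  expect_identical(unname(prov["channel_length"]), "assumed")
  expect_identical(unname(prov["channel_height"]), "printed")
  expect_identical(unname(prov["port_diameter"]), "printed")
  over <- disc_geometry(41.5e-3, 10e-3, 45e-3, 75e-6, 1.4e-3, 0.1, 2e-3, 8e-3,
                        provenance = c(r_inner = "printed"))
  expect_identical(unname(geometry_provenance(over)["r_inner"]), "printed")
  expect_error(
    disc_geometry(41.5e-3, 10e-3, 45e-3, 75e-6, 1.4e-3, 0.1, 2e-3, 8e-3,
                  provenance = c(nonsense = "printed")),
    "Unknown provenance"
  )
})

test_that("the bundled geometry passes all invariants", {
  findings <- validate_geometry(test_geom())
  expect_equal(nrow(findings), 0)
})

test_that("validate_geometry reports violations as data", {
  geom <- test_geom()
  g1 <- geom; g1$channel_height <- -1e-6
  f1 <- validate_geometry(g1)
  expect_true(any(f1$level == "error" & f1$field == "channel_height"))

  g2 <- geom; g2$r_inner <- 46e-3
  f2 <- validate_geometry(g2)
  expect_true(any(f2$level == "error" & f2$field == "r_inner"))

  g3 <- geom; g3$r_outer <- 60e-3
  f3 <- validate_geometry(g3)
  expect_true(any(f3$level == "error" & f3$field == "r_outer"))

  # aspect ratio h/w in (0.5, 1]: warning-level finding, not an error
  g4 <- geom; g4$channel_height <- 0.8e-3
  f4 <- validate_geometry(g4)
  expect_true(any(f4$level == "warning"))
  expect_false(any(f4$level == "error"))

  # h > w: error
  g5 <- geom; g5$channel_height <- 2e-3
  f5 <- validate_geometry(g5)
  expect_true(any(f5$level == "error"))
})

test_that("derived quantities inherit the weakest input provenance", {
  B <- B_from_geometry(test_geom(), test_fluid())
  expect_identical(attr(B, "provenance"), "assumed")
  all_printed <- disc_geometry(
    41.5e-3, 10e-3, 45e-3, 75e-6, 1.4e-3, 0.1, 2e-3, 8e-3,
    provenance = c(chamber_radius = "printed", r_inner = "printed",
                   r_outer = "printed", channel_length = "printed")
  )
  expect_identical(attr(B_from_geometry(all_printed, test_fluid()), "provenance"),
                   "printed")
})

test_that("geometry config YAML round-trips bit-exactly", {
  geom <- disc_geometry(
    chamber_radius = 41.5e-3 * (1 + 1e-15), r_inner = 1 / 3 * 0.03,
    r_outer = 45e-3, channel_height = 75e-6, channel_width = 1.4e-3,
    channel_length = 0.1 + 1e-16, port_diameter = 2e-3, head_height = 8e-3
  )
  path <- withr::local_tempfile(fileext = ".yaml")
  write_geometry_config(geom, path, fluid = test_fluid(),
                        metadata = list(note = "round trip"))
  cfg <- read_geometry_config(path)
  expect_identical(unclass(cfg$geometry), unclass(geom))
  expect_identical(geometry_provenance(cfg$geometry), geometry_provenance(geom))
  expect_identical(unclass(cfg$fluid), unclass(test_fluid()))
  expect_identical(cfg$metadata$note, "round trip")
})

test_that("the installed default config equals the in-code default", {
  path <- system.file("extdata", "organ_disc_default.yaml", package = "discflow")
  expect_true(nzchar(path))
  cfg <- read_geometry_config(path)
  expect_identical(unclass(cfg$geometry), unclass(test_geom()))
  expect_identical(unclass(cfg$fluid), unclass(test_fluid()))
})
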