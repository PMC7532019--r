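# Shared objects for the test suite.

test_geom <- function() organ_disc_geometry()
test_fluid <- function() water_properties(37)

# pinned truth calibrated through the two reference operating points
test_truth <- function(geom = test_geom(), fluid = test_fluid()) {
  calibrate_two_point(c(100, 97), c(200, 445), geometry = geom, fluid = fluid)
}

# exact (noiseless) per-speed summary generated by a model, with constant sd
exact_summary <- function(model, speeds_rpm, sd = 1, n = 4L) {
  pred <- predict_flow(model, speeds_rpm)
  tibble::tibble(
    speed_rpm = speeds_rpm,
    mean_ul_h = pred$flow_ul_h,
    sd_ul_h = sd,
    n = n
  )
}
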