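test_that("two_point_solve reproduces both inputs to machine precision", {
  sol <- two_point_solve(c(100, 97), c(200, 445))
  m <- calibrate_two_point(c(100, 97), c(200, 445))
  pred <- predict_flow(m, c(100, 200))$flow_ul_h
  expect_equal(pred, c(97, 445), tolerance = 1e-14)
  # hand-derived values of the reference pair
  expect_equal(sol$omega0_rad_s^2, 17.9619, tolerance = 1e-5)
  expect_equal(sol$B_ul_h_per_rad2_s2, 1.0578, tolerance = 1e-4)
  expect_equal(sol$omega0_rpm, 40.47, tolerance = 1e-3)
})

test_that("two_point_solve is symmetric and handles the quadratic edge case", {
  a <- two_point_solve(c(100, 97), c(200, 445))
  b <- two_point_solve(c(200, 445), c(100, 97))
  expect_identical(a, b)
  # points on a pure omega^2 law: ratio 4 at speed ratio 2 -> no threshold
  sol <- two_point_solve(c(100, 100), c(200, 400))
  expect_identical(sol$omega0_rad_s, 0)
  expect_equal(sol$B_ul_h_per_rad2_s2, 100 / rpm_to_rad_s(100)^2)
  expect_error(two_point_solve(c(100, 97), c(100, 200)), "distinct")
  expect_error(two_point_solve(c(100, 0), c(200, 445)), "> 0")
  # decreasing flow with speed implies a threshold beyond the slower point
  expect_error(two_point_solve(c(100, 97), c(200, 50)), "Inconsistent")
})

test_that("the weighted fitter matches the two-point closed form to 1e-9", {
  sol <- two_point_solve(c(100, 97), c(200, 445))
  data <- tibble::tibble(
    speed_rpm = c(100, 200), mean_ul_h = c(97, 445), sd_ul_h = c(5, 20), n = 8L
  )
  fit <- fit_threshold_model(data, test_geom(), test_fluid())
  expect_equal(fit$model$omega0, sol$omega0_rad_s, tolerance = 1e-9)
  expect_equal(m3_s_to_ul_h(fit$model$B_si), sol$B_ul_h_per_rad2_s2,
               tolerance = 1e-9)
  expect_lt(fit$weighted_ssr, 1e-12)
})

test_that("the fitter recovers exact pinned models across a parameter grid", {
  g <- test_geom(); fl <- test_fluid()
  speeds <- c(50, 100, 150, 200)
  for (B in c(0.5, 1.0578, 2.5)) {
    for (omega0 in c(0, 2.5, 4.24, 5.1)) {
      m <- flow_model("combined_pinned", geometry = g, fluid = fl,
                      B = B, omega0 = omega0)
      fit <- fit_threshold_model(exact_summary(m, speeds), g, fl)
      expect_equal(fit$model$omega0, omega0, tolerance = 1e-6,
                   label = sprintf("omega0 (B=%g, omega0=%g)", B, omega0))
      expect_equal(m3_s_to_ul_h(fit$model$B_si), B, tolerance = 1e-8,
                   label = sprintf("B (B=%g, omega0=%g)", B, omega0))
    }
  }
})

test_that("weighting policy: all-zero sds fall back, mixed sds error", {
  m <- test_truth()
  d0 <- exact_summary(m, c(50, 100, 150, 200), sd = 0)
  expect_warning(fit0 <- fit_threshold_model(d0, test_geom(), test_fluid()),
                 "unweighted")
  expect_false(fit0$weighted)
  dmix <- exact_summary(m, c(50, 100, 150, 200), sd = 1)
  dmix$sd_ul_h[2] <- 0
  expect_error(fit_threshold_model(dmix, test_geom(), test_fluid()),
               "undefined")
})

test_that("degenerate data are rejected with clear errors", {
  zeros <- tibble::tibble(speed_rpm = c(0, 100), mean_ul_h = 0, sd_ul_h = 1, n = 8L)
  expect_error(fit_threshold_model(zeros), "unidentifiable")
  one_pos <- tibble::tibble(speed_rpm = c(0, 100), mean_ul_h = c(0, 97),
                            sd_ul_h = 1, n = 8L)
  expect_error(fit_threshold_model(one_pos), "at least two speeds")
  expect_error(
    fit_threshold_model(exact_summary(test_truth(), c(100, 200)),
                        B_mode = "fixed_from_geometry"),
    "requires"
  )
})

test_that("B_mode = fixed_from_geometry pins B and only fits the threshold", {
  g <- test_geom(); fl <- test_fluid()
  Bg <- m3_s_to_ul_h(as.numeric(B_from_geometry(g, fl)))
  truth <- flow_model("combined_pinned", geometry = g, fluid = fl,
                      B = Bg, omega0 = 4.0)
  fit <- fit_threshold_model(exact_summary(truth, c(50, 100, 150, 200)),
                             g, fl, B_mode = "fixed_from_geometry")
  expect_equal(m3_s_to_ul_h(fit$model$B_si), Bg, tolerance = 1e-14)
  expect_equal(fit$model$omega0, 4.0, tolerance = 1e-6)
  expect_identical(fit$model$B_provenance, "assumed")
})

test_that("p_v conversion requires geometry; omega0 is reported regardless", {
  d <- exact_summary(test_truth(), c(50, 100, 150, 200))
  fit <- fit_threshold_model(d)
  expect_true(is.na(fit$p_v_pa))
  expect_gt(fit$model$omega0, 0)
  u <- fit_uncertainty(fit, n_boot = 100, seed = 1)
  expect_identical(u$parameter, "omega0_rad_s")
})

test_that("fit_uncertainty is deterministic and degenerate-safe", {
  camp <- simulate_campaign(campaign_design(seed = 11))
  fit <- fit_threshold_model(camp, test_geom(), test_fluid())
  u1 <- fit_uncertainty(fit, n_boot = 100, seed = 42)
  u2 <- fit_uncertainty(fit, n_boot = 100, seed = 42)
  expect_identical(u1$ci95, u2$ci95)
  expect_identical(u1$boot, u2$boot)
  u3 <- fit_uncertainty(fit, n_boot = 100, seed = 43)
  expect_false(identical(u1$ci95, u3$ci95))
  expect_true(u1$ci95[1] <= fit$p_v_pa && fit$p_v_pa <= u1$ci95[2])
  expect_error(fit_uncertainty(fit, n_boot = 50), "n_boot")

  # sd 0 everywhere: the noiseless degenerate case has zero standard error
  expect_warning(
    fit0 <- fit_threshold_model(exact_summary(test_truth(), c(100, 200), sd = 0),
                                test_geom(), test_fluid())
  )
  u0 <- fit_uncertainty(fit0, n_boot = 100, seed = 1)
  expect_identical(u0$se, 0)
  expect_identical(unname(u0$ci95), c(fit0$p_v_pa, fit0$p_v_pa))
})

test_that("tidy and glance expose the fit as tibbles", {
  camp <- simulate_campaign(campaign_design(seed = 5))
  fit <- fit_threshold_model(camp, test_geom(), test_fluid())
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_identical(td$term, c("B", "omega0", "p_v"))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_identical(gl$variant, "combined_pinned")
  expect_lte(gl$r_squared, 1)
  expect_gte(gl$weighted_ssr, 0)
  expect_equal(gl$p_v_pa, fit$p_v_pa)
})

test_that("fit reports serialize to the documented JSON schema", {
  camp <- simulate_campaign(campaign_design(seed = 5))
  fit <- fit_threshold_model(camp, test_geom(), test_fluid())
  unc <- fit_uncertainty(fit, n_boot = 100, seed = 1)
  path <- withr::local_tempfile(fileext = ".json")
  write_fit_report(fit, path, uncertainty = unc)
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_true(all(c("variant", "B", "omega0_rad_s", "p_v_Pa", "se_Pa",
                    "ci95_Pa", "weighted_SSR", "r_squared", "provenance")
                  %in% names(rep)))
  expect_equal(rep$p_v_Pa, fit$p_v_pa)
  expect_equal(rep$ci95_Pa, unname(unc$ci95))
  expect_identical(rep$provenance, "assumed")
})

test_that("compare_variants scores all four variants with the fit's weights", {
  camp <- simulate_campaign(campaign_design(seed = 3))
  tab <- compare_variants(camp, test_geom(), test_fluid())
  expect_setequal(tab$variant, c("hydrostatic_only", "centrifugal_only",
                                 "combined", "combined_pinned"))
  expect_true(!is.unsorted(tab$weighted_ssr))
  expect_true(is.finite(tab$p_v_pa[tab$variant == "combined_pinned"]))
  expect_true(all(is.na(tab$p_v_pa[tab$variant != "combined_pinned"])))
})
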