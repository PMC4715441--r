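evisc_model <- function() fit_loglog_ols(subset_by_preparation(pigeons(), "eviscerated"))

test_that("an identity model maps volume to mass unchanged", {
  d <- make_calibration_dataset(n = 10, a = 0, b = 1, sigma = 0, seed = 1)
  m <- fit_loglog_ols(d)
  est <- predict_mass(m, 123)
  expect_equal(est$point_mass_g, 123, tolerance = 1e-10)
  expect_equal(est$corrected_mass_g, 123, tolerance = 1e-10)
})

test_that("prediction follows the closed-form chain step by step", {
  m <- structure(list(a = -2.1, b = 0.87, n = 11, mean_x = 5.3, Sxx = 2.4,
                      SSE = 0.05, MSE = 0.05 / 9, r2 = 0.9,
                      subset_tag = "combined", predictor_variant = "minus_feet"),
                 class = "calibration_model")
  v <- 3.2e6
  x0 <- log10(v)
  yhat <- -2.1 + 0.87 * x0
  se <- sqrt(m$MSE * (1 + 1 / 11 + (x0 - 5.3)^2 / 2.4))
  tq <- qt(0.975, 9)
  est <- predict_mass(m, v)
  expect_equal(est$point_mass_g, 10^yhat, tolerance = 1e-12)
  expect_equal(est$corrected_mass_g, 10^yhat * exp(m$MSE / 2), tolerance = 1e-12)
  expect_equal(est$pi_low_g, 10^(yhat - tq * se) * exp(m$MSE / 2), tolerance = 1e-12)
  expect_equal(est$pi_high_g, 10^(yhat + tq * se) * exp(m$MSE / 2), tolerance = 1e-12)
  expect_true(est$pi_low_g <= est$point_mass_g && est$point_mass_g <= est$pi_high_g)
  expect_gte(est$corrected_mass_g, est$point_mass_g)
})

test_that("predicted mass scales as 2^b when the volume doubles", {
  m <- evisc_model()
  e1 <- predict_mass(m, 5e6)
  e2 <- predict_mass(m, 1e7)
  expect_equal(e2$point_mass_g / e1$point_mass_g, 2^m$b, tolerance = 1e-10)
  expect_gt(e2$point_mass_g, e1$point_mass_g) # monotone for b > 0
})

test_that("the interval is narrowest at the calibration centroid and log-symmetric", {
  m <- evisc_model()
  vols <- 10^seq(m$mean_x - 1.5, m$mean_x + 1.5, length.out = 41)
  pis <- prediction_interval(m, vols)
  width <- log10(pis[, 2]) - log10(pis[, 1])
  expect_equal(which.min(width), 21L)
  expect_true(all(diff(width[21:41]) > 0)) # widening under extrapolation

  est <- predict_mass(m, 8445134)
  expect_lt(abs(log10(est$pi_high_g / est$corrected_mass_g) -
                log10(est$corrected_mass_g / est$pi_low_g)), 1e-8)
})

test_that("dodo predictions from the eviscerated calibration match the published table", {
  m <- evisc_model()
  dodo <- load_dodo_fixture()
  est <- predict_mass(m, dodo$ch_vol_minus_feet_mm3)
  expect_equal(round(est$corrected_mass_g[1]), 7967)
  expect_equal(as_kg(est$corrected_mass_g), c(8.0, 8.7, 10.7))
  # published: 7,980 / 8,687 / 10,760 g; agreement within 0.3%
  expect_equal(est$corrected_mass_g, c(7980, 8687, 10760), tolerance = 0.003)
  # Tring 95% PI, published 4,653-13,685 g
  expect_equal(est$pi_low_g[1], 4653, tolerance = 0.005)
  expect_equal(est$pi_high_g[1], 13685, tolerance = 0.005)
})

test_that("prediction-interval coverage is nominal over simulated draws", {
  truth <- list(a = -2.31, b = 0.9, sigma = 0.07)
  x0 <- 5.9
  covered <- vapply(seq_len(1000), function(i) {
    d <- make_calibration_dataset(n = 13, a = truth$a, b = truth$b,
                                  sigma = truth$sigma, seed = 20000 + i)
    m <- fit_loglog_ols(d)
    pi <- prediction_interval(m, 10^x0)
    smear <- exp(m$MSE / 2) # undo the reporting correction: coverage is on the raw PI
    y_new <- withr::with_seed(50000 + i,
                              truth$a + truth$b * x0 + rnorm(1, 0, truth$sigma))
    10^y_new >= pi[1] / smear && 10^y_new <= pi[2] / smear
  }, logical(1))
  expect_gt(mean(covered), 0.93)
  expect_lt(mean(covered), 0.97)
})

test_that("density floors convert units exactly", {
  expect_equal(density_floor(1, 1000), 0.001)
  dodo <- load_dodo_fixture()
  floors <- density_floor(dodo$ch_vol_mm3, 648)
  expect_equal(as_kg(floors), c(5.8, 6.3, 7.9))
  expect_equal(round(floors[1]), 5795)
  expect_error(density_floor(-1, 648), class = "chm_nonpositive_value")
})

test_that("viscera correction multiplies and validates", {
  expect_equal(viscera_correction(8000), 10640)
  expect_equal(as_kg(viscera_correction(8000)), 10.6)
  expect_equal(as_kg(viscera_correction(10760)), 14.3)
  expect_equal(viscera_correction(500, 1), 500)
  expect_error(viscera_correction(500, 0.9), class = "chm_nonpositive_value")
  expect_error(viscera_correction(-5), class = "chm_nonpositive_value")
})

test_that("external coefficients evaluate directly and defer to full stats", {
  expect_equal(apply_external_model(0, 0, 12345), 1)
  gd <- apply_external_model(-1.65, 0.82, 8942820)
  expect_equal(gd, 10^(-1.65 + 0.82 * log10(8942820)), tolerance = 1e-12)
  expect_equal(round(gd / 1000, 1), 11.2) # rounded printed coefficients

  m <- evisc_model()
  full <- apply_external_model(m$a, m$b, 8445134,
                               stats = list(n = m$n, mean_x = m$mean_x,
                                            Sxx = m$Sxx, MSE = m$MSE, SSE = m$SSE))
  ref <- predict_mass(m, 8445134)
  expect_equal(full$corrected_mass_g, ref$corrected_mass_g, tolerance = 1e-12)
  expect_equal(full$pi_low_g, ref$pi_low_g, tolerance = 1e-12)
})

test_that("a serialized model yields bit-identical predictions after reload", {
  m <- evisc_model()
  f <- withr::local_tempfile(fileext = ".json")
  write_model_json(m, f)
  m2 <- read_model_json(f)
  v <- c(8445134, 9283795, 11787000)
  expect_identical(predict_mass(m2, v)$corrected_mass_g,
                   predict_mass(m, v)$corrected_mass_g)
  expect_identical(prediction_interval(m2, v), prediction_interval(m, v))
})

test_that("the mass report enforces the model's feet convention", {
  m <- evisc_model()
  dodo <- load_dodo_fixture()
  rep <- mass_report(m, dodo)
  expect_identical(rep$variant, rep("minus_feet", 3))
  expect_equal(rep$ch_vol_mm3, dodo$ch_vol_minus_feet_mm3)
  expect_equal(rep$density_floor_g, density_floor(dodo$ch_vol_mm3))
  expect_equal(rep$viscera_corrected_g, rep$corrected_mass_g * 1.33)

  m_bad <- m; m_bad$predictor_variant <- NULL
  expect_error(mass_report(m_bad, dodo), class = "chm_variant_mismatch")
  expect_error(predict_mass(m, -3), class = "chm_nonpositive_value")
})
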