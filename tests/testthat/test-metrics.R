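# RMSE, coefficient of determination, blank leverages, detection limits.

test_that("rmse matches hand computation and a loop oracle", {
  expect_equal(rmse(c(1, 2, 3), c(2, 2, 1)), sqrt(5 / 3))
  expect_equal(rmse(1:5, 1:5), 0)
  expect_equal(rmse(1:5 + 2.5, 1:5), 2.5)   # constant offset
  set.seed(2)
  for (i in 1:5) {
    p <- rnorm(20); a <- rnorm(20)
    acc <- 0
    for (j in 1:20) acc <- acc + (p[j] - a[j])^2
    expect_equal(rmse(p, a), sqrt(acc / 20), tolerance = 1e-12)
  }
  expect_error(rmse(numeric(0), numeric(0)), "empty")
  expect_error(rmse(1:3, 1:4), "mismatch")
})

test_that("r_squared follows the regression definition, sign included", {
  a <- c(2, 2, 1)
  expect_equal(r_squared(a, a), 1)
  expect_equal(r_squared(rep(mean(a), 3), a), 0)
  # poor model: SS_res = 5, SS_tot = 2/3 => R^2 = -6.5
  expect_equal(r_squared(c(1, 2, 3), a), -6.5)
  set.seed(3)
  for (i in 1:5) {
    p <- rnorm(15); y <- rnorm(15)
    num <- 0; den <- 0; m <- mean(y)
    for (j in 1:15) {
      num <- num + (y[j] - p[j])^2
      den <- den + (y[j] - m)^2
    }
    expect_equal(r_squared(p, y), 1 - num / den, tolerance = 1e-12)
  }
  expect_error(r_squared(c(1, 2), c(3, 3)), "undefined")
})

test_that("blank leverage is the centered quadratic form", {
  # one component, calibration scores (-1, 0, 1): T'T = 2, blank at 1
  lev <- blank_leverage(cbind(c(-1, 0, 1)), cbind(1))
  expect_equal(lev$h0, 0.5)
  # a blank at the calibration centroid has zero leverage
  expect_equal(blank_leverage(cbind(c(-1, 0, 1)), cbind(0))$h0, 0)
  # leverage grows monotonically away from the centroid
  h <- blank_leverage(cbind(c(-1, 0, 1)), cbind(c(0.5, 1, 2, 4)))$h0
  expect_true(all(diff(h) > 0))
  expect_lte(blank_leverage(cbind(c(-1, 0, 1)),
                            cbind(c(0.3, 2)))$h0_min,
             blank_leverage(cbind(c(-1, 0, 1)), cbind(c(0.3, 2)))$h0_max)
  # two-component sanity against a direct solve
  set.seed(5)
  Tm <- matrix(rnorm(20), 10, 2); b0 <- rnorm(2)
  ctr <- colMeans(Tm); Tc <- sweep(Tm, 2, ctr)
  expect_equal(blank_leverage(Tm, rbind(b0))$h0,
               as.numeric(t(b0 - ctr) %*% solve(crossprod(Tc)) %*%
                            (b0 - ctr)),
               tolerance = 1e-12)
  expect_error(blank_leverage(matrix(rnorm(4), 2, 2), cbind(1, 1)),
               "singular")
})

test_that("detection limits follow the leverage-inflated variance sum", {
  # h0 = 0 reduces to the univariate IUPAC form
  expect_equal(detection_limits(sigma_b = 2, S0 = 4, sigma_ycal = 9,
                                h0 = 0), 3.3 * 2 / 4)
  # hand evaluation: 3.3 * sqrt(0.25 + 0.01 + 0.0004)
  expect_equal(detection_limits(1, 2, 0.1, 0.04),
               3.3 * sqrt(0.2604), tolerance = 1e-12)
  # LOQ / LOD = 10 / 3.3 exactly, for any inputs
  set.seed(8)
  for (i in 1:10) {
    sb <- runif(1, 0.1, 5); s0 <- runif(1, 0.5, 3)
    sy <- runif(1, 0, 2); h0 <- runif(1, 0, 1)
    lod <- detection_limits(sb, s0, sy, h0, 3.3)
    loq <- detection_limits(sb, s0, sy, h0, 10)
    expect_equal(loq / lod, 10 / 3.3, tolerance = 1e-12)
    # joint homogeneity in (sigma_b, sigma_ycal)
    expect_equal(detection_limits(3 * sb, s0, 3 * sy, h0),
                 3 * detection_limits(sb, s0, sy, h0), tolerance = 1e-12)
  }
  # monotone in leverage
  lims <- detection_limits(1, 1, 0.5, c(0.01, 0.1, 0.5, 2))
  expect_true(all(diff(lims) > 0))
  expect_error(detection_limits(1, 0, 1, 0), "sensitivity")
  expect_error(detection_limits(-1, 1, 1, 0), "non-negative")
})

test_that("calibration reports assemble, print and round-trip", {
  p <- c(1, 5, 20, 40); a <- c(1.2, 4.5, 21, 39)
  rep1 <- build_report("gh", p, a, p / 2 + 10, a, sigma_b = 0.05, S0 = 1,
                       sigma_ycal = 0.4, h0_min = 0.01, h0_max = 0.2)
  expect_s3_class(rep1, "calibration_report")
  expect_equal(rep1$rmse_train, rmse(p, a))
  expect_equal(rep1$loq_min / rep1$lod_min, 10 / 3.3, tolerance = 1e-12)
  expect_lte(rep1$lod_min, rep1$lod_max)
  expect_output(print(rep1), "Calibration report")

  # perfect model with noiseless blanks: zero error, zero limits
  perfect <- build_report("te", a, a, a, a, sigma_b = 0, S0 = 1,
                          sigma_ycal = 0, h0_min = 0, h0_max = 0)
  expect_equal(perfect$rmse_validation, 0)
  expect_equal(perfect$r2_validation, 1)
  expect_equal(perfect$lod_max, 0)

  tmp <- tempfile(fileext = ".json")
  write_calibration_report(rep1, tmp)
  back <- read_calibration_report(tmp)
  for (f in c("rmse_train", "rmse_validation", "r2_train", "r2_validation",
              "lod_min", "lod_max", "loq_min", "loq_max")) {
    expect_equal(back[[f]], rep1[[f]], tolerance = 1e-12)
  }
  tab <- report_table(rep1)
  expect_equal(nrow(tab), 8)
  expect_equal(tab$value[tab$metric == "lod_min"], rep1$lod_min)
  unlink(tmp)
})
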