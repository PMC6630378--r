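test_that("allometric size multiplier matches fixed points", {
  expect_equal(size_function(70, 0.75, 70), 1)
  expect_equal(size_function(70, 1.9, 70), 1)
  # mean weights of the two neonatal/child cohorts
  expect_equal(size_function(3.2, 0.75, 70), 0.09886418, tolerance = 1e-7)
  expect_equal(size_function(12.9, 1, 70), 0.1842857, tolerance = 1e-7)
  expect_error(size_function(-1, 0.75), "positive")
})

test_that("log size multiplier is linear in log weight with slope = power", {
  set.seed(2)
  for (i in 1:20) {
    pw <- runif(1, 0.2, 1.5)
    w1 <- runif(1, 0.5, 30); w2 <- runif(1, 0.5, 30)
    slope <- (log(size_function(w1, pw)) - log(size_function(w2, pw))) /
      (log(w1) - log(w2))
    expect_equal(slope, pw, tolerance = 1e-10)
  }
})

test_that("maturation function is a proper sigmoid in PCA", {
  # half the adult value exactly at tm50, for any hill
  for (hill in c(0.5, 1, 3.68, 5.99, 40))
    expect_identical(maturation_function(48.2, 48.2, hill), 0.5)
  # preterm-cohort mean PCA against the fixed maturation parameters
  expect_equal(maturation_function(41.2, 33.3, 3.68), 0.6864128,
               tolerance = 1e-6)
  expect_equal(maturation_function(1e8, 48.2, 5.99), 1, tolerance = 1e-9)
  pca <- seq(25, 120, by = 0.5)
  fm <- maturation_function(pca, 48.2, 5.99)
  expect_true(all(diff(fm) > 0))
  expect_true(all(fm > 0 & fm < 1))
  # no overflow at extreme hill
  expect_equal(maturation_function(30, 40, 500), 0, tolerance = 1e-12)
  expect_error(maturation_function(-1, 48.2, 5.99), "positive")
})

test_that("individual parameters compose typical value, size, maturation and eta", {
  phb <- pm_spec(theta = c(CL = 0.569, Vd = 5.51, ka = 50, F = 0.724),
                 size = list(CL = list(power = 0.75), Vd = list(power = 1)),
                 maturation = list(CL = list(tm50 = 48.2, hill = 5.99)),
                 iiv = c(CL = 0.1, Vd = 0.2),
                 error = list(model = "proportional", sigma_pro = 0.356))
  # reference weight, PCA at tm50: CL = 0.569 * 1 * 0.5
  p <- individual_parameters(phb, list(WT = 70, PCA = 48.2))
  expect_equal(unname(p["CL"]), 0.2845, tolerance = 1e-12)
  expect_equal(unname(p["Vd"]), 5.51)
  # eta shifts multiplicatively
  p2 <- individual_parameters(phb, list(WT = 70, PCA = 48.2),
                              eta = c(CL = 0.3, Vd = -0.1))
  expect_equal(unname(p2["CL"]), 0.2845 * exp(0.3), tolerance = 1e-12)
  expect_equal(unname(p2["Vd"]), 5.51 * exp(-0.1), tolerance = 1e-12)
  # PCA derived from GA + PNA when absent
  p3 <- individual_parameters(phb, list(WT = 70, GA = 40, PNA = 8.2))
  expect_equal(p3["CL"], p["CL"])
  expect_error(individual_parameters(phb, list(WT = 70)), "maturation")

  csa <- pm_spec(theta = c(CL = 21.3, Vd = 218),
                 size = list(CL = list(power = 0.75), Vd = list(power = 1)),
                 error = list(model = "proportional", sigma_pro = 0.468))
  pc <- individual_parameters(csa, list(WT = 12.9))
  expect_equal(unname(pc["CL"]), 21.3 * (12.9 / 70)^0.75, tolerance = 1e-12)
  expect_equal(unname(pc["Vd"]), 218 * 12.9 / 70, tolerance = 1e-12)
})

test_that("typical values are returned exactly at reference covariates", {
  spec <- pm_spec(theta = c(CL = 2, Vd = 20),
                  size = list(CL = list(power = 0.75), Vd = list(power = 1)),
                  maturation = list(CL = list(tm50 = 45, hill = 4)),
                  iiv = c(CL = 0.1),
                  error = list(model = "proportional", sigma_pro = 0.3))
  p <- individual_parameters(spec, list(WT = 70, PCA = 1e9))
  expect_equal(unname(p["CL"]), 2, tolerance = 1e-9)
  expect_equal(unname(p["Vd"]), 20)
})

test_that("maturation attaches only to clearance", {
  expect_error(
    pm_spec(theta = c(CL = 1, Vd = 10),
            maturation = list(Vd = list(tm50 = 45, hill = 4))),
    "clearance")
})

test_that("residual variance menu follows the error model", {
  lin <- function(model, sp = 0, sa = 0)
    pm_spec(theta = c(CL = 1, Vd = 10),
            error = list(model = model, sigma_pro = sp, sigma_add = sa),
            scale = "linear")
  expect_equal(residual_variance(20, lin("proportional", sp = 0.356)),
               50.6944, tolerance = 1e-10)
  expect_equal(residual_variance(c(1, 7, 100), lin("additive", sa = 2)),
               rep(4, 3))
  # combined with no proportional part degenerates to additive
  expect_equal(residual_variance(13, lin("combined", sp = 0, sa = 2)),
               residual_variance(13, lin("additive", sa = 2)))
  expect_error(residual_variance(-1, lin("proportional", sp = 0.3)),
               "non-positive")
  # log scale: constant variance regardless of the prediction
  logspec <- pm_spec(theta = c(CL = 1, Vd = 10),
                     error = list(model = "proportional", sigma_pro = 0.356),
                     scale = "log")
  expect_equal(residual_variance(c(0.001, 50), logspec), rep(0.356^2, 2))
})

test_that("IIV CV conversions are mutually consistent", {
  expect_equal(iiv_cv(cv_to_omega2(40.8)), 40.8, tolerance = 1e-10)
  expect_equal(iiv_cv(0.04, "approx"), 20)
  expect_lt(iiv_cv(0.04, "approx"), iiv_cv(0.04, "exact"))
})
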