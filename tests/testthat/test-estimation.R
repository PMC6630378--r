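# The inner conditional objective and the FOCE approximation are checked
# against hand evaluation, closed-form Gaussians and the adaptive
# Gauss-Hermite quadrature oracle.

# one subject, bolus dose, observations on the linear scale with additive
# error; parameters chosen so the prediction at t = 2 is exactly 8 mg/L
single_obs_ds <- function() {
  ev <- data.frame(ID = 1, TIME = c(0, 2), AMT = c(100, NA), RATE = 0,
                   DV = c(NA, 10), EVID = c(1, 0), CMT = 1)
  pk_dataset(ev, data.frame(ID = 1, WT = 70))
}
single_obs_spec <- function(omega = 1e-10)
  pm_spec(theta = c(CL = -5 * log(0.8), Vd = 10), iiv = c(CL = omega),
          error = list(model = "additive", sigma_add = 2), scale = "linear")

test_that("conditional objective matches hand evaluation", {
  m <- build_model(1, "iv")
  # (y - f)^2 / v + log v = 4/4 + log 4
  expect_equal(conditional_objective(m, single_obs_spec(1), single_obs_ds(),
                                     1, c(CL = 0)),
               1 + log(4), tolerance = 1e-10)
  # eta prior term adds eta' Omega^-1 eta to the residual part
  spec <- single_obs_spec(0.5)
  f_eta <- predict_concentrations(
    m, pk_regimen(0, 100),
    individual_parameters(spec, list(WT = 70), c(CL = 0.3)), 2)
  resid_part <- (10 - f_eta)^2 / 4 + log(4)
  expect_equal(conditional_objective(m, spec, single_obs_ds(), 1, c(CL = 0.3)),
               resid_part + 0.3^2 / 0.5, tolerance = 1e-6)
})

test_that("vanishing-Omega OFV equals the fixed-effects normal likelihood", {
  m <- build_model(1, "iv")
  # -2 log N(10; 8, 4) = log(2 pi 4) + 4/4
  expect_equal(foce_ofv(m, single_obs_spec(1e-12), single_obs_ds()),
               log(2 * pi * 4) + 1, tolerance = 1e-6)
  expect_equal(marginal_ofv_oracle(m, single_obs_spec(1e-12), single_obs_ds()),
               log(2 * pi * 4) + 1, tolerance = 1e-6)
})

test_that("a dataset without observations has OFV zero", {
  ev <- data.frame(ID = 1, TIME = 0, AMT = 100, RATE = 0, DV = NA_real_,
                   EVID = 1, CMT = 1)
  ds <- pk_dataset(ev, data.frame(ID = 1, WT = 70))
  spec <- single_obs_spec(0.2)
  expect_equal(foce_ofv(build_model(1, "iv"), spec, ds), 0)
})

test_that("FOCE is exact for a model linear in eta with additive error", {
  # bolus observed at the dose instant under LTBS: log C = log(amt/Vd) - eta,
  # exactly linear in the volume eta, so Laplace = quadrature = closed form
  m <- build_model(1, "iv")
  set.seed(3)
  n <- 6
  ev <- do.call(rbind, lapply(seq_len(n), function(i)
    data.frame(ID = i, TIME = 0, AMT = c(100, NA), RATE = 0,
               DV = c(NA, exp(rnorm(1, log(10), 0.4))),
               EVID = c(1, 0), CMT = 1)))
  ds <- pk_dataset(ev, data.frame(ID = seq_len(n), WT = 70))
  omega2 <- 0.09; sigma <- 0.25
  spec <- pm_spec(theta = c(CL = 1, Vd = 10), iiv = c(Vd = omega2),
                  error = list(model = "proportional", sigma_pro = sigma),
                  scale = "log")
  y <- log(ev$DV[ev$EVID == 0])
  # marginally y ~ N(log(amt/Vd), sigma^2 + omega^2)
  vtot <- sigma^2 + omega2
  analytic <- sum(log(2 * pi * vtot) + (y - log(10))^2 / vtot)
  expect_equal(foce_ofv(m, spec, ds), analytic, tolerance = 1e-8)
  expect_equal(marginal_ofv_oracle(m, spec, ds, n_nodes = 16), analytic,
               tolerance = 1e-8)
})

test_that("FOCE tracks the quadrature oracle on nonlinear problems", {
  st <- generate_study("phb", n = 5, seed = 7)
  spec <- st$truth
  spec$iiv <- spec$iiv["CL"]          # one eta per subject
  fo <- foce_ofv(st$model, spec, st$dataset)
  qo <- marginal_ofv_oracle(st$model, spec, st$dataset, n_nodes = 32)
  expect_lt(abs(fo - qo), 0.5)
  # node-count convergence of the oracle itself
  q8 <- marginal_ofv_oracle(st$model, spec, st$dataset, n_nodes = 8)
  q64 <- marginal_ofv_oracle(st$model, spec, st$dataset, n_nodes = 64)
  expect_lt(abs(q8 - q64), 1e-4)
})

test_that("OFV is invariant to subject ordering", {
  st <- generate_study("van", n = 8, seed = 5)
  ds <- st$dataset
  o1 <- foce_ofv(st$model, st$truth, ds)
  ids <- unique(ds$events$ID)
  perm <- rev(ids)
  ev2 <- do.call(rbind, lapply(perm, function(i)
    ds$events[ds$events$ID == i, ]))
  cov2 <- ds$covariates[match(perm, ds$covariates$ID), ]
  o2 <- foce_ofv(st$model, st$truth, pk_dataset(ev2, cov2))
  expect_equal(o1, o2, tolerance = 1e-9)
})

test_that("noise-free rich data identifies CL and Vd almost exactly", {
  # no IIV, no residual noise: DV is the model curve; the fit must land on
  # the generating parameters from distant starting values
  toy <- toy_study(n = 6, seed = 4, sigma = 1e-8, iiv_cl = 0)
  spec <- toy$spec
  spec$error$sigma_pro <- 1e-3
  spec$fixed <- c(spec$fixed, "sigma_pro")
  fit <- fit_foce(toy$model, spec, toy$dataset,
                  inits = c(CL = 0.5, Vd = 60), control = quick_ctl)
  expect_lt(abs(fit$estimates["CL"] / 2 - 1), 1e-3)
  expect_lt(abs(fit$estimates["Vd"] / 20 - 1), 1e-3)
})

test_that("refitting from the optimum leaves the OFV unchanged", {
  toy <- toy_study(n = 10, seed = 8)
  fit <- fit_foce(toy$model, toy$spec, toy$dataset, control = quick_ctl)
  fit2 <- fit_foce(toy$model, fit$spec, toy$dataset, control = quick_ctl)
  expect_lt(abs(fit2$ofv - fit$ofv), 0.01)
})

test_that("adding a free parameter cannot worsen the optimal OFV", {
  toy <- toy_study(n = 12, seed = 9)
  restricted <- toy$spec
  restricted$size <- list()               # drop allometric scaling
  fit_r <- fit_foce(toy$model, restricted, toy$dataset, control = quick_ctl)
  freed <- restricted
  freed$size <- list(CL = list(power = 0.01, estimate = TRUE))
  fit_f <- fit_foce(toy$model, freed, toy$dataset, control = quick_ctl)
  expect_lte(fit_f$ofv, fit_r$ofv + 0.1)
})

test_that("likelihood-ratio comparison handles signs, df and thresholds", {
  a <- compare_models(100, 96.159, df = 1)
  expect_equal(a$p_value, 0.05, tolerance = 1e-3)
  # the size-scaling improvement reported for the children's cohort
  b <- compare_models(-121.986, -153.115, df = 1)
  expect_equal(b$delta_ofv, -31.129)
  expect_equal(b$p_value, 2.414e-8, tolerance = 1e-3)
  expect_true(b$significant)
  worse <- compare_models(100, 105, df = 1)
  expect_equal(worse$p_value, 1)
  expect_false(worse$significant)
  fixed_form <- compare_models(100, 95, df = 0)
  expect_true(is.na(fixed_form$p_value))
  expect_true(fixed_form$significant)
  expect_false(compare_models(100, 97, df = 0)$significant)
})

test_that("standard errors are reported as finite RSE percentages", {
  toy <- toy_study(n = 15, seed = 10)
  fit <- fit_foce(toy$model, toy$spec, toy$dataset,
                  control = list(restarts = 0L, maxit = 600L, se = TRUE))
  expect_true(all(is.finite(fit$rse_percent[c("CL", "Vd")])))
  expect_lt(fit$rse_percent["CL"], 50)
})
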