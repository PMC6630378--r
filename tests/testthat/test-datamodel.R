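test_that("construction enforces event-record invariants", {
  ds <- tiny_dataset()
  expect_s3_class(ds, "pk_dataset")
  expect_equal(n_subjects(ds), 2)

  ev <- ds$events
  expect_error(pk_dataset(transform(ev, DV = 5), ds$covariates),
               "DV present on dose")
  bad_amt <- ev; bad_amt$AMT[2] <- 50
  expect_error(pk_dataset(bad_amt, ds$covariates), "AMT present on observation")
  bad_t <- ev; bad_t$TIME[2] <- -1
  expect_error(pk_dataset(bad_t, ds$covariates), "negative TIME")
  expect_error(pk_dataset(ev[, setdiff(names(ev), "EVID")], ds$covariates),
               "mandatory column")
})

test_that("dose events sort before observations at tied times", {
  ev <- data.frame(ID = 1, TIME = c(2, 2, 0), AMT = c(NA, 50, 100), RATE = 0,
                   DV = c(4, NA, NA), EVID = c(0, 1, 1), CMT = 1)
  ds <- pk_dataset(ev, data.frame(ID = 1, WT = 5))
  expect_equal(ds$events$EVID, c(1, 1, 0))
})

test_that("write -> read round-trips a synthetic study field-for-field", {
  st <- generate_study("phb", n = 8, seed = 42)
  path <- tempfile(fileext = ".csv")
  write_pk_dataset(st$dataset, path)
  back <- read_pk_dataset(path)
  expect_equal(back$events$ID, st$dataset$events$ID)
  for (col in c("TIME", "AMT", "RATE", "DV")) {
    expect_equal(back$events[[col]], st$dataset$events[[col]],
                 tolerance = 1e-12, label = col)
  }
  for (col in setdiff(names(st$dataset$covariates), "ID"))
    expect_equal(back$covariates[[col]], st$dataset$covariates[[col]],
                 tolerance = 1e-12, label = col)
})

test_that("missing lab covariates survive the round trip as missing", {
  set.seed(7)
  for (rep in 1:3) {
    st <- generate_study("van", n = 6, seed = 100 + rep)
    cov <- st$dataset$covariates
    holes <- matrix(runif(nrow(cov) * 2) < 0.4, ncol = 2)
    cov$SCR[holes[, 1]] <- NA
    cov$ALB[holes[, 2]] <- NA
    ds <- pk_dataset(st$dataset$events, cov)
    path <- tempfile(fileext = ".csv")
    write_pk_dataset(ds, path)
    back <- read_pk_dataset(path)
    expect_identical(is.na(back$covariates$SCR), is.na(cov$SCR))
    expect_identical(is.na(back$covariates$ALB), is.na(cov$ALB))
  }
})

test_that("an empty dataset writes a header-only file", {
  ds <- pk_dataset(data.frame(ID = numeric(), TIME = numeric(),
                              AMT = numeric(), RATE = numeric(),
                              DV = numeric(), EVID = integer(),
                              CMT = integer()),
                   data.frame(ID = numeric(), WT = numeric()))
  path <- tempfile(fileext = ".csv")
  write_pk_dataset(ds, path)
  expect_length(readLines(path), 1L)
})

test_that("reader reports format and validation problems", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("ID,TIME,DV,AMT", "1,0,.,100"), path)
  expect_error(read_pk_dataset(path), "EVID")
  writeLines(c("ID,TIME,DV,AMT,EVID,WT",
               "1,0,5,100,1,3.2",
               "1,2,4,.,0,3.2"), path)
  expect_error(read_pk_dataset(path), "DV present on dose")
  writeLines(c("ID,TIME,DV,AMT,EVID,WT",
               "1,-3,.,100,1,3.2",
               "1,2,4,.,0,3.2"), path)
  expect_error(read_pk_dataset(path), "negative TIME")
})

test_that("column mapping resolves nonstandard headers", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("SUBJ,TIME,CONC,AMT,EVID,WT",
               "1,0,.,100,1,3.2",
               "1,2,4,.,0,3.2"), path)
  ds <- read_pk_dataset(path, column_map = c(ID = "SUBJ", DV = "CONC"))
  expect_equal(n_subjects(ds), 1)
  expect_equal(ds$events$DV[2], 4)
})

test_that("post-conceptional age matches the demographic summaries", {
  # term-range neonate: 36.7 wk gestation + 32.4 days ~ 41.3 wk
  expect_equal(compute_pca(36.7, 32.4, "days"), 41.32857, tolerance = 1e-6)
  expect_equal(compute_pca(40, 0, "days"), 40)
  # preterm cohort mean: 31.9 wk + 9.3 wk postnatal = 41.2 wk
  expect_equal(compute_pca(31.9, 9.3, "weeks"), 41.2)
  expect_error(compute_pca(36, 10, "fortnights"))
  expect_error(compute_pca(0, 10, "days"), "positive")
})

test_that("compute_pca is additive and unit-invariant", {
  set.seed(11)
  for (i in 1:25) {
    ga <- runif(1, 23, 42)
    d <- runif(1, 0, 200)
    expect_equal(compute_pca(ga, d, "days"), compute_pca(ga, d / 7, "weeks"),
                 tolerance = 1e-12)
    m <- runif(1, 0, 24)
    expect_equal(compute_pca(ga, m, "months"),
                 ga + m * (365.25 / 12) / 7, tolerance = 1e-12)
  }
})

test_that("validation flags estimation-blocking issues and only those", {
  st <- generate_study("phb", n = 5, seed = 3)
  expect_equal(nrow(validate_pk_dataset(st$dataset)), 0)

  cov <- st$dataset$covariates
  cov$WT[2] <- NA
  ds <- pk_dataset(st$dataset$events, cov)
  iss <- validate_pk_dataset(ds)
  expect_equal(nrow(iss), 1)
  expect_match(iss$issue, "weight")
  expect_equal(iss$subject, 2)

  ev <- st$dataset$events
  ev <- ev[!(ev$ID == 4 & ev$EVID == 0), ]
  iss2 <- validate_pk_dataset(pk_dataset(ev, st$dataset$covariates))
  expect_true(any(iss2$subject == 4 & iss2$issue == "no observations"))
})

test_that("a YAML config round-trips the parameter model and column map", {
  skip_if_not_installed("yaml")
  path <- tempfile(fileext = ".yaml")
  writeLines(c(
    "theta: {CL: 0.6, Vd: 5.5, ka: 50, F: 0.7}",
    "size:",
    "  CL: {power: 0.75}",
    "  Vd: {power: 1}",
    "maturation:",
    "  CL: {tm50: 48.2, hill: 5.99, estimate: true}",
    "iiv: {CL: 0.15, Vd: 0.48}",
    "error: {model: proportional, sigma_pro: 0.356}",
    "scale: log",
    "fixed: [ka]",
    "column_map: {ID: SUBJ, DV: CONC}"), path)
  cfg <- pm_spec_from_yaml(path)
  expect_s3_class(cfg$spec, "pm_spec")
  expect_equal(cfg$spec$theta[["CL"]], 0.6)
  expect_equal(cfg$spec$maturation$CL$tm50, 48.2)
  expect_true(cfg$spec$maturation$CL$estimate)
  expect_equal(cfg$spec$iiv[["Vd"]], 0.48)
  expect_equal(cfg$column_map[["DV"]], "CONC")
  # composes with individual_parameters like a hand-built spec
  p <- individual_parameters(cfg$spec, list(WT = 70, PCA = 48.2))
  expect_equal(unname(p["CL"]), 0.3, tolerance = 1e-12)
})
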