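# Shared fixtures, built in code at test time.

# Optimiser settings for fast, SE-free refits inside tests.
quick_ctl <- list(se = FALSE, restarts = 0L, maxit = 600L, reltol = 1e-7)

# A minimal well-formed two-subject dataset (one dose + two observations each).
tiny_dataset <- function() {
  ev <- data.frame(
    ID = c(1, 1, 1, 2, 2, 2),
    TIME = c(0, 1, 4, 0, 2, 6),
    AMT = c(100, NA, NA, 80, NA, NA),
    RATE = 0,
    DV = c(NA, 8.1, 5.2, NA, 6.3, 3.9),
    EVID = c(1, 0, 0, 1, 0, 0),
    CMT = 1)
  cov <- data.frame(ID = c(1, 2), WT = c(10, 8), GA = c(38, 36),
                    PNA = c(4, 6), PCA = c(42, 42), SCR = c(0.4, NA))
  pk_dataset(ev, cov)
}

# Small intravenous-bolus study for diagnostics/covariate-search tests:
# one-compartment, rich 4-point sampling, log-scale proportional error.
# `scr_coef` plants a power effect of serum creatinine on clearance;
# `iiv` can be zeroed for deterministic checks.
toy_study <- function(n = 20, seed = 1, scr_coef = 0, sigma = 0.2,
                      iiv_cl = 0.09, iiv_vd = 0, n_null = 0) {
  set.seed(seed)
  model <- build_model(1, "iv")
  cov <- data.frame(ID = seq_len(n),
                    WT = exp(rnorm(n, log(10), 0.35)),
                    SCR = exp(rnorm(n, log(0.5), 0.3)))
  iiv <- c(CL = iiv_cl, Vd = iiv_vd)
  spec <- pm_spec(
    theta = c(CL = 2, Vd = 20),
    size = list(CL = list(power = 0.75), Vd = list(power = 1)),
    iiv = iiv[iiv > 0],
    error = list(model = "proportional", sigma_pro = sigma),
    scale = "log")
  if (scr_coef != 0)
    spec$covariate_effects <- list(CL = list(SCR = list(
      coef = scr_coef, center = 0.5, form = "power")))
  ev <- do.call(rbind, lapply(seq_len(n), function(i) {
    obs_t <- c(runif(1, 0.5, 2), runif(1, 3, 6), runif(1, 7, 10),
               runif(1, 12.5, 16))
    rbind(data.frame(ID = i, TIME = c(0, 12), AMT = 10 * cov$WT[i],
                     RATE = 0, DV = NA_real_, EVID = 1L, CMT = 1L),
          data.frame(ID = i, TIME = obs_t, AMT = NA_real_,
                     RATE = 0, DV = NA_real_, EVID = 0L, CMT = 1L))
  }))
  ds <- simulate_observations(model, spec, pk_dataset(ev, cov))
  if (n_null > 0) ds <- add_null_covariates(ds, n_null)
  list(model = model, spec = spec, dataset = ds)
}

# Wrap a parameter-model spec as a fit object without running the
# optimiser, for diagnostics that evaluate a model at known parameters.
as_fit <- function(model, spec, ds, constant = TRUE) {
  det <- pedpk:::foce_details(model, spec, ds, constant = constant)
  an <- det$eta_names
  eta_hat <- do.call(rbind, lapply(det$per_subject, function(p)
    if (length(an)) p$eta else numeric(0)))
  if (length(an)) colnames(eta_hat) <- an
  structure(list(model = model, spec = spec, ofv = det$ofv,
                 eta_hat = eta_hat, converged = TRUE, constant = constant,
                 estimates = pedpk:::get_free(spec, pedpk:::free_params(spec, model)),
                 theta = spec$theta, omega2 = spec$iiv,
                 sigma = c(pro = spec$error$sigma_pro,
                           add = spec$error$sigma_add)),
            class = "pk_fit")
}

# Heavy fits shared between acceptance-level tests, computed once per run.
.fit_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (is.null(.fit_cache[[key]])) .fit_cache[[key]] <- force(expr)
  .fit_cache[[key]]
}
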