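#!/usr/bin/env Rscript
# Fit the final population models (one-compartment + allometric size on CL
# and Vd + sigmoid-Emax maturation on CL for the neonatal drugs) to the
# three simulated studies and tabulate estimates with RSEs, in the layout
# of a population-PK parameter table. Run 01_simulate_studies.R first.

library(pedpk)

studies <- list(
  csa = list(file = "results/sim_csa.csv",
             inits = c(CL = 10, Vd = 100, omega2_CL = 0.05, omega2_Vd = 0.05,
                       sigma_pro = 0.3)),
  phb = list(file = "results/sim_phb.csv",
             inits = c(CL = 1, Vd = 3, F = 0.5, omega2_CL = 0.1,
                       omega2_Vd = 0.3, sigma_pro = 0.3)),
  van = list(file = "results/sim_van.csv",
             inits = c(CL = 30, Vd = 8, omega2_CL = 0.1, omega2_Vd = 0.1,
                       sigma_pro = 0.3)))

rows <- list()
fits <- list()
for (nm in names(studies)) {
  ds <- read_pk_dataset(studies[[nm]]$file)
  design <- study_design(nm)
  spec <- design$truth              # same structure; estimates start anew
  # maturation parameters at reference values: at these cohort sizes the
  # sigmoid is not jointly identifiable with the clearance typical value
  # (see the methods vignette), the standard reason the field fixes them
  if (length(spec$maturation))
    spec$fixed <- union(spec$fixed, c("tm50_CL", "hill_CL"))
  fit <- fit_foce(design$model, spec, ds, inits = studies[[nm]]$inits,
                  control = list(restarts = 1L))
  fits[[nm]] <- fit
  est <- fit$estimates
  rse <- fit$rse_percent
  truth_of <- function(p) {
    tr <- design$truth
    if (p %in% names(tr$theta)) tr$theta[[p]]
    else if (startsWith(p, "omega2")) iiv_cv(tr$iiv[[sub("omega2_", "", p)]])
    else if (p == "sigma_pro") 100 * tr$error$sigma_pro
    else NA_real_
  }
  for (p in names(est)) {
    val <- est[[p]]
    shown <- if (startsWith(p, "omega2")) iiv_cv(val)
             else if (p == "sigma_pro") 100 * val
             else val
    rows[[paste(nm, p)]] <- data.frame(
      study = nm, parameter = p, estimate = shown,
      generating = truth_of(p),
      units = if (startsWith(p, "omega2") || p == "sigma_pro") "CV%"
              else "",
      rse_percent = if (!is.null(rse)) rse[[p]] else NA)
  }
  message(sprintf("%s: OFV %.2f, %s", nm, fit$ofv,
                  if (fit$converged) "converged" else "NOT converged"))
}

tab <- do.call(rbind, rows)
write.csv(tab, "results/final_estimates.csv", row.names = FALSE)
saveRDS(fits, "results/final_fits.rds")   # consumed by 04/05 only
print(tab, digits = 3, row.names = FALSE)
message("Compare the estimate and generating columns: the large vancomycin ",
        "cohort recovers its truths closely, while the sparse designs (2 ",
        "samples/subject for cyclosporine, troughs only for the n=28 ",
        "phenobarbital cohort) show the expected wide sampling variability ",
        "in clearance and volume.")
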