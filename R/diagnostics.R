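# Model evaluation: goodness-of-fit tables, conditional weighted residuals,
# visual predictive checks, nonparametric bootstrap.

#' Goodness-of-fit table
#'
#' Per-observation population prediction (eta = 0), individual prediction
#' (at the empirical Bayes eta), and conditional weighted residual.
#' Predictions are reported on the concentration scale (mg/L); `cwres` is
#' computed on the fitting scale (log concentrations under LTBS).
#'
#' @param fit a `pk_fit` from [fit_foce()]
#' @param ds the fitted `pk_dataset`
#' @return data.frame: subject, time, dv, pred, ipred, cwres
#' @export
gof_table <- function(fit, ds) {
  det <- foce_details(fit$model, fit$spec, ds, constant = fit$constant)
  cw <- cwres_per_subject(fit, det)
  rows <- lapply(seq_along(det$per_subject), function(i) {
    ps <- det$per_subject[[i]]
    subj <- det$subjects[[i]]
    if (isTRUE(ps$skipped)) {
      warning("subject ", subj$id, " has no observations; skipped")
      return(NULL)
    }
    lpred0 <- subject_predict(fit$model, fit$spec, subj,
                              stats::setNames(rep(0, ncol(fit$eta_hat)),
                                              colnames(fit$eta_hat)))
    to_conc <- function(f) if (fit$spec$scale == "log") exp(f) else f
    dv <- if (fit$spec$scale == "log") exp(subj$y) else subj$y
    data.frame(subject = subj$id, time = subj$times, dv = dv,
               pred = to_conc(lpred0), ipred = to_conc(ps$f),
               cwres = cw[[i]])
  })
  do.call(rbind, rows)
}

# FOCE-linearised conditional weighted residuals for each subject, given
# the foce_details of the fit.
cwres_per_subject <- function(fit, det) {
  an <- det$eta_names
  q <- length(an)
  Om <- if (q) diag(fit$spec$iiv[an], nrow = q) else matrix(0, 0, 0)
  lapply(seq_along(det$per_subject), function(i) {
    ps <- det$per_subject[[i]]
    subj <- det$subjects[[i]]
    if (isTRUE(ps$skipped)) return(numeric(0))
    if (q == 0L) return((subj$y - ps$f) / sqrt(ps$v))
    G <- ps$G
    # residual about the linearisation: y - (f(eta_hat) - G eta_hat)
    r <- subj$y - (ps$f - drop(G %*% ps$eta))
    C <- G %*% Om %*% t(G) + diag(ps$v, nrow = length(ps$v))
    drop(sym_inv_sqrt(C) %*% r)
  })
}

#' Conditional weighted residuals
#'
#' Residuals decorrelated under the FOCE linearisation at the empirical
#' Bayes etas: `res = y - (f(eta_hat) - G eta_hat)` with `G = df/deta`, and
#' `cwres = C^{-1/2} res` with `C = G Omega G' + V(eta_hat)` and the symmetric
#' (eigen) matrix square root, so the result is invariant to observation
#' ordering. Near-singular `C` is ridged by 1e-10 with a warning. For a
#' well-specified model CWRES is approximately standard normal; values
#' beyond +-4 flag misfit.
#'
#' @inheritParams gof_table
#' @return numeric vector, one value per observation (dataset event order)
#' @export
compute_cwres <- function(fit, ds) {
  det <- foce_details(fit$model, fit$spec, ds, constant = fit$constant)
  unlist(cwres_per_subject(fit, det), use.names = FALSE)
}

#' Visual predictive check
#'
#' Simulates `n_sim` replicates of the dataset at the fitted estimates
#' (same subjects, covariates, regimens and sampling times; new etas and
#' residual noise), computes observation percentiles per time bin in every
#' replicate, and returns the across-replicate confidence band for each
#' percentile with the observed percentiles overlaid. Percentiles are
#' computed on the fitting scale and reported in mg/L. Time bins are
#' quantile-based; bins with fewer than 5 observations merge into their
#' neighbour with a warning.
#'
#' @inheritParams gof_table
#' @param n_sim number of simulation replicates (>= 100)
#' @param percentiles observation percentiles to track
#' @param ci band coverage, percent
#' @param bins number of quantile time bins
#' @param seed RNG seed
#' @return object of class `pk_vpc`: `table` (bin, time span and midpoint,
#'   percentile, observed value, band lo/hi), `n_sim`, `inside` fraction of
#'   observed percentile points inside their band
#' @export
vpc <- function(fit, ds, n_sim = 1000L, percentiles = c(5, 50, 95),
                ci = 95, bins = 8L, seed = NULL) {
  if (n_sim < 100L) stop("n_sim must be >= 100")
  if (!is.null(seed)) set.seed(seed)
  spec <- fit$spec
  model <- fit$model
  subs <- build_subjects(model, spec, ds)
  subs <- subs[vapply(subs, function(s) length(s$y) > 0, TRUE)]
  times <- unlist(lapply(subs, `[[`, "times"))
  yobs <- unlist(lapply(subs, `[[`, "y"))   # fitting scale
  n_obs <- length(yobs)

  edges <- unique(stats::quantile(times, probs = seq(0, 1, length.out = bins + 1)))
  bin <- cut(times, edges, include.lowest = TRUE, labels = FALSE)
  bin <- match(bin, sort(unique(bin)))     # drop empty intervals
  # merge small bins leftward
  repeat {
    cnt <- tabulate(bin, nbins = max(bin))
    small <- which(cnt < 5)
    if (!length(small) || max(bin) == 1L) break
    s <- small[1]
    warning("time bin with <5 observations merged with neighbour")
    bin[bin == s] <- if (s == 1L) 2L else s - 1L
    bin <- match(bin, sort(unique(bin)))
  }
  nb <- max(bin)

  an <- active_etas(spec)
  sdl <- if (spec$scale == "log")
    sqrt(spec$error$sigma_pro^2 + spec$error$sigma_add^2) else NULL
  et <- err_terms(spec)
  p <- percentiles / 100
  # percentiles per bin for one vector of observations (fitting scale)
  bin_pct <- function(y) {
    out <- matrix(NA_real_, nb, length(p))
    for (b in seq_len(nb))
      out[b, ] <- stats::quantile(y[bin == b], probs = p, names = FALSE)
    out
  }
  obs_pct <- bin_pct(yobs)

  preds <- lapply(subs, function(s) make_predictor(model, spec, s))
  sim_pct <- array(NA_real_, c(n_sim, nb, length(p)))
  for (s in seq_len(n_sim)) {
    ysim <- numeric(n_obs)
    pos <- 1L
    for (j in seq_along(subs)) {
      subj <- subs[[j]]
      eta <- stats::rnorm(length(an), 0, sqrt(spec$iiv[an]))
      lf <- preds[[j]](eta)
      n_i <- length(lf)
      ysim[pos:(pos + n_i - 1)] <- if (spec$scale == "log") {
        lf + stats::rnorm(n_i, 0, sdl)
      } else {
        v <- et$v(lf)
        lf + stats::rnorm(n_i, 0, sqrt(v))
      }
      pos <- pos + n_i
    }
    sim_pct[s, , ] <- bin_pct(ysim)
  }
  alpha <- (100 - ci) / 200
  to_conc <- function(x) if (spec$scale == "log") exp(x) else x
  tab <- do.call(rbind, lapply(seq_len(nb), function(b) {
    do.call(rbind, lapply(seq_along(p), function(k) {
      band <- stats::quantile(sim_pct[, b, k], probs = c(alpha, 1 - alpha),
                              names = FALSE)
      data.frame(bin = b,
                 t_lo = min(times[bin == b]), t_hi = max(times[bin == b]),
                 t_mid = stats::median(times[bin == b]),
                 percentile = percentiles[k],
                 observed = to_conc(obs_pct[b, k]),
                 lo = to_conc(band[1]), hi = to_conc(band[2]),
                 n_obs = sum(bin == b))
    }))
  }))
  tab$inside <- tab$observed >= tab$lo & tab$observed <= tab$hi
  structure(list(table = tab, n_sim = n_sim, ci = ci,
                 inside = mean(tab$inside)),
            class = "pk_vpc")
}

#' @export
print.pk_vpc <- function(x, ...) {
  cat(sprintf("pk_vpc: %d simulations, %d bins, %.0f%% of observed percentile points inside %g%% bands\n",
              x$n_sim, max(x$table$bin), 100 * x$inside, x$ci))
  invisible(x)
}

#' Nonparametric bootstrap of a population PK fit
#'
#' Resamples subjects with replacement (same study size), refits each
#' resample starting from the original point estimates, and reports the
#' 5th and 95th percentiles of the converged refit estimates per parameter.
#' Flagged unreliable when fewer than half the refits converge.
#'
#' @inheritParams gof_table
#' @param n_resamples number of bootstrap datasets
#' @param seed RNG seed
#' @param control passed to [fit_foce()] (standard errors are disabled for
#'   refits regardless)
#' @return object of class `pk_bootstrap`: `summary` (parameter, estimate,
#'   p5, p95), `estimates` matrix, `n_converged`, `reliable`
#' @export
bootstrap_fit <- function(fit, ds, n_resamples = 1000L, seed = NULL,
                          control = list()) {
  if (n_resamples < 1L) stop("n_resamples must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  control$se <- FALSE
  ids <- unique(ds$events$ID)
  n <- length(ids)
  est_names <- names(fit$estimates)
  out <- matrix(NA_real_, n_resamples, length(est_names),
                dimnames = list(NULL, est_names))
  conv <- logical(n_resamples)
  for (b in seq_len(n_resamples)) {
    pick <- sample(ids, n, replace = TRUE)
    ev <- do.call(rbind, lapply(seq_len(n), function(j) {
      e <- ds$events[ds$events$ID == pick[j], , drop = FALSE]
      e$ID <- j
      e
    }))
    cv <- do.call(rbind, lapply(seq_len(n), function(j) {
      c1 <- ds$covariates[ds$covariates$ID == pick[j], , drop = FALSE]
      c1$ID <- j
      c1
    }))
    dsb <- pk_dataset(ev, cv, pna_unit = ds$pna_unit)
    fb <- tryCatch(fit_foce(fit$model, fit$spec, dsb, control = control),
                   error = function(e) NULL)
    if (!is.null(fb)) {
      out[b, ] <- fb$estimates[est_names]
      conv[b] <- fb$converged
    }
  }
  ok <- conv & stats::complete.cases(out)
  summ <- data.frame(
    parameter = est_names,
    estimate = unname(fit$estimates[est_names]),
    p5 = apply(out[ok, , drop = FALSE], 2, stats::quantile, probs = 0.05,
               na.rm = TRUE),
    p95 = apply(out[ok, , drop = FALSE], 2, stats::quantile, probs = 0.95,
                na.rm = TRUE),
    row.names = NULL)
  structure(list(summary = summ, estimates = out[ok, , drop = FALSE],
                 n_resamples = n_resamples, n_converged = sum(ok),
                 reliable = sum(ok) >= n_resamples / 2),
            class = "pk_bootstrap")
}

#' @export
print.pk_bootstrap <- function(x, ...) {
  cat(sprintf("pk_bootstrap: %d/%d converged resamples%s\n",
              x$n_converged, x$n_resamples,
              if (x$reliable) "" else " (UNRELIABLE: <50% converged)"))
  print(transform(x$summary, estimate = signif(estimate, 4),
                  p5 = signif(p5, 4), p95 = signif(p95, 4)))
  invisible(x)
}
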