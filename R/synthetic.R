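# Synthetic pediatric PK studies.
#
# Three built-in designs emulate the trial structures the package is aimed
# at: "csa" (children on two 24-h cyclosporine infusions with one sample at
# 20 h into each), "phb" (neonates on an intravenous phenobarbital loading
# dose followed by daily oral maintenance, trough-sampled), and "van"
# (neonates on intermittent 1-h vancomycin infusions every 6-24 h with
# sparse post-dose sampling). Demographics are truncated normals; the true
# parameter models carry allometric size scaling on CL and Vd and, for the
# neonatal designs, sigmoid-Emax maturation on CL.

tn <- function(mean, sd, lower, upper) list(mean = mean, sd = sd,
                                            lower = lower, upper = upper)

#' Built-in synthetic study designs
#'
#' @param name "csa", "phb" or "van"
#' @param scr_effect optional planted serum-creatinine power effect on CL
#'   (`CL x (SCR/median)^-scr_effect`), for covariate-search power studies;
#'   0 disables it
#' @return a `study_design` list: structural `model`, true parameter model
#'   `truth`, demographic distributions, dosing and sampling rules
#' @export
study_design <- function(name = c("csa", "phb", "van"), scr_effect = 0) {
  name <- match.arg(name)
  d <- switch(
    name,
    csa = list(
      name = "csa", n_default = 34L,
      model = build_model(1, "iv"),
      demog = list(WT = tn(12.9, 3.8, 5, 24),
                   PNA_MO = tn(26.8, 17.8, 1, 79)),
      wt_age_cor = 0.6,
      labs = list(SCR = tn(0.34, 0.09, 0.2, 0.8),
                  ALB = tn(4.5, 0.3, 3.4, 5.2),
                  HCT = tn(31.7, 3.4, 23.8, 40.8),
                  CHOL = tn(167.3, 29.7, 102, 240)),
      truth = pm_spec(
        theta = c(CL = 21.3, Vd = 218),
        size = list(CL = list(power = 0.75), Vd = list(power = 1)),
        iiv = c(CL = cv_to_omega2(16.8), Vd = cv_to_omega2(12.3)),
        error = list(model = "proportional", sigma_pro = 0.468),
        scale = "log"),
      dose_mgkg = 15, infusion_h = 24),
    phb = list(
      name = "phb", n_default = 28L,
      model = build_model(1, "mixed"),
      demog = list(GA = tn(36.7, 4.4, 23.6, 41.7),
                   PNA_D = tn(32.4, 30.7, 3, 150),
                   WT = tn(3.3, 1, 1, 6.9)),
      wt_age_cor = 0.6,
      labs = list(SCR = tn(0.6, 0.59, 0.2, 3.8),
                  AST = tn(64, 102.7, 11, 676),
                  TBIL = tn(3.8, 3.3, 0.2, 14.5)),
      truth = pm_spec(
        theta = c(CL = 0.569, Vd = 5.51, ka = 50, F = 0.724),
        size = list(CL = list(power = 0.75), Vd = list(power = 1)),
        maturation = list(CL = list(tm50 = 48.2, hill = 5.99,
                                    estimate = TRUE)),
        iiv = c(CL = cv_to_omega2(40.8), Vd = cv_to_omega2(78.7)),
        error = list(model = "proportional", sigma_pro = 0.356),
        scale = "log", fixed = "ka"),
      load_mgkg = c(15, 20), maint_mgkg_d = c(3, 5),
      maint_delay_h = c(12, 24), n_maint = 5L, load_infusion_h = 0.25),
    van = list(
      name = "van", n_default = 93L,
      model = build_model(1, "iv"),
      demog = list(GA = tn(31.9, 4.7, 22.9, 40.3),
                   PNA_WK = tn(9.3, 12.4, 0.1, 80.4),
                   WT = tn(3.2, 2.6, 0.4, 14.9)),
      wt_age_cor = 0.6,
      labs = list(SCR = tn(0.4, 0.3, 0.1, 3.37),
                  CYSC = tn(1.8, 0.5, 0.7, 3.6),
                  ALB = tn(2.7, 0.6, 1.6, 4.9),
                  TP = tn(4.4, 0.8, 1.7, 6.9)),
      truth = pm_spec(
        theta = c(CL = 69.4, Vd = 3.23),
        size = list(CL = list(power = 0.75), Vd = list(power = 1)),
        maturation = list(CL = list(tm50 = 33.3, hill = 3.68,
                                    estimate = FALSE)),
        iiv = c(CL = cv_to_omega2(10.4), Vd = cv_to_omega2(52.8)),
        error = list(model = "proportional", sigma_pro = 0.408),
        scale = "log"),
      dose_mgkg = 15, infusion_h = 1, n_doses = 6L,
      interval_h = c(6, 24), sample_window_h = c(0.5, 23.5),
      peak_window_h = c(0.5, 2), n_samples = 3L)
  )
  if (scr_effect != 0) {
    d$truth$covariate_effects <- list(
      CL = list(SCR = list(coef = -scr_effect,
                           center = d$labs$SCR$mean, form = "power")))
  }
  class(d) <- "study_design"
  d
}

#' Draw a synthetic cohort's covariates
#'
#' Demographics come from the design's truncated normals (inverse-CDF
#' sampling, so draws are exact and reproducible); body weight shares a
#' normal score with age (design correlation) so heavier subjects are older.
#' Laboratory covariates are truncated normals correlated with the weight
#' score by `lab_cor`. PCA is derived as GA + PNA in weeks.
#'
#' @param design a [study_design()]
#' @param n number of subjects
#' @param seed optional RNG seed
#' @param lab_cor correlation of laboratory scores with the weight score
#' @return covariate data.frame (ID, WT, age variables in weeks, labs)
#' @export
generate_cohort <- function(design, n, seed = NULL, lab_cor = 0.3) {
  if (n < 1) stop("n must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  dm <- design$demog
  draw_tn <- function(p, z) {
    plo <- stats::pnorm(p$lower, p$mean, p$sd)
    phi <- stats::pnorm(p$upper, p$mean, p$sd)
    q <- stats::qnorm(plo + stats::pnorm(z) * (phi - plo), p$mean, p$sd)
    pmin(pmax(q, p$lower), p$upper)
  }
  z_age <- stats::rnorm(n)
  r <- design$wt_age_cor
  z_wt <- r * z_age + sqrt(1 - r^2) * stats::rnorm(n)
  cov <- data.frame(ID = seq_len(n))
  cov$WT <- draw_tn(dm$WT, z_wt)
  if (!is.null(dm$GA)) cov$GA <- draw_tn(dm$GA, stats::rnorm(n))
  if (!is.null(dm$PNA_D)) cov$PNA <- draw_tn(dm$PNA_D, z_age) / 7
  if (!is.null(dm$PNA_WK)) cov$PNA <- draw_tn(dm$PNA_WK, z_age)
  if (!is.null(dm$PNA_MO)) cov$PNA <- draw_tn(dm$PNA_MO, z_age) * (365.25 / 12) / 7
  if (!is.null(cov$GA)) cov$PCA <- cov$GA + cov$PNA
  for (lab in names(design$labs)) {
    zl <- lab_cor * z_wt + sqrt(1 - lab_cor^2) * stats::rnorm(n)
    cov[[lab]] <- draw_tn(design$labs[[lab]], zl)
  }
  if (design$name == "van")   # BSA deliberately deterministic in WT
    cov$BSA <- round(0.1 * cov$WT^0.67, 3)
  cov
}

#' Draw one subject's dosing regimen and sampling schedule
#'
#' Doses are per-kg rules with uniform draws inside the design's stated
#' windows; sampling times follow the design's rule (fixed 20-h draws for
#' "csa", pre-dose troughs for "phb", sparse post-dose windows for "van").
#'
#' @param design a [study_design()]
#' @param subject one row of a [generate_cohort()] table (needs `WT`)
#' @param rich_sampling replace the design's sparse rule with 6 samples
#'   spread uniformly over the treatment course (identifiability-rich
#'   variant)
#' @return list: `regimen` ([pk_regimen()]), `sample_times` (sorted, h)
#' @export
generate_regimen <- function(design, subject, rich_sampling = FALSE) {
  wt <- subject$WT
  if (is.null(wt) || is.na(wt)) stop("subject needs WT")
  if (design$name == "csa") {
    amt <- design$dose_mgkg * wt
    reg <- pk_regimen(time = c(0, 24), amt = amt,
                      rate = amt / design$infusion_h, route = "iv")
    st <- c(20, 44)
  } else if (design$name == "phb") {
    load <- stats::runif(1, design$load_mgkg[1], design$load_mgkg[2]) * wt
    t1 <- stats::runif(1, design$maint_delay_h[1], design$maint_delay_h[2])
    maint_t <- t1 + 24 * (seq_len(design$n_maint) - 1)
    maint_amt <- stats::runif(design$n_maint, design$maint_mgkg_d[1],
                              design$maint_mgkg_d[2]) * wt
    reg <- pk_regimen(time = c(0, maint_t), amt = c(load, maint_amt),
                      rate = c(load / design$load_infusion_h,
                               rep(0, design$n_maint)),
                      route = c("iv", rep("oral", design$n_maint)))
    next_doses <- c(maint_t, max(maint_t) + 24)[-1]
    st <- if (rich_sampling) {
      # stratified rich design: two samples in the intravenous loading
      # phase (these separate bioavailability from clearance and volume),
      # four across the oral maintenance course
      sort(c(stats::runif(2, 0.5, t1),
             stats::runif(4, t1, max(maint_t) + 24)))
    } else {
      sort(next_doses - stats::runif(length(next_doses), 5 / 60, 3))
    }
  } else {
    iv <- stats::runif(design$n_doses - 1, design$interval_h[1],
                       design$interval_h[2])
    dose_t <- c(0, cumsum(iv))
    amt <- design$dose_mgkg * wt
    reg <- pk_regimen(time = dose_t, amt = amt,
                      rate = amt / design$infusion_h, route = "iv")
    gaps <- c(iv, design$interval_h[2])
    n_s <- if (rich_sampling) 6L else design$n_samples
    picks <- sample.int(design$n_doses, n_s, replace = TRUE)
    # therapeutic drug monitoring draws: half peak-type samples shortly
    # after the infusion, half trough-type late in the interval, all inside
    # the design's post-dose window
    is_peak <- stats::runif(n_s) < 0.5
    hi <- pmin(gaps[picks] - 0.1, design$sample_window_h[2])
    lo_trough <- pmin(design$peak_window_h[2], hi - 0.1)
    dt <- ifelse(is_peak,
                 stats::runif(n_s, design$peak_window_h[1],
                              pmin(design$peak_window_h[2], hi)),
                 stats::runif(n_s, lo_trough, hi))
    st <- sort(dose_t[picks] + dt)
  }
  list(regimen = reg, sample_times = st)
}

central_cmt <- function(model) if (model$route %in% c("oral", "mixed")) 2L else 1L

# Assemble the event table for one subject from a regimen + sampling times.
events_from_regimen <- function(model, id, reg, sample_times) {
  ic <- central_cmt(model)
  dose <- data.frame(ID = id, TIME = reg$time, AMT = reg$amt,
                     RATE = reg$rate, DV = NA_real_, EVID = 1L,
                     CMT = ifelse(reg$route == "oral", 1L, ic))
  obs <- data.frame(ID = id, TIME = sample_times, AMT = NA_real_,
                    RATE = 0, DV = NA_real_, EVID = 0L, CMT = ic)
  rbind(dose, obs)
}

#' Simulate observations into a dataset
#'
#' Draws per-subject etas from N(0, Omega), computes individual parameters
#' and model predictions at the observation times, and applies residual
#' error on the spec's observation scale (log-normal under LTBS, so DV > 0
#' by construction). Observations whose concentration underflows double
#' precision (hundreds of half-lives post dose) are dropped with a message.
#'
#' @param model a [build_model()] object
#' @param spec the true [pm_spec()]
#' @param ds a `pk_dataset` whose observation rows have empty DV
#' @param seed optional RNG seed
#' @return the dataset with DV filled; attribute `eta` holds the simulated
#'   eta matrix
#' @export
simulate_observations <- function(model, spec, ds, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  an <- active_etas(spec)
  ev <- ds$events
  cov <- ds$covariates
  ids <- unique(ev$ID)
  etas <- matrix(0, length(ids), length(an),
                 dimnames = list(as.character(ids), an))
  keep <- rep(TRUE, nrow(ev))
  for (i in seq_along(ids)) {
    id <- ids[i]
    rows <- which(ev$ID == id & ev$EVID == 0)
    if (!length(rows)) next
    sub_ev <- ev[ev$ID == id, , drop = FALSE]
    dose <- sub_ev[sub_ev$EVID == 1, , drop = FALSE]
    reg <- pk_regimen(dose$TIME, dose$AMT, dose$RATE,
                      dose_routes(model, dose))
    crow <- as.list(cov[cov$ID == id, , drop = FALSE][1, ])
    eta <- stats::rnorm(length(an), 0, sqrt(spec$iiv[an]))
    names(eta) <- an
    etas[i, ] <- eta
    pars <- individual_parameters(spec, crow, eta)
    lf <- predict_concentrations(model, reg, pars, ev$TIME[rows], log = TRUE)
    if (spec$scale == "log") {
      sdl <- sqrt(spec$error$sigma_pro^2 + spec$error$sigma_add^2)
      dv <- exp(lf + stats::rnorm(length(rows), 0, sdl))
    } else {
      f <- exp(lf)
      dv <- f * (1 + stats::rnorm(length(rows), 0, spec$error$sigma_pro)) +
        stats::rnorm(length(rows), 0, spec$error$sigma_add)
    }
    dead <- !is.finite(dv) | dv == 0
    keep[rows[dead]] <- FALSE
    ev$DV[rows] <- dv
  }
  n_drop <- sum(!keep)
  if (n_drop > 0)
    message(n_drop, " observation(s) below double-precision underflow dropped")
  out <- pk_dataset(ev[keep, , drop = FALSE], cov, pna_unit = ds$pna_unit)
  attr(out, "eta") <- etas
  out
}

#' Generate a complete synthetic study
#'
#' End-to-end composition: cohort demographics, per-subject regimens and
#' sampling schedules, and simulated observations under the design's true
#' parameter model. The result is ready for [fit_foce()]; the generating
#' truth travels alongside for recovery tests.
#'
#' @param name "csa", "phb" or "van"
#' @param n number of subjects (default: the design's study size)
#' @param seed RNG seed covering cohort, regimen and observation noise
#' @param rich_sampling see [generate_regimen()]
#' @param scr_effect see [study_design()]
#' @return a `pk_study` list: `dataset` (a `pk_dataset`), `model`, `truth`
#'   (the generating [pm_spec()]), `design`
#' @export
generate_study <- function(name, n = NULL, seed = NULL,
                           rich_sampling = FALSE, scr_effect = 0) {
  design <- study_design(name, scr_effect = scr_effect)
  if (is.null(n)) n <- design$n_default
  if (!is.null(seed)) set.seed(seed)
  cov <- generate_cohort(design, n)
  ev <- do.call(rbind, lapply(seq_len(n), function(i) {
    rs <- generate_regimen(design, cov[i, , drop = FALSE],
                           rich_sampling = rich_sampling)
    events_from_regimen(design$model, cov$ID[i], rs$regimen, rs$sample_times)
  }))
  skel <- pk_dataset(ev, cov)
  ds <- simulate_observations(design$model, design$truth, skel)
  structure(list(dataset = ds, model = design$model, truth = design$truth,
                 design = design), class = "pk_study")
}

#' Append independent null covariates to a dataset
#'
#' Laboratory-like (log-normal, unit median) covariates with no relation to
#' anything in the data; used for covariate-search type-I-error studies.
#' Positivity keeps the power-form covariate relation well defined.
#'
#' @param ds a `pk_dataset`
#' @param k number of covariates (`NULL1` ... `NULLk`)
#' @param seed optional RNG seed
#' @return the dataset with covariate columns added
#' @export
add_null_covariates <- function(ds, k, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(ds$covariates)
  for (j in seq_len(k))
    ds$covariates[[paste0("NULL", j)]] <- exp(stats::rnorm(n, 0, 0.4))
  ds
}
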