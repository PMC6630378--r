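#' Allometric size multiplier
#'
#' Power-law scaling of a PK parameter with body weight relative to a
#' reference adult weight: `(wt / wt_ref)^power`. The classical fixed
#' exponents are 0.75 for clearance-like and 1 for volume-like parameters.
#'
#' @param wt body weight, kg (> 0)
#' @param power allometric exponent
#' @param wt_ref reference weight, kg (default 70)
#' @return dimensionless multiplier
#' @export
size_function <- function(wt, power, wt_ref = 70) {
  if (any(wt <= 0) || wt_ref <= 0) stop("weights must be positive")
  exp(power * (base::log(wt) - base::log(wt_ref)))
}

#' Sigmoid-Emax maturation multiplier
#'
#' Fraction of the adult parameter value reached at a given post-conceptional
#' age: `pca^hill / (pca^hill + tm50^hill)`. Evaluated in log space so large
#' Hill coefficients do not overflow. Strictly increasing in `pca`, equal to
#' 0.5 at `pca = tm50`, with asymptote 1.
#'
#' @param pca post-conceptional age, weeks (> 0)
#' @param tm50 age at 50% of the adult value, weeks (> 0)
#' @param hill sigmoidicity coefficient (> 0)
#' @return maturation fraction in (0, 1)
#' @export
maturation_function <- function(pca, tm50, hill) {
  if (any(pca <= 0) || tm50 <= 0 || hill <= 0)
    stop("pca, tm50 and hill must be positive")
  # 1 / (1 + (tm50/pca)^hill), computed via plogis on the log scale
  stats::plogis(hill * (base::log(pca) - base::log(tm50)))
}

#' Convert a log-normal variance to a CV percentage
#'
#' Inter-individual variability of an exponential random-effect model
#' `P_i = theta * exp(eta)`, `eta ~ N(0, omega2)`, reported as a coefficient
#' of variation. The exact log-normal form is `sqrt(exp(omega2) - 1)`; the
#' first-order approximation `sqrt(omega2)` is selectable.
#'
#' @param omega2 variance of eta
#' @param method "exact" or "approx"
#' @return CV, percent
#' @export
iiv_cv <- function(omega2, method = c("exact", "approx")) {
  method <- match.arg(method)
  100 * switch(method,
               exact = sqrt(expm1(omega2)),
               approx = sqrt(omega2))
}

#' @rdname iiv_cv
#' @param cv_percent CV in percent
#' @export
cv_to_omega2 <- function(cv_percent) log1p((cv_percent / 100)^2)

#' Specify the population parameter model
#'
#' Maps typical values, covariate functions (allometric size, sigmoid-Emax
#' maturation, stepwise-selected covariate relations), exponential
#' inter-individual variability and the residual-error model onto the
#' structural parameters of a [build_model()] model.
#'
#' @param theta named positive typical values for the structural parameters
#'   (e.g. `c(CL = 0.6, Vd = 5.5, ka = 50, F = 0.7)`)
#' @param size named list of allometric terms, e.g.
#'   `list(CL = list(power = 0.75), Vd = list(power = 1))`; add
#'   `estimate = TRUE` to free the exponent.
#' @param maturation named list with at most a `CL` entry,
#'   `list(CL = list(tm50 = , hill = , estimate = FALSE, clock = "PCA"))`;
#'   `clock` selects the age variable ("PCA", "GA" or "PNA", weeks).
#' @param iiv named vector of eta variances (omega^2) for parameters with
#'   inter-individual variability
#' @param error list: `model` one of "proportional", "additive", "combined";
#'   `sigma_pro` (fractional SD), `sigma_add` (mg/L, or log-SD when
#'   `scale = "log"`).
#' @param scale observation scale for estimation/simulation: "log"
#'   (log-transform-both-sides, additive error on log concentrations, the
#'   default) or "linear" (the literal proportional/additive/combined menu).
#' @param wt_ref reference weight, kg
#' @param fixed character vector of component names excluded from estimation
#'   (e.g. `c("ka", "tm50_CL", "hill_CL")`)
#' @param covariate_effects named list (by parameter) of named lists (by
#'   covariate): `list(coef = , center = , form = "power"|"linear")`, applied
#'   multiplicatively as `(cov/center)^coef` or `1 + coef*(cov - center)`.
#' @return an object of class `pm_spec`
#' @export
pm_spec <- function(theta, size = list(), maturation = list(),
                    iiv = numeric(), error = list(model = "proportional",
                                                  sigma_pro = 0.3,
                                                  sigma_add = 0),
                    scale = c("log", "linear"), wt_ref = 70,
                    fixed = character(), covariate_effects = list()) {
  scale <- match.arg(scale)
  if (any(theta <= 0)) stop("typical values must be positive")
  bad_mat <- setdiff(names(maturation), "CL")
  if (length(bad_mat))
    stop("maturation is only attachable to clearance (CL), not: ",
         paste(bad_mat, collapse = ", "))
  for (nm in names(maturation)) {
    m <- maturation[[nm]]
    if (m$tm50 <= 0 || m$hill <= 0) stop("tm50 and hill must be positive")
    if (is.null(m$clock)) maturation[[nm]]$clock <- "PCA"
    if (is.null(m$estimate)) maturation[[nm]]$estimate <- FALSE
  }
  for (nm in names(size))
    if (is.null(size[[nm]]$estimate)) size[[nm]]$estimate <- FALSE
  if (any(iiv < 0)) stop("omega^2 must be non-negative")
  if (is.null(error$sigma_pro)) error$sigma_pro <- 0
  if (is.null(error$sigma_add)) error$sigma_add <- 0
  if (error$sigma_pro < 0 || error$sigma_add < 0)
    stop("sigma components must be non-negative")
  structure(list(theta = theta, size = size, maturation = maturation,
                 iiv = iiv, error = error, scale = scale, wt_ref = wt_ref,
                 fixed = fixed, covariate_effects = covariate_effects),
            class = "pm_spec")
}

#' @export
print.pm_spec <- function(x, ...) {
  cat("pm_spec\n  theta:",
      paste(sprintf("%s=%.4g", names(x$theta), x$theta), collapse = ", "),
      "\n")
  if (length(x$size))
    cat("  size:",
        paste(sprintf("%s^%.3g", names(x$size),
                      vapply(x$size, function(s) s$power, 0)),
              collapse = ", "), sprintf("(wt_ref %g kg)", x$wt_ref), "\n")
  for (nm in names(x$maturation))
    cat(sprintf("  maturation on %s: tm50=%.3g wk, hill=%.3g, clock=%s\n",
                nm, x$maturation[[nm]]$tm50, x$maturation[[nm]]$hill,
                x$maturation[[nm]]$clock))
  if (length(x$iiv))
    cat("  iiv (omega^2):",
        paste(sprintf("%s=%.4g", names(x$iiv), x$iiv), collapse = ", "), "\n")
  cat(sprintf("  error: %s (sigma_pro=%.3g, sigma_add=%.3g), %s scale\n",
              x$error$model, x$error$sigma_pro, x$error$sigma_add, x$scale))
  invisible(x)
}

# Age variable (weeks) selected by the maturation clock, deriving PCA from
# GA + PNA when absent.
maturation_age <- function(cov, clock) {
  get <- function(nm) if (!is.null(cov[[nm]]) && !is.na(cov[[nm]])) cov[[nm]] else NULL
  if (clock == "PCA") {
    pca <- get("PCA")
    if (is.null(pca)) {
      ga <- get("GA"); pna <- get("PNA")
      if (!is.null(ga) && !is.null(pna)) pca <- ga + pna
    }
    pca
  } else get(clock)
}

#' Individual structural parameters from the population model
#'
#' Composes `P_i = theta_i x F_size x F_mat x covariate terms x exp(eta_i)`.
#' Parameters without an attached function or eta keep their typical value.
#'
#' @param spec a [pm_spec()]
#' @param covariates named list or one-row data.frame with `WT` (kg) and,
#'   when maturation is attached, the clock age variable in weeks (`PCA`, or
#'   `GA` + `PNA` from which PCA is derived)
#' @param eta named vector of random effects; omitted names are taken as 0
#' @return named vector of positive individual parameters
#' @export
individual_parameters <- function(spec, covariates, eta = numeric()) {
  cov <- as.list(covariates)
  out <- spec$theta
  for (nm in names(spec$size)) {
    if (is.null(cov$WT) || is.na(cov$WT))
      stop("size function attached but WT missing")
    out[nm] <- out[nm] * size_function(cov$WT, spec$size[[nm]]$power,
                                       spec$wt_ref)
  }
  for (nm in names(spec$maturation)) {
    m <- spec$maturation[[nm]]
    if (is.null(m$clock)) m$clock <- "PCA"
    age <- maturation_age(cov, m$clock)
    if (is.null(age) || is.na(age))
      stop("maturation attached but ", m$clock, " missing")
    out[nm] <- out[nm] * maturation_function(age, m$tm50, m$hill)
  }
  for (pnm in names(spec$covariate_effects)) {
    for (cnm in names(spec$covariate_effects[[pnm]])) {
      ce <- spec$covariate_effects[[pnm]][[cnm]]
      v <- cov[[cnm]]
      if (is.null(v) || is.na(v)) stop("covariate ", cnm, " missing")
      mult <- if (identical(ce$form, "linear")) {
        1 + ce$coef * (v - ce$center)
      } else {
        (v / ce$center)^ce$coef
      }
      out[pnm] <- out[pnm] * max(mult, 1e-12)
    }
  }
  for (nm in names(spec$iiv)) {
    e <- if (nm %in% names(eta)) eta[[nm]] else 0
    out[nm] <- out[nm] * exp(e)
  }
  out
}

#' Residual variance of an observation
#'
#' Implements the residual-error menu on the observation scale of the spec:
#' on the linear scale, additive `sigma_add^2`, proportional (constant CV)
#' `pred^2 sigma_pro^2`, or their sum (combined); on the log scale the error
#' is additive on log concentrations with variance `sigma_pro^2` (a
#' fractional SD is first-order equivalent to a log-scale SD).
#'
#' @param pred model prediction on the linear scale, mg/L
#' @param spec a [pm_spec()]
#' @return residual variance (scale of the observations used in fitting)
#' @export
residual_variance <- function(pred, spec) {
  err <- spec$error
  if (spec$scale == "log")
    return(rep_len(err$sigma_pro^2 + err$sigma_add^2, length(pred)))
  switch(err$model,
         additive = rep_len(err$sigma_add^2, length(pred)),
         proportional = {
           if (any(pred <= 0))
             stop("proportional error undefined for non-positive prediction")
           pred^2 * err$sigma_pro^2
         },
         combined = err$sigma_add^2 + pmax(pred, 0)^2 * err$sigma_pro^2,
         stop("unknown error model: ", err$model))
}
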