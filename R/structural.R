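#' Build a linear compartmental structural model
#'
#' Canonical parameterisations: `CL`, `Vd` for one compartment; `Q`, `Vp`
#' (and `Q2`, `Vp2`) added for two and three compartments; `ka` and `F`
#' added for any model with an oral absorption route. `route = "mixed"`
#' allows both intravenous and oral dose records in one regimen (oral doses
#' enter a first-order depot, intravenous doses the central compartment).
#'
#' @param n_compartments 1, 2 or 3 disposition compartments
#' @param route "iv", "oral" or "mixed"
#' @return a `pk_model` object with element `params`, the required
#'   parameter names
#' @examples
#' build_model(1, "iv")$params      # CL, Vd
#' build_model(1, "mixed")$params   # CL, Vd, ka, F
#' @export
build_model <- function(n_compartments, route = c("iv", "oral", "mixed")) {
  route <- match.arg(route)
  if (!n_compartments %in% 1:3)
    stop("n_compartments must be 1, 2 or 3")
  params <- c("CL", "Vd")
  if (n_compartments >= 2) params <- c(params, "Q", "Vp")
  if (n_compartments >= 3) params <- c(params, "Q2", "Vp2")
  if (route %in% c("oral", "mixed")) params <- c(params, "ka", "F")
  structure(list(n_cmt = n_compartments, route = route, params = params),
            class = "pk_model")
}

#' @export
print.pk_model <- function(x, ...) {
  cat(sprintf("pk_model: %d-compartment, route %s, parameters %s\n",
              x$n_cmt, x$route, paste(x$params, collapse = ", ")))
  invisible(x)
}

#' Construct a dosing regimen
#'
#' @param time dose start times, h (non-decreasing)
#' @param amt dose amounts, mg (> 0)
#' @param rate zero-order input rate, mg/h; 0 means bolus (iv) or first-order
#'   absorption input (oral)
#' @param route per-dose route, "iv" or "oral"
#' @return data.frame of class `pk_regimen`
#' @export
pk_regimen <- function(time, amt, rate = 0, route = "iv") {
  n <- length(time)
  reg <- data.frame(time = time, amt = amt, rate = rep_len(rate, n),
                    route = rep_len(route, n), stringsAsFactors = FALSE)
  if (is.unsorted(reg$time)) reg <- reg[order(reg$time), , drop = FALSE]
  if (any(reg$amt <= 0)) stop("dose amounts must be positive")
  if (any(reg$rate < 0)) stop("rate must be non-negative")
  class(reg) <- c("pk_regimen", "data.frame")
  reg
}

#' Predict concentration-time profiles
#'
#' Central-compartment concentration (amount / central volume) under an
#' arbitrary multiple-dose regimen, by superposition of per-dose solutions
#' of the linear system. One-compartment profiles use closed forms evaluated
#' on the log scale and combined by log-sum-exp, so very fast elimination
#' (many half-lives between dose and sample) yields finite log predictions
#' instead of underflowing to zero. Two- and three-compartment profiles are
#' propagated piecewise with the matrix exponential of the rate matrix.
#'
#' @param model a [build_model()] object
#' @param regimen a [pk_regimen()]
#' @param params named positive numerics covering `model$params`
#' @param times observation times, h (any order; returned in input order)
#' @param log if `TRUE` return log-concentration (mg/L, natural log)
#' @return numeric vector, one prediction per time
#' @export
predict_concentrations <- function(model, regimen, params, times, log = FALSE) {
  missing_par <- setdiff(model$params, names(params))
  if (length(missing_par))
    stop("missing parameter(s): ", paste(missing_par, collapse = ", "))
  p <- as.list(params)
  if (any(unlist(p[model$params]) <= 0))
    stop("structural parameters must be positive")
  if (any(times < 0)) stop("times must be non-negative")

  out <- if (model$n_cmt == 1) {
    pred_onecmt_log(regimen, p, times)
  } else {
    lp <- suppressWarnings(base::log(pred_multicmt(model, regimen, p, times)))
    lp[is.nan(lp)] <- -Inf
    lp
  }
  if (any(is.nan(out)))
    stop("non-finite prediction; check parameters and regimen")
  if (log) out else exp(out)
}

# log-concentration for the one-compartment model, all routes.
pred_onecmt_log <- function(regimen, p, times) {
  ke <- p$CL / p$Vd
  nt <- length(times)
  contrib <- matrix(-Inf, nrow = nt, ncol = nrow(regimen))
  for (d in seq_len(nrow(regimen))) {
    td <- regimen$time[d]; amt <- regimen$amt[d]
    rate <- regimen$rate[d]; rt <- regimen$route[d]
    tau <- times - td
    act <- tau >= 0          # dose-before-observation at identical times
    if (!any(act)) next
    lc <- rep(-Inf, nt)
    if (rt == "oral") {
      ka <- p$ka; Fb <- p$F
      if (abs(ka - ke) < 1e-8 * ke) {
        lc[act] <- base::log(Fb * amt * ke / p$Vd) + base::log(tau[act]) -
          ke * tau[act]
      } else if (ka > ke) {
        lc[act] <- base::log(Fb * amt * ka / (p$Vd * (ka - ke))) +
          logdiffexp(-ke * tau[act], -ka * tau[act])
      } else {
        lc[act] <- base::log(Fb * amt * ka / (p$Vd * (ke - ka))) +
          logdiffexp(-ka * tau[act], -ke * tau[act])
      }
    } else if (rate > 0) {
      dur <- amt / rate
      during <- act & tau <= dur
      after <- act & tau > dur
      lR <- base::log(rate / p$CL)
      if (any(during))
        lc[during] <- lR + log1p(-exp(pmax(-ke * tau[during], -745)))
      if (any(after))
        lc[after] <- lR + log1p(-exp(max(-ke * dur, -745))) -
          ke * (tau[after] - dur)
    } else {
      lc[act] <- base::log(amt / p$Vd) - ke * tau[act]
    }
    contrib[, d] <- lc
  }
  if (ncol(contrib) == 1L) contrib[, 1L] else logsumexp_rows(contrib)
}

# Precomputed dose/time geometry for the one-compartment fast path used in
# estimation inner loops: everything that does not depend on parameters.
fast_prep <- function(regimen, times) {
  nd <- nrow(regimen); nt <- length(times)
  TAU <- outer(times, regimen$time, "-")
  type <- ifelse(regimen$route == "oral", "oral",
                 ifelse(regimen$rate > 0, "inf", "bolus"))
  dur <- ifelse(type == "inf", regimen$amt / regimen$rate, 0)
  list(TAU = TAU, act = TAU >= 0,
       oral = which(type == "oral"), inf = which(type == "inf"),
       bol = which(type == "bolus"),
       type_code = c(bolus = 0L, inf = 1L, oral = 2L)[type],
       amt = regimen$amt, rate = regimen$rate, dur = dur,
       nt = nt, nd = nd)
}

# log central concentration for the one-compartment model from the
# precomputed geometry; vectorised over the full (time x dose) grid.
fast_logpred <- function(fp, CL, V, ka = NA_real_, Fb = 1) {
  ke <- CL / V
  L <- matrix(-Inf, fp$nt, fp$nd)
  if (length(fp$bol)) {
    TB <- fp$TAU[, fp$bol, drop = FALSE]
    LB <- rep(base::log(fp$amt[fp$bol] / V), each = fp$nt) - ke * TB
    LB[TB < 0] <- -Inf
    L[, fp$bol] <- LB
  }
  if (length(fp$inf)) {
    TI <- pmax(fp$TAU[, fp$inf, drop = FALSE], 0)
    DUR <- matrix(fp$dur[fp$inf], fp$nt, length(fp$inf), byrow = TRUE)
    lR <- rep(base::log(fp$rate[fp$inf] / CL), each = fp$nt)
    LI <- ifelse(TI <= DUR,
                 lR + log1p(-exp(pmax(-ke * TI, -745))),
                 lR + log1p(-exp(pmax(-ke * DUR, -745))) - ke * (TI - DUR))
    LI[fp$TAU[, fp$inf, drop = FALSE] < 0] <- -Inf
    L[, fp$inf] <- LI
  }
  if (length(fp$oral)) {
    TO <- pmax(fp$TAU[, fp$oral, drop = FALSE], 0)
    amt <- rep(fp$amt[fp$oral], each = fp$nt)
    LO <- if (abs(ka - ke) < 1e-8 * ke) {
      base::log(Fb * amt * ke / V) + base::log(TO) - ke * TO
    } else if (ka > ke) {
      base::log(Fb * amt * ka / (V * (ka - ke))) +
        logdiffexp(-ke * TO, -ka * TO)
    } else {
      base::log(Fb * amt * ka / (V * (ke - ka))) +
        logdiffexp(-ka * TO, -ke * TO)
    }
    LO[fp$TAU[, fp$oral, drop = FALSE] <= 0] <- -Inf
    L[, fp$oral] <- LO
  }
  if (fp$nd == 1L) L[, 1L] else logsumexp_rows(L)
}

# Rate matrix for the linear system. State order: (depot,) central,
# peripheral(s). Concentrations are central amount / Vd.
rate_matrix <- function(model, p) {
  has_depot <- model$route %in% c("oral", "mixed")
  ncomp <- model$n_cmt + has_depot
  A <- matrix(0, ncomp, ncomp)
  ic <- 1L + has_depot             # index of central
  if (has_depot) {
    A[1, 1] <- -p$ka
    A[ic, 1] <- p$ka
  }
  ke <- p$CL / p$Vd
  A[ic, ic] <- A[ic, ic] - ke
  if (model$n_cmt >= 2) {
    k12 <- p$Q / p$Vd; k21 <- p$Q / p$Vp
    ip <- ic + 1L
    A[ic, ic] <- A[ic, ic] - k12
    A[ip, ic] <- k12
    A[ic, ip] <- k21
    A[ip, ip] <- -k21
  }
  if (model$n_cmt >= 3) {
    k13 <- p$Q2 / p$Vd; k31 <- p$Q2 / p$Vp2
    ip2 <- ic + 2L
    A[ic, ic] <- A[ic, ic] - k13
    A[ip2, ic] <- k13
    A[ic, ip2] <- k31
    A[ip2, ip2] <- -k31
  }
  list(A = A, central = ic, depot = if (has_depot) 1L else NA_integer_)
}

# Piecewise matrix-exponential propagation for >= 2 compartments.
pred_multicmt <- function(model, regimen, p, times) {
  rm <- rate_matrix(model, p)
  A <- rm$A; ic <- rm$central
  ncomp <- nrow(A)
  starts <- regimen$time
  ends <- ifelse(regimen$rate > 0 & regimen$route != "oral",
                 regimen$time + regimen$amt / regimen$rate, regimen$time)
  brk <- sort(unique(c(0, starts, ends, times)))
  x <- numeric(ncomp)
  preds <- numeric(length(times))
  eAh <- function(h) as.matrix(Matrix::expm(A * h))
  for (k in seq_along(brk)) {
    t0 <- brk[k]
    # apply bolus/oral doses starting exactly at t0
    for (d in which(starts == t0)) {
      if (regimen$route[d] == "oral") {
        x[rm$depot] <- x[rm$depot] + p$F * regimen$amt[d]
      } else if (regimen$rate[d] == 0) {
        x[ic] <- x[ic] + regimen$amt[d]
      }
    }
    preds[times == t0] <- x[ic] / p$Vd
    if (k == length(brk)) break
    h <- brk[k + 1] - t0
    # constant infusion input over (t0, t0+h]
    u <- numeric(ncomp)
    for (d in seq_len(nrow(regimen))) {
      if (regimen$route[d] != "oral" && regimen$rate[d] > 0 &&
          starts[d] <= t0 && ends[d] >= brk[k + 1] - 1e-12)
        u[ic] <- u[ic] + regimen$rate[d]
    }
    if (any(u != 0)) {
      # augmented-matrix exponential handles the constant-input integral
      # without inverting A (robust for stiff parameter draws)
      M <- rbind(cbind(A, u), 0)
      EM <- as.matrix(Matrix::expm(M * h))
      x <- as.numeric(EM[seq_len(ncomp), seq_len(ncomp)] %*% x +
                        EM[seq_len(ncomp), ncomp + 1L])
    } else {
      x <- as.numeric(eAh(h) %*% x)
    }
    x[x < 0 & x > -1e-12] <- 0
  }
  preds[preds < 0] <- 0
  preds
}
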