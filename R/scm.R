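# Stepwise covariate modelling with a correlation pre-filter and
# forward/backward likelihood-ratio thresholds.

#' Pre-filter covariate candidates by correlation with size and age
#'
#' Drops any candidate whose absolute Pearson correlation with body weight
#' or with any available age variable (PNA, PCA, GA) exceeds the threshold;
#' such candidates would only re-express the size/maturation functions
#' already in the model. Constant covariates have undefined correlation and
#' are retained with a warning.
#'
#' @param ds a `pk_dataset`
#' @param candidates covariate column names to screen (default: every
#'   covariate column that is not ID, WT or an age variable)
#' @param threshold absolute correlation cut-off (default 0.5)
#' @return list: `retained` (names), `excluded` (names), `correlations`
#'   (data.frame of candidate, versus, r)
#' @export
prefilter_covariates <- function(ds, candidates = NULL, threshold = 0.5) {
  cov <- ds$covariates
  base_cols <- c("ID", "WT", "PNA", "PCA", "GA")
  if (is.null(candidates)) candidates <- setdiff(names(cov), base_cols)
  missing_cand <- setdiff(candidates, names(cov))
  if (length(missing_cand))
    stop("unknown covariate(s): ", paste(missing_cand, collapse = ", "))
  against <- intersect(c("WT", "PNA", "PCA", "GA"), names(cov))
  cors <- list()
  retained <- character()
  for (cand in candidates) {
    x <- cov[[cand]]
    if (length(unique(x[!is.na(x)])) < 2L) {
      warning("covariate ", cand, " is constant; correlation undefined, retained")
      retained <- c(retained, cand)
      next
    }
    rs <- vapply(against, function(a)
      suppressWarnings(stats::cor(x, cov[[a]], use = "complete.obs")), 0)
    cors[[cand]] <- data.frame(candidate = cand, versus = against, r = rs,
                               row.names = NULL)
    if (all(abs(rs) <= threshold, na.rm = TRUE))
      retained <- c(retained, cand)
  }
  list(retained = retained, excluded = setdiff(candidates, retained),
       correlations = do.call(rbind, cors))
}

# Add one covariate relation (free coefficient, initialised near null) to a
# spec. Power form: P * (cov/center)^beta; linear: P * (1 + beta*(cov-center)).
add_covariate_relation <- function(spec, ds, parameter, covariate,
                                   form = "power", init = 0.01) {
  vals <- ds$covariates[[covariate]]
  if (is.null(vals)) stop("covariate not in dataset: ", covariate)
  n_imp <- sum(is.na(vals))
  if (n_imp) {
    message(n_imp, " missing ", covariate, " value(s) imputed with the median")
    ds$covariates[[covariate]][is.na(vals)] <- stats::median(vals, na.rm = TRUE)
  }
  center <- stats::median(ds$covariates[[covariate]])
  if (form == "power" && any(ds$covariates[[covariate]] <= 0)) {
    message("covariate ", covariate,
            " has non-positive values; using the linear form")
    form <- "linear"
  }
  if (is.null(spec$covariate_effects[[parameter]]))
    spec$covariate_effects[[parameter]] <- list()
  spec$covariate_effects[[parameter]][[covariate]] <-
    list(coef = init, center = center, form = form)
  list(spec = spec, ds = ds)
}

drop_covariate_relation <- function(spec, parameter, covariate) {
  spec$covariate_effects[[parameter]][[covariate]] <- NULL
  if (!length(spec$covariate_effects[[parameter]]))
    spec$covariate_effects[[parameter]] <- NULL
  spec
}

#' Stepwise covariate model search
#'
#' Forward selection then backward elimination on likelihood-ratio criteria
#' (one coefficient per relation, df = 1): forward repeatedly adds the
#' candidate with the smallest p-value below `forward_p` (delta OFV at most
#' -3.84); backward repeatedly removes the least significant inclusion whose
#' removal p-value exceeds `backward_p` (retention requires a 6.63-point
#' worsening on removal). Ties break by larger |delta OFV|, then by name.
#' Candidates whose refit fails are skipped and logged in the trace. The
#' procedure is deterministic given the data.
#'
#' @param model a [build_model()] object
#' @param spec base [pm_spec()] (typically the size + maturation model)
#' @param ds a `pk_dataset`
#' @param candidates data.frame with columns `covariate`, `parameter`
#'   (default "CL") and `form` ("power" default, or "linear"); or a
#'   character vector of covariate names tested on CL with the power form
#' @param forward_p,backward_p inclusion and retention significance levels
#' @param control passed to [fit_foce()] for every refit (standard errors
#'   are disabled during the search)
#' @return list: `fit` (final `pk_fit`), `spec`, `included` (data.frame of
#'   retained relations), `trace` (one row per tested step)
#' @export
scm_search <- function(model, spec, ds, candidates,
                       forward_p = 0.05, backward_p = 0.01,
                       control = list()) {
  if (is.character(candidates))
    candidates <- data.frame(covariate = candidates,
                             parameter = rep("CL", length(candidates)),
                             form = rep("power", length(candidates)),
                             stringsAsFactors = FALSE)
  if (is.null(candidates$parameter)) candidates$parameter <- "CL"
  if (is.null(candidates$form)) candidates$form <- "power"
  ctl <- control
  ctl$se <- FALSE

  trace <- list()
  log_step <- function(phase, cand_key, ofv_ref, ofv_new, delta, p, action)
    trace[[length(trace) + 1]] <<- data.frame(
      step = length(trace) + 1L, phase = phase, candidate = cand_key,
      ofv_reference = ofv_ref, ofv_candidate = ofv_new,
      delta_ofv = delta, p = p, action = action, stringsAsFactors = FALSE)

  cur_fit <- fit_foce(model, spec, ds, control = ctl)
  cur_spec <- cur_fit$spec
  pool <- candidates
  pool$key <- if (nrow(pool)) paste0(pool$parameter, "~", pool$covariate)
              else character(0)
  included <- pool[0, , drop = FALSE]

  # forward selection
  repeat {
    if (!nrow(pool)) break
    rows <- list()
    for (i in seq_len(nrow(pool))) {
      cand <- pool[i, ]
      added <- tryCatch(
        add_covariate_relation(cur_spec, ds, cand$parameter, cand$covariate,
                               form = cand$form),
        error = function(e) NULL)
      fit_c <- if (is.null(added)) NULL else tryCatch(
        fit_foce(model, added$spec, added$ds, control = ctl),
        error = function(e) NULL)
      if (is.null(fit_c)) {
        log_step("forward", cand$key, cur_fit$ofv, NA, NA, NA, "refit failed")
        next
      }
      cmp <- compare_models(cur_fit, fit_c, df = 1L)
      log_step("forward", cand$key, cur_fit$ofv, fit_c$ofv, cmp$delta_ofv,
               cmp$p_value, "tested")
      rows[[cand$key]] <- list(cand = cand, fit = fit_c, cmp = cmp)
    }
    if (!length(rows)) break
    ps <- vapply(rows, function(r) r$cmp$p_value, 0)
    dl <- vapply(rows, function(r) r$cmp$delta_ofv, 0)
    ord <- order(ps, dl, names(rows))       # smallest p, then largest |dOFV|
    best <- rows[[ord[1]]]
    if (!(best$cmp$p_value < forward_p && best$cmp$delta_ofv <= -3.84)) break
    cur_fit <- best$fit
    cur_spec <- cur_fit$spec
    included <- rbind(included, pool[pool$key == best$cand$key, ])
    pool <- pool[pool$key != best$cand$key, , drop = FALSE]
    log_step("forward", best$cand$key, NA, cur_fit$ofv, best$cmp$delta_ofv,
             best$cmp$p_value, "included")
  }

  # backward elimination
  repeat {
    if (!nrow(included)) break
    worst <- NULL
    for (i in seq_len(nrow(included))) {
      cand <- included[i, ]
      sp_wo <- drop_covariate_relation(cur_spec, cand$parameter,
                                       cand$covariate)
      fit_wo <- tryCatch(fit_foce(model, sp_wo, ds, control = ctl),
                         error = function(e) NULL)
      if (is.null(fit_wo)) {
        log_step("backward", cand$key, cur_fit$ofv, NA, NA, NA, "refit failed")
        next
      }
      worsening <- fit_wo$ofv - cur_fit$ofv       # >= 0 when relation helps
      p_rm <- stats::pchisq(max(worsening, 0), df = 1, lower.tail = FALSE)
      log_step("backward", cand$key, cur_fit$ofv, fit_wo$ofv, worsening,
               p_rm, "tested")
      if (is.null(worst) || p_rm > worst$p ||
          (p_rm == worst$p && cand$key < worst$cand$key))
        worst <- list(cand = cand, fit = fit_wo, p = p_rm)
    }
    if (is.null(worst) || worst$p <= backward_p) break
    cur_fit <- worst$fit
    cur_spec <- cur_fit$spec
    included <- included[included$key != worst$cand$key, , drop = FALSE]
    log_step("backward", worst$cand$key, NA, cur_fit$ofv, NA, worst$p,
             "removed")
  }

  list(fit = cur_fit, spec = cur_spec,
       included = included[, c("covariate", "parameter", "form")],
       trace = do.call(rbind, trace))
}
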