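#' Construct a population PK event dataset
#'
#' A `pk_dataset` bundles a NONMEM-style event table (one row per dosing or
#' observation event) with a per-subject covariate table. Times are hours
#' since each subject's first event; doses are mg, concentrations mg/L.
#'
#' @param events data.frame with columns `ID`, `TIME`, `EVID` (0 observation,
#'   1 dose), `AMT` (mg, dose rows), `RATE` (mg/h, 0 for bolus or oral
#'   absorption input), `CMT` (1-based compartment), `DV` (mg/L, observation
#'   rows).
#' @param covariates data.frame with one row per subject: `ID`, `WT` (kg) and
#'   optionally `GA` (weeks), `PNA` (unit per `pna_unit`), `PCA` (weeks), plus
#'   any named laboratory covariates (SCR, BSA, ALB, ...).
#' @param pna_unit unit of the `PNA` column: "days", "weeks" or "months".
#' @return an object of class `pk_dataset`
#' @export
pk_dataset <- function(events, covariates, pna_unit = "weeks") {
  events <- as.data.frame(events)
  covariates <- as.data.frame(covariates)
  need <- c("ID", "TIME", "EVID")
  miss <- setdiff(need, names(events))
  if (length(miss))
    stop("event table lacks mandatory column(s): ", paste(miss, collapse = ", "))
  if (!"AMT" %in% names(events)) events$AMT <- NA_real_
  if (!"DV" %in% names(events)) events$DV <- NA_real_
  if (!"RATE" %in% names(events)) events$RATE <- 0
  if (!"CMT" %in% names(events)) events$CMT <- 1L
  events$RATE[is.na(events$RATE)] <- 0
  if (!"ID" %in% names(covariates)) stop("covariate table lacks ID column")
  if (anyDuplicated(covariates$ID))
    stop("duplicate subject_id in covariate table")

  bad_time <- which(!is.na(events$TIME) & events$TIME < 0)
  if (length(bad_time))
    stop("negative TIME at event row(s): ", paste(utils::head(bad_time, 5), collapse = ", "))
  bad_amt <- which(events$EVID == 1 & (is.na(events$AMT) | events$AMT <= 0))
  if (length(bad_amt))
    stop("dose row(s) without positive AMT: ", paste(utils::head(bad_amt, 5), collapse = ", "))
  bad_dv <- which(events$EVID == 1 & !is.na(events$DV))
  if (length(bad_dv))
    stop("DV present on dose row(s): ", paste(utils::head(bad_dv, 5), collapse = ", "))
  bad_obs <- which(events$EVID == 0 & !is.na(events$AMT))
  if (length(bad_obs))
    stop("AMT present on observation row(s): ", paste(utils::head(bad_obs, 5), collapse = ", "))
  if (any(events$RATE < 0)) stop("negative RATE")

  # Dose-before-observation at identical times (EVID descending).
  ord <- order(match(events$ID, unique(events$ID)), events$TIME, -events$EVID)
  events <- events[ord, , drop = FALSE]
  rownames(events) <- NULL
  rownames(covariates) <- NULL

  structure(list(events = events, covariates = covariates,
                 pna_unit = pna_unit),
            class = "pk_dataset")
}

#' @export
print.pk_dataset <- function(x, ...) {
  ev <- x$events
  cat(sprintf("pk_dataset: %d subjects, %d dose events, %d observations\n",
              length(unique(ev$ID)), sum(ev$EVID == 1), sum(ev$EVID == 0)))
  invisible(x)
}

#' Number of subjects in a pk_dataset
#' @param ds a `pk_dataset`
#' @return integer count
#' @export
n_subjects <- function(ds) length(unique(ds$events$ID))

#' Read a population PK dataset from a NONMEM-style CSV file
#'
#' The file holds one row per event with covariates repeated on every row of
#' a subject; missing values are "." or empty. Time-constant covariates take
#' the first non-missing value per subject.
#'
#' @param path CSV file path
#' @param column_map optional named character vector mapping the canonical
#'   names (names of the vector) to the file's column names, e.g.
#'   `c(ID = "SUBJ", DV = "CONC")`.
#' @param pna_unit unit of the PNA column if present
#' @return a [pk_dataset()]
#' @export
read_pk_dataset <- function(path, column_map = NULL, pna_unit = "weeks") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, na.strings = c(".", "", "NA"),
                         check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      src <- column_map[[canon]]
      if (!src %in% names(raw)) stop("mapped column not in file: ", src)
      names(raw)[names(raw) == src] <- canon
    }
  }
  mandatory <- c("ID", "TIME", "DV", "AMT", "EVID")
  miss <- setdiff(mandatory, names(raw))
  if (length(miss))
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "))
  ev_cols <- intersect(c("ID", "TIME", "AMT", "RATE", "DV", "EVID", "CMT"),
                       names(raw))
  cov_cols <- setdiff(names(raw), setdiff(ev_cols, "ID"))
  events <- raw[, ev_cols, drop = FALSE]
  first_nonmissing <- function(v) {
    v <- v[!is.na(v)]
    if (length(v)) v[1] else NA
  }
  ids <- unique(raw$ID)
  covariates <- do.call(rbind, lapply(ids, function(id) {
    block <- raw[raw$ID == id, setdiff(cov_cols, "ID"), drop = FALSE]
    as.data.frame(c(list(ID = id), lapply(block, first_nonmissing)))
  }))
  pk_dataset(events, covariates, pna_unit = pna_unit)
}

#' Write a pk_dataset to a NONMEM-style CSV file
#'
#' Inverse of [read_pk_dataset()]: events are written one row per record with
#' the subject's covariates repeated on every row, missing values as ".".
#'
#' @param ds a `pk_dataset`
#' @param path output file path
#' @return invisibly, the path
#' @export
write_pk_dataset <- function(ds, path) {
  ev <- ds$events
  cov <- ds$covariates
  out <- merge(ev, cov, by = "ID", sort = FALSE)
  ord <- order(match(out$ID, unique(ev$ID)), out$TIME, -out$EVID)
  out <- out[ord, , drop = FALSE]
  lead <- intersect(c("ID", "TIME", "AMT", "RATE", "DV", "EVID", "CMT"),
                    names(out))
  out <- out[, c(lead, setdiff(names(out), lead)), drop = FALSE]
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot open path for writing: ", path))
  on.exit(close(con))
  utils::write.csv(format_missing(out), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

format_missing <- function(df) {
  for (j in seq_along(df)) {
    v <- df[[j]]
    ch <- as.character(v)
    ch[is.na(v)] <- "."
    df[[j]] <- ch
  }
  df
}

#' Post-conceptional age from gestational and postnatal age
#'
#' PCA = GA + PNA with PNA converted to weeks (days / 7, months x 365.25/12/7).
#'
#' @param ga gestational age, weeks
#' @param pna postnatal age in `unit`
#' @param unit "days", "weeks" or "months"
#' @return post-conceptional age, weeks
#' @examples
#' compute_pca(36.7, 32.4, "days")   # ~41.3 weeks, a term-range neonate
#' @export
compute_pca <- function(ga, pna, unit = c("weeks", "days", "months")) {
  unit <- match.arg(unit)
  if (any(ga <= 0)) stop("ga must be positive")
  if (any(pna < 0)) stop("pna must be non-negative")
  pna_wk <- switch(unit,
                   weeks = pna,
                   days = pna / 7,
                   months = pna * (365.25 / 12) / 7)
  ga + pna_wk
}

#' Validate a pk_dataset for estimation readiness
#'
#' Reports, without erroring, every rule violation that would exclude a
#' subject from analysis: missing body weight, missing age (no PNA, GA or
#' PCA), no observations, or no dose events.
#'
#' @param ds a `pk_dataset`
#' @param require_age if `FALSE`, missing age variables are not flagged (the
#'   cyclosporine-style design carries no gestational age).
#' @return data.frame of issues (subject, issue); zero rows when clean
#' @export
validate_pk_dataset <- function(ds, require_age = TRUE) {
  ev <- ds$events
  cov <- ds$covariates
  issues <- list()
  add <- function(id, what) issues[[length(issues) + 1]] <<- data.frame(
    subject = id, issue = what, stringsAsFactors = FALSE)
  age_cols <- intersect(c("PNA", "GA", "PCA"), names(cov))
  for (i in seq_len(nrow(cov))) {
    id <- cov$ID[i]
    if (!"WT" %in% names(cov) || is.na(cov$WT[i]) || cov$WT[i] <= 0)
      add(id, "missing body weight")
    if (require_age) {
      has_age <- length(age_cols) > 0 &&
        any(!is.na(unlist(cov[i, age_cols, drop = FALSE])))
      if (!has_age) add(id, "missing age")
    }
    sub <- ev[ev$ID == id, , drop = FALSE]
    if (!any(sub$EVID == 0 & !is.na(sub$DV))) add(id, "no observations")
    if (!any(sub$EVID == 1)) add(id, "no dose events")
  }
  orphan <- setdiff(unique(ev$ID), cov$ID)
  for (id in orphan) add(id, "no covariate record")
  if (length(issues)) do.call(rbind, issues)
  else data.frame(subject = character(), issue = character(),
                  stringsAsFactors = FALSE)
}
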