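# YAML configuration helpers: a parameter-model spec and a dataset column
# mapping can live in one config file, so an analysis is reproducible from
# data + config alone.

#' Read a parameter-model spec (and column mapping) from a YAML file
#'
#' Expected layout (all blocks optional except `theta`):
#'
#' ```yaml
#' theta: {CL: 0.6, Vd: 5.5, ka: 50, F: 0.7}
#' size:
#'   CL: {power: 0.75}
#'   Vd: {power: 1, estimate: false}
#' maturation:
#'   CL: {tm50: 48.2, hill: 5.99, estimate: true, clock: PCA}
#' iiv: {CL: 0.15, Vd: 0.48}
#' error: {model: proportional, sigma_pro: 0.356}
#' scale: log
#' fixed: [ka]
#' column_map: {ID: SUBJ, DV: CONC}
#' ```
#'
#' @param path YAML file path
#' @return list with elements `spec` (a [pm_spec()]) and `column_map`
#'   (named character vector or NULL), for use with [read_pk_dataset()]
#' @export
pm_spec_from_yaml <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required to read config files")
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$theta)) stop("config lacks a theta block")
  spec <- pm_spec(
    theta = unlist(cfg$theta),
    size = if (is.null(cfg$size)) list() else cfg$size,
    maturation = if (is.null(cfg$maturation)) list() else cfg$maturation,
    iiv = if (is.null(cfg$iiv)) numeric() else unlist(cfg$iiv),
    error = if (is.null(cfg$error)) list(model = "proportional",
                                         sigma_pro = 0.3) else cfg$error,
    scale = if (is.null(cfg$scale)) "log" else cfg$scale,
    wt_ref = if (is.null(cfg$wt_ref)) 70 else cfg$wt_ref,
    fixed = if (is.null(cfg$fixed)) character() else unlist(cfg$fixed))
  cmap <- if (!is.null(cfg$column_map)) unlist(cfg$column_map)
  list(spec = spec, column_map = cmap)
}
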