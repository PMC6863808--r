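#' Read a study configuration file
#'
#' A study configuration is a YAML (or JSON) file with a `conditions` list,
#' optional `fit` overrides applied to every condition, and an optional
#' `base_seed`. Each condition entry accepts the [condition_config()] fields.
#'
#' @param path path to a YAML/JSON study configuration
#' @param base_seed overrides the file's base seed when not `NULL`
#' @return list with `conditions` (list of [condition_config()]) and
#'   `fit_cfg` (a [fit_config()])
#' @examples
#' \dontrun{
#' cfg <- read_study_config("study.yaml")
#' results <- lapply(cfg$conditions, run_condition, fit_cfg = cfg$fit_cfg)
#' }
#' @export
read_study_config <- function(path, base_seed = NULL) {
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
         else yaml::read_yaml(path)
  seed <- base_seed %||% raw$base_seed %||% 1L
  conds <- lapply(raw$conditions, function(cc) {
    do.call(condition_config, c(cc[setdiff(names(cc), "base_seed")],
                                list(base_seed = cc$base_seed %||% seed)))
  })
  fit_cfg <- do.call(fit_config, as.list(raw$fit))
  list(conditions = conds, fit_cfg = fit_cfg, base_seed = seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
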