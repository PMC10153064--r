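#' Read a configuration file
#'
#' Reads a plain-text YAML configuration with one section per module
#' (`arm`, `muscle`, `control`, `task`, `optimizer`); each entry overrides
#' the corresponding default parameter. Unknown sections are kept verbatim.
#'
#' @param path path to a YAML file.
#' @return A named list of sections.
#' @export
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' writeLines("arm:\n  dt: 0.001\nmuscle:\n  v_max: 2.0", f)
#' cfg <- read_config(f)
#' arm_model("FMAX", config = cfg)$params$dt
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config file must contain a mapping of sections")
  cfg
}

#' Extract a configuration section
#'
#' @param config a configuration list (or `NULL`).
#' @param name section name.
#' @return The section as a list (empty if absent).
#' @export
config_section <- function(config, name) {
  if (is.null(config) || is.null(config[[name]])) return(list())
  sec <- config[[name]]
  # yaml returns nested lists for vector-valued entries; flatten numerics
  lapply(sec, function(v) if (is.list(v)) unlist(v) else v)
}
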