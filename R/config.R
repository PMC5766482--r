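#' Read a package configuration file
#'
#' Parameters for all modules can be kept in a single YAML file with
#' optional top-level sections \code{polymer}, \code{geometry},
#' \code{topology}, \code{rates} and \code{noise}; each section holds
#' constructor arguments for the corresponding class.
#'
#' @param path YAML file path.
#' @return A named list of sections.
#' @export
readConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}

#' Build parameter objects from a configuration list
#'
#' Each function applies the matching section of a configuration list
#' (see \code{\link{readConfig}}) on top of the package defaults.
#'
#' @param config list as returned by \code{\link{readConfig}}.
#' @return The corresponding parameter object.
#' @export
polymerFromConfig <- function(config)
  do.call(polymerParams, config$polymer %||% list())

#' @rdname polymerFromConfig
#' @export
geometryFromConfig <- function(config)
  do.call(domainGeometry, config$geometry %||% list())

#' @rdname polymerFromConfig
#' @export
topologyFromConfig <- function(config)
  do.call(disulfideTopology, config$topology %||% list())

#' @rdname polymerFromConfig
#' @export
ratesFromConfig <- function(config)
  do.call(defaultRates, config$rates %||% list())

#' @rdname polymerFromConfig
#' @export
noiseFromConfig <- function(config)
  do.call(noiseModel, config$noise %||% list())

`%||%` <- function(a, b) if (is.null(a)) b else a
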