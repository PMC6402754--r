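#' Load custom index definitions from YAML
#'
#' Reads a YAML list of index definitions, each with fields \code{name},
#' \code{kind}, \code{bands} and optional \code{constants}, into
#' \linkS4class{SpectralIndex} objects ready for
#' \code{\link{indexTable}}.
#'
#' @param path YAML file
#' @return named list of \linkS4class{SpectralIndex}
#' @examples
#' p <- tempfile(fileext = ".yaml")
#' writeLines(c("- name: NDI_1450_900", "  kind: normalized_difference",
#'              "  bands: [1450, 900]"), p)
#' readIndexDefinitions(p)
#' @export
readIndexDefinitions <- function(path) {
  if (!file.exists(path)) stop("definitions file not found: ", path)
  raw <- yaml::read_yaml(path)
  defs <- lapply(raw, function(d) {
    for (f in c("name", "kind", "bands"))
      if (is.null(d[[f]]))
        stop("index definition misses field '", f, "'")
    SpectralIndex(d$name, d$kind, as.numeric(d$bands),
                  constants = as.numeric(d$constants %||% numeric()))
  })
  names(defs) <- vapply(defs, function(d) d@name, "")
  if (anyDuplicated(names(defs)))
    stop("duplicate index names in ", path)
  defs
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write and read a synthetic configuration as YAML
#'
#' Serializes every scalar/vector field of a
#' \code{\link{syntheticConfig}} (the grid as start/end/step) so that a
#' simulated experiment's conditions travel with its outputs.
#'
#' @param config a \code{\link{syntheticConfig}}
#' @param path YAML file to write
#' @return \code{path}, invisibly
#' @export
writeSyntheticConfig <- function(config, path) {
  stopifnot(inherits(config, "SyntheticConfig"))
  lst <- unclass(config)
  lst$grid <- list(startNm = config$grid@startNm,
                   endNm = config$grid@endNm,
                   stepNm = config$grid@stepNm)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @param path YAML file written by \code{\link{writeSyntheticConfig}}
#' @rdname writeSyntheticConfig
#' @return \code{readSyntheticConfig}: the reconstructed configuration
#' @export
readSyntheticConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lst <- yaml::read_yaml(path)
  lst$grid <- WavelengthGrid(lst$grid$startNm, lst$grid$endNm,
                             lst$grid$stepNm)
  do.call(syntheticConfig, lst)
}
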