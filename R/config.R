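#' Read and write model configurations as JSON
#'
#' Serializers for the package's parameter objects: [eye_model()],
#' [cascade_params()] and [expression_scaling()]. Fields missing from a
#' JSON file fall back to the constructor defaults, so a config file may
#' override only the parameters it cares about.
#'
#' @param path JSON file path.
#' @return The corresponding parameter object.
#' @export
read_eye_model <- function(path) {
  do.call(eye_model, jsonlite::read_json(path, simplifyVector = TRUE))
}

#' @rdname read_eye_model
#' @export
read_cascade_params <- function(path) {
  do.call(cascade_params, jsonlite::read_json(path, simplifyVector = TRUE))
}

#' @rdname read_eye_model
#' @export
read_expression_scaling <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(cfg$transducin_subunits))
    cfg$transducin_subunits <- unlist(cfg$transducin_subunits)
  do.call(expression_scaling, cfg)
}

#' @param x An `eye_model`, `cascade_params` or `expression_scaling`.
#' @rdname read_eye_model
#' @export
write_config <- function(x, path) {
  keep <- setdiff(names(unclass(x)), "transducin_subunits")
  obj <- unclass(x)[keep]
  if (inherits(x, "expression_scaling")) {
    obj <- list(transducin_subunits = as.list(x$transducin_subunits),
                gc3 = x$gc3, rec2 = x$rec2, cnga3 = x$cng)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
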