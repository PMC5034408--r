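MODEL_SCHEMA <- "prosthermal-gp"
MODEL_SCHEMA_VERSION <- 1L

#' Serialize and restore a fitted GP model
#'
#' The model file is a single portable JSON document (schema-versioned)
#' holding the hyperparameters at full precision, the training pairs and
#' the mean offset; no binary serialisation is used, so files are
#' auditable and diffable. `read_model()` rebuilds the covariance
#' factorisation, so restored models predict identically to the original.
#'
#' @param model A [gp_fit()].
#' @param path File path.
#' @return `read_model()` returns a [gp_fit()]; `write_model()` invisibly
#'   returns `path`.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "gp_fit"))
  doc <- list(schema = MODEL_SCHEMA, version = MODEL_SCHEMA_VERSION,
              input = model$input, target = model$target,
              hyper = model$hyper, mean_offset = model$mean_offset,
              train_x = model$train_x, train_y = model$train_y)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("no such file: ", path), class = "prosthermal_format_error")
  }
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) {
                    abort(sprintf("cannot parse model file '%s': %s", path,
                                  conditionMessage(e)),
                          class = "prosthermal_format_error")
                  })
  if (!identical(doc$schema, MODEL_SCHEMA)) {
    abort(sprintf("'%s' is not a %s model file", path, MODEL_SCHEMA),
          class = "prosthermal_format_error")
  }
  if (!identical(as.integer(doc$version), MODEL_SCHEMA_VERSION)) {
    abort(sprintf("model file schema version %s != supported version %d",
                  doc$version, MODEL_SCHEMA_VERSION),
          class = "prosthermal_format_error")
  }
  need <- c("input", "target", "hyper", "mean_offset", "train_x", "train_y")
  missing <- need[!need %in% names(doc)]
  if (length(missing) > 0) {
    abort(paste0("model file is missing field(s): ",
                 paste(missing, collapse = ", ")),
          class = "prosthermal_format_error")
  }
  h <- doc$hyper
  gp_model_from_hyper(as.numeric(doc$train_x), as.numeric(doc$train_y),
                      theta1 = h$theta1, length_scale = h$length_scale,
                      noise_var = h$noise_var, input = doc$input,
                      target = doc$target, mean_offset = doc$mean_offset)
}
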