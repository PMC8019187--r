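#' Save or load a model as a self-describing JSON container
#'
#' Serialises any of the package's model objects (`rbm`, `dbm`,
#' `im_model`, `mice_model`, `generator_model`) to a single JSON file
#' holding the named parameter arrays plus metadata (format name, version,
#' model class). Doubles are written at full precision, so a write/read
#' round trip reproduces the model exactly.
#'
#' @param model a supported model object.
#' @param path destination file.
#' @export
write_model <- function(model, path) {
  cls <- class(model)[1L]
  if (!cls %in% c("rbm", "dbm", "im_model", "mice_model", "generator_model")) {
    stopf("cannot serialize objects of class '%s'", cls,
          class = "boltzgen_validation_error")
  }
  payload <- unclass(model)
  if (cls == "generator_model") {
    payload$fitted <- list(class = class(model$fitted)[1L],
                           payload = unclass(model$fitted))
  }
  container <- list(format = "boltzgen-model", version = 1L, class = cls,
                    payload = payload)
  jsonlite::write_json(container, path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_model
#' @param path file written by [write_model()].
#' @return the restored model object.
#' @export
read_model <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = TRUE)
  if (!identical(raw$format, "boltzgen-model")) {
    stopf("%s is not a boltzgen model container", path,
          class = "boltzgen_format_error")
  }
  restore_model(raw$class, raw$payload)
}

restore_model <- function(cls, p) {
  switch(cls,
    rbm = rbm(as_matrix(p$weights), p$visible_bias, p$hidden_bias),
    dbm = dbm(lapply(p$layer_weights, as_matrix), p$biases),
    im_model = structure(list(frequencies = as.numeric(p$frequencies),
                              variable_names = p$variable_names),
                         class = "im_model"),
    mice_model = restore_mice(p),
    generator_model = generator_model(
      p$type, restore_model(p$fitted$class, p$fitted$payload),
      p$variable_names, as.integer(p$burnin)),
    stopf("unknown model class '%s' in container", cls,
          class = "boltzgen_format_error"))
}

as_matrix <- function(x) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  dimnames(x) <- NULL
  x
}

restore_mice <- function(p) {
  regressions <- lapply(p$regressions, function(r) {
    if (is.null(r)) return(NULL)
    if (identical(r$type, "constant")) {
      list(target = as.integer(r$target), type = "constant",
           value = as.numeric(r$value))
    } else {
      list(target = as.integer(r$target), type = "regression",
           predictors = as.integer(r$predictors %||% integer()),
           coefficients = as.numeric(r$coefficients %||% numeric()),
           intercept = as.numeric(r$intercept))
    }
  })
  structure(list(order = as.integer(p$order),
                 first_prob = as.numeric(p$first_prob),
                 regressions = regressions,
                 dropped = as.integer(p$dropped %||% integer()),
                 variable_names = p$variable_names),
            class = "mice_model")
}
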