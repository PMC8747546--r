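#' @title Model checkpoints
#' @description Portable JSON serialization of trained models, detectors
#'   and their normalization parameters. Matrices are stored with full
#'   double precision so a reloaded detector reproduces its training-time
#'   decisions; everything is plain structured text.
#' @name checkpoint
NULL

.ser_node <- function(x) {
  if (is.null(x)) {
    NULL
  } else if (is.data.frame(x)) {
    list(`_t` = "data.frame", cols = lapply(x, identity))
  } else if (is.matrix(x)) {
    list(`_t` = "matrix", dim = dim(x), data = as.vector(x))
  } else if (is.function(x)) {
    stop("cannot serialize a function-backed model")
  } else if (is.list(x)) {
    fields <- lapply(x, .ser_node)
    fields <- fields[!vapply(fields, is.null, TRUE)]
    if (!is.null(attr(x, "class"))) {
      list(`_t` = "obj", class = class(x), fields = fields)
    } else {
      fields
    }
  } else {
    x
  }
}

.deser_node <- function(x) {
  if (!is.list(x)) {
    return(x)
  }
  tag <- x[["_t"]]
  if (is.null(tag)) {
    # unnamed list of scalars = a serialized atomic vector
    scalar <- vapply(x, function(e) is.atomic(e) && length(e) == 1L, TRUE)
    if (length(x) > 0L && is.null(names(x)) && all(scalar)) {
      return(unlist(x))
    }
    return(lapply(x, .deser_node))
  }
  switch(tag,
    matrix = matrix(unlist(x$data), nrow = x$dim[[1]], ncol = x$dim[[2]]),
    data.frame = as.data.frame(lapply(x$cols, unlist)),
    obj = structure(lapply(x$fields, .deser_node), class = unlist(x$class)),
    stop("unknown checkpoint node tag: ", tag)
  )
}

#' Save / load a trained object as a JSON checkpoint
#'
#' Works for any of the package's fitted objects (`ae_model`, `vae_model`,
#' `lstm_model`, `threshold_detector`) and for the bundles written by
#' [cmd_train()].
#'
#' @param object the fitted object.
#' @param path checkpoint file path (`.json`).
#' @return `save_checkpoint()` returns `path` invisibly; `load_checkpoint()`
#'   returns the restored object with its class and all parameter matrices
#'   intact.
#' @export
save_checkpoint <- function(object, path) {
  # 17 significant digits round-trip IEEE doubles exactly
  jsonlite::write_json(
    .ser_node(object), path,
    auto_unbox = TRUE, digits = 17, null = "null"
  )
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  .deser_node(jsonlite::read_json(path))
}
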