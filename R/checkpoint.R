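#' Save / load model checkpoints
#'
#' A checkpoint is a single JSON file holding the model kind, its full
#' configuration (including the initialization seed), the training state
#' and every parameter tensor (complex tensors are stored as separate real
#' and imaginary parts at full precision). The polar-graph coarsening
#' hierarchy is deterministic and is rebuilt on load rather than stored.
#'
#' @param model A `polargcn_model`.
#' @param path Destination file path.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the restored `polargcn_model`.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "polargcn_model"))
  ser <- lapply(model$params, function(p) {
    list(
      dim = if (is.null(dim(p))) length(p) else dim(p),
      re = as.numeric(Re(p)),
      im = if (is.complex(p)) as.numeric(Im(p)) else NULL
    )
  })
  obj <- list(
    package = "polargcn", format = 1L,
    kind = model$kind,
    config = unclass(model$config),
    trained = isTRUE(model$trained),
    loss_trace = model$loss_trace,
    params = ser
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @param hierarchy Optional [coarsen] hierarchy for graph models (rebuilt
#'   from the polar grid when omitted).
#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path, hierarchy = NULL) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$package, "polargcn")) {
    stop("not a polargcn checkpoint: ", path, call. = FALSE)
  }
  cfg_args <- obj$config
  cfg_args <- cfg_args[setdiff(names(cfg_args), c("n_input", "n_classes"))]
  config <- do.call(model_config, cfg_args)
  model <- build_model(config, hierarchy = hierarchy)
  params <- model$params
  for (nm in names(params)) {
    s <- obj$params[[nm]]
    if (is.null(s)) stop("checkpoint is missing parameter ", nm, call. = FALSE)
    v <- if (!is.null(s$im)) complex(real = s$re, imaginary = s$im) else s$re
    d <- as.integer(s$dim)
    params[[nm]] <- if (length(d) > 1L) array(v, dim = d) else {
      if (is.null(dim(params[[nm]]))) v else array(v, dim = dim(params[[nm]]))
    }
  }
  model$params <- params
  model$trained <- isTRUE(obj$trained)
  model$loss_trace <- obj$loss_trace
  model
}
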