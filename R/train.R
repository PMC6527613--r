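#' Training configuration
#'
#' Plain stochastic gradient descent with learning rate 1e-3 and
#' categorical cross-entropy loss. Default batch sizes are 64 for the
#' FCN/CNN baselines, 30 for the Chebyshev GCNN and 20 for the Cayley
#' GCNN; default epoch counts are 70 for the baselines and 60 for the
#' graph models. No momentum, weight decay or schedule is applied.
#'
#' @param learning_rate SGD step size.
#' @param batch_size Mini-batch size; `NULL` selects the per-model default.
#' @param epochs Number of epochs; `NULL` selects the per-model default.
#' @param seed Seed controlling data shuffling during training.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-3, batch_size = NULL,
                         epochs = NULL, seed = 0L) {
  stopifnot(learning_rate > 0, is.finite(learning_rate))
  structure(
    list(
      learning_rate = learning_rate, batch_size = batch_size,
      epochs = epochs, seed = as.integer(seed)
    ),
    class = "train_config"
  )
}

default_batch_size <- function(kind) {
  switch(kind, fcn = 64L, cnn = 64L, gcnn_cheb = 30L, gcnn_cayley = 20L)
}

default_epochs <- function(kind) {
  switch(kind, fcn = 70L, cnn = 70L, gcnn_cheb = 60L, gcnn_cayley = 60L)
}

label_to_binary <- function(label) {
  if (is.numeric(label)) {
    stopifnot(all(label %in% c(0, 1)))
    return(as.integer(label))
  }
  out <- ifelse(label == "abnormal", 1L, ifelse(label == "normal", 0L, NA))
  if (anyNA(out)) stop("labels must be 'normal' or 'abnormal'", call. = FALSE)
  out
}

#' Assemble a design matrix and label vector from polar maps
#'
#' @param maps List of labeled [polar_map] objects.
#' @return List with `X` (samples x 460), `y` (0 = normal, 1 = abnormal),
#'   `ids`, `condition`.
#' @export
polarmap_dataset <- function(maps) {
  stopifnot(length(maps) > 0, all(vapply(maps, inherits, logical(1), "polar_map")))
  labels <- vapply(maps, function(m) m$label, character(1))
  if (anyNA(labels)) {
    stop("all maps must carry a normal/abnormal label for training",
      call. = FALSE
    )
  }
  list(
    X = as_value_matrix(maps),
    y = label_to_binary(labels),
    ids = vapply(maps, function(m) m$sample_id, character(1)),
    condition = vapply(maps, function(m) m$condition, character(1))
  )
}

as_dataset <- function(dataset) {
  if (is.list(dataset) && !is.null(dataset$X) && !is.null(dataset$y)) {
    return(list(X = dataset$X, y = label_to_binary(dataset$y)))
  }
  polarmap_dataset(dataset)
}

cross_entropy <- function(probs, y) {
  eps <- 1e-12
  -mean(log(pmax(probs[cbind(seq_along(y), y + 1L)], eps)))
}

sgd_step <- function(params, grads, lr) {
  for (nm in names(grads)) {
    params[[nm]] <- params[[nm]] - lr * grads[[nm]]
  }
  # the Cayley spectral zoom must stay positive
  for (nm in intersect(names(params), c("h1", "h2"))) {
    params[[nm]] <- max(as.numeric(params[[nm]]), 1e-6)
  }
  params
}

#' Train a classifier with seeded SGD
#'
#' Minimizes categorical cross-entropy by plain mini-batch stochastic
#' gradient descent. Given identical seeds (model initialization seed and
#' shuffling seed) and identical data order, training is bit-deterministic.
#'
#' @param model A `polargcn_model` from [build_model].
#' @param dataset A list of labeled [polar_map] objects (one condition), or
#'   a list with elements `X` (samples x 460) and `y` (0/1 or
#'   normal/abnormal).
#' @param cfg A [train_config].
#' @return The trained model, with `$loss_trace` holding the mean training
#'   loss per epoch.
#' @export
train <- function(model, dataset, cfg = train_config()) {
  stopifnot(inherits(model, "polargcn_model"), inherits(cfg, "train_config"))
  ds <- as_dataset(dataset)
  n <- nrow(ds$X)
  if (n == 0L) stop("cannot train on an empty dataset", call. = FALSE)
  if (length(unique(ds$y)) < 2L) {
    stop("training requires both classes to be present", call. = FALSE)
  }
  bs <- cfg$batch_size %||% default_batch_size(model$kind)
  epochs <- cfg$epochs %||% default_epochs(model$kind)
  lr <- cfg$learning_rate
  trace <- numeric(epochs)
  .with_seed(cfg$seed, {
    for (e in seq_len(epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = bs)
      ep_loss <- 0
      for (s in starts) {
        idx <- ord[s:min(s + bs - 1L, n)]
        Xb <- ds$X[idx, , drop = FALSE]
        yb <- ds$y[idx]
        fw <- model_forward(model, Xb)
        ep_loss <- ep_loss + cross_entropy(fw$probs, yb) * length(idx)
        onehot <- matrix(0, length(idx), 2L)
        onehot[cbind(seq_along(idx), yb + 1L)] <- 1
        dlogits <- (fw$probs - onehot) / length(idx)
        grads <- model_backward(model, fw$cache, dlogits)
        model$params <- sgd_step(model$params, grads, lr)
      }
      trace[e] <- ep_loss / n
    }
  })
  model$trained <- TRUE
  model$loss_trace <- trace
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a
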