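# The four classifier architectures: a fully connected baseline, a 2-D CNN
# baseline on the 23 x 20 raster, and two spectral graph CNNs (Chebyshev
# and Cayley filters) on the polar graph. Forward and reverse passes are
# written out explicitly; all parameters live in plain named arrays so that
# seeded SGD is bit-reproducible.

.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = .GlobalEnv)
    } else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
      rm(".Random.seed", envir = .GlobalEnv)
    }
  })
  set.seed(seed)
  code
}

glorot_uniform <- function(fan_in, fan_out, dims = c(fan_in, fan_out)) {
  s <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -s, s), dim = dims)
}

relu <- function(x) pmax(x, 0)

softmax_rows <- function(logits) {
  z <- logits - apply(logits, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Model configuration
#'
#' Defaults reproduce the published architectures: FCN 460 -> 460 -> 2;
#' CNN with 64 5x5 and 128 3x3 filters, 2x2 max-pooling and a 256-unit
#' dense layer; GCNNs with two graph-convolution layers (Chebyshev orders
#' 16/32, Cayley orders 4/6) with pooling sizes 4 then 2. Graph feature
#' widths per layer default to 32 and 64.
#'
#' @param kind One of `"fcn"`, `"cnn"`, `"gcnn_cheb"`, `"gcnn_cayley"`.
#' @param hidden Hidden width of the FCN.
#' @param conv_filters,conv_kernels,dense_units CNN filter counts, kernel
#'   sizes and dense width.
#' @param gc_features GCNN feature widths per layer.
#' @param cheb_orders,cayley_orders Spectral filter orders per layer.
#' @param pool_sizes Graph pooling sizes per layer.
#' @param seed Seed for parameter initialization.
#' @return An object of class `model_config`.
#' @export
model_config <- function(kind = c("fcn", "cnn", "gcnn_cheb", "gcnn_cayley"),
                         hidden = 460L,
                         conv_filters = c(64L, 128L),
                         conv_kernels = c(5L, 3L),
                         dense_units = 256L,
                         gc_features = c(32L, 64L),
                         cheb_orders = c(16L, 32L),
                         cayley_orders = c(4L, 6L),
                         pool_sizes = c(4L, 2L),
                         seed = 0L) {
  kind <- match.arg(kind)
  structure(
    list(
      kind = kind, hidden = hidden, conv_filters = conv_filters,
      conv_kernels = conv_kernels, dense_units = dense_units,
      gc_features = gc_features, cheb_orders = cheb_orders,
      cayley_orders = cayley_orders, pool_sizes = pool_sizes,
      n_input = 460L, n_classes = 2L, seed = as.integer(seed)
    ),
    class = "model_config"
  )
}

#' Build a classifier model
#'
#' @param config A [model_config].
#' @param hierarchy For graph models, a [coarsen] hierarchy of the polar
#'   graph with 3 levels (built automatically when omitted).
#' @return An object of class `polargcn_model`.
#' @export
build_model <- function(config = model_config(), hierarchy = NULL) {
  stopifnot(inherits(config, "model_config"))
  switch(config$kind,
    fcn = .build_fcn(config),
    cnn = .build_cnn(config),
    gcnn_cheb = ,
    gcnn_cayley = .build_gcnn(config, hierarchy)
  )
}

#' @rdname build_model
#' @param seed Seed forwarded to [model_config].
#' @export
build_fcn <- function(seed = 0L) build_model(model_config("fcn", seed = seed))

#' @rdname build_model
#' @export
build_cnn <- function(seed = 0L) build_model(model_config("cnn", seed = seed))

#' @rdname build_model
#' @param kind `"cheb"` or `"cayley"`.
#' @export
build_gcnn <- function(kind = c("cheb", "cayley"), hierarchy = NULL,
                       seed = 0L) {
  kind <- match.arg(kind)
  build_model(
    model_config(paste0("gcnn_", kind), seed = seed),
    hierarchy = hierarchy
  )
}

new_model <- function(config, params, extra = list()) {
  structure(
    c(
      list(
        kind = config$kind, config = config, params = params,
        trained = FALSE, loss_trace = NULL
      ),
      extra
    ),
    class = "polargcn_model"
  )
}

#' @export
print.polargcn_model <- function(x, ...) {
  cat(sprintf(
    "polargcn_model '%s': %s parameters, %s\n",
    x$kind, format(n_params(x), big.mark = ","),
    if (x$trained) "trained" else "untrained"
  ))
  invisible(x)
}

#' Number of trainable scalar parameters
#'
#' Complex coefficients count as two scalars (real and imaginary part).
#'
#' @param model A `polargcn_model`.
#' @return Integer parameter count.
#' @export
n_params <- function(model) {
  sum(vapply(model$params, function(p) {
    if (is.complex(p)) 2L * length(p) else length(p)
  }, integer(1)))
}

.build_fcn <- function(config) {
  .with_seed(config$seed, {
    params <- list(
      W1 = glorot_uniform(config$n_input, config$hidden),
      b1 = numeric(config$hidden),
      W2 = glorot_uniform(config$hidden, config$n_classes),
      b2 = numeric(config$n_classes)
    )
    new_model(config, params)
  })
}

# --- 2-D CNN helpers -------------------------------------------------------

# Gather indices for same-padded k x k convolution on an H x W image stored
# pixel-major (column-major, rows fast). Index H*W + 1 is the zero-pad slot.
conv_gather_idx <- function(H, W, k) {
  pad <- (k - 1L) %/% 2L
  p <- seq_len(H * W)
  r <- (p - 1L) %% H + 1L
  c <- (p - 1L) %/% H + 1L
  idx <- matrix(0L, H * W, k * k)
  col <- 0L
  for (dc in 0:(k - 1L)) {
    for (dr in 0:(k - 1L)) {
      col <- col + 1L
      rr <- r + dr - pad
      cc <- c + dc - pad
      ok <- rr >= 1L & rr <= H & cc >= 1L & cc <= W
      idx[, col] <- ifelse(ok, (cc - 1L) * H + rr, H * W + 1L)
    }
  }
  idx
}

# Gather indices for 2 x 2 stride-2 max pooling with ceiling-mode output
# (odd trailing rows/columns are padded with -Inf).
pool_gather_idx <- function(H, W) {
  Ho <- ceiling(H / 2)
  Wo <- ceiling(W / 2)
  p <- seq_len(Ho * Wo)
  r <- (p - 1L) %% Ho + 1L
  c <- (p - 1L) %/% Ho + 1L
  idx <- matrix(0L, Ho * Wo, 4L)
  col <- 0L
  for (dc in 0:1) {
    for (dr in 0:1) {
      col <- col + 1L
      rr <- 2L * (r - 1L) + 1L + dr
      cc <- 2L * (c - 1L) + 1L + dc
      ok <- rr <= H & cc <= W
      idx[, col] <- ifelse(ok, (cc - 1L) * H + rr, H * W + 1L)
    }
  }
  idx
}

.build_cnn <- function(config) {
  H1 <- 23L
  W1 <- 20L
  k1 <- config$conv_kernels[1L]
  k2 <- config$conv_kernels[2L]
  f1 <- config$conv_filters[1L]
  f2 <- config$conv_filters[2L]
  H2 <- as.integer(ceiling(H1 / 2))
  W2 <- as.integer(ceiling(W1 / 2)) # after pool 1
  H3 <- as.integer(ceiling(H2 / 2))
  W3 <- as.integer(ceiling(W2 / 2)) # after pool 2
  flat <- H3 * W3 * f2
  shapes <- list(
    H1 = H1, W1 = W1, H2 = H2, W2 = W2, H3 = H3, W3 = W3,
    f1 = f1, f2 = f2, flat = flat,
    idx1 = conv_gather_idx(H1, W1, k1),
    idx2 = conv_gather_idx(H2, W2, k2),
    pidx1 = pool_gather_idx(H1, W1),
    pidx2 = pool_gather_idx(H2, W2)
  )
  .with_seed(config$seed, {
    params <- list(
      W1 = glorot_uniform(k1 * k1 * 1L, f1, c(k1 * k1 * 1L, f1)),
      b1 = numeric(f1),
      W2 = glorot_uniform(k2 * k2 * f1, f2, c(k2 * k2 * f1, f2)),
      b2 = numeric(f2),
      W3 = glorot_uniform(flat, config$dense_units),
      b3 = numeric(config$dense_units),
      W4 = glorot_uniform(config$dense_units, config$n_classes),
      b4 = numeric(config$n_classes)
    )
    new_model(config, params, extra = list(shapes = shapes))
  })
}

.build_gcnn <- function(config, hierarchy) {
  if (is.null(hierarchy)) {
    hierarchy <- coarsen(build_polar_adjacency(polar_grid()), n_levels = 3L)
  }
  stopifnot(inherits(hierarchy, "graph_hierarchy"))
  steps_needed <- as.integer(round(sum(log2(config$pool_sizes))))
  if (hierarchy$n_levels < steps_needed) {
    stop(sprintf(
      "hierarchy has %d levels but the pooling schedule needs %d",
      hierarchy$n_levels, steps_needed
    ), call. = FALSE)
  }
  F1 <- config$gc_features[1L]
  F2 <- config$gc_features[2L]
  M3 <- hierarchy$n_padded[4L]
  cheb <- config$kind == "gcnn_cheb"
  # conv operators, precomputed once (rescaled for Chebyshev, plain
  # Laplacian for Cayley)
  ops <- if (cheb) {
    list(
      L0 = rescale_laplacian(
        hierarchy$levels[[1L]]$L, hierarchy$levels[[1L]]$lambda_max
      ),
      L2 = rescale_laplacian(
        hierarchy$levels[[3L]]$L, hierarchy$levels[[3L]]$lambda_max
      )
    )
  } else {
    list(
      L0 = hierarchy$levels[[1L]]$L,
      L2 = hierarchy$levels[[3L]]$L
    )
  }
  .with_seed(config$seed, {
    params <- if (cheb) {
      K <- config$cheb_orders
      list(
        theta1 = cheb_filter_params(K[1L], 1L, F1)$theta,
        bias1 = numeric(F1),
        theta2 = cheb_filter_params(K[2L], F1, F2)$theta,
        bias2 = numeric(F2),
        W = glorot_uniform(M3 * F2, config$n_classes),
        b = numeric(config$n_classes)
      )
    } else {
      K <- config$cayley_orders
      p1 <- cayley_filter_params(K[1L], 1L, F1)
      p2 <- cayley_filter_params(K[2L], F1, F2)
      list(
        c01 = p1$c0, cc1 = p1$cc, h1 = 1, bias1 = numeric(F1),
        c02 = p2$c0, cc2 = p2$cc, h2 = 1, bias2 = numeric(F2),
        W = glorot_uniform(M3 * F2, config$n_classes),
        b = numeric(config$n_classes)
      )
    }
    new_model(config, params, extra = list(hierarchy = hierarchy, ops = ops))
  })
}

# --- forward / backward passes --------------------------------------------

.forward_fcn <- function(model, X) {
  p <- model$params
  Z1 <- add_bias(X %*% p$W1, p$b1)
  H <- relu(Z1)
  logits <- add_bias(H %*% p$W2, p$b2)
  list(probs = softmax_rows(logits), cache = list(X = X, Z1 = Z1, H = H))
}

.backward_fcn <- function(model, cache, dlogits) {
  p <- model$params
  dW2 <- crossprod(cache$H, dlogits)
  db2 <- colSums(dlogits)
  dH <- dlogits %*% t(p$W2)
  dZ1 <- dH * (cache$Z1 > 0)
  list(
    W1 = crossprod(cache$X, dZ1), b1 = colSums(dZ1),
    W2 = dW2, b2 = db2
  )
}

conv2d_forward <- function(Xpix, idx, W, b, B, C) {
  HW <- nrow(Xpix)
  KK <- ncol(idx)
  O <- ncol(W)
  Xz <- rbind(Xpix, 0)
  P <- Xz[as.vector(idx), , drop = FALSE]
  dim(P) <- c(HW, KK, B, C)
  Pm <- matrix(aperm(P, c(1L, 3L, 2L, 4L)), HW * B, KK * C)
  Y <- add_bias(Pm %*% W, b) # (HW*B) x O, sample-major rows
  Ypix <- matrix(array(Y, c(HW, B, O)), HW, B * O)
  list(Ypix = Ypix, Pm = Pm)
}

conv2d_backward <- function(dYpix, idx, W, Pm, B, C) {
  HW <- nrow(dYpix)
  KK <- ncol(idx)
  O <- ncol(W)
  dY <- matrix(array(dYpix, c(HW, B, O)), HW * B, O)
  dW <- crossprod(Pm, dY)
  db <- colSums(dY)
  dP <- dY %*% t(W) # (HW*B) x (KK*C)
  dP <- aperm(array(dP, c(HW, B, KK, C)), c(1L, 3L, 2L, 4L))
  dXz <- matrix(0, HW + 1L, B * C)
  for (kk in seq_len(KK)) {
    dXz[idx[, kk], ] <- dXz[idx[, kk], ] + matrix(dP[, kk, , ], HW, B * C)
  }
  list(dW = dW, db = db, dXpix = dXz[seq_len(HW), , drop = FALSE])
}

pool2d_forward <- function(Xpix, pidx) {
  Xz <- rbind(Xpix, -Inf)
  best <- Xz[pidx[, 1L], , drop = FALSE]
  arg <- matrix(1L, nrow(best), ncol(best))
  for (k in 2:4) {
    g <- Xz[pidx[, k], , drop = FALSE]
    upd <- g > best
    best[upd] <- g[upd]
    arg[upd] <- k
  }
  list(Y = best, arg = arg)
}

pool2d_backward <- function(dY, pidx, arg, HW) {
  dXz <- matrix(0, HW + 1L, ncol(dY))
  for (k in 1:4) {
    sel <- arg == k
    dk <- dY
    dk[!sel] <- 0
    dXz[pidx[, k], ] <- dXz[pidx[, k], ] + dk
  }
  dXz[seq_len(HW), , drop = FALSE]
}

.forward_cnn <- function(model, X) {
  p <- model$params
  s <- model$shapes
  B <- nrow(X)
  Xpix <- t(X) # 460 x B, pixel-major raster values
  c1 <- conv2d_forward(Xpix, s$idx1, p$W1, p$b1, B, 1L)
  A1 <- relu(c1$Ypix) # (H1*W1) x (B*f1)
  p1 <- pool2d_forward(A1, s$pidx1) # (H2*W2) x (B*f1)
  c2 <- conv2d_forward(p1$Y, s$idx2, p$W2, p$b2, B, s$f1)
  A2 <- relu(c2$Ypix)
  p2 <- pool2d_forward(A2, s$pidx2) # (H3*W3) x (B*f2)
  flat <- t(matrix(
    aperm(array(p2$Y, c(s$H3 * s$W3, B, s$f2)), c(1L, 3L, 2L)),
    s$flat, B
  )) # B x flat
  Z3 <- add_bias(flat %*% p$W3, p$b3)
  H3 <- relu(Z3)
  logits <- add_bias(H3 %*% p$W4, p$b4)
  list(
    probs = softmax_rows(logits),
    cache = list(
      B = B, c1 = c1, A1 = A1, p1 = p1, c2 = c2, A2 = A2, p2 = p2,
      flat = flat, Z3 = Z3, H3 = H3
    )
  )
}

.backward_cnn <- function(model, cache, dlogits) {
  p <- model$params
  s <- model$shapes
  B <- cache$B
  dW4 <- crossprod(cache$H3, dlogits)
  db4 <- colSums(dlogits)
  dH3 <- dlogits %*% t(p$W4)
  dZ3 <- dH3 * (cache$Z3 > 0)
  dW3 <- crossprod(cache$flat, dZ3)
  db3 <- colSums(dZ3)
  dflat <- dZ3 %*% t(p$W3) # B x flat
  dp2 <- matrix(
    aperm(array(t(dflat), c(s$H3 * s$W3, s$f2, B)), c(1L, 3L, 2L)),
    s$H3 * s$W3, B * s$f2
  )
  dA2 <- pool2d_backward(dp2, s$pidx2, cache$p2$arg, s$H2 * s$W2)
  dC2 <- dA2 * (cache$c2$Ypix > 0)
  g2 <- conv2d_backward(dC2, s$idx2, p$W2, cache$c2$Pm, B, s$f1)
  dA1 <- pool2d_backward(g2$dXpix, s$pidx1, cache$p1$arg, s$H1 * s$W1)
  dC1 <- dA1 * (cache$c1$Ypix > 0)
  g1 <- conv2d_backward(dC1, s$idx1, p$W1, cache$c1$Pm, B, 1L)
  list(
    W1 = g1$dW, b1 = g1$db, W2 = g2$dW, b2 = g2$db,
    W3 = dW3, b3 = db3, W4 = dW4, b4 = db4
  )
}

# mask rows of padded fake nodes (replicated across the B sample blocks)
fake_rows <- function(mask, n, B) {
  idx <- which(mask)
  if (!length(idx)) {
    return(integer(0))
  }
  as.vector(outer(idx, (seq_len(B) - 1L) * n, `+`))
}

.forward_gcnn <- function(model, X) {
  p <- model$params
  hier <- model$hierarchy
  cfg <- model$config
  B <- nrow(X)
  M0 <- hier$n_padded[1L]
  M2 <- hier$n_padded[3L]
  M3 <- hier$n_padded[4L]
  cheb <- cfg$kind == "gcnn_cheb"
  L0 <- model$ops$L0
  L2 <- model$ops$L2
  X0 <- matrix(perm_input(X, hier), M0 * B, 1L)

  if (cheb) {
    f1 <- .cheb_forward(X0, M0, L0, p$theta1, p$bias1)
  } else {
    f1 <- .cayley_forward(X0, M0, L0, p$c01, p$cc1, p$h1, p$bias1)
  }
  Y1 <- f1$Y
  fr0 <- fake_rows(hier$fake_mask[[1L]], M0, B)
  Y1m <- Y1
  Y1m[fr0, ] <- -Inf
  pl1 <- .pool_forward(Y1m, cfg$pool_sizes[1L]) # -> level 2
  fr2 <- fake_rows(hier$fake_mask[[3L]], M2, B)
  P1 <- pl1$Y
  P1[fr2, ] <- 0
  A1 <- relu(P1)

  if (cheb) {
    f2 <- .cheb_forward(A1, M2, L2, p$theta2, p$bias2)
  } else {
    f2 <- .cayley_forward(A1, M2, L2, p$c02, p$cc2, p$h2, p$bias2)
  }
  Y2 <- f2$Y
  Y2m <- Y2
  Y2m[fr2, ] <- -Inf
  pl2 <- .pool_forward(Y2m, cfg$pool_sizes[2L]) # -> level 3
  fr3 <- fake_rows(hier$fake_mask[[4L]], M3, B)
  P2 <- pl2$Y
  P2[fr3, ] <- 0
  A2 <- relu(P2)

  F2w <- ncol(A2)
  flat <- t(matrix(aperm(array(A2, c(M3, B, F2w)), c(1L, 3L, 2L)), M3 * F2w, B))
  logits <- add_bias(flat %*% p$W, p$b)
  list(
    probs = softmax_rows(logits),
    cache = list(
      B = B, X0 = X0, L0 = L0, L2 = L2, M0 = M0, M2 = M2, M3 = M3,
      f1 = f1, pl1 = pl1, P1 = P1, A1 = A1,
      f2 = f2, pl2 = pl2, P2 = P2, A2 = A2,
      fr0 = fr0, fr2 = fr2, fr3 = fr3, flat = flat
    )
  )
}

.backward_gcnn <- function(model, cache, dlogits) {
  p <- model$params
  cfg <- model$config
  B <- cache$B
  cheb <- cfg$kind == "gcnn_cheb"
  dW <- crossprod(cache$flat, dlogits)
  db <- colSums(dlogits)
  dflat <- dlogits %*% t(p$W) # B x (M3*F2)
  F2w <- ncol(cache$A2)
  dA2 <- matrix(
    aperm(array(t(dflat), c(cache$M3, F2w, B)), c(1L, 3L, 2L)),
    cache$M3 * B, F2w
  )
  dP2 <- dA2 * (cache$P2 > 0)
  dP2[cache$fr3, ] <- 0
  dY2 <- .pool_backward(dP2, cache$pl2$takes)
  dY2[cache$fr2, ] <- 0
  if (cheb) {
    g2 <- .cheb_backward(dY2, cache$f2, cache$M2, cache$L2, p$theta2)
    dA1 <- g2$dX
  } else {
    g2 <- .cayley_backward(
      dY2, cache$A1, cache$f2, cache$M2, p$c02, p$cc2,
      p$h2
    )
    dA1 <- g2$dX
  }
  dP1 <- dA1 * (cache$P1 > 0)
  dP1[cache$fr2, ] <- 0
  dY1 <- .pool_backward(dP1, cache$pl1$takes)
  dY1[cache$fr0, ] <- 0
  if (cheb) {
    g1 <- .cheb_backward(dY1, cache$f1, cache$M0, cache$L0, p$theta1,
      need_dx = FALSE
    )
    list(
      theta1 = g1$dtheta, bias1 = g1$dbias,
      theta2 = g2$dtheta, bias2 = g2$dbias, W = dW, b = db
    )
  } else {
    g1 <- .cayley_backward(
      dY1, cache$X0, cache$f1, cache$M0, p$c01, p$cc1,
      p$h1,
      need_dx = FALSE
    )
    list(
      c01 = g1$dc0, cc1 = g1$dcc, h1 = g1$dh, bias1 = g1$dbias,
      c02 = g2$dc0, cc2 = g2$dcc, h2 = g2$dh, bias2 = g2$dbias,
      W = dW, b = db
    )
  }
}

model_forward <- function(model, X) {
  switch(model$kind,
    fcn = .forward_fcn(model, X),
    cnn = .forward_cnn(model, X),
    gcnn_cheb = ,
    gcnn_cayley = .forward_gcnn(model, X)
  )
}

model_backward <- function(model, cache, dlogits) {
  switch(model$kind,
    fcn = .backward_fcn(model, cache, dlogits),
    cnn = .backward_cnn(model, cache, dlogits),
    gcnn_cheb = ,
    gcnn_cayley = .backward_gcnn(model, cache, dlogits)
  )
}

#' Predicted class probabilities or labels
#'
#' @param object A `polargcn_model`.
#' @param newdata A matrix (samples x 460), a single [polar_map] or a list
#'   of them.
#' @param type `"prob"` for a samples x 2 matrix with columns `normal` and
#'   `abnormal`, `"class"` for hard labels (ties at exactly 0.5 go to
#'   `normal`).
#' @param ... Unused.
#' @export
predict.polargcn_model <- function(object, newdata, type = c("prob", "class"),
                                   ...) {
  type <- match.arg(type)
  X <- as_value_matrix(newdata)
  probs <- model_forward(object, X)$probs
  colnames(probs) <- c("normal", "abnormal")
  if (type == "prob") {
    return(probs)
  }
  c("normal", "abnormal")[max.col(probs, ties.method = "first")]
}

as_value_matrix <- function(x) {
  if (is.matrix(x)) {
    return(x)
  }
  if (inherits(x, "polar_map")) {
    return(matrix(x$values, 1L, 460L))
  }
  if (is.list(x)) {
    return(t(vapply(x, function(m) m$values, numeric(460))))
  }
  if (is.numeric(x) && length(x) == 460L) {
    return(matrix(x, 1L, 460L))
  }
  stop("cannot interpret newdata as polar-map values", call. = FALSE)
}
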