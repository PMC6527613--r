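# Spectral graph filters.
#
# Node signals are carried internally as (n*B) x F matrices: B sample
# blocks of n node rows stacked vertically (sample-major), F feature
# columns. Reinterpreting such a matrix as n x (B*F) (pure dim change,
# column-major) exposes the node dimension for sparse Laplacian products.

to_node_major <- function(X, n) {
  dim(X) <- c(n, length(X) / n)
  X
}

graph_apply <- function(M, X, n) {
  nr <- nrow(X)
  nc <- ncol(X)
  Y <- as.matrix(M %*% to_node_major(X, n))
  dim(Y) <- c(nr, nc)
  Y
}

add_bias <- function(Y, bias) Y + rep(bias, each = nrow(Y))

#' Chebyshev filter parameters
#'
#' Coefficients `theta` of a polynomial spectral filter of order `K`
#' (array K x F_in x F_out) plus one bias per output feature map. Random
#' initialization is zero-mean uniform with scale `1/sqrt(K * f_in)`.
#'
#' @param K Polynomial order (number of Chebyshev terms), >= 1.
#' @param f_in,f_out Input/output feature widths.
#' @param theta,bias Optional explicit values.
#' @return An object of class `cheb_filter_params`.
#' @export
cheb_filter_params <- function(K, f_in = 1L, f_out = 1L, theta = NULL,
                               bias = NULL) {
  if (K < 1L) stop("Chebyshev order K must be >= 1", call. = FALSE)
  scale <- 1 / sqrt(K * f_in)
  if (is.null(theta)) {
    theta <- array(stats::runif(K * f_in * f_out, -scale, scale),
      dim = c(K, f_in, f_out)
    )
  }
  theta <- array(theta, dim = c(K, f_in, f_out))
  if (is.null(bias)) bias <- numeric(f_out)
  stopifnot(all(is.finite(theta)), length(bias) == f_out)
  structure(list(K = as.integer(K), theta = theta, bias = bias),
    class = "cheb_filter_params"
  )
}

.cheb_forward <- function(X, n, L_tilde, theta, bias) {
  K <- dim(theta)[1L]
  f_in <- dim(theta)[2L]
  f_out <- dim(theta)[3L]
  if (ncol(X) != f_in || nrow(X) %% n != 0L) {
    stop("signal shape does not match filter parameters", call. = FALSE)
  }
  cols <- function(k) ((k - 1L) * f_in + 1L):(k * f_in)
  Tcat <- matrix(0, nrow(X), K * f_in) # (nB) x (K*f_in), feature-fast in k
  Tcat[, cols(1L)] <- X
  if (K >= 2L) {
    t_pp <- X
    t_p <- graph_apply(L_tilde, X, n)
    Tcat[, cols(2L)] <- t_p
    if (K >= 3L) {
      for (k in 3:K) {
        t_new <- 2 * graph_apply(L_tilde, t_p, n) - t_pp
        Tcat[, cols(k)] <- t_new
        t_pp <- t_p
        t_p <- t_new
      }
    }
  }
  W <- matrix(aperm(theta, c(2L, 1L, 3L)), K * f_in, f_out)
  list(Y = add_bias(Tcat %*% W, bias), Tcat = Tcat)
}

.cheb_backward <- function(dY, cache, n, L_tilde, theta, need_dx = TRUE) {
  K <- dim(theta)[1L]
  f_in <- dim(theta)[2L]
  f_out <- dim(theta)[3L]
  dW <- crossprod(cache$Tcat, dY)
  dtheta <- aperm(array(dW, c(f_in, K, f_out)), c(2L, 1L, 3L))
  dbias <- colSums(dY)
  if (!need_dx) {
    return(list(dtheta = dtheta, dbias = dbias, dX = NULL))
  }
  # reverse-mode through the three-term recurrence for the signal gradient:
  # a_j = g_j + 2 L a_{j+1} - a_{j+2} for j >= 2, a_1 = g_1 + L a_2 - a_3,
  # with g_j = dY theta_j^T; only two accumulators stay live.
  G <- dY %*% t(matrix(aperm(theta, c(2L, 1L, 3L)), K * f_in, f_out))
  cols <- function(k) ((k - 1L) * f_in + 1L):(k * f_in)
  ap1 <- NULL # a_{j+1}
  ap2 <- NULL # a_{j+2}
  for (j in K:1) {
    aj <- G[, cols(j), drop = FALSE]
    if (!is.null(ap1)) {
      aj <- aj + (if (j >= 2L) 2 else 1) * graph_apply(L_tilde, ap1, n)
    }
    if (!is.null(ap2)) aj <- aj - ap2
    ap2 <- ap1
    ap1 <- aj
  }
  list(dtheta = dtheta, dbias = dbias, dX = ap1)
}

#' Chebyshev spectral graph convolution
#'
#' Evaluates `y = sum_k T_k(L_tilde) x theta_k + bias` through the
#' three-term recurrence `T_0 = I`, `T_1 = L_tilde`,
#' `T_k = 2 L_tilde T_{k-1} - T_{k-2}` applied to the signal itself, so no
#' n x n polynomial of the Laplacian is ever formed (cost O(K |E|) per
#' feature pair).
#'
#' @param x Signal matrix n x F_in (or a vector, taken as F_in = 1).
#' @param L_tilde Rescaled Laplacian with spectrum in [-1, 1]
#'   (see [rescale_laplacian]).
#' @param params A [cheb_filter_params].
#' @return Filtered signal, n x F_out.
#' @export
cheb_conv <- function(x, L_tilde, params) {
  stopifnot(inherits(params, "cheb_filter_params"))
  if (is.null(dim(x))) x <- matrix(x, ncol = 1L)
  .cheb_forward(x, nrow(x), L_tilde, params$theta, params$bias)$Y
}

#' Cayley filter parameters
#'
#' A Cayley rational filter of order `K` has one real coefficient `c0` and
#' `K` complex coefficients per (input, output) feature pair, plus the
#' positive real spectral zoom `h` (shared per layer) and one bias per
#' output map. Random initialization is zero-mean uniform with scale
#' `1/sqrt((K + 1) * f_in)` (real and imaginary parts independently).
#'
#' @param K Rational order, >= 0 (K = 0 reduces to a per-pair scaling).
#' @param f_in,f_out Feature widths.
#' @param h Spectral zoom, positive real (default 1).
#' @param c0,cc,bias Optional explicit values (`cc` complex,
#'   K x F_in x F_out).
#' @return An object of class `cayley_filter_params`.
#' @export
cayley_filter_params <- function(K, f_in = 1L, f_out = 1L, h = 1,
                                 c0 = NULL, cc = NULL, bias = NULL) {
  if (K < 0L) stop("Cayley order K must be >= 0", call. = FALSE)
  if (!is.numeric(h) || h <= 0) stop("spectral zoom h must be > 0", call. = FALSE)
  scale <- 1 / sqrt((K + 1) * f_in)
  if (is.null(c0)) {
    c0 <- matrix(stats::runif(f_in * f_out, -scale, scale), f_in, f_out)
  }
  c0 <- matrix(c0, f_in, f_out)
  if (is.null(cc)) {
    cc <- array(
      complex(
        real = stats::runif(K * f_in * f_out, -scale, scale),
        imaginary = stats::runif(K * f_in * f_out, -scale, scale)
      ),
      dim = c(K, f_in, f_out)
    )
  }
  cc <- array(as.complex(cc), dim = c(K, f_in, f_out))
  if (is.null(bias)) bias <- numeric(f_out)
  stopifnot(all(is.finite(c0)), all(is.finite(Re(cc))), length(bias) == f_out)
  structure(
    list(K = as.integer(K), c0 = c0, cc = cc, h = h, bias = bias),
    class = "cayley_filter_params"
  )
}

.cayley_operators <- function(L, h) {
  Ld <- as.matrix(L)
  n <- nrow(Ld)
  Ap <- h * Ld
  diag(Ap) <- diag(Ap) + 1i
  Am <- h * Ld
  diag(Am) <- diag(Am) - 1i
  list(Ld = Ld, Ap = Ap, Am = Am, n = n)
}

# z |-> M z with M = (hL - iI)(hL + iI)^{-1}, by one complex solve
.cayley_M <- function(ops, Z, n) {
  nr <- nrow(Z)
  nc <- ncol(Z)
  Y <- solve(ops$Ap, ops$Am %*% to_node_major(Z, n))
  dim(Y) <- c(nr, nc)
  Y
}

.cayley_forward <- function(X, n, L, c0, cc, h, bias) {
  K <- dim(cc)[1L]
  f_in <- dim(cc)[2L]
  f_out <- dim(cc)[3L]
  if (ncol(X) != f_in || nrow(X) %% n != 0L) {
    stop("signal shape does not match filter parameters", call. = FALSE)
  }
  ops <- .cayley_operators(L, h)
  Y <- add_bias(X %*% c0, bias)
  zs <- vector("list", K)
  z <- X + 0i
  for (k in seq_len(K)) {
    z <- .cayley_M(ops, z, n)
    zs[[k]] <- z
    Y <- Y + 2 * Re(z %*% matrix(cc[k, , ], f_in, f_out))
  }
  list(Y = Y, zs = zs, ops = ops)
}

.cayley_backward <- function(dY, X, cache, n, c0, cc, h, need_dx = TRUE) {
  K <- dim(cc)[1L]
  f_in <- dim(cc)[2L]
  f_out <- dim(cc)[3L]
  ops <- cache$ops
  dc0 <- crossprod(X, dY)
  dbias <- colSums(dY)
  dcc <- array(0i, dim = dim(cc))
  dX <- NULL
  for (k in seq_len(K)) {
    # gradient w.r.t. complex coefficients, stored as d/dRe + i d/dIm
    dcc[k, , ] <- 2 * (t(Conj(cache$zs[[k]])) %*% dY)
  }
  if (need_dx) {
    dX <- dY %*% t(c0)
    w <- dY + 0i
    for (k in seq_len(K)) {
      w <- .cayley_M(ops, w, n)
      dX <- dX + 2 * Re(w %*% t(matrix(cc[k, , ], f_in, f_out)))
    }
  }
  # spectral zoom: forward-mode through z_k = M z_{k-1},
  # dM/dh = (I - M) L (hL + iI)^{-1}
  dh <- 0
  if (K >= 1L) {
    zp <- matrix(0i, nrow(X), ncol(X))
    zprev <- X + 0i
    for (k in seq_len(K)) {
      nr <- nrow(zprev)
      s <- solve(ops$Ap, to_node_major(zprev, n))
      Ls <- ops$Ld %*% s
      dim(Ls) <- c(nr, ncol(zprev))
      Mzp <- .cayley_M(ops, zp, n)
      MLs <- .cayley_M(ops, Ls, n)
      zp <- Mzp + Ls - MLs
      dh <- dh +
        2 * sum(dY * Re(zp %*% matrix(cc[k, , ], f_in, f_out)))
      zprev <- cache$zs[[k]]
    }
  }
  list(dc0 = dc0, dcc = dcc, dh = dh, dbias = dbias, dX = dX)
}

#' Cayley spectral graph convolution
#'
#' Evaluates `y = c0 x + 2 Re{ sum_k c_k M^k x } + bias` where
#' `M = (hL - iI)(hL + iI)^{-1}` is the Cayley transform of the (unscaled)
#' Laplacian zoomed by `h`. The K powers are applied by sequential complex
#' linear solves with `hL + iI`; the output is real.
#'
#' @param x Signal matrix n x F_in (or a vector).
#' @param L Combinatorial Laplacian of the graph.
#' @param params A [cayley_filter_params].
#' @return Filtered signal, n x F_out.
#' @export
cayley_conv <- function(x, L, params) {
  stopifnot(inherits(params, "cayley_filter_params"))
  if (is.null(dim(x))) x <- matrix(x, ncol = 1L)
  .cayley_forward(
    x, nrow(x), L, params$c0, params$cc, params$h,
    params$bias
  )$Y
}

.pool_pair <- function(X) {
  i1 <- seq(1L, nrow(X), by = 2L)
  X1 <- X[i1, , drop = FALSE]
  X2 <- X[i1 + 1L, , drop = FALSE]
  list(Y = pmax(X1, X2), take_first = X1 >= X2)
}

.pool_forward <- function(X, size) {
  steps <- as.integer(round(log2(size)))
  takes <- vector("list", steps)
  for (s in seq_len(steps)) {
    if (nrow(X) %% 2L != 0L) {
      stop("signal length not divisible by pooling size", call. = FALSE)
    }
    p <- .pool_pair(X)
    X <- p$Y
    takes[[s]] <- p$take_first
  }
  list(Y = X, takes = takes)
}

.pool_backward <- function(dY, takes) {
  for (s in rev(seq_along(takes))) {
    take <- takes[[s]]
    dX <- matrix(0, 2L * nrow(dY), ncol(dY))
    i1 <- seq(1L, nrow(dX), by = 2L)
    d1 <- dY
    d1[!take] <- 0
    d2 <- dY
    d2[take] <- 0
    dX[i1, ] <- d1
    dX[i1 + 1L, ] <- d2
    dY <- dX
  }
  dY
}

#' Graph max-pooling over contiguous sibling blocks
#'
#' Reduces every block of `size` consecutive rows (siblings under the
#' coarsening permutation, see [coarsen]) to their maximum; size 4 is two
#' consecutive pair reductions. Fake-node entries should carry the sentinel
#' `-Inf` so they never win against a real sibling.
#'
#' @param x Signal matrix (rows = padded, permuted nodes; possibly several
#'   stacked sample blocks) or vector.
#' @param size Pooling size, 2 or 4.
#' @return Pooled signal with `nrow(x)/size` rows.
#' @export
graph_max_pool <- function(x, size = 2L) {
  if (!size %in% c(2L, 4L)) stop("pooling size must be 2 or 4", call. = FALSE)
  if (is.null(dim(x))) x <- matrix(x, ncol = 1L)
  if (nrow(x) %% size != 0L) {
    stop("signal length not divisible by pooling size", call. = FALSE)
  }
  .pool_forward(x, size)$Y
}
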