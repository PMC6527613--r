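test_that("order-1 Chebyshev filter is a pure scaling", {
  A <- random_adjacency(8)
  L <- laplacian(A)
  lmax <- eigen(as.matrix(L), symmetric = TRUE, only.values = TRUE)$values[1]
  Lt <- rescale_laplacian(L, lmax)
  p <- cheb_filter_params(1, 1, 1, theta = 2.5, bias = 0)
  x <- rnorm(8)
  expect_equal(as.numeric(cheb_conv(x, Lt, p)), 2.5 * x, tolerance = 1e-12)
})

test_that("Chebyshev filter on the 2-node graph reproduces the hand calculation", {
  # A = [[0,1],[1,0]], lambda_max = 2, L_tilde = [[0,-1],[-1,0]];
  # K = 2, theta = (0, 1): y = T_1 x = L_tilde x = (-x2, -x1)
  L <- laplacian(rbind(c(0, 1), c(1, 0)))
  Lt <- rescale_laplacian(L, 2)
  p <- cheb_filter_params(2, 1, 1, theta = c(0, 1), bias = 0)
  x <- c(1.3, -0.7)
  expect_equal(as.numeric(cheb_conv(x, Lt, p)), c(0.7, -1.3), tolerance = 1e-12)
})

test_that("Chebyshev recurrence matches the dense spectral oracle", {
  set.seed(41)
  worst <- 0
  for (i in 1:12) {
    n <- sample(5:30, 1)
    A <- random_adjacency(n)
    L <- laplacian(A)
    lmax <- eigen(as.matrix(L), symmetric = TRUE, only.values = TRUE)$values[1]
    Lt <- rescale_laplacian(L, lmax)
    p <- cheb_filter_params(sample(1:8, 1), sample(1:3, 1), sample(1:3, 1))
    p$bias <- rnorm(dim(p$theta)[3])
    x <- matrix(rnorm(n * dim(p$theta)[2]), n)
    y <- cheb_conv(x, Lt, p)
    yo <- cheb_oracle(x, L, lmax, p)
    worst <- max(worst, max(abs(y - yo)) / max(abs(yo)))
  }
  expect_lt(worst, 1e-8)
})

test_that("order-0 Cayley filter is the real coefficient alone", {
  A <- random_adjacency(7)
  L <- laplacian(A)
  p <- cayley_filter_params(0, 1, 1, c0 = -1.2, bias = 0)
  x <- rnorm(7)
  expect_equal(as.numeric(cayley_conv(x, L, p)), -1.2 * x, tolerance = 1e-12)
})

test_that("Cayley filter acts analytically on the constant eigenvector", {
  # L 1 = 0, so M 1 = ((-i)/(i)) 1 = -1 and
  # y = (c0 + 2 Re sum_k c_k (-1)^k) 1
  A <- random_adjacency(9)
  L <- laplacian(A)
  K <- 3
  p <- cayley_filter_params(K, 1, 1, h = 0.7)
  x <- rep(1, 9)
  expected <- (p$c0[1, 1] +
    2 * sum(Re(p$cc[, 1, 1] * (-1)^seq_len(K)))) * x
  expect_equal(as.numeric(cayley_conv(x, L, p)), expected, tolerance = 1e-10)
})

test_that("Cayley solves match the dense spectral oracle and stay real", {
  set.seed(43)
  worst <- 0
  for (i in 1:12) {
    n <- sample(5:30, 1)
    A <- random_adjacency(n)
    L <- laplacian(A)
    p <- cayley_filter_params(sample(0:4, 1), sample(1:3, 1), sample(1:3, 1),
      h = runif(1, 0.3, 2)
    )
    p$bias <- rnorm(dim(p$cc)[3])
    x <- matrix(rnorm(n * dim(p$cc)[2]), n)
    y <- cayley_conv(x, L, p)
    expect_true(is.numeric(y) && !is.complex(y))
    yo <- cayley_oracle(x, L, p)
    worst <- max(worst, max(abs(y - yo)) / max(abs(yo)))
  }
  expect_lt(worst, 1e-8)
})

test_that("the full Cayley rational (filter plus conjugate) has no imaginary part", {
  set.seed(44)
  n <- 12
  A <- random_adjacency(n)
  L <- as.matrix(laplacian(A))
  K <- 3
  p <- cayley_filter_params(K, 1, 1, h = 1.3)
  x <- rnorm(n)
  M <- solve(p$h * L + 1i * diag(n), p$h * L - 1i * diag(n))
  y_full <- p$c0[1, 1] * (x + 0i)
  z <- x + 0i
  zc <- x + 0i
  for (k in seq_len(K)) {
    z <- M %*% z
    zc <- Conj(M) %*% zc
    y_full <- y_full + p$cc[k, 1, 1] * z + Conj(p$cc[k, 1, 1]) * zc
  }
  expect_lt(max(abs(Im(y_full))), 1e-10)
  expect_equal(as.numeric(Re(y_full)), as.numeric(cayley_conv(x, L, p)),
    tolerance = 1e-10
  )
})

test_that("both convolutions are linear in the signal and permutation equivariant", {
  set.seed(45)
  n <- 14
  A <- random_adjacency(n)
  L <- laplacian(A)
  lmax <- eigen(as.matrix(L), symmetric = TRUE, only.values = TRUE)$values[1]
  Lt <- rescale_laplacian(L, lmax)
  pc <- cheb_filter_params(4, 2, 3)
  py <- cayley_filter_params(2, 2, 3, h = 0.9)
  x <- matrix(rnorm(n * 2), n)
  z <- matrix(rnorm(n * 2), n)
  # linearity (bias is zero by default)
  expect_equal(cheb_conv(2 * x - 3 * z, Lt, pc),
    2 * cheb_conv(x, Lt, pc) - 3 * cheb_conv(z, Lt, pc),
    tolerance = 1e-10
  )
  expect_equal(cayley_conv(2 * x - 3 * z, L, py),
    2 * cayley_conv(x, L, py) - 3 * cayley_conv(z, L, py),
    tolerance = 1e-10
  )
  # permutation equivariance
  perm <- sample(n)
  Lp <- as.matrix(L)[perm, perm]
  Ltp <- as.matrix(Lt)[perm, perm]
  expect_equal(cheb_conv(x[perm, ], Ltp, pc), cheb_conv(x, Lt, pc)[perm, ],
    tolerance = 1e-10
  )
  expect_equal(cayley_conv(x[perm, ], Lp, py), cayley_conv(x, L, py)[perm, ],
    tolerance = 1e-10
  )
})

test_that("analytic layer gradients match finite differences", {
  set.seed(46)
  n <- 10
  A <- random_adjacency(n)
  L <- laplacian(A)
  lmax <- eigen(as.matrix(L), symmetric = TRUE, only.values = TRUE)$values[1]
  Lt <- rescale_laplacian(L, lmax)
  x <- matrix(rnorm(n * 2), n)
  dY <- matrix(rnorm(n * 3), n)
  eps <- 1e-6

  pc <- cheb_filter_params(4, 2, 3)
  fw <- polargcn:::.cheb_forward(x, n, Lt, pc$theta, pc$bias)
  bw <- polargcn:::.cheb_backward(dY, fw, n, Lt, pc$theta)
  for (probe in 1:5) {
    j <- sample(length(pc$theta), 1)
    th2 <- pc$theta
    th2[j] <- th2[j] + eps
    num <- (sum(dY * polargcn:::.cheb_forward(x, n, Lt, th2, pc$bias)$Y) -
      sum(dY * fw$Y)) / eps
    expect_equal(bw$dtheta[j], num, tolerance = 1e-4)
    j <- sample(length(x), 1)
    x2 <- x
    x2[j] <- x2[j] + eps
    num <- (sum(dY * polargcn:::.cheb_forward(x2, n, Lt, pc$theta, pc$bias)$Y) -
      sum(dY * fw$Y)) / eps
    expect_equal(bw$dX[j], num, tolerance = 1e-4)
  }

  py <- cayley_filter_params(3, 2, 3, h = 1.1)
  fwc <- polargcn:::.cayley_forward(x, n, L, py$c0, py$cc, py$h, py$bias)
  bwc <- polargcn:::.cayley_backward(dY, x, fwc, n, py$c0, py$cc, py$h)
  loss_at <- function(p) {
    sum(dY * polargcn:::.cayley_forward(x, n, L, p$c0, p$cc, p$h, p$bias)$Y)
  }
  base <- loss_at(py)
  for (probe in 1:4) {
    j <- sample(length(py$cc), 1)
    p2 <- py
    p2$cc[j] <- p2$cc[j] + eps
    expect_equal(Re(bwc$dcc[j]), (loss_at(p2) - base) / eps, tolerance = 1e-4)
    p2 <- py
    p2$cc[j] <- p2$cc[j] + eps * 1i
    expect_equal(Im(bwc$dcc[j]), (loss_at(p2) - base) / eps, tolerance = 1e-4)
  }
  p2 <- py
  p2$h <- p2$h + eps
  expect_equal(bwc$dh, (loss_at(p2) - base) / eps, tolerance = 1e-4)
  j <- sample(length(x), 1)
  x2 <- x
  x2[j] <- x2[j] + eps
  fwc2 <- polargcn:::.cayley_forward(x2, n, L, py$c0, py$cc, py$h, py$bias)
  expect_equal(bwc$dX[j], (sum(dY * fwc2$Y) - base) / eps, tolerance = 1e-4)
})

test_that("graph max-pooling reduces sibling blocks and honours the sentinel", {
  expect_equal(as.numeric(graph_max_pool(c(1, 5, 2, 0), 2)), c(5, 2))
  expect_equal(as.numeric(graph_max_pool(c(-Inf, 3), 2)), 3)
  expect_equal(as.numeric(graph_max_pool(c(1, 5, 2, 0), 4)), 5)
  set.seed(47)
  x <- matrix(rnorm(32 * 3), 32, 3)
  expect_equal(
    graph_max_pool(x, 4),
    graph_max_pool(graph_max_pool(x, 2), 2)
  )
  expect_error(graph_max_pool(matrix(rnorm(6), 3), 2), "divisible")
  expect_error(graph_max_pool(x, 3), "size")
})
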