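#' Graph container with Laplacian and spectral bound
#'
#' @param A Symmetric nonnegative adjacency matrix with zero diagonal
#'   (dense or `Matrix` sparse).
#' @return An object of class `pm_graph` with elements `n`, `A` (sparse),
#'   `L` (combinatorial Laplacian `D - A`) and `lambda_max` (largest
#'   Laplacian eigenvalue, dense symmetric eigensolver).
#' @export
pm_graph <- function(A) {
  A <- methods::as(methods::as(Matrix::Matrix(A, sparse = TRUE), "generalMatrix"), "CsparseMatrix")
  L <- laplacian(A)
  lmax <- laplacian_lambda_max(L)
  structure(list(n = nrow(A), A = A, L = L, lambda_max = lmax),
    class = "pm_graph"
  )
}

#' @export
print.pm_graph <- function(x, ...) {
  cat(sprintf(
    "pm_graph: %d nodes, %d edges, lambda_max = %.4f\n",
    x$n, Matrix::nnzero(x$A) / 2, x$lambda_max
  ))
  invisible(x)
}

#' Unit-weight adjacency of the polar-map graph
#'
#' Each node (ring r, sector s) is connected to its angular neighbours
#' (r, s +/- 1 mod 23) - the rings wrap around - and to its radial
#' neighbours (r +/- 1, s) where the ring exists. All edges have weight 1;
#' apex-ring nodes are not connected across the pole.
#'
#' @param grid A [polar_grid()].
#' @return A `pm_graph` on 460 nodes with 897 edges.
#' @export
build_polar_adjacency <- function(grid = polar_grid()) {
  pm_graph(polar_adjacency_sparse(grid))
}

# raw sparse adjacency, memoized (it is a fixed 460-node graph)
.polargcn_cache <- new.env(parent = emptyenv())

polar_adjacency_sparse <- function(grid = polar_grid()) {
  if (!is.null(.polargcn_cache$A)) {
    return(.polargcn_cache$A)
  }
  stopifnot(inherits(grid, "polar_grid"))
  nr <- grid$n_rings
  ns <- grid$n_sectors
  r <- grid$ring
  s <- grid$sector
  idx <- function(ring, sector) ring * ns + sector + 1L # 1-based
  # angular edges (wrap)
  ai <- idx(r, s)
  aj <- idx(r, (s + 1L) %% ns)
  # radial edges
  rad <- r < nr - 1L
  ri <- idx(r[rad], s[rad])
  rj <- idx(r[rad] + 1L, s[rad])
  A <- Matrix::sparseMatrix(
    i = c(ai, aj, ri, rj), j = c(aj, ai, rj, ri),
    x = 1, dims = c(grid$n_nodes, grid$n_nodes)
  )
  .polargcn_cache$A <- A
  A
}

#' Combinatorial graph Laplacian L = D - A
#'
#' @param A Symmetric nonnegative adjacency with zero diagonal.
#' @return Sparse Laplacian matrix.
#' @export
laplacian <- function(A) {
  A <- Matrix::Matrix(A, sparse = TRUE)
  if (!Matrix::isSymmetric(A)) stop("adjacency must be symmetric", call. = FALSE)
  A <- methods::as(methods::as(A, "generalMatrix"), "CsparseMatrix")
  if (any(A@x < 0)) stop("adjacency must be nonnegative", call. = FALSE)
  if (any(Matrix::diag(A) != 0)) {
    stop("adjacency must have zero diagonal", call. = FALSE)
  }
  Matrix::Diagonal(nrow(A), x = Matrix::rowSums(A)) - A
}

#' Largest Laplacian eigenvalue (dense symmetric eigensolver)
#' @param L Laplacian matrix.
#' @keywords internal
laplacian_lambda_max <- function(L) {
  ev <- eigen(as.matrix(L), symmetric = TRUE, only.values = TRUE)$values
  max(ev)
}

#' Rescale a Laplacian to the Chebyshev domain [-1, 1]
#'
#' Computes `L_tilde = (2 / lambda_max) * L - I`, mapping the Laplacian
#' spectrum [0, lambda_max] onto [-1, 1] (the constant eigenvector attains
#' eigenvalue -1).
#'
#' @param L Laplacian matrix.
#' @param lambda_max Largest eigenvalue of `L`; must be positive.
#' @return Sparse rescaled Laplacian.
#' @export
rescale_laplacian <- function(L, lambda_max) {
  if (!is.numeric(lambda_max) || length(lambda_max) != 1 || lambda_max <= 0) {
    stop("lambda_max must be a positive scalar", call. = FALSE)
  }
  (2 / lambda_max) * L - Matrix::Diagonal(nrow(L))
}
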