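#' Greedy pairwise matching for one coarsening level
#'
#' Nodes are visited in ascending order of (weighted) degree, ties broken by
#' lowest index. An unmatched node is merged with the unmatched neighbour
#' maximizing the normalized-cut score `A_ij * (1/d_i + 1/d_j)` (ties again
#' to the lowest index); if none exists it stays a singleton. Cluster ids
#' are assigned in visiting order, making the matching fully deterministic.
#'
#' @param A Sparse symmetric adjacency.
#' @return Integer vector mapping each fine node to its coarse cluster id.
#' @keywords internal
graclus_matching <- function(A) {
  n <- nrow(A)
  d <- Matrix::rowSums(A)
  A <- methods::as(methods::as(A, "generalMatrix"), "CsparseMatrix")
  ptr <- A@p
  rows <- A@i + 1L
  wts <- A@x
  ord <- order(d, seq_len(n))
  matched <- logical(n)
  cluster <- integer(n)
  cid <- 0L
  for (i in ord) {
    if (matched[i]) next
    matched[i] <- TRUE
    cid <- cid + 1L
    cluster[i] <- cid
    if (ptr[i + 1L] > ptr[i]) {
      span <- (ptr[i] + 1L):ptr[i + 1L]
      nbr <- rows[span]
      w <- wts[span]
      keep <- !matched[nbr]
      if (any(keep)) {
        nbr <- nbr[keep]
        w <- w[keep]
        score <- w * (1 / d[i] + 1 / d[nbr])
        j <- nbr[order(-score, nbr)][1L]
        matched[j] <- TRUE
        cluster[j] <- cid
      }
    }
  }
  cluster
}

coarse_adjacency <- function(A, cluster) {
  m <- max(cluster)
  P <- Matrix::sparseMatrix(
    i = seq_along(cluster), j = cluster, x = 1,
    dims = c(length(cluster), m)
  )
  Ac <- Matrix::t(P) %*% A %*% P
  Matrix::diag(Ac) <- 0
  Matrix::drop0(Ac)
}

#' Coarsen a graph into a pooling hierarchy
#'
#' Repeated greedy pairwise matching (see [graclus_matching]) produces
#' `n_levels` successively coarser graphs. Coarse edge weights are the sums
#' of the merged fine edges (self-loops dropped). Unmatched singletons are
#' padded with isolated fake nodes so that every padded level holds exactly
#' twice the nodes of the next, and a permutation of each level's nodes is
#' computed so that all descendants of a coarse node occupy a contiguous
#' block - graph max-pooling then reduces consecutive blocks.
#'
#' @param graph A [pm_graph].
#' @param n_levels Number of coarsening levels (>= 1); the default 3
#'   supports pooling sizes 4 then 2.
#' @param seed Accepted for interface stability; the matching itself is
#'   deterministic (fixed visiting order and tie-breaks), so the result does
#'   not depend on it.
#' @return An object of class `graph_hierarchy`: padded permuted `levels`
#'   (list of `pm_graph`, level 1 = original), `parent` maps, per-level
#'   `perm` and `fake_mask`, and the real/padded node counts.
#' @export
coarsen <- function(graph, n_levels = 3L, seed = 0L) {
  stopifnot(inherits(graph, "pm_graph"))
  if (n_levels < 1L) stop("n_levels must be >= 1", call. = FALSE)
  if (graph$n < 1L) stop("cannot coarsen an empty graph", call. = FALSE)

  adjs <- vector("list", n_levels + 1L)
  parents <- vector("list", n_levels)
  adjs[[1L]] <- graph$A
  for (l in seq_len(n_levels)) {
    parents[[l]] <- graclus_matching(adjs[[l]])
    adjs[[l + 1L]] <- coarse_adjacency(adjs[[l]], parents[[l]])
    if (nrow(adjs[[l + 1L]]) < 1L) {
      stop("coarsening produced fewer than one node", call. = FALSE)
    }
  }
  n_real <- vapply(adjs, nrow, integer(1))

  # sibling-contiguous permutations, coarsest to finest, with fake padding
  perms <- vector("list", n_levels + 1L)
  perms[[n_levels + 1L]] <- seq_len(n_real[n_levels + 1L])
  for (l in n_levels:1L) {
    par <- parents[[l]]
    next_fake <- n_real[l]
    perm_new <- integer(2L * length(perms[[l + 1L]]))
    pos <- 0L
    for (j in perms[[l + 1L]]) {
      ch <- which(par == j) # empty when j is itself a fake coarse node
      if (length(ch) == 2L) {
        app <- sort(ch)
      } else if (length(ch) == 1L) {
        next_fake <- next_fake + 1L
        app <- c(ch, next_fake)
      } else {
        app <- next_fake + c(1L, 2L)
        next_fake <- next_fake + 2L
      }
      perm_new[pos + 1:2] <- app
      pos <- pos + 2L
    }
    perms[[l]] <- perm_new
  }
  n_padded <- lengths(perms)
  fake_mask <- lapply(seq_along(perms), function(l) perms[[l]] > n_real[l])

  levels <- lapply(seq_along(adjs), function(l) {
    M <- n_padded[l]
    n <- n_real[l]
    Aext <- if (M > n) {
      Matrix::bdiag(adjs[[l]], Matrix::Matrix(0, M - n, M - n, sparse = TRUE))
    } else {
      adjs[[l]]
    }
    pm_graph(Aext[perms[[l]], perms[[l]], drop = FALSE])
  })

  structure(
    list(
      levels = levels, parent = parents, perm = perms,
      fake_mask = fake_mask, n_real = n_real, n_padded = n_padded,
      n_levels = n_levels
    ),
    class = "graph_hierarchy"
  )
}

#' @export
print.graph_hierarchy <- function(x, ...) {
  cat(sprintf(
    "graph_hierarchy: %d levels, real sizes %s, padded sizes %s\n",
    x$n_levels, paste(x$n_real, collapse = " > "),
    paste(x$n_padded, collapse = " > ")
  ))
  invisible(x)
}

#' Permute raw node signals into the padded pooling order
#'
#' @param X Matrix of samples by node values (B x 460), or a vector.
#' @param hierarchy A [coarsen] result for that graph.
#' @param fill Value placed at fake-node positions (0 for convolution
#'   input).
#' @return Matrix of size `n_padded[1]` x B.
#' @export
perm_input <- function(X, hierarchy, fill = 0) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  perm <- hierarchy$perm[[1L]]
  n <- hierarchy$n_real[1L]
  stopifnot(ncol(X) == n)
  M <- length(perm)
  out <- matrix(fill, M, nrow(X))
  real <- perm <= n
  out[real, ] <- t(X)[perm[real], , drop = FALSE]
  out
}
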