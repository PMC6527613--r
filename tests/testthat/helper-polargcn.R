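# Shared fixtures and independent oracles for the test suite. Everything is
# generated in code; the coarsening hierarchy of the fixed polar graph is
# computed once per session.

.fixtures <- new.env(parent = emptyenv())

polar_hierarchy <- function() {
  if (is.null(.fixtures$hier)) {
    .fixtures$hier <- coarsen(build_polar_adjacency(polar_grid()), n_levels = 3L)
  }
  .fixtures$hier
}

# random connected-ish unit-weight graph (symmetric 0/1, no self loops,
# at least one edge)
random_adjacency <- function(n, p = 0.3) {
  repeat {
    A <- matrix(stats::rbinom(n * n, 1, p), n, n)
    A[lower.tri(A, diag = TRUE)] <- 0
    A <- A + t(A)
    if (sum(A) > 0) {
      return(A)
    }
  }
}

# independent spectral oracle for the Chebyshev filter: evaluates
# U g(lambda) U^T x with T_k(lambda) = cos(k acos(lambda)) per feature pair
cheb_oracle <- function(x, L, lambda_max, params) {
  e <- eigen(as.matrix(L), symmetric = TRUE)
  lt <- pmin(pmax(2 * e$values / lambda_max - 1, -1), 1)
  K <- params$K
  f_in <- dim(params$theta)[2]
  f_out <- dim(params$theta)[3]
  y <- matrix(0, nrow(x), f_out)
  for (fo in seq_len(f_out)) {
    for (fi in seq_len(f_in)) {
      glam <- rowSums(vapply(
        seq_len(K),
        function(k) params$theta[k, fi, fo] * cos((k - 1) * acos(lt)),
        numeric(length(lt))
      ))
      y[, fo] <- y[, fo] + e$vectors %*% (glam * (t(e$vectors) %*% x[, fi]))
    }
  }
  y + rep(params$bias, each = nrow(x))
}

# independent spectral oracle for the Cayley filter:
# g(lambda) = c0 + 2 Re sum_k c_k ((h lambda - i)/(h lambda + i))^k
cayley_oracle <- function(x, L, params) {
  e <- eigen(as.matrix(L), symmetric = TRUE)
  K <- params$K
  f_in <- dim(params$cc)[2]
  f_out <- dim(params$cc)[3]
  r <- ((params$h * e$values - 1i) / (params$h * e$values + 1i))
  y <- matrix(0, nrow(x), f_out)
  for (fo in seq_len(f_out)) {
    for (fi in seq_len(f_in)) {
      glam <- rep(params$c0[fi, fo], length(e$values))
      if (K >= 1) {
        for (k in seq_len(K)) {
          glam <- glam + 2 * Re(params$cc[k, fi, fo] * r^k)
        }
      }
      y[, fo] <- y[, fo] + e$vectors %*% (glam * (t(e$vectors) %*% x[, fi]))
    }
  }
  y + rep(params$bias, each = nrow(x))
}

# small labeled cohort for fast training tests
small_cohort <- function(n_normal = 30, n_abnormal = 30, seed = 11,
                         severity = 0.5) {
  generate_cohort(synthetic_config("rest",
    n_normal = n_normal,
    n_abnormal = n_abnormal, defect_severity = severity, seed = seed
  ))
}

map_labels <- function(maps) vapply(maps, function(m) m$label, character(1))

accuracy_of <- function(model, X, y) {
  mean(predict(model, X, type = "class") == c("normal", "abnormal")[y + 1])
}
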