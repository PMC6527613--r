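test_that("FCN architecture has exactly 212,982 trainable parameters", {
  m <- build_fcn(seed = 0)
  expect_identical(n_params(m), 212982L)
})

test_that("FCN outputs proper softmax probabilities, bias-determined at zero input", {
  m <- build_fcn(seed = 1)
  X <- matrix(runif(5 * 460), 5, 460)
  p <- predict(m, X, type = "prob")
  expect_equal(rowSums(p), rep(1, 5), tolerance = 1e-12)
  expect_true(all(p >= 0 & p <= 1))
  # zero input: hidden layer is relu(b1) regardless of weights, so all rows equal
  p0 <- predict(m, matrix(0, 3, 460), type = "prob")
  expect_equal(p0[1, ], p0[2, ], tolerance = 1e-14)
  expect_equal(p0[1, ], p0[3, ], tolerance = 1e-14)
})

test_that("CNN layer shapes and parameter counts follow from the architecture", {
  m <- build_cnn(seed = 0)
  # conv1: 64 filters of 5x5x1 plus biases
  expect_identical(length(m$params$W1) + length(m$params$b1), 1664L)
  # ceiling-mode 2x2 pooling: 23x20 -> 12x10 -> 6x5
  expect_identical(c(m$shapes$H2, m$shapes$W2), c(12L, 10L))
  expect_identical(c(m$shapes$H3, m$shapes$W3), c(6L, 5L))
  # frozen total from the declared shapes:
  # 1664 + 128*(3*3*64+1) + (6*5*128)*256+256 + 256*2+2
  expect_identical(n_params(m), 1664L + 73856L + 983296L + 514L)
  p <- predict(m, matrix(runif(3 * 460), 3, 460), type = "prob")
  expect_equal(rowSums(p), rep(1, 3), tolerance = 1e-12)
})

test_that("GCNN node counts shrink by the pooling schedule and fakes stay inert", {
  h <- polar_hierarchy()
  m <- build_gcnn("cheb", hierarchy = h, seed = 0)
  n0 <- h$n_padded[1]
  expect_identical(h$n_padded[3], n0 %/% 4L) # after pool 4
  expect_identical(h$n_padded[4], n0 %/% 8L) # after pool 2
  # with all filter coefficients and head weights zero, output depends on
  # biases only: identical for any input
  m$params$theta1[] <- 0
  m$params$theta2[] <- 0
  m$params$W[] <- 0
  p <- predict(m, matrix(runif(2 * 460), 2, 460), type = "prob")
  expect_equal(p[1, ], p[2, ], tolerance = 1e-14)
  expect_equal(as.numeric(p[1, ]), c(0.5, 0.5), tolerance = 1e-14)
})

test_that("GCNN predictions are invariant to consistent node relabeling", {
  h <- polar_hierarchy()
  m <- build_gcnn("cheb", hierarchy = h, seed = 2)
  X <- matrix(runif(2 * 460), 2, 460)
  p0 <- predict(m, X, type = "prob")
  # swap two graph nodes: relabel the input and the hierarchy's level-0 perm
  i <- 17L
  j <- 231L
  m2 <- m
  perm <- m2$hierarchy$perm[[1]]
  perm[perm == i] <- -1L
  perm[perm == j] <- i
  perm[perm == -1L] <- j
  m2$hierarchy$perm[[1]] <- perm
  X2 <- X
  X2[, c(i, j)] <- X[, c(j, i)]
  expect_equal(predict(m2, X2, type = "prob"), p0, tolerance = 1e-12)
})

test_that("Cayley GCNN trains end to end and stays real", {
  h <- polar_hierarchy()
  maps <- small_cohort(20, 20, seed = 21)
  m <- build_gcnn("cayley", hierarchy = h, seed = 0)
  m <- train(m, maps, train_config(learning_rate = 0.05, epochs = 2, seed = 3))
  expect_true(m$trained)
  expect_length(m$loss_trace, 2)
  expect_true(all(is.finite(m$loss_trace)))
  expect_gt(m$params$h1, 0)
  p <- predict(m, maps[1:4], type = "prob")
  expect_true(is.numeric(p) && all(is.finite(p)))
})

test_that("CNN backward pass matches finite differences and training runs", {
  set.seed(77)
  m <- build_cnn(seed = 7)
  X <- matrix(runif(4 * 460), 4, 460)
  y <- c(0L, 1L, 1L, 0L)
  loss_of <- function(model) {
    p <- polargcn:::model_forward(model, X)$probs
    -mean(log(p[cbind(1:4, y + 1)]))
  }
  fw <- polargcn:::model_forward(m, X)
  onehot <- matrix(0, 4, 2)
  onehot[cbind(1:4, y + 1)] <- 1
  g <- polargcn:::model_backward(m, fw$cache, (fw$probs - onehot) / 4)
  base <- loss_of(m)
  eps <- 1e-6
  for (nm in c("W1", "b2", "W3", "W4")) {
    j <- sample(length(m$params[[nm]]), 1)
    m2 <- m
    m2$params[[nm]][j] <- m2$params[[nm]][j] + eps
    expect_equal(g[[nm]][j], (loss_of(m2) - base) / eps, tolerance = 1e-3)
  }
  maps <- small_cohort(10, 10, seed = 26)
  mt <- train(build_cnn(0), maps, train_config(epochs = 3, seed = 1))
  expect_length(mt$loss_trace, 3)
  expect_true(all(is.finite(mt$loss_trace)))
})

test_that("training is deterministic given seeds and rejects degenerate datasets", {
  maps <- small_cohort(15, 15, seed = 22)
  m1 <- train(build_fcn(5), maps, train_config(epochs = 3, seed = 9))
  m2 <- train(build_fcn(5), maps, train_config(epochs = 3, seed = 9))
  expect_identical(m1$loss_trace, m2$loss_trace)
  expect_identical(m1$params, m2$params)
  expect_error(train(build_fcn(0), list(), train_config()), "polar_map|empty|0")
  normals <- Filter(function(m) m$label == "normal", maps)
  expect_error(
    train(build_fcn(0), normals, train_config()),
    "both classes"
  )
})

test_that("training loss decreases and the model can overfit a tiny sample", {
  maps <- small_cohort(10, 10, seed = 23)
  ds <- polarmap_dataset(maps)
  m <- train(
    build_fcn(0), maps,
    train_config(learning_rate = 0.01, batch_size = 10, epochs = 500, seed = 1)
  )
  expect_lt(tail(m$loss_trace, 1), m$loss_trace[1])
  expect_identical(accuracy_of(m, ds$X, ds$y), 1)
})

test_that("evaluation metrics follow their defining formulas", {
  # TP=8 TN=9 FP=1 FN=2
  preds <- c(rep(1, 8), rep(0, 9), 1, 0, 0)
  labs <- c(rep(1, 8), rep(0, 9), 0, 1, 1)
  r <- evaluate(preds, labs)
  expect_equal(r$agreement, 85)
  expect_equal(r$sensitivity, 80)
  expect_equal(r$specificity, 90)
  expect_identical(c(r$tp, r$tn, r$fp, r$fn), c(8L, 9L, 1L, 2L))
  expect_error(evaluate(integer(0), integer(0)), "nonempty")
  expect_error(evaluate(c(1, 0), c(1)), "equal length")
})

test_that("Cohen's kappa matches hand calculations and flags the undefined case", {
  a <- c(1, 0, 1, 0, 1, 1)
  expect_equal(cohen_kappa(a, a), 1)
  # complement with balanced marginals: p_o = 0, p_e = 1/2 -> kappa = -1
  b <- c(0, 0, 1, 1)
  expect_equal(cohen_kappa(b, 1 - b), -1)
  expect_warning(k <- cohen_kappa(c(1, 1, 1), c(1, 1, 1)), "undefined")
  expect_true(is.na(k))
  expect_equal(cohen_kappa(c("normal", "abnormal"), c("normal", "abnormal")), 1)
})

test_that("4-fold cross-validation stratifies, partitions, and pools correctly", {
  maps <- small_cohort(26, 22, seed = 24)
  ds <- polarmap_dataset(maps)
  cv <- crossval_4fold(maps, model_config("fcn", seed = 0),
    train_config(epochs = 2, seed = 1),
    seed = 7
  )
  expect_length(cv$folds, 4)
  # every sample in exactly one test fold
  expect_identical(sort(unique(cv$fold_of)), 1:4)
  expect_identical(length(cv$fold_of), 48L)
  # per-class fold sizes differ by at most one
  for (cls in 0:1) {
    sizes <- table(cv$fold_of[ds$y == cls])
    expect_lte(max(sizes) - min(sizes), 1)
  }
  # pooled agreement equals the sample-weighted mean of fold agreements
  ns <- vapply(cv$folds, `[[`, numeric(1), "n")
  ags <- vapply(cv$folds, `[[`, numeric(1), "agreement")
  expect_equal(cv$mean$agreement, sum(ns * ags) / sum(ns), tolerance = 1e-12)
  expect_identical(cv$mean$n, sum(ns))
  expect_error(
    crossval_4fold(maps[1:6], model_config("fcn"), train_config()),
    "at least 8"
  )
})

test_that("checkpoints round-trip parameters, config and predictions", {
  h <- polar_hierarchy()
  maps <- small_cohort(10, 10, seed = 25)
  for (kind in c("fcn", "gcnn_cayley")) {
    m <- build_model(model_config(kind, seed = 4), hierarchy = h)
    m <- train(m, maps, train_config(epochs = 1, seed = 2))
    path <- withr::local_tempfile(fileext = ".json")
    save_checkpoint(m, path)
    m2 <- load_checkpoint(path, hierarchy = h)
    expect_identical(m2$kind, m$kind)
    expect_true(m2$trained)
    X <- polarmap_dataset(maps)$X
    expect_equal(predict(m2, X), predict(m, X), tolerance = 1e-12)
  }
})
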