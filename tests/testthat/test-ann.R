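separable_data <- function(n = 200L, sep = 3, seed = 17L) {
  set.seed(seed)
  y <- rep(c(0L, 1L), length.out = n)
  X <- matrix(rnorm(n * 4, mean = rep(y * sep, 4)), nrow = n)
  colnames(X) <- c("ed20_mg_kg", "index", "ed20_umol_kg", "level")
  list(X = X, y = y)
}

test_that("constant labels are fit trivially", {
  d <- separable_data(40)
  m <- train_mlp(d$X, rep(1L, 40), n_hidden = 3, split_seed = 1, init_seed = 2)
  expect_equal(m$train_accuracy, 1)
  expect_equal(m$test_accuracy, 1)
})

test_that("well-separated classes are learnt by every activation pairing", {
  d <- separable_data(200, sep = 3)
  grid <- expand.grid(h = c("Logistic", "Tanh", "Sine"),
                      o = c("Softmax", "Logistic", "Identity"),
                      stringsAsFactors = FALSE)
  for (r in seq_len(nrow(grid))) {
    m <- train_mlp(d$X, d$y, n_hidden = 5, hidden_activation = grid$h[r],
                   output_activation = grid$o[r], split_seed = 7, init_seed = 8)
    expect_gte(m$test_accuracy, 0.95)
  }
})

test_that("training is deterministic given its seeds", {
  d <- separable_data(60)
  m1 <- train_mlp(d$X, d$y, n_hidden = 4, split_seed = 3, init_seed = 9)
  m2 <- train_mlp(d$X, d$y, n_hidden = 4, split_seed = 3, init_seed = 9)
  expect_identical(m1$par, m2$par)
  expect_identical(m1$idx_train, m2$idx_train)
})

test_that("the stratified split respects the train fraction and classes", {
  d <- separable_data(100)
  m <- train_mlp(d$X, d$y, split_seed = 5, init_seed = 6)
  expect_length(m$idx_train, 80L)
  expect_length(m$idx_test, 20L)
  expect_setequal(unique(d$y[m$idx_train]), c(0L, 1L))
  expect_setequal(unique(d$y[m$idx_test]), c(0L, 1L))
  expect_length(intersect(m$idx_train, m$idx_test), 0L)
})

test_that("softmax outputs form a probability simplex", {
  d <- separable_data(60)
  m <- train_mlp(d$X, d$y, output_activation = "Softmax", split_seed = 2, init_seed = 4)
  p <- predict(m, d$X, type = "prob")
  expect_equal(rowSums(p), rep(1, 60), tolerance = 1e-12)
  expect_true(all(p >= 0))
  expect_error(predict(m, d$X[, 1:3]), "expects")
})

test_that("the forward pass reproduces a hand-computed network", {
  # 4-2-2 identity/identity network with fixed weights, no standardization
  W1 <- matrix(c(1, 0, 0, 0,
                 0, 1, 1, 0), nrow = 4)   # h1 = x1, h2 = x2 + x3
  b1 <- c(0.5, -0.5)
  W2 <- matrix(c(1, 0,
                 0, 2), nrow = 2, byrow = TRUE)  # o1 = h1, o2 = 2*h2
  b2 <- c(0, 1)
  model <- structure(
    list(dim_in = 4L, n_hidden = 2L, dim_out = 2L,
         hidden_activation = "Identity", output_activation = "Identity",
         par = c(W1, b1, W2, b2), mu = rep(0, 4), sd = rep(1, 4),
         classes = c(0L, 1L)),
    class = "iopqsar_mlp"
  )
  x <- matrix(c(2, 3, 4, 5), nrow = 1)
  # h = (2 + 0.5, 3 + 4 - 0.5) = (2.5, 6.5); o = (2.5, 2*6.5 + 1) = (2.5, 14)
  expect_equal(unname(predict(model, x, type = "prob")), matrix(c(2.5, 14), nrow = 1))
  expect_equal(predict(model, x, type = "class"), 1L)
})

test_that("a serialized model reproduces its forward pass bit for bit", {
  d <- separable_data(80)
  m <- train_mlp(d$X, d$y, n_hidden = 6, hidden_activation = "Exponential",
                 split_seed = 11, init_seed = 12)
  path <- withr::local_tempfile(fileext = ".json")
  write_mlp_json(m, path)
  m2 <- read_mlp_json(path)
  expect_identical(predict(m2, d$X, type = "prob"), predict(m, d$X, type = "prob"))
  expect_identical(m2$par, m$par)
})

test_that("ensemble ranking equals a brute-force sort and is reproducible", {
  d <- separable_data(60)
  ens <- run_ensemble(d$X, d$y, n_networks = 30L, n_retain = 10L, master_seed = 99)
  s <- ens$summary
  ok <- which(!is.na(s$test_accuracy))
  brute <- ok[order(-s$test_accuracy[ok], -s$train_accuracy[ok], s$n_hidden[ok], ok)]
  expect_equal(ens$retained, brute[1:10])
  expect_equal(ens$best_index, brute[1])
  expect_equal(s$rank[brute], seq_along(brute))

  ens2 <- run_ensemble(d$X, d$y, n_networks = 30L, n_retain = 10L, master_seed = 99)
  expect_identical(ens$summary, ens2$summary)
  expect_identical(ens$best_model$par, ens2$best_model$par)

  ens3 <- run_ensemble(d$X, d$y, n_networks = 30L, n_retain = 10L, master_seed = 100)
  expect_false(identical(ens$summary$split_seed, ens3$summary$split_seed))
})

test_that("ensemble configurations stay inside the requested protocol", {
  d <- separable_data(50)
  ens <- run_ensemble(d$X, d$y, n_networks = 25L, n_retain = 5L,
                      hidden_range = c(3L, 10L), master_seed = 7)
  expect_true(all(ens$summary$n_hidden >= 3L & ens$summary$n_hidden <= 10L))
  expect_true(all(ens$summary$hidden_activation %in%
                    c("Identity", "Logistic", "Tanh", "Exponential", "Sine")))
  expect_true(all(ens$summary$output_activation %in%
                    c("Identity", "Logistic", "Tanh", "Exponential", "Sine", "Softmax")))
  expect_true(all(ens$summary$test_accuracy >= 0 & ens$summary$test_accuracy <= 1,
                  na.rm = TRUE))
  # Softmax never appears as a hidden activation
  expect_error(train_mlp(d$X, d$y, hidden_activation = "Softmax",
                         split_seed = 1, init_seed = 1), "hidden activation")
})
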