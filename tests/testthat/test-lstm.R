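test_that("zero parameters give the closed-form cell outputs", {
  p <- zero_lstm_params(2, 3)
  # zero state in, zero state out (sigmoid(0)=0.5 gates a zero candidate)
  st <- lstm_cell_forward(c(0, 0), NULL, p)
  expect_equal(st$h, rep(0, 3))
  expect_equal(st$c, rep(0, 3))
  # scalar cell with c = 1: c' = 0.5, h' = 0.5 * tanh(0.5)
  p1 <- zero_lstm_params(1, 1)
  st1 <- lstm_cell_forward(0, list(h = 0, c = 1), p1)
  expect_equal(st1$c, 0.5)
  expect_equal(st1$h, 0.5 * tanh(0.5))
})

test_that("saturated gates implement a perfect memory carry", {
  p <- zero_lstm_params(1, 2)
  p$b_f[] <- 50    # f -> 1
  p$b_i[] <- -50   # i -> 0
  st <- lstm_cell_forward(0.3, list(h = c(0.1, -0.2), c = c(0.7, -1.4)), p)
  expect_equal(st$c, c(0.7, -1.4), tolerance = 1e-12)
})

test_that("gate activations stay inside their ranges on random instances", {
  set.seed(31)
  for (k in 1:50) {
    p <- random_lstm_params(3, 4)
    st <- lstm_cell_forward(rnorm(3, sd = 3),
                            list(h = rnorm(4), c = rnorm(4, sd = 2)), p)
    g <- st$gates
    expect_true(all(g$f > 0 & g$f < 1))
    expect_true(all(g$i > 0 & g$i < 1))
    expect_true(all(g$o > 0 & g$o < 1))
    expect_true(all(g$g > -1 & g$g < 1))
    expect_true(all(abs(st$h) < 1))
  }
})

test_that("cell forward matches the scalar-loop oracle to 1e-10", {
  set.seed(17)
  for (k in 1:100) {
    ins <- sample(1:5, 1); hid <- sample(1:5, 1)
    p <- random_lstm_params(ins, hid)
    x <- rnorm(ins); h <- rnorm(hid); c <- rnorm(hid)
    got <- lstm_cell_forward(x, list(h = h, c = c), p)
    want <- scalar_lstm_cell(x, h, c, p)
    expect_equal(got$h, want$h, tolerance = 1e-10)
    expect_equal(got$c, want$c, tolerance = 1e-10)
  }
})

test_that("sequence forward is the left fold of the cell", {
  set.seed(23)
  p <- random_lstm_params(2, 3)
  xs <- lapply(1:3, function(i) rnorm(2))
  # base case: length-1 sequence == one cell call
  s1 <- sequence_forward(xs[1], p)
  c1 <- lstm_cell_forward(xs[[1]], NULL, p)
  expect_equal(s1$h, c1$h); expect_equal(s1$c, c1$c)
  # 3-step sequence == three chained manual calls
  manual <- NULL
  for (x in xs) manual <- lstm_cell_forward(x, manual, p)
  folded <- sequence_forward(xs, p)
  expect_equal(folded$h, manual$h, tolerance = 1e-12)
  expect_equal(folded$c, manual$c, tolerance = 1e-12)
  # all-zero inputs with zero params stay at zero
  pz <- zero_lstm_params(2, 3)
  sz <- sequence_forward(lapply(1:4, function(i) c(0, 0)), pz)
  expect_equal(sz$h, rep(0, 3))
  expect_error(sequence_forward(list(), p), "non-empty")
})

test_that("the literal-output variant adds the gate instead of multiplying", {
  p <- zero_lstm_params(1, 1)
  st <- lstm_cell_forward(0, list(h = 0, c = 1), p, paper_literal = TRUE)
  expect_equal(st$h, tanh(0.5) + 0.5)  # unbounded form: tanh(C) + O
})

test_that("analytic training gradients match finite differences", {
  set.seed(41)
  n <- 6; p_feat <- 4; hid <- 3; chunk <- 2
  x <- matrix(rnorm(n * p_feat), n, p_feat)
  y <- rep(0:1, 3)
  params <- texhawk:::with_seed(1, random_lstm_params(chunk, hid))
  w_out <- rnorm(hid, sd = 0.3); b_out <- 0.1
  xs <- texhawk:::chunk_sequence(x, chunk)
  loss_of <- function(params, w_out, b_out) {
    fw <- texhawk:::lstm_forward_cached(xs, params)
    pr <- 1 / (1 + exp(-(drop(fw$h %*% w_out) + b_out)))
    -mean(y * log(pr) + (1 - y) * log(1 - pr))
  }
  fw <- texhawk:::lstm_forward_cached(xs, params)
  pr <- 1 / (1 + exp(-(drop(fw$h %*% w_out) + b_out)))
  dz <- (pr - y) / n
  G <- texhawk:::lstm_backward(fw$cache, params, outer(dz, w_out))
  eps <- 1e-6
  for (nm in c("W_f", "U_i", "b_o", "W_c", "U_c")) {
    idx <- if (is.matrix(params[[nm]])) c(1, 1) else 1
    bumped <- params
    if (is.matrix(params[[nm]])) {
      bumped[[nm]][idx[1], idx[2]] <- bumped[[nm]][idx[1], idx[2]] + eps
      want <- (loss_of(bumped, w_out, b_out) - loss_of(params, w_out, b_out)) / eps
      expect_equal(G[[nm]][idx[1], idx[2]], want, tolerance = 1e-4,
                   label = paste("grad", nm))
    } else {
      bumped[[nm]][idx] <- bumped[[nm]][idx] + eps
      want <- (loss_of(bumped, w_out, b_out) - loss_of(params, w_out, b_out)) / eps
      expect_equal(G[[nm]][idx], want, tolerance = 1e-4,
                   label = paste("grad", nm))
    }
  }
})

test_that("training separates a separable fixture and is seed-deterministic", {
  fx <- separable_fixture(n = 200, gap = 2, seed = 3)
  cfg <- classifier_config(hidden_size = 8, chunk_len = 2, epochs = 100,
                           lr = 0.3, seed = 1)
  m <- train_classifier(fx$x, fx$y, cfg)
  expect_gte(mean(predict(m, fx$x)$label == fx$y), 0.95)
  expect_lt(m$loss_history[100], m$loss_history[1])   # loss decreased
  m2 <- train_classifier(fx$x, fx$y, cfg)
  expect_identical(m$params, m2$params)               # identical final weights
  expect_identical(m$readout, m2$readout)
})

test_that("shuffled labels give chance-level holdout accuracy", {
  fx <- separable_fixture(n = 200, gap = 2, seed = 3)
  set.seed(4)
  ysh <- sample(fx$y)
  cfg <- classifier_config(hidden_size = 8, chunk_len = 2, epochs = 100,
                           lr = 0.3, seed = 1)
  m <- train_classifier(fx$x[1:140, ], ysh[1:140], cfg)
  acc <- mean(predict(m, fx$x[141:200, ])$label == ysh[141:200])
  expect_gte(acc, 0.3); expect_lte(acc, 0.7)
})

test_that("prediction obeys the >= 0.5 tie rule and batching invariance", {
  fx <- separable_fixture(n = 60, gap = 3, seed = 5)
  m <- train_classifier(fx$x, fx$y,
                        classifier_config(hidden_size = 4, chunk_len = 2,
                                          epochs = 60, lr = 0.3, seed = 2))
  batch <- predict(m, fx$x)
  expect_true(all(batch$probability >= 0 & batch$probability <= 1))
  expect_identical(batch$label, as.integer(batch$probability >= 0.5))
  single <- vapply(seq_len(10), function(i) {
    predict(m, fx$x[i, , drop = FALSE])$probability
  }, numeric(1))
  expect_equal(single, batch$probability[1:10], tolerance = 1e-12)
  # memorized tiny set: training points classified correctly
  expect_gte(mean(batch$label == fx$y), 0.95)
  expect_error(predict(m, fx$x[, 1, drop = FALSE]), "feature count")
})

test_that("models round-trip through the flat text serialization", {
  fx <- separable_fixture(n = 40, gap = 2, seed = 6)
  m <- train_classifier(fx$x, fx$y,
                        classifier_config(hidden_size = 3, chunk_len = 2,
                                          epochs = 20, lr = 0.2, seed = 3))
  path <- withr::local_tempfile(fileext = ".json")
  save_classifier(m, path)
  back <- load_classifier(path)
  expect_equal(predict(back, fx$x)$probability, predict(m, fx$x)$probability,
               tolerance = 1e-12)
})
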