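tiny_cfg <- function() cnn_config(1, input_rows = 5, n_samples = 8L,
                                  kernel = c(3L, 3L), n_filters = 2L,
                                  n_conv_layers = 3L, skip_period = 2L)

test_that("network shapes and parameter counts", {
  # device configs: input shape = output shape = (2m - 1) x 1792
  for (d in 1:3) {
    rows <- c(27L, 45L, 75L)[d]
    cfg <- cnn_config(d, input_rows = rows)
    expect_identical(cfg$input_rows, rows)
    expect_identical(cfg$n_samples, 1792L)
    expect_identical(cfg$kernel, c(7L, 77L))
    expect_identical(cfg$n_filters, 64L)
  }
  # parameter count oracle: sum over layers of kh*kw*cin*cout + cout
  cfg <- tiny_cfg()
  expected <- (3 * 3 * 1 * 2 + 2) + (3 * 3 * 2 * 2 + 2) + (3 * 3 * 2 * 1 + 1)
  expect_identical(cnn_n_params(cfg), as.numeric(expected))
  expect_length(build_cnn(cfg)$par, expected)
  expect_error(cnn_config(1, 9, kernel = c(4L, 7L)), "odd")
})

test_that("zero-initialized output layer with identity skip reproduces input", {
  cfg <- cnn_config(1, input_rows = 9, n_samples = 40L, kernel = c(3L, 7L),
                    n_filters = 4L, n_conv_layers = 4L)
  m <- build_cnn(cfg, seed = 5)
  x <- hemipa:::with_seed(1, matrix(rnorm(9 * 40), 9, 40))
  expect_identical(cnn_forward(m, x), x)
  # deterministic inference: two forward passes are bit-identical
  m$par <- m$par + hemipa:::with_seed(2, rnorm(length(m$par), sd = 0.05))
  expect_identical(cnn_forward(m, x), cnn_forward(m, x))
  # batch forward preserves shape
  xb <- array(rnorm(3 * 9 * 40), c(3, 9, 40))
  expect_identical(dim(cnn_forward(m, xb)), c(3L, 9L, 40L))
})

test_that("analytic gradients match central finite differences", {
  cfg <- tiny_cfg()
  m <- build_cnn(cfg, seed = 7)
  par <- m$par + hemipa:::with_seed(3, rnorm(length(m$par), sd = 0.1))
  a <- hemipa:::cfg_args(cfg)
  x <- hemipa:::with_seed(4, array(rnorm(2 * 5 * 8), c(2, 5, 8)))
  y <- hemipa:::with_seed(5, array(rnorm(2 * 5 * 8), c(2, 5, 8)))
  lg <- hemipa:::cnn_loss_grad_cpp(par, as.numeric(x), as.numeric(y), 2,
                                   a$H, a$W, a$kh, a$kw, a$F, a$L, a$skip)
  loss_at <- function(p)
    hemipa:::cnn_loss_grad_cpp(p, as.numeric(x), as.numeric(y), 2,
                               a$H, a$W, a$kh, a$kw, a$F, a$L, a$skip)$loss
  eps <- 1e-6
  num <- vapply(seq_along(par), function(i) {
    p1 <- par; p2 <- par
    p1[i] <- p1[i] + eps; p2[i] <- p2[i] - eps
    (loss_at(p1) - loss_at(p2)) / (2 * eps)
  }, numeric(1))
  expect_lt(max(abs(lg$grad - num)), 1e-7)
})

test_that("the network can overfit a single sample (capacity sanity)", {
  cfg <- cnn_config(1, input_rows = 9, n_samples = 64L, kernel = c(3L, 9L),
                    n_filters = 8L, n_conv_layers = 3L)
  x <- hemipa:::with_seed(6, array(rnorm(9 * 64, sd = 0.5), c(1, 9, 64)))
  # target: a smooth linear map of the input (time smoothing + rescaling),
  # well inside the model's capacity
  sm <- x
  for (j in 2:63) sm[1, , j] <- (x[1, , j - 1] + x[1, , j] + x[1, , j + 1]) / 3
  y <- 0.6 * sm
  ts <- structure(list(inputs = x, targets = y, normalization = 1,
                       direction = 1L, phantom_of = 1L),
                  class = "training_set")
  m <- build_cnn(cfg, seed = 2)
  tc <- train_config(learning_rate = 3e-4, epochs = 400L, batch_size = 1L,
                     seed = 9, scale = "reduced")
  trained <- train_cnn(m, ts, tc)
  expect_lt(tail(trained$loss_history, 1), 0.01 * trained$loss_history[1])

  # determinism: same seed and data reproduce the loss trace exactly
  trained2 <- train_cnn(m, ts, tc)
  expect_identical(trained$loss_history, trained2$loss_history)
  expect_identical(trained$par, trained2$par)
})

test_that("training sets have the documented composition", {
  geo <- toy_geo()
  tm <- toy_time()
  # n_phantoms x chains_per_direction samples (8 chains at interval 8)
  ts <- make_training_set(2, 1, geo, tm, sensor_response(), snr_db = 30,
                          seed = 21, spec = toy_phantom_spec())
  expect_identical(dim(ts$inputs), c(16L, 9L, 256L))
  expect_identical(dim(ts$targets), dim(ts$inputs))
  expect_identical(ts$phantom_of, rep(1:2, each = 8L))

  # target real rows are the noise-free simulation; input real rows carry
  # calibrated noise on top of them
  real_rows <- seq(1, 9, 2)
  diffs <- (ts$inputs[1, real_rows, ] - ts$targets[1, real_rows, ]) *
    ts$normalization
  ref <- reference_amplitude(sensor_response(), tm, R = 20)
  expect_equal(sd(diffs), ref * 10^(-30 / 20), tolerance = 0.1)
  # virtual target rows differ from the linear input rows (they are the
  # simulated truth, not an average)
  virt <- seq(2, 8, 2)
  expect_gt(mean(abs(ts$inputs[1, virt, ] - ts$targets[1, virt, ])), 0)
})

test_that("prediction validates shapes and de-normalizes", {
  cfg <- cnn_config(2, input_rows = 9, n_samples = 64L, kernel = c(3L, 9L),
                    n_filters = 2L, n_conv_layers = 3L)
  m <- build_cnn(cfg, seed = 1)
  m$normalization <- 2.5
  ip <- structure(list(values = matrix(rnorm(9 * 64), 9, 64),
                       chain_ref = c(direction = 2, residue = 1),
                       row_kind = "interleaved"),
                  class = "interleaved_pattern")
  out <- cnn_predict(m, ip)
  # zero output layer + identity skip + de-normalization: exact round trip
  expect_equal(out$values, ip$values, tolerance = 1e-12)

  zero <- ip; zero$values <- matrix(0, 9, 64)
  expect_true(all(is.finite(cnn_predict(m, zero)$values)))

  wrong <- ip; wrong$values <- matrix(0, 7, 64)
  expect_error(cnn_predict(m, wrong), "does not match model")
})
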