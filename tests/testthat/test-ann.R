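test_that("forward pass matches the composed layer equations", {
  arch <- network_arch(n_inputs = 2, n_hidden = 3, output_activation = "logistic")
  zero <- unflatten_params(rep(0, 13), arch)
  # all-zero weights with a logistic output give 0.5 everywhere
  expect_equal(forward(zero, c(4, -7)), 0.5)
  expect_equal(forward(zero, matrix(rnorm(10), ncol = 2)), rep(0.5, 5))

  # 1 input, 1 hidden tanh node, linear output, x = 0 -> s = 0
  a1 <- network_arch(1, 1, hidden_activation = "tanh",
                     output_activation = "linear")
  p1 <- network_params(0, matrix(1), 0, 1, a1)
  expect_equal(forward(p1, 0), 0)
  expect_equal(forward(p1, 1), tanh(1))

  expect_error(forward(zero, c(1, 2, 3)), class = "graftann_config_error")
})

test_that("linear activations collapse to the composed affine map", {
  withr::with_seed(77, {
    for (case in 1:100) {
      p <- sample(1:5, 1)
      nh <- sample(1:4, 1)
      arch <- network_arch(p, nh, hidden_activation = "linear",
                          output_activation = "linear")
      v <- rnorm(nh * (p + 2) + 1)
      params <- unflatten_params(v, arch)
      x <- rnorm(p)
      # s = (a + b'm) + (b' Mu) x
      expected <- params$output_bias +
        sum(params$output_weights * params$hidden_intercepts) +
        as.numeric((params$output_weights %*% params$hidden_weights) %*% x)
      expect_equal(forward(params, x), expected, tolerance = 1e-12)
    }
  })
})

test_that("parameter flattening is a documented exact round trip", {
  arch <- network_arch(2, 3)
  expect_equal(3 * (2 + 2) + 1, 13)
  v <- rnorm(13)
  params <- unflatten_params(v, arch)
  expect_identical(flatten_params(params), v)

  zero <- unflatten_params(rep(0, 13), arch)
  expect_true(all(flatten_params(zero) == 0))
  expect_error(unflatten_params(rep(0, 12), arch),
               class = "graftann_config_error")
})

test_that("the ABO-trained network separates two clusters", {
  d <- two_clusters(n = 200, gap = 2, seed = 1)
  fit <- train_with_abo(d[c("x1", "x2")], d$y,
                        abo = abo_config(n_buffalo = 20, max_iterations = 100,
                                         seed = 1))
  expect_gte(fit$train_accuracy, 0.95)
  # optimizer bookkeeping: the returned objective is the best seen
  expect_true(all(diff(fit$history) <= 0))
  expect_equal(fit$objective_value, min(fit$history))
  expect_lte(fit$objective_value, fit$history[1])
})

test_that("training refuses single-class labels and non-binary labels", {
  d <- data.frame(x = rnorm(10))
  expect_error(train_with_abo(d, rep(1, 10)), class = "graftann_data_error")
  expect_error(train_with_abo(d, c(rep(1, 5), rep(2, 5))),
               class = "graftann_data_error")
})

test_that("label flipping leaves accuracy statistically unchanged", {
  d <- two_clusters(n = 120, gap = 2.5, seed = 4)
  cfg <- abo_config(n_buffalo = 15, max_iterations = 80, seed = 9)
  fit <- train_with_abo(d[c("x1", "x2")], d$y, abo = cfg)
  flip <- train_with_abo(d[c("x1", "x2")], 1L - d$y, abo = cfg)
  expect_gte(fit$train_accuracy, 0.9)
  expect_gte(flip$train_accuracy, 0.9)
  expect_lt(abs(fit$train_accuracy - flip$train_accuracy), 0.1)
})

test_that("prediction semantics follow the cutoff conventions", {
  arch <- network_arch(1, 3)
  d <- data.frame(x = c(rep(0, 10), rep(1, 10)))
  fit <- train_with_abo(d, rep(0:1, each = 10),
                        abo = abo_config(max_iterations = 30, seed = 2))
  prob <- predict(fit, d, type = "prob")
  expect_true(all(prob >= 0 & prob <= 1))
  # raising the cutoff never adds positives
  n_pos <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9),
                  function(ct) sum(predict(fit, d, type = "class", cutoff = ct)),
                  numeric(1))
  expect_true(all(diff(n_pos) <= 0))

  # boundary s == cutoff classifies positive: an all-zero logistic net
  # outputs exactly 0.5
  zero_fit <- fit
  zero_fit$params <- unflatten_params(rep(0, length(flatten_params(fit$params))),
                                      fit$arch)
  expect_equal(unique(predict(zero_fit, d, type = "class", cutoff = 0.5)), 1L)

  # a linear output has no probability semantics
  lin <- train_with_abo(d, rep(0:1, each = 10),
                        arch = network_arch(1, 3, output_activation = "linear"),
                        abo = abo_config(max_iterations = 10, seed = 2))
  expect_error(predict(lin, d, type = "prob"), class = "graftann_config_error")
})

test_that("standardization and encoding come from training rows only", {
  train <- data.frame(num = c(1, 2, 3, 4), cat = c("a", "a", "b", "b"))
  fit <- train_with_abo(train, c(0, 0, 1, 1),
                        abo = abo_config(max_iterations = 5, seed = 1))
  enc <- fit$encoder
  expect_equal(unname(enc$center[["num"]]), 2.5)
  expect_equal(unname(enc$center[["cat=a"]]), 0.5)
  # the same statistics are reused verbatim on new data
  new <- data.frame(num = c(100, 200), cat = c("b", "a"))
  X <- graftann:::encode_features(new, enc)$X
  expect_equal(unname(X[, "num"]), (c(100, 200) - 2.5) / enc$scale[["num"]])
  # unseen columns are an error
  expect_error(predict(fit, data.frame(num = 1), type = "prob"),
               class = "graftann_data_error")
})

test_that("last-layer training freezes the hidden layer", {
  d <- two_clusters(n = 100, gap = 2, seed = 6)
  f1 <- train_with_abo(d[c("x1", "x2")], d$y, scope = "last_layer",
                       abo = abo_config(max_iterations = 40, seed = 3))
  f2 <- train_with_abo(d[c("x1", "x2")], d$y, scope = "last_layer",
                       abo = abo_config(max_iterations = 40, seed = 3))
  expect_identical(f1$params$hidden_weights, f2$params$hidden_weights)
  expect_gte(f1$train_accuracy, 0.8)
})

test_that("network parameters serialize to text and back exactly", {
  arch <- network_arch(3, 4, hidden_activation = "logistic")
  params <- unflatten_params(rnorm(4 * 5 + 1), arch)
  path <- withr::local_tempfile(fileext = ".csv")
  write_network_params(params, path)
  back <- read_network_params(path)
  expect_equal(back$arch, params$arch)
  expect_equal(flatten_params(back), flatten_params(params))
})

test_that("tidy and glance summarise a fit", {
  d <- two_clusters(n = 60, gap = 2, seed = 8)
  fit <- train_with_abo(d[c("x1", "x2")], d$y,
                        abo = abo_config(max_iterations = 20, seed = 4))
  td <- tidy(fit)
  expect_equal(nrow(td), length(flatten_params(fit$params)))
  g <- glance(fit)
  expect_equal(g$n_params, nrow(td))
  expect_equal(g$train_accuracy, fit$train_accuracy)
  expect_s3_class(autoplot(fit), "ggplot")
})
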