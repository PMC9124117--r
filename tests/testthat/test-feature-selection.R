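test_that("ig_filter keeps exactly the strictly informative features", {
  labels <- rep(c(0, 1), each = 10)
  d <- data.frame(flat = rep(1, 20), perfect = labels)
  mask <- ig_filter(d, labels, threshold = 0)
  expect_equal(mask$selected, c(FALSE, TRUE))
  expect_equal(mask$provenance, rep("ig_filter", 2))

  # threshold zero keeps the strictly-positive-gain set
  withr::with_seed(5, {
    d2 <- data.frame(a = rnorm(40), b = sample(c("x", "y"), 40, TRUE),
                     c = rep(2, 40))
    y2 <- sample(0:1, 40, TRUE)
    mask2 <- ig_filter(d2, y2, threshold = 0)
    gains <- vapply(d2, information_gain, numeric(1), labels = y2)
    expect_equal(mask2$selected, unname(gains > 0))
  })

  # nothing passes: repaired to the single top-ranked feature
  d3 <- data.frame(u = rep(1, 10), v = rep(2, 10))
  mask3 <- ig_filter(d3, rep(0:1, 5))
  expect_equal(sum(mask3$selected), 1L)
  expect_error(ig_filter(d3, rep(0:1, 5), threshold = -1),
               class = "graftann_config_error")
})

test_that("the wrapper recovers the exhaustive optimum on a two-feature space", {
  # 3 non-empty subsets: the ABO search must find the best of them, and its
  # result can never score worse than the incoming full mask on the same split
  ctrl <- selection_control(abo = abo_config(n_buffalo = 8, max_iterations = 12))
  for (s in 1:5) {
    withr::with_seed(100 + s, {
      n <- 80
      y <- rep(0:1, each = n / 2)
      d <- data.frame(signal = y * 1.6 + rnorm(n), noise = rnorm(n))
    })
    mask <- abo_wrapper_select(d, y, control = ctrl, seed = s)
    split <- graftann:::internal_split(
      y, 0.2, graftann:::derive_seed(s, "internal_split"))
    accs <- vapply(list("signal", "noise", c("signal", "noise")),
                   function(cols) graftann:::subset_accuracy(d, y, cols, split,
                                                             "logistic"),
                   numeric(1))
    full_fitness <- 1 - accs[3]
    expect_equal(attr(mask, "fitness"), 1 - max(accs))
    expect_lte(attr(mask, "fitness"), full_fitness)
    expect_true("signal" %in% selected_features(mask))
  }
})

test_that("a single-feature mask passes through the wrapper unchanged", {
  d <- data.frame(only = rnorm(30))
  y <- rep(0:1, 15)
  m_in <- feature_mask("only", TRUE)
  m_out <- abo_wrapper_select(d, y, m_in, selection_control(), seed = 1)
  expect_equal(selected_features(m_out), "only")
  expect_equal(m_out$provenance, "abo_wrapper")
})

test_that("backward elimination drops a feature that hurts validation accuracy", {
  n <- 60
  seed <- 3
  withr::with_seed(41, {
    x1 <- rnorm(n)
    y <- as.integer(x1 + rnorm(n, sd = 0.4) > 0)
  })
  # plant a saboteur: aligned with the label on the fit rows (so the
  # classifier leans on it) and reversed on the validation rows
  split <- graftann:::internal_split(
    y, 0.2, graftann:::derive_seed(seed, "internal_split"))
  saboteur <- numeric(n)
  saboteur[split$fit] <- ifelse(y[split$fit] == 1, 2, -2)
  saboteur[split$val] <- ifelse(y[split$val] == 1, -2, 2)
  d <- data.frame(x1 = x1, saboteur = saboteur)

  mask <- backward_eliminate(d, y, control = selection_control(), seed = seed)
  expect_equal(selected_features(mask), "x1")
  expect_gt(attr(mask, "final_accuracy"), attr(mask, "initial_accuracy"))
  log <- attr(mask, "elimination_log")
  expect_true(log$dropped[log$feature == "saboteur"][1])
})

test_that("elimination keeps necessary features and keeps ties conservatively", {
  withr::with_seed(42, {
    n <- 120
    x1 <- rnorm(n)
    x2 <- rnorm(n)
    y <- as.integer(x1 + x2 + rnorm(n, sd = 0.3) > 0)
    d <- data.frame(x1 = x1, x2 = x2)
  })
  mask <- backward_eliminate(d, y, control = selection_control(), seed = 1)
  expect_setequal(selected_features(mask), c("x1", "x2"))

  # a constant column never changes the classifier, so its removal ties and
  # the conservative rule keeps it
  d2 <- data.frame(perfect = y, flat = rep(1, n))
  mask2 <- backward_eliminate(d2, y, control = selection_control(), seed = 1)
  expect_setequal(selected_features(mask2), c("perfect", "flat"))
  expect_equal(attr(mask2, "final_accuracy"), attr(mask2, "initial_accuracy"))
})

test_that("elimination never decreases internal validation accuracy", {
  for (s in 1:6) {
    withr::with_seed(300 + s, {
      n <- 80
      p <- 6
      X <- as.data.frame(matrix(rnorm(n * p), n, p))
      y <- as.integer(X[[1]] - X[[2]] + rnorm(n, sd = 0.8) > 0)
    })
    mask <- backward_eliminate(X, y, control = selection_control(), seed = s)
    expect_gte(attr(mask, "final_accuracy"), attr(mask, "initial_accuracy"))
  }
})

test_that("hybrid selection composes, shrinks and can be disabled", {
  withr::with_seed(50, {
    n <- 300
    y <- rep(0:1, each = n / 2)
    d <- data.frame(s1 = y * 1.5 + rnorm(n), s2 = -y + rnorm(n),
                    n1 = rnorm(n), n2 = rnorm(n),
                    n3 = sample(c("a", "b"), n, TRUE))
  })
  off <- selection_control(use_ig = FALSE, use_wrapper = FALSE,
                           use_elimination = FALSE)
  full <- hybrid_select(d, y, off, seed = 1)
  expect_true(all(full$selected))
  expect_equal(full$provenance, rep("full", 5))

  ctrl <- selection_control(abo = abo_config(n_buffalo = 8, max_iterations = 10))
  mask <- hybrid_select(d, y, ctrl, seed = 1)
  stages <- attr(mask, "stages")
  expect_true(all(c("s1", "s2") %in% selected_features(mask)))
  # stages only remove or keep: the final mask nests inside the filter mask
  expect_true(all(mask$selected <= stages$ig_filter$selected))
  expect_lte(sum(mask$selected), sum(stages$ig_filter$selected))
})

test_that("feature masks refuse to be empty", {
  expect_error(feature_mask(c("a", "b"), c(FALSE, FALSE)),
               class = "graftann_config_error")
})
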