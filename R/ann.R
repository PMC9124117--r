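#' Architecture of the single-hidden-layer perceptron
#'
#' The network is the classical multilayer feed-forward perceptron with one
#' hidden layer: hidden node `n` computes
#' `t_n = f(m_n + sum_p mu_np * l_p)` over the covariates `l_p`, and the
#' output is `s = g(a + sum_n b_n * t_n)`, where `f` and `g` are the hidden
#' and output activations. Hyperbolic tangent, logistic or linear
#' activations are supported; a logistic output gives `s` probability
#' semantics.
#'
#' @param n_inputs Number of covariates after encoding.
#' @param n_hidden Hidden-layer size; default `max(3, ceiling(sqrt(n_inputs)))`.
#' @param hidden_activation One of `"tanh"` (default), `"logistic"`,
#'   `"linear"`.
#' @param output_activation One of `"logistic"` (default) or `"linear"`.
#' @return An object of class `network_arch`.
#' @export
network_arch <- function(n_inputs, n_hidden = NULL,
                         hidden_activation = c("tanh", "logistic", "linear"),
                         output_activation = c("logistic", "linear")) {
  assert_scalar_number(n_inputs, "n_inputs", min = 1)
  if (is.null(n_hidden)) n_hidden <- max(3, ceiling(sqrt(n_inputs)))
  assert_scalar_number(n_hidden, "n_hidden", min = 1)
  structure(
    list(n_inputs = as.integer(n_inputs), n_hidden = as.integer(n_hidden),
         hidden_activation = match.arg(hidden_activation),
         output_activation = match.arg(output_activation)),
    class = "network_arch"
  )
}

activation_fn <- function(name) {
  switch(name,
         tanh = tanh,
         logistic = plogis,
         linear = identity,
         abort(paste0("Unknown activation: ", name),
               class = "graftann_config_error"))
}

#' Network parameters and their flat-vector encoding
#'
#' `network_params()` bundles hidden intercepts, hidden weights, output bias
#' and output weights with an architecture. `flatten_params()` /
#' `unflatten_params()` convert to and from the flat numeric vector searched
#' by the optimizer, in the documented order: hidden intercepts
#' (length `n_hidden`), hidden weights column-major (all hidden-node weights
#' for covariate 1, then covariate 2, ...), output bias (1), output weights
#' (length `n_hidden`) — `n_hidden * (n_inputs + 2) + 1` numbers in total.
#' The round trip is exact.
#'
#' @param hidden_intercepts Numeric vector, length `n_hidden`.
#' @param hidden_weights Numeric matrix, `n_hidden` by `n_inputs`.
#' @param output_bias Scalar.
#' @param output_weights Numeric vector, length `n_hidden`.
#' @param arch A [network_arch()].
#' @return `network_params()` and `unflatten_params()` return a
#'   `network_params` object; `flatten_params()` returns a numeric vector.
#' @export
network_params <- function(hidden_intercepts, hidden_weights, output_bias,
                           output_weights, arch) {
  hidden_weights <- as.matrix(hidden_weights)
  if (length(hidden_intercepts) != arch$n_hidden ||
      !all(dim(hidden_weights) == c(arch$n_hidden, arch$n_inputs)) ||
      length(output_bias) != 1L ||
      length(output_weights) != arch$n_hidden) {
    abort("Parameter dimensions are inconsistent with the architecture.",
          class = "graftann_config_error")
  }
  structure(
    list(hidden_intercepts = as.numeric(hidden_intercepts),
         hidden_weights = hidden_weights,
         output_bias = as.numeric(output_bias),
         output_weights = as.numeric(output_weights),
         arch = arch),
    class = "network_params"
  )
}

#' @rdname network_params
#' @param params A `network_params` object.
#' @export
flatten_params <- function(params) {
  c(params$hidden_intercepts, as.numeric(params$hidden_weights),
    params$output_bias, params$output_weights)
}

#' @rdname network_params
#' @param v Flat numeric vector of length `n_hidden * (n_inputs + 2) + 1`.
#' @export
unflatten_params <- function(v, arch) {
  nh <- arch$n_hidden
  p <- arch$n_inputs
  expected <- nh * (p + 2L) + 1L
  if (length(v) != expected) {
    abort(sprintf("Expected a parameter vector of length %d, got %d.",
                  expected, length(v)),
          class = "graftann_config_error")
  }
  network_params(
    hidden_intercepts = v[seq_len(nh)],
    hidden_weights = matrix(v[nh + seq_len(nh * p)], nrow = nh, ncol = p),
    output_bias = v[nh + nh * p + 1L],
    output_weights = v[nh + nh * p + 1L + seq_len(nh)],
    arch = arch
  )
}

#' Forward pass of the perceptron
#'
#' Evaluates `s = g(a + sum_n b_n * f(m_n + sum_p mu_np * l_p))` for one
#' covariate vector or a whole matrix of rows at once.
#'
#' @param params A [network_params()] object.
#' @param x Numeric vector of length `n_inputs`, or a matrix with
#'   `n_inputs` columns (one row per observation).
#' @return Network output(s) `s`, one per observation.
#' @export
forward <- function(params, x) {
  x <- if (is.null(dim(x))) matrix(x, nrow = 1L) else as.matrix(x)
  if (ncol(x) != params$arch$n_inputs) {
    abort(sprintf("Expected %d covariates, got %d.",
                  params$arch$n_inputs, ncol(x)),
          class = "graftann_config_error")
  }
  f <- activation_fn(params$arch$hidden_activation)
  g <- activation_fn(params$arch$output_activation)
  hidden <- f(sweep(x %*% t(params$hidden_weights), 2L,
                    params$hidden_intercepts, "+"))
  as.numeric(g(params$output_bias + hidden %*% params$output_weights))
}

# One-indicator-per-level encoding plus training-set standardization.
# Returns the design matrix and an encoder reusable verbatim on new data.
encode_features <- function(data, encoder = NULL) {
  data <- as_tibble(data)
  if (is.null(encoder)) {
    encoder <- list(columns = names(data), levels = list())
    for (col in names(data)) {
      v <- data[[col]]
      if (is.character(v) || is.factor(v)) {
        encoder$levels[[col]] <- sort(unique(as.character(v)))
      }
    }
  }
  blocks <- lapply(encoder$columns, function(col) {
    v <- data[[col]]
    if (is.null(v)) {
      abort(sprintf("Column `%s` missing from new data.", col),
            class = "graftann_data_error")
    }
    lv <- encoder$levels[[col]]
    if (is.null(lv)) {
      m <- matrix(as.numeric(v), ncol = 1L,
                  dimnames = list(NULL, col))
    } else {
      v <- as.character(v)
      m <- vapply(lv, function(l) as.numeric(v == l),
                  numeric(length(v)))
      m <- matrix(m, ncol = length(lv),
                  dimnames = list(NULL, paste0(col, "=", lv)))
    }
    m
  })
  X <- do.call(cbind, blocks)
  if (is.null(encoder$center)) {
    encoder$center <- colMeans(X)
    s <- apply(X, 2L, stats::sd)
    s[!is.finite(s) | s == 0] <- 1
    encoder$scale <- s
  }
  X <- sweep(sweep(X, 2L, encoder$center, "-"), 2L, encoder$scale, "/")
  list(X = X, encoder = encoder)
}

#' Train the perceptron with African Buffalo Optimization
#'
#' Fits the single-hidden-layer network to a binary outcome by minimizing
#' the mean squared error between the network output and the 0/1 label
#' (or, optionally, the misclassification rate) over the flattened weight
#' vector with [abo_minimize()] — no gradients are used. Covariates are
#' standardized with training-set statistics and categoricals are coded one
#' indicator per level; both transformations are stored in the fit and
#' reused verbatim at prediction time.
#'
#' With `scope = "last_layer"` the hidden layer is frozen at random weights
#' (drawn once from the seed) and only the output bias and weights are
#' searched, echoing the use of the optimizer on the network's last layer.
#'
#' @param data Training covariates (data frame; numeric and
#'   character/factor columns).
#' @param labels Binary outcome: 0/1 numeric or a two-level factor (the
#'   second level is the positive "survive" class).
#' @param arch A [network_arch()]; by default sized from the encoded input
#'   dimension.
#' @param abo An [abo_config()]; bounds default to \[-5, 5\] per weight.
#' @param scope `"all_weights"` (default) or `"last_layer"`.
#' @param objective `"mse"` (default) or `"misclassification"`.
#' @param seed Integer seed used when `abo$seed` is unset.
#' @return An object of class `abann` containing the trained
#'   [network_params()], encoder, optimizer history and training metrics.
#' @examples
#' \donttest{
#' set.seed(1)
#' d <- data.frame(x1 = c(rnorm(30, -2), rnorm(30, 2)), x2 = rnorm(60))
#' y <- rep(c(0, 1), each = 30)
#' fit <- train_with_abo(d, y, abo = abo_config(max_iterations = 50, seed = 1))
#' glance(fit)
#' }
#' @export
train_with_abo <- function(data, labels,
                           arch = NULL,
                           abo = abo_config(),
                           scope = c("all_weights", "last_layer"),
                           objective = c("mse", "misclassification"),
                           seed = 1L) {
  scope <- match.arg(scope)
  objective <- match.arg(objective)
  y <- encode_labels(labels)
  if (length(unique(y$values)) < 2L) {
    abort("Training labels contain a single class.",
          class = "graftann_data_error")
  }
  enc <- encode_features(data)
  X <- enc$X
  if (is.null(arch)) arch <- network_arch(n_inputs = ncol(X))
  if (arch$n_inputs != ncol(X)) {
    abort("`arch$n_inputs` does not match the encoded design matrix.",
          class = "graftann_config_error")
  }
  if (is.null(abo$seed)) abo$seed <- derive_seed(seed, "train")

  loss <- function(s) {
    if (objective == "mse") mean((s - y$values)^2) else
      mean(as.integer(s >= 0.5) != y$values)
  }

  fixed <- NULL
  if (scope == "last_layer") {
    fixed <- with_seed_(derive_seed(abo$seed, "hidden_layer"), list(
      hidden_intercepts = runif(arch$n_hidden, -1, 1),
      hidden_weights = matrix(runif(arch$n_hidden * arch$n_inputs, -1, 1),
                              nrow = arch$n_hidden)
    ))
    dims <- 1L + arch$n_hidden
    obj <- function(v) {
      p <- network_params(fixed$hidden_intercepts, fixed$hidden_weights,
                          v[1L], v[-1L], arch)
      loss(forward(p, X))
    }
  } else {
    dims <- arch$n_hidden * (arch$n_inputs + 2L) + 1L
    obj <- function(v) loss(forward(unflatten_params(v, arch), X))
  }

  res <- abo_minimize(obj, dims = dims, config = abo)
  params <- if (scope == "last_layer") {
    network_params(fixed$hidden_intercepts, fixed$hidden_weights,
                   res$best_x[1L], res$best_x[-1L], arch)
  } else {
    unflatten_params(res$best_x, arch)
  }
  s <- forward(params, X)
  structure(
    list(params = params, arch = arch, encoder = enc$encoder,
         positive_level = y$positive_level, scope = scope,
         objective = objective, objective_value = res$best_f,
         history = res$history, n_restarts = res$n_restarts,
         train_accuracy = mean(as.integer(s >= 0.5) == y$values),
         n_train = nrow(X)),
    class = "abann"
  )
}

encode_labels <- function(labels) {
  if (is.factor(labels) || is.character(labels)) {
    lv <- if (is.factor(labels)) levels(labels) else sort(unique(labels))
    if (length(lv) != 2L) {
      abort("Labels must be binary.", class = "graftann_data_error")
    }
    list(values = as.integer(as.character(labels) == lv[2]),
         positive_level = lv[2])
  } else {
    v <- as.integer(labels)
    if (!all(v %in% c(0L, 1L))) {
      abort("Numeric labels must be 0/1.", class = "graftann_data_error")
    }
    list(values = v, positive_level = 1L)
  }
}

#' Predict from a trained network
#'
#' `type = "prob"` returns the network output `s` (a survival probability;
#' requires a logistic output activation), `type = "class"` thresholds it at
#' `cutoff`, with the boundary value `s == cutoff` classified positive.
#' Raising the cutoff never increases the number of predicted positives.
#'
#' @param object An `abann` fit.
#' @param newdata Data frame of covariates.
#' @param type `"prob"` or `"class"`.
#' @param cutoff Classification cutoff (default 0.5).
#' @param ... Unused.
#' @return Numeric probabilities or integer 0/1 classes.
#' @export
predict.abann <- function(object, newdata, type = c("prob", "class"),
                          cutoff = 0.5, ...) {
  type <- match.arg(type)
  if (type == "prob" && object$arch$output_activation != "logistic") {
    abort("Probabilities require a logistic output activation.",
          class = "graftann_config_error")
  }
  s <- forward(object$params, encode_features(newdata, object$encoder)$X)
  if (type == "prob") s else as.integer(s >= cutoff)
}

#' @exportS3Method generics::tidy
tidy.abann <- function(x, ...) {
  p <- x$params
  nh <- x$arch$n_hidden
  input_names <- colnames(x$params$hidden_weights) %||%
    paste0("input_", seq_len(x$arch$n_inputs))
  tibble(
    term = c(paste0("hidden_", seq_len(nh), "_intercept"),
             paste0("hidden_", rep(seq_len(nh), x$arch$n_inputs), "_",
                    rep(input_names, each = nh)),
             "output_bias",
             paste0("output_weight_", seq_len(nh))),
    estimate = flatten_params(p)
  )
}

#' @exportS3Method generics::glance
glance.abann <- function(x, ...) {
  tibble(
    n_inputs = x$arch$n_inputs, n_hidden = x$arch$n_hidden,
    n_params = length(flatten_params(x$params)),
    scope = x$scope, objective = x$objective,
    objective_value = x$objective_value,
    train_accuracy = x$train_accuracy,
    iterations = length(x$history), n_restarts = x$n_restarts,
    n_train = x$n_train
  )
}

#' Training-history plot for an ABO-trained network
#'
#' @param object An `abann` fit.
#' @param ... Unused.
#' @return A ggplot of the best training objective per optimizer iteration.
#' @exportS3Method ggplot2::autoplot
autoplot.abann <- function(object, ...) {
  df <- tibble(iteration = seq_along(object$history),
               objective = object$history)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$objective)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Iteration", y = paste0("Training ", object$objective),
                  title = "ABO training history")
}

#' @export
print.abann <- function(x, ...) {
  cat("<abann> ", x$arch$n_inputs, "inputs,", x$arch$n_hidden,
      "hidden nodes (", x$arch$hidden_activation, "/",
      x$arch$output_activation, ")\n")
  cat("  training", x$objective, "=", format(x$objective_value, digits = 5),
      "; training accuracy =", format(x$train_accuracy, digits = 4), "\n")
  invisible(x)
}

#' Serialize network parameters to a flat key-value file
#'
#' Writes the flattened weight vector (documented order, see
#' [flatten_params()]) together with the architecture as `key,value` CSV
#' lines; `read_network_params()` restores the object exactly.
#'
#' @param params A [network_params()] object.
#' @param path Output file path.
#' @return `write_network_params()` returns `path` invisibly;
#'   `read_network_params()` returns a `network_params` object.
#' @export
write_network_params <- function(params, path) {
  arch <- params$arch
  header <- c(
    paste0("n_inputs,", arch$n_inputs),
    paste0("n_hidden,", arch$n_hidden),
    paste0("hidden_activation,", arch$hidden_activation),
    paste0("output_activation,", arch$output_activation)
  )
  v <- flatten_params(params)
  body <- paste0("w", seq_along(v), ",",
                 formatC(v, format = "g", digits = 17))
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_network_params
#' @export
read_network_params <- function(path) {
  lines <- strsplit(readLines(path), ",", fixed = TRUE)
  kv <- setNames(vapply(lines, `[[`, character(1), 2L),
                 vapply(lines, `[[`, character(1), 1L))
  arch <- network_arch(
    n_inputs = as.integer(kv[["n_inputs"]]),
    n_hidden = as.integer(kv[["n_hidden"]]),
    hidden_activation = kv[["hidden_activation"]],
    output_activation = kv[["output_activation"]]
  )
  v <- as.numeric(kv[grepl("^w[0-9]+$", names(kv))])
  unflatten_params(v, arch)
}
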