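#' Configure the African Buffalo Optimization metaheuristic
#'
#' ABO is a swarm method in which each buffalo carries an exploitation
#' position `w` and an exploration move `m`. Each iteration the move is
#' updated by a *democratic* pull toward the herd-wide best position
#' (learning factor `le1`) and an *intelligence* pull toward the buffalo's
#' own best position (learning factor `le2`):
#' `m' = m + le1 * (bg - w) + le2 * (bp - w)`,
#' after which the position advances by `w' = w + m' / lambda_star` and is
#' clamped to the search box. When the herd best stagnates for
#' `restart_patience` iterations, all buffalo except the incumbent best are
#' re-seeded: half uniformly over the box (exploration) and half in a
#' neighbourhood of the herd best whose radius contracts geometrically with
#' each restart (`restart_shrink`), which is what allows the otherwise
#' undamped swarm dynamics to refine the solution.
#'
#' @param n_buffalo Herd size (default 20).
#' @param le1,le2 Non-negative learning factors for the herd-best and
#'   personal-best pulls (defaults 0.6 and 0.5, the values conventional in
#'   the metaheuristic's literature).
#' @param lambda_star Positive time-unit divisor in the position update
#'   (default 1).
#' @param lower,upper Box bounds, recycled per dimension (defaults -5, 5).
#' @param max_iterations Iteration budget (default 200).
#' @param restart_patience Stagnant iterations before a restart (default 10).
#' @param local_fraction Fraction of re-seeded buffalo placed near the herd
#'   best on restart (default 0.5).
#' @param restart_shrink Geometric contraction factor of the local restart
#'   radius (default 0.5).
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @return An object of class `abo_config`.
#' @export
abo_config <- function(n_buffalo = 20, le1 = 0.6, le2 = 0.5, lambda_star = 1,
                       lower = -5, upper = 5, max_iterations = 200,
                       restart_patience = 10, local_fraction = 0.5,
                       restart_shrink = 0.5, seed = NULL) {
  assert_scalar_number(n_buffalo, "n_buffalo", min = 1)
  assert_scalar_number(le1, "le1", min = 0)
  assert_scalar_number(le2, "le2", min = 0)
  assert_scalar_number(lambda_star, "lambda_star", min = .Machine$double.eps)
  assert_scalar_number(max_iterations, "max_iterations", min = 1)
  assert_scalar_number(restart_patience, "restart_patience", min = 1)
  assert_scalar_number(local_fraction, "local_fraction", min = 0, max = 1)
  assert_scalar_number(restart_shrink, "restart_shrink", min = 0, max = 1)
  if (any(upper <= lower)) {
    abort("Bounds must satisfy lower < upper in every dimension.",
          class = "graftann_config_error")
  }
  structure(
    list(n_buffalo = as.integer(n_buffalo), le1 = le1, le2 = le2,
         lambda_star = lambda_star, lower = lower, upper = upper,
         max_iterations = as.integer(max_iterations),
         restart_patience = as.integer(restart_patience),
         local_fraction = local_fraction, restart_shrink = restart_shrink,
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "abo_config"
  )
}

expand_bounds <- function(config, dims) {
  list(lower = rep_len(config$lower, dims), upper = rep_len(config$upper, dims))
}

evaluate_herd <- function(objective, w) {
  f <- apply(w, 1L, objective)
  if (!all(is.finite(f))) {
    bad <- which(!is.finite(f))[1]
    abort(paste0("Objective returned a non-finite value at point (",
                 toString(signif(w[bad, ], 6)), ")."),
          class = "graftann_objective_error")
  }
  as.numeric(f)
}

#' Initialize a buffalo herd
#'
#' Positions `w` are drawn uniformly within the bounds, exploration moves
#' `m` start at zero, and personal/herd bests are set from the initial
#' objective evaluations. `init` optionally overrides the first rows of `w`
#' with caller-chosen starting positions (used e.g. to seed the
#' feature-selection wrapper with the incoming full subset).
#'
#' @param objective Function mapping a numeric vector of length `dims` to a
#'   scalar to be minimized.
#' @param dims Number of dimensions.
#' @param config An [abo_config()].
#' @param init Optional numeric matrix (rows = starting positions).
#' @return A list of class `abo_herd` with elements `w`, `m`, `bp`, `bp_f`,
#'   `bg`, `bg_f`.
#' @export
init_herd <- function(objective, dims, config = abo_config(), init = NULL) {
  stopifnot(dims >= 1)
  b <- expand_bounds(config, dims)
  w <- with_seed_(config$seed, {
    matrix(runif(config$n_buffalo * dims, rep(b$lower, each = config$n_buffalo),
                 rep(b$upper, each = config$n_buffalo)),
           nrow = config$n_buffalo, ncol = dims)
  })
  if (!is.null(init)) {
    init <- matrix(init, ncol = dims)
    rows <- seq_len(min(nrow(init), nrow(w)))
    w[rows, ] <- clamp(init[rows, , drop = FALSE],
                       rep(b$lower, each = length(rows)),
                       rep(b$upper, each = length(rows)))
  }
  f <- evaluate_herd(objective, w)
  gi <- which.min(f)
  structure(
    list(w = w, m = matrix(0, nrow = config$n_buffalo, ncol = dims),
         bp = w, bp_f = f, bg = w[gi, ], bg_f = f[gi]),
    class = "abo_herd"
  )
}

#' ABO exploration-move update
#'
#' Applies the democratic/intelligence update to every buffalo's exploration
#' move: `m' = m + le1 * (bg - w) + le2 * (bp - w)`, elementwise.
#'
#' @param herd An `abo_herd`.
#' @param config An [abo_config()].
#' @return The herd with updated `m`.
#' @export
update_exploration <- function(herd, config = abo_config()) {
  herd$m <- herd$m +
    config$le1 * sweep(-herd$w, 2L, herd$bg, "+") +
    config$le2 * (herd$bp - herd$w)
  herd
}

#' ABO position update
#'
#' Advances every position by `w' = w + m / lambda_star`, then clamps to the
#' search box.
#'
#' @inheritParams update_exploration
#' @param dims_bounds Optional precomputed bounds (internal use).
#' @return The herd with updated `w`.
#' @export
update_position <- function(herd, config = abo_config(), dims_bounds = NULL) {
  b <- dims_bounds %||% expand_bounds(config, ncol(herd$w))
  w <- herd$w + herd$m / config$lambda_star
  herd$w <- clamp(w, rep(b$lower, each = nrow(w)), rep(b$upper, each = nrow(w)))
  herd
}

#' Minimize a function with African Buffalo Optimization
#'
#' Runs the full ABO loop: exploration update, position update, evaluation,
#' best-keeping, and the contracting elitist restart on stagnation. The
#' best-so-far history is monotone non-increasing by construction.
#'
#' @inheritParams init_herd
#' @return A list of class `abo_result`: `best_x`, `best_f`, `history`
#'   (best-so-far objective per iteration), `n_restarts`, `herd`.
#' @examples
#' res <- abo_minimize(function(x) sum(x^2), dims = 3,
#'                     abo_config(max_iterations = 50, seed = 1))
#' res$best_f
#' @export
abo_minimize <- function(objective, dims, config = abo_config(), init = NULL) {
  b <- expand_bounds(config, dims)
  herd <- init_herd(objective, dims, config, init = init)
  run <- function() {
    history <- numeric(config$max_iterations)
    stall <- 0L
    n_restarts <- 0L
    for (t in seq_len(config$max_iterations)) {
      herd <- update_exploration(herd, config)
      herd <- update_position(herd, config, dims_bounds = b)
      f <- evaluate_herd(objective, herd$w)
      better <- f < herd$bp_f
      herd$bp[better, ] <- herd$w[better, , drop = FALSE]
      herd$bp_f[better] <- f[better]
      if (min(herd$bp_f) < herd$bg_f) {
        gi <- which.min(herd$bp_f)
        herd$bg <- herd$bp[gi, ]
        herd$bg_f <- herd$bp_f[gi]
        stall <- 0L
      } else {
        stall <- stall + 1L
      }
      if (stall >= config$restart_patience && t < config$max_iterations) {
        n_restarts <- n_restarts + 1L
        herd <- restart_herd(herd, config, b, n_restarts)
        f2 <- evaluate_herd(objective, herd$w)
        better <- f2 < herd$bp_f
        herd$bp[better, ] <- herd$w[better, , drop = FALSE]
        herd$bp_f[better] <- f2[better]
        if (min(herd$bp_f) < herd$bg_f) {
          gi <- which.min(herd$bp_f)
          herd$bg <- herd$bp[gi, ]
          herd$bg_f <- herd$bp_f[gi]
        }
        stall <- 0L
      }
      history[t] <- herd$bg_f
    }
    list(history = history, n_restarts = n_restarts, herd = herd)
  }
  # init_herd consumed the seeded stream; derive a child seed for restarts so
  # the whole run is reproducible.
  out <- if (is.null(config$seed)) run() else
    with_seed_(derive_seed(config$seed, "abo_loop"), run())
  structure(
    list(best_x = out$herd$bg, best_f = out$herd$bg_f, history = out$history,
         n_restarts = out$n_restarts, herd = out$herd),
    class = "abo_result"
  )
}

# Elitist stagnation restart: keep the best buffalo untouched; re-seed half
# of the rest near the herd best with a geometrically contracting radius and
# the other half uniformly over the box.
restart_herd <- function(herd, config, b, n_restart) {
  n_b <- nrow(herd$w)
  dims <- ncol(herd$w)
  keep <- which.min(herd$bp_f)
  others <- setdiff(seq_len(n_b), keep)
  if (!length(others)) return(herd)
  n_local <- floor(length(others) * config$local_fraction)
  local <- others[seq_len(n_local)]
  global <- setdiff(others, local)
  radius <- (b$upper - b$lower) * config$restart_shrink^n_restart
  for (i in local) {
    herd$w[i, ] <- clamp(herd$bg + runif(dims, -radius, radius), b$lower, b$upper)
    herd$m[i, ] <- 0
  }
  for (i in global) {
    herd$w[i, ] <- runif(dims, b$lower, b$upper)
    herd$m[i, ] <- 0
  }
  herd
}

#' Binarize an ABO position into a feature mask
#'
#' Maps a continuous buffalo position to a boolean feature subset, either by
#' a sigmoid transfer (`1/(1+exp(-x))` compared to `cutoff`) or by direct
#' thresholding of the raw coordinates. An all-false mask is repaired by
#' switching on the single highest-scoring coordinate, so a mask is never
#' empty.
#'
#' @param w_row Numeric position vector.
#' @param transfer `"sigmoid"` or `"threshold"`.
#' @param cutoff Comparison cutoff (default 0.5).
#' @return A logical vector of the same length.
#' @examples
#' binarize_position(c(-10, 10)) # FALSE TRUE
#' @export
binarize_position <- function(w_row, transfer = c("sigmoid", "threshold"),
                              cutoff = 0.5) {
  transfer <- match.arg(transfer)
  score <- if (transfer == "sigmoid") plogis(w_row) else w_row
  mask <- score >= cutoff
  if (!any(mask)) mask[which.max(score)] <- TRUE
  mask
}

#' @exportS3Method generics::glance
glance.abo_result <- function(x, ...) {
  tibble(best_f = x$best_f, iterations = length(x$history),
         n_restarts = x$n_restarts)
}

#' @exportS3Method generics::tidy
tidy.abo_result <- function(x, ...) {
  tibble(dimension = seq_along(x$best_x), value = as.numeric(x$best_x))
}

#' Convergence plot for an ABO run
#'
#' @param object An `abo_result`.
#' @param ... Unused.
#' @return A ggplot of best-so-far objective value against iteration, on a
#'   log scale when all values are positive.
#' @exportS3Method ggplot2::autoplot
autoplot.abo_result <- function(object, ...) {
  df <- tibble(iteration = seq_along(object$history), best_f = object$history)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$best_f)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Iteration", y = "Best objective value",
                  title = "ABO convergence")
  if (all(df$best_f > 0)) p <- p + ggplot2::scale_y_log10()
  p
}

#' @export
print.abo_result <- function(x, ...) {
  cat("<abo_result> best_f =", format(x$best_f, digits = 6),
      "after", length(x$history), "iterations,",
      x$n_restarts, "restart(s)\n")
  invisible(x)
}
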