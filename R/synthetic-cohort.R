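#' Specify a synthetic transplant cohort
#'
#' Describes a simulated kidney-transplant cohort: a rectangular table of
#' donor/recipient covariates in which a known minority of pre-operative
#' features drive a binary five-year graft-survival outcome through a
#' logistic model. The generator exists so that every downstream stage —
#' cleaning, imputation, censoring, feature selection, network training —
#' can be tested against planted ground truth; it makes no claim of clinical
#' realism (marginal distributions, HLA structure and informative censoring
#' are out of scope).
#'
#' `n_features` counts *all* feature columns: `n_identifier` identifier
#' columns and `n_postop` post-operative columns are part of it, so the
#' number of pre-operative covariates is
#' `n_features - n_identifier - n_postop` (61 under the defaults).
#' Identifier and post-operative columns are generated independently of the
#' outcome — they carry no signal and exist to be removed by
#' [clean_table()].
#'
#' @param n_patients Number of rows (patients).
#' @param n_features Total feature columns including identifiers and
#'   post-operative columns (default 67).
#' @param n_informative Number of pre-operative covariates with non-zero
#'   effect on the outcome (default 10).
#' @param n_postop,n_identifier Counts of injected post-operative and
#'   identifier columns (defaults 4 and 2).
#' @param coefficients Log-odds effect sizes, length `n_informative`. The
#'   default alternates sign with magnitudes between 0.7 and 1.2 — moderate
#'   to strong effects on standardized covariates.
#' @param intercept Log-odds intercept (default 0, i.e. outcome prevalence
#'   near one half).
#' @param missing_rate Fraction of pre-/post-operative feature cells set
#'   missing, completely at random except that no two vertically adjacent
#'   cells of one column (in temporal order) are ever both missing, so
#'   temporal-neighbour imputation is always defined. Default 0.01.
#' @param categorical_fraction Fraction of pre-operative covariates that are
#'   three-level categoricals (levels `A`/`B`/`C`, entering the logistic
#'   model through the fixed integer coding -1/0/1). Default 0.4.
#' @param horizon_days Survival horizon in days; default 1826 (five years).
#' @param date_window Two dates bounding the transplant dates, which are
#'   drawn uniformly and define the temporal row order.
#' @param seed Integer seed; the same spec yields a byte-identical table.
#' @return An object of class `cohort_spec`.
#' @seealso [generate_cohort()]
#' @export
cohort_spec <- function(n_patients,
                        n_features = 67,
                        n_informative = 10,
                        n_postop = 4,
                        n_identifier = 2,
                        coefficients = NULL,
                        intercept = 0,
                        missing_rate = 0.01,
                        categorical_fraction = 0.4,
                        horizon_days = 1826,
                        date_window = as.Date(c("2005-01-01", "2014-12-31")),
                        seed = 1L) {
  assert_scalar_number(n_patients, "n_patients", min = 1)
  assert_scalar_number(n_features, "n_features", min = 1)
  assert_scalar_number(n_informative, "n_informative", min = 1)
  assert_scalar_number(n_postop, "n_postop", min = 0)
  assert_scalar_number(n_identifier, "n_identifier", min = 0)
  assert_scalar_number(missing_rate, "missing_rate", min = 0, max = 1)
  assert_scalar_number(categorical_fraction, "categorical_fraction", min = 0, max = 1)
  assert_scalar_number(horizon_days, "horizon_days", min = 1)
  n_preop <- n_features - n_postop - n_identifier
  if (n_preop < 1) {
    abort("`n_features` must exceed `n_postop + n_identifier`.",
          class = "graftann_config_error")
  }
  if (n_informative > n_preop) {
    abort("`n_informative` cannot exceed the number of pre-operative columns.",
          class = "graftann_config_error")
  }
  if (is.null(coefficients)) {
    coefficients <- rep_len(
      c(1.2, -1.0, 0.9, -0.8, 0.7, 1.1, -0.9, 0.8, -0.7, 1.0), n_informative
    )
  }
  if (length(coefficients) != n_informative) {
    abort("`coefficients` must have length `n_informative`.",
          class = "graftann_config_error")
  }
  structure(
    list(
      n_patients = as.integer(n_patients), n_features = as.integer(n_features),
      n_informative = as.integer(n_informative), n_postop = as.integer(n_postop),
      n_identifier = as.integer(n_identifier), n_preop = as.integer(n_preop),
      coefficients = as.numeric(coefficients), intercept = as.numeric(intercept),
      missing_rate = missing_rate, categorical_fraction = categorical_fraction,
      horizon_days = as.integer(horizon_days),
      date_window = as.Date(date_window), seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

#' Logistic outcome probability
#'
#' The generator's link function: the probability of five-year graft
#' survival given covariate values and log-odds coefficients,
#' `plogis(intercept + sum(coefficients * covariates))`.
#'
#' @param covariates,coefficients Numeric vectors of equal length.
#' @param intercept Scalar log-odds intercept.
#' @return A probability in \[0, 1\].
#' @examples
#' outcome_probability(c(0, 0), c(1.5, -2), 0) # 0.5
#' @export
outcome_probability <- function(covariates, coefficients, intercept = 0) {
  if (length(covariates) != length(coefficients)) {
    abort("`covariates` and `coefficients` must have equal length.",
          class = "graftann_config_error")
  }
  plogis(intercept + sum(coefficients * covariates))
}

# Integer coding used for categorical covariates in the logistic model.
cat_levels <- c("A", "B", "C")
cat_codes <- c(A = -1, B = 0, C = 1)

#' Generate a synthetic transplant cohort with planted ground truth
#'
#' Draws a cohort according to a [cohort_spec()]: mixed numeric/categorical
#' pre-operative covariates (a known subset informative through a logistic
#' model), outcome-independent identifier and post-operative columns, three
#' date columns (transplant, dialysis initiation — present only when the
#' graft failed — and last follow-up), a binary graft-survival outcome, and
#' sparse missingness placed so that temporal-neighbour imputation is always
#' applicable. Rows are ordered by transplant date.
#'
#' Date structure mirrors the censoring arithmetic used for labelling:
#' failed grafts get a dialysis-initiation date within the horizon, so
#' `dialysis_start_date - transplant_date` is the graft time; functioning
#' grafts get only a last-follow-up date, uniform between 0.4 and 2.2 times
#' the horizon after transplant, so a minority are administratively censored
#' before five years.
#'
#' @param spec A [cohort_spec()].
#' @return A list with elements `table` (a cohort table with schema, see
#'   [cohort_table()]) and `truth` (class `cohort_truth`): the informative
#'   column names and indices, their coefficients, and each patient's latent
#'   survival probability.
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_patients = 50, seed = 42))
#' dim(cohort$table)
#' cohort$truth$informative_features
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed_(spec$seed, {
    n <- spec$n_patients
    n_preop <- spec$n_preop

    n_cat <- round(spec$categorical_fraction * n_preop)
    cat_idx <- sort(sample.int(n_preop, n_cat))
    inf_idx <- sort(sample.int(n_preop, spec$n_informative))

    preop_names <- sprintf("preop_%02d", seq_len(n_preop))
    preop <- vector("list", n_preop)
    codes <- matrix(0, nrow = n, ncol = n_preop)
    for (j in seq_len(n_preop)) {
      if (j %in% cat_idx) {
        v <- sample(cat_levels, n, replace = TRUE, prob = c(0.3, 0.4, 0.3))
        preop[[j]] <- v
        codes[, j] <- cat_codes[v]
      } else {
        v <- rnorm(n)
        preop[[j]] <- v
        codes[, j] <- v
      }
    }
    names(preop) <- preop_names

    eta <- spec$intercept + codes[, inf_idx, drop = FALSE] %*% spec$coefficients
    p <- plogis(as.numeric(eta))
    y <- rbinom(n, 1L, p)

    # Temporal order: rows sorted by transplant date.
    transplant <- sort(spec$date_window[1] +
                         sample.int(as.integer(diff(spec$date_window)) + 1L, n,
                                    replace = TRUE) - 1L)
    horizon <- spec$horizon_days
    followup_gap <- round(runif(n, 0.4 * horizon, 2.2 * horizon))
    failure_gap <- round(runif(n, 30, horizon - 1))
    dialysis <- as.Date(ifelse(y == 0L, transplant + failure_gap, NA),
                        origin = "1970-01-01")
    last_followup <- as.Date(ifelse(
      y == 0L,
      dialysis + round(runif(n, 0, 365)),
      transplant + followup_gap
    ), origin = "1970-01-01")

    postop <- list()
    if (spec$n_postop > 0) {
      for (k in seq_len(spec$n_postop)) {
        postop[[sprintf("postop_%02d", k)]] <-
          if (k %% 2L == 1L) rnorm(n, mean = 1) else
            sample(c("yes", "no"), n, replace = TRUE)
      }
    }

    ids <- list()
    if (spec$n_identifier >= 1) {
      ids$patient_id <- sprintf("P%06d", sample.int(999999L, n))
    }
    if (spec$n_identifier >= 2) {
      ids$center_id <- sample(c("C1", "C2", "C3"), n, replace = TRUE)
    }
    if (spec$n_identifier > 2) {
      for (k in seq(3L, spec$n_identifier)) {
        ids[[sprintf("record_id_%d", k)]] <- sprintf("R%06d", sample.int(999999L, n))
      }
    }

    tbl <- tibble::as_tibble(c(
      ids, preop, postop,
      list(transplant_date = transplant,
           dialysis_start_date = dialysis,
           last_followup_date = last_followup,
           graft_survival = y)
    ))

    schema <- c(
      setNames(rep("identifier", length(ids)), names(ids)),
      setNames(rep("preop", n_preop), preop_names),
      setNames(rep("postop", length(postop)), names(postop)),
      transplant_date = "date", dialysis_start_date = "date",
      last_followup_date = "date", graft_survival = "outcome"
    )

    feature_cols <- c(preop_names, names(postop))
    if (spec$missing_rate > 0 && length(feature_cols) > 0) {
      tbl <- sprinkle_missing(tbl, feature_cols, spec$missing_rate)
    }

    table <- cohort_table(tbl, schema)
    truth <- structure(
      list(
        informative_features = preop_names[inf_idx],
        informative_indices = match(preop_names[inf_idx], names(tbl)),
        coefficients = spec$coefficients,
        latent_probabilities = p
      ),
      class = "cohort_truth"
    )
    list(table = table, truth = truth)
  })
}

# Set a fraction of feature cells missing, completely at random, rejecting
# any cell whose vertical neighbour in the same column is already missing.
sprinkle_missing <- function(tbl, feature_cols, rate) {
  n <- nrow(tbl)
  p <- length(feature_cols)
  n_cells <- n * p
  target <- round(rate * n_cells)
  if (target == 0) return(tbl)
  order <- sample.int(n_cells)
  miss <- matrix(FALSE, nrow = n, ncol = p)
  placed <- 0L
  for (cell in order) {
    i <- ((cell - 1L) %% n) + 1L
    j <- ((cell - 1L) %/% n) + 1L
    if (i > 1L && miss[i - 1L, j]) next
    if (i < n && miss[i + 1L, j]) next
    miss[i, j] <- TRUE
    placed <- placed + 1L
    if (placed >= target) break
  }
  for (j in seq_len(p)) {
    col <- feature_cols[j]
    tbl[[col]][miss[, j]] <- NA
  }
  tbl
}
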