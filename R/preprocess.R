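#' Remove identifier and post-operative columns
#'
#' Because the model forecasts graft survival *before* transplantation, all
#' operative and post-operative measurements are removed, as are columns with
#' no predictive value (patient and hospital identifiers). Date columns are
#' retained for label derivation and the outcome column is kept. The removal
#' is recorded in the `"run_log"` attribute of the result. Idempotent.
#'
#' @param data A cohort table with schema (see [cohort_table()]).
#' @return The cleaned cohort table.
#' @export
clean_table <- function(data) {
  sc <- cohort_schema(data)
  keep <- names(data)[sc[names(data)] %in% c("preop", "date", "outcome")]
  dropped <- setdiff(names(data), keep)
  if (!any(sc[keep] == "preop")) {
    abort("No pre-operative columns would remain after cleaning.",
          class = "graftann_data_error")
  }
  out <- keep_cols(data, keep)
  prev <- attr(data, "run_log")
  if (length(dropped) || !is.null(prev)) {
    log <- tibble(
      action = "drop_column",
      target = dropped,
      reason = unname(sc[dropped])
    )
    attr(out, "run_log") <- dplyr::bind_rows(prev, log)
  }
  out
}

#' Temporal-neighbour mean imputation
#'
#' Replaces each missing value with the arithmetic mean of the nearest
#' preceding and nearest following observed values in temporal order (rows
#' ordered by transplant date). Edge cases fall back to the single nearest
#' observed neighbour: a missing value at the first or last position, or one
#' of an adjacent missing pair, takes the closer observed value (ties broken
#' toward the preceding value). Character vectors use nearest-neighbour
#' carry, since a mean is undefined. Observed entries are never altered.
#'
#' @param x A vector in temporal order, possibly with `NA` entries.
#' @return `x` with missing entries filled.
#' @examples
#' impute_temporal_mean(c(2, NA, 4)) # 2 3 4
#' impute_temporal_mean(c(NA, 8, 6)) # 8 8 6
#' @export
impute_temporal_mean <- function(x) {
  miss <- which(is.na(x))
  if (!length(miss)) return(x)
  obs <- which(!is.na(x))
  if (!length(obs)) {
    abort("Cannot impute a fully missing column.", class = "graftann_data_error")
  }
  out <- x
  numeric_mean <- is.numeric(x)
  for (i in miss) {
    prev <- obs[obs < i]
    nxt <- obs[obs > i]
    prev <- if (length(prev)) max(prev) else NA_integer_
    nxt <- if (length(nxt)) min(nxt) else NA_integer_
    if (!is.na(prev) && !is.na(nxt) && i - prev == 1L && nxt - i == 1L &&
        numeric_mean) {
      out[i] <- (x[prev] + x[nxt]) / 2
    } else if (is.na(prev)) {
      out[i] <- x[nxt]
    } else if (is.na(nxt)) {
      out[i] <- x[prev]
    } else if (i - prev <= nxt - i) {
      out[i] <- x[prev]
    } else {
      out[i] <- x[nxt]
    }
  }
  out
}

#' Impute a cohort table and drop sparsely observed rows
#'
#' Orders rows by transplant date (the temporal order), drops rows whose
#' missing fraction across feature columns exceeds `max_missing`, then
#' applies [impute_temporal_mean()] to every pre- and post-operative column.
#' Dropped rows are recorded in the `"run_log"` attribute.
#'
#' @param data A cohort table with schema.
#' @param max_missing Rows with a higher fraction of missing feature cells
#'   are deleted before imputation (default 0.3).
#' @return The imputed cohort table.
#' @export
impute_cohort <- function(data, max_missing = 0.3) {
  sc <- cohort_schema(data)
  date_cols <- cols_with_tag(data, "date")
  tcol <- intersect("transplant_date", date_cols)
  if (length(tcol)) {
    data <- keep_rows(data, order(data[[tcol]]))
  }
  feat <- cols_with_tag(data, c("preop", "postop"))
  if (!length(feat)) return(data)
  miss_frac <- rowMeans(is.na(data[, feat, drop = FALSE]))
  drop <- which(miss_frac > max_missing)
  log <- NULL
  if (length(drop)) {
    log <- tibble(action = "drop_row", target = as.character(drop),
                  reason = "missing_fraction")
    data <- keep_rows(data, setdiff(seq_len(nrow(data)), drop))
  }
  out <- data
  for (col in feat) out[[col]] <- impute_temporal_mean(data[[col]])
  attr(out, "schema") <- sc
  attr(out, "run_log") <- dplyr::bind_rows(attr(data, "run_log"), log)
  out
}

#' Derive the censored five-year graft outcome from dates
#'
#' Applies the censoring arithmetic used to label each record. If the
#' patient returned to dialysis (or died with a failing graft), the graft
#' time is the dialysis-initiation date minus the transplant date; a graft
#' time shorter than the horizon means the graft failed within five years
#' (`status = "failed"`), and a longer one means it survived the horizon
#' (`status = "survived"`). If the graft was still functioning at last
#' contact, the graft time is the last-follow-up date minus the transplant
#' date: `"survived"` when it reaches the horizon, `"censored"` when
#' follow-up ended earlier with the graft still alive.
#'
#' The binary modelling label treats `"survived"` and `"censored"` (alive
#' with a functioning graft at last contact) as class 1 ("survive") and
#' `"failed"` as class 0.
#'
#' @param data A data frame with `transplant_date`, `dialysis_start_date`
#'   (NA when the graft never failed) and `last_followup_date` columns of
#'   class `Date`.
#' @param horizon_days Event horizon in days (default 1826, five years).
#' @return A tibble with columns `graft_time_days`, `status`
#'   (`failed`/`survived`/`censored`) and `label` (0/1).
#' @examples
#' derive_graft_outcome(data.frame(
#'   transplant_date = as.Date("2000-01-01"),
#'   dialysis_start_date = as.Date("2001-01-01"),
#'   last_followup_date = as.Date("2001-06-01")
#' ))
#' @export
derive_graft_outcome <- function(data, horizon_days = 1826) {
  tr <- as.Date(data$transplant_date)
  di <- as.Date(data$dialysis_start_date)
  fu <- as.Date(data$last_followup_date)
  if (anyNA(tr)) {
    abort("Every record needs a transplant date.", class = "graftann_data_error")
  }
  if (any(is.na(di) & is.na(fu))) {
    abort("Each record needs a dialysis-initiation or last-follow-up date.",
          class = "graftann_data_error")
  }
  if (any(!is.na(di) & di < tr)) {
    abort("Dialysis initiation before transplant date.",
          class = "graftann_data_error")
  }
  failed_graft <- !is.na(di)
  gt <- ifelse(failed_graft, as.integer(di - tr), as.integer(fu - tr))
  if (any(gt < 0, na.rm = TRUE)) {
    abort("Last follow-up before transplant date.", class = "graftann_data_error")
  }
  status <- dplyr::case_when(
    failed_graft & gt < horizon_days ~ "failed",
    gt >= horizon_days ~ "survived",
    .default = "censored"
  )
  tibble(
    graft_time_days = as.integer(gt),
    status = status,
    label = as.integer(status != "failed")
  )
}

#' Split a cohort into training and test partitions
#'
#' Disjoint row partition with `round(train_fraction * n)` training rows,
#' reproducible under `seed`. By default the split is stratified on the
#' outcome column (largest-remainder allocation keeps the overall training
#' size exact); set `stratify = FALSE` for a simple random split.
#'
#' @param data A cohort table (or any data frame; stratification requires an
#'   outcome-tagged column or a `label` column).
#' @param train_fraction Fraction of rows assigned to training, in (0, 1).
#'   Default 0.7.
#' @param seed Integer seed.
#' @param stratify Stratify on the outcome? Default `TRUE`.
#' @return A list with cohort tables `train` and `test`.
#' @export
split_train_test <- function(data, train_fraction = 0.7, seed = 1L,
                             stratify = TRUE) {
  n <- nrow(data)
  if (n < 2L) {
    abort("Need at least two rows to split.", class = "graftann_data_error")
  }
  if (!(train_fraction > 0 && train_fraction < 1)) {
    abort("`train_fraction` must be strictly between 0 and 1.",
          class = "graftann_config_error")
  }
  n_train <- round(train_fraction * n)
  n_train <- min(max(n_train, 1L), n - 1L)

  strata <- rep(1L, n)
  if (stratify) {
    out_col <- tryCatch(cols_with_tag(data, "outcome"), error = function(e) character())
    y <- if (length(out_col)) data[[out_col[1]]] else data[["label"]]
    if (!is.null(y)) strata <- as.integer(factor(y))
  }

  idx_train <- with_seed_(seed, {
    groups <- split(seq_len(n), strata)
    quota <- vapply(groups, length, integer(1)) * train_fraction
    take <- floor(quota)
    remainder <- n_train - sum(take)
    if (remainder > 0) {
      extra <- order(quota - take, decreasing = TRUE)[seq_len(remainder)]
      take[extra] <- take[extra] + 1L
    } else if (remainder < 0) {
      shrink <- order(quota - take)[seq_len(-remainder)]
      take[shrink] <- take[shrink] - 1L
    }
    sort(unlist(Map(function(rows, k) {
      if (k <= 0) return(integer())
      rows[sample.int(length(rows), min(k, length(rows)))]
    }, groups, take), use.names = FALSE))
  })

  subset_fn <- if (!is.null(attr(data, "schema"))) keep_rows else
    function(d, i) d[i, , drop = FALSE]
  list(
    train = subset_fn(data, idx_train),
    test = subset_fn(data, setdiff(seq_len(n), idx_train))
  )
}
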