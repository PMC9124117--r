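test_that("clean_table keeps only pre-operative, date and outcome columns", {
  cohort <- generate_cohort(cohort_spec(n_patients = 50, seed = 1))
  cleaned <- clean_table(cohort$table)
  sc <- cohort_schema(cleaned)
  expect_equal(sum(sc == "preop"), 61L)
  expect_setequal(unique(unname(sc)), c("preop", "date", "outcome"))
  expect_equal(ncol(cleaned), 61L + 3L + 1L)
  log <- attr(cleaned, "run_log")
  expect_equal(sort(log$target),
               sort(c("patient_id", "center_id",
                      paste0("postop_0", 1:4))))
  # idempotent
  expect_identical(as.data.frame(clean_table(cleaned)), as.data.frame(cleaned))
})

test_that("clean_table passes through a table with nothing to drop and errors with no preop", {
  tbl <- cohort_table(data.frame(age = c(1, 2), graft_survival = c(0, 1)),
                      c(age = "preop", graft_survival = "outcome"))
  expect_identical(as.data.frame(clean_table(tbl)), as.data.frame(tbl))
  bad <- cohort_table(data.frame(creat = c(1, 2), graft_survival = c(0, 1)),
                      c(creat = "postop", graft_survival = "outcome"))
  expect_error(clean_table(bad), class = "graftann_data_error")
})

test_that("temporal-neighbour imputation follows the mean and fallback rules", {
  expect_equal(impute_temporal_mean(c(2, NA, 4)), c(2, 3, 4))
  expect_equal(impute_temporal_mean(c(5, 5, 5)), c(5, 5, 5))
  # boundary: nearest observed neighbour
  expect_equal(impute_temporal_mean(c(NA, 8, 6)), c(8, 8, 6))
  expect_equal(impute_temporal_mean(c(3, 7, NA)), c(3, 7, 7))
  # adjacent pair: single nearest neighbour, tie broken toward the past
  expect_equal(impute_temporal_mean(c(2, NA, NA, 6)), c(2, 2, 6, 6))
  # categorical carry
  expect_equal(impute_temporal_mean(c("a", NA, "b")), c("a", "a", "b"))
  expect_error(impute_temporal_mean(c(NA_real_, NA_real_)),
               class = "graftann_data_error")
})

test_that("imputation never alters observed values and preserves row count", {
  withr::with_seed(42, {
    for (rep in 1:20) {
      n <- sample(5:40, 1)
      x <- rnorm(n)
      drop <- sample(n, max(1, floor(n / 5)))
      xm <- x
      xm[drop] <- NA
      out <- impute_temporal_mean(xm)
      expect_equal(length(out), n)
      expect_equal(out[-drop], x[-drop])
      expect_false(anyNA(out))
    }
  })
})

test_that("impute_cohort fills feature cells and drops overly sparse rows", {
  cohort <- generate_cohort(cohort_spec(n_patients = 200, missing_rate = 0.01,
                                        seed = 31))
  cleaned <- clean_table(cohort$table)
  imputed <- impute_cohort(cleaned)
  feats <- imputed[, cols_with_tag_test(imputed, "preop")]
  expect_false(anyNA(feats))
  expect_equal(nrow(imputed), nrow(cleaned))

  # a row that is mostly missing gets dropped
  tbl <- cohort_table(
    data.frame(a = c(1, NA, 3), b = c(4, NA, 6), c = c(7, NA, 9),
               graft_survival = c(1, 0, 1)),
    c(a = "preop", b = "preop", c = "preop", graft_survival = "outcome")
  )
  out <- impute_cohort(tbl, max_missing = 0.5)
  expect_equal(nrow(out), 2L)
  expect_equal(attr(out, "run_log")$action, "drop_row")
})

test_that("graft outcomes follow the five-year censoring arithmetic", {
  # failed graft: dialysis minus transplant, spanning a leap day
  out <- derive_graft_outcome(data.frame(
    transplant_date = as.Date("2000-01-01"),
    dialysis_start_date = as.Date("2001-01-01"),
    last_followup_date = as.Date("2001-06-01")
  ))
  expect_equal(out$graft_time_days, 366L)
  expect_equal(out$status, "failed")
  expect_equal(out$label, 0L)

  # functioning graft, zero-length follow-up: censored
  out <- derive_graft_outcome(data.frame(
    transplant_date = as.Date("2000-01-01"),
    dialysis_start_date = as.Date(NA),
    last_followup_date = as.Date("2000-01-01")
  ))
  expect_equal(out$graft_time_days, 0L)
  expect_equal(out$status, "censored")
  expect_equal(out$label, 1L)

  # functioning graft past the horizon: survived
  out <- derive_graft_outcome(data.frame(
    transplant_date = as.Date("2000-01-01"),
    dialysis_start_date = as.Date(NA),
    last_followup_date = as.Date("2006-01-01")
  ), horizon_days = 1826)
  expect_equal(out$graft_time_days, 2192L)
  expect_equal(out$status, "survived")
  expect_equal(out$label, 1L)

  expect_error(derive_graft_outcome(data.frame(
    transplant_date = as.Date("2000-06-01"),
    dialysis_start_date = as.Date("2000-01-01"),
    last_followup_date = as.Date("2001-01-01")
  )), class = "graftann_data_error")
})

test_that("train/test split has exact sizes and is a reproducible partition", {
  tbl <- tibble::tibble(x = rnorm(10), label = rep(c(0, 1), 5))
  parts <- split_train_test(tbl, 0.7, seed = 1)
  expect_equal(nrow(parts$train), 7L)
  expect_equal(nrow(parts$test), 3L)

  tbl <- tibble::tibble(x = seq_len(100), label = rep(c(0, 1), 50))
  p1 <- split_train_test(tbl, 0.7, seed = 1)
  p2 <- split_train_test(tbl, 0.7, seed = 1)
  expect_identical(p1$train$x, p2$train$x)
  expect_setequal(c(p1$train$x, p1$test$x), tbl$x)
  expect_length(intersect(p1$train$x, p1$test$x), 0)

  # stratification keeps the class balance in both partitions
  tbl2 <- tibble::tibble(x = seq_len(200), label = rep(c(0, 1), c(160, 40)))
  p3 <- split_train_test(tbl2, 0.7, seed = 2)
  expect_equal(sum(p3$train$label), 28)
  expect_equal(sum(p3$test$label), 12)

  expect_error(split_train_test(tbl[1, ], 0.7), class = "graftann_data_error")
  expect_error(split_train_test(tbl, 1.2), class = "graftann_config_error")
})
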