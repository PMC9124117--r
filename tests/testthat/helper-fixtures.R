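# Shared fixtures, all generated in code.

# Small fully observed cohort for preprocessing tests.
small_cohort <- function(n = 60, seed = 11, ...) {
  generate_cohort(cohort_spec(n_patients = n, n_features = 12, n_informative = 3,
                              n_postop = 2, n_identifier = 2, missing_rate = 0,
                              seed = seed, ...))
}

# A manually built one-buffalo herd for stepping the update equations by hand.
manual_herd <- function(w, m, bp, bg) {
  structure(
    list(w = matrix(w, nrow = 1), m = matrix(m, nrow = 1),
         bp = matrix(bp, nrow = 1), bp_f = 0, bg = bg, bg_f = 0),
    class = "abo_herd"
  )
}

# Two-cluster separable classification problem.
two_clusters <- function(n = 200, gap = 2, seed = 1) {
  withr::with_seed(seed, {
    y <- rep(c(0L, 1L), each = n / 2)
    data.frame(
      x1 = rnorm(n, mean = ifelse(y == 1, gap, -gap)),
      x2 = rnorm(n),
      y = y
    )
  })
}

# Independent mutual-information oracle: joint-distribution formula over the
# contingency table, a different computation path from the package's
# conditional-entropy implementation.
ig_oracle <- function(feature, labels) {
  tab <- table(feature, labels)
  n <- sum(tab)
  p_joint <- tab / n
  p_f <- rowSums(p_joint)
  p_y <- colSums(p_joint)
  mi <- 0
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      if (p_joint[i, j] > 0) {
        mi <- mi + p_joint[i, j] * log2(p_joint[i, j] / (p_f[i] * p_y[j]))
      }
    }
  }
  as.numeric(mi)
}

cols_with_tag_test <- function(data, tag) {
  sc <- cohort_schema(data)
  names(data)[sc[names(data)] %in% tag]
}
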