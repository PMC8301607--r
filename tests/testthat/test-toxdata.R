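# Toxicity matrices, aggregate entropy and activity calls.

test_that("incidence_from_binary computes per-endpoint proportions", {
  expect_equal(incidence_from_binary(matrix(0, 32, 18))$incidence, rep(0, 18))
  expect_equal(incidence_from_binary(matrix(1, 32, 18))$incidence, rep(1, 18))
  m <- matrix(0, 32, 18)
  m[1:8, 3] <- 1
  expect_equal(incidence_from_binary(m)$incidence[3], 0.25)
  # missing entries excluded from numerator and denominator
  m[9:16, 3] <- NA
  expect_equal(incidence_from_binary(m)$incidence[3], 8 / 24)
  # endpoint with zero evaluable replicates errors by name
  m2 <- matrix(0, 4, 18, dimnames = list(NULL, sprintf("E%02d", 1:18)))
  m2[, 5] <- NA
  expect_error(incidence_from_binary(m2), "E05")
  expect_error(incidence_from_binary(matrix(0, 32, 17)), "18")
  expect_error(incidence_from_binary(matrix(2, 32, 18)), "0, 1 or NA")
})

test_that("aggregate entropy matches the pinned monotone-entropy form", {
  expect_equal(agg_entropy(rep(0, 18)), 0)
  expect_equal(agg_entropy(rep(1, 18)), 36)
  expect_equal(agg_entropy(rep(0.5, 18)), 18)
  # s is continuous through 1/2 and monotone on a fine grid
  q <- seq(0, 1, by = 1e-3)
  s <- vapply(q, function(p) agg_entropy(c(p, rep(0, 17))), 0)
  expect_true(all(diff(s) >= -1e-12))
  expect_equal(s[q == 0.5], 1)
  expect_error(agg_entropy(c(1.2, rep(0, 17))), "outside")
})

test_that("AggE never decreases when any single incidence rises", {
  set.seed(31)
  for (i in 1:25) {
    p <- runif(18)
    j <- sample(18, 1)
    p2 <- p
    p2[j] <- min(1, p[j] + runif(1) * (1 - p[j]))
    expect_gte(agg_entropy(p2), agg_entropy(p) - 1e-12)
  }
})

test_that("grouping by max never exceeds the singleton-group AggE", {
  set.seed(32)
  groupings <- list(
    c(rep(1, 6), rep(2, 6), rep(3, 6)),
    c(rep(1, 9), rep(2, 9)),
    rep(1, 18)
  )
  for (i in 1:10) {
    p <- runif(18)
    singleton <- agg_entropy(p)
    for (g in groupings) {
      panel <- endpoint_panel(grouping = split(seq_len(18), g))
      expect_lte(agg_entropy(p, panel), singleton + 1e-12)
    }
  }
  expect_error(endpoint_panel(grouping = list(1:17)), "partition")
})

test_that("classification at the threshold uses >= and is threshold-monotone", {
  expect_false(classify(0)$active)
  expect_true(classify(9.35)$active)      # >= convention at the threshold
  expect_true(classify(36)$active)
  expect_false(classify(9.349999)$active)
  expect_error(classify(5, threshold = -1), "non-negative")
  set.seed(33)
  aggs <- runif(50, 0, 36)
  for (th in c(0, 5, 9.35, 20, 36)) {
    lo <- classify(aggs, th)$active
    hi <- classify(aggs, th + 3)$active
    expect_true(all(lo | !hi))  # raising threshold never activates a call
  }
})

test_that("toxicity CSV round-trips losslessly and validates endpoint count", {
  set.seed(34)
  tms <- lapply(1:10, function(i) {
    toxicity_matrix(sprintf("chem%02d", i), runif(18),
                    n_replicates = 32, concentration_label = "64 uM")
  })
  f <- withr::local_tempfile(fileext = ".csv")
  write_toxicity_csv(tms, f)
  back <- read_toxicity_csv(f)
  for (i in seq_along(tms)) {
    expect_equal(back[[i]]$incidence, tms[[i]]$incidence, tolerance = 1e-9)
    expect_equal(back[[i]]$chemical_id, tms[[i]]$chemical_id)
    expect_equal(back[[i]]$n_replicates, tms[[i]]$n_replicates)
  }
  # 17 endpoint columns -> error
  df <- utils::read.csv(f, check.names = FALSE)
  utils::write.csv(df[, -2], f, row.names = FALSE)
  expect_error(read_toxicity_csv(f), "18")
})

test_that("long-form replicate files agree with an independent pivot", {
  set.seed(35)
  mat <- matrix(rbinom(32 * 18, 1, 0.3), 32, 18)
  long <- do.call(rbind, lapply(1:32, function(r) {
    data.frame(chemical_id = "c1", replicate = r,
               endpoint = sprintf("E%02d", 1:18), value = mat[r, ])
  }))
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(long, f, row.names = FALSE)
  tm <- read_toxicity_csv(f)[[1]]
  expect_equal(tm$incidence, unname(colMeans(mat)))   # oracle: plain pivot
  expect_equal(tm$n_replicates, 32L)
})
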