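# Evaluation: confusion metrics, consensus, cross-validation, shuffle null,
# random search, prioritization arithmetic.

test_that("metrics agree with a brute-force label-loop recount", {
  set.seed(61)
  for (rep in 1:20) {
    n <- sample(10:200, 1)
    pred <- runif(n) < 0.3
    truth <- runif(n) < 0.2
    r <- metrics(confusion_from_calls(pred, truth))
    tp <- fp <- fn <- tn <- 0
    for (i in seq_len(n)) {        # oracle: explicit loop over labels
      if (pred[i] && truth[i]) tp <- tp + 1
      else if (pred[i]) fp <- fp + 1
      else if (truth[i]) fn <- fn + 1
      else tn <- tn + 1
    }
    expect_equal(unclass(r$confusion),
                 list(TP = tp, FP = fp, FN = fn, TN = tn))
    if (tp + fn > 0) expect_equal(r$SE, 100 * tp / (tp + fn))
    if (tn + fp > 0) expect_equal(r$SP, 100 * tn / (tn + fp))
    if (!is.na(r$auroc)) expect_equal(r$auroc, (r$SE + r$SP) / 200)
    # kappa cross-checked against the closed form on observed marginals
    po <- (tp + tn) / n
    pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
    if (pe < 1) expect_equal(r$kappa, (po - pe) / (1 - pe))
  }
})

test_that("undefined metrics are explicit markers, never zero", {
  r <- metrics(confusion(TP = 0, FP = 0, FN = 0, TN = 20))
  expect_true(is.na(r$SE))      # no true actives
  expect_true(is.na(r$PPV))     # no positive calls
  expect_true(is.na(r$kappa))   # single-class truth and calls
  expect_true(is.na(r$auroc))
  perfect <- metrics(confusion(TP = 7, FP = 0, FN = 0, TN = 49))
  expect_equal(perfect$SE, 100)
  expect_equal(perfect$SP, 100)
  expect_equal(perfect$PPV, 100)
  expect_equal(perfect$kappa, 1)
  expect_equal(perfect$auroc, 1)
})

test_that("AND-consensus semantics: idempotent, intersective, never more positives", {
  set.seed(62)
  ids <- sprintf("c%02d", 1:40)
  a <- data.frame(chemical_id = ids, active = runif(40) < 0.4)
  b <- data.frame(chemical_id = sample(ids), active = runif(40) < 0.4)
  expect_equal(consensus_and(a, a)$active, a$active)
  cons <- consensus_and(a, b)
  b_al <- b$active[match(ids, b$chemical_id)]
  expect_equal(cons$active, a$active & b_al)
  expect_lte(sum(cons$active), min(sum(a$active), sum(b$active)))
  # disjoint active sets -> zero actives
  d1 <- data.frame(chemical_id = ids, active = seq_along(ids) <= 5)
  d2 <- data.frame(chemical_id = ids, active = seq_along(ids) > 35)
  expect_equal(sum(consensus_and(d1, d2)$active), 0)
  expect_error(consensus_and(a, b[1:10, ]), "same chemical set")
})

test_that("cross-validation: constant classifier, determinism, summary recompute", {
  set.seed(63)
  truth <- runif(80) < 0.2
  never <- function(train_idx, test_idx) rep(FALSE, length(test_idx))
  cv <- cross_validate(truth, never, k = 10, seed = 7)
  expect_equal(unname(cv$mean["SE"]), 0)
  expect_equal(unname(cv$mean["SP"]), 100)
  # identical split memberships across runs with the same seed
  cv2 <- cross_validate(truth, never, k = 10, seed = 7)
  expect_identical(cv$splits, cv2$splits)
  # mean/sd equal an independent recomputation from the stored fold reports
  kappas <- vapply(cv$folds, `[[`, 0, "kappa")
  expect_equal(unname(cv$mean["kappa"]), mean(kappas))
  expect_equal(unname(cv$sd["kappa"]), sd(kappas))
  # stratification keeps both classes in every validation set
  for (s in cv$splits) expect_true(any(truth[s]) && any(!truth[s]))
})

test_that("shuffle null is deterministic and centered at chance", {
  set.seed(64)
  pred <- runif(56) < 0.16
  truth <- runif(56) < 0.125
  n1 <- shuffle_null(pred, truth, n = 200, seed = 3)
  n2 <- shuffle_null(pred, truth, n = 200, seed = 3)
  expect_identical(n1$kappa, n2$kappa)
  expect_lt(abs(n1$mean["kappa"]), 0.1)
  expect_lt(abs(n1$mean["auroc"] - 0.5), 0.1)
})

test_that("random search samples the space and logs reproducible scores", {
  # a single-point space returns that point
  one <- random_search(list(width = 16L, lr = list(min = 0.1, max = 0.1)),
                       function(cfg, seed) cfg$width + cfg$lr,
                       n_trials = 3, seed = 5)
  expect_equal(one$best_config$width, 16L)
  expect_equal(one$best_score, 16.1)

  space <- list(width = c(8L, 16L, 32L),
                lr = list(min = 1e-3, max = 1e-1, log = TRUE))
  obj <- function(cfg, seed) sin(seed) + log(cfg$width) - cfg$lr
  rs1 <- random_search(space, obj, n_trials = 6, seed = 11)
  rs2 <- random_search(space, obj, n_trials = 6, seed = 11)
  expect_identical(rs1$log, rs2$log)
  # logged objective values match recomputation for the logged seeds
  for (i in 1:2) {
    cfg <- list(width = rs1$log$width[i], lr = rs1$log$lr[i])
    expect_equal(rs1$log$score[i], obj(cfg, rs1$log$seed[i]))
  }
  expect_error(random_search(list(), obj, 2, 1), "empty")
})

test_that("prioritization arithmetic behaves at the identity point and rejects ppv 0", {
  p <- prioritization_estimate(1000, 1, 1)
  expect_equal(p$expected_actives, 1000)
  expect_equal(p$screening_list_size, 1000)
  expect_error(prioritization_estimate(1000, 0.5, 0), "positive")
})
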