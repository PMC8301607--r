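# The Go-ZT generator: weighted-sum pooling, forward contracts, regression
# training, and the composed prediction pipeline.

make_pairs <- function(n, seed, vcfg = view_config(max_atoms_per_view = 8)) {
  ds <- synth_dataset(synth_config(n_chemicals = n, seed = seed))
  list(pairs = lapply(seq_len(n), function(i) {
    list(views = build_views(ds$molecules[[i]], vcfg), tox = ds$tox[[i]])
  }), ds = ds, vcfg = vcfg)
}

small_cfg <- function(seed = 1, epochs = 20L, ...) {
  go_zt_config(width = 16, feature_dim = 8, max_atoms = 8, epochs = epochs,
               seed = seed, ...)
}

test_that("weighted-sum pooling equals the brute-force oracle", {
  set.seed(41)
  for (rep in 1:10) {
    B <- sample(2:6, 1)
    nv <- sample(3:12, B, replace = TRUE)
    feats <- matrix(rnorm(sum(nv) * 7), sum(nv), 7)
    w <- runif(sum(nv))
    group <- rep(seq_len(B), nv)
    s <- weighted_view_sum(feats, w, group, B)
    # oracle: direct per-chemical summation loop
    for (b in seq_len(B)) {
      acc <- numeric(7)
      for (i in which(group == b)) acc <- acc + feats[i, ] * w[i]
      expect_lt(max(abs(s[b, ] - acc)), 1e-6)
    }
  }
})

test_that("an identity feature stub reduces pooling to the weighted view average", {
  vs <- build_views(fixture_molecule("methyl_isothiocyanate"),
                    view_config(max_atoms_per_view = 8))
  pt <- pad_to_tensor(vs, 8)
  s <- weighted_view_sum(pt$flat, pt$weights, rep(1L, nrow(pt$flat)), 1L)
  oracle <- colSums(pt$flat * pt$weights)
  expect_equal(drop(s), oracle, tolerance = 1e-12)
})

test_that("forward is invariant to view duplication-with-halved-weights and view order", {
  set.seed(42)
  md <- make_pairs(3, seed = 42)
  cfg <- small_cfg()
  set.seed(1)
  model <- viewtox:::new_generator(cfg)
  vs <- md$pairs[[1]]$views
  p0 <- forward_generator(model, list(vs))

  dup <- vs
  dup$views <- c(vs$views, vs$views)
  dup$weights <- c(vs$weights, vs$weights) / 2
  expect_equal(forward_generator(model, list(dup)), p0, ignore_attr = TRUE,
               tolerance = 1e-9)

  perm <- sample(length(vs$views))
  shuf <- vs
  shuf$views <- vs$views[perm]
  shuf$weights <- vs$weights[perm]
  expect_equal(forward_generator(model, list(shuf)), p0, ignore_attr = TRUE,
               tolerance = 1e-9)
})

test_that("training reduces MSE, is seed-deterministic, and records its history", {
  md <- make_pairs(50, seed = 43)
  m1 <- train_go_zt(md$pairs, small_cfg(seed = 5, epochs = 75L))
  expect_length(m1$loss_history, 75L)
  expect_lt(tail(m1$loss_history, 1), m1$loss_history[1])
  m2 <- train_go_zt(md$pairs, small_cfg(seed = 5, epochs = 75L))
  expect_identical(m1$loss_history, m2$loss_history)
  p1 <- forward_generator(m1, list(md$pairs[[1]]$views))
  p2 <- forward_generator(m2, list(md$pairs[[1]]$views))
  expect_identical(p1, p2)   # bit-identical prediction under a fixed seed
  expect_equal(ncol(p1), 18L)
  expect_true(all(p1 >= 0 & p1 <= 1))
})

test_that("a dataset of one repeated chemical is memorized to near-zero loss", {
  md <- make_pairs(4, seed = 44)
  pairs <- rep(md$pairs[1], 8)
  m <- train_go_zt(pairs, small_cfg(seed = 2, epochs = 75L))
  expect_lt(tail(m$loss_history, 1), 0.02)
})

test_that("a runaway learning rate aborts with a diagnostic", {
  md <- make_pairs(4, seed = 45)
  expect_error(train_go_zt(md$pairs, small_cfg(learning_rate = 1e5)),
               "learning_rate")
  expect_error(train_go_zt(md$pairs[1], small_cfg()), "2")
})

test_that("predict_activity composes views -> forward -> AggE -> classify", {
  md <- make_pairs(4, seed = 46)
  cfg <- small_cfg()
  set.seed(3)
  model <- viewtox:::new_generator(cfg)
  # force the output layer to a constant: swish(b) with weights zero
  nl <- length(model$gnet$layers)
  model$gnet$layers[[nl]]$W[] <- 0

  # all-zero predictions -> every chemical inactive
  model$gnet$layers[[nl]]$b[] <- -30       # swish(-30) ~ 0
  calls <- predict_activity(model, md$ds$molecules, md$vcfg)
  expect_false(any(calls$active))

  # all-one predictions -> AggE = 36 -> every chemical active
  b_one <- uniroot(function(x) x / (1 + exp(-x)) - 1, c(1, 2),
                   tol = 1e-12)$root
  model$gnet$layers[[nl]]$b[] <- b_one     # swish(b) = 1
  calls <- predict_activity(model, md$ds$molecules, md$vcfg)
  expect_true(all(calls$active))
  expect_equal(calls$agg_entropy, rep(36, 4), tolerance = 1e-6)

  # domain-filtered molecules are excluded from calls but logged
  mols <- c(md$ds$molecules, list(fixture_molecule("perfluorodecane")))
  calls <- suppressMessages(predict_activity(model, mols, md$vcfg))
  excl <- attr(calls, "exclusions")
  expect_false("perfluorodecane" %in% calls$chemical_id)
  expect_equal(excl$chemical_id, "perfluorodecane")
  expect_match(excl$reason, "perfluorinated")
})

test_that("checkpoints round-trip a trained model", {
  md <- make_pairs(4, seed = 47)
  m <- train_go_zt(md$pairs, small_cfg(epochs = 3L))
  f <- withr::local_tempfile(fileext = ".ckpt")
  save_checkpoint(m, f)
  m2 <- load_checkpoint(f)
  expect_identical(forward_generator(m2, list(md$pairs[[2]]$views)),
                   forward_generator(m, list(md$pairs[[2]]$views)))
  expect_identical(m2$loss_history, m$loss_history)
})
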