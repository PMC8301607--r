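# Imbalance-aware evaluation of binary activity calls: confusion-matrix
# metrics (SE/SP/PPV in percent, Cohen's kappa, balanced-accuracy AUROC),
# AND-consensus of two models, repeated random-split cross-validation,
# a label-shuffle null, random-search tuning, and screening-prioritization
# arithmetic.

#' Confusion counts
#'
#' @param TP,FP,FN,TN Non-negative integer counts.
#' @return List of class `vt_confusion`.
#' @export
confusion <- function(TP, FP, FN, TN) {
  counts <- c(TP = TP, FP = FP, FN = FN, TN = TN)
  stopifnot(all(counts >= 0), sum(counts) > 0)
  structure(as.list(counts), class = "vt_confusion")
}

#' Confusion counts from predicted and true calls
#'
#' @param pred Logical vector of predicted active calls.
#' @param truth Logical vector of true active labels.
#' @return A `vt_confusion`.
#' @export
confusion_from_calls <- function(pred, truth) {
  stopifnot(length(pred) == length(truth), !anyNA(pred), !anyNA(truth))
  confusion(TP = sum(pred & truth), FP = sum(pred & !truth),
            FN = sum(!pred & truth), TN = sum(!pred & !truth))
}

#' Classification metrics from a confusion matrix
#'
#' SE = TP/(TP+FN), SP = TN/(TN+FP) and PPV = TP/(TP+FP), reported in
#' percent; Cohen's kappa with the standard chance-agreement marginals;
#' and AUROC computed as (SE+SP)/2 — the balanced accuracy, i.e. the ROC
#' area of a single binary operating point, which is how AUROC is defined
#' for thresholded generator calls here (flagged as binary-call AUROC).
#' A metric whose denominator is zero (e.g. PPV with no positive calls, or
#' kappa with a single-class truth) is reported as `NA` — explicitly
#' undefined, never silently 0.
#'
#' @param c A `vt_confusion`.
#' @return List of class `vt_eval_report`: `SE`, `SP`, `PPV` (percent),
#'   `kappa`, `auroc`, `auroc_kind`, `confusion`.
#' @examples
#' metrics(confusion(TP = 5, FP = 4, FN = 2, TN = 45))  # the Go-ZT test row
#' @export
metrics <- function(c) {
  stopifnot(inherits(c, "vt_confusion"))
  TP <- c$TP; FP <- c$FP; FN <- c$FN; TN <- c$TN
  n <- TP + FP + FN + TN
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  se <- ratio(TP, TP + FN)
  sp <- ratio(TN, TN + FP)
  ppv <- ratio(TP, TP + FP)
  p_o <- (TP + TN) / n
  p_e <- ((TP + FP) / n) * ((TP + FN) / n) + ((FN + TN) / n) * ((FP + TN) / n)
  kappa <- if (p_e < 1) (p_o - p_e) / (1 - p_e) else NA_real_
  auroc <- if (is.na(se) || is.na(sp)) NA_real_ else (se + sp) / 2
  structure(list(SE = 100 * se, SP = 100 * sp, PPV = 100 * ppv,
                 kappa = kappa, auroc = auroc,
                 auroc_kind = "binary-call (balanced accuracy)",
                 confusion = c),
            class = "vt_eval_report")
}

#' @export
print.vt_eval_report <- function(x, ...) {
  fmt <- function(v, d = 1) if (is.na(v)) "undefined" else round(v, d)
  cat(sprintf("SE %s%%  SP %s%%  PPV %s%%  kappa %s  AUROC %s [%s]\n",
              fmt(x$SE), fmt(x$SP), fmt(x$PPV), fmt(x$kappa, 3),
              fmt(x$auroc, 3), x$auroc_kind))
  invisible(x)
}

#' AND-consensus of two sets of activity calls
#'
#' A chemical is called active only when both models call it active.
#'
#' @param callsA,callsB Data frames with `chemical_id` and `active` columns
#'   over the same chemical set.
#' @return Data frame of consensus calls.
#' @export
consensus_and <- function(callsA, callsB) {
  if (!setequal(callsA$chemical_id, callsB$chemical_id) ||
      anyDuplicated(callsA$chemical_id)) {
    stop("consensus requires the same chemical set in both call sets")
  }
  b <- callsB$active[match(callsA$chemical_id, callsB$chemical_id)]
  data.frame(chemical_id = callsA$chemical_id,
             active = callsA$active & b, stringsAsFactors = FALSE)
}

#' Repeated random-split cross-validation
#'
#' k independent randomized train/validation splits (repeated random
#' subsampling with an 80:20 default), stratified by activity class by
#' default so the minority class is present in every validation set.
#' Reports per-split metrics plus their mean and SD.
#'
#' @param truth Logical vector of true activity labels (length n).
#' @param trainer Function `(train_idx, test_idx) -> logical predictions`
#'   for the test indices.
#' @param k Number of repeats.
#' @param test_fraction Fraction held out per split.
#' @param seed Seed controlling split membership.
#' @param stratified Stratify splits by class (default TRUE). Unstratified
#'   splits whose validation set is single-class are resampled (with a
#'   message), up to 100 attempts.
#' @return List with `folds` (per-split `vt_eval_report`), `splits`,
#'   `mean`, `sd`.
#' @export
cross_validate <- function(truth, trainer, k = 10L, test_fraction = 0.2,
                           seed = 1L, stratified = TRUE) {
  n <- length(truth)
  stopifnot(n >= 10L, any(truth), any(!truth))
  set.seed(seed)
  n_test <- max(1L, round(test_fraction * n))
  folds <- vector("list", k)
  splits <- vector("list", k)
  for (i in seq_len(k)) {
    if (stratified) {
      pos <- which(truth); neg <- which(!truth)
      n_pos <- max(1L, round(test_fraction * length(pos)))
      test_idx <- c(sample(pos, n_pos),
                    sample(neg, min(length(neg), n_test - n_pos)))
    } else {
      for (attempt in seq_len(100L)) {
        test_idx <- sample.int(n, n_test)
        if (length(unique(truth[test_idx])) == 2L) break
        message("resampling split ", i, ": single-class validation set")
        if (attempt == 100L) stop("could not draw a two-class validation set")
      }
    }
    train_idx <- setdiff(seq_len(n), test_idx)
    pred <- trainer(train_idx, test_idx)
    folds[[i]] <- metrics(confusion_from_calls(pred, truth[test_idx]))
    splits[[i]] <- test_idx
  }
  metric_names <- c("SE", "SP", "PPV", "kappa", "auroc")
  tab <- vapply(folds, function(f) unlist(f[metric_names]),
                numeric(length(metric_names)))
  list(folds = folds, splits = splits,
       mean = rowMeans(tab, na.rm = TRUE),
       sd = apply(tab, 1, stats::sd, na.rm = TRUE))
}

#' Label-shuffle null distribution
#'
#' Permutes the truth labels n times against fixed predictions and
#' recomputes kappa and AUROC each time; under the null both concentrate
#' at 0 and 0.5 respectively.
#'
#' @param pred Logical vector of fixed predictions.
#' @param truth Logical vector of labels to permute.
#' @param n Number of shuffles.
#' @param seed Seed.
#' @return List with `kappa` and `auroc` draws plus `mean`/`sd` summaries.
#' @export
shuffle_null <- function(pred, truth, n = 1000L, seed = 1L) {
  stopifnot(length(pred) == length(truth), n >= 1L)
  set.seed(seed)
  kap <- auc <- numeric(n)
  for (i in seq_len(n)) {
    rep_i <- metrics(confusion_from_calls(pred, sample(truth)))
    kap[i] <- rep_i$kappa
    auc[i] <- rep_i$auroc
  }
  list(kappa = kap, auroc = auc,
       mean = c(kappa = mean(kap, na.rm = TRUE), auroc = mean(auc, na.rm = TRUE)),
       sd = c(kappa = stats::sd(kap, na.rm = TRUE),
              auroc = stats::sd(auc, na.rm = TRUE)))
}

#' Random-search hyperparameter tuning
#'
#' Samples `n_trials` configurations from the search space and scores each
#' with the supplied objective (by convention the cross-validated mean
#' kappa); returns the best configuration and the full trial log.
#'
#' @param space Named list; each element is either a vector of discrete
#'   choices or a `list(min =, max =)` continuous range (optionally
#'   `log = TRUE` for log-uniform sampling).
#' @param objective Function `(config, seed) -> numeric score`.
#' @param n_trials Number of sampled configurations.
#' @param seed Seed controlling the trial sequence.
#' @return List with `best_config`, `best_score`, `log` (data.frame of
#'   configs, per-trial seeds, scores).
#' @export
random_search <- function(space, objective, n_trials = 10L, seed = 1L) {
  if (length(space) == 0L) stop("empty search space")
  set.seed(seed)
  draws <- vector("list", n_trials)
  trial_seeds <- sample.int(1e6, n_trials)
  for (i in seq_len(n_trials)) {
    draws[[i]] <- lapply(space, function(dim) {
      if (is.list(dim)) {
        u <- stats::runif(1)
        if (isTRUE(dim$log)) {
          exp(log(dim$min) + u * (log(dim$max) - log(dim$min)))
        } else dim$min + u * (dim$max - dim$min)
      } else if (length(dim) == 1L) dim else sample(dim, 1)
    })
  }
  scores <- vapply(seq_len(n_trials), function(i) {
    objective(draws[[i]], trial_seeds[i])
  }, 0)
  log <- cbind(data.frame(trial = seq_len(n_trials), seed = trial_seeds,
                          score = scores),
               do.call(rbind, lapply(draws, as.data.frame)))
  best <- which.max(scores)
  list(best_config = draws[[best]], best_score = scores[best], log = log)
}

#' Screening-prioritization arithmetic
#'
#' Given a registry of untested chemicals, an expected active fraction and
#' a model PPV: the expected number of active chemicals is
#' `n_registered * active_fraction` (rounded to the nearest 10), and the
#' screening list needed to capture them at the given precision is
#' `expected_actives / ppv`.
#'
#' @param n_registered Number of registered untested chemicals.
#' @param active_fraction Expected fraction active, in (0, 1].
#' @param ppv Positive predictive value as a fraction in (0, 1].
#' @return List with `expected_actives` and `screening_list_size`.
#' @examples
#' prioritization_estimate(80000, 166 / 1059, 5 / 7)
#' @export
prioritization_estimate <- function(n_registered, active_fraction, ppv) {
  stopifnot(active_fraction > 0, active_fraction <= 1)
  if (ppv <= 0) stop("ppv must be positive")
  expected <- round(n_registered * active_fraction / 10) * 10
  list(expected_actives = expected,
       screening_list_size = expected / ppv)
}
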