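# End-to-end pipeline: synthesize or load data, featurize, train, predict,
# score with AggE, evaluate, optionally form the AND-consensus and the
# label-shuffle null. Every artifact is written with config + seed
# provenance so a rerun with an identical config reproduces it.

#' Default run configuration
#'
#' @param seed Master seed; every stage derives its randomness from it.
#' @param n_chemicals Synthetic dataset size.
#' @param models Which generators to train: subset of
#'   `c("go_zt", "gan_zt")`.
#' @param consensus Evaluate the AND-consensus when both models run.
#' @param shuffle_n Label shuffles for the null (0 disables).
#' @param threshold AggE activity threshold (bits).
#' @param test_fraction Held-out fraction.
#' @param view ViewConfig overrides (list).
#' @param go_zt Go-ZT config overrides (list).
#' @param gan GAN config overrides (list: epochs, disc_width, ...).
#' @param synth Synthetic-data config overrides (list).
#' @return Nested list of class `vt_run_config`.
#' @export
run_config <- function(seed = 1L, n_chemicals = 150L,
                       models = c("go_zt", "gan_zt"), consensus = TRUE,
                       shuffle_n = 0L, threshold = 9.35,
                       test_fraction = 0.2, view = list(), go_zt = list(),
                       gan = list(), synth = list()) {
  structure(list(seed = as.integer(seed),
                 n_chemicals = as.integer(n_chemicals),
                 models = match.arg(models, c("go_zt", "gan_zt"),
                                    several.ok = TRUE),
                 consensus = isTRUE(consensus),
                 shuffle_n = as.integer(shuffle_n), threshold = threshold,
                 test_fraction = test_fraction, view = view, go_zt = go_zt,
                 gan = gan, synth = synth),
            class = "vt_run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file; keys as in [run_config()].
#' @return A `vt_run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

# Deterministic polynomial checksum of the serialized config, used to stamp
# artifacts with their provenance.
config_hash <- function(config) {
  txt <- yaml::as.yaml(unclass(config))
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

report_to_list <- function(rep) {
  c(rep[c("SE", "SP", "PPV", "kappa", "auroc", "auroc_kind")],
    list(confusion = unclass(rep$confusion)))
}

#' Run the full pipeline end to end
#'
#' Synthesize data, split train/test (stratified on the empirical activity
#' label), train the configured generators, predict activity on the
#' held-out chemicals, evaluate, and write all artifacts (config echo,
#' predictions CSV, checkpoints, JSON report) into `outdir`. Any stage
#' failure leaves a `FAILED` marker next to the partial artifacts and
#' rethrows the error.
#'
#' @param config A `vt_run_config`.
#' @param outdir Run directory (created; must not exist or be empty).
#' @return The evaluation report list, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config = run_config(), outdir = tempfile("vtrun")) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  yaml::write_yaml(c(unclass(config), list(config_hash = hash)),
                   file.path(outdir, "config.yaml"))
  tryCatch(
    run_pipeline_stages(config, outdir, hash),
    error = function(e) {
      writeLines(conditionMessage(e), file.path(outdir, "FAILED"))
      stop(e)
    })
}

run_pipeline_stages <- function(config, outdir, hash) {
  scfg <- do.call(synth_config,
                  c(list(n_chemicals = config$n_chemicals, seed = config$seed,
                         threshold = config$threshold), config$synth))
  ds <- synth_dataset(scfg)
  write_synth_dataset(ds, file.path(outdir, "data"))

  vcfg <- do.call(view_config, config$view)
  gcfg <- do.call(go_zt_config,
                  c(list(max_atoms = vcfg$max_atoms_per_view,
                         seed = config$seed), config$go_zt))

  n <- length(ds$molecules)
  truth <- ds$truth$emp_active
  set.seed(config$seed)
  pos <- which(truth); neg <- which(!truth)
  test_idx <- sort(c(sample(pos, max(1L, round(config$test_fraction * length(pos)))),
                     sample(neg, round(config$test_fraction * length(neg)))))
  train_idx <- setdiff(seq_len(n), test_idx)

  pairs <- lapply(train_idx, function(i) {
    list(views = build_views(ds$molecules[[i]], vcfg), tox = ds$tox[[i]])
  })
  test_mols <- ds$molecules[test_idx]
  test_truth <- truth[test_idx]

  report <- list(config_hash = hash, seed = config$seed,
                 n_train = length(train_idx), n_test = length(test_idx))
  calls <- list()
  if ("go_zt" %in% config$models) {
    model <- train_go_zt(pairs, gcfg)
    save_checkpoint(model, file.path(outdir, "go_zt.ckpt"))
    calls$go_zt <- predict_activity(model, test_mols, vcfg, config$threshold)
  }
  if ("gan_zt" %in% config$models) {
    ganc <- do.call(gan_config,
                    c(list(generator = gcfg, seed = config$seed), config$gan))
    gm <- train_gan_zt(pairs, ganc)
    save_checkpoint(gm, file.path(outdir, "gan_zt.ckpt"))
    calls$gan_zt <- predict_activity_gan(gm, test_mols, vcfg, config$threshold)
  }

  for (nm in names(calls)) {
    df <- calls[[nm]]
    df$truth_active <- test_truth[match(df$chemical_id,
                                        ds$truth$chemical_id[test_idx])]
    df$config_hash <- hash
    utils::write.csv(df, file.path(outdir, paste0("predictions_", nm, ".csv")),
                     row.names = FALSE)
    report[[nm]] <- report_to_list(
      metrics(confusion_from_calls(df$active, df$truth_active)))
    if (config$shuffle_n > 0L) {
      nul <- shuffle_null(df$active, df$truth_active, n = config$shuffle_n,
                          seed = config$seed)
      report[[paste0(nm, "_null")]] <- list(mean = as.list(nul$mean),
                                            sd = as.list(nul$sd))
    }
  }
  if (config$consensus && all(c("go_zt", "gan_zt") %in% names(calls))) {
    cons <- consensus_and(calls$go_zt, calls$gan_zt)
    cons$truth_active <- test_truth[match(cons$chemical_id,
                                          ds$truth$chemical_id[test_idx])]
    utils::write.csv(cons, file.path(outdir, "predictions_consensus.csv"),
                     row.names = FALSE)
    report$consensus <- report_to_list(
      metrics(confusion_from_calls(cons$active, cons$truth_active)))
  }
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
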