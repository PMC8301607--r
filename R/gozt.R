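# Go-ZT: the regression-trained generator. A per-view feature network f
# maps each flattened view matrix to a feature vector; the chemical's
# representation is the weighted sum s = sum_i f(v_i) w_i over its views;
# a toxicity network g maps s to the 18-endpoint incidence vector. Trained
# with mean squared error by stochastic gradient descent.

#' Go-ZT configuration
#'
#' Architecture and training settings for the regression generator. The
#' published architecture uses three feature hidden layers and eleven
#' toxicity hidden layers with swish activation on hidden and output
#' layers, batch normalization between layers, no dropout, Gaussian weight
#' init, MSE loss, an SGD optimizer and 75 training epochs; hidden widths
#' were tuned by random search and default to 128 here.
#'
#' @param feature_hidden_layers Hidden layers in the per-view feature net.
#' @param toxicity_hidden_layers Hidden layers in the toxicity net.
#' @param width Hidden-layer width (search-tunable).
#' @param feature_dim Dimension of the per-view feature vector / weighted
#'   sum.
#' @param max_atoms Rows per padded view (atoms per view).
#' @param learning_rate SGD learning rate.
#' @param epochs Training epochs.
#' @param batch_size Chemicals per mini-batch.
#' @param batch_norm Batch normalization between layers (on by default).
#' @param seed Seed for init and batching.
#' @return List of class `vt_gozt_config`.
#' @export
go_zt_config <- function(feature_hidden_layers = 3L,
                         toxicity_hidden_layers = 11L,
                         width = 128L, feature_dim = 32L, max_atoms = 10L,
                         learning_rate = 0.1, epochs = 75L,
                         batch_size = 32L, batch_norm = TRUE, seed = 1L) {
  stopifnot(feature_hidden_layers >= 1L, toxicity_hidden_layers >= 1L,
            epochs >= 1L, width >= 1L, feature_dim >= 1L, max_atoms >= 1L)
  structure(list(feature_hidden_layers = as.integer(feature_hidden_layers),
                 toxicity_hidden_layers = as.integer(toxicity_hidden_layers),
                 width = as.integer(width), feature_dim = as.integer(feature_dim),
                 max_atoms = as.integer(max_atoms),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 batch_norm = isTRUE(batch_norm), seed = as.integer(seed)),
            class = "vt_gozt_config")
}

# Stack a list of vt_viewset into flat view rows + weights + chemical index.
stack_viewsets <- function(viewsets, max_atoms) {
  pads <- lapply(viewsets, pad_to_tensor, max_atoms = max_atoms)
  X <- do.call(rbind, lapply(pads, `[[`, "flat"))
  w <- unlist(lapply(pads, `[[`, "weights"))
  group <- rep(seq_along(pads),
               vapply(pads, function(p) length(p$weights), 0L))
  list(X = X, w = w, group = group)
}

#' Weighted sum of per-view features
#'
#' Computes s_b = sum over views i of chemical b of `feats[i, ] * w[i]`,
#' exactly the weight-scaled sum the generator pools views with.
#'
#' @param feats Matrix, one row per view.
#' @param w View weights.
#' @param group Integer chemical index per view (1..B).
#' @param n_groups Number of chemicals B.
#' @return Matrix B x ncol(feats).
#' @export
weighted_view_sum <- function(feats, w, group, n_groups = max(group)) {
  s <- rowsum(feats * w, group = factor(group, levels = seq_len(n_groups)))
  unname(as.matrix(s))
}

new_generator <- function(cfg) {
  fnet <- mlp_new(c(5L * cfg$max_atoms,
                    rep(cfg$width, cfg$feature_hidden_layers),
                    cfg$feature_dim),
                  out_activation = "swish", use_bn = cfg$batch_norm)
  gnet <- mlp_new(c(cfg$feature_dim,
                    rep(cfg$width, cfg$toxicity_hidden_layers),
                    N_ENDPOINTS),
                  out_activation = "swish", use_bn = cfg$batch_norm)
  structure(list(fnet = fnet, gnet = gnet, config = cfg,
                 loss_history = numeric(0)),
            class = "vt_generator")
}

# One full forward pass through f, weighted sum, g.
generator_forward <- function(model, stacked, training = FALSE) {
  B <- max(stacked$group)
  ff <- mlp_forward(model$fnet, stacked$X, training = training)
  s <- weighted_view_sum(ff$out, stacked$w, stacked$group, B)
  gf <- mlp_forward(model$gnet, s, training = training)
  list(pred = gf$out, s = s, ff = ff, gf = gf)
}

#' Predict toxicity matrices with a trained generator
#'
#' @param model A `vt_generator` (from [train_go_zt()]) or the generator of
#'   a trained GAN.
#' @param viewsets List of `vt_viewset`, one per chemical.
#' @param clip Clip predictions into `[0, 1]` (the AggE interface); raw
#'   regression outputs are returned in attribute `"raw"`.
#' @return Matrix, chemicals x 18.
#' @export
forward_generator <- function(model, viewsets, clip = TRUE) {
  stopifnot(inherits(model, "vt_generator"))
  stacked <- stack_viewsets(viewsets, model$config$max_atoms)
  raw <- generator_forward(model, stacked, training = FALSE)$pred
  rownames(raw) <- vapply(viewsets, function(v) v$molecule_id, "")
  out <- if (clip) pmin(pmax(raw, 0), 1) else raw
  attr(out, "raw") <- raw
  out
}

#' Train the Go-ZT regression generator
#'
#' Minimizes mean squared error between predicted and empirical 18-endpoint
#' incidence vectors by mini-batch SGD for `cfg$epochs` epochs. The
#' per-epoch training loss is recorded; the run is deterministic given
#' `cfg$seed`.
#'
#' @param data List of pairs; each element is `list(views = vt_viewset,
#'   tox = vt_toxmat)`.
#' @param cfg A `vt_gozt_config`.
#' @return A trained `vt_generator` with `loss_history`.
#' @export
train_go_zt <- function(data, cfg = go_zt_config()) {
  stopifnot(length(data) >= 2L)
  set.seed(cfg$seed)
  model <- new_generator(cfg)
  viewsets <- lapply(data, `[[`, "views")
  targets <- do.call(rbind, lapply(data, function(d) d$tox$incidence))
  stacked_all <- stack_viewsets(viewsets, cfg$max_atoms)
  per_chem <- split(seq_along(stacked_all$group), stacked_all$group)
  n <- length(data)

  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
    ep_loss <- 0
    for (idx in batches) {
      rows <- unlist(per_chem[idx], use.names = FALSE)
      st <- list(X = stacked_all$X[rows, , drop = FALSE],
                 w = stacked_all$w[rows],
                 group = match(stacked_all$group[rows], idx))
      Tb <- targets[idx, , drop = FALSE]
      fw <- generator_forward(model, st, training = TRUE)
      model$fnet <- fw$ff$net; model$gnet <- fw$gf$net
      resid <- fw$pred - Tb
      loss <- mean(resid^2)
      if (!is.finite(loss) || loss > 1e8) {
        stop("training loss diverged (", format(loss), ") at epoch ", epoch,
             "; try a smaller learning_rate than ", cfg$learning_rate)
      }
      dPred <- 2 * resid / length(resid)
      bg <- mlp_backward(model$gnet, fw$gf$caches, dPred, training = TRUE)
      dFeats <- bg$dX[st$group, , drop = FALSE] * st$w
      bf <- mlp_backward(model$fnet, fw$ff$caches, dFeats, training = TRUE)
      model$gnet <- mlp_sgd_step(model$gnet, bg$grads, cfg$learning_rate)
      model$fnet <- mlp_sgd_step(model$fnet, bf$grads, cfg$learning_rate)
      ep_loss <- ep_loss + loss * length(idx)
    }
    model$loss_history[epoch] <- ep_loss / n
  }
  model
}

#' Predict activity calls for molecules
#'
#' Composes the whole downstream pipeline: domain filter -> views ->
#' generator forward -> AggE -> threshold classification. Molecules
#' rejected by the domain-of-applicability filter are excluded from the
#' calls and listed (with the triggered rule) in the `"exclusions"`
#' attribute of the result.
#'
#' @param model A trained `vt_generator`.
#' @param molecules List of `vt_molecule`.
#' @param view_cfg A `vt_view_config`.
#' @param threshold AggE activity threshold in bits.
#' @param panel Endpoint panel for AggE.
#' @return Data frame of activity calls (see [classify()]), with attribute
#'   `"exclusions"`.
#' @export
predict_activity <- function(model, molecules, view_cfg = view_config(
                               max_atoms_per_view = model$config$max_atoms),
                             threshold = 9.35, panel = endpoint_panel()) {
  stopifnot(inherits(model, "vt_generator"))
  verdicts <- lapply(molecules, domain_filter)
  ok <- vapply(verdicts, `[[`, TRUE, "accepted")
  excl <- data.frame(
    chemical_id = vapply(molecules[!ok], function(m) m$id, ""),
    reason = vapply(verdicts[!ok], `[[`, "", "reason"),
    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(excl))) {
    message("excluded ", excl$chemical_id[i], ": ", excl$reason[i])
  }
  kept <- molecules[ok]
  if (length(kept) == 0L) {
    calls <- classify(numeric(0), threshold, chemical_id = character(0))
  } else {
    viewsets <- lapply(kept, build_views, cfg = view_cfg)
    pred <- forward_generator(model, viewsets, clip = TRUE)
    agg <- apply(pred, 1, agg_entropy, panel = panel)
    calls <- classify(agg, threshold,
                      chemical_id = vapply(kept, function(m) m$id, ""))
  }
  attr(calls, "exclusions") <- excl
  calls
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a single-file archive bundling config, parameters and
#' loss history.
#'
#' @param model Model object.
#' @param path Checkpoint file path.
#' @return `path` invisibly (`save_checkpoint`); the model
#'   (`load_checkpoint`).
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)
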