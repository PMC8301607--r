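# GAN-ZT: the conditional adversarial trainer. The generator has exactly
# the Go-ZT shape (feature net, weighted sum over views, toxicity net);
# the discriminator is a fully-connected network that scores a
# (weighted-sum feature vector s, toxicity matrix) pair as real or fake.
# The adversarial objective is the least-squares form (MSE to targets
# 1 = real, 0 = fake), with SGD for the generator and Adam for the
# discriminator.

#' GAN-ZT configuration
#'
#' @param generator A `vt_gozt_config` describing the shared generator
#'   shape (epochs/learning-rate fields of that config are ignored here).
#' @param disc_hidden_layers Hidden layers of the discriminator.
#' @param disc_width Discriminator hidden width.
#' @param epochs Adversarial epochs (published run: 2000).
#' @param lr_generator SGD learning rate for the generator.
#' @param lr_discriminator Adam learning rate for the discriminator.
#' @param batch_size Chemicals per mini-batch.
#' @param seed Seed for init and batching.
#' @return List of class `vt_gan_config`.
#' @export
gan_config <- function(generator = go_zt_config(),
                       disc_hidden_layers = 3L, disc_width = 64L,
                       epochs = 2000L, lr_generator = 0.01,
                       lr_discriminator = 1e-3, batch_size = 32L,
                       seed = 1L) {
  stopifnot(epochs >= 1L, disc_hidden_layers >= 1L)
  structure(list(generator = generator,
                 disc_hidden_layers = as.integer(disc_hidden_layers),
                 disc_width = as.integer(disc_width),
                 epochs = as.integer(epochs), lr_generator = lr_generator,
                 lr_discriminator = lr_discriminator,
                 batch_size = as.integer(batch_size), seed = as.integer(seed)),
            class = "vt_gan_config")
}

new_discriminator <- function(cfg) {
  net <- mlp_new(c(cfg$generator$feature_dim + N_ENDPOINTS,
                   rep(cfg$disc_width, cfg$disc_hidden_layers), 1L),
                 out_activation = "linear",
                 use_bn = cfg$generator$batch_norm)
  structure(list(net = net, config = cfg), class = "vt_discriminator")
}

#' Score (features, toxicity matrix) pairs as real or fake
#'
#' @param disc A `vt_discriminator`.
#' @param s Matrix of weighted-sum feature vectors (chemicals x D).
#' @param t Matrix of toxicity vectors (chemicals x 18).
#' @return Numeric vector of realness scores (least-squares targets:
#'   1 real, 0 fake).
#' @export
discriminate <- function(disc, s, t) {
  s <- rbind(s); t <- rbind(t)
  stopifnot(nrow(s) == nrow(t))
  if (ncol(s) + ncol(t) != disc$net$sizes[1]) {
    stop("dimension mismatch: discriminator expects input of size ",
         disc$net$sizes[1])
  }
  drop(mlp_forward(disc$net, cbind(s, t), training = FALSE)$out)
}

#' Train the GAN-ZT conditional adversarial model
#'
#' Alternating updates, one discriminator step then one generator step per
#' mini-batch. The discriminator is trained on stacked (real, generated)
#' pairs with MSE-to-target loss via Adam; the generator is trained via SGD
#' to push the discriminator's score on generated pairs toward the real
#' target, with gradients flowing through both the toxicity path and the
#' shared conditioning features s. Per-epoch generator and discriminator
#' losses are recorded. Training aborts with a diagnostic if either loss
#' exceeds 1e6.
#'
#' @param data List of pairs, as for [train_go_zt()].
#' @param cfg A `vt_gan_config`.
#' @return List of class `vt_ganzt`: `generator` (a `vt_generator`, usable
#'   with [forward_generator()]/[predict_activity()]), `discriminator`,
#'   and `traces` (per-epoch d_loss/g_loss data.frame).
#' @export
train_gan_zt <- function(data, cfg = gan_config()) {
  stopifnot(length(data) >= 2L)
  set.seed(cfg$seed)
  gen <- new_generator(cfg$generator)
  disc <- new_discriminator(cfg)
  adam <- adam_init(disc$net)
  viewsets <- lapply(data, `[[`, "views")
  targets <- do.call(rbind, lapply(data, function(d) d$tox$incidence))
  stacked_all <- stack_viewsets(viewsets, cfg$generator$max_atoms)
  per_chem <- split(seq_along(stacked_all$group), stacked_all$group)
  n <- length(data)
  D <- cfg$generator$feature_dim
  d_trace <- g_trace <- numeric(cfg$epochs)

  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
    d_ep <- g_ep <- 0
    for (idx in batches) {
      rows <- unlist(per_chem[idx], use.names = FALSE)
      st <- list(X = stacked_all$X[rows, , drop = FALSE],
                 w = stacked_all$w[rows],
                 group = match(stacked_all$group[rows], idx))
      B <- length(idx)
      t_real <- targets[idx, , drop = FALSE]

      # --- discriminator step (generator frozen) ---
      fw <- generator_forward(gen, st, training = TRUE)
      Xd <- rbind(cbind(fw$s, t_real), cbind(fw$s, fw$pred))
      y <- c(rep(1, B), rep(0, B))
      df <- mlp_forward(disc$net, Xd, training = TRUE)
      disc$net <- df$net
      score <- drop(df$out)
      d_loss <- mean((score - y)^2)
      dScore <- matrix(2 * (score - y) / length(y), ncol = 1)
      db <- mlp_backward(disc$net, df$caches, dScore, training = TRUE)
      res <- adam_step(disc$net, db$grads, adam, cfg$lr_discriminator)
      disc$net <- res$net; adam <- res$state

      # --- generator step (discriminator frozen, eval-mode stats) ---
      fw <- generator_forward(gen, st, training = TRUE)
      gen$fnet <- fw$ff$net; gen$gnet <- fw$gf$net
      Xg <- cbind(fw$s, fw$pred)
      dg <- mlp_forward(disc$net, Xg, training = FALSE)
      g_score <- drop(dg$out)
      g_loss <- mean((g_score - 1)^2)
      dScore <- matrix(2 * (g_score - 1) / B, ncol = 1)
      dXg <- mlp_backward(disc$net, dg$caches, dScore, training = FALSE)$dX
      ds_cond <- dXg[, seq_len(D), drop = FALSE]
      dt <- dXg[, D + seq_len(N_ENDPOINTS), drop = FALSE]
      bg <- mlp_backward(gen$gnet, fw$gf$caches, dt, training = TRUE)
      ds <- bg$dX + ds_cond
      dFeats <- ds[st$group, , drop = FALSE] * st$w
      bf <- mlp_backward(gen$fnet, fw$ff$caches, dFeats, training = TRUE)
      gen$gnet <- mlp_sgd_step(gen$gnet, bg$grads, cfg$lr_generator)
      gen$fnet <- mlp_sgd_step(gen$fnet, bf$grads, cfg$lr_generator)

      if (!is.finite(d_loss) || !is.finite(g_loss) ||
          d_loss > 1e6 || g_loss > 1e6) {
        stop("adversarial training diverged at epoch ", epoch,
             " (d_loss = ", format(d_loss), ", g_loss = ", format(g_loss),
             "); reduce the learning rates")
      }
      d_ep <- d_ep + d_loss * B
      g_ep <- g_ep + g_loss * B
    }
    d_trace[epoch] <- d_ep / n
    g_trace[epoch] <- g_ep / n
  }
  gen$loss_history <- g_trace
  structure(list(generator = gen, discriminator = disc,
                 traces = data.frame(epoch = seq_len(cfg$epochs),
                                     d_loss = d_trace, g_loss = g_trace),
                 config = cfg),
            class = "vt_ganzt")
}

#' Activity prediction with a trained GAN-ZT
#'
#' Identical pipeline to [predict_activity()] (domain filter -> views ->
#' generator -> AggE -> threshold), using the adversarially trained
#' generator.
#'
#' @param model A `vt_ganzt`.
#' @inheritParams predict_activity
#' @return Data frame of activity calls with attribute `"exclusions"`.
#' @export
predict_activity_gan <- function(model, molecules,
                                 view_cfg = view_config(
                                   max_atoms_per_view =
                                     model$generator$config$max_atoms),
                                 threshold = 9.35, panel = endpoint_panel()) {
  stopifnot(inherits(model, "vt_ganzt"))
  predict_activity(model$generator, molecules, view_cfg, threshold, panel)
}
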