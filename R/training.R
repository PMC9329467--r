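#' Training configuration
#'
#' Adversarial training hyperparameters. Defaults follow the published
#' protocol: Adam with beta1 = 0.9, beta2 = 0.999, learning rate 1e-5,
#' batch size 5, 400 epochs for the baseline translator and 200 for the
#' style-modulated one, and an L1 regularisation weight of 100 (the
#' canonical choice for sketch-to-image translation; the weight trades
#' adversarial sharpness against per-pixel fidelity to the paired target).
#'
#' @param learning_rate Adam learning rate.
#' @param beta1,beta2 Adam moment decays.
#' @param epochs Number of passes over the paired dataset (>= 1).
#' @param batch_size Minibatch size (>= 1).
#' @param lambda_l1 Weight of the L1 term in the generator objective (>= 0).
#' @param seed Integer seed governing shuffling and latent draws.
#' @param checkpoint_dir Optional directory for per-epoch checkpoints.
#' @return List of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-5, beta1 = 0.9, beta2 = 0.999,
                         epochs = 400L, batch_size = 5L, lambda_l1 = 100,
                         seed = 0L, checkpoint_dir = NULL) {
  if (epochs < 1L) stop("epochs must be >= 1")
  if (batch_size < 1L) stop("batch_size must be >= 1")
  if (lambda_l1 < 0) stop("lambda_l1 must be >= 0")
  structure(list(learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lambda_l1 = lambda_l1, seed = as.integer(seed),
                 checkpoint_dir = checkpoint_dir),
            class = "train_config")
}

clamp_scores <- function(s, eps = 1e-7) ag_clamp(s, eps, 1 - eps)

#' Discriminator loss
#'
#' Negated conditional-GAN value: `-[mean log D(x|y) + mean log(1 -
#' D(G(z|y)))]`. At the symmetric equilibrium D = 0.5 everywhere this
#' equals `2 log 2`. Scores are clamped to `[1e-7, 1 - 1e-7]` for numerical
#' stability.
#'
#' @param real_scores,fake_scores Probabilities in `(0,1)` (arrays or graph
#'   nodes).
#' @return Scalar loss (a graph node if inputs are nodes).
#' @export
d_loss <- function(real_scores, fake_scores) {
  if (length(ag_value(real_scores)) == 0L || length(ag_value(fake_scores)) == 0L)
    stop("empty score batch")
  lr_ <- ag_mean(ag_log(clamp_scores(real_scores)))
  lf_ <- ag_mean(ag_log(ag_sub(1, clamp_scores(fake_scores))))
  ag_scale(ag_add(lr_, lf_), -1)
}

#' Generator loss
#'
#' Non-saturating adversarial term plus weighted L1 reconstruction:
#' `-mean log D(G(z|y)) + lambda * mean |x - G(z|y)|`. At D = 0.5 the
#' adversarial part equals `log 2`.
#'
#' @param fake_scores Discriminator probabilities on generated images.
#' @param generated,real Images in `[-1, 1]`, same shape.
#' @param lambda_l1 L1 weight (>= 0).
#' @return Scalar loss (a graph node if inputs are nodes).
#' @export
g_loss <- function(fake_scores, generated, real, lambda_l1 = 100) {
  parts <- g_loss_parts(fake_scores, generated, real, lambda_l1)
  ag_add(parts$adv, ag_scale(parts$l1, lambda_l1))
}

g_loss_parts <- function(fake_scores, generated, real, lambda_l1) {
  if (!identical(dim(ag_value(generated)), dim(ag_value(real))))
    stop("generated/real shape mismatch")
  adv <- ag_scale(ag_mean(ag_log(clamp_scores(fake_scores))), -1)
  l1 <- ag_mean(ag_abs(ag_sub(real, generated)))
  list(adv = adv, l1 = l1)
}

set_requires <- function(model, flag) {
  for (p in model$params) p$requires <- flag
  invisible(model)
}

#' Train a translator adversarially
#'
#' Alternating one-discriminator-step / one-generator-step training on
#' paired (sketch, CT) images, with seeded shuffling, fresh standard-normal
#' latents per sample per step for style generators, optional per-epoch
#' checkpoints, and a per-epoch loss history. Aborts with a diagnostic if a
#' loss becomes non-finite.
#'
#' @param pairs List of pairs: each `list(ct = 8-bit matrix, sketch =
#'   binary matrix)` (as produced by [voi_to_pairs()]).
#' @param generator Generator model (baseline or style).
#' @param discriminator Discriminator model.
#' @param config A [train_config()].
#' @return List with `generator`, `discriminator`, `history` (data frame:
#'   epoch, d_loss, g_adv, g_l1, wall_secs).
#' @export
train_pix2pix <- function(pairs, generator, discriminator, config = train_config()) {
  if (!inherits(config, "train_config")) stop("config must be a train_config")
  n <- length(pairs)
  if (n == 0L) stop("empty training dataset")
  cfg <- generator$config
  H <- cfg$image_size
  sks <- vapply(pairs, function(p) sketch_to_model(p$sketch), array(0, c(H, H)))
  cts <- vapply(pairs, function(p) img_to_model(p$ct), array(0, c(H, H)))
  dim(sks) <- c(H, H, 1L, n); dim(cts) <- c(H, H, 1L, n)
  adam_g <- opt_adam(model_params(generator), lr = config$learning_rate,
                     beta1 = config$beta1, beta2 = config$beta2)
  adam_d <- opt_adam(model_params(discriminator), lr = config$learning_rate,
                     beta1 = config$beta1, beta2 = config$beta2)
  hist <- vector("list", config$epochs)
  local_seed(config$seed, {
    for (ep in seq_len(config$epochs)) {
      t0 <- Sys.time()
      ord <- sample.int(n)
      sums <- c(d = 0, adv = 0, l1 = 0); nb <- 0L
      for (b0 in seq(1L, n, by = config$batch_size)) {
        idx <- ord[b0:min(b0 + config$batch_size - 1L, n)]
        y <- sks[, , , idx, drop = FALSE]
        x <- cts[, , , idx, drop = FALSE]
        B <- length(idx)
        lat <- if (cfg$use_style) matrix(stats::rnorm(cfg$latent_dim * B), cfg$latent_dim, B)

        # discriminator step (inference-mode generator forward: no graph)
        fake <- generator_forward(generator, y, latent = lat, grad = FALSE)
        ld <- d_loss(discriminator_forward(discriminator, y, x, grad = TRUE),
                     discriminator_forward(discriminator, y, fake, grad = TRUE))
        if (!is.finite(ag_value(ld))) stop("discriminator loss diverged (NaN/Inf) at epoch ", ep)
        ag_backward(ld)
        adam_d$step()

        # generator step: fresh latents; D provides gradients but is not updated
        lat2 <- if (cfg$use_style) matrix(stats::rnorm(cfg$latent_dim * B), cfg$latent_dim, B)
        set_requires(discriminator, FALSE)
        fake_n <- generator_forward(generator, y, latent = lat2, grad = TRUE)
        parts <- g_loss_parts(discriminator_forward(discriminator, y, fake_n, grad = TRUE),
                              fake_n, x, config$lambda_l1)
        lg <- ag_add(parts$adv, ag_scale(parts$l1, config$lambda_l1))
        if (!is.finite(ag_value(lg))) stop("generator loss diverged (NaN/Inf) at epoch ", ep)
        ag_backward(lg)
        set_requires(discriminator, TRUE)
        adam_g$step()

        sums <- sums + c(ag_value(ld), ag_value(parts$adv), ag_value(parts$l1))
        nb <- nb + 1L
      }
      hist[[ep]] <- data.frame(epoch = ep, d_loss = sums[1] / nb,
                               g_adv = sums[2] / nb, g_l1 = sums[3] / nb,
                               wall_secs = as.numeric(Sys.time() - t0, units = "secs"))
      if (!is.null(config$checkpoint_dir)) {
        dir.create(config$checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
        save_bundle(list(generator = generator, discriminator = discriminator,
                         epoch = ep),
                    file.path(config$checkpoint_dir, sprintf("epoch_%04d.rds", ep)))
      }
    }
  })
  history <- do.call(rbind, hist)
  rownames(history) <- NULL
  list(generator = generator, discriminator = discriminator, history = history)
}
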