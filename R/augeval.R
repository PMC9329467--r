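# Data-augmentation evaluation: generate labeled images from class-wise edge
# sets, pretrain a classifier on them, fine-tune its fully connected layers
# on real images, and score with repeated stratified cross-validation.

#' Classifier training configuration
#'
#' Defaults follow the published augmentation protocol: SGD throughout;
#' pretraining on generated images at learning rate 1e-5 for 100 epochs
#' with batch size 32; fine-tuning of the fully connected layers only on
#' real images at 1e-4 for 100 epochs with batch size 8.
#'
#' @param pretrain_lr,pretrain_epochs,pretrain_batch Pretraining phase.
#' @param finetune_lr,finetune_epochs,finetune_batch Fine-tuning phase.
#' @param seed Integer seed.
#' @return List of class `classifier_config`.
#' @export
classifier_config <- function(pretrain_lr = 1e-5, pretrain_epochs = 100L,
                              pretrain_batch = 32L, finetune_lr = 1e-4,
                              finetune_epochs = 100L, finetune_batch = 8L,
                              seed = 0L) {
  stopifnot(pretrain_lr > 0, finetune_lr > 0, pretrain_epochs >= 0,
            finetune_epochs >= 1, pretrain_batch >= 1, finetune_batch >= 1)
  structure(list(pretrain_lr = pretrain_lr, pretrain_epochs = as.integer(pretrain_epochs),
                 pretrain_batch = as.integer(pretrain_batch),
                 finetune_lr = finetune_lr, finetune_epochs = as.integer(finetune_epochs),
                 finetune_batch = as.integer(finetune_batch), seed = as.integer(seed)),
            class = "classifier_config")
}

#' Build a small convolutional classifier
#'
#' AlexNet-like layout scaled to desk size: a stack of 3x3 stride-2
#' convolutions (instance norm + leaky-ReLU) followed by two fully
#' connected layers. Convolutional parameters are named `conv*` and dense
#' ones `fc*`; fine-tuning restricted to the fully connected layers relies
#' on this split.
#'
#' @param image_size Input side (must be divisible by `2^n_conv`).
#' @param n_classes Number of output classes.
#' @param base_channels First-stage channels (default 8).
#' @param n_conv Number of conv stages (default 3).
#' @param hidden Width of the hidden dense layer (default 64).
#' @param seed Weight seed.
#' @return Classifier model object.
#' @export
build_classifier <- function(image_size = 32L, n_classes = 3L, base_channels = 8L,
                             n_conv = 3L, hidden = 64L, seed = 0L) {
  if (image_size %% 2L^n_conv != 0L) stop("image_size must be divisible by 2^n_conv")
  model <- new.env(parent = emptyenv())
  model$params <- list()
  model$config <- list(image_size = as.integer(image_size), n_classes = as.integer(n_classes),
                       base_channels = as.integer(base_channels), n_conv = as.integer(n_conv),
                       hidden = as.integer(hidden))
  local_seed(seed, {
    cin <- 1L
    for (i in seq_len(n_conv)) {
      cout <- base_channels * 2L^(i - 1L)
      model$params[[paste0("conv", i, "_W")]] <- ag_leaf(winit(3L, 3L, cin, cout))
      model$params[[paste0("conv", i, "_b")]] <- ag_leaf(numeric(cout))
      cin <- cout
    }
    flat <- (image_size %/% 2L^n_conv)^2 * cin
    model$params[["fc1_W"]] <- ag_leaf(winit(hidden, flat) * 2)
    model$params[["fc1_b"]] <- ag_leaf(numeric(hidden))
    model$params[["fc2_W"]] <- ag_leaf(winit(n_classes, hidden) * 2)
    model$params[["fc2_b"]] <- ag_leaf(numeric(n_classes))
  })
  model$type <- "classifier"
  class(model) <- c("sk_classifier", "sk_model")
  model
}

classifier_forward <- function(model, images, grad = FALSE) {
  x <- images
  for (i in seq_len(model$config$n_conv)) {
    x <- ag_conv2d(x, pget(model, paste0("conv", i, "_W"), grad),
                   pget(model, paste0("conv", i, "_b"), grad), stride = 2L, pad = 1L)
    x <- ag_instnorm(x)
    x <- ag_lrelu(x, 0.2)
  }
  h <- ag_lrelu(ag_linear(ag_flatten(x), pget(model, "fc1_W", grad),
                          pget(model, "fc1_b", grad)), 0.2)
  ag_linear(h, pget(model, "fc2_W", grad), pget(model, "fc2_b", grad))
}

#' Predict classes for a set of images
#'
#' @param model Classifier from [build_classifier()].
#' @param images List of 8-bit image matrices.
#' @return Integer class indices (1-based).
#' @export
predict_classifier <- function(model, images) {
  H <- model$config$image_size
  x <- array(vapply(images, img_to_model, matrix(0, H, H)), c(H, H, 1L, length(images)))
  logits <- ag_value(classifier_forward(model, x, grad = FALSE))
  max.col(t(logits))
}

# SGD training of (a subset of) classifier parameters on labeled 8-bit images
train_classifier <- function(model, images, labels, lr, epochs, batch,
                             param_names = names(model$params), seed = 0L) {
  n <- length(images)
  if (epochs == 0L || n == 0L) return(invisible(model))
  H <- model$config$image_size
  xs <- array(vapply(images, img_to_model, matrix(0, H, H)), c(H, H, 1L, n))
  trainable <- model$params[param_names]
  frozen <- setdiff(names(model$params), param_names)
  for (nm in frozen) model$params[[nm]]$requires <- FALSE
  opt <- opt_sgd(trainable, lr = lr)
  local_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      for (b0 in seq(1L, n, by = batch)) {
        idx <- ord[b0:min(b0 + batch - 1L, n)]
        loss <- ag_softmax_xent(
          classifier_forward(model, xs[, , , idx, drop = FALSE], grad = TRUE),
          labels[idx])
        ag_backward(loss)
        opt$step()
      }
    }
  })
  for (nm in frozen) model$params[[nm]]$requires <- TRUE
  invisible(model)
}

#' Generate a labeled augmentation set from class-wise edges
#'
#' For each class, every edge image conditions the generator; style models
#' draw `n_per_edge` fresh latents per edge (count = n_edges x n_per_edge),
#' while the one-to-one baseline generates a single image per edge (with a
#' warning if `n_per_edge > 1` was requested, since the copies would be
#' exact duplicates).
#'
#' @param model Generator model.
#' @param edges_by_class Named list: class -> list of binary sketch
#'   matrices.
#' @param n_per_edge Images per edge (>= 1).
#' @param seed Integer seed for latent draws.
#' @param chunk Number of images per generator batch (default 48).
#' @return List with `images` (8-bit matrices), `labels` (class strings).
#' @export
generate_augmented_set <- function(model, edges_by_class, n_per_edge = 1L,
                                   seed = 0L, chunk = 48L) {
  if (n_per_edge < 1L) stop("n_per_edge must be >= 1")
  cfg <- model$config
  if (!cfg$use_style && n_per_edge > 1L) {
    warning("baseline generator is one-to-one; generating 1 image per edge ",
            "(deduplicated from the requested ", n_per_edge, ")")
    n_per_edge <- 1L
  }
  images <- list(); labels <- character(0)
  local_seed(seed, {
    for (cls in names(edges_by_class)) {
      edges <- edges_by_class[[cls]]
      if (length(edges) == 0L) next
      # expand to (edge, replicate) jobs and process in batches
      jobs_edge <- rep(seq_along(edges), each = n_per_edge)
      for (b0 in seq(1L, length(jobs_edge), by = chunk)) {
        jb <- jobs_edge[b0:min(b0 + chunk - 1L, length(jobs_edge))]
        B <- length(jb)
        sk <- array(0, c(cfg$image_size, cfg$image_size, 1L, B))
        for (k in seq_len(B)) sk[, , 1L, k] <- sketch_to_model(edges[[jb[k]]])
        lat <- if (cfg$use_style)
          matrix(stats::rnorm(cfg$latent_dim * B), cfg$latent_dim, B)
        out <- generator_forward(model, sk, latent = lat, grad = FALSE)
        for (k in seq_len(B)) {
          img <- model_to_img(out[, , 1L, k])
          storage.mode(img) <- "integer"     # 8-bit content; halves memory
          images[[length(images) + 1L]] <- img
        }
        labels <- c(labels, rep(cls, B))
      }
    }
  })
  list(images = images, labels = labels)
}

#' Pretrain on generated images, then fine-tune on real ones
#'
#' Trains all classifier layers on the generated set, then freezes the
#' convolutional stack and updates only the fully connected layers on the
#' real set (both phases SGD). With `pretrain_epochs = 0` this reduces to
#' fine-tuning from random weights.
#'
#' @param generated_set,real_set Lists with `images` and `labels`; all
#'   classes must appear in each non-skipped phase.
#' @param config A [classifier_config()].
#' @param classifier Optional pre-built classifier (built fresh otherwise).
#' @param classes Class-label ordering (defaults to sorted union).
#' @return The trained classifier; attribute `"classes"` maps indices to
#'   labels.
#' @export
pretrain_then_finetune <- function(generated_set, real_set,
                                   config = classifier_config(),
                                   classifier = NULL, classes = NULL) {
  classes <- classes %||% sort(unique(c(generated_set$labels, real_set$labels)))
  if (length(real_set$images) == 0L) stop("empty real set")
  if (config$pretrain_epochs > 0L) {
    if (!all(classes %in% generated_set$labels)) stop("missing class in generated set")
  }
  if (!all(classes %in% real_set$labels)) stop("missing class in real set")
  H <- dim(real_set$images[[1]])[1]
  model <- classifier %||% build_classifier(image_size = H,
                                            n_classes = length(classes),
                                            seed = config$seed)
  if (config$pretrain_epochs > 0L) {
    train_classifier(model, generated_set$images,
                     match(generated_set$labels, classes),
                     lr = config$pretrain_lr, epochs = config$pretrain_epochs,
                     batch = config$pretrain_batch, seed = config$seed + 1L)
  }
  fc <- grep("^fc", names(model$params), value = TRUE)
  train_classifier(model, real_set$images, match(real_set$labels, classes),
                   lr = config$finetune_lr, epochs = config$finetune_epochs,
                   batch = config$finetune_batch, param_names = fc,
                   seed = config$seed + 2L)
  attr(model, "classes") <- classes
  model
}

# stratified fold assignment at the tumor (VOI) level
stratified_folds <- function(labels, n_folds, seed) {
  fold <- integer(length(labels))
  local_seed(seed, {
    for (cls in unique(labels)) {
      idx <- which(labels == cls)
      if (length(idx) < n_folds) stop("class ", cls, " smaller than fold count")
      fold[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
    }
  })
  fold
}

#' Repeated stratified cross-validation of augmented pretraining
#'
#' Runs `n_repeats` iterations of `n_folds`-fold cross-validation (default
#' 3 x 3 = 9 evaluations). Folds are stratified by class at the tumor
#' level, so no image derived from a held-out tumor ever enters its fold's
#' training inputs. When `generated_set` is NULL the classifier is trained
#' on real images only (all layers, fine-tune hyperparameters) -- the
#' no-pretraining baseline; otherwise each fold pretrains on the generated
#' set and fine-tunes on its real training folds.
#'
#' @param real_set List with `images`, `labels`, and `voi_id` (one entry
#'   per tumor).
#' @param generated_set Optional list with `images`, `labels`.
#' @param config A [classifier_config()].
#' @param n_repeats,n_folds Repetition and fold counts (defaults 3, 3).
#' @return List with `per_fold_acc`, `mean`, `sd`, `per_fold_train_acc`,
#'   `train_mean` (memorisation check on the training folds), `counts`.
#' @export
cross_validate <- function(real_set, generated_set = NULL,
                           config = classifier_config(),
                           n_repeats = 3L, n_folds = 3L) {
  classes <- sort(unique(real_set$labels))
  accs <- tr_accs <- numeric(0)
  for (r in seq_len(n_repeats)) {
    fold <- stratified_folds(real_set$labels, n_folds, seed = config$seed + 1000L * r)
    for (f in seq_len(n_folds)) {
      tr <- which(fold != f); te <- which(fold == f)
      cfg_f <- config
      cfg_f$seed <- config$seed + 1000L * r + f
      if (is.null(generated_set)) {
        # no-pretraining baseline: all layers trained on real images only
        H <- dim(real_set$images[[1]])[1]
        model <- build_classifier(image_size = H, n_classes = length(classes),
                                  seed = cfg_f$seed)
        train_classifier(model, real_set$images[tr],
                         match(real_set$labels[tr], classes),
                         lr = cfg_f$finetune_lr, epochs = cfg_f$finetune_epochs,
                         batch = cfg_f$finetune_batch, seed = cfg_f$seed + 2L)
        attr(model, "classes") <- classes
      } else {
        model <- pretrain_then_finetune(
          generated_set,
          list(images = real_set$images[tr], labels = real_set$labels[tr]),
          config = cfg_f, classes = classes)
      }
      pred <- predict_classifier(model, real_set$images[te])
      accs <- c(accs, mean(classes[pred] == real_set$labels[te]))
      pred_tr <- predict_classifier(model, real_set$images[tr])
      tr_accs <- c(tr_accs, mean(classes[pred_tr] == real_set$labels[tr]))
    }
  }
  list(per_fold_acc = accs, mean = mean(accs), sd = stats::sd(accs),
       per_fold_train_acc = tr_accs, train_mean = mean(tr_accs),
       counts = table(real_set$labels))
}
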