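mk_edges <- function(nA, nB = NULL) {
  sk <- lapply(fx_pairs(32L), `[[`, "sketch")
  out <- list(ADC_like = sk[seq_len(nA)])
  if (!is.null(nB)) out$SCC_like <- sk[seq_len(nB)]
  out
}

test_that("generated-set counts obey n_edges x n_per_edge exactly", {
  gs <- build_style_generator(fx_cfg(32L, style = TRUE), seed = 1)
  aug <- generate_augmented_set(gs, mk_edges(3, 2), n_per_edge = 4, seed = 2)
  expect_equal(as.vector(table(aug$labels)[c("ADC_like", "SCC_like")]),
               c(12L, 8L))
  expect_length(aug$images, 20L)
  expect_identical(aug, generate_augmented_set(gs, mk_edges(3, 2), 4, seed = 2))
  expect_length(generate_augmented_set(gs, list(A = list()), 3)$images, 0L)
  expect_error(generate_augmented_set(gs, mk_edges(2), n_per_edge = 0), ">= 1")
})

test_that("the one-to-one baseline deduplicates multi-latent requests", {
  g0 <- build_generator(fx_cfg(32L), seed = 1)
  expect_warning(aug <- generate_augmented_set(g0, mk_edges(3), n_per_edge = 5),
                 "one-to-one")
  expect_length(aug$images, 3L)
})

test_that("fine-tuning updates only the fully connected layers", {
  set.seed(6)
  imgs <- lapply(1:12, function(i) matrix((i %% 3) * 80 + sample(0:30, 1024, TRUE), 32, 32))
  labs <- rep(c("ADC_like", "SCC_like", "SCLC_like"), 4)
  cfg <- classifier_config(pretrain_lr = 1e-3, pretrain_epochs = 3,
                           finetune_lr = 1e-3, finetune_epochs = 3,
                           pretrain_batch = 4, finetune_batch = 4, seed = 1)
  model <- build_classifier(32L, 3L, seed = 1)
  # run pretraining only, snapshot conv weights, then fine-tune
  cfg0 <- cfg; cfg0$finetune_epochs <- 1L
  m <- pretrain_then_finetune(list(images = imgs, labels = labs),
                              list(images = imgs, labels = labs), cfg,
                              classifier = model)
  conv_names <- grep("^conv", names(m$params), value = TRUE)
  snap <- lapply(m$params[conv_names], function(p) p$value)
  fc_snap <- lapply(m$params[grep("^fc", names(m$params))], function(p) p$value)
  # another fine-tune pass must leave conv weights bit-identical
  sketch2ct:::train_classifier(m, imgs, match(labs, sort(unique(labs))),
                               lr = 1e-3, epochs = 2, batch = 4,
                               param_names = grep("^fc", names(m$params), value = TRUE),
                               seed = 3)
  expect_identical(lapply(m$params[conv_names], function(p) p$value), snap)
  expect_false(identical(lapply(m$params[grep("^fc", names(m$params))],
                                function(p) p$value), fc_snap))
})

test_that("zero pretraining epochs reduce to the fine-tune-only limit", {
  set.seed(7)
  imgs <- lapply(1:9, function(i) matrix(sample(0:255, 1024, TRUE), 32, 32))
  labs <- rep(c("a", "b", "c"), 3)
  cfg <- classifier_config(pretrain_epochs = 0, finetune_lr = 1e-3,
                           finetune_epochs = 2, finetune_batch = 3, seed = 5)
  m1 <- pretrain_then_finetune(list(images = list(), labels = character(0)),
                               list(images = imgs, labels = labs), cfg)
  m2 <- build_classifier(32L, 3L, seed = cfg$seed)
  sketch2ct:::train_classifier(m2, imgs, match(labs, c("a", "b", "c")),
                               lr = cfg$finetune_lr, epochs = cfg$finetune_epochs,
                               batch = cfg$finetune_batch,
                               param_names = grep("^fc", names(m2$params), value = TRUE),
                               seed = cfg$seed + 2L)
  expect_equal(lapply(m1$params, function(p) p$value),
               lapply(m2$params, function(p) p$value))
})

test_that("missing classes are rejected", {
  imgs <- lapply(1:4, function(i) matrix(0, 32, 32))
  expect_error(pretrain_then_finetune(
    list(images = imgs, labels = rep("a", 4)),
    list(images = imgs, labels = rep(c("a", "b"), 2)),
    classifier_config(pretrain_epochs = 1, finetune_epochs = 1)),
    "missing class")
})

test_that("folds are stratified, deterministic, and leak-free at the tumor level", {
  labs <- rep(c("a", "b", "c"), each = 6)
  f1 <- sketch2ct:::stratified_folds(labs, 3, seed = 1)
  f2 <- sketch2ct:::stratified_folds(labs, 3, seed = 1)
  expect_identical(f1, f2)
  expect_setequal(unique(f1), 1:3)
  for (cl in unique(labs)) expect_equal(as.vector(table(f1[labs == cl])), rep(2L, 3))
  # each tumor appears in exactly one fold: train/test indices are disjoint
  for (f in 1:3) expect_length(intersect(which(f1 == f), which(f1 != f)), 0L)
  expect_error(sketch2ct:::stratified_folds(c("a", "a", "b"), 3, 1), "smaller")
})

test_that("a constant classifier scores at chance on balanced data", {
  set.seed(8)
  imgs <- lapply(1:12, function(i) matrix(sample(0:255, 1024, TRUE), 32, 32))
  labs <- rep(c("a", "b", "c"), 4)
  m <- build_classifier(32L, 3L, seed = 1)
  m$params$fc2_W$value <- m$params$fc2_W$value * 0
  m$params$fc2_b$value <- c(1, 0, 0)
  pred <- predict_classifier(m, imgs)
  expect_true(all(pred == 1L))
  expect_equal(mean(c("a", "b", "c")[pred] == labs), 1 / 3)
})
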