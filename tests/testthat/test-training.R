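# Stratified splitting and supervised training of the MIL stack.

make_manifest <- function(n1, n0) {
  data.frame(bag_id = sprintf("b%03d", seq_len(n1 + n0)),
             label = c(rep(1, n1), rep(0, n0)))
}

test_that("stratified split reproduces the study cohort sizes", {
  m <- make_manifest(163, 138)
  sp <- split_stratified(m, c(0.7, 0.1, 0.2), seed = 1)
  expect_equal(length(sp$train), 211)
  expect_equal(length(sp$validation), 30)
  expect_equal(length(sp$test), 60)
  # per-class arithmetic: round(.7*163)=114, round(.1*163)=16, rest 33;
  # round(.7*138)=97, round(.1*138)=14, rest 27
  cnt <- sp$counts
  expect_equal(as.integer(cnt$train), c(97, 114))
  expect_equal(as.integer(cnt$validation), c(14, 16))
  expect_equal(as.integer(cnt$test), c(27, 33))
  # disjoint and exhaustive
  all_ids <- c(sp$train, sp$validation, sp$test)
  expect_equal(sort(all_ids), sort(m$bag_id))
})

test_that("split rounding rule: 10 bags, 5/5, ratios 80:10:10", {
  # per class: round(4.0)=4 train, round(0.5)=1 validation (half-up),
  # remainder 0 test -> totals (8, 2, 0)
  m <- make_manifest(5, 5)
  sp <- split_stratified(m, c(0.8, 0.1, 0.1), seed = 3)
  expect_equal(length(sp$train), 8)
  expect_equal(length(sp$validation), 2)
  expect_equal(length(sp$test), 0)
})

test_that("splits are seeded, reproducible, and row-order invariant", {
  m <- make_manifest(20, 15)
  s1 <- split_stratified(m, seed = 9)
  s2 <- split_stratified(m, seed = 9)
  expect_identical(s1$train, s2$train)
  expect_identical(s1$test, s2$test)
  shuffled <- m[sample(nrow(m)), ]
  s3 <- split_stratified(shuffled, seed = 9)
  expect_identical(sort(s1$train), sort(s3$train))
  expect_identical(sort(s1$validation), sort(s3$validation))
  s4 <- split_stratified(m, seed = 10)
  expect_false(identical(sort(s1$train), sort(s4$train)))
})

test_that("split precondition errors", {
  m <- make_manifest(5, 5)
  expect_error(split_stratified(m, c(0.5, 0.5, 0.5)), "sum to 1")
  expect_error(split_stratified(m, c(0.7, 0.3, 0)), "positive")
  expect_error(split_stratified(make_manifest(2, 8)), "at least one per split")
  m$label[1] <- NA
  expect_error(split_stratified(m), "labelled")
})

test_that("training defaults echo the published hyperparameters", {
  ctrl <- dmil_control()
  expect_equal(ctrl$learning_rate, 1e-5)
  expect_equal(ctrl$batch_bags, 32L)
  expect_equal(ctrl$epochs, 50L)
  expect_equal(ctrl$optimizer, "adam")
  expect_equal(ctrl$loss, "bce")
})

test_that("training reduces the loss on separable embedding bags", {
  co <- generate_embedding_cohort(synthetic_config(
    n_bags = 60, noise_sd = 1, signal_effect = 4, signal_fraction = 1,
    n_instances = 16, embed_dim = 8, seed = 51))
  fit <- dmil(co$bags, co$labels, pooling = "attention", backbone = NULL,
              control = dmil_control(epochs = 20, learning_rate = 1e-3,
                                     seed = 5))
  h <- fit$history
  expect_equal(nrow(h), 20)
  expect_lt(tail(h$train_loss, 1), h$train_loss[1])
})

test_that("training is deterministic given seed and data", {
  co <- generate_embedding_cohort(synthetic_config(
    n_bags = 20, noise_sd = 1, signal_effect = 3, n_instances = 8,
    embed_dim = 4, seed = 52))
  ctrl <- dmil_control(epochs = 4, learning_rate = 1e-3, seed = 8)
  f1 <- dmil(co$bags, co$labels, backbone = NULL, control = ctrl)
  f2 <- dmil(co$bags, co$labels, backbone = NULL, control = ctrl)
  expect_identical(f1$history, f2$history)
  expect_identical(coef(f1), coef(f2))
})

test_that("zero learning rate leaves parameters unchanged", {
  co <- generate_embedding_cohort(synthetic_config(
    n_bags = 12, noise_sd = 1, signal_effect = 3, n_instances = 8,
    embed_dim = 4, seed = 53))
  fit <- dmil(co$bags, co$labels, pooling = "attention", backbone = NULL,
              control = dmil_control(epochs = 3, learning_rate = 0, seed = 2))
  # head starts at zero and cannot move -> every score is exactly 0.5
  expect_true(all(fit$fitted == 0.5))
  expect_true(all(coef(fit)$head$weight == 0))
  expect_equal(coef(fit)$head$bias, 0)
})

test_that("prediction is deterministic and validates compatibility", {
  co <- generate_embedding_cohort(synthetic_config(
    n_bags = 16, noise_sd = 1, signal_effect = 3, n_instances = 8,
    embed_dim = 4, seed = 54))
  fit <- dmil(co$bags, co$labels, backbone = NULL,
              control = dmil_control(epochs = 2, learning_rate = 1e-3))
  p1 <- predict(fit, co$bags[1:3])
  p2 <- predict(fit, co$bags[1:3])
  expect_identical(p1, p2)
  expect_true(all(p1 >= 0 & p1 <= 1))
  wrongD <- list(matrix(0, 8, 5))
  expect_error(predict(fit, wrongD), "does not match")
  # single-class training set refused
  expect_error(dmil(co$bags[co$labels == 1], rep(1, sum(co$labels == 1)),
                    backbone = NULL), "single class")
})

test_that("a trained model separates held-out separable embedding bags", {
  cfg <- synthetic_config(n_bags = 120, noise_sd = 1, signal_effect = 4,
                          signal_fraction = 1, n_instances = 16,
                          embed_dim = 8, seed = 55)
  co <- generate_embedding_cohort(cfg)
  tr <- 1:80; te <- 81:120
  fit <- dmil(co$bags[tr], co$labels[tr], pooling = "attention",
              backbone = NULL,
              control = dmil_control(epochs = 20, learning_rate = 1e-3,
                                     seed = 4))
  auc <- roc_auc(predict(fit, co$bags[te]), co$labels[te])$auc
  expect_gte(auc, 0.9)
})

test_that("attention localizes signal instances in positive bags", {
  # weak-supervision property: after training, signal instances get more
  # attention than noise instances (effect 3 sd, 1/8 of instances)
  cfg <- synthetic_config(n_bags = 120, noise_sd = 1, signal_effect = 3,
                          signal_fraction = 1 / 8, n_instances = 16,
                          embed_dim = 8, seed = 56)
  co <- generate_embedding_cohort(cfg)
  fit <- dmil(co$bags, co$labels, pooling = "attention", backbone = NULL,
              control = dmil_control(epochs = 30, learning_rate = 1e-3,
                                     seed = 6))
  aw <- attention_weights(fit, co$bags)
  pos <- which(co$labels == 1)
  w_sig <- w_noise <- numeric(0)
  for (i in pos) {
    w <- aw$weight[aw$bag_id == names(co$bags)[i]]
    s <- co$signal_instances[[i]]
    w_sig <- c(w_sig, w[s])
    w_noise <- c(w_noise, w[-s])
  }
  expect_gt(mean(w_sig), mean(w_noise))
})

test_that("image-route training works end to end on a small cohort", {
  cfg <- synthetic_config(n_bags = 16, volume_shape = c(72, 72, 40),
                          seed = 57)
  co <- generate_image_cohort(cfg)
  bags <- make_image_bags(co, size = 32)
  fit <- dmil(bags, co$labels, pooling = "max", backbone = "tiny_test",
              control = dmil_control(epochs = 2, batch_bags = 8, seed = 3))
  p <- predict(fit, bags)
  expect_length(p, 16)
  expect_true(all(is.finite(p)))
  # model methods exercise
  expect_output(print(fit), "Deep MIL")
  expect_output(summary(fit), "trainable parameters")
  expect_length(residuals(fit), 16)
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_equal(dim(sims), c(16, 2))
})
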