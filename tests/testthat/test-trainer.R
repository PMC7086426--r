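test_that("iterations per epoch is the ceiling of n over batch", {
  expect_identical(iterations_per_epoch(680, 128), 6L)
  expect_identical(iterations_per_epoch(128, 128), 1L)
  expect_identical(iterations_per_epoch(129, 128), 2L)
  expect_error(iterations_per_epoch(0, 128))
})

test_that("training config defaults match the reference regime", {
  cfg <- train_config()
  expect_equal(cfg$learning_rate, 1e-4)
  expect_equal(cfg$momentum, 0.9)
  expect_equal(cfg$l2_regularization, 5e-4)
  expect_equal(cfg$mini_batch_size, 128L)
  expect_equal(cfg$epochs, 30L)
})

test_that("training is deterministic given the seed and rejects bad input", {
  segs <- toy_segments(n = 10, seed = 3)
  topo <- make_topology(11, 16, layout = c("conv", "pool", "conv"),
                        conv_f = 3)
  cfg <- train_config(learning_rate = 0.05, mini_batch_size = 5, epochs = 4,
                      seed = 9)
  m1 <- train_cnn(topo, segs, cfg)
  m2 <- train_cnn(topo, segs, cfg)
  expect_identical(m1$training_log, m2$training_log)
  expect_identical(m1$layers[[1]]$W, m2$layers[[1]]$W)
  expect_equal(nrow(m1$training_log), 4)

  m3 <- train_cnn(topo, segs, train_config(learning_rate = 0.05,
                                           mini_batch_size = 5, epochs = 4,
                                           seed = 10))
  expect_false(identical(m1$layers[[1]]$W, m3$layers[[1]]$W))

  one_class <- toy_segments(n = 6, labels = rep("tbi", 6))
  expect_error(train_cnn(topo, one_class, cfg), "training error")
  wrong <- toy_segments(n = 6, h = 9, w = 16)
  expect_error(train_cnn(topo, wrong, cfg), "shape error")
})

test_that("a vanishing learning rate leaves the parameters unchanged", {
  segs <- toy_segments(n = 8, seed = 4)
  topo <- make_topology(11, 16, layout = c("conv", "pool", "conv"),
                        conv_f = 3)
  mk <- function(ep) train_cnn(topo, segs,
                               train_config(learning_rate = 1e-300,
                                            mini_batch_size = 4,
                                            epochs = ep, seed = 2))
  m1 <- mk(1); m4 <- mk(4)
  expect_equal(m1$layers[[1]]$W, m4$layers[[1]]$W, tolerance = 1e-12)
  expect_equal(m1$layers[[3]]$W, m4$layers[[3]]$W, tolerance = 1e-12)
})

test_that("a large L2 penalty shrinks weight norms monotonically", {
  segs <- toy_segments(n = 8, seed = 5)
  topo <- make_topology(11, 16, layout = c("conv", "pool", "conv"),
                        conv_f = 3)
  norms <- vapply(c(1, 4, 8), function(ep) {
    m <- train_cnn(topo, segs, train_config(learning_rate = 0.005,
                                            momentum = 0,
                                            l2_regularization = 10,
                                            mini_batch_size = 8,
                                            epochs = ep, seed = 2))
    sum(vapply(m$layers, function(L) if (!is.null(L$W)) sum(L$W^2) else 0, 0))
  }, 0)
  expect_true(all(diff(norms) < 0))
})

test_that("softmax outputs normalize and predictions are pure", {
  segs <- toy_segments(n = 10, seed = 6)
  topo <- make_topology(11, 16, layout = c("conv", "pool", "conv"),
                        conv_f = 3)
  m <- train_cnn(topo, segs, train_config(learning_rate = 0.05,
                                          mini_batch_size = 5, epochs = 3,
                                          seed = 1))
  p <- predict(m, segs)
  expect_true(all(abs(p$p_healthy + p$p_tbi - 1) < 1e-6))
  expect_true(all(p$p_healthy >= 0 & p$p_tbi >= 0))

  # duplicated segment gives identical outputs
  pdup <- predict(m, list(segs[[1]], segs[[1]]))
  expect_identical(pdup[1, -1], structure(pdup[2, -1], row.names = 1L))

  expect_error(predict(m, toy_segments(n = 2, h = 9, w = 16)), "shape error")
})

test_that("a separated synthetic cohort is learned to high training accuracy", {
  coh <- effect_cohort()
  segs <- unlist(lapply(coh$recordings[c(1:10, 16:25)], function(r) {
    segment_recording(discard_initial(
      apply_montage(r, montage(r$channel_labels, "CPz")), 2), 1, 14)
  }), recursive = FALSE)
  topo <- make_topology(15, 32)
  m <- train_cnn(topo, segs, cnn_test_config())
  expect_gt(tail(m$training_log$train_accuracy, 1), 90)

  # majority of held-out TBI segments get p(tbi) > 0.5
  held <- unlist(lapply(coh$recordings[26:30], function(r) {
    segment_recording(discard_initial(
      apply_montage(r, montage(r$channel_labels, "CPz")), 2), 1, 14)
  }), recursive = FALSE)
  p <- predict(m, held)
  expect_gt(mean(p$p_tbi > 0.5), 0.5)
})

test_that("randomly permuted labels give chance-level held-out accuracy", {
  coh <- tiny_cohort()
  prep <- function(r) segment_recording(discard_initial(
    apply_montage(r, montage(r$channel_labels,
                             intersect("CPz", r$channel_labels))), 1), 1, 5)
  segs_by <- lapply(coh$recordings, prep)
  set.seed(31)
  fake <- sample(rep(c("healthy", "tbi"), 4))
  for (i in seq_along(segs_by)) {
    for (j in seq_along(segs_by[[i]])) segs_by[[i]][[j]]$class_label <- fake[i]
  }
  tr <- unlist(segs_by[1:6], recursive = FALSE)
  te <- unlist(segs_by[7:8], recursive = FALSE)
  topo <- make_topology(7, 64, layout = c("conv", "conv", "pool"))
  m <- train_cnn(topo, tr, train_config(learning_rate = 0.02,
                                        mini_batch_size = 16, epochs = 10,
                                        seed = 3))
  p <- predict(m, te)
  acc <- mean(p$label == vapply(te, function(s) s$class_label, ""))
  # no systematic generalization of shuffled labels; the tight chance-level
  # calibration at full scale is covered by the null-cohort bootstrap test
  expect_lte(acc, 0.9)
  expect_gt(tail(m$training_log$train_accuracy, 1), 60)
})
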