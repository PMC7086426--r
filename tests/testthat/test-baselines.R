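# Baseline feature-extraction arithmetic on a light cohort, plus the
# interchangeability contract each pipeline must satisfy.

test_that("naive Bayes features count 4 per retained electrode", {
  coh <- baseline_cohort()
  p <- naive_bayes_pipeline(coh$recordings[c(1, 2, 16, 17)],
                            epoch_seconds = 2, discard_seconds = 2,
                            max_epochs = 2)
  feats <- p$prep$table
  n_ch <- 15  # 16-channel montage minus CPz
  expect_equal(ncol(feats) - 2, n_ch + 3 * n_ch)
  expect_true(all(is.finite(as.matrix(feats[, -(1:2)]))))
  expect_true(all(as.matrix(feats[, grep("beta_pow", names(feats))]) >= 0))
  # 2 epochs per subject
  expect_equal(nrow(feats), 4 * 2)
})

test_that("naive Bayes chain requires a sampling rate above 200 Hz", {
  coh <- tiny_cohort()  # 64 Hz
  expect_error(naive_bayes_pipeline(coh$recordings), "fs >= 200")
})

test_that("AdaBoost features are 8 log-PSD values from the frontal derivations", {
  coh <- baseline_cohort()
  p <- adaboost_pipeline(coh$recordings[c(1, 2, 16, 17)], epoch_seconds = 2,
                         discard_seconds = 2, max_epochs = 3)
  expect_equal(ncol(p$prep$table) - 2, 8)
  nm <- names(p$prep$table)[-(1:2)]
  expect_equal(sum(grepl("^AF7", nm)), 4)
  expect_equal(sum(grepl("^AF8", nm)), 4)
})

test_that("doubling the amplitude raises each log-PSD feature by log10(4)", {
  coh <- baseline_cohort()
  rec <- coh$recordings[[1]]
  doubled <- rec
  doubled$signal <- rec$signal * 2
  p1 <- adaboost_pipeline(list(rec), epoch_seconds = 2,
                          discard_seconds = 2, max_epochs = 3)
  p2 <- adaboost_pipeline(list(doubled), epoch_seconds = 2,
                          discard_seconds = 2, max_epochs = 3)
  delta <- as.matrix(p2$prep$table[, -(1:2)]) -
    as.matrix(p1$prep$table[, -(1:2)])
  expect_equal(unname(delta), matrix(log10(4), nrow(delta), ncol(delta)),
               tolerance = 1e-8)
})

test_that("AdaBoost requires the frontal channels", {
  spec <- cohort_spec(n_per_class = 1, n_channels = 8, fs = 250,
                      duration_s = 6, seed = 55)
  rec <- generate_subject(spec, "healthy", 1)
  rec$channel_labels[rec$channel_labels == "AF7"] <- "XX"
  rownames(rec$signal) <- rec$channel_labels
  expect_error(adaboost_pipeline(list(rec)), "montage error")
})

test_that("MRMR-SVM builds 34 features per electrode and feeds 10 to the SVM", {
  coh <- baseline_cohort()
  p <- svm_mrmr_pipeline(coh$recordings[c(1:4, 16:19)], epoch_seconds = 2,
                         discard_seconds = 2, max_epochs = 3)
  expect_equal(ncol(p$prep$table) - 2, 34 * 15)
  ids <- p$subjects$subject_id
  model <- p$fit(p$prep, ids)
  expect_length(model$sel, 10)
  pred <- p$predict(p$prep, model, ids[1:2])
  expect_true(all(pred$pred %in% c("healthy", "tbi")))
})

test_that("alpha-power SVM uses one feature per electrode", {
  coh <- baseline_cohort()
  p <- svm_alpha_pipeline(coh$recordings[c(1:3, 16:18)], epoch_seconds = 2,
                          discard_seconds = 2, max_epochs = 3)
  expect_equal(ncol(p$prep$table) - 2, 15)
  expect_true(all(as.matrix(p$prep$table[, -(1:2)]) >= 0))
})

test_that("the alpha-power pipeline detects an alpha effect above chance", {
  coh <- baseline_cohort()   # alpha attenuation 0.4 present
  plan <- make_fold_plan(coh$recordings, scheme = "fixed_threefold")
  cv <- cross_validate(coh$recordings, plan,
                       svm_alpha_pipeline(epoch_seconds = 2,
                                          discard_seconds = 2,
                                          max_epochs = 5))
  expect_gt(cv$mean_accuracy, 65)
})

test_that("the alpha-power pipeline is blind to a pure theta effect", {
  coh <- generate_cohort(cohort_spec(n_per_class = 8, n_channels = 12,
                                     fs = 250, duration_s = 8,
                                     alpha_attenuation = 1, theta_gain = 2,
                                     seed = 105))
  plan <- make_fold_plan(coh$recordings, k = 2, scheme = "balanced_random",
                         seed = 1)
  cv <- cross_validate(coh$recordings, plan,
                       svm_alpha_pipeline(epoch_seconds = 2,
                                          discard_seconds = 1,
                                          max_epochs = 3))
  # chance band at 16 subjects x 3 epochs
  expect_lt(cv$mean_accuracy, 75)
})

test_that("every pipeline fulfils the cross-validation contract", {
  coh <- baseline_cohort()
  sub <- coh$recordings[c(1:4, 16:19)]
  plan <- make_fold_plan(sub, k = 2, scheme = "balanced_random", seed = 2)
  factories <- list(
    cnn_pipeline(config = train_config(learning_rate = 0.02,
                                       mini_batch_size = 32, epochs = 2,
                                       seed = 1),
                 discard_seconds = 2, max_segments = 4),
    naive_bayes_pipeline(epoch_seconds = 2, discard_seconds = 2,
                         max_epochs = 2),
    adaboost_pipeline(epoch_seconds = 2, discard_seconds = 2,
                      max_epochs = 2),
    svm_mrmr_pipeline(epoch_seconds = 2, discard_seconds = 2,
                      max_epochs = 2),
    svm_alpha_pipeline(epoch_seconds = 2, discard_seconds = 2,
                       max_epochs = 2))
  for (f in factories) {
    cv <- cross_validate(sub, plan, f)
    expect_s3_class(cv, "cv_result")
    expect_length(cv$fold_accuracy, 2)
    expect_true(all(cv$fold_accuracy >= 0 & cv$fold_accuracy <= 100))
  }
})
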