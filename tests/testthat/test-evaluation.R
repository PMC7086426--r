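test_that("confusion accuracy follows the TP+TN over total formula", {
  expect_equal(accuracy(list(TP = 5, TN = 5, FP = 0, FN = 0)), 100)
  expect_equal(accuracy(list(TP = 0, TN = 0, FP = 5, FN = 5)), 0)
  expect_equal(accuracy(list(TP = 3, TN = 4, FP = 1, FN = 2)), 70)
  expect_error(accuracy(list(TP = 0, TN = 0, FP = 0, FN = 0)),
               "undefined metric")
})

test_that("accuracy is invariant to ordering and class relabeling", {
  set.seed(1)
  truth <- sample(c("healthy", "tbi"), 40, replace = TRUE)
  pred <- sample(c("healthy", "tbi"), 40, replace = TRUE)
  a1 <- accuracy(confusion_counts(truth, pred))
  ord <- sample(40)
  expect_equal(accuracy(confusion_counts(truth[ord], pred[ord])), a1)
  flip <- function(x) ifelse(x == "tbi", "healthy", "tbi")
  expect_equal(accuracy(confusion_counts(flip(truth), flip(pred))), a1)
})

test_that("the literal threefold plan assigns subjects 11-15, 1-5, 6-10 to testing", {
  subjects <- data.frame(
    subject_id = c(sprintf("Patient %d", 1:15), sprintf("Healthy %d", 1:15)),
    class_label = rep(c("tbi", "healthy"), each = 15))
  plan <- make_fold_plan(subjects, scheme = "fixed_threefold")
  expect_equal(plan$k, 3)
  expect_setequal(plan$folds[[1]]$test,
                  c(sprintf("Patient %d", 11:15), sprintf("Healthy %d", 11:15)))
  expect_setequal(plan$folds[[2]]$test,
                  c(sprintf("Patient %d", 1:5), sprintf("Healthy %d", 1:5)))
  expect_setequal(plan$folds[[3]]$test,
                  c(sprintf("Patient %d", 6:10), sprintf("Healthy %d", 6:10)))
  for (fold in plan$folds) {
    expect_length(fold$train, 20)
    expect_length(intersect(fold$train, fold$test), 0)
  }
  expect_error(make_fold_plan(subjects[1:20, ], scheme = "fixed_threefold"),
               "plan error")
})

test_that("every subject is tested exactly once under any plan", {
  subjects <- data.frame(
    subject_id = sprintf("s%02d", 1:24),
    class_label = rep(c("healthy", "tbi"), each = 12))
  for (seed in 1:5) {
    plan <- make_fold_plan(subjects, k = 3, scheme = "balanced_random",
                           seed = seed)
    tested <- unlist(lapply(plan$folds, `[[`, "test"))
    expect_setequal(tested, subjects$subject_id)
    expect_length(tested, 24)
    for (fold in plan$folds) {
      cls <- subjects$class_label[match(fold$test, subjects$subject_id)]
      expect_equal(as.integer(table(cls)), c(4L, 4L))  # balanced 4+4
      expect_length(intersect(fold$train, fold$test), 0)
    }
  }
})

test_that("a constant classifier scores exactly 50% on class-balanced folds", {
  coh <- tiny_cohort()
  always_healthy <- local({
    tab <- data.frame(
      subject_id = vapply(coh$recordings, function(r) r$subject_id, ""),
      class_label = vapply(coh$recordings, function(r) r$class_label, ""))
    eegtbi:::new_pipeline(
      "always_healthy", list(), tab,
      fit = function(prep, train_ids) list(),
      predict = function(prep, model, test_ids) {
        cls <- tab$class_label[match(test_ids, tab$subject_id)]
        data.frame(subject_id = test_ids, truth = cls,
                   pred = "healthy", stringsAsFactors = FALSE)
      })
  })
  plan <- make_fold_plan(coh$recordings, k = 2, scheme = "balanced_random",
                         seed = 1)
  cv <- cross_validate(coh$recordings, plan, always_healthy)
  expect_equal(cv$fold_accuracy, c(50, 50))

  bad_plan <- plan
  bad_plan$folds[[1]]$test <- c(bad_plan$folds[[1]]$test, "missing_id")
  expect_error(cross_validate(coh$recordings, bad_plan, always_healthy),
               "plan error")
})

test_that("bootstrap resampling preserves size and is seeded", {
  ids <- sprintf("s%02d", 1:30)
  r1 <- bootstrap_resample(ids, seed = 5)
  r2 <- bootstrap_resample(ids, seed = 5)
  expect_length(r1, 30)
  expect_identical(r1, r2)
  expect_true(all(r1 %in% ids))
  expect_false(identical(sort(unique(r1)), ids) &&
                 identical(r1, ids))  # with-replacement draw, not a permutation
})

test_that("the expected distinct-subject fraction matches 1 - (1 - 1/n)^n", {
  ids <- sprintf("s%02d", 1:30)
  fr <- vapply(seq_len(10000), function(s) {
    length(unique(bootstrap_resample(ids, seed = s))) / 30
  }, 0)
  expect_equal(mean(fr), 1 - (1 - 1 / 30)^30, tolerance = 0.01 / 0.638)
})

test_that("bootstrap of an oracle classifier is exactly 100 with zero spread", {
  coh <- tiny_cohort()
  res <- run_bootstrap_cv(coh$recordings, oracle_pipeline(n_units = 5),
                          n_iterations = 10, base_seed = 3, k = 2)
  expect_equal(res$mean_acc, 100)
  expect_equal(res$sd, 0)
  expect_equal(unname(res$ci95), c(100, 100))
  expect_length(res$per_iteration_acc, 10)
})

test_that("bootstrap of a coin-flip classifier is centred on 50%", {
  coh <- null_cohort()
  res <- run_bootstrap_cv(coh$recordings, coinflip_pipeline(n_units = 10),
                          n_iterations = 100, base_seed = 11)
  expect_length(res$per_iteration_acc, 100)
  expect_gt(res$mean_acc, 47)
  expect_lt(res$mean_acc, 53)
  # percentile CI endpoints lie inside the sample range
  expect_gte(res$ci95[1], min(res$per_iteration_acc))
  expect_lte(res$ci95[2], max(res$per_iteration_acc))
  expect_gte(res$ci95[2], res$ci95[1])
})

test_that("no subject identity straddles a bootstrap fold split", {
  coh <- tiny_cohort()
  seen <- new.env(); seen$bad <- 0L; seen$calls <- 0L
  tab <- data.frame(
    subject_id = vapply(coh$recordings, function(r) r$subject_id, ""),
    class_label = vapply(coh$recordings, function(r) r$class_label, ""))
  spy <- eegtbi:::new_pipeline(
    "spy", list(), tab,
    fit = function(prep, train_ids) list(train = train_ids),
    predict = function(prep, model, test_ids) {
      seen$calls <- seen$calls + 1L
      if (length(intersect(unique(model$train), unique(test_ids)))) {
        seen$bad <- seen$bad + 1L
      }
      cls <- tab$class_label[match(test_ids, tab$subject_id)]
      data.frame(subject_id = test_ids, truth = cls, pred = cls,
                 stringsAsFactors = FALSE)
    })
  res <- run_bootstrap_cv(coh$recordings, spy, n_iterations = 25,
                          base_seed = 2, k = 2)
  expect_gte(seen$calls, 50L)
  expect_identical(seen$bad, 0L)
  # duplicated subjects contribute duplicated evaluation units
  expect_equal(res$mean_acc, 100)
})
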