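# Evaluation protocol: subject-level threefold cross-validation, confusion
# accuracy, and the bootstrap wrapper that yields mean accuracy, SD and a
# 95% percentile confidence interval over resampled cohorts.

#' Classification accuracy from confusion counts
#'
#' `100 * (TP + TN) / (TP + TN + FP + FN)` where TP counts TBI segments
#' predicted TBI and TN healthy segments predicted healthy.
#'
#' @param counts Named list or vector with elements `TP`, `TN`, `FP`, `FN`.
#' @return Accuracy as a percentage.
#' @export
accuracy <- function(counts) {
  counts <- as.list(counts)
  total <- counts$TP + counts$TN + counts$FP + counts$FN
  if (total <= 0) stop("undefined metric: no evaluated segments", call. = FALSE)
  100 * (counts$TP + counts$TN) / total
}

#' Confusion counts from truth/prediction vectors
#'
#' @param truth,pred Character vectors of `"healthy"`/`"tbi"` labels.
#' @return Named list with `TP`, `TN`, `FP`, `FN` (TBI is the positive
#'   class).
#' @export
confusion_counts <- function(truth, pred) {
  stopifnot(length(truth) == length(pred))
  list(TP = sum(truth == "tbi" & pred == "tbi"),
       TN = sum(truth == "healthy" & pred == "healthy"),
       FP = sum(truth == "healthy" & pred == "tbi"),
       FN = sum(truth == "tbi" & pred == "healthy"))
}

subject_table <- function(subjects) {
  if (is.data.frame(subjects)) {
    stopifnot(all(c("subject_id", "class_label") %in% names(subjects)))
    data.frame(subject_id = as.character(subjects$subject_id),
               class_label = as.character(subjects$class_label),
               stringsAsFactors = FALSE)
  } else if (is.list(subjects) && length(subjects) &&
             inherits(subjects[[1]], "eeg_recording")) {
    data.frame(subject_id = vapply(subjects, function(r) r$subject_id, ""),
               class_label = vapply(subjects, function(r) r$class_label, ""),
               stringsAsFactors = FALSE)
  } else {
    stop("subjects must be a data.frame or a list of recordings", call. = FALSE)
  }
}

#' Build a subject-level cross-validation fold plan
#'
#' With `scheme = "fixed_threefold"` the literal reference assignment for a
#' 15 TBI + 15 healthy cohort is reproduced: fold 1 tests subjects 11-15 of
#' each class, fold 2 tests 1-5, fold 3 tests 6-10 (subject order within
#' class follows the input order). With `scheme = "balanced_random"`,
#' subjects are shuffled within class under `seed` and dealt into `k`
#' near-balanced test folds. Every subject is tested exactly once and whole
#' subjects (all their segments) stay on one side of each split.
#'
#' @param subjects A data.frame with `subject_id` and `class_label`
#'   columns, or a list of `eeg_recording`s.
#' @param k Fold count (default 3).
#' @param scheme `"fixed_threefold"` or `"balanced_random"`.
#' @param seed Seed for `balanced_random`.
#' @return An object of class `fold_plan`: `folds` (list of
#'   `list(train, test)` subject-id vectors), `k`, `scheme`.
#' @export
make_fold_plan <- function(subjects, k = 3,
                           scheme = c("fixed_threefold", "balanced_random"),
                           seed = 1) {
  scheme <- match.arg(scheme)
  tab <- subject_table(subjects)
  tab$instance <- seq_len(nrow(tab))
  classes <- c("healthy", "tbi")
  if (!all(tab$class_label %in% classes)) {
    stop("plan error: class labels must be healthy/tbi", call. = FALSE)
  }
  by_class <- split(tab$instance, tab$class_label)

  if (scheme == "fixed_threefold") {
    if (k != 3 || any(vapply(by_class, length, 0L) != 15) ||
        length(by_class) != 2) {
      stop("plan error: fixed_threefold requires k = 3 and exactly 15 subjects per class",
           call. = FALSE)
    }
    test_ranges <- list(11:15, 1:5, 6:10)
    folds <- lapply(test_ranges, function(rng) {
      test <- unlist(lapply(by_class, function(idx) idx[rng]), use.names = FALSE)
      list(train = tab$subject_id[setdiff(tab$instance, test)],
           test = tab$subject_id[test])
    })
  } else {
    stopifnot(k >= 2)
    if (any(vapply(by_class, length, 0L) < k)) {
      stop("plan error: each class needs at least k subjects", call. = FALSE)
    }
    set.seed(seed)
    assign_fold <- integer(nrow(tab))
    for (idx in by_class) {
      shuffled <- sample(idx)
      assign_fold[shuffled] <- rep_len(seq_len(k), length(shuffled))
    }
    folds <- lapply(seq_len(k), function(f) {
      list(train = tab$subject_id[assign_fold != f],
           test = tab$subject_id[assign_fold == f])
    })
  }
  structure(list(folds = folds, k = length(folds), scheme = scheme),
            class = "fold_plan")
}

#' @export
#' @method print fold_plan
print.fold_plan <- function(x, ...) {
  cat(sprintf("Fold plan (%s): %d folds\n", x$scheme, x$k))
  for (i in seq_len(x$k)) {
    cat(sprintf("  fold %d: %d train / %d test subjects\n", i,
                length(x$folds[[i]]$train), length(x$folds[[i]]$test)))
  }
  invisible(x)
}

resolve_pipeline <- function(cohort, pipeline) {
  if (inherits(pipeline, "tbi_pipeline")) return(pipeline)
  if (is.function(pipeline)) return(pipeline(cohort))
  stop("pipeline must be a tbi_pipeline or a factory function", call. = FALSE)
}

#' Subject-level cross-validation of a classifier pipeline
#'
#' For each fold, fits the pipeline on the training subjects' segments and
#' evaluates confusion accuracy on the test subjects' segments. Segments of
#' one subject never straddle the train/test split. Accepts any pipeline
#' conforming to the prepare/fit/predict contract (see [cnn_pipeline()]),
#' so the CNN and the four feature-engineered baselines are interchangeable.
#'
#' @param cohort List of `eeg_recording`s (may be `NULL` if `pipeline` is
#'   already prepared).
#' @param plan A `fold_plan` over the cohort's subjects.
#' @param pipeline A `tbi_pipeline` or a factory `function(cohort)`.
#' @return An object of class `cv_result`: per-fold confusion counts and
#'   accuracies plus their mean.
#' @export
cross_validate <- function(cohort, plan, pipeline) {
  stopifnot(inherits(plan, "fold_plan"))
  pipeline <- resolve_pipeline(cohort, pipeline)
  known <- pipeline$subjects$subject_id
  for (fold in plan$folds) {
    missing <- setdiff(unique(c(fold$train, fold$test)), known)
    if (length(missing)) {
      stop("plan error: subject(s) not in cohort: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  per_fold <- lapply(seq_len(plan$k), function(i) {
    fold <- plan$folds[[i]]
    if (length(intersect(unique(fold$train), unique(fold$test)))) {
      stop("plan error: train/test subject overlap in fold ", i, call. = FALSE)
    }
    model <- pipeline$fit(pipeline$prep, fold$train)
    pred <- pipeline$predict(pipeline$prep, model, fold$test)
    counts <- confusion_counts(pred$truth, pred$pred)
    list(counts = counts, accuracy = accuracy(counts))
  })
  fold_acc <- vapply(per_fold, function(f) f$accuracy, 0)
  structure(
    list(per_fold = per_fold, fold_accuracy = fold_acc,
         mean_accuracy = mean(fold_acc), pipeline = pipeline$name,
         k = plan$k),
    class = "cv_result")
}

#' @export
#' @method print cv_result
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation of '%s': mean accuracy %.2f%% (folds: %s)\n",
              x$k, x$pipeline, x$mean_accuracy,
              paste(sprintf("%.1f", x$fold_accuracy), collapse = ", ")))
  invisible(x)
}

#' Resample a subject list with replacement
#'
#' Draws a bootstrap sample of the same size as the input, so some subjects
#' appear repeatedly and some not at all (over many draws the expected
#' fraction of distinct subjects approaches `1 - (1 - 1/n)^n`, about 0.638
#' for n = 30).
#'
#' @param subjects Vector of subject identifiers (nonempty).
#' @param seed Integer seed.
#' @return Vector of the same length drawn with replacement.
#' @export
bootstrap_resample <- function(subjects, seed) {
  stopifnot(length(subjects) >= 1)
  set.seed(seed)
  subjects[sample.int(length(subjects), replace = TRUE)]
}

balanced_instance_folds <- function(ids, classes, k) {
  # ids may contain duplicates (bootstrap copies); copies of one subject are
  # distinct instances and may land in different folds, but a fold's train
  # and test sides never share a subject identity (enforced by caller).
  folds_train <- folds_test <- rep(list(character(0)), k)
  for (cl in unique(classes)) {
    idx <- which(classes == cl)
    idx <- idx[sample.int(length(idx))]
    f <- rep_len(seq_len(k), length(idx))
    for (j in seq_len(k)) {
      folds_test[[j]] <- c(folds_test[[j]], ids[idx[f == j]])
      folds_train[[j]] <- c(folds_train[[j]], ids[idx[f != j]])
    }
  }
  lapply(seq_len(k), function(j) list(train = folds_train[[j]],
                                      test = folds_test[[j]]))
}

#' Bootstrap of the cross-validation accuracy
#'
#' Repeats, `n_iterations` times: resample the cohort's subjects with
#' replacement (a subject drawn twice contributes its segments twice),
#' build a class-balanced subject-level k-fold plan on the resample, run
#' cross-validation, and record the mean fold accuracy. Duplicated copies
#' of a subject are forced onto one side of every split so subject identity
#' never leaks between train and test. Returns the mean, sample SD
#' (n-1 denominator) and 95% percentile confidence interval of the recorded
#' accuracies. Resamples in which a class has fewer than `k` members are
#' redrawn (counted in `n_redrawn`).
#'
#' @param cohort List of `eeg_recording`s.
#' @param pipeline A `tbi_pipeline` or factory function.
#' @param n_iterations Number of bootstrap iterations (>= 2; 50-200 is the
#'   recommended range, 100 the reference setting).
#' @param base_seed Integer seed from which all per-iteration seeds derive.
#' @param k Fold count (default 3).
#' @return An object of class `bootstrap_result` with
#'   `per_iteration_acc`, `mean_acc`, `sd`, `ci95`, `n_iterations`,
#'   `n_redrawn`.
#' @export
run_bootstrap_cv <- function(cohort, pipeline, n_iterations = 100,
                             base_seed = 1, k = 3) {
  stopifnot(n_iterations >= 2)
  pipeline <- resolve_pipeline(cohort, pipeline)
  subj <- pipeline$subjects
  cls <- stats::setNames(subj$class_label, subj$subject_id)
  acc <- numeric(n_iterations)
  n_redrawn <- 0L
  set.seed(base_seed)
  iter_seeds <- sample.int(2^30, n_iterations + 1000L)
  seed_ptr <- 0L
  for (i in seq_len(n_iterations)) {
    repeat {
      seed_ptr <- seed_ptr + 1L
      if (seed_ptr > length(iter_seeds)) stop("exhausted redraw seeds")
      set.seed(iter_seeds[seed_ptr])
      ids <- subj$subject_id[sample.int(nrow(subj), replace = TRUE)]
      uc <- cls[unique(ids)]
      if (all(table(factor(uc, c("healthy", "tbi"))) >= k)) break
      n_redrawn <- n_redrawn + 1L
    }
    # subjects sampled more than once are kept together so train/test never
    # share an identity
    uniq <- unique(ids)
    mult <- table(ids)[uniq]
    folds <- balanced_instance_folds(uniq, cls[uniq], k)
    fold_acc <- vapply(folds, function(fold) {
      train_ids <- rep(fold$train, times = mult[fold$train])
      test_ids <- rep(fold$test, times = mult[fold$test])
      model <- pipeline$fit(pipeline$prep, train_ids)
      pred <- pipeline$predict(pipeline$prep, model, test_ids)
      accuracy(confusion_counts(pred$truth, pred$pred))
    }, 0)
    acc[i] <- mean(fold_acc)
  }
  structure(
    list(per_iteration_acc = acc, mean_acc = mean(acc),
         sd = stats::sd(acc),
         ci95 = unname(stats::quantile(acc, c(0.025, 0.975))),
         n_iterations = n_iterations, n_redrawn = n_redrawn,
         pipeline = pipeline$name),
    class = "bootstrap_result")
}

#' @export
#' @method print bootstrap_result
print.bootstrap_result <- function(x, ...) {
  cat(sprintf(
    "Bootstrap CV of '%s' (%d iterations): mean ACC %.2f%%, SD %.2f, 95%% CI [%.2f, %.2f]\n",
    x$pipeline, x$n_iterations, x$mean_acc, x$sd, x$ci95[1], x$ci95[2]))
  invisible(x)
}
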