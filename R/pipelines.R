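# Classifier pipelines under one prepare/fit/predict contract, so the CNN
# and the four feature-engineered baselines are interchangeable inside
# cross_validate() and run_bootstrap_cv().
#
# A prepared pipeline is a `tbi_pipeline`: list(name, prep, subjects,
# fit(prep, train_ids), predict(prep, model, test_ids)); fit/predict receive
# subject-id vectors, possibly with bootstrap-duplicated entries, and
# predict returns one row per evaluation unit with `truth` and `pred`.
# Each exported *_pipeline() function returns a factory `function(cohort)`
# when called without a cohort, or the prepared pipeline when given one.

new_pipeline <- function(name, prep, subjects, fit, predict) {
  structure(list(name = name, prep = prep, subjects = subjects,
                 fit = fit, predict = predict),
            class = "tbi_pipeline")
}

#' @export
#' @method print tbi_pipeline
print.tbi_pipeline <- function(x, ...) {
  cat(sprintf("Classifier pipeline '%s': %d prepared subjects\n", x$name,
              nrow(x$subjects)))
  invisible(x)
}

as_factory <- function(cohort, build) {
  if (is.null(cohort)) {
    return(function(cohort) build(cohort_recordings(cohort)))
  }
  build(cohort_recordings(cohort))
}

cohort_recordings <- function(cohort) {
  if (is.list(cohort) && !is.null(cohort$recordings)) cohort$recordings
  else cohort
}

rows_for_ids <- function(df, ids) {
  # honors multiplicity: a duplicated id contributes its rows twice
  do.call(rbind, lapply(ids, function(id) df[df$subject_id == id, ,
                                             drop = FALSE]))
}

# ---- CNN pipeline ----------------------------------------------------------

#' The raw-matrix CNN pipeline
#'
#' Prepares each recording with montage exclusion, initial discard,
#' optional amplitude-threshold artifact rejection and one-second
#' segmentation, then trains/applies the CNN per fold. With the defaults
#' each subject contributes up to 60 segments of 63 x 1000 and the
#' nine-layer reference topology is used; smaller inputs get a reduced
#' topology built with the same shape algebra unless one is supplied.
#'
#' @param cohort List of `eeg_recording`s (or a cohort list); omit to get a
#'   factory for [cross_validate()] / [run_bootstrap_cv()].
#' @param topology A `cnn_topology`, or `NULL` to choose by segment size.
#' @param config A [train_config()].
#' @param exclude Channel labels to exclude (only those present are
#'   dropped).
#' @param discard_seconds Initial seconds to discard.
#' @param window_seconds Segment length in seconds.
#' @param max_segments Segments retained per subject.
#' @param artifact_threshold Amplitude threshold in uV for window
#'   rejection, or `NULL` to skip (the default; synthetic data carries no
#'   artifact model).
#' @return A `tbi_pipeline` or its factory.
#' @export
cnn_pipeline <- function(cohort = NULL, topology = NULL,
                         config = train_config(), exclude = "CPz",
                         discard_seconds = 60, window_seconds = 1,
                         max_segments = 60, artifact_threshold = NULL) {
  build <- function(recs) {
    seg_by_subject <- lapply(recs, function(rec) {
      m <- montage(rec$channel_labels,
                   excluded = intersect(exclude, rec$channel_labels))
      rec <- apply_montage(rec, m)
      rec <- discard_initial(rec, discard_seconds)
      if (!is.null(artifact_threshold)) {
        rec <- reject_artifacts(rec, artifact_threshold)$recording
      }
      segment_recording(rec, window_seconds, max_segments)
    })
    names(seg_by_subject) <- vapply(recs, function(r) r$subject_id, "")
    dims <- dim(seg_by_subject[[1]][[1]]$matrix)
    topo <- topology
    if (is.null(topo)) {
      topo <- if (dims[1] == 63 && dims[2] == 1000) build_reference_topology()
              else default_small_topology(dims[1], dims[2])
    }
    new_pipeline(
      name = "cnn",
      prep = list(segments = seg_by_subject, topology = topo,
                  config = config),
      subjects = subject_table(recs),
      fit = function(prep, train_ids) {
        segs <- unlist(prep$segments[train_ids], recursive = FALSE,
                       use.names = FALSE)
        train_cnn(prep$topology, segs, prep$config)
      },
      predict = function(prep, model, test_ids) {
        segs <- unlist(prep$segments[test_ids], recursive = FALSE,
                       use.names = FALSE)
        out <- predict(model, segs)
        data.frame(subject_id = out$subject_id,
                   truth = vapply(segs, function(s) s$class_label, ""),
                   pred = out$label, stringsAsFactors = FALSE)
      })
  }
  as_factory(cohort, build)
}

# ---- shared feature-pipeline machinery ------------------------------------

feature_pipeline <- function(name, recs, feature_fn, fit_fn, predict_fn) {
  feats <- lapply(recs, function(rec) {
    f <- feature_fn(rec)
    data.frame(subject_id = rec$subject_id, truth = rec$class_label,
               f, stringsAsFactors = FALSE, check.names = FALSE)
  })
  table <- do.call(rbind, feats)
  if (any(!is.finite(as.matrix(table[, -(1:2), drop = FALSE])))) {
    stop("non-finite feature values", call. = FALSE)
  }
  new_pipeline(
    name = name,
    prep = list(table = table),
    subjects = subject_table(recs),
    fit = function(prep, train_ids) {
      tr <- rows_for_ids(prep$table, train_ids)
      x <- as.matrix(tr[, -(1:2), drop = FALSE])
      y <- factor(tr$truth, levels = c("healthy", "tbi"))
      ctr <- colMeans(x)
      scl <- apply(x, 2, stats::sd)
      scl[scl < 1e-12] <- 1
      xs <- scale(x, center = ctr, scale = scl)
      c(fit_fn(xs, y), list(center = ctr, scale = scl))
    },
    predict = function(prep, model, test_ids) {
      te <- rows_for_ids(prep$table, test_ids)
      x <- as.matrix(te[, -(1:2), drop = FALSE])
      xs <- scale(x, center = model$center, scale = model$scale)
      data.frame(subject_id = te$subject_id, truth = te$truth,
                 pred = predict_fn(model, xs), stringsAsFactors = FALSE)
    })
}

epoch_matrix <- function(rec, epoch_seconds, discard_seconds, max_epochs) {
  if (discard_seconds > 0) rec <- discard_initial(rec, discard_seconds)
  segment_recording(rec, epoch_seconds, max_epochs)
}

# ---- Gaussian Naive Bayes on band power + envelope connectivity -----------

#' Naive Bayes baseline on beta power and envelope connectivity
#'
#' Preprocessing: mains notch filter, 100 Hz low-pass, 0.5 Hz high-pass;
#' two-second epochs. Features per epoch: beta band power of every
#' electrode plus, for the delta, theta and gamma bands, each electrode's
#' mean orthogonalized-envelope connectivity with all other electrodes
#' (the all-pairs set is summarised per electrode to keep the feature count
#' linear in the montage). Classifier: Gaussian Naive Bayes.
#'
#' @inheritParams cnn_pipeline
#' @param notch_hz Mains frequency for the notch filter (default 50).
#' @param epoch_seconds Epoch length (default 2).
#' @param discard_seconds Initial seconds to discard.
#' @param max_epochs Epochs retained per subject.
#' @param exclude Channels excluded before feature extraction.
#' @return A `tbi_pipeline` or its factory.
#' @export
naive_bayes_pipeline <- function(cohort = NULL, notch_hz = 50,
                                 epoch_seconds = 2, discard_seconds = 0,
                                 max_epochs = 30, exclude = "CPz") {
  conn_bands <- c("delta", "theta", "gamma")
  build <- function(recs) {
    if (recs[[1]]$fs < 200) {
      stop("naive_bayes_pipeline requires fs >= 200 Hz", call. = FALSE)
    }
    feature_fn <- function(rec) {
      m <- montage(rec$channel_labels,
                   excluded = intersect(exclude, rec$channel_labels))
      rec <- apply_montage(rec, m)
      sig <- rec$signal
      sig <- notch_filter(sig, rec$fs, notch_hz)
      sig <- filter_band(sig, rec$fs, 0, 100)       # low-pass 100 Hz
      sig <- filter_band(sig, rec$fs, 0.5, rec$fs)  # high-pass 0.5 Hz
      rec$signal <- sig
      epochs <- epoch_matrix(rec, epoch_seconds, discard_seconds, max_epochs)
      n_ch <- nrow(sig)
      t(vapply(epochs, function(ep) {
        beta <- band_power(ep$matrix, rec$fs, "beta")
        conn <- unlist(lapply(conn_bands, function(b) {
          rng <- band_range(b)
          filt <- filter_band(ep$matrix, rec$fs, rng[1], rng[2])
          logenv <- t(apply(filt, 1, function(ch)
            log(pmax(amplitude_envelope(ch), 1e-12))))
          per_el <- numeric(n_ch)
          cnt <- numeric(n_ch)
          for (i in seq_len(n_ch - 1)) {
            for (j in (i + 1):n_ch) {
              a <- filt[i, ]; bsig <- filt[j, ]
              bo <- bsig - a * (sum(a * bsig) / sum(a * a))
              ao <- a - bsig * (sum(a * bsig) / sum(bsig * bsig))
              c1 <- stats::cor(logenv[i, ],
                               log(pmax(amplitude_envelope(bo), 1e-12)))
              c2 <- stats::cor(logenv[j, ],
                               log(pmax(amplitude_envelope(ao), 1e-12)))
              v <- (c1 + c2) / 2
              per_el[i] <- per_el[i] + v; cnt[i] <- cnt[i] + 1
              per_el[j] <- per_el[j] + v; cnt[j] <- cnt[j] + 1
            }
          }
          per_el / pmax(cnt, 1)
        }))
        stats::setNames(c(beta, conn),
                        c(paste0("beta_pow_", rec$channel_labels),
                          paste0(rep(conn_bands, each = n_ch), "_conn_",
                                 rep(rec$channel_labels, length(conn_bands)))))
      }, numeric(n_ch * 4)))
    }
    feature_pipeline(
      "naive_bayes", recs, feature_fn,
      fit_fn = function(xs, y) list(nb = e1071::naiveBayes(xs, y)),
      predict_fn = function(model, xs)
        as.character(predict(model$nb, xs, type = "class")))
  }
  as_factory(cohort, build)
}

# ---- AdaBoost on frontal log-PSD features ---------------------------------

ada_fit <- function(x, y, n_rounds = 50) {
  df <- data.frame(y = y, x, check.names = FALSE)
  n <- nrow(df)
  w <- rep(1 / n, n)
  stumps <- list(); alphas <- numeric(0)
  for (t in seq_len(n_rounds)) {
    stump <- rpart::rpart(y ~ ., data = df, weights = w, method = "class",
                          control = rpart::rpart.control(
                            maxdepth = 1, minsplit = 2, cp = -1, xval = 0))
    pred <- predict(stump, df, type = "class")
    err <- sum(w * (pred != y)) / sum(w)
    if (err >= 0.5) break
    err <- max(err, 1e-10)
    alpha <- 0.5 * log((1 - err) / err)
    stumps[[length(stumps) + 1]] <- stump
    alphas <- c(alphas, alpha)
    miss <- pred != y
    w <- w * exp(ifelse(miss, alpha, -alpha))
    w <- w / sum(w)
    if (err <= 1e-9) break
  }
  list(stumps = stumps, alphas = alphas, levels = levels(y))
}

ada_predict <- function(model, x) {
  df <- as.data.frame(x, check.names = FALSE)
  if (length(model$stumps) == 0) {
    return(rep(model$levels[1], nrow(df)))
  }
  score <- numeric(nrow(df))
  for (t in seq_along(model$stumps)) {
    pred <- predict(model$stumps[[t]], df, type = "class")
    score <- score + model$alphas[t] * ifelse(pred == model$levels[2], 1, -1)
  }
  ifelse(score > 0, model$levels[2], model$levels[1])
}

#' AdaBoost baseline on frontal log-PSD features
#'
#' Preprocessing: 0.1-100 Hz band-pass. Features per two-second epoch: the
#' base-10 logarithm of the average power spectral density of the delta,
#' theta, alpha and gamma bands for the two frontal bipolar derivations
#' AF7-Fpz and AF8-Fpz (8 features). Classifier: AdaBoost over decision
#' stumps.
#'
#' @inheritParams naive_bayes_pipeline
#' @param n_rounds Number of boosting rounds (default 50).
#' @return A `tbi_pipeline` or its factory.
#' @export
adaboost_pipeline <- function(cohort = NULL, epoch_seconds = 2,
                              discard_seconds = 0, max_epochs = 30,
                              n_rounds = 50) {
  ada_bands <- c("delta", "theta", "alpha", "gamma")
  build <- function(recs) {
    labels <- recs[[1]]$channel_labels
    need <- c("AF7", "AF8", "Fpz")
    pos <- match(tolower(need), tolower(labels))
    if (anyNA(pos)) {
      stop("montage error: channels required but absent: ",
           paste(need[is.na(pos)], collapse = ", "), call. = FALSE)
    }
    feature_fn <- function(rec) {
      der <- rbind(rec$signal[pos[1], ] - rec$signal[pos[3], ],
                   rec$signal[pos[2], ] - rec$signal[pos[3], ])
      der <- filter_band(der, rec$fs, 0.1, 100)
      rec2 <- recording(der, rec$fs, c("AF7-Fpz", "AF8-Fpz"),
                        rec$subject_id, rec$class_label)
      epochs <- epoch_matrix(rec2, epoch_seconds, discard_seconds, max_epochs)
      t(vapply(epochs, function(ep) {
        vals <- unlist(lapply(1:2, function(ch) {
          w <- welch_psd(ep$matrix[ch, ], rec$fs)
          vapply(ada_bands, function(b) {
            rng <- band_range(b)
            sel <- w$freq >= rng[1] & w$freq < rng[2]
            log10(mean(w$psd[sel]))
          }, 0)
        }))
        stats::setNames(vals, paste0(rep(c("AF7", "AF8"), each = 4), "_",
                                     rep(ada_bands, 2), "_logpsd"))
      }, numeric(8)))
    }
    feature_pipeline(
      "adaboost", recs, feature_fn,
      fit_fn = function(xs, y) list(ada = ada_fit(xs, y, n_rounds)),
      predict_fn = function(model, xs) ada_predict(model$ada, xs))
  }
  as_factory(cohort, build)
}

# ---- SVM on MRMR-selected spectral features --------------------------------

#' SVM baseline with MRMR feature selection
#'
#' Preprocessing: 0.5-30 Hz band-pass. Features per two-second epoch and
#' electrode: average band power of theta, alpha, beta1, beta2 and beta3
#' plus the power in each 1 Hz bin from 1 to 30 Hz (34 features per
#' electrode; 2142 on the full 63-channel montage). The top `n_keep`
#' features are selected by greedy mutual-information MRMR on the training
#' fold only, then classified with a radial-kernel SVM.
#'
#' @inheritParams naive_bayes_pipeline
#' @param n_keep Features reaching the SVM (default 10).
#' @return A `tbi_pipeline` or its factory.
#' @export
svm_mrmr_pipeline <- function(cohort = NULL, epoch_seconds = 2,
                              discard_seconds = 0, max_epochs = 30,
                              n_keep = 10, exclude = "CPz") {
  mr_bands <- c("theta", "alpha", "beta1", "beta2", "beta3")
  build <- function(recs) {
    if (recs[[1]]$fs < 60) {
      stop("svm_mrmr_pipeline requires fs >= 60 Hz", call. = FALSE)
    }
    feature_fn <- function(rec) {
      m <- montage(rec$channel_labels,
                   excluded = intersect(exclude, rec$channel_labels))
      rec <- apply_montage(rec, m)
      rec$signal <- filter_band(rec$signal, rec$fs, 0.5, 30)
      epochs <- epoch_matrix(rec, epoch_seconds, discard_seconds, max_epochs)
      n_ch <- nrow(rec$signal)
      nms <- c(outer(c(paste0(mr_bands, "_pow"),
                       paste0("hz", 1:29, "_pow")),
                     rec$channel_labels, paste, sep = "_"))
      t(vapply(epochs, function(ep) {
        vals <- unlist(lapply(seq_len(n_ch), function(ch) {
          w <- welch_psd(ep$matrix[ch, ], rec$fs,
                         nperseg = ncol(ep$matrix))
          df <- w$freq[2] - w$freq[1]
          bp <- vapply(mr_bands, function(b) {
            rng <- band_range(b)
            sum(w$psd[w$freq >= rng[1] & w$freq < rng[2]]) * df
          }, 0)
          hz <- vapply(1:29, function(f0)
            sum(w$psd[w$freq >= f0 & w$freq < f0 + 1]) * df, 0)
          c(bp, hz)
        }))
        stats::setNames(vals, nms)
      }, numeric(34 * n_ch)))
    }
    feature_pipeline(
      "svm_mrmr", recs, feature_fn,
      fit_fn = function(xs, y) {
        sel <- mrmr_select(xs, y, n_keep)
        list(sel = sel,
             svm = e1071::svm(xs[, sel, drop = FALSE], y,
                              kernel = "radial", cost = 1, scale = FALSE))
      },
      predict_fn = function(model, xs)
        as.character(predict(model$svm, xs[, model$sel, drop = FALSE])))
  }
  as_factory(cohort, build)
}

# ---- SVM on alpha band power ----------------------------------------------

#' SVM baseline on per-electrode alpha power
#'
#' One feature per electrode: the alpha (8-13 Hz) band power of each
#' two-second epoch, classified with a radial-kernel SVM.
#'
#' @inheritParams naive_bayes_pipeline
#' @return A `tbi_pipeline` or its factory.
#' @export
svm_alpha_pipeline <- function(cohort = NULL, epoch_seconds = 2,
                               discard_seconds = 0, max_epochs = 30,
                               exclude = "CPz") {
  build <- function(recs) {
    if (recs[[1]]$fs < 30) {
      stop("svm_alpha_pipeline requires fs >= 30 Hz", call. = FALSE)
    }
    feature_fn <- function(rec) {
      m <- montage(rec$channel_labels,
                   excluded = intersect(exclude, rec$channel_labels))
      rec <- apply_montage(rec, m)
      epochs <- epoch_matrix(rec, epoch_seconds, discard_seconds, max_epochs)
      t(vapply(epochs, function(ep) {
        stats::setNames(band_power(ep$matrix, rec$fs, "alpha"),
                        paste0("alpha_pow_", rec$channel_labels))
      }, numeric(nrow(rec$signal))))
    }
    feature_pipeline(
      "svm_alpha", recs, feature_fn,
      fit_fn = function(xs, y)
        list(svm = e1071::svm(xs, y, kernel = "radial", cost = 1,
                              scale = FALSE)),
      predict_fn = function(model, xs) as.character(predict(model$svm, xs)))
  }
  as_factory(cohort, build)
}

# ---- reference pipelines for calibration ----------------------------------

#' Oracle and coin-flip reference pipelines
#'
#' Degenerate pipelines for calibrating the evaluation machinery: the
#' oracle always predicts the true class (bootstrap mean 100%, SD 0); the
#' coin flip predicts uniformly at random from the run's RNG stream
#' (bootstrap mean near 50%). Each subject contributes `n_units`
#' evaluation units.
#'
#' @param cohort Cohort (or `NULL` for a factory).
#' @param n_units Evaluation units per subject (default 10).
#' @return A `tbi_pipeline` or its factory.
#' @export
oracle_pipeline <- function(cohort = NULL, n_units = 10) {
  build <- function(recs) {
    tab <- subject_table(recs)
    new_pipeline("oracle", list(n_units = n_units), tab,
                 fit = function(prep, train_ids) list(),
                 predict = function(prep, model, test_ids) {
                   tab2 <- rows_for_ids(tab, test_ids)
                   data.frame(
                     subject_id = rep(tab2$subject_id, each = prep$n_units),
                     truth = rep(tab2$class_label, each = prep$n_units),
                     pred = rep(tab2$class_label, each = prep$n_units),
                     stringsAsFactors = FALSE)
                 })
  }
  as_factory(cohort, build)
}

#' @rdname oracle_pipeline
#' @export
coinflip_pipeline <- function(cohort = NULL, n_units = 10) {
  build <- function(recs) {
    tab <- subject_table(recs)
    new_pipeline("coinflip", list(n_units = n_units), tab,
                 fit = function(prep, train_ids) list(),
                 predict = function(prep, model, test_ids) {
                   tab2 <- rows_for_ids(tab, test_ids)
                   n <- nrow(tab2) * prep$n_units
                   data.frame(
                     subject_id = rep(tab2$subject_id, each = prep$n_units),
                     truth = rep(tab2$class_label, each = prep$n_units),
                     pred = sample(c("healthy", "tbi"), n, replace = TRUE),
                     stringsAsFactors = FALSE)
                 })
  }
  as_factory(cohort, build)
}

#' Look up a pipeline factory by name
#'
#' @param name One of `"cnn"`, `"naive_bayes"`, `"adaboost"`,
#'   `"svm_mrmr"`, `"svm_alpha"`.
#' @param ... Passed to the pipeline function.
#' @return A pipeline factory `function(cohort)`.
#' @export
pipeline_by_name <- function(name, ...) {
  switch(match.arg(name, c("cnn", "naive_bayes", "adaboost", "svm_mrmr",
                           "svm_alpha")),
         cnn = cnn_pipeline(...),
         naive_bayes = naive_bayes_pipeline(...),
         adaboost = adaboost_pipeline(...),
         svm_mrmr = svm_mrmr_pipeline(...),
         svm_alpha = svm_alpha_pipeline(...))
}
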