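# Content-unaware classification: a linear support-vector machine predicts
# attended-scene parity (attended_odd vs attended_even) from interval-
# averaged blink-rate vectors, with leave-one-out cross-validation, a
# nested 75/25 search over the regularization parameter C, and a label-
# permutation null. The margin solver is libsvm (via e1071); the
# cross-validation, hyperparameter selection, and permutation machinery
# are implemented here.

#' SVM classifier configuration
#'
#' @param c_grid candidate regularization values; default the decade grid
#'   `10^-2 ... 10^10` (13 values). With a single value the inner search is
#'   skipped.
#' @param inner_train_frac fraction of the training set used to train
#'   during the inner C search (default 0.75; the remaining 25% scores each
#'   C).
#' @param standardize center/scale features using training-set statistics
#'   (default TRUE; the left-out participant never contributes).
#' @return validated list of class `svm_config`.
#' @export
svm_config <- function(c_grid = 10^seq(-2, 10), inner_train_frac = 0.75,
                       standardize = TRUE) {
  cfg <- list(c_grid = as.numeric(c_grid),
              inner_train_frac = inner_train_frac,
              standardize = isTRUE(standardize))
  if (any(cfg$c_grid <= 0) || is.unsorted(cfg$c_grid, strictly = TRUE)) {
    abort("svm_config: c_grid must be strictly increasing and positive",
          class = "blinkengage_validation_error")
  }
  if (cfg$inner_train_frac <= 0 || cfg$inner_train_frac >= 1) {
    abort("svm_config: inner_train_frac must be in (0, 1)",
          class = "blinkengage_validation_error")
  }
  class(cfg) <- "svm_config"
  cfg
}

# Center/scale columns by training statistics; constant columns get unit
# scale so they standardize to zero rather than NaN.
std_stats <- function(x) {
  n <- nrow(x)
  mu <- colMeans(x)
  s <- sqrt(pmax(colSums(x^2) - n * mu^2, 0) / (n - 1))
  s[s == 0 | is.na(s)] <- 1
  list(mu = mu, s = s)
}

apply_std <- function(x, st) {
  nr <- nrow(x); nc <- ncol(x)
  (x - matrix(st$mu, nr, nc, byrow = TRUE)) /
    matrix(st$s, nr, nc, byrow = TRUE)
}

# Features are validated NA-free upstream, so NA screening is skipped
# (na.omit on wide data frames dominates the fit cost otherwise).
fit_linear_svm <- function(x, y, cost) {
  e1071::svm(x, y, kernel = "linear", cost = cost, scale = FALSE,
             fitted = FALSE, na.action = stats::na.pass)
}

# Manual linear-kernel decision rule for binary C-classification fits with
# scale = FALSE: f(x) = K(x, SV) coefs - rho, predicting the class libsvm
# ordered first when f > 0. Equivalent to predict.svm (asserted in the
# tests) but without its per-call data-frame overhead, which dominates the
# permutation-test cost.
predict_svm <- function(fit, x) {
  dec <- as.vector(x %*% crossprod(fit$SV, fit$coefs)) - fit$rho
  pos <- fit$levels[fit$labels[1]]
  neg <- fit$levels[fit$labels[2]]
  factor(ifelse(dec > 0, pos, neg), levels = fit$levels)
}

# Stratified split of indices into (1 - frac) test / frac train; re-drawn
# (up to max_attempts) if the training side would lose a class. A singleton
# class stays in training (it cannot be spared for the test side).
stratified_inner_split <- function(y, frac, max_attempts = 100) {
  for (attempt in seq_len(max_attempts)) {
    test_idx <- integer(0)
    for (lev in levels(y)) {
      idx <- which(y == lev)
      n_test <- min(max(1L, round((1 - frac) * length(idx))),
                    length(idx) - 1L)
      if (n_test > 0) test_idx <- c(test_idx, sample(idx, n_test))
    }
    train_idx <- setdiff(seq_along(y), test_idx)
    if (length(unique(y[train_idx])) == 2 && length(test_idx) > 0) {
      return(list(train = train_idx, test = test_idx))
    }
  }
  abort("inner split left a class empty after 100 attempts",
        class = "blinkengage_runtime_error")
}

#' Leave-one-out SVM classification of attended-scene parity
#'
#' For each fold, one participant is left out; the linear SVM is trained on
#' the remaining participants. The regularization parameter is chosen per
#' fold by a seeded stratified 75/25 split of the training set: each
#' candidate C is trained on the 75% and scored on the 25%, and the most
#' accurate C (ties broken towards the smallest C, i.e. the strongest
#' regularization) is refit on the full training set to predict the
#' left-out participant. Features are standardized with statistics from
#' the training rows only.
#'
#' @param x numeric feature matrix, one row per participant.
#' @param labels two-level factor of parity labels.
#' @param config an [svm_config()].
#' @param seed integer seed controlling the inner splits.
#' @return object of class `classifier_report`: list with `predicted`,
#'   `truth`, `n_correct`, `percent_correct`, `chosen_c` (per fold), `n`,
#'   `seed`.
#' @export
loocv_classify <- function(x, labels, config = svm_config(), seed = 1L) {
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2) {
    abort("loocv_classify: labels must have exactly two levels",
          class = "blinkengage_validation_error")
  }
  if (min(table(labels)) < 2) {
    abort("loocv_classify: need >= 2 participants per label",
          class = "blinkengage_validation_error")
  }
  n <- nrow(x)
  predicted <- character(n)
  chosen_c <- numeric(n)
  for (i in seq_len(n)) {
    xtr <- x[-i, , drop = FALSE]
    ytr <- labels[-i]
    st <- if (config$standardize) std_stats(xtr) else
      list(mu = rep(0, ncol(x)), s = rep(1, ncol(x)))
    xtr_s <- apply_std(xtr, st)
    xte_s <- apply_std(x[i, , drop = FALSE], st)
    if (length(config$c_grid) > 1) {
      set.seed(seed + i)
      sp <- stratified_inner_split(ytr, config$inner_train_frac)
      acc <- vapply(config$c_grid, function(cost) {
        fit <- fit_linear_svm(xtr_s[sp$train, , drop = FALSE],
                              ytr[sp$train], cost)
        mean(predict_svm(fit, xtr_s[sp$test, , drop = FALSE]) ==
               ytr[sp$test])
      }, numeric(1))
      best_c <- config$c_grid[which.max(acc)]  # which.max: first max = smallest C
    } else {
      best_c <- config$c_grid[1]
    }
    fit <- fit_linear_svm(xtr_s, ytr, best_c)
    predicted[i] <- as.character(predict_svm(fit, xte_s))
    chosen_c[i] <- best_c
  }
  out <- list(
    predicted = factor(predicted, levels = levels(labels)),
    truth = labels,
    n_correct = sum(predicted == as.character(labels)),
    percent_correct = 100 * mean(predicted == as.character(labels)),
    chosen_c = chosen_c,
    n = n,
    seed = seed
  )
  class(out) <- "classifier_report"
  out
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("<classifier_report: %d/%d correct (%.2f%%)>\n",
              x$n_correct, x$n, x$percent_correct))
  invisible(x)
}

#' Permutation test of classifier accuracy
#'
#' Re-runs the full leave-one-out classification `n_perm` times with parity
#' labels randomly reassigned without replacement, building a null
#' distribution of accuracies. The p-value uses the add-one estimator
#' `p = (1 + #(null >= observed)) / (n_perm + 1)` so it is never exactly
#' zero; `cutoff_95` is the empirical 95th percentile of the null.
#'
#' @param x,labels,config as in [loocv_classify()].
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed; permutation `k` draws from seed `seed + k`
#'   while the inner splits reuse `seed` as in the observed fit.
#' @param observed optionally, a precomputed observed `classifier_report`.
#' @return list with `observed` (report), `null_percent_correct`,
#'   `cutoff_95`, `p_value`, `n_perm`.
#' @export
permutation_test <- function(x, labels, config = svm_config(),
                             n_perm = 1000, seed = 1L, observed = NULL) {
  if (n_perm < 100) {
    abort("permutation_test: n_perm must be >= 100",
          class = "blinkengage_validation_error")
  }
  if (is.null(observed)) {
    observed <- loocv_classify(x, labels, config, seed = seed)
  }
  null_acc <- numeric(n_perm)
  for (k in seq_len(n_perm)) {
    set.seed(seed + 100000L + k)
    perm <- sample(as.character(labels))   # reassignment without replacement
    null_acc[k] <- loocv_classify(
      x, factor(perm, levels = levels(as.factor(labels))),
      config, seed = seed)$percent_correct
  }
  list(
    observed = observed,
    null_percent_correct = null_acc,
    cutoff_95 = as.numeric(quantile(null_acc, 0.95, type = 1)),
    p_value = (1 + sum(null_acc >= observed$percent_correct)) / (n_perm + 1),
    n_perm = n_perm
  )
}

#' Content-unaware classification across interval sizes
#'
#' Runs [build_features()] plus [loocv_classify()] for each interval size,
#' optionally adding a permutation test, and returns one summary row per
#' interval size (the shape of a results table over interval sizes 1-10 s).
#'
#' @param participants,events,schedules domain tables.
#' @param intervals_s interval sizes in seconds (default 1--10).
#' @param config an [svm_config()].
#' @param n_perm permutations per interval (0 disables the test).
#' @param seed integer seed.
#' @return tibble `interval_s, n_correct, n, percent_correct, p_value,
#'   cutoff_95` with the per-interval reports in attribute `reports`.
#' @export
classify_unaware_sweep <- function(participants, events, schedules,
                                   intervals_s = 1:10,
                                   config = svm_config(), n_perm = 0,
                                   seed = 1L) {
  rows <- vector("list", length(intervals_s))
  reports <- vector("list", length(intervals_s))
  for (k in seq_along(intervals_s)) {
    feats <- build_features(participants, events, schedules, intervals_s[k])
    rep <- loocv_classify(feats$x, feats$labels, config, seed = seed)
    p_value <- NA_real_; cutoff <- NA_real_
    if (n_perm > 0) {
      pt <- permutation_test(feats$x, feats$labels, config, n_perm = n_perm,
                             seed = seed, observed = rep)
      p_value <- pt$p_value; cutoff <- pt$cutoff_95
      reports[[k]] <- pt
    } else {
      reports[[k]] <- rep
    }
    rows[[k]] <- tibble(
      interval_s = intervals_s[k],
      n_correct = rep$n_correct,
      n = rep$n,
      percent_correct = rep$percent_correct,
      p_value = p_value,
      cutoff_95 = cutoff
    )
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "reports") <- setNames(reports, paste0("interval_", intervals_s))
  out
}
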