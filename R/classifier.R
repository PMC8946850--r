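#' Build a labeled feature set from processed sessions
#'
#' Assembles the parietal high-beta features (P3, P4 band power) of every
#' labeled epoch. Multitask levels 1-2 are labeled low (0), levels 6-7 high
#' (1); middle levels 3-5 and rest epochs are excluded. Driving runs are
#' labeled by their run condition. Artifact-flagged epochs are absent by
#' construction (feature series only hold retained epochs).
#'
#' @param feature_tab data frame with columns `P3`, `P4`, `condition`,
#'   `repetition_id` (and any others), one row per retained epoch.
#' @param subject_id subject label.
#' @return object of class `labeled_feature_set`: list with `features`
#'   (n x 2 matrix), `labels`, `groups` (repetition id) and `subject_id`.
#' @export
labeled_feature_set <- function(feature_tab, subject_id = NA_character_) {
  lab <- condition_to_label(feature_tab$condition)
  keep <- !is.na(lab)
  x <- as.matrix(feature_tab[keep, c("P3", "P4")])
  if (any(!is.finite(x)) || any(x < 0)) stop("features must be finite and >= 0")
  structure(list(features = x,
                 labels = lab[keep],
                 groups = feature_tab$repetition_id[keep],
                 synthetic = rep(FALSE, sum(keep)),
                 subject_id = subject_id),
            class = "labeled_feature_set")
}

#' @export
print.labeled_feature_set <- function(x, ...) {
  cat(sprintf("<labeled_feature_set %s> %d epochs (%d high, %d synthetic)\n",
              x$subject_id, length(x$labels), sum(x$labels == 1),
              sum(x$synthetic)))
  invisible(x)
}

#' ADASYN class balancing
#'
#' Adaptive synthetic oversampling of the minority class: each minority
#' point receives a share of the synthetic budget proportional to the
#' fraction of majority points among its k nearest neighbors, and synthetic
#' points are drawn on segments between the point and one of its minority
#' neighbors. Balancing is only triggered when the minority/majority ratio
#' is below `ratio_gate`; when the minority class has fewer than `k + 1`
#' members the method falls back to random duplication (with a message).
#'
#' @param data a [labeled_feature_set()].
#' @param seed integer seed.
#' @param k neighborhood size (default 5).
#' @param ratio_gate imbalance ratio below which balancing is applied.
#' @return a `labeled_feature_set` with synthetic rows flagged in
#'   `$synthetic`.
#' @export
balance_classes <- function(data, seed = 1L, k = 5L, ratio_gate = 0.8) {
  stopifnot(inherits(data, "labeled_feature_set"))
  y <- data$labels
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  minority <- if (n1 <= n0) 1L else 0L
  n_min <- min(n1, n0); n_maj <- max(n1, n0)
  if (n_min / n_maj >= ratio_gate) return(data)
  g <- n_maj - n_min                      # synthetic budget

  x <- data$features
  mi <- which(y == minority)
  with_seed(seed, {
    if (length(mi) < k + 1) {
      message("minority class too small for ADASYN; duplicating at random")
      pick <- sample(mi, g, replace = TRUE)
      new_x <- x[pick, , drop = FALSE]
    } else {
      # ratio of majority neighbors among the k nearest (any class)
      d2 <- as.matrix(stats::dist(x))
      r <- vapply(mi, function(i) {
        nb <- order(d2[i, ])[-1][seq_len(k)]
        sum(y[nb] != minority) / k
      }, numeric(1))
      if (sum(r) == 0) r <- rep(1, length(r))
      gi <- round(r / sum(r) * g)
      # minority-only neighborhoods for interpolation
      dmin <- as.matrix(stats::dist(x[mi, , drop = FALSE]))
      new_x <- matrix(0, 0, ncol(x))
      for (j in seq_along(mi)) {
        if (gi[j] == 0) next
        nbm <- order(dmin[j, ])[-1][seq_len(min(k, length(mi) - 1))]
        pick <- sample(nbm, gi[j], replace = TRUE)
        u <- stats::runif(gi[j])
        base <- x[mi[j], , drop = FALSE][rep(1, gi[j]), , drop = FALSE]
        targ <- x[mi[pick], , drop = FALSE]
        new_x <- rbind(new_x, base + u * (targ - base))
      }
    }
    m <- nrow(new_x)
    structure(list(features = rbind(x, new_x),
                   labels = c(y, rep(minority, m)),
                   groups = c(data$groups, rep(NA, m)),
                   synthetic = c(data$synthetic, rep(TRUE, m)),
                   subject_id = data$subject_id),
              class = "labeled_feature_set")
  })
}

#' Hyperparameter search space for the random-forest comparator
#'
#' Ranges follow the model as published: number of trees 50-500, maximum
#' depth 2-30, minimum samples to split 0.01-0.5 (fraction of n), minimum
#' samples per leaf 0.01-0.5, maximum leaf nodes 2-40. The leaf-count cap
#' is enforced through an equivalent depth bound (`ceil(log2(max_leaf_nodes))`)
#' in the ranger backend.
#'
#' @param search_budget number of random draws evaluated.
#' @param seed integer seed for sampling and fitting.
#' @param n_folds inner stratified cross-validation folds.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(search_budget = 50L, seed = 1L, n_folds = 3L) {
  structure(list(n_estimators = c(50L, 500L),
                 max_depth = c(2L, 30L),
                 min_samples_split = c(0.01, 0.5),
                 min_samples_leaf = c(0.01, 0.5),
                 max_leaf_nodes = c(2L, 40L),
                 search_budget = as.integer(search_budget),
                 n_folds = as.integer(n_folds),
                 seed = as.integer(seed)),
            class = "model_spec")
}

sample_spec <- function(space) {
  list(n_estimators = sample(space$n_estimators[1]:space$n_estimators[2], 1),
       max_depth = sample(space$max_depth[1]:space$max_depth[2], 1),
       min_samples_split = stats::runif(1, space$min_samples_split[1],
                                        space$min_samples_split[2]),
       min_samples_leaf = stats::runif(1, space$min_samples_leaf[1],
                                       space$min_samples_leaf[2]),
       max_leaf_nodes = sample(space$max_leaf_nodes[1]:space$max_leaf_nodes[2], 1))
}

fit_ranger <- function(x, y, par, seed) {
  n <- nrow(x)
  df <- data.frame(x, y = factor(y, levels = c(0, 1)))
  ranger::ranger(y ~ ., data = df,
                 num.trees = par$n_estimators,
                 max.depth = min(par$max_depth,
                                 ceiling(log2(par$max_leaf_nodes))),
                 min.node.size = max(2L, ceiling(par$min_samples_split * n)),
                 min.bucket = max(1L, ceiling(par$min_samples_leaf * n)),
                 probability = TRUE, importance = "impurity",
                 num.threads = 1, seed = seed)
}

predict_prob <- function(fit, x) {
  p <- stats::predict(fit, data.frame(x))$predictions
  as.numeric(p[, "1"])
}

#' Train the random-forest stress classifier with randomized search
#'
#' Randomized hyperparameter search over the published ranges, scored by
#' stratified cross-validated AUC inside the training split only; the best
#' configuration is refit on the full training split.
#'
#' @param data a balanced [labeled_feature_set()] with >= 20 rows per class.
#' @param spec_space a [model_spec()].
#' @return object of class `trained_model` with the chosen configuration,
#'   the fitted forest and normalized feature importances.
#' @export
train_rf <- function(data, spec_space = model_spec()) {
  stopifnot(inherits(data, "labeled_feature_set"),
            inherits(spec_space, "model_spec"))
  x <- data$features; y <- data$labels
  if (min(table(y)) < 20) stop("need at least 20 rows per class")
  if (any(apply(x, 2, function(c) length(unique(c))) < 2))
    stop("degenerate single-valued feature")

  with_seed(spec_space$seed, {
    folds <- make_stratified_folds(y, spec_space$n_folds)
    best <- NULL
    for (b in seq_len(spec_space$search_budget)) {
      par <- sample_spec(spec_space)
      aucs <- vapply(seq_len(spec_space$n_folds), function(f) {
        tr <- folds != f; te <- !tr
        fit <- fit_ranger(x[tr, , drop = FALSE], y[tr], par,
                          seed = spec_space$seed + b)
        compute_auc(predict_prob(fit, x[te, , drop = FALSE]), y[te])
      }, numeric(1))
      sc <- mean(aucs)
      if (is.null(best) || sc > best$score) best <- list(par = par, score = sc)
    }
    fit <- fit_ranger(x, y, best$par, seed = spec_space$seed)
    imp <- fit$variable.importance
    imp <- pmax(imp, 0)
    if (sum(imp) > 0) imp <- imp / sum(imp)
    structure(list(spec = best$par, cv_auc = best$score, fit = fit,
                   feature_importances = imp),
              class = "trained_model")
  })
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf("<trained_model> %d trees, inner-CV AUC %.3f\n",
              x$spec$n_estimators, x$cv_auc))
  invisible(x)
}

make_stratified_folds <- function(y, n_folds) {
  f <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    f[idx] <- sample(rep(seq_len(n_folds), length.out = length(idx)))
  }
  f
}

#' Intra-subject train/test protocol
#'
#' For every ordered pair of repetitions of the chosen task, a model is
#' trained (with ADASYN balancing and inner-CV hyperparameter search) on
#' one repetition and emits the per-epoch high-stress probability on the
#' other, so every repetition appears as a test set. Synthetic rows never
#' enter a test split.
#'
#' @param data a [labeled_feature_set()] whose `groups` hold repetition ids.
#' @param spec_space a [model_spec()].
#' @param epoch_info optional data frame (same rows as `data`) with
#'   `epoch_time` and `block` columns carried onto the score series.
#' @return list of [score_series()] (measure `"rf_intra"`), one per ordered
#'   train/test pair, named `"<train>-><test>"`.
#' @export
intra_subject_protocol <- function(data, spec_space = model_spec(),
                                   epoch_info = NULL) {
  stopifnot(inherits(data, "labeled_feature_set"))
  reps <- sort(unique(data$groups))
  if (length(reps) < 2) stop("at least 2 repetitions required")
  out <- list()
  for (tr_rep in reps) {
    for (te_rep in setdiff(reps, tr_rep)) {
      tr_idx <- data$groups == tr_rep
      te_idx <- data$groups == te_rep
      train <- subset_lfs(data, tr_idx)
      bal <- balance_classes(train, seed = spec_space$seed)
      model <- train_rf(bal, spec_space)
      prob <- predict_prob(model$fit, data$features[te_idx, , drop = FALSE])
      ei <- if (is.null(epoch_info)) NULL else epoch_info[te_idx, , drop = FALSE]
      out[[paste0(tr_rep, "->", te_rep)]] <- score_series(
        prob,
        epoch_times = ei$epoch_time %||% seq_len(sum(te_idx)),
        labels = data$labels[te_idx],
        blocks = ei$block %||% 1L,
        measure = "rf_intra", subject_id = data$subject_id)
    }
  }
  out
}

#' Cross-task protocol: train on multitasking, test on driving
#'
#' One model per subject is trained on all labeled multitask epochs (after
#' balancing) and scored on all labeled driving epochs of the same subject.
#'
#' @param multitask,driving [labeled_feature_set()] objects of one subject.
#' @param spec_space a [model_spec()].
#' @param epoch_info optional data frame (rows matching `driving`) with
#'   `epoch_time` and `block` columns.
#' @return a [score_series()] with measure `"rf_cross"`.
#' @export
cross_task_protocol <- function(multitask, driving,
                                spec_space = model_spec(),
                                epoch_info = NULL) {
  stopifnot(inherits(multitask, "labeled_feature_set"),
            inherits(driving, "labeled_feature_set"))
  if (length(multitask$labels) == 0 || length(driving$labels) == 0)
    stop("both tasks must be available")
  bal <- balance_classes(multitask, seed = spec_space$seed)
  model <- train_rf(bal, spec_space)
  prob <- predict_prob(model$fit, driving$features)
  score_series(prob,
               epoch_times = epoch_info$epoch_time %||% seq_along(prob),
               labels = driving$labels,
               blocks = epoch_info$block %||% 1L,
               measure = "rf_cross", subject_id = driving$subject_id)
}

subset_lfs <- function(data, idx) {
  structure(list(features = data$features[idx, , drop = FALSE],
                 labels = data$labels[idx],
                 groups = data$groups[idx],
                 synthetic = data$synthetic[idx],
                 subject_id = data$subject_id),
            class = "labeled_feature_set")
}
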