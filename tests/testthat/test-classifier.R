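test_that("epoch labeling keeps only low/high conditions with clean features", {
  tab <- data.frame(
    P3 = runif(7 * 60, 1, 2), P4 = runif(7 * 60, 1, 2),
    condition = rep(c("low", "low", "middle", "middle", "middle",
                      "high", "high"), each = 60),
    repetition_id = 1L)
  lfs <- labeled_feature_set(tab, "S01")
  expect_equal(length(lfs$labels), 240)        # levels 1-2 and 6-7 only
  expect_equal(sum(lfs$labels == 0), 120)
  expect_equal(sum(lfs$labels == 1), 120)

  drv <- data.frame(P3 = runif(120), P4 = runif(120),
                    condition = "low", repetition_id = 1L)
  lfs_d <- labeled_feature_set(drv)
  expect_equal(length(lfs_d$labels), 120)
  expect_true(all(lfs_d$labels == 0))

  bad <- tab; bad$P3[1] <- -1
  expect_error(labeled_feature_set(bad))
})

test_that("ADASYN balances classes only when needed, on minority segments", {
  balanced <- make_lfs(100, 100)
  expect_identical(balance_classes(balanced, seed = 1), balanced)

  imb <- make_lfs(100, 50)
  bal <- balance_classes(imb, seed = 1)
  n1 <- sum(bal$labels == 1)
  expect_gte(n1, 95)
  expect_lte(n1, 105)
  expect_true(all(bal$synthetic[bal$labels == 0] == FALSE))

  # every synthetic row lies on a segment between two real minority rows
  real_min <- imb$features[imb$labels == 1, ]
  syn <- bal$features[bal$synthetic, , drop = FALSE]
  on_segment <- function(p) {
    for (i in seq_len(nrow(real_min))) {
      a <- real_min[i, ]
      for (j in seq_len(nrow(real_min))[-i]) {
        b <- real_min[j, ]
        v <- b - a; w <- p - a
        if (sum(v^2) < 1e-12) next
        u <- sum(w * v) / sum(v^2)
        if (u >= -1e-8 && u <= 1 + 1e-8 &&
            sqrt(sum((w - u * v)^2)) < 1e-8) return(TRUE)
      }
    }
    FALSE
  }
  expect_true(all(apply(syn, 1, on_segment)))

  # tiny minority class falls back to duplication with a message
  tiny <- make_lfs(40, 4)
  expect_message(btiny <- balance_classes(tiny, seed = 1), "duplicating")
  expect_gte(sum(btiny$labels == 1), 36)
})

test_that("randomized-search training is reproducible and sane", {
  sep <- make_lfs(60, 60, shift = 30, sd = 0.5)    # fully separable
  m <- train_rf(sep, model_spec(search_budget = 4, seed = 3))
  expect_equal(compute_auc(neurostress:::predict_prob(m$fit, sep$features),
                           sep$labels), 1)
  expect_equal(sum(m$feature_importances), 1, tolerance = 1e-8)
  expect_true(all(m$feature_importances >= 0))

  m2 <- train_rf(sep, model_spec(search_budget = 4, seed = 3))
  expect_identical(m$spec, m2$spec)
  expect_identical(m$cv_auc, m2$cv_auc)

  # permuted labels: inner-CV AUC hovers around chance
  perm <- make_lfs(80, 80, shift = 1)
  set.seed(11)
  perm$labels <- sample(perm$labels)
  mp <- train_rf(perm, model_spec(search_budget = 4, seed = 5))
  expect_gt(mp$cv_auc, 0.35)
  expect_lt(mp$cv_auc, 0.65)

  degenerate <- make_lfs(30, 30)
  degenerate$features[, 1] <- 1; degenerate$features[, 2] <- 1
  expect_error(train_rf(degenerate), "degenerate")
})

test_that("intra-subject protocol scores every repetition as a held-out set", {
  lfs <- make_lfs(120, 120, shift = 2)
  lfs$groups <- rep(c(1L, 2L), 120)
  out <- intra_subject_protocol(lfs, model_spec(search_budget = 3, seed = 2))
  expect_named(out, c("1->2", "2->1"))
  for (s in out) {
    expect_true(all(s$value >= 0 & s$value <= 1))
    expect_equal(nrow(s), 120)          # only real test-repetition rows
  }
  expect_gt(mean(vapply(out, compute_auc, numeric(1))), 0.7)

  single <- lfs; single$groups <- rep(1L, 240)
  expect_error(intra_subject_protocol(single), "2 repetitions")
})

subset_empty <- function(lfs)
  neurostress:::subset_lfs(lfs, rep(FALSE, length(lfs$labels)))

test_that("cross-task transfer matches intra-subject when distributions match and degrades under feature scaling", {
  proc <- fixture_subject(1)
  mt <- task_features(proc, "multitask")
  dr <- task_features(proc, "driving")
  spec <- model_spec(search_budget = 5, seed = 7)

  cross <- cross_task_protocol(mt$data, dr$data, spec, dr$epoch_info)
  expect_true(all(cross$value >= 0 & cross$value <= 1))
  auc_cross <- compute_auc(cross)

  intra <- intra_subject_protocol(dr$data, spec, dr$epoch_info)
  auc_intra <- mean(vapply(intra, compute_auc, numeric(1)))
  expect_lt(abs(auc_cross - auc_intra), 0.12)   # matched distributions

  # a task shift pushing the driving features outside the training support
  # saturates the calibrated model and wrecks its discrimination
  scaled <- dr$data
  scaled$features <- scaled$features * 30
  auc_shift <- compute_auc(cross_task_protocol(mt$data, scaled, spec,
                                               dr$epoch_info))
  expect_lt(auc_shift, auc_cross - 0.15)

  expect_error(cross_task_protocol(mt$data, subset_empty(dr$data)),
               "both tasks")
})

test_that("cross-task scores disperse more than the Neurometric under task shift", {
  # qualitative mirror of the instability of cross-task calibration: scale
  # the driving features of each subject and compare AUC dispersion
  aucs <- t(vapply(c(1, 2, 3, 4, 5, 6), function(seed) {
    proc <- fixture_subject(seed)
    mt <- task_features(proc, "multitask")
    dr <- task_features(proc, "driving")
    fac <- c(0.05, 0.3, 1, 1, 8, 40)[seed]        # subject-specific shift
    dr$data$features <- dr$data$features * fac
    cross <- compute_auc(cross_task_protocol(
      mt$data, dr$data, model_spec(search_budget = 4, seed = seed),
      dr$epoch_info))
    neuro <- mean(vapply(measure_scores(proc, "neurometric", "driving"),
                         compute_auc, numeric(1)))
    c(cross = cross, neuro = neuro)
  }, numeric(2)))
  expect_gt(stats::IQR(aucs[, "cross"]), stats::IQR(aucs[, "neuro"]))
})
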