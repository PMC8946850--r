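test_that("decimation is a block-wise trailing mean with expanding warm-up", {
  s <- score_series(values = rnorm(30), epoch_times = 0:29,
                    labels = rep(c(0L, 1L), each = 15),
                    blocks = rep(c("a", "b"), each = 15))
  expect_equal(moving_average_decimate(s, 1), s)

  const <- score_series(rep(3, 20), 0:19, rep(0L, 20), rep("a", 20))
  expect_equal(moving_average_decimate(const, 10)$value, rep(3, 20))

  alt <- score_series(rep(c(0, 1), 10), 0:19, rep(0L, 20), "a")
  d2 <- moving_average_decimate(alt, 2)
  expect_equal(d2$value[3:20], rep(0.5, 18))   # steady state after warm-up

  # direct convolution oracle within one block
  set.seed(4)
  v <- rnorm(40)
  one <- score_series(v, 0:39, 0L, "a")
  d10 <- moving_average_decimate(one, 10)$value
  oracle <- vapply(seq_along(v), function(i)
    mean(v[max(1, i - 9):i]), numeric(1))
  expect_equal(d10, oracle)

  # block boundaries are respected: second block restarts its warm-up
  d10b <- moving_average_decimate(s, 10)$value
  expect_equal(d10b[16], s$value[16])          # first epoch of block b

  # labels untouched, block means conserved
  expect_equal(d2$label, alt$label)
  expect_equal(mean(moving_average_decimate(const, 10)$value),
               mean(const$value))

  expect_error(moving_average_decimate(s, 2.5), "integer")
})

test_that("AUC equals exhaustive pair counting with half-weight ties", {
  expect_equal(compute_auc(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0)), 1)
  expect_equal(compute_auc(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)

  brute_auc <- function(s, y) {
    pos <- s[y == 1]; neg <- s[y == 0]
    mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
  }
  expect_equal(compute_auc(c(3, 1, 2, 0), c(1, 0, 1, 0)),
               brute_auc(c(3, 1, 2, 0), c(1, 0, 1, 0)))
  set.seed(9)
  for (i in 1:20) {
    n <- sample(4:10, 1)
    s <- sample(0:5, n, replace = TRUE)   # ties likely
    y <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    expect_equal(compute_auc(s, y), brute_auc(s, y))
  }

  # invariance under strictly monotone transforms
  s <- runif(30); y <- rep(c(0, 1), 15)
  expect_equal(compute_auc(exp(3 * s) + 1, y), compute_auc(s, y))
  expect_error(compute_auc(s, rep(1, 30)), "both classes")
})

test_that("curve normalization and comparison behave on known cases", {
  s <- score_series(c(2, 4, 6), 0:2, 0L, "a")
  expect_equal(normalize_curve(s)$value, c(0, 0.5, 1))
  u <- score_series(c(0, 0.3, 1), 0:2, 0L, "a")
  expect_equal(normalize_curve(u)$value, u$value)
  expect_equal(which.max(normalize_curve(s)$value), which.max(s$value))
  expect_warning(z <- normalize_curve(score_series(rep(1, 5), 0:4, 0L, "a")),
                 "constant")
  expect_equal(z$value, rep(0.5, 5))

  a <- score_series(c(0, 0.2, 0.7, 1), 0:3, 0L, "a")
  same <- compare_curves(a, a)
  expect_equal(same$r, 1)
  expect_equal(same$rmse, 0)
  anti <- score_series(1 - a$value, 0:3, 0L, "a")
  expect_equal(compare_curves(a, anti)$r, -1)

  b <- score_series(c(0, 1, 0, 1), 0:3, 0L, "a")
  h <- compare_curves(score_series(c(0, 0, 1, 1), 0:3, 0L, "a"), b)
  expect_equal(h$r, 0)                        # hand-computed on 4 points
  expect_equal(h$rmse, sqrt(0.5))
  expect_error(compare_curves(a, score_series(1:3, 0:2, 0L, "a"),
                              match_times = FALSE), "mismatch")
})

test_that("Friedman/Dunn matches hand rank computation and gates the post hoc", {
  # identical columns: zero statistic, p = 1
  same <- matrix(rep(1:8, 3), 8, 3)
  r0 <- friedman_dunn(same)
  expect_equal(r0$friedman$chi2, 0)
  expect_gt(r0$friedman$p, 0.99)
  expect_null(r0$dunn)

  # hand enumeration on a 3x3 toy matrix without ties
  toy <- matrix(c(1, 2, 3,
                  2, 3, 1,
                  3, 1, 2,
                  1, 3, 2,
                  2, 1, 3,
                  1, 2, 3), 6, 3, byrow = TRUE)
  rk <- t(apply(toy, 1, rank))
  n <- nrow(toy); k <- 3
  chi2_hand <- 12 / (n * k * (k + 1)) * sum(colSums(rk)^2) - 3 * n * (k + 1)
  rt <- friedman_dunn(toy)
  expect_equal(rt$friedman$chi2, chi2_hand)

  # a stochastically dominant column is detected at n = 18
  set.seed(21)
  base <- matrix(runif(18 * 3, 0.4, 0.6), 18, 3,
                 dimnames = list(NULL, c("a", "b", "c")))
  base[, "c"] <- base[, "c"] + 0.25
  rs <- friedman_dunn(base)
  expect_lt(rs$friedman$p, 0.05)
  expect_false(is.null(rs$dunn))
  zc <- rs$dunn[rs$dunn$a == "c" | rs$dunn$b == "c", ]
  expect_true(all(zc$p < 0.05))

  expect_error(friedman_dunn(base[1:4, ]), "6 subjects")
  expect_error(friedman_dunn(base[, 1:2]), "3 measures")
})

test_that("Wilcoxon signed-rank matches the exact sign-flip distribution", {
  up <- 1:18 + 0.5
  r <- wilcoxon_signed_rank(up, rep(0, 18))
  expect_lt(r$p, 0.05)
  expect_gt(r$Z, 0)

  anti <- c(1, -1, 2, -2, 3, -3, 4, -4)
  expect_equal(wilcoxon_signed_rank(anti)$Z, 0)

  # exact p at n = 8 against exhaustive 2^8 sign enumeration
  d <- c(1.3, -0.4, 2.2, 0.9, -1.7, 3.1, 0.6, 2.8)
  res <- wilcoxon_signed_rank(d)
  expect_equal(res$method, "exact")
  r_abs <- rank(abs(d))
  w_obs <- sum(r_abs[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), 8))
  w_all <- as.matrix(signs) %*% r_abs
  mu <- sum(r_abs) / 2
  p_exact <- if (w_obs > mu) 2 * mean(w_all >= w_obs) else 2 * mean(w_all <= w_obs)
  expect_equal(res$p, min(1, p_exact))

  expect_error(wilcoxon_signed_rank(c(0, 0, 0, 0, 0, 0)), "non-zero")
})
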