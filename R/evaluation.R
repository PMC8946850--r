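#' Time-indexed continuous stress score
#'
#' Common container for all four stress measures (Neurometric, mean SCL,
#' intra-subject and cross-task random-forest probability): one value per
#' 1 s epoch, with a binary stress label (`NA` for unlabeled epochs) and a
#' block identifier marking contiguous same-condition segments, across which
#' the moving-average decimation never averages.
#'
#' @param values numeric scores.
#' @param epoch_times epoch start times in seconds.
#' @param labels integer 0 (low), 1 (high) or `NA`.
#' @param blocks block identifier per epoch.
#' @param measure one of `"neurometric"`, `"scl"`, `"rf_intra"`, `"rf_cross"`.
#' @param subject_id optional subject label.
#' @return object of class `score_series` (a data frame).
#' @export
score_series <- function(values, epoch_times, labels = NA_integer_,
                         blocks = 1L, measure = "neurometric",
                         subject_id = NA_character_) {
  stopifnot(all(is.finite(values)))
  df <- data.frame(epoch_time = epoch_times, value = as.numeric(values),
                   label = as.integer(labels), block = blocks)
  if (!all(df$label %in% c(0L, 1L, NA_integer_)))
    stop("labels must be 0, 1 or NA")
  structure(df, class = c("score_series", "data.frame"),
            measure = measure, subject_id = subject_id)
}

#' Concatenate score series (e.g. blocks of one evaluation session)
#' @param ... `score_series` objects sharing a measure.
#' @return a single `score_series`.
#' @export
bind_scores <- function(...) {
  parts <- list(...)
  if (length(parts) == 1 && is.list(parts[[1]]) &&
      !inherits(parts[[1]], "score_series")) parts <- parts[[1]]
  stopifnot(all(vapply(parts, inherits, TRUE, "score_series")))
  df <- do.call(rbind, lapply(seq_along(parts), function(i) {
    d <- as.data.frame(parts[[i]])
    d$block <- paste0(i, "_", d$block)
    d
  }))
  rownames(df) <- NULL
  structure(df, class = c("score_series", "data.frame"),
            measure = attr(parts[[1]], "measure"),
            subject_id = attr(parts[[1]], "subject_id"))
}

#' Moving-average decimation of a score series
#'
#' Emulates a coarser time resolution by applying a trailing (causal) moving
#' average of `window` epochs to the scores. Averaging is restricted to
#' epochs of the same block, so values never mix across condition
#' boundaries; at the start of a block the window expands from 1 up to
#' `window` (warm-up). `window = 1` is the identity. Labels are unchanged.
#'
#' @param series a [score_series()].
#' @param window window length in epochs (a positive integer; the standard
#'   evaluation grid is [DECIMATIONS]).
#' @return the decimated `score_series`.
#' @export
moving_average_decimate <- function(series, window) {
  stopifnot(inherits(series, "score_series"))
  if (length(window) != 1 || window < 1 || window != round(window))
    stop("window must be a positive integer number of epochs")
  if (window == 1) return(series)
  out <- series
  for (b in unique(series$block)) {
    sel <- series$block == b
    out$value[sel] <- trailing_mean(series$value[sel], window)
  }
  out
}

#' ROC AUC by pairwise comparison (Mann-Whitney formulation)
#'
#' Probability that a uniformly drawn high-stress epoch outscores a
#' low-stress epoch, ties counted one half. Unlabeled epochs are dropped.
#'
#' @param series a [score_series()], or a numeric vector of scores if
#'   `labels` is given.
#' @param labels optional binary labels when `series` is a plain vector.
#' @return AUC in `[0, 1]`.
#' @export
compute_auc <- function(series, labels = NULL) {
  if (inherits(series, "score_series")) {
    keep <- !is.na(series$label)
    s <- series$value[keep]; y <- series$label[keep]
  } else {
    s <- as.numeric(series); y <- as.integer(labels)
    keep <- !is.na(y); s <- s[keep]; y <- y[keep]
  }
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(s)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Min-max normalize a score series to [0, 1]
#'
#' Used for curve plotting and curve comparison only; AUC is invariant to
#' monotone transforms and is always computed on raw scores.
#'
#' @param series a [score_series()].
#' @return normalized `score_series`; a constant series maps to 0.5
#'   everywhere (with a warning).
#' @export
normalize_curve <- function(series) {
  stopifnot(inherits(series, "score_series"))
  rng <- range(series$value)
  if (diff(rng) == 0) {
    warning("constant series; normalized to 0.5")
    series$value <- rep(0.5, nrow(series))
    return(series)
  }
  series$value <- (series$value - rng[1]) / diff(rng)
  series
}

#' Compare two stress curves: Pearson correlation and RMSE
#'
#' Curves are matched on `epoch_time` (inner join), so measures with
#' different artifact-rejection patterns can be compared on their common
#' epochs. Inputs are expected to be normalized to `[0, 1]`.
#'
#' @param a,b [score_series()] objects.
#' @param match_times logical; if `FALSE`, both series must have equal
#'   length and are compared position-wise.
#' @return list with elements `r` (Pearson correlation) and `rmse`.
#' @export
compare_curves <- function(a, b, match_times = TRUE) {
  stopifnot(inherits(a, "score_series"), inherits(b, "score_series"))
  if (match_times) {
    m <- merge(as.data.frame(a)[, c("epoch_time", "value")],
               as.data.frame(b)[, c("epoch_time", "value")],
               by = "epoch_time")
    if (nrow(m) < 3) stop("fewer than 3 common epochs")
    va <- m$value.x; vb <- m$value.y
  } else {
    if (nrow(a) != nrow(b)) stop("curve length mismatch")
    va <- a$value; vb <- b$value
  }
  list(r = stats::cor(va, vb), rmse = sqrt(mean((va - vb)^2)))
}

#' Friedman test with Dunn post hoc on a subjects x measures AUC block
#'
#' Friedman chi-square on within-subject ranks (delegated to
#' [stats::friedman.test()]); when the Friedman test is significant at
#' `alpha`, pairwise Dunn Z statistics on mean ranks are computed,
#' `Z_ij = (Rbar_i - Rbar_j) / sqrt(k (k + 1) / (6 n))`.
#'
#' @param auc_block numeric matrix, subjects in rows, measures in columns
#'   (no missing cells).
#' @param alpha significance gate for the post hoc stage.
#' @param p_adjust `"none"` (default) or `"bonferroni"` for the Dunn
#'   p-values.
#' @return list with `friedman` (statistic, df, p) and `dunn` (data frame of
#'   pairwise Z and p, or `NULL` when not significant).
#' @export
friedman_dunn <- function(auc_block, alpha = 0.05,
                          p_adjust = c("none", "bonferroni")) {
  p_adjust <- match.arg(p_adjust)
  auc_block <- as.matrix(auc_block)
  if (any(!is.finite(auc_block))) stop("missing cells in AUC block")
  n <- nrow(auc_block); k <- ncol(auc_block)
  if (k < 3) stop("at least 3 measures required")
  if (n < 6) stop("at least 6 subjects required")
  ft <- stats::friedman.test(auc_block)
  chi2 <- unname(ft$statistic); p <- ft$p.value
  if (!is.finite(chi2)) {
    # every row fully tied: zero rank variance, nothing to test
    chi2 <- 0; p <- 1
  }
  res <- list(friedman = list(chi2 = chi2, df = unname(ft$parameter), p = p),
              dunn = NULL)
  if (p < alpha) {
    rk <- t(apply(auc_block, 1, rank))
    rbar <- colMeans(rk)
    se <- sqrt(k * (k + 1) / (6 * n))
    pairs <- utils::combn(k, 2)
    nm <- colnames(auc_block) %||% paste0("m", seq_len(k))
    z <- (rbar[pairs[1, ]] - rbar[pairs[2, ]]) / se
    p <- 2 * stats::pnorm(-abs(z))
    if (p_adjust == "bonferroni") p <- pmin(1, p * ncol(pairs))
    res$dunn <- data.frame(a = nm[pairs[1, ]], b = nm[pairs[2, ]],
                           Z = as.numeric(z), p = as.numeric(p))
  }
  res
}

#' Wilcoxon signed-rank test for paired condition scores
#'
#' Tests the high-minus-low paired differences. Zero differences are
#' dropped; `Z` is the standardized signed-rank statistic (sign follows the
#' direction of `x - y`). For fewer than 10 non-zero differences without
#' ties the p-value is exact (signed-rank distribution); otherwise the
#' normal approximation with continuity correction and tie correction is
#' used.
#'
#' @param x,y paired numeric vectors (e.g. high- and low-stress scores per
#'   subject), or `y = NULL` to test differences in `x` directly.
#' @return list with `Z`, `p`, `n` (non-zero differences) and `method`.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL) {
  d <- if (is.null(y)) as.numeric(x) else as.numeric(x) - as.numeric(y)
  d <- d[d != 0]
  n <- length(d)
  if (n < 6) stop("need at least 6 non-zero differences")
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / 48
  sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24 - tie_term)
  z <- (w_pos - mu - sign(w_pos - mu) * 0.5) / sigma
  has_ties <- any(duplicated(abs(d)))
  if (n < 10 && !has_ties) {
    # exact two-sided p from the signed-rank distribution
    p <- if (w_pos > mu) 2 * (1 - stats::psignrank(w_pos - 1, n))
         else 2 * stats::psignrank(w_pos, n)
    p <- min(1, p)
    method <- "exact"
  } else {
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation"
  }
  list(Z = unname(z), p = unname(p), n = n, method = method)
}
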