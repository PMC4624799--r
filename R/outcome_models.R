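# Statistical layer: per-metric one-tailed t-tests, the LOOCV alpha sweep,
# exploratory full-data fits, accuracy bookkeeping, and the linear SVM
# separating hyperplane.

#' Unpaired one-tailed t-test (pooled variance)
#'
#' @param groupA,groupB numeric vectors (each >= 2 values).
#' @param direction `"auto"` (tail in the direction of the observed mean
#'   difference; note that under the null this convention rejects at twice
#'   the nominal rate), `"greater"` (A > B) or `"less"` (A < B).
#' @return list with `t`, `p`, `direction`, `df`; a `flag` notes the
#'   zero-variance convention p = 0.5 when both groups are identical
#'   constants.
#' @export
onetail_ttest <- function(groupA, groupB, direction = c("auto", "greater", "less")) {
  direction <- match.arg(direction)
  nA <- length(groupA); nB <- length(groupB)
  if (nA < 2L || nB < 2L) stop_hq("each group needs at least 2 values")
  mA <- mean(groupA); mB <- mean(groupB)
  df <- nA + nB - 2L
  sp2 <- ((nA - 1) * var(groupA) + (nB - 1) * var(groupB)) / df
  flag <- NULL
  if (sp2 == 0) {
    if (mA == mB) {
      flag <- "zero pooled variance with equal means: p = 0.5 by convention"
      return(list(t = 0, p = 0.5, direction = "none", df = df, flag = flag))
    }
    tt <- sign(mA - mB) * Inf
  } else {
    tt <- (mA - mB) / sqrt(sp2 * (1 / nA + 1 / nB))
  }
  p <- switch(direction,
    auto = pt(abs(tt), df, lower.tail = FALSE),
    greater = pt(tt, df, lower.tail = FALSE),
    less = pt(-tt, df, lower.tail = FALSE))
  obs_dir <- if (mA > mB) "A>B" else if (mA < mB) "B>A" else "none"
  list(t = tt, p = p,
       direction = if (direction == "auto") obs_dir else direction,
       df = df, flag = flag)
}

#' Per-metric group comparison over a cohort
#'
#' Runs [onetail_ttest()] for every feature column, bridge group vs
#' no-bridge group.
#'
#' @param cohort a `cohort_table`.
#' @param direction passed to [onetail_ttest()].
#' @return data.frame with columns `metric`, `t`, `p`, `direction`.
#' @export
cohort_ttests <- function(cohort, direction = "auto") {
  X <- cohort_features(cohort); y <- cohort_outcome(cohort)
  res <- lapply(colnames(X), function(nm) {
    tt <- onetail_ttest(X[y == 1, nm], X[y == 0, nm], direction)
    data.frame(metric = nm, t = tt$t, p = tt$p, direction = tt$direction,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Prediction accuracy from error counts
#'
#' @param n_false number of false predictions (0..n_total).
#' @param n_total number of subjects (> 0).
#' @return accuracy in percent, rounded to one decimal.
#' @export
accuracy_from_counts <- function(n_false, n_total) {
  if (n_total <= 0) stop_hq("n_total must be > 0")
  if (n_false < 0 || n_false > n_total) stop_hq("n_false must be in [0, n_total]")
  round(100 * (n_total - n_false) / n_total, 1)
}

#' Leave-one-out cross-validated alpha sweep
#'
#' For each alpha on the grid and each held-out subject, a model is fit on
#' the remaining subjects at the one-standard-error lambda, the held-out
#' probability is rounded at `threshold` into a binary prediction, and
#' false-prediction counts are recorded; the nonzero-coefficient count of
#' the full-data fit at that alpha is recorded alongside.
#'
#' @param cohort a `cohort_table` (N >= 3).
#' @param alpha_grid alphas to sweep (default 0..1 step 0.01).
#' @param threshold classification threshold (default 0.5).
#' @param n_folds inner CV folds for the lambda rule (`"loo"` or integer;
#'   coarser folds make large sweeps substantially cheaper).
#' @param nlambda,lambda_min_ratio lambda path geometry.
#' @param seed seed for stratified inner folds.
#' @return object of class `sweep_result`: data.frame with per-alpha
#'   `n_false`, `n_false_bridge`, `n_false_nobridge`, `n_retained` (plus an
#'   `error` column logging aborted alphas), with the per-subject prediction
#'   matrix in attribute `predictions`.
#' @export
loocv_sweep <- function(cohort, alpha_grid = seq(0, 1, by = 0.01),
                        threshold = 0.5, n_folds = "loo", nlambda = 100L,
                        lambda_min_ratio = 1e-4, seed = 1L) {
  X <- cohort_features(cohort); y <- cohort_outcome(cohort)
  n <- nrow(X)
  if (n < 3L) stop_hq("need at least 3 subjects for LOOCV")
  preds <- matrix(NA_real_, n, length(alpha_grid))
  res <- data.frame(alpha = alpha_grid, n_false = NA_integer_,
                    n_false_bridge = NA_integer_, n_false_nobridge = NA_integer_,
                    n_retained = NA_integer_, error = NA_character_,
                    stringsAsFactors = FALSE)
  for (k in seq_along(alpha_grid)) {
    a <- alpha_grid[k]
    out <- tryCatch({
      prob <- vapply(seq_len(n), function(i) {
        Xi <- X[-i, , drop = FALSE]; yi <- y[-i]
        sel <- select_lambda_1se(Xi, yi, a, n_folds = n_folds,
                                 nlambda = nlambda,
                                 lambda_min_ratio = lambda_min_ratio,
                                 seed = seed)
        fit <- fit_elastic_net_logistic(Xi, yi, a, sel$lambda_1se)
        predict(fit, X[i, , drop = FALSE])
      }, 1)
      yhat <- as.integer(prob >= threshold)
      full_sel <- select_lambda_1se(X, y, a, n_folds = n_folds,
                                    nlambda = nlambda,
                                    lambda_min_ratio = lambda_min_ratio,
                                    seed = seed)
      full_fit <- fit_elastic_net_logistic(X, y, a, full_sel$lambda_1se)
      list(prob = prob,
           n_false = sum(yhat != y),
           n_false_bridge = sum(yhat == 0L & y == 1L),
           n_false_nobridge = sum(yhat == 1L & y == 0L),
           n_retained = sum(full_fit$beta_std != 0))
    }, error = function(e) e)
    if (inherits(out, "error")) {
      res$error[k] <- conditionMessage(out)
    } else {
      preds[, k] <- out$prob
      res$n_false[k] <- out$n_false
      res$n_false_bridge[k] <- out$n_false_bridge
      res$n_false_nobridge[k] <- out$n_false_nobridge
      res$n_retained[k] <- out$n_retained
    }
  }
  structure(res, predictions = preds, class = c("sweep_result", "data.frame"))
}

#' Exploratory full-data fit at a fixed alpha
#'
#' Single fit on all observations at the one-standard-error lambda; used to
#' identify the most predictive metrics.
#'
#' @param cohort a `cohort_table`.
#' @param alpha fixed mixing parameter (default 0.9).
#' @param ... passed to [select_lambda_1se()].
#' @return the fitted `enet_logistic` model, with the retained feature names
#'   in `$retained`.
#' @export
exploratory_fit <- function(cohort, alpha = 0.9, ...) {
  X <- cohort_features(cohort); y <- cohort_outcome(cohort)
  sel <- select_lambda_1se(X, y, alpha, ...)
  fit <- fit_elastic_net_logistic(X, y, alpha, sel$lambda_1se)
  fit$retained <- names(fit$beta_std)[fit$beta_std != 0]
  fit$lambda_selection <- sel
  fit
}

#' Linear soft-margin SVM separating hyperplane
#'
#' Trains a linear support vector machine by sequential minimal optimization
#' on the dual (maximal-violating-pair selection; deterministic). Intended
#' for the two-metric exploratory separating hyperplane.
#'
#' @param features N x p feature matrix (typically p = 2).
#' @param y binary outcomes (0/1 or -1/+1), both classes present.
#' @param C soft-margin cost (default 1).
#' @param tol KKT violation tolerance.
#' @param max_iter iteration cap.
#' @return object of class `svm_hyperplane` with weight vector `w`, offset
#'   `b`, `margin` (geometric margin, min_i y_i f(x_i) / ||w||),
#'   `n_misclassified` on the training data, and the support vector indices.
#' @export
svm_hyperplane <- function(features, y, C = 1, tol = 1e-6, max_iter = 20000L) {
  X <- as.matrix(features)
  yy <- as.numeric(y)
  if (all(yy %in% c(0, 1))) yy <- 2 * yy - 1
  if (!all(yy %in% c(-1, 1))) stop_hq("y must be binary")
  if (length(unique(yy)) < 2L)
    stop_hq("both classes must be present for an SVM hyperplane")
  n <- nrow(X)
  K <- tcrossprod(X)
  Q <- (yy %o% yy) * K
  a <- numeric(n)
  grad <- rep(-1, n)                 # grad of 1/2 a'Qa - e'a at a = 0
  for (it in seq_len(max_iter)) {
    up <- (yy > 0 & a < C - 1e-12) | (yy < 0 & a > 1e-12)
    lo <- (yy < 0 & a < C - 1e-12) | (yy > 0 & a > 1e-12)
    score <- -yy * grad
    i <- which(up)[which.max(score[up])]
    j <- which(lo)[which.min(score[lo])]
    if (!length(i) || !length(j) || score[i] - score[j] <= tol) break
    g <- yy[i] * grad[i] - yy[j] * grad[j]
    h <- K[i, i] + K[j, j] - 2 * K[i, j]
    t_step <- -g / max(h, 1e-12)
    # box limits for a[i] + yi*t and a[j] - yj*t in [0, C]
    lim <- function(ai, yi, sgn) {
      if (yi * sgn > 0) c(-ai, C - ai) / (yi * sgn) else rev(c(-ai, C - ai) / (yi * sgn))
    }
    li <- lim(a[i], yy[i], 1); lj <- lim(a[j], yy[j], -1)
    t_step <- min(max(t_step, max(li[1], lj[1])), min(li[2], lj[2]))
    if (abs(t_step) < 1e-14) break
    dai <- yy[i] * t_step; daj <- -yy[j] * t_step
    a[i] <- a[i] + dai; a[j] <- a[j] + daj
    grad <- grad + Q[, i] * dai + Q[, j] * daj
  }
  w <- as.vector(crossprod(X, a * yy))
  free <- a > 1e-8 & a < C - 1e-8
  b <- if (any(free)) {
    mean(yy[free] - X[free, , drop = FALSE] %*% w)
  } else {
    # no free support vectors: place b by minimizing the hinge loss directly
    rng <- range(yy - X %*% w)
    optimize(function(bb) sum(pmax(0, 1 - yy * (X %*% w + bb))),
             interval = c(rng[1] - 1, rng[2] + 1))$minimum
  }
  f <- as.vector(X %*% w + b)
  structure(list(w = setNames(w, colnames(X)), b = b,
                 margin = min(yy * f) / sqrt(sum(w^2)),
                 n_misclassified = sum(sign(f) != yy),
                 support = which(a > 1e-8), alpha_dual = a, C = C),
            class = "svm_hyperplane")
}

#' @export
print.svm_hyperplane <- function(x, ...) {
  cat(sprintf("linear SVM hyperplane: w = (%s), b = %.4g\n",
              paste(signif(x$w, 5), collapse = ", "), x$b))
  cat(sprintf("  geometric margin %.4g, %d misclassified, %d support vectors\n",
              x$margin, x$n_misclassified, length(x$support)))
  invisible(x)
}
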