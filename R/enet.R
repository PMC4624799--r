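# Elastic-net regularized logistic regression by iteratively reweighted
# least squares with cyclic coordinate descent.
#
# Objective: (1/N) * Deviance(b0, b) + lambda * P_alpha(b), with
# Deviance = -2 * sum[y log p + (1-y) log(1-p)] and
# P_alpha(b) = (1-alpha)/2 * ||b||_2^2 + alpha * ||b||_1.
# Features are standardized internally (mean 0, SD 1 with 1/N variance);
# the intercept is unpenalized; coefficients are returned on the original
# scale. A step-halving safeguard makes the objective non-increasing across
# outer iterations (recorded in the objective trace).

enet_standardize <- function(X) {
  X <- as.matrix(X)
  ctr <- colMeans(X)
  scl <- sqrt(colMeans(sweep(X, 2L, ctr)^2))
  ok <- scl > 0
  Z <- sweep(X, 2L, ctr)
  Z[, ok] <- sweep(Z[, ok, drop = FALSE], 2L, scl[ok], "/")
  Z[, !ok] <- 0
  list(Z = Z, center = ctr, scale = scl, ok = ok)
}

#' Elastic-net penalty
#'
#' @param beta coefficient vector.
#' @param alpha mixing parameter in \[0, 1\] (0 = ridge, 1 = lasso).
#' @return penalty value (1-alpha)/2 ||beta||_2^2 + alpha ||beta||_1.
#' @export
enet_penalty <- function(beta, alpha) {
  (1 - alpha) / 2 * sum(beta^2) + alpha * sum(abs(beta))
}

#' Binomial deviance
#' @param y binary outcomes (0/1).
#' @param prob fitted probabilities.
#' @return -2 log-likelihood.
#' @export
binomial_deviance <- function(y, prob) {
  prob <- pmin(pmax(prob, 1e-10), 1 - 1e-10)
  -2 * sum(y * log(prob) + (1 - y) * log(1 - prob))
}

enet_objective <- function(y, Z, b0, b, lambda, alpha) {
  eta <- b0 + as.vector(Z %*% b)
  binomial_deviance(y, plogis(eta)) / length(y) + lambda * enet_penalty(b, alpha)
}

#' Smallest lambda that zeroes all coefficients
#'
#' At the null model (intercept = logit of prevalence), all penalized
#' coefficients stay exactly zero for `lambda >= lambda_max`.
#'
#' @param X feature matrix.
#' @param y binary outcomes.
#' @param alpha mixing parameter (values below 0.001 are floored for this
#'   bound, as ridge has no finite zeroing lambda).
#' @return lambda_max.
#' @export
enet_lambda_max <- function(X, y, alpha) {
  st <- enet_standardize(X)
  n <- length(y)
  max(abs(crossprod(st$Z, y - mean(y)))) * 2 / (n * max(alpha, 0.001))
}

# Core fitter on standardized features. Returns standardized-scale
# coefficients plus the objective trace.
enet_fit_std <- function(Z, y, alpha, lambda, b0_init = NULL, b_init = NULL,
                         tol = 1e-9, max_outer = 200L, max_inner = 200L) {
  n <- nrow(Z); p <- ncol(Z)
  b <- if (is.null(b_init)) numeric(p) else b_init
  b0 <- if (is.null(b0_init)) qlogis(min(max(mean(y), 1e-6), 1 - 1e-6)) else b0_init
  obj <- enet_objective(y, Z, b0, b, lambda, alpha)
  trace <- obj
  converged <- FALSE
  for (outer in seq_len(max_outer)) {
    eta <- b0 + as.vector(Z %*% b)
    pr <- plogis(eta)
    w <- pmax(pr * (1 - pr), 1e-5)
    zw <- eta + (y - pr) / w
    # Gram formulation: coordinate updates cost O(p), not O(n)
    wZ <- w * Z
    G <- crossprod(Z, wZ)
    cvec <- as.vector(crossprod(Z, w * zw))
    wz_col <- colSums(wZ)
    sw <- sum(w); swz <- sum(w * zw)
    Gdiag <- diag(G)
    denom <- pmax(2 / n * Gdiag + lambda * (1 - alpha), 1e-12)
    b_old <- b; b0_old <- b0
    Gb <- as.vector(G %*% b)
    la <- lambda * alpha
    # active-set cyclic coordinate descent with vectorized KKT screening
    work <- which(b != 0)
    for (inner in seq_len(max_inner)) {
      delta_max <- 0
      for (j in work) {
        rho <- 2 / n * (cvec[j] - Gb[j] + Gdiag[j] * b[j] - wz_col[j] * b0)
        ar <- abs(rho) - la
        bj_new <- if (ar > 0) sign(rho) * ar / denom[j] else 0
        d <- bj_new - b[j]
        if (d != 0) {
          Gb <- Gb + G[, j] * d
          b[j] <- bj_new
          ad <- abs(d)
          if (ad > delta_max) delta_max <- ad
        }
      }
      b0_new <- (swz - sum(wz_col * b)) / sw
      ad <- abs(b0_new - b0)
      if (ad > delta_max) delta_max <- ad
      b0 <- b0_new
      if (delta_max < tol) {
        rho_all <- 2 / n * (cvec - Gb + Gdiag * b - wz_col * b0)
        viol <- which(b == 0 & abs(rho_all) > la + 1e-12)
        viol <- setdiff(viol, work)
        if (!length(viol)) break
        work <- sort(c(work, viol))
      }
    }
    # safeguard: accept only objective-decreasing steps (convex objective:
    # backtracking along the segment to the previous iterate)
    obj_new <- enet_objective(y, Z, b0, b, lambda, alpha)
    if (obj_new > obj + 1e-12) {
      gamma <- 1
      repeat {
        gamma <- gamma / 2
        if (gamma < 1e-8) { b <- b_old; b0 <- b0_old; obj_new <- obj; break }
        b_try <- b_old + gamma * (b - b_old)
        b0_try <- b0_old + gamma * (b0 - b0_old)
        obj_try <- enet_objective(y, Z, b0_try, b_try, lambda, alpha)
        if (obj_try <= obj + 1e-12) { b <- b_try; b0 <- b0_try; obj_new <- obj_try; break }
      }
    }
    trace <- c(trace, obj_new)
    if (abs(obj - obj_new) < 1e-10 * max(1, abs(obj))) { obj <- obj_new; converged <- TRUE; break }
    obj <- obj_new
  }
  list(b0 = b0, b = b, objective_trace = trace, converged = converged)
}

#' Fit elastic-net regularized logistic regression
#'
#' Minimizes (1/N) Deviance + lambda * P_alpha(beta) by IRLS with cyclic
#' coordinate descent; the intercept is unpenalized and features are
#' standardized internally.
#'
#' @param X N x p feature matrix (or data.frame).
#' @param y binary outcomes (0/1), both classes present.
#' @param alpha elastic-net mixing parameter in \[0, 1\].
#' @param lambda regularization weight >= 0.
#' @param ... passed to the internal fitter (tolerances, iteration caps).
#' @return object of class `enet_logistic` with original-scale `beta0` and
#'   `beta`, the standardized-scale solution, `alpha`, `lambda`,
#'   standardization parameters, the per-outer-iteration `objective_trace`
#'   (non-increasing) and a `converged` flag (complete separation at
#'   lambda = 0 is flagged, not an error).
#' @export
fit_elastic_net_logistic <- function(X, y, alpha, lambda, ...) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (lambda < 0) stop_hq("lambda must be >= 0")
  if (alpha < 0 || alpha > 1) stop_hq("alpha must be in [0, 1]")
  if (nrow(X) < 2L) stop_hq("need at least 2 observations")
  if (length(unique(y)) < 2L) stop_hq("both outcome classes must be present")
  st <- enet_standardize(X)
  fit <- enet_fit_std(st$Z, y, alpha, lambda, ...)
  if (!fit$converged && lambda == 0)
    warning("non-convergence at lambda = 0 (possible complete separation)")
  b_orig <- numeric(ncol(X))
  b_orig[st$ok] <- fit$b[st$ok] / st$scale[st$ok]
  b0_orig <- fit$b0 - sum(b_orig * st$center)
  nms <- colnames(X)
  if (is.null(nms)) nms <- paste0("x", seq_len(ncol(X)))
  structure(list(beta0 = b0_orig, beta = setNames(b_orig, nms),
                 beta0_std = fit$b0, beta_std = setNames(fit$b, nms),
                 alpha = alpha, lambda = lambda,
                 standardization = list(center = st$center, scale = st$scale),
                 feature_names = nms,
                 objective_trace = fit$objective_trace,
                 converged = fit$converged),
            class = "enet_logistic")
}

#' @export
print.enet_logistic <- function(x, ...) {
  nz <- sum(x$beta_std != 0)
  cat(sprintf("elastic-net logistic model: alpha = %.3g, lambda = %.4g, %d/%d nonzero\n",
              x$alpha, x$lambda, nz, length(x$beta)))
  cat(sprintf("  intercept %.4g\n", x$beta0))
  for (nm in names(x$beta)[x$beta != 0])
    cat(sprintf("  %-10s %.4g\n", nm, x$beta[[nm]]))
  invisible(x)
}

#' Predict from an elastic-net logistic model
#' @param object an `enet_logistic`.
#' @param newX feature matrix on the original scale.
#' @param type `"response"` (probability), `"link"`, or `"class"` (rounded
#'   at `threshold`).
#' @param threshold classification threshold for `type = "class"`.
#' @param ... unused.
#' @export
predict.enet_logistic <- function(object, newX, type = c("response", "link", "class"),
                                  threshold = 0.5, ...) {
  type <- match.arg(type)
  newX <- matrix(as.numeric(as.matrix(newX)), ncol = length(object$beta))
  eta <- object$beta0 + as.vector(newX %*% object$beta)
  switch(type, link = eta, response = plogis(eta),
         class = as.integer(plogis(eta) >= threshold))
}

# Fit a descending lambda path with warm starts; returns standardized-scale
# coefficient matrices for fast downstream prediction.
enet_path_std <- function(Z, y, alpha, lambdas) {
  p <- ncol(Z)
  B <- matrix(0, p, length(lambdas))
  b0s <- numeric(length(lambdas))
  b <- NULL; b0 <- NULL
  for (k in seq_along(lambdas)) {
    fit <- enet_fit_std(Z, y, alpha, lambdas[k], b0_init = b0, b_init = b,
                        tol = 1e-7, max_outer = 60L)
    b <- fit$b; b0 <- fit$b0
    B[, k] <- b; b0s[k] <- b0
  }
  list(B = B, b0 = b0s, lambdas = lambdas)
}

default_lambda_path <- function(X, y, alpha, nlambda = 100L,
                                lambda_min_ratio = 1e-4) {
  lmax <- enet_lambda_max(X, y, alpha)
  exp(seq(log(lmax), log(lmax * lambda_min_ratio), length.out = nlambda))
}

# Deterministic stratified fold assignment (outcome-balanced); "loo" gives
# one fold per observation.
make_folds <- function(y, n_folds, seed = NULL) {
  n <- length(y)
  if (identical(n_folds, "loo") || (is.numeric(n_folds) && n_folds >= n))
    return(seq_len(n))
  folds <- integer(n)
  for (cls in unique(y)) {
    idx <- which(y == cls)
    if (!is.null(seed)) idx <- with_seed(child_seed(seed, cls), sample(idx))
    folds[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  folds
}

#' Select lambda by cross-validation with the one-standard-error rule
#'
#' Computes cross-validated binomial deviance over a descending log-spaced
#' lambda path and returns the largest lambda whose CV deviance is within
#' one standard error of the minimum.
#'
#' @param X,y features and binary outcomes.
#' @param alpha elastic-net mixing parameter.
#' @param n_folds `"loo"` (default; appropriate at the cohort sizes this
#'   package targets) or an integer number of stratified folds.
#' @param nlambda,lambda_min_ratio lambda path geometry.
#' @param seed seed used only to shuffle stratified folds (and on fold
#'   reshuffles when a fold degenerates to a single class).
#' @return list with `lambda_1se`, `lambda_min`, `lambdas`, `cvm` (mean CV
#'   deviance per observation), `cvsd` (its standard error).
#' @export
select_lambda_1se <- function(X, y, alpha, n_folds = "loo", nlambda = 100L,
                              lambda_min_ratio = 1e-4, seed = 1L) {
  X <- as.matrix(X); y <- as.numeric(y)
  lambdas <- default_lambda_path(X, y, alpha, nlambda, lambda_min_ratio)
  folds <- make_folds(y, n_folds, seed)
  for (try in 1:5) {
    bad <- any(vapply(unique(folds), function(f)
      length(unique(y[folds != f])) < 2L, logical(1)))
    if (!bad) break
    seed <- child_seed(seed, try)
    warning(sprintf("degenerate CV fold; reshuffling with seed %d", seed))
    folds <- make_folds(y, n_folds, seed)
  }
  n <- length(y)
  dev_obs <- matrix(NA_real_, n, length(lambdas))
  for (f in unique(folds)) {
    tr <- folds != f; te <- !tr
    st <- enet_standardize(X[tr, , drop = FALSE])
    path <- enet_path_std(st$Z, y[tr], alpha, lambdas)
    Zte <- sweep(X[te, , drop = FALSE], 2L, st$center)
    Zte[, st$ok] <- sweep(Zte[, st$ok, drop = FALSE], 2L, st$scale[st$ok], "/")
    Zte[, !st$ok] <- 0
    eta <- sweep(Zte %*% path$B, 2L, path$b0, "+")
    pr <- pmin(pmax(plogis(eta), 1e-10), 1 - 1e-10)
    yy <- y[te]
    dev_obs[te, ] <- -2 * (yy * log(pr) + (1 - yy) * log(1 - pr))
  }
  fold_ids <- sort(unique(folds))
  fold_means <- t(vapply(fold_ids, function(f)
    colMeans(dev_obs[folds == f, , drop = FALSE]), numeric(length(lambdas))))
  cvm <- colMeans(dev_obs)
  cvsd <- apply(fold_means, 2L, stats::sd) / sqrt(length(fold_ids))
  k_min <- which.min(cvm)
  ok <- cvm <= cvm[k_min] + cvsd[k_min]
  list(lambda_1se = lambdas[which(ok)[1]], lambda_min = lambdas[k_min],
       lambdas = lambdas, cvm = cvm, cvsd = cvsd)
}
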