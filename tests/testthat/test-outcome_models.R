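test_that("one-tailed t-test handles its boundary conventions", {
  x <- c(1, 2, 3, 4)
  tt <- onetail_ttest(x, x)
  expect_equal(tt$t, 0); expect_equal(tt$p, 0.5)
  # zero pooled variance with equal means: flagged p = 0.5
  tt0 <- onetail_ttest(c(2, 2), c(2, 2))
  expect_equal(tt0$p, 0.5)
  expect_match(tt0$flag, "zero pooled variance")
  # direction of the observed difference is reported under "auto"
  tt1 <- onetail_ttest(c(5, 6, 7), c(1, 2, 3))
  expect_equal(tt1$direction, "A>B")
  expect_lt(tt1$p, 0.05)
  # fixed-direction p-values are complementary
  tg <- onetail_ttest(c(5, 6, 7), c(1, 2, 3), "greater")$p
  tl <- onetail_ttest(c(5, 6, 7), c(1, 2, 3), "less")$p
  expect_equal(tg + tl, 1)
  expect_error(onetail_ttest(1, c(1, 2)), "at least 2")
})

test_that("accuracy bookkeeping matches the printed worked examples", {
  expect_equal(accuracy_from_counts(4, 26), 84.6)
  expect_equal(accuracy_from_counts(6, 26), 76.9)
  expect_equal(accuracy_from_counts(0, 17), 100)
  expect_error(accuracy_from_counts(5, 0), "n_total")
  expect_error(accuracy_from_counts(-1, 10), "n_false")
})

test_that("calibrated cohorts separate shape metrics but not distance metrics", {
  # strong-effect metrics (hernia volume A, anterior area E) should reject in
  # the majority of replicate cohorts; the near-null xiphoid distance (L)
  # should typically not
  pA <- pE <- pL <- numeric(20)
  for (r in 1:20) {
    co <- make_cohort(9, 17, seed = 2000L + r)
    X <- cohort_features(co); y <- cohort_outcome(co)
    pA[r] <- onetail_ttest(X[y == 1, "A"], X[y == 0, "A"])$p
    pE[r] <- onetail_ttest(X[y == 1, "E"], X[y == 0, "E"])$p
    pL[r] <- onetail_ttest(X[y == 1, "L"], X[y == 0, "L"])$p
  }
  expect_gt(mean(pA < 0.05), 0.5)
  expect_gt(mean(pE < 0.05), 0.5)
  expect_gt(mean(pL > 0.05), 0.5)
})

test_that("the penalty interpolates ridge and lasso and is linear in alpha", {
  b <- c(1.5, -2, 0, 0.25)
  expect_equal(enet_penalty(b, 0), sum(b^2) / 2)
  expect_equal(enet_penalty(b, 1), sum(abs(b)))
  a <- c(0.25, 0.5, 0.75)
  vals <- vapply(a, function(aa) enet_penalty(b, aa), 1)
  expect_equal(diff(vals, differences = 2), 0, tolerance = 1e-12)
})

test_that("lambda >= lambda_max zeroes all coefficients exactly", {
  set.seed(15)
  X <- matrix(rnorm(40 * 6), 40, 6)
  y <- rbinom(40, 1, 0.4)
  lmax <- enet_lambda_max(X, y, 1)
  fit <- fit_elastic_net_logistic(X, y, 1, lmax * 1.000001)
  expect_identical(unname(fit$beta), rep(0, 6))
  expect_equal(fit$beta0, qlogis(mean(y)), tolerance = 1e-9)
  # just below lambda_max at least one coefficient activates
  fit2 <- fit_elastic_net_logistic(X, y, 1, lmax * 0.95)
  expect_gt(sum(fit2$beta != 0), 0)
})

test_that("lambda = 0 matches an independent Newton solver to 1e-5", {
  set.seed(16)
  n <- 150
  X <- matrix(rnorm(n * 4), n, 4)
  y <- rbinom(n, 1, plogis(0.3 + X %*% c(0.8, -0.6, 0.3, 0)))
  fit <- fit_elastic_net_logistic(X, y, alpha = 0.5, lambda = 0)
  oracle <- glm(y ~ X, family = binomial)   # IRLS Newton solver
  expect_lt(max(abs(c(fit$beta0, fit$beta) - coef(oracle))), 1e-5)
})

test_that("penalized objective matches a brute-force grid oracle (p = 2)", {
  set.seed(17)
  X <- matrix(rnorm(24), 12, 2)
  y <- c(0, 1, 0, 1, 1, 0, 0, 1, 1, 0, 1, 1)
  alpha <- 0.7; lambda <- 0.08
  fit <- fit_elastic_net_logistic(X, y, alpha, lambda)
  # independent objective evaluation (standardized scale, from scratch)
  ctr <- colMeans(X); scl <- sqrt(colMeans(sweep(X, 2, ctr)^2))
  Z <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  obj <- function(b0, b1, b2) {
    p <- plogis(b0 + Z %*% c(b1, b2))
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    dev <- -2 * sum(y * log(p) + (1 - y) * log(1 - p))
    dev / 12 + lambda * ((1 - alpha) / 2 * (b1^2 + b2^2) +
                           alpha * (abs(b1) + abs(b2)))
  }
  # coarse-to-fine grid minimization around the origin
  best <- Inf; ctr_pt <- c(0, 0, 0); span <- 3
  for (level in 1:4) {
    g <- seq(-span, span, length.out = 21)
    for (b0 in ctr_pt[1] + g) for (b1 in ctr_pt[2] + g) for (b2 in ctr_pt[3] + g) {
      v <- obj(b0, b1, b2)
      if (v < best) { best <- v; arg <- c(b0, b1, b2) }
    }
    ctr_pt <- arg; span <- span / 5
  }
  fit_obj <- obj(fit$beta0_std, fit$beta_std[1], fit$beta_std[2])
  expect_lt(abs(fit_obj - best), 1e-3)
  expect_lte(fit_obj, best + 1e-6)   # the fitter should not be beaten
})

test_that("the objective trace is non-increasing (Eq-1 descent invariant)", {
  set.seed(18)
  for (rep in 1:5) {
    X <- matrix(rnorm(30 * 8), 30, 8)
    y <- rbinom(30, 1, 0.5); y[1] <- 1; y[2] <- 0
    a <- runif(1); l <- runif(1, 0.01, 0.5)
    fit <- fit_elastic_net_logistic(X, y, a, l)
    expect_true(all(diff(fit$objective_trace) <= 1e-10))
  }
})

test_that("path solutions agree with glmnet at matched lambda", {
  skip_if_not_installed("glmnet")
  set.seed(19)
  n <- 80
  X <- matrix(rnorm(n * 5), n, 5)
  y <- rbinom(n, 1, plogis(X %*% c(1.2, -0.8, 0, 0, 0.4)))
  for (a in c(0.3, 0.9, 1)) {
    for (lam in c(0.02, 0.1)) {
      gfit <- glmnet::glmnet(X, y, family = "binomial", alpha = a,
                             lambda = lam, standardize = TRUE, thresh = 1e-12)
      # this package's deviance convention makes lambda twice glmnet's
      ours <- fit_elastic_net_logistic(X, y, a, 2 * lam)
      expect_equal(unname(ours$beta), as.numeric(gfit$beta),
                   tolerance = 1e-4)
      expect_equal(ours$beta0, as.numeric(gfit$a0), tolerance = 1e-4)
    }
  }
})

test_that("1-SE selection returns a lambda at least as large as the minimizer", {
  set.seed(20)
  X <- matrix(rnorm(60 * 8), 60, 8)
  y <- rbinom(60, 1, plogis(X %*% c(1.5, -1.5, rep(0, 6))))
  sel <- select_lambda_1se(X, y, 0.9, n_folds = 5, nlambda = 40)
  expect_gte(sel$lambda_1se, sel$lambda_min)
  expect_equal(length(sel$cvm), 40L)
  # pure-noise features: the 1-SE model is (almost always) empty
  empty <- vapply(1:10, function(r) {
    Xn <- matrix(rnorm(60 * 8), 60, 8)
    yn <- rbinom(60, 1, 0.4)
    s <- select_lambda_1se(Xn, yn, 0.9, n_folds = 5, nlambda = 30,
                           seed = 100L + r)
    f <- fit_elastic_net_logistic(Xn, yn, 0.9, s$lambda_1se)
    sum(f$beta != 0) == 0
  }, logical(1))
  expect_gte(mean(empty), 0.9)
})

test_that("LOOCV predictions are invariant to subject ordering", {
  set.seed(22)
  n <- 12
  X <- matrix(rnorm(n * 3), n, 3)
  colnames(X) <- c("B", "E", "Q")
  y <- rbinom(n, 1, plogis(1.5 * X[, 1])); y[1] <- 1; y[2] <- 0
  co <- cohort_table(as.data.frame(X), y)
  sw <- loocv_sweep(co, alpha_grid = 0.5, n_folds = "loo", nlambda = 15)
  perm <- c(7, 3, 1, 12, 5, 9, 2, 11, 4, 10, 6, 8)
  co2 <- cohort_table(as.data.frame(X[perm, ]), y[perm])
  sw2 <- loocv_sweep(co2, alpha_grid = 0.5, n_folds = "loo", nlambda = 15)
  expect_equal(attr(sw, "predictions")[perm, 1], attr(sw2, "predictions")[, 1],
               tolerance = 1e-8)
  expect_equal(sw$n_false, sw2$n_false)
})

test_that("a perfectly separated cohort gives zero false predictions", {
  set.seed(23)
  n <- 16
  X <- cbind(B = c(rnorm(8, 20, 0.5), rnorm(8, 5, 0.5)),
             E = c(rnorm(8, 600, 10), rnorm(8, 100, 10)))
  y <- rep(c(1, 0), each = 8)
  co <- cohort_table(as.data.frame(X), y)
  sw <- loocv_sweep(co, alpha_grid = c(0.2, 0.9), n_folds = 5, nlambda = 30)
  expect_equal(sw$n_false, c(0L, 0L))
})

test_that("ridge keeps all coefficients; exploratory fit reports the retained set", {
  set.seed(24)
  co <- make_cohort(20, 20, seed = 55L)
  f_ridge <- exploratory_fit(co, alpha = 0, n_folds = 5, nlambda = 30)
  expect_equal(sum(f_ridge$beta != 0), 20L)   # no exact zeros under ridge
  f_sparse <- exploratory_fit(co, alpha = 0.9, n_folds = 5, nlambda = 30)
  expect_lte(length(f_sparse$retained), 20L)
  expect_setequal(f_sparse$retained,
                  names(f_sparse$beta_std)[f_sparse$beta_std != 0])
})

test_that("SVM solves the two-point geometry and matches the angular oracle", {
  sv <- svm_hyperplane(rbind(c(1, 1), c(-1, -1)), c(1, 0), C = 10)
  expect_equal(sv$b, 0, tolerance = 1e-8)
  expect_equal(sv$w[[1]], sv$w[[2]], tolerance = 1e-8)
  expect_equal(sv$margin, sqrt(2), tolerance = 1e-6)
  expect_equal(sv$n_misclassified, 0L)
  # separable cloud: geometric margin equals the best over a 1-degree sweep
  set.seed(25)
  Xp <- cbind(rnorm(15, 3), rnorm(15, 3))
  Xn <- cbind(rnorm(15, -3), rnorm(15, -3))
  X <- rbind(Xp, Xn); y <- rep(c(1, 0), each = 15)
  sv2 <- svm_hyperplane(X, y, C = 1000)
  yy <- 2 * y - 1
  oracle <- max(vapply(seq(0, 179, by = 1) * pi / 180, function(phi) {
    w <- c(cos(phi), sin(phi))
    pr <- X %*% w
    (min(pr[yy == 1]) - max(pr[yy == -1])) / 2
  }, 1))
  expect_equal(sv2$n_misclassified, 0L)
  expect_gte(sv2$margin, oracle * 0.999)  # SMO at least as good as the grid
  expect_lte(sv2$margin, oracle * 1.05)   # and within the 1-degree resolution
  expect_error(svm_hyperplane(Xp, rep(1, 15)), "both classes")
})
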