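# Ridge logistic regression (Newton), classification metrics, RBF kernel,
# epsilon-SVR and both cross-validation protocols.

test_that("logistic probability is exact, complementary and saturating", {
  expect_equal(rlr_probability(c(1, -1), c(0, 0)), 0.5)
  set.seed(5)
  for (i in 1:20) {
    W <- rnorm(4); x <- rnorm(4)
    p1 <- rlr_probability(W, x)
    p0 <- 1 / (1 + exp(sum(W * x)))
    expect_equal(p1 + p0, 1, tolerance = 1e-12)
  }
  expect_equal(rlr_probability(1000, 1), 1)    # no overflow
  expect_equal(rlr_probability(-1000, 1), 0)
  expect_error(rlr_probability(1:2, 1:3), "length")
})

test_that("Newton fit recovers symmetric and separable solutions", {
  # perfectly balanced data: every x carries both labels, forcing W = 0
  X <- rbind(diag(3), diag(3))
  y <- c(1, 1, 1, 0, 0, 0)
  fit <- fit_rlr(X, y, sigma = 1)
  expect_true(all(abs(fit$W) < 1e-8))
  # separable 1-D data: ridge keeps W finite, training accuracy 1
  X2 <- matrix(c(-2, -1.5, -1, 1, 1.5, 2), ncol = 1)
  y2 <- c(0, 0, 0, 1, 1, 1)
  fit2 <- fit_rlr(X2, y2, sigma = 2)
  expect_true(is.finite(fit2$W))
  expect_true(fit2$converged)
  expect_identical(as.integer(predict(fit2, X2) >= 0.5), as.integer(y2))
  expect_error(fit_rlr(X2, rep(1, 6)), "single class")
  expect_error(fit_rlr(X2, c(0, 0, 0, 1, 1, 2)), "binary")
})

test_that("Newton solution matches an independent BFGS optimizer", {
  set.seed(42)
  n <- 5L; m <- 40L; sigma <- 1.5
  X <- matrix(rbinom(n * m, 1, 0.4), nrow = m)
  y <- rbinom(m, 1, plogis(X %*% c(1.2, -0.8, 0.5, 0, 0.3)))
  if (length(unique(y)) < 2L) y[1:2] <- 0:1
  fit <- fit_rlr(X, y, sigma = sigma, tol = 1e-10)
  lambda <- 1 / sigma^2
  negobj <- function(W) {
    z <- drop(X %*% W)
    -(sum(y * z - log1p(exp(-abs(z))) - pmax(z, 0)) - lambda / 2 * sum(W^2))
  }
  neggrad <- function(W) {
    p <- plogis(drop(X %*% W))
    -(drop(crossprod(X, y - p)) - lambda * W)
  }
  ref <- optim(rep(0, n), negobj, neggrad, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-15))
  expect_lt(max(abs(fit$W - ref$par)), 1e-4)
})

test_that("Newton objective is monotone along iterations", {
  set.seed(9)
  X <- matrix(rbinom(200, 1, 0.5), nrow = 40)
  y <- rbinom(40, 1, 0.5); y[1:2] <- 0:1
  fit <- fit_rlr(X, y, sigma = 1)
  expect_true(fit$converged)
  # refitting from the solution cannot improve the objective noticeably
  expect_gte(fit$objective + 1e-8, fit_rlr(X, y, sigma = 1)$objective)
})

test_that("classification metrics match their definitions", {
  scores <- c(rep(0.9, 9), 0.1,        # 9 TP, 1 FN
              rep(0.2, 7), rep(0.8, 3))  # 7 TN, 3 FP
  labels <- c(rep(1, 10), rep(0, 10))
  m <- evaluate_classification(scores, labels)
  expect_equal(m$sensitivity, 0.9)
  expect_equal(m$specificity, 0.7)
  expect_equal(m$accuracy, 0.8)
  # all-tied scores give AUC 1/2; separation gives 1
  expect_equal(evaluate_classification(rep(0.5, 10),
                                       rep(0:1, 5))$roc_auc, 0.5)
  expect_equal(evaluate_classification(c(1:5 / 10, 6:10 / 10),
                                       c(rep(0, 5), rep(1, 5)))$roc_auc, 1)
  expect_error(evaluate_classification(1:3 / 3, c(1, 1, 1)), "single class")
})

test_that("rank-based AUC agrees with an independent ROC implementation", {
  set.seed(13)
  scores <- c(rnorm(30, 1), rnorm(30))
  labels <- rep(c(1, 0), each = 30)
  ours <- evaluate_classification(scores, labels)$roc_auc
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("random sub-sampling CV partitions, reproduces and recovers", {
  set.seed(31)
  n <- 90L
  planted <- rbinom(n, 1, 0.5)
  X <- cbind(planted, matrix(rbinom(n * 4, 1, 0.3), nrow = n))
  y <- planted                         # labels = presence of one fragment
  cv1 <- cv_random_subsampling(X, y, repeats = 5L, seed = 7)
  cv2 <- cv_random_subsampling(X, y, repeats = 5L, seed = 7)
  expect_identical(cv1$repeats, cv2$repeats)   # same seed, same stream
  expect_gt(cv1$roc_auc, 0.95)
  cv3 <- cv_random_subsampling(X, y, repeats = 5L, seed = 8)
  expect_false(identical(cv1$repeats, cv3$repeats))
})

test_that("the RBF kernel satisfies its identities", {
  expect_equal(rbf_kernel(c(1, 2), c(1, 2), 1), 1)
  sigma <- 0.7
  x1 <- c(0, 0); x2 <- c(sqrt(2) * sigma, 0)   # ||d||^2 = 2 sigma^2
  expect_equal(rbf_kernel(x1, x2, sigma), exp(-1))
  set.seed(3)
  for (i in 1:10) {
    a <- rnorm(5); b <- rnorm(5)
    expect_equal(rbf_kernel(a, b, 2), rbf_kernel(b, a, 2))
  }
  expect_error(rbf_kernel(1, 1, 0), "sigma")
  expect_error(rbf_kernel(1:2, 1:3, 1), "length")
})

test_that("RBF Gram matrices are positive semidefinite", {
  set.seed(21)
  X <- matrix(rnorm(40), nrow = 8)
  K <- outer(seq_len(8), seq_len(8), Vectorize(function(i, j)
    rbf_kernel(X[i, ], X[j, ], 1.3)))
  expect_equal(K, t(K))
  expect_gte(min(eigen(K, symmetric = TRUE)$values), -1e-9)
})

test_that("SVR interpolates, ignores duplication and flags constants", {
  set.seed(11)
  X <- matrix(rbinom(60, 1, 0.5), nrow = 20)
  y <- 5 + X %*% c(1.5, 1, 0.5)
  fit <- fit_svr(X, y, cost = 100, epsilon = 0.05)
  # residuals live inside the epsilon tube, so the MSE is bounded by
  # epsilon^2 up to solver tolerance
  expect_lte(mean((predict(fit, X) - y)^2), 0.05^2 * (1 + 1e-2))
  # duplicating every training point changes nothing
  fit2 <- fit_svr(rbind(X, X), c(y, y), cost = 100, epsilon = 0.05)
  expect_equal(predict(fit2, X), predict(fit, X), tolerance = 1e-3)
  expect_warning(cfit <- fit_svr(X, rep(2, 20)), "constant")
  expect_equal(predict(cfit, X), rep(2, 20))
  expect_error(fit_svr(X[1:3, ], y[1:3]), "at least 5")
})

test_that("explicit kernel-expansion predictions match the fitted SVM", {
  set.seed(14)
  X <- matrix(rnorm(100), nrow = 20)
  y <- rnorm(20)
  fit <- fit_svr(X, y, sigma = 2, cost = 5, epsilon = 0.1)
  svm_ref <- e1071::svm(x = X, y = y, type = "eps-regression",
                        kernel = "radial", gamma = 1 / (2 * 2^2),
                        cost = 5, epsilon = 0.1, scale = FALSE)
  expect_equal(predict(fit, X), unname(predict(svm_ref, X)),
               tolerance = 1e-8)
})

test_that("k-fold regression CV partitions, reproduces and recovers", {
  set.seed(15)
  X <- matrix(rbinom(300, 1, 0.5), nrow = 100)
  y <- drop(5 + X %*% c(1.5, 1, 0.5))          # noise-free linear target
  cv1 <- cv_kfold_regression(X, y, k = 5, seed = 3, cost = 100,
                             epsilon = 0.01)
  cv2 <- cv_kfold_regression(X, y, k = 5, seed = 3, cost = 100,
                             epsilon = 0.01)
  expect_identical(cv1$folds, cv2$folds)
  expect_gte(cv1$pearson_r, 0.99)
  expect_error(cv_kfold_regression(X[1:3, ], y[1:3], k = 5), "k exceeds")
})
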