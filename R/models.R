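# Activity models on substructure descriptors: ridge-regularized logistic
# regression fitted by Newton iteration (the classifier), and epsilon-SVR
# with an RBF kernel (the pIC50 regressor), plus their cross-validation
# protocols and metrics.

#' Logistic activity probability
#'
#' p(active | x, W) = exp(W.x) / (1 + exp(W.x)), evaluated overflow-safely;
#' the inactive probability is its complement.
#'
#' @param W Weight vector.
#' @param x Descriptor vector of the same length.
#' @return Probability in (0, 1).
#' @export
rlr_probability <- function(W, x) {
  if (length(W) != length(x)) stop("length mismatch between W and x")
  stats::plogis(sum(W * x))
}

# design matrix (compounds x features) from a descriptor matrix or plain matrix
.design <- function(X) {
  if (inherits(X, "descriptor_matrix")) t(unclass(X)) else as.matrix(X)
}

#' Fit ridge-regularized logistic regression by Newton iteration
#'
#' Maximizes sum_j [ y_j W.x_j - log(1 + exp(W.x_j)) ] - ||W||^2 / (2
#' sigma^2), the log-likelihood under a Gaussian prior on W with scale
#' sigma.  The objective is strictly concave, so Newton steps (with step
#' halving whenever a step would decrease the objective) converge to the
#' unique maximum; iteration stops when the gradient norm falls below
#' `tol`.  There is no intercept: the model scores activity purely from
#' fragment content.
#'
#' @param X Descriptor matrix (fragments x compounds, as from
#'   [vectorize()]) or a plain compounds x features matrix.
#' @param y Binary labels (0/1), one per compound.
#' @param sigma Prior scale; larger means weaker shrinkage.
#' @param tol Convergence tolerance on the gradient norm.
#' @param max_iter Iteration cap.
#' @return Object of class `rlr_model`: `W` (named), `sigma`,
#'   `iterations`, `grad_norm`, `converged`, `objective`.
#' @export
fit_rlr <- function(X, y, sigma = 1, tol = 1e-6, max_iter = 100L) {
  Xd <- .design(X)
  y <- as.numeric(y)
  if (length(y) != nrow(Xd)) stop("length(y) must match the number of compounds")
  if (!all(y %in% c(0, 1))) stop("y must be binary 0/1")
  if (length(unique(y)) < 2L) stop("y has a single class")
  if (any(table(y) < 2L)) stop("need >= 2 samples per class")
  if (sigma <= 0) stop("sigma must be > 0")
  p_feat <- ncol(Xd)
  W <- numeric(p_feat)
  lambda <- 1 / sigma^2

  obj <- function(W) {
    z <- drop(Xd %*% W)
    sum(y * z - log1p(exp(-abs(z))) - pmax(z, 0)) - lambda / 2 * sum(W^2)
  }
  grad <- function(W) {
    p <- stats::plogis(drop(Xd %*% W))
    drop(crossprod(Xd, y - p)) - lambda * W
  }

  it <- 0L; gn <- Inf
  while (it < max_iter) {
    it <- it + 1L
    z <- drop(Xd %*% W)
    p <- stats::plogis(z)
    g <- drop(crossprod(Xd, y - p)) - lambda * W
    gn <- sqrt(sum(g^2))
    if (gn < tol) break
    s <- p * (1 - p)
    H <- crossprod(Xd, Xd * s) + diag(lambda, p_feat)
    step <- solve(H, g)
    f0 <- obj(W); alpha <- 1
    while (obj(W + alpha * step) < f0 && alpha > 1e-8) alpha <- alpha / 2
    W <- W + alpha * step
  }
  names(W) <- colnames(Xd)
  structure(list(W = W, sigma = sigma, iterations = it, grad_norm = gn,
                 converged = gn < tol, objective = obj(W)),
            class = "rlr_model")
}

#' @export
print.rlr_model <- function(x, ...) {
  cat("<rlr_model> ", length(x$W), " weights, sigma = ", x$sigma,
      ", ", x$iterations, " Newton iterations (|grad| = ",
      format(x$grad_norm, digits = 3), ")\n", sep = "")
  invisible(x)
}

#' @export
predict.rlr_model <- function(object, newdata, ...) {
  Xd <- .design(newdata)
  stats::plogis(drop(Xd %*% object$W))
}

#' Classification metrics at a threshold plus rank-based ROC AUC
#'
#' Sensitivity TP/(TP+FN), specificity TN/(TN+FP) and accuracy are computed
#' at the score threshold; the area under the ROC curve comes from the
#' Mann-Whitney rank statistic with ties averaged, so it is threshold-free.
#'
#' @param scores Numeric activity scores.
#' @param labels Binary labels (0/1).
#' @param threshold Decision threshold on the score (default 0.5).
#' @return Object of class `classification_metrics` with fields
#'   `sensitivity`, `specificity`, `roc_auc`, `accuracy`.
#' @export
evaluate_classification <- function(scores, labels, threshold = 0.5) {
  if (length(scores) != length(labels)) stop("length mismatch")
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) stop("labels contain a single class")
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & labels == 1L); fn <- sum(pred == 0L & labels == 1L)
  tn <- sum(pred == 0L & labels == 0L); fp <- sum(pred == 1L & labels == 0L)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  r <- rank(scores)
  auc <- (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  structure(list(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
                 roc_auc = auc, accuracy = (tp + tn) / length(labels)),
            class = "classification_metrics")
}

#' @export
print.classification_metrics <- function(x, ...) {
  cat(sprintf("sensitivity %.3f  specificity %.3f  ROC AUC %.3f  accuracy %.3f\n",
              x$sensitivity, x$specificity, x$roc_auc, x$accuracy))
  invisible(x)
}

#' Random sub-sampling cross-validation for classification
#'
#' Per repeat the data are randomly split into `n_subsets` near-equal
#' subsets; all but one (chosen at random) train the model and the held-out
#' subset is scored, giving a 2:1 train:validation ratio at the default of
#' three subsets.  Metrics are averaged over repeats.  Fully seeded: the
#' same seed reproduces the same split stream and metrics.
#'
#' @param X Descriptor matrix (fragments x compounds) or design matrix.
#' @param y Binary labels.
#' @param n_subsets Number of subsets per split (default 3).
#' @param repeats Number of random splits.
#' @param seed RNG seed.
#' @param sigma Ridge prior scale passed to [fit_rlr()].
#' @param max_retry How often to redraw a degenerate split (training data
#'   with a single class) before failing.
#' @return Object of class `cv_classification`: averaged
#'   `classification_metrics` plus a per-repeat data frame `repeats`.
#' @export
cv_random_subsampling <- function(X, y, n_subsets = 3L, repeats = 10L,
                                  seed = 1L, sigma = 1, max_retry = 20L) {
  Xd <- .design(X)
  n <- nrow(Xd)
  if (n < n_subsets) stop("not enough samples for ", n_subsets, " subsets")
  rows <- NULL
  with_preserved_seed(seed, {
    for (rep_i in seq_len(repeats)) {
      for (attempt in seq_len(max_retry + 1L)) {
        if (attempt > max_retry) stop("could not draw a non-degenerate split")
        grp <- sample(rep_len(seq_len(n_subsets), n))
        hold <- sample.int(n_subsets, 1L)
        tr <- grp != hold
        if (length(unique(y[tr])) == 2L && all(table(y[tr]) >= 2L) &&
            length(unique(y[!tr])) == 2L) break
      }
      fit <- fit_rlr(Xd[tr, , drop = FALSE], y[tr], sigma = sigma)
      m <- evaluate_classification(predict(fit, Xd[!tr, , drop = FALSE]),
                                   y[!tr])
      rows <- rbind(rows, data.frame(repeat_id = rep_i,
                                     sensitivity = m$sensitivity,
                                     specificity = m$specificity,
                                     roc_auc = m$roc_auc,
                                     accuracy = m$accuracy))
    }
  })
  avg <- colMeans(rows[, -1L])
  structure(list(sensitivity = avg[["sensitivity"]],
                 specificity = avg[["specificity"]],
                 roc_auc = avg[["roc_auc"]], accuracy = avg[["accuracy"]],
                 repeats = rows),
            class = c("cv_classification", "classification_metrics"))
}

#' RBF kernel
#'
#' k(x1, x2) = exp(-||x1 - x2||^2 / (2 sigma^2)), in (0, 1].
#'
#' @param x1,x2 Numeric vectors of equal length.
#' @param sigma Kernel width, > 0.
#' @return Similarity value.
#' @export
rbf_kernel <- function(x1, x2, sigma) {
  if (sigma <= 0) stop("sigma must be > 0")
  if (length(x1) != length(x2)) stop("length mismatch")
  exp(-sum((x1 - x2)^2) / (2 * sigma^2))
}

#' Fit epsilon-SVR with an RBF kernel
#'
#' Thin wrapper around `e1071::svm` (eps-regression) storing the support
#' coefficients alpha_j and offset b so that predictions can be evaluated
#' explicitly as f(x) = sum_j alpha_j k(x_j, x) + b.  A constant target
#' cannot be fitted by SVR; it yields a constant predictor with a warning.
#'
#' @param X Descriptor matrix (fragments x compounds) or design matrix.
#' @param y Numeric targets (pIC50).
#' @param sigma RBF width; default sqrt(n_features / 2).
#' @param cost Box constraint C.
#' @param epsilon Epsilon-insensitive band half-width.
#' @return Object of class `svr_model`: `alpha`, `b`, `sv` (support
#'   vectors), `sigma`, `cost`, `epsilon`.
#' @export
fit_svr <- function(X, y, sigma = NULL, cost = 10, epsilon = 0.1) {
  Xd <- .design(X)
  if (nrow(Xd) < 5L) stop("need at least 5 samples")
  if (!is.null(sigma) && sigma <= 0) stop("sigma must be > 0")
  if (cost <= 0 || epsilon <= 0) stop("cost and epsilon must be > 0")
  if (is.null(sigma)) sigma <- sqrt(ncol(Xd) / 2)
  if (stats::sd(y) == 0) {
    warning("constant target; returning a constant predictor")
    return(structure(list(alpha = numeric(), b = y[1L],
                          sv = Xd[0L, , drop = FALSE], sigma = sigma,
                          cost = cost, epsilon = epsilon, constant = TRUE),
                     class = "svr_model"))
  }
  fit <- e1071::svm(x = Xd, y = y, type = "eps-regression",
                    kernel = "radial", gamma = 1 / (2 * sigma^2),
                    cost = cost, epsilon = epsilon, scale = FALSE)
  structure(list(alpha = drop(fit$coefs), b = -fit$rho,
                 sv = as.matrix(fit$SV), sigma = sigma, cost = cost,
                 epsilon = epsilon, constant = FALSE),
            class = "svr_model")
}

#' @export
print.svr_model <- function(x, ...) {
  cat("<svr_model> ", length(x$alpha), " support vectors, sigma = ",
      format(x$sigma, digits = 4), ", C = ", x$cost, ", epsilon = ",
      x$epsilon, "\n", sep = "")
  invisible(x)
}

#' @export
predict.svr_model <- function(object, newdata, ...) {
  Xd <- .design(newdata)
  if (object$constant) return(rep(object$b, nrow(Xd)))
  vapply(seq_len(nrow(Xd)), function(i) {
    k <- vapply(seq_len(nrow(object$sv)), function(j)
      rbf_kernel(object$sv[j, ], Xd[i, ], object$sigma), 0)
    sum(object$alpha * k) + object$b
  }, 0)
}

#' Seeded k-fold cross-validation for SVR
#'
#' Folds partition the compounds; per fold the model is trained on the
#' remainder and the fold is predicted, reporting MSE and the Pearson
#' correlation of predicted vs observed values, averaged over folds.
#'
#' @param X Descriptor matrix or design matrix.
#' @param y Numeric targets.
#' @param k Number of folds (default 5).
#' @param seed RNG seed.
#' @param ... Passed to [fit_svr()].
#' @return Object of class `regression_metrics`: `mse`, `pearson_r`, and a
#'   per-fold data frame `folds`.
#' @export
cv_kfold_regression <- function(X, y, k = 5L, seed = 1L, ...) {
  Xd <- .design(X)
  n <- nrow(Xd)
  if (k > n) stop("k exceeds the number of samples")
  rows <- NULL
  with_preserved_seed(seed, {
    grp <- sample(rep_len(seq_len(k), n))
    for (fold in seq_len(k)) {
      tr <- grp != fold
      fit <- fit_svr(Xd[tr, , drop = FALSE], y[tr], ...)
      pred <- predict(fit, Xd[!tr, , drop = FALSE])
      obs <- y[!tr]
      rows <- rbind(rows, data.frame(
        fold = fold, mse = mean((pred - obs)^2),
        pearson_r = if (stats::sd(pred) == 0 || stats::sd(obs) == 0) NA_real_
        else stats::cor(pred, obs)))
    }
  })
  structure(list(mse = mean(rows$mse),
                 pearson_r = mean(rows$pearson_r, na.rm = TRUE),
                 folds = rows),
            class = "regression_metrics")
}

#' @export
print.regression_metrics <- function(x, ...) {
  cat(sprintf("MSE %.3f  Pearson r %.3f\n", x$mse, x$pearson_r))
  invisible(x)
}

#' Small grid search for SVR hyperparameters
#'
#' Evaluates every (sigma, cost, epsilon) combination by k-fold CV and
#' returns the grid sorted by mean MSE.
#'
#' @param X,y As in [cv_kfold_regression()].
#' @param sigma,cost,epsilon Candidate values.
#' @param k,seed CV controls.
#' @return `data.frame` of combinations with `mse` and `pearson_r`.
#' @export
tune_svr <- function(X, y, sigma = c(1, 2, 4), cost = c(1, 10),
                     epsilon = 0.1, k = 5L, seed = 1L) {
  grid <- expand.grid(sigma = sigma, cost = cost, epsilon = epsilon)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    m <- cv_kfold_regression(X, y, k = k, seed = seed,
                             sigma = grid$sigma[i], cost = grid$cost[i],
                             epsilon = grid$epsilon[i])
    c(mse = m$mse, pearson_r = m$pearson_r)
  })
  out <- cbind(grid, do.call(rbind, res))
  out[order(out$mse), ]
}

#' Serialize a model to JSON
#'
#' @param model An `rlr_model` or `svr_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  obj <- unclass(model)
  obj$model_class <- class(model)[1]
  obj$format_version <- 1L
  if (!is.null(obj$sv)) obj$sv <- as.data.frame(obj$sv)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
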