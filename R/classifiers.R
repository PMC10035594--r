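# One-vs-all logistic regression (linear and polynomial-expanded), trained
# by full-batch gradient descent with F1-maximising decision thresholds,
# and closed-form pooled-covariance linear discriminant analysis.

#' Logistic function
#'
#' @param z Numeric vector.
#' @return `1 / (1 + exp(-z))`, in (0, 1) for finite `z`.
#' @export
logistic <- function(z) 1 / (1 + exp(-z))

#' Polynomial feature expansion
#'
#' Degree 1 returns the input unchanged. Degree 2 appends, in fixed order,
#' the pairwise products \eqn{x_i x_j} (i < j, lexicographic) and the
#' squares \eqn{x_i^2} to the linear terms, giving `d + d(d+1)/2`
#' dimensions (495 for the 30 window features). No constant term is added
#' (the bias is separate).
#'
#' @param X Numeric matrix `[n x d]` or vector (treated as one row).
#' @param degree 1 or 2.
#' @return Expanded matrix.
#' @export
poly_expand <- function(X, degree = 1L) {
  if (degree < 1) stop("degree must be >= 1")
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (degree == 1) return(X)
  if (degree > 2) stop("degrees above 2 are not supported")
  d <- ncol(X)
  cross <- if (d >= 2) {
    ij <- utils::combn(d, 2)
    X[, ij[1, ], drop = FALSE] * X[, ij[2, ], drop = FALSE]
  } else NULL
  cbind(X, cross, X^2)
}

#' Training configuration for gradient-descent logistic regression
#'
#' @param learning_rate Step size on standardised inputs (default 0.1).
#' @param max_iter Maximum full-batch iterations (default 5000).
#' @param tol Relative loss-change stopping tolerance (default 1e-7).
#' @param l2 Ridge penalty on the weights, bias excluded (default 1e-4).
#' @param seed Seed for the validation carve-out used in threshold
#'   selection.
#' @param threshold_grid Candidate decision thresholds in (0, 1).
#' @param val_frac Fraction of the training part held out (stratified) for
#'   threshold selection (default 0.2).
#' @return Object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.1, max_iter = 5000L,
                         tol = 1e-7, l2 = 1e-4, seed = 1L,
                         threshold_grid = seq(0.05, 0.95, by = 0.05),
                         val_frac = 0.2) {
  stopifnot(learning_rate > 0, max_iter >= 1, tol >= 0, l2 >= 0,
            all(threshold_grid > 0), all(threshold_grid < 1),
            val_frac > 0, val_frac < 1)
  structure(list(learning_rate = learning_rate,
                 max_iter = as.integer(max_iter), tol = tol, l2 = l2,
                 seed = as.integer(seed), threshold_grid = threshold_grid,
                 val_frac = val_frac),
            class = "train_config")
}

# Penalised cross-entropy: mean CE + (l2 / 2n) * ||theta||^2 (bias free).
logreg_loss <- function(theta, theta0, X, y, l2) {
  p <- logistic(drop(X %*% theta) + theta0)
  eps <- 1e-12
  -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps)) +
    l2 / (2 * length(y)) * sum(theta^2)
}

#' Train one binary logistic model by gradient descent
#'
#' Full-batch gradient descent on the L2-regularised cross-entropy, from a
#' zero initialisation, with a step-halving safeguard: a step that would
#' increase the loss is retried at half the step size, so the accepted loss
#' sequence is non-increasing. Stops at `max_iter` or when the relative
#' loss change drops below `tol`.
#'
#' @param X Numeric feature matrix (already expanded/standardised).
#' @param y01 0/1 response; both classes must be present.
#' @param cfg A [train_config()].
#' @return List with `theta`, `theta0`, `loss` (final), `iterations`.
#' @export
gd_train_binary <- function(X, y01, cfg = train_config()) {
  X <- as.matrix(X)
  y01 <- as.numeric(y01)
  if (!all(y01 %in% c(0, 1))) stop("y01 must be 0/1")
  if (length(unique(y01)) < 2)
    stop("both classes must be present in the training response")
  if (!all(is.finite(X))) stop("non-finite values in feature matrix")
  n <- nrow(X)
  theta <- numeric(ncol(X)); theta0 <- 0
  lr <- cfg$learning_rate
  loss <- logreg_loss(theta, theta0, X, y01, cfg$l2)
  iter <- 0L
  while (iter < cfg$max_iter) {
    iter <- iter + 1L
    p <- logistic(drop(X %*% theta) + theta0)
    resid <- p - y01
    g_theta <- drop(crossprod(X, resid)) / n + cfg$l2 * theta / n
    g_theta0 <- mean(resid)
    step <- lr
    repeat {
      th_new <- theta - step * g_theta
      th0_new <- theta0 - step * g_theta0
      loss_new <- logreg_loss(th_new, th0_new, X, y01, cfg$l2)
      if (!is.finite(loss_new))
        stop("training diverged; reduce learning_rate")
      if (loss_new <= loss || step < 1e-12) break
      step <- step / 2
    }
    stopped <- abs(loss - loss_new) < cfg$tol * max(loss, .Machine$double.eps)
    theta <- th_new; theta0 <- th0_new; loss <- loss_new
    if (stopped) break
  }
  list(theta = theta, theta0 = theta0, loss = loss, iterations = iter)
}

#' One-vs-rest F1 of a probability vector at a threshold
#'
#' @param p Predicted class-membership probabilities.
#' @param y01 True 0/1 labels.
#' @param threshold Decision threshold; predictions are positive when
#'   `p >= threshold`.
#' @return F1 score (0 when precision + recall is 0).
#' @export
binary_f1 <- function(p, y01, threshold) {
  pred <- as.numeric(p >= threshold)
  tp <- sum(pred == 1 & y01 == 1)
  fp <- sum(pred == 1 & y01 == 0)
  fn <- sum(pred == 0 & y01 == 1)
  if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
}

#' Select per-class decision thresholds maximising F1
#'
#' For each class, evaluates every candidate threshold on validation data
#' and keeps the one maximising that class's one-vs-rest F1; ties are
#' broken toward 0.5, then toward the lower threshold. A class absent from
#' the validation labels falls back to 0.5 with a warning.
#'
#' @param prob Matrix `[n_val x n_classes]` of per-class probabilities.
#' @param y_val Validation labels.
#' @param class_set Class vocabulary (column order of `prob`).
#' @param grid Candidate thresholds.
#' @return Named numeric vector of thresholds.
#' @export
select_thresholds <- function(prob, y_val, class_set,
                              grid = seq(0.05, 0.95, by = 0.05)) {
  stopifnot(length(grid) >= 1)
  thr <- setNames(numeric(length(class_set)), class_set)
  for (k in seq_along(class_set)) {
    cl <- class_set[k]
    if (!cl %in% y_val) {
      warning("class '", cl, "' absent from validation data; ",
              "threshold defaults to 0.5")
      thr[k] <- 0.5
      next
    }
    f1 <- vapply(grid, function(t)
      binary_f1(prob[, k], as.numeric(y_val == cl), t), numeric(1))
    best <- which(f1 == max(f1))
    # ties toward 0.5, then toward the lower threshold
    best <- best[order(abs(grid[best] - 0.5), grid[best])][1]
    thr[k] <- grid[best]
  }
  thr
}

#' Train a one-vs-all logistic model
#'
#' Fits one binary gradient-descent logistic classifier per class (that
#' class vs. the rest) on degree-expanded inputs (`degree = 1` is plain
#' LR, `degree = 2` the polynomial NLR). A stratified validation carve-out
#' (`cfg$val_frac` of the training rows, seeded) is held out from fitting
#' and used to pick each class's F1-maximising decision threshold.
#'
#' @param ds Training `labeled_dataset` (raw rows or feature windows).
#' @param cfg A [train_config()].
#' @param degree Polynomial expansion degree (1 = LR, 2 = NLR).
#' @param normalize Fit a z-score normaliser on the training rows and
#'   store it in the model (default TRUE).
#' @return Object of class `logistic_model` with per-class `theta`,
#'   `theta0`, `thresholds`, the `class_set`, `degree` and `norm`.
#' @export
train_ova <- function(ds, cfg = train_config(), degree = 1L,
                      normalize = TRUE) {
  class_set <- sort(unique(ds$y))
  if (length(class_set) < 2) stop("need >= 2 classes")
  norm <- if (normalize) fit_norm(ds$X) else NULL
  X <- if (normalize) apply_norm(ds$X, norm) else ds$X
  Xe <- poly_expand(X, degree)
  # stratified validation carve-out for threshold selection
  idx_val <- integer(0)
  with_seed(cfg$seed, {
    for (cl in class_set) {
      rows <- which(ds$y == cl)
      n_val <- max(1L, floor(cfg$val_frac * length(rows) + 0.5))
      idx_val <- c(idx_val, sample(rows)[seq_len(n_val)])
    }
  })
  idx_fit <- setdiff(seq_along(ds$y), idx_val)
  fits <- lapply(class_set, function(cl)
    gd_train_binary(Xe[idx_fit, , drop = FALSE],
                    as.numeric(ds$y[idx_fit] == cl), cfg))
  names(fits) <- class_set
  prob_val <- vapply(fits, function(f)
    logistic(drop(Xe[idx_val, , drop = FALSE] %*% f$theta) + f$theta0),
    numeric(length(idx_val)))
  prob_val <- matrix(prob_val, nrow = length(idx_val))
  thresholds <- select_thresholds(prob_val, ds$y[idx_val], class_set,
                                  cfg$threshold_grid)
  structure(list(family = "logistic", class_set = class_set,
                 degree = as.integer(degree),
                 theta = lapply(fits, `[[`, "theta"),
                 theta0 = vapply(fits, `[[`, numeric(1), "theta0"),
                 thresholds = thresholds, norm = norm),
            class = "logistic_model")
}

#' Per-class membership probabilities of a logistic model
#'
#' One-vs-all probabilities are independent binary posteriors and are
#' deliberately not renormalised to sum to one.
#'
#' @param model A `logistic_model`.
#' @param X Feature matrix or single feature vector (unexpanded,
#'   unstandardised).
#' @return Matrix `[n x n_classes]` of probabilities in (0, 1).
#' @export
predict_prob <- function(model, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (!is.null(model$norm)) X <- apply_norm(X, model$norm)
  Xe <- poly_expand(X, model$degree)
  if (ncol(Xe) != length(model$theta[[1]]))
    stop("feature dimension mismatch: model expects ",
         length(model$theta[[1]]), " expanded features, got ", ncol(Xe))
  p <- vapply(seq_along(model$class_set), function(k)
    logistic(drop(Xe %*% model$theta[[k]]) + model$theta0[k]),
    numeric(nrow(Xe)))
  p <- matrix(p, nrow = nrow(Xe))
  colnames(p) <- model$class_set
  p
}

#' Predict class labels
#'
#' Among classes whose probability reaches their decision threshold, the
#' most probable wins; if none reaches its threshold the globally most
#' probable class is taken as a fallback. Exact ties go to the class
#' earliest in the class set.
#'
#' @param model A `logistic_model` or `lda_model`.
#' @param X Feature matrix or vector.
#' @return Character vector of predicted labels.
#' @export
predict_class <- function(model, X) UseMethod("predict_class")

#' @export
predict_class.logistic_model <- function(model, X) {
  p <- predict_prob(model, X)
  apply(p, 1, function(pi) {
    ok <- which(pi >= model$thresholds)
    pool <- if (length(ok) > 0) ok else seq_along(pi)
    model$class_set[pool[which.max(pi[pool])]]
  })
}

#' Fit linear discriminant analysis
#'
#' Closed-form LDA under the equal-covariance Gaussian model: per-class
#' affine discriminants \eqn{\beta_c^T x + \beta_{0c}} with
#' \eqn{\beta_c = \Sigma^{-1}\mu_c} and
#' \eqn{\beta_{0c} = -\tfrac12 \mu_c^T \Sigma^{-1} \mu_c + \log \pi_c},
#' where \eqn{\Sigma} is the pooled within-class covariance (ridge of
#' `1e-6 * trace / d` added to the diagonal) and \eqn{\pi_c} the empirical
#' class frequencies. Prediction is the argmax of the affine scores.
#'
#' @param ds Training `labeled_dataset`.
#' @param normalize Store a z-score normaliser fitted on the training rows
#'   (default TRUE).
#' @return Object of class `lda_model` with per-class `beta`, `beta0`.
#' @export
lda_fit <- function(ds, normalize = TRUE) {
  class_set <- sort(unique(ds$y))
  if (length(class_set) < 2) stop("need >= 2 classes")
  norm <- if (normalize) fit_norm(ds$X) else NULL
  X <- if (normalize) apply_norm(ds$X, norm) else as.matrix(ds$X)
  d <- ncol(X); n <- nrow(X)
  means <- t(vapply(class_set, function(cl)
    colMeans(X[ds$y == cl, , drop = FALSE]), numeric(d)))
  Sw <- matrix(0, d, d)
  for (k in seq_along(class_set)) {
    Xc <- sweep(X[ds$y == class_set[k], , drop = FALSE], 2, means[k, ])
    Sw <- Sw + crossprod(Xc)
  }
  Sw <- Sw / (n - length(class_set))
  ridge <- 1e-6 * sum(diag(Sw)) / d
  Sw <- Sw + diag(ridge, d)
  Sinv <- tryCatch(solve(Sw), error = function(e)
    stop("pooled within-class covariance is singular even after ridge"))
  priors <- as.numeric(table(factor(ds$y, levels = class_set))) / n
  beta <- lapply(seq_along(class_set), function(k) drop(Sinv %*% means[k, ]))
  beta0 <- vapply(seq_along(class_set), function(k)
    -0.5 * drop(means[k, ] %*% Sinv %*% means[k, ]) + log(priors[k]),
    numeric(1))
  names(beta) <- class_set
  structure(list(family = "lda", class_set = class_set, beta = beta,
                 beta0 = setNames(beta0, class_set), norm = norm),
            class = "lda_model")
}

#' Affine LDA scores
#'
#' @param model An `lda_model`.
#' @param X Feature matrix or vector.
#' @return Matrix `[n x n_classes]` of discriminant scores.
#' @export
lda_scores <- function(model, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (!is.null(model$norm)) X <- apply_norm(X, model$norm)
  if (ncol(X) != length(model$beta[[1]]))
    stop("feature dimension mismatch: model expects ",
         length(model$beta[[1]]), " features, got ", ncol(X))
  s <- vapply(seq_along(model$class_set), function(k)
    drop(X %*% model$beta[[k]]) + model$beta0[k], numeric(nrow(X)))
  s <- matrix(s, nrow = nrow(X))
  colnames(s) <- model$class_set
  s
}

#' @export
predict_class.lda_model <- function(model, X) {
  s <- lda_scores(model, X)
  model$class_set[apply(s, 1, which.max)]
}

MODEL_FORMAT_VERSION <- "1"

#' Model JSON round trip
#'
#' Logistic and LDA models share one JSON envelope distinguished by a
#' `family` field; parameters are written at full double precision and a
#' format-version tag is checked on load.
#'
#' @param model A `logistic_model` or `lda_model`.
#' @param path JSON file path.
#' @return `save_model` returns `path` invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  body <- unclass(model)
  body$format_version <- MODEL_FORMAT_VERSION
  jsonlite::write_json(body, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  j <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                error = function(e)
                  stop("cannot parse model file '", path, "': ",
                       conditionMessage(e), call. = FALSE))
  if (is.null(j$format_version) || j$format_version != MODEL_FORMAT_VERSION)
    stop("model format version mismatch (expected ", MODEL_FORMAT_VERSION,
         ", found ", j$format_version %||% "none", ")")
  norm <- if (is.null(j$norm)) NULL else
    list(mean = as.numeric(j$norm$mean), sd = as.numeric(j$norm$sd))
  if (identical(j$family, "logistic")) {
    structure(list(family = "logistic", class_set = j$class_set,
                   degree = as.integer(j$degree),
                   theta = lapply(j$theta, as.numeric),
                   theta0 = setNames(as.numeric(j$theta0), j$class_set),
                   thresholds = setNames(as.numeric(j$thresholds),
                                         j$class_set),
                   norm = norm),
              class = "logistic_model")
  } else if (identical(j$family, "lda")) {
    structure(list(family = "lda", class_set = j$class_set,
                   beta = lapply(j$beta, as.numeric),
                   beta0 = setNames(as.numeric(j$beta0), j$class_set),
                   norm = norm),
              class = "lda_model")
  } else stop("unknown model family '", j$family, "'")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
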