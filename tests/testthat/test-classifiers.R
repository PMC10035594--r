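test_that("logistic and score follow the membership-probability form", {
  expect_equal(logistic(0), 0.5)
  expect_equal(logistic(c(-Inf, Inf)), c(0, 1))
  # theta = [1, -1], theta0 = 0, x = [2, 1] -> 1 / (1 + e^-1)
  z <- sum(c(1, -1) * c(2, 1)) + 0
  expect_equal(logistic(z), 1 / (1 + exp(-1)), tolerance = 1e-12)
})

test_that("poly_expand produces the documented monomial order", {
  expect_equal(drop(poly_expand(c(3, 5), 2)),
               c(3, 5, 15, 9, 25))          # x1, x2, x1*x2, x1^2, x2^2
  x <- rnorm(7)
  expect_equal(drop(poly_expand(x, 1)), x)
  expect_equal(ncol(poly_expand(matrix(rnorm(60), ncol = 30), 2)),
               495L)                        # 30 + 30 * 31 / 2
  expect_error(poly_expand(x, 0), ">= 1")
})

test_that("gradient descent separates a toy problem and matches a convex
           solver", {
  with_seed(15, {
    X <- rbind(cbind(rnorm(10, -2, 0.5), rnorm(10, -2, 0.5)),
               cbind(rnorm(10, 2, 0.5), rnorm(10, 2, 0.5)))
  })
  y <- rep(c(0, 1), each = 10)
  cfg <- train_config(learning_rate = 1, max_iter = 20000L, tol = 1e-12,
                      l2 = 1e-2)
  fit <- gd_train_binary(X, y, cfg)
  p <- logistic(drop(X %*% fit$theta) + fit$theta0)
  expect_equal(as.numeric(p >= 0.5), y)     # training accuracy 1 at 0.5
  # loss is below the theta = 0 starting loss of log(2)
  expect_lt(fit$loss, log(2))

  # independent quasi-Newton minimiser of the same penalised objective
  obj <- function(par) {
    th <- par[-length(par)]; th0 <- par[length(par)]
    pr <- 1 / (1 + exp(-(drop(X %*% th) + th0)))
    -mean(y * log(pr + 1e-12) + (1 - y) * log(1 - pr + 1e-12)) +
      cfg$l2 / (2 * length(y)) * sum(th^2)
  }
  ref <- optim(rep(0, 3), obj, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
  expect_lt(sqrt(sum((fit$theta - ref$par[1:2])^2)) /
              sqrt(sum(ref$par[1:2]^2)), 1e-2)

  expect_error(gd_train_binary(X, rep(1, 20)), "both classes")
  expect_error(gd_train_binary(X, y * 2), "0/1")
})

test_that("threshold selection maximises one-vs-rest F1 with stated
           tie-breaks", {
  # perfectly separated: every mid threshold ties at F1 = 1 -> 0.5 wins
  prob <- matrix(c(0.9, 0.9, 0.1, 0.1), ncol = 1)
  y <- c("a", "a", "b", "b")
  thr <- select_thresholds(prob, y, "a", grid = c(0.2, 0.5, 0.8))
  expect_equal(unname(thr), 0.5)

  # constructed case where a low threshold wins on recall
  p2 <- matrix(c(0.45, 0.35, 0.8, 0.2, 0.1), ncol = 1)
  y2 <- c("a", "a", "a", "b", "b")
  # brute force over the grid
  grid <- c(0.3, 0.5)
  f1s <- vapply(grid, function(t) binary_f1(p2[, 1],
                                            as.numeric(y2 == "a"), t),
                numeric(1))
  expect_gt(f1s[1], f1s[2])
  thr2 <- select_thresholds(p2, y2, "a", grid = grid)
  expect_equal(unname(thr2), 0.3)

  expect_equal(unname(select_thresholds(p2, y2, "a", grid = 0.5)), 0.5)
  expect_warning(
    thr3 <- select_thresholds(prob, c("a", "a", "a", "a"), c("a", "c"),
                              grid = c(0.3, 0.5)),
    "absent from validation")
  expect_equal(unname(thr3["c"]), 0.5)
})

test_that("one-vs-all prediction applies thresholds, fallback and
           tie-break", {
  model <- structure(
    list(family = "logistic", class_set = c("a", "b", "c"), degree = 1L,
         theta = list(c(10, 0), c(0, 10), c(0, 0)),
         theta0 = c(a = 0, b = 0, c = 0),
         thresholds = c(a = 0.5, b = 0.5, c = 0.5), norm = NULL),
    class = "logistic_model")
  # class a clears its threshold, others do not
  expect_equal(predict_class(model, c(1, -1)), "a")
  # nothing clears 0.5 except c at exactly 0.5; tie logic: c eligible
  expect_equal(predict_class(model, c(-1, -1)), "c")
  # exact tie between a and b resolves to the earlier class
  expect_equal(predict_class(model, c(1, 1)), "a")
  expect_error(predict_class(model, c(1, 2, 3)), "dimension mismatch")
})

test_that("train_ova fits one binary model per class and degree-1 equals
           plain LR", {
  ds <- blob_dataset(n_per = 40)
  cfg <- train_config(max_iter = 500L, seed = 2)
  m <- train_ova(ds, cfg, degree = 1L)
  expect_equal(m$class_set, c("a", "b"))
  expect_length(m$theta, 2)
  expect_length(m$theta[[1]], 2)
  expect_true(all(m$thresholds > 0 & m$thresholds < 1))
  expect_equal(predict_class(m, ds$X), ds$y)

  m2 <- train_ova(ds, cfg, degree = 2L)
  expect_length(m2$theta[[1]], 5)           # d + d(d+1)/2 for d = 2

  # the degree-1 polynomial model is exactly the linear model
  m1b <- train_ova(ds, cfg, degree = 1L)
  expect_identical(m$theta, m1b$theta)
  expect_identical(predict_class(m, ds$X), predict_class(m1b, ds$X))
})

test_that("LDA matches the closed-form pooled-covariance discriminant", {
  ds <- blob_dataset(n_per = 100, sd = 0.1)
  m <- lda_fit(ds, normalize = FALSE)
  expect_equal(predict_class(m, ds$X), ds$y)

  # hand-computed two-class direction: beta_b - beta_a = Sigma^-1 (mu_b - mu_a)
  Xa <- ds$X[ds$y == "a", ]; Xb <- ds$X[ds$y == "b", ]
  mu_a <- colMeans(Xa); mu_b <- colMeans(Xb)
  Sw <- (crossprod(sweep(Xa, 2, mu_a)) + crossprod(sweep(Xb, 2, mu_b))) /
    (nrow(ds$X) - 2)
  Sw <- Sw + diag(1e-6 * sum(diag(Sw)) / 2, 2)
  dir_oracle <- solve(Sw, mu_b - mu_a)
  expect_equal(m$beta[["b"]] - m$beta[["a"]], dir_oracle,
               tolerance = 1e-9, ignore_attr = TRUE)

  # affine decision scores: a constant input shift changes all scores by
  # beta^T dx, preserving the argmax structure
  dx <- c(0.3, -0.2)
  s1 <- lda_scores(m, ds$X[1:5, ])
  s2 <- lda_scores(m, sweep(ds$X[1:5, ], 2, -dx))
  shift <- vapply(m$beta, function(b) sum(b * dx), numeric(1))
  expect_equal(s2, sweep(s1, 2, -shift), tolerance = 1e-10)

  # equal class means and priors: scores tie, earlier class code wins
  Xeq <- rbind(c(0, 0), c(1, 1), c(0, 1), c(1, 0))
  dse <- make_dataset(rbind(Xeq, Xeq), rep(c("a", "b"), each = 4))
  me <- lda_fit(dse, normalize = FALSE)
  expect_equal(unname(me$beta0["a"]), unname(me$beta0["b"]))
  expect_equal(predict_class(me, c(0.5, 0.5)), "a")
})

test_that("model JSON round trip preserves predictions across families", {
  ds <- blob_dataset(n_per = 30)
  probe <- blob_dataset(n_per = 10, seed = 77)$X
  for (maker in list(function() train_ova(ds, train_config(max_iter = 300L),
                                          degree = 2L),
                     function() lda_fit(ds))) {
    m <- maker()
    path <- withr::local_tempfile(fileext = ".json")
    save_model(m, path)
    m2 <- load_model(path)
    expect_identical(class(m2), class(m))
    expect_equal(predict_class(m2, probe), predict_class(m, probe))
  }

  bad <- withr::local_tempfile(fileext = ".json")
  writeLines("{ not json", bad)
  expect_error(load_model(bad), "cannot parse")
  jsonlite::write_json(list(family = "logistic", format_version = "999"),
                       bad, auto_unbox = TRUE)
  expect_error(load_model(bad), "version mismatch")
})
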