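brute_confusion <- function(y_true, y_pred, classes) {
  m <- matrix(0L, length(classes), length(classes),
              dimnames = list(classes, classes))
  for (i in seq_along(y_true))
    m[y_true[i], y_pred[i]] <- m[y_true[i], y_pred[i]] + 1L
  m
}
brute_f1 <- function(y_true, y_pred, cl) {
  tp <- sum(y_true == cl & y_pred == cl)
  fp <- sum(y_true != cl & y_pred == cl)
  fn <- sum(y_true == cl & y_pred != cl)
  if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
}

test_that("confusion, accuracy and F1 match hand arithmetic", {
  y <- c("a", "a", "b", "b")
  cm <- confusion(y, y)
  expect_equal(diag(cm), c(a = 2L, b = 2L), ignore_attr = TRUE)
  expect_equal(accuracy(cm), 1)
  expect_equal(unname(f1_per_class(cm)), c(1, 1))

  # 2-class counts TP = 8, FP = 2, FN = 2, TN = 8 -> F1 = 0.8 both ways
  y_true <- rep(c("pos", "neg"), each = 10)
  y_pred <- c(rep("pos", 8), rep("neg", 2), rep("pos", 2), rep("neg", 8))
  cm2 <- confusion(y_true, y_pred)
  expect_equal(unname(f1_per_class(cm2)), c(0.8, 0.8))
  expect_equal(macro_f1(cm2), 0.8)

  # all-one-class predictions on balanced 7-class truth
  classes <- names(motion_classes())
  yt <- rep(classes, each = 10)
  cm7 <- confusion(yt, rep("rest", 70), class_set = classes)
  expect_equal(accuracy(cm7), 1 / 7)

  expect_error(confusion(c("a", "z"), c("a", "a"), class_set = "a"),
               "outside the class set")
  expect_error(confusion("a", c("a", "b")), "length")
})

test_that("metrics agree with brute-force counting on random instances", {
  with_seed(101, {
    for (i in 1:200) {
      k <- sample(2:5, 1)
      n <- sample(5:40, 1)
      classes <- letters[1:k]
      yt <- sample(classes, n, replace = TRUE)
      yp <- sample(classes, n, replace = TRUE)
      cm <- confusion(yt, yp, class_set = classes)
      expect_equal(unclass(cm), brute_confusion(yt, yp, classes),
                   ignore_attr = TRUE)
      expect_equal(accuracy(cm), mean(yt == yp))
      expect_equal(unname(f1_per_class(cm)),
                   vapply(classes, function(cl) brute_f1(yt, yp, cl),
                          numeric(1)), ignore_attr = TRUE)
      expect_equal(unname(rowSums(cm)),
                   unname(as.vector(table(factor(yt, classes)))))
    }
  })
})

test_that("Mann-Whitney U: exact enumeration, ties, and the printed gate", {
  # identical samples: no detectable difference
  r <- mann_whitney_u(c(5, 5, 5), c(5, 5, 5))
  expect_gte(r$p, 0.99)

  # {1,2,3} vs {4,5,6}: U = 0, two-sided exact p = 2 * 1/20
  r2 <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r2$U, 0)
  expect_equal(r2$p, 0.1)
  expect_equal(r2$method, "exact")

  # independent reference on tie-free samples
  with_seed(33, {
    for (i in 1:20) {
      a <- rnorm(sample(3:8, 1))
      b <- rnorm(sample(3:8, 1))
      mine <- mann_whitney_u(a, b)
      ref <- wilcox.test(a, b, exact = TRUE, correct = FALSE)
      expect_equal(mine$U, unname(ref$statistic))
      expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
    }
  })

  # gate: p = 0.02 against alpha/m = 0.05/3 is not significant
  g <- bonferroni_gate(c(0.02, 0.001), m = 3)
  expect_equal(g$gate, 0.05 / 3, tolerance = 1e-12)
  expect_equal(g$significant, c(FALSE, TRUE))

  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("normal approximation tracks the exact distribution for
           mid-size samples", {
  for (n in 9:12) {
    with_seed(200 + n, {
      a <- rnorm(n); b <- rnorm(n, 0.5)
    })
    appr <- mann_whitney_u(a, b, method = "approx")
    u <- appr$U
    # exact two-sided p from the null U distribution (tie-free)
    p_exact <- min(1, 2 * min(pwilcox(u, n, n),
                              1 - pwilcox(u - 1, n, n)))
    expect_lt(abs(appr$p - p_exact), 0.02)
  }
})

test_that("simulate_stream ticks at the decision stride", {
  h <- small_hierarchy()
  s <- generate_stream(noise_free_profile(), "point", duration_s = 5)
  trial <- simulate_stream(h, s, stride_ms = 90)
  expect_equal(nrow(trial$predictions), 54L)  # floor((5000-150)/90) + 1
  expect_equal(trial$predictions$time_s[1], 0.150)
  expect_true(all(trial$predictions$gesture == "point"))
  expect_true(all(is.na(trial$predictions$force)))
  expect_equal(online_accuracy(trial), 100)

  # stride as long as the stream: a single decision
  t1 <- simulate_stream(h, s, stride_ms = 5000)
  expect_equal(nrow(t1$predictions), 1L)

  short <- generate_stream(noise_free_profile(), "point", duration_s = 0.1)
  expect_error(simulate_stream(h, short), "shorter than one window")
})

test_that("online accuracy and MCR count ticks against the target class", {
  tr <- fake_trial(20, 54)
  expect_equal(online_accuracy(tr), 100 * 20 / 54, tolerance = 1e-12)
  expect_equal(mcr(list(tr)), 100)            # 20 >= ceil(1000/90) = 12
  expect_equal(mcr(list(fake_trial(11, 54))), 0)
  expect_equal(mcr(list(fake_trial(20, 54), fake_trial(3, 54),
                        fake_trial(0, 54))), 100 / 3, tolerance = 1e-12)

  # grasp targets require gesture AND level to match
  g_ok <- fake_trial(54, 54, target_gesture = "tip", target_force = "low")
  expect_equal(online_accuracy(g_ok), 100)
  g_wrong_level <- g_ok
  g_wrong_level$predictions$force <- "high"
  expect_equal(online_accuracy(g_wrong_level), 0)
})

test_that("the simulated real-time experiment covers 11 classes x 3
           trials", {
  h <- small_hierarchy()
  report <- run_realtime_experiment(h, noise_free_profile(), n_trials = 3,
                                    duration_s = 1.5)
  expect_equal(nrow(report), 11L)
  expect_length(attr(report, "trials"), 33L)
  expect_true(all(report$online_accuracy == 100))
  expect_true(all(report$mcr == 100))
  expect_equal(report$label[report$gesture == "spherical"],
               c("spherical/low", "spherical/medium", "spherical/high"))
})

test_that("offline experiment reports are reproducible and separable at
           the default profile", {
  sess <- small_session(seed = 23)
  r1 <- run_offline_experiment(sess, "lda", fe = TRUE, per_rep_keep = 400,
                               seed = 5)
  r2 <- run_offline_experiment(sess, "lda", fe = TRUE, per_rep_keep = 400,
                               seed = 5)
  expect_identical(r1$gesture$confusion, r2$gesture$confusion)
  expect_named(r1, c("gesture", "spherical_force", "tip_force"))
  expect_equal(attr(r1$spherical_force$confusion, "class_set"),
               sort(force_levels()))
  expect_gt(r1$gesture$macro_f1, 0.8)
})
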