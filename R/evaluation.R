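# Offline metrics, Mann-Whitney U comparison with Bonferroni gating, and
# the simulated real-time decision loop (90 ms stride, 5-s trials, online
# accuracy and motion completion rate).

#' Confusion matrix
#'
#' @param y_true True labels.
#' @param y_pred Predicted labels (same length).
#' @param class_set Label vocabulary; labels outside it are an error.
#' @return Object of class `confusion_matrix`: integer matrix with rows =
#'   true class, columns = predicted class.
#' @export
confusion <- function(y_true, y_pred, class_set = sort(unique(y_true))) {
  stopifnot(length(y_true) == length(y_pred))
  bad <- setdiff(unique(c(y_true, y_pred)), class_set)
  if (length(bad) > 0)
    stop("label(s) outside the class set: ", paste(bad, collapse = ", "))
  m <- table(factor(y_true, levels = class_set),
             factor(y_pred, levels = class_set))
  structure(unclass(m), class = "confusion_matrix", class_set = class_set)
}

#' Metrics from a confusion matrix
#'
#' `accuracy` is trace/total; `f1_per_class` the one-vs-rest F1 of each
#' class (0 when precision + recall is 0); `macro_f1` their unweighted
#' mean.
#'
#' @param cm A [confusion()] matrix.
#' @return `accuracy`/`macro_f1`: scalar in `[0, 1]`; `f1_per_class`:
#'   named vector.
#' @export
accuracy <- function(cm) sum(diag(cm)) / sum(cm)

#' @rdname accuracy
#' @export
f1_per_class <- function(cm) {
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  f1 <- ifelse(2 * tp + fp + fn == 0, 0, 2 * tp / (2 * tp + fp + fn))
  setNames(as.numeric(f1), attr(cm, "class_set"))
}

#' @rdname accuracy
#' @export
macro_f1 <- function(cm) mean(f1_per_class(cm))

# Mann-Whitney U of sample a (midranks for ties).
u_statistic <- function(a, b) {
  r <- rank(c(a, b))
  sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
}

#' Two-sided Mann-Whitney U test
#'
#' Exact enumeration of the permutation distribution of U (handles ties)
#' when the smaller sample has at most 8 observations and the arrangement
#' count is tractable; otherwise the tie-corrected normal approximation
#' with continuity correction. `method` can force either route.
#'
#' @param a,b Numeric samples (non-empty).
#' @param method `"auto"` (default), `"exact"` or `"approx"`.
#' @return List with `U` (for sample `a`), `p` (two-sided) and the
#'   `method` used.
#' @export
mann_whitney_u <- function(a, b, method = c("auto", "exact", "approx")) {
  method <- match.arg(method)
  if (length(a) == 0 || length(b) == 0) stop("samples must be non-empty")
  n1 <- length(a); n2 <- length(b); n <- n1 + n2
  u <- u_statistic(a, b)
  use_exact <- switch(method,
    exact = TRUE, approx = FALSE,
    auto = min(n1, n2) <= 8 && choose(n, n1) <= 5e5)
  if (use_exact) {
    pool <- c(a, b)
    idx <- utils::combn(n, n1)
    us <- apply(idx, 2, function(i) u_statistic(pool[i], pool[-i]))
    p <- min(1, 2 * min(mean(us <= u), mean(us >= u)))
    return(list(U = u, p = p, method = "exact"))
  }
  mu <- n1 * n2 / 2
  ties <- table(c(a, b))
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) return(list(U = u, p = 1, method = "approx"))
  z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
  list(U = u, p = min(1, 2 * stats::pnorm(-abs(z))), method = "approx")
}

#' Bonferroni significance gate
#'
#' Compares each p-value to `alpha / m`; with the conventional alpha of
#' 0.05 and three pairwise algorithm comparisons the gate is p < 0.0167
#' (printed as 0.016).
#'
#' @param p_values Numeric p-values.
#' @param m Number of comparisons (default `length(p_values)`).
#' @param alpha Family-wise error rate (default 0.05).
#' @return List with `gate` and logical `significant`.
#' @export
bonferroni_gate <- function(p_values, m = length(p_values), alpha = 0.05) {
  stopifnot(m >= 1, alpha > 0, alpha < 1)
  gate <- alpha / m
  list(gate = gate, significant = p_values < gate)
}

#' Train one classifier with the requested algorithm
#'
#' Dispatcher over the three classification algorithms: `"lr"` (linear
#' one-vs-all logistic regression), `"nlr"` (degree-2 polynomial logistic
#' regression) and `"lda"` (closed-form linear discriminant analysis).
#'
#' @param ds Training `labeled_dataset`.
#' @param algorithm One of `"lr"`, `"nlr"`, `"lda"`.
#' @param cfg A [train_config()] (ignored by LDA).
#' @return A fitted `logistic_model` or `lda_model`.
#' @export
train_algorithm <- function(ds, algorithm = c("lr", "nlr", "lda"),
                            cfg = train_config()) {
  algorithm <- match.arg(algorithm)
  switch(algorithm,
         lr = train_ova(ds, cfg, degree = 1L),
         nlr = train_ova(ds, cfg, degree = 2L),
         lda = lda_fit(ds))
}

#' Select the recordings feeding the gesture classifier
#'
#' The protocol's per-class sample budget: non-grasp gestures contribute
#' all repetitions; each grasp contributes 2 repetitions per force level,
#' so every gesture class spans 6 recordings (4,800 central samples each
#' at defaults) and the session matrix has 7 x 4,800 = 33,600 rows.
#' Training the grasp gestures across all three force levels keeps the
#' gesture classifier robust to contraction intensity.
#'
#' @param recordings Session recordings.
#' @param n_reps_kept Recordings kept per gesture class (default 6).
#' @return Filtered list of recordings.
#' @export
gesture_subset <- function(recordings, n_reps_kept = 6L) {
  keep <- vapply(recordings, function(r) {
    if (!r$label %in% grasp_classes()) TRUE
    else r$repetition <= max(1L, n_reps_kept %/% length(force_levels()))
  }, logical(1))
  recordings[keep]
}

offline_report <- function(cm, algorithm, fe) {
  structure(list(algorithm = algorithm, fe = fe, accuracy = accuracy(cm),
                 f1 = f1_per_class(cm), macro_f1 = macro_f1(cm),
                 confusion = cm),
            class = "offline_report")
}

#' @export
print.offline_report <- function(x, ...) {
  cat(sprintf("<offline_report> %s %s FE: accuracy %.3f, macro-F1 %.3f\n",
              toupper(x$algorithm), if (x$fe) "with" else "without",
              x$accuracy, x$macro_f1))
  print(round(x$f1, 3))
  invisible(x)
}

evaluate_on <- function(model, test) {
  pred <- predict_class(model, test$X)
  confusion(test$y, pred, class_set = model$class_set)
}

#' Run the offline experiment for one algorithm
#'
#' Builds the three training problems from a session's recordings —
#' 7-gesture dataset (33,600 raw rows at protocol defaults) and the two
#' grasp force datasets — then, per problem: optional feature extraction,
#' stratified 70/30 split, training and test-set evaluation. With feature
#' extraction the 70/30 split is applied to the analysis windows (windows
#' are never cut across the split); without it, to the raw sample rows.
#'
#' @param recordings Session recordings (e.g. from [generate_session()]).
#' @param algorithm `"lr"`, `"nlr"` or `"lda"`.
#' @param fe Apply the five-feature extraction step (default TRUE).
#' @param cfg A [train_config()].
#' @param wcfg A [window_config()].
#' @param per_rep_keep Central samples kept per repetition (default 800).
#' @param train_frac Training fraction (default 0.7).
#' @param seed Split seed.
#' @return List of three `offline_report`s: `gesture`, `spherical_force`,
#'   `tip_force`.
#' @export
run_offline_experiment <- function(recordings, algorithm = "lr", fe = TRUE,
                                   cfg = train_config(),
                                   wcfg = window_config(),
                                   per_rep_keep = 800, train_frac = 0.7,
                                   seed = 1L) {
  datasets <- list(
    gesture = assemble_dataset(gesture_subset(recordings), per_rep_keep,
                               label_by = "gesture"),
    spherical_force = assemble_dataset(
      Filter(function(r) r$label == "spherical" && !is.na(r$force),
             recordings), per_rep_keep, label_by = "force"),
    tip_force = assemble_dataset(
      Filter(function(r) r$label == "tip" && !is.na(r$force), recordings),
      per_rep_keep, label_by = "force"))
  reports <- lapply(seq_along(datasets), function(i) {
    ds <- datasets[[i]]
    if (fe) ds <- featurize(ds, wcfg)
    parts <- split_dataset(ds, train_frac, seed = derive_seed(seed, i))
    model <- train_algorithm(parts$train, algorithm, cfg)
    offline_report(evaluate_on(model, parts$test), algorithm, fe)
  })
  names(reports) <- names(datasets)
  reports
}

#' Train the full hierarchical classifier from a session
#'
#' Trains the 7-gesture classifier and both 3-level force classifiers on
#' all of a session's recordings (the real-time protocol trains offline on
#' the complete session, then validates online on fresh streams).
#'
#' @inheritParams run_offline_experiment
#' @param feature_mode `"extracted"` or `"raw"`.
#' @return A [hierarchical_classifier()].
#' @export
train_hierarchical <- function(recordings, algorithm = "lr",
                               feature_mode = c("extracted", "raw"),
                               cfg = train_config(),
                               wcfg = window_config(),
                               per_rep_keep = 800) {
  feature_mode <- match.arg(feature_mode)
  prep <- function(ds) if (feature_mode == "extracted")
    featurize(ds, wcfg) else ds
  g_ds <- prep(assemble_dataset(gesture_subset(recordings), per_rep_keep,
                                label_by = "gesture"))
  s_ds <- prep(assemble_dataset(
    Filter(function(r) r$label == "spherical" && !is.na(r$force),
           recordings), per_rep_keep, label_by = "force"))
  t_ds <- prep(assemble_dataset(
    Filter(function(r) r$label == "tip" && !is.na(r$force), recordings),
    per_rep_keep, label_by = "force"))
  hierarchical_classifier(
    gesture_clf = train_algorithm(g_ds, algorithm, cfg),
    spherical_force_clf = train_algorithm(s_ds, algorithm, cfg),
    tip_force_clf = train_algorithm(t_ds, algorithm, cfg),
    feature_cfg = wcfg, feature_mode = feature_mode)
}

#' Simulate the real-time decision loop on a stream
#'
#' Every `stride_ms` the most recent full analysis window is featurized
#' and classified hierarchically; the first decision fires once one full
#' window is available. A 5-s stream at the 150 ms window and 90 ms
#' stride yields `floor((5000 - 150) / 90) + 1 = 54` decisions.
#'
#' @param h A [hierarchical_classifier()].
#' @param stream An [emg_recording()] (its label/force are the trial
#'   target).
#' @param stride_ms Decision stride in milliseconds (default 90).
#' @return Object of class `realtime_trial`: target gesture/force and a
#'   data frame of time-stamped predictions.
#' @export
simulate_stream <- function(h, stream, stride_ms = 90) {
  X <- stream$samples
  win <- h$feature_cfg$win
  if (nrow(X) < win)
    stop("stream of ", nrow(X), " samples is shorter than one window")
  stride <- max(1L, round(stride_ms * stream$fs / 1000))
  ends <- seq(win, nrow(X), by = stride)
  preds <- lapply(ends, function(e)
    predict_hierarchical(h, X[(e - win + 1L):e, , drop = FALSE]))
  structure(
    list(target_gesture = stream$label, target_force = stream$force,
         stride_ms = stride_ms, duration_s = nrow(X) / stream$fs,
         predictions = data.frame(
           time_s = ends / stream$fs,
           gesture = vapply(preds, `[[`, character(1), "gesture"),
           force = vapply(preds, `[[`, character(1), "force"),
           stringsAsFactors = FALSE)),
    class = "realtime_trial")
}

correct_ticks <- function(trial) {
  p <- trial$predictions
  sum(p$gesture == trial$target_gesture &
        (is.na(p$force) & is.na(trial$target_force) |
           !is.na(p$force) & !is.na(trial$target_force) &
           p$force %in% trial$target_force))
}

#' Online accuracy of a real-time trial
#'
#' Percentage of decision ticks whose prediction equals the target motion
#' class exactly — for a grasp target both the gesture and the force level
#' must match. Every tick from the first full window counts.
#'
#' @param trial A [simulate_stream()] result.
#' @return Percentage in `[0, 100]`.
#' @export
online_accuracy <- function(trial) {
  n <- nrow(trial$predictions)
  if (n == 0) stop("trial has no predictions")
  100 * correct_ticks(trial) / n
}

#' Motion completion rate
#'
#' A trial counts as completed when the target motion class is predicted
#' for a cumulative `complete_s` seconds within the trial (at the 90 ms
#' stride and 1 s requirement: at least 12 of the 54 decision ticks). MCR
#' is the percentage of completed trials among those attempted.
#'
#' @param trials List of [simulate_stream()] trials (same target class).
#' @param complete_s Cumulative correct time required (default 1 s).
#' @return Percentage in `[0, 100]`.
#' @export
mcr <- function(trials, complete_s = 1.0) {
  stopifnot(length(trials) >= 1)
  done <- vapply(trials, function(tr) {
    need <- ceiling(complete_s * 1000 / tr$stride_ms)
    correct_ticks(tr) >= need
  }, logical(1))
  100 * mean(done)
}

#' Run the simulated real-time experiment
#'
#' Generates `n_trials` fresh 5-s streams for each of the 11 motion
#' classes (33 trials at defaults), runs the decision loop on each, and
#' aggregates per-class online accuracy and MCR.
#'
#' @param h A trained [hierarchical_classifier()].
#' @param profile The [subject_profile()] generating the streams.
#' @param n_trials Trials per motion class (default 3).
#' @param duration_s Trial length in seconds (default 5).
#' @param stride_ms Decision stride (default 90).
#' @param complete_s MCR completion requirement (default 1 s).
#' @return Object of class `realtime_report`: data frame with one row per
#'   motion class (`gesture`, `force`, `label`, `online_accuracy`, `mcr`,
#'   `n_trials`) plus the trial list as attribute `"trials"`.
#' @export
run_realtime_experiment <- function(h, profile, n_trials = 3L,
                                    duration_s = 5, stride_ms = 90,
                                    complete_s = 1.0) {
  classes <- motion_classes11()
  rows <- vector("list", nrow(classes))
  all_trials <- list()
  for (i in seq_len(nrow(classes))) {
    g <- classes$gesture[i]; f <- classes$force[i]
    trials <- lapply(seq_len(n_trials), function(t)
      simulate_stream(h, generate_stream(profile, g, f, duration_s,
                                         trial = t), stride_ms))
    all_trials <- c(all_trials, trials)
    rows[[i]] <- data.frame(
      gesture = g, force = f, label = motion_label(g, f),
      online_accuracy = mean(vapply(trials, online_accuracy, numeric(1))),
      mcr = mcr(trials, complete_s), n_trials = n_trials,
      stringsAsFactors = FALSE)
  }
  structure(do.call(rbind, rows), class = c("realtime_report",
                                            "data.frame"),
            trials = all_trials)
}
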