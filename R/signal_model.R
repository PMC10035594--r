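# Core data types for enveloped-EMG recordings, dataset assembly and I/O.

#' Motion-class vocabulary
#'
#' The seven hand/wrist gestures recognised by the first-stage classifier,
#' coded 1--7: rest, spherical, platform, point, tip, supination, pronation.
#' Spherical and tip are the two grasp classes; only they carry a force level.
#'
#' @return Named integer vector of the seven gesture codes.
#' @export
motion_classes <- function() {
  c(rest = 1L, spherical = 2L, platform = 3L, point = 4L,
    tip = 5L, supination = 6L, pronation = 7L)
}

#' @rdname motion_classes
#' @export
grasp_classes <- function() c("spherical", "tip")

#' Force-level vocabulary
#'
#' The three relative grasp-force levels, totally ordered low < medium < high.
#'
#' @return Character vector `c("low", "medium", "high")`.
#' @export
force_levels <- function() c("low", "medium", "high")

#' The 11 combined motion classes
#'
#' Five non-grasp gestures plus the two grasps crossed with the three force
#' levels: the class set used by the real-time protocol.
#'
#' @return Data frame with columns `gesture` and `force` (`NA` for non-grasp
#'   gestures); exactly 11 rows.
#' @export
motion_classes11 <- function() {
  g <- names(motion_classes())
  non_grasp <- setdiff(g, grasp_classes())
  rbind(
    data.frame(gesture = non_grasp, force = NA_character_,
               stringsAsFactors = FALSE),
    expand.grid(force = force_levels(), gesture = grasp_classes(),
                stringsAsFactors = FALSE)[, c("gesture", "force")]
  )
}

#' Canonical label for a (gesture, force) pair
#'
#' @param gesture Gesture name.
#' @param force Force-level name or `NA`.
#' @return Character label such as `"point"` or `"spherical/high"`.
#' @export
motion_label <- function(gesture, force = NA_character_) {
  ifelse(is.na(force), gesture, paste(gesture, force, sep = "/"))
}

.check_gesture <- function(label) {
  if (!label %in% names(motion_classes()))
    stop("unknown gesture label '", label, "'; valid labels: ",
         paste(names(motion_classes()), collapse = ", "), call. = FALSE)
  label
}

.check_force <- function(force) {
  if (!is.na(force) && !force %in% force_levels())
    stop("unknown force level '", force, "'; valid levels: ",
         paste(force_levels(), collapse = ", "), call. = FALSE)
  force
}

#' Construct an enveloped-EMG recording
#'
#' One labelled multi-channel hold of enveloped (rectified, low-passed,
#' hence nonnegative) surface-EMG amplitudes.
#'
#' @param samples Numeric matrix `[n_samples x n_channels]`, amplitudes >= 0
#'   in arbitrary sensor units.
#' @param fs Sampling rate in Hz (default 1000).
#' @param label Gesture name (one of [motion_classes()]).
#' @param force Force level for grasp holds, `NA` otherwise.
#' @param repetition Repetition index, >= 1.
#' @param subject_id Subject identifier.
#' @param n_channels Required channel count (default 6).
#' @return Object of class `emg_recording`.
#' @export
emg_recording <- function(samples, fs = 1000, label, force = NA_character_,
                          repetition = 1L, subject_id = "S1",
                          n_channels = 6L) {
  samples <- as.matrix(samples)
  if (ncol(samples) != n_channels)
    stop("expected ", n_channels, " channels, got ", ncol(samples),
         call. = FALSE)
  if (nrow(samples) < 1) stop("recording must contain >= 1 sample")
  if (any(samples < 0))
    stop("negative amplitude in envelope recording (first at row ",
         which(rowSums(samples < 0) > 0)[1], ")", call. = FALSE)
  .check_gesture(label)
  .check_force(force)
  if (!is.na(force) && !label %in% grasp_classes())
    stop("force level only applies to grasp classes (spherical, tip)")
  structure(
    list(samples = unname(samples), fs = fs, label = label, force = force,
         repetition = as.integer(repetition), subject_id = subject_id),
    class = "emg_recording")
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("<emg_recording> %s%s rep %d: %d x %d @ %g Hz (%s)\n",
              x$label, if (is.na(x$force)) "" else paste0("/", x$force),
              x$repetition, nrow(x$samples), ncol(x$samples), x$fs,
              x$subject_id))
  invisible(x)
}

#' Construct a dynamometer force recording
#'
#' One grip-force calibration trace (newtons) for a grasp held at a
#' perceived force level.
#'
#' @param trace Numeric vector of force values, >= 0 (N).
#' @param fs Sampling rate in Hz.
#' @param grasp `"spherical"` or `"tip"`.
#' @param perceived_level One of [force_levels()].
#' @param repetition Repetition index.
#' @return Object of class `force_recording`.
#' @export
force_recording <- function(trace, fs = 1000, grasp, perceived_level,
                            repetition = 1L) {
  if (!grasp %in% grasp_classes())
    stop("grasp must be one of: ", paste(grasp_classes(), collapse = ", "))
  stopifnot(perceived_level %in% force_levels(), all(trace >= 0))
  structure(
    list(trace = as.numeric(trace), fs = fs, grasp = grasp,
         perceived_level = perceived_level,
         repetition = as.integer(repetition)),
    class = "force_recording")
}

#' Assemble labelled recordings into a sample-wise dataset
#'
#' Retains the central contiguous `per_rep_keep` samples of each recording
#' (discarding onset/offset ramps) and stacks them row-wise in input order,
#' reproducing the protocol's per-class sample budget: 6 repetitions at 800
#' steady-state samples give 4,800 rows per class, 33,600 over 7 classes.
#'
#' @param recordings List of [emg_recording()] objects sharing fs and
#'   channel count.
#' @param per_rep_keep Samples kept per recording (central segment),
#'   default 800.
#' @param label_by `"gesture"` labels rows with the gesture; `"force"`
#'   labels them with the force level (for training force classifiers).
#' @return A `labeled_dataset`: list with `X` (numeric matrix), `y`
#'   (character labels), `feature_mode = "raw"`, and `meta` (one row per
#'   source recording: gesture, force, repetition, subject, start_row,
#'   n_rows).
#' @export
assemble_dataset <- function(recordings, per_rep_keep = 800,
                             label_by = c("gesture", "force")) {
  label_by <- match.arg(label_by)
  stopifnot(length(recordings) >= 1)
  nch <- vapply(recordings, function(r) ncol(r$samples), integer(1))
  if (length(unique(nch)) != 1)
    stop("mixed channel counts across recordings: ",
         paste(unique(nch), collapse = ", "))
  fs <- vapply(recordings, function(r) r$fs, numeric(1))
  if (length(unique(fs)) != 1)
    stop("mixed sampling rates across recordings")
  blocks <- vector("list", length(recordings))
  meta <- vector("list", length(recordings))
  row0 <- 0L
  for (i in seq_along(recordings)) {
    r <- recordings[[i]]
    n <- nrow(r$samples)
    if (n < per_rep_keep)
      stop("recording ", i, " (", motion_label(r$label, r$force), " rep ",
           r$repetition, ") has ", n, " samples, fewer than per_rep_keep = ",
           per_rep_keep, call. = FALSE)
    start <- floor((n - per_rep_keep) / 2) + 1L
    blocks[[i]] <- r$samples[start:(start + per_rep_keep - 1L), , drop = FALSE]
    y_i <- if (label_by == "gesture") r$label else {
      if (is.na(r$force))
        stop("recording ", i, " has no force label; cannot assemble by force")
      r$force
    }
    meta[[i]] <- data.frame(
      gesture = r$label, force = r$force, repetition = r$repetition,
      subject_id = r$subject_id, label = y_i,
      start_row = row0 + 1L, n_rows = per_rep_keep,
      stringsAsFactors = FALSE)
    row0 <- row0 + as.integer(per_rep_keep)
  }
  meta <- do.call(rbind, meta)
  structure(
    list(X = do.call(rbind, blocks),
         y = rep(meta$label, meta$n_rows),
         feature_mode = "raw", meta = meta),
    class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset> %d x %d (%s mode), classes: %s\n",
              nrow(x$X), ncol(x$X), x$feature_mode,
              paste(names(table(x$y)), collapse = ", ")))
  invisible(x)
}

.subset_dataset <- function(ds, idx) {
  out <- ds
  out$X <- ds$X[idx, , drop = FALSE]
  out$y <- ds$y[idx]
  out$meta <- NULL  # row-level provenance lost after shuffling
  out
}

#' Stratified train/test split
#'
#' Splits rows per class so every class contributes its `train_frac` share
#' (rounded to nearest, ties toward training) to the training part — the
#' "random shuffle with proper class proportions" two-way split. The 70/30
#' default applied to the 33,600-row session matrix yields 23,520 training
#' and 10,080 test rows.
#'
#' @param ds A `labeled_dataset` (raw rows or feature windows).
#' @param train_frac Training fraction in (0, 1), default 0.7.
#' @param seed Integer seed; the split is deterministic given the seed.
#' @return List with elements `train` and `test`, both `labeled_dataset`s.
#' @export
split_dataset <- function(ds, train_frac = 0.7, seed = 1L) {
  stopifnot(train_frac > 0, train_frac < 1)
  counts <- table(ds$y)
  if (any(counts < 2))
    stop("every class needs >= 2 rows; offending class(es): ",
         paste(names(counts)[counts < 2], collapse = ", "))
  idx_train <- integer(0)
  with_seed(seed, {
    for (cl in names(counts)) {
      rows <- which(ds$y == cl)
      n_tr <- floor(train_frac * length(rows) + 0.5)  # ties toward training
      rows <- sample(rows)
      idx_train <- c(idx_train, rows[seq_len(n_tr)])
    }
  })
  idx_train <- sort(idx_train)
  idx_test <- setdiff(seq_along(ds$y), idx_train)
  list(train = .subset_dataset(ds, idx_train),
       test = .subset_dataset(ds, idx_test))
}

#' Recording CSV + JSON sidecar I/O
#'
#' A recording is stored as a CSV of samples (columns `channel_1` ..
#' `channel_6`, one row per sample, dot decimal, 15 significant digits)
#' plus a JSON sidecar `<path>.json` holding fs, label, force, repetition
#' and subject. The round trip reproduces values bit-exactly at double
#' precision.
#'
#' @param rec An [emg_recording()].
#' @param path CSV path; sidecar written to `paste0(path, ".json")`.
#' @return `write_recording_csv` returns `path` invisibly;
#'   `read_recording_csv` returns an [emg_recording()].
#' @export
write_recording_csv <- function(rec, path) {
  df <- as.data.frame(rec$samples)
  names(df) <- paste0("channel_", seq_len(ncol(df)))
  utils::write.csv(format(df, digits = 17, scientific = TRUE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(fs = rec$fs, label = rec$label, force = rec$force,
         repetition = rec$repetition, subject_id = rec$subject_id),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, null = "null",
    na = "null")
  invisible(path)
}

#' @rdname write_recording_csv
#' @param n_channels Expected channel count.
#' @export
read_recording_csv <- function(path, n_channels = 6L) {
  df <- utils::read.csv(path, check.names = FALSE)
  want <- paste0("channel_", seq_len(n_channels))
  missing <- setdiff(want, names(df))
  if (length(missing) > 0 || ncol(df) != n_channels)
    stop("expected ", n_channels, " channels (columns ", want[1], "..",
         want[n_channels], "); file has: ",
         paste(names(df), collapse = ", "), call. = FALSE)
  X <- as.matrix(df[, want])
  bad <- which(rowSums(X < 0) > 0)
  if (length(bad) > 0)
    stop("negative amplitude at data row ", bad[1], call. = FALSE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  force <- if (is.null(side$force)) NA_character_ else side$force
  emg_recording(X, fs = side$fs, label = .check_gesture(side$label),
                force = .check_force(force),
                repetition = side$repetition, subject_id = side$subject_id,
                n_channels = n_channels)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed`, restoring the previous
#' RNG state afterwards so library calls do not perturb user randomness.
#'
#' @param seed Integer seed (kept below 2^31 by callers).
#' @param expr Expression to evaluate.
#' @return Value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

# Deterministic sub-seed derivation: fold a base seed and stream indices
# into [0, 2^31 - 1) so repeated generation is reproducible per item.
derive_seed <- function(seed, ...) {
  ix <- c(...)
  h <- as.double(seed) %% 2147483647
  for (v in ix) h <- (h * 48271 + as.double(v) + 1) %% 2147483647
  as.integer(h)
}
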