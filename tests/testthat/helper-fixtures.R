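# Shared fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

# Full default session at the acceptance profile (seed 7), cached.
default_session <- function() {
  if (is.null(.fixtures$session))
    .fixtures$session <- generate_session(subject_profile(seed = 7))
  .fixtures$session
}

# Small, fast session: 2 reps of 1.2-s holds; pair with per_rep_keep = 400.
small_session <- function(noise_cv = 0.2, seed = 11) {
  generate_session(subject_profile(noise_cv = noise_cv, seed = seed),
                   session_spec(n_reps = 2L, hold_s = 1.2))
}

noise_free_profile <- function(seed = 3)
  subject_profile(noise_cv = 0, rep_jitter = 0, seed = seed)

# A constant-amplitude recording (one value per channel).
const_recording <- function(amps, n = 1000, label = "rest",
                            force = NA_character_, repetition = 1L) {
  emg_recording(matrix(rep(amps, each = n), nrow = n), label = label,
                force = force, repetition = repetition)
}

# Build a labeled_dataset directly from a matrix and labels.
make_dataset <- function(X, y, feature_mode = "raw") {
  structure(list(X = as.matrix(X), y = y, feature_mode = feature_mode,
                 meta = NULL),
            class = c("labeled_dataset"))
}

# Two well-separated Gaussian blobs in 2-D.
blob_dataset <- function(n_per = 100, sd = 0.1, gap = 6 * 0.1, seed = 5) {
  with_seed(seed, {
    X <- rbind(cbind(rnorm(n_per, 0, sd), rnorm(n_per, 0, sd)),
               cbind(rnorm(n_per, gap, sd), rnorm(n_per, gap, sd)))
    make_dataset(X, rep(c("a", "b"), each = n_per))
  })
}

# A minimal trained hierarchical LDA classifier on a small near-noise-free
# session (cached): fast and perfectly separable. Noise is kept slightly
# positive so the pooled within-class covariance is invertible.
small_hierarchy <- function() {
  if (is.null(.fixtures$hier)) {
    sess <- generate_session(
      subject_profile(noise_cv = 0.01, rep_jitter = 0, seed = 3),
      session_spec(n_reps = 2L, hold_s = 1.2))
    .fixtures$hier <- train_hierarchical(sess, "lda", per_rep_keep = 400)
  }
  .fixtures$hier
}

# Hand-rolled realtime_trial for metric arithmetic tests.
fake_trial <- function(n_correct, n_total, target_gesture = "point",
                       target_force = NA_character_, stride_ms = 90) {
  gestures <- c(rep(target_gesture, n_correct),
                rep("rest", n_total - n_correct))
  if (target_gesture == "rest")
    gestures[seq_len(n_total - n_correct) + n_correct] <- "platform"
  structure(
    list(target_gesture = target_gesture, target_force = target_force,
         stride_ms = stride_ms, duration_s = 5,
         predictions = data.frame(
           time_s = seq_len(n_total) * stride_ms / 1000,
           gesture = gestures,
           force = ifelse(gestures %in% grasp_classes() &
                            gestures == target_gesture,
                          target_force, NA_character_),
           stringsAsFactors = FALSE)),
    class = "realtime_trial")
}
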