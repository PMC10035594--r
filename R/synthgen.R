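# Synthetic enveloped-sEMG session, calibration-trace and stream generation.
# Emulates the acquisition protocol (7 gestures x 6 reps x 3 s holds at
# 1 kHz; 3 force levels for the grasps; 3-s dynamometer calibration reps;
# 5-s real-time trials) so the full pipeline is testable without subjects.

#' Default gesture activation template
#'
#' Mean envelope amplitude per (gesture, channel) in arbitrary sensor
#' units. Each gesture is dominated by two or three of the six forearm
#' channels, mimicking distinct muscle synergies; rest is a low uniform
#' baseline. Users may supply their own matrix to [subject_profile()].
#'
#' @return 7 x 6 numeric matrix, rows named by gesture.
#' @export
default_activation <- function() {
  m <- rbind(
    rest       = c(0.5, 0.5, 0.5, 0.5, 0.5, 0.5),
    spherical  = c(8, 6, 4, 1, 1, 1),
    platform   = c(1, 1, 1, 6, 8, 4),
    point      = c(1, 6, 1, 1, 7, 2),
    tip        = c(6, 1, 1, 1, 1, 7),
    supination = c(1, 1, 7, 1, 1, 6),
    pronation  = c(3, 1, 1, 7, 1, 1))
  colnames(m) <- paste0("channel_", 1:6)
  m
}

#' Synthetic subject profile
#'
#' Parameters of the envelope model used by all generators: per-gesture
#' channel activations, force-level gain applied to grasp classes,
#' multiplicative envelope noise (coefficient of variation), and
#' repetition-to-repetition amplitude jitter.
#'
#' @param activation 7 x 6 matrix of mean envelope amplitudes (>= 0), rows
#'   in gesture-code order; rows must be pairwise distinct.
#' @param force_gain Named multipliers for low/medium/high grasp force;
#'   must be strictly increasing.
#' @param noise_cv Coefficient of variation of the multiplicative envelope
#'   noise (default 0.2).
#' @param rep_jitter Fractional repetition-to-repetition amplitude
#'   variation (default 0.1).
#' @param seed Base seed; every generated item derives its own sub-seed
#'   from it.
#' @param subject_id Identifier stamped on generated recordings.
#' @return Object of class `subject_profile`.
#' @export
subject_profile <- function(activation = default_activation(),
                            force_gain = c(low = 0.5, medium = 1.0,
                                           high = 1.9),
                            noise_cv = 0.2, rep_jitter = 0.08,
                            seed = 7L, subject_id = "SYN1") {
  activation <- as.matrix(activation)
  stopifnot(nrow(activation) == 7, ncol(activation) == 6,
            all(activation >= 0), noise_cv >= 0, rep_jitter >= 0,
            length(force_gain) == 3)
  if (any(duplicated(apply(activation, 1, paste, collapse = ","))))
    stop("activation rows must be pairwise distinct")
  if (is.null(names(force_gain))) names(force_gain) <- force_levels()
  force_gain <- force_gain[force_levels()]
  if (any(diff(force_gain) <= 0))
    stop("force_gain must be strictly increasing with level")
  dimnames(activation) <- list(names(motion_classes()),
                               paste0("channel_", 1:6))
  structure(list(activation = activation, force_gain = force_gain,
                 noise_cv = noise_cv, rep_jitter = rep_jitter,
                 seed = as.integer(seed), subject_id = subject_id),
            class = "subject_profile")
}

#' Session acquisition spec
#'
#' @param n_reps Repetitions per (gesture, level) combination, default 6.
#' @param hold_s Hold duration in seconds, default 3.
#' @param fs Sampling rate in Hz, default 1000.
#' @param grasp_levels Whether the grasps are repeated at all 3 force
#'   levels (default TRUE).
#' @return Object of class `session_spec`.
#' @export
session_spec <- function(n_reps = 6L, hold_s = 3, fs = 1000,
                         grasp_levels = TRUE) {
  stopifnot(n_reps >= 1, hold_s > 0, fs > 0)
  structure(list(n_reps = as.integer(n_reps), hold_s = hold_s, fs = fs,
                 grasp_levels = isTRUE(grasp_levels)),
            class = "session_spec")
}

# Smooth positive multiplicative noise with exact coefficient of variation:
# a moving-average-smoothed Gaussian field (50 ms kernel) is re-standardised,
# scaled to the log-normal sigma matching the requested CV and exponentiated,
# so the marginal mean is 1 and sd/mean equals cv.
envelope_noise <- function(n, cv, fs) {
  if (cv <= 0) return(rep(1, n))
  k <- max(1L, round(0.050 * fs))
  w <- stats::rnorm(n + k - 1)
  s <- as.numeric(stats::filter(w, rep(1 / k, k), sides = 1))[k:(n + k - 1)]
  s <- (s - mean(s)) / max(stats::sd(s), .Machine$double.eps)
  sigma <- sqrt(log(1 + cv^2))
  exp(sigma * s - sigma^2 / 2)
}

# One hold: plateau at level `amp` per channel, 200 ms linear on/off ramps,
# channel-independent smooth multiplicative noise, clipped at zero.
synth_hold <- function(amp, n, fs, cv, ramp_s = 0.2) {
  ramp <- rep(1, n)
  nr <- min(n, round(ramp_s * fs))
  if (nr > 0) {
    ramp[seq_len(nr)] <- seq(0, 1, length.out = nr)
    ramp[n - seq_len(nr) + 1] <- seq(0, 1, length.out = nr)
  }
  X <- sapply(seq_along(amp), function(ch)
    pmax(0, amp[ch] * ramp * envelope_noise(n, cv, fs)))
  matrix(X, nrow = n)
}

#' Generate a synthetic acquisition session
#'
#' One recording per (gesture, repetition) — and per force level for the
#' two grasp classes — following the training-step protocol: 3-s holds at
#' 1 kHz, six repetitions, grasps modulated over the three force levels.
#' With defaults this yields 5 non-grasp x 6 + 2 grasps x 3 levels x 6 =
#' 66 recordings. Deterministic given the profile seed.
#'
#' @param profile A [subject_profile()].
#' @param spec A [session_spec()].
#' @return List of [emg_recording()] objects.
#' @export
generate_session <- function(profile = subject_profile(),
                             spec = session_spec()) {
  n <- round(spec$hold_s * spec$fs)
  out <- list()
  for (g in names(motion_classes())) {
    levels_g <- if (g %in% grasp_classes() && spec$grasp_levels)
      force_levels() else NA_character_
    for (lv in levels_g) {
      gain <- if (is.na(lv)) 1 else profile$force_gain[[lv]]
      for (rep_i in seq_len(spec$n_reps)) {
        sd_seed <- derive_seed(profile$seed, motion_classes()[[g]],
                               match(lv, force_levels(), nomatch = 0L),
                               rep_i)
        rec <- with_seed(sd_seed, {
          rf <- exp(profile$rep_jitter * stats::rnorm(1) -
                      profile$rep_jitter^2 / 2)
          emg_recording(
            synth_hold(profile$activation[g, ] * gain * rf, n, spec$fs,
                       profile$noise_cv),
            fs = spec$fs, label = g, force = lv, repetition = rep_i,
            subject_id = profile$subject_id)
        })
        out[[length(out) + 1L]] <- rec
      }
    }
  }
  out
}

#' Generate dynamometer calibration traces
#'
#' Grip-force traces for one grasp at one perceived level: a plateau whose
#' mean is proportional to the profile's force gain for that level, with
#' the same smooth multiplicative noise; three 3-s repetitions by default.
#'
#' @param profile A [subject_profile()].
#' @param grasp `"spherical"` or `"tip"`.
#' @param level One of [force_levels()].
#' @param n_reps Repetitions (default 3).
#' @param hold_s Trace duration in seconds (default 3).
#' @param fs Sampling rate in Hz.
#' @param base_force_n Force (N) corresponding to unit gain; default 20 N
#'   puts the three plateaus at 12/20/30 N.
#' @return List of [force_recording()] objects.
#' @export
generate_force_calibration <- function(profile = subject_profile(), grasp,
                                       level, n_reps = 3L, hold_s = 3,
                                       fs = 1000, base_force_n = 20) {
  if (!grasp %in% grasp_classes())
    stop("calibration is defined for grasp classes only (spherical, tip)")
  stopifnot(level %in% force_levels())
  n <- round(hold_s * fs)
  lapply(seq_len(n_reps), function(rep_i) {
    sd_seed <- derive_seed(profile$seed, 1000L,
                           match(grasp, grasp_classes()),
                           match(level, force_levels()), rep_i)
    with_seed(sd_seed, {
      rf <- exp(profile$rep_jitter * stats::rnorm(1) -
                  profile$rep_jitter^2 / 2)
      force_recording(
        pmax(0, base_force_n * profile$force_gain[[level]] * rf *
               envelope_noise(n, profile$noise_cv, fs)),
        fs = fs, grasp = grasp, perceived_level = level,
        repetition = rep_i)
    })
  })
}

#' Generate a continuous real-time trial stream
#'
#' A steady 5-s labelled stream of one of the 11 motion classes under the
#' same envelope-noise model (no onset ramp: the trial captures a
#' maintained contraction), for the simulated real-time decision loop.
#'
#' @param profile A [subject_profile()].
#' @param gesture Target gesture name.
#' @param force Target force level (required iff gesture is a grasp).
#' @param duration_s Stream length in seconds (default 5).
#' @param fs Sampling rate in Hz.
#' @param trial Trial index, folded into the derived seed.
#' @return An [emg_recording()] of `duration_s * fs` samples.
#' @export
generate_stream <- function(profile = subject_profile(), gesture,
                            force = NA_character_, duration_s = 5,
                            fs = 1000, trial = 1L) {
  .check_gesture(gesture)
  is_grasp <- gesture %in% grasp_classes()
  if (is_grasp && is.na(force))
    stop("grasp stream requires a force level")
  if (!is_grasp && !is.na(force))
    stop("non-grasp stream cannot carry a force level")
  n <- round(duration_s * fs)
  gain <- if (is_grasp) profile$force_gain[[force]] else 1
  sd_seed <- derive_seed(profile$seed, 2000L, motion_classes()[[gesture]],
                         match(force, force_levels(), nomatch = 0L), trial)
  with_seed(sd_seed, {
    rf <- exp(profile$rep_jitter * stats::rnorm(1) -
                profile$rep_jitter^2 / 2)
    emg_recording(
      synth_hold(profile$activation[gesture, ] * gain * rf, n, fs,
                 profile$noise_cv, ramp_s = 0),
      fs = fs, label = gesture, force = if (is_grasp) force else NA_character_,
      repetition = as.integer(trial), subject_id = profile$subject_id)
  })
}

#' Profile JSON round trip
#'
#' @param profile A [subject_profile()].
#' @param path JSON file path.
#' @return `write_profile_json` returns `path` invisibly;
#'   `read_profile_json` returns a [subject_profile()].
#' @export
write_profile_json <- function(profile, path) {
  jsonlite::write_json(
    list(activation = profile$activation, force_gain = as.list(profile$force_gain),
         noise_cv = profile$noise_cv, rep_jitter = profile$rep_jitter,
         seed = profile$seed, subject_id = profile$subject_id),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_profile_json
#' @export
read_profile_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  subject_profile(activation = j$activation,
                  force_gain = unlist(j$force_gain),
                  noise_cv = j$noise_cv, rep_jitter = j$rep_jitter,
                  seed = j$seed, subject_id = j$subject_id)
}
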