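# Gesture-to-force cascade, dynamometer force-threshold calibration and
# prosthesis command mapping.

#' Assemble a hierarchical classifier
#'
#' First-stage 7-gesture classifier plus two second-stage 3-level force
#' classifiers; the force stage runs only when the gesture stage outputs
#' the matching grasp class. All three share one window/feature
#' configuration.
#'
#' @param gesture_clf Classifier over the 7 gestures (`logistic_model` or
#'   `lda_model`).
#' @param spherical_force_clf 3-level classifier for the spherical grasp.
#' @param tip_force_clf 3-level classifier for the tip grasp.
#' @param feature_cfg A [window_config()].
#' @param feature_mode `"extracted"` (30 window features) or `"raw"`
#'   (per-channel window means feed the classifiers directly).
#' @return Object of class `hierarchical_classifier`.
#' @export
hierarchical_classifier <- function(gesture_clf, spherical_force_clf,
                                    tip_force_clf,
                                    feature_cfg = window_config(),
                                    feature_mode = c("extracted", "raw")) {
  feature_mode <- match.arg(feature_mode)
  stopifnot(setequal(gesture_clf$class_set, names(motion_classes())),
            setequal(spherical_force_clf$class_set, force_levels()),
            setequal(tip_force_clf$class_set, force_levels()))
  structure(list(gesture_clf = gesture_clf,
                 spherical_force_clf = spherical_force_clf,
                 tip_force_clf = tip_force_clf,
                 feature_cfg = feature_cfg, feature_mode = feature_mode),
            class = "hierarchical_classifier")
}

# Feature vector of one analysis window under the classifier's mode.
window_vector <- function(h, window, dead_zone = 0) {
  if (h$feature_mode == "extracted") window_features(window, dead_zone)
  else colMeans(window)
}

#' Hierarchical prediction for one analysis window
#'
#' Runs the gesture classifier first; if (and only if) its output is
#' spherical or tip, the matching force classifier evaluates the same
#' feature vector and its level is attached. The two stages are evaluated
#' sequentially on the same window, which is what "simultaneous" gesture
#' and force output means at the decision stride.
#'
#' @param h A [hierarchical_classifier()].
#' @param window Numeric matrix `[win x 6]` of envelope samples.
#' @return List with `gesture` and `force` (`NA` unless a grasp).
#' @export
predict_hierarchical <- function(h, window) {
  v <- window_vector(h, window)
  g <- predict_class(h$gesture_clf, v)
  force <- NA_character_
  if (g == "spherical") force <- predict_class(h$spherical_force_clf, v)
  else if (g == "tip") force <- predict_class(h$tip_force_clf, v)
  list(gesture = g, force = force)
}

.force_bands <- function(L, M, H, f_max, grasp) {
  if (!(L < M && M < H))
    stop("non-monotone force thresholds for ", grasp, ": low = ",
         signif(L, 4), ", medium = ", signif(M, 4), ", high = ",
         signif(H, 4), call. = FALSE)
  if (H > f_max)
    stop("high threshold exceeds maximum observed force for ", grasp)
  if (1.1 * L > 0.9 * M)
    warning("low and medium force bands overlap for ", grasp,
            " ([", signif(0.9 * L, 4), ", ", signif(1.1 * L, 4), "] vs [",
            signif(0.9 * M, 4), ", ", signif(1.1 * M, 4), "])")
  structure(list(grasp = grasp, L = L, M = M, H = H, f_max = f_max,
                 bands = list(low = c(0.9 * L, 1.1 * L),
                              medium = c(0.9 * M, 1.1 * M),
                              high = c(0.9 * H, f_max))),
            class = "force_thresholds")
}

#' Calibrate force thresholds from perceived-force dynamometer traces
#'
#' The perceived-force method: the subject grips at self-selected low,
#' medium and high intensities; each level's threshold is the mean of the
#' per-repetition plateau means (plateau = central 80\% of each trace).
#' Bands follow the +/-10\% rule — low `[0.9L, 1.1L]`, medium
#' `[0.9M, 1.1M]`, high from `0.9H` up to the maximum observed force.
#' Non-monotone thresholds are a calibration error.
#'
#' @param recs List of [force_recording()]s for one grasp covering all
#'   three levels (>= 1 repetition each).
#' @param grasp `"spherical"` or `"tip"` (checked against the recordings).
#' @return Object of class `force_thresholds` with `L`, `M`, `H`, `f_max`
#'   and the three `bands`.
#' @export
calibrate_thresholds <- function(recs, grasp) {
  stopifnot(all(vapply(recs, inherits, logical(1), "force_recording")))
  if (!all(vapply(recs, `[[`, character(1), "grasp") == grasp))
    stop("recordings mix grasps; expected all '", grasp, "'")
  lv <- vapply(recs, `[[`, character(1), "perceived_level")
  if (!setequal(unique(lv), force_levels()))
    stop("calibration needs recordings at all three levels; got: ",
         paste(sort(unique(lv)), collapse = ", "))
  plateau_mean <- function(r) {
    n <- length(r$trace)
    lo <- floor(0.1 * n) + 1L
    hi <- ceiling(0.9 * n)
    mean(r$trace[lo:hi])
  }
  m <- vapply(force_levels(), function(l)
    mean(vapply(recs[lv == l], plateau_mean, numeric(1))), numeric(1))
  f_max <- max(vapply(recs, function(r) max(r$trace), numeric(1)))
  .force_bands(m[["low"]], m[["medium"]], m[["high"]], f_max, grasp)
}

#' Maximum-force-fraction thresholds
#'
#' The alternative calibration: thresholds at 30, 60 and 90\% of the
#' maximum voluntary force, with the same +/-10\% band construction.
#' Provided for completeness; the perceived-force calibration
#' ([calibrate_thresholds()]) proved more natural and repeatable and is
#' the default route.
#'
#' @param f_max Maximum voluntary contraction force (N), > 0.
#' @param grasp Grasp name the thresholds apply to.
#' @return Object of class `force_thresholds`.
#' @export
method1_thresholds <- function(f_max, grasp = "spherical") {
  if (f_max <= 0) stop("f_max must be positive")
  .force_bands(0.30 * f_max, 0.60 * f_max, 0.90 * f_max, f_max, grasp)
}

#' @export
print.force_thresholds <- function(x, ...) {
  cat(sprintf("<force_thresholds> %s: L/M/H = %.3g/%.3g/%.3g N, f_max = %.3g N\n",
              x$grasp, x$L, x$M, x$H, x$f_max))
  for (l in names(x$bands))
    cat(sprintf("  %-6s [%.3g, %.3g] N\n", l, x$bands[[l]][1],
                x$bands[[l]][2]))
  invisible(x)
}

# PWM duty cycles commanding the prosthetic hand closing speed, and the
# grip forces (N) they were measured to produce.
.force_pwm <- c(low = 25, medium = 50, high = 75)
.force_newtons <- c(low = 7.5, medium = 15, high = 30)

#' Map a hierarchical prediction to a prosthesis command
#'
#' Grasp predictions command a hand close (power grip for spherical, pinch
#' for tip) at PWM 25/50/75\% for low/medium/high force — duty cycles
#' producing roughly 7.5, 15 and 30 N of grip force. Platform and point
#' command the hand at a fixed 50\% PWM, supination/pronation the wrist
#' rotator at 50\%, and rest is the null command.
#'
#' @param gesture Predicted gesture name.
#' @param force Predicted force level (`NA` unless a grasp).
#' @return Object of class `prosthesis_command` with `dof`, `action`,
#'   `pwm` and `force_n` (nominal grip force, grasps only).
#' @export
map_to_command <- function(gesture, force = NA_character_) {
  .check_gesture(gesture)
  if (gesture %in% grasp_classes() && is.na(force))
    stop("grasp prediction requires a force level")
  cmd <- switch(gesture,
    rest = list(dof = NA_character_, action = "none", pwm = NA_real_,
                force_n = NA_real_),
    spherical = list(dof = "hand", action = "close_power",
                     pwm = .force_pwm[[force]],
                     force_n = .force_newtons[[force]]),
    tip = list(dof = "hand", action = "close_pinch",
               pwm = .force_pwm[[force]],
               force_n = .force_newtons[[force]]),
    platform = list(dof = "hand", action = "open", pwm = 50,
                    force_n = NA_real_),
    point = list(dof = "hand", action = "point", pwm = 50,
                 force_n = NA_real_),
    supination = list(dof = "wrist", action = "supinate", pwm = 50,
                      force_n = NA_real_),
    pronation = list(dof = "wrist", action = "pronate", pwm = 50,
                     force_n = NA_real_))
  structure(cmd, class = "prosthesis_command")
}

#' @export
print.prosthesis_command <- function(x, ...) {
  if (x$action == "none") cat("<prosthesis_command> null (rest)\n")
  else cat(sprintf("<prosthesis_command> %s %s @ PWM %g%%%s\n", x$dof,
                   x$action, x$pwm,
                   if (is.na(x$force_n)) "" else
                     sprintf(" (~%g N)", x$force_n)))
  invisible(x)
}

#' Force-threshold JSON round trip
#'
#' @param ft A `force_thresholds` object.
#' @param path JSON file path.
#' @return `write_thresholds_json` returns `path` invisibly;
#'   `read_thresholds_json` the object.
#' @export
write_thresholds_json <- function(ft, path) {
  jsonlite::write_json(unclass(ft), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_thresholds_json
#' @export
read_thresholds_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  .force_bands(j$L, j$M, j$H, j$f_max, j$grasp)
}
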