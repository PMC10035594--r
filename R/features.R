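# Sliding-window segmentation and the five time-domain features:
# enhanced mean absolute value (EMAV), enhanced wavelength (EWL),
# slope sign change (SSC), root mean square (RMS) and variance (VAR).

#' Analysis-window configuration
#'
#' Sliding windows of `win_ms` with `overlap_ms` shared between consecutive
#' windows, i.e. a step of `win_ms - overlap_ms` (150/50 ms by default,
#' step 100 ms).
#'
#' @param win_ms Window length in milliseconds (default 150).
#' @param overlap_ms Overlap between consecutive windows in ms (default 50).
#' @param fs Sampling rate in Hz (default 1000).
#' @return Object of class `window_config` with derived `win`, `step`
#'   (samples).
#' @export
window_config <- function(win_ms = 150, overlap_ms = 50, fs = 1000) {
  stopifnot(overlap_ms >= 0, overlap_ms < win_ms, fs > 0)
  win <- round(win_ms * fs / 1000)
  step <- round((win_ms - overlap_ms) * fs / 1000)
  structure(list(win_ms = win_ms, overlap_ms = overlap_ms, fs = fs,
                 win = as.integer(win), step = as.integer(step)),
            class = "window_config")
}

#' Segment a recording into analysis windows
#'
#' Windows start at multiples of the step; a trailing partial window is
#' discarded. A 4,800-sample class block at 150/50 ms yields 47 windows.
#'
#' @param x An [emg_recording()] or a numeric matrix `[n x channels]`.
#' @param cfg A [window_config()].
#' @return List of `win x channels` matrices.
#' @export
segment_windows <- function(x, cfg = window_config()) {
  X <- if (inherits(x, "emg_recording")) x$samples else as.matrix(x)
  n <- nrow(X)
  if (n < cfg$win)
    stop("recording of ", n, " samples is shorter than one window (",
         cfg$win, " samples)")
  starts <- seq(1L, n - cfg$win + 1L, by = cfg$step)
  lapply(starts, function(s) X[s:(s + cfg$win - 1L), , drop = FALSE])
}

# Position-dependent amplitude exponent shared by EMAV and EWL: samples in
# the central 60% of the window (0.2N <= i <= 0.8N, 1-based) are raised to
# 0.75, the tails to 0.5, de-emphasising window-edge transients.
p_rule <- function(n) {
  i <- seq_len(n)
  ifelse(i >= 0.2 * n & i <= 0.8 * n, 0.75, 0.5)
}

#' Time-domain window features
#'
#' The five per-channel descriptors computed on each analysis window:
#' \describe{
#'   \item{`feat_emav`}{enhanced mean absolute value,
#'     \eqn{\frac{1}{N}\sum_i |x_i|^{p(i)}} with the positional exponent
#'     `p(i)` of 0.75 in the central 60\% of the window and 0.5 at the
#'     edges.}
#'   \item{`feat_ewl`}{enhanced wavelength,
#'     \eqn{\sum_{i=2}^{N} |x_i - x_{i-1}|^{p(i)}}, same exponent rule.}
#'   \item{`feat_ssc`}{slope-sign-change count: interior samples where
#'     \eqn{(x_i - x_{i-1})(x_i - x_{i+1})} exceeds the dead-zone
#'     threshold (strictly positive when `dead_zone = 0`).}
#'   \item{`feat_rms`}{root mean square.}
#'   \item{`feat_var`}{sample variance (mean-subtracted, N-1 denominator).}
#' }
#'
#' @param x Numeric vector: one channel of one window.
#' @param dead_zone SSC dead-zone threshold, >= 0 (default 0).
#' @return Scalar feature value.
#' @export
feat_emav <- function(x) {
  n <- length(x)
  if (n < 1) stop("empty window")
  mean(abs(x)^p_rule(n))
}

#' @rdname feat_emav
#' @export
feat_ewl <- function(x) {
  n <- length(x)
  if (n < 2) stop("EWL needs >= 2 samples")
  sum(abs(diff(x))^p_rule(n)[-1])
}

#' @rdname feat_emav
#' @export
feat_ssc <- function(x, dead_zone = 0) {
  n <- length(x)
  if (n < 3) stop("SSC needs >= 3 samples")
  stopifnot(dead_zone >= 0)
  i <- 2:(n - 1)
  f <- (x[i] - x[i - 1]) * (x[i] - x[i + 1])
  if (dead_zone > 0) sum(f >= dead_zone) else sum(f > 0)
}

#' @rdname feat_emav
#' @export
feat_rms <- function(x) {
  if (length(x) < 1) stop("empty window")
  sqrt(mean(x^2))
}

#' @rdname feat_emav
#' @export
feat_var <- function(x) {
  if (length(x) < 2) stop("variance needs >= 2 samples")
  stats::var(x)
}

#' Names of the feature-table columns
#'
#' Fixed column order: the five features for channel 1, then channel 2, ...
#'
#' @param n_channels Channel count (default 6).
#' @return Character vector of length `5 * n_channels`.
#' @export
feature_names <- function(n_channels = 6L) {
  as.vector(vapply(seq_len(n_channels), function(ch)
    paste0(c("emav", "ewl", "ssc", "rms", "var"), "_ch", ch),
    character(5)))
}

window_features <- function(w, dead_zone = 0) {
  as.vector(apply(w, 2, function(x)
    c(feat_emav(x), feat_ewl(x), feat_ssc(x, dead_zone),
      feat_rms(x), feat_var(x))))
}

#' Build a feature table from recordings or a raw dataset
#'
#' Segments the input into analysis windows and computes the 30-column
#' feature matrix (5 features x 6 channels, fixed order). A raw
#' `labeled_dataset` is windowed per contiguous same-label block, matching
#' the session matrix layout where each class contributes one 4,800-row
#' block (47 windows at defaults); a list of recordings is windowed per
#' recording. Window labels are inherited from the source block.
#'
#' @param x List of [emg_recording()]s or a raw `labeled_dataset`.
#' @param cfg A [window_config()].
#' @param dead_zone SSC dead-zone threshold.
#' @return A `labeled_dataset` with `feature_mode = "extracted"`, `X` of
#'   `n_windows x 30`, and `y` of window labels.
#' @export
featurize <- function(x, cfg = window_config(), dead_zone = 0) {
  if (inherits(x, "labeled_dataset")) {
    if (x$feature_mode != "raw") stop("dataset is already featurized")
    runs <- rle(x$y)
    stops <- cumsum(runs$lengths)
    starts <- c(1L, utils::head(stops, -1) + 1L)
    blocks <- lapply(seq_along(starts), function(i)
      x$X[starts[i]:stops[i], , drop = FALSE])
    labels <- runs$values
  } else {
    stopifnot(is.list(x), all(vapply(x, inherits, logical(1),
                                     "emg_recording")))
    blocks <- lapply(x, `[[`, "samples")
    labels <- vapply(x, `[[`, character(1), "label")
  }
  rows <- list(); y <- character(0)
  for (i in seq_along(blocks)) {
    ws <- segment_windows(blocks[[i]], cfg)
    rows[[i]] <- t(vapply(ws, window_features, numeric(5 * ncol(blocks[[i]])),
                          dead_zone = dead_zone))
    y <- c(y, rep(labels[i], length(ws)))
  }
  X <- do.call(rbind, rows)
  colnames(X) <- feature_names(ncol(blocks[[1]]))
  structure(list(X = X, y = y, feature_mode = "extracted", meta = NULL),
            class = "labeled_dataset")
}

#' Column z-score normalisation
#'
#' `fit_norm` estimates per-column mean and sd on training data;
#' `apply_norm` standardises any later matrix with those parameters.
#' Constant columns (sd 0, e.g. variance features of a noise-free
#' fixture) keep sd 1 so they pass through centred but unscaled.
#'
#' @param X Numeric matrix (or `labeled_dataset`, whose `X` is used).
#' @return `fit_norm`: list with `mean` and `sd` vectors. `apply_norm`:
#'   matrix (or dataset) of the same shape, standardised.
#' @export
fit_norm <- function(X) {
  if (inherits(X, "labeled_dataset")) X <- X$X
  m <- colMeans(X)
  s <- apply(X, 2, stats::sd)
  s[s == 0 | !is.finite(s)] <- 1
  list(mean = m, sd = s)
}

#' @rdname fit_norm
#' @param norm A fit from `fit_norm`.
#' @export
apply_norm <- function(X, norm) {
  if (inherits(X, "labeled_dataset")) {
    X$X <- apply_norm(X$X, norm)
    return(X)
  }
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  sweep(sweep(X, 2, norm$mean, "-"), 2, norm$sd, "/")
}
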