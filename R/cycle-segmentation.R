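# Gait-cycle division from the periodicity of the silhouette's
# width-to-height ratio.  A person's height is nearly constant while walking
# and the width swings with the legs, so the ratio of the tight bounding
# rectangle oscillates with two troughs (legs-together poses) per gait cycle;
# three consecutive troughs span one full cycle.

#' Extract the silhouette contour with the Sobel operator
#'
#' Computes the Sobel gradient magnitude and keeps pixels where it is
#' positive, intersected with the foreground so a filled region yields its
#' one-pixel inner boundary ring.
#'
#' @param frame a binary [silhouette_frame()].
#' @return A binary matrix (0/255) marking contour pixels; empty frames give
#'   an empty edge map.
#' @export
contour_extract <- function(frame) {
  m <- unclass(frame) / 255
  if (!any(m > 0)) return(matrix(0, nrow(m), ncol(m)))
  H <- nrow(m); W <- ncol(m)
  pad <- matrix(0, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- m
  sh <- function(di, dj) pad[(1:H) + 1 + di, (1:W) + 1 + dj]
  gx <- -sh(-1, -1) - 2 * sh(0, -1) - sh(1, -1) +
         sh(-1,  1) + 2 * sh(0,  1) + sh(1,  1)
  gy <- -sh(-1, -1) - 2 * sh(-1, 0) - sh(-1, 1) +
         sh( 1, -1) + 2 * sh( 1, 0) + sh( 1, 1)
  mag <- sqrt(gx^2 + gy^2)
  matrix(255 * as.numeric(mag > 0 & m > 0), H, W)
}

#' Width-to-height ratio series of a silhouette sequence
#'
#' Per frame, the ratio of the tight bounding rectangle (width / height) of
#' the silhouette contour; frames with empty foreground are recorded as
#' missing and linearly interpolated from their neighbours.  The series is
#' smoothed by a centered moving average.
#'
#' @param seq a [silhouette_sequence()] of binary frames.
#' @param smooth_window odd window length (frames) of the moving average.
#' @return An `aspect_ratio_series` list with `values` (raw ratios) and
#'   `smoothed`.
#' @export
aspect_ratio_series <- function(seq, smooth_window = 3) {
  if (length(seq$frames) < 2L) stop("need at least 2 frames")
  if (smooth_window %% 2 == 0) stop("smooth_window must be odd")
  vals <- vapply(seq$frames, function(f) {
    bb <- fg_bbox(unclass(f))
    if (is.null(bb)) return(NA_real_)
    (bb$c1 - bb$c0 + 1) / (bb$r1 - bb$r0 + 1)
  }, numeric(1))
  if (anyNA(vals)) {
    ok <- which(!is.na(vals))
    if (length(ok) < 2L) stop("too few frames with foreground")
    vals <- approx(ok, vals[ok], xout = seq_along(vals), rule = 2)$y
  }
  smoothed <- vals
  if (smooth_window > 1 && length(vals) >= smooth_window) {
    k <- rep(1 / smooth_window, smooth_window)
    sm <- stats::filter(vals, k, sides = 2)
    # shrink the window near the edges instead of dropping to NA
    half <- (smooth_window - 1) / 2
    for (i in seq_along(vals)) {
      if (is.na(sm[i])) {
        w <- min(i - 1, length(vals) - i, half)
        sm[i] <- mean(vals[(i - w):(i + w)])
      }
    }
    smoothed <- as.numeric(sm)
  }
  structure(list(values = vals, smoothed = smoothed),
            class = "aspect_ratio_series")
}

# topographic prominence of a local minimum at index i: the smaller of the
# climbs to the highest point reached before descending below series[i] on
# each side (boundary = climb available on that side)
.trough_prominence <- function(series, i) {
  n <- length(series)
  climb <- function(idx) {
    best <- 0
    for (j in idx) {
      if (series[j] < series[i]) break
      best <- max(best, series[j] - series[i])
    }
    best
  }
  left  <- if (i > 1) climb((i - 1):1) else Inf
  right <- if (i < n) climb((i + 1):n) else Inf
  min(left, right)
}

#' Detect troughs of the aspect-ratio series
#'
#' Finds local minima of the smoothed series with at least the given
#' topographic prominence, keeping the deepest minima under the pairwise
#' separation constraint.  The first/last sample also counts as a trough when
#' the series rises away from it with sufficient prominence, which captures
#' legs-together poses truncated at the ends of a recording.
#'
#' @param series an [aspect_ratio_series()] (or a plain numeric vector).
#' @param min_separation minimum index distance between accepted troughs.
#' @param prominence minimum prominence (ratio units) of a trough.
#' @return Increasing integer vector of trough frame indices (1-based).
#'   Errors if fewer than 3 troughs are found (no full cycle).
#' @export
detect_troughs <- function(series, min_separation = 5, prominence = 0.01) {
  s <- if (inherits(series, "aspect_ratio_series")) series$smoothed else as.numeric(series)
  n <- length(s)
  if (n < 3L) stop("sequence too short for one full cycle")
  # group consecutive equal values into plateaus; a plateau is a trough when
  # the series is strictly higher on both sides (image boundary counts as
  # higher: a legs-together pose truncated at either end of the recording)
  grp_end <- which(c(s[-1] != s[-n], TRUE))
  grp_start <- c(1L, head(grp_end, -1L) + 1L)
  cand <- integer(0)
  for (g in seq_along(grp_start)) {
    l <- grp_start[g]; r <- grp_end[g]
    lower_left  <- l == 1L || s[l - 1L] > s[l]
    lower_right <- r == n  || s[r + 1L] > s[r]
    if (lower_left && lower_right) {
      cand <- c(cand, l + (r - l) %/% 2L)  # plateau center
    }
  }
  if (length(cand) > 0) {
    prom <- vapply(cand, function(i) .trough_prominence(s, i), numeric(1))
    cand <- cand[prom >= prominence]
    # greedy: accept deepest first, enforce pairwise separation
    ord <- cand[order(s[cand])]
    kept <- integer(0)
    for (i in ord) {
      if (all(abs(kept - i) >= min_separation)) kept <- c(kept, i)
    }
    cand <- sort(kept)
  }
  if (length(cand) < 3L) {
    stop("sequence too short for one full cycle: fewer than 3 troughs found")
  }
  cand
}

#' Split a sequence into full gait cycles
#'
#' Two adjacent troughs delimit half a gait cycle, so cycle *k* spans troughs
#' `2k-1 .. 2k+1` (1-based).  The shared boundary frame belongs to both
#' neighbouring cycles; trailing partial half-cycles are discarded.
#'
#' @param seq a [silhouette_sequence()].
#' @param troughs increasing trough indices from [detect_troughs()].
#' @return List of `gait_cycle` objects with `start_frame`, `end_frame`
#'   (inclusive), and `frames`.
#' @export
segment_cycles <- function(seq, troughs) {
  if (length(troughs) < 3L) stop("need at least 3 troughs for one full cycle")
  n_cycles <- (length(troughs) - 1L) %/% 2L
  lapply(seq_len(n_cycles), function(k) {
    s <- troughs[2L * k - 1L]
    e <- troughs[2L * k + 1L]
    structure(list(start_frame = s, end_frame = e,
                   frames = seq$frames[s:e]),
              class = "gait_cycle")
  })
}

#' @export
print.gait_cycle <- function(x, ...) {
  cat(sprintf("<gait_cycle: frames %d..%d (%d frames)>\n",
              x$start_frame, x$end_frame, length(x$frames)))
  invisible(x)
}

#' Detect and segment gait cycles of a sequence in one call
#'
#' @param seq a [silhouette_sequence()] of binary frames.
#' @param smooth_window,min_separation,prominence see
#'   [aspect_ratio_series()] and [detect_troughs()].
#' @return List with `series`, `troughs`, and `cycles`.
#' @export
find_gait_cycles <- function(seq, smooth_window = 3, min_separation = 5,
                             prominence = 0.01) {
  series <- aspect_ratio_series(seq, smooth_window)
  troughs <- detect_troughs(series, min_separation, prominence)
  list(series = series, troughs = troughs,
       cycles = segment_cycles(seq, troughs))
}
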