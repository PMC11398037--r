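# The three classical energy templates computed per gait cycle.
#
# GEI  = per-pixel temporal mean of the binary silhouettes (static + dynamic).
# GEnI = min-max-scaled per-pixel Shannon entropy of foreground occupancy
#        (dynamic limbs bright, static torso zero).
# AEI  = mean absolute difference of consecutive frames (pure motion).
#
# Frames encode foreground as 255, so the GEI mean lands directly in
# [0, 255]; the entropy uses occupancy probabilities and is encoding-free.

.cycle_frames_list <- function(cycle) {
  frames <- if (inherits(cycle, "gait_cycle")) cycle$frames else cycle
  if (length(frames) < 2L) stop("a cycle needs at least 2 frames")
  dims <- vapply(frames, dim, integer(2))
  if (any(dims != dims[, 1])) stop("mixed frame sizes in cycle")
  lapply(frames, unclass)
}

#' Gait energy image (GEI)
#'
#' Per-pixel average of the cycle's binary silhouettes.
#'
#' @param cycle a `gait_cycle` or list of binary 0/255 frames.
#' @return An [energy_image()] of kind `"GEI"`.
#' @export
compute_gei <- function(cycle) {
  frames <- .cycle_frames_list(cycle)
  energy_image(Reduce(`+`, frames) / length(frames), kind = "GEI")
}

#' Per-pixel Shannon entropy of foreground occupancy
#'
#' For binary silhouettes each pixel is a two-state source (K = 2):
#' `p1` = fraction of frames in which the pixel is foreground,
#' `H = -p0 log2 p0 - p1 log2 p1` with `0 log2 0 := 0`, so `H` lies in
#' \[0, 1\] bits.
#'
#' @param cycle a `gait_cycle` or list of binary frames.
#' @return An `entropy_field` list with `values` (matrix of bits), `h_min`,
#'   `h_max`.
#' @export
compute_entropy_field <- function(cycle) {
  frames <- .cycle_frames_list(cycle)
  p1 <- Reduce(`+`, lapply(frames, function(f) f > 0)) / length(frames)
  plogp <- function(p) ifelse(p > 0, p * log2(p), 0)
  H <- -(plogp(p1) + plogp(1 - p1))
  structure(list(values = H, h_min = min(H), h_max = max(H)),
            class = "entropy_field")
}

#' Gait entropy image (GEnI)
#'
#' Min-max scaling of the per-pixel entropy to \[0, 255\].  If the entropy
#' field is constant (e.g. all frames identical) the image is all zeros and a
#' warning is raised.
#'
#' @param cycle a `gait_cycle` or list of binary frames.
#' @return An [energy_image()] of kind `"GEnI"`.
#' @export
compute_geni <- function(cycle) {
  ef <- compute_entropy_field(cycle)
  if (ef$h_max - ef$h_min < .Machine$double.eps) {
    warning("degenerate entropy field: all pixels have equal entropy")
    return(energy_image(matrix(0, nrow(ef$values), ncol(ef$values)), kind = "GEnI"))
  }
  energy_image((ef$values - ef$h_min) * 255 / (ef$h_max - ef$h_min), kind = "GEnI")
}

#' Active energy image (AEI)
#'
#' Mean absolute difference between consecutive binary frames, normalized by
#' the number of frame pairs so a fully alternating pixel reaches 255; static
#' pixels are 0.
#'
#' @param cycle a `gait_cycle` or list of >= 2 binary frames.
#' @return An [energy_image()] of kind `"AEI"`.
#' @export
compute_aei <- function(cycle) {
  frames <- .cycle_frames_list(cycle)
  n <- length(frames)
  acc <- matrix(0, nrow(frames[[1]]), ncol(frames[[1]]))
  for (t in 2:n) acc <- acc + abs(frames[[t]] - frames[[t - 1]])
  energy_image(acc / (n - 1), kind = "AEI")
}

#' Compute all three templates of a cycle
#'
#' @param cycle a `gait_cycle` or list of binary frames.
#' @return List with elements `gei`, `geni`, `aei`.
#' @export
compute_templates <- function(cycle) {
  list(gei = compute_gei(cycle), geni = compute_geni(cycle),
       aei = compute_aei(cycle))
}

#' Write an energy image as an 8-bit grayscale PNG
#'
#' @param img an [energy_image()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_energy_png <- function(img, path) {
  png::writePNG(pmin(pmax(unclass(img), 0), 255) / 255, path)
  invisible(path)
}
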