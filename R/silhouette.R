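#' @useDynLib pathogait, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif filter approx
#' @importFrom utils head tail
NULL

# Silhouette frames are plain numeric matrices (rows = y, cols = x) with
# values in {0, 255}; 255 is foreground.  A silhouette sequence is an ordered
# list of same-sized frames plus optional metadata.

#' Construct a silhouette frame
#'
#' @param pixels numeric matrix with values 0/255 (255 = foreground).
#' @param empty_foreground logical flag set when cleaning removed everything.
#' @return A `silhouette_frame`: the matrix with class and flag attributes.
#' @export
silhouette_frame <- function(pixels, empty_foreground = !any(pixels > 0)) {
  stopifnot(is.matrix(pixels))
  if (!all(pixels %in% c(0, 255))) {
    stop("silhouette frame pixels must be exactly 0 or 255")
  }
  storage.mode(pixels) <- "integer"  # halves memory for long sequences
  structure(pixels,
            class = c("silhouette_frame", "matrix", "array"),
            empty_foreground = isTRUE(empty_foreground))
}

#' Construct a silhouette sequence
#'
#' @param frames list of silhouette frames (or plain 0/255 matrices), all of
#'   equal dimension.
#' @param frame_rate optional frames-per-second metadata.
#' @param ground_truth_troughs optional integer vector of known legs-together
#'   frame indices (1-based), as emitted by the synthetic walker.
#' @param params optional generator parameters for provenance.
#' @return A `silhouette_sequence` object.
#' @export
silhouette_sequence <- function(frames, frame_rate = NULL,
                                ground_truth_troughs = NULL, params = NULL) {
  if (length(frames) < 2L) stop("a silhouette sequence needs at least 2 frames")
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all frames in a sequence must share dimensions")
  }
  structure(list(frames = frames,
                 frame_rate = frame_rate,
                 ground_truth_troughs = ground_truth_troughs,
                 params = params),
            class = "silhouette_sequence")
}

#' @export
length.silhouette_sequence <- function(x) length(x$frames)

#' @export
print.silhouette_sequence <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<silhouette_sequence: %d frames of %dx%d>\n",
              length(x$frames), d[1], d[2]))
  if (!is.null(x$params) && !is.null(x$params$class_label)) {
    cat(sprintf("  class: %s\n", x$params$class_label))
  }
  invisible(x)
}

#' Construct an energy image
#'
#' @param pixels numeric matrix with values in \[0, 255\].
#' @param kind one of `"GEI"`, `"GEnI"`, `"AEI"`, `"FEI"`.
#' @return An `energy_image` object (matrix with `kind` attribute).
#' @export
energy_image <- function(pixels, kind = c("GEI", "GEnI", "AEI", "FEI")) {
  kind <- match.arg(kind)
  stopifnot(is.matrix(pixels))
  if (min(pixels) < -1e-9 || max(pixels) > 255 + 1e-9) {
    stop("energy image pixels must lie in [0, 255]")
  }
  structure(pixels, class = c("energy_image", "matrix", "array"), kind = kind)
}

#' @export
print.energy_image <- function(x, ...) {
  cat(sprintf("<energy_image %s: %dx%d, range [%.2f, %.2f]>\n",
              attr(x, "kind"), nrow(x), ncol(x), min(x), max(x)))
  invisible(x)
}

# bounding box of foreground pixels: list(r0, r1, c0, c1) or NULL when empty
fg_bbox <- function(pixels) {
  idx <- which(pixels > 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(NULL)
  list(r0 = min(idx[, 1]), r1 = max(idx[, 1]),
       c0 = min(idx[, 2]), c1 = max(idx[, 2]))
}

# run a block of code with a private, seeded RNG stream and restore the
# caller's .Random.seed afterwards
with_private_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}
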