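# Preprocessing: grayscale -> clean binary -> person crop -> 256x256
# normalization.  Morphology and resizing are delegated to EBImage; frames
# stay plain R matrices (rows = y, cols = x) at the module surface.

# EBImage stores images (x, y); convert both ways explicitly.
.to_eb <- function(m) EBImage::Image(t(m) / 255)
.from_eb <- function(img) {
  round(t(EBImage::imageData(img)) * 255)
}

#' Binarize a grayscale frame and clean it morphologically
#'
#' Thresholds at `threshold`, then applies morphological opening (removes
#' speckles smaller than the structuring element) followed by closing (fills
#' comparable holes), both with disc-shaped elements.
#'
#' @param frame numeric matrix; grayscale in \[0, 255\] (or already binary).
#' @param threshold intensity cut in (0, 255); pixels strictly above are
#'   foreground.
#' @param open_radius,close_radius radii (pixels) of the disc structuring
#'   elements; radius 1 gives a 3x3 element.
#' @return A [silhouette_frame()]; its `empty_foreground` attribute is set
#'   when cleaning removed every pixel.
#' @export
binarize_and_clean <- function(frame, threshold = 127, open_radius = 1,
                               close_radius = 1) {
  if (threshold <= 0 || threshold >= 255) stop("threshold must lie in (0, 255)")
  bin <- matrix(255 * as.numeric(frame > threshold), nrow(frame), ncol(frame))
  if (any(bin > 0)) {
    img <- .to_eb(bin)
    if (open_radius > 0) {
      img <- EBImage::opening(img, EBImage::makeBrush(2 * open_radius + 1, "disc"))
    }
    if (close_radius > 0) {
      img <- EBImage::closing(img, EBImage::makeBrush(2 * close_radius + 1, "disc"))
    }
    bin <- .from_eb(img)
    bin <- matrix(255 * as.numeric(bin > 127), nrow(bin), ncol(bin))
  }
  if (!any(bin > 0)) {
    warning("empty foreground after cleaning")
    return(silhouette_frame(bin, empty_foreground = TRUE))
  }
  silhouette_frame(bin)
}

#' Crop a frame to the largest connected foreground component
#'
#' Stands in for a person detector on clean silhouettes: labels 8-connected
#' foreground components, keeps the largest, and crops to its bounding box
#' expanded by `margin` (clipped to the image).
#'
#' @param frame a binary [silhouette_frame()].
#' @param margin pixels of padding around the bounding box.
#' @return The cropped [silhouette_frame()] containing only that component.
#' @export
crop_to_person <- function(frame, margin = 0) {
  if (!any(frame > 0)) stop("no person found: empty foreground")
  lab <- EBImage::bwlabel(.to_eb(unclass(frame)))
  labm <- t(EBImage::imageData(lab))
  sizes <- tabulate(labm[labm > 0])
  keep <- which.max(sizes)
  comp <- matrix(255 * as.numeric(labm == keep), nrow(labm), ncol(labm))
  bb <- fg_bbox(comp)
  r0 <- max(1L, bb$r0 - margin); r1 <- min(nrow(comp), bb$r1 + margin)
  c0 <- max(1L, bb$c0 - margin); c1 <- min(ncol(comp), bb$c1 + margin)
  silhouette_frame(comp[r0:r1, c0:c1, drop = FALSE])
}

#' Size-normalize a silhouette to a square frame
#'
#' Scales the silhouette isotropically (nearest-neighbour, so the output
#' stays binary with no gray halo) until its tight bounding box fills the
#' output height, then centers it horizontally on its centroid against a
#' background of zeros.
#'
#' @param frame a binary [silhouette_frame()] (typically a person crop).
#' @param out_size output side length in pixels (default 256).
#' @return A binary `out_size` x `out_size` [silhouette_frame()].
#' @export
normalize_silhouette <- function(frame, out_size = 256) {
  bb <- fg_bbox(unclass(frame))
  if (is.null(bb)) stop("cannot normalize an empty silhouette")
  tight <- unclass(frame)[bb$r0:bb$r1, bb$c0:bb$c1, drop = FALSE]
  h <- nrow(tight)
  if (h < 2L) stop("degenerate silhouette: height < 2 pixels")
  scale <- out_size / h
  new_w <- max(1L, as.integer(round(ncol(tight) * scale)))
  resized <- EBImage::resize(.to_eb(tight), w = new_w, h = out_size,
                             filter = "none")
  rm_ <- .from_eb(resized)
  rm_ <- matrix(255 * as.numeric(rm_ > 127), nrow(rm_), ncol(rm_))
  out <- matrix(0, out_size, out_size)
  cols <- which(colSums(rm_) > 0)
  centroid_x <- sum(which(rm_ > 0, arr.ind = TRUE)[, 2]) / sum(rm_ > 0)
  shift <- as.integer(round(out_size / 2 - centroid_x))
  src <- seq_len(ncol(rm_))
  dst <- src + shift
  ok <- dst >= 1L & dst <= out_size
  out[, dst[ok]] <- rm_[, src[ok]]
  silhouette_frame(out)
}

#' Preprocess every frame of a sequence
#'
#' Runs [binarize_and_clean()], [crop_to_person()], and
#' [normalize_silhouette()] over a sequence; frames whose foreground
#' disappears during cleaning are dropped with a warning.
#'
#' @param seq a [silhouette_sequence()] of raw (grayscale or binary) frames.
#' @param threshold,open_radius,close_radius passed to [binarize_and_clean()].
#' @param out_size passed to [normalize_silhouette()].
#' @param margin passed to [crop_to_person()].
#' @return A [silhouette_sequence()] of normalized binary frames; ground
#'   truth troughs and params metadata are carried over.
#' @export
prep_sequence <- function(seq, threshold = 127, open_radius = 1,
                          close_radius = 1, out_size = 256, margin = 0) {
  frames <- lapply(seq$frames, function(f) {
    b <- binarize_and_clean(unclass(f), threshold, open_radius, close_radius)
    if (isTRUE(attr(b, "empty_foreground"))) return(NULL)
    normalize_silhouette(crop_to_person(b, margin), out_size)
  })
  keep <- !vapply(frames, is.null, logical(1))
  if (!all(keep)) warning(sum(!keep), " empty frames dropped during preprocessing")
  silhouette_sequence(frames[keep], frame_rate = seq$frame_rate,
                      ground_truth_troughs = seq$ground_truth_troughs,
                      params = seq$params)
}
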