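# Parametric side-view walker generator.
#
# The walker is closed-form geometry: a lean-able torso ellipse, a head disc,
# and two articulated legs (hip -> knee -> foot thick segments) whose
# horizontal separation follows sin(2*pi*t/cycle_frames).  Legs are together
# (aspect-ratio trough) whenever t is a multiple of cycle_frames/2, so the
# generator knows the true trough frames and emits them as ground truth.
# The five gait classes are caricatures of the clinical descriptions:
# festinating = forward lean + small fast steps, scissor = knees/feet crossing
# the midline, hemiparetic = one leg swung wide with a circumduction arc,
# shuffling = near-zero foot lift and small steps.

.gait_classes <- c("festinating", "scissor", "hemiparetic", "shuffling", "normal")

.class_style <- function(class_label) {
  switch(class_label,
    normal      = list(cycle_frames = 24L, stride_amplitude = 60, trunk_lean = 0,
                       step_height = 14, asymmetry = 0,   crossing = 0),
    festinating = list(cycle_frames = 14L, stride_amplitude = 36, trunk_lean = 18,
                       step_height = 8,  asymmetry = 0,   crossing = 0),
    scissor     = list(cycle_frames = 26L, stride_amplitude = 38, trunk_lean = 4,
                       step_height = 10, asymmetry = 0,   crossing = 0.7),
    hemiparetic = list(cycle_frames = 26L, stride_amplitude = 48, trunk_lean = 0,
                       step_height = 12, asymmetry = 0.6, crossing = 0),
    shuffling   = list(cycle_frames = 28L, stride_amplitude = 30, trunk_lean = 6,
                       step_height = 2,  asymmetry = 0,   crossing = 0),
    stop("unknown gait class: ", class_label)
  )
}

#' Parameters of the synthetic side-view walker
#'
#' Builds a validated parameter set for [generate_walker_sequence()].  Any
#' field left `NULL` takes the class-specific default, so
#' `walker_params("scissor")` is a ready-to-render scissor-gait walker.
#'
#' @param class_label gait class, one of `"festinating"`, `"scissor"`,
#'   `"hemiparetic"`, `"shuffling"`, `"normal"`.
#' @param cycle_frames integer >= 8, frames per full gait cycle.
#' @param n_cycles integer >= 1, number of cycles to render.
#' @param stride_amplitude pixels, maximum horizontal foot separation.
#' @param trunk_lean degrees of forward trunk lean.
#' @param step_height pixels of foot lift during swing (shuffling ~ 0).
#' @param asymmetry in \[0, 1\]; > 0 swings one leg wider and higher
#'   (hemiparetic circumduction).
#' @param crossing in \[0, 1\]; > 0 pulls knees and feet across the midline
#'   (scissor gait).
#' @param noise_rate fraction of pixels flipped per frame, in \[0, 0.05\].
#' @param seed integer RNG seed; identical parameter sets (including seed)
#'   produce bit-identical sequences.
#' @return A `walker_params` list.
#' @export
walker_params <- function(class_label = "normal", cycle_frames = NULL,
                          n_cycles = 3L, stride_amplitude = NULL,
                          trunk_lean = NULL, step_height = NULL,
                          asymmetry = NULL, crossing = NULL,
                          noise_rate = 0, seed = 1L) {
  class_label <- match.arg(class_label, .gait_classes)
  style <- .class_style(class_label)
  p <- list(
    class_label      = class_label,
    cycle_frames     = as.integer(if (is.null(cycle_frames)) style$cycle_frames else cycle_frames),
    n_cycles         = as.integer(n_cycles),
    stride_amplitude = if (is.null(stride_amplitude)) style$stride_amplitude else stride_amplitude,
    trunk_lean       = if (is.null(trunk_lean)) style$trunk_lean else trunk_lean,
    step_height      = if (is.null(step_height)) style$step_height else step_height,
    asymmetry        = if (is.null(asymmetry)) style$asymmetry else asymmetry,
    crossing         = if (is.null(crossing)) style$crossing else crossing,
    noise_rate       = noise_rate,
    seed             = as.integer(seed)
  )
  if (p$cycle_frames < 8L) stop("cycle_frames must be >= 8")
  if (p$n_cycles < 1L) stop("n_cycles must be >= 1")
  if (p$noise_rate < 0 || p$noise_rate > 0.05) stop("noise_rate must lie in [0, 0.05]")
  if (p$asymmetry < 0 || p$asymmetry > 1) stop("asymmetry must lie in [0, 1]")
  if (p$crossing < 0 || p$crossing > 1) stop("crossing must lie in [0, 1]")
  if (p$stride_amplitude <= 0) stop("stride_amplitude must be positive")
  class(p) <- "walker_params"
  p
}

# pixel-coordinate grids, shared by all render calls
.walker_grid <- local({
  X <- matrix(rep(seq_len(256), each = 256), 256, 256)
  Y <- matrix(rep(seq_len(256), times = 256), 256, 256)
  list(X = X, Y = Y)
})

# squared distance from every grid pixel to segment AB, vectorized
.seg_mask <- function(ax, ay, bx, by, halfwidth) {
  X <- .walker_grid$X; Y <- .walker_grid$Y
  vx <- bx - ax; vy <- by - ay
  len2 <- vx * vx + vy * vy
  if (len2 < 1e-12) {
    d2 <- (X - ax)^2 + (Y - ay)^2
  } else {
    tt <- ((X - ax) * vx + (Y - ay) * vy) / len2
    tt[tt < 0] <- 0; tt[tt > 1] <- 1
    d2 <- (X - (ax + tt * vx))^2 + (Y - (ay + tt * vy))^2
  }
  d2 <= halfwidth^2
}

# render one 256x256 logical mask of the walker at cycle phase `t` (frames,
# 0-based, continuous allowed)
.render_walker_mask <- function(t, p) {
  X <- .walker_grid$X; Y <- .walker_grid$Y
  x0 <- 128; y_ground <- 236; y_hip <- 140
  torso_a <- 17; torso_b <- 42; head_r <- 13; leg_w <- 7
  al <- p$trunk_lean * pi / 180
  dirx <- sin(al); diry <- -cos(al)

  # torso ellipse, long axis along the lean direction, rooted at the hip
  cx <- x0 + dirx * torso_b; cy <- y_hip + diry * torso_b
  dx <- X - cx; dy <- Y - cy
  along <- dx * dirx + dy * diry
  perp  <- dx * diry - dy * dirx
  mask <- (perp / torso_a)^2 + (along / torso_b)^2 <= 1

  # head disc overlapping the torso top
  hx <- x0 + dirx * (2 * torso_b + 9); hy <- y_hip + diry * (2 * torso_b + 9)
  mask <- mask | ((X - hx)^2 + (Y - hy)^2 <= head_r^2)

  s <- sin(2 * pi * t / p$cycle_frames)
  for (leg in 1:2) {
    si <- if (leg == 1) s else -s
    amp <- p$stride_amplitude / 2 * (1 + if (leg == 1) p$asymmetry else 0)
    foot_x <- x0 + amp * si
    lift <- p$step_height * max(0, si) +
      (if (leg == 1) p$asymmetry * 16 * abs(s) else 0)
    foot_y <- y_ground - lift
    # crossing pulls the knee to the far side of the midline during swing,
    # drawing the scissor X while keeping legs-together the narrowest pose
    knee_x <- (x0 + foot_x) / 2 - p$crossing * 22 * si
    knee_y <- (y_hip + foot_y) / 2
    mask <- mask | .seg_mask(x0, y_hip, knee_x, knee_y, leg_w)
    mask <- mask | .seg_mask(knee_x, knee_y, foot_x, foot_y, leg_w)
  }
  mask
}

#' Generate a seeded synthetic walker silhouette sequence
#'
#' Renders `n_cycles * cycle_frames` binary 256x256 frames.  The legs-together
#' pose falls on every multiple of `cycle_frames / 2`, so the width-to-height
#' ratio of the silhouette has a trough there; the in-range frame nearest each
#' such instant is reported as ground truth (the closing trough of the last
#' cycle lands on the final frame).
#'
#' @param params a [walker_params()] object.
#' @return A [silhouette_sequence()] whose `ground_truth_troughs` holds the
#'   1-based trough frame indices.
#' @export
generate_walker_sequence <- function(params) {
  if (!inherits(params, "walker_params")) params <- do.call(walker_params, params)
  n_frames <- params$n_cycles * params$cycle_frames
  frames <- with_private_seed(params$seed, {
    lapply(seq_len(n_frames) - 1L, function(t) {
      mask <- .render_walker_mask(t, params)
      if (params$noise_rate > 0) {
        flip <- matrix(runif(length(mask)) < params$noise_rate, nrow(mask))
        mask <- xor(mask, flip)
      }
      silhouette_frame(matrix(255 * as.numeric(mask), 256, 256))
    })
  })
  instants <- seq(0, params$n_cycles * params$cycle_frames, by = params$cycle_frames / 2)
  troughs <- unique(pmin(as.integer(round(instants)) + 1L, n_frames))
  silhouette_sequence(frames, ground_truth_troughs = troughs, params = params)
}

#' Generate a labeled multi-class walker dataset
#'
#' Draws `n_per_class` walkers for each of the five gait classes, applying
#' seeded per-sample jitter to stride, cadence, lean, and step height so
#' samples within a class differ while classes stay separable.
#'
#' @param n_per_class integer >= 1, sequences per class.
#' @param base optional [walker_params()] whose class-independent fields
#'   (`n_cycles`, `noise_rate`) are carried over to every sample.
#' @param seed integer seed controlling both jitter and per-sample noise.
#' @return A list with one element per sequence, each a list
#'   `(sequence, class_label)`; classes appear in a fixed interleaved order.
#' @export
generate_labeled_dataset <- function(n_per_class, base = NULL, seed = 1L) {
  lapply(dataset_plan(n_per_class, base, seed), function(pl) {
    list(sequence = generate_walker_sequence(pl), class_label = pl$class_label)
  })
}

#' Plan the per-sample parameters of a labeled walker dataset
#'
#' Returns only the jittered [walker_params()] of every sample (classes
#' interleaved, `5 * n_per_class` entries), so callers can render sequences
#' one at a time instead of holding the whole dataset in memory.
#' [generate_labeled_dataset()] is `generate_walker_sequence()` mapped over
#' this plan.
#'
#' @inheritParams generate_labeled_dataset
#' @return List of `walker_params`.
#' @export
dataset_plan <- function(n_per_class, base = NULL, seed = 1L) {
  if (n_per_class < 1L) stop("n_per_class must be >= 1")
  n_cycles <- if (is.null(base)) 3L else base$n_cycles
  noise_rate <- if (is.null(base)) 0 else base$noise_rate
  jitters <- with_private_seed(seed, {
    lapply(seq_len(5L * n_per_class), function(i) {
      list(stride = runif(1, 0.92, 1.08),
           dT = sample(-2:2, 1),
           lean = rnorm(1, 0, 1),
           step = runif(1, 0.9, 1.1),
           sub_seed = sample.int(.Machine$integer.max, 1))
    })
  })
  plan <- vector("list", 5L * n_per_class)
  k <- 0L
  for (i in seq_len(n_per_class)) {
    for (cl in .gait_classes) {
      k <- k + 1L
      style <- .class_style(cl)
      j <- jitters[[k]]
      plan[[k]] <- walker_params(
        class_label = cl,
        cycle_frames = max(8L, style$cycle_frames + j$dT),
        n_cycles = n_cycles,
        stride_amplitude = style$stride_amplitude * j$stride,
        trunk_lean = style$trunk_lean + j$lean,
        step_height = style$step_height * j$step,
        noise_rate = noise_rate,
        seed = j$sub_seed
      )
    }
  }
  plan
}

#' Write a silhouette sequence as numbered PNG frames plus a JSON sidecar
#'
#' @param seq a [silhouette_sequence()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_walker_sequence <- function(seq, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(seq$frames)) {
    png::writePNG(unclass(seq$frames[[i]]) / 255,
                  file.path(dir, sprintf("frame_%04d.png", i)))
  }
  sidecar <- list(ground_truth_troughs = seq$ground_truth_troughs,
                  n_frames = length(seq$frames),
                  params = seq$params[setdiff(names(seq$params), "")])
  jsonlite::write_json(sidecar, file.path(dir, "sequence.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(dir)
}

#' Read a silhouette sequence from a directory of image frames
#'
#' Frames are read in lexicographic order; grayscale values are binarized at
#' 127.  If a `sequence.json` sidecar is present its ground-truth troughs are
#' attached.
#'
#' @param dir directory containing `*.png` frames.
#' @return A [silhouette_sequence()].
#' @export
read_silhouette_sequence <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (length(files) < 2L) stop("need at least 2 PNG frames in ", dir)
  frames <- lapply(files, function(f) {
    m <- png::readPNG(f)
    if (length(dim(m)) == 3L) m <- m[, , 1]
    silhouette_frame(matrix(255 * as.numeric(m * 255 > 127), nrow(m), ncol(m)))
  })
  troughs <- NULL
  sc <- file.path(dir, "sequence.json")
  if (file.exists(sc)) {
    troughs <- as.integer(jsonlite::read_json(sc, simplifyVector = TRUE)$ground_truth_troughs)
  }
  silhouette_sequence(frames, ground_truth_troughs = troughs)
}
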