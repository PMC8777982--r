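#' Parameters for the synthetic fundus generator
#'
#' The generator emulates the statistical structure the segmenter assumes:
#' a bright circular field of view (FOV) on a dark background, non-uniform
#' (radial plus linear) illumination, a branching dark-on-light vessel tree
#' occupying roughly 7-13% of FOV pixels, optional central vessel reflex,
#' blur and additive Gaussian noise. The tree is a recursive bifurcating
#' random walk - a deliberately simple, non-physiological stand-in for real
#' vasculature.
#'
#' @param size image side length in pixels (square images).
#' @param n_roots number of root branches leaving the optic-disc point.
#' @param max_depth branching levels.
#' @param branch_prob probability that a segment bifurcates at its end.
#' @param initial_width root vessel width in pixels (>= 1).
#' @param width_decay child width ratio, in (0, 1).
#' @param tortuosity heading jitter per step (radians, sd).
#' @param segment_steps steps per branch segment (1 px per step).
#' @param target_fraction target vessel fraction of the FOV area; roots are
#'   added (up to `4 * n_roots`) until the rendered fraction reaches
#'   `target_fraction - fraction_tol`.
#' @param fraction_tol acceptance half-band around `target_fraction`.
#' @param vessel_contrast relative darkening of vessel pixels, in `[0, 1]`.
#' @param central_reflex brightening of vessel-interior pixels emulating
#'   the central light reflex (0 disables).
#' @param illumination_gradient strength of the radial + linear shading.
#' @param noise_sigma additive Gaussian noise sd on the `[0, 1]` scale.
#' @param fov_radius_frac FOV disc radius as a fraction of `size / 2`.
#' @param seed integer seed; identical parameters give identical output.
#' @return object of class `vessel_tree_params`.
#' @export
vessel_tree_params <- function(size = 128L,
                               n_roots = 4L,
                               max_depth = 4L,
                               branch_prob = 0.35,
                               initial_width = max(1, size * 0.024),
                               width_decay = 0.8,
                               tortuosity = 0.15,
                               segment_steps = max(8L, round(size / 4)),
                               target_fraction = 0.10,
                               fraction_tol = 0.03,
                               vessel_contrast = 0.55,
                               central_reflex = 0,
                               illumination_gradient = 0.25,
                               noise_sigma = 0.03,
                               fov_radius_frac = 0.94,
                               seed = 1L) {
  stopifnot(initial_width >= 1, width_decay > 0, width_decay < 1,
            fov_radius_frac > 0, fov_radius_frac <= 1,
            branch_prob >= 0, branch_prob <= 1, size >= 16)
  structure(as.list(environment()), class = "vessel_tree_params")
}

#' Generate a synthetic binary vessel-tree mask
#'
#' Rasterizes a recursive bifurcating random walk: each branch is a
#' heading-jittered walk drawn at its current width; children inherit
#' `width * width_decay`. All vessel pixels lie inside the circular FOV.
#' Deterministic for a given seed.
#'
#' @param params a [vessel_tree_params()].
#' @return binary `size x size` integer matrix (vessel = 1).
#' @export
generate_vessel_tree <- function(params) {
  stopifnot(inherits(params, "vessel_tree_params"))
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(params$seed)

  n <- params$size
  cx <- (n + 1) / 2
  R <- params$fov_radius_frac * n / 2
  # optic-disc point, offset toward the right of the FOV
  ox <- cx + 0.45 * R
  oy <- cx

  pts_x <- numeric(0)
  pts_y <- numeric(0)
  pts_w <- numeric(0)

  walk <- function(x, y, heading, width, depth) {
    for (s in seq_len(params$segment_steps)) {
      heading <- heading + rnorm(1L, 0, params$tortuosity)
      x <- x + cos(heading)
      y <- y + sin(heading)
      if ((x - cx)^2 + (y - cx)^2 > (R - width / 2)^2) return(invisible())
      pts_x[[length(pts_x) + 1L]] <<- x
      pts_y[[length(pts_y) + 1L]] <<- y
      pts_w[[length(pts_w) + 1L]] <<- width
    }
    if (depth < params$max_depth) {
      cw <- max(1, width * params$width_decay)
      if (runif(1L) < params$branch_prob) {
        a <- runif(1L, 0.2, 0.5)
        walk(x, y, heading + a, cw, depth + 1L)
        walk(x, y, heading - a, cw, depth + 1L)
      } else {
        walk(x, y, heading + rnorm(1L, 0, 0.1), cw, depth + 1L)
      }
    }
    invisible()
  }

  fov <- .fov_disc(n, R)
  fov_area <- sum(fov)
  mask <- matrix(0L, n, n)
  spawn <- function(i) {
    base <- atan2(oy - cx, ox - cx) + pi  # aim into the FOV
    heading <- base + (((i - 1) %% params$n_roots) / params$n_roots - 0.5) *
      1.5 * pi + rnorm(1L, 0, 0.2)
    walk(ox, oy, heading, params$initial_width, 1L)
  }
  max_roots <- 4L * params$n_roots
  i <- 0L
  repeat {
    i <- i + 1L
    if (i > max_roots) break
    spawn(i)
    if (i >= params$n_roots) {
      mask <- .rasterize(pts_x, pts_y, pts_w, n) & fov
      if (sum(mask) / fov_area >= params$target_fraction -
          params$fraction_tol) {
        break
      }
    }
  }
  mask <- .rasterize(pts_x, pts_y, pts_w, n) & fov
  if (sum(mask) == 0L) {
    stop("generation error: parameters produced an empty vessel mask",
         call. = FALSE)
  }
  matrix(as.integer(mask), n, n)
}

#' Render a synthetic RGB fundus image from a vessel mask
#'
#' Draws a reddish-orange FOV disc on a black background, applies the
#' illumination field, darkens vessel pixels by `vessel_contrast` (with an
#' optional bright interior centerline emulating the central vessel
#' reflex), blurs with a small Gaussian kernel and adds clipped Gaussian
#' noise. Deterministic for a given seed.
#'
#' @param mask binary vessel mask from [generate_vessel_tree()].
#' @param params the [vessel_tree_params()] used for the mask.
#' @return numeric array `size x size x 3` in `[0, 1]`.
#' @export
render_fundus <- function(mask, params) {
  stopifnot(inherits(params, "vessel_tree_params"))
  n <- nrow(mask)
  if (!identical(dim(mask), c(n, n))) {
    stop("mask must be square", call. = FALSE)
  }
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(params$seed + 10000L)

  cx <- (n + 1) / 2
  R <- params$fov_radius_frac * n / 2
  fov <- .fov_disc(n, R)
  rr <- sqrt(outer((seq_len(n) - cx)^2, (seq_len(n) - cx)^2, "+")) / R
  g <- params$illumination_gradient
  illum <- 1 - g * pmin(rr, 1)^2 -
    0.3 * g * matrix(seq_len(n) / n, n, n, byrow = TRUE)

  base <- c(0.82, 0.45, 0.22)  # fundus ground colour
  dark <- 1 - params$vessel_contrast * (mask == 1)
  if (params$central_reflex > 0) {
    core <- .erode3(mask == 1)
    dark <- dark + params$central_reflex * core
  }
  img <- array(0.04, c(n, n, 3))
  for (c in 1:3) {
    ch <- base[c] * illum * dark
    img[, , c] <- ifelse(fov, ch, 0.04)
  }
  img <- .gauss_blur(img, sigma = 0.7)
  if (params$noise_sigma > 0) {
    img <- img + array(rnorm(n * n * 3, 0, params$noise_sigma), c(n, n, 3))
  }
  img[img < 0] <- 0
  img[img > 1] <- 1
  img
}

#' Generate a synthetic dataset catalog
#'
#' Produces `n` image/mask pairs with per-sample seeds `seed + index`.
#' When `dir` is given, PNG images and masks plus a [read_manifest()]
#' -compatible manifest (`manifest.tsv`) are written; regeneration with the
#' same seed is byte-identical.
#'
#' @param n number of pairs (>= 1).
#' @param params a [vessel_tree_params()]; its `seed` is ignored in favour
#'   of `seed + index`.
#' @param seed base seed.
#' @param dir optional output directory.
#' @param split optional character vector (length 1 or `n`) of split tags
#'   written to the manifest; defaults to `"train"`.
#' @param prefix file-name prefix.
#' @return list of [sample_pair()]s; when `dir` is given, with attribute
#'   `manifest` holding the manifest path.
#' @export
generate_dataset <- function(n, params = vessel_tree_params(), seed = 1L,
                             dir = NULL, split = "train",
                             prefix = "synth") {
  stopifnot(n >= 1)
  split <- rep_len(split, n)
  pairs <- vector("list", n)
  rows <- vector("list", n)
  if (!is.null(dir)) dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(n)) {
    p <- params
    p$seed <- as.integer(seed) + i
    mask <- generate_vessel_tree(p)
    img <- render_fundus(mask, p)
    id <- sprintf("%s_%04d", prefix, i)
    pairs[[i]] <- sample_pair(id, img, mask)
    if (!is.null(dir)) {
      ipath <- file.path(dir, paste0(id, ".png"))
      mpath <- file.path(dir, paste0(id, "_mask.png"))
      png::writePNG(img, ipath)
      write_mask_png(mask, mpath)
      rows[[i]] <- data.frame(id = id, image = basename(ipath),
                              mask = basename(mpath), split = split[i])
    }
  }
  if (!is.null(dir)) {
    mpath <- file.path(dir, "manifest.tsv")
    write_manifest(do.call(rbind, rows), mpath)
    attr(pairs, "manifest") <- mpath
  }
  attr(pairs, "split") <- split
  pairs
}

.fov_disc <- function(n, R) {
  cx <- (n + 1) / 2
  outer((seq_len(n) - cx)^2, (seq_len(n) - cx)^2, "+") <= R^2
}

.rasterize <- function(xs, ys, ws, n) {
  mask <- matrix(FALSE, n, n)
  if (length(xs) == 0L) return(mask)
  xs <- unlist(xs)
  ys <- unlist(ys)
  ws <- unlist(ws)
  for (w in unique(round(ws * 2) / 2)) {
    sel <- round(ws * 2) / 2 == w
    r <- w / 2
    rr <- ceiling(r)
    off <- expand.grid(di = -rr:rr, dj = -rr:rr)
    off <- off[off$di^2 + off$dj^2 <= max(r, 0.5)^2 + 0.25, ]
    ci <- rep(round(ys[sel]), each = nrow(off)) + off$di
    cj <- rep(round(xs[sel]), each = nrow(off)) + off$dj
    ok <- ci >= 1 & ci <= n & cj >= 1 & cj <= n
    mask[cbind(ci[ok], cj[ok])] <- TRUE
  }
  mask
}

# 3x3 (4-neighbour) erosion, used for the central-reflex core
.erode3 <- function(m) {
  n1 <- nrow(m)
  n2 <- ncol(m)
  p <- matrix(FALSE, n1 + 2L, n2 + 2L)
  p[2:(n1 + 1), 2:(n2 + 1)] <- m
  p[2:(n1 + 1), 2:(n2 + 1)] & p[1:n1, 2:(n2 + 1)] & p[3:(n1 + 2), 2:(n2 + 1)] &
    p[2:(n1 + 1), 1:n2] & p[2:(n1 + 1), 3:(n2 + 2)]
}

# separable Gaussian blur via banded matrix products (edge-normalized)
.gauss_blur <- function(img, sigma = 0.7, half = 2L) {
  n1 <- dim(img)[1]
  n2 <- dim(img)[2]
  kern <- exp(-(0:half)^2 / (2 * sigma^2))
  band <- function(n) {
    K <- matrix(0, n, n)
    for (d in 0:half) {
      idx <- seq_len(n - d)
      K[cbind(idx, idx + d)] <- kern[d + 1]
      K[cbind(idx + d, idx)] <- kern[d + 1]
    }
    K / rowSums(K)
  }
  K1 <- band(n1)
  K2 <- band(n2)
  out <- img
  for (c in seq_len(dim(img)[3])) {
    out[, , c] <- K1 %*% img[, , c] %*% t(K2)
  }
  out
}
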