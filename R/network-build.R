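#' Build a dual-stream segmentation model
#'
#' Instantiates the layer graph described by a [network_spec()]: input block
#' -> (stream A || stream B) -> merge -> final block -> two transposed
#' convolutions -> 1x1 classifier -> per-pixel softmax. Every 3x3
#' convolution is followed by batch normalization and ReLU (convolutions
#' carry no bias; BN makes it redundant). Weights use He-uniform
#' initialization (`U(-sqrt(6/fan_in), sqrt(6/fan_in))`), BN scale 1 /
#' shift 0, so models are trained from scratch with no pretrained scheme.
#'
#' @param spec a [network_spec()]; see [dsf_net_spec()], [dsa_net_spec()].
#' @param seed integer seed for weight initialization (the model is
#'   reproducible bit-for-bit for a given seed).
#' @param bn_eps batch-normalization variance floor.
#' @return an object of class `segmentation_model`.
#' @export
build_network <- function(spec, seed = 1L, bn_eps = 1e-5) {
  validate_network_spec(spec)
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(as.integer(seed))

  he_conv <- function(k, cin, cout) {
    lim <- sqrt(6 / (k * k * cin))
    list(
      W = array(runif(k * k * cin * cout, -lim, lim), c(k, k, cin, cout)),
      gamma = rep(1, cout), beta = rep(0, cout),
      rmean = rep(0, cout), rvar = rep(1, cout)
    )
  }
  he_tconv <- function(cin, cout) {
    lim <- sqrt(6 / (16 * cin))
    # stored (k, k, cout, cin) so the flattened matrix groups kernel taps
    # with their output channel
    list(
      W = array(runif(16 * cout * cin, -lim, lim), c(4L, 4L, cout, cin)),
      b = rep(0, cout),
      gamma = rep(1, cout), beta = rep(0, cout),
      rmean = rep(0, cout), rvar = rep(1, cout)
    )
  }

  params <- list()
  cin <- spec$in_channels
  for (w in spec$input_block) {
    params[[length(params) + 1L]] <- he_conv(3L, cin, w)
    cin <- w
  }
  trunk_out <- cin
  for (i in seq_len(nrow(spec$stream_a))) {
    params[[length(params) + 1L]] <- he_conv(3L, cin, spec$stream_a$width[i])
    cin <- spec$stream_a$width[i]
  }
  cin <- trunk_out
  for (i in seq_len(nrow(spec$stream_b))) {
    params[[length(params) + 1L]] <- he_conv(3L, cin, spec$stream_b$width[i])
    cin <- spec$stream_b$width[i]
  }
  cin <- if (spec$variant == "dsa") {
    spec$stream_a$width[nrow(spec$stream_a)] +
      spec$stream_b$width[nrow(spec$stream_b)]
  } else {
    spec$stream_a$width[nrow(spec$stream_a)]
  }
  for (w in spec$final_block) {
    params[[length(params) + 1L]] <- he_conv(3L, cin, w)
    cin <- w
  }
  for (w in spec$decoder) {
    params[[length(params) + 1L]] <- he_tconv(cin, w)
    cin <- w
  }
  lim <- sqrt(6 / cin)
  params[[length(params) + 1L]] <- list(
    W = array(runif(cin * spec$n_classes, -lim, lim),
              c(1L, 1L, cin, spec$n_classes)),
    b = rep(0, spec$n_classes)
  )

  structure(
    list(
      spec = spec,
      params = params,
      plan = list(
        n_input = length(spec$input_block),
        strides_a = spec$stream_a$stride,
        pool_b = as.integer(spec$stream_b$pool),
        merge_cat = if (spec$variant == "dsa") 1L else 0L,
        n_final = length(spec$final_block),
        bn_eps = bn_eps
      ),
      seed = as.integer(seed),
      history = NULL
    ),
    class = "segmentation_model"
  )
}

#' Count the trainable parameters of a model
#'
#' Counts every trainable scalar: convolution and transposed-convolution
#' weights and biases, BN scale/shift and the classifier. BN running
#' moments are statistics, not parameters, and are excluded. Both reference
#' variants total 1,503,890 (1.5 M at one decimal).
#'
#' @param model a `segmentation_model`.
#' @return integer parameter count.
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "segmentation_model"))
  trainable <- c("W", "b", "gamma", "beta")
  sum(vapply(model$params, function(lay) {
    sum(vapply(lay[names(lay) %in% trainable], length, integer(1)))
  }, numeric(1)))
}

#' Segment a fundus image
#'
#' Runs the forward pass in inference mode (BN running moments) and returns
#' the per-pixel class probabilities together with the binary vessel mask
#' (vessel = 1, background = 0, the argmax per pixel with ties broken
#' toward background). The decoder output is center-cropped to the exact
#' input size, so the mask shape always equals the image shape.
#'
#' @param model a `segmentation_model`.
#' @param image numeric array `H x W x 3` with intensities in `[0, 1]`
#'   (values in 0..255 are rescaled).
#' @return list with `prob` (`H x W x 2` array, background then vessel,
#'   per-pixel probabilities summing to 1), `mask` (`H x W` integer matrix),
#'   and `encoder_size` (spatial dims of the pre-decoder feature map).
#' @export
segment <- function(model, image) {
  stopifnot(inherits(model, "segmentation_model"))
  d <- dim(image)
  if (length(d) != 3L || d[3] != model$spec$in_channels) {
    stop("input error: image must have ", model$spec$in_channels,
         " channels", call. = FALSE)
  }
  if (any(d[1:2] < 4L)) {
    stop("input error: spatial dimensions must be >= 4", call. = FALSE)
  }
  if (max(image) > 1.5) image <- image / 255
  out <- cpp_net_predict(model$params, model$plan, image)
  prob <- out$prob
  mask <- matrix(as.integer(prob[, , 2] > prob[, , 1]), d[1], d[2])
  list(prob = prob, mask = mask,
       encoder_size = c(out$enc_h, out$enc_w))
}

#' Save / load a model checkpoint
#'
#' The checkpoint is self-describing (spec, weights, BN moments, training
#' history and seed) and round-trips bit-exactly.
#'
#' @param model a `segmentation_model`.
#' @param path file path for the checkpoint.
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "segmentation_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "segmentation_model")) {
    stop("checkpoint error: ", path, " is not a segmentation_model",
         call. = FALSE)
  }
  model
}

#' @export
print.segmentation_model <- function(x, ...) {
  cat(sprintf("<segmentation_model> %s: %s 3x3 convolutions, %s parameters\n",
              toupper(x$spec$variant), count_conv3x3(x$spec),
              format(count_parameters(x), big.mark = ",")))
  if (!is.null(x$history)) {
    cat(sprintf("  trained: %d iterations, final loss %.4f\n",
                nrow(x$history$iterations),
                x$history$iterations$loss[nrow(x$history$iterations)]))
  }
  invisible(x)
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
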