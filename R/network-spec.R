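#' Declarative description of a dual-stream segmentation network
#'
#' A `network_spec` describes one of the two shallow dual-stream
#' architectures: an input convolutional block feeding two parallel encoder
#' streams (stream A downsamples by strided convolutions and uses no
#' pooling; stream B uses stride-1 convolutions with exactly two max-pooling
#' layers), a merge (element-wise addition for the fusion variant `"dsf"`,
#' depth-wise concatenation followed by a bottleneck for the aggregation
#' variant `"dsa"`), a final convolutional block, and a two-layer
#' transposed-convolution decoder ending in a 1x1 classifier with per-pixel
#' softmax. Every 3x3 convolution is followed by batch normalization and
#' ReLU.
#'
#' Structural invariants enforced by [validate_network_spec()]:
#' * stream A's stride product is 4 and it contains no pooling;
#' * stream B has exactly two pooling layers and stride-1 convolutions;
#' * both streams end at the same channel depth;
#' * the total number of 3x3 convolutions (input block + both streams +
#'   final block) is 9.
#'
#' @param variant `"dsf"` (element-wise fusion) or `"dsa"` (depth-wise
#'   aggregation with a bottleneck first final-block convolution).
#' @param input_block integer vector of 3x3 conv widths applied at full
#'   resolution before the streams split.
#' @param stream_a data.frame with columns `width`, `stride` (one row per
#'   3x3 convolution; strides must multiply to 4).
#' @param stream_b data.frame with columns `width`, `pool` (logical: is the
#'   convolution followed by a 2x2/stride-2 ceil-mode max pool).
#' @param final_block integer vector of 3x3 conv widths applied after the
#'   merge.
#' @param decoder integer vector (length 2) of transposed-convolution widths
#'   (kernel 4, stride 2, each followed by BN + ReLU).
#' @param in_channels,n_classes input image channels and output classes.
#' @return an object of class `network_spec`.
#' @seealso [dsf_net_spec()], [dsa_net_spec()], [build_network()]
#' @export
network_spec <- function(variant = c("dsa", "dsf"),
                         input_block,
                         stream_a,
                         stream_b,
                         final_block,
                         decoder,
                         in_channels = 3L,
                         n_classes = 2L) {
  variant <- match.arg(variant)
  spec <- structure(
    list(
      variant = variant,
      in_channels = as.integer(in_channels),
      n_classes = as.integer(n_classes),
      input_block = as.integer(input_block),
      stream_a = data.frame(width = as.integer(stream_a$width),
                            stride = as.integer(stream_a$stride)),
      stream_b = data.frame(width = as.integer(stream_b$width),
                            pool = as.logical(stream_b$pool)),
      final_block = as.integer(final_block),
      decoder = as.integer(decoder)
    ),
    class = "network_spec"
  )
  validate_network_spec(spec)
  spec
}

#' Validate the structural contract of a network specification
#'
#' @param spec a [network_spec()].
#' @return `spec`, invisibly; otherwise an error naming the violated
#'   invariant.
#' @export
validate_network_spec <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  if (any(c(spec$input_block, spec$stream_a$width, spec$stream_b$width,
            spec$final_block, spec$decoder) < 1L)) {
    stop("invalid network_spec: all layer widths must be >= 1", call. = FALSE)
  }
  if (prod(spec$stream_a$stride) != 4L) {
    stop("invalid network_spec: stream A stride product must be 4 (got ",
         prod(spec$stream_a$stride), ")", call. = FALSE)
  }
  if (sum(spec$stream_b$pool) != 2L) {
    stop("invalid network_spec: stream B must contain exactly 2 pooling ",
         "layers (got ", sum(spec$stream_b$pool), ")", call. = FALSE)
  }
  wa <- spec$stream_a$width[nrow(spec$stream_a)]
  wb <- spec$stream_b$width[nrow(spec$stream_b)]
  if (wa != wb) {
    stop("invalid network_spec: stream output depths differ (",
         wa, " vs ", wb, ")", call. = FALSE)
  }
  n3 <- count_conv3x3(spec)
  if (n3 != 9L) {
    stop("invalid network_spec: total 3x3 convolution count must be 9 (got ",
         n3, ")", call. = FALSE)
  }
  if (length(spec$decoder) != 2L) {
    stop("invalid network_spec: decoder must have exactly 2 transposed ",
         "convolutions", call. = FALSE)
  }
  invisible(spec)
}

#' Reference DSF-Net specification
#'
#' The fusion variant: streams are merged by element-wise addition. Channel
#' schedule: input block (32, 64); stream A (128 stride 2, 256 stride 2);
#' stream B (128 + pool, 256 + pool); final block (224, 80, 48); decoder
#' (32, 16). The schedule has 9 3x3 convolutions and 1,503,890 trainable
#' parameters, identical to [dsa_net_spec()].
#'
#' @return a [network_spec()].
#' @export
dsf_net_spec <- function() {
  network_spec(
    variant = "dsf",
    input_block = c(32L, 64L),
    stream_a = data.frame(width = c(128L, 256L), stride = c(2L, 2L)),
    stream_b = data.frame(width = c(128L, 256L), pool = c(TRUE, TRUE)),
    final_block = c(224L, 80L, 48L),
    decoder = c(32L, 16L)
  )
}

#' Reference DSA-Net specification
#'
#' The aggregation variant: streams are concatenated depth-wise (256 + 256 =
#' 512 channels) and the first final-block convolution acts as a bottleneck
#' reducing the doubled depth to 96 channels. Final block (96, 208, 48);
#' all other blocks as in [dsf_net_spec()]. The final-block widths solve the
#' exact parameter-parity constraint: both variants total 1,503,890
#' trainable parameters with 9 3x3 convolutions each.
#'
#' @return a [network_spec()].
#' @export
dsa_net_spec <- function() {
  network_spec(
    variant = "dsa",
    input_block = c(32L, 64L),
    stream_a = data.frame(width = c(128L, 256L), stride = c(2L, 2L)),
    stream_b = data.frame(width = c(128L, 256L), pool = c(TRUE, TRUE)),
    final_block = c(96L, 208L, 48L),
    decoder = c(32L, 16L)
  )
}

#' Count the 3x3 convolutions of a network
#'
#' Counts only 3x3 convolutions (input block, both encoder streams and the
#' final block); transposed convolutions and the 1x1 classifier are
#' excluded.
#'
#' @param x a [network_spec()] or a model built by [build_network()].
#' @return integer count.
#' @export
count_conv3x3 <- function(x) {
  if (inherits(x, "segmentation_model")) x <- x$spec
  stopifnot(inherits(x, "network_spec"))
  length(x$input_block) + nrow(x$stream_a) + nrow(x$stream_b) +
    length(x$final_block)
}

#' Spatial size of the deepest encoder feature map
#'
#' Both encoder streams halve the spatial dimensions twice in ceil mode
#' (stream A by two stride-2 convolutions with 'same' padding, stream B by
#' two 2x2/stride-2 ceil-mode max pools), so the merged feature map measures
#' `ceil(ceil(h/2)/2) x ceil(ceil(w/2)/2)`. A 650x650 input yields 163x163.
#'
#' @param h,w input height and width in pixels (>= 4).
#' @return integer vector `c(height, width)` of the pre-decoder feature map.
#' @export
encoder_output_size <- function(h, w) {
  if (any(c(h, w) < 4) || any(c(h, w) != as.integer(c(h, w)))) {
    stop("input dimensions must be integers >= 4", call. = FALSE)
  }
  half <- function(n) (n + 1L) %/% 2L
  c(half(half(as.integer(h))), half(half(as.integer(w))))
}

#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf("<network_spec> variant=%s  in=%d  classes=%d\n",
              toupper(x$variant), x$in_channels, x$n_classes))
  cat("  input block :", paste(x$input_block, collapse = ", "), "\n")
  cat("  stream A    :", paste(sprintf("%d(s%d)", x$stream_a$width,
                                       x$stream_a$stride), collapse = ", "), "\n")
  cat("  stream B    :", paste(sprintf("%d%s", x$stream_b$width,
                                       ifelse(x$stream_b$pool, "+pool", "")),
                               collapse = ", "), "\n")
  cat("  merge       :", if (x$variant == "dsf") "element-wise addition"
      else "depth-wise concatenation + bottleneck", "\n")
  cat("  final block :", paste(x$final_block, collapse = ", "), "\n")
  cat("  decoder     :", paste(x$decoder, collapse = ", "),
      "(transposed, kernel 4, stride 2)\n")
  invisible(x)
}
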