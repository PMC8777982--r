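#' Residual fusion of two stream features (element-wise addition)
#'
#' Merges the outputs of the two encoder streams the DSF way: the feature
#' maps are added element by element, so the merged map keeps the common
#' shape of its inputs.
#'
#' @param g,k numeric arrays of identical dimensions `height x width x
#'   depth` (stream A and stream B outputs).
#' @return array of the same shape, `g + k`.
#' @export
fuse_residual <- function(g, k) {
  dg <- dim(g) %||% length(g)
  dk <- dim(k) %||% length(k)
  if (!identical(dg, dk)) {
    stop("merge error: residual fusion requires identical shapes (",
         paste(dg, collapse = "x"), " vs ", paste(dk, collapse = "x"), ")",
         call. = FALSE)
  }
  .check_depth(g)
  .check_depth(k)
  g + k
}

#' Dense aggregation of two stream features (depth-wise concatenation)
#'
#' Merges the outputs of the two encoder streams the DSA way: the maps are
#' stacked along the channel axis, `g`'s channels first, so the merged depth
#' is the sum of the input depths (two 256-deep maps become one 512-deep
#' map).
#'
#' @param g,k numeric arrays `height x width x depth`, equal in height and
#'   width (depths may differ).
#' @return array `height x width x (depth(g) + depth(k))`.
#' @export
aggregate_dense <- function(g, k) {
  dg <- .dim3(g)
  dk <- .dim3(k)
  if (!identical(dg[1:2], dk[1:2])) {
    stop("merge error: dense aggregation requires identical spatial size (",
         paste(dg[1:2], collapse = "x"), " vs ", paste(dk[1:2], collapse = "x"),
         ")", call. = FALSE)
  }
  .check_depth(g)
  .check_depth(k)
  out <- array(0, c(dg[1], dg[2], dg[3] + dk[3]))
  out[, , seq_len(dg[3])] <- g
  out[, , dg[3] + seq_len(dk[3])] <- k
  out
}

.dim3 <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("feature map must be an array", call. = FALSE)
  if (length(d) == 2L) d <- c(d, 1L)
  d
}

.check_depth <- function(x) {
  d <- .dim3(x)
  if (any(d < 1L)) {
    stop("invalid feature map: height, width and depth must be >= 1",
         call. = FALSE)
  }
  invisible(d)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
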