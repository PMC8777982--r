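# Shared fixtures: a narrow network schedule (structurally valid: 9 3x3
# convolutions, stride product 4, two pools, equal stream depths) that is
# cheap enough for shape checks on full-size fundus dimensions, plus small
# synthetic catalogs.

tiny_spec <- function(variant = "dsa") {
  network_spec(
    variant = variant,
    input_block = c(4L, 4L),
    stream_a = data.frame(width = c(6L, 8L), stride = c(2L, 2L)),
    stream_b = data.frame(width = c(6L, 8L), pool = c(TRUE, TRUE)),
    final_block = c(8L, 6L, 4L),
    decoder = c(4L, 4L)
  )
}

tiny_model <- function(variant = "dsa", seed = 1L) {
  build_network(tiny_spec(variant), seed = seed)
}

tiny_pairs <- function(n, size = 32L, seed = 1L) {
  generate_dataset(n, vessel_tree_params(size = size), seed = seed)
}

random_image <- function(h, w, seed = 1L) {
  set.seed(seed)
  array(runif(h * w * 3), c(h, w, 3))
}

random_mask <- function(h, w, p = 0.1, seed = 1L) {
  set.seed(seed)
  matrix(as.integer(runif(h * w) < p), h, w)
}

# direct 'same'-padded ceil-mode convolution, written as naive loops: the
# independent oracle for the im2col-based native path
naive_conv2d <- function(x, w, stride) {
  h <- dim(x)[1]; wd <- dim(x)[2]; cin <- dim(x)[3]
  k <- dim(w)[1]; cout <- dim(w)[4]
  ho <- ceiling(h / stride); wo <- ceiling(wd / stride)
  pt <- max((ho - 1) * stride + k - h, 0) %/% 2
  pl <- max((wo - 1) * stride + k - wd, 0) %/% 2
  y <- array(0, c(ho, wo, cout))
  for (o in seq_len(cout)) for (i in seq_len(ho)) for (j in seq_len(wo)) {
    acc <- 0
    for (c in seq_len(cin)) for (ki in seq_len(k)) for (kj in seq_len(k)) {
      ii <- (i - 1) * stride - pt + ki
      jj <- (j - 1) * stride - pl + kj
      if (ii >= 1 && ii <= h && jj >= 1 && jj <= wd) {
        acc <- acc + x[ii, jj, c] * w[ki, kj, c, o]
      }
    }
    y[i, j, o] <- acc
  }
  y
}

# brute-force pairwise Mann-Whitney AUC oracle (midpoint tie convention)
brute_force_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}
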