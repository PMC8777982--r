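test_that("reference schedules satisfy the structural contract", {
  dsf <- dsf_net_spec()
  dsa <- dsa_net_spec()
  expect_equal(count_conv3x3(dsf), 9L)
  expect_equal(count_conv3x3(dsa), 9L)
  expect_equal(tail(dsf$stream_a$width, 1), 256L)
  expect_equal(tail(dsf$stream_b$width, 1), 256L)
  expect_equal(prod(dsf$stream_a$stride), 4L)
  expect_equal(sum(dsa$stream_b$pool), 2L)
})

test_that("invalid specifications are rejected with the violated invariant", {
  base <- dsa_net_spec()
  # three pooling layers
  expect_error(
    network_spec("dsa", c(32L, 64L),
                 data.frame(width = c(128L, 256L), stride = c(2L, 2L)),
                 data.frame(width = c(64L, 128L, 256L),
                            pool = c(TRUE, TRUE, TRUE)),
                 base$final_block[1:2], c(32L, 16L)),
    "exactly 2 pooling")
  # stride product != 4
  expect_error(
    network_spec("dsf", c(32L, 64L),
                 data.frame(width = c(128L, 256L), stride = c(2L, 4L)),
                 data.frame(width = c(128L, 256L), pool = c(TRUE, TRUE)),
                 c(224L, 80L, 48L), c(32L, 16L)),
    "stride product")
  # unequal stream output depths
  expect_error(
    network_spec("dsf", c(32L, 64L),
                 data.frame(width = c(128L, 128L), stride = c(2L, 2L)),
                 data.frame(width = c(128L, 256L), pool = c(TRUE, TRUE)),
                 c(224L, 80L, 48L), c(32L, 16L)),
    "depths differ")
  # 8 convolutions instead of 9
  expect_error(
    network_spec("dsf", c(32L, 64L),
                 data.frame(width = c(128L, 256L), stride = c(2L, 2L)),
                 data.frame(width = c(128L, 256L), pool = c(TRUE, TRUE)),
                 c(224L, 80L), c(32L, 16L)),
    "must be 9")
})

test_that("parameter totals match an independent arithmetic oracle", {
  # hand-summed: conv 9*cin*cout weights + 2*cout BN; tconv 16*cin*cout
  # weights + cout bias + 2*cout BN; classifier cin*2 + 2
  spec_total <- function(spec) {
    tot <- 0
    cin <- 3
    conv <- function(ci, co) 9 * ci * co + 2 * co
    for (w in spec$input_block) { tot <- tot + conv(cin, w); cin <- w }
    trunk <- cin
    for (w in spec$stream_a$width) { tot <- tot + conv(cin, w); cin <- w }
    cin <- trunk
    for (w in spec$stream_b$width) { tot <- tot + conv(cin, w); cin <- w }
    cin <- if (spec$variant == "dsa") 2 * cin else cin
    for (w in spec$final_block) { tot <- tot + conv(cin, w); cin <- w }
    for (w in spec$decoder) { tot <- tot + 16 * cin * w + 3 * w; cin <- w }
    tot + cin * 2 + 2
  }
  dsf <- build_network(dsf_net_spec(), seed = 1)
  dsa <- build_network(dsa_net_spec(), seed = 2)
  expect_equal(count_parameters(dsf), spec_total(dsf_net_spec()))
  expect_equal(count_parameters(dsa), spec_total(dsa_net_spec()))
  # parameter parity across variants, rounding to 1.5 million
  expect_identical(count_parameters(dsf), count_parameters(dsa))
  expect_equal(round(count_parameters(dsf) / 1e6, 1), 1.5)
  # a single 3x3 256->256 convolution carries 589,824 weights, the same as
  # a 3x3 512->128 bottleneck: the identity behind DSF/DSA parity
  expect_equal(3 * 3 * 256 * 256, 589824)
  expect_equal(3 * 3 * 512 * 128, 3 * 3 * 256 * 256)
})

test_that("residual fusion adds element-wise and preserves shape", {
  z <- array(0, c(5, 4, 3))
  expect_equal(fuse_residual(z, z), z)
  g <- array(1.5, c(5, 4, 3))
  k <- array(-0.5, c(5, 4, 3))
  expect_equal(fuse_residual(g, k), array(1.0, c(5, 4, 3)))
  # spatial size of the merged deep feature is conserved (163 x 163)
  a <- array(rnorm(163 * 163 * 2), c(163, 163, 2))
  expect_equal(dim(fuse_residual(a, a)), c(163, 163, 2))
  expect_error(fuse_residual(array(0, c(4, 4, 2)), array(0, c(4, 5, 2))),
               "merge error")
  # commutative and associative
  set.seed(3)
  x <- array(rnorm(24), c(2, 3, 4)); y <- array(rnorm(24), c(2, 3, 4))
  w <- array(rnorm(24), c(2, 3, 4))
  expect_equal(fuse_residual(x, y), fuse_residual(y, x))
  expect_equal(fuse_residual(fuse_residual(x, y), w),
               fuse_residual(x, fuse_residual(y, w)))
})

test_that("dense aggregation concatenates depth-wise, stream A first", {
  g <- array(seq_len(12), c(2, 3, 2))
  k <- array(100 + seq_len(6), c(2, 3, 1))
  s <- aggregate_dense(g, k)
  expect_equal(dim(s), c(2, 3, 3))
  expect_equal(s[, , 1:2], g)
  expect_equal(s[, , 3], k[, , 1])
  expect_equal(s[1, 1, ], c(g[1, 1, ], k[1, 1, 1]))
  # two 256-deep maps make one 512-deep map
  a <- array(1, c(4, 4, 256)); b <- array(2, c(4, 4, 256))
  expect_equal(dim(aggregate_dense(a, b))[3], 512L)
  # non-commutative, spatially strict, depth >= 1
  expect_false(isTRUE(all.equal(aggregate_dense(g, k)[, , 1],
                                aggregate_dense(k, g)[, , 1])))
  expect_error(aggregate_dense(array(0, c(2, 2, 1)), array(0, c(3, 2, 1))),
               "merge error")
  expect_error(aggregate_dense(array(0, c(2, 2, 0)), array(0, c(2, 2, 1))),
               "invalid feature map")
})

test_that("encoder output size follows two ceil-mode halvings", {
  expect_equal(encoder_output_size(650, 650), c(163L, 163L))
  expect_equal(encoder_output_size(4, 4), c(1L, 1L))
  expect_equal(encoder_output_size(565, 584), c(142L, 146L))
  expect_error(encoder_output_size(0, 10), "must be integers >= 4")
  # independent oracle: a ceil-mode stride-2 window visits seq(1, n, 2)
  halve <- function(n) length(seq(1, n, by = 2))
  set.seed(42)
  for (n in sample(4:1024, 50)) {
    expect_equal(encoder_output_size(n, n)[1], halve(halve(n)))
  }
})

test_that("forward pass conserves shape and normalizes probabilities", {
  m <- tiny_model()
  for (d in list(c(64, 64), c(565, 584), c(605, 700), c(960, 999))) {
    res <- segment(m, random_image(d[1], d[2]))
    expect_equal(dim(res$mask), d)
    expect_equal(dim(res$prob), c(d, 2))
    expect_true(all(res$mask %in% c(0L, 1L)))
    expect_lt(max(abs(res$prob[, , 1] + res$prob[, , 2] - 1)), 1e-5)
    expect_equal(res$encoder_size, encoder_output_size(d[1], d[2]))
  }
  # 650 x 650 input reaches the decoder from a 163 x 163 map
  res <- segment(m, random_image(650, 650, seed = 2))
  expect_equal(res$encoder_size, c(163L, 163L))
})

test_that("segmentation is deterministic and rejects bad channels", {
  m <- tiny_model(seed = 9)
  img <- random_image(40, 52, seed = 5)
  r1 <- segment(m, img)
  r2 <- segment(m, img)
  expect_identical(r1$prob, r2$prob)
  expect_identical(r1$mask, r2$mask)
  expect_error(segment(m, array(0.5, c(16, 16, 1))), "channels")
  expect_error(segment(m, array(0.5, c(2, 16, 3))), ">= 4")
})

test_that("native convolution and pooling match naive oracles", {
  set.seed(11)
  x <- array(rnorm(7 * 6 * 2), c(7, 6, 2))
  w <- array(rnorm(3 * 3 * 2 * 3), c(3, 3, 2, 3))
  for (s in c(1L, 2L)) {
    got <- dsvessel:::cpp_conv2d(x, w, s)
    expect_equal(got, naive_conv2d(x, w, s), tolerance = 1e-5)
  }
  # ceil-mode pool: 5x5 -> 3x3, border windows are partial
  xp <- array(rnorm(5 * 5 * 2), c(5, 5, 2))
  got <- dsvessel:::cpp_maxpool2(xp)
  ref <- array(0, c(3, 3, 2))
  for (c in 1:2) for (i in 1:3) for (j in 1:3) {
    ref[i, j, c] <- max(xp[(2 * i - 1):min(2 * i, 5),
                           (2 * j - 1):min(2 * j, 5), c])
  }
  expect_equal(got, ref, tolerance = 1e-6)
})

test_that("checkpoints round-trip bit-exactly", {
  m <- tiny_model(seed = 4)
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m, path)
  expect_identical(load_model(path), m)
  bad <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(1), bad)
  expect_error(load_model(bad), "checkpoint error")
})
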