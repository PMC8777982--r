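test_that("image/mask pairs load with threshold binarization", {
  d <- withr::local_tempdir()
  img <- array(runif(20 * 24 * 3), c(20, 24, 3))
  png::writePNG(img, file.path(d, "img.png"))
  # mask with intensities 0, 128, 255: threshold 128 keeps 128 and 255
  mvals <- matrix(c(0, 128, 255) / 255, 20, 24)
  png::writePNG(mvals, file.path(d, "mask.png"))
  pr <- load_pair(file.path(d, "img.png"), file.path(d, "mask.png"))
  expect_s3_class(pr, "sample_pair")
  expect_equal(dim(pr$image), c(20, 24, 3))
  expect_equal(unique(as.vector(pr$mask[mvals == 128 / 255])), 1L)
  expect_equal(unique(as.vector(pr$mask[mvals == 0])), 0L)
  # all-white mask -> all ones
  png::writePNG(matrix(1, 20, 24), file.path(d, "white.png"))
  expect_true(all(load_pair(file.path(d, "img.png"),
                            file.path(d, "white.png"))$mask == 1L))
  # dimension mismatch
  png::writePNG(matrix(1, 10, 10), file.path(d, "small.png"))
  expect_error(load_pair(file.path(d, "img.png"), file.path(d, "small.png")),
               "dimension mismatch")
  expect_error(load_pair(file.path(d, "nope.png"), file.path(d, "mask.png")),
               "not found")
  expect_error(read_image(file.path(d, "mask.gif")), "not found")
  file.create(file.path(d, "m.gif"))
  expect_error(read_image(file.path(d, "m.gif")), "GIF")
})

test_that("a DRIVE-sized pair carries 329,960 pixels", {
  d <- withr::local_tempdir()
  png::writePNG(array(0.5, c(584, 565, 3)), file.path(d, "drive.png"))
  png::writePNG(matrix(0, 584, 565), file.path(d, "drive_mask.png"))
  pr <- load_pair(file.path(d, "drive.png"), file.path(d, "drive_mask.png"))
  expect_equal(prod(dim(pr$mask)), 329960)
})

test_that("the PPM/PGM reader decodes all four magics", {
  d <- withr::local_tempdir()
  # P2 (ascii grayscale), 3x2
  writeLines(c("P2", "3 2", "255", "0 128 255", "64 32 16"),
             file.path(d, "a.pgm"))
  g <- read_image(file.path(d, "a.pgm"))
  expect_equal(dim(g), c(2, 3))
  expect_equal(g[1, ], c(0, 128, 255) / 255)
  expect_equal(g[2, ], c(64, 32, 16) / 255)
  # P5 (binary grayscale), same pixels
  con <- file(file.path(d, "b.pgm"), "wb")
  writeChar("P5\n3 2\n255\n", con, eos = NULL)
  writeBin(as.raw(c(0, 128, 255, 64, 32, 16)), con)
  close(con)
  expect_equal(read_image(file.path(d, "b.pgm")), g)
  # P3 / P6 (colour)
  writeLines(c("P3", "# comment", "2 1", "255",
               "255 0 0  0 255 0"), file.path(d, "c.ppm"))
  rgb <- read_image(file.path(d, "c.ppm"))
  expect_equal(dim(rgb), c(1, 2, 3))
  expect_equal(rgb[1, 1, ], c(1, 0, 0))
  expect_equal(rgb[1, 2, ], c(0, 1, 0))
  con <- file(file.path(d, "d.ppm"), "wb")
  writeChar("P6\n2 1\n255\n", con, eos = NULL)
  writeBin(as.raw(c(255, 0, 0, 0, 255, 0)), con)
  close(con)
  expect_equal(read_image(file.path(d, "d.ppm")), rgb)
})

test_that("manifests round-trip and resolve relative paths", {
  d <- withr::local_tempdir()
  m <- data.frame(id = c("a", "b"), image = c("a.png", "b.png"),
                  mask = c("a_m.png", "b_m.png"),
                  split = c("train", "test"))
  write_manifest(m, file.path(d, "manifest.tsv"))
  got <- read_manifest(file.path(d, "manifest.tsv"))
  expect_equal(got$id, m$id)
  expect_equal(got$split, m$split)
  expect_true(all(startsWith(got$image, normalizePath(d))))
  writeLines("id\timage", file.path(d, "bad.tsv"))
  expect_error(read_manifest(file.path(d, "bad.tsv")), "columns")
})

test_that("split schemes partition the catalog as published", {
  ids20 <- sprintf("im%02d", 1:20)
  loo <- make_splits(ids20, "leave_one_out")
  expect_length(loo$experiments, 20)
  for (e in loo$experiments) {
    expect_length(e$train, 19)
    expect_length(e$test, 1)
    expect_length(intersect(e$train, e$test), 0)
    expect_setequal(c(e$train, e$test), ids20)
  }
  ids28 <- sprintf("c%02d", 1:28)
  tf <- make_splits(ids28, "two_fold")
  expect_length(tf$experiments, 2)
  expect_length(tf$experiments[[1]]$train, 14)
  expect_length(tf$experiments[[1]]$test, 14)
  expect_equal(tf$experiments[[1]]$train, tf$experiments[[2]]$test)
  expect_equal(tf$experiments[[1]]$test, tf$experiments[[2]]$train)
  fx <- make_splits(c("a", "b", "c"), "fixed",
                    split = c("train", "train", "test"))
  expect_equal(fx$experiments[[1]]$train, c("a", "b"))
  expect_equal(fx$experiments[[1]]$test, "c")
  expect_error(make_splits("one", "leave_one_out"), "at least 2")
  expect_error(make_splits(c("a", "b", "c"), "two_fold"), "even")
  expect_error(make_splits(character(0), "fixed"), "empty")
})

test_that("augmentation applies paired transforms and expands by the grid", {
  pairs <- tiny_pairs(2, size = 32, seed = 3)
  ident <- list(c(0L, 0L))
  # horizontal flip is an involution
  once <- augment(pairs, flips = "h", translations = ident)
  twice <- augment(once, flips = "h", translations = ident)
  expect_equal(twice[[1]]$image, pairs[[1]]$image)
  expect_equal(twice[[1]]$mask, pairs[[1]]$mask)
  # flips conserve shape and the vessel-pixel count exactly
  flips <- augment(pairs, flips = c("none", "h", "v", "hv"),
                   translations = ident)
  expect_equal(vapply(flips, function(a) sum(a$mask), numeric(1)),
               rep(vapply(pairs, function(p) sum(p$mask), numeric(1)),
                   each = 4))
  for (a in flips) expect_equal(dim(a$mask), dim(pairs[[1]]$mask))
  # cross-product expansion: 2 pairs x 4 flips x 9 offsets
  grid <- translation_grid(3, 3, 2)
  expect_length(grid, 9)
  aug <- augment(pairs, translations = grid)
  expect_length(aug, 2 * 4 * 9)
  expect_equal(augment_expansion(20, 4, 48), 3840L)
  expect_length(translation_grid(8, 6, 3), 48)
  # translation fills with background and respects bounds
  tr <- augment(pairs[1], flips = "none", translations = list(c(5L, -3L)))
  expect_equal(dim(tr[[1]]$mask), dim(pairs[[1]]$mask))
  expect_true(all(tr[[1]]$mask[, 1:5] == 0L))
  expect_true(all(tr[[1]]$image[30:32, , ] == 0))
  expect_error(augment(pairs, translations = list(c(30L, 0L))),
               "augmentation error")
})

test_that("synthetic catalogs regenerate byte-identically", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p <- vessel_tree_params(size = 32)
  generate_dataset(3, p, seed = 5, dir = d1)
  generate_dataset(3, p, seed = 5, dir = d2)
  f1 <- list.files(d1, full.names = TRUE)
  f2 <- list.files(d2, full.names = TRUE)
  expect_equal(basename(f1), basename(f2))
  expect_equal(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})
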