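#' Read an image file
#'
#' Decodes PNG, TIFF, JPEG or PPM/PGM (P2/P3/P5/P6) into a numeric array
#' with intensities in `[0, 1]`. GIF is not supported; DRIVE-style GIF
#' masks should be converted to PNG first.
#'
#' @param path image file.
#' @return numeric array `H x W` (grayscale) or `H x W x channels`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) {
    stop("I/O error: file not found: ", path, call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    jpg = ,
    jpeg = jpeg::readJPEG(path),
    ppm = ,
    pgm = .read_pnm(path),
    gif = stop("I/O error: GIF is not supported; convert ", path,
               " to PNG", call. = FALSE),
    stop("I/O error: unsupported image format: ", path, call. = FALSE)
  )
  if (length(dim(img)) == 3L && dim(img)[3] == 4L) img <- img[, , 1:3]
  img
}

# minimal PPM/PGM decoder (ASCII P2/P3 and binary P5/P6, maxval <= 255)
.read_pnm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  tok <- function() {
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L) stop("I/O error: truncated PNM: ", path,
                                 call. = FALSE)
      if (ch == "#") {
        repeat {
          ch <- readChar(con, 1L, useBytes = TRUE)
          if (length(ch) == 0L || ch == "\n") break
        }
      } else if (!grepl("[ \t\r\n]", ch)) {
        break
      }
    }
    out <- ch
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L || grepl("[ \t\r\n]", ch)) break
      out <- paste0(out, ch)
    }
    out
  }
  magic <- tok()
  if (!magic %in% c("P2", "P3", "P5", "P6")) {
    stop("I/O error: unsupported PNM magic '", magic, "' in ", path,
         call. = FALSE)
  }
  w <- as.integer(tok())
  h <- as.integer(tok())
  maxval <- as.integer(tok())
  nch <- if (magic %in% c("P3", "P6")) 3L else 1L
  n <- w * h * nch
  vals <- if (magic %in% c("P5", "P6")) {
    as.integer(readBin(con, "raw", n))
  } else {
    out <- integer(n)
    for (i in seq_len(n)) out[i] <- as.integer(tok())
    out
  }
  # PNM is row-major; transpose into R's column-major H x W layout
  if (nch == 1L) {
    matrix(vals, h, w, byrow = TRUE) / maxval
  } else {
    a <- array(0, c(h, w, 3L))
    for (c in 1:3) {
      a[, , c] <- matrix(vals[seq(c, n, by = 3L)], h, w, byrow = TRUE)
    }
    a / maxval
  }
}

#' Write a binary mask as an 8-bit PNG
#'
#' Vessel pixels (1) map to intensity 255, background (0) to 0.
#'
#' @param mask binary matrix.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Load a fundus image / vessel mask pair
#'
#' The mask is binarized at `binarize_threshold` on the 8-bit scale
#' (grayscale >= threshold becomes vessel = 1); expert masks are near
#' binary, so the midpoint 128 is a safe default.
#'
#' @param image_path RGB fundus image (PNG/TIFF/JPEG/PPM).
#' @param mask_path expert vessel mask (grayscale or RGB; first channel
#'   used).
#' @param binarize_threshold intensity threshold in 0..255.
#' @param id sample identifier (defaults to the image file stem).
#' @param pathology optional logical pathology flag.
#' @return object of class `sample_pair` with `id`, `image` (`H x W x 3`,
#'   `[0, 1]`), `mask` (`H x W` integer, values 0/1), `pathology`.
#' @export
load_pair <- function(image_path, mask_path, binarize_threshold = 128,
                      id = NULL, pathology = NA) {
  img <- read_image(image_path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  msk <- read_image(mask_path)
  if (length(dim(msk)) == 3L) msk <- msk[, , 1]
  if (!identical(dim(img)[1:2], dim(msk)[1:2])) {
    stop("I/O error: image/mask dimension mismatch for ", image_path,
         " (", paste(dim(img)[1:2], collapse = "x"), ") vs ", mask_path,
         " (", paste(dim(msk)[1:2], collapse = "x"), ")", call. = FALSE)
  }
  sample_pair(
    id = id %||% tools::file_path_sans_ext(basename(image_path)),
    image = img,
    mask = matrix(as.integer(round(msk * 255) >= binarize_threshold),
                  nrow(msk), ncol(msk)),
    pathology = pathology
  )
}

#' Construct a sample pair in memory
#'
#' @param id identifier string.
#' @param image `H x W x 3` numeric array in `[0, 1]`.
#' @param mask `H x W` binary matrix.
#' @param pathology optional logical flag.
#' @return object of class `sample_pair`.
#' @export
sample_pair <- function(id, image, mask, pathology = NA) {
  if (!identical(dim(image)[1:2], dim(mask)[1:2])) {
    stop("sample_pair: image and mask spatial dimensions differ",
         call. = FALSE)
  }
  if (!all(mask %in% c(0L, 1L))) {
    stop("sample_pair: mask values must be 0/1", call. = FALSE)
  }
  structure(list(id = as.character(id), image = image,
                 mask = matrix(as.integer(mask), nrow(mask), ncol(mask)),
                 pathology = pathology),
            class = "sample_pair")
}

#' Read or write a dataset manifest
#'
#' The manifest is a tab-separated text file with header columns `id`,
#' `image`, `mask`, `split`; relative paths are resolved against the
#' manifest's directory. Any DRIVE-/STARE-/CHASE-DB1-like layout can be
#' described this way without hard-coded paths.
#'
#' @param path manifest file.
#' @return `read_manifest`: data.frame with absolute paths.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) {
    stop("I/O error: manifest not found: ", path, call. = FALSE)
  }
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "image", "mask", "split")
  if (!all(need %in% names(m))) {
    stop("manifest must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  base <- dirname(normalizePath(path))
  abs <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p,
                            file.path(base, p))
  m$image <- abs(m$image)
  m$mask <- abs(m$mask)
  m
}

#' @rdname read_manifest
#' @param manifest data.frame with columns `id`, `image`, `mask`, `split`.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.table(manifest[, c("id", "image", "mask", "split")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load every pair referenced by a manifest
#'
#' @param manifest path to a manifest file or a data.frame from
#'   [read_manifest()].
#' @param binarize_threshold passed to [load_pair()].
#' @return list of [sample_pair()] objects, with a `split` attribute
#'   carrying the manifest's split tags.
#' @export
load_catalog <- function(manifest, binarize_threshold = 128) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  pairs <- lapply(seq_len(nrow(manifest)), function(i) {
    load_pair(manifest$image[i], manifest$mask[i],
              binarize_threshold = binarize_threshold, id = manifest$id[i])
  })
  attr(pairs, "split") <- manifest$split
  pairs
}

#' Realize a train/test split scheme over a catalog
#'
#' Three schemes mirror common fundus benchmark protocols: `fixed` (one
#' experiment with provider-defined train/test tags, as in DRIVE),
#' `leave_one_out` (N experiments of N-1 train / 1 test, as in STARE), and
#' `two_fold` (2 experiments with swapped halves, as in CHASE-DB1).
#'
#' @param ids character vector of sample ids (catalog order is preserved
#'   and determines fold membership).
#' @param kind `"fixed"`, `"leave_one_out"` or `"two_fold"`.
#' @param split for `kind = "fixed"`: character vector parallel to `ids`
#'   with values `"train"` / `"test"`.
#' @return object of class `split_scheme`: a list of experiments, each with
#'   `train` and `test` id vectors.
#' @export
make_splits <- function(ids, kind = c("fixed", "leave_one_out", "two_fold"),
                        split = NULL) {
  kind <- match.arg(kind)
  ids <- as.character(ids)
  n <- length(ids)
  if (n == 0L) stop("split error: empty catalog", call. = FALSE)
  if (anyDuplicated(ids)) {
    stop("split error: duplicated sample ids", call. = FALSE)
  }
  experiments <- switch(kind,
    fixed = {
      if (is.null(split) || length(split) != n) {
        stop("split error: 'fixed' needs a split tag per sample",
             call. = FALSE)
      }
      list(list(train = ids[split == "train"], test = ids[split == "test"]))
    },
    leave_one_out = {
      if (n < 2L) {
        stop("split error: leave-one-out needs at least 2 samples",
             call. = FALSE)
      }
      lapply(seq_len(n), function(i) list(train = ids[-i], test = ids[i]))
    },
    two_fold = {
      if (n %% 2L != 0L) {
        stop("split error: two-fold needs an even catalog size",
             call. = FALSE)
      }
      h1 <- ids[seq_len(n / 2)]
      h2 <- ids[(n / 2 + 1):n]
      list(list(train = h1, test = h2), list(train = h2, test = h1))
    }
  )
  structure(list(kind = kind, experiments = experiments),
            class = "split_scheme")
}

#' @export
print.split_scheme <- function(x, ...) {
  cat(sprintf("<split_scheme> %s: %d experiment(s)\n", x$kind,
              length(x$experiments)))
  for (i in seq_along(x$experiments)) {
    e <- x$experiments[[i]]
    cat(sprintf("  [%d] train=%d test=%d\n", i, length(e$train),
                length(e$test)))
  }
  invisible(x)
}

#' Translation offset lattice for augmentation
#'
#' A rectangular `nx x ny` lattice of pixel offsets with stride `s`,
#' centered as symmetrically as the (possibly even) extent allows and
#' always containing the identity offset `(0, 0)`. The DRIVE-like default
#' in [augment()] uses an 8 x 6 lattice (48 offsets) so that 20 source
#' pairs x 4 flips x 48 offsets = 3840 augmented pairs. The published
#' augmentation counts do not determine the grid, so this lattice is a
#' reconstruction, not a benchmark fact.
#'
#' @param nx,ny lattice extents.
#' @param s stride in pixels.
#' @return list of `c(dx, dy)` offsets (dx right, dy down), identity first.
#' @export
translation_grid <- function(nx = 8L, ny = 6L, s = 3L) {
  dxs <- s * (seq_len(nx) - (nx %/% 2L + 1L))
  dys <- s * (seq_len(ny) - (ny %/% 2L + 1L))
  offs <- expand.grid(dx = dxs, dy = dys)
  ord <- order(offs$dx != 0 | offs$dy != 0)
  offs <- offs[ord, ]
  lapply(seq_len(nrow(offs)), function(i) c(offs$dx[i], offs$dy[i]))
}

#' Augment a catalog with flips and X-Y translations
#'
#' Every output pair receives one flip from `flips` and one translation
#' from `translations` (full cross product), applied identically to image
#' and mask; the output count is exactly
#' `length(pairs) * length(flips) * length(translations)`. Translations
#' fill vacated pixels with background (0 in the mask, black in the image,
#' matching the dark border of a fundus photograph). Flips conserve the
#' vessel-pixel count exactly. The defaults reproduce the 192-fold
#' DRIVE-style expansion (4 flips x 48 offsets).
#'
#' @param pairs list of [sample_pair()] objects.
#' @param flips subset of `c("none", "h", "v", "hv")`.
#' @param translations list of `c(dx, dy)` integer offsets (see
#'   [translation_grid()]); each offset must stay within 25% of the
#'   corresponding image dimension.
#' @return list of augmented [sample_pair()]s with ids suffixed by the
#'   transform.
#' @export
augment <- function(pairs, flips = c("none", "h", "v", "hv"),
                    translations = translation_grid()) {
  flips <- match.arg(flips, c("none", "h", "v", "hv"), several.ok = TRUE)
  out <- vector("list", length(pairs) * length(flips) * length(translations))
  k <- 0L
  for (pr in pairs) {
    d <- dim(pr$mask)
    for (tr in translations) {
      if (abs(tr[1]) > 0.25 * d[2] || abs(tr[2]) > 0.25 * d[1]) {
        stop("augmentation error: translation (", tr[1], ",", tr[2],
             ") exceeds 25% of the image size", call. = FALSE)
      }
    }
    for (fl in flips) {
      fi <- .flip(pr$image, fl)
      fm <- .flip(pr$mask, fl)
      for (tr in translations) {
        k <- k + 1L
        out[[k]] <- sample_pair(
          id = sprintf("%s_%s_t%+d%+d", pr$id, fl, tr[1], tr[2]),
          image = .translate(fi, tr[1], tr[2], fill = 0),
          mask = .translate(fm, tr[1], tr[2], fill = 0L),
          pathology = pr$pathology
        )
      }
    }
  }
  out
}

#' Augmented catalog size under the cross-product expansion
#'
#' @param n_pairs number of source pairs.
#' @param n_flips,n_translations factor sizes (identity included in each).
#' @return expected [augment()] output count.
#' @export
augment_expansion <- function(n_pairs, n_flips = 4L, n_translations = 48L) {
  as.integer(n_pairs) * as.integer(n_flips) * as.integer(n_translations)
}

# flip about the vertical axis (h: left-right), horizontal axis (v:
# top-bottom), or both
.flip <- function(x, how) {
  if (how == "none") return(x)
  d <- dim(x)
  ri <- if (how %in% c("v", "hv")) rev(seq_len(d[1])) else seq_len(d[1])
  ci <- if (how %in% c("h", "hv")) rev(seq_len(d[2])) else seq_len(d[2])
  if (length(d) == 3L) x[ri, ci, , drop = FALSE] else x[ri, ci, drop = FALSE]
}

# shift dx pixels right, dy pixels down (row-major, origin top-left)
.translate <- function(x, dx, dy, fill = 0) {
  d <- dim(x)
  out <- if (length(d) == 3L) array(fill, d) else
    matrix(fill, d[1], d[2])
  src_r <- seq_len(d[1]) - dy
  src_c <- seq_len(d[2]) - dx
  ok_r <- src_r >= 1L & src_r <= d[1]
  ok_c <- src_c >= 1L & src_c <= d[2]
  if (any(ok_r) && any(ok_c)) {
    if (length(d) == 3L) {
      out[which(ok_r), which(ok_c), ] <- x[src_r[ok_r], src_c[ok_c], ,
                                           drop = FALSE]
    } else {
      out[which(ok_r), which(ok_c)] <- x[src_r[ok_r], src_c[ok_c],
                                         drop = FALSE]
    }
  }
  if (is.integer(x)) storage.mode(out) <- "integer"
  out
}
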