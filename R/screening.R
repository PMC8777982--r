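#' Vessel-ratio screening statistic
#'
#' The vessel ratio `V_r` is the number of vessel pixels divided by the
#' number of background pixels in a binary segmentation mask. Being a
#' ratio, it is less sensitive to acquisition geometry than a raw vessel
#' pixel count, and tracked over successive visits it flags vascular
#' change: retinal vessel swelling (diabetic retinopathy) raises `V_r`,
#' vessel narrowing (hypertensive retinopathy) lowers it. A 565 x 584 DRIVE
#' mask with 26,566 vessel pixels has 303,394 background pixels and
#' `V_r = 0.0876` (4 decimals).
#'
#' @param mask binary mask (vessel = 1, background = 0).
#' @param patient patient identifier.
#' @param visit visit label or date.
#' @param fov optional binary FOV mask restricting the counts.
#' @return object of class `screening_record` with `patient`, `visit`,
#'   `vessel_pixels`, `background_pixels`, `v_r` (full precision; printed
#'   to 4 decimals).
#' @export
vessel_ratio <- function(mask, patient = NA_character_,
                         visit = NA_character_, fov = NULL) {
  m <- as.integer(mask)
  if (length(m) == 0L) stop("domain error: empty mask", call. = FALSE)
  if (!all(m %in% c(0L, 1L))) {
    stop("domain error: mask values must be 0/1", call. = FALSE)
  }
  if (!is.null(fov)) m <- m[as.logical(fov)]
  vp <- sum(m == 1L)
  bp <- sum(m == 0L)
  if (bp == 0L) {
    stop("division-undefined error: mask contains no background pixels",
         call. = FALSE)
  }
  structure(list(patient = as.character(patient),
                 visit = as.character(visit),
                 vessel_pixels = vp, background_pixels = bp,
                 v_r = vp / bp),
            class = "screening_record")
}

#' Compare the vessel ratio between two visits
#'
#' The relative change `(curr - prev) / prev` of `V_r` between two
#' consecutive visits of the same patient is classified against a relative
#' threshold: an increase beyond it is diabetic-indicative (vessel
#' swelling), a decrease beyond it is hypertensive-indicative (vessel
#' narrowing), otherwise the record is stable. The output is indicative,
#' not diagnostic.
#'
#' @param prev,curr [vessel_ratio()] records for the same patient
#'   (`prev$v_r > 0`).
#' @param rel_threshold relative-change threshold (default 5%); raw
#'   equality comparison would flag segmentation noise.
#' @return object of class `screening_verdict` with `direction`
#'   (`"diabetic_indicative"`, `"hypertensive_indicative"` or `"stable"`),
#'   `relative_change` and `threshold`.
#' @export
compare_visits <- function(prev, curr, rel_threshold = 0.05) {
  stopifnot(inherits(prev, "screening_record"),
            inherits(curr, "screening_record"))
  if (!identical(prev$patient, curr$patient)) {
    stop("record error: records belong to different patients (",
         prev$patient, " vs ", curr$patient, ")", call. = FALSE)
  }
  if (prev$v_r <= 0) {
    stop("record error: previous V_r must be positive", call. = FALSE)
  }
  rel <- (curr$v_r - prev$v_r) / prev$v_r
  direction <- if (rel > rel_threshold) {
    "diabetic_indicative"
  } else if (rel < -rel_threshold) {
    "hypertensive_indicative"
  } else {
    "stable"
  }
  structure(list(direction = direction, relative_change = rel,
                 threshold = rel_threshold),
            class = "screening_verdict")
}

#' Signed change map between two visit masks
#'
#' Image subtraction of two binary masks: `+1` marks a vessel pixel gained
#' at the current visit, `-1` a vessel pixel lost, `0` no change; the
#' summary counts satisfy `gained - lost = sum(curr) - sum(prev)`.
#'
#' @param mask_prev,mask_curr binary masks of identical shape.
#' @return list with `map` (integer matrix in `{-1, 0, 1}`), `gained`,
#'   `lost`.
#' @export
change_map <- function(mask_prev, mask_curr) {
  if (!identical(dim(mask_prev), dim(mask_curr))) {
    stop("input error: mask shapes differ", call. = FALSE)
  }
  d <- matrix(as.integer(mask_curr) - as.integer(mask_prev),
              nrow(mask_curr), ncol(mask_curr))
  list(map = d, gained = sum(d == 1L), lost = sum(d == -1L))
}

#' Append a screening record to a patient's longitudinal store
#'
#' The store is an append-only tab-separated file (one per patient) with
#' columns `visit`, `vessel_pixels`, `background_pixels`, `v_r`.
#'
#' @param record a [vessel_ratio()] record.
#' @param path store file (created with a header if absent).
#' @return `path`, invisibly.
#' @export
append_screening_record <- function(record, path) {
  stopifnot(inherits(record, "screening_record"))
  new <- !file.exists(path)
  line <- sprintf("%s\t%d\t%d\t%.6f", record$visit, record$vessel_pixels,
                  record$background_pixels, record$v_r)
  con <- file(path, "a")
  on.exit(close(con))
  if (new) writeLines("visit\tvessel_pixels\tbackground_pixels\tv_r", con)
  writeLines(line, con)
  invisible(path)
}

#' @export
print.screening_record <- function(x, ...) {
  cat(sprintf(
    "<screening_record> patient=%s visit=%s vessels=%d background=%d V_r=%.4f\n",
    x$patient, x$visit, x$vessel_pixels, x$background_pixels, x$v_r))
  invisible(x)
}

#' @export
print.screening_verdict <- function(x, ...) {
  cat(sprintf("<screening_verdict> %s (relative change %+.1f%%, threshold %.0f%%)\n",
              x$direction, 100 * x$relative_change, 100 * x$threshold))
  invisible(x)
}
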