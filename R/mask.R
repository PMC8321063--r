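#' Coerce to a binary segmentation mask
#'
#' A binary mask is a logical matrix (rows x cols, origin top-left) where
#' `TRUE` marks foreground (the subject silhouette) and `FALSE` background.
#' Numeric input is thresholded: any nonzero value reads as foreground, which
#' matches the 8-bit PNG convention (255 = foreground) used on disk.
#'
#' @param x A logical or numeric matrix.
#' @return A logical matrix.
#' @export
as_binary_mask <- function(x) {
  if (!is.matrix(x)) abort("A mask must be a matrix.")
  if (is.logical(x)) return(x)
  if (is.numeric(x)) {
    if (anyNA(x)) abort("Mask contains missing values.")
    return(x != 0)
  }
  abort("A mask must be logical or numeric.")
}

check_same_dim <- function(a, b, what = c("masks")) {
  if (!identical(dim(a)[1:2], dim(b)[1:2])) {
    abort(sprintf("Dimension mismatch: %s are %dx%d vs %dx%d.",
                  what[1], nrow(a), ncol(a), nrow(b), ncol(b)))
  }
  invisible(TRUE)
}

#' Tightest bounding rectangle of a mask's foreground
#'
#' Returns the minimax rectangle: the smallest axis-aligned rectangle
#' containing every foreground pixel of the reference mask. This rectangle is
#' the region of interest over which frame-level segmentation metrics are
#' evaluated, so that large empty background margins do not inflate accuracy.
#'
#' @param reference A binary mask (see [as_binary_mask()]).
#' @return An integer vector `c(row_min, col_min, row_max, col_max)`,
#'   1-based inclusive bounds.
#' @examples
#' m <- matrix(FALSE, 8, 8); m[3:5, 2:6] <- TRUE
#' minimax_roi(m)
#' @export
minimax_roi <- function(reference) {
  reference <- as_binary_mask(reference)
  idx <- which(reference, arr.ind = TRUE)
  if (nrow(idx) == 0) abort("Mask has no foreground pixels: no RoI definable.")
  roi <- c(row_min = min(idx[, 1]), col_min = min(idx[, 2]),
           row_max = max(idx[, 1]), col_max = max(idx[, 2]))
  as.integer(roi) |> stats::setNames(names(roi))
}

check_roi <- function(roi, mask) {
  roi <- as.integer(roi)
  if (length(roi) != 4) abort("`roi` must be c(row_min, col_min, row_max, col_max).")
  if (roi[1] < 1 || roi[2] < 1 || roi[3] > nrow(mask) || roi[4] > ncol(mask) ||
      roi[1] > roi[3] || roi[2] > roi[4]) {
    abort("`roi` out of mask bounds or inverted.")
  }
  roi
}

#' Pixel confusion counts between a predicted and a reference mask
#'
#' Pixels are counted inside `roi` only; the positive condition is membership
#' in the reference (manually segmented) mask. By default the RoI is the
#' minimax rectangle of the reference, the convention used for frame-level
#' metric tables; pass `roi = "full"` to count over the whole frame.
#'
#' @param pred,reference Binary masks of identical dimensions.
#' @param roi Integer vector `c(row_min, col_min, row_max, col_max)`
#'   (1-based, inclusive), or `"full"` for the whole frame. Default:
#'   `minimax_roi(reference)`.
#' @return A one-row tibble with columns `tp`, `fp`, `fn`, `tn`, and the RoI
#'   bounds `row_min`, `col_min`, `row_max`, `col_max`.
#' @export
mask_confusion <- function(pred, reference, roi = NULL) {
  pred <- as_binary_mask(pred)
  reference <- as_binary_mask(reference)
  check_same_dim(pred, reference)
  if (is.null(roi)) roi <- minimax_roi(reference)
  if (identical(roi, "full")) roi <- c(1L, 1L, nrow(reference), ncol(reference))
  roi <- check_roi(roi, reference)
  p <- pred[roi[1]:roi[3], roi[2]:roi[4], drop = FALSE]
  r <- reference[roi[1]:roi[3], roi[2]:roi[4], drop = FALSE]
  tibble::tibble(
    tp = sum(p & r), fp = sum(p & !r), fn = sum(!p & r), tn = sum(!p & !r),
    row_min = roi[1], col_min = roi[2], row_max = roi[3], col_max = roi[4]
  )
}

safe_ratio <- function(num, den) ifelse(den > 0, num / den, NA_real_)

#' Segmentation quality metrics from confusion counts
#'
#' Computes the standard pixel-wise mask metrics: Hamming loss
#' (fraction of disagreeing pixels), Jaccard index (intersection over union),
#' F-measure, accuracy, false-positive rate and false-negative rate. An
#' undefined ratio (zero denominator, e.g. FPR of an all-foreground RoI) is
#' reported as `NA` rather than silently as 0, so that means across frames
#' are not corrupted.
#'
#' @param counts A one-row data frame (or named vector) with `tp`, `fp`,
#'   `fn`, `tn`, as produced by [mask_confusion()]. A multi-row tibble is
#'   processed row-wise.
#' @return A tibble with columns `hamming_loss`, `jaccard`, `f_measure`,
#'   `accuracy`, `fpr`, `fnr`, one row per input row.
#' @examples
#' mask_metrics(tibble::tibble(tp = 2, fp = 1, fn = 2, tn = 4))
#' @export
mask_metrics <- function(counts) {
  if (!is.data.frame(counts)) counts <- tibble::as_tibble(as.list(counts))
  need <- c("tp", "fp", "fn", "tn")
  if (!all(need %in% names(counts))) abort("`counts` needs tp, fp, fn, tn.")
  tp <- as.numeric(counts$tp); fp <- as.numeric(counts$fp)
  fn <- as.numeric(counts$fn); tn <- as.numeric(counts$tn)
  if (any(c(tp, fp, fn, tn) < 0)) abort("Confusion counts must be non-negative.")
  total <- tp + fp + fn + tn
  if (any(total == 0)) abort("Confusion counts sum to zero.")
  hamming <- (fp + fn) / total
  tibble::tibble(
    hamming_loss = hamming,
    jaccard = safe_ratio(tp, tp + fp + fn),
    f_measure = safe_ratio(2 * tp, 2 * tp + fp + fn),
    accuracy = 1 - hamming,  # complement by definition; identity exact
    fpr = safe_ratio(fp, fp + tn),
    fnr = safe_ratio(fn, fn + tp)
  )
}

#' Per-frame mask evaluation
#'
#' Convenience wrapper chaining [mask_confusion()] and [mask_metrics()] over
#' one or more frames.
#'
#' @param preds,references A binary mask or a list of binary masks.
#' @inheritParams mask_confusion
#' @return A tibble with one row per frame: frame index, confusion counts and
#'   all metrics.
#' @export
evaluate_masks <- function(preds, references, roi = NULL) {
  if (is.matrix(preds)) preds <- list(preds)
  if (is.matrix(references)) references <- list(references)
  if (length(preds) != length(references)) {
    abort("`preds` and `references` must have the same length.")
  }
  purrr::map2_dfr(preds, references, function(p, r) {
    cc <- mask_confusion(p, r, roi = roi)
    dplyr::bind_cols(cc, mask_metrics(cc))
  }) |>
    dplyr::mutate(frame = dplyr::row_number(), .before = 1)
}

#' Average binary cross-entropy between a reference mask and a probability mask
#'
#' The loss is \eqn{-\frac{1}{N}\sum_{ij} [y_{ij}\log\hat y_{ij} +
#' (1-y_{ij})\log(1-\hat y_{ij})]} over all `N` pixels, where \eqn{y} is the
#' binary reference and \eqn{\hat y} the predicted foreground probability.
#' Predictions are clipped to `[eps, 1 - eps]` before taking logs so that
#' saturated predictions yield a finite loss; the default `eps = 1e-12`
#' introduces negligible bias.
#'
#' @param reference A binary mask.
#' @param pred A numeric matrix of probabilities in `[0, 1]`, same dimensions.
#' @param eps Clipping constant for the probabilities.
#' @return A non-negative scalar.
#' @examples
#' m <- matrix(c(TRUE, FALSE, FALSE, TRUE), 2, 2)
#' mask_bce_loss(m, matrix(0.5, 2, 2))  # log(2)
#' @export
mask_bce_loss <- function(reference, pred, eps = 1e-12) {
  reference <- as_binary_mask(reference)
  if (!is.matrix(pred) || !is.numeric(pred)) {
    abort("`pred` must be a numeric probability matrix.")
  }
  check_same_dim(pred, reference)
  if (any(pred < 0 | pred > 1)) abort("Probabilities must lie in [0, 1].")
  p <- pmin(pmax(pred, eps), 1 - eps)
  y <- as.numeric(reference)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Chroma-key background replacement
#'
#' Copies foreground pixels bit-exact from the frame and replaces every
#' background pixel with a uniform key colour (pure green by default), the
#' preprocessing that lets structure-from-motion feature matching ignore the
#' background entirely.
#'
#' @param frame An `H x W x 3` integer array, 8-bit channels in `[0, 255]`.
#' @param mask A binary mask of the same height and width; `TRUE` = keep.
#' @param chroma_rgb Length-3 integer vector, the replacement colour.
#' @return An array of the same shape as `frame`.
#' @export
apply_chroma <- function(frame, mask, chroma_rgb = c(0L, 255L, 0L)) {
  if (!is.array(frame) || length(dim(frame)) != 3 || dim(frame)[3] != 3) {
    abort("`frame` must be an H x W x 3 array.")
  }
  if (any(frame < 0 | frame > 255)) abort("Frame channels must lie in [0, 255].")
  mask <- as_binary_mask(mask)
  check_same_dim(frame, mask, what = "frame and mask")
  chroma_rgb <- as.integer(chroma_rgb)
  if (length(chroma_rgb) != 3 || any(chroma_rgb < 0 | chroma_rgb > 255)) {
    abort("`chroma_rgb` must be three 8-bit values.")
  }
  out <- frame
  bg <- !mask
  for (ch in 1:3) {
    plane <- out[, , ch]
    plane[bg] <- chroma_rgb[ch]
    out[, , ch] <- plane
  }
  out
}

#' Frame-to-frame segmentation consistency of two mask sequences
#'
#' Compares two aligned sequences of masks (e.g. two segmentation models run
#' on the same video) by the per-frame Jaccard index, computed over the full
#' frame, with `masks_b` as the reference. Summaries target the worst-case
#' behaviour that damages photogrammetric reconstruction: the minimum Jaccard
#' over frames, the fraction of frames below a similarity threshold, and the
#' maximum per-frame false-negative pixel count.
#'
#' @param masks_a,masks_b Lists of binary masks, same length; per-frame
#'   dimensions must match.
#' @param threshold Similarity threshold for the "bad frame" fraction
#'   (default 0.8).
#' @return An object of class `sequence_consistency`; see [tidy()] for the
#'   per-frame table and [glance()] for the summary row.
#' @export
sequence_consistency <- function(masks_a, masks_b, threshold = 0.8) {
  if (is.matrix(masks_a)) masks_a <- list(masks_a)
  if (is.matrix(masks_b)) masks_b <- list(masks_b)
  if (length(masks_a) != length(masks_b)) {
    abort("Mask sequences differ in length.")
  }
  if (length(masks_a) < 1) abort("Empty mask sequences.")
  per_frame <- purrr::map2_dfr(masks_a, masks_b, function(a, b) {
    cc <- mask_confusion(a, b, roi = "full")
    dplyr::bind_cols(cc[c("tp", "fp", "fn", "tn")], mask_metrics(cc)["jaccard"])
  }) |>
    dplyr::mutate(frame = dplyr::row_number(), .before = 1)
  structure(
    list(
      per_frame = per_frame,
      per_frame_jaccard = per_frame$jaccard,
      min_jaccard = min(per_frame$jaccard),
      frac_below_threshold = mean(per_frame$jaccard < threshold),
      threshold = threshold,
      max_fn = max(per_frame$fn)
    ),
    class = "sequence_consistency"
  )
}

#' @export
print.sequence_consistency <- function(x, ...) {
  cat(sprintf(
    "Mask sequence consistency over %d frames\n  min Jaccard: %.4f\n  frames with Jaccard < %.2f: %.2f%%\n  max false negatives: %d\n",
    length(x$per_frame_jaccard), x$min_jaccard, x$threshold,
    100 * x$frac_below_threshold, x$max_fn))
  invisible(x)
}

# ---- raster I/O -----------------------------------------------------------

#' Read and write masks and frames as PNG
#'
#' Masks are stored as 8-bit grayscale PNG with foreground = 255 and
#' background = 0; on read, any nonzero gray value counts as foreground.
#' Frames are RGB PNG with 8-bit channels.
#'
#' @param path File path.
#' @param mask A binary mask.
#' @param frame An `H x W x 3` integer array in `[0, 255]`.
#' @return `read_mask()` a logical matrix; `read_frame()` an integer array;
#'   writers return the path invisibly.
#' @name mask_io
NULL

#' @rdname mask_io
#' @export
read_mask <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img > 0
}

#' @rdname mask_io
#' @export
write_mask <- function(mask, path) {
  mask <- as_binary_mask(mask)
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' @rdname mask_io
#' @export
read_frame <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  storage.mode(img) <- "double"
  arr <- round(img[, , 1:3, drop = FALSE] * 255)
  storage.mode(arr) <- "integer"
  arr
}

#' @rdname mask_io
#' @export
write_frame <- function(frame, path) {
  png::writePNG(frame / 255, path)
  invisible(path)
}
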