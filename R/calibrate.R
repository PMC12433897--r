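#' Identify the reference card among contours by aspect ratio
#'
#' The card is found by its known side ratio (38/26 by default) computed
#' from the minimum-area rotated rectangle; intensity plays no role. Among
#' several in-tolerance candidates the largest enclosed area wins, since the
#' reference board is larger than any slice.
#'
#' @param contours Non-empty list of contour matrices.
#' @param expected_ratio Expected long/short side ratio (default `38/26`).
#' @param tol Relative tolerance on the ratio (default 0.1).
#' @return The card contour, with attributes `index` (position in the input
#'   list), `ratio` and `area_px`.
#' @export
find_reference <- function(contours, expected_ratio = 38 / 26, tol = 0.1) {
  if (length(contours) == 0) stop("no contours supplied", call. = FALSE)
  ratios <- rep(NA_real_, length(contours))
  areas <- rep(NA_real_, length(contours))
  for (i in seq_along(contours)) {
    g <- contour_geometry(contours[[i]])
    if (g$min_rect$short > 0) {
      ratios[i] <- g$min_rect$long / g$min_rect$short
      areas[i] <- g$area_px
    }
  }
  ok <- which(!is.na(ratios) & abs(ratios / expected_ratio - 1) <= tol)
  if (length(ok) == 0) {
    closest <- ratios[which.min(abs(ratios - expected_ratio))]
    stop(sprintf(
      "calibration failure: no contour with side ratio within %.0f%% of %.4f (closest seen: %.4f)",
      100 * tol, expected_ratio, closest), call. = FALSE)
  }
  pick <- ok[which.max(areas[ok])]
  structure(contours[[pick]], index = pick, ratio = ratios[pick], area_px = areas[pick])
}

#' Pixel-per-millimeter calibration from the reference card
#'
#' The calibration ratio is the card's short rectangle side in pixels
#' divided by its physical width (26 mm by default). The long (38 mm) side
#' provides a consistency cross-check: disagreement beyond 3% raises a
#' warning, beyond 10% a calibration failure.
#'
#' @param card Card contour (from [find_reference()]).
#' @param wmm Physical length of the short card side in mm (default 26).
#' @param lmm Physical length of the long card side in mm (default 38).
#' @return Object of class `calibration`: list with `ppm`, `card_contour`,
#'   `card_px` (short and long side in px).
#' @export
compute_ppm <- function(card, wmm = 26, lmm = 38) {
  mr <- min_area_rect(card)
  ppm <- mr$short / wmm
  ppm_long <- mr$long / lmm
  dev <- abs(ppm_long / ppm - 1)
  if (dev > 0.10) {
    stop(sprintf("calibration failure: card side lengths disagree by %.1f%%", 100 * dev),
         call. = FALSE)
  }
  if (dev > 0.03) {
    warning(sprintf("card side-length cross-check off by %.1f%%", 100 * dev), call. = FALSE)
  }
  structure(list(ppm = ppm, card_contour = card,
                 card_px = c(short = mr$short, long = mr$long)),
            class = "calibration")
}

#' @export
print.calibration <- function(x, ...) {
  cat(sprintf("calibration: %.3f px/mm (card %.1f x %.1f px)\n",
              x$ppm, x$card_px["short"], x$card_px["long"]))
  invisible(x)
}

#' Convert a slice contour to physical measurements
#'
#' Long and short diameters come from the minimum-area rotated rectangle
#' (rotation-invariant, unlike the axis-aligned box); the axis-aligned
#' extents are also reported for comparison. Contours below the minimum
#' pixel area are measurement noise and are filtered (returns `NULL`).
#'
#' @param contour Slice contour (must not be the card).
#' @param cal A [compute_ppm()] calibration.
#' @param id Integer object id for reporting.
#' @param min_area_px Minimum enclosed pixel area (default 400).
#' @return Object of class `slice_measurement` (a one-row data frame with
#'   `object_id`, `long_mm`, `short_mm`, `area_mm2`, `bbox_w_mm`,
#'   `bbox_h_mm`, `row_px`, `col_px`) or `NULL` if filtered.
#' @export
measure_slice <- function(contour, cal, id, min_area_px = 400) {
  stopifnot(inherits(cal, "calibration"))
  g <- contour_geometry(contour)
  if (g$area_px < min_area_px) return(NULL)
  ppm <- cal$ppm
  out <- data.frame(
    object_id = as.integer(id),
    long_mm = g$min_rect$long / ppm,
    short_mm = g$min_rect$short / ppm,
    area_mm2 = g$area_px / ppm^2,
    bbox_w_mm = g$bbox[["w_px"]] / ppm,
    bbox_h_mm = g$bbox[["h_px"]] / ppm,
    row_px = mean(contour[, 1]),
    col_px = mean(contour[, 2]))
  class(out) <- c("slice_measurement", class(out))
  out
}

#' Measure every slice in an image
#'
#' Full measurement chain: grayscale, Gaussian blur, Canny edges, contour
#' extraction, card identification and calibration, then physical
#' measurement of every remaining contour.
#'
#' @param image RGB array (H x W x 3) or grayscale matrix, 0--255 or 0--1.
#' @param params [edge_params()] controlling blur and thresholds.
#' @param card_mm Physical card size `(short, long)` in mm.
#' @param min_area_px Minimum slice area in px^2 (default 400).
#' @return List with `measurements` (data frame, one row per slice, ordered
#'   by decreasing area), `calibration`, `contours`, and `n_filtered`.
#' @export
measure_image <- function(image, params = edge_params(), card_mm = c(26, 38),
                          min_area_px = 400) {
  gray <- if (is.matrix(image)) {
    if (max(image) <= 1 + 1e-9) image * 255 else image
  } else {
    to_grayscale(image)
  }
  edges <- edge_map(gaussian_blur(gray, params), params)
  contours <- find_contours(edges)
  card <- find_reference(contours, expected_ratio = max(card_mm) / min(card_mm))
  cal <- compute_ppm(card, wmm = min(card_mm), lmm = max(card_mm))
  card_idx <- attr(card, "index")
  rest <- contours[setdiff(seq_along(contours), card_idx)]
  rows <- list()
  n_filtered <- 0L
  for (i in seq_along(rest)) {
    m <- measure_slice(rest[[i]], cal, id = length(rows) + 1L, min_area_px = min_area_px)
    if (is.null(m)) n_filtered <- n_filtered + 1L else rows[[length(rows) + 1L]] <- m
  }
  measurements <- if (length(rows)) do.call(rbind, rows) else NULL
  list(measurements = measurements, calibration = cal,
       contours = rest, card_contour = card, n_filtered = n_filtered)
}

#' Relative error and accuracy of a predicted measurement
#'
#' `error = |pred - actual| / actual * 100`, reported at one decimal
#' (half-up, matching how measurement tables are printed), and
#' `accuracy = 100 - error`, so `error + accuracy == 100` exactly.
#'
#' @param pred,actual Predicted and true values in mm (vectorized);
#'   `actual` must be positive.
#' @return Data frame of class `error_report` with columns `pred`, `actual`,
#'   `error_pct`, `acc_pct`.
#' @export
error_accuracy <- function(pred, actual) {
  if (any(actual <= 0)) stop("actual must be > 0", call. = FALSE)
  err <- round_half_up(abs(pred - actual) / actual * 100, 1)
  out <- data.frame(pred = pred, actual = actual,
                    error_pct = err, acc_pct = 100 - err)
  class(out) <- c("error_report", class(out))
  out
}

#' Summarize error reports
#'
#' @param ... One or more [error_accuracy()] data frames (or plain data
#'   frames with an `error_pct` column). Named arguments appear under that
#'   name in `per_column`.
#' @return List with `mean_error_pct` and `max_error_pct` over all pooled
#'   errors and `per_column`, the named vector of per-report means.
#' @export
summarize_errors <- function(...) {
  reports <- list(...)
  if (length(reports) == 1 && is.list(reports[[1]]) && !is.data.frame(reports[[1]])) {
    reports <- reports[[1]]
  }
  if (length(reports) == 0) stop("no error reports supplied", call. = FALSE)
  errs <- lapply(reports, function(r) r$error_pct)
  all_err <- unlist(errs)
  if (length(all_err) == 0) stop("no error values supplied", call. = FALSE)
  per_col <- vapply(errs, mean, numeric(1))
  if (is.null(names(reports))) names(per_col) <- NULL
  list(mean_error_pct = mean(all_err), max_error_pct = max(all_err),
       per_column = per_col)
}

#' Percent reduction between two model sizes or costs
#'
#' @param old,new Positive scalars (e.g. parameter counts in millions).
#' @return `100 * (old - new) / old`.
#' @export
percent_reduction <- function(old, new) {
  stop_if_not_scalar_pos(old, "old")
  100 * (old - new) / old
}
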