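# End-to-end measurement pipeline: image in, annotated overlays and a
# per-object measurement report out.

.read_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path, call. = FALSE)
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3))
  if (dim(img)[3] == 4L) img <- img[, , 1:3]
  img * 255
}

# Burn a contour outline (and a small center cross) into an RGB array.
.draw_contour <- function(image, contour, rgb = c(255, 0, 0)) {
  h <- dim(image)[1]; w <- dim(image)[2]
  r <- pmin(pmax(round(contour[, 1]), 1), h)
  cc <- pmin(pmax(round(contour[, 2]), 1), w)
  for (ch in 1:3) image[cbind(r, cc, ch)] <- rgb[ch]
  cr <- round(mean(r)); ccol <- round(mean(cc))
  for (dd in -3:3) {
    for (ch in 1:3) {
      image[pmin(pmax(cr + dd, 1), h), ccol, ch] <- rgb[ch]
      image[cr, pmin(pmax(ccol + dd, 1), w), ch] <- rgb[ch]
    }
  }
  image
}

.draw_box <- function(image, box, rgb = c(255, 255, 0)) {
  h <- dim(image)[1]; w <- dim(image)[2]
  x1 <- pmin(pmax(round(box[1]), 1), w); x2 <- pmin(pmax(round(box[3]), 1), w)
  y1 <- pmin(pmax(round(box[2]), 1), h); y2 <- pmin(pmax(round(box[4]), 1), h)
  for (ch in 1:3) {
    image[y1:y2, c(x1, x2), ch] <- rgb[ch]
    image[c(y1, y2), x1:x2, ch] <- rgb[ch]
  }
  image
}

#' Stub feature pyramid from an image
#'
#' Average-pools the grayscale image to each stride's resolution and
#' projects it to the requested channel counts with fixed sinusoidal
#' channel mixes. This is deterministic plumbing that lets the detection
#' head run end-to-end on raw images without a trained backbone; it carries
#' no learned semantics.
#'
#' @param image RGB array or grayscale matrix.
#' @param in_channels Per-level channel counts.
#' @param strides Per-level strides.
#' @return List of `c(1, C_l, H_l, W_l)` arrays.
#' @export
image_pyramid_features <- function(image, in_channels = c(64, 128, 256),
                                   strides = c(8, 16, 32)) {
  gray <- if (is.matrix(image)) image else to_grayscale(image)
  gray <- gray / 255 - 0.5
  lapply(seq_along(strides), function(l) {
    s <- strides[l]
    h <- floor(nrow(gray) / s); w <- floor(ncol(gray) / s)
    pooled <- matrix(0, h, w)
    for (i in seq_len(h)) {
      for (j in seq_len(w)) {
        pooled[i, j] <- mean(gray[((i - 1) * s + 1):(i * s), ((j - 1) * s + 1):(j * s)])
      }
    }
    cc <- in_channels[l]
    out <- array(0, c(1, cc, h, w))
    for (ch in seq_len(cc)) out[1, ch, , ] <- pooled * sin(ch)
    out
  })
}

#' Decode head outputs into discrete detections
#'
#' Applies sigmoid to the class logits, decodes boxes with [dfl_decode()],
#' keeps cells above the confidence threshold and suppresses overlaps with
#' [nms_boxes()].
#'
#' @param output A [lsd_head_forward()] result (batch size 1).
#' @param p The matching [head_params()].
#' @param conf_thr Minimum class confidence (default 0.25).
#' @param iou_thr NMS threshold (default 0.45).
#' @param top_k Keep at most this many candidates (by score) before NMS
#'   (default 300, the usual detector budget).
#' @return Data frame `image_id, class_id, score, x1, y1, x2, y2`.
#' @export
decode_detections <- function(output, p, conf_thr = 0.25, iou_thr = 0.45,
                              top_k = 300) {
  stopifnot(inherits(output, "detection_output"))
  rows <- list()
  for (l in seq_along(output$levels)) {
    lev <- output$levels[[l]]
    boxes <- dfl_decode(lev$reg, p$reg_max, output$strides[l])
    conf <- sigmoid(lev$cls)  # 1 x nc x H x W
    d <- dim(conf)
    cm <- matrix(conf[1, , , ], d[2], d[3] * d[4])
    cl <- max.col(t(cm), ties.method = "first")
    sc <- cm[cbind(cl, seq_along(cl))]
    bm <- matrix(boxes[1, , , ], 4, d[3] * d[4])
    keep <- sc >= conf_thr
    if (any(keep)) {
      rows[[length(rows) + 1L]] <- data.frame(
        image_id = 1L, class_id = as.integer(cl[keep]), score = sc[keep],
        x1 = bm[1, keep], y1 = bm[2, keep], x2 = bm[3, keep], y2 = bm[4, keep])
    }
  }
  if (!length(rows)) {
    return(data.frame(image_id = integer(0), class_id = integer(0),
                      score = numeric(0), x1 = numeric(0), y1 = numeric(0),
                      x2 = numeric(0), y2 = numeric(0)))
  }
  det <- do.call(rbind, rows)
  det <- det[order(det$score, decreasing = TRUE), , drop = FALSE]
  if (nrow(det) > top_k) det <- det[seq_len(top_k), , drop = FALSE]
  keep <- nms_boxes(as.matrix(det[, c("x1", "y1", "x2", "y2")]), det$score, iou_thr)
  det[keep, , drop = FALSE]
}

.write_report <- function(measurements, txt_path, csv_path) {
  fmt <- function(x) formatC(round_half_up(x, 1), format = "f", digits = 1)
  lines <- if (is.null(measurements)) character(0) else {
    paste(measurements$object_id, fmt(measurements$long_mm),
          fmt(measurements$short_mm), fmt(measurements$area_mm2), sep = "\t")
  }
  writeLines(lines, txt_path)
  df <- if (is.null(measurements)) {
    data.frame(object_id = integer(0), long_mm = numeric(0),
               short_mm = numeric(0), area_mm2 = numeric(0))
  } else {
    data.frame(object_id = measurements$object_id,
               long_mm = as.numeric(fmt(measurements$long_mm)),
               short_mm = as.numeric(fmt(measurements$short_mm)),
               area_mm2 = as.numeric(fmt(measurements$area_mm2)))
  }
  utils::write.csv(df, csv_path, row.names = FALSE, quote = FALSE)
}

#' Run the full inspection pipeline on one image
#'
#' Measurement path: grayscale, blur, Canny, contours, card calibration,
#' per-slice physical measurement; writes `report.txt` (tab-separated
#' `id long_mm short_mm area_mm2`, one decimal), `report.csv`, and
#' `measurement_overlay.png` (card outlined blue, slices green).
#' If head weights are supplied, the detection head additionally runs on a
#' stub feature pyramid and writes `detections.csv` and
#' `defect_overlay.png`.
#'
#' @param image_path Path to a PNG image containing one reference card.
#' @param out_dir Output directory (created if missing).
#' @param params An [edge_params()].
#' @param card_mm Physical card size in mm (default `c(26, 38)`).
#' @param min_area_px Minimum slice contour area (default 400).
#' @param weights Optional path to [save_head_weights()] output.
#' @param conf_thr,iou_thr Detection decoding thresholds.
#' @return Invisibly, a list with `measurements`, `calibration`,
#'   `detections` (or `NULL`), and the output `paths`. Fails with a
#'   calibration-failure error when no card-like contour is present.
#' @export
run_pipeline <- function(image_path, out_dir, params = edge_params(),
                         card_mm = c(26, 38), min_area_px = 400,
                         weights = NULL, conf_thr = 0.25, iou_thr = 0.45) {
  image <- .read_image(image_path)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- measure_image(image, params, card_mm, min_area_px)

  txt_path <- file.path(out_dir, "report.txt")
  csv_path <- file.path(out_dir, "report.csv")
  .write_report(res$measurements, txt_path, csv_path)

  overlay <- image
  overlay <- .draw_contour(overlay, res$card_contour, c(0, 80, 255))
  for (ct in res$contours) overlay <- .draw_contour(overlay, ct, c(0, 200, 0))
  overlay_path <- file.path(out_dir, "measurement_overlay.png")
  png::writePNG(overlay / 255, overlay_path)

  detections <- NULL
  paths <- c(report_txt = txt_path, report_csv = csv_path,
             measurement_overlay = overlay_path)
  if (!is.null(weights)) {
    p <- load_head_weights(weights)
    feats <- image_pyramid_features(image, p$in_channels, p$strides)
    out <- lsd_head_forward(feats, p)
    detections <- decode_detections(out, p, conf_thr, iou_thr)
    det_csv <- file.path(out_dir, "detections.csv")
    utils::write.csv(detections, det_csv, row.names = FALSE, quote = FALSE)
    defect <- image
    for (r in seq_len(nrow(detections))) {
      defect <- .draw_box(defect, as.numeric(detections[r, c("x1", "y1", "x2", "y2")]))
    }
    defect_path <- file.path(out_dir, "defect_overlay.png")
    png::writePNG(defect / 255, defect_path)
    paths <- c(paths, detections_csv = det_csv, defect_overlay = defect_path)
  }
  invisible(list(measurements = res$measurements, calibration = res$calibration,
                 detections = detections, paths = paths))
}
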