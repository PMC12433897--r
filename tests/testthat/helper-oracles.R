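# Independent oracles used across the suite. These deliberately use naive
# per-element loops so they share no code path with the implementation.

# plain quadruple-loop 2-D convolution (zero-padded, stride 1)
naive_conv2d <- function(x, w) {
  dx <- dim(x); dw <- dim(w)
  n <- dx[1]; cc <- dx[2]; h <- dx[3]; ww <- dx[4]
  o <- dw[1]; kh <- dw[3]; kw <- dw[4]
  ph <- (kh - 1) / 2; pw <- (kw - 1) / 2
  out <- array(0, c(n, o, h, ww))
  for (ni in seq_len(n)) for (oi in seq_len(o)) for (yi in seq_len(h)) for (xi in seq_len(ww)) {
    acc <- 0
    for (ci in seq_len(cc)) for (i in seq_len(kh)) for (j in seq_len(kw)) {
      yy <- yi + i - 1 - ph; xx <- xi + j - 1 - pw
      if (yy >= 1 && yy <= h && xx >= 1 && xx <= ww) {
        acc <- acc + w[oi, ci, i, j] * x[ni, ci, yy, xx]
      }
    }
    out[ni, oi, yi, xi] <- acc
  }
  out
}

# Direct difference-form evaluation of each branch on a single-channel
# image: taps on intensity differences, never building a transformed
# kernel. Zero padding, "same" size.
difference_conv_direct <- function(img, w, kind, pattern = NULL) {
  k <- nrow(w); c0 <- (k + 1) / 2
  h <- nrow(img); ww <- ncol(img)
  at <- function(y, x) if (y >= 1 && y <= h && x >= 1 && x <= ww) img[y, x] else 0
  if (is.null(pattern)) { pattern <- matrix(0, k, k); pattern[c0, c0] <- 1 }
  out <- matrix(0, h, ww)
  for (yi in seq_len(h)) for (xi in seq_len(ww)) {
    acc <- 0
    for (i in seq_len(k)) for (j in seq_len(k)) {
      y <- yi + i - c0; x <- xi + j - c0
      f <- at(y, x)
      acc <- acc + switch(kind,
        vanilla = w[i, j] * f,
        cd = w[i, j] * (f - at(yi, xi)),
        # tap minus its cyclic right/lower neighbor inside the window
        hd = w[i, j] * (f - at(yi + i - c0, xi + (j %% k) + 1 - c0)),
        vd = w[i, j] * (f - at(yi + (i %% k) + 1 - c0, xi + j - c0)),
        ad = {
          ref <- 0
          for (a in seq_len(k)) for (b in seq_len(k)) {
            ref <- ref + pattern[a, b] * at(yi + a - c0, xi + b - c0)
          }
          w[i, j] * (f - ref)
        })
    }
    out[yi, xi] <- acc
  }
  out
}

# explicit double-loop greedy matcher, written independently of the package
brute_match <- function(preds, gts, iou_thr) {
  iou1 <- function(a, b) {
    ix <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
    iy <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
    inter <- ix * iy
    un <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
    if (un <= 0) 0 else inter / un
  }
  tp <- 0; fp <- 0
  taken <- rep(FALSE, nrow(gts))
  for (i in order(-preds$score)) {
    best <- 0; best_j <- 0
    for (j in seq_len(nrow(gts))) {
      if (taken[j]) next
      if (gts$image_id[j] != preds$image_id[i] || gts$class_id[j] != preds$class_id[i]) next
      v <- iou1(as.numeric(preds[i, c("x1", "y1", "x2", "y2")]),
                as.numeric(gts[j, c("x1", "y1", "x2", "y2")]))
      if (v > best) { best <- v; best_j <- j }
    }
    if (best >= iou_thr && best_j > 0) { tp <- tp + 1; taken[best_j] <- TRUE } else fp <- fp + 1
  }
  list(tp = tp, fp = fp, fn = sum(!taken))
}

# dense boundary polygon of a rotated rectangle centered at (cy, cx)
rect_polygon <- function(cy, cx, width, height, angle_deg, n_per_side = 200) {
  th <- angle_deg * pi / 180
  t <- seq(0, 1, length.out = n_per_side)
  u <- c(t * width - width / 2, rep(width / 2, n_per_side),
         width / 2 - t * width, rep(-width / 2, n_per_side))
  v <- c(rep(-height / 2, n_per_side), t * height - height / 2,
         rep(height / 2, n_per_side), height / 2 - t * height)
  cbind(row = cy + u * sin(th) + v * cos(th),
        col = cx + u * cos(th) - v * sin(th))
}

make_gt <- function(...) {
  df <- data.frame(...)
  df
}

# a unit test scene small enough to render quickly
small_scene <- function(seed = 7, noise_sigma = 3, ppm = 10, angle = 25) {
  scene_spec(
    ppm = ppm, image_size_px = c(60 * ppm, 70 * ppm),
    slices = list(ellipse_spec(c(50, 30), 20, 15, angle)),
    card_center_mm = c(18, 30), card_angle_deg = 8,
    noise_sigma = noise_sigma, seed = seed)
}
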