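#' Edge-detection parameters
#'
#' @param t_low,t_high Hysteresis thresholds on the Sobel gradient magnitude
#'   of an 8-bit image; `0 < t_low <= t_high`. Defaults 50/150, common Canny
#'   practice for controlled-contrast scenes.
#' @param blur_kernel Odd Gaussian kernel size (default 5).
#' @param blur_sigma Gaussian s.d. in px (default 1).
#' @return An object of class `edge_params`.
#' @export
edge_params <- function(t_low = 50, t_high = 150, blur_kernel = 5, blur_sigma = 1.0) {
  if (!(t_low > 0 && t_low <= t_high)) {
    stop("thresholds must satisfy 0 < t_low <= t_high", call. = FALSE)
  }
  if (blur_kernel < 1 || blur_kernel %% 2 != 1) {
    stop("blur_kernel must be an odd integer >= 1", call. = FALSE)
  }
  stop_if_not_scalar_pos(blur_sigma, "blur_sigma")
  structure(list(t_low = t_low, t_high = t_high,
                 blur_kernel = as.integer(blur_kernel), blur_sigma = blur_sigma),
            class = "edge_params")
}

#' Convert an RGB image to 8-bit grayscale
#'
#' Uses the ITU-R BT.601 luminance weights `0.299 R + 0.587 G + 0.114 B`,
#' rounded to the nearest integer. Inputs on the `[0, 1]` scale (as returned
#' by [png::readPNG()]) are rescaled to 0--255 first.
#'
#' @param image H x W x 3 numeric array.
#' @return H x W matrix of intensities in 0--255.
#' @export
to_grayscale <- function(image) {
  d <- dim(image)
  if (length(d) != 3L || d[3] != 3L) {
    stop("expected an H x W x 3 RGB array", call. = FALSE)
  }
  if (max(image) <= 1 + 1e-9) image <- image * 255
  g <- 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
  floor(g + 0.5)
}

# symmetric (edge-repeating) padding indices: conserves total intensity
# under a normalized symmetric kernel
.reflect_idx <- function(n, pad) {
  c(rev(seq_len(pad)), seq_len(n), n + 1 - seq_len(pad))
}

.gauss_kernel <- function(size, sigma) {
  half <- (size - 1) / 2
  k <- exp(-((-half):half)^2 / (2 * sigma^2))
  k / sum(k)
}

# separable 1-D convolution along rows then columns with reflective border
.sep_conv <- function(m, k) {
  size <- length(k)
  pad <- (size - 1) / 2
  if (pad == 0) return(m * k)
  h <- nrow(m); w <- ncol(m)
  mp <- m[.reflect_idx(h, pad), , drop = FALSE]
  out <- matrix(0, h, w)
  for (j in seq_len(size)) out <- out + k[j] * mp[(j - 1) + seq_len(h), , drop = FALSE]
  mp <- out[, .reflect_idx(w, pad), drop = FALSE]
  out <- matrix(0, h, w)
  for (j in seq_len(size)) out <- out + k[j] * mp[, (j - 1) + seq_len(w), drop = FALSE]
  out
}

#' Gaussian blur with reflective border
#'
#' Separable Gaussian convolution; the kernel is normalized to sum to one,
#' so constant images are unchanged and, with the symmetric border, total
#' intensity is conserved.
#'
#' @param img Grayscale matrix.
#' @param params An [edge_params()] (uses `blur_kernel`, `blur_sigma`).
#' @return Blurred matrix, same shape.
#' @export
gaussian_blur <- function(img, params = edge_params()) {
  stopifnot(is.matrix(img))
  if (params$blur_kernel %% 2 != 1) stop("blur kernel must be odd", call. = FALSE)
  .sep_conv(img, .gauss_kernel(params$blur_kernel, params$blur_sigma))
}

# 3x3 Sobel responses via shifted sums with edge-replicated padding
.sobel <- function(m) {
  h <- nrow(m); w <- ncol(m)
  p <- m[c(1, seq_len(h), h), c(1, seq_len(w), w)]
  sh <- function(dr, dc) p[dr + seq_len(h), dc + seq_len(w)]
  gx <- (sh(0, 2) + 2 * sh(1, 2) + sh(2, 2)) - (sh(0, 0) + 2 * sh(1, 0) + sh(2, 0))
  gy <- (sh(2, 0) + 2 * sh(2, 1) + sh(2, 2)) - (sh(0, 0) + 2 * sh(0, 1) + sh(0, 2))
  list(gx = gx, gy = gy, mag = sqrt(gx^2 + gy^2))
}

# 8-connected labeling of a sparse binary mask via union-find over its
# foreground pixels (EBImage::bwlabel is 4-connected, which breaks thin
# diagonal edge chains)
.label8_sparse <- function(mask) {
  idx <- which(mask > 0)
  n <- length(idx)
  labels <- integer(length(mask))
  if (n == 0) return(matrix(labels, nrow(mask), ncol(mask)))
  h <- nrow(mask)
  pos <- integer(length(mask))
  pos[idx] <- seq_len(n)
  r <- ((idx - 1) %% h) + 1
  cc <- ((idx - 1) %/% h) + 1
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  # forward neighbors: E, S, SE, SW
  offs <- list(c(0, 1), c(1, 0), c(1, 1), c(-1, 1))
  w <- ncol(mask)
  for (o in offs) {
    rr <- r + o[1]; ccn <- cc + o[2]
    ok <- rr >= 1 & rr <= h & ccn >= 1 & ccn <= w
    ni <- (ccn[ok] - 1) * h + rr[ok]
    src <- which(ok)[pos[ni] > 0]
    dst <- pos[ni][pos[ni] > 0]
    for (k in seq_along(src)) {
      a <- find(src[k]); b <- find(dst[k])
      if (a != b) parent[b] <- a
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  labels[idx] <- match(roots, unique(roots))
  matrix(labels, nrow(mask), ncol(mask))
}

#' Canny edge map
#'
#' Sobel gradient magnitude, non-maximum suppression along the quantized
#' gradient direction, then dual-threshold hysteresis: pixels with magnitude
#' `>= t_high` are strong edges; pixels `>= t_low` survive only when
#' 8-connected to a strong edge. The thresholding step corresponds to the
#' strong-edge test; the hysteresis pair suppresses insignificant edges
#' while keeping key edges contiguous. Being gradient-based, the result is
#' invariant to adding a constant intensity.
#'
#' @param img Blurred grayscale matrix (apply [gaussian_blur()] first).
#' @param params An [edge_params()].
#' @return Binary H x W matrix (1 = edge).
#' @export
edge_map <- function(img, params = edge_params()) {
  stopifnot(is.matrix(img))
  if (params$t_low > params$t_high) stop("t_low must be <= t_high", call. = FALSE)
  s <- .sobel(img)
  h <- nrow(img); w <- ncol(img)

  # quantize gradient orientation into 4 sectors (mod pi)
  ang <- atan2(s$gy, s$gx)
  ang <- ang %% pi
  sector <- as.integer(floor((ang + pi / 8) / (pi / 4))) %% 4L
  # sector 0: E-W, 1: SE-NW, 2: N-S, 3: NE-SW (row grows downward)
  dr <- c(0L, 1L, 1L, 1L)[sector + 1L]
  dc <- c(1L, 1L, 0L, -1L)[sector + 1L]

  pmag <- matrix(0, h + 2, w + 2)
  pmag[1 + seq_len(h), 1 + seq_len(w)] <- s$mag
  rows <- rep(seq_len(h), times = w)
  cols <- rep(seq_len(w), each = h)
  n_plus <- matrix(pmag[cbind(rows + dr + 1L, cols + dc + 1L)], h, w)
  n_minus <- matrix(pmag[cbind(rows - dr + 1L, cols - dc + 1L)], h, w)
  # >= toward the positive direction, strict > toward the negative one:
  # keeps exactly one pixel of a two-pixel plateau
  nms <- s$mag * (s$mag >= n_plus & s$mag > n_minus)

  strong <- nms >= params$t_high
  weak <- nms >= params$t_low
  if (!any(strong)) return(matrix(0L, h, w))
  labels <- .label8_sparse(weak)
  keep_labels <- unique(labels[strong])
  mask <- matrix(0L, h, w)
  mask[weak & (labels %in% keep_labels)] <- 1L
  mask
}
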