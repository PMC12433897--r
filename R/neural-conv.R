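#' 2-D convolution on N x C x H x W tensors
#'
#' Stride-1, zero-padded "same" convolution (cross-correlation convention,
#' as in deep-learning frameworks). Implemented as k^2 accumulated matrix
#' products, which keeps the loop count independent of image size.
#'
#' @param x Input array of dim `c(N, C, H, W)`.
#' @param w Kernel array of dim `c(O, C, kh, kw)` with odd `kh`, `kw`.
#' @param bias Optional length-`O` bias vector.
#' @return Array of dim `c(N, O, H, W)`.
#' @export
conv2d <- function(x, w, bias = NULL) {
  dx <- dim(x); dw <- dim(w)
  if (length(dx) != 4L) stop("x must be a 4-D N x C x H x W array", call. = FALSE)
  if (length(dw) != 4L || dw[2] != dx[2]) {
    stop("kernel must be O x C x kh x kw with C matching the input", call. = FALSE)
  }
  n <- dx[1]; cc <- dx[2]; h <- dx[3]; ww <- dx[4]
  o <- dw[1]; kh <- dw[3]; kw <- dw[4]
  if (kh %% 2 != 1 || kw %% 2 != 1) stop("kernel size must be odd", call. = FALSE)
  ph <- (kh - 1) / 2; pw <- (kw - 1) / 2
  xp <- array(0, c(n, cc, h + 2 * ph, ww + 2 * pw))
  xp[, , ph + seq_len(h), pw + seq_len(ww)] <- x
  acc <- matrix(0, o, n * h * ww)
  for (i in seq_len(kh)) {
    for (j in seq_len(kw)) {
      patch <- xp[, , (i - 1) + seq_len(h), (j - 1) + seq_len(ww), drop = FALSE]
      pm <- matrix(aperm(patch, c(2, 1, 3, 4)), nrow = cc)
      wm <- matrix(w[, , i, j], nrow = o, ncol = cc)
      acc <- acc + wm %*% pm
    }
  }
  out <- aperm(array(acc, c(o, n, h, ww)), c(2, 1, 3, 4))
  if (!is.null(bias)) {
    stopifnot(length(bias) == o)
    out <- out + aperm(array(bias, c(o, n, h, ww)), c(2, 1, 3, 4))
  }
  out
}

#' Transform a difference-convolution kernel to its vanilla equivalent
#'
#' Each difference convolution computes taps on intensity *differences*
#' rather than raw intensities; by linearity every variant collapses to an
#' ordinary convolution with a transformed kernel:
#'
#' * `vanilla` — identity.
#' * `cd` (center difference) — `sum_p w(p) (F(p) - F(center))`: the center
#'   weight becomes `w(center) - sum(w)`.
#' * `hd` / `vd` (horizontal / vertical difference) — each weight minus its
#'   left / upper neighbor within the kernel window (cyclically), i.e.
#'   taps on adjacent-column / adjacent-row differences; transformed rows /
#'   columns sum to zero.
#' * `ad` (adaptive difference) — `sum_p w(p) (F(p) - sum_q a(q) F(q))` with
#'   a learnable reference pattern `a`; with `a` one-hot at the center this
#'   is exactly the center difference, which is its initialization.
#'
#' @param kind One of `"vanilla"`, `"cd"`, `"hd"`, `"vd"`, `"ad"`.
#' @param w A k x k matrix or an `O x C x k x k` array (odd k); transforms
#'   are applied to each k x k slice.
#' @param pattern For `kind = "ad"`: k x k reference pattern `a`; defaults
#'   to one-hot at the center.
#' @return Transformed weights, same shape as `w`.
#' @export
transform_kernel <- function(kind, w, pattern = NULL) {
  kinds <- c("vanilla", "cd", "hd", "vd", "ad")
  if (!kind %in% kinds) {
    stop(sprintf("unknown kernel kind '%s'", kind), call. = FALSE)
  }
  tx <- function(m) {
    k <- nrow(m)
    if (k %% 2 != 1 || ncol(m) != k) stop("kernels must be odd square", call. = FALSE)
    c0 <- (k + 1) / 2
    switch(kind,
      vanilla = m,
      cd = { m2 <- m; m2[c0, c0] <- m[c0, c0] - sum(m); m2 },
      hd = m - m[, c(k, seq_len(k - 1)), drop = FALSE],
      vd = m - m[c(k, seq_len(k - 1)), , drop = FALSE],
      ad = {
        a <- pattern
        if (is.null(a)) { a <- matrix(0, k, k); a[c0, c0] <- 1 }
        stopifnot(all(dim(a) == c(k, k)))
        m - a * sum(m)
      })
  }
  if (is.matrix(w)) return(tx(w))
  dw <- dim(w)
  stopifnot(length(dw) == 4L)
  out <- w
  for (o in seq_len(dw[1])) for (ci in seq_len(dw[2])) {
    out[o, ci, , ] <- tx(matrix(w[o, ci, , ], dw[3], dw[4]))
  }
  out
}

#' Create a bank of the five detail-enhancing convolution branches
#'
#' Five parallel k x k convolution branches — vanilla, center-, horizontal-,
#' vertical- and adaptive-difference — whose transformed kernels sum into a
#' single equivalent kernel at inference (structural reparameterization).
#'
#' @param c_in,c_out Channel counts.
#' @param k Odd kernel size (default 3).
#' @param seed Integer seed for the random weight initialization.
#' @param pattern Adaptive-difference reference pattern (see
#'   [transform_kernel()]); default one-hot at the center.
#' @return Object of class `kernel_bank`: list with `kinds`, `weights`
#'   (list of five `c_out x c_in x k x k` arrays), `pattern`, and `merged`
#'   (`NULL` until [merge_kernels()] is called).
#' @export
kernel_bank <- function(c_in, c_out, k = 3, seed = 1L, pattern = NULL) {
  stopifnot(k %% 2 == 1)
  kinds <- c("vanilla", "cd", "hd", "vd", "ad")
  sdev <- 1 / sqrt(c_in * k * k)
  weights <- withr::with_seed(as.integer(seed), {
    lapply(kinds, function(kind) {
      array(stats::rnorm(c_out * c_in * k * k, 0, sdev), c(c_out, c_in, k, k))
    })
  })
  names(weights) <- kinds
  structure(list(kinds = kinds, weights = weights, pattern = pattern,
                 k = as.integer(k), c_in = as.integer(c_in),
                 c_out = as.integer(c_out), merged = NULL),
            class = "kernel_bank")
}

#' Merge the five branch kernels into the equivalent single kernel
#'
#' Elementwise sum of the five transformed kernels: convolving once with
#' the merged kernel equals summing the five branch outputs.
#'
#' @param bank A [kernel_bank()].
#' @return The bank with `$merged` set to the `c_out x c_in x k x k`
#'   equivalent kernel.
#' @export
merge_kernels <- function(bank) {
  stopifnot(inherits(bank, "kernel_bank"))
  shapes <- lapply(bank$weights, dim)
  if (!all(vapply(shapes, identical, logical(1), shapes[[1]]))) {
    stop("branch kernels must share one shape", call. = FALSE)
  }
  merged <- array(0, dim(bank$weights[[1]]))
  for (kind in bank$kinds) {
    merged <- merged + transform_kernel(kind, bank$weights[[kind]], bank$pattern)
  }
  bank$merged <- merged
  bank
}

#' Detail-enhancing convolution forward pass
#'
#' @param x Input array `c(N, C, H, W)` with `C = bank$c_in`.
#' @param bank A [kernel_bank()].
#' @param mode `"merged"` (single convolution with the equivalent kernel;
#'   the inference path) or `"parallel"` (sum of the five branch outputs;
#'   the training-time view). The two agree to numerical precision.
#' @return Array `c(N, c_out, H, W)`; spatial size is preserved.
#' @export
deconv_forward <- function(x, bank, mode = c("merged", "parallel")) {
  mode <- match.arg(mode)
  stopifnot(inherits(bank, "kernel_bank"))
  if (dim(x)[2] != bank$c_in) stop("channel count does not match bank", call. = FALSE)
  if (mode == "merged") {
    if (is.null(bank$merged)) bank <- merge_kernels(bank)
    return(conv2d(x, bank$merged))
  }
  out <- NULL
  for (kind in bank$kinds) {
    y <- conv2d(x, transform_kernel(kind, bank$weights[[kind]], bank$pattern))
    out <- if (is.null(out)) y else out + y
  }
  out
}
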