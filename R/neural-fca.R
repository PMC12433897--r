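#' Global average pooling
#'
#' Channel-wise spatial mean of a feature map.
#'
#' @param x Array `c(N, C, H, W)`.
#' @return `N x C` matrix of channel means.
#' @export
gap <- function(x) {
  stopifnot(length(dim(x)) == 4L)
  apply(x, c(1, 2), mean)
}

#' Parameters of the fine-grained channel attention
#'
#' The attention fuses two views of the pooled channel vector `U`: a local
#' view `Ulc` from a width-`k` 1-D convolution across the channel axis
#' (circular padding), and a global view `Ugc` from a learnable per-channel
#' diagonal scaling. Their outer product forms a cross-correlation matrix
#' whose row and column means are blended through a learnable scalar
#' `theta`.
#'
#' @param channels Channel count `C`.
#' @param k Odd width of the 1-D channel convolution; default 3, the
#'   minimal local-context choice.
#' @param seed Seed for the random initialization.
#' @param theta Initial fusion scalar (default 0, an even blend since
#'   `sigmoid(0) = 0.5`).
#' @return Object of class `fca_params`: list with `b` (length-`k` 1-D
#'   kernel), `d` (length-`C` diagonal), `theta`, `k`, `channels`.
#' @export
fca_params <- function(channels, k = 3, seed = 1L, theta = 0) {
  stopifnot(channels >= 1, k %% 2 == 1)
  init <- withr::with_seed(as.integer(seed), list(
    b = stats::rnorm(k, 0, 1 / sqrt(k)),
    d = stats::rnorm(channels, 1, 0.1)))
  structure(list(b = init$b, d = init$d, theta = theta,
                 k = as.integer(k), channels = as.integer(channels)),
            class = "fca_params")
}

#' Compute fine-grained channel attention weights
#'
#' Pipeline per sample: `U = gap(F)`; `Ulc = circular 1-D conv of U with b`;
#' `Ugc = d * U`; cross-correlation `M = Ugc %o% Ulc` (C x C);
#' `Uwgc = rowMeans(M)`, `Uwlc = colMeans(M)` (each branch's view of the
#' cross-correlation); final weights
#' `W = sigmoid(sigmoid(theta) * sigmoid(Uwgc) + (1 - sigmoid(theta)) * sigmoid(Uwlc))`.
#' All weights are strictly inside `(0, 1)`.
#'
#' @param x Feature map `c(N, C, H, W)`.
#' @param p An [fca_params()] with matching channel count.
#' @return Object of class `channel_weights`: list with `w` (`N x C`
#'   weights) and intermediates `U`, `Ulc`, `Ugc`, `M` (list of per-sample
#'   C x C matrices), `Uwgc`, `Uwlc`.
#' @export
fca_weights <- function(x, p) {
  stopifnot(inherits(p, "fca_params"))
  if (dim(x)[2] != p$channels) stop("channel count does not match params", call. = FALSE)
  u <- gap(x)                                  # N x C
  n <- nrow(u); cc <- ncol(u)
  half <- (p$k - 1) / 2
  # circular 1-D convolution across channels
  ulc <- matrix(0, n, cc)
  for (j in seq_len(p$k)) {
    shift <- j - 1 - half
    idx <- ((seq_len(cc) - 1 + shift) %% cc) + 1
    ulc <- ulc + p$b[j] * u[, idx, drop = FALSE]
  }
  ugc <- sweep(u, 2, p$d, `*`)
  m_list <- vector("list", n)
  uwgc <- matrix(0, n, cc); uwlc <- matrix(0, n, cc)
  for (i in seq_len(n)) {
    m <- outer(ugc[i, ], ulc[i, ])             # C x C
    m_list[[i]] <- m
    uwgc[i, ] <- rowMeans(m)
    uwlc[i, ] <- colMeans(m)
  }
  st <- sigmoid(p$theta)
  w <- sigmoid(st * sigmoid(uwgc) + (1 - st) * sigmoid(uwlc))
  structure(list(w = w, U = u, Ulc = ulc, Ugc = ugc, M = m_list,
                 Uwgc = uwgc, Uwlc = uwlc),
            class = "channel_weights")
}

#' Apply channel attention weights to a feature map
#'
#' Channel-wise broadcast multiply `F* = W (x) F`; shape is preserved.
#'
#' @param x Feature map `c(N, C, H, W)`.
#' @param w A [fca_weights()] result or an `N x C` weight matrix.
#' @return Weighted feature map, same shape as `x`.
#' @export
fca_apply <- function(x, w) {
  if (inherits(w, "channel_weights")) w <- w$w
  d <- dim(x)
  stopifnot(length(d) == 4L, all(dim(w) == d[1:2]))
  x * array(rep(as.vector(w), times = d[3] * d[4]), dim = d)
}
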