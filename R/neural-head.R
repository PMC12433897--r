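#' Group normalization
#'
#' Per-sample, per-group standardization over `(C/groups) x H x W`
#' elements; batch-size independent. Without an affine transform the output
#' of each group has zero mean and (eps-stabilized) unit variance.
#'
#' @param x Array `c(N, C, H, W)` with `C` divisible by `groups`.
#' @param groups Number of channel groups.
#' @param eps Variance stabilizer (default 1e-5).
#' @param gamma,beta Optional per-channel affine parameters (length `C`).
#' @return Normalized array, same shape.
#' @export
group_norm <- function(x, groups, eps = 1e-5, gamma = NULL, beta = NULL) {
  d <- dim(x)
  stopifnot(length(d) == 4L)
  n <- d[1]; cc <- d[2]
  if (cc %% groups != 0) stop("C must be divisible by groups", call. = FALSE)
  per <- cc %/% groups
  out <- x
  for (i in seq_len(n)) {
    for (g in seq_len(groups)) {
      ch <- ((g - 1) * per + 1):(g * per)
      v <- x[i, ch, , , drop = FALSE]
      mu <- mean(v)
      va <- mean((v - mu)^2)
      out[i, ch, , ] <- (v - mu) / sqrt(va + eps)
    }
  }
  if (!is.null(gamma)) {
    stopifnot(length(gamma) == cc)
    out <- out * aperm(array(gamma, c(cc, n, d[3], d[4])), c(2, 1, 3, 4))
  }
  if (!is.null(beta)) {
    stopifnot(length(beta) == cc)
    out <- out + aperm(array(beta, c(cc, n, d[3], d[4])), c(2, 1, 3, 4))
  }
  out
}

#' Parameters of the lightweight shared detection head
#'
#' Per pyramid level, a 1 x 1 convolution reduces channels to a common
#' hidden width; a single detail-enhancing convolution (with group
#' normalization and SiLU) and single 1 x 1 classification and regression
#' layers are then *shared across levels*, with a learnable per-level
#' scalar rescaling the regression output to compensate for stride
#' differences. Sharing removes the per-level copies of the heaviest
#' layers, which is where the parameter saving comes from.
#'
#' @param in_channels Per-level input channel counts (default
#'   `c(64, 128, 256)`).
#' @param hidden Width after the 1 x 1 reduction (default 64).
#' @param nc Number of classes (default 3 varieties).
#' @param reg_max Number of distribution bins per box side (default 16).
#' @param strides Per-level strides (default `c(8, 16, 32)`).
#' @param gn_groups Groups of the shared group normalization (default 8).
#' @param seed Seed for weight initialization.
#' @return Object of class `head_params`.
#' @export
head_params <- function(in_channels = c(64, 128, 256), hidden = 64, nc = 3,
                        reg_max = 16, strides = c(8, 16, 32), gn_groups = 8,
                        seed = 1L) {
  stopifnot(length(in_channels) == length(strides), reg_max >= 2,
            hidden %% gn_groups == 0)
  seed <- as.integer(seed)
  reduce <- withr::with_seed(seed, lapply(in_channels, function(ci) {
    array(stats::rnorm(hidden * ci, 0, 1 / sqrt(ci)), c(hidden, ci, 1, 1))
  }))
  shared_deconv <- kernel_bank(hidden, hidden, k = 3, seed = seed + 1L)
  cls_reg <- withr::with_seed(seed + 2L, list(
    cls_w = array(stats::rnorm(nc * hidden, 0, 1 / sqrt(hidden)), c(nc, hidden, 1, 1)),
    reg_w = array(stats::rnorm(4 * reg_max * hidden, 0, 1 / sqrt(hidden)),
                  c(4 * reg_max, hidden, 1, 1))))
  structure(list(
    in_channels = as.integer(in_channels), hidden = as.integer(hidden),
    nc = as.integer(nc), reg_max = as.integer(reg_max),
    strides = as.numeric(strides), gn_groups = as.integer(gn_groups),
    reduce = reduce, shared_deconv = merge_kernels(shared_deconv),
    cls_w = cls_reg$cls_w, cls_b = rep(0, nc),
    reg_w = cls_reg$reg_w, reg_b = rep(0, 4 * reg_max),
    level_scales = rep(1, length(strides))),
    class = "head_params")
}

#' Forward pass of the shared detection head
#'
#' @param levels List of feature maps `c(N, C_l, H_l, W_l)`, one per stride,
#'   channels matching `p$in_channels`.
#' @param p A [head_params()].
#' @return Object of class `detection_output`: list with `levels` (each
#'   holding `cls` logits `N x nc x H x W` and `reg` logits
#'   `N x 4*reg_max x H x W`, spatial dims matching the input level) and
#'   `strides`.
#' @export
lsd_head_forward <- function(levels, p) {
  stopifnot(inherits(p, "head_params"))
  if (length(levels) != length(p$strides)) {
    stop("wrong number of pyramid levels", call. = FALSE)
  }
  out <- vector("list", length(levels))
  for (l in seq_along(levels)) {
    x <- levels[[l]]
    if (dim(x)[2] != p$in_channels[l]) {
      stop(sprintf("level %d has %d channels, expected %d",
                   l, dim(x)[2], p$in_channels[l]), call. = FALSE)
    }
    h <- conv2d(x, p$reduce[[l]])
    h <- deconv_forward(h, p$shared_deconv, mode = "merged")
    h <- group_norm(h, p$gn_groups)
    h <- silu(h)
    cls <- conv2d(h, p$cls_w, p$cls_b)
    reg <- conv2d(h, p$reg_w, p$reg_b) * p$level_scales[l]
    out[[l]] <- list(cls = cls, reg = reg)
  }
  structure(list(levels = out, strides = p$strides), class = "detection_output")
}

#' Parameter count of the head, shared vs. per-level copies
#'
#' @param p A [head_params()].
#' @param shared If `FALSE`, counts an equivalent head in which the
#'   detail-enhancing convolution and the classification/regression layers
#'   are duplicated per level instead of shared.
#' @return Integer parameter count.
#' @export
head_n_params <- function(p, shared = TRUE) {
  n_levels <- length(p$strides)
  reduce_n <- sum(vapply(p$reduce, length, numeric(1)))
  deconv_n <- sum(vapply(p$shared_deconv$weights, length, numeric(1)))
  cls_n <- length(p$cls_w) + length(p$cls_b)
  reg_n <- length(p$reg_w) + length(p$reg_b)
  shared_part <- deconv_n + cls_n + reg_n
  reduce_n + n_levels + if (shared) shared_part else n_levels * shared_part
}

#' Decode distribution-based box regressions
#'
#' Each box side is predicted as a discrete distribution over
#' `0 .. reg_max-1` bins; the decoded side distance is the distribution's
#' expectation (softmax then `sum(b * p(b))`) times the level stride. The
#' four sides are offsets left/top/right/bottom from the anchor point (the
#' cell center), giving `(x1, y1, x2, y2)` boxes clamped so `x2 >= x1`,
#' `y2 >= y1`.
#'
#' @param reg_logits Array `c(N, 4*reg_max, H, W)`.
#' @param reg_max Bin count.
#' @param stride Level stride in px.
#' @param anchor_points Optional `(H*W) x 2` matrix of `(x, y)` anchor
#'   centers in image px; defaults to the stride-scaled cell centers.
#' @return Array `c(N, 4, H, W)` of box coordinates `(x1, y1, x2, y2)`.
#' @export
dfl_decode <- function(reg_logits, reg_max, stride, anchor_points = NULL) {
  d <- dim(reg_logits)
  stopifnot(length(d) == 4L)
  if (d[2] != 4 * reg_max) {
    stop("regression channel count must equal 4 * reg_max", call. = FALSE)
  }
  n <- d[1]; h <- d[3]; w <- d[4]
  # channel layout: reg_max contiguous bins per side (l, t, r, b)
  probs <- array(reg_logits, c(n, reg_max, 4, h, w))
  probs <- exp(sweep(probs, c(1, 3, 4, 5), apply(probs, c(1, 3, 4, 5), max), `-`))
  probs <- sweep(probs, c(1, 3, 4, 5), apply(probs, c(1, 3, 4, 5), sum), `/`)
  bins <- array(rep(0:(reg_max - 1), each = n), c(n, reg_max, 4, h, w))
  dist <- apply(probs * bins, c(1, 3, 4, 5), sum) * stride  # N x 4 x H x W
  if (is.null(anchor_points)) {
    ax <- (matrix(rep(seq_len(w), each = h), h, w) - 0.5) * stride
    ay <- (matrix(rep(seq_len(h), times = w), h, w) - 0.5) * stride
  } else {
    stopifnot(nrow(anchor_points) == h * w)
    ax <- matrix(anchor_points[, 1], h, w)
    ay <- matrix(anchor_points[, 2], h, w)
  }
  out <- array(0, c(n, 4, h, w))
  for (i in seq_len(n)) {
    out[i, 1, , ] <- ax - dist[i, 1, , ]
    out[i, 2, , ] <- ay - dist[i, 2, , ]
    out[i, 3, , ] <- pmax(ax + dist[i, 3, , ], out[i, 1, , ])
    out[i, 4, , ] <- pmax(ay + dist[i, 4, , ], out[i, 2, , ])
  }
  out
}

#' Greedy non-maximum suppression
#'
#' Standard score-descending greedy NMS used only to emit discrete
#' detections; ties are broken by insertion order.
#'
#' @param boxes m x 4 matrix `(x1, y1, x2, y2)`.
#' @param scores Length-m score vector.
#' @param iou_thr Overlap threshold (default 0.45).
#' @return Integer indices of the kept boxes, in score order.
#' @export
nms_boxes <- function(boxes, scores, iou_thr = 0.45) {
  if (length(scores) == 0) return(integer(0))
  ord <- order(scores, decreasing = TRUE)
  keep <- integer(0)
  while (length(ord) > 0) {
    i <- ord[1]
    keep <- c(keep, i)
    ord <- ord[-1]
    if (length(ord) > 0) {
      ious <- vapply(ord, function(j) box_iou(boxes[i, ], boxes[j, ]), numeric(1))
      ord <- ord[ious <= iou_thr]
    }
  }
  keep
}

#' Save / load head weights
#'
#' Serializes the [head_params()] list (documented, flat named schema:
#' `reduce`, `shared_deconv$weights`, `cls_w`, `cls_b`, `reg_w`, `reg_b`,
#' `level_scales`, plus the integer configuration fields) so fixture
#' weights are reproducible across sessions.
#'
#' @param p A [head_params()].
#' @param path File path.
#' @return `save_head_weights`: the path, invisibly. `load_head_weights`:
#'   the restored `head_params`.
#' @export
save_head_weights <- function(p, path) {
  stopifnot(inherits(p, "head_params"))
  saveRDS(unclass(p), path)
  invisible(path)
}

#' @rdname save_head_weights
#' @export
load_head_weights <- function(path) {
  p <- readRDS(path)
  structure(p, class = "head_params")
}
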