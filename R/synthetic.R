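#' Specify an elliptical slice for a synthetic scene
#'
#' Slices are modeled as rotated ellipses with known physical axes, the
#' ground-truth stand-in for caliper-measured long/short diameters.
#'
#' @param center_mm Numeric length-2, `(x, y)` center in mm from the top-left
#'   image corner (x along columns, y along rows).
#' @param long_axis_mm,short_axis_mm Full axis lengths in mm. Must satisfy
#'   `long_axis_mm >= short_axis_mm > 0` and lie within 5--40 mm, the
#'   realistic size range of decoction slices.
#' @param angle_deg Rotation of the long axis, degrees counter-clockwise from
#'   the x (column) axis.
#' @return An object of class `ellipse_spec`.
#' @export
ellipse_spec <- function(center_mm, long_axis_mm, short_axis_mm, angle_deg = 0) {
  stopifnot(length(center_mm) == 2L, is.finite(center_mm))
  stop_if_not_scalar_pos(long_axis_mm, "long_axis_mm")
  stop_if_not_scalar_pos(short_axis_mm, "short_axis_mm")
  if (short_axis_mm > long_axis_mm) {
    stop("long_axis_mm must be >= short_axis_mm", call. = FALSE)
  }
  if (long_axis_mm > 40 || short_axis_mm < 5) {
    stop("axes must lie within 5-40 mm", call. = FALSE)
  }
  structure(
    list(center_mm = as.numeric(center_mm), long_axis_mm = long_axis_mm,
         short_axis_mm = short_axis_mm, angle_deg = angle_deg),
    class = "ellipse_spec"
  )
}

#' Specify a synthetic measurement scene
#'
#' A scene emulates the controlled acquisition setup the measurement pipeline
#' is designed for: a uniform backplate, bright quasi-elliptical slices, and
#' exactly one rectangular reference card of known physical size placed in
#' the frame. The card is rendered at an intensity distinct from the slices
#' so that identifying it must rely on its aspect ratio, which is the
#' mechanism the calibration stage actually uses.
#'
#' @param ppm Pixels per millimeter of the rendering (> 0).
#' @param image_size_px Integer length-2 `(H, W)` in pixels.
#' @param slices List of [ellipse_spec()] objects (may be empty).
#' @param card_center_mm `(x, y)` card center in mm.
#' @param card_angle_deg Card rotation in degrees.
#' @param card_size_mm Physical card size `(width, height)` in mm; default
#'   `c(26, 38)`, the printed size of the ID-card-shaped reference board.
#' @param background_level,foreground_level,card_level Intensities in 0--255.
#'   Both foreground and card must exceed the background by at least 60 so
#'   edges are detectable.
#' @param noise_sigma Additive Gaussian noise s.d. in intensity units,
#'   clipped to `[0, 255]`; default 3, mild sensor noise consistent with
#'   indoor imaging.
#' @param seed Integer seed; rendering with the same spec is bit-identical.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(ppm, image_size_px, slices = list(),
                       card_center_mm, card_angle_deg = 0,
                       card_size_mm = c(26, 38),
                       background_level = 20, foreground_level = 200,
                       card_level = 120, noise_sigma = 3, seed = 1L) {
  stop_if_not_scalar_pos(ppm, "ppm")
  stopifnot(length(image_size_px) == 2L, image_size_px >= 8,
            length(card_size_mm) == 2L, card_size_mm > 0,
            length(card_center_mm) == 2L, noise_sigma >= 0)
  if (foreground_level - background_level < 60 || card_level - background_level < 60) {
    stop("foreground and card levels must exceed background by >= 60", call. = FALSE)
  }
  for (s in slices) {
    if (!inherits(s, "ellipse_spec")) stop("slices must be ellipse_spec objects", call. = FALSE)
  }
  structure(
    list(ppm = ppm, image_size_px = as.integer(image_size_px), slices = slices,
         card_center_mm = as.numeric(card_center_mm),
         card_angle_deg = card_angle_deg, card_size_mm = as.numeric(card_size_mm),
         background_level = background_level, foreground_level = foreground_level,
         card_level = card_level, noise_sigma = noise_sigma, seed = as.integer(seed)),
    class = "scene_spec"
  )
}

# Pixel-center coordinate grids in px units (x along columns, y along rows).
.pixel_grid <- function(h, w) {
  list(x = matrix(rep(seq_len(w) - 0.5, each = h), h, w),
       y = matrix(rep(seq_len(h) - 0.5, times = w), h, w))
}

# Signed distance (px) from pixel centers to an ellipse boundary,
# first-order approximation valid for semi-axes >> 1 px.
.ellipse_sdf <- function(grid, cx, cy, a, b, angle_deg) {
  th <- angle_deg * pi / 180
  u <- cos(th) * (grid$x - cx) + sin(th) * (grid$y - cy)
  v <- -sin(th) * (grid$x - cx) + cos(th) * (grid$y - cy)
  q <- sqrt((u / a)^2 + (v / b)^2)
  g <- sqrt(u^2 / a^4 + v^2 / b^4)
  d <- ifelse(q > 1e-12, (q - 1) * q / pmax(g, 1e-12), -pmin(a, b))
  d
}

.rect_sdf <- function(grid, cx, cy, hw, hh, angle_deg) {
  th <- angle_deg * pi / 180
  u <- cos(th) * (grid$x - cx) + sin(th) * (grid$y - cy)
  v <- -sin(th) * (grid$x - cx) + cos(th) * (grid$y - cy)
  dx <- abs(u) - hw
  dy <- abs(v) - hh
  pmin(pmax(dx, dy), 0) + sqrt(pmax(dx, 0)^2 + pmax(dy, 0)^2)
}

# Anti-aliased coverage from a signed distance field: soft 1-px ramp.
.coverage <- function(d) pmin(pmax(0.5 - d, 0), 1)

#' Render a synthetic scene with exact ground truth
#'
#' Shapes are drawn with an anti-aliased 1-px edge ramp so that sub-pixel
#' measurement error behaves realistically rather than staircase-exactly.
#' Seeded Gaussian noise is added last and clipped to `[0, 255]`.
#'
#' @param spec A [scene_spec()].
#' @return A list with `image` (H x W x 3 numeric array, 0--255 integers) and
#'   `truth`, a data frame with columns `object_id`, `long_mm`, `short_mm`,
#'   `area_mm2`, `card_flag` plus center/angle columns used by tests. The
#'   card is row `object_id = 0`; ellipse areas are `pi * a * b / 4`.
#' @export
render_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  h <- spec$image_size_px[1]; w <- spec$image_size_px[2]
  ppm <- spec$ppm
  grid <- .pixel_grid(h, w)

  # bounds check: every shape fully inside with >= 2 px margin
  margin <- 2
  check_inside <- function(cx, cy, ex, ey, id) {
    if (cx - ex < margin || cx + ex > w - margin ||
        cy - ey < margin || cy + ey > h - margin) {
      stop(sprintf("shape out of bounds: object %s", id), call. = FALSE)
    }
  }

  canvas <- matrix(spec$background_level, h, w)
  paint <- function(canvas, cov, level) canvas * (1 - cov) + level * cov

  # reference card
  th <- spec$card_angle_deg * pi / 180
  hw <- spec$card_size_mm[1] / 2 * ppm
  hh <- spec$card_size_mm[2] / 2 * ppm
  cx <- spec$card_center_mm[1] * ppm; cy <- spec$card_center_mm[2] * ppm
  check_inside(cx, cy, abs(hw * cos(th)) + abs(hh * sin(th)),
               abs(hw * sin(th)) + abs(hh * cos(th)), 0)
  canvas <- paint(canvas, .coverage(.rect_sdf(grid, cx, cy, hw, hh, spec$card_angle_deg)),
                  spec$card_level)

  rows <- list(data.frame(
    object_id = 0L,
    long_mm = max(spec$card_size_mm), short_mm = min(spec$card_size_mm),
    area_mm2 = prod(spec$card_size_mm), card_flag = TRUE,
    center_x_mm = spec$card_center_mm[1], center_y_mm = spec$card_center_mm[2],
    angle_deg = spec$card_angle_deg
  ))

  for (i in seq_along(spec$slices)) {
    s <- spec$slices[[i]]
    a <- s$long_axis_mm / 2 * ppm; b <- s$short_axis_mm / 2 * ppm
    thi <- s$angle_deg * pi / 180
    cx <- s$center_mm[1] * ppm; cy <- s$center_mm[2] * ppm
    check_inside(cx, cy, sqrt((a * cos(thi))^2 + (b * sin(thi))^2),
                 sqrt((a * sin(thi))^2 + (b * cos(thi))^2), i)
    canvas <- paint(canvas, .coverage(.ellipse_sdf(grid, cx, cy, a, b, s$angle_deg)),
                    spec$foreground_level)
    rows[[i + 1L]] <- data.frame(
      object_id = i,
      long_mm = s$long_axis_mm, short_mm = s$short_axis_mm,
      area_mm2 = pi * s$long_axis_mm * s$short_axis_mm / 4, card_flag = FALSE,
      center_x_mm = s$center_mm[1], center_y_mm = s$center_mm[2],
      angle_deg = s$angle_deg
    )
  }

  if (spec$noise_sigma > 0) {
    canvas <- canvas + withr::with_seed(
      spec$seed, matrix(stats::rnorm(h * w, 0, spec$noise_sigma), h, w))
  }
  canvas <- pmin(pmax(floor(canvas + 0.5), 0), 255)

  image <- array(canvas, dim = c(h, w, 3))
  truth <- do.call(rbind, rows)
  list(image = image, truth = truth)
}

#' Write a rendered scene to disk
#'
#' @param scene Result of [render_scene()].
#' @param dir Output directory (created if missing).
#' @param stem File stem; writes `<stem>.png` and `<stem>_truth.csv` with
#'   header `object_id,long_mm,short_mm,area_mm2,card_flag`.
#' @return Invisibly, the two paths written.
#' @export
write_scene <- function(scene, dir, stem = "scene") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  png_path <- file.path(dir, paste0(stem, ".png"))
  csv_path <- file.path(dir, paste0(stem, "_truth.csv"))
  png::writePNG(scene$image / 255, png_path)
  utils::write.csv(
    scene$truth[, c("object_id", "long_mm", "short_mm", "area_mm2", "card_flag")],
    csv_path, row.names = FALSE, quote = FALSE)
  invisible(c(png = png_path, csv = csv_path))
}

#' Draw a random measurement scene specification
#'
#' The sampler reproduces the study conditions the pipeline is validated
#' under: 3--6 well-separated elliptical slices 10--30 mm across, one
#' reference card at a mild rotation, calibration of at least 10 px/mm, and
#' mild noise. Slices are placed on a jittered grid whose cell pitch exceeds
#' the largest possible slice, so objects never touch.
#'
#' @param seed Integer seed controlling every random draw.
#' @param n_slices Number of slices, or `NULL` to draw from 3--6.
#' @param ppm Pixels per mm, or `NULL` to draw uniformly from 10--12.5.
#' @param noise_sigma Noise s.d., or `NULL` to draw uniformly from 1--5.
#' @return A [scene_spec()].
#' @export
sample_scene_spec <- function(seed, n_slices = NULL, ppm = NULL, noise_sigma = NULL) {
  withr::with_seed(as.integer(seed), {
    n <- n_slices %||% sample(3:6, 1)
    ppm <- ppm %||% stats::runif(1, 10, 12.5)
    noise_sigma <- noise_sigma %||% stats::runif(1, 1, 5)
    canvas_mm <- c(106, 120)  # (H, W) in mm
    card_center <- c(25, 53) + stats::runif(2, -2, 2)
    card_angle <- stats::runif(1, -12, 12)
    cells <- expand.grid(x = c(64, 98), y = c(20, 54, 88))
    cells <- cells[sample(nrow(cells), n), , drop = FALSE]
    slices <- lapply(seq_len(n), function(i) {
      long <- stats::runif(1, 10, 30)
      short <- max(long * stats::runif(1, 0.55, 0.92), 5.01)
      ellipse_spec(
        center_mm = c(cells$x[i], cells$y[i]) + stats::runif(2, -1.5, 1.5),
        long_axis_mm = long, short_axis_mm = short,
        angle_deg = stats::runif(1, 0, 180))
    })
    scene_spec(
      ppm = ppm,
      image_size_px = c(round(canvas_mm[1] * ppm), round(canvas_mm[2] * ppm)),
      slices = slices, card_center_mm = card_center, card_angle_deg = card_angle,
      noise_sigma = noise_sigma, seed = as.integer(seed))
  })
}

#' Seeded random feature-map tensor
#'
#' @param seed Integer seed.
#' @param n,c,h,w Positive tensor dimensions (batch, channels, height, width).
#' @param distribution One of `"normal"`, `"uniform"`, `"constant"`.
#' @param mean,sd Normal parameters.
#' @param min,max Uniform bounds.
#' @param value Constant value.
#' @return A numeric array of dim `c(n, c, h, w)`.
#' @export
random_feature_map <- function(seed, n, c, h, w,
                               distribution = c("normal", "uniform", "constant"),
                               mean = 0, sd = 1, min = 0, max = 1, value = 0) {
  distribution <- match.arg(distribution)
  for (d in list(n = n, c = c, h = h, w = w)) {
    if (!is.numeric(d) || length(d) != 1L || d < 1) {
      stop("all dimensions must be positive", call. = FALSE)
    }
  }
  size <- n * c * h * w
  vals <- switch(distribution,
    normal = withr::with_seed(as.integer(seed), stats::rnorm(size, mean, sd)),
    uniform = withr::with_seed(as.integer(seed), stats::runif(size, min, max)),
    constant = rep(value, size))
  array(vals, dim = c(n, c, h, w))
}
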