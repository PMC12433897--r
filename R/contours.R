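#' Polygon area by the shoelace formula
#'
#' @param points n x 2 matrix of `(row, col)` vertices of a closed polygon
#'   (closure implied between last and first vertex).
#' @return Absolute enclosed area.
#' @export
shoelace_area <- function(points) {
  x <- points[, 2]; y <- points[, 1]
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

#' Minimum-area rotated rectangle of a point set
#'
#' Rotating-calipers over convex-hull edge directions: the minimum-area
#' enclosing rectangle has a side collinear with a hull edge. Side lengths
#' are coordinate extents in the rotated frame, so they are
#' rotation-invariant up to discretization.
#'
#' @param points n x 2 matrix of `(row, col)` coordinates (n >= 3).
#' @return List with `long`, `short` (long >= short), `angle_deg` (direction
#'   of the long side, degrees from the column axis, in `[0, 180)`).
#' @export
min_area_rect <- function(points) {
  if (nrow(points) < 3) stop("degenerate contour: need >= 3 points", call. = FALSE)
  x <- points[, 2]; y <- points[, 1]
  hull <- grDevices::chull(x, y)
  hx <- x[hull]; hy <- y[hull]
  nh <- length(hull)
  if (nh < 2) stop("degenerate contour: collinear or single point", call. = FALSE)
  thetas <- unique(atan2(diff(c(hy, hy[1])), diff(c(hx, hx[1]))) %% pi)
  best <- NULL
  for (th in thetas) {
    u <- hx * cos(th) + hy * sin(th)
    v <- -hx * sin(th) + hy * cos(th)
    du <- max(u) - min(u); dv <- max(v) - min(v)
    if (is.null(best) || du * dv < best$area - 1e-12) {
      best <- list(area = du * dv, du = du, dv = dv, th = th)
    }
  }
  if (best$du >= best$dv) {
    long <- best$du; short <- best$dv; angle <- best$th
  } else {
    long <- best$dv; short <- best$du; angle <- best$th + pi / 2
  }
  list(long = long, short = short, angle_deg = (angle * 180 / pi) %% 180)
}

#' Extract outer contours from an edge map
#'
#' Raw Canny rings can carry 1-px gaps, so contours are taken from the
#' closed regions bounded by the edges: a 3 x 3 morphological closing seals
#' small gaps, interior holes are filled, connected regions are labeled, and
#' each region's outer boundary is traced into an ordered closed polygon.
#' Contours are returned in order of decreasing enclosed area.
#'
#' @param mask Binary matrix (an [edge_map()] result).
#' @param min_pixels Regions smaller than this many pixels are dropped
#'   before tracing (default 9, removes isolated noise responses).
#' @return List of n x 2 matrices of 1-based `(row, col)` boundary points.
#' @export
find_contours <- function(mask, min_pixels = 9) {
  stopifnot(is.matrix(mask))
  if (!any(mask > 0)) return(list())
  m <- EBImage::closing(mask > 0, EBImage::makeBrush(3, "box"))
  m <- EBImage::fillHull(m)
  lab <- EBImage::bwlabel(m)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_pixels)
  if (length(keep) == 0) return(list())
  oc <- EBImage::ocontour(lab)
  contours <- lapply(keep, function(i) {
    p <- oc[[i]] + 1L  # ocontour is 0-based
    cbind(row = p[, 1], col = p[, 2])
  })
  contours <- Filter(function(p) nrow(p) >= 3, contours)
  areas <- vapply(contours, shoelace_area, numeric(1))
  contours[order(areas, decreasing = TRUE)]
}

#' Geometric descriptors of a contour
#'
#' @param contour n x 2 matrix of `(row, col)` points (n >= 3).
#' @return List with `area_px` (shoelace area), `bbox` = `c(w_px, h_px)`
#'   axis-aligned coordinate extents (width along columns), and `min_rect`
#'   from [min_area_rect()]. The min-rect sides satisfy
#'   `long * short >= area_px`.
#' @export
contour_geometry <- function(contour) {
  if (!is.matrix(contour) || nrow(contour) < 3) {
    stop("degenerate contour: need >= 3 points", call. = FALSE)
  }
  list(
    area_px = shoelace_area(contour),
    bbox = c(w_px = max(contour[, 2]) - min(contour[, 2]),
             h_px = max(contour[, 1]) - min(contour[, 1])),
    min_rect = min_area_rect(contour)
  )
}
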