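circle_polygon <- function(cy, cx, r, n = 300) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-1]
  cbind(row = cy + r * sin(th), col = cx + r * cos(th))
}

test_that("reference card is found by aspect ratio, largest area on ties", {
  card <- rect_polygon(200, 200, 260, 380, 12)        # ratio 38/26
  circ <- circle_polygon(500, 500, 120)               # ratio ~1
  found <- find_reference(list(circ, card))
  expect_equal(attr(found, "index"), 2L)

  expect_error(find_reference(list(circ)), "calibration failure")
  expect_error(find_reference(list(circ)), "closest")

  big <- rect_polygon(300, 300, 300, 438, 0)          # in tolerance, bigger
  small <- rect_polygon(800, 300, 130, 190, 45)       # in tolerance, smaller
  picked <- find_reference(list(small, circ, big))
  # oracle: exhaustive scan over all candidates
  cands <- list(small, circ, big)
  ratios <- vapply(cands, function(p) { m <- min_area_rect(p); m$long / m$short }, numeric(1))
  areas <- vapply(cands, shoelace_area, numeric(1))
  in_tol <- abs(ratios / (38 / 26) - 1) <= 0.1
  expect_equal(attr(picked, "index"), which(in_tol)[which.max(areas[in_tol])])
  expect_equal(attr(picked, "index"), 3L)
})

test_that("ppm comes from the short card side with a long-side cross-check", {
  card <- rect_polygon(300, 300, 260, 380, 20)
  cal <- compute_ppm(card)
  expect_lt(abs(cal$ppm - 10), 0.05)

  half <- rect_polygon(200, 200, 130, 190, 0)
  expect_lt(abs(compute_ppm(half)$ppm - 5), 0.05)

  # long side 4% off the expected 38:26 proportion -> warning
  skew <- rect_polygon(300, 300, 260, 395, 0)
  expect_warning(compute_ppm(skew), "cross-check")
})

test_that("render-and-recover calibration is accurate to 1%", {
  spec <- small_scene(seed = 21, ppm = 12.5)
  res <- measure_image(render_scene(spec)$image)
  expect_lt(abs(res$calibration$ppm / 12.5 - 1), 0.01)
})

test_that("slice measurement converts px to mm and filters specks", {
  cal <- compute_ppm(rect_polygon(300, 300, 260, 380, 0))
  sq <- rect_polygon(600, 600, 100, 100, 0)
  m <- measure_slice(sq, cal, id = 1)
  expect_equal(m$long_mm, 10, tolerance = 0.01)
  expect_equal(m$short_mm, 10, tolerance = 0.01)
  expect_equal(m$area_mm2, 100, tolerance = 0.5)

  speck <- circle_polygon(50, 50, 2.5)   # ~20 px^2, below min area
  expect_null(measure_slice(speck, cal, id = 2))
})

test_that("a rendered 20 x 15 mm ellipse measures within tolerance", {
  spec <- small_scene(seed = 7, ppm = 10, angle = 25)
  res <- measure_image(render_scene(spec)$image)
  m <- res$measurements
  expect_equal(nrow(m), 1)
  expect_lt(abs(m$long_mm - 20), 0.4)
  expect_lt(abs(m$short_mm - 15), 0.4)
  expect_lt(abs(m$area_mm2 / (pi * 10 * 7.5) - 1), 0.05)
})

test_that("error/accuracy follows the benchmark convention", {
  r1 <- error_accuracy(17.4, 17.0)
  expect_equal(r1$error_pct, 2.4)
  expect_equal(r1$acc_pct, 97.6)

  r2 <- error_accuracy(13.2, 15.8)
  expect_equal(r2$error_pct, 16.5)
  expect_equal(r2$acc_pct, 83.5)

  r3 <- error_accuracy(5, 5)
  expect_equal(r3$error_pct, 0)
  expect_equal(r3$acc_pct, 100)

  expect_error(error_accuracy(1, 0), "actual")

  # error + accuracy is exactly 100, and the measure is asymmetric
  set.seed(4)
  p <- runif(50, 5, 30); a <- runif(50, 5, 30)
  rep <- error_accuracy(p, a)
  expect_true(all(rep$error_pct + rep$acc_pct == 100))
  expect_false(isTRUE(all.equal(error_accuracy(p, a)$error_pct,
                                error_accuracy(a, p)$error_pct)))
})

test_that("error summaries pool and average per column", {
  one <- error_accuracy(10.3, 10)
  expect_equal(summarize_errors(one)$mean_error_pct, 3)

  bench <- slice_benchmark()
  long_rep <- error_accuracy(bench$long_pred, bench$long_actual)
  s <- summarize_errors(long = long_rep)
  expect_equal(round(s$per_column[["long"]], 1), 4.1)

  both <- summarize_errors(long = long_rep,
                           short = error_accuracy(bench$short_pred, bench$short_actual))
  expect_lte(both$mean_error_pct, 5)
  expect_error(summarize_errors(), "no error reports")
})

test_that("measurements are scale-invariant across rendering resolution", {
  lo <- small_scene(seed = 13, ppm = 8)
  hi <- small_scene(seed = 13, ppm = 16)
  m_lo <- measure_image(render_scene(lo)$image)$measurements
  m_hi <- measure_image(render_scene(hi)$image)$measurements
  expect_lt(abs(m_lo$long_mm / m_hi$long_mm - 1), 0.02)
  expect_lt(abs(m_lo$short_mm / m_hi$short_mm - 1), 0.02)
})
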