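test_that("group normalization standardizes per sample and group", {
  x <- array(7, c(2, 4, 3, 3))
  out <- group_norm(x, groups = 2)
  expect_lt(max(abs(out)), 1e-2)  # constant input collapses to ~0

  y <- random_feature_map(3, 2, 8, 5, 5, sd = 2)
  g <- group_norm(y, groups = 4)
  for (n in 1:2) for (gr in 1:4) {
    v <- g[n, ((gr - 1) * 2 + 1):(gr * 2), , ]
    expect_lt(abs(mean(v)), 1e-6)
    expect_lt(abs(mean((v - mean(v))^2) - 1), 1e-4)
  }

  # groups = 1 is layer-style normalization over C x H x W
  ln <- group_norm(y, groups = 1)
  v <- y[1, , , ]
  expect_equal(ln[1, , , ], (v - mean(v)) / sqrt(mean((v - mean(v))^2) + 1e-5),
               tolerance = 1e-10)

  expect_error(group_norm(y, groups = 3), "divisible")
})

test_that("the shared head preserves spatial dims and shares weights", {
  p <- head_params(in_channels = c(8, 8, 8), hidden = 8, nc = 3, reg_max = 4,
                   gn_groups = 2, seed = 5)
  lv <- list(random_feature_map(1, 1, 8, 8, 8), random_feature_map(2, 1, 8, 4, 4),
             random_feature_map(3, 1, 8, 2, 2))
  out <- lsd_head_forward(lv, p)
  for (l in 1:3) {
    expect_equal(dim(out$levels[[l]]$cls), c(1L, 3L, dim(lv[[l]])[3], dim(lv[[l]])[4]))
    expect_equal(dim(out$levels[[l]]$reg), c(1L, 16L, dim(lv[[l]])[3], dim(lv[[l]])[4]))
  }

  # weight sharing: swapping two same-shaped levels swaps outputs exactly
  lv2 <- list(random_feature_map(1, 1, 8, 6, 6), random_feature_map(2, 1, 8, 6, 6),
              random_feature_map(3, 1, 8, 2, 2))
  p_eq <- p
  p_eq$in_channels <- c(8L, 8L, 8L)
  p_eq$reduce <- list(p$reduce[[1]], p$reduce[[1]], p$reduce[[3]])
  a <- lsd_head_forward(lv2, p_eq)
  b <- lsd_head_forward(list(lv2[[2]], lv2[[1]], lv2[[3]]), p_eq)
  expect_equal(a$levels[[1]]$cls, b$levels[[2]]$cls)
  expect_equal(a$levels[[2]]$reg, b$levels[[1]]$reg)

  # zero level scale silences regression but not classification
  p0 <- p
  p0$level_scales[2] <- 0
  out0 <- lsd_head_forward(lv, p0)
  expect_true(all(out0$levels[[2]]$reg == 0))
  expect_equal(out0$levels[[2]]$cls, out$levels[[2]]$cls)

  expect_error(lsd_head_forward(lv[1:2], p), "levels")
  expect_error(lsd_head_forward(list(lv[[1]], lv[[1]], random_feature_map(1, 1, 4, 2, 2)), p),
               "channels")
})

test_that("weight sharing cuts parameters versus per-level copies", {
  p <- head_params()
  expect_lt(head_n_params(p, shared = TRUE), head_n_params(p, shared = FALSE))
  # the shared trunk is counted once instead of once per level
  shared_part <- head_n_params(p, shared = FALSE) - head_n_params(p, shared = TRUE)
  expect_gt(shared_part, 0)
})

test_that("distribution decoding takes bin expectations times stride", {
  reg_max <- 16
  logits <- array(-30, c(1, 4 * reg_max, 1, 1))
  logits[1, 5 + 1, 1, 1] <- 30  # side 1 one-hot at bin 5
  # other sides one-hot at bin 0
  for (s in 2:4) logits[1, (s - 1) * reg_max + 1, 1, 1] <- 30
  boxes <- dfl_decode(logits, reg_max, stride = 8)
  ax <- 0.5 * 8; ay <- 0.5 * 8
  expect_equal(boxes[1, 1, 1, 1], ax - 40, tolerance = 1e-6)  # bin 5 * stride 8
  expect_equal(boxes[1, 2, 1, 1], ay - 0, tolerance = 1e-6)

  unif <- array(0, c(1, 4 * reg_max, 2, 2))
  b2 <- dfl_decode(unif, reg_max, stride = 4)
  # uniform distribution: expectation (reg_max - 1) / 2 = 7.5 bins
  expect_equal(b2[1, 3, 1, 1] - (0.5 * 4), 7.5 * 4, tolerance = 1e-9)
  expect_true(all(b2[1, 3, , ] >= b2[1, 1, , ]))
  expect_true(all(b2[1, 4, , ] >= b2[1, 2, , ]))

  # raising a higher bin's logit never shrinks the decoded distance
  base <- array(withr::with_seed(9, rnorm(4 * reg_max)), c(1, 4 * reg_max, 1, 1))
  d0 <- dfl_decode(base, reg_max, 8)[1, 3, 1, 1]
  prev <- d0
  for (bump in seq(0, 6, by = 1.5)) {
    pert <- base
    pert[1, 2 * reg_max + reg_max, 1, 1] <- pert[1, 2 * reg_max + reg_max, 1, 1] + bump
    dd <- dfl_decode(pert, reg_max, 8)[1, 3, 1, 1]
    expect_gte(dd + 1e-12, prev)
    prev <- dd
  }

  expect_error(dfl_decode(array(0, c(1, 10, 2, 2)), reg_max, 8), "4 \\* reg_max")
})

test_that("nms drops overlapping duplicates and keeps distinct boxes", {
  boxes <- rbind(c(0, 0, 10, 10), c(1, 1, 11, 11), c(40, 40, 50, 50))
  keep <- nms_boxes(boxes, scores = c(0.9, 0.8, 0.7), iou_thr = 0.45)
  expect_equal(sort(keep), c(1L, 3L))
})

test_that("head weights round-trip through the archive format", {
  p <- head_params(in_channels = c(4, 4, 4), hidden = 4, nc = 2, reg_max = 4,
                   gn_groups = 2, seed = 99)
  path <- withr::local_tempfile(fileext = ".rds")
  save_head_weights(p, path)
  q <- load_head_weights(path)
  expect_equal(q, p)
  lv <- list(random_feature_map(1, 1, 4, 4, 4), random_feature_map(2, 1, 4, 2, 2),
             random_feature_map(3, 1, 4, 2, 2))
  expect_equal(lsd_head_forward(lv, q), lsd_head_forward(lv, p))
})
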