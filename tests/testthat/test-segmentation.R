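cfg28 <- seg_config(pixels_per_cm = 28)

test_that("seg_config holds the protocol defaults and validates input", {
  cfg <- seg_config()
  expect_equal(cfg$c1_h, c(35, 100))
  expect_equal(cfg$c1_s, c(50, 255))
  expect_equal(cfg$c1_v, c(40, 226))
  expect_equal(cfg$c2_ratio_max, 0.625)
  expect_equal(cfg$t1_radius, 25)
  expect_equal(cfg$t1_threshold, 110)
  expect_equal(cfg$t2_window, 100)
  expect_equal(cfg$t2_threshold, 4.7)
  expect_equal(cfg$gauss_size, 5)
  expect_equal(cfg$e1_threshold, 29)
  expect_equal(cfg$e2_center, 15)
  expect_equal(cfg$e2_scale, 13)
  expect_equal(cfg$e2_threshold, 230)
  expect_equal(cfg$e3_threshold, 27)
  expect_equal(cfg$e4_threshold, 15)
  expect_equal(cfg$e4_binarize, 1)
  expect_equal(cfg$element_radius, 5)    # disc radius at 74.36 px/cm
  expect_equal(seg_config(pixels_per_cm = 28)$element_radius, 2)
  expect_error(seg_config(c1_h = c(100, 35)), "lower bound")
  expect_error(seg_config(e1_threshold = -1), "non-negative")
})

test_that("config files round-trip through the flat key-value format", {
  cfg <- seg_config(pixels_per_cm = 28, t2_stride = 2)
  f <- withr::local_tempfile(fileext = ".txt")
  write_seg_config(cfg, f)
  back <- read_seg_config(f)
  expect_equal(back[names(back)], cfg[names(cfg)])
  writeLines("no_such_key = 1", f)
  expect_error(read_seg_config(f), "unknown config key")
})

test_that("C1 applies the inclusive HSV windows per pixel", {
  mk <- function(h, s, v) {
    a <- array(0, c(20, 20, 3))
    a[, , 1] <- h; a[, , 2] <- s; a[, , 3] <- v
    raster_image(a, "HSV8")
  }
  expect_gt(sum(segment_c1(mk(85, 200, 100), cfg28)), 0)
  expect_equal(sum(segment_c1(mk(20, 200, 100), cfg28)), 0)  # H below 35
  expect_equal(sum(segment_c1(mk(85, 200, 240), cfg28)), 0)  # V above 226
  # bounds are inclusive
  expect_gt(sum(segment_c1(mk(35, 50, 40), cfg28)), 0)
  expect_gt(sum(segment_c1(mk(100, 255, 226), cfg28)), 0)
})

test_that("C2 keeps pixels with B/G strictly below the ratio threshold", {
  expect_gt(sum(segment_c2(flat_rgb(20, 20, c(50, 100, 60)), cfg28)), 0)
  expect_equal(sum(segment_c2(flat_rgb(20, 20, c(100, 100, 100)), cfg28)), 0)
  expect_equal(sum(segment_c2(flat_rgb(20, 20, c(10, 0, 10)), cfg28)), 0)
  # 0.625 itself is excluded (strict comparison)
  expect_equal(sum(segment_c2(flat_rgb(20, 20, c(0, 160, 100)), cfg28)), 0)
})

test_that("T1 preserves DC and recovers a large disk", {
  expect_gt(sum(segment_t1(matrix(150, 64, 64), cfg28)), 0)
  expect_equal(sum(segment_t1(matrix(90, 64, 64), cfg28)), 0)

  # DC preservation before thresholding
  h <- tillerview:::raised_cosine_lowpass(64, 64, 25)
  x <- matrix(150, 64, 64)
  lp <- Re(stats::fft(stats::fft(x) * h, inverse = TRUE)) / length(x)
  expect_lt(max(abs(lp - 150)), 1e-6)

  # large bright disk: interior retained, speckle suppressed
  set.seed(2)
  img <- disk_image(128, 35, 200, 40)
  img <- img + matrix(sample(c(0, 120), 128 * 128, TRUE, c(0.97, 0.03)),
                      128, 128)          # high-frequency speckle
  img <- pmin(img, 255)
  m <- segment_t1(img, cfg28)
  truth <- disk_mask(128, 35)
  expect_gte(mask_iou(m, truth), 0.85)
})

test_that("local entropy matches histogram closed forms", {
  expect_equal(max(abs(tillerview:::img_data(
    local_entropy(matrix(7, 30, 30), 8)))), 0, tolerance = 1e-12)

  # alternating 1-px stripes: every even window holds the two values in
  # equal proportion -> exactly 1 bit away from the border
  img <- matrix(0, 40, 40); img[, seq(2, 40, 2)] <- 255
  e <- tillerview:::img_data(local_entropy(img, 8))
  expect_equal(max(abs(e[5:36, 5:36] - 1)), 0, tolerance = 1e-12)

  # iid uniform values, window 100: near the 8-bit maximum
  set.seed(3)
  u <- matrix(sample(0:255, 120 * 120, TRUE), 120, 120)
  e <- tillerview:::img_data(local_entropy(u, 100))
  expect_lt(abs(e[60, 60] - 8), 0.05)

  # strided approximation stays close to the exact filter
  e2 <- tillerview:::img_data(local_entropy(u, 100, stride = 4))
  expect_equal(dim(e2), dim(u))
  expect_lt(max(abs(e2 - e)), 0.2)
  expect_error(local_entropy(u, 1), "window")
})

test_that("T2 thresholds the entropy image", {
  expect_equal(sum(segment_t2(matrix(100, 120, 120), cfg28)), 0)
  set.seed(4)
  noisy <- matrix(sample(0:255, 120 * 120, TRUE), 120, 120)
  m <- segment_t2(noisy, cfg28)
  expect_gt(sum(m) / length(m), 0.8)     # ~8 bits everywhere
})

test_that("prewitt_gradient responds only near edges and L1 >= L2", {
  expect_equal(max(tillerview:::img_data(
    prewitt_gradient(matrix(50, 10, 10), "L2"))), 0)

  step <- matrix(0, 16, 16); step[, 9:16] <- 255
  g <- tillerview:::img_data(prewitt_gradient(step, "L2"))
  expect_true(all(g[, c(1:6, 11:16)] == 0))
  expect_true(all(g[, 8:9] > 0))

  set.seed(6)
  x <- matrix(runif(400, 0, 255), 20, 20)
  l1 <- tillerview:::img_data(prewitt_gradient(x, "L1"))
  l2 <- tillerview:::img_data(prewitt_gradient(x, "L2"))
  expect_true(all(l1 - l2 >= -1e-9))
})

test_that("edge operators recover a solid disk and reject flat input", {
  # moderate-contrast disk, large relative to the ~1.5 px gradient band
  # that straddles the boundary after smoothing
  img <- disk_image(128, 45, 90, 50)
  truth <- disk_mask(128, 45)
  for (f in list(segment_e1, segment_e3, segment_e2)) {
    expect_equal(sum(f(matrix(128, 64, 64), cfg28)), 0)
  }
  expect_gte(mask_iou(segment_e1(img, cfg28), truth), 0.9)
  expect_gte(mask_iou(segment_e3(img, cfg28), truth), 0.9)
  expect_gte(mask_iou(segment_e4(img, cfg28), truth), 0.85)
  # E1 and E3 see the same edges: strong overlap
  f13 <- precision_recall_f(segment_e1(img, cfg28), segment_e3(img, cfg28))
  expect_gte(f13$f_value, 0.9)

  # faint step (amplitude 5) stays below the E1 threshold after smoothing
  faint <- matrix(100, 32, 32); faint[, 17:32] <- 105
  expect_equal(sum(segment_e1(faint, cfg28)), 0)

  # gentle ramp of slope 1 intensity/px: Prewitt L1 response is 6 < 27
  ramp <- matrix(rep(1:64, each = 64), 64, 64)
  expect_equal(sum(segment_e3(ramp, cfg28)), 0)
})

test_that("E2 closed-form constant responses", {
  # constant v: response = v * 23 / 13, clipped to [0, 255], >= 230 keeps
  expect_equal(sum(segment_e2(matrix(128, 40, 40), cfg28)), 0)  # 226.5
  m <- segment_e2(matrix(200, 40, 40), cfg28)                   # clipped 255
  expect_gt(sum(m) / 1600, 0.8)
  expect_equal(sum(segment_e2(matrix(0, 40, 40), cfg28)), 0)
})

test_that("thinning reduces an edge band to curves with no 2x2 block", {
  # an annulus, as produced by thresholding an edge gradient
  m <- tillerview:::as_mask(disk_mask(40, 12) & !disk_mask(40, 7))
  th <- thin_mask(m)
  expect_gt(sum(th), 0)
  blocks <- th[-nrow(th), -ncol(th)] + th[-1, -ncol(th)] +
    th[-nrow(th), -1] + th[-1, -1]
  expect_true(all(blocks < 4))
})

test_that("raising a scalar threshold never grows the raw mask", {
  img <- disk_image(96, 25)
  sm <- tillerview:::img_data(gaussian_smooth(img, 5, 1))
  g2 <- tillerview:::img_data(prewitt_gradient(sm, "L2"))
  g1 <- tillerview:::img_data(prewitt_gradient(sm, "L1"))
  ent <- tillerview:::img_data(local_entropy(img, 20))
  for (x in list(g2, g1, ent)) {
    counts <- vapply(quantile(x, c(0.1, 0.3, 0.5, 0.7, 0.9)),
                     function(th) sum(x > th), numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("segment_all routes channels, returns 8 same-shape clean masks", {
  sc <- generate_scene(scene_params(seed = 21))
  ms <- segment_all(sc$image, cfg28, image_id = "scene21")
  expect_s3_class(ms, "mask_set")
  expect_setequal(names(ms$masks), c("C1", "C2", "T1", "T2",
                                     "E1", "E2", "E3", "E4"))
  dims <- vapply(ms$masks, dim, integer(2))
  expect_true(all(dims == dim(sc$truth)))
  # every cleaned mask has at most one connected component
  for (m in ms$masks)
    expect_lte(max(tillerview:::cpp_label8(m)), 1)
  # most methods find the plant on a default scene
  f <- vapply(ms$masks, function(m)
    precision_recall_f(m, sc$truth)$f_value, numeric(1))
  expect_gte(sum(f >= 0.5), 6)

  # all-black image: every operator returns an empty mask
  black <- flat_rgb(64, 64, c(0, 0, 0))
  ms0 <- segment_all(black, cfg28)
  expect_true(all(vapply(ms0$masks, sum, numeric(1)) == 0))
})

test_that("mask_set validates completeness and shape agreement", {
  m <- random_mask(8, 8)
  good <- setNames(replicate(8, m, simplify = FALSE),
                   c("C1", "C2", "T1", "T2", "E1", "E2", "E3", "E4"))
  expect_s3_class(mask_set(good, "x"), "mask_set")
  expect_error(mask_set(good[1:7], "x"), "exactly the 8")
  bad <- good; bad$E4 <- random_mask(4, 4)
  expect_error(mask_set(bad, "x"), "share one shape")
})
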