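test_that("erode_mask reproduces the hand-derived square example", {
  m <- matrix(TRUE, 10, 10)
  e <- erode_mask(m, 0.30)
  # snapshots 1.00 / 0.64 / 0.36 / 0.16: 0.36 is closest to 0.30
  expect_equal(e$retained_fraction, 0.36)
  expect_equal(sum(e$mask), 36)
  expect_equal(e$iterations, 2L)
  # the survivor is the 6x6 interior square
  expect_true(all(which(e$mask, arr.ind = TRUE) >= 3))
  expect_true(all(which(e$mask, arr.ind = TRUE) <= 8))
})

test_that("erode_mask identity, degenerate and error cases", {
  m <- matrix(TRUE, 10, 10)
  e <- erode_mask(m, target_fraction = 1.0)
  expect_identical(e$mask, m)
  expect_equal(e$iterations, 0L)
  small <- matrix(FALSE, 8, 8)
  small[4:5, 4:5] <- TRUE  # 4 px < default 25 px minimum
  d <- erode_mask(small, 0.30)
  expect_true(d$degenerate)
  expect_identical(d$mask, small)
  expect_error(erode_mask(matrix(FALSE, 4, 4)), "no foreground")
  expect_error(erode_mask(m, 0), "target_fraction")
  expect_error(erode_mask(m, 1.2), "target_fraction")
})

test_that("erode_mask matches the neighbor-scan oracle on random masks", {
  for (seed in 1:8) {
    set.seed(seed)
    m <- matrix(runif(32 * 32) < 0.6, 32, 32)
    if (sum(m) < 25) next
    expect_identical(erode_mask(m, 0.30)$mask, oracle_erode_mask(m, 0.30))
  }
})

test_that("erosion output is nested and snapshot fractions decrease", {
  set.seed(5)
  m <- matrix(runif(40 * 40) < 0.7, 40, 40)
  e <- erode_mask(m, 0.1)
  expect_true(all(m[e$mask]))        # subset of the input
  # fractions along the snapshot sequence are non-increasing
  cur <- m
  fr <- 1
  for (i in 1:5) {
    cur <- hbimage:::erode_once(cur)
    f2 <- sum(cur) / sum(m)
    expect_lte(f2, fr)
    fr <- f2
  }
})

test_that("large convex masks erode to within 0.05 of the 30% target", {
  expect_lt(abs(erode_mask(big_ellipse_mask())$retained_fraction - 0.30),
            0.05)
  # non-circular ellipse and a big square too
  expect_lt(abs(erode_mask(big_ellipse_mask(201, a = 100, b = 60)
                           )$retained_fraction - 0.30), 0.05)
  expect_lt(abs(erode_mask(matrix(TRUE, 120, 120))$retained_fraction -
                  0.30), 0.05)
})

test_that("detect_eyelid_arc recovers a drawn circle within 2 px", {
  img <- draw_disk_image(128, 128, row = 70, col = 64, radius = 40)
  fit <- detect_eyelid_arc(img)
  expect_true(fit$found)
  expect_lte(abs(fit$row - 70), 2)
  expect_lte(abs(fit$col - 64), 2)
  expect_lte(abs(fit$radius - 40), 2)
})

test_that("blank images yield a detection-failure signal", {
  blank <- array(200L, dim = c(64, 64, 3))
  fit <- detect_eyelid_arc(blank)
  expect_false(fit$found)
})

test_that("the stronger of two concentric circles wins", {
  img <- matrix(0.5, 128, 128)
  img <- draw_ring(img, 64, 64, 45, 0.05)  # strong outer
  img <- draw_ring(img, 64, 64, 30, 0.40)  # faint inner
  fit <- detect_eyelid_arc(gray_to_rgb(img), min_votes = 10)
  expect_true(fit$found)
  expect_lte(abs(fit$radius - 45), 2)
})

test_that("detection is consistent under 180-degree rotation", {
  img <- draw_disk_image(128, 128, row = 50, col = 80, radius = 35)
  f1 <- detect_eyelid_arc(img)
  rot <- img[128:1, 128:1, , drop = FALSE]
  f2 <- detect_eyelid_arc(rot)
  expect_true(f1$found && f2$found)
  expect_lte(abs((129 - f1$row) - f2$row), 1)
  expect_lte(abs((129 - f1$col) - f2$col), 1)
  expect_lte(abs(f1$radius - f2$radius), 1)
})

test_that("lower_segment_mask returns the clipped lower half-disk", {
  circ <- structure(list(row = 60, col = 60, radius = 30, score = 100,
                         found = TRUE), class = "circle_fit")
  m <- lower_segment_mask(circ, c(128, 128))
  # about half the disk area, within discretization slack
  expect_lt(abs(sum(m) - pi * 30^2 / 2), 30 * 4)
  expect_true(all(which(m, arr.ind = TRUE)[, 1] >= 60))
  # center on the bottom row leaves at most one pixel row
  low <- structure(list(row = 128, col = 60, radius = 20, score = 1,
                        found = TRUE), class = "circle_fit")
  ml <- lower_segment_mask(low, c(128, 128))
  expect_true(all(which(ml, arr.ind = TRUE)[, 1] == 128))
  # radius 1: the open disk keeps only the center pixel
  tiny <- structure(list(row = 64, col = 64, radius = 1, score = 1,
                         found = TRUE), class = "circle_fit")
  expect_lte(sum(lower_segment_mask(tiny, c(128, 128))), 3)
  outside <- structure(list(row = -500, col = -500, radius = 10,
                            score = 1, found = TRUE),
                       class = "circle_fit")
  expect_error(lower_segment_mask(outside, c(128, 128)), "outside")
  bad <- structure(list(found = FALSE), class = "circle_fit")
  expect_error(lower_segment_mask(bad, c(128, 128)), "not valid")
})

test_that("refine_roi routes by modality and falls back on failure", {
  entry <- list(patient_id = "P1", visit_index = 0L, hb_true = 6)
  imgs <- render_visit_images(entry, render_params(), seed = 4)
  eyelid <- imgs[[1]]
  nail <- imgs[[3]]
  re <- refine_roi(eyelid)
  expect_true(re$method %in% c("hough_arc", "fallback_erosion"))
  rn <- refine_roi(nail)
  expect_equal(rn$method, "erosion")
  expect_lt(abs(rn$retained_fraction - 0.30), 0.06)
  # impossible detection threshold forces the fallback route
  rf <- refine_roi(eyelid, min_votes = 1e6)
  expect_equal(rf$method, "fallback_erosion")
  expect_true(is.matrix(rf$mask))
})
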