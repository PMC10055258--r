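test_that("brightest plane selection with leftmost ties", {
  a <- matrix(1, 4, 4); b <- matrix(5, 4, 4); b2 <- matrix(5, 4, 4)
  expect_identical(brightest_plane(list(a)), a)
  expect_identical(brightest_plane(list(a, b, a)), b)
  expect_identical(brightest_plane(list(a, b, b2)), b)  # lower index wins
  expect_error(brightest_plane(list()), "empty")
})

test_that("rolling-ball subtraction removes gradients and keeps spots", {
  # constant image -> zeros
  expect_equal(rolling_ball_subtract(matrix(7, 40, 40), 5),
               matrix(0, 40, 40))
  # planar gradient + compact spot: gradient removed, spot preserved
  nr <- 64
  grad <- outer(seq(0, 50, length.out = nr), rep(1, nr))
  spot <- matrix(0, nr, nr)
  ctr <- 32
  for (i in -3:3) for (j in -3:3)
    if (i^2 + j^2 <= 9) spot[ctr + i, ctr + j] <- 100
  out <- rolling_ball_subtract(grad + spot, 8)
  inner <- out[12:52, 12:52]
  bgmask <- spot[12:52, 12:52] == 0
  expect_lt(max(inner[bgmask]), 5)  # gradient removed away from edges
  expect_equal(out[ctr, ctr], 100, tolerance = 5)  # amplitude within 5%
  # approximate idempotence
  out2 <- rolling_ball_subtract(out, 8)
  expect_lt(max(abs(out2 - out)[12:52, 12:52]), 5)
  expect_error(rolling_ball_subtract(matrix(1, 10, 10), 10), "smaller")
})

test_that("the Default threshold matches an exhaustive intermeans oracle", {
  # two-level image: threshold strictly between the levels
  img <- matrix(c(rep(10, 200), rep(200, 56)), 16, 16)
  th <- threshold_default(img)
  expect_gt(th$threshold, 10); expect_lt(th$threshold, 200)
  expect_equal(sum(th$mask), 56)
  expect_error(threshold_default(matrix(3, 5, 5)), "constant")
  # oracle: direct scan over all 256 levels for the smallest level whose
  # value reaches the midpoint of the two class means
  oracle_level <- function(img) {
    rng <- range(img); binw <- diff(rng) / 256
    b <- pmin(pmax(floor((img - rng[1]) / binw), 0), 255)
    for (t in 0:254) {
      lo <- b[b <= t]; hi <- b[b > t]
      if (!length(lo) || !length(hi)) next
      if (t >= (mean(lo) + mean(hi)) / 2) return(t)
    }
    NA_integer_
  }
  set.seed(4)
  for (rep in 1:10) {
    im <- matrix(sample(0:255, 400, replace = TRUE,
                        prob = c(rep(4, 64), rep(1, 128), rep(3, 64))),
                 20, 20)
    expect_equal(threshold_default(im)$level, oracle_level(im))
  }
})

test_that("object statistics match closed-form shapes", {
  # uniform disc: cv = 0, ar ~ 1
  img <- matrix(0, 41, 41)
  for (i in -10:10) for (j in -10:10)
    if (i^2 + j^2 <= 100) img[21 + i, 21 + j] <- 50
  st <- object_stats(img, label_components(img > 0))
  expect_equal(st$cv, 0)
  expect_equal(st$ar, 1, tolerance = 0.05)
  # uniform 25x5 rectangle: second-moment AR exactly 5
  img2 <- matrix(0, 40, 40)
  img2[10:34, 10:14] <- 80
  st2 <- object_stats(img2, label_components(img2 > 0))
  expect_equal(st2$ar, 5, tolerance = 1e-10)
  expect_equal(st2$area, 125)
  # two-intensity object: hand-computed mean/sd/cv
  img3 <- matrix(0, 5, 5)
  img3[2, 2] <- 1; img3[2, 3] <- 3
  st3 <- object_stats(img3, label_components(img3 > 0))
  expect_equal(st3$mean, 2)
  expect_equal(st3$sd, sd(c(1, 3)))
  expect_equal(st3$cv, sd(c(1, 3)) / 2 * 100)
  # single pixel: ar defined as 1, sd 0
  img4 <- matrix(0, 5, 5); img4[3, 3] <- 9
  st4 <- object_stats(img4, label_components(img4 > 0))
  expect_equal(st4$ar, 1)
  expect_equal(st4$sd, 0)
  expect_error(object_stats(img4, matrix(0L, 5, 5)), "no components")
})

test_that("components are labeled with 8-connectivity", {
  m <- matrix(FALSE, 5, 5)
  m[1, 1] <- TRUE; m[2, 2] <- TRUE  # diagonal touch -> one component
  m[5, 5] <- TRUE
  lab <- label_components(m)
  expect_equal(max(lab), 2)
  expect_equal(lab[1, 1], lab[2, 2])
})

test_that("CV/AR rules apply exactly at both printed threshold sets", {
  expect_identical(classify_morphology(60, 1.2, "set1"), "fibrillar")
  expect_identical(classify_morphology(60, 1.0, "set1"), "punctate")
  expect_identical(classify_morphology(10, 1.0, "set1"), "diffuse")
  # uncovered combination and boundary gaps are flagged, not assigned
  expect_identical(classify_morphology(10, 1.5, "set1"), "unclassified")
  expect_identical(classify_morphology(55, 1.0, "set1"), "unclassified")
  expect_identical(classify_morphology(60, 1.1595, "set1"), "unclassified")
  expect_identical(classify_morphology(20, 1.5, "set2"), "fibrillar")
  expect_identical(classify_morphology(20, 1.2, "set2"), "punctate")
  expect_identical(classify_morphology(15, 1.2, "set2"), "diffuse")
  expect_identical(classify_morphology(20, 1.405, "set2"), "unclassified")
  expect_identical(classify_morphology(17.5, 1.2, "set2"), "unclassified")
  expect_identical(classify_morphology(NA, 1.2, "set2"), "unclassified")
})

test_that("classification is invariant to intensity scaling", {
  ro <- render_objects(c("diffuse", "punctate", "fibrillar"), rng_seed = 5)
  s1 <- analyze_image(ro$image, radius = 14)
  s2 <- analyze_image(ro$image * 3.7, radius = 14)
  expect_identical(s1$class, s2$class)
  expect_equal(s2$cv, s1$cv, tolerance = 1e-6)
  expect_equal(s2$ar, s1$ar, tolerance = 1e-6)
})

test_that("planted morphologies are recovered end to end", {
  ro <- render_objects(rep(c("diffuse", "punctate", "fibrillar"), each = 5),
                       rng_seed = 3)
  st <- analyze_image(ro$image, radius = 14)
  tr <- ro$truth
  called <- vapply(seq_len(nrow(tr)), function(i) {
    d <- sqrt((st$centroid_row - tr$row[i])^2 + (st$centroid_col - tr$col[i])^2)
    if (length(d) && min(d) < 12) st$class[which.min(d)] else NA_character_
  }, character(1))
  expect_gte(mean(called == tr$class, na.rm = TRUE), 0.9)
  expect_gte(mean(!is.na(called)), 0.9)
})

test_that("ROI CV time courses report cluster formation", {
  nr <- 32
  uniform <- matrix(100, nr, nr)
  punctum <- uniform
  punctum[14:18, 14:18] <- 1500
  roi <- matrix(TRUE, nr, nr)
  cvs <- roi_cv_timecourse(list(uniform, uniform, punctum, punctum), list(roi))
  expect_lt(max(cvs[1, 1:2]), 1)
  expect_gt(cvs[1, 3], 50)
  expect_gt(cvs[1, 3], 10 * cvs[1, 1])
  expect_error(roi_cv_timecourse(list(uniform), list(matrix(TRUE, 3, 3))),
               "outside")
  expect_error(roi_cv_timecourse(list(uniform), list(matrix(FALSE, nr, nr))),
               "empty")
})
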