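test_that("Scott's rule matches the direct formula and scaling law", {
  set.seed(1)
  x <- as.numeric(scale(rnorm(1000)))  # sd exactly 1
  e <- scott_bins(x)
  width_expected <- 3.49 * 1 * 1000^(-1 / 3)
  k_expected <- ceiling(diff(range(x)) / width_expected)
  expect_length(e, k_expected + 1)
  expect_equal(range(e), range(x))
  # doubling n grows the bin count by about 2^(1/3)
  x2 <- as.numeric(scale(c(x, rnorm(1000)))); x2 <- x2 / sd(x2)
  k2 <- length(scott_bins(x2)) - 1
  expect_equal(k2 / k_expected, 2^(1 / 3), tolerance = 0.25)
  expect_error(scott_bins(rep(1, 10)), "zero variance")
  expect_error(scott_bins(1), "at least 2")
})

test_that("density filter applies the 20/500/25% rules", {
  r <- density_filter(list(rnorm(19)))
  expect_false(r$eligible)
  expect_match(r$reason, "count")
  # count 100, IQR 0.5 -> density 200 < 500
  v <- seq(0, 1, length.out = 100)  # quartiles 0.25 and 0.75 exactly
  expect_equal(IQR(v), 0.5)
  r <- density_filter(list(v))
  expect_false(r$eligible)
  expect_equal(r$density, 200)
  # dense tight bin with a tolerable outlier fraction
  set.seed(2)
  v <- c(rnorm(900, 0, 0.02), rnorm(100, 0, 0.5))
  r <- density_filter(list(v))
  expect_true(r$density >= 500)
  expect_lte(r$outlier_frac, 0.25)
  expect_true(r$eligible)
  # zero IQR -> infinite density is eligible on that criterion
  r <- density_filter(list(rep(1, 50)))
  expect_true(r$eligible)
})

test_that("the spline bootstrap is deterministic and preserves plateaus", {
  set.seed(3)
  n <- 30000
  lx <- runif(n, 1, 4)
  am <- ifelse(lx > 2.5, 0.3, 0) + rnorm(n, 0, 0.01)
  ev <- data.table::data.table(acceptor = 10^lx, amfret = am)
  p1 <- fit_spline_profile(ev, n_boot = 5, rng_seed = 4)
  p2 <- fit_spline_profile(ev, n_boot = 5, rng_seed = 4)
  expect_identical(p1$spline, p2$spline)
  # plateau levels survive the zero-phase filter (away from the step;
  # the mild ringing of the low-pass filter is localized near the edge)
  left <- p1$grid < 2.0
  right <- p1$grid > 3.2
  expect_lt(max(abs(p1$spline[left] - 0)), 0.02 * 0.3 + 0.005)
  expect_lt(max(abs(p1$spline[right] - 0.3)), 0.02 * 0.3 + 0.005)
  # constant profile stays constant (filter passes DC)
  evc <- data.table::data.table(acceptor = 10^runif(20000, 1, 4),
                                amfret = rnorm(20000, 0.2, 0.01))
  pc <- fit_spline_profile(evc, n_boot = 3, rng_seed = 1)
  expect_lt(diff(range(pc$spline)), 0.02)
})

test_that("transition metrics find a logistic inflection and flag flats", {
  grid <- seq(1, 4, length.out = 256)
  c0 <- 2.4
  y <- 0.3 / (1 + exp(-(grid - c0) * 8))
  prof <- structure(list(grid = grid, boot = rbind(y, y), spline = y),
                    class = "spline_profile")
  tr <- transition_metrics(prof)
  step <- diff(grid)[1]
  expect_lt(abs(tr$transition_point - c0), 2 * step)
  expect_true(tr$transition_start < c0 && c0 < tr$transition_end)
  expect_false(tr$degenerate)
  # replicate order does not change the medians
  y2 <- 0.3 / (1 + exp(-(grid - 2.0) * 8))
  pa <- structure(list(grid = grid, boot = rbind(y, y2, y)), class = "spline_profile")
  pb <- structure(list(grid = grid, boot = rbind(y2, y, y)), class = "spline_profile")
  expect_equal(transition_metrics(pa)$transition_point,
               transition_metrics(pb)$transition_point)
  # flat spline degenerates to the full grid
  flat <- structure(list(grid = grid, boot = rbind(rep(0.1, 256))),
                    class = "spline_profile")
  trf <- transition_metrics(flat)
  expect_true(trf$degenerate)
  expect_equal(c(trf$transition_start, trf$transition_end), range(grid))
})

test_that("continuity calls follow the 0.05 rule with a documented boundary", {
  expect_identical(classify_continuity(0.049), "discontinuous")
  expect_identical(classify_continuity(0.05), "continuous")
  expect_identical(classify_continuity(0.9), "continuous")
  expect_error(classify_continuity(NA_real_), "undefined")
})

test_that("continuous subtypes follow the reference comparisons", {
  expect_identical(classify_continuous_subtype(0.01, 0.02, 0.1), "low")
  expect_identical(classify_continuous_subtype(0.2, 0.3, 0.1), "high")
  expect_identical(classify_continuous_subtype(0.01, 0.3, 0.1), "low_to_high")
  expect_identical(classify_continuous_subtype(0.3, 0.01, 0.1), "anomalous")
  expect_error(classify_continuous_subtype(0.1, 0.2), "reference")
})

test_that("majority classification reports ties as unresolved", {
  expect_identical(majority_classification(c("disc", "disc", "cont")), "disc")
  expect_identical(majority_classification(c("disc", "cont")), "unresolved")
  expect_identical(majority_classification(c("low", "low", "low")), "low")
  expect_error(majority_classification(character(0)), "no replicates")
})

test_that("classification abstains gracefully on starved inputs", {
  ev <- data.table::data.table(acceptor = 10^runif(100, 1, 4),
                               amfret = rnorm(100, 0, 0.05))
  out <- classify_well(ev, n_boot = 3, rng_seed = 1)
  expect_s3_class(out, "continuity_abstain")
  expect_match(out$reason, "eligible bins")
})

test_that("single wells of each behavior classify correctly end to end", {
  dd <- make_well("discontinuous", n = 60000, seed = 21, true_c50 = 300)
  cd <- classify_well(dd, rng_seed = 21)
  expect_identical(cd$class, "discontinuous")
  cc <- classify_well(make_well("continuous_low_to_high", n = 60000, seed = 22,
                                true_c50 = 150), rng_seed = 22)
  expect_identical(cc$class, "continuous")
  expect_identical(cc$subtype, "low_to_high")
  cl <- classify_well(make_well("one_state_low", n = 60000, seed = 23),
                      rng_seed = 23)
  expect_identical(cl$class, "continuous")
  expect_identical(cl$subtype, "low")
})
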