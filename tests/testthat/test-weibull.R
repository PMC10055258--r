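test_that("the stretched exponential obeys its closed-form identities", {
  # midpoint identity holds exactly for any steepness
  for (a in c(0.1, 0.5, 1, 2, 5, 10))
    expect_equal(weibull_eval(100, Amp = 0.37, C50 = 100, a = a), 0.37 / 2)
  expect_equal(weibull_eval(0, 1, 100, 2), 0)
  # a = 1, c = 2 C50: 1 - exp(-2 ln 2) = 0.75
  expect_equal(weibull_eval(200, 1, 100, 1), 0.75)
  # strictly increasing in c and Amp
  cc <- seq(1, 300, length.out = 200)  # beyond ~3 C50 the curve saturates
  expect_true(all(diff(weibull_eval(cc, 0.3, 100, 2)) > 0))
  expect_lt(weibull_eval(50, 0.2, 100, 2), weibull_eval(50, 0.4, 100, 2))
  expect_error(weibull_eval(-1, 1, 100, 2), ">= 0")
  expect_error(weibull_eval(1, 1, -5, 2), "> 0")
})

test_that("mean curves keep only well-populated bins", {
  set.seed(1)
  ev <- data.table::data.table(acceptor = 10^rnorm(5000, 2.5, 0.5),
                               amfret = rnorm(5000, 0.1, 0.05))
  mc <- mean_curve(bin_events(ev), min_count = 100)
  expect_true(all(mc$count >= 100))
  expect_true(all(diff(mc$conc) > 0))
})

test_that("window selection brackets a sigmoid rise and honors overrides", {
  conc <- 10^seq(1, 4, length.out = 40)
  y <- weibull_eval(conc, 0.3, 300, 2)
  curve <- data.frame(conc = conc, mean_amfret = y, count = 1000)
  w <- select_fit_window(curve)
  expect_false(w$overridden)
  # the window covers the rise and excludes the flat left tail
  expect_lt(curve$conc[w$start], 300)
  expect_gt(curve$conc[w$end], 300)
  expect_gt(w$start, 1)
  ov <- select_fit_window(curve, override = c(5, 20))
  expect_true(ov$overridden)
  expect_equal(c(ov$start, ov$end), c(5, 20))
  # flat curve: no rising segment
  flat <- data.frame(conc = conc, mean_amfret = rep(0.2, 40), count = 1000)
  expect_null(select_fit_window(flat))
})

test_that("noise-free curves are recovered to optimizer tolerance", {
  conc <- 10^seq(1.5, 3.5, length.out = 30)
  y <- weibull_eval(conc, 0.3, 100, 2)
  fit <- fit_weibull(data.frame(conc = conc, mean_amfret = y, count = 1000))
  expect_true(fit$converged)
  expect_equal(fit$Amp, 0.3, tolerance = 1e-4)
  expect_equal(fit$C50, 100, tolerance = 1e-3)
  expect_equal(fit$a, 2, tolerance = 1e-3)
})

test_that("a truth far outside the 2-fold box pins the fit at a bound", {
  # curve whose half-max concentration guess is far from the true C50:
  # truncate the curve so the plateau is invisible
  conc <- 10^seq(1, 2, length.out = 20)
  y <- weibull_eval(conc, 0.5, 1000, 1)  # observed segment is all early rise
  fit <- fit_weibull(data.frame(conc = conc, mean_amfret = y, count = 1000),
                     window = list(start = 1, end = 20, overridden = TRUE))
  expect_false(is.null(fit$at_bound))
  expect_false(fit$converged)
})

test_that("Monte-Carlo errors behave like errors", {
  conc <- 10^seq(1.5, 3.5, length.out = 30)
  y <- weibull_eval(conc, 0.3, 100, 2)
  fit <- fit_weibull(data.frame(conc = conc, mean_amfret = y, count = 1000))
  # zero residuals -> zero parameter errors
  e0 <- mc_errors(fit, n_mc = 10, rng_seed = 1)
  expect_true(all(e0 < 1e-6))
  # reproducible under a fixed seed
  set.seed(5)
  fitn <- fit_weibull(data.frame(conc = conc,
                                 mean_amfret = y + rnorm(30, 0, 0.01),
                                 count = 1000))
  e1 <- mc_errors(fitn, n_mc = 30, rng_seed = 2)
  e2 <- mc_errors(fitn, n_mc = 30, rng_seed = 2)
  expect_identical(e1, e2)
  expect_true(all(e1 > 0))
  # denser sampling of the same window shrinks the C50 error like 1/sqrt(m)
  mk <- function(m) {
    cc2 <- 10^seq(1.5, 3.5, length.out = m)
    fit_weibull(data.frame(conc = cc2,
                           mean_amfret = weibull_eval(cc2, 0.3, 100, 2) +
                             rnorm(m, 0, 0.01),
                           count = 1000),
                window = list(start = 1, end = m, overridden = TRUE))
  }
  set.seed(6)
  e_sparse <- mc_errors(mk(30), n_mc = 30, rng_seed = 2)
  e_dense <- mc_errors(mk(120), n_mc = 30, rng_seed = 2)
  expect_lt(e_dense["C50_sd"], e_sparse["C50_sd"])
})

test_that("fits are invariant to rescaling the concentration axis", {
  conc <- 10^seq(1.5, 3.5, length.out = 30)
  set.seed(8)
  y <- weibull_eval(conc, 0.3, 100, 2) + rnorm(30, 0, 0.005)
  f1 <- fit_weibull(data.frame(conc = conc, mean_amfret = y, count = 1000))
  f2 <- fit_weibull(data.frame(conc = conc * 7, mean_amfret = y, count = 1000))
  expect_equal(f2$C50 / f1$C50, 7, tolerance = 1e-3)
  expect_equal(f2$Amp, f1$Amp, tolerance = 1e-6)
  expect_equal(f2$a, f1$a, tolerance = 1e-3)
})

test_that("supersaturability is the same-batch stochastic/seeded ratio", {
  r <- supersaturability(400, 100, "b1", "b1")
  expect_equal(r$fold_reduction, 4)
  expect_equal(r$seeded_over_stochastic, 0.25)
  expect_equal(supersaturability(100, 100)$fold_reduction, 1)
  expect_error(supersaturability(400, 100, "b1", "b2"), "same batch")
})

test_that("planted supersaturability is recovered from paired wells", {
  fold <- 4
  base <- phenotype_spec("discontinuous", true_c50 = 400, true_amp = 0.3,
                         seed_fold_reduction = fold)
  seeded <- phenotype_spec("discontinuous", true_c50 = 400, true_amp = 0.3,
                           seeded = TRUE, seed_fold_reduction = fold)
  c50_of <- function(sp, s) {
    ev <- compute_amfret(apply_gates(simulate_events(sp, 1e5, rng_seed = s)))
    fit_weibull(mean_curve(bin_events(ev)))$C50
  }
  r <- supersaturability(c50_of(base, 31), c50_of(seeded, 32))
  expect_equal(r$fold_reduction, fold, tolerance = 0.15)
})
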