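#' Stretched-exponential (Weibull) assembly curve
#'
#' \deqn{AmFRET(c) = Amp (1 - e^{-\ln 2 \, (c/C_{50})^a})}
#' `Amp` is the asymptotic AmFRET, `C50` the concentration at which the
#' curve reaches half its asymptote (exactly, for any steepness `a`), and
#' `a` the steepness of the stretched exponential.
#'
#' @param c concentration (expression, p.d.u.), >= 0
#' @param Amp asymptote, > 0
#' @param C50 half-asymptote concentration, > 0
#' @param a steepness, > 0
#' @return AmFRET values
#' @export
weibull_eval <- function(c, Amp, C50, a) {
  if (any(c < 0)) stop("c must be >= 0")
  if (C50 <= 0 || a <= 0 || Amp <= 0) stop("Amp, C50 and a must be > 0")
  Amp * (1 - exp(-log(2) * (c / C50)^a))
}

#' Mean DAmFRET curve over populated expression bins
#'
#' Mean AmFRET per 64-bin log-expression histogram bin, restricted to bins
#' with at least `min_count` cells.
#'
#' @param profile a `binned_profile` from [bin_events()]
#' @param min_count minimum cells per bin (default 100)
#' @return data.frame with `conc` (bin geometric centers), `mean_amfret`,
#'   `count`
#' @export
mean_curve <- function(profile, min_count = 100) {
  stopifnot(inherits(profile, "binned_profile"))
  keep <- which(profile$count >= min_count)
  data.frame(conc = profile$bin_centers[keep],
             mean_amfret = profile$mean_amfret[keep],
             count = profile$count[keep])
}

# Gaussian smoothing of a short sequence (sigma in samples)
.gauss_smooth <- function(y, sigma = 2) {
  n <- length(y)
  if (n < 3 || sigma <= 0) return(y)
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-half):half)^2 / (2 * sigma^2))
  k <- k / sum(k)
  ypad <- c(rep(y[1], half), y, rep(y[n], half))
  as.numeric(stats::filter(ypad, k, sides = 2))[(half + 1):(half + n)]
}

#' Automatic fit window for the mean curve
#'
#' A reproducible surrogate for choosing curve limits by eye: on the
#' Gaussian-smoothed curve, the window starts at the first bin whose slope
#' exceeds `frac` of the maximum slope for two consecutive bins, and ends at
#' the first later bin where the slope falls back below that level. A manual
#' `override` (start and end indices) wins when supplied.
#'
#' @param curve data.frame from [mean_curve()]
#' @param frac slope fraction defining "rising" (default 0.05)
#' @param sigma smoothing sigma in bins (default 2)
#' @param override optional integer c(start, end) indices
#' @return list with `start`, `end` (indices into `curve`), `overridden`; or
#'   `NULL` when the curve never rises
#' @export
select_fit_window <- function(curve, frac = 0.05, sigma = 2, override = NULL) {
  n <- nrow(curve)
  if (!is.null(override)) {
    stopifnot(length(override) == 2, override[1] >= 1, override[2] <= n,
              override[1] < override[2])
    return(list(start = override[1], end = override[2], overridden = TRUE))
  }
  if (n < 6) stop("need at least 6 eligible bins")
  ys <- .gauss_smooth(curve$mean_amfret, sigma)
  slope <- diff(ys) / diff(log10(curve$conc))
  smax <- max(slope)
  if (!(smax > 0)) return(NULL)
  thr <- frac * smax
  rising <- slope > thr
  # both ends require the condition sustained for two consecutive bins, and
  # the end is sought after the maximum slope, so single noisy dips in a
  # densely sampled curve cannot truncate the window
  sustained <- which(rising[-length(rising)] & rising[-1])
  if (!length(sustained)) return(NULL)
  start <- sustained[1]
  imax <- which.max(slope)
  flat2 <- which(!rising[-length(rising)] & !rising[-1])
  after <- flat2[flat2 > imax]
  end <- if (length(after)) min(after) + 1L else n
  end <- min(max(end, start + 3), n)
  list(start = start, end = end, overridden = FALSE)
}

#' Bounded Weibull fit of the mean DAmFRET curve
#'
#' Least-squares fit of the stretched exponential over the fit window.
#' Initial guesses come from the Gaussian-smoothed curve: `Amp` = smoothed
#' maximum, `C50` = concentration at half that maximum, `a` = 2. `Amp` and
#' `C50` are box-constrained to within 2-fold of their guesses, and `a` to
#' `[0.1, 10]`.
#'
#' @param curve data.frame from [mean_curve()]
#' @param window list from [select_fit_window()] (or NULL to select
#'   automatically)
#' @param sigma smoothing sigma for initial guesses
#' @return a `weibull_fit` list: `Amp`, `C50`, `a`, `converged`,
#'   `at_bound`, `residual_sd`, `window`, `fitted`, `curve`
#' @export
fit_weibull <- function(curve, window = NULL, sigma = 2) {
  if (is.null(window)) window <- select_fit_window(curve, sigma = sigma)
  if (is.null(window))
    return(structure(list(converged = FALSE, reason = "no rising segment"),
                     class = "weibull_fit"))
  idx <- window$start:window$end
  if (length(idx) < 4)
    return(structure(list(converged = FALSE, reason = "window too short"),
                     class = "weibull_fit"))
  cc <- curve$conc[idx]
  yy <- curve$mean_amfret[idx]
  ys <- .gauss_smooth(yy, sigma)
  amp0 <- max(ys)
  if (!(amp0 > 0))
    return(structure(list(converged = FALSE, reason = "nonpositive curve"),
                     class = "weibull_fit"))
  c50_0 <- cc[which.min(abs(ys - amp0 / 2))]
  a0 <- 2
  lower <- c(Amp = amp0 / 2, C50 = c50_0 / 2, a = 0.1)
  upper <- c(Amp = amp0 * 2, C50 = c50_0 * 2, a = 10)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ Amp * (1 - exp(-log(2) * (conc / C50)^a)),
      data = data.frame(conc = cc, y = yy),
      start = list(Amp = amp0, C50 = c50_0, a = a0),
      lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-10)),
    error = function(e) NULL)
  if (is.null(fit))
    return(structure(list(converged = FALSE, reason = "optimizer failure",
                          window = window),
                     class = "weibull_fit"))
  p <- coef(fit)
  eps <- 1e-6
  # Amp or C50 pinned to the 2-fold box invalidates the fit; the steepness
  # bound a in [0.1, 10] is a hard constraint and may legitimately bind for
  # step-like seeded curves.
  box <- c("Amp", "C50")
  at_bound <- any(abs(p[box] - lower[box]) < eps * pmax(abs(lower[box]), 1)) ||
    any(abs(p[box] - upper[box]) < eps * pmax(abs(upper[box]), 1))
  structure(list(Amp = unname(p["Amp"]), C50 = unname(p["C50"]),
                 a = unname(p["a"]),
                 converged = !at_bound, at_bound = at_bound,
                 residual_sd = sd(resid(fit)),
                 window = window,
                 fitted = weibull_eval(cc, p["Amp"], p["C50"], p["a"]),
                 curve = data.frame(conc = cc, mean_amfret = yy)),
            class = "weibull_fit")
}

#' Monte-Carlo parameter errors for a Weibull fit
#'
#' Residual-parametric bootstrap: the fitted curve is perturbed `n_mc` times
#' with Gaussian noise of SD equal to the residual SD, refit, and the SD of
#' each parameter across refits reported.
#'
#' @param fit a converged `weibull_fit`
#' @param n_mc refits (default 100)
#' @param rng_seed integer seed
#' @return named numeric: `Amp_sd`, `C50_sd`, `a_sd`
#' @export
mc_errors <- function(fit, n_mc = 100, rng_seed = 1) {
  stopifnot(inherits(fit, "weibull_fit"))
  if (!isTRUE(fit$converged)) stop("mc_errors requires a converged fit")
  set.seed(rng_seed)
  cc <- fit$curve$conc
  base <- fit$fitted
  s <- fit$residual_sd
  if (!is.finite(s)) s <- 0
  pars <- matrix(NA_real_, n_mc, 3)
  for (i in seq_len(n_mc)) {
    ysim <- base + rnorm(length(base), 0, s)
    f <- fit_weibull(data.frame(conc = cc, mean_amfret = ysim),
                     window = list(start = 1, end = length(cc),
                                   overridden = TRUE))
    if (!is.null(f$C50)) pars[i, ] <- c(f$Amp, f$C50, f$a)
  }
  sds <- apply(pars, 2, sd, na.rm = TRUE)
  sds[!is.finite(sds)] <- 0
  c(Amp_sd = sds[1], C50_sd = sds[2], a_sd = sds[3])
}

#' Supersaturability: fold reduction of C50 by seeding
#'
#' The ratio of the null-seeded (stochastic) C50 to the self-seeded C50.
#' Values >= 1 mean seeding lowers the transition concentration; the
#' inverse orientation is also returned explicitly. Both C50s must come
#' from the same experimental batch.
#'
#' @param c50_stochastic C50 with a null seed
#' @param c50_seeded C50 with the cognate seed
#' @param batch_stochastic,batch_seeded batch identifiers (must match)
#' @return list with `fold_reduction` (stochastic/seeded) and
#'   `seeded_over_stochastic`
#' @export
supersaturability <- function(c50_stochastic, c50_seeded,
                              batch_stochastic = "b1", batch_seeded = "b1") {
  if (!identical(batch_stochastic, batch_seeded))
    stop("C50 ratio requires both fits from the same batch run")
  if (c50_stochastic <= 0 || c50_seeded <= 0) stop("C50s must be positive")
  list(fold_reduction = c50_stochastic / c50_seeded,
       seeded_over_stochastic = c50_seeded / c50_stochastic)
}
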