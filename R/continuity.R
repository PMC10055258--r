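#' Scott's-rule histogram bin edges on the log-expression axis
#'
#' Bin width `3.49 * sd(x) * n^(-1/3)`; the bin count is the range divided by
#' that width, rounded up.
#'
#' @param values log10 expression values, n >= 2, nonzero variance
#' @return numeric vector of bin edges spanning the data range
#' @export
scott_bins <- function(values) {
  n <- length(values)
  if (n < 2) stop("need at least 2 values")
  s <- sd(values)
  if (!is.finite(s) || s == 0) stop("zero variance")
  width <- 3.49 * s * n^(-1 / 3)
  rng <- range(values)
  k <- max(1L, ceiling(diff(rng) / width))
  seq(rng[1], rng[2], length.out = k + 1)
}

#' Bin-eligibility mask for the continuity spline
#'
#' A bin is eligible iff it holds at least `min_count` cells, its density
#' (count / IQR of AmFRET within the bin) is at least `min_density`, and no
#' more than `max_outlier_frac` of its cells are outliers (Tukey fences:
#' beyond 1.5 IQR outside the quartiles). Zero IQR gives infinite density
#' (eligible on that criterion).
#'
#' @param amfret_by_bin list of per-bin AmFRET vectors
#' @param min_count minimum cells per bin (default 20)
#' @param min_density minimum count/IQR density (default 500)
#' @param max_outlier_frac maximum outlier fraction (default 0.25)
#' @return data.frame with per-bin `count`, `iqr`, `density`,
#'   `outlier_frac`, `eligible`, `reason`
#' @export
density_filter <- function(amfret_by_bin, min_count = 20, min_density = 500,
                           max_outlier_frac = 0.25) {
  res <- lapply(amfret_by_bin, function(v) {
    cnt <- length(v)
    if (cnt == 0)
      return(data.frame(count = 0L, iqr = NA_real_, density = NA_real_,
                        outlier_frac = NA_real_, eligible = FALSE,
                        reason = "count"))
    iqr <- IQR(v)
    dens <- if (iqr == 0) Inf else cnt / iqr
    q <- quantile(v, c(0.25, 0.75), names = FALSE)
    of <- mean(v < q[1] - 1.5 * (q[2] - q[1]) | v > q[2] + 1.5 * (q[2] - q[1]))
    reason <- c(if (cnt < min_count) "count",
                if (dens < min_density) "density",
                if (of > max_outlier_frac) "outliers")
    data.frame(count = cnt, iqr = iqr, density = dens, outlier_frac = of,
               eligible = length(reason) == 0,
               reason = paste(reason, collapse = "+"))
  })
  do.call(rbind, res)
}

# zero-phase low-pass denoising of a median sequence. The sequence is
# extended by odd reflection at both ends before forward-backward filtering
# so that edge transients cancel (filtfilt alone pads with zeros, which
# drags plateau edges toward zero); short sequences are returned unchanged.
.denoise_medians <- function(y, order = 2, cutoff = 0.2) {
  n <- length(y)
  if (n < 8) return(y)
  bf <- signal::butter(order, cutoff)
  pad <- min(n - 1, 12)
  head_ref <- 2 * y[1] - y[(pad + 1):2]
  tail_ref <- 2 * y[n] - y[(n - 1):(n - pad)]
  out <- try(signal::filtfilt(bf, c(head_ref, y, tail_ref)), silent = TRUE)
  if (inherits(out, "try-error") || any(!is.finite(out))) return(y)
  out[(pad + 1):(pad + n)]
}

#' Bootstrapped denoised median-AmFRET spline for one well
#'
#' Cells are resampled with replacement `n_boot` times; each replicate is
#' rebinned (Scott's rule bins fixed from the original data), the per-bin
#' median AmFRET of eligible bins is denoised with a zero-phase Butterworth
#' low-pass filter, and interpolated cubically onto a common 256-point grid.
#' The reported spline is the pointwise mean of replicates; per-replicate
#' splines are kept for the transition-metric bootstrap.
#'
#' @param events event table with `acceptor`, `amfret` (gated rows used)
#' @param n_boot bootstrap replicates (default 100)
#' @param rng_seed integer seed
#' @param grid_n evaluation grid size (default 256)
#' @param min_eligible minimum eligible bins to proceed (default 4)
#' @param filter_order,filter_cutoff Butterworth design (defaults 2, 0.2)
#' @return a `spline_profile` list, or a classification abstention (class
#'   `continuity_abstain`) when fewer than `min_eligible` bins qualify
#' @export
fit_spline_profile <- function(events, n_boot = 100, rng_seed = 1,
                               grid_n = 256, min_eligible = 4,
                               filter_order = 2, filter_cutoff = 0.2) {
  ev <- data.table::as.data.table(events)
  if ("gate_final" %in% names(ev)) ev <- ev[gate_final == TRUE]
  if ("amfret_valid" %in% names(ev)) ev <- ev[amfret_valid == TRUE]
  lx <- log10(ev$acceptor)
  am <- ev$amfret
  edges <- scott_bins(lx)
  nb <- length(edges) - 1
  centers <- (edges[-1] + edges[-(nb + 1)]) / 2
  bin0 <- pmin(pmax(findInterval(lx, edges, rightmost.closed = TRUE), 1L), nb)
  split0 <- split(am, factor(bin0, levels = seq_len(nb)))
  elig <- density_filter(split0)
  keep <- which(elig$eligible)
  if (length(keep) < min_eligible) {
    return(structure(list(reason = sprintf(
      "only %d eligible bins (need %d)", length(keep), min_eligible)),
      class = "continuity_abstain"))
  }
  grid <- seq(centers[min(keep)], centers[max(keep)], length.out = grid_n)
  n <- length(am)
  set.seed(rng_seed)
  boot <- matrix(NA_real_, n_boot, grid_n)
  # cell bootstrap drawn as multinomial bin counts plus within-bin
  # resampling: the same law as resampling cell indices, but it only
  # materializes the eligible bins
  binvals <- split0[keep]
  p_all <- tabulate(bin0, nbins = nb) / n
  for (b in seq_len(n_boot)) {
    cnt <- stats::rmultinom(1, n, p_all)[, 1]
    xb <- numeric(0); mb <- numeric(0)
    for (j in seq_along(keep)) {
      k <- keep[j]
      if (cnt[k] == 0) next
      v <- binvals[[j]][sample.int(length(binvals[[j]]), cnt[k], replace = TRUE)]
      xb <- c(xb, centers[k]); mb <- c(mb, stats::median(v))
    }
    if (length(xb) >= 2) {
      yb <- .denoise_medians(mb, filter_order, filter_cutoff)
      boot[b, ] <- spline(xb, yb, xout = grid, method = "natural")$y
    }
  }
  boot <- boot[stats::complete.cases(boot), , drop = FALSE]
  if (nrow(boot) == 0)
    return(structure(list(reason = "all bootstrap replicates failed"),
                     class = "continuity_abstain"))
  structure(list(grid = grid, spline = colMeans(boot), boot = boot,
                 bin_centers = centers, eligible = elig, keep = keep,
                 events = ev),
            class = "spline_profile")
}

# transition metrics for one spline evaluated on a grid; ties go leftmost
.transition_one <- function(grid, y, flat_tol = 1e-4) {
  d1 <- diff(y) / diff(grid)
  mid <- (grid[-1] + grid[-length(grid)]) / 2
  if (max(abs(d1)) < flat_tol) {
    return(list(point = NA_real_, start = grid[1], end = grid[length(grid)],
                degenerate = TRUE))
  }
  ip <- which.max(d1)
  tp <- mid[ip]
  d2 <- diff(d1) / diff(mid)
  mid2 <- (mid[-1] + mid[-length(mid)]) / 2
  before <- which(mid2 < tp)
  after <- which(mid2 > tp)
  ts <- if (length(before)) mid2[before[which.max(d2[before])]] else grid[1]
  te <- if (length(after)) mid2[after[which.min(d2[after])]] else grid[length(grid)]
  list(point = tp, start = ts, end = te, degenerate = FALSE)
}

#' Transition point and range from the bootstrapped spline
#'
#' The transition point is the grid position of the maximum first derivative
#' of each replicate spline; the transition start (end) is the maximum
#' (minimum) of the second derivative before (after) it. Medians across
#' replicates are reported. A flat spline yields a degenerate transition
#' spanning the whole grid.
#'
#' @param profile a `spline_profile` from [fit_spline_profile()]
#' @return list with `transition_point`, `transition_start`,
#'   `transition_end` (bootstrap medians), per-replicate values, and a
#'   `degenerate` flag
#' @export
transition_metrics <- function(profile) {
  stopifnot(inherits(profile, "spline_profile"))
  reps <- apply(profile$boot, 1, function(y) .transition_one(profile$grid, y))
  pts <- vapply(reps, `[[`, numeric(1), "point")
  sts <- vapply(reps, `[[`, numeric(1), "start")
  ens <- vapply(reps, `[[`, numeric(1), "end")
  deg <- vapply(reps, `[[`, logical(1), "degenerate")
  list(transition_point = median(pts, na.rm = TRUE),
       transition_start = median(sts, na.rm = TRUE),
       transition_end = median(ens, na.rm = TRUE),
       replicates = data.frame(point = pts, start = sts, end = ens),
       degenerate = mean(deg) > 0.5)
}

#' Hartigan's dip test of unimodality
#'
#' The dip statistic is the minimum over all unimodal distribution functions
#' of the sup-distance to the empirical CDF, computed by the greatest convex
#' minorant / least concave majorant algorithm. The p-value is Monte-Carlo:
#' the fraction of uniform(0,1) samples of the same size with a dip at least
#' as large (with an add-one correction). Null tables are cached per sample
#' size within a session.
#'
#' @param values numeric sample, n >= 4
#' @param n_null Monte-Carlo null samples (default 2000)
#' @param rng_seed seed for the subsampling step
#' @param max_n samples larger than this are subsampled (without
#'   replacement) before testing, for speed; set `Inf` to disable
#' @param null_seed seed for the null table; the null distribution does not
#'   depend on the data, so a fixed seed lets the table be cached across
#'   wells of the same size
#' @return list with `dip`, `p_value`, `n`
#' @export
dip_test <- function(values, n_null = 2000, rng_seed = 1, max_n = 10000,
                     null_seed = 20251231) {
  values <- values[is.finite(values)]
  n0 <- length(values)
  if (n0 < 4) stop("dip test needs n >= 4")
  if (n0 > max_n) {
    set.seed(rng_seed)
    values <- sample(values, max_n)
  }
  n <- length(values)
  d <- dip_stat(values)
  key <- sprintf("dipnull_%d_%d_%d", n, n_null, null_seed)
  null <- .damfretr_cache[[key]]
  if (is.null(null)) {
    set.seed(null_seed)
    null <- dip_null_cpp(n, n_null)
    .damfretr_cache[[key]] <- null
  }
  p <- (1 + sum(null >= d)) / (n_null + 1)
  list(dip = d, p_value = p, n = n)
}

#' Dip statistic of a sample
#'
#' @param values numeric sample
#' @return the dip statistic (in `[1/(2n), 0.25]` for samples with at least
#'   two distinct values)
#' @export
dip_stat <- function(values) {
  values <- values[is.finite(values)]
  dip_stat_cpp(values)
}

#' Continuity call from the dip p-value
#'
#' Discontinuous iff `p < 0.05`; equality goes to continuous.
#'
#' @param dip_p dip-test p-value
#' @param alpha threshold (default 0.05)
#' @return `"discontinuous"` or `"continuous"`
#' @export
classify_continuity <- function(dip_p, alpha = 0.05) {
  if (!is.finite(dip_p)) stop("dip_p undefined")
  if (dip_p < alpha) "discontinuous" else "continuous"
}

#' Subtype of a continuous profile
#'
#' Compares the spline's minimum and ending AmFRET against a monomer-control
#' reference: both below = "low"; both above = "high"; minimum below and end
#' above = "low_to_high". The remaining combination (minimum above, end
#' below) is flagged `"anomalous"`.
#'
#' @param spline_min minimum AmFRET of the mean spline
#' @param spline_end AmFRET at the spline's upper end
#' @param reference_amfret control reference level
#' @return one of "low", "high", "low_to_high", "anomalous"
#' @export
classify_continuous_subtype <- function(spline_min, spline_end, reference_amfret) {
  if (missing(reference_amfret) || !is.finite(reference_amfret))
    stop("reference_amfret required")
  below_min <- spline_min < reference_amfret
  below_end <- spline_end < reference_amfret
  if (below_min && below_end) "low"
  else if (!below_min && !below_end) "high"
  else if (below_min && !below_end) "low_to_high"
  else "anomalous"
}

#' Majority classification across replicate wells
#'
#' @param labels character vector of per-replicate class labels
#' @return the modal label, or `"unresolved"` on a tie (flagged for manual
#'   review)
#' @export
majority_classification <- function(labels) {
  if (!length(labels)) stop("no replicates")
  tb <- sort(table(labels), decreasing = TRUE)
  if (length(tb) > 1 && tb[1] == tb[2]) "unresolved" else names(tb)[1]
}

#' End-to-end continuity classification of one well
#'
#' Runs the spline bootstrap, locates the transition range, applies the dip
#' test to AmFRET values of cells whose expression falls inside it, and
#' calls the class (plus subtype for continuous profiles).
#'
#' @param events event table (gated, with `amfret`)
#' @param n_boot bootstrap replicates (default 100)
#' @param rng_seed integer seed
#' @param reference_amfret subtype reference level (default 0.1)
#' @param alpha dip significance threshold (default 0.05)
#' @param ... passed to [fit_spline_profile()] and [dip_test()]
#' @return list with `class`, `subtype`, `transition`, `dip`, `profile`; or
#'   an abstention with its reason
#' @export
classify_well <- function(events, n_boot = 100, rng_seed = 1,
                          reference_amfret = 0.1, alpha = 0.05, ...) {
  prof <- fit_spline_profile(events, n_boot = n_boot, rng_seed = rng_seed, ...)
  if (inherits(prof, "continuity_abstain")) return(prof)
  tr <- transition_metrics(prof)
  ev <- prof$events
  lx <- log10(ev$acceptor)
  inwin <- lx >= tr$transition_start & lx <= tr$transition_end
  vals <- ev$amfret[inwin]
  if (sum(is.finite(vals)) < 4) {
    return(structure(list(reason = "fewer than 4 cells in transition range"),
                     class = "continuity_abstain"))
  }
  dp <- dip_test(vals, rng_seed = rng_seed)
  cls <- classify_continuity(dp$p_value, alpha)
  subtype <- "none"
  if (cls == "continuous") {
    subtype <- classify_continuous_subtype(min(prof$spline),
                                           prof$spline[length(prof$spline)],
                                           reference_amfret)
  }
  list(class = cls, subtype = subtype, transition = tr, dip = dp,
       profile = prof)
}
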