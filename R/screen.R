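#' Within-batch standardization to mean 0, variance 1
#'
#' @param values numeric vector
#' @param batch batch identifiers (same length)
#' @param sd_type `"sample"` (n-1 denominator, default) or `"population"`
#' @return list with `z` (standardized values; NA for excluded batches) and
#'   `excluded` (batches that were singleton or constant, with reasons)
#' @export
standardize_batch <- function(values, batch, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  stopifnot(length(values) == length(batch))
  z <- rep(NA_real_, length(values))
  excluded <- character(0)
  for (b in unique(batch)) {
    i <- which(batch == b)
    v <- values[i]
    ok <- is.finite(v)
    if (sum(ok) < 2) { excluded <- c(excluded, sprintf("%s:singleton", b)); next }
    s <- if (sd_type == "sample") sd(v[ok]) else sqrt(mean((v[ok] - mean(v[ok]))^2))
    if (!is.finite(s) || s == 0) { excluded <- c(excluded, sprintf("%s:constant", b)); next }
    z[i] <- (v - mean(v[ok])) / s
  }
  list(z = z, excluded = excluded)
}

#' Directional IQR outlier degree
#'
#' How many interquartile ranges a value lies below (or above) the median of
#' its protein's values across all seeds. Clipped at zero in the
#' non-indicated direction.
#'
#' @param values one protein's values across seeds (>= 4)
#' @param direction `"below"` or `"above"`
#' @return nonnegative degrees, same length as `values`; all NA with a
#'   warning when the IQR is zero
#' @export
outlier_degree <- function(values, direction = c("below", "above")) {
  direction <- match.arg(direction)
  if (sum(is.finite(values)) < 4) stop("need >= 4 values per protein")
  m <- median(values, na.rm = TRUE)
  iqr <- IQR(values, na.rm = TRUE)
  if (iqr == 0) {
    warning("zero IQR: outlier degrees undefined")
    return(rep(NA_real_, length(values)))
  }
  if (direction == "below") pmax(0, (m - values) / iqr)
  else pmax(0, (values - m) / iqr)
}

#' Seedability score: mean of the C50 and fgate outlier degrees
#'
#' @param c50_degree degree of C50 reduction (below-median direction)
#' @param fgate_degree degree of fgate increase (above-median direction)
#' @return elementwise arithmetic mean (NA when either is undefined)
#' @export
seedability_score <- function(c50_degree, fgate_degree) {
  (c50_degree + fgate_degree) / 2
}

#' Assemble per-well screen records into seedability scores
#'
#' Pipeline order: log10(C50) -> per-batch standardization of log10 C50 and
#' fgate -> per-protein directional outlier degrees (C50 below, fgate
#' above; negative-control wells included in the median/IQR) -> seedability.
#'
#' @param records data.frame with columns `dfd_id`, `seed_id`, `batch`,
#'   `c50`, `fgate`, optional `is_negative_control`
#' @param sd_type standardization convention (see [standardize_batch()])
#' @return data.table with standardized values, degrees and `seedability`
#' @export
score_screen <- function(records, sd_type = "sample") {
  rec <- data.table::as.data.table(records)
  req <- c("dfd_id", "seed_id", "batch", "c50", "fgate")
  missing <- setdiff(req, names(rec))
  if (length(missing)) stop("missing columns: ", paste(missing, collapse = ", "))
  if (!"is_negative_control" %in% names(rec))
    rec[, is_negative_control := grepl("^neg", seed_id)]
  rec[, log10_c50 := log10(c50)]
  rec[, c50_std := standardize_batch(log10_c50, batch, sd_type)$z]
  rec[, fgate_std := standardize_batch(fgate, batch, sd_type)$z]
  rec[, c50_outlier_degree := outlier_degree(c50_std, "below"), by = dfd_id]
  rec[, fgate_outlier_degree := outlier_degree(fgate_std, "above"), by = dfd_id]
  rec[, seedability := seedability_score(c50_outlier_degree, fgate_outlier_degree)]
  rec[]
}

#' Call nucleating-interaction hits at mean + 3 SD of all seedability values
#'
#' @param scored output of [score_screen()] (needs `seedability`), >= 10
#'   defined values
#' @param n_sd threshold in SDs above the mean (default 3)
#' @param sd_type `"sample"` or `"population"` SD convention
#' @return list with `records` (with `is_hit`), `hit_threshold`, `n_hits`,
#'   `hit_fraction`, and a negative-control partition diagnostic
#' @export
call_hits <- function(scored, n_sd = 3, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  rec <- data.table::as.data.table(scored)
  s <- rec$seedability
  ok <- is.finite(s)
  if (sum(ok) < 10) stop("need >= 10 defined seedability values")
  mu <- mean(s[ok])
  sdev <- if (sd_type == "sample") sd(s[ok]) else sqrt(mean((s[ok] - mu)^2))
  if (!is.finite(sdev) || sdev == 0) stop("zero SD of seedability values")
  thr <- mu + n_sd * sdev
  rec[, is_hit := is.finite(seedability) & seedability >= thr]
  negdiag <- NULL
  if ("is_negative_control" %in% names(rec)) {
    negdiag <- rec[, .(
      n = .N,
      n_hits = sum(is_hit),
      median_seedability = median(seedability, na.rm = TRUE)
    ), by = is_negative_control]
  }
  list(records = rec[], hit_threshold = thr,
       n_hits = sum(rec$is_hit, na.rm = TRUE),
       hit_fraction = mean(rec$is_hit[ok]),
       negative_control_diagnostic = negdiag)
}

#' Replicate consistency of hit calling, with Wald confidence interval
#'
#' Records are matched on (protein, seed). Consistency is the fraction of
#' matched pairs with the same hit call, with a Wald 95% CI (Wilson
#' optional). The Pearson correlation of seedability values is reported with
#' and without double-negative pairs (both replicates non-hits).
#'
#' @param calls_1,calls_2 data.frames with `dfd_id`, `seed_id`, `is_hit`,
#'   `seedability`
#' @param level confidence level (default 0.95)
#' @param ci `"wald"` (default) or `"wilson"`
#' @return list with `n_matched`, `n_inconsistent`, `consistency`, `ci`,
#'   `pearson_r`, `pearson_r_no_double_negative`
#' @export
replicate_consistency <- function(calls_1, calls_2, level = 0.95,
                                  ci = c("wald", "wilson")) {
  ci <- match.arg(ci)
  a <- data.table::as.data.table(calls_1)
  b <- data.table::as.data.table(calls_2)
  m <- merge(a, b, by = c("dfd_id", "seed_id"), suffixes = c("_1", "_2"))
  if (nrow(m) == 0) stop("no matched records")
  n <- nrow(m)
  ninc <- sum(m$is_hit_1 != m$is_hit_2)
  rate <- 1 - ninc / n
  interval <- if (ci == "wald") wald_ci(n - ninc, n, level)
              else wilson_ci(n - ninc, n, level)
  r_all <- stats::cor(m$seedability_1, m$seedability_2,
                      use = "complete.obs", method = "pearson")
  keep <- m$is_hit_1 | m$is_hit_2
  r_nodn <- if (sum(keep) >= 3)
    stats::cor(m$seedability_1[keep], m$seedability_2[keep],
               use = "complete.obs", method = "pearson") else NA_real_
  list(n_matched = n, n_inconsistent = ninc, consistency = rate,
       ci = interval, pearson_r = r_all,
       pearson_r_no_double_negative = r_nodn)
}

#' Analyze a simulated (or real) screen from wells to hit calls
#'
#' Per well: gate, compute AmFRET, QC, 64-bin profile, fgate against the
#' batch monomer-control gate, mean-curve Weibull fit for C50. Wells failing
#' QC or without a converged fit are dropped; survivors go through
#' [score_screen()] and [call_hits()].
#'
#' @param screen output of [simulate_screen()] (or a list with the same
#'   shape)
#' @param gate_cfg [gate_config()] for cell gating
#' @param min_events,min_acceptor well QC thresholds
#' @param bin_range,n_bins profile binning parameters
#' @param min_bin_count minimum cells per bin for the mean curve
#' @return list with `result` (from [call_hits()]), `records` (per-well
#'   summaries incl. dropped wells), `meta`
#' @export
analyze_screen <- function(screen, gate_cfg = gate_config(),
                           min_events = 2500, min_acceptor = 3.5,
                           bin_range = c(10^0.5, 10^4.5), n_bins = 64,
                           min_bin_count = 100) {
  meta <- screen$meta
  # per-batch control gates
  gates <- lapply(screen$controls, function(ctrl) {
    ev <- compute_amfret(apply_gates(ctrl, gate_cfg))
    fret_positive_gate(bin_events(ev, bin_range, n_bins))
  })
  out <- vector("list", nrow(meta))
  for (i in seq_len(nrow(meta))) {
    mi <- meta[i]
    ev <- compute_amfret(apply_gates(screen$wells[[mi$well_id]], gate_cfg))
    qc <- well_qc(ev, min_events, min_acceptor)
    rowbase <- data.table::data.table(
      well_id = mi$well_id, dfd_id = mi$dfd_id, seed_id = mi$seed_id,
      batch = mi$batch, rep = mi$rep, truth = mi$truth,
      is_negative_control = mi$is_negative_control,
      qc_pass = qc$pass, c50 = NA_real_, fgate = NA_real_)
    if (!qc$pass) { out[[i]] <- rowbase; next }
    prof <- bin_events(ev, bin_range, n_bins)
    fa <- fraction_assembled(prof, gates[[mi$batch]])
    fit <- fit_weibull(mean_curve(prof, min_bin_count))
    if (isTRUE(fit$converged)) rowbase$c50 <- fit$C50
    rowbase$fgate <- fa$fgate
    out[[i]] <- rowbase
  }
  records <- data.table::rbindlist(out)
  usable <- records[qc_pass == TRUE & is.finite(c50) & is.finite(fgate)]
  scored <- score_screen(usable)
  res <- call_hits(scored)
  list(result = res, records = records, meta = meta)
}
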