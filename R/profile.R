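#' Bin events into the 64-bin logarithmic expression histogram
#'
#' Events are assigned to `n_bins` equal-log-width expression (acceptor) bins
#' over a fixed global range. Bins are left-closed, right-open; the top bin
#' is right-closed. Events outside the range are counted in overflow tallies
#' and excluded from the bins. Rows flagged invalid (gate or amfret flags)
#' are excluded first.
#'
#' @param events event table with `acceptor` and `amfret` columns
#' @param range expression range `(lo, hi)` in p.d.u., both positive;
#'   default spans 4 decades
#' @param n_bins number of bins (default 64)
#' @return a `binned_profile` list: `bin_edges` (length `n_bins + 1`),
#'   `bin_centers` (geometric), per-bin `count`, `median_amfret`,
#'   `mean_amfret`, `q99_amfret`, plus `n_total`, `n_under`, `n_over`
#' @export
bin_events <- function(events, range = c(10^0.5, 10^4.5), n_bins = 64) {
  lo <- range[1]; hi <- range[2]
  if (!(lo > 0) || !(hi > lo)) stop("range bounds must satisfy 0 < lo < hi")
  ev <- data.table::as.data.table(events)
  if ("gate_final" %in% names(ev)) ev <- ev[gate_final == TRUE]
  if ("amfret_valid" %in% names(ev)) ev <- ev[amfret_valid == TRUE]
  if (!"amfret" %in% names(ev)) stop("amfret column missing; run compute_amfret()")
  edges <- 10^seq(log10(lo), log10(hi), length.out = n_bins + 1)
  lx <- log10(ev$acceptor)
  n_under <- sum(lx < log10(lo))
  n_over <- sum(lx > log10(hi))
  keep <- lx >= log10(lo) & lx <= log10(hi)
  lxk <- lx[keep]; am <- ev$amfret[keep]
  # left-closed bins; top edge folded into last bin
  idx <- findInterval(lxk, log10(edges), rightmost.closed = TRUE)
  idx[idx > n_bins] <- n_bins
  dt <- data.table::data.table(bin = idx, amfret = am)
  agg <- dt[, .(count = .N,
                median_amfret = stats::median(amfret),
                mean_amfret = mean(amfret),
                q99_amfret = stats::quantile(amfret, 0.99, names = FALSE)),
            by = bin]
  count <- integer(n_bins)
  med <- mea <- q99 <- rep(NA_real_, n_bins)
  count[agg$bin] <- agg$count
  med[agg$bin] <- agg$median_amfret
  mea[agg$bin] <- agg$mean_amfret
  q99[agg$bin] <- agg$q99_amfret
  structure(list(bin_edges = edges,
                 bin_centers = sqrt(edges[-1] * edges[-(n_bins + 1)]),
                 count = count, median_amfret = med, mean_amfret = mea,
                 q99_amfret = q99,
                 n_total = nrow(ev), n_under = n_under, n_over = n_over,
                 events = dt),
            class = "binned_profile")
}

#' Per-bin FRET-positive gate from a monomer-only control
#'
#' The gate in each expression bin is the 99th percentile of the control's
#' AmFRET distribution in that bin; cells above it in a sample are counted
#' as assembled. Bins with fewer than `min_count` control cells take the
#' gate of the nearest populated bin.
#'
#' @param control a `binned_profile` of the monomer (e.g. mEos3-only) control
#' @param probs gate quantile (default 0.99)
#' @param min_count minimum control cells per bin for a direct gate
#' @return numeric vector of per-bin gate values
#' @export
fret_positive_gate <- function(control, probs = 0.99, min_count = 20) {
  stopifnot(inherits(control, "binned_profile"))
  n_bins <- length(control$count)
  gate <- rep(NA_real_, n_bins)
  ok <- which(control$count >= min_count)
  if (!length(ok)) stop("control has no sufficiently populated bins")
  ev <- control$events
  g <- ev[bin %in% ok, .(g = stats::quantile(amfret, probs, names = FALSE)), by = bin]
  gate[g$bin] <- g$g
  empty <- which(!seq_len(n_bins) %in% ok)
  if (length(empty)) {
    # nearest populated neighbor (leftmost on ties)
    for (i in empty) gate[i] <- gate[ok[which.min(abs(ok - i))]]
  }
  gate
}

#' Fraction of assembled (FRET-positive) cells per bin and overall
#'
#' Per-bin fraction is the count above the gate divided by the bin total;
#' `fgate` is the gross fraction: all above-gate cells over all binned cells.
#' Empty bins yield `NA` fractions and contribute nothing to `fgate`.
#'
#' @param sample a `binned_profile`
#' @param gate per-bin gate values from [fret_positive_gate()]
#' @return list with `fraction` (per bin), `n_above` (per bin), `fgate`
#' @export
fraction_assembled <- function(sample, gate) {
  stopifnot(inherits(sample, "binned_profile"))
  n_bins <- length(sample$count)
  if (length(gate) != n_bins) stop("gate must have one value per bin")
  ev <- sample$events
  ab <- ev[, .(n_above = sum(amfret > gate[bin])), by = bin]
  n_above <- integer(n_bins)
  n_above[ab$bin] <- ab$n_above
  frac <- ifelse(sample$count > 0, n_above / sample$count, NA_real_)
  tot <- sum(sample$count)
  list(fraction = frac, n_above = n_above,
       fgate = if (tot > 0) sum(n_above) / tot else NA_real_)
}
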