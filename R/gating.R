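#' Logicle (biexponential) scale parameters
#'
#' The logicle scale maps instrument intensities, which can be negative near
#' zero after compensation, onto a display scale that is linear around zero
#' and logarithmic at high intensity. It is the inverse of the biexponential
#' \deqn{S(x) = a e^{bx} - c e^{-dx} - f} with coefficients determined by the
#' top of scale `T`, the number of displayed decades `M`, the linearization
#' width `W` (decades) and the additional negative range `A` (decades).
#'
#' @param T top of scale (maximum expected intensity, p.d.u.), > 0
#' @param M total display width in decades, > 0
#' @param W linearization width in decades, `0 <= W < M/2`
#' @param A additional negative display decades, `-W <= A`
#' @return an object of class `logicle_params`
#' @export
logicle_params <- function(T = 262144, M = 4.5, W = 0.5, A = 0) {
  if (!(T > 0) || !(M > 0) || W < 0 || W >= M / 2 || A < -W)
    stop("invalid logicle parameters: need T>0, M>0, 0<=W<M/2, A>=-W")
  w <- W / (M + A)
  x2 <- A / (M + A)
  x1 <- x2 + w
  x0 <- x2 + 2 * w
  b <- (M + A) * log(10)
  # d solves 2 (log d - log b) + w (b + d) = 0 on (0, b)
  d <- if (w == 0) b else {
    f <- function(d) 2 * (log(d) - log(b)) + w * (b + d)
    stats::uniroot(f, c(b * 1e-12, b), tol = 1e-14)$root
  }
  c_a <- exp(x0 * (b + d))
  mf_a <- exp(b * x1) - c_a / exp(d * x1)
  a <- T / ((exp(b) - mf_a) - c_a / exp(d))
  cc <- c_a * a
  f <- mf_a * a   # S(x1) = 0: the zero intensity point maps to scale x1
  structure(list(T = T, M = M, W = W, A = A,
                 a = a, b = b, c = cc, d = d, f = f),
            class = "logicle_params")
}

#' Evaluate the biexponential (inverse logicle) at scale positions
#'
#' @param y scale positions in `[0, M]` display decades (values outside are
#'   extrapolated smoothly)
#' @param p a [logicle_params()] object
#' @return intensities on the instrument scale
#' @export
logicle_inverse <- function(y, p) {
  stopifnot(inherits(p, "logicle_params"))
  s <- y / (p$M + p$A)  # normalized scale in [0, 1]
  p$a * exp(p$b * s) - p$c * exp(-p$d * s) - p$f
}

#' Logicle transform of instrument intensities
#'
#' Strictly monotone map from intensities to display decades, computed by
#' Newton inversion of the biexponential (with bisection fallback). The
#' transform is near-linear around zero and logarithmic at high intensity.
#'
#' @param values numeric intensities (may be negative)
#' @param p a [logicle_params()] object
#' @param tol convergence tolerance on the scale axis
#' @return transformed values in display decades (scale `[0, M]` for
#'   intensities in `[S(0), T]`)
#' @export
logicle_transform <- function(values, p = logicle_params(), tol = 1e-10) {
  stopifnot(inherits(p, "logicle_params"))
  lo_y <- -0.5 * (p$M + p$A)
  hi_y <- 1.5 * (p$M + p$A)
  out <- numeric(length(values))
  # vectorized Newton on the normalized scale
  s <- rep(0.5, length(values))
  for (iter in 1:80) {
    fv <- p$a * exp(p$b * s) - p$c * exp(-p$d * s) - p$f - values
    dv <- p$a * p$b * exp(p$b * s) + p$c * p$d * exp(-p$d * s)
    step <- fv / dv
    s <- s - step
    s <- pmin(pmax(s, lo_y / (p$M + p$A)), hi_y / (p$M + p$A))
    if (max(abs(step), na.rm = TRUE) < tol / (p$M + p$A)) break
  }
  out <- s * (p$M + p$A)
  bad <- !is.finite(out)
  if (any(bad)) {  # bisection fallback for pathological starts
    for (i in which(bad)) {
      g <- function(yy) logicle_inverse(yy, p) - values[i]
      out[i] <- stats::uniroot(g, c(lo_y, hi_y), tol = tol, extendInt = "yes")$root
    }
  }
  out
}

#' Inverse hyperbolic sine transform (simple logicle alternative)
#'
#' @param values intensities
#' @param cofactor divisor before asinh; larger values widen the linear zone
#' @return transformed values
#' @export
asinh_transform <- function(values, cofactor = 150) {
  asinh(values / cofactor)
}

#' Gate configuration for per-cell filtering
#'
#' Gates are rectangular thresholds (or optional polygons) applied to channel
#' pairs after transformation: (fsc_a, ssc_a) for debris, (fsc_h, fsc_w) for
#' singlets, and (donor, autofluor) for expressing cells.
#'
#' @param scatter named list with `fsc_a` and `ssc_a` ranges (length-2)
#' @param singlet named list with `fsc_h` and `fsc_w` ranges
#' @param expression named list with `donor` and `autofluor` ranges
#' @param polygons optional named list of 2-column polygon matrices, keyed
#'   `scatter`, `singlet`, `expression`; when present, a polygon overrides the
#'   rectangle for that gate
#' @param transform transform applied to gate channels before comparison:
#'   `"logicle"`, `"asinh"` or `"identity"`
#' @param transform_params [logicle_params()] for the logicle transform, or a
#'   cofactor for asinh
#' @return a `gate_config` object
#' @export
gate_config <- function(scatter = list(fsc_a = c(2e4, 2.5e5), ssc_a = c(1e2, 2.5e5)),
                        singlet = list(fsc_h = c(1e4, 2.6e5), fsc_w = c(30, 95)),
                        expression = list(donor = c(5, Inf), autofluor = c(-Inf, 400)),
                        polygons = NULL,
                        transform = c("identity", "logicle", "asinh"),
                        transform_params = NULL) {
  transform <- match.arg(transform)
  if (!is.null(polygons)) {
    for (nm in names(polygons)) {
      pg <- polygons[[nm]]
      if (!is.matrix(pg) || ncol(pg) != 2 || nrow(pg) < 3)
        stop("degenerate polygon for gate '", nm, "'")
    }
  }
  structure(list(scatter = scatter, singlet = singlet,
                 expression = expression, polygons = polygons,
                 transform = transform, transform_params = transform_params),
            class = "gate_config")
}

.apply_channel_transform <- function(v, cfg) {
  switch(cfg$transform,
         identity = v,
         logicle = logicle_transform(v, cfg$transform_params %||% logicle_params()),
         asinh = asinh_transform(v, cfg$transform_params %||% 150))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.point_in_polygon <- function(x, y, poly) {
  # ray casting; boundary counted as inside
  np <- nrow(poly)
  inside <- rep(FALSE, length(x))
  j <- np
  for (i in seq_len(np)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

.rect_gate <- function(events, cfg, gate_name, chans) {
  pg <- cfg$polygons[[gate_name]]
  v1 <- .apply_channel_transform(events[[chans[1]]], cfg)
  v2 <- .apply_channel_transform(events[[chans[2]]], cfg)
  if (!is.null(pg)) {
    .point_in_polygon(v1, v2, pg)
  } else {
    r1 <- cfg[[gate_name]][[chans[1]]]
    r2 <- cfg[[gate_name]][[chans[2]]]
    v1 >= r1[1] & v1 <= r1[2] & v2 >= r2[1] & v2 <= r2[2]
  }
}

#' Apply cell-level gates, flagging rows rather than deleting them
#'
#' Three sequential gates mirror the standard DAmFRET gating scheme:
#' scatter (fsc_a vs ssc_a), singlet (fsc_h vs fsc_w) and expressing cells
#' (donor vs autofluor). Flags are stored in logical columns
#' `gate_scatter`, `gate_singlet`, `gate_expression`, and their intersection
#' in `gate_final`. Row count is conserved.
#'
#' @param events a `data.table` event table (see [simulate_events()] for the
#'   schema)
#' @param cfg a [gate_config()]
#' @return the event table with gate flag columns added (copy)
#' @export
apply_gates <- function(events, cfg = gate_config()) {
  needed <- c("fsc_a", "ssc_a", "fsc_h", "fsc_w", "donor", "autofluor")
  missing <- setdiff(needed, names(events))
  if (length(missing))
    stop("missing channels: ", paste(missing, collapse = ", "))
  ev <- data.table::as.data.table(events)
  ev[, gate_scatter := .rect_gate(ev, cfg, "scatter", c("fsc_a", "ssc_a"))]
  ev[, gate_singlet := .rect_gate(ev, cfg, "singlet", c("fsc_h", "fsc_w"))]
  ev[, gate_expression := .rect_gate(ev, cfg, "expression", c("donor", "autofluor"))]
  ev[, gate_final := gate_scatter & gate_singlet & gate_expression]
  ev[]
}

#' Compute the AmFRET ratio (FRET intensity / acceptor intensity)
#'
#' Rows with acceptor at or below `acceptor_floor` are flagged in
#' `amfret_valid` and their `amfret` set to `NA` rather than divided.
#'
#' @param events event table with `fret` and `acceptor` columns
#' @param acceptor_floor positive floor below which the ratio is undefined
#' @return event table with `amfret` and `amfret_valid` columns (copy)
#' @export
compute_amfret <- function(events, acceptor_floor = 0) {
  if (!"acceptor" %in% names(events)) stop("acceptor channel missing")
  if (!"fret" %in% names(events)) stop("fret channel missing")
  ev <- data.table::as.data.table(events)
  ev[, amfret_valid := acceptor > acceptor_floor]
  ev[, amfret := ifelse(amfret_valid, fret / acceptor, NA_real_)]
  ev[]
}

#' Well-level quality control
#'
#' A well passes iff it has at least `min_events` gated events and a mean
#' acceptor intensity of at least `min_acceptor` p.d.u. Boundaries are
#' inclusive: the failing conditions are "fewer than" / "less than".
#'
#' @param events a gated event table (uses `gate_final` when present)
#' @param min_events minimum gated event count (default 2500)
#' @param min_acceptor minimum mean acceptor intensity, p.d.u. (default 3.5)
#' @return list with `n_events`, `mean_acceptor`, `pass`, `reasons`
#' @export
well_qc <- function(events, min_events = 2500, min_acceptor = 3.5) {
  ev <- data.table::as.data.table(events)
  if ("gate_final" %in% names(ev)) ev <- ev[gate_final == TRUE]
  n <- nrow(ev)
  ma <- if (n > 0) mean(ev$acceptor) else NaN
  reasons <- character(0)
  if (n < min_events) reasons <- c(reasons, "n_events")
  if (!is.finite(ma) || ma < min_acceptor) reasons <- c(reasons, "mean_acceptor")
  list(n_events = n, mean_acceptor = ma,
       pass = length(reasons) == 0, reasons = reasons)
}

#' Drop proteins or seeds that lost too many instances to QC
#'
#' An identifier is retained iff `retained/original >= min_fraction`
#' (boundary inclusive; the failing condition is "less than").
#'
#' @param original named integer vector of original instance counts
#' @param retained named integer vector of post-QC counts (same names)
#' @param min_fraction minimum retained fraction (default 0.25)
#' @return character vector of retained identifiers
#' @export
instance_retention_filter <- function(original, retained, min_fraction = 0.25) {
  if (any(original <= 0)) stop("zero original instances for: ",
                               paste(names(original)[original <= 0], collapse = ", "))
  ids <- names(original)
  r <- retained[ids]
  r[is.na(r)] <- 0
  ids[r / original >= min_fraction]
}
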