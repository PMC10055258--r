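#' Select the brightest plane of a z-stack
#'
#' @param zstack list of image matrices
#' @return the plane with maximal summed intensity (lowest index on ties)
#' @export
brightest_plane <- function(zstack) {
  if (!length(zstack)) stop("empty z-stack")
  sums <- vapply(zstack, sum, numeric(1))
  zstack[[which.max(sums)]]
}

# grayscale erosion/dilation with a disc footprint via shifted min/max;
# edges use replicate padding
.disc_offsets <- function(radius) {
  r <- floor(radius)
  off <- expand.grid(dy = -r:r, dx = -r:r)
  off[off$dy^2 + off$dx^2 <= radius^2, ]
}

.shift_pad <- function(img, dy, dx) {
  nr <- nrow(img); nc <- ncol(img)
  ri <- pmin(pmax(seq_len(nr) + dy, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) + dx, 1L), nc)
  img[ri, ci, drop = FALSE]
}

.gray_erode <- function(img, off) {
  out <- .shift_pad(img, off$dy[1], off$dx[1])
  for (i in seq_len(nrow(off))[-1]) out <- pmin(out, .shift_pad(img, off$dy[i], off$dx[i]))
  out
}

.gray_dilate <- function(img, off) {
  out <- .shift_pad(img, off$dy[1], off$dx[1])
  for (i in seq_len(nrow(off))[-1]) out <- pmax(out, .shift_pad(img, off$dy[i], off$dx[i]))
  out
}

#' Rolling-ball background subtraction
#'
#' Estimates the background as the grayscale opening of the image with a
#' disc structuring element of the given radius (the flat limit of a wide,
#' shallow rolling ball: structures narrower than the ball stay out of the
#' background and survive subtraction; smooth gradients are removed). The
#' result is clamped at zero.
#'
#' @param image numeric matrix
#' @param radius ball radius in pixels (default 100); must be smaller than
#'   the smallest image dimension
#' @return background-subtracted image (same shape)
#' @export
rolling_ball_subtract <- function(image, radius = 100) {
  if (radius < 1) stop("radius must be >= 1")
  if (radius >= min(dim(image))) stop("radius must be smaller than the image")
  off <- .disc_offsets(radius)
  bg <- .gray_dilate(.gray_erode(image, off), off)
  pmax(image - bg, 0)
}

#' "Default" (iterative intermeans / isodata) threshold
#'
#' The image is rescaled to a 256-bin histogram and the intermeans criterion
#' `t = round((mean_below(t) + mean_above(t)) / 2)` is solved exhaustively
#' over all levels. Multimodal histograms can admit several fixed points;
#' the smallest is returned, which is the background/foreground split (the
#' behavior of the classical method on fluorescence images, where the
#' dominant dark mode is the background). The threshold is reported on the
#' original intensity scale.
#'
#' @param image numeric matrix, non-constant
#' @return list with `threshold` (intensity), `mask` (logical matrix,
#'   pixels strictly above threshold) and `level` (0-255 histogram level)
#' @export
threshold_default <- function(image) {
  rng <- range(image)
  if (!(rng[2] > rng[1])) stop("constant image has no threshold")
  nb <- 256L
  binw <- diff(rng) / nb
  bin <- pmin(pmax(floor((image - rng[1]) / binw), 0L), nb - 1L)  # 0..255
  h <- tabulate(bin + 1L, nbins = nb)
  lev <- 0:(nb - 1)
  csum_n <- cumsum(h)
  csum_s <- cumsum(h * lev)
  tot_n <- csum_n[nb]; tot_s <- csum_s[nb]
  cand <- which(csum_n > 0 & csum_n < tot_n)  # levels with both classes
  mu0 <- csum_s[cand] / csum_n[cand]
  mu1 <- (tot_s - csum_s[cand]) / (tot_n - csum_n[cand])
  # smallest level satisfying the intermeans criterion t >= (mu0 + mu1)/2
  ok <- which(lev[cand] >= (mu0 + mu1) / 2)
  if (!length(ok)) stop("no intermeans threshold found")
  t0 <- lev[cand][min(ok)]
  thr <- rng[1] + (t0 + 1) * binw  # upper edge of the threshold bin
  list(threshold = thr, mask = image > thr, level = t0)
}

#' Label 8-connected components of a binary mask
#'
#' @param mask logical matrix
#' @return integer matrix of component labels (0 = background)
#' @export
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  idx <- which(mask)
  for (start in idx) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    stack <- start
    lab[start] <- cur
    while (length(stack)) {
      p <- stack[length(stack)]
      stack <- stack[-length(stack)]
      r <- ((p - 1L) %% nr) + 1L
      cl <- ((p - 1L) %/% nr) + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- cl + dc
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc) {
          q <- (cc - 1L) * nr + rr
          if (mask[q] && lab[q] == 0L) { lab[q] <- cur; stack <- c(stack, q) }
        }
      }
    }
  }
  lab
}

#' Per-object intensity and shape statistics
#'
#' For each labeled component: mean, SD, coefficient of variation
#' (SD/mean*100), area, and aspect ratio from the best-fit ellipse
#' (square root of the ratio of the eigenvalues of the second central
#' moments of the pixel coordinates). Single-pixel objects get AR = 1 and
#' SD = 0.
#'
#' @param image intensity matrix
#' @param labels integer label matrix from [label_components()]
#' @return data.frame with `label`, `area`, `mean`, `sd`, `cv`, `ar`,
#'   `centroid_row`, `centroid_col`
#' @export
object_stats <- function(image, labels) {
  ids <- setdiff(sort(unique(as.integer(labels))), 0L)
  if (!length(ids)) stop("mask has no components")
  out <- lapply(ids, function(id) {
    px <- which(labels == id)
    v <- image[px]
    nr <- nrow(image)
    r <- ((px - 1L) %% nr) + 1L
    cl <- ((px - 1L) %/% nr) + 1L
    m <- mean(v)
    s <- if (length(v) > 1) sd(v) else 0
    ar <- if (length(px) < 2) 1 else {
      mu_rr <- mean((r - mean(r))^2) + 1 / 12  # pixel-extent correction
      mu_cc <- mean((cl - mean(cl))^2) + 1 / 12
      mu_rc <- mean((r - mean(r)) * (cl - mean(cl)))
      tr <- mu_rr + mu_cc
      det <- mu_rr * mu_cc - mu_rc^2
      disc <- sqrt(max(tr^2 / 4 - det, 0))
      l1 <- tr / 2 + disc; l2 <- tr / 2 - disc
      if (l2 <= 0) Inf else sqrt(l1 / l2)
    }
    data.frame(label = id, area = length(px), mean = m, sd = s,
               cv = if (m > 0) s / m * 100 else NA_real_,
               ar = ar, centroid_row = mean(r), centroid_col = mean(cl))
  })
  do.call(rbind, out)
}

#' Classify object morphology from CV and aspect ratio
#'
#' Two printed threshold sets:
#' \describe{
#'   \item{set1}{fibrillar: CV > 55 and AR > 1.159; punctate: CV > 55 and
#'     AR < 1.16; diffuse: CV < 55 and AR < 1.16.}
#'   \item{set2}{fibrillar: CV > 17 and AR > 1.4; punctate: CV > 17 and
#'     AR < 1.41; diffuse: CV < 18 and AR < 1.41.}
#' }
#' Combinations the rules leave uncovered (e.g. set1 with CV < 55 and
#' AR > 1.16, or values in the razor-thin boundary gaps) return
#' `"unclassified"` rather than being silently assigned.
#'
#' @param cv coefficient of variation (percent)
#' @param ar aspect ratio (>= 1)
#' @param threshold_set `"set1"` (default) or `"set2"`
#' @return character class, vectorized over inputs
#' @export
classify_morphology <- function(cv, ar, threshold_set = c("set1", "set2")) {
  threshold_set <- match.arg(threshold_set)
  f <- function(cv, ar) {
    if (!is.finite(cv) || !is.finite(ar)) return("unclassified")
    # the printed rules overlap in thin AR/CV bands (1.159-1.16, 1.4-1.41,
    # 17-18); a value is classified only when exactly one rule matches
    hits <- if (threshold_set == "set1") {
      c(fibrillar = cv > 55 && ar > 1.159,
        punctate = cv > 55 && ar < 1.16,
        diffuse = cv < 55 && ar < 1.16)
    } else {
      c(fibrillar = cv > 17 && ar > 1.4,
        punctate = cv > 17 && ar < 1.41,
        diffuse = cv < 18 && ar < 1.41)
    }
    if (sum(hits) == 1) names(hits)[hits] else "unclassified"
  }
  mapply(f, cv, ar, USE.NAMES = FALSE)
}

#' Full morphology analysis of one image
#'
#' Rolling-ball background subtraction, Default threshold, component
#' labeling, object statistics and CV/AR classification.
#'
#' @param image intensity matrix (or list of planes; brightest used)
#' @param radius rolling-ball radius
#' @param threshold_set CV/AR threshold set
#' @param min_area drop components smaller than this (pixels)
#' @return data.frame of object statistics with `class`
#' @export
analyze_image <- function(image, radius = 100, threshold_set = "set1",
                          min_area = 9) {
  if (is.list(image)) image <- brightest_plane(image)
  sub <- rolling_ball_subtract(image, radius)
  th <- threshold_default(sub)
  lab <- label_components(th$mask)
  st <- object_stats(sub, lab)
  st <- st[st$area >= min_area, , drop = FALSE]
  st$class <- classify_morphology(st$cv, st$ar, threshold_set)
  st
}

#' Per-ROI coefficient of variation over a time course
#'
#' Cluster formation in a cell manifests as a rising CV of its fluorescence
#' distribution.
#'
#' @param frames list of image matrices (time ordered)
#' @param rois list of logical matrices (one per ROI, image-shaped) or
#'   index vectors into the image
#' @return matrix of CV values, ROIs x frames
#' @export
roi_cv_timecourse <- function(frames, rois) {
  stopifnot(length(frames) >= 1, length(rois) >= 1)
  dimg <- dim(frames[[1]])
  idx <- lapply(rois, function(rr) {
    if (is.logical(rr)) {
      if (!identical(dim(rr), dimg)) stop("roi outside image")
      which(rr)
    } else {
      if (any(rr < 1 | rr > prod(dimg))) stop("roi outside image")
      as.integer(rr)
    }
  })
  if (any(vapply(idx, length, integer(1)) == 0)) stop("empty roi")
  out <- matrix(NA_real_, length(rois), length(frames))
  for (f in seq_along(frames)) {
    for (r in seq_along(idx)) {
      v <- frames[[f]][idx[[r]]]
      out[r, f] <- if (mean(v) > 0) sd(v) / mean(v) * 100 else NA_real_
    }
  }
  out
}

#' Write a matrix as 16-bit TIFF (when the tiff package is available)
#'
#' @param image numeric matrix (scaled to the 16-bit range by its maximum)
#' @param path output path
#' @export
write_image_tiff <- function(image, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required to write TIFF files")
  mx <- max(image)
  tiff::writeTIFF(pmin(pmax(image / ifelse(mx > 0, mx, 1), 0), 1),
                  path, bits.per.sample = 16L)
  invisible(path)
}
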