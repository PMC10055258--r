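#' Phenotype specification for synthetic DAmFRET wells
#'
#' Describes the ground-truth concentration-dependence of self-assembly for
#' one simulated well. Behaviors:
#' \describe{
#'   \item{one_state_low}{no assembly at any concentration: AmFRET ~
#'     Normal(0, noise_sd) everywhere.}
#'   \item{one_state_high}{fully assembled at all concentrations.}
#'   \item{continuous_low_to_high}{mean AmFRET follows the stretched
#'     exponential `Amp (1 - exp(-ln2 (c/C50)^a))` — every cell tracks the
#'     mean, so the distribution is unimodal at all concentrations.}
#'   \item{discontinuous}{each cell is assembled with a probability rising
#'     from 0 to 1 over `nucleation_width` decades around `true_c50`
#'     (log-logistic in concentration), producing a bimodal AmFRET mixture in
#'     the transition window — the signature of a nucleation barrier.}
#' }
#' With `seeded = TRUE` the barrier is removed in trans: all cells above
#' `true_c50 / seed_fold_reduction` are assembled.
#'
#' @param behavior one of the four behaviors above
#' @param true_c50 mid-transition expression (p.d.u.), within the simulated
#'   range
#' @param true_amp asymptotic AmFRET of the assembled state, > 0
#' @param true_a steepness of the stretched exponential (continuous case)
#' @param nucleation_width decades over which the assembled fraction rises
#'   from ~5% to ~95% (discontinuous case), > 0
#' @param seeded logical; seed present in trans
#' @param seed_fold_reduction factor (>= 1) by which seeding lowers the
#'   transition concentration
#' @param noise_sd AmFRET measurement noise SD
#' @param batch_shift multiplicative expression-scale shift for batch effects
#' @param expr_mean,expr_sd mean and SD of log10 expression (p.d.u.)
#' @return a `phenotype_spec` object
#' @export
phenotype_spec <- function(behavior = c("one_state_low", "one_state_high",
                                        "continuous_low_to_high", "discontinuous"),
                           true_c50 = 100, true_amp = 0.3, true_a = 2,
                           nucleation_width = 0.5, seeded = FALSE,
                           seed_fold_reduction = 4, noise_sd = 0.05,
                           batch_shift = 1, expr_mean = 2.5, expr_sd = 0.8) {
  behavior <- match.arg(behavior)
  if (!(true_amp > 0)) stop("true_amp must be > 0")
  if (!(nucleation_width > 0)) stop("nucleation_width must be > 0")
  if (seed_fold_reduction < 1) stop("seed_fold_reduction must be >= 1")
  if (!(true_c50 > 10^0.5 && true_c50 < 10^4.5))
    stop("true_c50 must lie within the simulated expression range")
  structure(list(behavior = behavior, true_c50 = true_c50,
                 true_amp = true_amp, true_a = true_a,
                 nucleation_width = nucleation_width, seeded = seeded,
                 seed_fold_reduction = seed_fold_reduction,
                 noise_sd = noise_sd, batch_shift = batch_shift,
                 expr_mean = expr_mean, expr_sd = expr_sd),
            class = "phenotype_spec")
}

#' Canonical instrument channel aliases
#'
#' Maps the cytometer channel names used in DAmFRET acquisitions to the
#' schema column names used throughout this package.
#'
#' @return named character vector (instrument name -> schema name)
#' @export
channel_aliases <- function() {
  c("FS00.A" = "fsc_a", "FS00.H" = "fsc_h", "FS00.W" = "fsc_w",
    "SS02.A" = "ssc_a", "FL03.A" = "donor", "FL17.A" = "autofluor",
    "acceptor" = "acceptor", "FRET" = "fret")
}

#' Simulate a single-well event table with known ground truth
#'
#' Expression (the acceptor intensity proxy) is log-normal on a log10 p.d.u.
#' axis; AmFRET follows the behavior encoded in `spec` plus Gaussian noise;
#' scatter, donor and autofluorescence channels are filled so that at least
#' ~90% of events pass the default gates. The `fret` channel is set to
#' `amfret * acceptor`, so the measured ratio reproduces the latent AmFRET.
#'
#' @param spec a [phenotype_spec()]
#' @param n_cells number of events, >= 1
#' @param rng_seed integer seed; fixing it makes the well bit-reproducible
#' @return a `data.table` with channels `fsc_a, fsc_h, fsc_w, ssc_a, donor,
#'   autofluor, acceptor, fret` and truth columns `true_assembled`
#' @export
simulate_events <- function(spec, n_cells, rng_seed = 1) {
  stopifnot(inherits(spec, "phenotype_spec"))
  if (n_cells < 1) stop("n_cells must be >= 1")
  set.seed(rng_seed)
  lx <- rnorm(n_cells, spec$expr_mean, spec$expr_sd)
  lx <- pmin(pmax(lx, 0.55), 4.45)      # keep within the global binning range
  acceptor <- 10^lx * spec$batch_shift

  lc50 <- log10(spec$true_c50 * spec$batch_shift)
  assembled <- switch(spec$behavior,
    one_state_low = rep(FALSE, n_cells),
    one_state_high = rep(TRUE, n_cells),
    continuous_low_to_high = rep(NA, n_cells),   # graded, not binary
    discontinuous = {
      if (spec$seeded) {
        log10(acceptor) > lc50 - log10(spec$seed_fold_reduction)
      } else {
        # log-logistic nucleation probability: 5% -> 95% over nucleation_width
        slope <- 2 * log(19) / (spec$nucleation_width * log(10))
        p <- stats::plogis((log(acceptor) - lc50 * log(10)) * slope)
        runif(n_cells) < p
      }
    })

  mean_amfret <- switch(spec$behavior,
    one_state_low = rep(0, n_cells),
    one_state_high = rep(spec$true_amp, n_cells),
    continuous_low_to_high = {
      c50 <- if (spec$seeded) 10^(lc50 - log10(spec$seed_fold_reduction)) else 10^lc50
      weibull_eval(acceptor, Amp = spec$true_amp, C50 = c50, a = spec$true_a)
    },
    discontinuous = ifelse(assembled, spec$true_amp, 0))

  amfret <- mean_amfret + rnorm(n_cells, 0, spec$noise_sd)

  fsc_a <- rnorm(n_cells, 1.2e5, 1.5e4)
  ev <- data.table::data.table(
    fsc_a = fsc_a,
    fsc_h = fsc_a * rnorm(n_cells, 0.95, 0.03),
    fsc_w = rnorm(n_cells, 65, 8),
    ssc_a = 10^rnorm(n_cells, 4, 0.3),
    donor = acceptor * 10^rnorm(n_cells, -0.3, 0.1),
    autofluor = pmax(rnorm(n_cells, 50, 15), 0),
    acceptor = acceptor,
    fret = amfret * acceptor,
    true_assembled = assembled
  )
  data.table::setattr(ev, "phenotype_spec", spec)
  ev
}

#' Simulate an all-by-all seeding screen with planted truth
#'
#' Builds one well per (protein, seed) pair. Each protein (the mEos3-fused
#' query) has a discontinuous phenotype; wells whose pair is planted as a
#' true nucleating interaction are simulated `seeded = TRUE` (reduced C50,
#' increased assembled fraction). Two negative-control seeds per protein are
#' always included and never seed. Per-batch multiplicative expression shifts
#' emulate day effects. A monomer control well per batch provides the
#' FRET-positive gate.
#'
#' @param n_dfd number of query proteins
#' @param n_seed number of seeds (in addition to the two negative controls)
#' @param frac_positive fraction of (protein, seed) pairs planted as true
#'   nucleating interactions
#' @param n_cells events per well
#' @param n_batch number of batches (proteins split across batches)
#' @param reps replicate wells per pair
#' @param rng_seed integer seed
#' @param seed_fold_reduction C50 fold reduction for true interactions
#' @param batch_sd SD of log10 batch shifts
#' @param well_jitter_sd SD (decades) of per-well biological variability in
#'   the transition concentration
#' @return list with `wells` (list of event tables), `meta` (data.table of
#'   well_id, dfd_id, seed_id, batch, rep, truth flag), `controls` (list of
#'   monomer control tables keyed by batch)
#' @export
simulate_screen <- function(n_dfd = 10, n_seed = 10, frac_positive = 0.05,
                            n_cells = 10000, n_batch = 2, reps = 1,
                            rng_seed = 1, seed_fold_reduction = 4,
                            batch_sd = 0.05, well_jitter_sd = 0.05) {
  if (n_dfd < 1 || n_seed < 0) stop("empty screen matrix")
  set.seed(rng_seed)
  dfds <- sprintf("DFD%02d", seq_len(n_dfd))
  seeds <- c(sprintf("seed%02d", seq_len(n_seed)), "negctrl1", "negctrl2")
  grid <- data.table::CJ(dfd_id = dfds, seed_id = seeds)
  is_candidate <- !grepl("^negctrl", grid$seed_id)
  n_pos <- round(frac_positive * sum(is_candidate))
  pos_idx <- sample(which(is_candidate), n_pos)
  grid[, truth := FALSE]
  grid[pos_idx, truth := TRUE]
  batches <- sprintf("batch%d", ((match(grid$dfd_id, dfds) - 1) %% n_batch) + 1)
  grid[, batch := batches]
  shift <- setNames(10^rnorm(n_batch, 0, batch_sd), sprintf("batch%d", seq_len(n_batch)))

  # per-protein phenotype parameters, fixed across that protein's wells
  c50s <- setNames(10^runif(n_dfd, 2.4, 2.9), dfds)
  amps <- setNames(runif(n_dfd, 0.25, 0.4), dfds)

  wells <- list(); meta <- list(); k <- 0L
  for (r in seq_len(reps)) {
    for (i in seq_len(nrow(grid))) {
      k <- k + 1L
      row <- grid[i]
      sp <- phenotype_spec(
        behavior = "discontinuous",
        true_c50 = c50s[[row$dfd_id]] * 10^rnorm(1, 0, well_jitter_sd),
        true_amp = amps[[row$dfd_id]],
        nucleation_width = 0.5,
        seeded = row$truth,
        seed_fold_reduction = seed_fold_reduction,
        batch_shift = shift[[row$batch]])
      wid <- sprintf("w%05d", k)
      wells[[wid]] <- simulate_events(sp, n_cells,
                                      rng_seed = rng_seed + 13L * k)
      meta[[k]] <- data.table::data.table(
        well_id = wid, dfd_id = row$dfd_id, seed_id = row$seed_id,
        batch = row$batch, rep = r, truth = row$truth,
        is_negative_control = grepl("^negctrl", row$seed_id))
    }
  }
  controls <- lapply(setNames(nm = sprintf("batch%d", seq_len(n_batch))), function(b) {
    sp <- phenotype_spec("one_state_low", batch_shift = shift[[b]])
    simulate_events(sp, max(n_cells, 20000),
                    rng_seed = rng_seed + 997L * match(b, names(shift)))
  })
  list(wells = wells, meta = data.table::rbindlist(meta), controls = controls)
}

#' Render a synthetic fluorescence image with labeled objects
#'
#' Draws objects of three morphology classes on a noisy background:
#' \describe{
#'   \item{diffuse}{wide, near-circular, uniform low-contrast ellipse (low
#'     coefficient of variation, aspect ratio near 1).}
#'   \item{punctate}{compact isotropic Gaussian spot (high CV, AR near 1).}
#'   \item{fibrillar}{elongated anisotropic Gaussian ridge at a random
#'     orientation (high CV, high AR).}
#' }
#'
#' @param classes character vector of object classes to draw (placement is
#'   on a jittered grid so objects do not overlap)
#' @param image_shape integer c(rows, cols)
#' @param rng_seed integer seed
#' @param background mean background level
#' @param noise_sd background noise SD
#' @return list with `image` (matrix), `truth` (data.table of row, col,
#'   class per object)
#' @export
render_objects <- function(classes, image_shape = c(192, 192), rng_seed = 1,
                           background = 100, noise_sd = 3) {
  set.seed(rng_seed)
  nr <- image_shape[1]; nc <- image_shape[2]
  img <- matrix(rnorm(nr * nc, background, noise_sd), nr, nc)
  n <- length(classes)
  if (n == 0) return(list(image = img, truth = data.table::data.table(
    row = numeric(0), col = numeric(0), class = character(0))))
  # jittered grid placement, margin wide enough for the largest object
  ngrid <- ceiling(sqrt(n))
  margin <- 24
  if ((nr - 2 * margin) / ngrid < 30 || (nc - 2 * margin) / ngrid < 30)
    stop("objects do not fit inside the image without overlap")
  gy <- seq(margin, nr - margin, length.out = ngrid)
  gx <- seq(margin, nc - margin, length.out = ngrid)
  pos <- data.table::CJ(y = gy, x = gx)[seq_len(n)]
  pos <- pos[sample(.N)]
  rows <- seq_len(nr); cols <- seq_len(nc)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    cy <- pos$y[i] + runif(1, -3, 3)
    cx <- pos$x[i] + runif(1, -3, 3)
    cls <- classes[i]
    dy <- outer(rows - cy, rep(1, nc))
    dx <- outer(rep(1, nr), cols - cx)
    add <- switch(cls,
      diffuse = {
        # wide uniform low-contrast plateau, near-circular; its pixel mass
        # anchors the global threshold below the plateau level
        th <- runif(1, 0, pi)
        a <- runif(1, 12, 14); b <- a * runif(1, 0.94, 1)
        u <- dy * cos(th) + dx * sin(th)
        v <- -dy * sin(th) + dx * cos(th)
        inside <- (u / a)^2 + (v / b)^2 <= 1
        (700 + matrix(rnorm(nr * nc, 0, 8), nr, nc)) * inside
      },
      punctate = {
        # bright condensed core over a graded halo: high in-object contrast
        s <- runif(1, 2.3, 2.7)
        r2 <- dy^2 + dx^2
        4000 * exp(-r2 / (2 * s^2)) + 2500 * exp(-r2 / (2 * 0.9^2))
      },
      fibrillar = {
        th <- runif(1, 0, pi)
        u <- dy * cos(th) + dx * sin(th)
        v <- -dy * sin(th) + dx * cos(th)
        u2 <- u^2 / (2 * 8^2)
        4000 * exp(-(u2 + v^2 / (2 * 2.2^2))) +
          2500 * exp(-(u2 + v^2 / (2 * 0.8^2)))
      },
      stop("unknown object class: ", cls))
    img <- img + add
    truth[[i]] <- data.table::data.table(row = cy, col = cx, class = cls)
  }
  list(image = img, truth = data.table::rbindlist(truth))
}

#' Write an event table as CSV with the documented header
#'
#' @param events event table
#' @param path output file
#' @export
write_well_csv <- function(events, path) {
  data.table::fwrite(data.table::as.data.table(events), path)
  invisible(path)
}

#' Read an event table CSV (accepting instrument channel aliases)
#'
#' @param path CSV file
#' @return data.table in the package schema
#' @export
read_well_csv <- function(path) {
  ev <- data.table::fread(path)
  al <- channel_aliases()
  hit <- intersect(names(ev), names(al))
  if (length(hit)) data.table::setnames(ev, hit, unname(al[hit]))
  ev
}
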