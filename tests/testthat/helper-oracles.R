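# Independent oracles used across the suite.

# Exact minimax dip oracle from the definition, for small tie-free samples.
# A unimodal CDF restricted to the data points is characterized by monotone
# values within sup-norm bands around the empirical CDF whose slope sequence
# is nondecreasing left of the mode and nonincreasing right of it, with
# exactly one unconstrained slope pair at the mode; an atom at a data point
# splits that point's value into left/right copies with relaxed bands.
# Each modal structure is an LP, solved as a ridge-regularized QP.
dip_oracle <- function(x, ridge = 1e-10) {
  x <- sort(x); n <- length(x); dx <- diff(x)
  stopifnot(n >= 4, all(dx > 0))
  solve_lp <- function(Amat, bvec, nv) {
    D <- diag(ridge, nv); d <- rep(0, nv); d[nv] <- -1
    r <- tryCatch(quadprog::solve.QP(D, d, t(Amat), bvec),
                  error = function(e) NULL)
    if (is.null(r)) NA_real_ else r$solution[nv]
  }
  slope_pair_row <- function(nv, i1, i2, i3, d1, d2, sgn) {
    r <- rep(0, nv)
    r[i1] <- -1 / d1; r[i2] <- 1 / d1 + 1 / d2; r[i3] <- -1 / d2
    sgn * -r
  }
  best <- Inf
  for (P in 0:(n - 1)) {  # one absent slope pair at the mode
    nv <- n + 1
    A <- NULL; b <- NULL
    add <- function(row, rhs) { A <<- rbind(A, row); b <<- c(b, rhs) }
    for (i in 1:n) {
      r <- rep(0, nv); r[i] <- 1; r[nv] <- 1; add(r, i / n)
      r <- rep(0, nv); r[i] <- -1; r[nv] <- 1; add(r, -(i - 1) / n)
    }
    for (i in 1:(n - 1)) { r <- rep(0, nv); r[i + 1] <- 1; r[i] <- -1; add(r, 0) }
    r <- rep(0, nv); r[1] <- 1; add(r, 0)
    r <- rep(0, nv); r[n] <- -1; add(r, -1)
    for (i in 1:(n - 2)) {
      if (i == P) next
      sgn <- if (i < P) +1 else -1
      add(slope_pair_row(nv, i, i + 1, i + 2, dx[i], dx[i + 1], sgn), 0)
    }
    v <- solve_lp(A, b, nv)
    if (is.finite(v)) best <- min(best, v)
  }
  for (k in 1:n) {  # atom at data point k
    nv <- n + 2; iL <- n + 1; it <- n + 2
    A <- NULL; b <- NULL
    add <- function(row, rhs) { A <<- rbind(A, row); b <<- c(b, rhs) }
    for (i in 1:n) {
      lo <- if (i == k) k / n else i / n
      hi <- if (i == k) k / n else (i - 1) / n
      r <- rep(0, nv); r[i] <- 1; r[it] <- 1; add(r, lo)
      r <- rep(0, nv); r[i] <- -1; r[it] <- 1; add(r, -hi)
    }
    r <- rep(0, nv); r[iL] <- 1; r[it] <- 1; add(r, (k - 1) / n)
    r <- rep(0, nv); r[iL] <- -1; r[it] <- 1; add(r, -(k - 1) / n)
    for (i in 1:(n - 1)) {
      if (i == k - 1) { r <- rep(0, nv); r[i] <- 1; r[iL] <- -1; add(-r, 0) }
      r <- rep(0, nv); r[i + 1] <- 1; r[i] <- -1; add(r, 0)
    }
    r <- rep(0, nv); r[k] <- 1; r[iL] <- -1; add(r, 0)
    r <- rep(0, nv); r[1] <- 1; add(r, 0)
    r <- rep(0, nv); r[n] <- -1; add(r, -1)
    if (k >= 3) for (i in 1:(k - 2)) {
      j2 <- if (i + 1 == k) iL else i + 1
      j3 <- if (i + 2 == k) iL else i + 2
      add(slope_pair_row(nv, i, j2, j3, dx[i], dx[i + 1], +1), 0)
    }
    if (n - k >= 2) for (i in k:(n - 2)) {
      add(slope_pair_row(nv, i, i + 1, i + 2, dx[i], dx[i + 1], -1), 0)
    }
    v <- solve_lp(A, b, nv)
    if (is.finite(v)) best <- min(best, v)
  }
  best
}

# Brute-force betweenness centrality by explicit shortest-path enumeration
# (BFS path counting, independent of igraph's accumulation algorithm).
betweenness_bruteforce <- function(adj) {
  n <- nrow(adj)
  btw <- numeric(n)
  for (s in 1:(n - 1)) for (t in (s + 1):n) {
    # BFS from s: distances and path counts
    dist <- rep(Inf, n); dist[s] <- 0
    npaths <- numeric(n); npaths[s] <- 1
    frontier <- s
    while (length(frontier)) {
      nxt <- integer(0)
      for (v in frontier) for (w in which(adj[v, ] == 1)) {
        if (is.infinite(dist[w])) { dist[w] <- dist[v] + 1; nxt <- c(nxt, w) }
        if (dist[w] == dist[v] + 1) npaths[w] <- npaths[w] + npaths[v]
      }
      frontier <- unique(nxt)
    }
    if (is.infinite(dist[t]) || npaths[t] == 0) next
    # count shortest s-t paths through each interior vertex: paths from s to v
    # times paths from v to t (recompute from t)
    dist_t <- rep(Inf, n); dist_t[t] <- 0
    npaths_t <- numeric(n); npaths_t[t] <- 1
    frontier <- t
    while (length(frontier)) {
      nxt <- integer(0)
      for (v in frontier) for (w in which(adj[v, ] == 1)) {
        if (is.infinite(dist_t[w])) { dist_t[w] <- dist_t[v] + 1; nxt <- c(nxt, w) }
        if (dist_t[w] == dist_t[v] + 1) npaths_t[w] <- npaths_t[w] + npaths_t[v]
      }
      frontier <- unique(nxt)
    }
    for (v in setdiff(1:n, c(s, t))) {
      if (dist[v] + dist_t[v] == dist[t])
        btw[v] <- btw[v] + npaths[v] * npaths_t[v] / npaths[t]
    }
  }
  btw
}

# gated synthetic well shortcut used in several tests
make_well <- function(behavior, n = 20000, seed = 1, ...) {
  ev <- simulate_events(phenotype_spec(behavior, ...), n, rng_seed = seed)
  compute_amfret(apply_gates(ev))
}
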