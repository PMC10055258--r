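#' Build the filtered protein-interaction graph
#'
#' Keeps physical-interaction edges with confidence score >= `min_score`
#' (inclusive), deduplicates parallel edges keeping the maximum score,
#' drops self-loops, and attaches node attributes. A protein with several
#' assayed domains is labeled discontinuous if any of its domains is.
#'
#' @param edges data.frame with columns `a`, `b`, `score`
#' @param min_score minimum confidence score (default 900)
#' @param node_class optional data.frame with `protein`, `domain_class`
#'   (continuous/discontinuous per domain; aggregated by the any-rule)
#' @return an igraph undirected simple graph
#' @export
build_network <- function(edges, min_score = 900, node_class = NULL) {
  ed <- data.table::as.data.table(edges)
  req <- c("a", "b", "score")
  if (!all(req %in% names(ed))) stop("edge list needs columns a, b, score")
  bad <- !is.finite(ed$score) | is.na(ed$a) | is.na(ed$b)
  if (any(bad)) {
    warning(sum(bad), " malformed edge rows skipped")
    ed <- ed[!bad]
  }
  ed <- ed[score >= min_score & a != b]
  if (nrow(ed)) {
    key <- ifelse(ed$a < ed$b, paste(ed$a, ed$b), paste(ed$b, ed$a))
    ed[, k := key]
    ed <- ed[, .(a = a[1], b = b[1], score = max(score)), by = k][, k := NULL]
  }
  g <- igraph::graph_from_data_frame(ed[, .(a, b, score)], directed = FALSE)
  if (!is.null(node_class)) {
    nc <- data.table::as.data.table(node_class)
    agg <- nc[, .(class = if (any(domain_class == "discontinuous"))
      "discontinuous" else "continuous"), by = protein]
    idx <- match(igraph::V(g)$name, agg$protein)
    g <- igraph::set_vertex_attr(g, "continuity", value = agg$class[idx])
  }
  g
}

#' Degree and betweenness centralities
#'
#' Degree centrality is degree/(n-1); betweenness uses shortest-path
#' accumulation, reported both raw and normalized by (n-1)(n-2)/2.
#'
#' @param g an igraph graph
#' @return data.frame with `node`, `degree`, `degree_centrality`,
#'   `betweenness`, `betweenness_centrality`
#' @export
centralities <- function(g) {
  n <- igraph::vcount(g)
  if (n == 0) stop("empty graph")
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, directed = FALSE, weights = NA)
  norm <- if (n > 2) (n - 1) * (n - 2) / 2 else 1
  data.frame(node = igraph::V(g)$name %||% as.character(seq_len(n)),
             degree = as.numeric(deg),
             degree_centrality = if (n > 1) deg / (n - 1) else 0,
             betweenness = as.numeric(btw),
             betweenness_centrality = as.numeric(btw) / norm)
}

#' Mann-Whitney U test (two-sided, midranks for ties)
#'
#' U is reported for the first sample (`U = W` of `wilcox.test`, i.e. the
#' number of (x, y) pairs with x > y, plus half the ties).
#'
#' @param x,y numeric samples
#' @return list with `U`, `p_value`, `n1`, `n2`
#' @export
mann_whitney <- function(x, y) {
  if (!length(x) || !length(y)) stop("empty sample")
  wt <- suppressWarnings(stats::wilcox.test(x, y, correct = FALSE))
  list(U = unname(wt$statistic), p_value = wt$p.value,
       n1 = length(x), n2 = length(y))
}

#' Pearson chi-square test of a 2x2 table with Cramer's V
#'
#' No continuity correction by default; `V = sqrt(X^2 / n)` for 2x2 tables.
#'
#' @param table 2x2 matrix of nonnegative counts
#' @param correct apply Yates continuity correction
#' @return list with `statistic`, `p_value`, `cramers_v`, `n`
#' @export
chi_square_2x2 <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2, 2)), all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero margin")
  ct <- suppressWarnings(stats::chisq.test(table, correct = correct))
  n <- sum(table)
  list(statistic = unname(ct$statistic), p_value = ct$p.value,
       cramers_v = cramers_v(unname(ct$statistic), n), n = n)
}

#' Cramer's V from a chi-square statistic (2x2 convention)
#'
#' @param chisq chi-square statistic
#' @param n total count
#' @return `sqrt(chisq / n)`
#' @export
cramers_v <- function(chisq, n) sqrt(chisq / n)

#' Spearman rank correlation (midranks, two-tailed)
#'
#' @param x,y numeric vectors, n >= 3
#' @return list with `rho`, `p_value`, `n`
#' @export
spearman <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (sd(x) == 0 || sd(y) == 0) stop("constant input")
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         alternative = "two.sided"))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Wald (normal-approximation) binomial confidence interval
#'
#' `p_hat +/- z * sqrt(p_hat (1 - p_hat) / n)`, clipped to [0, 1].
#'
#' @param successes number of successes
#' @param n trials, >= 1
#' @param level confidence level (default 0.95)
#' @return c(lo, hi)
#' @export
wald_ci <- function(successes, n, level = 0.95) {
  stopifnot(n >= 1, successes >= 0, successes <= n)
  p <- successes / n
  z <- qnorm(1 - (1 - level) / 2)
  half <- z * sqrt(p * (1 - p) / n)
  c(max(0, p - half), min(1, p + half))
}

#' Wilson score binomial confidence interval
#'
#' @inheritParams wald_ci
#' @return c(lo, hi)
#' @export
wilson_ci <- function(successes, n, level = 0.95) {
  stopifnot(n >= 1, successes >= 0, successes <= n)
  p <- successes / n
  z <- qnorm(1 - (1 - level) / 2)
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, ctr - half), min(1, ctr + half))
}

#' Power-law fit by linear regression in log-log space
#'
#' OLS of log10(y) on log10(x); the slope is the power-law exponent. A
#' pointwise 95% confidence band for the mean line and the Spearman
#' correlation are reported alongside.
#'
#' @param x,y positive numeric vectors, n >= 3
#' @param level band confidence level (default 0.95)
#' @return list with `slope`, `intercept` (log10 scale), `slope_ci`,
#'   `band` (data.frame log10x, fit, lo, hi), `spearman_rho`,
#'   `spearman_p`
#' @export
loglog_powerlaw_fit <- function(x, y, level = 0.95) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (any(x <= 0) || any(y <= 0)) stop("x and y must be positive")
  lx <- log10(x); ly <- log10(y)
  fit <- lm(ly ~ lx)
  cf <- coef(fit)
  ci <- stats::confint(fit, level = level)
  grid <- seq(min(lx), max(lx), length.out = 50)
  pr <- predict(fit, newdata = data.frame(lx = grid),
                interval = "confidence", level = level)
  sp <- spearman(x, y)
  list(slope = unname(cf[2]), intercept = unname(cf[1]),
       slope_ci = ci[2, ],
       band = data.frame(log10x = grid, fit = pr[, "fit"],
                         lo = pr[, "lwr"], hi = pr[, "upr"]),
       spearman_rho = sp$rho, spearman_p = sp$p_value)
}

#' Ward clustering of a seedability matrix on a log scale
#'
#' Zeros are replaced by a pseudocount (smallest positive value / 10)
#' before taking log10; rows and columns are clustered with Ward linkage
#' (`ward.D2` on Euclidean distances, the variance-minimization algorithm)
#' and leaf orders returned.
#'
#' @param mat numeric matrix of seedability values (>= 2 rows and columns)
#' @return list with `row_order`, `col_order`, `row_hclust`, `col_hclust`
#' @export
cluster_interaction_matrix <- function(mat) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2 || ncol(mat) < 2) stop("need a matrix with >= 2 rows and columns")
  pos <- mat[mat > 0]
  if (!length(pos)) stop("all-zero matrix cannot be log-clustered")
  if (max(mat) == min(mat)) stop("all-equal matrix")
  pseudo <- min(pos) / 10
  lm10 <- log10(pmax(mat, pseudo))
  hr <- hclust(dist(lm10), method = "ward.D2")
  hc <- hclust(dist(t(lm10)), method = "ward.D2")
  list(row_order = hr$order, col_order = hc$order,
       row_hclust = hr, col_hclust = hc)
}
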