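#' Names of the structural-property profile, in fixed order
#' @return character vector of length 15
#' @export
structural_profile_names <- function() {
  c("regulators_pct", "direct_interactions", "self_regulation_pct",
    "max_out_connectivity_pct", "density", "weakly_connected_components",
    "giant_component_pct", "feedforward_circuits",
    "complex_feedforward_circuits", "feedback_loops_3", "avg_shortest_path",
    "diameter", "avg_clustering_coefficient", "r2adj_Pk", "r2adj_Ck")
}

#' Structural-property profile of a network
#'
#' Computes the fixed-order vector of fifteen global properties used for
#' network comparison: percentage of regulators (out-degree > 0), number of
#' direct regulatory interactions, percentage of self-regulated genes,
#' maximum out-connectivity as a percentage of genes, directed density
#' (self-loops excluded), number of weakly connected components, percentage
#' of genes in the giant component, feed-forward circuits, complex
#' feed-forward circuits, 3-gene feedback loops, average shortest path and
#' diameter of the undirected giant component, average clustering
#' coefficient of the undirected simple graph, and the adjusted R-squared of
#' the P(k) and C(k) power-law regressions.
#'
#' Motif conventions: a feed-forward circuit is an ordered triple of distinct
#' genes (A,B,C) with edges A->B, A->C, B->C; a "complex" feed-forward
#' circuit additionally has at least one of its three edges reciprocated
#' (this counter can be swapped via `complex_ffc_counter`); 3-feedback loops
#' are directed 3-cycles counted once per node set. Self-loops are excluded
#' from motif and clustering computations.
#'
#' @param network a `grn`
#' @param complex_ffc_counter optional function(triples, has_edge) replacing
#'   the built-in complex-FFC rule; see [count_motifs()]
#' @return named numeric vector of length 15 (class `structural_profile`)
#' @export
structural_profile <- function(network, complex_ffc_counter = NULL) {
  stopifnot(inherits(network, "grn"))
  n <- nrow(network$genes)
  if (n == 0L) stop("network is empty")
  ints <- network$interactions
  e_all <- nrow(ints)
  self <- tolower(ints$regulator) == tolower(ints$target)
  outdeg <- table(ints$regulator)

  g_dir <- grn_to_igraph(network, directed = TRUE)
  g_simple <- igraph::simplify(g_dir, remove.loops = TRUE, remove.multiple = TRUE)
  g_und <- igraph::as_undirected(g_simple, mode = "collapse")

  comp <- igraph::components(g_dir, mode = "weak")
  giant_id <- which.max(comp$csize)
  giant_v <- names(comp$membership)[comp$membership == giant_id]
  g_giant <- igraph::induced_subgraph(g_und, giant_v)

  motifs <- count_motifs(network, complex_ffc_counter = complex_ffc_counter)

  avg_path <- if (igraph::vcount(g_giant) > 1L)
    igraph::mean_distance(g_giant, directed = FALSE) else 0
  diam <- if (igraph::vcount(g_giant) > 1L)
    igraph::diameter(g_giant, directed = FALSE) else 0
  local_cc <- igraph::transitivity(g_und, type = "local", isolates = "zero")
  avg_cc <- mean(local_cc)

  degs <- igraph::degree(g_und)
  r2_pk <- tryCatch(fit_powerlaw_regression(degs)$r2adj, error = function(e) NA_real_)
  r2_ck <- tryCatch(fit_ck_scaling(network)$r2adj, error = function(e) NA_real_)

  prof <- c(
    regulators_pct = 100 * length(outdeg) / n,
    direct_interactions = e_all,
    self_regulation_pct = 100 * length(unique(tolower(ints$regulator[self]))) / n,
    max_out_connectivity_pct = 100 * (if (length(outdeg)) max(outdeg) else 0) / n,
    density = if (n > 1L) igraph::ecount(g_simple) / (n * (n - 1)) else 0,
    weakly_connected_components = comp$no,
    giant_component_pct = 100 * max(comp$csize) / n,
    feedforward_circuits = motifs$ffc,
    complex_feedforward_circuits = motifs$complex_ffc,
    feedback_loops_3 = motifs$feedback_3,
    avg_shortest_path = avg_path,
    diameter = diam,
    avg_clustering_coefficient = avg_cc,
    r2adj_Pk = r2_pk,
    r2adj_Ck = r2_ck
  )
  structure(prof, class = c("structural_profile", "numeric"))
}

#' Count three-gene motifs of a directed network
#'
#' Feed-forward circuits (FFC) are ordered triples of distinct genes (A,B,C)
#' with edges A->B, A->C and B->C. Complex FFCs are, by the package's
#' default rule, FFCs with at least one reciprocated edge; pass
#' `complex_ffc_counter` (a function taking the FFC triple matrix and an
#' edge-test function, returning a count) to substitute another definition.
#' 3-feedback loops are directed 3-cycles counted once per node set.
#' Self-loops are ignored.
#'
#' @param network a `grn` or igraph directed graph
#' @param complex_ffc_counter optional replacement counter
#' @return list with `ffc`, `complex_ffc`, `feedback_3`
#' @export
count_motifs <- function(network, complex_ffc_counter = NULL) {
  g <- if (inherits(network, "grn")) grn_to_igraph(network) else network
  g <- igraph::simplify(g, remove.loops = TRUE, remove.multiple = TRUE)
  el <- igraph::as_edgelist(g, names = FALSE)
  nv <- igraph::vcount(g)
  succ <- lapply(seq_len(nv), function(i) integer())
  if (nrow(el)) {
    sp <- split(el[, 2], el[, 1])
    for (nm in names(sp)) succ[[as.integer(nm)]] <- as.integer(sp[[nm]])
  }
  has_edge <- function(a, b) b %in% succ[[a]]

  triples <- NULL
  ffc <- 0L
  if (nrow(el)) {
    acc <- vector("list", nrow(el))
    for (r in seq_len(nrow(el))) {
      a <- el[r, 1]; b <- el[r, 2]
      common <- intersect(succ[[a]], succ[[b]])
      common <- setdiff(common, c(a, b))
      if (length(common))
        acc[[r]] <- cbind(a = a, b = b, c = common)
    }
    triples <- do.call(rbind, acc)
    ffc <- if (is.null(triples)) 0L else nrow(triples)
  }

  complex_ffc <- 0L
  if (!is.null(triples) && nrow(triples)) {
    if (is.null(complex_ffc_counter)) {
      recip <- apply(triples, 1, function(t)
        has_edge(t[2], t[1]) || has_edge(t[3], t[1]) || has_edge(t[3], t[2]))
      complex_ffc <- sum(recip)
    } else {
      complex_ffc <- complex_ffc_counter(triples, has_edge)
    }
  }

  # directed 3-cycles, deduplicated by node set
  fb_sets <- character()
  if (nrow(el)) {
    for (r in seq_len(nrow(el))) {
      a <- el[r, 1]; b <- el[r, 2]
      if (a == b) next
      thirds <- intersect(succ[[b]], which(vapply(seq_len(nv), function(c) has_edge(c, a), TRUE)))
      thirds <- setdiff(thirds, c(a, b))
      if (length(thirds))
        fb_sets <- c(fb_sets, vapply(thirds, function(c)
          paste(sort(c(a, b, c)), collapse = "-"), character(1)))
    }
  }
  list(ffc = as.integer(ffc), complex_ffc = as.integer(complex_ffc),
       feedback_3 = length(unique(fb_sets)))
}

#' Ultra-small-world reference value ln(ln(N))
#'
#' Scale-free networks in the ultra-small-world regime have average shortest
#' path lengths proportional to the iterated logarithm of the gene count.
#'
#' @param n gene count, at least 3
#' @param digits decimals for reporting (default 2)
#' @return ln(ln(n)) rounded to `digits`
#' @export
ultra_small_world_reference <- function(n, digits = 2) {
  if (!is.numeric(n) || length(n) != 1L || n < 3)
    stop("n must be a single count >= 3")
  round(log(log(n)), digits)
}

#' Power-law exponent by robust regression on the degree CCDF
#'
#' Fits a Huber-weighted iteratively reweighted least-squares line to the
#' log-log complementary cumulative degree distribution and corrects the
#' exponent: for P(k) ~ k^-alpha the CCDF slope is -(alpha - 1), so
#' alpha = |slope| + 1.
#'
#' @param degrees integer degree sequence (zeros are dropped); at least three
#'   distinct positive values required
#' @return list of class `powerlaw_fit` with `alpha`, `slope`, `r2adj`,
#'   `method = "regression"`, and the CCDF `points`
#' @export
fit_powerlaw_regression <- function(degrees) {
  k <- as.numeric(degrees[degrees > 0])
  ks <- sort(unique(k))
  if (length(ks) < 3L)
    stop("need at least three distinct positive degrees")
  ccdf <- vapply(ks, function(v) mean(k >= v), numeric(1))
  # the smallest degree always has CCDF = 1 whatever the distribution; that
  # anchor point only bends the fit, so it is excluded when enough points remain
  keep <- ccdf < 1
  if (sum(keep) >= 3L) { ks <- ks[keep]; ccdf <- ccdf[keep] }
  x <- log10(ks); y <- log10(ccdf)
  ols <- stats::lm(y ~ x)
  fit <- if (max(abs(stats::residuals(ols))) < 1e-10) ols
  else MASS::rlm(y ~ x, maxit = 50, acc = 1e-8)
  slope <- unname(stats::coef(fit)[2])
  yhat <- stats::fitted(fit)
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  n <- length(y)
  r2adj <- 1 - (1 - r2) * (n - 1) / (n - 2)
  structure(list(alpha = abs(slope) + 1, slope = slope, r2adj = r2adj,
                 method = "regression",
                 points = data.frame(k = ks, ccdf = ccdf)),
            class = "powerlaw_fit")
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat(sprintf("<powerlaw_fit/%s> alpha = %.3f", x$method, x$alpha))
  if (!is.null(x$r2adj) && !is.na(x$r2adj)) cat(sprintf(", R2adj = %.3f", x$r2adj))
  if (!is.null(x$xmin)) cat(sprintf(", xmin = %d, KS = %.4f", x$xmin, x$ks_distance))
  cat("\n")
  invisible(x)
}

# Hurwitz-zeta-style normalizer sum_{k=xmin}^inf k^-alpha
.plaw_norm <- function(alpha, xmin, kmax = 10000L) {
  ks <- seq.int(xmin, xmin + kmax)
  sum(ks^(-alpha)) + ((xmin + kmax + 0.5)^(1 - alpha)) / (alpha - 1)
}

# discrete power-law MLE on the tail x >= xmin
.plaw_mle_tail <- function(x, xmin) {
  nll <- function(a) length(x) * log(.plaw_norm(a, xmin)) + a * sum(log(x))
  stats::optimize(nll, c(1.01, 6))$minimum
}

# model CDF evaluated at the sorted unique tail values, for KS
.ks_distance <- function(x, cdf_fun) {
  xs <- sort(x)
  n <- length(xs)
  emp_hi <- seq_len(n) / n
  emp_lo <- (seq_len(n) - 1) / n
  mod <- cdf_fun(xs)
  max(abs(emp_hi - mod), abs(emp_lo - mod))
}

.discrete_cdf <- function(pmf_fun, xmin, kmax) {
  ks <- seq.int(xmin, kmax)
  p <- pmf_fun(ks)
  p <- p / sum(p)
  cs <- cumsum(p)
  function(v) cs[pmin(pmax(v, xmin), kmax) - xmin + 1]
}

#' Power-law exponent by discrete maximum likelihood with KS model selection
#'
#' Estimates the lower cutoff `xmin` by minimizing the Kolmogorov-Smirnov
#' distance of the discrete power-law fit over candidate cutoffs, then
#' compares the power law against alternative fat-tailed models (discrete
#' exponential, stretched exponential, lognormal, truncated power law)
#' fitted by maximum likelihood on the same tail; each candidate's KS
#' distance is reported and the preferred model is the KS minimizer.
#'
#' @param degrees degree sequence; at least 50 positive observations
#' @param candidates subset of `c("power_law", "exponential",
#'   "stretched_exponential", "lognormal", "truncated_power_law")`
#' @param xmin_max cap on cutoff candidates scanned (default 50 distinct
#'   values)
#' @return list of class `powerlaw_fit` with `alpha`, `xmin`, `ks_distance`,
#'   `model_comparison` (named KS distances), `preferred`, `method = "mle"`
#' @export
fit_powerlaw_mle <- function(degrees,
                             candidates = c("power_law", "exponential",
                                            "stretched_exponential", "lognormal",
                                            "truncated_power_law"),
                             xmin_max = 50L) {
  allowed <- c("power_law", "exponential", "stretched_exponential",
               "lognormal", "truncated_power_law")
  if (length(candidates) == 0L) stop("empty candidate set")
  bad <- setdiff(candidates, allowed)
  if (length(bad)) stop("unknown candidate distribution(s): ", paste(bad, collapse = ", "))
  x <- as.numeric(degrees[degrees > 0])
  if (length(x) < 50L) stop("need at least 50 positive observations for MLE")

  xmins <- sort(unique(x))
  xmins <- xmins[xmins <= stats::quantile(x, 0.9)] # keep a usable tail
  if (length(xmins) > xmin_max)
    xmins <- xmins[unique(round(seq(1, length(xmins), length.out = xmin_max)))]
  best <- NULL
  for (xm in xmins) {
    tail_x <- x[x >= xm]
    if (length(tail_x) < 25L) next
    a <- .plaw_mle_tail(tail_x, xm)
    kmax <- max(tail_x)
    cdf <- .discrete_cdf(function(k) k^(-a), xm, kmax)
    d <- .ks_distance(tail_x, cdf)
    if (is.null(best) || d < best$ks) best <- list(alpha = a, xmin = xm, ks = d)
  }
  if (is.null(best)) stop("no usable cutoff found")
  xm <- best$xmin
  tail_x <- x[x >= xm]
  kmax <- max(tail_x)
  n <- length(tail_x)

  comparison <- c()
  for (cand in candidates) {
    d <- switch(cand,
      power_law = best$ks,
      exponential = {
        lam <- log(1 + 1 / max(mean(tail_x - xm), 1e-9))
        cdf <- .discrete_cdf(function(k) exp(-lam * k), xm, kmax)
        .ks_distance(tail_x, cdf)
      },
      lognormal = {
        lx <- log(tail_x)
        fit <- stats::optim(c(mean(lx), max(stats::sd(lx), 0.1)), function(p) {
          if (p[2] <= 0) return(1e10)
          pmf <- function(k) stats::dlnorm(k, p[1], p[2])
          ks <- seq.int(xm, kmax); z <- sum(pmf(ks))
          if (z <= 0) return(1e10)
          -sum(log(pmf(tail_x) / z))
        }, method = "Nelder-Mead")
        cdf <- .discrete_cdf(function(k) stats::dlnorm(k, fit$par[1], fit$par[2]), xm, kmax)
        .ks_distance(tail_x, cdf)
      },
      stretched_exponential = {
        fit <- stats::optim(c(0.5, 0.5), function(p) {
          b <- p[1]; lam <- p[2]
          if (b <= 0.05 || b > 2 || lam <= 0) return(1e10)
          pmf <- function(k) k^(b - 1) * exp(-lam * k^b)
          ks <- seq.int(xm, kmax); z <- sum(pmf(ks))
          if (!is.finite(z) || z <= 0) return(1e10)
          -sum(log(pmf(tail_x) / z))
        }, method = "Nelder-Mead")
        b <- fit$par[1]; lam <- fit$par[2]
        cdf <- .discrete_cdf(function(k) k^(b - 1) * exp(-lam * k^b), xm, kmax)
        .ks_distance(tail_x, cdf)
      },
      truncated_power_law = {
        fit <- stats::optim(c(best$alpha, 0.01), function(p) {
          a <- p[1]; lam <- p[2]
          if (a <= 0 || lam <= 0) return(1e10)
          pmf <- function(k) k^(-a) * exp(-lam * k)
          ks <- seq.int(xm, kmax); z <- sum(pmf(ks))
          if (!is.finite(z) || z <= 0) return(1e10)
          -sum(log(pmf(tail_x) / z))
        }, method = "Nelder-Mead")
        a <- fit$par[1]; lam <- fit$par[2]
        cdf <- .discrete_cdf(function(k) k^(-a) * exp(-lam * k), xm, kmax)
        .ks_distance(tail_x, cdf)
      })
    comparison[cand] <- d
  }
  structure(list(alpha = best$alpha, xmin = as.integer(xm),
                 ks_distance = best$ks, n_tail = n,
                 model_comparison = comparison,
                 preferred = names(comparison)[which.min(comparison)],
                 r2adj = NA_real_, method = "mle"),
            class = "powerlaw_fit")
}

#' Degree statistics of a network
#'
#' Total (in+out) degree on the undirected simple graph, mean local
#' clustering per degree C(k), and CCDF points.
#'
#' @param network a `grn`
#' @return list with `degrees` (named), `ck` (data frame `k`, `ck`), `ccdf`
#'   (data frame `k`, `ccdf`)
#' @export
degree_stats <- function(network) {
  stopifnot(inherits(network, "grn"))
  g <- igraph::as_undirected(igraph::simplify(grn_to_igraph(network),
                                              remove.loops = TRUE,
                                              remove.multiple = TRUE),
                             mode = "collapse")
  degs <- igraph::degree(g)
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  names(cc) <- igraph::V(g)$name
  keep <- degs >= 2
  ck <- if (any(keep)) {
    agg <- tapply(cc[keep], degs[keep], mean)
    data.frame(k = as.integer(names(agg)), ck = as.numeric(agg))
  } else data.frame(k = integer(), ck = numeric())
  ks <- sort(unique(degs[degs > 0]))
  ccdf <- vapply(ks, function(v) mean(degs[degs > 0] >= v), numeric(1))
  list(degrees = degs, ck = ck, ccdf = data.frame(k = ks, ccdf = ccdf))
}

#' Scaling exponent of the clustering coefficient C(k)
#'
#' Hierarchically modular networks show C(k) ~ k^-1. Fits a linear
#' regression of log C(k) on log k over degrees with positive mean
#' clustering and reports the exponent as a positive magnitude.
#'
#' @param x a `grn` or the list returned by [degree_stats()]
#' @return list with `exponent`, `slope`, `r2adj`
#' @export
fit_ck_scaling <- function(x) {
  stats_in <- if (inherits(x, "grn")) degree_stats(x) else x
  ck <- stats_in$ck
  ck <- ck[ck$ck > 0, , drop = FALSE]
  if (nrow(stats_in$ck) && all(stats_in$ck$ck == 0))
    stop("all C(k) values are zero")
  if (nrow(ck) < 3L)
    stop("need at least three degrees with positive mean clustering")
  fit <- stats::lm(log10(ck$ck) ~ log10(ck$k))
  slope <- unname(stats::coef(fit)[2])
  s <- summary(fit)
  list(exponent = abs(slope), slope = slope, r2adj = s$adj.r.squared)
}

#' Cluster structural-property profiles
#'
#' Computes the pairwise Pearson correlation among profiles (optionally
#' after min-max scaling each property across networks) and clusters the
#' networks by Ward's method on the Euclidean distances between the rows of
#' the correlation matrix.
#'
#' @param profiles named list of `structural_profile` vectors (or a numeric
#'   matrix, networks in rows)
#' @param scaling `"none"` or `"minmax"`
#' @return list with `correlation` (matrix), `distance` (dist), `hclust`
#' @export
cluster_profiles <- function(profiles, scaling = c("none", "minmax")) {
  scaling <- match.arg(scaling)
  mat <- if (is.matrix(profiles)) profiles else do.call(rbind, profiles)
  if (is.null(rownames(mat))) rownames(mat) <- paste0("net", seq_len(nrow(mat)))
  if (nrow(mat) < 2L) stop("need at least two profiles")
  if (any(!is.finite(mat))) {
    mat[!is.finite(mat)] <- 0
    warning("non-finite profile entries replaced by 0")
  }
  if (scaling == "minmax") {
    rng <- apply(mat, 2, range)
    span <- rng[2, ] - rng[1, ]
    keep <- span > 0
    mat <- sweep(sweep(mat[, keep, drop = FALSE], 2, rng[1, keep]), 2, span[keep], "/")
  }
  sds <- apply(mat, 1, stats::sd)
  if (any(sds == 0))
    stop("constant profile(s): ", paste(rownames(mat)[sds == 0], collapse = ", "))
  corr <- stats::cor(t(mat))
  d <- stats::dist(corr)
  hc <- stats::hclust(d, method = "ward.D2")
  list(correlation = corr, distance = d, hclust = hc)
}

# ---------------------------------------------------------------------------
# pairwise graph dissimilarity (distance-distribution / NND / centrality form)

.shannon <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

.js_divergence <- function(p, q) {
  n <- max(length(p), length(q))
  p <- c(p, rep(0, n - length(p)))
  q <- c(q, rep(0, n - length(q)))
  m <- (p + q) / 2
  .shannon(m) - (.shannon(p) + .shannon(q)) / 2
}

# per-node distance distributions; bins 1..(n-1) plus one unreachable bin
.node_distance_dists <- function(g) {
  n <- igraph::vcount(g)
  if (n <= 1L) return(matrix(1, nrow = 1, ncol = 1))
  d <- igraph::distances(g)
  diag(d) <- NA
  nb <- n # bins 1..(n-1), unreachable in bin n
  out <- matrix(0, nrow = n, ncol = nb)
  for (i in seq_len(n)) {
    di <- d[i, ]
    di <- di[!is.na(di)]
    unreach <- sum(!is.finite(di))
    di <- di[is.finite(di)]
    if (length(di)) {
      tb <- tabulate(di, nbins = nb - 1L)
      out[i, seq_len(nb - 1L)] <- tb
    }
    out[i, nb] <- unreach
    out[i, ] <- out[i, ] / (n - 1)
  }
  out
}

.nnd <- function(dists, g) {
  n <- nrow(dists)
  if (n <= 1L) return(list(nnd = 0, mu = c(1)))
  mu <- colMeans(dists)
  jsd <- .shannon(mu) - mean(apply(dists, 1, .shannon))
  reach <- dists[, -ncol(dists), drop = FALSE]
  diam_bins <- which(colSums(reach) > 0)
  diam <- if (length(diam_bins)) max(diam_bins) else 0
  has_unreach <- sum(dists[, ncol(dists)]) > 0
  eff <- diam + has_unreach # unreachable bin behaves as one extra distance class
  nnd <- if (eff >= 1 && log(eff + 1) > 0) max(0, jsd) / log(eff + 1) else 0
  list(nnd = nnd, mu = mu)
}

.alpha_centrality_dist <- function(g) {
  n <- igraph::vcount(g)
  if (n == 0L) return(1)
  a <- igraph::alpha_centrality(g, alpha = 1 / n, exo = 1)
  a <- a - min(0, min(a)) + 1e-12
  sort(a / sum(a))
}

#' Pairwise network dissimilarity
#'
#' A weighted three-term dissimilarity on the undirected simple projections
#' of two networks: (1) the square-rooted, log(2)-normalized Jensen-Shannon
#' divergence between the graphs' averaged node-distance distributions;
#' (2) the absolute difference of the square roots of the graphs' network
#' node dispersions (the normalized divergence among each graph's own
#' node-distance distributions); (3) a centrality term comparing the
#' alpha-centrality value distributions of the graphs and of their
#' complements, averaged. Identical graphs score 0; the measure is symmetric
#' and bounded in `[0, 1]` when the weights sum to 1.
#'
#' @param g1,g2 `grn` objects or igraph graphs
#' @param weights numeric length-3 weights summing to 1; the default
#'   `c(0.45, 0.45, 0.1)` gives the size-discriminating third term a small
#'   share
#' @return dissimilarity value in `[0, 1]`
#' @export
network_dissimilarity <- function(g1, g2, weights = c(0.45, 0.45, 0.1)) {
  if (length(weights) != 3L || abs(sum(weights) - 1) > 1e-9)
    stop("weights must be three values summing to 1")
  as_und <- function(g) {
    if (inherits(g, "grn")) g <- grn_to_igraph(g)
    igraph::as_undirected(igraph::simplify(g, remove.loops = TRUE,
                                           remove.multiple = TRUE), mode = "collapse")
  }
  u1 <- as_und(g1); u2 <- as_und(g2)
  if (igraph::vcount(u1) == 0L || igraph::vcount(u2) == 0L)
    stop("both networks must be non-empty")
  d1 <- .node_distance_dists(u1); d2 <- .node_distance_dists(u2)
  n1 <- .nnd(d1, u1); n2 <- .nnd(d2, u2)
  term1 <- sqrt(max(0, .js_divergence(n1$mu, n2$mu)) / log(2))
  term2 <- abs(sqrt(n1$nnd) - sqrt(n2$nnd))
  term3 <- 0
  if (weights[3] > 0) {
    p1 <- .alpha_centrality_dist(u1); p2 <- .alpha_centrality_dist(u2)
    c1 <- .alpha_centrality_dist(igraph::complementer(u1))
    c2 <- .alpha_centrality_dist(igraph::complementer(u2))
    term3 <- (sqrt(max(0, .js_divergence(p1, p2)) / log(2)) +
                sqrt(max(0, .js_divergence(c1, c2)) / log(2))) / 2
  }
  unname(weights[1] * term1 + weights[2] * term2 + weights[3] * term3)
}
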