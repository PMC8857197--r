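#' Configuration for the synthetic-data generators
#'
#' Bundles the knobs shared by the generators. Defaults describe a
#' moderately sized bacterial regulatory network test bed: a scale-free
#' out-degree law with exponent 2.5, a 137-condition expression compendium
#' (the size of a typical public microarray compendium for one organism),
#' Gaussian noise of 0.5 SD on a unit-scale signal, 12-bp motifs at 1.5
#' bits per column against a GC-balanced background, and a sister organism
#' retaining 80% of the genes with 1:1 orthology.
#'
#' @param n_genes total gene count
#' @param n_tfs number of transcription factors (must be >= 1 and <= n_genes)
#' @param target_alpha power-law exponent for TF out-degrees, in (2, 3]
#' @param n_conditions expression conditions
#' @param noise_sd expression noise standard deviation
#' @param strong_fraction fraction of interactions labelled strong
#' @param motif_width planted motif width (>= 6)
#' @param motif_ic_per_column information content per motif column, bits
#' @param gc_content genomic GC fraction
#' @param ortholog_retention_fraction gene survival rate in the sister
#'   organism
#' @param seed mandatory integer seed; every generator is a pure function of
#'   (config, seed)
#' @return list of class `synth_config`
#' @export
synth_config <- function(n_genes = 200, n_tfs = 20, target_alpha = 2.5,
                         n_conditions = 137, noise_sd = 0.5,
                         strong_fraction = 0.3, motif_width = 12,
                         motif_ic_per_column = 1.5, gc_content = 0.5,
                         ortholog_retention_fraction = 0.8, seed) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  if (n_tfs < 1L || n_tfs > n_genes) stop("need 1 <= n_tfs <= n_genes")
  if (!(target_alpha > 1)) stop("target_alpha must exceed 1")
  structure(list(
    n_genes = as.integer(n_genes), n_tfs = as.integer(n_tfs),
    target_alpha = target_alpha, n_conditions = as.integer(n_conditions),
    noise_sd = noise_sd, strong_fraction = strong_fraction,
    motif_width = as.integer(motif_width),
    motif_ic_per_column = motif_ic_per_column, gc_content = gc_content,
    ortholog_retention_fraction = ortholog_retention_fraction,
    seed = as.integer(seed)
  ), class = "synth_config")
}

#' Draw from a discrete power law P(k) ~ k^-alpha
#'
#' Inverse-CDF sampling on the truncated support `1..kmax`.
#'
#' @param n sample size
#' @param alpha exponent (> 1)
#' @param kmax support cap (default 100000)
#' @return integer vector
#' @export
rpowerlaw <- function(n, alpha, kmax = 1e5L) {
  ks <- seq_len(kmax)
  w <- ks^(-alpha)
  cdf <- cumsum(w) / sum(w)
  findInterval(stats::runif(n), cdf) + 1L
}

#' Sample a scale-free regulatory network
#'
#' Transcription-factor out-degrees are drawn from a discrete power law
#' with exponent `target_alpha` (capped at `n_genes - 1`); targets are
#' attached preferentially (weight proportional to current in-degree + 1),
#' reproducing the fat-tailed degree structure of bacterial regulatory
#' networks. Interactions get random activation/repression effects and
#' strong/weak evidence labels at the configured strong fraction.
#' Deterministic under the config seed.
#'
#' @param config a [synth_config()]
#' @return a `grn` (genes without interactions do not appear)
#' @export
sample_grn <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  n <- config$n_genes; ntf <- config$n_tfs
  if (ntf == 0L) stop("n_tfs must be positive")
  genes <- sprintf("SG%04d", seq_len(n))
  tfs <- genes[seq_len(ntf)]
  outdeg <- rpowerlaw(ntf, config$target_alpha, kmax = max(2L, n - 1L))
  outdeg <- pmin(outdeg, n - 1L)
  # scale the hubs up so the largest TFs regulate a sizeable gene share
  outdeg[which.max(outdeg)] <- max(outdeg, min(n - 1L, ceiling(n / 4)))
  indeg_w <- rep(1, n)
  names(indeg_w) <- genes
  edges <- vector("list", ntf)
  for (i in seq_len(ntf)) {
    k <- outdeg[i]
    pool <- setdiff(genes, tfs[i])
    w <- indeg_w[pool]
    tg <- sample(pool, min(k, length(pool)), prob = w)
    indeg_w[tg] <- indeg_w[tg] + 1
    edges[[i]] <- data.frame(regulator = tfs[i], target = tg,
                             stringsAsFactors = FALSE)
  }
  ed <- do.call(rbind, edges)
  ed$effect <- sample(c("activation", "repression"), nrow(ed), replace = TRUE,
                      prob = c(0.6, 0.4))
  strong <- stats::runif(nrow(ed)) < config$strong_fraction
  ed$evidence <- ifelse(strong, "strong", "weak")
  ed$experiments <- ifelse(strong, "EMSA", "microarray")
  ed$sources <- "synthetic"
  grn(ed, label = sprintf("synthetic_seed%d", config$seed))
}

#' Simulate expression data from a known network
#'
#' Linear structural-equation model: per condition, regulator-free genes
#' draw from a standard normal; each regulated gene is the signed weighted
#' sum of its regulators' values plus Gaussian noise, with weights
#' `Uniform(0.5, 1.5)` signed by the interaction effect and scaled by
#' `1/sqrt(in-degree)` to keep feedback stable. Cycles are resolved by
#' damped fixed-point iteration (50 iterations, damping 0.5); failure to
#' converge is an error naming the genes.
#'
#' @param network a `grn`
#' @param config a [synth_config()]
#' @return genes x conditions matrix (gene rownames from the network)
#' @export
simulate_expression <- function(network, config) {
  stopifnot(inherits(network, "grn"), inherits(config, "synth_config"))
  set.seed(config$seed + 1L)
  genes <- grn_genes(network)
  g <- length(genes)
  ints <- network$interactions
  ints <- ints[tolower(ints$regulator) != tolower(ints$target), , drop = FALSE]
  ri <- match(ints$regulator, genes)
  ti <- match(ints$target, genes)
  sgn <- ifelse(ints$effect == "repression", -1,
                ifelse(ints$effect == "activation", 1,
                       sample(c(-1, 1), nrow(ints), replace = TRUE)))
  w <- stats::runif(nrow(ints), 0.5, 1.5) * sgn
  indeg <- tabulate(ti, nbins = g)
  w <- w / sqrt(pmax(1, indeg[ti]))
  W <- matrix(0, g, g)
  W[cbind(ti, ri)] <- w
  # feedback loops can push the system's spectral radius past 1; rescale the
  # coupling so the stationary solution exists and has bounded variance
  if (nrow(ints)) {
    rho <- max(Mod(eigen(W, only.values = TRUE)$values))
    if (rho >= 0.95) W <- W * (0.8 / rho)
  }
  is_root <- indeg == 0
  nc <- config$n_conditions
  E <- matrix(0, g, nc)
  E[is_root, ] <- stats::rnorm(sum(is_root) * nc)
  E[!is_root, ] <- config$noise_sd * stats::rnorm(sum(!is_root) * nc)
  # stationary solution of X = W X + E; fall back to damped fixed-point
  # iteration if the system is near-singular
  X <- tryCatch(solve(diag(g) - W, E), error = function(e) NULL)
  if (is.null(X)) {
    X <- E
    damping <- 0.5
    for (it in seq_len(200L)) {
      X_new <- (1 - damping) * X + damping * (W %*% X + E)
      delta <- max(abs(X_new - X))
      X <- X_new
      if (delta < 1e-10) break
    }
  }
  resid <- abs(X - (W %*% X + E))
  bad <- rowSums(resid > 1e-6) > 0
  if (any(bad))
    stop("expression model did not converge for gene(s): ",
         paste(utils::head(genes[bad], 10), collapse = ", "))
  rownames(X) <- genes
  colnames(X) <- sprintf("cond%03d", seq_len(nc))
  X
}

# column distribution with the requested information content (bits) against
# a uniform background: dominant base p, others (1-p)/3
.ic_to_prob <- function(ic) {
  if (ic <= 0) return(0.25)
  f <- function(p) {
    q <- (1 - p) / 3
    2 + p * log2(p) + 3 * q * log2(max(q, 1e-12)) - ic
  }
  stats::uniroot(f, c(0.2500001, 0.9999999))$root
}

#' Generate a genome with planted binding sites
#'
#' Lays the network's genes on one replicon with wide intergenic gaps,
#' fills the sequence with i.i.d. bases at the configured GC content,
#' builds one PWM per regulator at the configured per-column information
#' content, and embeds one site sampled from the regulator's PWM in the
#' upstream window (-300..+50 relative to the translation start) of each of
#' its targets, at a random offset and strand. The true site positions are
#' recorded.
#'
#' @param network a `grn`; sites are planted for every interaction
#' @param config a [synth_config()]
#' @return list with `genome` (named character), `gene_table` (tibble),
#'   `sites` (tibble `tf gene position strand`, positions relative to the
#'   region that [extract_upstream()] returns), `pwms` (named list)
#' @export
plant_genome <- function(network, config) {
  stopifnot(inherits(network, "grn"), inherits(config, "synth_config"))
  if (config$motif_width < 6L) stop("motif_width must be >= 6")
  if (config$motif_width > 351L) stop("motif width exceeds the upstream window")
  set.seed(config$seed + 2L)
  genes <- grn_genes(network)
  g <- length(genes)
  gene_len <- 600L
  spacing <- 1200L # leaves >= 351 bp untruncated upstream windows
  starts <- 500L + spacing * (seq_len(g) - 1L)
  gene_table <- tibble::tibble(
    locus_tag = genes, replicon = "chr",
    start = starts, end = starts + gene_len - 1L,
    strand = "+"
  )
  chrlen <- max(gene_table$end) + 500L
  gc <- config$gc_content
  base_p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  chr <- sample(names(base_p), chrlen, replace = TRUE, prob = base_p)

  tfs <- grn_regulators(network)
  p_dom <- .ic_to_prob(config$motif_ic_per_column)
  pwms <- list()
  for (tf in tfs) {
    w <- config$motif_width
    dom <- sample(1:4, w, replace = TRUE)
    mat <- matrix((1 - p_dom) / 3, nrow = 4, ncol = w, dimnames = list(.DNA, NULL))
    mat[cbind(dom, seq_len(w))] <- p_dom
    pwms[[tf]] <- structure(
      list(tf = tf, matrix = mat, width = w,
           background = stats::setNames(rep(0.25, 4), .DNA),
           source_sites = 0L),
      class = "pwm")
  }

  sample_site <- function(pwm) {
    paste(vapply(seq_len(pwm$width), function(j)
      sample(.DNA, 1L, prob = pwm$matrix[, j]), character(1)), collapse = "")
  }

  sites <- vector("list", nrow(network$interactions))
  ints <- network$interactions
  for (r in seq_len(nrow(ints))) {
    tf <- ints$regulator[r]; tg <- ints$target[r]
    gi <- gene_table[gene_table$locus_tag == tg, ]
    win_lo <- gi$start - 300L
    win_hi <- gi$start + 50L
    off <- sample.int(win_hi - win_lo + 1L - config$motif_width, 1L)
    site <- sample_site(pwms[[tf]])
    strand <- sample(c("+", "-"), 1L)
    planted <- if (strand == "+") site else .revcomp(site)
    pos <- win_lo + off - 1L
    chr[pos:(pos + config$motif_width - 1L)] <- strsplit(planted, "")[[1]]
    sites[[r]] <- tibble::tibble(tf = tf, gene = tg,
                                 position = off, strand = strand)
  }
  list(
    genome = c(chr = paste(chr, collapse = "")),
    gene_table = gene_table,
    sites = do.call(rbind, sites),
    pwms = pwms
  )
}

#' Derive an orthologous sister organism
#'
#' Organism B is a relabelled copy of the input network with a random
#' `(1 - retention)` fraction of genes deleted (their edges dropped); the
#' ortholog map lists the surviving pairs only.
#'
#' @param network a `grn` (organism A)
#' @param config a [synth_config()]; uses `ortholog_retention_fraction`
#' @return list with `network` (organism B `grn`) and `orthologs` (tibble
#'   `a`, `b`)
#' @export
make_ortholog_pair <- function(network, config) {
  stopifnot(inherits(network, "grn"), inherits(config, "synth_config"))
  ret <- config$ortholog_retention_fraction
  if (!(ret > 0 && ret <= 1)) stop("retention fraction must be in (0, 1]")
  set.seed(config$seed + 3L)
  genes <- grn_genes(network)
  n_keep <- round(ret * length(genes))
  keep <- sort(sample(genes, n_keep))
  relabel <- stats::setNames(sprintf("OB%04d", seq_along(keep)), keep)
  ints <- network$interactions
  sel <- ints$regulator %in% keep & ints$target %in% keep
  ints_b <- ints[sel, , drop = FALSE]
  if (nrow(ints_b) == 0L || length(intersect(keep, grn_regulators(network))) == 0L)
    warning("no regulator survived the deletion; organism B has no edges")
  ints_b$regulator <- unname(relabel[ints_b$regulator])
  ints_b$target <- unname(relabel[ints_b$target])
  netB <- grn(ints_b, label = paste0(network$label, "_orthoB"))
  list(network = netB,
       orthologs = tibble::tibble(a = keep, b = unname(relabel[keep])))
}
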