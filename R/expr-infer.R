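#' Read an expression matrix TSV
#'
#' Genes in rows, conditions in columns; first row holds condition ids,
#' first column gene ids. Missing values are an error — preprocessing
#' (normalization, batch correction) is expected upstream.
#'
#' @param path file path
#' @return numeric matrix with gene rownames and condition colnames
#' @export
read_expression <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, row.names = 1, sep = "\t",
                           quote = "", comment.char = "", check.names = FALSE)
  mat <- as.matrix(tab)
  storage.mode(mat) <- "double"
  if (anyNA(mat)) stop("expression matrix contains missing values")
  if (ncol(mat) < 2L) stop("need at least two conditions")
  if (anyDuplicated(rownames(mat))) stop("duplicate gene ids")
  mat
}

#' Write an expression matrix TSV
#' @param mat numeric matrix with gene rownames
#' @param path file path
#' @return `path`, invisibly
#' @export
write_expression <- function(mat, path) {
  tab <- data.frame(gene = rownames(mat), mat, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pairwise mutual information by equal-frequency discretization
#'
#' Each gene's values are discretized into equal-frequency bins (default
#' `floor(sqrt(conditions))`) and the maximum-likelihood plug-in mutual
#' information (in nats) is computed for every gene pair. Constant genes get
#' MI 0 for all of their pairs, with a warning.
#'
#' @param expr genes x conditions numeric matrix with gene rownames
#' @param bins number of bins, >= 2; conditions must be >= bins
#' @return symmetric gene x gene MI matrix with attributes `bins` and
#'   `estimator`
#' @export
mutual_information <- function(expr, bins = NULL) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)))
  n <- ncol(expr)
  if (is.null(bins)) bins <- max(2L, floor(sqrt(n)))
  if (bins < 2L) stop("bins must be >= 2")
  if (n < bins) stop("need at least as many conditions as bins")
  g <- nrow(expr)
  disc <- matrix(0L, nrow = g, ncol = n)
  constant <- logical(g)
  for (i in seq_len(g)) {
    x <- expr[i, ]
    if (length(unique(x)) == 1L) { constant[i] <- TRUE; disc[i, ] <- 1L; next }
    r <- rank(x, ties.method = "first")
    disc[i, ] <- as.integer(ceiling(r * bins / n))
  }
  if (any(constant))
    warning("constant gene row(s), MI set to 0: ",
            paste(utils::head(rownames(expr)[constant], 5), collapse = ", "))
  mi <- matrix(0, g, g, dimnames = list(rownames(expr), rownames(expr)))
  logn <- log(n)
  marg <- lapply(seq_len(g), function(i) tabulate(disc[i, ], nbins = bins))
  for (i in seq_len(g - 1L)) {
    if (constant[i]) next
    di <- disc[i, ]
    hi <- marg[[i]]
    for (j in (i + 1L):g) {
      if (constant[j]) next
      joint <- tabulate(di + bins * (disc[j, ] - 1L), nbins = bins * bins)
      nz <- joint > 0
      pij <- joint[nz] / n
      idx <- which(nz) - 1L
      pi_ <- hi[(idx %% bins) + 1L] / n
      pj_ <- marg[[j]][(idx %/% bins) + 1L] / n
      mi[i, j] <- mi[j, i] <- max(0, sum(pij * (log(pij) - log(pi_) - log(pj_))))
    }
  }
  attr(mi, "bins") <- bins
  attr(mi, "estimator") <- "ml_plugin_equalfreq"
  mi
}

#' Context-likelihood-of-relatedness (CLR) inference
#'
#' Scores each regulator-target pair by how exceptional their mutual
#' information is against both genes' MI backgrounds: per gene, the mean and
#' standard deviation of its off-diagonal MI row give z-scores clipped at 0,
#' and the edge score is `sqrt(z_i^2 + z_j^2)`. Causality is constrained by
#' the supplied regulator list — only TF -> gene edges are emitted, never
#' self-loops.
#'
#' @param mi symmetric MI matrix from [mutual_information()]
#' @param tf_list character vector of regulator gene ids (subset of rownames)
#' @return a `ranked_predictions`
#' @export
clr <- function(mi, tf_list) {
  genes <- rownames(mi)
  unknown <- setdiff(tolower(tf_list), tolower(genes))
  if (length(unknown))
    stop("tf_list contains unknown genes: ", paste(unknown, collapse = ", "))
  tf_list <- genes[tolower(genes) %in% tolower(tf_list)]
  g <- length(genes)
  z <- matrix(0, g, g, dimnames = dimnames(mi))
  for (i in seq_len(g)) {
    row <- mi[i, -i]
    mu <- mean(row); s <- stats::sd(row)
    zi <- if (is.na(s) || s == 0) rep(0, g) else (mi[i, ] - mu) / s
    z[i, ] <- pmax(0, zi)
  }
  score <- sqrt(z^2 + t(z)^2)
  tf_idx <- match(tf_list, genes)
  entries <- do.call(rbind, lapply(tf_idx, function(i) {
    j <- setdiff(seq_len(g), i)
    data.frame(regulator = genes[i], target = genes[j], score = score[i, j],
               stringsAsFactors = FALSE)
  }))
  if (is.null(entries)) entries <- data.frame(regulator = character(),
                                              target = character(), score = numeric())
  ranked_predictions(entries, method_label = "CLR")
}

#' Minimum-redundancy maximum-relevance network (MRNET) inference
#'
#' For each target gene, regulators are selected greedily from the TF list:
#' the first pick maximizes MI with the target; each further candidate is
#' scored by its MI with the target minus its mean MI with the already
#' selected regulators, and selection stops when the best score is not
#' positive. The edge score is the MRMR score at selection. Only TF ->
#' target edges are emitted, never self-loops.
#'
#' @inheritParams clr
#' @return a `ranked_predictions`
#' @export
mrnet <- function(mi, tf_list) {
  genes <- rownames(mi)
  unknown <- setdiff(tolower(tf_list), tolower(genes))
  if (length(unknown))
    stop("tf_list contains unknown genes: ", paste(unknown, collapse = ", "))
  tf_list <- genes[tolower(genes) %in% tolower(tf_list)]
  entries <- list()
  for (t in genes) {
    cands <- setdiff(tf_list, t)
    if (length(cands) == 0L) next
    selected <- character()
    scores <- stats::setNames(numeric(0), character(0))
    repeat {
      rest <- setdiff(cands, selected)
      if (length(rest) == 0L) break
      rel <- mi[rest, t]
      red <- if (length(selected) == 0L) 0
      else if (length(selected) == 1L) mi[rest, selected]
      else rowMeans(mi[rest, selected, drop = FALSE])
      sc <- rel - red
      best <- which.max(sc)
      if (length(selected) > 0L && sc[best] <= 0) break
      pick <- rest[best]
      scores[pick] <- sc[best]
      selected <- c(selected, pick)
      if (length(selected) == 0L) break
    }
    if (length(scores))
      entries[[t]] <- data.frame(regulator = names(scores), target = t,
                                 score = as.numeric(scores),
                                 stringsAsFactors = FALSE)
  }
  entries <- do.call(rbind, entries)
  if (is.null(entries)) entries <- data.frame(regulator = character(),
                                              target = character(), score = numeric())
  ranked_predictions(entries, method_label = "MRNET")
}
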