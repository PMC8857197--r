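# shared fixture builders; everything is generated in code

toy_grn <- function(edges, evidence = "weak", label = "toy") {
  # edges: character vector like c("A>B", "B>C")
  parts <- strsplit(edges, ">", fixed = TRUE)
  grn(data.frame(
    regulator = vapply(parts, `[`, character(1), 1),
    target = vapply(parts, `[`, character(1), 2),
    evidence = rep_len(evidence, length(edges)),
    stringsAsFactors = FALSE
  ), label = label)
}

edge_keys <- function(net) {
  paste(net$interactions$regulator, net$interactions$target, sep = ">")
}

pred_keys <- function(preds) {
  paste(preds$regulator, preds$target, sep = ">")
}

random_digraph_grn <- function(n, p, seed) {
  set.seed(seed)
  nodes <- paste0("n", seq_len(n))
  pairs <- expand.grid(from = nodes, to = nodes, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  sel <- pairs[runif(nrow(pairs)) < p, ]
  if (nrow(sel) == 0L) sel <- pairs[1, ]
  grn(data.frame(regulator = sel$from, target = sel$to, stringsAsFactors = FALSE))
}

# brute-force motif p-value: enumerate every width-w word, score it against
# the integer-discretized log-odds of the PWM, and accumulate background mass
# at or above the observed score. The observed score is the better of the
# word's two orientations, matching what the scanner reports; the null stays
# a single random word scored forward.
enumerate_pvalue <- function(pwm, word, granularity = 1e-3) {
  lo <- log2(pwm$matrix / pwm$background)
  int_sc <- round(lo / granularity)
  w <- pwm$width
  grid <- as.matrix(expand.grid(rep(list(1:4), w)))
  scores <- rowSums(matrix(int_sc[cbind(as.vector(grid), rep(seq_len(w), each = nrow(grid)))],
                           nrow = nrow(grid)))
  probs <- apply(grid, 1, function(b) prod(pwm$background[b]))
  b <- match(strsplit(word, "")[[1]], c("A", "C", "G", "T"))
  fwd <- sum(int_sc[cbind(b, seq_len(w))])
  rc_mat <- int_sc[4:1, w:1, drop = FALSE]
  rev_ <- sum(rc_mat[cbind(b, seq_len(w))])
  obs <- max(fwd, rev_)
  if (!is.finite(obs)) return(1)
  sum(probs[is.finite(scores) & scores >= obs])
}

# exhaustive motif counting over all ordered triples of distinct nodes
enumerate_motifs <- function(net) {
  ints <- net$interactions
  nodes <- grn_genes(net)
  has <- function(a, b) any(ints$regulator == a & ints$target == b)
  ffc <- 0L; cffc <- 0L; fb <- character()
  if (length(nodes) >= 3) {
    for (a in nodes) for (b in nodes) for (c in nodes) {
      if (a == b || b == c || a == c) next
      if (has(a, b) && has(a, c) && has(b, c)) {
        ffc <- ffc + 1L
        if (has(b, a) || has(c, a) || has(c, b)) cffc <- cffc + 1L
      }
      if (has(a, b) && has(b, c) && has(c, a))
        fb <- c(fb, paste(sort(c(a, b, c)), collapse = "-"))
    }
  }
  list(ffc = ffc, complex_ffc = cffc, feedback_3 = length(unique(fb)))
}

# step-function PR oracle: walk the ranked list one prediction at a time
# (distinct scores assumed), trapezoid over recall
oracle_aupr <- function(is_tp, n_pos) {
  tp <- cumsum(is_tp)
  n <- seq_along(is_tp)
  r <- c(0, tp / n_pos)
  p <- c((tp / n)[1], tp / n)
  sum(diff(r) * (head(p, -1) + tail(p, -1)) / 2)
}

# Mann-Whitney AUROC oracle over the full universe with unranked pairs at -Inf
oracle_auroc <- function(preds, gold) {
  regs <- grn_regulators(gold)
  genes <- grn_genes(gold)
  univ <- expand.grid(regulator = regs, target = genes, stringsAsFactors = FALSE)
  key <- paste(univ$regulator, univ$target, sep = ">")
  gk <- edge_keys(gold)
  pk <- pred_keys(preds)
  sc <- rep(-Inf, nrow(univ))
  m <- match(key, pk)
  sc[!is.na(m)] <- preds$score[m[!is.na(m)]]
  pos <- key %in% gk
  sp <- sc[pos]; sn <- sc[!pos]
  cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}
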