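#' Construct a ranked prediction list
#'
#' An ordered list of scored candidate interactions from one inference
#' method. Entries are sorted by decreasing score with lexicographic
#' (regulator, target) tie-breaking; duplicate (regulator, target) pairs are
#' an error.
#'
#' @param entries data frame with columns `regulator`, `target`, `score`
#' @param method_label string identifying the producing method
#' @return object of class `ranked_predictions`: a tibble with attribute
#'   `method_label`
#' @export
ranked_predictions <- function(entries, method_label = "") {
  ent <- tibble::as_tibble(as.data.frame(entries, stringsAsFactors = FALSE))
  stopifnot(all(c("regulator", "target", "score") %in% names(ent)))
  ent <- ent[, c("regulator", "target", "score",
                 setdiff(names(ent), c("regulator", "target", "score")))]
  ent$regulator <- as.character(ent$regulator)
  ent$target <- as.character(ent$target)
  ent$score <- as.numeric(ent$score)
  if (anyNA(ent$score)) stop("non-numeric or missing scores")
  key <- paste(tolower(ent$regulator), tolower(ent$target), sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (regulator, target) pairs: ",
         paste(utils::head(unique(key[duplicated(key)]), 5), collapse = ", "))
  }
  ord <- order(-ent$score, tolower(ent$regulator), tolower(ent$target), method = "radix")
  ent <- ent[ord, ]
  structure(ent, class = c("ranked_predictions", class(ent)), method_label = method_label)
}

#' @export
print.ranked_predictions <- function(x, ...) {
  cat(sprintf("<ranked_predictions> %s: %d entries\n",
              attr(x, "method_label"), nrow(x)))
  NextMethod()
}

#' Drop predictions involving genes outside the gold standard
#'
#' Entries with either endpoint absent from the gold network's gene set are
#' removed; the ranking order of the rest is preserved. Interactions among
#' genes unknown to the gold standard cannot be judged and would otherwise be
#' counted as false positives.
#'
#' @param predictions a `ranked_predictions`
#' @param gold a `grn` used as gold standard
#' @return a `ranked_predictions`
#' @export
restrict_to_gold <- function(predictions, gold) {
  stopifnot(inherits(predictions, "ranked_predictions"), inherits(gold, "grn"))
  gs <- tolower(grn_genes(gold))
  keep <- tolower(predictions$regulator) %in% gs & tolower(predictions$target) %in% gs
  out <- predictions[keep, ]
  structure(out, class = class(predictions), method_label = attr(predictions, "method_label"))
}

.gold_keys <- function(gold) {
  paste(tolower(gold$interactions$regulator), tolower(gold$interactions$target), sep = "\r")
}

.pred_keys <- function(predictions) {
  paste(tolower(predictions$regulator), tolower(predictions$target), sep = "\r")
}

#' Precision-recall curve and AUPR against a gold standard
#'
#' Walks the ranked list grouping tied scores into single curve points.
#' Precision is TP/(TP+FP) and recall TP/(TP+FN) with positives defined as
#' the gold network's interactions. The area is computed by trapezoidal
#' integration over recall, with the curve anchored at recall 0 using the
#' precision of the first tie group.
#'
#' @param predictions a `ranked_predictions` already restricted to gold genes
#' @param gold a `grn` with at least one interaction
#' @return list with `aupr` and `curve` (data frame `recall`, `precision`,
#'   `tp`, `fp` per tie group)
#' @export
pr_curve <- function(predictions, gold) {
  stopifnot(inherits(predictions, "ranked_predictions"), inherits(gold, "grn"))
  n_pos <- nrow(gold$interactions)
  if (n_pos == 0L) stop("gold standard has no positive interactions")
  is_tp <- .pred_keys(predictions) %in% .gold_keys(gold)
  if (nrow(predictions) == 0L) {
    return(list(aupr = 0, curve = data.frame(recall = 0, precision = NA_real_,
                                             tp = 0L, fp = 0L)))
  }
  grp <- cumsum(!duplicated(predictions$score)) # scores are sorted descending
  tp_g <- tapply(is_tp, grp, sum)
  n_g <- tapply(is_tp, grp, length)
  tp <- cumsum(tp_g)
  n_cum <- cumsum(n_g)
  precision <- tp / n_cum
  recall <- tp / n_pos
  r <- c(0, recall)
  p <- c(precision[1], precision)
  aupr <- sum(diff(r) * (utils::head(p, -1) + utils::tail(p, -1)) / 2)
  list(aupr = as.numeric(aupr),
       curve = data.frame(recall = as.numeric(recall),
                          precision = as.numeric(precision),
                          tp = as.integer(tp), fp = as.integer(n_cum - tp)))
}

#' ROC curve and AUROC against a gold standard
#'
#' The evaluation universe is every ordered (regulator, gene) pair where the
#' regulator has out-degree > 0 in the gold standard and the gene is any gold
#' gene (self-pairs included); negatives are universe pairs that are not gold
#' interactions. Tied scores form one curve point, and universe pairs absent
#' from the ranking are appended as a single tied block at the end. The area
#' is trapezoidal, equivalent to the Mann-Whitney rank-sum statistic with
#' ties counted half.
#'
#' @param predictions a `ranked_predictions` restricted to gold genes;
#'   entries outside the universe (non-regulator sources) are ignored
#' @param gold a `grn`
#' @return list with `auroc`, `curve` (data frame `fpr`, `tpr`), `universe`
#'   (pair count)
#' @export
roc_curve <- function(predictions, gold) {
  stopifnot(inherits(predictions, "ranked_predictions"), inherits(gold, "grn"))
  regs <- grn_regulators(gold)
  n_universe <- length(regs) * nrow(gold$genes)
  n_pos <- nrow(gold$interactions)
  n_neg <- n_universe - n_pos
  if (n_pos == 0L) stop("gold standard has no positive interactions")
  if (n_neg <= 0L) stop("gold standard universe has no negatives")
  in_univ <- tolower(predictions$regulator) %in% tolower(regs)
  preds <- predictions[in_univ, ]
  is_tp <- .pred_keys(preds) %in% .gold_keys(gold)
  if (nrow(preds)) {
    grp <- cumsum(!duplicated(preds$score))
    tp_g <- as.numeric(tapply(is_tp, grp, sum))
    n_g <- as.numeric(tapply(is_tp, grp, length))
  } else {
    tp_g <- numeric(); n_g <- numeric()
  }
  # unranked universe pairs: one tied block at the end
  tp_rest <- n_pos - sum(tp_g)
  n_rest <- n_universe - sum(n_g)
  if (n_rest > 0) { tp_g <- c(tp_g, tp_rest); n_g <- c(n_g, n_rest) }
  tp <- cumsum(tp_g); fp <- cumsum(n_g - tp_g)
  tpr <- c(0, tp / n_pos); fpr <- c(0, fp / n_neg)
  auroc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(auroc = as.numeric(auroc),
       curve = data.frame(fpr = as.numeric(fpr), tpr = as.numeric(tpr)),
       universe = n_universe)
}

#' Set-based scores for a global-regulator prediction
#'
#' Standard 2x2-table metrics over a fixed gene universe. The Matthews
#' correlation coefficient is defined as 0 whenever any table marginal is
#' zero; precision and F1 are 0 when undefined.
#'
#' @param predicted,gold,universe character vectors of locus tags; `predicted`
#'   and `gold` must be subsets of `universe`
#' @return list with `mcc`, `precision`, `recall`, `f1`, `counts`
#'   (`TP`, `FP`, `FN`, `TN`)
#' @export
gr_prediction_scores <- function(predicted, gold, universe) {
  universe <- unique(tolower(universe))
  if (length(universe) == 0L) stop("empty universe")
  predicted <- unique(tolower(predicted)); gold <- unique(tolower(gold))
  if (length(setdiff(predicted, universe)) || length(setdiff(gold, universe)))
    stop("predicted and gold sets must be subsets of the universe")
  tp <- length(intersect(predicted, gold))
  fp <- length(setdiff(predicted, gold))
  fn <- length(setdiff(gold, predicted))
  tn <- length(universe) - tp - fp - fn
  marg <- c(tp + fp, tp + fn, tn + fp, tn + fn)
  mcc <- if (any(marg == 0)) 0 else
    (tp * tn - fp * fn) / sqrt(prod(as.numeric(marg)))
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  list(mcc = mcc, precision = precision, recall = recall, f1 = f1,
       counts = c(TP = tp, FP = fp, FN = fn, TN = tn))
}

#' Simpson similarity index between two gene sets
#'
#' The size of the intersection relative to the smaller set:
#' `|A intersect B| / min(|A|, |B|)`. Identical sets (and any subset
#' relation) score 1; disjoint sets score 0. Both sets empty is undefined;
#' exactly one empty set returns 0 by convention.
#'
#' @param a,b character vectors (compared case-insensitively)
#' @return numeric in `[0, 1]`
#' @export
simpson_index <- function(a, b) {
  a <- unique(tolower(as.character(a))); b <- unique(tolower(as.character(b)))
  if (length(a) == 0L && length(b) == 0L)
    stop("Simpson index undefined for two empty sets")
  if (length(a) == 0L || length(b) == 0L) return(0)
  length(intersect(a, b)) / min(length(a), length(b))
}
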