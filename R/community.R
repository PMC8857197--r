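#' Integrate ranked prediction lists into a community ranking
#'
#' Wisdom-of-crowds rank aggregation: every interaction's community score is
#' the mean of its 1-based rank positions across the input lists. A list of
#' length L that does not contain the interaction contributes rank L + 1 (the
#' missing-rank penalty). Ranks are taken after each list's own deterministic
#' tie-breaking (descending score, then lexicographic pair order). The output
#' is sorted by ascending mean rank, ties broken lexicographically; its
#' `score` column is the negated mean rank so that higher still means more
#' confident.
#'
#' @param lists list of `ranked_predictions`
#' @param method_label label for the community list
#' @return a `ranked_predictions` with extra columns `mean_rank` and
#'   `support` (number of lists ranking the interaction)
#' @export
integrate_rankings <- function(lists, method_label = "community") {
  stopifnot(is.list(lists), length(lists) >= 1L,
            all(vapply(lists, inherits, TRUE, "ranked_predictions")))
  keys_by_list <- lapply(lists, .pred_keys)
  for (i in seq_along(keys_by_list)) {
    if (anyDuplicated(keys_by_list[[i]]))
      stop("duplicate interaction within input list ", i)
  }
  all_keys <- unique(unlist(keys_by_list))
  # preserve one canonical spelling per pair
  spell <- do.call(rbind, lapply(lists, function(l)
    data.frame(regulator = l$regulator, target = l$target, stringsAsFactors = FALSE)))
  spell <- spell[!duplicated(paste(tolower(spell$regulator), tolower(spell$target), sep = "\r")), ]
  rownames(spell) <- paste(tolower(spell$regulator), tolower(spell$target), sep = "\r")

  rank_sum <- setNames(numeric(length(all_keys)), all_keys)
  support <- setNames(integer(length(all_keys)), all_keys)
  for (i in seq_along(lists)) {
    L <- length(keys_by_list[[i]])
    m <- match(all_keys, keys_by_list[[i]])
    found <- !is.na(m)
    rank_sum[found] <- rank_sum[found] + m[found]
    rank_sum[!found] <- rank_sum[!found] + (L + 1)
    support[found] <- support[found] + 1L
  }
  mean_rank <- rank_sum / length(lists)
  out <- tibble::tibble(
    regulator = spell[all_keys, "regulator"],
    target = spell[all_keys, "target"],
    score = -mean_rank,
    mean_rank = as.numeric(mean_rank),
    support = as.integer(support)
  )
  ranked_predictions(out, method_label = method_label)
}

#' Keep the top-scoring predictions
#'
#' Truncates a ranked list to its first `min(k, length)` entries after the
#' deterministic tie-breaking applied at construction, e.g. pruning a
#' community network to the expected size of the complete regulatory network.
#'
#' @param predictions a `ranked_predictions`
#' @param k non-negative count
#' @return a `ranked_predictions`
#' @export
prune_top <- function(predictions, k) {
  stopifnot(inherits(predictions, "ranked_predictions"), k >= 0)
  out <- predictions[seq_len(min(k, nrow(predictions))), ]
  structure(out, class = class(predictions), method_label = attr(predictions, "method_label"))
}

#' Read a ranked prediction TSV
#'
#' Columns `regulator target score`, optional `#`-prefixed header. Rows are
#' validated (numeric scores, no duplicate pairs, errors report line numbers)
#' and sorted on load.
#'
#' @param path file path
#' @param method_label label (defaults to file name)
#' @return a `ranked_predictions`
#' @export
import_external_ranking <- function(path, method_label = basename(path)) {
  lines <- readLines(path)
  skip <- startsWith(lines, "#") | !nzchar(lines)
  body <- lines[!skip]
  lineno <- which(!skip)
  if (length(body) == 0L) return(ranked_predictions(
    data.frame(regulator = character(), target = character(), score = numeric()),
    method_label))
  parts <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3L))
    stop("malformed row(s) at line(s): ", paste(lineno[nf < 3L], collapse = ", "))
  reg <- vapply(parts, `[`, character(1), 1L)
  tgt <- vapply(parts, `[`, character(1), 2L)
  sco <- suppressWarnings(as.numeric(vapply(parts, `[`, character(1), 3L)))
  if (anyNA(sco))
    stop("non-numeric score(s) at line(s): ", paste(lineno[is.na(sco)], collapse = ", "))
  key <- paste(tolower(reg), tolower(tgt), sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate pair(s) at line(s): ", paste(lineno[duplicated(key)], collapse = ", "))
  ranked_predictions(data.frame(regulator = reg, target = tgt, score = sco,
                                stringsAsFactors = FALSE), method_label)
}

#' Write a ranked prediction TSV
#' @param predictions a `ranked_predictions`
#' @param path file path
#' @return `path`, invisibly
#' @export
write_ranking <- function(predictions, path) {
  stopifnot(inherits(predictions, "ranked_predictions"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("#regulator\ttarget\tscore", con)
  if (nrow(predictions)) {
    utils::write.table(
      data.frame(predictions$regulator, predictions$target,
                 format(predictions$score, digits = 12, trim = TRUE, scientific = FALSE)),
      con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
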