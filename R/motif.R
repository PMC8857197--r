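.DNA <- c("A", "C", "G", "T")

#' Extract non-overlapping upstream regions
#'
#' For each gene, takes the window from `window[1]` to `window[2]` relative
#' to the translation start codon (the annotated gene start on the coding
#' strand), truncated so it does not overlap the annotated extent of the
#' nearest upstream gene on the same replicon (regardless of that gene's
#' strand) and clipped at the replicon ends. Minus-strand genes are mirrored
#' and their sequence reverse-complemented, so the returned sequence always
#' reads 5'->3' on the coding strand. Coordinates are 1-based inclusive.
#'
#' @param genes gene table as from [read_gene_table()] (`locus_tag`,
#'   `replicon`, `start`, `end`, `strand`)
#' @param genome named character vector or `Biostrings::DNAStringSet` of
#'   replicon sequences
#' @param window integer length-2, default `c(-300, 50)`
#' @return tibble with columns `gene`, `replicon`, `start`, `end`, `strand`,
#'   `sequence`; genes whose window collapses to nothing are omitted
#' @export
extract_upstream <- function(genes, genome, window = c(-300, 50)) {
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  stopifnot(all(c("locus_tag", "replicon", "start", "end", "strand") %in% names(genes)))
  if (any(!genes$strand %in% c("+", "-"))) stop("unknown strand value(s)")
  seqs <- stats::setNames(as.character(genome), names(genome))
  out <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    gi <- genes[i, ]
    if (!gi$replicon %in% names(seqs)) stop("replicon not in genome: ", gi$replicon)
    chrlen <- nchar(seqs[[gi$replicon]])
    same <- genes[genes$replicon == gi$replicon & genes$locus_tag != gi$locus_tag, ]
    if (gi$strand == "+") {
      s <- gi$start
      lo <- s + window[1]; hi <- s + window[2]
      nb_end <- suppressWarnings(max(same$end[same$end < s]))
      if (is.finite(nb_end)) lo <- max(lo, nb_end + 1L)
      lo <- max(lo, 1L); hi <- min(hi, chrlen)
    } else {
      s <- gi$end
      lo <- s - window[2]; hi <- s - window[1]
      nb_start <- suppressWarnings(min(same$start[same$start > s]))
      if (is.finite(nb_start)) hi <- min(hi, nb_start - 1L)
      lo <- max(lo, 1L); hi <- min(hi, chrlen)
    }
    if (hi < lo) next
    seq <- substr(seqs[[gi$replicon]], lo, hi)
    if (gi$strand == "-") seq <- .revcomp(seq)
    out[[i]] <- tibble::tibble(gene = gi$locus_tag, replicon = gi$replicon,
                               start = as.integer(lo), end = as.integer(hi),
                               strand = gi$strand, sequence = toupper(seq))
  }
  do.call(rbind, out[!vapply(out, is.null, TRUE)])
}

.revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Build a position weight matrix from aligned binding sites
#'
#' Column probabilities are `(count + pseudocount * background) /
#' (n + pseudocount)`. At least three sites are required — regulon models
#' built from fewer known targets are refused — and all sites must share one
#' width.
#'
#' @param tf regulator locus tag the matrix models
#' @param site_sequences character vector of equal-length DNA strings
#' @param background length-4 probability vector over A,C,G,T (default
#'   uniform)
#' @param pseudocount default 0.1
#' @return object of class `pwm`: list with `tf`, `matrix` (4 x width, rows
#'   A,C,G,T, columns summing to 1), `width`, `background`, `source_sites`
#' @export
build_pwm <- function(tf, site_sequences, background = rep(0.25, 4), pseudocount = 0.1) {
  sites <- toupper(as.character(site_sequences))
  if (length(sites) < 3L)
    stop("at least 3 binding sites are required to build a PWM (got ", length(sites), ")")
  w <- unique(nchar(sites))
  if (length(w) != 1L) stop("sites have unequal widths: ", paste(w, collapse = ", "))
  if (w < 2L) stop("site width too small")
  background <- background / sum(background)
  mat <- matrix(0, nrow = 4, ncol = w, dimnames = list(.DNA, NULL))
  chars <- do.call(rbind, strsplit(sites, ""))
  if (any(!chars %in% .DNA)) stop("sites contain non-ACGT characters")
  for (j in seq_len(w)) {
    cnt <- table(factor(chars[, j], levels = .DNA))
    mat[, j] <- (as.numeric(cnt) + pseudocount * background) /
      (length(sites) + pseudocount)
  }
  structure(list(tf = tf, matrix = mat, width = w,
                 background = stats::setNames(background, .DNA),
                 source_sites = length(sites)),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  ic <- pwm_information_content(x)
  cat(sprintf("<pwm> %s: width %d, %d source sites, %.2f bits/column\n",
              x$tf, x$width, x$source_sites, mean(ic)))
  invisible(x)
}

#' Per-column information content of a PWM (bits, relative to background)
#' @param pwm a `pwm`
#' @return numeric vector, one value per column
#' @export
pwm_information_content <- function(pwm) {
  apply(pwm$matrix, 2, function(p) sum(p * log2(p / pwm$background)))
}

# integer-discretized log-odds scores and the exact null score distribution
# under the background model, by per-column convolution. PWM cells with zero
# probability score -Inf; words containing such a cell can never reach a
# finite threshold, so their background mass is simply left out of the
# finite-score distribution (the survival function already accounts for it).
.pwm_score_model <- function(pwm, granularity = 1e-3) {
  lo <- log2(pwm$matrix / pwm$background)
  int_sc <- round(lo / granularity) # -Inf survives the rounding
  offs <- apply(int_sc, 2, function(v) min(v[is.finite(v)]))
  span <- apply(int_sc, 2, function(v) max(v[is.finite(v)])) - offs
  pmf <- 1
  for (j in seq_len(ncol(int_sc))) {
    col_pmf <- numeric(span[j] + 1L)
    for (b in 1:4) {
      if (!is.finite(int_sc[b, j])) next
      idx <- int_sc[b, j] - offs[j] + 1L
      col_pmf[idx] <- col_pmf[idx] + pwm$background[b]
    }
    new_len <- length(pmf) + length(col_pmf) - 1L
    acc <- numeric(new_len)
    nz <- which(col_pmf > 0)
    for (k in nz) acc[k:(k + length(pmf) - 1L)] <-
      acc[k:(k + length(pmf) - 1L)] + col_pmf[k] * pmf
    pmf <- acc
  }
  surv <- rev(cumsum(rev(pmf))) # surv[i] = P(int score - min >= i - 1)
  list(int_scores = int_sc, offset = sum(offs), granularity = granularity,
       surv = surv)
}

# all window scores of a 4 x w score matrix over an integer-coded sequence;
# windows containing non-ACGT characters score NA
.window_scores <- function(score_mat, code) {
  w <- ncol(score_mat)
  n <- length(code)
  if (n < w) return(numeric(0))
  starts <- seq_len(n - w + 1L)
  idx <- outer(0:(w - 1L), starts, "+") # w x n_windows of positions
  b <- code[idx]
  flat <- score_mat[cbind(as.vector(b), rep.int(seq_len(w), length(starts)))]
  .colSums(matrix(flat, nrow = w), w, length(starts), na.rm = FALSE)
}

# best hit of one PWM on one sequence (both strands); returns NULL if the
# sequence is shorter than the PWM
.scan_sequence <- function(model, pwm, sequence) {
  w <- pwm$width
  n <- nchar(sequence)
  if (n < w) return(NULL)
  code <- match(strsplit(sequence, "")[[1]], .DNA) # N -> NA
  best <- NULL
  rc <- model$int_scores[4:1, ncol(model$int_scores):1, drop = FALSE]
  for (strand in c("+", "-")) {
    sc <- if (strand == "+") model$int_scores else rc
    scores <- .window_scores(sc, code)
    if (all(is.na(scores))) next
    pos <- which.max(scores) # NAs never win
    s_int <- scores[pos]
    if (is.null(best) || s_int > best$s_int)
      best <- list(pos = pos, strand = strand, s_int = s_int)
  }
  if (is.null(best)) return(NULL)
  # p-value: probability a random background word scores >= observed
  if (!is.finite(best$s_int)) {
    return(list(position = best$pos, strand = best$strand,
                score = -Inf, p_value = 1))
  }
  idx <- best$s_int - model$offset + 1L
  if (idx > length(model$surv)) idx <- length(model$surv)
  p <- if (idx < 1L) 1 else model$surv[idx]
  list(position = best$pos, strand = best$strand,
       score = best$s_int * model$granularity, p_value = min(1, p))
}

#' Scan upstream regions with a PWM
#'
#' Scores every offset of every region on both strands with the
#' log2-odds of the PWM against its background and computes, for the best
#' hit per gene, the exact p-value: the probability under the background
#' model that a random word of the PWM's width scores at least as high,
#' computed by dynamic programming over integer-discretized scores
#' (granularity `1e-3` on the log-odds scale, which bounds the exactness of
#' the p-values). Hits with `p_value < p_threshold` are returned.
#'
#' @param pwm a `pwm`
#' @param regions tibble from [extract_upstream()] (columns `gene`,
#'   `sequence`); regions shorter than the PWM width are skipped
#' @param p_threshold default `1e-4`
#' @return tibble `tf gene position strand score p_value`, best hit per
#'   gene, sorted by p-value
#' @export
scan_regions <- function(pwm, regions, p_threshold = 1e-4) {
  stopifnot(inherits(pwm, "pwm"))
  if (!(p_threshold > 0 && p_threshold < 1)) stop("p_threshold must be in (0,1)")
  model <- .pwm_score_model(pwm)
  hits <- vector("list", nrow(regions))
  for (i in seq_len(nrow(regions))) {
    h <- .scan_sequence(model, pwm, regions$sequence[i])
    if (is.null(h)) next
    hits[[i]] <- tibble::tibble(tf = pwm$tf, gene = regions$gene[i],
                                position = h$position, strand = h$strand,
                                score = h$score, p_value = h$p_value)
  }
  hits <- do.call(rbind, hits[!vapply(hits, is.null, TRUE)])
  if (is.null(hits)) return(.empty_hits())
  hits <- hits[hits$p_value < p_threshold, , drop = FALSE]
  hits[order(hits$p_value, tolower(hits$gene)), , drop = FALSE]
}

.empty_hits <- function() {
  tibble::tibble(tf = character(), gene = character(), position = integer(),
                 strand = character(), score = numeric(), p_value = numeric())
}

#' Discover a shared motif in a set of sequences
#'
#' A deliberately simple information-content-maximizing common-window
#' search: every word of the requested width in the first sequences seeds a
#' candidate; each seed is extended to a PWM by taking the best-matching
#' window of every sequence, and the PWM is refined by a few rounds of
#' rescan-and-rebuild. The candidate with the highest total information
#' content wins. External motifs (e.g. from dedicated discovery tools) can
#' be used instead wherever a `pwm` is accepted; see [read_meme()].
#'
#' @param sequences character vector of DNA sequences (>= 3)
#' @param width motif width (default 12)
#' @param background length-4 background probabilities (default: 0-order
#'   frequencies of `sequences`)
#' @param n_seeds number of seed words tried (default 60)
#' @param refine refinement rounds (default 3)
#' @return a `pwm` (the `tf` field is left empty)
#' @export
discover_motif <- function(sequences, width = 12, background = NULL,
                           n_seeds = 60, refine = 3) {
  seqs <- toupper(as.character(sequences))
  seqs <- seqs[nchar(seqs) >= width]
  if (length(seqs) < 3L) stop("need at least 3 sequences of length >= width")
  if (is.null(background)) {
    tab <- table(factor(unlist(strsplit(seqs, "")), levels = .DNA))
    background <- (as.numeric(tab) + 1) / (sum(tab) + 4)
  }
  background <- background / sum(background)

  words <- unlist(lapply(seqs, function(s) {
    n <- nchar(s)
    starts <- seq_len(n - width + 1L)
    vapply(starts, function(p) substr(s, p, p + width - 1L), character(1))
  }))
  words <- words[!grepl("[^ACGT]", words)]
  if (length(words) == 0L) stop("no clean seed words available")
  seeds <- unique(words)
  if (length(seeds) > n_seeds) {
    # deterministic spread over the word list
    seeds <- seeds[unique(round(seq(1, length(seeds), length.out = n_seeds)))]
  }

  best <- NULL
  for (seed in seeds) {
    pwm <- build_pwm("", rep(seed, 3), background = background, pseudocount = 1)
    ok <- TRUE
    for (it in seq_len(refine)) {
      wins <- vapply(seqs, function(s) .best_window(pwm, s), character(1))
      wins <- wins[!is.na(wins)]
      if (length(wins) < 3L) { ok <- FALSE; break }
      pwm <- build_pwm("", wins, background = background, pseudocount = 0.5)
    }
    if (!ok) next
    ic <- sum(pwm_information_content(pwm))
    if (is.null(best) || ic > best$ic) best <- list(pwm = pwm, ic = ic)
  }
  best$pwm
}

# best-scoring window of one sequence against a PWM, both strands,
# returned on the strand that matches the motif
.best_window <- function(pwm, s) {
  lo <- log2(pwm$matrix / pwm$background)
  w <- pwm$width
  code <- match(strsplit(s, "")[[1]], .DNA)
  fwd <- .window_scores(lo, code)
  rev_ <- .window_scores(lo[4:1, w:1, drop = FALSE], code)
  if (all(is.na(c(fwd, rev_)))) return(NA_character_)
  bf <- which.max(fwd); br <- which.max(rev_)
  if (length(br) && (!length(bf) || rev_[br] > fwd[bf]))
    .revcomp(substr(s, br, br + w - 1L))
  else substr(s, bf, bf + w - 1L)
}

#' Extend regulons by motif scanning
#'
#' For every regulator of the prior (strong-evidence) network with at least
#' three targets that have upstream regions, a binding motif is obtained
#' from those targets' regions — by the built-in common-window discovery or
#' from a user-supplied PWM list — and all regions are scanned. Hits are
#' returned as a ranked prediction list sorted by increasing p-value
#' (score = -log10 p).
#'
#' @param prior a `grn` of trusted (strong) interactions
#' @param regions tibble from [extract_upstream()] covering candidate genes
#' @param p_threshold FIMO-style p-value threshold, default `1e-4`
#' @param width motif width for discovery (default 12)
#' @param pwms optional named list of `pwm` objects (names = TF locus tags)
#'   bypassing discovery, e.g. imported with [read_meme()]
#' @return a `ranked_predictions` with extra column `p_value`
#' @export
extend_regulons <- function(prior, regions, p_threshold = 1e-4, width = 12,
                            pwms = NULL) {
  stopifnot(inherits(prior, "grn"))
  tfs <- grn_regulators(prior)
  all_hits <- list()
  for (tf in tfs) {
    tgs <- prior$interactions$target[tolower(prior$interactions$regulator) == tolower(tf)]
    tg_regions <- regions[tolower(regions$gene) %in% tolower(tgs), , drop = FALSE]
    if (nrow(tg_regions) < 3L) {
      message("skipping ", tf, ": fewer than 3 prior targets with upstream regions")
      next
    }
    pwm <- if (!is.null(pwms) && tf %in% names(pwms)) pwms[[tf]]
    else tryCatch(discover_motif(tg_regions$sequence, width = width),
                  error = function(e) NULL)
    if (is.null(pwm)) next
    pwm$tf <- tf
    hits <- scan_regions(pwm, regions, p_threshold = p_threshold)
    if (nrow(hits)) all_hits[[tf]] <- hits
  }
  hits <- do.call(rbind, all_hits)
  if (is.null(hits) || nrow(hits) == 0L) {
    return(ranked_predictions(
      data.frame(regulator = character(), target = character(), score = numeric()),
      method_label = "binding_sites"))
  }
  ranked_predictions(
    data.frame(regulator = hits$tf, target = hits$gene,
               score = -log10(hits$p_value), p_value = hits$p_value,
               stringsAsFactors = FALSE),
    method_label = "binding_sites")
}

#' Statistically validate ChIP-supported interactions by motif evidence
#'
#' Returns the weak ChIP-supported interactions that are also supported by a
#' motif hit — the intersection of the two evidence sources. The caller
#' merges these back into the network as strong.
#'
#' @param weak_chip a `grn` (or interaction data frame) of weak interactions
#'   supported by ChIP-type experiments
#' @param motif_hits hit table with columns `tf` and `gene` (as from
#'   [scan_regions()]) or a `ranked_predictions`
#' @return the validated subset of `weak_chip`'s interaction tibble, with
#'   evidence set to `"strong"`
#' @export
chip_validate <- function(weak_chip, motif_hits) {
  ints <- if (inherits(weak_chip, "grn")) weak_chip$interactions
  else tibble::as_tibble(weak_chip)
  if (inherits(motif_hits, "ranked_predictions")) {
    hk <- paste(tolower(motif_hits$regulator), tolower(motif_hits$target), sep = "\r")
  } else {
    hk <- paste(tolower(motif_hits$tf), tolower(motif_hits$gene), sep = "\r")
  }
  ik <- paste(tolower(ints$regulator), tolower(ints$target), sep = "\r")
  out <- ints[ik %in% hk, , drop = FALSE]
  if (nrow(out)) out$evidence <- "strong"
  out
}

#' Transfer regulons across species through 1:1 orthologs
#'
#' Builds a PWM for every source-organism regulator with at least three
#' targets that have upstream regions, scans the target organism's upstream
#' regions, and keeps predictions only where both the regulator and the
#' target gene have a one-to-one ortholog. For redundant predictions only
#' the best (lowest p-value) is kept. The returned network lists the target
#' organism's own strong interactions (if given) first, followed by the
#' transferred predictions sorted by p-value, labelled with the `regulogs`
#' experiment tag and weak evidence.
#'
#' @param source_strong a `grn` of strong interactions in the source organism
#' @param source_regions upstream regions of the source organism
#' @param target_regions upstream regions of the target organism
#' @param orthologs two-column data frame (`source`, `target` locus tags),
#'   strictly one-to-one; offending rows are an error
#' @param p_threshold default `1e-4`
#' @param target_strong optional `grn` of the target organism's own strong
#'   interactions, placed ahead of the predictions
#' @param width motif width for discovery (default 12)
#' @return list with `network` (complemented `grn` in target-organism
#'   coordinates) and `predictions` (tibble of transfers with p-values)
#' @export
regulogs_transfer <- function(source_strong, source_regions, target_regions,
                              orthologs, p_threshold = 1e-4,
                              target_strong = NULL, width = 12) {
  orth <- as.data.frame(orthologs, stringsAsFactors = FALSE)
  names(orth)[1:2] <- c("source", "target")
  dup_s <- orth$source[duplicated(tolower(orth$source))]
  dup_t <- orth$target[duplicated(tolower(orth$target))]
  if (length(dup_s) || length(dup_t))
    stop("ortholog map is not one-to-one; offenders: ",
         paste(unique(c(dup_s, dup_t)), collapse = ", "))
  map <- stats::setNames(orth$target, tolower(orth$source))

  tfs <- grn_regulators(source_strong)
  preds <- list()
  for (tf in tfs) {
    tf_orth <- map[tolower(tf)]
    if (is.na(tf_orth)) next # regulator has no 1:1 ortholog
    tgs <- source_strong$interactions$target[
      tolower(source_strong$interactions$regulator) == tolower(tf)]
    tg_regions <- source_regions[tolower(source_regions$gene) %in% tolower(tgs), , drop = FALSE]
    if (nrow(tg_regions) < 3L) next
    pwm <- tryCatch(discover_motif(tg_regions$sequence, width = width),
                    error = function(e) NULL)
    if (is.null(pwm)) next
    pwm$tf <- tf
    # scan only target genes that themselves have a 1:1 ortholog
    targetable <- target_regions[tolower(target_regions$gene) %in% tolower(orth$target), , drop = FALSE]
    hits <- scan_regions(pwm, targetable, p_threshold = p_threshold)
    if (nrow(hits))
      preds[[tf]] <- tibble::tibble(regulator = unname(tf_orth), target = hits$gene,
                                    p_value = hits$p_value, source_tf = tf)
  }
  preds <- do.call(rbind, preds)
  if (!is.null(preds) && nrow(preds)) {
    preds <- preds[order(preds$p_value), , drop = FALSE]
    key <- paste(tolower(preds$regulator), tolower(preds$target), sep = "\r")
    preds <- preds[!duplicated(key), , drop = FALSE]
  } else {
    preds <- tibble::tibble(regulator = character(), target = character(),
                            p_value = numeric(), source_tf = character())
  }
  pred_ints <- if (nrow(preds)) data.frame(
    regulator = preds$regulator, target = preds$target,
    effect = "unknown", evidence = "weak",
    experiments = "regulogs", sources = "regulogs_transfer",
    stringsAsFactors = FALSE) else NULL
  base_ints <- if (!is.null(target_strong)) target_strong$interactions else NULL
  all_ints <- rbind(
    if (!is.null(base_ints)) base_ints[, c("regulator", "target", "effect", "evidence")] else NULL,
    if (!is.null(pred_ints)) pred_ints[, c("regulator", "target", "effect", "evidence")] else NULL
  )
  net <- grn(all_ints, label = "regulogs_complemented")
  list(network = net, predictions = preds)
}

#' GRN-wide orthologous relationships
#'
#' The 1:1 ortholog pairs whose members are both present in their respective
#' organisms' networks.
#'
#' @param netA,netB `grn` objects
#' @param orthologs two-column data frame (gene in A, gene in B)
#' @return tibble with the surviving ortholog pairs
#' @export
grn_wide_orthologs <- function(netA, netB, orthologs) {
  orth <- as.data.frame(orthologs, stringsAsFactors = FALSE)
  if (nrow(orth) == 0L) return(tibble::tibble(a = character(), b = character()))
  names(orth)[1:2] <- c("a", "b")
  keep <- tolower(orth$a) %in% tolower(grn_genes(netA)) &
    tolower(orth$b) %in% tolower(grn_genes(netB))
  tibble::as_tibble(orth[keep, c("a", "b"), drop = FALSE])
}

# ---------------------------------------------------------------------------
# MEME minimal motif format

#' Write PWMs in MEME minimal motif format
#' @param pwms list of `pwm` objects
#' @param path file path
#' @return `path`, invisibly
#' @export
write_meme <- function(pwms, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  bg <- pwms[[1]]$background
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "", "Background letter frequencies",
               sprintf("A %.5f C %.5f G %.5f T %.5f", bg[1], bg[2], bg[3], bg[4]),
               ""), con)
  for (p in pwms) {
    writeLines(sprintf("MOTIF %s", p$tf), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
                       p$width, p$source_sites), con)
    for (j in seq_len(p$width))
      writeLines(sprintf(" %.6f %.6f %.6f %.6f",
                         p$matrix[1, j], p$matrix[2, j], p$matrix[3, j], p$matrix[4, j]), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read PWMs from a MEME minimal motif file
#' @param path file path
#' @return named list of `pwm` objects
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  bg <- rep(0.25, 4)
  bg_i <- grep("^Background letter frequencies", lines)
  if (length(bg_i)) {
    toks <- strsplit(trimws(lines[bg_i[1] + 1]), "\\s+")[[1]]
    bg <- as.numeric(toks[c(2, 4, 6, 8)])
  }
  motif_i <- grep("^MOTIF", lines)
  out <- list()
  for (mi in motif_i) {
    name <- strsplit(trimws(lines[mi]), "\\s+")[[1]][2]
    hdr_i <- mi + grep("letter-probability matrix", lines[(mi + 1):length(lines)])[1]
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[hdr_i]))
    nsites <- if (grepl("nsites=", lines[hdr_i]))
      as.integer(sub(".*nsites=\\s*(\\d+).*", "\\1", lines[hdr_i])) else 3L
    rows <- lines[(hdr_i + 1):(hdr_i + w)]
    mat <- t(vapply(rows, function(r) as.numeric(strsplit(trimws(r), "\\s+")[[1]]),
                    numeric(4)))
    m <- t(mat)
    dimnames(m) <- list(.DNA, NULL)
    out[[name]] <- structure(
      list(tf = name, matrix = m, width = w,
           background = stats::setNames(bg, .DNA), source_sites = nsites),
      class = "pwm")
  }
  out
}

#' Read sequences from a FASTA file
#' @param path file path
#' @return named character vector of sequences
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write sequences to a FASTA file
#' @param seqs named character vector
#' @param path file path
#' @return `path`, invisibly
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}
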