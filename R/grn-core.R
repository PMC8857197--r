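#' @importFrom tibble tibble as_tibble
#' @importFrom stats setNames
NULL

.EFFECTS <- c("activation", "repression", "dual", "unknown")
.EVIDENCE_LEVELS <- c("strong", "weak")

#' Construct a gene regulatory network
#'
#' A `grn` is a directed graph of regulatory interactions among genes keyed by
#' locus tag. Each interaction records its regulatory effect, an evidence
#' grade (`"strong"` when at least one supporting experiment demonstrates
#' physical binding of the regulator upstream of the target, `"weak"`
#' otherwise), the set of supporting experiment types, and provenance strings.
#'
#' Gene identifiers are case-preserved but compared case-insensitively: the
#' first spelling seen becomes canonical. Genes without any interaction are
#' dropped unless passed explicitly through `genes`.
#'
#' @param interactions data frame with columns `regulator`, `target` and
#'   optionally `effect`, `evidence`, `experiments`, `sources`. `experiments`
#'   and `sources` may be list columns of character vectors or
#'   semicolon-delimited strings.
#' @param genes optional data frame with columns `locus_tag` and optionally
#'   `name`, `replicon`; rows for genes absent from `interactions` are kept
#'   only if they appear here AND participate in an interaction elsewhere.
#' @param label character network label used in printing and summaries.
#' @param synonyms optional named character vector mapping alias -> canonical
#'   locus tag, applied before any merging.
#' @return An object of class `grn` with elements `genes` (tibble),
#'   `interactions` (tibble with list columns `experiments`, `sources`) and
#'   `label`.
#' @export
grn <- function(interactions = NULL, genes = NULL, label = "", synonyms = NULL) {
  if (is.null(interactions) || nrow(as.data.frame(interactions)) == 0L) {
    ints <- tibble(
      regulator = character(), target = character(),
      effect = character(), evidence = character(),
      experiments = list(), sources = list()
    )
    gen <- tibble(locus_tag = character(), name = NA_character_[0], replicon = NA_character_[0])
    out <- structure(list(genes = gen, interactions = ints, label = label), class = "grn")
    return(out)
  }
  ints <- as_tibble(as.data.frame(interactions, stringsAsFactors = FALSE))
  stopifnot(all(c("regulator", "target") %in% names(ints)))
  if (is.null(ints[["effect"]])) ints$effect <- "unknown"
  if (is.null(ints[["evidence"]])) ints$evidence <- "weak"
  ints$experiments <- .as_setcol(ints[["experiments"]], nrow(ints))
  ints$sources <- .as_setcol(ints[["sources"]], nrow(ints))
  ints$regulator <- as.character(ints$regulator)
  ints$target <- as.character(ints$target)
  if (!is.null(synonyms)) {
    ints$regulator <- .apply_synonyms(ints$regulator, synonyms)
    ints$target <- .apply_synonyms(ints$target, synonyms)
  }
  if (any(!nzchar(ints$regulator)) || any(!nzchar(ints$target)))
    stop("empty locus_tag in interaction table")
  bad_eff <- setdiff(unique(ints$effect), .EFFECTS)
  if (length(bad_eff)) stop("unknown effect value(s): ", paste(bad_eff, collapse = ", "))
  bad_ev <- setdiff(unique(ints$evidence), .EVIDENCE_LEVELS)
  if (length(bad_ev)) stop("unknown evidence level(s): ", paste(bad_ev, collapse = ", "))

  # canonicalize case: first spelling seen wins
  canon <- .canonical_case(c(rbind(ints$regulator, ints$target)))
  ints$regulator <- canon[tolower(ints$regulator)]
  ints$target <- canon[tolower(ints$target)]

  # collapse duplicate (regulator, target) records
  key <- paste(tolower(ints$regulator), tolower(ints$target), sep = "\r")
  if (anyDuplicated(key)) {
    idx <- split(seq_len(nrow(ints)), key)
    ints <- do.call(rbind, lapply(idx, function(i) .collapse_records(ints[i, , drop = FALSE])))
    ints <- as_tibble(ints)
  }
  ord <- order(tolower(ints$regulator), tolower(ints$target), method = "radix")
  ints <- ints[ord, ]

  tags <- unique(c(ints$regulator, ints$target))
  gen <- tibble(locus_tag = tags, name = NA_character_, replicon = NA_character_)
  if (!is.null(genes) && nrow(as.data.frame(genes)) > 0L) {
    gtab <- as_tibble(as.data.frame(genes, stringsAsFactors = FALSE))
    stopifnot("locus_tag" %in% names(gtab))
    gtab$locus_tag <- as.character(gtab$locus_tag)
    m <- match(tolower(gen$locus_tag), tolower(gtab$locus_tag))
    if (!is.null(gtab[["name"]])) gen$name <- as.character(gtab$name)[m]
    if (!is.null(gtab[["replicon"]])) gen$replicon <- as.character(gtab$replicon)[m]
  }
  gen <- gen[order(tolower(gen$locus_tag), method = "radix"), ]
  structure(list(genes = gen, interactions = ints, label = label), class = "grn")
}

.as_setcol <- function(x, n) {
  if (is.null(x)) return(replicate(n, character(), simplify = FALSE))
  if (is.list(x)) return(lapply(x, function(v) sort(unique(as.character(v[nzchar(v)])))))
  x <- as.character(x)
  lapply(x, function(v) {
    if (is.na(v) || !nzchar(v)) return(character())
    sort(unique(trimws(strsplit(v, ";", fixed = TRUE)[[1]])))
  })
}

.apply_synonyms <- function(tags, synonyms) {
  m <- match(tolower(tags), tolower(names(synonyms)))
  ifelse(is.na(m), tags, unname(synonyms[m]))
}

.canonical_case <- function(tags) {
  low <- tolower(tags)
  first <- !duplicated(low)
  setNames(tags[first], low[first])
}

# collapse several records for one (regulator, target) pair:
# evidence takes the maximum level, effects conflict to "dual",
# experiments and sources are unioned
.collapse_records <- function(recs) {
  eff <- setdiff(unique(recs$effect), "unknown")
  effect <- if (length(eff) == 0L) "unknown"
  else if (length(eff) == 1L && eff != "dual") eff
  else "dual"
  evidence <- if (any(recs$evidence == "strong")) "strong" else "weak"
  tibble(
    regulator = recs$regulator[1], target = recs$target[1],
    effect = effect, evidence = evidence,
    experiments = list(sort(unique(unlist(recs$experiments)))),
    sources = list(sort(unique(unlist(recs$sources))))
  )
}

#' @export
print.grn <- function(x, ...) {
  cat(sprintf(
    "<grn> %s: %d genes, %d interactions (%d strong)\n",
    if (nzchar(x$label)) x$label else "(unlabelled)",
    nrow(x$genes), nrow(x$interactions),
    sum(x$interactions$evidence == "strong")
  ))
  invisible(x)
}

#' Genes of a network
#' @param network a `grn`
#' @return character vector of locus tags
#' @export
grn_genes <- function(network) network$genes$locus_tag

#' Regulators of a network (out-degree > 0)
#' @param network a `grn`
#' @return character vector of locus tags with at least one outgoing edge
#' @export
grn_regulators <- function(network) sort(unique(network$interactions$regulator))

#' Default experiment-type evidence catalog
#'
#' Maps experiment-type strings to the two evidence grades. Experiments
#' demonstrating physical binding of the regulator to the target's upstream
#' region (EMSA with purified protein, in vitro transcription, DNase
#' footprinting) grade `"strong"`; experiments that only suggest a binding
#' site or an effect that may be indirect (ChIP variants, transcriptomics,
#' RT-PCR, DACA) grade `"weak"`. Extend with
#' `c(default_evidence_catalog(), "my assay" = "strong")`.
#'
#' @return named character vector, values `"strong"` or `"weak"`
#' @export
default_evidence_catalog <- function() {
  c(
    "EMSA" = "strong",
    "in vitro transcription" = "strong",
    "footprinting" = "strong",
    "DNase footprinting" = "strong",
    "site mutation" = "strong",
    "ChIP" = "weak",
    "ChIP-seq" = "weak",
    "ChIP-chip" = "weak",
    "ChIP-exo" = "weak",
    "ChIP-qPCR" = "weak",
    "microarray" = "weak",
    "RNA-seq" = "weak",
    "RT-PCR" = "weak",
    "RT-qPCR" = "weak",
    "qRT-PCR" = "weak",
    "DACA" = "weak",
    "knockout" = "weak",
    "overexpression" = "weak",
    "reporter fusion" = "weak",
    "inference" = "weak"
  )
}

#' Grade the evidence of an interaction from its supporting experiments
#'
#' An interaction is `"strong"` iff at least one supporting experiment maps to
#' the strong grade in the catalog; an empty experiment set grades `"weak"`.
#'
#' @param experiments character vector of experiment-type strings
#' @param catalog named character vector as from [default_evidence_catalog()]
#' @return `"strong"` or `"weak"`
#' @export
classify_evidence <- function(experiments, catalog = default_evidence_catalog()) {
  experiments <- as.character(experiments)
  experiments <- experiments[nzchar(experiments)]
  if (length(experiments) == 0L) return("weak")
  m <- match(tolower(experiments), tolower(names(catalog)))
  if (anyNA(m)) {
    stop("unknown experiment type(s) not in catalog: ",
         paste(unique(experiments[is.na(m)]), collapse = ", "))
  }
  if (any(catalog[m] == "strong")) "strong" else "weak"
}

#' Merge curated networks into a meta-curation
#'
#' Unions genes and interactions of several networks. Interactions sharing a
#' (regulator, target) pair collapse to a single record: experiments and
#' sources are unioned, evidence takes the maximum grade (strong > weak), and
#' conflicting effects resolve to `"dual"`. Locus tags are compared
#' case-insensitively.
#'
#' @param networks list of `grn` objects
#' @param label label for the merged network
#' @return a `grn`
#' @export
merge_networks <- function(networks, label = "merged") {
  stopifnot(is.list(networks), all(vapply(networks, inherits, TRUE, "grn")))
  if (length(networks) == 0L) return(grn(label = label))
  ints <- do.call(rbind, lapply(networks, function(g) g$interactions))
  gens <- do.call(rbind, lapply(networks, function(g) g$genes))
  gens <- gens[!duplicated(tolower(gens$locus_tag)) |
                 !is.na(gens$replicon) | !is.na(gens$name), ]
  gens <- gens[!duplicated(tolower(gens$locus_tag)), ]
  grn(ints, genes = gens, label = label)
}

#' Keep only interactions with strong evidence
#'
#' Genes left with no interaction are dropped, mirroring how strong-evidence
#' filtrations of curated networks are reported.
#'
#' @param network a `grn`
#' @param label optional label for the filtered network
#' @return a `grn`
#' @export
filter_strong <- function(network, label = NULL) {
  stopifnot(inherits(network, "grn"))
  keep <- network$interactions$evidence == "strong"
  lab <- if (is.null(label)) paste0(network$label, "(strong)") else label
  grn(network$interactions[keep, , drop = FALSE], genes = network$genes, label = lab)
}

#' Restrict a network to genes of one replicon
#'
#' Drops genes (and their incident interactions) not annotated on the named
#' replicon, e.g. to exclude plasmid genes when expression data come from a
#' plasmid-free strain.
#'
#' @param network a `grn` whose genes carry replicon annotation
#' @param replicon replicon name (non-empty string)
#' @return a `grn`
#' @export
restrict_to_replicon <- function(network, replicon) {
  stopifnot(inherits(network, "grn"))
  if (!is.character(replicon) || length(replicon) != 1L || !nzchar(replicon))
    stop("replicon must be a non-empty string")
  missing <- network$genes$locus_tag[is.na(network$genes$replicon)]
  if (length(missing))
    stop("genes without replicon annotation: ", paste(utils::head(missing, 10), collapse = ", "))
  keep_genes <- network$genes$locus_tag[network$genes$replicon == replicon]
  low <- tolower(keep_genes)
  ints <- network$interactions
  keep <- tolower(ints$regulator) %in% low & tolower(ints$target) %in% low
  grn(ints[keep, , drop = FALSE], genes = network$genes, label = network$label)
}

#' Summary counts of a network
#'
#' @param network a `grn`
#' @return list with `label`, `genes`, `interactions`, `regulators` (genes
#'   with out-degree > 0), `strong` and `strong_fraction` (in `[0, 1]`; `NA`
#'   for an empty network)
#' @export
network_summary <- function(network) {
  stopifnot(inherits(network, "grn"))
  n_int <- nrow(network$interactions)
  list(
    label = network$label,
    genes = nrow(network$genes),
    interactions = n_int,
    regulators = length(grn_regulators(network)),
    strong = sum(network$interactions$evidence == "strong"),
    strong_fraction = if (n_int > 0) sum(network$interactions$evidence == "strong") / n_int else NA_real_
  )
}

#' Convert a network to an igraph graph
#'
#' @param network a `grn`
#' @param directed logical
#' @return an igraph graph whose vertices are locus tags; edge attributes
#'   `effect` and `evidence` are carried over
#' @export
grn_to_igraph <- function(network, directed = TRUE) {
  stopifnot(inherits(network, "grn"))
  g <- igraph::graph_from_data_frame(
    data.frame(
      from = network$interactions$regulator,
      to = network$interactions$target,
      effect = network$interactions$effect,
      evidence = network$interactions$evidence,
      stringsAsFactors = FALSE
    ),
    directed = directed,
    vertices = data.frame(name = network$genes$locus_tag, stringsAsFactors = FALSE)
  )
  g
}

# ---------------------------------------------------------------------------
# file formats

#' Read an interaction TSV
#'
#' Columns `regulator target effect evidence experiments sources`; a
#' `#`-prefixed header line is allowed; `experiments` and `sources` are
#' semicolon-delimited. Missing optional columns are tolerated. When a
#' `catalog` is given the evidence column is recomputed from the experiments.
#'
#' @param path file path
#' @param label network label (defaults to file name)
#' @param catalog optional evidence catalog; when supplied, evidence is
#'   derived from the experiments column via [classify_evidence()]
#' @return a `grn`
#' @export
read_interactions <- function(path, label = basename(path), catalog = NULL) {
  first <- readLines(path, n = 1L)
  header_in_file <- startsWith(first, "#")
  cols <- c("regulator", "target", "effect", "evidence", "experiments", "sources")
  if (header_in_file) {
    hdr <- strsplit(sub("^#\\s*", "", first), "\t", fixed = TRUE)[[1]]
    tab <- utils::read.delim(path, header = FALSE, skip = 1L, sep = "\t",
                             quote = "", comment.char = "", stringsAsFactors = FALSE,
                             col.names = hdr, check.names = FALSE)
  } else {
    tab <- utils::read.delim(path, header = FALSE, sep = "\t", quote = "",
                             comment.char = "", stringsAsFactors = FALSE)
    names(tab) <- cols[seq_len(ncol(tab))]
  }
  if (!all(c("regulator", "target") %in% names(tab)))
    stop("interaction file must have regulator and target columns: ", path)
  if (!is.null(catalog)) {
    exps <- .as_setcol(tab[["experiments"]], nrow(tab))
    tab$evidence <- vapply(exps, classify_evidence, character(1), catalog = catalog)
  }
  grn(tab, label = label)
}

#' Write an interaction TSV
#'
#' @param network a `grn`
#' @param path file path
#' @return `path`, invisibly
#' @export
write_interactions <- function(network, path) {
  stopifnot(inherits(network, "grn"))
  ints <- network$interactions
  out <- data.frame(
    regulator = ints$regulator, target = ints$target,
    effect = ints$effect, evidence = ints$evidence,
    experiments = vapply(ints$experiments, paste, character(1), collapse = ";"),
    sources = vapply(ints$sources, paste, character(1), collapse = ";"),
    stringsAsFactors = FALSE
  )
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("#regulator\ttarget\teffect\tevidence\texperiments\tsources", con)
  if (nrow(out)) {
    utils::write.table(out, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a gene coordinate table
#'
#' TSV columns `locus_tag replicon start end strand` with 1-based inclusive
#' coordinates and strand `+`/`-`. A `#`-prefixed header is allowed.
#'
#' @param path file path
#' @return tibble with those columns, `start`/`end` integer
#' @export
read_gene_table <- function(path) {
  first <- readLines(path, n = 1L)
  skip <- if (startsWith(first, "#")) 1L else 0L
  tab <- utils::read.delim(path, header = FALSE, skip = skip, sep = "\t",
                           quote = "", comment.char = "", stringsAsFactors = FALSE)
  names(tab) <- c("locus_tag", "replicon", "start", "end", "strand")[seq_len(ncol(tab))]
  tab$start <- as.integer(tab$start)
  tab$end <- as.integer(tab$end)
  if (any(!tab$strand %in% c("+", "-")))
    stop("strand must be '+' or '-' in ", path)
  as_tibble(tab)
}

#' Write a gene coordinate table
#' @param genes data frame with columns `locus_tag replicon start end strand`
#' @param path file path
#' @return `path`, invisibly
#' @export
write_gene_table <- function(genes, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("#locus_tag\treplicon\tstart\tend\tstrand", con)
  utils::write.table(genes[, c("locus_tag", "replicon", "start", "end", "strand")],
                     con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
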