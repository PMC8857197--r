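#' Identify global regulators
#'
#' Global regulators are the highly connected transcription factors whose
#' removal fragments the network into modules. Three strategies are offered:
#' \describe{
#'   \item{`elbow`}{(default) rank regulators by out-degree (descending) and
#'     cut at the point of maximum perpendicular distance between the
#'     rank-connectivity curve and the chord joining its endpoints.}
#'   \item{`fixed_set`}{inject a user-provided list (e.g. a published
#'     global-regulator set) after validating membership.}
#'   \item{`threshold`}{all regulators with out-degree >= `value`.}
#' }
#'
#' @param network a `grn`
#' @param strategy one of `"elbow"`, `"fixed_set"`, `"threshold"`
#' @param fixed character vector of locus tags (for `fixed_set`)
#' @param value numeric out-degree cutoff (for `threshold`)
#' @return character vector of locus tags ordered by decreasing out-degree
#' @export
identify_global_regulators <- function(network,
                                       strategy = c("elbow", "fixed_set", "threshold"),
                                       fixed = NULL, value = NULL) {
  stopifnot(inherits(network, "grn"))
  if (nrow(network$genes) == 0L) stop("network is empty")
  strategy <- match.arg(strategy)
  outdeg <- table(network$interactions$regulator)
  if (length(outdeg) == 0L) {
    warning("network has no regulators; returning empty set")
    return(character())
  }
  regs <- names(outdeg)[order(-as.integer(outdeg), tolower(names(outdeg)), method = "radix")]
  degs <- as.integer(outdeg[regs])
  switch(strategy,
    fixed_set = {
      if (is.null(fixed)) stop("fixed_set strategy requires `fixed`")
      miss <- setdiff(tolower(fixed), tolower(regs))
      if (length(miss))
        stop("fixed set members are not regulators: ", paste(miss, collapse = ", "))
      regs[tolower(regs) %in% tolower(fixed)]
    },
    threshold = {
      if (is.null(value)) stop("threshold strategy requires `value`")
      regs[degs >= value]
    },
    elbow = {
      k <- .elbow_cut(degs)
      regs[seq_len(k)]
    }
  )
}

# maximum perpendicular distance between the rank-connectivity curve and its
# chord; the elbow point itself belongs to the tail, so the cut keeps the
# points strictly before it (at least one)
.elbow_cut <- function(degs) {
  n <- length(degs)
  if (n == 1L) return(1L)
  x <- seq_len(n); y <- degs
  x1 <- x[1]; y1 <- y[1]; x2 <- x[n]; y2 <- y[n]
  denom <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
  d <- abs((y2 - y1) * x - (x2 - x1) * y + x2 * y1 - y2 * x1) / denom
  max(1L, which.max(d) - 1L)
}

#' Natural decomposition of a regulatory network
#'
#' Partitions every gene of the network into exactly one of four system-level
#' classes, given a set of global regulators (GRs):
#' \enumerate{
#'   \item GRs and their incident edges are removed; self-loops in the
#'     residual graph are discarded (self-regulation alone creates no module
#'     structure).
#'   \item Genes isolated in the residual graph — regulated only by GRs, or
#'     not regulated at all — form the basal machinery.
#'   \item The module skeleton is the residual subgraph induced on residual
#'     regulators (out-degree > 0); its weakly connected components seed the
#'     modules.
#'   \item Every non-regulator gene attaches to the components of its direct
#'     regulators: genes whose regulators span two or more components are
#'     intermodular (they integrate the response of several modules at their
#'     promoter and belong to no module); genes regulated from a single
#'     component join that module.
#'   \item Submodules: within each module, genes that directly regulate an
#'     intermodular gene are bridge regulators; if removing them splits the
#'     module's residual subgraph into two or more weak components, the parts
#'     are recorded as the module's submodules.
#' }
#'
#' @param network a `grn`
#' @param gr_set character vector of global-regulator locus tags; must be a
#'   subset of the network's regulators
#' @return object of class `nda_result`: list with `class_of` (named
#'   character: `global_regulator`, `modular`, `intermodular`,
#'   `basal_machinery`), `modules` (named list of gene-set character
#'   vectors), `submodules` (named list: module id -> list of gene sets, only
#'   for modules that split), and `gr_set`
#' @export
nda_classify <- function(network, gr_set = character()) {
  stopifnot(inherits(network, "grn"))
  genes <- grn_genes(network)
  if (length(genes) == 0L) stop("network is empty")
  regs <- grn_regulators(network)
  gr_set <- as.character(gr_set)
  bad <- setdiff(tolower(gr_set), tolower(regs))
  if (length(bad)) stop("gr_set members are not regulators: ", paste(bad, collapse = ", "))
  gr_set <- regs[match(tolower(gr_set), tolower(regs))]

  ints <- network$interactions
  low_gr <- tolower(gr_set)
  resid <- ints[!(tolower(ints$regulator) %in% low_gr) &
                  !(tolower(ints$target) %in% low_gr), , drop = FALSE]
  resid <- resid[tolower(resid$regulator) != tolower(resid$target), , drop = FALSE]

  class_of <- setNames(rep("basal_machinery", length(genes)), genes)
  class_of[gr_set] <- "global_regulator"

  modules <- list()
  submodules <- list()

  if (nrow(resid) > 0L) {
    r_regs <- unique(resid$regulator)
    # skeleton: residual edges among residual regulators
    skel <- resid[resid$target %in% r_regs, , drop = FALSE]
    g_skel <- igraph::graph_from_data_frame(
      data.frame(from = skel$regulator, to = skel$target, stringsAsFactors = FALSE),
      directed = TRUE,
      vertices = data.frame(name = r_regs, stringsAsFactors = FALSE)
    )
    comp <- igraph::components(g_skel, mode = "weak")$membership
    comp_of <- setNames(as.integer(comp), names(comp))

    class_of[r_regs] <- "modular"
    member_comp <- comp_of[r_regs]

    pure_targets <- setdiff(unique(resid$target), r_regs)
    inter <- character()
    if (length(pure_targets)) {
      reg_comps <- split(comp_of[resid$regulator], resid$target)[pure_targets]
      n_comp <- vapply(reg_comps, function(v) length(unique(v)), integer(1))
      inter <- pure_targets[n_comp >= 2L]
      mod_targets <- pure_targets[n_comp == 1L]
      class_of[inter] <- "intermodular"
      class_of[mod_targets] <- "modular"
      member_comp <- c(member_comp, vapply(reg_comps[mod_targets],
                                           function(v) unique(v)[1], integer(1)))
    }

    comp_ids <- sort(unique(member_comp))
    modules <- lapply(comp_ids, function(ci) sort(names(member_comp)[member_comp == ci]))
    names(modules) <- sprintf("M%02d", seq_along(modules))

    if (length(inter)) {
      bridge_regs <- unique(resid$regulator[resid$target %in% inter])
      for (mid in names(modules)) {
        mem <- modules[[mid]]
        keep <- setdiff(mem, bridge_regs)
        if (length(keep) == 0L || length(keep) == length(mem)) next
        sub_edges <- resid[resid$regulator %in% keep & resid$target %in% keep, , drop = FALSE]
        g_sub <- igraph::graph_from_data_frame(
          data.frame(from = sub_edges$regulator, to = sub_edges$target,
                     stringsAsFactors = FALSE),
          directed = TRUE,
          vertices = data.frame(name = keep, stringsAsFactors = FALSE)
        )
        sc <- igraph::components(g_sub, mode = "weak")$membership
        if (max(sc) >= 2L) {
          parts <- split(names(sc), sc)
          submodules[[mid]] <- unname(lapply(parts, sort))
        }
      }
    }
  }

  structure(
    list(class_of = class_of, modules = modules, submodules = submodules,
         gr_set = gr_set, label = network$label),
    class = "nda_result"
  )
}

#' @export
print.nda_result <- function(x, ...) {
  tab <- table(factor(x$class_of, levels = c("global_regulator", "modular",
                                             "intermodular", "basal_machinery")))
  cat(sprintf(
    "<nda_result> %s: %d GRs, %d modular (in %d modules), %d intermodular, %d basal\n",
    if (nzchar(x$label)) x$label else "(unlabelled)",
    tab[["global_regulator"]], tab[["modular"]], length(x$modules),
    tab[["intermodular"]], tab[["basal_machinery"]]
  ))
  invisible(x)
}

#' Per-class counts and percentages of a decomposition
#'
#' @param result an `nda_result`, or a named/ordered numeric vector of four
#'   counts (global regulators, modular, intermodular, basal machinery)
#' @param n_genes total gene count the percentages refer to; defaults to the
#'   sum of counts
#' @return data frame with columns `class`, `count`, `percent` (2 decimals)
#' @export
nda_summary <- function(result, n_genes = NULL) {
  lev <- c("global_regulator", "modular", "intermodular", "basal_machinery")
  if (inherits(result, "nda_result")) {
    counts <- as.integer(table(factor(result$class_of, levels = lev)))
  } else {
    counts <- as.integer(result)
    if (length(counts) != 4L) stop("expected four class counts")
  }
  if (is.null(n_genes)) n_genes <- sum(counts)
  if (n_genes <= 0L) stop("n_genes must be positive")
  if (sum(counts) != n_genes)
    stop("class counts (", sum(counts), ") do not partition n_genes (", n_genes, ")")
  data.frame(
    class = lev,
    count = counts,
    percent = round(100 * counts / n_genes, 2),
    stringsAsFactors = FALSE
  )
}

#' Write an NDA gene-class table
#'
#' TSV `locus_tag class module_id submodule_id` (empty module fields for
#' genes outside modules).
#'
#' @param result an `nda_result`
#' @param path file path
#' @return `path`, invisibly
#' @export
write_nda_table <- function(result, path) {
  stopifnot(inherits(result, "nda_result"))
  tags <- names(result$class_of)
  mod_of <- setNames(rep("", length(tags)), tags)
  sub_of <- setNames(rep("", length(tags)), tags)
  for (mid in names(result$modules)) mod_of[result$modules[[mid]]] <- mid
  for (mid in names(result$submodules)) {
    parts <- result$submodules[[mid]]
    for (i in seq_along(parts)) sub_of[parts[[i]]] <- sprintf("%s.%d", mid, i)
  }
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("#locus_tag\tclass\tmodule_id\tsubmodule_id", con)
  utils::write.table(
    data.frame(tags, result$class_of[tags], mod_of[tags], sub_of[tags]),
    con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}
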