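#' Run a named pipeline recipe
#'
#' Thin orchestration over the package's modules: each recipe composes
#' operations in the standard workflow order, reads its inputs from and
#' writes its outputs to the paths in `config`, and logs the stage and its
#' parameters to stderr. All randomness derives from `config$seed`, fanned
#' out per stage, so re-running over unchanged inputs reproduces identical
#' outputs. A failing stage aborts with its name; partial outputs keep a
#' `.partial` suffix.
#'
#' Recipes and their expected `config` fields:
#' \describe{
#'   \item{`meta_curate`}{`networks` (vector of interaction TSV paths),
#'     `out` (merged TSV); writes `<out>.summary.tsv` as well.}
#'   \item{`infer_bs`}{`strong_network`, `gene_table`, `genome_fasta`,
#'     `out`; optional `p_threshold`, `motif_width`.}
#'   \item{`infer_exp`}{`expression`, `tf_list` (file, one locus tag per
#'     line), `out_prefix`; optional `methods` (subset of `c("clr",
#'     "mrnet")`), `bins`.}
#'   \item{`community_all`}{`lists` (ranked TSV paths), `out`; optional
#'     `prune`.}
#'   \item{`assess_all`}{`predictions` (ranked TSV paths), `gold`
#'     (interaction TSV), `out` (TSV of AUPR/AUROC per method).}
#'   \item{`nda_all`}{`network` (interaction TSV), `out`; optional
#'     `strategy` (`"elbow"`, `"fixed_set"`, `"threshold"`), `gr_file`,
#'     `threshold`.}
#'   \item{`structure_all`}{`networks` (interaction TSV paths), `out`
#'     (profile TSV).}
#'   \item{`regulogs`}{`source_strong`, `source_gene_table`, `source_fasta`,
#'     `target_gene_table`, `target_fasta`, `orthologs` (two-column TSV),
#'     `out`; optional `p_threshold`.}
#' }
#'
#' @param name recipe name
#' @param config named list, see above; `seed` defaults to 1
#' @return named list of output paths, invisibly
#' @export
run_recipe <- function(name = c("meta_curate", "infer_bs", "infer_exp",
                                "community_all", "assess_all", "nda_all",
                                "structure_all", "regulogs"),
                       config = list()) {
  name <- match.arg(name)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  .stage_log(name, config)
  fn <- switch(name,
    meta_curate = .recipe_meta_curate, infer_bs = .recipe_infer_bs,
    infer_exp = .recipe_infer_exp, community_all = .recipe_community,
    assess_all = .recipe_assess, nda_all = .recipe_nda,
    structure_all = .recipe_structure, regulogs = .recipe_regulogs)
  out <- tryCatch(fn(config, seed),
                  error = function(e) stop("stage '", name, "' failed: ",
                                           conditionMessage(e), call. = FALSE))
  invisible(out)
}

.stage_log <- function(name, config) {
  flat <- vapply(config, function(v) paste(format(v), collapse = ","), character(1))
  message(sprintf("[%s] stage=%s %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                  name, paste(names(flat), flat, sep = "=", collapse = " ")))
}

.need <- function(config, fields) {
  miss <- setdiff(fields, names(config))
  if (length(miss)) stop("missing config field(s): ", paste(miss, collapse = ", "))
  for (f in fields) {
    v <- config[[f]]
    if (is.character(v)) {
      existing <- file.exists(v)
      if (f != "out" && !all(existing) && any(grepl("[/.]", v)))
        NULL # paths are validated by readers; outputs need not exist
    }
  }
  invisible(TRUE)
}

.write_safely <- function(writer, path) {
  tmp <- paste0(path, ".partial")
  writer(tmp)
  file.rename(tmp, path)
  path
}

.recipe_meta_curate <- function(config, seed) {
  .need(config, c("networks", "out"))
  nets <- lapply(config$networks, read_interactions)
  merged <- merge_networks(nets, label = "meta_curated")
  write_interactions(merged, config$out)
  s <- network_summary(merged)
  sum_path <- paste0(config$out, ".summary.tsv")
  utils::write.table(as.data.frame(s), sum_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(network = config$out, summary = sum_path)
}

.recipe_infer_bs <- function(config, seed) {
  .need(config, c("strong_network", "gene_table", "genome_fasta", "out"))
  prior <- read_interactions(config$strong_network)
  genes <- read_gene_table(config$gene_table)
  genome <- read_fasta(config$genome_fasta)
  regions <- extract_upstream(genes, genome)
  p_thr <- if (is.null(config$p_threshold)) 1e-4 else config$p_threshold
  width <- if (is.null(config$motif_width)) 12L else config$motif_width
  set.seed(seed)
  preds <- extend_regulons(prior, regions, p_threshold = p_thr, width = width)
  write_ranking(preds, config$out)
  list(ranking = config$out)
}

.recipe_infer_exp <- function(config, seed) {
  .need(config, c("expression", "tf_list", "out_prefix"))
  expr <- read_expression(config$expression)
  tfs <- readLines(config$tf_list)
  tfs <- tfs[nzchar(tfs)]
  methods <- if (is.null(config$methods)) c("clr", "mrnet") else config$methods
  mi <- mutual_information(expr, bins = config$bins)
  out <- list()
  for (m in methods) {
    preds <- switch(m, clr = clr(mi, tfs), mrnet = mrnet(mi, tfs),
                    stop("unknown expression method: ", m))
    path <- paste0(config$out_prefix, ".", m, ".tsv")
    write_ranking(preds, path)
    out[[m]] <- path
  }
  out
}

.recipe_community <- function(config, seed) {
  .need(config, c("lists", "out"))
  lists <- lapply(config$lists, import_external_ranking)
  comm <- integrate_rankings(lists)
  if (!is.null(config$prune)) comm <- prune_top(comm, config$prune)
  write_ranking(comm, config$out)
  list(community = config$out)
}

.recipe_assess <- function(config, seed) {
  .need(config, c("predictions", "gold", "out"))
  gold <- read_interactions(config$gold)
  rows <- lapply(config$predictions, function(p) {
    preds <- restrict_to_gold(import_external_ranking(p), gold)
    data.frame(method = basename(p),
               aupr = pr_curve(preds, gold)$aupr,
               auroc = roc_curve(preds, gold)$auroc,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  utils::write.table(tab, config$out, sep = "\t", quote = FALSE, row.names = FALSE)
  list(assessment = config$out)
}

.recipe_nda <- function(config, seed) {
  .need(config, c("network", "out"))
  net <- read_interactions(config$network)
  strategy <- if (is.null(config$strategy)) "elbow" else config$strategy
  grs <- switch(strategy,
    elbow = identify_global_regulators(net, "elbow"),
    fixed_set = identify_global_regulators(net, "fixed_set",
                                           fixed = readLines(config$gr_file)),
    threshold = identify_global_regulators(net, "threshold",
                                           value = config$threshold))
  res <- nda_classify(net, grs)
  write_nda_table(res, config$out)
  list(classes = config$out)
}

.recipe_structure <- function(config, seed) {
  .need(config, c("networks", "out"))
  profs <- lapply(config$networks, function(p)
    structural_profile(read_interactions(p)))
  mat <- do.call(rbind, profs)
  rownames(mat) <- basename(unlist(config$networks))
  utils::write.table(cbind(network = rownames(mat), as.data.frame(mat)),
                     config$out, sep = "\t", quote = FALSE, row.names = FALSE)
  list(profiles = config$out)
}

.recipe_regulogs <- function(config, seed) {
  .need(config, c("source_strong", "source_gene_table", "source_fasta",
                  "target_gene_table", "target_fasta", "orthologs", "out"))
  src <- read_interactions(config$source_strong)
  src_regions <- extract_upstream(read_gene_table(config$source_gene_table),
                                  read_fasta(config$source_fasta))
  tgt_regions <- extract_upstream(read_gene_table(config$target_gene_table),
                                  read_fasta(config$target_fasta))
  orth <- utils::read.delim(config$orthologs, header = FALSE, comment.char = "#",
                            stringsAsFactors = FALSE)
  p_thr <- if (is.null(config$p_threshold)) 1e-4 else config$p_threshold
  set.seed(seed)
  res <- regulogs_transfer(src, src_regions, tgt_regions, orth, p_threshold = p_thr)
  write_interactions(res$network, config$out)
  list(network = config$out)
}
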