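make_toy_genome <- function() {
  # two + strand genes and one - strand gene with known spacing
  set.seed(123)
  chr <- paste(sample(c("A", "C", "G", "T"), 5000, replace = TRUE), collapse = "")
  genes <- tibble::tibble(
    locus_tag = c("up1", "mid", "minus"),
    replicon = "chr",
    start = c(500L, 1000L, 3000L),
    end = c(850L, 1600L, 3500L),
    strand = c("+", "+", "-"))
  list(chr = chr, genes = genes)
}

test_that("upstream extraction truncates at the neighbor and mirrors minus strand", {
  g <- make_toy_genome()
  regions <- extract_upstream(g$genes, c(chr = g$chr))
  mid <- regions[regions$gene == "mid", ]
  # candidate span [700, 1050] truncated at neighbor end 850 -> [851, 1050]
  expect_equal(mid$start, 851L)
  expect_equal(mid$end, 1050L)
  expect_equal(nchar(mid$sequence), 200L)
  expect_equal(mid$sequence, toupper(substr(g$chr, 851, 1050)))
  # no upstream neighbor within 300 bp: full 351-length window
  minus <- regions[regions$gene == "minus", ]
  expect_equal(nchar(minus$sequence), 351L)
  # minus-strand sequence is the reverse complement of [end-50, end+300]
  want <- substr(g$chr, 3500 - 50, 3500 + 300)
  want_rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(want)))
  expect_equal(minus$sequence, want_rc)
  # unknown strand errors
  bad <- g$genes; bad$strand[1] <- "?"
  expect_error(extract_upstream(bad, c(chr = g$chr)), "strand")
  # window clipped at the replicon start rather than erroring
  early <- tibble::tibble(locus_tag = "e", replicon = "chr", start = 100L,
                          end = 400L, strand = "+")
  r <- extract_upstream(early, c(chr = g$chr))
  expect_equal(r$start, 1L)
})

test_that("PWM construction normalizes columns and enforces the 3-site rule", {
  pwm <- build_pwm("tf", c("ACGT", "ACGT", "ACGT", "ACGT"))
  expect_equal(colSums(pwm$matrix), rep(1, 4), tolerance = 1e-9)
  expect_gt(pwm$matrix["A", 1], 0.9)
  expect_equal(pwm$source_sites, 4L)
  expect_error(build_pwm("tf", c("ACGT", "ACGT")), "at least 3")
  expect_error(build_pwm("tf", c("ACGT", "ACG", "ACGT")), "unequal")
})

test_that("exact p-values equal exhaustive word enumeration for widths up to 8", {
  # skewed and uniform backgrounds, soft and one-hot matrices
  cases <- list(
    list(sites = c("ACGTA", "ACGTA", "ACGAA", "TCGTA"), bg = rep(0.25, 4), pc = 0.5),
    list(sites = c("ACGTA", "ACGTA", "ACGAA", "TCGTA"),
         bg = c(0.15, 0.35, 0.35, 0.15), pc = 0.5),
    list(sites = rep("ACG", 3), bg = c(0.4, 0.1, 0.1, 0.4), pc = 0.1),
    list(sites = rep("ACGT", 4), bg = rep(0.25, 4), pc = 0)
  )
  words <- c("ACGTA", "TTTTT", "ACG", "GGG", "ACGT", "TTTT", "AAAAA", "CCG")
  for (cs in cases) {
    pwm <- build_pwm("tf", cs$sites, background = cs$bg, pseudocount = cs$pc)
    model <- grnforge:::.pwm_score_model(pwm)
    for (w in words[nchar(words) == pwm$width]) {
      region <- tibble::tibble(gene = "g", sequence = w)
      hit <- grnforge:::.scan_sequence(model, pwm, w)
      expect_equal(hit$p_value, enumerate_pvalue(pwm, w), tolerance = 1e-12)
    }
  }
  # width-8 one-hot: exact match passes the threshold at p = 4^-8
  pwm8 <- build_pwm("tf", rep("ACGTACGT", 4), pseudocount = 0)
  hits <- scan_regions(pwm8, tibble::tibble(gene = "g",
                                            sequence = "GGACGTACGTGG"))
  expect_equal(hits$p_value, 4^-8, tolerance = 1e-15)
  expect_equal(enumerate_pvalue(pwm8, "ACGTACGT"), 4^-8, tolerance = 1e-15)
  # width-4 one-hot: the best attainable p-value cannot pass 1e-4
  pwm4 <- build_pwm("tf", rep("ACGT", 4), pseudocount = 0)
  expect_equal(nrow(scan_regions(pwm4, tibble::tibble(gene = "g",
                                                      sequence = "AAACGTAAA"))), 0L)
  # p-value at the minimum attainable score is 1
  pwmu <- build_pwm("tf", c("AAAA", "CCCC", "GGGG", "TTTT"), pseudocount = 4)
  m <- grnforge:::.pwm_score_model(pwmu)
  worst <- grnforge:::.scan_sequence(m, pwmu, "ACGT")
  expect_equal(worst$p_value, 1)
})

test_that("scanning is strand-symmetric and skips short regions", {
  pwm <- build_pwm("tf", c("ACGTACGTACGT", "ACGTACGTACGT", "ACGTACGAACGT"),
                   pseudocount = 0.2)
  set.seed(9)
  seqs <- vapply(1:6, function(i)
    paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = ""), character(1))
  seqs[3] <- paste0(substr(seqs[3], 1, 20), "ACGTACGTACGT", substr(seqs[3], 33, 60))
  regions <- tibble::tibble(gene = paste0("g", 1:6), sequence = seqs)
  rc <- vapply(seqs, function(s)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s))), character(1))
  regions_rc <- tibble::tibble(gene = paste0("g", 1:6), sequence = rc)
  h1 <- scan_regions(pwm, regions, p_threshold = 0.5)
  h2 <- scan_regions(pwm, regions_rc, p_threshold = 0.5)
  expect_equal(h1$gene, h2$gene)
  expect_equal(h1$p_value, h2$p_value, tolerance = 1e-12)
  expect_setequal(paste(h1$gene, h1$score), paste(h2$gene, h2$score))
  # short region skipped silently
  short <- tibble::tibble(gene = "s", sequence = "ACGT")
  expect_equal(nrow(scan_regions(pwm, short, p_threshold = 0.999)), 0L)
})

test_that("regulon extension requires 3 prior targets and never invents regulators", {
  cfg <- synth_config(n_genes = 25, n_tfs = 2, seed = 31, strong_fraction = 1)
  net <- sample_grn(cfg)
  pg <- plant_genome(net, cfg)
  regions <- extract_upstream(pg$gene_table, pg$genome)
  preds <- suppressMessages(extend_regulons(net, regions))
  expect_true(all(preds$regulator %in% grn_regulators(net)))
  expect_true(all(preds$p_value < 1e-4))
  expect_true(all(diff(preds$score) <= 0))
  # a TF with only 2 prior targets is skipped
  small_prior <- grn(data.frame(regulator = "SGX", target = c("SG0003", "SG0004"),
                                evidence = "strong"))
  expect_message(out <- extend_regulons(small_prior, regions), "fewer than 3")
  expect_equal(nrow(out), 0L)
  # empty prior gives empty output
  expect_equal(nrow(suppressMessages(extend_regulons(grn(), regions))), 0L)
})

test_that("planted regulons are recovered from the synthetic genome", {
  cfg <- synth_config(n_genes = 30, n_tfs = 2, seed = 11, strong_fraction = 1)
  net <- sample_grn(cfg)
  pg <- plant_genome(net, cfg)
  regions <- extract_upstream(pg$gene_table, pg$genome)
  preds <- suppressMessages(extend_regulons(net, regions))
  truth <- edge_keys(net)
  tp <- sum(pred_keys(preds) %in% truth)
  expect_gte(tp / length(truth), 0.8) # recall on one seed
  expect_gte(tp / nrow(preds), 0.8) # precision on one seed
})

test_that("ChIP validation keeps exactly the motif-supported intersection", {
  weak_chip <- grn(data.frame(
    regulator = c("t1", "t1", "t2"), target = c("a", "b", "c"),
    evidence = "weak", experiments = "ChIP-seq"))
  hits <- tibble::tibble(tf = c("t1", "t2", "t3"), gene = c("a", "c", "z"))
  val <- chip_validate(weak_chip, hits)
  expect_equal(nrow(val), 2L)
  expect_true(all(val$evidence == "strong"))
  expect_setequal(paste(val$regulator, val$target), c("t1 a", "t2 c"))
  none <- chip_validate(weak_chip, tibble::tibble(tf = "x", gene = "y"))
  expect_equal(nrow(none), 0L)
})

test_that("MEME minimal format round-trips PWMs", {
  p1 <- build_pwm("tfA", c("ACGTAC", "ACGTAC", "ACCTAC"))
  p2 <- build_pwm("tfB", c("GGGTT", "GGGTT", "GGGTA", "GGCTT"))
  path <- withr::local_tempfile(fileext = ".meme")
  write_meme(list(p1, p2), path)
  back <- read_meme(path)
  expect_setequal(names(back), c("tfA", "tfB"))
  expect_equal(back$tfA$matrix, p1$matrix, tolerance = 1e-5)
  expect_equal(back$tfB$width, 5L)
  expect_equal(back$tfA$source_sites, 3L)
})

test_that("regulog transfer maps predictions through strict 1:1 orthologs", {
  cfg <- synth_config(n_genes = 25, n_tfs = 2, seed = 17, strong_fraction = 1,
                      ortholog_retention_fraction = 0.8)
  netA <- sample_grn(cfg)
  pgA <- plant_genome(netA, cfg)
  regionsA <- extract_upstream(pgA$gene_table, pgA$genome)
  # organism B: identical genome under relabelled genes
  pair <- make_ortholog_pair(netA, cfg)
  # build B's genome by relabelling A's gene table to B names (same sequence)
  surv <- pair$orthologs
  gtB <- pgA$gene_table[pgA$gene_table$locus_tag %in% surv$a, ]
  gtB$locus_tag <- surv$b[match(gtB$locus_tag, surv$a)]
  regionsB <- extract_upstream(gtB, pgA$genome)
  res <- regulogs_transfer(netA, regionsA, regionsB, surv)
  # every transfer involves orthologous endpoints
  expect_true(all(res$predictions$regulator %in% surv$b))
  expect_true(all(res$predictions$target %in% surv$b))
  # non-1:1 maps are rejected with offenders named
  badmap <- rbind(surv, surv[1, ])
  expect_error(regulogs_transfer(netA, regionsA, regionsB, badmap), "one-to-one")
  # a map without the TF transfers nothing for it
  tf <- grn_regulators(netA)[1]
  nomap <- surv[surv$a != tf, ]
  res2 <- regulogs_transfer(netA, regionsA, regionsB, nomap)
  expect_false(any(res2$predictions$source_tf == tf))
})

test_that("self-transfer with the identity map recovers detectable prior regulons", {
  cfg <- synth_config(n_genes = 20, n_tfs = 1, seed = 13, strong_fraction = 1)
  net <- sample_grn(cfg)
  pg <- plant_genome(net, cfg)
  regions <- extract_upstream(pg$gene_table, pg$genome)
  idmap <- data.frame(a = grn_genes(net), b = grn_genes(net))
  res <- regulogs_transfer(net, regions, regions, idmap)
  direct <- suppressMessages(extend_regulons(net, regions))
  expect_true(all(pred_keys(direct) %in%
                    paste(res$predictions$regulator, res$predictions$target, sep = ">")))
})

test_that("GRN-wide orthologs are the pairs present in both networks", {
  netA <- toy_grn(c("a1>a2", "a2>a3"))
  netB <- toy_grn(c("b1>b2"))
  orth <- data.frame(a = c("a1", "a2", "a3"), b = c("b1", "b2", "b9"))
  got <- grn_wide_orthologs(netA, netB, orth)
  expect_equal(nrow(got), 2L) # a3>b9 fails because b9 is not in netB
  # identity map over identical networks returns all genes
  idm <- data.frame(a = grn_genes(netA), b = grn_genes(netA))
  expect_equal(nrow(grn_wide_orthologs(netA, netA, idm)), 3L)
  expect_equal(nrow(grn_wide_orthologs(netA, netB, orth[0, ])), 0L)
})
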