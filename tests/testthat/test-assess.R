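test_that("ranked predictions sort deterministically and reject duplicates", {
  p <- ranked_predictions(data.frame(
    regulator = c("b", "a", "a"), target = c("x", "y", "x"),
    score = c(2, 3, 2)))
  expect_equal(p$regulator, c("a", "a", "b")) # 3 first, then ties lexicographic
  expect_true(all(diff(p$score) <= 0))
  expect_error(ranked_predictions(data.frame(
    regulator = c("a", "A"), target = c("x", "x"), score = 1:2)), "duplicate")
})

test_that("gold restriction drops entries with endpoints outside the gold gene set", {
  gold <- toy_grn(c("t1>g1", "t1>g2"))
  preds <- ranked_predictions(data.frame(
    regulator = c("t1", "t1", "X"), target = c("g1", "q", "g2"),
    score = c(3, 2, 1)))
  r <- restrict_to_gold(preds, gold)
  expect_equal(pred_keys(r), "t1>g1")
  expect_equal(nrow(restrict_to_gold(preds, grn())), 0L)
  allin <- ranked_predictions(data.frame(regulator = "t1", target = "g2", score = 1))
  expect_equal(nrow(restrict_to_gold(allin, gold)), 1L)
})

test_that("AUPR is 1 for a perfect ranking and matches the step-function oracle", {
  gold <- toy_grn(c("t>g1", "t>g2"))
  perfect <- ranked_predictions(data.frame(
    regulator = "t", target = c("g1", "g2", "g3"), score = c(3, 2, 1)))
  expect_equal(pr_curve(perfect, gold)$aupr, 1.0)
  # FP first
  worst_first <- ranked_predictions(data.frame(
    regulator = "t", target = c("g3", "g1", "g2"), score = c(3, 2, 1)))
  got <- pr_curve(worst_first, gold)$aupr
  expect_equal(got, oracle_aupr(c(FALSE, TRUE, TRUE), 2))
  # all scores equal: single PR point at full recall
  tied <- ranked_predictions(data.frame(
    regulator = "t", target = c("g1", "g2", "g3"), score = c(1, 1, 1)))
  expect_equal(pr_curve(tied, gold)$aupr, 2 / 3)
  expect_equal(nrow(pr_curve(tied, gold)$curve), 1L)
  expect_error(pr_curve(perfect, grn()), "no positive")
})

test_that("AUPR and AUROC match brute-force oracles on all small instances", {
  # every non-empty gold subset of a 2-regulator x 2-target pool, with the
  # full universe (including self-pairs) ranked in several seeded orders and
  # as truncated partial rankings
  pool <- expand.grid(regulator = c("t1", "t2"), target = c("g1", "g2"),
                      stringsAsFactors = FALSE)
  for (bits in 1:15) {
    sel <- as.logical(bitwAnd(bits, c(1L, 2L, 4L, 8L)))
    gold <- grn(pool[sel, ])
    regs <- grn_regulators(gold)
    genes <- grn_genes(gold)
    univ <- expand.grid(regulator = regs, target = genes,
                        stringsAsFactors = FALSE)
    if (nrow(univ) <= sum(sel)) next # no negatives: roc_curve must refuse
    gk <- edge_keys(gold)
    for (ord_seed in 1:4) {
      set.seed(ord_seed)
      ord <- sample(nrow(univ))
      for (keep in c(nrow(univ), max(1, nrow(univ) - 2))) {
        sub <- univ[ord[seq_len(keep)], ]
        preds <- ranked_predictions(data.frame(
          sub, score = seq(nrow(sub), 1)))
        lab <- paste(preds$regulator, preds$target, sep = ">") %in% gk
        expect_equal(pr_curve(preds, gold)$aupr,
                     oracle_aupr(lab, length(gk)), tolerance = 1e-12)
        expect_equal(roc_curve(preds, gold)$auroc,
                     oracle_auroc(preds, gold), tolerance = 1e-12)
      }
    }
  }
  # a universe with zero negatives is an error
  full <- grn(data.frame(regulator = "t", target = "t"))
  p <- ranked_predictions(data.frame(regulator = "t", target = "t", score = 1))
  expect_error(roc_curve(p, full), "negatives")
})

test_that("AUROC is 1 for perfect, 0.5 for all-tied, and tie blocks are shared points", {
  gold <- toy_grn(c("t>g1", "t>g2"))
  perfect <- ranked_predictions(data.frame(
    regulator = "t", target = c("g1", "g2", "g3"), score = c(3, 2, 1)))
  expect_equal(roc_curve(perfect, gold)$auroc, 1.0)
  tied <- ranked_predictions(data.frame(
    regulator = "t", target = c("g1", "g2", "g3"), score = c(1, 1, 1)))
  expect_equal(roc_curve(tied, gold)$auroc, 0.5)
  # universe counts TF -> gene ordered pairs including self-pairs
  expect_equal(roc_curve(perfect, gold)$universe, 1 * 3)
  # unranked pairs as a trailing tie block, cross-checked with the oracle
  partial <- ranked_predictions(data.frame(regulator = "t", target = "g1", score = 1))
  expect_equal(roc_curve(partial, gold)$auroc, oracle_auroc(partial, gold))
})

test_that("AUPR and AUROC are invariant under monotone score transformations", {
  gold <- toy_grn(c("t>g1", "t>g2", "t>g4"))
  base <- ranked_predictions(data.frame(
    regulator = "t", target = paste0("g", 1:5), score = c(9, 5, 4, 2, 1)))
  warped <- ranked_predictions(data.frame(
    regulator = "t", target = paste0("g", 1:5),
    score = exp(c(9, 5, 4, 2, 1) / 3)))
  expect_equal(pr_curve(base, gold)$aupr, pr_curve(warped, gold)$aupr)
  expect_equal(roc_curve(base, gold)$auroc, roc_curve(warped, gold)$auroc)
})

test_that("GR prediction scores follow the 2x2-table formulas", {
  u <- paste0("g", 1:20)
  s <- gr_prediction_scores(u[1:5], u[1:5], u)
  expect_equal(s$mcc, 1)
  expect_equal(s$f1, 1)
  # disjoint non-empty sets give negative MCC
  s2 <- gr_prediction_scores(u[1:5], u[6:10], u)
  expect_lt(s2$mcc, 0)
  expect_equal(s2$f1, 0)
  # balanced table TP=FP=FN=TN=1
  s3 <- gr_prediction_scores(c("a", "b"), c("a", "c"), c("a", "b", "c", "d"))
  expect_equal(s3$counts, c(TP = 1L, FP = 1L, FN = 1L, TN = 1L))
  expect_equal(s3$mcc, 0)
  # symmetry under swapping predicted and gold
  s4 <- gr_prediction_scores(u[1:4], u[3:8], u)
  s5 <- gr_prediction_scores(u[3:8], u[1:4], u)
  expect_equal(s4$mcc, s5$mcc)
  expect_error(gr_prediction_scores("a", "a", character()), "empty universe")
})

test_that("Simpson index is overlap over the smaller set", {
  expect_equal(simpson_index(c("a", "b", "c"), c("a", "b", "c")), 1)
  expect_equal(simpson_index(c("a", "b"), c("c", "d")), 0)
  expect_equal(simpson_index(c("a", "b"), c("b", "c", "d")), 0.5)
  # subset relation scores 1, and the index is symmetric
  expect_equal(simpson_index(c("a", "b"), c("a", "b", "c", "d")), 1)
  for (seed in 1:5) {
    set.seed(seed)
    a <- sample(letters, 8); b <- sample(letters, 12)
    expect_equal(simpson_index(a, b), simpson_index(b, a))
  }
  expect_error(simpson_index(character(), character()), "undefined")
})
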