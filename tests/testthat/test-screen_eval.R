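# Screen validation statistics: dropout hit calling, essentiality
# ranking, preranked enrichment, overlap tests, pathway enrichment.


test_that("call_dropout_hits reproduces the hand-enumerated hit set", {
  sc <- toy_screen()
  hits <- call_dropout_hits(sc, "baseline", "treated")
  expect_identical(hits, c("HIT1", "HIT2"))
})

test_that("hit calling is invariant to construct order and sub-floor constructs", {
  sc <- toy_screen()
  set.seed(8)
  perm <- sc[sample.int(nrow(sc)), ]
  expect_identical(call_dropout_hits(perm, "baseline", "treated"),
                   call_dropout_hits(sc, "baseline", "treated"))
  # constructs below the read floor never contribute
  extra <- sc[1, ]; extra$gene <- "NULL1"; extra$baseline <- 50; extra$treated <- 1
  extra$construct_id <- "sh99"
  expect_identical(call_dropout_hits(rbind(sc, extra), "baseline", "treated"),
                   call_dropout_hits(sc, "baseline", "treated"))
})

test_that("each hit-calling gate can be relaxed independently", {
  sc <- toy_screen()
  # disabling the mean-ratio gate admits WEAK
  expect_true("WEAK" %in% call_dropout_hits(sc, "baseline", "treated",
                                            mean_ratio = Inf))
  # lowering the construct floor admits FEW
  expect_true("FEW" %in% call_dropout_hits(sc, "baseline", "treated",
                                           min_constructs = 2))
})

test_that("score_mutation_essentiality picks the best construct and signs correctly", {
  lines <- c(paste0("M", 1:4), paste0("W", 1:4))
  sc <- data.frame(construct_id = sprintf("sh%02d", 1:9),
                   gene = rep(c("ESS", "NULL1", "TWO"), each = 3),
                   stringsAsFactors = FALSE)
  set.seed(12)
  m <- matrix(rnorm(9 * 8, 0, 0.2), 9, 8, dimnames = list(NULL, lines))
  m[1:3, 1:4] <- m[1:3, 1:4] - 1         # ESS depleted in mutant lines
  sc <- cbind(sc, m)
  sc <- sc[sc$gene != "TWO" | seq_len(nrow(sc)) %in% c(7, 8), ]  # TWO: 2 constructs
  class(sc) <- c("screen_table", "data.frame")
  rk <- score_mutation_essentiality(sc, paste0("M", 1:4), paste0("W", 1:4))
  expect_false("TWO" %in% rk$gene)                 # construct floor
  expect_equal(rk$gene[1], "ESS")
  expect_gt(rk$score[1], 0)                        # more essential => positive
  expect_lt(abs(rk$score[rk$gene == "NULL1"]), abs(rk$score[1]))

  # oracle: per-construct Welch t-test, min p, signed -log10 weight
  ps <- sapply(1:3, function(i)
    t.test(m[i, 1:4], m[i, 5:8])$p.value)
  best <- which.min(ps)
  want <- -log10(ps[best]) * (mean(m[best, 5:8]) - mean(m[best, 1:4]))
  expect_equal(rk$score[rk$gene == "ESS"], want, tolerance = 1e-10)

  # perturbation: depleting mutant scores further strictly improves the rank
  sc2 <- sc
  null_rows <- sc2$gene == "NULL1"
  sc2[null_rows, paste0("M", 1:4)] <- sc2[null_rows, paste0("M", 1:4)] - 3
  rk2 <- score_mutation_essentiality(sc2, paste0("M", 1:4), paste0("W", 1:4))
  expect_lt(which(rk2$gene == "NULL1"), which(rk$gene == "NULL1") + 1)
  expect_equal(rk2$gene[1], "NULL1")
})

test_that("preranked ES equals the explicit running-sum oracle", {
  set.seed(14)
  for (i in 1:15) {
    N <- sample(50:200, 1)
    scores <- sort(rnorm(N, 0, 2), decreasing = TRUE)
    rk <- data.frame(gene = sprintf("G%03d", 1:N), score = scores)
    hit_genes <- sample(rk$gene, sample(25:40, 1))
    res <- preranked_enrichment(rk, hit_genes, n_permutations = 50, seed = i)
    want <- gsea_es_oracle(scores, rk$gene %in% hit_genes)
    expect_equal(res$es, want, tolerance = 1e-12)
  }
})

test_that("preranked ES agrees with the independent fgsea implementation", {
  set.seed(16)
  for (i in 1:5) {
    N <- sample(80:200, 1)
    scores <- sort(rnorm(N, 0, 2), decreasing = TRUE)
    rk <- data.frame(gene = sprintf("G%03d", 1:N), score = scores)
    gs <- sample(rk$gene, 30)
    mine <- preranked_enrichment(rk, gs, n_permutations = 10, seed = i)$es
    theirs <- fgsea::calcGseaStat(stats::setNames(scores, rk$gene),
                                  selectedStats = which(rk$gene %in% gs),
                                  gseaParam = 1)
    expect_equal(mine, theirs, tolerance = 1e-12)
  }
})

test_that("preranked enrichment flags top sets, mirrors bottom sets, gates overlap", {
  N <- 150
  rk <- data.frame(gene = sprintf("G%03d", 1:N),
                   score = sort(rnorm(N, 0, 2), decreasing = TRUE))
  top <- preranked_enrichment(rk, rk$gene[1:30], n_permutations = 500, seed = 4)
  expect_gt(top$es, 0.9)
  expect_lte(top$p_value, 1 / 100)                 # at the permutation floor
  expect_gt(top$nes, 1)
  bottom <- preranked_enrichment(rk, rk$gene[(N - 29):N], n_permutations = 200,
                                 seed = 4)
  expect_lt(bottom$es, 0)
  expect_lt(bottom$nes, 0)
  expect_error(preranked_enrichment(rk, rk$gene[1:10], n_permutations = 50,
                                    seed = 1), "minimum overlap")
  small <- preranked_enrichment(rk, rk$gene[1:10], n_permutations = 50,
                                seed = 1, min_overlap = 5)
  expect_gt(small$es, 0)
})

test_that("overlap_test matches fisher.test, is symmetric, handles edge sets", {
  u <- sprintf("G%04d", 1:500)
  a <- u[1:60]; b <- u[41:140]
  got <- overlap_test(a, b, u)
  expect_equal(got$overlap, 20L)
  oracle <- fisher.test(matrix(c(20, 40, 80, 360), 2))$p.value
  expect_equal(got$p, oracle, tolerance = 1e-12)
  expect_equal(overlap_test(b, a, u)$p, got$p)
  # disjoint sets: depletion handled two-sided
  expect_lte(overlap_test(u[1:5], u[6:10], u)$p, 1)
  # identical sets reach the minimal p for their sizes
  same <- overlap_test(a, a, u)
  expect_equal(same$overlap, 60L)
  expect_lt(same$p, overlap_test(a, c(a[1:59], u[200]), u)$p)
  expect_error(overlap_test(a, b, character(0)), "empty universe")
  # screen-sized table: 61 candidates vs 776 hits in an 8,189-gene universe
  u2 <- sprintf("G%04d", 1:8189)
  a2 <- u2[1:61]; b2 <- u2[c(1:14, 1000:1761)]
  got2 <- overlap_test(a2, b2, u2)
  expect_equal(got2$overlap, 14L)
  oracle2 <- fisher.test(matrix(c(14, 47, 762, 7366), 2))$p.value
  expect_equal(got2$p, oracle2, tolerance = 1e-10)
})

test_that("same_pathway_enrichment gates, tests and prunes as specified", {
  univ <- sprintf("G%04d", 1:1000)
  cands <- univ[1:20]
  paths <- list(
    good = c("MUT", univ[1:10], univ[500:520]),
    dup_worse = c("MUT", univ[1:10], univ[600:680]),   # same overlap, larger p
    contained = c("MUT", univ[1:5]),                   # overlap strictly inside good's
    no_mut = univ[1:50],                               # lacks the mutated gene
    huge = c("MUT", sprintf("H%04d", 1:501)))          # >500 members
  res <- same_pathway_enrichment(cands, "MUT", paths, c(univ, "MUT"))
  expect_true("good" %in% res$pathway)
  expect_false("dup_worse" %in% res$pathway)   # identical overlap, worse p
  expect_false("contained" %in% res$pathway)   # strict containment
  expect_false("no_mut" %in% res$pathway)
  expect_false("huge" %in% res$pathway)
  # hypergeometric oracle
  pg <- length(intersect(paths$good, c(univ, "MUT")))
  ov <- length(intersect(cands, paths$good))
  want <- phyper(ov - 1, pg, 1001 - pg, length(cands), lower.tail = FALSE)
  expect_equal(res$p_value[res$pathway == "good"], want, tolerance = 1e-12)
})
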