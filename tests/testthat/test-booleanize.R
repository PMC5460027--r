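# Boolean alteration matrices: mutation booleanisation, segment filtering,
# normal subtraction, gene-level CNA calls, passenger annotation.

seg_df <- function(...) {
  rows <- list(...)
  out <- do.call(rbind, lapply(rows, function(r)
    data.frame(sample_id = r[[1]], sample_class = "tumour", chrom = r[[2]],
               start = r[[3]], end = r[[4]], n_markers = r[[5]],
               segment_mean = r[[6]], stringsAsFactors = FALSE)))
  class(out) <- c("segment_table", "data.frame")
  out
}

test_that("booleanize_mutations builds gene-level and per-type variables", {
  mt <- data.frame(sample_id = c("S1", "S2"), gene = c("TP53", "TP53"),
                   mutation_type = c("missense", "nonsense"))
  m <- booleanize_mutations(mt, c("S1", "S2", "S3"))
  expect_true(m["TP53", "S1"])
  expect_false(m["TP53", "S3"])
  mp <- booleanize_mutations(mt, c("S1", "S2", "S3"), per_type = TRUE)
  expect_true(mp["TP53:missense", "S1"])
  expect_false(mp["TP53:missense", "S2"])
  expect_true(mp["TP53:nonsense", "S2"])
  empty <- booleanize_mutations(mt[0, ], c("S1"))
  expect_equal(nrow(empty), 0L)
})

test_that("filter_segments applies the strict magnitude and marker gates idempotently", {
  seg <- seg_df(list("S1", "chr1", 0, 100, 5, 0.31),
                list("S1", "chr1", 0, 100, 50, 0.30),
                list("S1", "chr1", 0, 100, 4, -0.9),
                list("S1", "chr1", 0, 100, 5, -0.31))
  f <- filter_segments(seg)
  expect_equal(f$segment_mean, c(0.31, -0.31))
  expect_equal(filter_segments(f), f)           # idempotent
  expect_equal(nrow(filter_segments(seg[0, ])), 0L)
})

test_that("subtract_normal drops tumour segments covered >50% by normals", {
  t1 <- seg_df(list("S1", "chr1", 0, 100, 10, 0.5))
  n_over <- seg_df(list("S1", "chr1", 0, 51, 10, 0.5))
  n_half <- seg_df(list("S1", "chr1", 0, 50, 10, 0.5))
  expect_equal(nrow(subtract_normal(t1, n_over)), 0L)   # 51% > 0.5 dropped
  expect_equal(nrow(subtract_normal(t1, n_half)), 1L)   # exactly 50% kept
  expect_equal(subtract_normal(t1, t1[0, ]), t1)        # no normals: identity
  # union of normal segments counts once even if they overlap each other
  n_split <- seg_df(list("S1", "chr1", 0, 30, 10, 0.5),
                    list("S1", "chr1", 20, 52, 10, 0.5))
  expect_equal(nrow(subtract_normal(t1, n_split)), 0L)
  # other samples' normals never interfere
  n_other <- seg_df(list("S2", "chr1", 0, 100, 10, 0.5))
  expect_equal(nrow(subtract_normal(t1, n_other)), 1L)
})

test_that("subtract_normal never increases the segment count", {
  set.seed(42)
  for (i in 1:20) {
    tum <- seg_df(list("S1", "chr1", sample(0:50, 1), sample(60:200, 1), 10, 0.5))
    nrm <- do.call(rbind, lapply(1:3, function(j)
      seg_df(list("S1", "chr1", sample(0:100, 1), sample(110:300, 1), 10, -0.5))))
    expect_lte(nrow(subtract_normal(tum, nrm)), nrow(tum))
  }
})

test_that("call_gene_cna uses half-open overlap and resolves amp/del conflicts", {
  model <- data.frame(gene = c("G1", "G2", "G3"), chrom = "chr1",
                      start = c(100, 100, 1000), end = c(200, 200, 1100))
  class(model) <- c("gene_model", "data.frame")
  seg <- seg_df(list("S1", "chr1", 150, 300, 10, 0.5),   # overlaps G1/G2
                list("S2", "chr1", 200, 300, 10, 0.5),   # adjacent: no overlap
                list("S3", "chr1", 100, 160, 10, 0.5),   # amp on G1/G2 ...
                list("S3", "chr1", 160, 220, 10, -0.5))  # ... del on G1/G2: ambiguous
  calls <- call_gene_cna(seg, model, samples = c("S1", "S2", "S3"))
  expect_true(calls$amp["G1", "S1"])
  expect_false(calls$amp["G1", "S2"])              # half-open adjacency
  expect_false(calls$amp["G1", "S3"])              # ambiguous -> both FALSE
  expect_false(calls$del["G1", "S3"])
  expect_false(any(calls$amp["G3", ]))
  # sub-threshold segments change nothing
  seg2 <- rbind(seg, seg_df(list("S2", "chr1", 100, 200, 10, 0.2)))
  calls2 <- call_gene_cna(seg2, model, samples = c("S1", "S2", "S3"))
  expect_identical(calls, calls2)
})

test_that("welch_rows agrees with stats::t.test", {
  set.seed(1)
  x <- matrix(rnorm(60), 5, 12)
  w <- welch_rows(x, 1:5, 6:12)
  for (i in 1:5) {
    o <- t.test(x[i, 1:5], x[i, 6:12])
    expect_equal(w$p[i], o$p.value, tolerance = 1e-12)
    expect_equal(w$t[i], unname(o$statistic), tolerance = 1e-12)
  }
})

test_that("annotate_passengers detects concordant expression change", {
  set.seed(3)
  n <- 60
  del <- matrix(rep(c(TRUE, FALSE), each = n / 2), 1, n,
                dimnames = list("G1", NULL))
  expr <- matrix(rnorm(n, 5, 0.3), 1, n, dimnames = list("G1", NULL))
  expr[1, 1:(n / 2)] <- expr[1, 1:(n / 2)] - 1          # fold 2 in deleted samples
  co <- make_cohort(del = del, expr = expr)
  ann <- annotate_passengers(co, "del")
  expect_false(ann$is_passenger)
  # p agrees with the t.test oracle
  o <- t.test(expr[1, del[1, ]], expr[1, !del[1, ]])
  expect_equal(ann$p_value, o$p.value, tolerance = 1e-10)

  # identical distributions: passenger
  expr2 <- matrix(rnorm(n, 5, 0.3), 1, n, dimnames = list("G1", NULL))
  ann2 <- annotate_passengers(make_cohort(del = del, expr = expr2), "del")
  expect_true(ann2$is_passenger)

  # strong p but fold below 1.2: the fold gate keeps it a passenger
  expr3 <- matrix(rnorm(n, 5, 0.05), 1, n, dimnames = list("G1", NULL))
  expr3[1, del[1, ]] <- expr3[1, del[1, ]] - 0.2        # fold 1.15
  ann3 <- annotate_passengers(make_cohort(del = del, expr = expr3), "del")
  expect_lt(ann3$p_value, 0.001)
  expect_lt(ann3$fold_difference, 1.2)
  expect_true(ann3$is_passenger)

  # direction matters: deletion with HIGHER expression stays a passenger
  expr4 <- expr
  expr4[1, ] <- rev(expr4[1, ])
  ann4 <- annotate_passengers(make_cohort(del = del, expr = expr4), "del")
  expect_true(ann4$is_passenger)

  # too few altered samples: passenger by convention
  del5 <- matrix(c(TRUE, rep(FALSE, n - 1)), 1, n, dimnames = list("G1", NULL))
  ann5 <- annotate_passengers(make_cohort(del = del5, expr = expr), "del")
  expect_true(ann5$is_passenger)
})

test_that("annotate_passengers marks nearly all genes passenger under a null", {
  set.seed(99)
  frac <- replicate(5, {
    n <- 80; g <- 40
    del <- matrix(runif(g * n) < 0.2, g, n,
                  dimnames = list(sprintf("G%02d", 1:g), NULL))
    expr <- matrix(rnorm(g * n, 5, 0.4), g, n,
                   dimnames = list(sprintf("G%02d", 1:g), NULL))
    ann <- annotate_passengers(make_cohort(del = del, expr = expr), "del")
    mean(ann$is_passenger)
  })
  expect_gte(mean(frac), 0.95)
})
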