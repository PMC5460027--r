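# The core statistic: contingency counting, Fisher dependence gate,
# sparse-quadrant error rate, artificial normals, the pooled scan, and
# permutation FDR calibration.

test_that("contingency counts pairwise values exactly", {
  expect_equal(contingency(c(1, 1, 0), c(1, 0, 0)),
               c(n11 = 1L, n10 = 1L, n01 = 0L, n00 = 1L))
  expect_equal(contingency(rep(TRUE, 4), rep(TRUE, 4)),
               c(n11 = 4L, n10 = 0L, n01 = 0L, n00 = 0L))
  expect_error(contingency(c(TRUE, FALSE), TRUE), "length")
  set.seed(5)
  a <- runif(400) < 0.5; b <- runif(400) < 0.5
  tab <- contingency(a, b)
  expect_equal(sum(tab), 400)
  expect_equal(unname(tab["n11"]), sum(a & b))
})

test_that("fisher_p matches stats::fisher.test and handles degenerate margins", {
  expect_equal(fisher_p(5, 0, 0, 5),
               fisher.test(matrix(c(5, 0, 0, 5), 2))$p.value, tolerance = 1e-12)
  expect_equal(fisher_p(1, 1, 1, 1), 1.0)
  expect_equal(fisher_p(0, 0, 3, 7), 1.0)      # zero row margin
  expect_equal(fisher_p(0, 3, 0, 7), 1.0)      # zero column margin
  set.seed(7)
  for (i in 1:300) {
    tab <- random_table(60)
    if (sum(tab) == 0) next
    expect_equal(fisher_p(tab), fisher_oracle(tab), tolerance = 1e-10,
                 info = paste(tab, collapse = ","))
  }
})

test_that("error_rate follows the symmetric conditional formula and its properties", {
  expect_equal(error_rate(c(n11 = 2, n10 = 18, n01 = 38, n00 = 0), "n11"), 0.075)
  expect_equal(error_rate(c(n11 = 0, n10 = 5, n01 = 9, n00 = 4), "n11"), 0)
  expect_equal(error_rate(c(n11 = 3, n10 = 3, n01 = 3, n00 = 0), "n11"), 0.5)
  # an empty sparse quadrant wins over empty companions ...
  expect_equal(error_rate(c(n11 = 0, n10 = 0, n01 = 0, n00 = 5), "n11"), 0)
  # ... but violations filling both margins fail closed
  expect_equal(error_rate(c(n11 = 2, n10 = 0, n01 = 0, n00 = 5), "n11"), 1)
  # bounded and monotone in the sparse count with row/column companions fixed
  prev <- -1
  for (a in 0:20) {
    e <- error_rate(c(n11 = a, n10 = 7, n01 = 13, n00 = 0), "n11")
    expect_gte(e, 0); expect_lte(e, 1)
    expect_gte(e, prev)
    if (a == 0) expect_equal(e, 0) else expect_gt(e, 0)
    prev <- e
  }
  # the three sparse-cell orientations use the matching companions
  tab <- c(n11 = 2, n10 = 6, n01 = 10, n00 = 30)
  expect_equal(error_rate(tab, "n10"), 0.5 * (6 / (6 + 2) + 6 / (6 + 30)))
  expect_equal(error_rate(tab, "n01"), 0.5 * (10 / (10 + 30) + 10 / (10 + 2)))
})

test_that("artificial normals append all-false samples and enable HI-HI detection", {
  m <- matrix(TRUE, 3, 5, dimnames = list(c("A", "B", "C"), paste0("S", 1:5)))
  aug <- augment_artificial_normals(list(x = m), 10)
  expect_equal(dim(aug$x), c(3L, 15L))
  expect_equal(sum(aug$x), 15)
  expect_identical(augment_artificial_normals(list(x = m), 0)$x, m)

  # an alteration present in every tumour sample is invisible to Fisher
  # (degenerate margin) until artificial normals are added
  n <- 40
  mut <- matrix(TRUE, 1, n, dimnames = list("X", NULL))
  amp <- matrix(TRUE, 1, n, dimnames = list("B", NULL))
  co <- make_cohort(mut = mut, amp = amp)
  pre <- scan_implications(list(co), "X:mut", "hi_hi", artificial_normals = 0,
                           keep_all = TRUE)
  expect_equal(pre$fisher_p, 1.0)
  post <- scan_implications(list(co), "X:mut", "hi_hi", artificial_normals = "auto")
  expect_equal(post$partner, "B")
  expect_lt(post$fisher_p, 1e-10)
  expect_equal(post$sparse_count, 0L)
})

test_that("scan_implications equals the brute-force double loop on random fixtures", {
  set.seed(11)
  for (i in 1:40) {
    nv <- sample(2:20, 1); n <- sample(10:100, 1)
    kind <- sample(c("hi_lo", "hi_hi"), 1)
    mut <- matrix(runif(n) < 0.3, 1, n, dimnames = list("X", NULL))
    M <- matrix(runif((nv - 1) * n) < runif(1, 0.05, 0.5), nv - 1, n,
                dimnames = list(sprintf("P%02d", seq_len(nv - 1)), NULL))
    co <- if (kind == "hi_lo") make_cohort(mut = mut, del = M)
          else make_cohort(mut = mut, amp = M)
    got <- scan_implications(list(co), "X:mut", kind)
    want <- brute_force_scan(co, "X", kind)
    expect_identical(sort(got$partner), sort(as.character(names(want))))
    for (g in got$partner) {
      expect_equal(got$fisher_p[got$partner == g], unname(want[[g]]["p"]),
                   tolerance = 1e-10)
      expect_equal(got$error_rate[got$partner == g], unname(want[[g]]["e"]),
                   tolerance = 1e-12)
    }
  }
})

test_that("a planted perfect subset is reported with empty sparse quadrant", {
  set.seed(21)
  n <- 200
  mut <- matrix(runif(n) < 0.3, 1, n, dimnames = list("X", NULL))
  amp <- matrix(FALSE, 2, n, dimnames = list(c("B", "N"), NULL))
  amp["B", mut[1, ]] <- runif(sum(mut)) < 0.6       # subset of mutants
  amp["N", ] <- runif(n) < 0.1
  co <- make_cohort(mut = mut, amp = amp)
  res <- scan_implications(list(co), "X:mut", "hi_hi")
  expect_true("B" %in% res$partner)
  expect_equal(res$sparse_count[res$partner == "B"], 0L)
  expect_equal(res$antecedent[res$partner == "B"], "B:amp")
  expect_equal(res$consequent[res$partner == "B"], "X:mut")
})

test_that("the anchor never reports against itself and absent anchors warn", {
  n <- 50
  mut <- matrix(runif(n) < 0.4, 1, n, dimnames = list("X", NULL))
  del <- matrix(c(!mut[1, ], runif(n) < 0.2), 2, n, byrow = TRUE,
                dimnames = list(c("X", "B"), NULL))
  co <- make_cohort(mut = mut, del = del)
  res <- scan_implications(list(co), "X:mut", "hi_lo", keep_all = TRUE)
  expect_false("X" %in% res$partner)
  expect_warning(scan_implications(list(co), "ZZZ:mut", "hi_lo"), "absent")
})

test_that("independent variables are reported at no more than the gate rate", {
  set.seed(31)
  hits <- 0; trials <- 0
  for (r in 1:5) {
    n <- 100; nv <- 200
    mut <- matrix(runif(n) < 0.3, 1, n, dimnames = list("X", NULL))
    del <- matrix(runif(nv * n) < 0.15, nv, n,
                  dimnames = list(sprintf("P%03d", 1:nv), NULL))
    co <- make_cohort(mut = mut, del = del)
    res <- scan_implications(list(co), "X:mut", "hi_lo")
    hits <- hits + nrow(res); trials <- trials + nv
  }
  expect_lte(hits / trials, 0.05)
})

test_that("artificial normals are a HI-HI-only device: HI-LO scans ignore them", {
  set.seed(61)
  n <- 60
  mut <- matrix(runif(n) < 0.3, 1, n, dimnames = list("X", NULL))
  del <- matrix(runif(2 * n) < 0.25, 2, n, dimnames = list(c("A", "B"), NULL))
  co <- make_cohort(mut = mut, del = del)
  r0 <- scan_implications(list(co), "X:mut", "hi_lo", artificial_normals = 0,
                          keep_all = TRUE)
  r5 <- scan_implications(list(co), "X:mut", "hi_lo", artificial_normals = 50,
                          keep_all = TRUE)
  expect_identical(r0, r5)
})

test_that("jointly permuting sample labels leaves all statistics unchanged", {
  set.seed(41)
  n <- 80
  mut <- matrix(runif(n) < 0.3, 1, n, dimnames = list("X", NULL))
  del <- matrix(runif(3 * n) < 0.2, 3, n, dimnames = list(c("A", "B", "C"), NULL))
  co <- make_cohort(mut = mut, del = del)
  perm <- sample.int(n)
  co2 <- make_cohort(mut = mut[, perm, drop = FALSE],
                     del = del[, perm, drop = FALSE])
  r1 <- scan_implications(list(co), "X:mut", "hi_lo", keep_all = TRUE)
  r2 <- scan_implications(list(co2), "X:mut", "hi_lo", keep_all = TRUE)
  expect_equal(r1[, c("partner", "fisher_p", "error_rate", "sparse_count")],
               r2[, c("partner", "fisher_p", "error_rate", "sparse_count")])
})

test_that("passenger annotations restrict which cohorts pool samples", {
  set.seed(51)
  n <- 100
  make <- function(ct, plant) {
    mut <- matrix(runif(n) < 0.3, 1, n, dimnames = list("X", NULL))
    del <- matrix(FALSE, 1, n, dimnames = list("B", NULL))
    if (plant) del["B", !mut[1, ]] <- runif(sum(!mut[1, ])) < 0.3
    else del["B", ] <- runif(n) < 0.3        # violates the implication
    make_cohort(mut = mut, del = del, ct = ct)
  }
  co_good <- make("GOOD", TRUE)
  co_bad <- make("BAD", FALSE)
  pass <- data.frame(cancer_type = c("GOOD", "BAD"), gene = "B",
                     alteration = "del", is_passenger = c(FALSE, TRUE),
                     p_value = 0, fold_difference = 2)
  res <- scan_implications(list(co_good, co_bad), "X:mut", "hi_lo",
                           passenger = pass, keep_all = TRUE)
  expect_equal(res$cancer_types_used, "GOOD")
  expect_equal(res$n_samples, n)
  # with the passenger cohort admitted, the pooled table includes both
  res2 <- scan_implications(list(co_good, co_bad), "X:mut", "hi_lo",
                            keep_all = TRUE)
  expect_equal(res2$n_samples, 2L * n)
})

test_that("calibrate_fdr reports ~zero FDR for perfect implications and is seed-stable", {
  n <- 120
  mut <- matrix(rep(c(TRUE, FALSE), c(40, 80)), 1, n, dimnames = list("X", NULL))
  del <- matrix(rep(c(FALSE, TRUE), c(40, 80)), 1, n, dimnames = list("B", NULL))
  co <- make_cohort(mut = mut, del = del)
  cal <- calibrate_fdr(list(co), "X:mut", "hi_lo", n_permutations = 10, seed = 3)
  expect_equal(cal$observed_counts, rep(1, length(cal$cutoff_grid)))
  expect_true(all(cal$fdr_at_cutoff < 0.05))
  expect_equal(cal$chosen_cutoff, 0.05)
  cal2 <- calibrate_fdr(list(co), "X:mut", "hi_lo", n_permutations = 10, seed = 3)
  expect_identical(cal$null_mean_counts, cal2$null_mean_counts)
  expect_lte(cal$chosen_cutoff, 0.05)
})
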