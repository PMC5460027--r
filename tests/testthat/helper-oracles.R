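# Independent oracles used across tests. These are deliberately naive
# (explicit loops, stats::fisher.test, stats::t.test) so they share no code
# path with the package implementation.

# Build a one-cohort fixture from raw logical matrices.
make_cohort <- function(mut = NULL, amp = NULL, del = NULL, expr = NULL,
                        samples = NULL, ct = "CX", gene_chrom = NULL) {
  n <- max(ncol(mut %||% matrix(nrow = 0, ncol = 0)),
           ncol(amp %||% matrix(nrow = 0, ncol = 0)),
           ncol(del %||% matrix(nrow = 0, ncol = 0)),
           ncol(expr %||% matrix(nrow = 0, ncol = 0)))
  samples <- samples %||% sprintf("S%03d", seq_len(n))
  fix <- function(m) {
    if (is.null(m)) return(NULL)
    colnames(m) <- samples
    m
  }
  cancer_cohort(ct, samples, mut = fix(mut), amp = fix(amp), del = fix(del),
                expr = fix(expr), gene_chrom = gene_chrom)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Brute-force implication scan over a single cohort: explicit double loop,
# stats::fisher.test for the dependence gate, hand-written error-rate
# arithmetic for the sparse-quadrant gate.
brute_force_scan <- function(cohort, anchor_gene, kind,
                             fisher_cutoff = 0.05, error_cutoff = 0.1) {
  a <- cohort$mut[anchor_gene, ]
  M <- if (kind == "hi_lo") cohort$del else cohort$amp
  out <- list()
  for (g in setdiff(rownames(M), anchor_gene)) {
    b <- M[g, ]
    av <- a; bv <- b
    if (kind == "hi_hi") {
      k <- length(av)                      # "auto" artificial normals
      av <- c(av, rep(FALSE, k)); bv <- c(bv, rep(FALSE, k))
    }
    n11 <- sum(av & bv); n10 <- sum(av & !bv)
    n01 <- sum(!av & bv); n00 <- sum(!av & !bv)
    p <- stats::fisher.test(matrix(c(n11, n01, n10, n00), 2))$p.value
    if (kind == "hi_lo") {
      sa <- n11; sr <- n10; sc <- n01
    } else {                               # sparse = partner high, anchor low
      sa <- n01; sr <- n00; sc <- n11
    }
    e <- if (sa == 0) 0
    else if ((sa + sr) == 0 || (sa + sc) == 0) 1
    else 0.5 * (sa / (sa + sr) + sa / (sa + sc))
    if (p < fisher_cutoff && e < error_cutoff)
      out[[g]] <- c(p = p, e = e, sparse = sa)
  }
  out
}

# Step-by-step GSEA running sum, explicit loop.
gsea_es_oracle <- function(scores, hit, weight = 1) {
  N <- length(scores)
  Nh <- sum(hit)
  wsum <- sum(abs(scores[hit])^weight)
  run <- 0
  best <- 0
  for (i in seq_len(N)) {
    if (hit[i]) {
      run <- run + (if (wsum > 0) abs(scores[i])^weight / wsum else 1 / Nh)
    } else {
      run <- run - 1 / (N - Nh)
    }
    if (abs(run) > abs(best)) best <- run
  }
  best
}

# Random 2x2 table with total <= max_total (all margins possibly degenerate).
random_table <- function(max_total = 60) {
  n <- sample(1:max_total, 1)
  cuts <- sort(sample(0:n, 3, replace = TRUE))
  c(n11 = cuts[1], n10 = cuts[2] - cuts[1], n01 = cuts[3] - cuts[2],
    n00 = n - cuts[3])
}

fisher_oracle <- function(tab) {
  stats::fisher.test(matrix(c(tab[["n11"]], tab[["n01"]],
                              tab[["n10"]], tab[["n00"]]), 2))$p.value
}
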