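# Shared fixtures used by multiple test files.

# 20-construct toy screen exercising every hit-calling gate.
toy_screen <- function() {
  rows <- list(
    # HIT1: ratios 0.5, 0.55, 0.9 -> two qualify, mean 0.525 < 0.6 -> hit
    c("HIT1", 1000, 500), c("HIT1", 1000, 550), c("HIT1", 1000, 900),
    # WEAK: 0.79, 0.78, 0.9 -> two qualify but mean 0.785 >= 0.6 -> no
    c("WEAK", 1000, 790), c("WEAK", 1000, 780), c("WEAK", 1000, 900),
    # FEW: only two constructs -> excluded regardless of ratios
    c("FEW", 1000, 100), c("FEW", 1000, 100),
    # LOWREAD: three constructs but one below the read floor -> excluded
    c("LOWREAD", 99, 10), c("LOWREAD", 1000, 100), c("LOWREAD", 1000, 100),
    # ONEQ: only one construct qualifies -> no
    c("ONEQ", 1000, 500), c("ONEQ", 1000, 900), c("ONEQ", 1000, 950),
    # HIT2: all three qualify, mean (0.3+0.4+0.5)/3 = 0.4 -> hit
    c("HIT2", 1000, 300), c("HIT2", 500, 200), c("HIT2", 200, 100),
    # NULL1: no reduction at all
    c("NULL1", 1000, 1000), c("NULL1", 1000, 1100), c("NULL1", 1000, 950),
    # BORDER: ratio exactly 0.8 does not qualify (strict >20% reduction)
    c("BORDER", 1000, 800), c("BORDER", 1000, 800), c("BORDER", 1000, 500))
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(gene = r[1], baseline = as.numeric(r[2]), treated = as.numeric(r[3]),
               stringsAsFactors = FALSE)))
  df$construct_id <- sprintf("sh%02d", seq_len(nrow(df)))
  class(df) <- c("screen_table", "data.frame")
  df
}

# Two-cohort fixture: drug target Y; mutation X mutually exclusive with
# Y-deletion; decoy mutation D with the same pattern but on Y's chromosome.
biomarker_fixture <- function(seed = 23) {
  set.seed(seed)
  n <- 150
  x <- runif(n) < 0.3
  d <- x                                            # identical pattern to X
  mutC2 <- rbind(X = x, D = d)
  x1 <- runif(n) < 0.3
  mutC1 <- rbind(X = x1, D = x1)
  del <- matrix(FALSE, 1, n, dimnames = list("Y", NULL))
  del["Y", !x] <- runif(sum(!x)) < 0.35
  exprC2 <- matrix(rnorm(3 * n, 5, 0.3), 3, n, dimnames = list(c("X", "D", "Y"), NULL))
  exprC2["Y", del["Y", ]] <- exprC2["Y", del["Y", ]] - 1
  exprC1 <- matrix(rnorm(3 * n, 5, 0.3), 3, n, dimnames = list(c("X", "D", "Y"), NULL))
  exprC1["Y", mutC1["X", ]] <- exprC1["Y", mutC1["X", ]] + 1
  chrom <- c(X = "chr1", D = "chr7", Y = "chr7")
  c1 <- make_cohort(mut = mutC1, expr = exprC1, ct = "C1", gene_chrom = chrom)
  c2 <- make_cohort(mut = mutC2, del = del, expr = exprC2, ct = "C2",
                    gene_chrom = chrom)
  dg <- data.frame(drug = "DRUGX", gene = "Y", interaction = "inhibits",
                   stringsAsFactors = FALSE)
  list(cohorts = list(c1, c2), drug_gene = dg)
}
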