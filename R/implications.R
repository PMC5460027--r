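## Boolean implication mining between alteration variables: the two-part
## significance test (Fisher dependence + sparse-quadrant error rate),
## artificial-normal augmentation for HI-HI extraction, and permutation
## FDR calibration of the Fisher cutoff.
##
## A HI-HI implication "A high => B high" forbids the (A=1, B=0) quadrant;
## a HI-LO implication "A high => B low" forbids (A=1, B=1). The forbidden
## ("sparse") quadrant must be statistically empty: the Fisher test
## establishes dependence, the error rate bounds the fraction of points
## violating the implication conditioned on each margin.

#' Pairwise contingency table of two Boolean vectors
#'
#' @param a,b Logical vectors of equal positive length; `a` indexes rows
#'   of the 2x2 (n11 = both TRUE, n10 = a only, n01 = b only, n00 =
#'   neither).
#' @return Named integer vector `c(n11, n10, n01, n00)`.
#' @export
contingency <- function(a, b) {
  if (length(a) != length(b)) stop_format("contingency: length mismatch")
  if (length(a) == 0) stop_format("contingency: empty vectors")
  a <- as.logical(a); b <- as.logical(b)
  c(n11 = sum(a & b), n10 = sum(a & !b), n01 = sum(!a & b), n00 = sum(!a & !b))
}

#' Two-sided Fisher exact p-value of a 2x2 table
#'
#' Computed by hypergeometric enumeration over the support at fixed
#' margins: the p-value is the total probability of tables no more likely
#' than the observed one (with the customary `1 + 1e-7` relative
#' tolerance on the comparison). Any zero row or column margin returns
#' 1.0.
#'
#' @param n11,n10,n01,n00 Cell counts; alternatively pass the result of
#'   [contingency()] as `n11`.
#' @return p-value in `[0, 1]`.
#' @export
fisher_p <- function(n11, n10 = NULL, n01 = NULL, n00 = NULL) {
  if (is.null(n10)) { t <- n11; n11 <- t[["n11"]]; n10 <- t[["n10"]]; n01 <- t[["n01"]]; n00 <- t[["n00"]] }
  n <- n11 + n10 + n01 + n00
  if (n <= 0) stop_format("fisher_p: empty table")
  r1 <- n11 + n10; c1 <- n11 + n01
  if (r1 == 0 || c1 == 0 || r1 == n || c1 == n) return(1.0)
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(support, c1, n - c1, r1)
  pobs <- stats::dhyper(n11, c1, n - c1, r1)
  min(1, sum(probs[probs <= pobs * (1 + 1e-7)]))
}

#' Maximum-likelihood error rate of a sparse quadrant
#'
#' For sparse-quadrant count `a`, the other count `r` in the quadrant's
#' row and the other count `c` in its column, the estimate is
#' `e = 0.5 * (a/(a+r) + a/(a+c))` -- the average of the two conditional
#' violation probabilities. `a = 0` yields 0; an undefined denominator
#' (`a + r = 0` or `a + c = 0`, i.e. an empty margin) yields 1 (fail).
#'
#' @param tab Named counts as returned by [contingency()].
#' @param sparse Which cell is the forbidden quadrant: `"n11"` (HI-LO,
#'   antecedent in rows), `"n10"` (HI-HI, antecedent in rows) or `"n01"`
#'   (HI-HI, antecedent in columns).
#' @return Error rate in `[0, 1]`.
#' @export
error_rate <- function(tab, sparse = c("n11", "n10", "n01")) {
  sparse <- match.arg(sparse)
  a <- tab[[sparse]]
  rc <- switch(sparse,
               n11 = c(tab[["n10"]], tab[["n01"]]),
               n10 = c(tab[["n11"]], tab[["n00"]]),
               n01 = c(tab[["n00"]], tab[["n11"]]))
  .error_rate_num(a, rc[1], rc[2])
}

## vectorised core: a = sparse count, r/c = row/column companions
.error_rate_num <- function(a, r, c) {
  e <- 0.5 * (a / (a + r) + a / (a + c))
  e[(a + r) == 0 | (a + c) == 0] <- 1
  e[a == 0] <- 0
  e
}

#' Append artificial normal samples to alteration matrices
#'
#' Artificial normals are all-negative samples (no mutations, no CNAs)
#' appended so that HI-HI implications involving near-ubiquitous
#' alterations become detectable; they are used only during HI-HI
#' extraction and never touch expression data.
#'
#' @param matrices Named list of logical alteration matrices sharing a
#'   sample axis.
#' @param k Number of artificial normals (>= 0).
#' @return The list with `k` all-FALSE columns appended to each matrix.
#' @export
augment_artificial_normals <- function(matrices, k) {
  stopifnot(k >= 0)
  if (k == 0) return(matrices)
  lapply(matrices, function(m) {
    if (is.null(m)) return(NULL)
    extra <- matrix(FALSE, nrow(m), k,
                    dimnames = list(rownames(m), paste0("__an", seq_len(k))))
    cbind(m, extra)
  })
}

## Pull one variable's Boolean vector out of a cohort; genes absent from
## the class matrix give an all-FALSE vector.
cohort_variable <- function(cohort, id) {
  v <- parse_var_id(id)
  m <- cohort[[v$class]]
  if (is.null(m) || !(v$gene %in% rownames(m)))
    return(stats::setNames(rep(FALSE, length(cohort$samples)), cohort$samples))
  stats::setNames(m[v$gene, ], cohort$samples)
}

## Internal scan engine. For an anchor variable and a partner alteration
## class, pools per-cohort 2x2 counts over the cohorts flagged in
## `partner_ok` (genes x cohorts logical; which cohorts contribute samples
## for each partner), applies artificial normals to n00 when requested,
## and evaluates both gates. `sparse` names the forbidden cell with the
## anchor in rows.
.scan_engine <- function(cohorts, anchor, partner_class, sparse,
                         partner_ok = NULL, fisher_cutoff = 0.05,
                         error_cutoff = 0.1, artificial_normals = 0,
                         keep_all = FALSE) {
  stopifnot(length(cohorts) > 0)
  cnames <- vapply(cohorts, function(x) x$cancer_type, "")
  av <- parse_var_id(anchor)
  genes <- sort(unique(unlist(lapply(cohorts, function(co) {
    m <- co[[partner_class]]
    if (is.null(m)) character(0) else rownames(m)
  }))))
  genes <- setdiff(genes, av$gene)
  if (!length(genes))
    return(.implication_frame(character(0)))
  if (is.null(partner_ok)) {
    partner_ok <- matrix(TRUE, length(genes), length(cohorts),
                         dimnames = list(genes, cnames))
  } else {
    po <- matrix(FALSE, length(genes), length(cohorts),
                 dimnames = list(genes, cnames))
    shared <- intersect(rownames(partner_ok), genes)
    po[shared, colnames(partner_ok)] <- partner_ok[shared, , drop = FALSE]
    partner_ok <- po
  }
  ## cohorts lacking the partner-class matrix cannot contribute
  has_class <- vapply(cohorts, function(co) !is.null(co[[partner_class]]), TRUE)
  partner_ok[, !has_class] <- FALSE

  n11 <- n10 <- n01 <- n00 <- stats::setNames(numeric(length(genes)), genes)
  used <- matrix(FALSE, length(genes), length(cohorts),
                 dimnames = list(genes, cnames))
  for (j in seq_along(cohorts)) {
    co <- cohorts[[j]]
    inc <- partner_ok[, j]
    if (!any(inc)) next
    a <- cohort_variable(co, anchor)
    M <- co[[partner_class]]
    n_c <- length(co$samples)
    rows <- match(genes, rownames(M))
    p11 <- numeric(length(genes)); ptot <- numeric(length(genes))
    present <- !is.na(rows)
    if (any(present)) {
      Mp <- M[rows[present], , drop = FALSE]
      p11[present] <- as.numeric(Mp %*% a)
      ptot[present] <- rowSums(Mp)
    }
    na <- sum(a)
    n11[inc] <- n11[inc] + p11[inc]
    n10[inc] <- n10[inc] + (na - p11[inc])
    n01[inc] <- n01[inc] + (ptot[inc] - p11[inc])
    n00[inc] <- n00[inc] + (n_c - na - ptot[inc] + p11[inc])
    used[inc, j] <- TRUE
  }
  tested <- rowSums(used) > 0
  genes <- genes[tested]
  if (!length(genes)) return(.implication_frame(character(0)))
  n11 <- n11[genes]; n10 <- n10[genes]; n01 <- n01[genes]; n00 <- n00[genes]
  used <- used[genes, , drop = FALSE]
  pooled_n <- n11 + n10 + n01 + n00
  k <- if (identical(artificial_normals, "auto")) pooled_n
       else rep(as.numeric(artificial_normals), length(genes))
  n00 <- n00 + k

  p <- vapply(seq_along(genes), function(i)
    fisher_p(n11[i], n10[i], n01[i], n00[i]), numeric(1))
  sp <- switch(sparse,
               n11 = .error_rate_num(n11, n10, n01),
               n10 = .error_rate_num(n10, n11, n00),
               n01 = .error_rate_num(n01, n00, n11))
  sparse_count <- switch(sparse, n11 = n11, n10 = n10, n01 = n01)
  df <- data.frame(partner = genes, fisher_p = p, error_rate = sp,
                   sparse_count = as.integer(sparse_count),
                   n_samples = as.integer(pooled_n + k),
                   n11 = as.integer(n11), n10 = as.integer(n10),
                   n01 = as.integer(n01), n00 = as.integer(n00),
                   cancer_types_used = vapply(seq_along(genes), function(i)
                     paste(cnames[used[i, ]], collapse = ","), ""),
                   stringsAsFactors = FALSE)
  if (!keep_all)
    df <- df[df$fisher_p < fisher_cutoff & df$error_rate < error_cutoff, , drop = FALSE]
  df[order(df$fisher_p, df$error_rate, df$partner), , drop = FALSE]
}

.implication_frame <- function(genes) {
  data.frame(partner = genes, fisher_p = numeric(length(genes)),
             error_rate = numeric(length(genes)),
             sparse_count = integer(length(genes)),
             n_samples = integer(length(genes)),
             n11 = integer(length(genes)), n10 = integer(length(genes)),
             n01 = integer(length(genes)), n00 = integer(length(genes)),
             cancer_types_used = character(length(genes)),
             stringsAsFactors = FALSE)
}

#' Scan for Boolean implications anchored on one variable
#'
#' Detects implications of the requested kind between the anchor variable
#' and every partner alteration variable, pooling samples across the
#' supplied cohorts. For `kind = "hi_lo"` the implication is
#' "anchor high => partner deletion low" (mutual exclusion; sparse
#' quadrant anchor=1, partner=1) over partner deletions. For
#' `kind = "hi_hi"` it is "partner amplification high => anchor high"
#' (subset relationship; sparse quadrant partner=1, anchor=0) over
#' partner amplifications, with artificial normal samples appended.
#'
#' Cohort pooling per partner is controlled by `passenger`: a cohort
#' contributes samples for a partner only if the partner's alteration is
#' non-passenger there ("concordant expression change"). With
#' `passenger = NULL` all cohorts contribute.
#'
#' @param cohorts List of `cancer_cohort`s to pool.
#' @param anchor Variable id, e.g. `"IDH1:mut"`.
#' @param kind `"hi_lo"` or `"hi_hi"`.
#' @param passenger Optional passenger annotation `data.frame` (from
#'   [annotate_passengers()], rbind-ed over cohorts) for the partner
#'   alteration class.
#' @param fisher_cutoff Fisher gate (strict), must itself be < 0.05.
#' @param error_cutoff Error-rate gate (strict), default 0.1.
#' @param artificial_normals Count of artificial normals for HI-HI
#'   extraction; `"auto"` (default) uses the pooled sample count.
#' @param partner_class Override the partner alteration class (defaults
#'   to `"del"` for hi_lo, `"amp"` for hi_hi; biomarker mode scans
#'   `"mut"` partners).
#' @param keep_all Return all tested pairs, not only significant ones.
#' @return `data.frame` of class `boolean_implications` with columns
#'   `antecedent`, `consequent`, `kind`, `partner`, `fisher_p`,
#'   `error_rate`, `sparse_count`, `n_samples`, the 2x2 counts and
#'   `cancer_types_used`.
#' @export
scan_implications <- function(cohorts, anchor, kind = c("hi_lo", "hi_hi"),
                              passenger = NULL, fisher_cutoff = 0.05,
                              error_cutoff = 0.1, artificial_normals = "auto",
                              partner_class = NULL, keep_all = FALSE) {
  kind <- match.arg(kind)
  partner_class <- partner_class %||% switch(kind, hi_lo = "del", hi_hi = "amp")
  anchor_present <- any(vapply(cohorts, function(co)
    any(cohort_variable(co, anchor)), TRUE))
  if (!anchor_present)
    warning("anchor ", anchor, " absent from every cohort", call. = FALSE)
  partner_ok <- NULL
  if (!is.null(passenger) && nrow(passenger)) {
    pa <- passenger[passenger$alteration == partner_class, , drop = FALSE]
    cn <- vapply(cohorts, function(x) x$cancer_type, "")
    genes <- sort(unique(pa$gene))
    partner_ok <- matrix(FALSE, length(genes), length(cn),
                         dimnames = list(genes, cn))
    pa <- pa[pa$cancer_type %in% cn, , drop = FALSE]
    partner_ok[cbind(match(pa$gene, genes), match(pa$cancer_type, cn))] <-
      !pa$is_passenger
  }
  res <- .scan_engine(cohorts, anchor,
                      partner_class = partner_class,
                      sparse = if (kind == "hi_lo") "n11" else "n01",
                      partner_ok = partner_ok,
                      fisher_cutoff = fisher_cutoff, error_cutoff = error_cutoff,
                      artificial_normals = if (kind == "hi_hi") artificial_normals else 0,
                      keep_all = keep_all)
  pclass_id <- function(g) var_id(g, partner_class)
  if (kind == "hi_lo") {
    res$antecedent <- rep(anchor, nrow(res))
    res$consequent <- pclass_id(res$partner)
  } else {
    res$antecedent <- pclass_id(res$partner)
    res$consequent <- rep(anchor, nrow(res))
  }
  res$kind <- rep(if (kind == "hi_lo") "HI_LO" else "HI_HI", nrow(res))
  res <- res[, c("antecedent", "consequent", "kind", "partner", "fisher_p",
                 "error_rate", "sparse_count", "n_samples",
                 "n11", "n10", "n01", "n00", "cancer_types_used")]
  class(res) <- c("boolean_implications", "data.frame")
  res
}

#' Calibrate the Fisher cutoff by permutation FDR
#'
#' For each cutoff in `cutoff_grid`, counts observed significant
#' implications (both gates) and the mean count under a null in which the
#' sample labels of every variable are permuted independently; the FDR
#' estimate is null mean / observed (0/0 counts as 0). The chosen cutoff
#' is the largest grid value with estimated FDR below `fdr_target`, never
#' exceeding 0.05; if no grid value qualifies the smallest grid value is
#' chosen.
#'
#' @param cohorts List of `cancer_cohort`s.
#' @param anchors Anchor variable ids to scan (e.g. all recurrent
#'   mutations).
#' @param kind `"hi_lo"` or `"hi_hi"`.
#' @param cutoff_grid Candidate Fisher cutoffs (all <= 0.05).
#' @param n_permutations Number of null permutations (>= 10).
#' @param seed RNG seed recorded in the result.
#' @param error_cutoff Error-rate gate, default 0.1.
#' @param fdr_target Target FDR, default 0.05.
#' @return List of class `fdr_calibration` with the grid, observed and
#'   null mean counts, per-cutoff FDR estimates and the chosen cutoff.
#' @export
calibrate_fdr <- function(cohorts, anchors, kind = c("hi_lo", "hi_hi"),
                          cutoff_grid = c(0.05, 0.02, 0.01, 0.005, 0.002, 0.001),
                          n_permutations = 100, seed = 1,
                          error_cutoff = 0.1, fdr_target = 0.05) {
  kind <- match.arg(kind)
  stopifnot(n_permutations >= 10, all(cutoff_grid <= 0.05), all(cutoff_grid > 0))
  cutoff_grid <- sort(cutoff_grid, decreasing = TRUE)

  count_at <- function(chs) {
    res <- do.call(rbind, lapply(anchors, function(a)
      scan_implications(chs, a, kind, fisher_cutoff = 0.05,
                        error_cutoff = error_cutoff, keep_all = TRUE)))
    pass_err <- res$error_rate < error_cutoff
    vapply(cutoff_grid, function(cc) sum(res$fisher_p < cc & pass_err), 0)
  }
  observed <- count_at(cohorts)

  permute_cohorts <- function(chs) {
    lapply(chs, function(co) {
      perm_rows <- function(m) {
        if (is.null(m)) return(NULL)
        t(apply(m, 1, function(r) r[sample.int(length(r))]))
      }
      co$mut <- perm_rows(co$mut)
      co$amp <- perm_rows(co$amp)
      co$del <- perm_rows(co$del)
      co
    })
  }
  null_counts <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(i) count_at(permute_cohorts(cohorts)),
           numeric(length(cutoff_grid)))
  })
  null_mean <- if (is.matrix(null_counts)) rowMeans(null_counts) else mean(null_counts)
  fdr <- ifelse(observed == 0, ifelse(null_mean == 0, 0, 1), null_mean / observed)
  ok <- which(fdr < fdr_target)
  chosen <- if (length(ok)) cutoff_grid[min(ok)] else min(cutoff_grid)
  chosen <- min(chosen, 0.05)
  structure(list(cutoff_grid = cutoff_grid, observed_counts = observed,
                 null_mean_counts = null_mean, fdr_at_cutoff = fdr,
                 chosen_cutoff = chosen, n_permutations = n_permutations,
                 seed = seed),
            class = "fdr_calibration")
}

#' @export
print.fdr_calibration <- function(x, ...) {
  cat("<fdr_calibration> chosen cutoff:", x$chosen_cutoff, "\n")
  print(data.frame(cutoff = x$cutoff_grid, observed = x$observed_counts,
                   null_mean = x$null_mean_counts, fdr = x$fdr_at_cutoff))
  invisible(x)
}
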