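## Conversion of raw tables into per-cancer Boolean alteration matrices and
## the aligned expression matrix -- the cohort object every downstream
## statistic runs on.

#' Construct a cancer cohort
#'
#' Bundles one cancer type's Boolean alteration matrices (mutation,
#' amplification, deletion; genes x samples, logical) with its log2
#' expression matrix and a gene -> chromosome map, all aligned on a shared
#' sample axis. Cohorts without copy-number data (e.g. an AML-like cohort)
#' may pass `amp = NULL, del = NULL`; such cohorts still contribute
#' mutation and expression evidence.
#'
#' @param cancer_type Cohort label.
#' @param samples Character vector of sample ids (the shared axis).
#' @param mut,amp,del Logical matrices, genes x samples. Columns are
#'   reordered to `samples`; missing matrices may be `NULL`.
#' @param expr Numeric log2 expression matrix (genes x samples).
#' @param gene_chrom Named character vector mapping gene symbol to
#'   chromosome (used for same-chromosome exclusion rules).
#' @return An object of class `cancer_cohort`.
#' @export
cancer_cohort <- function(cancer_type, samples, mut, expr,
                          amp = NULL, del = NULL, gene_chrom = NULL) {
  samples <- as.character(samples)
  stopifnot(length(samples) > 0, !anyDuplicated(samples))
  align <- function(m, what) {
    if (is.null(m)) return(NULL)
    if (!all(samples %in% colnames(m)))
      stop_format("cohort ", cancer_type, ": ", what, " matrix lacks sample(s) ",
                  paste(setdiff(samples, colnames(m)), collapse = ", "))
    m <- m[, samples, drop = FALSE]
    m
  }
  mut <- align(mut, "mutation"); amp <- align(amp, "amp"); del <- align(del, "del")
  expr <- align(expr, "expression")
  if (!is.null(amp) && !is.null(del)) {
    shared <- intersect(rownames(amp), rownames(del))
    if (length(shared)) {
      conflict <- amp[shared, , drop = FALSE] & del[shared, , drop = FALSE]
      if (any(conflict))
        stop_format("cohort ", cancer_type,
                    ": amp and del both TRUE for the same (gene, sample)")
    }
  }
  structure(list(cancer_type = as.character(cancer_type), samples = samples,
                 mut = mut, amp = amp, del = del, expr = expr,
                 gene_chrom = gene_chrom),
            class = "cancer_cohort")
}

#' @export
print.cancer_cohort <- function(x, ...) {
  cat("<cancer_cohort> ", x$cancer_type, ": ", length(x$samples), " samples; ",
      if (is.null(x$mut)) 0L else nrow(x$mut), " mutated genes; ",
      if (is.null(x$amp)) "no" else nrow(x$amp), " amp / ",
      if (is.null(x$del)) "no" else nrow(x$del), " del genes; ",
      if (is.null(x$expr)) "no expression" else paste0(nrow(x$expr), " expressed genes"),
      "\n", sep = "")
  invisible(x)
}

#' Booleanize a mutation table
#'
#' One logical row per mutated gene, TRUE iff the sample carries any
#' mutation of that gene. With `per_type = TRUE` additional rows
#' `GENE:<type>` are emitted, one per observed mutation type, mirroring
#' the per-type Boolean variables used for type-specific runs.
#'
#' @param mut_table A `mutation_table`.
#' @param samples Sample universe (columns of the result); samples absent
#'   from the table get all-FALSE columns.
#' @param per_type Add per-mutation-type variables.
#' @return Logical matrix (variables x samples).
#' @export
booleanize_mutations <- function(mut_table, samples, per_type = FALSE) {
  samples <- as.character(samples)
  stopifnot(length(samples) > 0)
  tab <- mut_table[mut_table$sample_id %in% samples, , drop = FALSE]
  vars <- unique(tab$gene)
  if (per_type)
    vars <- c(vars, unique(paste0(tab$gene, ":", tab$mutation_type)))
  m <- matrix(FALSE, nrow = length(vars), ncol = length(samples),
              dimnames = list(vars, samples))
  if (nrow(tab)) {
    m[cbind(match(tab$gene, vars), match(tab$sample_id, samples))] <- TRUE
    if (per_type) {
      tv <- paste0(tab$gene, ":", tab$mutation_type)
      m[cbind(match(tv, vars), match(tab$sample_id, samples))] <- TRUE
    }
  }
  m
}

#' Filter copy-number segments on magnitude and marker support
#'
#' Retains segments with `|segment_mean| > 0.3` (strict) and
#' `n_markers >= 5`, for tumour and normal segments alike. Idempotent.
#'
#' @param seg A `segment_table`.
#' @param min_abs_mean Magnitude threshold (strict), default 0.3.
#' @param min_markers Minimum marker count (inclusive), default 5.
#' @return Filtered `segment_table`.
#' @export
filter_segments <- function(seg, min_abs_mean = 0.3, min_markers = 5L) {
  keep <- abs(seg$segment_mean) > min_abs_mean & seg$n_markers >= min_markers
  out <- seg[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

.seg_granges <- function(seg) {
  GenomicRanges::GRanges(seqnames = seg$chrom,
                         ranges = IRanges::IRanges(start = seg$start + 1, end = seg$end))
}

#' Remove tumour segments explained by the matched normal
#'
#' A tumour segment is dropped iff the fraction of its length covered by
#' the union of same-sample, same-chromosome normal segments exceeds 0.5
#' (strict). Tumour samples without any normal record are kept unchanged.
#'
#' @param tumour_seg,normal_seg Pre-filtered `segment_table`s (see
#'   [filter_segments()]); samples are matched by `sample_id`.
#' @param max_overlap Coverage fraction above which a tumour segment is
#'   considered germline-explained; default 0.5.
#' @return The surviving tumour segments.
#' @export
subtract_normal <- function(tumour_seg, normal_seg, max_overlap = 0.5) {
  if (nrow(tumour_seg) == 0 || nrow(normal_seg) == 0) return(tumour_seg)
  keep <- rep(TRUE, nrow(tumour_seg))
  no_normal <- character(0)
  for (s in unique(tumour_seg$sample_id)) {
    ti <- which(tumour_seg$sample_id == s)
    ni <- which(normal_seg$sample_id == s)
    if (!length(ni)) { no_normal <- c(no_normal, s); next }
    tg <- .seg_granges(tumour_seg[ti, , drop = FALSE])
    ng <- GenomicRanges::reduce(.seg_granges(normal_seg[ni, , drop = FALSE]))
    ov <- GenomicRanges::findOverlaps(tg, ng)
    if (!length(ov)) next
    w <- IRanges::width(IRanges::pintersect(tg[S4Vectors::queryHits(ov)],
                                            ng[S4Vectors::subjectHits(ov)]))
    cov <- tapply(w, S4Vectors::queryHits(ov), sum)
    frac <- as.numeric(cov) / IRanges::width(tg[as.integer(names(cov))])
    keep[ti[as.integer(names(cov))]] <- frac <= max_overlap
  }
  if (length(no_normal))
    .misl_log("subtract_normal: no normal record for sample(s) ",
              paste(no_normal, collapse = ", "), "; kept unchanged")
  out <- tumour_seg[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call gene-level amplification and deletion from segments
#'
#' A gene is amplified in a sample iff it overlaps (half-open
#' intersection, at least `min_fraction` of the gene, default any overlap
#' of >= 1 bp) a retained segment with `segment_mean > 0.3`, and deleted
#' iff it overlaps one with `segment_mean < -0.3`. A gene overlapping both
#' an amplified and a deleted segment in the same sample is ambiguous:
#' both calls are set FALSE and the event is logged.
#'
#' @param seg A filtered, normal-subtracted `segment_table`.
#' @param model A `gene_model`.
#' @param samples Sample universe; defaults to the samples present in
#'   `seg`.
#' @param min_abs_mean Call threshold on `|segment_mean|` (strict),
#'   default 0.3.
#' @param min_fraction Minimum fraction of the gene covered by the segment
#'   (0 keeps the >= 1 bp rule).
#' @return `list(amp = , del = )` of logical matrices (genes x samples).
#' @export
call_gene_cna <- function(seg, model, samples = NULL, min_abs_mean = 0.3,
                          min_fraction = 0) {
  samples <- samples %||% unique(seg$sample_id)
  genes <- model$gene
  amp <- matrix(FALSE, length(genes), length(samples), dimnames = list(genes, samples))
  del <- amp
  if (nrow(seg)) {
    gg <- GenomicRanges::GRanges(seqnames = model$chrom,
                                 ranges = IRanges::IRanges(start = model$start + 1,
                                                           end = model$end))
    n_ambiguous <- 0L
    for (s in intersect(unique(seg$sample_id), samples)) {
      ss <- seg[seg$sample_id == s & abs(seg$segment_mean) > min_abs_mean, , drop = FALSE]
      if (!nrow(ss)) next
      sg <- .seg_granges(ss)
      ov <- GenomicRanges::findOverlaps(gg, sg)
      if (!length(ov)) next
      qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
      if (min_fraction > 0) {
        w <- IRanges::width(IRanges::pintersect(gg[qh], sg[sh]))
        ok <- w / IRanges::width(gg[qh]) >= min_fraction
        qh <- qh[ok]; sh <- sh[ok]
      }
      is_amp <- ss$segment_mean[sh] > 0
      a_genes <- unique(qh[is_amp]); d_genes <- unique(qh[!is_amp])
      both <- intersect(a_genes, d_genes)
      n_ambiguous <- n_ambiguous + length(both)
      amp[setdiff(a_genes, both), s] <- TRUE
      del[setdiff(d_genes, both), s] <- TRUE
    }
    if (n_ambiguous > 0)
      .misl_log("call_gene_cna: ", n_ambiguous,
                " ambiguous amp+del gene call(s) set to FALSE")
  }
  list(amp = amp, del = del)
}

#' Annotate passenger copy-number alterations
#'
#' A deletion of gene A is a passenger in a cohort unless A's expression
#' is significantly lower in deleted samples (Welch two-sided t-test
#' p < `p_cutoff` with the mean lower in carriers) with fold difference
#' `2^|delta log2 mean| > fold_cutoff`; amplifications are symmetric with
#' higher expression in carriers. Genes with fewer than two samples on
#' either side of the split, or absent from the expression matrix, are
#' passengers by convention.
#'
#' @param cohort A `cancer_cohort` with expression data.
#' @param alteration `"amp"` or `"del"`.
#' @param fold_cutoff Fold-difference gate (strict), default 1.2.
#' @param p_cutoff t-test p gate (strict), default 0.05.
#' @return `data.frame` with columns `cancer_type`, `gene`, `alteration`,
#'   `is_passenger`, `p_value`, `fold_difference`.
#' @export
annotate_passengers <- function(cohort, alteration = c("del", "amp"),
                                fold_cutoff = 1.2, p_cutoff = 0.05) {
  alteration <- match.arg(alteration)
  m <- cohort[[alteration]]
  if (is.null(m) || nrow(m) == 0)
    return(data.frame(cancer_type = character(0), gene = character(0),
                      alteration = character(0), is_passenger = logical(0),
                      p_value = numeric(0), fold_difference = numeric(0)))
  genes <- rownames(m)
  res <- data.frame(cancer_type = cohort$cancer_type, gene = genes,
                    alteration = alteration, is_passenger = TRUE,
                    p_value = NA_real_, fold_difference = NA_real_,
                    stringsAsFactors = FALSE)
  in_expr <- genes %in% rownames(cohort$expr)
  n1 <- rowSums(m)
  n2 <- ncol(m) - n1
  testable <- which(in_expr & n1 >= 2 & n2 >= 2)
  if (length(testable)) {
    ## per-gene Welch t-test with a gene-specific carrier split, done in
    ## closed form over the whole matrix at once
    e <- cohort$expr[genes[testable], , drop = FALSE]
    mm <- m[testable, , drop = FALSE]
    n1t <- n1[testable]; n2t <- n2[testable]
    s1 <- rowSums(e * mm); s2 <- rowSums(e) - s1
    q1 <- rowSums(e^2 * mm); q2 <- rowSums(e^2) - q1
    m1 <- s1 / n1t; m2 <- s2 / n2t
    v1 <- (q1 - n1t * m1^2) / (n1t - 1)
    v2 <- (q2 - n2t * m2^2) / (n2t - 1)
    v1 <- pmax(v1, 0); v2 <- pmax(v2, 0)
    se2 <- v1 / n1t + v2 / n2t
    tt <- (m1 - m2) / sqrt(se2)
    df <- se2^2 / ((v1 / n1t)^2 / (n1t - 1) + (v2 / n2t)^2 / (n2t - 1))
    p <- 2 * stats::pt(abs(tt), df, lower.tail = FALSE)
    p[se2 == 0] <- ifelse(m1[se2 == 0] == m2[se2 == 0], 1, 0)
    d <- m1 - m2                       # carrier minus rest, log2 units
    fold <- 2^abs(d)
    concord <- if (alteration == "del") d < 0 else d > 0
    res$p_value[testable] <- p
    res$fold_difference[testable] <- fold
    res$is_passenger[testable] <- !(p < p_cutoff & fold > fold_cutoff & concord)
  }
  res
}
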