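## Validation statistics for pooled shRNA screens: dropout hit calling,
## mutation-stratified essentiality scoring, preranked gene-set
## enrichment, set-overlap tests and same-pathway enrichment with
## redundancy pruning.

#' Call dropout hits from a pooled shRNA screen
#'
#' Per-construct drop-out ratio = treated / baseline barcode reads.
#' Constructs with baseline reads below `min_reads` are excluded; genes
#' with fewer than `min_constructs` surviving constructs are excluded. A
#' construct qualifies if its ratio is below `1 - reduction` (default:
#' >20% read reduction); a gene is a hit if at least
#' `min_hit_constructs` constructs qualify and the mean ratio over its
#' qualifying constructs is below `mean_ratio`.
#'
#' @param screen A `screen_table` with read-count columns.
#' @param baseline_condition,treated_condition Column names.
#' @param min_reads Baseline read floor (constructs below are dropped),
#'   default 100.
#' @param min_constructs Minimum surviving constructs per gene, default 3.
#' @param reduction Minimum fractional read reduction for a construct to
#'   qualify (strict), default 0.2.
#' @param mean_ratio Gate on the mean ratio over qualifying constructs
#'   (strict), default 0.6. Set to `Inf` to disable.
#' @param min_hit_constructs Minimum qualifying constructs, default 2.
#'   The two gates are applied conjunctively; each can be relaxed
#'   independently.
#' @return Sorted character vector of hit genes.
#' @export
call_dropout_hits <- function(screen, baseline_condition, treated_condition,
                              min_reads = 100, min_constructs = 3L,
                              reduction = 0.2, mean_ratio = 0.6,
                              min_hit_constructs = 2L) {
  .require_cols(screen, c(baseline_condition, treated_condition), "screen table")
  base <- screen[[baseline_condition]]
  trt <- screen[[treated_condition]]
  keep <- is.finite(base) & base >= min_reads
  s <- screen[keep, , drop = FALSE]
  ratio <- s[[treated_condition]] / s[[baseline_condition]]
  n_constructs <- table(s$gene)
  genes <- names(n_constructs)[n_constructs >= min_constructs]
  hits <- vapply(genes, function(g) {
    r <- ratio[s$gene == g]
    q <- r[r < (1 - reduction)]
    length(q) >= min_hit_constructs && mean(q) < mean_ratio
  }, TRUE)
  sort(genes[hits])
}

#' Rank genes by mutation-stratified essentiality
#'
#' For per-cell-line shRNA essentiality scores (lower = more depleted =
#' more essential), each construct is tested mutated-vs-wild-type with a
#' Welch t-test; per gene the construct with the smallest p is picked and
#' the gene score is `-log10(p) * (mean_wildtype - mean_mutated)`, so
#' genes preferentially depleted in mutant lines receive strong positive
#' scores. Genes with fewer than `min_constructs` constructs are removed.
#'
#' @param screen A `screen_table` whose numeric columns are cell lines.
#' @param mutated_lines,wildtype_lines Column-name sets (>= 2 each).
#' @param min_constructs Minimum constructs per gene, default 3.
#' @return `data.frame` of class `essentiality_ranking`, sorted by
#'   descending score (ties broken by gene symbol): columns `gene`,
#'   `score`, `p_value`, `mean_diff` (wild-type minus mutated).
#' @export
score_mutation_essentiality <- function(screen, mutated_lines, wildtype_lines,
                                        min_constructs = 3L) {
  if (length(mutated_lines) < 2 || length(wildtype_lines) < 2)
    stop_format("need >= 2 cell lines per group")
  .require_cols(screen, c(mutated_lines, wildtype_lines), "screen table")
  n_constructs <- table(screen$gene)
  keep_genes <- names(n_constructs)[n_constructs >= min_constructs]
  s <- screen[screen$gene %in% keep_genes, , drop = FALSE]
  if (!nrow(s))
    return(structure(data.frame(gene = character(0), score = numeric(0),
                                p_value = numeric(0), mean_diff = numeric(0)),
                     class = c("essentiality_ranking", "data.frame")))
  x <- as.matrix(s[, c(mutated_lines, wildtype_lines), drop = FALSE])
  w <- welch_rows(x, seq_along(mutated_lines),
                  length(mutated_lines) + seq_along(wildtype_lines))
  ## per gene: construct with the smallest p
  ord <- order(s$gene, w$p)
  first <- ord[!duplicated(s$gene[ord])]
  p <- pmax(w$p[first], 1e-300)
  diff_wt_mut <- w$mean2[first] - w$mean1[first]
  out <- data.frame(gene = s$gene[first],
                    score = -log10(p) * diff_wt_mut,
                    p_value = w$p[first], mean_diff = diff_wt_mut,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("essentiality_ranking", "data.frame")
  out
}

## Weighted Kolmogorov-Smirnov running-sum enrichment score for a sorted
## score vector and a logical hit mask. Hit increments are proportional
## to |score|^weight, miss decrements are uniform; the ES is the running
## sum at its maximum absolute deviation.
.gsea_es <- function(scores, hit, weight = 1) {
  N <- length(scores); Nh <- sum(hit)
  w <- abs(scores[hit])^weight
  tot <- sum(w)
  step_hit <- if (tot > 0) w / tot else rep(1 / Nh, Nh)
  inc <- numeric(N)
  inc[hit] <- step_hit
  inc[!hit] <- -1 / (N - Nh)
  run <- cumsum(inc)
  run[which.max(abs(run))]
}

#' Preranked gene-set enrichment
#'
#' GSEA-style weighted running-sum statistic on an essentiality ranking.
#' The null is generated by gene-label permutation (random sets of the
#' same size); the normalised score divides the ES by the mean magnitude
#' of same-sign null scores, and the nominal p is estimated against the
#' same-sign portion of the null.
#'
#' @param ranking An `essentiality_ranking` (or data.frame with `gene`
#'   and `score`), already sorted.
#' @param gene_set Character vector of member genes.
#' @param n_permutations Null permutations, default 2000.
#' @param weight Score-weighting exponent, default 1.
#' @param seed RNG seed.
#' @param min_overlap Minimum `|gene_set intersect ranking|`, default 25
#'   (smaller overlaps make the statistic unstable and are refused).
#' @return List of class `enrichment_result`: `es`, `nes`, `p_value`,
#'   `n_overlap`, `n_permutations`, `seed`.
#' @export
preranked_enrichment <- function(ranking, gene_set, n_permutations = 2000L,
                                 weight = 1, seed = 1L, min_overlap = 25L) {
  scores <- ranking$score
  genes <- ranking$gene
  hit <- genes %in% gene_set
  n_overlap <- sum(hit)
  if (n_overlap < min_overlap)
    stop_format("gene-set overlap with the ranking is ", n_overlap,
                " (< minimum overlap ", min_overlap, ")")
  if (n_overlap == length(genes))
    stop_format("gene set covers the whole ranking")
  es <- .gsea_es(scores, hit, weight)
  N <- length(genes)
  null_es <- with_seed(seed, vapply(seq_len(n_permutations), function(i) {
    h <- logical(N)
    h[sample.int(N, n_overlap)] <- TRUE
    .gsea_es(scores, h, weight)
  }, numeric(1)))
  same_sign <- if (es >= 0) null_es[null_es >= 0] else null_es[null_es < 0]
  nes <- if (length(same_sign)) es / mean(abs(same_sign)) else sign(es) * Inf
  p <- if (es >= 0) {
    (1 + sum(same_sign >= es)) / (1 + length(same_sign))
  } else {
    (1 + sum(same_sign <= es)) / (1 + length(same_sign))
  }
  structure(list(es = es, nes = nes, p_value = p, n_overlap = n_overlap,
                 n_permutations = n_permutations, seed = seed),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("<enrichment_result> ES =", format(x$es, digits = 3),
      " NES =", format(x$nes, digits = 3),
      " p =", format(x$p_value, digits = 3),
      " (", x$n_overlap, "genes,", x$n_permutations, "permutations )\n")
  invisible(x)
}

#' Fisher overlap test of two gene sets
#'
#' @param list_a,list_b Gene sets (subsets of `universe`).
#' @param universe The gene universe both sets were drawn from.
#' @return List with `overlap` and two-sided Fisher `p`.
#' @export
overlap_test <- function(list_a, list_b, universe) {
  if (!length(universe)) stop_format("empty universe")
  universe <- unique(universe)
  a <- unique(intersect(list_a, universe))
  b <- unique(intersect(list_b, universe))
  n11 <- length(intersect(a, b))
  tab <- c(n11 = n11, n10 = length(a) - n11, n01 = length(b) - n11,
           n00 = length(universe) - length(a) - length(b) + n11)
  list(overlap = n11, p = fisher_p(tab))
}

#' Same-pathway enrichment of candidate partners
#'
#' Tests whether the candidate partners of a mutation over-represent
#' pathways that contain the mutated gene itself. Pathways with more than
#' `max_size` members are excluded before testing; the p-value is
#' hypergeometric (over-representation). Redundant results are pruned:
#' among pathways with identical candidate-overlap sets only the
#' smallest p survives, and a pathway whose overlap set is strictly
#' contained in another retained pathway's overlap set is removed.
#'
#' @param candidates Candidate partner genes.
#' @param mutation_gene The mutated gene anchoring the pathway gate.
#' @param pathways Named list of gene sets (see [read_gmt()]).
#' @param universe Gene universe (must contain `candidates`).
#' @param max_size Pathway size cap, default 500.
#' @param p_cutoff Significance gate applied before pruning, default
#'   0.05.
#' @return `data.frame` with `pathway`, `n_pathway`, `overlap`,
#'   `overlap_genes` (comma-joined), `p_value`, sorted by p.
#' @export
same_pathway_enrichment <- function(candidates, mutation_gene, pathways,
                                    universe, max_size = 500L, p_cutoff = 0.05) {
  mutation_gene <- norm_symbol(mutation_gene)
  universe <- unique(norm_symbol(universe))
  candidates <- unique(intersect(norm_symbol(candidates), universe))
  keep <- vapply(pathways, function(p)
    mutation_gene %in% norm_symbol(p) && length(p) <= max_size, TRUE)
  pathways <- pathways[keep]
  if (!length(pathways)) return(.empty_pathway_frame())
  rows <- lapply(names(pathways), function(nm) {
    pg <- intersect(norm_symbol(pathways[[nm]]), universe)
    ov <- intersect(candidates, pg)
    p <- stats::phyper(length(ov) - 1, length(pg), length(universe) - length(pg),
                       length(candidates), lower.tail = FALSE)
    data.frame(pathway = nm, n_pathway = length(pg), overlap = length(ov),
               overlap_genes = paste(sort(ov), collapse = ","),
               p_value = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res <- res[res$p_value < p_cutoff & res$overlap > 0, , drop = FALSE]
  if (!nrow(res)) return(.empty_pathway_frame())
  res <- res[order(res$p_value, res$pathway), , drop = FALSE]
  ## identical overlap sets: keep the smallest p (first after sorting)
  res <- res[!duplicated(res$overlap_genes), , drop = FALSE]
  ## strict containment: drop the contained pathway
  sets <- strsplit(res$overlap_genes, ",", fixed = TRUE)
  contained <- vapply(seq_along(sets), function(i)
    any(vapply(seq_along(sets), function(j)
      i != j && length(sets[[i]]) < length(sets[[j]]) &&
        all(sets[[i]] %in% sets[[j]]), TRUE)), TRUE)
  res <- res[!contained, , drop = FALSE]
  rownames(res) <- NULL
  res
}

.empty_pathway_frame <- function() {
  data.frame(pathway = character(0), n_pathway = integer(0),
             overlap = integer(0), overlap_genes = character(0),
             p_value = numeric(0), stringsAsFactors = FALSE)
}
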