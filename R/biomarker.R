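## Reverse mode: from a drug's inhibited gene set to the genomic
## alterations predicted to confer sensitivity, and the Fisher overlap
## score of those predictions against cell-line pharmacology.

#' Predict genetic biomarkers of drug sensitivity
#'
#' For each gene Y inhibited by `drug`, scans for alterations X with a
#' HI-LO implication "X => Y NOT deleted" (mutual exclusion of X and Y
#' deletion) or a HI-HI implication "Y amplified => X" (with artificial
#' normals). The scan pools samples from cancers where Y's alteration is
#' non-passenger intersected with cancers where X is recurrent
#' (>= `cfg$recurrence_fraction`). Alterations on Y's chromosome are
#' removed. A retained X must finally show Y overexpressed in X-altered
#' versus unaltered samples of the cancer of interest (Welch t-test
#' p < `cfg$overexpr_p`, higher mean in carriers).
#'
#' @param drug Drug name present in `drug_gene`.
#' @param drug_gene A `drug_gene_table`.
#' @param cohorts List of `cancer_cohort`s.
#' @param cancer_of_interest Cancer whose expression drives the final
#'   filter.
#' @param cfg A `misl_config`.
#' @param include_cna Also scan amp/del variables as candidate biomarkers
#'   (default scans gene-level mutations only).
#' @return `data.frame` of class `biomarker_predictions` with one row per
#'   (inhibited gene, biomarker) pair and the evidence trail.
#' @export
predict_biomarkers <- function(drug, drug_gene, cohorts, cancer_of_interest,
                               cfg = misl_config(), include_cna = FALSE) {
  hits <- drug_gene[drug_gene$drug == drug & drug_gene$interaction == "inhibits", ]
  if (!nrow(hits))
    stop_format("drug '", drug, "' has no inhibited genes; available drugs: ",
                paste(unique(drug_gene$drug), collapse = ", "))
  cnames <- vapply(cohorts, function(x) x$cancer_type, "")
  if (!(cancer_of_interest %in% cnames))
    stop_format("unknown cancer of interest '", cancer_of_interest, "'")
  coi <- cohorts[[match(cancer_of_interest, cnames)]]
  gene_chrom <- coi$gene_chrom
  out <- list()
  for (Y in unique(hits$gene)) {
    for (mode in c("del", "amp")) {
      anchor <- var_id(Y, mode)
      pass <- .pool_passengers(cohorts, mode, cfg)
      yp <- pass[pass$gene == Y, , drop = FALSE]
      ok_cancers <- yp$cancer_type[!yp$is_passenger]
      if (!length(ok_cancers)) next
      classes <- c("mut", if (include_cna) c("amp", "del"))
      for (cl in classes) {
        ## per-partner cohort gate: X recurrent in the cancer AND Y
        ## non-passenger there
        univ <- sort(unique(unlist(lapply(cohorts, function(co) {
          m <- co[[cl]]
          if (is.null(m)) character(0) else rownames(m)
        }))))
        if (!length(univ)) next
        partner_ok <- vapply(cohorts, function(co) {
          m <- co[[cl]]
          inc <- co$cancer_type %in% ok_cancers
          if (is.null(m) || !inc) return(stats::setNames(rep(FALSE, length(univ)), univ))
          f <- rep(0, length(univ)); names(f) <- univ
          f[rownames(m)] <- rowMeans(m)
          f >= cfg$recurrence_fraction
        }, logical(length(univ)))
        partner_ok <- matrix(partner_ok, nrow = length(univ),
                             dimnames = list(univ, cnames))
        ## anchor occupies the rows of the pooled 2x2; for the HI-HI
        ## "Y amplified => X" implication the forbidden cell is therefore
        ## (anchor=1, partner=0) = n10
        imp <- .scan_engine(cohorts, anchor, partner_class = cl,
                            sparse = if (mode == "del") "n11" else "n10",
                            partner_ok = partner_ok,
                            fisher_cutoff = cfg$fisher_cutoff,
                            error_cutoff = cfg$error_cutoff,
                            artificial_normals = if (mode == "amp") cfg$artificial_normal_k else 0)
        if (!nrow(imp)) next
        imp <- imp[imp$partner != Y, , drop = FALSE]
        ## same-chromosome exclusion
        if (!is.null(gene_chrom)) {
          ychr <- gene_chrom[Y]
          if (!is.na(ychr))
            imp <- imp[is.na(gene_chrom[imp$partner]) |
                         gene_chrom[imp$partner] != ychr, , drop = FALSE]
        }
        if (!nrow(imp)) next
        ## Y overexpressed in X-altered vs unaltered samples of the coi
        keep <- logical(nrow(imp)); oe_p <- rep(NA_real_, nrow(imp))
        if (Y %in% rownames(coi$expr)) {
          for (i in seq_len(nrow(imp))) {
            xv <- cohort_variable(coi, var_id(imp$partner[i], cl))
            if (sum(xv) < 2 || sum(!xv) < 2) next
            w <- welch_rows(coi$expr[Y, , drop = FALSE], xv, !xv)
            oe_p[i] <- w$p
            keep[i] <- w$p < cfg$overexpr_p && w$mean1 > w$mean2
          }
        }
        imp <- cbind(imp, overexpression_p = oe_p)[keep, , drop = FALSE]
        if (!nrow(imp)) next
        imp$drug <- drug
        imp$inhibited_gene <- Y
        imp$biomarker <- var_id(imp$partner, cl)
        imp$mode <- if (mode == "del") "deletion" else "amplification"
        imp$kind <- if (mode == "del") "HI_LO" else "HI_HI"
        imp$cancer_type <- cancer_of_interest
        out[[length(out) + 1L]] <- imp
      }
    }
  }
  if (!length(out)) {
    res <- data.frame(drug = character(0), inhibited_gene = character(0),
                      biomarker = character(0), mode = character(0),
                      kind = character(0), cancer_type = character(0),
                      partner = character(0), fisher_p = numeric(0),
                      error_rate = numeric(0), sparse_count = integer(0),
                      n_samples = integer(0), overexpression_p = numeric(0),
                      stringsAsFactors = FALSE)
  } else {
    res <- do.call(rbind, out)
    res <- res[, c("drug", "inhibited_gene", "biomarker", "mode", "kind",
                   "cancer_type", "partner", "fisher_p", "error_rate",
                   "sparse_count", "n_samples", "n11", "n10", "n01", "n00",
                   "cancer_types_used", "overexpression_p")]
    res <- res[order(res$fisher_p, res$error_rate, res$biomarker), , drop = FALSE]
    rownames(res) <- NULL
  }
  class(res) <- c("biomarker_predictions", "data.frame")
  res
}

#' Score biomarker predictions against cell-line pharmacology
#'
#' Cell lines predicted sensitive (harbouring at least one predicted
#' biomarker) are compared against "truly" sensitive lines -- those in
#' the first quartile of IC50 among all tested lines (inclusive
#' linear-interpolation quantile; ties at Q1 included). When several
#' drugs target one family, lines tested with any member are pooled with
#' the per-line minimum IC50. Overlap significance is a two-sided Fisher
#' exact test on the 2x2 of predicted x truly-sensitive.
#'
#' @param predictions `biomarker_predictions` (or anything with a
#'   `biomarker` column of variable ids).
#' @param cell_line_alterations Logical matrix, alteration variable ids x
#'   cell lines.
#' @param pharm A `pharmacology_table`.
#' @param drugs Drug name(s) forming the target family.
#' @param tissues Optional tissue filter applied to the tested lines.
#' @return List of class `sensitivity_evaluation`: predicted and truly
#'   sensitive line sets, overlap, Fisher p, and the Q1 used.
#' @export
evaluate_sensitivity <- function(predictions, cell_line_alterations, pharm,
                                 drugs, tissues = NULL) {
  ph <- pharm[pharm$drug %in% drugs, , drop = FALSE]
  if (!is.null(tissues)) ph <- ph[ph$tissue %in% tissues, , drop = FALSE]
  if (!nrow(ph)) stop_format("no pharmacology rows for drug(s) ",
                             paste(drugs, collapse = ", "))
  ic50 <- tapply(ph$ic50, ph$cell_line, min)
  lines <- names(ic50)
  if (length(lines) < 4)
    stop_format("need >= 4 tested cell lines, got ", length(lines))
  q1 <- unname(stats::quantile(as.numeric(ic50), 0.25, type = 7))
  truly <- lines[ic50 <= q1]
  vars <- intersect(unique(predictions$biomarker), rownames(cell_line_alterations))
  predicted <- if (length(vars)) {
    cols <- intersect(lines, colnames(cell_line_alterations))
    carriers <- colSums(cell_line_alterations[vars, cols, drop = FALSE]) > 0
    cols[carriers]
  } else character(0)
  tab <- c(n11 = length(intersect(predicted, truly)),
           n10 = length(setdiff(predicted, truly)),
           n01 = length(setdiff(truly, predicted)),
           n00 = length(setdiff(lines, union(predicted, truly))))
  structure(list(drugs = drugs, predicted_sensitive = predicted,
                 truly_sensitive = truly, tested_lines = lines,
                 ic50_q1 = q1, overlap = unname(tab[["n11"]]),
                 contingency = tab, fisher_p = fisher_p(tab)),
            class = "sensitivity_evaluation")
}

#' @export
print.sensitivity_evaluation <- function(x, ...) {
  cat("<sensitivity_evaluation> ", paste(x$drugs, collapse = "+"), ": ",
      length(x$predicted_sensitive), " predicted, ", length(x$truly_sensitive),
      " truly sensitive of ", length(x$tested_lines), " lines; overlap ",
      x$overlap, ", Fisher p = ", format(x$fisher_p, digits = 3), "\n", sep = "")
  invisible(x)
}
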