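## The forward pipeline: recurrence gating, deletion and amplification
## arms, passenger exclusion, and the final mutant-overexpression filter,
## producing candidate synthetic-lethal partner lists per
## (mutation, cancer of interest).

#' Pipeline configuration
#'
#' @param recurrence_fraction Minimum mutated-sample fraction for a
#'   cancer to enter the search (inclusive), default 0.025.
#' @param fisher_cutoff Fisher gate for implications (strict); must be
#'   <= 0.05. Use [calibrate_fdr()] to pick a tighter, FDR-controlled
#'   value.
#' @param error_cutoff Sparse-quadrant error-rate gate (strict), default
#'   0.1.
#' @param passenger_fold,passenger_p Passenger-filter gates (fold strict
#'   > 1.2, p strict < 0.05).
#' @param overexpr_p Mutant-overexpression t-test gate (strict), default
#'   0.05; the mutant mean must additionally exceed the wild-type mean.
#' @param artificial_normal_k Artificial-normal count for HI-HI
#'   extraction; `"auto"` (default) uses the pooled tumour sample count.
#' @param fdr_target Target FDR for cutoff calibration, default 0.05.
#' @param exclude_same_chromosome Drop partners on the anchor mutation's
#'   chromosome (the biomarker mode always does; the forward mode does
#'   not by default).
#' @param per_type Use per-mutation-type variables instead of gene-level
#'   mutation variables.
#' @param seed Seed consumed by any stochastic stage (FDR permutations).
#' @return List of class `misl_config`.
#' @export
misl_config <- function(recurrence_fraction = 0.025, fisher_cutoff = 0.05,
                        error_cutoff = 0.1, passenger_fold = 1.2,
                        passenger_p = 0.05, overexpr_p = 0.05,
                        artificial_normal_k = "auto", fdr_target = 0.05,
                        exclude_same_chromosome = FALSE, per_type = FALSE,
                        seed = 1L) {
  stopifnot(recurrence_fraction > 0, recurrence_fraction < 1,
            fisher_cutoff > 0, fisher_cutoff <= 0.05,
            error_cutoff > 0, passenger_fold > 0, passenger_p > 0,
            overexpr_p > 0, fdr_target > 0)
  structure(list(recurrence_fraction = recurrence_fraction,
                 fisher_cutoff = fisher_cutoff, error_cutoff = error_cutoff,
                 passenger_fold = passenger_fold, passenger_p = passenger_p,
                 overexpr_p = overexpr_p, artificial_normal_k = artificial_normal_k,
                 fdr_target = fdr_target,
                 exclude_same_chromosome = exclude_same_chromosome,
                 per_type = per_type, seed = as.integer(seed)),
            class = "misl_config")
}

#' Cancers in which a mutation is recurrent
#'
#' @param mutation Gene symbol (or per-type variable name matching a row
#'   of the cohort mutation matrices).
#' @param cohorts List of `cancer_cohort`s.
#' @param cfg A `misl_config`.
#' @return Character vector of cancer types where the mutated-sample
#'   fraction is at least `cfg$recurrence_fraction`.
#' @export
eligible_cancers <- function(mutation, cohorts, cfg = misl_config()) {
  mutation <- norm_symbol(mutation)
  frac <- vapply(cohorts, function(co) {
    if (is.null(co$mut) || !(mutation %in% rownames(co$mut))) return(0)
    mean(co$mut[mutation, ])
  }, numeric(1))
  vapply(cohorts, function(x) x$cancer_type, "")[frac >= cfg$recurrence_fraction]
}

## Passenger annotations for one alteration class across a cohort list.
.pool_passengers <- function(cohorts, alteration, cfg) {
  do.call(rbind, lapply(cohorts, annotate_passengers, alteration = alteration,
                        fold_cutoff = cfg$passenger_fold,
                        p_cutoff = cfg$passenger_p))
}

## Mutant-vs-wild-type overexpression test for a set of genes in one
## cohort. Returns p, fold (2^(mut - wt), signed direction kept in
## `higher_in_mutant`).
.overexpression_test <- function(cohort, mutation, genes) {
  out <- data.frame(partner = genes, overexpression_p = NA_real_,
                    overexpression_fold = NA_real_, higher_in_mutant = FALSE,
                    stringsAsFactors = FALSE)
  if (!length(genes)) return(out)
  mut_vec <- cohort_variable(cohort, var_id(mutation, "mut"))
  if (sum(mut_vec) < 2 || sum(!mut_vec) < 2) return(out)
  present <- genes %in% rownames(cohort$expr)
  if (!any(present)) return(out)
  e <- cohort$expr[genes[present], , drop = FALSE]
  w <- welch_rows(e, mut_vec, !mut_vec)
  out$overexpression_p[present] <- w$p
  out$overexpression_fold[present] <- 2^(w$mean1 - w$mean2)
  out$higher_in_mutant[present] <- w$mean1 > w$mean2
  out
}

#' Run the synthetic-lethal partner search for one mutation
#'
#' Implements the forward pipeline. Cancers where the mutation is
#' recurrent (>= 2.5% of samples by default) are pooled. The deletion arm
#' reports HI-LO implications "mutation => partner NOT deleted" (mutual
#' exclusion); the amplification arm reports HI-HI implications "partner
#' amplified => mutation present" (subset), with artificial normal
#' augmentation. For each arm a partner's cohort contributes samples only
#' where the partner's alteration is non-passenger (concordant expression
#' change). Surviving partners must finally be differentially
#' overexpressed in mutant versus wild-type samples of the cancer of
#' interest (Welch t-test p below `cfg$overexpr_p`, mutant mean higher).
#'
#' @param mutation Gene symbol of the anchor mutation.
#' @param cancer_of_interest Cancer type whose expression data drives the
#'   final filter (must have expression and the mutation).
#' @param cohorts List of `cancer_cohort`s.
#' @param cfg A `misl_config`.
#' @return `data.frame` of class `sl_candidates`: one row per candidate
#'   partner with the full evidence trail (implication statistics, pooled
#'   2x2 counts, contributing cancers, weakest passenger test among
#'   contributing cancers, overexpression test).
#' @export
run_misl <- function(mutation, cancer_of_interest, cohorts, cfg = misl_config()) {
  mutation <- norm_symbol(mutation)
  cnames <- vapply(cohorts, function(x) x$cancer_type, "")
  if (!(cancer_of_interest %in% cnames))
    stop_format("unknown cancer of interest '", cancer_of_interest, "'")
  coi <- cohorts[[match(cancer_of_interest, cnames)]]
  if (is.null(coi$expr))
    stop_format("cancer of interest '", cancer_of_interest, "' has no expression data")
  elig <- eligible_cancers(mutation, cohorts, cfg)
  if (!length(elig)) {
    warning("mutation ", mutation, " not recurrent in any cohort", call. = FALSE)
    return(.empty_candidates())
  }
  pool <- cohorts[cnames %in% elig]
  anchor <- var_id(mutation, "mut")

  arm <- function(kind, alteration) {
    pass <- .pool_passengers(pool, alteration, cfg)
    imp <- scan_implications(pool, anchor, kind, passenger = pass,
                             fisher_cutoff = cfg$fisher_cutoff,
                             error_cutoff = cfg$error_cutoff,
                             artificial_normals = cfg$artificial_normal_k)
    if (!nrow(imp)) return(cbind(imp, .passenger_cols(imp, pass)))
    cbind(imp, .passenger_cols(imp, pass))
  }
  del_arm <- arm("hi_lo", "del")
  amp_arm <- arm("hi_hi", "amp")
  del_arm$arm <- rep("deletion", nrow(del_arm))
  amp_arm$arm <- rep("amplification", nrow(amp_arm))
  cand <- rbind(del_arm, amp_arm)
  if (cfg$exclude_same_chromosome && nrow(cand) && !is.null(coi$gene_chrom)) {
    mchr <- coi$gene_chrom[mutation]
    if (!is.na(mchr))
      cand <- cand[is.na(coi$gene_chrom[cand$partner]) |
                     coi$gene_chrom[cand$partner] != mchr, , drop = FALSE]
  }
  if (!nrow(cand)) return(.empty_candidates())

  oe <- .overexpression_test(coi, mutation, cand$partner)
  cand$overexpression_p <- oe$overexpression_p
  cand$overexpression_fold <- oe$overexpression_fold
  keep <- !is.na(oe$overexpression_p) & oe$overexpression_p < cfg$overexpr_p &
    oe$higher_in_mutant
  cand <- cand[keep, , drop = FALSE]
  cand$mutation <- rep(mutation, nrow(cand))
  cand$cancer_type <- rep(cancer_of_interest, nrow(cand))
  cand <- cand[order(cand$fisher_p, cand$error_rate, cand$partner), , drop = FALSE]
  rownames(cand) <- NULL
  cand <- cand[, .candidate_cols()]
  class(cand) <- c("sl_candidates", "data.frame")
  cand
}

## Weakest (largest p) passenger evidence among the cancer types that
## actually contributed samples to each implication.
.passenger_cols <- function(imp, pass) {
  if (!nrow(imp))
    return(data.frame(passenger_p = numeric(0), passenger_fold = numeric(0)))
  pp <- pf <- rep(NA_real_, nrow(imp))
  for (i in seq_len(nrow(imp))) {
    cts <- strsplit(imp$cancer_types_used[i], ",", fixed = TRUE)[[1]]
    rows <- pass[pass$gene == imp$partner[i] & pass$cancer_type %in% cts, , drop = FALSE]
    if (nrow(rows)) {
      j <- which.max(rows$p_value)
      pp[i] <- rows$p_value[j]; pf[i] <- rows$fold_difference[j]
    }
  }
  data.frame(passenger_p = pp, passenger_fold = pf)
}

.candidate_cols <- function() {
  c("mutation", "partner", "cancer_type", "arm", "kind", "antecedent",
    "consequent", "fisher_p", "error_rate", "sparse_count", "n_samples",
    "n11", "n10", "n01", "n00", "cancer_types_used", "passenger_p",
    "passenger_fold", "overexpression_p", "overexpression_fold")
}

.empty_candidates <- function() {
  out <- data.frame(mutation = character(0), partner = character(0),
                    cancer_type = character(0), arm = character(0),
                    kind = character(0), antecedent = character(0),
                    consequent = character(0), fisher_p = numeric(0),
                    error_rate = numeric(0), sparse_count = integer(0),
                    n_samples = integer(0), n11 = integer(0), n10 = integer(0),
                    n01 = integer(0), n00 = integer(0),
                    cancer_types_used = character(0), passenger_p = numeric(0),
                    passenger_fold = numeric(0), overexpression_p = numeric(0),
                    overexpression_fold = numeric(0), stringsAsFactors = FALSE)
  class(out) <- c("sl_candidates", "data.frame")
  out
}

#' Summarise targetability across mutations and cancers
#'
#' A mutation with at least one candidate partner is "targetable". For
#' each cancer the summary reports the fraction of recurrent mutations
#' that are targetable and the fraction of samples carrying at least one
#' targetable mutation, plus per-mutation candidate counts and the
#' (mutation, partner) pairs shared across multiple cancers.
#'
#' @param candidates `sl_candidates` rows pooled over runs (possibly
#'   several mutations and cancers).
#' @param cohorts The cohorts the runs were performed on.
#' @param cfg A `misl_config` (for the recurrence threshold).
#' @param mutations_run Mutations that were actually run per cancer; a
#'   named list `cancer_type -> character vector`. Defaults to all
#'   recurrent mutations of each cancer appearing in `candidates`.
#' @return List with `per_cancer` (data.frame), `per_mutation` counts and
#'   `shared_pairs` (pairs found in more than one cancer).
#' @export
targetable_summary <- function(candidates, cohorts, cfg = misl_config(),
                               mutations_run = NULL) {
  cnames <- vapply(cohorts, function(x) x$cancer_type, "")
  cancers <- unique(c(candidates$cancer_type,
                      if (!is.null(mutations_run)) names(mutations_run)))
  per_cancer <- do.call(rbind, lapply(cancers, function(ct) {
    co <- cohorts[[match(ct, cnames)]]
    muts <- if (!is.null(mutations_run)) mutations_run[[ct]]
            else unique(candidates$mutation[candidates$cancer_type == ct])
    targetable <- vapply(muts, function(m)
      any(candidates$mutation == m & candidates$cancer_type == ct), TRUE)
    frac_mut <- if (length(muts)) mean(targetable) else 0
    tgt_muts <- muts[targetable]
    frac_samples <- if (length(tgt_muts) && !is.null(co$mut)) {
      rows <- intersect(tgt_muts, rownames(co$mut))
      if (length(rows)) mean(colSums(co$mut[rows, , drop = FALSE]) > 0) else 0
    } else 0
    data.frame(cancer_type = ct, n_mutations = length(muts),
               n_targetable = sum(targetable),
               fraction_targetable = frac_mut,
               fraction_samples_targetable = frac_samples,
               stringsAsFactors = FALSE)
  }))
  per_mutation <- if (nrow(candidates)) {
    pm <- stats::aggregate(partner ~ mutation + cancer_type,
                           data = as.data.frame(candidates), FUN = length)
    names(pm)[3] <- "n_candidates"
    pm
  } else {
    data.frame(mutation = character(0), cancer_type = character(0),
               n_candidates = integer(0))
  }
  pair <- unique(candidates[, c("mutation", "partner", "cancer_type")])
  pair_key <- paste(pair$mutation, pair$partner)
  shared <- names(which(table(pair_key) > 1))
  list(per_cancer = per_cancer, per_mutation = per_mutation,
       shared_pairs = shared)
}
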