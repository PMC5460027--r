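## Synthetic multi-cancer cohorts, screens and pharmacology tables with
## planted, parameterised structure, plus the ground truth needed for
## recovery scoring. The generator emulates the statistical structure the
## miner assumes: mutual exclusion of partner deletions with the anchor
## mutation (HI-LO), subset amplification within mutant samples (HI-HI),
## CNA-concordant expression shifts for driver-like events, passenger
## CNAs with no expression coupling, and mutant overexpression of planted
## partners in the designated cancer of interest. Planted partner CNAs
## are placed in every cohort except the cancer of interest, mirroring a
## cohort (such as AML) whose copy-number evidence must come from other
## cancers while the expression filter still runs locally.

#' Fixture specification
#'
#' Defaults define the standard fixture: 3 cancers x 200 samples, 500
#' genes, 10 HI-LO and 10 HI-HI planted pairs, 50 passengers, log2 effect
#' size 1.0, expression noise sd 0.4, seed 7. Rates are chosen to be
#' realistic for focal somatic events: anchor mutations in 15% of
#' samples, background amplification/deletion in 5%, planted deletions
#' in 15% of wild-type samples, planted amplifications in 60% of mutant
#' samples, passenger alterations in 10%.
#'
#' @param n_cancers,samples_per_cancer,n_genes Cohort dimensions.
#' @param mutation_freq Per-sample frequency of each planted anchor
#'   mutation.
#' @param amp_freq,del_freq Background per-gene alteration frequencies.
#' @param n_hi_lo,n_hi_hi,n_passengers Planted pair and passenger counts.
#' @param expression_noise_sd Gaussian log2 expression noise sd.
#' @param effect_size Log2 expression shift of non-passenger CNAs and of
#'   the mutant-overexpression signal.
#' @param planted_del_rate Deletion probability per wild-type sample for
#'   HI-LO partners.
#' @param planted_amp_rate Amplification probability per mutant sample
#'   for HI-HI partners.
#' @param leak_rate Probability of a planted alteration violating its
#'   implication (0 forces an empty sparse quadrant).
#' @param passenger_rate Alteration frequency of passenger genes.
#' @param n_background_mutations,background_mutation_freq Extra recurrent
#'   mutation variables without planted partners.
#' @param baseline_expr Baseline log2 expression.
#' @param mutant_overexpression Plant the final-filter signal (set FALSE
#'   to ablate it).
#' @param plant_in_interest Also place planted partner CNAs in the cancer
#'   of interest (default FALSE, see module description).
#' @param seed Master seed; every artifact derives its own stream.
#' @return List of class `fixture_spec`.
#' @export
fixture_spec <- function(n_cancers = 3L, samples_per_cancer = 200L,
                         n_genes = 500L, mutation_freq = 0.15,
                         amp_freq = 0.05, del_freq = 0.05,
                         n_hi_lo = 10L, n_hi_hi = 10L, n_passengers = 50L,
                         expression_noise_sd = 0.4, effect_size = 1.0,
                         planted_del_rate = 0.15, planted_amp_rate = 0.6,
                         leak_rate = 0, passenger_rate = 0.10,
                         n_background_mutations = 20L,
                         background_mutation_freq = 0.05,
                         baseline_expr = 5.0, mutant_overexpression = TRUE,
                         plant_in_interest = FALSE, seed = 7L) {
  spec <- list(n_cancers = as.integer(n_cancers),
               samples_per_cancer = as.integer(samples_per_cancer),
               n_genes = as.integer(n_genes), mutation_freq = mutation_freq,
               amp_freq = amp_freq, del_freq = del_freq,
               n_hi_lo = as.integer(n_hi_lo), n_hi_hi = as.integer(n_hi_hi),
               n_passengers = as.integer(n_passengers),
               expression_noise_sd = expression_noise_sd,
               effect_size = effect_size,
               planted_del_rate = planted_del_rate,
               planted_amp_rate = planted_amp_rate, leak_rate = leak_rate,
               passenger_rate = passenger_rate,
               n_background_mutations = as.integer(n_background_mutations),
               background_mutation_freq = background_mutation_freq,
               baseline_expr = baseline_expr,
               mutant_overexpression = isTRUE(mutant_overexpression),
               plant_in_interest = isTRUE(plant_in_interest),
               seed = as.integer(seed))
  stopifnot(spec$n_cancers >= 1, spec$samples_per_cancer >= 4,
            all(vapply(spec[c("mutation_freq", "amp_freq", "del_freq",
                              "planted_del_rate", "planted_amp_rate",
                              "passenger_rate", "background_mutation_freq")],
                       function(p) p >= 0 && p < 1, TRUE)),
            spec$leak_rate >= 0, spec$leak_rate < 1,
            spec$expression_noise_sd > 0, spec$effect_size > 0)
  needed <- 2L * (spec$n_hi_lo + spec$n_hi_hi) + spec$n_passengers +
    spec$n_background_mutations
  if (needed > spec$n_genes)
    stop_format("infeasible spec: ", needed, " planted genes > n_genes = ",
                spec$n_genes)
  class(spec) <- c("fixture_spec", "list")
  spec
}

## Synthetic gene model: genes laid out contiguously over 22 chromosomes.
.fixture_gene_model <- function(n_genes) {
  genes <- sprintf("G%04d", seq_len(n_genes))
  per_chrom <- ceiling(n_genes / 22)
  chrom <- paste0("chr", ((seq_len(n_genes) - 1) %/% per_chrom) + 1)
  within <- (seq_len(n_genes) - 1) %% per_chrom
  out <- data.frame(gene = genes, chrom = chrom,
                    start = within * 100000, end = within * 100000 + 50000,
                    stringsAsFactors = FALSE)
  class(out) <- c("gene_model", "data.frame")
  out
}

.drop_empty_rows <- function(m) m[rowSums(m) > 0, , drop = FALSE]

#' Generate synthetic cohorts with planted structure
#'
#' @param spec A [fixture_spec()].
#' @return List with `cohorts` (list of `cancer_cohort`), `truth`
#'   (class `synthetic_truth`: planted pairs, passengers, expression
#'   effects, cancer of interest, seed and the full parameter record) and
#'   `gene_model`.
#' @export
generate_cohorts <- function(spec = fixture_spec()) {
  model <- .fixture_gene_model(spec$n_genes)
  genes <- model$gene
  gene_chrom <- stats::setNames(model$chrom, genes)

  ## role assignment stream
  roles <- with_seed(derive_seed(spec$seed, 1L), {
    idx <- sample.int(spec$n_genes)
    take <- function(k) {
      if (k == 0L) return(integer(0))
      out <- idx[seq_len(k)]
      idx <<- idx[-seq_len(k)]
      out
    }
    list(hi_lo_mut = genes[take(spec$n_hi_lo)],
         hi_lo_partner = genes[take(spec$n_hi_lo)],
         hi_hi_mut = genes[take(spec$n_hi_hi)],
         hi_hi_partner = genes[take(spec$n_hi_hi)],
         passenger = genes[take(spec$n_passengers)],
         background_mut = genes[take(spec$n_background_mutations)])
  })
  planted_hi_lo <- data.frame(mutation = roles$hi_lo_mut,
                              partner = roles$hi_lo_partner,
                              stringsAsFactors = FALSE)
  planted_hi_hi <- data.frame(mutation = roles$hi_hi_mut,
                              partner = roles$hi_hi_partner,
                              stringsAsFactors = FALSE)
  pass_class <- rep(c("del", "amp"), length.out = spec$n_passengers)
  passengers <- data.frame(gene = roles$passenger, alteration = pass_class,
                           stringsAsFactors = FALSE)
  mut_genes <- c(roles$hi_lo_mut, roles$hi_hi_mut, roles$background_mut)
  mut_freqs <- c(rep(spec$mutation_freq, spec$n_hi_lo + spec$n_hi_hi),
                 rep(spec$background_mutation_freq, spec$n_background_mutations))
  coi <- "C1"

  cohorts <- lapply(seq_len(spec$n_cancers), function(ci) {
    ct <- paste0("C", ci)
    n <- spec$samples_per_cancer
    samples <- sprintf("%s_S%03d", ct, seq_len(n))
    with_seed(derive_seed(spec$seed, 10L + ci), {
      mut <- matrix(stats::rbinom(length(mut_genes) * n, 1,
                                  rep(mut_freqs, n)) == 1,
                    nrow = length(mut_genes), ncol = n,
                    dimnames = list(mut_genes, samples))
      amp <- matrix(stats::rbinom(spec$n_genes * n, 1, spec$amp_freq) == 1,
                    nrow = spec$n_genes, ncol = n,
                    dimnames = list(genes, samples))
      del <- matrix(stats::rbinom(spec$n_genes * n, 1, spec$del_freq) == 1,
                    nrow = spec$n_genes, ncol = n,
                    dimnames = list(genes, samples))
      ## passengers: controlled rate in their own class, nothing else
      for (k in seq_len(nrow(passengers))) {
        g <- passengers$gene[k]
        calls <- stats::rbinom(n, 1, spec$passenger_rate) == 1
        if (passengers$alteration[k] == "del") {
          del[g, ] <- calls; amp[g, ] <- FALSE
        } else {
          amp[g, ] <- calls; del[g, ] <- FALSE
        }
      }
      ## planted partners: their planted class is fully specified by the
      ## plant (background suppressed); absent from the cancer of
      ## interest unless plant_in_interest
      plant_here <- spec$plant_in_interest || ct != coi
      for (k in seq_len(nrow(planted_hi_lo))) {
        x <- planted_hi_lo$mutation[k]; b <- planted_hi_lo$partner[k]
        del[b, ] <- FALSE
        if (plant_here) {
          wt <- !mut[x, ]
          del[b, wt] <- stats::runif(sum(wt)) < spec$planted_del_rate
          del[b, !wt] <- stats::runif(sum(!wt)) < spec$leak_rate
        }
      }
      for (k in seq_len(nrow(planted_hi_hi))) {
        x <- planted_hi_hi$mutation[k]; b <- planted_hi_hi$partner[k]
        amp[b, ] <- FALSE
        if (plant_here) {
          mt <- mut[x, ]
          amp[b, mt] <- stats::runif(sum(mt)) < spec$planted_amp_rate
          amp[b, !mt] <- stats::runif(sum(!mt)) < spec$leak_rate
        }
      }
      ## resolve amp/del conflicts: ambiguous calls are dropped
      conflict <- amp & del
      amp[conflict] <- FALSE; del[conflict] <- FALSE
      ## expression: baseline + noise; CNA-concordant shifts for all
      ## non-passenger alterations; mutant overexpression of planted
      ## partners in the cancer of interest
      expr <- matrix(stats::rnorm(spec$n_genes * n, spec$baseline_expr,
                                  spec$expression_noise_sd),
                     nrow = spec$n_genes, ncol = n,
                     dimnames = list(genes, samples))
      coupled <- !(genes %in% passengers$gene)
      shift <- (amp[coupled, , drop = FALSE] - del[coupled, , drop = FALSE]) *
        spec$effect_size
      expr[coupled, ] <- expr[coupled, ] + shift
      if (ct == coi && spec$mutant_overexpression) {
        for (k in seq_len(nrow(planted_hi_lo))) {
          x <- planted_hi_lo$mutation[k]; b <- planted_hi_lo$partner[k]
          expr[b, mut[x, ]] <- expr[b, mut[x, ]] + spec$effect_size
        }
        for (k in seq_len(nrow(planted_hi_hi))) {
          x <- planted_hi_hi$mutation[k]; b <- planted_hi_hi$partner[k]
          expr[b, mut[x, ]] <- expr[b, mut[x, ]] + spec$effect_size
        }
      }
      cancer_cohort(ct, samples, mut = .drop_empty_rows(mut), expr = expr,
                    amp = .drop_empty_rows(amp), del = .drop_empty_rows(del),
                    gene_chrom = gene_chrom)
    })
  })
  truth <- structure(list(planted_hi_lo = planted_hi_lo,
                          planted_hi_hi = planted_hi_hi,
                          passengers = passengers,
                          expression_effects = list(
                            cna_shift = spec$effect_size,
                            mutant_overexpression =
                              if (spec$mutant_overexpression) spec$effect_size else 0),
                          cancer_of_interest = coi,
                          seed = spec$seed, generation_params = unclass(spec)),
                     class = "synthetic_truth")
  list(cohorts = cohorts, truth = truth, gene_model = model)
}

#' Serialise / restore a synthetic truth record
#' @param truth A `synthetic_truth`.
#' @param path JSON path.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$planted_hi_lo <- as.data.frame(x$planted_hi_lo, stringsAsFactors = FALSE)
  x$planted_hi_hi <- as.data.frame(x$planted_hi_hi, stringsAsFactors = FALSE)
  x$passengers <- as.data.frame(x$passengers, stringsAsFactors = FALSE)
  class(x) <- "synthetic_truth"
  x
}

#' Generate a dropout screen from a truth record
#'
#' Planted synthetic-lethal partner genes receive lowered
#' treated/baseline read ratios (`hit_depth`); all other genes get ratios
#' near 1 with multiplicative log-normal noise.
#'
#' @param truth A `synthetic_truth` (hit genes = planted partners), or
#'   NULL with explicit `hit_genes`.
#' @param genes Gene universe of the screen; defaults to the truth's
#'   generation universe.
#' @param hit_genes Overrides the hit set.
#' @param n_constructs Constructs per gene, default 5.
#' @param baseline_mean_reads Log-normal baseline read scale, default 500.
#' @param hit_depth Mean drop-out ratio of hit constructs, default 0.4.
#' @param noise_sd Log-scale sd of ratio noise, default 0.15.
#' @param seed RNG seed (defaults to a stream derived from the truth
#'   seed).
#' @return `screen_table` with columns `baseline` and `treated`.
#' @export
generate_screen <- function(truth = NULL, genes = NULL, hit_genes = NULL,
                            n_constructs = 5L, baseline_mean_reads = 500,
                            hit_depth = 0.4, noise_sd = 0.15, seed = NULL) {
  if (is.null(genes)) {
    stopifnot(!is.null(truth))
    genes <- sprintf("G%04d", seq_len(truth$generation_params$n_genes))
  }
  if (is.null(hit_genes) && !is.null(truth))
    hit_genes <- unique(c(truth$planted_hi_lo$partner, truth$planted_hi_hi$partner))
  hit_genes <- hit_genes %||% character(0)
  seed <- seed %||% derive_seed(truth$seed %||% 1L, 101L)
  with_seed(seed, {
    gene_col <- rep(genes, each = n_constructs)
    n <- length(gene_col)
    baseline <- round(stats::rlnorm(n, log(baseline_mean_reads), 0.5))
    ratio <- stats::rlnorm(n, ifelse(gene_col %in% hit_genes, log(hit_depth), 0),
                           noise_sd)
    out <- data.frame(construct_id = sprintf("sh%05d", seq_len(n)),
                      gene = gene_col, baseline = baseline,
                      treated = round(baseline * ratio),
                      stringsAsFactors = FALSE)
    class(out) <- c("screen_table", "data.frame")
    out
  })
}

#' Generate a per-cell-line essentiality score screen
#'
#' Emulates normalised shRNA summary scores across mutated and wild-type
#' cell lines: null constructs score N(0, `noise_sd`) everywhere;
#' essential genes score lower by `depth` in mutated lines.
#'
#' @param truth Optional `synthetic_truth` (essential genes = planted
#'   partners).
#' @param genes Gene universe.
#' @param essential_genes Overrides the essential set.
#' @param n_mut_lines,n_wt_lines Cell lines per group, default 8 each.
#' @param n_constructs Constructs per gene, default 5.
#' @param depth Score depression in mutant lines, default 1.0.
#' @param noise_sd Score noise sd, default 0.2.
#' @param seed RNG seed.
#' @return List: `screen` (a `screen_table` with one column per line),
#'   `mutated_lines`, `wildtype_lines`.
#' @export
generate_score_screen <- function(truth = NULL, genes = NULL,
                                  essential_genes = NULL, n_mut_lines = 8L,
                                  n_wt_lines = 8L, n_constructs = 5L,
                                  depth = 1.0, noise_sd = 0.2, seed = NULL) {
  if (is.null(genes)) {
    stopifnot(!is.null(truth))
    genes <- sprintf("G%04d", seq_len(truth$generation_params$n_genes))
  }
  if (is.null(essential_genes) && !is.null(truth))
    essential_genes <- unique(c(truth$planted_hi_lo$partner,
                                truth$planted_hi_hi$partner))
  essential_genes <- essential_genes %||% character(0)
  seed <- seed %||% derive_seed(truth$seed %||% 1L, 102L)
  mut_lines <- sprintf("MUT%02d", seq_len(n_mut_lines))
  wt_lines <- sprintf("WT%02d", seq_len(n_wt_lines))
  with_seed(seed, {
    gene_col <- rep(genes, each = n_constructs)
    n <- length(gene_col)
    m <- matrix(stats::rnorm(n * (n_mut_lines + n_wt_lines), 0, noise_sd),
                nrow = n, dimnames = list(NULL, c(mut_lines, wt_lines)))
    ess <- gene_col %in% essential_genes
    m[ess, mut_lines] <- m[ess, mut_lines] - depth
    out <- data.frame(construct_id = sprintf("sh%05d", seq_len(n)),
                      gene = gene_col, m, stringsAsFactors = FALSE,
                      check.names = FALSE)
    class(out) <- c("screen_table", "data.frame")
    list(screen = out, mutated_lines = mut_lines, wildtype_lines = wt_lines)
  })
}

#' Generate a pharmacology table with a planted biomarker association
#'
#' Cell lines carrying the biomarker draw IC50 from a low-mean
#' log-normal; others from a high-mean one.
#'
#' @param truth Optional `synthetic_truth`; the first planted HI-LO pair
#'   supplies the biomarker (mutation) and drug target (partner).
#' @param biomarker Variable id of the biomarker (e.g. `"G0001:mut"`).
#' @param target Inhibited gene of the drug.
#' @param drug Drug name, default `"DRUG1"`.
#' @param n_lines Cell lines, default 24.
#' @param biomarker_fraction Fraction of lines carrying the biomarker.
#' @param sensitive_ic50,resistant_ic50 Log-normal medians (uM).
#' @param sd_log IC50 log-sd, default 0.2.
#' @param tissue Tissue label applied to all lines.
#' @param seed RNG seed.
#' @return List: `pharm` (a `pharmacology_table`), `alterations`
#'   (variables x lines logical matrix), `drug_gene`
#'   (a `drug_gene_table`), `biomarker`, `target`.
#' @export
generate_pharmacology <- function(truth = NULL, biomarker = NULL, target = NULL,
                                  drug = "DRUG1", n_lines = 24L,
                                  biomarker_fraction = 0.25,
                                  sensitive_ic50 = 1.0, resistant_ic50 = 6.0,
                                  sd_log = 0.2, tissue = "breast", seed = NULL) {
  if (is.null(biomarker) && !is.null(truth))
    biomarker <- var_id(truth$planted_hi_lo$mutation[1], "mut")
  if (is.null(target) && !is.null(truth))
    target <- truth$planted_hi_lo$partner[1]
  stopifnot(!is.null(biomarker), !is.null(target))
  seed <- seed %||% derive_seed(truth$seed %||% 1L, 103L)
  with_seed(seed, {
    lines <- sprintf("CL%02d", seq_len(n_lines))
    n_carrier <- max(1L, round(n_lines * biomarker_fraction))
    carrier <- lines %in% sample(lines, n_carrier)
    ic50 <- stats::rlnorm(n_lines,
                          log(ifelse(carrier, sensitive_ic50, resistant_ic50)),
                          sd_log)
    pharm <- data.frame(cell_line = lines, tissue = tissue, drug = drug,
                        ic50 = ic50, stringsAsFactors = FALSE)
    class(pharm) <- c("pharmacology_table", "data.frame")
    alt <- matrix(carrier, nrow = 1, dimnames = list(biomarker, lines))
    dg <- data.frame(drug = drug, gene = norm_symbol(target),
                     interaction = "inhibits", stringsAsFactors = FALSE)
    class(dg) <- c("drug_gene_table", "data.frame")
    list(pharm = pharm, alterations = alt, drug_gene = dg,
         biomarker = biomarker, target = norm_symbol(target))
  })
}

#' Export a cohort as raw input tables
#'
#' Converts a cohort's Boolean matrices back into the raw formats the
#' readers consume: a mutation table, a segment table (one segment per
#' gene-level call, mean +0.5 for amplification and -0.5 for deletion,
#' 10 markers) and the expression matrix. Round-tripping these files
#' through [read_mutations()], [read_segments()], [booleanize_mutations()]
#' and [call_gene_cna()] reproduces the cohort matrices.
#'
#' @param cohort A `cancer_cohort`.
#' @param model The `gene_model` used for segment coordinates.
#' @return List: `mutations`, `segments`, `expression`.
#' @export
cohort_tables <- function(cohort, model) {
  mut_idx <- which(cohort$mut, arr.ind = TRUE)
  mutations <- data.frame(sample_id = cohort$samples[mut_idx[, 2]],
                          gene = rownames(cohort$mut)[mut_idx[, 1]],
                          mutation_type = "missense", stringsAsFactors = FALSE)
  mutations <- mutations[order(mutations$sample_id, mutations$gene), , drop = FALSE]
  rownames(mutations) <- NULL
  class(mutations) <- c("mutation_table", "data.frame")
  seg_rows <- function(m, mean) {
    if (is.null(m) || !any(m)) return(NULL)
    idx <- which(m, arr.ind = TRUE)
    g <- rownames(m)[idx[, 1]]
    mi <- match(g, model$gene)
    data.frame(sample_id = colnames(m)[idx[, 2]], sample_class = "tumour",
               chrom = model$chrom[mi], start = model$start[mi],
               end = model$end[mi], n_markers = 10L, segment_mean = mean,
               stringsAsFactors = FALSE)
  }
  segments <- rbind(seg_rows(cohort$amp, 0.5), seg_rows(cohort$del, -0.5))
  if (is.null(segments))
    segments <- data.frame(sample_id = character(0), sample_class = character(0),
                           chrom = character(0), start = numeric(0),
                           end = numeric(0), n_markers = integer(0),
                           segment_mean = numeric(0))
  segments <- segments[order(segments$sample_id, segments$chrom, segments$start), ,
                       drop = FALSE]
  rownames(segments) <- NULL
  class(segments) <- c("segment_table", "data.frame")
  list(mutations = mutations, segments = segments, expression = cohort$expr)
}

#' Write a complete synthetic input bundle
#'
#' Writes per-cohort mutation, segment and expression TSVs, the BED4 gene
#' model and the truth JSON under `dir`.
#'
#' @param gen Result of [generate_cohorts()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_cohort_bundle <- function(gen, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (co in gen$cohorts) {
    tabs <- cohort_tables(co, gen$gene_model)
    f <- file.path(dir, paste0(co$cancer_type, c("_mutations.tsv",
                                                 "_segments.tsv",
                                                 "_expression.tsv")))
    write_mutations(tabs$mutations, f[1])
    write_segments(tabs$segments, f[2])
    write_expression(tabs$expression, f[3])
    files <- c(files, f)
  }
  fm <- file.path(dir, "gene_model.bed")
  write_gene_model(gen$gene_model, fm)
  ft <- file.path(dir, "truth.json")
  write_truth(gen$truth, ft)
  invisible(c(files, fm, ft))
}

#' Load a cohort bundle written by [write_cohort_bundle()]
#'
#' @param dir Bundle directory.
#' @return List with `cohorts`, `truth`, `gene_model`.
#' @export
read_cohort_bundle <- function(dir) {
  model <- read_gene_model(file.path(dir, "gene_model.bed"))
  truth <- read_truth(file.path(dir, "truth.json"))
  mut_files <- list.files(dir, "_mutations\\.tsv$", full.names = TRUE)
  cts <- sub("_mutations\\.tsv$", "", basename(mut_files))
  gene_chrom <- stats::setNames(model$chrom, model$gene)
  cohorts <- lapply(cts, function(ct) {
    mt <- read_mutations(file.path(dir, paste0(ct, "_mutations.tsv")))
    seg <- read_segments(file.path(dir, paste0(ct, "_segments.tsv")))
    expr <- read_expression(file.path(dir, paste0(ct, "_expression.tsv")))
    samples <- colnames(expr)
    cna <- call_gene_cna(seg, model, samples = samples)
    cancer_cohort(ct, samples,
                  mut = booleanize_mutations(mt, samples), expr = expr,
                  amp = .drop_empty_rows(cna$amp),
                  del = .drop_empty_rows(cna$del), gene_chrom = gene_chrom)
  })
  list(cohorts = cohorts, truth = truth, gene_model = model)
}
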