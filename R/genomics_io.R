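## Readers and writers for every tabular format the pipeline touches.
## All tables are TSV with a header row, except BED4 (gene model) and GMT
## (gene sets) which follow their standard header-less dialects. Internal
## genomic coordinates are 0-based half-open everywhere; the segment reader
## is the only place conventions are converted.

.mutation_types <- c("missense", "nonsense", "frameshift", "splice_site", "other")

## Case- and punctuation-tolerant mapping from free-text mutation-type
## strings (e.g. TCGA level-3 "Missense_Mutation", "Frame_Shift_Del") onto
## the internal enum. Unknown strings map to "other" with a warning.
normalize_mutation_type <- function(x) {
  lx <- gsub("[^a-z]+", "_", tolower(as.character(x)))
  out <- rep("other", length(lx))
  out[grepl("missense", lx)] <- "missense"
  out[grepl("nonsense|stop_gain", lx)] <- "nonsense"
  out[grepl("frame_?shift", lx)] <- "frameshift"
  out[grepl("splice", lx)] <- "splice_site"
  known <- out != "other" | lx == "other"
  if (any(!known))
    warning(sum(!known), " unrecognised mutation-type string(s) mapped to 'other' (e.g. '",
            x[!known][1], "')", call. = FALSE)
  out
}

.read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
}

.require_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop_format(what, ": missing required column(s): ", paste(miss, collapse = ", "))
  invisible(df)
}

#' Read a mutation table
#'
#' Parses a MAF-like TSV with at least sample, gene and mutation-type
#' columns into a normalised mutation table: gene symbols are uppercased
#' and stripped, mutation-type strings are mapped onto the internal enum
#' (`missense`, `nonsense`, `frameshift`, `splice_site`, `other`), and
#' duplicate `(sample, gene, type)` rows are collapsed.
#'
#' @param path Path to a TSV with header columns `sample`, `gene`,
#'   `mutation_type` (aliases `sample_id`, `Tumor_Sample_Barcode`,
#'   `Hugo_Symbol`, `Variant_Classification` are accepted).
#' @return A `data.frame` of class `mutation_table` with columns
#'   `sample_id`, `gene`, `mutation_type`.
#' @export
read_mutations <- function(path) {
  df <- .read_tsv(path)
  alias <- c(sample = "sample_id", Tumor_Sample_Barcode = "sample_id",
             Hugo_Symbol = "gene", Variant_Classification = "mutation_type")
  for (a in names(alias))
    if (a %in% names(df) && !(alias[[a]] %in% names(df)))
      names(df)[names(df) == a] <- alias[[a]]
  .require_cols(df, c("sample_id", "gene", "mutation_type"), "mutation table")
  out <- data.frame(sample_id = as.character(df$sample_id),
                    gene = norm_symbol(df$gene),
                    mutation_type = if (nrow(df)) normalize_mutation_type(df$mutation_type) else character(0),
                    stringsAsFactors = FALSE)
  if (any(!nzchar(out$gene)))
    stop_format("mutation table: empty gene symbol in row ",
                which(!nzchar(out$gene))[1])
  out <- unique(out)
  rownames(out) <- NULL
  class(out) <- c("mutation_table", "data.frame")
  out
}

#' Write a mutation table
#' @param x A `mutation_table`.
#' @param path Output TSV path.
#' @export
write_mutations <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a segmented copy-number table
#'
#' Reads a SEG-like TSV (`sample`, `chrom`, `start`, `end`, `n_markers`,
#' `segment_mean`, optional `sample_class`) and converts coordinates to the
#' internal 0-based half-open convention.
#'
#' @param path TSV path.
#' @param coordinate_convention `"bed0"` (0-based half-open, kept as is) or
#'   `"one_based_inclusive"` (start decremented by one).
#' @param sample_class Default class (`"tumour"` or `"normal"`) applied when
#'   the file carries no `sample_class` column.
#' @return A `data.frame` of class `segment_table` with columns `sample_id`,
#'   `sample_class`, `chrom`, `start`, `end`, `n_markers`, `segment_mean`.
#' @export
read_segments <- function(path,
                          coordinate_convention = c("bed0", "one_based_inclusive"),
                          sample_class = c("tumour", "normal")) {
  coordinate_convention <- match.arg(coordinate_convention)
  df <- .read_tsv(path)
  if ("sample" %in% names(df) && !("sample_id" %in% names(df)))
    names(df)[names(df) == "sample"] <- "sample_id"
  .require_cols(df, c("sample_id", "chrom", "start", "end", "n_markers", "segment_mean"),
                "segment table")
  cls <- if ("sample_class" %in% names(df)) as.character(df$sample_class)
         else rep(match.arg(sample_class), nrow(df))
  if (!all(cls %in% c("tumour", "normal")))
    stop_format("segment table: sample_class must be 'tumour' or 'normal'")
  start <- as.numeric(df$start)
  end <- as.numeric(df$end)
  if (coordinate_convention == "one_based_inclusive") start <- start - 1
  bad <- which(end <= start)
  if (length(bad))
    stop_format("segment table: end <= start after conversion in row ", bad[1])
  if (any(start < 0))
    stop_format("segment table: negative start coordinate")
  out <- data.frame(sample_id = as.character(df$sample_id),
                    sample_class = cls,
                    chrom = as.character(df$chrom),
                    start = start, end = end,
                    n_markers = as.integer(df$n_markers),
                    segment_mean = as.numeric(df$segment_mean),
                    stringsAsFactors = FALSE)
  class(out) <- c("segment_table", "data.frame")
  out
}

#' Write a segment table (internal bed0 coordinates)
#' @param x A `segment_table`.
#' @param path Output TSV path.
#' @export
write_segments <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a log2 expression matrix
#'
#' First column holds gene symbols, remaining header names are sample ids,
#' values are log2-transformed normalised expression.
#'
#' @param path TSV path.
#' @return A numeric matrix (genes x samples).
#' @export
read_expression <- function(path) {
  df <- .read_tsv(path)
  genes <- norm_symbol(df[[1]])
  dup <- unique(genes[duplicated(genes)])
  if (length(dup))
    stop_format("expression matrix: duplicate gene id(s): ", paste(dup, collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  if (anyDuplicated(colnames(m)))
    stop_format("expression matrix: duplicate sample id(s)")
  if (any(!is.finite(m)))
    stop_format("expression matrix: non-finite values present")
  m
}

#' Write an expression matrix
#' @param x Numeric matrix (genes x samples).
#' @param path Output TSV path.
#' @export
write_expression <- function(x, path) {
  df <- data.frame(gene = rownames(x), x, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BED4 gene model
#'
#' @param path BED4 file (chrom, start, end, gene; 0-based half-open, no
#'   header).
#' @return `data.frame` of class `gene_model` with columns `gene`, `chrom`,
#'   `start`, `end`; one row per gene symbol.
#' @export
read_gene_model <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 4) stop_format("gene model: BED4 requires 4 columns")
  out <- data.frame(gene = norm_symbol(df[[4]]), chrom = as.character(df[[1]]),
                    start = as.numeric(df[[2]]), end = as.numeric(df[[3]]),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$gene))
    stop_format("gene model: duplicate gene symbol(s): ",
                paste(unique(out$gene[duplicated(out$gene)]), collapse = ", "))
  if (any(out$end <= out$start) || any(out$start < 0))
    stop_format("gene model: invalid coordinates")
  class(out) <- c("gene_model", "data.frame")
  out
}

#' Write a gene model as BED4
#' @param x A `gene_model`.
#' @param path Output path.
#' @export
write_gene_model <- function(x, path) {
  utils::write.table(data.frame(x$chrom, format(x$start, scientific = FALSE, trim = TRUE),
                                format(x$end, scientific = FALSE, trim = TRUE), x$gene),
                     path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Two-leading-column dialect: set name, description, then member genes.
#'
#' @param path GMT path.
#' @return Named list of character vectors of member genes.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f) {
    if (length(f) < 3) stop_format("GMT: line with fewer than 3 fields (empty set)")
    members <- unique(norm_symbol(f[-(1:2)]))
    members[nzchar(members)]
  })
  names(sets) <- vapply(strsplit(lines, "\t", fixed = TRUE), `[`, "", 1L)
  if (any(lengths(sets) == 0)) stop_format("GMT: empty gene set")
  sets
}

#' Write a GMT gene-set collection
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "na", sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a drug-gene interaction table
#'
#' @param path TSV with columns `drug`, `gene`, `interaction`.
#' @return `data.frame` of class `drug_gene_table`; interaction strings
#'   starting with "inhibit" normalise to `inhibits`, everything else to
#'   `other`.
#' @export
read_drug_gene <- function(path) {
  df <- .read_tsv(path)
  .require_cols(df, c("drug", "gene", "interaction"), "drug-gene table")
  out <- data.frame(drug = as.character(df$drug), gene = norm_symbol(df$gene),
                    interaction = ifelse(grepl("^inhibit", tolower(df$interaction)),
                                         "inhibits", "other"),
                    stringsAsFactors = FALSE)
  key <- paste(out$drug, out$gene)
  if (anyDuplicated(key))
    stop_format("drug-gene table: duplicate (drug, gene) pair(s): ",
                key[duplicated(key)][1])
  class(out) <- c("drug_gene_table", "data.frame")
  out
}

#' Read a cell-line pharmacology table
#'
#' @param path TSV with columns `cell_line`, `tissue`, `drug`, `ic50`
#'   (positive, micromolar).
#' @return `data.frame` of class `pharmacology_table`.
#' @export
read_pharmacology <- function(path) {
  df <- .read_tsv(path)
  .require_cols(df, c("cell_line", "tissue", "drug", "ic50"), "pharmacology table")
  out <- data.frame(cell_line = as.character(df$cell_line),
                    tissue = as.character(df$tissue),
                    drug = as.character(df$drug),
                    ic50 = as.numeric(df$ic50), stringsAsFactors = FALSE)
  if (any(!is.finite(out$ic50)) || any(out$ic50 <= 0))
    stop_format("pharmacology table: ic50 must be positive and finite")
  key <- paste(out$cell_line, out$drug)
  if (anyDuplicated(key))
    stop_format("pharmacology table: duplicate (cell_line, drug) record(s)")
  class(out) <- c("pharmacology_table", "data.frame")
  out
}

#' Read an shRNA screen table
#'
#' @param path TSV with columns `construct_id`, `gene`, then one numeric
#'   column per condition (barcode reads) or per cell line (essentiality
#'   scores).
#' @return `data.frame` of class `screen_table`.
#' @export
read_screen <- function(path) {
  df <- .read_tsv(path)
  .require_cols(df, c("construct_id", "gene"), "screen table")
  df$gene <- norm_symbol(df$gene)
  if (anyDuplicated(df$construct_id))
    stop_format("screen table: duplicate construct id(s)")
  num <- setdiff(names(df), c("construct_id", "gene"))
  for (cn in num) df[[cn]] <- as.numeric(df[[cn]])
  class(df) <- c("screen_table", "data.frame")
  df
}

#' Write a screen table
#' @param x A `screen_table`.
#' @param path Output TSV path.
#' @export
write_screen <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
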