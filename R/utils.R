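`%||%` <- function(x, y) if (is.null(x)) y else x

#' @keywords internal
#' @noRd
.misl_verbose <- function() isTRUE(getOption("misl.verbose", FALSE))

.misl_log <- function(...) {
  if (.misl_verbose()) message("[misl] ", ...)
  invisible(NULL)
}

## Evaluate `code` under a fixed seed without disturbing the caller's RNG
## stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## Deterministic sub-seed derivation so each synthetic artifact consumes its
## own stream; result always in [1, 2^31 - 2].
derive_seed <- function(master, index) {
  stopifnot(is.numeric(master), length(master) == 1L)
  s <- (abs(master) * 48271 + index * 2654435) %% 2147483646
  as.integer(s) + 1L
}

## Normalise a gene symbol: uppercase, strip surrounding whitespace.
## Gene identity in this package is the normalised symbol string.
norm_symbol <- function(x) toupper(trimws(as.character(x)))

## Variable identifiers are "GENE:class" with class one of mut/amp/del.
parse_var_id <- function(id) {
  stopifnot(is.character(id), length(id) == 1L)
  m <- regmatches(id, regexec("^(.+):(mut|amp|del)$", id))[[1]]
  if (length(m) != 3L)
    stop("malformed variable id '", id, "': expected '<GENE>:mut|amp|del'")
  list(gene = norm_symbol(m[2]), class = m[3])
}

var_id <- function(gene, class) {
  if (!length(gene)) return(character(0))
  paste0(norm_symbol(gene), ":", class)
}

## Row-wise Welch (unequal-variance) two-sided t-test over a numeric matrix.
## idx1/idx2 are column indices (or logical masks) for the two groups.
## Returns a data.frame with mean1, mean2, t, df, p. Degenerate rows
## (zero pooled standard error) get p = 1 when the means agree, p = 0
## otherwise.
welch_rows <- function(x, idx1, idx2) {
  x1 <- x[, idx1, drop = FALSE]
  x2 <- x[, idx2, drop = FALSE]
  n1 <- ncol(x1); n2 <- ncol(x2)
  if (n1 < 2L || n2 < 2L)
    stop("welch_rows needs at least 2 samples per group (got ", n1, " and ", n2, ")")
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  tt <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(abs(tt), df, lower.tail = FALSE)
  zero <- se2 == 0
  if (any(zero)) {
    p[zero] <- ifelse(m1[zero] == m2[zero], 1, 0)
    tt[zero] <- ifelse(m1[zero] == m2[zero], 0, Inf * sign(m1[zero] - m2[zero]))
    df[zero] <- NA_real_
  }
  data.frame(mean1 = m1, mean2 = m2, t = tt, df = df, p = p,
             row.names = NULL)
}

## Fast md5 of a set of files, sorted by path, for run manifests and
## determinism checks.
file_digests <- function(paths) {
  paths <- sort(paths)
  d <- tools::md5sum(paths)
  stats::setNames(unname(d), basename(paths))
}

stop_format <- function(...) stop(..., call. = FALSE)
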