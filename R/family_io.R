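#' Read a bulk expression matrix from tab-separated text
#'
#' Parses a samples-by-genes expression table on a linear, RSEM-like scale.
#' The expected dialect has a header row of gene symbols, a first column
#' named `sample_id`, and a non-negative numeric body.  Many repository
#' exports ship transposed (genes as rows, samples as columns); set
#' `transpose = TRUE` for those and the first column is read as gene symbols
#' with sample identifiers in the header.
#'
#' Gene symbols are upper-cased on read; downstream matching is exact string
#' matching after this normalization (no alias resolution).
#'
#' @param path Path to a TSV file.
#' @param transpose Logical; if `TRUE` the file stores genes as rows.
#' @return A numeric matrix with samples as rows (rownames are sample ids)
#'   and genes as columns (colnames are uppercased gene symbols).
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("sample_id\tALDH1A1\tALDH2", "s1\t10\t5", "s2\t0\t7"), tf)
#' read_expression_matrix(tf)
#' @export
read_expression_matrix <- function(path, transpose = FALSE) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (nrow(df) == 0L) stop("no samples: expression matrix body is empty")
  if (ncol(df) < 2L) stop("no genes: expression matrix needs at least one gene column")
  if (transpose) {
    genes <- toupper(trimws(df[[1L]]))
    samples <- colnames(df)[-1L]
    body <- df[, -1L, drop = FALSE]
    values <- .parse_numeric_body(body, rows = genes, cols = samples)
    values <- t(values)
    dimnames(values) <- list(samples, genes)
  } else {
    samples <- trimws(df[[1L]])
    genes <- toupper(colnames(df)[-1L])
    body <- df[, -1L, drop = FALSE]
    values <- .parse_numeric_body(body, rows = samples, cols = genes)
    dimnames(values) <- list(samples, genes)
  }
  .validate_expression_matrix(values)
  values
}

# Parse a character body to numeric, reporting the first offending cell.
.parse_numeric_body <- function(body, rows, cols) {
  values <- matrix(NA_real_, nrow = nrow(body), ncol = ncol(body))
  for (j in seq_along(body)) {
    col <- trimws(body[[j]])
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) & !(col %in% c("NA", "")))
    if (length(bad)) {
      stop(sprintf("non-numeric value '%s' at row '%s', column '%s'",
                   col[bad[1L]], rows[bad[1L]], cols[j]))
    }
    values[, j] <- num
  }
  values
}

.validate_expression_matrix <- function(x) {
  if (anyNA(x)) {
    idx <- which(is.na(x), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing value at row '%s', column '%s'",
                 rownames(x)[idx[1L]], colnames(x)[idx[2L]]))
  }
  neg <- which(x < 0, arr.ind = TRUE)
  if (nrow(neg)) {
    stop(sprintf("negative value %g at row '%s', column '%s'",
                 x[neg[1L, , drop = FALSE]],
                 rownames(x)[neg[1L, 1L]], colnames(x)[neg[1L, 2L]]))
  }
  if (anyDuplicated(rownames(x)))
    stop("duplicate sample ids: ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "))
  if (anyDuplicated(colnames(x)))
    stop("duplicate gene symbols: ",
         paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "))
  invisible(x)
}

#' Write an expression matrix to tab-separated text
#'
#' Values are written at full double precision (17 significant digits) so a
#' read/write/read cycle reproduces the matrix bit-exactly.
#'
#' @param x Numeric samples-by-genes matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
  header <- paste(c("sample_id", colnames(x)), collapse = "\t")
  rows <- vapply(seq_len(nrow(x)), function(i) {
    paste(c(rownames(x)[i], sprintf("%.17g", x[i, ])), collapse = "\t")
  }, character(1L))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Gene family definitions
#'
#' A gene family is a named, ordered list of at least two unique gene
#' symbols.  Two families ship with the package: `"ALDH"`, the 19 human
#' aldehyde dehydrogenase isoforms, and `"KRT"`, the 37 human epithelial
#' cytokeratins.  Family definition files are plain text — a first line
#' `#family=<name>` followed by one symbol per line — and the packaged
#' copies under `inst/extdata/` may be edited or replaced.
#'
#' @param name Short family name.
#' @param members Character vector of gene symbols (uppercased).
#' @return An object of class `gene_family`: a list with elements `name`
#'   and `members`.
#' @examples
#' gene_family("DEMO", c("GENE1", "GENE2"))
#' @export
gene_family <- function(name, members) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  members <- toupper(as.character(members))
  if (length(members) < 2L)
    stop("a gene family needs at least 2 members")
  if (anyDuplicated(members))
    stop("duplicate family members: ",
         paste(unique(members[duplicated(members)]), collapse = ", "))
  structure(list(name = name, members = members), class = "gene_family")
}

#' @export
print.gene_family <- function(x, ...) {
  cat(sprintf("Gene family '%s' (%d members)\n", x$name, length(x$members)))
  cat(" ", paste(x$members, collapse = ", "), "\n")
  invisible(x)
}

#' @export
length.gene_family <- function(x) length(x$members)

#' Load a packaged gene family
#'
#' @param name `"ALDH"` (19 aldehyde dehydrogenase isoforms) or `"KRT"`
#'   (37 epithelial cytokeratins).
#' @return A [gene_family()] object.
#' @examples
#' load_builtin_family("ALDH")
#' @export
load_builtin_family <- function(name) {
  available <- c("ALDH", "KRT")
  if (!is.character(name) || length(name) != 1L || !(name %in% available))
    stop("unknown gene family '", paste(name, collapse = ","),
         "'; available families: ", paste(available, collapse = ", "))
  path <- system.file("extdata", paste0("family_", name, ".txt"),
                      package = "famvar", mustWork = TRUE)
  read_gene_family(path)
}

#' Read a gene-family definition file
#'
#' @param path Text file: first line `#family=<name>`, then one gene symbol
#'   per line.
#' @return A [gene_family()] object.
#' @export
read_gene_family <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  if (!length(lines) || !grepl("^#family=", lines[1L]))
    stop("gene-family file must start with '#family=<name>': ", path)
  name <- sub("^#family=", "", lines[1L])
  gene_family(name, lines[-1L])
}

#' Read a per-sample clinical table
#'
#' The table carries the clinical annotations consumed by the cohort-level
#' analyses: a tumor class label (e.g. `"HPV16+/p53WT"` or
#' `"HPV-/p53HRmut"`), an optional stemness index `mrnasi` in \[0, 1\],
#' survival time in months and a binary event indicator (1 = death,
#' 0 = censored).  Missing `mrnasi` cells are kept as `NA`, never imputed.
#'
#' @param path TSV with required columns `sample_id`, `class_label`, `time`,
#'   `event`; optional columns `mrnasi` and `endpoint`.
#' @return A data frame with one row per sample.
#' @export
read_clinical <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  required <- c("sample_id", "class_label", "time", "event")
  missing <- setdiff(required, colnames(df))
  if (length(missing))
    stop("clinical table is missing required columns: ",
         paste(missing, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample ids in clinical table: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  if (!is.numeric(df$time) || anyNA(df$time) || any(df$time < 0))
    stop("survival time must be numeric and >= 0 (months)")
  if (anyNA(df$event) || !all(df$event %in% c(0, 1)))
    stop("event indicator must be 0 (censored) or 1 (event)")
  if (is.null(df$mrnasi)) {
    df$mrnasi <- NA_real_
  } else {
    df$mrnasi <- as.numeric(df$mrnasi)
    ok <- is.na(df$mrnasi) | (df$mrnasi >= 0 & df$mrnasi <= 1)
    if (!all(ok))
      stop("mrnasi values must lie in [0, 1] or be missing; offending sample: ",
           df$sample_id[which(!ok)[1L]])
  }
  if (is.null(df$endpoint)) df$endpoint <- "OS"
  df[, c("sample_id", "class_label", "mrnasi", "time", "event", "endpoint")]
}
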