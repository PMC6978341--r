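#' Fold change between two populations by the delta-delta-Ct method
#'
#' Standard relative quantification for qPCR: each population's target Ct is
#' normalized to a reference gene (e.g. GAPDH), the two normalized values
#' are differenced, and the fold change assumes ideal doubling per cycle:
#' \deqn{fold = 2^{-[(Ct_{t,high} - Ct_{r,high}) - (Ct_{t,low} - Ct_{r,low})]}}
#' Amplification efficiency is fixed at 2; efficiency calibration is out of
#' scope.  All arguments are vectorized.
#'
#' @param ct_t_high,ct_r_high Target and reference Ct in the high population.
#' @param ct_t_low,ct_r_low Target and reference Ct in the low population.
#' @return Positive fold enrichment of the high over the low population.
#' @examples
#' ddct_fold(20, 15, 24, 15)   # 16
#' @export
ddct_fold <- function(ct_t_high, ct_r_high, ct_t_low, ct_r_low) {
  vals <- c(ct_t_high, ct_r_high, ct_t_low, ct_r_low)
  if (!is.numeric(vals) || any(!is.finite(vals)))
    stop("all Ct values must be finite numbers")
  ddct <- (ct_t_high - ct_r_high) - (ct_t_low - ct_r_low)
  2^(-ddct)
}

#' Read a table of qPCR Ct measurements
#'
#' @param path TSV with columns `cell_line`, `gene`, `population`
#'   (`"high"`/`"low"`), `replicate`, `ct_target`, `ct_reference`.
#' @return Validated data frame of Ct records.
#' @export
read_ct_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  required <- c("cell_line", "gene", "population", "replicate",
                "ct_target", "ct_reference")
  missing <- setdiff(required, colnames(df))
  if (length(missing))
    stop("Ct table is missing columns: ", paste(missing, collapse = ", "))
  df$gene <- toupper(df$gene)
  if (!all(df$population %in% c("high", "low")))
    stop("population must be 'high' or 'low'")
  ct <- c(df$ct_target, df$ct_reference)
  if (any(!is.finite(ct)) || any(ct <= 0) || any(ct >= 45))
    stop("Ct values must lie in (0, 45) cycles")
  if (any(df$replicate < 1)) stop("replicate index must be >= 1")
  df[, required]
}

#' Per-gene enrichment profile of a sorted high vs low population
#'
#' For every cell line and gene, replicate `i` of the high population is
#' paired with replicate `i` of the low population and a per-replicate fold
#' is computed with [ddct_fold()]; the profile reports the mean fold and
#' s.e.m. across replicate pairs (mean-of-folds, the usual presentation for
#' n = 3 sorted-population panels).  The dominant gene is the one with the
#' maximal mean fold; exact ties are flagged.  Genes whose mean fold exceeds
#' `threshold` (default 5-fold) are counted as enriched.
#'
#' @param records Data frame of Ct records (see [read_ct_table()]).
#' @param threshold Fold-enrichment threshold for the enriched-gene count.
#' @return An object of class `enrichment_profile`: list with elements
#'   `folds` (cell_line, gene, fold_mean, fold_sem, n_replicates),
#'   `dominant` (cell_line, dominant_gene, tie), `n_enriched`
#'   (cell_line, n_above_threshold) and `threshold`.
#' @export
build_profile <- function(records, threshold = 5) {
  stopifnot(is.data.frame(records), threshold > 0)
  required <- c("cell_line", "gene", "population", "replicate",
                "ct_target", "ct_reference")
  stopifnot(all(required %in% colnames(records)))

  folds <- do.call(rbind, lapply(split(records, records[c("cell_line", "gene")], drop = TRUE),
    function(g) {
      hi <- g[g$population == "high", ]
      lo <- g[g$population == "low", ]
      hi <- hi[order(hi$replicate), ]
      lo <- lo[order(lo$replicate), ]
      if (nrow(hi) == 0L || nrow(lo) == 0L ||
          !identical(hi$replicate, lo$replicate))
        stop("unpaired high/low replicates for gene ", g$gene[1L],
             " in cell line ", g$cell_line[1L])
      f <- ddct_fold(hi$ct_target, hi$ct_reference, lo$ct_target, lo$ct_reference)
      data.frame(cell_line = g$cell_line[1L], gene = g$gene[1L],
                 fold_mean = mean(f),
                 fold_sem = if (length(f) > 1L) stats::sd(f) / sqrt(length(f)) else NA_real_,
                 n_replicates = length(f), stringsAsFactors = FALSE)
    }))
  rownames(folds) <- NULL
  folds <- folds[order(folds$cell_line, folds$gene), , drop = FALSE]

  by_line <- split(folds, folds$cell_line)
  dominant <- do.call(rbind, lapply(by_line, function(d) {
    top <- d$fold_mean == max(d$fold_mean)
    data.frame(cell_line = d$cell_line[1L],
               dominant_gene = d$gene[which(top)[1L]],
               tie = sum(top) > 1L, stringsAsFactors = FALSE)
  }))
  n_enriched <- do.call(rbind, lapply(by_line, function(d) {
    data.frame(cell_line = d$cell_line[1L],
               n_above_threshold = sum(d$fold_mean > threshold),
               stringsAsFactors = FALSE)
  }))
  rownames(dominant) <- rownames(n_enriched) <- NULL
  structure(list(folds = folds, dominant = dominant,
                 n_enriched = n_enriched, threshold = threshold),
            class = "enrichment_profile")
}

#' @export
print.enrichment_profile <- function(x, ...) {
  cat("Enrichment profile (high vs low population, mean fold over replicates)\n")
  for (i in seq_len(nrow(x$dominant))) {
    cat(sprintf("  %s: dominant %s%s; %d gene(s) > %g-fold\n",
                x$dominant$cell_line[i], x$dominant$dominant_gene[i],
                if (x$dominant$tie[i]) " (tied)" else "",
                x$n_enriched$n_above_threshold[i], x$threshold))
  }
  invisible(x)
}
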