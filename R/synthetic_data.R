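#' Configuration for a synthetic tumor cohort
#'
#' Defines a two-class cohort with the statistical structure the
#' family-variance analyses assume.  Each sample's family composition is
#' drawn from a class-specific Dirichlet distribution: the
#' dominant-isoform class concentrates mass on one member (default 8 on
#' ALDH1A3 with 0.3 elsewhere, giving high variance scores), while the
#' diverse class uses a symmetric concentration (default 3, low scores).
#' Compositions are scaled by a log-normal total to an RSEM-like linear
#' scale.  A stemness index is linked to the standardized score,
#' `mrnasi = clamp01(a + b * z_avs + Normal(0, tau))`, and survival is
#' exponential with per-class baseline hazard and a log-hazard effect of
#' the standardized score, with uniform administrative censoring.
#'
#' Defaults (documented in the methods vignette): class labels
#' `"HPV16+/p53WT"` (dominant) and `"HPV-/p53HRmut"` (diverse);
#' `total_meanlog = log(1000)`, `total_sdlog = 0.5`; stemness link
#' `a = 0.35`, `b = 0.04`, `tau = 0.12`; baseline hazards 0.004 and 0.012
#' per month (about 79% and 49% five-year survival); `beta_avs = -0.3`
#' per SD of the score (high variance protective); censoring
#' `Uniform(0, 120)` months.
#'
#' @param n_per_class Samples per class.
#' @param class_labels Length-2 labels; the first is the dominant class.
#' @param family A [gene_family()]; defaults to the packaged ALDH family.
#' @param alpha_dominant,alpha_diverse Dirichlet concentration vectors over
#'   the family members (length = family size).
#' @param total_meanlog,total_sdlog Log-normal parameters of per-sample
#'   total family expression.
#' @param mrnasi_a,mrnasi_b,mrnasi_tau Stemness-link intercept, slope per
#'   SD of the score (>= 0), and Gaussian noise SD.
#' @param lambda Length-2 positive baseline hazards per month, one per class.
#' @param beta_avs Log-hazard per SD of the score.
#' @param censor_max Upper bound of uniform censoring, months.
#' @param seed Optional integer seed.
#' @return List of class `synthetic_config`.
#' @export
synthetic_config <- function(n_per_class = 200,
                             class_labels = c("HPV16+/p53WT", "HPV-/p53HRmut"),
                             family = load_builtin_family("ALDH"),
                             alpha_dominant = NULL,
                             alpha_diverse = NULL,
                             total_meanlog = log(1000), total_sdlog = 0.5,
                             mrnasi_a = 0.35, mrnasi_b = 0.04,
                             mrnasi_tau = 0.12,
                             lambda = c(0.004, 0.012), beta_avs = -0.3,
                             censor_max = 120, seed = NULL) {
  stopifnot(inherits(family, "gene_family"), length(class_labels) == 2L)
  m <- length(family$members)
  if (is.null(alpha_dominant)) {
    alpha_dominant <- rep(0.3, m)
    dom <- match("ALDH1A3", family$members)
    alpha_dominant[if (is.na(dom)) 1L else dom] <- 8
  }
  if (is.null(alpha_diverse)) alpha_diverse <- rep(3, m)
  stopifnot(length(alpha_dominant) == m, length(alpha_diverse) == m,
            all(alpha_dominant > 0), all(alpha_diverse > 0),
            mrnasi_b >= 0, mrnasi_tau >= 0,
            length(lambda) == 2L, all(lambda > 0),
            total_sdlog >= 0, censor_max > 0, n_per_class >= 1)
  structure(list(n_per_class = n_per_class, class_labels = class_labels,
                 family = family, alpha_dominant = alpha_dominant,
                 alpha_diverse = alpha_diverse,
                 total_meanlog = total_meanlog, total_sdlog = total_sdlog,
                 mrnasi_a = mrnasi_a, mrnasi_b = mrnasi_b,
                 mrnasi_tau = mrnasi_tau, lambda = lambda,
                 beta_avs = beta_avs, censor_max = censor_max, seed = seed),
            class = "synthetic_config")
}

#' Generate a synthetic two-class cohort
#'
#' A pure function of `(config, seed)`: the same configuration and seed
#' reproduce the cohort bit-for-bit.
#'
#' @param config A [synthetic_config()].
#' @return List of class `synthetic_cohort` with elements `matrix`
#'   (samples-by-genes expression), `clinical` (as [read_clinical()]
#'   returns) and `truth` (per-sample class, true percent-profile variance
#'   score, standardized score and hazard rate).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_preserved_seed(config$seed, {
    m <- length(config$family$members)
    n_tot <- 2L * config$n_per_class
    cls <- rep(config$class_labels, each = config$n_per_class)
    ids <- sprintf("S%04d", seq_len(n_tot))

    props <- rbind(
      rdirichlet(config$n_per_class, config$alpha_dominant),
      rdirichlet(config$n_per_class, config$alpha_diverse))
    totals <- stats::rlnorm(n_tot, config$total_meanlog, config$total_sdlog)
    values <- props * totals
    dimnames(values) <- list(ids, config$family$members)

    true_avs <- apply(100 * props, 1L, function(x) mean((x - mean(x))^2))
    z <- as.numeric(scale(true_avs))

    mrnasi <- config$mrnasi_a + config$mrnasi_b * z +
      stats::rnorm(n_tot, 0, config$mrnasi_tau)
    mrnasi <- pmin(1, pmax(0, mrnasi))

    rate <- rep(config$lambda, each = config$n_per_class) *
      exp(config$beta_avs * z)
    t_event <- stats::rexp(n_tot, rate)
    t_cens <- stats::runif(n_tot, 0, config$censor_max)
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)

    clinical <- data.frame(sample_id = ids, class_label = cls,
                           mrnasi = mrnasi, time = time, event = event,
                           endpoint = "OS", stringsAsFactors = FALSE)
    truth <- data.frame(sample_id = ids, class_label = cls,
                        true_avs = true_avs, z_avs = z, hazard = rate,
                        stringsAsFactors = FALSE)
    structure(list(matrix = values, clinical = clinical, truth = truth),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d samples x %d genes; classes: %s\n",
              nrow(x$matrix), ncol(x$matrix),
              paste(unique(x$clinical$class_label), collapse = ", ")))
  invisible(x)
}

#' Generate a synthetic qPCR Ct table for a sorted-population panel
#'
#' Emulates a high/low sorted-population qPCR experiment: the dominant
#' gene's expected high-vs-low delta-delta-Ct equals `-log2(fold)` so the
#' noiseless recovered fold is exact; all other genes are unenriched
#' (expected fold 1).  Gaussian cycle noise of SD `noise_sd` is added to
#' every target Ct measurement.
#'
#' @param dominant_gene Symbol of the enriched gene.
#' @param fold True fold enrichment of the dominant gene (> 0).
#' @param genes Panel of gene symbols; defaults to the ALDH family.
#' @param n_replicates Replicates per population.
#' @param noise_sd SD of Gaussian Ct noise, cycles.
#' @param cell_line Cell-line label.
#' @param seed Optional integer seed.
#' @return Data frame of Ct records (see [read_ct_table()]).
#' @export
generate_ct_table <- function(dominant_gene, fold, genes = NULL,
                              n_replicates = 3, noise_sd = 0,
                              cell_line = "SYNTH", seed = NULL) {
  stopifnot(fold > 0, n_replicates >= 1, noise_sd >= 0)
  if (is.null(genes)) genes <- load_builtin_family("ALDH")$members
  dominant_gene <- toupper(dominant_gene)
  if (!(dominant_gene %in% genes)) genes <- c(dominant_gene, genes)
  with_preserved_seed(seed, {
    grid <- expand.grid(gene = genes, population = c("high", "low"),
                        replicate = seq_len(n_replicates),
                        stringsAsFactors = FALSE)
    ct_ref <- 15
    base <- 25
    shift <- ifelse(grid$gene == dominant_gene & grid$population == "high",
                    log2(fold), 0)
    ct_target <- base - shift + stats::rnorm(nrow(grid), 0, noise_sd)
    data.frame(cell_line = cell_line, gene = grid$gene,
               population = grid$population, replicate = grid$replicate,
               ct_target = ct_target, ct_reference = ct_ref,
               stringsAsFactors = FALSE)
  })
}
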