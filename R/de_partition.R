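#' TMM normalization factors
#'
#' Trimmed mean of M-values between-library normalization for count
#' matrices. The reference library is the one whose upper quartile of
#' counts-per-million is closest to the mean upper quartile. For each
#' library the factor is the inverse-variance-weighted mean of gene-wise
#' log2 ratios (M-values) against the reference, after two-sided trimming
#' of 30% of M-values and 5% of A-values. Factors are rescaled so their
#' geometric mean is 1.
#'
#' @param counts Non-negative integer matrix, genes x samples.
#' @param lib_sizes Optional library sizes (default column sums).
#' @return Named numeric vector of normalization factors, one per sample.
#' @export
tmm_factors <- function(counts, lib_sizes = NULL) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L) stop("need at least 2 samples")
  if (any(counts < 0)) stop("negative counts")
  if (is.null(lib_sizes)) lib_sizes <- colSums(counts)
  if (any(lib_sizes == 0)) stop("all-zero library: ",
                                paste(colnames(counts)[lib_sizes == 0],
                                      collapse = ", "))
  cpm <- t(t(counts) / lib_sizes) * 1e6
  uq <- apply(cpm, 2L, stats::quantile, probs = 0.75)
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(counts)), function(j) {
    tmm_pair(counts[, j], counts[, ref], lib_sizes[j], lib_sizes[ref])
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  f
}

# One library against the reference: trim, weight by the delta-method
# (binomial) variance of M, return 2^weighted-mean-M.
tmm_pair <- function(obs, ref, n_obs, n_ref,
                     logratio_trim = 0.3, abs_trim = 0.05) {
  keep <- obs > 0 & ref > 0
  obs <- obs[keep]; ref <- ref[keep]
  if (!length(obs)) return(1)
  m <- log2((obs / n_obs) / (ref / n_ref))
  a <- (log2(obs / n_obs) + log2(ref / n_ref)) / 2
  v <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  fin <- is.finite(m) & is.finite(a)
  m <- m[fin]; a <- a[fin]; v <- v[fin]
  if (!length(m) || max(abs(m)) < 1e-6) return(1)
  n <- length(m)
  lo_l <- floor(n * logratio_trim) + 1
  hi_l <- n + 1 - lo_l
  lo_s <- floor(n * abs_trim) + 1
  hi_s <- n + 1 - lo_s
  keep <- rank(m) >= lo_l & rank(m) <= hi_l & rank(a) >= lo_s & rank(a) <= hi_s
  if (!any(keep)) return(1)
  2^(sum(m[keep] / v[keep]) / sum(1 / v[keep]))
}

#' Negative-binomial Wald test for differential expression
#'
#' A deliberately simple NB testing framework: per-gene dispersions are
#' moment estimates (Pearson-based, with a degrees-of-freedom correction)
#' shrunk toward the genome-wide common estimate with a fixed weight, and
#' each gene is tested by a Wald statistic on the difference of log mean
#' normalized abundances, with NB-based (Var = mu + phi mu^2) variance and
#' a standard-normal reference. The log2 fold change uses a
#' pseudo-mean offset of 0.5 normalized counts so that zero-containing
#' genes stay finite. Genes with all-zero counts in both groups get
#' p = 1 and logFC = 0.
#'
#' This is not an edgeR re-implementation; its guarantees are calibration
#' (type-I error at the nominal level) and recovery of planted effects, not
#' numerical agreement with any specific tool.
#'
#' @param counts Genes x samples count matrix with column names.
#' @param conditions Factor or character vector of condition labels, one
#'   per sample.
#' @param contrast Character vector `c(treated, ctrl)`.
#' @param factors TMM factors from [tmm_factors()]; computed from `counts`
#'   when `NULL`.
#' @param shrink_weight Weight of the gene-wise moment estimate in the
#'   shrunk dispersion (default 0.3; the remainder goes to the common
#'   estimate).
#' @return Data frame of class `de_result`: `gene_id`, `contrast`, `logFC`
#'   (log2 treated/ctrl), `p_raw`, `q_bh`, `direction` (filled by
#'   [call_de()], `"ns"` here).
#' @export
nb_test <- function(counts, conditions, contrast, factors = NULL,
                    shrink_weight = 0.3) {
  counts <- as.matrix(counts)
  conditions <- as.character(conditions)
  stopifnot(length(conditions) == ncol(counts), length(contrast) == 2L)
  sel <- conditions %in% contrast
  counts <- counts[, sel, drop = FALSE]
  conditions <- conditions[sel]
  n_a <- sum(conditions == contrast[1])
  n_b <- sum(conditions == contrast[2])
  if (n_a < 2L || n_b < 2L) stop("need >= 2 replicates per group")
  if (is.null(factors)) factors <- tmm_factors(counts)
  if (length(factors) != ncol(counts)) factors <- factors[sel]
  eff <- colSums(counts) * factors          # effective library sizes
  ia <- conditions == contrast[1]
  ib <- conditions == contrast[2]

  # per-gene relative abundance per group, and fitted means
  qa <- rowSums(counts[, ia, drop = FALSE]) / sum(eff[ia])
  qb <- rowSums(counts[, ib, drop = FALSE]) / sum(eff[ib])
  mu <- outer(qa, eff * ia) + outer(qb, eff * ib)

  phi <- moment_dispersion(counts, mu, groups = 2L)
  expressed <- (qa + qb) > 0
  phi_common <- if (any(expressed)) {
    stats::weighted.mean(phi[expressed], w = rowSums(mu)[expressed])
  } else 0
  phi_shrunk <- pmax(0, (1 - shrink_weight) * phi_common + shrink_weight * phi)

  # Wald on log(q + eps) with delta-method variance; eps = 0.5 counts in an
  # average-size library
  eps <- 0.5 / mean(eff)
  var_q <- function(q, idx) {
    (q * sum(eff[idx]) + phi_shrunk * q^2 * sum(eff[idx]^2)) / sum(eff[idx])^2
  }
  se2 <- var_q(qa, ia) / (qa + eps)^2 + var_q(qb, ib) / (qb + eps)^2
  est <- log(qa + eps) - log(qb + eps)
  zstat <- est / sqrt(se2)
  p <- 2 * stats::pnorm(-abs(zstat))
  zero <- !expressed
  p[zero] <- 1
  est[zero] <- 0
  p[is.na(p)] <- 1

  out <- data.frame(
    gene_id = if (!is.null(rownames(counts))) rownames(counts) else
      sprintf("g%05d", seq_len(nrow(counts))),
    contrast = paste(contrast, collapse = "_vs_"),
    logFC = est / log(2),
    p_raw = p,
    q_bh = bh_adjust(p),
    direction = "ns",
    stringsAsFactors = FALSE)
  class(out) <- c("de_result", "data.frame")
  out
}

# Pearson-style moment estimator of the NB dispersion, per gene, with an
# n/(n - g) degrees-of-freedom correction; groups = number of fitted group
# means. Solves E[sum (x - mu)^2 / mu] ~= ((n - g)/n) (n + phi sum mu).
moment_dispersion <- function(counts, mu, groups) {
  n <- ncol(counts)
  stopifnot(n > groups)
  mu_safe <- pmax(mu, 1e-8)
  pearson <- rowSums((counts - mu)^2 / mu_safe)
  num <- pearson * n / (n - groups) - n
  den <- rowSums(mu)
  pmax(ifelse(den > 0, num / den, 0), 0)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment of raw p-values (monotone in rank, capped at 1).
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Vector of q-values.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Call regulated genes from one contrast
#'
#' A gene is regulated when its BH-adjusted p-value is at most `q_max`
#' (inclusive) and, if `min_abs_fc` is given, its linear fold change is
#' strictly greater than `min_abs_fc` in magnitude. Direction follows the
#' sign of logFC.
#'
#' @param results [nb_test()] output for a single contrast.
#' @param q_max Adjusted-p threshold (default 0.05, inclusive).
#' @param min_abs_fc Optional linear fold-change threshold (e.g. 1.5,
#'   strict).
#' @return List of class `de_calls`: `regulated`, `up`, `down` (gene id
#'   vectors), `results` (with `direction` filled), `universe`, `q_max`,
#'   `min_abs_fc`.
#' @export
call_de <- function(results, q_max = 0.05, min_abs_fc = NULL) {
  stopifnot(is.data.frame(results),
            all(c("gene_id", "logFC", "q_bh") %in% names(results)))
  if (length(unique(results$contrast)) > 1L) {
    stop("call_de expects results from a single contrast")
  }
  reg <- results$q_bh <= q_max
  if (!is.null(min_abs_fc)) reg <- reg & (2^abs(results$logFC) > min_abs_fc)
  reg[is.na(reg)] <- FALSE
  results$direction <- ifelse(!reg, "ns",
                              ifelse(results$logFC > 0, "up", "down"))
  structure(list(regulated = results$gene_id[reg],
                 up = results$gene_id[reg & results$logFC > 0],
                 down = results$gene_id[reg & results$logFC <= 0],
                 results = results, universe = results$gene_id,
                 q_max = q_max, min_abs_fc = min_abs_fc),
            class = "de_calls")
}

#' Partition regulated genes from two contrasts
#'
#' Three-way Venn partition of the regulated sets of two contrasts (A and
#' B) over an identical gene universe: A-specific, B-specific and shared
#' (co-regulated), with percentages relative to each contrast's regulated
#' set and a direction breakdown (including concordance of the shared set).
#'
#' @param calls_a,calls_b [call_de()] outputs for contrasts A and B.
#' @return Object of class `de_partition_summary`: counts `n_A_only`,
#'   `n_B_only`, `n_shared`, `n_A`, `n_B`; percentages `pct_shared_of_A`,
#'   `pct_specific_of_A`, `pct_shared_of_B`, `pct_specific_of_B`; and
#'   `directions` (per-set up/down counts, shared concordance).
#' @export
partition_de <- function(calls_a, calls_b) {
  stopifnot(inherits(calls_a, "de_calls"), inherits(calls_b, "de_calls"))
  if (!identical(sort(calls_a$universe), sort(calls_b$universe))) {
    stop("gene universes differ between the two contrasts")
  }
  a <- calls_a$regulated
  b <- calls_b$regulated
  shared <- intersect(a, b)
  a_only <- setdiff(a, b)
  b_only <- setdiff(b, a)
  pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  dir_of <- function(calls, genes) {
    d <- calls$results$direction[match(genes, calls$results$gene_id)]
    c(up = sum(d == "up"), down = sum(d == "down"))
  }
  da <- calls_a$results$direction[match(shared, calls_a$results$gene_id)]
  db <- calls_b$results$direction[match(shared, calls_b$results$gene_id)]
  structure(list(
    n_A = length(a), n_B = length(b),
    n_A_only = length(a_only), n_B_only = length(b_only),
    n_shared = length(shared),
    pct_shared_of_A = pct(length(shared), length(a)),
    pct_specific_of_A = pct(length(a_only), length(a)),
    pct_shared_of_B = pct(length(shared), length(b)),
    pct_specific_of_B = pct(length(b_only), length(b)),
    directions = list(A_only = dir_of(calls_a, a_only),
                      B_only = dir_of(calls_b, b_only),
                      shared_A = dir_of(calls_a, shared),
                      shared_B = dir_of(calls_b, shared),
                      shared_concordant = sum(da == db),
                      shared_discordant = sum(da != db)),
    genes = list(A_only = a_only, B_only = b_only, shared = shared)),
    class = "de_partition_summary")
}

#' @export
print.de_partition_summary <- function(x, ...) {
  cat("Two-condition DE partition\n")
  cat(sprintf("  A: %d regulated (%d specific, %.1f%%)\n",
              x$n_A, x$n_A_only, x$pct_specific_of_A))
  cat(sprintf("  B: %d regulated (%d specific, %.1f%%)\n",
              x$n_B, x$n_B_only, x$pct_specific_of_B))
  cat(sprintf("  shared: %d (%.1f%% of B, %.1f%% of A); %d concordant / %d discordant\n",
              x$n_shared, x$pct_shared_of_B, x$pct_shared_of_A,
              x$directions$shared_concordant, x$directions$shared_discordant))
  invisible(x)
}

#' Dual-condition differential-expression pipeline
#'
#' TMM normalization, NB Wald tests of each treated condition against the
#' control, BH adjustment, regulated-set calling and the two-condition Venn
#' partition, in one call.
#'
#' @param counts Genes x samples count matrix.
#' @param conditions Condition label per sample; `ctrl` plus exactly two
#'   treated levels (A first, B second, in `contrast_order` if given).
#' @param ctrl Name of the control condition (default `"ctrl"`).
#' @param contrast_order Optional character vector giving the treated
#'   conditions in (A, B) order.
#' @param q_max,min_abs_fc Passed to [call_de()].
#' @param shrink_weight Passed to [nb_test()].
#' @return List of class `de_partition_run`: `factors`, `results` (named
#'   list of [nb_test()] outputs), `calls`, `partition`.
#' @export
de_partition <- function(counts, conditions, ctrl = "ctrl",
                         contrast_order = NULL, q_max = 0.05,
                         min_abs_fc = NULL, shrink_weight = 0.3) {
  conditions <- as.character(conditions)
  treated <- setdiff(unique(conditions), ctrl)
  if (!is.null(contrast_order)) {
    stopifnot(setequal(contrast_order, treated))
    treated <- contrast_order
  }
  if (length(treated) != 2L) stop("expected exactly two treated conditions")
  factors <- tmm_factors(counts)
  results <- lapply(treated, function(tr) {
    nb_test(counts, conditions, contrast = c(tr, ctrl), factors = factors,
            shrink_weight = shrink_weight)
  })
  names(results) <- treated
  calls <- lapply(results, call_de, q_max = q_max, min_abs_fc = min_abs_fc)
  structure(list(factors = factors, results = results, calls = calls,
                 partition = partition_de(calls[[1]], calls[[2]])),
            class = "de_partition_run")
}

#' @export
print.de_partition_run <- function(x, ...) {
  cat("DE pipeline:", paste(names(x$results), collapse = " / "), "vs ctrl\n")
  for (nm in names(x$calls)) {
    cat(sprintf("  %s: %d regulated genes\n", nm,
                length(x$calls[[nm]]$regulated)))
  }
  print(x$partition)
  invisible(x)
}

#' Row standardization for heatmap display
#'
#' Centers and scales each row to mean 0 and sample (n - 1) standard
#' deviation 1; constant rows map to all zeros.
#'
#' @param m Numeric matrix.
#' @return Matrix of the same dimensions.
#' @export
row_standardize <- function(m) {
  m <- as.matrix(m)
  mu <- rowMeans(m)
  s <- apply(m, 1L, stats::sd)
  out <- (m - mu) / ifelse(s > 0, s, 1)
  out[s == 0, ] <- 0
  out
}
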