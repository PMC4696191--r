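#' FPKM normalization
#'
#' FPKM(g, s) = counts(g, s) * 1e9 / (length_nt(g) * total_counts(s)):
#' fragments per kilobase of CDS per million mapped fragments.
#'
#' @param counts a \code{\link{count_matrix}}.
#' @return numeric matrix of FPKM values, genes x samples.
#' @export
compute_fpkm <- function(counts) {
  stopifnot(inherits(counts, "CountMatrix"))
  totals <- colSums(counts$counts)
  if (any(totals == 0))
    abort("sample with zero total counts: ",
          colnames(counts$counts)[totals == 0][1L])
  sweep(counts$counts / counts$gene_length_nt, 2, totals, `/`) * 1e9
}

#' Median-of-ratios size factors
#'
#' DESeq-style normalization: each sample's factor is the median across genes
#' of its counts divided by the per-gene geometric mean, using only genes with
#' nonzero counts in every sample. Falls back to total-count scaling (totals
#' divided by their geometric mean) when fewer than 10 such genes exist.
#'
#' @param counts a \code{\link{count_matrix}}.
#' @return named numeric vector of size factors, one per sample.
#' @export
size_factors <- function(counts) {
  stopifnot(inherits(counts, "CountMatrix"))
  m <- counts$counts
  nonzero <- rowSums(m == 0) == 0
  if (sum(nonzero) < 10) {
    totals <- colSums(m)
    sf <- totals / exp(mean(log(totals)))
  } else {
    logm <- log(m[nonzero, , drop = FALSE])
    ref <- rowMeans(logm)                   # log geometric mean per gene
    sf <- apply(exp(logm - ref), 2, stats::median)
  }
  stats::setNames(sf, colnames(m))
}

#' Method-of-moments negative-binomial dispersion per gene
#'
#' On size-factor-normalized counts, estimates per gene the overdispersion of
#' the mean-variance relation var = mu + phi * mu^2 by the method of moments,
#' using condition-specific means and the within-condition variance pooled
#' across both conditions: phi = max(0, (s2_pooled - mbar) / mbar^2) with mbar
#' the grand mean. Floored at \code{min_disp}.
#'
#' @param counts a \code{\link{count_matrix}} with >= 2 replicates per
#'   condition.
#' @param min_disp floor applied to each estimate.
#' @return named numeric vector of per-gene dispersions.
#' @export
estimate_dispersion <- function(counts, min_disp = 1e-8) {
  stopifnot(inherits(counts, "CountMatrix"))
  cond <- counts$condition_of
  n_wt <- sum(cond == "wt"); n_mut <- sum(cond == "mut")
  if (n_wt < 2 || n_mut < 2)
    abort("dispersion estimation needs >= 2 replicates per condition")
  norm <- sweep(counts$counts, 2, size_factors(counts), `/`)
  wt <- norm[, cond == "wt", drop = FALSE]
  mut <- norm[, cond == "mut", drop = FALSE]
  ss_wt <- rowSums((wt - rowMeans(wt))^2)
  ss_mut <- rowSums((mut - rowMeans(mut))^2)
  s2 <- (ss_wt + ss_mut) / (n_wt + n_mut - 2)
  mbar <- rowMeans(norm)
  phi <- ifelse(mbar > 0, (s2 - mbar) / mbar^2, 0)
  stats::setNames(pmax(phi, min_disp), rownames(norm))
}

#' Differential expression between mutant and wild type
#'
#' Per gene: log2 fold change of mean expression (mutant over wild type, with
#' a pseudocount in FPKM units added to both means) and a two-sided Wald test
#' of equal negative-binomial means on size-factor-normalized counts.
#'
#' The fold change is computed on \emph{normalized} FPKM: counts are divided
#' by median-of-ratios size factors before the FPKM transformation, using a
#' common effective library size. Per-sample-total FPKM (the values reported
#' in \code{fpkm_wt}/\code{fpkm_mut}) is biased when a large, direction-skewed
#' fraction of the transcriptome changes -- the shifted totals leak into every
#' gene's ratio -- whereas the median-of-ratios reference is anchored on the
#' unchanged majority of genes.
#'
#' The Wald variance uses a single common dispersion -- the across-gene mean
#' of the per-gene method-of-moments estimates -- because with 3 replicates
#' per condition a per-gene plug-in dispersion makes the normal-reference
#' test strongly anti-conservative. Genes with zero counts everywhere get
#' p = 1.
#'
#' @param counts a \code{\link{count_matrix}} with >= 2 replicates per
#'   condition.
#' @param pseudo_fpkm pseudocount on the FPKM scale added to both condition
#'   means before the log-ratio (default 0.5; avoids infinite fold changes).
#' @param dispersion optional common dispersion; computed from the data when
#'   \code{NULL}.
#' @return data.frame of class \code{DEResult} with one row per gene:
#'   \code{gene_id}, \code{base_mean} (mean normalized count),
#'   \code{fpkm_wt}, \code{fpkm_mut} (condition means), \code{log2fc},
#'   \code{p_value}; \code{q_value} and \code{status} are NA until
#'   \code{\link{bh_fdr}} / \code{\link{classify_de}} are applied.
#' @export
de_test <- function(counts, pseudo_fpkm = 0.5, dispersion = NULL) {
  stopifnot(inherits(counts, "CountMatrix"))
  cond <- counts$condition_of
  n_wt <- sum(cond == "wt"); n_mut <- sum(cond == "mut")
  if (n_wt < 2 || n_mut < 2)
    abort("de_test needs >= 2 replicates per condition")

  fpkm <- compute_fpkm(counts)
  fpkm_wt <- rowMeans(fpkm[, cond == "wt", drop = FALSE])
  fpkm_mut <- rowMeans(fpkm[, cond == "mut", drop = FALSE])

  if (is.null(dispersion)) dispersion <- mean(estimate_dispersion(counts))
  sf <- size_factors(counts)
  norm <- sweep(counts$counts, 2, sf, `/`)

  # fold change on normalized counts expressed in FPKM units via a common
  # effective library size, so the pseudocount keeps its FPKM scale
  t0 <- mean(colSums(norm))
  fpkm_norm <- norm * 1e9 / (counts$gene_length_nt * t0)
  nf_wt <- rowMeans(fpkm_norm[, cond == "wt", drop = FALSE])
  nf_mut <- rowMeans(fpkm_norm[, cond == "mut", drop = FALSE])
  log2fc <- log2((nf_mut + pseudo_fpkm) / (nf_wt + pseudo_fpkm))
  mu_wt <- rowMeans(norm[, cond == "wt", drop = FALSE])
  mu_mut <- rowMeans(norm[, cond == "mut", drop = FALSE])
  var_wt <- mu_wt + dispersion * mu_wt^2
  var_mut <- mu_mut + dispersion * mu_mut^2
  se <- sqrt(var_wt / n_wt + var_mut / n_mut)
  z <- ifelse(se > 0, (mu_mut - mu_wt) / se, 0)
  p <- ifelse(se > 0, 2 * stats::pnorm(-abs(z)), 1)

  res <- data.frame(gene_id = rownames(counts$counts),
                    base_mean = rowMeans(norm),
                    fpkm_wt = fpkm_wt, fpkm_mut = fpkm_mut,
                    log2fc = log2fc, p_value = p,
                    q_value = NA_real_, status = NA_character_,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(res) <- c("DEResult", "data.frame")
  attr(res, "dispersion") <- dispersion
  res
}

#' Benjamini-Hochberg step-up q-values
#'
#' q_(i) = min over j >= i of m * p_(j) / j, capped at 1 and mapped back to
#' the input order.
#'
#' @param p_values numeric vector of p-values in [0, 1].
#' @return numeric vector of q-values in the input order.
#' @export
bh_fdr <- function(p_values) {
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1))
    abort("p-values must lie in [0, 1]")
  m <- length(p_values)
  if (m == 0L) return(numeric())
  ord <- order(p_values)
  q_sorted <- pmin(1, rev(cummin(rev(m * p_values[ord] / seq_len(m)))))
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

#' Classify genes as up-, down-regulated or not significant
#'
#' A gene is \code{up} when q < alpha and log2fc > lfc_threshold, \code{down}
#' when q < alpha and log2fc < -lfc_threshold, else \code{ns}. The default
#' threshold of 0 classifies by FDR alone; set \code{lfc_threshold = 2} to
#' additionally require a 4-fold change.
#'
#' @param results a \code{DEResult} data.frame from \code{\link{de_test}};
#'   q-values are filled in via \code{\link{bh_fdr}} if still missing.
#' @param alpha FDR significance level.
#' @param lfc_threshold minimum |log2fc| for significance calls.
#' @return \code{results} with \code{q_value} and \code{status} set.
#' @export
classify_de <- function(results, alpha = 0.05, lfc_threshold = 0) {
  stopifnot(is.data.frame(results))
  if (anyNA(results$q_value)) results$q_value <- bh_fdr(results$p_value)
  sig <- results$q_value < alpha
  results$status <- ifelse(sig & results$log2fc > lfc_threshold, "up",
                    ifelse(sig & results$log2fc < -lfc_threshold, "down", "ns"))
  results
}

#' Up/down split among significant genes
#'
#' @param results classified \code{DEResult} rows.
#' @return list with \code{n_significant}, \code{pct_up}, \code{pct_down}
#'   (percentages of significant genes, 2 decimals; both 0 with
#'   \code{empty = TRUE} when nothing is significant).
#' @export
summarize_direction <- function(results) {
  if (anyNA(results$status)) abort("statuses not set; run classify_de first")
  n_up <- sum(results$status == "up")
  n_down <- sum(results$status == "down")
  n_sig <- n_up + n_down
  if (n_sig == 0)
    return(list(n_significant = 0L, pct_up = 0, pct_down = 0, empty = TRUE))
  list(n_significant = n_sig,
       pct_up = round_half_up(100 * n_up / n_sig, 2),
       pct_down = round_half_up(100 * n_down / n_sig, 2),
       empty = FALSE)
}

#' FPKM submatrix of the n genes with the largest |log2fc|
#'
#' The heatmap-style selection: significant genes ranked by |log2fc|
#' descending, ties broken by gene id, top n (all of them when fewer than n
#' are significant).
#'
#' @param results classified \code{DEResult} rows.
#' @param fpkm FPKM matrix from \code{\link{compute_fpkm}}.
#' @param n number of genes to keep.
#' @return FPKM submatrix in rank order.
#' @export
top_n_by_abs_lfc <- function(results, fpkm, n = 100) {
  if (anyNA(results$status)) abort("statuses not set; run classify_de first")
  sig <- results[results$status != "ns", , drop = FALSE]
  ord <- order(-abs(sig$log2fc), sig$gene_id)
  ids <- sig$gene_id[ord][seq_len(min(n, nrow(sig)))]
  fpkm[ids, , drop = FALSE]
}
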