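## Normalization, expressed-gene sets, paired differential tests, consistency
## classification, rank-normal transform, hidden-factor inference and
## transcriptome-plasticity scoring for a paired control/heat expression panel.

#' Construct a paired-condition expression object
#'
#' @param counts_control,counts_heat genes x samples non-negative integer
#'   matrices with matching dimnames.
#' @param libsizes Optional list with `control` and `heat` per-sample library
#'   sizes; defaults to column sums.
#' @param cpm_mode Normalization mode passed to [cpm_normalize()]. The default
#'   `median_of_ratios` is robust to the strong compositional shift a heat
#'   response induces (a large upregulated mass deflates total-count CPM of
#'   unchanged genes).
#' @return An `expression_pair` list: gene_ids, sample_ids, counts_control,
#'   counts_heat, cpm_control, cpm_heat, libsizes.
#' @export
expression_pair <- function(counts_control, counts_heat, libsizes = NULL,
                            cpm_mode = "median_of_ratios") {
  stopifnot(all(dim(counts_control) == dim(counts_heat)),
            identical(rownames(counts_control), rownames(counts_heat)),
            identical(colnames(counts_control), colnames(counts_heat)))
  if (any(counts_control < 0) || any(counts_heat < 0)) {
    stop("counts must be non-negative")
  }
  ## normalize both conditions against one common reference so that
  ## cross-condition ratios are meaningful
  joint <- cpm_normalize(cbind(counts_control, counts_heat), mode = cpm_mode)
  ns <- ncol(counts_control)
  structure(list(
    gene_ids = rownames(counts_control),
    sample_ids = colnames(counts_control),
    counts_control = counts_control, counts_heat = counts_heat,
    cpm_control = joint[, seq_len(ns), drop = FALSE],
    cpm_heat = joint[, ns + seq_len(ns), drop = FALSE],
    libsizes = if (is.null(libsizes)) {
      list(control = colSums(counts_control), heat = colSums(counts_heat))
    } else libsizes), class = "expression_pair")
}

#' Counts-per-million normalization
#'
#' `total_count`: counts scaled so every column sums to one million.
#' `median_of_ratios`: per-sample size factors by the median-of-ratios rule
#' (median across genes of the ratio to the gene's geometric mean, computed on
#' genes with no zero counts), then rescaled to per-million units.
#'
#' @param counts genes x samples matrix with positive column sums.
#' @param mode `"total_count"` (default) or `"median_of_ratios"`.
#' @return CPM matrix of the same shape.
#' @export
cpm_normalize <- function(counts, mode = c("total_count", "median_of_ratios")) {
  mode <- match.arg(mode)
  cs <- colSums(counts)
  if (any(cs <= 0)) {
    stop("zero column sum for sample(s): ",
         paste(colnames(counts)[cs <= 0], collapse = ", "))
  }
  if (mode == "total_count") {
    sweep(counts, 2, cs, "/") * 1e6
  } else {
    lg <- rowMeans(log(counts))
    use <- is.finite(lg)
    if (!any(use)) stop("no gene has all-positive counts; cannot compute size factors")
    sf <- apply(counts[use, , drop = FALSE], 2, function(x) {
      exp(stats::median(log(x) - lg[use]))
    })
    ## effective library size sf_j * mean(cs/sf) keeps the average column
    ## total at one million while preserving the size-factor ratios
    sweep(counts, 2, sf * mean(cs / sf), "/") * 1e6
  }
}

#' Expressed-gene sets per condition
#'
#' A gene is expressed in a condition if CPM > `cpm_min` (strict) in at least
#' `ceiling(frac_min * n_samples)` genotypes.
#'
#' @param pair An [expression_pair()].
#' @param cpm_min CPM threshold (default 1, strict).
#' @param frac_min Minimum fraction of genotypes (default 0.10).
#' @return List of gene-id vectors: `control`, `heat`, `common`,
#'   `control_only`, `heat_only`.
#' @export
expressed_gene_sets <- function(pair, cpm_min = 1, frac_min = 0.10) {
  need <- ceiling(frac_min * length(pair$sample_ids))
  in_c <- rowSums(pair$cpm_control > cpm_min) >= need
  in_h <- rowSums(pair$cpm_heat > cpm_min) >= need
  g <- pair$gene_ids
  list(control = g[in_c], heat = g[in_h], common = g[in_c & in_h],
       control_only = g[in_c & !in_h], heat_only = g[in_h & !in_c])
}

#' Paired differential expression between conditions
#'
#' Per gene, a paired Wilcoxon signed-rank test over genotypes on CPM values,
#' BH adjustment across tested genes, and up/down calls by adjusted p-value
#' and the median log2 ratio (with +1 pseudocount on both CPMs).
#'
#' @param pair An [expression_pair()].
#' @param genes Gene ids to test (typically the union of expressed sets).
#' @param p_adj_max Adjusted-p threshold for significance (default 0.01).
#' @param lfc_min |log2 fold change| threshold for up/down calls (default 1).
#' @return data.frame per gene: log2fc_median, cv_heat, de_p, de_p_adj,
#'   up_DEG, down_DEG.
#' @export
paired_de <- function(pair, genes = pair$gene_ids, p_adj_max = 0.01,
                      lfc_min = 1) {
  if (length(pair$sample_ids) < 6L) {
    warning("fewer than 6 genotypes: paired test has low power")
  }
  idx <- match(genes, pair$gene_ids)
  cc <- pair$cpm_control[idx, , drop = FALSE]
  ch <- pair$cpm_heat[idx, , drop = FALSE]
  p <- vapply(seq_along(idx), function(i) {
    paired_signed_rank(cc[i, ], ch[i, ])$p
  }, numeric(1))
  lfc <- log2((apply(ch, 1, stats::median) + 1) /
                (apply(cc, 1, stats::median) + 1))
  mu_h <- rowMeans(ch)
  cv_heat <- ifelse(mu_h > 0, apply(ch, 1, stats::sd) / mu_h, NA_real_)
  p_adj <- adjust_pvalues(p, "bh")
  data.frame(gene_id = genes, log2fc_median = lfc, cv_heat = cv_heat,
             de_p = p, de_p_adj = p_adj,
             up_DEG = p_adj < p_adj_max & lfc > lfc_min,
             down_DEG = p_adj < p_adj_max & lfc < -lfc_min,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Consistently upregulated genes
#'
#' A gene is consistently upregulated if the median and the `quantile_q`
#' quantile (type-7) of the per-genotype log2((CPM_heat+1)/(CPM_control+1))
#' ratios are both strictly positive.
#'
#' @param pair An [expression_pair()].
#' @param genes Gene ids to assess (default all).
#' @param quantile_q Quantile to require > 0 (default 0.90, as an additional
#'   condition to the median; configurable).
#' @return Character vector of gene ids.
#' @export
consistent_upregulation <- function(pair, genes = pair$gene_ids,
                                    quantile_q = 0.90) {
  idx <- match(genes, pair$gene_ids)
  r <- log2((pair$cpm_heat[idx, , drop = FALSE] + 1) /
              (pair$cpm_control[idx, , drop = FALSE] + 1))
  med <- apply(r, 1, stats::median)
  qq <- apply(r, 1, stats::quantile, probs = quantile_q, type = 7)
  genes[med > 0 & qq > 0]
}

#' Rank-based inverse normal transform
#'
#' Blom-offset transform `qnorm((rank - 3/8) / (n + 1/4))`; ties receive the
#' average rank. A constant vector returns all zeros with a warning.
#'
#' @param x Numeric vector (length >= 3).
#' @return Transformed vector, strictly monotone on distinct values.
#' @export
inverse_normal_transform <- function(x) {
  if (length(x) < 3L) stop("need at least 3 values")
  if (length(unique(x)) == 1L) {
    warning("constant vector; inverse normal transform returns zeros")
    return(rep(0, length(x)))
  }
  stats::qnorm((rank(x, ties.method = "average") - 3 / 8) /
                 (length(x) + 1 / 4))
}

#' Infer hidden expression factors
#'
#' PCA surrogate for probabilistic hidden-factor models: expression is
#' standardized per gene, residualized on the known covariates (with
#' intercept), and the top `k` principal-component scores over samples are
#' returned with a deterministic sign convention.
#'
#' @param expr Normalized genes x samples matrix.
#' @param k Number of factors (default 25; use smaller k for small panels).
#' @param known_covariates Optional samples x c matrix to residualize on.
#' @return samples x k factor score matrix (empty matrix when `k = 0`).
#' @export
infer_hidden_factors <- function(expr, k = 25L, known_covariates = NULL) {
  n <- ncol(expr)
  if (k >= n) stop("k must be smaller than the number of samples")
  if (k == 0L) return(matrix(numeric(0), nrow = n, ncol = 0))
  sdv <- apply(expr, 1, stats::sd)
  z <- (expr[sdv > 0, , drop = FALSE] - rowMeans(expr[sdv > 0, , drop = FALSE])) /
    sdv[sdv > 0]
  m <- t(z)  # samples x genes
  if (!is.null(known_covariates)) {
    q <- qr(cbind(1, known_covariates))
    m <- m - qr.fitted(q, m)
  }
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE, rank. = k)
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  scores <- sweep(pc$x[, seq_len(k), drop = FALSE], 2, flip, "*")
  colnames(scores) <- paste0("F", seq_len(k))
  rownames(scores) <- colnames(expr)
  scores
}

#' Transcriptome plasticity per genotype
#'
#' PCA over the column-stacked control+heat expression matrix; the absolute
#' difference of PC1 between a genotype's heat and control columns measures
#' its transcriptome shift. Genotypes are classed into equal-size tertiles
#' (`small`, `medium`, `large`; ties go to the lower class).
#'
#' @param expr_control,expr_heat Normalized genes x samples matrices over the
#'   same genotypes.
#' @return data.frame with sample_id, delta_pc1, class.
#' @export
transcriptome_plasticity <- function(expr_control, expr_heat) {
  stopifnot(all(dim(expr_control) == dim(expr_heat)))
  n <- ncol(expr_control)
  stacked <- t(cbind(expr_control, expr_heat))  # (2n) x genes
  pc1 <- stats::prcomp(stacked, center = TRUE, rank. = 1)$x[, 1]
  d <- abs(pc1[n + seq_len(n)] - pc1[seq_len(n)])
  r <- rank(d, ties.method = "first")
  cls <- cut(r, breaks = stats::quantile(r, c(0, 1/3, 2/3, 1)),
             labels = c("small", "medium", "large"), include.lowest = TRUE)
  data.frame(sample_id = colnames(expr_control), delta_pc1 = unname(d),
             class = as.character(cls), stringsAsFactors = FALSE)
}
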