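## Variant statistics, filtering, LD pruning, population-structure PCs and
## diversity-based subset selection for an inbred-panel dosage matrix.

#' Per-variant summary statistics
#'
#' @param G A [genotype_matrix()].
#' @return data.frame with `maf` (minor allele frequency, <= 0.5), `het_rate`
#'   and `missing_rate`, all computed on non-missing calls.
#' @export
variant_stats <- function(G) {
  d <- G$dosage
  n_called <- colSums(!is.na(d))
  af <- colSums(d, na.rm = TRUE) / (2 * pmax(n_called, 1L))
  data.frame(
    id = G$variants$id,
    maf = pmin(af, 1 - af),
    het_rate = colSums(d == 1, na.rm = TRUE) / pmax(n_called, 1L),
    missing_rate = colSums(is.na(d)) / nrow(d),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Filter variants and optionally impute residual missing calls
#'
#' Retains variants with MAF >= `maf_min`, heterozygous rate <= `het_max` and
#' missing rate <= `max_missing` (boundary values retained). With
#' `impute = TRUE`, residual missing dosages are replaced by the variant mean
#' rounded to the nearest of \{0, 1, 2\} (ties toward 1).
#'
#' @param G A [genotype_matrix()].
#' @param maf_min,het_max,max_missing Thresholds (defaults 0.1 / 0.1 / 0).
#' @param impute Impute residual missing dosages (default `TRUE`).
#' @param indel_maf_exempt If `TRUE`, InDels are exempt from the MAF filter
#'   (they are still subject to the missingness rule). Default `FALSE`:
#'   all variants are treated uniformly.
#' @return The filtered (and imputed) [genotype_matrix()].
#' @export
variant_filter <- function(G, maf_min = 0.1, het_max = 0.1, max_missing = 0,
                           impute = TRUE, indel_maf_exempt = FALSE) {
  st <- variant_stats(G)
  keep_maf <- st$maf >= maf_min
  if (indel_maf_exempt) keep_maf <- keep_maf | G$variants$is_indel
  keep <- keep_maf & st$het_rate <= het_max & st$missing_rate <= max_missing
  if (!any(keep)) warning("all variants removed by filtering")
  out <- genotype_matrix(G$dosage[, keep, drop = FALSE],
                         G$variants[keep, , drop = FALSE])
  out$subpop <- G$subpop
  if (impute && anyNA(out$dosage)) out$dosage <- impute_dosage(out$dosage)
  out
}

#' Mean-round imputation of missing dosages
#'
#' Missing calls are replaced by the variant's mean dosage rounded to the
#' nearest of \{0, 1, 2\}; exact ties (mean 0.5 or 1.5) round toward 1.
#' @param dosage samples x variants matrix.
#' @return Matrix with no missing values.
#' @export
impute_dosage <- function(dosage) {
  mu <- colMeans(dosage, na.rm = TRUE)
  fill <- ifelse(mu < 0.5, 0L, ifelse(mu <= 1.5, 1L, 2L))
  idx <- which(is.na(dosage), arr.ind = TRUE)
  if (nrow(idx)) dosage[idx] <- fill[idx[, 2]]
  dosage
}

#' Squared dosage correlation (LD r^2) between two variants
#'
#' Pearson correlation squared over pairwise-complete samples. A constant
#' vector yields 0 with a warning.
#' @param d1,d2 Equal-length dosage vectors.
#' @return r^2 in \[0, 1\].
#' @export
pairwise_r2 <- function(d1, d2) {
  if (length(d1) != length(d2)) stop("dosage vectors must have equal length")
  ok <- !is.na(d1) & !is.na(d2)
  d1 <- d1[ok]; d2 <- d2[ok]
  if (stats::var(d1) == 0 || stats::var(d2) == 0) {
    warning("constant dosage vector; r^2 defined as 0")
    return(0)
  }
  stats::cor(d1, d2)^2
}

## One window of the greedy pruning rule: repeatedly drop the lower-MAF member
## (tie: later position) of the worst violating pair until no pair violates.
prune_window <- function(dos, maf, pos, r2_max) {
  keep <- seq_len(ncol(dos))
  repeat {
    if (length(keep) < 2L) break
    cm <- suppressWarnings(stats::cor(dos[, keep, drop = FALSE]))
    cm[is.na(cm)] <- 1  # constant columns: treat as fully redundant
    r2 <- cm^2
    r2[upper.tri(r2, diag = TRUE)] <- 0
    viol <- which(r2 > r2_max, arr.ind = TRUE)
    if (nrow(viol) == 0L) break
    pair <- keep[c(viol[1, "row"], viol[1, "col"])]
    drop <- if (maf[pair[1]] < maf[pair[2]]) pair[1]
            else if (maf[pair[2]] < maf[pair[1]]) pair[2]
            else pair[which.max(pos[pair])]
    keep <- setdiff(keep, drop)
  }
  keep
}

#' Windowed greedy LD pruning
#'
#' Mirrors the classical windowed pairwise rule (window of `window` variants
#' slid by `step`, per chromosome, left to right): within each window, while
#' any retained pair has r^2 > `r2_max`, the member with the lower MAF is
#' removed (tie: the later by position).
#'
#' @param G A filtered [genotype_matrix()] (no missing dosages).
#' @param window Window size in variants (default 50).
#' @param step Slide in variants (default 5).
#' @param r2_max Pruning threshold (default 0.99).
#' @return Character vector of retained variant ids.
#' @export
ld_prune <- function(G, window = 50L, step = 5L, r2_max = 0.99) {
  v <- G$variants
  maf <- variant_stats(G)$maf
  keep <- rep(TRUE, nrow(v))
  for (ch in unique(v$chrom)) {
    idx <- which(v$chrom == ch)
    start <- 1L
    while (start <= length(idx)) {
      win <- idx[start:min(start + window - 1L, length(idx))]
      act <- win[keep[win]]
      if (length(act) >= 2L) {
        kept <- prune_window(G$dosage[, act, drop = FALSE], maf[act],
                             v$pos[act], r2_max)
        keep[setdiff(act, act[kept])] <- FALSE
      }
      if (start + window - 1L >= length(idx)) break
      start <- start + step
    }
  }
  v$id[keep]
}

#' Population-structure principal components
#'
#' PCA of the samples x variants dosage matrix (columns mean-centered, not
#' scaled). Scores are ordered by decreasing explained variance with a fixed
#' sign convention (the largest-magnitude loading of each component is
#' positive).
#'
#' @param G A [genotype_matrix()] with no missing dosages.
#' @param n_components Number of PCs (default 5).
#' @return samples x components score matrix with an `explained` attribute
#'   (fraction of variance per component).
#' @export
compute_pcs <- function(G, n_components = 5L) {
  d <- G$dosage
  if (anyNA(d)) stop("missing dosages; impute first")
  if (n_components > min(dim(d))) {
    stop("n_components exceeds min(n_samples, n_variants)")
  }
  pc <- stats::prcomp(d, center = TRUE, scale. = FALSE, rank. = n_components)
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  scores <- sweep(pc$x, 2, flip, "*")
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  attr(scores, "explained") <- (pc$sdev^2 / sum(pc$sdev^2))[seq_len(n_components)]
  scores
}

#' Diversity-preserving subset selection
#'
#' Pre-filters variants (MAF > 0.05, het <= 0.2, no missing), randomly
#' subsamples up to `snps_per_chrom` variants per chromosome, computes
#' Euclidean distances between samples, cuts a Ward-linkage tree into
#' `n_clusters` clusters and returns one representative per cluster: the
#' cluster medoid (minimum mean within-cluster distance; ties broken by
#' lexicographic sample id).
#'
#' @param G A [genotype_matrix()].
#' @param n_clusters Number of clusters / representatives.
#' @param snps_per_chrom Variants sampled per chromosome (default 1000).
#' @param seed Seed for the variant subsample.
#' @return Character vector of selected sample ids.
#' @export
select_diverse_subset <- function(G, n_clusters, snps_per_chrom = 1000L,
                                  seed = 1L) {
  if (n_clusters > nrow(G$dosage)) stop("n_clusters exceeds sample count")
  st <- variant_stats(G)
  elig <- which(st$maf > 0.05 & st$het_rate <= 0.2 & st$missing_rate == 0)
  v <- G$variants
  pick <- with_seed(stage_seed(seed, "subset"), {
    unlist(lapply(unique(v$chrom), function(ch) {
      i <- intersect(which(v$chrom == ch), elig)
      if (length(i) < snps_per_chrom) {
        warning("fewer eligible variants than requested on ", ch,
                "; using all ", length(i))
        i
      } else sample(i, snps_per_chrom)
    }))
  })
  dmat <- stats::dist(G$dosage[, pick, drop = FALSE])
  cl <- stats::cutree(stats::hclust(dmat, method = "ward.D2"), k = n_clusters)
  dm <- as.matrix(dmat)
  ids <- rownames(G$dosage)
  reps <- vapply(seq_len(n_clusters), function(k) {
    members <- which(cl == k)
    within <- rowMeans(dm[members, members, drop = FALSE])
    cand <- members[within == min(within)]
    ids[cand[order(ids[cand])[1]]]
  }, character(1))
  sort(reps)
}
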