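## Per-condition gene-variant association scan with covariates, cis/trans
## classification, variance explained and trans-hotspot detection.
##
## The scan residualizes both expression and dosage on the covariates (QR
## projection) and converts the Pearson correlation of the residuals into the
## usual t statistic with df = n - c - 2: inference identical to per-pair
## ordinary least squares with covariates, at matrix speed. BH adjustment
## needs every raw p-value, so the scan runs in two passes over gene blocks:
## a compact first pass collecting (p, stratum) for the whole grid, then a
## second pass materializing full records only for retained pairs.

#' Signed distance of a variant to a gene body
#'
#' 0 inside \[start, end\]; otherwise the signed distance to the nearest gene
#' edge, negative upstream with respect to the gene's strand.
#' @keywords internal
gene_body_distance <- function(pos, start, end, strand) {
  d <- ifelse(pos < start, pos - start, ifelse(pos > end, pos - end, 0))
  ifelse(rep(strand == "-", length.out = length(d)), -d, d)
}

#' Proportion of expression variance explained by an association
#'
#' @param t_stat t statistic.
#' @param df Residual degrees of freedom (> 0).
#' @return `t^2 / (t^2 + df)`, in \[0, 1).
#' @export
variance_explained <- function(t_stat, df) {
  if (any(df <= 0)) stop("df must be positive")
  t_stat^2 / (t_stat^2 + df)
}

## residualized-correlation statistics for one block of genes; returns the
## pieces needed to assemble records
scan_block <- function(expr_rows, qx, Dn, ssd_ok, df, gm_rows, v, cis_bp) {
  E <- t(expr_rows)
  E <- E - qr.fitted(qx, E)
  sse <- colSums(E^2)
  En <- sweep(E, 2, sqrt(pmax(sse, 1e-300)), "/")
  r <- crossprod(En, Dn)
  r[, !ssd_ok] <- NA_real_
  r <- pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
  tt <- r * sqrt(df / (1 - r^2))
  dist <- matrix(NA_real_, nrow(r), nrow(v))
  for (k in seq_len(nrow(r))) {
    on <- which(gm_rows$chrom[k] == v$chrom)
    dist[k, on] <- gene_body_distance(v$pos[on], gm_rows$start[k],
                                      gm_rows$end[k], gm_rows$strand[k])
  }
  is_cis <- !is.na(dist) & abs(dist) <= cis_bp
  list(r = r, t = tt, sse = sse, dist = dist, is_cis = is_cis)
}

#' Gene-variant association scan
#'
#' Tests every gene x variant pair for association between (transformed)
#' expression and alt-allele dosage, controlling for covariates. Pairs are
#' classified cis (|gene-body distance| <= `cis_bp`, same chromosome) or
#' trans, and BH adjustment is applied within each stratum separately (or
#' jointly with `bh_strata = "joint"`).
#'
#' @param expr genes x samples matrix (typically inverse-normal transformed).
#' @param G A [genotype_matrix()] with no missing dosages.
#' @param covariates samples x c numeric matrix (intercept added internally);
#'   `NULL` for none.
#' @param genes Gene models (gene_id, chrom, start, end, strand).
#' @param condition Label stored in the result (`"control"` or `"heat"`).
#' @param p_adj_max Hit threshold on the BH-adjusted p (default 0.01, strict).
#' @param cis_bp cis window around the gene body (default 1e6, inclusive).
#' @param bh_strata `"separate"` (default) or `"joint"` adjustment.
#' @param keep `"significant"` (default) returns hits only; `"all"` returns
#'   every tested pair (intended for small scans).
#' @param block_size Genes per processing block.
#' @return data.frame of association records: gene_id, variant_id, chrom, pos,
#'   condition, beta, t_stat, df, p, p_adj, klass, distance_bp, var_explained.
#'   Attributes: `n_tested` (per stratum) and `n_skipped` (pairs dropped for
#'   constant residualized dosage).
#' @export
scan_associations <- function(expr, G, covariates, genes,
                              condition = "control", p_adj_max = 0.01,
                              cis_bp = 1e6, bh_strata = c("separate", "joint"),
                              keep = c("significant", "all"),
                              block_size = 200L) {
  bh_strata <- match.arg(bh_strata)
  keep <- match.arg(keep)
  n <- ncol(expr)
  stopifnot(nrow(G$dosage) == n)
  X <- if (is.null(covariates)) matrix(1, n, 1) else cbind(1, as.matrix(covariates))
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("collinear covariates")
  df <- n - ncol(X) - 1L
  if (df <= 0) stop("not enough samples for the covariate set")

  D <- G$dosage - qr.fitted(qx, G$dosage)
  ssd <- colSums(D^2)
  ssd_ok <- ssd >= 1e-12
  Dn <- sweep(D, 2, sqrt(pmax(ssd, 1e-300)), "/")
  gm <- genes[match(rownames(expr), genes$gene_id), , drop = FALSE]
  v <- G$variants
  blocks <- split(seq_len(nrow(expr)),
                  ceiling(seq_len(nrow(expr)) / block_size))

  ## pass 1: p-values and strata only
  p_all <- vector("list", length(blocks))
  cis_all <- vector("list", length(blocks))
  for (b in seq_along(blocks)) {
    rows <- blocks[[b]]
    sb <- scan_block(expr[rows, , drop = FALSE], qx, Dn, ssd_ok, df,
                     gm[rows, , drop = FALSE], v, cis_bp)
    p_all[[b]] <- as.vector(2 * stats::pt(-abs(sb$t), df))
    cis_all[[b]] <- as.vector(sb$is_cis)
  }
  p <- unlist(p_all, use.names = FALSE)
  is_cis <- unlist(cis_all, use.names = FALSE)
  tested <- !is.na(p)
  p_adj <- rep(NA_real_, length(p))
  if (bh_strata == "separate") {
    for (ci in c(TRUE, FALSE)) {
      i <- tested & (is_cis == ci)
      if (any(i)) p_adj[i] <- adjust_pvalues(p[i], "bh")
    }
  } else {
    p_adj[tested] <- adjust_pvalues(p[tested], "bh")
  }
  retain <- tested & (if (keep == "significant") p_adj < p_adj_max else TRUE)
  n_tested <- c(cis = sum(tested & is_cis), trans = sum(tested & !is_cis))
  n_skipped <- sum(!tested)

  ## pass 2: materialize records for retained pairs
  out <- vector("list", length(blocks))
  offset <- 0L
  for (b in seq_along(blocks)) {
    rows <- blocks[[b]]
    sz <- length(rows) * nrow(v)
    ret <- retain[offset + seq_len(sz)]
    if (any(ret)) {
      sb <- scan_block(expr[rows, , drop = FALSE], qx, Dn, ssd_ok, df,
                       gm[rows, , drop = FALSE], v, cis_bp)
      gi <- ((which(ret) - 1L) %% length(rows)) + 1L
      vi <- ((which(ret) - 1L) %/% length(rows)) + 1L
      beta <- sb$r[ret] * sqrt(sb$sse[gi] / ssd[vi])
      out[[b]] <- data.frame(
        gene_id = gm$gene_id[rows][gi], variant_id = v$id[vi],
        chrom = v$chrom[vi], pos = v$pos[vi], condition = condition,
        beta = beta, t_stat = sb$t[ret], df = df,
        p = p[offset + which(ret)], p_adj = p_adj[offset + which(ret)],
        klass = ifelse(sb$is_cis[ret], "cis", "trans"),
        distance_bp = sb$dist[ret],
        var_explained = variance_explained(sb$t[ret], df),
        stringsAsFactors = FALSE)
    }
    offset <- offset + sz
  }
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(), variant_id = character(),
                      chrom = character(), pos = integer(),
                      condition = character(), beta = numeric(),
                      t_stat = numeric(), df = integer(), p = numeric(),
                      p_adj = numeric(), klass = character(),
                      distance_bp = numeric(), var_explained = numeric(),
                      stringsAsFactors = FALSE)
  }
  out <- out[order(out$gene_id, out$p), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_tested") <- n_tested
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Trans-eQTL hotspot detection
#'
#' A variant is a candidate trans regulator if it targets at least
#' `min_targets_per_variant` genes remotely (> `remote_bp` or on another
#' chromosome). The genome is segmented into fixed `bin_bp` bins (0-based
#' grid); a bin is a hotspot if the union of target genes across its candidate
#' variants has at least `min_union_targets` members (strictly more than 10
#' with the defaults).
#'
#' @param hits Trans association records from [scan_associations()].
#' @param bin_bp Bin width (default 10 kb).
#' @param min_targets_per_variant Candidate rule (default 3, inclusive).
#' @param min_union_targets Hotspot rule (default 11: "more than 10").
#' @param remote_bp Remote threshold (default 1 Mb, exclusive).
#' @return data.frame of bins: chrom, bin_start (0-based), n_candidate_variants,
#'   n_union_targets, is_hotspot.
#' @export
detect_hotspots <- function(hits, bin_bp = 10000L, min_targets_per_variant = 3L,
                            min_union_targets = 11L, remote_bp = 1e6) {
  empty <- data.frame(chrom = character(), bin_start = integer(),
                      n_candidate_variants = integer(),
                      n_union_targets = integer(), is_hotspot = logical(),
                      stringsAsFactors = FALSE)
  h <- hits[hits$klass == "trans", , drop = FALSE]
  h <- h[is.na(h$distance_bp) | abs(h$distance_bp) > remote_bp, , drop = FALSE]
  if (nrow(h) == 0L) return(empty)
  per_var <- lapply(split(h$gene_id, h$variant_id), unique)
  cand <- names(per_var)[lengths(per_var) >= min_targets_per_variant]
  h <- h[h$variant_id %in% cand, , drop = FALSE]
  if (nrow(h) == 0L) return(empty)
  h$bin_start <- as.integer(floor((h$pos - 1) / bin_bp) * bin_bp)
  bins <- do.call(rbind, lapply(split(h, paste(h$chrom, h$bin_start)),
                                function(d) {
    data.frame(chrom = d$chrom[1], bin_start = d$bin_start[1],
               n_candidate_variants = length(unique(d$variant_id)),
               n_union_targets = length(unique(d$gene_id)),
               is_hotspot = length(unique(d$gene_id)) >= min_union_targets,
               stringsAsFactors = FALSE)
  }))
  bins <- bins[order(bins$chrom, bins$bin_start), , drop = FALSE]
  rownames(bins) <- NULL
  bins
}
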