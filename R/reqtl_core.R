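## Candidate cis-eQTL selection, genotype x condition interaction testing with
## a paired random-intercept mixed model, reQTL calling, responsive-gene
## classification, heat-expressed-only eGene detection and flanking rescans.
##
## The interaction model is
##   E = intercept + d + c + X_1..X_k + X_1:c..X_k:c + d:c + (1 | genotype)
## with d the alt-allele dosage, c the condition (control 0, heat 1) and X the
## sample-level covariates. With one control and one heat observation per
## genotype, an orthonormal within-genotype sum/difference transform makes the
## covariance diagonal with two strata (sum rows: sigma_e^2 + 2 sigma_g^2;
## difference rows: sigma_e^2), so REML reduces to a one-dimensional profile
## over the stratum variance ratio and the Satterthwaite denominator degrees
## of freedom for the d:c contrast have an analytic form. lmerTest fits the
## identical model and is used as an independent cross-check in the test
## suite.

#' Select candidate cis-eQTLs for interaction testing
#'
#' Per gene and condition, the top significant cis variant is selected (exact
#' p ties broken by a seeded uniform draw). Genes significant in both
#' conditions keep one variant if the two tops are identical or in high LD
#' (r^2 > `r2_ld`, seeded random pick), and both variants if in low LD
#' (r^2 <= `r2_ld`). Genes significant in one condition keep that variant.
#'
#' @param hits_control,hits_heat cis association records from
#'   [scan_associations()].
#' @param G A [genotype_matrix()] (for LD between non-identical tops).
#' @param genes_common Optional gene-id filter (genes expressed in both
#'   conditions).
#' @param r2_ld High-LD threshold (default 0.8, strict >).
#' @param seed Seed for tie and high-LD picks.
#' @return data.frame: gene_id, variant_id, selection_rule in
#'   \{identical_top, high_ld_pick, low_ld_both, single_condition\}.
#' @export
select_candidates <- function(hits_control, hits_heat, G, genes_common = NULL,
                              r2_ld = 0.8, seed = 1L) {
  top_per_gene <- function(hits) {
    h <- hits[hits$klass == "cis", , drop = FALSE]
    if (!is.null(genes_common)) h <- h[h$gene_id %in% genes_common, , drop = FALSE]
    split(h, h$gene_id)
  }
  tc <- top_per_gene(hits_control)
  th <- top_per_gene(hits_heat)
  genes <- sort(union(names(tc), names(th)))
  with_seed(stage_seed(seed, "candidates"), {
    rows <- lapply(genes, function(g) {
      pick_top <- function(h) {
        if (is.null(h) || nrow(h) == 0L) return(NA_character_)
        best <- h$variant_id[h$p == min(h$p)]
        if (length(best) > 1L) sample(sort(best), 1) else best
      }
      v1 <- pick_top(tc[[g]])
      v2 <- pick_top(th[[g]])
      if (is.na(v1) && is.na(v2)) return(NULL)
      if (is.na(v1) || is.na(v2)) {
        return(data.frame(gene_id = g, variant_id = ifelse(is.na(v1), v2, v1),
                          selection_rule = "single_condition",
                          stringsAsFactors = FALSE))
      }
      if (v1 == v2) {
        return(data.frame(gene_id = g, variant_id = v1,
                          selection_rule = "identical_top",
                          stringsAsFactors = FALSE))
      }
      r2 <- suppressWarnings(pairwise_r2(G$dosage[, v1], G$dosage[, v2]))
      if (r2 > r2_ld) {
        data.frame(gene_id = g, variant_id = sample(sort(c(v1, v2)), 1),
                   selection_rule = "high_ld_pick", stringsAsFactors = FALSE)
      } else {
        data.frame(gene_id = g, variant_id = c(v1, v2),
                   selection_rule = "low_ld_both", stringsAsFactors = FALSE)
      }
    })
    out <- do.call(rbind, rows)
    if (is.null(out)) {
      out <- data.frame(gene_id = character(), variant_id = character(),
                        selection_rule = character(), stringsAsFactors = FALSE)
    }
    rownames(out) <- NULL
    out
  })
}

#' Genotype x condition interaction mixed-model fit
#'
#' REML fit of the paired two-condition random-intercept model (see module
#' header) and a Satterthwaite-approximated t test of the dosage x condition
#' interaction. Genotypes lacking a complete control/heat pair are dropped.
#' Aliased fixed-effect columns (collinear covariates) are dropped with a
#' warning; if the interaction column itself is aliased the fit is flagged
#' non-converged with a missing p-value.
#'
#' @param y Numeric response (normalized expression), stacked over conditions.
#' @param d Alt-allele dosage per observation (constant within genotype).
#' @param condition 0/1 per observation (control 0, heat 1).
#' @param covariates Observation x k covariate matrix (or `NULL`).
#' @param genotype Genotype id per observation.
#' @return One-row data.frame: beta_interaction, se, df_satterthwaite, t_stat,
#'   p_raw, n_genotypes, sigma2_genotype, sigma2_resid, converged, n_dropped.
#' @export
fit_interaction_lmm <- function(y, d, condition, covariates = NULL, genotype) {
  stopifnot(length(d) == length(y), length(condition) == length(y),
            length(genotype) == length(y))
  condition <- as.numeric(condition)
  if (!all(condition %in% c(0, 1))) stop("condition must be coded 0/1")
  gid <- as.character(genotype)
  ctrl <- which(condition == 0)
  heat <- which(condition == 1)
  m_c <- ctrl[match(unique(gid), gid[ctrl])]
  m_h <- heat[match(unique(gid), gid[heat])]
  ok <- !is.na(m_c) & !is.na(m_h)
  n_dropped <- length(unique(gid)) - sum(ok)
  ic <- m_c[ok]; ih <- m_h[ok]
  n <- length(ic)
  bad_fit <- function() data.frame(
    beta_interaction = NA_real_, se = NA_real_, df_satterthwaite = NA_real_,
    t_stat = NA_real_, p_raw = NA_real_, n_genotypes = n,
    sigma2_genotype = NA_real_, sigma2_resid = NA_real_, converged = FALSE,
    n_dropped = n_dropped)
  if (n < 4L) return(bad_fit())
  dd <- d[ic]
  if (any(abs(d[ih] - dd) > 1e-9)) stop("dosage differs within a genotype")
  if (stats::var(dd) == 0) return(bad_fit())
  k <- if (is.null(covariates)) 0L else ncol(covariates)
  build_x <- function(idx, cval) {
    cv <- if (k > 0) as.matrix(covariates)[idx, , drop = FALSE] else NULL
    cbind(intercept = 1, d = dd, c = cval, cv,
          if (k > 0) cv * cval else NULL, d_c = dd * cval)
  }
  Xc <- build_x(ic, 0)
  Xh <- build_x(ih, 1)
  colnames(Xc) <- colnames(Xh) <- c(
    "intercept", "d", "c",
    if (k > 0) paste0("x", seq_len(k)),
    if (k > 0) paste0("x", seq_len(k), ":c"), "d:c")
  yv <- c(y[ic], y[ih])
  X <- rbind(Xc, Xh)
  ## drop aliased columns, keeping the interaction if at all estimable
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    keep_cols <- sort(qx$pivot[seq_len(qx$rank)])
    if (!(ncol(X) %in% keep_cols)) return(bad_fit())
    warning("dropping ", ncol(X) - qx$rank, " aliased covariate column(s)")
    X <- X[, keep_cols, drop = FALSE]
    Xc <- Xc[, keep_cols, drop = FALSE]
    Xh <- Xh[, keep_cols, drop = FALSE]
  }
  p <- ncol(X)
  N <- 2L * n
  if (N - p < 3L) return(bad_fit())

  ## orthonormal within-genotype transform: sum and difference strata
  sq <- sqrt(2)
  Xs <- (Xc + Xh) / sq; ys <- (yv[seq_len(n)] + yv[n + seq_len(n)]) / sq
  Xd <- (Xh - Xc) / sq; yd <- (yv[n + seq_len(n)] - yv[seq_len(n)]) / sq
  Xt <- rbind(Xs, Xd)
  yt <- c(ys, yd)
  stratum_s <- seq_len(n)

  Ms <- crossprod(Xs)
  Md <- crossprod(Xd)
  Xsy <- crossprod(Xs, ys)
  Xdy <- crossprod(Xd, yd)
  yy_s <- sum(ys^2); yy_d <- sum(yd^2)
  wls <- function(log_phi) {
    wphi <- exp(-log_phi)
    XtWX <- wphi * Ms + Md
    R <- tryCatch(chol(XtWX), error = function(e) NULL)
    if (is.null(R)) return(NULL)
    beta <- backsolve(R, forwardsolve(t(R), wphi * Xsy + Xdy))
    rss <- wphi * yy_s + yy_d - sum(beta * (wphi * Xsy + Xdy))
    list(R = R, beta = drop(beta), rss = max(rss, 1e-300),
         logdet = 2 * sum(log(diag(R))))
  }
  crit <- function(log_phi) {
    f <- wls(log_phi)
    if (is.null(f)) return(Inf)
    (N - p) * log(f$rss / (N - p)) + n * log_phi + f$logdet
  }
  opt <- stats::optimize(crit, interval = c(0, log(1e8)), tol = 1e-9)
  log_phi <- opt$minimum
  ## allow the boundary phi = 1 (sigma_g^2 = 0) to win exactly
  if (crit(0) <= opt$objective) log_phi <- 0
  f <- wls(log_phi)
  if (is.null(f)) return(bad_fit())
  phi <- exp(log_phi)
  sigma2_d <- f$rss / (N - p)
  sigma2_s <- phi * sigma2_d
  beta <- f$beta
  names(beta) <- colnames(X)
  C <- sigma2_d * chol2inv(f$R)
  j <- p  # d:c column
  g_var <- C[j, j]
  se <- sqrt(g_var)
  tval <- beta[j] / se

  ## Satterthwaite df from the two-stratum REML information
  CM <- list(s = C %*% Ms, d = C %*% Md)
  sig <- c(s = sigma2_s, d = sigma2_d)
  nk <- c(s = n, d = n)
  grad <- vapply(c("s", "d"), function(a) {
    (CM[[a]] %*% C)[j, j] / sig[[a]]^2
  }, numeric(1))
  info <- matrix(0, 2, 2, dimnames = list(c("s", "d"), c("s", "d")))
  for (a in c("s", "d")) for (b in c("s", "d")) {
    tr_cross <- sum(CM[[a]] * t(CM[[b]]))  # tr(C Ma C Mb)
    val <- tr_cross / (sig[[a]]^2 * sig[[b]]^2)
    if (a == b) {
      val <- nk[[a]] / sig[[a]]^2 - 2 * sum(diag(CM[[a]])) / sig[[a]]^3 +
        tr_cross / sig[[a]]^4
    }
    info[a, b] <- val / 2
  }
  denom <- tryCatch(drop(t(grad) %*% solve(info, grad)),
                    error = function(e) NA_real_)
  df_sat <- if (is.finite(denom) && denom > 0) 2 * g_var^2 / denom else N - p
  p_raw <- 2 * stats::pt(-abs(tval), df_sat)
  data.frame(beta_interaction = unname(beta[j]), se = se,
             df_satterthwaite = df_sat, t_stat = unname(tval), p_raw = p_raw,
             n_genotypes = n, sigma2_genotype = max(0, (sigma2_s - sigma2_d) / 2),
             sigma2_resid = sigma2_d, converged = TRUE, n_dropped = n_dropped)
}

#' Fit the interaction model for a set of candidate gene/variant pairs
#'
#' @param candidates data.frame with gene_id and variant_id.
#' @param tc,th Transformed genes x samples expression matrices (control,
#'   heat), same sample order as `G`.
#' @param G A [genotype_matrix()].
#' @param covariates Per-observation covariates for the stacked model: either
#'   a samples x k matrix (condition-invariant) or a (2 samples) x k matrix in
#'   stacked order (control block then heat block).
#' @return data.frame of [fit_interaction_lmm()] rows plus gene_id and
#'   variant_id.
#' @export
fit_candidates <- function(candidates, tc, th, G, covariates = NULL) {
  ns <- ncol(tc)
  cov2 <- stack_covariates(covariates, ns)
  cond <- rep(c(0, 1), each = ns)
  gid <- rep(colnames(tc), 2)
  out <- lapply(seq_len(nrow(candidates)), function(i) {
    g <- candidates$gene_id[i]; v <- candidates$variant_id[i]
    y <- c(tc[g, ], th[g, ])
    dv <- rep(G$dosage[, v], 2)
    cbind(candidates[i, , drop = FALSE],
          fit_interaction_lmm(y, dv, cond, cov2, gid))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

## expand condition-invariant covariates to stacked order (control then heat)
stack_covariates <- function(covariates, ns) {
  if (is.null(covariates)) return(NULL)
  covariates <- as.matrix(covariates)
  if (nrow(covariates) == ns) rbind(covariates, covariates)
  else if (nrow(covariates) == 2 * ns) covariates
  else stop("covariates must have n or 2n rows")
}

#' Call reQTLs by Bonferroni-adjusted interaction p-values
#'
#' Bonferroni with m = number of tested gene/variant pairs; a pair is a reQTL
#' if the adjusted p is strictly below `alpha`. When both candidates of a
#' two-candidate gene pass, the smaller-p pair defines the gene's reQTL and
#' the other is unflagged.
#'
#' @param fits Output of [fit_candidates()].
#' @param alpha Adjusted-p threshold (default 0.01).
#' @return `fits` with p_bonf and is_reqtl columns.
#' @export
call_reqtls <- function(fits, alpha = 0.01) {
  m <- nrow(fits)
  fits$p_bonf <- ifelse(is.na(fits$p_raw), NA_real_,
                        adjust_pvalues(pmin(fits$p_raw, 1), "bonferroni", m = m))
  fits$is_reqtl <- !is.na(fits$p_bonf) & fits$p_bonf < alpha
  for (g in unique(fits$gene_id[fits$is_reqtl])) {
    i <- which(fits$gene_id == g & fits$is_reqtl)
    if (length(i) > 1L) fits$is_reqtl[i[-which.min(fits$p_raw[i])]] <- FALSE
  }
  fits
}

## per-allele log2 response of homozygous groups, +1 pseudocount on median CPM
allele_responses <- function(gene, variant, pair, G) {
  dv <- G$dosage[, variant]
  gi <- match(gene, pair$gene_ids)
  ref <- which(dv == 0); alt <- which(dv == 2)
  lr <- function(idx) {
    log2((stats::median(pair$cpm_heat[gi, idx]) + 1) /
           (stats::median(pair$cpm_control[gi, idx]) + 1))
  }
  list(L_ref = if (length(ref)) lr(ref) else NA_real_,
       L_alt = if (length(alt)) lr(alt) else NA_real_,
       n_ref = length(ref), n_alt = length(alt))
}

#' Classify responsive genes by allele and direction
#'
#' For each reQTL gene, heterozygotes are excluded and the per-allele log2
#' heat/control response is computed from homozygous-group median CPM with a
#' +1 pseudocount. The gene is `Ref*` if |L_ref| > |L_alt| (else `Alt*`), and
#' `*Heat` if the larger-response allele is upregulated (L > 0), `*Control`
#' if downregulated. Genes with < `min_hom` homozygotes in either group, or
#' with exactly equal |L_ref| and |L_alt|, are excluded (reasons in the
#' `skipped` attribute).
#'
#' @param calls reQTL-flagged fits from [call_reqtls()] (rows with
#'   `is_reqtl = TRUE` are classified).
#' @param pair An [expression_pair()].
#' @param G A [genotype_matrix()].
#' @param min_hom Minimum homozygotes per allele group (default 3).
#' @return data.frame: gene_id, variant_id, category, L_ref, L_alt, n_ref_hom,
#'   n_alt_hom.
#' @export
classify_regenes <- function(calls, pair, G, min_hom = 3L) {
  sel <- calls[calls$is_reqtl, , drop = FALSE]
  skipped <- list()
  rows <- lapply(seq_len(nrow(sel)), function(i) {
    ar <- allele_responses(sel$gene_id[i], sel$variant_id[i], pair, G)
    if (ar$n_ref < min_hom || ar$n_alt < min_hom) {
      skipped[[sel$gene_id[i]]] <<- "too few homozygotes"
      return(NULL)
    }
    if (abs(ar$L_ref) == abs(ar$L_alt)) {
      skipped[[sel$gene_id[i]]] <<- "ambiguous (equal responses)"
      return(NULL)
    }
    ref_stronger <- abs(ar$L_ref) > abs(ar$L_alt)
    lead <- if (ref_stronger) ar$L_ref else ar$L_alt
    data.frame(gene_id = sel$gene_id[i], variant_id = sel$variant_id[i],
               category = paste0(if (ref_stronger) "Ref" else "Alt",
                                 if (lead > 0) "Heat" else "Control"),
               L_ref = ar$L_ref, L_alt = ar$L_alt,
               n_ref_hom = ar$n_ref, n_alt_hom = ar$n_alt,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(), variant_id = character(),
                      category = character(), L_ref = numeric(),
                      L_alt = numeric(), n_ref_hom = integer(),
                      n_alt_hom = integer(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Detect heat-expressed-only eGenes and classify them by allele
#'
#' A heo-eGene is a gene expressed only under heat that carries at least one
#' significant cis association in the heat scan. Its class is `RefHeat` or
#' `AltHeat` by which homozygous group has the greater median heat CPM at the
#' gene's top cis variant (equal medians -> excluded).
#'
#' @param sets Output of [expressed_gene_sets()].
#' @param hits_heat cis association records for the heat condition.
#' @param pair An [expression_pair()].
#' @param G A [genotype_matrix()].
#' @param min_hom Minimum homozygotes per group (default 3).
#' @return data.frame: gene_id, variant_id, class, median_cpm_ref,
#'   median_cpm_alt, n_ref_hom, n_alt_hom.
#' @export
detect_heo_egenes <- function(sets, hits_heat, pair, G, min_hom = 3L) {
  h <- hits_heat[hits_heat$klass == "cis" &
                   hits_heat$gene_id %in% sets$heat_only, , drop = FALSE]
  rows <- lapply(split(h, h$gene_id), function(d) {
    top <- d[order(d$p, abs(d$distance_bp), d$pos), ][1, ]
    dv <- G$dosage[, top$variant_id]
    gi <- match(top$gene_id, pair$gene_ids)
    ref <- which(dv == 0); alt <- which(dv == 2)
    if (length(ref) < min_hom || length(alt) < min_hom) return(NULL)
    mr <- stats::median(pair$cpm_heat[gi, ref])
    ma <- stats::median(pair$cpm_heat[gi, alt])
    if (mr == ma) return(NULL)
    data.frame(gene_id = top$gene_id, variant_id = top$variant_id,
               class = if (mr > ma) "RefHeat" else "AltHeat",
               median_cpm_ref = mr, median_cpm_alt = ma,
               n_ref_hom = length(ref), n_alt_hom = length(alt),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(), variant_id = character(),
                      class = character(), median_cpm_ref = numeric(),
                      median_cpm_alt = numeric(), n_ref_hom = integer(),
                      n_alt_hom = integer(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Interaction rescans over a gene's flanking window
#'
#' Fits the interaction model for every variant within `flank_bp` of the gene
#' body (inclusive boundaries). Raw p-values are returned unadjusted; they
#' feed the inside/outside footprint comparison.
#'
#' @param gene_id Gene to rescan.
#' @param genes Gene models.
#' @param G A [genotype_matrix()].
#' @param tc,th Transformed expression matrices (control, heat).
#' @param covariates As in [fit_candidates()].
#' @param flank_bp Window beyond the gene body (default 1000).
#' @return data.frame of fits (one row per qualifying variant); empty if no
#'   variant qualifies.
#' @export
rescan_flanking <- function(gene_id, genes, G, tc, th, covariates = NULL,
                            flank_bp = 1000L) {
  gm <- genes[genes$gene_id == gene_id, ]
  if (nrow(gm) != 1L) stop("unknown gene: ", gene_id)
  v <- G$variants
  idx <- which(v$chrom == gm$chrom & v$pos >= gm$start - flank_bp &
                 v$pos <= gm$end + flank_bp)
  if (!length(idx)) {
    return(data.frame(gene_id = character(), variant_id = character()))
  }
  cand <- data.frame(gene_id = gene_id, variant_id = v$id[idx],
                     stringsAsFactors = FALSE)
  fit_candidates(cand, tc, th, G, covariates)
}
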