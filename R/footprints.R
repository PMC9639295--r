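## TF-footprint interval handling: fragment centering, a replicate-count
## differential-occupancy test, gene assignment, enrichment near upregulated
## genes, top-variant prioritization and the inside/outside interaction-effect
## comparison. All footprint coordinates are BED-style 0-based half-open;
## gene models are 1-based inclusive.

fp_granges <- function(fp) {
  GenomicRanges::GRanges(fp$chrom,
                         IRanges::IRanges(start = fp$start + 1L, end = fp$end))
}

#' Center fragments to fixed-width footprints
#'
#' Fragments longer than `max_len` (or shorter than `out_width`) are dropped;
#' the rest are reduced to `out_width` bases centered on the middle base.
#' Odd-length fragments have a unique middle base; for even lengths one of the
#' two middle bases is chosen by a seeded coin flip. Windows are clamped to
#' stay within the original fragment.
#'
#' @param fragments data.frame with chrom, start, end (0-based half-open).
#' @param out_width Output width (default 20).
#' @param max_len Longest retained fragment (default 80: "< 81 bp").
#' @param seed Seed for the even-length middle-base choice.
#' @return data.frame with chrom, start, end, all widths = `out_width`.
#' @export
center_fragments <- function(fragments, out_width = 20L, max_len = 80L,
                             seed = 1L) {
  len <- fragments$end - fragments$start
  keep <- len <= max_len & len >= out_width
  fr <- fragments[keep, , drop = FALSE]
  len <- len[keep]
  half <- out_width %/% 2L
  with_seed(seed, {
    odd <- len %% 2L == 1L
    mid <- integer(nrow(fr))
    mid[odd] <- fr$start[odd] + (len[odd] - 1L) %/% 2L
    if (any(!odd)) {
      left <- fr$start[!odd] + len[!odd] %/% 2L - 1L
      mid[!odd] <- left + (stats::runif(sum(!odd)) < 0.5)
    }
    ws <- pmax(fr$start, pmin(mid - half, fr$end - out_width))
    data.frame(chrom = fr$chrom, start = as.integer(ws),
               end = as.integer(ws + out_width), stringsAsFactors = FALSE)
  })
}

#' Differential occupancy from replicate counts
#'
#' Per footprint, replicate counts are normalized to counts-per-million of the
#' replicate's interval total, log2(x+1) transformed, and compared between
#' conditions with a Welch two-sample t test; BH adjustment across intervals.
#' Status: `heat_enriched` if adjusted p < `fdr_max` and mean(heat) >
#' mean(control); `heat_depleted` for the opposite direction; else `stable`.
#'
#' @param fp A footprint data.frame with >= 2 `ctrl_*` and `heat_*` count
#'   columns.
#' @param fdr_max FDR threshold (default 0.05).
#' @return `fp` with `status` and `fdr` replaced by the test results.
#' @export
differential_occupancy <- function(fp, fdr_max = 0.05) {
  cc <- grep("^ctrl_", names(fp), value = TRUE)
  hc <- grep("^heat_", names(fp), value = TRUE)
  if (length(cc) < 2L || length(hc) < 2L) {
    stop("need >= 2 replicate count columns per condition ",
         "(or provide pre-called statuses)")
  }
  cm <- as.matrix(fp[cc]); hm <- as.matrix(fp[hc])
  cpm <- function(m) log2(sweep(m, 2, colSums(m) / 1e6, "/") + 1)
  lc <- cpm(cm); lh <- cpm(hm)
  n1 <- ncol(lc); n2 <- ncol(lh)
  m1 <- rowMeans(lc); m2 <- rowMeans(lh)
  v1 <- apply(lc, 1, stats::var); v2 <- apply(lh, 1, stats::var)
  se2 <- v1 / n1 + v2 / n2
  t <- (m2 - m1) / sqrt(pmax(se2, 1e-300))
  df <- se2^2 / pmax(v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1)),
                     1e-300)
  p <- ifelse(se2 == 0, 1, 2 * stats::pt(-abs(t), df))
  fdr <- adjust_pvalues(p, "bh")
  fp$fdr <- fdr
  fp$status <- ifelse(fdr < fdr_max & m2 > m1, "heat_enriched",
                      ifelse(fdr < fdr_max & m2 < m1, "heat_depleted",
                             "stable"))
  fp
}

#' Assign footprints to genes
#'
#' Overlap means any shared base. Three gene-relative windows: the 2-kb flank
#' (`[start - flank_bp, end + flank_bp]` of the gene body), the promoter
#' (`flank_bp` bases immediately upstream of the TSS, strand-aware) and the
#' gene body itself.
#'
#' @param fp A footprint data.frame (0-based half-open).
#' @param genes Gene models (1-based inclusive, with strand and tss).
#' @param flank_bp Flank / promoter depth (default 2000).
#' @return data.frame per gene: gene_id, n_flank, n_promoter, n_body,
#'   has_heat_enriched (any heat-enriched footprint in the flank window), plus
#'   list-columns `flank_idx`, `promoter_idx`, `body_idx` of footprint row
#'   indices.
#' @export
assign_footprints <- function(fp, genes, flank_bp = 2000L) {
  gr_fp <- fp_granges(fp)
  win <- function(start, end) {
    GenomicRanges::GRanges(genes$chrom,
                           IRanges::IRanges(start = pmax(1L, start), end = end))
  }
  gr_flank <- win(genes$start - flank_bp, genes$end + flank_bp)
  gr_body <- win(genes$start, genes$end)
  prom_start <- ifelse(genes$strand == "+", genes$tss - flank_bp, genes$tss + 1L)
  prom_end <- ifelse(genes$strand == "+", genes$tss - 1L, genes$tss + flank_bp)
  gr_prom <- win(prom_start, prom_end)
  by_gene <- function(gr) {
    ov <- GenomicRanges::findOverlaps(gr, gr_fp)
    split(S4Vectors::subjectHits(ov),
          factor(S4Vectors::queryHits(ov), levels = seq_len(nrow(genes))))
  }
  fl <- by_gene(gr_flank); pr <- by_gene(gr_prom); bd <- by_gene(gr_body)
  enr <- vapply(fl, function(i) any(fp$status[i] == "heat_enriched"), logical(1))
  out <- data.frame(gene_id = genes$gene_id, n_flank = lengths(fl),
                    n_promoter = lengths(pr), n_body = lengths(bd),
                    has_heat_enriched = unname(enr), stringsAsFactors = FALSE)
  out$flank_idx <- unname(fl)
  out$promoter_idx <- unname(pr)
  out$body_idx <- unname(bd)
  rownames(out) <- NULL
  out
}

#' Enrichment of heat-enriched footprints near upregulated genes
#'
#' Builds the 2x2 presence/absence table of a heat-enriched footprint in the
#' 2-kb flank for an upregulated gene set versus a disjoint background set and
#' tests it with a one-sided (greater) Fisher exact test.
#'
#' @param assignments Output of [assign_footprints()].
#' @param upregulated,background Disjoint gene-id sets.
#' @return List with `table` (2x2) and `p`.
#' @export
enrichment_vs_background <- function(assignments, upregulated, background) {
  if (length(intersect(upregulated, background))) {
    stop("gene sets must be disjoint")
  }
  has <- assignments$has_heat_enriched[match(c(upregulated, background),
                                             assignments$gene_id)]
  grp <- rep(c(TRUE, FALSE), c(length(upregulated), length(background)))
  tab <- matrix(c(sum(has & grp), sum(!has & grp),
                  sum(has & !grp), sum(!has & !grp)),
                2, 2, byrow = TRUE,
                dimnames = list(c("upregulated", "background"),
                                c("has_enriched", "none")))
  list(table = tab, p = fisher_exact(tab, "greater"))
}

#' Top-variant overlap with status-matching footprints
#'
#' Per gene, variants are ranked by raw p ascending (ties: smaller |distance
#' to TSS| first, then position); the gene is flagged if any of the top
#' `top_k` variant positions falls inside a footprint with the requested
#' status (0-based point in half-open interval).
#'
#' @param results data.frame with gene_id, variant_id, chrom, pos (1-based)
#'   and a raw p column named `p` or `p_raw`.
#' @param fp Footprint data.frame.
#' @param genes Gene models (for the TSS tie-break).
#' @param top_k Variants considered per gene (default 3).
#' @param status_filter Footprint status to match (default `"heat_enriched"`).
#' @param category Optional named vector (gene_id -> category) for per-category
#'   proportions.
#' @return List with `per_gene` (gene_id, flagged) and `per_category`
#'   (category, n_genes, prop_flagged; NULL when `category` is missing).
#' @export
top_variant_overlap <- function(results, fp, genes, top_k = 3L,
                                status_filter = "heat_enriched",
                                category = NULL) {
  pcol <- if ("p_raw" %in% names(results)) "p_raw" else "p"
  fps <- fp[fp$status == status_filter, , drop = FALSE]
  gr_fp <- fp_granges(fps)
  per_gene <- lapply(split(results, results$gene_id), function(d) {
    tssd <- abs(d$pos - genes$tss[match(d$gene_id[1], genes$gene_id)])
    d <- d[order(d[[pcol]], tssd, d$pos), , drop = FALSE]
    d <- d[seq_len(min(top_k, nrow(d))), , drop = FALSE]
    gr_v <- GenomicRanges::GRanges(d$chrom, IRanges::IRanges(d$pos, d$pos))
    data.frame(gene_id = d$gene_id[1],
               flagged = length(GenomicRanges::findOverlaps(gr_v, gr_fp)) > 0,
               stringsAsFactors = FALSE)
  })
  per_gene <- do.call(rbind, per_gene)
  rownames(per_gene) <- NULL
  per_category <- NULL
  if (!is.null(category)) {
    per_gene$category <- unname(category[per_gene$gene_id])
    per_category <- do.call(rbind, lapply(
      split(per_gene, per_gene$category), function(d) {
        data.frame(category = d$category[1], n_genes = nrow(d),
                   prop_flagged = mean(d$flagged), stringsAsFactors = FALSE)
      }))
    rownames(per_category) <- NULL
  }
  list(per_gene = per_gene, per_category = per_category)
}

#' Inside/outside footprint comparison of interaction effects
#'
#' Pools -log10(raw interaction p) across all rescanned variants of the genes
#' in each category, splits by whether the variant lies inside any
#' heat-enriched footprint, and compares the two groups with a two-sided
#' rank-sum test.
#'
#' @param rescan data.frame with gene_id, chrom, pos, a raw p column (`p_raw`
#'   or `p`) and `category`.
#' @param fp Footprint data.frame.
#' @param status_filter Footprint status defining "inside" (default
#'   `"heat_enriched"`).
#' @return data.frame per category: category, n_in, n_out, statistic, p,
#'   computable.
#' @export
inside_outside_comparison <- function(rescan, fp,
                                      status_filter = "heat_enriched") {
  pcol <- if ("p_raw" %in% names(rescan)) "p_raw" else "p"
  fps <- fp[fp$status == status_filter, , drop = FALSE]
  gr_fp <- fp_granges(fps)
  gr_v <- GenomicRanges::GRanges(rescan$chrom,
                                 IRanges::IRanges(rescan$pos, rescan$pos))
  inside <- GenomicRanges::countOverlaps(gr_v, gr_fp) > 0
  val <- -log10(pmax(rescan[[pcol]], 1e-300))
  out <- lapply(split(seq_len(nrow(rescan)), rescan$category), function(i) {
    vin <- val[i][inside[i]]; vout <- val[i][!inside[i]]
    ok <- length(vin) > 0 && length(vout) > 0 && !anyNA(c(vin, vout))
    rs <- if (ok) rank_sum(vin, vout) else list(statistic = NA_real_, p = NA_real_)
    data.frame(category = rescan$category[i[1]], n_in = length(vin),
               n_out = length(vout), statistic = rs$statistic, p = rs$p,
               computable = ok, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Position of a feature relative to a gene
#'
#' Strand-aware signed distances to TSS and TTS (upstream negative) and a
#' positional class.
#'
#' @param midpoint 1-based position of the feature midpoint.
#' @param gene One gene-model row (chrom, start, end, strand, tss, tts).
#' @param chrom Chromosome of the feature (must match the gene's).
#' @param proximal_bp Proximal window (default 2000).
#' @return List with dist_tss, dist_tts and class in \{distal_upstream,
#'   proximal_upstream, genic, proximal_downstream, distal_downstream\}.
#' @export
relative_position <- function(midpoint, gene, chrom = gene$chrom,
                              proximal_bp = 2000L) {
  if (chrom != gene$chrom) stop("feature and gene on different chromosomes")
  sgn <- if (gene$strand == "-") -1 else 1
  dist_tss <- sgn * (midpoint - gene$tss)
  dist_tts <- sgn * (midpoint - gene$tts)
  cls <- if (midpoint >= gene$start && midpoint <= gene$end) "genic"
  else if (dist_tss < 0) {
    if (-dist_tss <= proximal_bp) "proximal_upstream" else "distal_upstream"
  } else {
    if (dist_tts <= proximal_bp) "proximal_downstream" else "distal_downstream"
  }
  list(dist_tss = dist_tss, dist_tts = dist_tts, class = cls)
}
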