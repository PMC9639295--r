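## Synthetic paired-condition cohort with planted truth.
##
## Emulates the statistical structure of a resequenced inbred diversity panel
## assayed by RNA-seq under control and heat conditions: near-homozygous
## genotypes in LD blocks with mild population structure (Balding-Nichols),
## negative-binomial counts with planted cis effects, genotype-by-condition
## interaction effects, heat-expressed-only genes, trans-regulator hotspots,
## hidden confounders, and TF-footprint intervals enriched at causal
## promoters of upregulated genes.

#' Run code with a private RNG state
#'
#' Seeds the RNG, runs `expr`, and restores the caller's RNG state so
#' generators are deterministic without clobbering the session RNG.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Deterministic per-stage seed derivation from one global seed (kept < 2^31).
stage_seed <- function(seed, stage) {
  offs <- c(genotypes = 101L, genes = 211L, expression = 307L,
            footprints = 401L, candidates = 503L, subset = 601L,
            pipeline = 701L)
  (as.integer(seed) %% 1000000L) * 1009L + offs[[stage]]
}

#' Simulation configuration
#'
#' Defaults define the study conditions emulated by the simulator: ~120
#' near-homozygous genotypes from 4 subpopulations, 6000 variants in 20-variant
#' LD blocks on 3 chromosomes, 1200 genes with planted cis (30%), reQTL (5%),
#' heat-expressed-only (2%) and consistently-upregulated (5%) classes, two
#' trans hotspots, negative-binomial counts (dispersion 0.1) and 3 hidden
#' confounding factors.
#'
#' @param n_samples,n_chromosomes,chrom_length_bp,n_variants Cohort geometry.
#' @param indel_fraction Fraction of variants flagged as InDels.
#' @param n_subpops,fst Balding-Nichols population structure.
#' @param residual_het_rate Expected per-variant heterozygous leak.
#' @param ld_block_size,within_block_r LD-block construction: variants in a
#'   block copy the block-seed haplotype with switch probability
#'   `(1 - within_block_r)/2`.
#' @param n_genes Number of gene models.
#' @param frac_cis,frac_reqtl,frac_heo,frac_consistent_up Planted class
#'   fractions (must sum to <= 1 together with trans targets).
#' @param n_trans_hotspots,targets_per_hotspot Trans-regulator planting.
#' @param nb_dispersion Negative-binomial dispersion (size = 1/dispersion).
#' @param libsize_range Uniform range of per-library sequencing depth.
#' @param n_hidden_factors Hidden confounders (standard normal per sample,
#'   sparse loadings on 30% of genes).
#' @param seed Integer seed; fully determines all outputs.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_samples = 120L, n_chromosomes = 3L,
                       chrom_length_bp = 5e6, n_variants = 6000L,
                       indel_fraction = 0.09, n_subpops = 4L, fst = 0.1,
                       residual_het_rate = 0.02, ld_block_size = 20L,
                       within_block_r = 0.9, n_genes = 1200L,
                       frac_cis = 0.3, frac_reqtl = 0.05, frac_heo = 0.02,
                       frac_consistent_up = 0.05, n_trans_hotspots = 2L,
                       targets_per_hotspot = 15L, nb_dispersion = 0.1,
                       libsize_range = c(8e5, 1.2e6), n_hidden_factors = 3L,
                       seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples),
              n_chromosomes = as.integer(n_chromosomes),
              chrom_length_bp = chrom_length_bp,
              n_variants = as.integer(n_variants),
              indel_fraction = indel_fraction, n_subpops = as.integer(n_subpops),
              fst = fst, residual_het_rate = residual_het_rate,
              ld_block_size = as.integer(ld_block_size),
              within_block_r = within_block_r, n_genes = as.integer(n_genes),
              frac_cis = frac_cis, frac_reqtl = frac_reqtl, frac_heo = frac_heo,
              frac_consistent_up = frac_consistent_up,
              n_trans_hotspots = as.integer(n_trans_hotspots),
              targets_per_hotspot = as.integer(targets_per_hotspot),
              nb_dispersion = nb_dispersion, libsize_range = libsize_range,
              n_hidden_factors = as.integer(n_hidden_factors),
              seed = as.integer(seed))
  fr <- c(cfg$frac_cis, cfg$frac_reqtl, cfg$frac_heo, cfg$frac_consistent_up)
  if (any(fr < 0 | fr > 1)) stop("class fractions must lie in [0, 1]")
  n_trans <- cfg$n_trans_hotspots * cfg$targets_per_hotspot
  if (sum(fr) + n_trans / cfg$n_genes > 1) {
    stop("planted class fractions sum to more than 1")
  }
  if (cfg$fst <= 0 || cfg$fst >= 0.5) stop("fst must lie in (0, 0.5)")
  if (cfg$n_variants < cfg$ld_block_size) {
    stop("n_variants must be >= ld_block_size")
  }
  structure(cfg, class = "sim_config")
}

#' Construct a genotype matrix object
#'
#' @param dosage samples x variants matrix with values in \{0, 1, 2, NA\}.
#' @param variants data.frame with columns id, chrom, pos (1-based), ref, alt,
#'   is_indel, ordered by (chrom, pos).
#' @return A `genotype_matrix` (list of `dosage` and `variants`).
#' @export
genotype_matrix <- function(dosage, variants) {
  stopifnot(ncol(dosage) == nrow(variants),
            all(c("id", "chrom", "pos", "is_indel") %in% names(variants)))
  if (anyDuplicated(rownames(dosage))) stop("sample ids must be unique")
  ok <- is.na(dosage) | dosage %in% c(0, 1, 2)
  if (!all(ok)) stop("dosages must be 0, 1, 2 or NA")
  o <- order(variants$chrom, variants$pos)
  variants <- variants[o, , drop = FALSE]
  dosage <- dosage[, o, drop = FALSE]
  colnames(dosage) <- variants$id
  structure(list(dosage = dosage, variants = variants),
            class = "genotype_matrix")
}

#' Simulate inbred-panel genotypes
#'
#' Balding-Nichols subpopulation allele frequencies around ancestral
#' frequencies Uniform(0.05, 0.95); near-homozygous dosages (haplotype doubled,
#' with a small heterozygous leak); within-block LD by copying the block-seed
#' haplotype with switch probability `(1 - within_block_r)/2`.
#'
#' @param config A [sim_config()].
#' @return A [genotype_matrix()] sorted by (chrom, pos).
#' @export
generate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(stage_seed(config$seed, "genotypes"), {
    ns <- config$n_samples
    nv <- config$n_variants
    nchr <- config$n_chromosomes
    per_chr <- diff(round(seq(0, nv, length.out = nchr + 1)))
    chrom <- rep(paste0("chr", seq_len(nchr)), per_chr)
    pos <- unlist(lapply(per_chr, function(k) {
      sort(sample.int(config$chrom_length_bp - 1L, k))
    }))
    subpop <- rep(seq_len(config$n_subpops), length.out = ns)
    p0 <- stats::runif(nv, 0.05, 0.95)
    F <- config$fst
    ## subpop frequency per variant x subpop
    pf <- matrix(stats::rbeta(nv * config$n_subpops,
                              rep(p0, config$n_subpops) * (1 - F) / F,
                              rep(1 - p0, config$n_subpops) * (1 - F) / F),
                 nrow = nv)
    pf <- pmin(pmax(pf, 0.02), 0.98)
    ## block structure restarts at chromosome boundaries
    block <- unlist(lapply(per_chr, function(k) {
      rep(seq_len(ceiling(k / config$ld_block_size)),
          each = config$ld_block_size, length.out = k)
    }))
    block_id <- cumsum(c(TRUE, diff(as.integer(factor(
      paste(chrom, block)))) != 0))
    s <- (1 - config$within_block_r) / 2
    hap <- matrix(0L, nrow = ns, ncol = nv)
    seed_hap <- NULL
    for (v in seq_len(nv)) {
      if (v == 1L || block_id[v] != block_id[v - 1L]) {
        seed_hap <- as.integer(stats::runif(ns) < pf[v, subpop])
        hap[, v] <- seed_hap
      } else {
        flip <- stats::runif(ns) < s
        hap[, v] <- ifelse(flip, 1L - seed_hap, seed_hap)
      }
    }
    dosage <- 2L * hap
    het <- matrix(stats::runif(ns * nv) < config$residual_het_rate, ns, nv)
    dosage[het] <- 1L
    is_indel <- stats::runif(nv) < config$indel_fraction
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, nv, replace = TRUE)
    alt <- vapply(seq_len(nv), function(i) {
      if (is_indel[i]) paste0(ref[i], paste(sample(bases, 2), collapse = ""))
      else sample(setdiff(bases, ref[i]), 1)
    }, character(1))
    variants <- data.frame(
      id = sprintf("S%s_%d", sub("^chr", "", chrom), pos),
      chrom = chrom, pos = pos, ref = ref, alt = alt, is_indel = is_indel,
      stringsAsFactors = FALSE)
    rownames(dosage) <- sprintf("G%03d", seq_len(ns))
    gm <- genotype_matrix(dosage, variants)
    gm$subpop <- subpop
    gm
  })
}

#' Simulate non-overlapping gene models
#'
#' Genes are laid out one per equal-width slot per chromosome with >= 2.1 kb
#' margins, so every gene's +/-2 kb flank is private to it. TSS/TTS follow
#' strand (minus-strand TSS is the high coordinate).
#'
#' @param config A [sim_config()].
#' @return data.frame with gene_id, chrom, start, end (1-based inclusive),
#'   strand, tss, tts.
#' @export
generate_gene_models <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(stage_seed(config$seed, "genes"), {
    nchr <- config$n_chromosomes
    per_chr <- diff(round(seq(0, config$n_genes, length.out = nchr + 1)))
    out <- list()
    for (ch in seq_len(nchr)) {
      n <- per_chr[ch]
      slot <- config$chrom_length_bp / n
      lmax <- min(4000, slot - 4400)
      if (lmax < 1000) stop("genes cannot be packed into chromosome length")
      len <- round(stats::runif(n, 1000, lmax))
      start <- round((seq_len(n) - 1) * slot + 2200 +
                       stats::runif(n) * (slot - len - 4400))
      strand <- sample(c("+", "-"), n, replace = TRUE)
      out[[ch]] <- data.frame(
        gene_id = sprintf("gene_%d_%04d", ch, seq_len(n)),
        chrom = paste0("chr", ch), start = as.integer(start),
        end = as.integer(start + len - 1), strand = strand,
        stringsAsFactors = FALSE)
    }
    genes <- do.call(rbind, out)
    genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end)
    genes$tts <- ifelse(genes$strand == "+", genes$end, genes$start)
    rownames(genes) <- NULL
    genes
  })
}

## per-class planted log2 responses (L_ref = response of ref homozygotes,
## L_alt of alt homozygotes); interaction theta = (L_alt - L_ref)/2 per dose,
## |theta| >= 1 by construction.
reqtl_class_effects <- function(class, n) {
  big <- stats::runif(n, 2.5, 3.5)
  small <- stats::runif(n, -0.5, 0.5)
  switch(class,
    reqtl_RefHeat = list(L_ref = big, L_alt = small),
    reqtl_RefControl = list(L_ref = -big, L_alt = small),
    reqtl_AltHeat = list(L_ref = small, L_alt = big),
    reqtl_AltControl = list(L_ref = small, L_alt = -big))
}

#' Simulate paired-condition expression with planted truth
#'
#' Counts are negative binomial with log2-scale linear predictor
#' `eta = alpha + beta^(c) * d + delta * c + sum_k lambda_k f_k + g`, where
#' `d` is the causal-variant alt dosage, `c` the condition (control 0, heat 1),
#' `f` hidden factors and `g` a per-gene genotype random intercept N(0, 0.2^2).
#' Planted classes: cis-only (equal betas), four reQTL classes (interaction
#' `theta = beta_heat - beta_control`, |theta| >= 1 per alt dose), two
#' heat-expressed-only classes (silent in control, allele-dependent heat
#' level), consistent upregulation (condition effect only) and trans-hotspot
#' targets sharing a remote regulator variant.
#'
#' @param G A [genotype_matrix()].
#' @param genes Gene models from [generate_gene_models()].
#' @param config A [sim_config()].
#' @param placement Where causal variants may sit relative to their gene:
#'   `"any"` (gene body +/- 2 kb) or `"promoter"` (strand-aware 2 kb upstream
#'   of the TSS).
#' @return List with `pair` (an [expression_pair()]) and `truth` (per-gene
#'   class, causal variant, planted effects).
#' @export
generate_expression <- function(G, genes, config, placement = c("any", "promoter")) {
  stopifnot(inherits(config, "sim_config"))
  placement <- match.arg(placement)
  with_seed(stage_seed(config$seed, "expression"), {
    ns <- nrow(G$dosage)
    ng <- nrow(genes)
    v <- G$variants
    maf <- variant_stats(G)$maf

    ## eligible causal variant ids per gene (MAF >= 0.15 inside the window)
    eligible <- vector("list", ng)
    for (i in seq_len(ng)) {
      if (placement == "any") {
        w0 <- genes$start[i] - 2000; w1 <- genes$end[i] + 2000
      } else {
        w0 <- if (genes$strand[i] == "+") genes$tss[i] - 2000 else genes$tss[i] + 1
        w1 <- if (genes$strand[i] == "+") genes$tss[i] - 1 else genes$tss[i] + 2000
      }
      idx <- which(v$chrom == genes$chrom[i] & v$pos >= w0 & v$pos <= w1 &
                     maf >= 0.15)
      eligible[[i]] <- idx
    }
    has_causal <- lengths(eligible) > 0

    classes <- rep("null", ng)
    n_cis <- round(config$frac_cis * ng)
    reqtl_classes <- c("reqtl_RefHeat", "reqtl_RefControl",
                       "reqtl_AltHeat", "reqtl_AltControl")
    n_reqtl_each <- round(config$frac_reqtl * ng / 4)
    heo_classes <- c("heo_RefHeat", "heo_AltHeat")
    n_heo_each <- round(config$frac_heo * ng / 2)
    n_up <- round(config$frac_consistent_up * ng)
    need_causal <- n_cis + 4 * n_reqtl_each + 2 * n_heo_each
    pool <- sample(which(has_causal))
    if (length(pool) < need_causal) {
      stop("too few genes have an eligible causal variant (MAF >= 0.15)")
    }
    take <- function(k) { out <- pool[seq_len(k)]; pool <<- pool[-seq_len(k)]; out }
    classes[take(n_cis)] <- "cis_only"
    for (cl in reqtl_classes) classes[take(n_reqtl_each)] <- cl
    for (cl in heo_classes) classes[take(n_heo_each)] <- cl
    rest <- sample(which(classes == "null"))
    classes[rest[seq_len(n_up)]] <- "consistent_up"
    rest <- rest[-seq_len(n_up)]

    ## trans hotspots: one regulator variant each, remote target genes
    hotspot_id <- rep(NA_integer_, ng)
    hub_variant <- rep(NA_character_, ng)
    regulators <- character(config$n_trans_hotspots)
    if (config$n_trans_hotspots > 0) {
      reg_idx <- sample(which(maf >= 0.15), config$n_trans_hotspots)
      for (h in seq_len(config$n_trans_hotspots)) {
        rv <- reg_idx[h]
        regulators[h] <- v$id[rv]
        remote <- rest[genes$chrom[rest] != v$chrom[rv] |
                         pmin(abs(genes$start[rest] - v$pos[rv]),
                              abs(genes$end[rest] - v$pos[rv])) > 1e6]
        tg <- remote[seq_len(min(config$targets_per_hotspot, length(remote)))]
        classes[tg] <- "trans_target"
        hotspot_id[tg] <- h
        hub_variant[tg] <- v$id[rv]
        rest <- setdiff(rest, tg)
      }
    }

    causal <- rep(NA_character_, ng)
    idx_causal <- which(classes %in% c("cis_only", reqtl_classes, heo_classes))
    for (i in idx_causal) {
      e <- eligible[[i]]
      causal[i] <- v$id[e[sample.int(length(e), 1)]]
    }
    causal[classes == "trans_target"] <- hub_variant[classes == "trans_target"]

    ## gene-level parameters on the log2-CPM scale
    alpha <- stats::rnorm(ng, 4, 1.5)
    delta <- numeric(ng)
    beta_c <- numeric(ng)
    beta_h <- numeric(ng)
    for (cl in reqtl_classes) {
      ii <- which(classes == cl)
      if (!length(ii)) next
      eff <- reqtl_class_effects(cl, length(ii))
      delta[ii] <- eff$L_ref
      theta <- (eff$L_alt - eff$L_ref) / 2
      ## balanced allelic effects (+/- theta/2) keep the gene an eGene in both
      ## conditions with comparable per-condition genetic variance
      beta_c[ii] <- -theta / 2 + stats::rnorm(length(ii), 0, 0.15)
      beta_h[ii] <- beta_c[ii] + theta
    }
    ii <- which(classes == "cis_only")
    beta_c[ii] <- beta_h[ii] <- sample(c(-1, 1), length(ii), TRUE) *
      stats::runif(length(ii), 0.5, 1.2)
    ii <- which(classes == "consistent_up")
    delta[ii] <- stats::runif(length(ii), 2, 3)
    ii <- which(classes == "trans_target")
    beta_c[ii] <- beta_h[ii] <- sample(c(-1, 1), length(ii), TRUE) *
      stats::runif(length(ii), 0.8, 1.2)
    ii <- which(classes %in% heo_classes)
    alpha[ii] <- stats::runif(length(ii), -5.5, -4.5)
    delta[ii] <- stats::runif(length(ii), 7.5, 9)
    jj <- which(classes == "heo_AltHeat")
    beta_h[jj] <- stats::runif(length(jj), 0.75, 1.25)
    jj <- which(classes == "heo_RefHeat")
    beta_h[jj] <- -stats::runif(length(jj), 0.75, 1.25)

    ## hidden factors (per sample, condition-invariant), sparse loadings
    K <- config$n_hidden_factors
    fac <- matrix(stats::rnorm(ns * K), ns, K)
    lam <- matrix(0, ng, max(K, 1))
    if (K > 0) {
      nz <- matrix(stats::runif(ng * K) < 0.3, ng, K)
      lam[, seq_len(K)][nz] <- stats::rnorm(sum(nz), 0, 0.5)
    }
    gint <- matrix(stats::rnorm(ng * ns, 0, 0.2), ng, ns)

    d <- matrix(0, ng, ns)  # causal dosage per gene x sample
    ci <- !is.na(causal)
    d[ci, ] <- t(G$dosage[, causal[ci], drop = FALSE])

    lib <- matrix(stats::runif(2 * ns, config$libsize_range[1],
                               config$libsize_range[2]), ns, 2)
    base <- alpha + (if (K > 0) lam[, seq_len(K), drop = FALSE] %*% t(fac)
                     else 0) + gint
    ## heo genes: the genetic effect acts only under heat
    heo <- classes %in% heo_classes
    eta_c <- base + ifelse(heo, 0, 1) * beta_c * d
    eta_h <- base + beta_h * d + delta

    size <- 1 / config$nb_dispersion
    mu_c <- sweep(2^eta_c, 2, lib[, 1] / 1e6, "*")
    mu_h <- sweep(2^eta_h, 2, lib[, 2] / 1e6, "*")
    counts_c <- matrix(stats::rnbinom(ng * ns, size = size, mu = mu_c), ng, ns)
    counts_h <- matrix(stats::rnbinom(ng * ns, size = size, mu = mu_h), ng, ns)
    dimnames(counts_c) <- dimnames(counts_h) <-
      list(genes$gene_id, rownames(G$dosage))

    truth <- data.frame(
      gene_id = genes$gene_id, class = classes, causal_variant = causal,
      beta_control = ifelse(heo, 0, beta_c), beta_heat = beta_h,
      activation_delta = delta, hotspot_id = hotspot_id,
      stringsAsFactors = FALSE)
    attr(truth, "regulators") <- regulators
    attr(truth, "hidden_factors") <- fac

    list(pair = expression_pair(counts_c, counts_h,
                                libsizes = list(control = lib[, 1],
                                                heat = lib[, 2])),
         truth = truth)
  })
}

#' Simulate TF-footprint intervals
#'
#' Background footprints (median width ~34 bp) near the TSS of every gene;
#' for upregulated planted reQTL / heat-expressed-only genes, with probability
#' `p_true` an additional heat-enriched footprint covering the gene's causal
#' variant. Six replicate occupancy counts (3 control + 3 heat) are generated
#' consistently with each footprint's status (4-fold shifts for differential
#' footprints).
#'
#' @param truth Truth table from [generate_expression()].
#' @param genes Gene models.
#' @param config A [sim_config()].
#' @param p_true Probability that an upregulated planted gene's causal variant
#'   is covered by a heat-enriched footprint (default 0.8).
#' @param G Optional [genotype_matrix()]; required to locate causal variants
#'   (pass the matrix the truth was generated from).
#' @return A `footprint_set` data.frame: chrom, start, end (0-based half-open),
#'   status, fdr (NA; fill via [differential_occupancy()]), ctrl_1..3,
#'   heat_1..3 replicate counts, gene_id of the seeding gene.
#' @export
generate_footprints <- function(truth, genes, config, p_true = 0.8, G = NULL) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(stage_seed(config$seed, "footprints"), {
    ng <- nrow(genes)
    rows <- list()
    width_draw <- function(n) pmax(15L, stats::rpois(n, 34))
    ## background footprints near every TSS
    nbg <- sample(1:3, ng, replace = TRUE)
    for (i in seq_len(ng)) {
      w <- width_draw(nbg[i])
      off <- round(stats::rnorm(nbg[i], -400, 500))
      ctr <- if (genes$strand[i] == "+") genes$tss[i] + off else genes$tss[i] - off
      start <- pmax(0, ctr - 1 - floor(w / 2))
      u <- stats::runif(nbg[i])
      status <- ifelse(u < 0.05, "heat_enriched",
                       ifelse(u < 0.08, "heat_depleted", "stable"))
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = genes$chrom[i], start = as.integer(start),
        end = as.integer(start + w), status = status,
        gene_id = genes$gene_id[i], stringsAsFactors = FALSE)
    }
    ## heat-enriched footprints over causal variants of upregulated genes
    up_classes <- c("reqtl_RefHeat", "reqtl_AltHeat", "heo_RefHeat", "heo_AltHeat")
    idx <- which(truth$class %in% up_classes & !is.na(truth$causal_variant))
    if (length(idx) && is.null(G)) {
      stop("G is required to place causal-variant footprints")
    }
    for (i in idx) {
      if (stats::runif(1) > p_true) next
      vrow <- match(truth$causal_variant[i], G$variants$id)
      w <- width_draw(1)
      p0 <- G$variants$pos[vrow] - 1L  # 0-based point of the variant
      start <- p0 - sample.int(w, 1) + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = G$variants$chrom[vrow], start = as.integer(max(0, start)),
        end = as.integer(max(0, start) + w), status = "heat_enriched",
        gene_id = truth$gene_id[i], stringsAsFactors = FALSE)
    }
    fp <- do.call(rbind, rows)
    fp <- fp[fp$end <= config$chrom_length_bp, , drop = FALSE]
    ## replicate occupancy counts consistent with status
    nfp <- nrow(fp)
    depth <- stats::runif(6, 0.8, 1.2)  # per-replicate library factor
    lam <- stats::runif(nfp, 100, 300)  # deep occupancy coverage
    mult <- ifelse(fp$status == "heat_enriched", 4,
                   ifelse(fp$status == "heat_depleted", 0.25, 1))
    cnt <- matrix(0L, nfp, 6)
    for (r in 1:3) {
      cnt[, r] <- stats::rnbinom(nfp, size = 200, mu = lam * depth[r])
      cnt[, r + 3] <- stats::rnbinom(nfp, size = 200, mu = lam * mult * depth[r + 3])
    }
    colnames(cnt) <- c(paste0("ctrl_", 1:3), paste0("heat_", 1:3))
    fp <- cbind(fp[c("chrom", "start", "end", "status")],
                fdr = NA_real_, as.data.frame(cnt),
                gene_id = fp$gene_id)
    fp <- fp[order(fp$chrom, fp$start), , drop = FALSE]
    rownames(fp) <- NULL
    class(fp) <- c("footprint_set", "data.frame")
    fp
  })
}

#' Simulate a complete cohort
#'
#' Runs all four generators with per-stage seeds derived from `config$seed`.
#'
#' @param config A [sim_config()].
#' @param p_true Passed to [generate_footprints()].
#' @param footprints Generate footprints (default `TRUE`).
#' @return List with `G`, `genes`, `pair`, `truth`, `footprints`, `config`.
#' @export
simulate_cohort <- function(config = sim_config(), p_true = 0.8,
                            footprints = TRUE) {
  G <- generate_genotypes(config)
  genes <- generate_gene_models(config)
  expr <- generate_expression(G, genes, config)
  fp <- if (footprints) generate_footprints(expr$truth, genes, config,
                                            p_true = p_true, G = G) else NULL
  list(G = G, genes = genes, pair = expr$pair, truth = expr$truth,
       footprints = fp, config = config)
}
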