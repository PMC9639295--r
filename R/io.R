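## Readers and writers. Stage outputs are TSV; VCF / GFF3 / BED appear only at
## the ingestion boundary (VCF via vcfR, GFF3 via rtracklayer when installed).

#' Write a simulated cohort to disk
#'
#' Genotypes as dosage TSV and minimal VCFv4.2 (GT only, biallelic), gene
#' models as TSV and GFF3, per-condition count matrices as TSV, footprints as
#' BED6+ (status, fdr, six replicate counts) and the truth table as TSV.
#'
#' @param cohort Output of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fw <- function(x, f) data.table::fwrite(x, file.path(dir, f), sep = "\t")
  v <- cohort$G$variants
  dos <- data.table::data.table(v, t(cohort$G$dosage))
  fw(dos, "genotypes_dosage.tsv")
  write_minimal_vcf(cohort$G, file.path(dir, "genotypes.vcf"))
  fw(cohort$genes, "genes.tsv")
  write_gff3(cohort$genes, file.path(dir, "genes.gff3"))
  cm <- function(m) data.table::data.table(gene_id = rownames(m), m)
  fw(cm(cohort$pair$counts_control), "counts_control.tsv")
  fw(cm(cohort$pair$counts_heat), "counts_heat.tsv")
  fw(cohort$truth, "truth.tsv")
  if (!is.null(cohort$footprints)) {
    fp <- cohort$footprints
    bed <- data.table::data.table(
      chrom = fp$chrom, start = fp$start, end = fp$end,
      name = sprintf("fp%05d", seq_len(nrow(fp))), score = 0, strand = ".",
      status = fp$status, fdr = fp$fdr,
      fp[grep("^(ctrl|heat)_", names(fp))])
    data.table::fwrite(bed, file.path(dir, "footprints.bed"), sep = "\t",
                       col.names = FALSE)
  }
  invisible(dir)
}

write_minimal_vcf <- function(G, path) {
  v <- G$variants
  gt <- t(G$dosage)
  gtc <- matrix(c("0/0", "0/1", "1/1")[gt + 1L], nrow(gt), ncol(gt))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(G$dosage)), collapse = "\t")),
             con)
  body <- cbind(v$chrom, v$pos, v$id, v$ref, v$alt, ".", "PASS", ".", "GT", gtc)
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
}

write_gff3 <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  writeLines(sprintf("%s\treqtlmap\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     genes$chrom, genes$start, genes$end, genes$strand,
                     genes$gene_id), con)
}

#' Read a dosage TSV into a genotype matrix
#'
#' Expects variant metadata columns (id, chrom, pos, ref, alt, is_indel)
#' followed by one column per sample, as written by [write_cohort()].
#' @param path TSV path.
#' @return A [genotype_matrix()].
#' @export
read_dosage_tsv <- function(path) {
  d <- data.table::fread(path, sep = "\t", data.table = FALSE)
  meta <- c("id", "chrom", "pos", "ref", "alt", "is_indel")
  samp <- setdiff(names(d), meta)
  dos <- t(as.matrix(d[samp]))
  rownames(dos) <- samp
  genotype_matrix(dos, d[intersect(meta, names(d))])
}

#' Read genotypes from a minimal VCF (GT field)
#'
#' Requires the vcfR package. Variants with symbolic or multi-allelic ALT are
#' rejected; missing GT becomes NA dosage.
#' @param path VCF path.
#' @return A [genotype_matrix()].
#' @export
read_vcf_dosage <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the vcfR package")
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (any(grepl(",", fix$ALT))) stop("multi-allelic records are not supported")
  gt <- vcfR::extract.gt(vcf, element = "GT")
  alt_count <- function(x) {
    ifelse(is.na(x) | x %in% c(".", "./.", ".|."), NA_integer_,
           vapply(strsplit(gsub("\\|", "/", x), "/"), function(a) {
             sum(a == "1")
           }, integer(1)))
  }
  dos <- t(apply(gt, 1, alt_count))
  dos <- t(dos)  # samples x variants
  rownames(dos) <- colnames(gt)
  variants <- data.frame(
    id = ifelse(is.na(fix$ID) | fix$ID == ".",
                paste0(fix$CHROM, "_", fix$POS), fix$ID),
    chrom = fix$CHROM, pos = as.integer(fix$POS), ref = fix$REF, alt = fix$ALT,
    is_indel = nchar(fix$REF) != 1L | nchar(fix$ALT) != 1L,
    stringsAsFactors = FALSE)
  genotype_matrix(dos, variants)
}

#' Read gene models from TSV or GFF3
#'
#' TSV must carry gene_id, chrom, start, end, strand; GFF3 (via rtracklayer)
#' uses `gene` records with an ID attribute. TSS/TTS are derived from strand.
#' @param path File path (`.gff3`/`.gff` routed to rtracklayer).
#' @return Gene-model data.frame as produced by [generate_gene_models()].
#' @export
read_gene_models <- function(path) {
  if (grepl("\\.gff3?$", path)) {
    if (!requireNamespace("rtracklayer", quietly = TRUE)) {
      stop("reading GFF3 requires the rtracklayer package")
    }
    gr <- rtracklayer::import(path)
    gr <- gr[gr$type == "gene"]
    genes <- data.frame(
      gene_id = gr$ID, chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      stringsAsFactors = FALSE)
  } else {
    genes <- data.table::fread(path, sep = "\t", data.table = FALSE)
  }
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end)
  genes$tts <- ifelse(genes$strand == "+", genes$end, genes$start)
  genes
}

#' Read a counts TSV (gene_id column + one column per sample)
#' @param path TSV path.
#' @return genes x samples integer matrix.
#' @export
read_counts_tsv <- function(path) {
  d <- data.table::fread(path, sep = "\t", data.table = FALSE)
  m <- as.matrix(d[setdiff(names(d), "gene_id")])
  rownames(m) <- d$gene_id
  m
}

#' Read footprints from BED6+ as written by [write_cohort()]
#' @param path BED path (columns: chrom, start, end, name, score, strand,
#'   status, fdr, then replicate counts).
#' @return Footprint data.frame.
#' @export
read_footprints_bed <- function(path) {
  d <- data.table::fread(path, sep = "\t", data.table = FALSE, header = FALSE)
  base <- c("chrom", "start", "end", "name", "score", "strand", "status", "fdr")
  extra <- ncol(d) - length(base)
  names(d) <- c(base[seq_len(min(ncol(d), length(base)))],
                if (extra > 0) c(paste0("ctrl_", seq_len(ceiling(extra / 2))),
                                 paste0("heat_", seq_len(floor(extra / 2)))))
  fp <- d[c("chrom", "start", "end", "status", "fdr",
            grep("^(ctrl|heat)_", names(d), value = TRUE))]
  fp[order(fp$chrom, fp$start), , drop = FALSE]
}
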