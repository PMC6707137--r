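suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(S4Vectors)
  library(Biostrings)
})

# ApaSegments from 0-based half-open PRE/POST intervals
makeSegments <- function(gene_id, chrom, strand, pre, post,
                         proximal = "s1") {
  n <- length(gene_id)
  chrom <- rep_len(chrom, n)
  strand <- rep_len(strand, n)
  preM <- do.call(rbind, pre)
  postM <- do.call(rbind, post)
  gr <- GRanges(rep(chrom, 2),
                IRanges(c(preM[, 1], postM[, 1]) + 1,
                        c(preM[, 2], postM[, 2])),
                strand = rep(strand, 2))
  mcols(gr) <- DataFrame(gene_id = rep(gene_id, 2),
                         segment = rep(c("PRE", "POST"), each = n),
                         proximal_site_id = proximal,
                         distal_site_id = "gene_end")
  new("ApaSegments", segments = gr)
}

# single-exon GeneModelSet from 0-based half-open spans
makeModels <- function(gene_id, chrom, strand, start0, end0,
                       cds_start = NA_real_, cds_end = NA_real_) {
  gr <- GRanges(chrom, IRanges(start0 + 1, end0), strand = strand)
  mcols(gr) <- DataFrame(gene_id = gene_id,
                         cds_start = rep_len(cds_start, length(gr)),
                         cds_end = rep_len(cds_end, length(gr)))
  new("GeneModelSet", genes = gr,
      exons = GRangesList(lapply(seq_along(gr), function(i) granges(gr[i]))),
      excluded = data.frame(gene_id = character(), reason = character()))
}

# GenotypeMatrix from a dosage matrix (variants x individuals)
makeGeno <- function(d, pos = NULL, chrom = "chr1", ids = NULL,
                     vclass = "SNP", ref = "A", alt = "G") {
  n <- nrow(d)
  if (is.null(pos)) pos <- seq_len(n) * 100L
  if (is.null(ids)) ids <- paste0("v", seq_len(n))
  if (is.null(colnames(d))) colnames(d) <- paste0("i", seq_len(ncol(d)))
  storage.mode(d) <- "integer"
  gr <- GRanges(chrom, IRanges(pos, width = 1L))
  mcols(gr) <- DataFrame(id = ids, ref = rep_len(ref, n),
                         alt = rep_len(alt, n),
                         vclass = rep_len(vclass, n))
  new("GenotypeMatrix", ranges = gr, dosages = d)
}

# allele-window rows without a genome (for motif truth-table tests)
makeWindows <- function(variant_id, gene_id, ref_seq, alt_seq, var_offset,
                        pos0, strand = "+") {
  data.frame(variant_id = variant_id, gene_id = gene_id, strand = strand,
             ref_seq = ref_seq, alt_seq = alt_seq, var_offset = var_offset,
             pos0 = pos0, stringsAsFactors = FALSE)
}

uniformPwm <- function(L = 3, id = "U") {
  list(motif_id = id, rbp_id = id,
       matrix = matrix(0.25, 4, L, dimnames = list(c("A", "C", "G", "T"),
                                                   NULL)),
       background = c(A = .25, C = .25, G = .25, T = .25), expressed = TRUE)
}

# a PWM whose consensus is `cons`, with probability `pMax` on the consensus
# base and the remainder spread evenly
consensusPwm <- function(cons, pMax = 0.91, id = "M",
                         expressed = TRUE) {
  L <- nchar(cons)
  mat <- matrix((1 - pMax) / 3, 4, L,
                dimnames = list(c("A", "C", "G", "T"), NULL))
  for (k in seq_len(L)) mat[substr(cons, k, k), k] <- pMax
  list(motif_id = id, rbp_id = id, matrix = mat,
       background = c(A = .25, C = .25, G = .25, T = .25),
       expressed = expressed)
}
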