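#' @import methods
#' @importFrom GenomicRanges GRanges GRangesList seqnames strand start end width mcols mcols<- granges
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors DataFrame
NULL

## Coordinates are 0-based half-open internally everywhere in this package;
## GRanges slots store them as 1-based closed (the GRanges convention), and
## the helpers zhStart()/zhEnd() translate.  GTF/BED I/O converts explicitly.

#' Collapsed gene models
#'
#' One record per gene: the interval union of the exons of all transcripts
#' assigned to the gene, plus the collapsed coding span (most proximal coding
#' start to most distal coding end, in transcript orientation).  The 5' and 3'
#' UTRs of the collapsed model are defined relative to that span.
#'
#' @slot genes [GenomicRanges::GRanges] with one range per gene (the gene
#'   span) and metadata columns `gene_id`, `cds_start`, `cds_end` (0-based
#'   half-open genomic coordinates of the collapsed coding span, `NA` for
#'   non-coding genes).
#' @slot exons [GenomicRanges::GRangesList] parallel to `genes`: merged,
#'   disjoint, sorted exons of each gene.
#' @slot excluded data.frame with columns `gene_id`, `reason` for genes that
#'   could not be collapsed (e.g. transcripts on different chromosomes).
#' @export
setClass("GeneModelSet",
  representation(genes = "GRanges", exons = "GRangesList",
                 excluded = "data.frame"))

setValidity("GeneModelSet", function(object) {
  msg <- NULL
  if (length(object@genes) != length(object@exons))
    msg <- c(msg, "genes and exons must be parallel")
  need <- c("gene_id", "cds_start", "cds_end")
  if (!all(need %in% colnames(mcols(object@genes))))
    msg <- c(msg, "genes must carry gene_id, cds_start, cds_end")
  if (length(object@genes)) {
    disjoint <- vapply(seq_along(object@exons), function(i) {
      ex <- object@exons[[i]]
      length(ex) == length(GenomicRanges::reduce(ex))
    }, logical(1))
    if (!all(disjoint))
      msg <- c(msg, "exon sets must be disjoint (merged)")
  }
  if (is.null(msg)) TRUE else msg
})

#' Two-segment alternative 3' UTR model
#'
#' For each gene, the PRE segment (terminal-exon start to the proximal
#' poly(A) site, shared by the short and long isoform) and the POST segment
#' (proximal poly(A) site to the gene end, long isoform only).
#'
#' @slot segments [GenomicRanges::GRanges] with two ranges per gene and
#'   metadata columns `gene_id`, `segment` ("PRE"/"POST"),
#'   `proximal_site_id`, `distal_site_id`.
#' @export
setClass("ApaSegments", representation(segments = "GRanges"))

setValidity("ApaSegments", function(object) {
  gr <- object@segments
  need <- c("gene_id", "segment", "proximal_site_id", "distal_site_id")
  if (!all(need %in% colnames(mcols(gr))))
    return("segments must carry gene_id, segment, proximal_site_id, distal_site_id")
  if (!all(mcols(gr)$segment %in% c("PRE", "POST")))
    return("segment must be PRE or POST")
  if (length(gr)) {
    m <- mcols(gr)
    preIx <- which(m$segment == "PRE")
    postIx <- which(m$segment == "POST")
    preG <- m$gene_id[preIx]; postG <- m$gene_id[postIx]
    if (anyDuplicated(preG) || anyDuplicated(postG) ||
        !setequal(preG, postG))
      return("each gene needs exactly one PRE and one POST segment")
    j <- postIx[match(preG, postG)]
    i <- preIx
    neg <- as.character(strand(gr))[i] == "-"
    ok <- as.character(seqnames(gr))[i] == as.character(seqnames(gr))[j] &
      as.character(strand(gr))[i] == as.character(strand(gr))[j] &
      width(gr)[i] >= 1L & width(gr)[j] >= 1L &
      # adjacency: PRE precedes POST in transcript orientation
      ifelse(neg, start(gr)[i] == end(gr)[j] + 1L,
                  start(gr)[j] == end(gr)[i] + 1L)
    if (!all(ok))
      return(paste("invalid PRE/POST pair for gene(s):",
                   paste(preG[!ok], collapse = ", ")))
  }
  TRUE
})

#' Matrix of m/M values
#'
#' Genes x individuals matrix of m/M values (length-normalised short/long 3'
#' UTR isoform expression ratios) together with an explicit missingness mask.
#' A cell is missing when the POST segment received no reads (the ratio is
#' infinite) or the computed value is negative (PRE read density below POST
#' density).  m/M = 0 (no evidence for the short isoform) is kept as a value
#' but is additionally excluded from the log2 view, where it is undefined.
#'
#' @slot values numeric matrix (genes x samples); `NA` where the value is
#'   undefined (POST count 0).
#' @slot mask logical matrix, `TRUE` for missing cells.
#' @export
setClass("MMatrix", representation(values = "matrix", mask = "matrix"))

setValidity("MMatrix", function(object) {
  if (!identical(dim(object@values), dim(object@mask)))
    return("values and mask must have identical dimensions")
  if (!is.logical(object@mask)) return("mask must be logical")
  v <- object@values[!object@mask]
  if (any(!is.finite(v)) || any(v < 0, na.rm = TRUE))
    return("unmasked values must be finite and >= 0")
  TRUE
})

#' Genotype dosage matrix
#'
#' Variants x individuals dosages in the standard 0/1/2 codification (number
#' of alternative alleles), with per-variant genomic position, alleles and
#' variant class.
#'
#' @slot ranges [GenomicRanges::GRanges] of width-1 variant positions with
#'   metadata columns `id`, `ref`, `alt`, `vclass` ("SNP"/"indel"/"SV").
#' @slot dosages integer matrix (variants x individuals), values in
#'   `c(0L, 1L, 2L, NA)`.
#' @export
setClass("GenotypeMatrix",
  representation(ranges = "GRanges", dosages = "matrix"))

setValidity("GenotypeMatrix", function(object) {
  if (length(object@ranges) != nrow(object@dosages))
    return("ranges and dosage rows must be parallel")
  need <- c("id", "ref", "alt", "vclass")
  if (!all(need %in% colnames(mcols(object@ranges))))
    return("ranges must carry id, ref, alt, vclass")
  d <- object@dosages
  if (!all(d %in% c(0L, 1L, 2L) | is.na(d)))
    return("dosages must be 0, 1, 2 or NA")
  if (is.null(colnames(d))) return("dosages must have sample names")
  TRUE
})

## ---- accessors -----------------------------------------------------------

#' @describeIn GeneModelSet-class gene identifiers
#' @param x a `GeneModelSet`
#' @export
geneIds <- function(x) mcols(x@genes)$gene_id

#' @describeIn GeneModelSet-class gene spans as a `GRanges`
#' @export
geneRanges <- function(x) x@genes

#' @describeIn GeneModelSet-class merged exons, a `GRangesList` by gene
#' @export
exonsByGene <- function(x) x@exons

#' @describeIn GeneModelSet-class excluded genes and reasons
#' @export
excludedGenes <- function(x) x@excluded

#' Transcription start/end sites of collapsed models
#'
#' @param x a `GeneModelSet`
#' @return data.frame with `gene_id`, `chrom`, `strand`, `tss`, `tes`
#'   (0-based genomic positions; for a minus-strand gene the TSS is the
#'   genomically rightmost coordinate).
#' @export
tssTes <- function(x) {
  g <- x@genes
  plus <- as.character(strand(g)) != "-"
  data.frame(gene_id = mcols(g)$gene_id,
             chrom = as.character(seqnames(g)),
             strand = ifelse(plus, "+", "-"),
             tss = ifelse(plus, start(g) - 1L, end(g)),
             tes = ifelse(plus, end(g), start(g) - 1L),
             stringsAsFactors = FALSE)
}

#' @describeIn ApaSegments-class PRE segments as a `GRanges` named by gene
#' @param x an `ApaSegments`
#' @export
preRanges <- function(x) {
  gr <- x@segments[mcols(x@segments)$segment == "PRE"]
  names(gr) <- mcols(gr)$gene_id
  gr
}

#' @describeIn ApaSegments-class POST segments as a `GRanges` named by gene
#' @export
postRanges <- function(x) {
  gr <- x@segments[mcols(x@segments)$segment == "POST"]
  names(gr) <- mcols(gr)$gene_id
  gr
}

#' Per-gene segment table
#'
#' @param x an `ApaSegments`
#' @return data.frame with one row per gene: chrom, strand, 0-based half-open
#'   PRE/POST intervals, segment lengths `l_pre`, `l_post` and the
#'   proximal/distal site ids.
#' @export
segmentTable <- function(x) {
  pre <- preRanges(x); post <- postRanges(x)
  post <- post[names(pre)]
  data.frame(gene_id = names(pre),
             chrom = as.character(seqnames(pre)),
             strand = as.character(strand(pre)),
             pre_start = start(pre) - 1L, pre_end = end(pre),
             post_start = start(post) - 1L, post_end = end(post),
             l_pre = width(pre), l_post = width(post),
             proximal_site_id = mcols(pre)$proximal_site_id,
             distal_site_id = mcols(pre)$distal_site_id,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @describeIn MMatrix-class the raw m/M value matrix (`NA` where undefined)
#' @param x an `MMatrix`
#' @export
mmValues <- function(x) x@values

#' @describeIn MMatrix-class logical missingness mask (`TRUE` = missing)
#' @export
mmMask <- function(x) x@mask

#' @describeIn MMatrix-class gene ids (row names)
#' @export
mmGenes <- function(x) rownames(x@values)

#' @describeIn MMatrix-class sample ids (column names)
#' @export
mmSamples <- function(x) colnames(x@values)

#' log2 view of an m/M matrix
#'
#' `NA` wherever the cell is masked or the value is 0 (log2 undefined).
#'
#' @param x an `MMatrix`
#' @return numeric matrix of log2(m/M)
#' @export
log2MM <- function(x) {
  v <- x@values
  v[x@mask | (!is.na(v) & v <= 0)] <- NA_real_
  log2(v)
}

#' @describeIn GenotypeMatrix-class variant identifiers
#' @param x a `GenotypeMatrix`
#' @export
variantIds <- function(x) mcols(x@ranges)$id

#' @describeIn GenotypeMatrix-class variant positions as a `GRanges`
#' @export
variantRanges <- function(x) x@ranges

#' @describeIn GenotypeMatrix-class dosage matrix (variants x individuals)
#' @export
dosages <- function(x) x@dosages

#' @describeIn GenotypeMatrix-class cohort sample ids
#' @export
sampleIds <- function(x) colnames(x@dosages)

#' Subset a GenotypeMatrix by variant
#'
#' @param x a `GenotypeMatrix`
#' @param i variant index, logical vector, or vector of variant ids
#' @param j,...,drop ignored
#' @export
setMethod("[", "GenotypeMatrix", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, variantIds(x))
  new("GenotypeMatrix", ranges = x@ranges[i],
      dosages = x@dosages[i, , drop = FALSE])
})

## ---- show methods --------------------------------------------------------

setMethod("show", "GeneModelSet", function(object) {
  cat("GeneModelSet with", length(object@genes), "genes",
      sprintf("(%d excluded)\n", nrow(object@excluded)))
})

setMethod("show", "ApaSegments", function(object) {
  n <- length(unique(mcols(object@segments)$gene_id))
  cat("ApaSegments:", n, "genes with PRE/POST two-segment 3' UTR models\n")
})

setMethod("show", "MMatrix", function(object) {
  cat("MMatrix:", nrow(object@values), "genes x",
      ncol(object@values), "samples;",
      sum(object@mask), "masked cells\n")
})

setMethod("show", "GenotypeMatrix", function(object) {
  cat("GenotypeMatrix:", length(object@ranges), "variants x",
      ncol(object@dosages), "individuals;",
      sum(mcols(object@ranges)$vclass == "SNP"), "SNPs\n")
})
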