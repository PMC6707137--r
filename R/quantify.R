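#' @importFrom Rsamtools ScanBamParam scanBamFlag asBam scanBamHeader
#' @importFrom GenomicAlignments readGAlignments
#' @importFrom S4Vectors queryHits subjectHits
#' @importFrom IRanges findOverlaps
NULL

#' Count reads over PRE/POST segments
#'
#' Each primary, mapped alignment overlapping exactly one segment of a gene
#' increments that segment's count; an alignment overlapping both the PRE and
#' the POST segment increments POST only, since covering the proximal poly(A)
#' site boundary is evidence for the long isoform.  Unmapped, secondary and
#' (optionally) duplicate reads are ignored.  Counting is unstranded by
#' default, matching unstranded library preparations; set `stranded` for
#' stranded protocols.
#'
#' @param files named character vector of BAM (or SAM; converted on the fly)
#'   files, one per sample; names are sample ids (basenames used if unnamed).
#' @param segments an [ApaSegments-class]
#' @param stranded `"none"` (default), `"fr"` (read strand = gene strand) or
#'   `"rf"` (read strand opposite to gene strand)
#' @param ignoreDuplicates drop duplicate-flagged reads (default TRUE)
#' @param minMapq minimum mapping quality (default 0)
#' @return data.frame with columns `gene_id`, `sample_id`, `r_pre`, `r_post`
#' @export
countSegmentReads <- function(files, segments, stranded = c("none", "fr", "rf"),
                              ignoreDuplicates = TRUE, minMapq = 0L) {
  stranded <- match.arg(stranded)
  if (is.null(names(files)))
    names(files) <- sub("\\.(bam|sam)$", "", basename(files))
  pre <- preRanges(segments); post <- postRanges(segments)
  genes <- names(pre)
  out <- vector("list", length(files))
  for (k in seq_along(files)) {
    f <- files[k]
    if (grepl("\\.sam$", f)) f <- asBam(f, tempfile(), overwrite = TRUE)
    hdr <- names(scanBamHeader(f)[[1]]$targets)
    segChrom <- unique(as.character(seqnames(segments@segments)))
    missing <- setdiff(segChrom, hdr)
    if (length(missing) == length(segChrom))
      stop("chromosome names in segments absent from ", files[k], ": ",
           paste(missing, collapse = ", "))
    flag <- scanBamFlag(isUnmappedQuery = FALSE, isSecondaryAlignment = FALSE,
                        isDuplicate = if (ignoreDuplicates) FALSE else NA)
    aln <- readGAlignments(f, param = ScanBamParam(
      flag = flag, mapqFilter = minMapq))
    rd <- granges(aln)
    ignoreStrand <- stranded == "none"
    if (stranded == "rf") strand(rd) <- ifelse(
      as.character(strand(rd)) == "+", "-", "+")
    hitPre <- findOverlaps(rd, pre, ignore.strand = ignoreStrand)
    hitPost <- findOverlaps(rd, post, ignore.strand = ignoreStrand)
    # read x gene pairs; POST wins when a read touches both segments
    prePairs <- paste(queryHits(hitPre), subjectHits(hitPre))
    postPairs <- paste(queryHits(hitPost), subjectHits(hitPost))
    preOnly <- !(prePairs %in% postPairs)
    rPre <- tabulate(subjectHits(hitPre)[preOnly], nbins = length(genes))
    rPost <- tabulate(subjectHits(hitPost), nbins = length(genes))
    out[[k]] <- data.frame(gene_id = genes, sample_id = names(files)[k],
                           r_pre = rPre, r_post = rPost,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Compute the m/M matrix from segment counts
#'
#' The m/M value of gene a in individual i is
#' \deqn{m/M = (l_{POST} \times r_{PRE}) / (l_{PRE} \times r_{POST}) - 1,}
#' the length-normalised ratio between short- and long-isoform expression.
#' Cells where the POST count is 0 (infinite ratio) or the computed value is
#' negative (PRE read density below POST density) are masked as missing.
#' A value of exactly 0 (no short-isoform signal) is kept.
#'
#' @param counts data.frame with `gene_id`, `sample_id`, `r_pre`, `r_post`
#'   (non-negative integers), e.g. from [countSegmentReads()] or
#'   [readSegmentCounts()]
#' @param segments an [ApaSegments-class] supplying the segment lengths; all
#'   genes in `counts` must be present
#' @return an [MMatrix-class]
#' @export
computeMM <- function(counts, segments) {
  st <- segmentTable(segments)
  unknown <- setdiff(unique(counts$gene_id), st$gene_id)
  if (length(unknown))
    stop("counts reference gene(s) absent from segments: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  if (any(counts$r_pre < 0 | counts$r_post < 0))
    stop("negative read counts")
  genes <- st$gene_id[st$gene_id %in% counts$gene_id]
  samples <- unique(counts$sample_id)
  gi <- match(counts$gene_id, genes)
  si <- match(counts$sample_id, samples)
  lpre <- st$l_pre[match(genes, st$gene_id)]
  lpost <- st$l_post[match(genes, st$gene_id)]
  rPre <- matrix(NA_real_, length(genes), length(samples),
                 dimnames = list(genes, samples))
  rPost <- rPre
  rPre[cbind(gi, si)] <- counts$r_pre
  rPost[cbind(gi, si)] <- counts$r_post
  # cells with no counts row are treated as zero-coverage (missing)
  rPre[is.na(rPre)] <- 0; rPost[is.na(rPost)] <- 0
  vals <- (lpost * rPre) / (lpre * rPost) - 1
  inf <- rPost == 0
  vals[inf] <- NA_real_                       # infinite ratio: undefined
  mask <- inf | (!is.na(vals) & vals < 0)     # masked; negatives kept visible
  new("MMatrix", values = vals, mask = mask)
}

#' Filter genes of an m/M matrix
#'
#' Keeps genes on an allowed chromosome whose number of missing cells is
#' strictly below `maxMissing`, preserving gene order.
#'
#' @param mm an [MMatrix-class]
#' @param models the [GeneModelSet-class] the genes belong to
#' @param autosomes allowed chromosome names (default `chr1`-`chr22`)
#' @param maxMissing strict upper bound on missing cells per gene; default
#'   `ceiling(0.27 * n_samples)`, generalising a 100-of-373 rule
#' @return the filtered [MMatrix-class]
#' @export
filterGenes <- function(mm, models,
                        autosomes = paste0("chr", 1:22),
                        maxMissing = NULL) {
  if (is.null(maxMissing)) maxMissing <- ceiling(0.27 * ncol(mmValues(mm)))
  stopifnot(maxMissing >= 0)
  chrom <- as.character(seqnames(geneRanges(models)))
  names(chrom) <- geneIds(models)
  keep <- chrom[mmGenes(mm)] %in% autosomes &
    rowSums(mmMask(mm)) < maxMissing
  new("MMatrix", values = mmValues(mm)[keep, , drop = FALSE],
      mask = mmMask(mm)[keep, , drop = FALSE])
}

#' Read a precomputed PRE/POST counts table
#'
#' @param path TSV with columns `gene_id`, `sample_id`, `r_pre`, `r_post`
#' @return data.frame in the [computeMM()] input layout
#' @export
readSegmentCounts <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("gene_id", "sample_id", "r_pre", "r_post")
  if (!all(need %in% names(df)))
    stop("counts TSV must have columns ", paste(need, collapse = ", "))
  df
}

#' @rdname readSegmentCounts
#' @param counts counts data.frame
#' @export
writeSegmentCounts <- function(counts, path) {
  utils::write.table(counts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write an m/M matrix (and its log2 view) as TSV
#'
#' Masked cells are written as `NA`.
#'
#' @param mm an [MMatrix-class]
#' @param path output TSV (genes x samples)
#' @param log2 write the log2 view instead of raw values
#' @export
writeMMatrix <- function(mm, path, log2 = FALSE) {
  v <- if (log2) log2MM(mm) else { x <- mmValues(mm); x[mmMask(mm)] <- NA; x }
  utils::write.table(data.frame(gene_id = rownames(v), v,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an m/M matrix TSV written by [writeMMatrix()]
#'
#' @param path TSV file
#' @return an [MMatrix-class] (mask = NA cells)
#' @export
readMMatrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  v <- as.matrix(df[, -1, drop = FALSE])
  rownames(v) <- df$gene_id
  new("MMatrix", values = v, mask = is.na(v))
}
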