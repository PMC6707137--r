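#' @importFrom rtracklayer import export
#' @importFrom GenomicRanges reduce
NULL

#' Collapse transcript structures into per-gene models
#'
#' All transcripts assigned to a gene are merged into a single model: the
#' exon set is the interval union of the transcripts' exons, and the collapsed
#' coding span runs from the most proximal coding start to the most distal
#' coding end in transcript orientation (genomically, the union span of the
#' per-transcript CDS intervals).  Genes whose transcripts disagree on
#' chromosome or strand cannot be collapsed and are excluded with a reason.
#'
#' @param transcripts data.frame with one row per exon: `transcript_id`,
#'   `chrom`, `strand` ("+"/"-"), `start`, `end` (0-based half-open), and
#'   per-transcript `cds_start`, `cds_end` (0-based half-open genomic
#'   coordinates of the transcript's coding span, `NA` for non-coding).
#' @param geneMap data.frame mapping `transcript_id` to `gene_id`.
#' @return a [GeneModelSet-class]; excluded genes are available through
#'   [excludedGenes()].
#' @export
collapseGeneModels <- function(transcripts, geneMap) {
  stopifnot(all(c("transcript_id", "chrom", "strand", "start", "end") %in%
                  names(transcripts)),
            all(c("transcript_id", "gene_id") %in% names(geneMap)))
  if (!"cds_start" %in% names(transcripts)) transcripts$cds_start <- NA_real_
  if (!"cds_end" %in% names(transcripts)) transcripts$cds_end <- NA_real_
  tx <- transcripts
  tx$gene_id <- geneMap$gene_id[match(tx$transcript_id, geneMap$transcript_id)]
  unmapped <- unique(tx$transcript_id[is.na(tx$gene_id)])
  if (length(unmapped)) {
    warning("dropping ", length(unmapped),
            " transcript(s) absent from the gene map")
    tx <- tx[!is.na(tx$gene_id), , drop = FALSE]
  }
  genes <- unique(tx$gene_id)
  rows <- vector("list", length(genes))
  exl <- vector("list", length(genes))
  excluded <- data.frame(gene_id = character(), reason = character(),
                         stringsAsFactors = FALSE)
  keep <- logical(length(genes))
  for (i in seq_along(genes)) {
    g <- tx[tx$gene_id == genes[i], , drop = FALSE]
    if (length(unique(g$chrom)) > 1L || length(unique(g$strand)) > 1L) {
      excluded <- rbind(excluded, data.frame(
        gene_id = genes[i], reason = "transcripts_on_multiple_chrom_or_strand",
        stringsAsFactors = FALSE))
      next
    }
    ex <- reduce(GRanges(g$chrom[1],
                         IRanges(g$start + 1L, g$end), strand = g$strand[1]))
    cs <- suppressWarnings(min(g$cds_start, na.rm = TRUE))
    ce <- suppressWarnings(max(g$cds_end, na.rm = TRUE))
    if (!is.finite(cs)) { cs <- NA_real_; ce <- NA_real_ }
    rows[[i]] <- data.frame(chrom = g$chrom[1], strand = g$strand[1],
                            start = min(start(ex)), end = max(end(ex)),
                            gene_id = genes[i], cds_start = cs, cds_end = ce,
                            stringsAsFactors = FALSE)
    exl[[i]] <- ex
    keep[i] <- TRUE
  }
  rows <- do.call(rbind, rows[keep])
  if (is.null(rows)) {
    gr <- GRanges()
    mcols(gr) <- DataFrame(gene_id = character(0), cds_start = numeric(0),
                           cds_end = numeric(0))
    return(new("GeneModelSet", genes = gr,
               exons = GRangesList(), excluded = excluded))
  }
  gr <- GRanges(rows$chrom, IRanges(rows$start, rows$end),
                strand = rows$strand)
  mcols(gr) <- DataFrame(gene_id = rows$gene_id,
                         cds_start = rows$cds_start, cds_end = rows$cds_end)
  new("GeneModelSet", genes = gr,
      exons = GRangesList(exl[keep]), excluded = excluded)
}

#' Terminal (3'-most) exon of each collapsed model
#'
#' @param models a [GeneModelSet-class]
#' @return `GRanges` named by gene id: the genomically last exon for plus
#'   strand genes, the first for minus strand genes.
#' @export
terminalExons <- function(models) {
  out <- lapply(seq_along(models@exons), function(i) {
    ex <- sort(models@exons[[i]])
    if (as.character(strand(models@genes[i])) == "-") ex[1] else ex[length(ex)]
  })
  gr <- unlist(GRangesList(out))
  names(gr) <- geneIds(models)
  gr
}

#' Define PRE/POST alternative 3' UTR segments
#'
#' For each gene, the proximal poly(A) site is the transcript-orientation-most
#' -proximal catalog site inside the terminal exon (sites in the 3' UTR are
#' preferred over coding-exon sites when any exist); the distal site is the
#' gene end.  The PRE segment runs from the terminal-exon start to the
#' proximal site and the POST segment from that site to the gene end, both in
#' transcript orientation (for minus-strand genes the PRE segment is
#' genomically rightmost).  Genes with no eligible site, or whose PRE or POST
#' segment would be shorter than `minSegmentLen`, are excluded with a
#' machine-readable reason.
#'
#' @param models a [GeneModelSet-class]
#' @param sites poly(A) site catalog, a `GRanges` of width-1 positions with a
#'   `site_id` metadata column (see [readPolyABed()])
#' @param minSegmentLen minimum PRE/POST length in bp (default 1)
#' @return list with elements `segments` (an [ApaSegments-class]) and
#'   `excluded` (data.frame `gene_id`, `reason`)
#' @export
defineApaSegments <- function(models, sites, minSegmentLen = 1L) {
  stopifnot(minSegmentLen >= 1L, "site_id" %in% colnames(mcols(sites)))
  term <- terminalExons(models)
  g <- models@genes
  segs <- vector("list", length(g))
  excl <- list()
  for (i in seq_along(g)) {
    gid <- mcols(g)$gene_id[i]
    ex <- term[gid]
    chrom <- as.character(seqnames(ex))
    neg <- as.character(strand(ex)) == "-"
    e0 <- start(ex) - 1L; e1 <- end(ex)           # 0-based half-open
    cand <- sites[as.character(seqnames(sites)) == chrom &
                  as.character(strand(sites)) == as.character(strand(ex))]
    p0 <- start(cand) - 1L
    inside <- p0 >= e0 & p0 < e1
    cand <- cand[inside]; p0 <- p0[inside]
    if (neg) {
      lpre <- e1 - p0; lpost <- p0 - e0
    } else {
      lpre <- p0 - e0; lpost <- e1 - p0
    }
    okLen <- lpre >= minSegmentLen & lpost >= minSegmentLen
    if (!length(cand)) {
      excl[[length(excl) + 1L]] <- data.frame(
        gene_id = gid, reason = "no_proximal_site", stringsAsFactors = FALSE)
      next
    }
    if (!any(okLen)) {
      excl[[length(excl) + 1L]] <- data.frame(
        gene_id = gid, reason = "segment_too_short", stringsAsFactors = FALSE)
      next
    }
    cand <- cand[okLen]; p0 <- p0[okLen]
    # prefer 3' UTR sites (downstream of the distal coding end)
    ce <- mcols(g)$cds_end[i]; cs <- mcols(g)$cds_start[i]
    inUtr <- if (neg) !is.na(cs) & p0 < cs else !is.na(ce) & p0 >= ce
    pool <- if (any(inUtr)) which(inUtr) else seq_along(cand)
    pp <- p0[pool]
    best <- if (neg) pool[pp == max(pp)] else pool[pp == min(pp)]
    if (length(best) > 1L)  # deterministic tie-break
      best <- best[order(mcols(cand)$site_id[best])][1L]
    best <- best[1L]
    sp <- p0[best]
    if (neg) {
      pre <- c(sp, e1); post <- c(e0, sp)
    } else {
      pre <- c(e0, sp); post <- c(sp, e1)
    }
    two <- GRanges(chrom,
                   IRanges(c(pre[1], post[1]) + 1L, c(pre[2], post[2])),
                   strand = ifelse(neg, "-", "+"))
    mcols(two) <- DataFrame(gene_id = gid, segment = c("PRE", "POST"),
                            proximal_site_id = mcols(cand)$site_id[best],
                            distal_site_id = "gene_end")
    segs[[i]] <- two
  }
  segs <- segs[!vapply(segs, is.null, logical(1))]
  gr <- if (length(segs)) unlist(GRangesList(segs)) else {
    g0 <- GRanges()
    mcols(g0) <- DataFrame(gene_id = character(0), segment = character(0),
                           proximal_site_id = character(0),
                           distal_site_id = character(0))
    g0
  }
  excluded <- if (length(excl)) do.call(rbind, excl) else
    data.frame(gene_id = character(), reason = character(),
               stringsAsFactors = FALSE)
  list(segments = new("ApaSegments", segments = gr), excluded = excluded)
}

#' Write PRE/POST segments as GTF
#'
#' Two features per gene (`PRE`, `POST`), 1-based inclusive coordinates, with
#' `gene_id` and the site ids as attributes.  The output round-trips
#' losslessly through [readSegmentsGtf()].
#'
#' @param segments an [ApaSegments-class]
#' @param path output file
#' @export
writeSegmentsGtf <- function(segments, path) {
  gr <- segments@segments
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##gff-version 2",
               "#  PRE/POST alternative 3' UTR segments"), con)
  if (length(gr)) {
    m <- mcols(gr)
    attrs <- sprintf(
      'gene_id "%s"; proximal_site_id "%s"; distal_site_id "%s";',
      m$gene_id, m$proximal_site_id, m$distal_site_id)
    writeLines(paste(as.character(seqnames(gr)), "apaqtl", m$segment,
                     start(gr), end(gr), ".", as.character(strand(gr)), ".",
                     attrs, sep = "\t"), con)
  }
  invisible(path)
}

#' Read a PRE/POST segments GTF
#'
#' @param path a GTF written by [writeSegmentsGtf()]
#' @return an [ApaSegments-class]
#' @export
readSegmentsGtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  if (!length(gr)) {
    g0 <- GRanges()
    mcols(g0) <- DataFrame(gene_id = character(0), segment = character(0),
                           proximal_site_id = character(0),
                           distal_site_id = character(0))
    return(new("ApaSegments", segments = g0))
  }
  m <- mcols(gr)
  out <- granges(gr)
  mcols(out) <- DataFrame(gene_id = m$gene_id,
                          segment = as.character(m$type),
                          proximal_site_id = m$proximal_site_id,
                          distal_site_id = m$distal_site_id)
  new("ApaSegments", segments = out)
}

#' Read a poly(A) site catalog from BED
#'
#' The BED name column carries the site id; strand is required.  The cleavage
#' position is taken as the (0-based) BED start of each record.
#'
#' @param path BED file
#' @return `GRanges` of width-1 sites with a `site_id` column
#' @export
readPolyABed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  if (any(as.character(strand(gr)) == "*"))
    stop("poly(A) BED must have strand for every site")
  out <- GRanges(seqnames(gr), IRanges(start(gr), width = 1L),
                 strand = strand(gr))
  mcols(out) <- DataFrame(site_id = if (!is.null(gr$name)) gr$name else
    paste0("pas", seq_along(gr)))
  out
}

#' Read transcript structures from a GTF annotation
#'
#' Uses `exon` and `CDS` features grouped by `transcript_id` to build the
#' exon-level transcript table consumed by [collapseGeneModels()].
#'
#' @param path GTF/GFF file
#' @return data.frame in the [collapseGeneModels()] input layout
#' @export
readTranscriptsGtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  ex <- gr[gr$type == "exon"]
  if (!length(ex)) stop("no exon features in ", path)
  cds <- gr[gr$type == "CDS"]
  cs <- tapply(start(cds) - 1L, cds$transcript_id, min)
  ce <- tapply(end(cds), cds$transcript_id, max)
  tid <- as.character(ex$transcript_id)
  data.frame(transcript_id = tid,
             chrom = as.character(seqnames(ex)),
             strand = as.character(strand(ex)),
             start = start(ex) - 1L, end = end(ex),
             cds_start = as.numeric(cs[tid]),
             cds_end = as.numeric(ce[tid]),
             stringsAsFactors = FALSE)
}
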