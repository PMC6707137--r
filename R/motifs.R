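#' @importFrom Biostrings DNAStringSet reverseComplement subseq
NULL

.revcomp <- function(x) as.character(reverseComplement(DNAStringSet(x)))

#' REF/ALT sequence windows around SNPs
#'
#' Reconstructs the sense-strand (gene-strand) sequence of the reference and
#' the alternative allele in the region around each SNP (±`flank` bp),
#' reverse-complementing for minus-strand genes and clipping at chromosome
#' boundaries (the realised variant offset is recorded).  Restricted to
#' single-nucleotide substitutions: indels and structural variants are an
#' error.
#'
#' @param geno a [GenotypeMatrix-class] containing only SNPs
#' @param genome named [Biostrings::DNAStringSet] of chromosome sequences
#' @param models a [GeneModelSet-class]; each variant is assigned the strand
#'   of the analyzed gene containing it (variants outside all genes are
#'   dropped)
#' @param flank bp on each side of the variant (default 10)
#' @return data.frame: `variant_id`, `gene_id`, `strand`, `ref_seq`,
#'   `alt_seq`, `var_offset` (1-based offset of the variant inside the
#'   window), `pos0` (0-based genomic position)
#' @export
alleleWindows <- function(geno, genome, models, flank = 10L) {
  vr <- variantRanges(geno)
  m <- mcols(vr)
  if (any(m$vclass != "SNP"))
    stop("allele windows are defined for SNPs only; remove indels/SVs")
  g <- geneRanges(models)
  hit <- GenomicRanges::findOverlaps(vr, g, ignore.strand = TRUE)
  out <- vector("list", length(hit))
  qh <- S4Vectors::queryHits(hit); sh <- S4Vectors::subjectHits(hit)
  for (k in seq_along(qh)) {
    i <- qh[k]; gi <- sh[k]
    chrom <- as.character(seqnames(vr))[i]
    if (!chrom %in% names(genome)) stop("chromosome ", chrom, " not in genome")
    chromSeq <- genome[[chrom]]
    pos <- start(vr)[i]                      # 1-based
    lo <- max(1L, pos - flank)
    hi <- min(length(chromSeq), pos + flank)
    win <- as.character(subseq(chromSeq, lo, hi))
    off <- pos - lo + 1L
    refW <- win; altW <- win
    substr(refW, off, off) <- m$ref[i]
    substr(altW, off, off) <- m$alt[i]
    neg <- as.character(strand(g))[gi] == "-"
    if (neg) {
      refW <- .revcomp(refW); altW <- .revcomp(altW)
      off <- nchar(refW) - off + 1L
    }
    out[[k]] <- data.frame(variant_id = m$id[i],
                           gene_id = mcols(g)$gene_id[gi],
                           strand = ifelse(neg, "-", "+"),
                           ref_seq = refW, alt_seq = altW,
                           var_offset = off, pos0 = pos - 1L,
                           stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(variant_id = character(), gene_id = character(),
                      strand = character(), ref_seq = character(),
                      alt_seq = character(), var_offset = integer(),
                      pos0 = integer(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

# motif occurrences (exact string match) overlapping a 1-based offset
.hitsOverlapping <- function(seq, motif, offset) {
  L <- nchar(motif)
  starts <- gregexpr(motif, seq, fixed = TRUE)[[1]]
  if (starts[1] == -1) return(integer(0))
  starts[starts <= offset & offset <= starts + L - 1L]
}

#' PAS motif creation, destruction and interconversion
#'
#' A SNP is a candidate when its nearest transcript-orientation-downstream
#' poly(A) site lies within the gene's PRE/POST segments at a distance of
#' 10-100 nt (a polyadenylation signal acts upstream of the cleavage site it
#' drives).  Both allele windows are scanned for PAS hexamers overlapping
#' the variant position; the call is `created` (ALT only), `destroyed` (REF
#' only) or `interconverted` (different motifs in the two alleles, which can
#' change signal strength).
#'
#' @param windows data.frame from [alleleWindows()]
#' @param geno the [GenotypeMatrix-class] the windows came from
#' @param sites poly(A) catalog `GRanges` with `site_id` ([readPolyABed()])
#' @param segments an [ApaSegments-class]
#' @param pas character vector of PAS hexamers (DNA alphabet, see
#'   [readPasMotifs()])
#' @param minDist,maxDist allowed variant-to-site distance in nt (10, 100)
#' @return data.frame of alteration calls: `variant_id`, `mechanism`,
#'   `motif_id`, `status`, `detail`
#' @export
pasAlteration <- function(windows, geno, sites, segments, pas,
                          minDist = 10L, maxDist = 100L) {
  stopifnot(all(nchar(pas) == 6L))
  st <- segmentTable(segments)
  calls <- list()
  for (k in seq_len(nrow(windows))) {
    w <- windows[k, ]
    seg <- st[st$gene_id == w$gene_id, ]
    if (!nrow(seg)) next
    sameChrom <- as.character(seqnames(sites)) == seg$chrom &
      as.character(strand(sites)) == seg$strand
    p0 <- start(sites)[sameChrom] - 1L
    ids <- mcols(sites)$site_id[sameChrom]
    down <- if (w$strand == "-") p0 < w$pos0 else p0 > w$pos0
    if (!any(down)) next
    p0 <- p0[down]; ids <- ids[down]
    nearest <- if (w$strand == "-") which.max(p0) else which.min(p0)
    sitePos <- p0[nearest]
    lo <- min(seg$pre_start, seg$post_start)
    hi <- max(seg$pre_end, seg$post_end)
    if (sitePos < lo || sitePos >= hi) next     # site outside PRE/POST span
    dist <- abs(sitePos - w$pos0)
    if (dist < minDist || dist > maxDist) next
    refHit <- pas[vapply(pas, function(m)
      length(.hitsOverlapping(w$ref_seq, m, w$var_offset)) > 0, logical(1))]
    altHit <- pas[vapply(pas, function(m)
      length(.hitsOverlapping(w$alt_seq, m, w$var_offset)) > 0, logical(1))]
    if (!length(refHit) && !length(altHit)) next
    if (setequal(refHit, altHit)) next
    status <- if (!length(refHit)) "created"
              else if (!length(altHit)) "destroyed"
              else "interconverted"
    calls[[length(calls) + 1L]] <- data.frame(
      variant_id = w$variant_id, mechanism = "PAS",
      motif_id = paste(union(altHit, refHit), collapse = ","),
      status = status,
      detail = sprintf("ref=%s;alt=%s;site=%s;dist=%d",
                       paste(refHit, collapse = "|"),
                       paste(altHit, collapse = "|"), ids[nearest], dist),
      stringsAsFactors = FALSE)
  }
  if (!length(calls)) return(.emptyCalls())
  do.call(rbind, calls)
}

.emptyCalls <- function() data.frame(
  variant_id = character(), mechanism = character(), motif_id = character(),
  status = character(), detail = character(), stringsAsFactors = FALSE)

# Best microRNA site class at an 8-nt target window overlapping `offset`.
# The seed string holds miRNA positions 2-8; a site anchored at a spans
# a..a+7: 8mer = match to the full seed plus A opposite position 1,
# 7mer-m8 = seed match without the A, 7mer-A1 = match to positions 2-7 plus
# the A.  Anchoring classes at the same window lets a variant at the
# m8-match or A1 position register as a class transition rather than a
# creation/loss.  Returns 3/2/1/0 for 8mer/7mer-m8/7mer-A1/none.
.bestSiteClass <- function(seq, seed, offset) {
  m8 <- .revcomp(seed)                 # 7-nt match to seed positions 2-8
  a1 <- .revcomp(substr(seed, 1, 6))   # 6-nt match to seed positions 2-7
  n <- nchar(seq)
  best <- 0L
  for (a in seq.int(max(1L, offset - 7L), offset)) {
    hasA <- a + 7L <= n && substr(seq, a + 7L, a + 7L) == "A"
    cls <- if (a + 6L <= n && substr(seq, a, a + 6L) == m8) {
      if (hasA) 3L else 2L
    } else if (a + 6L <= n && substr(seq, a + 1L, a + 6L) == a1 && hasA) {
      1L
    } else 0L
    best <- max(best, cls)
  }
  best
}

#' MicroRNA binding-site alteration
#'
#' Candidates are SNPs inside the POST segment (sites there selectively
#' degrade the long isoform).  For each expressed, conserved microRNA
#' family, putative sites overlapping the variant are classified as 8mer,
#' 7mer-m8 or 7mer-A1 (6-mers excluded); a variant alters a site when a site
#' exists in exactly one allele or the class differs, with direction by the
#' hierarchy 8mer > 7mer-m8 > 7mer-A1.
#'
#' @param windows data.frame from [alleleWindows()]
#' @param families data.frame with `family_id`, `seed` (7-mer, positions
#'   2-8, DNA or RNA alphabet), `conserved` (logical), `expressed` (logical)
#' @param segments an [ApaSegments-class]
#' @return data.frame of alteration calls (`status` in created / destroyed /
#'   strengthened / weakened)
#' @export
mirnaSiteAlteration <- function(windows, families, segments) {
  families <- families[families$conserved & families$expressed, , drop = FALSE]
  families$seed <- toupper(chartr("Uu", "Tt", families$seed))
  stopifnot(all(nchar(families$seed) == 7L))
  post <- postRanges(segments)
  classes <- c("7mer-A1", "7mer-m8", "8mer")
  calls <- list()
  for (k in seq_len(nrow(windows))) {
    w <- windows[k, ]
    if (!w$gene_id %in% names(post)) next
    pr <- post[w$gene_id]
    inPost <- w$pos0 >= start(pr) - 1L & w$pos0 < end(pr)
    if (!inPost) next
    for (f in seq_len(nrow(families))) {
      rb <- .bestSiteClass(w$ref_seq, families$seed[f], w$var_offset)
      ab <- .bestSiteClass(w$alt_seq, families$seed[f], w$var_offset)
      if (rb == ab) next
      status <- if (rb == 0L) "created"
                else if (ab == 0L) "destroyed"
                else if (ab > rb) "strengthened" else "weakened"
      calls[[length(calls) + 1L]] <- data.frame(
        variant_id = w$variant_id, mechanism = "miRNA",
        motif_id = families$family_id[f], status = status,
        detail = sprintf("ref=%s;alt=%s",
                         ifelse(rb > 0, classes[rb], "none"),
                         ifelse(ab > 0, classes[ab], "none")),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(calls)) return(.emptyCalls())
  do.call(rbind, calls)
}

#' Log-odds PWM scan of a sequence
#'
#' Best sum of per-position log2(matrix probability / background) over all
#' offsets on the sense strand, plus the motif's perfect-match score (the
#' same sum using the per-column maxima).
#'
#' @param seq character sequence (DNA alphabet)
#' @param motif a PWM as returned by [readPwms()]: list with `matrix` (4 x L,
#'   rows A/C/G/T, columns summing to 1) and `background` (named nucleotide
#'   frequencies)
#' @param offsets optional subset of 1-based offsets to scan (default all)
#' @return list: `best`, `perfect`, `bestOffset`
#' @export
pwmScan <- function(seq, motif, offsets = NULL) {
  mat <- motif$matrix; bg <- motif$background
  if (any(bg <= 0)) stop("zero background frequency")
  L <- ncol(mat)
  if (nchar(seq) < L) stop("sequence shorter than motif")
  lods <- log2(mat / bg[rownames(mat)])
  if (is.null(offsets)) offsets <- seq_len(nchar(seq) - L + 1L)
  ch <- strsplit(seq, "")[[1]]
  scores <- vapply(offsets, function(q) {
    b <- match(ch[q:(q + L - 1L)], rownames(mat))
    if (anyNA(b)) return(-Inf)
    sum(lods[cbind(b, seq_len(L))])
  }, numeric(1))
  list(best = max(scores), perfect = sum(apply(lods, 2, max)),
       bestOffset = offsets[which.max(scores)])
}

#' RBP motif alteration between alleles
#'
#' A motif (an RNA-binding-protein binding specificity) is altered by a SNP
#' when its best score over occurrences overlapping the variant exceeds
#' `thresholdFrac` of the perfect-match score in exactly one of the two
#' alleles (strictly): `created` if ALT only, `destroyed` if REF only.
#'
#' @param windows data.frame from [alleleWindows()]
#' @param motif a PWM from [readPwms()]; skipped unless `expressed`
#' @param thresholdFrac fraction of the perfect score (default 0.8)
#' @return data.frame of alteration calls
#' @export
rbpMotifAlteration <- function(windows, motif, thresholdFrac = 0.8) {
  if (!isTRUE(motif$expressed)) return(.emptyCalls())
  L <- ncol(motif$matrix)
  calls <- list()
  for (k in seq_len(nrow(windows))) {
    w <- windows[k, ]
    loQ <- max(1L, w$var_offset - L + 1L)
    hiQ <- min(w$var_offset, nchar(w$ref_seq) - L + 1L)
    if (hiQ < loQ) next
    offs <- seq.int(loQ, hiQ)
    rr <- pwmScan(w$ref_seq, motif, offsets = offs)
    aa <- pwmScan(w$alt_seq, motif, offsets = offs)
    refHit <- rr$best > thresholdFrac * rr$perfect
    altHit <- aa$best > thresholdFrac * aa$perfect
    if (refHit == altHit) next
    calls[[length(calls) + 1L]] <- data.frame(
      variant_id = w$variant_id, mechanism = "RBP",
      motif_id = motif$motif_id,
      status = if (altHit) "created" else "destroyed",
      detail = sprintf("ref_ratio=%.3f;alt_ratio=%.3f",
                       rr$best / rr$perfect, aa$best / aa$perfect),
      stringsAsFactors = FALSE)
  }
  if (!length(calls)) return(.emptyCalls())
  do.call(rbind, calls)
}

#' Expression filter for motif resources
#'
#' A feature (microRNA, RBP) counts as expressed when its expression value
#' is > 0 in at least `minFrac` of the samples; a family is expressed when
#' at least one member is.
#'
#' @param expr numeric matrix, features x samples
#' @param minFrac minimum fraction of samples (default 0.5, inclusive)
#' @return named logical vector per feature
#' @export
expressionFilter <- function(expr, minFrac = 0.5) {
  stopifnot(nrow(expr) > 0)
  rowMeans(expr > 0) >= minFrac
}

#' @rdname expressionFilter
#' @param memberExpressed named logical vector per member feature
#' @param membership data.frame with `member`, `family`
#' @return named logical vector per family (OR over members)
#' @export
familyExpressed <- function(memberExpressed, membership) {
  tapply(memberExpressed[membership$member], membership$family, any)
}

#' Read a PAS hexamer list
#'
#' One motif per line (or a TSV whose first column is the motif); RNA
#' alphabet is mapped to DNA.
#'
#' @param path input file
#' @return character vector of unique 6-mers
#' @export
readPasMotifs <- function(path) {
  x <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)[[1]]
  x <- toupper(chartr("Uu", "Tt", x))
  if (any(nchar(x) != 6)) stop("PAS motifs must be hexamers")
  unique(x)
}

#' Bundled polyadenylation-signal hexamer catalog
#'
#' The two canonical signals (AATAAA, ATTAAA) plus the known alternative
#' hexamers from the high-confidence PAS atlases, 18 motifs in total.
#'
#' @return character vector of hexamers (DNA alphabet)
#' @export
pasMotifSet <- function() {
  readPasMotifs(system.file("extdata", "pas_motifs.txt", package = "apaqtl"))
}

#' Read microRNA seed families (TargetScan-style TSV)
#'
#' @param path TSV with columns `family_id`, `seed`, `conservation`
#'   (values containing "conserved" are treated as conserved)
#' @param expressed optional named logical vector per family
#' @return data.frame with `family_id`, `seed`, `conserved`, `expressed`
#' @export
readMirnaSeeds <- function(path, expressed = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stopifnot(all(c("family_id", "seed", "conservation") %in% names(df)))
  df$seed <- toupper(chartr("Uu", "Tt", df$seed))
  df$conserved <- grepl("conserved", df$conservation, ignore.case = TRUE)
  df$expressed <- if (is.null(expressed)) TRUE else
    unname(expressed[df$family_id])
  df
}

#' Read position weight matrices
#'
#' Accepts a simple column-probability text format (`>motif_id rbp_id`
#' header, then one line per motif position with A C G U/T probabilities)
#' or a MEME-like dialect (`MOTIF` + `letter-probability matrix` blocks).
#' Backgrounds are floored at 1e-6.
#'
#' @param path input file
#' @param background named nucleotide frequencies (default uniform)
#' @param expressed optional named logical vector per motif id
#' @return list of PWMs: each a list with `motif_id`, `rbp_id`, `matrix`,
#'   `background`, `expressed`
#' @export
readPwms <- function(path, background = c(A = .25, C = .25, G = .25, T = .25),
                     expressed = NULL) {
  background <- pmax(background, 1e-6)
  lines <- readLines(path)
  out <- list()
  if (any(grepl("^MEME version", lines))) {
    heads <- grep("^MOTIF", lines)
    for (h in heads) {
      toks <- strsplit(trimws(lines[h]), "\\s+")[[1]]
      id <- toks[2]; rbp <- if (length(toks) > 2) toks[3] else id
      s <- h + 1L
      while (s <= length(lines) && !grepl("letter-probability", lines[s]))
        s <- s + 1L
      rows <- list()
      i <- s + 1L
      while (i <= length(lines) && grepl("^\\s*[0-9.eE+-]", lines[i])) {
        rows[[length(rows) + 1L]] <-
          as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]])
        i <- i + 1L
      }
      mat <- t(do.call(rbind, rows))
      rownames(mat) <- c("A", "C", "G", "T")
      out[[id]] <- list(motif_id = id, rbp_id = rbp, matrix = mat,
                        background = background,
                        expressed = is.null(expressed) ||
                          isTRUE(expressed[id]))
    }
  } else {
    heads <- grep("^>", lines)
    bounds <- c(heads, length(lines) + 1L)
    for (j in seq_along(heads)) {
      toks <- strsplit(sub("^>", "", lines[heads[j]]), "\\s+")[[1]]
      id <- toks[1]; rbp <- if (length(toks) > 1) toks[2] else id
      body <- lines[(heads[j] + 1L):(bounds[j + 1L] - 1L)]
      body <- body[nzchar(trimws(body))]
      mat <- t(vapply(body, function(l)
        as.numeric(strsplit(trimws(l), "\\s+")[[1]]), numeric(4)))
      mat <- t(mat)
      rownames(mat) <- c("A", "C", "G", "T")
      out[[id]] <- list(motif_id = id, rbp_id = rbp, matrix = mat,
                        background = background,
                        expressed = is.null(expressed) ||
                          isTRUE(expressed[id]))
    }
  }
  bad <- vapply(out, function(m)
    any(abs(colSums(m$matrix) - 1) > 1e-6), logical(1))
  if (any(bad))
    stop("PWM columns must sum to 1: ", paste(names(out)[bad], collapse = ", "))
  out
}
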