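#' @importFrom stats rbinom rnorm rpois runif rlnorm median
#' @importFrom Biostrings writeXStringSet
NULL

#' Configuration for the synthetic apaQTL study generator
#'
#' Defaults describe the emulated study: a cohort of 373 individuals (the
#' size of the European RNA-seq + WGS cohort the method was designed for),
#' 50 common variants per gene cis window with haplotype-block LD, a uniform
#' MAF spectrum on [0.05, 0.5], log2 isoform-ratio noise of sd 0.5 around an
#' additive genotype effect, and Poisson segment counts at a depth giving
#' tens of reads per segment.
#'
#' @param seed mandatory RNG seed
#' @param nIndividuals cohort size
#' @param nGenes number of genes
#' @param nVariantsPerGene variants simulated in each gene's cis window
#' @param mafRange target minor-allele-frequency range
#' @param ldBlockSize variants per haplotype block
#' @param ldRho haplotype-copying probability within a block (controls r²)
#' @param causalFraction fraction of genes with a genetic effect
#' @param beta1 effect size on log2(m/M) per alternative allele
#' @param causalMaf optional fixed MAF for causal variants
#' @param noiseSd residual sd of the latent log2 isoform ratio
#' @param baselineLog2 baseline log2(m/M)
#' @param mLevel mean long-isoform abundance (arbitrary expression units)
#' @param mLevelCv lognormal coefficient of variation of the abundance
#' @param readDepth expected reads per bp per abundance unit
#' @param poisson draw Poisson counts (FALSE = noiseless expected counts)
#' @param nSubpop number of subpopulations (1 = unstructured)
#' @param divergence allele-frequency divergence between subpopulations
#' @param subpopShift phenotype shift of the second subpopulation (log2)
#' @param imputedFraction fraction of individuals flagged as imputed
#' @param lPreRange,lPostRange PRE/POST segment length ranges (bp)
#' @param geneSpacing bp between gene starts (keeps cis windows disjoint)
#' @param variantSpan bp around the gene within which its variants lie
#' @param indelFraction,svFraction fractions of non-SNP variants (exercise
#'   exclusion rules)
#' @return validated config list of class `apaSimConfig`
#' @export
simConfig <- function(seed, nIndividuals = 373L, nGenes = 200L,
                      nVariantsPerGene = 50L, mafRange = c(0.05, 0.5),
                      ldBlockSize = 10L, ldRho = 0.9,
                      causalFraction = 0, beta1 = 0, causalMaf = NULL,
                      noiseSd = 0.5, baselineLog2 = 0,
                      mLevel = 1, mLevelCv = 0.2, readDepth = 0.05,
                      poisson = TRUE, nSubpop = 1L, divergence = 0.1,
                      subpopShift = 0, imputedFraction = 0,
                      lPreRange = c(300, 1500), lPostRange = c(500, 2500),
                      geneSpacing = 2.2e6, variantSpan = 2e5,
                      indelFraction = 0, svFraction = 0) {
  if (missing(seed)) stop("seed is mandatory")
  cfg <- as.list(environment())
  stopifnot(cfg$nIndividuals > 2, cfg$nGenes > 0,
            all(cfg$mafRange > 0 & cfg$mafRange <= 0.5),
            cfg$causalFraction >= 0, cfg$causalFraction <= 1,
            cfg$ldRho >= 0, cfg$ldRho <= 1, cfg$noiseSd >= 0,
            cfg$nSubpop >= 1, cfg$indelFraction + cfg$svFraction < 1)
  class(cfg) <- "apaSimConfig"
  cfg
}

# haplotype-copying LD blocks: within a block, each variant copies the
# previous variant's allele with probability rho, else redraws Bernoulli(p)
.simHaplotypes <- function(nHap, p, blockId, rho) {
  H <- matrix(0L, length(p), nHap)
  for (i in seq_along(p)) {
    if (i == 1L || blockId[i] != blockId[i - 1L]) {
      H[i, ] <- rbinom(nHap, 1L, p[i])
    } else {
      copy <- runif(nHap) < rho
      H[i, ] <- ifelse(copy, H[i - 1L, ], rbinom(nHap, 1L, p[i]))
    }
  }
  H
}

#' Simulate genotypes with blockwise LD and a MAF spectrum
#'
#' Biallelic variants with per-block target allele frequencies drawn from
#' `mafRange`, haplotype-copying LD within blocks of `ldBlockSize`
#' consecutive variants, optional divergent subpopulations (Hardy-Weinberg
#' sampling within each), and optional indel/SV records to exercise
#' exclusion rules.  Does not touch the global RNG state unless `seed` is
#' given.
#'
#' @param cfg an `apaSimConfig` (or arguments via `...` to [simConfig()])
#' @param positions `GRanges` of variant positions (width 1); defaults to
#'   evenly spaced positions on `chr1`
#' @param ids variant ids (default `v1..vn`)
#' @param n number of variants when `positions` is NULL
#' @param seed optional seed (set by the caller otherwise)
#' @return list: `geno` ([GenotypeMatrix-class]), `subpop` (factor per
#'   individual), `targetMaf` (per variant)
#' @export
simulateGenotypes <- function(cfg, n = 100L, positions = NULL, ids = NULL,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(positions))
    positions <- GRanges("chr1", IRanges(seq_len(n) * 1000L, width = 1L))
  n <- length(positions)
  if (is.null(ids)) ids <- paste0("v", seq_len(n))
  nInd <- cfg$nIndividuals
  blockId <- ceiling(seq_len(n) / cfg$ldBlockSize)
  pBlock <- runif(max(blockId), cfg$mafRange[1], cfg$mafRange[2])
  p <- pBlock[blockId]
  subpop <- factor(rep_len(seq_len(cfg$nSubpop), nInd))
  H <- matrix(0L, n, 2L * nInd)
  hapSub <- rep(as.integer(subpop), each = 2L)
  for (s in seq_len(cfg$nSubpop)) {
    delta <- if (cfg$nSubpop == 1L) 0 else
      (s - (cfg$nSubpop + 1) / 2) / (cfg$nSubpop - 1) * 2 * cfg$divergence
    ps <- pmin(pmax(p + delta, 0.01), 0.99)
    cols <- hapSub == s
    H[, cols] <- .simHaplotypes(sum(cols), ps, blockId, cfg$ldRho)
  }
  d <- H[, seq(1, 2 * nInd, 2), drop = FALSE] +
       H[, seq(2, 2 * nInd, 2), drop = FALSE]
  storage.mode(d) <- "integer"
  colnames(d) <- paste0("ind", seq_len(nInd))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
  vclass <- sample(c("SNP", "indel", "SV"), n, replace = TRUE,
                   prob = c(1 - cfg$indelFraction - cfg$svFraction,
                            cfg$indelFraction, cfg$svFraction))
  ref[vclass == "indel"] <- paste0(ref[vclass == "indel"], "A")
  alt[vclass == "SV"] <- "<DEL>"
  gr <- positions
  mcols(gr) <- DataFrame(id = ids, ref = ref, alt = alt, vclass = vclass)
  list(geno = new("GenotypeMatrix", ranges = gr, dosages = d),
       subpop = subpop, targetMaf = pmin(p, 1 - p))
}

#' Simulate a complete apaQTL study
#'
#' Generates, under one seed, a cohort with genotypes (blockwise LD, one
#' window of variants per gene on a shared synthetic chromosome), PRE/POST
#' segment annotations, segment read counts whose latent log2 isoform ratio
#' is `baseline + beta1 * dosage (+ subpopulation shift) + noise`, the
#' resulting m/M matrix, cis windows and the truth table.  Presets:
#'
#' * `null` — no genetic effect anywhere (calibration runs);
#' * `powered` — every gene causal with beta1 = 0.5, causal MAF 0.3,
#'   noise sd 0.5, 100 genes (parameter-recovery runs);
#' * `structured` — two subpopulations with divergent allele frequencies and
#'   a phenotype shift (confounding studies).
#'
#' @param preset `"null"`, `"powered"`, `"structured"`, or `"custom"`
#' @param seed RNG seed
#' @param ... overrides passed to [simConfig()]
#' @return list: `cfg`, `geno` ([GenotypeMatrix-class]), `segments`
#'   ([ApaSegments-class]), `models` ([GeneModelSet-class]), `counts`
#'   (long data.frame), `mm` ([MMatrix-class]), `windows` (`GRanges`),
#'   `covariates`, `subpop`, `truth` (per gene: causal variant, true beta1)
#' @export
simulateApaStudy <- function(preset = c("custom", "null", "powered",
                                        "structured"),
                             seed, ...) {
  preset <- match.arg(preset)
  over <- list(...)
  base <- switch(preset,
    null = list(nGenes = 200L, causalFraction = 0, beta1 = 0),
    powered = list(nGenes = 100L, causalFraction = 1, beta1 = 0.5,
                   causalMaf = 0.3),
    structured = list(nGenes = 50L, nSubpop = 2L, divergence = 0.15,
                      subpopShift = 0.5),
    custom = list())
  args <- utils::modifyList(base, over)
  cfg <- do.call(simConfig, c(list(seed = seed), args))
  set.seed(cfg$seed)
  nG <- cfg$nGenes; nV <- cfg$nVariantsPerGene; nInd <- cfg$nIndividuals
  # gene geometry on one synthetic chromosome, cis windows pairwise disjoint
  lPre <- round(runif(nG, cfg$lPreRange[1], cfg$lPreRange[2]))
  lPost <- round(runif(nG, cfg$lPostRange[1], cfg$lPostRange[2]))
  gStart0 <- (seq_len(nG) - 1L) * cfg$geneSpacing + 1e6
  gEnd0 <- gStart0 + lPre + lPost
  strand <- sample(c("+", "-"), nG, replace = TRUE)
  gids <- sprintf("gene%03d", seq_len(nG))
  genes <- GRanges("chr1", IRanges(gStart0 + 1, gEnd0), strand = strand)
  mcols(genes) <- DataFrame(gene_id = gids, cds_start = NA_real_,
                            cds_end = NA_real_)
  models <- new("GeneModelSet", genes = genes,
                exons = GRangesList(lapply(seq_len(nG), function(i)
                  granges(genes[i]))),
                excluded = data.frame(gene_id = character(),
                                      reason = character()))
  segs <- vector("list", nG)
  for (i in seq_len(nG)) {
    neg <- strand[i] == "-"
    sp <- if (neg) gStart0[i] + lPost[i] else gStart0[i] + lPre[i]
    pre <- if (neg) c(sp, gEnd0[i]) else c(gStart0[i], sp)
    post <- if (neg) c(gStart0[i], sp) else c(sp, gEnd0[i])
    two <- GRanges("chr1", IRanges(c(pre[1], post[1]) + 1,
                                   c(pre[2], post[2])), strand = strand[i])
    mcols(two) <- DataFrame(gene_id = gids[i], segment = c("PRE", "POST"),
                            proximal_site_id = paste0("pas_", gids[i]),
                            distal_site_id = "gene_end")
    segs[[i]] <- two
  }
  segments <- new("ApaSegments", segments = unlist(GRangesList(segs)))
  # variants: one block-LD window per gene
  vpos <- unlist(lapply(seq_len(nG), function(i)
    sort(sample.int(cfg$variantSpan, nV)) + gStart0[i] - cfg$variantSpan / 2))
  positions <- GRanges("chr1", IRanges(round(vpos), width = 1L))
  ids <- paste0("v", seq_len(nG * nV))
  sg <- simulateGenotypes(cfg, positions = positions, ids = ids)
  geno <- sg$geno
  subpop <- sg$subpop
  # plant causal effects
  causal <- runif(nG) < cfg$causalFraction
  causalVar <- rep(NA_character_, nG)
  beta <- ifelse(causal, cfg$beta1, 0)
  d <- dosages(geno)
  for (i in which(causal)) {
    j <- (i - 1L) * nV + sample.int(nV, 1L)
    if (!is.null(cfg$causalMaf)) {
      # redraw the causal variant's genotypes at the requested MAF,
      # independent of the LD blocks
      d[j, ] <- rbinom(nInd, 2L, cfg$causalMaf)
    }
    causalVar[i] <- ids[j]
  }
  geno@dosages <- d
  # phenotype and counts
  shift <- if (cfg$nSubpop > 1L)
    cfg$subpopShift * (as.integer(subpop) - 1L) else rep(0, nInd)
  counts <- vector("list", nG)
  for (i in seq_len(nG)) {
    g <- if (is.na(causalVar[i])) rep(0, nInd) else
      d[match(causalVar[i], ids), ]
    latent <- cfg$baselineLog2 + beta[i] * g + shift +
      rnorm(nInd, 0, cfg$noiseSd)
    ratio <- 2^latent
    M <- cfg$mLevel * rlnorm(nInd, -cfg$mLevelCv^2 / 2, cfg$mLevelCv)
    ePost <- cfg$readDepth * lPost[i] * M
    ePre <- cfg$readDepth * lPre[i] * (ratio * M + M)
    rPre <- if (cfg$poisson) rpois(nInd, ePre) else ePre
    rPost <- if (cfg$poisson) rpois(nInd, ePost) else ePost
    counts[[i]] <- data.frame(gene_id = gids[i],
                              sample_id = colnames(d),
                              r_pre = rPre, r_post = rPost,
                              stringsAsFactors = FALSE)
  }
  counts <- do.call(rbind, counts)
  mm <- computeMM(counts, segments)
  mm <- new("MMatrix", values = mmValues(mm)[gids, colnames(d)],
            mask = mmMask(mm)[gids, colnames(d)])
  windows <- cisWindows(models)
  imputed <- if (cfg$imputedFraction > 0)
    rbinom(nInd, 1L, cfg$imputedFraction) else NULL
  covariates <- covariateMatrix(imputed = imputed)
  truth <- data.frame(gene_id = gids, causal_variant = causalVar,
                      true_beta1 = beta, stringsAsFactors = FALSE)
  list(cfg = cfg, geno = geno, segments = segments, models = models,
       counts = counts, mm = mm, windows = windows,
       covariates = covariates, subpop = subpop, truth = truth)
}

#' Simulate annotation inputs: genome, transcripts, poly(A) catalog
#'
#' Small random-sequence chromosomes carrying multi-exon genes on both
#' strands whose terminal exons contain a proximal poly(A) site in the 3'
#' UTR plus the gene-end distal site, guaranteed to pass
#' [defineApaSegments()].  Deterministic given the seed.
#'
#' @param cfg an `apaSimConfig`; genes are packed `nGenes` per chromosome
#' @param chromLength chromosome length in bp (default 1e6)
#' @param genesPerChrom genes per chromosome (default 10)
#' @return list: `genome` (DNAStringSet), `transcripts` (exon table for
#'   [collapseGeneModels()]), `geneMap`, `sites` (poly(A) `GRanges`),
#'   `models`, `segments`
#' @export
simulateAnnotation <- function(cfg, chromLength = 1e6, genesPerChrom = 10L) {
  set.seed(cfg$seed)
  nG <- cfg$nGenes
  nChrom <- ceiling(nG / genesPerChrom)
  slot <- floor(chromLength / genesPerChrom)
  geneWidth <- 8000L
  if (slot < geneWidth + 2000L)
    stop("infeasible packing: too many genes for the chromosome length")
  genome <- DNAStringSet(vapply(seq_len(nChrom), function(i)
    paste(sample(c("A", "C", "G", "T"), chromLength, replace = TRUE),
          collapse = ""), character(1)))
  names(genome) <- paste0("chr", seq_len(nChrom))
  tx <- list(); sites <- list()
  for (i in seq_len(nG)) {
    chrom <- paste0("chr", (i - 1L) %/% genesPerChrom + 1L)
    g0 <- ((i - 1L) %% genesPerChrom) * slot + 1000L
    neg <- runif(1) < 0.5
    gid <- sprintf("g%03d", i); tid <- paste0(gid, ".t1")
    # + orientation template: exon1 500, intron 1000, exon2 500, intron
    # 1000, terminal exon 3000; CDS from exon1+100 to terminal+500;
    # proximal poly(A) site 1200 bp into the terminal-exon 3' UTR
    ex <- rbind(c(0, 500), c(1500, 2000), c(3000, 6000))
    cds <- c(100, 3500)
    pas <- 4700
    if (neg) {            # mirror within the gene span
      W <- 6000
      ex <- cbind(W - ex[, 2], W - ex[, 1])[3:1, , drop = FALSE]
      cds <- c(W - cds[2], W - cds[1])
      pas <- W - pas
    }
    tx[[i]] <- data.frame(transcript_id = tid, chrom = chrom,
                          strand = ifelse(neg, "-", "+"),
                          start = g0 + ex[, 1], end = g0 + ex[, 2],
                          cds_start = g0 + cds[1], cds_end = g0 + cds[2],
                          gene_id = gid, stringsAsFactors = FALSE)
    sites[[i]] <- GRanges(chrom, IRanges(g0 + pas + 1L, width = 1L),
                          strand = ifelse(neg, "-", "+"),
                          site_id = paste0("pas_", gid))
  }
  tx <- do.call(rbind, tx)
  sites <- unlist(GRangesList(sites))
  geneMap <- unique(tx[, c("transcript_id", "gene_id")])
  models <- collapseGeneModels(tx[, setdiff(names(tx), "gene_id")], geneMap)
  segs <- defineApaSegments(models, sites)
  list(genome = genome, transcripts = tx[, setdiff(names(tx), "gene_id")],
       geneMap = geneMap, sites = sites, models = models,
       segments = segs$segments)
}

#' Simulate enrichment candidates with a planted odds ratio
#'
#' Candidate variants with apaQTL/null status and a binary feature whose
#' status-conditional frequencies realise the requested odds ratio; the MAF
#' covariate is drawn independently.
#'
#' @param n number of candidates
#' @param orTrue planted odds ratio
#' @param pApaqtl probability of apaQTL status (default 0.3)
#' @param pFeatureNull feature frequency among null variants (default 0.2)
#' @return data.frame: `status`, `feature`, `maf`
#' @export
simulateEnrichmentCandidates <- function(n = 5000L, orTrue = 1,
                                         pApaqtl = 0.3,
                                         pFeatureNull = 0.2) {
  status <- rbinom(n, 1L, pApaqtl)
  odds1 <- orTrue * pFeatureNull / (1 - pFeatureNull)
  p1 <- odds1 / (1 + odds1)
  feature <- rbinom(n, 1L, ifelse(status == 1L, p1, pFeatureNull))
  data.frame(status = status, feature = feature,
             maf = runif(n, 0.05, 0.5))
}

#' Simulate feature tracks with planted enrichment
#'
#' Assigns a binary feature over classified variants so that
#' Pr(feature | apaQTL) / Pr(feature | null) realises the planted odds
#' ratio, and materialises it as a chromatin-state-like BED track (feature
#' variants covered by `StateA` intervals, all others by `StateB`, so every
#' variant is state-annotated).
#'
#' @param calls data.frame from [classifyVariants()]
#' @param geno a [GenotypeMatrix-class]
#' @param orTrue planted odds ratio
#' @param pFeatureNull feature frequency among null variants
#' @return list: `featureById` (named logical), `states` (`GRanges` with
#'   `name`)
#' @export
simulateFeatureTracks <- function(calls, geno, orTrue = 3,
                                  pFeatureNull = 0.2) {
  odds1 <- orTrue * pFeatureNull / (1 - pFeatureNull)
  p1 <- odds1 / (1 + odds1)
  pr <- ifelse(calls$class == "apaQTL", p1,
               ifelse(calls$class == "null", pFeatureNull, 0))
  feat <- stats::setNames(rbinom(nrow(calls), 1L, pr) == 1L,
                          calls$variant_id)
  vr <- variantRanges(geno)
  ix <- match(names(feat), variantIds(geno))
  mk <- function(sel, nm) {
    if (!any(sel)) return(GRanges())
    g <- GRanges(seqnames(vr)[ix[sel]],
                 IRanges(pmax(1L, start(vr)[ix[sel]] - 2L),
                         start(vr)[ix[sel]] + 2L))
    g$name <- nm
    g
  }
  states <- c(mk(feat, "StateA"), mk(!feat, "StateB"))
  list(featureById = feat, states = states)
}

## ---- plain-text writers for simulated data -------------------------------

#' Write a GenotypeMatrix as a minimal VCF
#'
#' GT-only VCF 4.2 with unphased genotypes, readable by standard VCF
#' parsers and by [readVcfGenotypes()].
#'
#' @param geno a [GenotypeMatrix-class]
#' @param path output file
#' @export
writeSimVcf <- function(geno, path) {
  vr <- variantRanges(geno)
  m <- mcols(vr)
  d <- dosages(geno)
  gtmap <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow(d), ncol(d))
  gt[!is.na(d)] <- gtmap[d[!is.na(d)] + 1L]
  chroms <- unique(as.character(seqnames(vr)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=apaqtl-simulator",
               paste0("##contig=<ID=", chroms, ">"),
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", colnames(d)),
                     collapse = "\t")), con)
  alt <- ifelse(m$vclass == "SV", "<DEL>", m$alt)
  body <- paste(as.character(seqnames(vr)), start(vr), m$id, m$ref, alt,
                ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(body, con)
  invisible(path)
}

#' Write simulated transcripts as GTF
#'
#' `exon` and `CDS` features per transcript, consumable by
#' [readTranscriptsGtf()].
#'
#' @param transcripts exon table in the [collapseGeneModels()] layout
#' @param geneMap transcript-to-gene map
#' @param path output file
#' @export
writeTranscriptsGtf <- function(transcripts, geneMap, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 2", con)
  gid <- geneMap$gene_id[match(transcripts$transcript_id,
                               geneMap$transcript_id)]
  at <- sprintf('gene_id "%s"; transcript_id "%s";', gid,
                transcripts$transcript_id)
  writeLines(paste(transcripts$chrom, "sim", "exon",
                   transcripts$start + 1L, transcripts$end, ".",
                   transcripts$strand, ".", at, sep = "\t"), con)
  cds <- unique(transcripts[!is.na(transcripts$cds_start),
                            c("transcript_id", "chrom", "strand",
                              "cds_start", "cds_end")])
  if (nrow(cds)) {
    gidc <- geneMap$gene_id[match(cds$transcript_id, geneMap$transcript_id)]
    atc <- sprintf('gene_id "%s"; transcript_id "%s";', gidc,
                   cds$transcript_id)
    writeLines(paste(cds$chrom, "sim", "CDS", cds$cds_start + 1L,
                     cds$cds_end, ".", cds$strand, ".", atc, sep = "\t"),
               con)
  }
  invisible(path)
}

#' Write a poly(A) site catalog as BED
#'
#' @param sites `GRanges` with `site_id`
#' @param path output file
#' @export
writePolyABed <- function(sites, path) {
  writeLines(paste(as.character(seqnames(sites)), start(sites) - 1L,
                   start(sites), mcols(sites)$site_id, 0,
                   as.character(strand(sites)), sep = "\t"), path)
  invisible(path)
}

#' Write a SAM file of reads placed within PRE/POST segments
#'
#' Places `r_pre` reads fully inside the PRE segment and `r_post` fully
#' inside the POST segment of each gene for one sample, so that
#' [countSegmentReads()] reproduces the count table exactly.
#'
#' @param counts one sample's counts (`gene_id`, `r_pre`, `r_post`)
#' @param segments an [ApaSegments-class]
#' @param path output SAM file
#' @param readLen read length (clipped to the segment length)
#' @param chromLengths named chromosome lengths for the header (defaults to
#'   segment extents + 1000)
#' @export
writeSegmentSam <- function(counts, segments, path, readLen = 50L,
                            chromLengths = NULL) {
  st <- segmentTable(segments)
  if (is.null(chromLengths)) {
    ends <- tapply(pmax(st$pre_end, st$post_end), st$chrom, max)
    chromLengths <- ends + 1000
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:coordinate",
               paste0("@SQ\tSN:", names(chromLengths),
                      "\tLN:", as.integer(chromLengths))), con)
  qn <- 0L
  recs <- list()
  for (i in seq_len(nrow(counts))) {
    s <- st[st$gene_id == counts$gene_id[i], ]
    if (!nrow(s)) next
    place <- function(n, a0, b0) {
      if (n <= 0) return(NULL)
      L <- min(readLen, b0 - a0)
      starts <- floor(runif(n, a0, b0 - L + 1e-9)) + 1L   # 1-based
      qn <<- qn + n
      paste(paste0("r", seq.int(qn - n + 1L, qn)), 0, s$chrom, starts, 60,
            paste0(L, "M"), "*", 0, 0, strrep("A", L), "*", sep = "\t")
    }
    recs[[length(recs) + 1L]] <- c(
      place(counts$r_pre[i], s$pre_start, s$pre_end),
      place(counts$r_post[i], s$post_start, s$post_end))
  }
  body <- unlist(recs)
  if (length(body)) {
    # coordinate-sort for direct BAM conversion
    pos <- as.integer(vapply(strsplit(body, "\t"), `[`, character(1), 4))
    chr <- vapply(strsplit(body, "\t"), `[`, character(1), 3)
    writeLines(body[order(chr, pos)], con)
  }
  invisible(path)
}

#' Write the genome of a simulated annotation as FASTA
#'
#' @param genome `DNAStringSet`
#' @param path output file
#' @export
writeSimFasta <- function(genome, path) {
  writeXStringSet(genome, path)
  invisible(path)
}
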