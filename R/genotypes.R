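#' @importFrom stats cor
NULL

#' Minor allele frequency under two missing-data conventions
#'
#' `conservative` imputes missing dosages with the cohort's most frequent
#' homozygous genotype before counting alleles, which can only push variants
#' below a MAF threshold (used for the mapping MAF filter); `observed` simply
#' ignores individuals with missing data (used as the enrichment covariate).
#'
#' @param x a [GenotypeMatrix-class], a dosage matrix (variants x samples) or
#'   a single dosage vector in 0/1/2 with `NA` for missing
#' @param mode `"conservative"` or `"observed"`
#' @return numeric vector of frequencies in `[0, 0.5]`
#' @export
variantMaf <- function(x, mode = c("conservative", "observed")) {
  mode <- match.arg(mode)
  d <- if (is(x, "GenotypeMatrix")) dosages(x) else x
  if (is.null(dim(d))) d <- matrix(d, nrow = 1)
  if (any(rowSums(!is.na(d)) == 0))
    stop("variant with all dosages missing")
  if (mode == "conservative") {
    n0 <- rowSums(d == 0, na.rm = TRUE)
    n2 <- rowSums(d == 2, na.rm = TRUE)
    fill <- ifelse(n2 > n0, 2, 0)   # tie goes to the reference homozygote
    miss <- is.na(d)
    d[miss] <- fill[row(d)[miss]]
    f <- rowSums(d) / (2 * ncol(d))
  } else {
    f <- rowSums(d, na.rm = TRUE) / (2 * rowSums(!is.na(d)))
  }
  unname(pmin(f, 1 - f))
}

#' Pairwise genotypic r-squared
#'
#' Squared Pearson correlation of 0/1/2 dosages over complete pairs.  A
#' zero-variance vector yields 0 with attribute `degenerate = TRUE`.
#'
#' @param v1,v2 dosage vectors
#' @return r² in `[0, 1]`
#' @export
genotypicR2 <- function(v1, v2) {
  ok <- !is.na(v1) & !is.na(v2)
  if (sum(ok) < 3L) stop("fewer than 3 complete pairs")
  if (stats::var(v1[ok]) == 0 || stats::var(v2[ok]) == 0)
    return(structure(0, degenerate = TRUE))
  unname(cor(v1[ok], v2[ok])^2)
}

# pairwise r2 matrix on dosage rows (complete pairs; 0 where degenerate)
.r2Matrix <- function(d) {
  r <- suppressWarnings(cor(t(d), use = "pairwise.complete.obs"))
  r[!is.finite(r)] <- 0
  r^2
}

#' Sliding-window LD pruning
#'
#' Recursively excludes variants with pairwise genotypic r² above `r2Max`
#' within sliding windows of `windowSnps` SNPs advanced by `stepSnps`,
#' mirroring the classic `--indep-pairwise` procedure.  When a pair exceeds
#' the threshold, the member with the lower observed MAF is removed (ties go
#' to the later genomic position).  Sweeps repeat until no further removal,
#' so no retained pair within any window exceeds `r2Max`.
#'
#' @param geno a [GenotypeMatrix-class]; variants must be ordered by
#'   chromosome and position
#' @param windowSnps window size in SNPs (default 50)
#' @param stepSnps window increment in SNPs (default 5)
#' @param r2Max strict r² threshold (default 0.8)
#' @return character vector of retained variant ids
#' @export
ldPrune <- function(geno, windowSnps = 50L, stepSnps = 5L, r2Max = 0.8) {
  ids <- variantIds(geno)
  d <- dosages(geno)
  chrom <- as.character(seqnames(variantRanges(geno)))
  pos <- start(variantRanges(geno))
  maf <- variantMaf(geno, mode = "observed")
  keep <- rep(TRUE, length(ids))
  for (ch in unique(chrom)) {
    ix <- which(chrom == ch)
    ix <- ix[order(pos[ix])]
    repeat {
      changed <- FALSE
      cur <- ix[keep[ix]]
      if (length(cur) < 2L) break
      starts <- seq(1L, length(cur), by = stepSnps)
      for (s in starts) {
        win <- cur[s:min(s + windowSnps - 1L, length(cur))]
        win <- win[keep[win]]
        if (length(win) < 2L) next
        r2 <- .r2Matrix(d[win, , drop = FALSE])
        for (i in seq_len(length(win) - 1L)) {
          if (!keep[win[i]]) next
          for (j in seq((i + 1L), length(win))) {
            if (!keep[win[j]]) next
            if (r2[i, j] > r2Max) {
              a <- win[i]; b <- win[j]
              drop <- if (maf[a] < maf[b]) a
                      else if (maf[b] < maf[a]) b
                      else if (pos[a] > pos[b]) a else b
              keep[drop] <- FALSE
              changed <- TRUE
            }
          }
        }
      }
      if (!changed) break
    }
  }
  ids[keep]
}

#' Tagging variants of an index variant
#'
#' All variants within `window` bp of the index variant on the same
#' chromosome with genotypic r² strictly above `r2Min`, excluding the index
#' variant itself.
#'
#' @param variantId index variant id
#' @param geno a [GenotypeMatrix-class]
#' @param r2Min strict r² threshold (default 0.8)
#' @param window search window in bp on each side (default 1e6)
#' @return character vector of tagging variant ids
#' @export
taggingSet <- function(variantId, geno, r2Min = 0.8, window = 1e6) {
  ids <- variantIds(geno)
  k <- match(variantId, ids)
  if (is.na(k)) stop("variant ", variantId, " not in table")
  gr <- variantRanges(geno)
  near <- which(as.character(seqnames(gr)) ==
                  as.character(seqnames(gr))[k] &
                abs(start(gr) - start(gr)[k]) <= window)
  near <- setdiff(near, k)
  if (!length(near)) return(character(0))
  d <- dosages(geno)
  r2 <- vapply(near, function(i) {
    ok <- !is.na(d[k, ]) & !is.na(d[i, ])
    if (sum(ok) < 3L || stats::var(d[k, ok]) == 0 ||
        stats::var(d[i, ok]) == 0) return(0)
    cor(d[k, ok], d[i, ok])^2
  }, numeric(1))
  ids[near[r2 > r2Min]]
}

# feature status propagated through tagging variants: TRUE if the variant
# itself or any tagging partner (r2 > r2Min within window) has the feature
.selfOrTagFeature <- function(candidateIds, geno, featureById,
                              r2Min = 0.8, window = 1e6) {
  vapply(candidateIds, function(v) {
    if (isTRUE(featureById[v])) return(TRUE)
    tags <- taggingSet(v, geno, r2Min = r2Min, window = window)
    any(featureById[tags], na.rm = TRUE)
  }, logical(1))
}

#' Principal components of genotypic data
#'
#' Removes variants inside long-range LD regions, applies sliding-window LD
#' pruning, mean-imputes missing dosages, centres each variant column and
#' scales it by `sqrt(p(1-p))` (p = observed alternative-allele frequency),
#' and returns the top eigenvectors of the individual x individual
#' covariance.  The sign of each component is fixed so that its
#' largest-magnitude loading is positive.
#'
#' @param geno a [GenotypeMatrix-class]
#' @param lrld optional `GRanges` of long-range LD regions to exclude (see
#'   [lrldRegions()])
#' @param prune apply [ldPrune()] first (default TRUE)
#' @param k number of components (default 3)
#' @param windowSnps,stepSnps,r2Max pruning parameters
#' @return list with `gpcs` (individuals x k matrix), `varexp` (fraction of
#'   variance per component) and `nVariantsUsed`
#' @export
genotypePCA <- function(geno, lrld = NULL, prune = TRUE, k = 3L,
                        windowSnps = 50L, stepSnps = 5L, r2Max = 0.8) {
  if (!is.null(lrld)) {
    hit <- IRanges::overlapsAny(variantRanges(geno), lrld,
                                ignore.strand = TRUE)
    geno <- geno[!hit]
  }
  if (prune) geno <- geno[ldPrune(geno, windowSnps, stepSnps, r2Max)]
  X <- t(dosages(geno)) * 1.0            # individuals x variants
  n <- nrow(X)
  if (n < k + 1L) stop("need at least k+1 individuals")
  mu <- colMeans(X, na.rm = TRUE)
  miss <- is.na(X)
  X[miss] <- mu[col(X)[miss]]
  p <- mu / 2
  ok <- p > 0 & p < 1
  if (sum(ok) < k) stop("fewer than k variants after filtering")
  X <- sweep(X[, ok, drop = FALSE], 2, mu[ok])
  X <- sweep(X, 2, sqrt(p[ok] * (1 - p[ok])), "/")
  C <- tcrossprod(X) / ncol(X)
  eg <- eigen(C, symmetric = TRUE)
  pos <- eg$values > max(eg$values) * 1e-10
  kk <- min(k, sum(pos))
  if (kk < k) warning("degenerate covariance: returning ", kk, " components")
  V <- eg$vectors[, seq_len(kk), drop = FALSE]
  for (j in seq_len(kk)) {
    m <- which.max(abs(V[, j]))
    if (V[m, j] < 0) V[, j] <- -V[, j]
  }
  rownames(V) <- sampleIds(geno)
  colnames(V) <- paste0("gPC", seq_len(kk))
  list(gpcs = V, varexp = eg$values[seq_len(kk)] / sum(pmax(eg$values, 0)),
       nVariantsUsed = ncol(X))
}

#' Bundled long-range LD regions (hg19)
#'
#' The 24 long-range LD intervals commonly excluded before genotype PCA,
#' after Price et al. (2008), as propagated in the PLINK/flashpca exclusion
#' lists for hg19.
#'
#' @param path optional BED file overriding the bundled one
#' @return `GRanges` of regions to exclude
#' @export
lrldRegions <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "lrld_hg19.bed", package = "apaqtl")
  rtracklayer::import(path, format = "BED")
}

#' Read genotypes from a VCF
#'
#' Biallelic records only (others are dropped with a warning); dosages are
#' the number of alternative alleles in the GT field, `NA` for missing.
#'
#' @param path VCF file (plain or bgzipped)
#' @param samples optional sample subset, in the required cohort order
#' @return a [GenotypeMatrix-class]
#' @export
readVcfGenotypes <- function(path, samples = NULL) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("VariantAnnotation is required to read VCF files")
  vcf <- VariantAnnotation::readVcf(path)
  alt <- VariantAnnotation::alt(vcf)
  bi <- lengths(alt) == 1L
  if (!all(bi)) {
    warning("dropping ", sum(!bi), " multi-allelic record(s)")
    vcf <- vcf[bi]
    alt <- alt[bi]
  }
  gt <- VariantAnnotation::geno(vcf)$GT
  if (!is.null(samples)) {
    if (!all(samples %in% colnames(gt)))
      stop("samples absent from VCF: ",
           paste(setdiff(samples, colnames(gt)), collapse = ", "))
    gt <- gt[, samples, drop = FALSE]
  }
  dos <- matrix(NA_integer_, nrow(gt), ncol(gt),
                dimnames = dimnames(gt))
  known <- c("0/0" = 0L, "0|0" = 0L, "0/1" = 1L, "1/0" = 1L, "0|1" = 1L,
             "1|0" = 1L, "1/1" = 2L, "1|1" = 2L)
  dos[] <- known[gt]
  rr <- SummarizedExperiment::rowRanges(vcf)
  refs <- as.character(VariantAnnotation::ref(vcf))
  alts <- as.character(unlist(alt))
  vclass <- ifelse(grepl("[<\\[]", alts) |
                     abs(nchar(refs) - nchar(alts)) >= 50, "SV",
                   ifelse(nchar(refs) == 1 & nchar(alts) == 1 &
                            refs %in% c("A", "C", "G", "T") &
                            alts %in% c("A", "C", "G", "T"), "SNP", "indel"))
  gr <- GRanges(seqnames(rr), IRanges(start(rr), width = 1L), strand = "*")
  mcols(gr) <- DataFrame(id = names(rr), ref = refs, alt = alts,
                         vclass = vclass)
  names(gr) <- NULL
  new("GenotypeMatrix", ranges = gr, dosages = dos)
}

#' Assemble the mapping covariate matrix
#'
#' Binds the imputation-status indicator and the leading genotype principal
#' components into the covariate matrix used by [fitApaModel()].
#'
#' @param imputed 0/1 vector per individual (genotype imputed rather than
#'   sequenced), or NULL
#' @param gpcs individuals x k matrix from [genotypePCA()], or NULL
#' @return numeric matrix with one row per individual (NULL if both inputs
#'   are NULL)
#' @export
covariateMatrix <- function(imputed = NULL, gpcs = NULL) {
  parts <- list()
  if (!is.null(imputed)) parts$imputed <- as.numeric(imputed)
  if (!is.null(gpcs)) parts <- c(parts, as.data.frame(gpcs))
  if (!length(parts)) return(NULL)
  as.matrix(as.data.frame(parts))
}
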