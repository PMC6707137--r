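#' @importFrom stats pt p.adjust setNames
NULL

#' Cis windows for apaQTL mapping
#'
#' The cis window of a gene spans the gene body plus 1 Mbp on each side of
#' its TSS and TES, clipped at the chromosome boundaries.  The window is the
#' same for a gene and its mirror image on the opposite strand.
#'
#' @param models a [GeneModelSet-class]
#' @param flank flank size in bp (default 1e6)
#' @param chromLengths optional named vector of chromosome lengths for
#'   right-clipping
#' @return `GRanges` named by gene id (strand `*`)
#' @export
cisWindows <- function(models, flank = 1e6, chromLengths = NULL) {
  tt <- tssTes(models)
  lo <- pmax(0, pmin(tt$tss, tt$tes) - flank)
  hi <- pmax(tt$tss, tt$tes) + flank
  if (!is.null(chromLengths)) {
    len <- chromLengths[tt$chrom]
    hi <- ifelse(is.na(len), hi, pmin(hi, len))
  }
  gr <- GRanges(tt$chrom, IRanges(lo + 1, hi), strand = "*")
  names(gr) <- tt$gene_id
  gr
}

#' Fit the per-gene, per-variant linear model
#'
#' Ordinary least squares of the log2 m/M value on the genotype dosage plus
#' covariates (typically the imputation-status indicator and the leading
#' genotype principal components):
#' \deqn{log2(m/M_i) = \beta_0 + \beta_1 g_i + covariates + \epsilon_i}
#' with a two-sided t-test on the genotype coefficient, df = n_used - 2 -
#' #covariates.  Individuals missing either the phenotype or the genotype
#' are dropped.
#'
#' @param y log2 m/M vector
#' @param g dosage vector (0/1/2)
#' @param covariates optional numeric matrix, rows aligned with `y`
#' @return one-row data.frame: `beta0`, `beta1`, `se_beta1`, `t_stat`,
#'   `p_nominal`, `n_used`, `status` (`ok`, `untestable` when the genotype is
#'   constant/collinear after missing-removal, `constant_y` when the
#'   phenotype has no variance)
#' @export
fitApaModel <- function(y, g, covariates = NULL) {
  X <- cbind(intercept = 1, g = g, covariates)
  ok <- stats::complete.cases(cbind(y, X))
  y <- y[ok]; X <- X[ok, , drop = FALSE]
  n <- length(y)
  out <- data.frame(beta0 = NA_real_, beta1 = NA_real_, se_beta1 = NA_real_,
                    t_stat = NA_real_, p_nominal = NA_real_, n_used = n,
                    status = "ok", stringsAsFactors = FALSE)
  if (n <= ncol(X)) { out$status <- "untestable"; return(out) }
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) { out$status <- "untestable"; return(out) }
  beta <- qr.coef(qrx, y)
  res <- y - X %*% beta
  df <- n - ncol(X)
  sigma2 <- sum(res^2) / df
  XtXinv <- chol2inv(qr.R(qrx))
  se <- sqrt(sigma2 * XtXinv[2, 2])
  out$beta0 <- beta[1]; out$beta1 <- beta[2]; out$se_beta1 <- se
  if (stats::var(y) == 0) {
    out$status <- "constant_y"; out$t_stat <- NA; out$p_nominal <- NA
    out$beta1 <- 0
    return(out)
  }
  if (se == 0) { out$status <- "untestable"; return(out) }
  out$t_stat <- out$beta1 / se
  out$p_nominal <- 2 * pt(-abs(out$t_stat), df)
  out
}

# orthonormal basis of the nuisance design (intercept + covariates)
.nuisanceQ <- function(n, covariates) {
  X0 <- cbind(rep(1, n), covariates)
  qr.Q(qr(X0))
}

#' Map apaQTLs: one linear model per gene x in-window variant
#'
#' Fits the model of [fitApaModel()] for every (gene, variant) pair with the
#' variant inside the gene's cis window, gene by gene so that memory stays
#' bounded by one window.  With `permutations > 0`, each gene's phenotype
#' vector is randomly reshuffled across samples `permutations` times (one
#' shuffle per gene per round, shared by all its variants, preserving the
#' within-gene LD structure of the null) and all models refitted, yielding
#' the permutation p-value pool used by [empiricalPvalues()].
#'
#' Genes whose window dosage matrix is complete are fitted by a vectorised
#' residualisation path; genes with missing dosages fall back to per-pair
#' fits.  Both agree with [fitApaModel()] to numerical precision.
#'
#' @param mm an [MMatrix-class] (the log2 view is the response)
#' @param geno a [GenotypeMatrix-class]; sample columns must match
#'   `mmSamples(mm)` exactly (hard error otherwise)
#' @param windows `GRanges` of cis windows named by gene ([cisWindows()])
#' @param covariates optional numeric matrix (individuals x c)
#' @param permutations number of permutation rounds (default 100)
#' @param seed RNG seed for the permutation shuffles
#' @param genes optional subset of gene ids to map
#' @return list with `results` (data.frame: gene_id, variant_id, beta1,
#'   se_beta1, t_stat, p_nominal, n_used, status) and `permP` (per-gene
#'   matrices of permutation p-values, variants x rounds)
#' @export
mapApaQtl <- function(mm, geno, windows, covariates = NULL,
                      permutations = 100L, seed = 1L, genes = NULL) {
  if (!identical(mmSamples(mm), sampleIds(geno)))
    stop("sample ordering of m/M matrix and genotypes differs")
  if (!is.null(covariates) && nrow(covariates) != ncol(mmValues(mm)))
    stop("covariate rows must match the cohort size")
  Y <- log2MM(mm)
  gids <- if (is.null(genes)) intersect(rownames(Y), names(windows)) else genes
  vr <- variantRanges(geno)
  d <- dosages(geno)
  ids <- variantIds(geno)
  set.seed(seed)
  resList <- vector("list", length(gids))
  permP <- stats::setNames(vector("list", length(gids)), gids)
  for (gi in seq_along(gids)) {
    gene <- gids[gi]
    w <- windows[gene]
    vix <- which(as.character(seqnames(vr)) == as.character(seqnames(w)) &
                   start(vr) >= start(w) & start(vr) <= end(w))
    if (!length(vix)) next
    y <- Y[gene, ]
    obs <- !is.na(y)
    yob <- y[obs]
    n <- length(yob)
    G <- t(d[vix, obs, drop = FALSE]) * 1.0   # n x p
    cov <- if (is.null(covariates)) NULL else covariates[obs, , drop = FALSE]
    ncov <- if (is.null(cov)) 0L else ncol(cov)
    df <- n - 2L - ncov
    base <- data.frame(gene_id = gene, variant_id = ids[vix],
                       beta1 = NA_real_, se_beta1 = NA_real_,
                       t_stat = NA_real_, p_nominal = NA_real_,
                       n_used = n, status = "ok", stringsAsFactors = FALSE)
    if (anyNA(G) || df <= 0) {
      # slow path: per-pair complete cases
      for (j in seq_along(vix)) {
        f <- fitApaModel(y, d[vix[j], ], covariates)
        base[j, c("beta1", "se_beta1", "t_stat", "p_nominal")] <-
          f[c("beta1", "se_beta1", "t_stat", "p_nominal")]
        base$n_used[j] <- f$n_used; base$status[j] <- f$status
      }
      if (permutations > 0) {
        pp <- matrix(NA_real_, length(vix), permutations)
        for (r in seq_len(permutations)) {
          yp <- y
          yp[obs] <- yob[sample.int(n)]
          for (j in seq_along(vix))
            pp[j, r] <- fitApaModel(yp, d[vix[j], ], covariates)$p_nominal
        }
        permP[[gene]] <- pp
      }
      resList[[gi]] <- base
      next
    }
    Q <- .nuisanceQ(n, cov)
    Gr <- G - Q %*% crossprod(Q, G)
    gnorm <- sqrt(colSums(Gr^2))
    testable <- gnorm > 1e-10 * sqrt(n)
    yr <- yob - as.vector(Q %*% crossprod(Q, yob))
    ynorm <- sqrt(sum(yr^2))
    if (ynorm == 0) {
      base$status <- "constant_y"; base$beta1 <- 0
      resList[[gi]] <- base
      next
    }
    rho <- rep(NA_real_, length(vix))
    rho[testable] <- crossprod(Gr[, testable, drop = FALSE], yr) /
      (gnorm[testable] * ynorm)
    rho <- pmin(pmax(rho, -1), 1)
    tval <- rho * sqrt(df) / sqrt(pmax(1 - rho^2, .Machine$double.eps))
    base$beta1 <- rho * ynorm / gnorm
    base$t_stat <- tval
    base$se_beta1 <- base$beta1 / tval
    base$se_beta1[!is.finite(base$se_beta1)] <-
      (ynorm / sqrt(df)) / gnorm[!is.finite(base$se_beta1)]
    base$p_nominal <- 2 * pt(-abs(tval), df)
    base$status[!testable] <- "untestable"
    resList[[gi]] <- base
    if (permutations > 0) {
      P <- matrix(0, n, permutations)
      for (r in seq_len(permutations)) P[, r] <- yob[sample.int(n)]
      RP <- P - Q %*% crossprod(Q, P)
      rnorm2 <- sqrt(colSums(RP^2))
      RHO <- crossprod(Gr[, testable, drop = FALSE], RP) /
        outer(gnorm[testable], rnorm2)
      RHO <- pmin(pmax(RHO, -1), 1)
      TT <- RHO * sqrt(df) / sqrt(pmax(1 - RHO^2, .Machine$double.eps))
      pp <- matrix(NA_real_, length(vix), permutations)
      pp[testable, ] <- 2 * pt(-abs(TT), df)
      permP[[gene]] <- pp
    }
  }
  list(results = do.call(rbind, resList), permP = permP)
}

#' Empirical p-values from phenotype permutations
#'
#' For each gene-variant pair, the empirical p-value is the number of
#' permutation p-values smaller than the pair's nominal p-value divided by
#' the total number of permutation p-values in the chosen pool.
#'
#' @param fit result of [mapApaQtl()] (with `permutations > 0`)
#' @param pooling `"per_gene_pooled"` (default: pool all permutation
#'   p-values of the gene's variants across rounds), `"per_pair"` (each
#'   pair's own rounds only) or `"global_pooled"` (everything)
#' @param plusOne apply the (k+1)/(N+1) correction instead of the literal
#'   k/N ratio (default FALSE, matching the literal counting rule)
#' @return the `results` data.frame with a `p_empirical` column appended
#' @export
empiricalPvalues <- function(fit,
                             pooling = c("per_gene_pooled", "per_pair",
                                         "global_pooled"),
                             plusOne = FALSE) {
  pooling <- match.arg(pooling)
  res <- fit$results
  if (is.null(fit$permP) || all(vapply(fit$permP, is.null, logical(1))))
    stop("no permutation p-values available (empty pool)")
  emp <- function(nominal, pool) {
    pool <- sort(pool[!is.na(pool)])
    if (!length(pool)) return(rep(NA_real_, length(nominal)))
    k <- findInterval(nominal, pool, left.open = TRUE)  # strictly smaller
    if (plusOne) (k + 1) / (length(pool) + 1) else k / length(pool)
  }
  res$p_empirical <- NA_real_
  if (pooling == "global_pooled") {
    pool <- unlist(fit$permP, use.names = FALSE)
    res$p_empirical <- emp(res$p_nominal, pool)
  } else {
    for (gene in names(fit$permP)) {
      pp <- fit$permP[[gene]]
      if (is.null(pp)) next
      ix <- which(res$gene_id == gene)
      if (pooling == "per_gene_pooled") {
        res$p_empirical[ix] <- emp(res$p_nominal[ix], as.vector(pp))
      } else {
        for (j in seq_along(ix))
          res$p_empirical[ix[j]] <- emp(res$p_nominal[ix[j]], pp[j, ])
      }
    }
  }
  res$p_empirical[is.na(res$p_nominal)] <- NA_real_
  res
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up FDR adjustment (cumulative-minimum form, capped at 1),
#' applied across all gene-variant pairs jointly.
#'
#' @param p vector of p-values
#' @return adjusted p-values
#' @export
bhAdjust <- function(p) p.adjust(p, method = "BH")

#' Classify tested variants as apaQTL, null, or gray-area
#'
#' A variant is an apaQTL when its minimum BH-corrected empirical p-value
#' over all fitted genes is below `alpha`; a null variant when every nominal
#' p-value exceeds `nullCut`; a gray-area variant otherwise (suggestive but
#' not significant; excluded from enrichment contrasts).  Untestable fits do
#' not enter the accounting; variants with no testable fit are dropped.
#'
#' @param res data.frame from [empiricalPvalues()] with a `p_corrected`
#'   column (add it with `res$p_corrected <- bhAdjust(res$p_empirical)`)
#' @param alpha corrected-empirical significance cut (default 0.05)
#' @param nullCut nominal p floor for null variants (default 0.1)
#' @return data.frame: `variant_id`, `class`, `best_gene`,
#'   `min_p_corrected`, `min_p_nominal`
#' @export
classifyVariants <- function(res, alpha = 0.05, nullCut = 0.1) {
  if (is.null(res$p_corrected))
    stop("res must carry a p_corrected column")
  ok <- res$status == "ok" & !is.na(res$p_nominal)
  res <- res[ok, , drop = FALSE]
  sp <- split(res, res$variant_id)
  out <- lapply(sp, function(r) {
    mc <- suppressWarnings(min(r$p_corrected, na.rm = TRUE))
    mn <- min(r$p_nominal)
    cls <- if (is.finite(mc) && mc < alpha) "apaQTL"
           else if (all(r$p_nominal > nullCut)) "null"
           else "gray"
    bg <- if (is.finite(mc) && any(!is.na(r$p_corrected)))
      r$gene_id[which.min(r$p_corrected)] else r$gene_id[which.min(r$p_nominal)]
    data.frame(variant_id = r$variant_id[1], class = cls, best_gene = bg,
               min_p_corrected = ifelse(is.finite(mc), mc, NA_real_),
               min_p_nominal = mn, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
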