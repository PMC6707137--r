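#' @importFrom stats glm binomial glm.control qnorm pnorm complete.cases var
#' @importFrom IRanges overlapsAny
NULL

#' Logistic enrichment of a binary feature among apaQTLs
#'
#' Fits the multivariate logistic model
#' \deqn{t_j = \beta_0 + \beta_1 Feature_j + covariates + \epsilon_j,\qquad
#'       Pr(apaQTL)_j = 1 / (1 + e^{-t_j})}
#' by maximum likelihood (IRLS, at most 50 iterations, tolerance 1e-8) with
#' the apaQTL/null status as the response.  The feature coefficient is
#' reported as an odds ratio with a 95% Wald confidence interval and a
#' two-sided Wald p-value.  Non-convergence or (quasi-)separation is
#' reported through `converged = FALSE`, in which case the OR is not to be
#' interpreted.
#'
#' @param status logical or 0/1 vector: is the candidate an apaQTL?
#' @param feature logical or 0/1 feature vector
#' @param covariates optional numeric matrix/data.frame (e.g. observed MAF)
#' @param featureName label carried into the result
#' @return one-row data.frame: `feature_name`, `beta0`, `beta1`, `or`,
#'   `ci_low`, `ci_high`, `p_value`, `n_candidates`, `n_feature`,
#'   `n_apaqtl`, `converged`
#' @export
logisticEnrichment <- function(status, feature, covariates = NULL,
                               featureName = "feature") {
  status <- as.integer(status); feature <- as.integer(feature)
  if (length(unique(feature)) < 2L) stop("degenerate feature")
  if (sum(status == 1) < 2L || sum(status == 0) < 2L)
    stop("need at least 2 candidates in each status class")
  dat <- data.frame(status = status, feature = feature)
  if (!is.null(covariates)) dat <- cbind(dat, as.data.frame(covariates))
  w <- NULL
  fit <- withCallingHandlers(
    glm(status ~ ., data = dat, family = binomial(),
        control = glm.control(epsilon = 1e-8, maxit = 50)),
    warning = function(cond) {
      w <<- conditionMessage(cond)
      invokeRestart("muffleWarning")
    })
  co <- summary(fit)$coefficients
  b1 <- co["feature", "Estimate"]; se <- co["feature", "Std. Error"]
  separated <- !is.null(w) &&
    grepl("fitted probabilities numerically 0 or 1", w) &&
    (abs(b1) > 10 || se > 50)
  converged <- fit$converged && !separated && se < 100
  z <- qnorm(0.975)
  data.frame(feature_name = featureName,
             beta0 = co["(Intercept)", "Estimate"], beta1 = b1,
             or = exp(b1), ci_low = exp(b1 - z * se),
             ci_high = exp(b1 + z * se),
             p_value = 2 * pnorm(-abs(b1 / se)),
             n_candidates = length(status), n_feature = sum(feature),
             n_apaqtl = sum(status), converged = converged,
             stringsAsFactors = FALSE)
}

#' Build the pruned candidate set for an enrichment analysis
#'
#' Starting from the classified variants, keeps the requested candidates,
#' drops gray-area variants, LD-prunes the candidates only, evaluates the
#' binary feature (optionally propagated from tagging variants with r² >
#' `tagR2`), and attaches the observed-mode MAF covariate.
#'
#' @param calls data.frame from [classifyVariants()]
#' @param geno the full [GenotypeMatrix-class] (tags are searched here)
#' @param featureById named logical vector over variant ids: does the variant
#'   itself carry the feature?
#' @param candidateIds restrict candidates to these ids (default: all
#'   classified variants)
#' @param useTags propagate the feature through tagging variants
#' @param prune apply LD pruning to the candidates (default TRUE)
#' @param tagR2 strict r² threshold for tagging (default 0.8)
#' @param tagWindow tagging search window in bp (default 1e6)
#' @param windowSnps,stepSnps,r2Max pruning parameters
#' @return data.frame: `variant_id`, `status` (1 = apaQTL), `feature`, `maf`
#' @export
buildCandidates <- function(calls, geno, featureById, candidateIds = NULL,
                            useTags = FALSE, prune = TRUE, tagR2 = 0.8,
                            tagWindow = 1e6, windowSnps = 50L, stepSnps = 5L,
                            r2Max = 0.8) {
  keep <- calls$class %in% c("apaQTL", "null")
  cand <- calls$variant_id[keep]
  if (!is.null(candidateIds)) cand <- intersect(cand, candidateIds)
  cand <- intersect(cand, variantIds(geno))
  if (!length(cand)) stop("empty candidate set after filters")
  if (prune) {
    sub <- geno[cand]
    cand <- ldPrune(sub, windowSnps, stepSnps, r2Max)
  }
  if (!length(cand)) stop("empty candidate set after filters")
  feat <- if (useTags)
    .selfOrTagFeature(cand, geno, featureById, r2Min = tagR2,
                      window = tagWindow)
  else
    vapply(cand, function(v) isTRUE(featureById[v]), logical(1))
  maf <- variantMaf(geno[cand], mode = "observed")
  data.frame(variant_id = cand,
             status = as.integer(calls$class[match(cand, calls$variant_id)]
                                 == "apaQTL"),
             feature = as.integer(feat), maf = maf,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Gene-region feature maps for intragenic variants
#'
#' Labels each variant by the collapsed-model regions it falls in.  A
#' variant is intragenic when it lies between the start and the end of an
#' analyzed gene, or within 1,000 bp after the gene end (in transcript
#' orientation), allowing for 3' UTR mis-annotation.
#'
#' @param geno a [GenotypeMatrix-class]
#' @param models a [GeneModelSet-class] (the analyzed genes)
#' @param afterEnd bp after the gene end still counted intragenic (1000)
#' @return data.frame: `variant_id`, logical `intragenic`, `coding_exon`,
#'   `intron`, `utr5`, `utr3`
#' @export
geneRegionFeatures <- function(geno, models, afterEnd = 1000L) {
  g <- geneRanges(models)
  neg <- as.character(strand(g)) == "-"
  spanExt <- GRanges(seqnames(g),
                     IRanges(ifelse(neg, pmax(1L, start(g) - afterEnd),
                                    start(g)),
                             ifelse(neg, end(g), end(g) + afterEnd)),
                     strand = "*")
  exs <- exonsByGene(models)
  coding <- utr5 <- utr3 <- intron <- vector("list", length(g))
  for (i in seq_along(g)) {
    ex <- exs[[i]]
    strand(ex) <- "*"
    cs <- mcols(g)$cds_start[i]; ce <- mcols(g)$cds_end[i]
    span <- GRanges(seqnames(g)[i], IRanges(start(g)[i], end(g)[i]))
    intron[[i]] <- GenomicRanges::setdiff(span, ex)
    if (is.na(cs)) next
    cdsGr <- GRanges(seqnames(g)[i], IRanges(cs + 1L, ce))
    coding[[i]] <- GenomicRanges::intersect(ex, cdsGr)
    if (neg[i]) {
      up <- GRanges(seqnames(g)[i], IRanges(ce + 1L, max(end(g)[i], ce + 1L)))
      dn <- GRanges(seqnames(g)[i], IRanges(start(g)[i], max(cs, start(g)[i])))
    } else {
      up <- GRanges(seqnames(g)[i], IRanges(start(g)[i], max(cs, start(g)[i])))
      dn <- GRanges(seqnames(g)[i], IRanges(ce + 1L, max(end(g)[i], ce + 1L)))
    }
    utr5[[i]] <- GenomicRanges::intersect(ex, up)
    utr3[[i]] <- GenomicRanges::intersect(ex, dn)
  }
  cat2gr <- function(lst) {
    lst <- lst[!vapply(lst, is.null, logical(1))]
    if (!length(lst)) return(GRanges())
    unlist(GRangesList(lst))
  }
  vr <- variantRanges(geno)
  data.frame(variant_id = variantIds(geno),
             intragenic = overlapsAny(vr, spanExt, ignore.strand = TRUE),
             coding_exon = overlapsAny(vr, cat2gr(coding), ignore.strand = TRUE),
             intron = overlapsAny(vr, cat2gr(intron), ignore.strand = TRUE),
             utr5 = overlapsAny(vr, cat2gr(utr5), ignore.strand = TRUE),
             utr3 = overlapsAny(vr, cat2gr(utr3), ignore.strand = TRUE),
             stringsAsFactors = FALSE)
}

#' Chromatin-state enrichment of apaQTLs
#'
#' One logistic enrichment per chromatin state (or broad class).  Candidates
#' are all classified variants that carry at least one state annotation,
#' excluding structural variants (their length prevents unambiguous state
#' assignment) and gray-area variants.  MAF is the only covariate.
#'
#' @param calls data.frame from [classifyVariants()]
#' @param geno a [GenotypeMatrix-class]
#' @param states `GRanges` of state intervals with a `name` column
#' @param ... passed to [buildCandidates()]
#' @return data.frame of [logisticEnrichment()] rows, one per state
#' @export
chromatinStateEnrichment <- function(calls, geno, states, ...) {
  vr <- variantRanges(geno)
  annotated <- overlapsAny(vr, states, ignore.strand = TRUE)
  notSv <- mcols(vr)$vclass != "SV"
  candidateIds <- variantIds(geno)[annotated & notSv]
  out <- lapply(unique(states$name), function(st) {
    inState <- overlapsAny(vr, states[states$name == st], ignore.strand = TRUE)
    featureById <- stats::setNames(inState, variantIds(geno))
    cs <- buildCandidates(calls, geno, featureById,
                          candidateIds = candidateIds, ...)
    logisticEnrichment(cs$status, cs$feature,
                       covariates = cs[, "maf", drop = FALSE],
                       featureName = st)
  })
  do.call(rbind, out)
}

#' Gene-region enrichment of intragenic apaQTLs
#'
#' Independent logistic enrichments for coding exons, introns, 5' UTRs and
#' 3' UTRs among intragenic candidates, with MAF as the only covariate.
#'
#' @inheritParams chromatinStateEnrichment
#' @param models a [GeneModelSet-class]
#' @return data.frame of [logisticEnrichment()] rows, one per region class
#' @export
geneRegionEnrichment <- function(calls, geno, models, ...) {
  feats <- geneRegionFeatures(geno, models)
  candidateIds <- feats$variant_id[feats$intragenic]
  out <- lapply(c("coding_exon", "intron", "utr5", "utr3"), function(cl) {
    featureById <- stats::setNames(feats[[cl]], feats$variant_id)
    cs <- buildCandidates(calls, geno, featureById,
                          candidateIds = candidateIds, ...)
    logisticEnrichment(cs$status, cs$feature,
                       covariates = cs[, "maf", drop = FALSE],
                       featureName = cl)
  })
  do.call(rbind, out)
}

#' Cis-regulatory-domain enrichment of extragenic apaQTLs
#'
#' Candidates are the extragenic classified variants; the feature is lying
#' within a CRD; covariates are the observed MAF and the distance to the
#' nearest analyzed gene (variants closer to a gene are a priori more likely
#' to be apaQTLs).
#'
#' @inheritParams geneRegionEnrichment
#' @param crds `GRanges` of cis-regulatory domains
#' @return one [logisticEnrichment()] row
#' @export
crdEnrichment <- function(calls, geno, crds, models, ...) {
  feats <- geneRegionFeatures(geno, models)
  candidateIds <- feats$variant_id[!feats$intragenic]
  vr <- variantRanges(geno)
  inCrd <- overlapsAny(vr, crds, ignore.strand = TRUE)
  featureById <- stats::setNames(inCrd, variantIds(geno))
  cs <- buildCandidates(calls, geno, featureById,
                        candidateIds = candidateIds, ...)
  vix <- match(cs$variant_id, variantIds(geno))
  dist <- GenomicRanges::distanceToNearest(vr[vix], geneRanges(models),
                                           ignore.strand = TRUE)
  dd <- rep(NA_real_, length(vix))
  dd[S4Vectors::queryHits(dist)] <- mcols(dist)$distance
  if (anyNA(dd)) stop("distance to nearest gene not computable for all candidates")
  logisticEnrichment(cs$status, cs$feature,
                     covariates = data.frame(maf = cs$maf, dist = dd),
                     featureName = "CRD")
}

#' Concordance between extragenic apaQTLs and the CRDs of their genes
#'
#' Counts how many extragenic apaQTLs lie inside a CRD assigned to at least
#' one of the genes they are significant for, and compares the count with a
#' permutation null in which each apaQTL is associated to a uniformly random
#' analyzed gene whose cis window contains it.
#'
#' @param sigPairs data.frame of significant pairs with `gene_id`,
#'   `variant_id` (extragenic apaQTLs only)
#' @param geno a [GenotypeMatrix-class]
#' @param crds `GRanges` of CRDs with a `crd_id` column
#' @param crdGeneMap data.frame with `crd_id`, `gene_id`
#' @param windows cis windows (`GRanges` named by analyzed gene)
#' @param nRand permutation rounds (default 100)
#' @param seed RNG seed
#' @return list: `observed`, `nullCounts`, `nullMedian`, `pEmpirical`
#'   (computed as (#null >= observed + 1) / (nRand + 1))
#' @export
crdConcordanceTest <- function(sigPairs, geno, crds, crdGeneMap, windows,
                               nRand = 100L, seed = 1L) {
  set.seed(seed)
  vids <- unique(sigPairs$variant_id)
  vr <- variantRanges(geno)
  vix <- match(vids, variantIds(geno))
  # genes whose CRDs contain each variant
  hits <- GenomicRanges::findOverlaps(vr[vix], crds, ignore.strand = TRUE)
  crdGenes <- lapply(seq_along(vids), function(i) {
    ci <- mcols(crds)$crd_id[S4Vectors::subjectHits(hits)[
      S4Vectors::queryHits(hits) == i]]
    unique(crdGeneMap$gene_id[crdGeneMap$crd_id %in% ci])
  })
  sigGenes <- split(sigPairs$gene_id, sigPairs$variant_id)[vids]
  observed <- sum(mapply(function(a, b) length(intersect(a, b)) > 0,
                         crdGenes, sigGenes))
  # genes whose cis window contains each variant
  wHits <- GenomicRanges::findOverlaps(vr[vix], windows, ignore.strand = TRUE)
  windowGenes <- lapply(seq_along(vids), function(i) {
    names(windows)[S4Vectors::subjectHits(wHits)[
      S4Vectors::queryHits(wHits) == i]]
  })
  nullCounts <- vapply(seq_len(nRand), function(r) {
    sum(vapply(seq_along(vids), function(i) {
      wg <- windowGenes[[i]]
      if (!length(wg)) return(FALSE)
      sample(wg, 1L) %in% crdGenes[[i]]
    }, logical(1)))
  }, numeric(1))
  list(observed = observed, nullCounts = nullCounts,
       nullMedian = stats::median(nullCounts),
       pEmpirical = (sum(nullCounts >= observed) + 1) / (nRand + 1))
}

#' Parse a GWAS-catalog-style table
#'
#' Keeps records that refer to a single autosomal variant and have all of
#' CHR_ID, CHR_POS, SNPS, MERGED, SNP_ID_CURRENT and MAPPED_TRAIT_URI
#' available; coordinates are taken from the supplied rsid coordinate table;
#' EFO parent categories are attached from the trait map.
#'
#' @param catalog data.frame or TSV path with the catalog columns above plus
#'   a trait name column (`MAPPED_TRAIT` or `DISEASE.TRAIT`)
#' @param efoMap data.frame or TSV path with `trait_uri`, `parent_category`
#' @param coords data.frame or TSV path with `rsid`, `chrom`, `pos` giving
#'   positions on the working assembly
#' @return data.frame: `rsid`, `chrom`, `pos`, `trait`, `categories`
#'   (";"-joined); attribute `n_skipped` counts malformed/dropped rows
#' @export
parseGwasCatalog <- function(catalog, efoMap, coords) {
  rd <- function(x) if (is.character(x))
    utils::read.table(x, header = TRUE, sep = "\t", quote = "",
                      stringsAsFactors = FALSE, check.names = TRUE) else x
  cat <- rd(catalog); efo <- rd(efoMap); co <- rd(coords)
  need <- c("CHR_ID", "CHR_POS", "SNPS", "MERGED", "SNP_ID_CURRENT",
            "MAPPED_TRAIT_URI")
  if (!all(need %in% names(cat)))
    stop("catalog must have columns ", paste(need, collapse = ", "))
  traitCol <- intersect(c("MAPPED_TRAIT", "DISEASE.TRAIT"), names(cat))[1]
  n0 <- nrow(cat)
  full <- rowSums(is.na(cat[need]) | cat[need] == "") == 0
  single <- grepl("^rs[0-9]+$", cat$SNPS)
  auto <- sub("^chr", "", as.character(cat$CHR_ID)) %in% as.character(1:22)
  keep <- full & single & auto
  cat <- cat[keep, , drop = FALSE]
  pos <- co$pos[match(cat$SNPS, co$rsid)]
  chrom <- co$chrom[match(cat$SNPS, co$rsid)]
  located <- !is.na(pos)
  cat <- cat[located, , drop = FALSE]
  parents <- vapply(cat$MAPPED_TRAIT_URI, function(u) {
    uris <- trimws(strsplit(u, ",")[[1]])
    paste(unique(stats::na.omit(
      efo$parent_category[match(uris, efo$trait_uri)])), collapse = ";")
  }, character(1))
  out <- data.frame(rsid = cat$SNPS, chrom = chrom[located],
                    pos = pos[located],
                    trait = if (is.na(traitCol)) "" else cat[[traitCol]],
                    categories = parents,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "n_skipped") <- n0 - nrow(out)
  out
}

#' GWAS-hit enrichment among apaQTLs
#'
#' Enrichment of trait-associated variants (self or tagging partner) among
#' apaQTLs: one overall (any-trait) analysis plus one per trait and per EFO
#' parent category with at least `minHits` associated variants.  With
#' `excludeRegion` set (e.g. the MHC/HLA interval), candidates and tags
#' inside the region are removed before fitting.
#'
#' @inheritParams chromatinStateEnrichment
#' @param gwas data.frame from [parseGwasCatalog()]
#' @param minHits minimum GWAS hits for a trait/category (default 100)
#' @param excludeRegion optional `GRanges` interval to exclude
#' @param tagR2,tagWindow tagging parameters
#' @return data.frame of [logisticEnrichment()] rows with a `level` column
#'   (`overall`/`trait`/`category`)
#' @export
gwasEnrichment <- function(calls, geno, gwas, minHits = 100L,
                           excludeRegion = NULL, tagR2 = 0.8,
                           tagWindow = 1e6, ...) {
  vr <- variantRanges(geno)
  ids <- variantIds(geno)
  key <- paste(as.character(seqnames(vr)), start(vr))
  matchVariants <- function(g) {
    hit <- ids %in% g$rsid | key %in% paste(g$chrom, g$pos + 1L)
    stats::setNames(hit, ids)
  }
  genoUse <- geno
  callsUse <- calls
  if (!is.null(excludeRegion)) {
    inReg <- overlapsAny(vr, excludeRegion, ignore.strand = TRUE)
    genoUse <- geno[!inReg]
    callsUse <- calls[calls$variant_id %in% variantIds(genoUse), , drop = FALSE]
  }
  runOne <- function(g, name, level) {
    featureById <- matchVariants(g)[variantIds(genoUse)]
    cs <- buildCandidates(callsUse, genoUse, featureById, useTags = TRUE,
                          tagR2 = tagR2, tagWindow = tagWindow, ...)
    r <- logisticEnrichment(cs$status, cs$feature,
                            covariates = cs[, "maf", drop = FALSE],
                            featureName = name)
    r$level <- level
    r
  }
  out <- list(runOne(gwas, "any_trait", "overall"))
  traits <- table(gwas$trait[gwas$trait != ""])
  for (tr in names(traits[traits >= minHits]))
    out <- c(out, list(runOne(gwas[gwas$trait == tr, ], tr, "trait")))
  cats <- unlist(strsplit(gwas$categories, ";"))
  for (cc in names(table(cats)[table(cats) >= minHits])) {
    sel <- grepl(cc, gwas$categories, fixed = TRUE)
    out <- c(out, list(runOne(gwas[sel, ], cc, "category")))
  }
  do.call(rbind, out)
}
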