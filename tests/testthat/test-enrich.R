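test_that("2x2 logistic MLE equals the cross-product ratio", {
  status <- rep(c(1, 1, 0, 0), c(30, 70, 10, 90))
  feature <- rep(c(1, 0, 1, 0), c(30, 70, 10, 90))
  r <- logisticEnrichment(status, feature)
  expect_equal(r$or, 27 / 7, tolerance = 1e-6)
  expect_equal(r$beta1, log(27 / 7), tolerance = 1e-6)
  expect_true(r$converged)
  expect_equal(r$n_candidates, 200L)
  expect_equal(r$n_feature, 40L)
  # random non-degenerate tables
  set.seed(41)
  for (i in 1:200) {
    tab <- rmultinom(1, 400, runif(4, 0.05, 1))
    if (any(tab == 0)) next
    st <- rep(c(1, 1, 0, 0), tab)
    ft <- rep(c(1, 0, 1, 0), tab)
    cpr <- (tab[1] * tab[4]) / (tab[2] * tab[3])
    expect_equal(logisticEnrichment(st, ft)$or, cpr, tolerance = 1e-6)
  }
})

test_that("degenerate inputs are rejected or flagged", {
  expect_error(logisticEnrichment(rep(0:1, 50), rep(1, 100)),
               "degenerate feature")
  expect_error(logisticEnrichment(c(1, rep(0, 20)), rep(0:1, length.out = 21)),
               "each status class")
  # complete separation: every feature carrier is an apaQTL
  st <- c(rep(1, 20), rep(0, 40))
  ft <- c(rep(1, 20), rep(0, 40))
  r <- logisticEnrichment(st, ft)
  expect_false(r$converged)
})

test_that("independent features give uniform p-values under permutation", {
  set.seed(42)
  p <- replicate(300, {
    cs <- simulateEnrichmentCandidates(400, orTrue = 1)
    logisticEnrichment(cs$status, cs$feature)$p_value
  })
  expect_gt(suppressWarnings(ks.test(p, "punif"))$p.value, 0.01)
  expect_lt(mean(p < 0.05), 0.1)
})

test_that("planted odds ratios are recovered with nominal CI coverage", {
  set.seed(43)
  for (or in c(1.5, 3)) {
    hits <- replicate(60, {
      cs <- simulateEnrichmentCandidates(3000, or)
      r <- logisticEnrichment(cs$status, cs$feature,
                              covariates = cs[, "maf", drop = FALSE])
      r$ci_low <= or && or <= r$ci_high
    })
    expect_gte(mean(hits), 0.85)
  }
})

test_that("candidate sets exclude gray variants and propagate tag features", {
  set.seed(44)
  n <- 60
  d <- matrix(rbinom(4 * n, 2, 0.4), 4, n)
  d[2, ] <- d[1, ]                      # v2 tags v1 perfectly
  g <- makeGeno(d, pos = c(100, 100000, 5e5, 9e5))
  calls <- data.frame(variant_id = paste0("v", 1:4),
                      class = c("apaQTL", "null", "gray", "null"),
                      stringsAsFactors = FALSE)
  featureById <- setNames(c(FALSE, TRUE, TRUE, FALSE), paste0("v", 1:4))
  cs <- buildCandidates(calls, g, featureById, useTags = TRUE, prune = FALSE)
  expect_false("v3" %in% cs$variant_id)            # gray excluded
  expect_equal(cs$feature[cs$variant_id == "v1"], 1L)  # via tagging v2
  expect_equal(cs$feature[cs$variant_id == "v4"], 0L)
  expect_equal(cs$maf,
               variantMaf(g[cs$variant_id], "observed"))
  # with pruning, the perfectly correlated pair collapses to one candidate
  csP <- buildCandidates(calls, g, featureById, useTags = TRUE)
  expect_length(intersect(csP$variant_id, c("v1", "v2")), 1L)
  expect_error(buildCandidates(calls[calls$class == "gray", ], g,
                               featureById), "empty candidate")
})

test_that("gene-region features follow the collapsed model geometry", {
  # + strand gene: span [1000,3000), CDS [1200,2000), exons [1000,1500)
  # and [1800,3000) -> intron [1500,1800)
  ex <- GRanges("chr1", IRanges(c(1001, 1801), c(1500, 3000)), strand = "+")
  gr <- GRanges("chr1", IRanges(1001, 3000), strand = "+")
  mcols(gr) <- DataFrame(gene_id = "G", cds_start = 1200, cds_end = 2000)
  models <- new("GeneModelSet", genes = gr, exons = GRangesList(ex),
                excluded = data.frame(gene_id = character(),
                                      reason = character()))
  pos <- c(1100, 1300, 1600, 2500, 3400, 4600)
  g <- makeGeno(matrix(1L, 6, 4), pos = pos)
  f <- geneRegionFeatures(g, models)
  expect_equal(f$utr5, c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(f$coding_exon, c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(f$intron, c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(f$utr3, c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE))
  # 400 bp past the end is still intragenic, 1600 bp is not
  expect_equal(f$intragenic,
               c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE))
})

test_that("CRD enrichment recovers a planted odds ratio", {
  set.seed(45)
  n <- 4000; nInd <- 60
  d <- matrix(rbinom(n * nInd, 2, 0.4), n, nInd)
  pos <- seq_len(n) * 5000 + 1e6
  g <- makeGeno(d, pos = pos)
  calls <- data.frame(variant_id = paste0("v", 1:n),
                      class = sample(c("apaQTL", "null"), n, TRUE,
                                     prob = c(0.3, 0.7)),
                      stringsAsFactors = FALSE)
  tr <- simulateFeatureTracks(calls, g, orTrue = 3, pFeatureNull = 0.2)
  crds <- tr$states[tr$states$name == "StateA"]
  # one distant gene so every variant is extragenic
  models <- makeModels("G", "chr1", "+", 5e7, 5.001e7)
  r <- crdEnrichment(calls, g, crds, models, prune = FALSE)
  expect_true(r$converged)
  expect_true(r$ci_low <= 3 && 3 <= r$ci_high)
  # all variants outside CRDs: degenerate feature
  far <- GRanges("chr1", IRanges(1, 10))
  expect_error(crdEnrichment(calls, g, far, models, prune = FALSE),
               "degenerate")
})

test_that("CRD concordance matches the exhaustive-enumeration oracle", {
  # two variants, two genes; variant v1 sits in a CRD of geneA only
  g <- makeGeno(matrix(1L, 2, 4), pos = c(1000, 2000))
  crds <- GRanges("chr1", IRanges(c(900, 1900), c(1100, 2100)))
  mcols(crds) <- DataFrame(crd_id = c("c1", "c2"))
  crdMap <- data.frame(crd_id = c("c1", "c2"), gene_id = c("geneA", "geneB"))
  windows <- GRanges("chr1", IRanges(c(1, 1), c(10000, 10000)))
  names(windows) <- c("geneA", "geneB")
  sig <- data.frame(gene_id = c("geneA", "geneB"),
                    variant_id = c("v1", "v2"))
  res <- crdConcordanceTest(sig, g, crds, crdMap, windows,
                            nRand = 400, seed = 5)
  expect_equal(res$observed, 2L)     # both variants concordant
  # null: each variant picks geneA or geneB at random; concordance
  # probability is 1/2 each, so the enumeration mean is 1
  expect_lt(abs(mean(res$nullCounts) - 1), 3 * sqrt(0.5 / 400))
  # enumeration: P(null >= 2) = 1/4, so the empirical p sits near 0.25
  expect_lt(abs(res$pEmpirical - 0.25), 0.08)
  # no CRDs: observed 0, null all 0
  none <- GRanges("chr1", IRanges(1, 2))
  mcols(none) <- DataFrame(crd_id = "cx")
  res0 <- crdConcordanceTest(sig, g, none, crdMap, windows, nRand = 10)
  expect_equal(res0$observed, 0L)
  expect_true(all(res0$nullCounts == 0))
})

test_that("GWAS catalog parsing keeps single autosomal annotated records", {
  cat <- data.frame(
    CHR_ID = c("1", "2", "X", "3", "4"),
    CHR_POS = c(100, 200, 300, NA, 500),
    SNPS = c("rs1", "rs2; rs3", "rs4", "rs5", "rs6"),
    MERGED = 0, SNP_ID_CURRENT = c("1", "2", "4", "5", "6"),
    MAPPED_TRAIT_URI = c("efo:1", "efo:1", "efo:2", "efo:2", ""),
    MAPPED_TRAIT = c("asthma", "asthma", "height", "height", "bmi"),
    stringsAsFactors = FALSE)
  efo <- data.frame(trait_uri = c("efo:1", "efo:2"),
                    parent_category = c("immune", "other"))
  coords <- data.frame(rsid = c("rs1", "rs6"), chrom = c("chr1", "chr4"),
                       pos = c(99, 499))
  g <- parseGwasCatalog(cat, efo, coords)
  expect_equal(g$rsid, "rs1")           # rs2 multi, rs4 chrX, rs5 NA pos,
  expect_equal(g$categories, "immune")  # rs6 empty trait URI
  expect_equal(attr(g, "n_skipped"), 4L)
})

test_that("GWAS enrichment honors minHits and region exclusion", {
  set.seed(46)
  n <- 800; nInd <- 50
  d <- matrix(rbinom(n * nInd, 2, 0.4), n, nInd)
  pos <- seq_len(n) * 2000
  g <- makeGeno(d, pos = pos, ids = paste0("rs", 1:n))
  calls <- data.frame(variant_id = paste0("rs", 1:n),
                      class = sample(c("apaQTL", "null"), n, TRUE),
                      stringsAsFactors = FALSE)
  hit <- sample(n, 200)
  gwas <- data.frame(rsid = paste0("rs", hit), chrom = "chr1",
                     pos = pos[hit] - 1L,
                     trait = rep(c("traitBig", "traitSmall"), c(150, 50)),
                     categories = "catA", stringsAsFactors = FALSE)
  r <- gwasEnrichment(calls, g, gwas, minHits = 100, prune = FALSE,
                      tagWindow = 100)
  expect_true("any_trait" %in% r$feature_name)
  expect_true("traitBig" %in% r$feature_name)
  expect_false("traitSmall" %in% r$feature_name)   # < 100 hits
  expect_true("catA" %in% r$feature_name)
  # excluding a region only removes candidates
  excl <- GRanges("chr1", IRanges(1, 4e5))
  r2 <- gwasEnrichment(calls, g, gwas, minHits = 100, prune = FALSE,
                       tagWindow = 100, excludeRegion = excl)
  expect_lt(r2$n_candidates[1], r$n_candidates[1])
})
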