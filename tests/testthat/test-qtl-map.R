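test_that("cis windows span the gene body plus 1 Mbp each side", {
  mod <- makeModels(c("a", "b"), "chr1", c("+", "-"),
                    c(2e6, 2e6), c(2.01e6, 2.01e6))
  w <- cisWindows(mod)
  # 0-based [1e6, 3.01e6) regardless of strand
  expect_equal(start(w) - 1, c(1e6, 1e6))
  expect_equal(end(w), c(3.01e6, 3.01e6))
  # left clip at zero
  modL <- makeModels("c", "chr1", "+", 5e5, 5.1e5)
  wL <- cisWindows(modL)
  expect_equal(start(wL) - 1, 0)
  # right clip at the chromosome length
  wR <- cisWindows(mod, chromLengths = c(chr1 = 2.5e6))
  expect_equal(end(wR), c(2.5e6, 2.5e6))
})

test_that("the printed OLS toy gives beta1 = 1, beta0 = 0", {
  f <- fitApaModel(y = c(0.1, -0.1, 1.1, 0.9, 2.1, 1.9),
                   g = c(0, 0, 1, 1, 2, 2))
  expect_equal(f$beta1, 1.0)
  expect_equal(f$beta0, 0.0, tolerance = 1e-12)
  expect_equal(f$status, "ok")
})

test_that("fitApaModel matches a normal-equations oracle", {
  set.seed(31)
  for (i in 1:300) {
    n <- sample(10:60, 1)
    ncov <- sample(0:3, 1)
    g <- rbinom(n, 2, runif(1, 0.1, 0.5))
    if (var(g) == 0) next
    cov <- if (ncov) matrix(rnorm(n * ncov), n) else NULL
    y <- rnorm(n)
    f <- fitApaModel(y, g, cov)
    # independent oracle: explicit normal equations + t distribution
    X <- cbind(1, g, cov)
    bet <- solve(t(X) %*% X, t(X) %*% y)
    res <- y - X %*% bet
    df <- n - ncol(X)
    se <- sqrt(drop(crossprod(res)) / df * solve(t(X) %*% X)[2, 2])
    tt <- bet[2] / se
    expect_lt(abs(f$beta1 - bet[2]), 1e-8)
    expect_lt(abs(f$se_beta1 - se), 1e-8)
    expect_lt(abs(f$p_nominal - 2 * pt(-abs(tt), df)), 1e-8)
  }
})

test_that("degenerate fits are flagged instead of tested", {
  expect_equal(fitApaModel(rnorm(10), rep(1, 10))$status, "untestable")
  f <- fitApaModel(rep(2, 10), rbinom(10, 2, 0.5))
  expect_equal(f$status, "constant_y")
  expect_equal(f$beta1, 0)
  expect_true(is.na(f$p_nominal))
})

test_that("mapping fits every in-window pair and only those", {
  set.seed(32)
  mod <- makeModels("g1", "chr1", "+", 2e6, 2.01e6)
  w <- cisWindows(mod)
  d <- matrix(rbinom(4 * 30, 2, 0.4), 4, 30,
              dimnames = list(NULL, paste0("i", 1:30)))
  g <- makeGeno(d, pos = c(1.5e6, 2e6, 2.9e6, 3.5e6))  # 3 in window
  v <- matrix(rnorm(30), 1, dimnames = list("g1", colnames(d)))
  mm <- new("MMatrix", values = 2^v, mask = matrix(FALSE, 1, 30,
                                                   dimnames = dimnames(v)))
  fit <- mapApaQtl(mm, g, w, permutations = 0)
  expect_equal(nrow(fit$results), 3L)
  expect_setequal(fit$results$variant_id, c("v1", "v2", "v3"))
  # fast path equals the per-pair reference fit
  for (k in 1:3) {
    r <- fit$results[k, ]
    f <- fitApaModel(v["g1", ], d[match(r$variant_id, variantIds(g)), ])
    expect_equal(r$beta1, f$beta1, tolerance = 1e-10)
    expect_equal(r$se_beta1, f$se_beta1, tolerance = 1e-10)
    expect_equal(r$p_nominal, f$p_nominal, tolerance = 1e-10)
  }
})

test_that("mapping in chunks equals mapping in one pass", {
  study <- simulateApaStudy("custom", seed = 33, nGenes = 6,
                            nIndividuals = 40, nVariantsPerGene = 8)
  all1 <- mapApaQtl(study$mm, study$geno, study$windows, permutations = 0)
  gids <- mmGenes(study$mm)
  parts <- rbind(
    mapApaQtl(study$mm, study$geno, study$windows, permutations = 0,
              genes = gids[1:3])$results,
    mapApaQtl(study$mm, study$geno, study$windows, permutations = 0,
              genes = gids[4:6])$results)
  expect_equal(all1$results, parts, ignore_attr = TRUE)
})

test_that("sample-order mismatch is a hard error", {
  study <- simulateApaStudy("custom", seed = 34, nGenes = 2,
                            nIndividuals = 10, nVariantsPerGene = 4)
  swapped <- study$geno
  swapped@dosages <- swapped@dosages[, rev(seq_len(10))]
  expect_error(mapApaQtl(study$mm, swapped, study$windows), "ordering")
})

test_that("missing phenotypes and dosages fall back to per-pair fits", {
  set.seed(35)
  mod <- makeModels("g1", "chr1", "+", 2e6, 2.01e6)
  w <- cisWindows(mod)
  d <- matrix(rbinom(2 * 40, 2, 0.4), 2, 40,
              dimnames = list(NULL, paste0("i", 1:40)))
  d[1, 3] <- NA                          # missing dosage: slow path
  g <- makeGeno(d, pos = c(2e6, 2.005e6))
  v <- matrix(2^rnorm(40), 1, dimnames = list("g1", colnames(d)))
  v[1, 5] <- NA
  mm <- new("MMatrix", values = v, mask = is.na(v))
  fit <- mapApaQtl(mm, g, w, permutations = 0)
  y <- log2MM(mm)["g1", ]
  for (k in 1:2) {
    f <- fitApaModel(y, d[k, ])
    expect_equal(fit$results$beta1[k], f$beta1, tolerance = 1e-10)
    expect_equal(fit$results$n_used[k], f$n_used)
  }
})

test_that("empirical p-values implement the literal counting formula", {
  mkfit <- function(nominal, pool)
    list(results = data.frame(gene_id = "g", variant_id = "v",
                              p_nominal = nominal, status = "ok",
                              stringsAsFactors = FALSE),
         permP = list(g = matrix(pool, nrow = 1)))
  pool <- c(0.01, 0.02, 0.04, 0.2, 0.3, 0.5, 0.6, 0.7, 0.8, 0.9)
  expect_equal(empiricalPvalues(mkfit(0.05, pool))$p_empirical, 0.3)
  expect_equal(empiricalPvalues(mkfit(0.001, pool))$p_empirical, 0)
  expect_equal(empiricalPvalues(mkfit(0.45, pool))$p_empirical, 0.5)
  # brute-force count on random pools, all pooling modes
  set.seed(36)
  for (i in 1:20) {
    pool <- runif(50)
    nom <- runif(1)
    expect_equal(empiricalPvalues(mkfit(nom, pool))$p_empirical,
                 sum(pool < nom) / 50)
    expect_equal(empiricalPvalues(mkfit(nom, pool),
                                  pooling = "per_pair")$p_empirical,
                 sum(pool < nom) / 50)
    expect_equal(empiricalPvalues(mkfit(nom, pool), plusOne = TRUE)$p_empirical,
                 (sum(pool < nom) + 1) / 51)
  }
  expect_error(empiricalPvalues(list(results = data.frame(),
                                     permP = list(g = NULL))), "empty pool")
})

test_that("BH adjustment reproduces the step-up hand computations", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(0.3), 0.3)
  expect_equal(bhAdjust(c(0.001, 0.5)), c(0.002, 0.5))
})

test_that("variants are classified apaQTL / null / gray exhaustively", {
  res <- data.frame(
    gene_id = c("g1", "g1", "g2", "g2", "g3"),
    variant_id = c("vA", "vB", "vA", "vC", "vD"),
    p_nominal = c(1e-5, 0.5, 0.2, 0.05, 0.3),
    p_corrected = c(0.04, 0.9, 0.6, 0.2, 0.8),
    status = "ok", stringsAsFactors = FALSE)
  calls <- classifyVariants(res)
  cls <- setNames(calls$class, calls$variant_id)
  expect_equal(unname(cls["vA"]), "apaQTL")   # min corrected 0.04
  expect_equal(unname(cls["vB"]), "null")     # nominal 0.5 > 0.1
  expect_equal(unname(cls["vC"]), "gray")     # nominal 0.05 but ns
  expect_equal(unname(cls["vD"]), "null")
  expect_setequal(calls$class, c("apaQTL", "null", "gray"))
  expect_equal(calls$best_gene[calls$variant_id == "vA"], "g1")
})

test_that("adjusting for a confounding PC removes spurious associations", {
  # population PC drives both genotype frequency and phenotype
  set.seed(37)
  study <- simulateApaStudy("structured", seed = 37, nGenes = 12,
                            nIndividuals = 120, nVariantsPerGene = 12,
                            divergence = 0.3, subpopShift = 1.2)
  pca <- genotypePCA(study$geno, k = 2)
  raw <- mapApaQtl(study$mm, study$geno, study$windows, permutations = 0)
  adj <- mapApaQtl(study$mm, study$geno, study$windows,
                   covariates = pca$gpcs, permutations = 0)
  fpRaw <- mean(raw$results$p_nominal < 0.05, na.rm = TRUE)
  fpAdj <- mean(adj$results$p_nominal < 0.05, na.rm = TRUE)
  expect_gt(fpRaw, fpAdj)
  expect_lt(fpAdj, 0.12)
})
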