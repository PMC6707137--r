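# shared toy geometry: one + strand gene with PRE [100,250), POST [250,400)
toySegments <- function(strand = "+") {
  if (strand == "+")
    makeSegments("G", "chr1", "+", list(c(100, 250)), list(c(250, 400)))
  else
    makeSegments("G", "chr1", "-", list(c(250, 400)), list(c(100, 250)))
}
toyModels <- function(strand = "+")
  makeModels("G", "chr1", strand, 100, 400)

test_that("allele windows are sense-strand and clipped", {
  base <- strrep("C", 500)
  gs <- paste0(substr(base, 1, 200), "ATGCA", substr(base, 206, 500))
  genome <- DNAStringSet(c(chr1 = gs))
  vr <- GRanges("chr1", IRanges(203, width = 1))
  mcols(vr) <- DataFrame(id = "v1", ref = "G", alt = "T", vclass = "SNP")
  geno <- new("GenotypeMatrix", ranges = vr,
              dosages = matrix(0L, 1, 2, dimnames = list(NULL, c("a", "b"))))
  w <- alleleWindows(geno, genome, toyModels("+"))
  expect_equal(nchar(w$ref_seq), 21L)
  expect_equal(w$var_offset, 11L)
  expect_equal(substr(w$ref_seq, 11, 11), "G")
  expect_equal(substr(w$alt_seq, 11, 11), "T")
  # minus-strand gene: windows are reverse complements
  wм <- alleleWindows(geno, genome, toyModels("-"))
  expect_equal(wм$ref_seq,
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAStringSet(w$ref_seq))))
  expect_equal(wм$var_offset, 11L)
  # indels are rejected
  bad <- geno
  mcols(bad@ranges)$vclass <- "indel"
  expect_error(alleleWindows(bad, genome, toyModels("+")), "SNP")
})

test_that("PAS alteration calls every transition, with the distance gate", {
  pas <- c("AATAAA", "ATTAAA", "AATGAA")
  seg <- toySegments("+")
  geno <- makeGeno(matrix(0L, 1, 2), pos = 204, ids = "v1")
  site <- function(pos1) {
    s <- GRanges("chr1", IRanges(pos1, width = 1), strand = "+")
    mcols(s) <- DataFrame(site_id = "p1"); s
  }
  mkw <- function(ref, alt)
    makeWindows("v1", "G", ref, alt, 11, 203)
  flank <- strrep("C", 7)
  # interconversion toward the canonical signal (an AATGAA -> AATAAA swap)
  w <- mkw(paste0(flank, "AATGAA", flank), paste0(flank, "AATAAA", flank))
  call <- pasAlteration(w, geno, site(251), seg, pas)
  expect_equal(call$status, "interconverted")
  # creation and destruction are symmetric under REF/ALT swap
  w2 <- mkw(paste0(flank, "AATCAA", flank), paste0(flank, "AATAAA", flank))
  expect_equal(pasAlteration(w2, geno, site(251), seg, pas)$status, "created")
  w2s <- mkw(paste0(flank, "AATAAA", flank), paste0(flank, "AATCAA", flank))
  expect_equal(pasAlteration(w2s, geno, site(251), seg, pas)$status,
               "destroyed")
  # every catalog hexamer is detected when gained
  for (m in pas) {
    wm <- mkw(paste0(flank, "CCCCCC", flank), paste0(flank, m, flank))
    expect_equal(pasAlteration(wm, geno, site(251), seg, pas)$status,
                 "created")
  }
  # site too far (150 nt) or too close (5 nt): not a candidate
  expect_equal(nrow(pasAlteration(w, geno, site(354), seg, pas)), 0L)
  expect_equal(nrow(pasAlteration(w, geno, site(209), seg, pas)), 0L)
  # no PAS occurrence in either allele: no call
  wn <- mkw(paste0(flank, "CCCCCC", flank), paste0(flank, "CCCCGC", flank))
  expect_equal(nrow(pasAlteration(wn, geno, site(251), seg, pas)), 0L)
})

test_that("microRNA site classes and transitions follow the hierarchy", {
  fam <- data.frame(family_id = "fam1", seed = "CCUUCAA",
                    conservation = "broadly conserved", conserved = TRUE,
                    expressed = TRUE, stringsAsFactors = FALSE)
  seg <- toySegments("+")
  # m8 site = TTGAAGG (revcomp of seed), A1 site = TGAAGG + A
  mkw <- function(ref, alt, off = 8)
    makeWindows("v1", "G", ref, alt, off, 300)   # pos0 300 is in POST
  pad <- function(core) paste0("CCC", core, strrep("C", 18 - nchar(core)))
  # gain of an 8mer from nothing
  w <- mkw(pad("TTGCAGGA"), pad("TTGAAGGA"))
  call <- mirnaSiteAlteration(w, fam, seg)
  expect_equal(call$status, "created")
  expect_match(call$detail, "alt=8mer")
  # 8mer -> 7mer-m8 (weakened)
  w2 <- mkw(pad("TTGAAGGA"), pad("TTGAAGGC"), off = 11)
  call2 <- mirnaSiteAlteration(w2, fam, seg)
  expect_equal(call2$status, "weakened")
  expect_match(call2$detail, "ref=8mer;alt=7mer-m8")
  # 7mer-A1 -> 8mer (strengthened): gaining the m8-position match
  w3 <- mkw(pad("CTGAAGGA"), pad("TTGAAGGA"), off = 4)
  call3 <- mirnaSiteAlteration(w3, fam, seg)
  expect_equal(call3$status, "strengthened")
  expect_match(call3$detail, "ref=7mer-A1;alt=8mer")
  # symmetric destruction
  w4 <- mkw(pad("TTGAAGGA"), pad("TTGCAGGA"))
  expect_equal(mirnaSiteAlteration(w4, fam, seg)$status, "destroyed")
  # PRE-segment variants are not candidates
  wPre <- makeWindows("v1", "G", pad("TTGCAGGA"), pad("TTGAAGGA"), 8, 150)
  expect_equal(nrow(mirnaSiteAlteration(wPre, fam, seg)), 0L)
  # unexpressed or unconserved families are not scanned
  famOff <- fam; famOff$expressed <- FALSE
  expect_equal(nrow(mirnaSiteAlteration(w, famOff, seg)), 0L)
})

test_that("PWM scanning matches brute force and its identities", {
  # consensus scores the perfect match
  pwm <- consensusPwm("ACGT")
  sc <- pwmScan("CCACGTCC", pwm)
  expect_equal(sc$best, sc$perfect)
  expect_equal(sc$bestOffset, 3L)
  # uniform matrix against uniform background scores 0 everywhere
  expect_equal(pwmScan("ACGTACG", uniformPwm(3))$best, 0)
  # random sequences vs an independent all-offsets oracle
  set.seed(51)
  for (i in 1:200) {
    L <- sample(2:5, 1)
    m <- matrix(runif(4 * L), 4, L,
                dimnames = list(c("A", "C", "G", "T"), NULL))
    m <- sweep(m, 2, colSums(m), "/")
    bg <- runif(4, 0.1, 0.4); bg <- bg / sum(bg)
    names(bg) <- c("A", "C", "G", "T")
    motif <- list(motif_id = "m", rbp_id = "m", matrix = m,
                  background = bg, expressed = TRUE)
    seq <- paste(sample(c("A", "C", "G", "T"), 12, TRUE), collapse = "")
    got <- pwmScan(seq, motif)
    # oracle: enumerate offsets with plain arithmetic
    best <- -Inf
    for (q in 1:(12 - L + 1)) {
      s <- 0
      for (k in 1:L) {
        b <- substr(seq, q + k - 1, q + k - 1)
        s <- s + log2(m[b, k] / bg[b])
      }
      best <- max(best, s)
    }
    expect_equal(got$best, best, tolerance = 1e-12)
  }
})

test_that("RBP alteration uses the strict 80%-of-perfect rule", {
  # 5-column motif: columns 1-4 prefer T (0.9); column 5 has A at 0.5 and
  # G at a probability tuned so a G at that position gives a best/perfect
  # ratio of exactly {0.79, 0.80, 0.81}
  H <- log2(0.9 / 0.25)
  perfectBits <- 4 * H + log2(0.5 / 0.25)
  mk <- function(ref, alt) makeWindows("v1", "G", ref, alt, 15, 300)
  pad <- function(core) paste0(strrep("C", 10), core, strrep("C", 6))
  for (target in c(0.79, 0.80, 0.81)) {
    g <- 0.25 * 2^(target * perfectBits - 4 * H)
    mat <- matrix(0.1 / 3, 4, 5,
                  dimnames = list(c("A", "C", "G", "T"), NULL))
    mat["T", 1:4] <- 0.9
    mat[, 5] <- c(A = 0.5, C = (0.5 - g) / 2, G = g, T = (0.5 - g) / 2)
    pw <- list(motif_id = "M", rbp_id = "M", matrix = mat,
               background = c(A = .25, C = .25, G = .25, T = .25),
               expressed = TRUE)
    # engineered ratio check
    sc <- pwmScan("TTTTG", pw)
    expect_equal(sc$best / sc$perfect, target, tolerance = 1e-12)
    # variant at column 5: REF = G (ratio = target), ALT = A (ratio 1)
    w <- mk(pad("TTTTG"), pad("TTTTA"))
    calls <- rbpMotifAlteration(w, pw)
    if (target > 0.8) {
      expect_equal(nrow(calls), 0L)          # both alleles above threshold
    } else {
      expect_equal(calls$status, "created")  # strictly one allele (0.80
    }                                        # excluded by the strict rule)
    # symmetric destruction
    callsS <- rbpMotifAlteration(mk(pad("TTTTA"), pad("TTTTG")), pw)
    if (target > 0.8) expect_equal(nrow(callsS), 0L)
    else expect_equal(callsS$status, "destroyed")
  }
  # unexpressed motifs are skipped
  off <- consensusPwm("TTTTA"); off$expressed <- FALSE
  expect_equal(nrow(rbpMotifAlteration(mk(pad("TTTTG"), pad("TTTTA")), off)),
               0L)
})

test_that("expression filters apply the >0-in-half rule and family OR", {
  expr <- rbind(a = c(1, 2, 3, 0, 0), b = c(1, 0, 0, 0, 0),
                c = c(0, 0, 0, 0, 0), d = c(1, 1, 0, 0, 0))
  f <- expressionFilter(expr)
  expect_equal(unname(f), c(TRUE, FALSE, FALSE, FALSE))
  # exactly 50% counts as expressed (3-sample example: 2 of 4)
  expect_true(expressionFilter(rbind(x = c(1, 2, 0, 0)))[["x"]])
  fam <- familyExpressed(f, data.frame(member = c("a", "b", "c", "d"),
                                       family = c("F1", "F1", "F2", "F2")))
  expect_true(fam[["F1"]])
  expect_false(fam[["F2"]])
})

test_that("motif resources load from their text formats", {
  # PAS list
  fp <- tempfile(); writeLines(c("AAUAAA", "AUUAAA", "AATGAA"), fp)
  pas <- readPasMotifs(fp)
  expect_equal(pas, c("AATAAA", "ATTAAA", "AATGAA"))
  # seed TSV
  fs <- tempfile()
  writeLines(c("family_id\tseed\tconservation",
               "miR-1\tGGAAUGU\tbroadly conserved",
               "miR-2\tCAGUGCA\tpoor"), fs)
  seeds <- readMirnaSeeds(fs)
  expect_equal(seeds$seed[1], "GGAATGT")
  expect_equal(seeds$conserved, c(TRUE, FALSE))
  # simple PWM format
  fw <- tempfile()
  writeLines(c(">M1 RBP1", "0.7 0.1 0.1 0.1", "0.1 0.7 0.1 0.1"), fw)
  pw <- readPwms(fw)
  expect_equal(dim(pw$M1$matrix), c(4L, 2L))
  expect_equal(pw$M1$matrix["A", 1], 0.7)
  # MEME-like dialect
  fm <- tempfile()
  writeLines(c("MEME version 4", "", "MOTIF M2 RBP2",
               "letter-probability matrix: alength= 4 w= 2",
               " 0.25 0.25 0.25 0.25", " 0.40 0.30 0.20 0.10"), fm)
  pm <- readPwms(fm)
  expect_equal(unname(pm$M2$matrix["C", 2]), 0.30)
  # invalid columns rejected
  fb <- tempfile()
  writeLines(c(">bad x", "0.5 0.1 0.1 0.1"), fb)
  expect_error(readPwms(fb), "sum to 1")
})
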