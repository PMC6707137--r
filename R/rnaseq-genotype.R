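#' @importFrom Rsamtools pileup PileupParam BamFile
#' @importFrom stats pchisq dbinom binom.test kruskal.test
NULL

#' Count alleles at a SNP position from RNA-seq alignments
#'
#' Base calls at the exact SNP coordinate from primary alignments with
#' mapping quality at or above `minMapq`.
#'
#' @param file BAM (or SAM) file for one sample
#' @param chrom,pos 1-based SNP coordinate
#' @param ref,alt SNP alleles (single bases)
#' @param minMapq minimum mapping quality (default 20)
#' @param minBaseQ minimum base quality (default 0; RNA-seq base qualities
#'   are typically already filtered upstream)
#' @return data.frame: `ref_count`, `alt_count`, `other_count`
#' @export
countAllelesAtSite <- function(file, chrom, pos, ref, alt,
                               minMapq = 20L, minBaseQ = 0L) {
  if (grepl("\\.sam$", file)) file <- asBam(file, tempfile(), overwrite = TRUE)
  which <- GRanges(chrom, IRanges(pos, pos))
  p <- pileup(BamFile(file),
              scanBamParam = ScanBamParam(which = which,
                flag = scanBamFlag(isUnmappedQuery = FALSE,
                                   isSecondaryAlignment = FALSE)),
              pileupParam = PileupParam(max_depth = 1e6,
                min_mapq = minMapq, min_base_quality = minBaseQ,
                distinguish_strands = FALSE, distinguish_nucleotides = TRUE,
                include_deletions = FALSE))
  p <- p[p$pos == pos, , drop = FALSE]
  cnt <- function(b) sum(p$count[p$nucleotide == b])
  data.frame(ref_count = cnt(ref), alt_count = cnt(alt),
             other_count = sum(p$count) - cnt(ref) - cnt(alt))
}

#' Call a genotype from allele counts
#'
#' Initial call: homozygous when a single allele accounts for every read,
#' heterozygous as soon as both alleles are observed (a single discordant
#' read suffices).  A QC stage then demands total depth at least `minDepth`
#' and, for heterozygous calls, either a minor-allele fraction of at least
#' `minMinorFrac` or a binomial test rejecting a sequencing-error origin of
#' the minor allele at error rate `maxErrorRate`; failures become missing.
#'
#' @param refCount,altCount read counts supporting each allele
#' @param otherCount reads with neither allele (default 0); if they outnumber
#'   ref+alt the call is missing
#' @param minDepth minimum ref+alt depth (default 5)
#' @param minMinorFrac minimum minor-allele fraction for a het call (0.2)
#' @param maxErrorRate per-base sequencing error rate for the binomial
#'   fallback (default 0.01)
#' @return data.frame: `call` (0/1/2, `NA` missing), `qc_pass`, `depth`
#' @export
callGenotype <- function(refCount, altCount, otherCount = 0L,
                         minDepth = 5L, minMinorFrac = 0.2,
                         maxErrorRate = 0.01) {
  n <- max(length(refCount), length(altCount))
  refCount <- rep_len(refCount, n); altCount <- rep_len(altCount, n)
  otherCount <- rep_len(otherCount, n)
  out <- data.frame(call = rep(NA_integer_, n), qc_pass = FALSE,
                    depth = refCount + altCount)
  for (i in seq_len(n)) {
    d <- refCount[i] + altCount[i]
    if (d == 0 || otherCount[i] > d) next
    call <- if (refCount[i] == 0L) 2L else if (altCount[i] == 0L) 0L else 1L
    if (d < minDepth) next
    if (call == 1L) {
      minor <- min(refCount[i], altCount[i])
      pErr <- stats::binom.test(minor, d, p = maxErrorRate,
                                alternative = "greater")$p.value
      if (minor / d < minMinorFrac && pErr >= 0.05) next
    }
    out$call[i] <- call
    out$qc_pass[i] <- TRUE
  }
  out
}

#' Hardy-Weinberg chi-square test
#'
#' Pearson chi-square (df = 1) of observed genotype counts against the
#' proportions expected from the observed allele frequencies.  Monomorphic
#' samples give statistic 0, p = 1 with a `degenerate` flag.
#'
#' @param n0,n1,n2 counts of reference homozygotes, heterozygotes and
#'   alternative homozygotes
#' @return list: `chisq`, `p`, `df`, `degenerate`
#' @export
hweChisq <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  stopifnot(n > 0)
  p <- (2 * n0 + n1) / (2 * n)
  q <- 1 - p
  if (p == 0 || q == 0)
    return(list(chisq = 0, p = 1, df = 1L, degenerate = TRUE))
  e <- n * c(p^2, 2 * p * q, q^2)
  stat <- sum((c(n0, n1, n2) - e)^2 / e)
  list(chisq = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       df = 1L, degenerate = FALSE)
}

#' Exact Hardy-Weinberg test
#'
#' Conditional-on-allele-counts exact test: the two-sided p-value is the
#' total probability of heterozygote counts no more likely than the observed
#' one.
#'
#' @inheritParams hweChisq
#' @return p-value
#' @export
hweExact <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  nA <- 2 * n0 + n1           # rarer allele count computed below
  nB <- 2 * n2 + n1
  nMin <- min(nA, nB)
  hets <- seq.int(nMin %% 2, nMin, by = 2)
  logProb <- vapply(hets, function(h) {
    hom1 <- (nMin - h) / 2
    hom2 <- n - h - hom1
    lgamma(n + 1) - lgamma(hom1 + 1) - lgamma(h + 1) - lgamma(hom2 + 1) +
      h * log(2) + lgamma(nMin + 1) + lgamma(2 * n - nMin + 1) -
      lgamma(2 * n + 1)
  }, numeric(1))
  pr <- exp(logProb - max(logProb))
  pr <- pr / sum(pr)
  obs <- pr[match(n1, hets)]
  min(1, sum(pr[pr <= obs + 1e-12]))
}

#' Kruskal-Wallis test of m/M values across genotypes
#'
#' Rank-based H statistic with tie correction and a chi-square p-value with
#' df = number of genotype groups - 1.  Samples with missing calls or
#' missing m/M are excluded.
#'
#' @param values numeric vector of (log2) m/M values per sample
#' @param calls genotype vector (0/1/2, `NA` missing), aligned with `values`
#' @return list: `H`, `p`, `df`, `nPerGroup`
#' @export
kruskalByGenotype <- function(values, calls) {
  ok <- !is.na(values) & !is.na(calls)
  values <- values[ok]; calls <- factor(calls[ok])
  if (nlevels(calls) < 2L) stop("need at least 2 genotype groups")
  if (length(unique(values)) == 1L)
    return(list(H = 0, p = 1, df = nlevels(calls) - 1L,
                nPerGroup = table(calls)))
  kt <- stats::kruskal.test(values, calls)
  list(H = unname(kt$statistic), p = kt$p.value,
       df = unname(kt$parameter), nPerGroup = table(calls))
}
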