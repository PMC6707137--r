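#' @importFrom tools md5sum
#' @importFrom jsonlite toJSON write_json
NULL

#' Pipeline run configuration
#'
#' All stage parameters default to the study conventions: conservative MAF
#' filter > 0.05, 1 Mbp cis flank, 100 permutation rounds, corrected
#' empirical p < 0.05, nominal null cut 0.1, tagging r² > 0.8, pruning
#' windows of 50 SNPs stepped by 5 at r² 0.8, 3 genotype PCs.  Unknown keys
#' are rejected.
#'
#' @param gtf transcript annotation GTF
#' @param polyaBed poly(A) site catalog BED
#' @param geneMap transcript-to-gene TSV (`transcript_id`, `gene_id`)
#' @param counts precomputed PRE/POST counts TSV (alternative to `bamList`)
#' @param bamList named character vector of BAM files per sample
#' @param vcf genotype VCF
#' @param outDir output directory
#' @param autosomes allowed chromosomes for gene filtering
#' @param mafMin strict conservative-MAF lower bound for tested variants
#' @param flank cis window flank (bp)
#' @param permutations permutation rounds
#' @param alpha corrected-empirical significance threshold
#' @param nullCut nominal-p floor defining null variants
#' @param tagR2 tagging r² threshold
#' @param pruneWindow,pruneStep,pruneR2 LD pruning parameters
#' @param kPcs number of genotype PCs
#' @param maxMissing per-gene missing-cell bound (NULL = 27% rule)
#' @param minSegmentLen minimum PRE/POST length (bp)
#' @param seed RNG seed
#' @return validated config list of class `apaRunConfig`
#' @export
apaRunConfig <- function(gtf = NULL, polyaBed = NULL, geneMap = NULL,
                         counts = NULL, bamList = NULL, vcf = NULL,
                         outDir = "apaqtl_out",
                         autosomes = paste0("chr", 1:22),
                         mafMin = 0.05, flank = 1e6, permutations = 100L,
                         alpha = 0.05, nullCut = 0.1, tagR2 = 0.8,
                         pruneWindow = 50L, pruneStep = 5L, pruneR2 = 0.8,
                         kPcs = 3L, maxMissing = NULL, minSegmentLen = 1L,
                         seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "apaRunConfig"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys are [apaRunConfig()] arguments
#' @return `apaRunConfig` list
#' @export
readRunConfig <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required to read config files")
  vals <- yaml::read_yaml(path)
  known <- names(formals(apaRunConfig))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(apaRunConfig, vals)
}

.logLine <- function(con, stage, event, ...) {
  rec <- c(list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                stage = stage, event = event), list(...))
  writeLines(as.character(jsonlite::toJSON(rec, auto_unbox = TRUE)), con)
  message("[", stage, "] ", event,
          if (length(list(...)))
            paste0(" (", paste(names(list(...)), unlist(list(...)),
                               sep = "=", collapse = ", "), ")") else "")
}

#' Run the apaQTL pipeline
#'
#' Executes the requested stages in dependency order (`annotate` ->
#' `quantify` -> `genotypes` -> `map`), each reading its inputs from the
#' config or from the outputs of earlier stages in `outDir`.  Every run
#' writes a resolved-config copy, a JSON-lines log with the counts at every
#' filtering step, and a manifest of output checksums; re-running with
#' unchanged inputs reproduces identical outputs.
#'
#' @param config an `apaRunConfig` (or YAML path)
#' @param stages subset of `c("annotate", "quantify", "genotypes", "map")`
#' @return invisibly, the manifest data.frame (file, md5)
#' @export
runApaPipeline <- function(config,
                           stages = c("annotate", "quantify", "genotypes",
                                      "map")) {
  if (is.character(config)) config <- readRunConfig(config)
  order <- c("annotate", "quantify", "genotypes", "map")
  stages <- order[order %in% stages]
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$outDir, f)
  logCon <- file(out("run_log.jsonl"), "a")
  on.exit(close(logCon))
  cfgCopy <- config; class(cfgCopy) <- NULL
  jsonlite::write_json(cfgCopy[!vapply(cfgCopy, is.null, logical(1))],
                       out("resolved_config.json"), auto_unbox = TRUE)
  need <- function(f, stage)
    if (!file.exists(out(f)))
      stop("missing dependency output '", f, "': run the ", stage,
           " stage first")

  if ("annotate" %in% stages) {
    tx <- readTranscriptsGtf(config$gtf)
    gm <- utils::read.table(config$geneMap, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    models <- collapseGeneModels(tx, gm)
    sites <- readPolyABed(config$polyaBed)
    segs <- defineApaSegments(models, sites,
                              minSegmentLen = config$minSegmentLen)
    writeSegmentsGtf(segs$segments, out("segments.gtf"))
    utils::write.table(rbind(excludedGenes(models), segs$excluded),
                       out("excluded_genes.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    .logLine(logCon, "annotate", "done",
             genes = length(geneIds(models)),
             with_segments = nrow(segmentTable(segs$segments)),
             excluded = nrow(segs$excluded) + nrow(excludedGenes(models)))
  }

  if ("quantify" %in% stages) {
    need("segments.gtf", "annotate")
    segments <- readSegmentsGtf(out("segments.gtf"))
    counts <- if (!is.null(config$counts)) readSegmentCounts(config$counts)
      else countSegmentReads(config$bamList, segments)
    mm <- computeMM(counts, segments)
    # chromosome filter straight off the segments (collapsed models not
    # needed again at this stage)
    st <- segmentTable(segments)
    keep <- st$chrom[match(mmGenes(mm), st$gene_id)] %in% config$autosomes
    maxMiss <- if (is.null(config$maxMissing))
      ceiling(0.27 * length(mmSamples(mm))) else config$maxMissing
    keep <- keep & rowSums(mmMask(mm)) < maxMiss
    mm <- new("MMatrix", values = mmValues(mm)[keep, , drop = FALSE],
              mask = mmMask(mm)[keep, , drop = FALSE])
    writeMMatrix(mm, out("mm_matrix.tsv"))
    writeMMatrix(mm, out("mm_matrix_log2.tsv"), log2 = TRUE)
    .logLine(logCon, "quantify", "done", genes_kept = nrow(mmValues(mm)),
             genes_dropped = sum(!keep), samples = length(mmSamples(mm)))
  }

  if ("genotypes" %in% stages) {
    geno <- readVcfGenotypes(config$vcf)
    pca <- genotypePCA(geno, k = config$kPcs,
                       windowSnps = config$pruneWindow,
                       stepSnps = config$pruneStep, r2Max = config$pruneR2)
    utils::write.table(data.frame(sample_id = rownames(pca$gpcs), pca$gpcs),
                       out("genotype_pcs.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    .logLine(logCon, "genotypes", "done",
             variants_used = pca$nVariantsUsed, pcs = ncol(pca$gpcs))
  }

  if ("map" %in% stages) {
    need("mm_matrix.tsv", "quantify")
    need("segments.gtf", "annotate")
    mm <- readMMatrix(out("mm_matrix.tsv"))
    segments <- readSegmentsGtf(out("segments.gtf"))
    geno <- readVcfGenotypes(config$vcf, samples = mmSamples(mm))
    maf <- variantMaf(geno, mode = "conservative")
    common <- maf > config$mafMin
    .logLine(logCon, "map", "maf_filter", tested = sum(common),
             dropped_rare = sum(!common))
    geno <- geno[common]
    # cis windows from the segment spans (TSS/TES of the two-segment model)
    st <- segmentTable(segments)
    st <- st[st$gene_id %in% mmGenes(mm), ]
    gr <- GRanges(st$chrom, IRanges(pmin(st$pre_start, st$post_start) + 1,
                                    pmax(st$pre_end, st$post_end)),
                  strand = st$strand)
    mcols(gr) <- DataFrame(gene_id = st$gene_id, cds_start = NA_real_,
                           cds_end = NA_real_)
    models <- new("GeneModelSet", genes = gr,
                  exons = GRangesList(lapply(seq_along(gr), function(i)
                    granges(gr[i]))),
                  excluded = data.frame(gene_id = character(),
                                        reason = character()))
    windows <- cisWindows(models, flank = config$flank)
    gpcsFile <- out("genotype_pcs.tsv")
    cov <- if (file.exists(gpcsFile)) {
      pcs <- utils::read.table(gpcsFile, header = TRUE, sep = "\t")
      as.matrix(pcs[match(mmSamples(mm), pcs$sample_id), -1, drop = FALSE])
    } else NULL
    fit <- mapApaQtl(mm, geno, windows, covariates = cov,
                     permutations = config$permutations, seed = config$seed)
    res <- empiricalPvalues(fit)
    res$p_corrected <- bhAdjust(res$p_empirical)
    calls <- classifyVariants(res, alpha = config$alpha,
                              nullCut = config$nullCut)
    utils::write.table(res, out("associations.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    sig <- res[!is.na(res$p_corrected) & res$p_corrected < config$alpha, ]
    utils::write.table(sig, out("significant_pairs.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(calls, out("variant_classes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    .logLine(logCon, "map", "done", models = nrow(res),
             significant = nrow(sig),
             apaqtls = sum(calls$class == "apaQTL"),
             null = sum(calls$class == "null"),
             gray = sum(calls$class == "gray"))
  }

  files <- setdiff(list.files(config$outDir, full.names = TRUE),
                   c(out("manifest.tsv"), out("run_log.jsonl")))
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  utils::write.table(manifest, out("manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
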