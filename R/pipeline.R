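#' Export Manhattan-plot tables, one per block size
#'
#' Writes \code{manhattan_<s>snp.tsv} for each block size present (columns
#' \code{chrom, position, neglog10_p, n_snps, significance}; position is
#' the block midpoint; only converged fits are exported) plus a sidecar
#' \code{manhattan_thresholds.json} holding both threshold lines. Plot
#' rendering is left to the caller; the exported tables are the interface.
#'
#' @param scan a \linkS4class{ScanResult}, normally after
#'   [callSignificant()].
#' @param ts a \linkS4class{ThresholdSet}.
#' @param dir output directory (created if needed).
#' @return invisible character vector of written paths.
#' @export
manhattanExport <- function(scan, ts, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  res <- scan@results
  if (!nrow(res)) stop("manhattanExport: empty scan")
  res <- res[res$converged, , drop = FALSE]
  if (!"significance" %in% names(res)) res$significance <- "none"
  paths <- character(0)
  for (s in sort(unique(res$n_snps))) {
    sub <- res[res$n_snps == s, , drop = FALSE]
    df <- data.frame(chrom = sub$chrom,
                     position = floor((sub$start_bp + sub$end_bp) / 2),
                     neglog10_p = -log10(sub$p),
                     n_snps = sub$n_snps,
                     significance = sub$significance)
    p <- file.path(dir, sprintf("manhattan_%dsnp.tsv", s))
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  side <- file.path(dir, "manhattan_thresholds.json")
  jsonlite::write_json(
    list(bon_threshold = ts@bon, mbon_threshold = ts@mbon,
         bon_line = -log10(ts@bon), mbon_line = -log10(ts@mbon)),
    side, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, side))
}

.stageFail <- function(stage, msg) {
  stop(sprintf("[%s] %s", stage, msg), call. = FALSE)
}

.defaultRunConfig <- function() {
  list(min_maf = 0.05, max_block_snps = 4L, min_hap_count = 5L,
       alpha = 0.05, m_eff_method = "liJi", blocks = "gabriel")
}

#' Run the full haplotype-block GWAS pipeline
#'
#' Config-driven end-to-end run: simulate (or load) phased genotypes and a
#' phenotype, MAF-filter, detect blocks, scan, derive thresholds, call
#' significance, export Manhattan tables and (when annotation inputs are
#' given) nearest-gene and QTL-overlap reports. All outputs land in
#' \code{outDir} along with a machine-readable \code{manifest.json}
#' (settings, seed, package version); a rerun from the same settings
#' reproduces the outputs bit-for-bit. A failing stage aborts with the
#' stage name in the error.
#'
#' Config entries (a named list, or a path to a YAML file with the same
#' keys): either \code{simulate} (a list of [simConfig()] arguments,
#' \code{seed} mandatory) or \code{vcf} + \code{phenotype_tsv}; optional
#' \code{gene_annotation}, \code{qtl_table}, \code{covariates_tsv}; tuning
#' keys \code{min_maf} (0.05), \code{max_block_snps} (4),
#' \code{min_hap_count} (5), \code{alpha} (0.05), \code{m_eff_method}
#' (\code{"liJi"}), \code{blocks} (\code{"gabriel"} or, for simulated
#' data, \code{"planted"}).
#'
#' @param config named list or YAML path.
#' @param outDir run directory (created; user-named, no timestamps, for
#'   reproducibility).
#' @return invisibly, a list with the scan, thresholds, blocks and the
#'   output paths.
#' @export
runPipeline <- function(config, outDir) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  cfg <- modifyList(.defaultRunConfig(), config)
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  paths <- list()

  ## ---- inputs: simulate or load ----
  if (!is.null(cfg$simulate)) {
    sc <- tryCatch(do.call(simConfig, cfg$simulate),
                   error = function(e) .stageFail("simulate", conditionMessage(e)))
    geno <- simulateGenotypes(sc)
    sim <- simulatePhenotypes(geno, sc)
    phen <- sim$phenotype
    paths$vcf <- writePhasedVcf(geno, file.path(outDir, "genotypes.vcf"))
    paths$phenotype <- writePhenotypeTsv(phen, file.path(outDir, "phenotype.tsv"))
    paths$truth <- writeTruthJson(sim$truth, file.path(outDir, "truth.json"))
  } else {
    if (is.null(cfg$vcf))
      .stageFail("load", "config needs either 'simulate' or 'vcf'")
    geno <- tryCatch(readPhasedVcf(cfg$vcf),
                     error = function(e) .stageFail("load", conditionMessage(e)))
    if (is.null(cfg$phenotype_tsv))
      .stageFail("scan", "no phenotype file configured")
    phen <- tryCatch(readPhenotypeTsv(cfg$phenotype_tsv),
                     error = function(e) .stageFail("scan", conditionMessage(e)))
  }

  ## ---- filter, kinship, blocks ----
  geno <- mafFilter(geno, cfg$min_maf)
  if (nMarkers(geno) < 2L)
    .stageFail("filter", "fewer than 2 markers survive the MAF filter")
  kin <- grm(geno)
  blocks <- tryCatch({
    if (identical(cfg$blocks, "planted")) plantedBlocks(geno)
    else gabrielBlocks(geno, maxSnps = cfg$max_block_snps)
  }, error = function(e) .stageFail("blocks", conditionMessage(e)))
  paths$blocks <- writeBlockTable(blocks, geno,
                                  file.path(outDir, "blocks.tsv"))

  ## ---- scan, thresholds, significance ----
  X <- NULL
  if (!is.null(cfg$covariates_tsv)) {
    cv <- read.table(cfg$covariates_tsv, sep = "\t", header = TRUE)
    X <- as.matrix(cv[match(individualIds(geno), cv[[1L]]), -1L, drop = FALSE])
  }
  scan <- tryCatch(
    scanBlocks(geno, phen, blocks, kinship = kin, X = X,
               minHapCount = cfg$min_hap_count),
    error = function(e) .stageFail("scan", conditionMessage(e)))
  if (nrow(scan@results)) {
    tested <- names(scan@fits)
    testedBlocks <- blocks[vapply(blocks, function(b)
      b@blockId %in% tested, logical(1))]
    meff <- effectiveTests(leadSnpCorrelation(geno, testedBlocks),
                           method = cfg$m_eff_method)
    ts <- thresholdSet(cfg$alpha, nrow(scan@results), meff)
    scan <- callSignificant(scan, ts)
    paths$thresholds <- writeThresholdJson(ts, file.path(outDir, "thresholds.json"))
    paths$manhattan <- manhattanExport(scan, ts, outDir)
  } else {
    ts <- NULL
    message("runPipeline: no testable blocks; thresholds skipped")
  }
  paths$results <- writeResultsTsv(scan, file.path(outDir, "results.tsv"))

  ## ---- annotation (optional) ----
  if (!is.null(cfg$gene_annotation) && nrow(scan@results)) {
    ann <- tryCatch({
      genes <- readGeneAnnotation(cfg$gene_annotation)
      sig <- scan@results[scan@results$significance != "none", , drop = FALSE]
      target <- if (nrow(sig)) sig else scan@results
      snpIdx <- unlist(lapply(blocks, function(b)
        if (b@blockId %in% target$block_id) b@markerIndices else integer(0)))
      snps <- data.frame(
        chrom = as.character(seqnames(geno@map))[snpIdx],
        pos = start(geno@map)[snpIdx])
      nearestGene(snps, genes)
    }, error = function(e) .stageFail("annotate", conditionMessage(e)))
    paths$annotation <- file.path(outDir, "annotation.tsv")
    write.table(ann, paths$annotation, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  if (!is.null(cfg$qtl_table) && nrow(scan@results)) {
    qo <- tryCatch({
      qtls <- readQtlTable(cfg$qtl_table)
      do.call(rbind, lapply(blocks, function(b) {
        hit <- qtlOverlap(b, qtls)
        if (nrow(hit)) cbind(block_id = b@blockId, hit) else NULL
      }))
    }, error = function(e) .stageFail("annotate", conditionMessage(e)))
    paths$qtl <- file.path(outDir, "qtl_overlap.tsv")
    write.table(qo %||% data.frame(block_id = character(0)), paths$qtl,
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  ## ---- manifest ----
  manifest <- list(config = cfg,
                   package = "hapblockEB",
                   version = as.character(packageVersion("hapblockEB")),
                   n_individuals = nIndividuals(geno),
                   n_markers = nMarkers(geno),
                   n_blocks = length(blocks))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  paths$manifest <- file.path(outDir, "manifest.json")
  invisible(list(scan = scan, thresholds = ts, blocks = blocks,
                 genotypes = geno, paths = paths, outDir = outDir))
}
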