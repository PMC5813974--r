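#' Read phased genotypes from a VCF file
#'
#' Accepts the phased, biallelic, GT-only VCF dialect this package writes
#' (and that phasing tools such as BEAGLE emit). Every genotype must be
#' phased (\code{"|"} separator) and called; unphased, missing or
#' multiallelic records are hard errors naming the offending site and
#' sample, because imputation and phasing are upstream concerns.
#'
#' @param path VCF file (plain text or bgzipped; parsed with vcfR).
#' @return a \linkS4class{PhasedGenotypes}.
#' @seealso [writePhasedVcf()]
#' @export
readPhasedVcf <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L,
                                       dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt, fixed = TRUE)
  if (any(multi))
    stop(sprintf("multiallelic site at %s:%s",
                 fix[multi, "CHROM"][1L], fix[multi, "POS"][1L]))
  gt <- v@gt[, -1L, drop = FALSE]  # drop FORMAT column
  samples <- colnames(gt)
  ## FORMAT may carry extra fields; keep the GT token (sub() drops dims)
  gtOnly <- gt
  gtOnly[] <- sub(":.*$", "", gt)
  badFlag <- !grepl("^[01]\\|[01]$", gtOnly)
  dim(badFlag) <- dim(gtOnly)  # grepl drops dims
  bad <- which(badFlag, arr.ind = TRUE)
  if (nrow(bad)) {
    i <- bad[1L, 1L]; j <- bad[1L, 2L]
    stop(sprintf(
      "unphased, missing or non-biallelic genotype '%s' at %s:%s in sample %s",
      gtOnly[i, j], fix[i, "CHROM"], fix[i, "POS"], samples[j]))
  }
  h1 <- t(matrix(as.integer(substr(gtOnly, 1L, 1L)), nrow = nrow(gtOnly)))
  h2 <- t(matrix(as.integer(substr(gtOnly, 3L, 3L)), nrow = nrow(gtOnly)))
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste(fix[, "CHROM"], fix[, "POS"],
                                        sep = "_")[is.na(ids) | ids == "."]
  PhasedGenotypes(h1, h2, chrom = fix[, "CHROM"],
                  pos = as.integer(fix[, "POS"]),
                  ref = fix[, "REF"], alt = alt,
                  individualIds = samples, markerIds = ids)
}

#' Write phased genotypes as a VCF v4.2 subset
#'
#' Emits CHROM, POS, ID, REF, ALT and a GT-only FORMAT with "|" phased
#' calls; round-trips with [readPhasedVcf()] up to header cosmetics.
#'
#' @param geno a \linkS4class{PhasedGenotypes}.
#' @param path output file.
#' @export
writePhasedVcf <- function(geno, path) {
  map <- geno@map
  gtBody <- matrix(paste0(t(geno@hap1), "|", t(geno@hap2)),
                   nrow = nMarkers(geno))
  lines <- c(
    "##fileformat=VCFv4.2",
    "##source=hapblockEB",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", individualIds(geno)), collapse = "\t"),
    paste(as.character(seqnames(map)), start(map), names(map),
          mcols(map)$ref, mcols(map)$alt, ".", "PASS", ".", "GT",
          apply(gtBody, 1L, paste, collapse = "\t"), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a phenotype TSV (id, value)
#'
#' @param path two-column file.
#' @param header whether the file carries a header line.
#' @return named numeric vector.
#' @export
readPhenotypeTsv <- function(path, header = TRUE) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  df <- read.table(path, sep = "\t", header = header,
                   colClasses = c("character", "numeric"))
  setNames(df[[2L]], df[[1L]])
}

#' Per-marker allele frequency table
#'
#' MAF is \code{min(f, 1 - f)} with \code{f} the ALT-allele fraction over
#' the 2n chromosomes; major/minor allele labels are reported alongside.
#'
#' @param geno a \linkS4class{PhasedGenotypes}.
#' @return data.frame with one row per marker: \code{marker, chrom, pos,
#'   ref, alt, altFreq, maf, majorAllele, minorAllele}.
#' @export
computeMaf <- function(geno) {
  stopifnot(nIndividuals(geno) >= 1L)
  map <- geno@map
  f <- (colSums(geno@hap1) + colSums(geno@hap2)) / (2 * nIndividuals(geno))
  altIsMinor <- f <= 0.5
  data.frame(
    marker = names(map),
    chrom = as.character(seqnames(map)),
    pos = start(map),
    ref = mcols(map)$ref,
    alt = mcols(map)$alt,
    altFreq = unname(f),
    maf = unname(pmin(f, 1 - f)),
    majorAllele = ifelse(altIsMinor, mcols(map)$ref, mcols(map)$alt),
    minorAllele = ifelse(altIsMinor, mcols(map)$alt, mcols(map)$ref),
    stringsAsFactors = FALSE)
}

#' Remove markers below a minor-allele-frequency floor
#'
#' Marker order is preserved and the operation is idempotent; with
#' \code{minMaf = 0} it is the identity. May return zero markers.
#'
#' @param geno a \linkS4class{PhasedGenotypes}.
#' @param minMaf frequency floor in [0, 0.5]; default 0.05.
#' @return filtered \linkS4class{PhasedGenotypes}.
#' @export
mafFilter <- function(geno, minMaf = 0.05) {
  stopifnot(minMaf >= 0, minMaf <= 0.5)
  keep <- computeMaf(geno)$maf >= minMaf
  geno[, which(keep)]
}
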