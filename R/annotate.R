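#' Read gene features from GFF3 or BED
#'
#' GFF3 files are reduced to \code{type == "gene"} features; the gene name
#' is taken from the first available of \code{Name}, \code{gene_name},
#' \code{gene_id}, \code{ID}. BED files must carry a name column (BED4+).
#' Parsing is delegated to rtracklayer; coordinates are returned 1-based
#' inclusive in a \code{GRanges} with a \code{gene_name} metadata column.
#' No liftover is attempted: coordinates must match the genotype map build.
#'
#' @param path annotation file.
#' @param format \code{"auto"} (by extension), \code{"gff3"} or \code{"bed"}.
#' @return \code{GRanges} with \code{gene_name}.
#' @export
readGeneAnnotation <- function(path, format = c("auto", "gff3", "bed")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
    format <- if (ext %in% c("gff", "gff3")) "gff3" else "bed"
  }
  gr <- rtracklayer::import(path, format = if (format == "gff3") "GFF3" else "BED")
  if (format == "gff3") {
    if ("type" %in% colnames(mcols(gr)))
      gr <- gr[as.character(gr$type) == "gene"]
    nm <- NULL
    for (col in c("Name", "gene_name", "gene_id", "ID"))
      if (is.null(nm) && col %in% colnames(mcols(gr)))
        nm <- as.character(mcols(gr)[[col]])
    if (is.null(nm)) stop("no gene name attribute found in GFF3")
    mcols(gr) <- DataFrame(gene_name = nm)
  } else {
    if (!"name" %in% colnames(mcols(gr)))
      stop("BED annotation needs a name column (BED4+)")
    mcols(gr) <- DataFrame(gene_name = as.character(gr$name))
  }
  gr
}

#' Read a QTL interval table
#'
#' Headered TSV with columns \code{trait}, \code{chrom}, \code{start_bp},
#' \code{end_bp} (1-based inclusive), mirroring the layout of public QTL
#' databases.
#'
#' @param path TSV file.
#' @return data.frame of QTL intervals.
#' @export
readQtlTable <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE)
  need <- c("trait", "chrom", "start_bp", "end_bp")
  if (!all(need %in% names(df)))
    stop("QTL table needs columns: ", paste(need, collapse = ", "))
  if (any(df$start_bp > df$end_bp)) stop("QTL intervals with start > end")
  df$chrom <- as.character(df$chrom)
  df
}

#' Nearest gene of each SNP within a window
#'
#' Per SNP (as in block report tables, each SNP row carries its own
#' distance): distance 0 and label \code{"Within"} when the position falls
#' inside a gene interval, otherwise the gap to the nearest interval
#' boundary; SNPs with no gene within \code{window} bp (default 50 kb up-
#' and downstream) report no gene. Distance ties are broken by the smaller
#' gene start. Unknown chromosomes yield no gene, with a message rather
#' than an error.
#'
#' @param snps data.frame with \code{chrom} and \code{pos} columns (or a
#'   \code{GRanges}).
#' @param genes \code{GRanges} from [readGeneAnnotation()].
#' @param window maximum distance in bp, default 50000.
#' @return data.frame: \code{chrom, pos, gene, distance, within}; gene is
#'   NA when none is in range.
#' @export
nearestGene <- function(snps, genes, window = 50000L) {
  if (is(snps, "GRanges"))
    snps <- data.frame(chrom = as.character(seqnames(snps)),
                       pos = start(snps))
  gchrom <- as.character(seqnames(genes))
  gstart <- start(genes); gend <- end(genes)
  gname <- mcols(genes)$gene_name
  known <- unique(gchrom)
  out <- lapply(seq_len(nrow(snps)), function(i) {
    cc <- as.character(snps$chrom[i]); pos <- snps$pos[i]
    if (!cc %in% known) {
      message(sprintf("nearestGene: chromosome %s absent from annotation", cc))
      return(data.frame(chrom = cc, pos = pos, gene = NA_character_,
                        distance = NA_real_, within = FALSE))
    }
    j <- which(gchrom == cc)
    dist <- ifelse(pos < gstart[j], gstart[j] - pos,
                   ifelse(pos > gend[j], pos - gend[j], 0))
    inWin <- dist <= window
    if (!any(inWin))
      return(data.frame(chrom = cc, pos = pos, gene = NA_character_,
                        distance = NA_real_, within = FALSE))
    j <- j[inWin]; dist <- dist[inWin]
    best <- j[order(dist, gstart[j])][1L]
    d <- dist[order(dist, gstart[j])][1L]
    data.frame(chrom = cc, pos = pos, gene = gname[best],
               distance = d, within = d == 0)
  })
  do.call(rbind, out)
}

#' QTL intervals overlapping a block
#'
#' Closed-interval intersection on the same chromosome: a QTL is returned
#' when \code{[start, end]} intersects \code{[startBp, endBp]}. Invariant
#' to the order of the QTL table.
#'
#' @param block a \linkS4class{HaplotypeBlock} (or a list with
#'   \code{chrom}, \code{startBp}, \code{endBp}).
#' @param qtls data.frame from [readQtlTable()].
#' @return the overlapping subset of \code{qtls}.
#' @export
qtlOverlap <- function(block, qtls) {
  chrom <- if (is(block, "HaplotypeBlock")) block@chrom else block$chrom
  s <- if (is(block, "HaplotypeBlock")) block@startBp else block$startBp
  e <- if (is(block, "HaplotypeBlock")) block@endBp else block$endBp
  hit <- qtls$chrom == chrom & qtls$start_bp <= e & qtls$end_bp >= s
  qtls[hit, , drop = FALSE]
}

## a zero point estimate breaks the tie deterministically toward the major
## allele
.favoriteAllele <- function(effect, ref, alt, major) {
  if (effect > 0) alt else if (effect < 0) ref else major
}

#' Favorite-allele direction of significant SNPs
#'
#' For each marker, the single-locus kinship-adjusted model (one-column
#' random effect, see [singleSnpScan()]) is fitted and the allele whose
#' substitution effect on the phenotype is positive is called the
#' "favorite"; a zero point estimate defaults deterministically to the
#' major allele. The report states whether the favorite is the major
#' allele in the population.
#'
#' @param geno phased genotypes.
#' @param phenotype named phenotype vector.
#' @param kinship optional \linkS4class{KinshipEigen}.
#' @param markers marker indices to evaluate (e.g. the SNPs of significant
#'   blocks); monomorphic markers are skipped with a message.
#' @param control see [remlControl()].
#' @return data.frame: \code{marker, chrom, pos, ref, alt, altEffect,
#'   favoriteAllele, favoriteIsMajor}.
#' @export
alleleDirection <- function(geno, phenotype, kinship = NULL,
                            markers = seq_len(nMarkers(geno)),
                            control = remlControl()) {
  maf <- computeMaf(geno)
  poly <- vapply(markers, function(j) maf$maf[j] > 0, logical(1))
  if (any(!poly))
    message(sprintf("alleleDirection: skipping %d monomorphic marker(s)",
                    sum(!poly)))
  markers <- markers[poly]
  scan <- singleSnpScan(geno, phenotype, kinship, markers = markers,
                        control = control)
  out <- lapply(seq_along(markers), function(k) {
    j <- markers[k]
    eff <- scan@fits[[k]]@gammaHat[1L]  # ALT-dosage substitution effect
    fav <- .favoriteAllele(eff, maf$ref[j], maf$alt[j], maf$majorAllele[j])
    data.frame(marker = maf$marker[j], chrom = maf$chrom[j],
               pos = maf$pos[j], ref = maf$ref[j], alt = maf$alt[j],
               altEffect = unname(eff),
               favoriteAllele = fav,
               favoriteIsMajor = fav == maf$majorAllele[j],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
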