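#' Read gene models from a GTF or BED annotation
#'
#' Parses gene-level records into the package's internal representation:
#' 0-based half-open coordinates, with the transcription start site (`tss`)
#' and the far (stop-codon-side) boundary (`cds_end`) resolved by strand.
#' For `-` strand genes the TSS is the rightmost coordinate.
#'
#' GTF input follows the Ensembl dialect (1-based closed coordinates, a
#' `gene_id` attribute); records with `type == "gene"` are used when the file
#' distinguishes feature types, otherwise all records are taken as genes.
#' BED input is BED6 (already 0-based half-open; the `name` field is the
#' gene id).
#'
#' @param path path to the annotation file.
#' @param format `"gtf"` or `"bed"`.
#' @return a `data.frame` with columns `gene_id`, `chrom`, `strand`
#'   (`"+"`/`"-"`), `tss`, `cds_end` (both 0-based), one row per gene.
#' @export
read_gene_models <- function(path, format = c("gtf", "bed")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_msg("annotation file not found: %s", path)
  if (format == "bed") validate_bed_lines(path)
  gr <- tryCatch(
    rtracklayer::import(path, format = format),
    error = function(e) stop_msg("failed to parse %s as %s: %s",
                                 path, toupper(format), conditionMessage(e))
  )
  if (format == "gtf") {
    md <- S4Vectors::mcols(gr)
    if (!is.null(md$type) && any(md$type == "gene")) gr <- gr[md$type == "gene"]
    ids <- S4Vectors::mcols(gr)$gene_id
    if (is.null(ids)) stop_msg("GTF records lack a gene_id attribute: %s", path)
  } else {
    ids <- S4Vectors::mcols(gr)$name
    if (is.null(ids) || anyNA(ids)) {
      stop_msg("BED input must carry gene ids in the name field: %s", path)
    }
  }
  ids <- as.character(ids)
  if (anyDuplicated(ids)) {
    stop_msg("duplicate gene_id in %s: %s", path,
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  strand <- as.character(BiocGenerics::strand(gr))
  if (any(strand == "*")) stop_msg("gene records without strand in %s", path)
  # rtracklayer yields 1-based closed starts for both formats
  start0 <- BiocGenerics::start(gr) - 1L
  end0 <- BiocGenerics::end(gr)
  data.frame(
    gene_id = ids,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = strand,
    tss = ifelse(strand == "+", start0, end0),
    cds_end = ifelse(strand == "+", end0, start0),
    stringsAsFactors = FALSE
  )
}

validate_bed_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 6L)) {
    bad <- which(keep)[which(nf < 6L)[1L]]
    stop_msg("malformed BED line %d in %s: expected >= 6 tab-separated fields",
             bad, path)
  }
  starts <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  ends <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  if (anyNA(starts) || anyNA(ends)) {
    bad <- which(keep)[which(is.na(starts) | is.na(ends))[1L]]
    stop_msg("malformed BED line %d in %s: non-numeric coordinates", bad, path)
  }
  invisible(TRUE)
}

#' Write gene models as BED6
#'
#' Inverse of [read_gene_models()] for the BED dialect; re-reading the file
#' reproduces the same gene models (and hence identical gene regions).
#'
#' @param genes gene-model `data.frame` as returned by [read_gene_models()].
#' @param path output path.
#' @export
write_gene_models_bed <- function(genes, path) {
  bed <- data.frame(
    chrom = genes$chrom,
    start = pmin(genes$tss, genes$cds_end),
    end = pmax(genes$tss, genes$cds_end),
    name = genes$gene_id,
    score = 0L,
    strand = genes$strand
  )
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Build the promoter + gene-body region for one gene
#'
#' The region is the union of the gene body (TSS to stop-codon boundary) and
#' a window of `window_bp` base pairs on both sides of the TSS, merged and
#' clipped at the chromosome origin (coordinate 0). All coordinates are
#' 0-based half-open.
#'
#' @param gene a single-row gene-model `data.frame` (or a list with fields
#'   `gene_id`, `chrom`, `strand`, `tss`, `cds_end`).
#' @param window_bp non-negative window half-width in base pairs around the
#'   TSS (default 2000).
#' @return an object of class `GeneRegion`: a list with `gene_id`, `chrom`,
#'   `intervals` (two-column matrix of half-open `[start, end)` intervals,
#'   sorted, non-overlapping) and `window_bp`.
#' @export
build_gene_region <- function(gene, window_bp = 2000L) {
  stopifnot(window_bp >= 0)
  body <- c(min(gene$tss, gene$cds_end), max(gene$tss, gene$cds_end))
  win <- c(max(0, gene$tss - window_bp), gene$tss + window_bp)
  ir <- IRanges::IRanges(start = c(body[1], win[1]) + 1L,
                         end = c(body[2], win[2]))
  ir <- IRanges::reduce(ir[IRanges::width(ir) > 0L])
  structure(
    list(gene_id = gene$gene_id,
         chrom = gene$chrom,
         intervals = cbind(start = BiocGenerics::start(ir) - 1L,
                           end = BiocGenerics::end(ir)),
         window_bp = as.integer(window_bp)),
    class = "GeneRegion"
  )
}

#' Build gene regions for a whole annotation as a GRanges
#'
#' Vectorised companion of [build_gene_region()]: one `GRanges` with a
#' `gene_id` metadata column, the container the fragment counter consumes.
#'
#' @param genes gene-model `data.frame` from [read_gene_models()].
#' @inheritParams build_gene_region
#' @return a `GRanges` (1-based closed, the Bioconductor convention) whose
#'   0-based half-open image matches [build_gene_region()] per gene.
#' @export
build_gene_regions <- function(genes, window_bp = 2000L) {
  stopifnot(window_bp >= 0)
  body_lo <- pmin(genes$tss, genes$cds_end)
  body_hi <- pmax(genes$tss, genes$cds_end)
  lo <- pmin(body_lo, pmax(0, genes$tss - window_bp))
  hi <- pmax(body_hi, genes$tss + window_bp)
  GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = lo + 1L, end = hi),
    strand = genes$strand,
    gene_id = genes$gene_id
  )
}
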