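#' Construct a per-gene fragment count matrix
#'
#' @param counts non-negative integer matrix, genes in rows (rownames = gene
#'   ids), samples in columns (colnames = sample ids).
#' @param library_sizes named numeric vector of total fragments per sample;
#'   names must match `colnames(counts)`.
#' @return an object of class `CountMatrix`.
#' @export
count_matrix <- function(counts, library_sizes) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop_msg("counts must carry gene ids as rownames and sample ids as colnames")
  }
  if (anyDuplicated(rownames(counts))) stop_msg("duplicate gene ids in counts")
  if (any(counts < 0)) stop_msg("negative counts")
  if (!setequal(names(library_sizes), colnames(counts))) {
    stop_msg("library_sizes names must match sample ids")
  }
  library_sizes <- library_sizes[colnames(counts)]
  if (any(library_sizes <= 0)) stop_msg("library sizes must be positive")
  structure(list(counts = counts, library_sizes = library_sizes),
            class = "CountMatrix")
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat(sprintf("CountMatrix: %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat("library sizes:", paste(sprintf("%s=%g", names(x$library_sizes),
                                      x$library_sizes), collapse = ", "), "\n")
  invisible(x)
}

#' Assign fragments to gene regions by midpoint
#'
#' A fragment increments a gene's count iff its midpoint,
#' `floor((start + end) / 2)` in 0-based coordinates, lies inside the gene's
#' region. Midpoint assignment (rather than any-overlap) avoids
#' double-counting long fragments that straddle a region edge; a fragment
#' whose midpoint falls in several overlapping gene regions increments each
#' of them.
#'
#' @param fragments `data.frame` with columns `chrom`, `start`, `end`
#'   (0-based half-open, `start < end`).
#' @param regions `GRanges` of gene regions with a `gene_id` metadata column
#'   (from [build_gene_regions()]).
#' @return list with `counts` (named integer vector over all region gene
#'   ids), `n_fragments`, `n_unassigned` (midpoint in no region) and
#'   `n_unknown_chrom` (fragment chromosome absent from the regions; such
#'   fragments are skipped with a warning).
#' @export
assign_fragments <- function(fragments, regions) {
  stopifnot(all(c("chrom", "start", "end") %in% names(fragments)))
  if (any(fragments$start >= fragments$end)) {
    stop_msg("fragments must be half-open with start < end")
  }
  gene_ids <- S4Vectors::mcols(regions)$gene_id
  known <- fragments$chrom %in% GenomeInfoDb::seqlevels(regions)
  n_unknown <- sum(!known)
  if (n_unknown > 0) {
    warn_msg("%d fragment(s) on chromosomes absent from the annotation; skipped",
             n_unknown)
  }
  fr <- fragments[known, , drop = FALSE]
  mid0 <- floor((fr$start + fr$end) / 2)
  mids <- GenomicRanges::GRanges(
    seqnames = factor(fr$chrom, levels = GenomeInfoDb::seqlevels(regions)),
    ranges = IRanges::IRanges(start = mid0 + 1L, width = 1L)
  )
  hits <- GenomicRanges::findOverlaps(mids, regions, ignore.strand = TRUE)
  counts <- integer(length(regions))
  names(counts) <- gene_ids
  tab <- tabulate(S4Vectors::subjectHits(hits), nbins = length(regions))
  counts[] <- tab
  list(counts = counts,
       n_fragments = nrow(fragments),
       n_unassigned = nrow(fr) - length(unique(S4Vectors::queryHits(hits))),
       n_unknown_chrom = n_unknown)
}

#' Count fragments per gene across samples
#'
#' Runs [assign_fragments()] for each sample and assembles a [count_matrix()].
#' Library size of a sample is its total fragment count (assigned or not),
#' matching the library-size-proportional null of the caller.
#'
#' @param fragments_by_sample named list of fragment `data.frame`s.
#' @param regions `GRanges` of gene regions.
#' @return a `CountMatrix`.
#' @export
count_fragments <- function(fragments_by_sample, regions) {
  stopifnot(length(names(fragments_by_sample)) == length(fragments_by_sample))
  cols <- lapply(fragments_by_sample, function(fr) assign_fragments(fr, regions)$counts)
  counts <- do.call(cbind, cols)
  colnames(counts) <- names(fragments_by_sample)
  count_matrix(counts, vapply(fragments_by_sample, nrow, 0L))
}

#' Write / read a CountMatrix as a tab-separated table
#'
#' The file is a gene x sample table preceded by a `#library_sizes` header
#' line carrying the per-sample totals in column order.
#'
#' @param x a `CountMatrix`.
#' @param path file path.
#' @export
write_count_matrix <- function(x, path) {
  stopifnot(inherits(x, "CountMatrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("#library_sizes", x$library_sizes), collapse = "\t"), con)
  writeLines(paste(c("gene_id", colnames(x$counts)), collapse = "\t"), con)
  utils::write.table(cbind(gene_id = rownames(x$counts), x$counts), con,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(path) {
  first <- readLines(path, n = 1L)
  if (!startsWith(first, "#library_sizes")) {
    stop_msg("count table %s lacks the #library_sizes header line", path)
  }
  lib <- as.numeric(strsplit(first, "\t", fixed = TRUE)[[1]][-1])
  tab <- utils::read.table(path, sep = "\t", header = TRUE, skip = 1L,
                           check.names = FALSE, stringsAsFactors = FALSE)
  counts <- as.matrix(tab[, -1, drop = FALSE])
  rownames(counts) <- tab[[1]]
  names(lib) <- colnames(counts)
  count_matrix(counts, lib)
}
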