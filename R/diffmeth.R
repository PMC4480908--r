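#' Call per-gene differential methylation from sequencing counts
#'
#' A deliberately simple, fully specified caller for enriched-library
#' counts: counts are pooled within each condition, and for every gene the
#' pooled pair `(x_a, x_b)` is tested against the library-size-proportional
#' expectation with a two-sided exact binomial test
#' (`x_a` successes of `x_a + x_b` at rate `L_a / (L_a + L_b)`).
#' P values are adjusted across genes by Benjamini-Hochberg. The model is a
#' stand-in for replicate-aware dispersion modelling: it is exactly
#' calibrated for Poisson counts conditional on the gene total, and
#' anticonservative under overdispersion (see the package vignette).
#'
#' @param counts a `CountMatrix`.
#' @param cond_a,cond_b character vectors of sample ids defining the two
#'   conditions; direction `"hyper"` means a higher normalised rate in
#'   `cond_a`.
#' @param alpha BH-adjusted significance threshold for the returned calls
#'   (default 0.05).
#' @param all_genes if `TRUE`, return the full per-gene table (used for
#'   calibration checks); if `FALSE` (default) only genes with
#'   `p_adj <= alpha`.
#' @return a `data.frame` of methylation calls: `gene_id`, `direction`
#'   (`"hyper"`/`"hypo"`, relative to `cond_a`), `p_raw`, `p_adj`, `effect`
#'   (log2 ratio of normalised rates, with a 0.5 pseudocount). Genes with
#'   zero counts in both conditions receive no call; their number is
#'   reported in the `n_no_call` attribute.
#' @export
call_diffmeth_seq <- function(counts, cond_a, cond_b, alpha = 0.05,
                              all_genes = FALSE) {
  stopifnot(inherits(counts, "CountMatrix"))
  if (length(cond_a) == 0 || length(cond_b) == 0) {
    stop_msg("both conditions must contain at least one sample")
  }
  miss <- setdiff(c(cond_a, cond_b), colnames(counts$counts))
  if (length(miss)) stop_msg("unknown sample id(s): %s", paste(miss, collapse = ", "))
  if (length(intersect(cond_a, cond_b))) stop_msg("conditions share samples")

  xa <- rowSums(counts$counts[, cond_a, drop = FALSE])
  xb <- rowSums(counts$counts[, cond_b, drop = FALSE])
  la <- sum(counts$library_sizes[cond_a])
  lb <- sum(counts$library_sizes[cond_b])
  p0 <- la / (la + lb)

  tot <- xa + xb
  callable <- tot > 0
  n_no_call <- sum(!callable)

  p_raw <- vapply(which(callable), function(i) {
    stats::binom.test(xa[i], tot[i], p = p0, alternative = "two.sided")$p.value
  }, 0)
  p_adj <- stats::p.adjust(p_raw, method = "BH")
  rate_a <- xa[callable] / la
  rate_b <- xb[callable] / lb
  effect <- log2((xa[callable] + 0.5) / la) - log2((xb[callable] + 0.5) / lb)
  res <- data.frame(
    gene_id = rownames(counts$counts)[callable],
    direction = ifelse(rate_a >= rate_b, "hyper", "hypo"),
    p_raw = pmin(p_raw, 1),
    p_adj = p_adj,
    effect = effect,
    stringsAsFactors = FALSE
  )
  if (!all_genes) res <- res[res$p_adj <= alpha, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_no_call") <- n_no_call
  res
}

#' Extract hyper/hypo gene-id sets from a call table
#'
#' @param calls call table from [call_diffmeth_seq()].
#' @return list with elements `hyper` and `hypo` (character vectors).
#' @export
split_calls_by_direction <- function(calls) {
  list(hyper = calls$gene_id[calls$direction == "hyper"],
       hypo = calls$gene_id[calls$direction == "hypo"])
}

#' Configuration for replicate-concordance array peak acceptance
#'
#' @param score_cutoff per-replicate enrichment-score cutoff; scores are
#'   `-log10` of the per-probe-set P value, so the default 2.0 means
#'   P < 0.01. The comparison is strict: a score exactly at the cutoff fails.
#' @param min_replicates minimum number of replicates that must exceed the
#'   cutoff (default 2).
#' @param replicate_count number of biological replicates per gene
#'   (default 3).
#' @return an `ArrayPeakConfig` list.
#' @export
array_peak_config <- function(score_cutoff = 2.0, min_replicates = 2L,
                              replicate_count = 3L) {
  if (min_replicates < 1L || min_replicates > replicate_count) {
    stop_msg("min_replicates must lie in [1, replicate_count]")
  }
  structure(list(score_cutoff = score_cutoff,
                 min_replicates = as.integer(min_replicates),
                 replicate_count = as.integer(replicate_count)),
            class = "ArrayPeakConfig")
}

#' Call enriched genes from tiling-array replicate scores
#'
#' A gene is accepted as enriched iff strictly more than `score_cutoff` is
#' reached by at least `min_replicates` of its `replicate_count` replicate
#' scores — the "at least two of three replicates above a score of 2"
#' concordance rule.
#'
#' @param scores numeric matrix of per-replicate enrichment scores, genes in
#'   rows (rownames = gene ids), one column per replicate; or a `data.frame`
#'   whose first column is `gene_id`.
#' @param cfg an [array_peak_config()].
#' @return character vector of enriched gene ids.
#' @export
call_array_peaks <- function(scores, cfg = array_peak_config()) {
  if (is.data.frame(scores)) {
    m <- as.matrix(scores[, -1, drop = FALSE])
    rownames(m) <- scores[[1]]
    scores <- m
  }
  if (is.null(rownames(scores))) stop_msg("scores must carry gene ids as rownames")
  if (ncol(scores) != cfg$replicate_count) {
    stop_msg("replicate count mismatch: %d columns, config expects %d",
             ncol(scores), cfg$replicate_count)
  }
  bad <- !is.finite(scores)
  if (any(bad)) {
    bad_rows <- unique((which(bad) - 1L) %% nrow(scores) + 1L)
    stop_msg("non-finite score(s) for gene(s): %s",
             paste(rownames(scores)[bad_rows], collapse = ", "))
  }
  passes <- rowSums(scores > cfg$score_cutoff)
  rownames(scores)[passes >= cfg$min_replicates]
}

#' Presence/absence comparison of two enriched-gene sets
#'
#' Genes are scored as differentially methylated where they appear in only
#' one of the two enriched lists: `lost` (control only, i.e. hypomethylated
#' under treatment), `gained` (treatment only, hypermethylated), `unchanged`
#' (both).
#'
#' @param control_enriched,treatment_enriched character vectors of gene ids.
#' @return list with disjoint elements `lost`, `gained`, `unchanged`.
#' @export
score_presence_absence <- function(control_enriched, treatment_enriched) {
  control_enriched <- unique(control_enriched)
  treatment_enriched <- unique(treatment_enriched)
  list(lost = setdiff(control_enriched, treatment_enriched),
       gained = setdiff(treatment_enriched, control_enriched),
       unchanged = intersect(control_enriched, treatment_enriched))
}
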