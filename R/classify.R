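#' Classify directional methylation responses to a paired perturbation
#'
#' Combines the four directional call sets from the knockdown (kd) and
#' overexpression (oe) arms into response classes. A gene has a *positive*
#' methylation response when it lost methylation under knockdown and/or
#' gained methylation under overexpression; a *negative* response when it
#' responded in the opposite direction. Genes with evidence in both
#' directions are reported as `conflicted` and excluded from both classes,
#' keeping the enrichment inputs disjoint.
#'
#' @param hypo_kd,hyper_kd gene ids hypo-/hypermethylated under knockdown.
#' @param hyper_oe,hypo_oe gene ids hyper-/hypomethylated under
#'   overexpression; may be empty for a knockdown-only design.
#' @return an object of class `ResponseSets`: list with disjoint character
#'   vectors `positive`, `negative`, `conflicted`, and `provenance`, a
#'   `data.frame` mapping each gene to its evidence tags
#'   (`hypo_kd`, `hyper_oe`, `hyper_kd`, `hypo_oe`).
#' @export
classify_response <- function(hypo_kd, hyper_kd = character(),
                              hyper_oe = character(), hypo_oe = character()) {
  hypo_kd <- unique(as.character(hypo_kd))
  hyper_kd <- unique(as.character(hyper_kd))
  hyper_oe <- unique(as.character(hyper_oe))
  hypo_oe <- unique(as.character(hypo_oe))
  if (length(intersect(hypo_kd, hyper_kd))) {
    stop_msg("corrupt input: gene(s) both hypo- and hypermethylated under knockdown: %s",
             paste(utils::head(intersect(hypo_kd, hyper_kd), 5), collapse = ", "))
  }
  if (length(intersect(hypo_oe, hyper_oe))) {
    stop_msg("corrupt input: gene(s) both hypo- and hypermethylated under overexpression: %s",
             paste(utils::head(intersect(hypo_oe, hyper_oe), 5), collapse = ", "))
  }
  pos_evidence <- union(hypo_kd, hyper_oe)
  neg_evidence <- union(hyper_kd, hypo_oe)
  conflicted <- intersect(pos_evidence, neg_evidence)
  all_ids <- union(pos_evidence, neg_evidence)
  provenance <- data.frame(
    gene_id = all_ids,
    hypo_kd = all_ids %in% hypo_kd,
    hyper_oe = all_ids %in% hyper_oe,
    hyper_kd = all_ids %in% hyper_kd,
    hypo_oe = all_ids %in% hypo_oe,
    stringsAsFactors = FALSE
  )
  structure(
    list(positive = setdiff(pos_evidence, conflicted),
         negative = setdiff(neg_evidence, conflicted),
         conflicted = conflicted,
         provenance = provenance),
    class = "ResponseSets"
  )
}

#' @export
print.ResponseSets <- function(x, ...) {
  cat(sprintf("ResponseSets: %d positive, %d negative, %d conflicted\n",
              length(x$positive), length(x$negative), length(x$conflicted)))
  invisible(x)
}
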