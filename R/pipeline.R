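#' Combine directional calls from two siRNA arms
#'
#' Evidence from the two knockdown siRNAs can be pooled (`"union"`) or
#' required to agree (`"intersection"`). With `"union"`, a gene called in
#' opposite directions by the two arms is contradictory and is dropped from
#' both directions (the count is reported in the `n_contradictory`
#' attribute); with `"intersection"` contradictions cannot arise.
#'
#' @param direction_sets list of `list(hyper=, hypo=)` items, one per arm
#'   (as from [split_calls_by_direction()]).
#' @param mode `"union"` or `"intersection"`.
#' @return `list(hyper=, hypo=)` with an `n_contradictory` attribute.
#' @export
combine_directional_calls <- function(direction_sets,
                                      mode = c("union", "intersection")) {
  mode <- match.arg(mode)
  op <- if (mode == "union") union else intersect
  hyper <- Reduce(op, lapply(direction_sets, `[[`, "hyper"))
  hypo <- Reduce(op, lapply(direction_sets, `[[`, "hypo"))
  contradictory <- intersect(hyper, hypo)
  out <- list(hyper = setdiff(hyper, contradictory),
              hypo = setdiff(hypo, contradictory))
  attr(out, "n_contradictory") <- length(contradictory)
  out
}

#' Tabulate over-representation of query lists against target sets
#'
#' One [gene_set_enrichment()] row per (query, target) pair — the shape of a
#' PCGT over-representation table: representation factor, Yates chi-square,
#' exact P, and the universe size used, for every response class against
#' every target set.
#'
#' @param queries named list of query gene-id vectors (genes outside the
#'   universe are dropped before testing).
#' @param targets named list of target gene-id vectors.
#' @param universe character vector: the background gene universe.
#' @return `data.frame` with columns `query`, `target`, `query_size`,
#'   `target_size`, `observed`, `expected`, `rf`, `chi2`, `p_chi2`,
#'   `p_exact`, `universe_size`.
#' @export
enrichment_report <- function(queries, targets, universe) {
  universe <- unique(as.character(universe))
  rows <- list()
  for (qn in names(queries)) {
    q <- intersect(queries[[qn]], universe)
    for (tn in names(targets)) {
      er <- gene_set_enrichment(q, targets[[tn]], universe)
      rows[[length(rows) + 1L]] <- data.frame(
        query = qn, target = tn,
        query_size = er$size_a, target_size = er$size_b,
        observed = er$observed, expected = er$expected, rf = er$rf,
        chi2 = er$chi2, p_chi2 = er$p_chi2, p_exact = er$p_exact,
        universe_size = er$universe_size, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# Response sets for the sequencing arm of a synthetic dataset.
recover_seq_responses <- function(ds) {
  cfg <- ds$config
  counts <- ds$seq_counts
  call_dir <- function(a, b) {
    split_calls_by_direction(
      call_diffmeth_seq(counts, a, b, alpha = cfg$alpha))
  }
  kd <- combine_directional_calls(
    list(call_dir("kd_si1.enriched", "kd_control.enriched"),
         call_dir("kd_si2.enriched", "kd_control.enriched")),
    mode = cfg$sirna_combine)
  oe <- call_dir("oe.enriched", "oe_control.enriched")
  classify_response(hypo_kd = kd$hypo, hyper_kd = kd$hyper,
                    hyper_oe = oe$hyper, hypo_oe = oe$hypo)
}

# Response sets for the array arm: per-condition enriched lists by
# replicate concordance, then presence/absence between perturbation and its
# control.
recover_array_responses <- function(ds) {
  cfg <- ds$config
  pc <- array_peak_config(replicate_count = cfg$replicate_count)
  enr <- lapply(ds$array_scores, call_array_peaks, cfg = pc)
  pa_to_dir <- function(pa) list(hyper = pa$gained, hypo = pa$lost)
  kd <- combine_directional_calls(
    list(pa_to_dir(score_presence_absence(enr$kd_control, enr$kd_si1)),
         pa_to_dir(score_presence_absence(enr$kd_control, enr$kd_si2))),
    mode = cfg$sirna_combine)
  oe <- pa_to_dir(score_presence_absence(enr$oe_control, enr$oe))
  classify_response(hypo_kd = kd$hypo, hyper_kd = kd$hyper,
                    hyper_oe = oe$hyper, hypo_oe = oe$hypo)
}

#' Simulate an experiment and recover its planted structure end-to-end
#'
#' Runs the full chain — simulate, call differential methylation in both
#' arms, classify directional responses, test PCGT over-representation and
#' the cross-arm list overlap — and reports estimated against planted
#' quantities. The sequencing and array arms share the planted truth but
#' have independent measurement noise, standing in for the study's two cell
#' lines.
#'
#' @param cfg a [simulation_config()].
#' @param dataset optionally, an already-simulated `SyntheticDataset`
#'   (otherwise one is generated from `cfg`).
#' @return a list: `responses` (per arm), `table1` (over-representation
#'   report of both arms' classes against the PCGT sets), `cross_line`
#'   (`EnrichmentResult`s for the positive and negative cross-arm
#'   overlaps), `truth_rf` (realised RF of the planted classes against the
#'   PCGT pool), `metrics` (sensitivity, specificity, false discovery rate
#'   of the classification, per arm).
#' @export
end_to_end_recovery <- function(cfg, dataset = NULL) {
  ds <- dataset %||% simulate_experiment(cfg)
  universe <- ds$gene_models$gene_id
  responses <- list(seq = recover_seq_responses(ds),
                    array = recover_array_responses(ds))

  queries <- list(
    seq_positive = responses$seq$positive,
    seq_negative = responses$seq$negative,
    array_positive = responses$array$positive,
    array_negative = responses$array$negative)
  targets <- ds$pcgt_sets[c("suz12", "eed", "phc1", "rnf2", "all", "any")]
  table1 <- enrichment_report(queries, targets, universe)

  cross_line <- list(
    positive = cross_list_overlap(responses$seq$positive,
                                  responses$array$positive,
                                  length(universe)),
    negative = cross_list_overlap(responses$seq$negative,
                                  responses$array$negative,
                                  length(universe)))

  truth_pos <- ds$truth$gene_id[ds$truth$class == "positive"]
  truth_neg <- ds$truth$gene_id[ds$truth$class == "negative"]
  truth_none <- ds$truth$gene_id[ds$truth$class == "none"]
  truth_rf <- list(
    positive = gene_set_enrichment(truth_pos, ds$pcgt_sets$any, universe),
    negative = gene_set_enrichment(truth_neg, ds$pcgt_sets$any, universe))

  arm_metrics <- function(rs) {
    det <- union(rs$positive, rs$negative)
    tp <- length(intersect(rs$positive, truth_pos)) +
      length(intersect(rs$negative, truth_neg))
    list(
      sensitivity = tp / (length(truth_pos) + length(truth_neg)),
      specificity = 1 - length(intersect(det, truth_none)) / length(truth_none),
      fdr = if (length(det)) length(intersect(det, truth_none)) / length(det)
            else 0)
  }
  list(responses = responses, table1 = table1, cross_line = cross_line,
       truth_rf = truth_rf,
       metrics = lapply(responses, arm_metrics),
       dataset = ds)
}

#' Run the file-driven analysis pipeline
#'
#' Orchestrates the stages over files on disk: read the annotation, build
#' regions, load counts (and optionally array scores), call differential
#' methylation, classify responses, test over-representation against
#' supplied gene sets, and write response lists, the enrichment table and a
#' run manifest. Every reported P value is accompanied by the universe size
#' used.
#'
#' @param cfg a named list, or the path of a YAML file, with entries:
#'   `annotation` (path), `annotation_format` (`"gtf"`/`"bed"`),
#'   `window_bp`, `counts` (path of a [write_count_matrix()] table),
#'   `samples` (list with `kd` = character vector of knockdown enriched
#'   sample ids, `kd_control`, and optionally `oe`, `oe_control`),
#'   `gene_sets` (GMT path), `universe_policy` (`"annotation_all"` or
#'   `"explicit_list"`), `universe_list` (path, for the explicit policy),
#'   `alpha`, `sirna_combine`, `out_dir`, `seed`.
#' @return invisibly, a list with the response sets, the enrichment table
#'   and the manifest; files are written under `out_dir`.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- yaml::read_yaml(cfg)
  req <- c("annotation", "counts", "samples", "gene_sets", "out_dir")
  miss <- setdiff(req, names(cfg))
  if (length(miss)) stop_msg("pipeline config lacks: %s", paste(miss, collapse = ", "))
  for (f in c("annotation", "counts", "gene_sets")) {
    if (!file.exists(cfg[[f]])) stop_msg("stage input missing (%s): %s", f, cfg[[f]])
  }
  alpha <- cfg$alpha %||% 0.05
  window_bp <- cfg$window_bp %||% 2000L
  sirna_combine <- cfg$sirna_combine %||% "union"

  genes <- read_gene_models(cfg$annotation,
                            format = cfg$annotation_format %||% "bed")
  counts <- read_count_matrix(cfg$counts)
  drop <- setdiff(rownames(counts$counts), genes$gene_id)
  if (length(drop)) {
    warn_msg("%d counted gene(s) absent from the annotation; dropped", length(drop))
    keep <- rownames(counts$counts) %in% genes$gene_id
    counts <- count_matrix(counts$counts[keep, , drop = FALSE],
                           counts$library_sizes)
  }

  call_dir <- function(a, b) {
    split_calls_by_direction(call_diffmeth_seq(counts, a, b, alpha = alpha))
  }
  kd_sets <- lapply(cfg$samples$kd, call_dir, b = cfg$samples$kd_control)
  kd <- combine_directional_calls(kd_sets, mode = sirna_combine)
  if (!is.null(cfg$samples$oe)) {
    oe <- call_dir(cfg$samples$oe, cfg$samples$oe_control)
  } else {
    oe <- list(hyper = character(), hypo = character())
  }
  responses <- classify_response(hypo_kd = kd$hypo, hyper_kd = kd$hyper,
                                 hyper_oe = oe$hyper, hypo_oe = oe$hypo)

  universe_policy <- cfg$universe_policy %||% "annotation_all"
  universe <- switch(
    universe_policy,
    annotation_all = rownames(counts$counts),
    explicit_list = read_gene_list(cfg$universe_list),
    stop_msg("unknown universe policy: %s", universe_policy))

  targets <- read_gmt(cfg$gene_sets)
  table1 <- enrichment_report(
    list(positive = responses$positive, negative = responses$negative),
    targets, universe)

  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  for (cl in c("positive", "negative", "conflicted")) {
    writeLines(sort(responses[[cl]]),
               file.path(cfg$out_dir, paste0(cl, "_response_genes.txt")))
  }
  utils::write.table(responses$provenance,
                     file.path(cfg$out_dir, "provenance.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(table1, file.path(cfg$out_dir, "enrichment_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("methylshift")),
    r_version = R.version.string,
    parameters = list(alpha = alpha, window_bp = window_bp,
                      sirna_combine = sirna_combine,
                      universe_policy = universe_policy,
                      universe_size = length(universe),
                      seed = cfg$seed %||% NA),
    inputs = cfg[c("annotation", "counts", "gene_sets")],
    n_positive = length(responses$positive),
    n_negative = length(responses$negative),
    n_conflicted = length(responses$conflicted))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(responses = responses, table1 = table1, manifest = manifest))
}
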