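#' Solve for the sampling-odds multiplier that plants a target RF
#'
#' Responsive genes are drawn without replacement with weight
#' `enrichment_odds` for members of the biased gene pool and 1 otherwise
#' (sequential weighted sampling, i.e. the Wallenius noncentral
#' hypergeometric model). This inverts the Wallenius mean equation to find
#' the odds for which the *expected* representation factor of the drawn set
#' against the pool equals `target_rf`:
#' with pool size `m1`, draw size `n`, universe `N` and target overlap
#' `x1 = rf * n * m1 / N`, the mean equation
#' `x1/m1 = 1 - t^w`, `x2/m2 = 1 - t` gives
#' `w = log(1 - x1/m1) / log(1 - x2/m2)`.
#'
#' @param target_rf desired representation factor of the responsive set
#'   against the pool (1 = null).
#' @param pool_size size of the biased pool (e.g. number of polycomb target
#'   genes).
#' @param n_draw number of genes drawn (total responsive genes).
#' @param n_genes universe size.
#' @return the odds multiplier `w >= 0`.
#' @export
odds_for_rf <- function(target_rf, pool_size, n_draw, n_genes) {
  stopifnot(target_rf >= 0, pool_size > 0, n_draw > 0, n_genes > pool_size)
  x1 <- target_rf * n_draw * pool_size / n_genes
  if (x1 >= 0.95 * pool_size) {
    stop_msg("infeasible: target overlap (%.0f) would exhaust the pool (%d)",
             x1, pool_size)
  }
  if (x1 >= n_draw) stop_msg("infeasible: target overlap exceeds the draw size")
  x2 <- n_draw - x1
  m2 <- n_genes - pool_size
  if (x2 >= m2) stop_msg("infeasible: draw exceeds the non-pool complement")
  if (target_rf == 0) return(0)
  log(1 - x1 / pool_size) / log(1 - x2 / m2)
}

#' Configuration of a synthetic methylation-perturbation experiment
#'
#' Defaults emulate the scale of the study design the package targets: a
#' ~20000-gene annotation, polycomb target genes (PCGTs) as ~10% of genes
#' organised as four overlapping component sets, ~1600 genes per directional
#' response class (the observed response lists held 873-1845 genes per class
#' and line), a planted PCGT representation factor of 2, two knockdown
#' siRNAs plus control and an overexpression pair, three array replicates,
#' and negative-binomial enriched-library counts.
#'
#' @param n_genes number of genes in the annotation.
#' @param pcgt_fraction fraction of genes in the PCGT pool (union of the
#'   four component sets).
#' @param n_responsive number of truly responsive genes *per direction*
#'   (positive and negative classes each get this many).
#' @param target_rf planted representation factor of the responsive genes
#'   against the PCGT pool; used to derive `enrichment_odds` when that is
#'   `NULL`. `target_rf = 1` (odds 1) is the null.
#' @param enrichment_odds odds multiplier for a responsive gene being a
#'   PCGT; overrides `target_rf` when supplied.
#' @param effect_log2 log2 fold-shift applied to the methylation odds of
#'   responsive genes under perturbation (knockdown lowers positive-response
#'   genes and raises negative-response genes; overexpression mirrored).
#' @param library_size expected total fragments per sequencing library.
#' @param dispersion negative-binomial dispersion of the counts
#'   (`size = 1/dispersion`); 0 gives Poisson counts.
#' @param replicate_count biological replicates per array condition.
#' @param array_noise_sd Gaussian replicate noise of the array enrichment
#'   scores, in -log10(P) units.
#' @param score_present_mean,score_absent_mean mean array score of a gene
#'   whose methylation is above / below `presence_threshold`.
#' @param presence_threshold methylation level above which a gene is
#'   detectable as an array peak.
#' @param alpha BH threshold used by the downstream sequencing caller.
#' @param sirna_combine how evidence from the two siRNAs is combined
#'   downstream: `"union"` or `"intersection"`.
#' @param seed master seed; all layers draw from named substreams of it.
#' @return a `SimulationConfig` list.
#' @export
simulation_config <- function(n_genes = 20000L,
                              pcgt_fraction = 0.10,
                              n_responsive = 1600L,
                              target_rf = 2.0,
                              enrichment_odds = NULL,
                              effect_log2 = 2,
                              library_size = 2e6,
                              dispersion = 0.01,
                              replicate_count = 3L,
                              array_noise_sd = 0.75,
                              score_present_mean = 3.0,
                              score_absent_mean = 0.8,
                              presence_threshold = 0.5,
                              alpha = 0.05,
                              sirna_combine = c("union", "intersection"),
                              seed = 1L) {
  sirna_combine <- match.arg(sirna_combine)
  stopifnot(pcgt_fraction > 0, pcgt_fraction < 1,
            n_responsive >= 1, 2 * n_responsive < n_genes,
            dispersion >= 0, replicate_count >= 2, library_size > 0)
  pool_size <- round(n_genes * pcgt_fraction)
  if (is.null(enrichment_odds)) {
    enrichment_odds <- odds_for_rf(target_rf, pool_size,
                                   2L * n_responsive, n_genes)
  }
  stopifnot(enrichment_odds >= 0)
  structure(
    list(n_genes = as.integer(n_genes), pcgt_fraction = pcgt_fraction,
         n_responsive = as.integer(n_responsive), target_rf = target_rf,
         enrichment_odds = enrichment_odds, effect_log2 = effect_log2,
         library_size = library_size, dispersion = dispersion,
         replicate_count = as.integer(replicate_count),
         array_noise_sd = array_noise_sd,
         score_present_mean = score_present_mean,
         score_absent_mean = score_absent_mean,
         presence_threshold = presence_threshold,
         alpha = alpha, sirna_combine = sirna_combine,
         seed = as.integer(seed)),
    class = "SimulationConfig"
  )
}

#' Simulate a complete synthetic methylation-perturbation experiment
#'
#' Generates, from one seed, every layer the pipeline consumes: a toy
#' annotation, four overlapping PCGT component sets, a planted per-gene
#' response truth with PCGT bias, enriched- and input-library sequencing
#' counts for the five conditions (two knockdown siRNAs, knockdown control,
#' overexpression, vector control), replicate array enrichment scores per
#' condition, and qPCR Ct tables (spike-in QC and an expression assay).
#' The same seed reproduces the dataset exactly.
#'
#' @param cfg a [simulation_config()].
#' @param layers which layers to generate (a subset of
#'   `c("genes", "pcgt", "truth", "counts", "array", "qpcr")`); later layers
#'   require earlier ones. Restricting layers speeds up simulations that
#'   only need the truth structure.
#' @return a `SyntheticDataset` list with elements `gene_models`,
#'   `pcgt_sets` (components `suz12`, `eed`, `phc1`, `rnf2` plus derived
#'   `all` and `any`), `truth` (`data.frame` gene_id/class), `methylation`
#'   (per-condition true methylation levels), `seq_counts` (a
#'   `CountMatrix`), `array_scores` (per-condition score matrices),
#'   `ct_tables`, and `config`.
#' @export
simulate_experiment <- function(cfg,
                                layers = c("genes", "pcgt", "truth",
                                           "counts", "array", "qpcr")) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  layers <- match.arg(layers, several.ok = TRUE)
  # expand to prerequisite layers: counts need the annotation and the truth;
  # array scores and counts need the truth; the truth needs the PCGT sets
  if ("counts" %in% layers) layers <- union(layers, "genes")
  if (any(c("counts", "array") %in% layers)) layers <- union(layers, "truth")
  if ("truth" %in% layers) layers <- union(layers, "pcgt")
  gene_ids <- sprintf("g%05d", seq_len(cfg$n_genes))
  ds <- list(config = cfg)

  if ("genes" %in% layers) {
    ds$gene_models <- with_substream(cfg$seed, "genes",
                                     sim_gene_models(gene_ids))
  }
  if ("pcgt" %in% layers) {
    ds$pcgt_sets <- with_substream(cfg$seed, "pcgt",
                                   sim_pcgt_sets(gene_ids, cfg$pcgt_fraction))
  }
  if ("truth" %in% layers) {
    ds$truth <- with_substream(cfg$seed, "truth",
                               sim_truth(gene_ids, ds$pcgt_sets$any, cfg))
  }
  if (any(c("counts", "array") %in% layers)) {
    ds$methylation <- with_substream(cfg$seed, "meth",
                                     sim_methylation(gene_ids, ds$truth, cfg))
  }
  if ("counts" %in% layers) {
    ds$seq_counts <- with_substream(
      cfg$seed, "counts",
      sim_seq_counts(ds$gene_models, ds$methylation, cfg))
  }
  if ("array" %in% layers) {
    ds$array_scores <- with_substream(
      cfg$seed, "array", sim_array_scores(ds$methylation, cfg))
  }
  if ("qpcr" %in% layers) {
    ds$ct_tables <- with_substream(cfg$seed, "qpcr", sim_ct_tables(cfg))
  }
  structure(ds, class = "SyntheticDataset")
}

sim_conditions <- c("kd_si1", "kd_si2", "kd_control", "oe", "oe_control")

sim_gene_models <- function(gene_ids) {
  n <- length(gene_ids)
  n_chrom <- max(1L, ceiling(n / 1000))
  chrom <- sprintf("chr%d", 1L + (seq_len(n) - 1L) %% n_chrom)
  len <- round(stats::runif(n, 2000, 20000))
  strand <- sample(c("+", "-"), n, replace = TRUE)
  # tandem placement per chromosome with 5 kb gaps (> 2 kb TSS window, so
  # neighbouring regions never overlap)
  start <- integer(n)
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    start[i] <- cumsum(c(5000, len[i][-length(i)] + 5000))
  }
  end <- start + len
  data.frame(
    gene_id = gene_ids, chrom = chrom, strand = strand,
    tss = ifelse(strand == "+", start, end),
    cds_end = ifelse(strand == "+", end, start),
    stringsAsFactors = FALSE
  )
}

# Four overlapping component sets over a common pool, with a shared core
# present in all four, so that "all" <= each component <= "any" and the
# union of components equals the pool.
sim_pcgt_sets <- function(gene_ids, pcgt_fraction) {
  m1 <- round(length(gene_ids) * pcgt_fraction)
  pool <- sample(gene_ids, m1)
  core <- pool[seq_len(round(0.25 * m1))]
  rest <- setdiff(pool, core)
  member <- matrix(stats::runif(length(rest) * 4) < 0.45, ncol = 4)
  none <- rowSums(member) == 0
  if (any(none)) {
    member[cbind(which(none), sample.int(4, sum(none), replace = TRUE))] <- TRUE
  }
  comp <- lapply(1:4, function(j) c(core, rest[member[, j]]))
  names(comp) <- c("suz12", "eed", "phc1", "rnf2")
  comp$all <- combine_gene_sets(comp[1:4], "all")
  comp$any <- combine_gene_sets(comp[1:4], "at_least_one")
  comp
}

sim_truth <- function(gene_ids, pcgt_any, cfg) {
  n_draw <- 2L * cfg$n_responsive
  w <- ifelse(gene_ids %in% pcgt_any, cfg$enrichment_odds, 1)
  drawn <- sample(gene_ids, n_draw, prob = w)
  # sequential weighted draws are order-biased (high-weight genes come
  # earlier), so permute before splitting into the two classes
  drawn <- sample(drawn)
  cls <- rep("none", length(gene_ids))
  names(cls) <- gene_ids
  cls[drawn[seq_len(cfg$n_responsive)]] <- "positive"
  cls[drawn[(cfg$n_responsive + 1L):n_draw]] <- "negative"
  data.frame(gene_id = gene_ids, class = unname(cls),
             stringsAsFactors = FALSE)
}

# Per-condition true methylation levels. The baseline is Beta(2, 2); the
# perturbation shifts the methylation *odds* of responsive genes by
# 2^(+/- effect_log2), which keeps levels inside (0, 1).
sim_methylation <- function(gene_ids, truth, cfg) {
  base <- stats::rbeta(length(gene_ids), 2, 2)
  base <- pmin(pmax(base, 0.02), 0.98)
  shift <- function(m, log2_fold) {
    o <- m / (1 - m) * 2^log2_fold
    o / (1 + o)
  }
  e <- cfg$effect_log2
  pos <- truth$class == "positive"
  neg <- truth$class == "negative"
  kd <- base
  kd[pos] <- shift(base[pos], -e)
  kd[neg] <- shift(base[neg], +e)
  oe <- base
  oe[pos] <- shift(base[pos], +e)
  oe[neg] <- shift(base[neg], -e)
  m <- cbind(kd_si1 = kd, kd_si2 = kd, kd_control = base,
             oe = oe, oe_control = base)
  rownames(m) <- gene_ids
  m
}

sim_seq_counts <- function(gene_models, methylation, cfg) {
  len <- abs(gene_models$cds_end - gene_models$tss) + 4000  # region length
  draw <- function(mu) {
    if (cfg$dispersion == 0) stats::rpois(length(mu), mu)
    else stats::rnbinom(length(mu), mu = mu, size = 1 / cfg$dispersion)
  }
  cols <- list()
  for (cond in sim_conditions) {
    w_enr <- methylation[, cond] * len
    mu_enr <- cfg$library_size * w_enr / sum(w_enr)
    mu_inp <- cfg$library_size * len / sum(len)
    cols[[paste0(cond, ".enriched")]] <- draw(mu_enr)
    cols[[paste0(cond, ".input")]] <- draw(mu_inp)
  }
  counts <- do.call(cbind, cols)
  rownames(counts) <- gene_models$gene_id
  lib <- rep(cfg$library_size, ncol(counts))
  names(lib) <- colnames(counts)
  count_matrix(counts, lib)
}

sim_array_scores <- function(methylation, cfg) {
  out <- list()
  for (cond in sim_conditions) {
    present <- methylation[, cond] > cfg$presence_threshold
    mu <- ifelse(present, cfg$score_present_mean, cfg$score_absent_mean)
    s <- matrix(stats::rnorm(length(mu) * cfg$replicate_count, mean = mu,
                             sd = cfg$array_noise_sd),
                nrow = length(mu))
    s <- pmax(s, 0)  # scores are -log10 P, bounded below by 0
    rownames(s) <- rownames(methylation)
    colnames(s) <- paste0("rep", seq_len(cfg$replicate_count))
    out[[cond]] <- s
  }
  out
}

# Ct tables: a lambda spike-in QC panel with a true 1000-fold methylated
# over unmethylated recovery preference, and an expression assay with a true
# knockdown to fold 0.3 against GAPDH/TOP1 references.
sim_ct_tables <- function(cfg, spike_fold = 1000, expression_fold = 0.3,
                          ct_noise_sd = 0.15, n_rep = 3L) {
  noise <- function(n) stats::rnorm(n, 0, ct_noise_sd)
  base_ct <- 25
  ip_meth_ct <- base_ct - 7                       # 128-fold recovery
  ip_unmeth_ct <- base_ct - 7 + log2(spike_fold)  # 1000x less than methylated
  spike <- expand.grid(replicate = seq_len(n_rep),
                       target = c("lambda_meth", "lambda_unmeth"),
                       fraction = c("input", "enriched"),
                       stringsAsFactors = FALSE)
  spike$ct <- with(spike, ifelse(
    fraction == "input", base_ct,
    ifelse(target == "lambda_meth", ip_meth_ct, ip_unmeth_ct)
  )) + noise(nrow(spike))
  spike$role <- ifelse(spike$target == "lambda_meth",
                       "spike_methylated", "spike_unmethylated")
  spike$sample_id <- "caco2_pool"

  expr <- expand.grid(replicate = seq_len(n_rep),
                      target = c("SIRT1", "GAPDH", "TOP1"),
                      sample_id = c("kd", "control"),
                      stringsAsFactors = FALSE)
  expr$ct <- 22 + noise(nrow(expr))
  kd_target <- expr$sample_id == "kd" & expr$target == "SIRT1"
  expr$ct[kd_target] <- expr$ct[kd_target] - log2(expression_fold)
  expr$role <- ifelse(expr$target %in% c("GAPDH", "TOP1"),
                      "reference", "target")

  list(spike = spike, expression = expr,
       truth = list(spike_fold = spike_fold,
                    expression_fold = expression_fold))
}

#' @export
print.SyntheticDataset <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "SyntheticDataset: %d genes, %d per response class, planted RF %.2f (odds %.3f), seed %d\n",
    cfg$n_genes, cfg$n_responsive, cfg$target_rf, cfg$enrichment_odds,
    cfg$seed))
  invisible(x)
}
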