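#' Relative quantification of qPCR targets by the delta-delta-Ct method
#'
#' Replicate Ct values are averaged per (sample, target); each target Ct is
#' corrected by the arithmetic mean of the reference-gene Cts of the same
#' sample (equivalent to the geometric mean of the linear quantities);
#' `ddCt = dCt(treated) - dCt(control)` and `fold = 2^-ddCt`, assuming an
#' amplification efficiency of 2 per cycle.
#'
#' @param records `data.frame` with columns `sample_id`, `target`, `ct`
#'   (replicate rows allowed; other columns ignored).
#' @param reference_targets character vector of reference-gene target names
#'   (e.g. `c("GAPDH", "TOP1")`).
#' @param treated,control sample ids to compare.
#' @return `data.frame` with one row per non-reference target: `target`,
#'   `delta_delta_ct`, `fold`.
#' @export
delta_delta_ct <- function(records, reference_targets, treated, control) {
  stopifnot(all(c("sample_id", "target", "ct") %in% names(records)))
  mean_ct <- function(sample, target) {
    ct <- records$ct[records$sample_id == sample & records$target == target]
    if (length(ct) == 0) {
      stop_msg("missing Ct measurement for sample '%s', target '%s'",
               sample, target)
    }
    mean(ct)
  }
  ref_ct <- function(sample) {
    mean(vapply(reference_targets, function(r) mean_ct(sample, r), 0))
  }
  targets <- setdiff(unique(records$target), reference_targets)
  ddct <- vapply(targets, function(tg) {
    d_treat <- mean_ct(treated, tg) - ref_ct(treated)
    d_ctrl <- mean_ct(control, tg) - ref_ct(control)
    d_treat - d_ctrl
  }, 0)
  data.frame(target = targets, delta_delta_ct = unname(ddct),
             fold = 2^(-unname(ddct)), stringsAsFactors = FALSE)
}

#' Fold enrichment of a methylated over an unmethylated species
#'
#' Recovery of each species through the enrichment step is
#' `2^(Ct_input - Ct_IP)`; the fold enrichment is the ratio of the
#' methylated to the unmethylated recovery:
#' `2^(ct_input_meth - ct_ip_meth) / 2^(ct_input_unmeth - ct_ip_unmeth)`.
#' Serves both the spike-in QC (methylated vs unmethylated lambda phage)
#' and endogenous locus pairs (e.g. H19 vs UBE2B). Invariant under adding a
#' constant to all four Cts.
#'
#' @param ct_input_meth,ct_ip_meth Cts of the methylated species in the
#'   input and enriched (IP) fractions.
#' @param ct_input_unmeth,ct_ip_unmeth same for the unmethylated species.
#' @return the dimensionless fold enrichment.
#' @export
spikein_fold_enrichment <- function(ct_input_meth, ct_ip_meth,
                                    ct_input_unmeth, ct_ip_unmeth) {
  stopifnot(is.finite(ct_input_meth), is.finite(ct_ip_meth),
            is.finite(ct_input_unmeth), is.finite(ct_ip_unmeth))
  2^((ct_input_meth - ct_ip_meth) - (ct_input_unmeth - ct_ip_unmeth))
}

#' One-way ANOVA with Dunnett many-to-one comparisons (Monte Carlo)
#'
#' Fits the one-way ANOVA, then compares every treatment group with the
#' designated control. Adjusted P values come from the null distribution of
#' the maximum absolute Dunnett t statistic, estimated by `n_mc` Monte Carlo
#' replications of a same-shape experiment under equal-variance normality —
#' no closed form needed, seedable, and directly testable.
#'
#' @param groups list of numeric measurement vectors (>= 2 groups, each with
#'   >= 2 values).
#' @param control_index index of the control group in `groups` (default 1).
#' @param n_mc number of Monte Carlo replications (default 10000).
#' @param seed optional seed; if supplied the Monte Carlo draws use their
#'   own substream and the caller's RNG state is untouched.
#' @return list with `f`, `p_anova`, `df`, and `comparisons`, a `data.frame`
#'   with one row per non-control group: `group`, `estimate` (mean
#'   difference from control), `t`, `p_unadjusted` (two-sided t on the
#'   pooled error df) and `p_adjusted`.
#' @export
anova_dunnett <- function(groups, control_index = 1L, n_mc = 10000L,
                          seed = NULL) {
  k <- length(groups)
  stopifnot(k >= 2, all(vapply(groups, length, 0L) >= 2L))
  if (is.null(names(groups))) names(groups) <- paste0("group", seq_len(k))
  ns <- vapply(groups, length, 0L)
  N <- sum(ns)
  means <- vapply(groups, mean, 0)
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  if (ss_within == 0) stop_msg("zero within-group variance in every group")
  df_err <- N - k
  mse <- ss_within / df_err
  grand <- sum(ns * means) / N
  ss_between <- sum(ns * (means - grand)^2)
  f <- (ss_between / (k - 1)) / mse
  p_anova <- stats::pf(f, k - 1, df_err, lower.tail = FALSE)

  idx <- setdiff(seq_len(k), control_index)
  se <- sqrt(mse * (1 / ns[idx] + 1 / ns[control_index]))
  t_obs <- (means[idx] - means[control_index]) / se
  p_unadj <- 2 * stats::pt(abs(t_obs), df_err, lower.tail = FALSE)

  max_t_null <- dunnett_null_max_t(ns, control_index, n_mc, seed)
  p_adj <- vapply(abs(t_obs), function(tt) {
    (1 + sum(max_t_null >= tt)) / (n_mc + 1)
  }, 0)

  list(f = unname(f), p_anova = unname(p_anova),
       df = c(between = k - 1, error = df_err),
       comparisons = data.frame(
         group = names(groups)[idx],
         estimate = unname(means[idx] - means[control_index]),
         t = unname(t_obs),
         p_unadjusted = unname(pmin(1, p_unadj)),
         p_adjusted = unname(p_adj),
         stringsAsFactors = FALSE
       ))
}

# Null distribution of max_i |t_i| for the many-to-one design: simulate
# experiments of the same group sizes from N(0, 1) and recompute every
# Dunnett t. Fully vectorised over replications.
dunnett_null_max_t <- function(ns, control_index, n_mc, seed = NULL) {
  draw <- function() {
    k <- length(ns)
    group_means <- matrix(0, n_mc, k)
    ss <- numeric(n_mc)
    for (j in seq_len(k)) {
      x <- matrix(stats::rnorm(n_mc * ns[j]), n_mc, ns[j])
      m <- rowMeans(x)
      group_means[, j] <- m
      ss <- ss + rowSums((x - m)^2)
    }
    mse <- ss / (sum(ns) - k)
    idx <- setdiff(seq_len(k), control_index)
    tmax <- rep(0, n_mc)
    for (j in idx) {
      se <- sqrt(mse * (1 / ns[j] + 1 / ns[control_index]))
      tmax <- pmax(tmax, abs(group_means[, j] - group_means[, control_index]) / se)
    }
    tmax
  }
  if (is.null(seed)) draw() else with_substream(seed, "dunnett", draw())
}
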