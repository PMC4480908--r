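---
title: "Methods: differential methylation calling and polycomb-target enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential methylation calling and polycomb-target enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylshift)
```

## The inference chain

`methylshift` implements the analysis chain that leads from
methylation-enriched DNA measurements to a gene-set over-representation
claim: genes whose DNA methylation responds to the level of a regulator
(assayed by paired knockdown and overexpression) cluster at polycomb group
protein target genes (PCGTs). The chain has five stages, each a module of
the package:

1. **Gene regions** — genes are reduced to the genomic territory used for
   counting: the gene body (TSS to the stop-codon boundary) united with a
   2 kb window around the TSS.
2. **Differential methylation** — per-gene calls in a sequencing arm
   (enriched-library fragment counts) and an array arm (replicate
   enrichment scores with presence/absence comparison).
3. **Response classification** — the four directional call sets from the
   knockdown and overexpression arms are combined into *positive* (lost
   methylation under knockdown and/or gained under overexpression),
   *negative* (the mirror image) and *conflicted* classes.
4. **Over-representation** — response classes are tested against PCGT sets
   with the representation factor and the Yates-corrected chi-square,
   alongside an exact hypergeometric test.
5. **qPCR support** — ΔΔCt relative quantification, spike-in enrichment QC,
   and one-way ANOVA with Dunnett many-to-one comparisons.

A seeded synthetic-data generator produces complete experiments with a
recorded planted truth, so every stage — and the chain end-to-end — is
testable without any external data.

## Gene regions and fragment counting

Internally all coordinates are 0-based half-open (the BED convention); GTF
input is converted on read. For a `-` strand gene the TSS is the rightmost
coordinate. The counting region is

$$ R_g = \big[\mathrm{tss}-w,\ \mathrm{tss}+w\big) \cup \text{gene body},
   \qquad w = 2000\ \mathrm{bp}, $$

clipped at the chromosome origin. The window is symmetric about the TSS:
"within 2 kb of a TSS" does not by itself fix a direction, and a symmetric
window is the conservative reading; `window_bp` is a parameter everywhere it
matters. Because the TSS bounds the gene body, the union is always a single
interval.

Fragments are assigned to a gene when their **midpoint**
(`floor((start+end)/2)`) lies inside the region. Midpoint assignment was
chosen over any-overlap because a long fragment straddling a region edge
would otherwise be counted by neighbouring genes it barely touches; with
midpoints every fragment has exactly one location, and double counting can
only arise from genuinely overlapping gene regions (which is allowed and
logged). Fragments on chromosomes absent from the annotation are skipped
with a warning count.

## The sequencing-arm caller

The caller is a deliberately simple, fully specified stand-in for a
replicate-aware dispersion model (the original analysis used an external
package whose parameters are not part of this pipeline). Counts are pooled
within each condition; for gene $g$ with pooled counts $x_A, x_B$ and
library sizes $L_A, L_B$, the null of no differential methylation is
binomial:

$$ x_A \mid x_A + x_B \sim \mathrm{Bin}\!\left(x_A + x_B,\
   \frac{L_A}{L_A + L_B}\right), $$

tested two-sided and exactly, then adjusted across genes by
Benjamini–Hochberg (alpha defaults to 0.05). Direction is `hyper` when the
normalised rate is higher in condition A; the reported effect is the log2
ratio of normalised rates with a 0.5 pseudocount.

**What this model does and does not claim.** Conditional on Poisson
sampling the test is exactly calibrated, and the package verifies this on
simulated Poisson nulls (raw-p uniformity is not rejected at the 1% level
over 2000 genes). Under negative-binomial overdispersion the pooled
binomial is *anticonservative* — it treats biological variability as
sampling noise. This is a declared limitation, visible in the end-to-end
simulations as an inflated false-discovery rate in the recovered response
lists; the planted-signal recovery results below should be read with that
in mind. The caller is validated only on synthetic data and makes no claim
of reproducing any deposited gene list.

Evidence from the two knockdown siRNAs is combined by union by default
(pooled evidence, matching list sizes of the order the study reports);
intersection (requiring concordance) is available via
`sirna_combine = "intersection"`. A gene called in opposite directions by
the two siRNAs is contradictory and is dropped from both directions, with
the count logged.

## The array-arm caller

Array data arrive as per-gene, per-replicate enrichment scores, defined as
$-\log_{10} P$ of the probe-set-level enrichment P value. A gene is
accepted as enriched when **strictly more than** 2.0 (i.e. $P < 0.01$) is
reached in **at least 2 of 3** biological replicates; both numbers are
configurable (`array_peak_config()`). A score of exactly 2.0 fails — the
acceptance rule is a strict inequality, honoured at the boundary and
verified against exhaustive enumeration of all $2^3$ replicate pass/fail
patterns. Differential methylation between two conditions is then
presence/absence: genes enriched only in the control are *lost*
(hypomethylated under treatment), genes enriched only under treatment are
*gained*.

## Response classes

With knockdown (kd) and overexpression (oe) call sets,

* positive evidence: `hypo_kd ∪ hyper_oe`
* negative evidence: `hyper_kd ∪ hypo_oe`
* conflicted: genes with evidence in both directions.

Conflicted genes are excluded from both classes and reported separately.
The tie case has no canonical resolution; exclusion keeps the enrichment
inputs disjoint, which is what the downstream 2×2 tables assume. The three
classes always partition the union of the inputs, and swapping the
directional inputs swaps positive and negative exactly (both properties are
tested over random draws).

## Over-representation statistics

For a query list $A$ (a response class) and target set $B$ (a PCGT list) in
a universe of $N$ genes, the expected overlap is $E = |A||B|/N$ and the
**representation factor** is $\mathrm{RF} = O/E$ for observed overlap $O$;
$\mathrm{RF} \cdot E = O$ holds exactly. Significance uses the 2×2
chi-square with Yates' continuity correction,

$$ \chi^2 = \frac{N\,\big(\max(0,\ |ad-bc| - N/2)\big)^2}
   {(a+b)(c+d)(a+c)(b+d)}, $$

with the correction floored at zero so a table at exact independence gives
$\chi^2 = 0$, $P = 1$. Every result also carries a two-sided exact
hypergeometric P (summation over tables no more probable than the one
observed, the Fisher convention), plus an exact Poisson 95% interval for
the RF. An expected cell below 5 triggers a warning recommending the exact
test. On 1000 random tables with all expected cells ≥ 5, significance
calls at $\alpha = 0.01$ from the two tests disagree on fewer than 2% of
tables (in practice ~0.1%).

**The universe is a mandatory, explicit parameter.** The expected overlap —
hence every P value — scales with $1/N$, and no default could be neutral.
The file-driven pipeline offers two policies: all genes of the annotation
actually scored (the default, recorded in the manifest), or an explicit
background list. The package's consistency diagnostic illustrates the
sensitivity with printed response-list margins (1554 and 1845 with overlap
139; 1475 and 873 with overlap 49): the positive overlap is significant at
$P < 0.001$ for any universe above 30 000 genes, while the negative
overlap's P value matches a printed value of 0.005 only in a band of
universe sizes around $3.9 \times 10^4$ genes — outside roughly
33 000–50 000 the order of magnitude is lost.

PCGT target lists combine with two set operators, mirroring the
"targets of all / of at least one polycomb group protein" rows of an
over-representation table: intersection and union. Raw P values are
reported per row; no multiple-testing correction is applied across target
sets (an optional BH column is available in `enrichment_report` output via
`p.adjust` downstream), since the handful of deliberately overlapping PCGT
rows are not independent hypotheses.

## qPCR arithmetic

ΔΔCt quantification averages replicate Cts per (sample, target), corrects
each target by the arithmetic mean of the reference-gene Cts (equivalent
to the geometric mean of the linear quantities — the two reference genes
are weighted equally, the natural reading when no weighting is stated),
and reports $\mathrm{fold} = 2^{-\Delta\Delta Ct}$ at a fixed
amplification efficiency of 2. Spike-in enrichment compares the recovery
of a methylated and an unmethylated species through the enrichment step,
$2^{(Ct^{in}_m - Ct^{ip}_m)}/2^{(Ct^{in}_u - Ct^{ip}_u)}$ — invariant to
any constant shift of all four Cts, so plate effects cancel.

Dunnett many-to-one comparisons use the null distribution of
$\max_i |t_i|$ estimated by Monte Carlo under equal-variance normality
with the experiment's own group sizes, rather than quadrature over the
multivariate t: no closed form is needed, the draw count is explicit
(`n_mc`, default $10^4$), it is seedable, and it is directly testable —
adjusted P values agree with an established implementation to ~0.01 and
stabilise to < 0.005 when doubling $n_mc$ at $10^5$. The family-wise error
rate over 2000 simulated null experiments at $\alpha = 0.05$ falls within
[0.035, 0.065].

## The synthetic-data generator

`simulation_config()` fixes the study conditions; the defaults are the
conditions, not tuning knobs:

| parameter | default | meaning |
|---|---|---|
| `n_genes` | 20000 | annotation size (order of a genome-wide gene set) |
| `pcgt_fraction` | 0.10 | fraction of genes in the PCGT pool |
| `n_responsive` | 1600 | truly responsive genes per direction (the study's per-class lists held 873–1845 genes) |
| `target_rf` | 2.0 | planted RF of responsive genes against the PCGT pool |
| `effect_log2` | 2 | log2 shift of methylation odds under perturbation |
| `library_size` | 2×10⁶ | expected fragments per library (~100 per gene) |
| `dispersion` | 0.01 | NB dispersion of counts (0 = Poisson) |
| `replicate_count` | 3 | array biological replicates |
| `array_noise_sd` | 0.75 | replicate score noise, −log10 P units |

Per-gene baseline methylation is Beta(2, 2), clipped to (0.02, 0.98).
Perturbation shifts the methylation *odds* of responsive genes by
$2^{\pm\texttt{effect\_log2}}$ — knockdown lowers positive-response genes
and raises negative-response genes; overexpression is the mirror — which
keeps levels in (0, 1) without truncation artefacts. Enriched-library
expected counts are proportional to methylation × region length, scaled to
the library size, drawn negative-binomially; input libraries depend on
region length only. Array scores are Gaussian around a "present" mean of
3.0 or an "absent" mean of 0.8 (presence = methylation above 0.5), floored
at 0. The PCGT pool is organised as four overlapping component sets with a
common core, so the intersection/union lattice of real polycomb component
target lists ("all" ⊆ each component ⊆ "any") is reproduced.

**Planting the representation factor.** Responsive genes are drawn without
replacement with weight `enrichment_odds` on PCGT-pool members — the
Wallenius noncentral hypergeometric model, which is exactly what
sequential weighted sampling produces. `odds_for_rf()` inverts the
Wallenius mean equation in closed form so that the *expected* RF of the
drawn set equals the target; `target_rf = 1` gives odds 1, the exact null.
Because sequential weighted draws are order-biased (heavier genes arrive
earlier), the drawn set is permuted before being split into the positive
and negative classes. Over 200 simulations at 20 000 genes the mean
realised RF of a planted RF-2 configuration is within 1% of 2.0.

All randomness flows from a single seed through named substreams (one per
data layer, derived by a 31-bit hash), so adding or removing a layer never
perturbs the draws of the others, and the same seed reproduces a dataset
bit for bit.

**What the generator does not emulate.** Probe sequence effects, CpG
density and coupling, copy-number variation, fragment-length biases,
between-replicate correlation in the sequencing arm (conditions are single
pooled libraries, as in the emulated design), and any genuine biological
pathway structure. Passing end-to-end tests therefore demonstrates that
the *inference chain* is correct and calibrated under its stated model —
not that the caller would be well calibrated on real MeDIP data, where the
overdispersion caveat above applies.

## Problem sizes used in validation

The test-suite and acceptance runs use: exactness checks on hand-evaluable
2×2 tables; 1000 random tables for the chi-square/exact agreement; 1000
null universes of 5000 genes (both response classes tested, 2000 tests)
for enrichment-test calibration; 200 simulations at 20 000 genes for RF
recovery and interval coverage; one full end-to-end run at the default
20 000-gene scale; and 2000 null experiments (groups of 5, `n_mc` = 2000)
for the Dunnett family-wise error rate. These sizes put the Monte Carlo
standard error well inside each tolerance band while keeping a full run in
the order of a minute.

## Known limitations

* The sequencing caller ignores biological replication and overdispersion
  (see above); it is a transparent reference model, not a replacement for
  dispersion-aware callers.
* Probe-to-gene mapping for arrays is assumed done upstream; the array arm
  consumes per-gene scores.
* The exact test convention is minimum-likelihood two-sided; tail-doubling
  conventions give larger P values on asymmetric tables.
* Enrichment P values are reported raw per target set; the package leaves
  any cross-row correction to the caller because the target sets are
  nested by construction.
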