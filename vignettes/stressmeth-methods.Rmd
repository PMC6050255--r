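---
title: "Methods: spatially aware differential methylation and expression against a continuous stress score"
author: "stressmeth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatially aware differential methylation and expression against a continuous stress score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stressmeth)
```

## The problem

Severe early-life stress is associated with later psychiatric risk, and
DNA methylation is one plausible molecular intermediary. The design this
package supports is a small-cohort, saliva-based study: each participant
carries a continuous life-stress severity score (a 5-point interview
scale), an age, and an array batch label; molecular readouts are a
450k-style CpG methylation matrix (beta values with detection p-values)
and RNA-seq count matrices at the gene and isoform level. The analysis
asks three questions: which CpGs change methylation with stress exposure,
where in the genome those changes concentrate, and whether they coincide
with expression changes and known stress genes.

Two statistical features dominate the design. First, with ~20 samples,
per-CpG variance estimates are noisy, so the linear models use
empirical-Bayes variance moderation. Second, methylation is strongly
locally correlated along the genome, so multiple-testing adjustment that
treats probes as exchangeable wastes power; the package instead fits a
hidden Markov model over position-ordered test statistics and thresholds
the local index of significance (LIS), borrowing strength from adjacent
probes.

## The methylation model

Beta values $\beta \in [0,1]$ are converted to M-values
$m = \log_2(\beta' / (1-\beta'))$ with $\beta'$ clamped to
$[\epsilon, 1-\epsilon]$, $\epsilon = 10^{-6}$. Clamping rather than
dropping extreme values keeps the matrix shape stable; the transform is
strictly monotone elsewhere. Before modelling, probes are removed if they
are SNP-flagged, cross-reactive, or fail detection ($p > 0.01$) in more
than `max_failed_samples` samples. The detection default is 0 failed
samples — the strictest reading of standard array QC; the rule is
configurable because published descriptions of this filter are often
ambiguous about the tolerated failure count.

Each probe is regressed on `intercept + lsi_score + age + batch` by
ordinary least squares. Residual variances are shrunk toward a common
prior estimated by method of moments on the log sample variances
(digamma/trigamma inversion): with prior degrees of freedom $d_0$ and
prior variance $s_0^2$, the posterior variance is
$\tilde s^2 = (d_0 s_0^2 + d s^2)/(d_0 + d)$ and the moderated
$t = b / (c\,\tilde s)$ is referred to a t distribution on $d_0 + d$
degrees of freedom. The limits behave as expected and are tested:
$d_0 = 0$ reproduces the raw t exactly, $d_0 = \infty$ equalizes all
posterior variances.

Two-sided p-values are mapped to signed z-scores,
$z = \mathrm{sign}(b)\,\Phi^{-1}(1 - p/2)$, so that hyper- and
hypo-methylation remain distinguishable. An unsigned (folded) transform
was considered and rejected: the alternative emission below is a
two-component mixture precisely so that both effect directions can be
represented.

## The HMM-LIS procedure

Probes are ordered by chromosome and position. A two-state homogeneous
HMM is fitted to the z-scores by EM with forward–backward in log space:

* the null state emits $N(0,1)$ (fixed — the z construction guarantees
  this under the null);
* the alternative state emits a free two-component normal mixture
  (weights, means, SDs);
* transitions are a free 2×2 matrix; chains restart independently at
  every chromosome boundary;
* EM stops at relative log-likelihood change $<10^{-8}$ or 1000
  iterations; the default initialization (null prior 0.95, transitions
  [[0.95, 0.05], [0.3, 0.7]], means ±2, SD 1, equal weights) plus three
  randomly perturbed restarts are run and the best likelihood wins.

LIS$_i$ is the posterior probability that probe $i$ is null. Sorting LIS
ascending, the adjusted value at rank $k$ is the running mean of the $k$
smallest LIS values (aLIS); probes with aLIS $< \alpha$ (default 0.05)
are called, and the called set is always a prefix of the LIS ranking.
Thresholding the running mean controls the marginal FDR of the called
set under the fitted model.

Two design choices deserve explanation:

* **Initial-state distribution.** Each chromosome chain draws its first
  state from a shared initial distribution that is a free EM parameter,
  updated from the chain-start posteriors. Tying it instead to the
  stationary distribution of the transition matrix is appealing on
  stationarity grounds but makes the M-step no longer a maximizer of the
  EM surrogate, losing the guarantee that the log-likelihood never
  decreases — a property this package treats as a hard invariant (it is
  asserted in the tests on every fitted trace).
* **Separation constraint.** Each alternative mixture component's mean is
  constrained to $|\mu_k| \ge 1$ (in null-SD units). Without it the
  two-group decomposition is not identifiable when signal is absent or
  weak: an "alternative" that mimics $N(0,1)$ can absorb arbitrary
  occupancy at essentially equal likelihood, and posterior null
  probabilities become meaningless. Because the EM surrogate is quadratic
  in each mean, clamping to the nearest boundary is the exact constrained
  M-step, so monotonicity is untouched. The constraint reads as a mild
  scientific assumption: effects worth calling are at least one null SD
  in standardized units. Component SDs carry a floor of 0.1 for the same
  degeneracy reason.

Direction of each called DML is the sign of the Pearson correlation
between its beta values and the stress score — computed on the beta
scale, where the correlation is interpretable as a methylation-fraction
trend; an exactly zero correlation is assigned positive with a warning,
and zero-variance rows fall back to the regression coefficient sign.
Probes within 200 bp (inclusive) of a SNP are flagged as mQTL-proximal,
since such changes may be genetically rather than environmentally driven.

## Permutation enrichment

Called DMLs are tested for over/under-representation in genic structures
(TSS1500, TSS200, 5'UTR, first exon, body, 3'UTR, intergenic),
CpG-island relations (island, shores, shelves, open sea) and
chromosomes, separately for all, positive and negative DML subsets. For
structures, a probe contributes one tally per annotation it carries (a
CpG can sit in one gene's body and another's promoter); each permutation
replicate draws the same total number of annotations without replacement
from the pooled annotation multiset of all tested probes. `p_enrich` is
the fraction of replicates reaching the actual count. Ties are included
in both tails (non-strict inequalities): the degenerate universe in
which every annotation is identical then yields $p = 1$, where the
strict rule would give the anti-conservative $p = 0$. Strict mode is
available as a switch for literal reproduction of tally-above-actual
conventions, as is add-one smoothing.

For chromosomes the replicate statistic is the vector of per-chromosome
proportions among redrawn probe sets, and the default comparison is
family-wise: the actual proportion of a chromosome is compared against
the maximum permuted proportion over any chromosome (minimum for
depletion). This reads the multiple-testing correction across 22
autosomes plus X as a max-statistic adjustment; since the wording of
such procedures is often ambiguous, a marginal per-chromosome mode is
also provided, and both are tested against exhaustive enumeration on a
two-chromosome toy universe.

The default replicate count is 10,000. Sampling is without replacement;
with-replacement sampling would be defensible too, but without
replacement matches the finite-universe bookkeeping of the tally rule
and is what the hypergeometric cross-check in the tests assumes.

## The expression arm

Counts are transformed as $\log_2(x+1)$ and quantile-normalized: every
column's order statistics are replaced by the cross-column rank means,
so all columns share one empirical distribution afterwards. Ties within
a column receive the mean of the reference values their ranks span —
the common convention, stated explicitly because it matters for sparse
count data where zeros tie heavily (and it makes the exact
"identical sorted columns" property hold only for tie-free input). The
same moderated linear model as the methylation arm is then fitted, and
features with moderated $p < 0.05$ are called — deliberately with no
multiple-testing correction, matching the exploratory design this
pipeline reproduces; the unique DE gene set is the union of called genes
and parent genes of called isoforms. The base-2 logarithm is a
convention choice (the transform's base only rescales coefficients).

## Integration

Each DML is assigned to the gene whose span contains it, else the gene
with minimal distance to the nearer span boundary on the same chromosome
(ties alphabetical; TSS-distance mode available as an option — span
distance was chosen as the default because gene-body methylation is a
first-class signal in this design, not an afterthought of promoter
proximity). Genes enter the positive set if they host at least one
positive DML and likewise for negative, so a gene can carry both labels;
inclusion–exclusion ($|P| + |N| - |P \cap N| = |P \cup N|$) is
re-verified at run time and a violation aborts the run. Overlaps among
methylation genes, DE genes and a curated stress-gene list are reported
as seven-region Venn counts, and 2×2 enrichments against the curated
list use the Yates-corrected chi-square
$\sum (\max(|O-E| - 0.5,\, 0))^2 / E$ on 1 df. The correction term is
clamped at zero so that exact proportional agreement yields a statistic
of 0 (the unclamped textbook expression would otherwise report spurious
association at equality); this matches `stats::chisq.test(correct =
TRUE)`, against which the implementation is verified on random tables.
The chi-square universe retains the gene set itself (membership
dichotomy) rather than excluding it.

## Motif stage

Flanking sequence ±250 bp around each called DML is written as FASTA for
external discriminative motif tools. An internal k-mer check makes this
stage testable end to end: for every canonical k-mer (k-mer and reverse
complement collapsed; k from 4 to 8 by default) present in the
foreground, a sequence-level presence table against a background is
scored by a one-sided Fisher exact test, with E-value = p × number of
distinct k-mers tested. Presence counting (one hit per sequence,
ZOOPS-like) rather than occurrence counting follows discriminative-motif
convention and is robust to repeat-rich single sequences. The default
background is a per-sequence dinucleotide shuffle (Eulerian-path
construction, preserving the exact dinucleotide multiset and hence CpG
density); a mononucleotide mode exists for contrast. The internal
E-value cutoff defaults to $10^{-3}$, a desk-scale detectability choice;
external tools are typically run stricter, and the cutoff is a config
value.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes,
with planted truth for every arm:

* **Genome**: a miniature annotation (4 chromosomes × 50 genes by
  default) with ≥2 kb intergenic gaps and promoter CpG islands on ~60%
  of genes. Probes are annotated against it with the standard promoter
  windows (TSS200 = [TSS−200, TSS−1], TSS1500 = [TSS−1500, TSS−201],
  strand-adjusted) and island relations (shores ±2 kb, shelves 2–4 kb).
* **Cohort**: 22 samples, ages uniform on 9–12 years, stress score on
  [1, 5] with half the cohort drawn from the low and half from the high
  end, two alternating batches — the study design the pipeline targets.
* **Methylation**: M-values are `baseline + b·lsi + a·age + batch +
  AR(1) noise`, mapped through the inverse logit2. Baselines are bimodal
  (±2.5), emulating the two-mode beta distribution of real arrays.
  Effects are planted as 10 contiguous clusters of 12 probes (one slope
  per cluster, magnitude uniform on [0.25, 0.6] M-units per score unit,
  random sign), and noise is AR(1) along probe order within chromosome
  (marginal SD 0.5, ρ = 0.3). The local correlation is the feature the
  HMM exploits; AR(1) is the simplest stationary model with that
  property, chosen in the absence of a stated dependence model. Slope
  magnitudes give per-probe moderated |t| of roughly 3–8 at n = 22 —
  detectable but not trivial. `noise_sd = 0` is the exact noiseless
  regime used by recovery tests; only negative values are rejected.
* **Detection failures** are planted independently per (probe, sample)
  at rate 0.002; flags (SNP, cross-reactive) at 5% each.
* **Expression**: negative-binomial counts (dispersion 0.1) with log2
  mean linear in the centered stress score for planted DE features; gene
  abundance offsets are normalized so the cohort-average count equals
  the configured depth, making the generator's moments directly
  checkable and fitted log2-scale coefficients comparable to planted
  slopes. Half of the planted DE genes (configurable) are drawn from
  genes hosting methylation-effect probes, giving the integration stage
  real shared signal.
* **Gene list**: effect genes enter a curated-list emulation at
  `enrichment_factor ×` the base rate (capped at 1); factor 1 is the
  exact null, verified by simulation.
* **Motif**: a 4–12 bp motif can be overwritten (not inserted) at random
  flank offsets in a chosen fraction of probes; flanks are stored at a
  fixed 501 bp with N-padding at chromosome ends so the motif window and
  the flank window coincide.

What the generator does **not** emulate: raw array intensities and their
normalization chain, bisulfite chemistry, read-level RNA-seq, cell-type
composition, population structure, or any dependence between methylation
level and expression beyond the planted gene overlap. Passing tests
therefore demonstrate correctness of the statistical machinery under the
stated model, not robustness to the full messiness of real cohorts —
in particular, the FDR guarantees shown on synthetic data assume the
null z-scores really are N(0,1), which on real data is the job of the
covariate model (and diagnostics such as surrogate-variable analysis,
out of scope here).

## Numerical choices and degenerate inputs

* Variance-prior moments need ≥10 usable features; fewer is an error.
* Zero-residual-variance features get `p = NA`, are excluded from the
  HMM stage with a warning, and never silently propagate.
* Rank-deficient designs abort with the collinear columns named.
* LIS ties are broken by genomic order; the running mean is insensitive
  to the order within ties.
* Beta values are clamped to the open interval before the logit; p is
  clamped at $10^{-300}$ before the z transform.
* Permutation replicates below 1000 are rejected; the full permutation
  stream is a deterministic function of one seed.
* Every generator and every stochastic stage takes an explicit seed and
  is byte-reproducible; the pipeline derives per-stage seeds from one
  master seed and logs them, so stages can be re-run in isolation.

## Problem sizes used in validation

The packaged validation suite runs at deliberate desk scale: 2,000
probes × 22 samples × 20 replicates for the FDR/power benchmark, 10,000
permutation replicates for the enrichment oracle, 20 seeds for null
calibration of the expression arm, 200 random draws for permutation-p
uniformity, and 10 seeds × 200 sequences for motif recovery. These sizes
were chosen so that Monte-Carlo error is small relative to the margins
being asserted while a full run stays in the minutes range.

```{r demo, eval = FALSE}
# a complete miniature run
cfg <- pipeline_config(seed = 1, out_dir = "run1",
                       simulate = list(n_chromosomes = 2,
                                       genes_per_chromosome = 25,
                                       n_probes = 600, n_samples = 12,
                                       motif = "TACGTA"),
                       reps = 1000)
res <- run_pipeline(cfg)
res$integration$counts
```

## Known limitations

* Transitions are homogeneous; distance-dependent transition kernels
  (decaying dependence with genomic gap) are not implemented in v1.
* The alternative emission is fixed at K = 2 components; heavier-tailed
  effect distributions would need a larger K or a t-mixture.
* No surrogate-variable analysis or cell-type deconvolution: the
  covariate model is taken as given.
* The chi-square tests treat genes as exchangeable units, ignoring gene
  length and probe density, which is a known bias of list-enrichment
  tests on array designs.
* The k-mer stage ranks exact sequences only; it does not generalize to
  degenerate motifs, spacing constraints, or factor identity.
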