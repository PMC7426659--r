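---
title: "Quantitative microbiome profiling: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative microbiome profiling: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qmprofiler)
```

## Why absolute abundances

16S rRNA gene amplicon sequencing delivers *compositions*: per-sample read
counts whose total is an artifact of library preparation, not of the ecosystem.
Two very different gut states — a bloom of one genus versus a die-off of all
the others — produce identical proportion vectors. Relative microbiome
profiling (RMP) therefore cannot distinguish them, and changes in one abundant
taxon induce spurious, sign-flipped changes in every other taxon's proportion.

Quantitative microbiome profiling (QMP) breaks this degeneracy by anchoring
the sequencing profile to an externally measured *microbial load* (total
microbial cells per gram of feces). The anchor can come from flow-cytometry
cell counting, from qPCR/ddPCR quantification of total 16S copies, and either
can be combined with a viability-dye (PMAxx) pre-treatment that removes
extracellular DNA and DNA in membrane-compromised cells before amplification.
This package implements the four resulting normalizations — RMP, QMP, QMP-PMA,
QMP-qPCR — plus the instrument-level models behind the anchors, the statistics
used to compare the methods, and a synthetic cohort generator that makes the
whole workflow testable against known ground truth.

## The QMP normalization

Let $C_{ts}$ be reads of taxon $t$ in sample $s$, $k_t$ the 16S rRNA gene
copy number per genome of taxon $t$, and $L_s$ the measured load (cells/gram).

1. **Copy-number correction.** $C'_{ts} = \mathrm{round}(C_{ts}/k_t)$, with
   corrected depth $D_s = \sum_t C'_{ts}$. Rounding is half-away-from-zero by
   default; `floor` and expectation-preserving probabilistic rounding are
   options. A low count of a high-copy taxon can round to zero — this is
   reported, not hidden, because it is exactly the "rare taxa vanish at low
   sampling depth" behaviour the method trades for quantitative
   interpretability.
2. **Even sampling depth.** The sampling depth of a sample is
   $SD_s = D_s / L_s$ — corrected reads observed per cell/gram actually
   present. Samples are subsampled without replacement (multivariate
   hypergeometric) to $n_s = \lfloor SD_{\min} \cdot L_s \rfloor$ reads, so
   every sample represents its community with the same reads-per-cell. The
   floor guarantees feasibility ($n_s \le D_s$); a tiny numerical nudge keeps
   the $SD_{\min}$-defining sample from losing one read to floating-point
   round-off. Realized depths satisfy $|n_s/L_s - SD_{\min}| \le 1/L_s$.
3. **Scaling.** Abundances are $(r_{ts}/n_s) \cdot L_s$ cells/gram, where
   $r_{ts}$ are the rarefied counts. Row sums equal the anchored loads by
   construction.

QMP-PMA is the same algorithm applied to counts sequenced after PMA treatment
(so only intact cells contribute reads). QMP-qPCR derives the anchor from the
molecular side: the per-sample average 16S copy number
$A_s = R_s / D_s$ (raw over corrected depth) converts qPCR copies/gram $Q_s$
into $L_s = Q_s / A_s$, after which the standard QMP normalization runs
unchanged. When $Q_s$ encodes exactly $L_s \cdot A_s$, the two routes coincide
(bit-identically for unit copy numbers; to floating-point round-off of the
single extra division otherwise).

Rarefaction is implemented as sequential univariate hypergeometric draws,
which samples the exact multivariate hypergeometric distribution; tests verify
its marginals against full enumeration on small rows.

## Quantification models

* **Flow cytometry** counts only intact cells: gate events divided by the
  gravimetrically determined acquired volume, times dilution. The
  extracellular DNA compartment is invisible to it.
* **qPCR** is quantified against a standard curve, $Ct = a + b\log_{10}
  (\text{copies})$, fitted by ordinary least squares; amplification efficiency
  is $10^{-1/b} - 1$. Copies per reaction scale to copies/gram through
  user-supplied dilution and elution factors — these depend on the extraction
  protocol and are deliberately not constants.
* **ddPCR** uses droplet Poisson statistics: with positive fraction $p$ and
  droplet volume $v$ (default 0.00085 µL), concentration is $-\ln(1-p)/v$.
  A saturated well is a hard error rather than a clipped value — silent
  clipping would bias loads; a zero-positive well returns 0 with a
  below-detection flag.
* **PMA differencing.** For paired aliquots measured untreated and after PMA
  treatment on the same extract, $f_s = (U_s - T_s)/U_s$ estimates the
  fraction of metagenomic DNA that was extracellular or in dead cells. Because
  both measurements share the aliquot's extraction yield, that yield cancels
  in the ratio — the estimator is invariant to per-aliquot multiplicative
  bias, which is the argument for pairing on a shared extract.
* **ΔCt arithmetic.** A Ct increase of $\Delta$ at efficiency $E$ is a signal
  reduction of $1-(1+E)^{-\Delta}$. With several spiked samples, the default
  computes the reduction from the mean ΔCt; a `per_sample` mode averages
  per-sample reductions instead. The two differ by Jensen's inequality
  (99.968% vs. slightly less for a ΔCt spread of 10.2–12.7 around 11.6) and
  published roundings to four significant digits are consistent with either,
  so neither is asserted as canonical.

## The synthetic cohort generator

The generator emulates the study design the package targets: 16 subjects
sampled in duplicate, with three measurement channels per sample.

* **Community structure.** Each subject follows one of two enterotype
  templates — *Bacteroides*-dominant or *Prevotella*-dominant — via a
  Dirichlet draw (precision 120) around the template composition with
  additional per-taxon log-normal variation (CV 0.3). Two fixed templates are
  the simplest structure that makes enterotype recovery testable.
* **Loads.** Total intact loads are uniform on the log scale within
  1.2–5.3×10¹⁰ cells/gram. The underlying study reports only the min, max and
  median of its cohort, not a distribution; log-uniform is a deliberate,
  documented choice.
* **Extracellular compartment.** A per-sample fraction $f_s$ of metagenomic
  DNA is extracellular/dead, drawn from a Beta with mean 0.39 and precision
  150 (a realistic, tight spread; the printed evidence constrains the mean,
  not the dispersion). By default cell death is proportional across taxa, so
  PMA treatment changes load but not composition — matching the observation
  that treated and untreated quantitative profiles remain highly similar. A
  `death_bias = "biased"` switch draws per-taxon death propensities to test
  detection of the opposite scenario.
* **Moisture and richness.** Stool moisture is Beta-distributed on 10–40%,
  and genus richness is thinned monotonically in moisture with noise,
  targeting a rank-correlation magnitude around 0.7 at large cohort size. At
  n = 16 the realized correlation is, correctly, noisy.
* **Measurement noise.** Flow cytometry: log-normal counting noise (CV 0.05).
  Molecular loads: a log-normal extraction-yield factor (CV 0.5) drawn per
  aliquot and shared between the untreated/PMA halves of that aliquot and
  between qPCR and ddPCR on the same extract, plus independent per-measurement
  technical noise (CV 0.1). The shared-yield structure operationalizes the
  hypothesis that extraction yield, uncorrelated with true load, is the
  dominant error of molecular quantification. Sequencing depths are uniform
  over 153,527–282,297 reads. All noise is mean-1 multiplicative, so every
  channel returns its analytic expectation exactly in the zero-CV limit.
* **Seeding.** One master seed; every operation derives its own sub-seed
  deterministically, so a whole study is reproducible while stages remain
  independently re-runnable.

What the generator does **not** model: read-level errors, chimeras, primer
bias, taxonomic misclassification, compositional zeros from detection limits,
or any covariance between load and enterotype. Passing tests therefore
demonstrate correctness of the normalization and inference machinery under a
known sampling model — not robustness to the full messiness of real amplicon
data.

## Statistical comparison layer

Profiles are compared with per-sample observed genus richness, Bray–Curtis
dissimilarity ($\sum_t |x_t-y_t| / \sum_t (x_t+y_t)$) and classical PCoA
(negative eigenvalues reported, not corrected; Bray–Curtis is not a metric and
the triangle inequality is deliberately not asserted). Within-method
dissimilarity is the distance between a subject's two replicate profiles;
between-method dissimilarity pairs the same subject's profiles across methods,
replicate-matched by default (an `all-cross` option exists; the underlying
design is ambiguous on this point). Bray–Curtis on QMP-family profiles is
computed on the absolute cells/gram matrices by default — so scale differences
between methods count as dissimilarity — with a `normalize` option for purely
compositional comparison; note that comparing RMP (proportions) against a
QMP-family profile on the absolute scale is dominated by the scale gap and is
only meaningful with normalization.

Rank concordance between methods uses Kendall τ-b per genus across samples,
for the 15 most abundant genera ranked in a reference profile (RMP by
convention). Paired Wilcoxon signed-rank and Mann–Whitney U tests are exact by
enumeration for small samples — including tied data, via midrank
enumeration/dynamic programming — and normal approximations with tie and
continuity corrections otherwise; all tests are two-sided and families of
comparisons are corrected with Benjamini–Hochberg FDR.

## Enterotyping

Counts are clustered with a Dirichlet-multinomial mixture fitted by EM. Both
the E-step and the Minka fixed-point M-step are minorize-maximize steps, so
the log-likelihood is non-decreasing (asserted to 1e-8 in tests). k-means on
proportion rows seeds the responsibilities; three restarts per K by default;
convergence at relative log-likelihood change < 1e-6 or 500 iterations, with
Dirichlet parameters floored at 1e-10 against boundary collapse.

Model selection across K defaults to **BIC**. A Laplace approximation to the
model evidence is implemented (blockwise Hessian with the analytic
diagonal-plus-rank-one structure of each component's curvature), but measured
behaviour on data simulated from a single DM component shows it is
anticonservative precisely where it matters: when an extra component
duplicates an existing one, the likelihood surface is locally singular,
$\det(-H)$ collapses and the approximate evidence inflates, so K = 2 beats
K = 1 even on one-component data. BIC's explicit $\tfrac{p}{2}\log S$ penalty
selects correctly on both one- and two-template data at these sample sizes,
hence the default; `selection = "laplace"` remains available.

Two further notes. First, the number of DM components is only well-defined
relative to the DM family: the full generator adds log-normal and
richness-thinning variation beyond Dirichlet-multinomial sampling, so on deep
data the criterion can legitimately prefer K = 3 — real extra structure, not a
bug. The model-selection checks therefore run on data drawn from actual DM
components. Second, the end-to-end pipeline always retains the two-component
solution (`labels_k2`) for the binary enterotype comparison (load shift
between the two community types via Mann–Whitney), independent of the selected
K. Pipeline enterotyping runs on counts rarefied to an even 10,000 reads —
deep enough for clean template recovery, shallow enough to keep the DM
likelihood well-conditioned.

## Numerical and design choices worth knowing

* Replicate loads: per-subject load = mean of that subject's flow-cytometry
  replicate measurements, applied to both sequencing replicates (average total
  cell count per gram); per-replicate pairing is available.
* Taxa missing from the copy-number table take the table mean by default
  (logged); an explicit `NA` default turns this into an error.
* Samples whose sampling depth would drag $SD_{\min}$ down can be dropped via
  `min_sampling_depth`; the default keeps all samples.
* `rmp_profile` errors on samples below the target depth, listing them, with
  `drop_below = TRUE` to drop instead.
* The 12-species mock-community specification is synthetic: plausible species
  and copy numbers whose mean reproduces the 6.435 copies/genome average used
  in fixed-copy-number conversion, not a certified composition. Its dilution
  series is an exact 2-fold ladder even though published endpoint pairs are
  not exactly 2-fold.
* The divergence-mechanism demonstration (QMP vs QMP-qPCR) is run with the
  extracellular compartment switched off: with it on, the untreated qPCR
  anchor includes extracellular DNA and the two methods differ by a real
  systematic offset that does not vanish as extraction noise goes to zero,
  which would confound the statement "the divergence is driven by
  extraction-yield variability".
* PMA differencing recovery is assessed as a Monte-Carlo average over repeated
  cohorts of n = 16: the estimator's sampling SD in a single cohort (~0.018)
  is comparable to the ±0.02 band of interest, while its bias
  ($\mathbb{E}[e_2/e_1] > 1$ for the independent technical-noise pair) is
  about −0.006 and well within it.

## Problem sizes used in tests

Unit and acceptance tests run on cohorts of 6–16 subjects with 20–80 taxa and
depths of 4×10³–2×10⁵ reads, 10⁵ rarefaction draws for the hypergeometric
oracle, 20 cohorts for PMA recovery, and DMM fits at n = 32 samples × depth
10⁴. These sizes give the Monte-Carlo checks comfortable margins while keeping
the whole suite fast.

## Limitations

Absolute profiles inherit every bias of their anchor: flow-cytometry gating,
extraction yield for molecular anchors, and 16S copy-number tables that are
incomplete and genus-averaged. The package quantifies the propagation of such
biases under a known model; it cannot certify any particular anchor as
correct for a given real dataset. Reference-based enterotype classification
against external models, read-level processing, and taxonomy assignment are
out of scope.
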