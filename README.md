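# qmprofiler

Quantitative microbiome profiling (QMP) and microbial load quantification
for 16S rRNA gene amplicon data.

## The problem

Amplicon sequencing yields compositions: per-sample read proportions whose
total carries no information about how many microbes were actually present.
Under relative microbiome profiling (RMP), a bloom of one taxon and a die-off
of all others are indistinguishable, and any real change in one abundant genus
induces spurious opposite-signed changes in every other genus's proportion.

QMP removes this degeneracy by anchoring each sample's sequencing profile to
an independently measured microbial load. With read counts `C_ts`, 16S copy
numbers `k_t` (copies/genome) and load `L_s` (cells/gram):

1. copy-number-correct: `C'_ts = round(C_ts / k_t)`, depth `D_s = sum_t C'_ts`;
2. define the sampling depth `SD_s = D_s / L_s` (reads per cell/gram) and
   rarefy every sample to `n_s = floor(min_s SD_s * L_s)` reads — *even
   sampling depth* across samples;
3. scale: `abundance_ts = (r_ts / n_s) * L_s` cells/gram, so each sample's
   abundances sum to its measured load.

The load anchor can be a flow-cytometry cell count (QMP), the same after
viability-dye PMAxx pre-treatment that removes extracellular and dead-cell DNA
(QMP-PMA), or a qPCR 16S quantification converted to cells via the
sequencing-derived average copy number per cell `A_s = R_s / D_s` (QMP-qPCR).
The package implements all four normalizations, the instrument-level models
behind them (gravimetric FACS concentration, qPCR standard curves, ddPCR
Poisson quantification, paired PMA differencing of the extracellular DNA
fraction, ΔCt signal-reduction arithmetic), the statistical layer used to
compare methods (richness, Bray–Curtis + PCoA, per-genus Kendall τ-b rank
concordance, exact paired Wilcoxon / Mann–Whitney tests, Benjamini–Hochberg
FDR), Dirichlet-multinomial mixture enterotyping with BIC/Laplace model
selection, and a synthetic fecal-cohort generator that emulates all three
measurement channels so the entire workflow is testable against known ground
truth.

## Worked example

Simulate a cohort of 16 subjects in duplicate (two enterotype templates,
loads in 1.2–5.3e10 cells/g, ~39% extracellular DNA, 153,527–282,297
reads/sample) and run the full four-method comparison:

```r
library(qmprofiler)

cfg   <- qmp_sim_config(seed = 42)
study <- simulate_study(cfg)
res   <- run_qmp_study(cfg, study = study)

study$truth
#> Synthetic community truth
#>   80 taxa x 16 subjects (2 replicates/subject when measured)
#>   loads: 1.21e+10 - 5.18e+10 cells/g; enterotypes: Bacteroides=8, Prevotella=8
#>   mean extracellular DNA fraction: 0.395

res$profiles$QMP
#> QMP profile: 80 taxa x 32 samples (cells/gram)
#>   minimum sampling depth: 5.503e-07 reads per cell/gram
#>   rarefied depths: 7154 - 28342 reads

res$extracellular
#> PMA differencing on 32 paired samples
#>   mean extracellular fraction: 0.365 (36.5% of metagenomic DNA)
#>   mean absolute decrease: 1.003e+11 copies/gram
#>   paired Wilcoxon p = 8.3e-07

res$dissimilarity
#> Replicate/method dissimilarity analysis (Bray-Curtis, matched pairing)
#>   medians:
#>     QMP                          0.0208
#>     QMP-PMA                      0.0197
#>     QMP-qPCR                     0.0316
#>     RMP                          0.0059
#>     QMP vs QMP-PMA               0.0194
#>     QMP vs QMP-qPCR              0.2355
#>     ...
```

Reading the numbers: the PMA differencing estimator recovers the simulated
extracellular DNA fraction (0.365 estimated vs. 0.39 configured, within the
sampling noise of 16 subjects); replicate profiles of the same method agree
closely (within-method Bray–Curtis ≈ 0.02); PMA pre-treatment barely changes
quantitative profiles (QMP vs QMP-PMA ≈ 0.019, on par with replicate noise)
because simulated cell death is proportional across taxa; anchoring on qPCR
instead of cell counts produces much more divergent profiles
(QMP vs QMP-qPCR ≈ 0.24) because the per-aliquot DNA extraction yield varies
(CV 0.5) and the untreated qPCR anchor also sees extracellular DNA. RMP rows
are proportions, so their distance to any cells/gram profile is dominated by
scale — compare them with `normalize_bc = TRUE` if a compositional contrast
is wanted.

Individual stages are available directly: `rarefy_counts()`,
`copy_number_correct()`, `rmp_profile()`, `qmp_profile()`,
`qmp_qpcr_profile()`, `fit_standard_curve()` / `ct_to_copies()`,
`ddpcr_concentration()`, `estimate_extracellular_fraction()`,
`delta_ct_signal_reduction()`, `fit_dmm()` / `dmm_assign()`, and TSV
readers/writers (`read_count_table()`, `read_load_table()`, ...) so simulated
and real data are interchangeable on disk.

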