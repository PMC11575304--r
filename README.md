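# metacrispr

Personal identification from skin and saliva microbiomes by amplicon
sequencing of *Streptococcus* CRISPR spacers ("metaCRISPR typing").

## The problem

Forensic DNA analysis relies on STR typing of human DNA and fails on
extremely low-biomass traces — a swab of a touched keyboard may hold almost
no human cells. Skin, however, carries abundant bacterial DNA, and the
CRISPR arrays of *Streptococcus* record each strain's phage-encounter
history as an ordered set of unique 20–40 nt **spacers**, making spacer
composition a highly personalized marker. metaCRISPR typing amplifies the
spacers of two streptococcal loci (CRISPR3, CRISPR1) with primers annealing
inside the conserved repeat, sequences the amplicons on a MiSeq, and
compares spacer profiles between a questioned sample and the donor's
reference saliva.

`metacrispr` implements the complete desk side of the assay as a tidyverse-
style R package:

- **Spacer extraction** — modified-Mott quality trimming, repeat-primer
  removal (≤ 2 substitutions), read-through trimming, pair reconciliation,
  primer-dimer artifact classification, and the inclusive 20–40 nt length
  filter. Every read pair receives exactly one artifact label.
- **Denoising** — dereplication into amplicon sequence variants (ASVs) and
  an abundance-ratio collapse (parent ≥ 32× child within Hamming distance 1,
  per sample, to a fixed point).
- **Identity calling** — Bray–Curtis dissimilarity
  `1 − 2·Σ min(uᵢ,vᵢ)/(Σu + Σv)` on ASV counts, the strict `distance < 0.8`
  same-source rule, ROC/AUC threshold calibration, Kruskal–Wallis and
  Mann–Whitney group comparisons, significance-gated Spearman correlations.
- **Quantification QC** — qPCR standard-curve fitting (Cq vs log₁₀ copies),
  amplification efficiency, copies/µL estimation with duplicate averaging,
  and the ≥ 10² copies/µL quality gate below which typing is
  noise-dominated.
- **STR comparison** — exact allele-set comparison over a 21-locus
  autosomal panel with dropout/drop-in categories and correct-locus rates.
- **Simulation** — a seeded generative model (Poisson template sampling,
  lognormal PCR dispersion, dimer-mass library competition, household
  spacer sharing, per-base errors) that reproduces the assay's
  copy-number-dependent reproducibility and makes every module testable
  without any sequencing download.

## Worked example

```r
library(metacrispr)

# Spacer copy-number survey bundled with the package (22 skin, 11 saliva,
# 4 object samples): skin carries ~1000x fewer spacer copies than saliva.
tab <- survey_copy_table()
summarize_copies(tab, "skin",   "CRISPR3")   # 362.1 copies/uL
summarize_copies(tab, "saliva", "CRISPR3")   # 136955.8 copies/uL

# qPCR standard curve from a perfect 10-fold plasmid dilution series
std <- tibble::tibble(copies_per_ul = 10^(6:2),
                      cq = c(20.0, 23.3219, 26.6439, 29.9658, 33.2877))
glance(fit_standard_curve(std))
#>   slope intercept r_squared efficiency_pct loq_copies_per_ul n_points
#> 1 -3.32      39.9     1.000          100.0               100        5

# Simulated dilution series of a 4-spacer standard array, full pipeline:
# reproducibility collapses between 10^1 and 10^2 template copies.
arr <- make_array("CRISPR3", 4, seed = 1)
dilution_experiment(arr, config = sim_config(), seed = 42)
#> <dilution_result> reference: c1000_r1
#>   copies_per_ul mean_distance
#> 1          1000        0.0174
#> 2           100        0.345
#> 3            10        0.842
#> 4             1        0.999

# Bundled neat-sample typing results: 6 of 8 skin swabs are similar
# (distance < 0.8) to the donor's saliva at CRISPR3, while STR typing gave
# one full profile of eight (mean correct-locus rate 83%).
neat <- typing_comparison_table("neat")
table(identity_call(neat$bc_crispr3))
#> different_source      same_source
#>                2                6
summarize_profiles(profile_rates(neat$correct_loci))
#>   n_profiles full_profile_count mean_rate_pct
#> 1          8                  1            83
```

The mean distances show the assay's quality-control logic: at 10³ template
copies every replicate is nearly identical to the reference, at 10⁰ the
profile is noise. Hence the ≥ 10² spacer copies/µL gate enforced by
`qc_assess()` before a sample is typed.

## Package layout

| Area | Functions |
| --- | --- |
| IO | `read_fastq()`, `write_fastq()`, `read_paired_fastq()`, `read_copy_table()`, `read_asv_table()`, `write_asv_table()`, `read_str_profiles()` |
| Extraction | `quality_trim()`, `find_and_trim_primer()`, `reconcile_pair()`, `classify_artifact()`, `extract_sample()`, `extract_pairs()` |
| Denoising | `dereplicate()`, `collapse_errors()`, `drop_empty()` |
| Quantification | `fit_standard_curve()`, `copies_from_cq()`, `qc_assess()`, `summarize_copies()` |
| Diversity & identity | `bray_curtis()`, `alpha_diversity()`, `pairwise_distances()`, `call_identity()`, `roc_curve()`, `group_distances()`, `spearman_gated()` |
| STR | `compare_locus()`, `compare_profile()`, `profile_rates()`, `summarize_profiles()` |
| Simulation | `sim_config()`, `make_array()`, `make_household()`, `simulate_sample()`, `dilution_experiment()`, `write_paired_fastq()` |

Fitted objects (`standard_curve`, `roc_result`) have `tidy()`/`glance()`
methods and `autoplot()` figures; `plot_dilution_reproducibility()` draws
the copy-number readout. The methods vignette
(`vignettes/metacrispr-methods.Rmd`) documents the models, parameter
defaults and design decisions in detail.
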