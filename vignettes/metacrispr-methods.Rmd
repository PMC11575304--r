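---
title: "metaCRISPR typing: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{metaCRISPR typing: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metacrispr)
```

## The problem

Forensic personal identification rests on STR (short tandem repeat) typing
of human DNA, which fails on extremely low-biomass traces such as swabs of
touched objects. Skin, however, carries far more bacterial than human DNA,
and the CRISPR arrays of *Streptococcus* — alternating conserved repeats and
unique 20–40 nt spacers recording past phage encounters — are highly
personalized. metaCRISPR typing amplifies the spacers of two streptococcal
loci (CRISPR3 and CRISPR1) with primers annealing inside the repeat,
sequences the amplicons, and compares the resulting spacer-composition
profiles between a questioned sample and a reference. Saliva is used as the
reference material because the oral microbiome is rich in streptococcal
CRISPRs and shares its spacer repertoire with the skin of the same person.

This package implements the full desk side of that assay: spacer extraction
from paired-end reads, denoising into amplicon sequence variants (ASVs),
Bray–Curtis identity calling with ROC calibration, qPCR-based spacer
quantification with a copy-number quality gate, STR-profile comparison for
the complementation analysis, and a generative simulator that reproduces the
assay's copy-number-dependent reproducibility.

## Spacer extraction

Each read pair passes a fixed filter chain, and every pair receives exactly
one label (so label counts always sum to the input count):

1. **Quality trimming** (`quality_trim()`): a modified-Mott criterion with
   error limit 0.01 (the Q20 equivalent). Each base contributes
   $0.01 - 10^{-Q/10}$ and the contiguous window maximizing the cumulative
   score is kept; ties prefer the longer, leftmost window. A read whose
   bases all fall below Q20 trims to empty (`quality_fail`). The original
   assay used a commercial trimmer whose exact mode is not public;
   Mott-style trimming at the Q20 limit is the standard open equivalent, and
   the implementation is verified against an exhaustive $O(n^2)$
   window-search oracle.
2. **Primer removal** (`find_and_trim_primer()`): the locus-specific repeat
   primer must match as a prefix of its mate (forward primer on R1, reverse
   on R2) with at most 2 substitutions and no indels. Indel-tolerant
   matching would add alignment machinery for negligible yield on short,
   high-quality MiSeq primer regions.
3. **Read-through trimming**: because inserts (20–40 nt) are much shorter
   than the 151 nt reads, each mate reads through into the opposite primer;
   a 12 nt anchor of the opposite primer's reverse complement (≤ 1 mismatch)
   marks the cut.
4. **Pair reconciliation** (`reconcile_pair()`): equal-length inserts with
   at most one mismatch merge, the higher-Phred base winning; anything else
   is a `pair_conflict`. Because simulated (and most real) errors hit only
   one mate, reconciliation removes the bulk of sequencing errors before
   denoising.
5. **Artifact classification** (`classify_artifact()`): no-template controls
   of this assay are dominated by primer dimers whose post-trim inserts are
   fragments of the fusion primers. An insert whose reverse complement
   matches a prefix (≥ 15 nt, ≤ 1 mismatch) of an Illumina overhang tail is
   labelled `primer_dimer_rev_tail`; one sharing a ≥ 15 nt fragment
   (≤ 1 mismatch) with a fusion primer is `primer_dimer_fwd`. Detection is
   implemented as a fuzzy 15-mer dictionary lookup (two trusted-band
   dictionaries cover a mismatch at any position), which is exactly
   equivalent to a window scan but runs as one vectorized call.
6. **Length filter**: spacers must be 20–40 nt inclusive — the bounds are
   inclusive because the assay removes reads *shorter than* 20 or *longer
   than* 40 nt. Any `N` in the final spacer discards the pair
   (`quality_fail`), since ASV identity is exact-sequence.

Spacers are reported in forward-primer orientation; with a single locus and
fixed primer orientation no lexicographic canonicalization is needed.

## Denoising

`dereplicate()` collapses exact sequences per sample; `collapse_errors()`
then merges each sequence into the most abundant sequence within Hamming
distance 1 whose count exceeds it at least 32-fold, repeating per sample
until a fixed point. The 32-fold ratio is the one denoising parameter the
assay specifies (`min_fold_parent_over_abundance = 32` in its DADA2
configuration); full error-rate learning is deliberately not re-implemented
because the discriminative signal of the assay is the presence and abundance
of exact spacers, not subtle error structure. Merging is per-sample (the
DADA2 default), parents are chosen deterministically (most abundant, ties by
lexicographically smaller sequence), and per-sample totals are conserved.
Chimera removal is omitted: 20–40 nt inserts are below any meaningful
chimera-detection scale. This is a documented divergence from DADA2
defaults.

## Quantification and the copy-number quality gate

`fit_standard_curve()` regresses Cq on $\log_{10}$(copies/µL) over a serial
plasmid dilution (10⁶ down to 10² copies/µL); the amplification efficiency
is $(10^{-1/\text{slope}} - 1) \times 100$ and the limit of quantification
(LOQ) is the lowest standard, 10² copies/µL. `copies_from_cq()` inverts the
curve and averages qPCR duplicates on the linear copies scale (the assay
description is silent on the averaging scale; linear-scale averaging is the
conventional choice and is flagged here). Samples with no amplification in
any replicate are ND.

Numerical conventions in `summarize_copies()` were reverse-engineered from
the bundled survey table and verified in tests: ND contributes zero with the
row kept in the denominator, and below-LOQ values enter as printed. Under
exactly these conventions the four printed survey means (362.1 and 4,720.9
copies/µL for skin, 136,955.8 and 454,586.0 for saliva) are reproduced to
the printed decimal.

The QC gate (`qc_assess()`) passes a sample at ≥ 100 spacer copies/µL of
extract — the minimal spacer load at which typing is reproducible (see the
simulator section). Copies are interpreted as concentrations of the DNA
extract, not of the original sample volume; the assay tables do not state
the reference volume and the extract interpretation is the one under which
the published means recompute exactly.

## Identity calling, ROC and statistics

`bray_curtis()` implements
$d(u, v) = 1 - 2\sum_i \min(u_i, v_i) / (\sum_i u_i + \sum_i v_i)$ on raw
counts. Two all-zero profiles are defined to have distance 1 (with a
warning): diluted libraries can lose every read, and such samples must still
compare as maximally dissimilar. Raw (unrarefied) counts are used
deliberately — the depth imbalance between a noise-starved library and its
reference is part of the reproducibility signal.

`call_identity()` calls `same_source` when the distance is strictly below
the threshold (default 0.8); equality is `different_source`, because the
rule is "below 0.8". `roc_curve()` sweeps the same classifier over all
observed distances, computes sensitivity over same-individual pairs and
specificity over different-individual pairs, AUC by the trapezoid rule
(equivalent to Mann–Whitney pair counting with half-credit ties, verified
exhaustively), and reports the Youden-optimal threshold with deterministic
tie-breaks (higher specificity, then lower threshold). Same-individual pairs
are the positive class; within-household pairs count among the negatives,
which is the conservative convention for a forensic false-positive.

`group_distances()` partitions skin-versus-saliva pairs into
within-individual, within-household and between-household groups
(Kruskal–Wallis across groups; pairwise Mann–Whitney U, exact for group
sizes ≤ 8, normal approximation with tie correction otherwise; Bonferroni by
multiply-and-cap). `spearman_gated()` reports a rank correlation only when
its p-value clears 0.05, the reporting rule of the assay's own analyses.

`shannon()` uses log base 2 (configurable); the upstream pipeline this
mirrors does not record its log base, so the common amplicon convention was
chosen and flagged. Z-scoring uses the population (n) denominator;
binarization is presence/absence and idempotent.

## STR comparison

STR profiles are consumed as genotype tables (electropherogram peak calling,
RFU thresholds and stutter filtering are upstream and out of scope). A locus
is *correct* only under exact allele-set equality — the definition under
which 12/21 correct loci yields the published 57% — and homozygotes are
single-allele sets, so a heterozygous call against a homozygous reference
sharing the allele is a drop-in. Percentages round half-up to integers
(57.14 → 57, 61.90 → 62, 85.71 → 86), which reproduces every printed rate,
and `summarize_profiles()` reports the full-profile count and the half-up
rounded mean rate.

## The simulator

`simulate_sample()` is the package's fixture engine and the generative model
behind the reproducibility analysis. For a library at concentration $c$
copies/µL:

- **Template sampling.** $T \sim \text{Poisson}(c \cdot V)$ template
  molecules ($V$ = 1 µL by default), each assigned a spacer identity
  multinomially from the source pool — a standard cloned array (uniform) or
  an individual's saliva/skin repertoire. Poisson sampling is the physical
  model of diluting discrete molecules.
- **PCR dispersion.** Each template amplifies by an independent
  lognormal(0, σ = 0.6) factor — the simplest dispersion mechanism that
  makes replicate profiles diverge when only a handful of templates seed the
  reaction.
- **Library competition.** The sequencer allocates
  $D \cdot M_s / (M_s + M_d)$ read pairs to spacers ($D$ = 20,000 by
  default), where $M_s$ is the summed amplified template mass and $M_d$ a
  fixed primer-dimer mass of 150 template equivalents. This competition term
  is the model's one calibrated constant: it makes a 10³-copy library almost
  all signal while a 10⁰-copy library yields only tens of spacer reads, so
  the Bray–Curtis distance to a deep reference — computed on raw counts —
  collapses between 10¹ and 10² copies, the empirically observed window. A
  naive model that always grants low-template libraries the full read budget
  cannot reproduce that collapse: one surviving template would then produce
  a full-depth single-spacer profile at distance ≈ 0.75 to a 4-spacer
  reference, below the 0.8 threshold.
- **Noise.** Poisson(15,000) primer-dimer pairs are appended, with inserts
  equal to the two artifact fragments observed in real no-template controls,
  so `classify_artifact()` has realistic targets; a global contaminant pool
  (environmental spacer-like sequences, Dirichlet frequencies) contributes
  at rate 0.001 of the read budget. No-template controls therefore emit
  essentially only dimers and contaminants.
- **Errors and qualities.** Uniform per-base substitutions at 0.001 per
  mate; correct bases carry Q35 and error positions Q20. Quality realism
  beyond that (position-dependent error profiles, indels, chimeras) is a
  non-goal.

Households (`make_household()`) share a configurable fraction (default 0.3)
of the spacer repertoire at the support level with independent frequencies;
skin repertoires are random subsets (default 0.7) of the saliva repertoire
with lognormal-jittered frequencies, reflecting that spacers are conserved
in saliva and shared between saliva and skin. Default saliva richness is 30
spacers per individual per locus, a realistic repertoire size for a single
streptococcal CRISPR locus.

Everything random takes an explicit integer seed; identical seed and
configuration give bit-identical output, down to the FASTQ bytes.

### What the simulator does and does not establish

The simulator emulates dilution-driven template sampling, PCR dispersion,
dimer-dominated noise floors, household sharing and sequencing errors. It
does not emulate real error spectra, chimeric amplicons, primer-binding-site
polymorphism, or the true population distribution of spacer repertoires.
Pipeline tests on simulated data therefore certify the *software* — that
extraction, denoising and identity calling recover known truth under the
modelled noise — not the field accuracy of the assay. The published ROC
operating points (AUC 0.988/0.954) derive from the deposited sequencing runs
and are not desk-reproducible; ROC correctness is certified instead by exact
equivalence with a brute-force pair-counting oracle.

## Problem sizes and reproducibility checks

The bundled checks run the dilution experiment (4 concentrations × 3
replicates at the default 20,000-read depth) over 20 seeds and verify the
three-part phenomenon: mean distance to the reference non-increasing in copy
number, every replicate below 0.8 at 10³ copies, and a median above 0.8 at
10⁰ copies. Identity recovery is checked over 20 seeded runs of 2 households
× 2 individuals at 10⁴ copies. `scripts/acceptance.R` recomputes the
noiseless recovery of the 4- and 12-spacer standard arrays from scratch.

## Known limitations

- The abundance-ratio denoiser is an approximation keyed to a single
  published parameter; it does not model quality-aware error probabilities
  and is not numerically equivalent to DADA2.
- The dimer-mass constant (150 template equivalents) is a calibration, not a
  measurement; real libraries will sit elsewhere on the competition curve.
- Identity thresholds calibrated on simulated data transfer to real data
  only insofar as the generative assumptions hold; the 0.8 default is the
  assay's own operational threshold, not a property of the simulator.
- Household members sharing large parts of a repertoire can fall below the
  identity threshold against each other; the assay itself has this
  limitation, and the simulator reproduces it rather than solving it.
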