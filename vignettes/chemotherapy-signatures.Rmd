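---
title: "Quantifying chemotherapy's contribution to mutation and neoantigen burden"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying chemotherapy's contribution to mutation and neoantigen burden}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemosig)
```

## The problem

Tumors sampled after chemotherapy typically carry more somatic mutations than
untreated primaries. Raw counts cannot say whether the excess was *caused* by
treatment: relapse samples are also simply older, and subclones that were
below detection at surgery can expand to detectable frequency by relapse.
Mutational signatures — probability distributions over the 96 single-base
substitution classes (six pyrimidine-strand substitutions × sixteen flanking
base combinations) — separate these explanations, because chemotherapy drugs
such as cisplatin leave characteristic context preferences that differ from
endogenous processes. `chemosig` implements the full chain from preclinical
signature extraction to per-mutation attribution and cohort-level inference,
together with a synthetic cohort generator that makes every stage testable
against known ground truth.

This vignette explains the models, the tunable parameters, the numerical
choices, and what the synthetic tests do and do not establish about real
data.

## Variant processing

Mutation tables (CSV or VCF) carry DNA and RNA read support and per-mutation
neoantigen yields. Three filters, applied verbatim throughout:

* **presence** — alternate-allele VAF strictly above 5% *and* at least 6
  supporting reads (`is_present()`); zero coverage is "absent", not an error;
* **expression** — 3 or more RNA alternate reads (`is_expressed()`);
* **post-uniqueness** — in patients with a matched pre-treatment sample, a
  mutation is unique to the post-treatment sample when the pre-treatment
  sample has strictly more than 30 reads of coverage and zero variant reads
  (`is_unique_to_post()`); missing pre-treatment coverage means "not
  assessable" and fails the filter.

The VAF comparison is strict and the read-count comparisons inclusive —
boundary cases (6 of 100 reads present; 6 of 120 absent) are pinned by tests.

Runs of SNVs at consecutive positions for the same patient are merged into
MNVs (`merge_adjacent_snvs()`). Merging is applied within each
patient-and-sample table: a sample can only merge records it actually
contains, which is the operational reading of per-patient merging when
patients contribute several samples. An MNV inherits the element-wise
*minimum* of its constituents' read support (the MNV is present only if every
constituent is), the *sum* of their neoantigen yields, and the *maximum* of
pre-treatment variant reads (post-unique only if every constituent is). MNVs
and indels are carried through burden accounting but excluded from the
96-channel tabulation — signature arithmetic is SNV-only — and reported in a
separate `"MNV/indel"` attribution category.

Context classification (`classify_contexts()`) canonicalises to the
pyrimidine strand (purine-reference variants are reverse-complemented), uses
the fixed channel order substitution class → 5′ flank → 3′ flank, and rejects
records whose stated reference base disagrees with the reference sequence or
that sit at a contig edge. Rejections are logged counts, not fatal errors:
mutation tables from different callers routinely contain a handful of
dialect mismatches, and dropping them loudly is more robust than aborting.

## The Poisson treatment model

For a preclinical experiment with treated and control replicates, counts in
channel $j$ follow

$$C_{ij} \sim \mathrm{Poisson}(B_j + t_i T_j), \qquad B_j, T_j \ge 0,$$

with flat priors; channels are independent. `fit_treatment_model()` offers:

* **`method = "map"`** (default) — the exact maximiser of the likelihood.
  The log-likelihood is concave in $(B_j, T_j)$; the interior stationary
  point is $B_j = $ control mean, $T_j = $ treated mean $-$ control mean.
  When the treated mean falls *below* the control mean that point is
  infeasible and the maximum sits on the $T_j = 0$ boundary, where profiling
  gives $B_j$ = the pooled mean of *all* replicates — not the control mean.
  Tests verify this against a brute-force likelihood-grid maximiser.
  Negative treatment rates are never reported; the model constrains rates to
  be nonnegative, so apparent "protective" channels clip to zero.
* **`method = "mcmc"`** — a JAGS sampler over the same model, for credible
  intervals. Under the flat prior the posterior mean sits above the mode for
  small counts; tests check that it converges to the MAP as counts grow
  100-fold. The point estimate used downstream is the MAP: it is
  deterministic, exactly testable, and asymptotically equivalent.

The genome adjustment
$N_j = (T_j / \sum_{j'} T_{j'}) \, (h_j / m_j)$
re-weights each channel by the ratio of human to model-organism abundance of
its reference trinucleotide ($h$, $m$: both-strand counts of the 32
pyrimidine-centred trinucleotides, computable from any FASTA with
`count_trinucleotide_freq()`). The formula does not itself yield a
probability vector, but downstream deconvolution requires one, so the result
is renormalised to sum to one — a deliberate, documented deviation of
convenience that changes nothing else (the adjustment is scale-invariant in
$T$). Genome builds are supplied as data rather than bundled.

## Deconvolution

`deconvolve()` normalises a sample's SNV context counts to frequencies $f$
and solves $\min_{w \ge 0} \lVert f - H^\top w\rVert_2$ against the catalogue
$H$ by nonnegative least squares, then iteratively removes signatures whose
weight falls below the detection threshold (default 6% of SNVs, the cutoff
conventional for catalogue refitting) and re-solves until every surviving
weight clears it. Surviving weights are renormalised to sum to one —
necessary for the attribution posteriors to be coherent — and a signature is
"detected" when its final weight is at least the threshold (the comparison
is inclusive, with a $10^{-9}$ relative guard against floating-point
noise). Each iteration removes at least one signature, so termination is
guaranteed; identical inputs give identical weights.

The published refitting tool this mirrors uses an iterative golden-section
weight search; iterated thresholded NNLS optimises the same objective with
the same threshold semantics and is directly verifiable against a lattice
oracle, which is why it was chosen. Agreement with the original tool is a
qualitative, not numerical, goal.

Degenerate catalogues (pairwise cosine similarity above 0.99) trigger a
warning: the solver then resolves ties by catalogue order, and the user
should know the split is arbitrary. No exome/genome trinucleotide
renormalisation happens inside deconvolution; catalogue and samples are
assumed to live in the same genome space.

## Attribution

For a mutation in context $j$ of sample $i$,

$$\Pr[s \mid j] = \frac{H_{s,j}\, D_{i,s}}{\sum_{s'} H_{s',j}\, D_{i,s'}}$$

over the *detected* signatures (undetected signatures have weight zero after
thresholding, so including them would change nothing; the renormalised
weights make the posterior a proper distribution). Sums of posteriors give
expected per-signature SNV counts; weighting each term by the mutation's
neoantigen yield gives expected neoantigen counts, and restricting to
mutations passing the expression filter gives the expressed-neoantigen
analogue. Contexts with zero likelihood under every detected signature go to
an explicit `"Other SNV"` bucket rather than being dropped, so totals are
conserved exactly (tests assert conservation to $10^{-9}$). Attributions are
expectations: the package deliberately exports no per-mutation hard
assignments, since no individual mutation can be certified as
chemotherapy-induced.

For relapse samples with a patient-matched primary, two deconvolutions are
computed — all mutations, and post-unique mutations only — and each
mutation's attribution uses the matrix matching its uniqueness status
(`select_weight_matrix()`).

## Cohort analysis

* `patient_weights()` / `compare_groups()` — samples collapse to per-patient
  means within group × tissue stratum, so each patient contributes one
  observation ("each patient contributes equally" is read at the test level,
  the simplest interpretation); the estimate is the percent increase of
  group medians; the CI is a percentile bootstrap resampling *patients*
  (default 2000 resamples, seeded), which respects the dependence structure
  of multi-sample patients; the test is a two-sided Mann-Whitney on
  per-patient values. The pooled row combines stratum estimates weighted by
  patient counts (the natural default where no weighting is prescribed).
  BCa intervals were considered and percentile chosen for transparency and
  determinism at these small patient counts.
* `dose_response()` — OLS of attributed mutation counts on cycle counts with
  the closed-form normal-theory slope CI and Pearson correlation.
* `detection_association()` — two-sided Fisher exact test on the detection ×
  exposure 2×2 table, Bonferroni-corrected for the number of signatures
  tested. Tests verify it against a full hypergeometric enumeration on every
  table with margins up to 30.

Survival modelling is intentionally absent: proportional-hazards fits are
off-the-shelf (`survival::coxph`, stratified by stage with log-cellularity
as covariate) and contain no computation specific to this pipeline.

## The synthetic cohort generator

`simulate_cohort()` emulates the statistical structure of a mixed
primary/relapse ovarian-cancer cohort; its defaults are the study conditions
the test-suite runs under.

| Parameter | Default | Rationale |
|---|---|---|
| `snvs_per_sample` | 5000 | genome-wide SNV counts of the order seen in high-grade serous samples |
| `relapse_snv_multiplier` | 1.78 | relapse samples carry ~78% more burden than untreated primaries |
| `relapse_chemo_fraction` | 0.05 | mean chemotherapy-signature admixture of relapse-sample SNVs |
| `chemo_beta_shape1` | 1.5 | Beta spread of per-sample fractions; with mean 5% this reproduces a realistic 0–20% per-sample range |
| `post_unique_fraction` | 0.45 | fraction of a paired relapse sample's mutations unique to the post-treatment timepoint |
| `dna_depth`, `rna_depth` | 60, 30 | bulk WGS / RNA-seq depths |
| `vaf_shape1`, `vaf_shape2` | 6, 14 | Beta VAF, mean 0.3 — bulk tumor clonality abstracted to a VAF distribution |
| `neoantigens_per_snv` | 0.02 | of order 100 neoantigens per ~5000-SNV sample |
| `expression_prob` | 0.4 | ~40% of neoantigens expressed |
| `mnv_rate`, `indel_rate` | 0.01, 0.02 | MNVs/indels are a small minority of burden |

Per-sample chemotherapy fractions are Beta-distributed with mean
proportional to the sample's platinum cycle count (scaled so the group mean
equals `relapse_chemo_fraction`), building in both the dose-response and the
wide per-sample variability of real cumulative exposure.
Neoadjuvant-treated primaries get a zero chemotherapy fraction: exposure is
brief and the resected bulk predates it. Clonal structure is abstracted to
the VAF distribution — no subclone trees; subclonal outgrowth is an
interpretation, not a generative model here. Each SNV draws its signature
from the sample mixture, its context from that signature, and its position
uniformly among reference sites carrying the context's trinucleotide on
either strand, so context classification round-trips exactly. All
randomness flows from one master seed through deterministic per-sample
streams; identical specs give byte-identical cohorts.

The bundled catalogue (`synthetic_catalogue()`) is generated in code: five
background shapes (CpG-deamination ageing, APOBEC-like TpC, broad
BRCA-deficiency-like, a C>A/T>A process, a T>C process) and four
chemotherapy shapes (a C>A-heavy cisplatin signature preferring a 3′
cytosine, a second cisplatin signature requiring a 5′ cytosine and 3′
pyrimidine, a T>A + C>T cyclophosphamide shape, and a near-uniform etoposide
shape). It is *not* the curated COSMIC table, which is external reference
data; every function accepts a user catalogue in the standard 96-row CSV
layout. A small uniform floor (5%) in every signature keeps all contexts
attributable; the near-uniform etoposide shape is deliberately confusable
with the broad BRCA-like shape (cosine ≈ 0.9) because that confusability is
a real property of flat signatures — low-cosine subsets are used where tests
need identifiable mixtures.

## What the tests show — and what they cannot

The suite verifies, among others: exact agreement of the MAP fit with a
likelihood-grid oracle; recovery of treatment rates within three Poisson
standard errors in ≥95% of channels; exact recovery of noiseless mixtures
and unconditional zeroing of sub-threshold components; attribution
conservation to $10^{-9}$; coverage of a known 1.78× burden shift by the
bootstrap CI; and Fisher p-values against full enumeration.

The end-to-end check simulates cohorts with a mean 5% chemotherapy admixture
(8 patients, 2 paired, 5000 SNVs per sample, ten seeds) and asks that the
mean attributed chemotherapy fraction across relapse samples fall in
[0.02, 0.08], with zero-admixture cohorts staying at or below 0.02. The
attributed mean sits near 2–4%, systematically *below* the generating 5%,
for two structural reasons worth understanding: the 6% detection threshold
censors samples whose realised fraction is small (they attribute ~0), and in
paired samples the chemotherapy admixture lives only in the post-unique
~45% of mutations, diluting the whole-sample fraction. Attribution through
a detection threshold is conservative by construction; the same mechanism
operates on real data.

Passing these tests shows the machinery is correct on data matching the
generator's assumptions. It does not show that real tumors satisfy those
assumptions: real signatures are estimated (not known), real catalogues
contain many more, partially collinear processes, chemotherapy-induced
mutations may genuinely resemble endogenous signatures (in which case their
contribution is underestimated), and bulk sequencing cannot see highly
subclonal mutations at all. Those caveats bound any real-data conclusion
drawn with this pipeline.

## Problem sizes

Default test and acceptance runs use a 1 Mb random reference (41% GC),
cohorts of 8–36 patients at 2000–5000 SNVs per sample, 2000-replicate
bootstraps and ten-seed end-to-end repeats — sizes chosen so the full suite
exercises every stage at meaningful statistical resolution while remaining
comfortable on a laptop core.
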