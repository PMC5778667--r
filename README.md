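# chemosig

Does chemotherapy measurably add to the mutation — and therefore the
predicted-neoantigen — burden of relapsed tumors? `chemosig` implements a
complete, testable pipeline for answering that question from somatic variant
tables: it extracts treatment-associated mutational signatures from
treated/control preclinical mutagenesis experiments, deconvolves each tumor
sample's signature mixture, attributes every mutation (and its neoantigen
yield) to signatures by posterior probability, and runs patient-reweighted
cohort comparisons. It is aimed at cancer-genomics analysts working with
cohorts that mix pre- and post-chemotherapy samples, where "more mutations at
relapse" conflates treatment mutagenesis with processes that were already
operative.

## The model

**Signature extraction.** Preclinical replicate experiments (treated and
control) give counts C<sub>ij</sub> of mutations in replicate *i* and
trinucleotide context *j* (96 pyrimidine-strand substitution channels). The
package fits

&nbsp;&nbsp;&nbsp;&nbsp;C<sub>ij</sub> ~ Poisson(B<sub>j</sub> + t<sub>i</sub> T<sub>j</sub>)

with flat nonnegative priors, where t<sub>i</sub> flags treated replicates,
B<sub>j</sub> is the background rate and T<sub>j</sub> the treatment excess.
The default fit is the exact MAP (closed form; a JAGS sampler provides
credible intervals). The treatment-associated signature adjusts for genome
composition,

&nbsp;&nbsp;&nbsp;&nbsp;N<sub>j</sub> = (T<sub>j</sub> / Σ T<sub>j'</sub>) · (h<sub>j</sub> / m<sub>j</sub>),

with h and m the human and model-organism genome counts of each reference
trinucleotide, renormalised to a probability vector.

**Deconvolution.** Each sample's 96-channel SNV counts are fit against a
signature catalogue H by nonnegative least squares; weights under the 6%
detection threshold are zeroed and the reduced problem re-solved until all
surviving weights clear the threshold (signatures below it are considered
undetected).

**Attribution.** A mutation in context *j* of sample *i* is attributed to
detected signature *s* with posterior probability

&nbsp;&nbsp;&nbsp;&nbsp;Pr[s | j] = H<sub>s,j</sub> D<sub>i,s</sub> / Σ<sub>s'</sub> H<sub>s',j</sub> D<sub>i,s'</sub>,

and sums of these posteriors (optionally weighted by each mutation's
neoantigen yield) give expected per-signature mutation and neoantigen counts.
For relapse samples with a patient-matched primary, mutations unique to the
post-treatment timepoint (pre-treatment coverage > 30×, zero variant reads)
use a separate deconvolution of the post-unique mutation set.

**Cohort comparisons.** Burden contrasts are tissue-stratified, collapse
samples to per-patient means so each patient contributes equally, and report
the percent increase of group medians with a patient-resampling bootstrap CI
and a Mann-Whitney test; dose-response is an OLS fit of attributed mutations
on chemotherapy cycles, and signature-detection/drug-exposure association is
a Bonferroni-corrected Fisher exact test.

Because real cohorts of this kind are controlled-access, the package ships a
synthetic cohort generator (`simulate_cohort()`) with a known ground-truth
ledger, plus a synthetic signature catalogue (`synthetic_catalogue()`,
generated in code — not the COSMIC reference data) so the entire pipeline is
verifiable end to end.

## Worked example

```r
library(chemosig)

spec <- cohort_spec(n_patients = 36, n_paired = 6, n_primary_treated = 2,
                    n_relapse_unpaired = 12, seed = 42)   # mean 5% chemo admixture
sim  <- simulate_cohort(spec)
res  <- run_cohort_attribution(sim$mutations, sim$meta,
                               synthetic_catalogue(), sim$reference)
cf   <- merge(chemo_fraction_summary(res$attribution),
              sim$meta[, c("sample_id", "group", "chemo_fraction")])
head(cf[cf$group == "relapse_treated",
        c("sample_id", "chemo_fraction", "chemo_snv_fraction", "n_snvs")], 4)
#>   sample_id chemo_fraction chemo_snv_fraction n_snvs
#> 2    PT01-R        0.16943             0.1110   8510
#> 4    PT02-R        0.00329             0.0000   8329
#> 6    PT03-R        0.00786             0.0308   8369
#> 8    PT04-R        0.04313             0.0000   8645
mean(cf$chemo_snv_fraction[cf$group == "relapse_treated"])   # 0.0448
mean(cf$chemo_snv_fraction[cf$group == "primary_untreated"]) # 0.0101
```

`chemo_fraction` is each sample's true generating chemotherapy admixture;
`chemo_snv_fraction` is what the pipeline attributes back. Samples whose true
fraction falls below the 6% detection threshold are attributed ~0 (the
threshold makes attribution deliberately conservative), while the untreated
samples show only a ~1% chance-attribution floor.

```r
b <- burden_summary(sim$mutations, sim$meta)
b$value <- b$expressed_neoantigens
compare_groups(b, "primary_untreated", "relapse_treated", n_boot = 1000, seed = 1)
#>   stratum median_pct_increase ci_low ci_high    mw_p n_patients_a n_patients_b
#> 1 ascites                92.1   58.1     105 0.00908            3           15
#> 2   solid                81.0   26.1     115 0.00717           19            3
#> 3  pooled                86.0   40.5     111      NA           22           18
```

Relapse samples carry roughly 1.8× the expressed-neoantigen burden of
untreated primaries in this simulation (the generator's relapse burden
multiplier is 1.78), and the stratified comparison recovers it with
significant Mann-Whitney tests in both tissue strata.

A thin command-line wrapper (`exec/chemosig`) exposes the same steps as
`simulate`, `extract-signature`, `deconvolve`, `attribute` and `compare`
subcommands operating on CSV/FASTA files.

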