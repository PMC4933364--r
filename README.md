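# finemapcrc

Fine-mapping and functional-evidence scoring of colorectal cancer (CRC)
GWAS loci, re-implemented as a tested, fully synthetic-data-driven R
package.

GWAS index SNPs tag LD neighbourhoods rather than causal alleles. The
workflow this package implements takes each of 31 reported CRC index SNPs,
re-tests every variant in the surrounding 500-kb window on
imputation-densified case-control data, searches for additional
independent signals by conditional analysis, and ranks the
best-associated variants with an a-priori regulatory-evidence score so
that laboratory follow-up can focus on a few candidates. It is aimed at
statistical geneticists who want a reproducible, unit-tested skeleton of
that analysis — the consortium's individual-level genotypes are not
public, so a synthetic-data module generates multi-study case-control
cohorts with realistic LD, imputation-dosage error and plantable
annotation evidence, and the published summary tables are bundled as
worked examples.

## The model

Per study, log-additive unconditional logistic regression on allele
dosage `g ∈ [0, 2]`:

```
logit P(Y = 1) = α + β g + γᵀx,   OR = exp(β), CI = exp(β ± 1.96 se)
```

Studies combine by inverse-variance weighted fixed-effects
meta-analysis (`w = 1/se²`) with Cochran's Q heterogeneity
(`Q ~ χ²(k−1)`). Per region: the top SNP is the smallest meta-analysis P;
conditional scans add the top SNP as a covariate and test at the
per-region Bonferroni level `0.05 / n_SNPs`; annotation candidates are
the top SNP, the index SNP, top-10 variants with reference-panel
`r² > 0.5` to the index SNP, all perfect proxies (`r² = 1`), and
conditional hits at `P ≤ 5e-5`. Candidates are scored: +1 each for
histone modification, open chromatin, protein binding, binding in the
presence of open chromatin/histone marks, cancer-vs-normal histone
differential, and colorectal (CRC cell line or normal colon/rectum)
evidence; +0.5 each for motif alteration (|ΔLOD| > 5) and conservation —
max 7, with PolyPhen damaging overrides 8/9, and categories 3–3.5 weak,
4–4.5 moderate, ≥5 strong.

## Worked example

The numbered drivers under `analysis/` run the whole chain on one
synthetic consortium (3 studies of 300 cases / 300 controls over a 600-kb
segment, planted causal variant with per-allele OR 1.5 and a full
strong-evidence annotation profile):

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_quality_control.R
Rscript analysis/03_association_meta.R
Rscript analysis/04_fine_mapping.R
Rscript analysis/05_functional_scoring.R
Rscript analysis/06_power.R
```

Console output from a run (seed fixed in `analysis/settings.R`):

```
planted causal variant: var0050 (OR 1.50, panel frequency 0.09)
...
causal variant var0050: OR 1.310 (95% CI 1.020-1.683), P = 3.42e-02, P-het = 0.36
smallest meta P in the scan: var0015 (P = 5.66e-03)
...
top SNP: var0015; index SNP: var0050; r2(top, index) = 0.004
conditional scan: 82 variants at alpha = 0.05/83 = 6.02e-04; 0 significant
candidate set: var0015, var0050
...
 variant_id is_index score category
    var0015    FALSE     0     none
    var0050     TRUE     7   strong
published evidence table rescored: 21 strong candidates in 12 loci
  (15 intronic, 6 intergenic; 15 motif-altering; index SNP strong in 4 loci)
...
minimum detectable OR at 80% power (alpha = 2.77e-05):
  allele frequency 20%: OR = 1.115
  allele frequency 1%: OR = 1.496
```

Reading: at this deliberately modest sample size (900 cases / 900
controls) and a lowish-frequency causal allele, the meta-analysed OR
(1.31, CI 1.02–1.68) still covers the planted 1.5, but a noise variant
edges out the causal one for the smallest P — exactly the situation the
candidate rules are built for: the index SNP is always carried into the
annotation set, where the planted evidence scores it 7/7 ("strong")
while the noise top SNP scores 0. Conditioning leaves no significant
residual signal, as expected with a single planted causal. Rescoring the
bundled published evidence table reproduces its headline counts, and the
power module's minimum detectable ORs land on the published 1.12/1.51
figures under the stated (assumed) Bonferroni alpha. Stage outputs land
under `results/` as TSV (association tables are LocusZoom-column
compatible); `run_pipeline()` runs the same chain as one call with a
manifest of per-stage counts and md5 checksums.

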