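---
title: "Methods: synthetic fine-mapping of colorectal cancer GWAS loci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic fine-mapping of colorectal cancer GWAS loci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(finemapcrc)
```

## The problem

Genome-wide association studies of colorectal cancer (CRC) have reported
dozens of common risk variants. A GWAS "index SNP" is rarely the causal
variant itself: it tags a linkage-disequilibrium (LD) neighbourhood that may
contain the functional allele. Fine-mapping densifies the genotype data
around each index SNP (here by imputation-style dosages against a phased
reference panel), re-tests every variant in a 500-kb window, asks whether
any *additional* independent signals hide in the window, and then ranks the
best-associated variants by regulatory evidence so that laboratory
follow-up can concentrate on a handful of candidates.

`finemapcrc` re-implements that workflow end to end as a tested package:
a synthetic-data generator stands in for the consortium's individual-level
genotypes (which are not public), and every downstream stage — quality
control, per-study association, meta-analysis, LD, region logic,
conditional scanning, candidate selection, functional scoring, power — is
exercised against either closed-form oracles or the published worked
examples bundled under `inst/extdata/`.

## The statistical model

Per study, the association model is unconditional logistic regression with
a log-additive genetic effect: for subject $i$ with allele dosage
$g_i \in [0, 2]$ and covariates $x_i$,

$$\operatorname{logit} P(Y_i = 1) = \alpha + \beta g_i + \gamma^\top x_i,$$

fitted by IRLS (`stats::glm.fit`, at most 50 iterations, deviance
tolerance $10^{-8}$). Inference is Wald: $\widehat{OR} = e^{\hat\beta}$
with CI $\exp(\hat\beta \pm 1.96\,\widehat{se})$. Wald rather than
likelihood-ratio inference is used because the workflow reports symmetric
CIs on the OR scale. Separation is declared at $|\hat\beta| > 15$ and
reported as non-convergence, never as a silent estimate; no Firth
correction is attempted (a deliberate non-goal).

Study estimates are combined by inverse-variance weighted fixed-effects
meta-analysis, $w_i = 1/se_i^2$, with Cochran's
$Q = \sum_i w_i(\hat\beta_i - \hat\beta_{meta})^2 \sim \chi^2_{k-1}$ under
homogeneity. CRC and adenoma strata enter as separate units and are never
pooled at subject level. Heterogeneity is reported, not acted on; there is
no random-effects model anywhere in the chain.

Within each 500-kb region the *top SNP* is the variant with the smallest
meta-analysis P among converged results. Ties (possible on synthetic data)
are broken deterministically: larger $|\hat\beta_{meta}|$, then smaller
position. Independent-signal search conditions every other variant on the
top SNP (two variants per model) and applies a per-region Bonferroni
threshold $\alpha_{region} = 0.05 / n_{SNPs}$.

The annotation candidate set of a region is, exactly: (1) the top SNP;
(2) the index SNP (always annotated — if QC removed it from the scan it is
retained with a flag); (3) among the 10 smallest-P variants, those with
reference-panel $r^2 > 0.5$ with the index SNP; (4) every variant with
$r^2 = 1$ to a member of rules 1–3; plus any variant with conditional
$P \le 5\times10^{-5}$ and its perfect proxies. Because $r^2 = 1$ is an
equivalence relation on a fixed panel, one proxy-closure pass is complete
(chasing proxies of proxies changes nothing), which settles an otherwise
open question about rule-4 closure.

## The functional-evidence score

Each candidate variant gets a boolean evidence record read from local
track files (BED intervals tagged `source|cancer-or-normal|colorectal`,
plus motif and PolyPhen TSVs): histone modification, open chromatin,
protein binding, protein binding in the presence of open chromatin or a
histone mark, different histone patterns in cancerous vs non-cancerous
sources, regulatory evidence in a CRC cell line or normal colon/rectal
tissue (each +1), altered binding motif and vertebrate conservation (each
+0.5) — a maximum of 7 for non-coding variants. Coding variants predicted
possibly/probably damaging override to 8/9; benign or unknown coding
variants are scored as non-coding regulatory variants. Categories: 3–3.5
weak, 4–4.5 moderate, ≥5 strong.

Two operationalisations deserve a note, because the verbal rules
underdetermine them:

* **Cancer-vs-normal differential.** "Different patterns of histone
  modification in cancerous vs. noncancerous cell lines/tissues" is
  implemented as disagreement (XOR) in overlap *status* between the
  cancer-tagged and normal-tagged ENCODE cell-line histone sources; the
  Roadmap normal-colorectal-tissue column is a different assay programme
  and feeds the histone and colorectal-evidence booleans instead. This is
  the only boolean reading that reproduces the published per-variant
  scores (e.g. the score-5 candidate in *CCND2*, whose histone evidence
  is tissue-only), and it avoids arbitrary count-difference thresholds.
* **Motif alteration** is strict: $|\Delta LOD| > 5$, sign ignored, so a
  change of exactly 5 does not count.

`binding_in_context` is derived, not free: at point resolution,
"co-located" means protein binding together with open chromatin or a
histone mark at the same base, so the constructor computes it and rejects
inconsistent hand-built records.

Gene context uses proximity and orientation: a genic variant belongs to
its host gene (exonic by exon overlap, else intronic); an intergenic
variant is assigned the gene with the nearest transcript end, labelled 5′
or 3′ relative to that gene's strand. eQTL-based target-gene inference and
splice-site scoring are out of scope.

## The synthetic-data generator

The generator defines the study conditions; its defaults are fixed once:

* **Reference panel.** A founder-mosaic model: each of $2N$ haplotypes
  copies from a pool of founder haplotypes (default 20), switching
  founders between adjacent variants with per-bp probability $10^{-5}$
  (a handful of crossovers per 500 kb, i.e. block-like $r^2$ decay). This
  is *not* a coalescent simulator and makes no fidelity claims beyond
  monotone LD decay with distance, which is what the candidate-selection
  rules consume. Per-variant founder alleles are redrawn (paths fixed, so
  LD is untouched) until the realised MAF clears a floor; irreducible
  failures are flagged monomorphic or error, by choice.
* **Cohort.** Defaults emulate the target consortium: 14 studies,
  11,900 cases / 14,311 controls split uniformly (per-study sizes are not
  public, so a uniform split is the neutral choice; both are
  configurable), prevalence 10%, age ~ Normal(64.2, 9) matching the
  cohort mean age, sex Bernoulli(0.5), three standard-normal synthetic
  PCs with mild default effects. Disease status follows the logistic
  model above with the intercept solved (Monte-Carlo expectation +
  `uniroot`) to hit the prevalence; cases and controls are accumulated by
  rejection sampling — an $O(1/\text{prevalence})$ cost with an explicit
  exhaustion error when the draw budget (500 draws per requested subject
  by default) runs out.
* **Imputation error.** `degrade_to_dosage()` mimics posterior-mean
  shrinkage: $d = s\,g + (1-s)\,2p + \varepsilon$, clipped to $[0,2]$,
  re-centred on the genotype mean (clipping otherwise inflates rare-allele
  frequencies), with the raw signal fraction solved per variant by
  `uniroot` on the *clipped, re-centred* empirical correlation under
  common random numbers — so the returned matrix attains the target Rsq
  essentially exactly, and deterministically.
* **Annotation tracks.** Planted evidence records are written as width-1
  BED intervals covering exactly the variant base, so planted evidence
  can never leak onto neighbouring variants and the
  write-then-read round trip is the identity. Real regulatory intervals
  are of course wider; nothing downstream depends on interval width, and
  the point-overlap semantics are identical. Unplanted variants receive
  sparse independent background evidence at a configurable rate.

What passing tests on these synthetics do *not* show: robustness to real
LD (allelic heterogeneity, structural variation), population
stratification beyond synthetic PCs, differential imputation quality along
the frequency spectrum, or any property of real ENCODE/Roadmap signal
distributions. The published-table worked examples are the only contact
with real data, and they validate the bookkeeping and scoring algebra,
not the association engine.

## Numerical choices and degenerate inputs

* HWE: exact conditional test (enumeration over heterozygote counts given
  allele counts, log-gamma arithmetic, two-sided by summing
  configurations no more probable than observed); the test flavour is not
  specified by the source workflow, so the exact test is the default for
  correctness and a chi-square option exists for bulk QC. Monomorphic
  tables return 1.
* Imputation-filter strata: "MAF>0.01 / 0.005–0.01 / <0.005" are read as
  $(0.01, 0.5]$, $[0.005, 0.01]$, $[0, 0.005)$ — the printed comparator
  directions preserved exactly (note the non-strict `Rsq ≤ 0.3`), with
  the endpoint MAF = 0.01 in the middle stratum so there are no gaps or
  overlaps. The genotyped-SNP MAF cutoff is unstated upstream and is a
  surfaced parameter (default 0.005, mirroring the lowest stratum).
* LD is haplotype-based ($r^2$ from phased haplotype frequencies, no EM);
  monomorphic loci raise an undefined-LD error rather than returning 0.
  Published $r^2$ values reported only as "<0.2" are treated as interval
  data: they can be binned and compared under `max`, but are never used
  as point values.
* Region coordinates are 1-based inclusive internally; BED I/O converts
  to 0-based half-open at the file boundary. Regions clip at the
  chromosome start with a truncation flag instead of erroring.
* Power: normal-approximation power for the Wald trend test with the
  variance evaluated at the alternative's case/control allele
  frequencies. The published "80% power for OR 1.12 at 20% frequency"
  figure is matched under an assumed per-region Bonferroni alpha
  (0.05/1807 ≈ 2.8×10⁻⁵); the alpha actually used upstream is unstated,
  so this is documented as a calibration of the engine, not a
  reproduction claim, and kept out of the machine-readable targets.

## Problem sizes

The bundled analysis drivers and the test suite run at desk scale, chosen
as the smallest sizes at which the statistical checks are informative:
panels of 100–500 variants × 120–200 haplotypes, studies of a few hundred
cases/controls, 100 replicates for family-wise-error and CI-coverage
checks, 1,000 replicates for type-I error, 2,000 for the Cochran-Q
moment check. The full consortium scale (11,900/14,311 across 14
studies) remains the generator default and is used analytically in the
power module.

## Known limitations

* The founder-mosaic panel cannot produce realistic allele-frequency
  spectra or recombination hotspots; rare-variant behaviour
  (MAF < 0.005) is therefore exercised by the QC unit tests, not by the
  simulator defaults.
* Conditional scans refit per study on individual-level data (as the
  source workflow did); no summary-statistics approximation (GCTA-COJO
  style) is provided.
* The evidence booleans accept single-source overlap; requiring
  replication across cell lines would need per-source counts that the
  boolean records deliberately do not carry.
* The score is a prioritisation heuristic: annotation-to-function mapping
  is uncertain, assays come from transformed cell lines and bulk tissue,
  and the categories should be read as ranks, not probabilities.
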