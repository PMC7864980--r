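# lungdecon

Contaminant-aware analysis of low-biomass 16S rRNA amplicon OTU tables,
built around a single negative control per patient.

Lung tissue carries so little bacterial biomass that DNA-extraction-kit and
reagent contaminants can dominate an amplicon sequencing profile. When every
patient contributes a cancerous tissue, a matched healthy tissue and one
empty-tube negative control — all carried through the same wet-lab steps —
the control accumulates exactly the method's contaminants, and contaminant
OTUs can be removed by comparing relative abundances across the trio.

## The removal rule

For each OTU *i* with a positive read count in a patient's control, let
*p<sub>c,i</sub>*, *p<sub>h,i</sub>* and *p<sub>k,i</sub>* be its relative
abundance (reads of OTU *i* / total reads of the sample) in the cancerous
tissue, healthy tissue and control. With ratio threshold *r* (default 1000):

> keep OTU *i* ⟺ *p<sub>c,i</sub>* > *r·p<sub>k,i</sub>* **and**
> *p<sub>h,i</sub>* > *r·p<sub>k,i</sub>*; otherwise zero it in **both**
> tissues.

Removal is joint — from both tissues at once or not at all — so the filter
never injects artificial intra-patient variation, and the control row itself
is never modified. The strict inequality makes the boundary exact: a sample
consisting of a single OTU (relative abundance 1) paired with a 20,000-read
control tolerates up to 19 control reads of that OTU; 20 reads (0.1%)
trigger removal.

Around the rule, the package provides:

- **Diagnostics** — per-sample percent of observed OTUs remaining after
  removal, and Pearson correlation between each tissue and its control
  (computed on relative abundances over the full OTU universe, before
  removal), with Shapiro–Wilk normality p-values alongside.
- **Core contaminants** — per-extraction-kit "core" control OTUs (relative
  abundance ≥ 0.001% in ≥ 40% of the kit's controls, singletons removed
  first) and their Venn partition across kits with summed mean relative
  abundances and per-genus profiles.
- **Spike-in scoring** — recovery of a 20-strain even mock community at the
  genus rank (the packaged ATCC MSA-1002 panel collapses to 18 distinct
  genera), per replicate and averaged.
- **Diversity statistics** — Shannon index (nats), weighted/unweighted
  Bray–Curtis, classical PCoA, one-way permutation ADONIS with seeded
  exceedance counting, exact paired Wilcoxon signed-rank and paired
  *t*-tests, and DNA-yield-per-gram arithmetic.
- **I/O** — strict readers/writers for mothur `.shared` and
  `.cons.taxonomy` files plus metadata/QC TSVs.
- **A synthetic study generator** — patient triplets, kit-specific
  Dirichlet contaminant profiles, endogenous tissue communities,
  multinomial sequencing at fixed depth, and ground-truth contaminant
  labels for sensitivity/specificity evaluation.

## Worked example

```r
library(lungdecon)

study <- simulate_study(synth_config(seed = 42))   # 5 patients x 3 kits
study$table
#> otu_table: 45 samples x 140 OTUs, 9e+05 total reads
#>   sample types: cancerous=15, healthy=15, control=15
#>   extraction kits: Blood=15, Microbial=15, Powersoil=15

res <- decontaminate(study$table)
res
#> decontam_result: 15 patient triplet(s), ratio threshold 1000
#>   removed OTUs per triplet: 40, 40, 40, 40, 40, 40, 40, 40, 40, 40, 40, 39, 39, 40, 39
#>   percent remaining: 49.33-52.70%

ctl <- subset_samples(study$table, sample_type == "control")
permanova(bray_curtis(ctl), ctl$meta$extraction_kit,
          permutations = 5000, seed = 42)
#> One-way PERMANOVA (ADONIS)
#>   pseudo-F = 8552, R^2 = 0.9993, p = 0.0002 (5000 permutations)

core_contaminants(study$table)$regions[, 1:2]
#>                      region n_otus
#> 1                     Blood     30
#> 2                 Microbial     30
#> 3                 Powersoil     30
#> ...
#> 7 Blood+Microbial+Powersoil     10

evaluate_decontam(res, study)[c("sensitivity", "specificity")]
#> $sensitivity [1] 1   $specificity [1] 1
```

Reading: each of the 15 patient triplets loses ~40 OTUs — the contaminant
taxa planted by the generator — and roughly half of each tissue's observed
richness, consistent with the generator seeding as many contaminant as
endogenous taxa into tissues at a 5% read share. The ADONIS confirms the
kit-specific contaminant profiles separate the controls almost perfectly
(R² ≈ 1), and the Venn center recovers exactly the 10 contaminant taxa
shared across kits. Against ground truth the rule removes every contaminant
observed in tissues and never touches an endogenous taxon.

The genus-rank spike-in scorer reproduces detection percentages directly
from per-replicate detection outcomes; e.g. a kit that misses one genus in
all three replicates and a second genus in two of three scores
(16+16+17)/54 = 90.7%.

A command-line wrapper with `simulate`, `decontam`, `diversity`, `core`,
`spikein` and `run-all` subcommands is installed at
`inst/scripts/lungdecon-cli.R`, and `run_pipeline()` runs the whole
workflow (decontamination → diagnostics → diversity → core contaminants →
optional spike-in) writing TSV reports plus a run log.

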