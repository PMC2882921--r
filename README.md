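# mgfscreen

Compartment classification of myeloma growth factor (MGF) expression in
the multiple-myeloma bone marrow.

Myeloma cells depend on growth factors, but for most reported MGF it is
unclear which bone-marrow cells produce them: the tumor cells themselves,
the putative niche (stromal cells, osteoclasts), or the wider environment
(T cells, monocytes, neutrophils). `mgfscreen` implements the full
screening pipeline that answers this from Affymetrix-style microarray
data — a probe-set × sample signal matrix, its paired detection-call
matrix (P/M/A), and per-sample population labels — plus a synthetic
generator that plants known compartment structure at study-matched sample
sizes so every stage is verifiable without any external download.

## Method

For each pair of sample groups *a*, *b* and each gene *g* the contrast
engine computes a pooled-variance Student *t* on log2 signals, adjusts p
values across the gene set with the Benjamini–Hochberg step-up
(adj₍ᵢ₎ = min₍ⱼ≥ᵢ₎ p₍ⱼ₎·m/j), and a linear fold change FC = mean_a/mean_b.
Gene *g* is *significant over b* when

    p_adj ≤ α (0.05)   and   FC ≥ 2   and   the winner group has ≥ 1 present call.

Upstream, arrays are scaled to an average intensity of 100 with values
under 1 floored at 1; probe sets with an absent/marginal call in ≥ 95% of
all samples are discarded as non-informative; and one probe set per gene
is selected (highest presence, then highest variance, then identifier).
A deterministic rule cascade then assigns each gene to exactly one of:
`NOT_EXPRESSED`, `MYELOMA`, `NICHE_BMSC`, `NICHE_OC`, `ENVIRONMENT`,
`MYELOMA_RESCUED` (present only in tumor samples, absent everywhere
else), or `SHARED`. Details and rationale are in the vignette
(`vignettes/compartment-classification.Rmd`).

## Worked example

```r
library(mgfscreen)

## packaged transcription of the growth-factor catalog
cat1 <- load_catalog(system.file("extdata", "growth_factor_catalog.csv",
                                 package = "mgfscreen"))
count_interrogable(cat1, "FGF", "LIGAND")
#> n_interrogable        n_total
#>             13             22

## simulate a study-shaped cohort with planted compartments and classify it
sim <- generate_dataset(synthetic_config(seed = 42))
sim$dataset
#> Expression dataset: 61 probe sets x 178 samples
#>   populations: BMPC=7, BMSC=5, CD14=5, CD3=5, MB=6, MMC=131, OC=7, PMN=5, PPC=7
ds <- scale_dataset(sim$dataset)
asn <- classify_compartments(ds, gene_views(ds, sim$catalog))
category_counts(asn)
#>         MYELOMA MYELOMA_RESCUED      NICHE_BMSC        NICHE_OC     ENVIRONMENT
#>               3               3              11               3               8
#>          SHARED   NOT_EXPRESSED
#>              16               7
recovery_report(sim$truth, asn)$overall_recall
#> [1] 0.9215686
```

The panel plants 3 tumor-cell, 11 stromal-niche, 3 osteoclast-niche, 8
environment, 5 rescued, 12 shared and 9 silent genes. At this seed all
significance-based categories are recovered exactly; two rescued and two
silent genes drift into `SHARED` because a 2% false-present call rate
occasionally violates their zero-present-call rules — the vignette
derives this ceiling.

```r
## receptor presence buckets on the transcribed receptor table
rt <- read_receptor_table(system.file("extdata", "receptor_expression_mmc.csv",
                                      package = "mgfscreen"))
bucket_counts(rt)$counts
#>      ge50     eq100      eq99 gt90_lt99
#>        18         4         1         5
```

Of the 36 interrogable receptors, 18 are present in at least half of the
tumor samples, 4 in all of them, 1 in 99% and 5 in more than 90%.

A thin CLI wrapper over the same functions is installed at
`inst/cli/mgfscreen.R` (`simulate`, `classify`, `differentiation`,
`receptors` subcommands).

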