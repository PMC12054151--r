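# oralmpg

Coverage-based metapangenomics of the human oral cavity: given
read-recruitment results of shotgun metagenomes mapped onto a reference
genome collection, `oralmpg` quantifies where each bacterial population
lives among the oral sites (plaque, tongue dorsum, keratinized gingiva,
mucosa, tonsils, throat, saliva), classifies its habitat preference
objectively, and tests which gene functions and metabolic modules
distinguish the specialists of each habitat.

## What it computes

* **Coverage statistics.** Per (genome, sample): breadth of coverage
  (fraction of positions at ≥ 1×) and the Q2Q3 interquartile mean depth —
  sort positions by depth, drop the lowest and highest quartiles
  (`t = ⌊L/4⌋` positions each), average the middle slice. The midmean is
  exactly invariant to mobile-element coverage spikes in the top quartile.
  A genome is detected at breadth ≥ 50%; a gene at ≥ 90% of its
  nucleotides covered at ≥ 1×.
* **Abundance.** Undetected genomes are zeroed, then depths are normalized
  within the sample; species-level values sum member genomes and conserve
  per-sample totals exactly.
* **Habitat-preference classification.** All `2^(k-1) − 1` unordered
  bipartitions of the site universe (127 maps for the default 8 sites) are
  scored per clade: a pooled-variance Student *t* statistic on summed Q2Q3
  abundance, and a Rao score statistic on breadth-based detection — for one
  binary covariate, the Pearson χ² of the 2×2 table,
  `N(ad − bc)² / (n₁n₂m₁m₀)`. The map with the largest |statistic| wins;
  its higher-tendency side is the preferred habitat.
* **Genome curation.** QC filter (completeness ≥ 90%, contamination < 5%)
  and quality-ranked greedy ANI dereplication so that no retained pair
  exceeds 98% identity (provably maximal).
* **Functional enrichment.** Module completeness (fraction of steps with
  at least one ortholog present; complete at ≥ 0.75) and per-function
  group-association score (Rao/χ², `G − 1` df) with Benjamini–Hochberg
  q-values, significant at q < 0.01.
* **Sub-group structure.** Ward clustering (`ward.D2`, Euclidean) with
  gap-statistic selection of the cluster number.
* **Synthetic data.** A site-structured depth simulator
  (Poisson/negative-binomial by inversion, uniform dropout, outlier
  spikes, hashed per-profile substreams) with recorded ground truth, so
  the full chain is testable without any downloads.

## Worked example

Simulate a two-species survey — a tongue specialist at 20× on TD and a
plaque specialist at 15× on SUPP/SUBP, 0.5× background elsewhere, with
dropout, outliers and overdispersion — and classify habitat preferences:

```r
library(oralmpg)

sites <- classifier_sites()
pref <- matrix(0.5, nrow = 2, ncol = 8,
               dimnames = list(c("N_subflava", "K_oralis"), sites))
pref["N_subflava", "TD"] <- 20
pref["K_oralis", c("SUPP", "SUBP")] <- 15

cfg <- simulation_config(
  sites = sites, samples_per_site = 10,
  genomes = data.frame(
    genome_id = c("N_subflava_g1", "K_oralis_g1"),
    clade_id  = c("N_subflava", "K_oralis"),
    length    = 5000
  ),
  preference = pref, dropout = 0.05,
  outlier_fraction = 0.05, outlier_multiplier = 10,
  overdispersion = 0.5, seed = 20
)
sim <- simulate_community(cfg)
head(sim$summary, 3)
#>   sample_id     genome_id q2q3_mean_depth breadth detected
#> 1     BM_01 N_subflava_g1          0.2304  0.3652    FALSE
#> 2     BM_01   K_oralis_g1          0.2452  0.3726    FALSE
#> 3     BM_02 N_subflava_g1          0.2540  0.3770    FALSE

classify_habitats(sim$summary, sim$clade_map, sim$site_map)
#>     clade_id     metric                   group1    group2 statistic
#> 1   K_oralis  abundance        BM,KG,PT,SV,TD,TH SUBP,SUPP    -536.2
#> 2   K_oralis prevalence        BM,KG,PT,SV,TD,TH SUBP,SUPP      80.0
#> 3 N_subflava  abundance BM,KG,PT,SUBP,SUPP,SV,TH        TD    -736.1
#> 4 N_subflava prevalence BM,KG,PT,SUBP,SUPP,SV,TH        TD      80.0
#>   preferred_sites no_preference
#> 1       SUBP,SUPP         FALSE
#> 2       SUBP,SUPP         FALSE
#> 3              TD         FALSE
#> 4              TD         FALSE
```

At 0.5× background the off-site breadth (~0.37) stays below the 50%
detection threshold, so both clades are undetected away from their
habitat; both metrics recover the programmed preferences. The prevalence
statistic of 80 is the perfect-separation value: it equals the total
sample count N, the Pearson χ² ceiling for a 2×2 table.

A thin command-line front end with the same stages is installed under
`exec/oralmpg` (subcommands `simulate`, `coverage`, `abundance`,
`classify`, `dereplicate`, `enrich`, `gapstat`, `run`), and
`run_pipeline()` chains curation → coverage → abundance → classification →
enrichment with a JSON manifest (config echo, versions, seed, input
checksums) for reproducible runs.

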