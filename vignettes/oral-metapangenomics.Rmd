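---
title: "Coverage-based habitat-preference analysis of oral bacterial genomes"
author: "oralmpg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coverage-based habitat-preference analysis of oral bacterial genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oralmpg)
```

# The analysis problem

Shotgun metagenomes from the human mouth can be mapped competitively onto a
collection of reference genomes; the per-nucleotide depth of recruited reads
then measures how abundant each genome's population is at each oral site
(supragingival and sub-gingival plaque, tongue dorsum, buccal mucosa,
keratinized gingiva, palatine tonsils, throat, saliva, hard palate). `oralmpg`
implements the downstream computational chain of such a metapangenomic
survey: coverage statistics and detection, relative abundance, objective
classification of habitat preference, reference-genome curation, functional
enrichment between habitat groups, and sub-group structure detection — plus a
simulator that generates site-structured coverage data with known ground
truth so that the whole chain can be validated end to end.

Read mapping, gene calling, pangenome construction and functional annotation
are upstream of this package: it consumes their tabular outputs (per-base
depth tables, genome QC estimates, ANI matrices, genome-by-function
frequency tables).

# Coverage statistics

For a genome of length $L$ in one sample, with per-position depths
$d_1,\dots,d_L$:

* **Breadth of coverage** is the fraction of positions with $d_i \ge 1$. A
  genome is **detected** when breadth $\ge$ 0.5 (inclusive, "at least 50%").
  Breadth is the detection metric of choice because isolated high-coverage
  islands — mobile elements, conserved operons cross-recruiting reads from
  related taxa — can give a large *mean* depth for a genome whose population
  is absent.
* **Q2Q3 mean depth** ranks positions by depth, discards the lowest and
  highest quartiles, and averages the middle half. We implement this as a
  symmetric midmean: with $t = \lfloor L/4 \rfloor$, the mean of sorted
  depths at ranks $t+1$ through $L-t$. This convention is parameter-free,
  keeps the retained slice non-empty for every $L \ge 1$, and is exactly
  invariant to arbitrary inflation of the top $t$ depths — the property that
  makes it robust to mobile-element spikes. Whether the quartile boundaries
  themselves should be retained or dropped is not fixed by the verbal
  definition of "coverage within the interquartile range"; the midmean is a
  declared convention, and the package's tests pin it against a brute-force
  sort-and-slice oracle.
* **Gene detection** calls a gene present when $\ge$ 90% of its nucleotides
  have $\ge 1\times$ coverage (both bounds inclusive). Genes are 1-based
  inclusive intervals on their genome; strand is ignored because coverage is
  strandless.

# Abundance

Within one sample, the depth of every undetected genome is set to zero and
the remaining Q2Q3 depths are divided by their total. A sample in which no
genome is detected yields all-zero abundances rather than an error — empty
mucosal samples are an expected biological outcome, not a data defect.
Species-level relative abundance sums the member-genome values, so
per-sample totals are conserved exactly (to floating tolerance).

Two clade-level series feed the classifier:

* **abundance**: the per-sample *sum of raw Q2Q3 depths* over the clade's
  genomes, without detection zeroing;
* **prevalence**: a per-sample binary detection from the *maximum breadth*
  among the clade's genomes against the 0.5 threshold.

Summing raw depths (rather than zeroed ones) for the classifier keeps the
two published phrasings of clade abundance separate instead of conflating
them; the zeroed variant is available through `zero_undetected = TRUE` and
is what the relative-abundance heat-map convention uses.

# Habitat-preference classification

The classifier enumerates **all unordered bipartitions** of the site
universe into two non-empty groups — $2^{k-1}-1$ maps for $k$ sites, 127 for
the default eight-site universe — and scores each map with a two-sample
statistic:

* abundance metric: the pooled-variance **Student t** statistic (not Welch)
  comparing per-sample clade abundance between the groups;
* prevalence metric: the **Rao score statistic** for the group term in a
  binomial-logit model of detection on group membership. With a single
  binary covariate this score statistic equals the Pearson $\chi^2$ of the
  2×2 group-by-detection table, $N(ad-bc)^2/(n_1 n_2 m_1 m_0)$, which is how
  the package computes it; the GLM route serves as an independent oracle in
  the test suite.

The map with the **largest absolute statistic** wins, and the preferred
sites are the winning side with the higher mean abundance or detection
proportion. Unordered (not ordered) bipartitions suffice because both
statistics are symmetric up to sign under group exchange.

Choices the method statement leaves open, resolved as follows:

* Maps that leave one group without samples (or below 1 combined degree of
  freedom for the t test) are **skipped**, not scored zero — a zero score
  is a legitimate value and scoring degenerate maps 0 could mask a true
  maximum at 0.
* Zero pooled variance with equal means scores 0; with unequal means it
  scores signed infinity (perfect separation, which should and does win).
* Exact ties in $|$statistic$|$ break deterministically: fewer preferred
  sites first (parsimony), then lexicographic site order.
* The site universe excludes the hard palate by default: a site with a
  single sample cannot support a two-group contrast. A custom universe can
  be supplied.
* A `min_stat` threshold can flag "no preference" when even the best map is
  weak; it defaults to off because the published procedure always assigns
  a map.

# Genome curation

Quality control keeps genomes with completeness $\ge$ 90% (inclusive) and
contamination $<$ 5% (strict). Dereplication enforces that no retained pair
exceeds 98% ANI. The published constraint fixes the *what* but not the
*how*; we use the standard quality-ranked greedy rule: rank candidates by
completeness (desc), contamination (asc), length (desc), id (asc), and
accept each candidate iff its ANI to all previously accepted genomes is
$\le$ 98. The result provably satisfies the pairwise constraint and is
maximal (every rejected genome exceeds 98% to some retained one); both
properties are asserted exhaustively in tests. Because alignment-based ANI
is asymmetric, input matrices are symmetrized by the elementwise maximum —
the conservative direction, which merges more. Note that a different
retained-representative rule can change *which* genome represents a
redundant cluster, and at the margin the retained count, so counts from
other implementations need not match exactly.

# Functional enrichment

Module completeness is the fraction of a module's steps for which the
genome carries at least one alternative ortholog; a module is complete at
$\ge$ 0.75 (inclusive). The full nested boolean grammar of module
definitions (complexes, nested AND/OR) is out of scope: modules are
supplied pre-flattened as ordered step lists with comma-separated
alternatives.

Enrichment between habitat-preference groups binarizes per-genome
occurrence counts (presence = count $\ge 1$ — a binomial-family model of a
frequency table implies per-genome binarization), computes the Rao score
statistic of the group factor in a logit model — equivalently the Pearson
$\chi^2$ of the groups-by-presence table — with $(G-1)$ degrees of freedom,
and adjusts p-values by Benjamini–Hochberg (the conventional q-value
procedure of the upstream toolchain; the package calls `p.adjust` and tests
it against a brute-force step-up implementation). Significance is strict
$q < 0.01$. The full table is always emitted with the flag column, so the
cutoff never hides results.

# Sub-group structure

Genomes are clustered by Ward's minimum-variance criterion on Euclidean
distances (`hclust` method `ward.D2`, which is Ward's criterion for raw
Euclidean distances; `ward.D` would require squared ones). `hclust`'s
agglomeration order is deterministic for a given input, which is the
property that matters for reproducibility. The number of clusters is
chosen by the gap statistic: $\mathrm{Gap}(k)$ is the mean over $B$
uniform reference data sets of $\log W^*_k - \log W_k$, with references
drawn uniformly over each feature's observed range (the simpler of the two
classical reference schemes), and the selected $k$ is the smallest with
$\mathrm{Gap}(k) \ge \mathrm{Gap}(k+1) - s_{k+1}$,
$s_k = \mathrm{sd}^*_k\sqrt{1+1/B}$. $W_k$ is the plain within-cluster sum
of squares; the `cluster::clusGap` reference implementation computes W from
unordered pairwise distances and therefore differs by a constant factor of
2, which cancels in the gap — the test suite cross-checks both the offset
and the gap values. For ANI input, the feature matrix is the rows of the
symmetrized similarity matrix; the embedding is a declared choice, since
gap-statistic clustering needs a feature space and the similarity rows are
the natural one. When every $k$ up to `k_max` keeps improving, `k_max`
itself is returned, so the reported $k$ is a floor in that case.

# The simulator

`simulate_depth_profile()` emulates the *shape* of read-recruitment depth
data, not reads: baseline per-position counts are Poisson with the
programmed mean (negative binomial with variance $\mu + \phi\mu^2$ when
overdispersion $\phi > 0$), a dropout fraction of positions is forced to
exactly zero (uncovered regions; chosen uniformly, not in blocks — block
dropout is a non-goal), and an outlier fraction of the remaining positions
is drawn around `mean_depth × outlier_multiplier` to mimic mobile-element
spikes. No depth-distribution family is prescribed by the study design;
Poisson/negative-binomial is the standard count model and exercises
exactly the tail behaviour the Q2Q3 midmean is meant to resist.

Two numerical choices make the simulator a good test fixture:

* Counts are drawn by **inversion** (`qpois`/`qnbinom` applied to a fixed
  uniform stream), so raising the mean at a fixed seed raises every
  position's depth monotonically — the monotonicity invariant holds
  deterministically, not just in expectation.
* One global seed expands into per-(genome, sample) substreams via a
  deterministic polynomial string hash of the identifiers, so adding a
  sample to a configuration never perturbs existing profiles.

`simulate_community()` programs habitat preference as a clade-by-site mean
depth matrix. The recorded ground truth for a clade is the set of sites
whose programmed depth exceeds the midpoint of the clade's depth range —
single-site specialists yield that site, flat profiles yield "no
preference". The simulator emulates site structure, dropout, outliers and
overdispersion; it does **not** emulate read-level error, cross-mapping
between related genomes, compositional coupling between taxa, or
inter-subject variability. Classifier recovery on simulated surveys
therefore demonstrates the correctness of the statistical machinery, not
field performance on real metagenomes.

# Validation conditions and problem sizes

The test suite and the acceptance script validate on these scales, chosen
as the smallest sizes at which each property is informative:

* score statistics against an exhaustive Pearson $\chi^2$ sweep of all
  8,100 2×2 tables with margins $\le 12$, and against GLM score tests at
  IRLS convergence tolerance;
* Q2Q3 against a brute-force oracle on 1,000 random vectors of length
  1–50;
* bipartition enumeration against brute-force subset generation for
  $k = 2..10$;
* habitat recovery on 34 replicate simulated surveys of 8 sites × 20
  samples × 3 single-site specialist clades (102 scored clades; preferred
  site at 20× mean depth against 0.5× off-site, 5% dropout, 5% outliers at
  10×, overdispersion 0.5, 2 kb genome segments — coverage statistics are
  already stable at this segment length), requiring $\ge$ 95% recovery
  under both metrics;
* enrichment on 20 genomes in two groups of 10 with 5 planted
  perfect-separation functions over 1,000 background functions (all
  planted must be flagged) and on pure-null tables of 1,000 functions
  (flag rate $\le$ 1%);
* dereplication contract checks on 200 random ANI matrices of up to 30
  genomes.

# Limitations

* The classifier assigns the best of the enumerated maps; it reports no
  significance for the winning map, matching the published procedure.
* Greedy dereplication is deterministic and maximal but not guaranteed to
  maximize the retained-set size (maximum independent set is NP-hard); it
  maximizes quality priority instead, which is the field convention.
* Module completeness over flattened step lists cannot express enzyme
  complexes that require multiple simultaneous orthologs per step.
* The eight-site universe yields 127 candidate maps; enumeration scales as
  $2^{k-1}$ and is capped at 20 sites.
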