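---
title: "Detecting horizontal transposable-element transfer from synonymous divergence"
author: "tetransfer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting horizontal transposable-element transfer from synonymous divergence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tetransfer)
```

## The inference problem

Transposable elements (TEs) replicate within genomes but can also cross
species boundaries. Horizontal transfer leaves a characteristic footprint:
because synonymous sites are approximately neutral, a TE family inherited
vertically from the common ancestor of two species accumulates synonymous
divergence (dS) at roughly the same rate as the host's nuclear genes,
whereas a family exchanged recently between the two species shows dS far
below the genic distribution. The alternative neutral explanation for
gene-tree/species-tree discordance, incomplete lineage sorting, predicts the
opposite signature — TE lineages coalescing in the common ancestor and thus
*high* dS — so anomalously low dS is diagnostic.

`tetransfer` implements this comparison for a five-species clade of
*Drosophila* (labelled `pse`, `per`, `mir`, `low`, `aff` after the
*pseudoobscura* group), together with the surrounding machinery: consensus
building, codon statistics, polymorphism summaries, annotation filters and
small-RNA signatures. Everything runs on synthetic data with known ground
truth generated by the package's own simulators.

## The classification rule

For each species pair we take the distribution of per-gene dS values and
compute its 2.5% and 50% quantiles (type-7 linear interpolation — R's
default; no convention is canonical here, so the choice is documented and
configurable through `genic_ds_distribution()`). A TE family is then:

* **strong** evidence of exchange if its dS is *strictly below* the 2.5%
  quantile;
* **potential** if between the 2.5% and 50% quantiles (both ends
  inclusive);
* **none** if above the median;
* **undefined** if its dS is saturated or unavailable.

Boundary ties resolve toward the weaker category, i.e. a family exactly at
the lower quantile is only "potential". With fewer than 40 genic values the
2.5% quantile is dominated by one or two order statistics, so
`genic_ds_distribution()` warns. Saturated genic values are dropped before
quantile computation, with a count retained.

```{r classify}
genic <- genic_ds_distribution(rlnorm(500, -2, 0.5))
table(classify_htt(c(0.01, 0.05, 0.2, 2.0), genic))
```

## Divergence: NG86 rather than ML

Pairwise dS/dN is computed by Nei–Gojobori (1986) counting: fractional
synonymous site counts per codon (stop-codon neighbours excluded from the
per-position denominator, so s + n = 3 exactly for every sense codon),
difference counts averaged over all orderings of the positions at which a
codon pair differs (pathways through stop codons excluded), and the
Jukes–Cantor correction dS = −(3/4)·ln(1 − (4/3)·pS), flagged as saturated
when pS ≥ 3/4. Codon pairs containing gaps, ambiguity characters or stop
codons are excluded pairwise — simulated sequences can acquire stops, and
this mirrors the usual clean-data handling of codon-based estimators.

The downstream logic needs only dS values *comparable between TEs and
genes*, not maximum-likelihood point estimates, and NG86 is deterministic
and checkable against an exhaustive pathway-enumeration oracle (the test
suite does exactly that, to 1e-9, alongside a hand-computed worked
example). A maximum-likelihood estimator can be substituted upstream of
`classify_htt()`, which only consumes numbers.

## The ENC-conditioned confirmation

Selection on codon usage can depress dS at silent sites, mimicking
transfer. The confirmation step conditions on Wright's effective number of
codons, Nc = 2 + 9/F̄₂ + 1/F̄₃ + 5/F̄₄ + 3/F̄₆, with per-amino-acid
homozygosity F̂ = (nΣp² − 1)/(n − 1), class means over amino acids observed
at least twice, and Nc capped into [20, 61]. When an entire redundancy class
is unobserved (short TE ORFs), Nc is reported undefined with a reason rather
than imputed — imputation would silently bias exactly the short sequences
the filter exists to protect. A strong call is *confirmed* when the TE's dS
lies more than two standard deviations below the mean genic dS of genes
within a 5-Nc-unit window centred on the TE's Nc (a sliding per-TE window;
fewer than five genic points in the window yields an "insufficient window"
flag, no verdict).

## Trees and discordance

Per-family phylogenies are built by neighbor joining on the pairwise dS
matrix (negative branch lengths clamped to zero) and compared to the species
tree by unrooted Robinson–Foulds distance; any positive distance flags
discordance. Discordance here is a qualitative corroboration — NJ + RF is
deterministic and cheap, and the signal of interest (the recipient jumping
into the donor's clade) is topological. Note that a transfer between two
species that are already *adjacent in the unrooted topology* (e.g. the two
deepest-branching species) does not change the unrooted tree and is
invisible to RF; the power analysis in the test suite therefore injects
transfers across clades.

## Polymorphism within families

Within a species, TE copies of one family form a sample whose frequency
spectrum carries history. `tajimas_d()` computes S, π, Watterson's θ_W =
S/a₁ and Tajima's D with the copy number as the sample size (sites with
gaps or N excluded listwise; D undefined at S = 0 or n < 4). Significance
comes from `coalescent_null()`: a Hudson-style neutral coalescent under
infinite sites, evaluated directly on the genealogy — S ~ Poisson(θ/2 × tree
length), each mutation assigned to a branch with probability proportional to
its length, and π accumulated from derived-allele counts k(n−k)/C(n,2).
Replicates with S = 0 are excluded (with a count) rather than scored as
D = 0. The p-value is one-sided lower-tail with an add-one correction,
p = (1 + #{D_null ≤ D_obs})/(1 + R), because the question is whether D is
significantly *below* zero (an excess of rare variants, as after a
copy-number expansion).

Shared polymorphism between two species' copy sets counts sites polymorphic
in both species whose segregating allele sets overlap in at least two
alleles, over the union of sites polymorphic in either (the denominator is
configurable to the "sum" reading, since "out of total polymorphism sites"
admits both; union is the default because it keeps the proportion in [0, 1]
with a natural interpretation as site-sharing).

## The simulators and what they do (and do not) emulate

The generators define the study conditions; their defaults are fixed and
tests never tune them.

* **Species tree** — `species_tree_default()` is the rooted ultrametric
  topology ((((pse, per), mir), low), aff) with the sister-pair path
  anchored at dS 0.018, the published divergence of the closest pair in the
  group; deeper splits sit at 3x, 6x and 12x that depth. Absolute deep-node
  ages are placeholders (the literature gives relative, not absolute,
  calibrations) — only relative depths matter for quantile classification,
  which is scale-free within a pair.
* **Family evolution** — a random open reading frame (default 1,000 codons;
  300 in the power analyses) evolves by per-site sampling from JC69
  transition probabilities (K2P with configurable κ optionally). JC69 is the
  default because every calibration has a closed form: expected raw
  divergence p = (3/4)(1 − e^(−4d/3)), which the test suite checks to three
  binomial standard errors. Horizontal transfer is modelled by re-grafting:
  the recipient's lineage is cut at `time_fraction` of its root-to-tip depth
  and re-attached to the donor's lineage at the same time point, giving
  expected donor–recipient divergence 2 × time_fraction × depth while all
  other pairs keep their tree-path expectations.
* **Copy sets** — a Kingman coalescent with mutations Poisson on branches,
  applied oldest-first to a finite-sites copy of the consensus (repeat hits
  allowed; at the default θ per site this approximates infinite sites).
  E[S] = θ·a₁(n) is verified against 3 Monte-Carlo standard errors. An
  `expansion` flag stretches external branches, skewing the spectrum toward
  singletons and Tajima's D negative.
* **Coverage** — lognormal per-base depth with mean copy_number × baseline
  and a stated coefficient of variation (the choice of lognormal is a
  modelling convenience; real depth noise is overdispersed and
  position-correlated, which this does not emulate).
* **Ping-pong reads** — primary sense piRNAs get a 5′ U with probability
  `u1_freq` *by start-position choice on the consensus*, never by editing
  sequences; responders are antisense with 5′ ends exactly `offset` (10 nt)
  into the primary and sequences reverse-complemented from the consensus.
  The 10A responder bias is therefore emergent from complementarity — the
  package's detectors must recover it, not merely read back an imposed
  constant. Background reads are uniform-position noise.
* **Hit tables and genome mosaics** — structural fixtures for the decision
  tree, the filters and the window densities, with disjoint truth intervals
  and a target N fraction.

Passing tests on these simulators show the statistics are implemented
correctly and calibrated under their stated models; they do not show that
real TE annotations, real coverage noise or real small-RNA libraries meet
those models. In particular the pipeline consumes, not reproduces, the
outputs of repeat finders, mappers and insertion callers.

## Annotation-side rules

The candidate decision tree applies, after an e-value ≤ 1e-08 filter: one
TE subject family → known family; several TE families all in one
superfamily → potentially novel within that superfamily; one order but
several superfamilies → potentially novel within the order; no TE subjects
and the primary hit (lowest e-value, ties by percent identity then subject
id) an annotated or predicted gene → discarded; anything else, including no
hits, retained as unknown. Families are clustered by single linkage at
strictly > 90% identity (linkage is unstated in the original tooling chain;
single linkage matches the "chain of similar matches" behaviour of
cluster-then-group workflows), with the longest member as representative.

Filters: at least 25 repeat-mask hits in at least one species (inclusive);
relative coverage — keep when ≥ 80% of positions have depth ≥ 2-fold the
single-copy baseline (the source sentence is grammatically ambiguous; this
reading is implemented, both knobs configurable, boundary inclusive). As
written the rule would discard a genuinely single-copy family in a
homozygous line (~1x relative coverage), which is documented rather than
silently corrected. Copy number is median TE depth over the baseline median,
per segment and averaged when segments (solo LTR vs body) are supplied —
scale-invariant by construction. Insertions are kept at frequency ≥ 50%
(inclusive).

Densities use 0-based half-open intervals, 1-Mb windows sliding by 100 kb,
terminal windows kept at their actual span: TE bases (merged, clipped) over
(window span − N bases *in the window*). The N correction is applied
per window for both the base-density and the insertion-density variants (the
source formulas say "chromosome" once and "window" once; the per-window
reading is the consistent one). Insertions are assigned to windows by
midpoint, which is unambiguous for spanning elements.

## Small-RNA signatures

Reads of 21–23 nt are siRNAs and 24–29 nt piRNAs (inclusive). The overlap
spectrum counts, for every (+, −) read pair on a TE, the 5′-end offset
(minus-strand 5′ = rightmost base) over offsets 1–25, implemented as a
cross-correlation of 5′-coordinate counts so all pairs are enumerated
implicitly at any read depth. The ping-pong z-score standardizes the
offset-10 count against the other 24 offsets (a common background choice;
configurable). Positional composition reports per-position A/C/G/T
frequencies by strand class and the argmax positions of sense T and
antisense A. Ingest assumes reads pre-filtered against miRNA/viral/snoRNA
databases.

```{r pingpong}
reads <- simulate_pingpong_reads(n_pairs = 2000, seed = 7)
pir <- reads[classify_length(reads$length) == "piRNA", ]
overlap_spectrum(pir)
```

## Numerical and design choices

* Quantiles: type-7. Consensus ties: lexicographically smallest base;
  gap-majority columns dropped. All coordinates 0-based half-open
  internally.
* ng86 symmetry, S + N = 3 × codons, and dS monotonicity in pS are enforced
  by property tests; the dS saturation flag replaces exceptions so one
  saturated pair cannot abort a family sweep.
* The classifier's null calibration (the fraction of strong calls when TE
  dS is drawn from the genic distribution itself) converges to the quantile
  level; with 1,000 genes the type-7 2.5% quantile sits at the 25.975th
  order statistic, so the expected rate is 25.975/1001 ≈ 2.6% and a single
  10,000-draw estimate carries a standard deviation near 0.56 percentage
  points — dominated by the quantile estimate, not the TE draws. The
  calibration test therefore averages independent draws.
* Problem sizes in the test suite (300-codon ORFs, 60–100 genes, 200-family
  power sweeps, 1,000-replicate nulls) were chosen as the smallest sizes at
  which the closed-form calibrations are tight at 3 standard errors.
* Determinism: every simulator takes a seed, and `run_pipeline()` derives
  all stage seeds from the single config seed; identical configs give
  byte-identical artifacts, each stamped with the seed and a config hash.

## Limitations

Donor–recipient direction is not inferred; transfer events are not dated in
years; the codon-usage-bias *likelihood* machinery of dedicated
vertical/horizontal consistency tools is deliberately reduced to the stated
mean-minus-2-SD rule; no read-level FASTQ simulation, indels or structural
variation; and the pooled/read-pileup route to polymorphism (as opposed to
aligned copies) is out of scope.
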