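---
title: "Energetic cost analysis of GTA gene clusters: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Energetic cost analysis of GTA gene clusters: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gtacarbon)
```

## The scientific question

Gene transfer agents (GTAs) are phage-like particles encoded by bacterial
genomes that package random host DNA rather than their own genes. In
*Alphaproteobacteria*, the ~17-gene "head-tail" cluster that encodes most GTA
structural proteins has conspicuously elevated GC content relative to its
host genome. Two mechanisms could produce this: (i) the cluster sits in a
GC-rich chromosomal environment, in which case the elevation should appear at
*all* codon positions — most visibly at the largely synonymous third position
(GC3) — and should extend into neighboring genes; or (ii) selection acts on
the *amino-acid composition* of the encoded proteins, in which case only the
first and second codon positions (GC1, GC2), which constrain the amino acid,
should be elevated, GC3 should track the genome average, and the signal
should stop at the cluster boundary.

Mechanism (ii) has a concrete energetic interpretation: amino acids encoded
by GC-rich codons (alanine, glycine, proline, arginine) tend to have small,
carbon-poor side chains and low biosynthetic cost. If GTA particles are
produced under carbon/energy limitation — GTA production peaks in stationary
phase and is stimulated by carbon depletion — selection should favor cheap
amino acids in GTA proteins, and that selection should *relax* when a GTA
gene is horizontally acquired by a lytic virus, whose explosive reproduction
is not tied to host starvation.

This package implements the quantitative machinery to test all parts of that
argument: codon-position GC decomposition, per-protein energetic scoring,
housekeeping-normalized carbon utilization, dataset dereplication, ancestral
reconstruction of both a continuous carbon trait and protein sequences, a
column-resampling bootstrap for carbon change on branches leading to viral
homologs, and accounting of positively selected sites. A synthetic-data
generator reproduces the assumed statistical structure so that the entire
pipeline can be exercised, calibrated and tested offline.

## Energetic scoring

Two per-residue quantities are tabulated (`build_cost_table()`):

* **Side-chain carbon count** — carbon atoms in the side chain, from the
  structural formula: glycine 0 (its side chain is a hydrogen) up to
  tryptophan 9 (methylene + indole). Differences in carbon content between
  proteins are determined entirely by side chains, since the backbone is
  invariant.
* **Biosynthetic cost** — high-energy phosphate bonds (~P) consumed to
  synthesize one molecule, using the aerobic *Escherichia coli* values of
  Akashi & Gojobori (2002), appropriate because most GTA-bearing
  alphaproteobacteria are obligate or facultative aerobes.

`score_protein()` averages both quantities over the scored residues.
Ambiguity codes (X, B, Z, J) and the rare nonstandard residues (U, O) are
excluded from numerator and denominator, so scores are unbiased by ambiguous
positions. When protein sets are pooled (a genome's GTA region, a set of
housekeeping genes), the default is the *pooled-residue* (length-weighted)
mean, because the quantities are defined per amino acid, not per gene; an
unweighted variant is available via `weighted = FALSE` in
`relative_carbon_utilization()`.

**Relative carbon utilization** divides a taxon's focal-gene-set mean
carbons/site by the same taxon's housekeeping mean (in the real data, 26
single-copy genes). Genome-wide GC content shifts amino-acid composition of
*all* proteins; the ratio cancels that effect so values are comparable across
taxa.

## Codon-position GC and gene neighborhoods

`gc_by_codon_position()` pools codons over a gene set and counts G+C
separately at the three codon positions. A trailing stop codon is trimmed
first — the stop codons TAA/TAG/TGA are AT-rich and would systematically
deflate GC3 on short genes. Ambiguous bases are dropped from both numerator
and denominator of their position.

`partition_neighborhood()` builds the eight comparison groups used in the
GC analysis: the focal region, three non-overlapping 17-gene windows on each
side (51 genes per flank), and the whole-genome gene set. Windows that run
off a contig edge are truncated and flagged rather than discarded, so draft
genomes remain usable. Group differences are assessed with the
Kruskal–Wallis H test followed by Dunn's post hoc z-tests with Bonferroni
correction (`compare_groups()`), with one pooled GC value per genome per
group as the unit of observation — pooling within genome first avoids
pseudo-replication from the very different numbers of genes per group.

## Dataset dereplication and viral homolog curation

Closely related genomes would otherwise dominate every statistic, so genomes
are clustered into OTUs by furthest-neighbor (complete-linkage)
agglomeration on the distance 100 − ANI with a 95% cutoff
(`cluster_otus()`): two genomes share an OTU iff every pair within the
cluster has ANI ≥ 95%, with pairs at exactly the cutoff merged. One region
per OTU is kept (`select_representative()`: most labeled genes, ties broken
lexicographically for determinism), and regions with fewer than 9 labeled
genes are dropped (`filter_min_genes()`, boundary inclusive).

Viral homologs far from the bacterial radiation are vulnerable to long-branch
attraction, so `retain_nested_homologs()` keeps a viral leaf only when the
smallest clade containing it and at least one bacterial leaf (a) contains
bacteria of a single taxonomic order and (b) has bootstrap support ≥ 60. On
unrooted trees every rooting consistent with order monophyly is tried and a
leaf must pass under all of them — the conservative reading. The function is
designed for iterative use with external re-alignment/re-inference until the
retained set is stable. Where many homologs survive,
`top_k_closest_homologs()` keeps the 5 closest by minimum patristic
distance, after collapsing sequences identical once gaps are removed.

## Ancestral reconstruction

**Continuous trait (carbon utilization).** `bm_ancestral_states()` computes
marginal maximum-likelihood estimates under Brownian motion by a two-pass
message-passing scheme: a tip-to-root pass combines each node's descendant
information into a Gaussian "message" (precision-weighted mean), and a
root-to-tip pass combines each node's above-tree information, so that every
node's estimate uses the whole tree — equivalent to the GLS estimate obtained
by rerooting at that node, and validated in the tests against an explicit
dense-matrix GLS oracle and against an independent implementation
(`phytools::fastAnc`). The pass is linear in the number of tips. The ML rate
σ² is accumulated from the squared standardized contrasts formed during the
downpass. Zero-length branches are floored at 1e-8 to keep the covariance
nonsingular; the basal node of the supplied tree is treated as the root
(under Brownian motion the marginal estimates are invariant to root
placement). `branch_changes()` reports each branch's child-minus-parent
difference; negative values mean carbon utilization decreased toward the
child. Note that marginal estimates are shrunken: a discrete jump on one
branch is partially absorbed by neighboring estimates, so branch deltas are
best read as sign/rank statements (which branch decreased most), while
magnitude estimates of a clade-level shift are better taken from tip-level
clade contrasts.

**Protein sequences.** `marginal_asr()` reconstructs ancestral residues under
an empirical exchangeability model (packaged LG matrix read from PAML `.dat`
format by `load_paml_matrix()`; any matrix in that format can be
substituted) with discrete-Gamma rate heterogeneity (4 equal-probability
categories, conditional-mean rates by default, category medians by flag; the
shape is estimated by ML on the fixed tree unless supplied). Conditional
likelihoods are computed by the pruning algorithm with per-node scaling; each
internal node's marginal posterior over the 20 residues combines the
below-node and above-node partial likelihoods, mixing rate categories by
their per-site posterior weight. The ML residue is reported, with ties broken
alphabetically (deterministic). Indels are handled first and separately
(`infer_indel_states()`): each column's gap pattern is a binary
presence/absence character under a two-state model with equal gain and loss
rates estimated by ML, and a position is present at a node iff its marginal
presence posterior is ≥ 0.5; positions absent at a node appear as gaps in
its reconstructed sequence. This two-stage decoupling (indels, then residues)
mirrors standard ancestral-reconstruction practice; the equal-rates indel
model is a documented choice recorded in the output.

`filter_columns()` removes alignment columns below an occupancy threshold
(inclusive boundary; triplet-aware for codon alignments) and returns a
new→old column map so that site numbers remain traceable — important because
positively-selected-site tables are indexed against filtered alignments.

## The bootstrap test for viral carbon gain

For a viral homolog aligned to its inferred ancestral sequence,
`net_carbon_change()` is the mean side-chain carbon difference over the
columns where *both* sequences have a residue ("per amino acid" is only
defined where both residues exist; gapped columns are excluded from the
statistic and from the resampling universe). `bootstrap_net_change()`
resamples those shared columns with replacement (same length) and recomputes
the net change per replicate; the one-sided p-value is the fraction of
replicates with zero or negative net change. Replicates are direct seeded
column resamples, so results are bit-reproducible; the tests verify
convergence of the bootstrap p to the exact resampling probability computed
by integer convolution on small alignments. Reported alignment lengths are
in nucleotides (3 × shared amino-acid columns), the convention used in
per-gene result tables.

`cumulative_net_change()` combines genes conservatively: for each gene the
viral homolog with the *smallest* net change is chosen, and the cumulative
per-amino-acid change is the total carbon difference over the total shared
columns (length-weighted, keeping "per amino acid" units). The bootstrap
resamples columns within each gene independently and recombines.

## Positively selected site accounting

Site tables in codeml BEB style (`site`, `probability`) are filtered by
`filter_ps_sites()` with the three-part rule: posterior ≥ 0.95, and
presence (non-gap fraction) ≥ 0.5 in both the focal partition and the rest
— presence counted over sequences. `site_contribution()` then measures, per
retained site, the focal-partition mean side-chain carbons minus the
other-partition mean (gaps excluded; sites with an all-gap partition are
skipped but recorded), reports how many sites decrease carbon in the focal
clade, and scales the summed change per alignment position by default
(dividing by the protein alignment length); a per-selected-site variant is
available via `per = "site"` and the choice is recorded in the returned
object.

## The synthetic-data generator

The generator produces data with the statistical structure the analysis
assumes, so every stage has a ground truth:

* `generate_genome()` — one contig of (by default) 150 genes of 150–350
  codons with a central 17-gene region. Codons are drawn from a distribution
  over the 61 sense codons built from independent per-position G/C weights,
  with a fixed-point adjustment so the expected GC at each position matches
  its target despite stop-codon exclusion. This parameterization controls
  GC1/GC2/GC3 independently — exactly the dissociation under study (region
  GC1/GC2 elevated by 0.05; GC3 at the genome average of 0.70, typical of a
  GC-rich alphaproteobacterium). Realized GC lands within about ±0.02 of
  target at these gene counts; targets outside the feasible range raise an
  error.
* `evolve_family()` — protein families evolved under LG+Γ along a tree with
  a 16-tip focal clade (height 0.1) on a 0.25-substitutions/site stem joined
  to a 48-tip background clade (height 0.4): a derived order with a distinct
  ecological history. On the stem, a planted selective sweep replaces
  residues at randomly chosen sites with lower-carbon residues (sampled
  proportionally to stationary frequencies) until the sequence's mean
  carbons/site reaches the family baseline minus the configured shift
  (−0.4 by default). Targeting an absolute level, rather than a change
  relative to the drifted stem sequence, keeps the planted shift calibrated:
  at the 300-site default, the realized clade-level difference is the
  planted value to within a few hundredths. Swept sites are held invariant
  within the focal clade (maintained by purifying selection), which makes
  them a usable ground truth for the positively-selected-site accounting.
  True sequences at all nodes are retained as the reconstruction oracle.
* `spawn_viral_homolog()` — grafts a viral branch at the shifted ancestor,
  evolves it neutrally for 0.3 substitutions/site, then plants
  carbon-*increasing* replacements up to ancestor + 0.3 carbons/site: the
  relaxation of cost selection after horizontal transfer to a virus. The
  graft node's true sequence is the oracle ancestor for the bootstrap test.
* `generate_ani_matrix()` — block-structured ANI with configurable
  within/between means, for exercising OTU dereplication.

Every generator is a pure function of its seed. Default protein length is
300 residues — representative of GTA head-tail cluster proteins (roughly 100
to 650 residues across the cluster) and long enough that neutral drift noise
does not swamp the planted effects.

What the generator does **not** emulate: codon-level selection (dN/dS) — the
PS-site machinery is exercised with planted compositional sweeps, not a
branch-site codon model; indel evolution in families (gap handling is tested
on constructed patterns); intra-genome amino-acid composition gradients;
horizontal transfer of GTA regions between lineages. Passing tests therefore
demonstrate correctness of the statistical machinery under the assumed
structure, not robustness to every feature of real genomes.

## Numerical choices

* Transition probabilities come from a single symmetric eigendecomposition
  of the rate matrix, reused for all branches and rate categories; tiny
  negative entries from round-off are clipped and rows renormalized.
* Pruning uses per-node, per-site scaling (log-scale bookkeeping), so long
  trees do not underflow; posteriors are formed per rate category (scales
  cancel) and mixed by per-site category weights computed with log-sum-exp.
* The Gamma shape ML search is on log-shape over [0.05, 100]; the indel
  gain/loss rate over [1e-4, 50].
* Residue ties in ML reconstruction break alphabetically; complete-linkage
  ties follow `stats::hclust`'s deterministic merge order; representative
  ties break lexicographically by region id.
* The bootstrap p is one-sided ("zero or negative net change") and never
  doubled.

## Study sizes used in the automated checks

The test suite and the acceptance script run the pipeline at desk scale:
12 genomes per GC comparison, 10 shifted + 5 neutral families of 300 sites
on 64-tip trees per study, 1,000 bootstrap replicates (100,000 where the
bootstrap is compared with its exact distribution), 50 replicate GC studies
and 100 replicate family studies for the frequency-of-success checks. These
sizes give the power the checks require while keeping a full run within a
few minutes on one CPU.

## Known limitations

* Marginal BM estimates shrink discrete shifts (see above); magnitude
  recovery of a clade shift uses tip-level contrasts.
* The indel model is a two-state equal-rates approximation; overlapping
  gap structures in real alignments are richer than this.
* `retain_nested_homologs()` on unrooted trees enumerates rootings, which
  is quadratic in tree size and intended for the modest per-gene trees of
  this analysis, not for thousands of tips.
* The cumulative bootstrap treats genes as independent; shared phylogenetic
  history between genes of one region is not modeled.
* Branch-site model fitting (codeml) and its likelihood-ratio machinery are
  consumed as input tables, not reimplemented; ANI computation, alignment
  and tree inference are likewise upstream tools.
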