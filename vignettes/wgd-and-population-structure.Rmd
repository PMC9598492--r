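---
title: "Detecting whole-genome duplication and population structure with wgdpop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting whole-genome duplication and population structure with wgdpop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wgdpop)
```

# The two questions the package answers

`wgdpop` implements the two computational tracks used to characterise a newly
assembled plant genome and its germplasm panel:

1. **Has the genome undergone a whole-genome duplication (WGD), and how old is
   it relative to speciation events?** A WGD leaves genome-wide *colinear
   blocks* — runs of genes whose order is conserved between two chromosomal
   regions — and every duplicated gene pair starts diverging at the moment of
   duplication. Measuring neutral divergence per pair and looking at its
   distribution over all pairs reveals peaks: one peak per duplication (and,
   when a second genome is compared, one per speciation).

2. **How is diversity distributed across an accession panel, and how many
   ancestral populations explain it?** Filtered SNP genotypes feed per-locus
   diversity statistics, covariance-method principal components, and a
   maximum-likelihood admixture model whose number of clusters K is chosen by
   the Evanno ΔK criterion.

Both tracks share a gene-order model (`gene_catalog()`) built from a GFF3
annotation: one representative transcript per gene (the longest summed CDS,
ties broken by smallest transcript ID), CDS parts stored in transcription
order, and a dense per-chromosome rank used as the coordinate system for
colinearity.

# Track 1: colinear blocks and the 4DTv clock

## Anchors and chaining

All-vs-all protein homology hits (BLAST tabular, filtered at e-value ≤ 1e-10)
become *anchors*: gene pairs with their chromosome and rank attached. Two
pre-steps keep artefacts out in the intra-genomic case: self-hits are dropped,
reciprocal hits deduplicated, and *tandem arrays* — mutually homologous genes
within one rank of each other on the same chromosome — are collapsed to their
best-scoring member, because an array aligned against itself produces a
spurious diagonal.

Blocks are then maximal monotone chains of anchors found by dynamic
programming, per chromosome pair and orientation (same or inverted): anchor
*j* may follow *i* only if both rank coordinates advance strictly and the gap
on *each* side leaves at most 5 intervening genes ("fewer than six",
enforced per side). Chains are scored by anchor count, then summed bit score,
then smallest start rank — a fully deterministic tie-break — and extracted
greedily best-first, removing used anchors, until no chain reaches the
10-anchor block threshold. On instances small enough to enumerate
exhaustively, the DP provably returns the optimum; the test suite checks this
equivalence on 100 random instances.

## The 4DTv statistic

For each homeolog pair emitted by the blocks, the two proteins are aligned
globally (BLOSUM62, gap open 10, extend 1 — these defaults only decide which
codon columns exist, not the statistic), the alignment is back-translated to
codon columns, and columns are kept when **both** codons belong to
fourfold-degenerate families (CTN, GTN, TCN, CCN, ACN, GCN, CGN, GGN) **and**
their first two positions are identical — the strictest convention, which
guarantees both alleles at the third position are synonymous. Codons
containing N are never classified. The raw statistic is

$$p = \frac{\text{third-position transversions}}{\text{comparable fourfold sites}},$$

and the distance corrected for multiple substitutions is

$$d = -\tfrac{1}{2}\,\ln(1 - 2p),$$

the standard transversion-saturation correction: under symmetric models the
transversion proportion saturates at 1/2, and this inverts that decay. An
HKY-style alternative using the observed purine/pyrimidine composition,
$d = -2 g_R g_Y \ln(1 - p/(2 g_R g_Y))$, is available via
`correct_4dtv(method = "hky")` and reduces to the default at equal
composition. Pairs with fewer than 10 comparable sites are excluded as
`"short"`; pairs at or past saturation (p ≥ 0.5) are excluded as
`"saturated"` and counted — their distance is undefined.

## Peaks

Distances are pooled per distribution (intra-genomic for duplications,
inter-genomic for speciations) and the peak is the argmax of a Gaussian
kernel density with Silverman's rule-of-thumb bandwidth on a fixed 512-point
grid over [0, max + bandwidth], reported to 3 decimals. A density argmax
rather than a histogram bin is used because published peak locations carry
three decimals, finer than any defensible bin width. Secondary peaks are
reported when their topographic prominence exceeds half the maximum density
— plain height thresholds would flag every wiggle of a flat density.
`overlay_report()` flags distributions whose modes are closer than 0.02, the
signature of a duplication coincident with a speciation.

**A known estimator property.** When each pair contributes only ~100–150
fourfold sites, per-pair $\hat p$ is binomial and $d(\hat p)$ is a convex
transform. The change of variables compresses spacing at the low end
(Jacobian $1/d'(p)$), so the KDE argmax sits slightly *below* $d(p^\*)$ —
about one bandwidth at desk scale — while the median and mean of the
distances are unbiased. Parameter-recovery checks therefore bound the mode
error by max(0.01, 2·bandwidth) and additionally check the median. With
thousands of sites per pair the effect vanishes.

# Track 2: the SNP panel

## Filter cascade

`apply_filters()` applies three stages in a fixed, logged order:

1. **Depth mask** — genotypes whose `FORMAT/DP` lies outside [20, 200] are
   set to missing. The bound is applied *per genotype*, not per site: that
   is the unit the data provide, and masking composes cleanly with the next
   stage.
2. **Missingness** — loci with ≥ 10% missing calls are dropped ("less than
   10%" kept).
3. **MAF** — loci whose minor allele frequency, recomputed on the surviving
   calls, is not strictly > 0.05 are dropped.

The per-stage attrition table is attached to the result so alternative
orders can be audited. The cascade is idempotent. Optionally,
`restrict_to_4d_sites()` first keeps only loci at the third position of a
fourfold-degenerate codon of the representative CDS (classified on the
reference codon, strand-aware), so every retained SNP is synonymous by
construction; positions claimed by genes on both strands are ambiguous and
excluded.

## Diversity statistics

With allele frequencies $p_i$ over non-missing calls at a locus:
gene diversity $GD = 1 - \sum p_i^2$ (expected heterozygosity), polymorphism
information content $PIC = GD - \sum_{i<j} 2 p_i^2 p_j^2$, observed
heterozygosity $H_O$ = fraction of heterozygous calls, and
$MAF = \min(p, 1-p)$. These are closed forms; the tests recompute them by
brute force on a thousand random loci.

## PCA

`pca_covariance()` is the covariance method: missing genotypes imputed to
the locus mean (the simplest defensible choice, and it cannot manufacture
structure), locus-mean centring, no scaling, eigendecomposition of the
sample covariance. Eigenvalue proportions sum to one over the returned
components, and each component's largest-magnitude loading is made positive
so signs are reproducible.

## Admixture and ΔK

`admixture_em()` fits the standard binomial admixture model: individual *i*
has ancestry proportions $q_i$ over K clusters with cluster allele
frequencies $p_k$, and its alt-allele count at locus *l* is
Binomial(2, $\sum_k q_{ik} p_{kl}$). The log-likelihood (up to a
genotype-independent constant) is
$\sum_{il} [\, g_{il}\ln f_{il} + (2-g_{il})\ln(1-f_{il}) \,]$ with
$f = QP$; missing genotypes contribute nothing. The E-step assigns each
allele copy a cluster responsibility; the M-step renormalises Q rows and
sets P to responsibility-weighted allele fractions, clamped to
$[10^{-6}, 1-10^{-6}]$.

This is a deliberate *reimplementation choice*, not an emulation: the
Bayesian MCMC clustering used in the original analysis shares the same
frequency model, but a maximum-likelihood EM fit is deterministic given a
seed, orders of magnitude faster, and exposes a log-likelihood directly
usable by the Evanno criterion (in place of ln P(D)). Because plain EM
crawls near the optimum (it needed tens of thousands of iterations to move
the log-likelihood by less than 1e-6 at the 85 × ~2400 scale), the default
is a guarded SQUAREM accelerator: each recorded step is two EM map
evaluations plus a monotone extrapolation that falls back to the plain EM
result whenever it fails to improve the likelihood. The trace is therefore
non-decreasing by construction — an invariant the tests assert on every
input — and `accelerate = FALSE` recovers textbook EM. `max_iter` (default
2000) counts EM map evaluations; `tol` (default 1e-6) is the absolute
log-likelihood change.

`evanno_delta_k()` computes
$\Delta K = |\bar L(K{+}1) - 2\bar L(K) + \bar L(K{-}1)| / \mathrm{sd}(L(K))$
over replicate fits (distinct seeds per replicate), defined only for
interior K with positive replicate standard deviation; the selected K
maximises ΔK. K = 1 fits are deterministic (closed form), which is fine:
only their mean enters. When the likelihood curve is essentially flat the
report is flagged unreliable. Cluster labels are only identifiable up to
permutation; `align_q()` resolves the best permutation against a reference.

# The simulators define the test conditions

`simulate_wgd_genome()` emulates the duplication structure the detector
assumes: ancestral genes are random codon sequences with 60% of positions
drawn from fourfold-degenerate families (keeping the comparable-site count
high and binomial error bounds tight), every chromosome is duplicated, and
at each fourfold codon the duplicate's third base receives a transversion
with probability $p^\*$ and a transition with probability
$p^\* \cdot$ ts/tv (default ratio 2). Mutations touch only fourfold third
positions in the default mode, so proteins stay identical and the 4DTv
statistic is isolated from alignment error; gene loss and local
adjacent-swap shuffling perturb the duplicate's gene order. The truth table
records each pair's realised site and transversion counts, making every
downstream estimate a parameter-recovery check.

`simulate_admixed_genotypes()` mirrors a RAD-seq diversity panel under the
Balding–Nichols model: ancestral frequencies Uniform(0.1, 0.9), population
frequencies Beta-distributed with variance $p(1-p)F_{ST}$, default two
populations of 40 + 45 individuals and 2500 loci at $F_{ST} = 0.1$,
ancestry Dirichlet(5, 0.5) toward the population of origin (mostly-assigned
individuals with visible admixture), negative-binomial depths (mean 60,
size 8, straddling the 20–200 filter window) and 3% extra missingness.

What these simulations do *not* contain: linkage between loci, genotyping
error, tandem and segmental (non-whole-genome) duplications, alignment
error from protein divergence, or unequal substitution rates among lineages.
Passing the recovery tests therefore shows the estimators are correct under
their own model assumptions at realistic sizes — not that real data meet
those assumptions.

# Numerical and design choices

- **Coordinates** are 1-based inclusive throughout, matching GFF3, VCF and
  the R/Bioconductor container convention, so readers and writers perform
  no coordinate arithmetic.
- **Determinism**: every randomised stage takes a seed; replicate seeds are
  derived deterministically from the master seed. Re-running either track
  with an identical configuration reproduces byte-identical TSV/JSON
  artifacts (manifests carry no timestamps).
- **Degenerate inputs**: a distribution whose values are all equal reports
  that value as its mode without a density estimate; loci with zero called
  genotypes are flagged rather than propagating NaN; an empty post-filter
  matrix is an error carrying the stage-by-stage attrition table.
- **Problem sizes in the checks**: the acceptance surface runs the
  duplication track at 20 chromosomes × 60 genes × 200 codons (1200
  homeolog pairs) and the population track at 85 accessions × 2500 loci
  with K = 1..4 and 5 replicate fits — the scale of a typical RAD-seq diversity panel —
  while unit tests use toys small enough to verify by hand or enumerate
  exhaustively.
- **Interface**: the package is function-first. `run_wgd_track()` and
  `run_pop_track()` orchestrate the stages from a validated `run_config()`
  (JSON round-trip, thresholds checked up front, e.g. `dp_min > dp_max` is
  rejected before any stage runs) and write per-stage TSV/JSON artifacts
  plus a manifest echoing every parameter.

# Known limitations

- Absolute dating of a duplication in million years requires an external
  molecular clock and is out of scope; the package reports relative
  divergence only.
- Overlapping peaks are flagged by mode distance, not deconvolved by
  mixture modelling.
- The ΔK criterion cannot, by construction, select K = 1; the unreliability
  flag (flat likelihood curve) is the guard for structureless data.
- Allele-sharing distances and covariance PCA are computed independently;
  the package does not reproduce any specific third-party tool's distance
  matrix bit-for-bit.
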