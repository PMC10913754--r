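---
title: "Null-model inference of community assembly processes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Null-model inference of community assembly processes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecoassembly)
```

## The inference problem

Amplicon surveys of marine protist communities produce a samples × ASVs
count table, a phylogeny over the ASVs, and per-sample environmental
metadata. The question this package addresses is *which ecological
processes structured the observed turnover between communities*:
deterministic selection by the environment, or the stochastic processes
of dispersal and drift. Because raw β-diversity confounds all of them,
the inference works with two null models applied to every sample pair.

### βMNTD and βNTI

The β mean nearest taxon distance between samples $k$ and $m$ is

$$\beta\mathrm{MNTD} = \tfrac12 \sum_{i \in k} f_{ik}\, \min_{j \in m} d_{ij}
                     + \tfrac12 \sum_{j \in m} f_{jm}\, \min_{i \in k} d_{ij},$$

where $f$ are relative abundances and $d$ the patristic (cophenetic)
distances. Its z-score against a null in which taxon labels are shuffled
across all tips of the tree is the β nearest taxon index,
$\beta\mathrm{NTI} = (\beta\mathrm{MNTD}_{obs} - \overline{\beta\mathrm{MNTD}}_{null})
/ \mathrm{sd}(\beta\mathrm{MNTD}_{null})$.

The statistic assumes *phylogenetic niche conservatism*: close relatives
have similar environmental requirements, so selection leaves a signal in
nearest-taxon phylogenetic distances. βNTI < −2 indicates communities
more phylogenetically similar than chance (the same selective
environment: homogeneous selection); βNTI > +2 indicates divergent
selection (variable selection).

Two implementation details matter. First, taxa present in *both* samples
contribute zero to βMNTD under every tip shuffle, so the statistic is
driven entirely by the non-shared taxa; identical presence sets make the
null degenerate (sd = 0) and such pairs are flagged `NA` and excluded
from process fractions, with the exclusion count always reported. Second,
one joint tip permutation per null replicate is shared across all pairs
(the default), which preserves the correlation structure of the null
across pairs and is substantially cheaper; per-pair independent shuffles
are available via `joint_permutation = FALSE`.

### Abundance-based Raup–Crick

For pairs not classified by βNTI, the abundance-based Raup–Crick score
asks whether *taxonomic* turnover deviates from a stochastic-assembly
expectation. Each null replicate rebuilds both samples preserving their
observed richness and read totals: species are drawn without replacement
with probability proportional to regional occupancy (fraction of samples
occupied), each drawn species receives one read, and the remaining reads
are distributed multinomially in proportion to regional relative
abundance over the drawn species. With $n_{<}$ null replicates below the
observed Bray–Curtis value and $n_{=}$ ties (counted at half weight),

$$RC = 2\left(\frac{n_{<} + n_{=}/2}{n_{null}} - \frac12\right) \in [-1, 1].$$

RC > +0.95 indicates more turnover than the null can generate (dispersal
limitation acting with drift); RC < −0.95 indicates less (homogenizing
dispersal); otherwise the pair is undominated. RC is computed from raw
integer counts even though βNTI uses the relative-abundance table — the
null must preserve read totals to be meaningful. A `method = "exact"`
mode enumerates the null outcome distribution exhaustively for tiny
problems in which every read is a richness read; it exists to verify the
Monte-Carlo sampler against exact probabilities. The regional occupancy
and abundance profile is normally estimated from the input table itself;
`occupancy` / `rel_abund` arguments allow a larger reference pool (and
make the calibration experiments below exactly self-consistent).

### Classification

Per pair: βNTI > +2 → variable selection; βNTI < −2 → homogeneous
selection; else RC > +0.95 → dispersal limitation; RC < −0.95 →
homogenizing dispersal; otherwise undominated. All inequalities are
strict, so boundary values (βNTI exactly ±2, RC exactly ±0.95) fall
through to the stochastic/undominated side. Strata for the fraction
summaries follow the rule that a pair is *euphotic* only if both samples
are photic and *aphotic* only if both are aphotic; mixed pairs count
toward the entire-data-set summary only. This pair-stratification rule
is a package decision (recorded in output provenance), as is the choice
to keep boundary values stochastic.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `n_null` | 999 | replicates | null distributions for βNTI and RC; 999 matches the permutation count used for PERMANOVA |
| `n_perm` | 999 | permutations | PERMANOVA / Mantel |
| `abundance_weighted` | `TRUE` | — | βMNTD weighting; presence-based mode retained for diagnostics |
| `photic_depth` | 162 | m | photic/aphotic boundary (1% irradiance depth of the central-gyre stations); configurable per data set |
| rarefaction `depth` | min row sum | reads | only in `standardize_table(mode = "rarefy")` |

The default table standardization is relative abundance; rarefaction is
available and every standardized table carries its mode as an attribute
so no matrix is silently double-transformed. Shannon diversity is
reported in natural-log units (column `shannon_nats`) because the log
base is otherwise a silent convention; Faith's PD includes the path to
the root by default (`include_root`), the common default of the tools
this pipeline mirrors, and is switchable.

## The synthetic metacommunity generator

The generator exists so that every inference stage can be verified
against ground truth; it is first-class, tested code. It composes a Yule
(pure-birth) phylogeny rescaled to height 1, Brownian-motion niche
traits (optionally with an early-burst `conservatism` transform that
concentrates divergence on deep branches), depth-structured transect
metadata (stations along a fixed-latitude transect; temperature decaying
and nutrients increasing with depth; a subsurface chlorophyll maximum;
photic/aphotic at 162 m; epipelagic < 300 m, mesopelagic 300–1000 m,
bathypelagic ≥ 1000 m), and a count table drawn under one of five
regimes. All randomness derives from one scenario seed through a fixed
counter scheme, so every sub-component is independently reproducible.

The regional pool has log-normal(0, 2) relative abundances. The steep
rank-abundance curve is deliberate: real amplicon tables have a long
rare tail, and at finite read depth it is exactly the rare-taxon
sampling flicker that makes the dispersal regimes statistically
identifiable — with a flatter pool every taxon is present in every
sample and both null models degenerate.

The regimes are caricatures, each built to express one process strongly:

- **Homogeneous selection.** Every site filters for the same
  phylogenetically conserved niche, realized as the tree's most tightly
  clustered crown clade (maximizing the gap between the expected
  nearest-neighbour distance of a random tip set and the clade's own,
  scaled by $\sqrt{size}$). Within the clade, dominance is set by a
  damped pool ($pool^{0.1}$), mild per-site log-normal abundance drift
  (sd 0.3), and Bernoulli extinction/colonization turnover (each site
  realizes ~50% of the clade). The turnover term is essential: taxa
  shared by both samples contribute nothing to βMNTD, so detection
  requires same-environment sites to realize *different members* of the
  favoured clade.
- **Variable selection.** Four mutually distant disjoint crown clades
  stand for divergent environments; sites are assigned round-robin
  (availability ~95%). Cross-clade pairs carry the βNTI > +2 signal.
- **Dispersal limitation.** No environmental filtering; each taxon has a
  random home site upweighted by $1/m$ (mixing $m = 0.05$), with strong
  site-specific log-normal abundance drift (sd 2, priority effects) and
  a second multinomial resampling step (local drift). Observed
  Bray–Curtis turnover is high but below saturation — fully disjoint
  site pools would push observed dissimilarity to exactly 1, where the
  Raup–Crick null also mass-ties and the score collapses.
- **Homogenizing dispersal.** One shared realized community; each site
  subsamples a 5×-reads census of it, coupling sites *beyond*
  independent read-resampling noise. This is the one place the
  caricature exceeds what sequencing could show: if all sites were
  independent reads-deep resamples of one community, the regional mean
  would equal the shared community and RC would sit near zero by
  construction. Real data detect homogenizing dispersal only against a
  heterogeneous regional backdrop; the regime encodes the mass-effect
  coupling directly instead.
- **Drift.** Independent multinomial draws from the pool.

A note on the selection regimes: an earlier design filtered taxa by a
Gaussian window on the Brownian trait axis. At the scale used for
verification (60 taxa), Brownian trait windows mix convergent lineages —
taxa with similar trait values but distant positions on the tree — and
the nearest-taxon statistic loses its power. Crown-clade selection is
the cleaner statement of the phylogenetic-niche-conservatism assumption
the statistic itself makes, and is what the regimes now use. The
`scenario_spec` fields `selection_strength` and `niche_breadth` are
retained for interface stability and provenance; the clade regimes do
not consume them.

What the generator does **not** emulate: sequence-level artifacts (PCR
bias, chimeras), copy-number variation, taxonomically realistic
composition, spatial autocorrelation of dispersal (home sites are
random, so dispersal limitation produces no distance-decay signal), or
mixed regimes within one landscape. Passing the recovery tests therefore
shows the inference machinery is sound on data whose generating process
is known — not that any particular fraction estimated from real data is
correct.

## Numerical and design choices

- Permutation p-values use the $(count + 1)/(n_{perm} + 1)$ correction;
  exhaustive modes (n ≤ 8) report the exact fraction over all $n!$
  relabelings with the identity included, which is why a 2+2 design
  yields p-values in multiples of 1/3.
- PERMANOVA is single-factor (pseudo-F from the pairwise sums-of-squares
  decomposition); multi-term designs are approximated by running factors
  separately, which is reported as such because transect factors are not
  orthogonal. The implementation is cross-checked against
  `vegan::adonis2` in the test suite.
- Mantel defaults to the upper one-sided tail (positive association);
  two-sided by flag. Environmental distances z-score each variable with
  the sample (n−1) standard deviation.
- Distance-decay regresses *similarity* (1 − Bray–Curtis) on distance by
  default; pairs are the regression units and share samples, so the
  p-value is anti-conservative and documented as descriptive.
- Bray–Curtis ties in the RC null are detected with an absolute
  tolerance of 1e-9 (the values are ratios of small integers).
- PCoA reports negative eigenvalues without Lingoes/Cailliez correction;
  proportions explained are relative to the sum of positive eigenvalues.
- The diel coefficient of variation uses the sample (n−1) sd and is
  *undefined* (not zero) for units with zero mean, to avoid fabricating
  stability; depths with one time point are excluded with a warning.
- Trees are used rooted-as-written; ASVs absent from the tree (and taxa
  absent from the table) are dropped by `align_inputs()` with a logged
  audit trail, since silent mismatches corrupt Faith's PD and βMNTD.

## Verification scale

The test suite and the acceptance script verify the machinery at sizes a
desk machine handles in seconds: brute-force βMNTD oracles on ≤6 taxa ×
≤4 samples; null-calibration runs with 100–210 pairs and 299–999 null
replicates; regime recovery at 60 taxa × 12 sites × 5000 reads with 299
nulls; 500-replicate type-I-error simulations for PERMANOVA and Mantel
on 7–9 samples. These sizes were chosen to make the statistical
assertions sharp (binomial bands around nominal rates) while keeping a
full run fast.

## Known limitations

- βNTI has limited power at small regional richness; with tens of taxa
  only strongly expressed selection is detectable, which is why the
  verification regimes are deliberately strong caricatures.
- The RC null estimates the regional pool from the analyzed table; for
  few samples that estimate is noisy and RC tails inflate (the
  calibration experiment supplies the generating profile explicitly for
  this reason).
- Pairs sharing a sample are not independent in any pairwise summary
  (distance-decay, process fractions); reported uncertainties would
  understate this.
- Fungal ITS data would need copy-number-aware preprocessing upstream;
  the null models here are run on the protist-style table only.
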