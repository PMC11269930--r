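---
title: "Separating introgression from incomplete lineage sorting with coalscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating introgression from incomplete lineage sorting with coalscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coalscan)
```

## The problem

Rapid radiations leave two kinds of gene-tree/species-tree discordance that
are easy to confuse. Incomplete lineage sorting (ILS) arises when ancestral
polymorphism persists across consecutive speciation events: for a rooted
four-taxon sample (((P1,P2),P3),O) with an internal branch of length $t$
coalescent units (the ratio of the inter-speciation time to $2N_e$), the two
non-species-tree topologies each occur with probability $\frac{1}{3}e^{-t}$ —
and, crucially, with *equal* probability. Introgression breaks that symmetry:
gene flow between P3 and one of P1/P2 inflates exactly one of the two
discordant classes. Every analysis in this package is a different way of
measuring that asymmetry, or of quantifying the background discordance
itself.

coalscan implements four analyses over hard-called biallelic SNPs, window
trees and window alignments, plus a multispecies-coalescent (MSC) simulator
that generates all of these inputs with known truth:

* **Patterson's D** (`pattersonD`, `pattersonDAll`): frequency-weighted
  ABBA/BABA site-pattern sums over all species-tree-compatible triads,
  $D = (\sum \text{ABBA} - \sum \text{BABA})/(\sum \text{ABBA} + \sum
  \text{BABA})$, with a delete-one block jackknife for significance.
* **Ancestry-informative markers** (`findAims`, `profileHybrid`,
  `classifyHybrid`): sites fixed for alternative alleles between two groups;
  an F1 hybrid is heterozygous at essentially every AIM, any backcross skews
  toward one parent.
* **Four-taxon gene-tree frequencies** (`cartesianCombinations`,
  `scoreQuartet`, `tallyQuartets`, `telomereSkew`): window-tree topologies
  scored over the Cartesian product of role-assigned individuals, stratified
  by autosomes versus Z and by chromosome position.
* **Concordance factors** (`windowConcordance`, `siteConcordance`): the
  percentage of decisive window trees (wCF) or decisive alignment sites
  (sCF) supporting each internal species-tree branch.

## The simulator as the study design

`simulationConfig()` fixes the conditions every test and the acceptance
script run under. The defaults encode a four-species design
`(((P1:1,P2:1):1,P3:2):2,O:4)` in coalescent units — an internal branch of 1
unit gives roughly 12% of genealogies in each discordant class, deep enough
to be interesting and shallow enough that ILS is pervasive — with two diploid
individuals per species, 10-kb windows every 100 kb, ten 5-Mb autosomes and
one 5-Mb Z chromosome. The per-site mutation rate (2e-5 per coalescent unit)
yields a handful of SNPs per 10-kb window, comparable to resequencing-scale
SNP densities after hard filtering.

Within each species-tree branch, $k$ lineages coalesce with exponential
waiting times at rate $k(k-1)/2$ divided by the branch's relative $N_e$; one
genealogy is drawn per window (no intra-window recombination, matching the
one-tree-per-window analysis unit), and windows are independent.
Introgression is a *pulse*: at a stated time, every lineage currently in the
recipient branch jumps to the donor branch with probability $\gamma_w$.
Genotypes arise from infinite-sites mutations dropped on each genealogy
(clean biallelic SNPs for the site-pattern statistics), while window
*alignments* use finite-sites Jukes–Cantor evolution (`simulateSequences`,
via `phangorn::simSeq`) so that tree inference faces realistic homoplasy.

### The retention landscape

Avian recombination rises steeply toward telomeres, and purging of
introgressed ancestry is strongest where recombination is low. The observation this package is
built to probe — introgression-supporting
topologies concentrated in the outer chromosome, and nearly absent on the
low-recombining Z — is *an empirical pattern whose mechanism is debated*, so the
simulator encodes it directly as a sampling probability
(`retentionProbability`):

$$\gamma_w = \gamma \cdot \max\!\big(r_{\min},\ (2|x - L/2|/L)^{\alpha}\big)$$

for a window at position $x$ on an autosome of length $L$, and
$\gamma_w = \gamma\, r_{\min}\, z_{\text{scale}}$ on the Z. $\alpha = 0$
turns the landscape off (flat), $\alpha = 2$ gives a pronounced telomeric
skew. The defaults $r_{\min} = 0.1$ and $z_{\text{scale}} = 0.1$ keep a
small interior/Z floor rather than zero, which is the more conservative
choice for testing (a zero floor makes the Z contrast trivially perfect).
The Z additionally runs at $0.75\times$ the autosomal $N_e$ (`zNeScale`),
the neutral expectation for a ZW system; lek-mating systems plausibly push
this ratio lower, and the slot accepts any value.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `minMaf` | 0.03 | frequency | removes singleton-driven noise before D |
| `maxMissing` | 0.10 | fraction | 0.9 completeness per site |
| `minDepth`/`maxDepth` | 2 / 160 | reads | per-call mask, applied only when depth exists |
| `minMeanDepth`/`maxMeanDepth` | 10 / 50 | reads | site-level depth sanity band |
| `blockSize` (jackknife) | 1e6 | bp | matches the megabase binning used elsewhere |
| `maxOutgroupMinor` | 0.2 | frequency | drops unstably polarised sites |
| `f1Threshold` | 0.9 | het fraction | F1 call; a few percent genotyping error keeps true F1s near 0.96 |
| `backcrossBand` | [0.25, 0.75] | het fraction | BC1 expectation is 0.5 |
| `minAims` | 100 | count | below this a profile is UNRESOLVED |
| window `x` / interval `s` | 1e4 / 1e5 | bp | 10-kb trees sampled every 100 kb |

A historical wrinkle worth preserving: upstream variant-filtering practice
uses a per-individual depth ceiling of 150 in some analyses and 160 in
others. Both are plain config values here (`siteFilterConfig`); 160 is the
default because the D-statistic path is the package's centrepiece.

## Numerical and procedural choices

* **Window fallback.** When a candidate window fails the completeness filter
  (more than 50% of columns with at least half the individuals, at least 80%
  of rows under 40% missing — the comparisons are implemented with exactly
  these strict/non-strict senses), the scanner slides *rightward only*, in
  steps of one window length, and gives up when the slide would reach the
  next scheduled candidate start. "Adjacent" does not specify a direction;
  one direction keeps the scan a deterministic left-to-right pass. After an
  acceptance the next candidate is one full interval further, so accepted
  windows can never overlap.
* **Folded bins.** `assignBin` maps a position at folded distance $d$ from
  the chromosome midpoint to bin $\max(1, \min(20, \lceil d / (L/40)
  \rceil))$: bin 1 is the centre, bin 20 the telomere, each bin the union of
  two mirror-image 2.5%-length segments. The ceiling form assigns every
  basepair of $[0, L)$ to exactly one bin with the centre position landing
  in bin 1 and position 0 in bin 20. Windows are binned by midpoint — a
  10-kb window is 0.05% of a typical macrochromosome and never straddles
  bins meaningfully.
* **Quartet label convention.** BBAA = P1+P2 sisters, ABBA = P2+P3, BABA =
  P1+P3, always rooted by the outgroup. Because published figures sometimes
  attach the four-letter labels to differently-assigned roles, every output
  table prints the role-pair key alongside the label; downstream code should
  trust the role pair, never the label alone.
* **Two scoring routes.** `scoreQuartet` prunes and roots the window tree
  (handling polytomies and two-individual outgroups, which must be
  monophyletic after pruning or the window is UNRESOLVED).
  `scoreGenealogyQuartets` exploits ultrametricity: the ingroup pair with
  the smallest pairwise MRCA time is the sister pair. The two routes agree
  exactly on binary ultrametric trees — the suite asserts this — and the
  fast route makes scoring 10^5-window batches a vectorised operation.
* **Outgroup polarisation.** Derived-allele frequencies flip so the
  outgroup-major allele is ancestral; sites where the outgroup minor-allele
  frequency exceeds 0.2 are excluded entirely. Unstable polarisation
  manufactures spurious ABBA *and* BABA weight, which cancels in expectation
  but inflates variance; exclusion is the cheaper, more transparent fix. The
  exclusion rule is this package's decision and is flagged in the function
  documentation.
* **Jackknife.** Delete-one over contiguous 1-Mb blocks (configurable),
  $SE^2 = \frac{m-1}{m}\sum_j (D_{-j} - \bar D_{-})^2$; with a single
  usable block Z is reported as NA, never 0.
* **Null calibration checks use one Cartesian combination.** Window
  topologies are independent across windows, so for a single combination the
  ABBA/BABA count difference is binomial-scaled and "within 3 SE" is a
  well-defined 99.7% check. Counts pooled across combinations share
  genealogies and are strongly positively correlated, so a binomial SE would
  be anti-conservative there; pooled tallies are still reported, but the
  calibration assertion is made per combination.
* **NJ instead of ML window trees.** Topology-frequency analysis consumes
  topologies; branch-length-optimal ML adds hours of compute and an external
  dependency without changing a single BBAA/ABBA/BABA label in the regimes
  the simulator covers (the suite checks >= 95% true-topology recovery on
  20-kb shallow-tree alignments). `njTree` runs canonical neighbor-joining
  on lexicographically sorted taxa (deterministic tie-breaks), clamps
  negative branch lengths to zero and moves the deficit to the sibling so
  path lengths through the parent are preserved. Users with externally
  inferred ML trees feed them in as Newick via `readTrees`; nothing
  downstream cares where trees came from.
* **Triad enumeration.** `enumerateTriads` returns every pair {P1,P2} with
  each P3 for which the tree restricted to the three species shows P1 and
  P2 as sisters. Note this includes "nested" cases — in a ladder
  ((A,B),C),D the triple (A,C|D) is displayed even though A and C are not
  cherry-mates — which is exactly what "compatible with the species tree"
  means for triad-wise D testing against a fixed species tree.

## What the generator does and does not emulate

It *does* reproduce: MSC discordance levels with per-branch $N_e$;
directional pulses with truth flags per window; diploid genotypes with
missing-data-free hard calls; F1/BC1 hybrids with free recombination between
AIM sites (AIMs are sparse genome-wide, so linkage between them is
negligible at F1/BC1 depth); a telomere-folded retention gradient and a
suppressed, lower-$N_e$ Z.

It does *not* emulate: intra-window recombination; linked selection or any
mechanistic purging model (the retention landscape is a phenomenological
stand-in); sequencing depth and genotyping error except as the explicit
symmetric error knob (with probability $e$ a call becomes one of the other
two classes uniformly — so an F1's expected AIM heterozygosity is $1 - e$,
and $e = 0.04$ lands near 96% AIM heterozygosity, the scale typical of
degraded-specimen genotyping; the value is illustrative, not fitted); continuous migration; population
growth; W chromosomes or mitogenomes. Passing tests therefore validate the
statistical machinery, not the claim that any particular empirical system
matches the generator's assumptions.

## Problem sizes

The shipped checks run, per replicate, 5,000 windows (ten 50-Mb autosomes)
with 16 haploid lineages for the D-statistic calibrations (50 replicates
each for the null and the pulse design), 20,000 single-lineage-per-species
genealogies per branch length for the closed-form discordance checks, and
twenty 2,200-window genomes for the telomere-skew contrast. These sizes
keep every stochastic check's acceptance band at least three standard
errors wide while keeping a full run in the minutes range on one core; the
Rcpp coalescent core simulates roughly 10^5 genealogies per second at this
sample size.

## A worked run

```{r demo, eval = FALSE}
cfg <- simulationConfig(
  pulses = data.frame(time = 0.5, donor = "P3", recipient = "P2",
                      gamma = 0.1))
set.seed(1)
sim <- synthesizeGenotypes(cfg)
gmF <- filterSites(sim$gm, siteFilterConfig())
pattersonD(gmF, sim$pm, c("P1", "P2", "P3"), "O")

combos <- cartesianCombinations(sim$pm)
lab <- scoreGenealogyQuartets(sim$truth$batch, combos)
tl <- tallyQuartetLabels(lab, sim$truth$windows, cfg@chromTable)
telomereSkew(tl$perBin)
```

The end-to-end pipeline — simulate, filter, window trees, D, AIMs, quartet
tallies, concordance factors, manifest — is `runPipeline()`; the package's
exported stage functions are its interface, and the shipped
`inst/extdata/demo_config.yaml` documents every knob.

## Known limitations

* Polarisation assumes a single outgroup population; no ancestral-state
  reconstruction beyond the outgroup-major rule.
* The block jackknife assumes blocks are exchangeable; strong genome-scale
  heterogeneity (e.g. an uncorrected inversion) would violate it.
* `scoreGenealogyQuartets` requires ultrametric genealogies; for inferred
  (non-ultrametric) trees use `scoreQuartet`/`tallyQuartets`.
* Concordance factors require a binary species tree; polytomies must be
  resolved upstream.
* F1/backcross thresholds are heuristics for first-generation classes;
  later-generation hybrids need likelihood-based ancestry models, which are
  out of scope.
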