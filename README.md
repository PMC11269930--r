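# coalscan

Tools for telling **introgression** apart from **incomplete lineage sorting
(ILS)** in radiations of closely related species — the situation where
species split so quickly that most gene trees disagree with the species
tree, and the question is whether the disagreement is symmetric (ILS) or
skewed (gene flow).

For a rooted four-taxon sample (((P1,P2),P3),O) with internal branch length
*t* in coalescent units, ILS alone produces the two non-species-tree
topologies at equal frequency ⅓·e⁻ᵗ. Introgression breaks the symmetry.
coalscan measures that asymmetry four ways:

* **Patterson's D (ABBA-BABA)** over every species-tree-compatible triad,
  with frequency-weighted site patterns
  (abba = (1−p₁)p₂p₃(1−p₄), baba = p₁(1−p₂)p₃(1−p₄)) and a
  delete-one block-jackknife Z score:
  D = (ΣABBA − ΣBABA) / (ΣABBA + ΣBABA).
* **Ancestry-informative markers (AIMs)**: sites fixed for alternative
  alleles between two groups; F1 hybrids are heterozygous at ~all AIMs,
  first-generation backcrosses at ~50%.
* **Four-taxon gene-tree frequency scanning**: window-tree topologies
  (BBAA/ABBA/BABA) tallied over the Cartesian product of role-assigned
  individuals, stratified autosomes vs Z and binned along chromosomes —
  including telomere-folded 5% bins that proxy the avian recombination
  landscape.
* **Concordance factors**: per-branch window (wCF) and site (sCF) support
  for the species tree.

A built-in multispecies-coalescent simulator (Rcpp core) with directional
introgression pulses, hybrid-individual construction and a telomere-weighted
retention landscape generates VCFs, population maps, window trees and
alignments with known truth, so the entire pipeline runs and is tested
without any sequencing data.

## Worked example

Simulate a four-species design with a γ = 0.1 pulse from P3 into P2, filter
sites, and test the P1–P2–P3 triad:

```r
library(coalscan)
cfg <- simulationConfig(
  chromTable = data.frame(chrom = paste0("c", 1:10), length = 50e6,
                          is_z = FALSE),
  pulses = data.frame(time = 0.5, donor = "P3", recipient = "P2",
                      gamma = 0.1))
set.seed(1)
sim <- synthesizeGenotypes(cfg)
gmF <- filterSites(sim$gm, siteFilterConfig())
pattersonD(gmF, sim$pm, c("P1", "P2", "P3"), "O")
```

```
TriadDResult ((P1,P2),P3) outgroup O
  D = 0.38174 (ABBA 264.344, BABA 118.281), Z = 8.58 over 500 blocks, 796 sites
```

D > 0 means excess P2–P3 allele sharing — the simulated direction — and
Z ≫ 3 makes it decisive; under γ = 0 the same pipeline returns D within a
few jackknife SE of zero. Quartet tallies and the telomere contrast:

```r
lab <- scoreGenealogyQuartets(sim$truth$batch, cartesianCombinations(sim$pm))
tl  <- tallyQuartetLabels(lab, sim$truth$windows, cfg@chromTable)
tl$pooled
```

```
          BBAA  ABBA BABA UNRESOLVED
AUTOSOME 54944 15558 9498          0
Z            0     0    0          0
```

Pooled over all 16 Cartesian combinations, ABBA (P2+P3 sister) windows
outnumber BABA — the same asymmetry D measures, read from topologies
instead of site patterns.

Every number printed above was produced by the code shown (seed 1).

The end-to-end orchestration — simulate → filter → window trees → D + AIMs +
quartets + concordance, with a hash manifest — is:

```r
runPipeline(system.file("extdata", "demo_config.yaml", package = "coalscan"),
            outdir = "demo_out", seed = 42)
```

See `vignettes/introgression-inference.Rmd` for the model, parameter
defaults and design decisions.

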