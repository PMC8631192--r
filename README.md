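# ProphageKit

Temperate bacteriophages integrate into bacterial chromosomes as
prophages, and the traces they leave — attachment-site direct repeats, a
GC-poor hypervariable early gene region, discordance between phage and
host phylogenies — can be read back off genomic and phenotypic data.
ProphageKit packages that analysis for microbial genomicists and phage
ecologists characterizing a family of temperate phages:

* **Prophage discovery** — scan genomes for an attachment-site motif
  (default the 12-mer `CAGATTTAGGTT`), call prophages from same-strand
  direct-repeat pairs within a size window, locate attB sites in
  phage-free strains (inside an intact tRNA-Leu), excise and
  circular-normalize prophage sequences.
* **Genome regions** — GC profiles in 250-bp windows and a paired t-test
  of early-region GC depletion across a phage panel.
* **Intergenomic similarity** — a VIRIDIC-style fragment-seeded
  similarity in percent, with single-linkage threshold clustering for
  genus (>70%) and species (<97%) demarcation.
* **Phenotype statistics** — reduction in bacterial growth
  (RBG = 1 − ΔOD⁺/ΔOD⁻), spot-assay host-range grading, one-step growth
  fits (latent period, burst size), and the two-factor ANOVA/contrast
  layout used for virulence comparisons.
* **Cophylogeny** — undated duplication-transfer-loss maximum-parsimony
  reconciliation: minimum cost, exact MPR counts, deterministic
  enumeration, k-medoid clustering with representative scenarios,
  cost-space maps over (transfer, loss), and a permutation null for
  codivergence.
* **Synthetic data** — generators for lysogenized genomes, infection OD
  dynamics (lysis then lysogen-driven recovery), step-shaped one-step
  PFU curves, and host/phage tree pairs with a known event history, so
  every stage is testable end to end.

The reconciliation model scores each internal phage node as cospeciation
(cost 0 by default), duplication (2), or transfer (1), plus one loss
(1 or 2) per host edge a lineage passes; dynamic programming over
(phage node, host node) pairs yields the minimum total cost and the full
set of optima.

## Worked example

Simulate a lysogen, detect its prophage, test the GC structure of a
panel, and reconcile a simulated nine-strain cophylogeny:

```r
library(ProphageKit)

host    <- simHostGenome(seed = 11)                 # 100 kb, attB in tRNA-Leu
phage   <- genPhageGenome(seed = 7)                 # 42-45 kb, GC-poor early region
lysogen <- implantProphage(host, phage)
calls   <- callProphages(lysogen)
calls[[1]]
#> ProphageCall on 'synthetic_host': attL [50030,50041], attR [93532,93543],
#>   phage length 43502 bp (0 att mismatch(es))
```

The call reports the two 12-bp att copies and the inferred circular phage
length (interior plus one motif copy); the excised interior is the
implanted phage, base for base.

```r
panel <- lapply(1:10, function(i) genPhageGenome(seed = 700 + i,
                                                 id = paste0("phage", i)))
res <- compareEarlyVsRest(panel)
#> early GC 54.22%, rest 59.93%, t(9) = 27.69, p = 5.1e-10
```

Ten genomes give a paired test on 9 degrees of freedom; the early region
sits ~5.7 GC points below the rest of the genome, as built into the
generator.

```r
sc <- simCophylogeny(cophyloSimParams(9, transferRate = 0.15,
                                      lossRate = 0.05, seed = 42))
sc
#> CophylogenyScenario: host 9 tips, phage 4 tips | true events: 5 cosp,
#>   0 dup, 0 transfer, 2 loss
m <- enumerateMPRs(scenarioPair(sc), dtlCosts(loss = 1), cap = 500)
m
#> MPRSet: 3 MPR(s) at cost 1; 3 enumerated
m@sample[[1]]
#> Reconciliation: cost 1 (3 cospeciation, 0 duplication, 0 transfer, 1 loss)
permutationTest(scenarioPair(sc), dtlCosts(loss = 1),
                nPerm = 999, seed = 1)$p
#> [1] 0.327
```

Parsimony explains the four surviving prophages with one loss (cost 1),
cheaper than the true history's two — the minimum cost is always a lower
bound — and the permutation null shows this small congruent panel carries
no significant codivergence signal. One-step growth fitting recovers the
generator's parameters from a noisy curve:

```r
fitOneStep(simOneStep(latentMin = 50, burst = 255, noiseSd = 0.05,
                      seed = 4))
#> GrowthFit 'phageA' rep r1: latent 54.2 min, burst 264.0
```

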