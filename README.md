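# introgrescan

Multilocus population-genetic tests of **adaptive introgression** — the
movement of a beneficial allele from one hybridising species into another —
from per-locus phased haplotype alignments (FASTA) plus a specimen metadata
table (species, race, colour phenotype, geographic region). The motivating
system is the transfer of red wing-pattern alleles between mimetic
*Heliconius* butterfly species, where one colour locus shows phenotype-driven
clustering and unidirectional gene flow against a background of weakly
exchanging neutral loci.

## What it computes

* **Shared/exclusive-polymorphism LD test of gene flow.** Per species, the
  statistic `x = D_SS − D_SX` contrasts mean linkage disequilibrium among
  pairs of shared polymorphisms with pairs of one shared and one exclusive
  polymorphism. Gene-flow polymorphisms are younger than retained ancestral
  ones and have had less time to recombine, so positive `x` indicates gene
  flow and the recipient species carries the larger positive value.
  Significance comes from coalescent simulation of a no-migration isolation
  null (`geneflow_test()`, `infer_direction()`).
* **AMOVA / Φ-statistics.** One-factor analysis of molecular variance on
  pairwise nucleotide differences, run independently by phenotype, species
  and geography, with whole-haplotype permutation p-values
  (`amova_permutation_test()`, `amova_report()`).
* **Genealogies and topology tests.** Neighbour-joining on uncorrected
  p-distance with column-bootstrap support; Felsenstein-pruning likelihoods
  under GTR+I+Γ on fixed topologies; the Shimodaira–Hasegawa test (RELL)
  against constraint topologies encoding the competing histories — species
  tree, independent phenotypic convergence, ancestral polymorphism
  (`bootstrap_support()`, `tree_loglikelihood()`, `sh_test()`,
  `alternative_topologies()`).
* **Isolation-with-migration coalescent simulator.** Two-population
  structured coalescent with mutation-scaled parameters (θ = 4Nμ, t = Tμ,
  m = m/μ), intra-locus recombination (discretised ancestral recombination
  graph, compiled fast path), infinite-sites mutation, continuous migration
  and an admixture-pulse (selective-sweep) mechanism; unit conversions such
  as 2Nm = θm/2 and calibration of mutation rates from dated divergence
  (`simulate_genealogy()`, `simulate_locus()`, `convert_to_2Nm()`,
  `mu_from_divergence()`).
* **A synthetic study generator and pipeline.** `simulate_study()` builds a
  nine-locus, two-species dataset with one colour locus carrying a recent
  sweep of a donor haplotype and metadata whose phenotypes track the true
  simulated ancestry; `run_all()` drives AMOVA, gene-flow, NJ and SH stages
  from a configuration and writes reproducible TSV/JSON reports.

## Worked example

```r
library(introgrescan)

st  <- simulate_study(seed = 1)            # 9 loci x 40 haplotypes
md  <- st$metadata
mel <- select_haplotypes(md, "species=melpomene")
tim <- select_haplotypes(md, "species=timareta")

gt <- geneflow_test(st$alignments[["HmB453k"]], mel, tim,
                    n_sims = 2000, seed = 2, ancestral = "A",
                    labels = c("melpomene", "timareta"))
gt
#> <gene_flow_result> locus HmB453k
#>   melpomene    x = 0.1514 (Dss = -0.0032 over 15 pairs, Dsx = -0.1546 over 90 pairs)  simulated mean = 0.1095, p = 0.3421875
#>   timareta     x = 0.9861 (Dss = 0.5 over 28 pairs, Dsx = -0.4861 over 88 pairs)  simulated mean = 0.0953, p = 0.02514405
infer_direction(gt)
#> [1] "timareta"
```

The recipient species (here `timareta`, whose colour-locus haplotypes were
partly swept by a donor haplotype in the simulation) shows the larger
positive `x`, significant against its simulated isolation null, while the
donor's value is unremarkable — the directional-introgression signature.

AMOVA on the same dataset separates the colour locus from a neutral one:

```r
d <- pairwise_difference_matrix(st$alignments[["HmB453k"]])
amova_permutation_test(d, setNames(md$phenotype, md$haplotype_id),
                       n_perm = 999, seed = 3, factor_name = "phenotype")
#> <amova_result> factor phenotype (40 haplotypes, 3 groups)
#>   sigma2 among = 2.5774, within = 3.3543; % among = 43.45; Phi_ST = 0.4345
#>   permutation p = 0.001 (999 permutations)
```

At the colour locus phenotype explains ~43% of the molecular variance
(p = 0.001); at the neutral loci of the same dataset the phenotype share
collapses while species explains most of the structure — the hallmark
pattern of a phenotype-associated introgressed locus.

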