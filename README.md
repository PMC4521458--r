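# haplopop

Haplotype construction for population assignment from phased SNP data.

## The problem

Assigning individuals to predefined populations (in forensics, ecology,
fine-scale human population structure) is hard when allele-frequency
differentiation between the candidate populations is small.  Dense SNP data
contain more information than their individual markers: physically close
SNPs are in linkage disequilibrium (LD), and the *combination* of alleles
carried on one chromosome — the haplotype — can discriminate populations
that no single SNP can.  Most assignment workflows prune correlated
markers, throwing that information away.

`haplopop` does the opposite: it greedily merges phased SNPs into
multi-allelic haplotype loci chosen to maximise the information the data
carry about population membership, then assigns individuals with a standard
PCA classifier, evaluated honestly by split-validation.

## The statistic and the algorithm

**Informativeness for assignment.**  For a locus with alleles
\(j = 1..N\) and populations \(i = 1..K\), with \(p_j^{(i)}\) the frequency
of allele \(j\) in population \(i\) and \(\bar p_j\) the unweighted mean
across populations,

```
IA = sum_j ( -pbar_j log pbar_j + sum_i p_j^(i)/K log p_j^(i) )
```

(natural log, `0 log 0 = 0`).  IA is the mutual information between a
random allele and its population of origin under a uniform population
prior, so `0 <= IA <= log K`.

**Gain of informativeness.**  For two markers `M1`, `M2` and the combined
haplotype locus `H` whose alleles are the observed per-chromosome allele
pairs,

```
GIA = IA(H) - IA(M1) - IA(M2)
```

A positive GIA means the pair discriminates better jointly than separately;
under within-population linkage equilibrium GIA is non-positive.

**LEARN.**  Finding the partition of markers maximising the summed IA is
infeasible (Bell's number of partitions), so markers are first tiled into
user-sized genomic windows (markers, bp, or cM) and, within each window,
the pair of loci with the largest GIA is merged repeatedly — recursively,
so merged loci keep merging — while the best GIA exceeds a threshold
(default 0).  The result is a *haplotype coding file*: the partition plus
the map from constituent-allele tuples to haplotype-allele codes (numbered
0, 1, ... in order of first appearance in the individual list), learned
from training individuals only.

**APPLY.**  Any phased dataset with the same markers — including
individuals of unknown origin — is recoded by tuple lookup; tuples unseen
in training get fresh codes and a `novel` flag.

**Assignment.**  Haplotype-alleles are expanded to presence/absence columns
(one per allele), PC axes are computed from all chromosomes (columns
centred and scaled — for an indicator column that is the usual
`sqrt(p(1-p))` SNP normalisation), the top `K - 1` components are kept, an
individual sits at the mean of its two chromosome scores, and each
validation individual is assigned to the nearest training-set population
barycenter.  Accuracy is the Mean percentage of Incorrect Assignment (MIA)
of the held-out validation individuals.

## Worked example

Simulate the three-population divergence benchmark (three populations of
diploid size 1000 that split 100 and 200 generations ago; one 200 kb locus
with theta = 48, rho = 60; 100 diploid individuals per population), learn
50 kb haplotype windows on half of each population, and assign the other
half:

```r
library(haplopop)

x <- simulate_dataset(divergence_model(rho = 60, seed = 7))
split <- make_split(x$labels, 0.5, seed = 11)
map <- haplopop(x, training = split$training, window = window_spec("bp", 5e4))
print(map)
#> Haplotype map (LEARN output)
#>   Window: 50000 bp, GIA threshold 0
#>   496 markers -> 150 loci (346 merges)
#>   Training: 150 individuals, populations: pop1, pop2, pop3
#>   Total IA (training): 7.4369 genotype -> 11.8978 haplotype

report <- pca_assign(onehot(predict(map, x)), split)
print(report)
#> PCA assignment (2 components, populations: pop1, pop2, pop3)
#>   Validation MIA: 33.33%
#>     pop1: 20.00%
#>     pop2: 50.00%
#>     pop3: 30.00%
#>   Training-set MIA (overfitting diagnostic): 24.00%

baseline <- pca_assign(onehot(x), split)
baseline$mia
#> [1] 49.33333
```

Reading: 346 GIA-positive merges collapse 496 SNPs into 150 haplotype loci
and raise the training-set informativeness from 7.44 to 11.90 nats.
Assigning the 150 held-out individuals from the recoded data misassigns
33.3%, versus 49.3% from the raw genotypes — a 32% relative error
reduction from the same data and the same classifier.  The training-set
MIA (24%) is lower than the validation MIA, which is exactly why accuracy
must be measured on held-out individuals.

`write_haplomap()` / `read_haplomap()` persist the coding file as a
diffable TSV; `mia_curve()` and `training_fraction_curve()` sweep window
sizes and training fractions; `inst/cli/haplopop.R` exposes
`learn / apply / assign / simulate / validate` subcommands for shell use.

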