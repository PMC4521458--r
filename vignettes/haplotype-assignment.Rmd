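---
title: "Haplotype construction for population assignment: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplotype construction for population assignment: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the method it implements: the
model, the algorithm, every tunable parameter, the numerical conventions,
and the design decisions that were genuinely open — together with what the
synthetic benchmark does and does not establish about real data.

## The model

We assume phased diploid genotypes: `n` individuals contribute `2n`
chromosome rows over `l` markers, with allele codes `0 .. n_alleles - 1`
per marker (VCF allele indices for data read from VCF).  A subset of
*reference* (training) individuals carries population labels for `K >= 2`
populations.

The information a locus carries about population membership is the
*informativeness for assignment*

$$IA = \sum_{j=1}^{N}\Big(-\bar p_j \log \bar p_j +
  \sum_{i=1}^{K} \frac{p_j^{(i)}}{K}\log p_j^{(i)}\Big),$$

with $p_j^{(i)}$ the plug-in allele frequency in population $i$ and
$\bar p_j$ the unweighted across-population mean.  IA equals the mutual
information between a random allele and its population of origin under a
uniform prior over the $K$ populations; the test suite asserts this
equivalence to $10^{-12}$ against an independent entropy-based oracle, and
with it the bounds $0 \le IA \le \log K$.

Two loci `M1`, `M2` are worth fusing into the haplotype locus `H` (alleles
= observed per-chromosome tuples) when the *gain of informativeness*

$$GIA = IA(H) - IA(M_1) - IA(M_2)$$

is positive.  When haplotype frequencies factorise within every population
(within-population linkage equilibrium), $GIA = -I(M_1; M_2) \le 0$ under
the mixture distribution, so only markers in LD can be gained from —
the method is precisely a device for harvesting LD.

## The LEARN step

Maximising $\sum_{H \in \Gamma} IA(H)$ over all partitions $\Gamma$ of the
markers is infeasible (the number of partitions is Bell's number), so:

1. markers are tiled into windows (see below); merging never crosses a
   window boundary;
2. within each window the GIA of **all** pairs (not only adjacent ones) is
   tabulated;
3. while the largest GIA exceeds the threshold, that pair is merged, its
   rows/columns are dropped, and the GIA of the new locus against all
   survivors is computed.  Merged loci participate again (recursion).

Each merge increases the training objective by exactly the accepted GIA,
so the objective is strictly increasing; tests verify monotonicity, that
the output always partitions the markers, and — on fuzzed windows of five
markers, where full enumeration over set partitions is possible — that the
greedy score never exceeds the exact optimum and matches it on most random
instances.  No approximation guarantee is claimed.

**Degenerate inputs.**  Monomorphic markers have $IA = 0$ and merging with
them never helps ($GIA \le 0$), so they are naturally left alone.  A merge
that reaches one haplotype-allele per training chromosome (`2n` alleles)
is performed but triggers a warning — such a locus is private to every
chromosome and useless; `max_alleles` optionally vetoes such merges
instead.

**Tie-breaking.**  Exact GIA ties are resolved towards the pair whose
constituent original-marker indices are leftmost (smallest minimum, then
smallest second minimum).  Ties are measure-zero in real data but the rule
makes coding files byte-reproducible, which the tests require end to end.

## Parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| `window` | 50 kb | markers / bp / cM | the benchmark's plateau: most of the achievable error reduction is reached by 50 kb windows; larger windows overfit (see below) |
| `gia_threshold` | 0 | nats | merge while GIA is strictly positive.  Plug-in GIA estimates are positively biased (order `(N1-1)(N2-1)/n`), so at threshold 0 even unlinked markers are often merged on finite samples; a threshold above the bias scale (~0.02 at 300 chromosomes for biallelic pairs, verified in the tests) keeps linkage-equilibrium windows intact |
| `max_alleles` | 0 (off) | alleles | hard cap on haplotype-allele counts, a blunt overfitting guard |
| `fraction_training` | 0.5 | — | the benchmark's split; `training_fraction_curve()` shows accuracy is near-flat above ~10% |
| `n_pcs` | K − 1 | — | K clusters are separable in K − 1 dimensions; more axes admit noise |

Windows in bp/cM are half-open tiles `[c*size, (c+1)*size)` anchored at
coordinate 0 of each chromosome; anchoring at a fixed coordinate rather
than at the first marker keeps window boundaries independent of the marker
set.  Marker-count windows are consecutive blocks per chromosome,
the last possibly smaller.

## The APPLY step and the coding file

Haplotype-alleles are coded `0, 1, ...` in order of first appearance,
scanning chromosomes in the order of the individual list — the same rule
at learning time and when recoding new data, where unseen tuples extend
the coding with the next free codes and a `novel` flag.  Recoding the
training set itself therefore reproduces the learned coding exactly
(asserted byte-for-byte in the tests).  Unmerged markers keep their
original allele codes.  The coding file is a `#`-headed TSV (one row per
haplotype-allele, plus marker metadata), designed to be inspected and
diffed; `read_haplomap(write_haplomap(m))` is the identity.

Missing genotypes are rejected at load with a hard error naming the first
offending record: IA requires complete frequency tables, and silent
imputation would fabricate haplotypes.  Marker identity between a coding
file and a dataset is checked on (id, chromosome, position, allele count);
any mismatch is fatal because silent column misalignment is the worst
failure mode of a coding-file workflow.

## Assignment and split-validation

Presence/absence encoding: one column per haplotype-allele, 1 when the
chromosome carries it.  PC axes are computed from the chromosomes of
training *and* validation individuals; an individual's coordinate is the
mean of its two chromosome scores (the aggregation rule is not dictated by
the method; the mean is the natural linear choice); barycenters are
per-population means over training individuals; validation individuals go
to the nearest barycenter (Euclidean; ties to the lexicographically
smallest population id).  MIA is the percentage of misassigned validation
individuals.

**Column scaling.**  Columns are centred and scaled to unit variance by
default.  For a 0/1 indicator column with carrier frequency $p$ the sample
standard deviation is exactly $\sqrt{p(1-p)}$, i.e. scaling reproduces the
classical smartpca-style SNP normalisation on this encoding.  The choice
matters scientifically: scaling upweights rare haplotype-alleles, so the
many training-private alleles produced by overlarge windows audibly
degrade validation assignment — the overfitting signature the method's
window-size guidance rests on.  With plain centred PCA
(`scale_columns = FALSE`) rare-allele columns carry almost no variance,
overlarge windows are flattered, and in our replicated study the 200 kb
windows gained roughly three times more additional error reduction over
50 kb than with scaling; we therefore treat scaled PCA as the reference
behaviour and keep the unscaled variant as an option.

**Why split-validation.**  Haplotypes are constructed to separate the
training labels, so they separate the training individuals regardless of
any true stratification — the training-set MIA reported as the
`overfitting diagnostic` is systematically optimistic (asserted as a
tendency over 20 replicates in the tests).  Two controls matter: held-out
individuals must assign well (evidence of real structure), and a run with
labels randomly permuted before learning and assignment must sit at chance
(MIA statistically indistinguishable from 50% for two equal populations,
asserted by a pooled binomial test over 20 replicates).

## The synthetic benchmark

`divergence_model()` defaults encode the reference evaluation scenario:
three populations of constant diploid size $N_e = 1000$; populations 2 and
3 split $t_1 = 0.025$ coalescent units (of $4N_e$ generations, i.e. 100
generations) ago, their ancestor and population 1 at $t_2 = 0.05$ (200
generations); one 200 kb locus with locus-wide $\theta = 4N_e\mu = 48$ and
$\rho \in \{30, 60, 120, 240\}$; 100 diploid individuals sampled per
population.  The time conversion $t \cdot 4N_e$ generations is the single
most error-prone step and has a dedicated oracle test: the expected number
of segregating sites from an independent event-driven structured-coalescent
simulation (population structure inflates $E[S]$ well above the panmictic
Watterson value, which is why the naive Watterson expectation is only used
for the band width).  Simulation itself is delegated to msprime through a
bundled Python helper; mutations are biallelic infinite-sites variants
whose continuous positions are floored to integers, bumping collisions to
the next free integer so positions stay strictly increasing.

What the generator emulates: neutral divergence, realistic LD decay
controlled by $\rho$, exchangeable individuals, complete and perfectly
phased haplotypes.  What it does not: SNP ascertainment, phasing switch
errors, genotyping error, missingness, migration/admixture, variable
recombination maps, selection.  Passing the benchmark therefore shows the
machinery extracts LD information under the stated model — not that the
same window size or error reduction transfers to any particular real
dataset, where split-validated sweeps (`mia_curve()`) should choose the
window.

**Problem sizes used by the test-suite.**  The replicated study runs 10
replicates per recombination rate at the full scenario above; the
training-fraction and permuted-label experiments use 10 and 20 replicates
respectively; unit and property tests use small constructed datasets and,
where a simulated input suffices, reduced loci (e.g. 50–100 kb, 20–30
individuals per population) — reductions affect only those auxiliary
checks, never the replicated study.

## Known limitations

* Frequencies are plug-in estimates; no shrinkage.  Overfitting control is
  entirely via windows, thresholds and split-validation, never via the
  estimator.
* Windows never span chromosomes and merging never crosses windows; no
  global optimiser is provided.
* Only PCA/barycenter assignment is implemented; model-based assignment
  (Structure/ADMIXTURE-style) is out of scope, as is phasing, imputation
  and unphased-genotype recoding.
* The command-line wrapper accepts flags only (no config file) and runs
  single-threaded; windows are embarrassingly parallel but a parallel
  implementation would have to preserve the deterministic tie-break.
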