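"""Coalescent simulation of a three-population divergence model.

Simulates phased biallelic SNP haplotypes for three populations of constant
diploid size Ne that derive from a common ancestor: populations 2 and 3
split t1 coalescent time units (of 4*Ne generations) ago, and their
ancestor split from population 1 at t2.  Mutation and recombination are
parameterised by the locus-wide population-scaled rates theta = 4*Ne*mu_locus
and rho = 4*Ne*r_locus, the usual `ms` convention.

Output (TSV, written to --out):
  #POS  <tab-separated integer bp positions, strictly increasing>
  #POP  <tab-separated population name per diploid individual>
  then one row of 0/1 allele codes per chromosome; rows 2i and 2i+1 are the
  two chromosomes of individual i, individuals grouped pop1, pop2, pop3.
"""

import argparse
import sys

import msprime


def build_demography(ne, t1, t2):
    dem = msprime.Demography()
    for name in ("pop1", "pop2", "pop3"):
        dem.add_population(name=name, initial_size=ne)
    dem.add_population(name="anc23", initial_size=ne)
    dem.add_population(name="root", initial_size=ne)
    # time in generations; coalescent units are scaled by 4*Ne
    dem.add_population_split(time=t1 * 4 * ne, derived=["pop2", "pop3"],
                             ancestral="anc23")
    dem.add_population_split(time=t2 * 4 * ne, derived=["anc23", "pop1"],
                             ancestral="root")
    dem.sort_events()
    return dem


def integer_positions(positions, seq_len):
    """Floor continuous positions to integers, bumping collisions to the next
    free integer so positions stay strictly increasing."""
    out = []
    prev = -1
    for p in positions:
        q = int(p)
        if q <= prev:
            q = prev + 1
        out.append(q)
        prev = q
    return out


def main(argv=None):
    ap = argparse.ArgumentParser(description=__doc__)
    ap.add_argument("--ne", type=float, required=True)
    ap.add_argument("--n-ind", type=int, required=True,
                    help="diploid individuals per population")
    ap.add_argument("--seq-len", type=float, required=True)
    ap.add_argument("--theta", type=float, required=True,
                    help="4*Ne*mu for the whole locus")
    ap.add_argument("--rho", type=float, required=True,
                    help="4*Ne*r for the whole locus")
    ap.add_argument("--t1", type=float, required=True,
                    help="split of pops 2,3 (units of 4*Ne generations)")
    ap.add_argument("--t2", type=float, required=True,
                    help="split of (2,3) ancestor and pop 1")
    ap.add_argument("--seed", type=int, required=True)
    ap.add_argument("--out", required=True)
    args = ap.parse_args(argv)

    L = args.seq_len
    mu = args.theta / (4 * args.ne * L)   # per bp per generation
    r = args.rho / (4 * args.ne * L)

    dem = build_demography(args.ne, args.t1, args.t2)
    samples = [msprime.SampleSet(args.n_ind, population=p, ploidy=2)
               for p in ("pop1", "pop2", "pop3")]
    ts = msprime.sim_ancestry(
        samples=samples, demography=dem, sequence_length=L,
        recombination_rate=r, discrete_genome=False,
        random_seed=args.seed)
    mts = msprime.sim_mutations(
        ts, rate=mu, discrete_genome=False,
        model=msprime.BinaryMutationModel(),
        random_seed=args.seed + 1)

    if mts.num_sites == 0:
        sys.stderr.write(
            "no segregating sites were generated; "
            "re-run with a different seed or a larger theta\n")
        return 1

    G = mts.genotype_matrix()          # sites x sample nodes
    node_col = {node: j for j, node in enumerate(mts.samples())}
    pos = integer_positions([s.position for s in mts.sites()], L)

    pops = {p.id: p.metadata["name"] for p in mts.populations()}
    with open(args.out, "w") as fh:
        fh.write("#POS\t" + "\t".join(str(p) for p in pos) + "\n")
        ind_pops = []
        rows = []
        for ind in mts.individuals():
            nodes = ind.nodes
            ind_pops.append(pops[mts.node(nodes[0]).population])
            for node in nodes:
                rows.append(G[:, node_col[node]])
        fh.write("#POP\t" + "\t".join(ind_pops) + "\n")
        for row in rows:
            fh.write("\t".join(str(int(a)) for a in row) + "\n")
    return 0


if __name__ == "__main__":
    sys.exit(main())
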