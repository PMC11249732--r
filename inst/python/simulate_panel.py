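"""Coalescent panel simulator bridge.

Simulates diploid European-ancestry individuals under the Gutenkunst et al.
(2009) three-population out-of-Africa demographic model (CEU deme sampled),
drops binary mutations on the genealogy, and extracts within-individual IBD
segments (regions where an individual's two genomes descend from the same
ancestral node) together with that ancestor's id, which groups segments
sharing descent.

Outputs (plain TSV, written to --outdir):
  sites.tsv      pos (1-based)
  genotypes.tsv  M rows x N columns of 0/1/2 dosages, no header
  ibd.tsv        individual (0-based), bp_start, bp_end (1-based half-open),
                 group (ancestral node id)
"""

import argparse
import os

import msprime
import numpy as np

try:
    from numba import njit
except ImportError:  # pragma: no cover - numba is an optional accelerator
    njit = None


def _uf_find(uf, x):
    while uf[x] != x:
        uf[x] = uf[uf[x]]
        x = uf[x]
    return x


def _climb_and_union(parent, rep_seg, active_nodes, uf):
    # For every active descent node, union its representative segment with
    # that of its nearest active proper ancestor in the current local tree:
    # over this region both descend along one genealogical path.  Nearest-
    # ancestor links suffice -- nesting chains connect transitively.
    for idx in range(active_nodes.shape[0]):
        u = active_nodes[idx]
        p = parent[u]
        while p != -1:
            if rep_seg[p] >= 0:
                ru = _uf_find(uf, rep_seg[u])
                rp = _uf_find(uf, rep_seg[p])
                if ru != rp:
                    uf[ru] = rp
                break
            p = parent[p]


if njit is not None:
    _uf_find = njit(cache=False)(_uf_find)
    _climb_and_union = njit(cache=False)(_climb_and_union)


def merge_descent_groups(ts, segs):
    """Group within-individual IBD segments by shared genealogical descent.

    Two overlapping segments are painted with the same alleles when their
    ancestor nodes are nested in the local tree over the shared region (one
    descends from the other along an unbroken path), or when they descend
    from the same node.  The union is segment-scoped: the same ancestor node
    in disjoint regions of the genome does not tie those regions together
    unless its own segments bridge them.

    segs: list of (left, right, node); returns a group label per segment.
    """
    nseg = len(segs)
    nnodes = ts.num_nodes
    parent = np.full(nnodes, -1, dtype=np.int64)
    rep_seg = np.full(nnodes, -1, dtype=np.int64)  # an active segment per node
    active_of = {}  # node -> set of active segment ids
    uf = np.arange(nseg, dtype=np.int64)

    starts = sorted(range(nseg), key=lambda i: segs[i][0])
    ends = sorted(range(nseg), key=lambda i: segs[i][1])
    si = ei = 0
    n_active = 0
    live_nodes = set()

    for interval, eout, ein in ts.edge_diffs():
        for e in eout:
            parent[e.child] = -1
        for e in ein:
            parent[e.child] = e.parent
        left = interval.left
        while ei < nseg and segs[ends[ei]][1] <= left:
            s = ends[ei]
            n = segs[s][2]
            active_of[n].discard(s)
            if active_of[n]:
                rep_seg[n] = next(iter(active_of[n]))
            else:
                rep_seg[n] = -1
                live_nodes.discard(n)
            n_active -= 1
            ei += 1
        while si < nseg and segs[starts[si]][0] <= left:
            s = starts[si]
            n = segs[s][2]
            if rep_seg[n] >= 0:
                # same node already active: same descent group by definition
                ru = _uf_find(uf, s)
                rp = _uf_find(uf, int(rep_seg[n]))
                if ru != rp:
                    uf[ru] = rp
            else:
                active_of.setdefault(n, set())
            active_of[n].add(s)
            rep_seg[n] = s
            live_nodes.add(n)
            n_active += 1
            si += 1
        if n_active == 0:
            continue
        active_nodes = np.fromiter(live_nodes, dtype=np.int64, count=len(live_nodes))
        _climb_and_union(parent, rep_seg, active_nodes, uf)

    return [int(_uf_find(uf, i)) for i in range(nseg)]


def ooa_demography():
    # Gutenkunst et al. 2009 parameters, generation time 25 y
    N_A, N_AF, N_B = 7300, 12300, 2100
    N_EU0, N_AS0 = 1000, 510
    r_EU, r_AS = 0.004, 0.0055
    T_AF, T_B, T_EU_AS = 8800, 5600, 848
    dem = msprime.Demography()
    dem.add_population(name="YRI", initial_size=N_AF)
    dem.add_population(name="CEU", initial_size=N_EU0 * np.exp(r_EU * T_EU_AS),
                       growth_rate=r_EU)
    dem.add_population(name="CHB", initial_size=N_AS0 * np.exp(r_AS * T_EU_AS),
                       growth_rate=r_AS)
    dem.add_population(name="OOA", initial_size=N_B)
    dem.add_population(name="AMH", initial_size=N_AF)
    dem.add_population(name="ANC", initial_size=N_A)
    dem.set_symmetric_migration_rate(["YRI", "CEU"], 3e-5)
    dem.set_symmetric_migration_rate(["YRI", "CHB"], 1.9e-5)
    dem.set_symmetric_migration_rate(["CEU", "CHB"], 9.6e-5)
    dem.add_population_split(time=T_EU_AS, derived=["CEU", "CHB"], ancestral="OOA")
    dem.add_symmetric_migration_rate_change(time=T_EU_AS,
                                            populations=["YRI", "OOA"], rate=25e-5)
    dem.add_population_split(time=T_B, derived=["YRI", "OOA"], ancestral="AMH")
    dem.add_population_split(time=T_AF, derived=["AMH"], ancestral="ANC")
    return dem


def main():
    ap = argparse.ArgumentParser()
    ap.add_argument("--n-diploid", type=int, required=True)
    ap.add_argument("--length-bp", type=int, required=True)
    ap.add_argument("--seed", type=int, required=True)
    ap.add_argument("--min-ibd-bp", type=int, default=5000)
    ap.add_argument("--max-tmrca", type=float, default=1000.0)
    ap.add_argument("--mutation-rate", type=float, default=2.36e-8)
    ap.add_argument("--recombination-rate", type=float, default=1e-8)
    ap.add_argument("--outdir", required=True)
    args = ap.parse_args()

    ts = msprime.sim_ancestry(
        samples={"CEU": args.n_diploid},
        demography=ooa_demography(),
        sequence_length=args.length_bp,
        recombination_rate=args.recombination_rate,
        random_seed=args.seed,
    )
    ts = msprime.sim_mutations(
        ts, rate=args.mutation_rate,
        model=msprime.BinaryMutationModel(),
        random_seed=args.seed + 1,
    )

    os.makedirs(args.outdir, exist_ok=True)
    pos = (ts.tables.sites.position.astype(np.int64) + 1)  # 1-based
    with open(os.path.join(args.outdir, "sites.tsv"), "w") as fh:
        fh.write("pos\n")
        for p in pos:
            fh.write(f"{p}\n")

    G = ts.genotype_matrix()  # sites x haploid samples
    dosage = (G[:, 0::2] + G[:, 1::2]).T.astype(np.int8)  # individuals x sites
    np.savetxt(os.path.join(args.outdir, "genotypes.tsv"), dosage,
               fmt="%d", delimiter="\t")

    segs = []
    inds = []
    for i in range(args.n_diploid):
        res = ts.ibd_segments(within=[2 * i, 2 * i + 1],
                              min_span=args.min_ibd_bp,
                              max_time=args.max_tmrca,
                              store_segments=True)
        for _, seglist in res.items():
            for seg in seglist:
                segs.append((seg.left, seg.right, seg.node))
                inds.append(i)
    groups = merge_descent_groups(ts, segs)

    with open(os.path.join(args.outdir, "ibd.tsv"), "w") as fh:
        fh.write("individual\tbp_start\tbp_end\tgroup\n")
        for i, (left, right, _), g in zip(inds, segs, groups):
            fh.write(f"{i}\t{int(left) + 1}\t{int(right) + 1}\t{g}\n")


if __name__ == "__main__":
    main()
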