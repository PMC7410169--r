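"""Structured-coalescent simulator with ground-truth migrant tracts.

Reads a JSON config describing populations (piecewise-constant sizes,
optional exponential growth), population merges, pulse admixture events and
sampled haploid lineages; simulates ancestry + binary mutations with
msprime; extracts, per pulse, the intervals over which each recipient
lineage's ancestor at the pulse time sits in the migrant source population
(via census nodes placed just above the pulse); writes a JSON result.

Usage: python simulate_dataset.py config.json out.json
"""
import json
import sys

import msprime


def build_demography(cfg):
    dem = msprime.Demography()
    for pop in cfg["populations"]:
        epochs = sorted(pop["size_epochs"], key=lambda e: e["time_gen"])
        growth = pop.get("growth")
        dem.add_population(
            name=pop["name"],
            initial_size=epochs[0]["size"],
            growth_rate=growth["rate"] if growth else 0.0,
        )
        if growth:
            dem.add_population_parameters_change(
                time=growth["end_time_gen"], population=pop["name"],
                growth_rate=0.0)
        for ep in epochs[1:]:
            dem.add_population_parameters_change(
                time=ep["time_gen"], population=pop["name"],
                initial_size=ep["size"])
    for pulse in cfg["pulses"]:
        # forwards-in-time source -> dest: backwards, dest lineages move
        dem.add_mass_migration(time=pulse["time_gen"], source=pulse["dest"],
                               dest=pulse["source"],
                               proportion=pulse["proportion"])
    census_times = sorted({p["time_gen"] for p in cfg["pulses"]})
    eps = 1e-3
    for t in census_times:
        dem.add_census(time=t + eps)
    for mg in sorted(cfg["merges"], key=lambda m: m["time_gen"]):
        dem.add_mass_migration(time=mg["time_gen"], source=mg["child"],
                               dest=mg["parent"], proportion=1.0)
    dem.sort_events()
    return dem, {t: t + eps for t in census_times}


def rate_arg(spec, length):
    if "rate" in spec:
        return spec["rate"]
    m = spec["map"]
    pos = list(m["start"]) + [length]
    return msprime.RateMap(position=pos, rate=m["rate"])


def main(cfg_path, out_path):
    with open(cfg_path) as fh:
        cfg = json.load(fh)
    dem, census_of = build_demography(cfg)
    samples = [
        msprime.SampleSet(1, population=s["population"], time=s["time_gen"],
                          ploidy=1)
        for s in cfg["samples"]
    ]
    ts = msprime.sim_ancestry(
        samples=samples, demography=dem,
        sequence_length=cfg["length_bp"],
        recombination_rate=rate_arg(cfg["recomb"], cfg["length_bp"]),
        random_seed=cfg["seed"], ploidy=2)
    mts = msprime.sim_mutations(
        ts, rate=rate_arg(cfg["mut"], cfg["length_bp"]),
        model=msprime.BinaryMutationModel(), random_seed=cfg["seed"] + 1)

    lineages = [s["lineage"] for s in cfg["samples"]]
    node_time = ts.tables.nodes.time
    node_pop = ts.tables.nodes.population
    pop_id = {p.name: p.id for p in dem.populations}

    tracts = []
    for pulse in cfg["pulses"]:
        ct = census_of[pulse["time_gen"]]
        src = pop_id[pulse["source"]]
        recips = [lineages.index(x) for x in pulse["recipients"]]
        open_left = {}
        for tree in ts.trees():
            left, right = tree.interval
            for li in recips:
                u = li
                while u != -1 and node_time[u] < ct:
                    u = tree.parent(u)
                mig = (u != -1 and abs(node_time[u] - ct) < 1e-9
                       and node_pop[u] == src)
                if mig and li not in open_left:
                    open_left[li] = left
                elif not mig and li in open_left:
                    tracts.append((pulse["band"], lineages[li],
                                   open_left.pop(li), left))
        for li, l0 in open_left.items():
            tracts.append((pulse["band"], lineages[li], l0,
                           ts.sequence_length))

    positions = []
    alleles = []
    for var in mts.variants():
        a = [int(var.alleles[g]) for g in var.genotypes]
        if len(set(a)) < 2:
            continue
        positions.append(int(var.site.position) + 1)
        alleles.append(a)

    out = {
        "lineages": lineages,
        "positions": positions,
        # flat, site-major: each site's per-lineage alleles are consecutive
        "alleles_flat": [a for site in alleles for a in site],
        "tracts": [
            {"band": b, "lineage": ln, "start": int(l), "end": int(r)}
            for (b, ln, l, r) in tracts
        ],
        "num_trees": ts.num_trees,
        "num_sites": len(positions),
    }
    with open(out_path, "w") as fh:
        json.dump(out, fh)


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
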