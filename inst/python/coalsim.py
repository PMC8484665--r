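"""Batch coalescent simulation driver.

Reads a JSON job file, runs msprime for each job, writes all resulting
haplotype panels to one plain-text output file. Invoked by the R package;
not a user-facing tool.

Job modes:
  five_pop  -- (((G,R)GR,(U,P,B)UPB)GRUBP) split demography, sizes given as
               haploid chromosome counts (halved for msprime's diploid Ne),
               split times already converted to generations, symmetric
               migration m among the five terminal populations.
  single_pop -- one panmictic population (ne_hap chromosomes, n_dip samples).

Output format per job:
  #JOB <id> <n_sites> <n_haplotypes>
  P <0-based integer positions, space separated>      (omitted if 0 sites)
  <n_haplotypes lines of 0/1 strings>                 (omitted if 0 sites)
"""
import json
import sys

import msprime
import numpy as np

TERMINALS = ["G", "R", "U", "P", "B"]


def five_pop_demography(p, m):
    dem = msprime.Demography()
    for name in TERMINALS:
        dem.add_population(name=name, initial_size=p["Ne_" + name] / 2.0)
    dem.add_population(name="GR", initial_size=p["Ne_GR"] / 2.0)
    dem.add_population(name="UPB", initial_size=p["Ne_UPB"] / 2.0)
    dem.add_population(name="GRUBP", initial_size=p["Ne_GRUBP"] / 2.0)
    if m > 0:
        dem.set_symmetric_migration_rate(TERMINALS, m)
    dem.add_population_split(time=p["g_GR"], derived=["G", "R"], ancestral="GR")
    dem.add_population_split(time=p["g_UPB"], derived=["U", "P", "B"],
                             ancestral="UPB")
    dem.add_population_split(time=p["g_GRUBP"], derived=["GR", "UPB"],
                             ancestral="GRUBP")
    dem.sort_events()
    return dem


def run_job(job):
    cfg = job["config"]
    if job["mode"] == "five_pop":
        dem = five_pop_demography(job["params"], job["params"].get("m", 0.0))
        samples = [
            msprime.SampleSet(int(cfg["samples"][r]), population=r, ploidy=2)
            for r in TERMINALS if int(cfg["samples"].get(r, 0)) > 0
        ]
        ts = msprime.sim_ancestry(
            samples=samples, demography=dem,
            sequence_length=float(cfg["sequence_length"]),
            recombination_rate=float(cfg["recombination_rate"]),
            random_seed=int(cfg["ancestry_seed"]))
    elif job["mode"] == "single_pop":
        ts = msprime.sim_ancestry(
            samples=int(job["n_dip"]),
            population_size=float(job["ne_hap"]) / 2.0,
            sequence_length=float(cfg["sequence_length"]),
            recombination_rate=float(cfg["recombination_rate"]),
            random_seed=int(cfg["ancestry_seed"]))
    else:
        raise ValueError("unknown mode: %s" % job["mode"])

    mu = float(cfg["mutation_rate"])
    if mu > 0:
        ts = msprime.sim_mutations(
            ts, rate=mu, random_seed=int(cfg["mutation_seed"]),
            model=msprime.BinaryMutationModel())
    if ts.num_sites == 0:
        return np.empty((0, 0), dtype=np.int8), np.empty(0, dtype=np.int64)
    gm = ts.genotype_matrix()  # sites x haplotypes
    pos = ts.tables.sites.position.astype(np.int64)
    seg = (gm.sum(axis=1) > 0) & (gm.sum(axis=1) < gm.shape[1])
    biall = gm.max(axis=1) <= 1
    keep = seg & biall
    return gm[keep].T.astype(np.int8), pos[keep]


def main(job_path, out_path):
    with open(job_path) as fh:
        jobspec = json.load(fh)
    with open(out_path, "w") as out:
        for job in jobspec["jobs"]:
            haps, pos = run_job(job)
            out.write("#JOB %s %d %d\n" % (job["id"], len(pos), haps.shape[0]))
            if len(pos):
                out.write("P " + " ".join(str(int(x)) for x in pos) + "\n")
                chars = np.array(["0", "1"])
                for row in haps:
                    out.write("".join(chars[row]) + "\n")


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
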