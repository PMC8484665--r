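---
title: "Models and methods behind pyrenpop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pyrenpop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

pyrenpop studies fine-scale population structure in small, geographically
close rural populations, modelled on five valley populations of the Spanish
Eastern Pyrenees — Garrotxa (G), Ripollès (R), Alt Urgell (U), Pallars (P)
and Berguedà (B) — sampled along a ~140 km west–east axis. This vignette is
the package's own account of the models it implements, the parameters that
matter, and the choices made where the design was genuinely open.

## The demographic model

The five populations descend from a meta-population (GRUBP) that splits at
time $t_{GRUBP}$ into two clusters, GR and UPB; GR splits into G and R at
$t_{GR}$, and UPB splits simultaneously into U, P and B at $t_{UPB}$
(a trifurcation: one split time is attached to three populations).
Symmetric migration at rate $m$ per generation connects the five terminal
populations. All effective sizes are expressed in **chromosomes** (haploid
counts); the coalescent engine, which works with diploid sizes, receives
$N_e/2$. Times in years are converted to generations at 29 years per
generation and rounded to the nearest generation.

Priors are uniform: $N_{e,GRUBP} \sim U(15000, 40000)$,
$N_{e,GR}, N_{e,UPB} \sim U(1000, 5000)$,
$N_{e,G}, N_{e,R}, N_{e,P} \sim U(500, 2500)$, $N_{e,U} \sim U(200, 2000)$,
$N_{e,B} \sim U(500, 10000)$, $t_{GRUBP} \sim U(2320, 14500)$ years, and
$t_{GR}, t_{UPB} \sim U(870, t_{GRUBP})$ — the upper bound of the two inner
split times is the *drawn* root split time, so their marginal priors are
not uniform. The migration rate is not pinned down by any published value;
we give it a log-uniform prior on $[10^{-5}, 10^{-2}]$ per generation,
configurable, with $m = 0$ allowed. Mutation and recombination rates are
likewise unstated in the source material; we default to the standard human
values $1.25 \times 10^{-8}$ and $1 \times 10^{-8}$ per bp per generation.

Simulation is delegated to msprime through a bundled batch driver
(`inst/python/coalsim.py`); only segregating biallelic sites are returned.
Region coordinates default to a packaged, schematic 5-point west–east
configuration spanning 140 km (Pallars westmost, Garrotxa eastmost); real
analyses should supply a sample-map TSV.

## Coancestry painting and clustering

`paint_panel()` implements the Li–Stephens haplotype-copying model: each
recipient haplotype is explained as a mosaic of all *other* individuals'
haplotypes ("all-vs-all" painting). Switches occur with probability
$1 - e^{-r \Delta}$ per inter-site gap of $\Delta$ bp and emissions err
with a miscopy rate (default 0.01). The forward–backward posterior copying
mass, weighted by inter-site span, accumulates into an $N \times N$
expected-copied-length matrix whose columns each sum to twice the painted
span (posterior-mass conservation; this is a tested invariant). The switch
rate can be estimated by EM (`estimate_switch_rate()`): the E-step collects
expected switch counts per gap, the M-step maximizes the expected
complete-data log-likelihood exactly in one dimension, so the likelihood
trace is non-decreasing. The rate is initialized at the lower search bound:
a panel whose haplotypes never force a switch reports the floor, while
informative panels jump to the data-matched rate in the first iteration.

`cluster_coancestry()` stands in for the fineSTRUCTURE clustering step with
a deterministic surrogate: average-linkage agglomerative clustering on
$d_{ij} = -\log \tilde c_{ij}$, where $\tilde c$ is the row-normalized,
symmetrized coancestry. Copying fractions span orders of magnitude
(close kin absorb most of an individual's copying mass), which is why the
dissimilarity is taken on the log scale: on the raw scale a single pair of
relatives dominates every distance. The number of flat clusters is chosen
by mean silhouette width over $k = 2..k_{max}$. Because $-\log$ keeps the
absolute similarity level, a constant matrix plus noise yields silhouettes
near zero — "no structure" is reportable, not just "weakest structure".

## The anisotropy / genetic-barrier model

The spatial model explains normalized coancestry by distance-decay with
direction-dependent (anisotropic) distances and additive inter-group
barriers:

$$\tilde c_{ij} \approx \beta_0 + \beta_1 e^{-\lambda d_{ij}},\qquad
d_{ij} = \sqrt{\Delta x' \bar M \Delta x} + b_{gh},$$

where each group $g$ has a metric
$M_g = s_g R(\theta_g)' \mathrm{diag}(1, \rho_g^2) R(\theta_g)$
($\rho_g \ge 1$ the anisotropy ratio, $\theta_g$ the orientation), pairs in
different groups use the averaged metric $\bar M = (M_g + M_h)/2$, and
$b_{gh} \ge 0$ is the barrier (0 within a group). The exact functional form
of the original supplementary algorithm is not published in the main text;
this package fixes the reconstruction above, which reproduces every stated
property of that algorithm (coancestry input, per-group anisotropy,
additive inter-group barriers, a two-group result), and labels it as a
reconstruction here.

Identifiability dictates one normalization: with a free per-group scale
$s_g$, a free decay $\lambda$, *and* a free barrier, only $\lambda b$ is
identified. The first group's scale is therefore fixed at $s_1 = 1$, which
puts $\lambda$ in 1/km and barriers in km-equivalents, and makes barrier
recovery a well-posed question (noise-free fixtures recover $b$ to
optimizer tolerance). Coancestry is normalized by symmetrizing and dividing
by the grand off-diagonal mean, removing the painted-length scale.

Fitting profiles $\beta_0, \beta_1$ out analytically (ordinary least
squares given the decay basis, $\beta_1$ clamped at 0) and optimizes the
remaining parameters by seeded multi-start Nelder–Mead (default 20 starts,
relative tolerance $10^{-10}$). The no-barrier nested model (single shared
metric, $b \equiv 0$) is always included as a start of the barrier fit, so
the barrier model's residual sum of squares can never exceed the nested
model's — the nesting inequality holds structurally, not just
statistically. `search_partitions()` enumerates all set partitions of the
regions into $k$ groups (15 for five regions, $k = 2$) and ranks them by
fit score. Significance comes from a permutation test: region labels (with
their coordinates) are permuted jointly across individuals, both models are
refitted, and the observed improvement of the barrier model over the
no-barrier model is compared with its permutation distribution,
$p = (1 + \#\{null \ge obs\}) / (n_{perm} + 1)$.

## Diversity and autozygosity statistics

**HR.** The LD statistic is implemented as the phase-free squared Pearson
correlation of diploid dosages (composite LD). The reference work's exact
formula is not reproduced in the available text; squared dosage correlation
is the standard phase-free reading, and the signed $r$ is available by
flag. LD decay averages HR over intra-chromosome pairs whose minor-allele
frequencies differ by less than 0.05 (frequency matching, which removes the
strong MAF-dependence of LD measures), within distance bins of 10 kb up to
500 kb by default; empty bins report a count of 0 and an undefined (NA)
mean, never 0.

**RoH.** Runs of homozygosity use a sliding-window scan (defaults: 50-SNV
windows, at most 1 heterozygote per window, minimum segment 1 Mb and 50
SNVs, maximum internal gap 100 kb; all configurable, since the original
parameterization is not published). Segments are 0-based half-open. The
across-region comparison of per-individual RoH totals is a Kruskal–Wallis
rank test with the standard tie correction.

**HetR / nHetR.** HetR is the ratio of heterozygous to homozygous-alternate
genotype counts per individual; a zero denominator yields an explicitly
flagged undefined result. nHetR redraws 5 samples per region (5000
replicates by default), restricts to sites polymorphic within each pooled
draw, and averages each sample's HetR over the replicates that contain it.
The per-replicate polymorphism restriction is the reading under which
resampling actually changes per-sample HetR — it fixes the ascertainment
depth across cohorts of different size.

## ABC with a learned summary ("ABC-DL-lite")

The full deep-learning summary machinery of the original ABC-DL approach
(joint-SFS inputs to a DNN) is out of scope; the package implements a
desk-scale analogue. Each simulated panel is reduced to a fixed-order
summary vector: per-region normalized folded SFS, per-region mean
heterozygosity, all 10 pairwise Hudson $F_{ST}$ values, all 10 pairwise
$d_{xy}$ values (absolute divergence per bp — the component that pins the
root size, since cross-cluster divergence is dominated by deep
coalescence), per-region mean HR in three coarse distance bins, and
per-region mean total RoH under scaled-down detection parameters. A small
feed-forward regressor (two tanh hidden layers of 32, full-batch gradient
descent with backtracking line search, seeded) maps summaries to the 11
demographic parameters; observed and simulated summaries are projected
through it, standardized per dimension, and plain rejection keeps the
closest `accept_fraction` (default 5%) of reference simulations. The
regressor's backtracking step makes its recorded loss trace non-increasing
by construction. A raw-summary rejection path (no regressor) is available.
We deliberately do not apply post-rejection linear adjustment: with the
learned summaries it sharpened point estimates slightly but visibly
degraded credible-interval coverage in calibration runs, and calibrated
intervals matter more here than point precision.

Posterior summaries follow the study's reporting layout: mean, median,
half-range mode, the 95% credible interval as empirical 2.5/97.5 quantiles
(linear interpolation), and the 89% highest-density interval as the
shortest contiguous order-statistic interval containing
$\lceil 0.89 n \rceil$ values. The half-range mode iteratively keeps the
densest half-range window (leftmost on ties) until at most two points
remain and returns their mean; a brute-force oracle validates it on small
sets.

## What the synthetic data do and do not show

The generator reproduces the study's sampling design (29 diploids,
6/6/6/6/5 — the region with five samples is arbitrarily taken to be B),
its demographic topology and priors, human-like rates, and migration. It
does **not** simulate sequencing or genotyping error, phasing error,
exome-capture ascertainment, or real linkage maps; passing tests therefore
demonstrate the correctness and statistical behaviour of the methods under
the model, not the reproduction of any real-data estimate. Real WGS panels
differ most importantly in error structure and in marker density along the
genome.

Two scale choices keep everything desk-sized and are worth making explicit:

* Property checks run on 1–3 Mb panels instead of whole genomes. For the
  single-population diversity-direction checks (small-$N_e$ deme vs
  large-$N_e$ deme) the mutation rate is scaled as $\mu \propto 1/N_e$ so
  both demes have the same $\theta$ per bp ($\theta_0 = 4 \times 10^{-4}$),
  matching marker densities while leaving the drift-driven quantities (RoH,
  LD) governed by $N_e$ and recombination. Matching $\theta$ has one subtle
  consequence for RoH: within an autozygous tract of age $t$ the
  heterozygosity is $2 t \mu$, so relative to the background the tract is
  depleted only by a factor $t/N_{e,hap}$ — scale-free, and much milder for
  the small-$N_e$ deme whose $\mu$ is scaled up. RoH detection for these
  panels therefore uses 25-SNV windows tolerating 2 heterozygotes (tracts
  to $t \sim N_e/4$ pass; background windows carry ~8 heterozygotes and
  essentially never do) and a 300 kb minimum length, near the expected
  tract scale $1/(2 N_{e,dip} r) \approx 312$ kb at $N_{e,hap} = 320$;
  replicates are 10 Mb so that the large-$N_e$ deme's rare long tracts
  average out instead of dominating single replicates.
* ABC calibration uses 500 training + 500 reference simulations of 1 Mb
  and 20 pseudo-observed datasets; the pipeline defaults are larger
  (5 Mb, 2000 + 1000) and all counts are configurable upward.

## Numerical choices and degenerate inputs

* Distances in MDS: negative eigenvalue axes are dropped (with a warning),
  never imputed; `k` is truncated to the positive-eigenvalue count.
* Painting requires complete phased data; unphased VCFs can be read in an
  explicit dosage-only mode where half-calls become missing.
* Monomorphic sites make HR undefined and raise an error naming the site;
  monomorphic regions make the folded SFS all-zero and are flagged, and
  undefined $F_{ST}$ entries are encoded as 0 with a flag rather than NA so
  summary vectors keep a fixed length.
* Zero-variance summary dimensions are dropped (with a warning) before
  rejection distances are computed.
* A constant coancestry surface is fitted flat ($\beta_1 = 0$, RSS 0): the
  distance parameters are unidentifiable there, but the fit succeeds.
* All entry points that consume randomness take an explicit seed; batch
  simulation derives per-job seeds with an integer hash kept below
  $2^{31}$.

## Known limitations

* The barrier model's functional form is a reconstruction (see above); with
  more than two groups its cross-group metric averaging is a convention.
* The agglomerative + silhouette clustering is a surrogate for
  fineSTRUCTURE's MCMC model comparison; it reports no posterior
  uncertainty over partitions.
* HR and RoH parameterizations are reconstructions of unpublished defaults,
  exposed in configuration.
* The learned-summary regressor is far smaller than a production ABC-DL
  network; its role here is to weight informative summaries, not to extract
  new ones from raw data.
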