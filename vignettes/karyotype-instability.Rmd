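---
title: "Karyotype dynamics and chromosome instability: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Karyotype dynamics and chromosome instability: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

karyostab analyses whole-chromosome copy-number dynamics in aneuploid
budding yeast. Aneuploid strains with random karyotypes arise as spores
of a triploid: in meiosis I each chromosome's three homologs segregate
2:1, so every one of the 16 chromosomes of a spore independently
carries 1 or 2 copies. Following such strains over tens of generations
reveals that some karyotypes are stable while others gain and lose
chromosomes at high rates (chromosome instability, CIN). The package
implements the computational machinery needed to study this: karyotype
calling from flow-cytometry ploidy plus qPCR stoichiometry, two
stochastic simulators, parsimony reconstruction of karyotype networks
with a CIN classification, the association statistics, and a
synthetic-data generator that produces every input with known ground
truth.

## The karyotype model

A karyotype is a vector $c = (c_1, \dots, c_{16})$ of non-negative
integer copy numbers indexed by chromosome I–XVI. Copy number 0
(nullisomy) is lethal. Derived quantities:

* **Apparent ploidy** — total DNA content relative to the haploid
  genome, $\mathrm{AP}(c) = \sum_i c_i L_i / \sum_i L_i$ with $L_i$
  the chromosome length in base pairs. This is what a flow cytometer
  measures when a G1 peak is scaled to a haploid control. The bundled
  length table is the S288C reference assembly (R64); a user table can
  replace it. An unweighted variant (`method = "count"`, total
  chromosomes / 16) is exposed because "calculated ploidy" can
  reasonably mean either; the length-weighted form is the primary
  definition since it is the physical DNA content.
* **Basal ploidy** — the modal copy number. With eight chromosomes at
  1 and eight at 2 the mode is undefined (`NA`) and the strain cannot
  be assigned per-chromosome aneuploidy calls.
* **Aneuploid chromosomes** — those deviating from basal ploidy,
  gains and losses alike; megabases in aneuploidy counts each
  aneuploid chromosome's full length once, symmetrically for gains
  and losses.

Copy numbers above 2 are representable throughout (the simulator
produces trisomies from disomic chromosomes) even though strains from
triploid meiosis start between 1N and 2N.

## Karyotype calling from FACS and qPCR

qPCR gives each chromosome's abundance *relative* to a calibrator
sample, leaving an unknown global scale; FACS anchors the absolute
DNA content. `call_karyotype()` finds the integer vector $c$ and scale
$s$ minimising $\sum_i w_i (s r_i - c_i)^2$ subject to
$|\mathrm{AP}(c) - \mathrm{AP}_{\mathrm{FACS}}| \le$ `ploidy_tol`.
Given $s$ the objective separates per chromosome, so the search runs
over a geometric grid of scales (600 points spanning 0.4–2.5 times the
ploidy-matched scale), rounds $s r_i$ into the allowed copy range, and
refines each distinct integer assignment with its closed-form optimal
scale. Defaults, all configurable:

| parameter          | default | rationale |
|--------------------|---------|-----------|
| `copy_range`       | 1–3     | strains lie between 1N and 2N; 3 admits hyper-diploid deviants |
| `ploidy_tol`       | 0.15    | about half the smallest chromosome-gain ploidy step at 2N, and ~5 SD of a 2% CV FACS measurement |
| `residual_threshold` | 0.25  | a scaled ratio this far from any integer indicates a mixed (heterogeneous) population, as seen for chromosomes caught mid-sweep |
| `efficiency`       | 2.0     | perfect doubling per cycle; per-probe efficiencies accepted |

If no integer vector satisfies the ploidy constraint the strain is
declared `too_heterogeneous` and excluded, mirroring how strains whose
modal karyotype cannot be determined are dropped in practice.

Relative quantification follows the standard
$E^{\Delta C_t}$ / $\Delta\Delta C_t$ chain. Both normalisations used
in practice are exposed and neither is privileged: single
normalisation to the calibrator only (the free scale $s$ absorbs the
missing anchor), or double normalisation against an endogenous control
probe via `reference_probe`.

Ploidy stability of a strain is classified from the coefficient of
variation of 12 G1 peaks (spore + 11 colonies) against 12 haploid
control colonies processed identically: stable iff
$\mathrm{CV} \le \mathrm{CV}_{\mathrm{control}} \times$ `cv_factor`
(default 1). Strains with overtly heterogeneous DNA profiles can be
forced unstable before the CV is consulted, since a wild multi-peak
profile can have a deceptively low G1-peak CV.

The MAD2:MAD1 copy-ratio classes default to $\{0.5, 1, 1.5, 2\}$ —
the ratios realisable with copy numbers in 1–3. The exact class set
used for published four-class figures is not enumerated anywhere, so
the set is configurable; the binary split (ratio = 0.5 vs not) is
also returned directly, and is the split the headline association
uses.

## The mis-segregation simulator

`simulate_missegregation()` grows a colony from one seed cell. Each
generation every cell divides; each chromosome mis-segregates
independently with probability $p$; daughters that lose all copies of
any chromosome are discarded as dead; when the colony exceeds `cap`
cells it is downsampled uniformly without replacement (cap checked
after each full generation). The reported statistic is the fraction of
live cells whose karyotype differs from the seed after $g$
generations, over (by default) 30 replicates.

Two granularities of mis-segregation are implemented because the
verbal description — one daughter inherits both copies of a duplicated
chromosome, the other none — is ambiguous for $c \ge 2$:

* `mode = "single"` (default): one homolog's sister-chromatid pair
  mis-segregates, daughters receive $c+1$ and $c-1$. This is the only
  reading that produces the single-chromosome gains and losses
  observed in real colony karyotypes from disomic chromosomes, so it
  is the default.
* `mode = "all"`: the literal reading, $2c$ and $0$.

At most one event per chromosome per division. No fitness differences
or growth competition are modelled, matching the original design
(which therefore under-estimates diversity in competing populations).
For small $p$ and negligible death the mean deviant fraction
approaches $1-(1-p)^{16g}$; the exact small-tree expectation used in
tests is computed by full enumeration of the two-generation division
tree, including nullisomic death.

Benchmarks in the tests and the acceptance script use a population cap
of 10,000 rather than the 100,000 default; the deviant-fraction
statistic is insensitive to the cap (the original analysis made the
same control) and the smaller cap keeps a 30-replicate run in seconds.

## The meiosis simulator

`random_spore()` draws each chromosome's copy number as 1 or 2 with
probability 1/2. `spore_ploidy_distribution()` repeats batches of 41
spores (the number of viable strains karyotyped in one experiment)
10,000 times by default, returning per-bin means and SDs (bin width
0.1 on [1, 2]; the published histogram's bin width is unstated) plus
the pooled sample for ECDF work. Because there are only $2^{16}$
equally likely spores, `enumerate_spore_ploidies()` computes the exact
distribution; Monte-Carlo summaries are tested against it, and it can
serve directly as the expected sample in `ks_compare()`. The KS
comparison is implemented as a two-sample test between observed
ploidies and a large expected pool; whether the original comparison
was one- or two-sample is unknowable from the text, and with a $10^5$
pool (or the exact enumeration) the distinction is numerically
immaterial.

## Karyotype networks and CIN classification

The input is the standard 12×16 matrix: the g20 population karyotype
plus 11 colony karyotypes, 16 chromosomes as loci, copy numbers as
alleles. Duplicate rows collapse into nodes weighted by observation
frequency. `build_network()` reconstructs the network minimising the
total number of single-chromosome copy-number changes, inserting
unobserved intermediate ("median") karyotypes when they strictly
reduce the total — the median-joining idea, but solved exactly:

* Candidate vertices are all combinations of the per-chromosome
  observed states (for binary 1/2 data, the sub-hypercube spanned by
  the varying chromosomes). Restricting each locus to its observed
  states loses no optimality, by the usual parsimony argument.
* The minimum Steiner tree over the candidates with Hamming distances
  is found by Dreyfus–Wagner dynamic programming, exact whenever the
  candidate space is at most `max_candidates` (512) and there are at
  most 10 distinct karyotypes — comfortably covering 12-row
  instances. Beyond that the search falls back to the median-vector
  closure of the observed karyotypes, and past 10 distinct karyotypes
  to a greedy median-joining refinement of the minimum spanning tree;
  the result then carries `exact = FALSE`.
* Steiner vertices of degree below 3 are pruned or contracted: an
  unobserved karyotype that merely subdivides a path adds no
  information, and in an optimal tree the contraction is cost-neutral.
* Copy numbers outside {1, 2} need no special casing: any number of
  states per chromosome is handled as multi-state parsimony at unit
  cost per change.

Co-optimal networks genuinely occur (a published example notes a
strain with two equally probable networks) and can disagree about the
root's degree, so `enumerate_ties = TRUE` enumerates all optimal
topologies — by exhaustive search over Steiner subsets drawn from the
median closure (up to 3 extra vertices, pools capped at 48) with
branch-and-bound enumeration of all cost-optimal spanning trees,
deduplicated after pruning. Classification is then reported per
network with a consensus flag. The enumeration pool is a documented
compromise: exotic co-optimal Steiner points outside the median
closure would be missed, but the returned cost is always the exact
optimum on instances within the exact-search bounds.

`count_root_events()` counts the edges incident to the population
karyotype node. An edge whose label contains several chromosomes
(e.g. `+VII,-X`) is still one event — scored conservatively because
one erroneous mitosis and several consecutive ones cannot be
distinguished. Changes hanging off a deviant node are attributed to
the deviant, not the founder. Classes: 0 events stable (S), 1 mildly
unstable (MU), ≥2 highly unstable (HU). The verbal S/MU/HU
descriptions also mention *when* deviants were observed (later vs
early generations); the count-based rule is what is implemented, and
generation labels travel as metadata only, since the count rule is the
operational definition the published classification states.

## Association statistics

All standard tests are delegated to R's stats engine and wrapped with
the conventions fixed: `fisher_exact()` (two-sided minimum-likelihood
convention; exact for 2×2 and for moderate r×c, Monte-Carlo beyond),
`hypergeometric_enrichment()` (upper tail, $P(X \ge x)$),
`welch_t()` (two-sided, unpaired, Welch–Satterthwaite df),
`growth_rate()` (least-squares slope of $\log_2$ counts over hours =
generations/hour), `ks_compare()`, and `density_profile()` (Gaussian
kernel, Silverman bandwidth, peak normalised to 1 then scaled by the
class proportion — the construction used for per-class overlay
curves). Significance threshold α = 0.05 throughout.

`pairwise_imbalance_scan()` runs the hypergeometric enrichment over
all 120 chromosome pairs: for a pair, the "draw" is the strains whose
two copy numbers differ (ratio 0.5 or 2, not 1) and the "marked" set
is the unstable group, under either grouping (S vs MU+HU, or S+MU vs
HU). Raw p-values are the primary output — the published scan reports
raw values — with an optional Benjamini–Hochberg matrix attached on
request. The strain universe is whatever the caller passes; both
natural universes (all karyotyped strains, or only those with
assignable basal ploidy) are reasonable and neither is hard-coded.

## The synthetic-data generator

`generate_strain_collection()` emulates the experimental design end to
end: seed karyotype from triploid meiosis (optionally through a
viability filter that removes spores with apparent ploidy in
[1.4, 1.6] with probability 0.8, emulating the observed depletion of
mid-ploidy survivors), growth at a per-strain true mis-segregation
rate drawn from {0, 10⁻⁴, 5×10⁻⁴, 10⁻³}, and 11 colonies sampled
uniformly from the final live population. Lineages are tracked: each
cell remembers the event that first took its ancestry off the seed
karyotype, so the number of *distinct founding events among sampled
colonies* is known exactly and gives the ground-truth S/MU/HU class.
Extinct populations are redrawn and counted.

The noise model is deliberately simple. Ct values are the exact
$\mathrm{base} - \log_E(c_i)$ plus Gaussian noise per technical
replicate (SD 0.15 cycles by default, triplicates); the calibrator is
generated noise-free by default because it is the scaling anchor of
the relative-quantification chain — its uncertainty is statistically
equivalent to extra sample noise, and a separate
`calibrator_noise_sd` exposes it when wanted. FACS peaks are Gaussian
with a 2% CV around a mean proportional to apparent ploidy. These
defaults make recovery clean but not trivial: with 0.2-cycle sample
noise, about 98% of strains between 1N and 2N are called exactly;
with calibrator noise of the same size the effective log-ratio noise
doubles and recovery drops to roughly 80%, which is worth knowing
when mapping the generator onto a real protocol.

What the generator does *not* emulate: fitness differences and growth
competition between karyotypes, colony-size bias in picking, partial
or segmental aneuploidy, recombination, and raw fluorescence or
amplification curves. Passing tests therefore demonstrate that the
pipeline recovers whole-chromosome events under the stated noise
model, not that it is robust to biology outside that model.

## Problem sizes and reproducibility

The test-suite and acceptance-script runs use: 30 replicates for
deviant-fraction thresholds at a 10,000-cell cap; 50 synthetic strains
(25 at rate 0, 25 at 10⁻³) with colonies sampled at generation 30 for
the end-to-end class-recovery check — generation 30 because that is
the time point the experimental protocol itself uses for apparently
stable strains, precisely to maximise the chance of catching deviants;
at generation 20 a rate-10⁻³ strain samples 11 non-deviant colonies
~18% of the time, a detection limit of the design rather than a
reconstruction error. All generators are deterministic given
`set.seed()`; every CLI run requires or reports an explicit seed.

## Known limitations

* The network search is exact for the instance sizes the design
  produces (12 samples); far larger collections fall back to
  heuristics and say so.
* Tie enumeration explores Steiner points only within the median
  closure.
* The qPCR model assumes one probe per chromosome and whole-chromosome
  stoichiometry; partial aneuploidy silently biases the called copy
  number toward the covered fraction.
* The CV-based stability call inherits the control strain's
  measurement quality; `cv_factor` trades sensitivity for specificity
  and has no universally right value.
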