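---
title: "Simulating synthetic associations from rare causal variants"
author: "synthassoc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating synthetic associations from rare causal variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synthassoc)
```

## The phenomenon

A *synthetic association* is a genome-wide significant case-control signal
at a common variant that is driven indirectly by one or several much rarer
causal variants in the same genomic region. On a gene genealogy, rare
derived alleles cluster by chance on particular branches; any common
variant whose derived clade happens to partition the haplotypes carrying
the causal alleles from those that do not will pick up an association,
even though it has no causal role and is one to two orders of magnitude
more frequent than the variants doing the work.

This package simulates the full causal chain — neutral genealogy, rare
causal variants, a penetrance disease model, ascertained case-control
cohorts, and an additive logistic association scan — so that the
frequency, strength, geometry and conditional behaviour of synthetic
associations can be measured under controlled conditions.

## The simulation model

### Coalescent haplotype panels

`simulate_panel()` draws a standard neutral coalescent for
`n_haplotypes` samples (default 10,000) under a constant effective
population size `Ne` (default 10,000), with infinite-sites mutation at
rate `mu` per bp per generation (default $10^{-8}$) over a region of
100 kb by default. The region is divided into fragments (default 200
fragments of 500 bp); crossover occurs only at fragment boundaries, with
a per-meiosis probability `recomb_between_fragments` per boundary.
Setting that probability to 0 collapses the model to a single genealogy
for the whole region, in which case the four-gamete property holds for
every pair of sites — `four_gamete_violations()` must return zero, and
the test suite asserts exactly that.

Internally the simulator is a Hudson-style ancestral-recombination-graph
walk in units of $2N_e$ generations: pairs of lineages coalesce at rate
1, a lineage spanning $b$ fragment boundaries recombines at rate
$b\rho_b/2$ with $\rho_b = 4N_ec$, and mutations are dropped on the
marginal genealogies per fragment at rate $\theta_f/2 = 2N_e\mu L_f$.
Marginal trees are stored as an edge table over fragment intervals, in
the manner of succinct tree sequences. Two independent calibrations back
this implementation: the segregating-site count reproduces Watterson's
expectation $\theta\sum_{i<n}1/i$ within Monte-Carlo error, and the
decay of mean $r^2$ with physical distance at 1 cM/Mb matches an
independent coalescent implementation (msprime) bin for bin.

Positions are continuous 0-based bp offsets internally; the VCF exporter
converts to 1-based integer coordinates.

### Disease model and ascertainment

`disease_spec()` encodes a dominant, locus-level penetrance model.
Causal sites are drawn uniformly among panel sites with derived-allele
frequency in [0.005, 0.02] — rare enough to be invisible to a
common-variant scan, frequent enough to exist in a 10,000-haplotype
panel. An individual (a random pair of panel haplotypes, drawn with
replacement) is affected with probability $\gamma$ if it carries at
least one causal derived allele on either haplotype, and with baseline
probability $\varphi$ otherwise; the genotypic relative risk is
$\gamma/\varphi$. Only derived alleles are deleterious. `sample_cohort()`
ascertains equal numbers of cases and controls (sampling until both
quotas fill, surplus discarded) and materialises additive genotype codes.
Eligibility frequencies are always measured on the full panel, before
ascertainment, because causal status is a property of the genealogy, not
of a cohort.

When a genealogy has fewer eligible rare sites than requested, the
genealogy is redrawn with a fresh sub-seed and the redraw is counted in
the replicate record; if case/control quotas are unreachable (for
example $\varphi = 0$ with no carriers), ascertainment aborts with a
classed error after a cap of $10^7$ drawn individuals rather than
truncating silently.

### Association scan

`logistic_scan()` fits, per site, a logistic regression of status on the
additive genotype code and reports the Wald test of the genotype
coefficient; `OR = exp(beta)` exactly. Wald is the convention of
standard GWAS software; a likelihood-ratio test is available via
`test = "lrt"` for separation-prone sites (for the rare, high-penetrance
causal sites the two can differ by a few orders of magnitude in the
extreme tail, which matters little for threshold comparisons). Because
a single-covariate additive fit depends on the data only through the
genotype-by-status cell counts, each fit runs on at most nine weighted
cells in compiled code; this is what makes grids of $10^5$ fits cheap.
Unit tests pin the fits to `glm()` to six decimals and to an independent
Cochran-Armitage trend oracle within an order of magnitude.

"Common" means panel minor-allele frequency at least 0.05. Tested sites
exclude the causal sites themselves and, whenever recombination is
simulated, any site sharing a fragment with a causal site, so that
significant hits are separated from causal sites by at least one
recombination distance. Non-converged, separated or collinear fits are
flagged and report `NA`, never a silent 0 or 1; flagged sites are
excluded from minima and proportions and counted in the replicate
record.

Genome-wide significance is strict $p < 10^{-8}$. Ties on the minimum
p-value break to the leftmost position, for determinism under fixed
seeds.

### Conditional analysis and the one-log-drop criterion

`conditional_scan()` refits every remaining common site with the top
hit's genotype as a covariate — one conditioning round, no stepwise
iteration. A replicate has a *secondary, independent* association when
the conditional scan still contains a site with $p < 10^{-8}$, and *no
residual association* when its minimum conditional p exceeds 0.05.

`one_log_drop_distance()` asks which causal sites demonstrably feed a
synthetic hit: refit the hit's regression with one causal genotype as a
covariate; the causal site contributes when the hit's p-value weakens by
at least one order of magnitude
($\log_{10}p_{\mathrm{cond}} - \log_{10}p_{\mathrm{uncond}} \ge 1$),
and the reported distance is the largest |position difference| over
contributing sites. With a single causal site this reduces to the plain
distance between hit and causal variant whenever conditioning removes
the signal.

## Worked example

```{r example, eval = FALSE}
params <- sim_params()                                   # 10,000 haplotypes, 100 kb
dspec  <- disease_spec(phi = 0.01, grr = 4, n_causal = 9)
rec    <- run_replicate(params, dspec, n_per_arm = 3000, seed = 1)
rec[, c("disease_class", "min_common_p", "min_causal_p",
        "gw_significant", "raf", "cond_min_p")]
```

One replicate is exactly one "simulation" of the study design: draw a
genealogy (redrawing if the causal frequency window is empty), assign
causal sites, ascertain the cohort, scan the common variants, and — if a
hit reaches $10^{-8}$ — run the conditional scan. `run_grid()` iterates
this over the factorial grid (GRR 2–6; 1–9 causal sites; 1,000–3,000 per
arm; $\varphi \in \{0.01, 0.1\}$) and aggregates per-cell and pooled
proportions with binomial standard errors.

## The two-locus LD study

`ld_moment_curve()` isolates the mechanism by which low recombination
*enhances* synthetic association: for two loci separated by a
recombination probability $c$, it pools $r^2$ between rare
(derived frequency 0.005–0.02) sites of one locus and common
(MAF $\ge 0.05$) sites of the other over many simulations. The mean of
$r^2$ is nonincreasing in $c$, but its *variance* rises before it falls;
a wider spread of pairwise LD puts more mass in the upper tail, which is
where the strongest synthetic signal comes from. The defaults follow the
study design (rate grid 0 to $5\times10^{-3}$); the test suite verifies
both moment properties at a reduced scale (1,000 haplotypes, 1,200
simulations per rate, 2-kb loci) chosen so each rate finishes in
seconds while the rare-frequency window is still resolvable.

## Numerical and design choices

* **Statistic.** Wald by default, LRT behind a switch; surfaced as a
  parameter because the study this reproduces does not state its choice.
* **Frequencies.** All eligibility windows (causal 0.005–0.02, common
  MAF $\ge 0.05$) are evaluated on the panel. Cohort MAF is reported per
  tested site, and a cohort-based filter is available as an option.
* **Top-hit polarity.** The risk allele of a tested site is whichever
  allele carries the higher disease probability (derived when
  $\beta \ge 0$); its frequency (RAF) is recorded in the pooled cohort,
  with the control-only frequency alongside, since the study design does
  not say which was used.
* **The causal-versus-common comparison** is computed two ways and both
  are reported by `run_grid()`: the strict reading (minimum causal p
  below minimum common p, per replicate) and the restricted reading in
  which a causal variant is only "beaten" by a common variant that is
  itself genome-wide significant — i.e. by an actual synthetic
  association. The strict fraction is a few points lower because in
  weak-effect cells the minimum over ~120 near-null common sites
  undercuts the minimum over nine causal sites by multiple-testing
  alone.
* **The recombination-response cell** (GRR 4, nine causal variants,
  3,000 per arm) is run at $\varphi = 0.1$. The choice is identified by
  the data rather than assumed: under $\varphi = 0.1$ the whole response
  curve — roughly two-thirds of simulations significant without
  recombination, ~0.95 at $5\times10^{-5}$, ~0.30 at $5\times10^{-4}$
  and none of 60 at $5\times10^{-3}$ — matches the behaviour this cell
  is known for, while $\varphi = 0.01$ yields a uniformly weaker
  response (≈0.56/0.74 at the first two rates).
* **Null control.** Phenotypes generated by one genealogy are tested
  against the common variants of an independent genealogy. The marginal
  p-distribution is uniform; *pooled* p-values across sites of one
  region are strongly dependent (perfect-LD site pairs give exact ties),
  so the uniformity test in the suite draws one tested site per
  replicate — an independent sample — rather than applying a
  Kolmogorov–Smirnov test to dependent pooled values, which rejects for
  reasons unrelated to calibration.
* **Degenerate inputs.** Zero-site panels signal a classed warning;
  empty eligible sets return empty tables; collinear conditioning sites
  are flagged per site.
* **Problem sizes.** The test suite runs the pooled grid at 4
  replicates per cell, the single-cell recombination response at 40
  replicates per rate (12 at the highest rate), the null control at 40
  replicates and the 10-Mb distance experiment at 6 replicates; these
  sizes keep the whole suite within a desk-scale run while leaving
  Monte-Carlo bands (three binomial standard errors) tight enough to be
  informative. `scripts/acceptance.R` re-runs the grid at 20 replicates
  per cell and the recombination cells at 200 replicates.

## What the generator does and does not emulate

The panels are neutral, constant-size, panmictic coalescent samples:
realistic in their site-frequency spectrum, tree imbalance and LD decay
(verified against closed-form and independent-simulator oracles), but
with no demographic history, selection, gene conversion, genotyping
error or array ascertainment. Passing results therefore speak to the
*population-genetic mechanism* of synthetic association — they show what
rare causal clusters do to common-variant scans under idealised
sampling — and not to any particular human cohort. In real data,
commercial genotyping arrays over-sample higher-frequency variants, which
weakens the low-RAF skew of synthetic hits; and population structure,
relatedness and differential ascertainment can mimic or mask the
conditional-signal signatures simulated here.

## Known limitations

* The distance experiment over 10 Mb is the most expensive piece
  (roughly 20–25 s per replicate at 10,000 haplotypes) and its
  contributing-site distances are sensitive to the direction convention
  of the one-log-drop criterion; we require the hit to *weaken* when a
  causal effect is removed. Conditioning on a distal true cause in an
  ascertained sample can also *strengthen* a hit (explaining-away), and
  such sites are deliberately not counted as contributing. Under the
  exact coalescent, contributing sites concentrate at linkage-
  disequilibrium scale (mostly within 2 Mb at 1 cM/Mb, with occasional
  multi-megabase contributors picked out by top-hit selection); reports
  of typically multi-megabase contribution distances are not reproduced
  by this implementation, whose LD decay matches an independent
  coalescent simulator.
* Penetrance is dominant at the locus level; recessive and additive
  causal architectures are out of scope.
* One conditioning round only; no stepwise model selection.
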