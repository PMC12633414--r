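---
title: "Detecting rapidly evolved genomic regions between ancestral nodes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting rapidly evolved genomic regions between ancestral nodes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aqerscan)
library(dplyr)
```

## The problem

Comparative screens for rapidly evolved regions ask where a genome
accumulated far more changes than its neutral background since a given
ancestor. When each species is represented by a single assembly, two very
different things are conflated: fixed differences that separate lineages,
and polymorphisms segregating within a species that happen to distinguish
the chosen individuals. `aqerscan` implements a screen that separates them
by comparing two *internal* nodes of a phylogeny of many complete
haplotypes — for humans, the human–chimpanzee ancestor (`hcaT2T`) against
the most recent common ancestor of the sampled human haplotypes
(`HUMANanc`) — so that variation younger than the species coalescent never
masquerades as interspecies divergence. The same machinery screens any
lineage of the tree (chimpanzee, bonobo, gorilla) after rescaling the
expected rate by stem branch length.

## Ancestral sequences as probability vectors

Every alignment column is reconstructed at each internal node as a
posterior probability vector over A, C, G, T rather than a single best
base.

*Presence.* A node carries a base at a column only if at least two of its
incident lineage directions (each child subtree; for non-root nodes, the
complement through the parent) contain at least one aligned base. This
treats aligned bases as evidence of common origin and keeps
lineage-specific insertions out of the ancestor.

*Posterior.* For present nodes, the marginal posterior is computed by
Felsenstein's pruning algorithm under the Jukes–Cantor model with a
uniform root prior. Leaves with gaps or ambiguity codes contribute no
likelihood term (they are marginalised out, not treated as a fifth state).
Branch lengths come from a neutral model fit.

The package validates the pruning implementation against brute-force
enumeration of all internal-state assignments on small trees; the two
agree to better than 1e-10 per posterior entry.

## The neutral model

Branch lengths are estimated from fourfold degenerate (4D) codon sites —
third positions whose base never changes the encoded amino acid — judged
on the reference annotation only (`extract_4d_sites()`). The fitted
maximum-likelihood tree of 20 telomere-to-telomere great-ape haplotypes
ships with the package (`great_ape_tree()`).

`fit_branch_lengths()` maximises the Jukes–Cantor likelihood on the fixed
topology by coordinate-wise bounded scalar maximisation (tolerance 1e-8
per branch, cycled until the log-likelihood improves by less than 1e-10).
This is deliberately dependency-light and deterministic; the
log-likelihood trace is monotone by construction, and its maximum agrees
with an independent phylogenetics package on the same data. Two
conventions deserve note:

* Under a reversible model only the *sum* of the two root-adjacent branch
  lengths is identifiable (the two-leaf tree is the extreme case). The fit
  reports the maximum-likelihood sum split equally — the same convention
  visible in the shipped tree, whose two root edges are identical.
* Reported standard errors are profile (curvature) standard errors at the
  optimum. In replicate simulations they match the empirical spread of
  the estimator to within a few percent, so "within 3 SE" statements are
  calibrated.
* 4D sites do not require presence in every haplotype; all-absent
  patterns are dropped with a warning.

## Calling divergence events

Between the two node tracks, per column:

* **Substitutions.** The cosine distance `1 − u·v/(|u||v|)` between the
  two posterior vectors approximates the probability that a substitution
  occurred on the connecting branch. Columns with distance ≥ 0.8 are
  binarised to substitution events — a conservative cutoff: both
  reconstructions must be confident and different.
* **Gap events.** A maximal run of columns where exactly one node carries
  a base counts as a single event, irrespective of length, anchored at its
  first column so it is never double-counted across windows.
* Columns where both nodes are absent are silent; they are not callable.

## The window screen

Windows of 500 bp (default; configurable from 25 bp to 20 kbp, step 1 for
maximal sensitivity) are laid on reference coordinates; insertions within
a window's span count toward it, and the binomial trial count stays at
the window length. Significance is conservative by construction:

1. The expected event rate is the **maximum** rate observed in any 10-Mbp
   calibration window (non-overlapping tiles with at least half their
   bases callable), not the genome-wide mean — so regionally elevated but
   typical divergence cannot reach significance.
2. Each window's raw p-value is the exact binomial upper tail
   `P(X ≥ k)`, `X ~ Binomial(500, rate)`.
3. Benjamini–Hochberg step-up over all evaluated windows; windows with
   adjusted p below 3e-7 are retained and merged (book-ended windows
   merge) into calls carrying their peak event count and minimum adjusted
   p. At the default configuration this threshold corresponds to about 29
   events per 500-bp window.
4. For non-human lineages the calibrated rate is multiplied by the ratio
   of the lineage's stem branch length to the human stem branch
   (`scale_rate_for_lineage()`): longer stems get proportionally higher
   expected rates, which is why long-stem lineages yield fewer, more
   conservative calls.

Subsets are produced by `filter_calls()`: higher event-count thresholds,
or exclusion of repeat annotations supplied as BED.

A separate scan, `poly_div_windows()`, supports joint
polymorphism/divergence distribution analysis; there (and only there) a
posterior-confidence filter applies: columns count only when the
ancestor's maximum posterior is at least 0.8, and windows are retained
only when more than 90% of their callable bases are confident.

## Population-genetic evidence

Divergent sites (substitution columns only; gaps excluded so uneven gap
sizes cannot skew counts) are partitioned into *fixed* versus
*polymorphic* by intersection with population variants, compared across
region sets by Pearson chi-squared without continuity correction (the
intended use has large counts; an expected zero cell is an error that
advises an exact test). Variants are polarized against the reconstructed
ancestor only when one base reaches 99% posterior (`N` otherwise), and a
site is dropped when the ancestral allele matches neither observed
allele. Allele frequency spectra use derived allele counts (polarized) or
folded minor-allele counts; proximity blocking (`proximity_block()`)
greedily thins variants in a seeded shuffle order so retained sites are
at least 10 kb apart, which reduces linkage effects on the spectrum while
remaining reproducible (the conventional seeds are 10, 40, 70).

High-frequency derived polymorphic divergent sites (DAF > 0.95) are
classified by haplotype context: if any haplotype still carrying the
ancestral allele also carries the ancestral allele at another divergent
site within 2,000 bases, the site looks like an incompletely swept
ancestral haplotype; otherwise it is a reversion candidate. The context
window is a package default — no established value exists — and is a
tunable argument; sweeps over 500–10,000 bases mainly trade how often
sparse divergent-site neighbourhoods fall back to "reversion candidate".

## Interval enrichment

`overlap_enrichment()` models each query element as independently and
uniformly placed (with its own length) in the background — the genome
minus any excluded set — never crossing a background block boundary. The
per-element probability of touching the merged annotation gives a
Poisson-binomial null for the overlap count: exact dynamic-programming
convolution up to 5,000 elements, normal approximation with continuity
correction beyond. Two-sided p is twice the smaller tail, capped at 1;
Bonferroni is the default family adjustment (BH for large trait scans).
The null is validated against a 20,000-placement Monte-Carlo oracle and
is conservative (super-uniform p) on matched random regions.
`simulate_rand_regions()` draws those matched controls: same element
count, fixed length equal to the rounded mean length, uniform within the
background, non-self-overlapping, reproducible per seed.

## Enhancer activity from single-cell STARR-seq

After UMI deduplication (identical cell/UMI/construct triples collapse),
each construct's output count is divided by its input-library count and
then by the mean such ratio across negative-control constructs — so
negative controls average to score 1 in every scope by construction, and
scores are invariant to uniform rescaling of either library. Per-cell-type
scores repeat the same computation within each cell-type's cells.
Significance comes from a gamma distribution fitted to the
negative-control scores by maximum likelihood (method-of-moments
fallback with a warning): the reported p is the right tail at the
construct's score, with a BH-adjusted column alongside since the choice of
correcting across constructs is left to the analyst. If any negative
control has zero output in a scope, add-one smoothing is applied to the
negative-control outputs of that scope; an all-zero scope is an error.
`pseudoreplicate_bins()` randomly assorts cells into k bins (default 5)
and errors, naming the offending bins, unless every bin retains more than
one read of every negative control.

## What the generators emulate — and what they do not

`simulate_alignment()` evolves a uniform root sequence down the fixed
tree under Jukes–Cantor, with geometric-length deletions (mean 5 bp, rate
0.1 events per site per unit branch length — roughly one indel per ten
substitutions, a realistic ratio for primate divergence) and optional
planted windows where one branch's substitution rate is multiplied. The
default planted multiplier of 14 on the human stem makes the expected
true substitution count in a 500-bp window about 40
(`500 × 3/4 (1 − e^{−4·14t/3})`, t = 0.00606109), comfortably at or above
the 35-event design point even after posterior binarisation loses a few
low-confidence columns. `simulate_variants()` draws derived-allele counts
from the discretised Wright–Fisher stationary density
`f(x) ∝ (1 − e^{−γ(1−x)})/((1 − e^{−γ}) x(1−x))` (the neutral `1/x` at
γ = 0) on 1,002 alleles; `simulate_starr_counts()` uses lognormal input
counts and negative-binomial per-cell outputs.

These generators reproduce the statistical structure the methods assume —
independent sites, a correct tree, homogeneous rates outside planted
windows, no alignment error. Real genomes violate all of these:
context-dependent mutation (CpG), alignment uncertainty in repeats,
incomplete lineage sorting, and selection all add structure the
simulations lack. Passing tests therefore demonstrate the correctness and
calibration of the *implementation*, not that real-data calls are immune
to those artifacts — which is exactly why the screen's rate calibration
is taken as a genome-wide maximum and why repeat-exclusion subsets exist.

## Numerical choices and problem sizes

* Pruning is vectorised across columns; the JC transition product uses
  the model's rank-one structure (`e·L + (1−e)/4 · rowSums L`).
* Genome-scale simulation + reconstruction streams in 250-kb chunks
  (`simulate_divergence_screen()`), keeping only the two node tracks.
* The test suite exercises the screen at 4 Mb with 5 planted windows and
  20 neutral replicates of 200 kb; the acceptance script runs the full
  20-Mb screen. These sizes were chosen so the whole validation runs
  comfortably on a single CPU while leaving the per-window statistics
  unchanged (the screen's calibration and BH family scale with window
  count, which both runs exercise in the millions).
* Branch-length recovery is validated at 50,000 sites, where most
  branches of the shipped tree carry 20–600 expected substitutions.
* All generators take an explicit integer seed and restore the caller's
  RNG state; identical (parameters, seed) give bit-identical output.

## Known limitations

* Jukes–Cantor only; no transition/transversion asymmetry, rate
  heterogeneity, or context dependence. Cosine distances between sharp
  posteriors are robust to this, but branch lengths on real data would be
  mildly compressed relative to, say, GTR fits.
* Presence inference is per column; the ancestral state of an indel
  spanning many columns is summarised only through the one-gap-one-event
  rule.
* The enrichment null places elements independently and uniformly over
  the whole background; it does not condition on chromosome of origin or
  recapitulate clustering of real annotation.
* Joint (maximum a posteriori path) ancestral reconstruction is out of
  scope; posteriors are marginal per column.

## A worked run

```{r example, eval = FALSE}
tree <- great_ape_tree()
planted <- planted_windows(5, 4e6)
run <- simulate_divergence_screen(tree, 4e6, planted = planted, seed = 7)
glance(run$screen)
tidy(run$screen)       # the merged calls
autoplot(run$screen)   # events per window with calls highlighted
```
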