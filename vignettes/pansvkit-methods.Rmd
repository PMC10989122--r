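---
title: "pansvkit: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pansvkit: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pansvkit)
```

pansvkit analyses structural-variant (SV) and gene presence/absence
variation (PAV) in multi-breed livestock cohorts — the setting is a duck
pan-genome with wild, native (indigenous) and commercial breed groups, but
nothing in the code is species-specific. This vignette explains the models
behind each stage, the tunable parameters that matter, what the synthetic
cohort generator does and does not emulate, and the design decisions taken
where several defensible choices existed.

## Coordinates and containers

All internal coordinates are 0-based half-open, so `end - start` is always
a length; conversion to and from the 1-based conventions of VCF and GFF3
happens only in `read_sv_vcf()`/`write_sv_vcf()` and `read_intervals()`.
Genotypes live in an `sv_matrix`: a records table plus an SV × sample
dosage matrix with values 0/1/2 (ALT allele count) or `NA`. Missing
genotypes are excluded from every allele count, never imputed — the
frequency-based tests downstream are defined on called alleles.
Multi-allelic VCF records are dropped with a warning rather than guessed
at: a diploid ALT dosage is not well defined for them. Insertions carry
their inserted length in `svlen` while their interval is the 1-bp anchor
point, because they have no reference footprint.

## PAV calling and pan-genome modelling

A gene is called present in a sample when the pooled fraction of its
exonic bases covered by at least 2 reads exceeds 5% (`call_gene_presence`,
defaults `min_depth = 2`, `min_exon_fraction = 0.05`). Both thresholds are
strict: a gene at exactly 5% is absent. The pooled-bases reading of
"fraction of all exons" is the default; a per-exon-count variant
(`rule = "per_exon"`) is provided because the phrase is ambiguous. Sex
chromosomes distort presence frequencies through hemizygosity, so
`pav_call_matrix()` takes an exclusion list.

Occupancy classes partition genes by presence frequency *f* across
samples: core (*f* = 1), softcore (0.99 < *f* < 1), shell
(0.01 ≤ *f* ≤ 0.99), cloud (*f* < 0.01). Boundary frequencies fall to the
lower class.

Pan and core growth curves average gene-set unions and intersections over
random sample orderings (`pan_core_trajectories`, default
`n_orders = 100`; per-ordering trajectories are retained so monotonicity
is checkable). The pan curve is fitted with the power law
*y* = *A·x^B* + *C* and the core curve with *y* = *A·e^{Bx}* + *C*. When
*B* < 0 the curve is closed and *C* estimates the asymptote (total genes,
or the core floor). Fitting uses bounded Levenberg–Marquardt least squares
over a deterministic multi-start grid of *B* values, with *A* and *C*
profiled by a linear fit at each start; the best residual sum of squares
wins, so fits are reproducible without randomness. On noiseless curves the
parameters are recovered to 1e-6 relative error (tested); with only a
handful of trajectory points the three-parameter fit is genuinely
underdetermined below 4 distinct *x* values, which is an error.

## Selection scan

For a two-group contrast (domestication: wild → native; improvement:
native → commercial) each SV contributes a 2×2 table of derived vs other
allele counts. "Derived" is operationally the ALT allele: true
polarisation would need an outgroup the pipeline does not model. This
matters only for the `increased`/`decreased` direction labels — both the
Fisher p-value and Weir–Cockerham θ̂ are invariant under allele
relabelling (tested).

* `fisher_exact_two_sided()` enumerates the hypergeometric distribution
  directly and sums the probabilities of all tables no more likely than
  the observed one — the minimum-likelihood two-sided convention of
  mainstream statistics packages. It agrees with `stats::fisher.test` to
  1e-12 and with exhaustive enumeration on every 2×2 table with total
  ≤ 40 (tested). Allele counts are the default table unit; a
  genotype-carrier option exists since either reading is defensible.
* `bh_adjust()` is Benjamini–Hochberg (the concrete procedure chosen for
  the "FDR" requirement), via `stats::p.adjust`.
* `wc_fst()` implements the Weir & Cockerham (1984) single-locus moment
  estimator θ̂ = a/(a+b+c) from per-group sample sizes, allele frequencies
  and observed heterozygote proportions. One subtlety worth stating: θ̂ is
  *not* exactly zero at equal sample frequencies. The small-sample
  correction makes the a-component −(n̄/n_c)(p̄q̄ − h̄/4)/(n̄−1) there, which
  vanishes only when h̄ = 4p̄q̄ and is O(1/n̄) negative under
  Hardy–Weinberg heterozygosity. The tests therefore assert exact zero on
  the h̄ = 4p̄q̄ family, θ̂ = 1 at a fixed difference, and equality with an
  independent ANOVA-on-indicator-variables oracle to 1e-12 on random
  genotype configurations.
* `scan_selection()` intersects the two signals: selected ⇔ q ≤ 0.001 AND
  θ̂ at or above the empirical 99th percentile of the contrast's
  non-missing θ̂ values. The percentile is per-contrast, so "top 1%" means
  top 1% of that comparison. A structural consequence: at most ~1% of
  loci can ever be selected, so simulated cohorts plant selected SVs at
  well under 1% of loci (5 per 1000) when power is being measured.
* `delta_af()` ranks |AF difference| between two phenotype-defined groups
  inside a region, ties broken by ascending position so output is
  deterministic.

Monomorphic sites and groups with fewer than 2 called samples yield
missing θ̂ and are excluded from the percentile. The MAF filter
(`maf_filter`, pooled MAF < 0.01) runs before testing.

## TE–SV association

`sv_te_overlap()` computes, per reference-footprint SV (DEL/INV/DUP —
insertions are excluded because they occupy a point on the reference),
the TE-covered fraction after merging the TE track (fragmented
annotations of one element must not double-count; coverage is invariant
to fragmentation, tested). Classes: `partial` (> 0 overlap), `high`
(fraction ≥ 0.5), `intact_derived`. Class statistics follow the
convention of restricting to SVs longer than 100 bp.

`match_intact_derived()` calls an SV intact-TE-derived when an intact TE
has reciprocal overlap strictly above 0.95 — both overlap/len(SV) and
overlap/len(TE). The reciprocal reading is the default because "derived
from" an element implies near-coincident spans; a one-sided mode exists
(`reciprocal = FALSE`) but would mis-call small SVs inside long elements.

`window_occupancy()` tiles chromosomes with non-overlapping windows of
2/5/10 kb and `chi_square_2x2()` applies Pearson's χ² without continuity
correction (window counts are large; Yates is available as an option).
Two window-assignment modes exist, and the difference is statistical, not
cosmetic. With any-overlap assignment (default, matching the usual
sliding-window screen) a feature longer than a window marks several
adjacent windows; since both the TE and the SV tracks are clumped at the
2 kb scale, neighbouring windows are positively autocorrelated and the
χ² null is mildly anti-conservative there (measurably so in simulation).
Midpoint assignment marks exactly one window per feature, keeps window
occupancies exchangeable under independent placement, and is exactly
calibrated (null p-values uniform, tested by simulation). Use midpoint
assignment when a calibrated p-value matters; read 2 kb any-overlap
p-values as anti-conservative. At the effect sizes of interest the choice
does not change conclusions: with strong planted co-location both modes
reject at p < 0.001 essentially always.

`classify_context()` labels SVs gene_body (overlap with the gene span),
else upstream5k (within 5 kb 5′ of a TSS, strand-aware — the biological
convention, since regulatory "upstream" is defined relative to
transcription), else intergenic. `nearest_gene()` minimises edge-to-edge
distance with ties broken by ascending gene start.

## LTR insertion dating

At insertion the two long terminal repeats of an LTR retrotransposon are
identical; each then accumulates substitutions at rate *r* per site per
year, so their divergence *K* grows at 2*r* and the insertion age is
*T* = *K*/(2*r*). The default rate is 1.91e-9 substitutions/site/year
(avian). `align_ltr_pair()` computes a global Needleman–Wunsch alignment
(match +1, mismatch −1, gap −2, via Biostrings); when the two sequences
have equal length and the gapless score already attains the optimal
score, the gapless alignment is returned without the quadratic traceback
— an exact shortcut, not an approximation. `ltr_divergence()` drops gap
and N columns from numerator and denominator, requires ≥ 50 ungapped
columns, and corrects the mismatch proportion with JC69 by default
(*K* = −¾ ln(1 − 4*p*/3), undefined at *p* ≥ 0.75); raw and K2P models
are options and the model used is recorded. JC69 is the simplest model
consistent with dating from overall LTR homology; with the divergences
involved (*K* ≤ ~0.02) the three models differ by far less than the
binomial noise on *p*.

## Sweep statistics and marker association

`pi_per_site()` sums per-site unbiased heterozygosity
2*p̂*(1−*p̂*)·*n*/(*n*−1) and divides by window length (window length, not
callable-site count, is the default denominator; both readings exist in
practice and the length convention is what window-based scans usually
report). `tajimas_d()` uses the standard constants a₁…e₂ computed from
the haplotype count; D is undefined at S = 0 and reported missing.
Diploid dosages are expanded to 2n pseudo-haplotypes (0→00, 1→01, 2→11):
allele counts are exact, within-individual phase is arbitrary, and π and
D depend only on allele counts, so the expansion is not an approximation
for these two statistics — it would be for LD-based ones, which is why
none are offered. Windowed F_ST uses the ratio-of-sums estimator
Σa/Σ(a+b+c) over the window's sites, the standard windowed form of the
Weir–Cockerham estimator; it reduces exactly to the single-locus θ̂ for a
one-site window (tested). Presets: 20 kb window/20 kb step for π and
F_ST, 10 kb/5 kb for Tajima's D. Overlapping scans keep full windows
only; pure tilings keep the final partial window.

`single_marker_glm()` fits y = μ + β_sex·sex + β_g·g by OLS with the
marker coded additively (a 2-df genotype-class coding is an option). The
marker p-value is the F-test against the sex-only model and marker
R² = (RSS_sex-only − RSS_full)/TSS — the marker sum of squares after
fitting all other terms over the total sum of squares. R² = 1 exactly
requires the marker to be orthogonal to sex in the sample; with random
sex/genotype draws a noiseless marker explains marginally less because
sex absorbs a sliver of variance by chance.

## The synthetic cohort generator

`simulation_config()` fixes the study conditions; `simulate_cohort()`
runs all generators under one master seed (each stage offsets the seed
deterministically, and all randomness passes through a save/restore
helper, so cohorts are byte-identical across runs and platforms).

* **Cohort structure**: 131 samples in groups wild = 20, native = 70,
  commercial = 41. The commercial count is fixed by the study design;
  the 20/70 split of the remaining 90 is a simulation choice.
* **Genotypes**: null SVs share one Beta(0.5, 0.5) allele frequency
  across groups (a U-shaped spectrum, heavy near 0 and 1 as empirical SV
  frequency spectra are); planted SVs carry per-group frequency triples,
  by default (0.05, 0.89, 0.012) — a near-fixed native/commercial
  difference. Dosages are Binomial(2, AF): Hardy–Weinberg within groups
  and no linkage between SVs, the simplest null consistent with per-SV
  tests. Planted loci are spread deterministically across the locus list.
* **TE landscape**: TEs per Mb (default 50) placed uniformly with
  log-uniform lengths 500–8000 bp; half of LTR-class elements are flagged
  intact. With probability `rho` an SV start is drawn inside a TE-occupied
  2 kb window, otherwise uniformly. `intact_fraction` of SVs copy an
  intact TE span with per-endpoint jitter ≤ 1% of length, guaranteeing
  reciprocal overlap > 0.95; free SVs are rejection-sampled away from
  intact TE spans so the truth id set is unambiguous.
* **Coverage**: present genes get exonic bases covered ≥ 2 reads with
  probability P(Poisson(depth) ≥ 2) (≈ 1 at the 45× default). Absent
  genes attract mismapped reads on a small fraction of bases
  (`mismap_frac`, default 3%) at full local depth, putting their covered
  fraction just below the 5% presence threshold rather than at zero. A
  per-base Poisson background at 5% of a 45× depth would put two thirds
  of bases above 2 reads and make every absent gene look present — the
  patchy-pileup model is what makes the threshold meaningful. 10% of
  genes are dispensable with per-sample presence probability
  Uniform(0.1, 0.9).
* **LTR pairs**: each of two copies of a random seed sequence receives
  substitutions at per-site probability K/2 with a uniform choice among
  the other three bases, so expected pairwise divergence ≈ K for small K,
  consistent with the JC69 clock the dating step inverts. K > 0.75 is
  refused.
* **F2 phenotypes**: marker genotypes at the F2 ratios ¼:½:¼, balanced
  sexes, y = μ + s·sex + a·g + ε with a = √(v(s²/4 + σ²)/(½(1 − v))) so
  the marker explains fraction v (default 0.2761) of Var(y) in
  expectation.
* **Window haplotypes**: segregating sites with derived-allele counts
  ∝ 1/i (the neutral frequency spectrum), uniform positions.

What the generator deliberately does not emulate: linkage disequilibrium
and recombination (no coalescent), read-level errors, reference bias,
population structure within groups, TE nesting, indel evolution in LTRs.
Passing tests therefore demonstrate correctness of the statistics and the
pipeline's error control under its stated assumptions, not robustness to
those real-data complications; on real cohorts, LD in particular makes
neighbouring SV tests dependent, and the per-locus error control here
does not translate into locus-count guarantees.

## Problem sizes used in tests

The packaged checks run cohorts of 1000 SVs × 131 samples (20 null and 10
planted-power cohorts for the scan), 200 genes × 131 samples at 45× for
PAV, 200 null and 60 enriched TE landscapes on a 10 Mb genome, ~100
simulated 10 kb LTR pairs, and 20 F2 cohorts of n = 500 — sizes chosen so
each stochastic property is measured with comfortable margins while the
whole suite stays quick on a laptop.
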