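# pansvkit

Population-genetic analysis of structural variants (SVs) and gene
presence/absence variation (PAV) in multi-breed pan-genome cohorts. The
package is aimed at livestock and wildlife genomicists who have a
pan-genome-derived SV call set (VCF), TE annotations (BED), gene models
(GFF3) and per-exon coverage summaries, and want to answer the questions a
domestication study asks of them:

* Which genes are **core / softcore / shell / cloud** across individuals,
  and is the pan-genome closed? Presence is called per gene and sample
  when more than 5% of pooled exonic bases are covered by ≥ 2 reads;
  occupancy classes use presence frequency *f* (core *f* = 1, softcore
  0.99 < *f* < 1, shell 0.01 ≤ *f* ≤ 0.99, cloud *f* < 0.01); pan and
  core growth curves are fitted with *y* = *A·x^B* + *C* and
  *y* = *A·e^(Bx)* + *C*, whose asymptote *C* (when *B* < 0) estimates the
  total gene content.
* Which SVs changed frequency under **domestication** (wild → native) or
  **improvement** (native → commercial)? Each SV gets a two-sided
  Fisher's exact test on derived-allele counts and the Weir–Cockerham
  single-locus estimator θ̂ = a/(a+b+c); an SV is *selected* when the
  BH-adjusted q ≤ 0.001 **and** θ̂ reaches the contrast's 99th percentile,
  with increased/decreased direction labels. `delta_af()` ranks |ΔAF|
  between phenotype-defined groups inside a candidate region.
* Are SVs **co-located with transposable elements**? Per-SV TE coverage
  classes (> 0, ≥ 50%, and intact-TE-derived at reciprocal overlap
  > 95%), genome-wide 2/5/10 kb window occupancy χ² tests, genomic
  context (gene body / 5 kb upstream / intergenic) and nearest-gene
  annotation.
* How old are **LTR retrotransposon insertions**? The two LTRs of an
  element are aligned (global Needleman–Wunsch), divergence *K* is
  JC69-corrected, and the age is *T* = *K*/(2*r*) with
  *r* = 1.91 × 10⁻⁹ substitutions/site/year by default.
* Is there a **selective sweep** around a candidate locus, and how much
  phenotypic variance does a marker explain? Sliding-window π, Tajima's D
  and ratio-of-sums windowed F_ST (presets 20 kb/20 kb and 10 kb/5 kb),
  plus a single-marker GLM with sex as a fixed effect reporting marker
  R² = marker SS after all other terms / total SS.

Every stage is driven by standard formats (VCF 4.2, BED, GFF3, FASTA, TSV)
through a single I/O layer, and a fully seeded synthetic-cohort generator
(`simulate_cohort()`) produces ground-truth-bearing inputs for all of them,
so the whole pipeline is testable without sequencing data.

## Worked example

```r
library(pansvkit)

cfg <- simulation_config(seed = 42)   # 131 ducks: wild 20 / native 70 / commercial 41
co  <- simulate_cohort(cfg)
co$sv
#> sv_matrix: 1000 SVs x 131 samples (0.0% missing)

## PAV: call presence from exon coverage, classify, fit the pan curve
pav <- pav_call_matrix(co$coverage)
attr(classify_pav(pav), "counts")
#>     core softcore    shell    cloud
#>      189        0       11        0
tr  <- pan_core_trajectories(pav, n_orders = 100, seed = 1)
fit <- fit_growth_curve(tr[tr$kind == "pan", ], "power")
#> pan fit: y = -6.6 * x^-0.999 + 200.1  (closed: TRUE, asymptote 200 genes)

## Selection scan: Fisher q <= 0.001 intersected with top-1% F_ST
res <- scan_selection(maf_filter(co$sv), co$metadata, c("native", "commercial"))
res[res$selected, c("id", "af_a", "af_b", "q", "fst", "direction")]
#>       id      af_a af_b            q       fst direction
#>  SV00001 0.8642857    0 8.183036e-40 0.8328352 decreased

## LTR insertion dating: T = K/(2r)
date_ltr_pairs(co$ltr)
#>    element columns mismatches      p           K   T_years
#>  LTRelem01   10000         10 0.0010 0.001000667  261954.8
#>  LTRelem02   10000         39 0.0039 0.003910175 1023606.1
#>  LTRelem03   10000        201 0.0201 0.020374251 5333573.6

## Marker association with sex as a fixed effect
single_marker_glm(co$f2$phenotypes, "trait", co$f2$marker)$r2
#> [1] 0.3160  # true simulated variance fraction: 0.2761
```

The one selected SV is the planted near-fixed frequency shift (native AF
0.86 vs commercial 0; the generator's target triple is 0.05/0.89/0.012),
recovered with the correct `decreased` label during improvement. The LTR
ages are the three simulated divergences (K = 0.001/0.005/0.02) pushed
through alignment, JC69 correction and the molecular clock.

A thin command-line front end wraps the same functions:

```sh
CLI=$(Rscript -e 'cat(system.file("cli/pansvkit", package = "pansvkit"))')
Rscript $CLI simulate --seed 3 --outdir cohort
Rscript $CLI scan --vcf cohort/svs.vcf --groups cohort/groups.tsv \
        --contrast wild:native --out selection.tsv
Rscript $CLI date-ltr --fasta cohort/ltr_pairs.fasta --out ages.tsv
```

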