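# invgen

Population-genomic analyses of chromosomal inversion polymorphisms from
breakpoint-proximal sequence alignments.

Paracentric inversions suppress recombination in heterokaryotypes, so the
sequence just inside an inversion's breakpoints stays in linkage
disequilibrium with the arrangement and records its history. `invgen` is for
population geneticists who have aligned haplotypes of such regions (plus
sample metadata and annotations) and want to estimate:

- **how old** each inversion is — by rejection ABC under an
  exponential-growth coalescent, and by a divergence-based estimator;
- **where it arose** — African (ancestral) vs cosmopolitan (bottlenecked)
  origin, from divergence to reference panels;
- **how much genetic exchange** has occurred between arrangements — by
  detecting and masking tracts of shared polymorphisms on inverted
  haplotypes;
- **whether selection-related signals are present** — diversity and Hudson
  F\_ST scans, a breakpoint-vs-gene permutation test, and exact binomial
  tests for sex-ratio distortion in cross progeny;
- **whether a consensus sequence is trustworthy** — Poisson error bounds,
  Phred conversion, and a depth-titration bootstrap.

A first-class synthetic-data generator emulates the assumed data structure
(an inverted clade nested within a diverse African standard sample plus a
bottlenecked cosmopolitan sample, with exchange tracts, indels and missing
data) and emits ground-truth ledgers, so the whole pipeline is testable
end to end with no external data.

## The model in brief

The inverted class is treated as a population growing exponentially since
the inversion arose. With per-site divergence *d* to the sister species over
*t* generations, effective size *N<sub>e</sub>*, inversion frequency *f*,
and *L* aligned bases, the expected scaled mutation rate of the inverted
class is

> &theta;&#770; = 4 (N<sub>e</sub> f) &middot; (d / 2t) L = 2 N<sub>e</sub> f d L / t .

Rejection sampling draws &theta; ~ U(0, 10&theta;&#770;) and growth rate
&alpha; ~ U(0, 100), simulates coalescent samples (ms scaling: time in 4N<sub>0</sub>
units, per-pair rate 2e<sup>&alpha;t</sup>), and accepts draws whose
simulated S and &pi; are within 5% of the observed values (exact match for
zero-valued observations). Each accepted draw converts to years via

> age = T<sub>MRCA</sub> &middot; &theta; / &mu;<sub>region/year</sub> ,

because T<sub>MRCA</sub> is in 4N<sub>0</sub> generations and &theta; = 4N<sub>0</sub>&mu;.
Other core statistics: Hudson F\_ST = 1 &minus; H<sub>w</sub>/H<sub>b</sub>
with an unweighted H<sub>w</sub>; D&prime; = Tajima's D divided by |D| of
the all-singleton configuration; permutation p-values use the add-one rule
(1 + #{null &le; obs})/(B + 1); sex-ratio K = females/progeny with the exact
one-sided binomial tail.

## Worked example

Generate a synthetic breakpoint region with a known truth (age 5000 years,
African origin), mask exchange, and run the estimators:

```r
library(invgen)
set.seed(42)
cfg <- scenario_config(age_years = 5000, L = 20000, origin = "African")
g   <- generate_breakpoint_region(cfg)
aln <- g$alignment

masks <- detect_exchange_tracts(aln, "inv1")
res   <- apply_masks(aln, masks, inversion = "inv1")
aln   <- res$alignment          # recombinant haplotypes inv5, inv7 dropped

grp <- function(cond) intersect(aln$meta$sample_id[cond], rownames(aln$mat))
inv <- grp(aln$meta$inv1 == "inverted")
afr <- grp(aln$meta$inv1 == "standard" & aln$meta$population == "RG")
fr  <- grp(aln$meta$inv1 == "standard" & aln$meta$population == "FR")

s <- stats_suite(subset_alignment(aln, inv), "complete")
s
#> n=6 L=19394 S=4 pi_region=1.3333 pi_site=0.000069 theta_w=1.7518 D=-1.295 D'=-1.000 [complete deletion]

th   <- expected_theta(L = s$L, d = 0.06, f = 0.2)   # 15.52
post <- abc_rejection(s$S, s$pi_region, n = length(inv),
                      theta_prior_max = 10 * th, min_accept = 1000)
post
#> abc_posterior: 1151 accepted draws, acceptance rate 0.00767 (150000 attempts)
round(posterior_summary(ages_from_posterior(post, L = s$L, d = 0.06)))
#> median  lower  upper
#>   5626   2114  14174

classify_origin_breakpoint(aln, inv, fr, afr)
#> origin call: African (mean div cosmopolitan 0.00154, African 0.00345; nearest: afr16,afr18 [RG])
```

Reading the output: the six non-recombinant inverted haplotypes carry only
S = 4 segregating sites with a strongly negative D&prime; (all sites
singletons), the hallmark of a young, recently expanded arrangement. The
ABC posterior median age of ~5600 years brackets the planted truth of 5000
within its 95% credible interval, and the origin rule recovers the planted
African origin: the nearest standard neighbors are African and the inverted
class is about twice as divergent from the cosmopolitan panel as from the
African one.

The published In(1)Be distortion experiment is bundled as a constructor:

```r
cross_summary(inbe_crosses())
#>              role n_crosses mean_f1_males mean_progeny    mean_K
#> control       control     9      5.555556     535.6667 0.5107907
#> experimental experimental 11      6.272727     733.7273 0.5407211
sex_ratio_test(781, 670)   # the strongest single cross
#> $K 0.5382495  $p 0.001932557
```

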