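# solenoidal

Periodic pattern detection in sparse boolean sequences — sequences
`0100110…` in which the 1's ("sites": typically the transcription starts
of genes along a chromosome) are far rarer than the 0's. Groups of
co-regulated or co-functional genes have repeatedly been observed to
space themselves quasi-periodically along bacterial and yeast genomes,
but such gene sets are small, noisy and contaminated, which defeats
Fourier analysis of pair-distance histograms or autocorrelation
functions. This package implements the solenoidal coordinate method
(SCM): it is aimed at genome-organization analyses, but applies to any
sparse integer point pattern in which a hidden repeat distance is
suspected.

## The method

Wrap the support around a solenoid of candidate period `P` and project
onto its face view: a site at position `x` lands at the angle
`(x mod P)/P` on the unit circle. Sites of a `P`-periodic pattern align
and therefore *cluster* on the face view; unrelated sites stay uniform.
Clustering is scored through exact circular order statistics: for `N`
uniform sites, the normalized arc between two sites separated by `i`
intermediate sites has density

    rho_i^N(x) = (N-1) C(N-2, i) x^i (1-x)^(N-2-i),      x in [0, 1]

the Beta(i+1, N-1-i) law. Writing `F_{2j-1}^N` for its repartition
function with `i = 2j-1` (the j-th neighbors on each side of a site are
separated by `2j-1` sites) and

    p_j^N(x) = min( F_{2j-1}^N(x), 1 - F_{2j-1}^N(x) ),

the score at period `P` sums the self-information of the neighbor
spacings `x_{i,j}^P` around every site:

    S_scs(P) = - 1/(2 J N) * sum_{i=0}^{N-1} sum_{j=1}^{J} log p_j^N( x_{i,j}^P )

with `J = max(floor(N/16), 1)` neighbor orders. Small spacings (dense
clusters) and large ones (empty arcs) are both highly informative, so a
planted period produces a high score at `P` and its integer multiples.
Sweeping a period grid gives the solenoidal spectrum (SoS); calibrating
each score against `R` uniform-random site sets turns it into a p-valued
spectrum (pSoS, reported as `-log10 p`). A per-site positional score
`S_pos(i, P) = -log10 p_v(S'(i, P))` identifies which sites participate
in a given periodicity, where `S'` is the best information content over
site pairs straddling `i` on the face view.

## Worked example

A 5-site motif repeated every 10 kb over 80 kb (40 sites), distorted by
uniform positional jitter of amplitude 1 kb (10 % of the period), then
10 sites deleted and 10 random sites added:

```r
library(solenoidal)
motif <- c(3279, 4944, 6384, 7672, 8748)
train <- motif_train(motif, period = 10000, repeats = 8)   # 40 sites
noisy <- add_jitter(train, amplitude = 1000, seed = 7)
data  <- contaminate(noisy, n_delete = 10, n_add = 10, seed = 8)

sp <- solenoid_spectrum(data, periods = seq(2000, 40000, 10),
                        null_reps = 1000, seed = 9)
sp
#> Solenoidal spectrum: 3801 periods in [2000, 40000], N = 40 sites, J = 2
#>   null: R = 1000 replicates; p-value floor 0.001
#>   dominant period: 9980 (score 1.182, -log10 p = 2.10)
summary(sp)
#> Peaks with -log10 p >= 2: 1, in 1 harmonic group(s)
#> Fundamental periods by group significance:
#>   1: 9980
```

Despite 25 % contamination, 25 % missing sites and 10 % jitter, the only
significant harmonic group sits at 9980 — within 0.2 % of the planted
10 kb repeat. A pair-distance histogram + DFT on the same data shows no
usable peak there (`dft_of_histogram(pair_distance_histogram(data))`).
The positional scores then grade individual sites:

```r
ps <- positional_score(data, period = 10000, null_reps = 1000, seed = 10)
head(as.data.frame(ps), 3)
#>   site_index position period   S_prime       p_v     S_pos
#> 1          1     3768  10000 0.6819404 0.7092907 0.1491757
#> 2          2     4399  10000 1.0860428 0.5274725 0.2778001
#> 3          3     4842  10000 3.9303594 0.0569431 1.2445592
mean(ps$S_pos[data$positions %in% noisy$positions])    # surviving train sites
#> [1] 0.71
mean(ps$S_pos[!data$positions %in% noisy$positions])   # contaminating sites
#> [1] 0.43
```

`S_pos` is `-log10` of a p-value, so 0.71 vs 0.43 means the surviving
train sites are, on average, about twice as significant as the random
ones at this period; on noise-free data the contrast is maximal (train
sites saturate at `log10(R + 1)`). For two superposed trains,
`two_period_scatter()` separates the sites of each train (see the
vignette).

A thin command line covers the same pipeline:

```sh
Rscript inst/scripts/scm simulate --kind train --period 10000 --repeats 8 --jitter 1000 --seed 7 --out run/
Rscript inst/scripts/scm spectrum --in run/sites.txt --length 80000 --null-reps 1000 --seed 9 --out run/
Rscript inst/scripts/scm posscore --in run/sites.txt --length 80000 --period 10000 --out run/
Rscript inst/scripts/scm baseline --in run/sites.txt --length 80000 --method histogram --bin 50 --out run/
```

Inputs can be plain position lists, BED (0-based starts) or GFF3
(strand-aware transcription starts); every run writes TSV tables and a
JSON manifest recording configuration, seed and versions.

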