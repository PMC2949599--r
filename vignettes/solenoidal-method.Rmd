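---
title: "The solenoidal coordinate method: model, calibration and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The solenoidal coordinate method: model, calibration and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistics it
implements: the model behind the spectrum and positional scores, the
parameters that matter, what the synthetic generators do and do not
emulate, and the numerical and design choices made where more than one
reasonable option existed.

## The model

The data are a sparse boolean sequence on a support of length $L$:
$N$ integer *sites* (gene transcription starts, binding sites, any
point pattern) with $N \ll L$. The question is whether some subset of
the sites recurs with a hidden repeat distance $P$, despite positional
noise, missing sites and contaminating sites.

Folding the support modulo a candidate period maps site $x$ to the
angle $\theta = (x \bmod P)/P$ on the unit circle (the face view of a
$P$-periodic solenoid). A $P$-periodic subset collapses into tight
angular clusters; everything else stays spread out. Two properties make
this projection a robust detector:

* clustering survives jitter of amplitude small relative to $P$,
  missing sites, and added uniform sites — none of these move the
  surviving cluster centers;
* under the null of uniform site positions, the angles are uniform on
  the circle *for every* $P$, so a single null distribution calibrates
  the whole period sweep.

### Scoring clustering with exact spacing laws

For $N$ i.i.d. uniform points on the circle, the normalized arc between
two points separated by $i$ intermediate points is exactly
$\mathrm{Beta}(i+1,\,N-1-i)$ — the package's `spacing_law()`, with
density $(N-1)\binom{N-2}{i}x^i(1-x)^{N-2-i}$. The $j$-th nearest
neighbors on each side of a site are separated by $2j-1$ sites, so the
two-sided tail probability of their arc $x$ is approximated by
$p_j^N(x) = \min\!\big(F_{2j-1}^N(x),\, 1-F_{2j-1}^N(x)\big)$, exact in
both tails and at most $1/2$ at the median; the cusp at mid-range
distances is irrelevant because mid-range spacings carry almost no
information either way. The spectrum score averages the information
content over all sites and the first $J$ neighbor orders:

$$S_{scs}(P) = -\frac{1}{2JN}\sum_{i=0}^{N-1}\sum_{j=1}^{J}
  \log p_j^N\!\big(x_{i,j}^P\big).$$

The natural logarithm is used; only the ordering of scores across
periods matters, and the null calibration below is invariant to the
base. Both tails contribute by construction: tight clusters give small
$F$, the empty arcs that must accompany them give small $1-F$.

### Null calibration

At each period the score is referred to a Monte-Carlo ensemble of $R$
uniform configurations of the same $N$ and $J$ (`null_ensemble()`), and
the p-value is the add-one exceedance estimate
$(1 + \#\{\text{null} \ge \text{obs}\})/(R+1) \ge 1/(R+1)$. Because the
continuous-circle null is period-free, one ensemble serves the entire
grid; a discrete-lattice variant (integers modulo $P$) is available for
exactness studies and is statistically indistinguishable at these sizes
(the reduction of uniform integers modulo $P$ is uniform up to $O(P/L)$
edge effects). The p-valued spectrum is reported as $-\log_{10} p$.
With several spectrum peaks judged jointly, the family-wise probability
that the best of $N_p$ independent peaks reaches $p^\*$ is
$1-(1-p^\*)^{N_p}$ (`family_correction()`); the package takes $N_p$
from the number of harmonic groups found, overridable — peak
independence is an approximation the user can reject.

### Positional scores

The per-site statistic $S'(i,P)$ is the largest information content
$-\log p_<$ over pairs made of one of the $J$ nearest neighbors on each
side of $i$ (so $i$ is strictly inside the pair's arc), where $p_<$ is
the lower tail of the spacing law for a pair spanning $g$ gaps,
$\mathrm{Beta}(g,\,N-g)$. The Monte-Carlo p-value $p_v(S')$ redraws
whole uniform configurations and records the statistic of one site
drawn *uniformly at random* per replicate (exchangeability makes any
site representative, but the site must not be chosen by a rank rule:
the site adjacent to a fixed origin is size-biased, because the arc
containing the origin is stochastically larger — a bias we measured
before fixing the sampling). $S_{pos} = -\log_{10} p_v$ is bounded by
$\log_{10}(R+1)$.

The two-period diagnostic plots $10^{-S_{pos}(P_1)}$ against
$10^{-S_{pos}(P_2)}$ per site; in a superposition of two trains, each
train hugs its own axis. A site is assigned to $P_1$ when its $P_1$
p-value is smaller; exact ties (both saturated) fall back to the larger
raw $S'$, remaining ties to $P_2$.

## Tunable parameters

| parameter | default | meaning and rationale |
|---|---|---|
| `J` | `max(floor(N/16), 1)`, capped so $2J-1 \le N-2$ | neighbor depth; must grow with $N$ to feel dense regions, while cost grows as $NJ$ per period. Detection is insensitive to the precise rule. Scoring needs $N \ge 3$. |
| `periods` | integers, step such that the grid has ~4000 points, up to $\min(L/2, 40000)$ | the congruence is meaningless beyond $L/2$ (fewer than two turns); the step should resolve the peak width, roughly $P^2/L$. |
| `null_reps` (R) | 1000 | p-value floor $1/(R+1) \approx 10^{-3}$; raise it to resolve smaller p-values. Below 100 the resolution is too coarse (warned). |
| `eps` | $10^{-300}$ | floor on every spacing p-value so coincident sites (distance 0 modulo $P$) give finite information. |
| `resolution` | 1 position | half-lattice floor for the secondary score (below). |
| `tol` | 0.02 | relative tolerance for harmonic matching in `find_peaks()`. |
| jitter `amplitude` | — | *full width* of the uniform displacement law: "amplitude 10 % of $P$" means displacements in $\pm 0.05\,P$. A half-width reading is available (`half_width = TRUE`); the full-width reading is the package convention. |

## Numerical choices

**Tail precision.** Upper tails are computed as
`pbeta(..., lower.tail = FALSE)`, never as `1 - pbeta(...)`: for a site
set collapsed into a tight cluster the complementary arcs are close to
1 and the subtraction underflows to 0, which the epsilon floor would
then misread as astronomically significant (we observed spurious
per-term information of $-\log \epsilon \approx 690$ instead of the true
~60 before making this choice).

**Integer positions and the coincidence degeneracy.** Positions live on
a lattice, and noise-free integer patterns produce *exactly* coincident
angles. Under the continuous spacing laws a coincidence carries
infinite information, capped only by `eps` — with a drastic
consequence: a comb of spacing $D$ projects to a single point at $D$
*and at every divisor of $D$*, with bitwise-identical capped scores, and
a motif train repeated at $D$ forms equally perfect clusters at $D/2$,
$D/3$, ... The fundamental is then statistically indistinguishable from
its divisors within the continuous model. The information that breaks
the tie is the discreteness of the support: under a uniform law on
$\{1,\dots,P\}$ a coincidence has probability of order $1/P$ per gap,
so it is *more* surprising at larger periods. The package therefore
carries a second score per period, identical except that normalized
spacings are floored at $\mathrm{resolution}/(2P)$ — half a lattice
unit, the continuity correction of the discrete law. The defining score
is used for p-values (the continuous null matches it); the
lattice-corrected score is used where saturated peaks must be ranked,
and demotes divisor foldings by $\approx 2j\log k$ per floored term at
divisor $D/k$.

**Degenerate comb families.** When peaks reach the maximal attainable
capped score (all sites on one point), they are collected into a single
harmonic family whose fundamental is the *largest* tied period: each
smaller tied period is an exact refolding of it. The same reasoning
fixes the global-maximum tie-break in `dominant_period()`: among
exactly tied periods the largest is the generator of the tie set.
(Integer multiples are never part of such ties — folding a comb at
$2D$ yields two antipodal clusters and a strictly different score — so
the tie set consists of the spacing and its divisors.) For a pure
noise-free comb the ranking between $D$ and $2D$ under the discrete
correction is intrinsically marginal (both are perfectly clustered
configurations; their corrected scores differ by a few percent), which
is why the degenerate-family rule, not the corrected score, decides
that case.

**Fundamental of a harmonic group.** Peaks are strict local maxima of
the score, thresholded on $-\log_{10}p$, processed in decreasing
significance, and grouped by the integer-ratio rule
$|Q/(kP)-1| \le$ `tol`. Within a group the fundamental is the most
significant member at harmonic order one: under jitter a peak can split
into near-duplicate local maxima a grid step or two apart, and taking
the smallest member would bias the recovered period downward by up to
`tol`.

**Coincident sites in $S'$.** The clockwise order among exactly
coincident sites is arbitrary, so any per-site statistic must be
invariant to it: all members of a zero-width cluster receive the
cluster's maximal $S'$. Without this, the two outermost members (in the
arbitrary sort order) of a coincident cluster lose their zero-arc pair
and can be misclassified in the two-period diagnostic.

**Index conventions.** The correspondence "pair spanning $g$ gaps
$\sim \mathrm{Beta}(g, N-g)$" (and hence "$j$-th neighbors on each side
$\sim \mathrm{Beta}(2j, N-2j)$") is pinned by direct sampling
experiments in the test suite, with the reference site drawn uniformly
on the circle — see the positional-score note above for why the
reference must not be anchored at a sorted rank.

## Synthetic scenarios: what they emulate, and what they do not

The generators produce the study conditions used throughout the tests:
Dirac combs (`dirac_comb`), complex aperiodic motifs repeated at a
fixed distance (`motif_train`), uniform positional jitter
(`add_jitter`, full-width convention), contamination by deletion and
uniform insertion (`contaminate`), and superpositions of two trains
with labels retained (`mixture`). The benchmark settings are: repeat
distance 10000 on supports of 80–200 kb, 5-site motifs with 8 repeats
(40 sites), 10 % jitter, 10-of-40 deletion plus 10 insertions, and a
7270 + 10000 two-train mixture truncated at position 80000 (~57 sites,
three offsets per motif); spectra use the integer grid 2000–40000 in
steps of 10 with 1000-replicate nulls. These sizes keep a full spectrum
under a second and the complete benchmark suite within minutes on one
CPU.

**The aperiodicity screen.** "A complex aperiodic motif" is a real
condition, not a formality, and `is_aperiodic_motif()` makes it
explicit. Each clause corresponds to a failure mode we measured while
validating the generators:

* *repeated internal spacings* (two pairwise offset differences equal
  within 1 % of $P$) make two site pairs co-align when folding at a
  submultiple; near-evenly spaced offsets are the extreme case — the
  motif is itself a comb at $\approx P/n$ and the sweep rightly finds
  that period;
* *concentration modulo a submultiple* $P/k$, $k \le 5$ (pairwise
  separation below 4–5 %, or an empty arc above 65 % of the
  subcircle) hands genuine clustering to the subharmonic;
* *offsets closer than 10 % of $P$* merge under jitter of that
  amplitude.

`draw_motif_offsets()` rejection-samples until the screen passes.
Under these conditions the jittered-train benchmark recovers the
planted period as the modal fundamental across replicates for every
motif draw we tested; without them, particular draws reproducibly hand
the mode to $P/2$ or $P/5$.

**What passing these benchmarks does not show.** Real gene sets are not
stationary trains: repeat distances drift along the chromosome, site
density varies, supports are sometimes circular (a flag `read_sites()`
deliberately does not fold automatically), and contamination is not
uniform. The benchmarks establish sensitivity and calibration under the
stated noise models, nothing more. Two further caveats are inherent to
exact-lattice constructions. First, divisor foldings of a noise-free
integer train are *genuinely* perfect clusterings — reporting them as
secondary harmonic groups is correct, and only the discreteness
correction ranks the generator first. Second, low-order rational
resonances persist: in the two-train mixture, $6 \times 7270$ misses
$5 \times 8700$ by only 120 positions, so even at the "unrelated"
period 8700 every sixth site of the 7270-train nearly aligns, and a
sensitive enough test detects a few-percent association in the
two-period diagnostic there. The package's tests therefore require the
off-period classification to sit in the chance band (excess association
within $\pm 0.1$ against the label-permutation expectation) rather than
to vanish exactly.

## Baselines

The two classical comparisons are included with the conventions used in
this field: the histogram of all $N(N-1)/2$ pairwise distances (default
bin 50) read through a zero-padded, mean-subtracted DFT magnitude
spectrum; and the finite-length autocorrelation
$C(x) \propto \frac{1}{L-x}\sum_i \tilde X(i)\tilde X(i+x)$, normalized
to $C(0)=1$, of the square-window-smoothed sequence (default window
1000; Gaussian available), also read through a DFT. Both transforms
spread a periodic pattern's energy over near-equal frequency harmonics,
so the raw magnitude argmax is an unstable period reader;
`spectral_fundamental()` formalizes the usual visual reading (largest
period whose magnitude reaches half the range maximum, refined to the
magnitude peak of that region). On a pure comb all three methods agree
on the fundamental; on complex motifs and mixtures the baselines peak
at the internal spacing scale or show nothing at the true periods,
which is the methodological point of the spectrum.

## Limitations

* Cost per period is $O(NJ)$ after an $O(N\log N)$ sort, and the sweep
  multiplies by the grid size; with $J \sim N/16$ a spectrum scales as
  $N^2$. The method targets small $N$ (tens to a few hundred sites);
  for dense sequences a divergence-based density comparison on the face
  view would scale better but is unreliable at exactly the small $N$
  this package targets, and is not implemented.
* The p-value floor $1/(R+1)$ saturates strong peaks; ranking within
  saturated peaks relies on the scores, as described.
* Harmonic grouping assumes peaks at integer multiples within 2 %;
  patterns whose repeats drift by more than that across the support
  blur into wider, lower peaks.
* $N_p$ for the family-wise correction counts harmonic groups; peak
  independence across a finely-stepped grid is approximate at best.
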