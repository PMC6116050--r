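---
title: "Modelling replication dynamics of multi-origin E. coli chromosomes"
author: "forktrap developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling replication dynamics of multi-origin E. coli chromosomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forktrap)
```

## The problem

The *E. coli* chromosome is a 4.64 Mb circle that is normally duplicated by
two replication forks launched from the single origin *oriC*: one travels
clockwise (increasing coordinate, in the convention used throughout this
package), the other counter-clockwise, and they meet in a terminus region
bounded by ten polar *ter* sites (A–J) bound by the Tus protein. Each
*ter*/Tus complex lets a fork pass in one direction and arrests it in the
other, so forks can enter the terminus but not leave — the replication fork
trap.

Strains carrying an additional, ectopic copy of *oriC* (called *oriX*,
*oriY* or *oriZ*, integrated at 59, 76.5 and 7.4 min of the genetic map)
redistribute fork traffic. A fork from an ectopic origin reaches the trap
early and stalls at the first blocking *ter* site; forks travelling a
replichore "the wrong way" collide head-on with heavily transcribed rRNA
operons; and suppressor rearrangements — large inversions between
homologous IS5 elements, tandem duplications — appear spontaneously and
reshape the problem. All of this is visible in **marker frequency analysis
(MFA)**: sequencing an exponentially growing culture and reading relative
locus copy number from binned read depth, normalised against a
stationary-phase (non-replicating) control.

forktrap implements the full computational path: a replication-dynamics
model that predicts MFA profiles for arbitrary origin/trap configurations,
the profile-processing pipeline (normalisation, circular LOESS, feature
calls), rearrangement operators with continuity scoring, mixture
deconvolution of origin usage, and a synthetic-data generator that makes
every analysis reproducible offline.

## The replication model

For one *cell class* — a set of origins that fire simultaneously at $t = 0$
plus a trap status — `replication_schedule()` computes the first-arrival
time $t(x)$ of a replication fork at every bin midpoint $x$:

* every active origin launches one clockwise and one counter-clockwise fork
  moving at constant speed $v$ (default 1000 nt/s; published estimates are
  650–1000 nt/s);
* inside a highly transcribed feature traversed against its direction of
  transcription the speed becomes $v \cdot h$ with the head-on factor
  $h \in (0, 1]$ (default 1; an *rpo\**-like allele corresponds to pushing
  $h$ back towards 1; overlapping features slow a fork once, not twice);
* a fork reaching a *ter* site whose polarity matches its travel direction
  halts there and waits (a hard stop — deliberately the simplest treatment)
  until the converging fork arrives;
* a bin belongs to whichever fork arrives first; converging forks fuse
  where their arrival times meet, with simultaneous arrivals resolved to
  the clockwise fork so outputs are deterministic.

The analytic schedule is validated bin-for-bin against an independent
discrete-event simulation (`simulate_schedule_events()`), which moves forks
in small time steps, claims bin midpoints at exact crossing times, and
resolves blocking/fusion event-by-event. On randomised chromosomes the two
agree to within twice the simulation step; the event route alone honours a
stochastic `ter_leakage` probability, which the deterministic analytic route
refuses (it would not be a well-defined single schedule).

### From schedule to marker frequency

In a steady-state exponential population in which each class initiates
replication every $\tau$ minutes, the expected relative copy number of a
locus replicated at time $t$ after initiation is

$$f(x) = 2^{-t(x)/\tau},$$

normalised to 1 at active origins. This is the classical
exponential-age-distribution argument: origin:terminus ratios exceed 2
(overlapping rounds) whenever the last locus replicates later than $\tau$.
The study this package models defers its exact model parameterisation to an
appendix that is not reproduced in the main text; $2^{-t/\tau}$ is the
standard minimal form consistent with the stated "periodicity of origin
firing", and is documented here as the package's own choice. Whether the
original work used different $\tau$ values per cell class is unknown; we use
one $\tau$ (default 25 min) for all classes, and `fit_mixture(fit_tau =
TRUE)` can profile it over a grid (default 15–40 min).

Observed cultures are mixtures: `mixture_profile()` forms
$\sum_i w_i f_i(x)$ over cell classes with non-negative weights summing
to 1.

## The MG1655 fixture

`mg1655_map()` encodes the 4,641,652 bp reference chromosome with *oriC*,
the three ectopic origins at their genetic-map positions, *ter* A–J, the
seven rrn operons (A–E, G, H) plus the ribosomal-protein gene cluster
(GRP), and the three IS5 elements at 575, 1394 and 2288 kb. Exact
coordinates for *oriC*, *ter* and rrn are not part of the modelled study;
they come from the MG1655 reference annotation and the fork-trap
literature, and every test that depends on them carries a ±5 kb tolerance.

The *ter* polarities split 5/5: A, D, E, H, I (left replichore flank) block
counter-clockwise forks; C, B, F, G, J (right flank) block clockwise forks,
with the innermost pair terA/terC facing each other. This assignment is
forced by the modelled strains themselves: the 575–1394 kb inversion spans
*all* restrictive sites for a ΔoriC oriX⁺ chromosome and these are exactly
terA/D/E/H/I; the oriZ counter-clockwise fork must run ~500 kb to its
fusion point unimpeded; and the 1394–2288 kb inversion flips terC/B into
the path of the oriX fork, arresting it after ~650 kb. The coordinate of
terJ (placed at 2,520 kb, outermost right flank) is the least certain of
the ten; nothing downstream depends on it beyond its flank membership.

## The MFA pipeline

`normalize_counts()` forms the per-bin ratio of read proportions
(sample/control), masks bins whose control count is below a floor (default
10 — the paper states no floor; the value bounds ratio variance), and
rescales to mean 1.

`circular_loess()` is the paper's stated smoother: a local weighted
quadratic with tricube weights over the nearest 10% of bins (≈460 kbp on
the full chromosome) with periodic boundary conditions and no robustness
iterations (none are specified). Masked bins are excluded from every local
fit but still receive smoothed values. Because clean windows share one set
of regression weights the smoother is a circular convolution almost
everywhere (an exact algebraic shortcut, not an approximation); windows
touching masked bins fall back to explicit weighted least squares. Both
routes are tested to 1e-9 against a brute-force per-point regression.

The column-purification artifact — depleted coverage where tight
protein–DNA complexes (rrn operons, *ter*/Tus) survive proteolysis — is
handled by *masking* the annotated loci (±2 kb), not by correcting them
(`artifact_mask()`). Masking matters in two places with opposite signs:
smoothed origin peak heights are biased low near depleted loci if the bins
stay in (this is exactly how the artifact depresses the *oriX* peak next to
*rrnG*), while step *detection* benefits from the robustness of flanking
medians but is hurt by mask holes sitting exactly on the *ter* positions.
`process_counts()` masks by default.

### Feature calling

`find_extrema()` reports the global minimum and all local maxima above a
topographic-prominence threshold (default 2% of the dynamic range). Note
that a 460 kb smoothing window shifts the apex of an asymmetric peak by a
few tens of kb; position tests allow for this.

`detect_steps()` scans every circular bin boundary for a difference between
flanking 50 kb window medians. Two numerical choices matter and are this
package's own: the statistic is **trend-corrected** with a second pair of
outer windows (a smooth copy-number gradient otherwise produces
flank-median differences of the same size as the default threshold), and
the threshold is the larger of the stated default (10% of the profile IQR)
and a **noise floor** of 3.5 standard deviations of the statistic itself,
estimated from the profile's high-frequency residual — reporting jumps
smaller than their own sampling noise would be meaningless at typical
sequencing depth. Candidate runs are refined by a least-absolute-deviation
two-segment split; breakpoints within 5 kb of an annotated *ter* site are
labelled as trap steps (clean model profiles localise to one bin, but at
100 reads/bin the estimator jitters by a few bins, and the artifact mask
hole around each *ter* adds to that), everything else is reported as a free
discontinuity — a rearrangement candidate.

`origin_activity()` reads the smoothed value at each origin, scaled to the
strongest origin; with the artifact masked, equal-firing double origins
score within 2% of each other.

## Rearrangements and continuity

`apply_rearrangement()` implements inversions (features reflected,
polarities flipped: a *ter* site that blocked counter-clockwise forks
blocks clockwise forks afterwards) and tandem duplications (map grows by
(copies−1)×segment). `project_profile()` models what read mapping does to
data from a rearranged chromosome: inverted segments map back onto the
reference reversed in place (an involution), duplicated copies pile their
reads onto the single reference locus (values summed).

`continuity_score()` quantifies the study's visual argument that the
correct inversion "heals" a discontinuous profile: at each breakpoint, the
squared difference of flanking 50 kb window medians scaled by the local
median-detrended variance. `evaluate_candidate()` applies a candidate's
projection and reports the score before and after; the true rearrangement
drives the ratio below 0.1 while wrong candidates leave it above the noise
floor. Candidate enumeration defaults to pairs of annotated IS elements —
both inversions recovered in the study arose between homologous IS5 copies
— which also pins breakpoints to their exact positions rather than to the
few-bin precision of free step detection.

## Mixture deconvolution

`fit_mixture()` solves a non-negative least-squares problem (Lawson–Hanson
active set, written here because no NNLS solver is otherwise available, and
verified against exhaustive support-set enumeration) expressing the
observed mean-scaled profile in a basis of class model profiles smoothed
with the same LOESS settings — smoothing is linear, so fitting smoothed
against smoothed leaves weights unbiased. Because a class whose cells
replicate more holds more DNA, the NNLS weights are DNA shares; dividing by
each class's mean copy number and renormalising converts them to cell
fractions, which is what the study's "active in 50% / 40% of cells" figures
mean. Identical basis columns raise a non-identifiability flag rather than
returning silently. The remaining 10% of the stated 50/40 split is assigned
to the all-three-origins class by the generator; the study does not say
what the remainder is, and this choice is recorded as ours.

## Synthetic data: what it emulates and what it does not

`generate_scenario()` produces bundles (sample counts, stationary control,
truth record) for seven named configurations, at the study's stated
conditions: 1 kb bins over the full chromosome, v = 1000 nt/s, τ = 25 min,
Poisson noise at 100 reads/bin (~0.46 M reads/genome — deep enough for
±0.05 weight recovery while staying desk-scale), the depletion artifact at
0.5× over rrn/ter ±2 kb (the real magnitude is not quantified; 0.5 is a
documented placeholder), and rearranged-genome reads projected onto
reference coordinates. Negative-binomial noise is available for
overdispersion studies. One master seed fans out to per-stage substreams.

Two scenario-level notes. `doriC_oriX_inv820` reproduces the study's
reasoning directly: with the five restrictive *ter* sites flipped the trap
never engages and the forks fuse near the *oriX* antipode (~418 kb).
`doriC_oriX_rpo_inv895` arrests the counter-clockwise *oriX* fork at the
flipped terC after ~665 kb, leaving ~4 Mb to the clockwise fork.

The generator does **not** emulate: GC or mappability bias, read-level
error, per-cell initiation asynchrony, replication restart or
over-replication pathways, or cell-cycle (D-period) structure. A green
end-to-end test therefore establishes that the pipeline inverts the
generator's statistical model — including its trap steps, projection
discontinuities and depletion artifact — not that it is robust to every
bias of real libraries.

One quantitative caveat established by the tests themselves: at 100
reads/bin the LOESS minimum of a trap-free double-origin profile — which is
nearly flat, changing by ~1% over ±50 kb — localises to only ±50 kb for a
single dataset; the median across seeds sits within 20 kb of the arithmetic
midpoint, and the noise-free model profile localises to ~1 kb. The study's
0.991 vs 1.010 Mbp comparison was made at substantially higher depth.

## Numerical choices, degenerate inputs, limitations

* Coordinates are 0-based bp, intervals half-open, clockwise = increasing;
  the genetic-map conversion is linear (1 min = L/100).
* `arc_midpoint()` floors half-bp midpoints so rotation equivariance is
  exact; ties in fork arrival go to the clockwise fork.
* Rearrangement segments may not wrap coordinate 0 and breakpoints may not
  bisect an annotated feature (both are errors, not silent adjustments);
  profile projection requires bin-aligned breakpoints.
* A chromosome whose trap configuration leaves bins unreachable (possible
  on randomised maps, and a real possibility under the hard-stop
  idealisation) is an assertion failure in both schedule routes, never a
  silent partial result.
* Duplicated origins are permitted but flagged; duplicated feature names
  get `.2`, `.3`… suffixes to keep names unique.
* The hard-stop trap has no arrest reversibility; *ter* leakage exists only
  in the event simulator. Fork speed is constant per class apart from the
  head-on factor; no stochastic per-fork speed variation.
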