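---
title: "Polymer-physics analysis of multi-viewpoint 4C-seq data with poly4C"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Polymer-physics analysis of multi-viewpoint 4C-seq data with poly4C}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A 4C-seq experiment anchors one restriction fragment (the *viewpoint*) and
sequences its ligation partners genome-wide, yielding per-fragment capture
counts that estimate, up to severe technical biases, the probability that
the viewpoint contacts each other fragment of its chromosome. When the
genome itself is rearranged — here the motivating design is a heterozygous
multi-megabase deletion — contact changes of purely *physical* origin
(two formerly distant regions are now adjacent on the polymer, so entropy
alone makes them touch more often) must be separated from changes of
*biological* origin (gained or lost specific interactions, altered
compaction). poly4C implements a four-phase analysis that performs this
separation by treating chromatin explicitly as a polymer.

## The null model

Chromatin is modelled as a bead-on-string chain: bead positions
$x_1,\dots,x_N$ with joint density

$$
P(\{x_i\}) \;=\; \prod_{i=1}^{N-1}
\left(\frac{k_{i,i+1}}{2\pi}\right)^{3/2}
\exp\!\left[-\tfrac{1}{2}\,k_{i,i+1}\,(x_i - x_{i+1})^2\right],
$$

so successive displacements are independent 3D Gaussians with per-axis
variance $1/k_{i,i+1}$. Spring constants follow the local scaling law
$k_{i,i+1} \sim s_{i,i+1}^{\,2\nu/3}$ in the genomic segment length $s$;
contact probability then falls off as $P(s) \sim s^{\nu}$. The ideal
(random-walk) chain has $\nu = -3/2$; Hi-C-style compact chromatin is
closer to $\nu = -1$. More negative $\nu$ means less compact chromatin.

One modelling point deserves emphasis, because it shapes the simulator. A
chain of *independent* Gaussian springs has additive variance, so whatever
the local $k$ values, the separation variance between beads grows linearly
in the number of segments and the contact decay is always $s^{-3/2}$.
Exponents $\nu \ne -3/2$ therefore exist only in the model's *pairwise*
sense: the separation of two loci at genomic distance $s$ is taken 3D
Gaussian with per-axis variance $v(s) \propto s^{-2\nu/3}$. This is
exactly the form used to fit FISH distances and to define the null contact
probability, and it is what `theoretical_contact_profile()` implements
(anchored so that it coincides with the sampled chain at $\nu = -3/2$).
Monte-Carlo chain sampling (`sample_chain()`, `contact_probabilities()`)
is used where the strict chain is the right object: the ideal-chain
exponent check and the entropic effect of a deletion.

## Phase 1 — bias correction

Counts are first normalized by (viewpoint length × fragment length),
giving the biased contact probability (BCP) $F$: a longer fragment ligates
in proportion to its length, and that much is correctable without any
modelling. The remaining biases are modelled multiplicatively between
viewpoints,

$$F_{IJ} = C_I\, C_J\, K_I\, P_{IJ},$$

with $C$ a property of the viewpoint sequence, $K$ of the individual
capture experiment, and $P_{IJ}$ the true, necessarily *symmetric*,
contact probability. $F_{IJ}$ is read off viewpoint $I$'s smoothing-spline
fit of $\log F$ against $\log s$ evaluated at the pair separation
$s_{IJ}$ — deliberately not off the raw captures at viewpoint $J$'s own
fragments, which may be dominated by specific interactions.

The solver works in log space on nearest and next-nearest viewpoint pairs
(pairs $(I,I{+}1)$ and $(I,I{+}2)$ in chromosomal order):

* the antisymmetric part $\log F_{IJ} - \log F_{JI} = \log K_I - \log K_J$
  determines $K$ by ordinary least squares, up to gauge;
* the symmetrized sums, jointly with a two-parameter power-law model for
  $P$ over the selected pairs, determine $C$;
* the corrected symmetric $P_{IJ}$ is then implied for **all** pairs, not
  only the fitted ones.

Gauge convention: the geometric means of $C$ and of $K$ are 1; the scale
sits in $P$. Natural logarithms are used throughout. Residuals of both
least-squares systems are reported on the `bias_factors` object for
diagnostics.

**Identifiability.** With $n$ viewpoints there are $n(n-1)$ observable
$F_{IJ}$ against $2n$ bias parameters, so $n \ge 4$ is required and the
solver refuses fewer. A second, subtler limit: when $F_{IJ}$ comes from
the smoothed decay of experiment $I$, the other viewpoint's
fragment-level factor $C_J$ is averaged away, and the profile amplitude
carries only the product $C_I K_I$. The solver then attributes the
asymmetry to $K$ and returns $C$ near the gauge value — but the product
$C_I K_I$, which is the only combination entering the Phase 2 correction
$P_{I\alpha} = F_{I\alpha}/(C_I K_I)$, is recovered essentially exactly
(log-correlation with truth > 0.999 on synthetic studies). On a directly
observed pair matrix (counts at viewpoint fragments), $C$ and $K$ separate
exactly.

## Phase 2 — contact probability profiles

Raw counts are thresholded (counts $\le 5$ per fragment are zeroed, to
suppress Poisson noise in sparsely captured fragments) and then a
pseudo-count of 1 is added to every fragment, in that order, so the floor
value is exactly the pseudo-count and missing data cannot masquerade as
signal. The CPP is $P_{I\alpha} = F_{I\alpha}/(C_I K_I)$, and is smoothed
by Nadaraya–Watson kernel regression over fragment midpoints with a
Gaussian kernel of standard deviation $\sigma = 20$ kb truncated at a
total filter size of 80 kb ($\pm 2\sigma$). Working on the irregular
midpoints (each fragment one observation, unweighted — length bias was
already removed in the BCP) avoids aliasing from variable fragment sizes.
The default output grid step equals $\sigma$: the smoothing scale *is* the
genomic resolution of the measurement. Grid points with no fragment in the
window are missing, not zero.

## Phase 3 — differential interacting regions

The differential relative contact probability between a test (deletion)
and reference (wild-type) profile is

$$\mathrm{DRCP} = \frac{\log P_{\mathrm{test}} - \log P_{\mathrm{ref}}}
{|\log P_{\mathrm{ref}}|},$$

with the absolute value in the denominator so that positive DRCP means
increased contact in the test condition (the raw log of a probability
below 1 is negative, which would flip the sign). Before comparison the
test profile is rescaled by one common factor to match the reference mean
over shared covered grid points. We deliberately do **not** rescale each
profile to unit mean: that would place smoothed values near 1, where the
DRCP denominator $|\log P_{\mathrm{ref}}|$ crosses zero and the signal
diverges. Keeping CPPs on their natural count-per-bp² derived scale keeps
$\log P$ strongly negative everywhere and the DRCP well defined.

Candidate regions need $|\mathrm{DRCP}| \ge 5\%$ with consistent sign in
*both* biological replicates (a same-sign exceedance within one window
size in the other replicate counts as support). Each candidate is then
tested by a two-sided Mann–Whitney U test on the *raw* per-fragment CPPs
inside an 80-kb window (the filter size), independently per replicate,
at $\alpha = 0.05$ per replicate. Fragments carrying only the pseudo-count
are excluded from the ranks: they have zero within-condition variance, so
any residual correction-constant offset between experiments would
rank-separate them completely and manufacture significance out of missing
data — the precise artefact the pseudo-count exists to prevent. Windows
with fewer than 3 informative fragments on either side are untestable and
never called. Significant windows of the same sign are merged into maximal
intervals; the minimum reportable span is one 80-kb window. Grid points
inside a declared deletion are excluded from calling, and for deletion
chromosomes all separations (decay fits included) are computed in deleted
coordinates, which is what encodes the entropic null: contacts across the
deletion are compared against the probability expected at their *new*,
shorter separation, so purely physical gains are not called.

No multiple-testing correction is applied; the two-replicate intersection
is the guard (per-window false-positive rate $\approx \alpha^2$ by
independence, verified by simulation in the test suite).

A sensitivity consequence worth knowing: since
$\mathrm{DRCP} = \log(\text{fold})/|\log P_{\mathrm{ref}}|$ and
$|\log P_{\mathrm{ref}}|$ grows with separation, a 2-fold interaction
change crosses the 5 % threshold only out to roughly 2 Mb separation at
typical sequencing depth. The synthetic study's standard injected spike
(2-fold over a 300-kb block) is therefore placed 0.65–0.95 Mb from its
viewpoint, inside the regime the method is designed to detect.

## Phase 4 — local compaction

A smoothing spline of $\log P$ against $\log s$ is fitted per viewpoint
over the separations 10 kb–10 Mb (outside this range the scaling form
breaks down: measurement resolution below, contact starvation and
confinement above), and its analytic derivative at 100 kb is the local
compaction exponent $\nu_I$. The smoothing parameter is chosen by
generalized cross-validation with a floor of 4 effective degrees of
freedom. Replicate spread gives a standard error;
`compare_compaction()` flags $|\Delta\nu| > 1.96\,\mathrm{SE}$ (the
replicate-spread rule is this package's choice; with two replicates
per side it is indicative, not a calibrated test).

## FISH cross-validation

The same pairwise model predicts the distance distribution of two probes
tethered by an effective spring $k_{IJ}$:

$$P(r)\,dr = 4\pi r^2 \left(\frac{k_{IJ}}{2\pi}\right)^{3/2}
e^{-k_{IJ} r^2/2}\, dr,$$

a Maxwell-type density whose single parameter has the closed-form MLE
$\hat k = 3/\overline{r^2}$ (validated in the tests against direct
numerical likelihood maximization). Uncertainty comes from a seeded
nonparametric bootstrap (1000 resamples by default; the package's choice,
as replicate-based errors are rarely available per probe pair).
Comparisons are reported as $(k^{\mathrm{df}} - k^{\mathrm{wt}})/
k^{\mathrm{wt}}$ with a delta-method standard error; no conversion of
FISH distances into 4C contact probabilities is attempted because the
capture interaction volume is unknown — agreement is assessed in sign and
strength only. Wild-type fits pool both homologues' distances (they are
indistinguishable without a deletion-region probe).

## Enrichment

DIR/annotation overlap is tested by uniform random re-placement of the
annotation intervals (lengths preserved, query fixed, excluded regions
such as the deletion honored), with the empirical upper-tail p-value
$(1 + \#\{\text{null} \ge \text{obs}\})/(n_{\mathrm{perm}} + 1)$; with
999 permutations the reporting floor is $p = 0.001$. Both the overlap in
bp (primary) and the count of overlapping query intervals are available
as statistics. A 20-kb running-coverage track
(`density_track()`) displays binding-site footprints beside DIRs.

## The synthetic study

`simulate_study()` is the package's test substrate and defines the study
conditions: a 20-Mb chromosome of 2000 beads × 10 kb at $\nu = -3/2$;
12 viewpoints placed 2 upstream, 8 inside and 2 downstream of a 4.31-Mb
deletion (deletion analyses use the 4 outside viewpoints, the
identifiability minimum); viewpoint factors $C$ and experiment factors
$K$ log-uniform on $[0.5, 2]$; $10^6$ expected reads per experiment with
independent Poisson counts (replicates differ only in the Poisson draw);
and optionally the standard spike described above, present in the test
condition only. Deletion-condition profiles are generated on the rejoined
chain and mapped back to reference fragments. The capture radius defaults
to an adjacent-bead contact frequency of 0.5, keeping the radius small
relative to typical distances at larger separations.

What the generator does *not* emulate — and hence what passing tests do
not establish about real data: fragment-level GC/mappability biases
beyond the multiplicative model, trans contacts, domain structure (TADs,
LADs, loops) beyond injected spikes, excluded-volume and confinement
effects, and mapping artefacts. It emulates exactly the structure the
method assumes; real-data performance rests on how well that structure
holds.

## Numerical choices and degenerate inputs

* Logs are natural; all log-linear solves are ordinary (unweighted) least
  squares via QR, with gauge constraints appended as exact equations.
* Decay fits require ≥ 30 positive, non-self observations in range and at
  least a decade of separation span; otherwise they fail loudly, naming
  the viewpoint.
* Kernel smoothing returns missing (never zero) where a window is empty;
  DRCP is missing where either profile is missing or the reference window
  holds pseudo-count data only.
* Untestable windows (< 3 informative fragments a side) are recorded as
  such, not exceptions; empty DIR sets produce valid empty BED output.
* `relative_asymmetry` returns NA where both opposing entries are zero.
* All Monte-Carlo entry points take explicit integer seeds; identical
  seeds give bit-identical output.

## Worked example

```{r}
library(poly4C)

# a full two-condition, two-replicate study with a known spike
res <- run_pipeline(list(
  simulate = list(seed = 1, spike = "standard"),
  out = "run1"))
print(make_report(res))

# bias factors and the symmetry diagnostic for one experiment set
print(res$factors[["WT|1"]])
res$asymmetry

# compaction comparison between conditions
wt  <- subset(res$compaction, condition == "WT")
del <- subset(res$compaction, condition == "del")
compare_compaction(del, wt)

# FISH-side validation of a spring constant
r <- sample_fish_distances(k = 4, n = 200, seed = 7)
fit_spring_constant(r, seed = 7)
```

Problem sizes throughout the test suite and the acceptance script are the
study defaults above (2000-bead chains, 5000 Monte-Carlo configurations,
20 seeded pipeline runs for spike recovery, 1000 null windows), chosen as
the package's standard desk-scale study.

## Known limitations

* The multiplicative bias model ignores fragment-level covariates; it
  removes biases without modelling their sources, by design.
* With spline-derived pair matrices only the product $C_I K_I$ separates
  from the data (see Phase 1); downstream phases only ever use the
  product.
* The DRCP denominator ties the 5 % threshold to the absolute CPP scale;
  sensitivity to a given fold-change decreases with separation.
* Compaction significance with two replicates is indicative only.
* The generalized exponent is a pairwise (effective) description, not a
  consistent chain measure, for $\nu \ne -3/2$.
* Trans (inter-chromosomal) profiles are out of scope.
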