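---
title: "Counting and sizing DNA by mass photometry: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting and sizing DNA by mass photometry: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpdna)
```

Mass photometry detects single molecules landing on a glass--water
interface by the tiny change each binding event causes in the interface's
reflectivity. The interferometric contrast of one landing event is, to a
good approximation, proportional to the molecule's polarizability and hence
to its mass -- for DNA, to its number of bases. `mpdna` implements the
analysis chain that turns a movie of such events into species
concentrations and length estimates: ratiometric event detection, Gaussian
decomposition of the contrast distribution, contrast-to-length calibration,
and a diffusion correction that converts observed landing counts into
solution mole fractions. Because no public raw data exist for this kind of
measurement, the package also ships a synthetic-data generator that encodes
the same kinetic and contrast structure the analysis assumes, with ground
truth attached to every simulated molecule.

## The signal model

A molecule of length $L$ (bp for dsDNA, nt for ssDNA) produces a contrast
magnitude

$$ c = \kappa L + c_0, $$

with conversion factor $\kappa$ (default $1.22\times10^{-5}$ per bp, the
dsDNA value; ssDNA is about $0.71\times10^{-5}$ per nt) and intercept $c_0 = 0$
by default (direct proportionality). Molecule-to-molecule spread is
multiplicative Gaussian with a coefficient of variation that steps from
`cv_small` (2%) below a crossover length (400 bp) to `cv_large` (6%) above
it. This step reproduces the observed qualitative trend -- narrow peaks for
short, rigid fragments and much broader peaks for long ones, attributed to
the growing surface footprint of molecules beyond the persistence length --
without modelling its physical origin. No per-species widths are published,
so these CVs are plausible stand-ins, chosen once and exposed as
parameters; conclusions that depend on exact peak widths should not be
drawn from the defaults.

Landing events are stored as positive contrast magnitudes; the sign of the
underlying reflectivity change is an implementation detail of the movie
layer.

## Binding kinetics and the generator

Each molecule binds irreversibly, exactly once, at a time drawn from an
exponential distribution with a species rate

$$ k_i = \alpha\, L_i^{\beta}, \qquad \beta = -0.72, $$

the power law relating DNA diffusion coefficients to length. Time is
measured from sample addition ($t=0$); the camera only records the
acquisition window $[t_0, t_\mathrm{final}]$, by default 15 s to 135 s (a
120-s movie started 15 s after the sample is added). Short fragments
diffuse faster, bind faster, and are therefore relatively depleted from
solution before the window opens: the generator reproduces exactly the
depletion bias the correction must undo.

The paper trail for this instrument gives no binding-rate constant, so the
generator's default $\alpha = 0.2\ \mathrm{s^{-1}bp^{0.72}}$ was fixed once
at a moderate-depletion regime: per-species rates of about
$0.001$--$0.007\ \mathrm{s^{-1}}$ across a 100--2000 bp ladder, i.e.
depletion times of a few minutes, producing a roughly three-fold spread in
uncorrected mole fractions across the ladder -- the magnitude of the
before/after pattern the correction is known to repair in real
measurements. This matters because the correction's average-rate
approximation (below) is exact only in the limit of a single species; its
residual bias grows with depletion strength, and the regime in which the
published analysis demonstrably recovered equimolarity is the moderate one.
Default molecule counts (20 000 per species) give a few thousand in-window
events per species, comparable to a real acquisition.

`simulate_movie()` renders an event table into a frame stack: a static
random background (reference level 1, frozen spatial roughness), one 2-D
Gaussian PSF per event appearing at its landing time and persisting to the
end, and per-pixel Gaussian shot noise with standard deviation
$\sqrt{I/\mathrm{photon\ budget}}$. The PSF is an amplitude-scaled
Gaussian; partial coherence and pupil effects are deliberately out of
scope, so the movie layer validates the detection logic, not the optics.

## Detection

`ratiometric_stack()` averages consecutive non-overlapping batches of
`n_binned` frames and forms differential frames
$(\bar F_{j+1}-\bar F_j)/\bar F_j$, cancelling the static background.
A landing inside batch $m$ splits its step between differential frames
$m-1$ and $m$ in proportions $f$ and $1-f$, so `detect_events()` operates
on *paired* differential frames, $D_j + D_{j+1}$: the pair sum equals the
two-batch differential, always contains the full step of a landing in the
middle batch, and has the same noise level as a single differential frame
because the shared middle batch cancels. Without this pairing the recovered
contrast is biased low by up to 50% for landings near a batch centre.

Candidates are found on the paired frame after matched filtering with a
PSF-sized Gaussian, which suppresses single-pixel noise while preserving
PSF-shaped signal. Threshold 1 is a multiplier of the robust noise scale
(1.4826 x median absolute deviation) of the filtered frame -- a scale-free
reading of "contrast amplitude relative to the background". Candidates
within the patch radius of a brighter candidate are suppressed; survivors
are scored for radial symmetry and kept if the score reaches Threshold 2.
The symmetry score is the fraction of gradient energy pointing along the
radial direction through the patch centre: 1 for a perfect radially
symmetric spot, about 0.5 for pure noise, strictly lower for a stretched
PSF, and invariant under 90-degree rotation. The commercial metric behind
the published thresholds is unpublished; any monotone score with these
properties serves, and the published settings (0.2 default, 0.3 for
species near the diffraction limit) are kept as defaults. Whether the
choice of Threshold 2 shifts measured contrasts is verified as a property
in the test suite rather than assumed.

Event contrast is the magnitude of a least-squares 2-D Gaussian amplitude
fitted on the *unfiltered* paired patch; the event time is the timestamp of
the differential frame of first appearance (sub-frame timing is not
attempted). Same-site detections in consecutive paired frames -- one
landing appears in up to three, at partial amplitude in the outer two --
are merged keeping the larger amplitude. Events landing within the patch
radius of the field edge, or inside the first and last batch, cannot be
quantified and are dropped.

## Contrast distributions and peak areas

`contrast_kde()` computes a Gaussian-kernel density with an absolute
bandwidth in contrast units (default $2.1\times10^{-4}$, the published KDE
width); a relative `bw_factor` convention is available for plotting.
`find_contrast_peaks()` initializes the mixture fit from KDE modes with a
topographic-prominence floor (default 1% of the global maximum -- low
enough to keep the broad, low peak of the longest ladder species).

`fit_gaussian_mixture()` fits a sum of Gaussians to the binned contrast
histogram by Levenberg--Marquardt least squares. Two numerical choices
matter. First, each component's prediction for a bin is its *integrated*
mass over the bin (an erf expression), not the density at the bin centre;
with the default bin width of $1\times10^{-4}$ the narrowest ladder peaks
are a fraction of a bin wide and a midpoint rule would bias their centroids
by several bins. Second, if any fitted width comes out below the bin width
the fit is repeated once at a finer binning that resolves it, and the
heights are rescaled back to the requested convention. The component count
comes from the KDE modes, or from the user (the nominal species count); no
model selection is performed, and an under-parameterized fit is flagged
(`underfit`) rather than hidden. Whether the original analysis fitted the
histogram or the KDE curve is ambiguous; both targets are implemented and
the histogram is the default.

The area of a component, $a = A\sigma\sqrt{2\pi}$, divided by the bin
width, is the molecule count assigned to that species. Fitted components
are matched to nominal species by rank: ascending contrast to ascending
length, the assignment-by-inspection a ladder permits.

## Calibration and length errors

`fit_contrast_vs_length()` is ordinary least squares of peak-mean contrast
on nominal length, with a free intercept by default -- the published
description says "linear fit" while asserting proportionality, so a
through-origin flag covers the stricter reading. Species whose PSF deforms
near the diffraction limit (the 2000 bp fragment, conventionally) are
excluded by explicit label only; nothing is dropped automatically. With
fewer than three points $R^2$ is flagged undefined. Length estimates invert
the line, $(c - c_0)/\hat\kappa$; the conversion used for error evaluation
is the *replicate-averaged* slope. Error summaries report deviations
(estimated minus nominal), their mean, and the sample standard deviation
(denominator $n-1$, recorded in the output). `mass_contrast_ratio()`
divides the slope by a mass per unit length (default 0.649 kDa/bp, chosen
for consistency between the dsDNA slope and the published per-kDa ratio);
for ssDNA the per-nt slope is doubled first so ratios are per base-pair
equivalent.

## The diffusion correction

Observed landing counts under-represent slow (long) species twice over:
molecules bound before $t_0$ are unseen, and molecules still in solution at
$t_\mathrm{final}$ are unseen. For exponential depletion at rate $k_i$ the
observed fraction is $e^{-k_i t_0} - e^{-k_i t_\mathrm{final}}$, so the
corrected abundance is

$$ a_i' = a_i\,\frac{e^{k_i t_0}}{1 - e^{-k_i(t_\mathrm{final}-t_0)}}, $$

a factor always $\ge 1$. The chain in `correct_abundances()` is: fit one
average rate $k$ to the pooled arrival times by maximum likelihood under
the window-truncated exponential density (a binned least-squares
alternative is available -- the published description, an exponential fit
to events versus time, does not distinguish the two); form the
abundance-weighted mean length $\langle L\rangle = \sum L_i a_i / \sum
a_i$; set $\alpha = k / \langle L\rangle^{\beta}$; derive each $k_i$;
correct; renormalize. When arrivals are indistinguishable from uniform the
likelihood runs to $k \to 0$ and the fit is flagged rather than trusted.

Two conventions deserve a note. The printed mean-length formula divides by
the number of species, $N$, which is a mean only when the $a_i$ sum to
$N$; with fractional abundances it is dimensionally suspect, so the
normalized weighted mean is the default and the literal form sits behind a
flag. And the $a_i$ feeding $\langle L\rangle$ are the *raw* areas: the
procedure is a single pass. An optional fixed-point iteration to
self-consistency exists but is off by default -- on synthetic ladders it
amplifies, not reduces, the residual bias of the average-rate
approximation, because the corrected abundances pull $\langle L\rangle$
away from the value that compensates the pooled-rate estimate.

The average-rate step is the method's real approximation: a single $k$
fitted to a mixture of exponentials is an event-weighted compromise, and
$\langle L\rangle^\beta$ is not the event-weighted mean of $L_i^\beta$
(Jensen's gap). At moderate depletion the resulting bias in corrected mole
fractions stays within the Poisson sampling error of a few-thousand-event
acquisition; it grows with depletion strength and with event count (the
bias is fixed while sampling error shrinks), which is why the round-trip
checks run at realistic acquisition scale (6 000 molecules per species,
roughly 700--2 300 in-window events each) rather than at counts no real
measurement attains. Species whose peak mean sits within a few widths of
the contrast detection floor are flagged `near_detection_floor`: their
counts are depressed by non-unity detection efficiency (the known shortfall
of a 100 bp fragment) and no efficiency correction is attempted.

## What the tests do and do not show

The synthetic generator shares its contrast and kinetic structure with the
analysis assumptions, so passing tests demonstrate that the chain is
self-consistent and unbiased *under its own model*: linear contrast,
Gaussian spread, exponential depletion with the $-0.72$ power law,
irreversible single binding, and well-separated peaks. Real data add
surface heterogeneity, unbinding on poorly charged glass, buffer
contaminants, sequence-dependent polarizability, and PSF deformation for
long fragments -- none of which the generator emulates. Headline
experimental figures that depend on instrument repeatability (total-count
reproducibility, peak-area fluctuations, measured slopes) are inputs or
qualitative patterns here, not recoverable claims.

Problem sizes were chosen so the full suite runs comfortably on one CPU:
ladder runs of $5\times20\,000$ molecules, detection checks on
$128\times128$ px stacks of 2 000 frames with about 80 injected PSFs, and
oracle sweeps over $k \in [10^{-4}, 1]\ \mathrm{s^{-1}}$.

```{r example, eval = FALSE}
report <- run_pipeline(pipeline_preset("figure2_ladder", seed = 1),
                       out_dir = "results")
report$calibration_summary
make_figures(report, "figures")
```
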