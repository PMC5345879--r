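---
title: "Quantifying septal DNA translocation: models, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying septal DNA translocation: models, estimators, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(septrack)
```

## The problem

When an *E. coli* cell places its division septum over a nucleoid —
which happens routinely in mutants lacking nucleoid occlusion and Min
positioning — the membrane-anchored DNA translocase FtsK pumps the
trapped chromosome out of the closing constriction, partitioning whole
chromosomes between unevenly sized daughters. `septrack` quantifies this
process from multi-channel time-lapse movies: phase contrast locates the
constriction, nucleoid labels (DAPI-like conserved, HupA-like
stripped-and-frozen, SYTOX-like partially stripped) report where the DNA
is, and a septal-ring label (ZipA-GFP-like) marks the division machinery
and provides the time reference for all kinetics.

The central observable is the **normalized intensity**

$$\mathrm{NI}(t) = 100\,\frac{I_1(t)}{I_1(t) + I_2(t)}\ [\%],$$

where $I_1$ and $I_2$ are the background-subtracted, axially integrated
label intensities on the smaller- and larger-daughter sides of the
division plane. For a conserved label, NI is the fraction of total DNA in
the smaller compartment. A division that ends with $k$ of $n$ complete
chromosomes in the smaller daughter settles at $100\,k/n$ percent —
0, 25, 33, or 50 for the partitions accessible to cells with 2–4
chromosomes. The translocated amount follows from the NI change,

$$A_\mathrm{bp} = \frac{|\Delta \mathrm{NI}|}{100}\; n_\mathrm{genomes}
\times 4.6\times 10^6\ \mathrm{bp},$$

with 4.6 Mb per fully replicated chromosome ("genome unit"), and the
pumping speed divides $A_\mathrm{bp}$ by the pause-excluded active
duration.

## The synthetic world

Because no raw movies are deposited with the study this package
operationalizes, every stage is verified against a synthetic generator
whose defaults *are* the stated population:

| parameter | default | why |
|---|---|---|
| pumping speed $v$ | $\mathcal{N}(1700, 800)$ bp/s, truncated at 200 | reported speed distribution |
| pause incidence | 10% of cells, 8–12 min | reported pause statistics |
| start vs closure | $t_\mathrm{close} - t_\mathrm{start} \sim \mathcal{N}(8, 10)$ min, $\ge -20$ | translocation starts on average 8 min before ring dissociation |
| chromosomes | 2 if $L \le 4.5$ µm, else 4 | slow growth: replication completes before division |
| frame interval | 4 min | an 8-min pause spans two frames |
| pixel size | 0.111 µm/px | 9-px profile band ≈ 1 µm |
| PSF | Gaussian, FWHM 0.25 µm | stated resolution limit |
| cell geometry | $L \sim U(2.5, 7.5)$ µm, width 0.9 µm, plane at $U(0.2, 0.45)\,L$ | rod cells with clearly off-center constrictions |
| ring closure | $t_\mathrm{close} \sim \mathcal{N}(48, 8)$ min in [24, 80]; septum closes linearly over 32 min | places events mid-movie with a pre-constriction baseline |
| photon budget | $2\times10^5$ (nucleoid), $2\times10^4$ (ring) per frame; background 100 counts/px | bright-label wide-field imaging; NI shot noise ≈ 0.1–0.2 points |
| SYTOX retention | 0.5 | "partially removed" is not quantified; documented tunable |

Pumping direction goes toward the compartment already holding the
chromosome majority with probability 0.8. The final fraction is the
nearest whole-chromosome partition in the chosen direction, so
$\mathrm{final} \times n$ is always an integer.

Two deliberate idealizations deserve emphasis:

* **Pauses are defined at acquisition resolution.** A pause is an
  interval over which the *sampled* trace is flat for at least two
  frames, so generated pause onsets sit on the frame grid. With
  continuous sub-frame onsets, an 8–12-min pause frequently spans only
  one full frame interval and is undetectable in principle by a
  two-flat-steps rule; the grid-aligned definition matches how pauses
  are observed and counted (two frames or longer).
* **The nucleoid has constant transverse width** (0.8 × cell width, no
  pole-cap taper). With cap-shaped rendering, the 9-px-wide profile band
  captures a time-varying fraction of the signal as DNA crosses the
  plane, which would break intensity conservation at the 0.2% level for
  purely geometric reasons.

The phase channel is a stylized rendering — dark rod on bright
background with a bright septal bump whose amplitude grows as the septum
closes — not a physical phase-contrast simulation. The bump amplitude is
pre-compensated for PSF attenuation so that the modulation metric
reaches 1 at full closure. This is sufficient for constriction
localization and modulation trends, and it is the one acknowledged
divergence from real phase optics.

What a green test therefore establishes: that the estimators recover the
stated kinetic quantities from images with realistic blur, shot noise,
and label-specific artifacts. What it does not establish: robustness to
segmentation errors, cell growth or drift during the movie, touching
cells, photobleaching, or real phase-contrast ringing — all outside the
generated world.

## Estimators and numerical choices

**Profiles.** Axial line profiles average 9 px (≈1 µm) perpendicular to
the mask's principal axis with bilinear interpolation, sampled at 1-px
spacing, extended 0.7 µm beyond each pole. The extension is 0.2 µm more
than the minimum so that the background median can exclude a 0.25-µm
guard band past the poles, where the PSF tail of intracellular signal
still reaches; without the guard band, background subtraction alone
breaks intensity conservation at the 0.1% level. Background is a median
(robust to debris), and negative residuals are clipped at zero before
integration.

**Constriction.** The septal bump is the most prominent interior local
maximum of the phase profile above a threshold scaled to the cell's
phase depth, refined by a parabolic fit (noise-free accuracy ≈ 0.04 px).
Because the division plane is static once formed, the default
`constriction_mode = "static_median"` uses the temporal median of the
per-frame detections as the split position for all frames; per-frame
tracking jitter would otherwise dominate the NI noise budget and corrupt
the detector's noise estimate. A `"tracked"` mode (temporal 3-frame
median) remains available for drifting cells.

**Intensity split.** Diffraction mixes mass across the plane, so a plain
split of the blurred profile biases NI toward 50 in proportion to the
density difference between compartments (up to ~2 NI points at the end
state of a short cell). The default `split = "apportion"` assigns the
mass within ±0.25 µm (the resolution limit) of the plane to the two
sides in proportion to the flanking far-field densities; this is
unbiased when the axial density is locally uniform on each side, which
is the nucleoid approximation the whole analysis rests on.

**Event detection** is a transparent threshold-on-derivative detector
rather than change-point machinery: after 3-frame median smoothing, the
event spans the first through last pair of consecutive steps with
$|\Delta \mathrm{NI}| > 2\sigma$; pauses are runs of ≥2 intra-event
steps with $|\Delta \mathrm{NI}| \le \sigma$; reversals are sustained
counter-direction runs accumulating more than $4\sigma$. Three numerical
choices matter:

1. $\sigma$ is the *frame-to-frame* (step) noise, since every criterion
   compares steps; using the level noise would misscale both thresholds.
2. $\sigma$ is estimated in two passes — from the declared baseline
   (default 5 frames) first, then from the whole pre-event segment —
   because the standard deviation of a handful of diffs is too variable
   to set thresholds reliably.
3. Detected endpoints lie on the frame grid and straddle the true event,
   because the boundary steps are only partially filled with pumping.
   The refined endpoints scale each boundary step's size against the
   interior step size to estimate its filled fraction. Quantification
   uses the refined endpoints; without this correction mean speeds would
   be biased low by roughly one frame interval per event duration
   (~10–15%), and a fixed half-frame correction would conversely inflate
   short two-step events whose boundary steps are fully filled.

Both the frame-grid and refined endpoints are reported. Whether the
source study's "duration of translocation" excludes pauses is not
stated; speeds are therefore reported both ways (`speed_bps` excludes
pause time; `speed_incl_pauses_bps` does not), with the pause-excluded
value treated as the pumping rate.

**Ring width** is reported from the second-moment estimator
($2\sqrt{\mu_2}$ of the background-subtracted profile treated as a
density), which cannot fail to converge; the Gaussian-fit width
($2\hat\sigma$, `nls` with `scaleOffset` so exact data remain
well-posed) is kept as a QC column. On an exact Gaussian the two agree;
on a top-hat of width $w$ the moment estimator gives $w/\sqrt{3}$.

**Ring dissociation** is the first time the peak ring intensity falls to
≤20% of its early-movie median and stays there; the reported time is the
midpoint of the bracketing frame interval, so it is unbiased under
uniform event phase. It defines $t = 0$ for all relative timing. The
source study states no dissociation criterion; the 20% threshold with
2-frame persistence is this package's declared rule, tunable in the
configuration.

**Total DNA** uses the integer-genome rule by default (2 below 4.5 µm, 4
above). Cells within ~1 px of the threshold can be misclassified by the
mask-measured length, doubling or halving that cell's amount; this is a
faithful reproduction of the method's real failure mode and is left in.
The length-based alternative, DNA amount $= 0.92\,(L - 0.53)$ genome
units, is available as `total_dna_mode = "length_based"`.

**Calibration** finds the 2-genome peak as the dominant KDE mode
(`bw.nrd0` bandwidth), anchors amounts as $2 I/\hat p$, and fits the
length law by unweighted OLS (no weighting scheme is stated; the
intercept is fitted freely rather than constrained, another unstated
choice made here). KDE mode bias makes even the noise-free chain recover
the law to ~1% rather than exactly; the package's tests carry
Monte-Carlo envelopes computed before the tests were frozen.

## Known limitations

* Masks are inputs; there is no segmentation or tracking, and curved
  cells (medial-axis geometry) are out of scope.
* Events that outlast the movie are analyzed over their visible part;
  speeds remain unbiased but amounts are lower bounds, and pauses
  scheduled beyond the last frame are invisible — the main reason the
  detected pause fraction sits a few points below the generated
  incidence.
* The detector's pause rule operates at frame resolution; pauses
  coinciding with the detected window edges are not separable from a
  late start or early end.
* Sub-resolution ring diameters are not estimated — near closure the
  ring channel reports the PSF, which is exactly the regime the
  biology ends in.
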