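---
title: "Quantifying rapid colour change through predator vision: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying rapid colour change through predator vision: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(camochange)
```

## Overview

`camochange` implements the image-analysis and visual-modelling chain used
to ask whether a small benthic fish can rapidly change colour and improve
its camouflage against the background it sits on, as judged by an avian
predator's visual system. The chain is:

1. **Calibrated multispectral imaging.** Four camera channels (LW, MW, SW,
   UV) are linearized against a ladder of grey reflectance standards and
   equalized to an in-frame 40% standard, yielding reflectance-scale
   images.
2. **Cone-catch mapping.** A polynomial regression maps the four camera
   channels to the quantum catches of a violet-sensitive bird's five
   photoreceptor classes (uv, sw, mw, lw single cones and the double
   cone).
3. **Appearance metrics.** Per fish and time point: saturation (distance
   from the achromatic point in tetrahedral colour space), an opponent hue
   ratio, and double-cone luminance.
4. **Discrimination modelling.** Chromatic and achromatic
   just-noticeable differences (JNDs) between fish and background under
   the receptor-noise-limited model.
5. **Statistics.** Planned between-background comparisons at each time
   point with sequential Bonferroni correction, and Kruskal–Wallis tests
   of JND change over time.

Because the package is exercised entirely on synthetic imagery, a
first-class scene generator produces every input: smooth reflectance
spectra, a nonlinear four-channel camera, grey standards, and
fish-on-background image series with programmed colour-change dynamics.

## The visual model

### Quantum catches

The elementary quantity is the photon catch of receptor $i$ viewing a
surface with reflectance $R(\lambda)$ under illuminant $I(\lambda)$:

$$ q_i \;=\; \frac{\sum_\lambda R(\lambda)\, I(\lambda)\, S_i(\lambda)}
                 {\sum_\lambda I(\lambda)\, S_i(\lambda)} $$

normalised so a perfect (100%) reflector yields $q_i = 1$. Catches are
linear in $R$ and invariant to rescaling $I$. The working wavelength grid
is 300–700 nm at 1 nm: print measurements usually stop near 400 nm, but
avian UV-class receptors (and the camera's UV channel) require support
below it.

The receiver is a violet-sensitive bird. Measured cone curves are not
bundled; sensitivities are generated from the standard A1 visual-pigment
template (alpha plus beta band) at peaks of 432, 477, 537 and 605 nm for
the single cones and 565 nm for the double cone, and shipped as a CSV
(`inst/extdata/receiver_sensitivities_template.csv`) that can be replaced
by measured curves via `read_receiver_csv()`. Relative cone proportions
are lw 0.95, mw 1.00, sw 0.86, uv 0.45, and the Weber fraction of the most
abundant cone (mw) is $\omega = 0.05$.

### Receptor-noise-limited discrimination

Channel signals are logarithmic, $f_i = \ln q_i$, so that a signal
difference $\Delta f_i = \ln(q^A_i / q^B_i)$ is a Weber contrast. Channel
noise follows the cone proportions,
$e_i = \omega \sqrt{\eta_{\max}/\eta_i}$, anchoring the most abundant cone
at $e = \omega$ exactly. For the tetrachromat the chromatic distance is

$$ \Delta S^2 \;=\;
   \frac{\sum_{j<k} (e_l e_m)^2 (\Delta f_j - \Delta f_k)^2}
        {\sum_{\{a,b,c\}} (e_a e_b e_c)^2 }, $$

where $l, m$ are the two cones not in the pair $(j,k)$ and the denominator
runs over all cone triples. The achromatic distance uses the double cone
alone: $\Delta L = |\Delta f_{\mathrm{dbl}}| / \omega$. Units are JNDs:
values below 1 are indiscriminable, 1–3 (inclusive) marginal, above 3
increasingly likely to be discriminated. The implementation is verified
against an independent matrix-form oracle of the same model
($\Delta S^2 = \Delta f^\top A \Delta f$ with
$A = V^{-1} - V^{-1}\mathbf{1}\mathbf{1}^\top V^{-1} /
(\mathbf{1}^\top V^{-1} \mathbf{1})$, $V = \mathrm{diag}(e_i^2)$) to
1e-10 over 1,000 random stimulus pairs.

Two modelling choices are deliberate. Zero catches raise errors rather
than being silently floored, since a silent zero masquerades as an
achromatic stimulus; a `floor_catch`-style imputation was considered and
rejected for the synthetic pipeline, whose catches are strictly positive.
All four single cones enter the chromatic JND; with the low-UV stimuli
used here the UV channel contributes little, but dropping it is a
`channels` argument away.

### Tetrahedral colour space

Relative catches of the four single cones (each divided by their sum) are
mapped to $\sum_i \mathrm{rel}_i\, v_i$ with $v_i$ the vertices of a
regular tetrahedron centred on the achromatic point. **Saturation** is the
Euclidean distance from the centre. The vertex distance is 0.75 (a common
convention; some implementations use 1). Absolute saturation values scale
with this choice but every comparison in the pipeline is
convention-invariant, so the convention is shipped explicitly in
`tetra_vertices()` rather than guessed at.

**Hue** is an opponent-style ratio. With achromatic backgrounds there is
no predicted colour direction, so the long-versus-short ratio
$((\mathrm{LW}+\mathrm{MW})-(\mathrm{SW}+\mathrm{UV}))/
(\mathrm{LW}+\mathrm{MW}+\mathrm{SW}+\mathrm{UV})$ is used; with red/blue
backgrounds the directed ratio
$(\mathrm{LW}-\mathrm{SW})/(\mathrm{LW}+\mathrm{SW})$, higher = redder.
**Luminance** is the double-cone catch, unchanged.

## Calibration

The simulated camera applies a power-law nonlinearity
(response $= g\,q^{1/\gamma}$, default $\gamma = 2.2$) plus additive
Gaussian pixel noise, so the linearization stage has real work to do.
Linearization fits `response = a·R^b + c` per channel to the mean
responses over eight grey standards (2–99% reflectance) by
Levenberg–Marquardt least squares and inverts it; the form subsumes the
identity and any pure-gamma camera, and the fit records per-channel $R^2$
(warning below 0.99). Responses outside the fitted range are clamped to it
and counted, never dropped — masks must keep their geometry.

Equalization multiplies each channel by
(0.40 / mean linear value over the in-frame 40% standard), which pins the
standard to its known reflectance, cancels illuminant intensity
(the operation is idempotent and invariant to any global scaling), and
puts all channels on a 0–1 reflectance scale. Quantization to 8- or 16-bit
happens only at file export, never inside the pipeline. Each image is
equalized against its own in-frame standard, so a single reference
illuminant (CIE D65) suffices for synthesis even though field photographs
would be taken under variable light.

Two background-design helpers mirror how the experimental substrates are
built: `ratio_scale_midpoint()` returns the geometric mean — the unique
mid grey on a ratio scale — and `match_brightness()` rescales one spectrum
so its mean camera catch over LW, MW and SW (UV deliberately excluded)
matches another's, failing loudly if the required scale would push
reflectance above 1.

## Cone mapping

The polynomial map regresses each cone class's catch on all monomials of
the four camera-channel catches up to degree 2 (15 terms, interactions and
intercept included), requiring at least 10 training spectra per term. The
training library is 200 smooth random spectra (sums of 2–6 positive
Gaussian bumps, widths ~30–80 nm, clipped to [0,1] — natural reflectance
spectra are smooth at this scale) plus the eight flat standards. Degree 2
is the lowest degree whose held-out $R^2$ (disjoint seed) clears 0.99 for
every cone; with the default camera the minimum held-out $R^2$ is ≈0.992
(uv cone, the hardest: its pigment peak sits between the camera's UV and
SW channels). Negative per-pixel predictions are clamped to zero and
counted. ROI averaging precedes metric computation — one catch set per
fish per time point, matching whole-body analysis.

## The synthetic experiments

The generator emulates a 2 × 2 × 20 × 4 design: two experiments, two
backgrounds each, 20 fish per background, photographed at 0, 1, 10 and 60
minutes. Colour change is a per-wavelength exponential approach to a
target, rate 1.61 min⁻¹, so 80% of the change completes within the first
minute — "mostly within a minute" made quantitative.

* **Experiment 1 (brightness).** Flat black (4%) and white (90%) papers.
  Fish start at the ratio-scale mid grey (≈0.19) with between-fish jitter
  (sd 0.02) and shift their flat reflectance by +0.055 (white) or −0.035
  (black), with target jitter sd 0.015. The resulting between-group
  separation at 60 min is ≈0.09 in 0–1 catch units with group means a few
  hundredths apart — a deliberately modest, realistic effect, not a
  full-scale swing.
* **Experiment 2 (colour).** A long-pass red and a Gaussian blue
  background, the blue rescaled to equal mean visible camera brightness.
  Fish tilt their spectra along a red–blue ramp that is orthogonalised
  against the double-cone channel, so hue and saturation change while
  programmed luminance change is exactly zero (amplitudes +0.22 on red,
  −0.14 on blue).

Pixel noise (sd 0.004 response units) and the between-fish jitters are the
only stochastic elements; every stage is seeded, and a seeded run is
bit-reproducible. Rendering uses flat 48 × 48 px patches (background field,
fish ellipse, standard square): the analysis averages whole-body ROIs, so
spatial texture would be invisible to it, and none is rendered. What
passing tests therefore show is that the *pipeline* recovers programmed
appearance changes through a nonlinear, noisy camera; they cannot show
anything about real fish, real substrate texture, water-column optics, or
patterning — all out of scope.

## Statistics

The key prediction is a null difference at time 0 (all fish acclimated on
the same mid grey) and growing differences afterwards. Accordingly,
between-background tests are run separately at each time point:
Wilcoxon–Mann–Whitney for saturation, luminance and JNDs (typically
non-normal), Welch's t for hue. The reported W is the rank sum of the
first-listed background's sample, whose attainable range at $n=m=20$ is
210–610 and which reaches 610 under complete separation; Welch degrees of
freedom are kept at full precision internally and floored for display.
Each metric's four p-values are corrected by sequential Bonferroni (Holm):
ascending $p_{(i)}$ versus $\alpha/(k-i+1)$ with step-down stopping, so
the displayed thresholds for $\alpha = 0.05, k = 4$ are 0.050, 0.025,
0.016, 0.012 (truncated to three decimals for display; comparisons use
full precision). Camouflage change over time is tested per background by
tie-corrected Kruskal–Wallis across the four time-point groups (df = 3).

A record-level null simulator (`simulate_null_records()`) drives
Monte-Carlo checks that the familywise type-I error of the whole battery
stays at or below $\alpha$. Repeated-measures and mixed models are
deliberately not used: the design tests between-background differences at
fixed times, not within-individual change.

## Numerical choices and degenerate inputs

* Linearization refuses non-monotone standard responses (naming the
  channel) and warns when $R^2 < 0.99$.
* Equalization fails on a zero-mean standard region rather than dividing
  by zero.
* All-zero chromatic catches, zero hue denominators and nonpositive
  catches in the log-JND raise errors naming the offending channel.
* A Kruskal–Wallis input with no rank variation returns $H = 0, p = 1$
  (the tie-corrected statistic is otherwise 0/0).
* Wilcoxon p-values use exact enumeration only for small untied pooled
  samples ($n+m \le 20$); otherwise the normal approximation with tie and
  continuity correction.

## Problem sizes

The defaults used throughout the analysis scripts and tests: 48 px scene
tiles, 160 image stacks per experiment, a 208-spectrum training library
with a disjoint 208-spectrum held-out library, 1,000 stimulus pairs for
the discrimination oracle check, and 1,000 null replicates for the
familywise-error check. A full experiment (render → calibrate → map →
metrics → statistics) runs in a few seconds on one CPU.

## Worked example

```{r example, eval = FALSE}
res <- run_experiment(1, seed = 1)
subset(res$comparisons, metric == "luminance")
#>      metric time_min     test statistic df        p critical_threshold significant
#>   luminance        0 wilcoxon       441 NA 4.09e-01              0.050       FALSE
#>   luminance        1 wilcoxon       221 NA 3.42e-07              0.025        TRUE
#>   luminance       10 wilcoxon       212 NA 9.17e-08              0.012        TRUE
#>   luminance       60 wilcoxon       212 NA 9.17e-08              0.016        TRUE
```

Fish on black and white backgrounds are indistinguishable in luminance at
time 0 and separate almost completely from one minute on (W near the
attainable minimum 210: the first-listed black-background sample holds the
lowest ranks), while the achromatic JND to the white background declines —
the programmed improvement in camouflage, recovered through the full
imaging chain.

## Known limitations

* Flat-patch rendering: no texture, pattern or spatial metrics
  (granularity, edge disruption), and no pattern statistics downstream.
* No ocular-media transmission, no chromatic adaptation beyond
  equalization, no photon-shot noise term in the JND model, no viewing
  distance or acuity.
* The template sensitivities are stand-ins; swap in measured curves for
  real inference.
* Backgrounds and fish spectra are synthetic declarations, not
  measurements of any real substrate or animal.
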