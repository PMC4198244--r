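# camochange

Quantifying rapid colour change and background matching in small fish as
seen by an avian predator.

Many intertidal fish are thought to tune their appearance to the substrate
within minutes. Testing that claim quantitatively requires an imaging and
modelling chain, not just photographs: camera responses must be linearized
and scaled to reflectance, translated into the photon catches of a
predator's photoreceptors, summarised as colour and luminance metrics, and
finally converted into perceptual distances that say whether a predator
could actually see the difference. `camochange` implements that chain for
a tetrachromatic (violet-sensitive) avian observer, together with the
planned-comparison statistics used to test background matching over time,
and a synthetic-scene generator so the whole pipeline runs end to end
without any external imagery.

## The model at the core

For receptor *i* with sensitivity *S<sub>i</sub>(λ)* viewing reflectance
*R(λ)* under illuminant *I(λ)*, the quantum catch is

> *q<sub>i</sub>* = Σ *R·I·S<sub>i</sub>* / Σ *I·S<sub>i</sub>*  (1 for a perfect reflector)

Appearance metrics per fish: **saturation** — Euclidean distance of the
relative catches from the achromatic point in tetrahedral colour space
(regular tetrahedron, vertex distance 0.75); **hue** — an opponent ratio,
((LW+MW)−(SW+UV))/(LW+MW+SW+UV) for brightness experiments or
(LW−SW)/(LW+SW) for red/blue experiments; **luminance** — the double-cone
catch.

Discriminability uses the log form of the receptor-noise-limited
(Vorobyev–Osorio) model. With Δf<sub>i</sub> = ln(q<sub>i</sub><sup>A</sup>/q<sub>i</sub><sup>B</sup>)
and channel noise e<sub>i</sub> = ω·√(η<sub>max</sub>/η<sub>i</sub>)
(cone proportions η = 0.95/1.00/0.86/0.45 for lw/mw/sw/uv, Weber fraction
ω = 0.05 for the most abundant cone):

> ΔS² = Σ<sub>j&lt;k</sub> (e<sub>l</sub>e<sub>m</sub>)²(Δf<sub>j</sub>−Δf<sub>k</sub>)² / Σ<sub>triples</sub> (e<sub>a</sub>e<sub>b</sub>e<sub>c</sub>)²,  ΔL = |Δf<sub>dbl</sub>| / ω

in just-noticeable differences: &lt;1 indiscriminable, 1–3 marginal, &gt;3
likely discriminable.

## Worked example

```r
library(camochange)
res <- run_experiment(1, seed = 1)   # black/white backgrounds, 20 fish each
subset(res$comparisons, metric == "luminance")
#>      metric time_min     test statistic df        p critical_threshold significant
#>   luminance        0 wilcoxon       441 NA 4.09e-01              0.050       FALSE
#>   luminance        1 wilcoxon       221 NA 3.42e-07              0.025        TRUE
#>   luminance       10 wilcoxon       212 NA 9.17e-08              0.012        TRUE
#>   luminance       60 wilcoxon       212 NA 9.17e-08              0.016        TRUE
```

At time 0 (all fish acclimated on the same mid grey) the backgrounds do
not differ (p = 0.41 against the 0.050 step-down threshold). From one
minute on the groups separate almost completely: W is the rank sum of the
first-listed (black) sample, and 212 is close to the attainable minimum of
210 at n = m = 20, i.e. fish on black hold nearly all the lowest luminance
ranks. The camouflage consequence:

```r
subset(res$trends, background == "white" & jnd == "achromatic")
#>   background        jnd        H df            p significant
#>        white achromatic 33.91778  3 2.061969e-07        TRUE
```

— the achromatic JND of fish against the white background falls over time
(median ≈31 → ≈26.5 JND), a significant Kruskal–Wallis trend: the
programmed improvement in luminance match, recovered through the full
camera → calibration → cone-catch → JND chain.

The `analysis/` directory holds the numbered workflow
(`01_simulate_scenes.R` … `05_statistics.R`) that renders both
experiments, validates calibration and cone mapping, extracts the metric
records and writes all statistics tables under `results/`.

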