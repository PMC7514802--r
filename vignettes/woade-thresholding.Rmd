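---
title: "Multilevel thresholding by entropy maximization with a WOA-DE hybrid"
author: "whaleseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilevel thresholding by entropy maximization with a WOA-DE hybrid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(whaleseg)
```

## The model

An 8-bit channel is summarized by its 256-bin histogram
$p_j = n_j / N$. K thresholds $th_1 < \dots < th_K$ in $[1, 255]$ induce
the half-open classes $[0, th_1), [th_1, th_2), \dots, [th_K, 256)$.
Kapur's criterion scores a partition by the sum of the Shannon entropies
of the normalized within-class distributions,
$$H = \sum_i \left(\ln \omega_i - \frac{1}{\omega_i}
      \sum_{j \in c_i} p_j \ln p_j\right),
  \qquad \omega_i = \sum_{j \in c_i} p_j,$$
in nats, and the optimal thresholds maximize $H$. Bins with $p_j = 0$
contribute nothing ($0 \ln 0 := 0$) and empty classes
($\omega_i = 0$) contribute zero. This convention keeps the objective
finite everywhere, but it has a consequence worth knowing: on nearly
degenerate histograms (for instance two isolated spikes at interior
gray levels) the optimum may place all mass in a *single* class, whose
entropy can exceed the summed entropies of any split. Kapur's criterion
seeks informative classes, not valleys; the alternative objective,
Otsu's between-class variance
$\sigma_B^2 = \sum_i \omega_i (\mu_i - \mu_T)^2$, is the valley-seeking
choice and is exposed under `kind = "otsu"`. Both treat empty classes
as zero contributors, and $\sigma_B^2$ never exceeds the total
histogram variance.

For RGB images the criterion is applied to each color component
independently (three separate searches); the reported total fitness is
the sum of the three per-channel values, with the per-channel values
always retained, since no canonical single-number aggregation exists
for color images.

## The search

Thresholds are found by a population search over the continuous box
$[1, 255]^K$. Decoding a position sorts its coordinates, rounds to the
nearest integer, clamps to $[1, 255]$, and repairs duplicates by
incrementing collided values upward (spilling downward at 255). Sorting
plus rounding is the standard repair for threshold metaheuristics; it
keeps every evaluation on a valid, strictly increasing integer vector.

Each generation proceeds synchronously. The mean population fitness
$\bar f$, the best-so-far attractor $X^*$ and the donor pool are all
frozen at the top of the iteration, so results do not depend on the
order in which agents are visited and a single seed reproduces a run
bit-for-bit. Then:

* **Above-average agents** ($f_i > \bar f$) take a differential
  evolution step: rand/1 mutation $m = x_{r1} + SF (x_{r2} - x_{r3})$
  with the three donors drawn without replacement from the population
  excluding the target, binomial crossover at rate $CR$, and greedy
  selection that keeps the trial only on strict improvement (the
  textbook DE selection is written for minimization; it is mirrored
  here because the objective is maximized). Ties keep the incumbent.
* **The rest** take a whale optimization step. Per agent, a donor index
  is drawn first, then three uniforms giving $A = 2ar_1 - a$,
  $C = 2r_2$ and the branch selector $p$; if $p \ge 0.5$ a fourth draw
  $l \sim U[-1, 1]$ drives the logarithmic spiral
  $x' = |X^* - x|\, e^{bl} \cos(2\pi l) + X^*$; otherwise the move
  encircles $X^*$ when $|A| < 1$ or a random partner when $|A| \ge 1$.
  Positions are clamped to the bounds after every move. The donor index
  is drawn whether or not the exploration branch fires, so the RNG
  schedule is branch-independent and traces are easy to replay.

The coefficient $a = 2 - 2t/t_{max}$ decays linearly from 2 to 0, so
$|A| \le a$ is confined to $[-1, 1]$ from iteration $t_{max}/2$ onward
(iteration 250 of a 500-iteration run): past that point pure WOA has no
exploration moves left, which is precisely the regime in which it
stagnates on high-dimensional landscapes such as $K = 12$ thresholding.
The DE branch is what restores progress there, scaling the shrinking
inter-agent differences into fine local steps.

A and C are scalar per agent per iteration (fresh draws each time); the
branch rule operates at agent granularity. Whether $\bar f$ should be
computed before or after moves within an iteration is genuinely open;
the synchronous-generation choice above was made for reproducibility
and order-independence.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `nAgents` | 30 | population size; at least 4 so DE can draw donors |
| `maxIter` | 500 | iteration budget (full protocol) |
| `CR` | 0.9 | DE crossover probability |
| `SF` | 0.5 | DE mutation scaling factor |
| `b` | 1 | spiral shape constant (no canonical value; 1 is the common choice) |
| `lower`, `upper` | 1, 255 | admissible threshold gray levels |
| `seed` | NA | one RNG stream per run; NA inherits the caller's stream |

Channel seeds for RGB are `seed`, `seed + 1`, `seed + 2`, and the
repeated-run harness uses `baseSeed + run − 1`, so one integer fixes an
entire experiment.

## Reconstruction and quality metrics

Segmented images replace every pixel of class $[th_i, th_{i+1})$ with
the rounded mean gray level of that class's pixels. The class mean
minimizes the within-class squared error, which is the natural choice
when the reconstruction is subsequently scored against the original by
MSE-based metrics; a threshold-midpoint rule would be systematically
worse under PSNR without changing the thresholds themselves.

* **PSNR** $= 10 \log_{10}(255^2 / MSE)$, MSE pooled over all pixels
  and channels; identical images report `Inf` rather than erroring.
* **SSIM** uses local $11 \times 11$ Gaussian-weighted statistics
  ($\sigma = 1.5$, $c_1 = (0.01 \cdot 255)^2$,
  $c_2 = (0.03 \cdot 255)^2$) averaged over the image, per channel and
  averaged for RGB. The single-formula global variant is kept behind
  `method = "global"` for formula-exact testing; which variant produced
  any given published table is generally unrecoverable, so both are
  exposed.
* **FSIM** combines phase-congruency similarity
  $S_{PC} = (2 PC_1 PC_2 + T_1)/(PC_1^2 + PC_2^2 + T_1)$ and gradient
  similarity $S_G = (2 G_1 G_2 + T_2)/(G_1^2 + G_2^2 + T_2)$ with
  exponents $\alpha = \beta = 1$, weighted by
  $PC_m = \max(PC_1, PC_2)$. Constants follow the reference
  literature: $T_1 = 0.85$, $T_2 = 160$, log-Gabor bank with 4 scales
  (minimum wavelength 6, multiplier 2, radial bandwidth
  $\sigma_{Onf} = 0.55$) × 4 orientations, noise threshold 2 standard
  deviations above the estimated noise energy. Gradients use Scharr
  operators; RGB is scored on luminance
  $0.299R + 0.587G + 0.114B$. Images below $16$ pixels in either
  dimension are rejected (filter-bank support). Because the filters
  live on a discrete FFT grid, symmetries that are exact in continuous
  theory (e.g. invariance to flipping both images) hold only to about
  $10^{-3}$ on small even-sized images — the unpaired Nyquist
  frequency is the culprit.
* **Fitness STD** is the sample standard deviation ($n - 1$
  denominator) of best fitness over repeated runs; zero means a
  perfectly stable search.

## Statistical comparisons

`rankSumTest` is a two-sided Wilcoxon rank-sum on midranks: exact by
exhaustive enumeration of rank assignments when both samples have fewer
than 10 observations (so ties are handled exactly, matching the small
cell counts of MR-image comparisons), and a tie-corrected,
continuity-corrected normal approximation otherwise. The decision flag
applies $\alpha = 0.05$. `friedmanRanks` ranks methods within blocks
(midranks, rank 1 best), reports average ranks, and uses the
tie-corrected $\chi^2$ approximation on $k - 1$ degrees of freedom; a
fully tied matrix returns $p = 1$ rather than dividing by zero. In the
harness, rank-sum comparisons are per (image, K, objective) cell
against the first algorithm, and Friedman blocks are
(image, objective, run) triples within each K — which measure feeds
the tests is exposed as an argument since no single choice is
canonical.

## Synthetic fixtures

`generateImage` draws each pixel from a Gaussian mixture over the gray
axis (mode means, standard deviations and weights; rounded half-up,
clipped to $[0, 255]$), emulating the multimodal histograms of natural,
satellite and MR test images. `addGaussianNoise` perturbs on the unit
intensity scale — $x' = \mathrm{clip}(\mathrm{round}(x + 255 n))$ with
$n \sim N(\mu, \sigma^2)$ — matching how variances such as
$0.00625, \dots, 0.1$ are quoted for 8-bit images; the mean defaults
to 0, clipping (not wrapping) follows the noise.

What these fixtures do *not* emulate: spatial structure. Pixels are
i.i.d., so there are no edges, textures or objects; histograms are
faithful but SSIM/FSIM values on synthetic images exercise the metric
code without saying anything about perceptual quality on real scenes.
Passing tests certify the objective/optimizer/metric machinery, not
field performance on any particular image collection.

## Numerical choices and degenerate inputs

* Objectives use prefix-sum evaluation ($O(K)$ per candidate after a
  256-term scan); the exhaustive oracle enumerates all
  $\binom{255}{K}$ threshold vectors in compiled code with $O(1)$
  per-class costs, feasible for $K \le 3$, with ties broken to the
  lexicographically smallest maximizer.
* Optimizer tie-breaks: DE selection and best-so-far tracking both
  require strict improvement, so plateaus never cause churn.
* Delta histograms (constant images) give zero fitness for every
  partition; the oracle then returns $[1, 2, \dots, K]$ and the
  optimizer a flat history — no special-casing, the conventions above
  produce this.
* Thresholds are validated everywhere (strictly increasing integers in
  $[1, 255]$); invalid vectors raise errors rather than being silently
  repaired, except inside the optimizer's decoder where repair is the
  documented contract.

## Scale of the shipped checks

The test-suite and reproduction-script problem sizes are chosen to
exercise every claim at desk scale: mixture histograms from
$48^2$–$64^2$-pixel images, oracle comparisons over 20 histograms with
$K \in \{1, 2, 3\}$ at 30 agents × 200 iterations, the K = 12
hybrid-versus-WOA comparison over 10 images × 3 paired runs, 1000-run
null calibration of the rank-sum test, and 2-run benchmark determinism
checks. The full 30-run, 500-iteration protocol is the default of
`runExperiment()` and scales linearly from there.

## Known limitations

* Kapur's entropy with the zero-empty-class convention can prefer
  degenerate partitions on sparse histograms (see above); this is a
  property of the criterion, certified by the exhaustive oracle, not a
  search failure.
* The FSIM constants and the SSIM windowing variant are
  reference-literature defaults; published tables computed with other
  settings will differ by small systematic offsets.
* BMP input is not supported (no installed reader); PNG, JPEG and TIFF
  are, at 8 bits per channel only.
* The exhaustive oracle is limited to $K \le 3$; above that, optimizer
  claims are relative (hybrid versus baselines), not absolute.
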