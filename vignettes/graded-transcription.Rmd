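---
title: "Quantifying graded transcriptional responses to the Dorsal gradient"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying graded transcriptional responses to the Dorsal gradient}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gradedTS)
```

## The biological problem

In the early *Drosophila* embryo the nuclear concentration of the Dorsal
transcription factor forms a ventral-to-lateral gradient along the
dorsoventral (DV) axis and is the sole asymmetry cue on that axis. Within
the prospective mesoderm — the ventral band of roughly 20 nuclear columns
that later invaginates — two zygotic Dorsal targets encoding regulators of
actomyosin constriction accumulate mRNA in a *graded*, not switch-like,
pattern. `gradedTS` implements the quantitative analysis chain that links
single-molecule FISH (smFISH) images of such embryos to the two mechanisms
behind that gradient, and the forward models that test them:

1. **Graded activation probability.** Each gene locus (two per diploid
   nucleus) switches on permanently and stochastically; the per-minute
   activation probability `p(x)` scales with the local Dorsal level
   `D(x)`.
2. **Graded Pol II loading.** Once a locus is on, the rate at which
   polymerases load — read out as nascent-transcription-site (TS)
   intensity — also scales with `D(x)`.
3. **Intron delay.** Long introns postpone the first mature mRNA by the
   elongation time across the gene, decoupling transcription onset from
   protein production.

## The activation model

With exposure time $T$ (minutes of stable gradient) and per-minute
activation probability $p$, an allele's waiting time is exponential, so
the expected activated fraction is

$$F(x) = 1 - e^{-T\,p(x)}, \qquad p(x) = p_{\mathrm{mid}}\,D(x),$$

and an observed fraction $\hat F$ inverts to
$\hat p = -\ln(1-\hat F)/T$ (`activated_fraction()`,
`infer_probability()`). A saturated column ($\hat F = 1$) is capped at
$1 - 1/(2 n_{\text{alleles}})$ before inversion and flagged: with $n$
alleles observed, 1 is consistent with any probability above roughly
$\ln(2n)/T$, and the cap returns that finite boundary rather than
infinity. The identity $\hat p(p) = p$ holds to near machine precision
while $1-F$ is well represented in double precision (up to $pT \approx
20$); tests exercise it at $pT \le 5$ where the round-trip is accurate to
$10^{-12}$.

Correlations with the gradient (`correlate_with_dorsal()`) are plain
Pearson coefficients computed on column-level values, with a defined
degenerate rule: zero-variance input returns $r = 0$ with a warning
rather than `NA`, so switch-like simulations in which every column
saturates still produce a usable control value.

Accumulated mRNA under stable transcripts follows in closed form
(`simulate_accumulation()`):

$$M(x,T) = r(x)\left[T - \frac{1 - e^{-p(x)T}}{p(x)}\right],$$

with production rate $r(x) = 1$ (uniform loading) or $r(x) = D(x)$
(graded loading), and $M = 0$ at $p(x) = 0$ by continuity. A Monte-Carlo
mode re-derives $M$ from sampled activation times and serves as an
internal cross-check; loading is deterministic per column (an
expected-value model), so the Monte-Carlo spread reflects activation
stochasticity only.

## The elongation / intron-delay model

`simulate_elongation()` advances the first Pol II at a constant rate
(default 2 kb/min) from the activation time; a probe region becomes
detectable when that polymerase passes the region's start, and the first
mature mRNA appears when it reaches the gene end, with splicing treated
as instantaneous — the delay argument rests on elongation time alone.
Built-in gene models (`builtin_gene()`): the 29-kb *T48* with a 25-kb
intron and 5′/intron/3′ probe regions, its intronless 4-kb cDNA
transgene, the 9.3-kb *mist* and the 2.2-kb *twi*. At 2 kb/min the
endogenous *T48* matures 14.5 min after activation and the cDNA after
2 min, a 12.5-min delay. The elongation rate is a free parameter: in vivo
5′→3′ lags at lower temperature can exceed `L / 2 kb/min`, so the default
should be adjusted when modeling other conditions.
`simulate_probe_pattern()` combines activation draws with these timelines
to emit per-column fractions of 5′-only, intron-positive and mature TSs
over time; endogenous and transgene loci share activation draws by
default (they sit in the same nuclei under the same enhancer), which
makes the cDNA's earlier maturation a per-realization certainty rather
than a statistical tendency.

## Image analysis

The detection chain mirrors standard smFISH practice:

* **2D TS detection** (`detect_ts_2d()`): maximal z-projection, LoG
  filter of size 15 px and $\sigma = 2.5$ px, automatic threshold
  selection, 8-connected component calling.
* **3D single-molecule detection** (`detect_spots_3d()`): moving-sphere
  median background subtraction (radius 5 voxels, clipped at zero), 3D
  LoG, threshold selection, 18-connected components.

Numerical choices worth knowing:

* **LoG implementation.** The sampled analytic LoG kernel is applied as a
  sum of separable 1D convolutions with reflective (half-sample
  symmetric) boundaries, sign-flipped so spots are positive maxima, and
  shifted to exact zero sum so constant images give exactly zero
  response. The impulse response equals the sampled kernel.
* **Threshold selection** (`select_threshold()`): 100 geometrically
  spaced candidates are scanned from three robust (MAD-based) noise
  standard deviations of the response up to its maximum, counting
  connected components above each. The chosen threshold is the first
  candidate opening a five-candidate window whose counts stay within a
  10% band — the first threshold in whose environment the count is
  relatively constant. A windowed plateau is used rather than a
  single-step change criterion because per-step count changes in the
  noise regime of realistic images are small and would trigger a
  single-step rule far below the noise shoulder; the per-step
  $|\Delta\log_{10} n|$ trace is returned in the scan for audit. On an
  image with no measurable noise floor the scan starts at the median
  positive response; a completely flat scan picks the lowest candidate
  and warns. Component counts are guaranteed non-increasing in the
  threshold only on clean spot images; on noisy images counts can rise
  while the noise mask fragments, which is visible in the audit trace.
* **Intensity measurement** (`call_spots()`): the component mask from the
  thresholded LoG response is grown by 3 voxels (nearest component wins,
  ties to the lower label) before summing, because the super-threshold
  core of a dim spot covers a smaller flux fraction than that of a spot
  70 times brighter — the literal component sum would inflate the
  TS-to-mRNA ratio several-fold. Flux is summed over the grown mask on
  the raw image minus a *spot-excluded* moving-sphere mean background:
  excluding detected spot territory keeps a spot from inflating its own
  background estimate, and using the mean (not the median) avoids the
  systematic offset the Poisson-skewed median background carries into
  large masks. On noise-free fixtures per-spot flux is recovered to
  within a few tenths of a percent; planted TS/mRNA ratios of 70, 30 and
  10 are recovered within ~5% on noisy fixtures. Components with fewer
  than 4 core voxels are dropped as specks in the 3D path.
* **Coordinates** are 1-based voxel indices (R convention) throughout;
  column distances are real-valued and signed with 0 at the ventral
  midline.

Classification of calls into single mRNAs versus TSs
(`classify_spots()`) finds the minimum of a kernel density fitted to
$\log_{10}$ maximal intensities between the two dominant modes, requiring
the modes to sit at least 0.5 decades apart so that bandwidth wiggles
within one population are not mistaken for a second one; a histogram
without two such modes raises an explicit "no separation" error. The
cutoff is scale-invariant (a global intensity rescaling shifts the log
histogram rigidly). The TS-to-mRNA ratio of median cumulative intensities
is reported directly as the Pol II loading estimate $N$; no correction is
attempted for partially elongated (5′-biased) nascent transcripts — the
dual-probe gating of `match_dual_probes()` (mutual nearest neighbors
within 3 px, ties to the lower spot id) is the intended way to restrict
the analysis to steady-state loci. `polII_density()` converts $N$ to
base pairs per polymerase, $1000\,L_{kb}/N$.

## Embryo geometry

The ventral midline is the intensity-weighted centroid of the smoothed
(two column spacings) DV profile of a mesoderm-marker channel; in
practice this step is often done by hand, so the automated estimator is
a design choice, as is the rectangular (or absent) ROI.
Column spacing comes from DAPI: nucleus-scale LoG local maxima above 20%
of the strongest response are projected onto the DV axis, clustered into
columns by splitting at gaps larger than half the largest gap, and
adjacent column centers are averaged. Spots get real-valued signed
column distances, nearest-integer column bins, and nucleus assignments
by footprint containment with a nearest-centroid fallback (ties to the
lower nucleus id).

## The synthetic-embryo generator

Because the study's embryo images and measured Dorsal profile are not
published data, every quantitative check runs against synthetic embryos
with known ground truth:

* **Dorsal profile**: a Gaussian stand-in $D(x) = e^{-x^2/(2\sigma^2)}$
  with $\sigma = 4$ columns over a ~20-column mesoderm, normalized to 1
  at the midline. All correlation-style results in this package are
  therefore statements about the parameterized stand-in, not about the
  measured gradient.
* **Activation truth**: exponential waiting times per allele at rate
  $p_{\mathrm{mid}} D(x)$ — exactly the model the analysis assumes.
* **Rendering**: nuclei on a hexagonally offset column grid (DAPI
  blobs); one PSF-shaped Gaussian spot per active allele inside the
  nucleus footprint with integrated intensity `ratio_ts` (default 70)
  times the single-mRNA unit (default 400 photons); unit-intensity
  cytoplasmic mRNA spots outside nuclei; Poisson shot noise on expected
  photon counts plus Gaussian read noise (sd 1) over a uniform
  background (2 photons). Rendered spots are renormalized within their
  4-sigma truncation window, so total flux equals planted flux exactly
  with noise off. Spot pairs closer than a packing limit are flagged
  crowded and warned about.
* **Calibration fields** (`render_spot_field()`): well-separated TS and
  mRNA spots for intensity-ratio validation. In a rendered embryo at
  this scale, the two sister TSs of one nucleus often merge into a
  single 18-connected component and double the apparent TS intensity;
  real images resolve sister TSs, so ratio calibration uses the
  separated field instead.
* **Seeds**: one master seed is split deterministically per stage
  (`split_seed()`); identical seeds give bit-identical stacks and
  byte-identical pipeline outputs.

What passing these tests does **not** show: robustness to optical
aberrations, embryo curvature, nonuniform background, autofluorescence,
chromatic misregistration between probe channels, or segmentation of
touching nuclei — none of which the generator emulates.

## Problem sizes and runtimes

The shipped tests render stacks of about $140 \times 140 \times 20$
voxels with ~120 planted spots (detection in tens of seconds on one
core) and simulate 200–2000 nuclei per column for model-level checks;
the activation analysis itself is closed-form and effectively instant.
These sizes give binomial standard errors per column of about 0.02 on
activated fractions, small enough to resolve every correlation bound
tested while keeping the default test run short.

## Known limitations

* The Pol II count equates one TS/mRNA intensity unit with one complete
  transcript; nascent transcripts are incomplete, so $N$ is a biased
  (low-side) proxy whose magnitude of bias is not modeled.
* The activation model has no off switch and no bursting; it describes
  the initial permanent-activation window only, and mRNAs are treated as
  stable throughout.
* The threshold selector assumes spot populations produce a count
  plateau; images whose brightness spectrum is continuous (e.g. heavy
  clustering) have no plateau to find, and the audit trace should be
  inspected.
* The midline/ROI/column machinery assumes the DV axis is aligned with
  an image axis; arbitrary embryo orientation is out of scope.
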