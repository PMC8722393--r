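# gradedTS

Quantification of graded morphogen responses from single-molecule FISH
(smFISH) images of early *Drosophila* embryos.

Within the prospective mesoderm — the ventral ~20 nuclear columns of the
blastoderm — the nuclear Dorsal gradient `D(x)` (normalized to 1 at the
ventral midline, column `x = 0`) does more than draw an on/off expression
boundary: key zygotic targets such as *T48* and *mist* accumulate mRNA in
a graded pattern. `gradedTS` implements the analysis chain that measures
this from images and the models that explain it:

* **smFISH spot detection**: Laplacian-of-Gaussian filtering (2D
  projections for transcription sites, 3D stacks for single molecules),
  automatic threshold selection from a spot-count-vs-threshold scan,
  moving-sphere median background subtraction, 8/18-connected component
  calling with flux-accurate intensity measurement.
* **Embryo geometry**: ventral-midline estimation, pixel→nuclear-column
  conversion from DAPI, spot-to-nucleus assignment, linear interpolation
  of Dorsal levels at spot positions.
* **Quantification**: TS vs single-mRNA classification from the bimodal
  log-intensity histogram; the TS/mRNA median-intensity ratio `R` as a
  Pol II loading estimate `N`, and its packing density `1000·L/N` bp per
  complex; per-column activation summaries; cytoplasmic mRNA profiles;
  dual-probe (5′/intron/3′) maturation states.
* **Activation model**: stochastic, independent promoter activation with
  activated fraction `F = 1 − exp(−T·p)`, `p(x) = p_mid·D(x)`; inversion
  to per-column probabilities with a saturation cap; Pearson correlations
  against the gradient.
* **Expression simulation**: closed-form and Monte-Carlo mRNA
  accumulation `M(x,T) = r(x)·[T − (1 − e^{−pT})/p]` under uniform or
  Dorsal-graded Pol II loading, and a deterministic elongation model in
  which a 25-kb intron at 2 kb/min delays mature *T48* mRNA by >10 min
  relative to an intronless transgene.
* **Synthetic embryos**: a generator that renders multi-channel 3D
  stacks (DAPI + smFISH) with planted ground truth — nuclei on a
  hexagonal column grid, PSF-blurred TS and mRNA spots, Poisson + read
  noise — so the whole pipeline is testable without microscope data.

## Worked example

```r
library(gradedTS)

# 1. Simulate a ventral half-embryo: Dorsal-proportional activation
prof <- make_dorsal_profile(sigma = 4, half_width = 9)
prof <- prof[prof$column >= 0, ]
class(prof) <- c("dorsal_profile", "data.frame")
tab <- simulate_activation(prof, activation_config(p_mid = 1/15, T_min = 15,
                                                   n_nuclei_per_column = 200,
                                                   seed = 1))
fr <- activation_fractions(tab)
summ <- data.frame(column = fr$column, f_hat = fr$fraction,
                   n_nuclei = fr$n_alleles / 2)
fit_activation(summ, prof, T_min = 15)
#> Activation-model fit (T = 15 min)
#>   r(F_hat, Dorsal) = 0.985
#>   r(p_hat, Dorsal) = 0.991
#>   columns: 10  capped: 0

# 2. Pol II loading from a rendered calibration field
cfg <- render_config(shape = c(140, 140, 20), ratio_ts = 70, seed = 5)
field <- render_spot_field(n_mrna = 100, n_ts = 20, cfg = cfg)
det <- detect_spots_3d(field$stack)
cls <- classify_spots(det$spots)
cls$ratio
#> TS/mRNA intensity ratio R = 72.4  (planted: 70)
polII_density(cls$polII, builtin_gene("T48"))$bp_per_polII
#> Pol II density: one complex every 401 bp on T48 (29 kb)

# 3. Intron delay
endo <- simulate_elongation(builtin_gene("T48"))
cdna <- simulate_elongation(builtin_gene("T48_cDNA"))
endo$mature - cdna$mature
#> first mature mRNA: endogenous 14.5 min, cDNA 2.0 min, delay 12.5 min
```

The first block says that when each allele switches on with a rate
proportional to the local Dorsal level, the per-column active fraction
after 15 minutes — and the per-minute probability inferred by inverting
`F = 1 − exp(−T·p)` — both track the gradient almost perfectly. The
second block recovers the planted 70:1 TS-to-single-mRNA intensity ratio
from a rendered noisy stack within a few percent and converts it to a
polymerase packing density of ~400 bp per complex on a 29-kb gene. The
third block shows the 12.5-minute maturation delay the 25-kb intron
imposes at 2 kb/min.

A full pipeline (simulate → detect → geometry → quantify → fit →
expression → report) is available via `run_pipeline()` /
`run_stage()` or from a shell:

```sh
Rscript inst/scripts/gradedTS.R --stage all --seed 7 --out-dir run1
```

Outputs are deterministic per seed (byte-identical CSV/TIFF across
reruns).

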