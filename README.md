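# epicombine

Susceptibility-distortion handling for diffusion EPI acquired with
opposite phase-encoding (PE) polarities — "blip-up / blip-down" —
implemented in R. B0 inhomogeneity near tissue/air interfaces displaces
tissue along the PE axis in opposite directions for the two polarities,
locally squeezing the signal of one acquisition (irreversible resolution
loss) while stretching the other (information-preserving). The package
estimates the displacement field from such a pair, corrects both
acquisitions, and — its core purpose — combines them so that the locally
trustworthy polarity dominates, instead of blurring both together with a
plain average. Downstream it carries the correction into aggregate
MR g-ratio mapping, where residual misalignment between diffusion and
structural white matter silently zeroes out g-ratio voxels.

It is aimed at quantitative-MRI method developers who want a compact,
fully seeded test bed: every analysis step runs on a synthetic distorted
phantom with known ground truth.

## The model

A single field `b` (mm of displacement along the PE axis `p`,
parametrized on anatomical space) describes both acquisitions: blip-up
displaces tissue by `+b`, blip-down by `-b`. Correction of each polarity
resamples the acquired image through its map and undoes the intensity
modulation given by the Jacobians

    Jac_up = 1 + db/dp,    Jac_down = 1 - db/dp = 2 - Jac_up,

so the pair sums to 2 identically. `Jac > 1` marks the polarity that
sampled the local tissue stretched (dense, trustworthy); `Jac < 1` the
squeezed, blurred one. The corrected pair `S_up, S_down` is combined by
the Jacobian-weighted average

    S_wa = (S_up f(Jac_up) + S_down f(Jac_down)) / (f(Jac_up) + f(Jac_down)),
    f(x) = 2 - 2 / (exp((|x| - x0) k0) + 1),

a Fermi weighting with offset `x0` (default 1: unit Jacobian means equal
weighting) and steepness `k0` (default 10: a ±20 % Jacobian deviation
already shifts the weights to roughly 88/12). The field itself is
estimated variationally (Gauss–Newton on a multiresolution pyramid,
conjugate-gradient inner solves) and then refined in a second,
"consecutive" pass driven by fractional-anisotropy maps computed from
the corrected data — FA edges constrain the field inside white matter
where b0 contrast is flat.

For g-ratio mapping the package computes, per voxel,

    AWF = (1 - v_iso) * v_icvf,    MVF = alpha * MTsat,
    AVF = (1 - MVF) * AWF,         g = sqrt(1 - MVF / (MVF + AVF)),

with `alpha` calibrated by bisection so that a reference region (a
deep-WM block standing in for the splenium) attains a target mean
g-ratio of 0.7; voxels where the diffusion and structural white-matter
masks disagree are recorded as exactly zero.

## Worked example

```r
library(epicombine)

ph  <- make_phantom(phantom_spec(seed = 1))        # seeded synthetic pair
res <- consecutive_pipeline(ph$up, ph$down, combine_method = "wa")
res
#> <pipeline_result> sequential apply mode, WA combination, max |b1| 6.61 mm, max |b2| 0.465 mm
res$jacobians_step1
#> <jacobian_pair> jac_up in [0.3336, 1.654], PE axis 2
```

The phantom's true field peaks at 6.8 mm (4 voxels); the first-pass
estimate recovers 6.61 mm of it, and the residual second-pass field is
an order of magnitude smaller — the consecutive refinement is a small
correction on top of a good b0-driven estimate. Comparing the weighted
average (WA) against the arithmetic mean (AM) of the same corrected
data, inside the mask where the Jacobian deviates from unity by more
than 20 %:

```r
am      <- combine_series(res$corrected_up, res$corrected_down,
                          res$jacobians_step1, method = "am")
truth   <- mean_b0(ph$truth$clean_dwi)             # ground-truth b0
mask20  <- distortion_mask(res$jacobians_step1$jac_up, 0.20)
#  RMS b0 error vs truth in the 20% distortion mask:
#    WA: 0.126
#    AM: 0.156
```

and the white-matter coverage of the structural reference by
segmentations of each combination, overall and inside the 10/20/30 %
distortion masks:

```r
overlap_table(list(am = wm_probability(fit_tensor(am, res$brain_mask)),
                   wa = wm_probability(fit_tensor(res$combined, res$brain_mask))),
              ph$truth$wm_prob,
              epi_volume(res$jacobians_step1$jac_up, 1.7))
#>   method deviation overlap
#> 1     am       0.0   99.82
#> 2     am       0.1   99.20
#> 3     am       0.2   98.30
#> 4     am       0.3   96.82
#> 5     wa       0.0  100.00
#> 6     wa       0.1  100.00
#> 7     wa       0.2  100.00
#> 8     wa       0.3  100.00
```

The plain mean loses white-matter coverage exactly where distortion is
strongest (96.8 % in the 30 % mask), while the weighted average keeps
it — the coverage gap widens with the deviation threshold. Those lost
voxels are the ones that would be zero-filled in a g-ratio map.

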