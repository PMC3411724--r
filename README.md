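# mmtweezers

Quantitative models and analysis for **multiplexed magnetic tweezers
(MMT)** experiments on DNA-bead tethers, for single-molecule biophysicists
who want to design, simulate or analyze parallelized tweezers assays
without writing the numerics themselves.

Magnetic tweezers hold a DNA molecule between a surface and a
superparamagnetic bead and pull on it with an external magnet pair;
multiplexing tracks tens to hundreds of beads in one field of view. At that
scale the usual single-molecule shortcuts break: the force is no longer
uniform across the field of view, bead-specific magnetization and eccentric
DNA attachment can no longer be selected away, and every correction has to
run automatically. This package implements that machinery:

* **Magnetostatics** — the antiparallel magnet pair modelled as fictitious
  charge sheets (closed-form field of a uniformly charged rectangle), the
  induced bead moment `m(B) = V·M_sat·[coth(B/B₀) − B₀/B]`, force maps
  `F = m(|B|)∇|B|` across the field of view, force angles, and the
  exponential force–height law `F(Z) = F₀·exp(−(Z_mag − 1 mm)/l_dec)`.
* **WLC elasticity** — `F(x) = (k_BT/L_p)[1/4(1−x)⁻² − 1/4 + x + Σaᵢxⁱ]`
  with the Bouchiat seven-parameter correction, exact stretching energy,
  and the force→extension inverse.
* **Tether dynamics** — overdamped Euler–Maruyama simulation of the bead
  with Faxén wall-corrected drag, thermal noise, a magnet ramp, and a
  camera model (exposure blur + tracking noise).
* **Rotation analysis** — the bicircular Limaçon pattern traced by a
  misaligned, eccentrically attached tether under magnet rotation
  (precession at 2ω_mag, attachment rotation at ω_mag), fitted by linear
  least squares; attachment offset `A = R − √(R² − R_att²)` and its
  sphere-geometry probability density.
* **Elasticity pipeline** — surface-reference and attachment corrections,
  blur-corrected equipartition force calibration, reorder-then-integrate
  energy curves (`E(l) = ∫F dl`), WLC fitting of `E(l)`, the 28 nm
  multiple-tether classifier, and ensemble statistics.
* **Synthetic experiments** — a generator that emulates a full multiplexed
  protocol (holds, zero-force recording, rotation, calibration, ramp) with
  ground truth, so the entire chain is testable end to end.

## A worked example

Characterize a small synthetic ensemble of 7.3 kb tethers (contour length
2.482 µm) with realistic thermal and tracking noise:

```r
library(mmtweezers)

cfg <- ensemble_config(n = 24, contour_lengths = 2.482)
res <- run_full_protocol(cfg, seed = 2)
print(res)
```

```
MMT protocol run: 24/24 beads characterized (seed 2)
Ensemble of 24 tethers (0 outliers with L_p < 28 nm removed)
      group  n mean_L_p sd_L_p mean_L_c  sd_L_c
1 Lc=2.48um 24     48.2   1.36     2.49 0.00415
  sigma of F_0/<F_0>: 0.123
  attachment offsets vs expected density: KS D = 0.106 (p = 0.926)
```

Reading the output: the fitted contour length recovers the true 2.482 µm
almost exactly, while the mean persistence length (48.2 nm) sits below the
true 50 nm — the known downward bias of tweezers elasticity measurements
caused by thermal fluctuations through the nonlinear force law, which
grows as molecules get shorter. The spread of the per-bead force scale
(`sigma 0.123`) recovers the generated bead-to-bead magnetization spread
(0.11) within sampling error, and the measured attachment offsets are
statistically consistent with the sphere-geometry density.

The field model on its own:

```r
asm <- magnet_assembly()   # 5 mm cube magnets, 1.4 T, 2 mm gap
bead <- bead_model()       # MyOne: R = 0.525 um, M_sat = 43.3 kA/m, B_0 = 12 mT
force_map(asm, bead, Z_mag = 1, fov_extent = 400, grid_n = 41)
#> Force map at Z_mag = 1 mm (400 x 400 um, 41 x 41 grid, mode m_gradB)
#>   |F_z| variation: 1.263 %   |F| variation: 1.344 %   max angle: 4.28 deg

fit_force_decay(force_vs_height(asm, bead, c(1, 8), 50, mode = "grad_mB"))
#> Exponential force decay (Z_ref = 1 mm, range 1-8 mm, mode grad_mB):
#>   F_0 = 4.065 pN   l_dec = 1.867 mm
#>   max relative error 6.88 %   max absolute error 46.4 fN
```

So at a magnet height of 1 mm the force is uniform to ~1.3% over a
400×400 µm field of view, and the on-axis force decays exponentially with
a 1.87 mm decay length over the 1–8 mm working range.

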