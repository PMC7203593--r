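# spinewise

Multi-body quasi-statics of the lumbar spine, and the calibration problem
that comes with it: published ligament force–strain data scatter so widely
that a spine model inherits essentially arbitrary passive behaviour from the
data set it happens to import. `spinewise` implements the alternative:
extract the disk and ligament characteristics of a *specific* motion segment
by re-enacting a stepwise reduction experiment backwards — the protocol in
which the supraspinous, interspinous, flaval and capsular ligaments, the
vertebral arches, and the longitudinal ligaments are removed one at a time
from an L4–L5 functional spinal unit while the range of motion (ROM) under
pure moments of {0, 1, 2.5, 5, 7.5, 10} Nm is recorded at every stage.

The package is aimed at musculoskeletal modellers who want segment-specific
passive characteristics rather than literature transplants, and at anyone
who needs a lightweight, fully scriptable rigid-body spine segment model
in R.

## The model

Each motion segment couples two rigid vertebrae through

* an intervertebral-disk bushing with the odd tanh-cubic torque–angle law
  per anatomical axis,

  T(φ) = p₁ · tanh(φ³ / p₂) + p₃ · φ   (φ in rad, T in Nm),

  separate flexion/extension rows, a compression-only axial polynomial
  F(r) = 690 234 060 r² + 659 748 r and linear shear;
* point-to-point ligaments with the smooth softplus force–strain law

  F(ε) = a · ln(e^{(ε+b)/d} + 1) + c   (ε in %, F in N),

  physiological prestrain, optional negative-strain branch, and a
  non-negativity clamp (cables cannot push);
* facet joints as convex cubic regression surfaces
  f(x, y) = p₃₀x³ + p₀₃y³ + p₂₀x² + p₀₂y² + p₀₀ (mm) fitted to nine
  landmarks per articular process, with probe-point penalty contact
  (≈ 12 000 N/m);
* constant-force muscle cables (40 N per cable, 80 N per pair) for the
  chain experiments.

Equilibria are found by damped Newton iteration with finite-difference /
Broyden Jacobians, an active-set treatment of the piecewise force laws, and
a homotopy fallback. Intradiscal pressure (IDP) is estimated from the axial
disk force as IDP ≈ 1.68 · F / CSA.

The core method, `run_backward_calibration()`, walks the reduction stages
from the disk-only state back to the intact segment: each stage clamps the
recorded ROM, equilibrates the remaining degrees of freedom with the
already-calibrated elements, attributes the deficit moment to the one new
element, and fits its law by trust-region least squares. Forward drivers
re-simulate the full 8 × 4 × 5 = 160-scenario ROM protocol and the
7 × 7 = 49-scenario IDP protocol and count outliers against experimental
ranges.

## Worked example

The package ships a synthetic-data generator, so the complete
calibrate-then-validate loop runs without any external data:

```r
library(spinewise)

cfg   <- synth_config(seed = 1)
geom  <- make_synthetic_fsu(cfg)                 # non-anatomical L4-L5 unit
truth <- default_characteristics()               # packaged parameter set
eds1  <- simulate_eds1(geom, truth, cfg)         # stepwise-reduction table

cal   <- run_backward_calibration(eds1, geom)    # the backward calibration
print(cal)
#> <calibrated_model>
#> <disk_characteristic>
#>   flexion   p1 = 10.67     p2 = 0.005913  p3 = -1.685
#>   extension p1 = 5.196     p2 = 0.008417  p3 = 24.5
#>   lateral   p1 = 6.929     p2 = 0.001482  p3 = 19.76
#>   axial     p1 = 4.399     p2 = 0.001141  p3 = 42.38
#>   axial 6.90234e+08 r^2 + 659748 r (compression only); shear 2.6e+05 N/m
#>   facet stiffness 1.201e+04 N/m (from 6 samples)
#>   ALL  a =    172.8  b =   -10.05  c =   -26.55  d =    5.609  (rmse 0.00165 N)
#>   PLL  a =     35.6  b =   -38.06  c =   -2.477  d =    14.34  (rmse 0.00222 N)
#>   CL   a =    50.89  b =    6.116  c =   -39.23  d =    39.59  (rmse 2.05 N)
#>   FL   a =    48.56  b =    5.027  c =    56.49  d =   -11.28  (rmse 0.0768 N)
#>   ISL  a =   0.3602  b =   -3.389  c =  0.07053  d =  0.01924  (rmse 0.0474 N)
#>   SSL  a =        0  b =        0  c =        0  d =        1  (rmse 0.0498 N)

resim <- run_stepwise_forward(cal, geom)         # 192 forward equilibria
count_outliers(resim, eds1, mode = "range")$count
#> [1] 0
```

The printed disk rows reproduce the generating parameters to the four
significant digits they are conventionally reported at; the fitted facet
stiffness lands within a fraction of a percent of the generating
12 000 N/m; the anterior-longitudinal softplus row comes back at
(172.8, −10.05, −26.55, 5.609) against a generating
(173.5, −10.06, −26.82, 5.625), and even the concave flaval row is
recovered; the supraspinous ligament, which never engages in this
geometry's motion range, is correctly identified as force-free. The
re-simulated ROM stays inside every synthetic experimental range (zero
outliers of 160 scenarios). `tidy(cal)` returns every fitted parameter as
a tibble, `autoplot(cal)` draws the per-ligament characteristic panels.

For the chain experiment:

```r
spine <- make_synthetic_spine(cfg)
idp   <- run_idp_protocol(spine, cal)            # 49 chain equilibria
```

A thin CLI over the same functions lives at `inst/cli/spinewise.R`
(`synth`, `calibrate`, `simulate-rom`, `simulate-idp`, `count-outliers`,
`fit-facet`).

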