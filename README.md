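# oesoEIT

Simulation study of an internal (oesophageal) electrode for cardiac-region
electrical impedance tomography (EIT).

EIT reconstructs internal conductivity from boundary current injections and
voltage measurements. With all electrodes on the skin, sensitivity is worst
at the centre of the chest — where the heart sits, shielded by the
resistive lungs — so cardiac targets image poorly. This package asks, fully
in silico, how much a single electrode moved into the oesophagus (directly
behind the heart) improves cardiac-region difference imaging compared with
the conventional all-external ring.

It provides, end to end:

* **Phantoms** — a deterministic graded tetrahedral mesher for a cylindrical
  thorax (diameter 2, height 0.8 model units) with 16 electrodes (D = 0.1,
  centred at z = 0.4), two lung cylinders (0.13 S/m), a blood target
  (0.7 S/m) in a 0.48 S/m background and, in the internal arrangement, an
  axial oesophageal channel carrying electrode 16.
* **Forward model** — complete-electrode-model (CEM) FEM with contact
  impedance, adjacent-pair stimulation at 1 mA (16 x 13 = 208 voltages per
  frame), and Gaussian measurement noise at 0.05% of the signal.
* **Inversion** — adjoint-method conductivity Jacobian, one-step linearized
  Tikhonov difference reconstruction

  argmin ||L_n(dV − J dσ)||² + λ² ||L_δσ(dσ − dσ*)||²,

  with the regularization parameter chosen automatically at the L-curve
  corner (maximum curvature of the log residual / log seminorm curve).
* **Evaluation** — GREIT-style figures of merit on a 64 x 64 mid-plane
  raster: amplitude response (AR), position error (PE), resolution (RES),
  shape deformation (SD) and ringing (RNG), via the quarter-amplitude
  pixel set.
* **Study drivers** — the target position sweep (offsets 0.2 to 0.8 towards
  electrode 9), the arrangement comparison table at the cardiac position
  (offset 0.5), voltage-profile traces, and the near/far detectability
  pair, all deterministic under a single seed.

The forward and inverse stages always use distinct meshes (inverse-crime
guard). See the methods vignette (`vignettes/oesoEIT-methods.Rmd`) for the
model details, parameter choices and known limitations.

## Worked example

The headline experiment — both electrode arrangements, D = 0.1 blood target
at 0.5 units from the centre, 0.05% noise, metrics averaged over 60 noise
replicates (about a minute of compute):

```r
library(oesoEIT)
tb <- run_table1()        # defaults: seed 1, 60 noise replicates
print(tb$table, digits = 3)
#>   arrangement    AR     PE    RES   SD lambda_corner
#> 1    external 0.533 0.0449 0.1009 26.0      0.000284
#> 2    internal 0.617 0.0367 0.0962 24.7      0.000251
```

Reading the rows: moving electrode 16 into the oesophagus raises the
amplitude response of the cardiac target (0.62 vs 0.53 of the true
contrast), roughly 20% better localization (position error 0.037 vs 0.045
model units, i.e. a few percent of the tank radius), a slightly tighter
reconstructed blob (RES, SD), and a smaller optimal regularization
parameter (2.5e-4 vs 2.8e-4) — the inverse problem is better conditioned
with the internal electrode. All five orderings favour the internal
arrangement.

The lower-level API exposes each stage:

```r
spec <- phantom_spec("internal")
ph   <- build_phantom(spec, "forward")          # ~35k-element mesh
sig0 <- assign_conductivity(ph$mesh, spec, include_target = FALSE)
sig1 <- assign_conductivity(ph$mesh, spec, target_offset = 0.5)
prot <- adjacent_protocol(16)
f0   <- solve_forward(assemble_cem(ph$mesh, sig0, ph$electrodes), prot)$frame
f1   <- solve_forward(assemble_cem(ph$mesh, sig1, ph$electrodes), prot)$frame

inv  <- build_phantom(spec, "inverse")          # distinct discretization
J    <- compute_jacobian(inv$mesh,
                         assign_conductivity(inv$mesh, spec,
                                             include_target = FALSE),
                         inv$electrodes, prot)
rc   <- reconstruct_at_corner(J, difference_frame(f1, f0),
                              prior_model(L_dsigma = sqrt(inv$mesh$volumes)))
img  <- rasterize(rc$recon, inv$mesh)
merit_report(img, target_truth(spec, 0.5), rc$lcurve)
```

A thin command-line wrapper over the same drivers lives at
`inst/cli/oesoeit.R` (subcommands `build-phantom`, `simulate`, `sweep`,
`table1`, `profiles`, `image-pair`).

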