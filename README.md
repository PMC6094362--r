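# microswim

Tools for predicting and optimizing the swimming performance of a model
robotic bacterium in Stokes flow: a rigid spherical head of radius *R*
propelled by a rotating helical flagellum (amplitude *b*, pitch *λ*,
*N<sub>λ</sub>* turns, cross-section radius *r*), with a motor imposing the
relative rotation rate *ω* = Ω<sub>head</sub> − Ω<sub>flagellum</sub> about
the common axis.

The package is aimed at people designing or analyzing bioinspired
microswimmers who need to know how much the popular simplified predictions
can be trusted.  It implements three levels of hydrodynamic fidelity side
by side:

1. **Resistive force theory (RFT)** — local drag coefficients per unit
   filament length (Gray–Hancock and Lighthill models);
2. **Purcell's additive approximation (AA)** — the assembly resistance as
   the sum of the isolated head and flagellum resistances, with the
   force-free/torque-free balance

   *U* = *C₀B ω* / ((*C₀*+*C*)(*A₀*+*A*) − *B*²);

3. **the global approach (GA)** — a fully coupled regularized-Stokeslet
   boundary-integral solver for the rigid assembly, yielding partwise
   resistance blocks (each part's contribution computed *in the presence
   of* the other) whose sum is the true assembly resistance.

Because the additive approximation ignores hydrodynamic screening between
head and tail, its speed predictions are off by ~10% even for long tails,
and RFT predictions by up to ~40%.  The package implements the scalar
geometric correcting factor

υ = (*A₀*+*A*)(*B₁*+*B₂*) / ((*A₁*+*A₂*) *B*),

built from one coupled solve, which repairs the simplified speed
predictions by roughly an order of magnitude, plus six performance measures
(energetic, propulsion, and swimming efficiencies with corrected variants)
and flagellar-length sweeps and optimizers.

## Worked example

Solve the reference swimmer (helix *r* = *b*/16, *λ* = 8*b*,
*N<sub>λ</sub>* = 2, head *R* = 2*b*, with *μ* = *b* = *ω* = 1) and compare
all models:

```r
library(microswim)

asm  <- assembly_spec(head_spec(2), filament_spec(1, 8, 2, 1/16))
disc <- assemble(asm)                 # 600 head nodes + 64 flagellum panels
solve_global(disc, omega = 1)
#> Swim solution (global): U = -0.0879683, Omega = 0.187124, T_motor = 40.4287 (omega = 1)
#>   residuals: force 0, torque 7.11e-15

compare_speed_models(asm)
#>                        model        U error_pct
#> 1                     global -0.08797        NA
#> 2                   additive -0.09676     9.996
#> 3         additive_corrected -0.08494     3.440
#> 4           rft_gray_hancock -0.10099    14.802
#> 5 rft_gray_hancock_corrected -0.08962     1.877
#> 6              rft_lighthill -0.12476    41.827
#> 7    rft_lighthill_corrected -0.08201     6.768
```

`U` is the axial swimming speed (negative: a right-handed helix driven at
*ω* > 0 swims toward −x in this sign convention), `Omega` the head counter
rotation, `T_motor` the motor torque.  `error_pct` is each simplified
model's relative speed error against the coupled solution; the `_corrected`
rows apply the υ factor, cutting the Gray–Hancock RFT error from ~15% to
~2% and the Lighthill error from ~42% to ~7%.

Length sweeps and optimal design:

```r
fam <- assembly_spec(head_spec(2), filament_spec(1, 2.42, 2, 1/16))
sw  <- sweep_lengths(fam, 1:14)                 # global / additive / corrected
opt <- optimize_length(fam, metric = "speed", method = "global",
                       bracket = c(1, 20))      # interior optimum of |U|
```

A thin command-line wrapper (`inst/scripts/microswim.R`) drives the same
functionality from YAML configs:
`Rscript microswim.R swim --config cfg.yaml --out results/`.

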