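# extrurtd

Residence time distribution (RTD) analysis and image-based texture
prediction for twin-screw extrusion, in R.

## Who this is for

Food-process engineers texturizing plant protein (or running any
twin-screw extrusion) face two recurring measurement problems:

1. The barrel is a black box. How long does material actually spend
   inside, and is the flow closer to plug flow or to a stirred tank?
   The standard answer is a **pulse-tracer RTD experiment**: inject a
   dye pulse at the inlet, sample the die every few seconds, and reduce
   the concentration curve to a handful of numbers.
2. Texture profile analysis (TPA) of the product is destructive and
   slow. Can a photograph stand in for the texture analyzer? The
   standard answer is an **image-feature regression**: mean CIELAB
   colour plus a co-occurrence contrast statistic, fed to a small
   neural network.

`extrurtd` implements both workflows end to end, plus synthetic
generators that stand in for the extruder and the camera so everything
is testable offline.

## The statistics

From a sampled tracer curve `C(t_i)` the package computes, with
segment sums (`Δt_i = t_i − t_{i−1}`):

```
E(t_i) = C_i / Σ_j C_j Δt_j                exit-age density
F(t_i) = Σ_{j≤i} E_j Δt_j                  cumulative distribution
MRT    = Σ C_i t_i Δt_i / Σ C_i Δt_i       mean residence time
σ²     = Σ C_i t_i² Δt_i / Σ C_i Δt_i − MRT²
θ      = t/MRT,  E(θ) = MRT·E(t),  σθ² = σ²/MRT²
```

and the Peclet number by inverting the closed-vessel axial-dispersion
relation `σθ² = 2/Pe − (2/Pe²)(1 − e^(−Pe))` (bracketed root finding;
monotone, so always solvable for `σθ² ∈ (0,1)`).

The texture model is a 4-input sigmoid-hidden-layer regressor trained by
backpropagation (learning rate 0.01, max 1000 iterations), with initial
weights optionally chosen by particle swarm optimization or a real-coded
genetic algorithm, and evaluated by MAE, RMSE, MAPE and Pearson r.

## Worked example: RTD of a simulated run

```r
library(extrurtd)

spec <- sim_spec("tanks_in_series", mrt_true = 170, n_tanks = 12,
                 sample_interval = 10, duration = 1020,
                 noise_sd = 0.004, seed = 42)
run <- simulate_tracer(spec)
analyze_run(run, baseline = 0.008)
```

```
<rtd_summary> sim:tanks_in_series
  MRT            167.99 s
  variance      2116.80 s^2
  sigma_t^2     0.07501
  Peclet          25.62
```

The generator's ground truth is MRT = 170 s and σθ² = 1/12 ≈ 0.0833
(Pe ≈ 22.95): the MRT is recovered to ~1%, while the variance — the
noise-sensitive second moment at 10 s sampling with read noise of 1% of
peak — lands within ~10%, putting Pe within ~12%. A Pe above ~10 says
the simulated flow has limited axial mixing, i.e. leans toward plug
flow. Published operating-condition tables are reproduced exactly from
their printed moments:

```r
solve_peclet(5823.00 / 186.19^2)   # 10.8049  (printed 10.80 ± 0.46)
relative_change(186.19, 169.72)    # 8.8458   (printed "about 8.8%")
```

## Worked example: texture prediction on synthetic data

```r
dat <- generate_dataset(synth_dataset_spec(seed = 1))   # 118 samples
run_experiment(dat, "hardness", optimizer = "ga",
               config = train_config(seed = 7))
```

```
<texture_fit> hardness, optimizer = ga, 6 hidden nodes
<metric_report> n = 28
  MAE  94.8488
  RMSE 120.88
  MAPE 2.351%
  r    0.99597
```

The same seed without an optimizer (`optimizer = "none"`) gives test
RMSE 342.5: at the default learning rate plain backpropagation is badly
undertrained, which is exactly what the GA/PSO initialization fixes.

## Command line

```sh
extrurtd rtd simulate --model tanks --n-tanks 25 --mrt 170 --interval 10 \
         --noise 0.005 --seed 1 --out sim.csv
extrurtd rtd compute --input sim.csv --out summary.json --curves curves.csv
extrurtd calibrate feed --vmf 100 --cin 7 --cex 65
extrurtd synth dataset --seed 3 --out data.csv
extrurtd texture train --data data.csv --attribute hardness \
         --optimizer ga --seed 7 --out model.json
extrurtd features extract --images shots/ --out features.csv
extrurtd texture predict --model model.json --features features.csv \
         --out predictions.csv
```

Images are 8-bit PNM (PPM/PGM); see the methods vignette for why.

## Documentation

The methods vignette (`vignettes/extrusion-rtd-texture.Rmd`) documents
the models, discretization and baseline policy, optimizer defaults, what
the synthetic generators do and do not emulate, and known limitations.
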