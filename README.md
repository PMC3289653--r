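# pathcv

Free-energy simulation with **path collective variables** on desk-scale model
systems: steered guess-path generation, iterative path refinement, umbrella
sampling, WHAM reconstruction with bootstrap errors, and the downstream
free-energy-surface analyses — all exercised against systems whose answers
are known exactly.

## Who this is for

Methods developers and students of enhanced-sampling molecular simulation who
want a complete, tested, inspectable implementation of the path-variable
free-energy workflow used in computational enzymology — without a cluster, a
QM/MM engine, or opaque reference data. Every stage of the pipeline runs in
seconds-to-minutes on one core against analytic fixtures (double wells,
two-channel reactive surfaces, charged clusters), and every statistical claim
is graded against quadrature, closed forms, or dense-grid search.

## The method

Given a reference path of frames $R(1),\dots,R(N)$ and the mean-square
displacement metric $D$, the two path collective variables are

$$S(R) = \frac{\sum_i i\,e^{-\lambda D(R,R(i))}}{\sum_i e^{-\lambda D(R,R(i))}},
\qquad
Z(R) = -\tfrac{1}{\lambda} \ln \sum_i e^{-\lambda D(R,R(i))},$$

the progress along and squared distance from the path, with
$\lambda = 2.3/\langle D_{i,i+1}\rangle$. The workflow mirrors the enzyme
literature: steer simple reaction coordinates stage by stage to produce a
guess trajectory; reparameterize it into equally spaced frames; pull the
system along $S$ under a quartic wall on $Z$ and iterate until the path stops
changing; run umbrella windows along the converged path (or along a plain
distance coordinate); reconstruct $F$ by WHAM,

$$P(b) \propto \frac{\sum_w n_w(b)}{\sum_w N_w e^{(f_w - U_w(b))/kT}},
\qquad f_w = -kT\,\ln\sum_b P(b)\,e^{-U_w(b)/kT};$$

then analyse: minimax minimum free-energy path and its saddle, projection
onto $S$, observables binned along $S$, steered-work barriers
($\langle W\rangle \ge \Delta F$), gradient projections, and
zero-point-charge mutant scans. The methods vignette
(`vignettes/path-variable-free-energy-methods.Rmd`) documents every model,
parameter and design choice.

## Worked example

Recover the barrier of a tilted double well (the exact answer is
closed-form) from a 22-window umbrella campaign:

```r
library(pathcv)

dw <- make_double_well(barrier = 3, separation = 0.7, tilt = 1)
dw$analytic$barrier_forward
#> [1] 3.523422

params <- langevin_params(n_steps = 0, seed = 501, kT = kT_kcal(300),
                          friction = 5, timestep = 0.002)
camp <- umbrella_campaign(cv_coordinate(1, "x"),
                          centers = seq(-0.525, 0.525, by = 0.05), k = 300,
                          steps_per_window = 20000, seed = 501,
                          discard = 0.5, stride = 5, x0 = -0.35)
wins <- run_umbrella(dw, camp, params)
fes  <- bootstrap_errors(wins, n_boot = 30, seed = 501, bins = 100)
fes
#> <fes_grid> 100 bins over (x), 100 occupied, kT = 0.5962 kcal/mol
#>   F range: 0 .. 5.305 kcal/mol; mean error 0.107
#>   WHAM: 1 polish sweeps, residual 2.47e-08
```

The reconstructed profile tracks the analytic potential to ~0.1 kT on
well-sampled bins, and the recovered barrier brackets the analytic 3.52
kcal/mol within a few bootstrap errors — the residual gap is the known
binning bias plus sampling noise, both quantified by the tests. `plot(fes)`
draws the profile with its error band.

The two-channel pipeline (guess path → `optimize_path()` → 2D S/Z umbrella
campaign → `wham_solve()`/`bootstrap_errors()` → `minimum_free_energy_path()`)
is wired end-to-end in the `demo` subcommand of the thin CLI:

```sh
Rscript inst/scripts/pathcv demo config.yaml   # config: seed + output dir
```

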