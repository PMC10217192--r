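# landaucell

Stem cell differentiation as self-regulated symmetry breaking: a Landau
mean-field model in which the intrinsic gene-expression noise of a cell
population is itself a dynamical variable under negative feedback.

## The model

A scalar order parameter $m$ summarizes the population's average cell state
($m = 0$ pluripotent, $m \neq 0$ differentiated) and evolves on the Landau
free energy

$$V(m,\xi) = -\tfrac{1-\xi}{2}m^2 + \tfrac{\alpha}{3}m^3 +
\tfrac{\beta}{4}m^4 + \tfrac{\gamma}{6}m^6,$$

where the intrinsic noise $\xi$ plays temperature's role. Finite population
size enters as weak additive forcing, and the noise obeys a feedback law
with gain $G$ and set-point $M$:

$$dm_t = -\partial_m V\,dt + \sigma\,dW_t, \qquad
d\xi_t = G\,(m_t^2 - M^2)\,dt .$$

The feedback lets the population steer *itself* through pitchfork,
saddle-node, transcritical and Hopf bifurcations, so that differentiation —
including into oscillatory cell states (limit cycles) and noise-induced
hybrid states — happens by spontaneous symmetry breaking rather than by an
externally scheduled noise ramp. The package provides:

* the potential/drift/feedback laws and closed-form equilibria
  $E_\pm = (\pm M,\, 1 \mp \alpha M - \beta M^2 - \gamma M^4)$, with three
  named presets (`model1`, `model2`, `model3`);
* Jacobian, trace–determinant (Poincaré) classification, Hopf-point
  location, admissible parameter bounds;
* fixed-noise bifurcation analysis: branch diagrams, critical noise values,
  ground states, hysteresis sweeps;
* Euler–Maruyama simulation (compiled core) of paths and reproducible
  ensembles;
* ensemble observables: time-resolved densities, quasi-potential
  (Waddington landscape), fate fractions, limit-cycle summaries, phenotype
  switching statistics;
* ggplot2 `autoplot()` methods, broom-style `tidy()`/`glance()`, text
  writers/readers, and a thin CLI (`exec/landaucell`).

## Worked example

```r
library(landaucell)

m2 <- landau_model("model2")
tidy(critical_noise(m2))
#> # A tibble: 1 × 5
#>   model   xi_c xi_transition xi_saddle transition_order
#>   <chr>  <dbl>         <dbl>     <dbl> <chr>
#> 1 model2  1.00          1.19      1.25 first
```

Pluripotency destabilizes at `xi_c = 1`; the non-zero cell states appear at
the fold `xi_saddle = 1.25`; in between, at `xi_transition = 1.1875`, the
ground state jumps discontinuously — a first-order transition, so this model
shows hysteresis (phenotypic memory).

```r
run_stability(m2, G = 0.05, M = 0.68)
#> <landau_stability_report 'model2'> G = 0.05, M = 0.68 (admissible M < 1.27202)
#> # A tibble: 2 × 9
#>   branch      m    xi  trace    det discriminant re_lambda1 im_lambda1 label
#> 1 E_plus   0.68  1.25 0.0695 0.0462       -0.180     0.0348      0.212 unstable_spiral
#> 2 E_minus -0.68  1.25 0.0695 0.0462       -0.180     0.0348      0.212 unstable_spiral
#> <landau_hopf> Mc = 0.70710678 on branch E_both (det = 0.05 > 0), ...
```

At `M = 0.68`, just below the Hopf point `Mc = sqrt(2)/2`, both equilibria
are unstable spirals — the attractor is a limit cycle, an oscillatory cell
state:

```r
traj <- simulate_path(m2, G = 0.05, M = 0.68, sigma = 0,
                      m0 = 0.001, xi0 = 1.5, t_final = 800,
                      record_stride = 20L)
limit_cycle_summary(traj)
#> <landau_cycle> counterclockwise limit cycle: period 44.69, m-amplitude 0.318,
#>                mean point (0.6444, 1.171)
```

The canonical symmetry-breaking experiment — 200 stochastic trajectories
started pluripotent at high noise — commits half the population to each
differentiated fate:

```r
m1 <- landau_model("model1")
ens <- simulate_ensemble(m1, G = 0.6, M = 0.2, sigma = 1e-4, n_traj = 200,
                         master_seed = 10, m0 = 0, xi0 = 1.5, t_final = 150)
fate_fractions(ens, equilibria(m1, G = 0.6, M = 0.2), radius = 0.1)
#> # A tibble: 3 × 3
#>   label         n fraction
#> 1 E_plus      100      0.5
#> 2 E_minus     100      0.5
#> 3 undecided     0      0
```

`autoplot(pdf_over_time(ens))` shows the density funnelling from the
pluripotent ridge into the two differentiated valleys;
`autoplot(quasi_potential(pdf_over_time(ens)))` renders the same history as
a Waddington-style landscape.

## Layout

* `R/` — model core, stability analysis, fixed-noise bifurcation analysis,
  simulation wrappers, ensemble observables, tidiers, plots, runners and IO
* `src/em.cpp` — compiled Euler–Maruyama and relaxation loops
* `vignettes/self-regulated-landau.Rmd` — methods: model, assumptions,
  numerical choices, limitations
* `exec/landaucell` — command-line wrapper (`stability`, `bifurcate`,
  `simulate`)
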