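# homeostab

Stability analysis of homeostatic intrinsic plasticity in neurons and
recurrent networks.

Neurons regulate their own excitability: an activity sensor (intracellular
calcium, time constant τ₂ ≈ 50 ms) reads out a low-pass-filtered copy of
the firing rate (τ₁ ≈ 10 ms), and a perfect integrator accumulates the
deviation of that sensor from a target rate and feeds it back as a firing
threshold,

    τ₁ ṙ₁ = −r₁ + g(u − θ),   τ₂ ṙ₂ = −r₂ + r₁,   τ₃ ṙ₃ = r₂ − r_goal,
    θ = r₃ .

The integrator guarantees that the target rate is eventually reached — but
only if the loop is stable.  This package implements the analytic stability
theory of that loop and the numerical experiments that probe it:

- **Closed-form criteria.**  Routh–Hurwitz conditions for the
  characteristic cubic of one loop or one network eigenmode, for real
  (`tau3_crit_network()`) and complex (`tau3_crit_complex()`,
  `routh_hurwitz_complex()`) weight-matrix eigenvalues; the
  oscillation-free bound (`tau3_osc_free()`), i.e. the smallest integrator
  time constant for which even damped ringing disappears; regime
  classification (`classify_regime()`); critical recurrence
  (`critical_recurrence()`).
- **Nonlinear (global) criteria.**  Sector bounds in the sense of the
  Aizerman conjecture, replacing the set-point slope of the f-I curve by
  its envelope slope (`fi_envelope_slope()`, `aizerman_tau3_single()`,
  `aizerman_tau3_network()`, `sector_check()`).
- **Feedback cascades and parallel controllers.**  Characteristic
  polynomials of K-stage feedback chains (`cascade_roots()`,
  `cascade_max_recurrence()`) and of two integral controllers sharing one
  error signal (`parallel_controller_spectrum()`).
- **Rate-model simulation.**  A fast fixed-step integrator (RK4 /
  Euler–Maruyama with exact Ornstein–Uhlenbeck input noise) for single
  modes and heterogeneous networks (`simulate_rate()`), empirical regime
  detection (`detect_regime_empirical()`), heterogeneity and noise
  experiments (`heterogeneity_sweep()`, `fluctuation_vs_recurrence()`),
  and the interference of homeostasis with an integrating network
  (`integrator_interference()`).
- **Spiking network.**  A conductance-based leaky integrate-and-fire
  network whose population rate drives a homeostatic bias current
  (`simulate_spiking()`), with recurrence calibration against the rate
  model (`calibrate_recurrence()`), empirical f-I measurement
  (`measure_fi()`) and the integrator-speed stability experiment
  (`stability_experiment()`).

## A worked example

How slow does homeostasis have to be?  For the reference loop
(τ₁ = 10 ms, τ₂ = 50 ms, unit gain):

```r
library(homeostab)

tau3_min_single(10, 50)        # 8.333333  -- instability below ~8 ms
tau3_osc_free(10, 50)          # 221.5425  -- damped ringing below ~220 ms

# a recurrent network with a 1 s integration time constant (wm = 0.99)
tau3_crit_network(10, 50, 1, 0.99) / 1000   # 4.761905  s
tau3_osc_free(10, 50, 0.99) / 1000          # 410.1891  s

# and with a 10 s time constant (wm = 0.999)
tau3_crit_network(10, 50, 1, 0.999) / 1000  # 49.75124  s
tau3_osc_free(10, 50, 0.999) / 3.6e6        # 11.13894  hours

classify_regime(neuron_params(10, 50, 100))
#> regime: damped_oscillatory
#> dominant eigenvalue: -0.00881412 +0.0108479i 1/ms
#> tau3 critical: 8.33333 ms, oscillation-free: 221.543 ms
```

A single neuron is thus stable with near-millisecond homeostasis, but a
strongly recurrent network needs homeostasis slower by orders of
magnitude — and the oscillation-free requirement grows with the *square*
of the network time constant.  That is the package's central quantitative
story; the vignette (`vignettes/homeostatic-stability.Rmd`) walks through
the model, the criteria, and every numerical experiment.

Command-line interface (thin wrapper over the same functions):

```sh
Rscript inst/cli/homeostab.R stability --tau1 10 --tau2 50 --tau3 100
Rscript inst/cli/homeostab.R single-phase-diagram --seed 1 --out results/
Rscript inst/cli/homeostab.R fixture --n 10 --target 0.8 --out W.csv
```

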