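# cpgrate

Firing-rate network models of a spinal central pattern generator (CPG)
module, built to ask one question: **what does the recurrent architecture of
a rhythm-generating module do to the distribution of firing rates across its
population?**

Experimental recordings from motor circuits — spinal interneurons of
mudpuppy, macaque, cat and turtle, and calcium imaging of glycinergic
interneurons in larval zebrafish — consistently show firing-rate
distributions that are skewed toward zero with a long tail, close to
lognormal. That shape is hard to reconcile with the textbook picture of a
CPG module as a purely excitatory recurrent network: such a network is
supercritical, so any effective input ignites a runaway escalation that
drives every neuron to its maximal rate, producing a narrow peak-rate
distribution clustered at the ceiling. Adding recurrent inhibition
(a balanced network) replaces the all-or-none behavior with a graded
response and broad, zero-skewed, lognormal-like rate distributions — the
experimentally observed shape. This package implements both architectures
and the analyses that separate them.

## The model

Each of N = 200 neurons carries an activity variable `x_i` (analogous to a
membrane potential) mapped to a rate by a saturating C¹ nonlinearity

    phi(x) = r0 * (1 + tanh[(x - r0)/r0])      x <= r0
    phi(x) = r0 + rmax * tanh[(x - r0)/rmax]   x >  r0

with `r0 = 10` (rate at the inflection point), `rmax = 80`, hence a
saturation ceiling of 90 (rates are in arbitrary units). The dynamics are

    tau_m dx_i/dt = -x_i + sum_j J_ij phi(x_j) - g_w w_i + I_e(t)
    tau_a dw_i/dt = -w_i + phi(x_i)

with `tau_m = 50 ms`, `tau_a = 300 ms`, integrated by forward Euler
(`dt = 1 ms`). Two architectures:

* **Pure excitation + adaptation** — weights `J_ij` drawn i.i.d. from a
  zero-mean Gaussian of width `sigma = 0.05` with negatives truncated to
  zero (about half the connections are absent), and adaptation strength
  `g_w = (1/N) sum_ij J_ij` (~3.99 at the defaults).
* **Balanced excitation–inhibition** — same weights, but the second half
  of the neurons are inhibitory: their outgoing columns are scaled by
  `g_i = -1.5`, and adaptation is off (`g_w = 0`). `scale_inhibition()`
  attenuates the inhibitory columns toward zero, emulating a
  pharmacological block (strychnine / picrotoxin-like).

The external drive `I_e(t)` is a negative holding baseline (−20) with
rectangular pulses of increasing amplitude (30, 40, 50 by default; 1 s wide,
1 s apart) imitating a rhythmic drive.

Supporting modules: a Galton–Watson branching-process simulator quantifies
sub-/super-/criticality of activity propagation (avalanche-size power law
`p(n) ~ n^(-3/2)` at branching ratio 1, transition located by a survival
sweep); distribution statistics (adjusted Fisher–Pearson skewness,
lognormal maximum-likelihood fits, histogram modes); and a synthetic
calcium-imaging generator producing per-animal populations of fluorescence
traces whose peak ΔF/F amplitudes follow a configurable lognormal (or
normal) law, for cohort-level skewness analysis.

## Worked example

```r
library(cpgrate)

e <- run_excitatory(experiment_config("excitatory", seed = 1))
b <- run_balanced(experiment_config("balanced", seed = 1))
e$stats[, c("window", "mean_peak", "skew_linear", "mode_estimate", "top_bin_frac")]
#>   window mean_peak skew_linear mode_estimate top_bin_frac
#> 1      1    89.551      -2.507          88.5            1
#> 2      2    89.642      -2.557          88.5            1
#> 3      3    89.719      -2.605          88.5            1
b$stats[, c("window", "mean_peak", "skew_linear", "mode_estimate", "top_bin_frac")]
#>   window mean_peak skew_linear mode_estimate top_bin_frac
#> 1      1     5.933       0.929           4.5            0
#> 2      2    11.771       0.733           7.5            0
#> 3      3    17.628       0.653          10.5            0
```

One row per drive pulse. The pure-excitatory network is all-or-none: the
mean peak rate is pinned at the ceiling (~89.6 of 90) for every pulse, the
histogram mode sits in the top bin (center 88.5) and 100% of peaks land
there, regardless of input size. The balanced network is graded: the mean
peak grows with pulse amplitude (5.9 → 11.8 → 17.6), every distribution is
positively skewed, and the mode stays near zero (4.5–10.5, far below the
ceiling).

The criticality analysis, at branching ratio 1:

```r
fit_powerlaw_exponent(simulate_branching(1, n_trials = 1e5,
                                         max_generations = 1e4, seed = 1))
#> <powerlaw_fit> alpha = 1.5078 (se 0.0032), n = 25966 at n_min = 10
```

— the critical avalanche-size exponent 3/2. And the synthetic zebrafish-like
cohort (10 animals × 50 cells, lognormal amplitudes):

```r
res <- cohort_skewness_analysis(generate_calcium_dataset(seed = 1))
range(res$skew_linear)              # 0.73 .. 2.80, positive in all animals
attr(res, "mean_abs_skew_log")      # 0.288 — near-normal on the log scale
```

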