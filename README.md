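# dynastim

State-dependent effects of single-pulse stimulation in a whole-brain
oscillatory network model, as a tested, reusable R pipeline.

Non-invasive brain stimulation lands on a network whose functional state
keeps changing, and the same pulse can shift ongoing oscillations, leave
them alone, or push the whole network into a different
functional-connectivity (FC) configuration depending on *when* and *where*
it arrives. `dynastim` provides the full in-silico machinery to study this:

* **Network model** — each of N cortical regions is an exact mean-field
  reduction of coupled excitatory (E) and inhibitory (I) quadratic
  integrate-and-fire populations (a PING-type E–I loop). Per region j:

  ```
  tau_e dr_e/dt = Delta_e/(pi tau_e) + 2 V_e r_e
  tau_e dV_e/dt = V_e^2 + eta_e + I_ext + I_stim + tau_e s_ee - tau_e s_ei - (pi tau_e r_e)^2
  tau_s ds_ee/dt = -s_ee + J_ee r_e + G_ee * sum_k SC[j,k] r_e[k]
  tau_s ds_ei/dt = -s_ei + J_ei r_i
  ```

  with mirrored I-population equations whose long-range term is scaled by
  `Gamma * G_ee` (long-range excitation targets both E and I). Coupling is
  instantaneous and integration is deterministic Heun at `dt = 5e-5`
  (compiled, bit-reproducible), so every stimulated trajectory has an exact
  matched control.
* **Regime metrics** — trough-interpolated instantaneous phase, rate
  summaries (`R_tot`, `R_het`, `R_var`), pairwise phase-locking values
  (PLV) and the network summaries `PLV_all` / `PLV_top`, plus a
  `(G_ee, I_ext)` sweep driver for choosing a working point.
* **Dynamic FC states** — sliding-window PLV (140 samples, 75% overlap), a
  global 54th-percentile link threshold, hub vectors, cross-correlogram
  phase lags, double agglomerative clustering (hub and lag patterns),
  discrete states Psi1–Psi3 + None, typicality-ranked prototypes and a
  k-nearest-neighbour state classifier for unseen windows.
* **Stimulation experiments** — phased single pulses (amplitude 300,
  delivered at 10 phases x 5 prototype windows x 5 cycles per state) with
  paired unstimulated controls; phase-shifting portraits wrapped to
  [-pi/2, pi/2), state-conditioned effective phase-response curves (PRCs)
  and stimulation-induced state-switching probabilities (delta-P).
* **Prediction** — random-forest regression of the induced late-window
  phase shift from state-ignorant vs state-aware feature blocks, with
  stratified cross-validation and rank-sum comparisons.
* **Synthetic data** — a surrogate generator for dense, directed,
  heavy-tailed tracer-like connectomes, and a planted-synchrony generator
  with known hub coalitions, lags and states that gives every downstream
  stage a ground truth.

## Worked example

```r
library(dynastim)

con <- generate_connectome(seed = 1)     # 29-region surrogate connectome
con
#> Structural connectome: 29 regions, density 0.66, directed

sim <- simulate_network(sim_config(seed = 2), nm_params(), con)
sim
#> Multivariate neural-mass time series
#>   regions: 29, samples: 3000, sampling interval: 0.01
#>   r_e range: [0.00353, 1.91e+03]

m <- rate_metrics(sim)
sprintf("R_tot = %.3f, R_het = %.3f, R_var = %.3f", m$R_tot, m$R_het, m$R_var)
#> "R_tot = 2.727, R_het = 0.125, R_var = 5.201"

ph <- extract_phase(sim)
s <- plv_summaries(plv_matrix(ph))
sprintf("PLV_all = %.3f, PLV_top = %.3f", s$PLV_all, s$PLV_top)
#> "PLV_all = 0.766, PLV_top = 0.977"
```

`nm_params()` defaults to the working point `G_ee = 80`, `I_ext = 6`: the
network sustains collective oscillations (realized period about 36 samples,
i.e. 0.36 time units) that are strongly but not perfectly phase locked —
the network average PLV is about 0.75 while the top quartile of pairs is
nearly fully locked, and different initial conditions settle into
different transient locking configurations. Those configurations are what
the FC-state stage discretizes:

```r
runs <- lapply(1:13, function(i)
  simulate_network(sim_config(seed = 1 + i, save_full = TRUE), nm_params(), con))
catalog <- extract_fc_states(runs, hub_threshold = 14)
classifier <- fit_state_classifier(catalog)
experiments <- run_stimulation_experiments(runs, catalog, con, classifier,
                                           regions = 5)
prc <- effective_prc(experiments)
sw  <- switching_statistics(experiments)
```

The whole protocol — connectome, runs, states, stimulation, PRC/switching
tables, prediction comparison — can also be driven from one declarative
configuration with caching and CSV/JSON outputs:

```r
report <- run_study(study_config(out_dir = "study_out"))
```

## Limitations

The original tracer connectome is not redistributable, so all results are
produced on a calibrated surrogate; see the methods vignette
(`vignettes/methods.Rmd`) for the calibration protocol, the realized
oscillation scale, numerical choices, and what the surrogate does and does
not reproduce.
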