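# reflexgait

Predictive planar gait simulation with reflex-based muscle control, in R.

`reflexgait` asks a question experiments cannot isolate: *which gait
adaptations follow from a specific muscle deficit, and nothing else?*
Weakness and contracture of the ankle plantarflexors (soleus, SOL;
gastrocnemius, GAS) co-occur with neural and skeletal problems in cerebral
palsy, stroke, muscular dystrophy and sarcopenia, so their independent
effects are confounded in patient data.  The package's approach is to
generate walking *de novo* — no motion tracking — from a physiologically
structured controller, then introduce an isolated deficit and re-train,
so any change in the resulting gait is attributable to the deficit alone.
It is aimed at biomechanists and motor-control researchers who want a
self-contained, scriptable version of this workflow.

## The model and the optimization problem

* **Plant**: a planar skeleton (trunk with locked lumbar joint, thighs,
  shanks, feet; 9 mobile degrees of freedom) actuated by 18 Hill-type
  muscle–tendon units (9 sagittal muscle groups per leg), with
  Hunt–Crossley foot–ground contact spheres and exponential ligament
  limit springs.
* **Controller**: a 5-phase gait state machine (early stance, mid-stance,
  pre-swing, swing, landing preparation) gating delayed reflex laws —
  constant, muscle length/velocity/force feedback, and pelvis-tilt PD
  control on the hip muscles:

  $u_C = K_C$, 
  $u_{L+} = \max(0, K_{L+}[l(t-t_D) - l_o])$, 
  $u_{V+} = \max(0, K_{V+} v(t-t_D))$, 
  $u_{F\pm} = \pm K_{F\pm} F(t-t_D)$, 
  $u_{PD} = K_p[\theta(t-t_D) - \theta_o] + K_v\dot\theta(t-t_D)$

  with neural delays of 5/10/20 ms by most proximal joint (40 ms for the
  SOL→TA inhibition).
* **Fit**: a single-shooting optimization over 90 design variables
  (70 reflex gains/offsets + 4 phase-transition thresholds + 16 initial
  states) using rank-μ CMA-ES (λ = 16, μ = 8), minimizing

  $J = w_{cot} J_{cot} + w_{spd} J_{spd} + w_{inj} J_{inj} + w_{head} J_{head}$

  — gross cost of transport, a step-speed window term, squared ligament
  torques, and out-of-bounds head accelerations, with weights
  (1, 10 000, 0.1, 0.25).
* **Deficits**: weakness multiplies a muscle's maximum isometric force by
  0.25/0.125/0.0625; contracture multiplies its optimal fiber length by
  0.85/0.70/0.55; applied to SOL, GAS or both (PF), bilaterally — 18
  cases, each seeding the next severity in the optimization chain.
* **Analysis**: step/cycle segmentation from ground reaction forces,
  spatiotemporal measures, 101-point cycle normalization, RMSE in SD
  units, normalized cross-correlation, and Z-score panels against
  normative bands (a synthetic band generator stands in for laboratory
  datasets, which are not redistributed).

See the methods vignette (`vignettes/reflexgait-methods.Rmd`) for the
full account of equations, defaults and design decisions.

## A worked example

```r
library(reflexgait)

model      <- gait_model()        # shipped editable planar model
controller <- gait_controller()   # shipped reflex topology + pre-trained values
controller
#> Reflex gait controller: reflex-5phase-default
#>   44 laws (bilateral, shared parameters), 5-phase state machine
#>   free parameters: 70 gains/offsets + 4 thresholds + 16 initial-state = 90 design variables

# roll out the shipped controller values for 5 s
traj <- simulate_gait(model, controller, t_des = 5, strict = FALSE)
gait_objective(traj, degenerate = "penalize")

# introduce severe bilateral plantarflexor weakness and re-train briefly
weak <- apply_deficit(model, deficit_spec("PF", "weakness", "severe"))
fit  <- optimize_gait(weak, controller,
                      protocol = gait_protocol(t_des = 5, lambda = 8, mu = 4,
                                               max_gen = 40, rtol = 1e-3),
                      seed = 1)
fit            # best J and its four-term breakdown
coef(fit)      # the named 90-entry design vector
plot(fit)      # convergence history
```

The rollout + objective above prints (this exact output comes from running
the code on the shipped defaults):

```
#> Gait rollout: fell (t_end = 2.135 s, fell at 2.135 s)
#>   215 samples x 114 channels, model mass 75.16 kg
#>   COM travel 1.36 m, mean speed 0.64 m/s
#> J = 7248.9104
#>             cot        spd     inj   head
#> raw      13.784 7.0256e-01 1961.20 53.410
#> weight    1.000 1.0000e+04    0.10  0.250
#> weighted 13.784 7.0256e+03  196.12 13.353
#> distance 1.36 m over 2.14 s (fell at 2.14 s), 2 steps
```

Reading it: the pre-trained default moves the model forward for about two
seconds, and steps covering roughly 30% of the 5 s horizon earn in-range
credit (raw speed term 0.70, down from 1.0 for an immediate fall) before
the model falls.  That is a desk-scale *starting point* — early training,
not a converged gait; the full-scale presets in `protocol_presets()`
describe the cluster-size optimizations (thousands of generations in
parallel restart sets) that steady walking requires.  Severity chains,
prescribed-speed ladders and the restart protocol are available through
`protocol_presets()` and `restart_protocol()`.

A thin command-line wrapper covers the same workflow
(`validate`, `simulate`, `optimize`, `apply-deficit`, `analyze`,
`mtu-curves`, `controller-lint`, `fixtures`):

```sh
GS=$(Rscript -e 'cat(system.file("cli/gaitsim.R", package = "reflexgait"))')
Rscript $GS validate --model inst/extdata/default_model.yaml
Rscript $GS apply-deficit --model inst/extdata/default_model.yaml \
        --target PF --kind weakness --severity severe --out weak.yaml
```

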