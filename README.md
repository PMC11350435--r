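# mepdkndy

Simulation and numerical bifurcation analysis of a coupled model of how the
amygdala shapes reproductive hormone pulsatility.

Pulsatile luteinizing hormone (LH) secretion is driven by the GnRH pulse
generator — the arcuate KNDy neuron population — and modulated by upstream
limbic circuits.  The posterodorsal medial amygdala (MePD) sends both
glutamatergic (excitatory) and GABAergic (inhibitory) projections to the
arcuate nucleus, and stimulating the MePD changes the LH inter-pulse
interval (IPI).  This package implements a two-level mean-field model of
that pathway for computational neuroendocrinologists:

* a three-population Wilson–Cowan model of the MePD GABA–glutamate circuit
  (glutamatergic neurons `Gl`, GABA interneurons `Gi`, GABA efferents
  `Ge`), each population obeying
  `dG/dT = delta * (-G + (1 - G) * phi(a, F, theta))` with a rest-silent
  sigmoid response `phi` and linear synaptic input sums with kisspeptin
  drive `Kp` split by a ratio `alpha`;
* a coarse-grained KNDy relaxation oscillator (dynorphin `D`, neurokinin B
  `N`, firing rate `v`) whose pulses are the model analogue of LH pulses;
* strictly one-way coupling `I = I0 + p_v σ(N) v + j_l Gl - j_e Ge`, with
  projection weights `(j_l, j_e)` mimicking baseline drive or
  optogenetic stimulation of glutamatergic / GABAergic terminals.

On top of the simulator (a compiled adaptive Dormand–Prince 5(4) integrator
with dense output) the package provides a self-contained numerical
continuation toolkit: pseudo-arclength equilibrium branches with Hopf and
saddle-node detection, limit-cycle continuation by single shooting with
Floquet multipliers, two-parameter Hopf/saddle-node loci with
Bogdanov–Takens and cusp points, a period-blow-up homoclinic
approximation, torus-bifurcation location for the coupled system,
pulse/IPI statistics, and drivers for the in-silico experiments
(kisspeptin stimulation, receptor antagonism, projection stimulation).

See the methods vignette (`vignettes/mepd-kndy-methods.Rmd`) for the model,
its assumptions, and every numerical choice.

## Worked example

```r
library(mepdkndy)

# Where does the MePD circuit start to oscillate?  Continue the equilibrium
# branch in the kisspeptin drive and detect bifurcations:
br <- continue_equilibria(mepd_params(), "Kp", c(0, 3), guess = c(0, 0, 0))
detect_codim1(br)[[1]]
#> <mk_bifpoint> HB at Kp = 1.40243

# Above this Hopf point the circuit oscillates with a ~1.9 min period.
# The GABA-efferent output first grows with drive, peaks, then falls
# (disinhibition taking over) -- the gain switch:
find_gain_switch()$Kp
#> [1] 1.593071

# Feed the circuit's output into the KNDy pulse generator and mimic
# optogenetic stimulation of MePD GABAergic terminals: the pulse interval
# is first unchanged, then lengthens, then pulsing stops.
sw <- sweep_projection_stimulation("gaba_stim", c(0, 0.8, 1.2, 1.5))
sw$results[, c("param", "mean_ipi", "classification")]
#>   param mean_ipi classification
#> 1   0.0 17.86905      pulsatile
#> 2   0.8 17.53864      pulsatile
#> 3   1.2 21.06765      pulsatile
#> 4   1.5       NA      quiescent
```

`mean_ipi` is the model's inter-pulse interval in minutes (the analogue of
the LH IPI); ~17.9 min is the unstimulated rhythm.  A `quiescent`
classification means genuine relaxation pulses have ceased.

A file-based command line covers the same ground:

```sh
Rscript inst/cli/mepdkndy.R simulate --model coupled --preset glut_stim \
        --set Kp=0.8 --out out/
Rscript inst/cli/mepdkndy.R continue --free_param Kp --range 0,3 --out out/
Rscript inst/cli/mepdkndy.R scenario --scenario gain_switch --out out/
```

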