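---
title: "Modelling amygdala control of the GnRH pulse generator: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling amygdala control of the GnRH pulse generator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mepdkndy)
```

## The scientific problem

Luteinizing hormone (LH) is secreted in discrete pulses whose frequency is
set by the GnRH pulse generator — the KNDy neuron population of the arcuate
nucleus (ARC), co-expressing kisspeptin, neurokinin B (NKB) and dynorphin.
Upstream limbic structures modulate this rhythm; in particular the
posterodorsal subnucleus of the medial amygdala (MePD) sends both
glutamatergic (excitatory) and GABAergic (inhibitory) projections to the
ARC, and optogenetic work has shown that stimulating MePD kisspeptin
neurons or MePD projection terminals changes the LH inter-pulse interval
(IPI).

`mepdkndy` implements, and provides numerical bifurcation tools for, a
two-level mean-field description of this pathway:

1. **MePD circuit** — a three-population Wilson–Cowan model: glutamatergic
   neurons (`Gl`), GABA interneurons (`Gi`) and GABA efferent neurons
   (`Ge`).  Each population's activity obeys
   \[
   \frac{dG}{dT} \;=\; \delta\,\bigl(-G + (1 - G)\,
   \phi(a, F, \theta)\bigr),
   \qquad
   \phi(a, F, \theta) = \frac{1}{1 + e^{-a (F - \theta)}} -
                        \frac{1}{1 + e^{a\theta}},
   \]
   where the sigmoid is shifted so that an unstimulated population is
   silent (`phi(a, 0, theta)` is exactly 0), the refractory factor
   \((1-G)\) bounds activities by 1, and \(\delta\) (1/min) converts the
   dimensionless Wilson–Cowan time to minutes.  The synaptic inputs \(F\)
   are linear sums of the interaction strengths \(c_{ll}, c_{li}, c_{il},
   c_{le}, c_{ie}\); a kisspeptin drive \(K_p\) is split between the
   glutamatergic population (fraction \(\alpha\)) and the GABA
   interneurons (fraction \(1-\alpha\)).  Fractional antagonism
   coefficients \(\beta_1, \beta_2 \in [0,1]\) scale down all GABAergic /
   glutamatergic interactions, modelling partial receptor blockade.
   The wiring implements *disinhibition*: interneurons inhibit the
   efferent population, so exciting the interneurons reduces the circuit's
   inhibitory output.

2. **KNDy network** — a coarse-grained relaxation oscillator in dynorphin
   concentration `D` (nM), NKB concentration `N` (nM) and mean firing rate
   `v` (spikes/min): NKB excites firing through a saturating positive
   feedback, dynorphin suppresses NKB production, and the firing-rate
   response to total synaptic input \(I\) is a scaled sigmoid
   \(v_0 / (1 + e^{k(m - I)})\), which is non-negative by construction.
   With reference parameters the isolated network pulses with an IPI of
   ≈ 17.9 min, the physiological LH scale.

3. **One-way coupling** — the instantaneous MePD activities enter the KNDy
   input as \(I = I_0 + p_v\,\sigma(N)\,v + j_l G_l - j_e G_e\).  The
   weights \((j_l, j_e)\) are (1, 1) at baseline; projection-terminal
   stimulation is mimicked by (1.5, 0.5) (glutamatergic) or (0.5, 1.5)
   (GABAergic).  There is no feedback from the KNDy network to the MePD.

The mean MePD output over a window is \(\overline{G_l} - \overline{G_e}\)
(trapezoidal time averages): negative values mean net inhibition of the
pulse generator, positive values net excitation.

## What the package computes

* `integrate_model()` — adaptive Dormand–Prince 5(4) integration (compiled)
  with dense output on a uniform grid, for the MePD, KNDy and coupled
  systems.
* `continue_equilibria()` / `detect_codim1()` — pseudo-arclength
  equilibrium continuation with Hopf (HB) and saddle-node (SN) detection by
  Routh–Hurwitz test functions, refined by bisection.
* `continue_limit_cycle()` — single-shooting limit-cycle continuation with
  variational monodromy matrices, Floquet multipliers, and a
  homoclinic-proxy treatment of the branch end (below).
* `continue_codim1_locus()` / `detect_codim2()` — two-parameter HB and SN
  loci, Bogdanov–Takens (BT) and cusp (CP) points;
  `approximate_homoclinic()` for the homoclinic (HC) locus.
* `locate_torus_bifurcation()` / `poincare_section()` — the coupled
  system's limit-cycle → torus transition.
* `detect_pulses()` / `make_pulse_fixture()` — IPI statistics on firing-rate
  traces and a synthetic ground-truth generator for validating them.
* `sweep_kisspeptin()`, `sweep_antagonism()`,
  `sweep_projection_stimulation()`, `heatmap_mean_output()`,
  `find_gain_switch()` — the in-silico experiment drivers.
* `run_cli()` and `inst/cli/mepdkndy.R` — file-based command-line access.

## The bifurcation skeleton at reference parameters

With the reference parameter set (`mepd_params()` defaults, \(\alpha=0.9\),
\(\beta_1=\beta_2=0\)) the MePD circuit is quiescent at low drive; the
silent state is locally stable at \(K_p = 0\).  Continuation in \(K_p\)
gives, in order:

* a supercritical **Hopf bifurcation at \(K_p \approx 1.40\)** — onset of
  circuit oscillations with period ≈ 1.9 min (the experimentally observed
  calcium-activity timescale);
* a **gain switch at \(K_p \approx 1.59\)**: the limit-cycle maximum of the
  GABA-efferent activity peaks and then falls — beyond this drive,
  interneuron inhibition of the efferents outweighs their glutamatergic
  excitation, so *more* excitation produces *less* inhibitory output;
* a shrinking oscillation period down to ≈ 0.46 min, then a steep terminal
  rise of the period: the stable cycle is destroyed at
  \(K_p \approx 17.16\) by a fold of cycles sitting within \(\sim10^{-3}\)
  of a homoclinic connection of its unstable twin;
* a **bistable window between two saddle-node bifurcations**
  (\(K_p \approx 16.2\) and \(\approx 18.4\)), after which only the
  high-activity equilibrium remains.

In the \((K_p, \alpha)\) plane the Hopf locus closes the oscillatory
region: oscillations exist only when most of the kisspeptin drive reaches
the glutamatergic population (\(\alpha \gtrsim 0.78\)).  The HB and SN loci
coalesce at a Bogdanov–Takens point, and an HC curve emanates from its
neighbourhood.  In connectivity planes (e.g. `c_il` × `c_li`) the SN locus
carries a cusp where the bistable fold pair merges.

## Numerical choices

**Integration.**  deSolve is not part of the supported environment, so the
package ships its own Dormand–Prince 5(4) stepper (C++/Rcpp) with the
standard dense-output interpolant, relative tolerance `1e-8` and absolute
tolerance `1e-10` by default, tightened to `1e-10`/`1e-12` inside the
continuation code.  The coupled system proved non-stiff enough for an
explicit method at these tolerances (checked by step-halving convergence);
sigmoid arguments are clipped at ±500 before exponentiation, far outside
the operating range.  Integration results are deterministic and
bit-reproducible.

**Time scale.**  All integration and continuation use the minutes-scale
equations (the \(\delta\)-scaled right-hand side); the arbitrary-time form
is exposed only through `mepd_rhs(..., time_scaled = FALSE)` for unit
checks.  The two differ only by the positive factor \(\delta\), so
bifurcation locations are identical.

**Initial conditions and transients.**  The source publications do not
state initial conditions.  Defaults are `(0.1, 0.1, 0.1)` for the MePD and
`(0.1, 0.1, 1)` for the KNDy network; default windows are 30 min (MePD
alone) and 600 min (coupled — at least ten pulses), discarding the first
half of the window (capped at 200 min) before computing statistics.
Scenario sweeps warm-start each run from the previous grid point's end
state.  This matters: the KNDy oscillator is *bistable* against constant
drive in part of the glutamate-stimulation range, so a warm-started sweep
(the analogue of ramping stimulation in one animal) stays on the pulsing
branch where a cold start may land on the quiescent one.  The
warm-versus-cold agreement outside such hysteresis windows is tested.

**Firing-rate sigmoid.**  The KNDy rate response is implemented exactly as
the scaled sigmoid \(v_0/(1+e^{k(m-I)})\) with no additive constant.  (Its
derivation is described in the source literature as a vertically shifted
sigmoid, but the printed formula contains no shift term; the printed form
is what the package computes, and it is non-negative as required.)  The
printed units of `k`, `m`, `I0` are not mutually consistent; they are
treated as consistent dimensionless numerics.

**Hopf/saddle-node test functions.**  Rather than tracking individual
eigenvalues (which requires pairing heuristics across continuation steps),
detection uses the characteristic-polynomial coefficients of the analytic
Jacobian: for \(\lambda^3 + c_2\lambda^2 + c_1\lambda + c_0\), a fold has
\(c_0 = 0\) and a Hopf point \(c_1 c_2 - c_0 = 0\) with \(c_1 > 0\)
(\(c_1 = \omega^2\)).  These are smooth along branches, and the BT point is
simply where \(c_1\) changes sign along the Hopf locus.  Eigenvalues are
still recorded at every accepted point.

**Limit cycles.**  Cycles are located by single shooting on a Poincaré
section (the cycle's mid-range `Gl` level, re-anchored as the cycle
drifts), with the monodromy matrix from the 12-dimensional variational
flow; a 3-D smooth system does not warrant collocation.  The branch is
continued by pseudo-arclength in (section state, parameter, period), so
folds of cycles are rounded.

**The homoclinic proxy.**  The period of a near-homoclinic cycle grows
like \(|\log|p - p_{HC}||/\lambda_u\) with \(\lambda_u \approx 7\)/min,
so reaching a period of 50× the Hopf-onset period would require resolving
the parameter to \(e^{-300}\) — far below double precision.  In practice
the parameter pins at machine resolution once the period exceeds a few
times the onset period, and the single-shooting convergence basin then
shrinks exponentially.  The branch end is therefore reported as the
homoclinic proxy (`status = "hc_proxy"`) when it terminates with a rising
period, either past a fold of cycles (Floquet multiplier through +1) or
with the parameter numerically pinned; the default blow-up threshold
`hc_factor = 10` marks the few cases that climb further.  The recorded HC
parameter is insensitive to this threshold — doubling it moves the point
by less than a continuation step, which is exactly the convergence check
the test suite runs — and brackets the true homoclinic to about
\(10^{-3}\) in parameter.

**Torus bifurcation.**  Because the coupling is strictly one-way, the
coupled system's periodic orbit can only acquire a second frequency when
the MePD subsystem itself starts oscillating; the torus bifurcation is
therefore located at the MePD Hopf parameter, and verified dynamically:
just below the point the Poincaré returns of the coupled attractor cluster
to a point (scaled diameter < 1e-3), just above they spread along a curve.

**Pulse detection.**  Peaks are local maxima with topographic prominence of
at least 20% of the trace range, thinned to a 2-min minimum separation.
Two physiological guards apply to model traces, where the firing-rate
ceiling \(v_0/d_v = 2500\) spikes/min is known: a trace is quiescent when
its range is below 1% of that ceiling, and the prominence requirement is
taken relative to \(\max(\text{range}, v_0/d_v)\).  The second guard
matters because, once genuine relaxation pulses cease under strong
inhibition, the oscillatory MePD input still forces ripples of a few
hundred spikes/min in `v`; without an absolute scale those ripples would
be misread as high-frequency pulses.  On quasi-periodic (torus) traces the
IPI is reported as the mean over all detected pulses (windows hold ≥ 20),
and the peak-height coefficient of variation is reported as a
quasi-periodicity indicator but not used for classification.

**Gain switch.**  The switch is measured on the *cycle maximum* of `Ge`
(the limit-cycle amplitude branch): this is the quantity whose rise and
fall expresses the efferent population's gain change, and it peaks at
\(K_p = 1.59\text{–}1.60\) at reference parameters.  The cycle *average*
of `Ge`, by contrast, is maximal already at the Hopf point and decreases
monotonically thereafter, so it carries no interior switch.

**Synthetic pulse fixtures.**  `make_pulse_fixture()` builds Gaussian bumps
at prescribed times plus i.i.d. Gaussian noise on a uniform grid (default
0.5-min sampling, of the order of experimental blood-sampling intervals).
It emulates pulse timing and amplitude against measurement noise only — it
has no baseline drift, no pulse-shape asymmetry and no missing samples, so
a green detector test establishes timing recovery under noise, not
robustness to assay artefacts.  With 1% noise and 1.5-min-wide bumps the
detector recovers every peak to within one sample; at much finer sampling
the argmax of a wide noisy bump is not identifiable to one sample by any
detector, which is why the fixture's default sampling is the physiological
one.

**Configuration and outputs.**  Parameter sets and run configurations are
flat JSON keyed by the model symbol names (`delta`, `alpha`, `Kp`, ...,
`d_D`, ..., `j_l`, `j_e`); YAML is not used because no YAML parser is part
of the supported environment.  All numeric output is written with 12
significant digits, making identical runs byte-identical.

## Known limitations

* No spatial structure, no stochastic variant, no KNDy → MePD feedback, no
  receptor kinetics: the model inherits the mean-field assumptions of its
  sources.
* The homoclinic locus is an approximation by branch termination, not a
  boundary-value homoclinic solution; its stated accuracy (~1e-3 in
  parameter) is the distance between the fold of cycles and the true
  connection.
* Floquet-based torus detection is not implemented; TR location relies on
  the one-way-coupling argument plus the Poincaré diagnostic.
* The experimental LH statistics that the source work reports (e.g. IPI
  changes under optogenetic stimulation in vivo) are wet-lab results; the
  package reproduces the *qualitative* in-silico response curves, and none
  of its tests assert experimental numbers.

## A worked example

```{r example, eval = FALSE}
library(mepdkndy)

# Hopf onset of the MePD circuit
br <- continue_equilibria(mepd_params(), "Kp", c(0, 3), guess = c(0, 0, 0))
detect_codim1(br)[[1]]
#> <mk_bifpoint> HB at Kp = 1.40243

# gain switch of the GABA-efferent population
find_gain_switch()$Kp
#> [1] 1.593071

# coupled response to GABA-projection stimulation
sw <- sweep_projection_stimulation("gaba_stim", c(0, 0.8, 1.2, 1.5))
sw$results[, c("param", "mean_ipi", "classification")]
#>   param mean_ipi classification
#> 1   0.0 17.86905      pulsatile
#> 2   0.8 17.53864      pulsatile
#> 3   1.2 21.06765      pulsatile
#> 4   1.5       NA      quiescent
```
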