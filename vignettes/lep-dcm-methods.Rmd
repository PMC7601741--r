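---
title: "Modelling LEP habituation with dynamic causal models: methods and design choices"
author: "lepdcm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling LEP habituation with dynamic causal models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific question

Repeated painful stimulation normally produces *habituation*: the
vertex N2P2 component of the laser-evoked potential (LEP) shrinks from
the first to the last block of stimuli. In interictal migraine this
habituation is reduced or absent. `lepdcm` implements a desk-scale
version of the analysis chain used to ask *where in the pain network*
that difference arises: per-subject dynamic causal modelling (DCM) of
evoked responses over a seven-region thalamo-cortical network, followed
by a group-level parametric empirical Bayes (PEB) comparison of
effective connectivity between migraine patients and controls, plus the
classical scalp-level habituation statistics.

Because no raw EEG accompanies the study, the package ships a
first-class synthetic-cohort generator whose ground-truth defaults are
the study's reported group effects. The generator defines the study
conditions under which everything here is tested; what the tests show
about *real* data is discussed at the end.

## The network

The network (`build_study_network()`) contains the contralateral
primary somatosensory cortex (lS1), bilateral secondary somatosensory
cortices (lS2, rS2), bilateral insulae (lIns, rIns), the anterior
cingulate cortex (ACC), and a *hidden* source standing for the
thalamus (THAL) that shapes the dynamics but contributes nothing to the
sensors. Edges are typed forward / backward / lateral following
cortical-hierarchy conventions:

* forward: THAL to each of lS1, lS2, rS2, lIns, rIns; lS1→lS2;
  lS2→lIns; rS2→rIns; lIns→ACC; rIns→ACC (ascending pain pathways);
* backward: every region →THAL, plus lS2→lS1;
* lateral: lS2↔rS2 and lIns↔rIns, represented as *directed pairs* so
  that direction-specific interhemispheric effects are expressible.

Three choices here were genuinely open and are fixed as package design:
the stimulus enters only at THAL (the ascending relay); all 21 edges
may be modulated between blocks (the analyses report modulations in all
three classes, so no restriction is defensible); and the canonical
region order `lS1, lS2, rS2, lIns, rIns, ACC, THAL` is frozen so
parameter vectors are reproducible. MNI coordinates are configuration
metadata only — the synthetic observation model never uses them.

## The neural mass model

Each region is a convolution-based 'ERP' neural mass with three
subpopulations (spiny stellate, inhibitory interneurons, pyramidal).
Every postsynaptic potential $x$ obeys second-order kernel dynamics

$$\ddot x = \kappa H\,u_{\text{pre}} - 2\kappa\,\dot x - \kappa^2 x,$$

where $u_{\text{pre}}$ is the weighted sum of presynaptic normalized
firing, $S(v) = 1/(1+e^{-r v}) - 1/2$. Forward afferents drive the
stellate population, backward afferents the pyramidal and interneuron
populations, lateral afferents all three; the measured output is the
pyramidal depolarization. Intrinsic connectivity uses the loop gains
$\gamma_{1..4}$; the exogenous input is a Gaussian bump
(`stimulus_spec()`, peak at 100 ms, SD 16 ms).

Defaults (all in `neural_params()`):

| parameter | default | meaning |
|---|---|---|
| $\kappa_e,\ \kappa_i$ | 250, 62.5 s⁻¹ | 4 ms / 16 ms synaptic time constants |
| $H_e,\ H_i$ | 4, 32 mV | maximum PSP amplitudes |
| $\gamma_{1..4}$ | 128, 102, 26, 26 | intrinsic loop gains |
| $r$ | 0.56 mV⁻¹ | sigmoid slope |
| class gains | 128 / 256 / 32 | nominal forward / backward / lateral strength |

Per-edge coupling is `class gain × exp(a + b·modulated)`, with `a` the
baseline log-strength and `b` the block-1→block-3 log-modulation, so
`a = b = 0` is the nominal network and the estimated quantities are the
unitless log-scalings — the same parameterisation the group analysis
compares.

Two of these constants deserve comment. First, at the default stimulus
the operating point is sub-millivolt, where $S$ is nearly linear; this
keeps the cohort dynamics well damped for log-strength excursions up to
about ±1 (verified by stress simulation under random draws far wider
than the generator produces). Second, the *backward* class gain is set
higher than the forward gain. A backward afferent excites both the
pyramidal population (directly) and, via the interneurons, its
inhibition; with these kinetics the two limbs nearly cancel
($H_e/\kappa_e \ll H_i/\kappa_i$), so backward influences are
intrinsically faint. At equal class gains the backward parameters are
essentially invisible to the sensors; raising their nominal strength to
256 keeps them identifiable while leaving the network comfortably
inside its stable regime. This is a property of the model class worth
knowing about when interpreting backward-edge posteriors anywhere.

Integration is fixed-step classical Runge–Kutta on a grid oversampled
4× relative to the output rate, then decimated; halving the step
changes trajectories by well under 0.1%, and zero input from rest stays
at exactly zero (the model is centred). Conduction delays are omitted:
the tested claims concern connection strengths and their modulations,
and delay-free dynamics keep the integrator simple and testable.

## Observation model

Channels are a linear gain map of pyramidal depolarizations,
`data = gain %*% sources` (µV per mV), with an i.i.d. Gaussian noise
option. The anatomical forward model of the original pipeline (canonical
T1 + boundary element method) is deliberately replaced by a *seeded
synthetic lead field* (`synthesize_leadfield()`): smooth random spatial
profiles per observed region, full column rank, and an exactly zero
column for THAL — the inference machinery is agnostic to where the gain
matrix came from, and a user-supplied matrix is accepted for real data.
The default montage is 16 channels; a 61-channel × 206-sample preset
(`paper_geometry_config()`) reproduces the import geometry of the
original averages for format-conformance tests. The sampling rate
implied by 206 samples over 0–800 ms is a fixture constant, not a
recorded fact.

## Inversion: variational Laplace

`dcm_fit()` fits one subject's block-1/block-3 pair jointly: block 1 is
the baseline condition, block 3 activates the `B:` modulations, and the
objective is the variational free energy under the Laplace (Gaussian)
approximation,

$$F = \underbrace{-\tfrac{\tau}{2}\big(r^\top r + \mathrm{tr}(J \Sigma J^\top)\big) + \tfrac{N}{2}\log\tfrac{\tau}{2\pi}}_{\text{accuracy}} - \underbrace{\mathrm{KL}\big(q(\theta)\,\|\,p(\theta)\big)}_{\text{complexity}},$$

maximised by Gauss–Newton steps with step halving (a candidate step is
accepted only if it does not lower $F$, so the recorded $F$ trace is
non-decreasing by construction). The single noise precision $\tau$ is a
hyperparameter updated by EM; it can be fixed for linear-regime
checks. Jacobians are central finite differences (step $10^{-3}$),
batched through the compiled integrator. Priors are zero-mean Gaussians
with variance 1/16 on every `A:`, `B:` and `C:` entry — conventional
shrinkage for log-couplings — and the intrinsic constants are fixed,
which keeps the desk-scale recovery surface identifiable. Convergence:
$|\Delta F| < 0.01$ nats for 3 consecutive iterations, or 64
iterations. In the linearised regime the fitted posterior matches the
conjugate closed form to $10^{-3}$, and for linear models $F$ equals
the analytic log evidence (both are asserted in the test suite).

Note one nonlinearity that is easy to overlook: even when the dynamics
are linearised by a small stimulus, the forward map remains nonlinear
*in the parameters*, because couplings enter as $e^{a}$ and compound
along paths. Linear-Gaussian equivalence therefore holds only close to
the prior mean, which is how the oracle tests are constructed.

## Group level: PEB, BMR and greedy search

`peb()` implements the hierarchical Gaussian model
$\theta_i = X\beta + \varepsilon_i$ over subjects' posterior means, with
each subject's posterior covariance carrying first-level uncertainty
upward, an isotropic between-subject covariance $e^{-\gamma} I$ whose
log-precision is optimized against the second-level free energy, and
$N(0, 1/16)$ priors on the effects. The design matrix is a column of
ones (commonality, $\beta_0$) and a 0/1 dummy (control/migraine,
$\beta_1$). Following the study's two analyses, PEB is run separately
on the baseline strengths (`A:`) and on the modulations (`B:`).

`bmr_evidence()` computes reduced-model evidence and posteriors
analytically from the full posterior/prior pair (exact Gaussian
algebra; a point mass at zero is represented by prior variance
$10^{-8}$, and the result matches explicit refits to well under 0.01
nats). `peb_search()` prunes greedily — each round it removes the
effect whose removal costs least evidence, as long as the cost is not
positive, re-evaluating every survivor each round with a cap of 256
evaluations — and returns the Bayesian model average over the final
search generation. Posterior probabilities of each effect being nonzero
come from on/off evidence comparisons with uniform model priors; the
study's reporting rule is $p > 0.99$. Under null simulations this rule
keeps false positives well below 5% of effects tested.

## Scalp-level habituation statistics

`n2p2_amplitude()` is max(P2 window) − min(N2 window); the window
defaults (N2 130–300 ms, P2 280–500 ms) are fixture choices — the study
does not print its windows — and are configurable. The habituation
index is `(block1 − block3)/block1 × 100`, positive for habituation.
Group comparisons use the Welch $t$ (the printed statistics match the
unequal-variance form, verified numerically from the printed
summaries), either directly from summary statistics (`welch_t()`) or as
the observed statistic of a permutation test (`permutation_t_test()`,
add-one p estimator, mandatory seed, exact enumeration available for
small samples). Sidedness is a flag: the printed p values are
internally consistent with two-sided testing for the ratings and with
one-sided testing for the HI and N2P2 comparisons, so no single default
reproduces all three and the package defaults to two-sided.
`fir_order_hamming()` implements the windowed-sinc default order
heuristic (transition bandwidth `min(max(0.25·edge, 2 Hz), edge)`,
order `3.3·rate/bandwidth` rounded up to even); at 256 Hz — the rate
implied by the reported order, recorded here as an assumption — a
1–40 Hz band gives 846 taps.

## The synthetic cohort

`generate_cohort()` draws, per subject, `a = a_base + group·a_effect +
N(0, sd_bs)` and `b` from the group's modulation means, simulates both
block averages, and adds channel noise. Defaults are the study
conditions: 20 controls + 23 patients, `a_effect` equal to the reported
first-block group differences (e.g. THAL→lIns +0.47, rS2→rIns +0.72,
rIns→ACC −0.80), group modulation means equal to the reported
commonality and commonality-plus-difference values (e.g. THAL→lS2
−0.37 in controls vs −0.05 in migraine), between-subject SD 0.1
(unstated in the study; chosen once as a spread that keeps groups
separable at the default noise), and noise SD 0.25 µV. Everything
regenerates bit-identically from `(config, seed)`. `make_trialset()`
emits 3 blocks × 5 noisy trials per subject for block-averaging
demonstrations; the middle block, absent from the two-block DCM design,
is simulated at half modulation as a geometric midpoint. Using the
reported posterior expectations as generating values is what makes
"recovery of the reported effect pattern" a testable surface; it does
not assert that the real data looked like this.

## Problem sizes, tolerances, degenerate inputs

* End-to-end checks run a reduced cohort of 8 + 8 subjects at low noise
  (0.02 µV) — chosen as the smallest cohort in which every strongly
  planted group effect (|effect| ≥ 0.4) is sign-recoverable — and
  complete in a few minutes on one CPU. Inversion unit tests use a
  three-region subnetwork where each fit takes seconds.
* Numerical guards: posterior precision matrices are symmetrised before
  inversion; candidate steps with non-finite predictions are rejected
  and halved; a subject whose fit errors is excluded from the group
  stage and reported, not fatal.
* Degenerate inputs are rejected loudly: non-uniform time grids,
  parameter keys that do not match the network, montage/grid mismatches
  between blocks, zero first-block N2P2 in the habituation index,
  zero-variance permutation samples, rank-deficient PEB designs.

## What passing tests do and do not show

The generator produces exactly the structure the model family assumes:
i.i.d. Gaussian channel noise, a gain matrix of the same form the
fitter uses, no artifacts, no inter-trial variability beyond noise, and
subjects drawn around the modelled network. Passing recovery tests
therefore validates the *machinery* — simulation, free-energy ascent,
Gaussian algebra, reduction, statistics — under the study's reported
effect sizes. It does not validate the biological model against real
EEG, and it cannot reproduce the study's real-data posteriors, which
would require the unavailable recordings.

Two honest limitations surfaced by the synthetic work are worth
stating. Backward-edge parameters, and especially their block-to-block
*modulations*, are weakly identified: near the nominal (symmetric)
network their sensor signatures are almost exactly collinear with
combinations of the other parameters, so single-subject posteriors
shrink heavily toward zero and group effects on these edges are
recovered with the right sign but at a fraction of their planted
magnitude. Relatedly, identifiability of anything routed through the
hidden source depends on asymmetries (lead field, planted effects)
breaking the nominal symmetry of the seven-region model. Both caveats
apply with equal force to interpreting such estimates on real data.
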