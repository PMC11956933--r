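---
title: "Methods: Boolean state-transition analysis of CBGT decision dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Boolean state-transition analysis of CBGT decision dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, estimators and numerical choices behind
`clawcbgt`. The package has two halves: a stochastic population-rate
simulator of the cortico-basal ganglia-thalamic (CBGT) circuit performing a
two-choice task, and an analysis chain — binarization, integer state
encoding, transition-graph construction and pruning, zone partition,
drift-diffusion model (DDM) fitting, and canonical correlation analysis
(CCA) of activity against decision policy — that turns the simulated
trajectories into a compact account of how the circuit's pathways steer a
decision.

## The circuit model

The network holds 18 population instances: cortex (Cx), direct and indirect
striatal projection neurons (dSPN, iSPN), prototypic and arkypallidal
external pallidum (GPeP, GPeA), subthalamic nucleus (STN), internal
pallidum (GPi) and thalamus (Th), each duplicated into left and right
action channels, plus shared cortical interneurons (CxI) and striatal
fast-spiking interneurons (FSI). Connectivity follows the three classical
pathways: direct (Cx to dSPN to GPi to Th), indirect (Cx to iSPN to GPeP to
STN/GPi) and pallidostriatal (STN to GPeA to striatum, with GPeP
inhibition of GPeA). The full signed edge list is in
`connectivityTable()`. Two edges deserve comment because circuit diagrams
rarely pin them down: we include a cortico-subthalamic (hyperdirect)
projection, and we make the STN-to-GPi projection diffuse across channels,
reflecting the anatomically broad subthalamic output; the diffuse edge is
also what lets a surge in one channel transiently brake the other.

Each population's rate obeys a noisy leaky integrator,

$$ r_i(t + \Delta) = r_i(t) + \frac{\Delta}{\tau_i}\left(-r_i(t) +
\phi\!\big(\textstyle\sum_j W_{ij} r_j(t) + I_i\big)\right) +
\sigma_i \sqrt{\Delta}\, \xi_{i,t}, $$

with $\phi(x) = \min(\max(x, 0), r_{\max})$ a saturating non-negative
transfer ($r_{\max} = 200$ Hz), Euler step $\Delta = 1$ ms, time constants
$\tau$ of 10-25 ms per population, and independent Gaussian noise. This is
a deliberate population-level surrogate for a spiking implementation: the
analysis chain only consumes binned rates, so the simulator's job is to
produce the right *statistical regimes*, not membrane dynamics.

Tonic inputs are derived from target baseline rates by solving the
noise-free fixed point ($I = r^\ast - W r^\ast$, valid while the fixed
point sits in the linear range of $\phi$). The shipped baselines put the
pallidal output nuclei high (GPeP 60 Hz, GPi 70 Hz) and striatum,
arkypallidal cells and STN low-to-moderate, so that before the stimulus
the circuit sits in the classic tonically-inhibited state.

A trial runs 200 ms of baseline, then applies equal stimulus drive
(10 Hz-equivalent input units per channel) to both cortices. The cascade
that follows — cortex up, striatum up, GPeP dips through iSPN inhibition,
STN and GPeA rise, GPi dips through dSPN inhibition, thalamus ramps — ends
when a thalamic population's 10-ms-binned rate first reaches the 30 Hz
decision threshold, which defines the decision time (DT) and choice. A
1000 ms timeout marks undecided trials (`choice = "none"`); these are
excluded from every downstream stage and their fraction is reported.
After the decision the selected channel keeps half its cortical drive for
a 150 ms consolidation phase, followed by a 150 ms inter-trial interval;
both phases are simulated for fidelity of the full trial time course but
never enter the analysis, which uses bins up to the decision only.

Default weights were tuned once so that the symmetric model reproduces the
intended regimes: balanced left/right choices, a decision-time
distribution with a few-hundred-millisecond body and spread (median near
180 ms under the defaults), timeouts well under 1%, pallidal dips and
striatal surges of realistic magnitude, and positive trial-wise
correlation between cortical and striatal mean activity. Decision-making
is a race: left and right cascades run in parallel and accumulated noise
(plus the soft winner-take-all provided by the shared interneurons and the
diffuse STN edge) decides which thalamus crosses first.

Networks for a study run are generated by jittering the 13 searchable
synaptic weights (they span all three pathways) multiplicatively by ±12%
around the defaults and keeping configurations that pass the feasibility
screen: per-population mean rates inside `defaultRateTargets()` ranges,
no timeouts in the screening trials, and positive cortex-striatum
correlation. `geneticSearch()` offers the same feasibility filter as a
proper genetic algorithm (tournament selection, uniform crossover,
clipped Gaussian mutation) and accepts a pluggable evaluator; the jitter
route is the pipeline default because at desk scale it reaches the same
feasible family at a fraction of the cost.

### Randomness

All randomness flows from one integer seed through named substreams
(network, trial, screen, GA, DDM). Sub-seeds are derived with a 32-bit
avalanche mixer rather than by offsetting the seed: R's generator produces
noticeably correlated first draws when seeded with consecutive integers,
which at one seed per trial is enough to bias a whole experiment's choice
fractions. The mixer scatters consecutive indices across the full seed
space and restores independence (this is checked by the choice-balance
test). Identical configuration and seed give bit-identical output
everywhere.

## Binarization

Per network, rates are pooled over all non-timeout trials and bins up to
each trial's decision, and one histogram per population is built with
Freedman-Diaconis bin widths, floored at 1 Hz and capped at 1/15 of the
range so that well-separated modes keep enough bins to be resolved.
Modality is called by smoothing the counts with a 5-bin moving average and
counting local maxima whose prominence reaches 10% of the tallest count:
two maxima mean bimodal, anything else unimodal.

Thresholds follow the three-rule scheme. Unimodal populations whose
baseline (pre-stimulus) rate exceeds their rate close to decision times
(the last 3 pre-decision bins) — the dipping pallidal outputs — take the
rate at which cumulative counts first reach 10% of the total; unimodal
populations that rise toward the decision take 90%; bimodal histograms
take the midpoint between the two peaks. The cumulative cut is
interpolated linearly inside the crossing bin, so it converges to the
matching quantile of the generating distribution. Comparison at the
threshold is strict: a rate exactly at threshold binarizes to 0. Both the
pooling scope (per network) and the per-channel treatment of lateralized
populations are choices; they match the per-network analyses downstream.

## States, the transition graph and zones

Ten populations define the Boolean state: dSPN, iSPN, GPi, GPeP and Th for
both channels. The label is the base-2 value of the pattern under the
fixed bit order (MSB to LSB) dSPN-L, dSPN-R, iSPN-L, iSPN-R, GPi-L, GPi-R,
GPeP-L, GPeP-R, Th-L, Th-R, giving labels 0-1023. This order is not
arbitrary: it is the unique assignment under which the landmark states of
the decision graph take their published labels (the pre-stimulated state
60, the launch state 63, the left-commitment chain 575 to 543, the
deliberation loop 63-55-183-191, the second deliberation triad
247/243/251, and the neutral state 783), so the encoding doubles as a
cross-check of the population bookkeeping. STN and GPeA are binarized too
but kept out of the label; their conditional activation probabilities are
reported per state.

Transitions are counted per label-change event by default (dwell
repetitions collapsed), because a 10 ms chain dominated by self-loops
carries little structure; the per-bin mode (self-transitions included) is
retained as an option. A state's end count increments when it closes a
trial; probabilities are normalized per source state over outgoing
transitions plus ends, so before pruning each state's mass sums to one.
Pruning sorts each state's outgoing probabilities and keeps the head of
the list up to the first relative drop of at least 25%; if no drop
qualifies, everything stays. End probabilities are never pruned.

Per state we report mean DT over visiting trials, left/right counts of
visiting trials, and the Kullback-Leibler divergence between the
choice-conditioned DT histograms, computed over shared bin edges with
additive smoothing of one over the total visiting-trial count and natural
logarithms. The direction is KL(left || right), with a Jensen-Shannon
option; states visited by a single choice class report the divergence as
undefined rather than infinite. Decision-time tertiles use type-1
empirical quantiles at 1/3 and 2/3 of the pooled distribution, so classes
are equal-count up to ties.

The zone partition starts from the canonical map: zone I is the launch
set {60, 61, 62, 63}; zone II the initial deliberation loop
{55, 59, 183, 191, 123, 127}; zone V the second deliberation triad
{247, 243, 251}; zone VI the neutral state {783}; zones III and IV the
left and right commitment arms, seeded with {575, 543, 535, 663, 759} and
its channel-mirror. Arms are then closed under retained outgoing edges,
but a successor may join an arm only if its direct pathway is dominant on
that side (ipsilateral dSPN bit on, contralateral off), and the mirror
state joins the opposite arm, which keeps the two arms exact mirror
images and stops the closure from swallowing noise states. Everything
else stays unassigned, mirroring the restriction of the analysis to
high-frequency states. Zone-level transition probabilities aggregate raw
transition counts; a zone's stay probability pools its within-zone and
end mass.

## Drift-diffusion model

The DDM has boundary height $a$, drift $v$ (signed toward the left/upper
boundary), non-decision time $t$ and relative start $z$, with unit
diffusion — the standard identifiability convention. The simulator is
Euler-Maruyama between absorbing boundaries; the closed-form absorption
probability $(e^{-2vza} - 1)/(e^{-2va} - 1)$ and the central-start mean
decision time $(a/2v)\tanh(va/2)$ serve as its oracles. Boundary-crossing
discretization biases absorption fractions by $O(\sqrt{\Delta})$, so
validation runs use steps of 0.25-0.5 ms.

Fitting is per-network maximum likelihood: each network contributes an
independent sample of choices and decision times, and the ensemble
analysis needs only the point estimates, so hierarchical pooling buys
little here. The first-passage density uses the standard truncated-series
evaluation with the small-time/large-time switch chosen by whichever
expansion needs fewer terms at tolerance $10^{-7}$. The optimizer is
Nelder-Mead on transformed parameters ($\log a$; $v$ free; $t$ as a logit
fraction of the fastest response; $z$ on a logit), started from
moment-based (EZ-style) estimates. The starting bias is fitted freely —
its loadings downstream are expected to be weak, and fixing it would
presuppose that. All-one-choice samples are fitted with a warning flag
rather than rejected, and non-convergence is always flagged.

## Control ensembles

Each network is summarized by 18 activity features: the across-channel sum
and the left-minus-right difference of the trial-averaged rate for each of
the eight lateralized populations, plus the CxI and FSI rates. CCA between
the feature matrix and the fitted DDM parameters is solved by
standardizing both sides, whitening with a ridge of $10^{-8}$ for
conditioning, and taking the SVD of the whitened cross-covariance. Signs
are fixed by making each component's largest-magnitude activity loading
positive.

Because the two channels share all connectivity parameters, the network
family is statistically invariant under the channel swap, which fixes sum
features, $a$ and $t$, and negates difference features, $v$ and the
centred $z$. `fitControlEnsembles()` enforces this symmetry by augmenting
the training set with its channel-swapped image before the CCA. The
augmentation zeroes the cross-covariance between swap-even and swap-odd
sectors — which at a few dozen networks is pure sampling noise that
otherwise mixes the components badly — and makes every canonical component
exactly even or exactly odd, so the choice ensemble is purely a
difference-feature/drift component by construction. At the study's full
scale this matters little; at desk scale it is the difference between
interpretable and scrambled loadings.

Components are labeled by their structure, not their order: choice is the
component with the largest loading mass on difference features and on
$v$; of the remaining two, the one whose $a$ and $t$ loadings share a
sign is responsiveness and the one whose $a$ and $t$ loadings oppose is
pliancy. Ambiguous sign patterns fall back to the $a \cdot t$ product and
set a low-confidence flag.

Within-trial dynamics are translated into ensemble drives by differencing
the standardized per-bin feature vector from stimulus onset to decision
($\Delta F_0 = 0$) and projecting onto the activity loadings,
$W_k = \Delta F_k^{\mathsf T} U$. Trials are grouped fast/slow (pooled DT
tertiles; the middle tertile is kept but not plotted against the
extremes) crossed with choice, and group summaries are aligned backward
from the decision bin. Cumulative drives are also reported as a
percentage of the group's mean pre-stimulus standardized feature
magnitude — a baseline convention we had to pick, since percent scales
for such plots are rarely pinned down. Drive onset, used when comparing
ensemble timing, is the first aligned bin at which the absolute
cumulative group-mean drive reaches half its peak deviation; the peak
anchors the normalization because drives can return toward baseline as
the network passes into commitment, which makes final-value-relative
onsets meaningless.

Zone-to-zone policy changes use zone-occupancy mean features per network:
$\Delta F_{ij}$ stacks (zone $j$ mean minus zone $i$ mean) over the
networks in which the direct transition occurs, $W_{ij} = \Delta F_{ij} U$
maps it to ensemble space and $P_{ij} = W_{ij} V^{\mathsf T}$ onward to
DDM space; column medians summarize each pair, and percentage changes are
taken relative to each network's fitted static parameters (converted back
to raw units through the training standard deviations). Zone means rather
than entry/exit snapshots represent each zone because occupancy-averaged
rates are what the static CCA was trained on.

## Problem sizes and what the tests show

The shipped end-to-end configuration runs 30 networks of 50 trials — the
package's desk scale, one tenth of the study scale in networks — and the
test suite exercises it together with closed-form, brute-force and
hand-computed oracles for every estimator (transition counting, pruning,
KL, DDM density and recovery, CCA). Passing these shows the machinery is
correct and that the simulator reproduces the intended qualitative
signatures: launch-state dominance early in trials, sub-1% timeouts, and
earlier responsiveness/pliancy than choice engagement on fast trials.

The synthetic generator emulates the statistical structure of the target
regimes — baselines, surges and dips, ramping thalamus, DT spread — but
not spiking microstructure, conductance synapses, bursting, dopaminergic
plasticity or reward feedback. Conclusions about real recordings
therefore require feeding real binned rates through
`readExternalTables()`; the analysis chain is agnostic to where the rates
came from. Known limitations: at 30 networks the CCA correlations are
optimistic (n is small relative to 22 variables, even with the symmetry
augmentation doubling effective rows in a dependent way); zone-projection
percentage changes can be large when a network's fitted parameter sits
near zero; and the arm-closure rule beyond the published landmark states
is an assumption, albeit one constrained by the mirror symmetry.
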