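# clawcbgt

Boolean state-transition analysis of decision dynamics in the
cortico-basal ganglia-thalamic (CBGT) circuit.

During a two-choice decision, activity flows through the CBGT loop —
cortex, striatum (dSPN/iSPN), external pallidum (prototypic GPeP and
arkypallidal GPeA), subthalamic nucleus, internal pallidum and thalamus —
along three interacting pathways (direct, indirect, pallidostriatal).
`clawcbgt` is for computational neuroscientists who want to trace that
flow moment by moment. It simulates two-choice trials in a stochastic
population-rate model of the circuit (two mirrored action channels, a
choice when a thalamic population first reaches 30 Hz) and analyses the
resulting trajectories with a Boolean state-transition framework:

1. **Binarization.** Rates in 10 ms bins are thresholded per population;
   thresholds come from pooled rate histograms (10% cumulative count for
   populations that dip under drive, 90% for populations that surge,
   peak midpoint for bimodal histograms).
2. **State encoding.** The Boolean pattern over ten populations (dSPN,
   iSPN, GPi, GPeP, Th; both channels) is encoded as its base-2 integer
   under the fixed bit order dSPN-L … Th-R, so every network
   configuration in a trial is one label in 0–1023 — e.g. the
   pre-stimulus state (bilateral GPi + GPeP) is state 60.
3. **Transition graph.** Label sequences from all trials are pooled into
   a transition matrix with per-state end (pre-decision) probabilities;
   per source state, edges are kept up to the first ≥ 25% relative drop
   in sorted probability. States group into functional zones (launch,
   two deliberation phases, left/right commitment arms, a neutral zone).
4. **Decision policy.** Per network, choices and decision times are
   fitted with a drift-diffusion model (boundary `a`, drift `v`, onset
   `t`, bias `z`) by maximum likelihood on a truncated-series
   first-passage density. Canonical correlation analysis between 18
   activity features (per-region channel sums and left-minus-right
   differences) and the DDM parameters yields three control ensembles —
   *choice*, *responsiveness*, *pliancy* — and bin-to-bin feature changes
   projected onto them (`W_k = ΔF_kᵀU`, `P_ij = W_ij Vᵀ`) give
   time-resolved and zone-resolved decision-policy changes.

## Worked example

```r
library(clawcbgt)

cfg    <- defaultNetworkConfig()           # tuned symmetric network
traces <- runExperiment(cfg, nTrials = 50, seed = 1)
traces
#> RateTraceSet: 1 network(s), 50 trials, 10 ms bins
#>   decisions: 62% left, 38% right, 0.00% timeouts

bin <- binarizeTraces(traces)              # per-network thresholds
bin@networks[[1]]$thresholds@table[c(5, 9, 17), ]
#>        population threshold_hz   rule
#> dSPN-L     dSPN-L     11.49878 high90
#> GPeP-L     GPeP-L     42.31136  low10
#> Th-L         Th-L     24.73180 high90

seqs <- extractSequences(bin)
g <- pruneGraph(estimateTransitions(seqs), stats = computeStateStats(seqs))
g
#> ClawGraph: 166 states, 204 retained / 316 raw edges (mode per_change, gap 0.25)

head(g@stats[order(-g@stats$occupancy),
             c("state", "occupancy", "mean_dt_ms", "n_left", "n_right")], 3)
#>  state occupancy mean_dt_ms n_left n_right
#>     60      1347      172.2     31      19
#>    361        31      178.0      1       9
#>    662        22      180.0     10       0

beh <- behaviorTable(traces)
fitDdm(beh$choice, beh$decision_time_ms / 1000)
#> DdmFit (n = 50): a = 0.734, v = 0.750, t = 0.047, z = 0.492
#>   loglik 28.23, converged TRUE
```

The state labels read directly as circuit configurations: state 60 is the
resting pattern (pallidal output active, everything else silent), its
occupancy dominates because every trial launches from it; states 361/662
are right/left pre-commitment patterns; the positive fitted drift
reflects this run's left-leaning choices.

The full analysis — many networks, zone partition, control ensembles,
drive time series and zone-to-DDM projections, with all tables written as
CSV plus graph exports (JSON/GraphML/DOT) — is one call:

```r
report <- runPipeline(pipelineConfig(nNetworks = 30, nTrials = 50,
                                     seed = 1, outDir = "claw-out"))
report$model        # labeled control ensembles
report$partition    # zone partition of the CLAW graph
```

A thin command-line front end is installed at
`inst/scripts/claw-cbgt.R` (`report`, `simulate`, `claw`, `ddm-fit`
subcommands); externally recorded binned rates enter the same chain
through `readExternalTables()`.

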