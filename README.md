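# erpnet

Rate-network models of oddball event-related potentials: mismatch negativity
(MMN) and P300 from short-term synaptic depression.

## The problem

In the auditory oddball paradigm a frequent *standard* stimulus is
occasionally replaced by a rare *deviant*, which evokes two canonical EEG
deflections: the MMN (~150-250 ms, sensory cortex) and the P300 (~300 ms,
frontal/association cortex, enhanced when the deviant is behaviorally
relevant). `erpnet` implements a mechanistic account in which both arise
from one synaptic mechanism - short-term synaptic depression (STD) - inside
small excitatory-inhibitory (E/I) rate networks, and provides the full
analysis stack needed to quantify the account: trial-aligned difference
traces and peak latencies, probability and interstimulus-interval (ISI)
sweeps, frontal amplification ratios, population-trajectory PCA with conic
ellipse fitting, and sliding-window linear decoding under observation
noise. It is aimed at computational neuroscientists studying ERP generation
mechanisms and predictive-coding alternatives.

## The model

A sensory region of 80 excitatory (E) and 20 inhibitory (I) rectified-linear
rate units receives a one-hot two-channel drive $u(t)$ through depressing
input synapses:

$$\tau\,\dot r_I = -r_I + f(W_{EI} r_E - W_{II} r_I + W_{in,I}\,x \odot u),$$
$$\tau\,\dot r_E = -r_E + f(W_{EE} r_E - W_{IE} r_I + W_{in,E}\,x \odot u),$$
$$\dot x = (1 - x)/\tau_x - x \odot u,$$

with $f(z)=\max(0,z)$, $\tau = 100$ ms, $\tau_x = 20$ s, forward Euler at
$dt = 10$ ms. Recurrent blocks are sampled $U[0,1)$, normalized to spectral
radius 1, then E/I-balanced (`?init_weights` documents the construction and
its gauge options). A frequent stimulus depletes its resource $x$; a rare
one does not; deviants therefore evoke larger responses - the MMN analogue,
peaking at stimulus offset. A second, *frontal* region driven only by an
E-to-E projection $W_{12} \sim U[0,g)$ (density $d$) amplifies and low-pass
filters the difference - the P300 analogue - with amplification proportional
to $g \cdot d$. In the *active* task a linear readout $y = W_{out} r_{2E}$,
trained by FORCE/recursive least squares, feeds back onto the frontal
network through depressing synapses, selectively enhancing responses to the
rare, behaviorally relevant stimulus.

## Worked example

```r
library(erpnet)

proto <- stimulus_protocol(n_trials = 100, p_x = 0.8, isi = 2, seed = 42)
seqn  <- generate_sequence(proto)
seqn
#> Oddball sequence: 100 trials (77 X, 23 Y), deviant = Y

inst <- network_instance(model_config(seed = 1))
rec  <- simulate_sensory(inst, render_input(seqn, proto))
erp  <- trial_average(rec, seqn)

erp$peak_latency_ms
#> [1] 190
round(c(peak = erp$peak_amplitude, mean_0_500 = erp$mean_amplitude), 3)
#>       peak mean_0_500
#>      0.082      0.039
round(rec$x_trace[, 19801], 3)   # pre-stimulus STD resource, last trial
#> [1] 0.398 0.796
```

The frequent stimulus X has depleted its input resource to ~0.40 while the
rare Y retains ~0.80, so Y evokes the larger population response; the
deviant-minus-standard difference peaks 190 ms after onset (just before
stimulus offset on the 10 ms grid), the MMN-like signature. Adding the
frontal region (`hierarchical_instance()`, `simulate_hierarchy()`) delays
and amplifies this difference; `run_experiment(list(experiment = "fig1"))`
and friends orchestrate the full multi-instance experiments and write
CSV/JSON summaries, and `inst/cli/erpnet.R` exposes the same entry points
from a shell.

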