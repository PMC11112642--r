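---
title: "A rate-network model of memory-engram allocation and linking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A rate-network model of memory-engram allocation and linking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(engramsim)
```

## The model

`engramsim` simulates a recurrent network of $N = 60$ rate neurons receiving
input from a layer of $N^{in} = 30$ neurons. The firing rate $r_i$ of neuron
$i$ follows

$$\tau_r \frac{dr_i}{dt} + r_i =
  \mathrm{ReLU}\Big(\sum_j W_{ij} r_j + \sum_j W^{FF}_{ij} r^{in}_j
  - I + \epsilon_i(t)\Big),
  \qquad I = I_0 + I_1 \sum_j r_j ,$$

with $\tau_r = 15$ ms. Global inhibition is subtractive, with a baseline
$I_0 = 6$ and a term proportional to the summed population rate
($I_1 = 0.9$): it is the substrate of competition between neurons for
engram membership. Excitability $\epsilon_i$ is an additive, per-neuron,
slowly varying bias inside the rectifier.

The feed-forward weights are fixed and define three receptive fields (RFs):
inputs 1–10 project with weight 0.3 onto neurons 1–15, inputs 11–20 onto
16–30, and 21–30 onto 31–45; all other entries carry the background weight
0.2. Presenting a "context" sets the 10 input neurons of one group to
$r_{CS} = 4$ Hz, so an RF neuron receives a drive of 12 and every other
neuron a drive of 8.

Recurrent weights are plastic under a bounded Hebbian rule,

$$\tau_W \frac{dW_{ij}}{dt} = (1 + US(t))\,
  \tanh\!\big(r_j \,(r_i - \bar r_i)\big), \qquad W_{ij} \in [0, 1],$$

where $\bar r_i$ is the mean rate of the postsynaptic neuron over the
trailing $\delta = 15$ s (zero-padded at phase onset), and $US(t)$ equals
$US^+$ while an aversive unconditioned stimulus is paired with a
presentation and 0 otherwise — a three-factor rule in which neuromodulation
scales the learning rate. Connectivity is all-to-all, *including* each
neuron's autapse. This reading is load-bearing: with the diagonal forced to
zero, the net recurrent gain of a $k$-assembly at the weight cap is
$(k-1) - I_1 k < 0$, winner rates saturate near 4.4 Hz, and no neuron can
ever reach the 6 Hz active threshold — no engram, no pattern completion.
With plastic autapses the gain is $k(1 - I_1) = 0.1k$, trained assemblies
fire at 9–10 Hz, and 5–7 neurons tag, matching the published behaviour.

Excitability implements the activity-dependent intrinsic plasticity
attributed to CREB-like mechanisms: when a neuron's rate reaches the active
threshold $\theta$ during a tagging window (training sessions; recall only
in one analysis variant), it is *tagged*, and 2.9 s later its excitability
is set to the elevated value $E$, after which it relaxes exponentially to
its baseline $\epsilon^0_i$ with time constant $\tau_\epsilon$ (24 h by
default). Baselines are drawn per trial from a half-normal distribution
(the absolute value of a zero-mean normal with scale 0.5). The 2.9 s delay
always lands inside the 3 s fine-resolution window that follows each
training session, which is presumably why that window exists.

## Protocols and integration

Stimulation schedules are tibbles of sessions. A training session presents
one context $N_{stim}$ times for $\Delta T = 40$ ms with a 150 ms gap; a
recall probe presents it once. Manipulations are per-session flags: an
excitability boost (+5 drive to the first 8 neurons), an optogenetic-style
block (−0.5 drive to the first 6 of those), a reduced inhibition gain
($I_1^- = 0.88$), and per-step uniform drive noise.

Integration is explicit Euler at 0.5 ms during every session plus a
trailing window (3 s after training, 300 ms after recall), and at 20 s in
the gaps, where the recurrent weights are frozen and excitability relaxes
by its exact exponential (the closed form makes the decay independent of
how a gap is subdivided). Rates below $10^{-5}$ Hz are set to exactly zero;
in practice every assembly's activity dies out well before a fine phase
ends, so the coarse phases only carry the excitability state. Trials in
which any rate reaches 100 Hz at any step are flagged excluded and never
enter aggregates.

Read-outs: the engram $\Omega$ of a recall is the set of neurons whose
rate reaches $\theta$ at any sample during the 40 ms probe; the memory
strength is the ideal observer
$F = \sum_{i\in\Omega}\int_{t_r}^{t_r+100\,\mathrm{ms}} r_i\,dt$
(trapezoidal on the fine grid, units Hz·s), a proxy for freezing; overlap
between two recalls is $|\Omega_1 \cap \Omega_2| / |\Omega_1|$.

## Parameter presets

`engram_params()` exposes four presets. `"default"`, `"overlap"` and
`"competition"` share one calibration (chosen to match lateral-amygdala
engram statistics); `"fear"` is a second calibration for the
fear-conditioning protocol, matched to hippocampal dCA1 overlap kinetics:
$\tau_\epsilon = 12$ h, $E = 4$, $\theta = 4$ Hz, 15 presentations,
$\tau_W = 500$ ms, $US^+ = 0.5$. All other constants are documented, with
units and defaults, in `?engram_params`.

## What a simulated experiment shows

```{r, eval = FALSE}
p <- engram_params()
ex <- run_experiment("two_context", p, n_trials = 20, seed = 1,
                     delays = c(6, 24))
glance(ex)
```

Training one context recruits a winner-take-all assembly: all 15 RF neurons
depolarise, mutual weights of an eventual core saturate at the cap, global
inhibition then parks the rest just below threshold, and typically 5–7
neurons tag. A second context presented 6 h later meets the first assembly
while its excitability is still elevated
($3.5\,e^{-6/24} \approx 2.73$); the old assembly re-ignites through its
capped weights, joins the new engram, and the recall of context 2
reactivates much of engram 1 (overlap ≈ 0.5–0.7). At 24 h
($3.5/e \approx 1.29$) the old assembly loses the competition and the
engrams are disjoint. Freezing excitability at baseline abolishes the
overlap entirely, and a delay sweep is monotonically non-increasing.

## Design decisions on points the sources leave open

* **Hebbian orientation.** The dynamical equation and the learning-rule
  narration index pre and post oppositely; written in one convention they
  agree on `pre_gates_post` (presynaptic rate gating the postsynaptic
  deviation), which is the default. The transpose is available as
  `hebbian = "post_gates_pre"` for sensitivity checks; engram statistics
  are indistinguishable between the two.
* **Jump semantics.** Tagging *sets* excitability to $E$ (a set-point, not
  an increment); re-tagging in a later session sets it again. At most one
  jump is scheduled per neuron per session.
* **Noise amplitude.** "Amplitude 4" is read as the full width of the
  uniform distribution, i.e. $U(-2, 2)$ per neuron per step. The
  peak-amplitude reading $U(-4, 4)$ was rejected empirically: it destroys
  the temporal overlap gradient and excludes most trials, contradicting
  the observation that ongoing noise leaves the results intact.
* **Partial-cue recall.** The mechanism that delivers a partial cue is not
  specified. Here the chosen 4 tagged neurons receive a direct
  depolarizing current (`partial_cue_drive = 16`, driving them to
  training-like rates of ~20–25 Hz) for the 100 ms read-out window while
  the input layer stays silent. Both choices matter quantitatively: with a
  feed-forward-equivalent drive of 12 over only 40 ms, the non-cued
  members of a 6-neuron assembly peak ≈ 1 Hz short of threshold (the
  steady state is $r = (0.4c - 6 + \epsilon) / (1 - 0.1k)$ for cue
  strength $c$ and assembly size $k$, and the two-stage transient reaches
  only ~40% of it in 40 ms), whereas the stronger, longer cue completes
  the assembly robustly for $k \ge 5$.
* **Single-context recall delay.** The single-context protocol probes
  recall 1 h after training by default (`recall_delay_h`), while assembly
  excitability is still near $E$; completion from a partial cue degrades
  as excitability decays.
* **Fear-conditioning control.** The conditioning session *is* the shock
  application, so the no-shock control omits that session rather than
  repeating the context without the shock. Under the alternative reading
  (same timeline, shock gain off) the extra exposure alone nearly saturates
  the context-3 assembly and the shocked and control conditions become
  indistinguishable, contradicting the published low control bars.

## Known limitations

* **Coexistence versus displacement.** When the earlier assembly re-ignites
  during the second context's training, global inhibition usually lets it
  *displace* the new RF winners rather than coexist with them: the second
  engram is then built largely from first-engram neurons. The published
  account describes both populations co-firing. The overlap, allocation
  and competition results survive this difference; two do not. First,
  co-active sets self-limit to ≤ 10 neurons, while runaway ($\ge 100$ Hz)
  requires ≥ 11 mutually saturated co-active neurons
  ($k(1-I_1) > 1$) — so the ~10% trial-exclusion rate reported for these
  protocols does not occur here (0 of hundreds of trials; maximum rates
  ~16–19 Hz). Second, in the fear-linking protocol the 5 h-earlier context's
  assembly (trained without the shock gain, hence with weaker weights)
  rarely joins the to-be-shocked context's encoding, so the fear transfer
  to the linked context is not reproduced, although the shocked context's
  own contrast with control is.
* The network has a single homogeneous inhibitory channel, no spiking, no
  spontaneous activity outside the noise variant, and no synaptic
  tagging/consolidation mechanisms; between-session weight evolution is
  absent by construction.
* Problem sizes used by the test suite (50 single-context trials, 20
  trials per delay, 10–12 trials per manipulation condition, 100-trial
  exclusion censuses) match the protocol sizes stated in the figure
  captions, scaled to a desk machine.
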