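---
title: "From sinus-node proteomes to pacemaking: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From sinus-node proteomes to pacemaking: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pacemakeR)
```

## The scientific problem

The sinus node is the heart's natural pacemaker: a small cluster of
specialised myocytes in the right atrial wall that fire spontaneous action
potentials. Two mechanisms compete to explain that automaticity — the
*membrane clock* (an ensemble of plasma-membrane channels, foremost the
hyperpolarisation-activated HCN "funny" channels, plus T- and L-type
Ca²⁺ channels and opposing K⁺ currents) and the *Ca²⁺ clock*
(sarcoplasmic-reticulum Ca²⁺ cycling through Ryr2 release, Serca2 uptake
and electrogenic Na⁺/Ca²⁺ exchange). Deep label-free proteomics of sinus
node (SN) versus neighbouring right atrial muscle (RA) can arbitrate:
if pacemaking is proteomically encoded, the differential proteins should
be membrane-clock components, and feeding the measured abundance ratios
into a biophysical myocyte model should convert an atrial action
potential into a sinus-node one.

`pacemakeR` implements that computational chain as reusable, testable
pieces:

1. **proteome statistics** — Perseus-style differential abundance on LFQ
   intensities: isoform collapse, valid-value filtering, quantile
   normalisation, left-censored ("downshift") imputation, S0-moderated
   t-statistics with permutation FDR, and a post-hoc imputation sanity
   check;
2. **copy numbers** — conversion of iBAQ intensities into absolute
   channels per myocyte via subunit stoichiometry, anchored on an
   independent estimate of HCN4 channels per cell;
3. **single-channel Markov models** — Monte-Carlo simulation of unitary
   gating, unitary-conductance fitting, master-equation occupancies, and
   the whole-cell-conductance channel count that provides the anchor;
4. **action-potential modelling** — a config-driven Hodgkin–Huxley
   myocyte model and the proteomics-driven conversion between atrial and
   sinus-node phenotypes;
5. **synthetic data** — generators with known ground truth so that every
   stage is testable without downloading any repository data.

## Differential abundance statistics

### Filtering and normalisation

Decoy and contaminant rows are removed and protein isoforms collapsed to
the most abundant isoform (highest summed intensity). Proteins are kept
when quantified in at least `minValidPerGroup = 3` samples in SN *or* in
RA — a protein quantified only in one tissue is informative, which is
exactly why left-censored imputation is needed downstream — and when
identified with at least two peptides.

Quantile normalisation replaces each sample's sorted observed values
with across-sample mean order statistics. Missing entries are ignored
and stay missing: a sample with *k* observed values is interpolated onto
the reference at its *k* rank positions (average ranks for ties). For
complete matrices this reproduces the standard algorithm exactly (the
test suite cross-checks against `limma::normalizeQuantiles`).

### Downshift imputation

Missing values in label-free proteomics are predominantly
missing-not-at-random: low-abundance ions fall below detection. Each
missing entry in sample *s* is therefore drawn from
$\mathcal N(\mu_s - d\,\sigma_s,\ (w\,\sigma_s)^2)$ with the Perseus
standard settings, width $w = 0.3$ and downshift $d = 1.8$, where
$\mu_s, \sigma_s$ summarise the sample's observed distribution.
Imputation is per-sample, observed entries are never altered, and both
the pre-imputation matrix and the imputed mask are retained so that
significance calls can later be audited against raw evidence.

### Moderated statistic and permutation FDR

For each protein the two-sample statistic is

$$d = \frac{\bar x_{SN} - \bar x_{RA}}{se_{pooled} + S_0},\qquad S_0 = 0.1,$$

the SAM-style moderation that damps small-fold-change, low-variance
proteins; the reported p-value is the ordinary two-sided Student t on
the unmoderated statistic. Significance is decided by a Tusher-style
permutation procedure: |d| is recomputed under relabelings of the sample
group assignment that preserve group sizes, and at a cutoff *t*

$$\widehat{FDR}(t) = \frac{1 + \#\{|d^{*}| \ge t\}}{(B+1)\,\cdot\,\#\{|d| \ge t\}},$$

with the significance set taken as the largest one whose estimate stays
at or below `fdrQ = 0.05`. Three numerical choices deserve a note:

* **Exhaustive enumeration.** With 3 vs 3 samples there are only
  $\binom{6}{3} = 20$ distinct balanced relabelings; whenever the number
  of distinct relabelings is at most `nPermutations` (default 750) they
  are enumerated exhaustively rather than sampled, and sampling (for
  larger designs) draws distinct assignments without replacement.
* **Trivial relabelings are excluded.** The identity assignment and its
  group-swap mirror reproduce the observed statistics exactly. Including
  them puts a hard floor of $2/20 = 0.1$ under the estimated FDR of a
  3 vs 3 design, so a 5 % cutoff could never be met by construction;
  they carry no information about the null and are dropped (18
  relabelings remain at 3 vs 3).
* **Add-one correction.** The $+1$ in numerator and denominator is the
  finite-permutation correction that treats the observed labeling as one
  more relabeling; without it the exceedance probability of the top
  statistics is underestimated and, at 18 permutations, null data yield
  spurious calls in well over 5 % of simulations. With it, 500-fold null
  simulation keeps the realized false-call rate within the binomial
  bound of the nominal 5 % (this is asserted in the test suite).

### Imputation sanity check

Significant proteins with two or fewer quantified values in either
tissue may owe their call to imputation. For those, the pre-imputation
log2 ratio is compared with the post-imputation one; deviations larger
than `maxLog2Deviation = 2` (or a tissue with no raw evidence at all)
raise a flag. Flags are reported alongside the results, never silently
removed — exclusion is an analyst's decision.

## Channel copy numbers from iBAQ

iBAQ intensities are comparable *across* proteins, so dividing a
channel's iBAQ by its subunits-per-channel $s_X$ gives a quantity
proportional to the number of assembled channels. One absolute anchor
converts proportionality into counts:

$$N_X = N_{HCN4} \cdot \frac{iBAQ_X / s_X}{iBAQ_{HCN4} / 4},$$

with $N_{HCN4} = 6255$ channels per myocyte obtained independently from
the Markov-chain analysis below. The shipped stoichiometry table fixes
HCN4 as a tetramer and Cav1.2 as one pore-forming subunit per channel;
the remaining entries (tetrameric Kir/Kv/Ryr, dimeric two-pore K⁺
channels, monomeric Serca2/Ncx1/Cav α-subunits) follow standard channel
biochemistry and are deliberately user-overridable, because stoichiometry
is an assumption, not a measurement.

Replicate handling is *replicate-matched*: the ratio to the anchor is
formed within each replicate and the per-replicate counts are then
averaged — this preserves the pairing between a channel's intensity and
the anchor intensity measured in the same sample, and yields the
dispersion that the per-channel error bars represent. The dispersion
default is the standard deviation with a standard-error option
(`dispersion = "sem"`), since both conventions occur for such plots and
the choice should be explicit rather than guessed.

## Single-channel Markov simulation

### From HH gates to rates

The HCN4 scheme is the two-state chain C ⇌ O whose occupancy reproduces
a Hodgkin–Huxley activation gate: $\alpha(V) = y_\infty(V)/\tau(V)$ and
$\beta(V) = (1-y_\infty(V))/\tau(V)$, the unique such mapping
($\alpha/(\alpha+\beta) = y_\infty$, $1/(\alpha+\beta) = \tau$
identically). The shipped HCN4 gate is a Boltzmann activation with
half-activation −87 mV, slope 9.6 mV, and a bell-shaped time constant
(130–730 ms) peaking near the half-activation voltage — this package's
parameterisation of standard sinoatrial funny-current kinetics, with a
unitary conductance of 1.0 pS and reversal at −30 mV. Channels with
inactivation (Cav1.2, Cav3.2, ERG) use a linear four-state chain
C ⇌ O ⇌ I₁ ⇌ I₂ in which the O ⇌ I₁ edge carries the inactivation gate
and I₁ ⇌ I₂ is a slower replica (default factor 0.1) providing a deep
inactivated state; the topology *within* the two inactive states is a
modelling choice — nothing in a two-gate HH description pins it down —
and is therefore isolated behind the `fourStateScheme()` constructor.
Unitary conductances other than HCN4's 1.0 pS are placeholders and
should come from the user's configuration when absolute numbers matter.

### Monte Carlo engine

The stochastic simulation realises the discrete-time jump process with
step `dtMc = 0.02` ms: per step, state *i* moves to *j* with probability
$r_{ij}(V)\,\Delta t$. Sojourn lengths of that chain are geometric, so
the engine draws them directly (`rgeom`) instead of looping over steps —
an exact, loop-free realisation of the same law, validated in the tests
against a literal per-step Bernoulli chain and against analytic dwell
distributions. The step is guarded: if any total exit rate times `dtMc`
reaches 0.1 the simulation refuses to run and demands a smaller step
(at ≥ 1 the discrete chain is not even a probability model). Sweeps
start from the stationary distribution at the holding potential, and
the recorded current is $g_u (V - E_{rev})$ in the conducting state and
0 otherwise — single-channel noise, flicker and subconductance levels
are out of scope.

The deterministic counterpart, `occupancyODE()`, integrates the master
equation $\dot p = Q(V)^\top p$ with `deSolve::lsoda` per protocol
segment; probability conservation is asserted to 10⁻⁸ in the tests, and
Monte-Carlo ensemble averages converge to it at the binomial
$1/\sqrt{n_{sweeps}}$ rate (tested at 100 / 1 000 / 10 000 sweeps).

### The copy-number anchor

The unitary current–voltage relation is fitted from the maximum
open-level current per test potential (10 sweeps per voltage, test
pulses −140…−80 mV from a holding potential of −30 mV); its slope
recovers the 1.0 pS unitary conductance. Dividing the sinus-node
model's whole-cell HCN4 conductance (6.255 nS) by the fitted unitary
conductance and rounding gives 6 255 HCN4 channels per myocyte — the
anchor used by the copy-number module. Both the fit and the division
are recomputed from scratch by `scripts/acceptance.R`.

## Action-potential modelling

### A config-driven HH ensemble

The cited atrial and sinus-node models are not redistributed here;
instead `CellModel` is a generic Hodgkin–Huxley ensemble driven entirely
by data: each current has a maximal conductance (nS), reversal potential
(mV) and parametric gates (Boltzmann steady state, constant-plus-bell
time constant, optional instantaneous rectification), so substituting a
corrected parameter set never touches code. The shipped `atrialCellModel()`
(50 pF; I_Na, I_CaL, I_Kr, I_to, I_Kur, I_K1, background) and
`sinusNodeCellModel()` (25 pF; small I_Na, I_CaL, I_CaT, discrete HCN4
and HCN1 funny currents, I_Kr, residual I_to, no I_K1) are this
package's own reduced parameterisations, tuned to reproduce the
defining phenotypes: the atrial cell rests near −80 mV and fires
triggered, triangular APs at 200 ms pacing; the sinus-node cell fires
spontaneous APs (~110–150 ms cycle length) with a prominent diastolic
depolarisation. They are electrophysiological caricatures — adequate
for testing the *conversion logic*, not for quantitative predictions
about mouse myocytes.

Integration uses `deSolve::lsoda` (adaptive, stiff-capable) with output
on a fixed grid (`dt = 0.1` ms default); pacing (2 ms, −2000 pA square
pulses, cycle length 200 ms, all configurable) is integrated
segment-by-segment so stimulus edges are exact. Runs default to 20 s to
reach a steady state, and features are extracted from the last two
action potentials. Divergence (|V| > 200 mV) aborts with the last state.
Calcium handling is a deliberately passive two-pool SR subsystem (uptake,
gated release, leak) that carries the SR scaling entries of the
conversion table but feeds no current back onto the membrane — a known
limitation that keeps the electrical dynamics analysable; consequently
the model pair cannot exhibit Ca²⁺-clock-driven automaticity, which is
consistent with the membrane-clock reading of the proteomics but not a
test of it.

### Proteomics-driven conversion

`convertAtrialToSN()` applies, in order: capacitance 50 → 25 pF;
LFQ-ratio scaling of g(I_Na), g(I_CaL), g(I_Kr); insertion of SN-level
I_f and I_CaT (unscaled for the SN phenotype); a −7 mV shift of the
T-type half-activation; I_Kur to 0 % and I_to to 10 % (the underlying
Kv channels being undetected, these fractions are a modelling necessity
rather than a proteomic measurement); SR uptake/release scaling (ratios
of 1 — calcium-cycling proteins are not differential); and I_K1 left
unchanged by default with an optional Kir3.1/TASK-1-motivated reduction
(`scaleIK1 = TRUE`), which speeds pacemaking but changes little else.
Scaling ratios can be regenerated from any volcano result via
`computeScalingFromLFQ()` (linear ratios $2^{log_2 fc}$, geometric-mean
pooling over subunits of one current).

The reverse conversion restores a forward-converted model *exactly* from
the conversion log recorded during the forward pass — a set-to-zero
action is not otherwise invertible — and converts a genuine sinus-node
model structurally: inverse ratio scaling, funny/T-type conductances
divided by their SN/RA ratios (reduced, not removed), I_to restored,
I_Kur and the atrial I_K1 inserted (the SN model has none; without an
inward rectifier the converted cell would not rest). The result is
quiescent and, under pacing, fires one AP per stimulus.

`detectAutomaticity()` operationalises "spontaneous": at least two
upstrokes (crossing −20 mV at > 5 V/s, stimulus samples masked) in the
final quarter of the trace with a cycle-length coefficient of variation
under 10 %; a single upstroke returns an explicit *inconclusive* status
rather than a boolean, because a window shorter than two cycles cannot
distinguish slow pacemaking from a solitary event.

## The synthetic-data generator

`simulateProteome()` emulates the study design downstream code assumes:
two tissues, three replicates each, log-normal intensities
($\mu_i \sim \mathcal N(25, 2^2)$ log2 units, replicate SD 0.3), a
designated differential subset with a ±half-effect group shift (default
2 log2 units), and logistic missing-not-at-random censoring
$p_{miss}(x) = 1/(1+e^{k(x - x_0)})$ with midpoint $x_0 = 21$ (two SD
below the abundance centre, concentrating censoring in the low tail at
~5–7 % missing overall, the few-percent range typical of deep LFQ tissue
proteomes) and steepness 1 per log2 unit. Real experiments rarely reveal
their missingness mechanism; logistic left-censoring is the standard
proteomics assumption and is precisely what makes the downshift
imputation test meaningful. `generateChannelTable()` produces iBAQ
tables whose ground-truth copy numbers are known: the anchor's realized
per-replicate intensity is a shared multiplicative factor and
channel-specific noise (CV 0.1 by default) multiplies on top, so
within-replicate anchor ratios carry only the channel's own noise and
the round-trip through `summarizeReplicates()` is unbiased — exact at
CV 0, within 1 % in the median at CV 0.1.

What the generator does *not* emulate: peptide-level quantification,
match-between-runs structure, correlated missingness across samples,
intensity-dependent variance, or batch effects. Passing tests therefore
demonstrate correctness of the algorithms under the stated generative
model, not robustness to every pathology of real LFQ data.

## Problem sizes and reproducibility

The test suite runs at deliberately modest sizes — 150–400 proteins for
volcano analyses, 500 null simulations for FDR calibration, 1 000 seeds
for the copy-number round-trip, up to 10 000 sweeps for the Monte-Carlo
convergence law, and 10 s cell-model runs for the automaticity
assertions — sizes at which every distributional bound in the tests is
already sharp. All randomness flows through explicit integer seeds into
R's Mersenne-Twister generator, restored after use; re-running the
pipeline with the same configuration and seed reproduces every output
file byte-for-byte, and the run manifest records seeds, configuration
and input checksums.

## Known limitations

* The FDR procedure controls the error rate under exchangeability of
  samples across groups; strong imputation artefacts can inflate the
  realized false-discovery proportion on heavily censored proteins —
  that is exactly what the sanity-check flags surface.
* Copy numbers inherit every assumption of iBAQ linearity, the
  stoichiometry table, the myocyte-origin assumption for channel
  protein, and the single HCN4 anchor; errors in the anchor rescale all
  counts proportionally.
* The cell models are reduced caricatures with passive calcium handling
  and in-house kinetics; conversion results are statements about the
  scaling logic and the shipped parameterisation, not about the cited
  published models.
* Four-state inactivation topology and the I₁ ⇌ I₂ rate factor are
  conventions; alternative connectivities reproduce the same two-gate
  HH behaviour.
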