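---
title: "A stochastic kinetic model of H3K27 modification dynamics around the TSS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A stochastic kinetic model of H3K27 modification dynamics around the TSS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromK27)
```

## The model

Histone H3 lysine 27 (H3K27) integrates the antagonism between Polycomb
silencing and transcriptional activity. chromK27 simulates the dynamics of
this residue on a one-dimensional lattice of 200 H3 tails (two independent
tails per nucleosome, 100 bp per tail) spanning 20 kbp around a
transcription start site. Each tail carries one of five mutually exclusive
states — unmodified (u), acetylated (ac), mono-, di- or tri-methylated
(me1/me2/me3) — and evolves as a continuous-time Markov jump process whose
propensities are driven by per-site occupancy densities of three enzymes:
SUZ12 (a proxy for bound PRC2), p300 and UTX.

The reactions, per site $i$ with state ladder $u \leftrightarrow me1
\leftrightarrow me2 \leftrightarrow me3$ and the acetylation branch $u
\leftrightarrow ac$:

* **Methylation** $me_{x-1} \to me_x$ at rate
  $k_{me_x}\,\psi_{suz12}(i) + \epsilon_{me_x}\sum_{j\neq i}
  P(i,j)\,\psi_{suz12}(j)\,\delta_{j,me3}$. The first term is local
  nucleation by bound PRC2; the second is the long-range allosteric
  spreading by PRC2 complexes bound at trimethylated sites, weighted by the
  polymer contact kernel $P(i,j) = |i-j|^{-\lambda}$ with $\lambda = 1$
  (the average power law seen in chromosome contact data). The spreading
  rates are $\epsilon_{me_x} = R\,k_{me_x}$, with a single
  spreading-to-nucleation ratio $R$ for every methylation level. The kernel
  diagonal is zero — the on-site action *is* the nucleation term — and the
  kernel is not normalized; any constant is absorbed into $R$.
* **Demethylation** $me_x \to me_{x-1}$ at rate $\gamma_{me}\,\psi_{UTX}(i)$,
  independent of the methylation level.
* **Acetylation** $u \to ac$ at rate $k_{ac}\,\psi_{p300}(i)$ and
  deacetylation $ac \to u$ at rate $\gamma_{ac}$.
* **Turnover**: every site exchanges its histone at rate $\gamma_{turn}$,
  resetting any modification to u. The exchange is state-blind: it also
  fires on unmodified sites, where it only flips the old/new pool label.
  This keeps the old-histone fraction independent of the epigenetic state,
  as a physical exchange process must be.
* **Replication**, every $T$ hours: each site independently keeps its state
  or is reset to u with probability 1/2 (random partition of parental
  histones onto the sister chromatids). Replication is a scheduled event,
  not a stochastic reaction; the Gillespie clock is truncated there and the
  waiting time redrawn, which is exact for a time-homogeneous process.

Default parameters (1/h unless noted): $k_{me3} = 0.81$ with ratios
$r_{13} = k_{me1}/k_{me3} = 3$ and $r_{23} = k_{me2}/k_{me3} = 3$,
$R = 0.85$, $\gamma_{me} = 1.5$, $k_{ac} = 1.03$, $\gamma_{ac} = 0.6$,
$\gamma_{turn} = 0.03$, $T = 13.5$ h. These are the wild-type mESC values;
`modelParams()` returns them and every one can be overridden.

The spreading ratio maps onto an allosteric fold change of PRC2 activity
through the contact geometry, $F = R / [(6/\pi)(a/d_0)^3]$ with capture
distance $a = 10$ nm and distance prefactor $d_0 = 22$ nm
(`allosteryFoldChange`). Literal evaluation gives $F \approx 5.6 R$
($\approx 4.7$ at $R = 0.85$); claims elsewhere of $F \sim 8R$ from the same
numbers do not follow from the formula, and we implement the formula.

## Enzyme profiles

Profiles are dimensionless densities on the lattice, either read from
bedGraph / two-column text (`readProfileTrack`, with quantile-capped
normalization `normalizeTrack` and 300-bp moving-average smoothing
`smoothProfile` for user tracks) or generated from Gaussian presets:
$\psi(x) = \psi_m e^{-(x-i_0)^2/2\sigma_0^2} + \psi_b$, $x$ in kbp from the
TSS.

The p300 constants are the published wild-type fit around PcG-target
promoters ($\psi_b = 0.1196$, $\psi_m = 0.1666$, $i_0 = -0.5438$,
$\sigma_0 = 5.1875$; we interpret the printed $i_0, \sigma_0$ in kbp, the
axis on which such profiles are plotted). Preset profiles scale peak
heights — never backgrounds — by recruitment factors $\alpha$ (SUZ12) and
$\beta$ (p300 and UTX jointly): `pcg_target` is $(\alpha,\beta) = (1,0.3)$,
`active` $(0,1)$, `bivalent` $(0.4,0.5)$. The active-gene p300 amplitude is
defined as $0.1666/0.3$ so the PcG preset at $\beta = 0.3$ reproduces the
wild-type fit exactly.

The SUZ12 and UTX peak constants are not published; they are packaged
values fixed once by `scripts/calibrate_presets.R` (seeded) so that, under
the default rates: the $(1, 0.3)$ preset shows the PcG-target valency with
a me3/me2 crossover near 5 kbp; the $(0, 1)$ preset the active valency; the
admissible windows of the inference scheme (below) are centred near
$\gamma_{me} = 1.5$ and $R = 0.85$; and the establishment tempos (washout
recovery $\approx 1$–$2\,T$ over the region, near-TSS establishment
$\approx 1\,T$ after a profile switch) fall in their expected ranges. The
static valencies constrain mostly amplitude *ratios*; the tempo pins the
absolute amplitude scale. Shipped values: SUZ12 $\psi_b = 0.005$,
$\psi_m = 0.22$, $\sigma_0 = 1.7$; UTX $\psi_b = 0.030$, $\psi_m = 0.12$,
$\sigma_0 = 2.0$ (both centred on the TSS).

## Simulation engine

`simulateTrajectory` / `runEnsemble` run a statistically exact Gillespie
algorithm (compiled core) with a per-site spreading-sum cache updated
incrementally when any site enters or leaves me3. Protocols
(`simulationProtocol`) define burn-in (default 25 cell cycles from a fully
unmodified lattice), duration, the recording grid (default 0.5 h; a sample
falling exactly on an event time shows the pre-event state),
synchronization (common replication phase 0, or one uniform phase per
trajectory), scheduled parameter/profile change events
(`washoutProtocol`, `switchProtocol`), and the pool label epoch after
which replaced histones count as "new". Ensembles derive per-trajectory
sub-seeds deterministically from one master seed
($s_j = (1000003\,s + 7919\,j) \bmod (2^{31}-1)$), so results are
reproducible regardless of execution order.

```{r quick-example}
prof <- makePresetProfile("pcg_target")
prot <- simulationProtocol(duration = 2 * 13.5, burnInCycles = 10,
                           recordInterval = 1)
ens <- runEnsemble(prof, modelParams(), prot, nTraj = 8, seed = 1)
P <- meanProfiles(ens)
round(rowMeans(P[, abs(positionsKbp(prof)) <= 2.5]), 3)
```

## Observables

* `meanProfiles`: per-site state probabilities averaged over trajectories
  and recorded samples (the asynchronous-population steady state).
* `classifyValency` / `valencyCall`: the threshold rules on the ±2.5 kbp
  window means — PcG-target-like iff $\bar P_{me2} > \bar P_{me1}$ and
  $\bar P_{me3} > 1.5 \bar P_{me2}$; active-like iff $\bar P_{me1} > \bar
  P_{me2}$ and $\bar P_{me2} > 1.5 \bar P_{me3}$; otherwise intermediate.
* `crossoverDistance`: the distance at which me2 overtakes me3, scanning
  outward from the TSS on each side and requiring the inversion to persist
  for 3 consecutive sites (a run reaching the lattice edge counts); the two
  side distances are averaged. The scan direction, persistence length and
  averaging are our choices — the quantity is otherwise ill-defined on
  noisy profiles.
* `correlationMap`: Pearson correlations between (site, state) indicator
  variables pooled over time and trajectories. Degenerate indicators (mean
  0 or 1) are flagged and reported as NA rather than silently zeroed.
* `phaseDiagram`: valency labels over the recruitment grid $\alpha \in
  \{0, 0.2, \ldots, 1.4\}$, $\beta \in \{0, 0.2, \ldots, 2.0\}$.

Time-resolved analyses: `cellCycleAverage` folds synchronized trajectories
modulo $T$; `trackPools` follows mark proportions in the old and new
histone pools; `effectiveDecayTime` fits $e^{-t/t_e}$ to the old-histone
fraction. The exact uniform-phase expectation is available in closed form
(`oldFractionClosedForm`): $f(t) = e^{-\gamma_{turn} t} 2^{-\lfloor t/T
\rfloor}(1 - r/2T)$ with $r = t \bmod T$. The default $t_e$ fit is
unweighted least squares on the linear scale over the full window, which
weights early times more and yields $\approx 12.8$ h on the ideal curve;
the log-scale alternative recovers the asymptotic slope $1/(\gamma_{turn} +
\ln 2/T) \approx 12.3$ h. Both are exposed; the linear fit is the default
because it matches how such decay curves are usually fit to labeling data.

## Exact oracles and validation

Two independent solutions back the engine in the test suite: a dense
master-equation solution of a two-site system (25 joint states, matrix
exponential) built from the pure-R propensity table, and
`singleSitePeriodicSteadyState`, the periodic fixed point of the five-state
single-site master equation with the replication map $p \mapsto p/2 +
e_u/2$, exact for the full lattice when $R = 0$ (sites decouple). The
closed-form acetylation steady state
$P_{ac} = k_{ac}\psi / (k_{ac}\psi + \gamma_{ac} + \gamma_{turn} + \ln 2/T)$
treats dilution as an effective first-order rate; against the exact
periodic solution this approximation is good to better than 0.02 absolute
at the default rates, and the tests assert that bound.

## Parameter inference

`iterateInference` mirrors the multi-step scheme used to parameterize the
model from perturbation conditions:

1. **Acetylation** (`fitAcetylation`): in the methyltransferase-null
   condition the model reduces to u/ac; $(k_{ac}, \alpha_{bg})$ minimize an
   unweighted chi-squared between the closed form and the observed
   acetylation profile, with the null-condition p300 modeled as the
   wild-type Gaussian peak over a corrected background
   $\alpha_{bg}\psi_b$.
2. **Demethylation** (`fitGammaMe`): the no-spreading condition ($R = 0$)
   is simulated over a $\gamma_{me}$ grid; values reproducing the observed
   promoter valency me2 > me3 > me1 are admissible, and the midpoint of the
   admissible interval is returned.
3. **Spreading** (`fitR`): the wild type is simulated over an $R$ grid;
   admissible values give the PcG valency *and* a me3/me2 crossover within
   5.0 ± 0.5 kbp.
4. **Nucleation** (`fitKme3`): the demethylase-null condition
   ($\gamma_{me} = 0$, acetylation off) is on the absolute probability
   scale; $k_{me3}$ minimizes chi-squared over a grid with one bisection
   refinement.

Steps 2–4 repeat until all three parameters change by less than `tolRel`
(default 5%) or a step fails (`failed_valency`), and `ratioGridScan`
repeats the loop over integer $(r_{13}, r_{23})$ pairs with $r_{13} \ge
r_{23}$ and several $k_{me3}$ initializations. Chi-squared scores are
unweighted sums over the full ±10 kbp window. Numerical choices that
matter, all taken because the scans are Monte-Carlo-noisy: the $k_{me3}$
grid is evaluated with common random numbers so the noise cancels in the
argmin; the $\gamma_{me}$/$R$ scans use independent seeds per grid point
and return the midpoint of the longest contiguous admissible run; the
crossover test smooths profiles over 3 bins first. The goodness score of a
converged pair combines the absolute demethylase-null me3 chi-squared with
scale-fitted chi-squareds of the relative no-spreading and wild-type
methylation profiles (one free scale per condition, since normalized ChIP
signal is only proportional to modification probability); the relative
terms carry most of the information about the ratios, which the absolute
me3 profile alone cannot discriminate. Scores are computed with a tripled
trajectory budget.

`makeSyntheticTargets` generates all four observation conditions at known
parameters with independent truncated-Gaussian per-site noise (default 5%
coefficient of variation — the noise model of real normalized tracks is
not specified anywhere, so this is a package choice) for parameter-recovery
testing.

## What the synthetic presets do and do not emulate

The presets reproduce the *average* enzyme landscape of gene classes as
smooth Gaussians. Real ChIP tracks have sequence-specific structure,
binning noise, and condition-dependent occupancy changes that the presets
deliberately lack; the EZH2-null and demethylase-null conditions reuse the
wild-type p300/UTX occupancies (as the original parameterization did, for
want of measured ones). Passing tests therefore show that the machinery —
engine, observables, inference — is correct and self-consistent under the
stated model, not that the model fits any particular locus; fitting real
loci requires supplying normalized tracks through `readProfileTrack`.

## Problem sizes

Default test and example budgets are chosen for practicality on a single
CPU: steady-state summaries use 8–32 trajectories over 10–25 burn-in
cycles; dynamics protocols 100–500 trajectories; inference scans 8–16
trajectories per grid point with grids restricted to brackets around the
admissible windows. All are configurable; the defaults in exported
functions match the reference conditions (32 trajectories, 25 cycles for
profiles; 500 trajectories, 100 h for pool dynamics).

## Known limitations

* No transcription feedback, PRC1/H2AK119ub or H3K4/H3K36 crosstalk: the
  model is deliberately restricted to the H3K27 subsystem.
* The contact kernel is locus-independent ($|i-j|^{-\lambda}$); any
  user-supplied symmetric kernel with zero diagonal is accepted, but no
  locus-specific contact maps are shipped.
* One 20-kbp window per run; this is not a genome-wide track engine.
* Replication is symmetric; leading/lagging-strand asymmetries are not
  modeled.
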