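# chromK27

Stochastic kinetic simulation of H3K27 acetylation and methylation dynamics
around transcription start sites, with the associated parameter-inference
scheme.

## The problem

Polycomb silencing in stem cells is written on lysine 27 of histone H3: the
residue can be unmodified (u), acetylated (ac) or mono/di/tri-methylated
(me1/me2/me3), and the balance between PRC2 (methylation), UTX
(demethylation), p300 (acetylation), histone turnover and replication
dilution decides whether a gene's chromatin is repressed, active or
bivalent. chromK27 implements a quantitative five-state Markov model of
this system on a lattice of 200 H3 tails covering ±10 kbp around a TSS, for
anyone who wants to simulate these dynamics, reproduce the wild-type mESC
parameterization on synthetic data, or fit the model to their own
normalized enzyme-occupancy tracks.

Per site *i*, the methylation propensity me<sub>x-1</sub> → me<sub>x</sub> is

    k_mex * psi_suz12(i)  +  R * k_mex * sum_j |i-j|^-1 * psi_suz12(j) * [j is me3]

(local nucleation by bound PRC2 plus allosteric long-range spreading from
trimethylated, PRC2-bound sites through 3D contacts); demethylation runs at
`gammaMe * psi_utx(i)`, acetylation of u at `kAc * psi_p300(i)`,
deacetylation at `gammaAc`, turnover at `gammaTurn`, and every 13.5 h
replication randomly resets half the sites to u. Wild-type rates
(`modelParams()`): kMe3 = 0.81/h, kMe1 = kMe2 = 3 kMe3, R = 0.85,
gammaMe = 1.5/h, kAc = 1.03/h, gammaAc = 0.6/h, gammaTurn = 0.03/h.

The engine (Gillespie algorithm, compiled core) is statistically exact,
tracks old/new histone pools, and supports scheduled protocols: inhibitor
washout (spreading off → on), enzyme-profile switches, synchronized
cell-cycle averages. Observables include mark profiles, methylation-valency
classification, me3/me2 crossover distance, state–state correlation maps
and the (alpha, beta) recruitment phase diagram. The inference module
re-implements the multi-step scheme that fixed the wild-type parameters
from methyltransferase-null, no-spreading, wild-type and demethylase-null
profiles, plus a synthetic-target generator for parameter-recovery tests.

## Worked example

Steady state of a wild-type Polycomb-target gene (synthetic preset, 16
trajectories, 15-cycle burn-in):

```r
library(chromK27)
prof <- makePresetProfile("pcg_target")         # (alpha, beta) = (1, 0.3)
prot <- simulationProtocol(duration = 3 * 13.5, burnInCycles = 15,
                           recordInterval = 1)
ens  <- runEnsemble(prof, modelParams(), prot, nTraj = 16, seed = 1)
P    <- meanProfiles(ens)
valencyCall(ens)
#> $label
#> [1] "pcg_like"
#> $means
#>     u    ac   me1   me2   me3
#> 0.040 0.018 0.042 0.168 0.732
crossoverDistance(smoothProfile(P["me3", ]), smoothProfile(P["me2", ]),
                  lattice(prof))
#> [1] 4.95
```

Within ±2.5 kbp of the TSS, 73% of H3 tails carry me3 and the valency
me3 >> me2 > me1 classifies the locus as Polycomb-target-like; moving away
from the TSS, me2 overtakes me3 at ~5 kbp, the signature of
nucleation-limited spreading. Setting `R = 0` in `modelParams()` reproduces
the no-spreading (EZH2-null-like) state, `makePresetProfile("active")` the
active-gene landscape.

A shell entry point with the same functionality is installed as
`exec/chromk27` (subcommands `simulate`, `infer`, `phase-diagram`,
`dynamics`, `fit-ac`, `normalize-track`; each run writes TSV outputs and a
JSON manifest).

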