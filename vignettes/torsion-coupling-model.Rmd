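---
title: "Modelling torsion-mediated coupling between adjacent genes"
author: "torsionCouple"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling torsion-mediated coupling between adjacent genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(torsionCouple)
```

## The model

Transcription twists DNA. As the polymerase tracks the helical groove of
the template, rotational drag prevents the large elongation complex from
spinning around the molecule; instead the DNA itself is overwound ahead
of the complex and underwound behind it (the twin-supercoiled-domain
picture). Negative superhelical density $\sigma$ destabilises base
pairing and makes promoter opening cheaper; positive $\sigma$ stabilises
the duplex. A gene therefore broadcasts a mechanical signal along the
chromosome: it *represses* promoters downstream of its 3' end and
*activates* promoters upstream of its own promoter, out to a few
kilobases. When two genes sit within that range, each modifies the
other's initiation rate, and the pair must be solved self-consistently.

`torsionCouple` implements this model in four layers, plus a genomics
pipeline and synthetic-data generators.

### 1. The torsion field

The time-averaged superhelical density generated by one transcribed unit
decays exponentially from its edges,

$$\Delta\sigma(x) \;=\; \pm\,\sigma_a\, e^{-d(x)/b},
  \qquad \sigma_a = \alpha\,k\,l,$$

with $d(x)$ the distance to the nearer unit edge, $+$ downstream of the
3' end and $-$ upstream of the TSS. The amplitude is proportional to the
expression rate $k$ and transcript length $l$, consistent with the
polymerase injecting about one turn of twist per helical repeat
transcribed; the decay length $b$ reflects how efficiently
topoisomerases relax the stress.

Tunable parameters (`torsionParameters()`):

* `b = 1000` bp — in vivo measurements of the propagation of
  transcription-generated stress, in organisms as different as bacteria
  and human cells, consistently give a decay scale of about one
  kilobase.
* `alpha = 3e-5` per (rate × bp) — a calibration constant tying the
  arbitrary expression unit to $\sigma$; the default makes a 1-kb gene
  at unit rate radiate $\sigma_a = 0.03$, comparable to measured local
  supercoiling near active genes.
* `sigma0` — the basal density of the region: around $-0.06$ for
  exponentially growing bacteria (range $-0.03$ to $-0.09$), near $0$
  for eukaryotic free DNA.

Fields from several genes superpose additively (`fieldAt()`), which
reduces to the pair treatment for two genes and extends to chains.
Inside a transcribed unit the profile is drawn by linear interpolation
between the $-\sigma_a$ and $+\sigma_a$ edges; this is a plotting
convention only — promoters of valid pairs never sit inside a partner's
unit, and the coupling model never consumes interior values.

### 2. Opening energy of a promoter sequence

The probability that the initiation site is melted at a given $\sigma$
is computed with a single-bubble stress-induced duplex destabilization
(SIDD) ensemble (`siddProfile()`): the closed duplex plus every state
with one denatured run of up to `maxBubble` bases. A state's free energy
is the nucleation cost $a$, the per-base pairing energies of the open
run (A:T cheaper than G:C), and a torsional term found by minimising,
over the twist $\tau$ retained by the open strands,

$$E(\tau) = \tfrac{C}{2} n \tau^2
  + \tfrac{K}{2}\Big(\alpha_{Lk} + \tfrac{n}{h}
  - \tfrac{n\tau}{2\pi}\Big)^2,
  \qquad K = \frac{2200\,RT}{N},$$

which has the closed form used by the engine and is checked in the test
suite against an exhaustive enumeration with numerical minimisation.
$\alpha_{Lk} = \sigma N / h$ is the linking difference of the domain of
size $N$. The site-opening free energy is the log-odds
$\Delta G_{open}(\sigma) = -RT \log[p/(1-p)]$, capped (and flagged) when
$p$ underflows.

Default energetics (all overridable in `siddParameters()`): nucleation
10.8 kcal/mol, A:T 0.26 and G:C 1.30 kcal/mol per bp at 37 °C, open-strand
torsional stiffness 2.5 kcal/mol/rad²/bp, helical repeat 10.4 bp/turn.
These are conventional duplex-destabilization values declared here as
package defaults so that every computation is reproducible from the
configuration alone.

One design choice deserves emphasis. With $K \propto 1/N$ and
$\alpha_{Lk} \propto N$, the opening energy of a site depends on how
much flanking sequence is included in the analysed fragment — padding
the fragment enlarges the stress budget, which is unphysical if the
fragment merely samples a larger fixed domain (a plasmid, a topological
domain). The `domainSize` parameter therefore pins $N$ independently of
the fragment length; with the domain pinned, adding random flanks
changes the site's $\Delta G_{open}$ by less than 0.1%. The default
(`NA`) keeps the conventional fragment-length behaviour.

At extreme positive torsion a second, elastic destabilization of the
duplex exists in thermodynamic models; it is deliberately excluded here,
and only a monotone fitted dependence is used downstream.

The coupling simulations consume a five-parameter sigmoid
(`fitSigmoid()`, `sigmoidOpening()`):

$$\Delta G_{open}(\sigma) = q + v\sigma
  + m\,\Lambda\!\Big(\frac{\sigma-\sigma_c}{w}\Big),$$

with $\Lambda$ the standard logistic, $\sigma_c$ the sequence-dependent
destabilization threshold and $w$ the transition width. This is the
minimal form with exactly those five degrees of freedom that covers both
plateaus of the crossover. The fit is a Levenberg–Marquardt least
squares on the non-capped profile points, with a Nelder–Mead fallback;
under 0.1 kcal/mol Gaussian noise on 50 grid points the threshold is
recovered to better than $\pm 0.005$.

The reference promoter used throughout the pair simulations is
`sigmoidOpening()`'s default ($\sigma_c = -0.05$, $w = 0.015$,
$m = 8$ kcal/mol, $v = 0$, $q = 2$ kcal/mol): essentially closed at
relaxed DNA and opening sharply across the physiological range, the
qualitative shape computed for strong viral and bacterial promoters.

### 3. From opening energy to a rate

Initiation is treated as a two-state binding equilibrium with total free
energy $\Delta G_{init}(\sigma) = \Delta G_{open}(\sigma) + \Delta
G_{bind}$, the binding term independent of $\sigma$ (twist deformations
under physiological stress are smaller than thermal fluctuations over
the footprint of an individual factor). Bubble formation in vivo is not
purely thermal — polymerases, notably eukaryotic Pol II with its
ATP-consuming helicase subunit, assist it — so the equilibrium is
evaluated at an *effective temperature* $T_e$:

$$k(\sigma) = k_{max}\, e^{-\Delta G_{init}(\sigma)/k_B T_e}.$$

The unsaturated Boltzmann form is adopted deliberately: it is the only
form under which the fold-change

$$\rho(\sigma;\sigma_0) =
  e^{-[\Delta G_{open}(\sigma)-\Delta G_{open}(\sigma_0)]/k_B T_e}$$

is *exactly* independent of $\Delta G_{bind}$ and $k_{max}$, so that
coupling predictions need no knowledge of the binding energetics. The
default $T_e = 1.8 \times 310\,\mathrm{K}$ is an explicit placeholder of
the right order for in vivo eukaryotic expression;
`calibrateEffectiveTemperature()` fits $T_e$ from paired
$(\sigma, \text{expression})$ measurements by log-linear regression, and
every quantitative result in this package that matters is a
$T_e$-parameterised ratio, never a hard-coded temperature.

### 4. Self-consistent coupling

For genes $i = 1 \ldots n$ with rates $k_i$, each promoter sees

$$\sigma_i = \sigma_0 + \sum_{j \neq i} G_{ij}\, k_j,$$

where $G_{ij}$ is the signed exponential factor of gene $j$'s field at
gene $i$'s TSS per unit rate. A gene's own lobes are excluded from its
own promoter: self-influence would produce unconditional
self-activation, whereas the mechanism under study is the influence of a
*neighbouring* gene. `solveCoupling()` iterates the map with synchronous
damped updates (damping 0.5, relative tolerance $10^{-8}$, at most
10 000 iterations), starting from the rates in the absence of local
supercoiling. The symmetric start plus synchronous updates preserve any
symmetry of the construction, so identical divergent or convergent genes
converge to exactly equal rates rather than to one of the asymmetric
extinction states that mutual repression can harbour. Amplitudes are
recomputed from the current rates at every step, so the torsional output
of a gene always reflects its current activity.

Numerical honesty notes: the damped difference is compared to
`relTol * damping` so that the test is on the undamped residual;
exponents are capped at $\pm 500$ with a warning; non-convergence
returns a flagged result rather than an error. In the strongly
activating regime (close divergent pairs at relaxed $\sigma_0$) the
self-reinforcing loop saturates at the opening plateau of the sigmoid —
fold-changes then approach the promoter's full dynamic range
($e^{m/k_B T_e}$, about $10^3$ with the defaults) and the nominal
promoter-local $\sigma$ can leave the physical range; this is the
expected behaviour of a mean-field model with a rate-proportional source
and should be read as "fully switched on", not as a physical density.

`phaseDiagram()` maps fold-change over (distance, $\sigma_0$) grids for
the three orientations, reporting one gene for the symmetric divergent
and convergent constructions and both genes for tandem. The sweep runs
on the same numeric fixed-point core as `solveCoupling()` (verified
identical in the tests), building each distance geometry once; a 50 × 50
diagram takes seconds.

Promoter distance on diagram axes is TSS-to-TSS by default, so
convergent diagrams begin at the summed gene lengths; `distanceMode =
"gap"` switches to intergenic-gap spacing (the ambiguity between the two
conventions is real, so both are exposed).

## The genomics pipeline

`selectIsolatedPairs()` reproduces the genome-scale analysis: walk
adjacent non-overlapping genes per chromosome and keep pairs that are
(i) *close* — each transcription unit within 5 kb (nearest point,
strict) of the partner's TSS — and (ii) *torsionally isolated* — both
TSSs more than 3 kb from every other annotated transcription unit.
Every annotated gene counts as a perturber in (ii), including non-coding
genes and genes dropped from pairing because they overlap another gene.
The promoter is operationalised as the annotated TSS point. Orientation
follows the strand pattern of the left/right genes (divergent `-/+`,
convergent `+/-`, tandem otherwise), and separation defaults to the
intergenic gap — under TSS-to-TSS spacing, convergent pairs of multi-kb
genes could never populate sub-3-kb bins.

`binnedStatistics()` aggregates pairs into 200-bp separation windows:
pair counts, correlated-pair counts, the expressed fraction (nonzero
entries over all gene × experiment entries — the reading that yields a
genome-wide average near one half for deep RNA-Seq of 24 lines; a
per-gene reading would not), and total and mean expression per window,
with the exact identity total $= 2 \times$ count $\times$ mean. Two
genes are *correlated* when they are jointly expressed in at least 6 of
the experiments **and** their Pearson correlation across all experiments
(zeros included) exceeds 0.5; zero-variance profiles fail the criterion,
and no multiple-testing correction is applied — the criterion is a fixed
threshold, not a p-value procedure. Tandem windows are additionally
summarised separately for upstream and downstream members.

## The synthetic-data generators

`makeGenome()` plants neighbour-gene pairs with known orientation,
separation, and isolation status on one chromosome. Cassettes are spaced
7–9 kb apart so that unspoiled pairs are isolated *by construction*;
spoiled pairs receive a cluster of three perturber genes whose nearest
edge sits 2 kb from the pair's left TSS — inside the isolation radius —
and whose members mutually spoil any pair they could themselves form.
Background genes are laid out in tight triplets (plus distant singles)
for the same reason. The truth table thus enumerates exactly which pairs
a correct filter must accept, independently of the filter itself.
Defaults follow the observed dominance of divergent isolated pairs
(75 divergent : 55 tandem : 10 convergent, a roughly one-tenth-scale
genome), 1-kb genes, and gap ranges that keep most divergent and tandem
pairs below 1 kb with convergent gaps up to 3 kb.

`makeExpression()` emulates the gross structure of a 24-cell-line
RNA-Seq compendium: per-gene log-normal baselines (meanlog 2, sdlog 1),
per-entry Bernoulli dropout (0.5, matching the genome-wide expressed
fraction near one half), and then two signals: accepted pairs are
multiplied by the fold-changes the coupling model assigns to their
orientation and separation, and a designated fraction of sub-kilobase
accepted pairs shares a per-experiment latent factor (at strength 1 the
two profiles are exactly proportional, passing the Pearson criterion by
construction). What the generator does **not** emulate: count
overdispersion, isoform structure, chromatin-domain correlations,
cross-pair chains of coupling. Passing tests on these fixtures therefore
demonstrate the internal consistency of the pipeline and model — not
that real genomes satisfy the model.

`makePromoters()` emits random sequences with an AT-rich central core,
the minimal sequence feature that gives a promoter-like destabilization
threshold. All generators are pure functions of their (spec, seed) and
restore the caller's RNG state.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use desk-scale sizes chosen
as the smallest that exercise every code path with clear margins:
40-mer exhaustive-oracle comparisons (20-point $\sigma$ grids), 50-point
sigmoid fits, 20 randomized pair configurations against a
scan-plus-bisection fixed-point oracle, 50 × 50 phase diagrams,
50-planted-pair genomes, and 100-seed ensembles for the selection-bias
property. Ties in the correlation criterion are impossible by
construction (strict inequalities); degenerate inputs (flat profiles,
zero-variance expression, non-positive rates, overlapping geometries)
raise errors or fail criteria explicitly rather than propagating NaN.

## Known limitations

* The mean-field, time-averaged picture ignores transcription bursts,
  polymerase collisions on convergent genes, and all elongation
  kinetics; it cannot say *when* two genes are co-transcribed, only what
  their average coupled rates are.
* Competing stress-absorbing transitions (Z-DNA, cruciforms,
  G-quadruplexes) and regulatory proteins binding melted distal sites
  are out of scope; promoters governed by those mechanisms (notably
  non-monotone supercoiling responses) are outside the model class.
* Nucleosome dynamics are subsumed into the single decay length $b$.
* The single-bubble SIDD ensemble omits multi-run states; it is adequate
  here because downstream simulations consume only the fitted monotone
  sigmoid.
* Fold-change magnitudes in the saturated divergent regime depend on the
  sigmoid amplitude $m$ and $T_e$; orientation signs and distance decay
  do not.
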