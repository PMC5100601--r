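---
title: "Modelling ribosome traffic and tRNA-depletion sensitivity with codonqueue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling ribosome traffic and tRNA-depletion sensitivity with codonqueue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonqueue)
```

## The model

codonqueue simulates the translation of a single mRNA as a totally
asymmetric simple exclusion process (TASEP) with extended particles. The
coding sequence is a lattice of $L$ sense codons; each ribosome occludes
$\ell = 9$ codons (its physical footprint) and is tracked by the codon in
its A-site, with the footprint extending downstream, over codons
$p \ldots \min(p+\ell-1, L)$. Dynamics are continuous-time:

* **Initiation.** A ribosome loads with its A-site at codon 1 at rate
  $\alpha$ (s$^{-1}$), but only when codons $1\ldots\ell$ are all free.
* **Two-state elongation.** At codon $i$ a ribosome first waits for its
  cognate tRNA, arriving at rate $k_i$ proportional to the concentration of
  the decoding tRNA species, then translocates one codon at rate
  $\gamma = 35\,\mathrm{s}^{-1}$, provided the codon entering its footprint
  is free. Blocked ribosomes simply wait; there is no drop-off and no
  overtaking.
* **Termination.** From the last sense codon the ribosome exits at rate
  $\beta = \gamma$ (termination is not limiting). The stop codon is stripped
  at ingest and is not a lattice site.

The observables are the steady-state current $J$ (proteins produced per
second, equal to the long-run initiation and termination rates) and the
per-codon A-site density $\rho_i$. Exact waiting times are exponential and
events are selected by the Gillespie algorithm, implemented in C++ with one
seeded 64-bit generator per run, so a run is bit-reproducible from its seed.

Codon 1 (AUG) is an ordinary two-state site using the initiator-tRNA
abundance; no special start kinetics beyond $\alpha$ are modelled.

## Arrival rates from tRNA abundance

`build_rate_table()` maps a tRNA complement to per-codon arrival rates:
$k(\mathrm{codon}) = c \sum_s a_s$ over the species $s$ decoding the codon
(additive iso-acceptor decoding), with $a_s$ the species' relative
abundance, by default its genomic gene copy number (GCN). An in silico
depletion multiplies one species' abundance by a factor in $(0,1]$; the
default 0.25 mimics a mutant with a quarter of the wild-type tRNA level.

The proportionality constant defaults to $c = 3\,\mathrm{s^{-1}}$ per
abundance unit. This places a codon decoded only by a single-gene-copy tRNA
at $k = 3\,\mathrm{s^{-1}}$ — a strong arrival-limited pause
(net $\approx 2.8$ codons/s against $\gamma = 35$) — while abundantly
decoded codons (summed abundance 5–16) run at 15–48 s$^{-1}$, fast relative
to both translocation and physiological initiation demand. Two regimes
follow, and they are the point of the model: wild-type translation at
$\alpha = 0.3\,\mathrm{s^{-1}}$ is initiation-dominated, and only rare
(single-copy-decoded) codons can seed ribosome queues once depleted. We
considered calibrating $c$ from a mean-rate target instead; any calibration
that pushes single-copy codons well below $\approx 2.5\,\mathrm{s^{-1}}$
puts even the *wild type* of a rare-codon-rich mRNA into the jammed phase
at physiological initiation, which inverts the 5' density signature the
screens rely on, so the fixed per-unit constant is the default. Both $c$
and the whole codon→tRNA assignment are data, not code: the packaged
complement (`inst/extdata/scerevisiae_trna_synthetic.tsv`) is a synthetic
curation of a yeast-like 42-species complement from standard wobble rules
and approximate gene copy numbers, and any table with the same columns can
be supplied.

Tunable parameters, defaults, and meaning:

| parameter | default | meaning |
|---|---|---|
| `alpha` | 0.3 s$^{-1}$ | initiation attempts; physiological reference rate |
| `gamma` | 35 s$^{-1}$ | translocation after tRNA binding, codon-independent |
| `beta` | `gamma` | termination from the last sense codon |
| `footprint` | 9 codons | ribosome width, sets exclusion and the initiation clearance rule |
| `scaling` (c) | 3 s$^{-1}$/unit | tRNA arrival per abundance unit |
| depletion `factor` | 0.25 | mutant-mimicking abundance reduction |
| sensitivity `threshold` | 0.5 | ratio below which an ORF is called sensitive (2-fold down) |

## Measurement protocol

Each run discards a burn-in of
$\max(10\,T_1,\ \text{time to the first 20 terminations})$, where
$T_1 = 1/\alpha + \sum_i 1/k_i + (L-1)/\gamma + 1/\beta$ is the
single-ribosome transit time. A short pilot (a tenth of the termination
target) then estimates $J$ to size equal-length measurement batches; whole
batches are appended until at least `target_terminations` (default 1000)
proteins have been released or `max_time` (default $10^5$) simulated
seconds have elapsed, with a minimum of 10 batches. $J$ is the termination
count over the measured time and its standard error comes from the batch
means; densities are time-weighted A-site occupancies accumulated per
batch, giving per-codon standard errors the same way. Because batch
boundaries stop the clock between events, the exponential memorylessness
makes the frozen-state resumption exact.

The heavier analyses in this package's tests and acceptance script use
3000–4000 terminations per run (and a raised time cap at the smallest
initiation rates); at those sizes the relative standard error of $J$ is
1–2% and a full six-point initiation scan of a 221-codon mRNA takes well
under a second.

One invariant deserves a note: the *exact* current always satisfies
$J \le \alpha$, but a finite measured current is a ratio of a thinned
Poisson count to a time span and fluctuates above $\alpha$ about half the
time in the initiation-limited regime. `validate_sim_result()` therefore
asserts the bound statistically, at three standard errors.

## The exact oracle

For small lattices the full continuous-time Markov chain is tractable:
`enumerate_states()` lists every configuration of disjoint, ordered
ribosomes with their two internal states (e.g. 19 states at $L = \ell = 9$),
and `exact_current()` solves the global balance equations with a sparse LU
factorisation, one balance row replaced by the normalisation. The exact
current is read off the termination flux,
$J = \beta\,P(\text{tRNA-bound ribosome at } L)$, and satisfies
$\alpha\,P(\text{codons } 1..\ell \text{ free}) = J$ exactly — both
identities are tested. Because a 9-codon footprint on a tractable lattice
admits at most two ribosomes, the oracle supports any footprint, and the
engine is cross-validated at $\ell = 3$ where three or four ribosomes
interact. When exactly one ribosome fits ($L = \ell$), translation is a
renewal process and $J = [1/\alpha + \sum 1/k_i + \ell/\gamma]^{-1}$, which
the solver reproduces to $10^{-10}$ and the simulator to within three
standard errors.

A subtlety the enumeration settles: the footprint truncates at the last
codon, so on a 10-codon lattice a ribosome at $p = 10$ occupies only codon
10 and a second ribosome can initiate behind it — 25 states, not the 21 a
"one ribosome only" intuition suggests.

## Screens, scans, and densities

`run_screen()` compares wild-type and depleted translation ORF by ORF. The
design is paired: both conditions use the same per-ORF seed, derived
deterministically from the master seed and the `orf_id`. A factor-1
"depletion" is then bit-identical to wild type and every ratio is exactly
1 — so ratio noise is attributable to the depletion, screens are
reproducible, and results are independent of row order and scheduling. The
ratio's standard error uses first-order propagation from the two currents'
batch-means errors; a deterministic seed-per-condition variant was
rejected because it breaks the exactness of the factor-1 and
synonymous-swap controls.

`alpha_scan()` traces the depleted/wild-type ratio over an initiation-rate
grid; `density_compare()` contrasts 5'-window A-site densities between
conditions at a physiological (0.3 s$^{-1}$) and a slow (0.05 s$^{-1}$)
initiation rate; `multi_trna_screen()` repeats the screen for every tRNA
species in turn; `correlate_sensitivity()` regresses the
translation-efficiency ratio of the most sensitive ORFs on their focal
rare-codon content (the focal count normalised to other rare codons, with
explicit `Inf`/`NaN` sentinels for empty denominators excluded and
counted).

"Rare codon" defaults to a codon decoded exclusively by single-gene-copy
tRNA species; the set is configurable.

## What the synthetic fixtures emulate — and what they do not

`make_trna_complement()` builds a complement with a controlled contrast:
single-copy species (GCN = 1), each the exclusive decoder of one rare
codon (the first is always the CAG decoder, with synonymous CAA decoded
abundantly, so swap experiments work out of the box), and abundant species
(GCN drawn from 5..11, the documented within-isoacceptor spread)
partitioning the background codons. `make_transcriptome()` plants focal
codons into ORFs at three placements: `clustered_5prime`, `dispersed`, and
`clustered_3prime`, and emits a truth table of planted properties
alongside the sequences and an initiation-rate table (constant
0.3 s$^{-1}$ by default, or log-uniform; empirical per-mRNA rates are not
modelled).

Two deliberate design choices make the fixtures *sharper* than real data:

* Background ORFs avoid rare codons entirely, so depletion-immunity
  controls are exact (bit-identical trajectories) rather than statistical.
* `clustered_5prime` places the focal cluster within codons 10–24:
  inside the 5' region, but downstream of the 9-codon initiation clearance
  window. A depleted codon *inside* codons 1–9 suppresses initiation by
  direct occlusion — a single-ribosome effect that decays only linearly in
  $\alpha$ — whereas the phenomenon of interest is collective: a queue at
  the cluster grows back into the clearance window at high $\alpha$ and
  dissipates at low $\alpha$. Downstream placement isolates that
  queueing mechanism, and the fixture then shows the full signature: ratio
  $\approx 0.35$ at $\alpha = 0.3$, $\approx 1$ at $\alpha = 0.01$, and a
  5' density differential at high but not low initiation.

Real transcriptomes differ in ways the fixtures do not attempt to capture:
codon usage is biased but not partitioned, rare codons occur at low rates
everywhere (so immunity is approximate), initiation rates vary over more
than a decade between mRNAs, and decoding is shared across iso-acceptors
with wobble. Passing the fixture-based tests therefore demonstrates that
the machinery detects elongation-limited, queue-mediated sensitivity where
it exists by construction — not that any particular real mRNA is sensitive.

A related, honest caveat: with arrival rates tied to gene copy number over
an 11-fold spread, depleting an *abundant* species to 25% is not strictly
invisible — its codons slow from ~15–35 s$^{-1}$ to ~4–8 s$^{-1}$, which
shaves a few percent off the current of ORFs rich in those codons at
physiological initiation. No sensitivity calls result (ratios stay far
above the 0.5 threshold, as the robustness analyses expect), but the
deviation from 1 is systematic and exceeds its standard error. Making
abundant depletion fully invisible would require an abundance dynamic
range much wider than gene copy number provides, or per-mRNA initiation
rates well below 0.3 s$^{-1}$; both are properties of data this package
does not ship.

## Numerical choices and degenerate inputs

* State keys and seeds: per-ORF seeds are a 31-bit hash of the master seed
  and `orf_id`; all seeds stay below $2^{31}$.
* The stationary solve rejects solutions with negative mass or
  normalisation error above $10^{-10}$; state enumeration refuses more
  than $2\times10^5$ configurations.
* ORFs shorter than the footprint cannot be simulated and are skipped with
  a warning (screens record them); sequences whose length is not a multiple
  of three, or with ambiguity codes, fail per record at ingest.
* Internal stop codons are kept as lattice sites with a warning; trailing
  stops are stripped and re-appended on FASTA export so round-trips are
  exact. `U` and `T` are interchangeable on input; internally everything
  is DNA.
* Ratio of two currents with a zero denominator cannot arise in practice
  (rates are strictly positive and runs measure at least one batch), but
  composition ratios use explicit `Inf`/`NaN` sentinels.

## Problem sizes used in the tests

Unit tests run at 200–800 terminations per run on ORFs of 60–221 codons;
the oracle comparisons use 4000 terminations on lattices of 9–12 codons;
the transcriptome-scale robustness check simulates 100 ORFs under three
abundant-tRNA depletions at 1000 terminations per run. These sizes keep the
whole suite in the low tens of seconds while holding Monte-Carlo standard
errors at the 1–5% level the assertions need.

## Known limitations

* No drop-off, frameshifting, collision-induced abortion, mRNA decay, or
  shared ribosome/tRNA pools across mRNAs — each mRNA is simulated in
  isolation with fixed rates, and tRNA charging is folded into abundance.
* The A-site convention (footprint downstream of the tracked codon) is one
  of several used in the literature; density profiles should be compared
  across conventions only qualitatively.
* Exact solutions are limited to small state spaces; at transcriptome
  scale the Gillespie engine is the only route, with statistical rather
  than exact guarantees.
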