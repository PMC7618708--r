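---
title: "Modeling premature termination by RNA polymerase I and profiling nascent-transcript ends"
author: "polterm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling premature termination by RNA polymerase I}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polterm)
```

## The problem

In growing yeast each active ribosomal DNA (rDNA) repeat carries on the
order of 50 RNA polymerase I (RNAPI) complexes transcribing the ~7 kb
pre-rRNA. Elongation is a Brownian ratchet: thermally driven forward and
backward translocation, biased by nucleotide addition and by the local free
energies of the nascent transcript and the transcription bubble. Because
one full DNA rotation is needed per ~10.3 nt synthesized, and the bulky
nascent pre-ribosomes block rotation of the polymerase itself, the
polymerases on one repeat are coupled by accumulated DNA twist ("torsional
entrainment"): any relative movement between neighbours builds torque that
resists it. Near the transcription start site the nascent transcript is
short, rotation is less hindered, and this coupling is weak — polymerases
there pause, backtrack, and are exposed to the RNA surveillance machinery,
so a fraction of transcription events terminates prematurely.

`polterm` provides (i) a stochastic lattice simulator of one transcription
unit with a tunable premature-termination probability, (ii) the demand
bookkeeping that converts simulated per-unit output into per-generation
ribosome numbers, and (iii) the profile-level analyses used on
nucleotide-resolution nascent-transcript data (CRAC): 5'/3'-end tracks,
unit normalization, Blackman smoothing, replicate bands, oligo(A)
selection, peak calling, metaplots, readthrough fractions, and a
rolling-window folding-energy track. A synthetic-data generator emulates
the statistical structure of the real sequencing data so that every
analysis stage runs and is tested without any download.

## The lattice model

One transcription unit is a 1D lattice of `geneLength` (7000) positions.
Polymerases occupy `footprint` (38) nt and are advanced with time step
`dt` (0.004 s). Each step, in order:

1. **Initiation.** Every `initiationInterval` (2.0 s) an attempt is made;
   it succeeds with `initiationProb` (0.8) if positions 1..38 are free.
   The interval is a calibration choice: the attempt schedule behind the
   per-attempt probability is not observable, and an attempt every 4 ms
   would saturate the lattice far above the ~50 polymerases seen per
   repeat. With 0.8 per 2 s, the steady-state load is ~54 polymerases and
   the initiation flux ~0.4 s^-1 per unit, which together reproduce both
   the observed load and (scaled to 75 active repeats) a per-generation
   output near the cell's demand.
2. **Translocation.** Each polymerase, iterated downstream to upstream,
   draws one move (+1, -1, or stay) from an exponential-bias ratchet
   (below). A move is vetoed when it would bring two polymerases within
   one footprint (steric exclusion) or off the template.
3. **Premature termination.** Every polymerase at position <=
   `ptDistance` is removed with probability `hazard * dt`, where
   `hazard = pPt * vBar / ptDistance`. Scaling the total per-transit
   probability `pPt` by the expected residence time in the
   termination-competent region makes termination proportional to
   occupancy time, so slow or paused polymerases are hit more often —
   matching the observation that surveillance marks concentrate at sites
   of slow elongation. The hazard is applied per second (x `dt` per
   step); in the constant-velocity limit the terminated fraction is
   exactly `1 - exp(-pPt)`, which is why `pPt` only approximates the
   complement of processivity rather than equaling it.
4. **Run-off.** A polymerase reaching `geneLength` is counted as
   productive and removed.

Processivity is `productive / (productive + nonProductive)`.

### The translocation bias

The detailed force field of the ratchet is a design decision of this
package. Both directions share a baseline attempt probability
`p0 = 0.25`; a bias energy `E` (in thermal units) tilts them as
`p_f = p0 * exp(+E/2)` and `p_b = p0 * exp(-E/2)`. The baseline bias
`E0 = 2 * asinh(vBar * dt / (2 * p0))` makes the drift on a neutral
template exactly `vBar * dt` per step — the calibration contract
(50 nt/s by default), which the test suite verifies empirically to
within 5%. Three additive terms modify the baseline:

* **Structure.** Paired nascent RNA in the `structureWindow` (11) nt
  behind the polymerase blocks reverse translocation: the mean folding
  bias over that window, weighted by `dgStructure` (1.25), is subtracted
  from the backward log-rate only.
* **Hybrid.** The RNA:DNA hybrid (11 nt) contributes the same way with
  weight `dgHybridRatio * dgStructure` (0.48 ratio).
* **Torsion.** Each adjacent pair of polymerases carries an accumulated
  relative twist: a forward step adds 1/10.3 turn between the mover and
  each neighbour. The resulting bias is linear in the twist difference
  with stiffness `torsionC` (0.5), scaled by both partners' entrainment
  factors, and applied symmetrically (it pushes a leader back and pulls a
  laggard forward). Twist relaxes to zero whenever a pairing changes
  (initiation, termination, run-off) — an abstraction of topoisomerase
  swivel activity.

The entrainment factor of a polymerase ramps linearly from 0 at the TSS to
1 at `lerLength` (2000) nt of transcript — the low-entrainment region
(LER). Setting `lerLength = 0` disables the ramp (full entrainment
everywhere), the configuration used when isolating the effect of premature
termination on the 5' occupancy bias.

Biases are computed in a fixed downstream-to-upstream order with one
shared random stream, which prevents same-step pass-through collisions
deterministically; probabilities are clamped into [0, 1] (clamping events
are counted and reported).

The folding bias track fed to the simulator is the min-max normalized
folding-energy track (strongest folding = 1), decoupling the folding
engine's units from the ratchet's energy units. A neutral template
(all-zero track) is used wherever only fluxes and loads matter, since the
calibration fixes the mean velocity; the structure terms shape occupancy,
not mean throughput.

## From units to ribosomes

Following the replicate design of 16 parallel units standing in for 75
transcriptionally active repeats (half of 150), per-unit full-length
counts are multiplied by 4.7 (75/16 to one decimal; `activeRepeats / n`
for other unit counts) and extrapolated linearly in time from the
steady-state window to a 6000-s generation. The first transit
(`geneLength / vBar` = 140 s) is excluded as the empty-lattice start-up
transient. `pptThreshold()` scans a sweep for the smallest
premature-termination probability whose mean output falls below the
"decreased" boundary of 150,000 ribosomes per generation (the demand
model also carries the 200,000 demand and the 100,000 "insufficient"
boundary; the boundary used for the threshold is configurable since the
demand-compatible range could also be read as the lower boundary).

**Problem sizes.** The package's desk-scale defaults are 600-s runs with
4 seeds for load estimates and 1200-s runs with 32 independently seeded
units per sweep cell; at these sizes the Monte-Carlo standard error of a
cell's extrapolated output is ~0.5%, tight enough to resolve the ~1%
margin separating the 0.2 sweep point from the 150,000 boundary.
Full-scale mode (6000 s, 16 units) reproduces the generation-length
design exactly; output extrapolation is linear after burn-in, and
doubling the simulated time doubles productive counts within Monte-Carlo
error.

## The synthetic CRAC generator

`makeReference()` builds a 7000-nt unit with 1300-nt flanks: random
composition, a palindromic cassette spanning the two stem cleavage sites
(B0-1/B0-2, +14 and +49 nt past the 25S 3' end B2) so pairing-based
folding engines score a stem there, and a T-rich run at the terminator T1
(B2 + 93). `simulateReads()` draws per-replicate read sets with:

* 3'-end positions from a mixture of Gaussian peaks (defaults at unit
  positions 437, 647, and a 3'-ETS peak at 6932 = B0-2 + 25) over a 20%
  uniform background;
* a cleavage class (30%) whose 5' ends are pinned at B0-2, with read
  lengths from a shifted negative binomial whose median is 25 nt — the
  signature of fast co-transcriptional stem cleavage;
* non-templated oligo(A) tails (3 + geometric nt) attached with
  probability interpolating from 2% in background to 25% at planted
  peaks, emulating surveillance tailing at slow sites, plus a 2% rate of
  uninformative non-A-terminal tails.

What it does **not** emulate: sequencing error, PCR duplication,
multi-copy mapping ambiguity, or any sequence-composition signal outside
the planted elements. Round-trip tests on this generator therefore
demonstrate that the analysis stages recover planted structure, not that
they are robust to those real-data artifacts.

Reads are exchanged as BED6+1 (column 7 = tail sequence or "."), with the
tail stored explicitly rather than inferred from aligner soft-clips, so
the analysis is independent of aligner behaviour.

## Analysis conventions and numerical choices

* Coordinates are 0-based half-open on disk (BED/bedGraph) and 1-based
  in memory; unit-relative positions are reported against the TSS.
* Unit normalization divides by the total over the unit window and then
  adds a 1e-7 pseudocount to every position (pseudocount after
  normalization; the order is exposed via the `pseudo` argument). A flag
  prevents double normalization.
* Blackman smoothing (window 10) uses a kernel normalized to sum 1;
  edges use the truncated, renormalized kernel, so constants are exact
  fixed points and total signal is conserved away from edges.
* Replicate summaries use interpolated quartiles (R's default type-7
  quantile); the readthrough comparison is a two-sided Wilcoxon rank-sum
  test, exact for small tie-free samples and normal with continuity
  correction otherwise.
* The oligo(A) rule requires the terminal run of the tail to be >= 3
  adenosines (a tail ending in a non-A base disqualifies), the stringent
  reading given that the tailing machinery adds to the extreme 3' end;
  `tailAllA = TRUE` gives the stricter all-A mode.
* Peak calling smooths with a centered moving average (window 80) and
  calls positions strictly greater than everything within +/- 45 nt
  (ties to the leftmost); a height floor (default: the smoothed track
  mean, since no floor is inherent to the comparator) suppresses noise
  maxima, and positions within 45 nt of a boundary are not callable.
  Troughs are called by negating the track. A peak blacklist supports
  excluding a designated feature from metaplots.
* The folding track scores, for each position, the 65 nt of extruded RNA
  ending 15 nt behind the polymerase (the region inside the enzyme is
  skipped); incomplete windows are NA. The bundled engine is a maximum
  base-pairing dynamic program (Watson-Crick + G:U, minimum loop 3,
  -1 kcal/mol per pair) — deterministic and dependency-free, but not
  thermodynamically exact; any function mapping a sequence to a score
  <= 0 can be plugged in. Because the background pairing of random RNA
  is high under maximum-pairing scoring, relative dips at planted stems
  are modest; the simulator consumes only the normalized relative bias.

## A small run

```{r example, eval = FALSE}
params <- SimParams(simTime = 600, seed = 1)
out <- simulateUnit(params, burnIn = 140)
out
processivity(out)
fivePrimeBias(out)

sweep <- runGrid(SimParams(), pPtValues = c(0, 0.2, 0.5),
                 ptDistances = 7000L, replicates = 8L,
                 seeds = 1:8, simTime = 600, burnIn = 140)
sweep[, c("pPt", "ribosomesPerGeneration", "meanPolCount")]
pptThreshold(sweep)
```

## Limitations

* The ratchet's functional form (exponential biasing around a calibrated
  baseline) reproduces the calibration contract and the qualitative
  behaviours tested here, but is an independent re-design; no
  bit-compatibility with any other implementation is claimed.
* Backtrack-resolution kinetics (endonucleolytic cleavage of backtracked
  transcripts), topoisomerase recruitment kinetics, and
  surveillance-degradation kinetics are not modeled; a prematurely
  terminated transcript is simply discarded.
* Sequence-dependent hybrid thermodynamics and nucleosome dynamics of
  inactive repeats are out of scope.
* Absolute folding energies depend on the plugged-in engine; only
  relative, window-level comparisons are meaningful with the bundled
  maximum-pairing engine.
* With a generation-scale simulated time the processivity estimator is
  undefined until at least one polymerase has left the template; very
  short runs surface this as an error rather than a silent NA.
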