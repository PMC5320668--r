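---
title: "Methylation haplotype reconstruction: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methylation haplotype reconstruction: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methaplo)
```

# The inference problem

Bisulfite sequencing reads carry two layers of information: the
genotype of the fragment they come from, and its cytosine methylation.
Because conversion acts on one strand of the fragment and mapping
returns everything in forward orientation, a single position can look
very different depending on which strand the fragment was read from —
an unmethylated CpG yields T on forward-strand reads but C on
reverse-strand reads.  methaplo exploits exactly this asymmetry: it
jointly infers, for a genomic window, a partition of the reads into
*haplotype chains* (groups of reads from the same epi-allele), a
fragment strand for every read, and a six-state epigenotype sequence
for every chain.

## The observation model

The per-position state space is {A, C, G, T, meC, meG}; meG stands for
a G whose reverse-strand partner C is methylated, so that methylation
of a CpG is representable on both strands.  Conversion probabilities
P(Z | g, r) follow the fragment physics: with failed-conversion rate
`alpha_fail` and inappropriate-conversion rate `beta`,

| g    | forward read         | reverse read         |
|------|----------------------|----------------------|
| A    | A                    | A                    |
| T    | T                    | T                    |
| C    | T (1-a), C (a)       | C                    |
| G    | G                    | A (1-a), G (a)       |
| meC  | C (1-b), T (b)       | C                    |
| meG  | G                    | G (1-b), A (b)       |

(a = `alpha_fail`, b = `beta`).  With all error rates zero, a fragment
state maps to a unique pair of (forward-read, reverse-read) bases —
only six of the sixteen conceivable pairs can occur, and the map is
invertible; `enumerate_error_free_observables()` and
`decode_observable_pair()` expose it.  This is also why reads from both
strands are needed for unambiguous inference: a lone T is consistent
with both an unmethylated C and a plain T.

Sequencing error composes on top:
P(D = d | g, r) = (1 − 4ε/3) P(Z = d | g, r) + ε/3, where
ε = 10^(−Q/10) from the Phred score, clamped to [1e−6, 0.75].  The
upper clamp keeps a Phred-0 base a proper distribution; the lower
avoids exact zeros so all computation can stay in log space.  An N base
contributes factor 1 everywhere.

The *configured* conversion rate is the success rate (default 0.95, a
conservative choice for real libraries); the model's failed-conversion
rate is its complement.  Both numbers are reported by
`methaplo(verbose = TRUE)` so that there is no ambiguity about which
convention a run used.

## Priors and the posterior

The structure prior gives each read a factor √L_b (Σ l_j)² of its chain
(range length L_b, total member read bases Σ l_j): thick chains are
favored over long thin ones, which is what makes reads cluster at all —
without it the likelihood alone never rewards moving a read out of its
own singleton chain.  Mate pairs are one unit here: a pair counts once,
with l = the bases of both mates.  The genotype prior multiplies, per
chain position, q when the nucleotide projection (meC → C, meG → G) is
the reference base or a known variant, and 1 − q otherwise
(q = 0.9999 by default; q = 0.5 disables reference guidance).
Positions where the reference is N allow any nucleotide — a hard zero
would make windows with assembly gaps unusable.  The strand prior is
uniform and drops out.
All normalization constants are ignored; posterior values are therefore
comparable only within one data set.

## Feasibility

A read may be added to a chain only when their overlap spans at least
K0 bp and contains at least K1 CpGs, K2 isolated CpGs, and K3 isolated
GpCs; a chain is feasible when it has positive coverage over its whole
range and is buildable by such additions starting from a single read.
Isolation uses the standard HCGD / DGCH contexts (H = not G, D = not
C): an isolated CpG cannot be confused with enzymatic GpC methylation
and vice versa, which is what makes the NOMe decomposition possible.
Overlap counting uses the union of mate footprints and reference
contexts (contexts of the inferred genotype would make feasibility
depend on the current optimum; the reference is deterministic).
Defaults (single WGBS / paired WGBS / NOMe): K0 = 40/50/40,
K1 = 1/2/0, K2 = 0, K3 = 0/0/2.  Larger K0/K1 for paired data reflect
the longer effective reads; NOMe clusters on enzymatic GpC signal, so
K1 = 0 and K3 = 2.

## The epigenotype dynamic program

Given a chain's members and strands, the optimal strand-compatible
epigenotype sequence maximizes the summed emission log-likelihood plus
the genotype prior.  Strand compatibility is encoded in an eight-state
first-order Viterbi DP: methylation exists only as a pair — meC opening
a CpG pair must be followed by meG closing it, and in NOMe mode meG may
open a GpC pair closed by meC.  Consequences worth knowing:

* methylation can be called at non-reference CpGs (a variant creating a
  CpG is representable), because the pairing rule constrains the
  *inferred* sequence, not the reference;
* each position belongs to at most one pair, so in a GCG context the
  DP represents either the GpC pair or the CpG pair, not both
  simultaneously;
* the published compatibility rule for NOMe mode is nominally required
  only at isolated sites; the DP enforces pairing everywhere, a
  slightly stricter and much more tractable constraint (an unpaired,
  "isolated" meC would be unidentifiable anyway and is excluded
  outright).

The DP is exact; a test verifies it against exhaustive enumeration of
all strand-compatible sequences on small windows.

## Optimization

Fitting starts from the all-singleton structure (always feasible) and
sweeps the read units in genomic order: each unit is tentatively
detached — if that disconnects its chain or leaves a remainder that is
no longer buildable under the K rules, the remainder is decomposed into
buildable blocks — and the best strictly improving destination among
its own singleton chain and every feasible chain, at either strand, is
accepted.  Ties keep the current assignment; improvement uses a 1e-7
tolerance against floating-point jitter; the pass limit is 50.

Single-read moves alone have two systematic blind spots, both found by
testing against an exhaustive-search oracle and both addressed by
deterministic chain-level moves attempted only when a sweep accepts
nothing:

* **Merges.** Moving one read out of a chain shrinks the donor's
  range-length prior term, so merging two halves of the same epi-allele
  is near-zero-gain read by read even when the full merge improves the
  posterior substantially.  A merge is attempted for overlapping chain
  pairs whose union is buildable.
* **Tail swaps.** Two chains that each stitch together the left part of
  one epi-allele and the right part of the other are stable under
  single-read moves — every read agrees with its local mosaic segment.
  Exchanging the parts on either side of a breakpoint repairs this in
  one move.

Finally the whole search runs twice, sweeping left-to-right and
right-to-left, and keeps the higher posterior: greedy ascent is
trajectory dependent, and two deterministic starts blunt the worst
local optima while keeping runs exactly reproducible.  Every chain any
move produces is verified buildable, so the optimizer never leaves the
feasible space that the brute-force oracle (`brute_force_fit()`, pure
R, exhaustive over partitions, strand assignments, and addition orders)
searches — the test suite asserts the fit never exceeds the oracle and
matches it on at least 90% of small instances.

The posterior is non-decreasing across accepted moves and the
configuration space is finite, so termination is guaranteed; hitting
the pass limit is reported with a warning.

## Noise filtering and calls

The depth fraction of a chain is its total read bases divided by the
total read bases of all chains whose ranges overlap it, the chain
itself included (so a lone chain has depth fraction 1; the published
wording is ambiguous about whether overlapping chains contribute their
full read lengths or only the overlapped portion — this implementation
uses full lengths).  A chain is kept when
`a <= length + b * depth_fraction`, with a = 5000, b = 20000 for
single-layout WGBS and a = 10000, b = 28500 otherwise (the paired
values are reused for NOMe, which is paired here).  Filtering is purely
post-inference.

Per position and chain, the fit-ratio
F = 2(max_{x ∉ {g, ḡ}} ℓ(x) − max_{x ∈ {g, ḡ}} ℓ(x)) measures the
inferred epigenotype's support; F_R and F_A make the same comparison
for the reference and alternative nucleotide (paired with their
methylated variants when C or G).  The combined genotype at a position
aggregates the kept chains passing F ≤ −15 or |F_R − F_A| ≥ 15;
methylation levels are the fraction of covering reads whose chain is
methylated at the position; NOMe accessibility marks an isolated GpC
accessible when its chain carries the meG–meC pair, with inaccessible
intervals delimited by midpoints between a run of protected GpCs and
its accessible neighbors (truncated at chain ends — the midpoint
convention is a choice; only "approximate lengths" are meaningful at
~10 bp GpC spacing).

# The simulator

`simulate_reads()` is the generative mirror of the observation model:
fragments pick an epi-allele by frequency, a strand uniformly, and a
start uniformly; every covered base passes through the conversion table
and the Phred error channel; forward-mapped reads are emitted exactly
as a bisulfite mapper would present them, together with a full truth
record.  `empirical_conversion_rates()` closes the loop by recovering
the conversion parameters from simulated reads by method of moments.

What the simulator deliberately does **not** emulate: PCR duplicates
and chimeras, mapping errors, fragment-length biology beyond a fixed
span, context-dependent conversion efficiency, and base-quality decay
along the read (a constant or per-cycle Phred profile is supported).
Passing tests on simulated data therefore demonstrate correctness of
the inference given the model, not robustness to artifacts the model
excludes.

## Validation scenarios

The canned scenarios fix the study conditions so results are functions
of the seed alone:

* **ASM region** (`sim_asm_scenario`): 3 kb window whose 30 CpGs form a
  central CpG island (one CpG per 45 bp over ~1.3 kb — imprinted DMRs
  sit in CpG islands, and island-like density is what gives every
  fragment several methylation-informative positions); two epi-alleles
  at frequency 0.5, one fully methylated, one unmethylated with a
  distinguishing A>T SNV placed outside any CpG/GpC context; paired
  100 bp reads with a 220 bp fragment span at depth 20; conversion rate
  0.95, β = 0.05, Phred 30.  The island layout matters structurally:
  with CpGs spread uniformly over the window, the fragment span is
  smaller than twice the CpG spacing and the two-CpG overlap rule then
  caps chain growth at one CpG past the last accreted one — no
  optimizer could recover full-region chains from such data.
* **Homogeneous control**: the same geometry with a single methylated
  allele.
* **NOMe block** (`sim_nome_scenario`): 800 bp of a CG-free repeat with
  an isolated GpC every 10 bp, one allele accessible everywhere except
  a central 147 bp protected block, depth 30.
* **Small random instances** (`sim_random_instance`): ≤ 80 bp windows
  with 3–6 short reads for oracle comparisons, and 600 bp windows with
  10–50 reads for ascent/termination checks.

Problem sizes in the test suite and acceptance script (50 seeds for the
recovery scenarios in the tests, 15–25 in the faster acceptance script;
200 oracle instances; 100 ascent instances) were chosen so the full
suite completes in a few minutes on one core.

# Known limitations

* Windowed operation only; chains are never merged across windows.
* α, β, and q are global constants, not position- or context-dependent.
* Read pairs must be properly paired and strictly columnar (no indels
  or clipping); everything else is skipped with a count.
* The coordinate ascent is a local search: on regions whose read
  realization admits no feasible single chain per epi-allele (possible
  at low depth when two chain fragments interpenetrate by fewer than
  K1 CpGs), the epi-allele necessarily stays fragmented and may fall
  below the noise filter.
* No posterior uncertainty beyond the fit-ratios.
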