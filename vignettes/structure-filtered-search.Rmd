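---
title: "Structure-filtered search of enzyme variants: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-filtered search of enzyme variants: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(structfilter)
```

## The problem

Homology searches for orthologs of a seed enzyme — say, a fungal
non-ribosomal peptide synthetase (NRPS) whose product one wants to express
heterologously — routinely return tens of thousands of hits. Most of those
hits are redundant database entries, fragments, fusions with unrelated
domains, or proteins that share local sequence similarity without sharing
the seed's fold. Experimentally screening such a set is out of reach for
most laboratories, so the computational task is one of *aggressive,
auditable triage*: keep only candidates that plausibly share the seed's
global fold and its substrate-contacting residues, and rank what remains.

`structfilter` implements that triage as a deterministic pipeline of five
stages. Every candidate receives a verdict row recording the outcome of
every stage and, if eliminated, the reason.

## The pipeline, stage by stage

### 1. Redundancy clustering

Candidates are clustered greedily at a sequence-identity threshold
(default 0.99). Sequences are visited longest-first (ties broken by id);
each either joins the first cluster whose representative is at least the
threshold identical to it or founds a new cluster. Identity is computed as
identical columns of a global affine-gap alignment divided by the length
of the shorter sequence — the convention of the widely used greedy
clustering tools — so a perfect fragment of a longer sequence counts as
100% identical and is absorbed. The representative (the longest member)
proceeds; members keep a pointer to their representative. A config switch
(`identity_denominator = "alignment"`) changes the denominator to the
number of alignment columns for users who prefer that convention.

### 2. Length window

Candidates far longer than the seed tend to carry additional unrelated
domains; far shorter ones tend to lack the full catalytic machinery. An
inclusive window `[length_min, length_max]` around the seed length (e.g.
800–1500 aa for a ~1000-aa seed) is therefore applied to the cluster
representatives. For fragmented sources such as metagenome assemblies the
window should be relaxed, and the pipeline allows any bound to be
disabled.

### 3. Structure resolution

The structural filter needs a model per candidate. A candidate whose id
has a model in the supplied index uses it directly. Otherwise the
highest-identity sequence in a proxy pool with identity of at least
`proxy_identity_min` (default 0.95) lends its model; ties prefer the
longer proxy, then the lexicographically smaller id. A candidate with
neither is excluded with reason `"no model"` — absence of a model is a
verdict, not an error, because it is a real and common outcome.

### 4. Global structural similarity

Candidate and seed models are aligned with a TM-align-style iterative
heuristic operating on CA traces:

* **Superposition.** The rigid rotation/translation minimizing RMSD is the
  closed-form Kabsch solution via SVD, with reflection correction so the
  rotation determinant is always +1.
* **Score.** The TM-score of a correspondence is
  $\mathrm{TM} = \frac{1}{L}\sum_i \frac{1}{1+(d_i/d_0)^2}$ with
  $d_0 = \max\{0.5,\ 1.24\,(L-15)^{1/3} - 1.8\}$ Å, normalized by the
  *seed* length $L$. Normalizing by the seed makes scores comparable
  across candidates of different sizes and matches the seed-anchored
  coverage filter; the floor of 0.5 Å keeps $d_0$ positive for short
  chains.
* **Alignment.** Initial correspondences come from a global sequence
  alignment of the residue strings and from gapless diagonal offsets
  (strided to at most `max_starts`; small problems are covered
  exhaustively). Each initialization is refined by iterating: superimpose
  on the current correspondence; recompute all CA–CA distances; re-derive
  the correspondence by dynamic programming with per-pair score
  $1/(1+(d_{ij}/d_0)^2)$ and zero gap penalty; stop when the
  correspondence is stable or after 30 iterations. The zero gap penalty is
  the TM-score-family convention: distant pairs contribute almost nothing,
  so gaps are implicitly penalized by lost score rather than explicitly.
* **Robust scoring.** For a fixed correspondence the reported TM-score
  uses the best superposition found by refitting on
  progressively distance-trimmed subsets of the pairs (score always
  evaluated over all pairs). This prevents a few distant pairs from
  dragging the fit away from a well-superposed core.

A candidate passes when `tm_min <= TM <= tm_max` (default [0.5, 1.0] —
above 0.5 two structures conventionally share a fold) *and* seed coverage
(aligned pairs / seed length) is at least `coverage_min` (default 0.70).
Both bounds are inclusive. Coverage can alternatively be normalized by the
alignment length (`coverage_denominator = "alignment"`); seed-length
normalization is the default because the filter is seed-anchored.

### 5. Active site extraction, mapping and transfer

A ligand-bound reference complex (for NRPS adenylation domains, a
crystal structure with its co-crystallized amino-acid substrate) defines
the substrate-contact residues: every residue with any heavy atom within
`contact_cutoff` (default 5 Å, inclusive) of any heavy ligand atom.
Hydrogens are ignored because predicted models and most crystal structures
lack them. Residues whose backbone N or O lies within `polar_cutoff`
(default 3.5 Å, a standard donor–acceptor heuristic) of a ligand N/O are
annotated as polar backbone contacts; this annotation never filters
anything.

The contact residues are mapped onto the seed model by structural
superposition: after aligning seed to reference, each reference site
residue maps to the seed residue with the nearest CA, rejecting mappings
beyond 5 Å. This is a deterministic surrogate for the manual
molecular-graphics inspection such mappings are traditionally done with.
Multi-module enzymes carry one substrate pocket per adenylation domain, so
the caller may supply one residue window per domain; the mapping runs
independently per window and yields one profile per domain.

Finally the seed-anchored profile is transferred onto every structural
survivor by an affine-gap *local* alignment of the full sequences under
the scoring +2 match, −1 mismatch, −0.5 gap opening, −0.1 gap extension
(a gap of length $k$ scores $-0.5 - 0.1(k-1)$). A profile position in an
aligned column contributes `identical` or `substituted`; a position in a
gap or outside the local alignment counts as `deleted`. The comparison is
exact letter equality; a chemical-class annotation (conservative vs.
non-conservative substitution) is reported but never used for ranking,
because the priority cut is defined by identity alone.

### Ranking

Priority class 1: passed the structural filter with an identical
active-site composition. Class 2: passed the structural filter with a
substituted or deleted site. Class 3: eliminated earlier. Within a class,
candidates order by seed coverage descending, then TM-score descending,
then id — so two class-1 candidates with coverages 0.95 and 0.76 rank 1
and 2. All tie-breaks in the package (clustering order, proxy choice,
alignment traceback) are deterministic, so two runs on the same inputs
produce byte-identical reports.

## Numerical and design choices

* **Affine gap convention.** The first gap character of a run is charged
  the opening score only (−0.5), each further character −0.1. The scoring
  scheme's source tooling uses this convention; it is stated explicitly
  because the alternative (open + extend for the first character) changes
  scores.
* **Alignment tie-breaks.** Among co-optimal tracebacks the aligner
  prefers diagonal over a gap in the candidate over a gap in the seed, and
  the start cell with the smallest indices. Note a genuine degeneracy of
  the scoring scheme: a mismatch (−1) costs less than two
  facing length-1 gaps (−1.0 each side)
  only by the tie-break, and when a substituted residue can re-pair
  with an identical neighbour two columns away, a *higher*-scoring local
  alignment may legitimately route the site position into a gap. The
  synthetic fixtures therefore plant site substitutions that are locally
  unique within ±5 residues; on real sequences such degeneracies are
  possible and are faithfully reported as deletions.
* **X residues** never count as identical to anything, including another
  X, in any identity or site comparison.
* **`d0` floor** of 0.5 Å; chains of 15 residues or fewer use the floor
  directly (the cube-root formula would be non-positive).
* **Altloc resolution** keeps the highest-occupancy alternate location,
  ties to the lexicographically first altloc code. Water (HOH) is never a
  ligand; every other HETATM group is kept and the caller selects by het
  code, because reference complexes routinely contain both the substrate
  and cofactors (e.g. AMP) and the choice must be explicit.
* **Degenerate inputs.** Kabsch requires three point pairs and warns on
  (near-)collinear sets; the structural aligner requires 20 CA atoms per
  chain; an empty distance list yields TM-score 0 with a warning rather
  than an error.

## What the synthetic generators emulate — and what they do not

The generators produce: ideal α-helical CA traces (1.5 Å rise, 100°/residue,
2.3 Å radius — the canonical 3.8 Å CA spacing) and extended chains with
plausible backbone N/C/O offsets; Gaussian coordinate noise with a seeded
RNG; mutated sequence families with an exact, known substitution count;
and ligand pockets whose contact shell is planted and then verified
atom-by-atom against the same distance definitions the extractor uses
(requests that are geometrically unsatisfiable — e.g. a contact residue
whose spatial neighbour must stay out of the shell but cannot — fail
loudly rather than silently shifting the truth).

The planted 20-candidate pipeline fixture (`make_pipeline_fixture()`)
encodes one of each elimination mode: 5 redundant near-copies (≥99%
identity to a survivor), 5 sequences outside the length window, 5
candidates with an unrelated (extended) fold, 3 with one substituted site
position, and 2 with an identical site, so the stage counts telescope
20 → 15 → 10 → 5 → {2 class-1, 3 class-2} for every RNG seed.

These fixtures deliberately do *not* emulate real protein structure:
there are no side chains, no secondary-structure mixtures, no domain
movements, and sequence families are generated by uniform substitution
rather than by an evolutionary model. Passing the suite therefore
demonstrates the *algorithms* are correct (scores match exhaustive
enumeration, planted truths are recovered, filters honor their
boundaries) — it does not certify retrieval performance on real databases,
which additionally depends on search sensitivity and model quality.

## Problem sizes and determinism

The test suite and the acceptance script run the pipeline at desk scale:
120-residue seeds, 20-candidate sets, 25–60-residue structural fixtures,
500-trial alignment-oracle sweeps with sequences up to length 8 (the
largest size an exhaustive enumeration over all C(n,k)·C(m,k) aligned-pair
sets handles comfortably). These sizes were chosen so that every check has
an exact, independently computed expectation; the pipeline itself has no
intrinsic size limit beyond the O(nm) dynamic programs.

All randomness flows through explicit integer seeds; the fixture
generators save and restore the global RNG state so they never perturb a
caller's random stream.

## Known limitations

* Structural alignment is rigid-body and CA-only; flexible or
  domain-permuted variants score poorly even when each domain matches.
* The full TM-align heuristic also seeds from secondary-structure
  matching; this implementation's initializations (sequence alignment +
  gapless offsets) can in principle miss an optimum on hard topologies,
  though small cases are covered exhaustively.
* Proxy structures assume a ≥95%-identity protein has essentially the
  same fold — usually but not universally true.
* The upstream homology search is consumed as input (FASTA or tabular hit
  lists); the package does not run it, and retrieval completeness is
  outside its control.
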