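# structfilter

Structure-filtered search of functionally equivalent enzyme variants.

## The problem

Homology searches for orthologs of a seed enzyme — for example a fungal
non-ribosomal peptide synthetase whose product you want to produce in an
industrial host — return tens of thousands of hits. Most are redundant,
fragmented, fused with unrelated domains, or share local sequence
similarity without sharing the seed's fold, and no small laboratory can
screen them all. `structfilter` narrows such candidate sets down to a
short, ranked list of proteins that plausibly share the seed's global
fold *and* its substrate-contacting residues, with a fully audited verdict
for every input sequence.

## The method

Five deterministic stages, each with explicit thresholds:

1. **Redundancy clustering** — greedy, longest-first clustering at ≥ 99 %
   identity (identical columns of a global affine-gap alignment divided by
   the shorter sequence length); one representative per cluster proceeds.
2. **Length window** — inclusive bounds around the seed length (e.g.
   800–1500 aa for a ~1000 aa seed) to enrich for the seed's global
   architecture.
3. **Structure resolution** — each candidate uses its own structure model
   if available, otherwise the model of a ≥ 95 %-identity proxy protein;
   candidates with neither are excluded with reason `"no model"`.
4. **Global structural filter** — candidate models are aligned to the seed
   model with a TM-align-style iterative Kabsch + dynamic-programming
   aligner. With aligned-pair distances *dᵢ* and seed length *L*,

   TM = (1/L) Σᵢ 1 / (1 + (dᵢ/d₀)²),  d₀ = max(0.5, 1.24·(L−15)^⅓ − 1.8) Å

   A candidate passes when 0.5 ≤ TM ≤ 1.0 and seed coverage
   (aligned pairs / L) ≥ 70 %, both inclusive.
5. **Active-site comparison** — residues with any heavy atom within 5 Å of
   the substrate in a ligand-bound reference complex are mapped onto the
   seed model by superposition (nearest CA, 5 Å rejection radius), then
   transferred to every surviving candidate by Smith–Waterman local
   alignment scored +2 match / −1 mismatch / −0.5 gap open / −0.1 gap
   extend. Candidates split into priority class 1 (identical active-site
   composition), class 2 (substituted or deleted positions) and class 3
   (eliminated earlier), ranked within class by seed coverage, then
   TM-score, then id.

Synthetic generators (ideal helices, seeded coordinate noise, mutated
sequence families, planted ligand pockets, and a 20-candidate end-to-end
fixture with known per-stage outcomes) make every stage testable without
any database downloads.

## Worked example

```r
library(structfilter)

fix <- make_pipeline_fixture(rng_seed = 1)   # planted 20-candidate study
res <- run_pipeline(fix$seed_seq, fix$seed_model, fix$ref_complex,
                    fix$candidates, fix$models, fix$cfg, fix$ligand_code)
str(res$manifest$counts)
#> List of 8
#>  $ n_input          : int 20
#>  $ n_nonredundant   : int 15
#>  $ n_length_pass    : int 10
#>  $ n_with_structure : int 10
#>  $ n_structural_pass: int 5
#>  $ n_class1         : int 2
#>  $ n_class2         : int 3
#>  $ n_class3         : int 15

head(res$verdicts[, c("cand_id", "priority_class", "rank", "tm_score",
                      "seed_coverage", "site_status")], 6)
#>         cand_id priority_class rank tm_score seed_coverage site_status
#> cand_g1 cand_g1              1    1    0.987         1.000   identical
#> cand_g2 cand_g2              1    2    0.984         1.000   identical
#> cand_s2 cand_s2              2    1    0.985         1.000 substituted
#> cand_s3 cand_s3              2    2    0.984         1.000 substituted
#> cand_s1 cand_s1              2    3    0.983         1.000 substituted
#> cand_f2 cand_f2              3    1    0.338         0.408        <NA>
```

The stage counts telescope 20 → 15 → 10 → 5 survivors: five redundant
near-copies are absorbed by clustering, five sequences fall outside the
length window, five extended-chain decoys fail the structural filter
(TM ≈ 0.34 < 0.5), and of the five structural survivors two carry an
active site identical to the seed (class 1) and three carry one
substituted contact residue (class 2). `write_report(res$verdicts, path,
"tsv")` emits the byte-reproducible verdict table.

A thin command-line front end is included at `inst/cli/structfilter.R`
(subcommands `cluster`, `lenfilter`, `run`, `fixtures`).

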