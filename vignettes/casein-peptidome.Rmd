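---
title: "Genotype-aware in silico peptidome analysis with pepdigest"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotype-aware in silico peptidome analysis with pepdigest}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepdigest)
```

## The model

`pepdigest` compares protein allelic variants — built for the goat casein
system (α-S1, β, α-S2, κ; genes *CSN1S1*, *CSN2*, *CSN1S2*, *CSN3*) but
generic over any protein family — by the bioactive peptides they are
predicted to release under enzymatic digestion. The pipeline has five
stages, each exposed as ordinary functions:

1. **Sequences and variants.** Proteins are plain residue strings with
   gene/allele metadata (`protein_sequence()`, `read_fasta()`). Variants are
   constructed by applying edit lists to a reference (`apply_edits()`) and
   recovered by positional comparison (`diff_alleles()`).
2. **Digestion.** Declarative cleavage rules (`cleavage_rule()`,
   `enzyme()`); one-pot multi-enzyme digestion as the union of cut sites
   (`cut_sites()`, `digest()`).
3. **Occurrence statistics.** For a database of peptides annotated with
   activities, the frequency of bioactive fragments with activity *x* is
   `A = a / N`: positional occurrence count over residue count
   (`compute_A()`); `sigma_A` is the unweighted sum over activities
   (`compute_profile()`).
4. **Candidate filtering and annotation.** Released peptides are filtered by
   an external bioactivity-likelihood score and a length window
   (`filter_candidates()`), then annotated by exact database lookup
   (`annotate_peptides()`).
5. **Aggregation.** An allele × activity matrix counts distinct candidate
   peptides per activity (`build_matrix()`); allele-specific peptides are
   those released by exactly one allele of a gene
   (`allele_specific_peptides()`).

### Assumptions

* Digestion is deterministic and exhaustive: every matching bond is cut in
  complete mode. There is no kinetics, no pH/temperature dependence, and no
  probabilistic missed cleavage; *partial* mode covers missed cleavages
  combinatorially instead, by enumerating every fragment bounded by two cut
  boundaries.
* Database matching is exact-sequence: no Leu/Ile equivalence, no modified
  residues. This mirrors how fragment-occurrence profiling is normally done
  against curated peptide databases.
* Bioactivity likelihood is externally supplied. Scores enter only through a
  `peptide → score` table; the package deliberately does not approximate any
  published neural scorer, so score-dependent results are exactly
  reproducible from the table.

## Conventions and numerical choices

* **Coordinates** are 1-based inclusive in every user-facing structure
  ("position 134" means the 134th residue), matching how variant positions
  are reported in the casein literature; cut sites are inter-residue
  positions `p` with `0 < p < N` (a cut between residues `p` and `p+1`).
* **Terminal rule matches produce no cut**: a C-terminal rule on the last
  residue (or N-terminal on the first) would create an empty fragment and is
  ignored.
* **Edits apply in descending position order**, so all positions refer to the
  original reference even when deletions/insertions shift downstream
  coordinates. Multiple insertions at one position compose right-to-left;
  `diff_alleles()` emits blocks in the order that round-trips.
* **Unequal-length diffs** are handled only for a single contiguous indel
  (longest common prefix + suffix). This is sufficient for exon-loss variants
  such as the α-S1 F allele; anything more divergent raises an explicit
  "sequences not comparable" error rather than silently computing an
  alignment — multiple sequence alignment is out of scope.
* **Occurrence counting is positional**: `a` counts every (peptide, start)
  pair, overlapping occurrences included, summed over database peptides
  carrying the activity. Public profiling platforms do not document whether
  they count distinct fragment sequences or positional occurrences; the
  positional convention is used here because it makes `A × N` an exact
  integer invariant that brute-force oracles can verify. The digestion
  manifest reports fragment counts under *both* conventions (distinct
  positional intervals and distinct sequences) so either can be compared to
  external totals.
* **Matrix cells count distinct peptide sequences**, not positional
  intervals: two alleles releasing the same peptide at different positions
  contribute equally, and duplicates within an allele count once.
* **Precursor vs mature frame.** Published variant positions sometimes refer
  to the precursor (signal peptide included) and sometimes to the mature
  chain. A `signal_peptide_trim` parameter (default 0 = precursor frame)
  switches frames, and the manifest records which frame was used.
* **Ties at the threshold.** The default keep rule is strict (`score >
  threshold`), reflecting the usual "exceeds the threshold" phrasing; a
  greater-or-equal variant is available. All bundled fixture scores are
  strictly above 0.5, so the bundled analyses are insensitive to this
  choice.
* **Missing scores exclude the peptide** (logged) rather than scoring it 0,
  so absences stay visible instead of silently biasing per-allele counts.
* Profile TSVs print `A` and `sigma_A` with 4 decimals; full precision is
  kept in the objects.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `threshold` | 0.5 | score in [0,1] | conventional cutoff for "likely bioactive" |
| `min_length`, `max_length` | 2, 6 | residues | the window where database peptides are informative; shorter than 2 is meaningless, longer than 6 rarely matches curated dipeptide/tripeptide-rich databases |
| `keep_rule` | strict `>` | — | see ties above |
| `missing_score` | exclude | — | see above |
| `mode` | complete | — | headline per-allele counts use the partition; `partial` adds successive-cleavage products |
| `signal_peptide_trim` | 0 | residues | precursor frame unless the user states otherwise |

The bundled enzyme table encodes pepsin (C-terminal after F, L), trypsin
(C-terminal after K, R) and chymotrypsin A (C-terminal after Y, W, F, L, N,
H, M; N-terminal before I). Published platform specificity tables are
richer (subsite exceptions such as trypsin's K|P veto, which the rule schema
supports via `blocked_by_next`); reproducing another platform's exact
fragment counts may require supplying its full table.

## The synthetic-data generator

`synthetic_spec()` reserves *disjoint* residue alphabets for background
filler, planted bioactive fragments, planted cleavage residues, optional
fragment flanks, and database decoys, and lays planted tokens out with at
least one background residue between them. Consequences:

* planted fragments occur exactly at their stated multiplicities — never by
  accident — so `A` values, occurrence positions and cut sites are known a
  priori and recovery tests assert *equality*, not statistics;
* decoy database peptides (drawn from the decoy alphabet) can never occur in
  a generated protein;
* with `flank_fragments = TRUE` each fragment sits between a C-terminal-rule
  residue and an N-terminal-rule residue, so complete digestion with
  `synthetic_enzymes()` releases the planted peptide exactly — this is what
  `simulate_study()` uses for end-to-end recovery;
* allele families (`generate_allele_family()`) apply recorded substitutions
  that cycle through destroying a fragment, destroying a cleavage site and
  creating one, so per-allele differences at every stage are known.

What the generator does **not** emulate: realistic amino-acid composition
(a disjoint-alphabet protein is compositionally artificial), evolutionary
divergence between alleles, indel variants (family edits are substitutions),
and realistic database sparsity. Passing the synthetic recovery tests
therefore demonstrates that the *machinery* is exact — parsing, coordinate
bookkeeping, rule evaluation, counting, aggregation — not that predictions
transfer to real proteins, which additionally depends on the completeness of
the user's enzyme table, peptide database and score table.

Default study conditions: 60-residue proteins (90 in the end-to-end study),
3–4 alleles, one edit per variant, fragments GY ×2 (ACE-I) and PW ×1
(DPP-IV-I), two planted tryptic-style cleavage residues, three decoys, seed
42 for the bundled analysis scripts.

## What the bundled analyses compute

* `analysis/01_simulate.R` — the synthetic end-to-end study; asserts exact
  recovery of planted cut sites, candidate sets, `A` values and the matrix.
* `analysis/02_replay_candidates.R` — replays the bundled released-peptide
  table for the goat casein alleles (35 peptides with external scores,
  per-allele release marks, and the curated activity excerpt) through
  filter → annotate → matrix, printing the per-gene and per-allele candidate
  counts and the allele-specific peptides (e.g. AAM only in α-S1 E, AGPF
  only in α-S2 F).
* `analysis/03_variant_effects.R` — a variant-effect comparison showing how
  a T→A/T→A double substitution converts an inert TTM context into the
  released AAM peptide.
* `scripts/acceptance.R` — recomputes the replay counts and the synthetic
  exact-recovery rate from scratch and writes them as JSON.

The test suite cross-checks each stage against independent brute-force
oracles (per-boundary cleavage scan, exhaustive substring enumeration,
boundary-pair interval enumeration) on dozens of random instances per run,
at sizes (30–90 residues, ≤ 10-peptide databases) chosen to keep the whole
suite under a minute while exercising every rule interaction.

## Known limitations

* The bundled peptide-activity database is a small curated excerpt (32
  peptides, 27 activity codes) sufficient for the casein candidate analysis;
  whole-protein `sigma_A` computed against it is **not** comparable to values
  computed against complete public databases (thousands of peptides, ~90
  activities). Users wanting database-scale profiles must supply their own
  TSV.
* Accession-dependent results (per-allele fragment totals of the real casein
  sequences) require the accession FASTA files and the digestion platform's
  full specificity tables; neither ships with the package. The bundled
  hypothetical-allele edit list is a labelled synthetic example — users must
  supply literature-derived edit lists to reconstruct unpublished alleles.
* Digestion ignores enzyme kinetics and substrate structure; partial mode
  enumerates combinatorially rather than sampling missed-cleavage
  probabilities.
* The bioactivity matrix is raw counts; no normalisation or statistical
  comparison of rows is provided, by design.
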