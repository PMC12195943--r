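# pepdigest

In silico proteolysis and bioactive peptide profiling of milk protein
allelic variants.

## The problem

Milk caseins (the α-S1, β, α-S2 and κ families, encoded by *CSN1S1*, *CSN2*,
*CSN1S2* and *CSN3*) are highly polymorphic, and the peptides released when
they are digested carry documented bioactivities — most prominently
inhibition of angiotensin-converting enzyme (ACE-I, antihypertensive) and of
dipeptidyl peptidase IV (DPP-IV-I, antidiabetic). Which peptides a casein
releases depends on its allele: a single substitution can create or destroy
a protease recognition site or turn an inert fragment into a bioactive one.
`pepdigest` is for researchers who want to compare casein (or any protein)
allelic variants by the bioactive peptides they are predicted to release,
entirely in silico.

## The method

Three computations sit at the core:

1. **Occurrence frequency of bioactive fragments.** For a protein of *N*
   residues and a peptide database annotated with activities, the frequency
   of fragments with activity *x* is

   *A*ₓ = *a*ₓ / *N*

   where *a*ₓ counts every positional occurrence (overlaps included) of a
   database peptide carrying activity *x* inside the protein. The unweighted
   sum over activities, Σ*A*, summarises a sequence's overall potential as a
   bioactive-peptide precursor.

2. **Rule-based multi-enzyme digestion.** Enzymes are declarative rule sets:
   a target residue, the side of the scissile bond (C-terminal = cut after,
   N-terminal = cut before) and optional veto residues on the distal side.
   One-pot digestion by several enzymes is the union of all cut sites.
   Complete mode releases the maximal fragments between consecutive sites;
   partial mode also enumerates every fragment bounded by any two cut
   boundaries (the overlapping products of successive cleavage events). The
   bundled table encodes pepsin (cuts after F, L), trypsin (after K, R) and
   chymotrypsin A (after Y, W, F, L, N, H, M; before I).

3. **Candidate filtering and the bioactivity matrix.** Released peptides are
   filtered by an externally supplied bioactivity-likelihood score
   (retain score > 0.5 by default) and a 2–6 residue length window, annotated
   against the peptide-activity database, and aggregated into an
   allele × activity matrix whose cells count the distinct candidate peptides
   of each allele carrying each activity — the quantitative content of a
   bioactivity heatmap.

A synthetic-data generator plants fragments, cleavage sites and allele
families with disjoint residue alphabets, so every pipeline stage can be
verified against exact, known-in-advance ground truth.

## Worked example

Digest two alleles that differ by one substitution and compare what they
release:

```r
library(pepdigest)

ref <- protein_sequence("demo", "GGKTTMGGKGYL", gene = "SYNT", allele = "A")
var <- apply_edits(ref, list(
  variant_edit("substitution", 4, ref = "T", alt = "A"),
  variant_edit("substitution", 5, ref = "T", alt = "A")), new_allele = "E")

enz <- default_enzymes()
digest(var, enz)$peptides$peptide
#> [1] "GGK" "AAM" "GGK" "GY"  "L"

db <- bioactive_db(list(AAM = c("ACE-I", "H")))
allele_specific_peptides(list(
  A = digest(ref, enz)$peptides$peptide,
  E = digest(var, enz)$peptides$peptide))
#>   peptide allele
#> 1     AAM      E
#> 2     TTM      A

compute_profile(var, db)$sigma_A   # one AAM occurrence, two activities
#> [1] 0.1666667
```

The substitution turns the inert TTM fragment into AAM, which only the E
allele releases; its Σ*A* rises from 0 to 2/12.

The numbered scripts under `analysis/` run the full studies: a synthetic
ground-truth recovery study (`01_simulate.R`), the replay of the bundled
released-peptide table for the goat casein alleles with per-gene counts
14/9/10/7 and 35 total candidates (`02_replay_candidates.R`), and a
variant-effect comparison (`03_variant_effects.R`). Each writes its tables
under `results/`.

## Scope notes

The bundled peptide-activity database is a small curated excerpt sufficient
for the candidate peptides of the goat casein alleles; it is not a complete
bioactive-peptide database, and whole-protein Σ*A* values computed against it
are not comparable to values computed against the full public databases.
Bioactivity-likelihood scores are taken from a user-supplied table — the
package does not reimplement any published neural scorer. See the methods
vignette (`vignettes/casein-peptidome.Rmd`) for the full model description,
parameter defaults and limitations.
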