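#!/usr/bin/env Rscript
# Variant-effect demonstration: apply a literature-style double substitution
# (T->A at positions 209/210, turning a TTM context into AAM) to a synthetic
# casein-sized reference, digest both alleles with the default three-enzyme
# system, and compare released peptides and occurrence profiles.
# Outputs under results/variants/.

suppressMessages(library(pepdigest))

outdir <- "results/variants"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

# Synthetic 214-residue reference with a TTM context at 209-211, flanked so
# the tripeptide at that position is released by trypsin/chymotrypsin cuts.
set.seed(42)
background <- c("A", "D", "E", "G", "Q", "S", "T", "V")
residues <- paste(sample(background, 214, replace = TRUE), collapse = "")
substr(residues, 208, 212) <- "KTTMG" # K| cut, TTM, M| cut
ref <- protein_sequence("SYNREF", residues, gene = "SYNT", allele = "A")

edits <- read_edit_table(pep_example("edits_synthetic_example.tsv"))
var <- apply_edits(ref, edits, new_allele = "E")

cat("Edits applied to the reference:\n")
for (e in diff_alleles(ref, var)) print(e)

enz <- default_enzymes()
d_ref <- digest(ref, enz)
d_var <- digest(var, enz)
cat(sprintf("\nReleased fragments: reference %d, variant %d\n",
            d_ref$n_intervals, d_var$n_intervals))

specific <- allele_specific_peptides(list(
  A = d_ref$peptides$peptide, E = d_var$peptides$peptide))
cat("\nAllele-specific released peptides:\n")
print(specific, row.names = FALSE)

db <- bioactive_db(list(AAM = c("ACE-I", "A-B", "H", "DPP-IV-I")),
                   source = "demo")
cat(sprintf("\nOccurrence frequency of AAM-carrying activities (A = a/N):\n"))
cat(sprintf("  reference sigma_A = %.4f\n", compute_profile(ref, db)$sigma_A))
cat(sprintf("  variant   sigma_A = %.4f\n", compute_profile(var, db)$sigma_A))

write_digest_tsv(d_ref, file.path(outdir, "digest_reference.tsv"))
write_digest_tsv(d_var, file.path(outdir, "digest_variant.tsv"))
write_tsv_path <- file.path(outdir, "allele_specific.tsv")
utils::write.table(specific, write_tsv_path, sep = "\t", quote = FALSE,
                   row.names = FALSE)
cat("\nwrote", outdir, "\n")
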