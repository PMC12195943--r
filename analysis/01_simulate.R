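#!/usr/bin/env Rscript
# Synthetic ground-truth study: generate an allele family with planted
# bioactive fragments and cleavage sites, push it through the full pipeline
# (digest -> filter -> annotate -> matrix -> profiles), and verify that every
# stage returns exactly the planted truth. Outputs under results/synthetic/.

suppressMessages(library(pepdigest))

outdir <- "results/synthetic"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

spec <- synthetic_spec(seed = 42, n_alleles = 4, protein_length = 90)
sim <- suppressMessages(simulate_study(spec, outdir = outdir))

cat("Synthetic study (seed 42): 4 alleles of a 90-residue protein,\n")
cat("planted fragments:",
    paste(vapply(spec$planted_fragments, function(f) {
      sprintf("%s x%d (%s)", f$peptide, f$multiplicity, f$activity)
    }, character(1)), collapse = ", "), "\n\n")

for (al in names(sim$candidates)) {
  cat(sprintf("  allele %-5s cut sites: %-2d candidates: %s\n", al,
              length(sim$digests[[al]]$cut_sites),
              paste(sim$candidates[[al]]$peptide, collapse = ", ")))
}
cat("\nStage checks (engine output == planted truth):\n")
print(sim$checks)
cat(sprintf("\nExact end-to-end recovery: %s\n", sim$exact_recovery))

write_fasta(unname(sim$family$alleles$alleles),
            file.path(outdir, "synthetic_alleles.fasta"))
cat("wrote", outdir, "\n")
stopifnot(sim$exact_recovery)
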