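#!/usr/bin/env Rscript

# Build the synthetic RHD reference and the 24-sample EQA panel, and export
# them as plain-text fixtures (FASTA haplotypes, truth table, plate order,
# FASTQ traces) under results/panel/.

suppressPackageStartupMessages(library(rhdtyper))

seed <- 20240806L
model <- build_synthetic_reference(seed = seed)
db <- load_allele_db()

cat("Gene model: ", nchar(model$genomic), " nt genomic, CDS ",
    model$cds_length, " nt over 10 exons, ", nrow(model$primer_sites),
    " registered primer sites.\n", sep = "")

panel <- make_eqa_panel(model, db)
truth <- attr(panel, "truth")
cat("Panel: ", length(panel), " samples (",
    sum(truth$genotype == "RHD*01"), " RHD*01, ",
    sum(truth$genotype == "RHD*01N.01"), " deletions, ",
    sum(!truth$genotype %in% c("RHD*01", "RHD*01N.01")),
    " aberrant alleles).\n", sep = "")

export_gene_model(model, "results/reference")
paths <- write_panel_files(panel, model, "results/panel", seed = seed)
cat("Wrote:\n"); for (p in paths) cat("  ", p, "\n", sep = "")
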