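#!/usr/bin/env Rscript
# Step 1 - generate the synthetic study data.
#
# The downstream steps need a mitochondrial-like data set with known ground
# truth: ortholog alignments with a planted CUA/CUU -> Ala reassignment at
# 81 conserved sites (49 CUA, 32 CUU), an A+T-biased target CDS set with 24
# avoided codons, an alanine-identity tRNA with a UAG anticodon, small-RNA
# reads over its precursor and mature(+CCA) forms, and an aminoacylation
# velocity table. One seed reproduces everything byte-identically.

library(mitocodon)

seed <- as.integer(Sys.getenv("MITOCODON_SEED", "1"))
out <- "results/simulation"
dir.create("results", showWarnings = FALSE)

truth <- synthetic_truth("ashbya-like", seed = seed)
write_simulation(truth, out)

cfg <- list(step = "simulate", seed = seed, preset = "ashbya-like",
            out = out)
jsonlite::write_json(cfg, "results/01_config.json", auto_unbox = TRUE)

cat("Simulated", truth$n_genes, "genes x", length(truth$species),
    "species into", out, "\n")
cat("Planted:", sum(truth$planted_counts), "family codons (",
    paste(sprintf("%s=%d", names(truth$planted_counts),
                  truth$planted_counts), collapse = ", "), ") ->",
    truth$planted_aa, "\n")
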