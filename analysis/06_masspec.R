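#!/usr/bin/env Rscript
# Step 6 - variant proteomes and peptide-level mass-spec discrimination.
#
# Builds the three proteome variants in which every CUA/CUU codon is read as
# Leu, Thr or Ala, digests them in silico with trypsin, and matches observed
# peptides. An observation covering a variant site is consistent only with
# the variant whose residue it carries; here the observations are the target
# genome's own Ala-variant discriminating peptides (sequence mode) plus
# their monoisotopic masses (10 ppm mass mode), so every observed site
# should come out Ala-only.

library(mitocodon)

seed <- as.integer(Sys.getenv("MITOCODON_SEED", "1"))
truth <- synthetic_truth("ashbya-like", seed = seed)
sim <- simulate_ortholog_set(truth)

vp <- variant_proteomes(sim$cds, family = truth$family,
                        candidates = c("L", "T", "A"),
                        code = genetic_code("yeast-mito"))
db <- digest_proteomes(vp, missed_cleavages = 1)

# "observe" a handful of Ala-variant discriminating peptides, as an
# experiment identifying mitochondrial proteins would
disc <- db[db$variant == "A" & db$discriminating & db$n_missed == 0, ]
set.seed(seed)
obs_rows <- disc[sample(nrow(disc), min(6L, nrow(disc))), ]
observed <- data.frame(sequence = c(obs_rows$seq[1:3], rep(NA, 3)),
                       mass = c(rep(NA, 3), obs_rows$mass[4:6]))

mv <- match_observed(observed, vp, tolerance_ppm = 10, missed_cleavages = 1)
write.table(mv$evidence, "results/ms_evidence.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
jsonlite::write_json(mv$site_verdicts, "results/ms_site_verdicts.json",
                     auto_unbox = TRUE, digits = NA)
jsonlite::write_json(list(step = "masspec", seed = seed,
                          tolerance_ppm = 10, missed_cleavages = 1,
                          fixed_mods = list(C = 57.02146)),
                     "results/06_config.json", auto_unbox = TRUE)

sv <- mv$site_verdicts
obs_sites <- sv[sv$observed, ]
cat("Variant sites:", nrow(sv), "| observed:", nrow(obs_sites), "\n")
cat("Verdicts at observed sites:",
    paste(unique(obs_sites$consistent_variants), collapse = " / "), "\n")
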