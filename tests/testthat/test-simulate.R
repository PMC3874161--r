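test_that("simulation is deterministic under its seed", {
  a <- simulate_ortholog_set(synthetic_truth("ashbya-like", seed = 5))
  b <- simulate_ortholog_set(synthetic_truth("ashbya-like", seed = 5))
  expect_identical(a$alignments, b$alignments)
  expect_identical(a$cds, b$cds)
  c <- simulate_ortholog_set(synthetic_truth("ashbya-like", seed = 6))
  expect_false(identical(a$cds, c$cds))
  r1 <- simulate_trna_and_reads(synthetic_truth("ashbya-like", seed = 5))
  r2 <- simulate_trna_and_reads(synthetic_truth("ashbya-like", seed = 5))
  expect_identical(r1$reads_mature, r2$reads_mature)
  k1 <- simulate_kinetics(2, 1, noise_frac = 0.1, seed = 3)
  k2 <- simulate_kinetics(2, 1, noise_frac = 0.1, seed = 3)
  expect_identical(k1, k2)
})

test_that("alignments are gap-consistent and round-trip into inference
           objects", {
  sim <- simulate_ortholog_set(synthetic_truth("ashbya-like", seed = 2))
  for (g in names(sim$alignments)) {
    expect_length(unique(nchar(sim$alignments[[g]])), 1L)
  }
  als <- as_ortholog_alignments(sim)
  expect_length(als, 8L)
  for (a in als) {
    expect_length(a$column_map, length(a$target_codons))
    expect_true(all(diff(a$column_map) > 0))
  }
})

test_that("zero substitution rates give identical rows and unanimity calls", {
  tru <- synthetic_truth("ashbya-like", seed = 3,
                         sub_prob = c(invariant = 0, conserved = 0,
                                      variable = 0))
  sim <- simulate_ortholog_set(tru)
  for (g in names(sim$alignments)) {
    expect_length(unique(sim$alignments[[g]]), 1L)
  }
  cl <- score_codon_family(as_ortholog_alignments(sim), c("CUA", "CUU"))
  expect_identical(cl$call, "A")
  expect_equal(unname(cl$support[["A"]]), 1.0)
})

test_that("planted family codons appear at the planted counts and nowhere
           else", {
  sim <- simulate_ortholog_set(synthetic_truth("ashbya-like", seed = 11))
  tab <- count_codons(sim$cds, genetic_code("ashbya-mito"))
  expect_identical(unname(tab$counts[["CUA"]]), 49L)
  expect_identical(unname(tab$counts[["CUU"]]), 32L)
  expect_identical(unname(tab$counts[["CUC"]]), 0L)
  expect_identical(unname(tab$counts[["CUG"]]), 0L)
  expect_identical(nrow(sim$planted_sites), 81L)
  # planted sites hold the planted amino acid in the target row
  for (i in seq_len(20)) {
    row <- sim$planted_sites[i, ]
    res <- substr(sim$alignments[[row$gene]][["target_sp"]],
                  row$codon_index, row$codon_index)
    expect_identical(res, "A")
  }
})

test_that("an infeasible truth is rejected with a clear error", {
  tru <- synthetic_truth("ashbya-like", seed = 1, gene_length = 10L)
  expect_error(simulate_ortholog_set(tru), "infeasible")
  expect_error(simulate_ortholog_set(
    synthetic_truth("ashbya-like", species = c("a", "b"))),
    "at least 4 species")
})

test_that("synthetic tRNA reads are exact substrings of their source form at
           zero error rate", {
  tru <- synthetic_truth("ashbya-like", seed = 13,
                         reads = list(depth_precursor = 1L,
                                      depth_mature = 1L,
                                      read_len = c(25L, 45L),
                                      error_rate = 0, flank = 30L))
  sr <- simulate_trna_and_reads(tru)
  expect_true(grepl(sr$reads_precursor[1], sr$flanked, fixed = TRUE))
  mature_dna <- gsub("U", "T", sr$mature, fixed = TRUE)
  expect_true(grepl(sr$reads_mature[1], mature_dna, fixed = TRUE))
  # depth 0 yields an empty read set
  tru0 <- synthetic_truth("ashbya-like", seed = 13,
                          reads = list(depth_precursor = 0L,
                                       depth_mature = 0L,
                                       read_len = c(25L, 45L),
                                       error_rate = 0, flank = 30L))
  sr0 <- simulate_trna_and_reads(tru0)
  expect_length(sr0$reads_mature, 0L)
})

test_that("the tRNA element spec flows to an orthogonal AlaRS call and a
           CCA-positive scan", {
  tru <- synthetic_truth("ashbya-like", seed = 14)
  sr <- simulate_trna_and_reads(tru)
  g <- parse_cloverleaf(sr$trna$seq, minus_one = "none")
  cl <- classify_synthetase(g)
  expect_identical(
    cl$predictions$synthetase[cl$predictions$match == "match"], "AlaRS")
  expect_true(cl$orthogonal)
  ws <- build_windows(sr$flanked, sr$gene_start, sr$gene_end)
  d <- scan_reads(sr$reads_mature, ws)$derived
  expect_gt(d[["mature_cca"]], 0)
  expect_identical(d[["leader_junction"]] + d[["trailer_junction"]], 0L)
})

test_that("a written simulation directory round-trips through the package
           readers", {
  dir <- withr::local_tempdir()
  tru <- synthetic_truth("ashbya-like", seed = 27, n_genes = 2L,
                         gene_length = 150L)
  write_simulation(tru, dir)
  expect_setequal(list.files(file.path(dir, "alignments")),
                  c("gene1.fasta", "gene2.fasta"))
  cds <- Biostrings::readDNAStringSet(file.path(dir, "cds.fasta"))
  expect_length(cds, 2L)
  sim <- simulate_ortholog_set(tru)
  oa <- read_ortholog_alignment(file.path(dir, "alignments", "gene1.fasta"),
                                "gene1", "target_sp",
                                cds = as.character(cds[["gene1"]]),
                                code = genetic_code("ashbya-mito"),
                                family = c("CUA", "CUU"))
  expect_identical(oa$aln, sim$alignments$gene1)
  kin <- read_kinetics_tsv(file.path(dir, "kinetics.tsv"))
  f <- fit_michaelis_menten(kin$substrate, kin$velocity)
  expect_equal(f$kcat, tru$kinetics$kcat, tolerance = 1e-6)
  truth_back <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_identical(truth_back$preset, "ashbya-like")
  ln <- readLines(file.path(dir, "reads.fastq"))
  expect_identical(length(ln) %% 4L, 0L)
  expect_gt(length(ln), 0L)
})
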