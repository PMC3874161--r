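test_that("codon-to-column mapping skips gaps and validates residues", {
  expect_identical(map_codons_to_columns("AUGAAAUUAUGG", "M-KLW",
                                         family = "UUA"),
                   c(1L, 3L, 4L, 5L))
  # gapless row is the identity map; terminal stop trimmed
  expect_identical(map_codons_to_columns("AUGAAAUGGUAA", "MKW"), 1:3)
  expect_error(map_codons_to_columns("AUGAAA", "MKW"), "residues")
  expect_error(map_codons_to_columns("AUGGGG", "MK"), "disagree")
})

test_that("random gap insertion round-trips through the column map", {
  code <- genetic_code("standard")
  set.seed(31)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    codons <- sample(sense_codons(code), n, replace = TRUE)
    cds <- paste(codons, collapse = "")
    prot <- translate_cds(cds, code)
    res <- strsplit(prot, "")[[1]]
    row <- character(n + sample(0:10, 1))
    gap_at <- sample(length(row), length(row) - n)
    row[gap_at] <- "-"
    row[setdiff(seq_along(row), gap_at)] <- res
    cm <- map_codons_to_columns(cds, paste(row, collapse = ""), code)
    expect_identical(paste(row[cm], collapse = ""), prot)
    expect_true(all(diff(cm) > 0))
  }
})

test_that("column profiles are frequencies with modal-conservation weight", {
  aln <- c(target = "A", setNames(rep("A", 10), paste0("s", 1:10)))
  oa <- ortholog_alignment("g", aln, "target")
  p <- column_profile(oa, 1, exclude = "target")
  expect_equal(p$freq, c(A = 1.0))
  expect_equal(p$weight, 1.0)

  aln2 <- c(target = "X", setNames(c(rep("T", 6), rep("S", 4)),
                                   paste0("s", 1:10)))
  p2 <- column_profile(ortholog_alignment("g", aln2, "target"), 1,
                       exclude = "target")
  expect_equal(p2$freq, c(T = 0.6, S = 0.4))
  expect_equal(p2$weight, 0.6)

  # all-gap column after exclusion is flagged unusable
  aln3 <- c(target = "A", s1 = "-")
  p3 <- column_profile(ortholog_alignment("g", aln3, "target"), 1,
                       exclude = "target")
  expect_false(p3$usable)
  expect_error(column_profile(ortholog_alignment("g", aln3, "target"), 5),
               "out of range")
})

make_family_fixture <- function(n_sites, other_rows_fn,
                                family_codon = "CUA", n_sp = 9L) {
  # one gene whose target CDS is n_sites family codons; each column's other
  # species are produced by other_rows_fn(site)
  rows <- vapply(seq_len(n_sp), function(sp) {
    paste(vapply(seq_len(n_sites),
                 function(i) other_rows_fn(i)[sp], character(1)),
          collapse = "")
  }, character(1))
  aln <- c(setNames(paste(rep("A", n_sites), collapse = ""), "target"),
           setNames(rows, paste0("s", 1:n_sp)))
  cds <- paste(rep(family_codon, n_sites), collapse = "")
  ortholog_alignment("g1", aln, "target", cds = cds,
                     code = genetic_code("standard"),
                     family = family_codon)
}

test_that("family scoring reproduces hand-computed weighted averages", {
  # 30 CUA sites; others are 9/10 Ala + 1/10 Ser at every column
  oa <- make_family_fixture(30, function(i) c(rep("A", 9), "S"), n_sp = 10L)
  call <- score_codon_family(list(oa), "CUA")
  expect_equal(unname(call$support[["A"]]), 0.9, tolerance = 1e-12)
  expect_equal(unname(call$support[["S"]]), 0.1, tolerance = 1e-12)
  expect_identical(call$call, "A")
  expect_gte(call$support[["A"]], 0.9 - 1e-9)
  expect_identical(call$n_sites, 30L)
  # unanimity: 10 sites at invariant-Thr columns
  oa2 <- make_family_fixture(10, function(i) rep("T", 9))
  call2 <- score_codon_family(list(oa2), "CUA")
  expect_identical(call2$call, "T")
  expect_equal(unname(call2$support[["T"]]), 1.0)
})

test_that("mixed-weight sites: weighting and min_weight filtering follow the
           formula", {
  # 4 strong Ala columns (weight 1) and 2 weak columns (weight 4/9 < 0.5)
  fn <- function(i) if (i <= 4) rep("A", 9) else
    c(rep("L", 4), "S", "T", "V", "I", "F")
  oa <- make_family_fixture(6, fn)
  call <- score_codon_family(list(oa), "CUA", min_weight = 0.5)
  expect_identical(call$n_sites, 4L)
  expect_equal(unname(call$support[["A"]]), 1.0)
  # with min_weight 0 the weak columns dilute support per the formula:
  # support(A) = 4*1*1 / (4*1 + 2*(4/9))
  call0 <- score_codon_family(list(oa), "CUA", min_weight = 0)
  expect_equal(unname(call0$support[["A"]]), 4 / (4 + 8 / 9),
               tolerance = 1e-12)
})

test_that("support is invariant to species order and is a convex combination", {
  sim <- simulate_ortholog_set(synthetic_truth("ashbya-like", seed = 17))
  als <- as_ortholog_alignments(sim)
  call <- score_codon_family(als, c("CUA", "CUU"))
  als_shuf <- lapply(als, function(a) {
    set.seed(99)
    a$aln <- a$aln[sample(names(a$aln))]
    a
  })
  call2 <- score_codon_family(als_shuf, c("CUA", "CUU"))
  expect_equal(call$support, call2$support)
  expect_true(all(call$support >= 0 & call$support <= 1))
  expect_equal(sum(call$support), 1.0, tolerance = 1e-9)
})

test_that("ambiguity margin and degenerate-signal paths behave as specified", {
  # an even Ala/Thr split across strong columns is AMBIGUOUS under margin 0.2
  fn <- function(i) if (i %% 2 == 0) rep("A", 9) else rep("T", 9)
  oa <- make_family_fixture(10, fn)
  expect_identical(score_codon_family(list(oa), "CUA")$call, "AMBIGUOUS")
  # all columns below min_weight: NO-SIGNAL, not a call
  weak <- make_family_fixture(5, function(i) c("L", "L", "S", "T", "V",
                                               "I", "F", "Y", "W"))
  res <- score_codon_family(list(weak), "CUA", min_weight = 0.5)
  expect_identical(res$call, "NO-SIGNAL")
  expect_identical(res$n_total_sites, 5L)
  # family never used: ABSENT
  expect_identical(score_codon_family(list(oa), "GGG")$call, "ABSENT")
})

test_that("genome-wide sweep: null genome matches its code, planted family is
           the only reassignment, absent family is ABSENT", {
  simn <- simulate_ortholog_set(synthetic_truth("standard-null", seed = 5))
  cafn <- call_all_families(as_ortholog_alignments(simn),
                            genetic_code("standard"))
  expect_identical(sum(cafn$summary$non_standard), 0L)
  expect_true(all(cafn$summary$matches_code[cafn$summary$n_sites > 0]))

  sima <- simulate_ortholog_set(synthetic_truth("ashbya-like", seed = 6))
  cafa <- call_all_families(as_ortholog_alignments(sima),
                            genetic_code("yeast-mito"), singles = TRUE)
  reassigned <- cafa$summary$family[cafa$summary$non_standard]
  expect_identical(reassigned, "CUN")
  expect_identical(cafa$families[["CUN"]]$call, "A")
  # per-single-codon calls: CUA and CUU each called Ala on their own
  expect_identical(cafa$codons[["CUA"]]$call, "A")
  expect_identical(cafa$codons[["CUU"]]$call, "A")

  simk <- simulate_ortholog_set(synthetic_truth("klactis-like", seed = 7))
  cafk <- call_all_families(as_ortholog_alignments(simk),
                            genetic_code("yeast-mito"))
  expect_identical(cafk$summary$call[cafk$summary$family == "CUN"], "ABSENT")
})

test_that("aligned FASTA reader reconstructs the alignment object", {
  sim <- simulate_ortholog_set(synthetic_truth("ashbya-like", seed = 23,
                                               n_genes = 1L))
  tf <- withr::local_tempfile(fileext = ".fasta")
  writeLines(as.vector(rbind(paste0(">", names(sim$alignments$gene1)),
                             unname(sim$alignments$gene1))), tf)
  oa <- read_ortholog_alignment(tf, "gene1", "target_sp",
                                cds = sim$cds[["gene1"]],
                                code = genetic_code("ashbya-mito"),
                                family = c("CUA", "CUU"))
  expect_identical(oa$aln, sim$alignments$gene1)
  expect_length(oa$column_map, nchar(sim$cds[["gene1"]]) / 3 - 1)
})
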