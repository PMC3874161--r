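test_that("cloverleaf parsing recovers designed landmarks", {
  tr <- ala_trna()
  g <- parse_cloverleaf(tr$seq, minus_one = "none", id = "ala")
  expect_identical(g$anticodon, "UAG")
  expect_identical(g$loop_len, 7L)
  expect_identical(g$landmarks$L, 73L)
  # a base inserted 5' of the anticodon gives an 8-nt loop, anticodon intact
  g8 <- apply_mutation(g, list(list(position = 31, op = "insert", base = "U")))
  expect_identical(g8$loop_len, 8L)
  expect_identical(g8$anticodon, "UAG")
  # CCA-bearing input is stripped before numbering
  gc <- parse_cloverleaf(paste0(tr$seq, "CCA"), minus_one = "none",
                         cca_3prime = TRUE)
  expect_identical(gc$landmarks$L, 73L)
  expect_identical(gc$anticodon, "UAG")
})

test_that("dot-bracket and heuristic parses agree on 50 seeded tRNAs", {
  bases <- c("U", "C", "A", "G")
  for (s in 1:50) {
    set.seed(s * 31)
    spec <- trna_spec(
      pair3_70 = sample(c("G:U", "A:U", "C:G", "U:A"), 1),
      anticodon = paste(sample(bases, 3, replace = TRUE), collapse = ""),
      loop_len = sample(c(7L, 8L), 1),
      disc = sample(bases, 1))
    tr <- build_synthetic_trna(spec, seed = s)
    gh <- parse_cloverleaf(tr$body, minus_one = "none")
    gs <- parse_cloverleaf(tr$body, structure = tr$structure,
                           minus_one = "none")
    expect_identical(gh$anticodon, gs$anticodon)
    expect_identical(gh$loop_len, gs$loop_len)
    expect_identical(gh$anticodon, spec$anticodon)
  }
})

test_that("sequences without a viable cloverleaf fail with diagnostics", {
  set.seed(4)
  junk <- paste(sample(c("A", "C"), 70, replace = TRUE), collapse = "")
  expect_error(parse_cloverleaf(junk), "no viable cloverleaf")
  expect_error(parse_cloverleaf("ACGU"), "outside the plausible")
})

test_that("identity elements are read off the landmarks", {
  g <- parse_cloverleaf(ala_trna()$seq, minus_one = "none")
  el <- extract_identity_elements(g)
  expect_identical(el$pair3_70, "G:U")
  expect_identical(el$anticodon, "UAG")
  expect_false(el$minus1_73_pair)

  gh <- parse_cloverleaf(his_trna()$seq)  # G-1 auto-detected from the 5' end
  elh <- extract_identity_elements(gh)
  expect_identical(elh$minus1, "G")
  expect_identical(elh$base73, "C")
  expect_true(elh$minus1_73_pair)

  # unknown -1 propagates as UNDETERMINED only when it is decisive: a
  # His-like body (C73, GUG) parsed without upstream context cannot be
  # called either way, while a body already violating known HisRS elements
  # is a plain no-match
  hislike <- build_synthetic_trna(trna_spec(pair3_70 = "C:G",
                                            anticodon = "GUG",
                                            minus_one = "none", disc = "C"),
                                  seed = 15)
  gu <- parse_cloverleaf(hislike$body, minus_one = NA)
  cl <- classify_synthetase(gu)
  expect_identical(
    cl$predictions$match[cl$predictions$synthetase == "HisRS"],
    "UNDETERMINED")
  expect_true(is.na(cl$orthogonal))
  known_bad <- classify_synthetase(parse_cloverleaf(ala_trna()$seq,
                                                    minus_one = NA))
  expect_identical(
    known_bad$predictions$match[known_bad$predictions$synthetase == "HisRS"],
    "no-match")
})

test_that("classification matches each synthetase's element signature", {
  ala <- classify_synthetase(parse_cloverleaf(ala_trna()$seq,
                                              minus_one = "none"))
  expect_identical(
    ala$predictions$synthetase[ala$predictions$match == "match"], "AlaRS")
  expect_true(ala$orthogonal)

  thr <- classify_synthetase(parse_cloverleaf(thr_trna()$seq,
                                              minus_one = "none"))
  expect_identical(
    thr$predictions$synthetase[thr$predictions$match == "match"],
    "ThrRS-MST1")
  expect_true(thr$orthogonal)

  his <- classify_synthetase(parse_cloverleaf(his_trna()$seq))
  expect_identical(
    his$predictions$synthetase[his$predictions$match == "match"], "HisRS")
  expect_true(his$orthogonal)

  # relaxed-anticodon HisRS rule admits a UCG-anticodon histidine decoder
  ucg <- build_synthetic_trna(trna_spec(pair3_70 = "C:G", anticodon = "UCG",
                                        minus_one = "G", disc = "C"), 12)
  g <- parse_cloverleaf(ucg$seq)
  strict <- classify_synthetase(g)
  relaxed <- classify_synthetase(g, default_identity_rules(TRUE))
  expect_identical(
    strict$predictions$match[strict$predictions$synthetase == "HisRS"],
    "no-match")
  expect_identical(
    relaxed$predictions$match[relaxed$predictions$synthetase == "HisRS"],
    "match")
})

test_that("the acceptor-stem and loop mutations switch charging identity", {
  ala <- parse_cloverleaf(ala_trna()$seq, minus_one = "none")
  matches <- function(cl) {
    cl$predictions$synthetase[cl$predictions$match == "match"]
  }
  # G3A abolishes the alanine signature
  g3a <- apply_mutation(ala, list(list(position = 3, op = "substitute",
                                       base = "A")))
  expect_false("AlaRS" %in% matches(classify_synthetase(g3a)))

  thr <- parse_cloverleaf(thr_trna()$seq, minus_one = "none")
  # A3G gains AlaRS recognition while the enlarged loop keeps MST1: ambiguous
  a3g <- apply_mutation(thr, list(list(position = 3, op = "substitute",
                                       base = "G")))
  cl <- classify_synthetase(a3g)
  expect_setequal(matches(cl), c("AlaRS", "ThrRS-MST1"))
  expect_false(cl$orthogonal)
  # deleting the inserted loop base restores orthogonality toward AlaRS
  du31 <- apply_mutation(a3g, list(list(position = 31, op = "delete")))
  cl2 <- classify_synthetase(du31)
  expect_identical(matches(cl2), "AlaRS")
  expect_true(cl2$orthogonal)
})

test_that("edits are invertible on the element report", {
  g <- parse_cloverleaf(ala_trna()$seq, minus_one = "none")
  el0 <- extract_identity_elements(g)
  g2 <- apply_mutation(g, list(list(position = 3, op = "substitute",
                                    base = "A")))
  g3 <- apply_mutation(g2, list(list(position = 3, op = "substitute",
                                     base = "G")))
  expect_identical(extract_identity_elements(g3), el0)
  g4 <- apply_mutation(g, list(list(position = 31, op = "insert", base = "U")))
  g5 <- apply_mutation(g4, list(list(position = 31, op = "delete")))
  expect_identical(extract_identity_elements(g5), el0)
})

test_that("classification is a pure function of the element report", {
  # randomizing non-element regions (stems, loops, spacers) with the same
  # element spec never changes the call
  spec <- trna_spec()
  ref <- classify_synthetase(parse_cloverleaf(
    build_synthetic_trna(spec, seed = 1)$seq, minus_one = "none"))
  for (s in 2:20) {
    cl <- classify_synthetase(parse_cloverleaf(
      build_synthetic_trna(spec, seed = s)$seq, minus_one = "none"))
    expect_identical(cl$predictions$match, ref$predictions$match)
  }
})

test_that("planted single-identity tRNAs are classified orthogonal to their
           synthetase across 200 seeded cases", {
  bases <- c("U", "C", "A", "G")
  synths <- c("AlaRS", "ThrRS-MST1", "HisRS", "LeuRS")
  for (s in 1:200) {
    set.seed(s * 7 + 1)
    target <- synths[(s %% 4) + 1]
    spec <- switch(target,
      "AlaRS" = trna_spec(pair3_70 = "G:U",
                          anticodon = paste(sample(c("C", "A", "G"), 3, TRUE),
                                            collapse = ""),
                          disc = sample(c("C", "G", "U"), 1)),
      "ThrRS-MST1" = trna_spec(pair3_70 = sample(c("A:U", "C:G", "U:A"), 1),
                               anticodon = "UAG", loop_len = 8L,
                               disc = sample(c("C", "G", "U"), 1)),
      "HisRS" = trna_spec(pair3_70 = sample(c("A:U", "C:G", "U:A"), 1),
                          anticodon = "GUG", minus_one = "G", disc = "C"),
      "LeuRS" = trna_spec(pair3_70 = sample(c("A:U", "C:G", "U:A"), 1),
                          anticodon = paste(sample(c("C", "A", "G"), 3, TRUE),
                                            collapse = ""),
                          disc = "A"))
    tr <- build_synthetic_trna(spec, seed = s)
    g <- parse_cloverleaf(tr$seq,
                          minus_one = if (identical(spec$minus_one, "none"))
                            "none" else NA)
    cl <- classify_synthetase(g)
    hit <- cl$predictions$synthetase[cl$predictions$match == "match"]
    expect_identical(hit, target)
    expect_true(cl$orthogonal)
  }
})

test_that("rules shipped as TSV equal the in-code defaults", {
  path <- system.file("extdata", "identity_rules.tsv", package = "mitocodon")
  expect_true(nzchar(path))
  expect_identical(read_identity_rules(path), default_identity_rules())
})
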