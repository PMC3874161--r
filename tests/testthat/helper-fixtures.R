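# Shared fixture builders and independent oracles.

# CDS encoding M-K-<peptide> with the family codon CUA at the peptide's sixth
# residue (an Ala in the Ala variant), so a tryptic cut precedes the peptide.
peptide_fixture_cds <- function(peptide = "FIVTAADVIHDFAVPSLGIK",
                                family_at = 6L, family_codon = "CTA") {
  aa2cod <- c(F = "TTT", I = "ATT", V = "GTT", T = "ACT", A = "GCT",
              D = "GAT", H = "CAT", S = "TCT", L = "TTA", G = "GGT",
              K = "AAA", P = "CCT", M = "ATG", R = "AGA", N = "AAT",
              Q = "CAA", E = "GAA", W = "TGG", Y = "TAT", C = "TGT")
  cods <- aa2cod[strsplit(peptide, "")[[1]]]
  cods[family_at] <- family_codon
  paste0("ATGAAA", paste(cods, collapse = ""), "TAA")
}

trna_spec <- function(pair3_70 = "G:U", anticodon = "UAG", loop_len = 7L,
                      minus_one = "none", disc = "G", cca_encoded = FALSE) {
  list(pair3_70 = pair3_70, anticodon = anticodon, loop_len = loop_len,
       minus_one = minus_one, disc = disc, cca_encoded = cca_encoded)
}

ala_trna <- function(seed = 7L) build_synthetic_trna(trna_spec(), seed)
thr_trna <- function(seed = 8L) {
  build_synthetic_trna(trna_spec(pair3_70 = "A:U", loop_len = 8L), seed)
}
his_trna <- function(seed = 9L) {
  build_synthetic_trna(trna_spec(pair3_70 = "C:G", anticodon = "GUG",
                                 minus_one = "G", disc = "C"), seed)
}

# independent single-pass codon counter (substring step 3)
naive_codon_count <- function(seqs, drop_terminal_stop_of, include_stops = FALSE) {
  counts <- setNames(integer(64), rna_codons())
  stops <- names(drop_terminal_stop_of$table)[drop_terminal_stop_of$table == "*"]
  for (s in seqs) {
    rna <- gsub("T", "U", toupper(s), fixed = TRUE)
    i <- 1L
    while (i + 2L <= nchar(rna)) {
      cd <- substr(rna, i, i + 2L)
      if (include_stops || !(cd %in% stops)) counts[cd] <- counts[cd] + 1L
      i <- i + 3L
    }
  }
  counts
}

# independent two-pointer tryptic digest (no regex, no vector trickery)
naive_digest <- function(protein) {
  out <- character()
  start <- 1L
  n <- nchar(protein)
  for (i in seq_len(n)) {
    aa <- substr(protein, i, i)
    nxt <- if (i < n) substr(protein, i + 1L, i + 1L) else ""
    if ((aa == "K" || aa == "R") && nxt != "P" || i == n) {
      out <- c(out, substr(protein, start, i))
      start <- i + 1L
    }
  }
  out
}

# brute-force minimal anticodon cover: bitmask subset enumeration per box
brute_force_min_anticodons <- function(code, classes = wobble_classes()) {
  total <- 0L
  for (bx in unique(substr(rna_codons(), 1L, 2L))) {
    codons <- paste0(bx, c("U", "C", "A", "G"))
    targets <- codons[code$table[codons] != "*"]
    if (!length(targets)) next
    read_sets <- list()
    for (i in seq_len(nrow(classes))) {
      ac <- paste0(classes$base34[i],
                   chartr("ACGU", "UGCA", substr(bx, 2, 2)),
                   chartr("ACGU", "UGCA", substr(bx, 1, 1)))
      rs <- tryCatch(anticodon_read_set(ac, classes$label[i]),
                     error = function(e) NULL)
      if (is.null(rs)) next
      aas <- unique(unname(code$table[rs]))
      if (length(aas) == 1L && aas != "*") read_sets[[length(read_sets) + 1L]] <- rs
    }
    k <- length(read_sets)
    best <- NA_integer_
    if (k > 0L) {
      for (mask in 1:(2^k - 1L)) {
        idx <- which(bitwAnd(mask, 2^(seq_len(k) - 1L)) > 0L)
        if (all(targets %in% unlist(read_sets[idx]))) {
          best <- min(best, length(idx), na.rm = TRUE)
        }
      }
    }
    if (is.na(best)) stop("box ", bx, " uncoverable")
    total <- total + best
  }
  total
}

# O(reads x windows) membership oracle: a window counts a read when it is
# among the read's own k-mers
naive_window_counts <- function(reads, windows, k) {
  vapply(windows, function(w) {
    hits <- 0L
    for (r in reads) {
      rr <- gsub("T", "U", toupper(r), fixed = TRUE)
      if (nchar(rr) < k) next
      kmers <- substring(rr, 1:(nchar(rr) - k + 1L), k:nchar(rr))
      if (w %in% kmers) hits <- hits + 1L
    }
    hits
  }, integer(1), USE.NAMES = FALSE)
}

# coarse grid + one refinement for Michaelis-Menten least squares
grid_fit_mm <- function(S, v, enzyme = 1) {
  sse <- function(kcat, Km) sum((v - kcat * enzyme * S / (Km + S))^2)
  kc <- seq(0.1, 10, length.out = 60)
  km <- seq(0.01, 10, length.out = 60)
  g <- expand.grid(kcat = kc, Km = km)
  errs <- mapply(sse, g$kcat, g$Km)
  b <- g[which.min(errs), ]
  kc2 <- seq(b$kcat * 0.7, b$kcat * 1.3, length.out = 80)
  km2 <- seq(b$Km * 0.7, b$Km * 1.3, length.out = 80)
  g2 <- expand.grid(kcat = kc2, Km = km2)
  errs2 <- mapply(sse, g2$kcat, g2$Km)
  g2[which.min(errs2), ]
}
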