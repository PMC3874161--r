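#' Monoisotopic residue masses (Da)
#'
#' Standard monoisotopic masses of the 20 amino-acid residues (peptide-bond
#' residues, i.e. amino acid minus water).
#' @return named numeric vector
#' @export
residue_masses <- function() {
  c(G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
    T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406,
    N = 114.04293, D = 115.02694, Q = 128.05858, K = 128.09496,
    E = 129.04259, M = 131.04049, H = 137.05891, F = 147.06841,
    R = 156.10111, Y = 163.06333, W = 186.07931)
}

WATER_MONO <- 18.010565
CARBAMIDOMETHYL <- 57.02146

#' Monoisotopic peptide mass
#'
#' Sum of residue monoisotopic masses plus one water, with fixed modifications
#' added per residue. Carbamidomethylation of cysteine (+57.02146 Da, the
#' standard alkylation adduct) is on by default.
#'
#' @param seq peptide sequence (one-letter)
#' @param fixed_mods named numeric: mass to add per occurrence of each residue
#' @return mass in Da; the empty peptide returns the water mass (degenerate)
#' @examples
#' peptide_mass("G")  # 75.03203
#' @export
peptide_mass <- function(seq, fixed_mods = c(C = CARBAMIDOMETHYL)) {
  if (nchar(seq) == 0L) return(WATER_MONO)
  aa <- strsplit(toupper(seq), "")[[1]]
  rm <- residue_masses()
  if (any(!aa %in% names(rm))) {
    stop("unknown residue(s): ",
         paste(unique(aa[!aa %in% names(rm)]), collapse = ", "), call. = FALSE)
  }
  m <- sum(rm[aa]) + WATER_MONO
  for (res in names(fixed_mods)) {
    m <- m + fixed_mods[[res]] * sum(aa == res)
  }
  m
}

#' In-silico tryptic digestion
#'
#' Cleaves after K or R except when the next residue is P, then appends
#' missed-cleavage concatenations up to the limit. The 0-missed peptides
#' concatenate back to the protein.
#'
#' @param protein residue string
#' @param missed_cleavages maximum missed cleavages (default 0)
#' @return data.frame: `start`, `end` (1-based inclusive residue coords),
#'   `seq`, `n_missed`
#' @examples
#' tryptic_digest("MKRPLG")$seq  # "MK", "RPLG"
#' @export
tryptic_digest <- function(protein, missed_cleavages = 0L) {
  protein <- toupper(protein)
  n <- nchar(protein)
  if (n == 0L) {
    return(data.frame(start = integer(), end = integer(),
                      seq = character(), n_missed = integer()))
  }
  aa <- strsplit(protein, "")[[1]]
  cut_after <- which(aa %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n & aa[cut_after + 1L] != "P" |
                         cut_after == n]
  bounds <- c(0L, cut_after[cut_after < n], n)
  starts <- bounds[-length(bounds)] + 1L
  ends <- bounds[-1L]
  base <- data.frame(start = starts, end = ends,
                     seq = substring(protein, starts, ends),
                     n_missed = 0L, stringsAsFactors = FALSE)
  out <- base
  if (missed_cleavages > 0L) {
    for (m in seq_len(missed_cleavages)) {
      if (m + 1L > nrow(base)) break
      i <- seq_len(nrow(base) - m)
      out <- rbind(out, data.frame(
        start = base$start[i], end = base$end[i + m],
        seq = substring(protein, base$start[i], base$end[i + m]),
        n_missed = m, stringsAsFactors = FALSE))
    }
  }
  out
}

#' Build variant proteomes for a codon family
#'
#' Translates every CDS several times, substituting each candidate amino acid
#' at the family's codon positions, yielding one proteome per candidate. The
#' variants differ only at those positions. This reproduces the
#' three-database strategy used to let observed peptides discriminate which
#' amino acid a reassigned codon encodes.
#'
#' @param cds_set named character vector of CDS (or FASTA path)
#' @param family codon set under assessment, e.g. `c("CUA", "CUU")`
#' @param candidates one-letter amino acids to try, e.g. `c("L", "T", "A")`
#' @param code genetic code for all other codons
#' @return object of class `variant_proteomes`: list with `variants` (named
#'   list: candidate -> named character vector of proteins), and
#'   `variant_positions` (data.frame: gene, residue_index, codon)
#' @export
variant_proteomes <- function(cds_set, family = c("CUA", "CUU"),
                              candidates = c("L", "T", "A"),
                              code = genetic_code("yeast-mito")) {
  seqs <- read_cds_input(cds_set)
  family <- as_rna(family)
  stops <- names(code$table)[code$table == "*"]
  pos <- list()
  base_prot <- character(length(seqs))
  names(base_prot) <- names(seqs)
  codon_lists <- list()
  for (g in names(seqs)) {
    rna <- as_rna(seqs[[g]])
    if (nchar(rna) %% 3L != 0L) {
      stop("gene '", g, "' length is not a multiple of 3", call. = FALSE)
    }
    cd <- split_codons(rna)
    if (length(cd) && cd[length(cd)] %in% stops) cd <- cd[-length(cd)]
    codon_lists[[g]] <- cd
    hit <- which(cd %in% family)
    if (length(hit)) {
      pos[[g]] <- data.frame(gene = g, residue_index = hit, codon = cd[hit],
                             stringsAsFactors = FALSE)
    }
  }
  vp <- do.call(rbind, pos)
  if (is.null(vp)) {
    warning("family {", paste(family, collapse = ","),
            "} absent from every gene; variant proteomes are identical")
    vp <- data.frame(gene = character(), residue_index = integer(),
                     codon = character(), stringsAsFactors = FALSE)
  }
  variants <- lapply(candidates, function(a) {
    prots <- vapply(names(seqs), function(g) {
      cd <- codon_lists[[g]]
      aa <- unname(code$table[cd])
      aa[cd %in% family] <- a
      if (any(aa == "*")) {
        stop("internal stop codon in gene '", g, "'", call. = FALSE)
      }
      paste(aa, collapse = "")
    }, character(1))
    prots
  })
  names(variants) <- candidates
  structure(list(variants = variants, variant_positions = vp,
                 family = family, candidates = candidates),
            class = "variant_proteomes")
}

#' @export
print.variant_proteomes <- function(x, ...) {
  cat(sprintf("<variant_proteomes> %d genes x {%s}; %d variant positions\n",
              length(x$variants[[1L]]), paste(x$candidates, collapse = ","),
              nrow(x$variant_positions)))
  invisible(x)
}

#' Digest all variant proteomes into peptide records
#'
#' @param proteomes a `variant_proteomes`
#' @param missed_cleavages passed to [tryptic_digest()]
#' @param fixed_mods passed to [peptide_mass()]
#' @return data.frame: `variant`, `gene`, `start`, `end`, `seq`, `n_missed`,
#'   `mass`, `discriminating` (peptide overlaps >= 1 variant position),
#'   `sites` (semicolon-joined residue indices of covered variant positions)
#' @export
digest_proteomes <- function(proteomes, missed_cleavages = 0L,
                             fixed_mods = c(C = CARBAMIDOMETHYL)) {
  vp <- proteomes$variant_positions
  rows <- list()
  for (v in names(proteomes$variants)) {
    for (g in names(proteomes$variants[[v]])) {
      dg <- tryptic_digest(proteomes$variants[[v]][[g]], missed_cleavages)
      if (!nrow(dg)) next
      gvp <- vp$residue_index[vp$gene == g]
      covered <- lapply(seq_len(nrow(dg)), function(i) {
        gvp[gvp >= dg$start[i] & gvp <= dg$end[i]]
      })
      dg$variant <- v
      dg$gene <- g
      dg$mass <- vapply(dg$seq, peptide_mass, numeric(1),
                        fixed_mods = fixed_mods, USE.NAMES = FALSE)
      dg$discriminating <- lengths(covered) > 0L
      dg$sites <- vapply(covered, paste, character(1), collapse = ";")
      rows[[length(rows) + 1L]] <- dg
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[, c("variant", "gene", "start", "end", "seq", "n_missed", "mass",
          "discriminating", "sites")]
}

#' Match observed peptides against variant proteomes
#'
#' Each observation (a peptide sequence, or a measured monoisotopic mass
#' matched within a ppm tolerance) is assigned to the peptides it matches in
#' each variant's digest. The verdict for each variant codon site is the set
#' of variants whose discriminating peptide covering that site is matched by
#' some observation; an observation matching only non-discriminating peptides
#' constrains nothing (all variants stay consistent). Verdicts do not depend
#' on observation order.
#'
#' @param observed data.frame with column `sequence` and/or `mass`
#' @param proteomes a `variant_proteomes`
#' @param tolerance_ppm mass tolerance in parts per million (default 10)
#' @param missed_cleavages passed to the digest
#' @return object of class `ms_evidence`: list with `evidence` (per
#'   observation x matched peptide), `site_verdicts` (data.frame: gene,
#'   residue_index, codon, consistent_variants), and `unmatched` (indices of
#'   observations matching nothing)
#' @export
match_observed <- function(observed, proteomes, tolerance_ppm = 10,
                           missed_cleavages = 0L) {
  if (tolerance_ppm <= 0) stop("tolerance_ppm must be > 0", call. = FALSE)
  db <- digest_proteomes(proteomes, missed_cleavages)
  has_seq <- "sequence" %in% names(observed)
  has_mass <- "mass" %in% names(observed)
  if (!has_seq && !has_mass) {
    stop("observed needs a 'sequence' or 'mass' column", call. = FALSE)
  }
  ev <- list()
  unmatched <- integer()
  for (i in seq_len(nrow(observed))) {
    sq <- if (has_seq) observed$sequence[i] else NA_character_
    ms <- if (has_mass) observed$mass[i] else NA_real_
    hit <- if (!is.na(sq) && nzchar(sq)) {
      db$seq == toupper(sq)
    } else if (!is.na(ms)) {
      abs(db$mass - ms) / db$mass * 1e6 <= tolerance_ppm
    } else rep(FALSE, nrow(db))
    if (!any(hit)) {
      unmatched <- c(unmatched, i)
      next
    }
    h <- db[hit, ]
    h$observation <- i
    ev[[length(ev) + 1L]] <- h
  }
  evidence <- if (length(ev)) do.call(rbind, ev) else db[0, ]
  vp <- proteomes$variant_positions
  verdicts <- lapply(seq_len(nrow(vp)), function(j) {
    g <- vp$gene[j]; ri <- vp$residue_index[j]
    covering <- evidence[evidence$gene == g & evidence$discriminating &
                         evidence$start <= ri & evidence$end >= ri, ]
    consistent <- if (nrow(covering)) sort(unique(covering$variant))
                  else proteomes$candidates
    data.frame(gene = g, residue_index = ri, codon = vp$codon[j],
               observed = nrow(covering) > 0L,
               consistent_variants = paste(consistent, collapse = ","),
               stringsAsFactors = FALSE)
  })
  site_verdicts <- if (length(verdicts)) do.call(rbind, verdicts) else
    data.frame(gene = character(), residue_index = integer(),
               codon = character(), observed = logical(),
               consistent_variants = character())
  structure(list(evidence = evidence, site_verdicts = site_verdicts,
                 unmatched = unmatched),
            class = "ms_evidence")
}

#' @export
print.ms_evidence <- function(x, ...) {
  n_obs_sites <- sum(x$site_verdicts$observed)
  cat(sprintf("<ms_evidence> %d peptide matches; %d/%d variant sites observed; %d unmatched observations\n",
              nrow(x$evidence), n_obs_sites, nrow(x$site_verdicts),
              length(x$unmatched)))
  invisible(x)
}
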