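#' Count codon usage over a set of coding sequences
#'
#' Builds a codon usage table from a set of CDS. Each gene must be
#' triplet-clean; genes containing internal stop codons are rejected rather
#' than skipped, because they usually signal the wrong genetic code or frame.
#' Stop codons are excluded from `total_codons` by default, as sense-usage
#' tables conventionally are.
#'
#' @param cds_set named character vector of CDS (DNA or RNA alphabet), or a
#'   path to a multi-FASTA file, or a `Biostrings::DNAStringSet`.
#' @param code a `genetic_code` (used for the sense/stop partition)
#' @param include_stops logical; count stop codons and include them in
#'   `total_codons`
#' @return An object of class `codon_usage`: list with `counts` (named integer
#'   over all 64 codons), `per_gene` (gene x codon integer matrix),
#'   `total_codons`, `include_stops`, and `code_name`.
#' @examples
#' tab <- count_codons(c(g1 = "ATGCTACTTTAA"), genetic_code("ashbya-mito"))
#' tab$counts[c("AUG", "CUA", "CUU")]
#' @export
count_codons <- function(cds_set, code, include_stops = FALSE) {
  seqs <- read_cds_input(cds_set)
  codons <- rna_codons()
  per_gene <- matrix(0L, nrow = length(seqs), ncol = 64L,
                     dimnames = list(names(seqs), codons))
  stops <- names(code$table)[code$table == "*"]
  for (i in seq_along(seqs)) {
    rna <- as_rna(seqs[[i]])
    if (nchar(rna) %% 3L != 0L) {
      stop("gene '", names(seqs)[i], "' length is not a multiple of 3",
           call. = FALSE)
    }
    cd <- split_codons(rna)
    is_stop <- cd %in% stops
    if (any(is_stop[-length(cd)])) {
      stop("gene '", names(seqs)[i], "' has an internal stop codon under '",
           code$name, "'", call. = FALSE)
    }
    if (!include_stops) cd <- cd[!is_stop]
    tb <- table(factor(cd, levels = codons))
    per_gene[i, ] <- as.integer(tb)
  }
  counts <- setNames(as.integer(colSums(per_gene)), codons)
  structure(list(counts = counts, per_gene = per_gene,
                 total_codons = sum(counts), include_stops = include_stops,
                 code_name = code$name),
            class = "codon_usage")
}

read_cds_input <- function(cds_set) {
  if (inherits(cds_set, "DNAStringSet") || inherits(cds_set, "RNAStringSet")) {
    return(setNames(as.character(cds_set), names(cds_set)))
  }
  if (is.character(cds_set) && length(cds_set) == 1L && file.exists(cds_set) &&
      !grepl("^[ACGTUacgtu]+$", cds_set)) {
    ss <- Biostrings::readDNAStringSet(cds_set)
    nm <- sub("\\s.*$", "", names(ss))
    return(setNames(as.character(ss), nm))
  }
  if (!is.character(cds_set) || is.null(names(cds_set))) {
    stop("cds_set must be a named character vector, DNAStringSet, or a FASTA path",
         call. = FALSE)
  }
  cds_set
}

#' @export
print.codon_usage <- function(x, ...) {
  cat(sprintf("<codon_usage> %d genes, %d codons counted (code '%s', stops %s)\n",
              nrow(x$per_gene), x$total_codons, x$code_name,
              if (x$include_stops) "included" else "excluded"))
  invisible(x)
}

#' Unused (liberated) sense codons
#'
#' Sense codons with zero observed usage are candidates for codon capture: a
#' codon family that disappears from a genome can later reappear with a new
#' amino-acid identity. A+T-rich mitochondrial genomes typically liberate
#' codons with C or G in the third position first.
#'
#' @param table a `codon_usage`
#' @param code the `genetic_code` the table was built under
#' @return list with `unused` (character vector of zero-count sense codons) and
#'   `third_position` (named integer breakdown of their third bases; sums to
#'   the number of unused codons).
#' @export
unused_codons <- function(table, code) {
  sense <- sense_codons(code)
  unused <- sense[table$counts[sense] == 0L]
  third <- substr(unused, 3L, 3L)
  breakdown <- setNames(integer(4L), RNA_BASES)
  tb <- base::table(factor(third, levels = RNA_BASES))
  breakdown[] <- as.integer(tb)
  list(unused = unused, third_position = breakdown)
}

#' Per-family codon occupancy report
#'
#' Summarizes usage per codon box (the four codons sharing first and second
#' positions), reporting used and unused codons and the fraction of family
#' usage with A or U in the third position.
#'
#' @param table a `codon_usage`
#' @param code a `genetic_code`
#' @return data.frame with one row per box: `family`, `amino_acids`
#'   (comma-joined), `used`, `unused`, `n_codons`, `fraction_third_AU`.
#' @export
family_occupancy <- function(table, code) {
  boxes <- unique(substr(rna_codons(), 1L, 2L))
  rows <- lapply(boxes, function(bx) {
    codons <- paste0(bx, RNA_BASES)
    sense <- codons[code$table[codons] != "*"]
    cts <- table$counts[sense]
    used <- sense[cts > 0L]
    third_au <- sense[substr(sense, 3L, 3L) %in% c("A", "U")]
    tot <- sum(cts)
    data.frame(
      family = paste0(bx, "N"),
      amino_acids = paste(unique(unname(code$table[sense])), collapse = ","),
      used = paste(used, collapse = ","),
      unused = paste(setdiff(sense, used), collapse = ","),
      n_codons = tot,
      fraction_third_AU = if (tot > 0L) sum(table$counts[third_au]) / tot else NA_real_,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a codon usage table as TSV in 16-box layout
#'
#' @param table a `codon_usage`
#' @param code a `genetic_code`
#' @param path output TSV path
#' @return the written data.frame, invisibly
#' @export
write_usage_tsv <- function(table, code, path) {
  codons <- rna_codons()
  df <- data.frame(codon = codons,
                   amino_acid = unname(code$table[codons]),
                   count = unname(table$counts[codons]),
                   family = paste0(substr(codons, 1L, 2L), "N"),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
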