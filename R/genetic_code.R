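RNA_BASES <- c("U", "C", "A", "G")

AA_ONE <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
            "M", "F", "P", "S", "T", "W", "Y", "V")

#' All 64 RNA codons
#'
#' Codons are enumerated in the conventional U/C/A/G base order, so codons
#' sharing first and second positions (a "box" or codon family) are adjacent.
#'
#' @return Character vector of 64 RNA codons, 5'-to-3'.
#' @export
rna_codons <- function() {
  grid <- expand.grid(p3 = RNA_BASES, p2 = RNA_BASES, p1 = RNA_BASES,
                      stringsAsFactors = FALSE)
  paste0(grid$p1, grid$p2, grid$p3)
}

#' Complement of RNA bases
#' @param x character vector of single RNA bases
#' @return complementary bases
#' @keywords internal
rna_complement <- function(x) {
  unname(c(A = "U", U = "A", G = "C", C = "G")[x])
}

#' Reverse complement of an RNA string
#' @param x single RNA string
#' @keywords internal
rna_revcomp <- function(x) {
  paste(rev(rna_complement(strsplit(x, "")[[1]])), collapse = "")
}

#' Convert a nucleotide string to the RNA alphabet
#'
#' DNA input is transcribed T to U; all codon reporting in this package uses
#' the RNA alphabet. Case is normalized to upper.
#'
#' @param x character vector of nucleotide strings (alphabet ACGTU, any case)
#' @return character vector in upper-case RNA alphabet
#' @export
as_rna <- function(x) {
  x <- toupper(x)
  bad <- grepl("[^ACGTU]", x)
  if (any(bad)) {
    stop("invalid nucleotide character in sequence ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  }
  gsub("T", "U", x, fixed = TRUE)
}

#' Construct a genetic code
#'
#' Built-in codes:
#' \describe{
#'   \item{standard}{The standard nuclear code.}
#'   \item{yeast-mito}{Yeast mitochondrial code: the CUN family is Thr,
#'     AUA is Met, UGA is Trp.}
#'   \item{ashbya-mito}{The Ashbya gossypii mitochondrial code: as yeast-mito
#'     but with the whole CUN family assigned to Ala. CUC and CUG are flagged
#'     as avoided (unused in practice); their Ala assignment is the superwobble
#'     prediction for a single U34 anticodon reading the whole family, not an
#'     observed translation.}
#'   \item{vertebrate-mito}{Vertebrate mitochondrial code: AUA Met, UGA Trp,
#'     AGA/AGG stop.}
#' }
#'
#' @param name one of `"standard"`, `"yeast-mito"`, `"ashbya-mito"`,
#'   `"vertebrate-mito"`, or any label when `table` is supplied.
#' @param table optional named character vector of 64 entries, RNA codons to
#'   one-letter amino acids with `"*"` for stop, to define a custom code.
#' @param avoided codons flagged unused-in-practice; must be sense codons.
#' @return An object of class `genetic_code`: a list with `name`, `table`
#'   (named character of length 64, values one-letter amino acid or `"*"`),
#'   and `avoided`.
#' @examples
#' code <- genetic_code("ashbya-mito")
#' code$table[["CUA"]]  # "A"
#' @export
genetic_code <- function(name, table = NULL, avoided = character()) {
  if (is.null(table)) {
    table <- switch(name,
      "standard" = standard_code_table(),
      "yeast-mito" = {
        tb <- standard_code_table()
        tb[c("CUU", "CUC", "CUA", "CUG")] <- "T"
        tb["AUA"] <- "M"
        tb["UGA"] <- "W"
        tb
      },
      "ashbya-mito" = {
        tb <- standard_code_table()
        tb[c("CUU", "CUC", "CUA", "CUG")] <- "A"
        tb["AUA"] <- "M"
        tb["UGA"] <- "W"
        if (!length(avoided)) avoided <- c("CUC", "CUG")
        tb
      },
      "vertebrate-mito" = {
        tb <- standard_code_table()
        tb["AUA"] <- "M"
        tb["UGA"] <- "W"
        tb[c("AGA", "AGG")] <- "*"
        tb
      },
      stop("unknown genetic code: ", name, call. = FALSE)
    )
  }
  validate_genetic_code(name, table, avoided)
}

standard_code_table <- function() {
  tb <- Biostrings::GENETIC_CODE
  names(tb) <- gsub("T", "U", names(tb), fixed = TRUE)
  tb[rna_codons()]
}

validate_genetic_code <- function(name, table, avoided) {
  codons <- rna_codons()
  if (length(table) != 64L || !setequal(names(table), codons)) {
    stop("genetic code table must have exactly the 64 RNA codons as names",
         call. = FALSE)
  }
  table <- table[codons]
  ok <- table %in% c(AA_ONE, "*")
  if (!all(ok)) {
    stop("invalid amino-acid symbol(s): ",
         paste(unique(table[!ok]), collapse = ", "), call. = FALSE)
  }
  sense <- names(table)[table != "*"]
  if (!all(avoided %in% sense)) {
    stop("avoided codons must be sense codons under the code", call. = FALSE)
  }
  structure(list(name = name, table = table, avoided = avoided),
            class = "genetic_code")
}

#' Load a custom genetic code from a two-column TSV
#'
#' @param path TSV with columns `codon` (RNA or DNA alphabet) and `amino_acid`
#'   (one-letter, `STOP` or `*` for stop).
#' @param name label for the code
#' @param avoided optional avoided codons
#' @return a `genetic_code`
#' @export
read_genetic_code <- function(path, name = basename(path),
                              avoided = character()) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("codon", "amino_acid") %in% names(df))) {
    stop("genetic code TSV needs columns 'codon' and 'amino_acid'",
         call. = FALSE)
  }
  aa <- toupper(df$amino_acid)
  aa[aa == "STOP"] <- "*"
  tb <- stats::setNames(aa, as_rna(df$codon))
  genetic_code(name, table = tb, avoided = as_rna(avoided))
}

#' @export
print.genetic_code <- function(x, ...) {
  n_sense <- sum(x$table != "*")
  cat(sprintf("<genetic_code> %s: %d sense codons, %d stops, %d avoided\n",
              x$name, n_sense, 64L - n_sense, length(x$avoided)))
  invisible(x)
}

#' Sense codons of a genetic code
#' @param code a `genetic_code`
#' @return character vector of codons not translated as stop
#' @export
sense_codons <- function(code) {
  names(code$table)[code$table != "*"]
}

#' Split a nucleotide sequence into codons
#' @keywords internal
split_codons <- function(rna) {
  n <- nchar(rna)
  substring(rna, seq(1L, n - 2L, by = 3L), seq(3L, n, by = 3L))
}

#' Translate a coding sequence
#'
#' Translates a triplet-clean CDS under a given genetic code. A terminal stop
#' codon is trimmed from the protein. Internal stops are an error by default
#' (they usually signal the wrong code or frame) or can be marked `*`.
#'
#' @param cds nucleotide string (DNA or RNA alphabet; transcribed internally)
#' @param code a `genetic_code`
#' @param frame_policy `"error"` rejects non-triplet lengths; `"trim"` drops
#'   trailing bases beyond the last complete codon.
#' @param internal_stop `"error"` or `"mark"` (emit `*` and continue)
#' @return one-letter amino-acid string, one residue per codon, terminal stop
#'   removed. The empty sequence translates to the empty protein.
#' @examples
#' translate_cds("CUA", genetic_code("ashbya-mito"))  # "A"
#' translate_cds("CUA", genetic_code("yeast-mito"))   # "T"
#' translate_cds("CUA", genetic_code("standard"))     # "L"
#' @export
translate_cds <- function(cds, code, frame_policy = c("error", "trim"),
                          internal_stop = c("error", "mark")) {
  frame_policy <- match.arg(frame_policy)
  internal_stop <- match.arg(internal_stop)
  rna <- as_rna(cds)
  if (nchar(rna) %% 3L != 0L) {
    if (frame_policy == "error") {
      stop("sequence length ", nchar(rna), " is not a multiple of 3",
           call. = FALSE)
    }
    rna <- substr(rna, 1L, nchar(rna) - nchar(rna) %% 3L)
  }
  if (nchar(rna) == 0L) return("")
  aa <- unname(code$table[split_codons(rna)])
  if (aa[length(aa)] == "*") aa <- aa[-length(aa)]
  if (any(aa == "*") && internal_stop == "error") {
    stop("internal stop codon at codon ", which(aa == "*")[1L],
         " under code '", code$name, "'", call. = FALSE)
  }
  paste(aa, collapse = "")
}
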