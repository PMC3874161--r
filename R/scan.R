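#' Scan configuration for exact-window read counting
#'
#' @param k window length in nt (the published scan used 15-mers)
#' @param flank genomic flank carried on each side of the gene; must be at
#'   least `k - 1` so junction-spanning windows exist
#' @param count_revcomp also count reverse-complement read matches
#' @return list of class `scan_config`
#' @export
scan_config <- function(k = 15L, flank = 30L, count_revcomp = FALSE) {
  k <- as.integer(k); flank <- as.integer(flank)
  if (k < 8L) stop("window length k must be >= 8", call. = FALSE)
  if (flank < k - 1L) stop("flank must be >= k - 1", call. = FALSE)
  structure(list(k = k, flank = flank, count_revcomp = count_revcomp),
            class = "scan_config")
}

#' Build the labeled k-mer window set for a tRNA gene
#'
#' Windows are every k-mer of the precursor (gene plus genomic flanks) and of
#' the mature form (gene body, with CCA appended when not genome-encoded).
#' Labels formalize what a window proves when found in a read:
#' \describe{
#'   \item{leader_junction}{spans the 5' flank/gene boundary: precursor-only
#'     evidence (unprocessed or 5'-intermediate).}
#'   \item{trailer_junction}{spans the gene/3' flank boundary: precursor-only.}
#'   \item{mature_body}{entirely within the gene: present in precursor and
#'     mature forms alike (expression evidence).}
#'   \item{mature_cca}{spans the gene 3' end into the appended CCA: evidence
#'     of CCA maturation. Only CCA-specific windows are emitted: a candidate
#'     whose sequence also occurs in the genomic precursor (including every
#'     such window when the CCA is genome-encoded, or a short CCA overlap
#'     that the trailer happens to reproduce) proves nothing and is dropped.}
#'   \item{ambiguous}{entirely within a flank; matches the precursor but
#'     carries no processing information about this gene.}
#' }
#'
#' @param flanked full genomic sequence: 5' flank + gene + 3' flank
#' @param gene_start,gene_end 0-based half-open gene coordinates within
#'   `flanked`
#' @param cca_encoded is the terminal CCA part of the genomic gene
#' @param cfg a [scan_config()]
#' @return data.frame of class `window_set`: columns `window` (k-mer, RNA
#'   alphabet), `label`, `source` (`precursor`/`mature`), `start` (0-based in
#'   the source sequence)
#' @export
build_windows <- function(flanked, gene_start, gene_end, cca_encoded = FALSE,
                          cfg = scan_config()) {
  rna <- as_rna(flanked)
  k <- cfg$k
  n <- nchar(rna)
  if (gene_start < 0L || gene_end > n || gene_end <= gene_start) {
    stop("gene coordinates outside the flanked sequence", call. = FALSE)
  }
  if (gene_end - gene_start < k) {
    stop("gene shorter than the window length k", call. = FALSE)
  }
  starts <- 0:(n - k)
  ends <- starts + k  # half-open
  label <- rep("mature_body", length(starts))
  label[ends <= gene_start | starts >= gene_end] <- "ambiguous"
  label[starts < gene_start & ends > gene_start] <- "leader_junction"
  label[starts < gene_end & ends > gene_end] <- "trailer_junction"
  prec <- data.frame(
    window = substring(rna, starts + 1L, ends),
    label = label, source = "precursor", start = starts,
    stringsAsFactors = FALSE)
  gene <- substr(rna, gene_start + 1L, gene_end)
  mature <- if (cca_encoded) gene else paste0(gene, "CCA")
  if (!cca_encoded) {
    mstarts <- 0:(nchar(mature) - k)
    mends <- mstarts + k
    cca_at <- nchar(gene)
    keep <- mends > cca_at  # windows reaching into the appended CCA
    # CCA-specific only: drop windows the genomic precursor also contains
    keep[keep] <- !vapply(substring(mature, mstarts[keep] + 1L, mends[keep]),
                          grepl, logical(1), x = rna, fixed = TRUE,
                          USE.NAMES = FALSE)
    if (any(keep)) {
      cca <- data.frame(
        window = substring(mature, mstarts[keep] + 1L, mends[keep]),
        label = "mature_cca", source = "mature", start = mstarts[keep],
        stringsAsFactors = FALSE)
      prec <- rbind(prec, cca)
    }
  }
  class(prec) <- c("window_set", "data.frame")
  attr(prec, "cfg") <- cfg
  attr(prec, "gene") <- gene
  attr(prec, "mature") <- mature
  prec
}

#' Count reads containing each labeled window
#'
#' A read counts once per window when it contains the window as an exact
#' substring (grep semantics on reads); no mismatches are tolerated, matching
#' the published literal 15-mer scan. Optionally the reverse complement of
#' each read is searched too.
#'
#' @param reads character vector of read sequences, or a path to a
#'   FASTA/FASTQ file
#' @param windows a `window_set` from [build_windows()]
#' @return object of class `processing_summary`: list with `per_window` (the
#'   window table plus a `count` column) and `derived` (named integer:
#'   `mature_body`, `mature_cca`, `leader_junction`, `trailer_junction`,
#'   `mature_5prime`, `ambiguous`, `n_reads`). `mature_5prime` is the count of
#'   the window anchored at the gene 5' terminus.
#' @export
scan_reads <- function(reads, windows) {
  cfg <- attr(windows, "cfg")
  reads <- read_reads_input(reads)
  rna_reads <- if (length(reads)) as_rna(reads) else character()
  if (cfg$count_revcomp && length(rna_reads)) {
    rc <- vapply(rna_reads, rna_revcomp, character(1), USE.NAMES = FALSE)
  }
  counts <- integer(nrow(windows))
  if (length(rna_reads)) {
    for (i in seq_len(nrow(windows))) {
      hit <- grepl(windows$window[i], rna_reads, fixed = TRUE)
      if (cfg$count_revcomp) hit <- hit | grepl(windows$window[i], rc, fixed = TRUE)
      counts[i] <- sum(hit)
    }
  }
  per_window <- windows
  per_window$count <- counts
  five_prime <- which(per_window$source == "precursor" &
                      per_window$label == "mature_body")
  mature5 <- if (length(five_prime)) {
    gene_first <- min(per_window$start[five_prime])
    sum(counts[five_prime][per_window$start[five_prime] == gene_first])
  } else 0L
  derived <- c(
    mature_body = sum(counts[per_window$label == "mature_body"]),
    mature_cca = sum(counts[per_window$label == "mature_cca"]),
    leader_junction = sum(counts[per_window$label == "leader_junction"]),
    trailer_junction = sum(counts[per_window$label == "trailer_junction"]),
    ambiguous = sum(counts[per_window$label == "ambiguous"]),
    mature_5prime = mature5,
    n_reads = length(rna_reads))
  structure(list(per_window = per_window, derived = derived),
            class = "processing_summary")
}

read_reads_input <- function(reads) {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads) &&
      !grepl("^[ACGTUNacgtun]*$", reads)) {
    if (grepl("\\.(fastq|fq)$", reads)) {
      ln <- readLines(reads)
      return(ln[seq(2L, length(ln), by = 4L)])
    }
    ss <- Biostrings::readDNAStringSet(reads)
    return(unname(as.character(ss)))
  }
  as.character(reads)
}

#' @export
print.processing_summary <- function(x, ...) {
  d <- x$derived
  cat(sprintf(paste0("<processing_summary> %d reads: mature_body %d, ",
                     "mature_cca %d, leader %d, trailer %d\n"),
              d[["n_reads"]], d[["mature_body"]], d[["mature_cca"]],
              d[["leader_junction"]], d[["trailer_junction"]]))
  invisible(x)
}

#' Relative expression across tRNAs
#'
#' Summarizes expression as the mean mature-body window count per tRNA, and
#' its ratio to the median across tRNAs (a single tRNA has ratio exactly 1).
#'
#' @param summaries named list of `processing_summary`, one per tRNA, built
#'   with the same configuration
#' @return data.frame: `trna`, `mean_mature_body`, `ratio_to_median`
#' @export
expression_report <- function(summaries) {
  if (!length(summaries)) stop("no summaries given", call. = FALSE)
  means <- vapply(summaries, function(s) {
    pw <- s$per_window
    sel <- pw$label == "mature_body"
    if (!any(sel)) return(0)
    mean(pw$count[sel])
  }, numeric(1))
  med <- stats::median(means)
  data.frame(trna = names(summaries),
             mean_mature_body = unname(means),
             ratio_to_median = unname(if (med > 0) means / med else NA_real_),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Post-transcriptional editing check
#'
#' Compares the genomic gene sequence with an observed mature sequence (CCA
#' excluded on both sides). Identity supports the conclusion that the tRNA is
#' not edited; this is a sequence-equality report, not an alignment.
#'
#' @param genomic genomic gene sequence
#' @param mature observed mature sequence (may carry a terminal CCA, which is
#'   stripped when not genome-encoded)
#' @param cca_encoded is CCA part of the genomic gene
#' @return list: `identical` (logical), `n_diff`, `positions` (1-based
#'   mismatch positions; length difference reported as `length_mismatch`)
#' @export
editing_report <- function(genomic, mature, cca_encoded = FALSE) {
  g <- as_rna(genomic)
  m <- as_rna(mature)
  if (!cca_encoded && endsWith(m, "CCA")) m <- substr(m, 1L, nchar(m) - 3L)
  if (nchar(g) != nchar(m)) {
    return(list(identical = FALSE, n_diff = NA_integer_,
                positions = integer(), length_mismatch = TRUE))
  }
  gb <- strsplit(g, "")[[1]]; mb <- strsplit(m, "")[[1]]
  pos <- which(gb != mb)
  list(identical = length(pos) == 0L, n_diff = length(pos),
       positions = pos, length_mismatch = FALSE)
}
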