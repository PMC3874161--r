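#' Wobble pairing classes at anticodon position 34
#'
#' The decoding capacity of a tRNA is set by the base at anticodon position 34
#' (the first base of the anticodon read 5'-to-3') and its modification state.
#' An unmodified U34 "superwobbles", pairing with any of the four bases at the
#' codon third position; a modified U34 reads only A and G; G34 reads C and U;
#' C34 reads only G; A34 reads only U. Inosine and rarer pairings are not part
#' of the default table.
#'
#' @return data.frame with columns `label`, `base34`, `reads` (list column of
#'   third-codon-position bases).
#' @export
wobble_classes <- function() {
  data.frame(
    label = c("U-unmodified", "U-modified", "G", "C", "A"),
    base34 = c("U", "U", "G", "C", "A"),
    reads = I(list(c("A", "C", "G", "U"), c("A", "G"), c("C", "U"), "G", "U")),
    stringsAsFactors = FALSE
  )
}

#' Codons read by an anticodon under a wobble class
#'
#' The anticodon is given 5'-to-3' (positions 34-35-36). Codon and anticodon
#' pair antiparallel: codon positions 1 and 2 are Watson-Crick matched to
#' anticodon positions 36 and 35, and the codon third position is wobble-matched
#' to position 34 per the class table.
#'
#' @param anticodon 3-mer RNA string, 5'-to-3'
#' @param wobble a class label from [wobble_classes()]
#' @return character vector of codons read
#' @examples
#' anticodon_read_set("UAG", "U-unmodified")  # the whole CUN family
#' anticodon_read_set("GUG", "G")             # the His codons CAU, CAC
#' @export
anticodon_read_set <- function(anticodon, wobble) {
  wc <- wobble_classes()
  row <- wc[wc$label == wobble, ]
  if (nrow(row) != 1L) stop("unknown wobble class: ", wobble, call. = FALSE)
  ac <- strsplit(as_rna(anticodon), "")[[1]]
  if (length(ac) != 3L) stop("anticodon must be a 3-mer", call. = FALSE)
  if (ac[1L] != row$base34) {
    stop("wobble class '", wobble, "' requires base ", row$base34,
         " at anticodon position 34, got ", ac[1L], call. = FALSE)
  }
  p1 <- rna_complement(ac[3L])
  p2 <- rna_complement(ac[2L])
  paste0(p1, p2, row$reads[[1L]])
}

#' All valid anticodon candidates for one codon box
#'
#' A candidate is valid when its read set contains no stop codon and does not
#' mix amino acids under the code.
#' @keywords internal
box_candidates <- function(box_prefix, code, classes) {
  out <- list()
  for (i in seq_len(nrow(classes))) {
    ac <- paste0(classes$base34[i],
                 rna_complement(substr(box_prefix, 2L, 2L)),
                 rna_complement(substr(box_prefix, 1L, 1L)))
    reads <- anticodon_read_set(ac, classes$label[i])
    aas <- unique(unname(code$table[reads]))
    if (length(aas) == 1L && aas != "*") {
      out[[length(out) + 1L]] <- list(anticodon = ac,
                                      class = classes$label[i],
                                      reads = reads)
    }
  }
  out
}

#' Exact minimal anticodon set covering all sense codons
#'
#' Computes the minimum number of distinct anticodons (with wobble-class
#' assignments) sufficient to read every sense codon of a genetic code, under
#' the constraint that no anticodon's read set spans two amino acids or
#' includes a stop. Because codon positions 1-2 fix the box, the 16 four-codon
#' boxes decouple and each box is solved exactly by exhaustive subset search
#' over its valid candidates.
#'
#' With superwobble (unmodified U34) available, codes rich in four-codon
#' families need far fewer than 32 anticodons; the yeast mitochondrial code
#' needs 23.
#'
#' @param code a `genetic_code`
#' @param classes wobble class table, default [wobble_classes()]
#' @return list with `count` (exact minimum), `chosen` (data.frame: anticodon,
#'   class, box, n_read), and `per_box` (named integer of per-box minima).
#' @export
minimal_anticodon_set <- function(code, classes = wobble_classes()) {
  boxes <- unique(substr(rna_codons(), 1L, 2L))
  chosen <- list()
  per_box <- setNames(integer(length(boxes)), boxes)
  for (bx in boxes) {
    codons <- paste0(bx, RNA_BASES)
    targets <- codons[code$table[codons] != "*"]
    if (!length(targets)) next
    cands <- box_candidates(bx, code, classes)
    best <- NULL
    n_c <- length(cands)
    if (n_c > 0L) {
      # exhaustive search over candidate subsets, smallest first
      for (k in seq_len(n_c)) {
        combs <- utils::combn(n_c, k, simplify = FALSE)
        for (idx in combs) {
          covered <- unique(unlist(lapply(cands[idx], `[[`, "reads")))
          if (all(targets %in% covered)) { best <- idx; break }
        }
        if (!is.null(best)) break
      }
    }
    if (is.null(best)) {
      covered <- unique(unlist(lapply(cands, `[[`, "reads")))
      missing <- setdiff(targets, covered)
      stop("sense codon(s) uncoverable under the wobble class table: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    per_box[bx] <- length(best)
    for (i in best) {
      chosen[[length(chosen) + 1L]] <- data.frame(
        anticodon = cands[[i]]$anticodon, class = cands[[i]]$class,
        box = bx, n_read = length(cands[[i]]$reads),
        stringsAsFactors = FALSE)
    }
  }
  chosen <- do.call(rbind, chosen)
  list(count = sum(per_box), chosen = chosen, per_box = per_box)
}
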