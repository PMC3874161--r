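#' Pairing check allowing the G:U wobble pair
#' @keywords internal
bases_pair <- function(a, b, allow_gu = TRUE) {
  wc <- (a == "A" & b == "U") | (a == "U" & b == "A") |
        (a == "G" & b == "C") | (a == "C" & b == "G")
  gu <- (a == "G" & b == "U") | (a == "U" & b == "G")
  wc | (allow_gu & gu)
}

#' Parse a tRNA sequence into numbered landmarks
#'
#' Assigns conventional tRNA landmarks to a sequence: acceptor-stem pairs
#' 1:72 through 7:66 (anchored at the molecule ends), the discriminator base
#' 73 (3' of pair 1:72, 5' of the CCA end), the anticodon-loop span, and the
#' anticodon itself (positions 34-36). The anticodon loop may have 7
#' (canonical), 8 or 9 nucleotides; for an 8-nt loop the triplet following the
#' base inserted on the 31 side is taken as the anticodon, matching how
#' enlarged-loop threonine decoders align against canonical tRNAs.
#'
#' When a dot-bracket structure is supplied, the anticodon loop is the hairpin
#' loop of the structure closest to the sequence centre; otherwise a heuristic
#' scans for the best-supported central hairpin (5-bp stem, at most one
#' non-pairing position, G:U allowed).
#'
#' If the first base does not fit the acceptor stem but the remainder does,
#' it is interpreted as a genomically encoded -1 base (as in histidine tRNAs)
#' and recorded as such.
#'
#' @param seq tRNA sequence, 5'-to-3', DNA or RNA alphabet
#' @param structure optional dot-bracket string, same length as `seq`
#' @param minus_one the base at position -1: a base character when known
#'   present, `"none"` when known absent, `NA` when the input does not say
#' @param cca_3prime logical; `seq` ends with the (encoded or added) CCA,
#'   which is stripped before numbering
#' @param cca_encoded logical; whether a terminal CCA is genome-encoded
#' @param id identifier
#' @return object of class `trna_gene`: list with `id`, `body` (RNA string,
#'   positions 1..L, no -1 base, no CCA), `minus_one`, `cca_encoded`,
#'   `landmarks` (list: `L`, `loop_start`, `loop_len`, `anticodon_idx`,
#'   `stem_score`), and convenience fields `anticodon`, `loop_len`.
#' @export
parse_cloverleaf <- function(seq, structure = NULL, minus_one = NA,
                             cca_3prime = FALSE, cca_encoded = FALSE,
                             id = "tRNA") {
  rna <- as_rna(seq)
  if (!is.null(structure) && nchar(structure) != nchar(rna)) {
    stop("structure length differs from sequence length", call. = FALSE)
  }
  if (cca_3prime) {
    if (!endsWith(rna, "CCA")) {
      stop("cca_3prime = TRUE but sequence does not end in CCA", call. = FALSE)
    }
    rna <- substr(rna, 1L, nchar(rna) - 3L)
    if (!is.null(structure)) structure <- substr(structure, 1L, nchar(rna))
  }
  # a leading base that breaks the acceptor stem while the rest pairs is a
  # genomic -1 base (histidine-type tRNAs)
  sc0 <- acceptor_stem_score(rna)
  sc1 <- acceptor_stem_score(substr(rna, 2L, nchar(rna)))
  if (sc1 > sc0) {
    minus_one <- substr(rna, 1L, 1L)
    rna <- substr(rna, 2L, nchar(rna))
    if (!is.null(structure)) structure <- substr(structure, 2L, nchar(structure))
    stem_score <- sc1
  } else {
    stem_score <- sc0
  }
  L <- nchar(rna)
  if (L < 55L || L > 95L) {
    stop("sequence of ", L, " nt is outside the plausible tRNA body range",
         call. = FALSE)
  }
  if (stem_score < 5L) {
    stop("no viable cloverleaf: acceptor stem pairs only ", stem_score,
         "/7 at either end anchor", call. = FALSE)
  }
  loop <- if (!is.null(structure)) {
    find_loop_structure(structure)
  } else {
    find_loop_heuristic(rna)
  }
  if (is.null(loop)) {
    stop("no viable cloverleaf: no central anticodon hairpin found (id '",
         id, "')", call. = FALSE)
  }
  ac_start <- loop$start + anticodon_offset(loop$len)
  g <- structure(list(
    id = id, body = rna, minus_one = minus_one, cca_encoded = cca_encoded,
    structure = structure,
    landmarks = list(L = L, loop_start = loop$start, loop_len = loop$len,
                     anticodon_idx = ac_start:(ac_start + 2L),
                     stem_score = stem_score)),
    class = "trna_gene")
  g$anticodon <- substr(rna, ac_start, ac_start + 2L)
  g$loop_len <- loop$len
  g
}

# anticodon position within the loop: 3rd base of a 7-nt loop; one later for
# enlarged loops whose extra base sits on the 31 (5') side
anticodon_offset <- function(len) {
  if (len == 7L) 2L else 3L
}

acceptor_stem_score <- function(rna) {
  L <- nchar(rna)
  if (L < 20L) return(0L)
  b <- strsplit(rna, "")[[1]]
  sum(bases_pair(b[1:7], b[L - 1:7]))
}

find_loop_heuristic <- function(rna) {
  # In a cloverleaf the stretch 3' of the anticodon loop is nearly constant:
  # anticodon stem (5) + short variable loop (~5) + T arm (17) + acceptor
  # 3' strand (7) + discriminator (1) ~ 35 nt. The D arm side varies more, so
  # equal-score hairpin candidates are disambiguated by their distance from
  # the 3' end, not the molecule centre. Long-variable-arm tRNAs need a
  # dot-bracket structure instead.
  b <- strsplit(rna, "")[[1]]
  L <- length(b)
  best <- NULL
  for (len in c(7L, 8L, 9L)) {
    for (p in 12L:(L - len - 16L)) {
      i5 <- (p - 5L):(p - 1L)
      i3 <- (p + len + 4L):(p + len)
      score <- sum(bases_pair(b[i5], b[i3]))
      if (score < 4L) next
      dist <- abs((p + len - 1L) - (L - 35L))
      cand <- list(start = p, len = len, score = score, dist = dist)
      if (is.null(best) ||
          score > best$score ||
          (score == best$score && dist < best$dist) ||
          (score == best$score && dist == best$dist && len < best$len)) {
        best <- cand
      }
    }
  }
  best
}

find_loop_structure <- function(structure) {
  ch <- strsplit(structure, "")[[1]]
  if (sum(ch == "(") != sum(ch == ")")) {
    stop("unbalanced dot-bracket structure", call. = FALSE)
  }
  stack <- integer()
  pairs <- list()
  for (i in seq_along(ch)) {
    if (ch[i] == "(") stack <- c(stack, i)
    if (ch[i] == ")") {
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pairs[[length(pairs) + 1L]] <- c(j, i)
    }
  }
  # hairpin loops: paired (i,j) with only dots strictly between
  centre <- (length(ch) + 1) / 2
  best <- NULL
  for (pr in pairs) {
    inner <- if (pr[2] - pr[1] > 1L) ch[(pr[1] + 1L):(pr[2] - 1L)] else character()
    if (length(inner) && all(inner == ".")) {
      len <- length(inner)
      if (len < 3L || len > 11L) next
      dist <- abs((pr[1] + pr[2]) / 2 - centre)
      if (is.null(best) || dist < best$dist) {
        best <- list(start = pr[1] + 1L, len = len, dist = dist)
      }
    }
  }
  best
}

#' @export
print.trna_gene <- function(x, ...) {
  cat(sprintf("<trna_gene> %s: %d nt body, anticodon %s, %d-nt loop, -1 %s\n",
              x$id, x$landmarks$L, x$anticodon, x$loop_len,
              if (is.na(x$minus_one)) "unknown" else x$minus_one))
  invisible(x)
}

canonical_index <- function(g, position) {
  lm <- g$landmarks
  if (position >= 1L && position <= 7L) return(position)
  if (position >= 66L && position <= 72L) return(lm$L - (73L - position))
  if (position == 73L) return(lm$L)
  if (position %in% 34:36) return(lm$anticodon_idx[position - 33L])
  if (position == 31L) {
    # 5' edge of the anticodon loop: the inserted base for enlarged loops,
    # the last 5'-stem base for canonical 7-nt loops
    return(if (lm$loop_len >= 8L) lm$loop_start else lm$loop_start - 1L)
  }
  if (position %in% c(32L, 33L, 37L, 38L)) {
    off <- anticodon_offset(lm$loop_len)
    return(lm$loop_start + off + (position - 34L))
  }
  stop("unsupported landmark position: ", position, call. = FALSE)
}

#' Read identity elements off a parsed tRNA
#'
#' The elements are the handles aminoacyl-tRNA synthetases are known to
#' recognize: the 3:70 acceptor-stem pair (G:U is the alanine signature), the
#' -1 base and its pairing with the discriminator (G-1:C73 is the histidine
#' signature), the discriminator base 73 (A73 for leucine enzymes), the
#' anticodon, and the anticodon-loop length with the identity of the base on
#' its 31 side (an inserted U marks the enlarged threonine-decoder loop).
#'
#' @param g a `trna_gene`
#' @return list: `pair3_70` (e.g. `"G:U"`), `minus1` (base, `"none"`, or `NA`
#'   for unknown), `base73`, `anticodon`, `loop_len`, `loop_ins_U31`
#'   (logical), `minus1_73_pair` (TRUE only when a known -1 base Watson-Crick
#'   pairs the discriminator).
#' @export
extract_identity_elements <- function(g) {
  b3 <- substr(g$body, canonical_index(g, 3L), canonical_index(g, 3L))
  b70 <- substr(g$body, canonical_index(g, 70L), canonical_index(g, 70L))
  b73 <- substr(g$body, canonical_index(g, 73L), canonical_index(g, 73L))
  m1 <- g$minus_one
  pair_flag <- if (is.na(m1) || identical(m1, "none")) FALSE else {
    bases_pair(m1, b73, allow_gu = FALSE)
  }
  first_loop <- substr(g$body, g$landmarks$loop_start, g$landmarks$loop_start)
  list(pair3_70 = paste0(b3, ":", b70),
       minus1 = m1,
       base73 = b73,
       anticodon = g$anticodon,
       loop_len = g$loop_len,
       loop_ins_U31 = (g$loop_len == 8L && first_loop == "U"),
       minus1_73_pair = pair_flag)
}

#' Default synthetase identity rules
#'
#' Rules are data, not code: each row requires one element value for one
#' synthetase, and a synthetase matches when all of its rows hold.
#' \itemize{
#'   \item AlaRS: pair 3:70 is G:U.
#'   \item HisRS: G at -1, discriminator C73, anticodon GUG (the anticodon row
#'     can be dropped to score proposed UCG-anticodon histidine decoders).
#'   \item ThrRS-MST1: 8-nt anticodon loop with an inserted U on the 31 side,
#'     anticodon UAG.
#'   \item LeuRS-candidate: discriminator A73 (the anticodon is not read).
#' }
#' @param relax_his_anticodon drop the HisRS anticodon requirement
#' @return data.frame with columns `synthetase`, `element`, `value`
#' @export
default_identity_rules <- function(relax_his_anticodon = FALSE) {
  df <- data.frame(
    synthetase = c("AlaRS",
                   "HisRS", "HisRS", "HisRS",
                   "ThrRS-MST1", "ThrRS-MST1", "ThrRS-MST1",
                   "LeuRS"),
    element = c("pair3_70",
                "minus1", "base73", "anticodon",
                "loop_len", "loop_ins_U31", "anticodon",
                "base73"),
    value = c("G:U",
              "G", "C", "GUG",
              "8", "TRUE", "UAG",
              "A"),
    stringsAsFactors = FALSE)
  if (relax_his_anticodon) {
    df <- df[!(df$synthetase == "HisRS" & df$element == "anticodon"), ]
  }
  df
}

#' Read an identity-rule table from TSV
#' @param path TSV with columns synthetase, element, value
#' @return data.frame usable by [classify_synthetase()]
#' @export
read_identity_rules <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("synthetase", "element", "value")
  if (!all(need %in% names(df))) {
    stop("rule TSV needs columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  df$value <- as.character(df$value)
  df
}

#' Classify which synthetases would charge a tRNA
#'
#' Evaluates the identity-element rules against the element report of a
#' parsed tRNA. A synthetase matches when every one of its required elements
#' holds; if an element needed by a rule is unknown (for example the -1 base
#' when the input gave no upstream context) the prediction is `UNDETERMINED`
#' rather than no-match. The tRNA is orthogonal when exactly one synthetase
#' matches and none is undetermined.
#'
#' @param g a `trna_gene`
#' @param rules rule table, default [default_identity_rules()]
#' @return object of class `identity_call`: list with `predictions`
#'   (data.frame: synthetase, match, matched_elements, violated_elements) and
#'   `orthogonal` (logical, NA when undetermined predictions exist).
#' @export
classify_synthetase <- function(g, rules = default_identity_rules()) {
  el <- extract_identity_elements(g)
  el_chr <- list(
    pair3_70 = el$pair3_70,
    minus1 = if (is.na(el$minus1)) NA_character_ else as.character(el$minus1),
    base73 = el$base73,
    anticodon = el$anticodon,
    loop_len = as.character(el$loop_len),
    loop_ins_U31 = as.character(el$loop_ins_U31))
  synths <- unique(rules$synthetase)
  preds <- lapply(synths, function(s) {
    rr <- rules[rules$synthetase == s, ]
    got <- unlist(el_chr[rr$element])
    if (length(got) != nrow(rr)) {
      stop("rule references unknown element for ", s, call. = FALSE)
    }
    unknown <- is.na(got)
    ok <- !unknown & got == rr$value
    match <- if (any(unknown) && all(ok | unknown)) "UNDETERMINED"
             else if (all(ok)) "match" else "no-match"
    data.frame(
      synthetase = s, match = match,
      matched_elements = paste(sprintf("%s=%s", rr$element[ok], rr$value[ok]),
                               collapse = ";"),
      violated_elements = paste(
        sprintf("%s=%s(need %s)", rr$element[!ok & !unknown],
                got[!ok & !unknown], rr$value[!ok & !unknown]),
        collapse = ";"),
      stringsAsFactors = FALSE)
  })
  preds <- do.call(rbind, preds)
  n_match <- sum(preds$match == "match")
  orthogonal <- if (any(preds$match == "UNDETERMINED")) NA else n_match == 1L
  structure(list(predictions = preds, orthogonal = orthogonal,
                 elements = el),
            class = "identity_call")
}

#' @export
print.identity_call <- function(x, ...) {
  hits <- x$predictions$synthetase[x$predictions$match == "match"]
  cat(sprintf("<identity_call> matches: %s; orthogonal: %s\n",
              if (length(hits)) paste(hits, collapse = ", ") else "(none)",
              format(x$orthogonal)))
  invisible(x)
}

#' Apply point edits to a tRNA in landmark coordinates
#'
#' Edits are expressed in conventional tRNA numbering (e.g. position 3 for the
#' G3A acceptor-stem change, 31 for insertion or deletion of the extra
#' anticodon-loop base). Edits are applied one at a time, re-parsing between
#' edits so later coordinates refer to the edited molecule, and the final
#' molecule is re-parsed from scratch; an edit that destroys the cloverleaf
#' surfaces as a parse failure.
#'
#' @param g a `trna_gene`
#' @param edits list of edits, each a list with `position` (canonical number),
#'   `op` (`"substitute"`, `"insert"`, `"delete"`), and `base` (for
#'   substitute/insert). An insertion at position p places the base
#'   immediately 3' of p, so inserting at 31 grows the anticodon loop on its
#'   5' side (the InsU31 construct); deleting at 31 on an 8-nt loop removes
#'   that inserted base, the exact inverse.
#' @return a re-parsed `trna_gene`
#' @examples
#' \dontrun{
#' g2 <- apply_mutation(g, list(list(position = 3, op = "substitute", base = "A")))
#' }
#' @export
apply_mutation <- function(g, edits) {
  for (e in edits) {
    if (!all(c("position", "op") %in% names(e))) {
      stop("each edit needs 'position' and 'op'", call. = FALSE)
    }
    idx <- canonical_index(g, as.integer(e$position))
    b <- strsplit(g$body, "")[[1]]
    if (e$op == "substitute") {
      b[idx] <- as_rna(e$base)
    } else if (e$op == "insert") {
      b <- append(b, as_rna(e$base), after = idx)
    } else if (e$op == "delete") {
      b <- b[-idx]
    } else {
      stop("unknown edit op: ", e$op, call. = FALSE)
    }
    g <- parse_cloverleaf(paste(b, collapse = ""), structure = NULL,
                          minus_one = g$minus_one,
                          cca_encoded = g$cca_encoded, id = g$id)
  }
  g
}
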