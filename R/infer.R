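#' Construct an ortholog alignment object
#'
#' Bundles one gene's aligned protein sequences across species with the codon
#' to alignment-column correspondence for the target species.
#'
#' @param gene gene identifier
#' @param aln named character vector of equal-length gapped residue strings;
#'   names are species identifiers
#' @param target species identifier of the target row
#' @param cds optional target CDS (nucleotide string); when given, the column
#'   map is computed and the target row is validated against the translation.
#' @param code genetic code used for validation of non-family positions
#' @param family codon set whose residues are exempt from validation (the
#'   family under assessment; a permissive wildcard)
#' @return object of class `ortholog_alignment`: list with `gene`, `aln`,
#'   `target`, `column_map` (integer vector, 1-based alignment columns, one per
#'   target codon), and `target_codons` (RNA codons of the target CDS).
#' @export
ortholog_alignment <- function(gene, aln, target, cds = NULL,
                               code = genetic_code("standard"),
                               family = character()) {
  if (is.null(names(aln)) || !target %in% names(aln)) {
    stop("alignment rows must be named by species and include the target '",
         target, "'", call. = FALSE)
  }
  if (length(unique(nchar(aln))) != 1L) {
    stop("aligned rows must all have equal length (gene '", gene, "')",
         call. = FALSE)
  }
  column_map <- NULL
  target_codons <- NULL
  if (!is.null(cds)) {
    column_map <- map_codons_to_columns(cds, aln[[target]],
                                        code = code, family = family)
    rna <- as_rna(cds)
    target_codons <- split_codons(rna)
    stops <- names(code$table)[code$table == "*"]
    if (length(target_codons) &&
        target_codons[length(target_codons)] %in% stops) {
      target_codons <- target_codons[-length(target_codons)]
    }
  }
  structure(list(gene = gene, aln = aln, target = target,
                 column_map = column_map, target_codons = target_codons),
            class = "ortholog_alignment")
}

#' @export
print.ortholog_alignment <- function(x, ...) {
  cat(sprintf("<ortholog_alignment> gene %s: %d species x %d columns (target %s)\n",
              x$gene, length(x$aln), nchar(x$aln[[1L]]), x$target))
  invisible(x)
}

#' Map target codons to alignment columns
#'
#' Pairs each codon of the target CDS with the alignment column holding the
#' corresponding residue, skipping gap columns in the target row. The mapping
#' is a strictly increasing bijection between codons and the non-gap columns
#' of the target row.
#'
#' @param cds target coding sequence (terminal stop allowed, trimmed)
#' @param target_row gapped residue string for the target species
#' @param code genetic code used to check that target-row residues equal the
#'   translation at positions outside `family`
#' @param family codons exempt from the residue check (assessed family sites)
#' @return integer vector of 1-based alignment columns, one per codon
#' @examples
#' map_codons_to_columns("AUGAAAUUAUGG", "M-KLW", family = "UUA")
#' @export
map_codons_to_columns <- function(cds, target_row,
                                  code = genetic_code("standard"),
                                  family = character()) {
  rna <- as_rna(cds)
  if (nchar(rna) %% 3L != 0L) {
    stop("CDS length is not a multiple of 3", call. = FALSE)
  }
  codons <- split_codons(rna)
  stops <- names(code$table)[code$table == "*"]
  if (length(codons) && codons[length(codons)] %in% stops) {
    codons <- codons[-length(codons)]
  }
  chars <- strsplit(target_row, "")[[1]]
  cols <- which(chars != "-")
  if (length(cols) != length(codons)) {
    stop("ungapped target row has ", length(cols),
         " residues but the CDS has ", length(codons), " codons",
         call. = FALSE)
  }
  residues <- toupper(chars[cols])
  expected <- unname(code$table[codons])
  exempt <- codons %in% family
  bad <- !exempt & residues != expected
  if (any(bad)) {
    stop("target row residue(s) disagree with translation at codon(s) ",
         paste(utils::head(which(bad), 5L), collapse = ", "),
         " outside the assessed family", call. = FALSE)
  }
  cols
}

#' Residue frequency profile of an alignment column
#'
#' Frequencies are over the non-gap residues of the non-excluded species; the
#' conservation weight is the modal frequency. Columns that are entirely gaps
#' after exclusion yield an empty profile flagged `usable = FALSE`.
#'
#' @param alignment an `ortholog_alignment`
#' @param column 1-based alignment column
#' @param exclude species identifiers to exclude (the target row is always
#'   excluded in family scoring to avoid circularity)
#' @return list with `freq` (named numeric summing to 1, or empty), `weight`
#'   (modal frequency, 0 if empty), `n` (residues used), `usable`
#' @export
column_profile <- function(alignment, column, exclude = character()) {
  rows <- alignment$aln[setdiff(names(alignment$aln), exclude)]
  if (column < 1L || column > nchar(alignment$aln[[1L]])) {
    stop("column ", column, " out of range", call. = FALSE)
  }
  res <- toupper(substr(rows, column, column))
  res <- res[res != "-"]
  if (!length(res)) {
    return(list(freq = numeric(), weight = 0, n = 0L, usable = FALSE))
  }
  tb <- sort(base::table(res), decreasing = TRUE)
  freq <- as.numeric(tb) / sum(tb)
  names(freq) <- names(tb)
  list(freq = freq, weight = freq[[1L]], n = length(res), usable = TRUE)
}

#' Score the amino-acid identity of a codon family from conservation
#'
#' The core reassignment inference: at every target CDS site carrying a codon
#' of the assessed family, the residues of the other species at the aligned
#' column vote for the amino acid the codon encodes. Each site's column
#' profile (target excluded) contributes its residue frequencies, weighted by
#' the column's conservation weight (the modal frequency); sites below
#' `min_weight` are dropped. The support for candidate amino acid a is
#'
#'   support(a) = sum_i w_i f_i(a) / sum_i w_i
#'
#' over passing sites i. The winning amino acid is called when its support
#' exceeds the runner-up by at least `margin`; otherwise the call is
#' `AMBIGUOUS`. If no site passes `min_weight` the result is `NO-SIGNAL`.
#'
#' @param alignments list of `ortholog_alignment` (with column maps)
#' @param family character vector of RNA codons, e.g. `c("CUU","CUC","CUA","CUG")`
#' @param code_for_others genetic code assumed for the non-target species
#'   (only used downstream for comparison; scoring is code-free)
#' @param min_weight minimum column conservation weight for a site to count
#' @param margin minimum lead of the top candidate over the runner-up
#' @param exclude further species to exclude from profiles (e.g. relatives
#'   suspected of sharing the reassignment)
#' @return object of class `reassignment_call`: list with `family`, `n_sites`
#'   (sites passing min_weight), `n_total_sites`, `support` (named numeric in
#'   [0,1]), `call` (amino acid, `"AMBIGUOUS"`, `"NO-SIGNAL"`, or `"ABSENT"`),
#'   and `sites` (data.frame: gene, codon_index, codon, column, weight,
#'   top_residue, top_freq).
#' @export
score_codon_family <- function(alignments, family,
                               code_for_others = genetic_code("standard"),
                               min_weight = 0.5, margin = 0.2,
                               exclude = character()) {
  family <- as_rna(family)
  sites <- list()
  for (al in alignments) {
    if (is.null(al$column_map)) {
      stop("alignment for gene '", al$gene, "' lacks a column map; ",
           "construct it with a target CDS", call. = FALSE)
    }
    hit <- which(al$target_codons %in% family)
    for (i in hit) {
      prof <- column_profile(al, al$column_map[i],
                             exclude = c(al$target, exclude))
      if (!prof$usable) next
      sites[[length(sites) + 1L]] <- list(
        gene = al$gene, codon_index = i, codon = al$target_codons[i],
        column = al$column_map[i], weight = prof$weight, freq = prof$freq)
    }
  }
  if (!length(sites)) {
    return(new_reassignment_call(family, call = "ABSENT"))
  }
  pass <- vapply(sites, function(s) s$weight >= min_weight, logical(1))
  site_df <- do.call(rbind, lapply(sites[pass], function(s) data.frame(
    gene = s$gene, codon_index = s$codon_index, codon = s$codon,
    column = s$column, weight = s$weight,
    top_residue = names(s$freq)[1L], top_freq = s$freq[[1L]],
    stringsAsFactors = FALSE)))
  if (!any(pass)) {
    return(new_reassignment_call(family, call = "NO-SIGNAL",
                                 n_total_sites = length(sites)))
  }
  used <- sites[pass]
  wsum <- sum(vapply(used, `[[`, numeric(1), "weight"))
  support <- numeric()
  for (s in used) {
    for (a in names(s$freq)) {
      support[a] <- (if (is.na(support[a])) 0 else support[a]) +
        s$weight * s$freq[[a]]
    }
  }
  support <- sort(support / wsum, decreasing = TRUE)
  call <- if (length(support) == 1L || support[1L] - support[2L] >= margin) {
    names(support)[1L]
  } else "AMBIGUOUS"
  new_reassignment_call(family, support = support, call = call,
                        n_sites = length(used),
                        n_total_sites = length(sites), sites = site_df)
}

new_reassignment_call <- function(family, support = numeric(),
                                  call = "ABSENT", n_sites = 0L,
                                  n_total_sites = 0L, sites = NULL) {
  structure(list(family = family, n_sites = n_sites,
                 n_total_sites = n_total_sites,
                 support = support, call = call, sites = sites),
            class = "reassignment_call")
}

#' @export
print.reassignment_call <- function(x, ...) {
  cat(sprintf("<reassignment_call> {%s}: call %s (%d sites)\n",
              paste(x$family, collapse = ","), x$call, x$n_sites))
  if (length(x$support)) {
    top <- utils::head(x$support, 3L)
    cat("  support:", paste(sprintf("%s=%.3f", names(top), top),
                            collapse = "  "), "\n")
  }
  invisible(x)
}

#' Genome-wide codon identity sweep
#'
#' Runs [score_codon_family()] for every codon box (four-codon family) and for
#' every individual sense codon. Families with zero usage in the target CDS
#' are reported `ABSENT` — candidates for codon capture.
#'
#' @inheritParams score_codon_family
#' @param singles also produce per-single-codon calls
#' @return list with `families` and (optionally) `codons`, each a named list
#'   of `reassignment_call`, plus `summary`, a data.frame with the family
#'   calls and the amino acid expected under `code_for_others`.
#' @export
call_all_families <- function(alignments,
                              code_for_others = genetic_code("standard"),
                              min_weight = 0.5, margin = 0.2,
                              exclude = character(), singles = FALSE) {
  # families = synonymous codon sets within a box: a full four-codon family
  # (e.g. CUN) or the two-codon halves of a split box (e.g. CAU/CAC vs CAA/CAG)
  boxes <- unique(substr(rna_codons(), 1L, 2L))
  fam_sets <- list()
  for (bx in boxes) {
    codons <- paste0(bx, RNA_BASES)
    codons <- codons[code_for_others$table[codons] != "*"]
    if (!length(codons)) next
    for (aa in unique(unname(code_for_others$table[codons]))) {
      fam <- codons[code_for_others$table[codons] == aa]
      nm <- if (length(fam) == 4L) paste0(bx, "N") else
        paste(fam, collapse = "/")
      fam_sets[[nm]] <- fam
    }
  }
  fams <- lapply(fam_sets, function(fam) {
    score_codon_family(alignments, fam, code_for_others,
                       min_weight = min_weight, margin = margin,
                       exclude = exclude)
  })
  summary <- do.call(rbind, lapply(names(fams), function(nm) {
    x <- fams[[nm]]
    expected <- unique(unname(code_for_others$table[x$family]))
    data.frame(family = nm, call = x$call, n_sites = x$n_sites,
               expected = paste(expected, collapse = ","),
               matches_code = x$call %in% expected,
               non_standard = !(x$call %in% c(expected, "AMBIGUOUS",
                                              "NO-SIGNAL", "ABSENT")),
               stringsAsFactors = FALSE)
  }))
  out <- list(families = fams, summary = summary)
  if (singles) {
    sng <- lapply(sense_codons(code_for_others), function(cd) {
      score_codon_family(alignments, cd, code_for_others,
                         min_weight = min_weight, margin = margin,
                         exclude = exclude)
    })
    names(sng) <- sense_codons(code_for_others)
    out$codons <- sng
  }
  out
}

#' Read one gene's aligned FASTA plus target CDS into an ortholog alignment
#'
#' @param aln_path aligned FASTA of protein sequences (ids are species)
#' @param gene gene id
#' @param target target species id
#' @param cds target CDS string (or NULL to skip the column map)
#' @param code,family passed to [ortholog_alignment()]
#' @return an `ortholog_alignment`
#' @export
read_ortholog_alignment <- function(aln_path, gene, target, cds = NULL,
                                    code = genetic_code("standard"),
                                    family = character()) {
  ss <- Biostrings::readAAStringSet(aln_path)
  nm <- sub("\\s.*$", "", names(ss))
  ortholog_alignment(gene, setNames(as.character(ss), nm), target,
                     cds = cds, code = code, family = family)
}
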