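#' Ground-truth parameter set for the synthetic-data generator
#'
#' Bundles every parameter the generator needs, with three shipped presets:
#' \describe{
#'   \item{ashbya-like}{10 species, 8 genes; the CUA/CUU family is planted as
#'     Ala at 81 conserved sites (49 CUA, 32 CUU, mirroring the published
#'     mitochondrial usage), the target CDS is back-translated under the
#'     Ashbya mitochondrial code with a strong third-position A/U bias
#'     (0.9) and a 24-codon avoided set (C/G third positions, including CUC
#'     and CUG).}
#'   \item{klactis-like}{as above but the CUN family is entirely absent from
#'     the target genome and nothing is planted (codon-capture donor state).}
#'   \item{standard-null}{a genome generated under the standard code with no
#'     reassignment and no avoided codons; every family call should match the
#'     code.}
#' }
#'
#' @param preset preset name
#' @param seed integer seed; regenerating with the same truth reproduces
#'   identical outputs
#' @param ... overrides for individual fields
#' @return list of class `synthetic_truth`
#' @export
synthetic_truth <- function(preset = c("ashbya-like", "klactis-like",
                                       "standard-null"),
                            seed = 1L, ...) {
  preset <- match.arg(preset)
  base <- list(
    preset = preset,
    seed = as.integer(seed),
    species = c("target_sp", paste0("sp", sprintf("%02d", 1:9))),
    target = "target_sp",
    n_genes = 8L,
    gene_length = 250L,
    class_probs = c(invariant = 0.40, conserved = 0.35, variable = 0.25),
    sub_prob = c(invariant = 0, conserved = 0.05, variable = 0.5),
    family = c("CUA", "CUU"),
    planted_aa = "A",
    planted_counts = c(CUA = 49L, CUU = 32L),
    third_AU_prob = 0.9,
    avoided = avoided_codons_24(),
    code = "ashbya-mito",
    trna = list(pair3_70 = "G:U", anticodon = "UAG", loop_len = 7L,
                minus_one = "none", disc = "G", cca_encoded = FALSE),
    reads = list(depth_precursor = 50L, depth_mature = 100L,
                 read_len = c(25L, 45L), error_rate = 0, flank = 30L),
    kinetics = list(kcat = 2.1, Km = 0.53, enzyme = 1,
                    substrate = c(0.1, 0.25, 0.5, 1, 2, 5, 10, 20),
                    noise_frac = 0)
  )
  if (preset == "klactis-like") {
    base$family <- character()
    base$planted_counts <- integer()
    base$avoided <- unique(c(base$avoided, c("CUU", "CUC", "CUA", "CUG")))
    base$code <- "yeast-mito"
  }
  if (preset == "standard-null") {
    base$family <- character()
    base$planted_counts <- integer()
    base$avoided <- character()
    base$third_AU_prob <- 0.7
    base$code <- "standard"
  }
  over <- list(...)
  for (nm in names(over)) base[[nm]] <- over[[nm]]
  structure(base, class = "synthetic_truth")
}

# 24 sense codons, all with C or G in the third position, that the biased
# target genome never uses: the liberated-codon pattern of an extreme A+T-rich
# mitochondrial genome
avoided_codons_24 <- function() {
  c("CUC", "CUG",
    "GCC", "GCG", "CCC", "CCG", "ACC", "ACG", "GUC", "GUG",
    "UCC", "UCG", "CGC", "CGG", "GGC", "GGG",
    "UUC", "CAC", "AAC", "GAC", "UAC", "UGC", "AUC", "AGC")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("<synthetic_truth> preset %s (seed %d): %d genes x %d aa, %d species\n",
              x$preset, x$seed, x$n_genes, x$gene_length, length(x$species)))
  invisible(x)
}

sample_aa <- function(n) sample(AA_ONE, n, replace = TRUE)

#' Simulate an ortholog family set with a planted codon reassignment
#'
#' Draws one ancestral protein per gene, assigns each site a conservation
#' class (invariant / conserved / variable), and derives each species' row by
#' independent class-rate substitution from the ancestor (a star phylogeny:
#' the inference deliberately ignores tree structure, so simulating one adds
#' nothing testable). The target CDS is back-translated from the target row
#' under the truth's code with a third-position A/U bias and the avoided
#' codons never emitted; at the planted sites (invariant columns forced to the
#' planted amino acid) the target emits the planted family codons at exactly
#' the planted counts. Family codons are never emitted elsewhere, so the
#' planted counts are exact by construction.
#'
#' @param truth a [synthetic_truth()]
#' @return list with `alignments` (per gene, named character vector of
#'   residue rows), `cds` (named character vector, DNA alphabet, terminal UAA
#'   stop), `planted_sites` (data.frame: gene, codon_index, codon), `truth`
#' @export
simulate_ortholog_set <- function(truth) {
  set.seed(truth$seed)
  code <- genetic_code(truth$code)
  if (length(truth$species) < 4L || truth$n_genes < 1L) {
    stop("need at least 4 species and 1 gene", call. = FALSE)
  }
  genes <- paste0("gene", seq_len(truth$n_genes))
  n_sites <- truth$gene_length
  classes_all <- list(); anc_all <- list()
  for (g in genes) {
    anc_all[[g]] <- sample_aa(n_sites)
    classes_all[[g]] <- sample(names(truth$class_probs), n_sites,
                               replace = TRUE, prob = truth$class_probs)
  }
  # plant the reassigned-family sites on invariant columns
  planted <- NULL
  n_plant <- sum(truth$planted_counts)
  if (n_plant > 0L) {
    pool <- do.call(rbind, lapply(genes, function(g) {
      data.frame(gene = g, site = which(classes_all[[g]] == "invariant"),
                 stringsAsFactors = FALSE)
    }))
    if (nrow(pool) < n_plant) {
      stop("infeasible truth: only ", nrow(pool),
           " invariant sites for ", n_plant, " planted codons", call. = FALSE)
    }
    pick <- pool[sample(nrow(pool), n_plant), ]
    codon_draw <- sample(rep(names(truth$planted_counts),
                             truth$planted_counts))
    pick$codon <- codon_draw
    planted <- pick[order(pick$gene, pick$site), ]
    for (g in genes) {
      anc_all[[g]][planted$site[planted$gene == g]] <- truth$planted_aa
    }
  }
  alignments <- list(); cds <- character()
  planted_out <- list()
  for (g in genes) {
    anc <- anc_all[[g]]
    cls <- classes_all[[g]]
    rows <- vapply(truth$species, function(sp) {
      p <- truth$sub_prob[cls]
      mut <- stats::runif(n_sites) < p
      res <- anc
      if (any(mut)) {
        res[mut] <- vapply(res[mut], function(a) {
          sample(setdiff(AA_ONE, a), 1L)
        }, character(1))
      }
      paste(res, collapse = "")
    }, character(1))
    target_res <- strsplit(rows[[truth$target]], "")[[1]]
    p_sites <- if (is.null(planted)) integer() else
      planted$site[planted$gene == g]
    p_codons <- if (is.null(planted)) character() else
      planted$codon[planted$gene == g]
    # planted sites sit on invariant columns, so the target row still holds
    # the planted amino acid there
    codons <- back_translate(target_res, code, truth$family, truth$avoided,
                             truth$third_AU_prob)
    codons[p_sites] <- p_codons
    cds[[g]] <- gsub("U", "T", paste(c(codons, "UAA"), collapse = ""),
                     fixed = TRUE)
    alignments[[g]] <- rows
    if (length(p_sites)) {
      planted_out[[g]] <- data.frame(gene = g, codon_index = p_sites,
                                     codon = p_codons,
                                     stringsAsFactors = FALSE)
    }
  }
  planted_sites <- if (length(planted_out)) do.call(rbind, planted_out) else
    data.frame(gene = character(), codon_index = integer(),
               codon = character(), stringsAsFactors = FALSE)
  rownames(planted_sites) <- NULL
  list(alignments = alignments, cds = cds, planted_sites = planted_sites,
       truth = truth)
}

# biased synonymous codon choice, never emitting avoided or family codons
back_translate <- function(residues, code, family, avoided, third_AU_prob) {
  tb <- code$table
  choices <- lapply(AA_ONE, function(a) {
    cods <- names(tb)[tb == a]
    cods <- setdiff(cods, c(avoided, family))
    if (!length(cods)) {
      stop("amino acid ", a, " has no allowed codon under the truth",
           call. = FALSE)
    }
    split(cods, substr(cods, 3L, 3L) %in% c("A", "U"))
  })
  names(choices) <- AA_ONE
  vapply(residues, function(a) {
    ch <- choices[[a]]
    au <- ch[["TRUE"]]; cg <- ch[["FALSE"]]
    grp <- if (is.null(au)) cg
           else if (is.null(cg)) au
           else if (stats::runif(1) < third_AU_prob) au else cg
    if (length(grp) == 1L) grp else sample(grp, 1L)
  }, character(1), USE.NAMES = FALSE)
}

#' Ortholog alignments from a simulation, ready for inference
#'
#' @param sim output of [simulate_ortholog_set()]
#' @param family codons exempt from residue validation (defaults to the
#'   truth's planted family)
#' @param code code used for validation (defaults to the truth's code)
#' @return list of `ortholog_alignment`
#' @export
as_ortholog_alignments <- function(sim, family = sim$truth$family,
                                   code = genetic_code(sim$truth$code)) {
  lapply(names(sim$alignments), function(g) {
    ortholog_alignment(g, sim$alignments[[g]], sim$truth$target,
                       cds = sim$cds[[g]], code = code, family = family)
  })
}

#' Build a synthetic tRNA with chosen identity elements
#'
#' Assembles a canonical cloverleaf (7-bp acceptor stem, D arm, anticodon arm,
#' variable loop, T arm, discriminator; 73-nt body for a 7-nt anticodon loop)
#' with the requested identity elements, plus the matching dot-bracket
#' structure. All stems are Watson-Crick complementary except the 3:70 pair,
#' which is set exactly as requested (G:U included).
#'
#' @param spec list with `pair3_70` (e.g. `"G:U"`), `anticodon`, `loop_len`
#'   (7 or 8; 8 inserts a U on the 31 side), `minus_one` (base or `"none"`),
#'   `disc` (discriminator base), `cca_encoded`
#' @param seed seed for the random stem/loop fill
#' @return list: `body` (RNA, no -1/CCA), `seq` (full sequence as a gene
#'   would be annotated: -1 base if any, body, CCA if encoded), `structure`
#'   (dot-bracket for `body`), `spec`
#' @export
build_synthetic_trna <- function(spec, seed = 1L) {
  set.seed(seed)
  rb <- function(n) sample(RNA_BASES, n, replace = TRUE)
  pair <- strsplit(spec$pair3_70, ":")[[1]]
  acc5 <- rb(7L); acc5[3L] <- pair[1L]
  acc3 <- rev(rna_complement(acc5))          # positions 66..72
  acc3[5L] <- pair[2L]                        # position 70 pairs position 3
  dstem <- rb(4L); dloop <- rb(8L)
  acstem <- rb(5L)
  loop7 <- c("C", "U", strsplit(as_rna(spec$anticodon), "")[[1]], "A", "A")
  acloop <- if (spec$loop_len == 8L) c("U", loop7) else loop7
  varloop <- rb(5L)
  tstem <- rb(5L); tloop <- c("U", "U", "C", "G", "A", "A", "U")
  body <- c(acc5, c("U", "A"),
            dstem, dloop, rev(rna_complement(dstem)), "A",
            acstem, acloop, rev(rna_complement(acstem)),
            varloop,
            tstem, tloop, rev(rna_complement(tstem)),
            acc3, spec$disc)
  db <- c(rep("(", 7L), "..",
          rep("(", 4L), rep(".", 8L), rep(")", 4L), ".",
          rep("(", 5L), rep(".", length(acloop)), rep(")", 5L),
          rep(".", 5L),
          rep("(", 5L), rep(".", 7L), rep(")", 5L),
          rep(")", 7L), ".")
  body_str <- paste(body, collapse = "")
  seq <- body_str
  if (!identical(spec$minus_one, "none") && !is.na(spec$minus_one)) {
    seq <- paste0(spec$minus_one, seq)
  }
  if (isTRUE(spec$cca_encoded)) seq <- paste0(seq, "CCA")
  list(body = body_str, seq = seq,
       structure = paste(db, collapse = ""), spec = spec)
}

#' Simulate a tRNA gene with flanks and small-RNA reads over its forms
#'
#' Builds the truth's tRNA, embeds it in random genomic flanks, and samples
#' reads from the unprocessed precursor and the mature (CCA-added) form at
#' the configured depths, with an optional uniform substitution error rate.
#' Read start and length are uniform within the form.
#'
#' @param truth a [synthetic_truth()]
#' @return list: `trna` (from [build_synthetic_trna()]), `flanked` (DNA
#'   alphabet genomic sequence), `gene_start`, `gene_end` (0-based half-open),
#'   `reads_precursor`, `reads_mature` (character vectors, DNA alphabet),
#'   `mature` (RNA), `truth`
#' @export
simulate_trna_and_reads <- function(truth) {
  set.seed(truth$seed + 1L)
  tr <- build_synthetic_trna(truth$trna, seed = truth$seed)
  fl <- truth$reads$flank
  flank5 <- paste(sample(RNA_BASES, fl, replace = TRUE), collapse = "")
  flank3 <- paste(sample(RNA_BASES, fl, replace = TRUE), collapse = "")
  if (!isTRUE(truth$trna$cca_encoded)) {
    # cca_encoded = FALSE means the genome does not continue the gene with
    # CCA; a trailer starting with C would blur that truth, so redraw its
    # first base
    substr(flank3, 1L, 1L) <- sample(c("A", "G", "U"), 1L)
  }
  gene <- tr$seq                       # genomic gene incl -1/CCA if encoded
  flanked <- paste0(flank5, gene, flank3)
  gene_start <- fl
  gene_end <- fl + nchar(gene)
  mature <- if (isTRUE(truth$trna$cca_encoded)) gene else paste0(gene, "CCA")
  sample_reads <- function(form, depth) {
    if (depth == 0L) return(character())
    n <- nchar(form)
    lens <- sample(seq(truth$reads$read_len[1L], truth$reads$read_len[2L]),
                   depth, replace = TRUE)
    lens <- pmin(lens, n)
    starts <- vapply(lens, function(l) sample(n - l + 1L, 1L), integer(1))
    reads <- substring(form, starts, starts + lens - 1L)
    if (truth$reads$error_rate > 0) {
      reads <- vapply(reads, function(r) {
        b <- strsplit(r, "")[[1]]
        err <- stats::runif(length(b)) < truth$reads$error_rate
        if (any(err)) {
          b[err] <- vapply(b[err], function(x) sample(setdiff(RNA_BASES, x), 1L),
                           character(1))
        }
        paste(b, collapse = "")
      }, character(1), USE.NAMES = FALSE)
    }
    reads
  }
  list(trna = tr,
       flanked = gsub("U", "T", flanked, fixed = TRUE),
       gene_start = gene_start, gene_end = gene_end,
       reads_precursor = gsub("U", "T",
         sample_reads(flanked, truth$reads$depth_precursor), fixed = TRUE),
       reads_mature = gsub("U", "T",
         sample_reads(mature, truth$reads$depth_mature), fixed = TRUE),
       mature = mature, truth = truth)
}

#' Simulate a Michaelis-Menten velocity table
#'
#' Velocities follow v = kcat * E * S / (Km + S) with optional multiplicative
#' Gaussian noise (fraction of the true velocity), truncated at zero.
#'
#' @param kcat,Km,enzyme kinetic parameters
#' @param substrate substrate concentrations (uM)
#' @param noise_frac relative noise standard deviation (0 = noiseless)
#' @param seed seed
#' @return data.frame: `substrate`, `velocity`
#' @export
simulate_kinetics <- function(kcat, Km, enzyme = 1,
                              substrate = c(0.1, 0.25, 0.5, 1, 2, 5, 10, 20),
                              noise_frac = 0, seed = 1L) {
  if (kcat <= 0 || Km <= 0) stop("kcat and Km must be positive", call. = FALSE)
  set.seed(seed)
  v <- kcat * enzyme * substrate / (Km + substrate)
  if (noise_frac > 0) {
    v <- pmax(0, v * (1 + stats::rnorm(length(v), sd = noise_frac)))
  }
  data.frame(substrate = substrate, velocity = v)
}

#' Write a full simulation to a directory tree
#'
#' Emits `alignments/<gene>.fasta` (aligned proteins), `cds.fasta`,
#' `trna/trna.fasta` with a `trna/trna.dot` sidecar and a BED-like
#' `trna/gene.bed` (0-based half-open gene coordinates in the flanked
#' sequence), `reads.fastq`, `kinetics.tsv`, and `truth.json`.
#'
#' @param truth a [synthetic_truth()]
#' @param dir output directory (created)
#' @return `dir`, invisibly
#' @export
write_simulation <- function(truth, dir) {
  dir.create(file.path(dir, "alignments"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(dir, "trna"), showWarnings = FALSE)
  sim <- simulate_ortholog_set(truth)
  for (g in names(sim$alignments)) {
    writeLines(as_fasta(sim$alignments[[g]]),
               file.path(dir, "alignments", paste0(g, ".fasta")))
  }
  writeLines(as_fasta(sim$cds), file.path(dir, "cds.fasta"))
  tr <- simulate_trna_and_reads(truth)
  writeLines(as_fasta(c(trna = gsub("U", "T", tr$trna$seq, fixed = TRUE))),
             file.path(dir, "trna", "trna.fasta"))
  writeLines(tr$trna$structure, file.path(dir, "trna", "trna.dot"))
  writeLines(sprintf("flanked\t%d\t%d\ttrna\t0\t+", tr$gene_start, tr$gene_end),
             file.path(dir, "trna", "gene.bed"))
  reads <- c(tr$reads_precursor, tr$reads_mature)
  fq <- unlist(lapply(seq_along(reads), function(i) {
    c(sprintf("@read%04d", i), reads[i], "+",
      strrep("I", nchar(reads[i])))
  }))
  writeLines(fq, file.path(dir, "reads.fastq"))
  kin <- simulate_kinetics(truth$kinetics$kcat, truth$kinetics$Km,
                           truth$kinetics$enzyme, truth$kinetics$substrate,
                           truth$kinetics$noise_frac, seed = truth$seed)
  utils::write.table(kin, file.path(dir, "kinetics.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  tj <- truth
  class(tj) <- NULL
  jsonlite::write_json(tj, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

as_fasta <- function(x) {
  as.vector(rbind(paste0(">", names(x)), unname(x)))
}
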