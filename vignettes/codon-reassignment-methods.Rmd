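---
title: "Methods: detecting and validating mitochondrial codon reassignment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting and validating mitochondrial codon reassignment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitocodon)
```

# The problem

Mitochondrial genomes are small, A+T-rich and strongly codon-biased, which
makes them the natural habitat of genetic-code change. A codon family that
falls out of use ("liberation") can later be recaptured by a tRNA whose
charging identity has switched — in yeast mitochondria the CUN family moved
from Leu to Thr and, in *Ashbya*-type lineages, on to Ala. Establishing such
an event computationally requires several independent lines of evidence:
codon usage showing the family is rare or biased, alignment conservation
showing what amino acid the family's sites actually hold in other species,
a tRNA whose identity elements select the right synthetase, reads showing
that tRNA is transcribed and matured, and peptide evidence at the protein
level. `mitocodon` implements each line as a small, separately testable
module; this vignette records the models, parameter choices and numerical
decisions behind them.

# Genetic codes and wobble

Codes are explicit 64-entry tables in the RNA alphabet (DNA input is
transcribed internally; all reporting is RNA, matching how codons are
conventionally printed). Four built-ins are shipped; the `ashbya-mito`
table assigns the whole CUN family to Ala while flagging CUC and CUG as
`avoided`: a single unmodified-U34 anticodon would superwobble-read all
four codons, so the table encodes the superwobble *prediction* for the two
codons the genome never uses. Whether CUC/CUG would really be translated
Ala in vivo is unknowable from sequence data; the `avoided` set keeps that
distinction explicit rather than silently asserting either answer.

The wobble model is deliberately minimal: unmodified U34 reads A/C/G/U,
modified U34 reads A/G, G34 reads C/U, C34 reads G, A34 reads U. Inosine
and rarer pairings are omitted because they play no role in the organellar
decoding argument; they would be configuration, not defaults. One
consequence is worth knowing: under this table the *standard* code is not
coverable — AUA (Ile) has no valid anticodon, since reading it without a
modified C34/inosine tRNA would corecruit AUG (Met). `minimal_anticodon_set`
reports that codon explicitly instead of guessing. The minimal-set
computation itself is exact: codon positions 1–2 fix the box, so the 16
four-codon boxes decouple and each is solved by exhaustive subset search
over its at-most-five valid anticodon candidates.

# The reassignment score

The inference that a codon family encodes amino acid *a* rests on
conservation: at columns where all other species agree, the target's codon
must encode the agreed residue. The package turns this reading-by-eye
argument into a statistic. For family sites *i* with column profiles
$f_i(\cdot)$ (residue frequencies over non-gap rows, target species
excluded) and conservation weights $w_i = \max_a f_i(a)$,

$$\mathrm{support}(a) = \frac{\sum_{i:\,w_i \ge w_{\min}} w_i f_i(a)}
                             {\sum_{i:\,w_i \ge w_{\min}} w_i}.$$

Support values are convex combinations of column frequencies, hence lie in
[0, 1] and sum to 1 over residues. The winner is called only when it leads
the runner-up by at least `margin`; otherwise `AMBIGUOUS`. Degenerate
situations have explicit non-call results: a family with no usage is
`ABSENT` (the codon-capture donor state), and sites that all fail
$w_{\min}$ give `NO-SIGNAL`.

Defaults: `min_weight = 0.5` (a column whose modal residue is in the
minority carries no usable signal), `margin = 0.2` (a call needs a clear
plurality, not a coin flip). Both are declared choices — no quantitative
threshold exists to inherit — and both are arguments. The target species is
always excluded from its own profiles to avoid circularity, and an
`exclude` argument removes relatives suspected of sharing the reassignment
(the reason the Thr-decoding Saccharomycetaceae would otherwise vote
"T" on each other). Similarity credit across biochemically related residues
is deliberately off: the argument is about identity-level conservation, and
a substitution-class table would add a free parameter with no calibration
data. No multiple-testing correction is applied because the scores are
descriptive with an ambiguity margin, not p-values.

The genome-wide sweep (`call_all_families`) scores synonymous codon sets
within each box — the full family for a four-codon box, the two halves of a
split box — because a "family call" on a split box would mix two amino
acids by construction. Per-single-codon calls are also available, since in
practice only part of a family may carry protein-level confirmation.

# tRNA landmarks and identity rules

`parse_cloverleaf` numbers a tRNA by the conventional landmarks the
identity literature uses (acceptor pairs 1:72…7:66, anticodon 34–36,
discriminator 73, the −1 base). The acceptor stem is anchored at the
molecule's two ends; a first base that breaks the stem while the remainder
pairs is interpreted as a genomically encoded −1 base, which is how
histidine-type tRNAs arrive in plain FASTA. Without a dot-bracket
structure, the anticodon hairpin is found heuristically: a 5-bp stem
(at most one non-pairing position, G:U allowed) enclosing a 7–9-nt loop.
Equal-scoring candidates are disambiguated by distance from the 3′ end
rather than the molecule centre, because the 3′ side of the anticodon loop
(anticodon stem + short variable loop + T arm + acceptor strand +
discriminator ≈ 35 nt) is far more constant than the D-arm side. This
assumes a short variable arm; class-II-like long-variable-arm tRNAs should
be supplied with a dot-bracket sidecar, which takes precedence. A sequence
with no viable cloverleaf is a parse error with diagnostics, never a
best-effort guess.

Loop numbering follows the mutation vocabulary of the field: position 31
denotes the 5′ edge of the anticodon loop — the inserted base itself when
the loop has 8 nt, the last 5′-stem base for a canonical loop. An insertion
at 31 therefore grows the loop on its 5′ side (the InsU31 construct) and a
deletion at 31 removes exactly that base; the two operations are inverses,
which the tests exercise on the element report. For 8-nt loops the
anticodon is the triplet *after* the inserted base, matching how
enlarged-loop threonine decoders align against canonical tRNAs.

Identity rules are data (a three-column table, also shipped as TSV), not
code: AlaRS ⇔ 3:70 is G:U; HisRS ⇔ G−1 ∧ C73 ∧ anticodon GUG; ThrRS-MST1 ⇔
8-nt loop with inserted U on the 31 side ∧ anticodon UAG; LeuRS candidate ⇔
A73. The HisRS anticodon row can be dropped
(`default_identity_rules(relax_his_anticodon = TRUE)`) to score proposed
UCG-anticodon histidine decoders, which match every HisRS element except
the anticodon. G:U counts as a pair for stem purposes throughout — the
wobble pair *is* the alanine identity element. A synthetase whose known
elements already violate a rule is a plain no-match even if another element
is unknown; `UNDETERMINED` is reserved for the case where the unknown
element is decisive (e.g. a C73/GUG body whose upstream context was never
provided). Orthogonality is `TRUE` when exactly one synthetase matches,
and `NA` while any prediction is undetermined.

# The 15-mer processing scan

The read scan formalizes a deliberately primitive published procedure:
count reads containing each 15-mer exactly (grep semantics — one count per
read per window, no mismatches). Windows are labeled by what finding them
proves: junction windows spanning the flank/gene boundaries are
precursor-only; windows inside the gene body occur in precursor and mature
forms alike and measure expression; windows spanning the gene 3′ end into
the appended CCA prove maturation. The operational distinction between
"intermediate" and "mature" was never defined in the original procedure;
this labeling is one explicit formalization. Two subtleties are handled
conservatively: when the CCA is genome-encoded there is no CCA-specific
signal and no such windows are emitted; and a candidate CCA window whose
sequence happens to occur in the genomic precursor (a trailer starting
with C can reproduce a 1–2-nt CCA overlap) is dropped as non-specific
rather than miscounted. Editing status is a sequence-equality report
between genomic gene and observed mature sequence, not an alignment — the
claim it supports is exact identity.

# Variant proteomes and peptide matching

The mass-spec module reproduces the three-database strategy at peptide
level: build proteomes in which every family codon is read as each
candidate amino acid, digest with trypsin (cleave after K/R, not before P;
missed cleavages appended up to a limit), and match observations either by
exact sequence or by monoisotopic mass within a ppm tolerance (default
10 ppm, the modern LC-MS/MS convention; the source protocol states none).
Carbamidomethyl-Cys (+57.02146 Da) is a fixed modification by default,
matching standard alkylation. A verdict is per variant *site*: the set of
variants whose discriminating peptide covering that site was matched.
Observations matching only non-discriminating peptides constrain nothing,
and verdicts are independent of observation order. Spectral scoring, FDR
and PTM search are out of scope — the scientific conclusion rests on which
variant's peptide is identified, which peptide-level matching captures.

# Kinetics

`fit_michaelis_menten` is a Levenberg–Marquardt least-squares fit of
$v = k_{cat} E S / (K_m + S)$ with non-negativity bounds and standard
errors from the fit curvature. The enzyme concentration must be supplied —
it is not derivable from a velocity table — and with the default $E = 1$
the fitted "$k_{cat}$" is $V_{max}$. Velocities may also be derived from
product-vs-time courses as early-window linear slopes (window size
configurable, default 3 points). Relative efficiency is
$100 (k_{cat}/K_m)/(k_{cat}/K_m)_{ref}$ rounded to the nearest integer, as
efficiency tables display it, and accepts bare ratios so that published
ratio columns can be used directly; published kinetic tables often carry a
per-replicate-averaged ratio column that does not equal the quotient of
the printed constants, and the two should not be silently mixed.

# What the generator emulates — and what it does not

`synthetic_truth` fixes the study conditions: 10 species diverging
independently from a common ancestor (a star phylogeny — the inference
ignores tree structure, so simulating one would add nothing testable),
8 genes of 250 residues, per-site conservation classes (invariant 40%,
conserved 35% at substitution probability 0.05, variable 25% at 0.5), a
planted CUA/CUU→Ala reassignment at 81 invariant sites (49 CUA + 32 CUU,
mirroring the published mitochondrial usage), third-position A/U
probability 0.9, and a 24-codon avoided set on C/G third positions
(including CUC/CUG). Family codons are emitted only at planted sites, so
the planted counts are exact by construction. The tRNA is a canonical
73-nt cloverleaf with the requested identity elements; its discriminator
base is a synthetic choice (G), as the real Ashbya discriminator is not
printed anywhere and fixtures must not assert it. Reads are uniform
substrings (25–45 nt) of the precursor and mature(+CCA) forms, with the
trailer drawn so it does not begin with C — otherwise the genome would
contradict the truth's `cca_encoded = FALSE`. Everything is deterministic
under the seed.

What real data adds that the generator does not: alignment gaps and
alignment error, phylogenetic correlation between species (which inflates
apparent support), heterogeneous gene lengths and compositions, modified
nucleosides, sequencing-depth structure along the tRNA, and chimeric or
adapter-contaminated reads. Passing the recovery tests therefore shows the
statistics are implemented correctly and behave as designed under their
own model, not that the defaults are optimal for any particular real
genome.

Test and driver problem sizes (8×250-residue genes, 10 species, 50
recovery replicates, read depths of 50–300, 200 random tRNAs) were chosen
as the smallest sets at which the binomial checks have power; they run in
seconds.

# Known limitations

* The anticodon-loop heuristic assumes a short variable arm; long-arm
  tRNAs need the structure sidecar.
* Identity rules are the minimal published set and intentionally
  provisional; they classify the four synthetases relevant to the CUN
  story, not the full synthetase complement.
* The scan has no mismatch tolerance by design; sequencing error shifts
  counts down uniformly rather than being modeled.
* `minimal_anticodon_set` is exact only because boxes decouple under the
  fixed wobble table; adding cross-box pairing rules would require a
  global set cover.
* Codon-usage inputs must be clean CDS: internal stops are rejected, not
  skipped, because they usually mean the wrong code or frame — the
  pipeline's first hint that a genome deviates from its assumed code.
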