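---
title: "Annotating and typing the lacertid mitochondrial control region"
author: "mitoCR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating and typing the lacertid mitochondrial control region}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoCR)
```

## The problem

The vertebrate mitochondrial control region (CR) is the long non-coding
segment between tRNA-Pro and tRNA-Phe. It carries short conserved signals —
two termination-associated sequences (TAS1, TAS2) near its 5' end and three
conserved sequence blocks (CSB1, CSB2, CSB3) near its 3' end — interspersed
with rapidly evolving spacers and tandem-repeat (TR) arrays. In lacertid
lizards these elements are conventionally located by comparison against the
*Lacerta dugesii* reference motifs, and whole CR architectures can be
grouped into a small number of types by which elements are present and
where the repeat arrays sit. `mitoCR` implements this comparative workflow
end to end: GenBank/FASTA input, CR extraction, element and repeat
annotation, variant typing against shipped reference tables, architecture
classification, and the accessory comparative statistics (composition
skews, codon usage, p-distance, NG86 dN/dS).

## Element annotation

Element search is substitution-only fuzzy matching of the *L. dugesii*
reference motifs (all tabulated variants are length-preserving, so indels
are deliberately excluded). The per-element mismatch budgets default to a
quarter of the motif length, rounded down:

```{r}
defaultMaxMismatches()
```

These budgets cover every variant in the shipped tables except the single
most divergent CSB3 row, which needs an explicit override and is otherwise
reported as absent/"novel" — a deliberate, conservative default. TAS2 is
searched with both the classic reference `CATACATTAA` and the updated
family-level anchor `TATGCATTAA`; mismatches are always reported against
the classic string so that dot patterns line up with the variant tables.
The literature prints the updated anchor in two non-identical forms; both
are shipped verbatim (`tas2Anchors()`) and neither is silently corrected.

Hits are ranked by (mismatch count, start), ties resolved 5'-most. With
`restrictDownstream = TRUE` each element is searched downstream of the
previous best hit, enforcing the canonical layout; with the restriction
off, candidates from all five elements are pooled and accepted greedily by
mismatch count with overlap exclusion. The pooled mode exists because the
updated TAS2 anchor is only two substitutions away from the tail of the
TAS1 motif itself, so an unrestricted naive search would hallucinate a TAS2
inside every TAS1; overlap exclusion removes that class of artefact while
still allowing out-of-order (displaced) elements to be detected.

Variant tables for all five elements ship as editable TSV fixtures in dot
notation (ASCII `.` for the typographic middle dot). A handful of rows in
the source tables print a substitution letter at a column where the letter
equals the reference base, which is inconsistent with dot notation; the
fixtures normalise such letters to dots where the row stays distinct and
shift them minimally otherwise, with every emendation documented in the
fixture headers. `parseVariantTable()` warns if a user-supplied table
contains such rows.

## Tandem-repeat detection

The detector replaces an external web service, so its semantics are spelled
out exactly and are simple enough to re-derive by brute force (the test
suite does exactly that). For each candidate period $p$ the sequence is
compared against itself shifted by $p$, giving a binary self-match vector.
Candidate loci are the containment-maximal intervals whose self-match
identity is at least `minIdentity`; within each locus the reported array is
the maximum-scoring core under weights $+(1-\theta)$ per match and
$-\theta$ per mismatch, with score ties broken shortest-then-leftmost.
The core construction guarantees array boundaries sit on self-matches and
that chance matches in the flanking background are not absorbed. Identity
thresholds are handled as exact rationals (numerator over 10\,000) so that
boundary ties are deterministic and bit-identical between the
implementation and the exhaustive oracle. Hits are then filtered by
`minArrayLength` (default 20 nt), `minCopies` (default 2; the copy-number
filter the original workflow applied is not quantified in the literature,
so 2 is a documented choice), and consensus identity, and overlapping hits
across periods are pruned keeping the longest array (then highest identity,
smallest period, smallest start). The per-column majority consensus breaks
ties alphabetically for determinism.

Two consequences are worth knowing. First, a perfect array flanked by a
base that happens to continue the periodic pattern is reported with that
partial extra copy (fractional copy number), exactly as an alignment-based
detector would. Second, at the default thresholds (80% identity over
20 nt), weak chance repeats do occur in random AT-rich sequence — the
thresholds are intentionally permissive, and downstream typing is protected
by the generator's screening (below) rather than by silently raising them.

Repeat positions are classified relative to the annotated elements:
`before_TAS1` and `after_CSB3` are "normal" placements, the `between_*`
classes are "anormal", and anything overlapping an element (or between
elements that are not canonically adjacent) is `unplaced`. The
genus-diagnostic repeat motifs (`diagnosticTrMotifs()`) are matched against
the raw array and against all rotations of the consensus, since a repeat
array's phase is arbitrary.

## CR typing

Typing is rule-table-driven, not hard-coded. The shipped table encodes the
published scheme: general types I–IV require all five elements in canonical
order and are distinguished by the anormal repeat classes (I none, II
between CSB1 and CSB2, III between TAS2 and CSB1, IV between TAS1 and
TAS2); subtypes within a general type differ by the normal repeat pattern;
type V collects profiles with missing elements or a non-canonical element
order, with V-1…V-11 keyed to distinct presence/order patterns. The
published subtype layouts are defined only schematically, so the concrete
patterns in `cr_type_rules.tsv` are a documented reconstruction — editable
without touching code. "Unclassified" is a first-class outcome and is never
coerced into type V. Priorities resolve specificity; equal-priority
multiple matches raise an error rather than being silently ordered. One
species appears under two subtypes in the published membership lists (a
contradiction in the source); the shipped 21-profile fixture keeps it as
the type IV-2 representative only.

```{r}
prof <- subtypeProfiles()
asg <- classifyProfiles(prof)
table(asg$general_type)
```

## Synthetic data: what it does and does not emulate

Every stage is testable offline through seeded generators.
`generateCR()` assembles a CR from a preset (element dot patterns, spacer
lengths, repeat arrays by position class, background AT content); the
Eremias preset places one repeat array before TAS1 and one after CSB3 with
a 35 nt CSB2–CSB3 spacer, the Darevskia preset places the array between
CSB1 and CSB2, the Takydromus preset uses the 7 nt and 6 nt units. Spacer
randomness is redrawn — deterministically within the seeded stream — until
the annotation pipeline recovers exactly the embedded elements and repeat
intervals, so returned ground truth is machine-checkable by construction.
This screening is what makes exact round-trip tests meaningful despite the
permissive repeat thresholds.

`generateMitogenome()` lays the canonical 37 genes plus the light-strand
replication origin (O_L) and the CR on a circular H-strand sequence with
10 nt intergenic spacers. The four conserved overlaps are instantiated
(ATP8/ATP6 through `ATGGNNNTAA` with N drawn at random, ND4L/ND4 7 nt,
ND5/ND6 5 nt arranged so ND5 ends in the AGG stop while the
reverse-complemented ND6 ends in TAA, ATP6/COIII 1 nt sharing the stop/start
adenine). H-strand protein genes carry valid starts (ATG; GTG for COI),
canonical stops and no internal stops; generation retries codon draws until
the constraints hold. Default sizes give genomes of roughly 17 kb with a
~1.5 kb CR, inside the range of the real records the package emulates.

The generators deliberately do **not** emulate phylogenetic structure
(codon alignments evolve on a star tree), tRNA cloverleaf or rRNA secondary
structure, heteroplasmic repeat-length variation, or base-compositional
heterogeneity along the molecule. Passing round-trip tests therefore
demonstrates correctness of the annotation logic, not robustness to every
feature of real data; on real CRs the permissive repeat thresholds will
surface weak arrays that a score-thresholded tool would suppress, and users
should filter on copy number and identity as the original workflow did.

## Accessory statistics

Composition skews are computed from raw counts, AT-skew $=(A-T)/(A+T)$ and
GC-skew $=(G-C)/(G+C)$, with zero denominators flagged rather than
propagated. Codon usage pools in-frame codons under the vertebrate
mitochondrial code after trimming incomplete terminal codons (the truncated
stops T-- and TA-- seen in these genomes); CDpT (codons per thousand) sums
to 1000 over all codons including stops, while RSCU excludes stops and
normalises within synonymous families. Leucine is split into its CUN and
UUR boxes and serine into UCN and AGY — the boxes are not reachable from
each other by third-position exchange, and the split mirrors the per-box
presentation used for these genomes; the family-mean-1 identity holds per
box.

Pairwise dN/dS follows Nei–Gojobori (1986) with equal pathway weighting and
Jukes–Cantor correction $d=-\frac{3}{4}\ln(1-\frac{4}{3}p)$, the most
probable concrete method behind a MEGA-based workflow; raw proportions are
available via `correction = "none"`. Codons containing gaps, ambiguity or a
stop in either sequence are dropped pairwise; substitution orders passing
through a stop are excluded from pathway averaging (all orders are used
only if every one is blocked); $p \ge 0.75$ flags the correction undefined.
The gene-level average is the mean of defined pairwise ratios — not the
ratio of means — with undefined pairs (dS $= 0$) counted and reported. Note
that pathway averaging assigns fractional nonsynonymous counts to codons
hit more than once even under purely synonymous evolution, so the
"synonymous-only implies dN $= 0$" identity is exact only at low
divergence; the tests exercise it in that regime.

```{r}
sim <- simulateCodonAlignment(4, 300, synRate = 0.09, nonsynRate = 0.03,
                              seed = 1)
geneAverageRatio(sim$alignment)$summary
```

## Numerical and degenerate-input conventions

Coordinates are 0-based half-open on the H-strand everywhere inside the
package; GenBank's 1-based inclusive convention is converted exactly once
at the I/O boundary, and origin-wrapping features carry a flag rather than
a doubled sequence (motif scans append a transient prefix of motif length
minus one). Zero-length CRs, missing boundary tRNAs, empty sequences, empty
codon inputs and zero retained p-distance sites are errors with explicit
messages; undefined skews and undefined dN/dS ratios are flagged values,
not errors. All tie-breaks (hit ranking, consensus letters, repeat core
selection, rule priorities) are deterministic and documented above, so
identical inputs always produce identical reports.

## Problem sizes used in the shipped checks

The automated checks run on synthetic material sized for a laptop: CRs of
0.2–1.5 kb, whole genomes of ~17 kb, repeat-oracle comparisons on strings
of 160–400 nt with periods up to 20, codon alignments of 150–2000 codons,
and the 21-profile typing fixture. These sizes were chosen to exercise
every code path (wrapping features, all five presets, all 21 rules, multi-
substitution codons) while the exhaustive oracles remain enumerable.

## Known limitations

The repeat detector reports one array per self-similar locus and period;
two arrays bridged by a near-matching spacer can merge into the better
core. The typing reconstruction is faithful to the published criteria but
the per-subtype layouts are inferred, not transcribed, and should be
re-examined against new material. GenBank parsing supports the feature
dialect this workflow needs (CDS/tRNA/rRNA/D-loop/rep_origin, complement
and origin-spanning joins), not the full flat-file grammar. dN/dS is the
NG86 estimator only; model-based (codeml-style) selection inference is out
of scope.
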