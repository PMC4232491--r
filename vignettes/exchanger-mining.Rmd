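---
title: "Mining Na+/Ca2+ exchanger families: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining Na+/Ca2+ exchanger families: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ncxminer)
```

## The problem

Animal genomes carry three subtypes of Na+/Ca2+ exchanger: **NCX**
(sodium/calcium), **NCKX** (potassium-dependent sodium/calcium) and
**CCX/NCLX** (calcium/cation, lithium-permissive). All three share the
*alpha repeat*, a transport motif that occurs in two blocks (α1, α2)
separated by a cytoplasmic loop, but each subtype is diagnosable from a
small set of sequence features:

| feature | NCX | NCKX | CCX |
|---|---|---|---|
| K-dependent exchanger domain (e.g. InterPro IPR004481) | – | **yes** | – |
| Na_Ca_ex exchanger domain | yes | yes | yes |
| tandem CalX-beta (CBD1/CBD2) | **yes (2)** | – | **no (0)** |
| α1 / α2 consensus | G(S/G)SAPE / GTS(I/V/L)PD | as NCX | GNG(A/S)PD / (G/S)(N/D)SxGD |

`ncxminer` turns that diagnosis into a reproducible desk-scale pipeline:
motif and PSWM scanning, rule-based classification, reciprocal-best-hit
ortholog pairing, codon-aware back-translation, nucleotide diversity and
counting-based dN/dS, and in-silico PCR with split-gene-model bridging.
Draft nematode annotations are the intended substrate, but nothing is
nematode-specific.

## Motif scanning and the PSWM

Strict patterns (`parse_pattern`, `scan_pattern`) accept the printed
degenerate syntax — single residues, `(I/V/L)` alternations, `x` wildcard —
and report every (possibly overlapping) match. Divergent repeats that fail
the strict pattern are caught by a position-specific weight matrix built
from known repeat instances:

$$\mathrm{score}_{j,a} = \log_2 \frac{(c_{j,a} + k)/(N + 20k)}{b_a}$$

with pseudocount $k$ (default 0.5), instance count $N$ and background
frequencies $b_a$ (default uniform 0.05, overridable). Scores are in bits;
a window's `relative_score` is its score divided by the matrix's maximum
attainable score, so thresholds are transferable between matrices. The
default scan threshold is 0.8; both pseudocount and background are declared
package defaults, not values inherited from any published matrix, because no
training alignment or threshold for the original web tool is on record.

```{r}
m <- build_pswm(c("GNGAPD", "GNGSPD", "GNGAPD"), label = "CCX_alpha1")
m
scan_pswm(c(q = "MKLGNGSPDRT"), m, min_relative_score = 0.8)
```

`find_alpha_repeat_pair` requires α1 to precede α2 with a separation of
50–1000 residues (configurable). The loop length is not standardized in the
literature, so the bounds are deliberately loose: long enough for every
documented exchanger loop, short enough to reject chance co-occurrence in
unrelated proteins. A protein with exactly one of the two repeats is flagged
`divergent` — the category the PSWM route exists to surface.

## The classifier

`classify_protein` applies a first-match-wins decision tree:

1. any K-dependent exchanger domain → **NCKX**;
2. exchanger evidence (domain or paired NCX-type repeats) plus ≥ 2
   CalX-beta domains → **NCX**;
3. exchanger evidence (domain or paired CCX-type repeats) with zero
   CalX-beta → **CCX**;
4. otherwise **UNCLASSIFIED**.

The tandem requirement (2 CalX-beta) reflects the CBD1/CBD2 arrangement of
full-length NCX proteins; `min_calx = 1` admits fragmentary models at the
cost of specificity. In the absence of any domain annotation the motif
pairs alone can classify (NCX motifs checked before CCX); such calls are
marked lower-confidence in the rationale. The conserved α2 aspartate said
to confer potassium dependence has no published coordinate, so it is
surfaced as a note, never used as a rule.

## Orthologs, codon alignments, selection

`reciprocal_best_hits` replaces genome-scale BLAST with exact
Smith–Waterman alignment (BLOSUM62, gap open 11 / extend 1 — BLAST's
protein defaults) over curated sets: a pair is reported only when each
sequence is the other's *unique* best score; ties go to an `ambiguous`
side-table rather than into pairs. Scores are symmetric by construction;
because optimal alignments need not be unique, `percent_identity`
canonicalizes argument order so identity is symmetric too.

`back_translate` recodes a protein alignment into codons from each
sequence's CDS. A terminal stop codon is trimmed with a warning; an
*internal* stop is fatal by design — spurious stops are precisely what
splits gene models in draft annotations, and silently tolerating them would
hide the misannotations the bridging module detects.

Nucleotide diversity π is the proportion of differing valid sites (gap or
ambiguity in either row excludes the site from numerator and denominator).
Sliding windows follow DnaSP conventions: alignment coordinates, default
100-column windows advancing by 25, trailing partial windows dropped; for
more than two rows the window value is the mean over row pairs. Summaries
report the across-window sample variance (n−1) and type-7 quantiles with
1.5×IQR whiskers.

dN/dS uses Nei–Gojobori (1986) counting: per-codon synonymous-site
fractions from exhaustive single-nucleotide mutant enumeration (mutations
to stops excluded from both numerator and denominator, preserving
N + S = 3 per codon), pathway-averaged difference counts over all stop-free
orderings, and the Jukes–Cantor correction
$d = -\tfrac{3}{4}\ln(1 - \tfrac{4}{3}p)$. Corrections with $p \ge 3/4$
are reported as undefined, never clamped. `global_dnds` pools counts over
all row pairs. This is a deliberate, documented substitution for tree-based
SLAC-style ancestor counting (which would require the phylogeny-inference
step that is out of scope here); pooled pairwise NG86 tracks but does not
exactly reproduce tree-based global estimates.

```{r}
pair <- simulate_ortholog_pair(length = 3000, rate = 0.08,
                               mode = "codon_free", seed = 42)
ng86_pair(pair$ancestor, pair$derived)
```

## In-silico PCR and gene-model bridging

`predict_amplicon` enumerates exact forward-strand primer sites against
minus-strand reverse sites (mismatch tolerance optional, default 0; no
melting-temperature model) and reports products up to 10 kb. `bridge_check`
asks whether a cDNA's genome-mapped exons overlap the spans of *two*
adjacent predicted genes; when they do, the models are merged with the cDNA
structure. Spliced alignment of the cDNA is consumed as intervals, not
performed. The published bridging primer pairs for the two documented split
CCX loci ship as `bridging_primers()`; running them against the deposited
cDNA accessions (expected products 813 bp and 674 bp) requires those
sequences locally and is therefore an external check, not part of the test
suite.

## What the simulator does and does not establish

`simulate_exchanger_set` plants subtype-true motifs at controlled offsets
in uniform-random background (default 900 residues, α1 at offset 60, a
loop-sized gap of 150–600 residues) and emits the matching domain
annotations; substitution noise is applied only outside motifs, so label
recovery at noise 0.05 certifies the classifier's plumbing, not robustness
to motif erosion. Real proteomes add everything the generator omits:
compositional bias, paralog families, fragmentary and chimeric gene models,
annotation errors. A green recovery test therefore establishes correctness
of the decision logic, not field performance.

`simulate_ortholog_pair` mutates a uniform-random ancestor per site under a
Jukes–Cantor kernel, so observed divergence is exactly binomial — which is
what makes the 3-standard-error recovery criterion meaningful. Two
deliberate restrictions in the codon modes: proposed mutations creating
stops are rejected, and the synonymous-only mode additionally allows **at
most one substitution per codon**. The latter matters: two synonymous
steps in one codon (TTA→CTA→CTC, all leucine) can leave an endpoint pair
one of whose NG86 orderings passes through a nonsynonymous intermediate
(TTA→TTC is Phe), so pathway averaging would report dN > 0 for a history
that was wholly synonymous. One hit per codon makes "dN = 0 exactly" a
construction, not an accident of seeds.

## Numerical and degenerate-input policy

* All coordinates are 0-based half-open internally; file formats emit
  1-based inclusive.
* Gap stripping removes columns with any gap by default (`max_gap_frac`
  generalizes); an all-gap result is a warning, not an error.
* Deterministic ordering everywhere: PSWM hits by descending score then
  offset, amplicons by length, RBH pairs by id.
* Smith–Waterman admits the empty alignment: when no pairing scores
  positive the score is 0 with undefined identity.
* Every generator takes an explicit seed and restores the caller's RNG
  state.

## Known limitations

No profile HMMs, E-values or alignment heuristics; no tree inference, REL or
MEME site tests (global pooled NG86 only); no frameshift-aware
back-translation; primer thermodynamics not modeled. Published numeric
anchors that depend on external accessions or assembly versions (deposited
cDNA amplicon sizes, genomic product lengths, re-built *Caenorhabditis*
dN/dS and π values) are reproducible with this toolkit once those sequences
are supplied, but are not bundled.
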