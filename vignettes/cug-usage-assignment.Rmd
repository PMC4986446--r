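---
title: "Assigning CUG codon translation from alignment conservation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assigning CUG codon translation from alignment conservation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cugusage)
```

## The problem

In most genomes CUG codes for leucine; in the yeast CTG clade it codes for
serine (the alternative yeast codon usage, AYCU). The translation scheme of
a species can be inferred comparatively: a CUG codon sitting at an
alignment column where the other species keep a strongly conserved leucine
is almost certainly read as leucine, and likewise for serine. `cugusage`
turns that idea into an explicit, tested procedure: map every CUG codon to
its alignment column, score how conserved that column is and for which
residue, and aggregate the evidence per species into a call.

Two design commitments shape everything else. First, codon-to-column
mapping uses a *wildcard* code in which CUG may sit under any residue, so
no stage of the pipeline presumes the answer it is trying to find; the
code setting affects validation only and never coordinates, which the test
suite asserts. Second, conservation is computed *locally* (see below), so
the classification of one column cannot be perturbed by unrelated parts of
a concatenated supermatrix.

## Conservation score

For an alignment column, residues are grouped into disjoint
chemical-property classes. With class distribution \(p\) over \(K\)
classes among non-gap residues and gap fraction \(g\),

\[ \mathrm{score} = \left(1 - \frac{H(p)}{\log K}\right)(1 - g), \qquad
   H(p) = -\sum_k p_k \log p_k . \]

Natural logarithms are used internally; the score is base-independent
because it is a ratio. A gap-free single-class column scores exactly 1, a
gap-free column spread over all classes exactly 0.

The default partition has six classes — \{AVLIMC\}, \{FWYH\}, \{STNQ\},
\{KR\}, \{DE\}, \{GP\} — chosen so that leucine and serine occupy
different classes (otherwise the score could not discriminate the two
candidate translations). It is configurable via `property_partition()` or
a plain-text partition file.

Both `-` (deletion or missing genome sequence) and `X` (unknown residue)
are excluded from the class distribution and counted into \(g\). Treating
them as distinct input symbols but giving both the same multiplicative
penalty is deliberate: conflating `X` with a real residue class would
reward low-coverage rows, and silently converting `X` to `-` (as some
older tools do) hides the distinction in the outputs.

### Focal subalignment protocol

Every column containing at least one leucine or serine among retained rows
is scored on a subalignment of the focal column plus `flank = 15` columns
to each side, clipped to the column's family block so windows never span
the artificial junction between concatenated families. Rows carrying a CUG
at the focal column are removed first — the residue encoded by the codon
being classified must not vote on what the column is conserved as.

Smoothing over neighbouring columns (window `w = 3`) uses

\[ s_c = (1-\lambda)\,r_c + \lambda \,\overline{r}_{\,|j-c|\le w,\ j\ne c} \]

with \(\lambda = 0.5\) by default. Only the window half-width is a fixed
methodological choice; the combination weight is not pinned down by any
published description we follow, so it is exposed in `run_config()` and
reported in every output header. `w = 0` bypasses smoothing entirely, and
both scores are always computed and reported side by side. Labelling and
the conserved-50 shared matrix default to the smoothed (`w3`) score.

Locality is a tested invariant, not an aspiration: mutating any column
outside the flank leaves a focal score bit-identical. All-gap columns
inside a window are unscorable (`NA`) and are simply dropped from the
neighbourhood mean.

### A note on monotonicity

Intuitively, replacing a residue by the column's modal residue should
never lower conservation. Under property classes that statement is false:
if the modal *residue*'s class is not the modal *class*, the replacement
can equalise class counts and raise entropy (e.g. V,V,V,L,L,S,S,S under
the default partition). The property that does hold — and is tested — is
that replacing a residue by a member of the modal *class* never lowers the
score, by a standard majorization argument.

## Labelling and the usage call

A column is a *Leu-position at level t* when its focal score is at least
`t` and its modal residue among retained non-gap rows is L (and likewise
for serine). Thresholds default to 0.9, 0.8, 0.5; labels are nested by
construction. Modal ties are broken in favour of L, then S, then
alphabetically, so a tie involving the residue of interest still yields a
usable label rather than an arbitrary one.

Per species, CUG codons are tallied against these labels and the call rule
walks the thresholds from strict to lax: the first threshold at which the
stronger side has at least `min_sites` codons decides, provided it
outweighs the other side `margin`-fold (defaults 1 and 3.0). The
published analyses this procedure follows decided group membership by
inspecting the per-species percentages; an automated pipeline needs an
explicit rule, so both knobs are configuration, printed in every report
header. The strict-to-lax cascade reproduces the qualitative behaviour
that matters: a species with no codons at the most conserved positions can
still be called at 80 % or 50 %, while a species with conflicting evidence
falls through to `ambiguous` rather than being forced into a group.

## Shared CUG positions

`shared_matrix()` counts, for each species pair, the distinct global
columns at which both species carry a CUG — over all columns and
restricted to columns with score ≥ 0.5. Positions, not codons, are
counted: paralogs collapse onto their column. Inherited, clade-level CUG
placements produce large within-clade entries and empty cross-clade
blocks; species-specific strays produce near-diagonal matrices. The
combined report puts the conserved-restricted counts in the upper
triangle, all-column counts in the lower, per-species totals on the
diagonal, and colours on a `log10(1 + x)` scale so zeros render.

## The synthetic cohort

`simulate_cohort()` generates the structure the analysis assumes, with
truth bookkeeping, so every stage is validated end to end without
downloads:

- two flat clades (12 standard + 12 AYCU species by default) over 2
  families × 500 columns;
- designated conserved-Leu (10 %), conserved-Ser (10 %) and
  conserved-other (40 %) columns carrying their consensus residue up to a
  per-species substitution noise (2 % by default), the remaining 40 %
  variable;
- clade-ancestral CUG placements drawn once per eligible conserved column
  (rate 0.15 at Leu columns for the standard clade, 0.08 at Ser columns
  for the AYCU clade — the serine clade carries fewer CUGs, as real CTG
  clade genomes do) and inherited with 15 % per-species loss; this yields
  within-clade sharing and, by construction, no cross-clade sharing at
  conserved columns;
- rare species-specific stray CUGs at variable columns (rate 0.002 per
  species per column), always encoding the species' own CUG translation —
  strays model recent, lineage-private codon gains, which is why they are
  scattered rather than shared;
- per-row gap blocks (15 % of rows, 20–80 columns) emulating incomplete
  genome assemblies; and one species stripped of all CUG codons, matching
  the observed existence of yeasts without a single CUG in such datasets.

Coding sequences are produced by back-translation with CUG sites set to
CTG and all other leucines/serines drawn from their synonymous sets minus
CTG, so no accidental CUG sites arise. Everything is deterministic given
the seed.

What the generator does *not* emulate: realistic substitution processes
(no rate matrices, no tree-shaped descent within clades), indels beyond
single gap blocks, subfamily structure within families, or the
heterogeneous conservation landscape of real proteins. Passing the
recovery tests therefore shows that the decision logic is correct under
the structural assumptions — conserved columns exist and CUGs concentrate
on them — not that real curated alignments will be as clean; on real data
the per-species percentages are far lower than the synthetic ones and the
threshold cascade does more work.

## Numerical and edge-case choices

- Coordinates are 1-based inclusive everywhere, including reports; the
  implementation language is 1-based and mixing conventions invites
  off-by-one errors.
- An all-gap column cannot be scored: `property_entropy()` raises an
  error, and profile construction skips columns with no scorable retained
  residue.
- A single trailing stop codon is trimmed from each CDS; an internal stop
  is a frame error (it indicates an annotation fault, not biology).
- Codons containing `N` translate to `X`, must sit under an `X` in the
  alignment, and are never CUG sites — uncertain sequence must not create
  codon-usage evidence.
- Paralogs: family alignments may keep several rows per species. CUG-site
  extraction inspects *all* rows; concatenation keeps one row per species
  per subfamily (`"longest"` non-gap content by default, `"first"` and
  `"strict"` available), and masking applies to the rows that entered the
  supermatrix. Which paralog should represent a species in a concatenated
  alignment is genuinely underdetermined; `"longest"` maximises retained
  signal and is logged whenever it fires.
- Histogram bins are half-bounded width-0.1 intervals with 1.0 included
  in the top bin.
- Reports carry no timestamps, so identical inputs give byte-identical
  outputs; the test suite asserts this.

## Problem sizes

The default cohort (24 species, 1,000 columns, ~250 CUG sites) runs the
full pipeline in about two seconds; the validation suite re-simulates ten
cohorts per noise level, which keeps the complete run within a few
minutes on a single core while still exercising every stage on hundreds
of species-level decisions.

## Limitations

- The assignment is comparative: a species whose CUG codons all fall at
  unconserved columns stays `ambiguous` or `no_data`; the method cannot
  detect a reassignment that leaves no conservation footprint, nor a
  third, unanticipated CUG meaning.
- Scores depend on the property partition and window weighting; with a
  different partition the absolute score scale shifts, which is why the
  thresholds are configuration rather than constants of nature.
- Tree annotation decorates an existing newick; no inference or dating is
  attempted.
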