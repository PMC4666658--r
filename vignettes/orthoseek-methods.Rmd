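---
title: "Methods: iterative homolog search with identity and length filters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: iterative homolog search with identity and length filters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthoseek)
```

## The procedure

`orthoseek` implements a recurrent homology search. One reference sequence
(the first query) anchors everything: database hits are always alignments
to the reference, and reported identities and expect values are those of
the alignment to the reference, even for members recruited later by the
profile. The loop is:

1. align the reference against every database sequence (affine-gap
   Smith–Waterman) and keep hits with expect value at or below the cutoff;
2. admit survivors through the identity filter and the length filter;
3. build a position-specific scoring matrix (PSSM) from the reference plus
   all accepted members (plus any extra query sequences the user supplied
   as known homologs), search the database with it, and apply the same
   cutoff and filters to *new* accessions;
4. repeat step 3 until an iteration adds nothing, then classify orthologs
   by reciprocal best hits against the reference's source proteome.

The underlying assumptions are the classical ones of similarity-based
homology inference: statistically significant local similarity implies
common ancestry once twilight-zone alignments are excluded, and a
reciprocal best hit between two proteomes is a workable operational
definition of orthology. A further, deliberately simple assumption is that
*protein length is a proxy for domain architecture*: two homologs whose
lengths differ by more than one domain's worth of residues probably do not
share an architecture.

## The two filters

**Identity filter.** A hit of alignment length $L$ (columns, gaps
included) is kept iff its percent identity reaches

$$pI(L) = n + 480 \, L^{-0.32\,(1 + e^{-L/d})},$$

the length-dependent twilight-zone threshold. Short alignments need very
high identity (the curve exceeds 100% below roughly 20 columns and can
therefore never pass); long alignments approach the curve's floor. The
offset $n$ (percentage points, default 33) is the main
sensitivity/specificity dial: with $n = 33$ the minimal identity is about
53% — the default operating point — and $n = 0$ relaxes it to the bare
curve.

The decay constant $d$ deserves a note. The package's default is
$d = 1000$, the original form of the curve, whose floor sits near 20%
identity around a few hundred residues; that floor is what makes the
"$n = 33 \Rightarrow$ 53% minimal identity" arithmetic work. A variant
with $d = 100$ circulates in print, but it raises the floor to ~63%
identity, which is inconsistent with both the 20% asymptote and the 53%
operating point; it remains selectable via
`filter_params(decay_constant = 100)` for users who want the stricter
curve.

**Length filter.** Let $S$ and $G$ be the shortest and longest lengths of
the current homolog set (the query lengths before anything is accepted)
and $m$ the minimal domain length (residues, default 28 — about the
smallest folded domains). A candidate of length $\ell \le S - m$ is
removed: it is missing at least a domain. A candidate with
$\ell > G + m$ carries extra sequence; it is kept, but its unaligned
terminal overhangs are trimmed — longest overhang first, whole overhangs
at a time, stopping once $\ell \le G + m$ or no overhang remains.

Several details here were genuinely open and are package decisions:

* *What exactly is trimmed.* Only unaligned terminal overhangs, never
  aligned residues, and the trim is recorded as a retained range rather
  than applied destructively — the database is never mutated, every
  decision is auditable (`filter_decisions.tsv`), and re-running a filter
  on its own output reproduces it exactly.
* *Which lengths later iterations compare against.* The trimmed
  (effective) lengths of accepted members, plus the query lengths. Using
  trimmed lengths keeps the band anchored to the shared architecture
  rather than to whatever extra domains trimmed members once carried.
* *$m = 0$ is legal.* The training procedure sweeps the e-value cutoff at
  $m = 0$, where the band degenerates to "not shorter than the shortest
  member, trimmed to the longest". Sequences rejected in one iteration are
  reconsidered in later ones, so as accepted members widen the band,
  previously removed candidates can re-enter — this is the mechanism that
  lets the iterative loop recover short true homologs.

## The search engine

The engine is a from-scratch affine-gap Smith–Waterman in C++ (sequence
vs. sequence, and profile vs. sequence over PSSM column scores), not a
wrapper around BLAST: the filters and the loop are the substance here, the
engine only has to rank local similarities reproducibly at desk scale, and
externally computed BLAST/PSI-BLAST tabular hits can be substituted via
`search_params(engine = "precomputed-hits")`.

Numerical conventions, all deterministic and covered by oracle tests:

* Scoring: BLOSUM62 (half-bit units) by default, BLOSUM50 selectable;
  the `X` residue scores 0 against everything. A gap of length $k$ costs
  $\mathrm{open} + (k-1)\,\mathrm{extend}$, so equal penalties give linear
  gaps.
* Traceback tie-breaks are fixed (diagonal over gap-in-subject over
  gap-in-query; start cell = first maximum in row-major order), making
  alignments — not just scores — bit-reproducible.
* Expect values use the ungapped Karlin–Altschul form
  $E = K m n e^{-\lambda S}$ with $K = 0.041$, $\lambda = 0.267$ applied
  uniformly. This is an approximation (gapped parameters differ), which is
  acceptable because the pipeline consumes only the induced ordering and a
  cutoff; non-positive scores are capped at $E = Kmn$.
* PSSM columns are log-odds in bits,
  $\log_2\frac{(c_a + \beta p_a)/(N + \beta)}{p_a}$, with counts from hit
  residues aligned to the reference position plus the reference residue
  itself, background $p$ = Robinson–Robinson frequencies, and pseudocount
  mass $\beta = 1$ by default ($\beta = 0$ is refused whenever a residue
  is unobserved, since it would produce $-\infty$). Columns no hit
  covers fall back to the substitution-matrix row of the reference
  residue rescaled to bits, so a profile built from the reference alone
  reproduces the pairwise search exactly — profile gap penalties are the
  scheme's penalties rescaled by the same bits-per-unit factor.
* Reciprocal best hits are decided per whole source proteome by bit
  score, with ties broken by lower e-value, then higher identity, then
  lexicographic accession.
* Iterations are numbered from 1 (the initial pairwise pass); profile
  passes are 2, 3, …; `iterations_run` is the last iteration that added a
  member, and a configurable cap (default 10) guarantees termination.

## Evaluation and parameter optimisation

Predictions are scored against truth by accession identity:
$Sn = TP/(TP+FN)$, $Sp = TP/(TP+FP)$, and the Relative Error Quotient
$REQ = (FN+FP)/(2\,TP)$, a single error figure that is 0 for a perfect
prediction and undefined at $TP = 0$ (reported as `NA`, never as a number).

`optimize_parameters()` reproduces the training procedure: a
coordinate-wise sweep of the e-value cutoff (at $m = 0$, $n = 0$), then
$m$, then $n$, each stage fixing the value with the lowest REQ pooled
(micro-averaged) over the benchmark before the next stage runs. Pooling
sums counts across benchmark items before forming REQ; ties resolve toward
stringency (smaller e-value, larger $m$, larger $n$), so the result is
deterministic. Coordinate descent is the procedure itself — it is not
guaranteed to find the global grid optimum, and the tests therefore verify
it against an exhaustive evaluation of the same grid.

## The synthetic benchmark

`generate_family()` emulates the statistical structure the filters act on,
with all randomness driven by R's default Mersenne–Twister generator under
an explicit seed (the caller's RNG state is saved and restored):

* an ancestral domain (default 150 aa) drawn from Robinson–Robinson
  background frequencies, mutated independently per species $i$ with
  per-site substitution probability $\min(0.9, i \cdot \mathrm{rate})$
  (default rate 0.05, six species — the farthest variant sits near 70%
  domain identity, above the default threshold with a visible but not
  trivial margin), embedded in fresh random linkers of 30–60 aa per side;
* decoys (default 10) of background composition and matched length, so
  the identity filter rather than composition bias rejects them;
* paralogs probing each rule: a *truncated* paralog (first third of the
  domain; length-filter rejection), a *diverged* paralog (domain mutated
  at 0.55, twilight-zone identity; Rost rejection), an optional
  *flanking-domain* paralog (extra terminal domain; kept but trimmed —
  deliberately excluded from the default benchmark truth because keeping
  the trimmed sequence is the intended behaviour, so "rejected" would be
  the wrong label), and a *reciprocal* in-paralog derived from a second
  source-proteome gene (accepted as homolog, removed by the reciprocal
  step).

The substitution model has no indels inside the domain — length variation
lives entirely in the linkers — and replacement is uniform over the 19
alternative residues, so the expected domain identity after one step at
rate $p$ is simply $1 - p$, which the generator tests verify. What the
benchmark therefore does *not* emulate: insertions/deletions within
domains, rate heterogeneity across sites, realistic substitution spectra
(no WAG/LG simulation), compositional bias, and fragmentary sequences.
Passing the benchmark shows the admission logic, iteration and reciprocity
machinery behave as specified under controlled geometry; it is not a claim
about recall on real proteomes, where twilight-zone homologs and domain
shuffling are harsher.

Default problem sizes (the package's own choice of scale): 20 families per
benchmark, 6 species variants each, ~19 database sequences of ~250 aa per
family. The alignment-engine oracle tests run on sequences of up to 12
residues, where an exhaustive dynamic-programming reference in plain R is
cheap and an independent aligner (Biostrings) cross-checks the scores.

## Known limitations

* The expect-value calibration is approximate (see above); absolute
  e-values should not be compared against NCBI BLAST output, though
  orderings agree.
* The length filter is a proxy: architectures can differ at equal length,
  and trimming assumes extra domains are terminal, never internal.
* RBH orthology is one-to-one by construction; co-orthologs arising from
  lineage-specific duplications after speciation will be classified as
  homologs only.
* With multiple queries from different organisms, the reciprocal step
  still uses a single user-supplied source proteome — the reference's —
  since reciprocity is only defined against the proteome the reference
  comes from.
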