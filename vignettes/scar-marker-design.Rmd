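---
title: "Duplex SCAR marker design and barcode authentication: methods"
author: "scarkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Duplex SCAR marker design and barcode authentication: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scarkit)
```

# The problem

A SCAR (sequence characterized amplified region) assay authenticates a
sample by the presence and size of a PCR product that only a specific taxon
can template. Given an aligned reference panel of barcode sequences — here
modelled on fungal nrDNA-ITS, where congeneric medicinal and adulterant
species differ by roughly 9–21% while conspecific sequences are nearly
identical — the task is to find primer pairs whose binding sites are fixed
in the target species and sufficiently different in every other species that
amplification fails there. scarkit implements this design, its in-silico
validation, the surrounding panel analytics (distances, trees), the
real-time PCR standard-curve arithmetic, and the authentication of unknown
samples.

Coordinates are 1-based and inclusive throughout, both internally and in
every report; BED export converts to that format's 0-based half-open
convention at the boundary.

# Distances and panel variability

Pairwise distances use pairwise deletion: per pair, only columns where both
sequences carry an unambiguous A/C/G/T are compared (gaps, N and all
ambiguity codes are excluded — conservative and deterministic). Over the L
comparable sites, P is the transition and Q the transversion proportion;
the p distance is P + Q and the Kimura two-parameter distance is

$$d = -\tfrac{1}{2}\,\ln\!\big((1 - 2P - Q)\sqrt{1 - 2Q}\big),$$

undefined (an error, not NaN) when either factor is non-positive
(saturation). The variability table reports, per species, the mean ± SD of
within-species pairwise distances (undefined, not zero, for single-record
species), the mean ± SD against all heterospecific records, the ungapped
length and GC content. Two conventions deserve note: the SD uses the
population (n) denominator, matching the convention of the standard
phylogenetics desktop software that such tables are usually produced with;
and the interspecific mean is taken over all heterospecific pairs, with a
per-species-pair-means alternative exposed as `inter_mode =
"species_means"` because published tables rarely state which was used.
Distances default to K2P for consistency with the tree; GC content counts
S and W (which are unambiguous with respect to GC) in both numerator and
denominator, and excludes gaps and all other codes, because the quantity
describes sequences, not alignment columns.

# Trees

`nj_tree()` performs Saitou–Nei neighbor joining (delegated to ape's
implementation behind the package surface); on additive matrices the
generating tree is recovered exactly, which the tests verify against an
exhaustive-topology least-squares oracle on random 4–8-leaf trees. Negative
branch lengths that NJ can produce are retained in the returned object so
additivity checks stay exact, and clamped to zero only when writing Newick
display output. Bootstrapping resamples alignment columns with replacement;
support of each internal bipartition of the reference tree is the
percentage of replicate trees containing it, written as internal node
labels. All resampling is driven by one explicit integer seed; the same
seed gives identical supports on any platform, and replicates on which a
distance is undefined are dropped (their count is reported as an
attribute). Rooting on an outgroup is a display operation only.

# Diagnostic sites and primer design

A column is *diagnostic* for a target species when (i) the target records
agree on a single plain state (A/C/G/T or gap) at a frequency of at least
`min_intraspecific_fixation` — 1.0 by default, because reference panels of
this kind have near-zero intraspecific variability, with the fraction
exposed for polymorphic panels — and (ii) that state is carried by no
non-target record, a background ambiguity code overlapping the state also
disqualifying the column. Sites involving a gap on either side are indels,
the rest substitutions.

Primer candidates are every window of the ungapped target reference (both
strands) that contains at least one diagnostic site and satisfies the
constraint windows. The defaults — length 18–23 nt, GC 0.40–0.80, Wallace
Tm 48–72 °C, homopolymer runs ≤ 5 — bracket the dimensions of published
ITS SCAR primers (20–23 nt, GC up to ~0.76) and are all overridable via
`design_constraints()`. Two additional rules are structural rather than
tunable: a primer window must be *fixed within the target species* (a
polymorphic footprint would silently drop conspecific templates under
exact-match PCR), and windows are taken on the ungapped reference, so a
primer can never contain a gap, while diagnostic coverage is counted over
the aligned columns spanned by the footprint — which credits diagnostic
indels where the target carries the gap to the covering window. The Wallace
rule (2(A+T) + 4(G+C)) is used as a window statistic, not a thermodynamic
prediction: the design constraint is Tm balance within a window, for which
any monotone GC-and-length proxy suffices.

Pairs are formed from all forward/reverse combinations with non-overlapping
footprints and an amplicon of 80–400 bp (published duplexes span
83–339 bp); the pair must carry **at least two diagnostic substitutions in
one of its primers**, the empirically grounded specificity rule for assays
of this kind. The expected amplicon is the inclusive span from one primer's
5′ end through the other's 5′ end, so both footprints count — this is the
convention under which the published primer tables' size arithmetic works
out. Ranking is by total diagnostic coverage, then the number of primers
with a diagnostic site in their 3′-terminal 3 nt (a 3′ mismatch is the
strongest amplification blocker), then Tm balance, then leftmost
coordinate; the ranking hierarchy is this package's construction, chosen so
that ties resolve deterministically.

`design_marker_set()` walks the ranked pairs, validating each by exact
in-silico PCR against every panel template, and accepts a marker only if
all conspecific templates amplify and no other template does. The second
accepted marker must differ from the first by at least 20 bp (a 1.5%
agarose gel resolves that); a species for which no such duplex exists is
flagged `INFEASIBLE_DUPLEX` rather than silently given one marker. To
bound design time the ranked candidate list is thinned to one candidate
per start position (up to 120 per strand) before pairing — without the
per-start thinning the top of the list is dozens of overlapping windows on
the single richest diagnostic cluster, which cannot form pairs 80 bp
apart.

# In-silico PCR

Binding-site search slides the primer along the template with IUPAC-aware
matching (two codes match when their expansion sets intersect; a gap
matches nothing), counting mismatches, and optionally rejecting any site
with a mismatch in the primer's 3′-terminal window (3 nt by default).
Because templates are double-stranded the primer pair is unordered: both
role assignments (forward on the plus strand with reverse downstream, and
the reverse assignment) are scanned, which makes predictions invariant
under reverse-complementing the template. Products must have
non-overlapping footprints and default size limits of 50–2000 bp, the
gel-visible range.

Two mismatch policies are used deliberately. Design-time validation uses
`max_mismatch = 0` — the strictest reading of "no off-target product" —
because whether a given internal mismatch blocks polymerase extension in
vitro is not predictable from sequence alone. The cross-species audit
(`audit_cross_species()`) instead relaxes to 2 mismatches with the
3′-window rule and reports, per marker and external template, the minimum
mismatch count achievable by each primer, flagging templates where both
primers come within 2 mismatches — mirroring the rationale that two or more
diagnostic substitutions per primer are protective. These defaults are
configuration, not fact.

`embed_markers()` builds synthetic templates that carry a published primer
table's binding sites at exactly the printed amplicon spacings (anchoring
to an already-placed motif when two markers of a species share a site, as
published duplexes sometimes do). These stand-ins validate the engine's
geometry against published sizes when the originating reference sequences
are not bundled; they reproduce primer geometry, not real flanking
sequence, and are labelled synthetic in their ids.

# qPCR standard curves

Ct is regressed by ordinary least squares on log10(quantity in ng) —
quantities are converted to ng before the log, so a 15 ng … 1.5 pg 10-fold
series spans 4 log units. R² is the squared Pearson correlation of the two
variables, matching the "correlation coefficient" language such assays are
reported with. Efficiency uses the standard exponential form

$$E = \big(10^{-1/\text{slope}} - 1\big) \times 100,$$

which is 100% at the perfect-doubling slope −1/log10 2 ≈ −3.32 and
strictly decreasing in |slope|. Integer reporting rounds half away from
zero (99.38 → 99, 130.5 → 131), the instrument-software convention, rather
than R's banker's rounding. The limit of detection is the smallest tested
quantity with observed Ct below the cutoff (40 cycles by default), with the
curve-extrapolated quantity at the cutoff, 10^((cutoff − intercept)/slope),
reported alongside.

# Authentication

An unknown sample is interrogated two ways, and the tests require the two
routes to agree on pure samples. The *virtual duplex assay* runs
exact-match in-silico PCR with every marker; a species fires only when both
members of its duplex yield a product of exactly the expected size.
Exactly one firing species is an identification; several yield
`"mixed/adulterated"` (adulteration detection is the assay's purpose, so
mixed signals are reported, never forced to one species); none, with the
universal-primer control product present, yields
`"unresolved (non-panel species)"`; a failed control invalidates the
sample. *Nearest-reference classification* globally aligns the query
against every ungapped reference (match +1, mismatch −1, gap −2 — plain
Needleman–Wunsch defaults, exposed as arguments) and scores identity as
matches over aligned columns excluding terminal gaps; below 99% identity,
or on a tie between species, the query is `"unresolved"` with the tie
logged. The classifier is a local computation by design: it replaces
online database searches so that authentication runs without network
access, at the cost of only knowing the species present in the panel.

# The synthetic panel generator

`generate_panel()` evolves a random ancestor (58% GC, 580 bp by default)
along a star-of-stars genealogy: one branch per species, then one short
branch per individual. A star topology was chosen over a realistic
phylogeny deliberately — it produces the observed divergence structure
(interspecific pairwise divergence drawn to land in the 9–21% band,
intraspecific in 0–0.3%) while keeping the ground truth trivially
recordable: every mutation is logged, and the planted diagnostic columns
are exactly the columns touched by one species branch and nothing else.
Substitutions are sampled at transition:transversion ratio 2, so K2P
estimation is well-specified on the synthetic data; indels are short
deletions (1–5 bp, ~0.5% of sites per species branch), which keeps the
alignment the identity mapping onto ancestor coordinates. The first and
last 21 bp are mutation-free conserved flanks that double as universal
primer sites for the assay control — emulating the conserved regions that
universal barcode primers target. The defaults (6 species × 3 records)
mirror a realistic reference panel of this kind.

What the generator does *not* emulate: concerted-evolution heterogeneity
within rDNA arrays, sequencing error, alignment error (the alignment is
known, not estimated), insertions, and rate variation across sites. Tests
passing on this generator therefore demonstrate correctness of the
algorithms under clean, well-specified input, not robustness to real-data
artefacts — which is the appropriate scope for validating design
arithmetic, distance formulas and assay logic.

# Numerical and degenerate-input choices

* K2P saturation raises an error naming the condition; no NaN propagation.
* A species with one record reports intraspecific variability as
  undefined, never 0.
* Dilution series with all-equal quantities are rejected; missing Cts are
  dropped with a warning.
* Design ties are broken deterministically (diagnostic coverage, 3′
  anchoring, Tm balance, leftmost coordinate), so a panel and a
  configuration fully determine the marker set.
* Every stochastic operation (panel generation, bootstrap, sampling) takes
  an explicit integer seed; identical seeds give byte-identical outputs.

# Problem sizes used in the validation suite

The test battery validates the end-to-end pipeline
(generate → design → validate, block-diagonal specificity with the
two-substitution rule) on 20 seeded panels at the default 6 × 3 × 580 bp
conditions; neighbor joining against the exhaustive-topology oracle on
random trees of 4–8 leaves; the in-silico PCR engine against a
substring-search oracle on 1000 random primer/template pairs; and the
qPCR module on the packaged five-point dilution series. These sizes were
chosen to exercise every code path at the scale the method is used at
(barcode-length sequences, tens of references) while keeping the suite
fast enough to run routinely.

# Known limitations

* No thermodynamic screening: hairpins, primer dimers and annealing-energy
  calculations are out of scope; the Wallace Tm is a design-window
  statistic only.
* Exact-match validation is conservative in silico but cannot certify
  in-vitro failure of near-matching templates; the audit's mismatch
  thresholds are configuration.
* The classifier cannot identify species absent from the reference panel —
  it reports them as unresolved rather than guessing.
* Quantitative adulteration estimation from Ct values is not implemented;
  the assay reports presence and mixture, not proportions.
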