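---
title: "Designing Cas12a species-identification assays from alignments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing Cas12a species-identification assays from alignments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

LbCas12a-based DNA detection distinguishes closely related species — for
example quarantine fruit-fly pests whose larvae are morphologically
indistinguishable — by programming the nuclease with a guide RNA against a
species-private target. When the guide finds its double-stranded DNA target
(a protospacer preceded by a T-rich PAM, canonically TTTV for LbCas12a), the
activated enzyme's collateral single-stranded DNA cleavage releases a
fluorescent reporter. The assay works from crude extracts after isothermal
RPA amplification, so the entire diagnostic question reduces to a sequence
design problem:

1. Where in a marker (such as the mitochondrial genome) do the candidate
   species diverge enough to discriminate, while staying flanked by
   sequence conserved enough to amplify all of them with one primer pair?
2. Which PAM-adjacent windows inside those hotspots are recognised in one
   species but reliably rejected in every other?
3. Which RPA primers amplify those windows — universally (all species, one
   pooled reaction) or specifically (one species only)?

`pestid` answers these questions from a user-supplied multiple sequence
alignment. It deliberately does not run an aligner: alignment quality is a
separate concern, handled well by MAFFT and friends, and consuming a fixed
MSA keeps every downstream coordinate reproducible.

## Conservation model and region calling

For every alignment column the package records the fraction of sequences
carrying the most common non-gap residue (`identity_fraction`, with gaps
counted as a mismatching symbol class) and a strict flag `is_conserved` that
is true only when all species share one identical non-gap residue. The
strict flag drives flank detection because a universal primer must match
every species exactly; the fractional profile drives divergence scoring.
Gap columns always count as divergence — indels are diagnostic signal, often
the strongest available.

A *variable region* is the stretch between two conserved blocks of at least
`min_flank` columns (default 30, the minimum footprint of an RPA primer),
kept when it is at most `max_vr_len` columns long (default 500, so the
amplicon stays RPA-sized) and its mean divergence reaches `min_divergence`
(default 0.05; a small floor that stops near-conserved gaps from being
called hotspots). Regions are labelled `VR1`, `VR2`, ... left to right.
Stretches at the alignment ends lack one flank and are suppressed unless
`allow_terminal_regions = TRUE`, because universal amplification needs
primers on both sides.

All internal coordinates are 1-based closed intervals, the native R and
IRanges convention; conversion happens only at the I/O boundary (BED files
are written 0-based half-open, report tables 1-based inclusive).

## The concatenated template and guide enumeration

Guides are enumerated over a single template built by concatenating every
species' ungapped variable-region sequence (species-major order), separated
by a fixed linker — by default `GAGAGAGAGAGAGAGAGAGA`, a 20-nt purine repeat
containing no TTTV on either strand. Scanning one template keeps candidate
handling uniform; the linker exists so that no window spanning the stitch
between two fragments can ever be selected, and every linker occurrence is
additionally an excluded interval in the scanner. Any PAM-free string can be
substituted through the configuration.

`scan_pam_sites()` reports every IUPAC-compatible PAM match on both strands
whose full PAM + protospacer window (default 4 + 20 nt) fits in bounds and
avoids the excluded intervals. Ambiguity codes in the scanned sequence never
match — for a diagnostic assay it is safer to discard a window containing an
N than to gamble on it.

## Cross-reactivity scoring and the verdict rule

Each candidate window is mapped through the alignment onto every other
species and scored:

* `pam_intact` — does the orthologous PAM window still match the pattern?
* `total_mismatches` — Hamming distance over the protospacer columns; a gap
  or ambiguity code in the target counts as a mismatch.
* `seed_mismatches` — the same count restricted to the PAM-proximal seed
  (default 10 nt), where mismatches most strongly abolish Cas12a
  recognition.
* `indel_in_window` — any gap column inside the mapped window in either
  species.

A species is *safe* when the PAM is broken, an indel disrupts the window, or
there are at least `mm_threshold` (2) mismatches of which at least
`seed_threshold` (1) falls in the seed — the divergence patterns that
in-silico screens accept as non-recognising. A species is *reactive* when
the window matches perfectly under an intact PAM. Everything in between — a
single mismatch under an intact PAM, or two mismatches none of which touches
the seed — is *unresolved*: literature mismatch-tolerance data for Cas12a
are not sharp enough to call these safe, so the guide verdict flags them for
wet-lab validation rather than silently passing them. The guide is
`specific` only when every non-origin species is safe, `cross_reactive` if
any species is reactive, and `unresolved` otherwise. The rule is monotone:
adding divergence to any species can only move a verdict toward specific,
and a property test asserts exactly that.

Ranking is a deterministic total order: verdict class first, then the
worst-case discrimination margin (minimum over species of
`seed_mismatches + 2 * [PAM broken]`), then GC in [0.30, 0.70] preferred,
then absence of 5+ homopolymer runs, then position and strand. No on-target
activity model is applied — those scores are genome- and chemistry-specific,
and the panel-level specificity question is the one this package owns.

## RPA primer design

RPA runs at 37–42 °C with recombinase-mediated strand invasion, so melting
temperature is not the binding determinant it is in PCR; the package
therefore applies no thermodynamic model and instead uses RPA-appropriate
structural constraints: primer length 30–35 nt, GC fraction 0.20–0.70, no
homopolymer longer than 5, amplicon 100–600 nt (600 = a 500-column region
plus two primers). All are configurable.

Universal pairs are enumerated inside the conserved flanks, where every
window is column-identical and gap-free across species by construction;
validity is still re-verified per species, and per-species amplicons must
contain the full region projection. Specific pairs are enumerated inside the
target species' region sequence, and every primer must show at least one
mismatch or indel against every other species' mapped window; when guide
candidates are supplied, a pair is only kept if it flanks at least one guide
window. 3'-end-weighted mismatch rules and dimer/hairpin screens are
deliberately omitted by default: RPA's tolerance is not quantified well
enough to justify rejecting candidates on their account.

Pairs are ranked shortest-amplicon-first, then by proximity of the forward
primer to the region. Because that ranking prefers region-proximal windows,
the pairing search considers only windows within `max_amplicon` columns of
the region and caps each side at `max_windows_per_side` (200) candidates
nearest the region — a bound on the quadratic pairing step that cannot
displace the top-ranked pairs in any realistic flank.

## What the synthetic panels emulate

`generate_panel()` draws a uniform-ACGT backbone and plants variable
regions in which species 2..n mutate independently: substitutions at
`vr_substitution_rate` (default 0.15 per column, a realistic figure for
congeneric mitochondrial divergence), insertions and deletions at
`vr_indel_rate` (default 0.02, geometric lengths with mean 2). Outside the
regions the backbone is conserved (`background_substitution_rate = 0` by
default), emulating the input the tool expects: long, near-identical marker
sequences with localised divergence. The alignment is emitted from the known
edit history, never re-aligned, so truth coordinates are exact and no test
depends on an aligner.

Three post-processing guarantees make the planted intervals a well-defined
ground truth rather than a statistical tendency:

* the first and last column of each region are forced divergent;
* no internal run of conserved columns reaches `max_conserved_run`
  (default 25, safely below the 30-column flank threshold) — otherwise
  chance conservation would split a planted region and *no* caller could
  recover its exact coordinates;
* each region's realised divergence is topped up to
  `min_region_divergence` (default 0.08) — a marginal random draw at rate
  0.15 over two species can otherwise land below the caller's 0.05 floor.

`plant_discriminating_site()` additionally writes a perfect TTTA + 20-nt
site into one species and a controlled divergence pattern into the others
(PAM broken by a single T substitution; two mismatches with one in the seed;
one non-seed mismatch; or full identity), recording the verdict the screen
must return. The columns bordering the planted window are forced divergent
so the identical window cannot fuse with chance-conserved runs into a
region-splitting block.

What the panels do **not** model: tree-structured (phylogenetic)
divergence, transition/transversion bias, rate heterogeneity, sequencing
ambiguity codes, and real mitochondrial gene architecture. Passing tests
therefore demonstrate the correctness of the algorithms on inputs matching
the model's assumptions, not field performance on any particular taxon pair;
for real work the input should be a curated alignment of the actual marker
sequences, and unresolved guides still require wet-lab validation.

## Numerical and degenerate-input choices

* Strict identity (not a fractional threshold) defines conservation;
  `identity_fraction` is exposed so a future fractional flank rule could be
  configured, but 1.0 is the default and the only mode used here.
* Empty projections (a species fully deleted over a region) are represented
  as zero-length intervals at the insertion point; such species contribute
  no template fragment and are skipped in BED export.
* Ties in every ranking are broken positionally (then by strand, species,
  region), so identical inputs produce byte-identical outputs; end-to-end
  determinism is asserted in the test suite.
* Degenerate inputs produce structured results, not crashes: an alignment
  with no variable regions yields a `"no-design"` report (CLI exit code 3),
  an empty region list writes valid empty tables with headers, and
  constraint-eliminated primer searches return an empty set plus a
  diagnostic naming the constraint that removed the last candidate.
* Test and simulation problem sizes (4-kb backbones for region-recovery
  properties, 1.2–2-kb panels for primer and end-to-end properties, 100–200
  replicates per property) were chosen as the smallest sizes at which every
  structural feature — multiple regions, indels, both strands, 2–4 species —
  is exercised with comfortable margins.

## Known limitations

* Specificity is defined within the supplied panel only; there is no
  genome-wide off-target search. A guide specific within a two-species panel
  may still cross-react with an unconsidered relative — the panel should
  contain every species the assay could plausibly encounter.
* No on-target efficiency prediction: candidates that pass specificity may
  still differ several-fold in cleavage activity, which is why the ranked
  list retains alternates rather than a single answer.
* The unresolved verdict is intentionally conservative; panels of very
  closely related species may yield few or no `specific` guides, which is a
  property of the biology, not a failure of the search.
* IUPAC ambiguity in inputs is treated as always-mismatching, which can
  understate cross-reactivity risk if the ambiguity masks a true match in a
  non-target species; curated unambiguous references are preferable.
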