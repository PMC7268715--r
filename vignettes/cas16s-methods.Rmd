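---
title: "Designing host-depleting Cas9 guides for 16S amplicon sequencing"
author: "cas16s"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing host-depleting Cas9 guides for 16S amplicon sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cas16s)
```

## The problem

Broad-range universal primers used for 16S rRNA gene amplicon sequencing
(16S-seq) anneal in regions conserved across prokaryotes — and therefore
also amplify the 16S rRNA genes of plant mitochondria and plastids, which
descend from prokaryotic ancestors. In plant samples the organelle
amplicons can dominate the library almost completely (the phyllosphere is
the extreme case), drowning out the bacterial community the experiment is
meant to measure.

One remedy is enzymatic: between the two PCR steps of standard library
construction, digest the first-round amplicons with Cas9 loaded with a
guide RNA (gRNA) that matches the *host* organelle 16S sequence. Cleaved
host molecules lack intact priming sites and drop out of the index PCR, so
bacterial templates dominate the final library. The whole approach stands
or falls on the guide: it must sit inside the sequenced amplicon, cleave
the host gene efficiently, and — critically — cleave *no* bacterial 16S
gene, since Cas9 tolerates imperfect matches.

`cas16s` implements the computational side of this design problem:

1. enumerate every Cas9-targetable site on the host organelle 16S genes;
2. screen each candidate guide against a prokaryotic 16S reference set
   under relaxed (off-target-permissive) recognition rules and rank guides
   by their off-target counts;
3. intersect guides with the amplicon produced by a chosen universal
   primer pair (in-silico PCR);
4. predict the compositional effect of digestion on an amplicon community.

## Guide enumeration

Cas9 cleaves double-stranded DNA at sites of the form 5'-N20-NGG-3': a
20-bp protospacer followed by the NGG protospacer-adjacent motif (PAM).
`enumerate_guides()` reports every such window on both strands of the host
gene — the amplicon is double-stranded, so both orientations are cleavable
— with 0-based half-open plus-strand coordinates and the protospacer
written 5'→3' with the PAM-proximal base last. Overlapping sites are all
reported. Windows containing an ambiguous base in the protospacer, or at
one of the fixed (non-N) PAM positions, are skipped rather than expanded:
a guide must be synthesizable as one unambiguous oligo, and a degenerate
template base cannot be *confirmed* as a PAM.

Guide ids are positional: `<prefix><p>` where `p` is the 1-based
plus-strand coordinate of the PAM-proximal protospacer base. This follows
the field's convention of naming guides by position (e.g. an "mt-gRNA"
prefix for mitochondrial guides); the exact coordinate convention varies
between tools, so ours is fixed, documented, and configurable via
`id_prefix`. We do not claim to reproduce any other tool's labels. On the
rare collision (a plus- and a minus-strand guide mapping to the same
coordinate) a strand tag is appended so ids stay unique.

## Off-target screening

The screening model asks: which sequences in a prokaryotic 16S reference
set carry a site that Cas9 loaded with this guide might still cleave?
Because Cas9 tolerates mismatches — more so outside the ~12-bp
PAM-proximal *seed* region — and also weakly recognizes NAG PAMs, the
screen is deliberately permissive:

* **Candidate sites** are all 20-mers immediately 5' of an NGG *or* NAG
  trinucleotide, on both strands of every reference sequence
  (`extract_candidate_sites()`).
* **Alignment** (`align_guide_candidate()`): guide and candidate are
  globally aligned under unit cost per mismatch, insertion or deletion
  (M/D/I counted equally — no affine gap model, since each event is one
  recognition defect). The PAM-proximal column is *anchored*: candidate
  extraction places the 20-mer flush against the PAM, so the PAM-adjacent
  guide base is compared positionally and must match (`anchored_match`);
  the remaining 19-vs-19 problem is a free global alignment. Anchoring
  implements the rule that no mismatch or gap is allowed at the guide base
  next to the PAM, and removes alignment ambiguity at that end.
* **Seed assignment**: a mismatch or deletion is charged to the guide
  position it consumes; an insertion (gap in the guide) is charged to the
  adjacent PAM-proximal guide position. `seed_edits` is minimized over all
  co-optimal alignments (a lexicographic dynamic program: first total
  edits, then seed edits). Minimizing means the "all edits outside the
  seed" rescue fires whenever *any* optimal alignment permits it — the
  conservative choice for a depletion tool, since it maximizes off-target
  sensitivity.
* **Classification** (`classify_offtarget()`): with edit ceiling `T` (4
  for NGG, 2 for NAG by default), a site is an off-target iff the anchor
  matches and `total_edits < T`, or `total_edits == T` with `seed_edits
  == 0`. We read "`T` edits outside the seed region" strictly: all `T`
  edits must fall outside the seed; a site at the ceiling with even one
  seed edit is rejected. NAG sites are subject to the same anchored-match
  rule as NGG sites.

The lexicographic DP encodes cell weights as `100*edits + seed_edits`,
exact because both components are bounded by twice the guide length (< 50);
the alignment core is C++ for throughput. In tests, total edit distance is
cross-checked against `utils::adist` and minimal seed edits against an
exhaustive enumeration of co-optimal alignment paths on short strings.

### Counting, exclusion and ranking

`count_offtargets()` counts, per guide, reference *sequences* carrying at
least one qualifying site (default) or total qualifying *sites*
(`unit = "sites"`). Whether published off-target totals count sequences or
sites is usually ambiguous; we default to sequences — the biologically
relevant unit for "how many taxa could this guide silence" — and expose the
switch. When counting sequences, a sequence with both NGG and NAG
qualifying sites is attributed to NGG, so the per-class counts always sum
to the total.

Reference records named in `exclude_ref_ids` are dropped before counting —
this is how host-organelle homologs present in the reference set (e.g.
chloroplast records, when scoring plastid guides) are kept from being
counted as "off-targets" — and any record whose id equals a guide's source
gene is skipped for that guide. Guides are ranked by ascending off-target
count with a deterministic tie-break on id; `passes_cutoff` compares the
count against an absolute cutoff (default 3300) or, via `cutoff_fraction`,
against a fraction (e.g. 0.001) of the post-exclusion reference size — at
reference scale of a few million 16S sequences these coincide.

### The prefilter

Screening every guide against every candidate site is quadratic, so a
prefilter discards hopeless sites cheaply. Rather than a heuristic
identity filter, we use a provably lossless bound: an alignment with at
most `e` edits leaves at most `e + 1` untouched guide segments totalling at
least `20 − e` bases, so some exact k-mer of length
`ceil((20 − e)/(e + 1))` (4, for `e = 4`) is preserved contiguously in any
qualifying site. A site sharing no such k-mer with the guide cannot
qualify and is skipped. The word length is capped at that bound whenever
the criteria change, so prefiltering is *bitwise-neutral* to results — a
contract the suite enforces by comparing prefiltered and exhaustive counts
on seeded random instances. `prefilter = FALSE` disables it outright.
Any site within the edit ceilings has pairwise identity at least 0.8,
comfortably above the 0.6 identity floor recorded in the criteria object.

Degenerate reference bases: candidate windows containing non-ACGT
characters are skipped. An ambiguous base cannot be confirmed as a match;
skipping is deterministic, and sites lost this way would have to be
verified against the actual sequence anyway.

## In-silico PCR and guide-amplicon compatibility

`find_primer_sites()` matches degenerate primers (IUPAC codes, set
intersection semantics) against templates allowing mismatches only — no
indels, since a bulged primer-template duplex rarely primes — with a
default tolerance of 0 (universal 16S primers match their organelle
targets perfectly; tolerance is exposed for coverage studies).
`simulate_amplicon()` pairs forward sites with downstream reverse sites
and reports primer-inclusive products (that is how amplicon lengths are
conventionally stated); all products from multiple site pairs are
reported, flagged when they overlap, rather than silently picking a
"primary" product. `guides_in_amplicon()` keeps guides whose protospacer
*and* PAM lie strictly within the product, on either strand: Cas9 needs
the full site present on the amplicon to cleave it.

This matters because primer pairs differ in which organelle genes they
amplify at all. In the rice system that motivates the package, the
799F-1193R pair amplifies the mitochondrial but not the plastid 16S gene,
so mitochondrial guides inside that product suffice; 515F-806R amplifies
both organelles and needs a mitochondrial and a plastid guide
simultaneously. The bundled primer configuration
(`inst/extdata/universal_primers.tsv`) contains the canonical published
universal 16S primer sequences; it is an editable example, and no primer
sequence is hardcoded in package code.

## The digestion model

`digest_community()` is an expected-value model: member `i` with
pre-digestion fraction `f_i` and cleavage efficiency `e_i` (the fraction
of its molecules cut) survives with mass `f_i (1 − e_i)`, renormalized
over the community. For a two-member community with host fraction `h`,
the post-digestion host fraction is exactly `h(1 − e)/(1 − he)` — the
closed form the tests verify to 1e-12, alongside a molecule-counting
oracle. Complete depletion (total survival 0) is an error, not a silent
NaN: it means the community had no uncleaved member, which in practice
signals a degenerate input (e.g. a 100% host mock digested at full
efficiency).

Determinism at the fraction level is a deliberate split: gel readouts and
per-sample host fractions are ensemble quantities, so the model computes
expectations, and sampling noise enters only through `sample_counts()`, a
seeded multinomial draw emulating a rarefied OTU count table. PCR
amplification bias, chimera formation and index-cycle effects are not
modelled.

## The synthetic data generator

Two generators produce all test fixtures in code:

* `generate_reference_db()` builds seeded random reference sets and embeds
  planted near-matches specified by `plant_spec()`: a guide, an exact set
  of edited positions (1 = PAM-adjacent), and a PAM class. Edits are
  substitutions; each is drawn to differ from the guide base, and the draw
  is rejected (deterministically under the seed) until the planted site's
  anchored alignment statistics equal the per-position counts — random
  substitutions can otherwise admit a cheaper indel interpretation, which
  would silently change what the fixture tests. A spec with an edit at
  position 1 and `expected_call = TRUE` is refused: the anchored rule
  makes such a call impossible.
* `synthetic_16s_templates()` builds three ~1.5-kb templates standing in
  for a host mitochondrial, a host plastid and a bacterial 16S gene:
  seeded random backgrounds with concrete instances of the universal
  primers planted at canonical 16S coordinates. The planted geometry
  encodes the study conditions of the rice host-depletion system —
  799F-1193R amplifies the mitochondrial but not the plastid template and
  its mitochondrial product is 84 bp longer than the bacterial one;
  27F-338R and 1114F-1392R amplify only the plastid template; 515F-806R
  amplifies both.

What the generators *emulate*: PAM/site density of random sequence,
controlled edit structure of near-matches, amplicon geometry, mock
community composition. What they do *not* emulate: the phylogenetic
correlation structure of real 16S databases (real references are highly
similar to each other and to organelle genes, so real off-target counts
are far higher than on random backgrounds), sequencing error, chimeras,
and real primer-site degeneracy variation. Passing tests therefore
demonstrate that the algorithms implement their definitions exactly — not
that any particular guide is safe against a real database. Screening
against a real reference release (RDP/SILVA-scale, millions of sequences,
with chloroplast records excluded when scoring plastid guides) remains the
user's production step, and validating selected guides experimentally is
recommended regardless.

## Defaults and problem sizes

| Parameter | Default | Meaning |
|---|---|---|
| `guide_len` | 20 | Cas9 protospacer length (nt) |
| `pam_pattern` | NGG | Cas9 PAM; NAG additionally screened as off-target |
| `seed_len` | 12 | seed region, guide positions from the PAM (bp) |
| `max_edits_ngg` | 4 | M/D/I ceiling for NGG off-target sites |
| `max_edits_nag` | 2 | M/D/I ceiling for NAG off-target sites |
| `rank_cutoff` | 3300 | specificity cutoff on off-target count |
| `prefilter_word` | 4 | exact k-mer word (capped to stay lossless) |
| `max_product_len` | 5000 | in-silico PCR product ceiling (bp) |
| `max_mismatch` | 0 | primer annealing mismatch tolerance |

The test and acceptance batteries use reference sets of 50–200 sequences
of 140–300 nt and 8–50 guides per instance, with 10–20 seeded instances
per property and 100 planted-fixture sets — sizes chosen so the whole
suite characterises every rule yet runs in minutes on one core. The
algorithms themselves stream references one at a time and scale linearly
in total reference length.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open throughout the tables (converted to
  1-based only inside `substring` calls), matching the interval
  convention of BED-style genomics tables.
* Sequences shorter than protospacer + PAM yield empty results, not
  errors; empty guide lists and empty references yield empty or all-zero
  reports.
* `U` is normalized to `T` on load (RNA-alphabet reference sets), case is
  folded to upper, and alignment gap characters in aligned reference
  distributions are stripped with a warning — all matching operates on
  unaligned DNA.
* Ties in specificity ranking break on guide id, making ranks a
  deterministic permutation.
* Seeded functions save and restore the caller's RNG state, so library
  calls never perturb a user's simulation stream.
* The workflow manifest records package version, configuration, input
  checksums and seed — but no timestamp, so identical runs are
  byte-identical.

## A worked example

```{r example}
st <- synthetic_16s_templates(seed = 20)
guides <- enumerate_guides(st$templates["mt16S_synthetic"],
                           id_prefix = "mt-gRNA")
nrow(guides)

amp <- simulate_amplicon(st$templates["mt16S_synthetic"],
                         get_primer(st$primers, "799F"),
                         get_primer(st$primers, "1193R"))
amp$length

compatible <- guides_in_amplicon(guides, amp)
nrow(compatible)

# screen against a small synthetic reference set with one planted
# near-match of the first compatible guide
sp <- plant_spec(compatible$protospacer[1], 2, c(14, 17), "NGG")
db <- generate_reference_db(30, 300, list(sp), seed = 99)
report <- count_offtargets(compatible, db$sequences)
head(report, 3)

# predicted effect of digesting a 99.9% host mock with a perfect guide
mock <- community_profile(c("host", "bact"), c(0.999, 0.001),
                          c(TRUE, FALSE))
digest_community(mock, c(host = 1))
```

## Known limitations

* Off-target risk is assessed purely by sequence rules; no empirical
  cleavage-activity model (position-weighted mismatch penalties, CFD-like
  scores) is applied, and on-target efficiency is not predicted — guides
  passing the screen still differ in cleavage efficiency and should be
  validated in vitro.
* The screen is reference-bounded: taxa absent from the reference set are
  invisible to it.
* In-silico PCR ignores annealing thermodynamics; a primer site found at
  the sequence level may still fail to prime efficiently.
* The digestion model is compositional and deterministic; it does not
  model absolute yields, PCR bias or chimera formation.
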